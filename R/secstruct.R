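#' Backbone hydrogen-bond energy (Kabsch–Sander electrostatic model)
#'
#' `E = 27.888 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol with
#' distances in Angstrom between the donor amide (N, H) and the acceptor
#' carbonyl (C, O). A bond is called when `E < -0.5` kcal/mol. Any
#' interatomic distance below 0.5 Angstrom returns `+Inf` (clash guard).
#'
#' @param n,h,c,o Length-3 positions in nm (donor N and H, acceptor C and O).
#' @return Energy in kcal/mol.
#' @export
hbond_energy <- function(n, h, c, o) {
  stopifnot(all(is.finite(c(n, h, c, o))))
  r_on <- vnorm(o - n) * ANGSTROM_PER_NM
  r_ch <- vnorm(c - h) * ANGSTROM_PER_NM
  r_oh <- vnorm(o - h) * ANGSTROM_PER_NM
  r_cn <- vnorm(c - n) * ANGSTROM_PER_NM
  if (min(r_on, r_ch, r_oh, r_cn) < 0.5) return(Inf)
  27.888 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}

HB_CUTOFF <- -0.5      # kcal/mol, Kabsch-Sander bond threshold
HB_CA_MAX <- 0.9       # nm, CA-CA prefilter as in DSSP
CHAIN_BREAK_NM <- 0.25 # C(i)-N(i+1) beyond this breaks the chain

# Per-residue backbone bookkeeping for one frame
backbone_table <- function(frame, topology) {
  res <- topology$residues
  n_res <- nrow(res)
  idx <- matrix(NA_integer_, n_res, 4,
                dimnames = list(NULL, c("N", "CA", "C", "O")))
  a <- topology$atoms
  for (nm in colnames(idx)) {
    rows <- which(a$name == nm)
    idx[match(a$residue[rows], res$residue), nm] <- rows
  }
  list(idx = idx, chain = res$chain, resid = res$resid, n = n_res)
}

#' Assign five-class secondary structure to one frame
#'
#' DSSP-style assignment from backbone hydrogen-bond patterns: i,i+4 turns
#' give ALPHA, i,i+3 turns THREE10, parallel/antiparallel bridge ladders
#' STRAND, hydrogen-bonded turns and bends TURN, everything else COIL
#' (five-class folding of the eight DSSP classes: H->ALPHA, G->THREE10,
#' E/B->STRAND, T/S->TURN, remainder including pi->COIL). The amide H is
#' reconstructed along the previous residue's C=O direction (1.0 Angstrom
#' from N), the same convention the reference DSSP implementations use, so
#' stored H coordinates never influence the assignment. Helical patterns are
#' confined within chains; inter-chain bridges (sheets) are detected.
#'
#' @param frame `n_atoms x 3` coordinate matrix in nm (see [frame_coords()]).
#' @param topology The matching `topology`.
#' @return Character vector, one of `"ALPHA"`, `"THREE10"`, `"STRAND"`,
#'   `"TURN"`, `"COIL"` per residue. Residues missing backbone atoms are
#'   forced `"COIL"` with a warning.
#' @export
assign_ss <- function(frame, topology) {
  bt <- backbone_table(frame, topology)
  n <- bt$n
  ok <- !apply(is.na(bt$idx), 1, any)
  if (!all(ok)) {
    warning("residue(s) missing backbone atoms forced to COIL: ",
            paste(which(!ok), collapse = ","))
  }
  pos <- function(col) {
    m <- matrix(NA_real_, n, 3)
    m[ok, ] <- frame[bt$idx[ok, col], , drop = FALSE]
    m
  }
  N <- pos("N"); CA <- pos("CA"); C <- pos("C"); O <- pos("O")

  # chain continuity: same chain id and peptide-bond distance plausible
  linked <- rep(FALSE, n) # linked[i]: residue i-1 -> i is continuous
  if (n > 1) {
    for (i in 2:n) {
      if (!ok[i] || !ok[i - 1] || bt$chain[i] != bt$chain[i - 1]) next
      linked[i] <- vnorm(N[i, ] - C[i - 1, ]) <= CHAIN_BREAK_NM
    }
  }

  # donor H (DSSP reconstruction); proline and chain starts have none
  H <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (!ok[i] || bt$resid[i] == "PRO" || !linked[i]) next
    H[i, ] <- N[i, ] + 0.1 * vhat(C[i - 1, ] - O[i - 1, ])
  }

  # donor -> acceptor energies, keeping each donor's two best acceptors
  E <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    if (any(is.na(H[i, ]))) next
    for (j in seq_len(n)) {
      if (i == j || !ok[j]) next
      if (vnorm(CA[i, ] - CA[j, ]) > HB_CA_MAX) next
      E[i, j] <- hbond_energy(N[i, ], H[i, ], C[j, ], O[j, ])
    }
  }
  HB <- matrix(FALSE, n, n) # HB[d, a]: N-H of d bonded to C=O of a
  for (i in seq_len(n)) {
    ord <- order(E[i, ])[1:2]
    keep <- ord[E[i, ord] < HB_CUTOFF]
    HB[i, keep] <- TRUE
  }
  # Kabsch-Sander orientation: hbond(i, j) = CO of i accepts from NH of j
  ks <- function(i, j) {
    if (i < 1 || j < 1 || i > n || j > n) return(FALSE)
    HB[j, i]
  }

  # n-turn start flags (residues i..i+stride must be chain-continuous)
  contiguous <- function(i, j) all(linked[(i + 1):j])
  turn_flag <- list()
  for (stride in 3:5) {
    fl <- rep(FALSE, n)
    for (i in seq_len(n - stride)) {
      if (contiguous(i, i + stride) && ks(i, i + stride)) fl[i] <- TRUE
    }
    turn_flag[[as.character(stride)]] <- fl
  }

  # bridges (i < j, parallel or antiparallel)
  bridges <- list()
  for (i in 2:(n - 1)) {
    if (!ok[i] || !linked[i] || !linked[i + 1]) next
    if (i + 3 > n - 1) next
    for (j in (i + 3):(n - 1)) {
      if (!ok[j] || !linked[j] || !linked[j + 1]) next
      p <- (ks(i - 1, j) && ks(j, i + 1)) || (ks(j - 1, i) && ks(i, j + 1))
      a <- (ks(i, j) && ks(j, i)) || (ks(i - 1, j + 1) && ks(j - 1, i + 1))
      if (p) bridges[[length(bridges) + 1]] <- c(i, j, 1L)
      if (a) bridges[[length(bridges) + 1]] <- c(i, j, 2L)
    }
  }

  ss <- rep("COIL", n)
  ss[strand_residues(bridges)] <- "STRAND"

  # alpha helix: 4-turn starts at i-1 and i cover residues i..i+3
  for (i in 2:max(2, n - 4)) {
    if (turn_flag[["4"]][i] && turn_flag[["4"]][i - 1]) {
      ss[i:(i + 3)] <- "ALPHA"
    }
  }
  # 3-10 helix: only claims residues still coil/three10
  for (i in 2:max(2, n - 3)) {
    if (turn_flag[["3"]][i] && turn_flag[["3"]][i - 1]) {
      span <- i:(i + 2)
      if (all(ss[span] %in% c("COIL", "THREE10"))) ss[span] <- "THREE10"
    }
  }
  # hydrogen-bonded turn: residues strictly inside any n-turn
  for (i in seq_len(n)) {
    if (ss[i] != "COIL") next
    for (stride in 3:5) {
      ts <- (i - stride + 1):(i - 1)
      ts <- ts[ts >= 1]
      if (any(turn_flag[[as.character(stride)]][ts])) {
        ss[i] <- "TURN"
        break
      }
    }
  }
  # bend: CA kink angle > 70 degrees
  for (i in 3:max(3, n - 2)) {
    if (ss[i] != "COIL") next
    if (!all(linked[(i - 1):(i + 2)])) next
    u <- CA[i, ] - CA[i - 2, ]; v <- CA[i + 2, ] - CA[i, ]
    kappa <- acos(max(-1, min(1, sum(u * v) / (vnorm(u) * vnorm(v))))) * 180 / pi
    if (kappa > 70) ss[i] <- "TURN"
  }
  ss[!ok] <- "COIL"
  ss
}

# Ladder bookkeeping: group bridges into ladders (consecutive extension),
# merge ladders across beta-bulges (DSSP rule: gaps of at most 1 on one
# strand and at most 4 on the other), and return every residue covered by
# the merged strand spans. Isolated bridges (B) and extended strands (E)
# both fold to STRAND in the five-class scheme.
strand_residues <- function(bridges) {
  if (length(bridges) == 0) return(integer(0))
  b <- do.call(rbind, bridges)
  b <- b[order(b[, 3], b[, 1], b[, 2]), , drop = FALSE]
  # ladders: runs of bridges of one type with i ascending by 1 and j
  # stepping +1 (parallel) or -1 (antiparallel)
  ladder_id <- seq_len(nrow(b))
  for (k in seq_len(nrow(b))) {
    for (m in seq_len(nrow(b))) {
      if (m == k || b[m, 3] != b[k, 3]) next
      dj <- if (b[k, 3] == 1L) 1L else -1L
      if (b[m, 1] == b[k, 1] + 1L && b[m, 2] == b[k, 2] + dj) {
        ladder_id[ladder_id == ladder_id[m]] <- ladder_id[k]
      }
    }
  }
  ids <- unique(ladder_id)
  ladders <- lapply(ids, function(id) {
    rows <- b[ladder_id == id, , drop = FALSE]
    list(type = rows[1, 3],
         i = range(rows[, 1]), j = range(rows[, 2]))
  })
  # bulge merging
  grp <- seq_along(ladders)
  if (length(ladders) > 1) {
    for (k in seq_along(ladders)) {
      for (m in seq_along(ladders)) {
        if (m == k) next
        a <- ladders[[k]]; d <- ladders[[m]]
        if (a$type != d$type) next
        di <- d$i[1] - a$i[2]
        dj <- if (a$type == 1L) d$j[1] - a$j[2] else a$j[1] - d$j[2]
        if (di >= 1 && ((di < 6 && dj < 3 && dj >= -2) ||
                        (di < 3 && dj < 6 && dj >= -2))) {
          grp[grp == grp[m]] <- grp[k]
        }
      }
    }
  }
  out <- integer(0)
  for (id in unique(grp)) {
    ls <- ladders[grp == id]
    irange <- range(unlist(lapply(ls, `[[`, "i")))
    jrange <- range(unlist(lapply(ls, `[[`, "j")))
    out <- c(out, irange[1]:irange[2], jrange[1]:jrange[2])
  }
  sort(unique(out))
}

SS_CLASSES <- c("ALPHA", "THREE10", "STRAND", "TURN", "COIL")

#' Per-frame secondary-structure labels for an ensemble
#'
#' @param x An `ensemble`.
#' @return Character matrix `n_frames x n_residues`.
#' @export
assign_ss_ensemble <- function(x) {
  nf <- n_frames(x)
  out <- matrix(NA_character_, nf, n_residues(x$topology))
  for (k in seq_len(nf)) out[k, ] <- assign_ss(frame_coords(x, k), x$topology)
  out
}

#' Residue-wise secondary-structure propensity profile
#'
#' Mean percentage of frames in each of the five classes per residue, with
#' block standard errors from `n_blocks` contiguous equal-length frame
#' segments (SE = sample sd of block means / sqrt(n_blocks)).
#'
#' @param x An `ensemble`, or a precomputed label matrix from
#'   [assign_ss_ensemble()] via `labels =`.
#' @param n_blocks Number of error blocks (>= 2); the frame count must
#'   divide evenly into the blocks.
#' @param labels Optional precomputed `n_frames x n_residues` label matrix.
#' @return Tibble (class `ss_profile`): residue, resno, chain, class,
#'   mean_pct, se_pct. Class percentages sum to 100 per residue.
#' @export
ss_propensity <- function(x, n_blocks = 4, labels = NULL) {
  if (is.null(labels)) labels <- assign_ss_ensemble(x)
  nf <- nrow(labels)
  stopifnot(nf >= 1, n_blocks >= 2, n_blocks <= nf)
  if (nf %% n_blocks != 0) {
    stop(sprintf("frame count %d does not split into %d equal blocks (remainder %d)",
                 nf, n_blocks, nf %% n_blocks))
  }
  res <- x$topology$residues
  block <- rep(seq_len(n_blocks), each = nf / n_blocks)
  rows <- list()
  for (r in seq_len(ncol(labels))) {
    for (cl in SS_CLASSES) {
      ind <- as.numeric(labels[, r] == cl) * 100
      bm <- tapply(ind, block, mean)
      rows[[length(rows) + 1]] <- tibble::tibble(
        residue = res$residue[r], resno = res$resno[r], chain = res$chain[r],
        class = cl, mean_pct = mean(ind),
        se_pct = stats::sd(bm) / sqrt(n_blocks)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ss_profile", class(out))
  out
}

#' Bound-minus-free secondary-structure difference profile
#'
#' @param profile_bound,profile_free [ss_propensity()] results over the same
#'   residues and classes.
#' @return Tibble: residue, resno, chain, class, delta_pct (bound minus
#'   free; positive means more frequent in the bound ensemble), se_pct
#'   (quadrature-combined block SEs).
#' @export
ss_difference <- function(profile_bound, profile_free) {
  key <- c("residue", "class")
  if (!identical(sort(unique(profile_bound$residue)),
                 sort(unique(profile_free$residue)))) {
    stop("residue sets differ between profiles")
  }
  j <- dplyr::inner_join(
    profile_bound, profile_free, by = key, suffix = c("_b", "_f")
  )
  if (nrow(j) != nrow(profile_bound)) stop("profiles do not align")
  out <- tibble::tibble(
    residue = j$residue, resno = j$resno_b, chain = j$chain_b, class = j$class,
    delta_pct = j$mean_pct_b - j$mean_pct_f,
    se_pct = sqrt(j$se_pct_b^2 + j$se_pct_f^2)
  )
  class(out) <- c("ss_difference", class(out))
  out
}

#' Compact per-frame label strings
#'
#' One character per residue (`H`, `G`, `E`, `T`, `C`), one string per frame.
#' @param labels Matrix from [assign_ss_ensemble()].
#' @export
ss_strings <- function(labels) {
  code <- c(ALPHA = "H", THREE10 = "G", STRAND = "E", TURN = "T", COIL = "C")
  apply(labels, 1, function(row) paste(code[row], collapse = ""))
}
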