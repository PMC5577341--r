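#' Block means of a numeric series
#' @keywords internal
#' @noRd
block_means <- function(values, n_blocks, strict = FALSE) {
  nf <- length(values)
  stopifnot(n_blocks >= 2)
  if (strict && nf %% n_blocks != 0) {
    stop(sprintf("length %d does not split into %d equal blocks (remainder %d)",
                 nf, n_blocks, nf %% n_blocks))
  }
  len <- nf %/% n_blocks
  if (len < 1) stop("fewer values than blocks")
  vapply(seq_len(n_blocks), function(b) {
    mean(values[((b - 1) * len + 1):(b * len)])
  }, numeric(1))
}

#' Residue–residue contact probability map
#'
#' A residue pair is in contact in a frame when the Calpha–Calpha distance
#' (`mode = "ca"`) or the minimum heavy-atom distance (`mode = "heavy"`) is
#' below `cutoff`. Probabilities are frame fractions; intra-molecular maps
#' (`sel_a` identical to `sel_b`) zero out sequence-local pairs with
#' `|i - j| < min_seq_sep`. Block standard errors come from contiguous
#' equal-length frame blocks.
#'
#' @param x An `ensemble`.
#' @param sel_a,sel_b Global residue-index vectors for the two axes.
#' @param mode `"ca"` or `"heavy"`.
#' @param cutoff Contact cutoff in nm (> 0); defaults 0.65 nm for `"ca"`,
#'   0.4 nm for `"heavy"`.
#' @param min_seq_sep Minimum |i - j| for intra-molecular contacts
#'   (default 3, i.e. non-sequential contacts only).
#' @param n_blocks Blocks for the SE estimate.
#' @return Object of class `contact_map`: list with `prob` and `se`
#'   matrices (rows `sel_a`, columns `sel_b`), plus the settings.
#' @export
contact_map <- function(x, sel_a, sel_b, mode = c("ca", "heavy"),
                        cutoff = NULL, min_seq_sep = 3, n_blocks = 4) {
  mode <- match.arg(mode)
  if (is.null(cutoff)) cutoff <- if (mode == "ca") 0.65 else 0.40
  if (cutoff <= 0) stop("cutoff must be positive")
  intra <- identical(sort(sel_a), sort(sel_b))
  nf <- n_frames(x)
  na <- length(sel_a); nb <- length(sel_b)
  ind <- array(0, c(na, nb, nf))
  for (k in seq_len(nf)) {
    D <- residue_distance_matrix(frame_coords(x, k), x$topology, sel_a, sel_b, mode)
    ind[, , k] <- (D < cutoff) * 1
  }
  if (intra) {
    sep <- abs(outer(sel_a, sel_b, "-"))
    mask <- sep < min_seq_sep
    for (k in seq_len(nf)) ind[, , k][mask] <- 0
  }
  prob <- apply(ind, c(1, 2), mean)
  se <- matrix(0, na, nb)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      bm <- block_means(ind[i, j, ], n_blocks, strict = TRUE)
      se[i, j] <- stats::sd(bm) / sqrt(n_blocks)
    }
  }
  dimnames(prob) <- dimnames(se) <- list(sel_a, sel_b)
  structure(
    list(prob = prob, se = se, sel_a = sel_a, sel_b = sel_b, mode = mode,
         cutoff = cutoff, min_seq_sep = if (intra) min_seq_sep else 0L,
         intra = intra, n_frames = nf),
    class = "contact_map"
  )
}

# residue-pair distances for one frame: CA-CA or min heavy-heavy
residue_distance_matrix <- function(frame, topology, sel_a, sel_b, mode) {
  if (mode == "ca") {
    ia <- atom_select(topology, name = "CA", residue = sel_a)
    ib <- atom_select(topology, name = "CA", residue = sel_b)
    ia <- ia[order(match(topology$atoms$residue[ia], sel_a))]
    ib <- ib[order(match(topology$atoms$residue[ib], sel_b))]
    pa <- frame[ia, , drop = FALSE]; pb <- frame[ib, , drop = FALSE]
    d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * tcrossprod(pa, pb)
    sqrt(pmax(d2, 0))
  } else {
    D <- matrix(Inf, length(sel_a), length(sel_b))
    atoms_of <- lapply(seq_len(n_residues(topology)), function(r) {
      atom_select(topology, residue = r, heavy = TRUE)
    })
    for (i in seq_along(sel_a)) {
      pa <- frame[atoms_of[[sel_a[i]]], , drop = FALSE]
      for (j in seq_along(sel_b)) {
        pb <- frame[atoms_of[[sel_b[j]]], , drop = FALSE]
        d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * tcrossprod(pa, pb)
        D[i, j] <- sqrt(max(0, min(d2)))
      }
    }
    D
  }
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map [%s, cutoff %.2f nm]: %d x %d residues over %d frames\n",
              x$mode, x$cutoff, length(x$sel_a), length(x$sel_b), x$n_frames))
  invisible(x)
}

#' Thresholded contact-probability difference map
#'
#' Bound minus free; entries with `|delta| <= threshold` are masked to zero
#' (only differences exceeding the threshold are considered meaningful).
#'
#' @param map_bound,map_free [contact_map()] results with identical shape,
#'   mode and cutoff.
#' @param threshold Mask threshold on the absolute probability difference
#'   (default 0.06).
#' @return Object of class `difference_map` with `delta` (masked), the raw
#'   `delta_raw`, and the threshold.
#' @export
contact_difference <- function(map_bound, map_free, threshold = 0.06) {
  if (!identical(dim(map_bound$prob), dim(map_free$prob)) ||
      map_bound$mode != map_free$mode) {
    stop("contact maps differ in shape or mode")
  }
  delta <- map_bound$prob - map_free$prob
  masked <- delta
  masked[abs(masked) <= threshold] <- 0
  structure(
    list(delta = masked, delta_raw = delta, threshold = threshold,
         sel_a = map_bound$sel_a, sel_b = map_bound$sel_b,
         mode = map_bound$mode),
    class = "difference_map"
  )
}

#' Mean interchain heavy-atom contacts per residue
#'
#' For each residue of `chain_b` (the hexapeptide axis), the mean over
#' frames of the number of heavy-atom pairs it forms with any atom of
#' `chain_a` at distance below `cutoff`, with block SEs.
#'
#' @param x An `ensemble` whose topology has both chains.
#' @param chain_a,chain_b Distinct chain ids (counts reported per residue of
#'   `chain_b`).
#' @param cutoff Heavy-atom cutoff in nm (default 0.4).
#' @param n_blocks Blocks for SEs.
#' @return Tibble: residue, resno, resid, mean_contacts, se.
#' @export
per_residue_contact_count <- function(x, chain_a, chain_b, cutoff = 0.4,
                                      n_blocks = 4) {
  if (identical(chain_a, chain_b)) stop("chains must be distinct")
  top <- x$topology
  res_b <- top$residues[top$residues$chain == chain_b, ]
  ia <- atom_select(top, chain = chain_a, heavy = TRUE)
  nf <- n_frames(x)
  counts <- matrix(0, nf, nrow(res_b))
  for (k in seq_len(nf)) {
    fr <- frame_coords(x, k)
    pa <- fr[ia, , drop = FALSE]
    for (j in seq_len(nrow(res_b))) {
      ib <- atom_select(top, chain = chain_b, residue = res_b$residue[j],
                        heavy = TRUE)
      pb <- fr[ib, , drop = FALSE]
      d2 <- outer(rowSums(pb^2), rowSums(pa^2), "+") - 2 * tcrossprod(pb, pa)
      counts[k, j] <- sum(d2 < cutoff^2)
    }
  }
  se <- if (nf >= n_blocks) {
    vapply(seq_len(ncol(counts)), function(j) {
      stats::sd(block_means(counts[, j], n_blocks)) / sqrt(n_blocks)
    }, numeric(1))
  } else {
    rep(NA_real_, ncol(counts)) # too few frames for a block estimate
  }
  tibble::tibble(
    residue = res_b$residue, resno = res_b$resno, resid = res_b$resid,
    mean_contacts = colMeans(counts), se = se
  )
}

# side-chain functional-group atoms for salt bridges
ACIDIC_O <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
BASIC_N <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"))

#' Salt-bridge frequency between an acidic and a basic residue
#'
#' A frame is bridged when the minimum distance between the acidic
#' side-chain carboxylate oxygens and the basic side-chain nitrogens is
#' below `cutoff` (N–O minimum-distance definition, default 0.4 nm). The
#' classic stabilizer monitored here is D23–K28 of the 42-mer.
#'
#' @param x An `ensemble`.
#' @param acidic_res,basic_res Global residue indices (ASP/GLU and
#'   LYS/ARG/HIS respectively).
#' @param cutoff nm.
#' @param n_blocks Blocks for the SE.
#' @return One-row tibble: frequency_pct, se_pct, n_frames.
#' @export
salt_bridge_frequency <- function(x, acidic_res, basic_res, cutoff = 0.4,
                                  n_blocks = 4) {
  top <- x$topology
  rid_a <- top$residues$resid[top$residues$residue == acidic_res]
  rid_b <- top$residues$resid[top$residues$residue == basic_res]
  if (!rid_a %in% names(ACIDIC_O)) {
    stop("residue ", acidic_res, " (", rid_a, ") has no carboxylate oxygens")
  }
  if (!rid_b %in% names(BASIC_N)) {
    stop("residue ", basic_res, " (", rid_b, ") has no basic side-chain nitrogens")
  }
  io <- atom_select(top, name = ACIDIC_O[[rid_a]], residue = acidic_res)
  inn <- atom_select(top, name = BASIC_N[[rid_b]], residue = basic_res)
  nf <- n_frames(x)
  bridged <- vapply(seq_len(nf), function(k) {
    fr <- frame_coords(x, k)
    po <- fr[io, , drop = FALSE]; pn <- fr[inn, , drop = FALSE]
    d2 <- outer(rowSums(po^2), rowSums(pn^2), "+") - 2 * tcrossprod(po, pn)
    as.numeric(min(d2) < cutoff^2)
  }, numeric(1))
  bm <- block_means(bridged, n_blocks)
  tibble::tibble(
    frequency_pct = 100 * mean(bridged),
    se_pct = 100 * stats::sd(bm) / sqrt(n_blocks),
    n_frames = nf
  )
}

#' Reaction coordinates of the hairpin landscape
#'
#' Two normalized collective variables per frame: `nbeta`, the fraction of
#' CHC and CTR residues assigned STRAND (out of the 18 residues in the two
#' regions), and `ncontact`, the number of CHC–CTR Calpha contacts at
#' `ca_cutoff` divided by `norm_pairs` and clipped to `[0, 1]`.
#'
#' @param ss_labels Character vector of per-residue labels for the frame
#'   ([assign_ss()]), aligned with the topology's residues.
#' @param frame `n_atoms x 3` matrix (nm).
#' @param topology The matching `topology` (42-mer as chain of interest).
#' @param scheme A [region_scheme()].
#' @param ca_cutoff Calpha contact cutoff in nm (default 0.65).
#' @param norm_pairs Normalization constant for the contact count (default
#'   65, the 5 x 13 theoretical maximum of CHC x CTR pairs).
#' @param chain Chain holding the 42-mer (default first chain).
#' @return Named numeric vector `c(nbeta =, ncontact =)`.
#' @export
reaction_coordinates <- function(ss_labels, frame, topology, scheme = region_scheme(),
                                 ca_cutoff = 0.65, norm_pairs = 65,
                                 chain = NULL) {
  chain <- chain %||% topology$chains[1]
  res <- topology$residues
  chain_res <- res$residue[res$chain == chain]
  chc <- chain_res[region_residues(scheme, "CHC")]
  ctr <- chain_res[region_residues(scheme, "CTR")]
  both <- c(chc, ctr)
  nbeta <- sum(ss_labels[both] == "STRAND") / length(both)
  D <- residue_distance_matrix(frame, topology, chc, ctr, "ca")
  ncontact <- min(1, sum(D < ca_cutoff) / norm_pairs)
  c(nbeta = nbeta, ncontact = ncontact)
}

#' Reaction-coordinate series for an ensemble
#'
#' @param x An `ensemble`.
#' @param labels Optional precomputed label matrix ([assign_ss_ensemble()]).
#' @inheritParams reaction_coordinates
#' @return Tibble (class `rc_series`): frame, time, replica, nbeta,
#'   ncontact.
#' @export
rc_series <- function(x, labels = NULL, scheme = region_scheme(),
                      ca_cutoff = 0.65, norm_pairs = 65, chain = NULL) {
  if (is.null(labels)) labels <- assign_ss_ensemble(x)
  nf <- n_frames(x)
  vals <- t(vapply(seq_len(nf), function(k) {
    reaction_coordinates(labels[k, ], frame_coords(x, k), x$topology, scheme,
                         ca_cutoff, norm_pairs, chain)
  }, numeric(2)))
  out <- tibble::tibble(
    frame = x$frames$frame, time = x$frames$time, replica = x$frames$replica,
    nbeta = vals[, "nbeta"], ncontact = vals[, "ncontact"]
  )
  stopifnot(all(out$nbeta >= 0 & out$nbeta <= 1),
            all(out$ncontact >= 0 & out$ncontact <= 1))
  class(out) <- c("rc_series", class(out))
  out
}

#' Tidy a contact map into long format
#' @param x A `contact_map`.
#' @param ... Unused.
#' @return Tibble: res_a, res_b, prob, se.
#' @method tidy contact_map
#' @export
tidy.contact_map <- function(x, ...) {
  g <- expand.grid(a = seq_along(x$sel_a), b = seq_along(x$sel_b))
  tibble::tibble(
    res_a = x$sel_a[g$a], res_b = x$sel_b[g$b],
    prob = x$prob[cbind(g$a, g$b)], se = x$se[cbind(g$a, g$b)]
  )
}

#' @rdname tidy.contact_map
#' @method tidy difference_map
#' @export
tidy.difference_map <- function(x, ...) {
  g <- expand.grid(a = seq_along(x$sel_a), b = seq_along(x$sel_b))
  tibble::tibble(
    res_a = x$sel_a[g$a], res_b = x$sel_b[g$b],
    delta = x$delta[cbind(g$a, g$b)], delta_raw = x$delta_raw[cbind(g$a, g$b)]
  )
}
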