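# Shared fixtures and independent oracles, all built in code at test time.

five_code <- c(ALPHA = "H", THREE10 = "G", STRAND = "E", TURN = "T", COIL = "C")

# ideal helix ensemble
helix_frame <- function(n_res = 12, aa = "A") {
  top <- build_topology(strrep(aa, n_res))
  d <- class_dihedrals(rep("helix", n_res))
  list(top = top, coords = build_peptide_coords(top, d$phi, d$psi))
}

# calibrated CHC-CTR hairpin frame of the 42-mer
hairpin_frame <- function(seed = NULL) {
  spec <- state_mixture_spec(
    list(mixture_state("hp", 1, hairpin_p = 1, noise_sd = 0)),
    n_frames = 1, seed = seed %||% 1
  )
  res <- sample_mixture_ensemble(spec)
  list(top = res$ensemble$topology, coords = frame_coords(res$ensemble, 1),
       result = res)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# small mixture ensemble for map/series tests
small_mixture <- function(n_frames = 40, seed = 7, hairpin_p = 0.5) {
  spec <- state_mixture_spec(list(
    mixture_state("hp", hairpin_p, hairpin_p = 1, salt_bridge_p = 0.5),
    mixture_state("open", 1 - hairpin_p, helix_regions = 3:10,
                  salt_bridge_p = 0.5)
  ), n_frames = n_frames, seed = seed)
  sample_mixture_ensemble(spec)
}

# random rigid transform
random_rigid <- function(coords, seed = 1) {
  set.seed(seed)
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  sweep(coords %*% t(R), 2, stats::rnorm(3), "+")
}

# independent quaternion (Horn) superposition RMSD oracle
quaternion_rmsd <- function(a, b) {
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  M <- crossprod(bc, ac)
  S <- matrix(0, 4, 4)
  S[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  S[1, 2] <- S[2, 1] <- M[2, 3] - M[3, 2]
  S[1, 3] <- S[3, 1] <- M[3, 1] - M[1, 3]
  S[1, 4] <- S[4, 1] <- M[1, 2] - M[2, 1]
  S[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  S[2, 3] <- S[3, 2] <- M[1, 2] + M[2, 1]
  S[2, 4] <- S[4, 2] <- M[3, 1] + M[1, 3]
  S[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  S[3, 4] <- S[4, 3] <- M[2, 3] + M[3, 2]
  S[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  lam <- max(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(ac^2) + sum(bc^2) - 2 * lam) / nrow(a)
  sqrt(max(0, msd))
}

# brute-force residue contact probabilities (plain loops)
oracle_contact_map <- function(x, sel_a, sel_b, mode, cutoff, min_seq_sep) {
  top <- x$topology
  intra <- identical(sort(sel_a), sort(sel_b))
  prob <- matrix(0, length(sel_a), length(sel_b))
  for (k in seq_len(n_frames(x))) {
    fr <- frame_coords(x, k)
    for (i in seq_along(sel_a)) {
      for (j in seq_along(sel_b)) {
        if (intra && abs(sel_a[i] - sel_b[j]) < min_seq_sep) next
        if (mode == "ca") {
          pi_ <- fr[atom_select(top, name = "CA", residue = sel_a[i]), ]
          pj <- fr[atom_select(top, name = "CA", residue = sel_b[j]), ]
          d <- sqrt(sum((pi_ - pj)^2))
        } else {
          ai <- atom_select(top, residue = sel_a[i], heavy = TRUE)
          aj <- atom_select(top, residue = sel_b[j], heavy = TRUE)
          d <- Inf
          for (p in ai) for (q in aj) {
            d <- min(d, sqrt(sum((fr[p, ] - fr[q, ])^2)))
          }
        }
        if (d < cutoff) prob[i, j] <- prob[i, j] + 1
      }
    }
  }
  prob / n_frames(x)
}

# brute-force gromos clustering (re-implemented independently)
oracle_gromos <- function(m, cutoff) {
  n <- nrow(m)
  left <- seq_len(n)
  clusters <- list()
  while (length(left) > 0) {
    counts <- sapply(left, function(i) sum(m[i, left] < cutoff) - 1L)
    center <- left[which(counts == max(counts))[1]]
    members <- left[m[center, left] < cutoff]
    members <- sort(unique(c(center, members)))
    clusters[[length(clusters) + 1]] <- list(center = center, members = members)
    left <- setdiff(left, members)
  }
  sizes <- sapply(clusters, function(cl) length(cl$members))
  ord <- order(-sizes, sapply(clusters, function(cl) min(cl$members)))
  clusters[ord]
}

# reference DSSP (mdtraj) on a multi-model PDB; returns a character matrix
# of five-class labels (n_frames x n_residues)
dssp_reference <- function(ens) {
  pdb <- tempfile(fileext = ".pdb")
  write_ensemble(ens, pdb, "pdb")
  script <- paste0(
    "import mdtraj as md\n",
    "t = md.load('", pdb, "')\n",
    "d = md.compute_dssp(t, simplified=False)\n",
    "print('\\n'.join(''.join(r) for r in d))\n"
  )
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  lines <- out[nchar(out) > 0]
  m <- do.call(rbind, lapply(lines, function(l) strsplit(l, "")[[1]]))
  # fold the 8-class codes to the five classes (pi and blank to COIL)
  key <- c(H = "ALPHA", G = "THREE10", E = "STRAND", B = "STRAND",
           T = "TURN", S = "TURN", I = "COIL", ` ` = "COIL", C = "COIL")
  matrix(key[m], nrow(m), ncol(m))
}
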