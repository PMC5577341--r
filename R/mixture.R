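# Calibrated backbone dihedrals (degrees) for the CHC-CTR beta-hairpin
# template: residues 17-21 and 30-34 in ideal strand geometry, the 22-29
# turn frozen at values optimised once so that the Kabsch-Sander
# antiparallel bridge hydrogen bonds form at registry pairs
# (17,34), (19,32), (21,30).
HAIRPIN_TURN_PHI <- c(207.568664, -170.365799, 74.172780, -21.778377,
                      -203.891030, -41.888796, 19.247400, 66.971701)
HAIRPIN_TURN_PSI <- c(166.715871, 13.051257, 176.408509, 92.921550,
                      -108.384953, 59.957044, -29.448851, 153.709574)
HAIRPIN_PSI21 <- 119.962480
HAIRPIN_PHI30 <- -194.096856

#' Specify one state of a planted conformational mixture
#'
#' A state is a recipe for generating frames: a target population fraction,
#' per-region secondary-structure instructions, a CHC-CTR contact (hairpin)
#' probability, an optional D23-K28 salt-bridge probability, and Gaussian
#' coordinate noise.
#'
#' @param label State name.
#' @param fraction Target population fraction.
#' @param hairpin_p Probability that a frame of this state carries the
#'   CHC-CTR beta-hairpin (paired strands at residues 17-21/30-34 with
#'   Calpha contacts); non-hairpin frames are built from the per-residue
#'   `helix_regions` / coil instructions.
#' @param helix_regions Residue indices built with helical dihedrals in
#'   non-hairpin frames (e.g. `3:12`).
#' @param salt_bridge_p Probability that D23-K28 is bridged in a frame
#'   (side-chain N-O below 0.35 nm); otherwise the lysine amine is placed
#'   away (> 0.6 nm).
#' @param noise_sd Per-coordinate Gaussian noise, nm (default 0.002).
#' @return A `mixture_state`.
#' @export
mixture_state <- function(label, fraction, hairpin_p = 0, helix_regions = integer(0),
                          salt_bridge_p = 0, noise_sd = 0.002) {
  stopifnot(fraction >= 0, hairpin_p >= 0, hairpin_p <= 1,
            salt_bridge_p >= 0, salt_bridge_p <= 1, noise_sd >= 0)
  structure(list(label = label, fraction = fraction, hairpin_p = hairpin_p,
                 helix_regions = helix_regions, salt_bridge_p = salt_bridge_p,
                 noise_sd = noise_sd),
            class = "mixture_state")
}

#' Full mixture specification
#'
#' @param states List of [mixture_state()]s whose fractions sum to 1
#'   (within 1e-9).
#' @param n_frames Total frames to generate (> 0).
#' @param seed Integer seed.
#' @return A `state_mixture_spec`.
#' @export
state_mixture_spec <- function(states, n_frames, seed = 1) {
  stopifnot(length(states) >= 1, n_frames > 0)
  fr <- vapply(states, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-9) {
    stop(sprintf("state fractions sum to %.12f, not 1", sum(fr)))
  }
  structure(list(states = states, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "state_mixture_spec")
}

#' Generate an ensemble with planted state populations
#'
#' Each frame draws a state by its target fraction, then builds full-atom
#' 42-mer coordinates: hairpin frames chain the calibrated CHC-CTR
#' beta-hairpin template (ideal strand dihedrals at 17-21 and 30-34, frozen
#' turn at 22-29, coil tails redrawn per frame); non-hairpin frames chain
#' helix/coil dihedrals per the state's instructions. The D23-K28 salt
#' bridge is planted per frame by positioning the K28 side-chain amine, and
#' Gaussian coordinate noise is added last. Times advance 1 ps per frame on
#' a single pseudo-replica.
#'
#' Alongside the ensemble the generator returns its ground truth for
#' recovery tests: the per-frame state labels, the planted per-frame
#' hairpin/salt-bridge indicators, and per-state reference secondary
#' structure (the assignment of each state's noise-free hairpin and
#' non-hairpin templates).
#'
#' @param spec A [state_mixture_spec()].
#' @param topology Optional `topology`; defaults to the 42-mer alone. A
#'   two-chain complex topology adds a hexapeptide placed near the NTR.
#' @return List: `ensemble`, `truth` (tibble: frame, state, hairpin,
#'   salt_bridge), `templates` (per state, list with `hairpin_ss` and
#'   `open_ss` reference label vectors).
#' @export
sample_mixture_ensemble <- function(spec, topology = NULL) {
  stopifnot(inherits(spec, "state_mixture_spec"))
  if (is.null(topology)) topology <- build_topology(sequence_library()$ab42)
  set.seed(spec$seed)
  n <- spec$n_frames
  n_states <- length(spec$states)
  fracs <- vapply(spec$states, `[[`, numeric(1), "fraction")
  draw <- sample.int(n_states, n, replace = TRUE, prob = fracs)

  two_chain <- length(topology$chains) > 1
  chain_a_res <- topology$residues$residue[topology$residues$chain == topology$chains[1]]
  if (length(chain_a_res) != 42) {
    stop("mixture generator requires a 42-residue first chain")
  }
  templates <- lapply(spec$states, function(st) {
    list(hairpin_ss = NULL, open_ss = NULL)
  })
  names(templates) <- vapply(spec$states, `[[`, character(1), "label")

  nat <- n_atoms(topology)
  coords <- array(NA_real_, c(nat, 3, n))
  hairpin <- logical(n); bridge <- logical(n)
  for (k in seq_len(n)) {
    st <- spec$states[[draw[k]]]
    hairpin[k] <- stats::runif(1) < st$hairpin_p
    bridge[k] <- stats::runif(1) < st$salt_bridge_p
    co <- mixture_frame(topology, st, hairpin[k], bridge[k], two_chain)
    if (st$noise_sd > 0) {
      co <- co + matrix(stats::rnorm(length(co), 0, st$noise_sd), nrow(co), 3)
    }
    coords[, , k] <- co
  }
  # reference assignment of each state's noise-free templates; planted
  # STRAND is confined to the paired-core residues (17-21, 30-34) and
  # planted ALPHA to the helix instructions -- anything the freely drawn
  # coil segments do beyond that is incidental background, not plant
  core <- c(17:21, 30:34)
  for (s in seq_len(n_states)) {
    st <- spec$states[[s]]
    if (st$hairpin_p > 0) {
      co <- mixture_frame(topology, st, TRUE, FALSE, two_chain, fixed_coil = TRUE)
      lab <- assign_ss(co, topology)
      lab[setdiff(which(lab == "STRAND"), core)] <- "COIL"
      templates[[s]]$hairpin_ss <- lab
    }
    co <- mixture_frame(topology, st, FALSE, FALSE, two_chain, fixed_coil = TRUE)
    lab <- assign_ss(co, topology)
    lab[lab == "STRAND"] <- "COIL"
    lab[setdiff(which(lab == "ALPHA"), st$helix_regions)] <- "COIL"
    templates[[s]]$open_ss <- lab
  }
  labels <- vapply(spec$states, `[[`, character(1), "label")
  ens <- ensemble(topology, coords, time = seq_len(n), replica = 1L)
  truth <- tibble::tibble(
    frame = seq_len(n), state = labels[draw], hairpin = hairpin,
    salt_bridge = bridge
  )
  list(ensemble = ens, truth = truth, templates = templates)
}

# build one noise-free frame for a state
mixture_frame <- function(topology, st, hairpin, bridge, two_chain,
                          fixed_coil = FALSE) {
  res <- topology$residues
  n_res <- nrow(res)
  cl <- rep("coil", n_res)
  if (hairpin) {
    cl[c(17:21, 30:34)] <- "strand"
  } else if (length(st$helix_regions) > 0) {
    cl[st$helix_regions] <- "helix"
  }
  rng <- if (fixed_coil) NULL else stats::runif
  d <- class_dihedrals(cl, rng = rng)
  if (hairpin) {
    d$phi[22:29] <- HAIRPIN_TURN_PHI
    d$psi[22:29] <- HAIRPIN_TURN_PSI
    d$psi[21] <- HAIRPIN_PSI21
    d$phi[30] <- HAIRPIN_PHI30
  }
  if (two_chain) {
    # extended hexapeptide parked next to the NTR
    d$phi[43:n_res] <- -139; d$psi[43:n_res] <- 135
  }
  co <- build_peptide_coords(topology, d$phi, d$psi,
                             chain_offsets = hex_offset(topology, two_chain))
  if (two_chain) co <- separate_chains(topology, co, min_gap = 0.30)
  co <- plant_salt_bridge(topology, co, bridge)
  co
}

# push the second chain out along +y until the interchain minimum distance
# clears min_gap, keeping it parked at contact range of the 42-mer surface
separate_chains <- function(topology, co, min_gap = 0.30, step = 0.05) {
  rows_b <- which(topology$atoms$chain == topology$chains[2])
  rows_a <- which(topology$atoms$chain == topology$chains[1])
  pa <- co[rows_a, , drop = FALSE]
  for (it in seq_len(200)) {
    pb <- co[rows_b, , drop = FALSE]
    d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * tcrossprod(pa, pb)
    if (sqrt(max(0, min(d2))) >= min_gap) break
    co[rows_b, 2] <- co[rows_b, 2] + step
  }
  co
}

hex_offset <- function(topology, two_chain) {
  if (!two_chain) return(NULL)
  out <- list(c(0, 0, 0), c(0, 0.55, 0.2))
  names(out) <- topology$chains[1:2]
  out
}

# place the K28 side-chain amine near (bridged) or away from (open) the
# D23 carboxylate; both residues sit in the turn region so their backbone
# geometry is template-controlled
plant_salt_bridge <- function(topology, co, bridge) {
  resid <- topology$residues$resid
  if (length(resid) < 28 || resid[23] != "ASP" || resid[28] != "LYS") return(co)
  od1 <- atom_select(topology, name = "OD1", residue = 23)
  nz <- atom_select(topology, name = "NZ", residue = 28)
  ce <- atom_select(topology, name = "CE", residue = 28)
  if (length(od1) == 0 || length(nz) == 0) return(co)
  ca28 <- atom_select(topology, name = "CA", residue = 28)
  dir <- co[od1, ] - co[ca28, ]
  nd <- vnorm(dir)
  if (nd < 1e-6) return(co)
  u <- dir / nd
  if (bridge) {
    co[nz, ] <- co[od1, ] - 0.30 * u
    co[ce, ] <- co[od1, ] - 0.44 * u
  } else {
    co[nz, ] <- co[ca28, ] - 0.40 * u  # points away; > 0.6 nm from OD1/OD2
    co[ce, ] <- co[ca28, ] - 0.28 * u
  }
  co
}

#' Planted per-residue strand propensity of a mixture
#'
#' The ground-truth propensity implied by a generated mixture: for each
#' residue, the fraction of frames whose state template (hairpin or open,
#' per the frame's planted hairpin indicator) assigns STRAND (or any other
#' class) to it.
#'
#' @param result A [sample_mixture_ensemble()] result.
#' @param class Label class (default `"STRAND"`).
#' @return Numeric vector, one planted fraction in percent per residue.
#' @export
planted_ss_propensity <- function(result, class = "STRAND") {
  tr <- result$truth
  tmpl <- result$templates
  n_res <- length(tmpl[[tr$state[1]]]$open_ss)
  acc <- matrix(0, nrow(tr), n_res)
  for (k in seq_len(nrow(tr))) {
    t0 <- tmpl[[tr$state[k]]]
    lab <- if (tr$hairpin[k]) t0$hairpin_ss else t0$open_ss
    acc[k, ] <- lab == class
  }
  100 * colMeans(acc)
}
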