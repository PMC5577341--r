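#' Implicit-solvent model parameters
#'
#' Defaults follow standard MM-PB/GBSA practice: solute dielectric 1,
#' solvent dielectric 80, surface tension 0.00542 kcal/mol/A^2 with offset
#' 0.92 kcal/mol for the nonpolar term, and a 0.14 nm water probe.
#'
#' @param eps_in,eps_out Solute and solvent dielectric constants (>= 1).
#' @param gamma Surface tension, kcal/mol/A^2 (>= 0).
#' @param offset Nonpolar offset b, kcal/mol (applied per species, so it
#'   cancels in binding differences of one complex vs its two chains).
#' @param probe Probe radius, nm.
#' @param n_points SASA quadrature points.
#' @return A `solvent_model` list.
#' @export
solvent_model <- function(eps_in = 1, eps_out = 80, gamma = 0.00542,
                          offset = 0.92, probe = 0.14, n_points = 240) {
  stopifnot(eps_in >= 1, eps_out >= 1, gamma >= 0)
  structure(list(eps_in = eps_in, eps_out = eps_out, gamma = gamma,
                 offset = offset, probe = probe, n_points = n_points),
            class = "solvent_model")
}

cross_pair_distances <- function(frame, group_a, group_b) {
  pa <- frame[group_a, , drop = FALSE] * ANGSTROM_PER_NM
  pb <- frame[group_b, , drop = FALSE] * ANGSTROM_PER_NM
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * tcrossprod(pa, pb)
  sqrt(pmax(d2, 0))
}

#' Interchain Coulomb energy
#'
#' Bare Coulomb sum over all cross pairs, `ke * qi * qj / rij` with
#' `ke = 332.0636` kcal A / (mol e^2); no cutoff, no periodicity.
#'
#' @param topology A `topology` with charges.
#' @param frame `n_atoms x 3` matrix (nm).
#' @param group_a,group_b Disjoint atom index vectors.
#' @return kcal/mol.
#' @export
coulomb_energy <- function(topology, frame, group_a, group_b) {
  if (length(intersect(group_a, group_b)) > 0) stop("groups overlap")
  r <- cross_pair_distances(frame, group_a, group_b)
  if (min(r) < 0.1) stop("atomic clash: interatomic distance below 0.01 nm")
  q <- outer(topology$atoms$charge[group_a], topology$atoms$charge[group_b])
  KE_KCAL_A * sum(q / r)
}

#' Interchain Lennard-Jones energy
#'
#' `4 eps [(sigma/r)^12 - (sigma/r)^6]` summed over cross pairs with
#' Lorentz-Berthelot combination (arithmetic sigma, geometric epsilon).
#'
#' @inheritParams coulomb_energy
#' @return kcal/mol.
#' @export
lj_energy <- function(topology, frame, group_a, group_b) {
  if (length(intersect(group_a, group_b)) > 0) stop("groups overlap")
  r <- cross_pair_distances(frame, group_a, group_b) # Angstrom
  if (min(r) < 0.1) stop("atomic clash: interatomic distance below 0.01 nm")
  a <- topology$atoms
  sig <- outer(a$sigma[group_a], a$sigma[group_b], "+") / 2 * ANGSTROM_PER_NM
  eps <- sqrt(outer(a$epsilon[group_a], a$epsilon[group_b]))
  sr6 <- (sig / r)^6
  sum(4 * eps * (sr6^2 - sr6))
}

#' Effective Born radii by pairwise descreening (HCT)
#'
#' Intrinsic radii are reduced by the Hawkins–Cramer–Truhlar pairwise
#' integral over all other atoms of the group, with per-element scale
#' factors on the descreening radii.
#'
#' @param topology A `topology` with intrinsic Born radii.
#' @param frame `n_atoms x 3` (nm).
#' @param group Atom indices of the species.
#' @return Effective radii in Angstrom.
#' @export
effective_born_radii <- function(topology, frame, group) {
  a <- topology$atoms
  rho <- a$born[group] * ANGSTROM_PER_NM
  if (any(rho <= 0)) stop("non-positive intrinsic Born radius")
  scale <- hct_scale(a$element[group])
  n <- length(group)
  if (n == 1) return(rho)
  pos <- frame[group, , drop = FALSE] * ANGSTROM_PER_NM
  d2 <- outer(rowSums(pos^2), rowSums(pos^2), "+") - 2 * tcrossprod(pos)
  r <- sqrt(pmax(d2, 0))
  sj <- matrix(scale * rho, n, n, byrow = TRUE)   # descreener radius (col j)
  rho_i <- matrix(rho, n, n)                      # self radius (row i)
  U <- r + sj
  L <- pmax(abs(r - sj), rho_i)
  term <- 0.5 * (
    1 / L - 1 / U + (r / 4) * (1 / U^2 - 1 / L^2) +
      (1 / (2 * r)) * log(L / U) + (sj^2 / (4 * r)) * (1 / L^2 - 1 / U^2)
  )
  term[rho_i >= U] <- 0 # fully engulfed neighbor screens nothing
  diag(term) <- 0
  inv <- 1 / rho - rowSums(term)
  1 / pmax(inv, 1e-6)
}

#' Generalized-Born polar solvation free energy
#'
#' Still-style pairwise GB with HCT effective radii:
#' `dG = -(ke/2) (1/eps_in - 1/eps_out) sum_ij qi qj / fGB` with
#' `fGB = sqrt(r^2 + Ri Rj exp(-r^2 / (4 Ri Rj)))`. For a single ion this
#' reduces to the Born formula.
#'
#' @param topology A `topology`.
#' @param frame `n_atoms x 3` (nm).
#' @param group Atom indices of the species.
#' @param model A [solvent_model()].
#' @return kcal/mol.
#' @export
gb_polar_solvation <- function(topology, frame, group, model = solvent_model()) {
  q <- topology$atoms$charge[group]
  R <- effective_born_radii(topology, frame, group)
  pos <- frame[group, , drop = FALSE] * ANGSTROM_PER_NM
  pref <- -0.5 * KE_KCAL_A * (1 / model$eps_in - 1 / model$eps_out)
  r2 <- outer(rowSums(pos^2), rowSums(pos^2), "+") - 2 * tcrossprod(pos)
  r2 <- pmax(r2, 0)
  rr <- outer(R, R)
  fgb <- sqrt(r2 + rr * exp(-r2 / (4 * rr)))
  # ordered double sum: off-diagonal pairs twice, self terms once
  pref * sum(outer(q, q) / fgb)
}

#' Single-trajectory MM-GB/SA binding-energy decomposition
#'
#' Per frame of the complex ensemble: the molecular-mechanics interaction
#' terms are the interchain Coulomb and LJ sums (intra-chain terms cancel
#' exactly in the single-trajectory approximation); the polar solvation
#' change is `G_GB(complex) - G_GB(A) - G_GB(B)` with effective radii
#' recomputed per species; the nonpolar change is
#' `gamma * (SASA_complex - SASA_A - SASA_B)` (the per-species offset `b`
#' is a constant and is excluded from the binding difference, so separated
#' chains give exactly zero). Components are averaged over frames with block
#' standard errors; no configurational-entropy term is estimated.
#'
#' @param x An `ensemble` of the complex.
#' @param chain_a,chain_b The two chain ids.
#' @param model A [solvent_model()].
#' @param n_blocks Blocks for SEs (default 4).
#' @return Tibble (class `energy_decomposition`): component
#'   (dE_vdw, dE_elec, dG_polar, dG_nonpolar, dG_bind), mean_kcal_mol,
#'   se_kcal_mol.
#' @export
mmgbsa_binding <- function(x, chain_a, chain_b, model = solvent_model(),
                           n_blocks = 4) {
  top <- x$topology
  if (!all(c(chain_a, chain_b) %in% top$chains)) stop("chain missing from topology")
  if (n_frames(x) == 0) stop("empty ensemble")
  ga <- atom_select(top, chain = chain_a)
  gb <- atom_select(top, chain = chain_b)
  ha <- atom_select(top, chain = chain_a, heavy = TRUE)
  hb <- atom_select(top, chain = chain_b, heavy = TRUE)
  nf <- n_frames(x)
  comp <- matrix(NA_real_, nf, 4,
                 dimnames = list(NULL, c("dE_vdw", "dE_elec", "dG_polar", "dG_nonpolar")))
  for (k in seq_len(nf)) {
    fr <- frame_coords(x, k)
    comp[k, "dE_vdw"] <- lj_energy(top, fr, ga, gb)
    comp[k, "dE_elec"] <- coulomb_energy(top, fr, ga, gb)
    g_ab <- gb_polar_solvation(top, fr, c(ga, gb), model)
    g_a <- gb_polar_solvation(top, fr, ga, model)
    g_b <- gb_polar_solvation(top, fr, gb, model)
    comp[k, "dG_polar"] <- g_ab - g_a - g_b
    s_ab <- sasa(fr, top, model$probe, model$n_points, selection = c(ha, hb))$total
    s_a <- sasa(fr, top, model$probe, model$n_points, selection = ha)$total
    s_b <- sasa(fr, top, model$probe, model$n_points, selection = hb)$total
    comp[k, "dG_nonpolar"] <- model$gamma * (s_ab - s_a - s_b)
  }
  total <- rowSums(comp)
  rows <- lapply(colnames(comp), function(cn) {
    tibble::tibble(
      component = cn, mean_kcal_mol = mean(comp[, cn]),
      se_kcal_mol = block_standard_error(comp[, cn], n_blocks)
    )
  })
  rows[[length(rows) + 1]] <- tibble::tibble(
    component = "dG_bind", mean_kcal_mol = mean(total),
    se_kcal_mol = block_standard_error(total, n_blocks)
  )
  out <- dplyr::bind_rows(rows)
  tol <- 1e-9 * max(1, abs(out$mean_kcal_mol[5]))
  stopifnot(abs(out$mean_kcal_mol[5] - sum(out$mean_kcal_mol[1:4])) < tol)
  class(out) <- c("energy_decomposition", class(out))
  out
}
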