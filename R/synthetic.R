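#' Geometric (exponentially spaced) REMD temperature ladder
#'
#' `T_k = t_min * (t_max / t_min)^(k / (n - 1))`, the standard exponential
#' spacing giving approximately uniform exchange acceptance; endpoints are
#' exact. The production protocol emulated here spans 276.0-592.3 K over 64
#' replicas.
#'
#' @param t_min,t_max Ladder endpoints in K, `0 < t_min < t_max`.
#' @param n_replicas Number of replicas (>= 2).
#' @return Numeric vector of temperatures, length `n_replicas`.
#' @examples
#' geometric_ladder(276.0, 592.3, 64)[c(1, 64)]
#' @export
geometric_ladder <- function(t_min, t_max, n_replicas) {
  stopifnot(t_min > 0, t_max > t_min, n_replicas >= 2)
  k <- seq(0, n_replicas - 1)
  t_min * (t_max / t_min)^(k / (n_replicas - 1))
}

#' Metropolis acceptance probability of a replica exchange
#'
#' `min(1, exp((beta_i - beta_j) (E_i - E_j)))` with `beta = 1 / (kB T)`.
#'
#' @param t_i,t_j Temperatures in K (> 0).
#' @param e_i,e_j Potential energies in kcal/mol (finite).
#' @return Acceptance probability in `[0, 1]`.
#' @export
swap_acceptance <- function(t_i, t_j, e_i, e_j) {
  stopifnot(t_i > 0, t_j > 0, is.finite(e_i), is.finite(e_j))
  bi <- 1 / (KB_KCAL * t_i)
  bj <- 1 / (KB_KCAL * t_j)
  min(1, exp((bi - bj) * (e_i - e_j)))
}

#' Toy model specification for the coarse REMD sampler
#'
#' Two desk-scale flavours stand in for all-atom REMD. `"cartesian"`: a
#' bead chain (one bead per residue) with harmonic bonds and optional
#' square-well (Go-style) contacts, sampled by single-bead displacement
#' moves — useful for equipartition and detailed-balance checks.
#' `"torsion"`: a full-backbone peptide whose degrees of freedom are the
#' per-residue (phi, psi) torsions, biased by Gaussian basins at the helix
#' (-57, -47) and strand (-139, 135) minima plus Go wells on Calpha
#' distances; frames carry complete backbones so secondary structure can be
#' assigned.
#'
#' @param mode `"cartesian"` or `"torsion"`.
#' @param n_beads Chain length (cartesian mode).
#' @param sequence One-letter sequence (torsion mode).
#' @param bond_length Equilibrium bond length nm (cartesian; 0 gives an
#'   isotropic 3D spring with mean energy 3/2 kT per bond).
#' @param k_bond Spring constant kcal/mol/nm^2 (>= 0).
#' @param go_wells Data frame (i, j, depth, distance): square wells of depth
#'   `depth` kcal/mol active below `distance` nm between beads/Calphas.
#' @param basins Named numeric: depths (kcal/mol) of `helix` and `strand`
#'   torsion basins (torsion mode).
#' @param basin_sigma Basin width in degrees (default 30).
#' @param step Move size: nm (cartesian) or degrees (torsion).
#' @return A `toy_model_spec`.
#' @export
toy_model_spec <- function(mode = c("cartesian", "torsion"), n_beads = 10,
                           sequence = NULL, bond_length = 0.38, k_bond = 100,
                           go_wells = NULL, basins = c(helix = 0, strand = 0),
                           basin_sigma = 30, step = NULL) {
  mode <- match.arg(mode)
  stopifnot(k_bond >= 0, bond_length >= 0, basin_sigma > 0)
  if (!is.null(go_wells)) {
    stopifnot(all(c("i", "j", "depth", "distance") %in% names(go_wells)),
              all(go_wells$depth >= 0), all(go_wells$distance > 0))
  }
  if (mode == "torsion" && is.null(sequence)) sequence <- strrep("V", 16)
  if (is.null(step)) step <- if (mode == "cartesian") 0.05 else 25
  structure(
    list(mode = mode, n_beads = as.integer(n_beads), sequence = sequence,
         bond_length = bond_length, k_bond = k_bond, go_wells = go_wells,
         basins = basins, basin_sigma = basin_sigma, step = step),
    class = "toy_model_spec"
  )
}

toy_cart_energy <- function(coords, spec) {
  e <- 0
  if (spec$k_bond > 0) {
    d <- sqrt(rowSums((coords[-1, , drop = FALSE] -
                         coords[-nrow(coords), , drop = FALSE])^2))
    e <- e + sum(0.5 * spec$k_bond * (d - spec$bond_length)^2)
  }
  if (!is.null(spec$go_wells)) {
    w <- spec$go_wells
    d <- sqrt(rowSums((coords[w$i, , drop = FALSE] -
                         coords[w$j, , drop = FALSE])^2))
    e <- e - sum(w$depth[d < w$distance])
  }
  e
}

toy_torsion_energy <- function(phi, psi, ca, spec) {
  e <- 0
  b <- spec$basins; s2 <- 2 * spec$basin_sigma^2
  if (b[["helix"]] > 0) {
    e <- e - b[["helix"]] * sum(exp(-((phi + 57)^2 + (psi + 47)^2) / s2))
  }
  if (b[["strand"]] > 0) {
    e <- e - b[["strand"]] * sum(exp(-((phi + 139)^2 + (psi - 135)^2) / s2))
  }
  if (!is.null(spec$go_wells)) {
    w <- spec$go_wells
    d <- sqrt(rowSums((ca[w$i, , drop = FALSE] - ca[w$j, , drop = FALSE])^2))
    e <- e - sum(w$depth[d < w$distance])
  }
  e
}

#' Run the toy replica-exchange sampler
#'
#' Metropolis sampling within each temperature slot of the ladder, with
#' neighbour configuration exchanges attempted every `exchange_interval`
#' steps via [swap_acceptance()] (alternating even/odd neighbour pairs).
#' Frames are recorded every `sample_interval` steps per slot; pseudo-time
#' advances 1 ps per step, so the production-window logic applies
#' unchanged. Fully reproducible under a fixed seed.
#'
#' @param model A [toy_model_spec()].
#' @param ladder Temperature vector from [geometric_ladder()] (or any
#'   positive temperatures).
#' @param n_steps MC steps per replica (> 0).
#' @param exchange_interval Steps between exchange attempts (> 0).
#' @param seed Integer seed.
#' @param sample_interval Steps between recorded frames (default =
#'   `exchange_interval`).
#' @return An `ensemble` (cartesian mode: one CA-like bead per residue of a
#'   poly-glycine-like bead topology; torsion mode: full backbone), frames
#'   ordered by replica then time, with an attribute `energies` tibble
#'   (replica, time, energy).
#' @export
run_toy_remd <- function(model, ladder, n_steps, exchange_interval, seed = 1,
                         sample_interval = exchange_interval) {
  stopifnot(inherits(model, "toy_model_spec"), n_steps > 0,
            exchange_interval > 0, sample_interval > 0)
  nrep <- length(ladder)
  stopifnot(nrep >= 2)
  set.seed(seed)
  if (model$mode == "cartesian") {
    run_toy_remd_cart(model, ladder, n_steps, exchange_interval, sample_interval)
  } else {
    run_toy_remd_torsion(model, ladder, n_steps, exchange_interval, sample_interval)
  }
}

run_toy_remd_cart <- function(model, ladder, n_steps, exch, samp) {
  nrep <- length(ladder)
  nb <- model$n_beads
  # compact ring start: bonds near equilibrium length and chain ends close,
  # so contact wells are reachable at every temperature
  if (model$bond_length == 0) {
    init <- matrix(0, nb, 3)
  } else {
    th <- 2 * pi * (seq_len(nb) - 1) / nb
    b_eff <- model$bond_length / (2 * sin(pi / nb)) # chord -> bond length
    init <- cbind(b_eff * cos(th), b_eff * sin(th), 0)
  }
  states <- replicate(nrep, init, simplify = FALSE)
  energies <- vapply(states, toy_cart_energy, numeric(1), spec = model)
  rec <- list(); rec_meta <- list()
  for (step in seq_len(n_steps)) {
    for (r in seq_len(nrep)) {
      beta <- 1 / (KB_KCAL * ladder[r])
      i <- sample.int(nb, 1)
      prop <- states[[r]]
      prop[i, ] <- prop[i, ] + stats::runif(3, -model$step, model$step)
      de <- toy_cart_energy(prop, model) - energies[r]
      if (de <= 0 || stats::runif(1) < exp(-beta * de)) {
        states[[r]] <- prop
        energies[r] <- energies[r] + de
      }
    }
    if (step %% exch == 0) {
      first <- if ((step %/% exch) %% 2 == 0) 1 else 2
      for (r in if (first > nrep - 1) integer(0) else seq(first, nrep - 1, by = 2)) {
        p <- swap_acceptance(ladder[r], ladder[r + 1], energies[r], energies[r + 1])
        if (stats::runif(1) < p) {
          tmp <- states[[r]]; states[[r]] <- states[[r + 1]]; states[[r + 1]] <- tmp
          energies[c(r, r + 1)] <- energies[c(r + 1, r)]
        }
      }
    }
    if (step %% samp == 0) {
      for (r in seq_len(nrep)) {
        rec[[length(rec) + 1]] <- states[[r]]
        rec_meta[[length(rec_meta) + 1]] <- c(step, r, ladder[r], energies[r])
      }
    }
  }
  meta <- do.call(rbind, rec_meta)
  ord <- order(meta[, 2], meta[, 1])
  top <- bead_topology(nb)
  coords <- array(NA_real_, c(nb, 3, length(rec)))
  for (k in seq_along(ord)) coords[, , k] <- rec[[ord[k]]]
  out <- ensemble(top, coords, time = meta[ord, 1], replica = meta[ord, 2],
                  temperature = meta[ord, 3])
  attr(out, "energies") <- tibble::tibble(
    replica = as.integer(meta[ord, 2]), time = meta[ord, 1],
    temperature = meta[ord, 3], energy = meta[ord, 4]
  )
  out
}

# minimal one-bead-per-residue topology (CA pseudo-atoms)
bead_topology <- function(n) {
  atoms <- tibble::tibble(
    name = rep("CA", n), residue = seq_len(n), resno = seq_len(n),
    resid = "GLY", chain = "A", element = "C"
  )
  atoms <- assign_parameters(atoms)
  residues <- tibble::tibble(residue = seq_len(n), resno = seq_len(n),
                             resid = "GLY", chain = "A")
  structure(list(atoms = atoms, residues = residues, chains = "A"),
            class = "topology")
}

run_toy_remd_torsion <- function(model, ladder, n_steps, exch, samp) {
  nrep <- length(ladder)
  top <- build_topology(model$sequence)
  nres <- n_residues(top)
  ca_rows <- atom_select(top, name = "CA")
  rebuild <- function(phi, psi) build_peptide_coords(top, phi, psi)
  init <- list(phi = rep(-120, nres), psi = rep(130, nres))
  states <- replicate(nrep, init, simplify = FALSE)
  coords_cache <- replicate(nrep, rebuild(init$phi, init$psi), simplify = FALSE)
  energy_of <- function(st, co) {
    toy_torsion_energy(st$phi, st$psi, co[ca_rows, , drop = FALSE], model)
  }
  energies <- vapply(seq_len(nrep), function(r) {
    energy_of(states[[r]], coords_cache[[r]])
  }, numeric(1))
  rec <- list(); rec_meta <- list()
  for (step in seq_len(n_steps)) {
    for (r in seq_len(nrep)) {
      beta <- 1 / (KB_KCAL * ladder[r])
      i <- sample.int(nres, 1)
      st <- states[[r]]
      st$phi[i] <- wrap_angle(st$phi[i] + stats::runif(1, -model$step, model$step))
      st$psi[i] <- wrap_angle(st$psi[i] + stats::runif(1, -model$step, model$step))
      co <- rebuild(st$phi, st$psi)
      e_new <- energy_of(st, co)
      de <- e_new - energies[r]
      if (de <= 0 || stats::runif(1) < exp(-beta * de)) {
        states[[r]] <- st
        coords_cache[[r]] <- co
        energies[r] <- e_new
      }
    }
    if (step %% exch == 0) {
      first <- if ((step %/% exch) %% 2 == 0) 1 else 2
      for (r in if (first > nrep - 1) integer(0) else seq(first, nrep - 1, by = 2)) {
        p <- swap_acceptance(ladder[r], ladder[r + 1], energies[r], energies[r + 1])
        if (stats::runif(1) < p) {
          tmp <- states[[r]]; states[[r]] <- states[[r + 1]]; states[[r + 1]] <- tmp
          tmp <- coords_cache[[r]]; coords_cache[[r]] <- coords_cache[[r + 1]]
          coords_cache[[r + 1]] <- tmp
          energies[c(r, r + 1)] <- energies[c(r + 1, r)]
        }
      }
    }
    if (step %% samp == 0) {
      for (r in seq_len(nrep)) {
        rec[[length(rec) + 1]] <- coords_cache[[r]]
        rec_meta[[length(rec_meta) + 1]] <- c(step, r, ladder[r], energies[r])
      }
    }
  }
  meta <- do.call(rbind, rec_meta)
  ord <- order(meta[, 2], meta[, 1])
  coords <- array(NA_real_, c(n_atoms(top), 3, length(rec)))
  for (k in seq_along(ord)) coords[, , k] <- rec[[ord[k]]]
  out <- ensemble(top, coords, time = meta[ord, 1], replica = meta[ord, 2],
                  temperature = meta[ord, 3])
  attr(out, "energies") <- tibble::tibble(
    replica = as.integer(meta[ord, 2]), time = meta[ord, 1],
    temperature = meta[ord, 3], energy = meta[ord, 4]
  )
  out
}

wrap_angle <- function(a) ((a + 180) %% 360) - 180

#' Toy parameterized topology for energetics tests
#'
#' A small chain with valid per-atom charges, LJ and Born parameters and a
#' prescribed net-charge pattern. Charges are placed on side-chain tips
#' (CB; CA for glycine) on top of a zeroed background so the pattern is
#' exact.
#'
#' @param n_residues Chain length (>= 1).
#' @param charge_pattern `"neutral"` (all zero), `"dipolar"` (+1 on the
#'   first residue, -1 on the last), or a numeric vector of per-residue
#'   charges (length `n_residues`).
#' @param seed Seed for the residue-type draw.
#' @param chain_id Chain id.
#' @return List: `topology` and `parameters` (tibble mirroring the TSV
#'   parameter table).
#' @export
synthetic_topology <- function(n_residues, charge_pattern = "neutral", seed = 1,
                               chain_id = "A") {
  stopifnot(n_residues >= 1)
  set.seed(seed)
  pool <- c("A", "G", "S", "T", "V", "L")
  seqn <- paste(sample(pool, n_residues, replace = TRUE), collapse = "")
  top <- build_topology(seqn, chain_id = chain_id)
  if (is.character(charge_pattern)) {
    per_res <- switch(charge_pattern,
      neutral = rep(0, n_residues),
      dipolar = {
        if (n_residues < 2) stop("dipolar pattern needs at least 2 residues")
        c(1, rep(0, n_residues - 2), -1)
      },
      stop("unknown charge pattern: ", charge_pattern)
    )
  } else {
    if (length(charge_pattern) != n_residues) {
      stop("charge pattern length must equal the residue count")
    }
    per_res <- charge_pattern
  }
  top$atoms$charge <- 0
  for (r in seq_len(n_residues)) {
    nm <- if (top$residues$resid[r] == "GLY") "CA" else "CB"
    j <- atom_select(top, name = nm, residue = r)[1]
    top$atoms$charge[j] <- per_res[r]
  }
  params <- tibble::tibble(
    residue = top$atoms$residue, atom = top$atoms$name,
    charge = top$atoms$charge, sigma = top$atoms$sigma,
    epsilon = top$atoms$epsilon, born_radius = top$atoms$born,
    hydrophobic = top$atoms$hydrophobic
  )
  list(topology = top, parameters = params)
}
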