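# two-residue fixture with adjustable charges on the CB tips
charge_pair_fixture <- function(qa = 1, qb = -1, separation = 0.1) {
  st <- synthetic_topology(2, c(qa, qb), seed = 1)
  top <- st$topology
  fr <- matrix(0, n_atoms(top), 3)
  fr[, 1] <- seq(0, 3, length.out = n_atoms(top)) # spread everything out
  ia <- atom_select(top, residue = 1)
  ib <- atom_select(top, residue = 2)
  # put the charged tips at the prescribed separation, others far away
  ca <- which(top$atoms$charge != 0 & top$atoms$residue == 1)
  cb <- which(top$atoms$charge != 0 & top$atoms$residue == 2)
  fr[ca, ] <- c(0, 10, 0)
  fr[cb, ] <- c(separation, 10, 0)
  list(top = top, fr = fr, ga = ia, gb = ib)
}

test_that("Coulomb energy reproduces the conversion constant", {
  fx <- charge_pair_fixture(1, -1, separation = 0.1) # 1 Angstrom
  e <- coulomb_energy(fx$top, fx$fr, fx$ga, fx$gb)
  expect_equal(e, -332.0636, tolerance = 1e-6)
  # swapping groups changes nothing
  expect_equal(coulomb_energy(fx$top, fx$fr, fx$gb, fx$ga), e)
  # neutral groups
  neutral <- fx$top; neutral$atoms$charge <- 0
  expect_equal(coulomb_energy(neutral, fx$fr, fx$ga, fx$gb), 0)
  expect_error(coulomb_energy(fx$top, fx$fr, fx$ga, fx$ga), "overlap")
})

test_that("LJ energy has its zero crossing and minimum where it should", {
  fx <- charge_pair_fixture()
  top <- fx$top
  i <- fx$ga[1]; j <- fx$gb[1]
  sig <- (top$atoms$sigma[i] + top$atoms$sigma[j]) / 2
  eps <- sqrt(top$atoms$epsilon[i] * top$atoms$epsilon[j])
  mk <- function(r) {
    fr <- matrix(0, n_atoms(top), 3)
    fr[, 2] <- seq(0, 50, length.out = n_atoms(top)) # park everyone far
    fr[i, ] <- c(0, -30, 0)
    fr[j, ] <- c(r, -30, 0)
    fr
  }
  e_far <- lj_energy(top, mk(8), fx$ga, fx$gb)
  e_sigma <- lj_energy(top, mk(sig), fx$ga, fx$gb) - e_far
  expect_equal(e_sigma, 0, tolerance = 1e-8)
  e_min <- lj_energy(top, mk(2^(1 / 6) * sig), fx$ga, fx$gb) - e_far
  expect_equal(e_min, -eps, tolerance = 1e-6)
})

test_that("MM cross terms equal an explicit pair-sum oracle", {
  st <- synthetic_topology(3, c(1, 0, -1), seed = 4)
  top <- st$topology
  set.seed(2)
  fr <- matrix(runif(n_atoms(top) * 3, 0, 2), ncol = 3)
  ga <- atom_select(top, residue = 1)
  gb <- atom_select(top, residue = 3)
  ec <- 0; el <- 0
  for (i in ga) for (j in gb) {
    r <- sqrt(sum((fr[i, ] - fr[j, ])^2)) * 10
    ec <- ec + 332.0636 * top$atoms$charge[i] * top$atoms$charge[j] / r
    sig <- (top$atoms$sigma[i] + top$atoms$sigma[j]) / 2 * 10
    eps <- sqrt(top$atoms$epsilon[i] * top$atoms$epsilon[j])
    el <- el + 4 * eps * ((sig / r)^12 - (sig / r)^6)
  }
  expect_equal(coulomb_energy(top, fr, ga, gb), ec, tolerance = 1e-12)
  expect_equal(lj_energy(top, fr, ga, gb), el, tolerance = 1e-12)
})

test_that("GB solvation reduces to the Born ion and is asymptotically additive", {
  st <- synthetic_topology(1, 1, seed = 1)
  top <- st$topology
  ion <- which(top$atoms$charge == 1)
  top$atoms$born[ion] <- 0.2 # 2 Angstrom
  fr <- matrix(0, n_atoms(top), 3)
  fr[, 1] <- seq(0, 3, length.out = n_atoms(top))
  born <- -0.5 * 332.0636 * (1 - 1 / 80) * 1 / 2
  g <- gb_polar_solvation(top, fr, ion, solvent_model())
  expect_equal(g, born, tolerance = 1e-6)
  expect_equal(round(g, 2), -81.98)

  # all charges zero
  top0 <- top; top0$atoms$charge <- 0
  expect_equal(gb_polar_solvation(top0, fr, seq_len(n_atoms(top0))), 0)

  # two distant ions: sum of individual Born terms within 0.1%
  st2 <- synthetic_topology(2, c(1, -1), seed = 1)
  top2 <- st2$topology
  q_at <- which(top2$atoms$charge != 0)
  top2$atoms$born[q_at] <- 0.2
  fr2 <- matrix(0, n_atoms(top2), 3)
  fr2[q_at[1], ] <- c(0, 0, 0)
  fr2[q_at[2], ] <- c(1000, 0, 0)
  g2 <- gb_polar_solvation(top2, fr2, q_at, solvent_model())
  expect_equal(g2, 2 * born, tolerance = 1e-3)

  bad <- top; bad$atoms$born[ion] <- 0
  expect_error(effective_born_radii(bad, fr, ion), "Born radius")
})

test_that("binding decomposition is additive and vanishes for separated chains", {
  top <- combine_topologies(
    synthetic_topology(2, c(1, 0), seed = 5, chain_id = "A")$topology,
    synthetic_topology(2, c(-1, 0), seed = 6, chain_id = "B")$topology
  )
  d <- class_dihedrals(rep("strand", 4))
  near <- build_peptide_coords(top, d$phi, d$psi,
                               chain_offsets = list(A = c(0, 0, 0), B = c(0, 0.6, 0)))
  far <- build_peptide_coords(top, d$phi, d$psi,
                              chain_offsets = list(A = c(0, 0, 0), B = c(0, 1e5, 0)))
  co <- array(c(near, near, far, far), c(n_atoms(top), 3, 4))
  ens <- ensemble(top, co, time = 1:4)
  dec <- mmgbsa_binding(ens, "A", "B", n_blocks = 2)
  expect_equal(dec$mean_kcal_mol[dec$component == "dG_bind"],
               sum(dec$mean_kcal_mol[dec$component != "dG_bind"]),
               tolerance = 1e-9)

  far_only <- mmgbsa_binding(subset_frames(ens, 3:4), "A", "B", n_blocks = 2)
  expect_true(all(abs(far_only$mean_kcal_mol) < 1e-3))

  expect_error(mmgbsa_binding(ens, "A", "C"), "chain")
})

test_that("adding favorable charge pairs strictly deepens the electrostatics", {
  deltas <- sapply(1:3, function(n_pairs) {
    qa <- rep(0, 6); qb <- rep(0, 6)
    qa[seq_len(n_pairs)] <- 0.5
    qb[seq_len(n_pairs)] <- -0.5
    top <- combine_topologies(
      synthetic_topology(6, qa, seed = 7, chain_id = "A")$topology,
      synthetic_topology(6, qb, seed = 8, chain_id = "B")$topology
    )
    d <- class_dihedrals(rep("strand", 12))
    co <- build_peptide_coords(top, d$phi, d$psi,
                               chain_offsets = list(A = c(0, 0, 0), B = c(0, 0.7, 0)))
    coulomb_energy(top, co, atom_select(top, chain = "A"),
                   atom_select(top, chain = "B"))
  })
  expect_true(all(diff(deltas) < 0))
  expect_true(all(deltas < 0))
})
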