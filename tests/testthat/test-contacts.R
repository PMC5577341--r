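test_that("contact probabilities follow the distance definition", {
  # two residues with CA atoms fixed 0.5 nm apart across 4 frames
  top <- build_topology("GGGG")
  d <- class_dihedrals(rep("strand", 4))
  base <- build_peptide_coords(top, d$phi, d$psi)
  co <- array(rep(base, 4), c(n_atoms(top), 3, 4))
  ca <- atom_select(top, name = "CA")
  for (k in 1:4) co[ca[4], , k] <- co[ca[1], , k] + c(0.5, 0, 0)
  ens <- ensemble(top, co, time = 1:4)
  m <- contact_map(ens, 1:4, 1:4, "ca", cutoff = 0.65, min_seq_sep = 3,
                   n_blocks = 2)
  expect_equal(m$prob["1", "4"], 1)
  expect_equal(m$prob["4", "1"], 1)
  # |i - j| < min_seq_sep is exactly zero whatever the distance
  expect_true(all(m$prob[abs(outer(1:4, 1:4, "-")) < 3] == 0))
  expect_error(contact_map(ens, 1:4, 1:4, "ca", cutoff = -1), "positive")
})

test_that("contact maps equal the brute-force oracle on a toy ensemble", {
  res <- small_mixture(n_frames = 10, seed = 12)
  ens <- res$ensemble
  sel <- c(15:22, 29:35)
  for (mode in c("ca", "heavy")) {
    cutoff <- if (mode == "ca") 0.65 else 0.4
    m <- contact_map(ens, sel, sel, mode, cutoff, min_seq_sep = 3, n_blocks = 2)
    o <- oracle_contact_map(ens, sel, sel, mode, cutoff, min_seq_sep = 3)
    expect_equal(unname(m$prob), o, tolerance = 1e-12)
  }
})

test_that("difference maps mask at the probability threshold", {
  res <- small_mixture(n_frames = 8, seed = 2)
  m <- contact_map(res$ensemble, 1:42, 1:42, "ca", n_blocks = 2)
  same <- contact_difference(m, m, threshold = 0.06)
  expect_true(all(same$delta == 0))

  m2 <- m
  m2$prob["17", "31"] <- m$prob["17", "31"] + 0.05
  m2$prob["18", "32"] <- m$prob["18", "32"] + 0.07
  d <- contact_difference(m2, m, threshold = 0.06)
  expect_equal(d$delta["17", "31"], 0)        # 0.05 masked
  expect_equal(d$delta["18", "32"], 0.07)     # 0.07 retained
  swapped <- contact_difference(m, m2, threshold = 0.06)
  expect_equal(swapped$delta, -d$delta)
})

test_that("interchain per-residue counts match direct enumeration", {
  lib <- sequence_library()
  top <- combine_topologies(build_topology("AAA", "A"), build_topology("GG", "B"))
  d <- class_dihedrals(rep("strand", 5))
  co <- build_peptide_coords(top, d$phi, d$psi,
                             chain_offsets = list(A = c(0, 0, 0), B = c(0, 0, 5)))
  # place one atom of B residue 2 within cutoff of exactly three A atoms
  b2 <- atom_select(top, chain = "B", residue = 5, heavy = TRUE)
  a_heavy <- atom_select(top, chain = "A", heavy = TRUE)
  co[b2[1], ] <- co[a_heavy[1], ] + c(0.1, 0, 0)
  near <- sqrt(rowSums(sweep(co[a_heavy, , drop = FALSE], 2, co[b2[1], ])^2)) < 0.4
  ens <- ensemble(top, co)
  out <- per_residue_contact_count(ens, "A", "B", cutoff = 0.4, n_blocks = 2)
  expect_equal(out$mean_contacts[2], sum(near) +
                 sum(apply(co[setdiff(b2, b2[1]), , drop = FALSE], 1, function(p) {
                   sum(sqrt(rowSums(sweep(co[a_heavy, , drop = FALSE], 2, p)^2)) < 0.4)
                 })))
  expect_error(per_residue_contact_count(ens, "A", "A"), "distinct")

  # far-apart chains give all zeros
  co0 <- build_peptide_coords(top, d$phi, d$psi,
                              chain_offsets = list(A = c(0, 0, 0), B = c(0, 0, 9)))
  out0 <- per_residue_contact_count(ensemble(top, co0), "A", "B", n_blocks = 2)
  expect_true(all(out0$mean_contacts == 0))
})

test_that("salt-bridge frequency counts bridged frames", {
  # minimal ASP/LYS pair: chain D-x-x-x-x-K like the 23/28 motif
  top <- build_topology("ADGGGKG")
  d <- class_dihedrals(rep("coil", 7))
  base <- build_peptide_coords(top, d$phi, d$psi)
  od1 <- atom_select(top, name = "OD1", residue = 2)
  nz <- atom_select(top, name = "NZ", residue = 6)
  co <- array(rep(base, 2), c(n_atoms(top), 3, 2))
  co[nz, , 1] <- co[od1, , 1] + c(0.35, 0, 0)
  co[nz, , 2] <- co[od1, , 2] + c(0.50, 0, 0)
  ens <- ensemble(top, co, time = 1:2)
  out <- salt_bridge_frequency(ens, 2, 6, cutoff = 0.4, n_blocks = 2)
  expect_equal(out$frequency_pct, 50)

  co[nz, , 2] <- co[od1, , 2] + c(0.2, 0, 0)
  all_b <- salt_bridge_frequency(ensemble(top, co, time = 1:2), 2, 6,
                                 n_blocks = 2)
  expect_equal(all_b$frequency_pct, 100)

  expect_error(salt_bridge_frequency(ens, 1, 6), "carboxylate")
  expect_error(salt_bridge_frequency(ens, 2, 3), "basic")
})

test_that("reaction coordinates normalize strand counts and contacts", {
  hp <- hairpin_frame()
  top <- hp$top
  labels <- rep("COIL", 42)
  labels[c(17:21, 30:42)] <- "STRAND"
  rc <- reaction_coordinates(labels, hp$coords, top)
  expect_equal(rc[["nbeta"]], 1)
  labels2 <- rep("COIL", 42)
  labels2[c(17:21, 30:33)] <- "STRAND" # 9 of 18
  expect_equal(reaction_coordinates(labels2, hp$coords, top)[["nbeta"]], 0.5)

  # pull CTR far away: no CHC-CTR contacts
  far <- hp$coords
  ctr_atoms <- atom_select(top, residue = 30:42)
  far[ctr_atoms, 1] <- far[ctr_atoms, 1] + 50
  expect_equal(reaction_coordinates(labels, far, top)[["ncontact"]], 0)
  # hairpin frame has contacts
  expect_gt(reaction_coordinates(labels, hp$coords, top)[["ncontact"]], 0)
})

test_that("rc series stays in the unit square and aligns with frames", {
  res <- small_mixture(n_frames = 12, seed = 5)
  rc <- rc_series(res$ensemble)
  expect_equal(nrow(rc), 12)
  expect_true(all(rc$nbeta >= 0 & rc$nbeta <= 1))
  expect_true(all(rc$ncontact >= 0 & rc$ncontact <= 1))
})
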