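test_that("hydrogen-bond energy follows the electrostatic model", {
  # place four atoms on a line realizing the prescribed distances
  n <- c(0, 0, 0)
  o <- c(0.30, 0, 0)           # r_ON = 3.0 A
  h <- c(0.10, 0, 0)           # r_OH = 2.0 A
  ch <- c(-0.30, 0, 0)         # r_CH = 4.0 A, r_CN = 3.0 A -> adjust
  # adjust C to get r_CN = 3.9: C at x = -0.39 gives r_CH = 4.9; instead use
  # an off-axis C satisfying both: |C - H| = 4.0, |C - N| = 3.9
  # C = (x, y, 0): (x-1)^2 + y^2 = 16, x^2 + y^2 = 15.21 (Angstrom^2)
  x <- (15.21 - 16 + 1) / 2
  y <- sqrt(15.21 - x^2)
  cc <- c(x, y, 0) * 0.1
  e <- hbond_energy(n, h, cc, o)
  expect_equal(e, 27.888 * (1 / 3 + 1 / 4 - 1 / 2 - 1 / 3.9), tolerance = 1e-9)
  expect_equal(round(e, 2), -4.83)

  # all four distances equal -> exactly zero (symmetric kite geometry)
  n2 <- c(0, 0, 0); h2 <- c(0.1, 0, 0)
  y <- sqrt(0.3^2 - 0.05^2)
  o2 <- c(0.05, y, 0); c2 <- c(0.05, -y, 0)
  expect_equal(hbond_energy(n2, h2, c2, o2), 0)

  # clash guard
  expect_identical(hbond_energy(c(0, 0, 0), c(0.028, 0, 0), c(1, 0, 0),
                                c(0.05, 0, 0)), Inf)
})

test_that("ideal helices assign ALPHA in the interior", {
  hf <- helix_frame(12)
  ss <- assign_ss(hf$coords, hf$top)
  expect_true(all(ss[3:10] == "ALPHA"))
  expect_true(ss[1] != "ALPHA")
})

test_that("the calibrated hairpin pairs CHC with CTR strands", {
  hp <- hairpin_frame()
  ss <- assign_ss(hp$coords, hp$top)
  core <- c(17:21, 30:34)
  expect_gte(sum(ss[core] == "STRAND"), 8)
  # no helix anywhere in a pure hairpin frame
  expect_false(any(ss == "ALPHA"))
})

test_that("an isolated extended chain has no helix or strand", {
  top <- build_topology(strrep("A", 10))
  d <- class_dihedrals(rep("strand", 10))
  co <- build_peptide_coords(top, d$phi, d$psi)
  ss <- assign_ss(co, top)
  expect_false(any(ss %in% c("ALPHA", "STRAND", "THREE10")))
})

test_that("assignment is invariant under rigid motion", {
  hp <- hairpin_frame()
  ss1 <- assign_ss(hp$coords, hp$top)
  ss2 <- assign_ss(random_rigid(hp$coords, seed = 5), hp$top)
  expect_identical(ss1, ss2)
})

test_that("propensity profiles sum to 100 with block-mean errors", {
  res <- small_mixture(n_frames = 40)
  labels <- assign_ss_ensemble(res$ensemble)
  prof <- ss_propensity(res$ensemble, n_blocks = 4, labels = labels)
  sums <- tapply(prof$mean_pct, prof$residue, sum)
  expect_true(all(abs(sums - 100) < 1e-6))
  expect_true(all(prof$se_pct >= 0))

  # hand-check one entry: residue 18 STRAND indicator
  ind <- (labels[, 18] == "STRAND") * 100
  bm <- sapply(0:3, function(b) mean(ind[(b * 10 + 1):(b * 10 + 10)]))
  row <- prof[prof$residue == 18 & prof$class == "STRAND", ]
  expect_equal(row$mean_pct, mean(ind))
  expect_equal(row$se_pct, sd(bm) / 2)

  expect_error(ss_propensity(res$ensemble, n_blocks = 3, labels = labels),
               "remainder")
})

test_that("a residue always in one class reports 100% with zero error", {
  hf <- helix_frame(12)
  co <- array(rep(hf$coords, 8), c(n_atoms(hf$top), 3, 8))
  ens <- ensemble(hf$top, co, time = 1:8)
  prof <- ss_propensity(ens, n_blocks = 4)
  row <- prof[prof$residue == 5 & prof$class == "ALPHA", ]
  expect_equal(row$mean_pct, 100)
  expect_equal(row$se_pct, 0)
})

test_that("difference profiles subtract bound minus free and antisymmetrize", {
  res <- small_mixture(n_frames = 24, seed = 3)
  res2 <- small_mixture(n_frames = 24, seed = 4, hairpin_p = 0.2)
  a <- ss_propensity(res$ensemble, n_blocks = 2)
  b <- ss_propensity(res2$ensemble, n_blocks = 2)
  d_ab <- ss_difference(a, b)
  d_ba <- ss_difference(b, a)
  expect_equal(d_ab$delta_pct, -d_ba$delta_pct)
  zero <- ss_difference(a, a)
  expect_true(all(zero$delta_pct == 0))
  # mismatched residue sets rejected
  short <- ss_propensity(subset_ens <- res$ensemble, n_blocks = 2)
  short <- short[short$residue <= 10, ]
  expect_error(ss_difference(a, short), "residue")
})

test_that("per-frame label strings use one character per residue", {
  hf <- helix_frame(6)
  ens <- ensemble(hf$top, hf$coords)
  s <- ss_strings(assign_ss_ensemble(ens))
  expect_length(s, 1)
  expect_equal(nchar(s), 6)
  expect_match(s, "^[HGETC]+$")
})
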