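test_that("the geometric ladder hits its endpoints with constant ratios", {
  lad <- geometric_ladder(276.0, 592.3, 64)
  expect_equal(lad[1], 276.0)
  expect_equal(lad[64], 592.3)
  r <- lad[-1] / lad[-64]
  expect_lt(max(r) - min(r), 1e-12)

  lad5 <- geometric_ladder(300, 600, 5)
  expect_equal(lad5, 300 * 2^((0:4) / 4), tolerance = 1e-12)
  expect_equal(round(lad5, 2), c(300, 356.76, 424.26, 504.54, 600))
  expect_error(geometric_ladder(300, 600, 1), "n_replicas")
})

test_that("swap acceptance follows the Metropolis exchange rule", {
  expect_equal(swap_acceptance(300, 310, -50, -50), 1)
  p <- swap_acceptance(300, 310, -100, -90)
  db <- 1 / (0.0019872 * 300) - 1 / (0.0019872 * 310)
  expect_equal(p, exp(db * -10), tolerance = 1e-12)
  expect_equal(round(p, 3), 0.582)
  # relabelling the proposed pair leaves the acceptance unchanged
  expect_equal(swap_acceptance(310, 300, -90, -100), p)
  expect_error(swap_acceptance(300, 310, Inf, 0), "finite")
})

test_that("the toy sampler is reproducible and feels its temperature", {
  model <- toy_model_spec("cartesian", n_beads = 6, bond_length = 0.38,
                          k_bond = 500, step = 0.03)
  lad <- c(280, 400)
  e1 <- run_toy_remd(model, lad, n_steps = 1500, exchange_interval = 250, seed = 11)
  e2 <- run_toy_remd(model, lad, n_steps = 1500, exchange_interval = 250, seed = 11)
  expect_identical(e1$coords, e2$coords)
  expect_identical(attr(e1, "energies"), attr(e2, "energies"))
  expect_setequal(unique(e1$frames$temperature), lad)
  expect_error(run_toy_remd(model, lad, 0, 10), "n_steps")
})

test_that("a deep Go well is occupied more at low temperature", {
  wells <- data.frame(i = 1, j = 6, depth = 3, distance = 0.5)
  model <- toy_model_spec("cartesian", n_beads = 6, bond_length = 0.38,
                          k_bond = 300, go_wells = wells, step = 0.05)
  lad <- c(250, 900)
  ens <- run_toy_remd(model, lad, n_steps = 20000, exchange_interval = 1e9,
                      seed = 21, sample_interval = 20)
  f <- ens$frames
  occ <- sapply(seq_along(lad), function(r) {
    idx <- which(f$replica == r & f$time > 2000)
    d <- sapply(idx, function(k) {
      fr <- frame_coords(ens, k)
      sqrt(sum((fr[1, ] - fr[6, ])^2))
    })
    mean(d < 0.5)
  })
  expect_gt(occ[1], occ[2])
})

test_that("well occupancy matches the Boltzmann ratio at each temperature", {
  # two beads, one bond, one square well: the bound fraction has a closed
  # form as a ratio of radial configurational integrals
  wells <- data.frame(i = 1, j = 2, depth = 1.0, distance = 0.5)
  model <- toy_model_spec("cartesian", n_beads = 2, bond_length = 0.45,
                          k_bond = 50, go_wells = wells, step = 0.08)
  lad <- c(300, 500)
  ens <- run_toy_remd(model, lad, n_steps = 40000, exchange_interval = 1e9,
                      seed = 8, sample_interval = 10)
  f <- ens$frames
  for (r in 1:2) {
    beta <- 1 / (0.0019872 * lad[r])
    vb <- function(x) 0.5 * 50 * (x - 0.45)^2
    a <- integrate(function(x) x^2 * exp(-beta * (vb(x) - 1)), 0, 0.5)$value
    b <- integrate(function(x) x^2 * exp(-beta * vb(x)), 0.5, 10)$value
    p_theory <- a / (a + b)
    idx <- which(f$replica == r & f$time > 4000)
    d <- sapply(idx, function(k) {
      fr <- frame_coords(ens, k)
      sqrt(sum((fr[1, ] - fr[2, ])^2))
    })
    ind <- as.numeric(d < 0.5)
    expect_lt(abs(mean(ind) - p_theory), 3 * block_standard_error(ind, 4))
  }
})

test_that("torsion-mode frames carry assignable backbones", {
  model <- toy_model_spec("torsion", sequence = strrep("A", 12),
                          basins = c(helix = 3, strand = 1), step = 40)
  ens <- run_toy_remd(model, c(300, 380), n_steps = 200,
                      exchange_interval = 50, seed = 5, sample_interval = 50)
  expect_gt(n_frames(ens), 0)
  ss <- assign_ss(frame_coords(ens, n_frames(ens)), ens$topology)
  expect_length(ss, 12)
  expect_true(all(ss %in% c("ALPHA", "THREE10", "STRAND", "TURN", "COIL")))
})

test_that("mixture sampling recovers planted fractions at the binomial rate", {
  spec <- state_mixture_spec(list(
    mixture_state("hp", 0.47, hairpin_p = 1),
    mixture_state("open", 0.53)
  ), n_frames = 1000, seed = 31)
  res <- sample_mixture_ensemble(spec)
  p_hat <- mean(res$truth$state == "hp")
  expect_lt(abs(p_hat - 0.47), 3 * sqrt(0.47 * 0.53 / 1000))
  expect_equal(n_frames(res$ensemble), 1000)

  expect_error(state_mixture_spec(list(
    mixture_state("a", 0.6), mixture_state("b", 0.5)
  ), 10), "sum")
  expect_error(state_mixture_spec(list(mixture_state("a", 1)), 0), "n_frames")
})

test_that("a pure hairpin state scores the planted strand core downstream", {
  spec <- state_mixture_spec(
    list(mixture_state("hp", 1, hairpin_p = 1, noise_sd = 0)),
    n_frames = 3, seed = 2
  )
  res <- sample_mixture_ensemble(spec)
  labels <- assign_ss_ensemble(res$ensemble)
  planted <- planted_ss_propensity(res)
  core <- which(planted == 100)
  expect_gte(length(core), 8)
  expect_true(all(labels[, core] == "STRAND"))
  rc <- rc_series(res$ensemble, labels = labels)
  chc_ctr <- c(17:21, 30:42)
  expect_true(all(rc$nbeta >= length(intersect(core, chc_ctr)) / 18))
  expect_true(all(rc$ncontact > 0))
})

test_that("synthetic topologies honour their charge patterns", {
  a <- synthetic_topology(6, "neutral", seed = 3)
  expect_equal(sum(a$topology$atoms$charge), 0)
  b <- synthetic_topology(6, "dipolar", seed = 3)
  expect_equal(sum(b$topology$atoms$charge), 0)
  q <- tapply(b$topology$atoms$charge, b$topology$atoms$residue, sum)
  expect_equal(as.numeric(q), c(1, 0, 0, 0, 0, -1))
  c1 <- synthetic_topology(5, "neutral", seed = 9)
  c2 <- synthetic_topology(5, "neutral", seed = 9)
  expect_identical(c1$topology$atoms, c2$topology$atoms)
  expect_error(synthetic_topology(3, c(1, 2)), "length")
  expect_error(synthetic_topology(4, "weird"), "unknown charge pattern")
})
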