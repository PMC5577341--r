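test_that("topology construction follows the residue templates", {
  top <- build_topology("DAEFRH", chain_id = "B")
  expect_equal(n_residues(top), 6)
  # heavy atoms: D8 + A5 + E9 + F11 + R11 + H10 = 54
  expect_equal(sum(top$atoms$element != "H"), 54)
  # amide H on residues 2..6 only
  expect_equal(sum(top$atoms$name == "H"), 5)

  ala <- build_topology("A")
  expect_equal(sum(ala$atoms$element != "H"), 5)
  expect_setequal(ala$atoms$name, c("N", "CA", "C", "O", "CB"))

  oxt <- build_topology("A", terminal_mode = "oxt")
  expect_equal(sum(oxt$atoms$element != "H"), 6)

  expect_error(build_topology("AXA"), "position 2")
  expect_error(build_topology("X"), "position 1")
})

test_that("per-residue charges land on integer residue totals", {
  top <- build_topology(sequence_library()$ab42)
  q <- tapply(top$atoms$charge, top$atoms$residue, sum)
  resid <- top$residues$resid
  expected <- ifelse(resid %in% c("ASP", "GLU"), -1,
                     ifelse(resid %in% c("LYS", "ARG"), 1, 0))
  expect_equal(as.numeric(q), expected, tolerance = 1e-12)
})

test_that("region scheme partitions the 42-mer and serves lookups", {
  sc <- region_scheme()
  expect_equal(region_residues(sc, "CHC"), 17:21)
  expect_equal(region_residues(sc, "CTR"), 30:42)
  expect_length(region_residues(sc, c("CHC", "CTR")), 18)
  expect_equal(sort(region_residues(sc, c("NTR", "CHC", "turn", "CTR"))), 1:42)
  expect_equal(region_residues(sc, "preCHC"), 11:16)
  expect_error(region_residues(sc, "nope"), "unknown region")
  expect_error(region_scheme(ntr = c(1, 17)), "overlap")
})

test_that("sequence library holds the hexapeptide variants", {
  lib <- sequence_library()
  expect_equal(nchar(lib$ab42), 42)
  hx <- lib$hexapeptides
  expect_equal(substr(hx, 2, 2), c(WT = "A", A2V = "V", A2T = "T"))
  for (v in hx) {
    expect_equal(substr(v, 1, 1), "D")
    expect_equal(substr(v, 3, 6), "EFRH")
  }
})

test_that("multi-model PDB writing and reading round-trips", {
  hf <- helix_frame(6)
  co <- array(NA_real_, c(n_atoms(hf$top), 3, 3))
  for (k in 1:3) co[, , k] <- hf$coords + (k - 1) * 0.01
  ens <- ensemble(hf$top, co, time = 1:3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(ens, path, "pdb")
  txt <- readLines(path)
  expect_equal(sum(grepl("^MODEL", txt)), 3)
  expect_equal(sum(grepl("^TER", txt)), 3)
  back <- read_ensemble(hf$top, path, "pdb")
  expect_equal(n_frames(back), 3)
  expect_equal(back$coords, ens$coords, tolerance = 1e-4) # 0.001 Angstrom
})

test_that("two-chain PDB carries distinct chain ids and TER records", {
  lib <- sequence_library()
  top <- combine_topologies(build_topology("AAA", "A"), build_topology("GG", "B"))
  d <- class_dihedrals(rep("coil", 5))
  co <- build_peptide_coords(top, d$phi, d$psi)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(ensemble(top, co), path, "pdb")
  txt <- readLines(path)
  expect_equal(sum(grepl("^TER", txt)), 2)
  chains <- unique(substr(grep("^ATOM", txt, value = TRUE), 22, 22))
  expect_setequal(chains, c("A", "B"))
})

test_that("inconsistent model atom counts are rejected with both counts", {
  hf <- helix_frame(3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(ensemble(hf$top, hf$coords), path, "pdb")
  txt <- readLines(path)
  atoms <- grep("^ATOM", txt, value = TRUE)
  n <- length(atoms)
  broken <- c("MODEL        1", atoms, "ENDMDL",
              "MODEL        2", atoms[-n], "ENDMDL", "END")
  writeLines(broken, path)
  expect_error(read_ensemble(hf$top, path, "pdb"),
               paste0(n - 1, ".*", n, "|", n, ".*", n - 1))
})

test_that("the internal frame store round-trips coordinates and metadata", {
  hf <- helix_frame(4)
  co <- array(NA_real_, c(n_atoms(hf$top), 3, 2))
  co[, , 1] <- hf$coords; co[, , 2] <- hf$coords * 1.1
  ens <- ensemble(hf$top, co, time = c(10, 20), replica = c(1L, 1L),
                  temperature = 300)
  path <- withr::local_tempfile(fileext = ".dat")
  write_ensemble(ens, path, "store")
  back <- read_ensemble(hf$top, path, "store")
  expect_equal(back$coords, ens$coords)
  expect_equal(back$frames$time, ens$frames$time)
  expect_equal(back$frames$temperature, ens$frames$temperature)
})

test_that("production-window selection reproduces the protocol bookkeeping", {
  top <- build_topology("G")
  times <- seq(0, 200000, by = 50)
  n_rep <- 12
  nf <- length(times) * n_rep
  coords <- array(0, c(n_atoms(top), 3, nf))
  ens <- ensemble(top, coords, time = rep(times, n_rep),
                  replica = rep(seq_len(n_rep), each = length(times)))
  prod <- select_production(ens, 60000, 200000, 50)
  expect_equal(n_frames(prod), 33600)

  one <- select_production(ens, 60000, 200000, 50, replica_ids = 1L)
  expect_equal(n_frames(one), (200000 - 60000) / 50) # 2800

  # idempotence
  again <- select_production(prod, 60000, 200000, 50)
  expect_equal(again$coords, prod$coords)
  expect_equal(again$frames$time, prod$frames$time)

  expect_warning(out <- select_production(ens, -400, -200, 50),
                 "no frames")
  expect_equal(n_frames(out), 0)
  expect_error(select_production(ens, 0, 1000, 75), "not a multiple")
})

test_that("aggregate sampling bookkeeping scales replicas by length", {
  s <- aggregate_sampling(64, 200)
  expect_equal(s$total_ns, 12800)
  expect_equal(s$total_us, 12.8)
})

test_that("force-field parameter table round-trips through TSV", {
  st <- synthetic_topology(4, "dipolar", seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_parameters(st$topology, path)
  blank <- st$topology
  blank$atoms$charge <- 99
  back <- read_parameters(blank, path)
  expect_equal(back$atoms$charge, st$topology$atoms$charge)
  expect_equal(back$atoms$born, st$topology$atoms$born)
})
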