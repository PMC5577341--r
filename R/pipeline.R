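#' Pipeline configuration
#'
#' Assembles (and validates) every knob of the analysis sequence with the
#' package defaults: region scheme, contact cutoffs (Calpha 0.65 nm, heavy
#' 0.4 nm, salt bridge 0.4 nm), PMF binning (20 x 20 at 300 K), four error
#' blocks, the 0.3 nm cluster cutoff, the bundled state rectangles, and the
#' synthetic free/bound generation specs.
#'
#' @param seed Root seed for all synthesis.
#' @param outdir Output directory for the report bundle.
#' @param n_frames Frames per synthetic system.
#' @param free_hairpin_p,bound_hairpin_p Planted hairpin probabilities of
#'   the free and bound systems.
#' @param free_bridge_p,bound_bridge_p Planted D23-K28 salt-bridge
#'   probabilities.
#' @param ca_cutoff,heavy_cutoff,sb_cutoff Contact cutoffs, nm.
#' @param diff_threshold Contact-difference mask threshold.
#' @param n_bins,temperature PMF settings.
#' @param n_blocks Error blocks.
#' @param cluster_cutoff Gromos cutoff, nm.
#' @param states State rectangles (named list; see
#'   [default_state_rectangles()]).
#' @param config File path of a YAML/JSON config whose entries override the
#'   arguments above.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, outdir = tempfile("remscape_run_"),
                            n_frames = 400,
                            free_hairpin_p = 0.47, bound_hairpin_p = 0.21,
                            free_bridge_p = 0.13, bound_bridge_p = 0.085,
                            ca_cutoff = 0.65, heavy_cutoff = 0.4,
                            sb_cutoff = 0.4, diff_threshold = 0.06,
                            n_bins = 20, temperature = 300, n_blocks = 4,
                            cluster_cutoff = 0.3,
                            states = default_state_rectangles(),
                            config = NULL) {
  cfg <- list(
    seed = seed, outdir = outdir, n_frames = n_frames,
    free_hairpin_p = free_hairpin_p, bound_hairpin_p = bound_hairpin_p,
    free_bridge_p = free_bridge_p, bound_bridge_p = bound_bridge_p,
    ca_cutoff = ca_cutoff, heavy_cutoff = heavy_cutoff,
    sb_cutoff = sb_cutoff, diff_threshold = diff_threshold,
    n_bins = n_bins, temperature = temperature, n_blocks = n_blocks,
    cluster_cutoff = cluster_cutoff, states = states
  )
  if (!is.null(config)) {
    over <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
    for (nm in names(over)) {
      if (nm == "states") {
        cfg$states <- lapply(over$states, function(s) {
          state_rectangle(s$name, as.numeric(s$nbeta), as.numeric(s$ncontact))
        })
        names(cfg$states) <- vapply(cfg$states, `[[`, character(1), "name")
      } else {
        cfg[[nm]] <- over[[nm]]
      }
    }
  }
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  stopifnot(
    cfg$n_frames >= 4 * cfg$n_blocks, cfg$n_blocks >= 2,
    cfg$ca_cutoff > 0, cfg$heavy_cutoff > 0, cfg$sb_cutoff > 0,
    cfg$n_bins >= 2, cfg$temperature > 0, cfg$cluster_cutoff > 0,
    all(c(cfg$free_hairpin_p, cfg$bound_hairpin_p,
          cfg$free_bridge_p, cfg$bound_bridge_p) >= 0),
    all(c(cfg$free_hairpin_p, cfg$bound_hairpin_p,
          cfg$free_bridge_p, cfg$bound_bridge_p) <= 1)
  )
  states_disjoint(cfg$states)
  structure(cfg, class = "pipeline_config")
}

mixture_for <- function(hairpin_p, bridge_p, n_frames, seed) {
  states <- list(
    mixture_state("hairpin_rich", hairpin_p, hairpin_p = 1,
                  salt_bridge_p = bridge_p),
    mixture_state("open", round(1 - hairpin_p, 12), hairpin_p = 0,
                  helix_regions = 3:10, salt_bridge_p = bridge_p)
  )
  state_mixture_spec(states, n_frames, seed = seed)
}

#' Run the full analysis pipeline on a synthetic free/bound pair
#'
#' Generates a free 42-mer ensemble and a hexapeptide-bound complex
#' ensemble from planted mixtures, then runs the complete analysis
#' sequence: backbone-RMSD convergence series, secondary-structure
#' propensity profiles and bound-minus-free differences, intramolecular
#' Calpha contact maps and thresholded difference maps, interchain
#' per-residue heavy-atom contacts, the D23-K28 salt-bridge frequency,
#' radius-of-gyration series, reaction-coordinate series, the 2D PMF,
#' state populations, gromos clustering of the hairpin-rich subset, and the
#' MM-GB/SA decomposition of the complex. Tables are written as CSV files
#' named after the figure/table artifacts they correspond to, plus a
#' manifest JSON with the configuration.
#'
#' @param cfg A [pipeline_config()].
#' @param variant Hexapeptide variant for the bound system (`"WT"`,
#'   `"A2V"`, `"A2T"`).
#' @param energetics_frames Frames used for the (expensive) MM-GB/SA stage;
#'   0 skips it.
#' @return Invisible list with every intermediate result and `files`, the
#'   written file paths.
#' @export
run_pipeline <- function(cfg = pipeline_config(), variant = "WT",
                         energetics_frames = 10) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  lib <- sequence_library()
  scheme <- region_scheme()
  top_free <- build_topology(lib$ab42, chain_id = "A")
  top_cplx <- combine_topologies(
    top_free, build_topology(lib$hexapeptides[[variant]], chain_id = "B")
  )
  free <- sample_mixture_ensemble(
    mixture_for(cfg$free_hairpin_p, cfg$free_bridge_p, cfg$n_frames, cfg$seed)
  )
  bound <- sample_mixture_ensemble(
    mixture_for(cfg$bound_hairpin_p, cfg$bound_bridge_p, cfg$n_frames,
                cfg$seed + 1L),
    topology = top_cplx
  )
  out <- list(cfg = cfg, free = free, bound = bound)
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(cfg$outdir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files[[length(files) + 1]] <<- path
    path
  }

  ca_a <- atom_select(top_free, name = "CA")
  out$rmsd_free <- rmsd_series(free$ensemble, frame_coords(free$ensemble, 1),
                               selection = ca_a, ma_window = 10)
  put(out$rmsd_free, "fig1c_rmsd_series.csv")
  out$rg_free <- rg_series(free$ensemble)
  put(out$rg_free, "rg_distribution.csv")

  lab_free <- assign_ss_ensemble(free$ensemble)
  lab_bound <- assign_ss_ensemble(bound$ensemble)
  out$ss_free <- ss_propensity(free$ensemble, cfg$n_blocks, labels = lab_free)
  ab42_res <- seq_len(42)
  out$ss_bound <- ss_propensity(bound$ensemble, cfg$n_blocks, labels = lab_bound) |>
    dplyr::filter(.data$residue %in% ab42_res)
  out$ss_diff <- ss_difference(out$ss_bound, dplyr::filter(out$ss_free,
                                                           .data$residue %in% ab42_res))
  put(out$ss_free, "fig2_ss_profile_free.csv")
  put(out$ss_bound, "fig2_ss_profile_bound.csv")
  put(out$ss_diff, "fig2_ss_difference.csv")

  out$map_free <- contact_map(free$ensemble, ab42_res, ab42_res, "ca",
                              cfg$ca_cutoff, n_blocks = cfg$n_blocks)
  out$map_bound <- contact_map(bound$ensemble, ab42_res, ab42_res, "ca",
                               cfg$ca_cutoff, n_blocks = cfg$n_blocks)
  out$map_diff <- contact_difference(out$map_bound, out$map_free,
                                     cfg$diff_threshold)
  put(tidy(out$map_free), "fig3_contact_map_free.csv")
  put(tidy(out$map_diff), "fig3_contact_diff.csv")

  out$interchain <- per_residue_contact_count(bound$ensemble, "A", "B",
                                              cfg$heavy_cutoff, cfg$n_blocks)
  put(out$interchain, "fig4b_interchain_contacts.csv")
  out$sb_free <- salt_bridge_frequency(free$ensemble, 23, 28, cfg$sb_cutoff,
                                       cfg$n_blocks)
  out$sb_bound <- salt_bridge_frequency(bound$ensemble, 23, 28, cfg$sb_cutoff,
                                        cfg$n_blocks)
  put(dplyr::bind_rows(
    dplyr::mutate(out$sb_free, system = "free"),
    dplyr::mutate(out$sb_bound, system = "bound")
  ), "salt_bridge_frequency.csv")

  out$rc_free <- rc_series(free$ensemble, labels = lab_free, scheme = scheme,
                           ca_cutoff = cfg$ca_cutoff)
  out$pmf_free <- pmf2d(out$rc_free, cfg$n_bins, cfg$temperature)
  out$pop_free <- state_populations(out$rc_free, cfg$states, cfg$n_blocks)
  put(tidy(out$pmf_free), "fig5_pmf_free.csv")
  put(out$pop_free, "table1_state_populations_free.csv")
  out$rc_bound <- rc_series(bound$ensemble, labels = lab_bound, scheme = scheme,
                            ca_cutoff = cfg$ca_cutoff)
  out$pop_bound <- state_populations(out$rc_bound, cfg$states, cfg$n_blocks)
  put(out$pop_bound, "table1_state_populations_bound.csv")

  hp <- hairpin_subset(free$ensemble, out$rc_free, 0.6)
  if (n_frames(hp) >= 2) {
    sub <- subset_frames(hp, seq_len(min(n_frames(hp), 60)))
    m <- pairwise_rmsd_matrix(sub, selection = ca_a)
    out$clusters <- gromos_cluster(m, cfg$cluster_cutoff)
    put(tidy(out$clusters), "fig6_hairpin_clusters.csv")
  }

  if (energetics_frames > 0) {
    en <- subset_frames(bound$ensemble,
                        round(seq(1, n_frames(bound$ensemble),
                                  length.out = min(energetics_frames,
                                                   n_frames(bound$ensemble)))))
    nb <- min(cfg$n_blocks, n_frames(en))
    out$energetics <- mmgbsa_binding(en, "A", "B", n_blocks = nb)
    put(out$energetics, "fig4a_energetics.csv")
  }

  manifest <- list(
    package = "remscape",
    version = as.character(utils::packageVersion("remscape")),
    seed = cfg$seed, n_frames = cfg$n_frames, variant = variant,
    settings = cfg[setdiff(names(cfg), c("states", "outdir"))],
    files = basename(unlist(files))
  )
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out$files <- c(unlist(files), file.path(cfg$outdir, "manifest.json"))
  invisible(out)
}
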