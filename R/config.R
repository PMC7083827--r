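scheme_to_list <- function(scheme) {
  list(
    n_landmarks = scheme$n_landmarks,
    n_semilandmarks = scheme$n_semilandmarks,
    semilandmark_neighbours = lapply(scheme$semilandmark_neighbours, as.integer),
    subsets = lapply(scheme$subsets, as.integer)
  )
}

scheme_from_list <- function(x) {
  landmark_scheme(
    n_landmarks = x$n_landmarks,
    n_semilandmarks = x$n_semilandmarks,
    semilandmark_neighbours = lapply(x$semilandmark_neighbours, as.integer),
    subsets = lapply(x$subsets, as.integer)
  )
}

#' Write a ready-to-run fixture of the study design
#'
#' Emits TPS files for both simulated configurations, a Newick file for the
#' topology, and a YAML run config referencing them — a self-contained
#' miniature of the full analysis that [run_comparison_from_config()] can
#' execute directly.
#'
#' @param spec A [simulation_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the path of the run config.
#' @export
write_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) abort(paste0("cannot create directory: ", dir))
  }
  pair <- simulate_dataset(spec)
  write_tps(pair$astragalus_plus_centrale,
            file.path(dir, "astragalus_plus_centrale.tps"))
  write_tps(pair$astragalus_only, file.path(dir, "astragalus_only.tps"))
  ape::write.tree(spec$tree, file.path(dir, "tree.nwk"))
  cfg <- list(
    tps = list(astragalus_plus_centrale = "astragalus_plus_centrale.tps",
               astragalus_only = "astragalus_only.tps"),
    trees = list(sim = "tree.nwk"),
    reference = spec$reference,
    focal_clade = as.list(spec$focal_clade),
    medial_subset = "medial",
    scale_mode = "mm",
    divisor = "n-1",
    scheme = scheme_to_list(spec$scheme),
    simulation = list(scenario = spec$scenario, sigma = spec$sigma,
                      delta = spec$delta, noise = spec$noise,
                      seed = spec$seed)
  )
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}

#' Read a run configuration
#'
#' @param path Path to a YAML run config (as written by [write_fixture()]):
#'   TPS paths per configuration, Newick path(s) per topology, reference
#'   taxon, focal-clade leaf list, subset name, scale mode, divisor, and the
#'   landmark scheme.
#' @return A list with parsed `scheme`, resolved file paths, and options.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  cfg$tps <- lapply(cfg$tps, resolve)
  cfg$trees <- lapply(cfg$trees, resolve)
  cfg$focal_clade <- unlist(cfg$focal_clade)
  cfg$scheme <- scheme_from_list(cfg$scheme)
  cfg$scale_mode <- cfg$scale_mode %||% "unit"
  cfg$divisor <- cfg$divisor %||% "n-1"
  cfg$medial_subset <- cfg$medial_subset %||% "medial"
  cfg
}

#' Run the full two-configuration comparison from a run config
#'
#' Reads every TPS configuration and every topology named in the config,
#' runs [run_configuration()] for each pair, and assembles the
#' [comparison_report()].
#'
#' @param config Path to a YAML run config, or the list from
#'   [read_run_config()].
#' @return A `comparison_report`.
#' @export
run_comparison_from_config <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  results <- list()
  for (topo in names(cfg$trees)) {
    tree <- read_newick_tree(cfg$trees[[topo]])
    for (conf in names(cfg$tps)) {
      lm <- read_tps(cfg$tps[[conf]])
      results[[paste(topo, conf, sep = ".")]] <- run_configuration(
        lm, cfg$scheme, tree, cfg$reference, cfg$focal_clade,
        configuration_label = conf, topology_label = topo,
        medial_subset = cfg$medial_subset,
        scale_mode = cfg$scale_mode, divisor = cfg$divisor)
    }
  }
  comparison_report(results)
}

#' Default shipped fixture specification
#'
#' The conditions of the bundled miniature study: 8 taxa, seed 42,
#' loss_expansion scenario at delta/sigma = 5 (sigma 0.1 mm, delta 0.5 mm).
#' `write_fixture(default_fixture_spec(), dir)` reproduces the files under
#' `system.file("extdata", "fixture", package = "centrale")` byte for byte.
#'
#' @return A [simulation_spec()].
#' @export
default_fixture_spec <- function() {
  simulation_spec(scenario = "loss_expansion", sigma = 0.1, delta = 0.5,
                  noise = 0.02, seed = 42L)
}
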