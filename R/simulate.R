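#' Default ancestor shape for simulations
#'
#' An 11-point left-side proximal-tarsus outline in millimetres (anterior
#' view, +y dorsal, -x medial), roughly 12 mm wide — the size class of the
#' Triassic astragali the analysis targets. Points follow
#' [default_tarsus_scheme()]: nine landmarks then two medial-margin
#' semilandmarks.
#'
#' @return An 11 x 2 matrix of coordinates (mm).
#' @export
default_ancestor_shape <- function() {
  rbind(
    c( 0.0,  3.0),   # LM1 dorsal apex
    c(-5.5,  1.5),   # LM2 dorsomedial corner (medial)
    c( 3.5,  2.4),   # LM3 dorsolateral margin
    c( 5.8,  0.8),   # LM4 dorsal rim of calcaneal facet
    c( 6.0, -0.7),   # LM5 ventral rim of calcaneal facet
    c(-5.8, -0.8),   # LM6 medial margin (medial)
    c( 4.2, -2.2),   # LM7 ventrolateral corner
    c( 0.5, -3.0),   # LM8 ventral notch
    c(-3.8, -2.6),   # LM9 ventromedial corner (medial)
    c(-6.0,  0.3),   # SL1 medial margin, between LM2 and LM6
    c(-5.0, -1.9)    # SL2 medial margin, between LM6 and LM9
  )
}

#' Default 8-taxon study tree
#'
#' A rooted ladder topology with a three-taxon outgroup clade (`o1`-`o3`,
#' mirroring the allokotosaurian rooting clade) and a four-taxon focal clade
#' (`f1`-`f4`) whose stem is the focal branch; `p1` is the intervening
#' taxon. Branch durations default to 1 in simulations.
#'
#' @return An [ape::phylo] tree.
#' @export
default_study_tree <- function() {
  tr <- ape::read.tree(text = "((o1,(o2,o3)),(p1,(f1,(f2,(f3,f4)))));")
  tr
}

#' Specify a simulation of the two-configuration study design
#'
#' Landmark coordinates evolve independently down the tree as Brownian
#' motion (per-coordinate variance `sigma^2 *` branch duration), with
#' Gaussian digitization noise at the leaves. The scenario controls which
#' configuration's landmark homology is violated by the truth and therefore
#' receives an apparent medial jump of magnitude `delta` (in the -x,
#' i.e. medial, direction) on the focal branch, inherited by all its
#' descendants:
#' * `"loss_expansion"` (centrale truly lost, astragalus expands medially):
#'   the combined astragalus-plus-centrale configuration tracks a margin
#'   whose identity changes across the branch, so *it* jumps; the
#'   astragalus-only configuration evolves smoothly.
#' * `"fusion"` (centrale incorporated): the astragalus-only configuration
#'   jumps (its labelled astragalus suddenly includes former centrale
#'   territory — the observed ventromedial displacement pattern), the
#'   combined one evolves smoothly.
#'
#' `delta = 0` gives the no-signal null in either scenario.
#'
#' @param tree Rooted [ape::phylo]; branch durations taken from
#'   `edge.length` or 1 per branch if absent.
#' @param scheme A [landmark_scheme()]; its `"medial"` subset receives the
#'   shift.
#' @param ancestor_shape p x 2 matrix (mm) at the root.
#' @param sigma Brownian step scale (mm per unit branch duration), >= 0.
#' @param focal_clade Leaf labels whose stem branch carries the shift.
#' @param scenario `"loss_expansion"` or `"fusion"`.
#' @param delta Medial displacement magnitude (mm), >= 0.
#' @param noise Leaf digitization noise sd (mm), >= 0.
#' @param reference Reference taxon for downstream minimum-distance
#'   alignment; defaults to the first leaf outside the focal clade.
#' @param seed Integer root seed; all randomness derives from it.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(tree = default_study_tree(),
                            scheme = default_tarsus_scheme(),
                            ancestor_shape = default_ancestor_shape(),
                            sigma = 0.1,
                            focal_clade = c("f1", "f2", "f3", "f4"),
                            scenario = c("loss_expansion", "fusion"),
                            delta = 0.5,
                            noise = 0.02,
                            reference = NULL,
                            seed = 1L) {
  scenario <- match.arg(scenario)
  if (sigma < 0 || delta < 0 || noise < 0) {
    abort("sigma, delta and noise must be >= 0")
  }
  ancestor_shape <- config_matrix(ancestor_shape)
  if (nrow(ancestor_shape) != scheme$n_points) {
    abort("ancestor_shape point count does not match the scheme")
  }
  focal_branch <- find_branch(tree, focal_clade)  # validates existence
  if (is.null(reference)) {
    reference <- setdiff(tree$tip.label, focal_clade)[1]
  }
  structure(
    list(tree = tree, scheme = scheme, ancestor_shape = ancestor_shape,
         sigma = sigma, focal_clade = focal_clade,
         focal_branch = focal_branch, scenario = scenario, delta = delta,
         medial_subset = scheme$subsets$medial, noise = noise,
         reference = reference, seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat("<simulation_spec> ", length(x$tree$tip.label), " taxa, scenario = ",
      x$scenario, ", sigma = ", x$sigma, ", delta = ", x$delta,
      ", noise = ", x$noise, ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

# derived sub-seed k of a root seed (documented rule, kept < 2^31)
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(k)) %% 2147483647)
}

# one Brownian realization of all leaf configurations; `shifted` injects the
# focal-branch medial jump
simulate_one <- function(spec, shifted) {
  tree <- ape::reorder.phylo(spec$tree, "cladewise")  # parents before children
  n_tip <- length(tree$tip.label)
  p <- spec$scheme$n_points
  durations <- tree$edge.length %||% rep(1, nrow(tree$edge))
  states <- vector("list", n_tip + tree$Nnode)
  states[[n_tip + 1L]] <- spec$ancestor_shape
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
    st <- states[[par]] +
      matrix(rnorm(2 * p, 0, spec$sigma * sqrt(durations[e])), p, 2)
    if (shifted && chi == spec$focal_branch) {
      st[spec$medial_subset, 1] <- st[spec$medial_subset, 1] - spec$delta
    }
    states[[chi]] <- st
  }
  leaves <- do.call(rbind, states[seq_len(n_tip)])
  if (spec$noise > 0) {
    leaves <- leaves + matrix(rnorm(2 * p * n_tip, 0, spec$noise), ncol = 2)
  }
  tibble::tibble(specimen = rep(tree$tip.label, each = p),
                 point = rep.int(seq_len(p), n_tip),
                 x = leaves[, 1], y = leaves[, 2], side = "left")
}

#' Simulate the paired two-configuration dataset
#'
#' Generates independent Brownian realizations for the combined
#' (astragalus-plus-centrale) and astragalus-only configurations; the
#' scenario decides which of the two receives the focal-branch medial jump
#' (see [simulation_spec()]). Fully reproducible: configuration k uses the
#' derived seed `(seed + 1000003 * k) mod (2^31 - 1)`.
#'
#' @param spec A [simulation_spec()].
#' @return Named list `astragalus_plus_centrale`, `astragalus_only` of
#'   landmark tables, with the spec attached as attribute `"spec"`.
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  shift_combined <- spec$scenario == "loss_expansion"
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(derive_seed(spec$seed, 1))
  combined <- simulate_one(spec, shifted = shift_combined)
  set.seed(derive_seed(spec$seed, 2))
  astragalus <- simulate_one(spec, shifted = !shift_combined)
  out <- list(astragalus_plus_centrale = combined,
              astragalus_only = astragalus)
  attr(out, "spec") <- spec
  out
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Calibrate the focal-branch decision rule by simulation
#'
#' Runs the full two-configuration pipeline on `n_reps` simulated replicate
#' pairs and tallies which hypothesis the focal-branch medial-length rule
#' prefers. Replicate r uses root seed `spec$seed + r`, so any replicate is
#' individually reproducible.
#'
#' @param spec A [simulation_spec()].
#' @param n_reps Number of replicate pairs (>= 1).
#' @param ... Options forwarded to [run_configuration()] (e.g. `scale_mode`).
#' @return Object of class `calibration_summary`: `replicates` (tibble with
#'   per-replicate focal lengths, difference and preferred hypothesis) and
#'   `fractions` (tibble hypothesis x fraction).
#' @export
calibrate_decision_rule <- function(spec, n_reps, ...) {
  stopifnot(inherits(spec, "simulation_spec"), n_reps >= 1)
  reps <- purrr::map_dfr(seq_len(n_reps), function(r) {
    spec_r <- spec
    spec_r$seed <- derive_seed(spec$seed, 0) + r
    pair <- simulate_dataset(spec_r)
    res <- tryCatch(
      run_replicate(pair, spec_r, ...),
      error = function(e) abort(paste0("pipeline failed on replicate ", r,
                                       " (seed ", spec_r$seed, "): ",
                                       conditionMessage(e)))
    )
    res$rep <- r
    res$seed <- spec_r$seed
    res
  })
  fractions <- dplyr::count(reps, .data$hypothesis)
  fractions$fraction <- fractions$n / n_reps
  structure(list(replicates = reps, fractions = fractions, spec = spec),
            class = "calibration_summary")
}

run_replicate <- function(pair, spec, ...) {
  rc <- run_configuration(pair$astragalus_plus_centrale, spec$scheme,
                          spec$tree, spec$reference, spec$focal_clade,
                          configuration_label = "astragalus_plus_centrale",
                          topology_label = "sim", morphospace = FALSE, ...)
  ra <- run_configuration(pair$astragalus_only, spec$scheme,
                          spec$tree, spec$reference, spec$focal_clade,
                          configuration_label = "astragalus_only",
                          topology_label = "sim", morphospace = FALSE, ...)
  cmp <- compare_hypotheses(rc, ra)
  cmp[, c("focal_medial_combined", "focal_medial_astragalus",
          "difference", "preferred", "hypothesis")]
}

#' @export
print.calibration_summary <- function(x, ...) {
  cat("<calibration_summary> ", nrow(x$replicates), " replicates, scenario = ",
      x$spec$scenario, " (delta = ", x$spec$delta, ", sigma = ",
      x$spec$sigma, ")\n", sep = "")
  print(x$fractions)
  invisible(x)
}

#' @export
tidy.calibration_summary <- function(x, ...) x$replicates

#' @export
glance.calibration_summary <- function(x, ...) {
  frac <- function(h) {
    i <- match(h, x$fractions$hypothesis)
    if (is.na(i)) 0 else x$fractions$fraction[i]
  }
  tibble::tibble(
    n_reps = nrow(x$replicates),
    scenario = x$spec$scenario,
    delta = x$spec$delta,
    sigma = x$spec$sigma,
    fraction_loss = frac("loss"),
    fraction_fusion = frac("fusion"),
    fraction_inconclusive = frac("inconclusive"),
    mean_difference = mean(x$replicates$difference)
  )
}

#' @export
autoplot.calibration_summary <- function(object, ...) {
  ggplot2::ggplot(object$replicates, ggplot2::aes(.data$difference)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(title = "Focal-branch medial-length differences",
                  x = "astragalus-only minus combined", y = "replicates")
}
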