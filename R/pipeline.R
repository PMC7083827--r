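#' Run the full pipeline for one landmark configuration on one topology
#'
#' Chains GPA (with semilandmark sliding) -> minimum-distance re-alignment
#' onto the reference taxon -> minimum-displacement ancestral reconstruction
#' -> extraction of tree length, consistency index and the focal-branch
#' medial-subset length, alongside the PCA morphospace and Sum of Variances.
#'
#' @param landmarks Landmark table for one configuration (all taxa).
#' @param scheme A [landmark_scheme()] with a `"medial"` subset (or the
#'   subset named by `medial_subset`).
#' @param tree Rooted [ape::phylo] topology whose leaf set equals the
#'   specimen set.
#' @param reference Specimen id used as the minimum-distance reference
#'   taxon.
#' @param focal_clade Character vector of leaf labels; the focal branch is
#'   the stem of this clade (where the centrale disappears as a separate
#'   ossification).
#' @param configuration_label,topology_label Labels carried into reports
#'   (e.g. `"astragalus_plus_centrale"`, `"ezcurra"`).
#' @param medial_subset Name of the scheme subset summed on the focal
#'   branch. Default `"medial"`.
#' @param slide,scale_mode,divisor Options forwarded to [gpa_align()] and
#'   [sum_of_variances()]. The morphospace (PCA, Sum of Variances) is always
#'   computed in unit Procrustes space; `scale_mode` governs the parsimony
#'   leg: `"mm"` (default, the millimetre scaling applied for the
#'   optimization step, under which a medial expansion keeps its size
#'   component) aligns without rescaling, `"unit"` optimizes dimensionless
#'   Procrustes coordinates.
#' @param morphospace Compute the PCA morphospace and Sum of Variances?
#'   `FALSE` skips the unit-space alignment when only the parsimony
#'   quantities are needed (e.g. in simulation calibration).
#' @return Object of class `configuration_result` with fields
#'   `configuration_label`, `topology_label`, `tree_length`,
#'   `consistency_index`, `focal_branch`, `focal_branch_medial_length`,
#'   `morphospace`, `sum_of_variances`, `reconstruction`, `gpa`, `refalign`.
#' @export
run_configuration <- function(landmarks, scheme, tree, reference, focal_clade,
                              configuration_label = "configuration",
                              topology_label = "topology",
                              medial_subset = "medial",
                              slide = NULL,
                              scale_mode = c("mm", "unit"),
                              divisor = c("n-1", "n"),
                              morphospace = TRUE) {
  scale_mode <- match.arg(scale_mode)
  divisor <- match.arg(divisor)
  landmarks <- validate_landmarks(landmarks, scheme)
  sp <- unique(landmarks$specimen)
  if (!setequal(sp, tree$tip.label)) {
    abort(paste0(
      "specimen/leaf mismatch; only in data: ",
      paste(setdiff(sp, tree$tip.label), collapse = ", "),
      "; only in tree: ",
      paste(setdiff(tree$tip.label, sp), collapse = ", ")))
  }
  if (!medial_subset %in% names(scheme$subsets)) {
    abort(paste0("scheme has no subset named '", medial_subset, "'"))
  }
  focal <- find_branch(tree, focal_clade)

  fit <- if (morphospace || scale_mode == "unit") {
    gpa_align(landmarks, scheme, slide = slide, scale_mode = "unit")
  } else NULL
  morpho <- if (morphospace) shape_pca(fit) else NULL
  sov <- if (morphospace) sum_of_variances(fit, divisor = divisor) else NA_real_
  fit_shape <- if (scale_mode == "mm") {
    gpa_align(landmarks, scheme, slide = slide, scale_mode = "mm")
  } else fit
  ra <- minimum_distance_align(fit_shape, reference)
  recon <- reconstruct_ancestral(ra, tree)
  medial_len <- branch_subset_length(recon, focal, scheme$subsets[[medial_subset]])

  structure(
    list(configuration_label = configuration_label,
         topology_label = topology_label,
         tree_length = recon$tree_length,
         consistency_index = recon$consistency_index,
         focal_branch = focal,
         focal_branch_medial_length = medial_len,
         morphospace = morpho,
         sum_of_variances = sov,
         reconstruction = recon,
         gpa = fit,
         gpa_parsimony = fit_shape,
         refalign = ra,
         options = list(reference = reference, focal_clade = focal_clade,
                        medial_subset = medial_subset,
                        scale_mode = scale_mode, divisor = divisor)),
    class = "configuration_result"
  )
}

#' @export
print.configuration_result <- function(x, ...) {
  cat("<configuration_result> ", x$configuration_label, " on ",
      x$topology_label, "\n  tree length = ",
      format(x$tree_length, digits = 7),
      ", CI = ", format(x$consistency_index, digits = 4),
      ", focal medial length = ",
      format(x$focal_branch_medial_length, digits = 7),
      ", SoV = ", format(x$sum_of_variances, digits = 7), "\n", sep = "")
  invisible(x)
}

#' @export
glance.configuration_result <- function(x, ...) {
  tibble::tibble(
    configuration = x$configuration_label,
    topology = x$topology_label,
    tree_length = x$tree_length,
    consistency_index = x$consistency_index,
    focal_branch_medial_length = x$focal_branch_medial_length,
    sum_of_variances = x$sum_of_variances
  )
}

#' Compare the fusion and loss hypotheses on one topology
#'
#' The configuration whose focal-branch medial-subset length is strictly
#' smaller requires fewer steps where the centrale disappears, so its
#' associated homology hypothesis is preferred (combined configuration <->
#' fusion; astragalus-only <-> loss); equal lengths are inconclusive. The
#' parsimony argument accepts any difference, however small.
#'
#' @param result_combined `configuration_result` for the
#'   astragalus-plus-centrale configuration.
#' @param result_astragalus `configuration_result` for the astragalus-only
#'   configuration, same topology.
#' @return A one-row tibble: topology, the two focal lengths, their
#'   difference and ratio, `preferred` (a configuration label or
#'   `"inconclusive"`), and `hypothesis` (`"fusion"`, `"loss"`, or
#'   `"inconclusive"`).
#' @export
compare_hypotheses <- function(result_combined, result_astragalus) {
  stopifnot(inherits(result_combined, "configuration_result"),
            inherits(result_astragalus, "configuration_result"))
  if (!identical(result_combined$topology_label,
                 result_astragalus$topology_label)) {
    abort("results come from different topologies")
  }
  if (identical(result_combined$configuration_label,
                result_astragalus$configuration_label)) {
    abort("results carry the same configuration label")
  }
  a <- result_combined$focal_branch_medial_length
  b <- result_astragalus$focal_branch_medial_length
  preferred <- if (a < b) result_combined$configuration_label
               else if (b < a) result_astragalus$configuration_label
               else "inconclusive"
  hypothesis <- if (a < b) "fusion" else if (b < a) "loss" else "inconclusive"
  tibble::tibble(
    topology = result_combined$topology_label,
    focal_medial_combined = a,
    focal_medial_astragalus = b,
    difference = b - a,
    ratio = if (a > 0) b / a else NA_real_,
    preferred = preferred,
    hypothesis = hypothesis
  )
}

#' Assemble a two-configuration comparison report
#'
#' Pairs `configuration_result`s by topology, records the preferred
#' hypothesis per topology, the Sum-of-Variances contrast, and the
#' focal-branch per-landmark displacement vectors of every result.
#'
#' @param results List of `configuration_result`s: for each topology one
#'   combined (`astragalus_plus_centrale`) and one astragalus-only result.
#' @param combined_label,astragalus_label The two configuration labels.
#' @return Object of class `comparison_report` with `table` (one row per
#'   result, mirroring the tree-length / CI / medial-branch-length layout),
#'   `preferred_per_topology`, `sov_pair`, `landmark_displacements`.
#' @export
comparison_report <- function(results,
                              combined_label = "astragalus_plus_centrale",
                              astragalus_label = "astragalus_only") {
  stopifnot(length(results) >= 2)
  tab <- dplyr::bind_rows(lapply(results, glance))
  topos <- unique(tab$topology)
  prefs <- dplyr::bind_rows(lapply(topos, function(tp) {
    rs <- results[vapply(results, function(r) r$topology_label == tp, logical(1))]
    labs <- vapply(rs, function(r) r$configuration_label, character(1))
    compare_hypotheses(rs[[match(combined_label, labs)]],
                       rs[[match(astragalus_label, labs)]])
  }))
  sov <- dplyr::distinct(tab[, c("configuration", "sum_of_variances")])
  sov$lower <- sov$sum_of_variances == min(sov$sum_of_variances)
  disp <- dplyr::bind_rows(lapply(results, function(r) {
    dv <- displacement_vectors(r$reconstruction, r$focal_branch)
    dv$configuration <- r$configuration_label
    dv$topology <- r$topology_label
    dv
  }))
  structure(
    list(table = tab, preferred_per_topology = prefs, sov_pair = sov,
         landmark_displacements = disp,
         labels = c(combined = combined_label, astragalus = astragalus_label)),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  print(x$table)
  cat("\npreferred per topology:\n")
  print(x$preferred_per_topology[, c("topology", "preferred", "hypothesis")])
  invisible(x)
}

#' @export
tidy.comparison_report <- function(x, ...) x$table

#' Write a comparison report to disk
#'
#' Emits `report.json` (machine-readable, deterministic: no timestamps),
#' `table.tsv` (configuration x topology x tree length / CI / medial branch
#' length) and `displacements.tsv` (focal-branch landmark vectors).
#'
#' @param report A `comparison_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "comparison_report"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) abort(paste0("cannot create directory: ", dir))
  }
  paths <- file.path(dir, c("report.json", "table.tsv", "displacements.tsv"))
  jsonlite::write_json(
    list(table = report$table,
         preferred_per_topology = report$preferred_per_topology,
         sov_pair = report$sov_pair,
         landmark_displacements = report$landmark_displacements,
         labels = as.list(report$labels)),
    paths[1], digits = NA, auto_unbox = TRUE, pretty = TRUE)
  readr::write_tsv(report$table, paths[2])
  readr::write_tsv(report$landmark_displacements, paths[3])
  invisible(paths)
}

#' Read a comparison report back from JSON
#'
#' @param path Path to a `report.json` written by [write_report()].
#' @return A `comparison_report`.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(table = tibble::as_tibble(x$table),
         preferred_per_topology = tibble::as_tibble(x$preferred_per_topology),
         sov_pair = tibble::as_tibble(x$sov_pair),
         landmark_displacements = tibble::as_tibble(x$landmark_displacements),
         labels = unlist(x$labels)),
    class = "comparison_report"
  )
}

#' @export
autoplot.comparison_report <- function(object, ...) {
  ggplot2::ggplot(object$landmark_displacements,
                  ggplot2::aes(x = 0, y = 0, xend = .data$dx, yend = .data$dy)) +
    ggplot2::geom_segment(arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                          colour = "blue") +
    ggplot2::facet_grid(configuration ~ topology) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Focal-branch landmark displacement vectors",
                  x = "dx", y = "dy")
}
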