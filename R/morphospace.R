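#' Principal component morphospace of aligned coordinates
#'
#' Eigendecomposition of the covariance of the flattened aligned coordinates
#' (specimens x 2p). Scores are centred projections; the eigenvalue sum
#' equals the total coordinate variance (the Sum of Variances under the same
#' divisor).
#'
#' @param fit A `gpa_fit` (or a landmark table of already-aligned
#'   coordinates).
#' @return An object of class `morphospace`: `scores` (tibble, specimen x
#'   PC), `eigenvalues` (non-negative, non-increasing), `sum_of_variances`.
#' @export
shape_pca <- function(fit) {
  aligned <- if (inherits(fit, "gpa_fit")) fit$aligned else fit
  arr <- lm_array(aligned)
  n <- dim(arr)[3]
  if (n < 3) abort("PCA needs at least 3 specimens")
  X <- t(apply(arr, 3, function(m) as.vector(t(m))))  # n x 2p, (x1,y1,x2,y2,...)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  scores <- tibble::as_tibble(pc$x)
  scores <- dplyr::bind_cols(tibble::tibble(specimen = dimnames(arr)[[3]]), scores)
  structure(
    list(scores = scores, eigenvalues = ev, sum_of_variances = sum(ev),
         rotation = pc$rotation),
    class = "morphospace"
  )
}

#' @export
print.morphospace <- function(x, ...) {
  cat("<morphospace> ", nrow(x$scores), " specimens, ",
      length(x$eigenvalues), " components; SoV = ",
      format(x$sum_of_variances, digits = 8), "\n", sep = "")
  invisible(x)
}

#' Sum of Variances disparity
#'
#' Sum over all 2p coordinates of the per-coordinate variance across
#' specimens — the morphospace disparity descriptor. With all components
#' retained this equals the eigenvalue sum of [shape_pca()].
#'
#' @param fit A `gpa_fit` or landmark table of aligned coordinates.
#' @param divisor `"n-1"` (default, sample variance) or `"n"`.
#' @return Non-negative scalar.
#' @export
sum_of_variances <- function(fit, divisor = c("n-1", "n")) {
  divisor <- match.arg(divisor)
  aligned <- if (inherits(fit, "gpa_fit")) fit$aligned else fit
  arr <- lm_array(aligned)
  n <- dim(arr)[3]
  if (n < 2) abort("Sum of Variances needs at least 2 specimens")
  X <- t(apply(arr, 3, function(m) as.vector(t(m))))
  sov <- sum(apply(X, 2, var))
  if (divisor == "n") sov <- sov * (n - 1) / n
  sov
}

#' @export
tidy.morphospace <- function(x, ...) {
  tidyr::pivot_longer(x$scores, -"specimen",
                      names_to = "component", values_to = "score")
}

#' @export
glance.morphospace <- function(x, ...) {
  tibble::tibble(
    n_specimens = nrow(x$scores),
    n_components = length(x$eigenvalues),
    sum_of_variances = x$sum_of_variances,
    pc1_prop = if (x$sum_of_variances > 0)
      x$eigenvalues[1] / x$sum_of_variances else NA_real_
  )
}

#' @export
autoplot.morphospace <- function(object, ...) {
  ggplot2::ggplot(object$scores, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Morphospace (PC1 vs PC2)")
}
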