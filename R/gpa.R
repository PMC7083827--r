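#' Optimal rotation between two centred configurations
#'
#' Returns the proper rotation (determinant +1) minimizing the summed squared
#' distances between corresponding points of `rotate(A)` and `B`, from the
#' SVD of the cross-covariance matrix (Kabsch). Reflections are never
#' returned.
#'
#' @param A,B Centred p x 2 matrices with corresponding rows.
#' @return A 2 x 2 rotation matrix `R` such that `A %*% R` best matches `B`.
#' @export
optimal_rotation <- function(A, B) {
  A <- config_matrix(A); B <- config_matrix(B)
  if (nrow(A) != nrow(B)) abort("configurations have different point counts")
  H <- crossprod(A, B)  # 2x2
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, d)) %*% t(sv$v)
  R
}

# jointly slide one semilandmark across all specimens to the equilibrium of
# "each specimen projects the consensus point onto its tangent line, the
# consensus is the mean of the slid points": with positions a_j + t_j u_j the
# optimal offsets solve (I - M) t = b, M[j,l] = (u_j . u_l)/n,
# b_j = (mean(a) - a_j) . u_j. The system is solved by pseudoinverse: when
# all tangents are parallel the common-drift direction is objective-neutral
# and the minimum-norm solution pins it to zero (deterministic gauge).
slide_all_equilibrium <- function(arr, scheme) {
  n <- dim(arr)[3]
  for (k in seq_along(scheme$semilandmark_index)) {
    i <- scheme$semilandmark_index[k]
    nbp <- scheme$semilandmark_neighbours[[k]]
    U <- t(vapply(seq_len(n), function(j) {
      tg <- arr[nbp[2], , j] - arr[nbp[1], , j]
      len <- sqrt(sum(tg^2))
      if (len < 1e-12) c(0, 0) else tg / len
    }, numeric(2)))
    a <- t(arr[i, , ])                       # n x 2 current positions
    ok <- rowSums(U^2) > 0
    if (!any(ok)) next
    abar <- colMeans(a)
    b <- rowSums(sweep(-a, 2, abar, `+`) * U)
    # A = I - U U^T / n has at most two eigenvalues below 1 (on the left
    # singular directions of U); when tangents are near-parallel across
    # specimens the smallest mode is the collective drift of all
    # semilandmarks along their common tangent, along which the objective is
    # flat to first order. Truncating eigenvalues below 0.05 pins that gauge
    # (the informative relative-slide modes have eigenvalue ~1); the inverse
    # is applied through the rank-2 structure rather than a full n x n
    # decomposition.
    sv <- svd(U, nu = 2, nv = 0)
    lam <- 1 - sv$d^2 / n
    coef <- ifelse(lam > 0.05, 1 / lam, 0) - 1
    t_off <- b + sv$u %*% (coef * crossprod(sv$u, b))
    t_off[!ok] <- 0
    arr[i, 1, ] <- a[, 1] + t_off * U[, 1]
    arr[i, 2, ] <- a[, 2] + t_off * U[, 2]
  }
  arr
}

# slide semilandmarks of one configuration toward a target configuration:
# each semilandmark moves along the line through its current position with
# direction given by the chord between its two neighbours, to the foot of
# the perpendicular from the target point. Zero-length chords leave the
# point unmoved (with a warning).
slide_config <- function(m, target, scheme) {
  for (k in seq_along(scheme$semilandmark_index)) {
    i <- scheme$semilandmark_index[k]
    nb <- scheme$semilandmark_neighbours[[k]]
    tangent <- m[nb[2], ] - m[nb[1], ]
    len <- sqrt(sum(tangent^2))
    if (len < 1e-12) {
      warn(paste0("semilandmark ", i, ": coincident neighbours, not slid"))
      next
    }
    u <- tangent / len
    # projection of target point onto line {m[i,] + t * u}
    t_star <- sum((target[i, ] - m[i, ]) * u)
    m[i, ] <- m[i, ] + t_star * u
  }
  m
}

#' Generalized Procrustes alignment with semilandmark sliding
#'
#' Iteratively centres, scales (unit mode: to centroid size 1; mm mode:
#' leaves the millimetre scale untouched), rotates every configuration to
#' the current consensus, optionally slides semilandmarks along their
#' neighbour-chord tangents to the perpendicular foot of the consensus point
#' (the Procrustes-distance criterion), and recomputes the consensus, until
#' the consensus root-mean-square change falls below `tol` or `max_iter`
#' iterations. Non-convergence is recorded in the provenance, not fatal.
#'
#' @param landmarks Landmark table (see [validate_landmarks()]).
#' @param scheme A [landmark_scheme()]; required when `slide = TRUE`.
#' @param slide Slide semilandmarks? Default `TRUE` when the scheme declares
#'   any.
#' @param scale_mode `"unit"` (centroid size 1, dimensionless Procrustes
#'   coordinates) or `"mm"` (retain millimetre scale; no rescaling).
#' @param tol,max_iter Convergence tolerance on consensus RMS change and
#'   iteration cap.
#' @return An object of class `gpa_fit`: `aligned` (landmark table),
#'   `consensus` (tibble `point`, `x`, `y`; the coordinate-wise mean of the
#'   aligned configurations), `centroid_sizes`, `scheme`, `provenance`.
#' @export
gpa_align <- function(landmarks, scheme = NULL, slide = NULL,
                      scale_mode = c("unit", "mm"),
                      tol = 1e-12, max_iter = 100L) {
  scale_mode <- match.arg(scale_mode)
  arr <- lm_array(validate_landmarks(landmarks, scheme))
  p <- dim(arr)[1]; n <- dim(arr)[3]
  if (n < 2) abort("GPA needs at least 2 configurations")
  if (is.null(slide)) {
    slide <- !is.null(scheme) && scheme$n_semilandmarks > 0
  }
  if (slide && (is.null(scheme) || scheme$n_semilandmarks == 0)) {
    abort("slide = TRUE requires a scheme declaring at least one semilandmark")
  }

  csize <- apply(arr, 3, centroid_size)
  normalize <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    if (scale_mode == "unit") m <- m / sqrt(sum(m^2))
    m
  }
  # closed-form SO(2) Procrustes rotation of centred m onto target
  rotate_to <- function(m, target) {
    a <- sum(m * target)
    b <- sum(m[, 1] * target[, 2] - m[, 2] * target[, 1])
    r <- sqrt(a * a + b * b)
    if (r < 1e-300) return(m)
    co <- a / r; si <- b / r
    cbind(co * m[, 1] - si * m[, 2], si * m[, 1] + co * m[, 2])
  }
  for (j in seq_len(n)) arr[, , j] <- normalize(arr[, , j])
  # pre-rotate onto the first configuration so the iteration path (and the
  # gauge of any objective-flat sliding mode) depends on the input shapes
  # only, not on their arbitrary input orientations
  for (j in seq_len(n)[-1]) arr[, , j] <- rotate_to(arr[, , j], arr[, , 1])
  consensus <- apply(arr, c(1, 2), mean)
  it <- 0L; change <- Inf
  while (it < max_iter && change > tol) {
    it <- it + 1L
    for (j in seq_len(n)) {
      arr[, , j] <- rotate_to(normalize(arr[, , j]), consensus)
    }
    if (slide) arr <- slide_all_equilibrium(arr, scheme)
    new_consensus <- apply(arr, c(1, 2), mean)
    change <- sqrt(mean((new_consensus - consensus)^2))
    consensus <- new_consensus
  }
  converged <- change <= tol
  if (!converged) {
    warn(paste0("GPA did not converge in ", max_iter,
                " iterations (final change ", signif(change, 3), ")"))
  }
  # final pass without sliding so every configuration is exactly centred
  # (and unit-size in unit mode); rotation preserves both
  for (j in seq_len(n)) {
    arr[, , j] <- rotate_to(normalize(arr[, , j]), consensus)
  }
  consensus <- apply(arr, c(1, 2), mean)
  # canonical orientation: consensus principal axes, 180-degree ambiguity
  # resolved by the sign of its most lateral landmark — so the result does
  # not inherit an arbitrary rotation gauge from the input orientations and
  # re-aligning an aligned dataset reproduces it exactly
  ev <- eigen(crossprod(consensus), symmetric = TRUE)
  R <- ev$vectors
  if (det(R) < 0) R[, 2] <- -R[, 2]
  cr <- consensus %*% R
  k <- which.max(abs(cr[, 1]))
  if (cr[k, 1] < 0) R <- -R
  for (j in seq_len(n)) arr[, , j] <- arr[, , j] %*% R
  consensus <- consensus %*% R

  structure(
    list(aligned = lm_tibble(arr),
         consensus = tibble::tibble(point = seq_len(p),
                                    x = consensus[, 1], y = consensus[, 2]),
         centroid_sizes = tibble::tibble(specimen = dimnames(arr)[[3]],
                                         centroid_size = csize),
         scheme = scheme,
         provenance = list(slid = slide, scale_mode = scale_mode,
                           iterations = it, final_change = change,
                           converged = converged)),
    class = "gpa_fit"
  )
}

#' @export
print.gpa_fit <- function(x, ...) {
  n <- length(unique(x$aligned$specimen))
  cat("<gpa_fit> ", n, " configurations, ", nrow(x$consensus), " points; ",
      "scale_mode = ", x$provenance$scale_mode,
      if (x$provenance$slid) ", semilandmarks slid" else "",
      "; ", x$provenance$iterations, " iterations (final change ",
      signif(x$provenance$final_change, 3), ")\n", sep = "")
  invisible(x)
}

#' Slide semilandmarks of an aligned dataset toward its consensus
#'
#' One explicit sliding pass (the step [gpa_align()] interleaves with
#' re-alignment): each semilandmark moves along the chord direction of its
#' two neighbours to the point nearest the corresponding consensus point.
#' Fixed landmarks are untouched. Sliding never increases a specimen's
#' Procrustes distance to the consensus.
#'
#' @param fit A `gpa_fit` whose scheme declares semilandmarks.
#' @return A `gpa_fit` with slid coordinates and refreshed consensus.
#' @export
slide_semilandmarks <- function(fit) {
  stopifnot(inherits(fit, "gpa_fit"))
  scheme <- fit$scheme
  if (is.null(scheme) || scheme$n_semilandmarks == 0) {
    abort("the scheme declares no semilandmarks")
  }
  arr <- lm_array(fit$aligned)
  target <- as.matrix(fit$consensus[, c("x", "y")])
  for (j in seq_len(dim(arr)[3])) {
    arr[, , j] <- slide_config(arr[, , j], target, scheme)
  }
  fit$aligned <- lm_tibble(arr)
  cons <- apply(arr, c(1, 2), mean)
  fit$consensus$x <- cons[, 1]; fit$consensus$y <- cons[, 2]
  fit
}

#' @export
tidy.gpa_fit <- function(x, ...) x$aligned

#' @export
glance.gpa_fit <- function(x, ...) {
  tibble::tibble(
    n_specimens = length(unique(x$aligned$specimen)),
    n_points = nrow(x$consensus),
    scale_mode = x$provenance$scale_mode,
    slid = x$provenance$slid,
    iterations = x$provenance$iterations,
    final_change = x$provenance$final_change,
    converged = x$provenance$converged
  )
}

#' @export
autoplot.gpa_fit <- function(object, ...) {
  ggplot2::ggplot(object$aligned, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(ggplot2::aes(group = .data$specimen),
                        alpha = 0.4, size = 0.8) +
    ggplot2::geom_point(data = object$consensus, colour = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Procrustes-aligned configurations",
                  subtitle = "red: consensus shape")
}
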