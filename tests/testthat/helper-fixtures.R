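# small builders used across tests

# landmark table from a list of p x 2 matrices
lm_table <- function(configs, side = "unknown") {
  dplyr::bind_rows(lapply(names(configs), function(id) {
    m <- configs[[id]]
    tibble::tibble(specimen = id, point = seq_len(nrow(m)),
                   x = m[, 1], y = m[, 2], side = side)
  }))
}

# one specimen's coordinates as a p x 2 matrix, ordered by point
config_of <- function(landmarks, id) {
  d <- dplyr::arrange(dplyr::filter(landmarks, specimen == id), point)
  cbind(d$x, d$y)
}

rot2 <- function(theta) {
  matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
}

# apply a similarity transform to a p x 2 matrix (points as rows)
transform_config <- function(m, theta = 0, shift = c(0, 0), scale = 1) {
  sweep(scale * m %*% t(rot2(theta)), 2, shift, `+`)
}

# random blobby p-point shape
random_shape <- function(p, scale = 1) {
  matrix(stats::runif(2 * p, -scale, scale), p, 2)
}

# a tiny 3-point scheme: two fixed neighbours and one semilandmark between
mini_scheme <- function() {
  landmark_scheme(2, 1, list(`3` = c(1L, 2L)))
}

# hand-built gpa_fit wrapper so sliding can be tested in isolation
fake_gpa_fit <- function(configs, consensus, scheme) {
  structure(
    list(aligned = lm_table(configs),
         consensus = tibble::tibble(point = seq_len(nrow(consensus)),
                                    x = consensus[, 1], y = consensus[, 2]),
         centroid_sizes = tibble::tibble(specimen = names(configs),
                                         centroid_size = NA_real_),
         scheme = scheme,
         provenance = list(slid = FALSE, scale_mode = "unit",
                           iterations = 0L, final_change = 0, converged = TRUE)),
    class = "gpa_fit")
}

sum_sq_dist_to <- function(landmarks, consensus) {
  arr <- centrale:::lm_array(landmarks)
  sum(apply(arr, 3, function(m) sum((m - consensus)^2)))
}
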