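#' Declare a landmark scheme
#'
#' A scheme fixes the number of landmarks and sliding semilandmarks, the two
#' neighbour points that define each semilandmark's tangent chord, and named
#' subsets of points used downstream (the medial-margin subset drives the
#' focal-branch comparison). Points are indexed `1:(n_landmarks +
#' n_semilandmarks)`, fixed landmarks first, semilandmarks after.
#'
#' @param n_landmarks Number of fixed (type II/III) landmarks.
#' @param n_semilandmarks Number of sliding semilandmarks.
#' @param semilandmark_neighbours Named list; one entry per semilandmark,
#'   named by its point index, each an integer pair `c(before, after)` giving
#'   the neighbour points whose chord defines the sliding tangent.
#' @param subsets Named list of integer point-index vectors. Must contain a
#'   `"medial"` subset of exactly 5 points when used by the hypothesis test.
#'
#' @return An object of class `landmark_scheme`.
#' @export
#' @examples
#' landmark_scheme(3, 1, list(`4` = c(1, 2)), subsets = list(tip = c(3, 4)))
landmark_scheme <- function(n_landmarks, n_semilandmarks,
                            semilandmark_neighbours = list(),
                            subsets = list()) {
  p <- n_landmarks + n_semilandmarks
  if (p < 3) abort("a scheme needs at least 3 points in total")
  sl_idx <- if (n_semilandmarks > 0) seq(n_landmarks + 1L, p) else integer()
  if (length(semilandmark_neighbours) != n_semilandmarks) {
    abort("one neighbour pair is required per semilandmark")
  }
  if (n_semilandmarks > 0) {
    nm <- as.integer(names(semilandmark_neighbours))
    if (!setequal(nm, sl_idx)) {
      abort("semilandmark_neighbours must be named by the semilandmark point indices")
    }
    semilandmark_neighbours <- semilandmark_neighbours[as.character(sl_idx)]
    for (i in seq_along(semilandmark_neighbours)) {
      nb <- as.integer(semilandmark_neighbours[[i]])
      self <- sl_idx[i]
      if (length(nb) != 2 || anyNA(nb) || any(nb < 1) || any(nb > p) ||
          nb[1] == nb[2] || any(nb == self)) {
        abort(paste0("invalid neighbour pair for semilandmark ", self,
                     ": need two distinct in-range points other than itself"))
      }
      semilandmark_neighbours[[i]] <- nb
    }
  }
  for (nm in names(subsets)) {
    idx <- as.integer(subsets[[nm]])
    if (anyNA(idx) || any(idx < 1) || any(idx > p) || anyDuplicated(idx)) {
      abort(paste0("subset '", nm, "' has out-of-range or duplicated point indices"))
    }
    subsets[[nm]] <- idx
  }
  if ("medial" %in% names(subsets) && length(subsets$medial) != 5) {
    abort("the 'medial' subset must have exactly 5 members")
  }
  structure(
    list(n_landmarks = as.integer(n_landmarks),
         n_semilandmarks = as.integer(n_semilandmarks),
         n_points = as.integer(p),
         semilandmark_index = as.integer(sl_idx),
         semilandmark_neighbours = semilandmark_neighbours,
         subsets = subsets),
    class = "landmark_scheme"
  )
}

#' @export
print.landmark_scheme <- function(x, ...) {
  cat("<landmark_scheme> ", x$n_landmarks, " landmarks + ",
      x$n_semilandmarks, " semilandmarks\n", sep = "")
  if (length(x$subsets)) {
    for (nm in names(x$subsets)) {
      cat("  subset '", nm, "': ", paste(x$subsets[[nm]], collapse = ", "),
          "\n", sep = "")
    }
  }
  invisible(x)
}

#' Default 11-point proximal-tarsus scheme
#'
#' Nine fixed landmarks plus two semilandmarks sampling the outline of the
#' medial proximal tarsal (astragalus, or astragalus + centrale) in anterior
#' view, left side. The medial margin runs LM2 - SL1 (point 10) - LM6 - SL2
#' (point 11) - LM9, so the medial subset is {2, 6, 9, 10, 11}. Coordinates
#' follow the mathematical convention: +y dorsal, -x medial (after mirroring
#' to the left side).
#'
#' @return A [landmark_scheme()] with 9 landmarks and 2 semilandmarks.
#' @export
default_tarsus_scheme <- function() {
  landmark_scheme(
    n_landmarks = 9L,
    n_semilandmarks = 2L,
    semilandmark_neighbours = list(`10` = c(2L, 6L), `11` = c(6L, 9L)),
    subsets = list(medial = c(2L, 6L, 9L, 10L, 11L))
  )
}

#' Validate a landmark table against a scheme
#'
#' Landmark tables are long tibbles with one row per specimen x point:
#' columns `specimen` (character), `point` (integer), `x`, `y` (numeric,
#' millimetres) and optionally `side` (`"left"`, `"right"` or `"unknown"`).
#'
#' @param landmarks A landmark table.
#' @param scheme A [landmark_scheme()]; if supplied, every specimen must have
#'   exactly the scheme's points.
#' @return The table, invisibly, as a tibble (errors otherwise).
#' @export
validate_landmarks <- function(landmarks, scheme = NULL) {
  landmarks <- tibble::as_tibble(landmarks)
  need <- c("specimen", "point", "x", "y")
  miss <- setdiff(need, names(landmarks))
  if (length(miss)) abort(paste0("missing columns: ", paste(miss, collapse = ", ")))
  if (!all(is.finite(landmarks$x)) || !all(is.finite(landmarks$y))) {
    abort("non-finite coordinates in landmark table")
  }
  counts <- dplyr::count(landmarks, .data$specimen)
  if (!is.null(scheme)) {
    bad <- counts$specimen[counts$n != scheme$n_points]
    if (length(bad)) {
      abort(paste0("specimens with point count != ", scheme$n_points, ": ",
                   paste(bad, collapse = ", ")))
    }
  } else if (length(unique(counts$n)) > 1) {
    abort("specimens have unequal point counts")
  }
  if (any(counts$n < 3)) abort("each configuration needs at least 3 points")
  chk <- dplyr::summarise(
    dplyr::group_by(landmarks, .data$specimen),
    ok = identical(sort(as.integer(.data$point)), seq_len(dplyr::n()))
  )
  if (!all(chk$ok)) {
    abort(paste0("point indices must be 1..p within each specimen; offending: ",
                 paste(chk$specimen[!chk$ok], collapse = ", ")))
  }
  invisible(landmarks)
}

# long tibble -> p x 2 x n array; specimens in sorted label order, so every
# downstream computation is exactly invariant to input row order
lm_array <- function(landmarks) {
  landmarks <- validate_landmarks(landmarks)
  sp <- sort(unique(landmarks$specimen), method = "radix")
  landmarks <- dplyr::arrange(landmarks,
                              match(.data$specimen, sp), .data$point)
  p <- nrow(landmarks) / length(sp)
  arr <- array(NA_real_, dim = c(p, 2, length(sp)),
               dimnames = list(NULL, c("x", "y"), sp))
  arr[, 1, ] <- matrix(landmarks$x, nrow = p)
  arr[, 2, ] <- matrix(landmarks$y, nrow = p)
  arr
}

# p x 2 x n array -> long tibble
lm_tibble <- function(arr, side = NULL) {
  sp <- dimnames(arr)[[3]]
  p <- dim(arr)[1]
  out <- tibble::tibble(
    specimen = rep(sp, each = p),
    point = rep(seq_len(p), times = length(sp)),
    x = as.vector(arr[, 1, ]),
    y = as.vector(arr[, 2, ])
  )
  if (!is.null(side)) out$side <- rep(side, each = p)
  out
}

# single configuration (one specimen or bare coords) -> p x 2 matrix
config_matrix <- function(config) {
  if (is.matrix(config)) {
    stopifnot(ncol(config) == 2)
    return(config)
  }
  config <- tibble::as_tibble(config)
  if (all(c("specimen", "point") %in% names(config))) {
    if (length(unique(config$specimen)) != 1) {
      abort("expected a single specimen's configuration")
    }
    config <- dplyr::arrange(config, .data$point)
  }
  cbind(x = config$x, y = config$y)
}
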