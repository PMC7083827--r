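#' Weighted geometric median of 2D points
#'
#' The point minimizing the (weighted) sum of Euclidean distances to the
#' inputs, by the Vardi-Zhang damped fixed-point iteration with the standard
#' vertex optimality test: an input point x_k is itself the median when the
#' norm of the summed unit vectors toward the other points does not exceed
#' w_k (the >= 120 degree rule in the unweighted 3-point case).
#'
#' @param points m x 2 matrix (or data frame with `x`, `y`).
#' @param weights Optional positive weights, recycled to m.
#' @param tol Convergence tolerance on the iterate movement.
#' @return Length-2 numeric `c(x, y)`.
#' @export
#' @examples
#' geometric_median(rbind(c(0, 0), c(1, 0), c(0.5, 0.866025)))
geometric_median <- function(points, weights = NULL, tol = 1e-12) {
  m <- config_matrix_any(points)
  k <- nrow(m)
  if (k == 1) return(c(m[1, 1], m[1, 2]))
  w <- if (is.null(weights)) rep(1, k) else rep_len(as.numeric(weights), k)
  if (any(w <= 0)) abort("weights must be positive")
  scale <- max(1, max(abs(m)))
  y <- colSums(m * w) / sum(w)
  for (iter in 1:10000) {
    d <- sqrt((m[, 1] - y[1])^2 + (m[, 2] - y[2])^2)
    on_pt <- d < 1e-14 * scale
    wk <- if (any(on_pt)) sum(w[on_pt]) else 0
    j <- !on_pt
    if (!any(j)) return(y)  # all points coincide here
    rvec <- c(sum(w[j] * (m[j, 1] - y[1]) / d[j]),
              sum(w[j] * (m[j, 2] - y[2]) / d[j]))
    R <- sqrt(sum(rvec^2))
    if (wk > 0 && R <= wk + 1e-14) return(y)  # vertex rule
    Ty <- c(sum(w[j] * m[j, 1] / d[j]), sum(w[j] * m[j, 2] / d[j])) /
      sum(w[j] / d[j])
    y_new <- if (wk > 0) {
      pmin(1, wk / R) * y + max(0, 1 - wk / R) * Ty
    } else Ty
    if (sqrt(sum((y_new - y)^2)) < tol * scale) return(y_new)
    y <- y_new
  }
  y
}

# accepts matrix, data.frame with x/y, or list of length-2 vectors
config_matrix_any <- function(points) {
  if (is.list(points) && !is.data.frame(points)) {
    points <- do.call(rbind, points)
  }
  if (is.numeric(points) && is.null(dim(points)) && length(points) == 2) {
    points <- matrix(points, 1, 2)
  }
  config_matrix(points)
}

#' Superimpose configurations onto a reference by the minimum-distance
#' criterion
#'
#' Each non-reference configuration is rotated and translated (no
#' reflection; no rescaling unless `allow_scale = TRUE`) to minimize the sum
#' of unsquared Euclidean distances of corresponding landmarks to the
#' reference — the re-alignment applied before parsimony optimization. The
#' L1-type objective is solved by iteratively reweighted least squares
#' (weights 1/distance with a 1e-9 floor), each step a weighted Kabsch
#' superimposition, run to objective change below `tol`.
#'
#' @param fit A `gpa_fit` or an aligned landmark table.
#' @param reference Specimen id of the reference taxon (left unchanged).
#' @param allow_scale Also optimize a scale factor? Default `FALSE`.
#' @param tol Convergence tolerance on the objective. Default 1e-12.
#' @return An object of class `refalign`: `transformed` (landmark table),
#'   `objective` (tibble specimen x summed landmark distance to reference),
#'   `reference`.
#' @export
minimum_distance_align <- function(fit, reference, allow_scale = FALSE,
                                   tol = 1e-12) {
  aligned <- if (inherits(fit, "gpa_fit")) fit$aligned else fit
  arr <- lm_array(aligned)
  sp <- dimnames(arr)[[3]]
  if (!reference %in% sp) {
    abort(paste0("unknown reference taxon: ", reference))
  }
  ref <- arr[, , reference]
  objective <- numeric(length(sp))
  names(objective) <- sp
  for (s in sp) {
    if (s == reference) next
    res <- min_dist_fit(arr[, , s], ref, allow_scale = allow_scale, tol = tol)
    arr[, , s] <- res$transformed
    objective[s] <- res$objective
  }
  structure(
    list(transformed = lm_tibble(arr),
         objective = tibble::tibble(specimen = sp, objective = unname(objective)),
         reference = reference),
    class = "refalign"
  )
}

# IRLS rotation(+translation, optional scale) of X onto ref minimizing the
# summed unsquared distances
min_dist_fit <- function(X, ref, allow_scale = FALSE, tol = 1e-12,
                         max_iter = 1000L, eps = 1e-9) {
  cur <- X
  obj <- sum(sqrt(rowSums((cur - ref)^2)))
  for (it in seq_len(max_iter)) {
    d <- sqrt(rowSums((cur - ref)^2))
    w <- 1 / pmax(d, eps)
    sw <- sum(w)
    xc <- c(sum(X[, 1] * w), sum(X[, 2] * w)) / sw
    rc <- c(sum(ref[, 1] * w), sum(ref[, 2] * w)) / sw
    Xc <- cbind(X[, 1] - xc[1], X[, 2] - xc[2])
    Rc <- cbind(ref[, 1] - rc[1], ref[, 2] - rc[2])
    # closed-form weighted orthogonal Procrustes rotation over SO(2)
    a <- sum(w * (Xc[, 1] * Rc[, 1] + Xc[, 2] * Rc[, 2]))
    b <- sum(w * (Xc[, 1] * Rc[, 2] - Xc[, 2] * Rc[, 1]))
    r <- sqrt(a * a + b * b)
    if (r < 1e-300) { co <- 1; si <- 0 } else { co <- a / r; si <- b / r }
    XR <- cbind(co * Xc[, 1] - si * Xc[, 2], si * Xc[, 1] + co * Xc[, 2])
    s <- 1
    if (allow_scale) {
      s <- sum(w * (XR[, 1] * Rc[, 1] + XR[, 2] * Rc[, 2])) /
        sum(w * (Xc[, 1]^2 + Xc[, 2]^2))
      if (!is.finite(s) || s <= 0) s <- 1
    }
    new <- cbind(s * XR[, 1] + rc[1], s * XR[, 2] + rc[2])
    new_obj <- sum(sqrt(rowSums((new - ref)^2)))
    # IRLS converges linearly; extrapolating the rigid transform (angle and
    # offset) often halves the iteration count. Acceptance keeps it safe.
    th_new <- atan2(si, co)
    off_new <- c(rc[1] - s * (co * xc[1] - si * xc[2]),
                 rc[2] - s * (si * xc[1] + co * xc[2]))
    if (it > 1 && obj - new_obj > 1e-8) {
      th_e <- th_new + (th_new - th_prev)
      off_e <- off_new + (off_new - off_prev)
      ce <- cos(th_e); se <- sin(th_e)
      ext <- cbind(s * (ce * X[, 1] - se * X[, 2]) + off_e[1],
                   s * (se * X[, 1] + ce * X[, 2]) + off_e[2])
      ext_obj <- sum(sqrt(rowSums((ext - ref)^2)))
      if (ext_obj < new_obj) {
        new <- ext; new_obj <- ext_obj
        th_new <- th_e; off_new <- off_e
      }
    }
    th_prev <- th_new; off_prev <- off_new
    if (new_obj <= obj) cur <- new
    if (abs(obj - new_obj) < tol) { obj <- min(obj, new_obj); break }
    obj <- min(obj, new_obj)
  }
  list(transformed = cur, objective = obj)
}

#' @export
print.refalign <- function(x, ...) {
  cat("<refalign> reference = ", x$reference, "; total objective = ",
      format(sum(x$objective$objective), digits = 8), "\n", sep = "")
  invisible(x)
}

#' Ancestral landmark configurations by minimum total displacement
#'
#' Reconstructs one configuration per internal node of a fixed topology so
#' as to minimize the total Euclidean landmark displacement summed over
#' branches — the landmark-parsimony criterion. The objective decomposes
#' into one convex multifacility Weber problem per landmark, each solved by
#' iteratively reweighted least squares: every iteration solves the weighted
#' tree-Laplacian system (a majorize-minimize step, so the smoothed
#' objective never increases), with an epsilon-smoothing schedule (1e-3,
#' 1e-5, 1e-7, 1e-10, re-converged at each level) so the iteration cannot
#' stall on coincident points. The smoothed optimum also resolves non-unique
#' (collinear) optima to the midpoint of the optimal set. At convergence
#' every internal node that does not coincide with a neighbour satisfies the
#' zero-subgradient certificate of the exact convex problem. Branch lengths
#' are never taken from the tree: they are
#' the per-branch, per-landmark displacements this reconstruction yields.
#'
#' @param fit A `refalign`, `gpa_fit`, or landmark table in a common
#'   superimposed space; specimens must match the tree's leaf labels.
#' @param tree An [ape::phylo] rooted tree (polytomies allowed).
#' @param objective `"displacement"` (default: summed unsquared Euclidean
#'   distances) or `"squared"` (squared-change comparison option).
#' @param tol Objective-change convergence tolerance per smoothing level.
#' @param max_sweeps Total sweep cap across all smoothing levels; exceeding
#'   it is an error naming the unconverged landmarks.
#' @return Object of class `ancestral_recon`: `ancestral` (tibble `node`,
#'   `point`, `x`, `y` for internal nodes), `branch_lengths` (tibble
#'   `branch` = child node, `parent`, `point`, `length`), `tree_length`,
#'   `per_landmark_lengths`, `consistency_index`, `tree`, `convergence`.
#' @export
reconstruct_ancestral <- function(fit, tree, objective = c("displacement", "squared"),
                                  tol = 1e-10, max_sweeps = 10000L) {
  objective <- match.arg(objective)
  aligned <- if (inherits(fit, "refalign")) fit$transformed
             else if (inherits(fit, "gpa_fit")) fit$aligned else fit
  arr <- lm_array(aligned)
  sp <- dimnames(arr)[[3]]
  n_tip <- length(tree$tip.label)
  missing_tips <- setdiff(tree$tip.label, sp)
  if (length(missing_tips)) {
    abort(paste0("leaves without landmark data: ",
                 paste(missing_tips, collapse = ", ")))
  }
  p <- dim(arr)[1]
  n_node <- n_tip + tree$Nnode
  internal <- seq(n_tip + 1L, n_node)

  # node x landmark coordinate matrices, tips fixed
  X <- matrix(NA_real_, n_node, p); Y <- matrix(NA_real_, n_node, p)
  for (i in seq_len(n_tip)) {
    m <- arr[, , tree$tip.label[i]]
    X[i, ] <- m[, 1]; Y[i, ] <- m[, 2]
  }
  for (i in internal) {  # init: mean of subtended tips
    tips <- match(subtended_tips(tree, i), tree$tip.label)
    X[i, ] <- colMeans(X[tips, , drop = FALSE])
    Y[i, ] <- colMeans(Y[tips, , drop = FALSE])
  }

  epar <- tree$edge[, 1]; echi <- tree$edge[, 2]
  n_edge <- length(epar)
  n_int <- length(internal)

  # --- smoothed Weber solver on an arbitrary edge list -----------------
  # minimizes F_eps(q) = sum_e sqrt(||q[e1] - q[e2]||^2 + eps^2) over the
  # rows listed in `free`, alternating a damped Newton step (quadratic near
  # smooth optima) with an IRLS majorize-minimize step (geometric progress
  # through the kinks at vertex-type optima, where the Newton stride
  # collapses to O(eps)); both steps are monotone in the smoothed objective
  weber_level <- function(q, free, e1, e2, eps, tol_level, max_iter) {
    nf <- length(free)
    fmap <- integer(nrow(q)); fmap[free] <- seq_len(nf)
    af <- fmap[e1]; bf <- fmap[e2]          # 0 marks a fixed endpoint
    ridge <- diag(1e-14, 2 * nf)
    f_of <- function(q) {
      u1 <- q[e1, 1] - q[e2, 1]; u2 <- q[e1, 2] - q[e2, 2]
      sum(sqrt(u1 * u1 + u2 * u2 + eps * eps))
    }
    irls_step <- function(q, w) {
      A <- matrix(0, nf, nf); B <- matrix(0, nf, 2)
      for (e in seq_along(e1)) {
        ia <- af[e]; ib <- bf[e]; we <- w[e]
        if (ia > 0L) {
          A[ia, ia] <- A[ia, ia] + we
          if (ib > 0L) {
            A[ib, ib] <- A[ib, ib] + we
            A[ia, ib] <- A[ia, ib] - we
            A[ib, ia] <- A[ib, ia] - we
          } else B[ia, ] <- B[ia, ] + we * q[e2[e], ]
        } else if (ib > 0L) {
          A[ib, ib] <- A[ib, ib] + we
          B[ib, ] <- B[ib, ] + we * q[e1[e], ]
        }
      }
      q[free, ] <- solve(A, B)
      q
    }
    grad_hess <- function(q) {
      u1 <- q[e1, 1] - q[e2, 1]; u2 <- q[e1, 2] - q[e2, 2]
      s <- sqrt(u1 * u1 + u2 * u2 + eps * eps)
      s3 <- s * s * s
      ge1 <- u1 / s; ge2 <- u2 / s
      h11 <- 1 / s - u1 * u1 / s3
      h12 <- -u1 * u2 / s3
      h22 <- 1 / s - u2 * u2 / s3
      g <- numeric(2 * nf)
      H <- matrix(0, 2 * nf, 2 * nf)
      for (e in seq_along(e1)) {
        ia <- 2L * af[e] - 1L; ib <- 2L * bf[e] - 1L
        if (af[e] > 0L) {
          ja <- ia + 1L
          g[ia] <- g[ia] + ge1[e]; g[ja] <- g[ja] + ge2[e]
          H[ia, ia] <- H[ia, ia] + h11[e]
          H[ia, ja] <- H[ia, ja] + h12[e]
          H[ja, ia] <- H[ja, ia] + h12[e]
          H[ja, ja] <- H[ja, ja] + h22[e]
        }
        if (bf[e] > 0L) {
          jb <- ib + 1L
          g[ib] <- g[ib] - ge1[e]; g[jb] <- g[jb] - ge2[e]
          H[ib, ib] <- H[ib, ib] + h11[e]
          H[ib, jb] <- H[ib, jb] + h12[e]
          H[jb, ib] <- H[jb, ib] + h12[e]
          H[jb, jb] <- H[jb, jb] + h22[e]
        }
        if (af[e] > 0L && bf[e] > 0L) {
          ja <- ia + 1L; jb <- ib + 1L
          H[ia, ib] <- H[ia, ib] - h11[e]
          H[ia, jb] <- H[ia, jb] - h12[e]
          H[ja, ib] <- H[ja, ib] - h12[e]
          H[ja, jb] <- H[ja, jb] - h22[e]
          H[ib, ia] <- H[ib, ia] - h11[e]
          H[jb, ia] <- H[jb, ia] - h12[e]
          H[ib, ja] <- H[ib, ja] - h12[e]
          H[jb, ja] <- H[jb, ja] - h22[e]
        }
      }
      list(g = g, H = H)
    }
    # warm start with one IRLS step, then iterate best-of-both
    u1 <- q[e1, 1] - q[e2, 1]; u2 <- q[e1, 2] - q[e2, 2]
    q <- irls_step(q, 1 / sqrt(u1 * u1 + u2 * u2 + eps * eps))
    prev_obj <- f_of(q)
    objs <- prev_obj
    iters <- 1L
    repeat {
      gh <- grad_hess(q)
      step <- tryCatch(-solve(gh$H + ridge, gh$g), error = function(e) -gh$g)
      dir_deriv <- sum(gh$g * step)
      if (dir_deriv > 0) { step <- -gh$g; dir_deriv <- -sum(gh$g^2) }
      t_ls <- 1
      repeat {
        cand <- q
        cand[free, ] <- q[free, ] + t_ls * matrix(step, nf, 2, byrow = TRUE)
        obj <- f_of(cand)
        if (obj <= prev_obj + 1e-4 * t_ls * dir_deriv || t_ls < 1e-12) break
        t_ls <- t_ls / 2
      }
      if (prev_obj - obj < 1e-6) {  # Newton stride collapsed: try IRLS too
        u1 <- q[e1, 1] - q[e2, 1]; u2 <- q[e1, 2] - q[e2, 2]
        cand_i <- irls_step(q, 1 / sqrt(u1 * u1 + u2 * u2 + eps * eps))
        obj_i <- f_of(cand_i)
        if (obj_i < obj) { cand <- cand_i; obj <- obj_i }
      }
      iters <- iters + 1L
      if (obj > prev_obj) break       # no improving step: converged
      q <- cand
      objs <- c(objs, obj)
      change <- prev_obj - obj
      prev_obj <- obj
      if (change < tol_level || iters >= max_iter) break
    }
    list(q = q, iters = iters, objs = objs, converged = iters < max_iter)
  }

  # contract near-zero edges (vertex-type optima) and re-polish the reduced
  # problem at the final smoothing level; accept only if the unsmoothed
  # objective does not get worse
  snap_polish <- function(pos, n_tip, tol) {
    scale_l <- max(apply(pos[seq_len(n_tip), , drop = FALSE], 2,
                         function(v) diff(range(v))), 1e-12)
    unsmoothed <- function(q) {
      u1 <- q[epar, 1] - q[echi, 1]; u2 <- q[epar, 2] - q[echi, 2]
      sum(sqrt(u1 * u1 + u2 * u2))
    }
    obj_cur <- unsmoothed(pos)
    iters <- 0L
    for (thr in c(1e-2, 1e-3, 1e-4, 1e-5) * scale_l) {
      u1 <- pos[epar, 1] - pos[echi, 1]; u2 <- pos[epar, 2] - pos[echi, 2]
      short <- sqrt(u1 * u1 + u2 * u2) < thr
      if (!any(short)) next
      grp <- seq_len(nrow(pos))          # union-find over short edges
      find <- function(i) { while (grp[i] != i) i <- grp[i]; i }
      for (e in which(short)) {
        ra <- find(epar[e]); rb <- find(echi[e])
        if (ra != rb) grp[max(ra, rb)] <- min(ra, rb)
      }
      root_of <- vapply(seq_len(nrow(pos)), find, integer(1))
      reps <- unique(root_of)
      gid <- match(root_of, reps)
      gpos <- matrix(0, length(reps), 2)
      has_tip <- logical(length(reps))
      for (g in seq_along(reps)) {
        members <- which(gid == g)
        tips <- members[members <= n_tip]
        has_tip[g] <- length(tips) > 0
        gpos[g, ] <- if (has_tip[g]) pos[tips[1], ]
                     else colMeans(pos[members, , drop = FALSE])
      }
      keep <- gid[epar] != gid[echi]
      ge1 <- gid[epar[keep]]; ge2 <- gid[echi[keep]]
      free_g <- which(!has_tip)
      if (length(free_g) && length(ge1)) {
        res <- weber_level(gpos, free_g, ge1, ge2, eps = 1e-10,
                           tol_level = 1e-13, max_iter = 200L)
        gpos <- res$q
        iters <- iters + res$iters
      }
      cand <- gpos[gid, , drop = FALSE]
      obj_cand <- unsmoothed(cand)
      if (obj_cand <= obj_cur + tol) {  # contraction correct: accept
        pos <- cand
        obj_cur <- min(obj_cur, obj_cand)
        break
      }
      # rejected: a contracted edge was genuinely non-zero; retry finer
    }
    list(pos = pos, iters = iters)
  }

  schedule <- c(1e-3, 1e-5, 1e-7, 1e-10)
  sweeps <- 0L
  final_change <- 0
  trace <- vector("list", p)
  for (l in seq_len(p)) {
    pos <- cbind(X[, l], Y[, l])
    if (objective == "squared") {
      # squared-change optimum is the unit-weight harmonic (Laplacian)
      # solution, solved exactly in one step
      A <- matrix(0, n_int, n_int)
      B <- matrix(0, n_int, 2)
      for (e in seq_len(n_edge)) {
        ia <- epar[e] - n_tip; vb <- echi[e]
        A[ia, ia] <- A[ia, ia] + 1
        if (vb > n_tip) {
          ib <- vb - n_tip
          A[ib, ib] <- A[ib, ib] + 1
          A[ia, ib] <- A[ia, ib] - 1
          A[ib, ia] <- A[ib, ia] - 1
        } else {
          B[ia, ] <- B[ia, ] + pos[vb, ]
        }
      }
      pos[internal, ] <- solve(A, B)
      sweeps <- sweeps + 1L
    } else {
      tr_l <- list()
      for (eps in schedule) {
        budget <- max_sweeps - sweeps
        if (budget <= 0L) {
          abort(paste0("reconstruction did not converge in ", max_sweeps,
                       " sweeps; unconverged landmark index: ", l))
        }
        # per-level caps: Newton converges smooth optima in a handful of
        # iterations; the slow geometric crawl toward vertex-type optima is
        # finished off exactly by the contraction polish below
        res <- weber_level(pos, internal, epar, echi, eps,
                           tol_level = max(tol, 1e-2 * eps),
                           max_iter = min(budget, if (eps > 1e-8) 15L else 40L))
        pos <- res$q
        sweeps <- sweeps + res$iters
        tr_l[[length(tr_l) + 1L]] <- cbind(eps, res$objs)
      }
      polish <- snap_polish(pos, n_tip, tol)
      pos <- polish$pos
      sweeps <- sweeps + polish$iters
      u1 <- pos[epar, 1] - pos[echi, 1]; u2 <- pos[epar, 2] - pos[echi, 2]
      final_change <- max(final_change,
                          abs(tail(tr_l[[length(tr_l)]][, 2], 1) -
                                sum(sqrt(u1 * u1 + u2 * u2))))
      tr <- do.call(rbind, tr_l)
      trace[[l]] <- tibble::tibble(point = l, eps = tr[, 1], objective = tr[, 2])
    }
    X[, l] <- pos[, 1]; Y[, l] <- pos[, 2]
  }

  # tie-break: a two-neighbour internal node (e.g. the root of a rooted
  # binary tree) is optimal anywhere on the segment joining its neighbours;
  # report the midpoint. Branch-length sums are unchanged.
  deg <- tabulate(c(epar, echi[echi > n_tip]), nbins = n_node)
  for (i in internal[deg[internal] == 2]) {
    k <- c(echi[epar == i], epar[echi == i])
    X[i, ] <- colMeans(X[k, , drop = FALSE])
    Y[i, ] <- colMeans(Y[k, , drop = FALSE])
  }

  lens <- sqrt((X[epar, , drop = FALSE] - X[echi, , drop = FALSE])^2 +
                 (Y[epar, , drop = FALSE] - Y[echi, , drop = FALSE])^2)
  per_lm <- colSums(lens)
  tree_length <- sum(per_lm)

  # minimum conceivable length per landmark: Euclidean MST over terminals
  mst_len <- vapply(seq_len(p), function(l) {
    pts <- cbind(X[seq_len(n_tip), l], Y[seq_len(n_tip), l])
    mst_length(pts)
  }, numeric(1))
  ci <- if (tree_length <= .Machine$double.eps) 1 else sum(mst_len) / tree_length

  branch_lengths <- tibble::tibble(
    branch = rep(echi, times = p),
    parent = rep(epar, times = p),
    point = rep(seq_len(p), each = length(echi)),
    length = as.vector(lens)
  )
  ancestral <- tibble::tibble(
    node = rep(internal, each = p),
    point = rep(seq_len(p), times = length(internal)),
    x = as.vector(t(X[internal, , drop = FALSE])),
    y = as.vector(t(Y[internal, , drop = FALSE]))
  )
  structure(
    list(ancestral = ancestral,
         branch_lengths = branch_lengths,
         tree_length = tree_length,
         per_landmark_lengths = tibble::tibble(point = seq_len(p),
                                               length = per_lm,
                                               mst_length = mst_len),
         consistency_index = ci,
         tree = tree,
         tip_coords = lm_tibble(arr),
         objective = objective,
         convergence = list(sweeps = sweeps, final_change = final_change,
                            trace = if (objective == "squared") NULL
                                    else dplyr::bind_rows(trace))),
    class = "ancestral_recon"
  )
}

# Euclidean minimum spanning tree length (ape::mst; tiny n handled directly)
mst_length <- function(pts) {
  n <- nrow(pts)
  if (n < 2) return(0)
  D <- as.matrix(dist(pts))
  if (n == 2) return(D[1, 2])
  if (max(D) <= .Machine$double.eps) return(0)
  adj <- unclass(ape::mst(as.dist(D)))
  sum(D * adj) / 2
}

#' @export
print.ancestral_recon <- function(x, ...) {
  cat("<ancestral_recon> ", length(x$tree$tip.label), " terminals, ",
      x$tree$Nnode, " internal nodes; tree length = ",
      format(x$tree_length, digits = 8), ", CI = ",
      format(x$consistency_index, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Summed displacement of a landmark subset on one branch
#'
#' @param recon An `ancestral_recon`.
#' @param branch Branch id (child node).
#' @param subset Integer landmark indices (e.g. the scheme's medial subset);
#'   an empty subset returns 0.
#' @return Non-negative scalar.
#' @export
branch_subset_length <- function(recon, branch, subset) {
  stopifnot(inherits(recon, "ancestral_recon"))
  if (!length(subset)) return(0)
  subset <- as.integer(subset)
  p <- max(recon$branch_lengths$point)
  if (anyNA(subset) || any(subset < 1) || any(subset > p)) {
    abort("landmark indices out of range")
  }
  rows <- dplyr::filter(recon$branch_lengths,
                        .data$branch == !!branch, .data$point %in% subset)
  if (!nrow(rows)) abort(paste0("no such branch: ", branch))
  sum(rows$length)
}

#' Consistency index of a reconstruction
#'
#' Ratio of the summed per-landmark minimum conceivable lengths (the
#' Euclidean minimum spanning tree over each landmark's terminal positions)
#' to the realized tree length; 1 when the tree attains every landmark's
#' MST, lower with homoplasy. Defined as 1 for a zero-length tree. Because
#' ancestral (Steiner-type) nodes can realize a total length below the MST,
#' values slightly above 1 are possible for star-like optima.
#'
#' @param recon An `ancestral_recon`.
#' @return Positive scalar.
#' @export
consistency_index <- function(recon) {
  stopifnot(inherits(recon, "ancestral_recon"))
  recon$consistency_index
}

#' Per-landmark displacement vectors along a branch
#'
#' Child-node position minus parent-node position for every landmark —
#' the ancestor-descendant transformation arrows. Vector norms equal the
#' stored per-branch landmark lengths.
#'
#' @param recon An `ancestral_recon`.
#' @param branch Branch id (child node; a tip index gives the terminal
#'   branch).
#' @return Tibble `point`, `dx`, `dy`, `length`.
#' @export
displacement_vectors <- function(recon, branch) {
  stopifnot(inherits(recon, "ancestral_recon"))
  rows <- dplyr::filter(recon$branch_lengths, .data$branch == !!branch)
  if (!nrow(rows)) abort(paste0("no such branch: ", branch))
  parent <- rows$parent[1]
  get_pos <- function(node) {
    n_tip <- length(recon$tree$tip.label)
    if (node <= n_tip) {
      d <- dplyr::filter(recon$tip_coords,
                         .data$specimen == recon$tree$tip.label[node])
      if (!nrow(d)) abort(paste0("missing terminal data for node ", node))
      dplyr::arrange(d, .data$point)[, c("x", "y")]
    } else {
      dplyr::arrange(dplyr::filter(recon$ancestral, .data$node == !!node),
                     .data$point)[, c("x", "y")]
    }
  }
  child_pos <- get_pos(branch); parent_pos <- get_pos(parent)
  dx <- child_pos$x - parent_pos$x
  dy <- child_pos$y - parent_pos$y
  tibble::tibble(point = seq_along(dx), dx = dx, dy = dy,
                 length = sqrt(dx^2 + dy^2))
}

#' @export
tidy.ancestral_recon <- function(x, ...) x$branch_lengths

#' @export
glance.ancestral_recon <- function(x, ...) {
  tibble::tibble(
    tree_length = x$tree_length,
    consistency_index = x$consistency_index,
    n_terminals = length(x$tree$tip.label),
    n_internal = x$tree$Nnode,
    sweeps = x$convergence$sweeps,
    objective = x$objective
  )
}

#' @export
autoplot.ancestral_recon <- function(object, ...) {
  anc <- dplyr::mutate(object$ancestral, role = "ancestral")
  tips <- dplyr::mutate(dplyr::rename(object$tip_coords, node = "specimen"),
                        role = "terminal")
  dat <- dplyr::bind_rows(anc, dplyr::mutate(tips, node = as.character(.data$node)))
  ggplot2::ggplot(dat, ggplot2::aes(.data$x, .data$y, colour = .data$role)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Terminal and reconstructed ancestral configurations")
}
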