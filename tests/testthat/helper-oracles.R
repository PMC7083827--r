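# independent brute-force oracles; these never call the solvers they check

# ---- GPA consensus oracle (3 unit-normalized configurations) -------------
# GPA of unit-size centred configurations maximizes ||y1+y2+y3||^2 over the
# rotations of configurations 2 and 3 (configuration 1 pins the gauge);
# pairwise dot products are trigonometric in the angles, so an exhaustive
# angle grid is cheap: full sweep at 1e-2 rad, then a local window at 1e-4.
oracle_gpa_consensus <- function(m1, m2, m3) {
  norm1 <- function(m) { m <- sweep(m, 2, colMeans(m)); m / sqrt(sum(m^2)) }
  m1 <- norm1(m1); m2 <- norm1(m2); m3 <- norm1(m3)
  # y_j = R(theta_j) applied to rows: dot(y_i, y_j) = a cos(t) + b sin(t)
  dot_coeffs <- function(A, B) {  # dot(A, R(t) B) over row pairs
    c(a = sum(A * B), b = sum(A[, 2] * B[, 1] - A[, 1] * B[, 2]))
  }
  c12 <- dot_coeffs(m1, m2)
  c13 <- dot_coeffs(m1, m3)
  c23 <- dot_coeffs(m2, m3)  # dot(R(t2)m2, R(t3)m3) depends on t3 - t2
  score <- function(t2, t3) {
    3 + 2 * (c12["a"] * cos(t2) + c12["b"] * sin(t2) +
             c13["a"] * cos(t3) + c13["b"] * sin(t3) +
             c23["a"] * cos(t3 - t2) + c23["b"] * sin(t3 - t2))
  }
  sweep_grid <- function(t2s, t3s) {
    sc <- outer(t2s, t3s, score)
    ij <- arrayInd(which.max(sc), dim(sc))
    c(t2s[ij[1]], t3s[ij[2]])
  }
  coarse <- seq(0, 2 * pi, by = 1e-2)
  best <- sweep_grid(coarse, coarse)
  fine2 <- seq(best[1] - 2e-2, best[1] + 2e-2, by = 1e-4)
  fine3 <- seq(best[2] - 2e-2, best[2] + 2e-2, by = 1e-4)
  best <- sweep_grid(fine2, fine3)
  fine2 <- seq(best[1] - 2e-4, best[1] + 2e-4, by = 1e-6)
  fine3 <- seq(best[2] - 2e-4, best[2] + 2e-4, by = 1e-6)
  best <- sweep_grid(fine2, fine3)
  rot_rows <- function(m, t) m %*% rbind(c(cos(t), sin(t)), c(-sin(t), cos(t)))
  (m1 + rot_rows(m2, best[1]) + rot_rows(m3, best[2])) / 3
}

# optimally rotate shape A onto B (closed form, for modulo-rotation compare)
align_rotation_closed_form <- function(A, B) {
  theta <- atan2(sum(A[, 1] * B[, 2] - A[, 2] * B[, 1]), sum(A * B))
  A %*% rbind(c(cos(theta), sin(theta)), c(-sin(theta), cos(theta)))
}

# ---- minimum-distance superimposition oracle -----------------------------
# rotation grid (coarse 1e-2 rad then local 1e-4) with the translation
# refined per rotation by Nelder-Mead on the convex L1 objective
oracle_min_dist <- function(X, ref) {
  obj_at <- function(theta) {
    Xr <- X %*% rbind(c(cos(theta), sin(theta)), c(-sin(theta), cos(theta)))
    resid <- ref - Xr
    f <- function(t) sum(sqrt((resid[, 1] - t[1])^2 + (resid[, 2] - t[2])^2))
    stats::optim(colMeans(resid), f, method = "Nelder-Mead",
                 control = list(reltol = 1e-12, maxit = 2000))$value
  }
  coarse <- seq(0, 2 * pi, by = 1e-2)
  v <- vapply(coarse, obj_at, numeric(1))
  t0 <- coarse[which.min(v)]
  fine <- seq(t0 - 2e-2, t0 + 2e-2, by = 1e-4)
  vf <- vapply(fine, obj_at, numeric(1))
  min(vf)
}

# ---- fixed-topology Weber problem oracle ---------------------------------
# single landmark in [0,1]^2: iterated exhaustive per-node grid search
# (coarse 5e-3 full square, then 1e-3 local window), cycled to a joint fixed
# point from several starts; independent of the Newton solver
oracle_weber_grid <- function(tree, tip_xy, n_starts = 3, seed = 1) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  internal <- seq(n_tip + 1, n_node)
  epar <- tree$edge[, 1]; echi <- tree$edge[, 2]
  total_len <- function(pos) {
    sum(sqrt(rowSums((pos[epar, , drop = FALSE] - pos[echi, , drop = FALSE])^2)))
  }
  nbrs <- lapply(seq_len(n_node), function(i) {
    c(epar[echi == i], echi[epar == i])
  })
  grid_min <- function(xs, ys, targets) {
    gx <- rep(xs, times = length(ys)); gy <- rep(ys, each = length(xs))
    tot <- 0
    for (k in seq_len(nrow(targets))) {
      tot <- tot + sqrt((gx - targets[k, 1])^2 + (gy - targets[k, 2])^2)
    }
    i <- which.min(tot)
    c(gx[i], gy[i])
  }
  coarse <- seq(0, 1, by = 5e-3)
  best_len <- Inf; best_pos <- NULL
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  for (s in seq_len(n_starts)) {
    pos <- matrix(0, n_node, 2)
    pos[seq_len(n_tip), ] <- tip_xy
    pos[internal, 1] <- if (s == 1) mean(tip_xy[, 1]) else stats::runif(length(internal))
    pos[internal, 2] <- if (s == 1) mean(tip_xy[, 2]) else stats::runif(length(internal))
    node_update <- function(i, pos) {
      tg <- pos[nbrs[[i]], , drop = FALSE]
      cand <- grid_min(coarse, coarse, tg)
      fx <- seq(max(0, cand[1] - 5e-3), min(1, cand[1] + 5e-3), by = 1e-3)
      fy <- seq(max(0, cand[2] - 5e-3), min(1, cand[2] + 5e-3), by = 1e-3)
      grid_min(fx, fy, tg)
    }
    repeat {
      repeat {
        len_before <- total_len(pos)
        for (i in internal) {
          cur <- total_len(pos)
          saved <- pos[i, ]
          pos[i, ] <- node_update(i, pos)
          # keep strict improvements only (grid ties could cycle forever)
          if (total_len(pos) >= cur - 1e-12) pos[i, ] <- saved
        }
        if (total_len(pos) >= len_before - 1e-12) break
      }
      # per-node moves stall when several internal nodes must move in
      # lockstep (coincident clusters, or parallel-translation valleys the
      # per-node grid zigzag cannot descend): for every connected internal
      # subset, grid-search a common translation of the whole subset —
      # only boundary edges change, so the shift objective is a Weber
      # problem over the boundary difference vectors
      improved <- FALSE
      for (S in connected_internal_subsets(internal, e1 = epar, e2 = echi)) {
        inS <- seq_len(n_node) %in% S
        bnd_in <- c(epar[inS[epar] & !inS[echi]], echi[!inS[epar] & inS[echi]])
        bnd_out <- c(echi[inS[epar] & !inS[echi]], epar[!inS[epar] & inS[echi]])
        if (!length(bnd_in)) next
        diffs <- pos[bnd_out, , drop = FALSE] - pos[bnd_in, , drop = FALSE]
        rng <- range(diffs)
        xs <- seq(rng[1] - 5e-3, rng[2] + 5e-3, length.out = 201)
        cand <- grid_min(xs, xs, diffs)
        fx <- seq(cand[1] - diff(rng) / 100, cand[1] + diff(rng) / 100, by = 1e-3)
        fy <- seq(cand[2] - diff(rng) / 100, cand[2] + diff(rng) / 100, by = 1e-3)
        cand <- grid_min(fx, fy, diffs)
        old_len <- total_len(pos)
        saved <- pos[S, , drop = FALSE]
        pos[S, 1] <- pos[S, 1] + cand[1]; pos[S, 2] <- pos[S, 2] + cand[2]
        if (total_len(pos) < old_len - 1e-9) improved <- TRUE
        else pos[S, ] <- saved
      }
      if (!improved) break
    }
    len <- total_len(pos)
    if (len < best_len) { best_len <- len; best_pos <- pos }
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  list(length = best_len, pos = best_pos)
}

# all subsets of the internal nodes that are connected through
# internal-internal edges (small trees: brute-force enumeration)
connected_internal_subsets <- function(internal, e1, e2) {
  k <- length(internal)
  out <- list()
  for (mask in 1:(2^k - 1)) {
    S <- internal[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0]
    if (length(S) == 1) { out[[length(out) + 1L]] <- S; next }
    # connectivity over edges internal to S
    reach <- S[1]
    repeat {
      grow <- unique(c(e2[e1 %in% reach & e2 %in% S],
                       e1[e2 %in% reach & e1 %in% S]))
      new_reach <- union(reach, grow)
      if (length(new_reach) == length(reach)) break
      reach <- new_reach
    }
    if (setequal(reach, S)) out[[length(out) + 1L]] <- S
  }
  out
}

# random single-landmark Weber instance on a 3-5 leaf topology
random_weber_instance <- function() {
  n <- sample(3:5, 1)
  tree <- ape::rtree(n, br = NULL)
  tip_xy <- matrix(stats::runif(2 * n), n, 2)
  list(tree = tree, tip_xy = tip_xy)
}

# run the package solver on a single-landmark instance (pads with two
# anchor points so configurations meet the 3-point minimum; anchors are
# identical across taxa, so they contribute zero length)
solver_weber_length <- function(tree, tip_xy) {
  configs <- lapply(seq_len(nrow(tip_xy)), function(i) {
    rbind(tip_xy[i, ], c(100, 100), c(101, 100))
  })
  names(configs) <- tree$tip.label
  recon <- reconstruct_ancestral(lm_table(configs), tree)
  recon$per_landmark_lengths$length[1]
}
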