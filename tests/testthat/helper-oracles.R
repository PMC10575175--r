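# Independent oracles used to cross-check the implementation.  Each is coded
# from first principles, separately from the package's own code paths.

# Step-by-step pinhole projection: explicit camera basis, world-to-camera
# transform, perspective divide, intrinsic map.
oracle_project_point <- function(point, cam_pos, look_at, up, f, cc) {
  fwd <- look_at - cam_pos
  fwd <- fwd / sqrt(sum(fwd^2))
  right <- c(fwd[2] * up[3] - fwd[3] * up[2],
             fwd[3] * up[1] - fwd[1] * up[3],
             fwd[1] * up[2] - fwd[2] * up[1])
  right <- right / sqrt(sum(right^2))
  down <- c(fwd[2] * right[3] - fwd[3] * right[2],
            fwd[3] * right[1] - fwd[1] * right[3],
            fwd[1] * right[2] - fwd[2] * right[1])
  rel <- point - cam_pos
  xc <- sum(rel * right)
  yc <- sum(rel * down)
  zc <- sum(rel * fwd)
  c(f * xc / zc + cc[1], f * yc / zc + cc[2])
}

# Dense-sampling point-to-segment distance: minimum over points interpolated
# along the segment.
oracle_segment_distance <- function(p, a, b, n = 1e5) {
  t <- seq(0, 1, length.out = n)
  px <- a[1] + t * (b[1] - a[1])
  py <- a[2] + t * (b[2] - a[2])
  sqrt(min((p[1] - px)^2 + (p[2] - py)^2))
}

# Double loop over pixels and joints, scalar arithmetic only.
oracle_joint_heatmap <- function(joints, H, W, sigma) {
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      x <- j - 1; y <- i - 1
      for (k in seq_len(nrow(joints))) {
        d2 <- (x - joints[k, 1])^2 + (y - joints[k, 2])^2
        out[i, j] <- out[i, j] + exp(-d2 / sigma^2)
      }
    }
  }
  out
}

oracle_bone_heatmap <- function(joints, bones, H, W, sigma, n = 2000) {
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      x <- j - 1; y <- i - 1
      for (b in seq_len(nrow(bones))) {
        d <- oracle_segment_distance(c(x, y), joints[bones[b, 1], ],
                                     joints[bones[b, 2], ], n = n)
        out[i, j] <- out[i, j] + exp(-d^2 / sigma^2)
      }
    }
  }
  out
}

# Per-class metrics coded independently: explicit TP/FP/FN counting loops.
oracle_metrics <- function(truth, pred, k) {
  prec <- rec <- f1 <- numeric(k)
  for (c in seq_len(k) - 1L) {
    tp <- sum(truth == c & pred == c)
    fp <- sum(truth != c & pred == c)
    fn <- sum(truth == c & pred != c)
    prec[c + 1] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[c + 1] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[c + 1] <- if (prec[c + 1] + rec[c + 1] > 0)
      2 * prec[c + 1] * rec[c + 1] / (prec[c + 1] + rec[c + 1]) else 0
  }
  list(macro_precision = mean(prec), macro_recall = mean(rec),
       macro_f1 = mean(f1), accuracy = mean(truth == pred))
}

# Two blobs in opposite corners: trivially separable volumes for capacity
# checks.
make_separable_volumes <- function(n, dims = c(8L, 24L, 24L), seed = 1L) {
  set.seed(seed)
  vols <- vector("list", n)
  labels <- integer(n)
  for (i in seq_len(n)) {
    a <- array(0, dims)
    cls <- (i - 1L) %% 2L
    if (cls == 0L) a[, 3:8, 3:8] <- 1 else a[, 14:20, 14:20] <- 1
    vols[[i]] <- a + array(rnorm(length(a), 0, 0.05), dims)
    labels[i] <- cls
  }
  list(volumes = vols, labels = labels)
}

tiny_model_config <- function(...) {
  slowfast_config(base_channels = 8L, fast_channel_fraction = 0.25,
                  stage_depths = c(1L, 1L), ...)
}
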