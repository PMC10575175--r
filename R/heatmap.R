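#' Heatmap volume configuration
#'
#' Controls the conversion of a 2D skeleton clip into a `T x H x W` heatmap
#' volume: subject-centred cropping, uniform temporal sampling, then a
#' per-frame Gaussian map.  The per-pixel value is
#' `sum_k exp(-D(i,j,k)^2 / sigma^2)` over joints (joint map) or bone
#' segments (bone map), where `D` is the Euclidean distance to the joint, or
#' the shortest distance to the segment.  The denominator (`sigma^2` vs
#' `2 sigma^2`) and the accumulation rule (`sum` vs `max` over joints/bones)
#' are switchable; the defaults follow the bare-sum, `sigma^2` form.
#'
#' @param sigma Gaussian width, output-grid pixels.
#' @param out_height,out_width Output grid size `H`, `W`.
#' @param num_frames_out Temporal length `T` after uniform sampling.
#' @param padding_fraction Bounding-box padding per side (fraction of the
#'   box size) applied before cropping.
#' @param sampling_mode `"center"` (deterministic bin centres) or `"random"`
#'   (seeded random index within each bin, for training augmentation).
#' @param map_type `"joint"` or `"bone"`.
#' @param accumulate `"sum"` or `"max"` over joints/bones.
#' @param denominator `"sigma2"` or `"2sigma2"`.
#' @return A `heatmap_config` object.
#' @export
heatmap_config <- function(sigma = 1.5, out_height = 64L, out_width = 64L,
                           num_frames_out = 12L, padding_fraction = 0.1,
                           sampling_mode = c("center", "random"),
                           map_type = c("joint", "bone"),
                           accumulate = c("sum", "max"),
                           denominator = c("sigma2", "2sigma2")) {
  structure(list(
    sigma = check_number(sigma, "sigma", 0, strict_lower = TRUE),
    out_height = check_number(out_height, "out_height", 1, integer = TRUE),
    out_width = check_number(out_width, "out_width", 1, integer = TRUE),
    num_frames_out = check_number(num_frames_out, "num_frames_out", 1,
                                  integer = TRUE),
    padding_fraction = check_number(padding_fraction, "padding_fraction", 0),
    sampling_mode = match.arg(sampling_mode),
    map_type = match.arg(map_type),
    accumulate = match.arg(accumulate),
    denominator = match.arg(denominator)
  ), class = "heatmap_config")
}

#' Distance from a point to a closed line segment
#'
#' Euclidean distance from `p` to the segment `[a, b]`; for coincident
#' endpoints, the distance to the point.
#'
#' @param p,a,b Numeric 2-vectors (pixels).
#' @return Non-negative scalar distance.
#' @examples
#' point_segment_distance(c(5, 5), c(0, 0), c(10, 0)) # 5
#' @export
point_segment_distance <- function(p, a, b) {
  check_finite_array(c(p, a, b), "p, a, b")
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(sum((p - a)^2)))
  t <- max(0, min(1, sum((p - a) * ab) / len2))
  sqrt(sum((p - a - t * ab)^2))
}

# squared distances from every grid pixel to segment [a, b]; px/py are the
# flattened pixel-centre coordinate vectors
segment_dist2_grid <- function(px, py, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return((px - a[1L])^2 + (py - a[2L])^2)
  t <- pmin(1, pmax(0, ((px - a[1L]) * ab[1L] + (py - a[2L]) * ab[2L]) / len2))
  (px - a[1L] - t * ab[1L])^2 + (py - a[2L] - t * ab[2L])^2
}

heatmap_denom <- function(sigma, denominator) {
  if (denominator == "2sigma2") 2 * sigma^2 else sigma^2
}

#' Single-frame joint heatmap
#'
#' Pixel `(i, j)` (centres at integer 0-based coordinates, x = column,
#' y = row) holds the accumulated Gaussian `exp(-D^2 / sigma^2)` over all
#' joints, where `D` is the distance from the pixel centre to the joint.
#'
#' @param joints2d N x 2 matrix of joint pixel coordinates.
#' @param grid `(H, W)` output size.
#' @param sigma Gaussian width in pixels.
#' @param accumulate `"sum"` (default) or `"max"`.
#' @param denominator `"sigma2"` (default) or `"2sigma2"`.
#' @return H x W numeric matrix (rows = y).
#' @export
joint_heatmap_frame <- function(joints2d, grid, sigma,
                                accumulate = "sum", denominator = "sigma2") {
  joints2d <- rbind(joints2d)
  H <- grid[1L]; W <- grid[2L]
  px <- rep(seq_len(W) - 1, each = H)
  py <- rep(seq_len(H) - 1, times = W)
  den <- heatmap_denom(sigma, denominator)
  acc <- matrix(0, H, W)
  for (k in seq_len(nrow(joints2d))) {
    d2 <- (px - joints2d[k, 1L])^2 + (py - joints2d[k, 2L])^2
    g <- matrix(exp(-d2 / den), H, W)
    acc <- if (accumulate == "max") pmax(acc, g) else acc + g
  }
  acc
}

#' Single-frame bone heatmap
#'
#' Pixel values accumulate `exp(-d^2 / sigma^2)` over bone segments, with
#' `d` the shortest distance from the pixel centre to the segment joining
#' the bone's two joints.
#'
#' @param joints2d N x 2 matrix of joint pixel coordinates.
#' @param topology A [joint_topology()] providing the bone list.
#' @param grid `(H, W)` output size.
#' @inheritParams joint_heatmap_frame
#' @return H x W numeric matrix.
#' @export
bone_heatmap_frame <- function(joints2d, topology, grid, sigma,
                               accumulate = "sum", denominator = "sigma2") {
  joints2d <- rbind(joints2d)
  H <- grid[1L]; W <- grid[2L]
  px <- rep(seq_len(W) - 1, each = H)
  py <- rep(seq_len(H) - 1, times = W)
  den <- heatmap_denom(sigma, denominator)
  acc <- matrix(0, H, W)
  for (b in seq_len(nrow(topology$bones))) {
    a <- joints2d[topology$bones[b, 1L], ]
    bb <- joints2d[topology$bones[b, 2L], ]
    g <- matrix(exp(-segment_dist2_grid(px, py, a, bb) / den), H, W)
    acc <- if (accumulate == "max") pmax(acc, g) else acc + g
  }
  acc
}

#' Subject-centred crop of a 2D skeleton clip
#'
#' Computes the minimal axis-aligned bounding box enclosing every joint over
#' all frames of the clip, expands it by `padding_fraction` of its size per
#' side, and maps the keypoints affinely onto the `(H, W)` output grid with
#' a single uniform scale (aspect preserved, letterboxed and centred).
#'
#' @param seq2d A `skeleton2d` sequence.
#' @param padding_fraction Padding per side as a fraction of box size.
#' @param out_size Output grid `(H, W)`.
#' @return List with the transformed `skeleton2d` (`$sequence`), the padded
#'   crop box (`$crop_box` = xmin, xmax, ymin, ymax) and the affine scale.
#' @export
subject_centered_crop <- function(seq2d, padding_fraction = 0.1,
                                  out_size = c(64L, 64L)) {
  if (!inherits(seq2d, "skeleton2d"))
    stop_validation("`seq2d` must be a skeleton2d sequence")
  H <- out_size[1L]; W <- out_size[2L]
  xs <- seq2d$pixels[, , 1L]; ys <- seq2d$pixels[, , 2L]
  box <- c(min(xs), max(xs), min(ys), max(ys))
  wbox <- box[2L] - box[1L]; hbox <- box[4L] - box[3L]
  if (wbox <= 0 && hbox <= 0)
    stop_validation("degenerate clip: all keypoints coincide (zero-area box)")
  box <- box + c(-1, 1, -1, 1) * padding_fraction * c(wbox, wbox, hbox, hbox)
  wpad <- box[2L] - box[1L]; hpad <- box[4L] - box[3L]
  sx <- if (wpad > 0) (W - 1) / wpad else Inf
  sy <- if (hpad > 0) (H - 1) / hpad else Inf
  s <- min(sx, sy)
  cx <- (box[1L] + box[2L]) / 2; cy <- (box[3L] + box[4L]) / 2
  out <- seq2d
  out$pixels[, , 1L] <- (xs - cx) * s + (W - 1) / 2
  out$pixels[, , 2L] <- (ys - cy) * s + (H - 1) / 2
  out$image_size <- as.integer(c(H, W))
  list(sequence = out, crop_box = box, scale = s)
}

#' Uniformly sample frame indices
#'
#' Partitions the input frames `[0, T_in)` into `T_out` equal contiguous
#' bins and picks one index per bin: the bin centre in `"center"` mode
#' (deterministic), or a seeded uniform draw within the bin in `"random"`
#' mode.  When `T_in < T_out` empty bins repeat their boundary index.
#'
#' @param num_frames_in,num_frames_out Input and output frame counts.
#' @param mode `"center"` or `"random"`.
#' @param seed Seed for `"random"` mode.
#' @return Non-decreasing integer vector of `T_out` 0-based frame indices.
#' @examples
#' uniform_sample(100, 10) # 5 15 25 ... 95
#' @export
uniform_sample <- function(num_frames_in, num_frames_out,
                           mode = c("center", "random"), seed = 1L) {
  t_in <- check_number(num_frames_in, "num_frames_in", 1, integer = TRUE)
  t_out <- check_number(num_frames_out, "num_frames_out", 1, integer = TRUE)
  mode <- match.arg(mode)
  bounds <- floor(seq_len(t_out + 1L) - 1) * t_in / t_out
  lo <- floor(bounds[-(t_out + 1L)])
  hi <- pmax(lo, ceiling(bounds[-1L]) - 1)
  if (mode == "center") {
    idx <- lo + floor((hi - lo + 1) / 2)
    idx <- pmin(idx, hi)
  } else {
    idx <- with_seed(seed, {
      vapply(seq_len(t_out), function(k) {
        if (hi[k] > lo[k]) sample(lo[k]:hi[k], 1L) else lo[k]
      }, numeric(1L))
    })
  }
  as.integer(pmin(idx, t_in - 1L))
}

#' Build a heatmap volume from a 2D skeleton clip
#'
#' Runs the full conversion: subject-centred crop, uniform temporal
#' sampling to `T` frames, then a per-frame joint or bone heatmap, yielding
#' a `T x H x W` single-channel pseudo-video.
#'
#' @param seq2d A `skeleton2d` sequence.
#' @param topology A [joint_topology()] (needed for bone maps).
#' @param config A [heatmap_config()].
#' @param seed Seed used when `sampling_mode = "random"`.
#' @return A `heatmap_volume`: list with `values` (T x H x W array),
#'   `map_type`, `action_label`, `subject_id`, `viewpoint_deg`.
#' @export
build_volume <- function(seq2d, topology = default_topology(),
                         config = heatmap_config(), seed = 1L) {
  cropped <- subject_centered_crop(seq2d, config$padding_fraction,
                                   c(config$out_height, config$out_width))$sequence
  nf <- dim(cropped$pixels)[1L]
  idx <- uniform_sample(nf, config$num_frames_out, config$sampling_mode, seed)
  vol <- array(0, dim = c(config$num_frames_out, config$out_height,
                          config$out_width))
  grid <- c(config$out_height, config$out_width)
  for (t in seq_along(idx)) {
    j2d <- cropped$pixels[idx[t] + 1L, , , drop = TRUE]
    vol[t, , ] <- if (config$map_type == "bone")
      bone_heatmap_frame(j2d, topology, grid, config$sigma,
                         config$accumulate, config$denominator)
    else
      joint_heatmap_frame(j2d, grid, config$sigma,
                          config$accumulate, config$denominator)
  }
  structure(list(values = vol, map_type = config$map_type,
                 action_label = seq2d$action_label,
                 subject_id = seq2d$subject_id,
                 viewpoint_deg = seq2d$viewpoint_deg),
            class = "heatmap_volume")
}

#' @export
print.heatmap_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<heatmap_volume> %s map, %d x %d x %d (T x H x W), action %s, view %s deg\n",
              x$map_type, d[1L], d[2L], d[3L],
              format(x$action_label), format(x$viewpoint_deg)))
  invisible(x)
}
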