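#' Synthetic motion generator configuration
#'
#' The generator emulates the structure of a motion-capture unit-action
#' corpus: `num_subjects x num_actions x num_repetitions` clips of a 16-joint
#' skeleton.  Each action class is a fixed procedural "limb program"
#' (class-specific set of active bones, each swung sinusoidally about a
#' class-specific axis with its own amplitude, frequency and phase, layered
#' on a standing pose); each subject carries a fixed limb-length scale and
#' speed factor; repetitions differ by phase jitter; per-frame isotropic
#' Gaussian noise models sensor error.
#'
#' @param num_subjects,num_actions,num_repetitions Corpus dimensions.  The
#'   full-scale corpus is 40 x 16 x 12 (7680 clips); the default is a
#'   reduced 6 x 16 x 3 so the whole pipeline runs quickly on one CPU.
#' @param frames_per_clip Frames per clip (>= 2).
#' @param frame_rate Sampling rate, Hz.
#' @param noise_std Per-coordinate Gaussian sensor noise, metres.
#' @param subject_scale_range Range of the per-subject limb-length scale.
#' @param speed_jitter Fractional spread of the per-subject speed factor.
#' @param seed Integer seed; the full dataset is reproducible from it.
#' @return A `generator_config` object.
#' @export
generator_config <- function(num_subjects = 6L, num_actions = 16L,
                             num_repetitions = 3L, frames_per_clip = 48L,
                             frame_rate = 24, noise_std = 0.01,
                             subject_scale_range = c(0.92, 1.08),
                             speed_jitter = 0.1, seed = 1L) {
  cfg <- list(
    num_subjects = check_number(num_subjects, "num_subjects", 1, integer = TRUE),
    num_actions = check_number(num_actions, "num_actions", 1, integer = TRUE),
    num_repetitions = check_number(num_repetitions, "num_repetitions", 1,
                                   integer = TRUE),
    frames_per_clip = check_number(frames_per_clip, "frames_per_clip", 2,
                                   integer = TRUE),
    frame_rate = check_number(frame_rate, "frame_rate", 0, strict_lower = TRUE),
    noise_std = check_number(noise_std, "noise_std", 0),
    subject_scale_range = as.numeric(subject_scale_range),
    speed_jitter = check_number(speed_jitter, "speed_jitter", 0),
    seed = check_number(seed, "seed", integer = TRUE)
  )
  if (length(cfg$subject_scale_range) != 2L ||
      cfg$subject_scale_range[1L] > cfg$subject_scale_range[2L])
    stop_validation("`subject_scale_range` must be (min, max) with min <= max")
  structure(cfg, class = "generator_config")
}

# Standing rest pose for the canonical 16-joint skeleton, metres, world z
# vertical, origin at the pelvis.
canonical_rest_pose <- function() {
  rbind(
    head       = c( 0.00, 0, 0.70),
    neck       = c( 0.00, 0, 0.50),
    spine      = c( 0.00, 0, 0.25),
    pelvis     = c( 0.00, 0, 0.00),
    l_shoulder = c( 0.20, 0, 0.45),
    r_shoulder = c(-0.20, 0, 0.45),
    l_elbow    = c( 0.25, 0, 0.15),
    r_elbow    = c(-0.25, 0, 0.15),
    l_wrist    = c( 0.27, 0,-0.10),
    r_wrist    = c(-0.27, 0,-0.10),
    l_hip      = c( 0.12, 0,-0.05),
    r_hip      = c(-0.12, 0,-0.05),
    l_knee     = c( 0.13, 0,-0.50),
    r_knee     = c(-0.13, 0,-0.50),
    l_ankle    = c( 0.14, 0,-0.92),
    r_ankle    = c(-0.14, 0,-0.92)
  )
}

# Rest pose for an arbitrary topology: canonical when the joint names match,
# otherwise a reproducible random tree embedding with 0.3 m bones.
rest_pose_for <- function(topology) {
  canon <- canonical_rest_pose()
  if (identical(topology$joint_names, rownames(canon))) return(unname(canon))
  n <- length(topology$joint_names)
  pose <- matrix(0, n, 3L)
  for (b in seq_len(nrow(topology$bones))) {
    dir <- with_seed(derive_seed(4242L, b), stats::rnorm(3L))
    dir <- dir / sqrt(sum(dir^2))
    edge <- oriented_bones_from_root(topology)[b, ]
    pose[edge[2L], ] <- pose[edge[1L], ] + 0.3 * dir
  }
  pose
}

# Orients the bone list away from the root and returns it in traversal order
# (parents always before children).
oriented_bones_from_root <- function(topology) {
  n <- length(topology$joint_names)
  bones <- topology$bones
  adj <- vector("list", n)
  for (b in seq_len(nrow(bones))) {
    i <- bones[b, 1L]; j <- bones[b, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  ordered <- matrix(0L, nrow(bones), 2L)
  seen <- logical(n)
  seen[topology$root] <- TRUE
  queue <- topology$root
  k <- 0L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        k <- k + 1L
        ordered[k, ] <- c(v, w)
        queue <- c(queue, w)
      }
    }
  }
  ordered
}

# Class-specific limb program: which bones move, and how.  Seeded only by the
# class index so a given class always has the same kinematic signature.
action_template <- function(class_id, num_bones) {
  with_seed(derive_seed(7777L, class_id), {
    n_active <- 4L + class_id %% 3L
    active <- sample.int(num_bones, min(n_active, num_bones))
    axes <- matrix(stats::rnorm(3L * length(active)), ncol = 3L)
    axes <- axes / sqrt(rowSums(axes^2))
    list(active = active,
         axis = axes,
         amplitude = stats::runif(length(active), 0.35, 0.9),   # rad
         frequency = stats::runif(length(active), 0.5, 1.8),    # Hz
         phase = stats::runif(length(active), 0, 2 * pi),
         sway_amp = stats::runif(1L, 0.01, 0.05),               # m
         sway_freq = stats::runif(1L, 0.2, 0.6))                # Hz
  })
}

# Rodrigues rotation of a single offset vector about axis `n` by per-frame
# angles `theta` (vectorized over frames).
rotate_offsets <- function(v, n, theta) {
  cross <- c(n[2L] * v[3L] - n[3L] * v[2L],
             n[3L] * v[1L] - n[1L] * v[3L],
             n[1L] * v[2L] - n[2L] * v[1L])
  dot <- sum(n * v)
  outer(cos(theta), v) + outer(sin(theta), cross) +
    outer(1 - cos(theta), n * dot)
}

#' Generate a synthetic skeleton motion dataset
#'
#' @param config A [generator_config()].
#' @param topology A [joint_topology()]; defaults to the 16-joint skeleton.
#' @return A [skeleton_dataset()] with
#'   `num_subjects * num_actions * num_repetitions` sequences.  Subject ids
#'   are `"s01" ...`; action labels are `0 .. num_actions-1`; repetitions
#'   `0 .. num_repetitions-1`.  With `noise_std = 0` the bone lengths of each
#'   clip are constant over time (rigid-limb forward kinematics).
#' @examples
#' ds <- generate_dataset(generator_config(num_subjects = 2, num_actions = 3,
#'                                         num_repetitions = 1))
#' length(ds) # 6
#' @export
generate_dataset <- function(config, topology = default_topology()) {
  if (!inherits(config, "generator_config"))
    config <- do.call(generator_config, as.list(config))
  if (!inherits(topology, "joint_topology"))
    stop_validation("`topology` must be a joint_topology")
  nj <- length(topology$joint_names)
  edges <- oriented_bones_from_root(topology)
  nb <- nrow(edges)
  rest <- rest_pose_for(topology)
  rest <- sweep(rest, 2L, rest[topology$root, ])  # origin at rest-pose root
  templates <- lapply(seq_len(config$num_actions) - 1L, action_template,
                      num_bones = nb)
  subj_params <- lapply(seq_len(config$num_subjects), function(s) {
    with_seed(derive_seed(config$seed, 1000000L + s), list(
      scale = stats::runif(1L, config$subject_scale_range[1L],
                           config$subject_scale_range[2L]),
      speed = stats::runif(1L, 1 - config$speed_jitter,
                           1 + config$speed_jitter)
    ))
  })
  nf <- config$frames_per_clip
  tgrid <- (seq_len(nf) - 1L) / config$frame_rate
  sequences <- vector("list",
                      config$num_subjects * config$num_actions *
                        config$num_repetitions)
  k <- 0L
  for (s in seq_len(config$num_subjects)) {
    sp <- subj_params[[s]]
    for (a in seq_len(config$num_actions)) {
      tpl <- templates[[a]]
      for (r in seq_len(config$num_repetitions)) {
        k <- k + 1L
        clip <- with_seed(derive_seed(config$seed, k), {
          phase_shift <- stats::runif(1L, 0, 2 * pi)
          phase_jit <- stats::rnorm(length(tpl$active), 0, 0.1)
          pos <- array(0, dim = c(nf, nj, 3L))
          sway <- tpl$sway_amp *
            cbind(sin(2 * pi * tpl$sway_freq * sp$speed * tgrid),
                  cos(2 * pi * tpl$sway_freq * sp$speed * tgrid) - 1, 0)
          pos[, topology$root, ] <- sway
          for (b in seq_len(nb)) {
            par <- edges[b, 1L]; child <- edges[b, 2L]
            v <- sp$scale * (rest[child, ] - rest[par, ])
            ai <- match(b, tpl$active)
            if (!is.na(ai)) {
              theta <- tpl$amplitude[ai] *
                sin(2 * pi * tpl$frequency[ai] * sp$speed * tgrid +
                      tpl$phase[ai] + phase_shift + phase_jit[ai])
              pos[, child, ] <- pos[, par, ] +
                rotate_offsets(v, tpl$axis[ai, ], theta)
            } else {
              pos[, child, ] <- pos[, par, ] + rep(v, each = nf)
            }
          }
          if (config$noise_std > 0)
            pos <- pos + stats::rnorm(length(pos), 0, config$noise_std)
          pos
        })
        sequences[[k]] <- skeleton3d_sequence(
          clip, frame_rate = config$frame_rate,
          subject_id = sprintf("s%02d", s),
          action_label = a - 1L, repetition = r - 1L)
      }
    }
  }
  skeleton_dataset(sequences)
}

#' Leave-one-out 1-NN class separability of a dataset
#'
#' A quick learnability check on the generator's output: each clip is
#' summarised by the per-joint, per-axis variance of its coordinates over
#' time, and classified by its nearest neighbour (Euclidean distance, ties
#' broken towards the lowest clip index) among all other clips.  Returns the
#' leave-one-out accuracy in `[0, 1]`.
#'
#' @param dataset A [skeleton_dataset()] with at least two classes.
#' @param labels Optional label override (same length as `dataset`).
#' @return Leave-one-out 1-nearest-neighbour accuracy.
#' @export
class_separability_check <- function(dataset, labels = NULL) {
  labels <- labels %||% dataset_labels(dataset)
  if (length(unique(labels)) < 2L)
    stop_validation("separability needs at least two classes")
  nfeat <- prod(dim(dataset[[1L]]$positions)[2:3])
  feats <- t(vapply(dataset, function(s) {
    as.vector(apply(s$positions, c(2L, 3L), stats::var))
  }, numeric(nfeat)))
  d2 <- as.matrix(stats::dist(feats))^2
  diag(d2) <- Inf
  nn <- apply(d2, 1L, which.min)  # which.min breaks ties at lowest index
  mean(labels[nn] == labels)
}
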