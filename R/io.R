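#' Read and write skeleton dataset containers
#'
#' A dataset container is a directory holding a `manifest.json` with one
#' record per sequence (id, subject, action label, repetition, frame rate,
#' frame and joint counts, joint names) and a single `coordinates.parquet`
#' table in long form (`sequence_id, frame, joint, x, y[, z]`).  Parquet
#' stores IEEE doubles losslessly, so coordinates round-trip bit-exactly.
#'
#' @param sequences A [skeleton_dataset()] or list of `skeleton3d` /
#'   `skeleton2d` sequences (one kind per container).
#' @param path Directory to create (overwritten if it exists).
#' @param joint_names Optional joint names recorded in the manifest.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns a
#'   `skeleton_dataset` (or list of `skeleton2d` for a 2D container).
#' @export
write_dataset <- function(sequences, path, joint_names = NULL) {
  if (length(sequences) &&
      !all(vapply(sequences, inherits, logical(1L), "skeleton3d")) &&
      !all(vapply(sequences, inherits, logical(1L), "skeleton2d")))
    stop_validation("`sequences` must all be skeleton3d or all skeleton2d")
  is2d <- length(sequences) > 0L && inherits(sequences[[1L]], "skeleton2d")
  if (dir.exists(path)) unlink(path, recursive = TRUE)
  ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok || !dir.exists(path))
    stop(sprintf("cannot create dataset directory '%s'", path))

  records <- vector("list", length(sequences))
  tables <- vector("list", length(sequences))
  for (k in seq_along(sequences)) {
    s <- sequences[[k]]
    coords <- if (is2d) s$pixels else s$positions
    d <- dim(coords)
    rec <- list(id = k - 1L,
                subject_id = if (is2d) s$subject_id else s$subject_id,
                action_label = s$action_label,
                repetition = s$repetition,
                num_frames = d[1L], num_joints = d[2L])
    if (is2d) {
      rec$viewpoint_deg <- s$viewpoint_deg
      rec$image_size <- s$image_size
      rec$source <- s$source
    } else {
      rec$frame_rate <- s$frame_rate
    }
    records[[k]] <- rec
    grid <- expand.grid(frame = seq_len(d[1L]) - 1L,
                        joint = seq_len(d[2L]) - 1L)
    tab <- data.frame(sequence_id = k - 1L,
                      frame = grid$frame, joint = grid$joint,
                      x = as.vector(coords[, , 1L]),
                      y = as.vector(coords[, , 2L]))
    if (!is2d) tab$z <- as.vector(coords[, , 3L])
    tables[[k]] <- tab
  }
  manifest <- list(format = "viewact-skeleton-container",
                   version = 1L,
                   kind = if (is2d) "skeleton2d" else "skeleton3d",
                   num_sequences = length(sequences),
                   joint_names = joint_names,
                   sequences = records)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  all_tab <- if (length(tables)) do.call(rbind, tables) else
    data.frame(sequence_id = integer(), frame = integer(), joint = integer(),
               x = numeric(), y = numeric(), z = numeric())
  arrow::write_parquet(all_tab, file.path(path, "coordinates.parquet"))
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  mf <- file.path(path, "manifest.json")
  pq <- file.path(path, "coordinates.parquet")
  if (!dir.exists(path) || !file.exists(mf) || !file.exists(pq))
    stop(sprintf("'%s' is not a dataset container (missing manifest or coordinates)",
                 path))
  manifest <- jsonlite::read_json(mf)
  is2d <- identical(manifest$kind, "skeleton2d")
  tab <- as.data.frame(arrow::read_parquet(pq))
  n <- manifest$num_sequences %||% length(manifest$sequences)
  if (n == 0L) {
    return(if (is2d) list() else skeleton_dataset(list()))
  }
  ncoord <- if (is2d) 2L else 3L
  # order once, then slice contiguous blocks per sequence
  ord <- order(tab$sequence_id, tab$joint, tab$frame)
  tab <- tab[ord, , drop = FALSE]
  counts <- table(factor(tab$sequence_id, levels = seq_len(n) - 1L))
  offsets <- cumsum(c(0L, as.integer(counts)))
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rec <- manifest$sequences[[k]]
    nf <- rec$num_frames; nj <- rec$num_joints
    rows <- if (offsets[k + 1L] > offsets[k])
      (offsets[k] + 1L):offsets[k + 1L] else integer()
    if (length(rows) != nf * nj)
      stop_validation("record %d ('%s'): expected %d coordinate rows, found %d",
                      rec$id, rec$subject_id, nf * nj, length(rows))
    block <- tab[rows, , drop = FALSE]
    coords <- array(NA_real_, dim = c(nf, nj, ncoord))
    coords[, , 1L] <- block$x
    coords[, , 2L] <- block$y
    if (!is2d) coords[, , 3L] <- block$z
    if (anyNA(coords) || any(!is.finite(coords)))
      stop_validation("record %d ('%s'): non-finite coordinates",
                      rec$id, rec$subject_id)
    expected_joints <- length(manifest$joint_names %||% integer())
    if (expected_joints > 0L && nj != expected_joints)
      stop_validation("record %d ('%s'): has %d joints, container declares %d",
                      rec$id, rec$subject_id, nj, expected_joints)
    out[[k]] <- if (is2d) {
      skeleton2d_sequence(coords,
                          viewpoint_deg = rec$viewpoint_deg %||% NA_real_,
                          image_size = unlist(rec$image_size),
                          source = rec$source %||% "projected",
                          action_label = rec$action_label,
                          subject_id = rec$subject_id,
                          repetition = rec$repetition)
    } else {
      skeleton3d_sequence(coords, frame_rate = rec$frame_rate,
                          subject_id = rec$subject_id,
                          action_label = rec$action_label,
                          repetition = rec$repetition)
    }
  }
  if (is2d) out else skeleton_dataset(out)
}

#' Import externally estimated 2D keypoints from CSV
#'
#' Reads a per-frame keypoint table with columns `frame`, `joint_index`,
#' `x`, `y` and optionally `confidence` (0-based frame and joint indices) and
#' assembles it into a `skeleton2d` sequence with `source = "estimated"`.
#'
#' @param file CSV path.
#' @param image_size `(height, width)` of the source image.
#' @param min_confidence Rows below this confidence are rejected with an
#'   error (missing joints are not supported downstream).
#' @return A `skeleton2d` sequence.
#' @export
read_keypoints_csv <- function(file, image_size = c(256L, 256L),
                               min_confidence = 0) {
  tab <- utils::read.csv(file)
  need <- c("frame", "joint_index", "x", "y")
  if (!all(need %in% names(tab)))
    stop_validation("keypoint CSV needs columns: %s", paste(need, collapse = ", "))
  if ("confidence" %in% names(tab) && any(tab$confidence < min_confidence))
    stop_validation("keypoints below min_confidence = %g present", min_confidence)
  frames <- sort(unique(tab$frame))
  joints <- sort(unique(tab$joint_index))
  nf <- length(frames); nj <- length(joints)
  if (nrow(tab) != nf * nj)
    stop_validation("keypoint CSV is not a complete frames x joints grid")
  pixels <- array(NA_real_, dim = c(nf, nj, 2L))
  fi <- match(tab$frame, frames); ji <- match(tab$joint_index, joints)
  pixels[cbind(fi, ji, 1L)] <- tab$x
  pixels[cbind(fi, ji, 2L)] <- tab$y
  skeleton2d_sequence(pixels, image_size = image_size, source = "estimated")
}

#' Read and write heatmap-volume containers
#'
#' A volume container is a directory with `manifest.json` (per-volume label,
#' subject, viewpoint, map type and the common `T x H x W` shape) and a
#' `values.parquet` table holding each volume's values flattened in array
#' order.
#'
#' @param vset A [volume_set()].
#' @param path Directory to create (overwritten if present).
#' @return `write_volume_set` returns `path` invisibly; `read_volume_set`
#'   the reconstructed `volume_set`.
#' @export
write_volume_set <- function(vset, path) {
  if (!inherits(vset, "volume_set"))
    stop_validation("`vset` must be a volume_set")
  if (dir.exists(path)) unlink(path, recursive = TRUE)
  if (!dir.create(path, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create volume container '%s'", path))
  d <- if (length(vset$volumes)) dim(vset$volumes[[1L]]) else c(0L, 0L, 0L)
  manifest <- list(format = "viewact-volume-container", version = 1L,
                   map_type = vset$map_type, dim = as.integer(d),
                   num_volumes = length(vset$volumes),
                   labels = vset$labels, subjects = vset$subjects,
                   viewpoints = vset$viewpoints)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  values <- if (length(vset$volumes))
    unlist(lapply(vset$volumes, as.vector)) else numeric()
  tab <- data.frame(
    volume_id = if (length(vset$volumes))
      rep(seq_along(vset$volumes) - 1L, each = prod(d)) else integer(),
    value = values)
  arrow::write_parquet(tab, file.path(path, "values.parquet"))
  invisible(path)
}

#' @rdname write_volume_set
#' @export
read_volume_set <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf))
    stop(sprintf("'%s' is not a volume container", path))
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  tab <- as.data.frame(arrow::read_parquet(file.path(path, "values.parquet")))
  d <- manifest$dim
  n <- manifest$num_volumes
  vols <- vector("list", n)
  per <- prod(d)
  for (k in seq_len(n)) {
    vols[[k]] <- array(tab$value[((k - 1L) * per + 1L):(k * per)], dim = d)
  }
  volume_set(vols, manifest$labels,
             subjects = manifest$subjects, viewpoints = manifest$viewpoints,
             map_type = manifest$map_type)
}
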