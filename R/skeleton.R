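#' 3D skeleton motion sequence
#'
#' One labelled motion clip: per-frame 3D joint positions in metres (world
#' frame, z vertical, origin at the subject's initial pelvis position),
#' together with its recording metadata.
#'
#' @param positions Numeric array of dimension `frames x joints x 3`.
#' @param frame_rate Sampling rate in Hz.
#' @param subject_id Subject identifier (string).
#' @param action_label Integer action class in `[0, num_actions)`.
#' @param repetition Repetition index (integer, 0-based).
#'
#' @return An object of class `skeleton3d`.
#' @export
skeleton3d_sequence <- function(positions, frame_rate = 24,
                                subject_id = "s00", action_label = 0L,
                                repetition = 0L) {
  if (!is.array(positions) || length(dim(positions)) != 3L ||
      dim(positions)[3L] != 3L)
    stop_validation("`positions` must be a frames x joints x 3 array")
  if (dim(positions)[1L] < 1L)
    stop_validation("a sequence needs at least one frame")
  check_finite_array(positions, "positions")
  structure(
    list(positions = positions,
         frame_rate = check_number(frame_rate, "frame_rate", lower = 0,
                                   strict_lower = TRUE),
         subject_id = as.character(subject_id),
         action_label = check_number(action_label, "action_label", lower = 0,
                                     integer = TRUE),
         repetition = check_number(repetition, "repetition", lower = 0,
                                   integer = TRUE)),
    class = "skeleton3d"
  )
}

#' @export
print.skeleton3d <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf(
    "<skeleton3d> subject %s, action %d, rep %d: %d frames x %d joints @ %g Hz\n",
    x$subject_id, x$action_label, x$repetition, d[1L], d[2L], x$frame_rate))
  invisible(x)
}

#' 2D skeleton sequence
#'
#' Per-frame pixel coordinates of the skeleton joints for one viewpoint,
#' either projected from a 3D sequence or estimated externally.  Pixel
#' convention: origin at the top-left, x right, y down, continuous 0-based
#' coordinates.
#'
#' @param pixels Numeric array `frames x joints x 2` (x, y in pixels).
#' @param viewpoint_deg Orbit angle (degrees) the clip was projected from;
#'   `NA` for externally estimated keypoints.
#' @param image_size Integer `(height, width)` of the source image plane.
#' @param source Either `"projected"` or `"estimated"`.
#' @param action_label,subject_id,repetition Optional metadata carried along
#'   from the originating 3D sequence.
#'
#' @return An object of class `skeleton2d`.
#' @export
skeleton2d_sequence <- function(pixels, viewpoint_deg = NA_real_,
                                image_size = c(256L, 256L),
                                source = c("projected", "estimated"),
                                action_label = NA_integer_,
                                subject_id = NA_character_,
                                repetition = NA_integer_) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3L] != 2L)
    stop_validation("`pixels` must be a frames x joints x 2 array")
  check_finite_array(pixels, "pixels")
  source <- match.arg(source)
  if (length(image_size) != 2L || any(image_size < 1))
    stop_validation("`image_size` must be (height, width), both >= 1")
  structure(
    list(pixels = pixels,
         viewpoint_deg = as.numeric(viewpoint_deg),
         image_size = as.integer(image_size),
         source = source,
         action_label = as.integer(action_label),
         subject_id = as.character(subject_id),
         repetition = as.integer(repetition)),
    class = "skeleton2d"
  )
}

#' @export
print.skeleton2d <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<skeleton2d> %s, viewpoint %s deg: %d frames x %d joints (%dx%d px plane)\n",
              x$source,
              ifelse(is.na(x$viewpoint_deg), "?", format(x$viewpoint_deg)),
              d[1L], d[2L], x$image_size[1L], x$image_size[2L]))
  invisible(x)
}

#' Bundle sequences into a dataset
#'
#' @param sequences List of [skeleton3d_sequence()] objects.
#' @return An object of class `skeleton_dataset` (a list of sequences).
#' @export
skeleton_dataset <- function(sequences) {
  if (!all(vapply(sequences, inherits, logical(1L), "skeleton3d")))
    stop_validation("all elements must be skeleton3d sequences")
  structure(sequences, class = "skeleton_dataset")
}

#' @export
print.skeleton_dataset <- function(x, ...) {
  subj <- unique(vapply(x, `[[`, character(1L), "subject_id"))
  lab <- vapply(x, `[[`, numeric(1L), "action_label")
  cat(sprintf("<skeleton_dataset> %d sequences, %d subjects, %d action classes\n",
              length(x), length(subj), length(unique(lab))))
  invisible(x)
}

#' @export
`[.skeleton_dataset` <- function(x, i) {
  structure(unclass(x)[i], class = "skeleton_dataset")
}

dataset_labels <- function(dataset) {
  vapply(dataset, `[[`, numeric(1L), "action_label")
}

dataset_subjects <- function(dataset) {
  vapply(dataset, `[[`, character(1L), "subject_id")
}
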