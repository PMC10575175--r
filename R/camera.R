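#' Rotate a point about the world z axis
#'
#' Applies the right-handed rotation `R_z(theta)` used to move the camera
#' along its orbit: the camera position at angle theta is the initial
#' position rotated about the vertical axis.
#'
#' @param p0 Numeric 3-vector.
#' @param theta_deg Rotation angle in degrees (counter-clockwise seen from
#'   +z).
#' @return The rotated 3-vector.
#' @examples
#' rotate_about_z(c(2, 0, 1), 90) # ~ c(0, 2, 1)
#' @export
rotate_about_z <- function(p0, theta_deg) {
  if (length(p0) != 3L) stop_validation("`p0` must be a 3-vector")
  check_finite_array(p0, "p0")
  th <- check_number(theta_deg, "theta_deg") * pi / 180
  c(cos(th) * p0[1L] - sin(th) * p0[2L],
    sin(th) * p0[1L] + cos(th) * p0[2L],
    p0[3L])
}

#' Evenly spaced orbit viewpoint angles
#'
#' @param spacing_deg Angular spacing in degrees; must divide 360 evenly.
#' @return Sorted vector `c(0, spacing, 2*spacing, ...)` covering `[0, 360)`.
#' @examples
#' length(viewpoint_angles(10)) # 36
#' viewpoint_angles(90)         # 0 90 180 270
#' @export
viewpoint_angles <- function(spacing_deg) {
  spacing_deg <- check_number(spacing_deg, "spacing_deg", lower = 0,
                              strict_lower = TRUE)
  k <- 360 / spacing_deg
  if (abs(k - round(k)) > 1e-9)
    stop_validation("`spacing_deg` = %g does not divide 360 evenly", spacing_deg)
  seq(0, 360 - spacing_deg, by = spacing_deg)
}

#' Pinhole camera intrinsics
#'
#' Square pixels, zero skew.  The default focal length is chosen so that a
#' standing figure of `subject_height` metres seen from `radius` metres fills
#' about 80% of the image height.
#'
#' @param focal_px Focal length in pixels; computed from the framing rule
#'   when `NULL`.
#' @param principal_point `(cx, cy)` in pixels; image centre when `NULL`.
#' @param image_size `(height, width)` in pixels.
#' @param radius,subject_height Framing rule inputs for the default focal.
#' @return A `camera_intrinsics` object.
#' @export
camera_intrinsics <- function(focal_px = NULL, principal_point = NULL,
                              image_size = c(256L, 256L), radius = 3,
                              subject_height = 2.2) {
  if (length(image_size) != 2L || any(image_size < 1))
    stop_validation("`image_size` must be (height, width), both >= 1")
  image_size <- as.integer(round(image_size))
  if (is.null(focal_px))
    focal_px <- 0.8 * image_size[1L] * radius / subject_height
  focal_px <- check_number(focal_px, "focal_px", lower = 0, strict_lower = TRUE)
  if (is.null(principal_point))
    principal_point <- (rev(image_size) - 1) / 2  # (cx, cy), 0-based pixels
  structure(list(focal_px = focal_px,
                 principal_point = as.numeric(principal_point),
                 image_size = image_size),
            class = "camera_intrinsics")
}

#' Camera orbit configuration
#'
#' The camera circles the subject on a horizontal orbit about the vertical
#' axis through the orbit centre.  At angle 0 the camera sits at
#' `centre + (0, -radius, height)` and looks at the centre; at angle theta
#' its position is the angle-0 position rotated by [rotate_about_z()] about
#' the centre.
#'
#' @param radius Orbit radius, metres.
#' @param height Camera height above the orbit centre, metres (the centre
#'   sits at pelvis height, so 0 means a camera level with the pelvis).
#' @param center_mode `"sequence_centroid"` places the orbit centre at the
#'   per-clip median pelvis (root joint) position; `"fixed_origin"` uses the
#'   world origin.
#' @return An `orbit_config` object.
#' @export
orbit_config <- function(radius = 3, height = 0,
                         center_mode = c("sequence_centroid", "fixed_origin")) {
  structure(list(radius = check_number(radius, "radius", 0, strict_lower = TRUE),
                 height = check_number(height, "height"),
                 center_mode = match.arg(center_mode)),
            class = "orbit_config")
}

#' Camera pose (position + look-at)
#'
#' @param position Camera centre, metres.
#' @param look_at Point the optical axis passes through.
#' @param up World-space up hint (unit vector, default +z).
#' @return A `camera_pose` object.
#' @export
camera_pose <- function(position, look_at, up = c(0, 0, 1)) {
  check_finite_array(position, "position")
  check_finite_array(look_at, "look_at")
  if (length(position) != 3L || length(look_at) != 3L || length(up) != 3L)
    stop_validation("pose vectors must have length 3")
  if (sqrt(sum((position - look_at)^2)) < 1e-12)
    stop_validation("`position` must differ from `look_at`")
  structure(list(position = as.numeric(position),
                 look_at = as.numeric(look_at), up = as.numeric(up)),
            class = "camera_pose")
}

#' Build a 3x4 pinhole projection matrix
#'
#' Composes `P = K [R | t]`, where `[R | t]` maps world to camera
#' coordinates (camera looks from `position` toward `look_at`, x right,
#' y down, z along the optical axis) and `K` is the upper-triangular
#' intrinsic matrix with equal focal lengths and zero skew.
#'
#' @param intrinsics A [camera_intrinsics()].
#' @param pose A [camera_pose()].
#' @return A `projection_matrix` object: list with the 3x4 `matrix` plus the
#'   rotation and translation used to build it.
#' @export
build_projection <- function(intrinsics, pose) {
  if (!inherits(intrinsics, "camera_intrinsics"))
    stop_validation("`intrinsics` must be a camera_intrinsics")
  if (!inherits(pose, "camera_pose"))
    stop_validation("`pose` must be a camera_pose")
  fwd <- pose$look_at - pose$position
  fwd <- fwd / sqrt(sum(fwd^2))
  right <- c(fwd[2L] * pose$up[3L] - fwd[3L] * pose$up[2L],
             fwd[3L] * pose$up[1L] - fwd[1L] * pose$up[3L],
             fwd[1L] * pose$up[2L] - fwd[2L] * pose$up[1L])
  nr <- sqrt(sum(right^2))
  if (nr < 1e-9)
    stop_validation("degenerate pose: up vector parallel to viewing direction")
  right <- right / nr
  down <- c(fwd[2L] * right[3L] - fwd[3L] * right[2L],
            fwd[3L] * right[1L] - fwd[1L] * right[3L],
            fwd[1L] * right[2L] - fwd[2L] * right[1L])
  R <- rbind(right, down, fwd)
  t <- -R %*% pose$position
  K <- matrix(c(intrinsics$focal_px, 0, 0,
                0, intrinsics$focal_px, 0,
                intrinsics$principal_point[1L],
                intrinsics$principal_point[2L], 1), 3L, 3L)
  structure(list(matrix = unname(K %*% cbind(R, t)), R = unname(R),
                 t = as.numeric(t), K = K),
            class = "projection_matrix")
}

#' Project 3D points through a projection matrix
#'
#' Homogeneous projection with explicit perspective division.  Points at or
#' behind the camera plane (non-positive depth) raise an error.
#'
#' @param proj A [build_projection()] result.
#' @param points N x 3 matrix of world coordinates.
#' @return N x 2 matrix of pixel coordinates.
#' @export
project_points <- function(proj, points) {
  points <- rbind(points)
  h <- proj$matrix %*% t(cbind(points, 1))
  depth <- h[3L, ]
  if (any(depth <= 1e-9)) {
    bad <- which(depth <= 1e-9)[1L]
    stop(structure(class = c("viewact_projection_error", "error", "condition"),
                   list(message = sprintf(
                     "point %d is at or behind the camera plane (depth %.3g)",
                     bad, depth[bad]), call = NULL)))
  }
  cbind(h[1L, ] / depth, h[2L, ] / depth)
}

orbit_center <- function(seq3d, orbit, root = 4L) {
  if (orbit$center_mode == "fixed_origin") return(c(0, 0, 0))
  apply(seq3d$positions[, root, , drop = FALSE], 3L, stats::median)
}

orbit_camera_position <- function(orbit, center, theta_deg) {
  center + rotate_about_z(c(0, -orbit$radius, orbit$height), theta_deg)
}

#' Project a 3D skeleton sequence to a 2D skeleton at one orbit angle
#'
#' Places the camera on its orbit at `theta_deg` (the angle-0 position
#' rotated about the vertical axis through the orbit centre), aims it at the
#' centre, and projects every frame.  Equivalent, up to numerical precision,
#' to rotating all the skeleton joints by `-theta_deg` about the orbit axis
#' and projecting with the angle-0 camera.
#'
#' @param seq3d A `skeleton3d` sequence.
#' @param intrinsics A [camera_intrinsics()].
#' @param orbit An [orbit_config()].
#' @param theta_deg Orbit angle in degrees.
#' @param topology Topology (used to locate the root joint for the orbit
#'   centre).
#' @return A `skeleton2d` sequence with `viewpoint_deg = theta_deg` and the
#'   clip's metadata carried over.
#' @export
project_sequence <- function(seq3d, intrinsics = camera_intrinsics(),
                             orbit = orbit_config(), theta_deg = 0,
                             topology = default_topology()) {
  if (!inherits(seq3d, "skeleton3d"))
    stop_validation("`seq3d` must be a skeleton3d sequence")
  center <- orbit_center(seq3d, orbit, root = topology$root)
  pose <- camera_pose(orbit_camera_position(orbit, center, theta_deg), center)
  proj <- build_projection(intrinsics, pose)
  d <- dim(seq3d$positions)
  pts <- matrix(seq3d$positions, nrow = d[1L] * d[2L], ncol = 3L)
  px <- tryCatch(project_points(proj, pts), viewact_projection_error = function(e) {
    idx <- as.integer(sub(".*point ([0-9]+) .*", "\\1", conditionMessage(e)))
    frame <- (idx - 1L) %% d[1L] + 1L
    joint <- (idx - 1L) %/% d[1L] + 1L
    stop_validation("frame %d, joint %d: %s", frame, joint,
                    sub("^point [0-9]+ is", "point", conditionMessage(e)))
  })
  pixels <- array(px, dim = c(d[1L], d[2L], 2L))
  skeleton2d_sequence(pixels, viewpoint_deg = theta_deg %% 360,
                      image_size = intrinsics$image_size,
                      source = "projected",
                      action_label = seq3d$action_label,
                      subject_id = seq3d$subject_id,
                      repetition = seq3d$repetition)
}
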