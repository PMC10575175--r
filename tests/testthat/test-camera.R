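test_that("z-axis rotation matches closed forms and preserves norm and height", {
  expect_equal(rotate_about_z(c(2, 0, 1), 90), c(0, 2, 1))
  expect_equal(rotate_about_z(c(2, 0, 1), 0), c(2, 0, 1))
  set.seed(2)
  for (i in 1:20) {
    p <- rnorm(3)
    th <- runif(1, -720, 720)
    q <- rotate_about_z(p, th)
    expect_lt(abs(sqrt(sum(q^2)) - sqrt(sum(p^2))), 1e-12)
    expect_lt(abs(q[3] - p[3]), 1e-12)
    expect_lt(max(abs(rotate_about_z(p, 360) - p)), 1e-12)
  }
  expect_error(rotate_about_z(c(1, NA, 0), 10), "finite")
})

test_that("viewpoint grids have 360/spacing angles", {
  expect_length(viewpoint_angles(10), 36L)
  expect_length(viewpoint_angles(45), 8L)
  expect_equal(viewpoint_angles(90), c(0, 90, 180, 270))
  expect_error(viewpoint_angles(7), "divide 360")
  expect_error(viewpoint_angles(0), "> 0")
})

test_that("projection maps the optical axis to the principal point", {
  intr <- camera_intrinsics(focal_px = 50, principal_point = c(32, 32),
                            image_size = c(64, 64))
  pose <- camera_pose(c(0, -3, 0), c(0, 0, 0))
  proj <- build_projection(intr, pose)
  expect_equal(as.vector(project_points(proj, matrix(c(0, 0, 0), 1))),
               c(32, 32))
  # any look-at point lands on the principal point
  pose2 <- camera_pose(c(1.3, -2, 0.7), c(0.2, 0.1, 0.5))
  proj2 <- build_projection(intr, pose2)
  expect_equal(as.vector(project_points(proj2, matrix(c(0.2, 0.1, 0.5), 1))),
               c(32, 32), tolerance = 1e-9)
  expect_error(build_projection(intr, camera_pose(c(0, 0, 3), c(0, 0, 0))),
               "degenerate")
})

test_that("projection agrees with a step-by-step homogeneous-coordinate oracle", {
  set.seed(7)
  for (i in 1:20) {
    cam <- rnorm(3, sd = 3)
    look <- rnorm(3)
    if (sqrt(sum((cam - look)^2)) < 0.5) next
    f <- runif(1, 20, 400)
    cc <- runif(2, 10, 200)
    intr <- camera_intrinsics(focal_px = f, principal_point = cc,
                              image_size = c(256, 256))
    proj <- build_projection(intr, camera_pose(cam, look))
    fwd <- (look - cam) / sqrt(sum((look - cam)^2))
    pt <- look + rnorm(3, sd = 0.3)
    if (sum((pt - cam) * fwd) < 0.1) next
    got <- as.vector(project_points(proj, matrix(pt, 1)))
    want <- oracle_project_point(pt, cam, look, c(0, 0, 1), f, cc)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("a point at the orbit centre projects to the principal point at every angle", {
  topo1 <- joint_topology("pt", matrix(integer(), 0, 2), root = 1)
  seq1 <- skeleton3d_sequence(array(0, c(3, 1, 3)))
  intr <- camera_intrinsics(image_size = c(64, 64))
  for (th in seq(0, 350, by = 50)) {
    s2 <- project_sequence(seq1, intr, orbit_config(), th, topo1)
    expect_equal(as.vector(s2$pixels[1, 1, ]), intr$principal_point,
                 tolerance = 1e-9)
  }
})

test_that("projection is periodic in the orbit angle", {
  ds <- generate_dataset(generator_config(num_subjects = 1, num_actions = 1,
                                          num_repetitions = 1,
                                          frames_per_clip = 5))
  a <- project_sequence(ds[[1]], theta_deg = 30)
  b <- project_sequence(ds[[1]], theta_deg = 30 - 360)
  expect_equal(a$pixels, b$pixels, tolerance = 1e-9)
})

test_that("rotating the camera equals counter-rotating the skeleton", {
  ds <- generate_dataset(generator_config(num_subjects = 1, num_actions = 2,
                                          num_repetitions = 1,
                                          frames_per_clip = 6, seed = 3))
  intr <- camera_intrinsics()
  orb <- orbit_config(center_mode = "fixed_origin")
  for (clip in ds) {
    for (th in viewpoint_angles(10)) {
      cam_rot <- project_sequence(clip, intr, orb, th)
      rot <- clip
      d <- dim(rot$positions)
      pts <- matrix(rot$positions, ncol = 3)
      rot$positions <- array(t(apply(pts, 1, rotate_about_z, -th)), d)
      skel_rot <- project_sequence(rot, intr, orb, 0)
      expect_equal(cam_rot$pixels, skel_rot$pixels, tolerance = 1e-6)
    }
  }
})

test_that("collinear points stay collinear under projection", {
  set.seed(11)
  intr <- camera_intrinsics()
  proj <- build_projection(intr, camera_pose(c(0, -3, 1), c(0, 0, 1)))
  for (i in 1:10) {
    a <- rnorm(3, sd = 0.4)
    dirv <- rnorm(3, sd = 0.3)
    pts <- rbind(a, a + dirv, a + 2.5 * dirv)
    px <- project_points(proj, pts)
    v1 <- px[2, ] - px[1, ]
    v2 <- px[3, ] - px[1, ]
    cross <- v1[1] * v2[2] - v1[2] * v2[1]
    expect_lt(abs(cross) / max(1, sum(v1^2)), 1e-6)
  }
})

test_that("points behind the camera raise an error naming frame and joint", {
  pos <- array(0, c(2, 2, 3))
  pos[, 1, ] <- rep(c(0, 0, 0), each = 2)
  pos[2, 2, ] <- c(0, -10, 0)  # behind a camera orbiting at radius 3
  topo2 <- joint_topology(c("a", "b"), matrix(c(1, 2), 1), root = 1)
  seqb <- skeleton3d_sequence(pos)
  expect_error(
    project_sequence(seqb, camera_intrinsics(),
                     orbit_config(center_mode = "fixed_origin"), 0, topo2),
    "frame 2, joint 2")
})
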