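test_that("point-to-segment distance matches closed forms and a dense-sampling oracle", {
  expect_equal(point_segment_distance(c(5, 5), c(0, 0), c(10, 0)), 5)
  expect_equal(point_segment_distance(c(12, 1), c(0, 0), c(10, 0)), sqrt(5))
  expect_equal(point_segment_distance(c(3, 4), c(1, 1), c(1, 1)),
               sqrt(4 + 9))
  set.seed(5)
  for (i in 1:200) {
    p <- runif(2, -10, 10); a <- runif(2, -10, 10); b <- runif(2, -10, 10)
    expect_equal(point_segment_distance(p, a, b),
                 oracle_segment_distance(p, a, b), tolerance = 1e-4)
  }
})

test_that("joint heatmaps evaluate the Gaussian kernel exactly", {
  hm <- joint_heatmap_frame(matrix(c(3, 4), 1), c(8, 8), sigma = 1.5)
  expect_equal(hm[5, 4], 1.0)  # row = y+1, col = x+1
  hm2 <- joint_heatmap_frame(matrix(c(3, 4), 1), c(8, 8), sigma = 2)
  expect_equal(hm2[5, 6], exp(-1))  # pixel at distance 2
  two <- joint_heatmap_frame(rbind(c(3, 4), c(3, 4)), c(8, 8), sigma = 1.5)
  expect_equal(two[5, 4], 2.0)
  set.seed(8)
  joints <- matrix(runif(32, 0, 15), 16, 2)
  expect_equal(joint_heatmap_frame(joints, c(16, 16), 1.5),
               oracle_joint_heatmap(joints, 16, 16, 1.5), tolerance = 1e-10)
})

test_that("bone heatmaps use the shortest distance to each segment", {
  topo2 <- joint_topology(c("a", "b"), matrix(c(1, 2), 1), root = 1)
  joints <- rbind(c(1, 3), c(9, 3))
  hm <- bone_heatmap_frame(joints, topo2, c(8, 12), sigma = 1.5)
  expect_equal(hm[4, 6], 1.0)   # pixel (5, 3) lies on the segment
  # degenerate bone reduces to a joint Gaussian
  degen <- rbind(c(4, 4), c(4, 4))
  expect_equal(bone_heatmap_frame(degen, topo2, c(8, 8), 1.5),
               joint_heatmap_frame(matrix(c(4, 4), 1), c(8, 8), 1.5))
  set.seed(9)
  topo <- default_topology()
  j16 <- matrix(runif(32, 0, 15), 16, 2)
  expect_equal(bone_heatmap_frame(j16, topo, c(16, 16), 1.5),
               oracle_bone_heatmap(j16, topo$bones, 16, 16, 1.5, n = 3000),
               tolerance = 1e-4)
})

test_that("heatmap values decay monotonically away from an isolated joint", {
  hm <- joint_heatmap_frame(matrix(c(10, 10), 1), c(21, 21), sigma = 2)
  centre <- c(11, 11)
  for (r in 1:9) {
    expect_lt(hm[centre[1], centre[2] + r + 1], hm[centre[1], centre[2] + r])
    expect_lt(hm[centre[1] + r + 1, centre[2]], hm[centre[1] + r, centre[2]])
  }
})

test_that("the mass of a single-joint Gaussian approaches pi * sigma^2", {
  for (sigma in c(2, 3)) {
    hm <- joint_heatmap_frame(matrix(c(50, 50), 1), c(101, 101), sigma)
    expect_lt(abs(sum(hm) / (pi * sigma^2) - 1), 0.02)
  }
})

test_that("subject-centred cropping is translation invariant and bounded", {
  set.seed(10)
  px <- array(runif(5 * 16 * 2, 40, 200), c(5, 16, 2))
  s <- skeleton2d_sequence(px)
  out <- subject_centered_crop(s, 0.1, c(64, 64))$sequence
  expect_true(all(out$pixels[, , 1] >= 0 & out$pixels[, , 1] <= 63))
  expect_true(all(out$pixels[, , 2] >= 0 & out$pixels[, , 2] <= 63))
  shifted <- skeleton2d_sequence(sweep(px, 3, c(100, 37), "+"))
  out2 <- subject_centered_crop(shifted, 0.1, c(64, 64))$sequence
  expect_equal(out$pixels, out2$pixels, tolerance = 1e-9)
})

test_that("keypoints already spanning the padded grid are a fixed point of the crop", {
  px <- array(0, c(2, 4, 2))
  px[, , 1] <- rep(c(0, 63, 0, 63), each = 2)
  px[, , 2] <- rep(c(0, 0, 63, 63), each = 2)
  s <- skeleton2d_sequence(px)
  out <- subject_centered_crop(s, 0, c(64, 64))$sequence
  expect_equal(out$pixels, px, tolerance = 1e-12)
  degen <- skeleton2d_sequence(array(5, c(3, 16, 2)))
  expect_error(subject_centered_crop(degen, 0.1, c(64, 64)), "degenerate")
})

test_that("uniform sampling picks one index per equal bin", {
  expect_equal(uniform_sample(100, 10), seq(5, 95, by = 10))
  expect_equal(uniform_sample(10, 10), 0:9)
  r1 <- uniform_sample(100, 10, mode = "random", seed = 4)
  r2 <- uniform_sample(100, 10, mode = "random", seed = 4)
  expect_identical(r1, r2)
  expect_true(all(r1 %/% 10 == 0:9))  # one per bin
  set.seed(6)
  for (i in 1:20) {
    t_in <- sample(1:60, 1); t_out <- sample(1:20, 1)
    idx <- uniform_sample(t_in, t_out, mode = "random", seed = i)
    expect_length(idx, t_out)
    expect_true(all(diff(idx) >= 0))
    expect_true(all(idx >= 0 & idx < t_in))
  }
  expect_equal(uniform_sample(3, 6), c(0, 0, 1, 1, 2, 2))
})

test_that("build_volume yields the configured shape deterministically", {
  set.seed(12)
  s <- skeleton2d_sequence(array(runif(48 * 16 * 2, 0, 200), c(48, 16, 2)),
                           viewpoint_deg = 40, action_label = 5L)
  cfg <- heatmap_config(out_height = 64, out_width = 64, num_frames_out = 12)
  v <- build_volume(s, default_topology(), cfg)
  expect_identical(dim(v$values), c(12L, 64L, 64L))
  expect_true(all(v$values >= 0) && all(is.finite(v$values)))
  expect_lte(max(v$values), 16)  # sum of 16 unit-peak Gaussians
  expect_identical(v$values, build_volume(s, default_topology(), cfg)$values)
  expect_equal(v$action_label, 5L)
  expect_equal(v$viewpoint_deg, 40)
  # accumulation and denominator switches
  vmax <- build_volume(s, default_topology(),
                       heatmap_config(out_height = 32, out_width = 32,
                                      num_frames_out = 4, accumulate = "max"))
  expect_lte(max(vmax$values), 1)
  hm1 <- joint_heatmap_frame(matrix(c(3, 3), 1), c(8, 8), sigma = 2,
                             denominator = "2sigma2")
  expect_equal(hm1[4, 6], exp(-4 / (2 * 4)))
})
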