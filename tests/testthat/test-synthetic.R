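test_that("generator emits subjects x actions x repetitions sequences with intact metadata", {
  ds <- generate_dataset(generator_config(num_subjects = 2, num_actions = 3,
                                          num_repetitions = 1,
                                          frames_per_clip = 8))
  expect_length(ds, 6L)
  expect_setequal(unique(vapply(ds, `[[`, character(1), "subject_id")),
                  c("s01", "s02"))
  expect_setequal(unique(vapply(ds, `[[`, numeric(1), "action_label")), 0:2)
  expect_true(all(vapply(ds, function(s) dim(s$positions)[1], numeric(1)) == 8))
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- generator_config(num_subjects = 2, num_actions = 2,
                          num_repetitions = 2, frames_per_clip = 10, seed = 42)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a, b)
  c <- generate_dataset(generator_config(num_subjects = 2, num_actions = 2,
                                         num_repetitions = 2,
                                         frames_per_clip = 10, seed = 43))
  expect_false(identical(a, c))
})

test_that("noiseless clips have time-constant bone lengths", {
  topo <- default_topology()
  ds <- generate_dataset(generator_config(num_subjects = 2, num_actions = 4,
                                          num_repetitions = 1, noise_std = 0),
                         topo)
  for (s in ds) {
    bl <- apply(s$positions, 1, function(fr) {
      sqrt(rowSums((fr[topo$bones[, 1], ] - fr[topo$bones[, 2], ])^2))
    })
    spread <- apply(bl, 1, function(x) diff(range(x)))
    expect_lt(max(spread), 1e-9)
  }
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(num_subjects = 0), ">= 1")
  expect_error(generator_config(frames_per_clip = 1), ">= 2")
  expect_error(generator_config(noise_std = -0.1), ">= 0")
  expect_error(generator_config(subject_scale_range = c(1.1, 0.9)),
               "min <= max")
})

test_that("noiseless classes are perfectly 1-NN separable and match an independent oracle", {
  ds <- generate_dataset(generator_config(num_subjects = 5, num_actions = 3,
                                          num_repetitions = 2, noise_std = 0))
  sep <- class_separability_check(ds)
  expect_equal(sep, 1.0)
  feats <- t(sapply(ds, function(s) as.vector(apply(s$positions, c(2, 3), var))))
  labs <- factor(vapply(ds, `[[`, numeric(1), "action_label"))
  oracle <- mean(class::knn.cv(feats, labs, k = 1) == labs)
  expect_equal(sep, oracle)
})

test_that("separability collapses to chance for permuted or degenerate labels", {
  ds <- generate_dataset(generator_config(num_subjects = 5, num_actions = 3,
                                          num_repetitions = 2, noise_std = 0))
  labs <- vapply(ds, `[[`, numeric(1), "action_label")
  set.seed(1)
  perm_acc <- mean(replicate(100, {
    class_separability_check(ds, labels = sample(labs))
  }))
  expect_lt(abs(perm_acc - 1 / 3), 0.08)
  # identical clips with distinct labels: no signal at all
  clip <- ds[[1]]
  clones <- skeleton_dataset(lapply(0:8, function(i) {
    skeleton3d_sequence(clip$positions, subject_id = "s01",
                        action_label = i %% 3, repetition = i)
  }))
  expect_lte(class_separability_check(clones), 1 / 3 + 0.05)
  single <- skeleton_dataset(list(clip, clip))
  expect_error(class_separability_check(single), "two classes")
})

test_that("separability degrades monotonically with sensor noise", {
  seps <- vapply(c(0, 0.05, 0.2, 1.0), function(ns) {
    class_separability_check(generate_dataset(
      generator_config(num_subjects = 4, num_actions = 4,
                       num_repetitions = 2, noise_std = ns, seed = 5)))
  }, numeric(1))
  expect_true(all(diff(seps) <= 1e-12))
  expect_equal(seps[1], 1.0)
})
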