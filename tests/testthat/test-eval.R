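make_flat_dataset <- function(n_subj, n_act = 1, n_rep = 1, frames = 4) {
  generate_dataset(generator_config(num_subjects = n_subj,
                                    num_actions = n_act,
                                    num_repetitions = n_rep,
                                    frames_per_clip = frames))
}

test_that("subject splits are subject-disjoint partitions", {
  ds <- make_flat_dataset(40)
  sp <- subject_split(ds, 10, seed = 3)
  expect_length(sp$train_subjects, 30L)
  expect_length(sp$test_subjects, 10L)
  expect_length(intersect(sp$train_subjects, sp$test_subjects), 0L)
  expect_equal(length(sp$train) + length(sp$test), length(ds))
  tr_ids <- vapply(sp$train, `[[`, character(1), "subject_id")
  te_ids <- vapply(sp$test, `[[`, character(1), "subject_id")
  expect_length(intersect(unique(tr_ids), unique(te_ids)), 0L)
  sp2 <- subject_split(ds, 10, seed = 3)
  expect_identical(sp$test_subjects, sp2$test_subjects)
  expect_error(subject_split(ds, 40, seed = 1), "hold out")
})

test_that("training-set assembly yields clips x angles volumes with labels intact", {
  ds <- generate_dataset(generator_config(num_subjects = 5, num_actions = 2,
                                          num_repetitions = 1,
                                          frames_per_clip = 8))
  hm <- heatmap_config(out_height = 16, out_width = 16, num_frames_out = 4)
  vs <- assemble_training_set(ds, angles = c(0, 90, 180, 270), config = hm)
  expect_length(vs$volumes, 40L)
  clip_labels <- vapply(ds, `[[`, numeric(1), "action_label")
  expect_identical(vs$labels, as.integer(rep(clip_labels, each = 4)))
  expect_identical(dim(vs$volumes[[1]]), c(4L, 16L, 16L))
  vs36 <- assemble_training_set(ds, angles = viewpoint_angles(10), config = hm)
  expect_length(vs36$volumes, 360L)
  expect_setequal(unique(vs36$viewpoints), viewpoint_angles(10))
})

test_that("cross-validation folds are subject-disjoint, covering and seeded", {
  set.seed(20)
  subjects <- rep(sprintf("s%02d", 1:10), each = 4)
  vols <- replicate(40, array(runif(4 * 8 * 8), c(4, 8, 8)), simplify = FALSE)
  labels <- rep(rep(0:1, each = 2), 10)
  vs <- volume_set(vols, labels, subjects = subjects)
  cfg <- slowfast_config(base_channels = 2, fast_channel_fraction = 0.5,
                         stage_depths = 1, slow_stride = 2)
  cv <- cross_validate(vs, cfg, folds = 5, seed = 4,
                       control = slowfast_control(epochs = 1, batch_size = 16))
  expect_length(cv$reports, 5L)
  all_val <- unlist(cv$fold_subjects)
  expect_setequal(all_val, unique(subjects))
  expect_length(all_val, 10L)  # pairwise disjoint cover
  cv2 <- cross_validate(vs, cfg, folds = 5, seed = 4,
                        control = slowfast_control(epochs = 1,
                                                   batch_size = 16))
  expect_identical(cv$fold_subjects, cv2$fold_subjects)
  expect_identical(cv$accuracies, cv2$accuracies)
  expect_error(cross_validate(vs, cfg, folds = 11), "folds")
})

test_that("a trained model is more accurate at its own training viewpoints than across the full grid", {
  ds <- generate_dataset(generator_config(num_subjects = 4, num_actions = 6,
                                          num_repetitions = 2, seed = 9))
  sp <- subject_split(ds, 1, seed = 9)
  hm <- heatmap_config(out_height = 24, out_width = 24, num_frames_out = 8)
  angles_b <- c(0, 90, 180, 270)
  tr <- assemble_training_set(sp$train, angles = angles_b, config = hm)
  te <- assemble_training_set(sp$test, angles = viewpoint_angles(10),
                              config = hm)
  fit <- slowfast(tr, config = tiny_model_config(seed = 2),
                  control = slowfast_control(epochs = 10, lr = 0.05, seed = 2))
  pred <- predict(fit, te, type = "class")
  overall <- mean(pred == te$labels)
  in_view <- mean(pred[te$viewpoints %in% angles_b] ==
                    te$labels[te$viewpoints %in% angles_b])
  expect_gt(overall, 1 / 6)       # better than chance on unseen subjects
  expect_gte(in_view, overall)    # unseen viewpoints are the harder part
})

test_that("the viewpoint experiment reports one evaluation per model spec", {
  ds <- generate_dataset(generator_config(num_subjects = 3, num_actions = 4,
                                          num_repetitions = 2,
                                          frames_per_clip = 16, seed = 2))
  cfg <- viewpoint_experiment_config(
    model_specs = list(A = c(0, 90), B = c(0, 90, 180, 270)),
    test_angles = viewpoint_angles(90),
    num_test_subjects = 1,
    heatmap = heatmap_config(out_height = 16, out_width = 16,
                             num_frames_out = 4),
    model = slowfast_config(base_channels = 4, fast_channel_fraction = 0.5,
                            stage_depths = 1),
    control = slowfast_control(epochs = 1),
    seed = 6)
  res <- run_viewpoint_experiment(ds, cfg)
  expect_named(res$reports, c("A", "B"))
  expect_named(res$accuracies, c("A", "B"))
  for (rep in res$reports) {
    expect_s3_class(rep, "eval_report")
    expect_equal(rep$accuracy, sum(diag(rep$confusion)) / sum(rep$confusion))
    expect_true(all(c(rep$macro_precision, rep$macro_recall, rep$macro_f1,
                      rep$accuracy) >= 0 &
                      c(rep$macro_precision, rep$macro_recall, rep$macro_f1,
                        rep$accuracy) <= 1))
  }
  expect_equal(sum(res$reports$A$confusion), 8 * 4)  # 8 test clips x 4 angles
})
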