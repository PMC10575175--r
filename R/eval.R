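#' Subject-disjoint train/test split
#'
#' Partitions a dataset by subject: every clip of a subject lands on exactly
#' one side.  Test subjects are drawn uniformly with the given seed.
#'
#' @param dataset A [skeleton_dataset()].
#' @param num_test_subjects Number of subjects held out for testing.
#' @param seed RNG seed.
#' @return List with `train` and `test` (both `skeleton_dataset`) plus the
#'   subject id vectors `train_subjects`, `test_subjects`.
#' @export
subject_split <- function(dataset, num_test_subjects, seed = 1L) {
  subjects <- dataset_subjects(dataset)
  uniq <- sort(unique(subjects))
  num_test_subjects <- check_number(num_test_subjects, "num_test_subjects",
                                    1, integer = TRUE)
  if (num_test_subjects >= length(uniq))
    stop_validation("cannot hold out %d of %d subjects",
                    num_test_subjects, length(uniq))
  test_subj <- with_seed(seed, sort(sample(uniq, num_test_subjects)))
  in_test <- subjects %in% test_subj
  list(train = dataset[!in_test], test = dataset[in_test],
       train_subjects = setdiff(uniq, test_subj), test_subjects = test_subj)
}

#' A labelled collection of heatmap volumes
#'
#' @param volumes List of `T x H x W` arrays.
#' @param labels Integer action labels (0-based).
#' @param subjects Subject id per volume.
#' @param viewpoints Projection angle per volume (degrees).
#' @param map_type `"joint"` or `"bone"`.
#' @return A `volume_set` object.
#' @export
volume_set <- function(volumes, labels, subjects = NULL, viewpoints = NULL,
                       map_type = "joint") {
  if (length(volumes) != length(labels))
    stop_validation("`volumes` and `labels` lengths differ")
  structure(list(volumes = volumes, labels = as.integer(labels),
                 subjects = subjects %||% rep(NA_character_, length(volumes)),
                 viewpoints = viewpoints %||% rep(NA_real_, length(volumes)),
                 map_type = map_type),
            class = "volume_set")
}

#' @export
print.volume_set <- function(x, ...) {
  d <- if (length(x$volumes)) dim(x$volumes[[1L]]) else c(0L, 0L, 0L)
  cat(sprintf("<volume_set> %d %s-map volumes (%d x %d x %d), %d classes, %d viewpoints\n",
              length(x$volumes), x$map_type, d[1L], d[2L], d[3L],
              length(unique(x$labels)),
              length(unique(x$viewpoints[!is.na(x$viewpoints)]))))
  invisible(x)
}

#' @export
`[.volume_set` <- function(x, i) {
  volume_set(x$volumes[i], x$labels[i], x$subjects[i], x$viewpoints[i],
             x$map_type)
}

#' Project clips at a set of viewpoints and build heatmap volumes
#'
#' The training-set assembly stage: every clip is projected at every angle
#' in `angles` and rendered into a heatmap volume, so the output holds
#' `length(dataset) * length(angles)` volumes with labels, subjects and
#' viewpoints carried along.
#'
#' @param dataset A [skeleton_dataset()].
#' @param intrinsics A [camera_intrinsics()].
#' @param orbit An [orbit_config()].
#' @param angles Projection angles in degrees.
#' @param config A [heatmap_config()].
#' @param topology A [joint_topology()].
#' @param seed Seed for random-within-bin frame sampling (only used when
#'   `config$sampling_mode == "random"`).
#' @return A [volume_set()].
#' @export
assemble_training_set <- function(dataset, intrinsics = camera_intrinsics(),
                                  orbit = orbit_config(),
                                  angles = viewpoint_angles(90),
                                  config = heatmap_config(),
                                  topology = default_topology(), seed = 1L) {
  n <- length(dataset) * length(angles)
  volumes <- vector("list", n)
  labels <- integer(n)
  subjects <- character(n)
  viewpoints <- numeric(n)
  k <- 0L
  for (ci in seq_along(dataset)) {
    clip <- dataset[[ci]]
    for (th in angles) {
      k <- k + 1L
      s2d <- project_sequence(clip, intrinsics, orbit, th, topology)
      vol <- build_volume(s2d, topology, config,
                          seed = derive_seed(seed, k))
      volumes[[k]] <- vol$values
      labels[k] <- clip$action_label
      subjects[k] <- clip$subject_id
      viewpoints[k] <- th
    }
  }
  volume_set(volumes, labels, subjects, viewpoints, config$map_type)
}

#' Subject-disjoint k-fold cross-validation
#'
#' Splits the subjects of a training volume set into `folds` groups; each
#' fold trains the classifier on the other groups' volumes and evaluates on
#' its own, so a subject never straddles the train/validation boundary.
#'
#' @param vset A [volume_set()] with subject ids.
#' @param model_config A [slowfast_config()].
#' @param folds Number of folds (>= 2).
#' @param seed Seed controlling fold assignment and training.
#' @param control A [slowfast_control()].
#' @return A `cv_result`: list with `reports` (one `eval_report` per fold),
#'   `fold_subjects`, `accuracies` and `mean_accuracy`.
#' @export
cross_validate <- function(vset, model_config = slowfast_config(),
                           folds = 5L, seed = 1L,
                           control = slowfast_control()) {
  folds <- check_number(folds, "folds", 2, integer = TRUE)
  subjects <- vset$subjects
  uniq <- sort(unique(subjects))
  if (length(uniq) < folds)
    stop_validation("%d subjects cannot form %d subject-disjoint folds",
                    length(uniq), folds)
  shuffled <- with_seed(seed, sample(uniq))
  assignment <- rep(seq_len(folds), length.out = length(shuffled))
  fold_subjects <- split(shuffled, assignment)
  num_classes <- length(unique(vset$labels))
  reports <- vector("list", folds)
  for (f in seq_len(folds)) {
    val <- subjects %in% fold_subjects[[f]]
    ctrl <- control
    ctrl$seed <- derive_seed(seed, f)
    cfg <- model_config
    cfg$seed <- derive_seed(seed, 1000L + f)
    fit <- slowfast(vset[!val], config = cfg, control = ctrl)
    pred <- predict(fit, vset[val], type = "class")
    reports[[f]] <- evaluate_predictions(vset$labels[val], pred, num_classes)
  }
  acc <- vapply(reports, `[[`, numeric(1L), "accuracy")
  structure(list(reports = reports, fold_subjects = fold_subjects,
                 accuracies = acc, mean_accuracy = mean(acc)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds, accuracy %s (mean %.4f)\n",
              length(x$reports),
              paste(sprintf("%.3f", x$accuracies), collapse = " "),
              x$mean_accuracy))
  invisible(x)
}

#' Viewpoint-generalization experiment configuration
#'
#' Defines the training-viewpoint configurations compared by
#' [run_viewpoint_experiment()].  The default model specs mirror the
#' canonical four: A = frontal + lateral (0, 90), B = four cardinal views,
#' C = a 45-degree grid (8 views), D = a 10-degree grid (36 views); the test
#' set is projected on a 10-degree grid.
#'
#' @param model_specs Named list of angle vectors (degrees).
#' @param test_angles Angles the held-out subjects are projected at.
#' @param map_type `"joint"` or `"bone"` heatmaps.
#' @param num_test_subjects Held-out subjects.
#' @param folds Fold count recorded for optional cross-validation reporting.
#' @param heatmap A [heatmap_config()] for the experiment volumes (smaller
#'   grid than the rendering default, sized for CPU training).
#' @param model A [slowfast_config()].
#' @param control A [slowfast_control()] (short schedule by default: the
#'   heavily augmented training sets converge in a few epochs).
#' @param intrinsics,orbit Projection geometry.
#' @param seed Master seed.
#' @return A `viewpoint_experiment_config` object.
#' @export
viewpoint_experiment_config <- function(
    model_specs = list(A = c(0, 90),
                       B = c(0, 90, 180, 270),
                       C = viewpoint_angles(45),
                       D = viewpoint_angles(10)),
    test_angles = viewpoint_angles(10),
    map_type = c("joint", "bone"),
    num_test_subjects = 2L, folds = 5L,
    heatmap = heatmap_config(sigma = 1.5, out_height = 24L, out_width = 24L,
                             num_frames_out = 8L),
    model = slowfast_config(base_channels = 8L, fast_channel_fraction = 0.25,
                            stage_depths = c(1L, 1L)),
    control = slowfast_control(epochs = 2L, lr = 0.05, batch_size = 8L),
    intrinsics = camera_intrinsics(), orbit = orbit_config(), seed = 1L) {
  map_type <- match.arg(map_type)
  if (!length(model_specs) || any(!vapply(model_specs, length, integer(1L))))
    stop_validation("every model spec needs at least one angle")
  heatmap$map_type <- map_type
  structure(list(model_specs = model_specs, test_angles = test_angles,
                 map_type = map_type,
                 num_test_subjects = check_number(num_test_subjects,
                                                  "num_test_subjects", 1,
                                                  integer = TRUE),
                 folds = check_number(folds, "folds", 2, integer = TRUE),
                 heatmap = heatmap, model = model, control = control,
                 intrinsics = intrinsics, orbit = orbit,
                 seed = check_number(seed, "seed", integer = TRUE)),
            class = "viewpoint_experiment_config")
}

#' Run the viewpoint-generalization experiment
#'
#' Splits the dataset into subject-disjoint train/test sets, then, for each
#' model spec, assembles a training set of heatmap volumes projected at that
#' spec's angles, trains the classifier, and evaluates it on the held-out
#' subjects projected over the full test-angle grid.  Also reports each
#' model's "in-view" accuracy (test clips projected only at the model's own
#' training angles).
#'
#' @param dataset A [skeleton_dataset()].
#' @param config A [viewpoint_experiment_config()].
#' @param topology A [joint_topology()].
#' @param verbose Print progress.
#' @return A `viewpoint_experiment`: list with per-model `reports`
#'   (`eval_report`), `accuracies`, `in_view_accuracies`, the accuracy
#'   `ordering` (ascending), split subject ids, and the config.
#' @export
run_viewpoint_experiment <- function(dataset,
                                     config = viewpoint_experiment_config(),
                                     topology = default_topology(),
                                     verbose = FALSE) {
  if (!inherits(config, "viewpoint_experiment_config"))
    stop_validation("`config` must be a viewpoint_experiment_config")
  split <- subject_split(dataset, config$num_test_subjects, config$seed)
  num_classes <- length(unique(dataset_labels(dataset)))
  eval_hm <- config$heatmap
  eval_hm$sampling_mode <- "center"   # deterministic frames at test time
  all_test_angles <- sort(unique(c(config$test_angles,
                                   unlist(config$model_specs) %% 360)))
  if (verbose)
    message(sprintf("assembling test volumes at %d angles",
                    length(all_test_angles)))
  test_set <- assemble_training_set(split$test, config$intrinsics,
                                    config$orbit, all_test_angles, eval_hm,
                                    topology, seed = config$seed)
  reports <- list()
  in_view <- numeric()
  models <- list()
  for (mi in seq_along(config$model_specs)) {
    name <- names(config$model_specs)[mi] %||% as.character(mi)
    angles <- config$model_specs[[mi]]
    if (verbose)
      message(sprintf("model %s: training on %d viewpoints", name,
                      length(angles)))
    train_set <- assemble_training_set(split$train, config$intrinsics,
                                       config$orbit, angles, config$heatmap,
                                       topology,
                                       seed = derive_seed(config$seed, mi))
    cfg <- config$model
    cfg$num_classes <- num_classes
    cfg$seed <- derive_seed(config$seed, 500L + mi)
    ctrl <- config$control
    ctrl$seed <- derive_seed(config$seed, 900L + mi)
    fit <- slowfast(train_set, config = cfg, control = ctrl)
    on_grid <- test_set[test_set$viewpoints %in% (config$test_angles %% 360)]
    pred <- predict(fit, on_grid, type = "class")
    reports[[name]] <- evaluate_predictions(on_grid$labels, pred, num_classes)
    own <- test_set[test_set$viewpoints %in% (angles %% 360)]
    pred_own <- predict(fit, own, type = "class")
    in_view[name] <- mean(pred_own == own$labels)
    models[[name]] <- fit
    if (verbose)
      message(sprintf("model %s: accuracy %.4f (in-view %.4f)", name,
                      reports[[name]]$accuracy, in_view[name]))
  }
  acc <- vapply(reports, `[[`, numeric(1L), "accuracy")
  structure(list(reports = reports, accuracies = acc,
                 in_view_accuracies = in_view,
                 ordering = names(sort(acc)),
                 train_subjects = split$train_subjects,
                 test_subjects = split$test_subjects,
                 models = models, config = config),
            class = "viewpoint_experiment")
}

#' @export
print.viewpoint_experiment <- function(x, ...) {
  cat("<viewpoint_experiment>\n")
  for (nm in names(x$reports)) {
    cat(sprintf("  model %s: %2d viewpoints, accuracy %.4f, macro F1 %.4f, in-view %.4f\n",
                nm, length(x$config$model_specs[[nm]]),
                x$accuracies[nm], x$reports[[nm]]$macro_f1,
                x$in_view_accuracies[nm]))
  }
  cat(sprintf("  test subjects: %s; test angles: %d\n",
              paste(x$test_subjects, collapse = ", "),
              length(x$config$test_angles)))
  invisible(x)
}
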