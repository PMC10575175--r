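test_that("hand-chained gradients match finite differences", {
  set.seed(7)
  vol <- array(runif(4 * 8 * 8), c(4, 8, 8))
  cfg <- slowfast_config(num_classes = 3, slow_stride = 2,
                         fast_channel_fraction = 0.5, base_channels = 4,
                         stage_depths = c(1, 1), seed = 3)
  ns <- asNamespace("viewact")
  built <- ns$build_slowfast_params(cfg)
  model <- structure(list(params = built$params, slow_arch = built$slow_arch,
                          fast_arch = built$fast_arch,
                          fusion_units = built$fusion_units,
                          config = cfg, classes = 0:2, input_dim = dim(vol)),
                     class = "slowfast")
  fw <- ns$model_forward(model, vol, want_cache = TRUE)
  gr <- ns$model_backward(model, fw$cache, fw$prob, 2L)
  loss_at <- function(m) -log(ns$model_forward(m, vol)$prob[2])
  paths <- list(list("head", "w"), list("slow", 1L, "conv", "w"),
                list("slow", 2L, "conv1", "w"),
                list("slow", 2L, "norm1", "gamma"),
                list("slow", 3L, "norm2", "beta"),
                list("fast", 2L, "conv2", "w"),
                list("lateral", 1L, "w"), list("slow", 3L, "proj", "w"))
  getp <- function(x, p) { for (k in p) x <- x[[k]]; x }
  setp <- function(x, p, v) {
    if (length(p) == 1) x[[p[[1]]]] <- v
    else x[[p[[1]]]] <- setp(x[[p[[1]]]], p[-1], v)
    x
  }
  eps <- 1e-6
  for (p in paths) {
    g <- getp(gr, p)
    w <- getp(model$params, p)
    for (i in sample(length(w), min(3, length(w)))) {
      wp <- w; wp[i] <- wp[i] + eps
      m2 <- model; m2$params <- setp(model$params, p, wp)
      wm <- w; wm[i] <- wm[i] - eps
      m3 <- model; m3$params <- setp(model$params, p, wm)
      num <- (loss_at(m2) - loss_at(m3)) / (2 * eps)
      expect_lt(abs(num - g[i]) / max(1e-4, abs(num) + abs(g[i])), 1e-3)
    }
  }
})

test_that("parameter initialisation is reproducible and structure-sensitive", {
  ns <- asNamespace("viewact")
  cfg <- slowfast_config(num_classes = 4, seed = 11)
  a <- ns$build_slowfast_params(cfg)
  b <- ns$build_slowfast_params(cfg)
  expect_identical(a$params, b$params)
  count <- function(p) sum(unlist(ns$tree_leaves_apply(p, length)))
  nolat <- ns$build_slowfast_params(
    slowfast_config(num_classes = 4, lateral_connections = FALSE, seed = 11))
  expect_false(count(a$params) == count(nolat$params))
})

test_that("predictions are simplex-valued, deterministic and stateless", {
  sep <- make_separable_volumes(6)
  fit <- slowfast(sep$volumes, sep$labels, config = tiny_model_config(),
                  control = slowfast_control(epochs = 1))
  p <- predict(fit, sep$volumes)
  expect_equal(rowSums(p), rep(1, 6), tolerance = 1e-6)
  expect_true(all(p >= 0))
  expect_identical(p, predict(fit, sep$volumes))
  # permuting inputs permutes outputs identically
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(predict(fit, sep$volumes[perm]), p[perm, ],
               ignore_attr = TRUE)
  expect_identical(predict(fit, list()),
                   matrix(numeric(), 0, 2))
  out <- predict(fit, sep$volumes[1:2], type = "output")
  expect_length(out, 2L)
  expect_equal(out[[1]]$predicted_label,
               unname(fit$classes[which.max(out[[1]]$class_probabilities)]))
})

test_that("shape and label errors are caught", {
  sep <- make_separable_volumes(4)
  expect_error(
    slowfast(sep$volumes, sep$labels,
             config = tiny_model_config(num_classes = 3),
             control = slowfast_control(epochs = 1)),
    "absent")
  # temporal length not divisible by the slow stride
  bad <- list(array(runif(5 * 8 * 8), c(5, 8, 8)),
              array(runif(5 * 8 * 8), c(5, 8, 8)))
  expect_error(slowfast(bad, c(0, 1), config = tiny_model_config(),
                        control = slowfast_control(epochs = 1)),
               "divisible")
  fit <- slowfast(sep$volumes, sep$labels, config = tiny_model_config(),
                  control = slowfast_control(epochs = 1))
  expect_error(predict(fit, list(array(0, c(4, 8, 8)))), "shape")
})

test_that("training is seeded and bounded by the epoch cap", {
  sep <- make_separable_volumes(6)
  ctl <- slowfast_control(epochs = 3, seed = 5)
  f1 <- slowfast(sep$volumes, sep$labels, config = tiny_model_config(seed = 2),
                 control = ctl)
  f2 <- slowfast(sep$volumes, sep$labels, config = tiny_model_config(seed = 2),
                 control = ctl)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(coef(f1), coef(f2))
  expect_lte(length(f1$loss_history), 3L)
})

test_that("the tiny network overfits a separable two-class problem", {
  sep <- make_separable_volumes(8)
  fit <- slowfast(sep$volumes, sep$labels, config = tiny_model_config(seed = 1),
                  control = slowfast_control(epochs = 50, lr = 0.05, seed = 1))
  acc <- mean(predict(fit, sep$volumes, type = "class") == sep$labels)
  expect_equal(acc, 1.0)
  expect_lte(length(fit$loss_history), 50L)
})

test_that("the fitted-model interface behaves like a classical R model object", {
  sep <- make_separable_volumes(4)
  fit <- slowfast(sep$volumes, sep$labels, config = tiny_model_config(),
                  control = slowfast_control(epochs = 2))
  expect_output(print(fit), "slowfast")
  expect_output(summary(fit), "pathway|slow stride")
  cf <- coef(fit)
  expect_true(is.list(cf) && !is.null(cf$head$w))
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})
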