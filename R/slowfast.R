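# Two-pathway (slow/fast) 3D CNN over heatmap volumes.
#
# Feature maps are numeric vectors with an implicit (C, T, H, W) column-major
# layout; convolutions run through the compiled im2col/GEMM kernels, the
# remaining ops (instance normalisation, ReLU, pooling, softmax head) are
# plain R.  All gradients are hand-chained; see the finite-difference
# gradient check in the test suite.

NORM_EPS <- 1e-5

conv_init <- function(c_in, c_out, kdim, stride, pad) {
  K <- c_in * prod(kdim)
  list(w = matrix(stats::rnorm(c_out * K, 0, sqrt(2 / K)), c_out, K),
       b = numeric(c_out),
       kdim = as.integer(kdim), stride = as.integer(stride),
       pad = as.integer(pad), c_in = as.integer(c_in))
}

conv_fwd <- function(x, xdim, layer) {
  cpp_conv3d_forward(x, as.integer(xdim), layer$w, layer$b,
                     layer$kdim, layer$stride, layer$pad)
}

conv_bwd <- function(x, xdim, layer, dy, ydim) {
  cpp_conv3d_backward(x, as.integer(xdim), layer$w, dy, as.integer(ydim),
                      layer$kdim, layer$stride, layer$pad)
}

norm_init <- function(c_out) list(gamma = rep(1, c_out), beta = numeric(c_out))

norm_fwd <- function(x, C, par) {
  m <- matrix(x, nrow = C)
  mu <- rowMeans(m)
  xc <- m - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + NORM_EPS)
  xhat <- xc * inv
  list(y = as.vector(xhat * par$gamma + par$beta), xhat = xhat, inv = inv)
}

norm_bwd <- function(dy, C, par, cache) {
  dym <- matrix(dy, nrow = C)
  dgamma <- rowSums(dym * cache$xhat)
  dbeta <- rowSums(dym)
  dxhat <- dym * par$gamma
  dx <- cache$inv * (dxhat - rowMeans(dxhat) -
                       cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dx = as.vector(dx), gamma = dgamma, beta = dbeta)
}

# ---- pathway architecture -------------------------------------------------

pathway_arch <- function(width, stage_depths) {
  units <- list(list(type = "stem", c_in = 1L, c_out = width,
                     stride = c(1L, 2L, 2L)))
  c_prev <- width
  for (s in seq_along(stage_depths)) {
    c_out <- width * 2L^(s - 1L)
    for (b in seq_len(stage_depths[s])) {
      stride <- if (b == 1L && s > 1L) c(1L, 2L, 2L) else c(1L, 1L, 1L)
      units[[length(units) + 1L]] <-
        list(type = "block", c_in = c_prev, c_out = c_out, stride = stride)
      c_prev <- c_out
    }
  }
  units
}

pathway_init <- function(arch) {
  lapply(arch, function(u) {
    if (u$type == "stem") {
      list(conv = conv_init(u$c_in, u$c_out, c(3L, 3L, 3L), u$stride,
                            c(1L, 1L, 1L)),
           norm = norm_init(u$c_out))
    } else {
      p <- list(conv1 = conv_init(u$c_in, u$c_out, c(3L, 3L, 3L), u$stride,
                                  c(1L, 1L, 1L)),
                norm1 = norm_init(u$c_out),
                conv2 = conv_init(u$c_out, u$c_out, c(3L, 3L, 3L),
                                  c(1L, 1L, 1L), c(1L, 1L, 1L)),
                norm2 = norm_init(u$c_out))
      if (u$c_out != u$c_in || any(u$stride != 1L))
        p$proj <- conv_init(u$c_in, u$c_out, c(1L, 1L, 1L), u$stride,
                            c(0L, 0L, 0L))
      p
    }
  })
}

unit_fwd <- function(u, p, x, xdim) {
  if (u$type == "stem") {
    cv <- conv_fwd(x, xdim, p$conv)
    nm <- norm_fwd(cv$y, u$c_out, p$norm)
    y <- pmax(nm$y, 0)
    list(y = y, ydim = cv$ydim,
         cache = list(x = x, xdim = xdim, conv = cv, norm = nm,
                      mask = nm$y > 0))
  } else {
    c1 <- conv_fwd(x, xdim, p$conv1)
    n1 <- norm_fwd(c1$y, u$c_out, p$norm1)
    z1 <- pmax(n1$y, 0)
    c2 <- conv_fwd(z1, c1$ydim, p$conv2)
    n2 <- norm_fwd(c2$y, u$c_out, p$norm2)
    if (!is.null(p$proj)) {
      pr <- conv_fwd(x, xdim, p$proj)
      skip <- pr$y
    } else {
      pr <- NULL
      skip <- x
    }
    pre <- n2$y + skip
    y <- pmax(pre, 0)
    list(y = y, ydim = c2$ydim,
         cache = list(x = x, xdim = xdim, c1 = c1, n1 = n1, z1 = z1,
                      mask1 = n1$y > 0, c2 = c2, n2 = n2, proj = pr,
                      mask = pre > 0))
  }
}

unit_bwd <- function(u, p, cache, g) {
  if (u$type == "stem") {
    g <- g * cache$mask
    nb <- norm_bwd(g, u$c_out, p$norm, cache$norm)
    cb <- conv_bwd(cache$x, cache$xdim, p$conv, nb$dx, cache$conv$ydim)
    list(dx = cb$dx,
         grads = list(conv = list(w = cb$dw, b = cb$db),
                      norm = list(gamma = nb$gamma, beta = nb$beta)))
  } else {
    g <- g * cache$mask
    # branch: norm2 <- conv2 <- relu1 <- norm1 <- conv1
    n2b <- norm_bwd(g, u$c_out, p$norm2, cache$n2)
    c2b <- conv_bwd(cache$z1, cache$c1$ydim, p$conv2, n2b$dx, cache$c2$ydim)
    dz1 <- c2b$dx * cache$mask1
    n1b <- norm_bwd(dz1, u$c_out, p$norm1, cache$n1)
    c1b <- conv_bwd(cache$x, cache$xdim, p$conv1, n1b$dx, cache$c1$ydim)
    grads <- list(conv1 = list(w = c1b$dw, b = c1b$db),
                  norm1 = list(gamma = n1b$gamma, beta = n1b$beta),
                  conv2 = list(w = c2b$dw, b = c2b$db),
                  norm2 = list(gamma = n2b$gamma, beta = n2b$beta))
    if (!is.null(p$proj)) {
      pb <- conv_bwd(cache$x, cache$xdim, p$proj, g, cache$proj$ydim)
      grads$proj <- list(w = pb$dw, b = pb$db)
      dx <- c1b$dx + pb$dx
    } else {
      dx <- c1b$dx + g
    }
    list(dx = dx, grads = grads)
  }
}

pathway_fwd <- function(arch, params, x, xdim, fusion_in = list()) {
  caches <- vector("list", length(arch))
  acts <- vector("list", length(arch))
  for (u in seq_along(arch)) {
    r <- unit_fwd(arch[[u]], params[[u]], x, xdim)
    y <- r$y
    fu <- fusion_in[[as.character(u)]]
    if (!is.null(fu)) y <- y + fu
    caches[[u]] <- r$cache
    acts[[u]] <- list(y = y, ydim = r$ydim)
    x <- y
    xdim <- r$ydim
  }
  list(y = x, ydim = xdim, caches = caches, acts = acts)
}

pathway_bwd <- function(arch, params, caches, g, fusion_at = integer(),
                        extra = list()) {
  grads <- vector("list", length(arch))
  fusion_grads <- list()
  for (u in rev(seq_along(arch))) {
    if (u %in% fusion_at) fusion_grads[[as.character(u)]] <- g
    ex <- extra[[as.character(u)]]
    if (!is.null(ex)) g <- g + ex
    r <- unit_bwd(arch[[u]], params[[u]], caches[[u]], g)
    grads[[u]] <- r$grads
    g <- r$dx
  }
  list(dx = g, grads = grads, fusion_grads = fusion_grads)
}

# ---- model ----------------------------------------------------------------

#' Two-pathway 3D CNN configuration
#'
#' Architecture hyperparameters of the slow/fast classifier.  The slow
#' pathway sees every `slow_stride`-th frame at full channel width; the fast
#' pathway sees every frame at `fast_channel_fraction` of the width; optional
#' time-strided lateral convolutions fuse fast features into the slow
#' pathway after the stem and after each non-final stage.  Defaults are
#' deliberately tiny so that CPU training of the full viewpoint experiment
#' finishes in minutes; every dimension scales upward.
#'
#' @param num_classes Number of action classes (`NULL` to infer at fit time).
#' @param slow_stride Temporal subsampling factor of the slow pathway.
#' @param fast_channel_fraction Fast-pathway width as a fraction of
#'   `base_channels`.
#' @param base_channels Slow-pathway stem width.
#' @param stage_depths Residual blocks per stage; channels double per stage.
#' @param lateral_connections Enable fast-to-slow lateral fusion.
#' @param seed Seed for parameter initialisation.
#' @return A `slowfast_config` object.
#' @export
slowfast_config <- function(num_classes = NULL, slow_stride = 4L,
                            fast_channel_fraction = 1 / 8,
                            base_channels = 16L, stage_depths = c(2L, 2L),
                            lateral_connections = TRUE, seed = 1L) {
  if (!is.null(num_classes))
    num_classes <- check_number(num_classes, "num_classes", 2, integer = TRUE)
  structure(list(
    num_classes = num_classes,
    slow_stride = check_number(slow_stride, "slow_stride", 1, integer = TRUE),
    fast_channel_fraction = check_number(fast_channel_fraction,
                                         "fast_channel_fraction", 0, 1,
                                         strict_lower = TRUE),
    base_channels = check_number(base_channels, "base_channels", 1,
                                 integer = TRUE),
    stage_depths = vapply(stage_depths, check_number, integer(1L),
                          name = "stage_depths", lower = 1, integer = TRUE),
    lateral_connections = check_flag(lateral_connections,
                                     "lateral_connections"),
    seed = check_number(seed, "seed", integer = TRUE)
  ), class = "slowfast_config")
}

#' Training control for [slowfast()]
#'
#' Plain stochastic gradient descent with momentum on the cross-entropy
#' loss.  Training is fully reproducible from `seed` (deterministic
#' shuffling and initialisation).
#'
#' @param epochs Epoch cap.
#' @param lr Learning rate.
#' @param momentum Momentum coefficient.
#' @param batch_size Minibatch size.
#' @param weight_decay L2 penalty coefficient.
#' @param shuffle Reshuffle samples every epoch.
#' @param seed RNG seed for shuffling (and initialisation when the model
#'   config carries no seed).
#' @param verbose Print per-epoch loss.
#' @return A `slowfast_control` object.
#' @export
slowfast_control <- function(epochs = 30L, lr = 0.04, momentum = 0.9,
                             batch_size = 8L, weight_decay = 1e-4,
                             shuffle = TRUE, seed = 1L, verbose = FALSE) {
  structure(list(
    epochs = check_number(epochs, "epochs", 1, integer = TRUE),
    lr = check_number(lr, "lr", 0, strict_lower = TRUE),
    momentum = check_number(momentum, "momentum", 0, 1),
    batch_size = check_number(batch_size, "batch_size", 1, integer = TRUE),
    weight_decay = check_number(weight_decay, "weight_decay", 0),
    shuffle = check_flag(shuffle, "shuffle"),
    seed = check_number(seed, "seed", integer = TRUE),
    verbose = check_flag(verbose, "verbose")
  ), class = "slowfast_control")
}

build_slowfast_params <- function(config) {
  base <- config$base_channels
  fastw <- max(1L, as.integer(round(base * config$fast_channel_fraction)))
  slow_arch <- pathway_arch(base, config$stage_depths)
  fast_arch <- pathway_arch(fastw, config$stage_depths)
  S <- length(config$stage_depths)
  fusion_units <- integer()
  if (config$lateral_connections) {
    after_stage <- 1L + cumsum(config$stage_depths)
    fusion_units <- c(1L, after_stage[-S])
  }
  with_seed(config$seed, {
    params <- list(slow = pathway_init(slow_arch),
                   fast = pathway_init(fast_arch))
    if (length(fusion_units)) {
      params$lateral <- lapply(fusion_units, function(u) {
        cf <- fast_arch[[u]]$c_out
        cs <- slow_arch[[u]]$c_out
        conv_init(cf, cs, c(config$slow_stride, 1L, 1L),
                  c(config$slow_stride, 1L, 1L), c(0L, 0L, 0L))
      })
    }
    feat <- slow_arch[[length(slow_arch)]]$c_out +
      fast_arch[[length(fast_arch)]]$c_out
    K <- config$num_classes
    params$head <- list(w = matrix(stats::rnorm(K * feat, 0, sqrt(1 / feat)),
                                   K, feat),
                        b = numeric(K))
    list(params = params, slow_arch = slow_arch, fast_arch = fast_arch,
         fusion_units = fusion_units, feat = feat)
  })
}

split_slow_input <- function(vol, slow_stride) {
  d <- dim(vol)
  if (d[1L] %% slow_stride != 0L)
    stop_validation("temporal length %d is not divisible by slow_stride %d",
                    d[1L], slow_stride)
  vol[seq(1L, d[1L], by = slow_stride), , , drop = FALSE]
}

model_forward <- function(model, vol, want_cache = FALSE) {
  d <- dim(vol)
  xf <- as.vector(vol)
  xfdim <- c(1L, d)
  xs_arr <- split_slow_input(vol, model$config$slow_stride)
  xs <- as.vector(xs_arr)
  xsdim <- c(1L, dim(xs_arr))
  fast <- pathway_fwd(model$fast_arch, model$params$fast, xf, xfdim)
  fusion_in <- list()
  lat_cache <- list()
  for (i in seq_along(model$fusion_units)) {
    u <- model$fusion_units[i]
    act <- fast$acts[[u]]
    lat <- conv_fwd(act$y, act$ydim, model$params$lateral[[i]])
    fusion_in[[as.character(u)]] <- lat$y
    lat_cache[[i]] <- lat
  }
  slow <- pathway_fwd(model$slow_arch, model$params$slow, xs, xsdim,
                      fusion_in)
  cs <- slow$ydim[1L]; cf <- fast$ydim[1L]
  fs <- rowMeans(matrix(slow$y, nrow = cs))
  ff <- rowMeans(matrix(fast$y, nrow = cf))
  feat <- c(fs, ff)
  logits <- as.vector(model$params$head$w %*% feat + model$params$head$b)
  m <- max(logits)
  p <- exp(logits - m)
  p <- p / sum(p)
  out <- list(prob = p)
  if (want_cache)
    out$cache <- list(fast = fast, slow = slow, lat = lat_cache, feat = feat,
                      cs = cs, cf = cf)
  out
}

model_backward <- function(model, cache, prob, label_idx) {
  dlogits <- prob
  dlogits[label_idx] <- dlogits[label_idx] - 1
  head <- model$params$head
  dW <- outer(dlogits, cache$feat)
  db <- dlogits
  dfeat <- as.vector(crossprod(head$w, dlogits))
  cs <- cache$cs; cf <- cache$cf
  ls <- prod(cache$slow$ydim[-1L]); lf <- prod(cache$fast$ydim[-1L])
  dslow_out <- as.vector(matrix(dfeat[seq_len(cs)] / ls, cs, ls))
  dfast_out <- as.vector(matrix(dfeat[cs + seq_len(cf)] / lf, cf, lf))
  sb <- pathway_bwd(model$slow_arch, model$params$slow, cache$slow$caches,
                    dslow_out, fusion_at = model$fusion_units)
  extra <- list()
  lat_grads <- vector("list", length(model$fusion_units))
  for (i in seq_along(model$fusion_units)) {
    u <- model$fusion_units[i]
    act <- cache$fast$acts[[u]]
    lb <- conv_bwd(act$y, act$ydim, model$params$lateral[[i]],
                   sb$fusion_grads[[as.character(u)]], cache$lat[[i]]$ydim)
    lat_grads[[i]] <- list(w = lb$dw, b = lb$db)
    key <- as.character(u)
    extra[[key]] <- if (is.null(extra[[key]])) lb$dx else extra[[key]] + lb$dx
  }
  fb <- pathway_bwd(model$fast_arch, model$params$fast, cache$fast$caches,
                    dfast_out, extra = extra)
  grads <- list(slow = sb$grads, fast = fb$grads, head = list(w = dW, b = db))
  if (length(model$fusion_units)) grads$lateral <- lat_grads
  grads
}

# recursive tree ops over nested parameter lists (numeric leaves only)
tree_leaves_apply <- function(a, f) {
  if (is.list(a)) lapply(a, tree_leaves_apply, f = f) else f(a)
}

param_slots <- c("w", "b", "gamma", "beta")

# Which elements of a parameter list are trainable (recursed into)?  Lists
# always; numeric leaves only when named w/b/gamma/beta — conv metadata
# (kdim, stride, pad, c_in) stays untouched.
trainable_idx <- function(a) {
  nms <- names(a)
  vapply(seq_along(a), function(i) {
    is.list(a[[i]]) || (!is.null(nms) && nms[i] %in% param_slots)
  }, logical(1L))
}

tree_update <- function(params, grads, vel, lr, momentum, wd) {
  if (is.list(params)) {
    keys <- which(trainable_idx(params))
    if (!is.null(names(params))) keys <- names(params)[keys]
    for (i in keys) {
      r <- tree_update(params[[i]], grads[[i]], vel[[i]], lr, momentum, wd)
      params[[i]] <- r$p
      vel[[i]] <- r$v
    }
    list(p = params, v = vel)
  } else {
    g <- grads + wd * params
    v <- momentum * vel + g
    list(p = params - lr * v, v = v)
  }
}

tree_add <- function(a, b) {
  if (is.list(a)) {
    keys <- which(trainable_idx(a))
    if (!is.null(names(a))) keys <- names(a)[keys]
    for (i in keys) a[[i]] <- tree_add(a[[i]], b[[i]])
    a
  } else a + b
}

tree_scale <- function(a, s) {
  if (is.list(a)) {
    for (i in which(trainable_idx(a))) a[[i]] <- tree_scale(a[[i]], s)
    a
  } else a * s
}

param_zero_like <- function(params) tree_scale(params, 0)

extract_volumes <- function(x) {
  if (inherits(x, "volume_set"))
    return(list(vols = x$volumes, labels = x$labels))
  if (is.list(x) && length(x) && inherits(x[[1L]], "heatmap_volume"))
    return(list(vols = lapply(x, `[[`, "values"),
                labels = vapply(x, `[[`, numeric(1L), "action_label")))
  if (is.list(x)) return(list(vols = x, labels = NULL))
  stop_validation("`x` must be a volume_set, a list of heatmap_volume, or a list of T x H x W arrays")
}

#' Fit the two-pathway 3D CNN action classifier
#'
#' Trains a compact slow/fast 3D convolutional network on heatmap volumes by
#' minimising the multinomial cross-entropy with stochastic gradient descent
#' (momentum, optional weight decay).  Every source of randomness
#' (initialisation, shuffling) is seeded, so identical inputs give identical
#' fits.
#'
#' @param x Training volumes: a `volume_set` (see
#'   [assemble_training_set()]), a list of `heatmap_volume`s, or a list of
#'   `T x H x W` arrays.
#' @param y Integer class labels (0-based) when `x` carries none.
#' @param config A [slowfast_config()].
#' @param control A [slowfast_control()].
#' @return An object of class `slowfast`: the fitted network with
#'   `loss_history` (mean cross-entropy per epoch), `classes` (label set),
#'   `config` and the learned parameters (accessible via `coef()`).
#' @seealso [predict.slowfast()], [slowfast_control()]
#' @examples
#' \donttest{
#' vols <- replicate(8, array(runif(4 * 8 * 8), c(4, 8, 8)), simplify = FALSE)
#' fit <- slowfast(vols, y = rep(0:1, each = 4),
#'                 config = slowfast_config(slow_stride = 2, base_channels = 4,
#'                                          stage_depths = 1),
#'                 control = slowfast_control(epochs = 2))
#' predict(fit, vols[1:2])
#' }
#' @export
slowfast <- function(x, y = NULL, config = slowfast_config(),
                     control = slowfast_control()) {
  xs <- extract_volumes(x)
  vols <- xs$vols
  y <- y %||% xs$labels
  if (is.null(y) || length(y) != length(vols))
    stop_validation("labels are missing or do not match the number of volumes")
  if (length(vols) == 0L) stop_validation("no training volumes")
  classes <- sort(unique(as.integer(y)))
  if (!is.null(config$num_classes)) {
    if (length(classes) < config$num_classes) {
      missing <- setdiff(seq_len(config$num_classes) - 1L, classes)
      stop_validation("class(es) %s absent from training labels",
                      paste(missing, collapse = ", "))
    }
    classes <- sort(unique(c(classes, seq_len(config$num_classes) - 1L)))
  }
  config$num_classes <- length(classes)
  yidx <- match(as.integer(y), classes)
  d <- dim(vols[[1L]])
  if (length(d) != 3L) stop_validation("volumes must be T x H x W arrays")
  built <- build_slowfast_params(config)
  model <- structure(list(params = built$params,
                          slow_arch = built$slow_arch,
                          fast_arch = built$fast_arch,
                          fusion_units = built$fusion_units,
                          config = config, classes = classes,
                          input_dim = d, loss_history = numeric()),
                     class = "slowfast")
  vel <- param_zero_like(model$params)
  n <- length(vols)
  with_seed(control$seed, {
    for (epoch in seq_len(control$epochs)) {
      ord <- if (control$shuffle) sample.int(n) else seq_len(n)
      epoch_loss <- 0
      b0 <- 1L
      while (b0 <= n) {
        b1 <- min(b0 + control$batch_size - 1L, n)
        idx <- ord[b0:b1]
        gacc <- NULL
        for (i in idx) {
          fw <- model_forward(model, vols[[i]], want_cache = TRUE)
          p <- fw$prob
          epoch_loss <- epoch_loss - log(max(p[yidx[i]], 1e-12))
          g <- model_backward(model, fw$cache, p, yidx[i])
          gacc <- if (is.null(gacc)) g else tree_add(gacc, g)
        }
        gacc <- tree_scale(gacc, 1 / length(idx))
        upd <- tree_update(model$params, gacc, vel, control$lr,
                           control$momentum, control$weight_decay)
        model$params <- upd$p
        vel <- upd$v
        b0 <- b1 + 1L
      }
      model$loss_history <- c(model$loss_history, epoch_loss / n)
      if (control$verbose)
        message(sprintf("epoch %3d  loss %.4f", epoch, epoch_loss / n))
    }
  })
  model$control <- control
  model
}

#' Predict action classes for heatmap volumes
#'
#' @param object A fitted [slowfast()] model.
#' @param newdata Volumes in any form accepted by [slowfast()].
#' @param type `"prob"` for an N x K probability matrix, `"class"` for the
#'   predicted labels, `"output"` for a list of per-sample outputs
#'   (`class_probabilities`, `predicted_label`; argmax with lowest-index
#'   tie-break).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.slowfast <- function(object, newdata,
                             type = c("prob", "class", "output"), ...) {
  type <- match.arg(type)
  vols <- extract_volumes(newdata)$vols
  if (length(vols) == 0L) {
    return(switch(type,
                  prob = matrix(numeric(), 0L, length(object$classes)),
                  class = integer(), output = list()))
  }
  probs <- matrix(NA_real_, length(vols), length(object$classes))
  for (i in seq_along(vols)) {
    if (!identical(dim(vols[[i]]), object$input_dim))
      stop_validation("volume %d has shape (%s); model expects (%s)",
                      i, paste(dim(vols[[i]]), collapse = ", "),
                      paste(object$input_dim, collapse = ", "))
    probs[i, ] <- model_forward(object, vols[[i]])$prob
  }
  colnames(probs) <- object$classes
  switch(type,
         prob = probs,
         class = object$classes[max.col(probs, ties.method = "first")],
         output = lapply(seq_len(nrow(probs)), function(i) {
           list(class_probabilities = probs[i, ],
                predicted_label = object$classes[which.max(probs[i, ])])
         }))
}

n_parameters <- function(model) {
  sum(unlist(tree_leaves_apply(coef(model), length)))
}

#' @export
coef.slowfast <- function(object, ...) {
  strip <- function(a) {
    if (is.list(a)) {
      if (is.null(names(a))) return(lapply(a, strip))
      keep <- names(a) %in% param_slots | vapply(a, is.list, logical(1L))
      lapply(a[keep], strip)
    } else a
  }
  strip(object$params)
}

#' @export
print.slowfast <- function(x, ...) {
  cat(sprintf("<slowfast> %d classes, input %s, %d parameters\n",
              length(x$classes), paste(x$input_dim, collapse = "x"),
              n_parameters(x)))
  if (length(x$loss_history))
    cat(sprintf("  trained %d epochs, final cross-entropy %.4f\n",
                length(x$loss_history), tail(x$loss_history, 1L)))
  invisible(x)
}

#' @export
summary.slowfast <- function(object, ...) {
  cfg <- object$config
  cat("Two-pathway 3D CNN (slow/fast)\n")
  cat(sprintf("  input volume        : %s (T x H x W)\n",
              paste(object$input_dim, collapse = " x ")))
  cat(sprintf("  classes             : %d\n", length(object$classes)))
  cat(sprintf("  slow stride         : %d\n", cfg$slow_stride))
  cat(sprintf("  base channels       : %d (fast fraction %.3g)\n",
              cfg$base_channels, cfg$fast_channel_fraction))
  cat(sprintf("  stage depths        : %s\n",
              paste(cfg$stage_depths, collapse = ", ")))
  cat(sprintf("  lateral connections : %s\n", cfg$lateral_connections))
  cat(sprintf("  parameters          : %d\n", n_parameters(object)))
  if (length(object$loss_history))
    cat(sprintf("  epochs / final loss : %d / %.4f\n",
                length(object$loss_history), tail(object$loss_history, 1L)))
  invisible(object)
}

#' @export
plot.slowfast <- function(x, ...) {
  if (!length(x$loss_history)) stop("model has no training history")
  plot(seq_along(x$loss_history), x$loss_history, type = "b",
       xlab = "epoch", ylab = "mean cross-entropy", main = "training loss",
       ...)
  invisible(x)
}
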