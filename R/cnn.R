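# Optional trainable convolutional provider. A compact U-style encoder-decoder
# (paired 3x3 convolutions + ReLU + dropout per level, 2x2 max-pooling,
# nearest-neighbour up-convolutions with skip concatenation, final 1x1
# convolution + sigmoid) implemented natively: im2col convolutions backed by
# BLAS matrix products, manual backpropagation, Adam, binary cross-entropy,
# and plateau learning-rate decay. Intended for desk-scale experiments (small
# inputs, few filters); the level-set phase never depends on it.

#' CNN provider configuration
#'
#' Training defaults mirror the standard recipe for this family of models:
#' Adam with initial learning rate 1e-4, binary cross-entropy loss, dropout
#' 0.5, and a 10% learning-rate decay whenever the validation loss has not
#' improved for 10 consecutive epochs.
#'
#' @param architecture `"unt"` (plain encoder-decoder) or `"bcd_unt"` (dense
#'   connections in the deepest encoder block, skips fused by a bidirectional
#'   convolutional recurrent unit). Training is implemented for `"unt"`;
#'   `"bcd_unt"` is available for architecture inspection via [build_model()].
#' @param depth Number of encoder levels.
#' @param base_filters Filters at the first level (doubled per level).
#' @param dense_blocks Densely connected convolution stages in the deepest
#'   encoder block of `"bcd_unt"` (default 3).
#' @param dropout Dropout rate in \[0, 1).
#' @param loss `"bce"` or `"ds_bce"` (binary cross-entropy plus soft-Dice).
#' @param initial_learning_rate Positive Adam step size.
#' @param lr_decay_factor Multiplicative decay on plateau (0.9 = decay by 10%).
#' @param lr_patience Epochs without validation improvement before decaying.
#' @param epochs Training epochs (>= 1).
#' @param batch_size Mini-batch size.
#' @param input_size `(rows, cols)`; must be divisible by `2^depth`.
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return A validated list of class `cnn_config`.
#' @export
cnn_config <- function(architecture = c("unt", "bcd_unt"), depth = 2,
                       base_filters = 4, dense_blocks = 3, dropout = 0.5,
                       loss = c("bce", "ds_bce"), initial_learning_rate = 1e-4,
                       lr_decay_factor = 0.9, lr_patience = 10, epochs = 10,
                       batch_size = 4, input_size = c(64, 64), seed = 1L) {
  cfg <- list(architecture = match.arg(architecture), depth = as.integer(depth),
              base_filters = as.integer(base_filters),
              dense_blocks = as.integer(dense_blocks), dropout = dropout,
              loss = match.arg(loss),
              initial_learning_rate = initial_learning_rate,
              lr_decay_factor = lr_decay_factor,
              lr_patience = as.integer(lr_patience), epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              input_size = as.integer(input_size), seed = as.integer(seed))
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop("dropout must lie in [0, 1)", call. = FALSE)
  if (cfg$initial_learning_rate <= 0) stop("learning rate must be positive", call. = FALSE)
  if (cfg$epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (cfg$depth < 1) stop("depth must be >= 1", call. = FALSE)
  structure(cfg, class = "cnn_config")
}

#' Describe the network architecture
#'
#' Returns an inspectable layer table (no weights): layer name, type, output
#' spatial size and channels. The output spatial size always equals the input
#' size and the per-pixel output is a sigmoid probability in (0, 1).
#'
#' @param cfg A [cnn_config].
#' @return A tibble of class `cnn_model_description` with columns `layer`,
#'   `type`, `out_rows`, `out_cols`, `out_channels`.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "cnn_config"))
  h <- cfg$input_size[1]; w <- cfg$input_size[2]
  div <- 2^cfg$depth
  if (h %% div != 0 || w %% div != 0) {
    stop(sprintf("input size %dx%d not divisible by 2^depth = %d", h, w, div),
         call. = FALSE)
  }
  rows <- list()
  add <- function(layer, type, r, c, ch) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      layer = layer, type = type, out_rows = r, out_cols = c, out_channels = ch)
  }
  add("input", "input", h, w, 1L)
  ch <- cfg$base_filters
  hh <- h; ww <- w
  for (i in seq_len(cfg$depth)) {
    deepest <- i == cfg$depth && cfg$architecture == "bcd_unt"
    if (deepest) {
      acc <- ch
      for (j in seq_len(cfg$dense_blocks)) {
        add(sprintf("enc%d_dense%d", i, j), "conv3x3_relu_dense", hh, ww, ch)
        acc <- acc + ch
      }
      add(sprintf("enc%d_dropout", i), "dropout", hh, ww, ch)
    } else {
      add(sprintf("enc%d_conv1", i), "conv3x3_relu", hh, ww, ch)
      add(sprintf("enc%d_conv2", i), "conv3x3_relu", hh, ww, ch)
      add(sprintf("enc%d_dropout", i), "dropout", hh, ww, ch)
    }
    add(sprintf("enc%d_pool", i), "maxpool2x2", hh %/% 2, ww %/% 2, ch)
    hh <- hh %/% 2; ww <- ww %/% 2
    ch <- ch * 2L
  }
  add("bottleneck_conv1", "conv3x3_relu", hh, ww, ch)
  add("bottleneck_conv2", "conv3x3_relu", hh, ww, ch)
  for (i in rev(seq_len(cfg$depth))) {
    hh <- hh * 2L; ww <- ww * 2L; ch <- ch %/% 2L
    add(sprintf("dec%d_upconv", i), "upconv2x2", hh, ww, ch)
    fuse <- if (cfg$architecture == "bcd_unt") "bconvlstm_fuse" else "skip_concat"
    add(sprintf("dec%d_fuse", i), fuse, hh, ww, 2L * ch)
    add(sprintf("dec%d_conv1", i), "conv3x3_relu", hh, ww, ch)
    add(sprintf("dec%d_conv2", i), "conv3x3_relu", hh, ww, ch)
  }
  add("output", "conv1x1_sigmoid", h, w, 1L)
  out <- do.call(rbind, rows)
  class(out) <- c("cnn_model_description", class(out))
  attr(out, "config") <- cfg
  out
}

# ---- native tensor ops (H, W, C arrays) ------------------------------------

im2col3 <- function(x) { # 3x3 patches, zero padding 1
  h <- dim(x)[1]; w <- dim(x)[2]; ch <- dim(x)[3]
  pad <- array(0, c(h + 2, w + 2, ch))
  pad[2:(h + 1), 2:(w + 1), ] <- x
  cols <- matrix(0, h * w, 9 * ch)
  o <- 0
  for (dc in 0:2) for (dr in 0:2) {
    cols[, o + seq_len(ch)] <- pad[dr + seq_len(h), dc + seq_len(w), , drop = FALSE]
    o <- o + ch
  }
  cols
}

col2im3 <- function(dcols, h, w, ch) {
  dpad <- array(0, c(h + 2, w + 2, ch))
  o <- 0
  for (dc in 0:2) for (dr in 0:2) {
    dpad[dr + seq_len(h), dc + seq_len(w), ] <-
      dpad[dr + seq_len(h), dc + seq_len(w), , drop = FALSE] +
      array(dcols[, o + seq_len(ch)], c(h, w, ch))
    o <- o + ch
  }
  dpad[2:(h + 1), 2:(w + 1), , drop = FALSE]
}

conv_fwd <- function(x, Wm, b, k = 3) {
  h <- dim(x)[1]; w <- dim(x)[2]
  cols <- if (k == 3) im2col3(x) else matrix(x, h * w, dim(x)[3])
  y <- sweep(cols %*% Wm, 2, b, "+")
  list(y = array(y, c(h, w, ncol(Wm))), cols = cols)
}

conv_bwd <- function(dy, cache_cols, Wm, in_dim, k = 3) {
  h <- in_dim[1]; w <- in_dim[2]; ch <- in_dim[3]
  dym <- matrix(dy, h * w, length(dy) / (h * w))
  dW <- crossprod(cache_cols, dym)
  db <- colSums(dym)
  dcols <- dym %*% t(Wm)
  dx <- if (k == 3) col2im3(dcols, h, w, ch) else array(dcols, c(h, w, ch))
  list(dx = dx, dW = dW, db = db)
}

relu_fwd <- function(x) { m <- x > 0; list(y = x * m, mask = m) }

maxpool_fwd <- function(x) {
  h <- dim(x)[1]; w <- dim(x)[2]; ch <- dim(x)[3]
  a <- x[seq(1, h, 2), seq(1, w, 2), , drop = FALSE]
  b <- x[seq(1, h, 2), seq(2, w, 2), , drop = FALSE]
  cc <- x[seq(2, h, 2), seq(1, w, 2), , drop = FALSE]
  d <- x[seq(2, h, 2), seq(2, w, 2), , drop = FALSE]
  y <- pmax(a, b, cc, d)
  list(y = y, which = (y == a) * 1 + (y != a & y == b) * 2 +
         (y != a & y != b & y == cc) * 3 + (y != a & y != b & y != cc & y == d) * 4)
}

maxpool_bwd <- function(dy, which, in_dim) {
  dx <- array(0, in_dim)
  h2 <- dim(dy)[1]; w2 <- dim(dy)[2]
  dx[seq(1, in_dim[1], 2), seq(1, in_dim[2], 2), ] <- dy * (which == 1)
  dx[seq(1, in_dim[1], 2), seq(2, in_dim[2], 2), ] <-
    dx[seq(1, in_dim[1], 2), seq(2, in_dim[2], 2), , drop = FALSE] + dy * (which == 2)
  dx[seq(2, in_dim[1], 2), seq(1, in_dim[2], 2), ] <-
    dx[seq(2, in_dim[1], 2), seq(1, in_dim[2], 2), , drop = FALSE] + dy * (which == 3)
  dx[seq(2, in_dim[1], 2), seq(2, in_dim[2], 2), ] <-
    dx[seq(2, in_dim[1], 2), seq(2, in_dim[2], 2), , drop = FALSE] + dy * (which == 4)
  dx
}

upsample_fwd <- function(x) {
  x[rep(seq_len(dim(x)[1]), each = 2), rep(seq_len(dim(x)[2]), each = 2), ,
    drop = FALSE]
}

upsample_bwd <- function(dy) {
  h <- dim(dy)[1]; w <- dim(dy)[2]
  dy[seq(1, h, 2), seq(1, w, 2), , drop = FALSE] +
    dy[seq(1, h, 2), seq(2, w, 2), , drop = FALSE] +
    dy[seq(2, h, 2), seq(1, w, 2), , drop = FALSE] +
    dy[seq(2, h, 2), seq(2, w, 2), , drop = FALSE]
}

concat3 <- function(a, b) array(c(a, b), c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))

# He-normal initialization of all unt weights
init_unt_weights <- function(cfg) {
  params <- list()
  mk <- function(name, fan_in9, cout) {
    params[[paste0(name, "_W")]] <<- matrix(
      stats::rnorm(fan_in9 * cout, 0, sqrt(2 / fan_in9)), fan_in9, cout)
    params[[paste0(name, "_b")]] <<- numeric(cout)
  }
  ch_in <- 1L
  for (i in seq_len(cfg$depth)) {
    ch <- cfg$base_filters * 2^(i - 1)
    mk(sprintf("enc%d_c1", i), 9 * ch_in, ch)
    mk(sprintf("enc%d_c2", i), 9 * ch, ch)
    ch_in <- ch
  }
  chb <- cfg$base_filters * 2^cfg$depth
  mk("bott_c1", 9 * ch_in, chb)
  mk("bott_c2", 9 * chb, chb)
  ch_up <- chb
  for (i in rev(seq_len(cfg$depth))) {
    ch <- cfg$base_filters * 2^(i - 1)
    mk(sprintf("dec%d_up", i), 9 * ch_up, ch)
    mk(sprintf("dec%d_c1", i), 9 * (2 * ch), ch)
    mk(sprintf("dec%d_c2", i), 9 * ch, ch)
    ch_up <- ch
  }
  mk("out", cfg$base_filters, 1L) # 1x1 convolution
  params
}

# forward pass; `training` enables dropout (inverted scaling)
unt_forward <- function(x, params, cfg, training = FALSE) {
  cache <- list(x = x)
  cur <- x
  for (i in seq_len(cfg$depth)) {
    for (j in 1:2) {
      nm <- sprintf("enc%d_c%d", i, j)
      cv <- conv_fwd(cur, params[[paste0(nm, "_W")]], params[[paste0(nm, "_b")]])
      rl <- relu_fwd(cv$y)
      cache[[paste0(nm, "_cols")]] <- cv$cols
      cache[[paste0(nm, "_mask")]] <- rl$mask
      cache[[paste0(nm, "_indim")]] <- dim(cur)
      cur <- rl$y
    }
    if (training && cfg$dropout > 0) {
      dm <- (array(stats::runif(length(cur)), dim(cur)) >= cfg$dropout) /
        (1 - cfg$dropout)
      cache[[sprintf("enc%d_dropmask", i)]] <- dm
      cur <- cur * dm
    }
    cache[[sprintf("skip%d", i)]] <- cur
    mp <- maxpool_fwd(cur)
    cache[[sprintf("enc%d_poolwhich", i)]] <- mp$which
    cache[[sprintf("enc%d_pooldim", i)]] <- dim(cur)
    cur <- mp$y
  }
  for (j in 1:2) {
    nm <- sprintf("bott_c%d", j)
    cv <- conv_fwd(cur, params[[paste0(nm, "_W")]], params[[paste0(nm, "_b")]])
    rl <- relu_fwd(cv$y)
    cache[[paste0(nm, "_cols")]] <- cv$cols
    cache[[paste0(nm, "_mask")]] <- rl$mask
    cache[[paste0(nm, "_indim")]] <- dim(cur)
    cur <- rl$y
  }
  for (i in rev(seq_len(cfg$depth))) {
    up <- upsample_fwd(cur)
    nm <- sprintf("dec%d_up", i)
    cv <- conv_fwd(up, params[[paste0(nm, "_W")]], params[[paste0(nm, "_b")]])
    rl <- relu_fwd(cv$y)
    cache[[paste0(nm, "_cols")]] <- cv$cols
    cache[[paste0(nm, "_mask")]] <- rl$mask
    cache[[paste0(nm, "_indim")]] <- dim(up)
    cache[[sprintf("dec%d_updim", i)]] <- dim(cur)
    cur <- concat3(rl$y, cache[[sprintf("skip%d", i)]])
    for (j in 1:2) {
      nm <- sprintf("dec%d_c%d", i, j)
      cv <- conv_fwd(cur, params[[paste0(nm, "_W")]], params[[paste0(nm, "_b")]])
      rl <- relu_fwd(cv$y)
      cache[[paste0(nm, "_cols")]] <- cv$cols
      cache[[paste0(nm, "_mask")]] <- rl$mask
      cache[[paste0(nm, "_indim")]] <- dim(cur)
      cur <- rl$y
    }
  }
  cv <- conv_fwd(cur, params$out_W, params$out_b, k = 1)
  cache$out_cols <- cv$cols
  cache$out_indim <- dim(cur)
  z <- cv$y
  p <- 1 / (1 + exp(-z))
  cache$p <- p
  list(p = p, cache = cache)
}

# backward pass from dL/dz (z = pre-sigmoid logits); returns named gradients
unt_backward_ordered <- function(dz, params, cfg, cache) {
  grads <- list()
  bw <- function(nm, dy, k = 3) {
    g <- conv_bwd(dy, cache[[paste0(nm, "_cols")]], params[[paste0(nm, "_W")]],
                  cache[[paste0(nm, "_indim")]], k = k)
    grads[[paste0(nm, "_W")]] <<- g$dW
    grads[[paste0(nm, "_b")]] <<- g$db
    g$dx
  }
  dskip <- list()
  dcur <- bw("out", dz, k = 1)
  # decoder ran i = depth..1 in forward; reverse: i = 1..depth
  for (i in seq_len(cfg$depth)) {
    for (j in 2:1) {
      nm <- sprintf("dec%d_c%d", i, j)
      dcur <- bw(nm, dcur * cache[[paste0(nm, "_mask")]])
    }
    ch <- dim(dcur)[3] / 2
    d_up_out <- dcur[, , seq_len(ch), drop = FALSE]
    dskip[[i]] <- dcur[, , ch + seq_len(ch), drop = FALSE]
    nm <- sprintf("dec%d_up", i)
    d_up_in <- bw(nm, d_up_out * cache[[paste0(nm, "_mask")]])
    dcur <- upsample_bwd(d_up_in)
  }
  for (j in 2:1) {
    nm <- sprintf("bott_c%d", j)
    dcur <- bw(nm, dcur * cache[[paste0(nm, "_mask")]])
  }
  # encoder ran i = 1..depth in forward; reverse: i = depth..1
  for (i in rev(seq_len(cfg$depth))) {
    dpool <- maxpool_bwd(dcur, cache[[sprintf("enc%d_poolwhich", i)]],
                         cache[[sprintf("enc%d_pooldim", i)]])
    dcur <- dpool + dskip[[i]]
    dm <- cache[[sprintf("enc%d_dropmask", i)]]
    if (!is.null(dm)) dcur <- dcur * dm
    for (j in 2:1) {
      nm <- sprintf("enc%d_c%d", i, j)
      dcur <- bw(nm, dcur * cache[[paste0(nm, "_mask")]])
    }
  }
  grads
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

loss_and_dz <- function(p, y, loss) {
  n <- length(p)
  l <- bce_loss(p, y)
  dz <- (p - y) / n # sigmoid + BCE combined gradient
  if (loss == "ds_bce") {
    sp <- sum(p); sy <- sum(y); spy <- sum(p * y)
    l <- l + (1 - 2 * spy / (sp + sy))
    dp_dice <- -2 * (y * (sp + sy) - spy) / (sp + sy)^2
    dz <- dz + dp_dice * p * (1 - p)
  }
  list(loss = l, dz = dz)
}

prep_pair <- function(pr) {
  v <- normalize_intensity(pr$image)$pixels
  list(x = array(v, c(dim(v), 1L)), y = array(pr$mask$labels + 0, c(dim(v), 1L)))
}

#' Train the convolutional provider
#'
#' Seeded mini-batch training with Adam and (by default) binary cross-entropy,
#' emitting per-epoch loss and pixel-accuracy curves for the training and
#' validation sets (epoch 0 records the untrained network). The learning rate
#' decays by `1 - lr_decay_factor` whenever the validation loss has not
#' improved for `lr_patience` consecutive epochs. A non-finite loss aborts
#' with diagnostics.
#'
#' @param train,val Non-empty lists of `list(image = <image_grid>,
#'   mask = <label_mask>)` pairs.
#' @param cfg A [cnn_config] with `architecture = "unt"`.
#' @return A list of class `cnn_provider`: `params` (weights), `config`, and
#'   `curves` (tibble: epoch, lr, train_loss, val_loss, train_acc, val_acc).
#' @export
train_provider <- function(train, val, cfg) {
  stopifnot(inherits(cfg, "cnn_config"))
  if (!length(train)) stop("training set is empty", call. = FALSE)
  if (!length(val)) stop("validation set is empty", call. = FALSE)
  if (cfg$architecture != "unt") {
    stop("training is implemented for the 'unt' architecture; 'bcd_unt' is available for architecture inspection only",
         call. = FALSE)
  }
  build_model(cfg) # validates input-size divisibility
  tr <- lapply(train, prep_pair)
  vl <- lapply(val, prep_pair)
  for (p in c(tr, vl)) {
    if (!all(dim(p$x)[1:2] == cfg$input_size)) {
      stop("pair size does not match cfg$input_size", call. = FALSE)
    }
  }
  params <- with_seed(cfg$seed, init_unt_weights(cfg))
  mstate <- lapply(params, function(p) p * 0)
  vstate <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8; step <- 0
  lr <- cfg$initial_learning_rate

  eval_set <- function(set) {
    ls <- 0; acc <- 0
    for (p in set) {
      fw <- unt_forward(p$x, params, cfg, training = FALSE)
      ls <- ls + bce_loss(fw$p, p$y)
      acc <- acc + mean((fw$p > 0.5) == (p$y > 0.5))
    }
    c(loss = ls / length(set), acc = acc / length(set))
  }

  curves <- list()
  record <- function(epoch) {
    trm <- eval_set(tr); vlm <- eval_set(vl)
    curves[[length(curves) + 1]] <<- tibble::tibble(
      epoch = epoch, lr = lr, train_loss = trm["loss"], val_loss = vlm["loss"],
      train_acc = trm["acc"], val_acc = vlm["acc"])
    vlm["loss"]
  }
  best_val <- record(0)
  stall <- 0L
  rng_master <- cfg$seed + 1000L
  for (epoch in seq_len(cfg$epochs)) {
    order <- with_seed(rng_master + epoch, sample(length(tr)))
    batches <- split(order, ceiling(seq_along(order) / cfg$batch_size))
    bi <- 0
    for (batch in batches) {
      bi <- bi + 1
      grads_sum <- NULL
      for (idx in batch) {
        p <- tr[[idx]]
        fw <- with_seed(rng_master + epoch * 10000L + bi * 100L + idx, {
          unt_forward(p$x, params, cfg, training = TRUE)
        })
        ld <- loss_and_dz(fw$p, p$y, cfg$loss)
        if (!is.finite(ld$loss)) {
          stop(sprintf("divergent loss (%.3g) at epoch %d; reduce the learning rate",
                       ld$loss, epoch), call. = FALSE)
        }
        g <- unt_backward_ordered(ld$dz, params, cfg, fw$cache)
        if (is.null(grads_sum)) grads_sum <- g
        else for (nm in names(g)) grads_sum[[nm]] <- grads_sum[[nm]] + g[[nm]]
      }
      step <- step + 1
      for (nm in names(params)) {
        g <- grads_sum[[nm]] / length(batch)
        mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * g
        vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * g^2
        mhat <- mstate[[nm]] / (1 - beta1^step)
        vhat <- vstate[[nm]] / (1 - beta2^step)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + adam_eps)
      }
    }
    v <- record(epoch)
    if (v < best_val - 1e-9) { best_val <- v; stall <- 0L }
    else {
      stall <- stall + 1L
      if (stall >= cfg$lr_patience) { lr <- lr * cfg$lr_decay_factor; stall <- 0L }
    }
  }
  structure(list(params = params, config = cfg, curves = do.call(rbind, curves)),
            class = "cnn_provider")
}

#' Predict a probability map with a trained provider
#' @param model A `cnn_provider` from [train_provider()].
#' @param image An [image_grid] matching the training input size.
#' @return A [probability_map].
#' @export
predict_provider <- function(model, image) {
  stopifnot(inherits(model, "cnn_provider"), inherits(image, "image_grid"))
  v <- normalize_intensity(image)$pixels
  x <- array(v, c(dim(v), 1L))
  fw <- unt_forward(x, model$params, model$config, training = FALSE)
  probability_map(pmin(pmax(fw$p[, , 1], 0), 1), image$spacing)
}

#' Save / load a trained provider
#' @param model A `cnn_provider`.
#' @param path File path (`.rds`).
#' @return `save_provider` invisibly returns `path`; `load_provider` the model.
#' @export
save_provider <- function(model, path) { saveRDS(model, path); invisible(path) }

#' @rdname save_provider
#' @export
load_provider <- function(path) readRDS(path)

#' Write training curves as CSV
#' @param model A `cnn_provider`.
#' @param path Destination CSV path.
#' @return Invisibly, `path`.
#' @export
write_curves <- function(model, path) {
  utils::write.csv(model$curves, path, row.names = FALSE)
  invisible(path)
}

#' Plot training curves
#' @param object A `cnn_provider`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cnn_provider <- function(object, ...) {
  cv <- object$curves
  long <- rbind(
    data.frame(epoch = cv$epoch, value = cv$train_loss, series = "train", panel = "BCE loss"),
    data.frame(epoch = cv$epoch, value = cv$val_loss, series = "validation", panel = "BCE loss"),
    data.frame(epoch = cv$epoch, value = cv$train_acc, series = "train", panel = "pixel accuracy"),
    data.frame(epoch = cv$epoch, value = cv$val_acc, series = "validation", panel = "pixel accuracy"))
  ggplot2::ggplot(long, ggplot2::aes(x = epoch, y = value, colour = series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Provider training curves") +
    ggplot2::theme_minimal()
}
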