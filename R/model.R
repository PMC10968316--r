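#' Configuration of the artifact-reduction network
#'
#' Describes the encoder-decoder (U-Net style) network: `depth` contraction
#' levels, each of two 3x3 convolutions followed by ReLU and batch
#' normalization then stride-2 max pooling, channel count starting at
#' `base_channels` and doubling per level; a bottleneck block; a mirrored
#' expansion path with stride-2 transposed-convolution upsampling, channel
#' halving and skip connections by channel concatenation; and a final 1x1
#' convolution to one channel. Training minimizes the L2 (mean squared
#' error) loss with the Adam optimizer.
#'
#' The defaults (`depth = 4`, `base_channels = 64`, `learning_rate = 5e-4`,
#' `epochs = 300`) are the full-scale study configuration; tests and examples
#' use desk-scale settings (`depth = 2`, `base_channels = 8`, tens of
#' epochs) that train in minutes on a single CPU.
#'
#' @param depth number of contraction levels; input side lengths must be
#'   divisible by `2^depth`.
#' @param base_channels feature maps in the first level (doubled per level).
#' @param learning_rate Adam learning rate.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param mode `"direct"` (network maps artifact to clean image) or
#'   `"residual"` (network maps artifact to the signed residual map, and the
#'   correction subtracts the prediction from the artifact).
#' @param bn_inference normalization statistics at inference: `"running"`
#'   (default; exponential moving averages accumulated during training, the
#'   conventional batch-norm behavior) or `"batch"` (instance-style, each
#'   input normalized by its own statistics).
#' @param seed integer seed for weight initialization and batch shuffling.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(depth = 4L, base_channels = 64L,
                        learning_rate = 5e-4, epochs = 300L,
                        batch_size = 4L, mode = c("direct", "residual"),
                        bn_inference = c("running", "batch"),
                        seed = 1L) {
  mode <- match.arg(mode)
  bn_inference <- match.arg(bn_inference)
  if (!is_count(depth)) stop_msg("depth must be a positive integer")
  if (!is_count(base_channels)) stop_msg("base_channels must be positive")
  if (learning_rate <= 0) stop_msg("learning_rate must be positive")
  if (!is_count(epochs, min = 0L)) stop_msg("epochs must be >= 0")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), loss = "l2",
                 mode = mode, bn_inference = bn_inference,
                 seed = as.integer(seed)),
            class = "unet_config")
}

# Op list describing the network topology; each op references its parameter
# names in the flat parameter list.
unet_ops <- function(depth) {
  ops <- list()
  add <- function(type, name = NULL, level = NULL) {
    ops[[length(ops) + 1L]] <<- list(type = type, name = name, level = level)
  }
  block <- function(prefix) {
    add("conv3", paste0(prefix, "_c1"))
    add("relu")
    add("bn", paste0(prefix, "_b1"))
    add("conv3", paste0(prefix, "_c2"))
    add("relu")
    add("bn", paste0(prefix, "_b2"))
  }
  for (l in seq_len(depth)) {
    block(sprintf("enc%d", l))
    add("skip", level = l)
    add("pool")
  }
  block("bott")
  for (l in rev(seq_len(depth))) {
    add("tconv", sprintf("dec%d_up", l))
    add("concat", level = l)
    block(sprintf("dec%d", l))
  }
  add("conv1", "out")
  ops
}

unet_channels <- function(depth, base) {
  as.integer(base * 2^(seq_len(depth) - 1L))
}

#' Build an (untrained) artifact-reduction network
#'
#' Allocates and initializes all parameters (He-scaled Gaussian weights,
#' unit-gain batch-norm) for the architecture described by `cfg`.
#' Initialization is deterministic given `cfg$seed`.
#'
#' @param cfg a [unet_config()].
#' @param in_channels input channels (1 for grayscale slices).
#' @return An object of class `unet_model` with elements `config`, `params`,
#'   `channels` (encoder channel sequence), `loss_history` and
#'   `val_history`.
#' @export
build_unet <- function(cfg, in_channels = 1L) {
  stopifnot(inherits(cfg, "unet_config"))
  ch <- unet_channels(cfg$depth, cfg$base_channels)
  params <- list()
  init_conv <- function(kh, kw, cin, cout) {
    sd <- sqrt(2 / (kh * kw * cin))
    array(stats::rnorm(kh * kw * cin * cout, 0, sd), c(kh, kw, cin, cout))
  }
  add_conv3 <- function(prefix, cin, cout) {
    params[[paste0(prefix, "_W")]] <<- init_conv(3L, 3L, cin, cout)
    params[[paste0(prefix, "_bias")]] <<- numeric(cout)
  }
  add_bn <- function(prefix, c) {
    params[[paste0(prefix, "_g")]] <<- rep(1, c)
    params[[paste0(prefix, "_be")]] <<- numeric(c)
    params[[paste0(prefix, "_rm")]] <<- numeric(c)
    params[[paste0(prefix, "_rv")]] <<- rep(1, c)
  }
  add_block <- function(prefix, cin, cout) {
    add_conv3(paste0(prefix, "_c1"), cin, cout)
    add_bn(paste0(prefix, "_b1"), cout)
    add_conv3(paste0(prefix, "_c2"), cout, cout)
    add_bn(paste0(prefix, "_b2"), cout)
  }
  with_seed(cfg$seed, {
    cin <- in_channels
    for (l in seq_len(cfg$depth)) {
      add_block(sprintf("enc%d", l), cin, ch[l])
      cin <- ch[l]
    }
    cb <- cfg$base_channels * 2L^cfg$depth
    add_block("bott", cin, cb)
    cur <- cb
    for (l in rev(seq_len(cfg$depth))) {
      prefix <- sprintf("dec%d_up", l)
      sdw <- sqrt(2 / (4 * cur))
      params[[paste0(prefix, "_W")]] <-
        array(stats::rnorm(4 * cur * ch[l], 0, sdw), c(2L, 2L, cur, ch[l]))
      params[[paste0(prefix, "_bias")]] <- numeric(ch[l])
      add_block(sprintf("dec%d", l), 2L * ch[l], ch[l])
      cur <- ch[l]
    }
    # the 1x1 output head starts at zero so the untrained network predicts a
    # zero image/residual; training still proceeds because the head's own
    # gradient is nonzero from the first step
    params[["out_W"]] <- matrix(0, ch[1L], 1L)
    params[["out_bias"]] <- numeric(1L)
  })
  structure(list(config = cfg, params = params,
                 channels = ch, in_channels = as.integer(in_channels),
                 ops = unet_ops(cfg$depth),
                 loss_history = numeric(0), val_history = numeric(0)),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> depth %d, encoder channels %s, mode '%s'\n",
              x$config$depth, paste(x$channels, collapse = "-"),
              x$config$mode))
  cat(sprintf("  %d parameter tensors, %d epoch(s) trained\n",
              length(x$params), length(x$loss_history)))
  invisible(x)
}

# Forward pass over the op list. x is [H, W, C, N]. In training mode the
# returned tape carries every cache needed by unet_backward, and updated
# batch-norm running statistics are returned alongside.
unet_forward <- function(model, x, training = FALSE) {
  p <- model$params
  d <- dim(x)
  if (d[1L] %% 2L^model$config$depth != 0L ||
      d[2L] %% 2L^model$config$depth != 0L) {
    stop_msg("input size %dx%d is not divisible by 2^depth = %d",
             d[1L], d[2L], 2L^model$config$depth)
  }
  tape <- if (training) vector("list", length(model$ops)) else NULL
  skips <- list()
  for (i in seq_along(model$ops)) {
    op <- model$ops[[i]]
    switch(op$type,
      conv3 = {
        r <- conv3_forward(x, p[[paste0(op$name, "_W")]],
                           p[[paste0(op$name, "_bias")]])
        if (training) tape[[i]] <- r$cache
        x <- r$y
      },
      relu = {
        r <- relu_forward(x)
        if (training) tape[[i]] <- r$cache
        x <- r$y
      },
      bn = {
        use_batch <- training || model$config$bn_inference == "batch"
        r <- bn_forward(x, p[[paste0(op$name, "_g")]],
                        p[[paste0(op$name, "_be")]],
                        p[[paste0(op$name, "_rm")]],
                        p[[paste0(op$name, "_rv")]],
                        use_batch_stats = use_batch,
                        update_running = training)
        if (training) {
          p[[paste0(op$name, "_rm")]] <- r$rm
          p[[paste0(op$name, "_rv")]] <- r$rv
          tape[[i]] <- r$cache
        }
        x <- r$y
      },
      skip = {
        skips[[op$level]] <- x
      },
      pool = {
        r <- pool_forward(x)
        if (training) tape[[i]] <- r$cache
        x <- r$y
      },
      tconv = {
        r <- tconv_forward(x, p[[paste0(op$name, "_W")]],
                           p[[paste0(op$name, "_bias")]])
        if (training) tape[[i]] <- r$cache
        x <- r$y
      },
      concat = {
        r <- concat_forward(skips[[op$level]], x)
        if (training) tape[[i]] <- r$c_skip
        x <- r$y
      },
      conv1 = {
        r <- conv1_forward(x, p[[paste0(op$name, "_W")]],
                           p[[paste0(op$name, "_bias")]])
        if (training) tape[[i]] <- r$cache
        x <- r$y
      }
    )
  }
  list(y = x, tape = tape, params = p)
}

# Backward pass; returns the flat gradient list (trainable parameters only).
unet_backward <- function(model, tape, dy) {
  p <- model$params
  grads <- list()
  dskips <- list()
  dx <- dy
  for (i in rev(seq_along(model$ops))) {
    op <- model$ops[[i]]
    switch(op$type,
      conv3 = {
        r <- conv3_backward(dx, p[[paste0(op$name, "_W")]], tape[[i]])
        grads[[paste0(op$name, "_W")]] <- r$dW
        grads[[paste0(op$name, "_bias")]] <- r$db
        dx <- r$dx
      },
      relu = {
        dx <- relu_backward(dx, tape[[i]])
      },
      bn = {
        r <- bn_backward(dx, p[[paste0(op$name, "_g")]], tape[[i]])
        grads[[paste0(op$name, "_g")]] <- r$dgamma
        grads[[paste0(op$name, "_be")]] <- r$dbeta
        dx <- r$dx
      },
      skip = {
        lv <- op$level
        if (!is.null(dskips[[as.character(lv)]])) {
          dx <- dx + dskips[[as.character(lv)]]
        }
      },
      pool = {
        dx <- pool_backward(dx, tape[[i]])
      },
      tconv = {
        r <- tconv_backward(dx, p[[paste0(op$name, "_W")]], tape[[i]])
        grads[[paste0(op$name, "_W")]] <- r$dW
        grads[[paste0(op$name, "_bias")]] <- r$db
        dx <- r$dx
      },
      concat = {
        r <- concat_backward(dx, tape[[i]])
        dskips[[as.character(op$level)]] <- r$dskip
        dx <- r$dx
      },
      conv1 = {
        r <- conv1_backward(dx, p[[paste0(op$name, "_W")]], tape[[i]])
        grads[[paste0(op$name, "_W")]] <- r$dW
        grads[[paste0(op$name, "_bias")]] <- r$db
        dx <- r$dx
      }
    )
  }
  grads
}

stack_batch <- function(mats) {
  d <- dim(mats[[1L]])
  array(unlist(mats, use.names = FALSE), c(d[1L], d[2L], 1L, length(mats)))
}

#' Train the artifact-reduction network
#'
#' Minimizes the mean squared error between the network output and the
#' target with the Adam optimizer. Inputs are artifact slices; targets are
#' the clean slices (`mode = "direct"`) or the signed residual maps
#' (`mode = "residual"`) — the two modes differ only in the target tensor.
#' Per-epoch training (and, when a validation partition is supplied,
#' validation) loss is recorded. Deterministic given `cfg$seed` up to
#' floating-point summation order.
#'
#' @param model a [build_unet()] model.
#' @param samples list of `paired_sample`s.
#' @param split optional [split_dataset()] result; when given, training uses
#'   `split$train` and validation loss is tracked on `split$validation`.
#' @param epochs,batch_size,learning_rate optional overrides of the model
#'   config (the study-scale defaults are rarely wanted at desk scale).
#' @param lr_decay multiplicative step decay: the learning rate is scaled by
#'   this factor after 60% and again after 85% of the epochs (1 = constant).
#' @param verbose print per-epoch losses.
#' @return The trained `unet_model` (loss histories appended).
#' @export
train_unet <- function(model, samples, split = NULL, epochs = NULL,
                       batch_size = NULL, learning_rate = NULL,
                       lr_decay = 0.1, verbose = FALSE) {
  stopifnot(inherits(model, "unet_model"))
  cfg <- model$config
  epochs <- epochs %||% cfg$epochs
  batch_size <- batch_size %||% cfg$batch_size
  lr <- learning_rate %||% cfg$learning_rate
  idx_train <- if (is.null(split)) seq_along(samples) else split$train
  idx_val <- if (is.null(split)) integer(0) else split$validation
  if (!length(idx_train)) stop_msg("training partition is empty")
  if (epochs == 0L) return(model)

  target_of <- function(s) if (cfg$mode == "residual") s$residual else s$clean
  trainable <- grep("_(rm|rv)$", names(model$params), invert = TRUE,
                    value = TRUE)
  state <- adam_init(model$params[trainable])
  names(state$m) <- trainable
  names(state$v) <- trainable

  for (ep in seq_len(epochs)) {
    lr_ep <- lr * lr_decay^((ep > 0.6 * epochs) + (ep > 0.85 * epochs))
    ord <- with_seed(derive_seed(cfg$seed, ep),
                     sample(idx_train, length(idx_train)))
    batches <- base::split(ord, ceiling(seq_along(ord) / batch_size))
    ep_loss <- 0
    ep_n <- 0L
    for (bi in batches) {
      x <- stack_batch(lapply(samples[bi], `[[`, "artifact"))
      tgt <- stack_batch(lapply(samples[bi], target_of))
      fw <- unet_forward(model, x, training = TRUE)
      model$params <- fw$params  # batch-norm running stats
      diff <- fw$y - tgt
      loss <- mean(diff^2)
      dy <- 2 * diff / length(diff)
      grads <- unet_backward(model, fw$tape, dy)
      upd <- adam_step(model$params[trainable], grads[trainable], state, lr_ep)
      model$params[trainable] <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + loss * length(bi)
      ep_n <- ep_n + length(bi)
    }
    model$loss_history <- c(model$loss_history, ep_loss / ep_n)
    if (length(idx_val)) {
      xv <- stack_batch(lapply(samples[idx_val], `[[`, "artifact"))
      tv <- stack_batch(lapply(samples[idx_val], target_of))
      pv <- unet_forward(model, xv, training = FALSE)$y
      model$val_history <- c(model$val_history, mean((pv - tv)^2))
    }
    if (verbose) {
      cat(sprintf("epoch %3d  train mse %.6f%s\n", ep, ep_loss / ep_n,
                  if (length(idx_val))
                    sprintf("  val mse %.6f", utils::tail(model$val_history, 1))
                  else ""))
    }
  }
  model
}

#' Predict the raw network output for one slice
#'
#' @param model a trained `unet_model`.
#' @param slice 2D input matrix.
#' @return 2D matrix, the network output (clean-image estimate in direct
#'   mode, residual-map estimate in residual mode).
#' @export
predict_slice <- function(model, slice) {
  stopifnot(inherits(model, "unet_model"), is.matrix(slice))
  x <- array(slice, c(dim(slice), 1L, 1L))
  matrix(unet_forward(model, x, training = FALSE)$y, nrow(slice), ncol(slice))
}

#' Correct a motion-artifact slice
#'
#' In direct mode the network output is the corrected image; in residual
#' mode the predicted residual is subtracted from the artifact (consistent
#' with `residual = artifact - clean`, so a perfect residual prediction
#' recovers the clean slice exactly). Output is clipped at zero.
#'
#' @param model a trained `unet_model`.
#' @param artifact 2D artifact slice.
#' @return The corrected 2D slice (nonnegative).
#' @export
correct_image <- function(model, artifact) {
  pred <- predict_slice(model, artifact)
  out <- if (model$config$mode == "residual") artifact - pred else pred
  pmax(out, 0)
}
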