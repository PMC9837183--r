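#' U-Net model configuration
#'
#' Defaults follow the full-scale training recipe (30 epochs, batch 56,
#' Adam with initial learning rate 0.001, Dice loss, five resolution
#' levels, 128 x 128 inputs). [test_scale_config()] gives a reduced profile
#' for CPU-sized experiments.
#'
#' @param depth Number of resolution levels (encoder depth, >= 2); the
#'   input side length must be divisible by `2^(depth - 1)`.
#' @param base_filters Filters at the first level; doubled at each deeper
#'   level.
#' @param epochs,batch_size,learning_rate Optimization settings.
#' @param input_size Model grid side length.
#' @param seed Seed for weight initialization and batch shuffling.
#' @param smooth Additive smoothing constant of the soft Dice loss.
#' @return A `unet_config` list.
#' @export
unet_config <- function(depth = 5, base_filters = 32, epochs = 30,
                        batch_size = 56, learning_rate = 0.001,
                        input_size = 128, seed = 1, smooth = 1) {
  if (depth < 2) abort("`depth` must be >= 2.")
  if (input_size %% 2^(depth - 1) != 0) {
    abort(sprintf("Input size %d is not divisible by 2^(depth-1) = %d.",
                  input_size, 2^(depth - 1)))
  }
  if (epochs < 0 || batch_size < 1) abort("`epochs` >= 0 and `batch_size` >= 1 required.")
  stopifnot_scalar_number(learning_rate, "learning_rate", 0, strict = TRUE)
  structure(
    list(depth = as.integer(depth), base_filters = as.integer(base_filters),
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, input_size = as.integer(input_size),
         seed = as.integer(seed), smooth = smooth, loss = "dice"),
    class = "unet_config"
  )
}

#' Reduced desk-scale training profile
#'
#' Five levels with 8 base filters on a 64 x 64 grid, 10 epochs, batch 8.
#' The step size (0.02) is larger than the full-scale default because the
#' reduced runs take only a few hundred optimizer steps.
#'
#' @param ... Overrides passed on to [unet_config()].
#' @export
test_scale_config <- function(...) {
  args <- list(depth = 5, base_filters = 8, epochs = 10, batch_size = 8,
               learning_rate = 0.02, input_size = 64, seed = 1)
  over <- list(...)
  args[names(over)] <- over
  do.call(unet_config, args)
}

unet_filters <- function(config) config$base_filters * 2^(0:(config$depth - 1))

#' Build an (untrained) five-level U-Net
#'
#' Encoder-decoder with `depth` resolution levels. Each level applies two
#' Conv(3x3)-BatchNorm-ReLU blocks; 2x2 max pooling halves resolution
#' between encoder levels, 2x2 stride-2 transposed convolutions restore it
#' in the decoder, and skip connections concatenate encoder features at the
#' matching level. A 1x1 convolution with sigmoid produces per-pixel tumor
#' probabilities. Initialization is He-normal and deterministic given
#' `config$seed`.
#'
#' @param config A [unet_config()].
#' @return A `unet_model` list with elements `params`, `state` (batch-norm
#'   running statistics), `config`, `history`.
#' @export
build_unet <- function(config) {
  if (!inherits(config, "unet_config")) abort("`config` must be a unet_config.")
  D <- config$depth
  f <- unet_filters(config)
  params <- list()
  state <- list()
  with_seed(config$seed, {
    he <- function(nin, nout, k) {
      matrix(rnorm(k * nin * nout, 0, sqrt(2 / (k * nin))), k * nin, nout)
    }
    add_block <- function(prefix, cin, cout) {
      params[[paste0(prefix, "_W")]] <<- he(cin, cout, 9L)
      params[[paste0(prefix, "_b")]] <<- numeric(cout)
      bn <- sub("conv", "bn", prefix)
      params[[paste0(bn, "_gamma")]] <<- rep(1, cout)
      params[[paste0(bn, "_beta")]] <<- numeric(cout)
      state[[paste0(bn, "_mean")]] <<- numeric(cout)
      state[[paste0(bn, "_var")]] <<- rep(1, cout)
    }
    for (l in seq_len(D)) {
      cin <- if (l == 1) 3L else f[l - 1]
      add_block(sprintf("enc%d_conv1", l), cin, f[l])
      add_block(sprintf("enc%d_conv2", l), f[l], f[l])
    }
    for (l in seq_len(D - 1)) {
      # transposed conv from f[l+1] -> f[l]
      params[[sprintf("up%d_W", l)]] <- matrix(
        rnorm(4L * f[l] * f[l + 1], 0, sqrt(2 / f[l + 1])), 4L * f[l], f[l + 1])
      params[[sprintf("up%d_b", l)]] <- numeric(f[l])
      add_block(sprintf("dec%d_conv1", l), 2L * f[l], f[l])
      add_block(sprintf("dec%d_conv2", l), f[l], f[l])
    }
    params$out_W <- matrix(rnorm(f[1], 0, sqrt(1 / f[1])), f[1], 1L)
    params$out_b <- 0
  })
  structure(list(params = params, state = state, config = config,
                 history = tibble::tibble()),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  npar <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf(
    "<unet_model> depth %d, base filters %d, input %dx%dx3, %s parameters (%s)\n",
    x$config$depth, x$config$base_filters, x$config$input_size,
    x$config$input_size, format(npar, big.mark = ","),
    if (nrow(x$history) > 0) sprintf("trained %d epochs", max(x$history$epoch))
    else "untrained"
  ))
  invisible(x)
}

# Full forward pass. Returns probabilities and (if training) all caches.
unet_forward <- function(params, state, x, config, training = FALSE) {
  D <- config$depth
  caches <- list()
  block <- function(h, prefix, training) {
    bn <- sub("conv", "bn", prefix)
    cv <- conv3_forward(h, params[[paste0(prefix, "_W")]], params[[paste0(prefix, "_b")]])
    bf <- bn_forward(cv$y, params[[paste0(bn, "_gamma")]], params[[paste0(bn, "_beta")]],
                     state[[paste0(bn, "_mean")]], state[[paste0(bn, "_var")]], training)
    if (training) {
      state[[paste0(bn, "_mean")]] <<- bf$run_mean
      state[[paste0(bn, "_var")]] <<- bf$run_var
    }
    rl <- relu_forward(bf$y)
    caches[[prefix]] <<- list(conv = cv$cache, bn = bf$cache, relu = rl$cache)
    rl$y
  }
  skips <- list()
  h <- x
  for (l in seq_len(D)) {
    h <- block(h, sprintf("enc%d_conv1", l), training)
    h <- block(h, sprintf("enc%d_conv2", l), training)
    if (l < D) {
      skips[[l]] <- h
      mp <- maxpool_forward(h)
      caches[[sprintf("pool%d", l)]] <- mp$cache
      h <- mp$y
    }
  }
  for (l in seq(D - 1, 1)) {
    up <- upconv_forward(h, params[[sprintf("up%d_W", l)]], params[[sprintf("up%d_b", l)]])
    caches[[sprintf("up%d", l)]] <- up$cache
    cat_h <- array(0, dim(up$y) + c(0, 0, dim(skips[[l]])[3], 0))
    fu <- dim(up$y)[3]
    cat_h[, , seq_len(fu), ] <- up$y
    cat_h[, , fu + seq_len(dim(skips[[l]])[3]), ] <- skips[[l]]
    h <- block(cat_h, sprintf("dec%d_conv1", l), training)
    h <- block(h, sprintf("dec%d_conv2", l), training)
  }
  oc <- conv1_forward(h, params$out_W, params$out_b)
  caches$out <- oc$cache
  prob <- sigmoid(oc$y)
  list(prob = prob, caches = caches, state = state)
}

# Backward pass; returns named gradient list matching params.
unet_backward <- function(params, caches, dprob_z, config) {
  D <- config$depth
  grads <- list()
  block_back <- function(dy, prefix) {
    bn <- sub("conv", "bn", prefix)
    cc <- caches[[prefix]]
    dy <- cpp_relu_bw(dy, cc$relu)
    bb <- bn_backward(dy, params[[paste0(bn, "_gamma")]], cc$bn)
    grads[[paste0(bn, "_gamma")]] <<- bb$dgamma
    grads[[paste0(bn, "_beta")]] <<- bb$dbeta
    cb <- conv3_backward(bb$dx, params[[paste0(prefix, "_W")]], cc$conv)
    grads[[paste0(prefix, "_W")]] <<- cb$dW
    grads[[paste0(prefix, "_b")]] <<- cb$db
    cb$dx
  }
  ob <- conv1_backward(dprob_z, params$out_W, caches$out)
  grads$out_W <- ob$dW
  grads$out_b <- ob$db
  dh <- ob$dx
  dskips <- list()
  for (l in seq_len(D - 1)) {
    dh <- block_back(dh, sprintf("dec%d_conv2", l))
    dcat <- block_back(dh, sprintf("dec%d_conv1", l))
    fu <- nrow(params[[sprintf("up%d_W", l)]]) %/% 4L
    dup <- dcat[, , seq_len(fu), , drop = FALSE]
    dskips[[l]] <- dcat[, , fu + seq_len(dim(dcat)[3] - fu), , drop = FALSE]
    ub <- upconv_backward(dup, params[[sprintf("up%d_W", l)]],
                          caches[[sprintf("up%d", l)]])
    grads[[sprintf("up%d_W", l)]] <- ub$dW
    grads[[sprintf("up%d_b", l)]] <- ub$db
    dh <- ub$dx
  }
  for (l in seq(D, 1)) {
    if (l < D) {
      dh <- maxpool_backward(dh, caches[[sprintf("pool%d", l)]])
      dh <- dh + dskips[[l]]
    }
    dh <- block_back(dh, sprintf("enc%d_conv2", l))
    dh <- block_back(dh, sprintf("enc%d_conv1", l))
  }
  grads
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(pred * target) + smooth) / (sum(pred) + sum(target) + smooth)`,
#' differentiable in `pred`. For a binary prediction and `smooth -> 0` this
#' equals one minus the Dice similarity coefficient.
#'
#' @param pred Probability array, values in \[0, 1\].
#' @param target Binary array of the same shape.
#' @param smooth Small additive constant (default 1).
#' @return Scalar loss.
#' @export
dice_loss <- function(pred, target, smooth = 1) {
  if (!identical(dim(pred), dim(target)) ||
        (is.null(dim(pred)) && length(pred) != length(target))) {
    abort("`pred` and `target` must have identical shapes.")
  }
  if (any(pred < 0 | pred > 1)) abort("`pred` must lie in [0, 1].")
  if (!is_binary_array(target)) abort("`target` must be binary.")
  1 - (2 * sum(pred * target) + smooth) / (sum(pred) + sum(target) + smooth)
}

#' Patient-level cross-validation folds
#'
#' Partitions patients (never slices) into `k` folds of sizes differing by
#' at most one, deterministically given `seed`.
#'
#' @param patient_ids Character vector of unique patient identifiers.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Tibble with columns `patient_id`, `fold` (1..k).
#' @export
make_folds <- function(patient_ids, k = 5, seed = 1) {
  if (anyDuplicated(patient_ids)) abort("`patient_ids` must be unique.")
  n <- length(patient_ids)
  if (n < k) abort(sprintf("Need at least %d patients for %d folds.", k, k))
  with_seed(seed, {
    shuffled <- sample(patient_ids)
    tibble::tibble(patient_id = shuffled,
                   fold = rep(seq_len(k), length.out = n)) |>
      dplyr::arrange(.data$patient_id)
  })
}

# Stack model inputs and targets for a list of cases.
build_training_arrays <- function(cases, channel_mode, size) {
  xs <- lapply(cases, assemble_channels, channel_mode = channel_mode, size = size)
  ys <- lapply(cases, function(cs) mask_to_model_grid(cs$reference_mask, size))
  n_slices <- vapply(xs, function(a) dim(a)[4], numeric(1))
  total <- sum(n_slices)
  X <- array(0, c(size, size, 3, total))
  Y <- array(0, c(size, size, 1, total))
  at <- 0L
  for (i in seq_along(xs)) {
    idx <- at + seq_len(n_slices[i])
    X[, , , idx] <- xs[[i]]
    Y[, , 1, idx] <- ys[[i]]
    at <- at + n_slices[i]
  }
  list(X = X, Y = Y)
}

#' Train a U-Net on one cross-validation fold
#'
#' Optimizes the soft Dice loss over 2D slices with Adam. Training is
#' deterministic given the configuration seed. With `epochs = 0` the
#' initialized model is returned unchanged.
#'
#' @param model A `unet_model` from [build_unet()] (or `NULL` to build one
#'   from `config`).
#' @param train_cases,val_cases Disjoint lists of `patient_case` objects.
#' @param config A [unet_config()].
#' @param channel_mode Input mode, see [assemble_channels()].
#' @param quiet Suppress per-epoch progress.
#' @return The fitted `unet_model`; `model$history` holds per-epoch train
#'   and validation Dice loss.
#' @export
train_fold <- function(model = NULL, train_cases, val_cases = list(),
                       config, channel_mode = "multi", quiet = TRUE) {
  if (length(train_cases) == 0) abort("Empty training set.")
  train_ids <- vapply(train_cases, `[[`, "", "case_id")
  val_ids <- vapply(val_cases, `[[`, "", "case_id")
  if (length(intersect(train_ids, val_ids)) > 0) {
    abort("Training and validation patient sets overlap.")
  }
  if (is.null(model)) model <- build_unet(config)
  if (config$epochs == 0) return(model)
  size <- config$input_size
  tr <- build_training_arrays(train_cases, channel_mode, size)
  va <- if (length(val_cases) > 0) build_training_arrays(val_cases, channel_mode, size)
  params <- model$params
  state <- model$state
  mom <- lapply(params, function(p) p * 0)
  vel <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  n_tr <- dim(tr$X)[4]
  hist <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$seed, 7000L + ep), sample.int(n_tr))
    losses <- c()
    for (b0 in seq(1, n_tr, by = config$batch_size)) {
      idx <- ord[b0:min(b0 + config$batch_size - 1L, n_tr)]
      xb <- tr$X[, , , idx, drop = FALSE]
      yb <- tr$Y[, , , idx, drop = FALSE]
      fw <- unet_forward(params, state, xb, config, training = TRUE)
      state <- fw$state
      dl <- dice_loss_batch(fw$prob, yb, config$smooth)
      if (!is.finite(dl$loss)) {
        abort(sprintf("Non-finite Dice loss at epoch %d; aborting training.", ep))
      }
      losses <- c(losses, dl$loss)
      dprob <- dice_loss_grad(dl, dim(fw$prob))
      dz <- dprob * fw$prob * (1 - fw$prob)
      grads <- unet_backward(params, fw$caches, dz, config)
      t_step <- t_step + 1L
      lr_t <- config$learning_rate *
        sqrt(1 - beta2^t_step) / (1 - beta1^t_step)
      for (nm in names(params)) {
        g <- grads[[nm]]
        mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * g
        vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * g * g
        params[[nm]] <- params[[nm]] - lr_t * mom[[nm]] / (sqrt(vel[[nm]]) + eps)
      }
    }
    val_loss <- NA_real_
    if (!is.null(va)) {
      vp <- predict_prob_array(params, state, va$X, config)
      val_loss <- dice_loss_batch(vp, va$Y, config$smooth)$loss
    }
    hist[[ep]] <- tibble::tibble(epoch = ep, train_loss = mean(losses),
                                 val_loss = val_loss)
    if (!quiet) {
      message(sprintf("epoch %d: train %.4f val %.4f", ep, mean(losses), val_loss))
    }
  }
  model$params <- params
  model$state <- state
  model$history <- dplyr::bind_rows(hist)
  model
}

# Inference-mode probabilities for a (H, W, 3, N) input array, batched.
predict_prob_array <- function(params, state, X, config, batch = 16L) {
  N <- dim(X)[4]
  out <- array(0, c(dim(X)[1], dim(X)[2], 1, N))
  for (b0 in seq(1, N, by = batch)) {
    idx <- b0:min(b0 + batch - 1L, N)
    fw <- unet_forward(params, state, X[, , , idx, drop = FALSE], config,
                       training = FALSE)
    out[, , , idx] <- fw$prob
  }
  out
}

#' Five-fold cross-validation of the U-Net
#'
#' Trains one model per fold on that fold's 80% training split and reports
#' per-fold mean volumetric DSC on the training and validation patients.
#'
#' @param cohort List of `patient_case` objects (>= k patients).
#' @param config A [unet_config()].
#' @param channel_mode Input mode.
#' @param k Number of folds (default 5).
#' @param quiet Suppress progress output.
#' @return List with `models` (length k), `folds` (tibble), `per_fold`
#'   (tibble: fold, train_dsc, val_dsc), and `summary` (mean and range of
#'   validation DSC). Class `unet_cv`.
#' @export
cross_validate <- function(cohort, config, channel_mode = "multi", k = 5,
                           quiet = TRUE) {
  ids <- vapply(cohort, `[[`, "", "case_id")
  folds <- make_folds(ids, k = k, seed = config$seed)
  models <- vector("list", k)
  rows <- vector("list", k)
  for (fd in seq_len(k)) {
    val_ids <- folds$patient_id[folds$fold == fd]
    tr_cases <- cohort[!(ids %in% val_ids)]
    va_cases <- cohort[ids %in% val_ids]
    fit <- tryCatch(
      train_fold(NULL, tr_cases, va_cases,
                 config = replace_seed(config, derive_seed(config$seed, fd)),
                 channel_mode = channel_mode, quiet = quiet),
      error = function(e) abort(sprintf("Fold %d failed: %s", fd, conditionMessage(e)))
    )
    models[[fd]] <- fit
    dsc <- function(cases) {
      mean(vapply(cases, function(cs) {
        pred <- predict_mask(fit, assemble_channels(cs, channel_mode,
                                                    config$input_size))
        ref <- mask_to_model_grid(cs$reference_mask, config$input_size)
        dice_coefficient(ref, pred$voxels)
      }, numeric(1)))
    }
    rows[[fd]] <- tibble::tibble(fold = fd, train_dsc = dsc(tr_cases),
                                 val_dsc = dsc(va_cases))
    if (!quiet) message(sprintf("fold %d: val DSC %.3f", fd, rows[[fd]]$val_dsc))
  }
  per_fold <- dplyr::bind_rows(rows)
  structure(list(models = models, folds = folds, per_fold = per_fold,
                 summary = summarize_cv(per_fold$val_dsc)),
            class = "unet_cv")
}

replace_seed <- function(config, seed) {
  config$seed <- as.integer(seed)
  config
}

#' @export
print.unet_cv <- function(x, ...) {
  cat(sprintf("<unet_cv> %d folds; validation DSC mean %.3f (range %.3f-%.3f)\n",
              nrow(x$per_fold), x$summary$mean_dsc, x$summary$min_dsc,
              x$summary$max_dsc))
  invisible(x)
}
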