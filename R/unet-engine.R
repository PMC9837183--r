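# Minimal CPU neural-network engine for the segmentation U-Net.
#
# Activations are dense arrays of dim (H, W, C, N). Layout transforms
# (im2col/col2im, channel-major transposes, pooling, transposed-conv
# interleaving) are compiled (src/engine.cpp); all matrix products go
# through BLAS. Backward passes are hand-derived and validated against
# finite differences in the test suite.

# The 3x3 convolutions run in single precision by default (ample for Dice
# training and twice the SIMD throughput); `options(vesica.conv_double =
# TRUE)` switches to the double-precision reference kernels, used by the
# finite-difference gradient checks.
conv3_forward <- function(x, Wmat, b) {
  d <- dim(x)
  if (isTRUE(getOption("vesica.conv_double"))) {
    y <- cpp_conv3_fw(x, Wmat, b, d[1], d[2], d[3], d[4])
    return(list(y = y, cache = list(x = x, dims = d)))
  }
  r <- cpp_conv3f_fw(x, Wmat, b, d[1], d[2], d[3], d[4])
  list(y = r$y, cache = list(xf = r$xf, dims = d))
}

conv3_backward <- function(dy, Wmat, cache) {
  d <- cache$dims
  if (!is.null(cache[["x"]])) {
    ww <- cpp_conv3_bw_w(cache[["x"]], dy, d[1], d[2], d[3], d[4], ncol(Wmat))
    dx <- cpp_conv3_bw_x(dy, Wmat, d[1], d[2], d[3], d[4])
    return(list(dx = dx, dW = ww$dW, db = ww$db))
  }
  r <- cpp_conv3f_bw(cache$xf, dy, Wmat, d[1], d[2], d[3], d[4])
  list(dx = r$dx, dW = r$dW, db = r$db)
}

# Batch normalization: fused compiled kernels in training mode; running
# statistics in inference mode.
bn_forward <- function(x, gamma, beta, run_mean, run_var, training,
                       momentum = 0.1, eps = 1e-5) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  M <- HW * N
  if (training) {
    r <- cpp_bn_fw(x, gamma, beta, eps, HW, C, N)
    run_mean <- (1 - momentum) * run_mean + momentum * r$mu
    run_var <- (1 - momentum) * run_var + momentum * r$var * M / max(M - 1, 1)
    list(y = r$y, cache = list(xhat = r$xhat, inv = 1 / sqrt(r$var + eps),
                               dims = d),
         run_mean = run_mean, run_var = run_var)
  } else {
    inv <- 1 / sqrt(run_var + eps)
    xhat <- (x - rep(run_mean, each = HW)) * rep(inv, each = HW)
    y <- xhat * rep(gamma, each = HW) + rep(beta, each = HW)
    list(y = y, cache = list(xhat = xhat, inv = inv, dims = d),
         run_mean = run_mean, run_var = run_var)
  }
}

bn_backward <- function(dy, gamma, cache) {
  d <- cache$dims
  r <- cpp_bn_bw(dy, cache$xhat, gamma, cache$inv, d[1] * d[2], d[3], d[4])
  list(dx = r$dx, dgamma = r$dgamma, dbeta = r$dbeta)
}

relu_forward <- function(x) {
  y <- cpp_relu_fw(x)
  list(y = y, cache = y)
}

maxpool_forward <- function(x) {
  d <- dim(x)
  mp <- cpp_maxpool_fw(x, d[1], d[2], d[3], d[4])
  list(y = mp$y, cache = list(which = mp$which, dims = d))
}

maxpool_backward <- function(dy, cache) {
  d <- cache$dims
  cpp_maxpool_bw(dy, cache$which, d[1], d[2], d[3], d[4])
}

# 2x2 stride-2 transposed convolution; weight matrix (4F x C), row order
# (a fastest, b, f).
upconv_forward <- function(x, Wmat, b) {
  d <- dim(x)
  Fo <- nrow(Wmat) %/% 4L
  HWN <- d[1] * d[2] * d[4]
  xpix <- cpp_arr_to_pix(x, d[1], d[2], d[3], d[4])
  ymat <- tcrossprod(xpix, Wmat) + rep(rep(b, each = 4L), each = HWN)
  y <- cpp_up_to_spatial(ymat, d[1], d[2], Fo, d[4])
  list(y = y, cache = list(xpix = xpix, dims = d))
}

upconv_backward <- function(dy, Wmat, cache) {
  d <- cache$dims
  Fo <- nrow(Wmat) %/% 4L
  dymat <- cpp_spatial_to_up(dy, d[1], d[2], Fo, d[4])
  db <- colSums(matrix(colSums(dymat), 4L, Fo))
  dW <- crossprod(dymat, cache$xpix)
  dxpix <- dymat %*% Wmat
  dx <- cpp_pix_to_arr(dxpix, d[1], d[2], d[3], d[4])
  list(dx = dx, dW = dW, db = db)
}

conv1_forward <- function(x, Wmat, b) {
  d <- dim(x)
  Fo <- ncol(Wmat)
  HWN <- d[1] * d[2] * d[4]
  xpix <- cpp_arr_to_pix(x, d[1], d[2], d[3], d[4])
  ymat <- xpix %*% Wmat + rep(b, each = HWN)
  y <- cpp_pix_to_arr(ymat, d[1], d[2], Fo, d[4])
  list(y = y, cache = list(xpix = xpix, dims = d))
}

conv1_backward <- function(dy, Wmat, cache) {
  d <- cache$dims
  Fo <- ncol(Wmat)
  dypix <- cpp_arr_to_pix(dy, d[1], d[2], Fo, d[4])
  db <- colSums(dypix)
  dW <- crossprod(cache$xpix, dypix)
  dxpix <- tcrossprod(dypix, Wmat)
  dx <- cpp_pix_to_arr(dxpix, d[1], d[2], d[3], d[4])
  list(dx = dx, dW = dW, db = db)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Soft Dice loss averaged over the batch; returns per-sample sums needed by
# the gradient.
dice_loss_batch <- function(prob, target, smooth) {
  N <- dim(prob)[4]
  pm <- matrix(prob, ncol = N)
  tm <- matrix(target, ncol = N)
  A <- 2 * colSums(pm * tm) + smooth
  B <- colSums(pm) + colSums(tm) + smooth
  list(loss = mean(1 - A / B), A = A, B = B, pm = pm, tm = tm)
}

dice_loss_grad <- function(dl, dims) {
  N <- dims[4]
  gm <- -(2 * dl$tm * rep(dl$B, each = nrow(dl$tm)) -
            rep(dl$A, each = nrow(dl$tm))) /
    rep(dl$B^2, each = nrow(dl$tm)) / N
  array(gm, dims)
}
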