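# Minimal neural-network plumbing for the pix2pix networks: convolution /
# transposed-convolution wrappers over the compiled kernels, activations,
# instance normalization (batch size is 1, so per-image normalization is
# the batch-norm limit and makes inference deterministic), BCE-with-logits,
# and Adam. Tensors are H x W x C numeric arrays, single image.

NN_EPS <- 1e-5

conv_fw <- function(x, w, b, k = 4L, s = 2L, p = 1L) {
  nn_conv_fw(x, w, b, k, s, p)
}

conv_bw <- function(x, w, gy, k = 4L, s = 2L, p = 1L) {
  bw <- nn_conv_bw(x, w, gy, k, s, p)
  bw$gb <- as.numeric(bw$gb)
  bw
}

tconv_fw <- function(x, u, b, k = 4L, s = 2L, p = 1L) {
  nn_tconv_fw(x, u, b, k, s, p)
}

tconv_bw <- function(x, u, gy, k = 4L, s = 2L, p = 1L) {
  bw <- nn_tconv_bw(x, u, gy, k, s, p)
  bw$gb <- as.numeric(bw$gb)
  bw
}

lrelu_fw <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
lrelu_bw <- function(x, gy, slope = 0.2) gy * ifelse(x > 0, 1, slope)
relu_fw <- function(x) pmax(x, 0)
relu_bw <- function(x, gy) gy * (x > 0)

# instance norm: normalize each channel over its H*W pixels (vectorized
# as an HW x C matrix)
inorm_fw <- function(x, gamma, beta) {
  d <- dim(x)
  hw <- d[1] * d[2]
  xm <- matrix(x, hw, d[3])
  mu <- colMeans(xm)
  xc <- xm - matrix(mu, hw, d[3], byrow = TRUE)
  v <- colMeans(xc * xc)
  istd <- 1 / sqrt(v + NN_EPS)
  xhat <- xc * matrix(istd, hw, d[3], byrow = TRUE)
  y <- xhat * matrix(gamma, hw, d[3], byrow = TRUE) +
    matrix(beta, hw, d[3], byrow = TRUE)
  list(y = array(y, d), xhat = xhat, istd = istd)
}

inorm_bw <- function(cache, gamma, gy) {
  d <- dim(gy)
  hw <- d[1] * d[2]
  gym <- matrix(gy, hw, d[3])
  xh <- cache$xhat
  gg <- colSums(gym * xh)
  gb <- colSums(gym)
  gxhat <- gym * matrix(gamma, hw, d[3], byrow = TRUE)
  mg <- colMeans(gxhat)
  mgx <- colMeans(gxhat * xh)
  gx <- matrix(cache$istd, hw, d[3], byrow = TRUE) *
    (gxhat - matrix(mg, hw, d[3], byrow = TRUE) -
       xh * matrix(mgx, hw, d[3], byrow = TRUE))
  list(gx = array(gx, d), ggamma = gg, gbeta = gb)
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

# numerically stable binary cross-entropy on logits; target is 0 or 1
bce_logits <- function(x, target) {
  mean(pmax(x, 0) - x * target + log1p(exp(-abs(x))))
}

bce_logits_grad <- function(x, target) {
  (1 / (1 + exp(-x)) - target) / length(x)
}

init_conv_w <- function(cout, cin, k = 4L) {
  matrix(stats::rnorm(cout * k * k * cin, sd = 0.02), cout, k * k * cin)
}

init_tconv_u <- function(cin, cout, k = 4L) {
  matrix(stats::rnorm(cin * k * k * cout, sd = 0.02), cin, k * k * cout)
}

adam_init <- function(params) {
  list(t = 0L, m = zero_like(params), v = zero_like(params))
}

# mutates params and the moment buffers in place (the caller must
# deep-copy any snapshot it wants to keep, see deep_copy_params)
adam_step <- function(params, grads, state, lr, beta1, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  nn_adam_step_inplace(params, grads, state$m, state$v, lr, beta1, beta2,
                       eps, state$t)
  state
}

deep_copy_params <- function(params) lapply(params, function(p) p + 0)

zero_like <- function(params) {
  lapply(params, function(p) {
    if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
  })
}

acc_grad <- function(acc, nm, g) {
  acc[[nm]] <- acc[[nm]] + g
  acc
}
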