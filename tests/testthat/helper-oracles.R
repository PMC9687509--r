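# Independent oracles and small helpers shared by the test files.

# Naive centred orthonormal 2D DFT of one frame, built from explicit
# exponent matrices (no call to fft): X[k,l] = sum_ij x[i,j] *
# exp(-2pi*i*((i-H/2)(k-H/2)/H + (j-W/2)(l-W/2)/W)) / sqrt(HW).
naive_dft2c <- function(fr, inverse = FALSE) {
  h <- nrow(fr); w <- ncol(fr)
  sgn <- if (inverse) 2i else -2i
  ih <- 0:(h - 1) - h / 2
  iw <- 0:(w - 1) - w / 2
  Fh <- exp(sgn * pi * outer(ih, ih) / h)
  Fw <- exp(sgn * pi * outer(iw, iw) / w)
  (Fh %*% fr %*% Fw) / sqrt(h * w)
}

# Direct-summation SSIM over the same Gaussian windows (valid interior),
# written independently of the package implementation.
naive_ssim <- function(ref, rec, window = 11L, sigma = 1.5, L = max(ref)) {
  g <- exp(-((seq_len(window) - (window + 1) / 2)^2) / (2 * sigma^2))
  G <- outer(g, g); G <- G / sum(G)
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  h <- nrow(ref); w <- ncol(ref); pad <- (window - 1) / 2
  vals <- c()
  for (i in (pad + 1):(h - pad)) {
    for (j in (pad + 1):(w - pad)) {
      px <- ref[(i - pad):(i + pad), (j - pad):(j + pad)]
      py <- rec[(i - pad):(i + pad), (j - pad):(j + pad)]
      mx <- sum(G * px); my <- sum(G * py)
      vx <- sum(G * px^2) - mx^2; vy <- sum(G * py^2) - my^2
      cxy <- sum(G * px * py) - mx * my
      vals <- c(vals, ((2 * mx * my + c1) * (2 * cxy + c2)) /
                  ((mx^2 + my^2 + c1) * (vx + vy + c2)))
    }
  }
  mean(vals)
}

random_sequence <- function(h = 8, w = 8, tt = 2, seed = 1) {
  set.seed(seed)
  array(complex(real = rnorm(h * w * tt), imaginary = rnorm(h * w * tt)),
        c(h, w, tt))
}

# Tiny phantom dataset for training tests.
tiny_dataset <- function(n_train = 3, n_val = 1, n_test = 1, seed = 5,
                         frames = 4, h = 16, w = 16, af = 2) {
  make_fixture_dataset(n_train, n_val, n_test,
                       phantom_config(frames = frames, h = h, w = w),
                       af = af, n_acs = 4L, seed = seed)
}

tiny_backbone <- function(...) {
  crnn_config(n_iters = 2L, n_filters = 3L, n_crnn_layers = 2L, ...)
}

flat_params <- function(p) rapply(p, as.numeric, how = "unlist")

set_flat_params <- function(p, vec) {
  i <- 0
  bk <- attr(p, "backbone")
  out <- rapply(p, function(a) {
    n <- length(a)
    a[] <- vec[(i + 1):(i + n)]
    i <<- i + n
    a
  }, how = "replace")
  attr(out, "backbone") <- bk
  out
}
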