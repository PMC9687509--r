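# One shared toy problem for the backbone tests.
toy_problem <- function(seed = 4, af = 2) {
  ph <- generate_cine_phantom(phantom_config(frames = 2, h = 8, w = 8,
                                             seed = seed))
  k <- fft2c(ph)
  om <- generate_cartesian_mask(2, 8, 8, af = af, n_acs = 2, seed = seed + 1)
  y <- apply_mask(k, om)
  list(y = y, m = om, x0 = zero_filled(k, om))
}

test_that("initialization is deterministic, seed-sensitive and fan-in bounded", {
  cfg <- crnn_config(n_filters = 64, kernel = 3)
  p1 <- init_params(cfg, seed = 1)
  p2 <- init_params(cfg, seed = 1)
  p3 <- init_params(cfg, seed = 2)
  expect_identical(p1, p2)
  expect_false(identical(flat_params(p1), flat_params(p3)))
  # U(-s, s) with s = sqrt(1/(9 * C_in)) <= sqrt(1/18) < 1
  expect_lt(max(abs(flat_params(p1))), 1)
})

test_that("zero-parameter network is the identity on data-consistent input", {
  tp <- toy_problem()
  for (bk in c("crnn", "cascade")) {
    cfg <- tiny_backbone(backbone = bk)
    pz <- dynrecon:::zero_like(init_params(cfg, 1))
    attr(pz, "backbone") <- bk
    out <- crnn_reconstruct(tp$x0, tp$y, tp$m, pz, cfg)
    expect_lt(max(Mod(out - tp$x0)), 1e-12)
  }
})

test_that("hard DC makes any reconstruction exact at sampled entries", {
  tp <- toy_problem()
  for (seed in 1:3) {
    cfg <- tiny_backbone()
    p <- init_params(cfg, seed)
    out <- crnn_reconstruct(tp$x0, tp$y, tp$m, p, cfg)
    resid <- Mod((fft2c(out) - tp$y) * as.numeric(tp$m))
    expect_lt(max(resid), 1e-5)
  }
})

test_that("reconstruction is deterministic and validates its inputs", {
  tp <- toy_problem()
  cfg <- tiny_backbone()
  p <- init_params(cfg, 3)
  expect_identical(crnn_reconstruct(tp$x0, tp$y, tp$m, p, cfg),
                   crnn_reconstruct(tp$x0, tp$y, tp$m, p, cfg))
  y_bad <- tp$y + 0.1   # nonzero outside support
  expect_error(crnn_reconstruct(tp$x0, y_bad, tp$m, p, cfg), "support")
  pc <- init_params(tiny_backbone(backbone = "cascade"), 1)
  expect_error(crnn_reconstruct(tp$x0, tp$y, tp$m, pc, cfg), "backbone")
})

test_that("data consistency layer implements hard and soft replacement", {
  tp <- toy_problem()
  x <- ifft2c(random_sequence(8, 8, 2, seed = 6))
  # full mask, hard: output is ifft of measurements regardless of prediction
  m1 <- array(1, dim(x))
  y_full <- fft2c(ifft2c(random_sequence(8, 8, 2, seed = 7)))
  expect_lt(max(Mod(data_consistency(x, y_full, m1) - ifft2c(y_full))), 1e-10)
  # empty mask: no constraint
  m0 <- array(0, dim(x))
  y0 <- array(0i, dim(x))
  expect_lt(max(Mod(data_consistency(x, y0, m0) - x)), 1e-12)
  # soft single-entry averaging: (pred + lambda*meas)/(1+lambda)
  k_pred <- fft2c(x)
  i <- which(as.numeric(tp$m) == 1)[1]
  k_soft <- fft2c(data_consistency(x, tp$y, tp$m, dc_mode = "soft",
                                   dc_lambda = 1))
  expect_equal(k_soft[i], (k_pred[i] + tp$y[i]) / 2, tolerance = 1e-10)
  expect_error(data_consistency(x, fft2c(x), tp$m), "support")
})

test_that("spatial size is preserved for any odd kernel", {
  tp <- toy_problem()
  for (k in c(1, 3, 5)) {
    cfg <- tiny_backbone(kernel = k)
    out <- crnn_reconstruct(tp$x0, tp$y, tp$m, init_params(cfg, 2), cfg)
    expect_equal(dim(out), dim(tp$x0))
  }
})

test_that("scalar recurrence matches a hand-unrolled oracle", {
  # 1 channel, 1x1 kernel on a 4x4 constant image: every conv is a scalar
  # multiply, so the bidirectional recurrence can be unrolled by hand.
  cfg <- crnn_config(n_iters = 1, n_filters = 1, kernel = 1,
                     n_crnn_layers = 1)
  p <- init_params(cfg, 1)
  wx <- 0.5; whf <- 0.25; whb <- -0.3; wit <- 0.7; b <- 0.1
  p$bcrnn$Wx[] <- c(wx, 0)      # respond to the real channel only
  p$bcrnn$Whf[] <- whf
  p$bcrnn$Whb[] <- whb
  p$bcrnn$Wit[] <- wit
  p$bcrnn$b[] <- b
  p$layers[[1]]$Wx[] <- 2; p$layers[[1]]$Wi[] <- 0; p$layers[[1]]$b[] <- 0
  p$out$W[] <- c(1, 0)          # write into the real channel
  p$out$b[] <- 0

  v <- 0.6                      # constant real image value, 3 frames
  x0 <- array(v + 0i, c(4, 4, 3))
  y0 <- array(0i, dim(x0))
  m0 <- array(0, dim(x0))       # empty mask: DC is the identity
  out <- crnn_reconstruct(x0, y0, m0, p, cfg)

  base <- wx * v + b            # input conv + bias, no iteration hidden
  hf <- hb <- numeric(3)
  hprev <- 0
  for (t in 1:3) { hf[t] <- max(0, base + whf * hprev); hprev <- hf[t] }
  hprev <- 0
  for (t in 3:1) { hb[t] <- max(0, base + whb * hprev); hprev <- hb[t] }
  h1 <- hf + hb
  h2 <- pmax(0, 2 * h1)
  expected <- v + h2            # residual add into the real channel
  for (t in 1:3)
    expect_equal(Re(out[1, 1, t]), expected[t], tolerance = 1e-10)
  expect_equal(max(abs(Im(out))), 0, tolerance = 1e-10)
})

test_that("analytic gradients agree with finite differences (crnn and cascade)", {
  ph <- generate_cine_phantom(phantom_config(frames = 2, h = 8, w = 8, seed = 2))
  k <- fft2c(ph)
  om <- generate_cartesian_mask(2, 8, 8, af = 2, n_acs = 2, seed = 3)
  tri <- partition_mask(om, seed = 4)
  y_om <- apply_mask(k, om)
  y_th <- apply_mask(y_om, tri$theta)
  x0 <- zero_filled(y_om, tri$theta)
  for (bk in c("crnn", "cascade")) {
    cfg <- tiny_backbone(backbone = bk)
    p <- init_params(cfg, 5)
    lossfun <- function(pp) {
      f <- dynrecon:::net_forward(pp, x0, y_th, tri$theta, cfg)
      dynrecon:::masked_kspace_loss(fft2c(f$x), y_om, om)
    }
    f <- dynrecon:::net_forward(p, x0, y_th, tri$theta, cfg, tape = TRUE)
    ls <- dynrecon:::masked_kspace_loss(fft2c(f$x), y_om, om, grad = TRUE)
    g <- flat_params(dynrecon:::net_backward(p, f, ifft2c(ls$g), cfg))
    v0 <- flat_params(p)
    eps <- 1e-6
    set.seed(1)
    for (i in sample(length(v0), 12)) {
      vp <- v0; vp[i] <- vp[i] + eps
      vm <- v0; vm[i] <- vm[i] - eps
      fd <- (lossfun(set_flat_params(p, vp)) -
               lossfun(set_flat_params(p, vm))) / (2 * eps)
      expect_lt(abs(fd - g[i]) / max(abs(fd), abs(g[i]), 1e-8), 1e-3)
    }
  }
})
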