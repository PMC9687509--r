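# order of the first epoch under the package's shuffle substream
with_seed_order <- function(seed, n)
  dynrecon:::with_seed(sub_seed(seed, "shuffle-1"), sample.int(n))

# recompute the first colearn step's loss from freshly initialized params
recompute_first_loss <- function(ds, cfg, seed) {
  sq <- ds$train[[with_seed_order(seed, length(ds$train))[1]]]
  p1 <- init_params(cfg, sub_seed(seed, "init1"))
  p2 <- init_params(cfg, sub_seed(seed, "init2"))
  y_om <- apply_mask(sq$kspace, sq$masks$omega)
  y_th <- apply_mask(y_om, sq$masks$theta)
  y_la <- apply_mask(y_om, sq$masks$lambda)
  k1 <- fft2c(dynrecon:::net_forward(p1, ifft2c(y_th), y_th, sq$masks$theta,
                                     cfg)$x)
  k2 <- fft2c(dynrecon:::net_forward(p2, ifft2c(y_la), y_la, sq$masks$lambda,
                                     cfg)$x)
  co_loss(k1, k2, y_om, sq$masks$omega, loss_config())$l_co
}

test_that("training runs are deterministic and history bookkeeping is exact", {
  ds <- tiny_dataset()
  cfg <- tiny_backbone()
  f1 <- colearn_fit(ds, "colearn", backbone = cfg, steps = 4, seed = 3)
  f2 <- colearn_fit(ds, "colearn", backbone = cfg, steps = 4, seed = 3)
  expect_identical(flat_params(f1$params1), flat_params(f2$params1))
  expect_identical(flat_params(f1$params2), flat_params(f2$params2))
  expect_equal(nrow(f1$history), 4L)
  expect_identical(f1$history$l_co, f2$history$l_co)
  expect_true(all(is.finite(f1$history$l_co)))
  # recorded loss equals the loss recomputed from the pre-update parameters
  lb <- recompute_first_loss(ds, cfg, seed = 3)
  expect_equal(lb, f1$history$l_co[1], tolerance = 1e-12)
})

test_that("resuming from a checkpoint reproduces uninterrupted training", {
  ds <- tiny_dataset()
  cfg <- tiny_backbone()
  full <- colearn_fit(ds, "colearn", backbone = cfg, steps = 5, seed = 7)
  part <- colearn_fit(ds, "colearn", backbone = cfg, steps = 3, seed = 7)
  ckpt <- tempfile(fileext = ".rds")
  save_checkpoint(part, ckpt)
  resumed <- colearn_fit(ds, "colearn", init = load_checkpoint(ckpt),
                         steps = 2)
  expect_equal(resumed$history$l_co, full$history$l_co, tolerance = 1e-12)
  expect_equal(flat_params(resumed$params1), flat_params(full$params1),
               tolerance = 1e-12)
})

test_that("single-network strategies score only their target entries", {
  ds <- tiny_dataset()
  sq <- ds$train[[1]]
  cfg <- tiny_backbone()
  p <- init_params(cfg, 2)
  y_om <- apply_mask(sq$kspace, sq$masks$omega)
  y_th <- apply_mask(y_om, sq$masks$theta)
  k <- fft2c(dynrecon:::net_forward(p, ifft2c(y_th), y_th, sq$masks$theta,
                                    cfg)$x)
  la <- sq$masks$lambda
  y_la <- apply_mask(y_om, la)
  l0 <- dynrecon:::masked_kspace_loss(k, y_la, la)
  # perturbing the prediction outside lambda's support leaves the loss alone
  k_pert <- k + 5 * (1 - as.numeric(la))
  expect_equal(dynrecon:::masked_kspace_loss(k_pert, y_la, la), l0)
  # a prediction exactly consistent with the acquired data has zero loss
  expect_equal(dynrecon:::masked_kspace_loss(y_om, y_om, sq$masks$omega), 0)
})

test_that("with gamma 0 network-1 is decoupled from network-2", {
  ds <- tiny_dataset()
  cfg <- tiny_backbone()
  f_a <- colearn_fit(ds, "colearn", backbone = cfg,
                     loss = loss_config(gamma = 0), steps = 3, seed = 9)
  # perturb network-2's starting point by seeding it differently: reuse the
  # same run but with a different top-level-independent init2 by fitting a
  # modified dataset ordering is not possible; instead verify directly that
  # params1 updates ignore network-2 by comparing with the single-network run
  f_b <- colearn_fit(ds, "self-omega", backbone = cfg, steps = 3, seed = 9)
  expect_equal(flat_params(f_a$params1), flat_params(f_b$params1),
               tolerance = 1e-12)
  expect_equal(f_a$history$l_uc1, f_b$history$l_co, tolerance = 1e-12)
})

test_that("validation passes are recorded and finite", {
  ds <- tiny_dataset()
  fit <- colearn_fit(ds, "colearn", backbone = tiny_backbone(), steps = 2,
                     val_every = 1, seed = 4)
  expect_equal(nrow(fit$val_history), 2L)
  expect_true(all(is.finite(fit$val_history$psnr_db)))
})

test_that("reconstruction at test time is data-consistent and deterministic", {
  ds <- tiny_dataset()
  cfg <- tiny_backbone()
  fit <- colearn_fit(ds, "colearn", backbone = cfg, steps = 2, seed = 5)
  sq <- ds$test[[1]]
  y_om <- apply_mask(sq$kspace, sq$masks$omega)
  rec <- reconstruct_test(y_om, sq$masks$omega, fit)
  resid <- Mod((fft2c(rec) - y_om) * as.numeric(sq$masks$omega))
  expect_lt(max(resid), 1e-5)
  expect_identical(rec, reconstruct_test(y_om, sq$masks$omega, fit))
  # zero-parameter checkpoint returns the zero-filled input
  fit0 <- fit
  fit0$params1 <- dynrecon:::zero_like(fit$params1)
  attr(fit0$params1, "backbone") <- "crnn"
  expect_lt(max(Mod(reconstruct_test(y_om, sq$masks$omega, fit0) -
                      zero_filled(y_om, sq$masks$omega))), 1e-12)
  # predict() on a dataset reconstructs the chosen split
  recs <- predict(fit, ds, split = "test")
  expect_length(recs, length(ds$test))
  expect_equal(recs[[1]], rec)
})

test_that("training errors on empty or incompatible inputs", {
  ds <- tiny_dataset()
  ds_empty <- ds
  ds_empty$train <- list()
  expect_error(colearn_fit(ds_empty, "colearn", backbone = tiny_backbone(),
                           steps = 1), "empty")
  ds_noref <- ds
  ds_noref$train <- lapply(ds_noref$train, function(sq) {
    sq$image <- NULL; sq
  })
  expect_error(colearn_fit(ds_noref, "supervised", backbone = tiny_backbone(),
                           steps = 1), "reference")
})

test_that("fit object methods print, summarize, plot and expose coefficients", {
  ds <- tiny_dataset()
  fit <- colearn_fit(ds, "colearn", backbone = tiny_backbone(), steps = 2,
                     seed = 2)
  expect_output(print(fit), "strategy: colearn")
  expect_output(summary(fit), "mean l_co")
  expect_identical(coef(fit), fit$params1)
  expect_identical(coef(fit, network = 2), fit$params2)
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
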