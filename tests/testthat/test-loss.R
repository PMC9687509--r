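# 1-frame 2x2 toy grid with the first row sampled: 2 sampled, 2 unsampled
# entries; reductions can be enumerated by hand.
toy_grid <- function() {
  m <- array(0, c(2, 2, 1)); m[1, , 1] <- 1
  y <- array(0i, c(2, 2, 1)); y[1, , 1] <- c(1 + 0i, 2 + 0i)
  list(m = m, y = y)
}

test_that("uc_loss matches the hand-enumerated reduction on the toy grid", {
  tg <- toy_grid()
  k1 <- tg$y; k1[1, 1, 1] <- k1[1, 1, 1] + 0.1   # one sampled entry off by 0.1
  k1[2, 1, 1] <- 99                               # unsampled entries ignored
  k2 <- tg$y
  expect_equal(uc_loss(k1, k2, tg$y, tg$m), 0.01 / 2 + 0, tolerance = 1e-12)
  # quadratic scaling: doubling the deviation quadruples the term
  k4 <- tg$y; k4[1, 1, 1] <- k4[1, 1, 1] + 0.2
  expect_equal(uc_loss(k4, k2, tg$y, tg$m), 4 * 0.005, tolerance = 1e-12)
  # exact consistency on the sampled entries -> 0
  expect_equal(uc_loss(k2, k2, tg$y, tg$m), 0)
  expect_error(uc_loss(k1, k2, tg$y, array(0, c(2, 2, 1))), "no entries")
})

test_that("cc_loss matches the hand-enumerated reduction and conventions", {
  tg <- toy_grid()
  k1 <- tg$y; k2 <- tg$y
  k1[2, 1, 1] <- 0.2    # one unsampled entry differs by 0.2
  expect_equal(cc_loss(k1, k2, tg$m), 0.04 / 2, tolerance = 1e-12)
  expect_equal(cc_loss(k2, k1, tg$m), cc_loss(k1, k2, tg$m))  # symmetry
  expect_equal(cc_loss(k1, k1, tg$m), 0)
  expect_equal(cc_loss(k1, k2, array(1, c(2, 2, 1))), 0)  # full sampling
})

test_that("co_loss combines the terms with weight gamma and reports components", {
  tg <- toy_grid()
  k1 <- tg$y; k1[1, 1, 1] <- k1[1, 1, 1] + 0.1; k1[2, 1, 1] <- 0.2
  k2 <- tg$y
  lb <- co_loss(k1, k2, tg$y, tg$m, loss_config(gamma = 0.01))
  expect_equal(lb$l_uc, 0.005, tolerance = 1e-12)
  expect_equal(lb$l_cc, 0.02, tolerance = 1e-12)
  expect_equal(lb$l_co, 0.0052, tolerance = 1e-12)
  expect_equal(lb$l_co, lb$l_uc + 0.01 * lb$l_cc, tolerance = 1e-7)
  # degenerate weight
  lb0 <- co_loss(k1, k2, tg$y, tg$m, loss_config(gamma = 0))
  expect_equal(lb0$l_co, lb0$l_uc)
  # fully consistent pair
  lbz <- co_loss(k2, k2, tg$y, tg$m, loss_config())
  expect_equal(lbz$l_co, 0)
})

test_that("image-domain and k-space losses agree under the orthonormal transform", {
  set.seed(31)
  for (i in 1:5) {
    k1 <- random_sequence(16, 16, 2, seed = i)
    k2 <- random_sequence(16, 16, 2, seed = i + 100)
    m <- generate_cartesian_mask(2, 16, 16, af = 4, n_acs = 2, seed = i)
    y <- apply_mask(random_sequence(16, 16, 2, seed = i + 200), m)
    ck <- loss_config(uc_domain = "kspace", cc_domain = "kspace")
    ci <- loss_config(uc_domain = "image", cc_domain = "image")
    uk <- uc_loss(k1, k2, y, m, ck); ui <- uc_loss(k1, k2, y, m, ci)
    expect_lt(abs(uk - ui) / uk, 1e-6)
    vk <- cc_loss(k1, k2, m, ck); vi <- cc_loss(k1, k2, m, ci)
    expect_lt(abs(vk - vi) / vk, 1e-6)
  }
})

test_that("analytic loss gradients match finite differences in both domains", {
  m <- generate_cartesian_mask(1, 8, 8, af = 2, n_acs = 2, seed = 2)
  y <- apply_mask(random_sequence(8, 8, 1, seed = 3), m)
  k1 <- random_sequence(8, 8, 1, seed = 4)
  k2 <- random_sequence(8, 8, 1, seed = 5)
  eps <- 1e-6
  for (dom in c("kspace", "image")) {
    cfg <- loss_config(gamma = 0.3, uc_domain = dom, cc_domain = dom)
    lb <- co_loss(k1, k2, y, m, cfg, grad = TRUE)
    set.seed(6)
    for (i in sample(length(k1), 6)) {
      for (part in c("re", "im")) {
        dz <- if (part == "re") eps else 1i * eps
        fp <- co_loss(k1 + dz * (seq_along(k1) == i), k2, y, m, cfg)$l_co
        fm <- co_loss(k1 - dz * (seq_along(k1) == i), k2, y, m, cfg)$l_co
        fd <- (fp - fm) / (2 * eps)
        an <- if (part == "re") Re(lb$g1[i]) else Im(lb$g1[i])
        expect_lt(abs(fd - an), 1e-7 + 1e-4 * abs(fd))
      }
    }
  }
})

test_that("contrastive gradient vanishes at consensus", {
  m <- generate_cartesian_mask(1, 8, 8, af = 2, n_acs = 2, seed = 9)
  k <- random_sequence(8, 8, 1, seed = 10)
  g <- cc_loss(k, k, m, loss_config(), grad = TRUE)
  expect_equal(max(Mod(g$g1)), 0)
})
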