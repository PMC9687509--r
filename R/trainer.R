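#' Fit a self-supervised collaborative reconstruction model
#'
#' The main fitting function. In the `"colearn"` strategy, the acquired
#' k-space of every training sequence is re-split into two overlapping
#' subsets (theta, lambda); two independently initialized unrolled networks
#' reconstruct from the zero-filled images of the two subsets, and a single
#' joint Adam step minimizes the co-training loss
#' `L_UC + gamma * L_CC` — consistency with the acquired entries plus
#' consistency between the two predictions on non-acquired entries
#' (gradients of the contrastive term flow into both networks). No fully
#' sampled reference is used.
#'
#' Baseline strategies use a single network: `"ssdu"` feeds the theta
#' subset and scores the prediction against the held-out lambda entries
#' only; `"self-omega"` feeds the theta subset and scores against all
#' acquired entries; `"supervised"` feeds the full acquired data and scores
#' the image against the fully sampled reference (requiring references in
#' the dataset).
#'
#' Training is deterministic given `seed`: network initializations and the
#' per-epoch shuffle order derive from named sub-seeds, and the k-space
#' partition is fixed in the dataset. Batch size is 1 sequence per step.
#'
#' @param data a `recon_dataset` from [make_fixture_dataset()] or
#'   [read_dataset()]; `$train` is iterated, `$val` scored when
#'   `val_every > 0`.
#' @param strategy one of `"colearn"`, `"self-omega"`, `"ssdu"`,
#'   `"supervised"`.
#' @param backbone a [crnn_config()].
#' @param loss a [loss_config()] (used by `"colearn"`).
#' @param steps number of optimization steps to run.
#' @param lr,beta1,beta2 Adam hyperparameters (defaults 1e-4, 0.5, 0.999).
#' @param val_every validate on `data$val` every this many steps (0 = never).
#' @param seed top-level seed.
#' @param init a previous `colearn_fit` (or loaded checkpoint) to resume
#'   from; `data`, strategy and shapes must match.
#' @param log_csv optional path; per-step loss components are written there
#'   as CSV (`step, l_uc, l_cc, l_co, lr`).
#' @param verbose print progress every 50 steps.
#' @return an object of class `colearn_fit` with methods `print`,
#'   `summary`, `predict`, `plot` and `coef`.
#' @seealso [predict.colearn_fit()], [reconstruct_test()]
#' @export
colearn_fit <- function(data, strategy = c("colearn", "self-omega", "ssdu",
                                           "supervised"),
                        backbone = crnn_config(), loss = loss_config(),
                        steps = 300L, lr = 1e-4, beta1 = 0.5, beta2 = 0.999,
                        val_every = 0L, seed = 1L, init = NULL,
                        log_csv = NULL, verbose = FALSE) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(data, "recon_dataset"), lr > 0, steps >= 1)
  train <- data$train
  if (length(train) == 0) stop("empty training split")
  if (strategy == "supervised" && is.null(train[[1]]$image))
    stop("supervised training requires fully sampled reference images")
  dual <- strategy == "colearn"

  if (is.null(init)) {
    params1 <- init_params(backbone, sub_seed(seed, "init1"))
    params2 <- if (dual) init_params(backbone, sub_seed(seed, "init2"))
    opt <- list(m = NULL, v = NULL, t = 0L)
    step0 <- 0L
    history <- NULL
    val_history <- NULL
  } else {
    stopifnot(inherits(init, "colearn_fit"), identical(init$strategy, strategy))
    params1 <- init$params1; params2 <- init$params2
    opt <- init$opt; step0 <- init$step
    backbone <- init$backbone; loss <- init$loss
    seed <- init$seed
    history <- init$history; val_history <- init$val_history
  }
  joint <- if (dual) list(p1 = params1, p2 = params2) else list(p1 = params1)
  if (is.null(opt$m)) opt <- list(m = zero_like(joint), v = zero_like(joint),
                                  t = 0L)
  hp <- list(lr = lr, b1 = beta1, b2 = beta2, eps = 1e-8)

  n_seq <- length(train)
  rows <- vector("list", steps)
  val_rows <- list()
  for (s in seq_len(steps)) {
    gstep <- step0 + s
    epoch <- (gstep - 1L) %/% n_seq + 1L
    pos <- (gstep - 1L) %% n_seq + 1L
    order_e <- with_seed(sub_seed(seed, paste0("shuffle-", epoch)),
                         sample.int(n_seq))
    sq <- train[[order_e[pos]]]
    res <- train_step(joint, opt, sq, strategy, backbone, loss, hp)
    joint <- res$joint; opt <- res$opt
    lb <- res$loss
    if (!is.finite(lb$l_co))
      stop("non-finite loss at step ", gstep, " (l_uc = ", lb$l_uc,
           ", l_cc = ", lb$l_cc, "); try a smaller learning rate")
    rows[[s]] <- data.frame(step = gstep, l_uc = lb$l_uc, l_cc = lb$l_cc,
                            l_co = lb$l_co, l_uc1 = lb$l_uc1, lr = lr)
    if (val_every > 0 && (gstep %% val_every == 0) && length(data$val) > 0) {
      vm <- validate_pass(joint$p1, backbone, data$val)
      val_rows[[length(val_rows) + 1L]] <-
        cbind(data.frame(step = gstep), vm)
    }
    if (verbose && (gstep %% 50L == 0L))
      message(sprintf("step %d  l_co %.3e", gstep, lb$l_co))
  }
  history <- rbind(history, do.call(rbind, rows))
  if (length(val_rows))
    val_history <- rbind(val_history, do.call(rbind, val_rows))
  if (!is.null(log_csv)) utils::write.csv(history, log_csv, row.names = FALSE)

  fit <- structure(list(
    strategy = strategy, params1 = joint$p1,
    params2 = if (dual) joint$p2, opt = opt, step = step0 + steps,
    backbone = backbone, loss = loss, lr = lr, beta1 = beta1, beta2 = beta2,
    seed = seed, history = history, val_history = val_history,
    data_info = list(n_train = n_seq, dim = dim(train[[1]]$kspace)),
    call = match.call()
  ), class = "colearn_fit")
  fit
}

# One optimization step on one sequence; returns updated joint params,
# optimizer state and the loss breakdown.
train_step <- function(joint, opt, sq, strategy, cfg, lcfg, hp) {
  omega <- sq$masks$omega
  y_omega <- apply_mask(sq$kspace, omega)
  if (strategy == "colearn") {
    th <- sq$masks$theta; la <- sq$masks$lambda
    y_th <- apply_mask(y_omega, th)
    y_la <- apply_mask(y_omega, la)
    f1 <- net_forward(joint$p1, ifft2c(y_th), y_th, th, cfg, tape = TRUE)
    f2 <- net_forward(joint$p2, ifft2c(y_la), y_la, la, cfg, tape = TRUE)
    k1 <- fft2c(f1$x); k2 <- fft2c(f2$x)
    lb <- co_loss(k1, k2, y_omega, omega, lcfg, grad = TRUE)
    grads <- list(p1 = net_backward(joint$p1, f1, ifft2c(lb$g1), cfg),
                  p2 = net_backward(joint$p2, f2, ifft2c(lb$g2), cfg))
  } else {
    if (strategy == "supervised") {
      x0 <- ifft2c(y_omega)
      f1 <- net_forward(joint$p1, x0, y_omega, omega, cfg, tape = TRUE)
      ls <- supervised_loss(f1$x, sq$image, grad = TRUE)
      gx <- ls$g
    } else {
      th <- sq$masks$theta
      y_th <- apply_mask(y_omega, th)
      f1 <- net_forward(joint$p1, ifft2c(y_th), y_th, th, cfg, tape = TRUE)
      k1 <- fft2c(f1$x)
      ls <- if (strategy == "ssdu") {
        la <- sq$masks$lambda
        masked_kspace_loss(k1, apply_mask(y_omega, la), la, grad = TRUE)
      } else {  # self-omega
        masked_kspace_loss(k1, y_omega, omega, grad = TRUE)
      }
      gx <- ifft2c(ls$g)
    }
    lb <- list(l_uc = ls$value, l_cc = NA_real_, l_co = ls$value,
               l_uc1 = ls$value)
    grads <- list(p1 = net_backward(joint$p1, f1, gx, cfg))
  }
  opt$t <- opt$t + 1L
  upd <- adam_tree(joint, grads, opt$m, opt$v, hp, opt$t)
  list(joint = upd$p, opt = list(m = upd$m, v = upd$v, t = opt$t), loss = lb)
}

# Adam over a nested list of parameter arrays (elementwise, bias-corrected).
# Recurse by position: parameter subtrees (e.g. the layer list) may be unnamed.
adam_tree <- function(p, g, m, v, hp, t) {
  if (is.list(p)) {
    for (i in seq_along(p)) {
      r <- adam_tree(p[[i]], g[[i]], m[[i]], v[[i]], hp, t)
      p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
    }
    return(list(p = p, m = m, v = v))
  }
  m <- hp$b1 * m + (1 - hp$b1) * g
  v <- hp$b2 * v + (1 - hp$b2) * g * g
  mh <- m / (1 - hp$b1^t)
  vh <- v / (1 - hp$b2^t)
  list(p = p - hp$lr * mh / (sqrt(vh) + hp$eps), m = m, v = v)
}

validate_pass <- function(params, cfg, val) {
  refs <- lapply(val, `[[`, "image")
  recs <- lapply(val, function(sq) {
    y <- apply_mask(sq$kspace, sq$masks$omega)
    net_forward(params, ifft2c(y), y, sq$masks$omega, cfg)$x
  })
  attr(evaluate_recon(refs, recs), "summary")["mean", , drop = FALSE]
}

#' Reconstruct test data with a trained model
#'
#' At test time there is no re-splitting: the acquired undersampled k-space
#' is zero-filled and fed to collaborative network 1, with data consistency
#' against the full acquisition mask. The output is hard-data-consistent
#' with `y_omega` at every sampled entry when the backbone uses hard DC.
#'
#' @param y_omega acquired complex k-space `H x W x T`, zero outside the
#'   mask support.
#' @param omega the acquisition `sampling_mask`.
#' @param fit a `colearn_fit` (or loaded checkpoint).
#' @return complex reconstruction `H x W x T`.
#' @export
reconstruct_test <- function(y_omega, omega, fit) {
  stopifnot(inherits(fit, "colearn_fit"))
  crnn_reconstruct(zero_filled(y_omega, omega), apply_mask(y_omega, omega),
                   omega, fit$params1, fit$backbone)
}

#' Named experiment presets
#'
#' `"desk"` is the package's small-scale profile (32 x 32 frames, 8 time
#' points, 12 filters, 3 unrolled iterations, 300 steps) sized so a full
#' multi-strategy comparison runs on a laptop CPU in minutes; `"full"` is
#' the full-scale profile (128 x 128 x 14 sequences, 64 filters, 5
#' iterations) matching how such models are trained on real cine data.
#'
#' @param name `"desk"` or `"full"`.
#' @return list with elements `phantom` ([phantom_config()]), `backbone`
#'   ([crnn_config()]), `af`, `n_acs`, `steps`.
#' @export
train_preset <- function(name = c("desk", "full")) {
  name <- match.arg(name)
  if (name == "desk") {
    list(phantom = phantom_config(frames = 8L, h = 32L, w = 32L),
         backbone = crnn_config(n_iters = 3L, n_filters = 12L),
         af = 4, n_acs = 4L, steps = 300L)
  } else {
    list(phantom = phantom_config(frames = 14L, h = 128L, w = 128L),
         backbone = crnn_config(n_iters = 5L, n_filters = 64L),
         af = 8, n_acs = 4L, steps = 50000L)
  }
}

#' Run the desk-scale strategy-comparison experiment
#'
#' The package's end-to-end experiment: generate a synthetic cine cohort at
#' the desk profile (20 training, 2 validation, 5 test sequences of
#' 32 x 32 x 8 at 4-fold acceleration), train the requested strategies for
#' 300 steps each with the standard hyperparameters (Adam, lr 1e-4,
#' beta = (0.5, 0.999), batch 1, gamma = 0.01, tiny CRNN with 12 filters
#' and 3 unrolled iterations), and score mean test PSNR/SSIM against the
#' fully sampled references, alongside the zero-filled baseline. The
#' expected qualitative ordering is
#' supervised >= colearn > self-omega > zero-filled.
#'
#' @param seed top-level seed for the cohort and all training runs.
#' @param strategies character vector of strategies to train (see
#'   [colearn_fit()]).
#' @param steps training steps per strategy.
#' @param n_train,n_val,n_test cohort sizes.
#' @param verbose print progress.
#' @return a data frame with one row per method (including
#'   `"zero-filled"`): columns `method`, `psnr_db`, `ssim`, `mse`
#'   (cohort means over the test split).
#' @export
run_desk_experiment <- function(seed = 1L,
                                strategies = c("self-omega", "colearn",
                                               "supervised"),
                                steps = 300L, n_train = 20L, n_val = 2L,
                                n_test = 5L, verbose = FALSE) {
  pre <- train_preset("desk")
  ds <- make_fixture_dataset(n_train, n_val, n_test, pre$phantom,
                             af = pre$af, n_acs = pre$n_acs, seed = seed)
  refs <- lapply(ds$test, `[[`, "image")
  score <- function(recs) {
    s <- attr(evaluate_recon(refs, recs), "summary")["mean", ]
    data.frame(psnr_db = s$psnr_db, ssim = s$ssim, mse = s$mse)
  }
  zf <- lapply(ds$test, function(sq)
    zero_filled(apply_mask(sq$kspace, sq$masks$omega), sq$masks$omega))
  out <- cbind(data.frame(method = "zero-filled"), score(zf))
  for (st in strategies) {
    if (verbose) message("training strategy ", st)
    fit <- colearn_fit(ds, st, backbone = pre$backbone, steps = steps,
                       seed = seed, verbose = verbose)
    out <- rbind(out, cbind(data.frame(method = st), score(predict(fit, ds))))
  }
  out
}
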