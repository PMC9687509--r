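#' @export
print.colearn_fit <- function(x, ...) {
  d <- x$data_info$dim
  cat("Self-supervised dynamic MRI reconstruction fit\n")
  cat(sprintf("  strategy: %s   backbone: %s (%d iters, %d filters)\n",
              x$strategy, x$backbone$backbone, x$backbone$n_iters,
              x$backbone$n_filters))
  cat(sprintf("  trained %d steps on %d sequences of %d x %d x %d\n",
              x$step, x$data_info$n_train, d[1], d[2], d[3]))
  n <- nrow(x$history)
  cat(sprintf("  loss l_co: %.4e (first) -> %.4e (last)\n",
              x$history$l_co[1], x$history$l_co[n]))
  invisible(x)
}

#' @export
summary.colearn_fit <- function(object, ...) {
  print(object)
  h <- object$history
  tail_n <- min(20L, nrow(h))
  cat(sprintf("  mean l_co over last %d steps: %.4e\n", tail_n,
              mean(h$l_co[(nrow(h) - tail_n + 1):nrow(h)])))
  if (!is.null(object$val_history)) {
    v <- object$val_history
    cat("  validation (mean over split):\n")
    print(v, row.names = FALSE, digits = 4)
  }
  invisible(object)
}

#' Reconstruct sequences with a fitted model
#'
#' Applies the trained network (collaborative network 1) to undersampled
#' k-space. `newdata` may be a `recon_dataset` (the chosen split is
#' reconstructed sequence by sequence) or a single sequence entry
#' (`list(kspace, masks)`). Reconstruction always uses the full acquisition
#' mask — the training-time re-split plays no role at test time.
#'
#' @param object a `colearn_fit`.
#' @param newdata dataset or single sequence; the fit does not retain the
#'   training data, so `newdata` is always required.
#' @param split which split of a `recon_dataset` to reconstruct.
#' @param ... unused.
#' @return a list of complex reconstructions (or a single array for a
#'   single sequence).
#' @export
predict.colearn_fit <- function(object, newdata, split = "test", ...) {
  if (inherits(newdata, "recon_dataset")) {
    seqs <- newdata[[split]]
    return(lapply(seqs, function(sq)
      reconstruct_test(apply_mask(sq$kspace, sq$masks$omega),
                       sq$masks$omega, object)))
  }
  stopifnot(is.list(newdata), !is.null(newdata$kspace), !is.null(newdata$masks))
  reconstruct_test(apply_mask(newdata$kspace, newdata$masks$omega),
                   newdata$masks$omega, object)
}

#' @export
coef.colearn_fit <- function(object, network = 1L, ...) {
  if (network == 1L) object$params1 else object$params2
}

#' Plot the training loss trajectory
#'
#' Loss components against optimization step on a log scale, with the
#' validation PSNR overlaid (right axis) when periodic validation was run.
#'
#' @param x a `colearn_fit`.
#' @param ... passed to `plot.default`.
#' @export
plot.colearn_fit <- function(x, ...) {
  h <- x$history
  graphics::plot.default(h$step, h$l_co, type = "l", log = "y",
                         xlab = "step", ylab = "loss", col = "black", ...)
  if (any(is.finite(h$l_cc))) {
    graphics::lines(h$step, h$l_uc, col = "grey40", lty = 2)
    graphics::legend("topright", c("l_co", "l_uc"), col = c("black", "grey40"),
                     lty = c(1, 2), bty = "n")
  }
  if (!is.null(x$val_history)) {
    op <- graphics::par(new = TRUE)
    on.exit(graphics::par(op))
    v <- x$val_history
    graphics::plot.default(v$step, v$psnr_db, type = "b", col = "firebrick",
                           axes = FALSE, xlab = "", ylab = "",
                           xlim = range(h$step))
    graphics::axis(4, col.axis = "firebrick")
  }
  invisible(x)
}
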