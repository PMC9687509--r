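#' Reconstruction error metrics on magnitude images
#'
#' `mse_metric()` is the mean squared difference over all voxels;
#' `psnr_metric()` is `20*log10(MAX_ref / sqrt(MSE))` in dB with `MAX_ref`
#' the maximum of the reference (an `Inf` sentinel when MSE is exactly 0);
#' `ssim_metric()` is the structural similarity index, computed per frame
#' with an 11x11 Gaussian window (sigma 1.5) over the valid interior,
#' dynamic range `L = MAX_ref`, constants `c1 = (0.01 L)^2`,
#' `c2 = (0.03 L)^2`, averaged over windows and then over frames.
#'
#' @param ref,rec real nonnegative magnitude sequences (`H x W x T` arrays
#'   or matrices) of identical shape.
#' @return a scalar.
#' @examples
#' psnr_metric(array(1, c(8, 8, 1)), array(0.99, c(8, 8, 1)))  # 40 dB
#' @export
mse_metric <- function(ref, rec) {
  if (!identical(dim(ref), dim(rec))) stop("ref and rec shapes differ")
  mean((ref - rec)^2)
}

#' @rdname mse_metric
#' @export
psnr_metric <- function(ref, rec) {
  if (all(ref == 0)) stop("reference image is identically zero")
  m <- mse_metric(ref, rec)
  if (m == 0) return(Inf)
  20 * log10(max(ref) / sqrt(m))
}

#' @rdname mse_metric
#' @param window odd Gaussian window size (default 11).
#' @param sigma Gaussian window standard deviation in pixels (default 1.5).
#' @export
ssim_metric <- function(ref, rec, window = 11L, sigma = 1.5) {
  if (!identical(dim(ref), dim(rec))) stop("ref and rec shapes differ")
  if (is.matrix(ref)) { dim(ref) <- c(dim(ref), 1L); dim(rec) <- dim(ref) }
  d <- dim(ref)
  if (d[1] < window || d[2] < window)
    stop("image smaller than the SSIM window")
  L <- max(ref)
  if (L == 0) stop("reference image is identically zero")
  c1 <- (0.01 * L)^2
  c2 <- (0.03 * L)^2
  g <- exp(-((seq_len(window) - (window + 1) / 2)^2) / (2 * sigma^2))
  G <- outer(g, g)
  G <- G / sum(G)
  vals <- vapply(seq_len(d[3]), function(t)
    ssim_frame(ref[, , t], rec[, , t], G, c1, c2), numeric(1))
  mean(vals)
}

# Gaussian-weighted local statistics via same-padding convolution, cropped
# to the valid interior (centres with full windows), then the SSIM map.
ssim_frame <- function(x, y, G, c1, c2) {
  w <- nrow(G)
  pad <- (w - 1) / 2
  filt <- function(z) {
    dim(z) <- c(dim(z), 1L, 1L)
    k <- array(G, c(w, w, 1L, 1L))
    out <- cpp_conv_fwd(z, k, 0)
    out <- out[, , 1L, 1L]
    out[(pad + 1):(nrow(out) - pad), (pad + 1):(ncol(out) - pad)]
  }
  mx <- filt(x); my <- filt(y)
  sxx <- filt(x * x) - mx^2
  syy <- filt(y * y) - my^2
  sxy <- filt(x * y) - mx * my
  m <- ((2 * mx * my + c1) * (2 * sxy + c2)) /
    ((mx^2 + my^2 + c1) * (sxx + syy + c2))
  mean(m)
}

#' Per-sequence metrics and cohort summary
#'
#' Scores a list of reconstructions against the matching references on
#' magnitude images. Both sequences are normalized by the reference maximum
#' before scoring, so metrics are invariant to a common intensity scale.
#'
#' @param refs,recs lists of complex (or real magnitude) sequences of equal
#'   length.
#' @return a `metrics_report`: data frame with columns `id`, `mse`,
#'   `psnr_db`, `ssim`, carrying the cohort summary (mean and sample sd per
#'   metric) as attribute `summary`.
#' @export
evaluate_recon <- function(refs, recs) {
  stopifnot(length(refs) == length(recs), length(refs) >= 1)
  rows <- lapply(seq_along(refs), function(i) {
    ref <- Mod(refs[[i]]); rec <- Mod(recs[[i]])
    mx <- max(ref)
    ref <- ref / mx; rec <- rec / mx
    data.frame(id = i, mse = mse_metric(ref, rec),
               psnr_db = psnr_metric(ref, rec),
               ssim = ssim_metric(ref, rec))
  })
  df <- do.call(rbind, rows)
  structure(df, summary = summarize_metrics(df), class = c("metrics_report",
                                                           "data.frame"))
}

#' Cohort mean and standard deviation of per-sequence metrics
#'
#' @param df data frame with numeric metric columns (and optionally `id`).
#' @return data frame with rows `mean` and `sd`.
#' @export
summarize_metrics <- function(df) {
  stopifnot(nrow(df) >= 1)
  num <- df[, setdiff(names(df), "id"), drop = FALSE]
  out <- rbind(mean = vapply(num, mean, numeric(1)),
               sd = if (nrow(num) > 1) vapply(num, stats::sd, numeric(1))
                    else rep(0, ncol(num)))
  as.data.frame(out)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Per-sequence reconstruction metrics (", nrow(x), " sequences)\n",
      sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat("\nCohort summary:\n")
  print(attr(x, "summary"), digits = 4)
  invisible(x)
}
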