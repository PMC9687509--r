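#' Configuration of the self-supervised co-training loss
#'
#' The co-training objective is `L = L_UC + gamma * L_CC`: an
#' undersampled-consistency term scoring both networks' predicted k-space
#' against the acquired entries, plus a contrastive-consistency term scoring
#' the two predictions against each other on the non-acquired entries.
#' Either term can be evaluated in k-space or, equivalently under the
#' orthonormal transform, in the image domain (on the back-transform of the
#' masked residual); both terms are reduced by the count of selected k-space
#' entries, which makes the two domains agree to floating-point accuracy
#' (Parseval) and keeps the loss scale independent of grid size and
#' acceleration.
#'
#' @param gamma nonnegative weight of the contrastive term (default 0.01).
#' @param uc_domain,cc_domain `"kspace"` or `"image"` for each term
#'   (defaults: both `"kspace"`).
#' @return a `loss_config` list.
#' @export
loss_config <- function(gamma = 0.01, uc_domain = c("kspace", "image"),
                        cc_domain = c("kspace", "image")) {
  stopifnot(gamma >= 0)
  structure(list(gamma = gamma, uc_domain = match.arg(uc_domain),
                 cc_domain = match.arg(cc_domain)),
            class = "loss_config")
}

# squared complex modulus summed
sq_sum <- function(z) sum(Re(z)^2 + Im(z)^2)

#' Undersampled-consistency loss
#'
#' Mean squared complex modulus of `k1 - y_omega` plus of `k2 - y_omega`,
#' each over the sampled entries of the acquisition mask `p_t` only. In the
#' image-domain variant each residual is masked, back-transformed, and
#' scored over all pixels with the same divisor (the sampled-entry count).
#' `k2` may be `NULL` for single-network training.
#'
#' @param k1,k2 full predicted k-space sequences (complex `H x W x T`).
#' @param y_omega acquired k-space, zero outside `p_t`.
#' @param p_t the acquisition sampling mask.
#' @param cfg a [loss_config()].
#' @param grad if `TRUE`, also return gradients w.r.t. `k1`, `k2`.
#' @return the scalar loss, or `list(value, g1, g2)` when `grad = TRUE`.
#' @export
uc_loss <- function(k1, k2, y_omega, p_t, cfg = loss_config(), grad = FALSE) {
  mn <- as.numeric(p_t); dim(mn) <- dim(p_t)
  ns <- sum(mn)
  if (ns == 0) stop("acquisition mask samples no entries")
  if (!identical(dim(k1), dim(mn))) stop("k-space and mask shapes differ")
  term <- function(k) {
    r <- (k - y_omega) * mn
    if (cfg$uc_domain == "kspace") {
      list(v = sq_sum(r) / ns, g = 2 * r / ns)
    } else {
      ri <- ifft2c(r)
      list(v = sq_sum(ri) / ns, g = mn * fft2c(2 * ri / ns))
    }
  }
  t1 <- term(k1)
  t2 <- if (is.null(k2)) list(v = 0, g = NULL) else term(k2)
  if (!grad) return(t1$v + t2$v)
  list(value = t1$v + t2$v, g1 = t1$g, g2 = t2$g)
}

#' Contrastive-consistency loss
#'
#' Mean squared complex modulus of `k1 - k2` over the entries *not* sampled
#' by the acquisition mask; zero by convention when the mask samples
#' everything. Symmetric in its two arguments and stationary at consensus
#' (`k1 == k2`).
#'
#' @inheritParams uc_loss
#' @return the scalar loss, or `list(value, g1, g2)` when `grad = TRUE`.
#' @export
cc_loss <- function(k1, k2, p_t, cfg = loss_config(), grad = FALSE) {
  if (!identical(dim(k1), dim(k2))) stop("k1 and k2 shapes differ")
  mn <- as.numeric(p_t); dim(mn) <- dim(p_t)
  if (!identical(dim(k1), dim(mn))) stop("k-space and mask shapes differ")
  nu <- sum(1 - mn)
  if (nu == 0) {
    if (!grad) return(0)
    return(list(value = 0, g1 = k1 * 0, g2 = k1 * 0))
  }
  r <- (k1 - k2) * (1 - mn)
  if (cfg$cc_domain == "kspace") {
    v <- sq_sum(r) / nu
    g1 <- 2 * r / nu
  } else {
    ri <- ifft2c(r)
    v <- sq_sum(ri) / nu
    g1 <- (1 - mn) * fft2c(2 * ri / nu)
  }
  if (!grad) return(v)
  list(value = v, g1 = g1, g2 = -g1)
}

#' Combined co-training loss
#'
#' `l_co = l_uc + gamma * l_cc`, with the individual terms, the per-network
#' undersampled-consistency components and the entry counts reported.
#'
#' @inheritParams uc_loss
#' @return a `loss_breakdown` list: `l_uc`, `l_cc`, `l_co`, `l_uc1`,
#'   `l_uc2`, `n_sampled`, `n_unsampled`; when `grad = TRUE` also `g1`,
#'   `g2` (gradients w.r.t. `k1`, `k2`).
#' @export
co_loss <- function(k1, k2, y_omega, p_t, cfg = loss_config(), grad = FALSE) {
  mn <- as.numeric(p_t)
  u1 <- uc_loss(k1, NULL, y_omega, p_t, cfg, grad = grad)
  u2 <- uc_loss(k2, NULL, y_omega, p_t, cfg, grad = grad)
  cc <- cc_loss(k1, k2, p_t, cfg, grad = grad)
  val <- function(x) if (is.list(x)) x$value else x
  l_uc <- val(u1) + val(u2)
  l_cc <- val(cc)
  out <- list(l_uc = l_uc, l_cc = l_cc, l_co = l_uc + cfg$gamma * l_cc,
              l_uc1 = val(u1), l_uc2 = val(u2),
              n_sampled = sum(mn), n_unsampled = sum(1 - mn))
  if (grad) {
    out$g1 <- u1$g1 + cfg$gamma * cc$g1
    out$g2 <- u2$g1 + cfg$gamma * cc$g2
  }
  structure(out, class = "loss_breakdown")
}

# Masked single-network k-space loss: mean |k - y|^2 over the sampled
# entries of mask m (used by the single-network self-supervised baselines).
masked_kspace_loss <- function(k, y, m, grad = FALSE) {
  mn <- as.numeric(m); dim(mn) <- dim(m)
  ns <- sum(mn)
  if (ns == 0) stop("mask samples no entries")
  r <- (k - y) * mn
  v <- sq_sum(r) / ns
  if (!grad) return(v)
  list(value = v, g = 2 * r / ns)
}

# Supervised image-domain loss: mean |x - ref|^2 over all voxels.
supervised_loss <- function(x, ref, grad = FALSE) {
  n <- length(x)
  r <- x - ref
  v <- sq_sum(r) / n
  if (!grad) return(v)
  list(value = v, g = 2 * r / n)
}
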