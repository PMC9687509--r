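#' Generate a retrospective Cartesian undersampling mask
#'
#' Cartesian acceleration skips whole phase-encode lines (rows) of k-space.
#' Each frame keeps a fully sampled block of `n_acs` central (low-frequency,
#' autocalibration) rows plus `round(H / af) - n_acs` rows drawn uniformly
#' without replacement from the remaining rows, independently per frame
#' (a time-interleaved pattern). The readout direction (columns) is always
#' fully sampled, so every kept row is kept whole.
#'
#' @param n_frames,h,w grid dimensions (`h` phase-encode rows, `w` readout
#'   columns); `h`, `w` even.
#' @param af nominal acceleration factor (>= 1); the per-frame sampled-row
#'   count is `round(h / af)`.
#' @param n_acs number of central autocalibration rows (even, >= 2).
#' @param seed integer seed; masks are deterministic given the seed.
#' @return a `sampling_mask`: numeric 0/1 array `h x w x n_frames` with
#'   attributes `acs_rows` (1-based row indices), `nominal_af`, `n_acs`,
#'   `seed`.
#' @examples
#' m <- generate_cartesian_mask(1, 32, 32, af = 4, n_acs = 4, seed = 7)
#' sum(m[, 1, 1])      # 8 sampled rows
#' attr(m, "acs_rows") # rows 15:18 (0-based 14..17)
#' @export
generate_cartesian_mask <- function(n_frames, h, w, af, n_acs = 4L, seed = 1L) {
  stopifnot(n_frames >= 1, h >= 4, w >= 4, h %% 2 == 0, w %% 2 == 0)
  if (af < 1) stop("acceleration factor must be >= 1")
  if (n_acs < 2 || n_acs %% 2 != 0) stop("n_acs must be even and >= 2")
  n_keep <- round(h / af)
  if (n_keep < n_acs)
    stop("round(h / af) = ", n_keep, " is smaller than n_acs = ", n_acs)
  acs <- acs_rows(h, n_acs)
  mask <- array(0, c(h, w, n_frames))
  with_seed(seed, {
    for (t in seq_len(n_frames)) {
      extra <- sample(setdiff(seq_len(h), acs), n_keep - n_acs)
      mask[sort(c(acs, extra)), , t] <- 1
    }
  })
  new_sampling_mask(mask, acs, af, seed)
}

# Central fully sampled block: 0-based rows h/2 - n/2 ... h/2 + n/2 - 1.
acs_rows <- function(h, n_acs) (h / 2 - n_acs / 2 + 1):(h / 2 + n_acs / 2)

new_sampling_mask <- function(mask, acs, af, seed = NA_integer_) {
  structure(mask, acs_rows = as.integer(acs), nominal_af = af,
            n_acs = length(acs), seed = seed, class = "sampling_mask")
}

#' Sampled row indices of a Cartesian mask
#'
#' @param m a `sampling_mask` (or plain 0/1 array with Cartesian row
#'   structure).
#' @return list of integer vectors, one per frame (1-based row indices).
#' @export
mask_rows <- function(m) {
  d <- dim(m)
  lapply(seq_len(d[3]), function(t) which(m[, 1, t] != 0))
}

# Error unless every row of every frame is kept or dropped whole.
check_cartesian <- function(m, what = "mask") {
  d <- dim(m)
  for (t in seq_len(d[3])) {
    rng <- apply(m[, , t], 1, function(r) length(unique(r)))
    if (any(rng != 1L))
      stop(what, ": frame ", t, " has a partially sampled row; ",
           "Cartesian line structure violated")
  }
  invisible(TRUE)
}

#' Partition an acquired mask into two overlapping training masks
#'
#' The self-supervised split: the acquired lines of each frame (support of
#' `omega`) are divided into two subsets `theta` and `lambda` that (1) union
#' back to `omega`, (2) differ from each other, and (3) both keep the whole
#' low-frequency autocalibration block. `theta` receives the ACS rows plus a
#' uniformly chosen half (rounding up) of the non-ACS acquired rows — roughly
#' a further 2-fold acceleration of the high-frequency lines — and `lambda`
#' receives the ACS rows plus the complementary non-ACS rows. The split is
#' drawn independently per frame and is deterministic given `seed`.
#'
#' @param omega a `sampling_mask` from [generate_cartesian_mask()]; every
#'   frame must have at least 2 sampled non-ACS rows.
#' @param seed integer seed.
#' @return a `mask_triple`: list with elements `omega`, `theta`, `lambda`
#'   (each a `sampling_mask`).
#' @export
partition_mask <- function(omega, seed = 1L) {
  acs <- attr(omega, "acs_rows")
  if (is.null(acs)) stop("omega must carry acs_rows (use generate_cartesian_mask)")
  d <- dim(omega)
  rows <- mask_rows(omega)
  theta <- array(0, d); lam <- array(0, d)
  with_seed(seed, {
    for (t in seq_len(d[3])) {
      non_acs <- setdiff(rows[[t]], acs)
      if (length(non_acs) < 2)
        stop("frame ", t, " has fewer than 2 sampled non-ACS rows; ",
             "the two training masks would coincide")
      n_th <- ceiling(length(non_acs) / 2)
      th <- sample(non_acs, n_th)
      theta[c(acs, th), , t] <- 1
      lam[c(acs, setdiff(non_acs, th)), , t] <- 1
    }
  })
  n_th_rows <- sum(theta[, 1, 1])
  n_la_rows <- sum(lam[, 1, 1])
  structure(list(
    omega  = omega,
    theta  = new_sampling_mask(theta, acs, d[1] / n_th_rows, seed),
    lambda = new_sampling_mask(lam, acs, d[1] / n_la_rows, seed)
  ), class = "mask_triple")
}

#' Validate the three split principles of a mask triple
#'
#' Checks, per frame: union (`theta | lambda == omega`), difference
#' (`theta != lambda`), and ACS containment (both subsets keep every
#' autocalibration row).
#'
#' @param triple a `mask_triple`.
#' @return `TRUE` invisibly; errors describing the violated principle
#'   otherwise.
#' @export
validate_mask_triple <- function(triple) {
  stopifnot(inherits(triple, "mask_triple"))
  om <- unclass(triple$omega); th <- unclass(triple$theta); la <- unclass(triple$lambda)
  acs <- attr(triple$omega, "acs_rows")
  d <- dim(om)
  for (t in seq_len(d[3])) {
    u <- pmax(th[, , t], la[, , t])
    if (!isTRUE(all.equal(u, om[, , t], check.attributes = FALSE)))
      stop("frame ", t, ": union of theta and lambda differs from omega")
    if (identical(th[, , t], la[, , t]))
      stop("frame ", t, ": theta and lambda are identical")
    if (any(th[acs, , t] == 0) || any(la[acs, , t] == 0))
      stop("frame ", t, ": a subset mask drops an autocalibration row")
  }
  invisible(TRUE)
}

#' Apply a sampling mask to k-space
#'
#' Elementwise product; entries outside the mask support become exactly zero.
#'
#' @param k complex k-space array `H x W x T`.
#' @param m sampling mask of the same dimension.
#' @return masked k-space array.
#' @export
apply_mask <- function(k, m) {
  if (!identical(dim(k), dim(m))) stop("k-space and mask shapes differ")
  k * as.numeric(m)
}

#' Zero-filled reconstruction
#'
#' The inverse transform of undersampled k-space with missing entries left at
#' zero: the standard aliased baseline image and the input to the
#' reconstruction networks.
#'
#' @inheritParams apply_mask
#' @return complex image sequence `H x W x T`.
#' @export
zero_filled <- function(k, m) ifft2c(apply_mask(k, m))

#' Export the sampled row indices of a mask as plain text
#'
#' One line per frame: the 1-based indices of the sampled phase-encode rows,
#' space-separated. A portable interchange form for Cartesian line masks.
#'
#' @param m a `sampling_mask`.
#' @param file path to write.
#' @export
export_mask_rows <- function(m, file) {
  rows <- mask_rows(m)
  writeLines(vapply(rows, paste, character(1), collapse = " "), file)
}
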