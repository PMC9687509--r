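#' Centred orthonormal Fourier operators for dynamic sequences
#'
#' MR scanners acquire data in k-space, related to the image by a 2D discrete
#' Fourier transform per temporal frame. `fft2c()` maps an image sequence to
#' k-space with the DC (zero-frequency) component at the centre of each frame,
#' using the orthonormal (unitary) scaling `1/sqrt(H*W)`; `ifft2c()` is its
#' exact inverse. With this convention the transform preserves the l2 norm
#' (Parseval), so mean-squared errors measured in k-space and in the image
#' domain coincide — which is why the loss-domain choice barely matters for
#' training (see the methods vignette).
#'
#' Sequences are complex arrays of dimension `H x W x T` (rows are the
#' phase-encode direction). `H` and `W` must be even so that the DC bin sits
#' unambiguously at 0-based index `(H/2, W/2)` of each frame.
#'
#' @param x complex array `H x W x T` (a single `H x W` matrix is accepted and
#'   treated as one frame), all values finite.
#' @return complex array of the same dimension.
#' @examples
#' x <- array(1 + 0i, c(4, 4, 1))
#' k <- fft2c(x)           # sqrt(16) = 4 at the centre bin, zero elsewhere
#' max(Mod(ifft2c(k) - x)) # round trip ~ 1e-16
#' @export
fft2c <- function(x) {
  x <- as_sequence(x)
  frame_transform(x, inverse = FALSE)
}

#' @rdname fft2c
#' @param k complex array `H x W x T` of k-space data, DC at the centre.
#' @export
ifft2c <- function(k) {
  k <- as_sequence(k)
  frame_transform(k, inverse = TRUE)
}

# Coerce to a validated complex H x W x T array.
as_sequence <- function(x) {
  if (is.matrix(x)) dim(x) <- c(nrow(x), ncol(x), 1L)
  stopifnot(is.array(x), length(dim(x)) == 3L)
  d <- dim(x)
  if (d[1] < 4L || d[2] < 4L)
    stop("sequence frames must be at least 4 x 4")
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L)
    stop("frame dimensions must be even (centred DC convention)")
  if (!all(is.finite(Re(x))) || !all(is.finite(Im(x))))
    stop("non-finite values in sequence")
  if (!is.complex(x)) x <- x + 0i
  x
}

# Swap half-spaces along both frame axes (even dims: fftshift == ifftshift).
fftshift2 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  m[c((h / 2 + 1):h, 1:(h / 2)), c((w / 2 + 1):w, 1:(w / 2))]
}

frame_transform <- function(x, inverse) {
  d <- dim(x)
  s <- sqrt(d[1] * d[2])
  out <- array(0i, d)
  for (t in seq_len(d[3])) {
    f <- fftshift2(x[, , t])
    f <- stats::fft(f, inverse = inverse) / s
    out[, , t] <- fftshift2(f)
  }
  out
}

#' Normalize a complex sequence to unit peak magnitude
#'
#' Scales the whole sequence by `1 / max(Mod(x))` so magnitudes lie in
#' `[0, 1]`; the relative phase structure is untouched. Normalization is an
#' explicit preprocessing step, never implicit in other operations.
#'
#' @param x complex array `H x W x T`.
#' @return the rescaled array.
#' @export
normalize_sequence <- function(x) {
  x <- as_sequence(x)
  m <- max(Mod(x))
  if (m == 0) stop("cannot normalize an all-zero sequence")
  x / m
}
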