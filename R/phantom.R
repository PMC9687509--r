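#' Configuration for the synthetic beating-ellipse cine phantom
#'
#' The generator emulates the statistical structure of single-coil,
#' magnitude-normalized short-axis cardiac cine data: a handful of smooth
#' anti-aliased ellipses whose radii pulse once per sequence (one full cycle
#' over the `frames` frames, mimicking the cardiac cycle), a smooth linear
#' spatial phase ramp standing in for coil/off-resonance phase, and optional
#' complex Gaussian noise. Magnitudes are normalized to peak 1.
#'
#' Defaults are the desk-scale study conditions used throughout the package:
#' 32 x 32 frames, 8 time points, 4 shapes, 15% radial pulsation (about the
#' fractional wall motion of a beating heart), and complex noise of scale
#' 0.01 on unit-magnitude images.
#'
#' @param frames,h,w grid sizes; `frames >= 2`, `h`, `w` even.
#' @param n_shapes number of ellipses (>= 1).
#' @param pulse_amp fractional radius modulation in `[0, 0.5)`.
#' @param noise_sd complex Gaussian noise scale (>= 0), applied before the
#'   final normalization.
#' @param seed integer seed; generation is deterministic given the seed.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(frames = 8L, h = 32L, w = 32L, n_shapes = 4L,
                           pulse_amp = 0.15, noise_sd = 0.01, seed = 1L) {
  stopifnot(frames >= 2, h >= 4, w >= 4, h %% 2 == 0, w %% 2 == 0,
            n_shapes >= 1, pulse_amp >= 0, pulse_amp < 0.5, noise_sd >= 0)
  structure(list(frames = as.integer(frames), h = as.integer(h),
                 w = as.integer(w), n_shapes = as.integer(n_shapes),
                 pulse_amp = pulse_amp, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Generate a synthetic dynamic cine phantom
#'
#' Renders `cfg$n_shapes` ellipses with per-shape intensity in (0, 1],
#' centres and radii drawn once per sequence, and radii modulated over time
#' as `r_j(t) = r_j * (1 + pulse_amp * sin(2*pi*t/T + phi_j))` (t 0-based,
#' one full period across the sequence). Edges are anti-aliased with a
#' smooth ~1.5-pixel coverage ramp so that reconstruction errors vary
#' smoothly under small deformations. The summed magnitude image is
#' multiplied by a linear phase ramp `exp(i*(a*row + b*col))` whose total
#' excursion across the field of view is at most half a cycle per axis
#' (the residual smooth phase left after coil combination), complex
#' Gaussian noise of scale `noise_sd` is added, and the sequence is
#' normalized to peak magnitude 1.
#'
#' @param cfg a [phantom_config()].
#' @return complex array `h x w x frames`, peak magnitude 1.
#' @export
generate_cine_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  h <- cfg$h; w <- cfg$w; tt <- cfg$frames
  out <- with_seed(cfg$seed, {
    ns <- cfg$n_shapes
    # shape 1 is a large slowly modulated "torso"; the rest are inner shapes
    cx <- runif(ns, 0.3 * w, 0.7 * w)
    cy <- runif(ns, 0.3 * h, 0.7 * h)
    rx <- runif(ns, 0.10, 0.22) * w
    ry <- runif(ns, 0.10, 0.22) * h
    rx[1] <- 0.42 * w; ry[1] <- 0.42 * h; cx[1] <- w / 2 + 0.5; cy[1] <- h / 2 + 0.5
    ang <- runif(ns, 0, pi)
    inten <- runif(ns, 0.4, 1)
    phase_j <- runif(ns, 0, 2 * pi)
    # residual background phase after coil combination: a smooth ramp whose
    # total excursion across the field of view is at most one half-cycle
    # per axis, independent of grid size
    a <- runif(1, -pi, pi) / h
    b <- runif(1, -pi, pi) / w
    row_ix <- matrix(seq_len(h), h, w)
    col_ix <- matrix(seq_len(w), h, w, byrow = TRUE)
    x <- array(0i, c(h, w, tt))
    for (t in seq_len(tt)) {
      mod_t <- 1 + cfg$pulse_amp * sin(2 * pi * (t - 1) / tt + phase_j)
      frame <- matrix(0, h, w)
      for (j in seq_len(ns)) {
        dx <- col_ix - cx[j]; dy <- row_ix - cy[j]
        u <- (dx * cos(ang[j]) + dy * sin(ang[j])) / (rx[j] * mod_t[j])
        v <- (-dx * sin(ang[j]) + dy * cos(ang[j])) / (ry[j] * mod_t[j])
        dist <- sqrt(u^2 + v^2)                       # normalized radius
        edge <- 1.5 / min(rx[j], ry[j])               # ~1.5 px soft edge
        cov <- pmin(1, pmax(0, (1 - dist) / edge + 0.5))
        frame <- frame + inten[j] * cov
      }
      ph <- exp(1i * (a * row_ix + b * col_ix))
      noise <- if (cfg$noise_sd > 0)
        (rnorm(h * w) + 1i * rnorm(h * w)) * cfg$noise_sd else 0
      x[, , t] <- frame * ph + noise
    }
    x
  })
  normalize_sequence(out)
}

#' Build a synthetic training/validation/test dataset
#'
#' Generates `n_train + n_val + n_test` phantom sequences from independent
#' sub-seeds, computes their k-space, draws an acquisition mask per sequence,
#' partitions it into the two training masks, and stores everything in a
#' self-describing container. The partition is fixed at construction time
#' (not resampled during training).
#'
#' @param n_train,n_val,n_test sequence counts (>= 1).
#' @param cfg a [phantom_config()] template (its `seed` is ignored; per-
#'   sequence seeds derive from `seed`).
#' @param af,n_acs acquisition mask parameters, see
#'   [generate_cartesian_mask()].
#' @param seed top-level seed.
#' @param path optional file path; if given, the dataset is written with
#'   [write_dataset()].
#' @return a `recon_dataset`: list with elements `train`, `val`, `test`
#'   (lists of sequences, each `list(image, kspace, masks)` where `masks` is
#'   a `mask_triple`) and `config`.
#' @export
make_fixture_dataset <- function(n_train, n_val, n_test, cfg = phantom_config(),
                                 af = 4, n_acs = 4L, seed = 1L, path = NULL) {
  stopifnot(n_train >= 1, n_val >= 1, n_test >= 1,
            inherits(cfg, "phantom_config"))
  counts <- c(train = n_train, val = n_val, test = n_test)
  ds <- list(config = list(phantom = unclass(cfg), af = af, n_acs = n_acs,
                           seed = as.integer(seed)))
  i <- 0L
  for (split in names(counts)) {
    ds[[split]] <- vector("list", counts[[split]])
    for (s in seq_len(counts[[split]])) {
      i <- i + 1L
      cfg_i <- cfg
      cfg_i$seed <- sub_seed(seed, paste0("phantom-", i))
      img <- generate_cine_phantom(cfg_i)
      ksp <- fft2c(img)
      omega <- generate_cartesian_mask(cfg$frames, cfg$h, cfg$w, af, n_acs,
                                       seed = sub_seed(seed, paste0("mask-", i)))
      masks <- partition_mask(omega, seed = sub_seed(seed, paste0("partition-", i)))
      ds[[split]][[s]] <- list(image = img, kspace = ksp, masks = masks,
                               seed = cfg_i$seed)
    }
  }
  ds <- structure(ds[c("train", "val", "test", "config")], class = "recon_dataset")
  if (!is.null(path)) write_dataset(ds, path)
  ds
}
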