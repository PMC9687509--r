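#' Write and read reconstruction datasets
#'
#' Datasets are stored as a single self-describing RDS container holding the
#' `train`/`val`/`test` groups; each sequence carries the fully sampled
#' complex image, its k-space, and the acquisition/theta/lambda masks, with
#' the generating configuration and all seeds as attributes — enough
#' metadata to regenerate the file exactly. On read, every sequence is
#' validated: array shapes must agree, masks must have Cartesian line
#' structure, and the mask triple must satisfy the union / difference / ACS
#' principles; violations raise an error naming the offending entry.
#'
#' @param ds a `recon_dataset`.
#' @param path file path.
#' @return `read_dataset()` returns the validated `recon_dataset`.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "recon_dataset"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  saveRDS(ds, path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ds <- readRDS(path)
  if (!inherits(ds, "recon_dataset")) stop("not a recon_dataset file: ", path)
  for (split in c("train", "val", "test")) {
    for (i in seq_along(ds[[split]])) {
      sq <- ds[[split]][[i]]
      key <- paste0("/", split, "/", i)
      if (is.null(sq$kspace)) stop("missing kspace at ", key)
      if (!is.null(sq$image) && !identical(dim(sq$image), dim(sq$kspace)))
        stop("image/kspace shape mismatch at ", key)
      if (is.null(sq$masks)) {
        ds[[split]][[i]]$masks_absent <- TRUE
        next
      }
      for (mk in c("omega", "theta", "lambda"))
        check_cartesian(sq$masks[[mk]], paste0(key, "/mask_", mk))
      validate_mask_triple(sq$masks)
    }
  }
  ds
}

#' Save or load a fitted model checkpoint
#'
#' The checkpoint embeds the backbone and loss configuration, both parameter
#' sets, the Adam optimizer state, the step counter and the seed, so
#' training resumed from it reproduces the continuation of the original run
#' exactly.
#'
#' @param fit a `colearn_fit`.
#' @param path file path.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "colearn_fit"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  fit <- readRDS(path)
  if (!inherits(fit, "colearn_fit")) stop("not a checkpoint file: ", path)
  fit
}

# Run manifest: configuration + seeds + package version + input digests,
# written next to every CLI output artifact.
write_manifest <- function(path, config, seed, inputs = character()) {
  digests <- vapply(inputs, function(f)
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_,
    character(1))
  jsonlite::write_json(list(
    package = "dynrecon",
    version = as.character(utils::packageVersion("dynrecon")),
    seed = seed, config = config,
    inputs = as.list(digests),
    timestamp = format(Sys.time(), tz = "UTC")
  ), path, auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' A flat human-readable mapping mirroring the arguments of
#' [colearn_fit()], [phantom_config()] and the mask generator; unknown keys
#' are rejected.
#'
#' @param path YAML file path.
#' @return a named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("strategy", "steps", "lr", "beta1", "beta2", "gamma",
             "uc_domain", "cc_domain", "n_iters", "n_filters", "kernel",
             "n_crnn_layers", "backbone", "dc_mode", "dc_lambda", "seed",
             "af", "n_acs", "frames", "h", "w", "n_shapes", "pulse_amp",
             "noise_sd", "val_every", "n_train", "n_val", "n_test")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg
}
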