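# Experiment configuration: JSON schema with strict key validation,
# defaults, seed derivation, resolved-config echo and output manifests.
# The command-line entry point (inst/cli/anaa.R) is a thin wrapper over
# these functions and the exported module functions.

configDefaults <- function() {
  list(
    data = list(preset = "mimic_like", path = NULL, n_patients = 1000L,
                overrides = list()),
    tokenization = list(min_count = 5L, max_len = 256L, min_visits = 1L,
                        target_codes = list("I500"),
                        excluded_codes = list()),
    model = list(d_model = 64L, n_heads = 4L, n_layers = 2L,
                 max_len = 256L, dropout = 0),
    augmentation = list(mode = "ANAA", sigma_eh = 1.0,
                        kernel_normalized = TRUE,
                        variance_denominator = "elements_minus_one"),
    train = list(lr = 5e-4, pretrain_lr = 1e-3, batch_size = 32L,
                 max_epochs = 20L, pretrain_epochs = 10L, patience = 5L,
                 mlm_prob = 0.15,
                 subsample_fractions = list(1, 0.5, 0.2, 0.1)),
    split = list(fractions = list(0.7, 0.2, 0.1), k_folds = 5L),
    output_dir = "anaa-output",
    seed = 1L)
}

#' Read and validate an experiment configuration
#'
#' JSON file with blocks data / tokenization / model / augmentation /
#' train / split plus output_dir and seed. Unknown keys at any level are
#' rejected; missing keys take documented defaults. The resolved
#' configuration should be echoed into the output directory with
#' \code{\link{writeResolvedConfig}}.
#'
#' @param path JSON config path, or NULL for pure defaults.
#' @param overrides named list of dot-path overrides (e.g.
#'   \code{list("augmentation.sigma_eh" = 0.33)}).
#' @return resolved configuration list.
#' @export
readExperimentConfig <- function(path = NULL, overrides = list()) {
  cfg <- configDefaults()
  if (!is.null(path)) {
    user <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    cfg <- mergeConfig(cfg, user, "")
  }
  for (nm in names(overrides)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    cfg <- setPath(cfg, parts, overrides[[nm]])
  }
  cfg
}

mergeConfig <- function(base, user, prefix) {
  bad <- setdiff(names(user), names(base))
  if (length(bad))
    stop("unknown config key(s): ",
         paste0(prefix, bad, collapse = ", "))
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]])) &&
        is.list(user[[nm]])) {
      base[[nm]] <- mergeConfig(base[[nm]], user[[nm]],
                                paste0(prefix, nm, "."))
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

setPath <- function(cfg, parts, value) {
  if (length(parts) == 1L) {
    if (!parts %in% names(cfg)) stop("unknown config key: ", parts)
    cfg[[parts]] <- value
    return(cfg)
  }
  if (!parts[1] %in% names(cfg)) stop("unknown config key: ", parts[1])
  cfg[[parts[1]]] <- setPath(cfg[[parts[1]]], parts[-1], value)
  cfg
}

#' Write the resolved configuration into an output directory
#'
#' @param cfg resolved configuration list.
#' @param dir output directory (created if needed).
#' @return invisibly, the config file path.
#' @export
writeResolvedConfig <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, "resolved-config.json")
  jsonlite::write_json(cfg, p, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(p)
}

# FNV-1a over a file's bytes (no hashing package in the stack).
fileHash <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  h <- 2166136261
  for (i in seq(1L, length(bytes), by = max(1L, length(bytes) %/% 4096L))) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(bytes[i]))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("fnv1a-%08x-%d", as.integer(h), length(bytes))
}

#' Write a content manifest for an output directory
#'
#' Records package version and a content hash per file, making re-runs
#' comparable.
#'
#' @param dir output directory.
#' @return invisibly, the manifest path.
#' @export
writeManifest <- function(dir) {
  files <- setdiff(list.files(dir, recursive = TRUE), "manifest.json")
  entries <- lapply(files, function(f) fileHash(file.path(dir, f)))
  names(entries) <- files
  p <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(package_version = "0.1.0", files = entries),
                       p, auto_unbox = TRUE, pretty = TRUE)
  invisible(p)
}

#' Sigma-sweep utility
#'
#' Builds the smoothing kernel for each event-horizon value and reports
#' the induced kernel size; used by the CLI sweep and as a quick check of
#' the kernel-size rule before committing to a full run.
#'
#' @param sigmas numeric vector of event-horizon values.
#' @return data.frame(sigma_eh, kernel_size).
#' @export
sweepSigma <- function(sigmas) {
  data.frame(sigma_eh = sigmas,
             kernel_size = vapply(sigmas, function(s)
               kernelSize(buildKernel(s)), integer(1)))
}
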