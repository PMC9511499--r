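#' Pipeline configuration
#'
#' A pipeline config is a named list in a fixed key vocabulary.  Defaults
#' encode the analysis conventions used throughout the package: the
#' RB-ratio arrest threshold (0.7 on the peak-normalized phospho/total-RB
#' scale), the 15-cell minimum per pseudotime bin, 50 pseudotime bins, and
#' the embedding parameter set knn = 150, t = 20, gamma = 1 with kernel
#' decay exponent 40.
#'
#' @return A named list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(
    list(
      feature_list = NULL,          # embedding features; NULL = all features
      phase_features = phase_feature_names(),
      rb_threshold = 0.7,           # cycling iff normalized RB ratio >= this
      rb_feature = "rb_ratio_nucleus_ratio",
      dna_feature = "dna_nucleus_integrated",
      min_cells_per_bin = 15,
      n_bins = 50,
      knn = 150,
      t = 20,
      gamma = 1,
      decay_alpha = 40,
      stages = c("normalize", "phases", "embed", "pseudotime"),
      seed = NULL
    ),
    class = "pipeline_config"
  )
}

.stochastic_stages <- c("simulate", "phases", "embed")

#' Load and resolve a pipeline configuration
#'
#' Reads a YAML config file, checks every key against the documented
#' vocabulary (unknown keys are an error, never silently ignored), fills
#' defaults, and requires a seed whenever any stochastic stage is enabled.
#' Resolution is idempotent: resolving an already-resolved config returns
#' the same object.
#'
#' @param path Path to a YAML config file, or a named list already in
#'   memory.
#' @return A fully resolved `pipeline_config`.
#' @export
load_config <- function(path) {
  user <- if (is.character(path)) {
    if (!file.exists(path)) am_abort(paste0("Config not found: ", path), "arrestmap_io_error")
    yaml::read_yaml(path)
  } else if (is.list(path)) {
    unclass(path)
  } else {
    am_abort("Config must be a file path or a named list.", "arrestmap_config_error")
  }
  defaults <- default_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    am_abort(
      paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")),
      "arrestmap_config_error"
    )
  }
  cfg <- utils::modifyList(unclass(defaults), user, keep.null = TRUE)
  if (any(cfg$stages %in% .stochastic_stages) && is.null(cfg$seed)) {
    am_abort(
      "Config enables stochastic stage(s) but has no seed.",
      "arrestmap_config_error"
    )
  }
  structure(cfg, class = "pipeline_config")
}

#' Write a plain-text run manifest
#'
#' Echoes the fully resolved configuration (including the seed) to a log
#' file so a run can be reproduced from its manifest alone.
#'
#' @param config A resolved `pipeline_config`.
#' @param path Output path for the manifest.
#' @param append Append to an existing manifest?
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(config, path, append = FALSE) {
  lines <- c(
    paste0("# arrestmap run manifest ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    vapply(names(config), function(k) {
      v <- config[[k]]
      paste0(k, ": ", if (is.null(v)) "~" else paste(v, collapse = ", "))
    }, character(1))
  )
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
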