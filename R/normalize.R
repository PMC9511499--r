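#' Matched-control normalization and bimodal peak normalization
#'
#' The data-integration scheme: every feature of every cell is z-scored
#' with the mean and (sample) standard deviation of its matched control
#' condition, which preserves the relative fold-changes induced by
#' treatment.  Bimodal features destined for the embedding are instead
#' peak normalized: an affine map placing their two density modes at fixed
#' targets (DNA content 2C/4C to 2 and 4; phospho-RB and phospho/total-RB
#' hypo-/hyper-phosphorylation modes to 0 and 1).
#'
#' @name normalization
NULL

#' Fit per-feature control statistics
#'
#' Computes the control-condition mean and sample standard deviation for
#' each feature.  Features with zero control variance are reported and
#' excluded from normalization.  Missing values never enter the fits.
#'
#' @param table A feature table.
#' @param control_condition Condition label of the matched control.
#' @param features Features to fit; default all.
#' @return A `norm_params` tibble with columns `feature`, `mu`, `sigma`,
#'   `n`, `excluded`.
#' @export
fit_control_stats <- function(table, control_condition = "control",
                              features = NULL) {
  validate_feature_table(table)
  if (is.null(features)) features <- feature_names(table)
  ctrl <- table[table$condition == control_condition, , drop = FALSE]
  if (nrow(ctrl) == 0) {
    am_abort(paste0("No cells carry control condition '", control_condition, "'."),
             "arrestmap_config_error")
  }
  params <- purrr::map_dfr(features, function(f) {
    x <- ctrl[[f]][!is.na(ctrl[[f]])]
    if (length(x) < 2) {
      am_abort(paste0("Fewer than 2 non-missing control values for feature ", f),
               "arrestmap_config_error")
    }
    tibble::tibble(feature = f, mu = mean(x), sigma = sd(x), n = length(x))
  })
  params$excluded <- params$sigma == 0
  if (any(params$excluded)) {
    rlang::warn(paste0("Constant control feature(s) excluded from normalization: ",
                       paste(params$feature[params$excluded], collapse = ", ")))
  }
  structure(params,
            class = c("norm_params", class(params)),
            control_condition = control_condition)
}

#' Apply matched-control z-normalization
#'
#' Every cell's value becomes `(x - mu_ctrl) / sigma_ctrl` using the
#' control statistics regardless of the cell's own condition, so treatment
#' fold-changes are preserved on the z scale.  Missing values propagate as
#' missing.
#'
#' @param table A feature table.
#' @param params A `norm_params` object from [fit_control_stats()].
#' @param features Features to normalize; default all non-excluded
#'   features in `params` present in the table.
#' @return The table with normalized feature columns.
#' @export
apply_matched_normalization <- function(table, params, features = NULL) {
  stopifnot(inherits(params, "norm_params"))
  if (is.null(features)) {
    features <- intersect(params$feature[!params$excluded], feature_names(table))
  }
  missing_p <- setdiff(features, params$feature)
  if (length(missing_p) > 0) {
    am_abort(paste0("Feature(s) missing from normalization params: ",
                    paste(missing_p, collapse = ", ")),
             "arrestmap_config_error")
  }
  for (f in features) {
    row <- params[params$feature == f, ]
    if (row$excluded) next
    table[[f]] <- (table[[f]] - row$mu) / row$sigma
  }
  table
}

# half-sample mode (Bickel/Fruehwirth): recursively keep the half-width
# sub-sample containing the most points
.half_sample_mode <- function(x) {
  x <- sort(x)
  while (length(x) > 3) {
    n <- length(x)
    h <- ceiling(n / 2)
    widths <- x[h:n] - x[1:(n - h + 1)]
    i <- which.min(widths)
    x <- x[i:(i + h - 1)]
  }
  mean(x)
}

# mode locations of a sample by local maxima of a Gaussian KDE
# (Silverman/nrd0 bandwidth)
.kde_modes <- function(x, n_grid = 512) {
  den <- density(x, bw = "nrd0", n = n_grid)
  y <- den$y
  i <- which(y > c(-Inf, y[-length(y)]) & y >= c(y[-1], -Inf))
  tibble::tibble(location = den$x[i], height = y[i])
}

#' Detect the two dominant modes of a bimodal sample
#'
#' Finds density modes by Gaussian kernel density estimation (Silverman
#' bandwidth), keeps the two with the greatest prominence separated by at
#' least `min_separation` of the data range, then refines each mode
#' location with a per-component KDE (the sample split at the antimode,
#' each half with its own bandwidth) -- a single global bandwidth on a
#' bimodal sample is dominated by the between-mode spread and biases the
#' mode locations.
#'
#' @param values Numeric vector, at least 100 finite values.
#' @param min_prominence Minimum minor/major mode height ratio below which
#'   the sample is declared unimodal (an explicit error, never a silent
#'   guess).
#' @param min_separation Minimum mode separation as a fraction of the data
#'   range.
#' @return Named numeric `c(lo_peak, hi_peak)` with attribute
#'   `height_ratio` (minor/major mode height diagnostic).
#' @export
detect_bimodal_peaks <- function(values, min_prominence = 0.1,
                                 min_separation = 0.2) {
  x <- values[is.finite(values)]
  if (length(x) < 100) {
    am_abort("At least 100 finite values required for peak detection.",
             "arrestmap_config_error")
  }
  modes <- .kde_modes(x)
  if (nrow(modes) < 2) {
    am_abort("Sample is unimodal: a single density mode was found.",
             "arrestmap_unimodal_error")
  }
  major <- modes[which.max(modes$height), ]
  # robust data range: raw min/max are dominated by stray polyploid /
  # high-intensity tails in skewed intensity data
  rng <- diff(unname(quantile(x, c(0.01, 0.99))))
  cand <- modes[abs(modes$location - major$location) >= min_separation * rng, ]
  if (nrow(cand) == 0 || max(cand$height) / major$height < min_prominence) {
    am_abort("Sample is unimodal: no second mode with sufficient prominence/separation.",
             "arrestmap_unimodal_error")
  }
  minor <- cand[which.max(cand$height), ]
  ratio <- minor$height / major$height

  # refine each mode with its own bandwidth, splitting at the antimode
  lo0 <- min(major$location, minor$location)
  hi0 <- max(major$location, minor$location)
  den <- density(x, bw = "nrd0", n = 512)
  between <- den$x > lo0 & den$x < hi0
  split <- den$x[between][which.min(den$y[between])]
  refine <- function(xs, peak0) {
    # trim to a window around the first-pass peak, then use the half-sample
    # mode: robust to a one-sided shoulder (e.g. an S-phase continuum
    # abutting the 4C peak) that drags a kernel-density mode
    w <- 0.25 * (hi0 - lo0)
    xs <- xs[abs(xs - peak0) <= w]
    if (length(xs) < 10) return(peak0)
    .half_sample_mode(xs)
  }
  lo <- refine(x[x <= split], lo0)
  hi <- refine(x[x > split], hi0)
  structure(c(lo_peak = lo, hi_peak = hi), height_ratio = ratio)
}

#' Affine peak normalization
#'
#' Maps a feature so that its two density-mode anchors land exactly on the
#' targets: `v' = lo_target + (v - lo_peak) (hi_target - lo_target) /
#' (hi_peak - lo_peak)`.  Strictly increasing, hence invertible by
#' swapping anchors and targets.
#'
#' @param values Numeric vector.
#' @param lo_peak,hi_peak Raw anchor locations (`hi_peak > lo_peak`).
#' @param lo_target,hi_target Target locations (`hi_target > lo_target`).
#' @return Normalized vector.
#' @export
peak_normalize <- function(values, lo_peak, hi_peak, lo_target, hi_target) {
  if (hi_peak <= lo_peak) {
    am_abort("hi_peak must exceed lo_peak.", "arrestmap_config_error")
  }
  if (hi_target <= lo_target) {
    am_abort("hi_target must exceed lo_target.", "arrestmap_config_error")
  }
  lo_target + (values - lo_peak) * (hi_target - lo_target) / (hi_peak - lo_peak)
}

#' Full integration normalization of a feature table
#'
#' Convenience composition: bimodal features are peak normalized (modes
#' detected on the pooled sample, mapped to their stated targets); all
#' other features are matched-control z-normalized.
#'
#' @param table A feature table.
#' @param control_condition Matched control label.
#' @param bimodal Named list `feature -> c(lo_target, hi_target)`; default
#'   DNA content to (2, 4) and the phospho/total-RB ratio to (0, 1).
#' @return List with `table` (normalized) and `params` (the `norm_params`
#'   with a `bimodal` attribute recording detected peaks and targets).
#' @export
normalize_table <- function(table, control_condition = "control",
                            bimodal = list(dna_nucleus_integrated = c(2, 4),
                                           rb_ratio_nucleus_ratio = c(0, 1))) {
  feats <- feature_names(table)
  bimodal <- bimodal[intersect(names(bimodal), feats)]
  zfeats <- setdiff(feats, names(bimodal))
  params <- fit_control_stats(table, control_condition, zfeats)
  out <- apply_matched_normalization(table, params)
  peak_info <- purrr::imap_dfr(bimodal, function(targets, f) {
    pk <- detect_bimodal_peaks(out[[f]])
    out[[f]] <<- peak_normalize(out[[f]], pk[["lo_peak"]], pk[["hi_peak"]],
                                targets[1], targets[2])
    tibble::tibble(feature = f, lo_peak = pk[["lo_peak"]], hi_peak = pk[["hi_peak"]],
                   lo_target = targets[1], hi_target = targets[2])
  })
  attr(params, "bimodal") <- peak_info
  list(table = out, params = params)
}

#' @export
tidy.norm_params <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
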