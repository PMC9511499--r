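#' Population simulation configuration
#'
#' Conditions of the simulated 4i experiment.  The default state mix
#' mirrors the reported arrest architecture: a 56:44 split between the 4C
#' (G2-exit) and 2C (post-mitotic) replication-stress trajectories, a small
#' senescent / mitotic-skipping compartment, and ~2% endoreduplicated 8C
#' cells; the raw 4C DNA intensity is twice the 2C intensity.
#'
#' @param n_cells Number of cells to simulate.
#' @param state_mix Named proportions over the eight state labels; must sum
#'   to 1.
#' @param raw_2c,raw_4c Raw DNA-content intensities (arbitrary units) of
#'   the 2C and 4C histogram peaks; `raw_4c` must be twice `raw_2c` within
#'   `ploidy_tol`.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal measurement noise (0 = noiseless).  Ratio-statistic
#'   features use `noise_cv / 2` (shared illumination and size fluctuations
#'   cancel in a ratio).
#' @param ploidy_tol Relative tolerance for the `raw_4c == 2 * raw_2c`
#'   invariant.
#' @param depth_range Range the arrest depth `s` is drawn from (uniform).
#'   The default `c(0, 1)` emulates a snapshot with cells at every stage
#'   of arrest; a raised lower bound (e.g. `c(0.1, 1)`) emulates a
#'   population treated long enough ago that every arrested cell has
#'   committed to its trajectory.
#' @param seed Integer seed.
#' @return A list of class `population_sim_config`.
#' @export
population_sim_config <- function(n_cells = 5000,
                                  state_mix = c(cycling = 0.40,
                                                spontaneous_G0 = 0.05,
                                                hypomitogenic_G0 = 0.10,
                                                repstress_G0_2C = 0.154,
                                                repstress_G0_4C = 0.196,
                                                mitotic_skip = 0.04,
                                                senescent = 0.04,
                                                endoreduplicated_8C = 0.02),
                                  raw_2c = 100, raw_4c = 200,
                                  noise_cv = 0.15, ploidy_tol = 0.05,
                                  depth_range = c(0, 1),
                                  seed = 1L) {
  allowed <- c("cycling", names(.arrest_states))
  if (length(setdiff(names(state_mix), allowed)) > 0) {
    am_abort(paste0("Unknown state(s) in state_mix: ",
                    paste(setdiff(names(state_mix), allowed), collapse = ", ")),
             "arrestmap_config_error")
  }
  if (abs(sum(state_mix) - 1) > 1e-8) {
    am_abort("state_mix proportions must sum to 1.", "arrestmap_config_error")
  }
  if (noise_cv < 0) am_abort("noise_cv must be >= 0.", "arrestmap_config_error")
  if (abs(raw_4c - 2 * raw_2c) > ploidy_tol * 2 * raw_2c) {
    am_abort("raw_4c must be ~2 x raw_2c (DNA-content doubling).",
             "arrestmap_config_error")
  }
  if (length(depth_range) != 2 || depth_range[1] < 0 || depth_range[2] > 1 ||
      diff(depth_range) <= 0) {
    am_abort("depth_range must be an increasing sub-interval of [0, 1].",
             "arrestmap_config_error")
  }
  structure(
    list(n_cells = n_cells, state_mix = state_mix, raw_2c = raw_2c,
         raw_4c = raw_4c, noise_cv = noise_cv, depth_range = depth_range,
         seed = as.integer(seed)),
    class = "population_sim_config"
  )
}

# median-anchored log-normal noise: the median of the noisy feature equals
# the mean function, and the kernel-density peak of a flat-mean population
# stays within a couple of percent of it (the analytic mode sits slightly
# below, smoothing pulls slightly toward the mean).  cv = 0 returns the
# means unchanged.
.lognoise <- function(m, cv, n) {
  if (cv == 0) return(m)
  sigma <- sqrt(log(1 + cv^2))
  m * exp(sigma * rnorm(n))
}

#' Simulate a 4i single-cell population on the arrest manifold
#'
#' Draws cells from the configured state mix; cycling cells get a uniform
#' latent cycle position `theta` (ground-truth G1/S/G2/M phase from the
#' phase boundaries), arrested cells a uniform arrest depth `s` along
#' their branch.  Feature values are the marker-dynamics means under
#' multiplicative log-normal noise; DNA content is expressed in raw
#' intensity units (`raw_2c` at 2C).  Ground truth (`phase`,
#' `arrest_state`, `latent_pseudotime`, `ploidy`) is exported alongside.
#'
#' @param config A [population_sim_config()].
#' @param dynamics A marker-dynamics specification
#'   ([default_marker_dynamics()]).
#' @return A feature table tibble with ground-truth columns.
#' @export
simulate_population <- function(config = population_sim_config(),
                                dynamics = default_marker_dynamics()) {
  stopifnot(inherits(config, "population_sim_config"))
  set.seed(config$seed)
  n <- config$n_cells
  states <- sample(names(config$state_mix), n, replace = TRUE,
                   prob = config$state_mix)
  depth <- runif(n)            # theta for cyclers, arrest depth s otherwise
  arr <- states != "cycling"   # arrest depth drawn from the configured range
  depth[arr] <- config$depth_range[1] + depth[arr] * diff(config$depth_range)
  feats <- colnames(dynamics$cycling(0.5))

  means <- matrix(NA_real_, n, length(feats), dimnames = list(NULL, feats))
  is_cyc <- states == "cycling"
  if (any(is_cyc)) means[is_cyc, ] <- dynamics$cycling(depth[is_cyc])
  for (st in intersect(unique(states), names(dynamics$arrest))) {
    idx <- which(states == st)
    def <- dynamics$arrest[[st]]
    anchor <- .branch_anchor(st, dynamics)
    term <- .branch_terminal(st, dynamics)
    if (isTRUE(def$dna_constant)) {
      anchor["dna_nucleus_integrated"] <- term["dna_nucleus_integrated"]
    }
    s <- depth[idx]
    # per-feature progress: immediate-early features (and, for branches
    # flagged `early_global`, every feature) follow the saturating curve
    is_early <- feats %in% dynamics$early_features
    if (isTRUE(def$early_global)) is_early <- rep(TRUE, length(feats))
    u <- matrix(s, length(idx), length(feats))
    u[, is_early] <- dynamics$early_curve(s)
    means[idx, ] <- matrix(anchor[feats], length(idx), length(feats), byrow = TRUE) +
      u * matrix(term[feats] - anchor[feats], length(idx), length(feats), byrow = TRUE)
  }

  # phospho/total RB: hyperphosphorylated mode for cyclers, abrupt drop on
  # every arrest branch
  rb <- ifelse(is_cyc, dynamics$rb_cycling, dynamics$rb_arrest(depth))
  means <- cbind(means, rb_ratio_nucleus_ratio = rb)

  # C-units -> raw intensity units
  means[, "dna_nucleus_integrated"] <-
    means[, "dna_nucleus_integrated"] * config$raw_2c / 2

  values <- means
  for (f in colnames(values)) {
    cv <- if (f %in% dynamics$low_cv_features) config$noise_cv / 2 else config$noise_cv
    values[, f] <- .lognoise(values[, f], cv, n)
  }

  phase <- rep("G0", n)
  if (any(is_cyc)) {
    br <- dynamics$phase_breaks
    phase[is_cyc] <- as.character(
      cut(depth[is_cyc], breaks = c(br, 1), labels = names(br), right = FALSE)
    )
  }
  ploidy <- vapply(seq_len(n), function(i) {
    if (is_cyc[i]) {
      dna_c <- 2 * means[i, "dna_nucleus_integrated"] / config$raw_2c
      if (dna_c < 3) "2C" else "4C"
    } else {
      dynamics$arrest[[states[i]]]$ploidy
    }
  }, character(1))
  condition <- dplyr::case_match(
    states,
    c("cycling", "spontaneous_G0") ~ "control",
    "hypomitogenic_G0" ~ "serum_starved_d7",
    .default = "etoposide_d3"
  )

  out <- tibble::tibble(
    cell_id = sprintf("c%05d", seq_len(n)),
    condition = condition,
    replicate = "r1",
    phase = phase,
    arrest_state = states,
    latent_pseudotime = depth,
    ploidy = ploidy
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(values))
  validate_feature_table(out)
  out
}
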