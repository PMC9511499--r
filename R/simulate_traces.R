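#' Trace simulation configuration
#'
#' Time-lapse biosensor traces are sampled every 10 minutes (the imaging
#' interval of the live-cell experiments).  The default fate mix mirrors
#' the observed replication-stress bifurcation: among arrested cells,
#' 56% exit in G2 (4C trajectory, including the ~5% that later
#' endoreduplicate) and 44% complete mitosis and arrest post-mitotically.
#'
#' @param n_traces Number of traces.
#' @param frame_interval_min Frame interval in minutes (> 0).
#' @param duration_h Trace duration in hours.  When endoreduplication is in
#'   the mix, must be at least `max(dwell_range_h)` plus one cell cycle
#'   (24 h).
#' @param fate_mix Named proportions over `proliferative`, `G2_arrest_4C`,
#'   `postmitotic_arrest_2C`, `endoreduplication`; must sum to 1.
#' @param dwell_range_h Arrest dwell (hours) sampled uniformly for
#'   endoreduplicating cells before cell-cycle re-entry; default 15-30 h.
#' @param noise Per-channel noise: additive Gaussian sd for `cdk2`, `p21`,
#'   `dna`; `foci_lambda` is the background PCNA-foci Poisson rate outside
#'   S phase (0 = noiseless counts).
#' @param seed Integer seed.
#' @return A list of class `trace_sim_config`.
#' @export
trace_sim_config <- function(n_traces = 500,
                             frame_interval_min = 10,
                             duration_h = 72,
                             fate_mix = c(proliferative = 0.05,
                                          G2_arrest_4C = 0.482,
                                          postmitotic_arrest_2C = 0.418,
                                          endoreduplication = 0.05),
                             dwell_range_h = c(15, 30),
                             noise = list(cdk2 = 0.03, p21 = 8, dna = 0.08,
                                          foci_lambda = 0.2),
                             seed = 1L) {
  fates <- c("proliferative", "G2_arrest_4C", "postmitotic_arrest_2C",
             "endoreduplication")
  if (length(setdiff(names(fate_mix), fates)) > 0) {
    am_abort("Unknown fate label(s) in fate_mix.", "arrestmap_config_error")
  }
  if (abs(sum(fate_mix) - 1) > 1e-8) {
    am_abort("fate_mix proportions must sum to 1.", "arrestmap_config_error")
  }
  if (frame_interval_min <= 0) {
    am_abort("frame_interval_min must be > 0.", "arrestmap_config_error")
  }
  endo_p <- if ("endoreduplication" %in% names(fate_mix)) fate_mix[["endoreduplication"]] else 0
  if (endo_p > 0 && duration_h < max(dwell_range_h) + 24) {
    am_abort("duration_h must be at least max dwell + one cell cycle (24 h).",
             "arrestmap_config_error")
  }
  structure(
    list(n_traces = n_traces, frame_interval_min = frame_interval_min,
         duration_h = duration_h, fate_mix = fate_mix,
         dwell_range_h = dwell_range_h, noise = noise, seed = as.integer(seed)),
    class = "trace_sim_config"
  )
}

# deterministic archetype for one fate; t in hours.  Returns channel list +
# ground-truth events.  Cycle model: G1 0-9 h, S 9-17 h, G2 17-23 h,
# M 23-24 h; CDK2 rises 0.45 -> 1.35 across the cycle and resets at
# division; the DNA proxy doubles across S and halves in one frame at
# mitosis; PCNA foci (count 20) mark S.
.trace_archetype <- function(fate, t, dwell) {
  n <- length(t)
  cdk2 <- numeric(n); dna <- numeric(n); inS <- logical(n)
  p21 <- rep(5, n)
  mitoses <- numeric(0); s_int <- NULL
  cyc_len <- 24
  # p21 induction is fast (crosses its detection level within ~1 frame of
  # arrest onset, matching the simultaneity seen in live cells)
  p21_ramp <- function(t0) pmin(pmax((t - t0) / 1, 0), 1) * 295 + 5

  prolif_until <- function(t_stop) {
    seg <- t < t_stop
    tc <- t %% cyc_len
    cdk2[seg] <<- 0.45 + 0.9 * tc[seg] / cyc_len
    dna[seg] <<- ifelse(tc[seg] < 9, 2,
                        ifelse(tc[seg] < 17, 2 + 2 * (tc[seg] - 9) / 8, 4))
    inS[seg] <<- tc[seg] >= 9 & tc[seg] < 17
    cycles <- seq(cyc_len, max(t) + cyc_len, by = cyc_len)
    mitoses <<- cycles[cycles <= max(t) & cycles < t_stop]
    starts <- seq(9, max(t) + cyc_len, by = cyc_len)
    starts <- starts[starts < t_stop & starts <= max(t)]
    s_int <<- cbind(start = starts, end = pmin(starts + 8, t_stop, max(t)))
  }

  if (fate == "proliferative") {
    prolif_until(max(t) + 1)
  } else if (fate == "G2_arrest_4C") {
    ta <- 20                                  # arrest in G2 (CDK2 ~1.2)
    prolif_until(ta)
    seg <- t >= ta
    cdk2[seg] <- 0.2; dna[seg] <- 4; inS[seg] <- FALSE
    p21[seg] <- p21_ramp(ta)[seg]
    mitoses <- numeric(0)
    s_int <- s_int[s_int[, "start"] < ta, , drop = FALSE]
  } else if (fate == "postmitotic_arrest_2C") {
    prolif_until(cyc_len + 0.01)
    seg <- t >= cyc_len
    cdk2[seg] <- 0.25; dna[seg] <- 2; inS[seg] <- FALSE
    p21[seg] <- p21_ramp(cyc_len + 1)[seg]    # p21 rises ~1 h after division
    mitoses <- cyc_len
    s_int <- s_int[s_int[, "start"] < cyc_len, , drop = FALSE]
  } else if (fate == "endoreduplication") {
    ta <- 20
    prolif_until(ta)
    arrest <- t >= ta & t < ta + dwell
    cdk2[arrest] <- 0.2
    rise <- t >= ta + dwell & t < ta + dwell + 4
    cdk2[rise] <- 0.2 + (t[rise] - ta - dwell) / 4
    after <- t >= ta + dwell + 4
    cdk2[after] <- 1.2
    s2 <- c(ta + dwell + 4, ta + dwell + 12)  # second S phase, 8 h
    seg <- t >= ta
    dna[seg] <- 4; inS[seg] <- FALSE
    in_s2 <- t >= s2[1] & t < s2[2]
    dna[in_s2] <- 4 + 4 * (t[in_s2] - s2[1]) / 8
    dna[t >= s2[2]] <- 8
    inS[in_s2] <- TRUE
    p21[seg] <- p21_ramp(ta)[seg]
    p21[t >= ta + dwell] <- pmax(300 - 250 * pmin((t[t >= ta + dwell] - ta - dwell) / 6, 1), 50)
    mitoses <- numeric(0)
    s1 <- s_int[s_int[, "start"] < ta, , drop = FALSE]
    s_int <- rbind(s1, cbind(start = s2[1], end = min(s2[2], max(t))))
  }
  list(cdk2 = cdk2, p21 = p21, dna = dna, inS = inS,
       mitoses = mitoses, s_int = s_int,
       arrest_onset = if (fate %in% c("G2_arrest_4C", "postmitotic_arrest_2C",
                                      "endoreduplication")) {
         if (fate == "postmitotic_arrest_2C") cyc_len else 20
       } else NA_real_,
       dwell = if (fate == "endoreduplication") dwell else NA_real_)
}

#' Simulate time-lapse biosensor traces
#'
#' Generates CDK2-activity / p21 / PCNA-foci / DNA-proxy traces for the
#' four live-cell fate archetypes: proliferative cycling (CDK2 rising from
#' ~0.5 after mitosis to > 1 before division, DNA proxy halving at
#' mitosis); G2 arrest at 4C (CDK2 collapse below 0.5 with a simultaneous
#' p21 rise and no mitosis); post-mitotic arrest at 2C (a completed
#' mitosis followed by sustained low CDK2 with p21 rising shortly after
#' division); and endoreduplication (G2 arrest, a 15-30 h dwell, CDK2
#' re-rise and a second S phase with no intervening mitosis, DNA
#' proxy reaching 8).
#'
#' @param config A [trace_sim_config()].
#' @return A list of `cell_trace` tibbles (time in minutes; channels
#'   `cdk2_activity`, `p21`, `pcna_foci_count`, `dna_proxy`), each with
#'   ground-truth attributes `fate`, `mitoses`, `s_phase`, `arrest_onset`,
#'   `dwell` (hours).  See [trace_truth()] for a tabular view.
#' @export
simulate_traces <- function(config = trace_sim_config()) {
  stopifnot(inherits(config, "trace_sim_config"))
  set.seed(config$seed)
  dt <- config$frame_interval_min / 60
  t <- seq(0, config$duration_h, by = dt)
  fates <- sample(names(config$fate_mix), config$n_traces, replace = TRUE,
                  prob = config$fate_mix)
  ns <- config$noise
  lapply(seq_len(config$n_traces), function(i) {
    dwell <- runif(1, config$dwell_range_h[1], config$dwell_range_h[2])
    arch <- .trace_archetype(fates[i], t, dwell)
    n <- length(t)
    cdk2 <- pmax(arch$cdk2 + rnorm(n, sd = ns$cdk2), 0)
    p21 <- pmax(arch$p21 + rnorm(n, sd = ns$p21), 0)
    dna <- pmax(arch$dna + rnorm(n, sd = ns$dna), 0.1)
    foci <- if (ns$foci_lambda == 0) {
      ifelse(arch$inS, 20L, 0L)
    } else {
      as.integer(rpois(n, lambda = ifelse(arch$inS, 20, ns$foci_lambda)))
    }
    tr <- tibble::tibble(
      time_min = t * 60,
      cdk2_activity = cdk2,
      p21 = p21,
      pcna_foci_count = foci,
      dna_proxy = dna
    )
    structure(tr,
              class = c("cell_trace", class(tr)),
              trace_id = sprintf("t%04d", i),
              fate = fates[i],
              mitoses = arch$mitoses,
              s_phase = arch$s_int,
              arrest_onset = arch$arrest_onset,
              dwell = arch$dwell)
  })
}

#' Ground-truth table for simulated traces
#'
#' @param traces List of `cell_trace` objects from [simulate_traces()].
#' @return Tibble with `trace_id`, `fate`, event counts and timings.
#' @export
trace_truth <- function(traces) {
  purrr::map_dfr(traces, function(tr) {
    tibble::tibble(
      trace_id = attr(tr, "trace_id"),
      fate = attr(tr, "fate"),
      n_mitoses = length(attr(tr, "mitoses")),
      n_s_phases = nrow(attr(tr, "s_phase")),
      arrest_onset_h = attr(tr, "arrest_onset"),
      dwell_h = attr(tr, "dwell")
    )
  })
}
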