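#' S-phase intervals from PCNA foci counts
#'
#' Maximal runs of frames with foci count at or above the threshold,
#' merged across single-frame dropouts (PCNA foci flicker at S-phase
#' margins).
#'
#' @param trace A trace tibble with `time_min` and `pcna_foci_count`.
#' @param foci_threshold Minimum foci count for an S-phase frame.
#' @return Tibble of disjoint, sorted intervals (`start_min`, `end_min`);
#'   empty when no S phase is detected.
#' @export
detect_s_phase <- function(trace, foci_threshold = 3) {
  if (!"pcna_foci_count" %in% names(trace)) {
    am_abort("Trace has no pcna_foci_count channel.", "arrestmap_schema_error")
  }
  x <- trace$pcna_foci_count >= foci_threshold
  # bridge single-frame dropouts
  n <- length(x)
  if (n >= 3) {
    dropout <- !x & c(FALSE, x[-n]) & c(x[-1], FALSE)
    x[dropout] <- TRUE
  }
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble::tibble(
    start_min = trace$time_min[starts[keep]],
    end_min = trace$time_min[ends[keep]]
  )
}

#' Mitosis times from the DNA proxy
#'
#' A mitosis is a fall of the DNA proxy by at least `drop_fraction`
#' between consecutive frames (DNA content halves at division).
#'
#' @param trace A trace tibble with `time_min` and `dna_proxy`.
#' @param drop_fraction Minimum relative single-frame drop.
#' @return Numeric vector of mitosis times (minutes); empty when none.
#' @export
detect_mitosis <- function(trace, drop_fraction = 0.4) {
  if (!"dna_proxy" %in% names(trace)) {
    am_abort("Trace has no dna_proxy channel.", "arrestmap_schema_error")
  }
  x <- trace$dna_proxy
  n <- length(x)
  if (n < 2) return(numeric(0))
  rel_drop <- 1 - x[-1] / x[-n]
  trace$time_min[which(rel_drop >= drop_fraction) + 1]
}

#' Fate-classification thresholds
#'
#' CDK2 activity below `cdk2_low` marks arrest and above `cdk2_high`
#' full cell-cycle commitment (the conventional 0.5 / 1.0 cut-offs for
#' this sensor family); an arrest episode must last at least
#' `arrest_min_duration_h`.  The p21 rise must fall within
#' `p21_window_frames` of the CDK2 collapse for a G2 arrest call, and S
#' intervals shorter than `s_min_duration_h` are ignored by the
#' endoreduplication rule (foci noise, not replication).
#'
#' @param cdk2_low,cdk2_high CDK2 activity thresholds.
#' @param arrest_min_duration_h Minimum arrest duration (hours).
#' @param p21_rise p21 level (a.u.) counted as induced.
#' @param p21_window_frames Frame window pairing p21 onset with CDK2
#'   collapse.
#' @param s_min_duration_h Minimum S-interval duration (hours) for the
#'   endoreduplication rule.
#' @param foci_threshold Foci-count threshold for [detect_s_phase()].
#' @param mitosis_drop Drop fraction for [detect_mitosis()].
#' @param smooth_k Running-median window (frames, odd) applied to the CDK2
#'   and p21 channels before rule evaluation.
#' @return A list of class `fate_thresholds`.
#' @export
fate_thresholds <- function(cdk2_low = 0.5, cdk2_high = 1.0,
                            arrest_min_duration_h = 6, p21_rise = 50,
                            p21_window_frames = 2, s_min_duration_h = 0.5,
                            foci_threshold = 3, mitosis_drop = 0.4,
                            smooth_k = 5) {
  structure(
    list(cdk2_low = cdk2_low, cdk2_high = cdk2_high,
         arrest_min_duration_h = arrest_min_duration_h, p21_rise = p21_rise,
         p21_window_frames = p21_window_frames,
         s_min_duration_h = s_min_duration_h, foci_threshold = foci_threshold,
         mitosis_drop = mitosis_drop, smooth_k = smooth_k),
    class = "fate_thresholds"
  )
}

#' Classify the fate of a biosensor trace
#'
#' Decision rules, applied in order:
#' 1. *Endoreduplication*: an arrest episode (CDK2 below `cdk2_low` for at
#'    least `arrest_min_duration_h`) followed by CDK2 recovery above
#'    `cdk2_high` and a subsequent S-phase interval, with no mitosis
#'    between arrest onset and the second S phase.
#' 2. *G2 arrest (4C)*: CDK2 falls from above `cdk2_high` to sustained
#'    low until trace end, no subsequent mitosis, and p21 rises within
#'    `p21_window_frames` of the collapse.  When cyclin A/B1 channels are
#'    present and collapse without a mitosis, the call is refined to
#'    *mitotic skipping into senescence*.
#' 3. *Post-mitotic arrest (2C)*: a mitosis followed by sustained low CDK2
#'    to trace end, with the p21 rise after division.
#' 4. Otherwise *proliferative*.
#'
#' @param trace A trace tibble (`time_min`, `cdk2_activity`, `p21`,
#'   `pcna_foci_count`, `dna_proxy`; optional `cyclin_a`, `cyclin_b1`).
#' @param thresholds A [fate_thresholds()].
#' @return A one-row tibble (`fate`, `arrest_onset_h`, `p21_onset_h`,
#'   `dwell_h`); evidence fields are `NA` where not applicable.  Traces
#'   shorter than the minimum arrest duration are labeled
#'   `unclassifiable` (logged).
#' @export
classify_fate <- function(trace, thresholds = fate_thresholds()) {
  th <- thresholds
  t_h <- trace$time_min / 60
  n <- length(t_h)
  dt <- if (n > 1) t_h[2] - t_h[1] else NA_real_
  res <- function(fate, arrest = NA_real_, p21_onset = NA_real_, dwell = NA_real_) {
    tibble::tibble(fate = fate, arrest_onset_h = arrest,
                   p21_onset_h = p21_onset, dwell_h = dwell)
  }
  if (n < 2 || max(t_h) - min(t_h) < th$arrest_min_duration_h) {
    rlang::inform("Trace shorter than the minimum arrest duration; unclassifiable.")
    return(res("unclassifiable"))
  }
  k <- min(th$smooth_k, if (n %% 2 == 1) n else n - 1)
  cdk2 <- runmed(trace$cdk2_activity, k)
  p21 <- runmed(trace$p21, k)
  mitoses_h <- detect_mitosis(trace, th$mitosis_drop) / 60
  s_int <- detect_s_phase(trace, th$foci_threshold)
  s_int <- s_int[(s_int$end_min - s_int$start_min) / 60 >= th$s_min_duration_h, ]
  p21_onset <- if (any(p21 >= th$p21_rise)) t_h[which(p21 >= th$p21_rise)[1]] else NA_real_

  # arrest episodes: maximal runs of CDK2 below cdk2_low
  low <- cdk2 < th$cdk2_low
  r <- rle(low)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  epi <- tibble::tibble(start = starts[r$values], end = ends[r$values])
  epi$dur_h <- t_h[epi$end] - t_h[epi$start]
  long_epi <- epi[epi$dur_h >= th$arrest_min_duration_h, ]

  # rule 1: endoreduplication
  for (i in seq_len(nrow(long_epi))) {
    onset_i <- long_epi$start[i]
    after <- seq(long_epi$end[i], n)
    rec <- after[cdk2[after] > th$cdk2_high]
    if (length(rec) == 0) next
    t_rec <- t_h[rec[1]]
    s2 <- s_int[s_int$start_min / 60 >= t_rec, ]
    if (nrow(s2) == 0) next
    blocked <- any(mitoses_h > t_h[onset_i] & mitoses_h < s2$start_min[1] / 60)
    if (!blocked) {
      return(res("endoreduplication", arrest = t_h[onset_i],
                 p21_onset = p21_onset, dwell = t_rec - t_h[onset_i]))
    }
  }

  # rule 2: G2 arrest — sustained low to trace end, high before collapse,
  # no subsequent mitosis, p21 rise at the collapse
  if (nrow(epi) > 0) {
    last <- epi[nrow(epi), ]
    sustained <- last$end == n && last$dur_h >= th$arrest_min_duration_h
    if (sustained) {
      onset <- last$start
      high_before <- onset > 1 && max(cdk2[1:(onset - 1)]) > th$cdk2_high
      no_mitosis_after <- !any(mitoses_h >= t_h[onset])
      p21_at_collapse <- !is.na(p21_onset) &&
        abs(p21_onset - t_h[onset]) <= th$p21_window_frames * dt
      if (high_before && no_mitosis_after && p21_at_collapse) {
        fate <- "G2_arrest_4C"
        if (all(c("cyclin_a", "cyclin_b1") %in% names(trace)) &&
            length(mitoses_h) == 0) {
          tail_idx <- seq(max(1, n - 5), n)
          collapsed <- mean(trace$cyclin_a[tail_idx]) < 0.3 * max(trace$cyclin_a) &&
            mean(trace$cyclin_b1[tail_idx]) < 0.3 * max(trace$cyclin_b1)
          if (collapsed) fate <- "mitotic_skip_senescent"
        }
        return(res(fate, arrest = t_h[onset], p21_onset = p21_onset))
      }
      # rule 3: post-mitotic arrest — a division, then low CDK2 to end,
      # p21 rising after the division
      if (length(mitoses_h) > 0) {
        m_last <- max(mitoses_h)
        after_div <- t_h[onset] >= m_last - th$p21_window_frames * dt
        p21_after <- !is.na(p21_onset) && p21_onset > m_last
        if (after_div && p21_after) {
          return(res("postmitotic_arrest_2C", arrest = t_h[onset],
                     p21_onset = p21_onset))
        }
      }
    }
  }

  res("proliferative")
}

#' Classify many traces
#'
#' @param traces List of trace tibbles (e.g. from [simulate_traces()]).
#' @param thresholds A [fate_thresholds()].
#' @return Tibble with one row per trace (`trace_id`, `fate`, evidence
#'   fields).
#' @export
classify_fates <- function(traces, thresholds = fate_thresholds()) {
  purrr::imap_dfr(traces, function(tr, i) {
    id <- attr(tr, "trace_id")
    if (is.null(id)) id <- as.character(i)
    dplyr::bind_cols(tibble::tibble(trace_id = id), classify_fate(tr, thresholds))
  })
}
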