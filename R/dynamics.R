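#' Marker dynamics specification
#'
#' The generative model behind [simulate_population()].  A cycling cell sits
#' at a latent cycle position `theta` in `[0, 1)` with phase boundaries
#' G1 `[0, 0.45)`, S `[0.45, 0.75)`, G2 `[0.75, 0.97)`, M `[0.97, 1)`
#' (approximate human somatic phase durations).  Each marker has a strictly
#' positive piecewise-linear mean as a function of `theta`: DNA content
#' interpolates 2C to 4C across S; cyclin A accumulates through S/G2 and is
#' degraded at mitosis; cyclin B1 peaks in M; cyclin D1 rises in late G2
#' and stays elevated through M; CDH1 is high in G1 (APC/C-CDH1 active);
#' SKP2 and PCNA mark S; E2F1 and cyclin E peak at the G1/S boundary;
#' nuclear area grows through the cycle and drops at mitotic rounding.
#'
#' Arrested cells sit on one of eight branches at an arrest depth `s` in
#' `[0, 1]`.  Each branch is anchored either at a cycle position (the point
#' of cell-cycle exit) or at the terminus of a parent branch, and its means
#' interpolate linearly from the anchor profile to a terminal profile:
#' spontaneous and replication-stress arrests carry a p21 induction
#' (replication stress additionally elevates phospho-H2AX and p53);
#' hypomitogenic arrest shows a global decline of nearly every protein with
#' p27 the exception (non-decreasing along the branch); mitotic skipping
#' drops cyclins A/B1 to baseline with CDH1 up and SKP2 down while DNA
#' content stays 4C; the senescent terminus carries elevated GSK3beta,
#' p27, phospho-T157-p27, CDK4, cyclin D1 and cyclin E with a large cell
#' area and a low DNA:cytoplasm ratio; the 8C branch re-replicates to 8C
#' DNA content without p27/CDK4 elevation.
#'
#' The phospho/total-RB ratio is treated specially: cycling cells sit on
#' the hyperphosphorylated mode (mean 0.95) and every arrested cell drops
#' abruptly to the hypophosphorylated regime (mean `0.45 - 0.35 s`).
#'
#' @return An object of class `marker_dynamics`.
#' @export
default_marker_dynamics <- function() {
  structure(
    list(
      phase_breaks = c(G1 = 0, S = 0.45, G2 = 0.75, M = 0.97),
      cycling = .cycling_means,
      arrest = .arrest_states,
      rb_cycling = 0.95,
      rb_arrest = function(s) 0.45 - 0.35 * s,
      # high-precision readouts at half the global cv: ratio statistics
      # cancel shared illumination/size noise, and integrated DNA stain is
      # the classic low-CV cytometry measurement
      low_cv_features = c("rb_ratio_nucleus_ratio", "dna_cyto_ratio",
                          "dna_nucleus_integrated"),
      # immediate-early response: damage/stress signaling saturates early
      # along a branch (the response precedes the arrest it causes);
      # slow accumulation markers stay linear in arrest depth
      early_features = c("p21_nucleus_median", "h2ax_phospho_nucleus_median",
                         "p53_nucleus_median", "chk1_phospho_nucleus_median"),
      early_curve = function(s) (1 - exp(-2 * s)) / (1 - exp(-2))
    ),
    class = "marker_dynamics"
  )
}

#' The nine phase-model features
#'
#' Median nuclear PCNA, CDH1, SKP2, cyclin A, E2F1, cyclin B1 and
#' phospho-p27, plus nuclear area and DNA content -- the feature vector the
#' four-component phase mixture is trained on.
#'
#' @return Character vector of nine feature names.
#' @export
phase_feature_names <- function() {
  c("pcna_nucleus_median", "cdh1_nucleus_median", "skp2_nucleus_median",
    "cyclin_a_nucleus_median", "e2f1_nucleus_median", "cyclin_b1_nucleus_median",
    "p27_phospho_nucleus_median", "nucleus_area", "dna_nucleus_integrated")
}

# linear ramp of theta across [a, b] from lo to hi, clamped outside
.ramp <- function(theta, a, b, lo, hi) {
  f <- pmin(pmax((theta - a) / (b - a), 0), 1)
  lo + (hi - lo) * f
}

# piecewise means for cycling cells; returns a matrix cells x features.
# dna is in C-units (2..4); intensities in arbitrary units.
.cycling_means <- function(theta) {
  g1 <- theta < 0.45
  s  <- theta >= 0.45 & theta < 0.75
  g2 <- theta >= 0.75 & theta < 0.97
  m  <- theta >= 0.97
  pw <- function(v_g1, v_s, v_g2, v_m) {
    out <- numeric(length(theta))
    out[g1] <- v_g1[g1]; out[s] <- v_s[s]; out[g2] <- v_g2[g2]; out[m] <- v_m[m]
    out
  }
  k <- function(x) rep(x, length(theta))
  cbind(
    dna_nucleus_integrated = pw(k(2), .ramp(theta, 0.45, 0.75, 2, 4), k(4), k(4)),
    pcna_nucleus_median = pw(k(80), k(300), k(80), k(80)),
    cdh1_nucleus_median = pw(k(280), k(80), k(80), k(120)),
    skp2_nucleus_median = pw(k(60), k(250), k(250), k(150)),
    cyclin_a_nucleus_median = pw(k(40), .ramp(theta, 0.45, 0.75, 40, 200),
                                 .ramp(theta, 0.75, 0.97, 200, 320), k(50)),
    e2f1_nucleus_median = pw(.ramp(theta, 0, 0.45, 60, 280),
                             .ramp(theta, 0.45, 0.75, 280, 100), k(80), k(60)),
    cyclin_b1_nucleus_median = pw(k(40), .ramp(theta, 0.45, 0.75, 40, 100),
                                  .ramp(theta, 0.75, 0.97, 100, 300), k(380)),
    p27_phospho_nucleus_median = pw(k(150), k(100), k(80), k(80)),
    nucleus_area = pw(.ramp(theta, 0, 0.45, 160, 200),
                      .ramp(theta, 0.45, 0.75, 200, 240),
                      .ramp(theta, 0.75, 0.97, 240, 280), k(100)),
    p21_nucleus_median = k(50),
    cyclin_d1_nucleus_median = pw(.ramp(theta, 0, 0.45, 200, 140), k(120),
                                  .ramp(theta, 0.85, 0.97, 120, 280), k(280)),
    cyclin_e_nucleus_median = pw(.ramp(theta, 0, 0.45, 60, 250),
                                 .ramp(theta, 0.45, 0.75, 250, 100), k(80), k(60)),
    p27_nucleus_median = k(80),
    gsk3b_nucleus_median = k(100),
    cdk4_nucleus_median = k(100),
    cell_area = pw(.ramp(theta, 0, 0.97, 350, 650), .ramp(theta, 0, 0.97, 350, 650),
                   .ramp(theta, 0, 0.97, 350, 650), k(400)),
    dna_cyto_ratio = pw(k(1.0), k(1.1), k(1.2), k(2.0)),
    h2ax_phospho_nucleus_median = k(60),
    p53_nucleus_median = k(60),
    chk1_phospho_nucleus_median = pw(k(60), k(90), k(70), k(60))
  )
}

# Arrest branch definitions.  anchor_theta: cycle position of exit;
# parent: branch whose terminus is the anchor; overrides: terminal values
# for named features; global_factor: multiplier on every *intensity*
# feature not overridden (hypomitogenic global decline); ploidy: truth
# label; dna_constant: branch lives at its terminal DNA content for all s.
.intensity_features <- c(
  "pcna_nucleus_median", "cdh1_nucleus_median", "skp2_nucleus_median",
  "cyclin_a_nucleus_median", "e2f1_nucleus_median", "cyclin_b1_nucleus_median",
  "p27_phospho_nucleus_median", "p21_nucleus_median", "cyclin_d1_nucleus_median",
  "cyclin_e_nucleus_median", "p27_nucleus_median", "gsk3b_nucleus_median",
  "cdk4_nucleus_median", "h2ax_phospho_nucleus_median", "p53_nucleus_median",
  "chk1_phospho_nucleus_median"
)

.arrest_states <- list(
  spontaneous_G0 = list(
    anchor_theta = 0.02, ploidy = "2C",
    overrides = c(p21_nucleus_median = 300, cyclin_d1_nucleus_median = 60,
                  cyclin_e_nucleus_median = 40, cyclin_a_nucleus_median = 30,
                  cyclin_b1_nucleus_median = 30, e2f1_nucleus_median = 40,
                  pcna_nucleus_median = 60, skp2_nucleus_median = 40,
                  p27_nucleus_median = 200, p27_phospho_nucleus_median = 220,
                  cell_area = 800)
  ),
  hypomitogenic_G0 = list(
    anchor_theta = 0.02, ploidy = "2C", global_factor = 0.4,
    early_global = TRUE,  # translation inhibition is rapid on serum withdrawal
    overrides = c(p27_nucleus_median = 330, p21_nucleus_median = 35,
                  nucleus_area = 140, cell_area = 300)
  ),
  repstress_G0_2C = list(
    anchor_theta = 0.02, ploidy = "2C",
    overrides = c(p21_nucleus_median = 320, h2ax_phospho_nucleus_median = 300,
                  p53_nucleus_median = 260, cyclin_d1_nucleus_median = 70,
                  cyclin_e_nucleus_median = 50, cyclin_a_nucleus_median = 30,
                  cyclin_b1_nucleus_median = 30, e2f1_nucleus_median = 50,
                  pcna_nucleus_median = 70, skp2_nucleus_median = 50,
                  chk1_phospho_nucleus_median = 100)
  ),
  repstress_G0_4C = list(
    anchor_theta = 0.88, ploidy = "4C",
    overrides = c(p21_nucleus_median = 320, h2ax_phospho_nucleus_median = 200,
                  p53_nucleus_median = 150, cyclin_a_nucleus_median = 180,
                  cyclin_b1_nucleus_median = 170, pcna_nucleus_median = 70,
                  chk1_phospho_nucleus_median = 260)
  ),
  mitotic_skip = list(
    parent = "repstress_G0_4C", ploidy = "4C",
    overrides = c(cyclin_a_nucleus_median = 30, cyclin_b1_nucleus_median = 30,
                  cdh1_nucleus_median = 300, skp2_nucleus_median = 40,
                  cyclin_d1_nucleus_median = 250, h2ax_phospho_nucleus_median = 160,
                  p53_nucleus_median = 130, p21_nucleus_median = 300,
                  chk1_phospho_nucleus_median = 180)
  ),
  senescent = list(
    parent = "mitotic_skip", ploidy = "4C",
    overrides = c(gsk3b_nucleus_median = 260, p27_nucleus_median = 280,
                  p27_phospho_nucleus_median = 260, cdk4_nucleus_median = 240,
                  cyclin_d1_nucleus_median = 320, cyclin_e_nucleus_median = 280,
                  cell_area = 1200, nucleus_area = 340, dna_cyto_ratio = 0.45,
                  p21_nucleus_median = 300, h2ax_phospho_nucleus_median = 120,
                  p53_nucleus_median = 110, chk1_phospho_nucleus_median = 120)
  ),
  endoreduplicated_8C = list(
    parent = "senescent", ploidy = "8C", dna_constant = TRUE, dna_c = 8,
    overrides = c(e2f1_nucleus_median = 220, pcna_nucleus_median = 250,
                  p27_nucleus_median = 80, cdk4_nucleus_median = 90,
                  cyclin_e_nucleus_median = 300, cyclin_d1_nucleus_median = 300,
                  cell_area = 1100, dna_cyto_ratio = 0.8, skp2_nucleus_median = 80,
                  chk1_phospho_nucleus_median = 100)
  )
)

# Anchor mean profile of a branch: cycling profile at the exit position, or
# the parent's terminal profile.  Returns a named vector (dna in C-units).
.branch_anchor <- function(state, dynamics) {
  def <- dynamics$arrest[[state]]
  if (!is.null(def$anchor_theta)) {
    drop(dynamics$cycling(def$anchor_theta)[1, ])
  } else {
    .branch_terminal(def$parent, dynamics)
  }
}

# Terminal profile: anchor with overrides (and global decline) applied.
.branch_terminal <- function(state, dynamics) {
  def <- dynamics$arrest[[state]]
  term <- .branch_anchor(state, dynamics)
  if (!is.null(def$global_factor)) {
    term[.intensity_features] <- term[.intensity_features] * def$global_factor
  }
  term[names(def$overrides)] <- def$overrides
  if (isTRUE(def$dna_constant)) term["dna_nucleus_integrated"] <- def$dna_c
  term
}
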