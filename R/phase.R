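#' Arrest-call parameters
#'
#' Cells are labeled arrested (G0) or actively cycling by thresholding the
#' peak-normalized phospho/total-RB ratio: the hypophosphorylated mode
#' sits at 0 and the hyperphosphorylated mode at 1, and a threshold of 0.7
#' separates them.  The boundary value is assigned to cycling (the
#' threshold lies in the upper mode's basin); this is configurable.
#'
#' @param threshold Arrest threshold on the normalized ratio, in (0, 1).
#' @param rb_feature Name of the normalized phospho/total-RB feature.
#' @return A list of class `arrest_params`.
#' @export
arrest_params <- function(threshold = 0.7,
                          rb_feature = "rb_ratio_nucleus_ratio") {
  if (threshold <= 0 || threshold >= 1) {
    am_abort("Arrest threshold must lie in (0, 1).", "arrestmap_config_error")
  }
  structure(list(threshold = threshold, rb_feature = rb_feature),
            class = "arrest_params")
}

#' Classify cells as cycling or arrested by the RB ratio
#'
#' @param rb_ratio Numeric vector of normalized phospho/total-RB ratios.
#' @param params An [arrest_params()].
#' @return Character vector in `{cycling, arrested}`; missing ratios give
#'   `NA` (unclassifiable) and are counted in a message.
#' @export
classify_cycling <- function(rb_ratio, params = arrest_params()) {
  out <- ifelse(rb_ratio >= params$threshold, "cycling", "arrested")
  n_na <- sum(is.na(rb_ratio))
  if (n_na > 0) {
    rlang::inform(paste0(n_na, " cell(s) with missing RB ratio flagged unclassifiable."))
  }
  out
}

#' Fit the four-component cell-cycle phase mixture
#'
#' A four-component Gaussian mixture (full covariance) over the nine phase
#' features: median nuclear PCNA, CDH1, SKP2, cyclin A, E2F1, cyclin B1
#' and phospho-p27, plus nuclear area and DNA content.  Fit on cycling
#' cells only (arrest is handled by the RB threshold).  Components are
#' mapped to phases by marker logic rather than manual inspection: the
#' lowest-DNA component is G1; among the rest, the component maximizing
#' cyclin B1 relative to nuclear area is M (mitotic rounding), the
#' remaining component with the higher cyclin A is G2, and the last is S
#' (checked for high PCNA, with a warning otherwise).
#'
#' @details
#' The EM fit is anchored by a coarse marker-logic initialization (PCNA
#' separates S; DNA content separates G1 from G2/M; cyclin B1 and nuclear
#' area separate M from G2) so that the four components correspond to the
#' four phases rather than to an unconstrained likelihood optimum, which
#' on strongly elongated phase clusters tends to split G1 and absorb the
#' small M population.  A conjugate prior regularizes the covariances
#' (degenerate, e.g. noiseless, inputs remain fittable).
#'
#' @param table Feature table restricted to cycling cells.
#' @param features The nine phase features.
#' @param seed Integer seed (the fit itself is deterministic; the seed is
#'   recorded and set for reproducibility of any downstream sampling).
#' @return An object of class `phase_model`.
#' @export
fit_phase_model <- function(table, features = phase_feature_names(), seed = 1L) {
  missing_f <- setdiff(features, names(table))
  if (length(missing_f) > 0) {
    am_abort(paste0("Phase feature(s) missing from table: ",
                    paste(missing_f, collapse = ", ")),
             "arrestmap_schema_error")
  }
  X <- as.matrix(table[, features])
  keep <- complete.cases(X)
  if (sum(keep) < 4 * 50) {
    rlang::warn("Fewer than 200 complete cycling cells; phase fit may be unstable.")
  }
  Xk <- X[keep, , drop = FALSE]
  set.seed(seed)
  init <- .phase_init(Xk)
  z <- matrix(0, nrow(Xk), 4)
  z[cbind(seq_len(nrow(Xk)), init)] <- 1
  em <- tryCatch(
    mclust::me(data = Xk, modelName = "VVV", z = z,
               prior = mclust::priorControl()),
    error = function(e) NULL
  )
  log_lik <- NA_real_
  if (!is.null(em) && !anyNA(em$parameters$mean)) {
    pars <- list(pro = em$parameters$pro,
                 mean = em$parameters$mean,
                 sigma = em$parameters$variance$sigma)
    log_lik <- em$loglik
  } else {
    # degenerate (e.g. noiseless) covariances: fall back to per-component
    # Gaussians around the marker-anchored init, with a small ridge
    rlang::inform("EM unavailable on degenerate input; using marker-anchored component Gaussians.")
    pars <- .hard_phase_params(Xk, init)
  }
  rownames(pars$mean) <- features
  mu <- pars$mean
  dna <- mu["dna_nucleus_integrated", ]
  g1 <- which.min(dna)
  rest <- setdiff(1:4, g1)
  # rank-based: valid on raw or z-normalized scales alike
  m_score <- rank(mu["cyclin_b1_nucleus_median", ]) - rank(mu["nucleus_area", ])
  m <- rest[which.max(m_score[rest])]
  rest2 <- setdiff(rest, m)
  g2 <- rest2[which.max(mu["cyclin_a_nucleus_median", rest2])]
  s <- setdiff(rest2, g2)
  phase_map <- character(4)
  phase_map[c(g1, s, g2, m)] <- c("G1", "S", "G2", "M")
  if (mu["pcna_nucleus_median", s] < max(mu["pcna_nucleus_median", c(g1, g2)])) {
    rlang::warn("S-phase component does not have the highest PCNA; check marker mapping.")
  }
  structure(
    list(parameters = pars, log_lik = log_lik, phase_map = phase_map,
         features = features, seed = as.integer(seed), n = sum(keep)),
    class = "phase_model"
  )
}

# component Gaussians from hard labels, ridge-regularized
.hard_phase_params <- function(X, labels) {
  d <- ncol(X)
  mu <- matrix(NA_real_, d, 4)
  sigma <- array(0, c(d, d, 4))
  pro <- numeric(4)
  for (k in 1:4) {
    idx <- labels == k
    pro[k] <- mean(idx)
    mu[, k] <- colMeans(X[idx, , drop = FALSE])
    cv <- stats::cov(X[idx, , drop = FALSE])
    cv[is.na(cv)] <- 0
    ridge <- max(mean(diag(cv)) * 1e-6, 1e-10)
    sigma[, , k] <- cv + diag(ridge, d)
  }
  list(pro = pro, mean = mu, sigma = sigma)
}

# posterior component probabilities under the stored Gaussians
.phase_posterior <- function(model, X) {
  p <- model$parameters
  logd <- vapply(1:4, function(k) {
    mclust::dmvnorm(X, mean = p$mean[, k], sigma = p$sigma[, , k], log = TRUE)
  }, numeric(nrow(X)))
  logd <- sweep(logd, 2, log(p$pro), "+")
  logd
}

# coarse marker-logic initialization: component indices 1..4 in fixed
# order G1, S, G2, M
.phase_init <- function(X) {
  km2 <- function(x) {
    cl <- stats::kmeans(x, centers = range(x), iter.max = 50)
    cl$cluster == which.max(cl$centers)   # TRUE = high cluster
  }
  s_like <- km2(X[, "pcna_nucleus_median"])
  high_dna <- km2(X[, "dna_nucleus_integrated"])
  init <- ifelse(s_like, 2L, ifelse(high_dna, 3L, 1L))
  g2m <- which(init == 3L)
  if (length(g2m) >= 2) {
    sub <- scale(cbind(X[g2m, "cyclin_b1_nucleus_median"],
                       -X[g2m, "nucleus_area"]))
    score <- rowMeans(sub)
    m_like <- km2(score)
    init[g2m[m_like]] <- 4L
  }
  init
}

#' Assign cell-cycle phases
#'
#' Arrested cells are G0 regardless of the mixture posterior; cycling
#' cells get the argmax-posterior phase of the fitted mixture.  Cells with
#' missing phase features or missing cycling labels are unclassified
#' (`NA`) and counted in a message.
#'
#' @param model A `phase_model`.
#' @param table Feature table.
#' @param cycling_labels Character vector from [classify_cycling()],
#'   aligned with `table` rows.
#' @return Character vector of phases in `{G0, G1, S, G2, M}`.
#' @export
assign_phase <- function(model, table, cycling_labels) {
  stopifnot(inherits(model, "phase_model"))
  X <- as.matrix(table[, model$features])
  ok <- complete.cases(X) & !is.na(cycling_labels)
  out <- rep(NA_character_, nrow(table))
  arrested <- ok & cycling_labels == "arrested"
  out[arrested] <- "G0"
  cyc <- ok & cycling_labels == "cycling"
  if (any(cyc)) {
    post <- .phase_posterior(model, X[cyc, , drop = FALSE])
    out[cyc] <- model$phase_map[apply(post, 1, which.max)]
  }
  if (any(!ok)) {
    rlang::inform(paste0(sum(!ok), " cell(s) unclassified (missing features or labels)."))
  }
  out
}

#' Ploidy band parameters on the normalized DNA scale
#'
#' After peak normalization of DNA content to (2, 4), cells are banded as
#' 2C below 3, 4C in `[3, 6)` and 8C at or above 6.  The boundaries are a
#' design choice (midpoints between C-states on the normalized scale).
#'
#' @param boundaries Strictly increasing numeric length-2 vector
#'   `c(2C/4C, 4C/8C)`.
#' @return A list of class `ploidy_params`.
#' @export
ploidy_params <- function(boundaries = c(3, 6)) {
  if (length(boundaries) != 2 || diff(boundaries) <= 0) {
    am_abort("Ploidy boundaries must be strictly increasing length 2.",
             "arrestmap_config_error")
  }
  structure(list(boundaries = boundaries), class = "ploidy_params")
}

#' Label ploidy from normalized DNA content
#'
#' @param dna_content_normalized Numeric vector on the (2, 4) normalized
#'   scale; negative values are an error.
#' @param params A [ploidy_params()].
#' @return Character vector in `{2C, 4C, 8C}` (`NA` for missing input).
#' @export
label_ploidy <- function(dna_content_normalized, params = ploidy_params()) {
  if (any(dna_content_normalized < 0, na.rm = TRUE)) {
    am_abort("Negative DNA content.", "arrestmap_config_error")
  }
  b <- params$boundaries
  dplyr::case_when(
    is.na(dna_content_normalized) ~ NA_character_,
    dna_content_normalized < b[1] ~ "2C",
    dna_content_normalized < b[2] ~ "4C",
    TRUE ~ "8C"
  )
}

#' Annotate a normalized table with cycling, phase and ploidy calls
#'
#' Pipeline convenience: RB-threshold arrest call, phase-mixture fit on
#' the cycling cells, G0-overriding phase assignment, and ploidy banding.
#'
#' @param table Normalized feature table (RB ratio on the (0, 1) scale,
#'   DNA content on the (2, 4) scale).
#' @param arrest An [arrest_params()].
#' @param dna_feature Normalized DNA-content feature name.
#' @param phase_features The nine phase features.
#' @param seed Seed for the phase fit.
#' @return The table with `cycling_label`, `phase_call` and `ploidy_call`
#'   columns, plus the fitted model as attribute `phase_model`.
#' @export
annotate_phases <- function(table, arrest = arrest_params(),
                            dna_feature = "dna_nucleus_integrated",
                            phase_features = phase_feature_names(),
                            seed = 1L) {
  cyc <- classify_cycling(table[[arrest$rb_feature]], arrest)
  model <- fit_phase_model(table[!is.na(cyc) & cyc == "cycling", , drop = FALSE],
                           phase_features, seed = seed)
  out <- table %>%
    mutate(
      cycling_label = cyc,
      phase_call = assign_phase(model, table, cyc),
      ploidy_call = label_ploidy(.data[[dna_feature]])
    )
  attr(out, "phase_model") <- model
  out
}

#' @export
tidy.phase_model <- function(x, ...) {
  mu <- x$parameters$mean
  rownames(mu) <- x$features
  purrr::map_dfr(seq_len(ncol(mu)), function(k) {
    tibble::tibble(
      component = k,
      phase = x$phase_map[k],
      weight = x$parameters$pro[k],
      feature = rownames(mu),
      mean = mu[, k]
    )
  })
}

#' @export
glance.phase_model <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    k = 4L,
    log_lik = x$log_lik
  )
}
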