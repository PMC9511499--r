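#' Diffusion pseudotime and branch assignment
#'
#' Cells are ordered by their accumulated random-walk distance from a root
#' cell: with `P` the diffusion operator and `pi` its stationary
#' distribution, the accumulated transition matrix is
#' `M = (I - (P - 1 pi'))^-1 - I` (the summed series of centred powers of
#' `P`), and the diffusion-pseudotime distance between two cells is the
#' Euclidean distance between their rows of `M`.  Pseudotime is the
#' distance from the root, rescaled to `[0, 1]` by its maximum.  Branches
#' are assigned by nearest anchor in the same distance.
#'
#' @name trajectory
NULL

# connected components of the positive-kernel graph (BFS)
.graph_components <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(A[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Compute diffusion pseudotime from a root cell
#'
#' @param op A `diffusion_operator` from [diffusion_operator()].
#' @param root Root cell id (row name of the kernel) or row index.
#' @return A `pseudotime_result`: tibble columns `cell_id`, `pseudotime`
#'   (in `[0, 1]`, 0 at the root), with the accumulated matrix retained
#'   for branch assignment and the unscaled root distances as attributes.
#' @export
diffusion_pseudotime <- function(op, root) {
  stopifnot(inherits(op, "diffusion_operator"))
  P <- op$P
  n <- nrow(P)
  ids <- rownames(P)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  root_i <- if (is.character(root)) match(root, ids) else as.integer(root)
  if (is.na(root_i) || root_i < 1 || root_i > n) {
    am_abort("Root cell not found.", "arrestmap_config_error")
  }
  # off-diagonal structure of K decides connectivity
  A <- op$K
  diag(A) <- 0
  comp <- .graph_components(A > 0)
  if (max(comp) > 1) {
    sizes <- table(comp)
    am_abort(paste0("Neighbor graph is disconnected; component sizes: ",
                    paste(sizes, collapse = ", ")),
             "arrestmap_graph_error")
  }
  pi_st <- op$d / sum(op$d)          # stationary distribution (detailed balance)
  M <- solve(diag(n) - P + rep(1, n) %o% pi_st) - diag(n)
  delta <- sweep(M, 2, M[root_i, ])
  dpt_root <- unname(sqrt(rowSums(delta^2)))
  scale <- max(dpt_root)
  structure(
    tibble::tibble(cell_id = ids,
                   pseudotime = if (scale > 0) dpt_root / scale else dpt_root),
    class = c("pseudotime_result", class(tibble::tibble())),
    root = ids[root_i],
    M = M,
    dpt_root = dpt_root,
    scale = scale
  )
}

#' Default root: an early-G1 anchor
#'
#' The trajectory root is the cycling cell with minimal DNA content and
#' maximal phospho/total-RB ratio among G1 cells (ties broken by RB ratio,
#' then cell order): an early-G1 cell freshly re-entering the cycle.
#'
#' @param table Annotated feature table (with `cycling_label` and
#'   `phase_call` from [annotate_phases()]).
#' @param dna_feature,rb_feature Feature names.
#' @return A cell id.
#' @export
select_root <- function(table, dna_feature = "dna_nucleus_integrated",
                        rb_feature = "rb_ratio_nucleus_ratio") {
  cand <- table %>%
    filter(.data$cycling_label == "cycling", .data$phase_call == "G1")
  if (nrow(cand) == 0) am_abort("No cycling G1 cells to root at.", "arrestmap_config_error")
  cand <- cand %>%
    arrange(.data[[dna_feature]], dplyr::desc(.data[[rb_feature]]))
  cand$cell_id[1]
}

#' Assign branch labels by nearest anchor
#'
#' Each cell joins the branch whose anchor cell is closest in diffusion-
#' pseudotime distance; ties break to the smallest branch index (the order
#' of `anchors`); anchors always belong to their own branch.
#'
#' @param result A `pseudotime_result` (carries the accumulated matrix).
#' @param anchors Named character vector `branch_label = cell_id`; at
#'   least two branches.  A branch may contribute several anchors (repeat
#'   the name) -- placing anchors along an arm makes assignment local and
#'   robust near the branch point.  Coincident anchors of *different*
#'   branches (zero distance apart) are an error.
#' @return The result tibble with a `branch` column.
#' @export
assign_branches <- function(result, anchors) {
  stopifnot(inherits(result, "pseudotime_result"))
  if (length(unique(names(anchors))) < 2) {
    am_abort("At least two branch anchors required.", "arrestmap_config_error")
  }
  M <- attr(result, "M")
  ids <- result$cell_id
  anchor_i <- match(anchors, ids)
  if (anyNA(anchor_i)) {
    am_abort(paste0("Anchor cell(s) not found: ",
                    paste(anchors[is.na(anchor_i)], collapse = ", ")),
             "arrestmap_config_error")
  }
  # distances cell -> each anchor row of M
  dist_to <- vapply(anchor_i, function(a) {
    sqrt(rowSums(sweep(M, 2, M[a, ])^2))
  }, numeric(nrow(M)))
  a_dist <- dist_to[anchor_i, , drop = FALSE]
  cross <- outer(names(anchors), names(anchors), "!=")
  if (any(a_dist[cross & upper.tri(a_dist)] == 0)) {
    am_abort("Coincident anchors of different branches (zero diffusion distance apart).",
             "arrestmap_config_error")
  }
  nearest <- apply(dist_to, 1, which.min)   # which.min takes first on ties
  branch <- names(anchors)[nearest]
  branch[anchor_i] <- names(anchors)
  out <- result
  out$branch <- branch
  out
}

#' Bin a trajectory into a feature-dynamics profile
#'
#' Equal-width pseudotime bins over `[0, 1]` restricted to one branch;
#' per-bin, per-feature mean intensity.  Bins with fewer than `min_cells`
#' cells are excluded from the profile (the 15-cell rule).
#'
#' @param table Feature table (normalized), same cells as `result`.
#' @param result A `pseudotime_result`, with `branch` column if branch
#'   filtering is requested.
#' @param branch Branch label to profile, or `NULL` for all cells.
#' @param n_bins Number of equal-width bins (>= 2).
#' @param min_cells Minimum cells per retained bin.
#' @param features Features to profile; default all.
#' @return A `trajectory_profile`: list with `profile` (retained bins x
#'   features matrix), `bins` tibble (`bin`, `mid`, `n`, `retained`), and
#'   the feature set.
#' @export
bin_trajectory <- function(table, result, branch = NULL, n_bins = 50,
                           min_cells = 15, features = NULL) {
  stopifnot(inherits(result, "pseudotime_result"))
  if (n_bins < 2) am_abort("n_bins must be >= 2.", "arrestmap_config_error")
  if (is.null(features)) features <- feature_names(table)
  joined <- dplyr::inner_join(result, table, by = "cell_id")
  if (!is.null(branch)) {
    if (!"branch" %in% names(joined)) {
      am_abort("Result has no branch labels; run assign_branches() first.",
               "arrestmap_config_error")
    }
    joined <- joined[joined$branch == branch, , drop = FALSE]
  }
  if (nrow(joined) == 0) {
    am_abort("No cells on the requested branch.", "arrestmap_config_error")
  }
  breaks <- seq(0, 1, length.out = n_bins + 1)
  joined$bin <- cut(joined$pseudotime, breaks = breaks, include.lowest = TRUE,
                    labels = FALSE)
  counts <- tibble::tibble(bin = seq_len(n_bins)) %>%
    left_join(dplyr::count(joined, .data$bin), by = "bin") %>%
    mutate(n = dplyr::coalesce(.data$n, 0L),
           mid = (breaks[.data$bin] + breaks[.data$bin + 1]) / 2,
           retained = .data$n >= min_cells)
  kept <- counts$bin[counts$retained]
  prof <- joined %>%
    filter(.data$bin %in% kept) %>%
    group_by(.data$bin) %>%
    summarise(across(all_of(features), ~ mean(.x, na.rm = TRUE)), .groups = "drop") %>%
    arrange(.data$bin)
  mat <- as.matrix(prof[, features])
  rownames(mat) <- prof$bin
  structure(
    list(profile = mat, bins = counts, features = features,
         n_bins = n_bins, min_cells = min_cells, branch = branch),
    class = "trajectory_profile"
  )
}

#' @export
tidy.trajectory_profile <- function(x, ...) {
  mids <- x$bins$mid[match(as.integer(rownames(x$profile)), x$bins$bin)]
  tibble::as_tibble(x$profile) %>%
    mutate(bin = as.integer(rownames(x$profile)), pseudotime = mids) %>%
    tidyr::pivot_longer(cols = all_of(x$features), names_to = "feature",
                        values_to = "mean_intensity")
}

# recursive dendrogram leaf order with deterministic rotation: at every
# merge the subtree whose features peak earlier in pseudotime goes first
.leaf_order <- function(merge, scores) {
  leaves_of <- function(node) {
    if (node < 0) return(-node)
    c(leaves_of(merge[node, 1]), leaves_of(merge[node, 2]))
  }
  order_of <- function(node) {
    if (node < 0) return(-node)
    l <- order_of(merge[node, 1])
    r <- order_of(merge[node, 2])
    if (mean(scores[leaves_of(merge[node, 1])]) <= mean(scores[leaves_of(merge[node, 2])])) {
      c(l, r)
    } else {
      c(r, l)
    }
  }
  order_of(nrow(merge))
}

#' Order features by hierarchical clustering of their dynamics
#'
#' Agglomerative clustering (average linkage) of the feature profiles
#' under correlation distance `1 - r`; the display order is the dendrogram
#' leaf order with a deterministic rotation (at every merge, the subtree
#' whose mean profile peaks at the earlier pseudotime goes first).
#' Zero-variance profiles cannot enter the correlation and are placed
#' last, with a message.
#'
#' @param profile A `trajectory_profile` with >= 2 features and >= 2
#'   retained bins.
#' @return Character vector: the feature display order.
#' @export
order_features <- function(profile) {
  stopifnot(inherits(profile, "trajectory_profile"))
  mat <- profile$profile
  if (nrow(mat) < 2 || ncol(mat) < 2) {
    am_abort("Need >= 2 retained bins and >= 2 features to order.",
             "arrestmap_config_error")
  }
  vars <- apply(mat, 2, sd)
  flat <- colnames(mat)[vars == 0]
  if (length(flat) > 0) {
    rlang::inform(paste0("Zero-variance feature profile(s) placed last: ",
                         paste(flat, collapse = ", ")))
  }
  active <- setdiff(colnames(mat), flat)
  if (length(active) < 2) return(c(active, flat))
  sub <- mat[, active, drop = FALSE]
  dmat <- stats::as.dist(1 - cor(sub))
  hc <- hclust(dmat, method = "average")
  mids <- profile$bins$mid[match(as.integer(rownames(mat)), profile$bins$bin)]
  peak_pos <- apply(sub, 2, function(p) mids[which.max(p)])
  ord <- .leaf_order(hc$merge, peak_pos)
  c(active[ord], flat)
}

#' Default senescence signature
#'
#' Elevated GSK3beta, phospho-T157-p27, total p27, CDK4, cyclin D1 and
#' cyclin E, large cell area, and a low DNA:cytoplasm ratio.
#'
#' @return Tibble with columns `feature`, `direction` (+1 / -1).
#' @export
senescence_signature <- function() {
  tibble::tibble(
    feature = c("gsk3b_nucleus_median", "p27_phospho_nucleus_median",
                "p27_nucleus_median", "cdk4_nucleus_median",
                "cyclin_d1_nucleus_median", "cyclin_e_nucleus_median",
                "cell_area", "dna_cyto_ratio"),
    direction = c(1, 1, 1, 1, 1, 1, 1, -1)
  )
}

#' Score cells against a senescence marker signature
#'
#' Mean over the signature of direction times the control-z-normalized
#' value; linear in the inputs, 0 at the control means, higher = more
#' senescent.
#'
#' @param table Control-z-normalized feature table.
#' @param signature A signature tibble (`feature`, `direction`); default
#'   [senescence_signature()].
#' @return The table with a `senescence_score` column.
#' @export
senescence_score <- function(table, signature = senescence_signature()) {
  if (nrow(signature) == 0) {
    am_abort("Empty senescence signature.", "arrestmap_config_error")
  }
  if (!all(signature$direction %in% c(-1, 1))) {
    am_abort("Signature directions must be +1 or -1.", "arrestmap_config_error")
  }
  missing_f <- setdiff(signature$feature, names(table))
  if (length(missing_f) > 0) {
    am_abort(paste0("Signature feature(s) missing from table: ",
                    paste(missing_f, collapse = ", ")),
             "arrestmap_schema_error")
  }
  vals <- as.matrix(table[, signature$feature])
  score <- drop(vals %*% signature$direction) / nrow(signature)
  table %>% mutate(senescence_score = score)
}

# round half away from zero
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Fate fractions as whole percentages
#'
#' Converts fate/branch counts (or a vector of labels) to percentages
#' summing to exactly 100: each share is rounded half away from zero and
#' any rounding residual is assigned to the largest label.
#'
#' @param labels Character/factor vector of per-cell labels, or a named
#'   numeric vector of counts.
#' @return Tibble with `label`, `n`, `percent`.
#' @export
fate_fractions <- function(labels) {
  if (is.numeric(labels) && !is.null(names(labels))) {
    counts <- labels
  } else {
    if (length(labels) == 0) am_abort("Empty label input.", "arrestmap_config_error")
    counts <- table(as.character(labels))
    counts <- setNames(as.numeric(counts), names(counts))
  }
  if (length(counts) == 0 || sum(counts) == 0) {
    am_abort("Empty label input.", "arrestmap_config_error")
  }
  pct <- 100 * counts / sum(counts)
  rounded <- .round_half_away(pct)
  residual <- 100 - sum(rounded)
  if (residual != 0) {
    big <- which.max(counts)
    rounded[big] <- rounded[big] + residual
  }
  tibble::tibble(label = names(counts), n = as.numeric(counts),
                 percent = as.numeric(rounded))
}

#' @export
tidy.pseudotime_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.pseudotime_result <- function(x, ...) {
  tibble::tibble(
    n = nrow(x),
    root = attr(x, "root"),
    max_dpt = attr(x, "scale"),
    n_branches = if ("branch" %in% names(x)) length(unique(x$branch)) else 0L
  )
}
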