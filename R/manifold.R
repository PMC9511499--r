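#' Diffusion-geometry embedding ("cell cycle map")
#'
#' The embedding pipeline: an adaptive alpha-decay kernel, a row-stochastic
#' diffusion operator, potential distances after `t` diffusion steps
#' (log-transformed transition probabilities for `gamma = 1`, the power
#' transform otherwise), and a two-dimensional stress-minimizing
#' projection.  All computations are exact and dense.
#'
#' @name manifold
NULL

#' Embedding parameters
#'
#' @param knn Neighbor count for the adaptive kernel bandwidth (>= 2).
#' @param t Diffusion time steps (>= 1).
#' @param gamma Potential-transform parameter in `[-1, 1]`; 1 gives the
#'   log potential.
#' @param decay_alpha Kernel decay exponent (canonical default 40).
#' @param dims Output dimensionality (fixed at 2).
#' @param seed Integer seed recorded with the embedding.
#' @return A list of class `embedding_params`.
#' @export
embedding_params <- function(knn = 150, t = 20, gamma = 1, decay_alpha = 40,
                             dims = 2, seed = 1L) {
  if (knn < 2) am_abort("knn must be >= 2.", "arrestmap_config_error")
  if (t < 1) am_abort("t must be >= 1.", "arrestmap_config_error")
  if (gamma < -1 || gamma > 1) {
    am_abort("gamma must lie in [-1, 1].", "arrestmap_config_error")
  }
  if (dims != 2) am_abort("Output dimensionality is fixed at 2.", "arrestmap_config_error")
  structure(list(knn = knn, t = t, gamma = gamma, decay_alpha = decay_alpha,
                 dims = 2L, seed = as.integer(seed)),
            class = "embedding_params")
}

#' Build the adaptive alpha-decay kernel
#'
#' `K_ij = (exp(-(d_ij/sigma_i)^alpha) + exp(-(d_ij/sigma_j)^alpha)) / 2`
#' with `d` the Euclidean distance on the selected features and `sigma_i`
#' the distance from cell `i` to its `knn`-th neighbor.  `K_ii = 1`.
#' Duplicate points that force `sigma_i = 0` fall back to the smallest
#' positive neighbor distance (logged).
#'
#' @param X Numeric matrix, cells x features; no missing values;
#'   `nrow(X) > knn`.
#' @param knn Neighbor count.
#' @param decay_alpha Decay exponent.
#' @return Symmetric kernel matrix with unit diagonal.
#' @export
build_kernel <- function(X, knn = 150, decay_alpha = 40) {
  if (anyNA(X)) am_abort("X must not contain missing values.", "arrestmap_config_error")
  n <- nrow(X)
  if (n <= knn) am_abort("Need more cells than knn.", "arrestmap_config_error")
  d <- as.matrix(dist(X))
  k1 <- knn + 1                     # +1 skips self (0)
  sigma <- apply(d, 1, function(r) sort(r, partial = k1)[k1])
  zero_sigma <- sigma == 0
  if (any(zero_sigma)) {
    sigma[zero_sigma] <- apply(d[zero_sigma, , drop = FALSE], 1, function(r) {
      min(r[r > 0])
    })
    rlang::inform(paste0(sum(zero_sigma),
                         " cell(s) with duplicate-point bandwidth; using smallest positive neighbor distance."))
  }
  K <- (exp(-(d / sigma)^decay_alpha) + exp(-t(d / sigma)^decay_alpha)) / 2
  dimnames(K) <- dimnames(d)
  K
}

#' Row-normalize a kernel into a diffusion operator
#'
#' @param K Symmetric non-negative kernel matrix.
#' @return A `diffusion_operator`: list with `P` (row-stochastic), `K`,
#'   and the kernel row sums `d`.
#' @export
diffusion_operator <- function(K) {
  if (any(K < 0)) am_abort("Kernel must be non-negative.", "arrestmap_config_error")
  rs <- rowSums(K)
  if (any(rs == 0)) {
    bad <- which(rs == 0)
    am_abort(paste0("Isolated cell(s) with zero kernel row sum: ",
                    paste(utils::head(bad, 5), collapse = ", ")),
             "arrestmap_graph_error")
  }
  structure(list(P = K / rs, K = K, d = rs), class = "diffusion_operator")
}

# dense matrix power by binary exponentiation
.mat_power <- function(P, t) {
  stopifnot(t >= 1)
  result <- NULL
  base <- P
  while (t > 0) {
    if (t %% 2 == 1) result <- if (is.null(result)) base else result %*% base
    t <- t %/% 2
    if (t > 0) base <- base %*% base
  }
  result
}

#' Potential distances between cells
#'
#' Diffuses `t` steps, transforms the transition probabilities into
#' potentials (`-log(p + eps)` for `gamma = 1`, the power transform
#' `2/(1-gamma) p^((1-gamma)/2)` otherwise), and returns the Euclidean
#' distances between potential rows.
#'
#' @param op A `diffusion_operator` (or a row-stochastic matrix).
#' @param t Diffusion steps (>= 1).
#' @param gamma Potential-transform parameter.
#' @param eps Positive floor inside the transform; default is a
#'   machine-epsilon-scaled constant.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
potential_distances <- function(op, t = 20, gamma = 1,
                                eps = .Machine$double.eps) {
  P <- if (inherits(op, "diffusion_operator")) op$P else op
  if (t < 1) am_abort("t must be >= 1.", "arrestmap_config_error")
  if (eps <= 0) am_abort("eps must be positive.", "arrestmap_config_error")
  Pt <- .mat_power(P, t)
  U <- if (gamma == 1) {
    -log(Pt + eps)
  } else {
    2 / (1 - gamma) * (Pt + eps)^((1 - gamma) / 2)
  }
  D <- as.matrix(dist(U))
  dimnames(D) <- dimnames(P)
  D
}

#' Stress-minimizing 2-D embedding of a distance matrix
#'
#' Classical multidimensional scaling initialization followed by SMACOF
#' stress majorization; the stress sequence is non-increasing by
#' construction and iteration stops at relative improvement below `tol`.
#' Deterministic for a given input.
#'
#' @param D Distance matrix (finite, symmetric).
#' @param dims Output dimensionality.
#' @param seed Seed recorded with the result.
#' @param max_iter,tol Iteration controls.
#' @param cell_ids Optional cell identifiers for the coordinate table.
#' @return A `cell_embedding`: list with `coords` tibble (`cell_id`,
#'   `map1`, `map2`), final normalized `stress`, the `stress_trace`, and
#'   the parameters used.
#' @export
embed_distances <- function(D, dims = 2, seed = 1L, max_iter = 200,
                            tol = 1e-7, cell_ids = NULL) {
  D <- as.matrix(D)
  if (any(!is.finite(D))) am_abort("Non-finite distances.", "arrestmap_config_error")
  n <- nrow(D)
  set.seed(seed)
  Y <- cmdscale(D, k = dims)
  if (ncol(Y) < dims) {  # degenerate (e.g. all-equal) configurations
    Y <- cbind(Y, matrix(0, n, dims - ncol(Y)))
  }
  denom <- sum(D^2) / 2
  stress_of <- function(Y) {
    dy <- as.matrix(dist(Y))
    sqrt(sum((D - dy)^2) / 2 / denom)
  }
  trace <- stress_of(Y)
  for (it in seq_len(max_iter)) {
    dy <- as.matrix(dist(Y))
    ratio <- ifelse(dy > 0, D / dy, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    Y_new <- B %*% Y / n
    s_new <- stress_of(Y_new)
    trace <- c(trace, s_new)
    if (trace[it] - s_new < tol * max(trace[it], .Machine$double.eps)) {
      Y <- Y_new
      break
    }
    Y <- Y_new
  }
  if (is.null(cell_ids)) cell_ids <- rownames(D)
  if (is.null(cell_ids)) cell_ids <- as.character(seq_len(n))
  structure(
    list(coords = tibble::tibble(cell_id = cell_ids,
                                 map1 = Y[, 1], map2 = Y[, 2]),
         stress = trace[length(trace)],
         stress_trace = trace,
         params = list(dims = dims, seed = seed)),
    class = "cell_embedding"
  )
}

#' Embed a feature table into the 2-D cell cycle map
#'
#' Composes [build_kernel()], [diffusion_operator()],
#' [potential_distances()] and [embed_distances()] on the selected
#' (normalized) features.
#'
#' @param table Normalized feature table.
#' @param params An [embedding_params()].
#' @param feature_list Features to embed on; default all.
#' @return A `cell_embedding`, with the diffusion operator attached as
#'   attribute `operator` for downstream pseudotime.
#' @export
map_cells <- function(table, params = embedding_params(), feature_list = NULL) {
  if (is.null(feature_list)) feature_list <- feature_names(table)
  X <- as.matrix(table[, feature_list])
  rownames(X) <- table$cell_id
  K <- build_kernel(X, knn = params$knn, decay_alpha = params$decay_alpha)
  op <- diffusion_operator(K)
  D <- potential_distances(op, t = params$t, gamma = params$gamma)
  emb <- embed_distances(D, dims = params$dims, seed = params$seed,
                         cell_ids = table$cell_id)
  emb$params <- c(emb$params, params[c("knn", "t", "gamma", "decay_alpha")])
  emb$params$feature_list <- feature_list
  attr(emb, "operator") <- op
  emb
}

#' @export
tidy.cell_embedding <- function(x, ...) {
  x$coords
}

#' @export
glance.cell_embedding <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$coords),
    stress = x$stress,
    iterations = length(x$stress_trace),
    knn = x$params$knn %||% NA_integer_,
    t = x$params$t %||% NA_integer_,
    gamma = x$params$gamma %||% NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
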