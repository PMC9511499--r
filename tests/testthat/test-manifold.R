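# brute-force O(n^2) kernel oracle
kernel_oracle <- function(X, knn, alpha) {
  n <- nrow(X)
  d <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) d[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  sigma <- numeric(n)
  for (i in 1:n) sigma[i] <- sort(d[i, ])[knn + 1]
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    K[i, j] <- (exp(-(d[i, j] / sigma[i])^alpha) + exp(-(d[i, j] / sigma[j])^alpha)) / 2
  }
  K
}

test_that("alpha-decay kernel matches the brute-force double loop", {
  set.seed(101)
  X <- matrix(rnorm(50 * 5), 50, 5)
  K <- build_kernel(X, knn = 7, decay_alpha = 10)
  expect_equal(unname(K), kernel_oracle(X, 7, 10), tolerance = 1e-12)
  expect_true(isSymmetric(unname(K)))
  expect_equal(unname(diag(K)), rep(1, 50))

  # coincident points: K_ij = 1 and the duplicate bandwidth is replaced
  X2 <- rbind(X, X[1, ], X[1, ])
  expect_message(K2 <- build_kernel(X2, knn = 1, decay_alpha = 10), "duplicate")
  expect_equal(K2[51, 52], 1)

  # permutation equivariance
  perm <- sample(50)
  Kp <- build_kernel(X[perm, ], knn = 7, decay_alpha = 10)
  expect_equal(unname(Kp), unname(K[perm, perm]), tolerance = 1e-12)

  expect_error(build_kernel(X, knn = 50), class = "arrestmap_config_error")
  X[1, 1] <- NA
  expect_error(build_kernel(X, knn = 5), class = "arrestmap_config_error")
})

test_that("diffusion operator is row-stochastic and multiplies correctly", {
  expect_equal(diffusion_operator(diag(4))$P, diag(4))

  set.seed(7)
  X <- matrix(rnorm(20 * 3), 20, 3)
  op <- diffusion_operator(build_kernel(X, knn = 4, decay_alpha = 5))
  expect_equal(unname(rowSums(op$P)), rep(1, 20), tolerance = 1e-12)
  expect_true(all(op$P >= 0))

  # P^2 equals a brute-force triple loop product
  P2 <- arrestmap:::.mat_power(op$P, 2)
  oracle <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20) oracle[i, j] <- sum(op$P[i, ] * op$P[, j])
  expect_equal(unname(P2), oracle, tolerance = 1e-12)

  # isolated cell (zero row) is named in the error
  K <- diag(3)
  K[2, ] <- 0; K[, 2] <- 0; K[2, 2] <- 0
  expect_error(diffusion_operator(K), class = "arrestmap_graph_error")
})

test_that("potential distances match direct recomputation on a chain graph", {
  # 10-cell chain
  n <- 10
  K <- diag(n)
  for (i in 1:(n - 1)) K[i, i + 1] <- K[i + 1, i] <- 0.5
  op <- diffusion_operator(K)
  t_steps <- 3
  D <- potential_distances(op, t = t_steps, gamma = 1, eps = 1e-7)

  Pt <- op$P
  for (s in seq_len(t_steps - 1)) Pt <- Pt %*% op$P
  U <- -log(Pt + 1e-7)
  oracle <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) oracle[i, j] <- sqrt(sum((U[i, ] - U[j, ])^2))
  expect_equal(unname(D), oracle, tolerance = 1e-10)

  expect_true(isSymmetric(unname(D)))
  expect_equal(unname(diag(D)), rep(0, n))
  # two cells with identical diffusion rows are at distance 0
  K2 <- matrix(1, 4, 4)
  D2 <- potential_distances(diffusion_operator(K2), t = 2)
  expect_equal(unname(D2), matrix(0, 4, 4))
  expect_error(potential_distances(op, t = 3, eps = 0),
               class = "arrestmap_config_error")
})

test_that("gamma below 1 applies the power-transform potential", {
  n <- 8
  K <- diag(n)
  for (i in 1:(n - 1)) K[i, i + 1] <- K[i + 1, i] <- 0.4
  op <- diffusion_operator(K)
  eps <- 1e-7
  D <- potential_distances(op, t = 2, gamma = 0.25, eps = eps)
  Pt <- op$P %*% op$P
  U <- 2 / (1 - 0.25) * (Pt + eps)^((1 - 0.25) / 2)
  expect_equal(unname(D), unname(as.matrix(dist(U))), tolerance = 1e-10)
})

test_that("smoothing: mean potential distance is non-increasing in t", {
  set.seed(55)
  X <- matrix(rnorm(100 * 4), 100, 4)
  op <- diffusion_operator(build_kernel(X, knn = 10, decay_alpha = 2))
  means <- vapply(c(1, 2, 5, 10, 20), function(tt) {
    mean(potential_distances(op, t = tt))
  }, numeric(1))
  expect_true(all(diff(means) <= 1e-8))
})

test_that("stress embedding honors metric structure", {
  # 3 equidistant points -> equilateral triangle
  D <- matrix(1, 3, 3); diag(D) <- 0
  emb <- embed_distances(D, seed = 1)
  dd <- dist(as.matrix(emb$coords[, c("map1", "map2")]))
  expect_lt(max(abs(dd - mean(dd))) / mean(dd), 0.01)

  # duplicated cell lands on coincident coordinates
  D4 <- as.matrix(dist(c(0, 1, 3, 3)))
  emb4 <- embed_distances(D4, seed = 1)
  co <- as.matrix(emb4$coords[, c("map1", "map2")])
  expect_lt(sqrt(sum((co[3, ] - co[4, ])^2)), 1e-6)

  # stress is non-increasing over iterations
  set.seed(77)
  D100 <- as.matrix(dist(matrix(rnorm(60 * 6), 60, 6)))
  emb100 <- embed_distances(D100, seed = 2)
  expect_true(all(diff(emb100$stress_trace) <= 1e-10))
  expect_error(embed_distances(matrix(c(0, Inf, Inf, 0), 2, 2)),
               class = "arrestmap_config_error")
})

test_that("a 1-D curve in high dimension embeds in its true order", {
  set.seed(91)
  u <- sort(runif(150))
  basis <- matrix(rnorm(20 * 2), 20, 2)
  X <- cbind(u, u^2) %*% t(basis)      # noiseless curve in 20-D
  emb <- embed_distances(as.matrix(dist(X)), seed = 3)
  rho <- cor(emb$coords$map1, u, method = "spearman")
  expect_gte(abs(rho), 0.95)
})

test_that("map_cells separates clusters, is seed-stable and permutation-invariant", {
  skip_if_not_installed("vegan")
  set.seed(103)
  n <- 120
  centers <- rbind(rep(0, 6), rep(6, 6))
  lab <- rep(1:2, each = n / 2)
  X <- centers[lab, ] + matrix(rnorm(n * 6, sd = 0.5), n, 6)
  tbl <- dplyr::bind_cols(
    tibble::tibble(cell_id = sprintf("m%03d", 1:n), condition = "control",
                   replicate = "r1"),
    tibble::as_tibble(as.data.frame(X) |> stats::setNames(paste0("f", 1:6)))
  )
  prm <- embedding_params(knn = 10, t = 5, gamma = 1, decay_alpha = 2, seed = 4)
  emb <- map_cells(tbl, prm)
  co <- as.matrix(emb$coords[, c("map1", "map2")])

  # silhouette-style separation: between-centroid distance over within-spread
  sil <- cluster_silhouette(co, lab)
  expect_gt(sil, 0.5)

  # centroid separation exceeds within-group spread
  mu1 <- colMeans(co[lab == 1, ]); mu2 <- colMeans(co[lab == 2, ])
  spread <- mean(c(apply(co[lab == 1, ], 2, sd), apply(co[lab == 2, ], 2, sd)))
  expect_gt(sqrt(sum((mu1 - mu2)^2)), spread)

  # same seed twice: identical coordinates
  emb2 <- map_cells(tbl, prm)
  expect_identical(emb$coords, emb2$coords)

  # permutation invariance up to rigid motion (Procrustes residual)
  perm <- sample(n)
  embp <- map_cells(tbl[perm, ], prm)
  cop <- as.matrix(embp$coords[, c("map1", "map2")])[order(perm), ]
  proc <- vegan::procrustes(co, cop, symmetric = TRUE)
  expect_lt(proc$ss, 1e-6)

  # tidy/glance accessors
  expect_identical(tidy(emb), emb$coords)
  expect_equal(glance(emb)$n, n)
})
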