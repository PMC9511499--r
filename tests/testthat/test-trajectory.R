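# small chain operator shared by the DPT oracle tests
chain_operator <- function(n, w = 0.5) {
  K <- diag(n)
  for (i in 1:(n - 1)) K[i, i + 1] <- K[i + 1, i] <- w
  rownames(K) <- colnames(K) <- paste0("n", 1:n)
  diffusion_operator(K)
}

test_that("diffusion pseudotime matches the truncated-series oracle", {
  op <- chain_operator(10)
  pt <- diffusion_pseudotime(op, "n1")
  expect_equal(pt$pseudotime[1], 0)

  # oracle: M = sum_{s=1..500} (P^s - 1 pi')
  P <- op$P
  pi_st <- op$d / sum(op$d)
  Pi <- rep(1, 10) %o% pi_st
  M_oracle <- matrix(0, 10, 10)
  Ps <- diag(10)
  for (s in 1:500) {
    Ps <- Ps %*% P
    M_oracle <- M_oracle + (Ps - Pi)
  }
  d_oracle <- sqrt(colSums((t(M_oracle) - M_oracle[1, ])^2))
  expect_equal(unname(pt$pseudotime), d_oracle / max(d_oracle), tolerance = 1e-6)

  # strictly increasing along the chain (also on a 20-cell instance)
  pt20 <- diffusion_pseudotime(chain_operator(20), "n1")
  expect_true(all(diff(pt20$pseudotime) > 0))
  expect_true(all(pt20$pseudotime >= 0 & pt20$pseudotime <= 1))
})

test_that("disconnected graphs and missing roots are rejected", {
  K <- diag(6)
  K[1, 2] <- K[2, 1] <- 0.5
  K[4, 5] <- K[5, 4] <- 0.5
  op <- diffusion_operator(K)
  err <- tryCatch(diffusion_pseudotime(op, 1), error = identity)
  expect_s3_class(err, "arrestmap_graph_error")
  expect_match(conditionMessage(err), "component sizes")
  expect_error(diffusion_pseudotime(chain_operator(5), "zz"),
               class = "arrestmap_config_error")
})

test_that("branch anchors partition a Y-shaped chain correctly", {
  # Y graph: stem 1-5, arm A 6-10, arm B 11-15, both forking from node 5
  n <- 15
  K <- diag(n)
  link <- function(i, j) K[i, j] <<- K[j, i] <<- 0.5
  for (i in 1:4) link(i, i + 1)
  link(5, 6); for (i in 6:9) link(i, i + 1)
  link(5, 11); for (i in 11:14) link(i, i + 1)
  rownames(K) <- colnames(K) <- paste0("n", 1:n)
  op <- diffusion_operator(K)
  pt <- diffusion_pseudotime(op, "n1")
  br <- assign_branches(pt, c(A = "n10", B = "n15"))
  expect_identical(br$branch[6:10], rep("A", 5))
  expect_identical(br$branch[11:15], rep("B", 5))
  # anchors belong to their own branch
  expect_identical(br$branch[br$cell_id == "n10"], "A")

  # merging two anchors of the same arm leaves the arm partition unchanged
  br2 <- assign_branches(pt, c(A = "n10", A = "n8", B = "n15"))
  expect_identical(br2$branch[6:15], br$branch[6:15])

  # coincident anchors of different branches are an error
  K2 <- matrix(1, 4, 4)
  rownames(K2) <- colnames(K2) <- paste0("c", 1:4)
  pt2 <- diffusion_pseudotime(diffusion_operator(K2), "c1")
  expect_error(assign_branches(pt2, c(A = "c2", B = "c3")),
               class = "arrestmap_config_error")
  expect_error(assign_branches(pt, c(A = "n10")), class = "arrestmap_config_error")
})

test_that("trajectory binning applies the 15-cell exclusion rule exactly", {
  set.seed(61)
  n <- 1500
  tbl <- tibble::tibble(
    cell_id = sprintf("b%04d", 1:n), condition = "control", replicate = "r1",
    fA = rnorm(n), fB = rnorm(n)
  )
  pt <- structure(
    tibble::tibble(cell_id = tbl$cell_id, pseudotime = runif(n)),
    class = c("pseudotime_result", class(tibble::tibble())),
    root = tbl$cell_id[1]
  )
  prof <- bin_trajectory(tbl, pt, n_bins = 10, min_cells = 15)
  expect_equal(nrow(prof$profile), 10)            # ~150 per bin, all retained
  expect_true(all(prof$bins$n >= 15))

  # constructed sparse bin: push all but 10 cells out of bin 1
  pt2 <- pt
  low <- pt2$pseudotime < 0.1
  keep_low <- which(low)[1:10]
  pt2$pseudotime[setdiff(which(low), keep_low)] <-
    0.1 + 0.8 * runif(sum(low) - 10)
  prof2 <- bin_trajectory(tbl, pt2, n_bins = 10, min_cells = 15)
  expect_false(1 %in% as.integer(rownames(prof2$profile)))
  expect_false(prof2$bins$retained[1])
  expect_equal(prof2$bins$n[1], 10)
  # retained + excluded = n_bins
  expect_equal(sum(prof2$bins$retained) + sum(!prof2$bins$retained), 10)

  # bin means equal brute-force group-by means
  breaks <- seq(0, 1, length.out = 11)
  grp <- cut(pt$pseudotime, breaks, include.lowest = TRUE, labels = FALSE)
  oracle <- tapply(tbl$fA, grp, mean)
  expect_equal(unname(prof$profile[, "fA"]), as.vector(oracle), tolerance = 1e-12)

  expect_error(bin_trajectory(tbl, pt, n_bins = 1), class = "arrestmap_config_error")
  expect_error(bin_trajectory(tbl, pt, branch = "missing"),
               class = "arrestmap_config_error")
})

test_that("feature ordering clusters dynamics deterministically", {
  set.seed(63)
  base <- sin(seq(0, pi, length.out = 20))
  mat <- cbind(
    up = seq(0, 1, length.out = 20),
    up_twin = seq(0, 1, length.out = 20) + rnorm(20, sd = 0.01),
    down = seq(1, 0, length.out = 20),
    hump = base,
    flat = rep(1, 20)
  )
  prof <- structure(
    list(profile = `rownames<-`(mat, 1:20),
         bins = tibble::tibble(bin = 1:20, mid = (1:20 - 0.5) / 20, n = 50,
                               retained = TRUE),
         features = colnames(mat), n_bins = 20, min_cells = 15, branch = NULL),
    class = "trajectory_profile"
  )
  expect_message(ord <- order_features(prof), "flat")
  # zero-variance feature placed last
  expect_identical(ord[length(ord)], "flat")
  # identical profiles adjacent
  expect_equal(abs(match("up", ord) - match("up_twin", ord)), 1)
  # determinism
  expect_identical(order_features(prof), ord)

  # r = -1 profiles merge at the maximal correlation distance
  d <- 1 - cor(mat[, c("up", "down")])
  expect_equal(max(d), 2)
})

test_that("senescence score is a linear signed mean of z-values", {
  sig <- senescence_signature()
  n <- 10
  tbl <- dplyr::bind_cols(
    tibble::tibble(cell_id = sprintf("s%02d", 1:n), condition = "control",
                   replicate = "r1"),
    tibble::as_tibble(matrix(rnorm(n * nrow(sig)), n,
                             dimnames = list(NULL, sig$feature)))
  )
  scored <- senescence_score(tbl)
  oracle <- as.matrix(tbl[, sig$feature]) %*% sig$direction / nrow(sig)
  expect_equal(scored$senescence_score, drop(oracle))

  # cell at the control means scores 0; unit displacement scores 1
  zero <- tbl[1, ]
  zero[, sig$feature] <- 0
  expect_equal(senescence_score(zero)$senescence_score, 0)
  unit <- zero
  unit[, sig$feature] <- as.list(sig$direction)
  expect_equal(senescence_score(unit)$senescence_score, 1)

  # linearity: score(a z) = a score(z)
  doubled <- tbl
  doubled[, sig$feature] <- tbl[, sig$feature] * 3
  expect_equal(senescence_score(doubled)$senescence_score,
               3 * scored$senescence_score)

  expect_error(senescence_score(tbl[, 1:4]), class = "arrestmap_schema_error")
})

test_that("senescence score separates senescent from cycling cells", {
  skip_if_not_installed("pROC")
  mix <- c(cycling = 0.6, senescent = 0.2, repstress_G0_4C = 0.2)
  pop <- simulate_population(population_sim_config(n_cells = 2500, state_mix = mix,
                                                   seed = 67))
  res <- suppressMessages(normalize_table(pop))
  scored <- senescence_score(res$table)
  sub <- scored[scored$arrest_state %in% c("cycling", "senescent"), ]
  auc <- as.numeric(pROC::auc(pROC::roc(sub$arrest_state == "senescent",
                                        sub$senescence_score, quiet = TRUE)))
  expect_gte(auc, 0.9)
})

test_that("fate fractions reproduce printed percentages and always sum to 100", {
  # tracked-cell counts: 40 arrested in G2, 32 mothers completed mitosis
  ff <- fate_fractions(c(G2_arrest = 40, completed_mitosis = 32))
  expect_equal(ff$percent[ff$label == "G2_arrest"], 56)
  expect_equal(ff$percent[ff$label == "completed_mitosis"], 44)

  expect_equal(fate_fractions(rep("only", 7))$percent, 100)

  set.seed(71)
  for (i in 1:100) {
    k <- sample(2:6, 1)
    counts <- setNames(rmultinom(1, sample(20:500, 1), runif(k))[, 1],
                       paste0("l", 1:k))
    counts <- counts[counts > 0]
    if (length(counts) < 1) next
    expect_equal(sum(fate_fractions(counts)$percent), 100)
  }
  expect_error(fate_fractions(character(0)), class = "arrestmap_config_error")
})
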