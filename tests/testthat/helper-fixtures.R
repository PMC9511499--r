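# Shared fixtures, built in code at test time.

# tiny hand-written feature table
tiny_table <- function() {
  tibble::tibble(
    cell_id = c("c1", "c2", "c3"),
    condition = c("control", "control", "etoposide_d3"),
    replicate = "r1",
    dna_nucleus_integrated = c(100, 201.5, 398.25),
    p21_nucleus_median = c(10, 20, 1e-12)
  )
}

# small noiseless population (fast, deterministic)
noiseless_pop <- function(n = 600, seed = 2) {
  simulate_population(population_sim_config(n_cells = n, noise_cv = 0, seed = seed))
}

# random table for brute-force oracle comparisons
random_table <- function(n = 200, p = 4, seed = 9) {
  set.seed(seed)
  vals <- matrix(rexp(n * p, rate = 0.01), n, p)
  colnames(vals) <- paste0("f", seq_len(p))
  dplyr::bind_cols(
    tibble::tibble(
      cell_id = sprintf("r%04d", seq_len(n)),
      condition = sample(c("control", "treated"), n, replace = TRUE),
      replicate = "r1"
    ),
    tibble::as_tibble(vals)
  )
}

# mean silhouette width, brute force
cluster_silhouette <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  n <- nrow(coords)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(d[i, labels == l])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# noiseless trace set covering every fate archetype
noiseless_traces <- function(n = 40, seed = 5) {
  simulate_traces(trace_sim_config(
    n_traces = n,
    fate_mix = c(proliferative = 0.25, G2_arrest_4C = 0.25,
                 postmitotic_arrest_2C = 0.25, endoreduplication = 0.25),
    noise = list(cdk2 = 0, p21 = 0, dna = 0, foci_lambda = 0),
    seed = seed
  ))
}
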