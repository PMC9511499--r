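test_that("population config invariants are enforced", {
  expect_error(population_sim_config(state_mix = c(cycling = 0.5)),
               class = "arrestmap_config_error")
  expect_error(population_sim_config(noise_cv = -0.1),
               class = "arrestmap_config_error")
  expect_error(population_sim_config(raw_2c = 100, raw_4c = 300),
               class = "arrestmap_config_error")
  expect_error(population_sim_config(depth_range = c(0.5, 0.2)),
               class = "arrestmap_config_error")
})

test_that("zero-noise population equals its mean functions exactly", {
  pop <- noiseless_pop(n = 300)
  dyn <- default_marker_dynamics()
  cyc <- pop[pop$arrest_state == "cycling", ]
  mu <- dyn$cycling(cyc$latent_pseudotime)
  # intensity features match the mean functions exactly
  for (f in c("pcna_nucleus_median", "cyclin_b1_nucleus_median", "gsk3b_nucleus_median")) {
    expect_equal(cyc[[f]], unname(mu[, f]))
  }
  # DNA content is the C-unit mean scaled to raw intensity (raw_2c = 100)
  expect_equal(cyc$dna_nucleus_integrated, unname(mu[, "dna_nucleus_integrated"]) * 50)
  # RB ratio sits on the hyperphosphorylated mode for every cycler
  expect_true(all(cyc$rb_ratio_nucleus_ratio == dyn$rb_cycling))
  arr <- pop[pop$arrest_state != "cycling", ]
  expect_equal(arr$rb_ratio_nucleus_ratio, dyn$rb_arrest(arr$latent_pseudotime))
})

test_that("fixed seed gives bit-identical populations and traces", {
  p1 <- simulate_population(population_sim_config(n_cells = 400, seed = 77))
  p2 <- simulate_population(population_sim_config(n_cells = 400, seed = 77))
  expect_identical(p1, p2)
  t1 <- simulate_traces(trace_sim_config(n_traces = 10, seed = 3))
  t2 <- simulate_traces(trace_sim_config(n_traces = 10, seed = 3))
  expect_identical(t1, t2)
})

test_that("cycling DNA-content histogram has modes at the configured 2C/4C intensities", {
  cfg <- population_sim_config(n_cells = 20000, state_mix = c(cycling = 1),
                               seed = 11)
  pop <- simulate_population(cfg)
  pk <- detect_bimodal_peaks(pop$dna_nucleus_integrated)
  # oracle: modes of the generator's own mean values are the raw anchors
  expect_lt(abs(pk[["lo_peak"]] - cfg$raw_2c) / cfg$raw_2c, 0.02)
  expect_lt(abs(pk[["hi_peak"]] - cfg$raw_4c) / cfg$raw_4c, 0.02)
})

test_that("realized state fractions stay inside the binomial 99% CI", {
  # default mix: 56% of replication-stress arrests exit in G2 (4C)
  cfg <- population_sim_config(n_cells = 5000, seed = 13)
  pop <- simulate_population(cfg)
  rs <- pop$arrest_state %in% c("repstress_G0_2C", "repstress_G0_4C")
  p_4c <- 0.196 / (0.196 + 0.154)   # configured 56%
  n_rs <- sum(rs)
  realized <- mean(pop$arrest_state[rs] == "repstress_G0_4C")
  ci <- qnorm(0.995) * sqrt(p_4c * (1 - p_4c) / n_rs)
  expect_lt(abs(realized - p_4c), ci)
})

test_that("noisy marginals are log-normal around the mean functions", {
  pop <- simulate_population(population_sim_config(
    n_cells = 10000, state_mix = c(cycling = 1), noise_cv = 0.15, seed = 17
  ))
  # flat-mean marker: exact log-normal marginal (mode-anchored)
  x <- pop$gsk3b_nucleus_median
  sigma <- sqrt(log(1 + 0.15^2))
  ks <- suppressWarnings(
    stats::ks.test(x, stats::plnorm, meanlog = log(100), sdlog = sigma)
  )
  expect_gt(ks$p.value, 0.01)
})

test_that("trace archetypes carry the documented event structure", {
  traces <- noiseless_traces(n = 60)
  truth <- trace_truth(traces)

  endo <- traces[truth$fate == "endoreduplication"]
  for (tr in endo) {
    ev <- attr(tr, "s_phase")
    expect_equal(nrow(ev), 2)                      # exactly two S phases
    expect_length(attr(tr, "mitoses"), 0)          # and no mitosis
    expect_true(attr(tr, "dwell") >= 15 && attr(tr, "dwell") <= 30)
  }

  # noiseless G2 arrest: p21 onset coincides with CDK2 collapse (+- 1 frame)
  g2 <- traces[truth$fate == "G2_arrest_4C"][[1]]
  t_h <- g2$time_min / 60
  collapse <- t_h[which(g2$cdk2_activity < 0.5 & t_h > 5)[1]]
  p21_on <- t_h[which(g2$p21 > 50)[1]]
  expect_lte(abs(p21_on - collapse), 10 / 60 + 1e-9)

  # proliferative: CDK2 spans ~0.5 after mitosis to > 1 before, DNA halves
  pro <- traces[truth$fate == "proliferative"][[1]]
  m <- attr(pro, "mitoses")
  expect_gt(length(m), 0)
  i <- which.min(abs(pro$time_min / 60 - (m[1] - 0.2)))
  expect_gt(pro$cdk2_activity[i], 1)
  j <- which(pro$time_min / 60 >= m[1])[1]
  expect_lt(pro$dna_proxy[j] / pro$dna_proxy[j - 1], 0.6)
})

test_that("realized trace fate counts stay inside the multinomial 99% CI", {
  mix <- c(proliferative = 0.4, G2_arrest_4C = 0.3,
           postmitotic_arrest_2C = 0.2, endoreduplication = 0.1)
  traces <- simulate_traces(trace_sim_config(n_traces = 500, fate_mix = mix, seed = 23))
  counts <- table(trace_truth(traces)$fate)
  for (f in names(mix)) {
    ci <- qnorm(0.995) * sqrt(mix[[f]] * (1 - mix[[f]]) / 500)
    expect_lt(abs(counts[[f]] / 500 - mix[[f]]), ci)
  }
})

test_that("trace config guards reject impossible durations and mixes", {
  expect_error(trace_sim_config(duration_h = 40), class = "arrestmap_config_error")
  expect_error(trace_sim_config(fate_mix = c(proliferative = 0.7)),
               class = "arrestmap_config_error")
  expect_error(trace_sim_config(frame_interval_min = 0),
               class = "arrestmap_config_error")
  # no endoreduplication in the mix: short durations are fine
  expect_silent(trace_sim_config(duration_h = 40,
                                 fate_mix = c(proliferative = 0.5, G2_arrest_4C = 0.5)))
})

test_that("cell phantom renders exact geometry", {
  ph <- render_cell_image(nucleus_radius = 20, cell_radius = 45,
                          nuclear_intensity = 200, cytoplasm_intensity = 400,
                          background = 100, image_size = 101)
  # mask pixel count within 2% of pi r^2 (oracle: brute-force center distances)
  expect_lt(abs(sum(ph$nuclear_mask) - pi * 20^2) / (pi * 20^2), 0.02)
  # flat image when all intensities coincide
  flat <- render_cell_image(nuclear_intensity = 7, cytoplasm_intensity = 7,
                            background = 7)
  expect_true(all(flat$image == 7))
  # determinism
  ph2 <- render_cell_image(nucleus_radius = 20, cell_radius = 45,
                           nuclear_intensity = 200, cytoplasm_intensity = 400,
                           background = 100, image_size = 101)
  expect_identical(ph, ph2)
  # geometry guards
  expect_error(render_cell_image(nucleus_radius = 30, cell_radius = 45),
               class = "arrestmap_geometry_error")
  expect_error(render_cell_image(nucleus_radius = 20, cell_radius = 45,
                                 image_size = 80),
               class = "arrestmap_geometry_error")
})
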