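test_that("simulators are deterministic given a seed", {
  cfg <- bioassay_sim_config(2, 0.5, c(0.7, 1.4, 2.8))
  a <- simulate_bioassay(cfg, seed = 99)
  b <- simulate_bioassay(cfg, seed = 99)
  expect_identical(a$replicates, b$replicates)

  gcfg <- growth_sim_config(c(98.9, 86.6, 7.9), c(0.01, 0.04, 0.08),
                            c(1.6, 6.3, 1.9))
  ga <- simulate_growth_assay(gcfg, c(0.7, 3.5), seed = 5)
  gb <- simulate_growth_assay(gcfg, c(0.7, 3.5), seed = 5)
  expect_identical(ga$replicates, gb$replicates)
  # seeded calls leave the caller's RNG stream untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_bioassay(cfg, seed = 3)); after <- runif(1)
  expect_identical(before, after)
})

test_that("a very steep slope acts as a step function around the LC50", {
  cfg <- bioassay_sim_config(slope = 500, log_lc50 = 0,
                             concentrations = c(0.5, 2), replicates = 10)
  sim <- simulate_bioassay(cfg, seed = 2)
  reps <- sim$replicates
  expect_true(all(reps$mortality_pct[reps$concentration == 2] == 100))
  expect_true(all(reps$mortality_pct[reps$concentration == 0.5] == 0))
})

test_that("mortality at the LC50 averages 50% within binomial bounds", {
  cfg <- bioassay_sim_config(slope = 2, log_lc50 = log10(2),
                             concentrations = 2, control_mortality = 0,
                             n_per_replicate = 50, replicates = 200)
  sim <- simulate_bioassay(cfg, seed = 31)
  dead <- sim$replicates$n_dead[sim$replicates$concentration == 2]
  n_tot <- 200 * 50
  phat <- sum(dead) / n_tot
  half_width <- qnorm(0.995) * sqrt(0.25 / n_tot)
  expect_lt(abs(phat - 0.5), half_width)
})

test_that("expected mortality is non-decreasing in concentration", {
  cfg <- bioassay_sim_config(2.5, log10(1.8), seq(0.7, 3.5, by = 0.7),
                             n_per_replicate = 50, replicates = 40)
  sim <- simulate_bioassay(cfg, seed = 17)
  m <- aggregate(mortality_pct ~ concentration, data = sim$replicates, mean)
  m <- m[m$concentration > 0, ]
  expect_true(all(diff(m$mortality_pct) > -5)) # monotone up to noise
})

test_that("natural mortality is Abbott-invertible in expectation", {
  cfg <- bioassay_sim_config(2, log10(2), c(1, 2, 4),
                             control_mortality = 0.2,
                             n_per_replicate = 50, replicates = 200)
  sim <- simulate_bioassay(cfg, seed = 23)
  # aggregated series is Abbott-corrected by the realised control mortality;
  # corrected mortality at the LC50 should sit near 50%
  g <- sim$series$groups
  expect_lt(abs(g$mortality_pct[g$concentration == 2] - 50), 5)
})

test_that("growth simulation reduces to configured means at zero noise", {
  cfg <- growth_sim_config(c(98.9, 86.6, 7.9), c(0, 0, 0), c(0, 0, 0))
  sim <- simulate_growth_assay(cfg, concentrations = c(0.7, 3.5), seed = 1)
  out <- compatibility_report(sim$records)
  expect_equal(out$bi, c(100, 100))

  # inhibition placing the top dose 34% below control on every parameter
  # puts BI on the Moderately-Toxic boundary (weights sum to 100)
  cfg2 <- growth_sim_config(c(98.9, 86.6, 7.9), rep(0.34 / 3.5, 3),
                            c(0, 0, 0))
  sim2 <- simulate_growth_assay(cfg2, concentrations = 3.5, seed = 1)
  out2 <- compatibility_report(sim2$records)
  expect_equal(out2$bi, 66, tolerance = 1e-6)
  expect_equal(out2$bi_class, "Moderately Toxic")
})

test_that("germination is clipped to [0, 100] under heavy noise", {
  cfg <- growth_sim_config(c(98, 80, 7), c(0, 0, 0), c(30, 30, 5),
                           replicates = 50)
  sim <- simulate_growth_assay(cfg, concentrations = 1, seed = 9)
  expect_true(all(sim$replicates$germination_pct >= 0 &
                  sim$replicates$germination_pct <= 100))
  expect_true(all(sim$replicates$conidiation >= 0))
})

test_that("config validation names every offending field", {
  expect_error(bioassay_sim_config(-1, 0.5, c(1, 2), control_mortality = 2),
               "slope.*control_mortality")
  expect_error(growth_sim_config(c(98, 80, 7), c(-0.1, 0, 0), c(1, 1, 1)),
               "inhibition_per_unit")
})

test_that("mixture simulation carries coherent ground truth", {
  ca <- bioassay_sim_config(2.5, log10(3), seq(0.7, 3.5, by = 0.7))
  cb <- bioassay_sim_config(2.5, log10(3), seq(0.7, 3.5, by = 0.7))
  # identical components at p = 0.5: mixture LC50 equals the components'
  sim <- simulate_mixture_experiment(ca, cb, p_a = 0.5, interaction = 1,
                                     seed = 4)
  expect_equal(sim$truth$lc50_mix, 3)
  # interaction multiplier divides the additive expectation
  sim3 <- simulate_mixture_experiment(ca, cb, p_a = 0.5, interaction = 3,
                                      seed = 4)
  expect_equal(sim3$truth$lc50_mix, 1)
})

test_that("potentiated mixtures are recovered by the analysis chain", {
  ca <- bioassay_sim_config(2.5, log10(2), seq(0.7, 3.5, by = 0.7))
  cb <- bioassay_sim_config(2.0, log10(12), seq(4, 20, by = 4))
  idx <- vapply(1:30, function(i) {
    sim <- simulate_mixture_experiment(ca, cb, p_a = 0.6, interaction = 2,
                                       seed = 7000 + i)
    jt <- joint_toxicity(sim$series_a, sim$series_b, sim$series_mix,
                         p_a = 0.6, variant = "harmonic")
    jt$table$index[jt$table$primary]
  }, numeric(1))
  expect_lt(abs(median(idx) - 200) / 200, 0.2)
})
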