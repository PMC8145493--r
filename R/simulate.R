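#' Configuration for a simulated mortality bioassay
#'
#' Validated parameter set for [simulate_bioassay()]. Defaults mirror the
#' leaf-disk bioassay design the analysis assumes: 50 mites per leaf-disk,
#' five replicate disks per concentration.
#'
#' @param slope probit slope, per log10(mg/mL), > 0.
#' @param log_lc50 log10 of the true LC50, mg/mL.
#' @param concentrations positive concentration series, mg/mL.
#' @param control_mortality natural mortality proportion in \[0, 1).
#' @param n_per_replicate mites per replicate (default 50).
#' @param replicates replicate count per concentration (default 5).
#' @param time_profile optional named numeric vector of per-day fractions of
#'   the asymptotic kill probability (values in (0, 1\]), e.g.
#'   `c("2" = 0.5, "4" = 1)`; `NULL` simulates a single snapshot.
#' @return list of class `bioassay_sim_config`.
#' @examples
#' bioassay_sim_config(slope = 2, log_lc50 = 0.5,
#'                     concentrations = c(0.7, 1.4, 2.1, 2.8, 3.5))
#' @export
bioassay_sim_config <- function(slope, log_lc50, concentrations,
                                control_mortality = 0,
                                n_per_replicate = 50, replicates = 5,
                                time_profile = NULL) {
  bad <- character()
  if (!is.numeric(slope) || length(slope) != 1 || !is.finite(slope) ||
      slope <= 0) bad <- c(bad, "slope (positive scalar)")
  if (!is.numeric(log_lc50) || length(log_lc50) != 1 || !is.finite(log_lc50))
    bad <- c(bad, "log_lc50 (finite scalar)")
  if (!is.numeric(concentrations) || length(concentrations) < 1 ||
      any(!is.finite(concentrations)) || any(concentrations <= 0))
    bad <- c(bad, "concentrations (positive series)")
  if (!is.numeric(control_mortality) || length(control_mortality) != 1 ||
      control_mortality < 0 || control_mortality >= 1)
    bad <- c(bad, "control_mortality (proportion in [0, 1))")
  if (!is.numeric(n_per_replicate) || n_per_replicate < 1)
    bad <- c(bad, "n_per_replicate (positive count)")
  if (!is.numeric(replicates) || replicates < 1)
    bad <- c(bad, "replicates (positive count)")
  if (!is.null(time_profile) &&
      (!is.numeric(time_profile) || is.null(names(time_profile)) ||
       any(time_profile <= 0 | time_profile > 1)))
    bad <- c(bad, "time_profile (named fractions in (0, 1])")
  if (length(bad))
    abort("invalid bioassay_sim_config field(s): %s", paste(bad, collapse = "; "))
  structure(list(slope = slope, log_lc50 = log_lc50,
                 concentrations = sort(concentrations),
                 control_mortality = control_mortality,
                 n_per_replicate = as.integer(n_per_replicate),
                 replicates = as.integer(replicates),
                 time_profile = time_profile),
            class = "bioassay_sim_config")
}

#' Configuration for a simulated growth (compatibility) assay
#'
#' @param control_means named or positional numeric of length 3: control
#'   means for germination (%), vegetative growth (mm), conidiation.
#' @param inhibition_per_unit fractional decline of each mean per mg/mL
#'   (length 3, >= 0); the mean at concentration c is
#'   `control_mean * max(0, 1 - inhibition_per_unit * c)`.
#' @param noise_sd per-replicate normal standard deviations (length 3,
#'   >= 0).
#' @param replicates Petri dishes per concentration (default 10).
#' @return list of class `growth_sim_config`.
#' @examples
#' growth_sim_config(control_means = c(98.9, 86.6, 7.9),
#'                   inhibition_per_unit = c(0.01, 0.04, 0.08),
#'                   noise_sd = c(1.6, 6.3, 1.9))
#' @export
growth_sim_config <- function(control_means, inhibition_per_unit, noise_sd,
                              replicates = 10) {
  bad <- character()
  ok3 <- function(v) is.numeric(v) && length(v) == 3 && all(is.finite(v))
  if (!ok3(control_means) || any(control_means <= 0))
    bad <- c(bad, "control_means (3 positive values)")
  if (!ok3(inhibition_per_unit) || any(inhibition_per_unit < 0))
    bad <- c(bad, "inhibition_per_unit (3 non-negative values)")
  if (!ok3(noise_sd) || any(noise_sd < 0))
    bad <- c(bad, "noise_sd (3 non-negative values)")
  if (!is.numeric(replicates) || replicates < 1)
    bad <- c(bad, "replicates (positive count)")
  if (length(bad))
    abort("invalid growth_sim_config field(s): %s", paste(bad, collapse = "; "))
  structure(list(control_means = unname(control_means),
                 inhibition_per_unit = unname(inhibition_per_unit),
                 noise_sd = unname(noise_sd),
                 replicates = as.integer(replicates)),
            class = "growth_sim_config")
}

# run expr under a seeded, self-contained RNG stream, restoring the caller's
# stream afterwards so simulations never perturb unrelated randomness
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Simulate a quantal mortality bioassay
#'
#' Death counts per concentration and replicate are binomial with
#' probability `p = c + (1 - c) * pnorm(slope * (log10(conc) - log_lc50))`
#' where `c` is the control mortality: natural death acts as an independent
#' competing risk composed exactly as Abbott's correction assumes, so
#' [abbott_correct()] is its inverse in expectation. An untreated control
#' group (death probability `c`) is always included in the replicate table.
#'
#' @param config a [bioassay_sim_config()].
#' @param seed integer RNG seed; the same seed reproduces the table
#'   byte-for-byte. `NULL` continues the caller's RNG stream.
#' @param label series label.
#' @return list with `replicates` (data.frame: `time_d`, `concentration`
#'   (0 = control), `replicate`, `n_exposed`, `n_dead`, `mortality_pct`),
#'   `series` (a [bioassay_series()] pooled over replicates at the last
#'   time point, Abbott-corrected by the realised control mortality), and
#'   `truth` (the generating parameters).
#' @examples
#' cfg <- bioassay_sim_config(slope = 2, log_lc50 = 0.5,
#'                            concentrations = c(0.7, 1.4, 2.1, 2.8, 3.5))
#' sim <- simulate_bioassay(cfg, seed = 1)
#' sim$series
#' @export
simulate_bioassay <- function(config, seed = NULL, label = "simulated") {
  if (!inherits(config, "bioassay_sim_config"))
    abort("`config` must be a bioassay_sim_config")
  profile <- config$time_profile
  if (is.null(profile)) profile <- c("4" = 1)
  with_seed(seed, {
    rows <- list()
    for (ti in seq_along(profile)) {
      t_d <- as.numeric(names(profile)[ti])
      frac <- profile[[ti]]
      p_kill <- pnorm(config$slope *
                      (log10(config$concentrations) - config$log_lc50)) * frac
      p_all <- config$control_mortality +
        (1 - config$control_mortality) * c(0, p_kill) # first entry: control
      conc <- c(0, config$concentrations)
      for (ci in seq_along(conc)) {
        dead <- rbinom(config$replicates, config$n_per_replicate, p_all[ci])
        rows[[length(rows) + 1L]] <- data.frame(
          time_d = t_d, concentration = conc[ci],
          replicate = seq_len(config$replicates),
          n_exposed = config$n_per_replicate, n_dead = dead,
          mortality_pct = 100 * dead / config$n_per_replicate)
      }
    }
    reps <- do.call(rbind, rows)
    last_t <- max(reps$time_d)
    fin <- reps[reps$time_d == last_t, ]
    ctrl_pct <- 100 * sum(fin$n_dead[fin$concentration == 0]) /
      sum(fin$n_exposed[fin$concentration == 0])
    trt <- fin[fin$concentration > 0, ]
    pooled <- aggregate(cbind(n_exposed, n_dead) ~ concentration,
                        data = trt, sum)
    series <- bioassay_series(pooled$concentration,
                              mortality_pct = 100 * pooled$n_dead /
                                pooled$n_exposed,
                              n_exposed = pooled$n_exposed, label = label,
                              time_d = last_t,
                              control_mortality_pct = ctrl_pct)
    list(replicates = reps, series = series,
         truth = list(slope = config$slope, log_lc50 = config$log_lc50,
                      lc50 = 10^config$log_lc50,
                      control_mortality = config$control_mortality))
  })
}

#' Simulate a growth (compatibility) assay
#'
#' Replicate measurements are normal around linearly inhibited means;
#' germination is clipped to \[0, 100\] and the other parameters floored at
#' 0. Returns both the replicate table and the per-concentration means in
#' [growth_records()] form (including the control), ready for
#' [compatibility_report()].
#'
#' @param config a [growth_sim_config()].
#' @param concentrations positive toxin concentrations, mg/mL.
#' @param seed integer RNG seed (`NULL` = continue caller's stream).
#' @return list with `replicates` (data.frame: `concentration`, `replicate`,
#'   `germination_pct`, `vegetative_growth_mm`, `conidiation`) and `records`
#'   (mean [growth_records()] with the concentration-0 control row).
#' @examples
#' cfg <- growth_sim_config(c(98.9, 86.6, 7.9), c(0.01, 0.04, 0.08),
#'                          noise_sd = c(0, 0, 0))
#' simulate_growth_assay(cfg, concentrations = c(0.7, 3.5), seed = 1)$records
#' @export
simulate_growth_assay <- function(config, concentrations, seed = NULL) {
  if (!inherits(config, "growth_sim_config"))
    abort("`config` must be a growth_sim_config")
  check_numeric(concentrations, "concentrations")
  if (any(concentrations <= 0)) abort("`concentrations` must be > 0")
  conc <- c(0, sort(concentrations))
  with_seed(seed, {
    rows <- lapply(conc, function(cc) {
      mu <- config$control_means * pmax(0, 1 - config$inhibition_per_unit * cc)
      vals <- vapply(1:3, function(j)
        rnorm(config$replicates, mu[j], config$noise_sd[j]),
        numeric(config$replicates))
      vals <- matrix(vals, nrow = config$replicates)
      data.frame(concentration = cc, replicate = seq_len(config$replicates),
                 germination_pct = pmin(100, pmax(0, vals[, 1])),
                 vegetative_growth_mm = pmax(0, vals[, 2]),
                 conidiation = pmax(0, vals[, 3]))
    })
    reps <- do.call(rbind, rows)
    means <- aggregate(cbind(germination_pct, vegetative_growth_mm,
                             conidiation) ~ concentration,
                       data = reps, mean)
    records <- growth_records(means$concentration, means$germination_pct,
                              means$vegetative_growth_mm, means$conidiation)
    list(replicates = reps, records = records)
  })
}

#' Simulate a two-component mixture experiment
#'
#' Generates the three series a joint-toxicity analysis needs: each sole
#' component from its own config, and a mixture series on the
#' total-concentration scale whose true LC50 is the harmonic-additivity
#' expectation divided by the `interaction` multiplier (1 = additive,
#' > 1 potentiation, < 1 antagonism). The mixture's probit slope is the
#' category-weighted mean of the component slopes.
#'
#' @param config_a,config_b [bioassay_sim_config()] for the two components;
#'   their `concentrations` are the sole-application ladders (equal length).
#' @param p_a category weight of component A in (0, 1).
#' @param interaction positive interaction multiplier.
#' @param seed integer RNG seed.
#' @return list with `series_a`, `series_b`, `series_mix`
#'   ([bioassay_series()] objects) and `truth` (component LC50s, expected
#'   mixture LC50 under harmonic additivity, true mixture LC50, the
#'   interaction multiplier and `p_a`).
#' @examples
#' ca <- bioassay_sim_config(2.5, log10(3.4), seq(0.7, 3.5, by = 0.7))
#' cb <- bioassay_sim_config(2.0, log10(19), seq(4, 20, by = 4))
#' sim <- simulate_mixture_experiment(ca, cb, p_a = 0.8, interaction = 1,
#'                                    seed = 1)
#' sim$truth
#' @export
simulate_mixture_experiment <- function(config_a, config_b, p_a,
                                        interaction = 1, seed = NULL) {
  if (!inherits(config_a, "bioassay_sim_config") ||
      !inherits(config_b, "bioassay_sim_config"))
    abort("`config_a` and `config_b` must be bioassay_sim_config objects")
  if (length(p_a) != 1L || p_a <= 0 || p_a >= 1)
    abort("`p_a` must be a single proportion strictly in (0, 1)")
  if (!is.numeric(interaction) || length(interaction) != 1 || interaction <= 0)
    abort("`interaction` must be a positive scalar")
  if (length(config_a$concentrations) != length(config_b$concentrations))
    abort("component concentration ladders must have equal length")
  lc_a <- 10^config_a$log_lc50
  lc_b <- 10^config_b$log_lc50
  e_add <- expected_lc50(lc_a, lc_b, p_a, variant = "harmonic")
  lc_mix <- e_add / interaction
  slope_mix <- p_a * config_a$slope + (1 - p_a) * config_b$slope
  totals <- p_a * config_a$concentrations +
    (1 - p_a) * config_b$concentrations
  config_mix <- bioassay_sim_config(
    slope = slope_mix, log_lc50 = log10(lc_mix), concentrations = totals,
    control_mortality = config_a$control_mortality,
    n_per_replicate = config_a$n_per_replicate,
    replicates = config_a$replicates, time_profile = config_a$time_profile)
  with_seed(seed, {
    sa <- simulate_bioassay(config_a, seed = NULL, label = "component A")
    sb <- simulate_bioassay(config_b, seed = NULL, label = "component B")
    sm <- simulate_bioassay(config_mix, seed = NULL, label = "mixture")
    list(series_a = sa$series, series_b = sb$series, series_mix = sm$series,
         truth = list(lc50_a = lc_a, lc50_b = lc_b,
                      expected_lc50_harmonic = e_add, lc50_mix = lc_mix,
                      interaction = interaction, p_a = p_a))
  })
}
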