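# Shared fixture accessors: the packaged example study (growth means and
# 96-h mortality series for the toxin, the conidia and the four schemes).

example_growth <- function() {
  read_growth_csv(acaritox_example("growth_pinene.csv"))
}

example_series <- function(time_d = 4) {
  read_mortality_csv(acaritox_example("mortality_mite.csv"), time_d = time_d)
}

example_reference <- function() {
  read.csv(acaritox_example("reference_joint_toxicity.csv"),
           stringsAsFactors = FALSE)
}

# noiseless series lying exactly on a probit line: mortality evaluated from
# the model itself, so both fitters must recover the parameters exactly
model_series <- function(slope = 2, log_lc50 = 0.5,
                         conc = c(0.8, 1.6, 3.2, 6.4, 12.8), n = 250) {
  p <- pnorm(slope * (log10(conc) - log_lc50))
  bioassay_series(conc, mortality_pct = 100 * p, n_exposed = n,
                  label = "noiseless model")
}
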