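#' Build a proportional two-component mixture design
#'
#' A mixture scheme pairs, at each concentration level, a fraction `p_a` of
#' component A's sole-application concentration ladder with the
#' complementary fraction `1 - p_a` of component B's ladder. These
#' "category weights" are fractions of each component's own ladder, not
#' mass fractions of the resulting mixture; the realised mass fraction of A
#' is reported per level as `mass_frac_a`.
#'
#' @param p_a category weight of component A, strictly in (0, 1).
#' @param base_a,base_b sole-component concentration ladders (equal length,
#'   positive, increasing), mg/mL.
#' @param label scheme name.
#' @return object of class `mixture_scheme`: list with `p_a`, `p_b`,
#'   `label` and a `levels` data.frame (`level`, `conc_a`, `conc_b`,
#'   `total_conc`, `mass_frac_a`).
#' @examples
#' design_scheme(0.2, base_a = seq(0.7, 3.5, by = 0.7),
#'               base_b = seq(4, 20, by = 4))
#' @export
design_scheme <- function(p_a, base_a, base_b, label = NULL) {
  check_numeric(p_a, "p_a")
  if (length(p_a) != 1L || p_a <= 0 || p_a >= 1)
    abort("`p_a` must be a single proportion strictly in (0, 1)")
  check_numeric(base_a, "base_a")
  check_numeric(base_b, "base_b")
  if (length(base_a) != length(base_b))
    abort("`base_a` and `base_b` must have equal length")
  if (any(base_a <= 0) || any(base_b <= 0))
    abort("base series entries must be > 0")
  if (is.unsorted(base_a, strictly = TRUE) ||
      is.unsorted(base_b, strictly = TRUE))
    abort("base series must be strictly increasing")
  conc_a <- p_a * base_a
  conc_b <- (1 - p_a) * base_b
  lv <- data.frame(level = seq_along(base_a), conc_a = conc_a,
                   conc_b = conc_b, total_conc = conc_a + conc_b,
                   mass_frac_a = conc_a / (conc_a + conc_b))
  if (is.null(label))
    label <- sprintf("%d%% A : %d%% B", round(100 * p_a), round(100 * (1 - p_a)))
  structure(list(p_a = p_a, p_b = 1 - p_a, label = label, levels = lv),
            class = "mixture_scheme")
}

#' @export
print.mixture_scheme <- function(x, ...) {
  cat(sprintf("Mixture scheme '%s' (category weights %.2g : %.2g)\n",
              x$label, x$p_a, x$p_b))
  print(x$levels, ...)
  invisible(x)
}

#' Built-in mixture scheme presets
#'
#' The four standard toxin:conidia combination schemes used in date palm
#' dust mite joint-toxicity bioassays, built on the sole-application
#' ladders 0.7-3.5 mg/mL ((+)-alpha-pinene, steps of 0.7) and 4-20 mg/mL
#' (conidia, steps of 4): Scheme I = 20:80, II = 40:60, III = 60:40,
#' IV = 80:20 toxin:conidia category weights.
#'
#' @return named list of four [design_scheme()] objects ("I".."IV").
#' @examples
#' scheme_presets()$IV$levels
#' @export
scheme_presets <- function() {
  base_a <- seq(0.7, 3.5, by = 0.7)
  base_b <- seq(4, 20, by = 4)
  w <- c(I = 0.2, II = 0.4, III = 0.6, IV = 0.8)
  out <- lapply(names(w), function(s)
    design_scheme(w[[s]], base_a, base_b,
                  label = sprintf("Scheme %s: %d%% toxin : %d%% conidia",
                                  s, round(100 * w[[s]]),
                                  round(100 * (1 - w[[s]])))))
  names(out) <- names(w)
  out
}

#' Expected mixture LC50 under additivity
#'
#' Two additivity conventions are implemented:
#' \describe{
#'   \item{`"harmonic"`}{the standard co-toxicity expectation (harmonic
#'     additivity): `1/E = p_a/LC50_a + (1 - p_a)/LC50_b`. Satisfies the
#'     pure-component identity (`p_a = 1` returns `LC50_a`) and always lies
#'     between the two component LC50s.}
#'   \item{`"swapped"`}{harmonic additivity with the proportions exchanged:
#'     `E = (LC50_a * LC50_b) / (p_a * LC50_a + (1 - p_a) * LC50_b)`. This
#'     is the convention in use in fungus-metabolite joint-toxicity studies
#'     of date palm mites and is the variant that reproduces their reported
#'     indices. Note it violates the pure-component identity (`p_a = 1`
#'     returns `LC50_b`-weighted nonsense, not `LC50_a`); a warning is
#'     issued at the endpoints.}
#' }
#'
#' @param lc50_a,lc50_b sole-component LC50s, mg/mL, > 0.
#' @param p_a category weight of component A in \[0, 1\].
#' @param variant `"harmonic"` (default) or `"swapped"`.
#' @return expected mixture LC50, mg/mL.
#' @examples
#' expected_lc50(3.41, 19.16, p_a = 0.8, variant = "swapped")
#' @export
expected_lc50 <- function(lc50_a, lc50_b, p_a,
                          variant = c("harmonic", "swapped")) {
  variant <- match.arg(variant)
  check_numeric(lc50_a, "lc50_a")
  check_numeric(lc50_b, "lc50_b")
  check_numeric(p_a, "p_a")
  if (any(lc50_a <= 0) || any(lc50_b <= 0)) abort("LC50s must be > 0")
  if (any(p_a < 0 | p_a > 1)) abort("`p_a` must lie in [0, 1]")
  if (variant == "swapped") {
    if (any(p_a %in% c(0, 1)))
      warning("swapped variant does not satisfy the pure-component identity ",
              "at p_a = 0 or 1", call. = FALSE)
    lc50_a * lc50_b / (p_a * lc50_a + (1 - p_a) * lc50_b)
  } else {
    1 / (p_a / lc50_a + (1 - p_a) / lc50_b)
  }
}

#' Joint-toxicity index
#'
#' `100 * expected / observed`: the ratio of the additivity-expected mixture
#' LC50 to the observed one, on the x100 scale. Values at or above 100
#' indicate the mixture killed at least as efficiently as additivity
#' predicts (synergism); below 100, antagonism.
#'
#' @param expected additivity-expected mixture LC50, mg/mL, > 0.
#' @param observed observed (fitted) mixture LC50, mg/mL, > 0.
#' @return unrounded index; use [round_half_up()] for presentation.
#' @examples
#' joint_toxicity_index(9.96, 1.32)
#' @export
joint_toxicity_index <- function(expected, observed) {
  check_numeric(expected, "expected")
  check_numeric(observed, "observed")
  if (any(expected <= 0)) abort("`expected` must be > 0")
  if (any(observed <= 0)) abort("`observed` must be > 0")
  100 * expected / observed
}

#' Classify a joint-toxicity index
#'
#' Index >= 100 is Synergistic (boundary inclusive), < 100 Antagonistic.
#'
#' @param index finite positive joint-toxicity index value(s).
#' @return character vector: "Synergistic" or "Antagonistic".
#' @examples
#' classify_interaction(c(58, 100, 755))
#' @export
classify_interaction <- function(index) {
  check_numeric(index, "index")
  if (any(index <= 0)) abort("`index` must be > 0")
  ifelse(index >= 100, "Synergistic", "Antagonistic")
}

#' Full joint-toxicity analysis of a two-component mixture
#'
#' Fits probit models to the two sole-component series and the mixture
#' series, computes the additivity-expected mixture LC50 under both
#' variants, the joint-toxicity index and its classification.
#'
#' @param series_a,series_b sole-component [bioassay_series()].
#' @param series_mix mixture [bioassay_series()] on the total-concentration
#'   scale.
#' @param p_a category weight of component A, in (0, 1).
#' @param variant primary additivity variant for the reported index
#'   (`"harmonic"` or `"swapped"`); results for both are embedded.
#' @param method probit fitting method, see [fit_probit()].
#' @return object of class `joint_toxicity`: list with `lc50_a`, `lc50_b`,
#'   `lc50_mix` ([lc50_with_limits()] objects), `p_a`, `variant`, and a
#'   `table` data.frame with one row per variant (`expected_lc50`, `index`,
#'   `index_rounded`, `classification`, `primary`).
#' @examples
#' sa <- bioassay_series(c(0.7, 1.4, 2.1, 2.8, 3.5),
#'                       mortality_pct = c(12.4, 21.6, 28.8, 42.4, 56.8),
#'                       label = "toxin")
#' sb <- bioassay_series(c(4, 8, 12, 16, 20),
#'                       mortality_pct = c(15.6, 20.8, 32.4, 44.4, 56.4),
#'                       label = "conidia")
#' sm <- bioassay_series(c(1.36, 2.72, 4.08, 5.44, 6.8),
#'                       mortality_pct = c(51.6, 88, 94.8, 98.8, 99.2),
#'                       label = "80:20 mixture")
#' joint_toxicity(sa, sb, sm, p_a = 0.8, variant = "swapped")
#' @export
joint_toxicity <- function(series_a, series_b, series_mix, p_a,
                           variant = c("harmonic", "swapped"),
                           method = "ml") {
  variant <- match.arg(variant)
  if (length(p_a) != 1L || p_a <= 0 || p_a >= 1)
    abort("`p_a` must be a single proportion strictly in (0, 1)")
  fits <- lapply(list(a = series_a, b = series_b, mix = series_mix),
                 function(s) {
    tryCatch(lc50_with_limits(fit_probit(s, method = method)),
             error = function(e)
               abort("fitting series '%s' failed: %s", s$label,
                     conditionMessage(e)))
  })
  la <- fits$a$lc50; lb <- fits$b$lc50; lm_ <- fits$mix$lc50
  tab <- do.call(rbind, lapply(c("harmonic", "swapped"), function(v) {
    e <- expected_lc50(la, lb, p_a, variant = v)
    idx <- joint_toxicity_index(e, lm_)
    data.frame(variant = v, expected_lc50 = e, index = idx,
               index_rounded = round_half_up(idx),
               classification = classify_interaction(idx),
               primary = v == variant)
  }))
  structure(list(lc50_a = fits$a, lc50_b = fits$b, lc50_mix = fits$mix,
                 p_a = p_a, variant = variant, table = tab),
            class = "joint_toxicity")
}

#' @export
print.joint_toxicity <- function(x, ...) {
  pr <- x$table[x$table$primary, ]
  cat(sprintf("Joint toxicity (p_a = %.2g, variant = %s)\n", x$p_a, x$variant))
  cat(sprintf("  LC50 A = %.4g, B = %.4g, mixture = %.4g mg/mL\n",
              x$lc50_a$lc50, x$lc50_b$lc50, x$lc50_mix$lc50))
  cat(sprintf("  expected LC50 = %.4g mg/mL, index = %.1f (%d): %s\n",
              pr$expected_lc50, pr$index, pr$index_rounded,
              pr$classification))
  invisible(x)
}
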