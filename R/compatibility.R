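#' Express a treated measurement as a percentage of its control
#'
#' The normalisation underlying the Biological Index: each growth parameter
#' of the toxin-exposed fungus is expressed relative to the untreated
#' (solvent-only) control mean. Values above 100 are not clipped; a treated
#' value exceeding its control simply reports > 100%.
#'
#' @param treated non-negative measurement(s) under toxin exposure.
#' @param control positive control measurement (same units as `treated`).
#' @return `100 * treated / control`, a percentage.
#' @seealso [inhibition_percent()], its complement to 100.
#' @examples
#' relative_percent(98.0, 98.9)
#' @export
relative_percent <- function(treated, control) {
  check_numeric(treated, "treated")
  check_numeric(control, "control")
  if (any(control <= 0)) abort("`control` must be > 0 (got %s)", min(control))
  if (any(treated < 0)) abort("`treated` must be >= 0")
  100 * treated / control
}

#' Percent inhibition relative to control
#'
#' `100 * (control - treated) / control`. Negative values (stimulation above
#' the control) are reported as-is.
#'
#' @inheritParams relative_percent
#' @return percent inhibition.
#' @examples
#' inhibition_percent(98.9, 95.2) # germination inhibition at the top dose
#' @export
inhibition_percent <- function(control, treated) {
  check_numeric(treated, "treated")
  check_numeric(control, "control")
  if (any(control <= 0)) abort("`control` must be > 0 (got %s)", min(control))
  100 * (control - treated) / control
}

#' Biological Index of fungus-toxin compatibility
#'
#' Weighted combination of the three fungal growth parameters, each
#' expressed as percent of control: vegetative growth (VG, weight 47),
#' conidiation (SP, weight 43) and conidial germination (GR, weight 10):
#' \deqn{BI = (47 \cdot VG + 43 \cdot SP + 10 \cdot GR) / 100}
#' The weights sum to 100, so equal inputs are returned unchanged
#' (`biological_index(x, x, x) == x`).
#'
#' @param gr_rel germination as percent of control, >= 0.
#' @param vg_rel vegetative (radial) growth as percent of control, >= 0.
#' @param sp_rel conidiation as percent of control, >= 0.
#' @return the unrounded Biological Index. Use [round_half_up()] for the
#'   integer presentation value.
#' @examples
#' biological_index(gr_rel = 99.09, vg_rel = 98.61, sp_rel = 91.14)
#' @export
biological_index <- function(gr_rel, vg_rel, sp_rel) {
  for (nm in c("gr_rel", "vg_rel", "sp_rel")) {
    v <- get(nm)
    check_numeric(v, nm)
    if (any(v < 0)) abort("`%s` must be >= 0", nm)
  }
  (47 * vg_rel + 43 * sp_rel + 10 * gr_rel) / 100
}

#' Classify a Biological Index value
#'
#' Conventional compatibility bands: BI > 66 is Compatible, 42 <= BI <= 66
#' Moderately Toxic, BI < 42 Toxic. The middle band is closed at both ends.
#'
#' @param bi finite Biological Index value(s).
#' @return character vector: "Compatible", "Moderately Toxic" or "Toxic".
#' @examples
#' classify_compatibility(c(95, 66, 41.9))
#' @export
classify_compatibility <- function(bi) {
  check_numeric(bi, "bi")
  ifelse(bi > 66, "Compatible",
         ifelse(bi >= 42, "Moderately Toxic", "Toxic"))
}

#' Assemble growth-assay records
#'
#' Builds the validated per-concentration table of fungal growth parameters
#' consumed by [compatibility_report()]. Exactly one row must be the control
#' (concentration 0).
#'
#' @param concentration toxin concentration, mg/mL; 0 marks the control row.
#' @param germination_pct percent conidial germination, in \[0, 100\].
#' @param vegetative_growth_mm colony radial length, mm, >= 0.
#' @param conidiation conidia per mL (any consistent unit, e.g. x 1e7), >= 0.
#' @return a `data.frame` of class `growth_records`.
#' @examples
#' growth_records(c(0, 0.7), c(98.9, 98.0), c(86.6, 85.4), c(7.9, 7.2))
#' @export
growth_records <- function(concentration, germination_pct,
                           vegetative_growth_mm, conidiation) {
  check_numeric(concentration, "concentration")
  check_numeric(germination_pct, "germination_pct")
  check_numeric(vegetative_growth_mm, "vegetative_growth_mm")
  check_numeric(conidiation, "conidiation")
  n <- length(concentration)
  if (length(germination_pct) != n || length(vegetative_growth_mm) != n ||
      length(conidiation) != n)
    abort("all growth-record columns must have the same length")
  if (any(concentration < 0)) abort("`concentration` must be >= 0")
  if (any(germination_pct < 0 | germination_pct > 100))
    abort("`germination_pct` must lie in [0, 100]")
  if (any(vegetative_growth_mm < 0) || any(conidiation < 0))
    abort("growth measurements must be non-negative")
  out <- data.frame(concentration = concentration,
                    germination_pct = germination_pct,
                    vegetative_growth_mm = vegetative_growth_mm,
                    conidiation = conidiation)
  class(out) <- c("growth_records", "data.frame")
  out
}

#' Compatibility report: relative growth, Biological Index, classification
#'
#' For each treated concentration, expresses germination, vegetative growth
#' and conidiation as percent of the control row, computes the Biological
#' Index and classifies it. Results are ordered by concentration.
#'
#' @param records a `growth_records` table (or plain data.frame with the
#'   same columns) containing exactly one control row (concentration 0) and
#'   at least one treated row.
#' @param round_bi logical; if `TRUE` (default) `bi` additionally reported
#'   rounded half-away-from-zero to integer in column `bi_rounded`.
#' @return data.frame with columns `concentration`, `gr_rel`, `vg_rel`,
#'   `sp_rel`, `bi`, `bi_rounded` (if requested) and `bi_class`.
#' @examples
#' rec <- growth_records(c(0, 0.7, 3.5),
#'                       c(98.9, 98.0, 95.2),
#'                       c(86.6, 85.4, 74.2),
#'                       c(7.9, 7.2, 5.3))
#' compatibility_report(rec)
#' @export
compatibility_report <- function(records, round_bi = TRUE) {
  req <- c("concentration", "germination_pct", "vegetative_growth_mm",
           "conidiation")
  if (!all(req %in% names(records)))
    abort("`records` must have columns %s", paste(req, collapse = ", "))
  is_control <- records$concentration == 0
  if (sum(is_control) != 1L)
    abort("exactly one control row (concentration 0) required, found %d",
          sum(is_control))
  if (sum(!is_control) < 1L) abort("at least one treated row required")
  ctrl <- records[is_control, ]
  trt <- records[!is_control, , drop = FALSE]
  trt <- trt[order(trt$concentration), , drop = FALSE]

  gr <- relative_percent(trt$germination_pct, ctrl$germination_pct)
  vg <- relative_percent(trt$vegetative_growth_mm, ctrl$vegetative_growth_mm)
  sp <- relative_percent(trt$conidiation, ctrl$conidiation)
  bi <- biological_index(gr_rel = gr, vg_rel = vg, sp_rel = sp)

  out <- data.frame(concentration = trt$concentration,
                    gr_rel = gr, vg_rel = vg, sp_rel = sp, bi = bi)
  if (round_bi) out$bi_rounded <- round_half_up(bi)
  out$bi_class <- classify_compatibility(bi)
  rownames(out) <- NULL
  out
}
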