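growth_cols <- c("concentration", "germination_pct", "vegetative_growth_mm",
                 "conidiation")
mortality_cols <- c("treatment", "component_a_conc", "component_b_conc",
                    "total_conc", "time_d", "n_exposed", "mortality_pct")

read_checked_csv <- function(path, required, numeric_cols) {
  if (!file.exists(path)) abort("input file not found: %s", path)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) abort("cannot parse %s: %s", path,
                                           conditionMessage(e)))
  missing <- setdiff(required, names(df))
  if (length(missing))
    abort("%s: missing column(s) %s", path, paste(missing, collapse = ", "))
  if (nrow(df) == 0) abort("%s: no data rows", path)
  for (col in numeric_cols) {
    v <- df[[col]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      abort("%s: non-numeric value in column '%s', row %d", path, col, bad[1])
    if (anyNA(v))
      abort("%s: missing value in column '%s', row %d", path, col,
            which(is.na(v))[1])
    df[[col]] <- v
  }
  df
}

#' Read a growth-assay CSV
#'
#' Expected columns: `concentration`, `germination_pct`,
#' `vegetative_growth_mm`, `conidiation`; the control row is encoded as
#' concentration 0 and must occur exactly once.
#'
#' @param path CSV file path.
#' @return a [growth_records()] table.
#' @examples
#' read_growth_csv(acaritox_example("growth_pinene.csv"))
#' @export
read_growth_csv <- function(path) {
  df <- read_checked_csv(path, growth_cols, growth_cols)
  if (sum(df$concentration == 0) != 1L)
    abort("%s: exactly one control row (concentration 0) required, found %d",
          path, sum(df$concentration == 0))
  growth_records(df$concentration, df$germination_pct,
                 df$vegetative_growth_mm, df$conidiation)
}

#' Write a growth-assay CSV
#'
#' @param records a [growth_records()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_growth_csv <- function(records, path) {
  write.csv(as.data.frame(records)[growth_cols], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read a mortality CSV into bioassay series
#'
#' Expected columns: `treatment`, `component_a_conc`, `component_b_conc`,
#' `total_conc`, `time_d`, `n_exposed`, `mortality_pct`. Rows are grouped
#' into one [bioassay_series()] per treatment x time point.
#'
#' @param path CSV file path.
#' @param time_d optional; keep only this post-exposure duration (days).
#' @param control_mortality_pct control mortality applied as Abbott
#'   correction to every series (default 0: data already corrected).
#' @return named list of [bioassay_series()]; names are
#'   `"<treatment>@<time>d"` when several time points are present,
#'   otherwise the treatment names.
#' @examples
#' series <- read_mortality_csv(acaritox_example("mortality_mite.csv"),
#'                              time_d = 4)
#' names(series)
#' @export
read_mortality_csv <- function(path, time_d = NULL,
                               control_mortality_pct = 0) {
  num <- setdiff(mortality_cols, "treatment")
  df <- read_checked_csv(path, mortality_cols, num)
  if (any(df$mortality_pct < 0 | df$mortality_pct > 100))
    abort("%s: mortality_pct outside [0, 100] in row %d", path,
          which(df$mortality_pct < 0 | df$mortality_pct > 100)[1])
  if (any(df$total_conc <= 0))
    abort("%s: total_conc must be > 0 (row %d)", path,
          which(df$total_conc <= 0)[1])
  if (any(abs(df$component_a_conc + df$component_b_conc - df$total_conc) >
          1e-6))
    abort("%s: component concentrations do not sum to total_conc (row %d)",
          path,
          which(abs(df$component_a_conc + df$component_b_conc -
                    df$total_conc) > 1e-6)[1])
  if (!is.null(time_d)) {
    df <- df[df$time_d %in% time_d, , drop = FALSE]
    if (nrow(df) == 0) abort("%s: no rows at time_d = %s", path, time_d)
  }
  keys <- unique(df[c("treatment", "time_d")])
  single_time <- length(unique(keys$time_d)) == 1L
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$treatment == keys$treatment[i] &
              df$time_d == keys$time_d[i], ]
    bioassay_series(sub$total_conc, mortality_pct = sub$mortality_pct,
                    n_exposed = sub$n_exposed, label = keys$treatment[i],
                    time_d = keys$time_d[i],
                    control_mortality_pct = control_mortality_pct)
  })
  names(out) <- if (single_time) keys$treatment
                else sprintf("%s@%gd", keys$treatment, keys$time_d)
  out
}

#' Write bioassay series to a mortality CSV
#'
#' Inverse of [read_mortality_csv()] for single-component series (component
#' split columns are written as the total in `component_a_conc` with
#' `component_b_conc = 0` unless `split` supplies per-series proportions of
#' component A).
#'
#' @param series_list named list of [bioassay_series()].
#' @param path output path.
#' @param split optional numeric vector (recycled) of component-A fractions
#'   of the total concentration per series.
#' @return `path`, invisibly.
#' @export
write_mortality_csv <- function(series_list, path, split = 1) {
  split <- rep_len(split, length(series_list))
  rows <- lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    g <- s$groups
    data.frame(treatment = s$label,
               component_a_conc = split[i] * g$concentration,
               component_b_conc = (1 - split[i]) * g$concentration,
               total_conc = g$concentration, time_d = s$time_d,
               n_exposed = g$n_exposed, mortality_pct = g$mortality_pct)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Path to a packaged example dataset
#'
#' With no argument, lists the available files. The bundled set covers a
#' fungus-toxin study of *B. bassiana* conidia combined with
#' (+)-alpha-pinene against date palm dust mites: `growth_pinene.csv`
#' (growth-assay means), `mortality_mite.csv` (cumulative percent mortality
#' per treatment, concentration and exposure time) and
#' `reference_joint_toxicity.csv` (the accompanying LC50 and joint-toxicity
#' summary used in regression tests).
#'
#' @param file file name, e.g. `"growth_pinene.csv"`.
#' @return full path (or vector of available file names).
#' @examples
#' acaritox_example()
#' @export
acaritox_example <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "acaritox")))
  path <- system.file("extdata", file, package = "acaritox")
  if (path == "") abort("no packaged example file '%s'", file)
  path
}

#' Run the full compatibility / LC50 / joint-toxicity report
#'
#' End-to-end analysis: compatibility report from the growth CSV, probit
#' LC50 table for every series in the mortality CSV at the chosen time
#' point, and a joint-toxicity table for each mixture scheme (series whose
#' treatment name matches `scheme_pattern`, with the category weight parsed
#' from `scheme_weights`). Writes three CSVs to `out_dir` and returns the
#' tables invisibly. Progress and the defaults in effect are logged to
#' standard error.
#'
#' @param growth_csv path to a growth-assay CSV (or `NULL` to skip).
#' @param mortality_csv path to a mortality CSV (or `NULL` to skip).
#' @param out_dir output directory (created if needed).
#' @param time_d post-exposure duration to analyse (days, default 4).
#' @param method probit method (`"ml"` or `"ols"`).
#' @param variant additivity variant for the reported joint-toxicity index.
#' @param control_mortality_pct Abbott-correction control mortality.
#' @param scheme_weights named numeric: category weight of component A per
#'   mixture treatment name; defaults to the four standard schemes.
#' @param component_a,component_b treatment names of the sole-component
#'   series used as mixture references.
#' @return invisibly, a list with `compatibility`, `lc50` and
#'   `joint_toxicity` data.frames (entries `NULL` where skipped).
#' @examples
#' out <- run_report(acaritox_example("growth_pinene.csv"),
#'                   acaritox_example("mortality_mite.csv"),
#'                   out_dir = tempfile("report"), variant = "swapped")
#' out$joint_toxicity
#' @export
run_report <- function(growth_csv = NULL, mortality_csv = NULL,
                       out_dir = ".", time_d = 4, method = "ml",
                       variant = c("harmonic", "swapped"),
                       control_mortality_pct = 0,
                       scheme_weights = c(scheme_I = 0.2, scheme_II = 0.4,
                                          scheme_III = 0.6, scheme_IV = 0.8),
                       component_a = "pinene", component_b = "conidia") {
  variant <- match.arg(variant)
  if (is.null(growth_csv) && is.null(mortality_csv))
    abort("nothing to do: supply `growth_csv` and/or `mortality_csv`")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_msg <- function(...) message(sprintf(...))
  log_msg("report defaults: time_d = %g, method = %s, variant = %s, control mortality = %g%%",
          time_d, method, variant, control_mortality_pct)

  compat <- lc50_tab <- jt_tab <- NULL
  if (!is.null(growth_csv)) {
    compat <- compatibility_report(read_growth_csv(growth_csv))
    write.csv(compat, file.path(out_dir, "compatibility_report.csv"),
              row.names = FALSE, quote = FALSE)
    log_msg("compatibility report: %d concentrations", nrow(compat))
  }
  if (!is.null(mortality_csv)) {
    series <- read_mortality_csv(mortality_csv, time_d = time_d,
                                 control_mortality_pct = control_mortality_pct)
    ests <- lapply(series, function(s)
      lc50_with_limits(fit_probit(s, method = method)))
    lc50_tab <- do.call(rbind, lapply(names(ests), function(nm) {
      e <- ests[[nm]]; f <- e$fit
      data.frame(treatment = nm, time_d = f$series$time_d, slope = f$slope,
                 intercept = f$intercept, lc50 = e$lc50, lower = e$lower,
                 upper = e$upper, chi2_het = f$chi2_het, df = f$df,
                 method = f$method)
    }))
    write.csv(lc50_tab, file.path(out_dir, "lc50_table.csv"),
              row.names = FALSE, quote = FALSE)
    log_msg("LC50 table: %d series fitted", nrow(lc50_tab))

    have <- intersect(names(scheme_weights), names(ests))
    if (length(have) && all(c(component_a, component_b) %in% names(ests))) {
      la <- ests[[component_a]]$lc50
      lb <- ests[[component_b]]$lc50
      jt_tab <- do.call(rbind, lapply(have, function(nm) {
        p_a <- scheme_weights[[nm]]
        lmix <- ests[[nm]]$lc50
        e <- expected_lc50(la, lb, p_a, variant = variant)
        idx <- joint_toxicity_index(e, lmix)
        data.frame(scheme = nm, p_a = p_a, lc50_a = la, lc50_b = lb,
                   lc50_mix = lmix, expected_lc50 = e, index = idx,
                   index_rounded = round_half_up(idx),
                   classification = classify_interaction(idx),
                   variant = variant)
      }))
      write.csv(jt_tab, file.path(out_dir, "joint_toxicity.csv"),
                row.names = FALSE, quote = FALSE)
      log_msg("joint toxicity: %d schemes (%s variant)", nrow(jt_tab),
              variant)
    }
  }
  invisible(list(compatibility = compat, lc50 = lc50_tab,
                 joint_toxicity = jt_tab))
}
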