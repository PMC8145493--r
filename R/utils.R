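#' Round half away from zero
#'
#' Commercial rounding as used for presentation values throughout the
#' package: ties are rounded away from zero, so \code{round_half_up(0.5)} is
#' 1, unlike \code{\link[base]{round}} which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep (default 0).
#' @return numeric vector of the same length as \code{x}.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.5, -0.5))
#' @export
round_half_up <- function(x, digits = 0L) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# stop() with call. = FALSE and sprintf-style formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_numeric <- function(x, name, finite = TRUE) {
  if (!is.numeric(x)) abort("`%s` must be numeric", name)
  if (finite && any(!is.finite(x))) abort("`%s` must be finite", name)
  invisible(x)
}
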