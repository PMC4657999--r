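# Small shared helpers: sequence canonicalization and number rendering.

#' Canonicalize a nucleotide sequence to uppercase RNA (U-form)
#'
#' T and U are interchangeable on input; internally every sequence is stored
#' uppercase with U.
#'
#' @param x character vector of nucleotide sequences (A/C/G/U/T, any case).
#' @return character vector, uppercase, T replaced by U.
#' @export
canonical_rna <- function(x) {
  x <- toupper(as.character(x))
  bad <- grepl("[^ACGUT]", x)
  if (any(bad)) {
    stop("non-nucleotide characters in sequence(s): ",
         paste(utils::head(x[bad], 3L), collapse = ", "))
  }
  chartr("T", "U", x)
}

#' Render a ratio as a percentage at a fixed number of decimals
#'
#' `method = "round"` rounds half away from zero (e.g. 51/95 -> 53.68);
#' `method = "truncate"` drops the trailing digits, the convention used by
#' the read-accounting tables this package mirrors (e.g. 52.3969 -> 52.39).
#'
#' @param num,den numerators and denominators.
#' @param digits decimals to render (default 2).
#' @param method "round" (default) or "truncate".
#' @return numeric vector of rendered percentages.
#' @export
percent_of <- function(num, den, digits = 2,
                       method = c("round", "truncate")) {
  method <- match.arg(method)
  pct <- 100 * num / den
  if (method == "round") return(round_half_up(pct, digits))
  trunc(pct * 10^digits) / 10^digits
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; fixed-decimal renderings of reported
#' percentages use the conventional half-up rule instead.
#'
#' @param x numeric vector.
#' @param digits decimals.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# stop() with a consistent prefix for input validation failures
.fail <- function(...) stop(..., call. = FALSE)

# assert helper: all(cond) or fail with message
.check <- function(cond, ...) {
  if (!all(cond)) .fail(...)
  invisible(TRUE)
}
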