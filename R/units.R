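#' Unit system for concentration conversion
#'
#' Observed infliximab concentrations are reported in mg/L while the model
#' operates on molar concentrations (nM), in which drug and target are
#' directly comparable (1:1 binding stoichiometry). The conversion is linear:
#' `nM = mg/L * 1e6 / MW`. The molar mass defaults to 149,000 g/mol, the
#' nominal value for an IgG1 monoclonal antibody such as infliximab.
#'
#' @param mw Molar mass of the drug in g/mol. Must be strictly positive.
#' @return An object of class `unit_system`.
#' @examples
#' u <- unit_system()
#' convert_concentration(5, u) # ~33.6 nM
#' @export
unit_system <- function(mw = 149000) {
  if (!is.numeric(mw) || length(mw) != 1L || !is.finite(mw) || mw <= 0)
    stop("molar mass must be a single positive number", call. = FALSE)
  structure(list(mw = mw), class = "unit_system")
}

#' @export
print.unit_system <- function(x, ...) {
  cat("<unit_system> MW =", x$mw, "g/mol;",
      "1 mg/L =", format(1e6 / x$mw, digits = 6), "nM\n")
  invisible(x)
}

#' Convert drug concentrations between mg/L and nM
#'
#' Applied exactly once at the data boundary: datasets carry mg/L, model
#' internals are nM. The conversion is linear and exactly invertible.
#'
#' @param value Numeric vector of concentrations, all `>= 0`.
#' @param units A [unit_system()].
#' @param from Unit of `value`: `"mgL"` (default) or `"nM"`.
#' @return Numeric vector in the other unit.
#' @export
convert_concentration <- function(value, units = unit_system(),
                                  from = c("mgL", "nM")) {
  from <- match.arg(from)
  stopifnot(inherits(units, "unit_system"))
  if (any(value < 0, na.rm = TRUE))
    stop("concentrations must be non-negative", call. = FALSE)
  f <- 1e6 / units$mw
  if (from == "mgL") value * f else value / f
}
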