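`%||%` <- function(a, b) if (is.null(a)) b else a

## Gas constant in kJ/(mol K); RT at 298.15 K is the 2.479 kJ/mol used throughout.
GAS_CONSTANT_KJ <- 8.314e-3

#' Thermal energy R*T
#'
#' @param temperature Temperature in Kelvin.
#' @return R*T in kJ/mol (2.4788 kJ/mol at 298.15 K).
#' @export
rt_constant <- function(temperature = 298.15) {
  stopifnot(is.numeric(temperature), temperature > 0)
  GAS_CONSTANT_KJ * temperature
}

stop_pf <- function(...) stop(sprintf(...), call. = FALSE)

## look up a named-vector entry, 0 when absent
gv <- function(g, nm) if (nm %in% names(g)) g[[nm]] else 0

## named numeric helper: coerce list/vector from JSON to named numeric
as_named_num <- function(x) {
  if (is.null(x) || length(x) == 0) return(stats::setNames(numeric(0), character(0)))
  out <- vapply(x, function(v) as.numeric(v[[1]]), numeric(1))
  stats::setNames(out, names(x))
}
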