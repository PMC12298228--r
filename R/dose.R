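#' Oral dosing regimen
#'
#' A single oral dose of losartan potassium. The default molecular weight
#' (461.01 g/mol) converts the milligram dose to nanomoles.
#'
#' @param dose_mg Oral dose of losartan potassium (mg, >= 0).
#' @param molecular_weight Molecular weight (g/mol, > 0); default 461.01.
#' @param administration_time Time of administration (h, >= 0); default 0.
#' @return An object of class `dose_regimen`.
#' @export
#' @examples
#' dose_regimen(50)
dose_regimen <- function(dose_mg, molecular_weight = 461.01,
                         administration_time = 0) {
  stopifnot(is.numeric(dose_mg), length(dose_mg) == 1L, is.finite(dose_mg))
  if (dose_mg < 0) stop("dose_mg must be nonnegative", call. = FALSE)
  if (!is.numeric(molecular_weight) || molecular_weight <= 0)
    stop("molecular_weight must be strictly positive", call. = FALSE)
  if (administration_time < 0)
    stop("administration_time must be nonnegative", call. = FALSE)
  structure(list(dose_mg = dose_mg, molecular_weight = molecular_weight,
                 administration_time = administration_time),
            class = "dose_regimen")
}

#' @export
print.dose_regimen <- function(x, ...) {
  cat(sprintf("Oral dose: %g mg losartan potassium (MW %g g/mol) at t = %g h\n",
              x$dose_mg, x$molecular_weight, x$administration_time))
  cat(sprintf("  = %.1f nmol\n", dose_to_amount(x)))
  invisible(x)
}

#' Convert an oral dose to an amount in nanomoles
#'
#' `dose_mg * 1e6 / molecular_weight`: the factor 1e6 converts milligrams to
#' nanograms, division by the molecular weight converts nanograms to
#' nanomoles.
#'
#' @param dose A [dose_regimen()] object, or a dose in mg.
#' @param molecular_weight Used only when `dose` is numeric.
#' @return Amount in nmol.
#' @export
#' @examples
#' dose_to_amount(dose_regimen(50))  # 108457.5 nmol
dose_to_amount <- function(dose, molecular_weight = 461.01) {
  if (is.numeric(dose)) dose <- dose_regimen(dose, molecular_weight)
  stopifnot(inherits(dose, "dose_regimen"))
  dose$dose_mg * 1e6 / dose$molecular_weight
}
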