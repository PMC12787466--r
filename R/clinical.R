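#' Homeostasis Model Assessment of insulin resistance (HOMA-IR)
#'
#' `HOMA-IR = insulin (uIU/mL) x glucose (mg/dL) / 405`. Vectorised;
#' bilinear in both arguments.
#'
#' @param insulin Fasting insulin in uIU/mL (>= 0).
#' @param glucose Fasting glucose in mg/dL (>= 0).
#' @return The HOMA-IR index value(s).
#' @export
#' @examples
#' homa_ir(15, 108)  # 4
homa_ir <- function(insulin, glucose) {
  if (any(insulin < 0) || any(glucose < 0)) {
    stop("insulin and glucose must be non-negative", call. = FALSE)
  }
  insulin * glucose / 405
}

#' BMI class for a high-weight cohort
#'
#' Classifies body-mass index into the two inclusion categories of the
#' cohort: `overweight` for 25 <= BMI < 30 and `obesity` for BMI >= 30
#' (the WHO >= 30 convention resolves the boundary), with everything below
#' 25 reported as `out_of_range` (outside the cohort's inclusion window).
#'
#' @param bmi Body-mass index in kg/m^2 (> 0). Vectorised.
#' @return Character vector in `{"overweight", "obesity", "out_of_range"}`.
#' @export
#' @examples
#' bmi_class(c(24.9, 28.4, 31))
bmi_class <- function(bmi) {
  if (any(bmi <= 0)) stop("bmi must be positive", call. = FALSE)
  ifelse(bmi >= 30, "obesity", ifelse(bmi >= 25, "overweight", "out_of_range"))
}
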