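#' Variable specification for a cohort column
#'
#' A `variable_spec` describes one node of the health network: its label, its
#' measurement type, the marginal distribution used by the synthetic-cohort
#' generator, the latent correlation block it belongs to, and the network
#' dimension it is displayed under.
#'
#' @param name Variable label (column name in the cohort table).
#' @param vartype One of `"continuous"`, `"binary"`, `"ordinal"`.
#' @param mean,sd Marginal mean and standard deviation in native units
#'   (continuous variables only; `sd` must be positive).
#' @param category_probs Probability vector over coded levels `0, 1, ...`
#'   (binary/ordinal only). Must sum to 1 within `1e-12`.
#' @param block Latent-correlation block, one of `"metabolic_glycemic"`,
#'   `"lipid"`, `"psychosocial"`.
#' @param dimension Display dimension, one of `"sociodemographic"`,
#'   `"nutritional"`, `"physical"`, `"psychological"`.
#' @param positive Logical; if `TRUE` the variable is a strictly positive
#'   quantity and simulated draws are floored at 1% of the mean.
#'
#' @return An object of class `variable_spec`.
#' @export
variable_spec <- function(name, vartype,
                          mean = NULL, sd = NULL,
                          category_probs = NULL,
                          block = "psychosocial",
                          dimension = "physical",
                          positive = FALSE) {
  vartype <- match.arg(vartype, c("continuous", "binary", "ordinal"))
  block <- match.arg(block, c("metabolic_glycemic", "lipid", "psychosocial"))
  dimension <- match.arg(dimension, c("sociodemographic", "nutritional",
                                      "physical", "psychological"))
  if (vartype == "continuous") {
    if (is.null(mean) || is.null(sd)) {
      stop("continuous variable '", name, "' needs mean and sd", call. = FALSE)
    }
    if (sd <= 0) {
      stop("sd for '", name, "' must be > 0 (got ", sd, ")", call. = FALSE)
    }
    category_probs <- NULL
  } else {
    if (is.null(category_probs)) {
      stop(vartype, " variable '", name, "' needs category_probs",
           call. = FALSE)
    }
    if (abs(sum(category_probs) - 1) > 1e-12) {
      stop("category_probs for '", name, "' must sum to 1 (got ",
           format(sum(category_probs), digits = 15), ")", call. = FALSE)
    }
    if (vartype == "binary" && length(category_probs) != 2) {
      stop("binary variable '", name, "' needs exactly 2 category_probs",
           call. = FALSE)
    }
    mean <- NULL
    sd <- NULL
  }
  structure(
    list(name = name, vartype = vartype, mean = mean, sd = sd,
         category_probs = category_probs, block = block,
         dimension = dimension, positive = positive),
    class = "variable_spec"
  )
}

#' Default 17-variable cohort schema
#'
#' Returns the schema of the high-weight young-adult study cohort: 17
#' variables spanning sociodemographics (sex, age, marital status, social
#' position), three factor-analytic nutritional-pattern scores (NP1 minerals/
#' vitamins, NP2 carbohydrates, NP3 fat/sodium), physical/metabolic markers
#' (BMI, hypertension, glucose, insulin, total cholesterol, triacylglycerol,
#' HOMA-IR) and psychological scales (depression, anxiety, stress).
#'
#' Continuous marginals use the cohort's reported means and SDs (e.g. glucose
#' 147.80 mg/dL, SD 52.43; n = 188 participants); categorical frequencies are
#' stored as exact count fractions (e.g. 81/188 women, 48/188 hypertensive),
#' which reproduce the reported percentages at one decimal. NP scores are
#' standardised (mean 0, SD 1). Codings: sex 0 = man / 1 = woman; marital
#' 0 = single / 1 = married or cohabiting / 2 = divorced or separated;
#' social position 0 = low / 1 = medium / 2 = high; HTN 0 = no / 1 = yes.
#'
#' Correlation blocks follow the empirical clustering of the variables:
#' \{insulin, glucose, HOMA\} (glycemic), \{total cholesterol, TAG\} (lipid),
#' and everything else (psychosocial).
#'
#' @return A list of 17 [variable_spec()] objects, in the canonical column
#'   order `Sex, Age, Marital, Social, NP1, NP2, NP3, BMI, HTN, Glucose,
#'   Insulin, CholesT, TAG, HOMA, Depre, Anxiety, Stress`.
#' @export
#' @examples
#' sch <- default_schema()
#' vapply(sch, `[[`, "", "name")
default_schema <- function() {
  n <- 188
  list(
    variable_spec("Sex", "binary", category_probs = c(107, 81) / n,
                  dimension = "sociodemographic"),
    variable_spec("Age", "continuous", mean = 20.8, sd = 2.6,
                  dimension = "sociodemographic", positive = TRUE),
    variable_spec("Marital", "ordinal", category_probs = c(148, 35, 5) / n,
                  dimension = "sociodemographic"),
    variable_spec("Social", "ordinal", category_probs = c(71, 62, 55) / n,
                  dimension = "sociodemographic"),
    variable_spec("NP1", "continuous", mean = 0, sd = 1,
                  dimension = "nutritional"),
    variable_spec("NP2", "continuous", mean = 0, sd = 1,
                  dimension = "nutritional"),
    variable_spec("NP3", "continuous", mean = 0, sd = 1,
                  dimension = "nutritional"),
    variable_spec("BMI", "continuous", mean = 28.4, sd = 2.9,
                  dimension = "physical", positive = TRUE),
    variable_spec("HTN", "binary", category_probs = c(140, 48) / n,
                  dimension = "physical"),
    variable_spec("Glucose", "continuous", mean = 147.80, sd = 52.43,
                  block = "metabolic_glycemic", dimension = "physical",
                  positive = TRUE),
    variable_spec("Insulin", "continuous", mean = 2.54, sd = 0.78,
                  block = "metabolic_glycemic", dimension = "physical",
                  positive = TRUE),
    variable_spec("CholesT", "continuous", mean = 5.89, sd = 1.30,
                  block = "lipid", dimension = "physical", positive = TRUE),
    variable_spec("TAG", "continuous", mean = 5.21, sd = 1.55,
                  block = "lipid", dimension = "physical", positive = TRUE),
    variable_spec("HOMA", "continuous", mean = 10.69, sd = 2.62,
                  block = "metabolic_glycemic", dimension = "physical",
                  positive = TRUE),
    variable_spec("Depre", "continuous", mean = 98.9, sd = 11.2,
                  dimension = "psychological", positive = TRUE),
    variable_spec("Anxiety", "continuous", mean = 10.4, sd = 2.9,
                  dimension = "psychological", positive = TRUE),
    variable_spec("Stress", "continuous", mean = 193.2, sd = 52.1,
                  dimension = "psychological", positive = TRUE)
  )
}

#' @keywords internal
schema_names <- function(schema) vapply(schema, `[[`, "", "name")

#' @keywords internal
schema_field <- function(schema, field) {
  sapply(schema, function(s) if (is.null(s[[field]])) NA else s[[field]])
}

#' Validate a cohort schema
#'
#' Checks that every variable appears exactly once and each spec's own
#' invariants hold (they are enforced at construction).
#'
#' @param schema List of [variable_spec()] objects.
#' @return The schema, invisibly; errors on duplicates or wrong class.
#' @export
validate_schema <- function(schema) {
  if (!all(vapply(schema, inherits, TRUE, "variable_spec"))) {
    stop("schema must be a list of variable_spec objects", call. = FALSE)
  }
  nm <- schema_names(schema)
  if (anyDuplicated(nm)) {
    stop("duplicated variable names in schema: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  invisible(schema)
}

#' Write / read a schema as YAML
#'
#' @param schema List of [variable_spec()] objects.
#' @param path File path.
#' @return `write_schema_yaml` returns `path` invisibly; `read_schema_yaml`
#'   returns the schema list.
#' @export
write_schema_yaml <- function(schema, path) {
  validate_schema(schema)
  out <- lapply(schema, function(s) {
    s <- unclass(s)
    s[!vapply(s, is.null, TRUE)]
  })
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_schema_yaml
#' @export
read_schema_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  schema <- lapply(raw, function(s) {
    variable_spec(
      name = s$name, vartype = s$vartype,
      mean = s$mean, sd = s$sd,
      category_probs = if (!is.null(s$category_probs)) {
        as.numeric(s$category_probs)
      },
      block = s$block, dimension = s$dimension,
      positive = isTRUE(s$positive)
    )
  })
  validate_schema(schema)
}
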