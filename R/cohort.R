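#' Synthetic-cohort generator configuration
#'
#' Bundles everything [generate_cohort()] needs: the sample size, the variable
#' schema, the latent block-correlation structure and the seed. The latent
#' model is a Gaussian copula: a multivariate normal with correlation
#' `within_block_rho` for variable pairs sharing a block and
#' `between_block_rho` across blocks, pushed through each variable's marginal
#' (affine map for continuous variables, quantile thresholding for
#' binary/ordinal ones).
#'
#' @param n Number of participants (>= 20; the 17-variable partial
#'   correlations need n > 19 for positive degrees of freedom).
#' @param schema List of [variable_spec()]s; defaults to [default_schema()].
#' @param within_block_rho Latent correlation for same-block pairs.
#' @param between_block_rho Latent correlation for cross-block pairs.
#' @param homa_mode `"formula"` (default) recomputes the HOMA column
#'   deterministically as insulin x glucose / 405, so the table is internally
#'   consistent; `"sampled"` keeps the latent draw, matching the reported
#'   HOMA moments (10.69, SD 2.62) at the price of breaking the formula.
#' @param seed Integer RNG seed; the same configuration always yields a
#'   bit-identical cohort.
#'
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n = 188,
                             schema = default_schema(),
                             within_block_rho = 0.45,
                             between_block_rho = 0.10,
                             homa_mode = c("formula", "sampled"),
                             seed = 1L) {
  homa_mode <- match.arg(homa_mode)
  validate_schema(schema)
  if (n < 20) {
    stop("n must be >= 20 (17 conditioning variables leave no degrees of ",
         "freedom below that)", call. = FALSE)
  }
  if (abs(within_block_rho) >= 1 || abs(between_block_rho) >= 1) {
    stop("|rho| must be < 1 (within = ", within_block_rho,
         ", between = ", between_block_rho, ")", call. = FALSE)
  }
  structure(
    list(n = as.integer(n), schema = schema,
         within_block_rho = within_block_rho,
         between_block_rho = between_block_rho,
         homa_mode = homa_mode, seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Latent block-correlation matrix
#'
#' Builds the exchangeable-within-block correlation matrix implied by a
#' schema's block labels and verifies it is positive definite.
#'
#' @param schema List of [variable_spec()]s.
#' @param within_block_rho,between_block_rho Latent correlations.
#' @return A p x p correlation matrix with variable names on both margins.
#' @export
latent_correlation <- function(schema, within_block_rho, between_block_rho) {
  blocks <- schema_field(schema, "block")
  p <- length(schema)
  same <- outer(blocks, blocks, `==`)
  rho <- ifelse(same, within_block_rho, between_block_rho)
  diag(rho) <- 1
  dimnames(rho) <- list(schema_names(schema), schema_names(schema))
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop("latent correlation matrix is not positive definite ",
         "(within_block_rho = ", within_block_rho,
         ", between_block_rho = ", between_block_rho,
         "; smallest eigenvalue = ", format(min(ev), digits = 4), ")",
         call. = FALSE)
  }
  rho
}

#' Generate a synthetic cohort
#'
#' Draws `n` participants from the latent Gaussian copula described by a
#' [generator_config()] and maps each latent column to its native marginal:
#' continuous variables by the affine map `mean + sd * z` (floored at 1% of
#' the mean when flagged strictly positive), binary/ordinal variables by
#' thresholding the latent normal at the quantiles of the cumulative category
#' probabilities. With `homa_mode = "formula"` the HOMA column is then
#' overwritten row-wise with insulin x glucose / 405.
#'
#' @param config A [generator_config()].
#' @return An object of class `cohort_table`: a list with `values` (an
#'   n x p numeric matrix in native units, columns named after the schema),
#'   `schema`, and `id` (row labels `S001, S002, ...`).
#' @export
#' @examples
#' cohort <- generate_cohort(generator_config(n = 50, seed = 42))
#' colMeans(cohort$values)[c("Glucose", "Insulin")]
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  schema <- config$schema
  p <- length(schema)
  rho <- latent_correlation(schema, config$within_block_rho,
                            config$between_block_rho)
  z <- withr::with_seed(
    config$seed,
    MASS::mvrnorm(config$n, mu = rep(0, p), Sigma = rho)
  )
  values <- matrix(0, nrow = config$n, ncol = p,
                   dimnames = list(NULL, schema_names(schema)))
  for (j in seq_len(p)) {
    s <- schema[[j]]
    if (s$vartype == "continuous") {
      x <- s$mean + s$sd * z[, j]
      if (isTRUE(s$positive)) x <- pmax(x, 0.01 * s$mean)
      values[, j] <- x
    } else {
      cuts <- stats::qnorm(cumsum(s$category_probs))
      values[, j] <- rowSums(outer(z[, j], cuts[-length(cuts)], `>`))
    }
  }
  if (config$homa_mode == "formula") {
    need <- c("Insulin", "Glucose", "HOMA")
    if (all(need %in% colnames(values))) {
      values[, "HOMA"] <- homa_ir(values[, "Insulin"], values[, "Glucose"])
    }
  }
  structure(
    list(values = values, schema = schema,
         id = sprintf("S%03d", seq_len(config$n))),
    class = "cohort_table"
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$values), "participants x",
      ncol(x$values), "variables\n")
  cat("Variables:", paste(colnames(x$values), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.cohort_table <- function(x, ...) {
  df <- as.data.frame(x$values)
  rownames(df) <- x$id
  df
}

#' Write a cohort table to CSV (plus optional YAML schema)
#'
#' The CSV carries one header row with the canonical node labels and one row
#' per participant; row labels go in an `id` column.
#'
#' @param cohort A `cohort_table`.
#' @param path CSV output path.
#' @param schema_path Optional path for the companion YAML schema.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, schema_path = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  df <- cbind(id = cohort$id, as.data.frame(cohort$values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(schema_path)) write_schema_yaml(cohort$schema, schema_path)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Expects the 17 canonical columns (an `id` column is optional). Fails
#' naming the first missing column or non-numeric cell.
#'
#' @param path CSV path.
#' @param schema Schema the columns must match; default [default_schema()].
#' @return A `cohort_table`.
#' @export
read_cohort_csv <- function(path, schema = default_schema()) {
  validate_schema(schema)
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- if ("id" %in% names(df)) {
    as.character(df[["id"]])
  } else {
    sprintf("S%03d", seq_len(nrow(df)))
  }
  df[["id"]] <- NULL
  want <- schema_names(schema)
  missing <- setdiff(want, names(df))
  if (length(missing)) {
    stop("cohort CSV '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (nm in want) {
    col <- df[[nm]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(col)))))[1]
      stop("non-numeric cell in column '", nm, "', row ",
           ifelse(is.na(bad), 1L, bad), call. = FALSE)
    }
    if (anyNA(col)) {
      stop("missing value in column '", nm, "', row ", which(is.na(col))[1],
           call. = FALSE)
    }
  }
  values <- as.matrix(df[, want, drop = FALSE])
  structure(list(values = values, schema = schema, id = ids),
            class = "cohort_table")
}
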