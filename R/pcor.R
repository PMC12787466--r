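#' Full pairwise partial-correlation matrix with p-values
#'
#' For every pair of the cohort's variables, estimates the partial
#' correlation adjusting for all remaining variables, via the inverse of the
#' sample covariance matrix (precision matrix Omega):
#' `rp_ij = -Omega_ij / sqrt(Omega_ii * Omega_jj)`.
#' This equals the correlation of the residuals of the two variables after
#' linear regression on the other p - 2 columns. Categorical variables enter
#' as their numeric codes, giving one mixed Pearson-based matrix.
#'
#' Two-sided p-values use the t-transform for partial correlations with
#' `df = n - 2 - k`, where `k = p - 2` is the size of the conditioning set
#' (so df = 171 for n = 188, p = 17); see [pcor_pvalue()].
#'
#' @param cohort A `cohort_table`, or an n x p numeric matrix/data.frame with
#'   column names.
#' @return An object of class `pcor_result`: list with `rp` (p x p partial
#'   correlations, unit diagonal), `pvals` (p x p two-sided p-values, zero
#'   diagonal), `n`, `k` (conditioning-set size, p - 2), `labels`.
#' @export
#' @examples
#' cohort <- generate_cohort(generator_config(n = 80, seed = 7))
#' pc <- partial_correlations(cohort)
#' pc$rp["Insulin", "Glucose"]
partial_correlations <- function(cohort) {
  x <- if (inherits(cohort, "cohort_table")) cohort$values else as.matrix(cohort)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  n <- nrow(x)
  p <- ncol(x)
  if (n <= p + 2) {
    stop("need n > p + 2 observations (n = ", n, ", p = ", p, ")",
         call. = FALSE)
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  s <- stats::cov(x)  # n - 1 denominator
  omega <- tryCatch(
    solve(s),
    error = function(e) {
      qrx <- qr(scale(x, center = TRUE, scale = FALSE))
      dep <- colnames(x)[qrx$pivot[-seq_len(qrx$rank)]]
      stop("singular covariance matrix; collinear column(s): ",
           paste(dep, collapse = ", "), call. = FALSE)
    }
  )
  d <- sqrt(diag(omega))
  rp <- -omega / tcrossprod(d)
  diag(rp) <- 1
  rp <- (rp + t(rp)) / 2
  k <- p - 2L
  pvals <- matrix(pcor_pvalue(rp, n, k), p, p, dimnames = dimnames(rp))
  diag(pvals) <- 0
  structure(
    list(rp = rp, pvals = pvals, n = n, k = k, labels = colnames(x)),
    class = "pcor_result"
  )
}

#' @export
print.pcor_result <- function(x, ...) {
  cat("Partial correlations over", length(x$labels), "variables",
      sprintf("(n = %d, conditioning set k = %d, df = %d)\n",
              x$n, x$k, x$n - x$k - 2L))
  invisible(x)
}

#' Two-sided p-value for a partial correlation
#'
#' Uses the t-transform `t = r * sqrt(df / (1 - r^2))` with
#' `df = n - k - 2` degrees of freedom, where `k` is the number of
#' conditioning variables. `|r| = 1` maps to p = 0 (degenerate limit).
#'
#' @param r Partial correlation(s) in `[-1, 1]`. Matrices allowed.
#' @param n Sample size.
#' @param k Conditioning-set size.
#' @return Two-sided p-value(s), same shape as `r`.
#' @export
#' @examples
#' pcor_pvalue(0.2, n = 188, k = 15)
pcor_pvalue <- function(r, n, k) {
  df <- n - k - 2
  if (df < 1) {
    stop("degrees of freedom n - k - 2 = ", df, " < 1", call. = FALSE)
  }
  r <- pmin(1, pmax(-1, r))
  tstat <- abs(r) * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-tstat, df)
  p[abs(r) >= 1] <- 0
  p
}

#' Export a partial-correlation result as labelled CSV matrices
#'
#' @param pcor A `pcor_result`.
#' @param rp_path,pvals_path Output paths for the two square matrices.
#' @return Invisibly, a character vector of the paths written.
#' @export
write_pcor_csv <- function(pcor, rp_path, pvals_path) {
  stopifnot(inherits(pcor, "pcor_result"))
  utils::write.csv(as.data.frame(pcor$rp), rp_path, row.names = TRUE)
  utils::write.csv(as.data.frame(pcor$pvals), pvals_path, row.names = TRUE)
  invisible(c(rp_path, pvals_path))
}
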