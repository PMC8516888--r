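#' Pearson correlation with a two-tailed p-value
#'
#' Product-moment correlation; the p-value refers
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` to the t distribution with `n - 2`
#' degrees of freedom, two-tailed.
#'
#' @param x,y Numeric vectors of equal length, at least 3, both with
#'   non-zero variance.
#' @return An object of class `correlation_result` with `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) != length(y) || length(x) < 3L)
    stop("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("correlation undefined: an input has zero variance")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (p = %.3g, n = %d)\n", x$r, x$p, x$n))
  invisible(x)
}

#' Significance stars for a p-value
#'
#' The conventional mapping: `p < 0.001` three stars, `p < 0.01` two,
#' `p < 0.05` one, otherwise `"ns"`.
#'
#' @param p A p-value in `[0, 1]`.
#' @export
stars_for_p <- function(p) {
  stopifnot(p >= 0, p <= 1)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Two-tailed paired Student's t test with star annotation
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the paired differences `d = x - y`,
#' with `n - 1` degrees of freedom. Zero-variance differences (e.g. `x`
#' identical to `y`) are reported as a degenerate case rather than a
#' spurious statistic.
#'
#' @param x,y Paired numeric vectors of equal length, at least 2.
#' @return An object of class `ttest_result` with `t`, `p`, `stars`, `n`.
#' @export
paired_ttest <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) stop("need at least 2 complete pairs")
  d <- x - y
  if (stats::sd(d) == 0)
    stop("degenerate paired t test: differences have zero variance")
  tt <- stats::t.test(x, y, paired = TRUE, alternative = "two.sided")
  structure(list(t = unname(tt$statistic), p = tt$p.value,
                 stars = stars_for_p(tt$p.value), n = length(x)),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("paired t = %.4f (p = %.3g, n = %d) %s\n", x$t, x$p, x$n,
              x$stars))
  invisible(x)
}

#' Replicate summary: mean and sample standard deviation
#'
#' Results are conventionally expressed as mean +/- standard deviation over
#' replicates. The sample standard deviation (n - 1 denominator) is
#' undefined for a single value and reported as missing.
#'
#' @param values Numeric vector, at least one value.
#' @return List with `mean`, `sd` (`NA` for n = 1), `n`.
#' @export
summarize_reps <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no values to summarize")
  list(mean = mean(values),
       sd = if (length(values) > 1L) stats::sd(values) else NA_real_,
       n = length(values))
}

#' All-pairs correlation matrix over measurement variables
#'
#' Computes the full symmetric matrix of Pearson correlations (with
#' two-tailed p-values) between the measured variables, the numerical
#' content of the correlation heat map. By default replicate-level rows are
#' correlated; with `aggregate = "condition"` replicates are averaged per
#' condition first. Diagonal cells are `r = 1`, `p = 0` by convention. No
#' multiple-testing correction is applied.
#'
#' @param table Data frame with at least 3 rows (after any aggregation)
#'   containing the variables.
#' @param variables Character vector of column names to correlate.
#' @param aggregate `"replicate"` (default) or `"condition"`; the latter
#'   averages over `condition_id` before correlating.
#' @return An object of class `correlation_matrix`: numeric matrices `r`,
#'   `p`, `n` with variable dimnames.
#' @export
correlation_heatmap <- function(table,
                                variables = c("melanin_area_cm2",
                                              "ttc_white_area_cm2",
                                              "ttc_red_area_cm2",
                                              "current_A",
                                              "conductivity_ratio"),
                                aggregate = c("replicate", "condition")) {
  aggregate <- match.arg(aggregate)
  stopifnot(is.data.frame(table), all(variables %in% names(table)))
  if (aggregate == "condition") {
    stopifnot("condition_id" %in% names(table))
    table <- stats::aggregate(table[variables],
                              by = list(condition_id = table$condition_id),
                              FUN = mean)
  }
  if (nrow(table) < 3L)
    stop("need at least 3 rows (conditions) to correlate")
  k <- length(variables)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  for (i in seq_len(k)) {
    r[i, i] <- 1; p[i, i] <- 0
    n[i, i] <- sum(!is.na(table[[variables[i]]]))
    for (j in seq_len(k)) {
      if (j <= i) next
      cr <- pearson(table[[variables[i]]], table[[variables[j]]])
      r[i, j] <- r[j, i] <- cr$r
      p[i, j] <- p[j, i] <- cr$p
      n[i, j] <- n[j, i] <- cr$n
    }
  }
  structure(list(r = r, p = p, n = n, aggregate = aggregate),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("correlation matrix (%s level):\n", x$aggregate))
  print(round(x$r, digits))
  invisible(x)
}

#' Flatten a correlation matrix to a long table
#'
#' @param cm A `correlation_matrix`.
#' @return Data frame with columns `var_i`, `var_j`, `r`, `p`, `n`.
#' @export
correlation_table <- function(cm) {
  stopifnot(inherits(cm, "correlation_matrix"))
  vars <- rownames(cm$r)
  out <- expand.grid(var_i = vars, var_j = vars, stringsAsFactors = FALSE)
  out$r <- as.vector(cm$r)
  out$p <- as.vector(cm$p)
  out$n <- as.vector(cm$n)
  out
}
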