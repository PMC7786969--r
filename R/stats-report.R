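#' Simple linear regression with coefficient of determination
#'
#' Ordinary least squares of `y` on `x`; for a simple linear regression the
#' reported R2 equals the squared Pearson correlation.
#'
#' @param x,y paired numeric vectors; pairs with missing values are dropped.
#' @return A list with `slope`, `intercept`, `r2`, `n`.
#' @export
ols_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 paired finite values")
  if (var(x) == 0) stop("zero variance in x: slope undefined")
  f <- lm(y ~ x)
  rss <- sum(stats::residuals(f)^2)
  tss <- sum((y - mean(y))^2)
  list(slope = unname(coef(f)[2]), intercept = unname(coef(f)[1]),
       r2 = if (tss > 0) max(0, min(1, 1 - rss / tss)) else 0,
       n = length(x))
}

#' Summary statistics of a feature across samples
#'
#' Mean, sample standard deviation (n-1 denominator), relative standard
#' deviation in percent, minimum and maximum.
#'
#' @param values numeric vector, >= 2 finite values.
#' @return A list with `mean`, `sd`, `rsd_pct`, `min`, `max`, `n`.
#' @export
summary_stats <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need >= 2 values for a standard deviation")
  m <- mean(values); s <- sd(values)
  list(mean = m, sd = s,
       rsd_pct = if (m != 0) 100 * s / m else NA_real_,
       min = min(values), max = max(values), n = length(values))
}

#' Weighted size-distribution percentiles and span
#'
#' D10/D50/D90 of a weighted particle-size distribution, by linear
#' interpolation of the cumulative weight fraction evaluated at each size
#' with the midpoint convention (half of a size's own weight counts below
#' it), and the span `(D90 - D10) / D50`. The span is invariant under any
#' rescaling of the sizes.
#'
#' @param sizes_um ascending sizes in um.
#' @param weights non-negative weights, same length, positive total.
#' @return A `size_distribution_summary` list: `d10_um`, `d50_um`, `d90_um`,
#'   `span`.
#' @export
size_percentiles <- function(sizes_um, weights) {
  if (length(sizes_um) != length(weights)) stop("sizes and weights differ in length")
  if (is.unsorted(sizes_um, strictly = TRUE)) stop("sizes must be strictly ascending")
  if (any(weights < 0)) stop("weights must be >= 0")
  tot <- sum(weights)
  if (tot <= 0) stop("weights sum to zero")
  cdf <- (cumsum(weights) - weights / 2) / tot
  qfun <- function(p) {
    if (p <= cdf[1]) return(sizes_um[1])
    if (p >= cdf[length(cdf)]) return(sizes_um[length(sizes_um)])
    approx(cdf, sizes_um, xout = p, ties = "ordered")$y
  }
  d10 <- qfun(0.10); d50 <- qfun(0.50); d90 <- qfun(0.90)
  structure(list(d10_um = d10, d50_um = d50, d90_um = d90,
                 span = (d90 - d10) / d50),
            class = "size_distribution_summary")
}

#' @export
print.size_distribution_summary <- function(x, ...) {
  cat(sprintf("<size_distribution_summary> D10 %.4g, D50 %.4g, D90 %.4g um, span %.3g\n",
              x$d10_um, x$d50_um, x$d90_um, x$span))
  invisible(x)
}

#' Pairwise correlation report over a sample feature table
#'
#' Runs [ols_r2()] for each requested pair of named numeric features across
#' the samples of a feature table (rows = samples, e.g. dry-fractionation
#' fractions; columns = measured characteristics). Missing cells are dropped
#' pairwise; pairs with fewer than 3 complete observations are skipped with
#' a warning.
#'
#' @param table data frame with a `sample` column and numeric feature
#'   columns.
#' @param pairs list of length-2 character vectors `c(x_feature, y_feature)`.
#' @return A data frame with columns `x`, `y`, `n`, `slope`, `intercept`,
#'   `r2`, `samples` (comma-separated labels used).
#' @export
correlation_report <- function(table, pairs) {
  stopifnot(is.data.frame(table), "sample" %in% names(table))
  rows <- lapply(pairs, function(pr) {
    if (length(pr) != 2) stop("each pair must have exactly 2 feature names")
    if (!all(pr %in% names(table)))
      stop("features not in table: ", paste(setdiff(pr, names(table)), collapse = ", "))
    x <- table[[pr[1]]]; y <- table[[pr[2]]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) {
      warning("pair ", pr[1], " ~ ", pr[2], " has < 3 complete observations; skipped")
      return(NULL)
    }
    f <- ols_r2(x[ok], y[ok])
    data.frame(x = pr[1], y = pr[2], n = f$n, slope = f$slope,
               intercept = f$intercept, r2 = f$r2,
               samples = paste(table$sample[ok], collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(x = character(0), y = character(0),
                                      n = integer(0), slope = numeric(0),
                                      intercept = numeric(0), r2 = numeric(0),
                                      samples = character(0))
  out
}

#' Packaged fraction characterization tables
#'
#' Loads the packaged cross-fraction characterization fixtures: physical
#' characteristics (`table = 1`: yield, laser-diffraction D50, span,
#' specific surface area), chemical composition (`table = 2`: sugars, ash,
#' proteins, acetyl, Klason lignin, thioacidolysis, hydroxycinnamic acids)
#' and water-interaction properties (`table = 3`: swelling capacity, water
#' retention capacity) of a ground maize shoot (`M`) and its six dry
#' fractionation fractions (coarse/medium/fine x electrode polarity).
#' `table = "outcomes"` loads the saccharification endpoints of the five
#' hydrolyzed fractions and the unfractionated sample (7-h sugar release,
#' 7-h decrease of particle number and mean size, half-change times); where
#' the source reports a range, the midpoint is stored.
#'
#' @param table 1, 2, 3 or `"outcomes"`.
#' @return A data frame with a `sample` column.
#' @export
fraction_table <- function(table = 1) {
  file <- switch(as.character(table),
                 "1" = "table1.csv", "2" = "table2.csv", "3" = "table3.csv",
                 "outcomes" = "saccharification_outcomes.csv",
                 stop("`table` must be 1, 2, 3 or \"outcomes\""))
  read.csv(system.file("extdata", file, package = "sacchmon"),
           check.names = FALSE, stringsAsFactors = FALSE)
}

#' Merged sample feature table
#'
#' Joins the packaged characterization tables ([fraction_table()]) by
#' sample label into one feature table suitable for
#' [correlation_report()].
#'
#' @return A data frame, one row per sample.
#' @export
sample_feature_table <- function() {
  t1 <- fraction_table(1); t2 <- fraction_table(2); t3 <- fraction_table(3)
  out <- merge(merge(t1, t2, by = "sample", all = TRUE), t3, by = "sample", all = TRUE)
  oc <- fraction_table("outcomes")
  merge(out, oc, by = "sample", all = TRUE)
}
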