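#' Paired difference summary against PSA
#'
#' Per-hip differences `d_i = method_i - PSA_i`, their mean (the mean
#' difference, MD), sample standard deviation and a paired two-tailed t-test
#' with `n - 1` degrees of freedom.  When the differences have zero variance
#' the t statistic is undefined: an all-zero difference vector is reported
#' with `t_p = 1`, and a constant non-zero shift with `t_p = 0` and the
#' `zero_variance` flag set.
#'
#' @param method_vals numeric vector of method angles (degrees).
#' @param psa_vals numeric vector of PSA angles, same hips and length.
#' @return a list with `diff_mean`, `diff_sd`, `t_stat`, `t_p`, `n` and
#'   `zero_variance`.
#' @export
paired_difference_summary <- function(method_vals, psa_vals) {
  if (length(method_vals) != length(psa_vals)) {
    stop("method and PSA vectors differ in length")
  }
  ok <- is.finite(method_vals) & is.finite(psa_vals)
  d <- method_vals[ok] - psa_vals[ok]
  n <- length(d)
  if (n < 3L) stop("need at least 3 complete pairs")
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    return(list(diff_mean = md, diff_sd = 0,
                t_stat = if (md == 0) 0 else NA_real_,
                t_p = if (md == 0) 1 else 0,
                n = n, zero_variance = TRUE))
  }
  t_stat <- md / (sdd / sqrt(n))
  list(diff_mean = md, diff_sd = sdd, t_stat = t_stat,
       t_p = 2 * stats::pt(-abs(t_stat), df = n - 1),
       n = n, zero_variance = FALSE)
}

#' Pearson correlation with a two-tailed p-value
#'
#' Sample Pearson correlation, with the p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`, non-constant.
#' @return a list with `r`, `p`, and `n`.
#' @export
pearson_with_p <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs for a correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: an input is constant")
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Intraclass correlation coefficient for rater agreement
#'
#' Single-rater ICC from the two-way ANOVA decomposition of a complete
#' subjects-by-raters matrix.  The default `"two_way_random"` model is
#' ICC(2,1), absolute agreement:
#' `(MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n) (MS_C - MS_E))`;
#' `"two_way_mixed"` gives the consistency form ICC(3,1)
#' `(MS_R - MS_E) / (MS_R + (k-1) MS_E)`.
#'
#' @param ratings numeric matrix, one row per subject (>= 5), one column per
#'   rater (>= 2), no missing cells.
#' @param model `"two_way_random"` (ICC(2,1)) or `"two_way_mixed"`
#'   (ICC(3,1)).
#' @return an object of class `reliability_result` with `icc_value`,
#'   `model_label`, `n_subjects`, `n_raters` and the mean squares.
#' @export
icc_absolute_agreement <- function(ratings, model = c("two_way_random", "two_way_mixed")) {
  model <- match.arg(model)
  m <- as.matrix(ratings)
  if (any(!is.finite(m))) stop("ratings matrix has missing or non-finite cells")
  n <- nrow(m); k <- ncol(m)
  if (n < 5L) stop("need at least 5 subjects")
  if (k < 2L) stop("need at least 2 raters")
  g <- mean(m)
  rm_ <- rowMeans(m); cm <- colMeans(m)
  ssr <- k * sum((rm_ - g)^2)
  ssc <- n * sum((cm - g)^2)
  sst <- sum((m - g)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (sst < 1e-300) stop("degenerate ratings: zero total variance")
  icc <- if (model == "two_way_random") {
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
  structure(list(icc_value = icc,
                 model_label = if (model == "two_way_random") {
                   "ICC(2,1) two-way random, absolute agreement"
                 } else "ICC(3,1) two-way mixed, consistency",
                 n_subjects = n, n_raters = k,
                 mean_squares = c(MS_R = msr, MS_C = msc, MS_E = mse)),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("%s: ICC = %.3f (%d subjects, %d raters)\n",
              x$model_label, x$icc_value, x$n_subjects, x$n_raters))
  invisible(x)
}

METHOD_COLUMNS <- data.frame(
  method = c("AM-CT", "AM-CT", "AM-3D", "AM-3D", "AT-3D", "AT-3D"),
  height_mm = c(5, 10, 5, 10, 5, 10),
  column = c("am_ct_5", "am_ct_10", "am_3d_5", "am_3d_10", "at_3d_5", "at_3d_10"),
  stringsAsFactors = FALSE)

COHORT_COLUMNS <- c("hip_id", "side", "crowe_type", "psa_deg",
                    METHOD_COLUMNS$column, "truth_nfa_deg")

#' Summarize a measurement cohort against PSA
#'
#' Produces one summary row per (method, height) cell of a cohort table:
#' angle mean and SD, mean difference versus PSA with its SD, a t-test
#' p-value, and the Pearson correlation with PSA and its p-value; a PSA row
#' is appended.  Cells use pairwise-complete hips.  The default t-test is the
#' paired test on per-hip differences; `t_test = "two_sample"` uses the
#' two-sample equal-variance form instead.
#'
#' @param records a cohort data frame with columns `hip_id, side, crowe_type,
#'   psa_deg, am_ct_5, am_ct_10, am_3d_5, am_3d_10, at_3d_5, at_3d_10,
#'   truth_nfa_deg` (missing angles allowed as `NA`; cells with fewer than 3
#'   complete pairs are an error).
#' @param t_test `"paired"` or `"two_sample"`.
#' @return an object of class `anteversion_summary`: a data frame with one
#'   row per method/height plus the PSA row.
#' @export
summarize_cohort <- function(records, t_test = c("paired", "two_sample")) {
  t_test <- match.arg(t_test)
  if (!is.data.frame(records) || nrow(records) == 0L) stop("empty cohort")
  need <- setdiff(c("psa_deg", METHOD_COLUMNS$column), names(records))
  if (length(need)) stop("cohort lacks columns: ", paste(need, collapse = ", "))
  rows <- lapply(seq_len(nrow(METHOD_COLUMNS)), function(i) {
    col <- METHOD_COLUMNS$column[i]
    v <- records[[col]]; p <- records$psa_deg
    ok <- is.finite(v) & is.finite(p)
    if (sum(ok) < 3L) {
      stop(sprintf("cell %s has %d complete pairs (< 3); cannot compute r/p",
                   col, sum(ok)))
    }
    v <- v[ok]; p <- p[ok]
    pd <- paired_difference_summary(v, p)
    tp <- if (t_test == "paired") pd$t_p else {
      n <- length(v)
      se <- sqrt((stats::var(v) + stats::var(p)) / n)
      ts <- (mean(v) - mean(p)) / se
      2 * stats::pt(-abs(ts), df = 2 * n - 2)
    }
    ct <- pearson_with_p(v, p)
    data.frame(method = METHOD_COLUMNS$method[i],
               height_mm = METHOD_COLUMNS$height_mm[i],
               n = length(v),
               angle_mean = mean(v), angle_sd = stats::sd(v),
               diff_mean = pd$diff_mean, diff_sd = pd$diff_sd,
               t_p = tp, pearson_r = ct$r, r_p = ct$p,
               stringsAsFactors = FALSE)
  })
  psa <- records$psa_deg[is.finite(records$psa_deg)]
  rows[[length(rows) + 1L]] <- data.frame(
    method = "PSA", height_mm = NA_real_, n = length(psa),
    angle_mean = mean(psa), angle_sd = stats::sd(psa),
    diff_mean = NA_real_, diff_sd = NA_real_,
    t_p = NA_real_, pearson_r = NA_real_, r_p = NA_real_,
    stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  attr(out, "t_test") <- t_test
  class(out) <- c("anteversion_summary", "data.frame")
  out
}

fmt_p <- function(p) {
  ifelse(is.na(p), "N/A", sprintf("%.3f", p))
}

#' @export
print.anteversion_summary <- function(x, ...) {
  cat("Anteversion by reference landmark (difference = method - PSA)\n")
  cat(sprintf("%-6s %-6s %-14s %-14s %-8s %-6s %-8s\n",
              "Method", "Height", "Angle (deg)", "Diff (deg)", "t-p", "r", "r-p"))
  for (i in seq_len(nrow(x))) {
    ang <- sprintf("%.1f +/- %.1f", x$angle_mean[i], x$angle_sd[i])
    dif <- if (is.na(x$diff_mean[i])) "N/A" else {
      sprintf("%.1f +/- %.1f", x$diff_mean[i], x$diff_sd[i])
    }
    r <- if (is.na(x$pearson_r[i])) "N/A" else sprintf("%.2f", x$pearson_r[i])
    cat(sprintf("%-6s %-6s %-14s %-14s %-8s %-6s %-8s\n",
                x$method[i],
                ifelse(is.na(x$height_mm[i]), "N/A", format(x$height_mm[i])),
                ang, dif, fmt_p(x$t_p[i]), r, fmt_p(x$r_p[i])))
  }
  invisible(x)
}

#' Write a cohort table to CSV
#'
#' Writes with the exact canonical column order; blank cells encode missing
#' angles.
#'
#' @param records cohort data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(records, path) {
  for (col in setdiff(COHORT_COLUMNS, names(records))) records[[col]] <- NA
  utils::write.csv(records[, COHORT_COLUMNS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' @param path path to a cohort CSV (columns as in [write_cohort_csv()]).
#' @return a cohort data frame.
#' @export
read_cohort_csv <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- setdiff(c("hip_id", "psa_deg"), names(rec))
  if (length(need)) stop("cohort CSV lacks columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(rec$hip_id)) stop("hip_id values are not unique")
  rec
}
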