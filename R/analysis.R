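# Comparison layer: reconstruction accuracy, cross-condition structure
# plausibility, coefficient comparisons with step-down correction, and
# case-study percent differences.

#' Coefficient of determination of a reconstruction
#'
#' Standard `1 - SS_res / SS_tot` per spatial direction, then averaged over
#' the anterior-posterior, vertical and mediolateral directions.  A
#' zero-variance direction is omitted from the average with a warning.
#'
#' @param predicted,measured n x 3 matrices (or equal-length vectors).
#' @return List with `per_direction` (named) and `average`.
#' @export
#' @examples
#' m <- cbind(sin(1:100), cos(1:100), 1:100)
#' r_squared(m, m)$average  # 1
r_squared <- function(predicted, measured) {
  predicted <- cbind(predicted); measured <- cbind(measured)
  stopifnot(dim(predicted) == dim(measured))
  dirs <- if (ncol(measured) == 3) c("x", "y", "z")
          else as.character(seq_len(ncol(measured)))
  r2 <- stats::setNames(rep(NA_real_, ncol(measured)), dirs)
  for (d in seq_len(ncol(measured))) {
    sst <- sum((measured[, d] - mean(measured[, d]))^2)
    if (sst == 0) {
      warning("zero-variance direction ", dirs[d], " omitted from r^2")
      next
    }
    r2[d] <- 1 - sum((measured[, d] - predicted[, d])^2) / sst
  }
  list(per_direction = r2, average = mean(r2, na.rm = TRUE))
}

#' One-sample right-tailed test that mean relative AICc exceeds 3
#'
#' Tests whether a baseline signature structure is *less* plausible than
#' condition-specific structures: H0 `mean(x) <= threshold` against H1
#' `mean(x) > threshold`, where `x` are per-subject AICc differences
#' (baseline structure minus condition-specific structure).  With zero
#' variance the mean is compared to the threshold exactly.
#'
#' @param x per-subject AICc differences.
#' @param threshold plausibility margin (default 3).
#' @param alpha significance level.
#' @return List with `t`, `df`, `p`, `reject`, `mean`, `sd`.
#' @export
#' @examples
#' structure_plausibility_test(c(10, 12, 14, 16))
structure_plausibility_test <- function(x, threshold = 3, alpha = 0.05) {
  stopifnot(length(x) >= 2)
  m <- mean(x); s <- stats::sd(x)
  if (s == 0) {
    p <- if (m > threshold) 0 else if (m == threshold) 0.5 else 1
    return(list(t = if (m == threshold) 0 else sign(m - threshold) * Inf,
                df = length(x) - 1, p = p, reject = p < alpha,
                mean = m, sd = s))
  }
  tt <- stats::t.test(x, mu = threshold, alternative = "greater")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value), reject = tt$p.value < alpha,
       mean = m, sd = s)
}

#' Holm-Sidak step-down multiple-comparison correction
#'
#' Sorts the p values ascending; at rank `i` of `f` tests the critical level
#' is `1 - (1 - alpha)^(1 / (f - i + 1))`.  Hypotheses are rejected in
#' step-down order until the first failure; all later hypotheses are
#' retained.
#'
#' @param p p values in \[0, 1\].
#' @param alpha family-wise error rate.
#' @return Data frame in the input order with `p`, `rank`, `alpha_sidak`,
#'   `reject`.
#' @export
#' @examples
#' holm_sidak(c(0.001, 0.02, 0.2), alpha = 0.05)
holm_sidak <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  f <- length(p)
  ord <- order(p)
  crit <- 1 - (1 - alpha)^(1 / (f - seq_len(f) + 1))
  rej_sorted <- logical(f)
  for (i in seq_len(f)) {
    if (p[ord[i]] <= crit[i]) rej_sorted[i] <- TRUE else break
  }
  out <- data.frame(p = p, rank = match(seq_len(f), ord),
                    alpha_sidak = NA_real_, reject = NA)
  out$alpha_sidak <- crit[out$rank]
  out$reject <- rej_sorted[out$rank]
  out
}

#' Percent difference relative to an explicit reference
#'
#' `100 * (a - b) / |b|`; the reference `b` is the second argument.  A zero
#' reference yields `NA` with a warning.
#'
#' @param a value of interest; @param b reference value.
#' @return Percent difference.
#' @export
#' @examples
#' percent_difference(11.0, 10.4)  # +5.8%, i.e. ~6% stiffer
percent_difference <- function(a, b) {
  if (any(b == 0)) {
    warning("zero reference in percent_difference")
    return(ifelse(b == 0, NA_real_, 100 * (a - b) / abs(b)))
  }
  100 * (a - b) / abs(b)
}

#' Compare signature coefficient tables between two conditions
#'
#' Paired t-tests per (coefficient, gait phase) across subjects, pooling the
#' two legs' estimates as paired observations, with Holm-Sidak step-down
#' correction over the declared comparison family.
#'
#' @param tab_a,tab_b signature tables (as `signature_table` from
#'   [identify_signatures()], with an added `subject` column) for the two
#'   conditions.
#' @param alpha family-wise error rate.
#' @param family_size declared size of the comparison family; defaults to
#'   the number of (coefficient, phase) cells tested here.
#' @return Data frame with one row per (coefficient, gait phase): condition
#'   means, mean paired difference, t, p, Holm-Sidak critical alpha and
#'   reject flag.
#' @export
compare_conditions <- function(tab_a, tab_b, alpha = 0.05,
                               family_size = NULL) {
  key <- function(d) paste(d$subject, d$leg, d$gait_phase, d$coefficient)
  tab_b <- tab_b[match(key(tab_a), key(tab_b)), ]
  cells <- unique(tab_a[, c("coefficient", "gait_phase")])
  res <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- tab_a$coefficient == cells$coefficient[i] &
      tab_a$gait_phase == cells$gait_phase[i]
    a <- tab_a$boot_mean[sel]; b <- tab_b$boot_mean[sel]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 2) next
    d <- a[ok] - b[ok]
    tt <- if (stats::sd(d) == 0)
      list(statistic = 0, p.value = if (mean(d) == 0) 1 else 0)
    else stats::t.test(a[ok], b[ok], paired = TRUE)
    res[[length(res) + 1]] <- data.frame(
      coefficient = cells$coefficient[i], gait_phase = cells$gait_phase[i],
      mean_a = mean(a[ok]), mean_b = mean(b[ok]), mean_diff = mean(d),
      t = unname(tt$statistic), p = unname(tt$p.value),
      n = sum(ok), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  f <- if (is.null(family_size)) nrow(out) else family_size
  # correct within the declared family; untested cells count toward f
  crit <- holm_sidak(c(out$p, rep(1, max(0, f - nrow(out))))[seq_len(f)],
                     alpha)[seq_len(nrow(out)), ]
  out$alpha_sidak <- crit$alpha_sidak
  out$reject <- crit$reject
  attr(out, "family_size") <- f
  out
}
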