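#' Standardize one determinant measurement against the reference group
#'
#' A determinant score is the number of reference-group standard deviations
#' the measurement lies from the reference mean: `(value - ref_mean)/ref_sd`.
#' Larger raw values mean better performance for every determinant, so a
#' positive score is better-than-reference function.
#'
#' @param value numeric measurement(s), same units as the reference stats.
#' @param ref_mean reference-group mean.
#' @param ref_sd reference-group standard deviation; must be > 0.
#' @return numeric z-score(s).
#' @examples
#' determinant_score(160, 123.9, 28.9)  # 1.249 to 3 d.p.
#' @export
determinant_score <- function(value, ref_mean, ref_sd) {
  if (!is.numeric(ref_sd) || any(!is.finite(ref_sd)) || any(ref_sd <= 0))
    stop_domain("ref_sd must be finite and > 0")
  (value - ref_mean) / ref_sd
}

#' log10 transform for inverted-cling times
#'
#' Cling times are right-skewed; the composite is computed on the log10
#' scale. Zero-second times (a fall at release) are refused rather than
#' imputed with a pseudo-time.
#'
#' @param seconds positive cling time(s) in seconds.
#' @return log10(seconds).
#' @export
transform_inverted_cling <- function(seconds) {
  if (any(!is.finite(seconds)) || any(seconds <= 0))
    stop_domain("inverted cling times must be finite and > 0 (log10 scale)")
  log10(seconds)
}

#' Reference-group means and SDs per determinant
#'
#' Computes the per-determinant mean and sample SD (n-1 denominator) of the
#' reference (young) group. The inverted cling determinant is summarized on
#' the log10 scale, matching how it is scored.
#'
#' @param records data.frame with columns `animal_id` and the five
#'   determinants named in [CFAB_DETERMINANTS].
#' @return object of class `cfab_reference`: list with numeric vectors
#'   `mean` and `sd`, named by determinant (cling stats on log10 scale).
#' @export
reference_stats <- function(records) {
  records <- as.data.frame(records)
  miss <- setdiff(CFAB_DETERMINANTS, names(records))
  if (length(miss))
    stop_domain("missing determinant column(s): ", paste(miss, collapse = ", "))
  if (nrow(records) < 2)
    stop_domain("need at least 2 reference animals")
  vals <- records[CFAB_DETERMINANTS]
  if (any(!is.finite(as.matrix(vals))))
    stop_domain("non-finite determinant measurement in reference group")
  vals$inverted_cling_s <- transform_inverted_cling(vals$inverted_cling_s)
  m <- vapply(vals, mean, numeric(1))
  s <- vapply(vals, sd, numeric(1))
  if (any(s <= 0))
    stop_domain("zero variance in reference determinant(s): ",
                paste(CFAB_DETERMINANTS[s <= 0], collapse = ", "))
  structure(list(mean = m, sd = s), class = "cfab_reference")
}

#' @export
print.cfab_reference <- function(x, ...) {
  cat("CFAB reference stats (cling on log10 scale):\n")
  print(round(rbind(mean = x$mean, sd = x$sd), 4))
  invisible(x)
}

#' CFAB composite scores for a table of animals
#'
#' Scores each animal's five determinants against the reference stats
#' (inverted cling on the log10 scale) and sums them into the CFAB
#' composite. A more negative CFAB indicates worse overall physical
#' function relative to the reference group. Missing measurements are an
#' error, not imputed.
#'
#' @param records data.frame with `animal_id` and determinant columns.
#' @param ref a `cfab_reference` from [reference_stats()].
#' @return data.frame: `animal_id`, one z-score column per determinant
#'   (suffix `_z`), and `cfab` = their sum.
#' @export
cfab_table <- function(records, ref) {
  if (!inherits(ref, "cfab_reference")) stop_domain("ref must be cfab_reference")
  records <- as.data.frame(records)
  miss <- setdiff(c("animal_id", CFAB_DETERMINANTS), names(records))
  if (length(miss))
    stop_domain("missing column(s): ", paste(miss, collapse = ", "))
  vals <- records[CFAB_DETERMINANTS]
  if (any(!is.finite(as.matrix(vals))))
    stop_domain("non-finite determinant measurement; CFAB is undefined")
  vals$inverted_cling_s <- transform_inverted_cling(vals$inverted_cling_s)
  z <- mapply(function(v, d) determinant_score(v, ref$mean[[d]], ref$sd[[d]]),
              vals, CFAB_DETERMINANTS)
  z <- matrix(z, nrow = nrow(records),
              dimnames = list(NULL, paste0(CFAB_DETERMINANTS, "_z")))
  out <- data.frame(animal_id = records$animal_id, z, check.names = FALSE)
  out$cfab <- rowSums(z)
  out
}

#' Score a single animal
#'
#' Convenience wrapper around [cfab_table()] for one record.
#' @inheritParams cfab_table
#' @param record one-row data.frame (or coercible list) of measurements.
#' @return one-row data.frame of z-scores and `cfab`.
#' @export
cfab_score <- function(record, ref) {
  cfab_table(as.data.frame(record), ref)
}

#' One-way ANOVA with least-significant-difference post hoc tests
#'
#' Classical fixed-effects one-way ANOVA (F test) followed by unprotected
#' pairwise comparisons using the pooled within-group mean square (Fisher's
#' LSD): `t = (m_i - m_j) / sqrt(MSE (1/n_i + 1/n_j))` on N - k df, p-values
#' unadjusted. This is the standard analysis for group differences in CFAB,
#' its determinants, and muscle mass.
#'
#' @param values numeric response per animal.
#' @param groups group labels (coerced to factor), >= 2 groups with >= 2
#'   observations each.
#' @return list with `F`, `df` (c(between, within)), `p`, `group_means`,
#'   `mse`, and data.frame `lsd` (group1, group2, diff, t, p).
#' @export
group_anova_lsd <- function(values, groups) {
  if (length(values) != length(groups))
    stop_domain("values and groups differ in length")
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(factor(groups[keep]))
  k <- nlevels(groups)
  n_i <- tabulate(groups)
  if (k < 2 || any(n_i < 2))
    stop_domain("need >= 2 groups with >= 2 observations each")
  N <- length(values)
  m_i <- tapply(values, groups, mean)
  grand <- mean(values)
  ssb <- sum(n_i * (m_i - grand)^2)
  ssw <- sum((values - m_i[groups])^2)
  df1 <- k - 1; df2 <- N - k
  mse <- ssw / df2
  if (mse == 0) {
    # all groups internally constant; F is 0/0 if means also equal
    Fstat <- if (ssb == 0) 0 else Inf
  } else Fstat <- (ssb / df1) / mse
  p <- if (ssb == 0) 1 else pf(Fstat, df1, df2, lower.tail = FALSE)
  pairs <- utils::combn(levels(groups), 2)
  lsd <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    diff = m_i[pairs[1, ]] - m_i[pairs[2, ]],
    row.names = NULL
  )
  se <- sqrt(mse * (1 / n_i[match(lsd$group1, levels(groups))] +
                    1 / n_i[match(lsd$group2, levels(groups))]))
  lsd$t <- ifelse(se > 0, lsd$diff / se, ifelse(lsd$diff == 0, 0, Inf))
  lsd$p <- ifelse(lsd$diff == 0, 1, 2 * pt(abs(lsd$t), df2, lower.tail = FALSE))
  list(F = Fstat, df = c(between = df1, within = df2), p = p,
       group_means = m_i, mse = mse, lsd = lsd)
}
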