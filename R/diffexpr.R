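#' Median-of-ratios size factors
#'
#' Per-sample normalization constants: each gene's geometric mean across
#' samples is computed over genes with all-positive counts, and a sample's
#' factor is the median over those genes of count/geomean. Robust to
#' composition changes as long as most genes are not differentially
#' expressed.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @return positive numeric vector of per-sample factors, named by sample.
#' @export
size_factors <- function(counts) {
  counts <- as_count_matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop_domain("no gene has positive counts in every sample")
  lg <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(lg, 2, function(col) exp(median(col - geo)))
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop_domain("degenerate size factor")
  sf
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `padj_(i) = min_{j >= i} p_(j) * m / j`, capped
#' at 1, where p_(1) <= ... <= p_(m). NAs are passed through and do not
#' count toward m.
#'
#' @param pvals numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals)) stop_domain("pvals must be numeric")
  ok <- !is.na(pvals)
  p <- pvals[ok]
  if (any(p < 0 | p > 1)) stop_domain("p-values must lie in [0, 1]")
  m <- length(p)
  out <- rep(NA_real_, length(pvals))
  if (m > 0) {
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    adj <- pmin(1, cummin(p[o] * m / seq(m, 1)))[ro]
    out[ok] <- adj
  }
  out
}

#' Trend-shrunken negative-binomial dispersion estimates
#'
#' Per-gene method-of-moments dispersions on normalized counts, using the
#' pooled within-group variance so that real group differences do not
#' inflate the estimate: `alpha_hat = max((s2_within - mu)/mu^2, floor)`.
#' A mean-dispersion trend `alpha_tr(mu) = a0 + a1/mu` is fit across genes
#' by gamma-style iterated reweighted least squares with trimming, and the
#' final dispersion is the geometric interpolation
#' `exp(w log alpha_hat + (1-w) log alpha_tr)`, floored at `alpha_floor`.
#' By default `w` is chosen per gene empirically-Bayes style: the weight
#' on the gene-wise estimate is `s0^2 / (s0^2 + v_g)`, where `v_g`
#' approximates the sampling variance of `log alpha_hat` and `s0^2` is
#' the excess spread of gene-wise estimates around the trend. A fixed numeric `w` is honored when supplied. This is a
#' deliberately simplified stand-in for MAP dispersion estimators;
#' parameter-recovery and type-I calibration tests validate it.
#'
#' @param counts genes x samples count matrix.
#' @param factors per-sample size factors.
#' @param groups group labels per sample (used for within-group variance).
#' @param w weight on the per-gene estimate in the interpolation (0..1),
#'   or NULL (default) for the adaptive empirical-Bayes weight.
#' @param alpha_floor lower bound on dispersions.
#' @return list: `alpha` (final per-gene dispersion, NA for all-zero
#'   genes), `alpha_gene` (raw MoM), `alpha_trend`, `trend` (a0, a1),
#'   `base_mean` (mean normalized count).
#' @export
estimate_dispersions <- function(counts, factors, groups,
                                 w = NULL, alpha_floor = 1e-8) {
  counts <- as_count_matrix(counts)
  if (length(factors) != ncol(counts) || any(factors <= 0))
    stop_domain("factors must be positive, one per sample")
  groups <- factor(groups)
  if (length(groups) != ncol(counts))
    stop_domain("groups must have one label per sample")
  if (any(tabulate(groups) < 2))
    stop_domain("need >= 2 samples per group")
  norm <- sweep(counts, 2, factors, "/")
  mu <- rowMeans(norm)
  # pooled within-group variance, (n - k) denominator
  k <- nlevels(groups)
  ss <- 0
  for (g in levels(groups)) {
    sub <- norm[, groups == g, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
  }
  s2 <- ss / (ncol(norm) - k)
  alpha_gene <- ifelse(mu > 0, pmax((s2 - mu) / mu^2, alpha_floor), NA_real_)
  usable <- !is.na(alpha_gene) & mu > 0
  trend <- fit_dispersion_trend(mu[usable], alpha_gene[usable], alpha_floor)
  alpha_trend <- ifelse(mu > 0,
                        pmax(trend["a0"] + trend["a1"] / mu, alpha_floor),
                        NA_real_)
  # clamp the noisy gene-wise estimate to within 8x of the trend before
  # mixing: a floored estimate (observed variance <= mean) carries almost
  # no information at these sample sizes and would otherwise drag the
  # geometric interpolation to a uselessly small dispersion
  alpha_g_cl <- pmin(pmax(alpha_gene, alpha_trend / 8), alpha_trend * 8)
  if (is.null(w)) {
    # delta-method sampling variance of log alpha_hat under the trend
    # model, using exact NB cumulants (the kappa4 term matters: NB
    # fourth moments are far heavier than normal-theory 2 sigma^4/(n-1))
    n_g <- tabulate(groups)
    N <- ncol(norm)
    at <- alpha_trend
    sigma2 <- mu + at * mu^2
    kappa4 <- sigma2 * (1 + 6 * at * mu + 6 * at^2 * mu^2)
    mu4 <- kappa4 + 3 * sigma2^2
    var_ss <- Reduce(`+`, lapply(n_g, function(m)
      (m - 1)^2 / m * mu4 - (m - 1) * (m - 3) / m * sigma2^2))
    var_s2 <- var_ss / (N - k)^2
    var_alpha <- var_s2 / mu^4 + (1 / mu^2 + 2 * at / mu)^2 * sigma2 / N
    v_g <- var_alpha / at^2
    dev2 <- (log(alpha_g_cl) - log(alpha_trend))^2
    # excess (biological) spread of log dispersions around the trend;
    # if the observed spread is fully explained by sampling noise the
    # trend is trusted almost entirely (tiny floor is a numerical guard)
    s0_sq <- max(mean(dev2[usable]) - mean(v_g[usable]), 0.05^2)
    w <- s0_sq / (s0_sq + v_g)
  }
  alpha <- exp(w * log(alpha_g_cl) + (1 - w) * log(alpha_trend))
  alpha <- pmax(alpha, alpha_floor)
  list(alpha = alpha, alpha_gene = alpha_gene, alpha_trend = alpha_trend,
       trend = trend, base_mean = mu)
}

# Robust fit of the trend alpha_tr(mu) = a0 + a1/mu across genes.
# Gene-wise dispersion estimates are strongly right-skewed with a
# mean-dependent scale, so the fit targets the conditional MEAN via
# gamma-style IRLS (weights 1/fitted^2), iteratively trimming genes whose
# ratio to the current trend is extreme; a plain resistant (median-type)
# fit would track the mode and systematically underestimate the trend.
fit_dispersion_trend <- function(mu, alpha_hat, alpha_floor) {
  x <- 1 / mu
  y <- alpha_hat
  keep <- rep(TRUE, length(x))
  a <- c(mean(y), 0)
  for (it in 1:15) {
    f <- pmax(a[1] + a[2] * x, alpha_floor)
    ratio <- y / f
    keep_new <- ratio > 1e-4 & ratio < 15
    wts <- ifelse(keep_new, 1 / f^2, 0)
    sw <- sqrt(wts)
    fit <- tryCatch(lm.fit(cbind(sw, sw * x), sw * y),
                    error = function(e) NULL)
    if (is.null(fit)) break
    a_new <- fit$coefficients
    a_new[is.na(a_new)] <- 0
    done <- max(abs(a_new - a)) < 1e-10 && identical(keep_new, keep)
    a <- a_new; keep <- keep_new
    if (done) break
  }
  a0 <- max(a[1], 0)
  a1 <- max(a[2], 0)
  if (a0 == 0 && a1 == 0) a0 <- alpha_floor
  c(a0 = unname(a0), a1 = unname(a1))
}

#' Negative-binomial Wald test for a two-group contrast
#'
#' Per gene, fits the NB generalized linear model
#' `mu_gj = s_j * exp(b0 + b1 * I(group_j = old))` with variance
#' `mu + alpha mu^2` by iteratively reweighted least squares, reports the
#' group coefficient on the log2 scale (old over reference, so positive =
#' upregulated with age), its standard error from the information matrix,
#' the Wald statistic and its two-sided normal p-value, Benjamini-Hochberg
#' adjusted p-values over converged genes, and the a-priori DEG flag
#' (padj < alpha_cut and |log2fc| >= lfc_cut). All-zero genes are excluded
#' from testing; non-converged genes get NA p-values and do not count in
#' the BH m.
#'
#' @param counts genes x samples count matrix.
#' @param groups two-level factor (first level = reference/young).
#' @param factors optional size factors; computed if NULL.
#' @param dispersions optional per-gene dispersions; estimated if NULL.
#' @param alpha_cut adjusted-p DEG threshold (strict `<`), default 0.05.
#' @param lfc_cut absolute log2 fold-change DEG threshold (inclusive
#'   `>=`), default 1.
#' @param max_iter,tol IRLS iteration cap and coefficient tolerance.
#' @return data.frame of class `de_result`: gene_id, baseMean, log2fc,
#'   se, wald, pval, padj, is_deg, converged; attributes `size_factors`,
#'   `dispersions`, `groups`.
#' @export
nb_wald_test <- function(counts, groups, factors = NULL, dispersions = NULL,
                         alpha_cut = 0.05, lfc_cut = 1,
                         max_iter = 100, tol = 1e-8) {
  counts <- as_count_matrix(counts)
  groups <- factor(groups)
  if (nlevels(groups) != 2)
    stop_domain("exactly two groups required; got ", nlevels(groups))
  if (any(tabulate(groups) < 2))
    stop_domain("need >= 2 samples per group")
  if (is.null(factors)) factors <- size_factors(counts)
  if (is.null(dispersions))
    dispersions <- estimate_dispersions(counts, factors, groups)$alpha
  if (length(dispersions) != nrow(counts))
    stop_domain("one dispersion per gene required")

  norm <- sweep(counts, 2, factors, "/")
  base_mean <- rowMeans(norm)
  g_ind <- as.numeric(groups == levels(groups)[2])
  X <- cbind(1, g_ind)
  off <- log(factors)
  ln2 <- log(2)

  n_genes <- nrow(counts)
  log2fc <- se <- rep(NA_real_, n_genes)
  converged <- rep(FALSE, n_genes)
  testable <- base_mean > 0 & !is.na(dispersions)

  for (i in which(testable)) {
    fit <- nb_irls(counts[i, ], X, off, dispersions[i], max_iter, tol)
    if (fit$converged) {
      log2fc[i] <- fit$beta[2] / ln2
      se[i] <- fit$se[2] / ln2
      converged[i] <- TRUE
    }
  }

  wald <- log2fc / se
  pval <- 2 * pnorm(-abs(wald))
  padj <- bh_adjust(pval)
  is_deg <- !is.na(padj) & padj < alpha_cut & abs(log2fc) >= lfc_cut
  out <- data.frame(
    gene_id = rownames(counts), baseMean = base_mean,
    log2fc = log2fc, se = se, wald = wald, pval = pval, padj = padj,
    is_deg = is_deg, converged = converged,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "size_factors") <- factors
  attr(out, "dispersions") <- dispersions
  attr(out, "groups") <- groups
  class(out) <- c("de_result", "data.frame")
  out
}

# IRLS for one NB gene: log link, fixed dispersion alpha, offset off.
# Returns natural-log-scale coefficients and SEs from (X' W X)^-1 with
# W = mu / (1 + alpha mu).
nb_irls <- function(y, X, off, alpha, max_iter = 100, tol = 1e-8) {
  # initialize from group means of offset-corrected counts
  eta <- log(pmax(y / exp(off), 1e-8))
  beta <- tryCatch(qr.coef(qr(X), eta), error = function(e) rep(0, ncol(X)))
  beta[is.na(beta)] <- 0
  ok <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + off
    mu <- exp(pmin(eta, 700))
    if (any(!is.finite(mu))) break
    w <- mu / (1 + alpha * mu)
    z <- eta - off + (y - mu) / mu
    sw <- sqrt(w)
    fit <- tryCatch(qr.solve(qr(X * sw), sw * z), error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(fit))) break
    delta <- max(abs(fit - beta))
    beta <- fit
    if (delta < tol) { ok <- TRUE; break }
    # diverging fold changes (a group with all-zero counts) never settle
    if (max(abs(beta)) > 50) break
  }
  if (!ok) return(list(converged = FALSE))
  mu <- exp(pmin(drop(X %*% beta) + off, 700))
  w <- mu / (1 + alpha * mu)
  info <- crossprod(X * sqrt(w))
  cov <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(cov)) return(list(converged = FALSE))
  list(converged = TRUE, beta = beta, se = sqrt(diag(cov)))
}

#' log2 normalized counts
#'
#' `log2(count / size_factor + 1)`: a monotone, variance-damping transform
#' used in place of a regularized-log transform for regression, PCA, and
#' heatmaps. Zero counts map to 0.
#'
#' @param counts genes x samples count matrix.
#' @param factors positive per-sample size factors.
#' @return numeric matrix, same dimnames as `counts`.
#' @export
normalized_log2 <- function(counts, factors) {
  counts <- as_count_matrix(counts)
  if (length(factors) != ncol(counts) || any(factors <= 0))
    stop_domain("factors must be positive, one per sample")
  log2(sweep(counts, 2, factors, "/") + 1)
}

#' Express a log2 fold change as a truncated integer percent of baseline
#'
#' `trunc(100 * 2^log2fc)`: e.g. a log2fc of 3.599 is a 1211% expression
#' level relative to baseline, and 0 maps to 100 (no change).
#'
#' @param log2fc finite numeric.
#' @return integer percent (truncated toward zero).
#' @export
fold_change_percent <- function(log2fc) {
  if (any(!is.finite(log2fc))) stop_domain("log2fc must be finite")
  trunc(100 * 2^log2fc)
}

#' Express a negative log2 fold change as an x-fold decline
#'
#' `2^|log2fc|` truncated to two decimals: a log2fc of -2.51 is a
#' 5.69-fold decline.
#'
#' @param log2fc finite numeric (sign ignored).
#' @return fold value truncated to 2 decimal places.
#' @export
fold_decline <- function(log2fc) {
  if (any(!is.finite(log2fc))) stop_domain("log2fc must be finite")
  trunc(100 * 2^abs(log2fc)) / 100
}

#' PCA sample scores on the most variable genes
#'
#' Principal components of the samples, computed on the gene-wise-centered
#' normalized log2 matrix restricted to the `n_top` most variable genes
#' (the standard sample-clustering view of an RNA-seq experiment).
#'
#' @param norm normalized log2 matrix, genes x samples.
#' @param n_components number of components to return.
#' @param n_top number of most-variable genes used (default 500; all genes
#'   if fewer).
#' @return list: `scores` (samples x components), `percent_variance` (per
#'   returned component, out of total variance), `genes_used`.
#' @export
pca_scores <- function(norm, n_components = 2, n_top = 500) {
  norm <- as.matrix(norm)
  n_samp <- ncol(norm)
  if (n_samp < 2) stop_domain("need >= 2 samples")
  if (n_components > n_samp)
    stop_domain("more components requested than samples")
  v <- apply(norm, 1, var)
  keep <- order(v, decreasing = TRUE)[seq_len(min(n_top, nrow(norm)))]
  p <- prcomp(t(norm[keep, , drop = FALSE]), center = TRUE, scale. = FALSE)
  tot <- sum(p$sdev^2)
  pv <- if (tot > 0) 100 * p$sdev^2 / tot else rep(0, length(p$sdev))
  list(scores = p$x[, seq_len(n_components), drop = FALSE],
       percent_variance = pv[seq_len(n_components)],
       genes_used = rownames(norm)[keep])
}

#' Per-gene z-score matrix for the top differentially expressed genes
#'
#' Selects the top `k` DEGs by adjusted p-value, z-scores each gene's
#' normalized expression across samples, and clips to \[-3, 3\] (the
#' conventional heatmap color range). Constant genes (zero SD) are
#' excluded.
#'
#' @param norm normalized log2 matrix, genes x samples.
#' @param de `de_result` from [nb_wald_test()].
#' @param k number of genes (default 50); if fewer DEGs exist, all are
#'   returned with a warning.
#' @return numeric matrix, up to k genes x samples, values in \[-3, 3\].
#' @export
top_z_heatmap_data <- function(norm, de, k = 50) {
  norm <- as.matrix(norm)
  degs <- de[de$is_deg %in% TRUE, ]
  if (nrow(degs) == 0) stop_domain("no DEGs to plot")
  if (nrow(degs) < k) {
    warning("only ", nrow(degs), " DEGs available; returning all")
    k <- nrow(degs)
  }
  top <- degs$gene_id[order(degs$padj, degs$gene_id)][seq_len(k)]
  sub <- norm[top, , drop = FALSE]
  sds <- apply(sub, 1, sd)
  if (any(sds == 0)) sub <- sub[sds > 0, , drop = FALSE]
  z <- (sub - rowMeans(sub)) / apply(sub, 1, sd)
  pmin(pmax(z, -3), 3)
}

# Validate and coerce a count matrix: numeric, integer-valued,
# non-negative, unique dimnames.
as_count_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop_domain("counts must be numeric")
  if (any(is.na(counts)) || any(counts < 0))
    stop_domain("counts must be non-negative and complete")
  if (any(counts != floor(counts)))
    stop_domain("counts must be integers")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%06d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%03d", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop_domain("duplicate gene or sample ids")
  counts
}
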