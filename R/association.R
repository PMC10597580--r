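#' Regress a phenotype on one gene's normalized expression
#'
#' Ordinary least squares of phenotype (dependent) on normalized log2
#' expression (independent). The slope's null hypothesis (slope = 0) is
#' tested with `t = R sqrt((n-2)/(1-R^2))` on n-2 degrees of freedom; the
#' p-value is identical to the Pearson-correlation test, so R and its p
#' are symmetric in x and y while the slope is not.
#'
#' @param x numeric: normalized log2 expression per sample.
#' @param y numeric: phenotype value per sample (CFAB, one determinant
#'   z-score, or muscle mass), aligned to `x`.
#' @return list: slope, intercept, R, R2, pval, n.
#' @export
regress_gene <- function(x, y) {
  if (length(x) != length(y)) stop_domain("x and y differ in length")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_domain("non-finite values in regression input")
  n <- length(x)
  if (n < 3) stop_domain("need n >= 3 samples")
  sx <- sd(x)
  if (sx == 0) stop_domain("zero variance in expression; gene skipped")
  r <- cor(x, y)
  slope <- r * sd(y) / sx
  intercept <- mean(y) - slope * mean(x)
  if (sd(y) == 0) {
    # constant phenotype: flat line, no association
    return(list(slope = 0, intercept = mean(y), R = 0, R2 = 0,
                pval = 1, n = n))
  }
  r2 <- r^2
  if (abs(r) >= 1) {
    pval <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r2))
    pval <- 2 * pt(abs(tstat), n - 2, lower.tail = FALSE)
  }
  list(slope = slope, intercept = intercept, R = r, R2 = r2,
       pval = pval, n = n)
}

#' Classify an association by strength, direction, and regulation
#'
#' Strength uses inclusive thresholds: strong if |R| >= r_strong (0.70),
#' moderate if r_moderate (0.50) <= |R| < r_strong, else weak. Direction
#' is the sign of R. Regulation comes from the gene's differential-
#' expression log2 fold change: up if positive, down otherwise.
#'
#' @param R finite correlation coefficient.
#' @param de_log2fc the gene's DE log2 fold change (old over reference).
#' @param r_moderate,r_strong strength thresholds.
#' @return list: strength ("strong"/"moderate"/"weak"), direction
#'   ("positive"/"negative"), regulation ("up"/"down").
#' @export
classify_association <- function(R, de_log2fc,
                                 r_moderate = 0.50, r_strong = 0.70) {
  if (!is.finite(R)) stop_domain("R must be finite")
  if (abs(R) > 1 + 1e-12) stop_domain("|R| must be <= 1")
  strength <- if (abs(R) >= r_strong) "strong"
              else if (abs(R) >= r_moderate) "moderate" else "weak"
  direction <- if (R >= 0) "positive" else "negative"
  regulation <- if (!is.na(de_log2fc) && de_log2fc > 0) "up" else "down"
  list(strength = strength, direction = direction, regulation = regulation)
}

#' Screen all differentially expressed genes against phenotypes
#'
#' For every DEG and every supplied phenotype, regresses the phenotype on
#' the gene's normalized log2 expression, classifies the association, and
#' cross-tabulates strength x direction x regulation. Only the samples of
#' the contrast are regressed, and technical-replicate libraries each
#' carry their animal's single phenotype value (no averaging). Output is
#' ranked by |R| descending within phenotype, ties broken by gene_id.
#'
#' @param norm normalized log2 matrix (genes x samples) for the contrast's
#'   samples.
#' @param de `de_result` from [nb_wald_test()] (same genes); only rows
#'   with `is_deg` are screened.
#' @param phenotypes named list (or data.frame) of per-sample numeric
#'   vectors aligned to `colnames(norm)`.
#' @param r_moderate,r_strong strength thresholds passed to
#'   [classify_association()].
#' @return list of class `association_screen`: `table` (one row per
#'   DEG x phenotype: gene_id, phenotype, slope, intercept, R, R2, pval,
#'   log2fc, padj, strength, direction, regulation), `crosstab` (counts
#'   per phenotype x strength x direction x regulation), `skipped`
#'   (zero-variance genes per phenotype).
#' @export
association_screen <- function(norm, de, phenotypes,
                               r_moderate = 0.50, r_strong = 0.70) {
  norm <- as.matrix(norm)
  if (is.null(names(phenotypes)) || any(!nzchar(names(phenotypes))))
    stop_domain("phenotypes must be named")
  phenotypes <- as.list(as.data.frame(phenotypes))
  bad <- vapply(phenotypes,
                function(v) length(v) != ncol(norm) || any(!is.finite(v)),
                logical(1))
  if (any(bad))
    stop_domain("phenotype(s) misaligned or non-finite: ",
                paste(names(phenotypes)[bad], collapse = ", "))
  degs <- de[de$is_deg %in% TRUE, ]
  if (nrow(degs) == 0) stop_domain("no DEGs to screen")
  missing_genes <- setdiff(degs$gene_id, rownames(norm))
  if (length(missing_genes))
    stop_domain("DEG(s) absent from expression matrix: ",
                paste(head(missing_genes, 3), collapse = ", "))

  rows <- list()
  skipped <- list()
  for (ph in names(phenotypes)) {
    y <- phenotypes[[ph]]
    res <- lapply(degs$gene_id, function(g) {
      x <- norm[g, ]
      if (sd(x) == 0) return(NULL)
      fit <- regress_gene(x, y)
      cls <- classify_association(fit$R, degs$log2fc[degs$gene_id == g],
                                  r_moderate, r_strong)
      data.frame(gene_id = g, phenotype = ph,
                 slope = fit$slope, intercept = fit$intercept,
                 R = fit$R, R2 = fit$R2, pval = fit$pval,
                 log2fc = degs$log2fc[degs$gene_id == g],
                 padj = degs$padj[degs$gene_id == g],
                 strength = cls$strength, direction = cls$direction,
                 regulation = cls$regulation,
                 stringsAsFactors = FALSE)
    })
    null_i <- vapply(res, is.null, logical(1))
    skipped[[ph]] <- degs$gene_id[null_i]
    res <- res[!null_i]
    if (length(res)) {
      tab <- do.call(rbind, res)
      tab <- tab[order(-abs(tab$R), tab$gene_id), ]
      rows[[ph]] <- tab
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  crosstab <- as.data.frame(
    with(table, table(phenotype, strength, direction, regulation)),
    stringsAsFactors = FALSE)
  names(crosstab)[names(crosstab) == "Freq"] <- "n"
  structure(list(table = table, crosstab = crosstab, skipped = skipped),
            class = "association_screen")
}

#' @export
print.association_screen <- function(x, ...) {
  cat("Association screen:", length(unique(x$table$gene_id)), "DEGs x",
      length(unique(x$table$phenotype)), "phenotype(s)\n")
  for (ph in unique(x$table$phenotype)) {
    sub <- x$table[x$table$phenotype == ph, ]
    cat(sprintf("  %-12s strong %d, moderate %d, weak %d\n", ph,
                sum(sub$strength == "strong"),
                sum(sub$strength == "moderate"),
                sum(sub$strength == "weak")))
  }
  invisible(x)
}
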