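#' Read a GMT gene-set collection
#'
#' GMT is tab-separated: term id, description, then one gene id per field.
#' Sets must be non-empty; duplicate genes within a set are dropped.
#'
#' @param path path to a .gmt file.
#' @return named list of class `gene_set_collection`; each element is a
#'   character vector of gene ids with a `description` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_domain("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop_domain("GMT line ", i, ": need term, description, >=1 gene")
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop_domain("GMT line ", i, ": empty gene set")
    if (f[1] %in% names(sets)) stop_domain("duplicate term id: ", f[1])
    sets[[f[1]]] <- structure(genes, description = f[2])
  }
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#'
#' @param sets named list of character vectors (optionally with
#'   `description` attributes).
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- nm
    paste(c(nm, desc, as.character(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Hypergeometric over-representation of gene sets in a target list
#'
#' Fixed-threshold over-representation analysis: for each term, counts the
#' term genes in the background (B), in the target list (b), and reports
#' the enrichment ratio `E = (b/n)/(B/N)` together with the upper-tail
#' hypergeometric p-value `P[X >= b]` and Benjamini-Hochberg q-values
#' across terms. The background should be the set of all genes actually
#' tested (not the whole annotation). Terms with no background genes are
#' skipped.
#'
#' @param target character vector of target gene ids (e.g. the DEG list);
#'   must be a subset of `background`.
#' @param background character vector of background gene ids.
#' @param sets a `gene_set_collection` (named list of gene-id vectors).
#' @return data.frame: term, description, N, B, n, b, E, pval, qval;
#'   sorted by pval then term.
#' @export
hypergeometric_enrichment <- function(target, background, sets) {
  target <- unique(as.character(target))
  background <- unique(as.character(background))
  if (!length(background)) stop_domain("background is empty")
  if (length(setdiff(target, background)))
    stop_domain("target must be a subset of background")
  N <- length(background)
  n <- length(target)
  rows <- lapply(names(sets), function(nm) {
    in_bg <- intersect(sets[[nm]], background)
    B <- length(in_bg)
    if (B == 0) return(NULL)
    b <- length(intersect(in_bg, target))
    E <- if (b > 0) (b / n) / (B / N) else 0
    p <- phyper(b - 1, B, N - B, n, lower.tail = FALSE)
    desc <- attr(sets[[nm]], "description")
    data.frame(term = nm, description = if (is.null(desc)) nm else desc,
               N = N, B = B, n = n, b = b, E = E, pval = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop_domain("no term overlaps the background")
  out <- do.call(rbind, rows)
  out$qval <- bh_adjust(out$pval)
  out <- out[order(out$pval, out$term), ]
  rownames(out) <- NULL
  out
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score for hit
# positions `idx` (sorted) in a ranked list of length L with scores
# `scores` (full list, ranked order). Returns ES and leading-edge index
# range. Hits add |score|^w / NR; misses subtract 1/(L - k).
gsea_es <- function(idx, scores, weight_exponent) {
  k <- length(idx)
  L <- length(scores)
  wts <- abs(scores[idx])^weight_exponent
  nr <- sum(wts)
  if (nr == 0) wts <- rep(1, k) else wts <- wts / nr
  if (nr == 0) wts <- wts / k
  miss <- 1 / (L - k)
  cum_hit <- cumsum(wts)
  # running sum immediately after hit i, and immediately before hit i
  after <- cum_hit - (idx - seq_len(k)) * miss
  before <- c(0, cum_hit[-k]) - (idx - seq_len(k)) * miss
  top <- max(after)
  bottom <- min(before)
  if (top >= -bottom) {
    list(es = top, le_from = 1, le_to = which.max(after))
  } else {
    list(es = bottom, le_from = which.min(before), le_to = k)
  }
}

#' Preranked gene-set enrichment analysis (running-sum statistic)
#'
#' Genes are ranked by score (descending, ties broken by gene id); for
#' each set the weighted Kolmogorov-Smirnov running sum adds
#' `|score|^w / sum_set |score|^w` at set members and subtracts
#' `1/(L - |set|)` elsewhere; the enrichment score ES is the signed
#' maximum deviation from zero. The null distribution comes from random
#' gene-label permutations of set membership; NES divides ES by the mean
#' |null ES| of the same sign, the p-value is the same-sign permutation
#' tail fraction, and FDR compares the pooled null NES distribution with
#' the observed NES distribution (standard GSEA FDR). Sets with no
#' overlap, or covering the whole list, are skipped.
#'
#' @param ranked named numeric vector: gene id -> ranking score (e.g. the
#'   DE Wald statistic); names must be unique.
#' @param sets a `gene_set_collection`.
#' @param n_perm number of permutations (>= 100), default 1000.
#' @param weight_exponent running-sum weight w, default 1.
#' @param seed optional integer seed for the permutation stream.
#' @param fdr_cut significance threshold on FDR, default 0.25.
#' @return data.frame of class `gsea_result`: term, size, ES, NES, pval,
#'   fdr, significant, leading_edge (comma-separated gene ids), sorted by
#'   pval then term.
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 1000, weight_exponent = 1,
                           seed = NULL, fdr_cut = 0.25) {
  if (is.null(names(ranked)) || anyDuplicated(names(ranked)))
    stop_domain("ranked must be a named vector with unique gene ids")
  if (any(!is.finite(ranked))) stop_domain("ranking scores must be finite")
  if (n_perm < 100) stop_domain("n_perm must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  ord <- order(-ranked, names(ranked))
  scores <- unname(ranked[ord])
  genes <- names(ranked)[ord]
  L <- length(genes)
  pos <- setNames(seq_len(L), genes)

  keep <- character(0)
  obs <- list()
  for (nm in names(sets)) {
    idx <- sort(unname(pos[intersect(sets[[nm]], genes)]))
    if (length(idx) == 0 || length(idx) >= L) next  # no hits / no misses
    obs[[nm]] <- idx
    keep <- c(keep, nm)
  }
  if (!length(keep)) stop_domain("no usable gene set overlaps the ranking")

  res <- lapply(keep, function(nm) {
    idx <- obs[[nm]]
    e <- gsea_es(idx, scores, weight_exponent)
    k <- length(idx)
    null_es <- vapply(seq_len(n_perm), function(i) {
      ridx <- sort(sample.int(L, k))
      gsea_es(ridx, scores, weight_exponent)$es
    }, numeric(1))
    same <- if (e$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    pval <- if (length(same)) mean(abs(same) >= abs(e$es)) else 0
    denom <- if (length(same)) mean(abs(same)) else NA_real_
    nes <- if (!is.na(denom) && denom > 0) e$es / denom else NA_real_
    null_nes <- normalize_null(null_es)
    le <- genes[idx[seq(e$le_from, e$le_to)]]
    list(term = nm, size = k, ES = e$es, NES = nes, pval = pval,
         leading_edge = le, null_nes = null_nes)
  })

  pooled_null_nes <- unlist(lapply(res, `[[`, "null_nes"))
  obs_nes <- vapply(res, `[[`, numeric(1), "NES")
  fdr <- vapply(obs_nes, function(nes) gsea_fdr(nes, obs_nes, pooled_null_nes),
                numeric(1))
  out <- data.frame(
    term = vapply(res, `[[`, character(1), "term"),
    size = vapply(res, `[[`, numeric(1), "size"),
    ES = vapply(res, `[[`, numeric(1), "ES"),
    NES = obs_nes,
    pval = vapply(res, `[[`, numeric(1), "pval"),
    fdr = fdr,
    leading_edge = vapply(res, function(r) paste(r$leading_edge,
                                                 collapse = ","),
                          character(1)),
    stringsAsFactors = FALSE
  )
  out$significant <- !is.na(out$fdr) & out$fdr < fdr_cut
  out <- out[order(out$pval, out$term), ]
  rownames(out) <- NULL
  class(out) <- c("gsea_result", "data.frame")
  out
}

# NES-normalize one set's null ES vector (each sign by its mean |ES|).
normalize_null <- function(null_es) {
  pos <- null_es[null_es >= 0]; neg <- null_es[null_es < 0]
  out <- null_es
  if (length(pos) && mean(pos) > 0) out[null_es >= 0] <- pos / mean(pos)
  if (length(neg) && mean(abs(neg)) > 0)
    out[null_es < 0] <- neg / mean(abs(neg))
  out
}

# Standard GSEA FDR q-value for one observed NES against the pooled
# normalized null and the observed NES distribution.
gsea_fdr <- function(nes, obs_nes, null_nes) {
  if (is.na(nes)) return(NA_real_)
  if (nes >= 0) {
    null_frac <- mean(null_nes[null_nes >= 0] >= nes)
    obs_frac <- mean(obs_nes[obs_nes >= 0] >= nes)
  } else {
    null_frac <- mean(null_nes[null_nes < 0] <= nes)
    obs_frac <- mean(obs_nes[obs_nes < 0] <= nes)
  }
  if (is.nan(null_frac) || is.nan(obs_frac) || obs_frac == 0) return(NA_real_)
  min(1, null_frac / obs_frac)
}

#' Intersect over-representation and GSEA gene evidence
#'
#' High-confidence genes supported by both enrichment routes: the DEG
#' list intersected with the union of genes in over-represented terms and
#' with the union of leading-edge genes of significant GSEA terms.
#'
#' @param gorilla_genes character vector: union of genes belonging to
#'   over-represented terms (q-value below threshold).
#' @param gsea_genes character vector: union of leading-edge genes of
#'   significant GSEA terms (FDR below threshold).
#' @param degs character vector of DEG ids.
#' @return sorted character vector of the three-way intersection.
#' @export
intersect_methods <- function(gorilla_genes, gsea_genes, degs) {
  sort(intersect(intersect(unique(as.character(degs)),
                           unique(as.character(gorilla_genes))),
                 unique(as.character(gsea_genes))))
}
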