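#' Read a gene-by-sample count matrix from TSV
#'
#' First column gene_id, remaining columns one per sample, integer cells.
#' Duplicate ids, negative or non-integer counts are rejected with their
#' location.
#'
#' @param path TSV file path.
#' @return integer matrix, genes x samples.
#' @export
read_counts_tsv <- function(path) {
  if (!file.exists(path)) stop_domain("counts file not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_domain("counts TSV needs gene_id + >=1 sample")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop_domain("duplicate gene_id at line ",
                which(duplicated(ids))[1] + 1)
  m <- as.matrix(df[-1])
  if (!is.numeric(m)) stop_domain("non-numeric count cell(s)")
  bad <- which(is.na(m) | m < 0 | m != floor(m), arr.ind = TRUE)
  if (nrow(bad))
    stop_domain("invalid count at line ", bad[1, 1] + 1, ", column '",
                colnames(m)[bad[1, 2]], "'")
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' Write a count matrix to TSV
#' @param counts genes x samples matrix.
#' @param path output path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read sample metadata from TSV
#'
#' Requires columns sample_id, animal_id, age_group, run; determinant and
#' mass columns are carried through when present.
#'
#' @param path TSV file path.
#' @return data.frame with unique sample ids.
#' @export
read_metadata_tsv <- function(path) {
  if (!file.exists(path)) stop_domain("metadata file not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "animal_id", "age_group", "run")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_domain("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop_domain("duplicate sample_id at line ",
                which(duplicated(df$sample_id))[1] + 1)
  df
}

#' Write sample metadata to TSV
#' @param meta data.frame.
#' @param path output path.
#' @export
write_metadata_tsv <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Pipeline configuration
#'
#' Validates paths and thresholds for [run_pipeline()].
#'
#' @param counts_tsv,metadata_tsv input paths.
#' @param gmt_path optional GMT path; enrichment is skipped when NULL.
#' @param contrast length-2 character: c(reference group, old group).
#' @param alpha adjusted-p DEG cut-off (strict <), default 0.05.
#' @param lfc absolute log2fc DEG cut-off (inclusive >=), default 1.
#' @param r_moderate,r_strong association strength thresholds
#'   (0.50, 0.70).
#' @param gorilla_q q-value threshold for over-represented terms (0.05).
#' @param gsea_fdr GSEA significance FDR (0.25).
#' @param n_perm GSEA permutations.
#' @param seed integer seed (GSEA permutations).
#' @param out_dir output directory (created if needed).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts_tsv, metadata_tsv, gmt_path = NULL,
                            contrast = c("6m", "28m"),
                            alpha = 0.05, lfc = 1,
                            r_moderate = 0.50, r_strong = 0.70,
                            gorilla_q = 0.05, gsea_fdr = 0.25,
                            n_perm = 1000, seed = 1L,
                            out_dir = tempfile("cfabtx_out_")) {
  if (length(contrast) != 2 || contrast[1] == contrast[2])
    stop_domain("contrast must be two distinct group names")
  if (alpha <= 0 || lfc <= 0 || r_moderate <= 0 || gsea_fdr <= 0)
    stop_domain("thresholds must be positive")
  if (!(r_moderate < r_strong && r_strong <= 1))
    stop_domain("need r_moderate < r_strong <= 1")
  structure(list(counts_tsv = counts_tsv, metadata_tsv = metadata_tsv,
                 gmt_path = gmt_path, contrast = contrast, alpha = alpha,
                 lfc = lfc, r_moderate = r_moderate, r_strong = r_strong,
                 gorilla_q = gorilla_q, gsea_fdr = gsea_fdr,
                 n_perm = n_perm, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Composite scoring -> differential expression -> phenotype association
#' -> enrichment (when a GMT is supplied) -> result tables + manifest.
#' CFAB is computed per animal against the reference group; DE and the
#' association screen use the samples of the requested contrast (within
#' their own sequencing run), with technical-replicate reference
#' libraries kept separate and each carrying its animal's single CFAB
#' value. Every output CSV is listed in `manifest.json` with an md5
#' checksum; reruns with the same inputs and seed are byte-identical.
#'
#' @param config a `pipeline_config`.
#' @return (invisibly) list: cfab, anova, de, norm, screen, enrichment
#'   (gorilla, gsea, intersection, or NULL), files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  counts <- read_counts_tsv(config$counts_tsv)
  meta <- read_metadata_tsv(config$metadata_tsv)
  if (!setequal(colnames(counts), meta$sample_id))
    stop_domain("pipeline stage 'input': counts and metadata samples differ")
  meta <- meta[match(colnames(counts), meta$sample_id), ]
  ref <- config$contrast[1]; old <- config$contrast[2]
  if (!all(config$contrast %in% meta$age_group))
    stop_domain("pipeline stage 'input': contrast group(s) absent")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop_domain("pipeline stage '", name, "': ", conditionMessage(e)))

  # --- CFAB: one row per animal ------------------------------------
  res_cfab <- stage("cfab", {
    animals <- meta[!duplicated(meta$animal_id),
                    setdiff(names(meta), c("sample_id", "run"))]
    if (!all(CFAB_DETERMINANTS %in% names(animals)))
      stop_domain("metadata lacks determinant columns")
    ref_rec <- animals[animals$age_group == ref, ]
    rs <- reference_stats(ref_rec)
    scores <- cfab_table(animals, rs)
    scores$age_group <- animals$age_group
    an <- group_anova_lsd(scores$cfab, scores$age_group)
    list(ref_stats = rs, scores = scores, anova = an)
  })

  # --- Differential expression on the contrast's run ---------------
  in_run <- meta$age_group %in% config$contrast
  if ("run" %in% names(meta) && length(unique(meta$run)) > 1) {
    old_runs <- unique(meta$run[meta$age_group == old])
    in_run <- in_run & meta$run %in% old_runs
  }
  sub_counts <- counts[, meta$sample_id[in_run], drop = FALSE]
  sub_meta <- meta[in_run, ]
  de <- stage("diffexpr", {
    groups <- factor(sub_meta$age_group, levels = config$contrast)
    nb_wald_test(sub_counts, groups,
                 alpha_cut = config$alpha, lfc_cut = config$lfc)
  })
  norm <- normalized_log2(sub_counts, attr(de, "size_factors"))

  # --- Association screen ------------------------------------------
  screen <- stage("association", {
    sc <- res_cfab$scores
    i <- match(sub_meta$animal_id, sc$animal_id)
    ph <- list(cfab = sc$cfab[i])
    for (d in CFAB_DETERMINANTS)
      ph[[sub("_s$|_force$|_speed$", "", d)]] <- sc[[paste0(d, "_z")]][i]
    if ("ta_mass_mg" %in% names(sub_meta))
      ph$ta_mass <- sub_meta$ta_mass_mg
    if (any(de$is_deg))
      association_screen(norm, de, ph, config$r_moderate, config$r_strong)
    else NULL
  })

  # --- Enrichment ----------------------------------------------------
  enr <- NULL
  if (!is.null(config$gmt_path)) {
    enr <- stage("enrichment", {
      sets <- read_gmt(config$gmt_path)
      tested <- de$gene_id[de$converged]
      degs <- de$gene_id[de$is_deg]
      gor <- hypergeometric_enrichment(degs, tested, sets)
      ranked <- setNames(de$wald[de$converged], tested)
      gs <- gsea_preranked(ranked, sets, n_perm = config$n_perm,
                           seed = derive_seed(config$seed, 3L),
                           fdr_cut = config$gsea_fdr)
      gor_genes <- unique(unlist(
        sets[gor$term[!is.na(gor$qval) & gor$qval < config$gorilla_q]]))
      gsea_genes <- unique(unlist(
        strsplit(gs$leading_edge[gs$significant], ",", fixed = TRUE)))
      list(gorilla = gor, gsea = gs,
           intersection = intersect_methods(gor_genes, gsea_genes, degs))
    })
  }

  # --- Write outputs -------------------------------------------------
  files <- stage("write", {
    out <- function(f) file.path(config$out_dir, f)
    write.csv(res_cfab$scores, out("cfab_scores.csv"), row.names = FALSE)
    write.csv(res_cfab$anova$lsd, out("cfab_lsd.csv"), row.names = FALSE)
    write.csv(de, out(paste0("de_", ref, "_", old, ".csv")),
              row.names = FALSE)
    written <- c("cfab_scores.csv", "cfab_lsd.csv",
                 paste0("de_", ref, "_", old, ".csv"))
    if (!is.null(screen)) {
      write.csv(screen$table, out("associations.csv"), row.names = FALSE)
      write.csv(screen$crosstab, out("association_crosstab.csv"),
                row.names = FALSE)
      written <- c(written, "associations.csv", "association_crosstab.csv")
    }
    if (!is.null(enr)) {
      write.csv(enr$gorilla, out("enrichment_gorilla.csv"),
                row.names = FALSE)
      write.csv(enr$gsea, out("enrichment_gsea.csv"), row.names = FALSE)
      writeLines(enr$intersection, out("intersection_genes.txt"))
      written <- c(written, "enrichment_gorilla.csv",
                   "enrichment_gsea.csv", "intersection_genes.txt")
    }
    written
  })
  manifest <- list(
    inputs = list(counts = config$counts_tsv,
                  metadata = config$metadata_tsv,
                  gmt = config$gmt_path),
    contrast = config$contrast, seed = config$seed,
    thresholds = config[c("alpha", "lfc", "r_moderate", "r_strong",
                          "gorilla_q", "gsea_fdr")],
    package_version = as.character(utils::packageVersion("cfabtx")),
    outputs = as.list(tools::md5sum(file.path(config$out_dir, files)))
  )
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  } else {
    writeLines(utils::capture.output(utils::str(manifest)),
               file.path(config$out_dir, "manifest.txt"))
  }
  invisible(list(cfab = res_cfab, de = de, norm = norm, screen = screen,
                 enrichment = enr,
                 files = file.path(config$out_dir, files)))
}
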