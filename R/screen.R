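#' Read a differential-expression summary table
#'
#' One row per gene with the edgeR-style summary the screen consumes:
#' `gene`, `log2fc` (log2 fold change between the experiment's two contrast
#' groups), `fdr` (Benjamini-Hochberg adjusted p-value) and `mean_count`
#' (coverage proxy). Upstream model fitting is out of scope; this table is
#' an input.
#'
#' @param path CSV path with header gene,log2fc,fdr,mean_count.
#' @return data.frame of class `de_table`.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) {
    stop_rgstab(sprintf("file not found: %s", path), "rgstab_io_error")
  }
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE)
  de_table(df)
}

#' Construct and validate a differential-expression table
#' @param df data.frame with columns gene, log2fc, fdr, mean_count.
#' @return data.frame of class `de_table`.
#' @export
de_table <- function(df) {
  required <- c("gene", "log2fc", "fdr", "mean_count")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_rgstab(sprintf("DE table missing column(s): %s",
                        paste(missing_cols, collapse = ", ")),
                "rgstab_format_error")
  }
  if (any(df$fdr < 0 | df$fdr > 1, na.rm = TRUE)) {
    stop_rgstab("fdr must lie in [0, 1]", "rgstab_domain_error")
  }
  if (any(df$mean_count < 0, na.rm = TRUE)) {
    stop_rgstab("mean_count must be >= 0", "rgstab_domain_error")
  }
  df$gene <- as.character(df$gene)
  structure(df, class = c("de_table", "data.frame"))
}

#' Construct a gene-by-sample count matrix with a group design
#'
#' @param counts non-negative integer gene x sample matrix with dimnames.
#' @param groups named character vector mapping samples to groups.
#' @param experiment_id experiment label.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, groups, experiment_id = "experiment") {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop_rgstab("`counts` must be a numeric matrix", "rgstab_format_error")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_rgstab("counts must be non-negative integers", "rgstab_domain_error")
  }
  missing_samples <- setdiff(colnames(counts), names(groups))
  if (length(missing_samples)) {
    stop_rgstab(sprintf("design does not cover sample(s): %s",
                        paste(missing_samples, collapse = ", ")),
                "rgstab_format_error")
  }
  structure(
    list(counts = counts,
         groups = stats::setNames(as.character(groups[colnames(counts)]),
                                  colnames(counts)),
         experiment_id = experiment_id),
    class = "count_matrix"
  )
}

#' Read a count matrix (TSV) plus its two-column design file
#' @param counts_path TSV, genes as rows, first column `gene`.
#' @param design_path two-column delimited file `sample_id`, `group`.
#' @param experiment_id experiment label.
#' @return A [count_matrix].
#' @export
read_count_matrix <- function(counts_path, design_path,
                              experiment_id = "experiment") {
  if (!file.exists(counts_path)) {
    stop_rgstab(sprintf("file not found: %s", counts_path), "rgstab_io_error")
  }
  if (!file.exists(design_path)) {
    stop_rgstab(sprintf("design file not found: %s", design_path),
                "rgstab_io_error")
  }
  df <- utils::read.table(counts_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  design <- utils::read.table(design_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  count_matrix(m, stats::setNames(design$group, design$sample_id),
               experiment_id)
}

# counts-per-million normalisation; library-size confounding would dominate
# group tests on raw counts, so CPM is the default test scale.
cpm <- function(counts) {
  libsize <- colSums(counts)
  if (any(libsize == 0)) {
    stop_rgstab("sample with zero total counts", "rgstab_domain_error")
  }
  sweep(counts, 2L, libsize, "/") * 1e6
}

#' Filter genes by expression stability (non-differential expression)
#'
#' Keeps genes that are NOT significantly differentially expressed: absolute
#' log2 fold change at most `max_abs_log2fc` AND FDR at least `min_fdr`.
#'
#' @param de a [de_table].
#' @param max_abs_log2fc fold-change bound (default 1).
#' @param min_fdr FDR floor below which a gene counts as significant
#'   (default 0.05).
#' @return Character vector of retained gene names.
#' @export
filter_de_stability <- function(de, max_abs_log2fc = 1.0, min_fdr = 0.05) {
  # Inf / 0 give the vacuous filter
  stopifnot(!is.na(max_abs_log2fc), !is.na(min_fdr))
  keep <- abs(de$log2fc) <= max_abs_log2fc & de$fdr >= min_fdr
  de$gene[keep]
}

#' Filter genes by sequencing coverage
#' @param de a [de_table].
#' @param min_mean_count minimum mean (normalised) count; default 100,
#'   an arbitrary but documented choice.
#' @return Character vector of retained gene names.
#' @export
filter_coverage <- function(de, min_mean_count = 100) {
  stopifnot(min_mean_count >= 0)
  de$gene[de$mean_count >= min_mean_count]
}

#' One-way ANOVA p-value for a gene's counts across groups
#'
#' Classical fixed-effects one-way ANOVA on the gene's (by default
#' CPM-normalised) counts. When every group has zero within-group variance
#' and all group means are equal the p-value is 1 by convention.
#'
#' @param counts a [count_matrix] with >= 2 groups of >= 2 samples.
#' @param gene gene name.
#' @param normalize `"cpm"` (default) or `"none"`.
#' @return p-value.
#' @export
anova_counts <- function(counts, gene, normalize = c("cpm", "none")) {
  normalize <- match.arg(normalize)
  y <- gene_values(counts, gene, normalize)
  g <- factor(counts$groups)
  if (nlevels(g) < 2L) {
    stop_rgstab("ANOVA needs at least 2 groups", "rgstab_precondition_error")
  }
  if (any(table(g) < 2L)) {
    stop_rgstab("every group needs at least 2 samples",
                "rgstab_precondition_error")
  }
  if (all(tapply(y, g, stats::var) == 0)) {
    means <- tapply(y, g, mean)
    return(if (max(means) - min(means) == 0) 1 else 0)
  }
  fit <- stats::anova(stats::lm(y ~ g))
  unname(fit[["Pr(>F)"]][1])
}

#' Two-sample Student t-test p-value for a gene's counts
#'
#' Classic equal-variance (pooled) two-sided Student t-test; requires
#' exactly two groups, each with at least two samples.
#'
#' @inheritParams anova_counts
#' @return p-value.
#' @export
ttest_counts <- function(counts, gene, normalize = c("cpm", "none")) {
  normalize <- match.arg(normalize)
  y <- gene_values(counts, gene, normalize)
  g <- factor(counts$groups)
  if (nlevels(g) != 2L) {
    stop_rgstab("t-test needs exactly 2 groups", "rgstab_precondition_error")
  }
  if (any(table(g) < 2L)) {
    stop_rgstab("every group needs at least 2 samples",
                "rgstab_precondition_error")
  }
  a <- y[g == levels(g)[1]]
  b <- y[g == levels(g)[2]]
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    return(if (mean(a) == mean(b)) 1 else 0)
  }
  stats::t.test(a, b, var.equal = TRUE)$p.value
}

gene_values <- function(counts, gene, normalize) {
  stopifnot(inherits(counts, "count_matrix"))
  if (!gene %in% rownames(counts$counts)) {
    stop_rgstab(sprintf("gene '%s' not in count matrix", gene),
                "rgstab_format_error")
  }
  m <- if (normalize == "cpm") cpm(counts$counts) else counts$counts
  m[gene, ]
}

#' Screen candidate reference genes across several experiments
#'
#' A gene is selected iff, in EVERY experiment supplied, it passes the
#' stability filter (|log2FC| and FDR), the coverage filter, and shows no
#' significant group difference in counts (ANOVA p >= `alpha`; a Student
#' t-test p >= `alpha` too when the experiment has exactly two groups).
#'
#' @param experiments named list; each element is a list with components
#'   `de` (a [de_table]) and `counts` (a [count_matrix]). All experiments
#'   must share the same gene universe.
#' @param max_abs_log2fc,min_fdr passed to [filter_de_stability].
#' @param min_mean_count passed to [filter_coverage].
#' @param alpha non-significance level for the count tests (default 0.05).
#' @param normalize count normalisation for the tests, `"cpm"` or `"none"`.
#' @return A data.frame of class `screen_table`, one row per gene x
#'   experiment, with p-values, significance codes (ns / * / ** at
#'   0.05 / 0.01), component pass flags and the overall `selected` flag.
#' @export
select_candidates <- function(experiments, max_abs_log2fc = 1.0,
                              min_fdr = 0.05, min_mean_count = 100,
                              alpha = 0.05, normalize = c("cpm", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(length(experiments) >= 1L)
  if (is.null(names(experiments))) {
    names(experiments) <- paste0("experiment", seq_along(experiments))
  }
  universes <- lapply(experiments, function(e) sort(e$de$gene))
  ref <- universes[[1]]
  for (i in seq_along(universes)) {
    if (!identical(universes[[i]], ref)) {
      off <- union(setdiff(universes[[i]], ref), setdiff(ref, universes[[i]]))
      stop_rgstab(
        sprintf("gene universe mismatch in experiment '%s': %s",
                names(experiments)[i], paste(off, collapse = ", ")),
        "rgstab_integrity_error"
      )
    }
  }
  genes <- experiments[[1]]$de$gene

  per_exp <- lapply(names(experiments), function(id) {
    e <- experiments[[id]]
    kept_de  <- filter_de_stability(e$de, max_abs_log2fc, min_fdr)
    kept_cov <- filter_coverage(e$de, min_mean_count)
    two_groups <- length(unique(e$counts$groups)) == 2L
    anova_p <- vapply(genes, function(g)
      anova_counts(e$counts, g, normalize), numeric(1))
    t_p <- if (two_groups) {
      vapply(genes, function(g) ttest_counts(e$counts, g, normalize),
             numeric(1))
    } else rep(NA_real_, length(genes))
    data.frame(
      gene = genes, experiment = id,
      anova_p = anova_p, anova_code = sig_code(anova_p),
      t_p = t_p, t_code = ifelse(is.na(t_p), NA, sig_code(t_p)),
      passed_de = genes %in% kept_de,
      passed_coverage = genes %in% kept_cov,
      passed_anova = anova_p >= alpha & (is.na(t_p) | t_p >= alpha),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, per_exp)
  pass_all <- tab$passed_de & tab$passed_coverage & tab$passed_anova
  selected_genes <- names(which(tapply(pass_all, tab$gene, all)))
  tab$selected <- tab$gene %in% selected_genes
  rownames(tab) <- NULL
  structure(tab, class = c("screen_table", "data.frame"))
}

#' Write a screening table to CSV
#' @param screen a `screen_table` from [select_candidates].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_screen_table <- function(screen, path) {
  stopifnot(inherits(screen, "screen_table"))
  utils::write.table(as.data.frame(screen), path, sep = ",",
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
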