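#' Gene-by-sample expression matrix with an explicit scale
#'
#' The matrix carries one of three declared scales: `"CQ"` (mean raw
#' quantification cycles), `"CQE"` (efficiency-corrected cycles, the
#' equivalent cycle count at perfect doubling) or `"QUANTITY"` (relative
#' quantities, per-gene maximum exactly 1).
#'
#' @param values numeric gene x sample matrix with dimnames; no missing
#'   cells are allowed.
#' @param scale one of `"CQ"`, `"CQE"`, `"QUANTITY"`.
#' @param groups named character vector mapping every sample (column) to its
#'   experimental group.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, scale = c("CQ", "CQE", "QUANTITY"),
                              groups) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_rgstab("`values` must be a numeric matrix", "rgstab_format_error")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_rgstab("`values` needs gene rownames and sample colnames",
                "rgstab_format_error")
  }
  if (any(!is.finite(values))) {
    stop_rgstab("expression matrix has missing or non-finite cells",
                "rgstab_completeness_error")
  }
  if (scale == "QUANTITY" && any(values <= 0)) {
    stop_rgstab("QUANTITY-scale values must all be > 0", "rgstab_domain_error")
  }
  missing_samples <- setdiff(colnames(values), names(groups))
  if (length(missing_samples)) {
    stop_rgstab(
      sprintf("group map does not cover sample(s): %s",
              paste(missing_samples, collapse = ", ")),
      "rgstab_format_error"
    )
  }
  structure(
    list(values = values, scale = scale,
         groups = stats::setNames(as.character(groups[colnames(values)]),
                                  colnames(values)),
         gene_order = rownames(values), sample_order = colnames(values)),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> scale=%s: %d genes x %d samples, groups: %s\n",
              x$scale, nrow(x$values), ncol(x$values),
              paste(unique(x$groups), collapse = ", ")))
  print(utils::head(x$values), ...)
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Average technical replicates of a Cq table into a matrix
#'
#' Cell (gene, sample) is the arithmetic mean of that pair's replicate Cq
#' values; averaging is done on the Cq (log) scale. Every (gene, sample)
#' pair must be observed at least once.
#'
#' @param table a [cq_table].
#' @return An [expression_matrix] with `scale = "CQ"`.
#' @export
average_technical_replicates <- function(table) {
  stopifnot(inherits(table, "cq_table"))
  genes   <- unique(table$gene)
  samples <- unique(table$sample_id)
  m <- tapply(table$cq, list(factor(table$gene, genes),
                             factor(table$sample_id, samples)), mean)
  if (any(is.na(m))) {
    idx <- which(is.na(m), arr.ind = TRUE)
    pairs <- paste0("(", genes[idx[, 1]], ", ", samples[idx[, 2]], ")")
    stop_rgstab(
      sprintf("no Cq measurements for pair(s): %s",
              paste(utils::head(pairs, 5), collapse = ", ")),
      "rgstab_completeness_error"
    )
  }
  m <- matrix(m, nrow = length(genes),
              dimnames = list(genes, samples))
  expression_matrix(m, scale = "CQ", groups = cq_groups(table))
}

#' Correct Cq values for amplification efficiency
#'
#' Rescales each gene's cycles to the equivalent count at perfect doubling:
#' `CqE = Cq * log(E) / log(2)`. With E = 2 the transform is the identity.
#'
#' @param matrix an [expression_matrix] with `scale = "CQ"`.
#' @param efficiencies named numeric vector giving E for every gene,
#'   1 < E <= 2. There is no silent default; pass E = 2 explicitly to
#'   reproduce the uncorrected pipeline.
#' @return An [expression_matrix] with `scale = "CQE"`.
#' @export
#' @examples
#' m <- expression_matrix(matrix(c(30, 31), 1, dimnames = list("g", c("a", "b"))),
#'                        "CQ", c(a = "x", b = "x"))
#' efficiency_correct(m, c(g = 1.9))
efficiency_correct <- function(matrix, efficiencies) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (matrix$scale != "CQ") {
    stop_rgstab("efficiency correction applies to CQ-scale matrices",
                "rgstab_domain_error")
  }
  genes <- rownames(matrix$values)
  absent <- setdiff(genes, names(efficiencies))
  if (length(absent)) {
    stop_rgstab(
      sprintf("no efficiency supplied for gene(s): %s",
              paste(absent, collapse = ", ")),
      "rgstab_domain_error"
    )
  }
  e <- efficiencies[genes]
  bad <- genes[!is.finite(e) | e <= 1 | e > 2]
  if (length(bad)) {
    stop_rgstab(
      sprintf("efficiency outside (1, 2] for gene(s): %s",
              paste(bad, collapse = ", ")),
      "rgstab_domain_error"
    )
  }
  out <- matrix$values * (log(e) / log(2))
  expression_matrix(out, scale = "CQE", groups = matrix$groups)
}

#' Convert cycle values to relative quantities
#'
#' Per gene, `Q(g, s) = base^(min_s' Cq(g, s') - Cq(g, s))`, so the
#' highest-expressed sample of each gene gets quantity exactly 1 and each
#' additional cycle divides the quantity by `base`.
#'
#' @param matrix an [expression_matrix] on the `"CQ"` or `"CQE"` scale.
#' @param base amplification factor per cycle, > 1 (default 2).
#' @return An [expression_matrix] with `scale = "QUANTITY"`.
#' @export
to_relative_quantity <- function(matrix, base = 2) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (!matrix$scale %in% c("CQ", "CQE")) {
    stop_rgstab("relative quantities are computed from CQ or CQE scales",
                "rgstab_domain_error")
  }
  if (!is.finite(base) || base <= 1) {
    stop_rgstab("`base` must be > 1", "rgstab_domain_error")
  }
  if (length(matrix$values) == 0L) {
    stop_rgstab("empty matrix", "rgstab_domain_error")
  }
  mins <- apply(matrix$values, 1L, min)
  q <- base^sweep(-matrix$values, 1L, mins, "+")
  expression_matrix(q, scale = "QUANTITY", groups = matrix$groups)
}

#' Per-gene distribution summary of Cq values
#'
#' Quartiles use linear interpolation between order statistics
#' ([stats::quantile] type 7). Outliers are flagged by the Tukey rule
#' (outside the 1.5 x IQR fences); whiskers are the minimum and maximum of
#' the non-outlier values, so every outlier lies outside
#' `[whisker_low, whisker_high]`.
#'
#' @param matrix an [expression_matrix] with `scale = "CQ"`.
#' @return A data.frame with one row per gene: `gene`, `n`, `mean`,
#'   `median`, `q1`, `q3`, `whisker_low`, `whisker_high`, `n_outliers`, and
#'   a list column `outliers`.
#' @export
summarize_distribution <- function(matrix) {
  stopifnot(inherits(matrix, "expression_matrix"))
  rows <- lapply(rownames(matrix$values), function(g) {
    x <- matrix$values[g, ]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo <- q[1] - 1.5 * iqr
    hi <- q[3] + 1.5 * iqr
    out <- x[x < lo | x > hi]
    keep <- x[x >= lo & x <= hi]
    # whiskers extend from the box edges to the most extreme non-outlier,
    # so they never retract inside the box even when interpolated
    # quartiles fall below/above all retained observations
    data.frame(gene = g, n = length(x), mean = mean(x), median = q[2],
               q1 = q[1], q3 = q[3],
               whisker_low = min(keep, q[1]), whisker_high = max(keep, q[3]),
               n_outliers = length(out))
  })
  res <- do.call(rbind, rows)
  res$outliers <- lapply(rownames(matrix$values), function(g) {
    x <- matrix$values[g, ]
    q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    unname(x[x < q[1] - 1.5 * iqr | x > q[2] + 1.5 * iqr])
  })
  rownames(res) <- NULL
  res
}

#' Write an expression matrix (plus sidecar metadata) to CSV
#'
#' The matrix goes to `path` with genes as rows and a leading `gene`
#' column; scale and the sample-to-group map go to `<path>.meta` as
#' `key,value` lines so the pair round-trips through [read_expression_matrix].
#'
#' @param matrix an [expression_matrix].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "expression_matrix"))
  df <- data.frame(gene = rownames(matrix$values), matrix$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  meta <- c(paste0("scale,", matrix$scale),
            paste0("group:", names(matrix$groups), ",", matrix$groups))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' Read an expression matrix written by [write_expression_matrix]
#' @param path CSV path; `<path>.meta` must exist alongside.
#' @return An [expression_matrix].
#' @export
read_expression_matrix <- function(path) {
  meta_path <- paste0(path, ".meta")
  if (!file.exists(path) || !file.exists(meta_path)) {
    stop_rgstab(sprintf("matrix or sidecar metadata missing for %s", path),
                "rgstab_io_error")
  }
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  meta <- readLines(meta_path)
  scale <- sub("^scale,", "", meta[startsWith(meta, "scale,")])
  grp_lines <- meta[startsWith(meta, "group:")]
  keys <- sub(",.*$", "", sub("^group:", "", grp_lines))
  vals <- sub("^[^,]*,", "", sub("^group:", "", grp_lines))
  expression_matrix(m, scale = scale, groups = stats::setNames(vals, keys))
}
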