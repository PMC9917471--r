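#' Assign within-method ranks from stability values
#'
#' Ascending stability value maps to ranks 1..k (rank 1 = most stable).
#' Under the `average` policy tied values share the mean of their
#' positions (so ranks always sum to k(k+1)/2); under `strict_order` ties
#' are broken by gene-name order and ranks are the integers 1..k.
#'
#' @param stability named numeric vector of stability values (lower =
#'   more stable), or a `stability_result`.
#' @param tie_policy `"strict_order"` (default) or `"average"`.
#' @param method label stored on the result.
#' @return An object of class `method_ranking`: list with `method`,
#'   `ranks` (named numeric) and `source` (`"computed"` or `"supplied"`).
#' @export
assign_ranks <- function(stability, tie_policy = c("strict_order", "average"),
                         method = NULL) {
  tie_policy <- match.arg(tie_policy)
  if (inherits(stability, "stability_result")) {
    method <- method %||% stability$method
    stability <- stability$stability
    source <- "computed"
  } else {
    source <- "supplied"
  }
  if (any(is.na(stability))) {
    stop_rgstab("stability values contain NaN/NA", "rgstab_domain_error")
  }
  genes <- names(stability)
  stopifnot(!is.null(genes))
  ranks <- if (tie_policy == "average") {
    rank(stability, ties.method = "average")
  } else {
    ord <- order(stability, genes)
    stats::setNames(seq_along(ord)[order(ord)], genes)[genes]
  }
  method_ranking(stats::setNames(as.numeric(ranks), genes),
                 method = method %||% "unknown", source = source)
}

#' Construct a within-method ranking from explicit ranks
#' @param ranks named numeric vector, gene -> rank (>= 1; non-integer
#'   allowed for average-rank ties); ranks over k genes must sum to
#'   k(k+1)/2.
#' @param method method label.
#' @param source `"computed"` or `"supplied"`.
#' @return A `method_ranking`.
#' @export
method_ranking <- function(ranks, method, source = "supplied") {
  k <- length(ranks)
  if (abs(sum(ranks) - k * (k + 1) / 2) > 1e-8) {
    stop_rgstab("ranks must sum to k(k+1)/2", "rgstab_domain_error")
  }
  structure(list(method = method, ranks = ranks, source = source),
            class = "method_ranking")
}

#' @export
print.method_ranking <- function(x, ...) {
  cat(sprintf("<method_ranking> %s (%s)\n", x$method, x$source))
  print(sort(x$ranks), ...)
  invisible(x)
}

#' Comprehensive ranking by geometric mean of within-method ranks
#'
#' Aggregates two or more within-method rankings over the same gene set:
#' each gene's score is the geometric mean of its ranks, and the final
#' positions follow ascending geometric mean. Ties in the geometric mean
#' are broken by ascending arithmetic-mean rank, then by gene name.
#'
#' @param rankings list of [method_ranking] objects (>= 2) over an
#'   identical gene set.
#' @return An object of class `comprehensive_ranking`: a data.frame with
#'   columns `position`, `gene`, `gm_rank`, plus per-method rank columns;
#'   the aggregated method labels are stored in attribute `inputs`.
#' @export
geometric_mean_ranking <- function(rankings) {
  stopifnot(length(rankings) >= 2L,
            all(vapply(rankings, inherits, logical(1), "method_ranking")))
  gene_sets <- lapply(rankings, function(r) sort(names(r$ranks)))
  for (i in seq_along(gene_sets)) {
    if (!identical(gene_sets[[i]], gene_sets[[1]])) {
      off <- union(setdiff(gene_sets[[i]], gene_sets[[1]]),
                   setdiff(gene_sets[[1]], gene_sets[[i]]))
      stop_rgstab(sprintf("gene-set mismatch across rankings: %s",
                          paste(off, collapse = ", ")),
                  "rgstab_integrity_error")
    }
  }
  genes <- sort(names(rankings[[1]]$ranks))
  rank_mat <- vapply(rankings, function(r) r$ranks[genes],
                     numeric(length(genes)))
  rownames(rank_mat) <- genes
  labels <- vapply(rankings, function(r) r$method, character(1))
  colnames(rank_mat) <- make.unique(labels)

  gm <- apply(rank_mat, 1L, geo_mean)
  am <- rowMeans(rank_mat)
  ord <- order(gm, am, genes)
  df <- data.frame(position = seq_along(genes), gene = genes[ord],
                   gm_rank = unname(gm[ord]), stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(rank_mat[df$gene, , drop = FALSE],
                                row.names = seq_along(genes)))
  structure(df, inputs = labels,
            class = c("comprehensive_ranking", "data.frame"))
}

#' Subset comprehensive ranking for one input-scale family
#'
#' Aggregates only the efficiency-corrected methods
#' (`CqE_methods` = geNorm + NormFinder) or the raw-Cq methods
#' (`Cq_methods` = BestKeeper + DeltaCt).
#'
#' @param rankings list of [method_ranking] objects including the
#'   requested methods.
#' @param subset `"CqE_methods"` or `"Cq_methods"`.
#' @return A [geometric_mean_ranking] result over the two methods.
#' @export
subset_ranking <- function(rankings, subset = c("CqE_methods", "Cq_methods")) {
  subset <- match.arg(subset)
  wanted <- if (subset == "CqE_methods") c("geNorm", "NormFinder")
            else c("BestKeeper", "DeltaCt")
  labels <- vapply(rankings, function(r) r$method, character(1))
  missing_m <- setdiff(wanted, labels)
  if (length(missing_m)) {
    stop_rgstab(sprintf("ranking(s) missing for method(s): %s",
                        paste(missing_m, collapse = ", ")),
                "rgstab_domain_error")
  }
  geometric_mean_ranking(rankings[match(wanted, labels)])
}

#' Write a comprehensive ranking to CSV
#' @param ranking a `comprehensive_ranking`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_comprehensive_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "comprehensive_ranking"))
  utils::write.table(as.data.frame(ranking), path, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Published within-method rank orders shipped as a fixture
#'
#' Loads the packaged fixture of within-method stability rankings of six
#' candidate reference genes in three lettuce experiments (leaf-colour
#' comparison, leaf-vs-stem tissue comparison, drought stress), as printed
#' by the four estimators.
#'
#' @param experiment one of `"green_vs_red"`, `"leaf_vs_stem"`,
#'   `"drought"`.
#' @return Named list of four [method_ranking] objects (geNorm,
#'   NormFinder, BestKeeper, DeltaCt) with `source = "supplied"`.
#' @export
published_rankings <- function(experiment = c("green_vs_red", "leaf_vs_stem",
                                              "drought")) {
  experiment <- match.arg(experiment)
  path <- system.file("extdata", "published_method_ranks.csv",
                      package = "rgstab", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE)
  df <- df[df$experiment == experiment, ]
  methods <- c("geNorm", "NormFinder", "BestKeeper", "DeltaCt")
  out <- lapply(methods, function(m) {
    sub <- df[df$method == m, ]
    method_ranking(stats::setNames(as.numeric(sub$rank), sub$gene),
                   method = m, source = "supplied")
  })
  stats::setNames(out, methods)
}
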