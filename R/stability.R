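#' geNorm expression-stability analysis
#'
#' For each gene pair (j, k) the pairwise variation V_jk is the sample
#' standard deviation (n - 1 denominator), over samples, of the log2 ratio
#' of their relative quantities. A gene's M value is the mean of its V_jk
#' over all other genes; lower M means more stable expression. The least
#' stable gene (highest M) is removed and M recomputed, down to the final
#' pair, whose two genes share the 2-gene M (the SD of their log ratio) —
#' geNorm can never separate its two most stable genes.
#'
#' When two genes tie for the worst M mid-iteration, the lexicographically
#' last gene name is removed; this makes the exclusion order deterministic.
#'
#' @param matrix an [expression_matrix]. `QUANTITY` scale is expected (the
#'   ratio model); a `CQ`/`CQE` matrix is converted via
#'   [to_relative_quantity] with base 2, with a warning.
#' @param compute_v also compute the pairwise variations V_n/n+1 of
#'   normalisation factors built from the n and n + 1 most stable genes
#'   (default TRUE). No cutoff decision is taken on them.
#' @return An object of class `genorm_result` with components
#'   `stability` (named vector of M at each gene's exclusion step; the
#'   final pair shares the minimal M), `ranking` (gene names, most stable
#'   first), `exclusion_order` (first removed = least stable) and
#'   `pairwise_v` (named vector `V2/3`, ... or NULL).
#' @export
genorm <- function(matrix, compute_v = TRUE) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (matrix$scale != "QUANTITY") {
    warning("genorm expects QUANTITY scale; converting with base 2")
    matrix <- to_relative_quantity(matrix, base = 2)
  }
  q <- matrix$values
  k <- nrow(q)
  if (k < 3L) stop_rgstab("genorm needs >= 3 genes", "rgstab_precondition_error")
  if (ncol(q) < 2L) {
    stop_rgstab("genorm needs >= 2 samples", "rgstab_precondition_error")
  }
  if (any(q <= 0)) {
    stop_rgstab("quantities must be > 0", "rgstab_domain_error")
  }
  lq <- log2(q)
  genes <- rownames(q)

  m_of <- function(active) {
    sub <- lq[active, , drop = FALSE]
    vapply(active, function(g) {
      others <- setdiff(active, g)
      mean(vapply(others, function(h) sd1(sub[g, ] - sub[h, ]), numeric(1)))
    }, numeric(1))
  }

  active <- genes
  m_value <- stats::setNames(rep(NA_real_, k), genes)
  exclusion_order <- character(0)
  while (length(active) > 2L) {
    m <- m_of(active)
    worst_m <- max(m)
    tied <- names(m)[m == worst_m]
    worst <- sort(tied)[length(tied)]  # lexicographically last among ties
    m_value[worst] <- worst_m
    exclusion_order <- c(exclusion_order, worst)
    active <- setdiff(active, worst)
  }
  final_m <- sd1(lq[active[1], ] - lq[active[2], ])
  m_value[active] <- final_m
  # final pair ordered deterministically (alphabetical) for ranking output
  pair <- sort(active)
  exclusion_order <- c(exclusion_order, pair[2], pair[1])
  ranking <- rev(exclusion_order)

  pairwise_v <- NULL
  if (compute_v && k >= 4L) {
    ns <- 2:(k - 1)
    nf <- function(n) {
      top <- ranking[seq_len(n)]
      apply(lq[top, , drop = FALSE], 2L, mean)  # log2 geometric mean
    }
    pairwise_v <- stats::setNames(
      vapply(ns, function(n) sd1(nf(n) - nf(n + 1)), numeric(1)),
      paste0("V", ns, "/", ns + 1)
    )
  }

  structure(
    list(stability = m_value, ranking = ranking,
         exclusion_order = exclusion_order, pairwise_v = pairwise_v,
         method = "geNorm"),
    class = c("genorm_result", "stability_result")
  )
}

#' NormFinder expression-stability analysis
#'
#' ANOVA-type variance decomposition on log-scale expression (Cq is
#' inherently log-scale). Values are first centred per sample across genes;
#' then, per gene g and group j, the intragroup variance sigma^2_gj is
#' estimated from the within-group variance of the centred values with a
#' correction for the gene-averaging step; with two or more groups the
#' intergroup deviation d_gj (the gene x group interaction) is estimated
#' and shrunk towards zero by an empirical-Bayes factor. The stability
#' value combines both sources:
#' `SV(g) = mean_j( |d_gj~| + sqrt(sigma^2_gj / n_j) )`; with a single
#' group it reduces to `sqrt(sigma^2_g)`. Lower values mean more stability.
#'
#' @param matrix an [expression_matrix] on `CQE` (preferred) or `CQ`
#'   scale; a `QUANTITY` matrix draws a warning and is log2-transformed.
#' @param shrink apply the empirical-Bayes shrinkage of intergroup
#'   deviations (default TRUE); simplified reimplementations omit it.
#' @return An object of class `normfinder_result` with components
#'   `stability` (named vector, lower = more stable), `ranking`,
#'   `intra_var` (gene x group matrix of intragroup variance estimates) and
#'   `inter_dev` (gene x group matrix of shrunk intergroup deviations, NULL
#'   with one group).
#' @export
normfinder <- function(matrix, shrink = TRUE) {
  stopifnot(inherits(matrix, "expression_matrix"))
  y <- matrix$values
  if (matrix$scale == "QUANTITY") {
    warning("normfinder expects a log-like scale (CQ/CQE); taking log2")
    y <- log2(y)
  }
  k <- nrow(y)
  if (k < 3L) {
    stop_rgstab("normfinder needs >= 3 genes", "rgstab_precondition_error")
  }
  grp <- factor(matrix$groups)
  n_j <- table(grp)
  if (any(n_j < 2L)) {
    stop_rgstab("every group needs >= 2 samples", "rgstab_precondition_error")
  }
  G <- nlevels(grp)
  genes <- rownames(y)

  # centre each sample across genes: removes the sample effect
  z <- sweep(y, 2L, colMeans(y), "-")

  # intragroup variances, corrected for the per-sample gene averaging
  s2 <- matrix(NA_real_, k, G, dimnames = list(genes, levels(grp)))
  for (j in levels(grp)) {
    zj <- z[, grp == j, drop = FALSE]
    s2[, j] <- apply(zj, 1L, stats::var)
  }
  S_j <- (k / (k - 1)) * colSums(s2)
  sigma2 <- sweep(s2, 2L, S_j / k^2, "-") / (1 - 2 / k)
  sigma2[sigma2 < 0] <- 0

  inter_dev <- NULL
  if (G >= 2L) {
    a <- matrix(NA_real_, k, G, dimnames = list(genes, levels(grp)))
    for (j in levels(grp)) a[, j] <- rowMeans(z[, grp == j, drop = FALSE])
    d <- a - rowMeans(a)
    var_term <- sweep(sigma2, 2L, as.numeric(n_j), "/")
    if (shrink) {
      sigma2_d <- max(0, stats::var(as.vector(d)) - mean(var_term))
      gamma <- sigma2_d / (sigma2_d + var_term)
      gamma[!is.finite(gamma)] <- 0  # sigma2_d = var_term = 0
      d_tilde <- d * gamma
    } else {
      d_tilde <- d
    }
    stability <- rowMeans(abs(d_tilde) + sqrt(var_term))
    inter_dev <- d_tilde
  } else {
    stability <- sqrt(sigma2[, 1])
  }
  names(stability) <- genes

  structure(
    list(stability = stability,
         ranking = genes[order(stability, genes)],
         intra_var = sigma2, inter_dev = inter_dev, method = "NormFinder"),
    class = c("normfinder_result", "stability_result")
  )
}

#' BestKeeper descriptive stability analysis
#'
#' Per gene, descriptive statistics of the raw mean Cq values: sample SD
#' (n - 1), coefficient of variation (100 * SD / arithmetic mean), and the
#' Pearson correlation of the gene's Cq with the BestKeeper index — the
#' per-sample geometric mean of all candidate genes' Cq. Genes are ranked
#' by SD alone (CV and r are reported, not ranked on); an alternative
#' stability measure, the mean absolute deviation around the mean as in
#' the classic spreadsheet tool, is available via `use_mad`.
#'
#' @param matrix an [expression_matrix]; `CQ` scale expected, other scales
#'   draw a warning but are accepted.
#' @param use_mad rank by mean absolute deviation instead of SD
#'   (default FALSE).
#' @return An object of class `bestkeeper_result` with `stability` (the SD
#'   of Cq, or MAD when `use_mad`), `ranking`, a per-gene `summary`
#'   data.frame (geo_mean, arith_mean, min, max, sd_cq, cv_pct, mad_cq,
#'   r_index) and `index` (per-sample geometric-mean Cq).
#' @export
bestkeeper <- function(matrix, use_mad = FALSE) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (matrix$scale != "CQ") {
    warning("bestkeeper is defined on raw mean Cq; input scale is ",
            matrix$scale)
  }
  m <- matrix$values
  if (ncol(m) < 2L) {
    stop_rgstab("bestkeeper needs >= 2 samples", "rgstab_precondition_error")
  }
  if (any(m <= 0)) stop_rgstab("Cq must be > 0", "rgstab_domain_error")
  genes <- rownames(m)

  index <- apply(m, 2L, geo_mean)
  summary <- data.frame(
    gene = genes,
    geo_mean = apply(m, 1L, geo_mean),
    arith_mean = rowMeans(m),
    min = apply(m, 1L, min),
    max = apply(m, 1L, max),
    sd_cq = apply(m, 1L, sd1),
    mad_cq = apply(m, 1L, function(x) mean(abs(x - mean(x)))),
    row.names = NULL
  )
  summary$cv_pct <- 100 * summary$sd_cq / summary$arith_mean
  summary$r_index <- vapply(genes, function(g) {
    if (sd1(m[g, ]) == 0 || sd1(index) == 0) return(NA_real_)
    stats::cor(m[g, ], index)
  }, numeric(1))

  stability <- stats::setNames(
    if (use_mad) summary$mad_cq else summary$sd_cq, genes)

  structure(
    list(stability = stability,
         ranking = genes[order(stability, genes)],
         summary = summary, index = index, method = "BestKeeper"),
    class = c("bestkeeper_result", "stability_result")
  )
}

#' Comparative delta-Ct stability analysis
#'
#' For every ordered gene pair (g, h), the per-sample Cq difference
#' `dCq(s) = Cq_g(s) - Cq_h(s)` is formed and its sample SD (n - 1) taken
#' over samples. A gene's stability value is the mean of these pair SDs
#' over all partner genes; lower means more stable.
#'
#' @param matrix an [expression_matrix]; `CQ` scale expected, other scales
#'   draw a warning but are accepted.
#' @return An object of class `delta_ct_result` with `stability` (mean
#'   pairwise SD per gene), `ranking` and `pair_sd` (symmetric gene x gene
#'   SD matrix with zero diagonal).
#' @export
delta_ct <- function(matrix) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (matrix$scale != "CQ") {
    warning("delta_ct is defined on raw mean Cq; input scale is ",
            matrix$scale)
  }
  m <- matrix$values
  k <- nrow(m)
  if (k < 2L) stop_rgstab("delta_ct needs >= 2 genes",
                          "rgstab_precondition_error")
  if (ncol(m) < 2L) {
    stop_rgstab("delta_ct needs >= 2 samples", "rgstab_precondition_error")
  }
  genes <- rownames(m)
  pair_sd <- matrix(0, k, k, dimnames = list(genes, genes))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      s <- sd1(m[i, ] - m[j, ])
      pair_sd[i, j] <- s
      pair_sd[j, i] <- s
    }
  }
  stability <- rowSums(pair_sd) / (k - 1)

  structure(
    list(stability = stability,
         ranking = genes[order(stability, genes)],
         pair_sd = pair_sd, method = "DeltaCt"),
    class = c("delta_ct_result", "stability_result")
  )
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("<%s stability>\n", x$method))
  ord <- x$ranking
  df <- data.frame(rank = seq_along(ord), gene = ord,
                   stability = unname(x$stability[ord]))
  print(df, row.names = FALSE, ...)
  invisible(x)
}

#' Turn a stability result into a gene / stability_value / rank data.frame
#' @param x a `stability_result`.
#' @param ... unused.
#' @return data.frame with columns gene, stability_value, rank.
#' @export
as.data.frame.stability_result <- function(x, ...) {
  ord <- x$ranking
  data.frame(gene = ord, stability_value = unname(x$stability[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Write a stability result to CSV (gene, stability_value, rank)
#' @param result a `stability_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_stability_result <- function(result, path) {
  stopifnot(inherits(result, "stability_result"))
  df <- as.data.frame(result)
  # method-specific auxiliary columns
  if (inherits(result, "bestkeeper_result")) {
    df <- merge(df, result$summary[, c("gene", "sd_cq", "cv_pct", "r_index")],
                by = "gene", sort = FALSE)
    df <- df[order(df$rank), ]
  } else if (inherits(result, "delta_ct_result")) {
    df$mean_pair_sd <- df$stability_value
  }
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Run all four stability estimators on a Cq table
#'
#' Scale policy follows the standard workflow: BestKeeper and the
#' comparative delta-Ct method consume mean raw Cq; geNorm and NormFinder
#' consume efficiency-corrected CqE (geNorm via base-2 relative
#' quantities). With `efficiencies = NULL` and no efficiency column in the
#' table, E = 2 is required explicitly — pass `perfect_efficiency = TRUE`
#' to run the uncorrected pipeline.
#'
#' @param table a [cq_table].
#' @param efficiencies named per-gene efficiency vector; default taken from
#'   the table's efficiency column.
#' @param perfect_efficiency set TRUE to use E = 2 for all genes when no
#'   efficiencies are available.
#' @param methods subset of c("geNorm", "NormFinder", "BestKeeper",
#'   "DeltaCt").
#' @return Named list of `stability_result` objects.
#' @export
stability_suite <- function(table, efficiencies = NULL,
                            perfect_efficiency = FALSE,
                            methods = c("geNorm", "NormFinder",
                                        "BestKeeper", "DeltaCt")) {
  methods <- match.arg(methods, several.ok = TRUE)
  cq <- average_technical_replicates(table)
  needs_e <- any(c("geNorm", "NormFinder") %in% methods)
  out <- list()
  if (needs_e) {
    e <- efficiencies %||% cq_efficiencies(table)
    if (is.null(e)) {
      if (!perfect_efficiency) {
        stop_rgstab(paste("geNorm/NormFinder need per-gene efficiencies;",
                          "none supplied and none in the table",
                          "(set perfect_efficiency = TRUE for E = 2)"),
                    "rgstab_domain_error")
      }
      e <- stats::setNames(rep(2, nrow(cq$values)), rownames(cq$values))
    }
    cqe <- efficiency_correct(cq, e)
    if ("geNorm" %in% methods) {
      out$geNorm <- genorm(to_relative_quantity(cqe, base = 2))
    }
    if ("NormFinder" %in% methods) out$NormFinder <- normfinder(cqe)
  }
  if ("BestKeeper" %in% methods) out$BestKeeper <- bestkeeper(cq)
  if ("DeltaCt" %in% methods) out$DeltaCt <- delta_ct(cq)
  out[methods]
}
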