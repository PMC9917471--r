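#' Specification for a simulated qPCR Cq experiment
#'
#' The generative model is Gaussian on the Cq (log) scale — the standard
#' qPCR error model:
#' `Cq(g, s, r) = baseline_g + delta_g(group(s)) + u_s + eps_gs + eta_gsr`
#' with sample effect `u_s ~ N(0, sample_effect_sd^2)`, gene-by-sample
#' noise `eps ~ N(0, noise_sd_g^2)` and technical-replicate noise
#' `eta ~ N(0, replicate_sd^2)`.
#'
#' @param genes data.frame with columns `name`, `baseline_cq` (cycles,
#'   plausibly within (20, 40)), `efficiency` (in (1, 2]), `noise_sd`
#'   (>= 0 cycles), plus optional `delta.<group>` columns of per-group
#'   shifts in cycles.
#' @param groups data.frame with columns `label`, `n_samples`.
#' @param sample_effect_sd,replicate_sd non-negative SDs in cycles.
#' @param n_replicates technical replicates per sample (>= 1).
#' @param seed integer; mandatory, no global random state is used.
#' @return An object of class `cq_sim_spec`.
#' @export
cq_sim_spec <- function(genes, groups, sample_effect_sd = 0.3,
                        replicate_sd = 0.15, n_replicates = 2L, seed) {
  stopifnot(is.data.frame(genes), is.data.frame(groups))
  required <- c("name", "baseline_cq", "efficiency", "noise_sd")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols)) {
    stop_rgstab(sprintf("gene spec missing column(s): %s",
                        paste(missing_cols, collapse = ", ")),
                "rgstab_format_error")
  }
  if (!all(c("label", "n_samples") %in% names(groups))) {
    stop_rgstab("group spec needs columns label, n_samples",
                "rgstab_format_error")
  }
  if (any(genes$noise_sd < 0) || sample_effect_sd < 0 || replicate_sd < 0) {
    stop_rgstab("all SDs must be >= 0", "rgstab_domain_error")
  }
  if (any(genes$efficiency <= 1 | genes$efficiency > 2)) {
    stop_rgstab("efficiency must lie in (1, 2]", "rgstab_domain_error")
  }
  if (any(genes$baseline_cq <= 20 | genes$baseline_cq >= 40)) {
    stop_rgstab("baseline_cq must lie in the plausible (20, 40) window",
                "rgstab_domain_error")
  }
  if (n_replicates < 1L) {
    stop_rgstab("n_replicates must be >= 1", "rgstab_domain_error")
  }
  if (missing(seed)) stop_rgstab("seed is mandatory", "rgstab_domain_error")
  structure(list(genes = genes, groups = groups,
                 sample_effect_sd = sample_effect_sd,
                 replicate_sd = replicate_sd,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "cq_sim_spec")
}

#' Simulate a qPCR Cq table from a specification
#'
#' Deterministic given the spec (which includes the seed); the caller's
#' RNG state is untouched.
#'
#' @param spec a [cq_sim_spec].
#' @param experiment_id label for the resulting table.
#' @return A [cq_table] including the per-gene `efficiency` column.
#' @export
simulate_cq <- function(spec, experiment_id = "simulated") {
  stopifnot(inherits(spec, "cq_sim_spec"))
  genes <- spec$genes
  groups <- spec$groups
  delta_cols <- paste0("delta.", groups$label)

  with_seed(spec$seed, {
    sample_id <- character(0); sample_group <- character(0)
    for (i in seq_len(nrow(groups))) {
      ids <- sprintf("%s_%02d", groups$label[i], seq_len(groups$n_samples[i]))
      sample_id <- c(sample_id, ids)
      sample_group <- c(sample_group, rep(groups$label[i],
                                          groups$n_samples[i]))
    }
    n_s <- length(sample_id)
    k <- nrow(genes)
    r <- spec$n_replicates
    u <- stats::rnorm(n_s, 0, spec$sample_effect_sd)

    # per-gene group shifts as a k x n_s matrix
    delta <- matrix(0, k, n_s)
    for (i in seq_len(nrow(groups))) {
      dcol <- paste0("delta.", groups$label[i])
      if (dcol %in% names(genes)) {
        delta[, sample_group == groups$label[i]] <- genes[[dcol]]
      }
    }
    eps <- matrix(stats::rnorm(k * n_s), k, n_s) * genes$noise_sd
    base <- genes$baseline_cq + delta + eps + rep(u, each = k)  # k x n_s

    # replicate index varies fastest, then gene, then sample
    eta <- stats::rnorm(k * n_s * r, 0, spec$replicate_sd)
    df <- data.frame(
      sample_id = rep(sample_id, each = k * r),
      group = rep(sample_group, each = k * r),
      gene = rep(rep(genes$name, each = r), times = n_s),
      replicate = rep(seq_len(r), times = k * n_s),
      cq = rep(as.vector(base), each = r) + eta,
      efficiency = rep(rep(genes$efficiency, each = r), times = n_s),
      stringsAsFactors = FALSE
    )
    cq_table(df, experiment_id = experiment_id)
  })
}

#' Specification for a simulated RNA-seq count experiment
#'
#' Counts are negative binomial with
#' `mean = base_mean * 2^(group_log2fc) * library_factor` and the usual
#' RNA-seq dispersion parameterisation `var = mu + dispersion * mu^2`.
#'
#' @param genes data.frame with columns `name`, `base_mean` (> 0),
#'   `dispersion` (> 0), plus optional `lfc.<group>` columns of per-group
#'   log2 fold changes (reference group 0).
#' @param groups data.frame with columns `label`, `n_samples`.
#' @param library_size_range length-2 positive numeric; per-sample library
#'   factors are drawn uniformly from this interval.
#' @param seed integer; mandatory.
#' @return An object of class `count_sim_spec`.
#' @export
count_sim_spec <- function(genes, groups, library_size_range = c(0.8, 1.2),
                           seed) {
  stopifnot(is.data.frame(genes), is.data.frame(groups))
  if (!all(c("name", "base_mean", "dispersion") %in% names(genes))) {
    stop_rgstab("gene spec needs columns name, base_mean, dispersion",
                "rgstab_format_error")
  }
  if (any(genes$base_mean <= 0)) {
    stop_rgstab("base_mean must be > 0", "rgstab_domain_error")
  }
  if (any(genes$dispersion <= 0)) {
    stop_rgstab("dispersion must be > 0", "rgstab_domain_error")
  }
  if (length(library_size_range) != 2L || any(library_size_range <= 0) ||
      diff(library_size_range) < 0) {
    stop_rgstab("library_size_range must be two positive increasing values",
                "rgstab_domain_error")
  }
  if (missing(seed)) stop_rgstab("seed is mandatory", "rgstab_domain_error")
  structure(list(genes = genes, groups = groups,
                 library_size_range = library_size_range,
                 seed = as.integer(seed)),
            class = "count_sim_spec")
}

#' Simulate an RNA-seq count matrix plus its ground-truth DE table
#'
#' @param spec a [count_sim_spec].
#' @param experiment_id label.
#' @return List with components `counts` (a [count_matrix]) and `truth`
#'   (a [de_table] holding each gene's true maximal between-group log2FC,
#'   an indicator FDR — 1 for genes with no planted effect, 0 otherwise —
#'   and the expected mean count), so screening filters can be tested
#'   against the generator's truth.
#' @export
simulate_counts <- function(spec, experiment_id = "simulated") {
  stopifnot(inherits(spec, "count_sim_spec"))
  genes <- spec$genes
  groups <- spec$groups

  with_seed(spec$seed, {
    sample_id <- character(0); sample_group <- character(0)
    for (i in seq_len(nrow(groups))) {
      ids <- sprintf("%s_%02d", groups$label[i], seq_len(groups$n_samples[i]))
      sample_id <- c(sample_id, ids)
      sample_group <- c(sample_group,
                        rep(groups$label[i], groups$n_samples[i]))
    }
    n_s <- length(sample_id)
    libf <- stats::runif(n_s, spec$library_size_range[1],
                         spec$library_size_range[2])

    m <- matrix(0L, nrow(genes), n_s,
                dimnames = list(genes$name, sample_id))
    lfc_mat <- matrix(0, nrow(genes), nrow(groups),
                      dimnames = list(genes$name, groups$label))
    for (j in groups$label) {
      col <- paste0("lfc.", j)
      if (col %in% names(genes)) lfc_mat[, j] <- genes[[col]]
    }
    for (g in seq_len(nrow(genes))) {
      mu <- genes$base_mean[g] * 2^(lfc_mat[g, sample_group]) * libf
      size <- 1 / genes$dispersion[g]
      m[g, ] <- stats::rnbinom(n_s, mu = mu, size = size)
    }

    # truth: largest absolute between-group contrast on the log2 scale
    true_lfc <- apply(lfc_mat, 1L, function(x) {
      i <- which.max(abs(outer(x, x, "-")))
      outer(x, x, "-")[i]
    })
    truth <- de_table(data.frame(
      gene = genes$name,
      log2fc = true_lfc,
      fdr = ifelse(abs(true_lfc) > 0, 0, 1),
      mean_count = genes$base_mean * rowMeans(2^lfc_mat[, sample_group,
                                                        drop = FALSE]) *
        mean(libf),
      stringsAsFactors = FALSE
    ))
    list(counts = count_matrix(m, stats::setNames(sample_group, sample_id),
                               experiment_id),
         truth = truth)
  })
}

#' A deterministic, study-shaped example Cq specification
#'
#' Six genes with the shape (not the values) of a lettuce reference-gene
#' panel: baselines spread over 31-38 cycles, synthetic efficiencies,
#' 2 groups x 3 biological samples x 2 technical replicates. One gene can
#' be destabilised by a planted group effect.
#'
#' @param seed integer seed.
#' @param unstable_gene gene name receiving the planted effect, or NULL.
#' @param delta planted group shift in cycles (applied to the second
#'   group).
#' @param n_samples biological samples per group.
#' @param groups character vector of group labels (default two colours).
#' @return A [cq_sim_spec].
#' @export
paperlike_cq_spec <- function(seed, unstable_gene = NULL, delta = 2,
                              n_samples = 3L,
                              groups = c("green", "red")) {
  genes <- data.frame(
    name = c("ADF2", "CYB5", "iPGAM", "SCL13", "TRXL3-3", "VHA-H"),
    baseline_cq = c(31.5, 31.0, 37.5, 37.0, 34.0, 33.0),
    efficiency = c(1.93, 1.88, 1.80, 1.76, 1.97, 1.85),
    noise_sd = c(0.25, 0.3, 0.3, 0.35, 0.3, 0.4),
    stringsAsFactors = FALSE
  )
  for (g in groups) genes[[paste0("delta.", g)]] <- 0
  if (!is.null(unstable_gene)) {
    stopifnot(unstable_gene %in% genes$name)
    genes[[paste0("delta.", groups[length(groups)])]][
      genes$name == unstable_gene] <- delta
  }
  cq_sim_spec(
    genes = genes,
    groups = data.frame(label = groups,
                        n_samples = rep(n_samples, length(groups))),
    sample_effect_sd = 0.3, replicate_sd = 0.15, n_replicates = 2L,
    seed = seed
  )
}
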