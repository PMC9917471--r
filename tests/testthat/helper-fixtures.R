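# Shared fixture builders; everything is generated in code, no binary data.

# Expression matrix from a by-row numeric vector.
make_em <- function(values, ngenes, scale = "CQ", groups = NULL,
                    genes = NULL) {
  m <- matrix(values, nrow = ngenes, byrow = TRUE)
  rownames(m) <- genes %||% paste0("g", seq_len(ngenes))
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  if (is.null(groups)) {
    groups <- stats::setNames(rep("a", ncol(m)), colnames(m))
  }
  rgstab::expression_matrix(m, scale = scale, groups = groups)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random CQ-scale matrix in a plausible cycle window.
random_cq_em <- function(ngenes, nsamples, groups = NULL) {
  m <- matrix(stats::runif(ngenes * nsamples, 25, 38), ngenes,
              dimnames = list(paste0("g", seq_len(ngenes)),
                              paste0("s", seq_len(nsamples))))
  if (is.null(groups)) {
    groups <- stats::setNames(rep("a", nsamples), colnames(m))
  }
  rgstab::expression_matrix(m, scale = "CQ", groups = groups)
}

# Minimal long-format Cq data.frame: 2 genes x 2 samples x 2 replicates.
tiny_cq_df <- function(efficiency = TRUE) {
  df <- expand.grid(sample_id = c("S1", "S2"), gene = c("gA", "gB"),
                    replicate = 1:2, stringsAsFactors = FALSE)
  df$group <- ifelse(df$sample_id == "S1", "green", "red")
  df$cq <- c(30.0, 31.0, 28.0, 29.0, 30.2, 31.2, 28.2, 29.2)
  if (efficiency) df$efficiency <- ifelse(df$gene == "gA", 1.9, 2.0)
  df
}

# Independent brute-force oracle for the comparative delta-Ct method:
# double loop over gene pairs, stats::sd over per-sample differences.
oracle_delta_ct <- function(m) {
  genes <- rownames(m)
  k <- length(genes)
  stab <- numeric(k)
  for (i in seq_len(k)) {
    sds <- c()
    for (j in seq_len(k)) {
      if (i == j) next
      sds <- c(sds, stats::sd(m[i, ] - m[j, ]))
    }
    stab[i] <- mean(sds)
  }
  stats::setNames(stab, genes)
}

# Closed-form 3-gene geNorm M values: M_j = (V_ja + V_jb) / 2 directly.
oracle_genorm_k3 <- function(q) {
  lq <- log2(q)
  v <- function(i, j) stats::sd(lq[i, ] - lq[j, ])
  c(m1 = (v(1, 2) + v(1, 3)) / 2,
    m2 = (v(1, 2) + v(2, 3)) / 2,
    m3 = (v(1, 3) + v(2, 3)) / 2)
}
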