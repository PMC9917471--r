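test_that("genorm matches the hand-computed 3-gene example", {
  em <- make_em(c(30, 31, 30, 31, 28, 29, 28, 29, 25, 25, 26, 26), 3)
  g <- genorm(to_relative_quantity(em), compute_v = FALSE)
  # V12 = 0, V13 = V23 = sd({5,6,4,5}) = sqrt(2/3); first-pass M1 = M2,
  # g3 excluded at M3, final pair shares M = 0
  expect_equal(unname(g$stability["g3"]), sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(unname(g$stability[c("g1", "g2")]), c(0, 0))
  expect_equal(g$exclusion_order[1], "g3")
  expect_equal(sort(g$ranking[1:2]), c("g1", "g2"))
})

test_that("genorm final pair always shares the minimal M", {
  set.seed(21)
  for (i in 1:25) {
    k <- sample(3:8, 1)
    em <- to_relative_quantity(random_cq_em(k, sample(4:10, 1)))
    g <- genorm(em, compute_v = FALSE)
    m_sorted <- sort(g$stability)
    expect_equal(unname(m_sorted[1]), unname(m_sorted[2]))
    expect_equal(sort(unname(g$stability[g$ranking[1:2]])),
                 unname(m_sorted[1:2]))
  }
})

test_that("genorm k=3 equals the closed form without iteration", {
  set.seed(33)
  for (i in 1:25) {
    em <- to_relative_quantity(random_cq_em(3, sample(4:12, 1)))
    g <- genorm(em, compute_v = FALSE)
    closed <- oracle_genorm_k3(em$values)
    # the excluded gene's M equals its closed-form first-pass M
    excl <- g$exclusion_order[1]
    idx <- match(excl, rownames(em$values))
    expect_equal(unname(g$stability[excl]), unname(closed[idx]),
                 tolerance = 1e-12)
    # and it is the worst by the closed form
    expect_equal(unname(which.max(closed)), idx)
  }
})

test_that("genorm handles constant matrices and precondition errors", {
  em <- make_em(rep(c(30, 28, 26), each = 4), 3)
  g <- genorm(to_relative_quantity(em), compute_v = FALSE)
  expect_equal(unname(g$stability), rep(0, 3))
  # documented tie-break: lexicographically last removed first
  expect_equal(g$exclusion_order[1], "g3")
  expect_error(genorm(to_relative_quantity(make_em(c(30, 31, 29, 28), 2))),
               class = "rgstab_precondition_error")
})

test_that("genorm pairwise V values are SDs of log-ratio of normalisation
           factors", {
  set.seed(14)
  em <- to_relative_quantity(random_cq_em(5, 8))
  g <- genorm(em)
  expect_named(g$pairwise_v, c("V2/3", "V3/4", "V4/5"))
  # oracle for V2/3 from the reported stability order
  lq <- log2(em$values)
  top2 <- colMeans(lq[g$ranking[1:2], ])
  top3 <- colMeans(lq[g$ranking[1:3], ])
  expect_equal(unname(g$pairwise_v["V2/3"]), stats::sd(top2 - top3),
               tolerance = 1e-12)
})

test_that("normfinder degenerate and invariance behaviour", {
  groups <- stats::setNames(rep(c("a", "b"), each = 3), paste0("s", 1:6))
  # identical values -> all stabilities 0
  em <- make_em(rep(30, 18), 3, groups = groups)
  nf <- normfinder(em)
  expect_equal(unname(nf$stability), rep(0, 3))
  # adding a per-gene constant changes nothing
  set.seed(7)
  em2 <- random_cq_em(4, 8, groups = stats::setNames(
    rep(c("a", "b"), each = 4), paste0("s", 1:8)))
  shifted <- em2
  shifted$values[2, ] <- shifted$values[2, ] + 3
  expect_equal(normfinder(em2)$stability, normfinder(shifted)$stability,
               tolerance = 1e-12)
  # preconditions
  expect_error(normfinder(make_em(runif(8, 25, 30), 2,
                                  groups = stats::setNames(rep(c("a", "b"),
                                                               each = 2),
                                                           paste0("s", 1:4)))),
               class = "rgstab_precondition_error")
  g1 <- stats::setNames(c("a", "b", "b", "b"), paste0("s", 1:4))
  expect_error(normfinder(random_cq_em(3, 4, groups = g1)),
               class = "rgstab_precondition_error")
})

test_that("normfinder flags a planted group-unstable gene", {
  hits <- 0L
  for (s in 1:100) {
    spec <- paperlike_cq_spec(seed = 5000 + s, unstable_gene = "VHA-H",
                              delta = 2, n_samples = 10L)
    spec$genes$noise_sd <- 0.2
    tab <- simulate_cq(spec)
    cqe <- efficiency_correct(average_technical_replicates(tab),
                              rgstab:::cq_efficiencies(tab))
    nf <- normfinder(cqe)
    if (names(which.max(nf$stability)) == "VHA-H") hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("normfinder intragroup variance estimator is near-unbiased", {
  # single group, planted per-gene variances, n = 1000; bias is assessed
  # on the average estimate over replicate simulations (a single draw
  # carries ~ sigma^2 * sqrt(2/n) sampling error)
  set.seed(99)
  sds <- c(0.2, 0.35, 0.5, 0.8, 1.2, 0.6)
  n <- 1000
  est <- replicate(20, {
    m <- t(sapply(seq_along(sds), function(g) 30 + rnorm(n, 0, sds[g])))
    dimnames(m) <- list(paste0("g", seq_along(sds)), paste0("s", 1:n))
    em <- expression_matrix(m, "CQ",
                            stats::setNames(rep("a", n), colnames(m)))
    normfinder(em)$intra_var[, 1]
  })
  rel_bias <- abs(rowMeans(est) - sds^2) / sds^2
  expect_true(all(rel_bias < 0.10))
  # and with one group, stability = sqrt(intragroup variance)
  m <- t(sapply(seq_along(sds), function(g) 30 + rnorm(n, 0, sds[g])))
  dimnames(m) <- list(paste0("g", seq_along(sds)), paste0("s", 1:n))
  nf <- normfinder(expression_matrix(
    m, "CQ", stats::setNames(rep("a", n), colnames(m))))
  expect_equal(unname(nf$stability), unname(sqrt(nf$intra_var[, 1])))
})

test_that("bestkeeper descriptive statistics match hand computation", {
  bk <- bestkeeper(make_em(c(30, 32, 34, 32), 1, genes = "g"))
  expect_equal(bk$summary$sd_cq, stats::sd(c(30, 32, 34, 32)))
  expect_equal(bk$summary$sd_cq, 1.632993, tolerance = 1e-6)
  expect_equal(bk$summary$cv_pct, 100 * bk$summary$sd_cq / 32)
  expect_equal(bk$summary$r_index, 1)  # self-correlation with the index

  # constant gene
  bk0 <- bestkeeper(make_em(c(rep(30, 3), 28, 29, 30), 2))
  expect_equal(bk0$summary$sd_cq[1], 0)
  expect_equal(bk0$summary$cv_pct[1], 0)
  expect_true(is.na(bk0$summary$r_index[1]))
  expect_equal(bk0$ranking[1], "g1")

  # AM-GM and range invariants on random data
  set.seed(61)
  bk2 <- bestkeeper(random_cq_em(5, 9))
  with(bk2$summary, {
    expect_true(all(geo_mean <= arith_mean))
    expect_true(all(geo_mean >= min & arith_mean <= max))
  })
  expect_error(bestkeeper(make_em(30, 1)),
               class = "rgstab_precondition_error")
})

test_that("bestkeeper index and mad option", {
  set.seed(62)
  em <- random_cq_em(4, 7)
  bk <- bestkeeper(em)
  expect_equal(bk$index, exp(colMeans(log(em$values))))
  bkm <- bestkeeper(em, use_mad = TRUE)
  expect_equal(unname(bkm$stability),
               unname(apply(em$values, 1,
                            function(x) mean(abs(x - mean(x))))))
})

test_that("delta_ct matches the hand example and the brute-force oracle", {
  em <- make_em(c(30, 30, 30, 30, 32, 33, 32, 33, 35, 35, 36, 36), 3,
                genes = c("A", "B", "C"))
  d <- delta_ct(em)
  expect_equal(unname(d$stability),
               c(0.5773503, 0.6969234, 0.6969234), tolerance = 1e-6)
  expect_equal(d$pair_sd["A", "B"], d$pair_sd["B", "A"])
  expect_equal(unname(diag(d$pair_sd)), rep(0, 3))

  # oracle equivalence on all sizes up to 8 genes x 12 samples
  set.seed(77)
  for (k in 2:8) {
    for (n in c(2, 5, 12)) {
      em <- random_cq_em(k, n)
      d <- delta_ct(em)
      expect_equal(d$stability, oracle_delta_ct(em$values),
                   tolerance = 1e-12)
      expect_equal(unname(d$stability),
                   unname(rowSums(d$pair_sd) / (k - 1)))
    }
  }
  expect_error(delta_ct(make_em(c(30, 31), 1)),
               class = "rgstab_precondition_error")
})

test_that("all four estimators are invariant to per-gene Cq shifts", {
  set.seed(88)
  groups <- stats::setNames(rep(c("a", "b"), each = 4), paste0("s", 1:8))
  em <- random_cq_em(5, 8, groups = groups)
  shifted <- em
  shifts <- c(1.5, -2, 0.7, 3, -0.4)
  shifted$values <- em$values + shifts

  expect_equal(genorm(to_relative_quantity(em))$stability,
               genorm(to_relative_quantity(shifted))$stability,
               tolerance = 1e-10)
  expect_equal(normfinder(em)$stability, normfinder(shifted)$stability,
               tolerance = 1e-10)
  expect_equal(bestkeeper(em)$stability, bestkeeper(shifted)$stability,
               tolerance = 1e-10)
  expect_equal(delta_ct(em)$stability, delta_ct(shifted)$stability,
               tolerance = 1e-10)
})

test_that("stability_suite applies the per-method scale policy", {
  spec <- paperlike_cq_spec(seed = 404)
  tab <- simulate_cq(spec)
  res <- stability_suite(tab)
  expect_named(res, c("geNorm", "NormFinder", "BestKeeper", "DeltaCt"))
  expect_s3_class(res$geNorm, "genorm_result")
  # BestKeeper/DeltaCt run on raw mean Cq: equal to calling them directly
  cq <- average_technical_replicates(tab)
  expect_equal(res$BestKeeper$stability, bestkeeper(cq)$stability)
  expect_equal(res$DeltaCt$stability, delta_ct(cq)$stability)
  # efficiencies are required unless perfect efficiency is explicit
  tab2 <- tab
  tab2$efficiency <- NULL
  tab2 <- cq_table(as.data.frame(tab2))
  expect_error(stability_suite(tab2), class = "rgstab_domain_error")
  res2 <- stability_suite(tab2, perfect_efficiency = TRUE,
                          methods = c("geNorm", "NormFinder"))
  expect_named(res2, c("geNorm", "NormFinder"))
})

test_that("stability results export gene/stability_value/rank CSVs", {
  set.seed(12)
  em <- random_cq_em(4, 6)
  bk <- bestkeeper(em)
  path <- withr::local_tempfile(fileext = ".csv")
  write_stability_result(bk, path)
  back <- read.csv(path)
  expect_equal(back$gene, bk$ranking)
  expect_equal(back$rank, 1:4)
  expect_true(all(c("sd_cq", "cv_pct", "r_index") %in% names(back)))
  expect_equal(back$stability_value, unname(sort(bk$stability)))
})
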