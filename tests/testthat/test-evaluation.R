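test_that("decile assignment balances sizes and breaks ties lexicographically", {
  scores <- tibble::tibble(gene = sprintf("g%02d", 1:20),
                           forecASD = seq(1, 0.05, length.out = 20))
  d <- assign_deciles(scores)
  expect_equal(as.integer(table(d$decile)), rep(2L, 10))
  expect_equal(d$decile[d$gene == "g01"], 1L)

  # two genes tied at the decile boundary: smaller id gets the better decile
  tied <- tibble::tibble(gene = c("b1", "a9", sprintf("c%d", 1:8)),
                         forecASD = c(1, 1, seq(0.8, 0.1, length.out = 8)))
  dt <- assign_deciles(tied)  # n = 10, one gene per decile; tie at ranks 1-2
  expect_equal(dt$decile[dt$gene == "a9"], 1L)
  expect_equal(dt$decile[dt$gene == "b1"], 2L)

  rev_scores <- dplyr::mutate(scores, forecASD = -forecASD)
  dr <- assign_deciles(rev_scores)
  expect_equal(dr$decile, rev(d$decile))
  expect_error(assign_deciles(scores[1:5, ]), "at least 10")
})

test_that("binomial tail handles boundary cases and is monotone in k", {
  expect_equal(binomial_tail(0, 10, 0.3), 1)
  expect_equal(binomial_tail(3, 5, 0.5), 0.5)
  p <- vapply(0:20, binomial_tail, 1, n = 20, p0 = 0.3)
  expect_true(all(diff(p) < 0))
  expect_error(binomial_tail(5, 4, 0.3), "k <= n")
  expect_error(binomial_tail(1, 4, 1), "p0")
})

test_that("decile enrichment counts distinct individuals and uses the synonymous baseline", {
  n_genes <- 100
  genes <- sprintf("g%03d", 1:n_genes)
  scores <- tibble::tibble(gene = genes,
                           forecASD = seq(1, 0.01, length.out = n_genes))
  # targets: g001 (LOF in 2 people), g002 (LOF twice in the SAME person ->
  # singleton), g003 (1 LOF); baseline: synonymous in 10 genes, 2 in decile 1
  dnm <- tibble::tibble(
    gene = c("g001", "g001", "g002", "g002", "g003",
             sprintf("g%03d", c(5, 8, 21, 31, 41, 51, 61, 71, 81, 91))),
    individual_id = c("pA", "pB", "pC", "pC", "pD", sprintf("pS%d", 1:10)),
    cohort = "X",
    consequence = c(rep("LOF", 5), rep("synonymous", 10))
  )
  res <- decile_enrichment_test(scores, dnm, "recurrent_LOF")
  expect_equal(res$n, 1)  # only g001 is recurrent
  expect_equal(res$k, 1)
  expect_equal(res$p0, 0.2)
  expect_equal(res$p_value, 0.2)  # closed form: p0^n with all targets on top
  expect_equal(sum(res$per_decile$n_target), res$n)

  res_s <- decile_enrichment_test(scores, dnm, "singleton_LOF")
  expect_setequal(c("g002", "g003"),
                  scores$gene[scores$gene %in% c("g002", "g003")])
  expect_equal(res_s$n, 2)

  # unscored mutated genes are excluded with a message
  dnm2 <- dplyr::bind_rows(dnm, tibble::tibble(
    gene = "zzz", individual_id = c("p1", "p2"), cohort = "X",
    consequence = "LOF"))
  expect_message(res2 <- decile_enrichment_test(scores, dnm2, "recurrent_LOF"),
                 "excluded 1")
  expect_equal(res2$n, res$n)

  expect_error(
    decile_enrichment_test(scores, dnm[dnm$consequence == "LOF", ],
                           "recurrent_LOF"),
    "baseline"
  )
})

test_that("covariate-adjusted logistic benchmark has power and calibrated size", {
  n <- 3000
  n_sims <- 60
  hits <- 0
  for (s in 1:n_sims) {
    set.seed(1000 + s)
    covs <- matrix(rnorm(n * 5), n, 5)
    score <- rnorm(n)
    eta <- -2.5 + score + covs %*% rep(0.4, 5)
    y <- runif(n) < plogis(eta)
    genes <- sprintf("g%05d", 1:n)
    res <- covariate_adjusted_association(
      tibble::tibble(gene = genes, forecASD = score),
      tibble::tibble(gene = genes, c1 = covs[, 1], c2 = covs[, 2],
                     c3 = covs[, 3], c4 = covs[, 4], c5 = covs[, 5]),
      positive_set = genes[y]
    )
    hits <- hits + (res$z > 0 && res$p_value < 0.05)
  }
  expect_gte(hits / n_sims, 0.9)

  # type-I error under conditional independence
  rejections <- 0
  n_null <- 200
  for (s in 1:n_null) {
    set.seed(5000 + s)
    covs <- matrix(rnorm(n * 2), n, 2)
    score <- covs[, 1] + rnorm(n)      # correlated with covariates, not labels
    y <- runif(n) < plogis(-2 + covs %*% c(0.5, 0.5))
    genes <- sprintf("g%05d", 1:n)
    res <- covariate_adjusted_association(
      tibble::tibble(gene = genes, forecASD = score),
      tibble::tibble(gene = genes, c1 = covs[, 1], c2 = covs[, 2]),
      positive_set = genes[y]
    )
    rejections <- rejections + (abs(res$z) > 1.96)
  }
  expect_gt(rejections / n_null, 0.015)
  expect_lt(rejections / n_null, 0.095)
})

test_that("logistic benchmark flags collinearity, separation, and exclusions", {
  set.seed(3)
  n <- 200
  genes <- sprintf("g%03d", 1:n)
  score <- rnorm(n)
  scores <- tibble::tibble(gene = genes, forecASD = score)
  expect_error(
    covariate_adjusted_association(
      scores, tibble::tibble(gene = genes, dup = score), genes[1:50]),
    "collinear"
  )
  expect_error(
    covariate_adjusted_association(
      scores, tibble::tibble(gene = genes, c1 = rnorm(n)),
      positive_set = genes[score > 1]),  # membership determined by score
    "separation"
  )
  # excluded genes are removed before fitting
  res_all <- covariate_adjusted_association(
    scores, tibble::tibble(gene = genes, c1 = rnorm(n)), genes[1:50])
  res_ex <- covariate_adjusted_association(
    scores, tibble::tibble(gene = genes, c1 = rnorm(n)), genes[1:50],
    excluded = genes[51:100])
  expect_equal(res_ex$n, n - 50)
  expect_false(identical(res_all$z, res_ex$z))
})

test_that("rank-sum test matches exact enumeration and handles total ties", {
  set.seed(8)
  for (rep in 1:10) {
    n <- sample(8:12, 1)
    k <- sample(2:4, 1)
    vals <- rnorm(n)
    genes <- sprintf("g%02d", 1:n)
    subset_idx <- sample(n, k)
    p_pkg <- ranksum_test(tibble::tibble(gene = genes, forecASD = vals),
                          genes[subset_idx])
    expect_equal(p_pkg, ranksum_enum(vals, subset_idx), tolerance = 1e-12)
  }
  # subset = top k: minimal attainable tail 1/choose(n, k)
  vals <- c(10, 9, 8, 1, 2, 3, 4, 5, 6, 7)
  genes <- sprintf("g%02d", 1:10)
  expect_equal(ranksum_test(tibble::tibble(gene = genes, forecASD = vals),
                            genes[1:3]),
               1 / choose(10, 3), tolerance = 1e-12)
  expect_equal(ranksum_test(tibble::tibble(gene = genes, forecASD = rep(1, 10)),
                            genes[1:3]), 1)
  expect_error(ranksum_test(tibble::tibble(gene = genes, forecASD = vals),
                            genes), "non-empty")
})

test_that("rank-sum p-values are uniform under a random subset", {
  set.seed(12)
  ps <- replicate(500, {
    vals <- rnorm(40)
    genes <- sprintf("g%02d", 1:40)
    ranksum_test(tibble::tibble(gene = genes, forecASD = vals),
                 sample(genes, 10))
  })
  # exact p-values are discrete, so ks.test warns about ties; that is expected
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("fisher overlap equals enumeration oracles and is swap-consistent", {
  A <- sprintf("g%03d", 1:10)
  B <- sprintf("g%03d", c(1:5, 40:54))
  bg <- sprintf("g%03d", 1:100)
  res <- fisher_overlap(A, B, bg)
  expect_equal(res$n11, 5)
  expect_equal(res$p_value, fisher_p_enum(res$n11, res$n10, res$n01, res$n00),
               tolerance = 1e-12)
  expect_equal(res$odds_ratio,
               fisher_cmle_enum(res$n11, res$n10, res$n01, res$n00),
               tolerance = 1e-4)
  swapped <- fisher_overlap(B, A, bg)
  expect_equal(res$p_value, swapped$p_value)
  expect_equal(res$odds_ratio, swapped$odds_ratio)  # 2x2 transpose keeps OR

  disjoint <- fisher_overlap(A, setdiff(bg, A)[1:10], bg)
  expect_equal(disjoint$sample_or, 0)
  degen <- fisher_overlap(A, bg, bg)  # A subset of B = background
  expect_equal(degen$p_value, 1)
  expect_error(fisher_overlap(A, B, sprintf("g%03d", 1:12)), "subsets")
  expect_error(fisher_overlap(A, B, 10), "background smaller")
})

test_that("eqtl bin enrichment counts records and reports cumulative ORs", {
  set.seed(21)
  n_genes <- 400
  genes <- sprintf("g%04d", 1:n_genes)
  scores <- tibble::tibble(gene = genes, forecASD = runif(n_genes))
  top <- assign_deciles(scores, n_bins = 20)
  top_genes <- top$gene[top$decile == 1]
  recs <- tibble::tibble(
    snp = sprintf("rs%05d", 1:4000),
    gene = sample(genes, 4000, replace = TRUE)
  )
  hit_p <- ifelse(recs$gene %in% top_genes, 0.5, 0.08)
  recs$gwas_p <- ifelse(runif(4000) < hit_p, runif(4000, 0, 0.0099),
                        runif(4000, 0.011, 1))
  res <- eqtl_gwas_enrichment(scores, recs)
  expect_equal(nrow(res$cumulative), 19)
  expect_gt(res$top_bin$odds_ratio, 3)
  expect_lt(res$top_bin$p_value, 1e-6)
  expect_equal(res$cumulative$cum_or[1], res$top_bin$sample_or)

  # unscored records dropped with a message
  recs2 <- dplyr::bind_rows(recs,
                            tibble::tibble(snp = "rsX", gene = "zzz", gwas_p = 0.5))
  expect_message(eqtl_gwas_enrichment(scores, recs2), "dropped 1")
  # degenerate: no hits
  recs3 <- dplyr::mutate(recs, gwas_p = pmax(gwas_p, 0.02))
  expect_error(eqtl_gwas_enrichment(scores, recs3), "degenerate")
})
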