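# Independent oracles: brute-force / enumeration routines kept deliberately
# separate from the package implementations they check.

# Floyd-Warshall all-pairs shortest paths on an unweighted undirected graph.
fw_distances <- function(nodes, edges) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (i in seq_len(nrow(edges))) {
    a <- edges$gene_a[i]; b <- edges$gene_b[i]
    d[a, b] <- 1; d[b, a] <- 1
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Upper-tail binomial by direct term-by-term summation.
binom_tail_brute <- function(k, n, p0) {
  if (k == 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p0^i * (1 - p0)^(n - i), 1))
}

# Upper-tail hypergeometric P(X >= q) by summation: q successes drawn,
# m reference genes, bg background size, size draws.
hyper_tail_brute <- function(q, m, bg, size) {
  hi <- min(m, size)
  if (q <= 0) return(1)
  sum(vapply(q:hi, function(x) {
    exp(lchoose(m, x) + lchoose(bg - m, size - x) - lchoose(bg, size))
  }, 1))
}

# Two-sided Fisher exact p by enumeration of the conditional 2x2 support,
# using R's convention: sum probabilities <= observed (with slack).
fisher_p_enum <- function(n11, n10, n01, n00) {
  m <- n11 + n01        # column-1 total
  k <- n11 + n10        # row-1 total
  nn <- n11 + n10 + n01 + n00
  support <- max(0, k + m - nn):min(k, m)
  probs <- vapply(support, function(x) dhyper(x, m, nn - m, k), 1)
  obs <- dhyper(n11, m, nn - m, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Conditional MLE odds ratio by direct maximization of Fisher's noncentral
# hypergeometric likelihood over log(psi).
fisher_cmle_enum <- function(n11, n10, n01, n00) {
  m <- n11 + n01; k <- n11 + n10; nn <- n11 + n10 + n01 + n00
  support <- max(0, k + m - nn):min(k, m)
  if (n11 == min(k, m)) return(Inf)
  if (n11 == max(0, k + m - nn)) return(0)
  logw <- lchoose(m, support) + lchoose(nn - m, k - support)
  nll <- function(theta) {
    lt <- logw + support * theta
    -(n11 * theta + lchoose(m, n11) + lchoose(nn - m, k - n11) -
        max(lt) - log(sum(exp(lt - max(lt)))))
  }
  exp(stats::optimize(nll, c(-25, 25), tol = 1e-10)$minimum)
}

# Exact one-sided rank-sum p by full enumeration of subsets of size k.
ranksum_enum <- function(values, subset_idx) {
  n <- length(values)
  k <- length(subset_idx)
  r <- rank(values)
  obs <- sum(r[subset_idx])
  combos <- utils::combn(n, k)
  mean(colSums(matrix(r[combos], nrow = k)) >= obs)
}

# tiny deterministic expression bundle: per-region samples at given ages
make_bundle <- function(values, regions, ages, donors = NULL) {
  n_s <- ncol(values)
  meta <- tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(n_s)),
    donor_id = donors %||% sprintf("d%02d", seq_len(n_s)),
    region = regions,
    age_pcw = ages
  )
  colnames(values) <- meta$sample_id
  expression_bundle(values, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

with_seed_local <- function(seed, code) withr::with_seed(seed, code)

make_net <- function(ga, gb, score, nodes = NULL) {
  interaction_network(tibble::tibble(gene_a = ga, gene_b = gb, score = score),
                      nodes = nodes)
}

# random small graph for shortest-path checks
random_net <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  if (!any(keep)) keep[1] <- TRUE
  make_net(pairs[keep, 1], pairs[keep, 2],
           stats::runif(sum(keep), 0.5, 1), nodes = nodes)
}

# labelled feature matrix with informative and noise columns
make_class_data <- function(n_per_class, p_inf, p_noise, effect, seed,
                            prefix = "g") {
  set.seed(seed)
  n <- 2 * n_per_class
  y <- rep(c(TRUE, FALSE), each = n_per_class)
  x <- cbind(
    matrix(rnorm(n * p_inf, mean = effect * y), n, p_inf),
    matrix(rnorm(n * p_noise), n, p_noise)
  )
  dimnames(x) <- list(sprintf("%s%04d", prefix, seq_len(n)),
                      c(sprintf("inf%02d", seq_len(p_inf)),
                        sprintf("noise%03d", seq_len(p_noise))))
  list(x = x, y = y,
       informative = colnames(x)[seq_len(p_inf)],
       noise = colnames(x)[p_inf + seq_len(p_noise)])
}

# area under ROC, rank-based (independent of the package internal)
roc_auc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label); n0 <- sum(!label)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# small end-to-end synthetic pipeline inputs at reduced size
small_pipeline_config <- function(seed, n_genes = 300, n_positive = 30,
                                  n_negative = 100, n_trees = 100,
                                  per_class = 20, ...) {
  cfg <- simulation_config(
    n_genes = n_genes, n_positive = n_positive, n_negative = n_negative,
    n_donors = 40, region_samples_range = c(22, 30),
    n_exclusion_extra = 20, seed = seed, ...
  )
  expr <- simulate_expression(cfg)
  net <- simulate_network(cfg, expr$truth)
  ev <- simulate_evaluation_data(cfg, expr$truth,
                                 community = attr(net, "community"))
  positives <- expr$truth$gene[expr$truth$is_positive]
  exclusion <- c(positives,
                 head(setdiff(expr$truth$gene, positives), 20))
  list(
    config = pipeline_config(expr$bundle, net, ev$priors, positives, exclusion,
                             n_negative = n_negative, n_trees = n_trees,
                             per_class = per_class, seed = seed),
    truth = expr$truth, ev = ev, net = net
  )
}
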