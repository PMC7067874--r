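#' Assign score deciles
#'
#' Genes are ranked by score descending with ties broken by lexicographic gene
#' identifier; decile 1 holds the top scores. Decile sizes differ by at most 1.
#'
#' @param scores Tibble with a `gene` column and the score column.
#' @param score_col Name of the score column (default `"forecASD"`).
#' @param n_bins Number of quantile bins (default 10 = deciles).
#' @return Tibble with columns `gene` and `decile` (1 = top).
#' @export
assign_deciles <- function(scores, score_col = "forecASD", n_bins = 10) {
  scores <- as_tibble(scores)
  if (!all(c("gene", score_col) %in% names(scores))) {
    abort(sprintf("scores must have columns 'gene' and '%s'", score_col))
  }
  n <- nrow(scores)
  if (n < n_bins) abort(sprintf("need at least %d scored genes", n_bins))
  ord <- order(-scores[[score_col]], scores$gene)
  decile <- integer(n)
  decile[ord] <- ceiling(seq_len(n) * n_bins / n)
  tibble(gene = scores$gene, decile = decile)
}

#' Upper-tail binomial test
#'
#' Exact one-sided tail probability `P(X >= k)` for `X ~ Binomial(n, p0)`,
#' evaluated by the regularized incomplete beta function (log-space internally),
#' so extreme tails such as the method's reported 1e-14 enrichment p-values are
#' computed without underflow.
#'
#' @param k Observed successes (0 <= k <= n).
#' @param n Number of trials.
#' @param p0 Null success probability in (0, 1).
#' @return The p-value `P(X >= k)`.
#' @examples
#' binomial_tail(32, 44, 0.196)
#' @export
binomial_tail <- function(k, n, p0) {
  if (!is.finite(k) || !is.finite(n) || k < 0 || k > n || n < 1 ||
      k != round(k) || n != round(n)) {
    abort("require integers 0 <= k <= n")
  }
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1) abort("p0 must lie in (0, 1)")
  if (k == 0) return(1)
  pbinom(k - 1, n, p0, lower.tail = FALSE)
}

# classify genes by de novo mutation recurrence, counting distinct individuals
dnm_gene_classes <- function(dnm) {
  dnm <- validate_dnm_table(dnm)
  counts <- dnm %>%
    distinct(.data$gene, .data$individual_id, .data$consequence) %>%
    count(.data$gene, .data$consequence)
  list(
    recurrent_LOF = counts$gene[counts$consequence == "LOF" & counts$n >= 2],
    singleton_LOF = counts$gene[counts$consequence == "LOF" & counts$n == 1],
    recurrent_missense = counts$gene[counts$consequence == "missense" & counts$n >= 2],
    synonymous = counts$gene[counts$consequence == "synonymous" & counts$n >= 1]
  )
}

#' Mutation-rate-corrected decile enrichment test
#'
#' Tests whether genes hit by a de novo mutation class are over-represented in
#' the top score decile, using genes with at least one synonymous de novo
#' mutation as the baseline: the expected top-decile proportion `p0` is the
#' fraction of synonymous-hit genes falling in decile 1. This corrects for
#' scores that favor long, highly mutable genes. Classes count distinct
#' individuals: `recurrent_LOF` = loss-of-function mutations in >= 2 probands,
#' `singleton_LOF` = exactly 1, `recurrent_missense` analogous. Genes with
#' mutations but no score are excluded from numerator and denominator.
#'
#' @param scores Score table (tibble with `gene` and `score_col`).
#' @param dnm De novo mutation table (see [read_dnm_table()]).
#' @param target_class One of `"recurrent_LOF"`, `"singleton_LOF"`,
#'   `"recurrent_missense"`.
#' @param score_col Score column name (default `"forecASD"`).
#' @return An object of class `decile_enrichment`: per-decile target fractions,
#'   `k` (target genes in decile 1), `n` (scored target genes), `p0`, and the
#'   one-sided binomial `p_value`.
#' @export
decile_enrichment_test <- function(scores, dnm,
                                   target_class = c("recurrent_LOF",
                                                    "singleton_LOF",
                                                    "recurrent_missense"),
                                   score_col = "forecASD") {
  target_class <- match.arg(target_class)
  classes <- dnm_gene_classes(dnm)
  deciles <- assign_deciles(scores, score_col = score_col)
  target <- classes[[target_class]]
  baseline <- classes$synonymous
  n_unscored <- sum(!unique(c(target, baseline)) %in% deciles$gene)
  if (n_unscored > 0) {
    inform(sprintf("excluded %d mutated gene(s) absent from the score table",
                   n_unscored))
  }
  target <- intersect(target, deciles$gene)
  baseline <- intersect(baseline, deciles$gene)
  if (length(target) == 0 || length(baseline) == 0) {
    abort("empty target or baseline gene set after restriction to scored genes")
  }
  base_dec <- deciles$decile[match(baseline, deciles$gene)]
  p0 <- mean(base_dec == 1)
  if (p0 <= 0 || p0 >= 1) {
    abort("degenerate baseline: synonymous top-decile proportion is 0 or 1")
  }
  tgt_dec <- deciles$decile[match(target, deciles$gene)]
  per_decile <- tabulate(tgt_dec, nbins = 10)
  k <- per_decile[1]
  n <- length(target)
  structure(
    list(
      per_decile = tibble(decile = 1:10, n_target = per_decile,
                          fraction = per_decile / n),
      k = k, n = n, p0 = p0,
      p_value = binomial_tail(k, n, p0),
      target_class = target_class,
      n_baseline = length(baseline)
    ),
    class = "decile_enrichment"
  )
}

#' @export
print.decile_enrichment <- function(x, ...) {
  cat(sprintf("<decile_enrichment> %s: %d/%d genes in top decile (expected %.3f), P = %.3g\n",
              x$target_class, x$k, x$n, x$p0, x$p_value))
  invisible(x)
}

#' @rdname decile_enrichment_test
#' @param x,object A `decile_enrichment` result.
#' @param ... Unused.
#' @export
tidy.decile_enrichment <- function(x, ...) x$per_decile

#' @rdname decile_enrichment_test
#' @export
glance.decile_enrichment <- function(x, ...) {
  tibble(target_class = x$target_class, k = x$k, n = x$n, p0 = x$p0,
         n_baseline = x$n_baseline, p_value = x$p_value)
}

#' @rdname decile_enrichment_test
#' @export
autoplot.decile_enrichment <- function(object, ...) {
  ggplot2::ggplot(object$per_decile,
                  ggplot2::aes(x = factor(.data$decile), y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$p0, linetype = 2) +
    ggplot2::labs(x = "score decile (1 = top)",
                  y = sprintf("fraction of %s genes", object$target_class)) +
    ggplot2::theme_minimal()
}

#' Covariate-adjusted logistic association benchmark
#'
#' Fits a maximum-likelihood logistic regression of membership in a positive
#' gene set on a score plus covariate columns (typically the five
#' genetic-association columns), after removing an excluded gene set. Reports
#' the score coefficient, its Wald Z, and the two-sided p-value, quantifying
#' the score's signal beyond the covariates.
#'
#' @param scores Tibble with `gene` and `score_col`.
#' @param covariates Tibble with `gene` plus numeric covariate columns.
#' @param positive_set Character vector of positive genes.
#' @param excluded Genes removed before fitting (e.g. higher-confidence
#'   database entries).
#' @param score_col Score column name (default `"forecASD"`).
#' @return One-row tibble: `term`, `estimate`, `z`, `p_value`, `n`, `n_positive`.
#' @export
covariate_adjusted_association <- function(scores, covariates, positive_set,
                                           excluded = character(0),
                                           score_col = "forecASD") {
  scores <- as_tibble(scores)
  df <- left_join(scores[c("gene", score_col)], as_tibble(covariates), by = "gene")
  df <- filter(df, !.data$gene %in% excluded)
  df <- df[complete.cases(df), , drop = FALSE]
  y <- df$gene %in% positive_set
  if (sum(y) == 0 || sum(!y) == 0) {
    abort("positive set and its complement must both be non-empty after exclusions")
  }
  xcols <- setdiff(names(df), "gene")
  X <- as.matrix(df[xcols])
  if (qr(cbind(1, X))$rank < ncol(X) + 1) {
    abort("design matrix is rank-deficient: score is collinear with a covariate")
  }
  fit <- withCallingHandlers(
    glm(y ~ X, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        abort("perfect separation detected in logistic fit")
      }
      invokeRestart("muffleWarning")
    }
  )
  sm <- summary(fit)$coefficients
  row <- paste0("X", score_col)
  tibble(
    term = score_col,
    estimate = sm[row, "Estimate"],
    z = sm[row, "z value"],
    p_value = sm[row, "Pr(>|z|)"],
    n = length(y),
    n_positive = sum(y)
  )
}

#' One-sided rank-sum enrichment test
#'
#' Tests whether a gene subset has higher scores than all other scored genes
#' (Wilcoxon rank-sum, alternative "subset greater"). With no ties and small
#' samples the exact permutation distribution is used; otherwise the normal
#' approximation with tie and continuity corrections. If every score is
#' identical the p-value is 1.
#'
#' @param scores Tibble with `gene` and `score_col`.
#' @param subset Character vector of genes forming the test set.
#' @param score_col Score column name (default `"forecASD"`).
#' @return The one-sided p-value.
#' @export
ranksum_test <- function(scores, subset, score_col = "forecASD") {
  scores <- as_tibble(scores)
  inset <- scores$gene %in% subset
  if (sum(inset) == 0 || sum(!inset) == 0) {
    abort("subset and its complement must both be non-empty among scored genes")
  }
  x <- scores[[score_col]][inset]
  y <- scores[[score_col]][!inset]
  if (length(unique(c(x, y))) == 1) return(1)
  suppressWarnings(
    wilcox.test(x, y, alternative = "greater", correct = TRUE)$p.value
  )
}

#' Fisher's exact test of gene-set overlap
#'
#' Builds the 2x2 table (in/out of A x in/out of B) against a background
#' universe and reports the exact two-sided p-value, the conditional
#' maximum-likelihood odds ratio (the exact-test convention), and the sample
#' cross-product odds ratio.
#'
#' @param setA,setB Character gene sets (subsets of the background).
#' @param background Character vector of background genes, or an integer
#'   background size (must be >= the union of A and B).
#' @return One-row tibble: `odds_ratio` (conditional MLE), `sample_or`
#'   (cross-product), `p_value`, and the four table cells `n11`, `n10`, `n01`,
#'   `n00`.
#' @export
fisher_overlap <- function(setA, setB, background) {
  setA <- unique(setA)
  setB <- unique(setB)
  if (is.numeric(background) && length(background) == 1) {
    n_bg <- as.integer(background)
    n11 <- length(intersect(setA, setB))
    n10 <- length(setdiff(setA, setB))
    n01 <- length(setdiff(setB, setA))
  } else {
    background <- unique(background)
    if (!all(setA %in% background) || !all(setB %in% background)) {
      abort("setA and setB must be subsets of the background")
    }
    n_bg <- length(background)
    n11 <- length(intersect(setA, setB))
    n10 <- length(setdiff(setA, setB))
    n01 <- length(setdiff(setB, setA))
  }
  n00 <- n_bg - n11 - n10 - n01
  if (n00 < 0) abort("background smaller than the union of the two sets")
  fisher_table(n11, n10, n01, n00)
}

# shared 2x2 exact-test machinery
fisher_table <- function(n11, n10, n01, n00) {
  tab <- matrix(c(n11, n01, n10, n00), nrow = 2)
  ft <- fisher.test(tab)
  sample_or <- if (n10 == 0 || n01 == 0) {
    if (n11 == 0 || n00 == 0) NaN else Inf
  } else {
    (n11 * n00) / (n10 * n01)
  }
  tibble(
    odds_ratio = unname(ft$estimate),
    sample_or = sample_or,
    p_value = ft$p.value,
    n11 = n11, n10 = n10, n01 = n01, n00 = n00
  )
}

#' eQTL/GWAS quantile-bin enrichment
#'
#' Genes are split into score quantile bins (default 5% bins, bin 1 = top,
#' lexicographic tie-break as in [assign_deciles()]); each eQTL record is a
#' "hit" when its GWAS p-value is below `gwas_cut`. The unit of counting is the
#' eQTL record. The top bin is compared with all lower bins by Fisher's exact
#' test, and a cumulative odds ratio (each bin and all better bins versus all
#' lower bins) is reported per bin. Records whose gene is absent from the score
#' table are dropped with a message.
#'
#' @param scores Score table (tibble with `gene` and `score_col`).
#' @param eqtl eQTL table: tibble with `snp`, `gene`, `gwas_p`.
#' @param bin_width Quantile bin width (default 0.05 = 5% bins).
#' @param gwas_cut GWAS p-value dichotomization threshold (default 0.01).
#' @param score_col Score column name (default `"forecASD"`).
#' @return An object of class `eqtl_enrichment`: `top_bin` (one-row Fisher
#'   result for top bin vs rest) and `cumulative` (tibble of per-bin cumulative
#'   odds ratios, bins 1..n_bins-1).
#' @export
eqtl_gwas_enrichment <- function(scores, eqtl, bin_width = 0.05,
                                 gwas_cut = 0.01, score_col = "forecASD") {
  stopifnot(bin_width > 0, bin_width <= 0.5, gwas_cut > 0, gwas_cut < 1)
  n_bins <- as.integer(round(1 / bin_width))
  eqtl <- as_tibble(eqtl)
  scores <- as_tibble(scores)
  keep <- eqtl$gene %in% scores$gene
  if (any(!keep)) {
    inform(sprintf("dropped %d eQTL record(s) with unscored genes", sum(!keep)))
  }
  eqtl <- eqtl[keep, , drop = FALSE]
  if (nrow(eqtl) == 0) abort("no eQTL records left after joining to scored genes")
  bins <- assign_deciles(scores, score_col = score_col, n_bins = n_bins)
  eqtl$bin <- bins$decile[match(eqtl$gene, bins$gene)]
  eqtl$hit <- eqtl$gwas_p < gwas_cut
  if (all(eqtl$hit) || !any(eqtl$hit)) {
    abort("degenerate table: all or no eQTL records are GWAS hits")
  }
  cell <- function(top) {
    c(hit = sum(eqtl$hit[top]), miss = sum(!eqtl$hit[top]))
  }
  top <- eqtl$bin == 1
  a <- cell(top); b <- cell(!top)
  top_bin <- fisher_table(a[["hit"]], a[["miss"]], b[["hit"]], b[["miss"]])
  cumulative <- purrr::map_dfr(seq_len(n_bins - 1), function(bn) {
    hi <- eqtl$bin <= bn
    aa <- cell(hi); bb <- cell(!hi)
    or <- (aa[["hit"]] * bb[["miss"]]) / (aa[["miss"]] * bb[["hit"]])
    tibble(bin = bn, n_records = sum(hi), cum_or = or)
  })
  structure(
    list(top_bin = top_bin, cumulative = cumulative,
         n_records = nrow(eqtl), n_bins = n_bins, gwas_cut = gwas_cut),
    class = "eqtl_enrichment"
  )
}

#' @export
print.eqtl_enrichment <- function(x, ...) {
  cat(sprintf("<eqtl_enrichment> %d records in %d bins; top bin OR = %.2f, P = %.3g\n",
              x$n_records, x$n_bins, x$top_bin$odds_ratio, x$top_bin$p_value))
  invisible(x)
}

#' @rdname eqtl_gwas_enrichment
#' @param x,object An `eqtl_enrichment` result.
#' @param ... Unused.
#' @export
tidy.eqtl_enrichment <- function(x, ...) x$cumulative

#' @rdname eqtl_gwas_enrichment
#' @export
glance.eqtl_enrichment <- function(x, ...) {
  tibble(n_records = x$n_records, n_bins = x$n_bins,
         top_or = x$top_bin$odds_ratio, top_sample_or = x$top_bin$sample_or,
         p_value = x$top_bin$p_value)
}

#' @rdname eqtl_gwas_enrichment
#' @export
autoplot.eqtl_enrichment <- function(object, ...) {
  ggplot2::ggplot(object$cumulative,
                  ggplot2::aes(x = .data$bin, y = .data$cum_or)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "score bin (1 = top), cumulative",
                  y = "odds ratio vs lower bins") +
    ggplot2::theme_minimal()
}
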