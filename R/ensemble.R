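# Fixed level-2 feature order: the two level-1 scores followed by the prior
# gene-level predictors (one Bayes-factor column and four FDR columns of the
# transmission/de-novo association statistic, plus three published scores).
meta_feature_columns <- c(
  "BrainSpan_score", "STRING_score",
  "DAWN", "Krishnan", "DAMAGES",
  "TADA_BF", "tadaFdrAscSscExomeSscAgpSmallDel", "tadaFdrAscSscExome",
  "tadaFdrAscExome", "tadaFdrSscExome"
)

#' Construct the training label set
#'
#' Positives are the supplied high-confidence genes; negatives are a uniform
#' sample (without replacement) of `n_negative` genes from the universe after
#' removing both the positives and the full exclusion list (so no gene from the
#' excluded database, at any confidence level, can be a negative). The default
#' geometry is 76 positives + 1000 negatives = 1076 training labels.
#'
#' @param positives Character vector of positive-class genes (must be in
#'   `universe`).
#' @param exclusion Character vector of genes barred from the negative class.
#' @param universe Character vector of candidate genes.
#' @param n_negative Number of negatives to sample (default 1000).
#' @param seed Integer seed for the negative sample.
#' @return An object of class `label_set` with elements `positives`,
#'   `negatives`, `seed`.
#' @export
make_training_labels <- function(positives, exclusion, universe,
                                 n_negative = 1000, seed = 1) {
  positives <- assert_character_set(positives, "positives")
  exclusion <- assert_character_set(exclusion, "exclusion")
  universe <- assert_character_set(universe, "universe")
  if (!all(positives %in% universe)) {
    abort("all positives must be contained in the universe")
  }
  candidates <- sort(setdiff(universe, union(positives, exclusion)))
  if (length(candidates) < n_negative) {
    abort(sprintf("only %d candidate negatives available, %d requested",
                  length(candidates), n_negative))
  }
  negatives <- with_seed(seed, sample(candidates, n_negative))
  structure(
    list(positives = sort(positives), negatives = sort(negatives), seed = seed),
    class = "label_set"
  )
}

#' @export
print.label_set <- function(x, ...) {
  cat(sprintf("<label_set> %d positives + %d negatives = %d training genes\n",
              length(x$positives), length(x$negatives),
              length(x$positives) + length(x$negatives)))
  invisible(x)
}

label_genes <- function(labels) c(labels$positives, labels$negatives)

#' Assemble the level-2 meta-feature table
#'
#' The scored-gene universe is every gene with at least one level-1 base score.
#' Each of the ten meta-feature columns is completed by imputing missing values
#' with the training-set median of that column, and every imputation is flagged
#' in a companion `imputed_<column>` flag.
#'
#' @param base_scores Tibble with columns `gene`, `BrainSpan_score`,
#'   `STRING_score` (NA where a gene was not scorable by that level-1 model).
#' @param priors Tibble with column `gene` and the prior predictor columns
#'   `DAWN`, `Krishnan`, `DAMAGES`, `TADA_BF`,
#'   `tadaFdrAscSscExomeSscAgpSmallDel`, `tadaFdrAscSscExome`,
#'   `tadaFdrAscExome`, `tadaFdrSscExome`.
#' @param labels A [make_training_labels()] label set (medians are computed on
#'   its genes).
#' @return Tibble: `gene`, the ten meta-feature columns in fixed order, then
#'   ten `imputed_*` logical flags. No missing values remain.
#' @export
assemble_meta_features <- function(base_scores, priors, labels) {
  stopifnot(inherits(labels, "label_set"))
  base_scores <- as_tibble(base_scores)
  need_base <- c("gene", "BrainSpan_score", "STRING_score")
  if (!all(need_base %in% names(base_scores))) {
    abort("base_scores must have columns gene, BrainSpan_score, STRING_score")
  }
  universe <- base_scores$gene[!is.na(base_scores$BrainSpan_score) |
                               !is.na(base_scores$STRING_score)]
  tbl <- left_join(tibble(gene = universe), base_scores, by = "gene")
  tbl <- left_join(tbl, as_tibble(priors), by = "gene")
  prior_cols <- setdiff(meta_feature_columns, c("BrainSpan_score", "STRING_score"))
  for (col in prior_cols) {
    if (!col %in% names(tbl) || all(is.na(tbl[[col]]))) {
      abort(sprintf("prior column '%s' is entirely missing", col))
    }
  }
  training <- intersect(label_genes(labels), universe)
  tr_idx <- tbl$gene %in% training
  for (col in meta_feature_columns) {
    v <- tbl[[col]]
    med <- median(v[tr_idx], na.rm = TRUE)
    if (!is.finite(med)) {
      abort(sprintf("column '%s' has no training-set values to impute from", col))
    }
    miss <- is.na(v)
    v[miss] <- med
    tbl[[col]] <- v
    tbl[[paste0("imputed_", col)]] <- miss
  }
  tbl[c("gene", meta_feature_columns, paste0("imputed_", meta_feature_columns))]
}

#' Pipeline configuration
#'
#' Collects the inputs and tuning parameters of [run_pipeline()] with the
#' method's reference defaults.
#'
#' @param bundle An [expression_bundle()] (not yet region-filtered).
#' @param network An [interaction_network()] (unfiltered confidences).
#' @param priors Tibble of prior gene-level predictors (see
#'   [assemble_meta_features()]).
#' @param positives,exclusion Character gene sets: the positive class and the
#'   full exclusion list for negative sampling.
#' @param n_negative Negatives to sample (default 1000).
#' @param min_region_samples Region filter threshold (default 20).
#' @param grid_size Trajectory grid size (default 50).
#' @param min_edge_score Network confidence filter (default 0.4).
#' @param n_trees,per_class Forest geometry (defaults 1000 trees, 70 per class).
#' @param scale Trajectory z-scaling orientation (see
#'   [build_trajectory_features()]).
#' @param seed Single top-level seed; stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(bundle, network, priors, positives, exclusion,
                            n_negative = 1000, min_region_samples = 20,
                            grid_size = 50, min_edge_score = 0.4,
                            n_trees = 1000, per_class = 70,
                            scale = "gene", seed = 1) {
  structure(
    list(bundle = bundle, network = network, priors = priors,
         positives = positives, exclusion = exclusion,
         n_negative = n_negative, min_region_samples = min_region_samples,
         grid_size = grid_size, min_edge_score = min_edge_score,
         n_trees = n_trees, per_class = per_class, scale = scale, seed = seed),
    class = "pipeline_config"
  )
}

#' Run the full two-level stacked ensemble
#'
#' Executes the whole method: region filter, trajectory featurization, and the
#' level-1 expression forest; confidence filter, shortest-path matrix, backward
#' elimination, and the level-1 network forest; assembly of the ten-column
#' meta-feature table (out-of-bag level-1 scores for training genes, so the
#' level-2 model never sees a self-prediction); the level-2 balanced forest;
#' and the genome-wide score table. Fully deterministic given the config seed.
#'
#' Training genes are restricted to genes present in both the expression and
#' network data (both level-1 models need feature rows for every training
#' gene); the scored universe is the union of genes scorable by either model,
#' with median imputation for the missing side.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `ensemble_result` with elements `scores` (tibble
#'   with columns `gene`, `BrainSpan_score`, `STRING_score`, `forecASD`,
#'   `is_training`, `oob`), `importance` (level-2 impurity importances,
#'   normalized to sum to 1), `meta` (the meta-feature table), `labels`,
#'   `elimination_log`, and the three fitted models.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[%s] %s", what, conditionMessage(e)))
    })
  }

  bundle <- stage("filter_regions",
                  filter_regions(config$bundle, config$min_region_samples))
  traj <- stage("build_trajectory_features",
                build_trajectory_features(bundle, config$grid_size, config$scale))
  x_expr <- feature_matrix(traj)

  net <- stage("filter_edges", filter_edges(config$network, config$min_edge_score))
  spm <- stage("shortest_path_matrix", shortest_path_matrix(net))

  expr_genes <- rownames(x_expr)
  net_genes <- rownames(spm)
  both <- intersect(expr_genes, net_genes)
  positives <- intersect(config$positives, both)
  if (length(positives) < 2) {
    abort("[labels] fewer than 2 positive genes present in both data sources")
  }
  labels <- stage("labels", make_training_labels(
    positives, config$exclusion, universe = both,
    n_negative = config$n_negative, seed = derive_seed(seed, 3)
  ))
  train_genes <- label_genes(labels)
  y <- train_genes %in% labels$positives

  bs_model <- stage("brainspan_forest", train_balanced_forest(
    x_expr[train_genes, , drop = FALSE], y,
    n_trees = config$n_trees, per_class = config$per_class,
    seed = derive_seed(seed, 4)
  ))
  bs_scores <- stage("brainspan_scores", score_genes(bs_model, x_expr))

  elim <- stage("string_forest", backward_eliminate(
    spm[train_genes, , drop = FALSE], y,
    n_trees = config$n_trees, per_class = config$per_class,
    seed = derive_seed(seed, 5)
  ))
  st_scores <- stage("string_scores", score_genes(
    elim$model, spm[, elim$features, drop = FALSE]
  ))

  base_scores <- dplyr::full_join(
    rename(bs_scores[c("gene", "score")], BrainSpan_score = "score"),
    rename(st_scores[c("gene", "score")], STRING_score = "score"),
    by = "gene"
  )
  meta <- stage("meta_features",
                assemble_meta_features(base_scores, config$priors, labels))

  x_meta <- as.matrix(meta[meta_feature_columns])
  rownames(x_meta) <- meta$gene
  meta_train <- x_meta[train_genes, , drop = FALSE]
  final_model <- stage("final_forest", with_importance(
    meta_train, y, config, derive_seed(seed, 6)
  ))
  final_scores <- stage("final_scores", score_genes(final_model, x_meta))

  scores <- meta[c("gene", "BrainSpan_score", "STRING_score")] %>%
    left_join(rename(final_scores, forecASD = "score"), by = "gene") %>%
    mutate(is_training = .data$gene %in% train_genes) %>%
    select("gene", "BrainSpan_score", "STRING_score", "forecASD",
           "is_training", "oob")

  imp <- final_model$rf$variable.importance
  importance <- tibble(
    feature = names(imp),
    importance = as.numeric(imp) / sum(imp)
  ) %>% arrange(desc(.data$importance))

  structure(
    list(scores = scores, importance = importance, meta = meta,
         labels = labels, elimination_log = elim$log,
         models = list(brainspan = bs_model, string = elim$model,
                       final = final_model),
         config = config),
    class = "ensemble_result"
  )
}

# level-2 fit with impurity importance; same balanced in-bag machinery
with_importance <- function(x, y, config, seed) {
  model <- train_balanced_forest(
    x, y, n_trees = config$n_trees, per_class = config$per_class, seed = seed
  )
  yf <- as_binary_factor(y)
  n <- nrow(x)
  inbag <- lapply(seq_len(config$n_trees), function(t) model$inbag[, t])
  model$rf <- ranger::ranger(
    x = x, y = yf, num.trees = config$n_trees,
    mtry = model$params$mtry, min.node.size = 1, splitrule = "gini",
    inbag = inbag, importance = "impurity",
    seed = derive_seed(seed, 2), num.threads = 1, verbose = FALSE
  )
  model
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result> %d scored genes (%d training), %d network features retained\n",
              nrow(x$scores), sum(x$scores$is_training),
              length(x$models$string$feature_names)))
  invisible(x)
}

#' Tidy and summarize an ensemble result
#' @param x An `ensemble_result`.
#' @param ... Unused.
#' @return `tidy()` returns the per-gene score table; `glance()` a one-row
#'   summary.
#' @export
tidy.ensemble_result <- function(x, ...) x$scores

#' @rdname tidy.ensemble_result
#' @export
glance.ensemble_result <- function(x, ...) {
  tibble(
    n_genes = nrow(x$scores),
    n_training = sum(x$scores$is_training),
    n_positives = length(x$labels$positives),
    n_negatives = length(x$labels$negatives),
    n_network_features = length(x$models$string$feature_names),
    n_elimination_rounds = max(x$elimination_log$round),
    top_meta_feature = x$importance$feature[1]
  )
}

#' @rdname tidy.ensemble_result
#' @param object An `ensemble_result`.
#' @export
autoplot.ensemble_result <- function(object, ...) {
  df <- mutate(object$scores,
               class = if_else(.data$is_training, "training", "scored"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$forecASD, fill = .data$class)) +
    ggplot2::geom_histogram(bins = 40, position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "final ensemble score", y = "genes", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Write an ensemble score table
#'
#' Columns, in order: `gene`, `BrainSpan_score`, `STRING_score`, `forecASD`,
#' `is_training`, `oob`.
#'
#' @param result An `ensemble_result`.
#' @param file Output TSV path.
#' @return `file`, invisibly.
#' @export
write_score_table <- function(result, file) {
  write_gene_table(result$scores, file)
}
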