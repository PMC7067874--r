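#' Train a balanced random forest with exact per-tree class sampling
#'
#' Every tree is grown on an in-bag multiset of exactly `per_class` draws from
#' each class, sampled (by default with replacement) within class under this
#' function's own RNG; the draws are recorded per tree so out-of-bag scores and
#' in-bag counts are exactly reproducible. Trees use Gini impurity,
#' `mtry = floor(sqrt(p))` and minimum node size 1 unless overridden. The
#' reference configuration is 1000 trees with 70 draws per class.
#'
#' @param x Numeric feature matrix with gene rownames (or a data frame thereof).
#' @param y Binary labels: logical, or a factor/character with exactly two
#'   distinct values, where `TRUE`/`"pos"`/the second factor level marks the
#'   positive class. Logical input is recommended.
#' @param n_trees Number of trees (default 1000).
#' @param per_class In-bag draws per class per tree (default 70).
#' @param mtry Features tried per split; default `floor(sqrt(ncol(x)))`.
#' @param replace Sample within class with replacement (default TRUE).
#' @param seed Integer seed; identical seeds give byte-identical forests.
#' @return An object of class `balanced_forest` holding the fitted trees, the
#'   per-tree in-bag count matrix, feature names and parameters.
#' @export
train_balanced_forest <- function(x, y, n_trees = 1000, per_class = 70,
                                  mtry = NULL, replace = TRUE, seed = 1) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) abort("x must have gene rownames")
  y <- as_binary_factor(y)
  if (length(y) != nrow(x)) abort("length(y) must equal nrow(x)")
  if (nlevels(droplevels(y)) < 2) abort("both classes must be non-empty")
  stopifnot(n_trees >= 1, per_class >= 1)
  pos_rows <- which(y == "pos")
  neg_rows <- which(y == "neg")
  if (!replace && (per_class > length(pos_rows) || per_class > length(neg_rows))) {
    abort("per_class exceeds a class size and replace = FALSE")
  }
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(x))))
  n <- nrow(x)
  inbag <- with_seed(derive_seed(seed, 1), {
    lapply(seq_len(n_trees), function(t) {
      draws <- c(
        pos_rows[sample.int(length(pos_rows), per_class, replace = replace)],
        neg_rows[sample.int(length(neg_rows), per_class, replace = replace)]
      )
      tabulate(draws, nbins = n)
    })
  })
  rf <- ranger::ranger(
    x = x, y = y,
    num.trees = n_trees, mtry = mtry, min.node.size = 1,
    splitrule = "gini", inbag = inbag,
    seed = derive_seed(seed, 2), num.threads = 1, verbose = FALSE
  )
  structure(
    list(
      rf = rf,
      inbag = matrix(unlist(inbag), nrow = n, ncol = n_trees,
                     dimnames = list(rownames(x), NULL)),
      feature_names = colnames(x),
      training_genes = rownames(x),
      y = y,
      params = list(n_trees = n_trees, per_class = per_class, mtry = mtry,
                    replace = replace, seed = seed)
    ),
    class = "balanced_forest"
  )
}

as_binary_factor <- function(y) {
  if (is.logical(y)) return(factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos")))
  if (is.factor(y) || is.character(y)) {
    u <- sort(unique(as.character(y)))
    if (length(u) == 1) return(factor(as.character(y), levels = c(u, ".other")))
    if (length(u) != 2) abort("y must have exactly two classes")
    if (setequal(u, c("neg", "pos"))) {
      return(factor(as.character(y), levels = c("neg", "pos")))
    }
    return(factor(ifelse(as.character(y) == u[2], "pos", "neg"),
                  levels = c("neg", "pos")))
  }
  abort("y must be logical, factor, or character")
}

#' @export
print.balanced_forest <- function(x, ...) {
  cat(sprintf("<balanced_forest> %d trees, %d/%d in-bag per class, %d features, %d training genes\n",
              x$params$n_trees, x$params$per_class, x$params$per_class,
              length(x$feature_names), length(x$training_genes)))
  invisible(x)
}

#' Count split usage of every feature across all trees
#'
#' A feature is "used" when it appears in at least one internal split node of at
#' least one tree.
#'
#' @param model A [train_balanced_forest()] fit.
#' @return Named integer vector of split counts, one per feature.
#' @export
feature_usage <- function(model) {
  stopifnot(inherits(model, "balanced_forest"))
  forest <- model$rf$forest
  p <- length(model$feature_names)
  usage <- integer(p)
  for (t in seq_len(forest$num.trees)) {
    kids <- forest$child.nodeIDs[[t]]
    terminal <- kids[[1]] == 0 & kids[[2]] == 0
    used <- forest$split.varIDs[[t]][!terminal] + 1L  # varIDs are 0-based
    usage <- usage + tabulate(used, nbins = p)
  }
  setNames(usage, model$feature_names)
}

#' Score genes with a balanced forest, out-of-bag for training genes
#'
#' Non-training rows are scored as the fraction of all trees voting positive.
#' Training rows are scored using only the trees whose in-bag sample excluded
#' them (out-of-bag), giving an unbiased estimate; a training row that is
#' in-bag in every tree falls back to the all-trees score with a warning.
#'
#' @param model A [train_balanced_forest()] fit.
#' @param x Feature matrix to score, columns matching the model's features.
#' @param training_genes Genes of `x` to score out-of-bag; defaults to the rows
#'   the model was trained on.
#' @return Tibble with columns `gene`, `score` in \[0,1\], and `oob` (TRUE when
#'   the score is an out-of-bag estimate).
#' @export
score_genes <- function(model, x, training_genes = NULL) {
  stopifnot(inherits(model, "balanced_forest"))
  x <- as.matrix(x)
  if (!identical(colnames(x), model$feature_names)) {
    if (is.null(colnames(x)) || !all(model$feature_names %in% colnames(x))) {
      abort("feature mismatch between model and scoring matrix")
    }
    x <- x[, model$feature_names, drop = FALSE]
  }
  training_genes <- training_genes %||% model$training_genes
  votes <- tree_votes(model, x)
  score <- rowMeans(votes)
  oob <- rep(FALSE, nrow(x))
  names(oob) <- rownames(x)
  tr <- intersect(rownames(x), intersect(training_genes, model$training_genes))
  fallback <- character(0)
  for (g in tr) {
    oob_trees <- model$inbag[g, ] == 0
    if (!any(oob_trees)) {
      fallback <- c(fallback, g)
      next
    }
    score[match(g, rownames(x))] <- mean(votes[match(g, rownames(x)), oob_trees])
    oob[g] <- TRUE
  }
  if (length(fallback) > 0) {
    warn(sprintf("%d training gene(s) in-bag in every tree; using all-trees score: %s",
                 length(fallback), paste(fallback, collapse = ", ")))
  }
  tibble(gene = rownames(x), score = unname(score), oob = unname(oob))
}

# internal: logical n x n_trees matrix of per-tree positive votes
tree_votes <- function(model, x) {
  pr <- stats::predict(model$rf, data = x, predict.all = TRUE,
                       num.threads = 1)$predictions
  pos_idx <- match("pos", model$rf$forest$levels)
  pr == pos_idx
}

#' Backward elimination of unused features
#'
#' Fits a balanced forest, drops every feature not selected in any tree, and
#' refits, repeating until the model contains only features selected at least
#' once during tree construction. Each round refits with a fresh seed derived
#' deterministically from `(seed, round)`.
#'
#' @inheritParams train_balanced_forest
#' @return A list with `model` (the final [train_balanced_forest()] fit),
#'   `features` (retained feature names), and `log` (tibble of per-round
#'   feature counts and drops).
#' @export
backward_eliminate <- function(x, y, n_trees = 1000, per_class = 70,
                               mtry = NULL, replace = TRUE, seed = 1) {
  x <- as.matrix(x)
  features <- colnames(x)
  if (is.null(features)) abort("x must have feature column names")
  log <- list()
  round <- 0L
  repeat {
    round <- round + 1L
    model <- train_balanced_forest(
      x[, features, drop = FALSE], y,
      n_trees = n_trees, per_class = per_class, mtry = mtry,
      replace = replace, seed = derive_seed(seed, 100 + round)
    )
    usage <- feature_usage(model)
    zero <- names(usage)[usage == 0]
    log[[round]] <- tibble(
      round = round,
      n_features = length(features),
      n_zero_usage = length(zero)
    )
    if (length(zero) == 0) break
    features <- setdiff(features, zero)
    if (length(features) == 0) abort("all features eliminated")
  }
  list(model = model, features = features, log = bind_rows(log))
}

#' @rdname train_balanced_forest
#' @param x A `balanced_forest` object (for `tidy()`/`glance()`).
#' @param ... Unused.
#' @export
tidy.balanced_forest <- function(x, ...) {
  usage <- feature_usage(x)
  tibble(feature = names(usage), n_splits = as.integer(usage)) %>%
    arrange(desc(.data$n_splits), .data$feature)
}

#' @rdname train_balanced_forest
#' @export
glance.balanced_forest <- function(x, ...) {
  tibble(
    n_trees = x$params$n_trees,
    per_class = x$params$per_class,
    mtry = x$params$mtry,
    n_features = length(x$feature_names),
    n_training = length(x$training_genes),
    oob_error = x$rf$prediction.error
  )
}
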