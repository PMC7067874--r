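#' Drop brain regions with too few samples
#'
#' Regions containing fewer than `min_samples` samples are excluded (a region
#' with exactly `min_samples` stays). On the reference atlas this retains 16 of
#' 26 structures at the default threshold of 20.
#'
#' @param bundle An [expression_bundle()].
#' @param min_samples Minimum per-region sample count (default 20).
#' @return A filtered [expression_bundle()].
#' @export
filter_regions <- function(bundle, min_samples = 20) {
  stopifnot(inherits(bundle, "expression_bundle"), min_samples >= 1)
  counts <- table(bundle$sample_meta$region)
  keep_regions <- names(counts)[counts >= min_samples]
  if (length(keep_regions) == 0) {
    abort(sprintf("no region has at least %d samples", min_samples))
  }
  keep <- bundle$sample_meta$region %in% keep_regions
  expression_bundle(bundle$values[, keep, drop = FALSE],
                    bundle$sample_meta[keep, , drop = FALSE])
}

#' Smooth one trajectory and interpolate it onto a fixed grid
#'
#' Replicate measurements at identical ages are mean-averaged first (averaging
#' out redundant timepoints), the (age, value) pairs are LOWESS-smoothed
#' (span `f = 2/3`, 3 robustness iterations, the smoother's classical defaults),
#' and the smoothed curve is linearly interpolated onto `grid`. Grid points
#' outside the observed age range take the nearest smoothed endpoint value.
#'
#' @param ages Numeric ages (post-conception weeks) of the observations.
#' @param values Numeric expression values, same length as `ages`.
#' @param grid Ascending numeric grid of ages to interpolate onto.
#' @return Numeric vector of length `length(grid)`.
#' @export
smooth_interpolate_trajectory <- function(ages, values, grid) {
  stopifnot(length(ages) == length(values), !is.unsorted(grid))
  if (any(!is.finite(ages)) || any(!is.finite(values))) {
    abort("ages and values must be finite")
  }
  mu <- tapply(values, ages, mean)
  ax <- as.numeric(names(mu))
  if (length(ax) < 2) {
    abort("need at least 2 distinct ages after replicate averaging")
  }
  ord <- order(ax)
  lo <- lowess(ax[ord], as.numeric(mu)[ord], f = 2 / 3, iter = 3)
  approx(lo$x, lo$y, xout = grid, rule = 2)$y
}

#' Build the trajectory feature matrix
#'
#' One shared grid of `grid_size` equally spaced ages spans the global min-max
#' age across retained samples. Per gene and region, the trajectory is smoothed
#' and interpolated with [smooth_interpolate_trajectory()]; the concatenated
#' per-gene vector (regions in lexicographic order, grid index ascending within
#' region) is z-scaled to mean 0, sd 1. Constant gene vectors map to all zeros.
#' With 16 retained regions and the default 50-point grid this yields the
#' method's 800 trajectory measures per gene.
#'
#' @param bundle A region-filtered [expression_bundle()].
#' @param grid_size Number of grid timepoints per region (default 50).
#' @param scale `"gene"` (default) z-scales each gene's concatenated feature
#'   vector; `"timepoint"` z-scales each feature column across genes instead.
#' @return A tibble with a `gene` column and `n_regions * grid_size` feature
#'   columns named `<region>@t<k>`.
#' @export
build_trajectory_features <- function(bundle, grid_size = 50,
                                      scale = c("gene", "timepoint")) {
  stopifnot(inherits(bundle, "expression_bundle"), grid_size >= 2)
  scale <- match.arg(scale)
  meta <- bundle$sample_meta
  regions <- sort(unique(meta$region))
  ages_all <- meta$age_pcw
  grid <- seq(min(ages_all), max(ages_all), length.out = grid_size)
  genes <- rownames(bundle$values)
  blocks <- vector("list", length(regions))
  for (ri in seq_along(regions)) {
    r <- regions[ri]
    idx <- which(meta$region == r)
    ages <- meta$age_pcw[idx]
    if (length(unique(ages)) < 2) {
      abort(sprintf("region '%s' has fewer than 2 distinct ages", r))
    }
    sub <- bundle$values[, idx, drop = FALSE]
    if (any(!is.finite(sub))) {
      bad <- genes[which(rowSums(!is.finite(sub)) > 0)[1]]
      abort(sprintf("gene '%s' has missing values in region '%s'", bad, r))
    }
    block <- t(apply(sub, 1, smooth_interpolate_trajectory,
                     ages = ages, grid = grid))
    colnames(block) <- sprintf("%s@t%02d", r, seq_len(grid_size))
    blocks[[ri]] <- block
  }
  feats <- do.call(cbind, blocks)
  # a row/column is constant when its sd is negligible relative to its level
  # (the smoother can leave ~1e-16 ripple on exactly constant trajectories,
  # which plain z-scaling would blow up to order 1)
  if (scale == "gene") {
    mu <- rowMeans(feats)
    sdv <- apply(feats, 1, sd)
    const <- sdv <= 1e-9 * pmax(abs(mu), 1)
    feats <- (feats - mu) / ifelse(const, 1, sdv)
    feats[const, ] <- 0
  } else {
    mu <- colMeans(feats)
    sdv <- apply(feats, 2, sd)
    const <- sdv <= 1e-9 * pmax(abs(mu), 1)
    feats <- sweep(sweep(feats, 2, mu), 2, ifelse(const, 1, sdv), "/")
    feats[, const] <- 0
  }
  out <- as_tibble(feats)
  out <- dplyr::bind_cols(tibble(gene = genes), out)
  attr(out, "grid") <- grid
  attr(out, "regions") <- regions
  out
}

# internal: trajectory-feature tibble -> numeric matrix with gene rownames
feature_matrix <- function(tbl) {
  m <- as.matrix(tbl[setdiff(names(tbl), "gene")])
  rownames(m) <- tbl$gene
  m
}
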