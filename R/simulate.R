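#' Simulation configuration
#'
#' Collects the parameters of the synthetic-data generators with defaults that
#' mirror the reference study's geometry (76 positives, 1000 negatives, 16
#' retained regions on a 50-point grid, 1000-tree forests) at a problem size
#' that runs the full pipeline in minutes (2000 genes, 60 donors).
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_regions Number of brain regions passing the sample filter
#'   (default 16).
#' @param n_small_regions Extra regions kept below the 20-sample threshold to
#'   exercise the region filter (default 2).
#' @param small_region_samples Samples per under-sampled region (default 8).
#' @param region_samples_range Per-region sample count range for retained
#'   regions (default 24-40).
#' @param n_donors Number of donors (default 60); donor ages are irregular and
#'   integer-valued, so replicate timepoints occur.
#' @param n_positive,n_negative Training class sizes (defaults 76 and 1000).
#' @param n_exclusion_extra Additional lower-confidence genes barred from the
#'   negative class (default 100).
#' @param trajectory_effect Amplitude of the positive-class trajectory
#'   archetypes in log-expression units (default 1; 0 = null).
#' @param noise_sd Log-expression noise standard deviation (default 0.3).
#' @param n_communities Planted network communities (default 10).
#' @param positive_communities Communities in which positives concentrate
#'   (default 3).
#' @param p_within,p_between Within/between-community edge probabilities
#'   (defaults 0.05 and 0.002).
#' @param prior_effect Strength of the label signal in prior score columns
#'   (default 2; 0 = null).
#' @param prior_missingness Named missingness rates for prior columns.
#' @param lof_rate Mean loss-of-function de novo mutations per average-length
#'   gene (default 0.45).
#' @param lof_enrichment Rate multiplier for positives (default 10; 1 = null).
#' @param missense_rate,missense_enrichment Missense analogues (defaults 0.8, 3).
#' @param syn_rate Mean synonymous mutations per average-length gene (default
#'   0.8); synonymous rates follow gene length only, never the label.
#' @param n_individuals Proband pool size (default 3000).
#' @param mean_eqtl_per_gene Mean eQTL records per gene (default 5).
#' @param eqtl_base_hit,eqtl_top_hit GWAS hit probability for eQTL of ordinary
#'   genes and of top-scoring genes (defaults 0.1 and 0.3; equal = null).
#' @param eqtl_top_fraction Fraction of genes counted as top-scoring
#'   (default 0.05).
#' @param seed Master seed (mandatory).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 2000,
                              n_regions = 16,
                              n_small_regions = 2,
                              small_region_samples = 8,
                              region_samples_range = c(24, 40),
                              n_donors = 60,
                              n_positive = 76,
                              n_negative = 1000,
                              n_exclusion_extra = 100,
                              trajectory_effect = 1,
                              noise_sd = 0.3,
                              n_communities = 10,
                              positive_communities = 3,
                              p_within = 0.05,
                              p_between = 0.002,
                              prior_effect = 2,
                              prior_missingness = c(
                                DAWN = 0.2, Krishnan = 0.1, DAMAGES = 0.3,
                                TADA_BF = 0.05,
                                tadaFdrAscSscExomeSscAgpSmallDel = 0.05,
                                tadaFdrAscSscExome = 0.05,
                                tadaFdrAscExome = 0.05,
                                tadaFdrSscExome = 0.05
                              ),
                              lof_rate = 0.45,
                              lof_enrichment = 10,
                              missense_rate = 0.8,
                              missense_enrichment = 3,
                              syn_rate = 0.8,
                              n_individuals = 3000,
                              mean_eqtl_per_gene = 5,
                              eqtl_base_hit = 0.1,
                              eqtl_top_hit = 0.3,
                              eqtl_top_fraction = 0.05,
                              seed = NULL) {
  if (is.null(seed)) abort("simulation_config requires an explicit seed")
  cfg <- as.list(environment())
  counts <- c("n_genes", "n_regions", "n_donors", "n_positive", "n_negative",
              "n_communities", "positive_communities", "n_individuals")
  for (nm in counts) {
    if (cfg[[nm]] < 1) abort(sprintf("%s must be a positive count", nm))
  }
  probs <- c(cfg$p_within, cfg$p_between, cfg$prior_missingness,
             cfg$eqtl_base_hit, cfg$eqtl_top_hit, cfg$eqtl_top_fraction)
  if (any(probs < 0 | probs > 1)) abort("all probabilities must lie in [0, 1]")
  if (cfg$positive_communities > cfg$n_communities) {
    abort("positive_communities cannot exceed n_communities")
  }
  structure(cfg, class = "simulation_config")
}

gene_ids <- function(config) sprintf("g%05d", seq_len(config$n_genes))

# smooth trajectory archetypes over age in post-conception weeks
trajectory_archetypes <- list(
  prenatal_peak = function(age) exp(-(log(age) - log(16))^2 / (2 * 0.35)),
  postnatal_rise = function(age) plogis((log(age) - log(120)) / 0.5),
  prenatal_decline = function(age) 1 - plogis((log(age) - log(40)) / 0.4)
)

#' Simulate a developmental expression bundle with planted trajectory signal
#'
#' Positive-class genes follow one of three smooth trajectory archetypes
#' (prenatal peak, postnatal rise, prenatal decline) with region-specific
#' amplitudes plus log-normal noise; negatives are flat noise around a
#' gene-specific baseline. Donor ages are irregular integer-valued labels in
#' the atlas dialect (pcw/mos/yrs), so replicate timepoints occur, and
#' `n_small_regions` regions fall below the 20-sample filter threshold.
#'
#' @param config A [simulation_config()].
#' @return A list with `bundle` (an [expression_bundle()]; `sample_meta` keeps
#'   the original `age_label`) and `truth` (tibble `gene`, `is_positive`,
#'   `archetype`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(derive_seed(config$seed, 11), {
    genes <- gene_ids(config)
    positives <- sort(sample(genes, config$n_positive))
    is_pos <- genes %in% positives

    # donors: irregular ages spanning 8 pcw to 40 yrs, in label form
    n_pre <- ceiling(config$n_donors / 2)
    labels <- c(
      sprintf("%d pcw", sample(8:38, n_pre, replace = TRUE)),
      sprintf("%d mos", sample(2:24, ceiling(config$n_donors / 4), replace = TRUE)),
      sprintf("%d yrs", sample(1:40, config$n_donors - n_pre -
                                 ceiling(config$n_donors / 4), replace = TRUE))
    )
    donors <- tibble(
      donor_id = sprintf("d%03d", seq_len(config$n_donors)),
      age_label = labels,
      age_pcw = parse_age(labels)
    )

    regions <- c(sprintf("R%02d", seq_len(config$n_regions)),
                 if (config$n_small_regions > 0) {
                   sprintf("S%02d", seq_len(config$n_small_regions))
                 })
    n_per_region <- c(
      sample(config$region_samples_range[1]:config$region_samples_range[2],
             config$n_regions, replace = TRUE),
      rep(config$small_region_samples, config$n_small_regions)
    )
    donor_idx <- unlist(lapply(n_per_region, function(k) {
      sample.int(config$n_donors, k, replace = TRUE)
    }))
    meta <- tibble(
      sample_id = sprintf("s%04d", seq_along(donor_idx)),
      donor_id = donors$donor_id[donor_idx],
      region = rep(regions, n_per_region),
      age_pcw = donors$age_pcw[donor_idx],
      age_label = donors$age_label[donor_idx]
    )

    baseline <- rlnorm(config$n_genes, meanlog = 2, sdlog = 0.8)
    archetype <- ifelse(is_pos,
                        sample(names(trajectory_archetypes),
                               config$n_genes, replace = TRUE),
                        NA_character_)
    arch_vals <- vapply(trajectory_archetypes,
                        function(f) f(meta$age_pcw),
                        numeric(nrow(meta)))  # samples x archetypes
    # per gene x region amplitude (positives only)
    amp <- matrix(runif(config$n_genes * length(regions), 0.5, 1.5),
                  nrow = config$n_genes,
                  dimnames = list(genes, regions))
    amp <- amp * config$trajectory_effect * is_pos
    region_of <- match(meta$region, regions)
    signal <- matrix(0, config$n_genes, nrow(meta))
    pos_idx <- which(is_pos)
    if (length(pos_idx) > 0 && config$trajectory_effect > 0) {
      arch_of <- match(archetype[pos_idx], names(trajectory_archetypes))
      signal[pos_idx, ] <- amp[pos_idx, region_of, drop = FALSE] *
        t(arch_vals)[arch_of, , drop = FALSE]
    }
    noise <- matrix(rnorm(config$n_genes * nrow(meta), sd = config$noise_sd),
                    config$n_genes, nrow(meta))
    values <- exp(log(baseline) + signal + noise)
    dimnames(values) <- list(genes, meta$sample_id)
    list(
      bundle = expression_bundle(values, meta),
      truth = tibble(gene = genes, is_positive = is_pos, archetype = archetype)
    )
  })
}

#' Simulate a planted-partition interaction network
#'
#' Genes are assigned to `n_communities` planted communities, with the positive
#' class concentrated in the first `positive_communities`. Edges appear with
#' probability `p_within` inside communities and `p_between` across them.
#' Within-community edges carry higher confidences (uniform on 0.3-1) than
#' between-community edges (uniform on 0.05-0.95), so a fraction falls below
#' the 0.4 confidence filter.
#'
#' @param config A [simulation_config()].
#' @param truth The `truth` tibble from [simulate_expression()].
#' @return An [interaction_network()] whose `"community"` attribute maps each
#'   gene to its planted community.
#' @export
simulate_network <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(derive_seed(config$seed, 12), {
    genes <- truth$gene
    n <- length(genes)
    community <- sample.int(config$n_communities, n, replace = TRUE)
    community[truth$is_positive] <-
      sample.int(config$positive_communities, sum(truth$is_positive),
                 replace = TRUE)
    ord <- order(community)
    block_sizes <- tabulate(community, nbins = config$n_communities)
    pm <- matrix(config$p_between, config$n_communities, config$n_communities)
    diag(pm) <- config$p_within
    g <- igraph::sample_sbm(n, pref.matrix = pm, block.sizes = block_sizes)
    el <- igraph::as_edgelist(g, names = FALSE)
    ga <- genes[ord][el[, 1]]
    gb <- genes[ord][el[, 2]]
    comm_sorted <- community[ord]
    within <- comm_sorted[el[, 1]] == comm_sorted[el[, 2]]
    score <- ifelse(within, runif(nrow(el), 0.3, 1), runif(nrow(el), 0.05, 0.95))
    net <- interaction_network(
      tibble(gene_a = ga, gene_b = gb, score = score),
      nodes = genes
    )
    attr(net, "community") <- tibble(gene = genes, community = community)
    net
  })
}

#' Simulate prior scores, de novo mutations, eQTL/GWAS records, and pLI
#'
#' Prior columns are correlated with the true labels at strength
#' `prior_effect` with per-column missingness. De novo mutation counts are
#' Poisson with a gene-length-driven rate: synonymous mutations follow length
#' only (the baseline the decile test corrects with), while loss-of-function
#' and missense rates are multiplied by their enrichment factors in positive
#' genes. eQTL records are GWAS hits with elevated probability for genes in
#' the top `eqtl_top_fraction` of `scores` (the truth labels stand in when no
#' scores are supplied). pLI is elevated in the planted positive communities.
#'
#' @param config A [simulation_config()].
#' @param truth The `truth` tibble from [simulate_expression()].
#' @param scores Optional tibble with `gene` and `score` used to place eQTL
#'   signal; defaults to the binary truth labels.
#' @param community Optional tibble `gene`, `community` (the attribute from
#'   [simulate_network()]); defaults to treating positives as the high-pLI set.
#' @return A list with tibbles `priors`, `dnm`, `eqtl`, `pli`.
#' @export
simulate_evaluation_data <- function(config, truth, scores = NULL,
                                     community = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(derive_seed(config$seed, 13), {
    genes <- truth$gene
    n <- length(genes)
    pos <- truth$is_positive

    # prior gene-level predictors
    eff <- config$prior_effect
    priors <- tibble(
      gene = genes,
      DAWN = plogis(eff * pos + rnorm(n)),
      Krishnan = plogis(eff * pos + rnorm(n)),
      DAMAGES = plogis(eff * pos + rnorm(n)),
      TADA_BF = exp(eff * pos + rnorm(n)),
      tadaFdrAscSscExomeSscAgpSmallDel = rbeta(n, 1, 1 + eff * pos),
      tadaFdrAscSscExome = rbeta(n, 1, 1 + eff * pos),
      tadaFdrAscExome = rbeta(n, 1, 1 + eff * pos),
      tadaFdrSscExome = rbeta(n, 1, 1 + eff * pos)
    )
    for (col in names(config$prior_missingness)) {
      miss <- runif(n) < config$prior_missingness[[col]]
      priors[[col]][miss] <- NA_real_
    }

    # de novo mutations with a length-driven baseline
    len_rel <- rlnorm(n, 0, 0.6)
    len_rel <- len_rel / mean(len_rel)
    rates <- list(
      synonymous = config$syn_rate * len_rel,
      LOF = config$lof_rate * len_rel *
        ifelse(pos, config$lof_enrichment, 1),
      missense = config$missense_rate * len_rel *
        ifelse(pos, config$missense_enrichment, 1)
    )
    cohorts <- c("MSSNG", "ASC", "SPARK")
    dnm <- bind_rows(purrr::imap(rates, function(rate, consequence) {
      cnt <- pmin(rpois(n, rate), config$n_individuals)
      hit <- which(cnt > 0)
      if (length(hit) == 0) return(NULL)
      ind <- unlist(lapply(cnt[hit], function(k) sample.int(config$n_individuals, k)))
      tibble(
        gene = rep(genes[hit], cnt[hit]),
        individual_id = sprintf("p%05d", ind),
        cohort = sample(cohorts, sum(cnt[hit]), replace = TRUE),
        consequence = consequence
      )
    }))
    dnm <- validate_dnm_table(dnm)

    # eQTL records joined to GWAS p-values
    score_vec <- if (is.null(scores)) {
      as.numeric(pos)
    } else {
      scores$score[match(genes, scores$gene)]
    }
    n_top <- max(1L, round(config$eqtl_top_fraction * n))
    top_genes <- genes[order(-score_vec, genes)][seq_len(n_top)]
    n_rec <- rpois(n, config$mean_eqtl_per_gene)
    rec_gene <- rep(genes, n_rec)
    hit_p <- ifelse(rec_gene %in% top_genes,
                    config$eqtl_top_hit, config$eqtl_base_hit)
    is_hit <- runif(length(rec_gene)) < hit_p
    eqtl <- tibble(
      snp = sprintf("rs%06d", seq_along(rec_gene)),
      gene = rec_gene,
      gwas_p = ifelse(is_hit, runif(length(rec_gene), 1e-8, 0.01),
                      runif(length(rec_gene), 0.01, 1))
    )

    # haploinsufficiency scores, elevated in the planted positive communities
    high_pli <- if (!is.null(community)) {
      community$community[match(genes, community$gene)] <=
        config$positive_communities
    } else {
      pos
    }
    pli <- tibble(
      gene = genes,
      pLI = ifelse(high_pli, rbeta(n, 4, 1), rbeta(n, 1, 3))
    )

    list(priors = priors, dnm = dnm, eqtl = eqtl, pli = pli)
  })
}

#' Write an expression bundle in the atlas download dialect
#'
#' Emits the three-CSV dialect read by [read_expression_bundle()]: a
#' header-less matrix CSV with a leading row-index column, a row metadata CSV
#' with the gene identifiers, and a column metadata CSV with donor, structure,
#' and age label.
#'
#' @param bundle An [expression_bundle()]; if `sample_meta` has no `age_label`
#'   column, ages are written as `"<x> pcw"`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the three file paths, invisibly.
#' @export
write_expression_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- bundle$sample_meta
  age_label <- if ("age_label" %in% names(meta)) {
    meta$age_label
  } else {
    sprintf("%s pcw", format(meta$age_pcw, trim = TRUE))
  }
  paths <- file.path(dir, c("expression.csv", "rows_metadata.csv",
                            "columns_metadata.csv"))
  mat <- cbind(seq_len(nrow(bundle$values)), unname(bundle$values))
  readr::write_csv(as_tibble(as.data.frame(mat)), paths[1], col_names = FALSE,
                   progress = FALSE)
  readr::write_csv(tibble(gene = rownames(bundle$values)), paths[2],
                   progress = FALSE)
  readr::write_csv(
    tibble(sample_id = meta$sample_id, donor_id = meta$donor_id,
           structure_acronym = meta$region, age = age_label),
    paths[3], progress = FALSE
  )
  invisible(paths)
}

#' Simulate a complete input directory
#'
#' Runs all generators and writes every input the pipeline reads, in the exact
#' dialects the readers expect, plus a `manifest.json` with the resolved
#' configuration: the expression bundle CSVs, `edges.tsv`, `priors.tsv`,
#' `positives.txt`, `exclusion.txt` (positives plus `n_exclusion_extra`
#' lower-confidence genes), `dnm.tsv`, `eqtl.tsv`, `pli.tsv`, and `truth.tsv`.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
simulate_input_dir <- function(config, dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr <- simulate_expression(config)
  net <- simulate_network(config, expr$truth)
  ev <- simulate_evaluation_data(config, expr$truth,
                                 community = attr(net, "community"))
  write_expression_bundle(expr$bundle, dir)
  write_edge_list(net, file.path(dir, "edges.tsv"))
  write_gene_table(ev$priors, file.path(dir, "priors.tsv"))
  write_dnm_table(ev$dnm, file.path(dir, "dnm.tsv"))
  readr::write_tsv(ev$eqtl, file.path(dir, "eqtl.tsv"), progress = FALSE)
  write_gene_table(ev$pli, file.path(dir, "pli.tsv"))
  write_gene_table(expr$truth, file.path(dir, "truth.tsv"))
  positives <- expr$truth$gene[expr$truth$is_positive]
  exclusion <- with_seed(derive_seed(config$seed, 14), {
    extra <- sample(setdiff(expr$truth$gene, positives),
                    config$n_exclusion_extra)
    sort(c(positives, extra))
  })
  writeLines(sort(positives), file.path(dir, "positives.txt"))
  writeLines(exclusion, file.path(dir, "exclusion.txt"))
  cfg <- unclass(config)
  cfg$prior_missingness <- as.list(cfg$prior_missingness)
  jsonlite::write_json(cfg, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
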