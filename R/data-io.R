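#' Parse a developmental age label into post-conception weeks
#'
#' Age labels follow the atlas convention `"<number> pcw|mos|yrs"` (case
#' insensitive, whitespace tolerant). Post-natal ages are mapped onto a single
#' post-conception-week (pcw) scale with fixed constants: birth = 40 pcw,
#' 1 month = 52/12 weeks, 1 year = 52 weeks. Any strictly monotone convention
#' preserves downstream smoothing/interpolation up to grid placement; this one
#' is fixed so feature matrices are reproducible.
#'
#' @param label Character vector of age labels, e.g. `"8 pcw"`, `"4 mos"`,
#'   `"40 yrs"`.
#' @return Numeric vector of ages in post-conception weeks (finite, > 0).
#' @examples
#' parse_age(c("8 pcw", "4 mos", "40 yrs"))
#' @export
parse_age <- function(label) {
  if (!is.character(label)) abort("age labels must be character")
  m <- regmatches(
    label,
    regexec("^\\s*([0-9]+(?:\\.[0-9]+)?)\\s*(pcw|mos|yrs)\\s*$", label,
            ignore.case = TRUE)
  )
  bad <- vapply(m, length, integer(1)) == 0
  if (any(bad)) {
    abort(paste0("unparseable age label(s): ",
                 paste(sprintf("'%s'", label[bad]), collapse = ", ")))
  }
  num <- vapply(m, function(x) as.numeric(x[2]), numeric(1))
  unit <- tolower(vapply(m, function(x) x[3], character(1)))
  out <- ifelse(unit == "pcw", num,
         ifelse(unit == "mos", 40 + num * 52 / 12, 40 + num * 52))
  if (any(!is.finite(out) | out <= 0)) {
    abort("parsed age must be finite and > 0")
  }
  out
}

#' Construct an expression bundle
#'
#' An expression bundle couples a gene-by-sample non-negative expression matrix
#' (RPKM-like, unitless) with per-sample metadata: donor, brain region, and
#' numeric age in post-conception weeks.
#'
#' @param values Numeric gene x sample matrix with unique rownames (genes) and
#'   colnames (samples); all values finite and >= 0.
#' @param sample_meta Tibble with columns `sample_id`, `donor_id`, `region`,
#'   `age_pcw`, one row per column of `values`, in the same order.
#' @return An object of class `expression_bundle`.
#' @export
expression_bundle <- function(values, sample_meta) {
  sample_meta <- as_tibble(sample_meta)
  need <- c("sample_id", "donor_id", "region", "age_pcw")
  miss <- setdiff(need, names(sample_meta))
  if (length(miss) > 0) {
    abort(paste0("sample_meta missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)) > 0) {
    abort("duplicate or missing gene identifiers in expression matrix rows")
  }
  if (ncol(values) != nrow(sample_meta)) {
    abort(sprintf("dimension mismatch: matrix has %d samples, metadata has %d rows",
                  ncol(values), nrow(sample_meta)))
  }
  if (is.null(colnames(values))) colnames(values) <- sample_meta$sample_id
  if (!identical(colnames(values), as.character(sample_meta$sample_id))) {
    abort("sample identifiers in matrix columns and metadata disagree")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    abort("expression values must be finite and non-negative")
  }
  if (any(!is.finite(sample_meta$age_pcw) | sample_meta$age_pcw <= 0)) {
    abort("every sample must have finite age_pcw > 0")
  }
  if (any(is.na(sample_meta$region) | sample_meta$region == "")) {
    abort("every sample must have a region label")
  }
  structure(
    list(values = values, sample_meta = sample_meta),
    class = "expression_bundle"
  )
}

#' @export
print.expression_bundle <- function(x, ...) {
  cat(sprintf("<expression_bundle> %d genes x %d samples, %d regions, ages %.1f-%.1f pcw\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$sample_meta$region)),
              min(x$sample_meta$age_pcw), max(x$sample_meta$age_pcw)))
  invisible(x)
}

#' Genes and samples of an expression bundle
#' @param bundle An `expression_bundle`.
#' @return Character vector of identifiers.
#' @export
bundle_genes <- function(bundle) rownames(bundle$values)

#' Read an expression bundle in the atlas download dialect
#'
#' The dialect is three CSV files: a header-less expression matrix (optionally
#' with a leading row-index column), a row metadata CSV with a gene identifier
#' column, and a column metadata CSV with donor, structure, and age columns.
#' Age labels are parsed by [parse_age()].
#'
#' @param matrix_file Path to the expression matrix CSV (no header).
#' @param row_meta Path to the row (gene) metadata CSV.
#' @param col_meta Path to the column (sample) metadata CSV.
#' @return An [expression_bundle()].
#' @export
read_expression_bundle <- function(matrix_file, row_meta, col_meta) {
  rows <- readr::read_csv(row_meta, show_col_types = FALSE, progress = FALSE)
  cols <- readr::read_csv(col_meta, show_col_types = FALSE, progress = FALSE)
  gene_col <- intersect(c("gene", "gene_symbol", "gene_id", "ensembl_gene_id"),
                        names(rows))[1]
  if (is.na(gene_col)) abort("row metadata lacks a gene identifier column")
  genes <- as.character(rows[[gene_col]])
  if (anyDuplicated(genes) > 0) {
    abort(paste0("duplicate gene id in row metadata: ",
                 paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  }
  donor_col <- intersect(c("donor_id", "donor"), names(cols))[1]
  region_col <- intersect(c("structure_acronym", "structure", "region"), names(cols))[1]
  age_col <- intersect(c("age", "age_label"), names(cols))[1]
  if (is.na(donor_col) || is.na(region_col) || is.na(age_col)) {
    abort("column metadata must provide donor, structure/region, and age columns")
  }
  mat <- as.matrix(readr::read_csv(matrix_file, col_names = FALSE,
                                   show_col_types = FALSE, progress = FALSE))
  # a leading row-index column (exactly 1..n) is tolerated and dropped
  if (ncol(mat) == nrow(cols) + 1 &&
      isTRUE(all(mat[, 1] == seq_len(nrow(mat))))) {
    mat <- mat[, -1, drop = FALSE]
  }
  if (nrow(mat) != length(genes) || ncol(mat) != nrow(cols)) {
    abort(sprintf(
      "dimension mismatch: matrix is %d x %d but metadata describe %d genes and %d samples",
      nrow(mat), ncol(mat), length(genes), nrow(cols)))
  }
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  sample_id <- if ("sample_id" %in% names(cols)) {
    as.character(cols$sample_id)
  } else {
    sprintf("s%04d", seq_len(nrow(cols)))
  }
  colnames(mat) <- sample_id
  meta <- tibble(
    sample_id = sample_id,
    donor_id = as.character(cols[[donor_col]]),
    region = as.character(cols[[region_col]]),
    age_pcw = parse_age(as.character(cols[[age_col]]))
  )
  expression_bundle(mat, meta)
}

#' Construct an interaction network
#'
#' @param edges Tibble with columns `gene_a`, `gene_b`, `score` (confidence in
#'   \[0,1\]); unordered pairs must be unique and self-loops absent.
#' @param nodes Character vector of node identifiers (defaults to the genes in
#'   `edges`); isolated nodes are allowed.
#' @return An object of class `interaction_network`.
#' @export
interaction_network <- function(edges, nodes = NULL) {
  edges <- as_tibble(edges)
  need <- c("gene_a", "gene_b", "score")
  if (!all(need %in% names(edges))) {
    abort("edges must have columns gene_a, gene_b, score")
  }
  edges <- edges[need]
  if (any(edges$gene_a == edges$gene_b)) abort("self-loops are not allowed")
  if (any(!is.finite(edges$score) | edges$score < 0 | edges$score > 1)) {
    abort("edge scores must lie in [0, 1]")
  }
  # canonical orientation so unordered duplicates are detectable
  flip <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[flip]
  edges$gene_a[flip] <- edges$gene_b[flip]
  edges$gene_b[flip] <- tmp
  key <- paste(edges$gene_a, edges$gene_b, sep = "\r")
  if (anyDuplicated(key) > 0) abort("duplicate unordered gene pairs in edges")
  nodes <- sort(unique(c(nodes, edges$gene_a, edges$gene_b)))
  structure(
    list(edges = arrange(edges, .data$gene_a, .data$gene_b), nodes = nodes),
    class = "interaction_network"
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %d nodes, %d edges, scores %.3f-%.3f\n",
              length(x$nodes), nrow(x$edges),
              if (nrow(x$edges)) min(x$edges$score) else NA,
              if (nrow(x$edges)) max(x$edges$score) else NA))
  invisible(x)
}

#' Read a weighted edge list
#'
#' Whitespace- or tab-delimited rows of `geneA geneB score`; extra columns are
#' ignored and a header line is detected automatically. Scores on the 0-999
#' (`milli`) scale are divided by 1000. Self-loops are dropped; duplicate
#' unordered pairs collapse to their maximum score with a warning (confidence
#' dumps commonly carry both orientations).
#'
#' @param file Path to the edge list.
#' @param score_scale `"unit"` for scores already in \[0,1\], `"milli"` for 0-999.
#' @return An [interaction_network()].
#' @export
read_edge_list <- function(file, score_scale = c("unit", "milli")) {
  score_scale <- match.arg(score_scale)
  lines <- readr::read_lines(file, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("empty edge list")
  fields <- strsplit(trimws(lines), "[ \t]+")
  if (any(vapply(fields, length, integer(1)) < 3)) {
    abort("edge list rows must have at least 3 columns: geneA geneB score")
  }
  # header detection: third field of first row not numeric
  if (is.na(suppressWarnings(as.numeric(fields[[1]][3])))) fields <- fields[-1]
  ga <- vapply(fields, `[`, character(1), 1)
  gb <- vapply(fields, `[`, character(1), 2)
  sc <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3)))
  if (any(is.na(sc))) abort("non-numeric score in edge list")
  hi <- if (score_scale == "milli") 999 else 1
  if (any(sc < 0 | sc > hi)) {
    abort(sprintf("score outside declared %s range [0, %s]", score_scale, hi))
  }
  if (score_scale == "milli") sc <- sc / 1000
  nodes <- unique(c(ga, gb))
  keep <- ga != gb
  if (!all(keep)) inform(sprintf("dropped %d self-loop row(s)", sum(!keep)))
  ga <- ga[keep]; gb <- gb[keep]; sc <- sc[keep]
  flip <- ga > gb
  tmp <- ga[flip]; ga[flip] <- gb[flip]; gb[flip] <- tmp
  key <- paste(ga, gb, sep = "\r")
  if (anyDuplicated(key) > 0) {
    warn(sprintf("collapsed %d duplicate unordered pair(s) to their maximum score",
                 sum(duplicated(key))))
    ord <- order(key, -sc)
    keep2 <- !duplicated(key[ord])
    ga <- ga[ord][keep2]; gb <- gb[ord][keep2]; sc <- sc[ord][keep2]
  }
  interaction_network(tibble(gene_a = ga, gene_b = gb, score = sc), nodes = nodes)
}

#' Write an interaction network as a 3-column TSV edge list
#' @param net An [interaction_network()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_edge_list <- function(net, file) {
  readr::write_tsv(net$edges, file, progress = FALSE)
  invisible(file)
}

#' Read/write gene-keyed score tables
#'
#' Gene tables are TSVs with a header, a `gene` identifier column (unique,
#' case-sensitive, matched exactly), and named numeric/flag columns. Missing
#' values are serialized as `"NA"`. A write-then-read round trip reproduces
#' values to at least 12 significant digits.
#'
#' @param file Path to a TSV.
#' @param required Character vector of column names that must be present.
#' @return A tibble with unique `gene` values.
#' @export
read_gene_table <- function(file, required = "gene") {
  tbl <- readr::read_tsv(file, na = "NA", show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(required, names(tbl))
  if (length(miss) > 0) {
    abort(paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"gene" %in% names(tbl)) abort("missing required column(s): gene")
  tbl$gene <- as.character(tbl$gene)
  if (anyDuplicated(tbl$gene) > 0) {
    abort(paste0("duplicate gene id(s): ",
                 paste(unique(tbl$gene[duplicated(tbl$gene)]), collapse = ", ")))
  }
  tbl
}

#' @rdname read_gene_table
#' @param tbl Tibble with a unique `gene` column.
#' @export
write_gene_table <- function(tbl, file) {
  if (!"gene" %in% names(tbl)) abort("table must have a gene column")
  if (anyDuplicated(tbl$gene) > 0) abort("duplicate gene id(s) in table")
  readr::write_tsv(as_tibble(tbl), file, na = "NA", progress = FALSE)
  invisible(file)
}

#' Read/write de novo mutation tables
#'
#' Records of (gene, individual, cohort, consequence), consequence restricted to
#' `LOF`, `missense`, `synonymous`. Duplicate (gene, individual, consequence)
#' records are collapsed to one.
#'
#' @param file Path to a TSV with columns `gene`, `individual_id`, `cohort`,
#'   `consequence`.
#' @return A tibble of de novo mutation records.
#' @export
read_dnm_table <- function(file) {
  tbl <- readr::read_tsv(file, na = "NA", show_col_types = FALSE, progress = FALSE)
  need <- c("gene", "individual_id", "cohort", "consequence")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0) {
    abort(paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  }
  validate_dnm_table(tbl[need])
}

validate_dnm_table <- function(tbl) {
  tbl <- as_tibble(tbl)
  ok <- tbl$consequence %in% c("LOF", "missense", "synonymous")
  if (!all(ok)) {
    abort(paste0("invalid consequence value(s): ",
                 paste(unique(tbl$consequence[!ok]), collapse = ", ")))
  }
  distinct(tbl, .data$gene, .data$individual_id, .data$consequence, .keep_all = TRUE)
}

#' @rdname read_dnm_table
#' @param tbl Tibble of mutation records.
#' @export
write_dnm_table <- function(tbl, file) {
  readr::write_tsv(validate_dnm_table(tbl), file, na = "NA", progress = FALSE)
  invisible(file)
}

#' Read an eQTL/GWAS association table
#'
#' Records of (snp, gene, gwas_p) joining each eQTL's target gene to the GWAS
#' p-value of its SNP. p-values must lie in (0, 1].
#'
#' @param file Path to a TSV with columns `snp`, `gene`, `gwas_p`.
#' @return A tibble of eQTL records.
#' @export
read_eqtl_table <- function(file) {
  tbl <- readr::read_tsv(file, na = "NA", show_col_types = FALSE, progress = FALSE)
  need <- c("snp", "gene", "gwas_p")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0) {
    abort(paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(!is.finite(tbl$gwas_p) | tbl$gwas_p <= 0 | tbl$gwas_p > 1)) {
    abort("gwas_p must lie in (0, 1]")
  }
  tbl[need]
}
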