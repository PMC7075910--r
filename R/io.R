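# Readers and writers for every external table the pipeline touches.
# All readers are strict: malformed input is rejected with an informative
# error rather than silently coerced. Reads are gzip-transparent.

FEATURE_TYPES <- c("mRNA_coding", "mRNA_noncoding", "miRNA")
INTERACTION_SOURCES <- c("targetscan", "mirtarbase", "trrust", "fantom5", "encode")

read_tsv_lines <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  readLines(con)
}

split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

#' Construct a typed count matrix
#'
#' @param counts integer matrix, features in rows (rownames) and samples in
#'   columns (colnames); all values must be non-negative integers.
#' @param feature_type named character vector mapping every feature to one of
#'   `"mRNA_coding"`, `"mRNA_noncoding"`, `"miRNA"`; may be `NULL` when types
#'   are attached later with [attach_feature_types()].
#' @return an object of class `count_matrix` with elements `counts` and
#'   `feature_type`.
#' @export
count_matrix <- function(counts, feature_type = NULL) {
  if (!is.matrix(counts)) stopf("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("count matrix needs feature rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate feature id: %s",
          rownames(counts)[duplicated(rownames(counts))][1])
  if (anyDuplicated(colnames(counts)))
    stopf("duplicate sample id: %s",
          colnames(counts)[duplicated(colnames(counts))][1])
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stopf("counts must be non-negative integers")
  storage.mode(counts) <- "double"  # keeps exact integers, avoids overflow
  if (!is.null(feature_type)) {
    missing <- setdiff(rownames(counts), names(feature_type))
    if (length(missing))
      stopf("no feature type for: %s", paste(utils::head(missing, 3), collapse = ", "))
    feature_type <- feature_type[rownames(counts)]
    bad <- setdiff(unique(feature_type), FEATURE_TYPES)
    if (length(bad)) stopf("unknown feature type: %s", bad[1])
  }
  structure(list(counts = counts, feature_type = feature_type),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$feature_type)) {
    tt <- table(x$feature_type)
    cat("  feature types:",
        paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

as_counts <- function(x) {
  if (inherits(x, "count_matrix")) x$counts
  else if (is.matrix(x)) x
  else stopf("expected a count_matrix or matrix")
}

#' Read a feature-by-sample count table
#'
#' The expected layout is tab-separated: first column feature ids, header row
#' of sample ids, integer cells. Values are preserved exactly; row and column
#' order are kept.
#'
#' @param path file path (plain or gzip).
#' @return a [count_matrix()] without feature types (attach them with
#'   [attach_feature_types()]).
#' @export
read_count_table <- function(path) {
  lines <- read_tsv_lines(path)
  if (length(lines) < 1L) stopf("%s: empty file", path)
  fields <- split_fields(lines)
  header <- fields[[1L]]
  samples <- header[-1L]
  ncol_expect <- length(header)
  body <- fields[-1L]
  n <- length(body)
  widths <- lengths(body)
  if (any(widths != ncol_expect))
    stopf("%s: ragged row at line %d (expected %d fields, got %d)",
          path, which(widths != ncol_expect)[1] + 1L, ncol_expect,
          widths[widths != ncol_expect][1])
  ids <- vapply(body, `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stopf("%s: duplicate feature id '%s' at line %d", path,
          ids[duplicated(ids)][1], which(duplicated(ids))[1] + 1L)
  cells <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
  bad <- !grepl("^[0-9]+$", cells)
  if (any(bad)) {
    idx <- which(bad)[1]
    stopf("%s: non-integer count '%s' at line %d", path,
          cells[idx], (idx - 1L) %/% length(samples) + 2L)
  }
  mat <- matrix(as.numeric(cells), nrow = n, ncol = length(samples),
                byrow = TRUE, dimnames = list(ids, samples))
  count_matrix(mat)
}

#' Attach feature types to a count matrix
#'
#' @param x a [count_matrix()].
#' @param type_table either a named character vector (feature -> type) or a
#'   data frame with columns `feature` and `type`.
#' @return the count matrix with `feature_type` populated.
#' @export
attach_feature_types <- function(x, type_table) {
  counts <- as_counts(x)
  if (is.data.frame(type_table)) {
    if (!all(c("feature", "type") %in% names(type_table)))
      stopf("type table needs columns 'feature' and 'type'")
    type_table <- stats::setNames(as.character(type_table$type),
                                  as.character(type_table$feature))
  }
  count_matrix(counts, type_table)
}

#' Write a count matrix as TSV
#' @param x a [count_matrix()] or plain matrix.
#' @param path output path.
#' @export
write_count_table <- function(x, path) {
  counts <- as_counts(x)
  df <- data.frame(feature = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

SAMPLE_COLUMNS <- c("sample_id", "stage", "cell_line", "replicate", "batch", "library")

#' Read a sample metadata table
#'
#' Required columns: `sample_id`, `stage`, `cell_line`, `replicate`, `batch`,
#' `library` (one of `mrna`, `mirna`). Stages must come from the declared set.
#'
#' @param path TSV path.
#' @param stages allowed stage labels, in biological order.
#' @return a data frame with one row per sample.
#' @export
read_sample_table <- function(path, stages = c("0", "2", "3")) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  missing <- setdiff(SAMPLE_COLUMNS, names(df))
  if (length(missing)) stopf("%s: missing column '%s'", path, missing[1])
  validate_sample_table(df, stages)
  df
}

validate_sample_table <- function(df, stages = c("0", "2", "3")) {
  if (anyDuplicated(df$sample_id))
    stopf("duplicate sample id: %s", df$sample_id[duplicated(df$sample_id)][1])
  bad_stage <- setdiff(unique(df$stage), as.character(stages))
  if (length(bad_stage)) stopf("unknown stage label: %s", bad_stage[1])
  bad_lib <- setdiff(unique(df$library), c("mrna", "mirna"))
  if (length(bad_lib)) stopf("unknown library type: %s", bad_lib[1])
  invisible(df)
}

#' Write a sample table as TSV
#' @param samples sample data frame.
#' @param path output path.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

interaction_layouts <- list(
  targetscan = c(regulator = "mirna", target = "gene", score = "total_context_score"),
  mirtarbase = c(regulator = "mirna", target = "gene", evidence = "experiments"),
  trrust     = c(regulator = "tf", target = "gene"),
  fantom5    = c(regulator = "tf", target = "gene"),
  encode     = c(regulator = "tf", target = "gene")
)

#' Read a regulator-target interaction table
#'
#' Supported dialects and their required columns:
#' \describe{
#'   \item{targetscan}{`mirna`, `gene`, `total_context_score` (numeric)}
#'   \item{mirtarbase}{`mirna`, `gene`, `experiments` (free-text evidence)}
#'   \item{trrust, fantom5, encode}{`tf`, `gene` (extra columns ignored)}
#' }
#' No filtering happens at read time; score/evidence filters belong to the
#' database builders ([build_mirna_target_db()], [build_tf_target_db()]).
#'
#' @param path TSV path.
#' @param dialect one of `"targetscan"`, `"mirtarbase"`, `"trrust"`,
#'   `"fantom5"`, `"encode"`.
#' @return data frame with columns `regulator`, `target`, `source`, `score`,
#'   `evidence` (the latter two `NA` where the dialect lacks them).
#' @export
read_interaction_table <- function(path, dialect) {
  if (!dialect %in% INTERACTION_SOURCES)
    stopf("unknown interaction dialect '%s'", dialect)
  layout <- interaction_layouts[[dialect]]
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  missing <- setdiff(unname(layout), names(df))
  if (length(missing)) stopf("%s: missing column '%s'", path, missing[1])
  out <- data.frame(
    regulator = df[[layout[["regulator"]]]],
    target = df[[layout[["target"]]]],
    source = rep(dialect, nrow(df)),
    score = if ("score" %in% names(layout)) {
      s <- suppressWarnings(as.numeric(df[[layout[["score"]]]]))
      if (anyNA(s)) stopf("%s: non-numeric %s", path, layout[["score"]])
      s
    } else NA_real_,
    evidence = if ("evidence" %in% names(layout)) df[[layout[["evidence"]]]]
               else NA_character_,
    stringsAsFactors = FALSE
  )
  out
}

#' Write interaction records in a named dialect
#' @param records data frame as returned by [read_interaction_table()].
#' @param path output path.
#' @param dialect dialect to serialize as.
#' @export
write_interaction_table <- function(records, path, dialect) {
  if (!dialect %in% INTERACTION_SOURCES)
    stopf("unknown interaction dialect '%s'", dialect)
  layout <- interaction_layouts[[dialect]]
  df <- stats::setNames(
    data.frame(records$regulator, records$target, stringsAsFactors = FALSE),
    c(layout[["regulator"]], layout[["target"]]))
  if ("score" %in% names(layout)) df[[layout[["score"]]]] <- records$score
  if ("evidence" %in% names(layout)) df[[layout[["evidence"]]]] <- records$evidence
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member ids.
#'
#' @param path GMT path.
#' @return a `gene_set_collection`: list with `sets` (named list of character
#'   vectors) and `description` (named character vector).
#' @export
read_gene_sets <- function(path) {
  lines <- read_tsv_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- split_fields(lines)
  short <- lengths(fields) < 3L
  if (any(short))
    stopf("%s: gene set with empty member list at line %d", path, which(short)[1])
  names_ <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(names_))
    stopf("%s: duplicate set name '%s'", path, names_[duplicated(names_)][1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  desc <- vapply(fields, `[`, character(1), 2L)
  structure(list(sets = stats::setNames(sets, names_),
                 description = stats::setNames(desc, names_)),
            class = "gene_set_collection")
}

#' Write a gene-set collection in GMT format
#' @param collection a `gene_set_collection` or named list of character vectors.
#' @param path output path.
#' @export
write_gene_sets <- function(collection, path) {
  if (inherits(collection, "gene_set_collection")) {
    sets <- collection$sets
    desc <- collection$description
  } else {
    sets <- collection
    desc <- stats::setNames(rep("", length(sets)), names(sets))
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, median size %d\n",
              length(x$sets), as.integer(stats::median(lengths(x$sets)))))
  invisible(x)
}

#' Read a protein-protein interaction edge table (STRING dialect)
#'
#' Expected columns: `protein_a`, `protein_b`, `combined_score`. Scores are
#' accepted on either the 0-1000 integer scale or the 0-1 real scale
#' (auto-detected from the maximum value) and stored as 0-1000. Self-edges are
#' rejected; duplicate undirected edges are collapsed keeping the maximum
#' score; endpoints are stored in canonical (sorted) order.
#'
#' @param path TSV path.
#' @return a `ppi_network` data frame with columns `protein_a`, `protein_b`,
#'   `combined_score`.
#' @export
read_ppi_edges <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c("character", "character", "numeric"))
  needed <- c("protein_a", "protein_b", "combined_score")
  missing <- setdiff(needed, names(df))
  if (length(missing)) stopf("%s: missing column '%s'", path, missing[1])
  ppi_network(df$protein_a, df$protein_b, df$combined_score)
}

#' Construct a PPI network from edge vectors
#'
#' @param protein_a,protein_b endpoint ids.
#' @param combined_score STRING-style combined scores, 0-1000 integers or
#'   0-1 reals (auto-detected).
#' @return a `ppi_network` data frame.
#' @export
ppi_network <- function(protein_a, protein_b, combined_score) {
  if (length(protein_a) == 0L) {
    out <- data.frame(protein_a = character(), protein_b = character(),
                      combined_score = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("ppi_network", "data.frame")
    return(out)
  }
  score <- combined_score
  if (any(!is.finite(score) | score < 0)) stopf("PPI scores must be finite and >= 0")
  if (max(score) <= 1) score <- round(score * 1000)
  if (any(score > 1000)) stopf("PPI combined_score out of range (max %s)", max(score))
  if (any(protein_a == protein_b))
    stopf("self-edge not allowed: %s", protein_a[protein_a == protein_b][1])
  a <- pmin(protein_a, protein_b)
  b <- pmax(protein_a, protein_b)
  key <- paste(a, b, sep = "\r")
  keep <- !duplicated(key)
  score_max <- tapply(score, key, max)[key[keep]]
  out <- data.frame(protein_a = a[keep], protein_b = b[keep],
                    combined_score = as.numeric(score_max),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ppi_network", "data.frame")
  out
}

#' Write a PPI edge table as TSV
#' @param network a `ppi_network`.
#' @param path output path.
#' @export
write_ppi_edges <- function(network, path) {
  utils::write.table(as.data.frame(network), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
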