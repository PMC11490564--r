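#' ASV count table
#'
#' Container for a samples x ASVs table of non-negative integer read counts
#' from one kingdom (16S-like prokaryote or 18S-like eukaryote fraction).
#' Rows are samples ordered by sampling day, columns are ASVs.
#'
#' @param counts Integer matrix, samples x ASVs, with unique row and column
#'   names. Every sample must have at least one read.
#' @param kingdom `"prokaryote"` or `"eukaryote"`.
#' @return An object of class `count_table`: a list with elements `counts`
#'   and `kingdom`.
#' @export
count_table <- function(counts, kingdom = c("prokaryote", "eukaryote")) {
  kingdom <- match.arg(kingdom)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  x <- structure(list(counts = counts, kingdom = kingdom),
                 class = "count_table")
  validate_count_table(x)
  x
}

#' Validate a count table
#'
#' Checks the `count_table` invariants: non-negative integral counts, unique
#' sample and ASV ids, and positive per-sample totals.
#'
#' @param x A `count_table`.
#' @return `x`, invisibly; stops with an informative error otherwise.
#' @export
validate_count_table <- function(x) {
  stopifnot(inherits(x, "count_table"))
  m <- x$counts
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("count table needs sample (row) and ASV (column) names")
  if (anyDuplicated(rownames(m))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(m))) stop("duplicate ASV ids")
  if (any(m < 0)) stop("negative counts")
  if (any(m != round(m))) stop("non-integer counts")
  tot <- rowSums(m)
  if (any(tot <= 0))
    stop("samples with zero total reads: ",
         paste(rownames(m)[tot <= 0], collapse = ", "))
  invisible(x)
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %s: %d samples x %d ASVs, depth %s-%s\n",
              x$kingdom, nrow(x$counts), ncol(x$counts),
              format(min(rowSums(x$counts))), format(max(rowSums(x$counts)))))
  invisible(x)
}

#' Sample ids of a count table
#' @param x A `count_table`.
#' @return Character vector of sample ids (row order = day order).
#' @export
sample_ids <- function(x) rownames(x$counts)

#' ASV ids of a count table
#' @param x A `count_table`.
#' @return Character vector of ASV ids.
#' @export
asv_ids <- function(x) colnames(x$counts)

#' Per-sample relative abundances
#' @param x A `count_table`.
#' @return Matrix of row-closed relative abundances.
#' @export
rel_abundance <- function(x) {
  m <- x$counts
  m / rowSums(m)
}

#' Read a count table from TSV
#'
#' Expects a header line whose first field names the sample-id column and the
#' remaining fields are ASV ids; one row per sample.
#'
#' @param path Path to the TSV file.
#' @param kingdom Kingdom tag for the resulting table.
#' @return A `count_table`.
#' @export
read_count_tsv <- function(path, kingdom = c("prokaryote", "eukaryote")) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  count_table(m, match.arg(kingdom))
}

#' Read a count table from a BIOM-style JSON file
#'
#' Accepts the dense JSON BIOM layout (`rows` = observations/ASVs,
#' `columns` = samples, `data` = observation x sample matrix), as written
#' by the common QIIME-era tools.
#'
#' @param path Path to the BIOM JSON file.
#' @param kingdom Kingdom tag for the resulting table.
#' @return A `count_table`.
#' @export
read_count_biom <- function(path, kingdom = c("prokaryote", "eukaryote")) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(b$rows) || is.null(b$columns) || is.null(b$data))
    stop("not a BIOM-style JSON table")
  m <- if (identical(b$matrix_type, "sparse")) {
    idx <- if (is.matrix(b$data)) b$data
           else matrix(unlist(b$data), ncol = 3, byrow = TRUE)
    out <- matrix(0, length(b$rows$id), length(b$columns$id))
    out[cbind(idx[, 1] + 1, idx[, 2] + 1)] <- idx[, 3]   # 0-based indices
    out
  } else {
    as.matrix(b$data)
  }
  dimnames(m) <- list(b$rows$id, b$columns$id)
  count_table(t(m), match.arg(kingdom))     # BIOM rows are ASVs
}

#' Write a count table to TSV
#'
#' @param x A `count_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_tsv <- function(x, path) {
  df <- data.frame(sample_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata from CSV
#'
#' Requires at least `sample_id` and `day` columns; a `stage` column is added
#' from [assign_stage()] when absent. Days must be strictly increasing.
#'
#' @param path Path to the CSV file.
#' @return A data frame with one row per sample.
#' @export
read_env_csv <- function(path) {
  env <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "day") %in% names(env)))
    stop("metadata needs 'sample_id' and 'day' columns")
  if (is.unsorted(env$day, strictly = TRUE))
    stop("days must be strictly increasing")
  if (is.null(env$stage)) env$stage <- assign_stage(env$day)
  env$stage <- factor(env$stage,
                      levels = c("floccular", "intermediate", "granular"))
  env
}

#' Write per-sample metadata to CSV
#' @param env Metadata data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_env_csv <- function(env, path) {
  utils::write.csv(env, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load and cross-validate a dataset triple
#'
#' Reads a count table (TSV), a rooted phylogeny (Newick) and per-sample
#' metadata (CSV), and checks that the tree tips cover every ASV and the
#' metadata rows match the samples. Samples are returned in day order and
#' ASV columns in tree tip order (deterministic ordering).
#'
#' @param table_path Count-table TSV path.
#' @param tree_path Newick tree path.
#' @param env_path Metadata CSV path.
#' @param kingdom Kingdom tag for the count table.
#' @return A list with elements `table` (`count_table`), `tree`
#'   (`ape::phylo`) and `env` (data frame).
#' @export
load_dataset <- function(table_path, tree_path, env_path,
                         kingdom = c("prokaryote", "eukaryote")) {
  kingdom <- match.arg(kingdom)
  tab <- if (grepl("\\.(biom|json)$", table_path, ignore.case = TRUE))
    read_count_biom(table_path, kingdom)
  else read_count_tsv(table_path, kingdom)
  tree <- ape::read.tree(tree_path)
  env <- read_env_csv(env_path)
  missing_tips <- setdiff(asv_ids(tab), tree$tip.label)
  if (length(missing_tips))
    stop("ASVs absent from the tree: ", paste(missing_tips, collapse = ", "))
  if (!setequal(env$sample_id, sample_ids(tab)))
    stop("metadata samples do not match count-table samples")
  env <- env[order(env$day), , drop = FALSE]
  m <- tab$counts[as.character(env$sample_id), , drop = FALSE]
  m <- m[, intersect(tree$tip.label, colnames(m)), drop = FALSE]
  list(table = count_table(m, kingdom), tree = tree, env = env)
}

#' Rarefy a count table to even depth
#'
#' Subsamples every sample without replacement to exactly `depth` reads
#' (the study design rarefies the 16S and 18S tables to their own depths).
#'
#' @param table A `count_table`.
#' @param depth Target reads per sample; every sample total must reach it.
#' @param seed Integer seed for reproducible subsampling.
#' @return A rarefied `count_table` whose rows all sum to `depth`.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  validate_count_table(table)
  tot <- rowSums(table$counts)
  low <- tot < depth
  if (any(low))
    stop("samples below rarefaction depth ", depth, ": ",
         paste(rownames(table$counts)[low], collapse = ", "))
  m <- with_seed(seed, vegan::rrarefy(table$counts, depth))
  count_table(m, table$kingdom)
}

#' Filter ASVs on prevalence and overall relative abundance
#'
#' Retains ASVs detected (count > 0) in at least `min_prevalence` of samples
#' and whose overall relative abundance reaches `min_rel_abundance`. The
#' overall share is the ASV total over the grand total (`"pooled"`, default)
#' or the mean of its per-sample shares (`"mean"`).
#'
#' @param table A `count_table`.
#' @param min_prevalence Minimum occupancy fraction (default 0.10).
#' @param min_rel_abundance Minimum overall share (default 0.001, i.e. 0.1%).
#' @param abundance_mode `"pooled"` or `"mean"` denominator convention.
#' @return The filtered `count_table` (same samples, fewer ASVs).
#' @export
filter_prevalence_abundance <- function(table, min_prevalence = 0.10,
                                        min_rel_abundance = 0.001,
                                        abundance_mode = c("pooled", "mean")) {
  abundance_mode <- match.arg(abundance_mode)
  m <- table$counts
  prev <- colMeans(m > 0)
  share <- switch(abundance_mode,
                  pooled = colSums(m) / sum(m),
                  mean = colMeans(m / rowSums(m)))
  keep <- prev >= min_prevalence & share >= min_rel_abundance
  if (!any(keep))
    stop("prevalence/abundance filter removed every ASV")
  count_table(m[, keep, drop = FALSE], table$kingdom)
}

#' Assign granulation stage from sampling day
#'
#' Maps days since reactor start to the three granulation stages: floccular
#' (day 0 up to the first boundary), intermediate, and granular (from the
#' second boundary on). Defaults follow days 0-15 / 16-115 / 116-343.
#'
#' @param day Numeric vector of days (>= 0).
#' @param boundaries Length-2 numeric: last floccular day and last
#'   intermediate day (default `c(15, 115)`).
#' @return Factor with levels `floccular`, `intermediate`, `granular`.
#' @export
assign_stage <- function(day, boundaries = c(15, 115)) {
  if (any(day < 0)) stop("negative day")
  stopifnot(length(boundaries) == 2, boundaries[1] < boundaries[2])
  cut(day, breaks = c(-Inf, boundaries, Inf),
      labels = c("floccular", "intermediate", "granular"))
}
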