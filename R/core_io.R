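# Count-table and metadata I/O, validation, rarefaction and aggregation.
#
# A count table is a plain integer matrix, samples in rows, taxa in columns,
# with unique dimnames. Metadata is a data.frame with one row per sample.

GROUP_LEVELS <- c("AE", "AS", "control")
SAMPLE_TYPE_LEVELS <- c("baseline", "nonexacerbation", "exacerbation", "control")

#' Validate a count table
#'
#' Checks the invariants every downstream step relies on: a numeric matrix of
#' non-negative integral counts with unique, non-empty sample and taxon
#' identifiers.
#'
#' @param x matrix to validate, samples in rows, taxa in columns.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_count_table <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("count table must be a numeric matrix (samples x taxa)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("count table must carry sample ids (rownames) and taxon ids (colnames)")
  dup_s <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_s))
    stop("duplicated sample id(s): ", paste(dup_s, collapse = ", "))
  dup_t <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_t))
    stop("duplicated taxon id(s): ", paste(dup_t, collapse = ", "))
  bad <- which(is.na(x) | x < 0 | x != round(x), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("negative, missing or non-integer count at sample '",
         rownames(x)[bad[1, 1]], "', taxon '", colnames(x)[bad[1, 2]], "'")
  }
  invisible(x)
}

#' Read a count table from TSV
#'
#' Expects a tab-separated file with a header of taxon ids and sample ids in
#' the first column (or the transpose with `taxa_as_rows = TRUE`). The
#' orientation is normalised to samples x taxa.
#'
#' @param path path to a TSV file.
#' @param taxa_as_rows set `TRUE` when the file stores taxa in rows.
#' @return validated integer matrix, samples x taxa.
#' @export
read_count_table <- function(path, taxa_as_rows = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count table needs an id column plus at least one data column")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cell(s) in count table ", path)
  rownames(m) <- ids
  if (taxa_as_rows) m <- t(m)
  storage.mode(m) <- "double"
  validate_count_table(m)
  storage.mode(m) <- "integer"
  m
}

#' Write a count table to TSV
#'
#' @param x count (or composition) matrix, samples x taxa.
#' @param path output path.
#' @param id_column header for the sample-id column.
#' @export
write_count_table <- function(x, path, id_column = "sample_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate sample metadata
#'
#' Enforces the longitudinal-design invariants: required columns present,
#' controlled vocabularies for `group` and `sample_type`, strictly increasing
#' `collection_order` within subject, exactly one sample per control subject,
#' and the baseline sample (where labelled) sitting first in its subject's
#' series.
#'
#' @param meta data.frame with one row per sample.
#' @return the metadata sorted by (subject_id, collection_order).
#' @export
validate_metadata <- function(meta) {
  required <- c("sample_id", "subject_id", "collection_order", "group", "sample_type")
  missing <- setdiff(required, colnames(meta))
  if (length(missing))
    stop("metadata is missing required column(s): ", paste(missing, collapse = ", "))
  dup <- unique(meta$sample_id[duplicated(meta$sample_id)])
  if (length(dup)) stop("duplicated sample id(s) in metadata: ", paste(dup, collapse = ", "))
  bad_g <- setdiff(unique(meta$group), GROUP_LEVELS)
  if (length(bad_g))
    stop("unknown group value(s): ", paste(bad_g, collapse = ", "),
         " (allowed: ", paste(GROUP_LEVELS, collapse = ", "), ")")
  bad_t <- setdiff(unique(meta$sample_type), SAMPLE_TYPE_LEVELS)
  if (length(bad_t))
    stop("unknown sample_type value(s): ", paste(bad_t, collapse = ", "),
         " (allowed: ", paste(SAMPLE_TYPE_LEVELS, collapse = ", "), ")")
  if (any(is.na(meta$collection_order)))
    stop("collection_order contains missing values")
  meta <- meta[order(meta$subject_id, meta$collection_order), , drop = FALSE]
  rownames(meta) <- NULL
  for (sub in unique(meta$subject_id)) {
    rows <- meta[meta$subject_id == sub, , drop = FALSE]
    if (any(diff(rows$collection_order) <= 0))
      stop("collection_order not strictly increasing for subject '", sub, "'")
    if (rows$group[1] == "control" && nrow(rows) != 1)
      stop("control subject '", sub, "' has ", nrow(rows), " samples; exactly 1 expected")
    is_base <- rows$sample_type == "baseline"
    if (any(is_base) && !is_base[1])
      stop("baseline sample of subject '", sub,
           "' does not have the minimum collection_order")
  }
  meta
}

#' Read sample metadata from TSV
#'
#' @param path path to a TSV file with a header row.
#' @return validated data.frame sorted by (subject_id, collection_order).
#' @export
read_metadata <- function(path) {
  meta <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_metadata(meta)
}

#' Write sample metadata to TSV
#' @param meta metadata data.frame.
#' @param path output path.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy map (ASV to genus) from a two-column TSV
#'
#' @param path TSV with columns `asv_id` and `genus` (header required).
#' @return named character vector: names are ASV ids, values genus labels.
#' @export
read_taxonomy_map <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("taxonomy map needs two columns (asv_id, genus)")
  dup <- unique(df[[1]][duplicated(df[[1]])])
  if (length(dup)) stop("ASV(s) mapped more than once: ", paste(dup, collapse = ", "))
  map <- as.character(df[[2]])
  map[is.na(map) | map == ""] <- "unclassified"
  names(map) <- as.character(df[[1]])
  map
}

#' Drop rare taxa
#'
#' Removes taxa whose total count across all samples falls below `min_total`
#' (default 2, i.e. singletons and absent taxa are dropped).
#'
#' @param x count matrix, samples x taxa.
#' @param min_total minimum column total required to keep a taxon.
#' @return count matrix with rare taxa removed; sample order unchanged.
#' @export
filter_rare_taxa <- function(x, min_total = 2) {
  validate_count_table(x)
  if (min_total < 0) stop("min_total must be >= 0")
  keep <- colSums(x) >= min_total
  x[, keep, drop = FALSE]
}

#' Rarefy samples to an even depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric draw) down to exactly `depth` reads, so library-size
#' differences cannot masquerade as diversity differences. A single seeded
#' draw is used; samples already at `depth` are returned unchanged.
#'
#' @param x count matrix, samples x taxa.
#' @param depth target depth; default is the minimum sample total, which
#'   retains every sample.
#' @param seed integer seed making the draw reproducible.
#' @return rarefied count matrix; every row sums to `depth`.
#' @export
rarefy_counts <- function(x, depth = min(rowSums(x)), seed) {
  validate_count_table(x)
  if (missing(seed)) stop("rarefy_counts requires an explicit seed")
  totals <- rowSums(x)
  low <- rownames(x)[totals < depth]
  if (length(low))
    stop("sample(s) below rarefaction depth ", depth, ": ",
         paste(low, collapse = ", "))
  set.seed(seed)
  out <- x
  todo <- totals > depth
  if (any(todo)) {
    # rrarefy warns whenever the smallest count exceeds 1; depth validity is
    # already enforced above, so the heuristic warning is noise here
    sub <- suppressWarnings(vegan::rrarefy(x[todo, , drop = FALSE], depth))
    out[todo, ] <- sub
  }
  storage.mode(out) <- "integer"
  out
}

#' Aggregate an ASV-level table to genus level
#'
#' Sums columns sharing a genus label under the supplied taxonomy map; the
#' grand total is conserved.
#'
#' @param x count matrix, samples x ASVs.
#' @param map named character vector mapping every ASV id to a genus label.
#' @return count matrix, samples x genera.
#' @export
aggregate_to_genus <- function(x, map) {
  validate_count_table(x)
  unmapped <- setdiff(colnames(x), names(map))
  if (length(unmapped))
    stop("taxa missing from taxonomy map: ", paste(unmapped, collapse = ", "))
  genus <- factor(map[colnames(x)])
  agg <- t(rowsum(t(x), group = genus))
  storage.mode(agg) <- "integer"
  rownames(agg) <- rownames(x)
  agg
}

#' Convert counts to relative abundances
#'
#' @param x count matrix, samples x taxa; every sample total must be positive.
#' @return row-normalised matrix of fractions; each row sums to 1.
#' @export
to_relative <- function(x) {
  totals <- rowSums(x)
  zero <- rownames(x)[totals == 0]
  if (length(zero))
    stop("zero-total sample(s): ", paste(zero, collapse = ", "))
  x / totals
}

#' Validate a composition table
#'
#' @param x matrix of fractions, samples x taxa.
#' @return `x`, invisibly, if every row sums to 1 within 1e-9.
#' @export
validate_composition <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("composition must be a numeric matrix")
  if (any(x < 0 | x > 1)) stop("composition entries must lie in [0, 1]")
  dev <- abs(rowSums(x) - 1)
  if (any(dev > 1e-9))
    stop("composition row(s) do not sum to 1: ",
         paste(rownames(x)[dev > 1e-9], collapse = ", "))
  invisible(x)
}
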