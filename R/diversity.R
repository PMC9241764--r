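# Alpha diversity, pairwise dissimilarity and principal-coordinate ordination.

#' Alpha diversity per sample
#'
#' Shannon diversity (base-2 by default, so values are in bits), Pielou's
#' evenness J = H / log(observed taxa) and the observed-taxon count. Pielou
#' is reported as `NA` for single-taxon samples, where evenness is undefined.
#'
#' @param x count (or composition) matrix, samples x taxa; no zero-total rows.
#' @param base logarithm base for the Shannon index.
#' @return data.frame with columns `sample_id`, `shannon`, `pielou`,
#'   `observed`.
#' @export
alpha_diversity <- function(x, base = 2) {
  totals <- rowSums(x)
  if (any(totals == 0))
    stop("zero-total sample(s): ", paste(rownames(x)[totals == 0], collapse = ", "))
  h <- vegan::diversity(x, index = "shannon", base = base)
  s <- vegan::specnumber(x)
  j <- ifelse(s > 1, h / log(s, base = base), NA_real_)
  data.frame(sample_id = rownames(x), shannon = as.numeric(h),
             pielou = as.numeric(j), observed = as.integer(s),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(x, y) = 1 - 2 * sum(min(x_i, y_i)) / (sum x + sum y). Computed on
#' equal-depth counts or on relative abundances (equivalent at equal depth).
#'
#' @param x count or composition matrix, samples x taxa.
#' @return symmetric matrix of dissimilarities in [0, 1], zero diagonal.
#' @export
bray_curtis <- function(x) {
  totals <- rowSums(x)
  if (any(totals == 0))
    stop("zero-total sample(s): ", paste(rownames(x)[totals == 0], collapse = ", "))
  as.matrix(vegan::vegdist(x, method = "bray"))
}

#' Jaccard distance matrix on presence/absence
#'
#' J(x, y) = 1 - |A intersect B| / |A union B| over the sets of taxa present
#' (count > 0) in each sample.
#'
#' @param x count matrix, samples x taxa.
#' @return symmetric matrix of distances in [0, 1], zero diagonal.
#' @export
jaccard_distance <- function(x) {
  pres <- rowSums(x > 0)
  if (any(pres == 0))
    stop("sample(s) with empty presence set: ",
         paste(rownames(x)[pres == 0], collapse = ", "))
  as.matrix(vegan::vegdist(x, method = "jaccard", binary = TRUE))
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centres -0.5 * D^2, eigendecomposes, and scales eigenvectors by the
#' square roots of the positive eigenvalues. Negative eigenvalues are
#' reported but never used for coordinates; an optional Cailliez correction
#' adds the constant that removes them.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param k number of axes to return (at most the number of positive
#'   eigenvalues).
#' @param correction `"none"` (default, raw eigenvalues) or `"cailliez"`.
#' @return list with `coordinates` (samples x k), `eigenvalues` (descending,
#'   all of them) and `proportion_explained` (per returned axis, over the
#'   positive eigenvalues).
#' @export
pcoa_ordination <- function(d, k = 2, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12)))
    stop("distance matrix is not symmetric")
  n <- nrow(d)
  if (k > n - 1) stop("k must be <= n - 1")
  fit <- stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE,
                         add = correction == "cailliez")
  eig <- sort(fit$eig, decreasing = TRUE)
  pos <- eig[eig > sqrt(.Machine$double.eps) * max(abs(eig))]
  coords <- fit$points
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 1)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  prop <- eig[seq_len(ncol(coords))] / sum(pos)
  list(coordinates = coords, eigenvalues = eig,
       proportion_explained = prop)
}

#' Geometric mean of positive values
#'
#' @param v vector of strictly positive values.
#' @return exp(mean(log(v))).
#' @export
geometric_mean <- function(v) {
  if (any(is.na(v)) || any(v <= 0))
    stop("geometric_mean requires strictly positive values")
  exp(mean(log(v)))
}

#' Write a distance matrix as square TSV
#' @param d symmetric matrix with sample-id dimnames.
#' @param path output path.
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(sample_id = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square TSV distance matrix
#' @param path path written by [write_distance_matrix()].
#' @return symmetric numeric matrix.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
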