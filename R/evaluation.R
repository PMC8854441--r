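#' Arcsinh transform raw ion counts
#'
#' Standard CyTOF variance-stabilizing transform: `asinh(x / cofactor)`,
#' cofactor 5 by default. Refuses to transform data already marked
#' arcsinh; [inverse_arcsinh_transform] undoes it.
#'
#' @param sample a [cyto_sample] with `transform_state == "raw"`.
#' @param cofactor positive scaling divisor (default 5).
#' @return transformed [cyto_sample].
#' @export
arcsinh_transform <- function(sample, cofactor = 5) {
  stopifnot(inherits(sample, "cyto_sample"), cofactor > 0)
  if (sample$transform_state == "arcsinh")
    stop("sample '", sample$sample_id,
         "' is already arcsinh-transformed; refusing to transform twice")
  cyto_sample(asinh(sample$values / cofactor), sample$channel_labels,
              sample_id = sample$sample_id, batch_id = sample$batch_id,
              transform_state = "arcsinh")
}

#' @rdname arcsinh_transform
#' @export
inverse_arcsinh_transform <- function(sample, cofactor = 5) {
  stopifnot(inherits(sample, "cyto_sample"), cofactor > 0)
  if (sample$transform_state == "raw")
    stop("sample '", sample$sample_id, "' is not arcsinh-transformed")
  cyto_sample(sinh(sample$values) * cofactor, sample$channel_labels,
              sample_id = sample$sample_id, batch_id = sample$batch_id,
              transform_state = "raw")
}

#' Positivity threshold in transformed space
#'
#' Converts a raw-count positivity threshold (10 counts by convention)
#' into arcsinh space: `asinh(counts / cofactor)`.
#'
#' @param counts raw-count threshold (default 10).
#' @param cofactor arcsinh cofactor (default 5).
#' @return threshold on the arcsinh scale.
#' @export
positivity_threshold <- function(counts = 10, cofactor = 5) {
  asinh(counts / cofactor)
}

#' Rectangular gating of cell subpopulations
#'
#' Assigns each cell to the first population (in gate order) whose every
#' channel range contains the cell's value; cells matching no population
#' are `"UNASSIGNED"`. Gates are given in the same (arcsinh) space as the
#' data; use [positivity_threshold] to express count thresholds.
#'
#' @param sample a [cyto_sample].
#' @param gates data.frame with columns `population`, `channel`, `lower`,
#'   `upper` (one row per channel range; several rows per population).
#' @return list with `labels` (character, per cell) and `frequencies`
#'   (named vector, per-population counts / total cells; sums to <= 1).
#' @export
rectangular_gate <- function(sample, gates) {
  stopifnot(inherits(sample, "cyto_sample"))
  need <- c("population", "channel", "lower", "upper")
  stopifnot(all(need %in% names(gates)))
  if (any(gates$lower >= gates$upper))
    stop("every gate range needs lower < upper")
  missing <- setdiff(unique(gates$channel), sample$channel_labels)
  if (length(missing))
    stop("gate references channel(s) absent from sample: ",
         paste(missing, collapse = ", "))
  pops <- unique(gates$population)
  x <- sample$values
  labels <- rep("UNASSIGNED", nrow(x))
  unassigned <- rep(TRUE, nrow(x))
  for (p in pops) {
    g <- gates[gates$population == p, , drop = FALSE]
    inside <- unassigned
    for (r in seq_len(nrow(g))) {
      v <- x[, g$channel[r]]
      inside <- inside & v >= g$lower[r] & v <= g$upper[r]
    }
    labels[inside] <- p
    unassigned <- unassigned & !inside
  }
  freqs <- vapply(pops, function(p) mean(labels == p), numeric(1L))
  list(labels = labels, frequencies = freqs)
}

#' Root-mean-square deviation between two vectors
#'
#' @param a,b numeric vectors of equal length.
#' @return `sqrt(mean((a - b)^2))`.
#' @export
rmsd <- function(a, b) {
  if (length(a) != length(b))
    stop("length mismatch: ", length(a), " vs ", length(b))
  stopifnot(length(a) >= 1L)
  sqrt(mean((a - b)^2))
}

#' Squared Pearson correlation
#'
#' @param a,b numeric vectors of equal length (>= 2); `a` and `b` must
#'   have nonzero variance.
#' @return R-squared in \[0, 1\].
#' @export
r_squared <- function(a, b) {
  if (length(a) != length(b))
    stop("length mismatch: ", length(a), " vs ", length(b))
  stopifnot(length(a) >= 2L)
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("zero variance; correlation undefined")
  stats::cor(a, b)^2
}

#' Cosine-similarity sample network
#'
#' Builds the thresholded similarity network over sample mean-expression
#' vectors: nodes are samples, an (undirected) edge joins every pair
#' whose cosine similarity is at least `threshold`.
#'
#' @param sample_means numeric matrix, samples in rows (rownames = sample
#'   ids), channels in columns; or a named list of mean vectors.
#' @param threshold similarity threshold (default 0.9, inclusive).
#' @param groups optional character vector of group (e.g. cohort) labels
#'   per sample, for per-group mean degree.
#' @return list of class `similarity_network`: `nodes`, `edges`
#'   (data.frame source/target/weight), `degree` (named vector),
#'   `similarity` (full matrix), `threshold`, and `group_mean_degree`
#'   when `groups` is given.
#' @export
similarity_network <- function(sample_means, threshold = 0.9,
                               groups = NULL) {
  if (is.list(sample_means) && !is.data.frame(sample_means))
    sample_means <- do.call(rbind, sample_means)
  stopifnot(is.matrix(sample_means), nrow(sample_means) >= 2L)
  ids <- rownames(sample_means)
  if (is.null(ids)) ids <- paste0("sample", seq_len(nrow(sample_means)))
  norms <- sqrt(rowSums(sample_means^2))
  if (any(norms == 0))
    stop("zero mean-expression vector for sample(s): ",
         paste(ids[norms == 0], collapse = ", "))
  sim <- tcrossprod(sample_means / norms)
  dimnames(sim) <- list(ids, ids)
  pairs <- which(upper.tri(sim) & sim >= threshold, arr.ind = TRUE)
  edges <- data.frame(source = ids[pairs[, 1L]], target = ids[pairs[, 2L]],
                      weight = sim[pairs], stringsAsFactors = FALSE)
  degree <- stats::setNames(integer(length(ids)), ids)
  if (nrow(edges)) {
    tab <- table(c(edges$source, edges$target))
    degree[names(tab)] <- as.integer(tab)
  }
  out <- list(nodes = ids, edges = edges, degree = degree,
              similarity = sim, threshold = threshold)
  if (!is.null(groups)) {
    stopifnot(length(groups) == length(ids))
    out$group_mean_degree <- tapply(as.numeric(degree), groups, mean)
  }
  class(out) <- "similarity_network"
  out
}

#' Write a similarity network as an edge list
#'
#' Tab-separated `source target weight`, loadable by standard graph
#' tools.
#' @param network a `similarity_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Mean intra- and inter-batch cell-to-cell distance
#'
#' Mean Euclidean distance over all within-batch cell pairs and over all
#' between-batch cell pairs, optionally after subsampling each batch
#' (default 2000 cells, reproducible via `seed`). Well-normalized data
#' show inter close to intra.
#'
#' @param samples list of [cyto_sample]s on a shared channel set; batch
#'   identity is taken from each sample's `batch_id`.
#' @param subsample cells retained per batch (`Inf` disables).
#' @param seed RNG seed for the subsampling.
#' @return list with `intra`, `inter` (scalars; `intra` is `NA` with a
#'   warning when no batch has two cells) and `n_cells_used`.
#' @export
batch_distance_summary <- function(samples, subsample = 2000, seed = 1L) {
  check_shared_channels(samples)
  batch <- unlist(lapply(samples, function(s)
    rep(s$batch_id, nrow(s$values))))
  x <- do.call(rbind, lapply(samples, `[[`, "values"))
  if (length(unique(batch)) < 2L)
    stop("need cells from at least two batches")
  if (is.finite(subsample)) {
    keep <- integer(0L)
    set.seed(seed)
    for (b in unique(batch)) {
      idx <- which(batch == b)
      if (length(idx) > subsample) idx <- sort(sample(idx, subsample))
      keep <- c(keep, idx)
    }
    x <- x[keep, , drop = FALSE]
    batch <- batch[keep]
  }
  d <- as.matrix(stats::dist(x))
  same <- outer(batch, batch, "==")
  ut <- upper.tri(d)
  intra_pairs <- ut & same
  inter_pairs <- ut & !same
  intra <- if (any(intra_pairs)) mean(d[intra_pairs]) else {
    warning("no batch contributes two or more cells; intra-batch ",
            "distance undefined")
    NA_real_
  }
  list(intra = intra, inter = mean(d[inter_pairs]),
       n_cells_used = nrow(x))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same cells or
#' samples; 1 for identical partitions up to relabeling, ~0 for random
#' agreement. Computed with [mclust::adjustedRandIndex].
#'
#' @param labels_a,labels_b vectors of equal length (>= 2).
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("length mismatch: ", length(labels_a), " vs ", length(labels_b))
  stopifnot(length(labels_a) >= 2L)
  mclust::adjustedRandIndex(labels_a, labels_b)
}
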