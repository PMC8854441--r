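#' PCA-based non-redundancy score (NRS)
#'
#' Ranks marker variability across samples. For every sample, PCA is run
#' on the column-centered (not scaled) expression matrix; a marker's
#' score in that sample is the sum over the top `k` components of the
#' component variance times the absolute loading of the marker on that
#' component. The NRS of a marker is the average of this quantity over
#' samples. Low NRS identifies stable channels suitable as generalized
#' anchors. Absolute loadings make the score invariant to the arbitrary
#' sign of principal components.
#'
#' @param samples list of [cyto_sample]s on a shared channel set.
#' @param k number of principal components (default 3).
#' @return data.frame of class `nrs_table`: `channel`, `nrs`, `rank`
#'   (1 = most stable), `selected` (all `FALSE`; see
#'   [select_stable_channels]); attribute `n_samples`.
#' @export
compute_nrs <- function(samples, k = 3L) {
  stopifnot(length(samples) >= 1L, k >= 1L)
  labs <- check_shared_channels(samples)
  m <- length(labs)
  if (k > m) stop("k (", k, ") exceeds the number of channels (", m, ")")
  per_sample <- vapply(samples, function(s) {
    if (nrow(s$values) < k + 1L)
      stop("sample '", s$sample_id, "' has ", nrow(s$values),
           " cells; need at least k+1 = ", k + 1L, " for ", k, " PCs")
    if (all(apply(s$values, 2L, stats::var) == 0))
      stop("sample '", s$sample_id, "' has zero variance in every channel")
    pc <- stats::prcomp(s$values, center = TRUE, scale. = FALSE)
    kk <- min(k, length(pc$sdev))
    load_abs <- abs(pc$rotation[, seq_len(kk), drop = FALSE])
    as.numeric(load_abs %*% pc$sdev[seq_len(kk)]^2)
  }, numeric(m))
  scores <- if (is.matrix(per_sample)) rowMeans(per_sample) else per_sample
  ord <- order(scores, labs)
  tab <- data.frame(channel = labs, nrs = scores,
                    rank = match(seq_len(m), ord),
                    selected = FALSE, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  attr(tab, "n_samples") <- length(samples)
  class(tab) <- c("nrs_table", "data.frame")
  tab
}

#' Select stable channels from an NRS table
#'
#' Either the `n` lowest-NRS channels or all channels with NRS strictly
#' below `cutoff`; exactly one of the two must be given. Ties are broken
#' by channel name; the result is ordered by ascending NRS.
#'
#' @param nrs an `nrs_table` from [compute_nrs].
#' @param n number of stable channels to select (default 3 when neither
#'   argument is given).
#' @param cutoff strict NRS upper bound.
#' @return character vector of channel names, most stable first. The
#'   updated table is attached as attribute `"nrs_table"`.
#' @export
select_stable_channels <- function(nrs, n = NULL, cutoff = NULL) {
  if (!is.null(n) && !is.null(cutoff))
    stop("give exactly one of 'n' and 'cutoff', not both")
  if (is.null(n) && is.null(cutoff)) n <- 3L
  ord <- order(nrs$nrs, nrs$channel)
  if (!is.null(n)) {
    if (n < 1L || n > nrow(nrs))
      stop("n must be between 1 and the panel size (", nrow(nrs), ")")
    picked <- ord[seq_len(n)]
  } else {
    picked <- ord[nrs$nrs[ord] < cutoff]
    if (length(picked) == 0L)
      stop("cutoff ", cutoff, " selects zero channels (minimum NRS is ",
           format(min(nrs$nrs)), ")")
  }
  nrs$selected <- seq_len(nrow(nrs)) %in% picked
  out <- nrs$channel[picked]
  attr(out, "nrs_table") <- nrs
  out
}

#' Stable-channel bulk meanshift normalization
#'
#' Uses low-variance shared channels as generalized anchors. The
#' universal stable reference is the per-channel mean of the stable
#' channels over the concatenation of all samples; each sample is then
#' shifted by a single scalar — the difference between the mean of its
#' own stable-channel MSIs and the mean of the universal stable MSIs —
#' applied to every channel (meanshift bulk restricted to stable
#' channels).
#'
#' @param samples list of [cyto_sample]s on a shared channel set.
#' @param stable character vector of stable channel names (subset of the
#'   shared channels), e.g. from [select_stable_channels].
#' @return list with `samples` (normalized, input order), `audits`
#'   (per-sample `norm_audit`s; the scalar shift replicated across
#'   channels), and `universal_stable_msi` (named vector).
#' @export
normalize_stable <- function(samples, stable) {
  stopifnot(length(samples) >= 1L)
  labs <- check_shared_channels(samples)
  if (length(stable) == 0L) stop("empty stable channel set")
  missing <- setdiff(stable, labs)
  if (length(missing))
    stop("stable channel(s) absent from samples: ",
         paste(missing, collapse = ", "))
  pooled <- do.call(rbind, lapply(samples, function(s)
    s$values[, stable, drop = FALSE]))
  universal_msi <- colMeans(pooled)
  u_bulk <- mean(universal_msi)

  m <- length(labs)
  res <- lapply(samples, function(s) {
    s_bulk <- mean(colMeans(s$values[, stable, drop = FALSE]))
    shift <- s_bulk - u_bulk
    out <- s$values - shift
    audit <- structure(
      list(mode = "MSFTB-stable",
           shift = stats::setNames(rep(shift, m), labs),
           scale = stats::setNames(rep(1, m), labs),
           offset = stats::setNames(rep(0, m), labs),
           bl_slope = NA_real_,
           anchor_id = paste(stable, collapse = "+"),
           batch_id = s$batch_id),
      class = "norm_audit")
    list(sample = cyto_sample(out, labs, sample_id = s$sample_id,
                              batch_id = s$batch_id,
                              transform_state = s$transform_state),
         audit = audit)
  })
  list(samples = lapply(res, `[[`, "sample"),
       audits = lapply(res, `[[`, "audit"),
       universal_stable_msi = universal_msi)
}

#' Write an NRS table as CSV
#'
#' @param nrs an `nrs_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_nrs <- function(nrs, path) {
  utils::write.csv(as.data.frame(nrs), path, row.names = FALSE)
  invisible(path)
}
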