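#' Per-channel summary statistics of a sample
#'
#' Computes the mean signal intensity (MSI), variance and standard
#' deviation of every channel. Variance uses the population convention
#' (denominator = number of cells), matching the definition of the
#' universal reference statistics.
#'
#' @param sample a [cyto_sample].
#' @return object of class `channel_stats`: list with `msi`, `var`, `sd`
#'   (named numeric vectors), `n_cells` and `channel_labels`.
#' @export
channel_stats <- function(sample) {
  stopifnot(inherits(sample, "cyto_sample"))
  x <- sample$values
  n <- nrow(x)
  msi <- colMeans(x)
  v <- colMeans(sweep(x, 2L, msi, "-")^2)   # population variance
  structure(
    list(msi = msi, var = v, sd = sqrt(v), n_cells = n,
         channel_labels = sample$channel_labels),
    class = "channel_stats")
}

#' Universal reference from pooled anchors
#'
#' Pools the single-cell data of all per-batch anchors by row-wise
#' concatenation and returns the channel statistics of the pooled matrix.
#' Anchors with more cells therefore contribute proportionally more
#' (cell-weighted), which differs from averaging per-anchor means when
#' cell counts are unequal.
#'
#' @param anchors list of [cyto_sample]s sharing identical channel labels.
#' @return a [channel_stats] object.
#' @export
build_universal_reference <- function(anchors) {
  stopifnot(length(anchors) >= 1L)
  labs <- check_shared_channels(anchors)
  pooled <- do.call(rbind, lapply(anchors, `[[`, "values"))
  channel_stats(cyto_sample(pooled, labs, sample_id = "universal",
                            batch_id = "universal",
                            transform_state = anchors[[1L]]$transform_state))
}

#' Select the generalized anchor of one batch
#'
#' Among the anchor-flagged records of a batch, the sample whose
#' perturbation condition ranks earliest in `condition_priority` wins
#' (healthy basal samples are preferred over stimulation conditions);
#' conditions absent from the priority list rank last, and ties are
#' broken by lexicographic filename.
#'
#' @param metadata data.frame from [load_metadata].
#' @param batch_id the batch to select an anchor for.
#' @param condition_priority character vector, most preferred first.
#' @return the selected metadata row (one-row data.frame).
#' @export
select_anchor <- function(metadata, batch_id,
                          condition_priority = "basal") {
  rows <- metadata[metadata$batch_id == batch_id, , drop = FALSE]
  if (nrow(rows) == 0L) stop("unknown batch_id: '", batch_id, "'")
  rows <- rows[rows$is_anchor, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("no anchor sample in batch '", batch_id, "'")
  rank <- match(rows$condition, condition_priority,
                nomatch = length(condition_priority) + 1L)
  rows <- rows[order(rank, rows$filename), , drop = FALSE]
  rows[1L, , drop = FALSE]
}

#' Bead-like slope between anchor and reference
#'
#' Through-origin least-squares slope of the universal reference MSI on
#' the anchor MSI across channels: `sum(u*h) / sum(h^2)`. Multiplying the
#' anchor by this slope gives the best single-scalar fit to the
#' reference, mimicking bead-gain rescaling.
#'
#' @param anchor,universal [channel_stats] on the same channel set.
#' @return scalar slope.
#' @export
bl_slope <- function(anchor, universal) {
  stopifnot(identical(anchor$channel_labels, universal$channel_labels))
  h <- anchor$msi; u <- universal$msi
  denom <- sum(h^2)
  if (denom == 0) stop("anchor MSI is identically zero; slope undefined")
  sum(u * h) / denom
}

#' The five anchor normalization functions
#'
#' Applies one normalization mode to a target sample using its batch
#' anchor's statistics and the universal reference. All five modes are
#' per-channel affine maps chosen so that the *anchor* is moved onto the
#' reference:
#' \describe{
#'   \item{MSFT}{meanshift: subtract the per-channel anchor-minus-reference
#'     mean difference.}
#'   \item{MSFTB}{meanshift bulk: subtract one scalar, the difference of
#'     the channel-averaged means.}
#'   \item{VAR}{variance: meanshift, then scale each channel by
#'     `sd_universal / sd_anchor`.}
#'   \item{Z}{z-score: standardize against the anchor, rescale to the
#'     reference sd and recenter on the reference mean.}
#'   \item{BL}{bead-like: multiply all channels by the single
#'     through-origin regression slope ([bl_slope]).}
#' }
#'
#' @param target a [cyto_sample] from the anchor's batch.
#' @param anchor [channel_stats] of the batch's generalized anchor.
#' @param universal [channel_stats] of the universal reference.
#' @param mode one of `"MSFT"`, `"MSFTB"`, `"VAR"`, `"Z"`, `"BL"`.
#' @return list with `sample` (normalized [cyto_sample]) and `audit`
#'   (class `norm_audit`): the exact per-channel `shift`, `scale` and
#'   `offset` applied, as `out = (in - shift) * scale + offset`, plus
#'   `bl_slope` for BL.
#' @export
apply_normalization <- function(target, anchor, universal,
                                mode = c("MSFT", "MSFTB", "VAR", "Z", "BL")) {
  mode <- match.arg(mode)
  stopifnot(inherits(target, "cyto_sample"))
  if (!identical(target$channel_labels, anchor$channel_labels) ||
      !identical(target$channel_labels, universal$channel_labels))
    stop("target, anchor and universal reference must share channel set ",
         "and order")
  m <- length(anchor$msi)
  zero <- rep(0, m); one <- rep(1, m)
  slope <- NA_real_

  if (mode %in% c("VAR", "Z")) {
    bad <- anchor$sd == 0
    if (any(bad))
      stop("zero anchor standard deviation under ", mode,
           " for channel(s): ",
           paste(anchor$channel_labels[bad], collapse = ", "))
  }

  d <- anchor$msi - universal$msi
  params <- switch(mode,
    MSFT  = list(shift = d, scale = one, offset = zero),
    MSFTB = list(shift = rep(mean(anchor$msi) - mean(universal$msi), m),
                 scale = one, offset = zero),
    VAR   = list(shift = d, scale = universal$sd / anchor$sd,
                 offset = zero),
    Z     = list(shift = anchor$msi, scale = universal$sd / anchor$sd,
                 offset = universal$msi),
    BL    = {
      slope <- bl_slope(anchor, universal)
      list(shift = zero, scale = rep(slope, m), offset = zero)
    })

  out <- sweep(sweep(target$values, 2L, params$shift, "-"),
               2L, params$scale, "*")
  if (any(params$offset != 0)) out <- sweep(out, 2L, params$offset, "+")

  audit <- structure(
    list(mode = mode,
         shift = stats::setNames(params$shift, target$channel_labels),
         scale = stats::setNames(params$scale, target$channel_labels),
         offset = stats::setNames(params$offset, target$channel_labels),
         bl_slope = slope,
         anchor_id = attr(anchor, "sample_id"),
         batch_id = target$batch_id),
    class = "norm_audit")

  list(sample = cyto_sample(out, target$channel_labels,
                            sample_id = target$sample_id,
                            batch_id = target$batch_id,
                            transform_state = target$transform_state),
       audit = audit)
}

#' Replay a recorded normalization
#'
#' Applies the affine transform captured in a `norm_audit` to a raw
#' sample, reproducing [apply_normalization] output exactly.
#'
#' @param target a [cyto_sample].
#' @param audit a `norm_audit`.
#' @return normalized [cyto_sample].
#' @export
replay_audit <- function(target, audit) {
  stopifnot(inherits(audit, "norm_audit"))
  out <- sweep(sweep(target$values, 2L, audit$shift, "-"),
               2L, audit$scale, "*")
  if (any(audit$offset != 0)) out <- sweep(out, 2L, audit$offset, "+")
  cyto_sample(out, target$channel_labels, sample_id = target$sample_id,
              batch_id = target$batch_id,
              transform_state = target$transform_state)
}

#' Batch-normalize a full dataset with healthy-control anchors
#'
#' Selects one generalized anchor per batch ([select_anchor]), builds the
#' universal reference from the pooled anchors
#' ([build_universal_reference]), then applies the same per-batch
#' transform to every sample of the batch, the anchor included.
#'
#' @param samples list of homogenized [cyto_sample]s; each `sample_id`
#'   must appear in `metadata$filename` (with or without the `.fcs`
#'   extension).
#' @param metadata data.frame from [load_metadata].
#' @param mode normalization mode, see [apply_normalization].
#' @param condition_priority passed to [select_anchor].
#' @return list with `samples` (normalized, input order), `audits` (one
#'   `norm_audit` per batch, named by batch), and `universal`
#'   ([channel_stats]).
#' @export
normalize_dataset <- function(samples, metadata,
                              mode = c("MSFT", "MSFTB", "VAR", "Z", "BL"),
                              condition_priority = "basal") {
  mode <- match.arg(mode)
  check_shared_channels(samples)
  ids <- vapply(samples, `[[`, character(1L), "sample_id")
  md_key <- tools::file_path_sans_ext(metadata$filename)
  idx <- match(tools::file_path_sans_ext(ids), md_key)
  if (anyNA(idx))
    stop("sample(s) missing from metadata: ",
         paste(ids[is.na(idx)], collapse = ", "))
  batch_of <- metadata$batch_id[idx]
  batches <- unique(batch_of)

  anchor_rows <- lapply(batches, function(b)
    select_anchor(metadata, b, condition_priority))
  anchor_samples <- lapply(anchor_rows, function(r) {
    j <- which(idx == match(r$filename, metadata$filename))
    if (length(j) != 1L)
      stop("anchor file '", r$filename, "' of batch '", r$batch_id,
           "' not among the supplied samples")
    samples[[j]]
  })
  universal <- build_universal_reference(anchor_samples)

  audits <- stats::setNames(vector("list", length(batches)), batches)
  out <- vector("list", length(samples))
  for (bi in seq_along(batches)) {
    b <- batches[bi]
    a_stats <- channel_stats(anchor_samples[[bi]])
    attr(a_stats, "sample_id") <- anchor_samples[[bi]]$sample_id
    members <- which(batch_of == b)
    for (j in members) {
      res <- apply_normalization(samples[[j]], a_stats, universal, mode)
      out[[j]] <- res$sample
      if (is.null(audits[[b]])) {
        res$audit$anchor_id <- anchor_samples[[bi]]$sample_id
        audits[[b]] <- res$audit
      }
    }
  }
  list(samples = out, audits = audits, universal = universal)
}

#' Write per-batch normalization audits as CSV
#'
#' @param audits list of `norm_audit` objects (from [normalize_dataset]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_audits <- function(audits, path) {
  rows <- do.call(rbind, lapply(audits, function(a) {
    data.frame(batch_id = a$batch_id, mode = a$mode,
               anchor_id = if (is.null(a$anchor_id)) NA else a$anchor_id,
               bl_slope = a$bl_slope,
               channel = names(a$shift),
               shift = unname(a$shift), scale = unname(a$scale),
               offset = unname(a$offset), stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
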