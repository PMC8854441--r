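#' Single-sample expression matrix
#'
#' A `cyto_sample` holds the cells-by-channels expression matrix of one
#' mass cytometry sample together with its channel labels, sample and
#' batch identity, and the transformation state of the values (raw ion
#' counts or arcsinh-transformed expression).
#'
#' @param values numeric matrix, cells in rows, channels in columns. All
#'   values must be finite.
#' @param channel_labels character vector of unique channel names, one per
#'   column of `values`.
#' @param sample_id single string identifying the sample.
#' @param batch_id single string identifying the batch (barcode plate).
#' @param transform_state `"raw"` for ion counts, `"arcsinh"` for
#'   transformed expression.
#'
#' @return An object of class `cyto_sample`: a list with elements
#'   `values`, `channel_labels`, `sample_id`, `batch_id`,
#'   `transform_state`.
#' @examples
#' s <- cyto_sample(matrix(rnorm(30), 10, 3), c("CD3", "CD19", "CD45"),
#'                  sample_id = "s1", batch_id = "plate1")
#' n_cells(s)
#' @export
cyto_sample <- function(values, channel_labels,
                        sample_id = "sample", batch_id = "batch",
                        transform_state = c("arcsinh", "raw")) {
  transform_state <- match.arg(transform_state)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (nrow(values) < 1L)
    stop("a cyto_sample must contain at least one cell")
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != ncol(values))
    stop("length of 'channel_labels' (", length(channel_labels),
         ") does not match column count (", ncol(values), ")")
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique; duplicated: ",
         paste(unique(channel_labels[duplicated(channel_labels)]),
               collapse = ", "))
  if (!all(is.finite(values)))
    stop("non-finite values in expression matrix of sample '",
         sample_id, "'")
  colnames(values) <- channel_labels
  structure(
    list(values = values,
         channel_labels = channel_labels,
         sample_id = as.character(sample_id)[1L],
         batch_id = as.character(batch_id)[1L],
         transform_state = transform_state),
    class = "cyto_sample")
}

#' @rdname cyto_sample
#' @param x a `cyto_sample`.
#' @export
n_cells <- function(x) {
  stopifnot(inherits(x, "cyto_sample"))
  nrow(x$values)
}

#' @rdname cyto_sample
#' @export
n_channels <- function(x) {
  stopifnot(inherits(x, "cyto_sample"))
  ncol(x$values)
}

#' @export
print.cyto_sample <- function(x, ...) {
  cat(sprintf("cyto_sample '%s' (batch '%s'): %d cells x %d channels [%s]\n",
              x$sample_id, x$batch_id, nrow(x$values), ncol(x$values),
              x$transform_state))
  cat("channels:", paste(utils::head(x$channel_labels, 8L), collapse = ", "),
      if (length(x$channel_labels) > 8L) "..." else "", "\n")
  invisible(x)
}

# shared label check used across multi-sample operations
check_shared_channels <- function(samples) {
  labs <- samples[[1L]]$channel_labels
  for (s in samples[-1L]) {
    if (!identical(s$channel_labels, labs))
      stop("channel labels differ between samples '",
           samples[[1L]]$sample_id, "' and '", s$sample_id, "'")
  }
  labs
}
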