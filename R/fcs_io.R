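#' Read an FCS 3.0/3.1 file
#'
#' Minimal reader for list-mode FCS 3.0/3.1 files with a single data set.
#' Supports float (`$DATATYPE F`), double (`D`) and integer (`I`, uniform
#' 8/16/32-bit widths) data in either byte order. Channel labels are taken
#' from `$PnS` when present and non-empty, falling back to `$PnN`.
#'
#' @param path path to an FCS file.
#' @param sample_id sample identifier; defaults to the file name without
#'   extension.
#' @param batch_id batch identifier recorded on the returned object.
#' @param transform_state the transformation state of the stored values;
#'   FCS carries no such flag, so the caller states it (default `"raw"`).
#' @return a [cyto_sample]. The full keyword table is attached as
#'   attribute `"keywords"`.
#' @export
read_fcs <- function(path, sample_id = NULL, batch_id = "batch",
                     transform_state = c("raw", "arcsinh")) {
  transform_state <- match.arg(transform_state)
  if (!file.exists(path)) stop("FCS file not found: ", path)
  fsize <- file.info(path)$size
  if (fsize < 58) stop("malformed FCS header (file too short): ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  version <- rawToChar(readBin(con, "raw", 6L))
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("unsupported FCS version '", version, "' in ", path)
  readBin(con, "raw", 4L)                       # reserved spaces
  offs <- suppressWarnings(as.numeric(vapply(1:6, function(i)
    rawToChar(readBin(con, "raw", 8L)), character(1L))))
  if (any(is.na(offs[1:2])))
    stop("malformed FCS header (unreadable TEXT offsets): ", path)
  text_begin <- offs[1L]; text_end <- offs[2L]
  if (text_end <= text_begin || text_end >= fsize)
    stop("malformed FCS header (TEXT segment out of bounds): ", path)

  seek(con, text_begin)
  text_raw <- readBin(con, "raw", text_end - text_begin + 1L)
  kw <- parse_fcs_text(text_raw)

  kv <- function(key, required = TRUE) {
    v <- kw[[toupper(key)]]
    if (is.null(v) && required)
      stop("required FCS keyword ", key, " missing in ", path)
    v
  }
  n_par <- as.integer(kv("$PAR"))
  n_tot <- as.integer(kv("$TOT"))
  dtype <- toupper(trimws(kv("$DATATYPE")))
  mode  <- toupper(trimws(kv("$MODE")))
  if (mode != "L") stop("only list-mode ($MODE L) FCS supported, got ", mode)
  byteord <- gsub("\\s", "", kv("$BYTEORD"))
  endian <- if (byteord %in% c("1,2,3,4", "1,2")) "little"
            else if (byteord %in% c("4,3,2,1", "2,1")) "big"
            else stop("unsupported $BYTEORD '", byteord, "'")

  data_begin <- offs[3L]; data_end <- offs[4L]
  if (is.na(data_begin) || data_begin == 0) {
    data_begin <- as.numeric(kv("$BEGINDATA"))
    data_end <- as.numeric(kv("$ENDDATA"))
  }
  if (data_end >= fsize)
    stop("truncated FCS file: DATA segment ends at byte ", data_end,
         " but file has only ", fsize, " bytes: ", path)

  bits <- vapply(seq_len(n_par),
                 function(i) as.integer(kv(sprintf("$P%dB", i))), integer(1L))
  bytes_expected <- switch(dtype,
    F = 4L * n_par * n_tot,
    D = 8L * n_par * n_tot,
    I = sum(bits) %/% 8L * n_tot,
    stop("unsupported $DATATYPE '", dtype, "'"))
  bytes_avail <- data_end - data_begin + 1
  if (bytes_avail != bytes_expected)
    stop("DATA segment size (", bytes_avail, " bytes) does not match $PAR=",
         n_par, " x $TOT=", n_tot, " x $DATATYPE ", dtype,
         " (expected ", bytes_expected, " bytes): ", path)

  seek(con, data_begin)
  vals <- switch(dtype,
    F = readBin(con, "numeric", n_par * n_tot, size = 4L, endian = endian),
    D = readBin(con, "numeric", n_par * n_tot, size = 8L, endian = endian),
    I = {
      ub <- unique(bits)
      if (length(ub) != 1L || !ub %in% c(8L, 16L, 32L))
        stop("integer FCS data requires a uniform $PnB of 8, 16 or 32 bits")
      readBin(con, "integer", n_par * n_tot, size = ub %/% 8L,
              signed = ub >= 32L, endian = endian)
    })
  mat <- matrix(as.numeric(vals), nrow = n_tot, ncol = n_par, byrow = TRUE)

  labels <- vapply(seq_len(n_par), function(i) {
    pns <- kw[[sprintf("$P%dS", i)]]
    if (!is.null(pns) && nzchar(trimws(pns))) trimws(pns)
    else {
      pnn <- kv(sprintf("$P%dN", i))
      trimws(pnn)
    }
  }, character(1L))

  if (is.null(sample_id))
    sample_id <- tools::file_path_sans_ext(basename(path))
  out <- cyto_sample(mat, labels, sample_id = sample_id, batch_id = batch_id,
                     transform_state = transform_state)
  attr(out, "keywords") <- kw
  out
}

# Split a raw TEXT segment into a named list of keyword values.
# The first byte is the delimiter; doubled delimiters inside values are
# unescaped by re-joining the empty tokens they produce.
parse_fcs_text <- function(text_raw) {
  txt <- rawToChar(text_raw)
  delim <- substr(txt, 1L, 1L)
  body <- substr(txt, 2L, nchar(txt))
  # drop the single trailing delimiter, keep escaped ones intact
  if (endsWith(body, delim)) body <- substr(body, 1L, nchar(body) - 1L)
  toks <- strsplit(body, delim, fixed = TRUE)[[1L]]
  merged <- character(0L)
  i <- 1L
  while (i <= length(toks)) {
    if (toks[i] == "" && length(merged) > 0L && i < length(toks)) {
      merged[length(merged)] <-
        paste0(merged[length(merged)], delim, toks[i + 1L])
      i <- i + 2L
    } else {
      merged <- c(merged, toks[i])
      i <- i + 1L
    }
  }
  if (length(merged) %% 2L != 0L)
    stop("malformed FCS TEXT segment: odd number of tokens")
  keys <- toupper(trimws(merged[seq(1L, length(merged), by = 2L)]))
  vals <- merged[seq(2L, length(merged), by = 2L)]
  stats::setNames(as.list(vals), keys)
}

#' Write a `cyto_sample` as FCS 3.1
#'
#' Writes a single-dataset FCS 3.1 file with `$DATATYPE D` (64-bit
#' little-endian doubles), so a write/read round trip is lossless.
#' `$PnN` and `$PnS` are both set to the channel label.
#'
#' @param sample a [cyto_sample].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(sample, path) {
  stopifnot(inherits(sample, "cyto_sample"))
  mat <- sample$values
  n_tot <- nrow(mat); n_par <- ncol(mat)
  delim <- "/"
  esc <- function(x) gsub(delim, paste0(delim, delim), x, fixed = TRUE)

  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BEGINDATA", "%BD%", "$ENDDATA", "%ED%",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "D",
          "$MODE", "L", "$NEXTDATA", "0",
          "$PAR", as.character(n_par), "$TOT", as.character(n_tot))
  for (i in seq_len(n_par)) {
    lab <- esc(sample$channel_labels[i])
    rng <- max(1, ceiling(max(abs(mat[, i])) + 1))
    kw <- c(kw,
            sprintf("$P%dB", i), "64",
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dN", i), lab,
            sprintf("$P%dS", i), lab,
            sprintf("$P%dR", i), format(rng, scientific = FALSE))
  }
  # fixed-width placeholders keep TEXT length independent of the offsets
  build_text <- function(bd, ed) {
    k <- kw
    k[k == "%BD%"] <- sprintf("%010d", bd)
    k[k == "%ED%"] <- sprintf("%010d", ed)
    paste0(delim, paste(k, collapse = delim), delim)
  }
  text_len <- nchar(build_text(0L, 0L), type = "bytes")
  header_len <- 58L
  text_begin <- header_len
  text_end <- text_begin + text_len - 1L
  data_begin <- text_end + 1L
  data_end <- data_begin + 8L * n_par * n_tot - 1L
  text_seg <- build_text(data_begin, data_end)

  fmt8 <- function(x) {
    s <- if (x > 99999999) "0" else format(x, scientific = FALSE)
    formatC(s, width = 8L, flag = " ")
  }
  header <- paste0("FCS3.1    ",
                   fmt8(text_begin), fmt8(text_end),
                   if (data_end > 99999999) paste0(fmt8(0), fmt8(0))
                   else paste0(fmt8(data_begin), fmt8(data_end)),
                   fmt8(0), fmt8(0))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text_seg), con)
  writeBin(as.numeric(t(mat)), con, size = 8L, endian = "little")
  invisible(path)
}
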