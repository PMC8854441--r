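#' Load a consensus antigen panel template
#'
#' The template drives panel homogenization: each entry pairs a regular
#' expression with the standardized antigen name it maps to. Entries are
#' matched in file order, first match wins, so more specific patterns
#' (e.g. CD45 before CD4) must come first. Patterns are Perl-compatible
#' (PCRE), so negative lookahead such as `CD4(?!5)` can be used to keep
#' prefixes apart; see `system.file("extdata", "example_panel.csv",
#' package = "cytanchor")` for an illustrative template.
#'
#' @param path CSV file with columns exactly
#'   `metal,antigen,pattern,standardized_name`.
#' @return data.frame of class `panel_template`.
#' @export
load_panel_template <- function(path) {
  tpl <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("metal", "antigen", "pattern", "standardized_name")
  missing <- setdiff(required, names(tpl))
  if (length(missing))
    stop("panel template is missing required column(s): ",
         paste(missing, collapse = ", "))
  tpl <- tpl[required]
  validate_panel_template(tpl)
}

#' @rdname load_panel_template
#' @param template data.frame with the four template columns (used to
#'   build a template programmatically).
#' @export
validate_panel_template <- function(template) {
  if (nrow(template) < 1L) stop("panel template is empty")
  if (anyDuplicated(template$standardized_name))
    stop("duplicated standardized_name in panel template: ",
         paste(unique(template$standardized_name[
           duplicated(template$standardized_name)]), collapse = ", "))
  for (p in template$pattern) {
    ok <- tryCatch({ suppressWarnings(grepl(p, "x", perl = TRUE)); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop("invalid regular expression in panel template: '", p, "'")
  }
  class(template) <- c("panel_template", "data.frame")
  template
}

#' Load a sample metadata table
#'
#' One row per FCS file, describing cohort, batch (barcode plate),
#' patient, perturbation condition and whether the sample is a healthy
#' anchor for its batch.
#'
#' @param path CSV with header columns exactly
#'   `filename,cohort,batch_id,patient_id,condition,is_anchor`.
#' @return data.frame with `is_anchor` parsed to logical.
#' @export
load_metadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("filename", "cohort", "batch_id", "patient_id",
                "condition", "is_anchor")
  missing <- setdiff(required, names(md))
  if (length(missing))
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "))
  md <- md[required]
  if (nrow(md) < 1L) stop("metadata table is empty")
  dup <- unique(md$filename[duplicated(md$filename)])
  if (length(dup))
    stop("duplicated filename(s) in metadata: ", paste(dup, collapse = ", "))
  flag <- tolower(trimws(md$is_anchor))
  if (!all(flag %in% c("true", "false", "1", "0")))
    stop("is_anchor must be one of true/false/1/0 (case-insensitive)")
  md$is_anchor <- flag %in% c("true", "1")
  md
}

#' Match one channel label against the panel template
#'
#' Patterns are tried in template order, case-insensitively; the
#' standardized name of the first matching entry is returned, or
#' `NA_character_` when no pattern matches (non-antigen channels such as
#' event length or barcode channels).
#'
#' @param label channel label string.
#' @param template a [load_panel_template] data.frame.
#' @return standardized name, or `NA_character_` for no match.
#' @export
match_channel_label <- function(label, template) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  for (i in seq_len(nrow(template))) {
    if (grepl(template$pattern[i], label, ignore.case = TRUE,
              perl = TRUE))
      return(template$standardized_name[i])
  }
  NA_character_
}

#' Homogenize heterogeneous panels to a consensus panel
#'
#' Every file's channel labels are standardized via the template; the
#' consensus panel is the set of standardized names matched in *all*
#' files, ordered as in the template. Channels that do not match, or whose
#' standardized name is not in the consensus, are dropped (and logged in
#' the report). Values of retained channels are untouched: homogenization
#' only selects and renames columns, so it is idempotent.
#'
#' @param samples list of [cyto_sample] objects.
#' @param template a [load_panel_template] data.frame.
#' @return list with `samples` (homogenized [cyto_sample]s, consensus
#'   panel in template order) and `report` (data.frame: sample_id,
#'   original_label, standardized_name with `"DROPPED"` for discarded
#'   channels, plus attribute `consensus`).
#' @export
homogenize_files <- function(samples, template) {
  stopifnot(length(samples) >= 1L)
  if (nrow(template) < 1L) stop("panel template is empty")

  matches <- lapply(samples, function(s) {
    m <- vapply(s$channel_labels, match_channel_label, character(1L),
                template = template, USE.NAMES = FALSE)
    hit <- !is.na(m)
    dup <- unique(m[hit][duplicated(m[hit])])
    if (length(dup)) {
      offenders <- s$channel_labels[!is.na(m) & m %in% dup]
      stop("ambiguous channels in sample '", s$sample_id, "': labels [",
           paste(offenders, collapse = ", "),
           "] map to the same standardized name(s): ",
           paste(dup, collapse = ", "))
    }
    m
  })

  matched_sets <- lapply(matches, function(m) m[!is.na(m)])
  consensus <- Reduce(intersect, matched_sets)
  # template order
  consensus <- template$standardized_name[
    template$standardized_name %in% consensus]
  if (length(consensus) == 0L)
    stop("consensus panel is empty: no standardized name matched in all ",
         length(samples), " file(s)")

  report <- do.call(rbind, Map(function(s, m) {
    std <- ifelse(!is.na(m) & m %in% consensus, m, "DROPPED")
    data.frame(sample_id = s$sample_id,
               original_label = s$channel_labels,
               standardized_name = std,
               stringsAsFactors = FALSE)
  }, samples, matches))
  rownames(report) <- NULL
  attr(report, "consensus") <- consensus

  out <- Map(function(s, m) {
    keep <- match(consensus, m)      # one source column per consensus name
    cyto_sample(s$values[, keep, drop = FALSE], consensus,
                sample_id = s$sample_id, batch_id = s$batch_id,
                transform_state = s$transform_state)
  }, samples, matches)

  list(samples = out, report = report)
}
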