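#' Configuration for synthetic multi-batch cohorts
#'
#' Describes a simulated multi-batch CyTOF-like study with known ground
#' truth: cells are drawn from a Gaussian-mixture of subpopulations in
#' arcsinh space, every batch carries one healthy anchor sample drawn
#' from a shared healthy mixture, and per-batch affine batch effects
#' (`x -> gamma_b * x + delta_b`, per channel) are applied to every
#' sample of the batch. Defaults emulate a small barcode-plate study:
#' 3 batches of 4 samples, 2000 cells, 20 channels, 3 subpopulations
#' with channel means in the 0.5-4.5 arcsinh range and within-population
#' sd 0.3, and additive batch offsets drawn from N(0, 0.5^2).
#'
#' @param n_batches,samples_per_batch,cells_per_sample,n_channels study
#'   dimensions; `samples_per_batch` counts the anchor.
#' @param population_freq mixing frequencies of the patient-sample
#'   populations (must sum to 1).
#' @param anchor_freq mixing frequencies of the shared healthy anchor
#'   mixture over the same populations.
#' @param population_sd within-population per-channel sd (arcsinh units).
#' @param delta_sd sd of the per-batch, per-channel additive offsets
#'   (used when `delta` is `NULL`).
#' @param delta optional `n_batches x n_channels` matrix of additive
#'   offsets; overrides `delta_sd`.
#' @param gamma optional `n_batches x n_channels` matrix (or length-
#'   `n_batches` vector) of multiplicative scales; default all 1.
#' @param n_stable_injected number of channels turned into near-constant
#'   "stable" channels (common mean across populations, sd
#'   `stable_sd`); they occupy the last channel positions.
#' @param stable_sd sd of injected stable channels.
#' @param channels channel names; default `MK01..MKnn`.
#' @param seed RNG seed; same seed gives bit-identical cohorts.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_batches = 3L, samples_per_batch = 4L,
                              cells_per_sample = 2000L, n_channels = 20L,
                              population_freq = c(0.5, 0.3, 0.2),
                              anchor_freq = c(0.6, 0.25, 0.15),
                              population_sd = 0.3,
                              delta_sd = 0.5, delta = NULL, gamma = NULL,
                              n_stable_injected = 0L, stable_sd = 0.01,
                              channels = sprintf("MK%02d", seq_len(n_channels)),
                              seed = 1L) {
  stopifnot(n_batches >= 1L, samples_per_batch >= 1L,
            cells_per_sample >= 1L, n_channels >= 1L,
            length(channels) == n_channels,
            length(anchor_freq) == length(population_freq),
            population_sd > 0, stable_sd > 0,
            n_stable_injected >= 0L, n_stable_injected <= n_channels)
  if (abs(sum(population_freq) - 1) > 1e-8 ||
      abs(sum(anchor_freq) - 1) > 1e-8)
    stop("population frequencies must sum to 1")
  if (any(population_freq < 0) || any(anchor_freq < 0))
    stop("population frequencies must be non-negative")
  if (!is.null(delta))
    stopifnot(is.matrix(delta), nrow(delta) == n_batches,
              ncol(delta) == n_channels)
  if (!is.null(gamma)) {
    if (!is.matrix(gamma))
      gamma <- matrix(gamma, n_batches, n_channels)
    stopifnot(nrow(gamma) == n_batches, ncol(gamma) == n_channels)
    if (any(gamma <= 0)) stop("gamma scales must be positive")
  }
  structure(list(
    n_batches = as.integer(n_batches),
    samples_per_batch = as.integer(samples_per_batch),
    cells_per_sample = as.integer(cells_per_sample),
    n_channels = as.integer(n_channels),
    population_freq = population_freq, anchor_freq = anchor_freq,
    population_sd = population_sd, delta_sd = delta_sd,
    delta = delta, gamma = gamma,
    n_stable_injected = as.integer(n_stable_injected),
    stable_sd = stable_sd, channels = channels,
    seed = as.integer(seed)), class = "simulation_config")
}

#' Simulate a multi-batch cohort with known ground truth
#'
#' Draws every sample from the Gaussian-mixture model described by a
#' [simulation_config], applies the per-batch affine batch effects, and
#' returns the samples together with the full ground truth (population
#' means/sds, per-cell population labels, the applied `delta`/`gamma`,
#' and which channels are injected stable channels). Anchors are drawn
#' from the shared healthy mixture *before* the batch transform, so the
#' batch effect is the only systematic cross-batch difference between
#' anchors.
#'
#' @param config a [simulation_config].
#' @param dir optional directory; when given, FCS 3.1 files plus
#'   `metadata.csv`, `panel.csv`, `cell_labels.csv` and
#'   `batch_effects.csv` are written there.
#' @return list with `samples` (list of arcsinh-state [cyto_sample]s),
#'   `metadata` (data.frame as accepted by [load_metadata]), and `truth`
#'   (list: `pop_means`, `pop_sds`, `delta`, `gamma`, `labels`,
#'   `stable_channels`).
#' @export
simulate_cohorts <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_pop <- length(config$population_freq)
  m <- config$n_channels

  # population channel means in arcsinh space, well separated
  pop_means <- matrix(stats::runif(n_pop * m, 0.5, 4.5), n_pop, m)
  pop_sds <- matrix(config$population_sd, n_pop, m)
  stable_idx <- integer(0L)
  if (config$n_stable_injected > 0L) {
    stable_idx <- seq.int(m - config$n_stable_injected + 1L, m)
    common <- stats::runif(length(stable_idx), 1, 3)
    pop_means[, stable_idx] <- matrix(common, n_pop, length(stable_idx),
                                      byrow = TRUE)
    pop_sds[, stable_idx] <- config$stable_sd
  }

  delta <- config$delta
  if (is.null(delta))
    delta <- matrix(stats::rnorm(config$n_batches * m, 0, config$delta_sd),
                    config$n_batches, m)
  gamma <- config$gamma
  if (is.null(gamma)) gamma <- matrix(1, config$n_batches, m)

  draw_sample <- function(freq) {
    pop <- sample.int(n_pop, config$cells_per_sample, replace = TRUE,
                      prob = freq)
    x <- matrix(stats::rnorm(config$cells_per_sample * m), ncol = m)
    x <- x * pop_sds[pop, , drop = FALSE] + pop_means[pop, , drop = FALSE]
    list(values = x, pop = pop)
  }

  samples <- list(); meta <- list(); labels <- list()
  for (b in seq_len(config$n_batches)) {
    batch <- sprintf("batch%d", b)
    for (j in seq_len(config$samples_per_batch)) {
      is_anchor <- j == 1L
      id <- if (is_anchor) sprintf("b%d_anchor", b)
            else sprintf("b%d_s%d", b, j - 1L)
      drawn <- draw_sample(if (is_anchor) config$anchor_freq
                           else config$population_freq)
      x <- sweep(sweep(drawn$values, 2L, gamma[b, ], "*"),
                 2L, delta[b, ], "+")
      samples[[id]] <- cyto_sample(x, config$channels, sample_id = id,
                                   batch_id = batch,
                                   transform_state = "arcsinh")
      labels[[id]] <- drawn$pop
      meta[[id]] <- data.frame(
        filename = paste0(id, ".fcs"), cohort = "synthetic",
        batch_id = batch,
        patient_id = if (is_anchor) "healthy" else sprintf("pt%d_%d", b, j),
        condition = if (is_anchor) "basal" else "stim",
        is_anchor = is_anchor, stringsAsFactors = FALSE)
    }
  }
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL
  truth <- list(pop_means = pop_means, pop_sds = pop_sds,
                delta = delta, gamma = gamma, labels = labels,
                stable_channels = config$channels[stable_idx])
  out <- list(samples = unname(samples), metadata = metadata, truth = truth)

  if (!is.null(dir)) write_cohort(out, dir)
  out
}

#' Write a simulated cohort to disk as a self-contained fixture
#'
#' Emits one FCS 3.1 file per sample plus `metadata.csv`, a matching
#' `panel.csv` template, per-cell `cell_labels.csv` and the applied
#' `batch_effects.csv`.
#'
#' @param cohort result of [simulate_cohorts].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$samples)
    write_fcs(s, file.path(dir, paste0(s$sample_id, ".fcs")))
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  channels <- cohort$samples[[1L]]$channel_labels
  utils::write.csv(default_panel_template(channels),
                   file.path(dir, "panel.csv"), row.names = FALSE)
  lab <- do.call(rbind, lapply(names(cohort$truth$labels), function(id)
    data.frame(sample_id = id,
               cell = seq_along(cohort$truth$labels[[id]]),
               population = cohort$truth$labels[[id]],
               stringsAsFactors = FALSE)))
  utils::write.csv(lab, file.path(dir, "cell_labels.csv"),
                   row.names = FALSE)
  be <- expand.grid(batch = seq_len(nrow(cohort$truth$delta)),
                    channel = channels, stringsAsFactors = FALSE)
  be$delta <- as.vector(cohort$truth$delta)
  be$gamma <- as.vector(cohort$truth$gamma)
  utils::write.csv(be, file.path(dir, "batch_effects.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Default synonym table and panel template for simulated channels
#'
#' `default_synonym_table` lists, per channel, label variants as they
#' occur in the wild (metal-prefixed, isotope-suffixed, lower-case);
#' `default_panel_template` builds the regex template that standardizes
#' any of those variants back to the plain channel name.
#'
#' @param channels character vector of standardized channel names.
#' @return named list of synonym vectors, resp. a `panel_template`.
#' @export
default_synonym_table <- function(channels) {
  stats::setNames(lapply(seq_along(channels), function(i) {
    ch <- channels[i]
    metal <- sprintf("%dY", 88L + i)
    c(ch, paste0(metal, "_", ch), paste0(metal, "Di ", ch), tolower(ch))
  }), channels)
}

#' @rdname default_synonym_table
#' @export
default_panel_template <- function(channels) {
  validate_panel_template(data.frame(
    metal = sprintf("%dY", 88L + seq_along(channels)),
    antigen = channels,
    pattern = channels,           # substring match, case-insensitive
    standardized_name = channels,
    stringsAsFactors = FALSE))
}

#' Randomly synonymize channel labels across files
#'
#' Replaces every channel label of every sample by a synonym drawn at
#' random from the table, producing the heterogeneous panels that
#' [homogenize_files] must resolve. Values are untouched.
#'
#' @param samples list of [cyto_sample]s.
#' @param synonyms named list: channel name -> character vector of
#'   admissible labels (see [default_synonym_table]).
#' @param seed RNG seed for the label assignment.
#' @return list of relabeled [cyto_sample]s.
#' @export
synonymize_labels <- function(samples, synonyms, seed = 1L) {
  set.seed(seed)
  lapply(samples, function(s) {
    missing <- setdiff(s$channel_labels, names(synonyms))
    if (length(missing))
      stop("channel(s) missing from synonym table: ",
           paste(missing, collapse = ", "))
    labs <- vapply(s$channel_labels, function(ch) {
      opts <- synonyms[[ch]]
      opts[sample.int(length(opts), 1L)]
    }, character(1L), USE.NAMES = FALSE)
    cyto_sample(s$values, labs, sample_id = s$sample_id,
                batch_id = s$batch_id,
                transform_state = s$transform_state)
  })
}
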