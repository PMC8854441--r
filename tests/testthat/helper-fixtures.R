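# Shared fixtures and independent oracles used across test files.

make_sample <- function(values, labels = NULL, id = "s", batch = "b",
                        state = "arcsinh") {
  values <- as.matrix(values)
  if (is.null(labels)) labels <- paste0("ch", seq_len(ncol(values)))
  cyto_sample(values, labels, sample_id = id, batch_id = batch,
              transform_state = state)
}

# small simulated cohort for fast tests
small_sim <- function(seed = 1L, cells = 300L, channels = 8L, ...) {
  simulate_cohorts(simulation_config(
    cells_per_sample = cells, n_channels = channels, seed = seed, ...))
}

# scalar-loop oracle for the five normalization functions: one cell and
# one channel at a time, straight from the formula definitions
oracle_normalize <- function(mat, a_msi, a_sd, u_msi, u_sd, mode) {
  m <- ncol(mat)
  out <- matrix(NA_real_, nrow(mat), m)
  bulk_a <- mean(a_msi); bulk_u <- mean(u_msi)
  slope <- sum(u_msi * a_msi) / sum(a_msi^2)
  for (i in seq_len(nrow(mat))) {
    for (j in seq_len(m)) {
      x <- mat[i, j]
      out[i, j] <- switch(mode,
        MSFT  = x - (a_msi[j] - u_msi[j]),
        MSFTB = x - (bulk_a - bulk_u),
        VAR   = (x - (a_msi[j] - u_msi[j])) * (u_sd[j] / a_sd[j]),
        Z     = (x - a_msi[j]) * (u_sd[j] / a_sd[j]) + u_msi[j],
        BL    = x * slope)
    }
  }
  out
}

# independent NRS oracle via explicit covariance eigendecomposition
oracle_nrs <- function(mats, k) {
  per <- sapply(mats, function(x) {
    cc <- scale(x, center = TRUE, scale = FALSE)
    ev <- eigen(stats::cov(cc), symmetric = TRUE)
    lam <- ev$values[seq_len(k)]        # PC variances, sample convention
    as.numeric(abs(ev$vectors[, seq_len(k), drop = FALSE]) %*% lam)
  })
  rowMeans(as.matrix(per))
}

# pair-counting adjusted Rand index from the contingency table
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(0)
  (sum_ij - expected) / (maxi - expected)
}

# cross-batch deviation of population-matched channel means: for every
# (population, channel), the mean absolute deviation of per-batch means
# from their cross-batch average, averaged over all (population, channel)
pop_batch_deviation <- function(samples, truth_labels) {
  batches <- vapply(samples, function(s) s$batch_id, character(1L))
  pops <- sort(unique(unlist(truth_labels)))
  devs <- c()
  for (p in pops) {
    bm <- sapply(unique(batches), function(b) {
      rows <- do.call(rbind, lapply(which(batches == b), function(i)
        samples[[i]]$values[truth_labels[[i]] == p, , drop = FALSE]))
      colMeans(rows)
    })                                   # channels x batches
    devs <- c(devs, rowMeans(abs(bm - rowMeans(bm))))
  }
  mean(devs)
}

# a minimal FCS 3.1 byte stream built by hand, independently of
# write_fcs: 2 channels x n events, float32, $P2S intentionally absent
hand_built_fcs <- function(path, values, tot_override = NULL) {
  stopifnot(ncol(values) == 2L)
  n <- nrow(values)
  tot <- if (is.null(tot_override)) n else tot_override
  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BEGINDATA", "%BD%", "$ENDDATA", "%ED%",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$NEXTDATA", "0", "$PAR", "2", "$TOT", as.character(tot),
          "$P1B", "32", "$P1E", "0,0", "$P1N", "Y89Di", "$P1S", "CD45",
          "$P1R", "10000",
          "$P2B", "32", "$P2E", "0,0", "$P2N", "Time", "$P2R", "10000")
  mk_text <- function(bd, ed) {
    k <- kw
    k[k == "%BD%"] <- sprintf("%08d", bd)
    k[k == "%ED%"] <- sprintf("%08d", ed)
    paste0("/", paste(k, collapse = "/"), "/")
  }
  tlen <- nchar(mk_text(0, 0))
  bd <- 58L + tlen
  ed <- bd + 4L * 2L * n - 1L
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    58L, 58L + tlen - 1L, bd, ed, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(mk_text(bd, ed)), con)
  writeBin(as.numeric(t(values)), con, size = 4L, endian = "little")
  path
}
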