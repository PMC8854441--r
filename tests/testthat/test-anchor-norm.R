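test_that("channel statistics use the population variance", {
  s <- make_sample(matrix(c(1, 3, 2, 3, 5, 4), 3, 2))
  cs <- channel_stats(s)
  expect_equal(unname(cs$msi), c(2, 4))
  expect_equal(unname(cs$var), c(2 / 3, 2 / 3))
  expect_equal(unname(cs$sd), rep(sqrt(2 / 3), 2), tolerance = 1e-12)
  expect_equal(cs$n_cells, 3L)

  one <- channel_stats(make_sample(matrix(c(7, 7), 1, 2)))
  expect_equal(unname(one$msi), c(7, 7))
  expect_equal(unname(one$var), c(0, 0))
})

test_that("the universal reference is the cell-weighted pooled mean", {
  a1 <- make_sample(matrix(c(1, 3, 3, 5), 2, 2), id = "a1")
  a2 <- make_sample(matrix(c(2, 4), 1, 2), id = "a2")
  u <- build_universal_reference(list(a1, a2))
  expect_equal(unname(u$msi), c(2, 4))   # pooled over the 3 cells
  expect_equal(u$n_cells, 3L)
  # differs from the unweighted mean of per-anchor means when counts differ
  a2b <- make_sample(matrix(c(5, 7), 1, 2), id = "a2b")
  u2 <- build_universal_reference(list(a1, a2b))
  expect_equal(unname(u2$msi), c(3, 5))          # pooled over 3 cells
  unweighted <- (channel_stats(a1)$msi + channel_stats(a2b)$msi) / 2
  expect_false(isTRUE(all.equal(unname(u2$msi), unname(unweighted))))
  # single anchor degenerates to channel_stats
  expect_equal(build_universal_reference(list(a1))$msi,
               channel_stats(a1)$msi)
  a3 <- make_sample(matrix(1:4, 2, 2), labels = c("x", "y"))
  expect_error(build_universal_reference(list(a1, a3)), "differ")
})

md_anchor <- data.frame(
  filename = c("a.fcs", "b.fcs", "c.fcs", "d.fcs"),
  cohort = "c1", batch_id = c("p1", "p1", "p1", "p2"),
  patient_id = c("h1", "h2", "pt", "pt2"),
  condition = c("BCR", "basal", "basal", "IL7"),
  is_anchor = c(TRUE, TRUE, FALSE, FALSE),
  stringsAsFactors = FALSE)

test_that("anchor selection prefers basal and breaks ties by filename", {
  expect_identical(select_anchor(md_anchor, "p1")$filename, "b.fcs")
  two_basal <- md_anchor
  two_basal$condition[1] <- "basal"
  expect_identical(select_anchor(two_basal, "p1")$filename, "a.fcs")
  expect_error(select_anchor(md_anchor, "p2"), "p2")
  expect_error(select_anchor(md_anchor, "p9"), "unknown")
})

stats_of <- function(msi, sd = NULL, labels = paste0("ch", seq_along(msi))) {
  v <- if (is.null(sd)) rep(0, length(msi)) else sd^2
  structure(list(msi = stats::setNames(msi, labels), var = v,
                 sd = sqrt(v), n_cells = 100L, channel_labels = labels),
            class = "channel_stats")
}

test_that("bead-like slope is the through-origin regression slope", {
  expect_equal(bl_slope(stats_of(c(2, 4)), stats_of(c(1, 2))), 0.5)
  expect_equal(bl_slope(stats_of(c(1, 2)), stats_of(c(1, 2))), 1.0)
  expect_equal(bl_slope(stats_of(1), stats_of(3)), 3.0)
  expect_error(bl_slope(stats_of(c(0, 0)), stats_of(c(1, 2))), "zero")
})

test_that("the five normalization functions match their definitions", {
  cell2 <- make_sample(matrix(c(5, 5), 1, 2))
  res <- apply_normalization(cell2, stats_of(c(2, 4)), stats_of(c(1, 1)),
                             "MSFT")
  expect_equal(unname(res$sample$values), matrix(c(4, 2), 1, 2))
  res <- apply_normalization(cell2, stats_of(c(2, 4)), stats_of(c(1, 1)),
                             "MSFTB")
  expect_equal(unname(res$sample$values), matrix(c(3, 3), 1, 2))

  cell1 <- make_sample(matrix(5, 1, 1))
  res <- apply_normalization(cell1, stats_of(2, sd = 2), stats_of(1, sd = 1),
                             "Z")
  expect_equal(unname(res$sample$values), matrix(2.5, 1, 1))
  res <- apply_normalization(cell1, stats_of(2, sd = 2), stats_of(1, sd = 1),
                             "VAR")
  expect_equal(unname(res$sample$values), matrix(2.0, 1, 1))

  cell6 <- make_sample(matrix(c(6, 6), 1, 2))
  res <- apply_normalization(cell6, stats_of(c(2, 4)), stats_of(c(1, 2)),
                             "BL")
  expect_equal(unname(res$sample$values), matrix(c(3, 3), 1, 2))
  expect_equal(res$audit$bl_slope, 0.5)
})

test_that("identical anchor and reference statistics give the identity", {
  set.seed(42)
  s <- make_sample(matrix(rnorm(200), 40, 5))
  cs <- channel_stats(s)
  for (mode in c("MSFT", "MSFTB", "VAR", "Z", "BL")) {
    out <- apply_normalization(s, cs, cs, mode)$sample
    expect_lt(max(abs(out$values - s$values)), 1e-12)
  }
})

test_that("zero anchor sd under VAR/Z names the offending channel", {
  s <- make_sample(matrix(rnorm(20), 10, 2), labels = c("CD3", "DNA1"))
  a <- stats_of(c(1, 2), sd = c(1, 0), labels = c("CD3", "DNA1"))
  u <- stats_of(c(1, 2), sd = c(1, 1), labels = c("CD3", "DNA1"))
  expect_error(apply_normalization(s, a, u, "VAR"), "DNA1")
  expect_error(apply_normalization(s, a, u, "Z"), "DNA1")
})

test_that("audits replay to the exact normalized output", {
  set.seed(7)
  s <- make_sample(matrix(rnorm(300, 2), 60, 5))
  a <- channel_stats(make_sample(matrix(rnorm(300, 2.5), 60, 5)))
  u <- channel_stats(make_sample(matrix(rnorm(300, 2), 60, 5)))
  for (mode in c("MSFT", "MSFTB", "VAR", "Z", "BL")) {
    res <- apply_normalization(s, a, u, mode)
    expect_identical(replay_audit(s, res$audit)$values, res$sample$values)
  }
})

test_that("normalize_dataset maps every batch anchor onto the reference", {
  sim <- small_sim(seed = 9, cells = 400)
  for (mode in c("MSFT", "Z")) {
    res <- normalize_dataset(sim$samples, sim$metadata, mode = mode)
    anchors <- Filter(function(s) grepl("anchor", s$sample_id),
                      res$samples)
    for (a in anchors) {
      cs <- channel_stats(a)
      expect_lt(max(abs(cs$msi - res$universal$msi) /
                    pmax(abs(res$universal$msi), 1e-12)), 1e-6)
    }
  }
})

test_that("a single batch whose anchor is the only sample is unchanged", {
  set.seed(5)
  s <- make_sample(matrix(rnorm(500, 2), 100, 5), id = "only",
                   batch = "p1")
  md <- data.frame(filename = "only.fcs", cohort = "c", batch_id = "p1",
                   patient_id = "h", condition = "basal", is_anchor = TRUE,
                   stringsAsFactors = FALSE)
  for (mode in c("MSFT", "MSFTB", "VAR", "Z", "BL")) {
    out <- normalize_dataset(list(s), md, mode = mode)$samples[[1]]
    expect_lt(max(abs(out$values - s$values)), 1e-10)
  }
})

test_that("MSFT removes injected additive cross-batch offsets", {
  sim <- small_sim(seed = 21, cells = 1000, channels = 10)
  pre <- pop_batch_deviation(sim$samples, sim$truth$labels)
  res <- normalize_dataset(sim$samples, sim$metadata, mode = "MSFT")
  post <- pop_batch_deviation(res$samples, sim$truth$labels)
  expect_lt(post, pre * 0.2)
})
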