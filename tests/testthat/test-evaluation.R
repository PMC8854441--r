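test_that("arcsinh transform: fixed point, closed form, oddness, inverse", {
  s <- make_sample(matrix(c(0, 5, -5, 12), 2, 2), state = "raw")
  tr <- arcsinh_transform(s, cofactor = 5)
  expect_equal(unname(tr$values[1, 1]), 0)
  expect_equal(unname(tr$values[2, 1]), 0.88137, tolerance = 1e-4) # asinh(1)
  expect_equal(unname(tr$values[1, 2]), -0.88137, tolerance = 1e-4)
  expect_identical(tr$transform_state, "arcsinh")
  expect_error(arcsinh_transform(tr), "already")
  back <- inverse_arcsinh_transform(tr, cofactor = 5)
  expect_lt(max(abs(back$values - s$values)), 1e-9)
  expect_error(inverse_arcsinh_transform(s), "not arcsinh")
})

test_that("rectangular gating honors the 10-count positivity threshold", {
  thr <- positivity_threshold(10, 5)
  expect_equal(thr, asinh(2))
  raw <- make_sample(matrix(c(12, 8, 1000, 12, 8, 2), 3, 2,
                            byrow = FALSE),
                     labels = c("CD19", "CD3"), state = "raw")
  tr <- arcsinh_transform(raw)
  gates <- data.frame(population = c("CD19pos", "CD19neg"),
                      channel = "CD19",
                      lower = c(thr, -Inf), upper = c(Inf, thr),
                      stringsAsFactors = FALSE)
  g <- rectangular_gate(tr, gates)
  # 12 counts > 10 -> positive; 8 counts < 10 -> negative
  expect_identical(g$labels, c("CD19pos", "CD19neg", "CD19pos"))
  expect_equal(unname(g$frequencies), c(2 / 3, 1 / 3))
})

test_that("gating is first-match and leaves outsiders unassigned", {
  s <- make_sample(matrix(c(0.5, 2, 9), 3, 1), labels = "CD4")
  gates <- data.frame(population = c("dim", "bright"), channel = "CD4",
                      lower = c(0, 1), upper = c(3, 5),
                      stringsAsFactors = FALSE)
  g <- rectangular_gate(s, gates)
  expect_identical(g$labels, c("dim", "dim", "UNASSIGNED"))
  expect_lte(sum(g$frequencies), 1)
  expect_error(rectangular_gate(s, transform(gates, channel = "CD8")),
               "CD8")
  bad <- gates; bad$lower[1] <- 10
  expect_error(rectangular_gate(s, bad), "lower < upper")
})

test_that("gating recovers well-separated synthetic mixtures", {
  set.seed(31)
  n <- 2000
  pop <- sample(c("lo", "hi"), n, replace = TRUE)
  x <- rnorm(n, mean = ifelse(pop == "hi", 5, 1), sd = 0.3)
  s <- make_sample(matrix(x, ncol = 1), labels = "CD45")
  gates <- data.frame(population = c("hi", "lo"), channel = "CD45",
                      lower = c(3, -Inf), upper = c(Inf, 3),
                      stringsAsFactors = FALSE)
  g <- rectangular_gate(s, gates)
  expect_gte(mean(g$labels == pop), 0.99)
})

test_that("rmsd definition and homogeneity", {
  expect_equal(rmsd(c(1, 2), c(1, 2)), 0)
  expect_equal(rmsd(c(0, 0), c(3, 4)), sqrt(25 / 2), tolerance = 1e-10)
  set.seed(37)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(rmsd(3 * a, 3 * b), 3 * rmsd(a, b), tolerance = 1e-12)
  expect_error(rmsd(1:3, 1:4), "length")
  expect_true(rmsd(a, a) == 0)
})

test_that("r_squared is the squared Pearson correlation", {
  a <- c(1, 2, 3)
  expect_equal(r_squared(a, 2 * a + 1), 1.0)
  expect_equal(r_squared(a, c(1, 2, 4)), 0.9643, tolerance = 1e-4)
  expect_equal(r_squared(c(1, -1, 1, -1), c(1, 1, -1, -1)), 0)
  expect_error(r_squared(a, c(2, 2, 2)), "variance")
  expect_error(r_squared(a, 1:4), "length")
})

test_that("similarity networks threshold cosine similarity", {
  m <- rbind(a = c(1, 1), b = c(2, 2), c = c(1, 0))
  net <- similarity_network(m, threshold = 0.9)
  expect_equal(net$similarity["a", "b"], 1, tolerance = 1e-12)
  expect_equal(net$similarity["a", "c"], sqrt(2) / 2, tolerance = 1e-4)
  expect_equal(nrow(net$edges), 1L)      # only a-b reaches 0.9
  expect_equal(unname(net$degree), c(1L, 1L, 0L))
  # scale invariance and symmetry
  net2 <- similarity_network(m * 10, threshold = 0.9)
  expect_equal(net2$similarity, net$similarity, tolerance = 1e-12)
  expect_equal(net$similarity, t(net$similarity))
  # three mutually similar nodes form a triangle: degree 2 each
  tri <- similarity_network(rbind(x = c(1, 1), y = c(1.01, 1),
                                  z = c(1, 1.02)), threshold = 0.9)
  expect_equal(unname(tri$degree), c(2L, 2L, 2L))
  expect_error(similarity_network(rbind(c(0, 0), c(1, 1))), "zero")
  grp <- similarity_network(m, threshold = 0.9,
                            groups = c("g1", "g1", "g2"))
  expect_equal(unname(grp$group_mean_degree["g2"]), 0)
})

test_that("batch distances: 3-4-5 example, determinism, symmetry", {
  s1 <- make_sample(matrix(c(0, 0), 1, 2), id = "a", batch = "b1")
  s2 <- make_sample(matrix(c(3, 4), 1, 2), id = "b", batch = "b2")
  expect_warning(res <- batch_distance_summary(list(s1, s2)),
                 "intra")
  expect_equal(res$inter, 5)
  expect_true(is.na(res$intra))

  set.seed(41)
  x <- matrix(rnorm(100 * 3), 100, 3)
  dup1 <- make_sample(x, id = "d1", batch = "b1")
  dup2 <- make_sample(x, id = "d2", batch = "b2")
  res <- batch_distance_summary(list(dup1, dup2), subsample = Inf)
  expect_equal(res$inter, res$intra, tolerance = 0.05)

  big <- lapply(1:2, function(b)
    make_sample(matrix(rnorm(600), 200, 3), id = paste0("s", b),
                batch = paste0("b", b)))
  r1 <- batch_distance_summary(big, subsample = 50, seed = 3)
  r2 <- batch_distance_summary(big, subsample = 50, seed = 3)
  expect_identical(r1, r2)
})

test_that("adjusted Rand index matches the pair-counting formula", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1.0)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_equal(adjusted_rand_index(1:4, rep(1, 4)), 0)
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
  set.seed(43)
  for (i in 1:10) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), oracle_ari(a, b),
                 tolerance = 1e-12)
    # invariance to relabeling
    perm <- sample(4)
    expect_equal(adjusted_rand_index(perm[a], b),
                 adjusted_rand_index(a, b), tolerance = 1e-12)
    expect_lte(adjusted_rand_index(a, b), 1)
  }
})
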