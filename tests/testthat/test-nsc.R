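random_labelled_matrix <- function(n_genes, n_per_class, classes,
                                   shift = 2) {
  n <- n_per_class * length(classes)
  labels <- rep(classes, each = n_per_class)
  v <- matrix(stats::rnorm(n_genes * n, 5), nrow = n_genes,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%03d", seq_len(n))))
  for (i in seq_along(classes)) {
    idx <- which(labels == classes[i])
    g <- seq.int((i - 1) * 3 + 1, min(i * 3, n_genes))
    v[g, idx] <- v[g, idx] + shift
  }
  list(m = expr_matrix(v, scale = "log2"), labels = labels)
}

test_that("no shrinkage reproduces the raw class centroids", {
  set.seed(50)
  d <- random_labelled_matrix(10, 5, c("A", "B"))
  model <- train_nsc(d$m, d$labels, delta = 0)
  for (k in c("A", "B")) {
    raw <- rowMeans(unclass(d$m)[, d$labels == k])
    expect_equal(model$shrunken_centroids[, k], raw, tolerance = 1e-12)
  }
})

test_that("full shrinkage collapses every centroid onto the overall mean", {
  set.seed(51)
  d <- random_labelled_matrix(10, 5, c("A", "B", "C"))
  probe <- train_nsc(d$m, d$labels, delta = 0)
  dmax <- max(abs(probe$d))
  model <- train_nsc(d$m, d$labels, delta = dmax + 0.01)
  overall <- rowMeans(unclass(d$m))
  for (k in model$classes) {
    expect_equal(model$shrunken_centroids[, k], overall, tolerance = 1e-12)
  }
  expect_true(all(model$d == 0))
})

test_that("a two-gene two-class instance matches hand computation", {
  # 4 samples, 2 genes; class A = S1,S2; class B = S3,S4
  v <- matrix(c(1, 5,
                3, 7,
                9, 2,
                11, 4), nrow = 2,
              dimnames = list(c("G1", "G2"), c("S1", "S2", "S3", "S4")))
  m <- expr_matrix(v, scale = "log2")
  labels <- c("A", "A", "B", "B")
  model <- train_nsc(m, labels, delta = 0.5)

  # independent brute-force recomputation
  cent <- cbind(A = rowMeans(v[, 1:2]), B = rowMeans(v[, 3:4]))
  overall <- rowMeans(v)
  s <- sqrt((rowSums((v[, 1:2] - cent[, "A"])^2) +
             rowSums((v[, 3:4] - cent[, "B"])^2)) / (4 - 2))
  s0 <- stats::median(s)
  mk <- sqrt(1 / 2 + 1 / 4)
  d <- (cent - overall) / (mk * (s + s0))
  d_shr <- sign(d) * pmax(abs(d) - 0.5, 0)
  shrunk <- overall + mk * (s + s0) * d_shr

  expect_equal(model$d, d_shr, tolerance = 1e-10)
  expect_equal(model$shrunken_centroids, shrunk, tolerance = 1e-10)
  expect_equal(model$s0, s0)
})

test_that("the alternative normalization constant is supported", {
  set.seed(52)
  d <- random_labelled_matrix(8, 6, c("A", "B"))
  plus <- train_nsc(d$m, d$labels, delta = 0.3, norm_constant = "plus")
  minus <- train_nsc(d$m, d$labels, delta = 0.3, norm_constant = "minus")
  expect_false(identical(plus$d, minus$d))
  # sqrt(1/nk - 1/n) < sqrt(1/nk + 1/n): larger |d| before thresholding
  expect_true(mean(abs(minus$d)) >= mean(abs(plus$d)))
})

test_that("a sample at a shrunken centroid is assigned to that class", {
  set.seed(53)
  d <- random_labelled_matrix(10, 5, c("A", "B", "C"))
  model <- train_nsc(d$m, d$labels, delta = 0,
                     priors = c(1, 1, 1) / 3)
  for (k in model$classes) {
    got <- classify_nsc(model, model$shrunken_centroids[, k])
    expect_identical(unname(got$subtype), k)
  }
})

test_that("at full shrinkage only the priors decide", {
  set.seed(54)
  d <- random_labelled_matrix(10, 4, c("Basal", "LumA", "LumB", "Her2"))
  probe <- train_nsc(d$m, d$labels, delta = 0)
  model <- train_nsc(d$m, d$labels, delta = max(abs(probe$d)) + 1,
                     priors = c(0.7, 0.1, 0.1, 0.1))
  calls <- classify_nsc(model, d$m)$subtype
  expect_true(all(calls == "Basal"))
})

test_that("unshrunken classification equals the brute-force oracle", {
  set.seed(55)
  d <- random_labelled_matrix(12, 6, c("A", "B", "C"))
  model <- train_nsc(d$m, d$labels, delta = 0)
  x <- unclass(d$m)
  for (i in 1:20) {
    newx <- stats::rnorm(12, 5) + x[, sample(ncol(x), 1)] * 0.2
    names(newx) <- rownames(x)
    got <- classify_nsc(model, newx)$subtype
    want <- oracle_nearest_centroid(x, d$labels, newx)
    expect_identical(unname(got), want)
  }
})

test_that("the active gene count is non-increasing in delta", {
  set.seed(56)
  d <- random_labelled_matrix(20, 6, c("A", "B"))
  grid <- seq(0, 3, by = 0.25)
  active <- vapply(grid, function(del) {
    model <- train_nsc(d$m, d$labels, delta = del)
    sum(rowSums(model$d != 0) > 0)
  }, numeric(1))
  expect_true(all(diff(active) <= 0))
  # |d'| non-increasing in delta, gene by gene
  d1 <- train_nsc(d$m, d$labels, delta = 0.5)$d
  d2 <- train_nsc(d$m, d$labels, delta = 1.0)$d
  expect_true(all(abs(d2) <= abs(d1) + 1e-12))
})

test_that("classification is invariant to gene ordering", {
  set.seed(57)
  d <- random_labelled_matrix(15, 5, c("A", "B"))
  model <- train_nsc(d$m, d$labels, delta = 0.2)
  perm <- sample.int(15)
  m_perm <- expr_matrix(unclass(d$m)[perm, ], scale = "log2")
  expect_identical(classify_nsc(model, d$m)$subtype,
                   classify_nsc(model, m_perm)$subtype)
})

test_that("degenerate classes and missing genes are rejected", {
  set.seed(58)
  d <- random_labelled_matrix(6, 3, c("A", "B"))
  expect_error(train_nsc(d$m, c("A", "A", "A", "A", "A", "B")), "fewer than 2")
  model <- train_nsc(d$m, d$labels, delta = 0)
  short <- expr_matrix(unclass(d$m)[1:3, ], scale = "log2")
  expect_error(classify_nsc(model, short), "G004")
})

test_that("well-separated subtype centroids are recovered on holdout data", {
  cfg <- cohort_config(n_samples = 160, n_genes = 250, n_bins = 100,
                       bin_mean_count = 200, seed = 60)
  co <- generate_cohort(cfg)
  norm <- normalize_log_cpm(co$expression)
  panel <- intersect(readLines(system.file("extdata",
                                           "subtype_panel_genes.txt",
                                           package = "seqdx")),
                     rownames(norm))
  m <- expr_matrix(unclass(norm)[panel, ], scale = "log2")
  train <- 1:110
  test <- 111:160
  model <- train_nsc(expr_matrix(unclass(m)[, train], scale = "log2"),
                     co$truth$subtype[train], delta = 0)
  calls <- classify_nsc(model,
                        expr_matrix(unclass(m)[, test], scale = "log2"))
  acc <- mean(calls$subtype == co$truth$subtype[test])
  expect_gte(acc, 0.95)
})
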