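# Hand-built component model: intercept-only or fixed-coefficient binomial
# penalized_model structures, for testing the composite arithmetic without
# any fitting.
manual_component <- function(genes, coefs, intercept) {
  structure(list(coefficients = stats::setNames(coefs, genes),
                 intercept = intercept, alpha = 0.5, lambda = 1,
                 lambda_grid = 1, family = "binomial", genes = genes),
            class = "penalized_model")
}

manual_tg <- function(genes, boundary = NA_real_,
                      intercepts = c(0.5, -0.2, 1.0),
                      coefs = NULL) {
  comps <- lapply(seq_len(3), function(i) {
    manual_component(genes,
                     if (is.null(coefs)) rep(0, length(genes)) else coefs[[i]],
                     intercepts[i])
  })
  names(comps) <- c("mitotic", "nuclear_atypia", "tubular_formation")
  structure(list(components = comps, score_boundary = boundary,
                 cv_scores = numeric(), cv_grades = integer(),
                 cv_auc = NA_real_, audit = list()),
            class = "tg_model")
}

test_that("the summed score adds the three component probabilities", {
  genes <- c("G1", "G2")
  model <- manual_tg(genes, coefs = list(c(1, 0), c(0, -1), c(0.5, 0.5)),
                     intercepts = c(0, 0, 0))
  m <- as_log2_expr(matrix(c(1, 2, 3, 4), nrow = 2,
                           dimnames = list(genes, c("S1", "S2"))))
  s <- tg_scores(model, m)
  p <- sapply(model$components, predict, newdata = m)
  expect_equal(unname(s), unname(rowSums(p)), tolerance = 1e-12)
  expect_true(all(s >= 0 & s <= 3))
})

test_that("intercept-only components give every sample the same score", {
  model <- manual_tg(c("G1", "G2"))
  m <- as_log2_expr(matrix(stats::rnorm(10, 5), nrow = 2,
                           dimnames = list(c("G1", "G2"),
                                           sprintf("S%d", 1:5))))
  s <- tg_scores(model, m)
  expect_equal(max(s) - min(s), 0)
  expect_equal(unname(s[1]),
               stats::plogis(0.5) + stats::plogis(-0.2) + stats::plogis(1.0))
})

test_that("component probabilities sum identically on random samples", {
  set.seed(30)
  genes <- sprintf("G%02d", 1:6)
  model <- manual_tg(genes,
                     coefs = list(stats::rnorm(6), stats::rnorm(6),
                                  stats::rnorm(6)),
                     intercepts = stats::rnorm(3))
  v <- matrix(stats::rnorm(60, 5), nrow = 6,
              dimnames = list(genes, sprintf("S%02d", 1:10)))
  m <- as_log2_expr(v)
  s <- tg_scores(model, m)
  for (j in 1:10) {
    p <- vapply(model$components, function(cm) {
      stats::plogis(sum(cm$coefficients * v[, j]) + cm$intercept)
    }, numeric(1))
    expect_equal(unname(s[j]), sum(p), tolerance = 1e-12)
  }
})

test_that("gene-row permutation leaves scores unchanged", {
  set.seed(31)
  genes <- sprintf("G%02d", 1:6)
  model <- manual_tg(genes, coefs = list(stats::rnorm(6), stats::rnorm(6),
                                         stats::rnorm(6)))
  v <- matrix(stats::rnorm(36, 5), nrow = 6,
              dimnames = list(genes, sprintf("S%02d", 1:6)))
  perm <- sample.int(6)
  expect_equal(tg_scores(model, as_log2_expr(v)),
               tg_scores(model, as_log2_expr(v[perm, ])))
})

test_that("missing model genes are an error listing them", {
  model <- manual_tg(c("G1", "G2", "G3"))
  m <- as_log2_expr(matrix(1:4, nrow = 2,
                           dimnames = list(c("G1", "G4"), c("S1", "S2"))))
  expect_error(tg_scores(model, m), "G2")
  expect_error(tg_scores(model, m), "G3")
})

test_that("classification respects the boundary with ties going low", {
  genes <- c("G1")
  m <- as_log2_expr(matrix(c(1, 2), nrow = 1,
                           dimnames = list("G1", c("S1", "S2"))))
  model <- manual_tg(genes, boundary = 1.5)
  s <- tg_scores(model, m) # identical scores: 3 * plogis(intercepts)
  model$score_boundary <- unname(s[1]) # exact tie
  expect_identical(unname(classify_tg(model, m)), c("low", "low"))
  model$score_boundary <- unname(s[1]) - 0.1
  expect_identical(unname(classify_tg(model, m)), c("high", "high"))
  model$score_boundary <- NA_real_
  expect_error(classify_tg(model, m), "boundary")
})

test_that("fitting excludes score-2 samples and records the audit", {
  co <- generate_cohort(cohort_config(n_samples = 120, n_genes = 250,
                                      n_bins = 100, bin_mean_count = 200,
                                      grade_effect = 1.5, seed = 40))
  norm <- normalize_log_cpm(co$expression)
  tg <- fit_tg_model(norm, co$clinical[c("mitotic", "nuclear_atypia",
                                         "tubular_formation")],
                     co$clinical$grade, seed = 1)
  for (comp in names(tg$audit)) {
    n2 <- sum(co$clinical[[comp]] == 2L)
    expect_equal(unname(tg$audit[[comp]]["n_excluded_score2"]), n2)
    expect_equal(unname(tg$audit[[comp]]["n_used"]), 120 - n2)
  }
  expect_true(tg$score_boundary > 0 && tg$score_boundary < 3)
  expect_false(anyNA(tg$cv_scores))
})

test_that("a component without both extreme scores is an error naming it", {
  co <- generate_cohort(cohort_config(n_samples = 40, n_genes = 250,
                                      n_bins = 100, bin_mean_count = 200,
                                      seed = 41))
  norm <- normalize_log_cpm(co$expression)
  scores <- co$clinical[c("mitotic", "nuclear_atypia", "tubular_formation")]
  scores$nuclear_atypia <- rep(2L, 40)
  expect_error(fit_tg_model(norm, scores, co$clinical$grade, seed = 1),
               "nuclear_atypia")
})

test_that("reclassification tables conserve grade counts", {
  genes <- c("G1", "G2")
  model <- manual_tg(genes, boundary = 1.4,
                     coefs = list(c(2, 0), c(0, 2), c(1, 1)),
                     intercepts = c(-10, -10, -10))
  set.seed(32)
  m <- as_log2_expr(matrix(stats::runif(40, 0, 10), nrow = 2,
                           dimnames = list(genes, sprintf("S%02d", 1:20))))
  grades <- sample(1:3, 20, replace = TRUE)
  tab <- reclassification_table(model, m, grades)
  expect_equal(unname(rowSums(tab)), unname(as.integer(table(
    factor(grades, levels = 1:3)))))

  no2 <- ifelse(grades == 2L, 1L, grades)
  tab2 <- reclassification_table(model, m, no2)
  expect_equal(unname(tab2["2", ]), c(0L, 0L), ignore_attr = TRUE)
})
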