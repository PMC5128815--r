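#' Fit the composite transcriptomic grade (TG) model
#'
#' Fits one binomial elastic-net model per Nottingham grade subcomponent
#' (mitotic count, nuclear atypia, tubular formation), each trained only on
#' tumors whose clinical subcomponent score is 1 or 3 (event = score 3).
#' The per-sample TG score is the sum of the three predicted probabilities,
#' so it lies in \[0, 3\]. The low/high decision boundary on the summed
#' score is placed by [optimal_boundary()] on nested cross-validated summed
#' scores of overall grade 1 vs grade 3 samples, so the boundary is chosen
#' from predictions that never saw their own sample during fitting or
#' tuning.
#'
#' @param m an [expr_matrix()] on the log2 scale.
#' @param subcomponent_scores data.frame with columns `mitotic`,
#'   `nuclear_atypia`, `tubular_formation` (values 1-3), one row per sample
#'   in `m` (same order).
#' @param overall_grades integer overall grades 1-3 per sample.
#' @param outer_k,inner_k fold counts for the nested cross-validation.
#' @param alpha elastic-net mixing weight.
#' @param seed seed for fold assignment.
#' @return A `tg_model` with the three component `penalized_model`s, the
#'   `score_boundary`, the nested-CV summed scores of grade 1/3 samples
#'   (`cv_scores`, with grades in `cv_grades`), their AUC (`cv_auc`), and an
#'   `audit` record of per-component excluded (score 2) sample counts.
#' @export
fit_tg_model <- function(m, subcomponent_scores, overall_grades,
                         outer_k = 5L, inner_k = 5L, alpha = 0.5,
                         seed = 1L) {
  if (!inherits(m, "expr_matrix")) stop("not an expr_matrix")
  if (expr_scale(m) != "log2") stop("fit_tg_model expects scale = log2")
  comps <- grade_component_names()
  miss <- setdiff(comps, names(subcomponent_scores))
  if (length(miss)) {
    stop("subcomponent_scores missing column(s): ",
         paste(miss, collapse = ", "))
  }
  n <- ncol(m)
  stopifnot(nrow(subcomponent_scores) == n, length(overall_grades) == n)
  if (!all(overall_grades %in% 1:3)) stop("overall grades must be 1, 2 or 3")

  audit <- list()
  components <- list()
  for (comp in comps) {
    sc <- subcomponent_scores[[comp]]
    if (!all(sc %in% 1:3)) stop("subcomponent scores must be 1, 2 or 3")
    use <- sc %in% c(1L, 3L)
    if (!any(sc[use] == 1L) || !any(sc[use] == 3L)) {
      stop("component '", comp, "' lacks samples at both scores 1 and 3")
    }
    audit[[comp]] <- c(n_used = sum(use), n_excluded_score2 = sum(!use))
    components[[comp]] <- fit_elastic_net(
      expr_subset(m, samples = which(use)), as.integer(sc[use] == 3L),
      family = "binomial", alpha = alpha, inner_folds = inner_k,
      seed = stream_seed(seed, paste0("tg_", comp)))
  }

  # Nested CV over grade 1/3 samples for the decision boundary: in each
  # outer round the three component models are refit on training samples
  # only (each restricted to its own score-1/3 subset), then summed on the
  # held-out samples.
  g13 <- which(overall_grades %in% c(1L, 3L))
  if (!length(g13) || length(unique(overall_grades[g13])) < 2L) {
    stop("boundary placement needs samples at overall grade 1 and 3")
  }
  y13 <- as.integer(overall_grades[g13] == 3L)
  folds <- with_stream(seed, "tg_outer_cv",
                       make_folds(length(g13), outer_k, strata = y13))
  cv_scores <- rep(NA_real_, length(g13))
  names(cv_scores) <- colnames(m)[g13]
  for (f in seq_len(outer_k)) {
    te <- g13[folds == f]
    tr_pool <- setdiff(seq_len(n), te)
    m_te <- expr_subset(m, samples = te)
    total <- rep(0, length(te))
    for (comp in comps) {
      sc <- subcomponent_scores[[comp]]
      tr <- tr_pool[sc[tr_pool] %in% c(1L, 3L)]
      if (length(unique(sc[tr])) < 2L) {
        stop("component '", comp,
             "' lacks both extreme scores in an outer training fold")
      }
      fit <- fit_elastic_net(
        expr_subset(m, samples = tr), as.integer(sc[tr] == 3L),
        family = "binomial", alpha = alpha, inner_folds = inner_k,
        seed = stream_seed(seed, paste0("tg_cv_", comp, "_", f)))
      total <- total + predict(fit, m_te)
    }
    cv_scores[folds == f] <- total
  }
  curve <- roc_points(cv_scores, y13)
  structure(list(
    components = components,
    score_boundary = optimal_boundary(curve),
    cv_scores = cv_scores,
    cv_grades = overall_grades[g13],
    cv_auc = trapezoid_auc(curve$fpr, curve$tpr),
    audit = audit
  ), class = "tg_model")
}

#' @export
print.tg_model <- function(x, ...) {
  nz <- vapply(x$components, function(c) sum(c$coefficients != 0), 0L)
  cat(sprintf(paste0(
    "<tg_model> composite transcriptomic grade\n",
    "  non-zero genes: mitotic %d, nuclear_atypia %d, tubular_formation %d\n",
    "  score boundary %.4f (nested-CV grade 1 vs 3 AUC %.4f)\n"),
    nz[1], nz[2], nz[3], x$score_boundary, x$cv_auc))
  invisible(x)
}

#' Summed transcriptomic grade scores
#'
#' @param model a `tg_model`.
#' @param m an [expr_matrix()] on the log2 scale containing every model
#'   gene; missing genes are an error (no silent imputation).
#' @return Per-sample score in \[0, 3\]: the sum of the three component
#'   probabilities.
#' @export
tg_scores <- function(model, m) {
  if (!inherits(model, "tg_model")) stop("not a tg_model")
  probs <- lapply(model$components, predict, newdata = m)
  Reduce(`+`, probs)
}

#' Classify samples into low/high transcriptomic grade
#'
#' A sample is `high` iff its summed score exceeds the model's boundary;
#' scores exactly at the boundary are `low` (conservative toward the lower
#' grade).
#'
#' @inheritParams tg_scores
#' @return Character vector of `"low"`/`"high"` named by sample.
#' @export
classify_tg <- function(model, m) {
  if (!inherits(model, "tg_model")) stop("not a tg_model")
  if (is.na(model$score_boundary)) stop("score boundary is not set")
  s <- tg_scores(model, m)
  out <- ifelse(s > model$score_boundary, "high", "low")
  names(out) <- names(s)
  out
}

#' Cross-tabulate histological grade against transcriptomic grade
#'
#' @inheritParams tg_scores
#' @param grades integer histological grades 1-3 per sample of `m`.
#' @return A `tg_reclassification` table of counts (grade 1/2/3 x TG
#'   low/high); printing reports the grade-2 split with percentages.
#' @export
reclassification_table <- function(model, m, grades) {
  if (!all(grades %in% 1:3)) stop("grades must be 1, 2 or 3")
  if (length(grades) != ncol(m)) stop("one grade per sample is required")
  tg <- classify_tg(model, m)
  tab <- table(grade = factor(grades, levels = 1:3),
               tg = factor(tg, levels = c("low", "high")))
  structure(tab, class = c("tg_reclassification", class(tab)))
}

#' @export
print.tg_reclassification <- function(x, ...) {
  print(unclass(x))
  n2 <- sum(x["2", ])
  if (n2 > 0) {
    cat(sprintf(
      "grade 2: %d (%.0f%%) low TG, %d (%.0f%%) high TG of %d\n",
      x["2", "low"], 100 * x["2", "low"] / n2,
      x["2", "high"], 100 * x["2", "high"] / n2, n2))
  } else {
    cat("grade 2: no samples\n")
  }
  invisible(x)
}
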