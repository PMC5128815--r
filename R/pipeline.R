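#' Exact test of association in a 2 x k contingency table
#'
#' Two-sided Fisher exact p-value: the sum, over tables with the observed
#' margins, of hypergeometric probabilities no larger than the observed
#' table's (base R's network/enumeration implementation).
#'
#' @param counts non-negative integer matrix (2 x k, k <= 5 recommended).
#' @return Two-sided exact p-value.
#' @export
group_association <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)) || anyNA(counts)) {
    stop("counts must be non-negative integers")
  }
  stats::fisher.test(counts)$p.value
}

#' Welch two-sided t-test on group means
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @return Two-sided p-value.
#' @export
mean_difference_test <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("each group needs at least 2 values")
  }
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    if (length(values_a) == 2L || length(values_b) == 2L) {
      stop("degenerate input: zero variance in both groups")
    }
  }
  out <- tryCatch(stats::t.test(values_a, values_b, var.equal = FALSE),
                  error = function(e) stop("degenerate t-test input: ",
                                           conditionMessage(e)))
  out$p.value
}

#' Run the full diagnostic pipeline
#'
#' Orchestrates the end-to-end workflow on either a simulated cohort or
#' files on disk: ingest/simulate, log2-CPM normalization, single-gene
#' logistic models for ER/PR/HER2 with nested-CV ROC analysis, a linear
#' elastic net for the Ki-67 percent (evaluated as a classifier against the
#' 20% rule), the composite transcriptomic grade model with grade-2
#' reclassification, shrunken-centroid subtyping, per-sample ERBB2
#' copy-number calls, and actionability matching. Every table is written
#' under `outdir` and returned in a `report_bundle`.
#'
#' @param config list with either `simulate` (a [cohort_config()] or its
#'   argument list) or `inputs` (paths: expression, clinical, alterations,
#'   bins), plus optional `outer_k`, `inner_k`, `scope`, `kb_path`,
#'   `outdir`, `seed`.
#' @return A `report_bundle` list.
#' @export
run_pipeline <- function(config) {
  seed <- config$seed %||% 1L
  outer_k <- config$outer_k %||% 5L
  inner_k <- config$inner_k %||% 5L
  scope <- config$scope %||% "breast_only"
  outdir <- config$outdir
  if (!is.null(config$simulate) && !is.null(config$inputs)) {
    stop("config must have either a simulate block or inputs, not both")
  }

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    if (!inherits(sim, "cohort_config")) {
      if (is.null(sim$seed)) sim$seed <- seed
      sim <- do.call(cohort_config, sim)
    }
    cohort <- generate_cohort(sim)
    expression <- cohort$expression
    clinical <- cohort$clinical
    alterations <- cohort$alterations
    tumor_bins <- cohort$tumor_bins
    baseline_bins <- cohort$baseline_bins
    truth <- cohort$truth
    gene_regions <- cohort$gene_regions
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    expression <- read_expression(inp$expression)
    clinical <- read_clinical(inp$clinical)
    alterations <- read_alterations_maf(inp$alterations)
    b <- read_bins(inp$bins)
    tumor_bins <- b$tumor
    baseline_bins <- b$baseline
    truth <- NULL
    gene_regions <- erbb2_region()
  } else {
    stop("config needs a simulate block or inputs")
  }

  norm <- normalize_log_cpm(expression)

  # ER/PR/HER2: single-gene logistic models, nested-CV scores, ROC, AUC
  # with DeLong CI, probability boundary at the top-left-closest point.
  marker_genes <- c(ER = "ESR1", PR = "PGR", HER2 = "ERBB2")
  label_cols <- c(ER = "er", PR = "pr", HER2 = "her2")
  markers <- list()
  for (mk in names(marker_genes)) {
    labels <- clinical[[label_cols[mk]]]
    scores <- nested_cv_scores(
      norm, labels,
      list(type = "single_gene_logistic", gene = marker_genes[[mk]]),
      outer_k = outer_k, inner_k = inner_k,
      seed = stream_seed(seed, paste0("marker_", mk)))
    curve <- roc_points(scores, labels)
    fit <- fit_single_gene_logistic(
      unclass(norm)[marker_genes[[mk]], ], labels,
      marker = mk, gene = marker_genes[[mk]])
    fit$probability_boundary <- optimal_boundary(curve)
    markers[[mk]] <- list(model = fit, cv_scores = scores, roc = curve,
                          auc = auc_ci(scores, labels))
  }
  # Ki-67: linear elastic net on the percent, evaluated as a classifier
  # against the >=20% high rule.
  ki67_high <- ifelse(clinical$ki67_percent >= 20, "high", "low")
  ki67 <- NULL
  if (length(unique(ki67_high)) == 2L) {
    ki67_scores <- nested_cv_scores(
      norm, clinical$ki67_percent,
      list(type = "elastic_net", family = "linear", alpha = 0.5),
      outer_k = outer_k, inner_k = inner_k,
      seed = stream_seed(seed, "marker_Ki67"))
    ki67_curve <- roc_points(ki67_scores, ki67_high)
    ki67 <- list(cv_scores = ki67_scores, roc = ki67_curve,
                 auc = auc_ci(ki67_scores, ki67_high),
                 percent_boundary = optimal_boundary(ki67_curve))
  }

  # Transcriptomic grade.
  tg <- fit_tg_model(norm, clinical[grade_component_names()],
                     clinical$grade, outer_k = outer_k, inner_k = inner_k,
                     seed = stream_seed(seed, "tg"))
  reclass <- reclassification_table(tg, norm, clinical$grade)
  tg_class <- classify_tg(tg, norm)

  # Subtyping: train on molecular truth labels when simulating (standing in
  # for an external reference cohort); skipped when labels are unavailable.
  subtype <- NULL
  if (!is.null(truth) && length(unique(truth$subtype)) >= 2L) {
    nsc <- train_nsc(expr_subset(norm, genes = intersect(panel_genes(),
                                                         rownames(norm))),
                     truth$subtype, delta = 0)
    calls <- classify_nsc(nsc, norm)
    subtype <- list(model = nsc, calls = calls$subtype,
                    distribution = table(calls$subtype))
  }

  # ERBB2 copy-number call per sample.
  cnv_calls <- do.call(rbind, lapply(names(tumor_bins), function(s) {
    prof <- bin_log_ratio(tumor_bins[[s]], baseline_bins[[s]])
    cbind(sample = s, gene_cnv_call(prof, gene_regions))
  }))

  # Actionability against the packaged (or supplied) knowledge base.
  kb_path <- config$kb_path %||%
    system.file("extdata", "toy_knowledge_base.tsv", package = "seqdx")
  kb <- read_knowledge_base(kb_path)
  her2_by_patient <- stats::setNames(clinical$her2, clinical$sample)
  matches <- match_patient(alterations, kb, scope = scope,
                           her2_status = her2_by_patient)
  best <- best_match_per_patient(matches)
  act_summary <- summarize_cohort(best, matches, nrow(clinical))
  flags <- flag_key_genes(alterations, her2_by_patient)

  bundle <- structure(list(
    seed = seed, schema_version = "1.0",
    markers = markers, ki67 = ki67,
    tg = tg, tg_class = tg_class, reclassification = reclass,
    subtype = subtype, cnv_calls = cnv_calls,
    actionability = list(matches = matches, best = best,
                         summary = act_summary, flags = flags),
    clinical = clinical
  ), class = "report_bundle")

  if (!is.null(outdir)) write_report_bundle(bundle, outdir)
  bundle
}

write_report_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stamp <- function(df) {
    cbind(df, schema_version = bundle$schema_version, seed = bundle$seed)
  }
  tsv <- function(df, name) {
    utils::write.table(stamp(df), file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  aucs <- do.call(rbind, lapply(names(bundle$markers), function(mk) {
    m <- bundle$markers[[mk]]
    data.frame(marker = mk, auc = m$auc[["auc"]],
               ci_lower = m$auc[["lower"]], ci_upper = m$auc[["upper"]],
               boundary = m$model$probability_boundary)
  }))
  if (!is.null(bundle$ki67)) {
    aucs <- rbind(aucs, data.frame(
      marker = "Ki67", auc = bundle$ki67$auc[["auc"]],
      ci_lower = bundle$ki67$auc[["lower"]],
      ci_upper = bundle$ki67$auc[["upper"]],
      boundary = bundle$ki67$percent_boundary))
  }
  tsv(aucs, "marker_aucs.tsv")
  for (mk in names(bundle$markers)) {
    tsv(as.data.frame(bundle$markers[[mk]]$roc),
        paste0("roc_", mk, ".tsv"))
    tsv(data.frame(sample = names(bundle$markers[[mk]]$cv_scores),
                   score = unname(bundle$markers[[mk]]$cv_scores),
                   fold = attr(bundle$markers[[mk]]$cv_scores, "fold")),
        paste0("cv_scores_", mk, ".tsv"))
  }
  reclass <- as.data.frame(bundle$reclassification)
  tsv(reclass, "tg_reclassification.tsv")
  tg_coefs <- do.call(rbind, lapply(names(bundle$tg$components),
    function(comp) {
      cf <- bundle$tg$components[[comp]]$coefficients
      nz <- cf[cf != 0]
      if (!length(nz)) return(NULL)
      data.frame(component = comp, gene = names(nz), coefficient = unname(nz))
    }))
  if (!is.null(tg_coefs)) tsv(tg_coefs, "tg_model.tsv")
  if (!is.null(bundle$subtype)) {
    tsv(as.data.frame(bundle$subtype$distribution), "subtype_distribution.tsv")
  }
  tsv(bundle$cnv_calls, "cnv_calls.tsv")
  if (nrow(bundle$actionability$best)) {
    tsv(bundle$actionability$best, "actionability_best.tsv")
  }
  tsv(bundle$actionability$summary$by_phase, "actionability_by_phase.tsv")
  if (nrow(bundle$actionability$flags)) {
    tsv(bundle$actionability$flags, "key_gene_flags.tsv")
  }
  invisible(outdir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle> seed", x$seed, "\n")
  for (mk in names(x$markers)) {
    a <- x$markers[[mk]]$auc
    cat(sprintf("  %-5s nested-CV AUC %.3f (95%% CI %.3f-%.3f), boundary %.3f\n",
                mk, a[["auc"]], a[["lower"]], a[["upper"]],
                x$markers[[mk]]$model$probability_boundary))
  }
  if (!is.null(x$ki67)) {
    a <- x$ki67$auc
    cat(sprintf("  Ki-67 nested-CV AUC %.3f (95%% CI %.3f-%.3f)\n",
                a[["auc"]], a[["lower"]], a[["upper"]]))
  }
  cat(sprintf("  TG: grade 1 vs 3 AUC %.3f, boundary %.3f\n",
              x$tg$cv_auc, x$tg$score_boundary))
  print(x$reclassification)
  if (!is.null(x$subtype)) {
    cat("  subtype calls:\n")
    print(x$subtype$distribution)
  }
  s <- x$actionability$summary
  cat(sprintf("  actionable: %d patients (%.0f%%)\n", s$n_matched,
              s$pct_matched))
  invisible(x)
}
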