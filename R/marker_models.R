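#' Single-gene logistic marker model
#'
#' Fits a maximum-likelihood logistic regression of a binary receptor status
#' on the log2 expression of its marker gene (ESR1 for ER, PGR for PR, ERBB2
#' for HER2), by iteratively reweighted least squares with a tiny ridge
#' penalty (1e-8) on the slope so that perfectly separable data still yield
#' finite estimates.
#'
#' @param values per-sample log2 expression of the marker gene.
#' @param labels binary status labels.
#' @param marker optional marker name (ER, PR, HER2) for display.
#' @param gene optional gene identifier for display.
#' @param positive positive label when it cannot be inferred.
#' @return A `marker_model` with `intercept`, `slope` and (once set by the
#'   caller from ROC analysis) `probability_boundary`.
#' @export
fit_single_gene_logistic <- function(values, labels, marker = NA_character_,
                                     gene = NA_character_, positive = NULL) {
  y <- as_binary_labels(labels, positive)
  check_two_classes(y)
  if (length(values) != length(y)) stop("values and labels differ in length")
  if (length(y) < 4L) stop("at least 4 samples are required")
  # centring the predictor decouples slope and intercept, so the ridge
  # guard pins the slope (not the fitted mean) on degenerate inputs
  xbar <- mean(values)
  x <- unname(cbind(1, as.numeric(values) - xbar))
  beta <- c(stats::qlogis(mean(y)), 0)
  ridge <- diag(c(0, 1e-8))
  for (it in seq_len(200L)) {
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    xtw <- t(x * w)
    new <- solve(xtw %*% x + ridge, xtw %*% z)
    if (max(abs(new - beta)) < 1e-10) { beta <- drop(new); break }
    beta <- drop(new)
  }
  structure(list(marker = marker, gene = gene,
                 intercept = unname(beta[1L] - beta[2L] * xbar),
                 slope = unname(beta[2L]),
                 probability_boundary = NA_real_),
            class = "marker_model")
}

#' @export
print.marker_model <- function(x, ...) {
  cat(sprintf("<marker_model> %s (~%s): logit(p) = %.4f + %.4f * log2(expr)\n",
              x$marker, x$gene, x$intercept, x$slope))
  if (!is.na(x$probability_boundary)) {
    cat(sprintf("  probability boundary: %.4f\n", x$probability_boundary))
  }
  invisible(x)
}

#' @export
coef.marker_model <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.marker_model <- function(object, newdata, ...) {
  stats::plogis(object$intercept + object$slope * newdata)
}

#' Elastic-net model with inner-CV penalty selection
#'
#' Fits an elastic net (glmnet) with the L1/L2 mixing weight fixed at
#' `alpha` (default 0.5) and the penalty strength `lambda` chosen by
#' k-fold inner cross-validation: the grid value minimizing the mean
#' held-out deviance (binomial) or squared error (linear) wins, and the
#' model is refit on all supplied data at that value.
#'
#' @param m an [expr_matrix()] on the log2 scale (genes x samples).
#' @param response numeric response (family "linear") or binary labels
#'   (family "binomial").
#' @param family `"linear"` or `"binomial"`.
#' @param alpha elastic-net mixing weight.
#' @param lambda_grid penalty grid; by default 50 values log-spaced from
#'   the smallest lambda that zeroes all coefficients down by a factor 1e-4.
#' @param inner_folds folds for penalty selection.
#' @param seed seed controlling fold assignment.
#' @param positive positive label when it cannot be inferred.
#' @return A `penalized_model` with `coefficients` (named, genes),
#'   `intercept`, `alpha`, `lambda`, `lambda_grid`, `family`, `genes`.
#' @export
fit_elastic_net <- function(m, response, family = c("binomial", "linear"),
                            alpha = 0.5, lambda_grid = NULL,
                            inner_folds = 5L, seed = 1L, positive = NULL) {
  family <- match.arg(family)
  if (!inherits(m, "expr_matrix")) stop("not an expr_matrix")
  if (expr_scale(m) != "log2") stop("fit_elastic_net expects scale = log2")
  x <- t(unclass(m))
  n <- nrow(x)
  if (family == "binomial") {
    y <- as_binary_labels(response, positive)
    check_two_classes(y)
  } else {
    y <- as.numeric(response)
  }
  if (length(y) != n) stop("response length does not match sample count")
  if (n < inner_folds) stop("fewer samples than inner folds")
  glm_family <- if (family == "binomial") "binomial" else "gaussian"
  # small grade-1/3 training subsets legitimately trip glmnet's small-class
  # advisory; everything else is let through
  quiet_glmnet <- function(...) {
    withCallingHandlers(glmnet::glmnet(...), warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  }

  if (is.null(lambda_grid)) {
    # lambda_max from glmnet's own path start, then 50 log-spaced values
    # down by 1e-4.
    lmax <- quiet_glmnet(x, y, family = glm_family, alpha = alpha,
                         nlambda = 3, lambda.min.ratio = 0.5)$lambda[1L]
    lambda_grid <- exp(seq(log(lmax), log(lmax * 1e-4), length.out = 50L))
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)

  if (length(lambda_grid) > 1L) {
    folds <- with_stream(seed, "inner_cv",
      make_folds(n, inner_folds,
                 strata = if (family == "binomial") y else NULL))
    dev <- matrix(NA_real_, nrow = inner_folds, ncol = length(lambda_grid))
    for (f in seq_len(inner_folds)) {
      tr <- folds != f
      fit <- quiet_glmnet(x[tr, , drop = FALSE], y[tr],
                          family = glm_family, alpha = alpha,
                          lambda = lambda_grid)
      pred <- stats::predict(fit, newx = x[!tr, , drop = FALSE],
                             s = lambda_grid, type = "response")
      yv <- y[!tr]
      if (family == "binomial") {
        p <- pmin(pmax(pred, 1e-12), 1 - 1e-12)
        dev[f, ] <- colMeans(-2 * (yv * log(p) + (1 - yv) * log(1 - p)))
      } else {
        dev[f, ] <- colMeans((pred - yv)^2)
      }
    }
    lambda <- lambda_grid[which.min(colMeans(dev))]
  } else {
    lambda <- lambda_grid
  }

  fit <- quiet_glmnet(x, y, family = glm_family, alpha = alpha,
                      lambda = lambda_grid, thresh = 1e-12)
  cf <- stats::coef(fit, s = lambda)
  beta <- as.numeric(cf)[-1L]
  names(beta) <- rownames(m)
  structure(list(coefficients = beta, intercept = as.numeric(cf)[1L],
                 alpha = alpha, lambda = lambda, lambda_grid = lambda_grid,
                 family = family, genes = rownames(m)),
            class = "penalized_model")
}

#' @export
print.penalized_model <- function(x, ...) {
  cat(sprintf(
    "<penalized_model> %s elastic net (alpha = %g, lambda = %.4g): %d/%d non-zero genes\n",
    x$family, x$alpha, x$lambda, sum(x$coefficients != 0),
    length(x$coefficients)))
  invisible(x)
}

#' @export
coef.penalized_model <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' @export
predict.penalized_model <- function(object, newdata,
                                    type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "expr_matrix")) {
    miss <- setdiff(object$genes, rownames(newdata))
    if (length(miss)) {
      stop("model gene(s) missing from expression matrix: ",
           paste(miss, collapse = ", "))
    }
    newdata <- t(unclass(newdata)[object$genes, , drop = FALSE])
  }
  eta <- drop(newdata %*% object$coefficients) + object$intercept
  if (object$family == "binomial" && type == "response") {
    stats::plogis(eta)
  } else eta
}

#' Nested cross-validation out-of-fold scores
#'
#' Scores every sample exactly once with a model whose training and tuning
#' never saw it: outer folds hold out the test samples, and any penalty
#' selection happens in inner folds on outer-training data only. Fold
#' assignment is stratified by class and deterministic given the seed.
#'
#' @param m an [expr_matrix()] on the log2 scale.
#' @param labels response: binary labels, or numeric for a linear model.
#' @param model_spec a list describing the model: either
#'   `list(type = "single_gene_logistic", gene = "ESR1")` or
#'   `list(type = "elastic_net", family = "binomial"|"linear",
#'   alpha = 0.5)`.
#' @param outer_k,inner_k outer and inner fold counts (both >= 2).
#' @param seed fold-assignment seed.
#' @param positive positive label when it cannot be inferred.
#' @return Numeric out-of-fold scores named by sample (probabilities for
#'   classification, predicted values for linear models), with the fold
#'   assignment in attribute `"fold"`.
#' @export
nested_cv_scores <- function(m, labels, model_spec, outer_k = 5L,
                             inner_k = 5L, seed = 1L, positive = NULL) {
  if (!inherits(m, "expr_matrix")) stop("not an expr_matrix")
  if (outer_k < 2L || inner_k < 2L) stop("fold counts must be >= 2")
  n <- ncol(m)
  binomial <- !identical(model_spec$family, "linear")
  y <- if (binomial) as_binary_labels(labels, positive) else as.numeric(labels)
  if (binomial) check_two_classes(y)
  folds <- with_stream(seed, "outer_cv",
    make_folds(n, outer_k, strata = if (binomial) y else NULL))
  scores <- rep(NA_real_, n)
  names(scores) <- colnames(m)
  for (f in seq_len(outer_k)) {
    tr <- folds != f
    if (binomial && length(unique(y[tr])) < 2L) {
      stop("a class is absent from an outer training fold; use fewer folds")
    }
    m_tr <- expr_subset(m, samples = which(tr))
    m_te <- expr_subset(m, samples = which(!tr))
    if (identical(model_spec$type, "single_gene_logistic")) {
      g <- model_spec$gene
      if (!g %in% rownames(m)) stop("gene not in matrix: ", g)
      fit <- fit_single_gene_logistic(unclass(m_tr)[g, ], y[tr])
      scores[!tr] <- predict(fit, unclass(m_te)[g, ])
    } else if (identical(model_spec$type, "elastic_net")) {
      fit <- fit_elastic_net(
        m_tr, y[tr],
        family = if (binomial) "binomial" else "linear",
        alpha = model_spec$alpha %||% 0.5,
        inner_folds = inner_k,
        seed = stream_seed(seed, paste0("outer_fold_", f)))
      scores[!tr] <- predict(fit, m_te)
    } else {
      stop("unknown model_spec type: ", model_spec$type)
    }
  }
  attr(scores, "fold") <- folds
  scores
}
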