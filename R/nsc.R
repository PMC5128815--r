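#' Train a nearest shrunken centroid (NSC) classifier
#'
#' Implements the shrunken-centroid classifier used for intrinsic
#' breast-cancer subtyping over a PAM50-style gene panel (Basal, LumA, LumB,
#' Her2; the Normal-like class is not modelled). Standardized class-vs-
#' overall centroid differences
#' `d_ik = (xbar_ik - xbar_i) / (m_k * (s_i + s0))` are soft-thresholded by
#' the shrinkage parameter delta,
#' `d'_ik = sign(d_ik) * max(|d_ik| - delta, 0)`, and the shrunken
#' centroids are reconstructed as `xbar'_ik = xbar_i + m_k * (s_i + s0) *
#' d'_ik`. `s_i` is the pooled within-class standard deviation, `s0` its
#' median across genes.
#'
#' @param m an [expr_matrix()] on the log2 scale.
#' @param labels class label per sample (>= 2 classes, each with >= 2
#'   samples).
#' @param delta shrinkage amount (>= 0); 0 means no shrinkage.
#' @param priors class priors; defaults to empirical class frequencies.
#' @param norm_constant `"plus"` for `m_k = sqrt(1/n_k + 1/n)` (the
#'   published form) or `"minus"` for `sqrt(1/n_k - 1/n)` as used by some
#'   implementations.
#' @return A `nsc_model` with `classes`, `overall_centroid`,
#'   `shrunken_centroids` (genes x classes), `d` (shrunken standardized
#'   differences), `s`, `s0`, `priors`, `delta`, `genes`.
#' @export
train_nsc <- function(m, labels, delta = 0, priors = NULL,
                      norm_constant = c("plus", "minus")) {
  norm_constant <- match.arg(norm_constant)
  if (!inherits(m, "expr_matrix")) stop("not an expr_matrix")
  if (expr_scale(m) != "log2") stop("train_nsc expects scale = log2")
  if (delta < 0) stop("delta must be >= 0")
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(m))
  classes <- unique(labels)
  # canonical tie-break order for the intrinsic subtypes
  if (setequal(classes, subtype_classes())) classes <- subtype_classes()
  if (length(classes) < 2L) stop("at least 2 classes are required")
  nk <- table(factor(labels, levels = classes))
  small <- names(nk)[nk < 2L]
  if (length(small)) {
    stop("class(es) with fewer than 2 samples: ",
         paste(small, collapse = ", "))
  }
  x <- unclass(m)
  n <- ncol(x); K <- length(classes)
  overall <- rowMeans(x)
  centroids <- vapply(classes,
                      function(k) rowMeans(x[, labels == k, drop = FALSE]),
                      numeric(nrow(x)))
  # pooled within-class variance with n - K degrees of freedom
  ss <- 0
  for (k in classes) {
    xk <- x[, labels == k, drop = FALSE]
    ss <- ss + rowSums((xk - centroids[, k])^2)
  }
  s <- sqrt(ss / (n - K))
  s0 <- stats::median(s)
  mk <- if (norm_constant == "plus") sqrt(1 / as.numeric(nk) + 1 / n)
        else sqrt(pmax(1 / as.numeric(nk) - 1 / n, 0))
  names(mk) <- classes
  d <- sweep(centroids - overall, 1L, s + s0, "/")
  d <- sweep(d, 2L, mk, "/")
  d_shrunk <- sign(d) * pmax(abs(d) - delta, 0)
  shrunken <- overall + sweep(sweep(d_shrunk, 1L, s + s0, "*"), 2L, mk, "*")
  if (is.null(priors)) priors <- as.numeric(nk) / n
  if (length(priors) != K || any(priors < 0)) stop("invalid priors")
  priors <- priors / sum(priors)
  names(priors) <- classes
  structure(list(classes = classes, overall_centroid = overall,
                 shrunken_centroids = shrunken, d = d_shrunk, s = s,
                 s0 = s0, priors = priors, delta = delta,
                 norm_constant = norm_constant, genes = rownames(m)),
            class = "nsc_model")
}

#' @export
print.nsc_model <- function(x, ...) {
  active <- sum(rowSums(x$d != 0) > 0)
  cat(sprintf(
    "<nsc_model> %d classes (%s), %d genes (%d unshrunk), delta = %g\n",
    length(x$classes), paste(x$classes, collapse = ", "),
    length(x$genes), active, x$delta))
  invisible(x)
}

#' Classify samples with a shrunken-centroid model
#'
#' Computes the per-class discriminant
#' `delta_k(x) = sum_i (x_i - xbar'_ik)^2 / (s_i + s0)^2 - 2 log pi_k`
#' and assigns each sample to the class minimizing it; ties break by the
#' model's fixed class order.
#'
#' @param model a `nsc_model`.
#' @param m an [expr_matrix()] (or a named numeric vector for one sample)
#'   containing all model genes.
#' @return A list with `subtype` (named character) and `scores` (samples x
#'   classes discriminant matrix).
#' @export
classify_nsc <- function(model, m) {
  if (!inherits(model, "nsc_model")) stop("not a nsc_model")
  if (inherits(m, "expr_matrix")) {
    miss <- setdiff(model$genes, rownames(m))
    if (length(miss)) {
      stop("model gene(s) missing: ", paste(miss, collapse = ", "))
    }
    x <- unclass(m)[model$genes, , drop = FALSE]
  } else {
    miss <- setdiff(model$genes, names(m))
    if (length(miss)) {
      stop("model gene(s) missing: ", paste(miss, collapse = ", "))
    }
    x <- matrix(m[model$genes], ncol = 1,
                dimnames = list(model$genes, "sample"))
  }
  denom <- (model$s + model$s0)^2
  scores <- vapply(model$classes, function(k) {
    colSums((x - model$shrunken_centroids[, k])^2 / denom) -
      2 * log(model$priors[k])
  }, numeric(ncol(x)))
  if (ncol(x) == 1L) scores <- matrix(scores, nrow = 1,
                                      dimnames = list(colnames(x),
                                                      model$classes))
  assigned <- model$classes[apply(scores, 1L, which.min)]
  names(assigned) <- colnames(x)
  list(subtype = assigned, scores = scores)
}

#' @export
predict.nsc_model <- function(object, newdata, ...) {
  classify_nsc(object, newdata)$subtype
}
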