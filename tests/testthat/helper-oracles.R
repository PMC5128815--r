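# Independent brute-force oracles used across the suite. These are written
# against the definitions, not against the package internals.

# AUC as the fraction of (positive, negative) pairs ranked correctly, with
# 0.5 credit for ties.
oracle_auc_pairs01 <- function(scores, y01) {
  pos <- scores[y01 == 1L]
  neg <- scores[y01 == 0L]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# Standardized nearest-centroid assignment (no shrinkage), computed from
# first principles.
oracle_nearest_centroid <- function(x, labels, newx, priors = NULL) {
  classes <- unique(labels)
  n <- ncol(x); K <- length(classes)
  cent <- sapply(classes, function(k) rowMeans(x[, labels == k, drop = FALSE]))
  ss <- 0
  for (k in classes) {
    xk <- x[, labels == k, drop = FALSE]
    ss <- ss + rowSums((xk - cent[, k])^2)
  }
  s <- sqrt(ss / (n - K))
  s0 <- stats::median(s)
  if (is.null(priors)) priors <- table(factor(labels, levels = classes)) / n
  scores <- sapply(classes, function(k) {
    sum((newx - cent[, k])^2 / (s + s0)^2) - 2 * log(priors[[k]])
  })
  classes[which.min(scores)]
}

# Two-sided Fisher exact p for a 2 x k table by full enumeration over all
# tables with the observed margins (same <= tolerance as fisher.test).
oracle_fisher_2xk <- function(tab) {
  col_tot <- colSums(tab)
  r1 <- sum(tab[1, ])
  n <- sum(tab)
  log_p <- function(a) {
    sum(lchoose(col_tot, a)) - lchoose(n, r1)
  }
  k <- length(col_tot)
  cells <- vector("list", k)
  enumerate <- function(j, remaining, acc) {
    if (j == k) {
      if (remaining >= 0 && remaining <= col_tot[k]) {
        return(list(c(acc, remaining)))
      }
      return(list())
    }
    out <- list()
    for (a in 0:min(col_tot[j], remaining)) {
      out <- c(out, enumerate(j + 1L, remaining - a, c(acc, a)))
    }
    out
  }
  tables <- enumerate(1L, r1, integer(0))
  probs <- vapply(tables, function(a) exp(log_p(a)), numeric(1))
  p_obs <- exp(log_p(tab[1, ]))
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Welch two-sided t-test p from the textbook formula.
oracle_welch_p <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * stats::pt(-abs(t), df)
}

# Per-patient best-match tally computed by exhaustive looping over a match
# table, independent of the package's implementation.
oracle_best_matches <- function(matches) {
  phases <- c("approved", "late", "early")
  out <- list()
  for (p in sort(unique(matches$patient))) {
    sub <- matches[matches$patient == p, , drop = FALSE]
    best_rank <- min(match(sub$phase, phases))
    sub <- sub[match(sub$phase, phases) == best_rank, , drop = FALSE]
    sub <- sub[order(sub$gene, sub$therapy), , drop = FALSE]
    out[[p]] <- sub[1L, , drop = FALSE]
  }
  do.call(rbind, out)
}

# A tiny log2-scale expr_matrix from a plain matrix.
as_log2_expr <- function(values) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("G%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("S%03d", seq_len(ncol(values)))
  }
  expr_matrix(values, scale = "log2")
}

table1_path <- function() {
  system.file("extdata", "table1_reexam.csv", package = "seqdx")
}

toy_kb_path <- function() {
  system.file("extdata", "toy_knowledge_base.tsv", package = "seqdx")
}
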