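kb_phases <- function() c("approved", "late", "early")

#' Read an actionability knowledge base
#'
#' TSV with columns gene, alteration_class, therapy, indication
#' ("breast"/"other"), phase ("approved"/"late"/"early") and an optional
#' requires_her2_positive logical column for composite (two-condition)
#' entries. A 15-entry illustrative knowledge base ships with the package at
#' `system.file("extdata", "toy_knowledge_base.tsv", package = "seqdx")`.
#'
#' @param path TSV path.
#' @return data.frame knowledge base.
#' @export
read_knowledge_base <- function(path) {
  kb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "alteration_class", "therapy", "indication", "phase")
  miss <- setdiff(need, names(kb))
  if (length(miss)) {
    stop("knowledge base missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- setdiff(unique(kb$alteration_class), alteration_classes())
  if (length(bad)) {
    stop("unknown alteration_class in knowledge base: ",
         paste(bad, collapse = ", "))
  }
  if (!all(kb$phase %in% kb_phases())) {
    stop("phase must be one of: ", paste(kb_phases(), collapse = ", "))
  }
  if (!all(kb$indication %in% c("breast", "other"))) {
    stop("indication must be 'breast' or 'other'")
  }
  if (!"requires_her2_positive" %in% names(kb)) {
    kb$requires_her2_positive <- FALSE
  }
  kb$requires_her2_positive[is.na(kb$requires_her2_positive)] <- FALSE
  kb
}

#' Match patient alterations against a knowledge base
#'
#' An alteration matches an entry when gene and alteration class agree and
#' the entry's indication falls within scope. Only somatic alterations are
#' matched. Under `scope = "breast_only"` the ERBB2 amplification is
#' excluded (its therapy being already established practice for
#' HER2-positive disease). Entries flagged `requires_her2_positive` match
#' only patients whose HER2 status (if supplied) is positive.
#'
#' @param alterations data.frame: patient, gene, alteration_class, origin,
#'   protein_change.
#' @param kb knowledge base from [read_knowledge_base()].
#' @param scope `"breast_only"` or `"any_indication"`.
#' @param her2_status optional named vector of "+"/"-" per patient, used
#'   for composite entries.
#' @return data.frame of matches: patient, gene, alteration_class,
#'   protein_change, therapy, indication, phase.
#' @export
match_patient <- function(alterations, kb,
                          scope = c("breast_only", "any_indication"),
                          her2_status = NULL) {
  scope <- match.arg(scope)
  bad <- setdiff(unique(alterations$alteration_class), alteration_classes())
  if (length(bad)) {
    stop("unknown alteration_class: ", paste(bad, collapse = ", "))
  }
  if (!all(alterations$origin %in% c("somatic", "germline"))) {
    stop("origin must be 'somatic' or 'germline'")
  }
  som <- alterations[alterations$origin == "somatic", , drop = FALSE]
  kb_use <- if (scope == "breast_only") {
    kb[kb$indication == "breast" &
         !(kb$gene == "ERBB2" & kb$alteration_class == "amplification"), ,
       drop = FALSE]
  } else kb
  if (scope == "breast_only") {
    som <- som[!(som$gene == "ERBB2" &
                   som$alteration_class == "amplification"), , drop = FALSE]
  }
  out <- merge(som, kb_use, by = c("gene", "alteration_class"))
  if (nrow(out) && any(out$requires_her2_positive)) {
    ok <- !out$requires_her2_positive
    if (!is.null(her2_status)) {
      ok <- ok | (her2_status[out$patient] %in% "+")
    }
    out <- out[ok, , drop = FALSE]
  }
  cols <- c("patient", "gene", "alteration_class", "protein_change",
            "therapy", "indication", "phase")
  out <- out[cols]
  out[order(out$patient, out$gene, out$therapy), , drop = FALSE]
}

#' Keep each patient's single highest-priority match
#'
#' Priority is approved > late phase > early phase; ties within a phase
#' break by (gene, therapy) lexicographic order.
#'
#' @param matches match table from [match_patient()].
#' @return data.frame with at most one row per patient.
#' @export
best_match_per_patient <- function(matches) {
  if (!nrow(matches)) return(matches)
  rank <- match(matches$phase, kb_phases())
  ord <- order(matches$patient, rank, matches$gene, matches$therapy)
  m <- matches[ord, , drop = FALSE]
  out <- m[!duplicated(m$patient), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cohort-level actionability summary
#'
#' Counts matched patients per study phase (from the per-patient best
#' matches) and, separately, the matched patients harboring any snv/indel
#' match vs any amplification/deep-deletion match (from the full match
#' list; a patient can appear in both).
#'
#' @param best per-patient best matches from [best_match_per_patient()].
#' @param matches full match table from [match_patient()].
#' @param n_cohort cohort size for percentages.
#' @return List with `by_phase` (counts and percentages per phase),
#'   `n_matched`, `pct_matched`, `n_snv_indel`, `n_cnv`.
#' @export
summarize_cohort <- function(best, matches, n_cohort) {
  if (anyDuplicated(best$patient)) {
    stop("best matches must be unique per patient")
  }
  phase_counts <- vapply(kb_phases(),
                         function(p) sum(best$phase == p), 0L)
  snv_patients <- unique(matches$patient[
    matches$alteration_class %in% c("snv", "indel")])
  cnv_patients <- unique(matches$patient[
    matches$alteration_class %in% c("amplification", "deep_deletion")])
  list(
    by_phase = data.frame(phase = kb_phases(), n = as.integer(phase_counts),
                          pct = 100 * as.integer(phase_counts) / n_cohort),
    n_matched = nrow(best),
    pct_matched = 100 * nrow(best) / n_cohort,
    n_snv_indel = length(snv_patients),
    n_cnv = length(cnv_patients)
  )
}

#' Flag ERBB2-mutant/HER2-negative and BRCA1/2 carriers
#'
#' Flag A marks patients with a somatic ERBB2 snv or indel who are
#' HER2-negative by routine status (candidates for HER2 kinase-inhibitor
#' discussion: activating ERBB2 mutations can drive signaling at normal
#' protein levels). Flag B marks any BRCA1/BRCA2 alteration, annotated
#' somatic vs germline.
#'
#' @param alterations alteration table.
#' @param her2_status_per_patient named vector of "+"/"-" per patient.
#' @return data.frame: patient, flag ("erbb2_mutant_her2_negative" or
#'   "brca_carrier"), gene, origin, protein_change, her2_status.
#' @export
flag_key_genes <- function(alterations, her2_status_per_patient) {
  rows <- list()
  status_of <- function(p) {
    s <- her2_status_per_patient[p]
    if (is.null(s) || is.na(s)) "missing" else unname(s)
  }
  erbb2 <- alterations[alterations$gene == "ERBB2" &
                         alterations$origin == "somatic" &
                         alterations$alteration_class %in% c("snv", "indel"), ,
                       drop = FALSE]
  for (i in seq_len(nrow(erbb2))) {
    st <- status_of(erbb2$patient[i])
    if (st %in% c("-", "negative", "missing")) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient = erbb2$patient[i], flag = "erbb2_mutant_her2_negative",
        gene = "ERBB2", origin = "somatic",
        protein_change = erbb2$protein_change[i], her2_status = st,
        stringsAsFactors = FALSE)
    }
  }
  brca <- alterations[alterations$gene %in% c("BRCA1", "BRCA2"), ,
                      drop = FALSE]
  for (i in seq_len(nrow(brca))) {
    rows[[length(rows) + 1L]] <- data.frame(
      patient = brca$patient[i], flag = "brca_carrier",
      gene = brca$gene[i], origin = brca$origin[i],
      protein_change = brca$protein_change[i],
      her2_status = status_of(brca$patient[i]),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(patient = character(), flag = character(),
                      gene = character(), origin = character(),
                      protein_change = character(),
                      her2_status = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
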