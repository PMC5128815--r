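#' ER (or PR) status from routine assays
#'
#' Immunohistochemistry is preferred when both assays are present: a tumor
#' is positive when 10% or more cells stain. For the radioimmunoassay used
#' on older samples, positive means strictly more than 0.05 fmol/ug DNA.
#'
#' @param ihc_percent percent of positively stained cells (0-100), or `NA`.
#' @param ria_value radioimmunoassay value in fmol/ug DNA, or `NA`.
#' @return `"positive"` or `"negative"`.
#' @export
er_status <- function(ihc_percent = NA, ria_value = NA) {
  if (!is.na(ihc_percent)) {
    if (ihc_percent < 0 || ihc_percent > 100) {
      stop("ihc_percent must lie in [0, 100]")
    }
    return(if (ihc_percent >= 10) "positive" else "negative")
  }
  if (!is.na(ria_value)) {
    return(if (ria_value > 0.05) "positive" else "negative")
  }
  stop("er_status needs ihc_percent or ria_value")
}

#' @rdname er_status
#' @export
pr_status <- er_status

#' HER2 status from routine assays
#'
#' In-situ hybridization (FISH/SISH) is decisive when present: amplified
#' means positive. Without an ISH result, only an IHC grade of 3+ is
#' positive.
#'
#' @param ihc_grade HER2 IHC grade: one of "0", "1+", "2+", "3+", or `NA`.
#' @param ish_result "amplified", "not_amplified", or `NA`.
#' @return `"positive"` or `"negative"`.
#' @export
her2_status <- function(ihc_grade = NA, ish_result = NA) {
  if (!is.na(ish_result)) {
    if (!ish_result %in% c("amplified", "not_amplified")) {
      stop("ish_result must be 'amplified' or 'not_amplified'")
    }
    return(if (ish_result == "amplified") "positive" else "negative")
  }
  if (!is.na(ihc_grade)) {
    if (!ihc_grade %in% c("0", "1+", "2+", "3+")) {
      stop("ihc_grade must be one of 0, 1+, 2+, 3+")
    }
    return(if (ihc_grade == "3+") "positive" else "negative")
  }
  stop("her2_status needs ihc_grade or ish_result")
}

#' Ki-67 proliferation status
#'
#' A percent value of 20 or more is high; categorical "high"/"low" records
#' pass through unchanged.
#'
#' @param value percent of positively stained cells, or "high"/"low".
#' @return `"high"` or `"low"`.
#' @export
ki67_status <- function(value) {
  if (length(value) != 1L || is.na(value)) stop("ki67 value is missing")
  if (is.character(value)) {
    if (!value %in% c("high", "low")) {
      stop("categorical Ki-67 must be 'high' or 'low'")
    }
    return(value)
  }
  if (value < 0 || value > 100) stop("Ki-67 percent must lie in [0, 100]")
  if (value >= 20) "high" else "low"
}

#' Load re-examination records for discordant ER/HER2 tumors
#'
#' Reads a wide CSV transcription of a histopathological re-examination
#' table (one row per examined tumor piece; columns for the medical-record,
#' sequencing-based and re-examined status of ER and HER2) and reshapes it
#' into one long record per (patient, piece, marker). The packaged fixture
#' is available via
#' `system.file("extdata", "table1_reexam.csv", package = "seqdx")`.
#'
#' @param path CSV path.
#' @return data.frame: patient, piece, marker, medical_status, seq_status,
#'   reexam_status (statuses "positive"/"negative"/"missing").
#' @export
read_reexam_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  to_status <- function(x) {
    ifelse(is.na(x), "missing",
           ifelse(x == "+", "positive",
                  ifelse(x == "-", "negative", "missing")))
  }
  rows <- list()
  for (i in seq_len(nrow(df))) {
    markers <- strsplit(df$discordant_marker[i], "/", fixed = TRUE)[[1L]]
    for (mk in markers) {
      cols <- if (mk == "ER") c("med_er", "seq_er", "reexam_er")
              else c("med_her2", "seq_her2", "reexam_her2")
      rows[[length(rows) + 1L]] <- data.frame(
        patient = df$patient[i],
        piece = if (is.na(df$piece[i])) "" else as.character(df$piece[i]),
        marker = mk,
        medical_status = to_status(df[[cols[1L]]][i]),
        seq_status = to_status(df[[cols[2L]]][i]),
        reexam_status = to_status(df[[cols[3L]]][i]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Re-examination concordance summary
#'
#' For each marker, counts distinct re-examined patients and those
#' reclassified-and-concordant: a patient counts when ANY of its examined
#' pieces has a re-examined status that differs from the medical-record
#' status AND equals the sequencing-based status. Multi-piece patients
#' count once.
#'
#' @param records long-format records as from [read_reexam_records()].
#' @return data.frame per marker: n_reexamined, n_reclassified_concordant,
#'   percentage (`NA` when no patients were re-examined).
#' @export
reexam_concordance <- function(records) {
  need <- c("patient", "marker", "medical_status", "seq_status",
            "reexam_status")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("records missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- records$seq_status == "missing"
  if (any(bad)) {
    stop("record(s) missing sequencing-based status for patient(s): ",
         paste(unique(records$patient[bad]), collapse = ", "))
  }
  markers <- unique(records$marker)
  if (!length(markers)) {
    return(data.frame(marker = character(), n_reexamined = integer(),
                      n_reclassified_concordant = integer(),
                      percentage = numeric(), stringsAsFactors = FALSE))
  }
  out <- lapply(markers, function(mk) {
    sub <- records[records$marker == mk & records$reexam_status != "missing", ]
    patients <- unique(sub$patient)
    hit <- vapply(patients, function(p) {
      pieces <- sub[sub$patient == p, ]
      any(pieces$reexam_status != pieces$medical_status &
            pieces$reexam_status == pieces$seq_status)
    }, logical(1))
    data.frame(marker = mk, n_reexamined = length(patients),
               n_reclassified_concordant = sum(hit),
               percentage = if (length(patients)) {
                 100 * sum(hit) / length(patients)
               } else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
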