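#' Write a synthetic cohort to disk
#'
#' Persists the cohort in the plain-text formats the rest of the package
#' reads: expression as TSV, clinical labels as CSV, alterations both as a
#' MAF-like TSV and as a minimal VCF v4.2 (per-sample genotypes with
#' GENE/CLASS/ORIGIN INFO annotations), and copy-number bins as a BED-like
#' TSV (0-based half-open) with sample and role columns.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @param directory output directory; created if absent.
#' @return Named character vector of the five written files (the manifest).
#' @export
write_cohort <- function(cohort, directory) {
  if (!inherits(cohort, "synthetic_cohort")) stop("not a synthetic_cohort")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  manifest <- c(
    expression = file.path(directory, "expression.tsv"),
    clinical = file.path(directory, "clinical.csv"),
    alterations_maf = file.path(directory, "alterations.maf.tsv"),
    alterations_vcf = file.path(directory, "alterations.vcf"),
    bins = file.path(directory, "bins.tsv")
  )
  write_expression(cohort$expression, manifest[["expression"]])
  utils::write.csv(cohort$clinical, manifest[["clinical"]], row.names = FALSE)
  utils::write.table(cohort$alterations, manifest[["alterations_maf"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_alterations_vcf(cohort$alterations, cohort$clinical$sample,
                        manifest[["alterations_vcf"]])
  bins <- rbind(
    cbind(role = "tumor", bind_bins(cohort$tumor_bins)),
    cbind(role = "baseline", bind_bins(cohort$baseline_bins))
  )
  utils::write.table(bins, manifest[["bins"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest
}

bind_bins <- function(bin_list) {
  do.call(rbind, lapply(names(bin_list), function(s) {
    cbind(sample = s, bin_list[[s]])
  }))
}

#' Read a clinical label table
#'
#' @param path CSV with columns sample, er, pr, her2, ki67_percent, mitotic,
#'   nuclear_atypia, tubular_formation, grade.
#' @return data.frame.
#' @export
read_clinical <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read somatic/germline alterations from a MAF-like TSV
#'
#' @param path TSV with columns patient, gene, alteration_class, origin,
#'   protein_change.
#' @return data.frame of alterations.
#' @export
read_alterations_maf <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient", "gene", "alteration_class", "origin", "protein_change")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("alteration TSV missing column(s): ", paste(miss, collapse = ", "))
  }
  df$protein_change <- as.character(df$protein_change)
  df[need]
}

alteration_classes <- function() {
  c("snv", "indel", "amplification", "deep_deletion")
}

# One VCF record per distinct (gene, class, origin, protein_change) event,
# with a 0/1 genotype per cohort sample.
write_alterations_vcf <- function(alterations, samples, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Alteration class\">",
    "##INFO=<ID=ORIGIN,Number=1,Type=String,Description=\"somatic or germline\">",
    "##INFO=<ID=PCHANGE,Number=1,Type=String,Description=\"Protein change\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  ), con)
  if (!nrow(alterations)) return(invisible(path))
  key <- with(alterations, paste(gene, alteration_class, origin,
                                 ifelse(is.na(protein_change), ".",
                                        protein_change), sep = "|"))
  events <- alterations[!duplicated(key), , drop = FALSE]
  ekey <- key[!duplicated(key)]
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    alt <- switch(ev$alteration_class,
                  snv = "T", indel = "TA",
                  amplification = "<DUP>", deep_deletion = "<DEL>")
    info <- sprintf("GENE=%s;CLASS=%s;ORIGIN=%s", ev$gene,
                    ev$alteration_class, ev$origin)
    if (!is.na(ev$protein_change)) {
      info <- paste0(info, ";PCHANGE=", ev$protein_change)
    }
    carriers <- alterations$patient[key == ekey[i]]
    gt <- ifelse(samples %in% carriers, "0/1", "0/0")
    writeLines(paste(c("1", as.character(i * 1000L), ".", "A", alt, ".",
                       "PASS", info, "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read alterations from a minimal annotated VCF
#'
#' Parses a VCF v4.2 with per-sample genotypes and GENE/CLASS/ORIGIN (and
#' optional PCHANGE) INFO annotations into the same patient-level table as
#' [read_alterations_maf()].
#'
#' @param path VCF file path.
#' @return data.frame of alterations.
#' @export
read_alterations_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  empty <- data.frame(patient = character(), gene = character(),
                      alteration_class = character(), origin = character(),
                      protein_change = character(), stringsAsFactors = FALSE)
  if (nrow(vcf@fix) == 0L) return(empty)
  info <- vcf@fix[, "INFO"]
  get_tag <- function(info, tag) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", tag, "=([^;]+)"), info))
    vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_, "")
  }
  gene <- get_tag(info, "GENE")
  class <- get_tag(info, "CLASS")
  origin <- get_tag(info, "ORIGIN")
  pchange <- get_tag(info, "PCHANGE")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  rows <- list()
  for (i in seq_len(nrow(gt))) {
    carriers <- colnames(gt)[!is.na(gt[i, ]) & gt[i, ] %in% c("0/1", "1/1", "0|1", "1|1")]
    for (p in carriers) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient = p, gene = gene[i], alteration_class = class[i],
        origin = origin[i], protein_change = pchange[i],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$patient, out$gene, out$alteration_class), , drop = FALSE]
}

#' Read BED-like copy-number bins
#'
#' @param path TSV with columns role (tumor/baseline), sample, chrom, start,
#'   end, count; 0-based half-open intervals.
#' @return Named list with `tumor` and `baseline`, each a per-sample list of
#'   bin data frames.
#' @export
read_bins <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("role", "sample", "chrom", "start", "end", "count")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("bins TSV missing column(s): ", paste(miss, collapse = ", "))
  }
  split_role <- function(role) {
    sub <- df[df$role == role, c("sample", "chrom", "start", "end", "count")]
    out <- split(sub[, -1L], sub$sample)
    lapply(out, function(x) { rownames(x) <- NULL; x })
  }
  list(tumor = split_role("tumor"), baseline = split_role("baseline"))
}
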