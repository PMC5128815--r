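check_bins <- function(bins, what) {
  need <- c("chrom", "start", "end", "count")
  miss <- setdiff(need, names(bins))
  if (length(miss)) {
    stop(what, " bins missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(bins$count < 0)) stop(what, " bins contain negative counts")
  bins
}

#' Per-bin copy-number ratios from low-pass counts
#'
#' Computes, for every bin, the ratio of library-size-normalized tumor to
#' baseline counts: `(tumor_count / tumor_total) / (baseline_count /
#' baseline_total)`, plus its log2. Bins with zero baseline count are
#' flagged and excluded from downstream gene calls. Both inputs must share
#' an identical (chrom, start, end) grid of 0-based half-open intervals.
#'
#' @param tumor,baseline data.frames with columns chrom, start, end, count.
#' @return A `ratio_profile` data.frame: chrom, start, end, tumor_count,
#'   baseline_count, ratio, log2_ratio, flagged.
#' @export
bin_log_ratio <- function(tumor, baseline) {
  tumor <- check_bins(tumor, "tumor")
  baseline <- check_bins(baseline, "baseline")
  if (nrow(tumor) != nrow(baseline)) stop("bin grids differ in length")
  mism <- which(tumor$chrom != baseline$chrom |
                tumor$start != baseline$start |
                tumor$end != baseline$end)
  if (length(mism)) {
    i <- mism[1L]
    stop(sprintf("bin grids differ, first at %s:%s-%s vs %s:%s-%s",
                 tumor$chrom[i], tumor$start[i], tumor$end[i],
                 baseline$chrom[i], baseline$start[i], baseline$end[i]))
  }
  t_tot <- sum(tumor$count)
  b_tot <- sum(baseline$count)
  if (t_tot <= 0 || b_tot <= 0) stop("total count must be positive")
  flagged <- baseline$count == 0
  ratio <- (tumor$count / t_tot) / (baseline$count / b_tot)
  ratio[flagged] <- NA_real_
  out <- data.frame(chrom = tumor$chrom, start = tumor$start,
                    end = tumor$end, tumor_count = tumor$count,
                    baseline_count = baseline$count, ratio = ratio,
                    log2_ratio = log2(ratio), flagged = flagged,
                    stringsAsFactors = FALSE)
  class(out) <- c("ratio_profile", "data.frame")
  out
}

#' Categorize a mean copy-number ratio
#'
#' Half-open thresholds: ratio < 0.6 deep_deletion; 0.6 <= ratio < 1.8
#' neutral; 1.8 <= ratio < 3.0 low_amp (the "ratio close to two" regime);
#' ratio >= 3.0 high_amp.
#'
#' @param ratio numeric mean ratio(s).
#' @return Character category vector.
#' @export
cnv_category <- function(ratio) {
  ifelse(is.na(ratio), NA_character_,
    ifelse(ratio < 0.6, "deep_deletion",
      ifelse(ratio < 1.8, "neutral",
        ifelse(ratio < 3.0, "low_amp", "high_amp"))))
}

#' Gene-level copy-number calls from a ratio profile
#'
#' Averages bin ratios over each gene region, weighting by the length of
#' the bin/region overlap, skipping flagged (zero-baseline) bins, and
#' categorizes the mean with [cnv_category()]. A region with no usable bins
#' yields a call with an `NA` category and `no_usable_bins = TRUE`, with a
#' warning.
#'
#' @param profile a `ratio_profile` from [bin_log_ratio()].
#' @param gene_regions data.frame with columns gene, chrom, start, end
#'   (0-based half-open).
#' @return data.frame: gene, chrom, start, end, mean_ratio, category,
#'   no_usable_bins.
#' @export
gene_cnv_call <- function(profile, gene_regions) {
  if (!inherits(profile, "ratio_profile")) stop("not a ratio_profile")
  need <- c("gene", "chrom", "start", "end")
  miss <- setdiff(need, names(gene_regions))
  if (length(miss)) {
    stop("gene_regions missing column(s): ", paste(miss, collapse = ", "))
  }
  out <- gene_regions[need]
  out$mean_ratio <- NA_real_
  out$no_usable_bins <- FALSE
  for (i in seq_len(nrow(out))) {
    ov_len <- pmin(profile$end, out$end[i]) -
      pmax(profile$start, out$start[i])
    usable <- profile$chrom == out$chrom[i] & ov_len > 0 & !profile$flagged
    if (!any(usable)) {
      out$no_usable_bins[i] <- TRUE
      warning("no usable bins overlap gene ", out$gene[i])
      next
    }
    w <- ov_len[usable]
    out$mean_ratio[i] <- sum(profile$ratio[usable] * w) / sum(w)
  }
  out$category <- cnv_category(out$mean_ratio)
  out
}
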