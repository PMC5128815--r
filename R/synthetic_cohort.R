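# Gene panel used for subtype centroid structure. The four routine marker
# genes (ESR1, PGR, ERBB2, MKI67) are members of the panel, as in the
# intrinsic-subtype panels used clinically.
panel_genes <- function() {
  c("ACTR3B", "ANLN", "BAG1", "BCL2", "BIRC5", "BLVRA", "CCNB1", "CCNE1",
    "CDC20", "CDC6", "CDH3", "CENPF", "CEP55", "CXXC5", "EGFR", "ERBB2",
    "ESR1", "EXO1", "FGFR4", "FOXA1", "FOXC1", "GPR160", "GRB7", "KIF2C",
    "KRT14", "KRT17", "KRT5", "MAPT", "MDM2", "MELK", "MIA", "MKI67",
    "MLPH", "MMP11", "MYBL2", "MYC", "NAT1", "NDC80", "NUF2", "ORC6",
    "PGR", "PHGDH", "PTTG1", "RRM2", "SFRP1", "SLC39A6", "TMEM45B",
    "TYMS", "UBE2C", "UBE2T")
}

subtype_classes <- function() c("Basal", "LumA", "LumB", "Her2")

# ERBB2 locus on chromosome 17 (GRCh38-like coordinates), used for the
# simulated amplifications and the gene-level CNV call.
erbb2_region <- function() {
  data.frame(gene = "ERBB2", chrom = "chr17",
             start = 39687914L, end = 39730426L,
             stringsAsFactors = FALSE)
}

#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure of a simulated breast-cancer cohort:
#' bimodal marker-gene expression by receptor status, grade-correlated gene
#' programs for the three Nottingham grade subcomponents, subtype centroid
#' structure over a 50-gene panel, ERBB2 amplification in HER2-positive
#' tumors, and configurable discordance between recorded clinical labels and
#' molecular truth.
#'
#' @param n_samples number of tumors (>= 2).
#' @param n_genes total genes in the expression matrix (panel and program
#'   genes plus background filler).
#' @param marker_shift log2-units mean expression difference of each marker
#'   gene (ESR1, PGR, ERBB2, MKI67) between positive and negative status.
#' @param noise_sd log2-units residual standard deviation.
#' @param prevalence named numeric: positive fraction for ER, PR, HER2, Ki67.
#' @param grade_program_size genes per grade-subcomponent program.
#' @param grade_effect log2-units expression shift per unit of subcomponent
#'   score (centered at score 2).
#' @param subtype_weights named mixture weights over Basal, LumA, LumB, Her2;
#'   must sum to 1.
#' @param discordance_rate fraction of samples whose recorded label for each
#'   marker is flipped relative to molecular truth.
#' @param cnv_bin_size copy-number bin width in bases.
#' @param n_bins total number of copy-number bins across the simulated genome.
#' @param bin_mean_count expected reads per bin (default reflects ~0.5x
#'   low-pass coverage at 1-Mb bins).
#' @param erbb2_amp_ratio simulated copy-number ratio of the ERBB2 locus in
#'   HER2-positive tumors.
#' @param grade2_mixture if `TRUE`, samples recorded as overall grade 2 carry
#'   latent expression programs drawn 50:50 from grade-1-like and
#'   grade-3-like profiles, while their recorded labels stay grade 2.
#' @param seed master seed; fully determines the generated cohort.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 307L,
                          n_genes = 1000L,
                          marker_shift = 2.0,
                          noise_sd = 1.0,
                          prevalence = c(ER = 0.80, PR = 0.70,
                                         HER2 = 0.15, Ki67 = 0.40),
                          grade_program_size = 30L,
                          grade_effect = 1.0,
                          subtype_weights = c(Basal = 0.12, LumA = 0.50,
                                              LumB = 0.25, Her2 = 0.13),
                          discordance_rate = 0.05,
                          cnv_bin_size = 1e6,
                          n_bins = 1000L,
                          bin_mean_count = 5000,
                          erbb2_amp_ratio = 2.0,
                          grade2_mixture = FALSE,
                          seed) {
  if (missing(seed)) stop_config("seed", "a seed is required")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_config("seed", "must be a single integer")
  }
  if (!is.numeric(n_samples) || n_samples < 2) {
    stop_config("n_samples", "must be >= 2")
  }
  markers <- c("ER", "PR", "HER2", "Ki67")
  if (!all(markers %in% names(prevalence))) {
    stop_config("prevalence", "needs entries ER, PR, HER2, Ki67")
  }
  prevalence <- prevalence[markers]
  if (any(prevalence < 0 | prevalence > 1)) {
    stop_config("prevalence", "fractions must lie in [0, 1]")
  }
  if (discordance_rate < 0 || discordance_rate > 1) {
    stop_config("discordance_rate", "must lie in [0, 1]")
  }
  cls <- subtype_classes()
  if (!all(cls %in% names(subtype_weights))) {
    stop_config("subtype_weights", "needs weights for Basal, LumA, LumB, Her2")
  }
  subtype_weights <- subtype_weights[cls]
  if (any(subtype_weights < 0)) {
    stop_config("subtype_weights", "weights must be non-negative")
  }
  if (abs(sum(subtype_weights) - 1) > 1e-9) {
    stop_config("subtype_weights", "must sum to 1 (within 1e-9)")
  }
  if (noise_sd < 0) stop_config("noise_sd", "must be non-negative")
  if (marker_shift < 0) stop_config("marker_shift", "must be non-negative")
  if (grade_program_size < 1) stop_config("grade_program_size", "must be >= 1")
  if (cnv_bin_size <= 0) stop_config("cnv_bin_size", "must be positive")
  if (erbb2_amp_ratio <= 0) stop_config("erbb2_amp_ratio", "must be positive")
  n_chr17 <- ceiling(83e6 / cnv_bin_size)
  if (n_bins < n_chr17 + 1) {
    stop_config("n_bins", paste0("must be >= ", n_chr17 + 1,
                                 " at this cnv_bin_size"))
  }
  min_genes <- 4L + 3L * as.integer(grade_program_size) +
    length(panel_genes())
  if (n_genes < min_genes) {
    stop_config("n_genes", paste0("must be >= ", min_genes,
                                  " to hold all gene programs"))
  }
  structure(list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    marker_shift = marker_shift, noise_sd = noise_sd,
    prevalence = prevalence, grade_program_size = as.integer(grade_program_size),
    grade_effect = grade_effect, subtype_weights = subtype_weights,
    discordance_rate = discordance_rate, cnv_bin_size = cnv_bin_size,
    n_bins = as.integer(n_bins), bin_mean_count = bin_mean_count,
    erbb2_amp_ratio = erbb2_amp_ratio, grade2_mixture = isTRUE(grade2_mixture),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

grade_component_names <- function() {
  c("mitotic", "nuclear_atypia", "tubular_formation")
}

#' Derive overall Nottingham-style grade from subcomponent scores
#'
#' Sums the three subcomponent scores (each 1-3) and bins the total:
#' 3-5 -> grade 1, 6-7 -> grade 2, 8-9 -> grade 3.
#'
#' @param mitotic,nuclear_atypia,tubular_formation integer scores in 1..3.
#' @return Integer grades in 1..3.
#' @export
overall_grade <- function(mitotic, nuclear_atypia, tubular_formation) {
  s <- mitotic + nuclear_atypia + tubular_formation
  ifelse(s <= 5, 1L, ifelse(s <= 7, 2L, 3L))
}

# Per-class log2 shifts over the panel genes (subtype centroid structure).
subtype_program_shifts <- function() {
  basal <- c("KRT5", "KRT14", "KRT17", "FOXC1", "MIA", "SFRP1", "EGFR",
             "CDH3", "PHGDH", "ACTR3B")
  luminal <- c("FOXA1", "NAT1", "SLC39A6", "BCL2", "MAPT", "BAG1", "MLPH",
               "BLVRA", "CXXC5", "GPR160")
  prolif <- c("BIRC5", "CCNB1", "CCNE1", "CDC20", "CDC6", "CENPF", "CEP55",
              "EXO1", "KIF2C", "MELK", "MYBL2", "NDC80", "NUF2", "ORC6",
              "PTTG1", "RRM2", "TYMS", "UBE2C", "UBE2T", "ANLN")
  her2 <- c("GRB7")
  shifts <- matrix(0, nrow = length(panel_genes()), ncol = 4,
                   dimnames = list(panel_genes(), subtype_classes()))
  shifts[basal, "Basal"] <- 2.0
  shifts[luminal, c("LumA", "LumB")] <- 2.0
  shifts[prolif, "Basal"] <- 2.0
  shifts[prolif, "LumB"] <- 1.5
  shifts[prolif, "Her2"] <- 1.5
  shifts[her2, "Her2"] <- 2.5
  shifts
}

#' Generate a synthetic breast-cancer cohort
#'
#' Draws molecular truth (receptor status, subtype, grade subcomponents),
#' simulates expression on the log2 scale as Gaussian noise around gene
#' baselines plus the configured structural shifts, exponentiates to
#' abundances, simulates low-pass copy-number bin counts with ERBB2
#' amplification in HER2-positive tumors, sprinkles somatic/germline
#' alterations, and derives recorded clinical labels with the configured
#' discordance.
#'
#' @param config a [cohort_config()].
#' @return A `synthetic_cohort` list with elements `expression` (raw
#'   [expr_matrix()]), `clinical`, `truth`, `alterations`, `tumor_bins`,
#'   `baseline_bins`, `gene_regions` and `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    config <- do.call(cohort_config, as.list(config))
  }
  n <- config$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  comps <- grade_component_names()
  k <- config$grade_program_size

  program_genes <- list(
    mitotic = sprintf("MITO_%03d", seq_len(k)),
    nuclear_atypia = sprintf("NUCA_%03d", seq_len(k)),
    tubular_formation = sprintf("TUBF_%03d", seq_len(k))
  )
  core <- unique(c("ESR1", "PGR", "ERBB2", "MKI67", unlist(program_genes),
                   panel_genes()))
  n_bg <- config$n_genes - length(core)
  genes <- c(core, sprintf("BG_%04d", seq_len(n_bg)))

  baseline <- with_stream(config$seed, "gene_baselines",
                          stats::runif(length(genes), 3, 8))
  names(baseline) <- genes

  truth_status <- with_stream(config$seed, "marker_status", {
    vapply(config$prevalence,
           function(p) stats::rbinom(n, 1L, p), integer(n))
  })
  if (n == 1L) truth_status <- matrix(truth_status, nrow = 1,
                                      dimnames = list(NULL, names(config$prevalence)))
  colnames(truth_status) <- names(config$prevalence)

  subtype <- with_stream(config$seed, "subtype",
    sample(subtype_classes(), n, replace = TRUE,
           prob = config$subtype_weights))

  grade_scores <- with_stream(config$seed, "grade", {
    tendency <- sample(1:3, n, replace = TRUE, prob = c(0.20, 0.45, 0.35))
    jitter <- matrix(sample(c(-1L, 0L, 1L), n * 3L, replace = TRUE,
                            prob = c(0.15, 0.70, 0.15)), ncol = 3L)
    sc <- pmin(pmax(tendency + jitter, 1L), 3L)
    colnames(sc) <- comps
    sc
  })
  grade <- overall_grade(grade_scores[, 1], grade_scores[, 2],
                         grade_scores[, 3])

  # Expression-level subcomponent scores: normally identical to the recorded
  # truth; under grade2_mixture, recorded-grade-2 samples get latent extreme
  # (all-1 or all-3) programs while their labels stay grade 2.
  expr_scores <- grade_scores
  if (config$grade2_mixture) {
    g2 <- which(grade == 2L)
    if (length(g2)) {
      latent <- with_stream(config$seed, "grade2_mixture",
                            sample(c(1L, 3L), length(g2), replace = TRUE))
      expr_scores[g2, ] <- matrix(latent, nrow = length(g2), ncol = 3L)
    }
  }

  shifts <- subtype_program_shifts()
  mu <- matrix(baseline, nrow = length(genes), ncol = n,
               dimnames = list(genes, samples))
  mu["ESR1", ] <- mu["ESR1", ] + config$marker_shift * truth_status[, "ER"]
  mu["PGR", ] <- mu["PGR", ] + config$marker_shift * truth_status[, "PR"]
  mu["ERBB2", ] <- mu["ERBB2", ] + config$marker_shift * truth_status[, "HER2"]
  mu["MKI67", ] <- mu["MKI67", ] + config$marker_shift * truth_status[, "Ki67"]
  for (comp in comps) {
    pg <- program_genes[[comp]]
    mu[pg, ] <- mu[pg, ] + config$grade_effect *
      matrix(expr_scores[, comp] - 2, nrow = length(pg), ncol = n,
             byrow = TRUE)
  }
  mu[rownames(shifts), ] <- mu[rownames(shifts), ] +
    shifts[, subtype, drop = FALSE]

  log2_expr <- with_stream(config$seed, "expression",
    mu + matrix(stats::rnorm(length(mu), sd = config$noise_sd),
                nrow = nrow(mu)))
  expression <- expr_matrix(2^log2_expr, scale = "raw")

  # Ki-67 percent: logistic transform of proliferation signal scaled to
  # [0, 100]; anchored so Ki67-high truth lands mostly above the 20% rule.
  ki67_percent <- with_stream(config$seed, "ki67_percent", {
    z <- -2.2 + 3.3 * truth_status[, "Ki67"] +
      0.5 * (expr_scores[, "mitotic"] - 2) + stats::rnorm(n, sd = 0.6)
    round(100 * stats::plogis(z), 1)
  })

  clinical <- data.frame(
    sample = samples,
    er = ifelse(truth_status[, "ER"] == 1L, "+", "-"),
    pr = ifelse(truth_status[, "PR"] == 1L, "+", "-"),
    her2 = ifelse(truth_status[, "HER2"] == 1L, "+", "-"),
    ki67_percent = ki67_percent,
    mitotic = grade_scores[, "mitotic"],
    nuclear_atypia = grade_scores[, "nuclear_atypia"],
    tubular_formation = grade_scores[, "tubular_formation"],
    grade = grade,
    stringsAsFactors = FALSE
  )

  # Flip a discordance_rate fraction of recorded labels per marker.
  clinical <- with_stream(config$seed, "discordance", {
    n_flip <- round(config$discordance_rate * n)
    for (mk in c("er", "pr", "her2")) {
      if (n_flip > 0) {
        idx <- sample.int(n, n_flip)
        clinical[[mk]][idx] <- ifelse(clinical[[mk]][idx] == "+", "-", "+")
      }
    }
    if (n_flip > 0) {
      idx <- sample.int(n, n_flip)
      high <- truth_status[idx, "Ki67"] == 1L
      clinical$ki67_percent[idx] <- round(ifelse(
        high, stats::runif(length(idx), 5, 15),
        stats::runif(length(idx), 25, 60)), 1)
    }
    clinical
  })

  truth <- data.frame(
    sample = samples,
    er = ifelse(truth_status[, "ER"] == 1L, "+", "-"),
    pr = ifelse(truth_status[, "PR"] == 1L, "+", "-"),
    her2 = ifelse(truth_status[, "HER2"] == 1L, "+", "-"),
    # the pre-discordance percent defines the 20%-rule truth label
    ki67 = ifelse(ki67_percent >= 20, "high", "low"),
    subtype = subtype,
    mitotic = grade_scores[, "mitotic"],
    nuclear_atypia = grade_scores[, "nuclear_atypia"],
    tubular_formation = grade_scores[, "tubular_formation"],
    grade = grade,
    latent_mitotic = expr_scores[, "mitotic"],
    latent_nuclear_atypia = expr_scores[, "nuclear_atypia"],
    latent_tubular_formation = expr_scores[, "tubular_formation"],
    stringsAsFactors = FALSE
  )

  bins <- cnv_bin_grid(config$cnv_bin_size, config$n_bins)
  erbb2 <- erbb2_region()
  amp_bin <- bins$chrom == erbb2$chrom &
    bins$start < erbb2$end & bins$end > erbb2$start
  cnv <- with_stream(config$seed, "cnv", {
    tb <- vector("list", n); bb <- vector("list", n)
    for (i in seq_len(n)) {
      ratio <- rep(1, nrow(bins))
      if (truth_status[i, "HER2"] == 1L) {
        ratio[amp_bin] <- config$erbb2_amp_ratio
      }
      b <- bins
      b$count <- stats::rpois(nrow(bins), config$bin_mean_count)
      t <- bins
      t$count <- stats::rpois(nrow(bins), config$bin_mean_count * ratio)
      bb[[i]] <- b; tb[[i]] <- t
    }
    names(tb) <- samples; names(bb) <- samples
    list(tumor = tb, baseline = bb)
  })

  alterations <- with_stream(config$seed, "alterations",
    simulate_alterations(samples, truth_status))

  structure(list(
    expression = expression,
    clinical = clinical,
    truth = truth,
    alterations = alterations,
    tumor_bins = cnv$tumor,
    baseline_bins = cnv$baseline,
    gene_regions = erbb2,
    config = config
  ), class = "synthetic_cohort")
}

# Shared copy-number bin grid: chr17 (83 Mb, carries the ERBB2 locus) plus a
# generic chr1 filling out n_bins.
cnv_bin_grid <- function(bin_size, n_bins) {
  n17 <- ceiling(83e6 / bin_size)
  n1 <- n_bins - n17
  rbind(
    data.frame(chrom = "chr1",
               start = as.numeric(seq_len(n1) - 1) * bin_size,
               end = as.numeric(seq_len(n1)) * bin_size,
               stringsAsFactors = FALSE),
    data.frame(chrom = "chr17",
               start = as.numeric(seq_len(n17) - 1) * bin_size,
               end = as.numeric(seq_len(n17)) * bin_size,
               stringsAsFactors = FALSE)
  )
}

simulate_alterations <- function(samples, truth_status) {
  n <- length(samples)
  rows <- list()
  add <- function(patient, gene, class, origin, pchange = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      patient = patient, gene = gene, alteration_class = class,
      origin = origin, protein_change = pchange, stringsAsFactors = FALSE)
  }
  pik3ca_hot <- c("H1047R", "E545K", "E542K")
  erbb2_hot <- c("L755S", "V777L", "P1170A")
  for (i in seq_len(n)) {
    s <- samples[i]
    if (stats::runif(1) < 0.30) {
      add(s, "PIK3CA", "snv", "somatic", sample(pik3ca_hot, 1))
    }
    if (stats::runif(1) < 0.30) add(s, "TP53", "snv", "somatic")
    if (truth_status[i, "HER2"] == 1L) {
      add(s, "ERBB2", "amplification", "somatic")
    } else if (stats::runif(1) < 0.02) {
      add(s, "ERBB2", "snv", "somatic", sample(erbb2_hot, 1))
    }
    if (stats::runif(1) < 0.015) {
      add(s, "BRCA1", ifelse(stats::runif(1) < 0.5, "snv", "indel"),
          ifelse(stats::runif(1) < 0.8, "germline", "somatic"))
    }
    if (stats::runif(1) < 0.02) {
      add(s, "BRCA2", ifelse(stats::runif(1) < 0.5, "snv", "indel"),
          ifelse(stats::runif(1) < 0.45, "germline", "somatic"))
    }
    if (stats::runif(1) < 0.13) {
      add(s, "FGF3", "amplification", "somatic")
      add(s, "FGF4", "amplification", "somatic")
    }
    if (stats::runif(1) < 0.05) add(s, "TOP2A", "amplification", "somatic")
    if (stats::runif(1) < 0.05) add(s, "PTEN", "deep_deletion", "somatic")
  }
  if (!length(rows)) {
    return(data.frame(patient = character(), gene = character(),
                      alteration_class = character(), origin = character(),
                      protein_change = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0(
    "<synthetic_cohort> %d samples, %d genes\n",
    "  ER+ %d | PR+ %d | HER2+ %d | Ki67-high %d (truth)\n",
    "  grades 1/2/3: %d/%d/%d; %d alterations; %d CNV bins/sample\n"),
    nrow(x$clinical), nrow(x$expression),
    sum(x$truth$er == "+"), sum(x$truth$pr == "+"),
    sum(x$truth$her2 == "+"), sum(x$truth$ki67 == "high"),
    sum(x$truth$grade == 1), sum(x$truth$grade == 2),
    sum(x$truth$grade == 3), nrow(x$alterations),
    nrow(x$tumor_bins[[1]])))
  invisible(x)
}
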