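alt_row <- function(patient, gene, class, origin = "somatic",
                    pchange = NA_character_) {
  data.frame(patient = patient, gene = gene, alteration_class = class,
             origin = origin, protein_change = pchange,
             stringsAsFactors = FALSE)
}

kb_row <- function(gene, class, therapy, indication = "breast",
                   phase = "early", her2 = FALSE) {
  data.frame(gene = gene, alteration_class = class, therapy = therapy,
             indication = indication, phase = phase,
             requires_her2_positive = her2, stringsAsFactors = FALSE)
}

test_that("matching requires gene and class to agree, within scope", {
  kb <- kb_row("PIK3CA", "snv", "PI3Ki")
  expect_equal(nrow(match_patient(alt_row("P1", "PIK3CA", "snv"), kb[0, ])),
               0L)
  hit <- match_patient(alt_row("P1", "PIK3CA", "snv", pchange = "H1047R"), kb)
  expect_equal(nrow(hit), 1L)
  expect_identical(hit$therapy, "PI3Ki")
  miss <- match_patient(alt_row("P1", "PIK3CA", "amplification"), kb)
  expect_equal(nrow(miss), 0L)
})

test_that("germline alterations are never matched to the knowledge base", {
  kb <- kb_row("BRCA1", "snv", "olaparib", indication = "other")
  alt <- alt_row("P1", "BRCA1", "snv", origin = "germline")
  expect_equal(nrow(match_patient(alt, kb, scope = "any_indication")), 0L)
  alt$origin <- "somatic"
  expect_equal(nrow(match_patient(alt, kb, scope = "any_indication")), 1L)
})

test_that("breast-only scope drops non-breast entries and ERBB2 amplification", {
  kb <- rbind(kb_row("ERBB2", "amplification", "trastuzumab",
                     phase = "approved"),
              kb_row("CDK4", "amplification", "palbociclib",
                     indication = "other", phase = "approved"),
              kb_row("PIK3CA", "snv", "PI3Ki"))
  alts <- rbind(alt_row("P1", "ERBB2", "amplification"),
                alt_row("P1", "CDK4", "amplification"),
                alt_row("P1", "PIK3CA", "snv"))
  breast <- match_patient(alts, kb, scope = "breast_only")
  expect_identical(unique(breast$gene), "PIK3CA")
  any_ind <- match_patient(alts, kb, scope = "any_indication")
  expect_setequal(any_ind$gene, c("ERBB2", "CDK4", "PIK3CA"))
})

test_that("widening the scope never loses matches", {
  set.seed(80)
  kb <- read_knowledge_base(toy_kb_path())
  genes <- unique(kb$gene)
  for (i in 1:10) {
    alts <- do.call(rbind, lapply(1:15, function(j) {
      alt_row(sprintf("P%02d", sample(8, 1)), sample(genes, 1),
              sample(c("snv", "indel", "amplification", "deep_deletion"), 1),
              origin = sample(c("somatic", "germline"), 1, prob = c(0.8, 0.2)))
    }))
    narrow <- match_patient(alts, kb, scope = "breast_only")
    wide <- match_patient(alts, kb, scope = "any_indication")
    tally <- function(m) table(factor(m$patient,
                                      levels = sprintf("P%02d", 1:8)))
    expect_true(all(tally(wide) >= tally(narrow)))
  }
})

test_that("priority selection keeps the highest phase, ties lexicographic", {
  matches <- rbind(
    cbind(alt_row("P1", "PIK3CA", "snv"),
          therapy = "AKTi", indication = "breast", phase = "early"),
    cbind(alt_row("P1", "TOP2A", "amplification"),
          therapy = "anthracycline", indication = "breast", phase = "late"),
    cbind(alt_row("P2", "ERBB2", "amplification"),
          therapy = "trastuzumab", indication = "breast", phase = "approved"),
    cbind(alt_row("P2", "PIK3CA", "snv"),
          therapy = "AKTi", indication = "breast", phase = "late"),
    cbind(alt_row("P3", "PIK3CA", "snv"),
          therapy = "PI3K beta inhibitor", indication = "breast",
          phase = "early"),
    cbind(alt_row("P3", "PIK3CA", "snv"),
          therapy = "PI3K alpha inhibitor", indication = "breast",
          phase = "early"))
  best <- best_match_per_patient(matches)
  expect_equal(nrow(best), 3L)
  expect_false(anyDuplicated(best$patient) > 0)
  expect_identical(best$phase[best$patient == "P1"], "late")
  expect_identical(best$phase[best$patient == "P2"], "approved")
  expect_identical(best$therapy[best$patient == "P3"],
                   "PI3K alpha inhibitor")
})

test_that("random cohorts agree with the brute-force tally oracle", {
  set.seed(81)
  kb <- read_knowledge_base(toy_kb_path())
  for (i in 1:10) {
    alts <- do.call(rbind, lapply(1:25, function(j) {
      alt_row(sprintf("P%02d", sample(10, 1)), sample(unique(kb$gene), 1),
              sample(alt_classes <- c("snv", "indel", "amplification",
                                      "deep_deletion"), 1))
    }))
    matches <- match_patient(alts, kb, scope = "any_indication")
    best <- best_match_per_patient(matches)
    if (!nrow(matches)) next
    oracle <- oracle_best_matches(matches)
    expect_identical(best$patient, oracle$patient)
    expect_identical(best$phase, oracle$phase)
    expect_identical(best$therapy, oracle$therapy)
    s <- summarize_cohort(best, matches, 10)
    expect_equal(sum(s$by_phase$n), nrow(best))
    expect_equal(s$n_matched, length(unique(matches$patient)))
  }
})

test_that("cohort summaries count phases and alteration kinds", {
  matches <- rbind(
    cbind(alt_row("P1", "PIK3CA", "snv"),
          therapy = "AKTi", indication = "breast", phase = "late"),
    cbind(alt_row("P2", "FGF3", "amplification"),
          therapy = "dovitinib", indication = "breast", phase = "early"),
    cbind(alt_row("P3", "PIK3CA", "snv"),
          therapy = "PI3Ki", indication = "breast", phase = "early"))
  best <- best_match_per_patient(matches)
  s <- summarize_cohort(best, matches, 10)
  expect_equal(s$by_phase$n[s$by_phase$phase == "late"], 1L)
  expect_equal(s$by_phase$n[s$by_phase$phase == "early"], 2L)
  expect_equal(s$n_matched, 3L)
  expect_equal(s$pct_matched, 30)
  expect_equal(s$n_snv_indel, 2L)
  expect_equal(s$n_cnv, 1L)
  empty <- summarize_cohort(matches[0, ], matches[0, ], 10)
  expect_equal(empty$n_matched, 0L)
  expect_true(all(empty$by_phase$n == 0))
})

test_that("composite entries require a HER2-positive patient", {
  kb <- kb_row("TOP2A", "amplification", "anthracycline", phase = "late",
               her2 = TRUE)
  alt <- alt_row("P1", "TOP2A", "amplification")
  expect_equal(nrow(match_patient(alt, kb,
                                  her2_status = c(P1 = "+"))), 1L)
  expect_equal(nrow(match_patient(alt, kb,
                                  her2_status = c(P1 = "-"))), 0L)
  expect_equal(nrow(match_patient(alt, kb)), 0L)
})

test_that("key-gene flags follow the HER2 status and BRCA rules", {
  alts <- rbind(
    alt_row("P1", "ERBB2", "snv", pchange = "L755S"),
    alt_row("P2", "ERBB2", "snv", pchange = "V777L"),
    alt_row("P3", "BRCA1", "indel", origin = "germline"),
    alt_row("P4", "BRCA2", "snv", origin = "somatic"),
    alt_row("P5", "ERBB2", "amplification"))
  status <- c(P1 = "-", P2 = "+", P3 = "-", P4 = "+")
  flags <- flag_key_genes(alts, status)
  a <- flags[flags$flag == "erbb2_mutant_her2_negative", ]
  expect_identical(a$patient, "P1")
  expect_identical(a$protein_change, "L755S")
  b <- flags[flags$flag == "brca_carrier", ]
  expect_setequal(b$patient, c("P3", "P4"))
  expect_identical(b$origin[b$patient == "P3"], "germline")
  # missing status -> flag emitted with status recorded as missing
  flags2 <- flag_key_genes(alt_row("P9", "ERBB2", "snv", pchange = "S310F"),
                           status)
  expect_identical(flags2$her2_status, "missing")
})

test_that("unknown alteration classes in the KB are a format error", {
  kb <- kb_row("PIK3CA", "fusion", "X")
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(kb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_knowledge_base(path), "fusion")
  expect_error(match_patient(alt_row("P1", "PIK3CA", "fusion"),
                             kb_row("PIK3CA", "snv", "X")), "fusion")
})
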