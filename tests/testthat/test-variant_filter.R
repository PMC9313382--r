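test_that("population AF stage uses a strict 1% bound over non-missing databases", {
  cfg <- filter_config()
  expect_true(population_af_pass(0.0005, NA, 0.002, cfg))
  expect_false(population_af_pass(NA, 0.015, NA, cfg))
  expect_false(population_af_pass(0.01, NA, NA, cfg))   # exactly 1% fails
  expect_true(population_af_pass(NA, NA, NA, cfg))      # absent = rare
  expect_error(population_af_pass(1.5, NA, NA, cfg), "outside")
})

test_that("VAF support needs >=10% with >=5 reads in at least one sample", {
  cfg <- filter_config()
  expect_true(vaf_support_pass(0.08, 4, 0.12, 30, cfg))
  expect_false(vaf_support_pass(0.09, 20, 0.09, 18, cfg))
  expect_true(vaf_support_pass(0.10, 5, 0, 0, cfg))     # inclusive boundary
  expect_false(vaf_support_pass(0.20, 4, 0.09, 50, cfg)) # joint, same sample
})

test_that("predictor consensus honours the recurrent-gene exception", {
  cfg <- filter_config()
  two_of_six <- ann_row("chr1", 1, "A", "T", "G1",
                        pathogenic_preds = c("deogen2", "primateai"))
  expect_true(predictor_consensus_pass(two_of_six, FALSE, cfg))
  chasm_only <- ann_row("chr1", 1, "A", "T", "KRAS",
                        pathogenic_preds = "chasm")
  expect_false(predictor_consensus_pass(chasm_only, FALSE, cfg))
  expect_true(predictor_consensus_pass(chasm_only, TRUE, cfg))
  # deogen2 is not cancer-specific: one hit does not rescue a recurrent gene
  deogen_only <- ann_row("chr1", 1, "A", "T", "KRAS",
                         pathogenic_preds = "deogen2")
  expect_false(predictor_consensus_pass(deogen_only, TRUE, cfg))
  # missing verdicts count as non-pathogenic
  missing_all <- two_of_six
  for (col in paste0("pred_", mmclonetrack:::PREDICTOR_LABELS)) {
    missing_all[[col]] <- NA_character_
  }
  expect_false(predictor_consensus_pass(missing_all, FALSE, cfg))
})

test_that("the ACMG rejection stage reproduces the printed candidate arithmetic", {
  # 257 candidates of which 79 are benign/likely-benign; one of those is the
  # whitelisted KMT2C c.1173C>A; 179 retained and 78 rejected
  n_total <- 257; n_benign <- 79
  candidates <- tibble::tibble(
    gene = c("KMT2C", paste0("G", seq_len(n_total - 1))),
    cdna = c("c.1173C>A", paste0("c.", seq_len(n_total - 1), "A>G")),
    acmg_class = c("likely_benign",
                   rep(c("benign", "likely_benign"), length.out = n_benign - 1),
                   rep(c("pathogenic", "likely_pathogenic", "vus"),
                       length.out = n_total - n_benign)))
  out <- varsome_stage(candidates, filter_config())
  expect_equal(nrow(out$retained), 179)
  expect_equal(nrow(out$rejected), 78)
  expect_true("KMT2C" %in% out$retained$gene)
  expect_equal(nrow(out$retained) + nrow(out$rejected), n_total)
  expect_equal(nrow(dplyr::intersect(out$retained, out$rejected)), 0)
})

test_that("varsome stage keeps missing-class variants and handles empty input", {
  out <- varsome_stage(tibble::tibble(gene = "X", cdna = "c.1A>T",
                                      acmg_class = NA_character_))
  expect_equal(nrow(out$retained), 1)
  empty <- varsome_stage(tibble::tibble(gene = character(),
                                        cdna = character(),
                                        acmg_class = character()))
  expect_equal(nrow(empty$retained), 0)
  expect_equal(nrow(empty$rejected), 0)
})

# brute-force oracle: re-evaluate every criterion per variant in one pass
brute_force_keep <- function(po, cfg) {
  keep <- logical(nrow(po))
  for (i in seq_len(nrow(po))) {
    r <- po[i, ]
    afs <- c(r$af_g1000, r$af_gnomad, r$af_esp)
    ok_af <- all(is.na(afs) | afs < cfg$pop_af_max)
    ok_vaf <- (r$vaf_first >= cfg$vaf_min &&
                 r$alt_reads_first >= cfg$alt_reads_min) ||
      (r$vaf_paired >= cfg$vaf_min && r$alt_reads_paired >= cfg$alt_reads_min)
    verd <- unlist(r[paste0("pred_", mmclonetrack:::PREDICTOR_LABELS)])
    n_path <- sum(verd == "pathogenic", na.rm = TRUE)
    n_cancer <- sum(verd[paste0("pred_",
                                mmclonetrack:::CANCER_SPECIFIC_PREDICTORS)] ==
                      "pathogenic", na.rm = TRUE)
    ok_cons <- n_path >= cfg$consensus_min ||
      (isTRUE(r$recurrent_mm_gene) && n_cancer >= 1)
    benign <- !is.na(r$acmg_class) &&
      r$acmg_class %in% c("benign", "likely_benign")
    wl <- paste(r$gene, r$cdna) %in% paste(cfg$whitelist$gene,
                                           cfg$whitelist$cdna)
    keep[i] <- ok_af && ok_vaf && ok_cons && (!benign || wl)
  }
  keep
}

test_that("run_cascade agrees with a brute-force one-pass filter and its report balances", {
  sim <- simulate_cohort(simulation_config(n_patients = 12, seed = 21))
  cfg <- filter_config()
  res <- run_cascade(sim$cohort, cfg)
  po <- paired_observations(sim$cohort)
  keep <- brute_force_keep(po, cfg)
  key <- function(df) sort(paste(df$patient_id, df$chrom, df$pos, df$ref, df$alt))
  expect_equal(key(res$retained), key(po[keep, ]))

  rep <- res$report
  expect_equal(rep$retained[1] + rep$rejected[1], nrow(po))
  # conservation: retained at stage k feeds stage k+1
  for (k in 2:nrow(rep)) {
    expect_equal(rep$retained[k] + rep$rejected[k], rep$retained[k - 1])
  }
  # monotone non-increasing retained counts
  expect_true(all(diff(rep$retained) <= 0))
})

test_that("per-variant decisions are order-independent within the cascade", {
  sim <- simulate_cohort(simulation_config(n_patients = 8, seed = 5))
  co <- sim$cohort
  res1 <- run_cascade(co)
  set.seed(99)
  co2 <- co
  co2$variants <- co$variants[sample.int(nrow(co$variants)), ]
  co2$annotations <- co$annotations[sample.int(nrow(co$annotations)), ]
  res2 <- run_cascade(co2)
  key <- function(df) sort(paste(df$patient_id, df$chrom, df$pos, df$ref, df$alt))
  expect_equal(key(res1$retained), key(res2$retained))
  expect_equal(res1$report$retained, res2$report$retained)
})

test_that("vacuous thresholds retain everything until the ACMG stage", {
  sim <- simulate_cohort(simulation_config(n_patients = 6, seed = 13))
  cfg <- filter_config(pop_af_max = 1.1, vaf_min = 1e-9,
                       alt_reads_min = 1e-9, consensus_min = 0)
  res <- run_cascade(sim$cohort, cfg)
  n0 <- nrow(paired_observations(sim$cohort))
  expect_equal(res$report$retained[1:3], rep(n0, 3))
  expect_equal(res$report$rejected[1:3], rep(0L, 3))
})

test_that("a cohort with zero variants yields an all-zero report", {
  co <- tiny_cohort()
  co$variants <- co$variants[0, ]
  res <- run_cascade(co)
  expect_equal(res$report$retained, rep(0L, 4))
  expect_equal(res$report$rejected, rep(0L, 4))
})
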