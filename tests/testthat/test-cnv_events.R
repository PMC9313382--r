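seg <- function(chrom, start, end, log2, pid = "P", sidx = 1L) {
  tibble::tibble(patient_id = pid, sample_index = sidx, chrom = chrom,
                 start = start, end = end, log2 = log2,
                 n_markers = 5L)
}

region_1p22 <- default_region_defs()[
  default_region_defs()$label == "del1p_1p22_1", ]

test_that("region log2 is a length-weighted mean with coverage tracking", {
  cfg <- cnv_config()
  full <- seg("chr1", region_1p22$start, region_1p22$end, -0.6)
  r <- region_log2(full, region_1p22, cfg)
  expect_equal(r$value, -0.6)
  expect_equal(r$coverage, 1.0)

  mid <- (region_1p22$start + region_1p22$end) / 2
  halves <- dplyr::bind_rows(
    seg("chr1", region_1p22$start, mid, -0.6),
    seg("chr1", mid, region_1p22$end, 0.0))
  r2 <- region_log2(halves, region_1p22, cfg)
  expect_equal(r2$value, -0.3)
  expect_equal(r2$coverage, 1.0)

  r3 <- region_log2(seg("chr2", 0, 1e6, -1), region_1p22, cfg)
  expect_true(is.na(r3$value))
  expect_equal(r3$coverage, 0)

  # sliver below min_region_overlap is suppressed
  sliver_end <- region_1p22$start + 0.2 * (region_1p22$end - region_1p22$start)
  r4 <- region_log2(seg("chr1", region_1p22$start, sliver_end, -1), region_1p22, cfg)
  expect_true(is.na(r4$value))
  expect_equal(r4$coverage, 0.2, tolerance = 1e-9)
})

full_genome_segments <- function(shifts = list()) {
  defs <- default_region_defs()
  rows <- lapply(seq_len(nrow(defs)), function(i) {
    l2 <- if (!is.null(shifts[[defs$label[i]]])) shifts[[defs$label[i]]] else 0
    seg(defs$chrom[i], defs$start[i], defs$end[i], l2)
  })
  dplyr::bind_rows(rows)
}

test_that("event calls use directional thresholds and the del1p composite ORs sub-regions", {
  ev <- call_events(full_genome_segments(list(del1p_1p22_1 = -0.5)))
  expect_true(ev[["del1p"]])
  expect_false(ev[["gain1q21"]])
  ev2 <- call_events(full_genome_segments())
  expect_false(any(ev2))
  ev3 <- call_events(full_genome_segments(list(del17p = -0.6,
                                               gain1q21 = 0.45)))
  expect_true(ev3[["del17p"]])
  expect_true(ev3[["gain1q21"]])
  # manual check of the 17p threshold rule: weighted mean -0.6 <= -0.25
  expect_true(ev3[["del17p"]] ==
                (region_log2(full_genome_segments(list(del17p = -0.6)),
                             default_region_defs()[
                               default_region_defs()$label == "del17p", ],
                             cnv_config())$value <= -0.25))
})

test_that("del1p equals the OR of its sub-region calls on random segment sets", {
  defs <- default_region_defs()
  sub_labels <- c("del1p_1p12", "del1p_1p22_1", "del1p_1p32_3")
  cfg <- cnv_config()
  set.seed(404)
  for (rep in 1:50) {
    shifts <- stats::setNames(
      as.list(stats::runif(nrow(defs), -0.8, 0.6)), defs$label)
    segs <- full_genome_segments(shifts)
    ev <- call_events(segs, defs, cfg)
    sub_calls <- vapply(sub_labels, function(lab) {
      d <- defs[defs$label == lab, ]
      region_log2(segs, d, cfg)$value <= cfg$loss_log2_max
    }, TRUE)
    expect_identical(unname(ev[["del1p"]]), any(sub_calls))
  }
})

test_that("shrinking all log2 values toward zero never creates events", {
  set.seed(77)
  defs <- default_region_defs()
  for (rep in 1:25) {
    shifts <- stats::setNames(
      as.list(stats::runif(nrow(defs), -0.8, 0.6)), defs$label)
    segs <- full_genome_segments(shifts)
    ev_full <- call_events(segs, defs)
    for (s in c(0.8, 0.5, 0.2)) {
      segs_s <- segs
      segs_s$log2 <- segs_s$log2 * s
      ev_s <- call_events(segs_s, defs)
      # no event present in the shrunk profile that was absent originally
      expect_false(any(ev_s & !ev_full, na.rm = TRUE))
    }
  }
})

test_that("CNV evolution classifies the four transitions and the stable profile", {
  e1 <- c(del1p = FALSE, gain1q21 = FALSE, del17p = TRUE,
          del13q = TRUE, del14q = FALSE)
  e2 <- c(del1p = FALSE, gain1q21 = TRUE, del17p = FALSE,
          del13q = TRUE, del14q = FALSE)
  ce <- classify_cnv_evolution(e1, e2)
  expect_equal(unname(ce$transitions),
               c("stable_absent", "acquired", "lost", "stable_present",
                 "stable_absent"))
  expect_false(ce$stable_profile)
  same <- classify_cnv_evolution(e1, e1)
  expect_true(same$stable_profile)
  # missing regions are excluded from the judgment but counted
  e1na <- e1; e1na[["del14q"]] <- NA
  ce2 <- classify_cnv_evolution(e1na, e1)
  expect_equal(ce2$n_missing, 1)
  expect_true(ce2$stable_profile)
})

test_that("biallelic detection excludes amplified loci and is monotone in VAF", {
  tr <- tibble::tibble(chrom = "chr17", pos = 7675100, vaf_first = 0.85,
                       vaf_paired = 0.3)
  neutral <- seg("chr17", 6.5e6, 10.8e6, 0.0)
  amplified <- seg("chr17", 6.5e6, 10.8e6, 0.5)
  expect_true(detect_biallelic(tr, neutral, neutral))
  expect_false(detect_biallelic(tr, amplified, amplified))
  # amplification only at the non-qualifying sample does not block
  expect_true(detect_biallelic(tr, neutral, amplified))
  low <- tr; low$vaf_first <- 0.79; low$vaf_paired <- 0.79
  expect_false(detect_biallelic(low, neutral, neutral))
  # no segment coverage counts as not amplified
  expect_true(detect_biallelic(tr, neutral[0, ], neutral[0, ]))
  # monotone non-decreasing in VAF holding CNV fixed
  set.seed(9)
  vafs <- sort(stats::runif(20))
  calls <- vapply(vafs, function(v) {
    t2 <- tr; t2$vaf_first <- v; t2$vaf_paired <- 0
    detect_biallelic(t2, neutral, neutral)
  }, TRUE)
  expect_true(all(diff(as.integer(calls)) >= 0))
})

test_that("double and triple hits count distinct high-risk lesions", {
  no_fish <- list(del17p = "absent", t_4_14 = "absent", t_14_16 = "absent")
  ev <- c(del1p = TRUE, gain1q21 = TRUE, del17p = TRUE,
          del13q = FALSE, del14q = FALSE)
  hit <- detect_double_hit(ev, no_fish)
  expect_true(hit$triple_hit)
  expect_true(hit$double_hit)
  expect_equal(hit$n_lesions, 3)

  ev2 <- c(del1p = TRUE, gain1q21 = TRUE, del17p = FALSE,
           del13q = FALSE, del14q = FALSE)
  hit2 <- detect_double_hit(ev2, no_fish)
  expect_true(hit2$double_hit)
  expect_false(hit2$triple_hit)

  # FISH t(4;14) contributes a lesion; TP53 double hit needs del17p + mutation
  fish414 <- list(del17p = "absent", t_4_14 = "present", t_14_16 = "absent")
  hit3 <- detect_double_hit(ev2, fish414)
  expect_true(hit3$triple_hit)
  ev_17 <- c(del1p = FALSE, gain1q21 = FALSE, del17p = TRUE,
             del13q = FALSE, del14q = FALSE)
  hit4 <- detect_double_hit(ev_17, no_fish, variant_genes = "TP53")
  expect_true(hit4$tp53_double_hit)
  expect_false(hit4$double_hit)
  hit5 <- detect_double_hit(ev_17, no_fish, variant_genes = "KRAS")
  expect_false(hit5$tp53_double_hit)
})
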