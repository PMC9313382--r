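# Fixtures are built in code: a hand-sized two-patient cohort with known
# variants, plus row constructors used across the unit tests.

ann_row <- function(chrom, pos, ref, alt, gene,
                    afs = c(NA, NA, NA),
                    pathogenic_preds = c("cravat", "chasm"),
                    acmg = "vus", recurrent = FALSE, druggable = NA) {
  verdicts <- stats::setNames(
    as.list(ifelse(mmclonetrack:::PREDICTOR_LABELS %in% pathogenic_preds,
                   "pathogenic", "benign")),
    paste0("pred_", mmclonetrack:::PREDICTOR_LABELS))
  tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt,
                 gene = gene, af_g1000 = afs[1], af_gnomad = afs[2],
                 af_esp = afs[3], !!!verdicts, acmg_class = acmg,
                 recurrent_mm_gene = recurrent,
                 druggable_sources = druggable)
}

obs_row <- function(patient_id, sample_index, chrom, pos, ref, alt, gene,
                    cdna, depth, alt_reads) {
  tibble::tibble(patient_id = patient_id, sample_index = sample_index,
                 chrom = chrom, pos = pos, ref = ref, alt = alt,
                 gene = gene, cdna = cdna, depth = as.integer(depth),
                 alt_reads = as.integer(alt_reads),
                 vaf = ifelse(depth > 0, alt_reads / depth, 0))
}

clin_row <- function(patient_id, sample_index, role,
                     timepoint_label = if (sample_index == 1) "Dx" else "PD",
                     purity = 0.9, albumin = 4.0, b2m = 3.0,
                     ldh = "normal", fish_del17p = "absent",
                     fish_t_4_14 = "absent", fish_t_14_16 = "absent",
                     response = NA_character_) {
  tibble::tibble(patient_id = patient_id,
                 sample_index = as.integer(sample_index),
                 timepoint_label = timepoint_label, role = role,
                 purity = purity, albumin = albumin, b2m = b2m, ldh = ldh,
                 ecog = 1L, fish_del17p = fish_del17p,
                 fish_t_4_14 = fish_t_4_14, fish_t_14_16 = fish_t_14_16,
                 fish_t_11_14 = "absent", fish_igh_other = "absent",
                 response = response, refractory_pi = FALSE,
                 refractory_imid = FALSE, refractory_alkylator = FALSE)
}

# Two patients, two samples each. PA: one stable KRAS variant and one lost
# TP53 variant; PB: one acquired BRAF variant.
tiny_cohort <- function() {
  variants <- dplyr::bind_rows(
    obs_row("PA", 1, "chr12", 25245100, "C", "T", "KRAS", "c.35G>A", 200, 60),
    obs_row("PA", 2, "chr12", 25245100, "C", "T", "KRAS", "c.35G>A", 200, 66),
    obs_row("PA", 1, "chr17", 7675100, "G", "T", "TP53", "c.796G>T", 200, 60),
    obs_row("PA", 2, "chr17", 7675100, "G", "T", "TP53", "c.796G>T", 210, 0),
    obs_row("PB", 1, "chr7", 140753100, "A", "T", "BRAF", "c.1799T>A", 220, 0),
    obs_row("PB", 2, "chr7", 140753100, "A", "T", "BRAF", "c.1799T>A", 220, 55))
  annotations <- dplyr::bind_rows(
    ann_row("chr12", 25245100, "C", "T", "KRAS", recurrent = TRUE,
            druggable = "oncokb,target"),
    ann_row("chr17", 7675100, "G", "T", "TP53", acmg = "pathogenic"),
    ann_row("chr7", 140753100, "A", "T", "BRAF", recurrent = TRUE))
  clinical <- dplyr::bind_rows(
    clin_row("PA", 1, "first"),
    clin_row("PA", 2, "paired", b2m = 6.0, ldh = "high", response = "PR"),
    clin_row("PB", 1, "first", albumin = 3.0),
    clin_row("PB", 2, "paired", response = "VGPR"))
  segments <- tibble::tibble(
    patient_id = c("PA", "PA", "PB", "PB"),
    sample_index = c(1L, 2L, 1L, 2L),
    chrom = c("chr17", "chr17", "chr7", "chr7"),
    start = c(6000000, 6000000, 140000000, 140000000),
    end = c(11000000, 11000000, 141000000, 141000000),
    log2 = c(0.0, -0.6, 0.02, -0.01),
    n_markers = c(10L, 10L, 4L, 4L))
  survival <- tibble::tibble(
    patient_id = c("PA", "PB"),
    pfs_months = c(4, 15), pfs_event = c(TRUE, FALSE),
    os1_months = c(20, 40), os1_event = c(TRUE, FALSE),
    os2_months = c(12, 30), os2_event = c(TRUE, FALSE))
  new_cohort(variants, annotations, clinical, segments, survival)
}
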