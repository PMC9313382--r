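make_traj_input <- function(patient_id, gene, pos,
                            d1, a1, d2, a2, cdna = "c.1A>T",
                            chrom = "chr2") {
  tibble::tibble(patient_id = patient_id, chrom = chrom, pos = pos,
                 ref = "A", alt = "T", gene = gene, cdna = cdna,
                 depth_first = d1, alt_reads_first = a1,
                 vaf_first = ifelse(d1 > 0, a1 / d1, 0),
                 depth_paired = d2, alt_reads_paired = a2,
                 vaf_paired = ifelse(d2 > 0, a2 / d2, 0))
}

test_that("presence calls use the read-count and VAF floor inclusively", {
  cfg <- trajectory_config()
  expect_false(presence_call(0, 0, cfg))
  expect_true(presence_call(30, 0.12, cfg))
  expect_true(presence_call(3, 0.02, cfg))   # boundary inclusive
  expect_false(presence_call(2, 0.10, cfg))
  expect_false(presence_call(10, 0.019, cfg))
})

test_that("trajectories classify acquisition, loss, expansion, decline and stability", {
  inp <- dplyr::bind_rows(
    make_traj_input("P1", "PABPC1", 100, 200, 60, 210, 0),   # lost
    make_traj_input("P1", "TP53", 200, 220, 0, 220, 55),     # acquired
    make_traj_input("P1", "KRAS", 300, 200, 30, 200, 90),    # expanded
    make_traj_input("P1", "BRCA2", 400, 200, 60, 200, 66))   # stable
  out <- classify_trajectory(inp, trajectory_config())
  expect_equal(out$trajectory_class,
               c("lost", "acquired", "expanded", "stable"))
  # expansion call backed by the two-proportion test: p = 5.89e-11 (both z
  # and exact routes reject at 0.05) with delta VAF 0.30 >= 0.10
  expect_lt(out$change_p[3], 0.05)
  expect_equal(out$change_p[3], 5.888668e-11, tolerance = 1e-6)
  # stable: p = 0.518, fails to reject; delta 0.03 < 0.10
  expect_gt(out$change_p[4], 0.05)
  # significant but small shifts stay stable (effect-size guard)
  big_depth <- make_traj_input("P2", "ATM", 500, 20000, 5000, 20000, 5600)
  out2 <- classify_trajectory(big_depth, trajectory_config())
  expect_lt(out2$change_p, 0.05)
  expect_equal(out2$trajectory_class, "stable")
})

test_that("a variant absent at both timepoints is a hard error", {
  inp <- make_traj_input("P1", "KRAS", 100, 200, 0, 200, 0)
  expect_error(classify_trajectory(inp), "absent at both")
})

test_that("clonality uses the 0.40 threshold inclusively and flags transitions", {
  inp <- dplyr::bind_rows(
    make_traj_input("P1", "KRAS", 100, 200, 36, 200, 104),  # 0.18 -> 0.52
    make_traj_input("P1", "ATM", 200, 200, 90, 200, 96),    # 0.45 -> 0.48
    make_traj_input("P1", "RET", 300, 200, 80, 200, 80))    # 0.40 exactly
  out <- classify_trajectory(inp)
  expect_equal(out$clonality_first, c("subclonal", "clonal", "clonal"))
  expect_equal(out$clonality_paired, c("clonal", "clonal", "clonal"))
  expect_equal(out$clonal_transition, c(TRUE, FALSE, FALSE))
  # absent timepoint is 'absent'
  acq <- classify_trajectory(make_traj_input("P2", "TP53", 1, 200, 0, 200, 110))
  expect_equal(acq$clonality_first, "absent")
})

test_that("patient patterns partition patients by acquired/lost counts", {
  inp <- dplyr::bind_rows(
    make_traj_input("Pbr", "A1", 1, 200, 0, 200, 50),
    make_traj_input("Pbr", "A2", 2, 200, 50, 200, 0),
    make_traj_input("Pbr", "A3", 3, 200, 60, 200, 62),
    make_traj_input("Pacq", "B1", 4, 200, 0, 200, 50),
    make_traj_input("Pacq", "B2", 5, 200, 0, 200, 70),
    make_traj_input("Plos", "C1", 6, 200, 50, 200, 0),
    make_traj_input("Pst", "D1", 7, 200, 60, 200, 62),
    make_traj_input("Pst", "D2", 8, 200, 80, 200, 84))
  pat <- classify_patient_pattern(classify_trajectory(inp))
  got <- stats::setNames(pat$pattern, pat$patient_id)
  expect_equal(got[["Pbr"]], "branching")
  expect_equal(got[["Pacq"]], "acquisition")
  expect_equal(got[["Plos"]], "loss")
  expect_equal(got[["Pst"]], "stable")
  # partition: one pattern per patient, counts add up
  expect_equal(sort(unique(pat$patient_id)),
               sort(unique(inp$patient_id)))
  expect_error(classify_patient_pattern(
    classify_trajectory(inp[0, ])), "no classified")
})

test_that("swapping the samples maps acquired<->lost and fixes stable", {
  sim <- simulate_cohort(simulation_config(n_patients = 15, seed = 31))
  res <- run_cascade(sim$cohort)
  fwd <- classify_trajectory(res$retained)
  swapped <- res$retained
  swap <- function(df, a, b) { tmp <- df[[a]]; df[[a]] <- df[[b]]; df[[b]] <- tmp; df }
  swapped <- swap(swapped, "depth_first", "depth_paired")
  swapped <- swap(swapped, "alt_reads_first", "alt_reads_paired")
  swapped <- swap(swapped, "vaf_first", "vaf_paired")
  rev <- classify_trajectory(swapped)
  map <- c(acquired = "lost", lost = "acquired", expanded = "declined",
           declined = "expanded", stable = "stable")
  expect_equal(unname(map[fwd$trajectory_class]), rev$trajectory_class)
  # classes partition the variants
  expect_true(all(fwd$trajectory_class %in%
                    c("acquired", "lost", "expanded", "declined", "stable")))
  # pattern symmetry: acquisition <-> loss, branching and stable fixed
  p_fwd <- classify_patient_pattern(fwd)
  p_rev <- classify_patient_pattern(rev)
  pmap <- c(acquisition = "loss", loss = "acquisition",
            branching = "branching", stable = "stable")
  merged <- dplyr::inner_join(p_fwd, p_rev, by = "patient_id")
  expect_equal(unname(pmap[merged$pattern.x]), merged$pattern.y)
})

test_that("parallel evolution needs two distinct co-present variants of one gene", {
  inp <- dplyr::bind_rows(
    make_traj_input("P21", "TP53", 550, 200, 0, 200, 40, cdna = "c.550G>C"),
    make_traj_input("P21", "TP53", 814, 200, 0, 200, 30, cdna = "c.814G>A"),
    make_traj_input("P21", "KRAS", 35, 200, 60, 200, 66),
    make_traj_input("P22", "ATM", 10, 200, 50, 200, 55))
  traj <- classify_trajectory(inp)
  ev <- detect_parallel_evolution(traj)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$gene, "TP53")
  expect_equal(ev$sample, "paired")
  expect_equal(ev$n_variants, 2L)
  # acquired-only mode drops co-presence of non-acquired pairs
  inp2 <- dplyr::bind_rows(
    make_traj_input("P9", "CYLD", 1, 200, 50, 200, 52, cdna = "c.1C>T"),
    make_traj_input("P9", "CYLD", 2, 200, 0, 200, 52, cdna = "c.2C>T"))
  traj2 <- classify_trajectory(inp2)
  expect_equal(nrow(detect_parallel_evolution(traj2)), 1)
  cfg_acq <- trajectory_config(parallel_acquired_only = TRUE)
  expect_equal(nrow(detect_parallel_evolution(traj2, cfg_acq)), 0)
})

test_that("pathway and druggable summaries match brute-force set algebra", {
  sim <- simulate_cohort(simulation_config(n_patients = 10, seed = 17))
  res <- run_cascade(sim$cohort)
  traj <- classify_trajectory(res$retained)
  drg <- default_druggable_lists()
  s <- summarize_pathways_and_druggable(traj, druggable_lists = drg)
  pw_map <- default_pathway_map()
  for (i in seq_len(nrow(s$pathways))) {
    genes_i <- traj$gene[traj$patient_id == s$pathways$patient_id[i]]
    for (lab in names(pw_map)) {
      expect_identical(s$pathways[[lab]][i],
                       length(intersect(genes_i, pw_map[[lab]])) > 0)
    }
  }
  for (db in names(drg)) {
    for (cl in c("expanded", "declined", "stable", "acquired")) {
      n_bf <- sum(traj$gene %in% drg[[db]] & traj$trajectory_class == cl)
      row <- s$druggable[s$druggable$database == db &
                           s$druggable$trajectory_class == cl, ]
      expect_equal(row$n_variants, n_bf)
    }
  }
  empty <- summarize_pathways_and_druggable(traj,
                                            druggable_lists = list(none = character()))
  expect_true(all(empty$druggable$n_variants == 0))
})

test_that("trajectory classes are recovered on deep synthetic cohorts", {
  # depth 300, CCF changes >= 0.25 or exactly 0 by construction
  cfg <- simulation_config(n_patients = 200, mean_depth = 300, seed = 2024)
  sim <- simulate_cohort(cfg)
  res <- run_cascade(sim$cohort)
  traj <- classify_trajectory(res$retained)
  truth <- dplyr::filter(sim$truth$variants, !is.na(trajectory_class))
  merged <- dplyr::inner_join(
    traj, truth, by = c("patient_id", "chrom", "pos", "ref", "alt"))
  acc <- mean(merged$trajectory_class.x == merged$trajectory_class.y)
  expect_gte(acc, 0.95)
  # patient patterns recovered for >= 95% of patients
  pat <- classify_patient_pattern(traj)
  pm <- dplyr::inner_join(pat, sim$truth$patients, by = "patient_id")
  expect_gte(mean(pm$pattern.x == pm$pattern.y), 0.95)
})
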