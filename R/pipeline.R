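# End-to-end orchestration: filter -> trajectories -> CNV -> staging ->
# survival, with a run manifest and a cohort report mirroring the
# paired-sample summaries (variant counts, trajectory fractions, pattern
# counts, CNV evolution, stage redistribution, survival comparisons).

#' Run the full paired-sample pipeline
#'
#' Validates the cohort (refusing to run on hard validation errors), then
#' executes the filter cascade, trajectory classification, patient pattern
#' calls, parallel-evolution and clonality summaries, CNV event calling and
#' evolution, biallelic and double-hit detection, staging at both
#' timepoints with the restaging matrix, the R-ISS-group survival
#' comparisons (PFS, OS from first sample, OS from paired sample) and the
#' pattern-response association.
#'
#' @param cohort An `mm_cohort`.
#' @param filter_cfg,traj_cfg,cnv_cfg Stage configurations.
#' @param region_defs CNV region definitions.
#' @param druggable_lists Named list of druggable-gene sets.
#' @param out_dir Optional directory; when given, each stage's table is
#'   written as TSV and the manifest records the paths.
#' @return List of class `mm_pipeline_result` with elements `filter`,
#'   `trajectories`, `patterns`, `parallel`, `summaries`, `cnv_events`,
#'   `cnv_evolution`, `biallelic`, `double_hits`, `staging`,
#'   `restaging`, `survival`, `response`, `manifest`.
#' @export
run_pipeline <- function(cohort,
                         filter_cfg = filter_config(),
                         traj_cfg = trajectory_config(),
                         cnv_cfg = cnv_config(),
                         region_defs = default_region_defs(),
                         druggable_lists = default_druggable_lists(),
                         out_dir = NULL) {
  t0 <- Sys.time()
  validation <- validate_cohort(cohort)
  if (!isTRUE(attr(validation, "ok"))) {
    stop("cohort failed validation at stage 'validate': ",
         paste(unique(validation$issue[validation$severity == "error"]),
               collapse = "; "))
  }

  casc <- run_cascade(cohort, filter_cfg)
  traj <- classify_trajectory(casc$retained, traj_cfg)
  patterns <- if (nrow(traj) > 0) classify_patient_pattern(traj) else
    tibble::tibble(patient_id = character(), pattern = character(),
                   n_acquired = integer(), n_lost = integer(),
                   n_shared = integer(), n_clonal_transitions = integer())
  parallel <- detect_parallel_evolution(traj, traj_cfg)
  summaries <- summarize_pathways_and_druggable(
    traj, druggable_lists = druggable_lists)

  cnv_ev <- call_events_cohort(cohort, region_defs, cnv_cfg)
  pairs <- sample_pairs(cohort)
  cnv_evo <- list()
  for (i in seq_len(nrow(pairs))) {
    e1 <- cnv_ev[cnv_ev$patient_id == pairs$patient_id[i] &
                   cnv_ev$sample_index == pairs$first_index[i], ]
    e2 <- cnv_ev[cnv_ev$patient_id == pairs$patient_id[i] &
                   cnv_ev$sample_index == pairs$paired_index[i], ]
    if (nrow(e1) != 1 || nrow(e2) != 1) next
    ev1 <- unlist(e1[CNV_EVENT_LABELS])
    ev2 <- unlist(e2[CNV_EVENT_LABELS])
    names(ev1) <- names(ev2) <- CNV_EVENT_LABELS
    ce <- classify_cnv_evolution(ev1, ev2)
    cnv_evo[[i]] <- tibble::tibble(
      patient_id = pairs$patient_id[i], region = CNV_EVENT_LABELS,
      transition = unname(ce$transitions),
      stable_profile = ce$stable_profile)
  }
  cnv_evolution <- dplyr::bind_rows(cnv_evo)

  biallelic <- detect_biallelic_cohort(traj, cohort, cnv_cfg)

  hits <- list()
  for (i in seq_len(nrow(pairs))) {
    pid <- pairs$patient_id[i]
    for (tp in c("first", "paired")) {
      sidx <- if (tp == "first") pairs$first_index[i] else
        pairs$paired_index[i]
      e <- cnv_ev[cnv_ev$patient_id == pid & cnv_ev$sample_index == sidx, ]
      if (nrow(e) != 1) next
      cl <- cohort$clinical[cohort$clinical$patient_id == pid &
                              cohort$clinical$sample_index == sidx, ]
      fish <- list(del17p = cl$fish_del17p, t_4_14 = cl$fish_t_4_14,
                   t_14_16 = cl$fish_t_14_16)
      genes <- traj$gene[traj$patient_id == pid &
                           traj[[paste0("present_", tp)]]]
      ev <- unlist(e[CNV_EVENT_LABELS])
      names(ev) <- CNV_EVENT_LABELS
      dh <- detect_double_hit(ev, fish, genes)
      hits[[length(hits) + 1]] <- tibble::tibble(
        patient_id = pid, timepoint = tp, n_lesions = dh$n_lesions,
        lesions = paste(dh$lesions, collapse = ";"),
        double_hit = dh$double_hit, triple_hit = dh$triple_hit,
        tp53_double_hit = dh$tp53_double_hit)
    }
  }
  double_hits <- dplyr::bind_rows(hits)

  staging <- stage_cohort(cohort, cnv_ev)
  restaging <- restaging_matrix(staging, "riss")

  surv_results <- list()
  if (nrow(cohort$survival) > 0) {
    riss2 <- staging[staging$timepoint == "paired", ]
    sv <- dplyr::inner_join(cohort$survival, riss2, by = "patient_id")
    sv <- dplyr::filter(sv, .data$riss != "not_reported")
    sv$risk_group <- factor(ifelse(sv$riss == "III", "R-ISS 3", "R-ISS 1-2"),
                            levels = c("R-ISS 1-2", "R-ISS 3"))
    endpoints <- list(pfs = c("pfs_months", "pfs_event"),
                      os1 = c("os1_months", "os1_event"),
                      os2 = c("os2_months", "os2_event"))
    for (ep in names(endpoints)) {
      cols <- endpoints[[ep]]
      ok <- !is.na(sv[[cols[1]]]) & !is.na(sv[[cols[2]]])
      if (sum(ok) < 2 || length(unique(sv$risk_group[ok])) < 2) next
      surv_results[[ep]] <- survival_compare(
        sv[[cols[1]]][ok], sv[[cols[2]]][ok], sv$risk_group[ok])
    }
  }

  responses <- dplyr::select(
    dplyr::filter(cohort$clinical, .data$role == "paired"),
    "patient_id", "response")
  resp <- response_association(patterns, responses)

  manifest <- list(
    seed = NA_integer_,
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    n_patients = n_patients(cohort),
    stages = c("filter", "track", "cnv", "stage", "survive"),
    outputs = character())

  result <- list(filter = casc, trajectories = traj, patterns = patterns,
                 parallel = parallel, summaries = summaries,
                 cnv_events = cnv_ev, cnv_evolution = cnv_evolution,
                 biallelic = biallelic, double_hits = double_hits,
                 staging = staging, restaging = restaging,
                 survival = surv_results, response = resp,
                 manifest = manifest)
  class(result) <- "mm_pipeline_result"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      filter_report = "filter_report.tsv",
      trajectories = "trajectories.tsv",
      patterns = "patterns.tsv",
      parallel = "parallel_evolution.tsv",
      cnv_events = "cnv_events.tsv",
      cnv_evolution = "cnv_evolution.tsv",
      biallelic = "biallelic_events.tsv",
      double_hits = "double_hits.tsv",
      staging = "staging.tsv")
    write_tsv_dot(casc$report, file.path(out_dir, paths["filter_report"]))
    write_tsv_dot(traj, file.path(out_dir, paths["trajectories"]))
    write_tsv_dot(patterns, file.path(out_dir, paths["patterns"]))
    write_tsv_dot(parallel, file.path(out_dir, paths["parallel"]))
    write_tsv_dot(cnv_ev, file.path(out_dir, paths["cnv_events"]))
    write_tsv_dot(cnv_evolution, file.path(out_dir, paths["cnv_evolution"]))
    write_tsv_dot(biallelic, file.path(out_dir, paths["biallelic"]))
    write_tsv_dot(double_hits, file.path(out_dir, paths["double_hits"]))
    write_tsv_dot(staging, file.path(out_dir, paths["staging"]))
    utils::write.table(restaging, file.path(out_dir, "restaging_matrix.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    result$manifest$outputs <- file.path(out_dir, unname(paths))
  }
  result
}

round_pct <- function(x) {
  # nearest-integer percentages, as in the text summaries
  ifelse(is.na(x), NA_integer_, as.integer(round(100 * x)))
}

#' Render a cohort report
#'
#' Produces a structured report (list, serializable to JSON) plus a
#' human-readable text rendering with the headline cohort summaries:
#' variants per patient, trajectory class counts with integer-percent
#' fractions, evolution-pattern counts, parallel-evolution and biallelic
#' listings, the CNV evolution table, the stage redistribution matrix and
#' the survival comparisons. All numbers are recomputed from the stage
#' outputs held in the pipeline result; the text report rounds percentages
#' to the nearest integer while the structured form keeps full precision.
#'
#' @param result An `mm_pipeline_result` from [run_pipeline()].
#' @return List with `report` (nested list) and `text` (character vector of
#'   report lines).
#' @export
render_report <- function(result) {
  stopifnot(inherits(result, "mm_pipeline_result"))
  traj <- result$trajectories
  per_pat <- dplyr::count(traj, .data$patient_id)
  vpp <- if (nrow(per_pat) > 0) {
    list(median = stats::median(per_pat$n),
         min = min(per_pat$n), max = max(per_pat$n))
  } else list(median = 0, min = 0, max = 0)

  cls_counts <- table(factor(traj$trajectory_class,
                             levels = TRAJECTORY_CLASSES))
  shared_n <- sum(cls_counts[c("expanded", "declined", "stable")])
  cls <- lapply(TRAJECTORY_CLASSES, function(cl) {
    n <- unname(cls_counts[[cl]])
    denom <- if (cl %in% c("expanded", "declined", "stable")) shared_n
             else nrow(traj)
    list(class = cl, n = n,
         fraction = if (denom > 0) n / denom else NA_real_)
  })

  pat_counts <- table(factor(result$patterns$pattern,
                             levels = EVOLUTION_PATTERNS))

  report <- list(
    n_patients = result$manifest$n_patients,
    filter_report = result$filter$report,
    variants_per_patient = vpp,
    trajectory_classes = cls,
    patterns = as.list(pat_counts),
    parallel_evolution = result$parallel,
    biallelic_events = result$biallelic,
    cnv_evolution = result$cnv_evolution,
    restaging_matrix = result$restaging,
    survival = lapply(result$survival, function(s) {
      list(groups = s$groups, hr = s$hr, ci95 = s$ci95,
           p_logrank = s$p_logrank, p_wald = s$p_wald)
    }),
    response_association = list(table = result$response$table,
                                p = result$response$p))

  txt <- c(
    sprintf("Cohort report: %d patients", report$n_patients),
    "",
    "Filter cascade:",
    sprintf("  %-20s retained %4d  rejected %4d",
            result$filter$report$stage, result$filter$report$retained,
            result$filter$report$rejected),
    "",
    sprintf("Variants per patient (retained): median %s (range, %s-%s)",
            vpp$median, vpp$min, vpp$max),
    "Trajectory classes:",
    vapply(cls, function(x) {
      sprintf("  %-9s %4d%s", x$class, x$n,
              if (!is.na(x$fraction))
                sprintf(" (%d%%)", round_pct(x$fraction)) else "")
    }, ""),
    "Evolution patterns:",
    sprintf("  %-12s %3d (%d%%)", names(pat_counts), as.integer(pat_counts),
            round_pct(as.integer(pat_counts) /
                        max(1, sum(pat_counts)))),
    "",
    sprintf("Parallel-evolution events: %d", nrow(result$parallel)),
    sprintf("Biallelic events: %d", nrow(result$biallelic)),
    sprintf("Stable CNV profiles: %d of %d",
            sum(tapply(result$cnv_evolution$stable_profile,
                       result$cnv_evolution$patient_id, any)),
            length(unique(result$cnv_evolution$patient_id))),
    "")
  for (ep in names(result$survival)) {
    s <- result$survival[[ep]]
    txt <- c(txt, sprintf(
      "%s: medians %s vs %s months; HR %.1f (95%% CI %.1f-%.1f); log-rank p = %.3g",
      toupper(ep), format(s$groups$median_months[1]),
      format(s$groups$median_months[2]), s$hr, s$ci95[1], s$ci95[2],
      s$p_logrank))
  }
  if (!is.na(result$response$p)) {
    txt <- c(txt, sprintf(
      "Response (>=VGPR) loss vs acquisition: Fisher p = %.3g",
      result$response$p))
  }
  list(report = report, text = txt)
}
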