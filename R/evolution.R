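# Paired-sample trajectory classification and patient-level evolution
# patterns. Each filtered variant is tracked between the first and the
# paired sample: acquired, lost, expanded, declined or stable. Patients are
# then classified into branching / acquisition / loss / stable evolution
# from the acquired and lost counts.

TRAJECTORY_CLASSES <- c("acquired", "lost", "expanded", "declined", "stable")
EVOLUTION_PATTERNS <- c("branching", "acquisition", "loss", "stable")

#' Trajectory classification configuration
#'
#' @param presence_alt_reads_min Minimum supporting reads for a variant to
#'   count as present at a timepoint (default 3). Together with
#'   `presence_vaf_min` this is the noise floor that defines "disappeared".
#' @param presence_vaf_min Minimum VAF for presence (default 0.02).
#' @param change_alpha Significance level of the two-sided two-proportion
#'   test on the (alt_reads, depth) pairs used to call expansion/decline
#'   (default 0.05).
#' @param change_delta_min Minimum absolute VAF difference additionally
#'   required for expansion/decline (default 0.10); guards against
#'   over-calling tiny but significant shifts at high depth.
#' @param clonal_vaf_min VAF at or above which a present variant is called
#'   clonal (default 0.40); below it, subclonal.
#' @param parallel_acquired_only If `TRUE`, parallel evolution requires the
#'   co-present variants of a gene to both be acquired; default `FALSE`
#'   (co-presence in the same sample suffices).
#' @return A list of class `trajectory_config`.
#' @export
trajectory_config <- function(presence_alt_reads_min = 3L,
                              presence_vaf_min = 0.02,
                              change_alpha = 0.05,
                              change_delta_min = 0.10,
                              clonal_vaf_min = 0.40,
                              parallel_acquired_only = FALSE) {
  stopifnot(presence_vaf_min > 0, presence_vaf_min < clonal_vaf_min,
            clonal_vaf_min <= 1, change_alpha > 0, change_alpha < 1)
  structure(list(presence_alt_reads_min = as.integer(presence_alt_reads_min),
                 presence_vaf_min = presence_vaf_min,
                 change_alpha = change_alpha,
                 change_delta_min = change_delta_min,
                 clonal_vaf_min = clonal_vaf_min,
                 parallel_acquired_only = parallel_acquired_only),
            class = "trajectory_config")
}

#' Presence call at one timepoint
#'
#' A variant is present iff it has at least `presence_alt_reads_min`
#' supporting reads and VAF at least `presence_vaf_min` (both inclusive).
#'
#' @param alt_reads,vaf Observation at one timepoint; vectorized.
#' @param config A [trajectory_config()].
#' @return Logical vector.
#' @export
presence_call <- function(alt_reads, vaf, config = trajectory_config()) {
  unname(alt_reads >= config$presence_alt_reads_min &
           vaf >= config$presence_vaf_min)
}

vaf_change_test_p <- function(alt_first, depth_first, alt_paired,
                              depth_paired) {
  # two-sided two-proportion test without continuity correction; degenerate
  # margins (all or no successes at both timepoints) give p = 1
  mapply(function(a1, d1, a2, d2) {
    if (d1 == 0 || d2 == 0) return(NA_real_)
    if (a1 + a2 == 0 || a1 + a2 == d1 + d2) return(1)
    suppressWarnings(
      stats::prop.test(c(a1, a2), c(d1, d2), correct = FALSE)$p.value)
  }, alt_first, depth_first, alt_paired, depth_paired)
}

#' Classify the trajectory of each variant across the sample pair
#'
#' Presence at each timepoint is determined by [presence_call()]. A variant
#' present only at the paired sample is `acquired`; only at the first
#' sample, `lost`. A variant present at both is `expanded` when the
#' two-sided two-proportion test on its read counts rejects at
#' `change_alpha` with a VAF increase of at least `change_delta_min`
#' (`declined` symmetrically), and `stable` otherwise. Clonality is attached
#' by the same call: a present timepoint is `clonal` at
#' `vaf >= clonal_vaf_min`, else `subclonal`; absent timepoints are
#' `absent`.
#'
#' @param retained Tibble in the wide paired-observation format (see
#'   [paired_observations()] / [run_cascade()]); a variant absent at both
#'   timepoints violates the filter precondition and is an error.
#' @param config A [trajectory_config()].
#' @return The input tibble with columns `present_first`, `present_paired`,
#'   `trajectory_class`, `change_p`, `clonality_first`, `clonality_paired`,
#'   `clonal_transition` added.
#' @export
classify_trajectory <- function(retained, config = trajectory_config()) {
  retained <- tibble::as_tibble(retained)
  require_columns(retained,
                  c("patient_id", variant_key_cols(), "gene", "cdna",
                    "depth_first", "alt_reads_first", "vaf_first",
                    "depth_paired", "alt_reads_paired", "vaf_paired"),
                  "retained variants")
  if (nrow(retained) == 0) {
    retained$present_first <- logical(0)
    retained$present_paired <- logical(0)
    retained$trajectory_class <- character(0)
    retained$change_p <- double(0)
    retained$clonality_first <- character(0)
    retained$clonality_paired <- character(0)
    retained$clonal_transition <- logical(0)
    return(retained)
  }

  p1 <- presence_call(retained$alt_reads_first, retained$vaf_first, config)
  p2 <- presence_call(retained$alt_reads_paired, retained$vaf_paired, config)
  if (any(!p1 & !p2)) {
    stop(sum(!p1 & !p2), " variant(s) absent at both timepoints reached ",
         "trajectory classification; the filter should have removed them")
  }

  pvals <- rep(NA_real_, nrow(retained))
  both <- p1 & p2
  if (any(both)) {
    pvals[both] <- vaf_change_test_p(
      retained$alt_reads_first[both], retained$depth_first[both],
      retained$alt_reads_paired[both], retained$depth_paired[both])
  }
  delta <- retained$vaf_paired - retained$vaf_first
  cls <- rep(NA_character_, nrow(retained))
  cls[!p1 & p2] <- "acquired"
  cls[p1 & !p2] <- "lost"
  signif_up <- both & !is.na(pvals) & pvals < config$change_alpha &
    delta >= config$change_delta_min
  signif_dn <- both & !is.na(pvals) & pvals < config$change_alpha &
    -delta >= config$change_delta_min
  cls[signif_up] <- "expanded"
  cls[signif_dn] <- "declined"
  cls[both & is.na(cls)] <- "stable"

  clon <- function(present, vaf) {
    ifelse(!present, "absent",
           ifelse(vaf >= config$clonal_vaf_min, "clonal", "subclonal"))
  }
  retained$present_first <- p1
  retained$present_paired <- p2
  retained$trajectory_class <- cls
  retained$change_p <- pvals
  retained$clonality_first <- clon(p1, retained$vaf_first)
  retained$clonality_paired <- clon(p2, retained$vaf_paired)
  retained$clonal_transition <- retained$clonality_first == "subclonal" &
    retained$clonality_paired == "clonal"
  retained
}

#' Patient-level evolution pattern
#'
#' From the trajectory classes of one patient's variants:
#' `branching` when at least one variant was acquired and at least one lost;
#' `acquisition` with acquisitions only; `loss` with losses only; `stable`
#' when no variant was acquired or lost.
#'
#' @param trajectories Classified tibble from [classify_trajectory()]
#'   (any number of patients).
#' @return Tibble with one row per patient: `patient_id`, `pattern`,
#'   `n_acquired`, `n_lost`, `n_shared`, `n_clonal_transitions`.
#' @export
classify_patient_pattern <- function(trajectories) {
  if (nrow(trajectories) == 0) {
    stop("no classified trajectories; at least one variant per patient is required")
  }
  dplyr::summarise(
    dplyr::group_by(trajectories, .data$patient_id),
    n_acquired = sum(.data$trajectory_class == "acquired"),
    n_lost = sum(.data$trajectory_class == "lost"),
    n_shared = sum(.data$trajectory_class %in%
                     c("expanded", "declined", "stable")),
    n_clonal_transitions = sum(.data$clonal_transition, na.rm = TRUE),
    pattern = if (n_acquired[1] >= 1 && n_lost[1] >= 1) "branching"
              else if (n_acquired[1] >= 1) "acquisition"
              else if (n_lost[1] >= 1) "loss"
              else "stable",
    .groups = "drop")
}

#' Detect parallel evolution within genes
#'
#' Emits one event per (patient, gene) where at least two distinct variants
#' of the same gene are present in the same sample. With
#' `parallel_acquired_only` in the config, both variants must additionally
#' be acquired.
#'
#' @param trajectories Classified tibble from [classify_trajectory()].
#' @param config A [trajectory_config()].
#' @return Tibble `patient_id`, `gene`, `sample` (`"first"`/`"paired"`),
#'   `n_variants`, `variant_keys` (semicolon-joined `chrom:pos:ref:alt`).
#' @export
detect_parallel_evolution <- function(trajectories,
                                      config = trajectory_config()) {
  tr <- trajectories
  if (config$parallel_acquired_only) {
    tr <- dplyr::filter(tr, .data$trajectory_class == "acquired")
  }
  key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  out <- list()
  for (tp in c("first", "paired")) {
    pres <- tr[tr[[paste0("present_", tp)]], , drop = FALSE]
    if (nrow(pres) == 0) next
    grp <- dplyr::summarise(
      dplyr::group_by(pres, .data$patient_id, .data$gene),
      n_variants = dplyr::n_distinct(paste(.data$chrom, .data$pos,
                                           .data$ref, .data$alt)),
      variant_keys = paste(sort(unique(paste(.data$chrom, .data$pos,
                                             .data$ref, .data$alt,
                                             sep = ":"))),
                           collapse = ";"),
      .groups = "drop")
    grp <- dplyr::filter(grp, .data$n_variants >= 2, !is.na(.data$gene))
    if (nrow(grp) > 0) {
      grp$sample <- tp
      out[[tp]] <- grp
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(patient_id = character(), gene = character(),
                          n_variants = integer(), variant_keys = character(),
                          sample = character()))
  }
  dplyr::bind_rows(out)
}

#' Default pathway gene sets
#'
#' The three functional groups summarized for this panel: MAPK/ERK
#' signaling, DNA repair, and epigenetic regulators.
#'
#' @return Named list of character vectors.
#' @export
default_pathway_map <- function() {
  list(
    mapk_erk = c("KRAS", "BRAF", "EGFR", "FGFR3", "DUSP2"),
    dna_repair = c("ATM", "ATR", "FANCA", "BRCA2", "BRIP1", "MLH1", "TP53"),
    epigenetic = c("ARID1A", "ARID2", "ARID4B", "CCND1", "CREBBP", "EP300",
                   "KMT2B", "KMT2C", "KMT2D", "NCOR2", "PRDM9"))
}

#' Pathway and druggable-gene summaries
#'
#' Per patient, whether at least one retained variant falls in each pathway
#' gene set; per druggable-gene database, how many shared variants (present
#' at both timepoints) in druggable genes fall into each trajectory class,
#' plus acquired druggable variants.
#'
#' @param trajectories Classified tibble from [classify_trajectory()].
#' @param pathway_map Named list of gene vectors
#'   (default [default_pathway_map()]).
#' @param druggable_lists Named list of gene vectors, e.g.
#'   `list(oncokb = c(...), target = c(...))`; default empty.
#' @return List with tibbles `pathways` (patient x pathway logical) and
#'   `druggable` (database, trajectory_class, n_variants, n_patients).
#' @export
summarize_pathways_and_druggable <- function(trajectories,
                                             pathway_map = default_pathway_map(),
                                             druggable_lists = list()) {
  patients <- unique(trajectories$patient_id)
  pw <- tibble::tibble(patient_id = patients)
  for (label in names(pathway_map)) {
    genes <- pathway_map[[label]]
    hit <- dplyr::summarise(
      dplyr::group_by(trajectories, .data$patient_id),
      hit = any(.data$gene %in% genes), .groups = "drop")
    pw[[label]] <- hit$hit[match(pw$patient_id, hit$patient_id)]
  }

  drg <- list()
  classes <- c("expanded", "declined", "stable", "acquired")
  for (db in names(druggable_lists)) {
    genes <- druggable_lists[[db]]
    sub <- dplyr::filter(trajectories, .data$gene %in% genes,
                         .data$trajectory_class %in% classes)
    counts <- dplyr::summarise(
      dplyr::group_by(sub, trajectory_class = .data$trajectory_class),
      n_variants = dplyr::n(),
      n_patients = dplyr::n_distinct(.data$patient_id),
      .groups = "drop")
    counts <- dplyr::right_join(
      counts, tibble::tibble(trajectory_class = classes),
      by = "trajectory_class")
    counts$n_variants[is.na(counts$n_variants)] <- 0L
    counts$n_patients[is.na(counts$n_patients)] <- 0L
    counts$database <- db
    drg[[db]] <- counts
  }
  druggable <- if (length(drg) == 0) {
    tibble::tibble(database = character(), trajectory_class = character(),
                   n_variants = integer(), n_patients = integer())
  } else {
    dplyr::select(dplyr::bind_rows(drg), "database", "trajectory_class",
                  "n_variants", "n_patients")
  }
  list(pathways = pw, druggable = druggable)
}
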