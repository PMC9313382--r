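# Consensus somatic-variant inclusion cascade for tumor-only panel data:
# (1) rare in the general population, (2) adequate VAF / read support in at
# least one of the paired samples, (3) pathogenic consensus across
# predictors with a recurrent-gene exception, (4) rejection of
# benign / likely-benign ACMG classifications with a whitelist.

#' Filter cascade configuration
#'
#' @param pop_af_max Maximum population allele frequency; a variant passes
#'   only when every non-missing database AF is strictly below this
#'   (default 0.01, i.e. "< 1 percent").
#' @param vaf_min Minimum VAF required in at least one of the paired samples
#'   (default 0.10, inclusive).
#' @param alt_reads_min Minimum supporting reads required together with
#'   `vaf_min` in the same sample (default 5, inclusive).
#' @param consensus_min Minimum number of pathogenic predictor verdicts
#'   (default 2, out of the six predictors).
#' @param whitelist Data frame with columns `gene`, `cdna` of variants kept
#'   at the ACMG rejection stage regardless of class. Default: the single
#'   KMT2C c.1173C>A entry.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(pop_af_max = 0.01, vaf_min = 0.10,
                          alt_reads_min = 5L, consensus_min = 2L,
                          whitelist = default_whitelist()) {
  stopifnot(pop_af_max > 0, vaf_min > 0, alt_reads_min > 0,
            consensus_min >= 0, consensus_min <= 6)
  structure(list(pop_af_max = pop_af_max, vaf_min = vaf_min,
                 alt_reads_min = as.integer(alt_reads_min),
                 consensus_min = as.integer(consensus_min),
                 whitelist = tibble::as_tibble(whitelist)),
            class = "filter_config")
}

#' @rdname filter_config
#' @export
default_whitelist <- function() {
  tibble::tibble(gene = "KMT2C", cdna = "c.1173C>A")
}

#' Population allele-frequency stage
#'
#' `TRUE` iff every non-missing database allele frequency (1000 Genomes,
#' gnomAD, ESP) is strictly below `pop_af_max`. A variant missing from all
#' three databases passes: absence from population databases is itself
#' evidence of rarity.
#'
#' @param af_g1000,af_gnomad,af_esp Population AFs in [0, 1] or `NA`;
#'   vectorized.
#' @param config A [filter_config()].
#' @return Logical vector.
#' @export
population_af_pass <- function(af_g1000, af_gnomad, af_esp,
                               config = filter_config()) {
  afs <- cbind(af_g1000, af_gnomad, af_esp)
  if (nrow(afs) == 0) return(logical(0))
  if (any(afs < 0 | afs > 1, na.rm = TRUE)) {
    stop("population allele frequency outside [0,1]")
  }
  # pmax over rows, treating all-NA as -Inf (passes)
  worst <- suppressWarnings(apply(afs, 1, max, na.rm = TRUE))
  worst[!is.finite(worst)] <- -Inf
  unname(worst < config$pop_af_max)
}

#' VAF / read-support stage over the sample pair
#'
#' `TRUE` iff at least one of the two observations of a variant has
#' `vaf >= vaf_min` and `alt_reads >= alt_reads_min` simultaneously
#' (both boundaries inclusive).
#'
#' @param vaf_first,alt_first VAF and supporting reads at the first sample;
#'   vectorized.
#' @param vaf_paired,alt_paired Same at the paired sample.
#' @param config A [filter_config()].
#' @return Logical vector.
#' @export
vaf_support_pass <- function(vaf_first, alt_first, vaf_paired, alt_paired,
                             config = filter_config()) {
  ok1 <- vaf_first >= config$vaf_min & alt_first >= config$alt_reads_min
  ok2 <- vaf_paired >= config$vaf_min & alt_paired >= config$alt_reads_min
  unname(ok1 | ok2)
}

#' Predictor consensus stage
#'
#' `TRUE` iff the variant has a pathogenic verdict from at least
#' `consensus_min` of the six predictors, or — for genes recurrently mutated
#' in myeloma — from at least one of the cancer-specific predictors
#' (CRAVAT, CHASM, FATHMM Cancer, CScape). Missing verdicts count as
#' non-pathogenic.
#'
#' @param verdicts Data frame (or tibble row set) with the six `pred_*`
#'   columns; values `"pathogenic"`, `"benign"` or `NA`.
#' @param recurrent_mm_gene Logical vector; `NA` treated as `FALSE`.
#' @param config A [filter_config()].
#' @return Logical vector.
#' @export
predictor_consensus_pass <- function(verdicts, recurrent_mm_gene,
                                     config = filter_config()) {
  cols <- predictor_cols()
  require_columns(verdicts, cols, "predictor verdicts")
  vals <- as.matrix(verdicts[cols])
  bad <- setdiff(stats::na.omit(unique(as.vector(vals))),
                 c("pathogenic", "benign"))
  if (length(bad) > 0) {
    stop("unknown predictor verdict(s): ", paste(bad, collapse = ", "))
  }
  patho <- vals == "pathogenic"
  patho[is.na(patho)] <- FALSE
  n_patho <- rowSums(patho)
  cancer_cols <- paste0("pred_", CANCER_SPECIFIC_PREDICTORS)
  n_cancer <- rowSums(patho[, cols %in% cancer_cols, drop = FALSE])
  rec <- recurrent_mm_gene
  rec[is.na(rec)] <- FALSE
  unname(n_patho >= config$consensus_min | (rec & n_cancer >= 1))
}

#' ACMG-class rejection stage
#'
#' Rejects variants with ACMG class benign or likely benign unless their
#' (gene, cDNA) pair is whitelisted. Variants with any other class —
#' including a missing class — are retained: rejection requires affirmative
#' benign evidence.
#'
#' @param variants Data frame with columns `gene`, `cdna`, `acmg_class`.
#' @param config A [filter_config()].
#' @return List with tibbles `retained` and `rejected` (disjoint, union =
#'   input).
#' @export
varsome_stage <- function(variants, config = filter_config()) {
  variants <- tibble::as_tibble(variants)
  require_columns(variants, c("gene", "cdna", "acmg_class"), "variants")
  if (nrow(variants) == 0) {
    return(list(retained = variants, rejected = variants))
  }
  benign <- variants$acmg_class %in% c("benign", "likely_benign")
  wl <- paste(variants$gene, variants$cdna) %in%
    paste(config$whitelist$gene, config$whitelist$cdna)
  keep <- !benign | wl
  list(retained = variants[keep, , drop = FALSE],
       rejected = variants[!keep, , drop = FALSE])
}

#' Run the full inclusion cascade over a cohort
#'
#' Applies, in order, the population-AF, VAF/read-support, predictor
#' consensus and ACMG rejection stages to every (patient, variant-key) unit
#' of the designated sample pair. A variant passes or fails as a unit using
#' its two paired-sample observations; observations at extra samples play no
#' role.
#'
#' @param cohort A validated `mm_cohort`.
#' @param config A [filter_config()].
#' @return A list with:
#'   \describe{
#'     \item{retained}{tibble of retained (patient, variant) rows, the wide
#'       paired-observation format of [paired_observations()];}
#'     \item{report}{tibble `stage`, `retained`, `rejected` — the counts of
#'       (patient, variant) units surviving each stage;}
#'     \item{cohort}{the input cohort with `variants` restricted to retained
#'       (patient, key) units.}
#'   }
#' @export
run_cascade <- function(cohort, config = filter_config()) {
  po <- paired_observations(cohort)
  n0 <- nrow(po)

  stage_counts <- list()
  note <- function(stage, before, after) {
    stage_counts[[length(stage_counts) + 1]] <<- tibble::tibble(
      stage = stage, retained = after, rejected = before - after)
  }

  if (n0 == 0) {
    report <- tibble::tibble(
      stage = c("population_af", "vaf_support", "predictor_consensus",
                "varsome"),
      retained = 0L, rejected = 0L)
    return(list(retained = po, report = report, cohort = cohort))
  }

  p1 <- population_af_pass(po$af_g1000, po$af_gnomad, po$af_esp, config)
  po1 <- po[p1, , drop = FALSE]
  note("population_af", n0, nrow(po1))

  p2 <- vaf_support_pass(po1$vaf_first, po1$alt_reads_first,
                         po1$vaf_paired, po1$alt_reads_paired, config)
  po2 <- po1[p2, , drop = FALSE]
  note("vaf_support", nrow(po1), nrow(po2))

  p3 <- predictor_consensus_pass(po2, po2$recurrent_mm_gene, config)
  po3 <- po2[p3, , drop = FALSE]
  note("predictor_consensus", nrow(po2), nrow(po3))

  vs <- varsome_stage(po3, config)
  note("varsome", nrow(po3), nrow(vs$retained))

  retained <- vs$retained
  report <- dplyr::bind_rows(stage_counts)

  keep_keys <- dplyr::distinct(retained, .data$patient_id,
                               dplyr::across(dplyr::all_of(variant_key_cols())))
  filtered <- cohort
  filtered$variants <- dplyr::semi_join(
    cohort$variants, keep_keys,
    by = c("patient_id", variant_key_cols()))

  list(retained = retained, report = report, cohort = filtered)
}
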