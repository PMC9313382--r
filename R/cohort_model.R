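# Cohort container, file readers/writers and validation shared by all
# pipeline stages. Variants use 1-based positions (VCF convention); copy
# number segments use 0-based half-open coordinates (BED convention).

#' Predictor and enum vocabularies
#'
#' The six pathogenicity predictors consulted by the consensus filter, the
#' cancer-specific subset among them, the ACMG classification levels and the
#' IMWG response categories.
#'
#' @name vocabularies
#' @keywords internal
NULL

PREDICTOR_LABELS <- c("cravat", "chasm", "cscape", "fathmm_cancer",
                      "deogen2", "primateai")
CANCER_SPECIFIC_PREDICTORS <- c("cravat", "chasm", "fathmm_cancer", "cscape")
ACMG_LEVELS <- c("benign", "likely_benign", "vus",
                 "likely_pathogenic", "pathogenic")
RESPONSE_LEVELS <- c("CR", "VGPR", "PR", "SD", "PD")
POP_AF_DATABASES <- c("g1000", "gnomad", "esp")
FISH_FLAGS <- c("del17p", "t_4_14", "t_14_16", "t_11_14", "igh_other")
CNV_REGION_LABELS <- c("del1p_1p12", "del1p_1p22_1", "del1p_1p32_3",
                       "gain1q21", "del17p", "del13q", "del14q")

MISSING_TOKEN <- "."

predictor_cols <- function() paste0("pred_", PREDICTOR_LABELS)
pop_af_cols <- function() paste0("af_", POP_AF_DATABASES)
fish_cols <- function() paste0("fish_", FISH_FLAGS)

variant_key_cols <- function() c("chrom", "pos", "ref", "alt")

#' Construct a longitudinal myeloma cohort
#'
#' Bundles the five tables the pipeline operates on into a single validated
#' container. Each patient contributes a designated pair of samples (the
#' first sample and a later "paired" progression sample); additional samples
#' may be present with role `"extra"` and are ignored by paired-sample
#' statistics.
#'
#' @param variants Tibble of per-sample variant observations with columns
#'   `patient_id`, `sample_index`, `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `gene`, `cdna`, `depth`, `alt_reads`, `vaf`.
#' @param annotations Tibble keyed by (`chrom`,`pos`,`ref`,`alt`) with
#'   population allele frequencies (`af_g1000`, `af_gnomad`, `af_esp`),
#'   one verdict column per predictor (`pred_cravat`, ..., values
#'   `"pathogenic"`, `"benign"` or `NA`), `acmg_class`, `recurrent_mm_gene`
#'   and `druggable_sources` (comma-separated database labels or `NA`).
#' @param clinical Tibble with one row per (patient, sample): `patient_id`,
#'   `sample_index`, `timepoint_label`, `role` (`"first"`, `"paired"` or
#'   `"extra"`), `purity`, `albumin` (g/dL), `b2m` (mg/L), `ldh`
#'   (`"normal"`/`"high"`/`NA`), `ecog`, the five FISH flags
#'   (`"present"`/`"absent"`/`NA`), `response` (IMWG category achieved
#'   between the paired samples, meaningful on the paired row) and
#'   refractoriness flags.
#' @param segments Tibble of copy-number segments: `patient_id`,
#'   `sample_index`, `chrom`, `start`, `end` (0-based half-open), `log2`,
#'   `n_markers`.
#' @param survival Tibble with one row per patient: `pfs_months`,
#'   `pfs_event`, `os1_months`, `os1_event` (from the first sample),
#'   `os2_months`, `os2_event` (from the paired sample).
#'
#' @return An object of class `mm_cohort`.
#' @export
new_cohort <- function(variants, annotations, clinical,
                       segments = NULL, survival = NULL) {
  variants <- tibble::as_tibble(variants)
  annotations <- tibble::as_tibble(annotations)
  clinical <- tibble::as_tibble(clinical)
  segments <- if (is.null(segments)) empty_segments() else tibble::as_tibble(segments)
  survival <- if (is.null(survival)) empty_survival() else tibble::as_tibble(survival)

  require_columns(variants, c("patient_id", "sample_index", variant_key_cols(),
                              "gene", "cdna", "depth", "alt_reads", "vaf"),
                  "variants")
  require_columns(annotations, c(variant_key_cols(), "gene",
                                 pop_af_cols(), predictor_cols(),
                                 "acmg_class", "recurrent_mm_gene",
                                 "druggable_sources"),
                  "annotations")
  require_columns(clinical, c("patient_id", "sample_index", "timepoint_label",
                              "role", "purity", "albumin", "b2m", "ldh",
                              "ecog", fish_cols(), "response",
                              "refractory_pi", "refractory_imid",
                              "refractory_alkylator"),
                  "clinical")
  require_columns(segments, c("patient_id", "sample_index", "chrom",
                              "start", "end", "log2", "n_markers"),
                  "segments")
  require_columns(survival, c("patient_id", "pfs_months", "pfs_event",
                              "os1_months", "os1_event",
                              "os2_months", "os2_event"),
                  "survival")

  bad <- !is.na(variants$depth) & !is.na(variants$alt_reads) &
    variants$alt_reads > variants$depth
  if (any(bad)) {
    stop("alt_reads exceeds depth for ", sum(bad),
         " variant observation(s), first at row ", which(bad)[1])
  }
  if (any(variants$depth < 0, na.rm = TRUE)) stop("negative depth")
  with_depth <- variants$depth > 0 & !is.na(variants$depth)
  dev <- abs(variants$vaf[with_depth] -
               variants$alt_reads[with_depth] / variants$depth[with_depth])
  if (any(dev > 1e-6)) {
    stop("vaf inconsistent with alt_reads/depth (max deviation ",
         format(max(dev)), ")")
  }
  if (any(segments$start >= segments$end)) {
    stop("segment with start >= end")
  }

  structure(list(variants = variants, annotations = annotations,
                 clinical = clinical, segments = segments,
                 survival = survival),
            class = "mm_cohort")
}

empty_segments <- function() {
  tibble::tibble(patient_id = character(), sample_index = integer(),
                 chrom = character(), start = double(), end = double(),
                 log2 = double(), n_markers = integer())
}

empty_survival <- function() {
  tibble::tibble(patient_id = character(),
                 pfs_months = double(), pfs_event = logical(),
                 os1_months = double(), os1_event = logical(),
                 os2_months = double(), os2_event = logical())
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop("table '", what, "' is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(df)
}

#' @export
print.mm_cohort <- function(x, ...) {
  n_pat <- length(unique(x$clinical$patient_id))
  n_samp <- nrow(dplyr::distinct(x$clinical, .data$patient_id, .data$sample_index))
  cat("<mm_cohort> ", n_pat, " patients, ", n_samp, " samples, ",
      nrow(dplyr::distinct(x$variants, dplyr::across(dplyr::all_of(variant_key_cols())))),
      " distinct variants, ", nrow(x$segments), " CNV segments\n", sep = "")
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort An `mm_cohort`.
#' @return Integer count.
#' @export
n_patients <- function(cohort) length(unique(cohort$clinical$patient_id))

# ---------------------------------------------------------------------------
# Readers / writers. TSV dialect: UTF-8, tab-separated, header row, "." for
# missing values.

read_tsv_dot <- function(path, col_types) {
  readr::read_tsv(path, na = c(MISSING_TOKEN, "NA", ""),
                  col_types = col_types, progress = FALSE)
}

write_tsv_dot <- function(df, path) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.logical),
                                        ~ ifelse(is.na(.x), NA_character_,
                                                 ifelse(.x, "TRUE", "FALSE"))))
  readr::write_tsv(df, path, na = MISSING_TOKEN, progress = FALSE)
}

variant_col_types <- function() {
  readr::cols(patient_id = "c", sample_index = "i", chrom = "c", pos = "d",
              ref = "c", alt = "c", gene = "c", cdna = "c",
              depth = "i", alt_reads = "i", vaf = "d")
}

annotation_col_types <- function() {
  spec <- list(chrom = "c", pos = "d", ref = "c", alt = "c", gene = "c",
               acmg_class = "c", recurrent_mm_gene = "l",
               druggable_sources = "c")
  for (col in pop_af_cols()) spec[[col]] <- "d"
  for (col in predictor_cols()) spec[[col]] <- "c"
  do.call(readr::cols, spec)
}

clinical_col_types <- function() {
  spec <- list(patient_id = "c", sample_index = "i", timepoint_label = "c",
               role = "c", purity = "d", albumin = "d", b2m = "d",
               ldh = "c", ecog = "i", response = "c",
               refractory_pi = "l", refractory_imid = "l",
               refractory_alkylator = "l")
  for (col in fish_cols()) spec[[col]] <- "c"
  do.call(readr::cols, spec)
}

segment_col_types <- function() {
  readr::cols(patient_id = "c", sample_index = "i", chrom = "c",
              start = "d", end = "d", log2 = "d", n_markers = "i")
}

survival_col_types <- function() {
  readr::cols(patient_id = "c", pfs_months = "d", pfs_event = "l",
              os1_months = "d", os1_event = "l",
              os2_months = "d", os2_event = "l")
}

#' Load a cohort from tabular files
#'
#' Reads the variant, annotation, segment, clinical and survival tables and
#' joins annotations to variants by the identity key
#' (`chrom`, `pos`, `ref`, `alt`). Variants without a matching annotation are
#' retained with an all-missing annotation and a warning. When the gene
#' symbol differs between the variant and annotation tables the annotation
#' file wins (a message is emitted).
#'
#' @param variant_path Path to the variant TSV, or a VCF 4.2 file
#'   (`.vcf`) with per-sample `AD`/`DP` FORMAT fields.
#' @param annotation_path Path to the annotation TSV.
#' @param segment_path Path to the copy-number segment TSV
#'   (columns `chrom`, `start`, `end`, `log2`, `n_markers` plus patient and
#'   sample keys), or `NULL`.
#' @param clinical_path Path to the clinical TSV.
#' @param survival_path Path to the survival TSV, or `NULL`.
#'
#' @return An `mm_cohort`.
#' @export
load_cohort <- function(variant_path, annotation_path, clinical_path,
                        segment_path = NULL, survival_path = NULL) {
  variants <- if (grepl("\\.vcf(\\.gz)?$", variant_path)) {
    read_variants_vcf(variant_path)
  } else {
    read_tsv_dot(variant_path, variant_col_types())
  }
  annotations <- read_tsv_dot(annotation_path, annotation_col_types())
  clinical <- read_tsv_dot(clinical_path, clinical_col_types())
  segments <- if (is.null(segment_path)) NULL else
    read_tsv_dot(segment_path, segment_col_types())
  survival <- if (is.null(survival_path)) NULL else
    read_tsv_dot(survival_path, survival_col_types())

  unknown_acmg <- setdiff(stats::na.omit(unique(annotations$acmg_class)),
                          ACMG_LEVELS)
  if (length(unknown_acmg) > 0) {
    stop("unknown acmg_class value(s): ", paste(unknown_acmg, collapse = ", "))
  }

  keyed <- dplyr::anti_join(
    dplyr::distinct(variants, dplyr::across(dplyr::all_of(variant_key_cols()))),
    annotations, by = variant_key_cols())
  if (nrow(keyed) > 0) {
    warning(nrow(keyed), " variant key(s) have no annotation; ",
            "retained with all-missing annotation")
  }

  conflicts <- dplyr::inner_join(
    dplyr::distinct(variants, dplyr::across(dplyr::all_of(c(variant_key_cols(), "gene")))),
    dplyr::select(annotations, dplyr::all_of(variant_key_cols()),
                  anno_gene = "gene"),
    by = variant_key_cols())
  conflicts <- dplyr::filter(conflicts, !is.na(.data$anno_gene),
                             .data$gene != .data$anno_gene)
  if (nrow(conflicts) > 0) {
    message(nrow(conflicts), " gene symbol conflict(s); ",
            "annotation file takes precedence")
    variants <- dplyr::left_join(
      variants,
      dplyr::select(annotations, dplyr::all_of(variant_key_cols()),
                    anno_gene = "gene"),
      by = variant_key_cols())
    variants <- dplyr::mutate(
      variants,
      gene = dplyr::coalesce(.data$anno_gene, .data$gene))
    variants$anno_gene <- NULL
  }

  new_cohort(variants, annotations, clinical, segments, survival)
}

#' Load a cohort from a directory of standard-named TSVs
#'
#' Convenience wrapper over [load_cohort()] expecting `variants.tsv`,
#' `annotations.tsv`, `clinical.tsv` and optionally `segments.tsv` and
#' `survival.tsv` in `dir`.
#'
#' @param dir Directory path.
#' @return An `mm_cohort`.
#' @export
load_cohort_dir <- function(dir) {
  p <- function(f) {
    fp <- file.path(dir, f)
    if (file.exists(fp)) fp else NULL
  }
  load_cohort(variant_path = file.path(dir, "variants.tsv"),
              annotation_path = file.path(dir, "annotations.tsv"),
              clinical_path = file.path(dir, "clinical.tsv"),
              segment_path = p("segments.tsv"),
              survival_path = p("survival.tsv"))
}

#' Write a cohort to a directory of TSVs
#'
#' Writes `variants.tsv`, `annotations.tsv`, `clinical.tsv`, `segments.tsv`
#' and `survival.tsv` using the package's TSV dialect ("." for missing).
#' Round-tripping through [load_cohort_dir()] preserves all variant
#' observations exactly.
#'
#' @param cohort An `mm_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_dot(cohort$variants, file.path(dir, "variants.tsv"))
  write_tsv_dot(cohort$annotations, file.path(dir, "annotations.tsv"))
  write_tsv_dot(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_tsv_dot(cohort$segments, file.path(dir, "segments.tsv"))
  write_tsv_dot(cohort$survival, file.path(dir, "survival.tsv"))
  invisible(dir)
}

#' Read variant observations from a VCF
#'
#' Parses a VCF 4.2 file with per-sample `AD` (ref,alt depths) and `DP`
#' FORMAT fields into the observation table. Sample column names are parsed
#' as `<patient_id>_<sample_index>`. Multi-allelic sites are split into one
#' record per alternate allele, with that allele's `AD` entry as
#' `alt_reads`. Gene and cDNA strings are taken from `GENE=` / `CDNA=` INFO
#' keys when present.
#'
#' @param path VCF path.
#' @return Tibble of variant observations.
#' @export
read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  dp <- vcfR::extract.gt(v, element = "DP")
  samples <- colnames(ad)
  m <- regmatches(samples, regexec("^(.*)_([0-9]+)$", samples))
  if (any(lengths(m) != 3)) {
    stop("VCF sample names must look like <patient_id>_<sample_index>")
  }
  pid <- vapply(m, `[`, "", 2)
  sidx <- as.integer(vapply(m, `[`, "", 3))

  info_field <- function(info, key) {
    hit <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))
    vapply(hit, function(h) if (length(h) == 2) h[2] else NA_character_, "")
  }
  gene <- info_field(fix$INFO, "GENE")
  cdna <- info_field(fix$INFO, "CDNA")

  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (s in seq_along(samples)) {
      ad_parts <- suppressWarnings(
        as.integer(strsplit(ad[i, s], ",", fixed = TRUE)[[1]]))
      depth_s <- suppressWarnings(as.integer(dp[i, s]))
      for (a in seq_along(alts)) {
        alt_reads <- if (length(ad_parts) >= a + 1) ad_parts[a + 1] else NA_integer_
        if (is.na(alt_reads) || is.na(depth_s)) next
        rows[[length(rows) + 1]] <- tibble::tibble(
          patient_id = pid[s], sample_index = sidx[s],
          chrom = fix$CHROM[i], pos = as.numeric(fix$POS[i]),
          ref = fix$REF[i], alt = alts[a],
          gene = gene[i], cdna = cdna[i],
          depth = depth_s, alt_reads = alt_reads,
          vaf = if (depth_s > 0) alt_reads / depth_s else 0)
      }
    }
  }
  if (length(rows) == 0) {
    stop("no usable AD/DP genotype entries in ", path)
  }
  dplyr::bind_rows(rows)
}

# ---------------------------------------------------------------------------
# Validation

#' Validate a cohort before analysis
#'
#' Produces a report of structural problems: patients without a valid
#' (first, paired) sample designation, VAF/read-count inconsistencies,
#' overlapping copy-number segments, and purity values outside [0, 1].
#' Issues of severity `"error"` make the cohort unfit for the downstream
#' paired-sample stages, which refuse to run (see [run_pipeline()]).
#'
#' @param cohort An `mm_cohort`.
#' @return A tibble with columns `patient_id`, `severity`
#'   (`"error"`/`"warning"`) and `issue`; zero rows for a clean cohort.
#'   The attribute `ok` is `TRUE` when no `"error"` rows are present.
#' @export
validate_cohort <- function(cohort) {
  issues <- list()
  add <- function(patient_id, severity, issue) {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      patient_id = patient_id, severity = severity, issue = issue)
  }

  roles <- dplyr::summarise(
    dplyr::group_by(cohort$clinical, .data$patient_id),
    n_first = sum(.data$role == "first", na.rm = TRUE),
    n_paired = sum(.data$role == "paired", na.rm = TRUE),
    nondecr = !is.unsorted(.data$sample_index, strictly = TRUE),
    .groups = "drop")
  for (i in seq_len(nrow(roles))) {
    if (roles$n_first[i] != 1 || roles$n_paired[i] != 1) {
      add(roles$patient_id[i], "error",
          sprintf("unpaired: %d 'first' and %d 'paired' samples designated",
                  roles$n_first[i], roles$n_paired[i]))
    }
    if (!roles$nondecr[i]) {
      add(roles$patient_id[i], "error",
          "sample_index not strictly increasing")
    }
  }

  bad_purity <- dplyr::filter(cohort$clinical,
                              !is.na(.data$purity) &
                                (.data$purity < 0 | .data$purity > 1))
  for (pid in bad_purity$patient_id) add(pid, "error", "purity outside [0,1]")

  v <- cohort$variants
  with_depth <- !is.na(v$depth) & v$depth > 0
  dev <- abs(v$vaf - v$alt_reads / v$depth)
  bad_vaf <- with_depth & !is.na(dev) & dev > 1e-6
  for (pid in unique(v$patient_id[bad_vaf])) {
    add(pid, "error", "vaf inconsistent with alt_reads/depth")
  }

  seg <- dplyr::arrange(cohort$segments, .data$patient_id,
                        .data$sample_index, .data$chrom, .data$start)
  if (nrow(seg) > 1) {
    # sorted within group: overlap iff some next start < current end
    ov <- dplyr::summarise(
      dplyr::group_by(seg, .data$patient_id, .data$sample_index, .data$chrom),
      overlap = dplyr::n() > 1 &&
        any(utils::head(.data$end, -1) > utils::tail(.data$start, -1)),
      .groups = "drop")
    for (i in which(ov$overlap)) {
      add(ov$patient_id[i], "error",
          sprintf("overlapping segments on %s (sample %d)",
                  ov$chrom[i], ov$sample_index[i]))
    }
  }

  out <- if (length(issues) == 0) {
    tibble::tibble(patient_id = character(), severity = character(),
                   issue = character())
  } else {
    dplyr::bind_rows(issues)
  }
  attr(out, "ok") <- !any(out$severity == "error")
  out
}

# ---------------------------------------------------------------------------
# Paired-sample views

#' Designated sample pair per patient
#'
#' @param cohort An `mm_cohort`.
#' @return Tibble `patient_id`, `first_index`, `paired_index`.
#' @export
sample_pairs <- function(cohort) {
  cl <- dplyr::filter(cohort$clinical, .data$role %in% c("first", "paired"))
  out <- tidyr::pivot_wider(
    dplyr::select(cl, "patient_id", "role", "sample_index"),
    names_from = "role", values_from = "sample_index")
  dplyr::select(out, "patient_id", first_index = "first",
                paired_index = "paired")
}

#' Wide per-variant table over the designated sample pair
#'
#' One row per (patient, variant key) with the observation at the first and
#' at the paired sample side by side, joined to the variant's annotation.
#' A variant not observed at one of the two timepoints gets `depth = 0`,
#' `alt_reads = 0`, `vaf = 0` there.
#'
#' @param cohort An `mm_cohort`.
#' @return Tibble with `_first` / `_paired` suffixed observation columns and
#'   the annotation columns.
#' @export
paired_observations <- function(cohort) {
  pairs <- sample_pairs(cohort)
  v <- dplyr::inner_join(cohort$variants, pairs, by = "patient_id")
  v <- dplyr::filter(v, .data$sample_index == .data$first_index |
                       .data$sample_index == .data$paired_index)
  v <- dplyr::mutate(v, timepoint = ifelse(.data$sample_index ==
                                             .data$first_index,
                                           "first", "paired"))
  wide <- tidyr::pivot_wider(
    dplyr::select(v, "patient_id", dplyr::all_of(variant_key_cols()),
                  "gene", "cdna", "timepoint", "depth", "alt_reads", "vaf"),
    names_from = "timepoint",
    values_from = c("depth", "alt_reads", "vaf"),
    values_fn = dplyr::first)
  for (col in c("depth_first", "alt_reads_first", "vaf_first",
                "depth_paired", "alt_reads_paired", "vaf_paired")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
    wide[[col]][is.na(wide[[col]])] <- 0
  }
  dplyr::left_join(wide, cohort$annotations,
                   by = variant_key_cols(), suffix = c("", "_anno"))
}

# ---------------------------------------------------------------------------
# Coordinate converters (tested explicitly; trivial but easy to get wrong)

#' Convert 1-based inclusive coordinates to 0-based half-open
#' @param pos 1-based position (start of a 1-bp feature).
#' @return List with `start` and `end` in BED convention.
#' @export
pos_to_bed <- function(pos) list(start = pos - 1, end = pos)

#' Convert a 0-based half-open interval to 1-based inclusive
#' @param start,end BED-convention interval.
#' @return List with 1-based `first` and `last` positions.
#' @export
bed_to_pos <- function(start, end) list(first = start + 1, last = end)
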