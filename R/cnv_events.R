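# Prognostic copy-number event calling from segment log2 ratios: the del1p
# composite (1p12 / 1p22.1 / 1p32.3), gain1q21, del17p, del13q and del14q,
# their evolution between the sample pair, and biallelic / double-hit
# detection against FISH translocation flags.

CNV_EVENT_LABELS <- c("del1p", "gain1q21", "del17p", "del13q", "del14q")
HIGH_RISK_LESIONS <- c("del17p", "gain1q21", "del1p", "t_4_14", "t_14_16")

#' CNV calling configuration
#'
#' @param loss_log2_max Segment log2 ratio at or below which a
#'   loss-direction region fires (default -0.25).
#' @param gain_log2_min Log2 at or above which a gain-direction region fires
#'   (default +0.20).
#' @param amplified_log2_min Log2 at or above which a locus counts as
#'   amplified for the biallelic-event exclusion (default +0.30).
#' @param min_region_overlap Minimum fraction of a region's length that must
#'   be covered by segments for its log2 value to be reported (default
#'   0.5); below it the region is missing.
#' @return List of class `cnv_config`.
#' @export
cnv_config <- function(loss_log2_max = -0.25, gain_log2_min = 0.20,
                       amplified_log2_min = 0.30, min_region_overlap = 0.5) {
  stopifnot(loss_log2_max < 0, gain_log2_min > 0,
            gain_log2_min <= amplified_log2_min,
            min_region_overlap >= 0, min_region_overlap <= 1)
  structure(list(loss_log2_max = loss_log2_max,
                 gain_log2_min = gain_log2_min,
                 amplified_log2_min = amplified_log2_min,
                 min_region_overlap = min_region_overlap),
            class = "cnv_config")
}

#' Default prognostic region definitions
#'
#' GRCh38 cytoband-scale windows for the seven monitored regions, 0-based
#' half-open. The exact windows are editable assumptions; the shipped file
#' `inst/extdata/cnv_regions.tsv` carries the same table. "del17p" is
#' represented by the 17p13.1 window alone.
#'
#' @return Tibble `label`, `chrom`, `start`, `end`, `direction`.
#' @export
default_region_defs <- function() {
  tibble::tribble(
    ~label,          ~chrom,  ~start,      ~end,        ~direction,
    "del1p_1p12",    "chr1",  117600000,   120400000,   "loss",
    "del1p_1p22_1",  "chr1",  92000000,    94300000,    "loss",
    "del1p_1p32_3",  "chr1",  50200000,    55600000,    "loss",
    "gain1q21",      "chr1",  143200000,   147500000,   "gain",
    "del17p",        "chr17", 6500000,     10800000,    "loss",
    "del13q",        "chr13", 46200000,    50600000,    "loss",
    "del14q",        "chr14", 89800000,    106800000,   "loss")
}

#' Read region definitions from a BED-like TSV
#' @param path TSV with columns `label`, `chrom`, `start`, `end`,
#'   `direction`.
#' @return Tibble as [default_region_defs()].
#' @export
read_region_defs <- function(path) {
  defs <- read_tsv_dot(path, readr::cols(label = "c", chrom = "c",
                                         start = "d", end = "d",
                                         direction = "c"))
  stopifnot(all(defs$start < defs$end), !any(duplicated(defs$label)))
  defs
}

#' Length-weighted mean log2 over a region
#'
#' Intersects the sample's segments with the region and returns the
#' length-weighted mean log2 of the intersecting portions together with the
#' fraction of the region covered. The value is `NA` when coverage is below
#' `min_region_overlap`.
#'
#' @param segments Tibble of one sample's segments (`chrom`, `start`, `end`,
#'   `log2`), non-overlapping per chromosome.
#' @param region One-row region definition (`chrom`, `start`, `end`).
#' @param config A [cnv_config()].
#' @return List with `value` and `coverage`.
#' @export
region_log2 <- function(segments, region, config = cnv_config()) {
  seg <- segments[segments$chrom == region$chrom, , drop = FALSE]
  if (nrow(seg) == 0) return(list(value = NA_real_, coverage = 0))
  ov_start <- pmax(seg$start, region$start)
  ov_end <- pmin(seg$end, region$end)
  len <- pmax(0, ov_end - ov_start)
  total <- sum(len)
  region_len <- region$end - region$start
  coverage <- total / region_len
  if (total == 0 || coverage < config$min_region_overlap) {
    return(list(value = NA_real_, coverage = coverage))
  }
  list(value = sum(seg$log2 * len) / total, coverage = coverage)
}

#' Call the prognostic CNV events for one sample
#'
#' A loss-direction region fires when its length-weighted log2 is at or
#' below `loss_log2_max`; a gain-direction region at or above
#' `gain_log2_min`. The composite del1p is the OR of its three sub-regions.
#' Regions whose log2 is missing (insufficient coverage) yield `NA` calls;
#' an OR with a missing sub-region is `TRUE` if any sub-region fired, else
#' `NA`.
#'
#' @param segments One sample's segment tibble.
#' @param region_defs Region definitions (default
#'   [default_region_defs()]).
#' @param config A [cnv_config()].
#' @return Named logical vector (with possible `NA`s) over
#'   `del1p`, `gain1q21`, `del17p`, `del13q`, `del14q`.
#' @export
call_events <- function(segments, region_defs = default_region_defs(),
                        config = cnv_config()) {
  calls <- stats::setNames(rep(NA, nrow(region_defs)), region_defs$label)
  for (i in seq_len(nrow(region_defs))) {
    rl <- region_log2(segments, region_defs[i, ], config)
    if (is.na(rl$value)) next
    calls[i] <- if (region_defs$direction[i] == "loss") {
      rl$value <= config$loss_log2_max
    } else {
      rl$value >= config$gain_log2_min
    }
  }
  sub1p <- calls[c("del1p_1p12", "del1p_1p22_1", "del1p_1p32_3")]
  del1p <- if (any(sub1p, na.rm = TRUE)) TRUE
           else if (any(is.na(sub1p))) NA
           else FALSE
  c(del1p = del1p,
    gain1q21 = unname(calls["gain1q21"]),
    del17p = unname(calls["del17p"]),
    del13q = unname(calls["del13q"]),
    del14q = unname(calls["del14q"]))
}

#' CNV events for every sample of a cohort
#'
#' @param cohort An `mm_cohort`.
#' @param region_defs,config See [call_events()].
#' @return Tibble `patient_id`, `sample_index`, one logical column per
#'   event label.
#' @export
call_events_cohort <- function(cohort, region_defs = default_region_defs(),
                               config = cnv_config()) {
  keys <- dplyr::distinct(cohort$clinical, .data$patient_id,
                          .data$sample_index)
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    seg <- dplyr::filter(cohort$segments,
                         .data$patient_id == keys$patient_id[i],
                         .data$sample_index == keys$sample_index[i])
    ev <- call_events(seg, region_defs, config)
    tibble::tibble(patient_id = keys$patient_id[i],
                   sample_index = keys$sample_index[i],
                   !!!as.list(ev))
  })
  dplyr::bind_rows(rows)
}

#' Classify CNV evolution between the sample pair
#'
#' Per region, the transition between the first and paired event calls:
#' `stable_present`, `stable_absent`, `acquired` or `lost` (or `NA` when
#' either call is missing). A patient's CNV profile is stable iff no region
#' was acquired or lost; missing regions are excluded from that judgment
#' and counted in `n_missing`.
#'
#' @param events_first,events_paired Named logical vectors from
#'   [call_events()] (same labels).
#' @return List with `transitions` (named character vector),
#'   `stable_profile` (logical) and `n_missing`.
#' @export
classify_cnv_evolution <- function(events_first, events_paired) {
  stopifnot(identical(names(events_first), names(events_paired)))
  tr <- mapply(function(a, b) {
    if (is.na(a) || is.na(b)) return(NA_character_)
    if (a && b) "stable_present"
    else if (!a && !b) "stable_absent"
    else if (!a && b) "acquired"
    else "lost"
  }, events_first, events_paired)
  n_missing <- sum(is.na(tr))
  stable <- !any(tr %in% c("acquired", "lost"))
  list(transitions = tr, stable_profile = stable, n_missing = n_missing)
}

locus_log2 <- function(segments, chrom, pos) {
  # pos is 1-based; segment coordinates 0-based half-open
  seg <- segments[segments$chrom == chrom &
                    segments$start < pos & segments$end >= pos, ,
                  drop = FALSE]
  if (nrow(seg) == 0) NA_real_ else seg$log2[1]
}

#' Detect a biallelic event for one variant trajectory
#'
#' A biallelic event is a variant with VAF of at least 0.80 in at least one
#' sample whose locus is not amplified at that sample (locus log2 below
#' `amplified_log2_min`; absent segment coverage counts as not amplified).
#'
#' @param trajectory One-row classified trajectory (wide paired format).
#' @param segments_first,segments_paired Segment tibbles for the two
#'   samples (may be empty).
#' @param config A [cnv_config()].
#' @param vaf_min Biallelic VAF threshold (default 0.80).
#' @return Logical scalar.
#' @export
detect_biallelic <- function(trajectory, segments_first, segments_paired,
                             config = cnv_config(), vaf_min = 0.80) {
  check_one <- function(vaf, segments) {
    if (is.na(vaf) || vaf < vaf_min) return(FALSE)
    l2 <- locus_log2(segments, trajectory$chrom, trajectory$pos)
    is.na(l2) || l2 < config$amplified_log2_min
  }
  check_one(trajectory$vaf_first, segments_first) ||
    check_one(trajectory$vaf_paired, segments_paired)
}

#' Biallelic events across a cohort
#'
#' @param trajectories Classified trajectories (wide paired format).
#' @param cohort The `mm_cohort` providing segments.
#' @param config A [cnv_config()].
#' @param vaf_min Biallelic VAF threshold (default 0.80).
#' @return Tibble of biallelic events: `patient_id`, `gene`, `cdna`,
#'   variant key columns, `vaf_first`, `vaf_paired`.
#' @export
detect_biallelic_cohort <- function(trajectories, cohort,
                                    config = cnv_config(), vaf_min = 0.80) {
  pairs <- sample_pairs(cohort)
  out <- list()
  for (i in seq_len(nrow(trajectories))) {
    tr <- trajectories[i, ]
    pr <- pairs[pairs$patient_id == tr$patient_id, ]
    if (nrow(pr) != 1) next
    seg1 <- dplyr::filter(cohort$segments,
                          .data$patient_id == tr$patient_id,
                          .data$sample_index == pr$first_index)
    seg2 <- dplyr::filter(cohort$segments,
                          .data$patient_id == tr$patient_id,
                          .data$sample_index == pr$paired_index)
    if (detect_biallelic(tr, seg1, seg2, config, vaf_min)) {
      out[[length(out) + 1]] <- dplyr::select(
        tr, "patient_id", "gene", "cdna",
        dplyr::all_of(variant_key_cols()), "vaf_first", "vaf_paired")
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(patient_id = character(), gene = character(),
                          cdna = character(), chrom = character(),
                          pos = double(), ref = character(),
                          alt = character(), vaf_first = double(),
                          vaf_paired = double()))
  }
  dplyr::bind_rows(out)
}

#' Detect double- and triple-hit events for one sample
#'
#' Counts distinct high-risk lesions among del17p, gain1q21, del1p, t(4;14)
#' and t(14;16): two or more is a double hit, three or more a triple hit.
#' Separately flags a TP53 double hit: del17p (from CNV or FISH)
#' co-occurring with a retained TP53 mutation in the sample.
#'
#' @param events Named logical event vector from [call_events()].
#' @param fish Named list/vector with entries `del17p`, `t_4_14`, `t_14_16`
#'   (values `"present"`, `"absent"` or `NA`).
#' @param variant_genes Character vector of mutated genes present in the
#'   sample (retained variants only).
#' @return List `lesions` (character vector of lesions present), `n_lesions`,
#'   `double_hit`, `triple_hit`, `tp53_double_hit`.
#' @export
detect_double_hit <- function(events, fish, variant_genes = character()) {
  present <- function(x) !is.na(x) & x == "present"
  del17p <- isTRUE(events[["del17p"]]) || present(fish[["del17p"]])
  lesions <- c(
    if (del17p) "del17p",
    if (isTRUE(events[["gain1q21"]])) "gain1q21",
    if (isTRUE(events[["del1p"]])) "del1p",
    if (present(fish[["t_4_14"]])) "t_4_14",
    if (present(fish[["t_14_16"]])) "t_14_16")
  n <- length(lesions)
  list(lesions = lesions, n_lesions = n,
       double_hit = n >= 2, triple_hit = n >= 3,
       tp53_double_hit = del17p && "TP53" %in% variant_genes)
}
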