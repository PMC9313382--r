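# Synthetic-cohort simulator. Generates complete longitudinal cohorts with
# the statistical structure the analysis assumes -- paired samples per
# patient, subclone cancer-cell-fraction trajectories producing binomial
# read counts at panel-like depth, annotation verdicts with controllable
# error rates, CNV segments with Gaussian log2 noise, and survival times
# tied to the R-ISS group at the paired sample -- together with ground-truth
# labels keyed identically to the cohort tables.
#
# The observed-VAF model is diploid heterozygous: E[VAF] = purity * CCF / 2.
# Biallelic fixtures are produced by an explicit high-VAF override rather
# than a copy-number-coupled VAF model.

#' Simulation configuration
#'
#' Defaults emulate a 30-patient paired-sample myeloma panel cohort:
#' average depth 267x, plasma-cell purity 0.82-0.98, evolution-pattern mix
#' 8/11/7/4 (branching/acquisition/loss/stable), a handful of shared
#' variants per patient, CCF changes of 0.25-0.55 for expanding/declining
#' subclones, Gaussian segment log2 noise (sd 0.10) around loss/gain shifts
#' of -0.5/+0.4, and exponential survival with medians tied to the R-ISS
#' group at the paired sample (PFS 11 vs 3 months; OS from the paired
#' sample 21 vs 9 months) under ~20% censoring.
#'
#' @param n_patients Number of patients.
#' @param mean_depth Mean sequencing depth; per-observation depths are
#'   negative-binomial with this mean.
#' @param depth_dispersion Negative-binomial size parameter (smaller =
#'   more overdispersed).
#' @param purity_range Uniform range for per-patient plasma-cell purity.
#' @param pattern_mix Named probabilities over
#'   branching/acquisition/loss/stable (must sum to 1).
#' @param shared_mean Mean number of extra shared variants per patient
#'   beyond the guaranteed one.
#' @param shared_class_probs Probabilities of expanded/declined/stable for
#'   shared variants.
#' @param ccf_change_range CCF change magnitude for expanded/declined.
#' @param ccf_present_range CCF range for acquired/lost variants at their
#'   present timepoint.
#' @param ccf_stable_range CCF range for stable shared variants.
#' @param contaminant_mean,artifact_mean,passenger_mean,benign_mean Mean
#'   counts (Poisson) per patient of the four decoy variant kinds removed by
#'   the four filter stages: common SNPs (population AF >= 1%), low-support
#'   artifacts, non-consensus passengers, benign/likely-benign rejects.
#' @param predictor_sensitivity Probability that a predictor calls a truly
#'   pathogenic variant pathogenic.
#' @param predictor_missing_rate Probability of a missing predictor verdict.
#' @param biallelic_rate Per-patient probability of injecting one
#'   high-VAF (>= 0.85) biallelic variant.
#' @param cnv_noise_sd Gaussian sd of segment log2 noise.
#' @param event_log2_loss,event_log2_gain True log2 shifts of loss/gain
#'   events.
#' @param cnv_prob_first Named per-region probabilities of an event at the
#'   first sample (composite del1p assigned to one random sub-region).
#' @param cnv_prob_acquired Named conditional probabilities of acquiring an
#'   absent event by the paired sample.
#' @param cnv_prob_lost Probability a present event is lost.
#' @param pfs_medians,os2_medians Exponential survival medians (months),
#'   named `lower` (R-ISS I/II at the paired sample) and `higher`
#'   (R-ISS III).
#' @param censoring_rate Target fraction of censored observations.
#' @param missing_clinical_rate Probability that albumin/b2m is missing at
#'   a timepoint (produces "not reported" stages).
#' @param seed Integer master seed; all randomness derives from it through
#'   deterministic per-patient substreams.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 30L,
                              mean_depth = 267,
                              depth_dispersion = 12,
                              purity_range = c(0.82, 0.98),
                              pattern_mix = c(branching = 8 / 30,
                                              acquisition = 11 / 30,
                                              loss = 7 / 30,
                                              stable = 4 / 30),
                              shared_mean = 3,
                              shared_class_probs = c(expanded = 35 / 141,
                                                     declined = 41 / 141,
                                                     stable = 65 / 141),
                              ccf_change_range = c(0.25, 0.55),
                              ccf_present_range = c(0.35, 0.90),
                              ccf_stable_range = c(0.25, 0.90),
                              contaminant_mean = 1.5,
                              artifact_mean = 1.0,
                              passenger_mean = 1.5,
                              benign_mean = 1.0,
                              predictor_sensitivity = 0.85,
                              predictor_missing_rate = 0.05,
                              biallelic_rate = 0.2,
                              cnv_noise_sd = 0.10,
                              event_log2_loss = -0.5,
                              event_log2_gain = 0.4,
                              cnv_prob_first = c(del1p = 0.33,
                                                 gain1q21 = 0.63,
                                                 del17p = 0.27,
                                                 del13q = 0.43,
                                                 del14q = 0.20),
                              cnv_prob_acquired = c(del1p = 0.21,
                                                    gain1q21 = 0.38,
                                                    del17p = 0.19,
                                                    del13q = 0.30,
                                                    del14q = 0.125),
                              cnv_prob_lost = 0.07,
                              pfs_medians = c(lower = 11, higher = 3),
                              os2_medians = c(lower = 21, higher = 9),
                              censoring_rate = 0.2,
                              missing_clinical_rate = 0.03,
                              seed = 1L) {
  stopifnot(abs(sum(pattern_mix) - 1) < 1e-8,
            all(names(pattern_mix) == EVOLUTION_PATTERNS),
            length(purity_range) == 2, purity_range[1] <= purity_range[2],
            purity_range[1] >= 0, purity_range[2] <= 1,
            censoring_rate >= 0, censoring_rate < 1)
  cfg <- as.list(environment())
  cfg$n_patients <- as.integer(n_patients)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "simulation_config")
}

# Small synthetic gene panel (GRCh38-scale coordinates) with recurrence and
# druggability flags; positions are representative loci, not exact CDS.
panel_genes <- function() {
  tibble::tribble(
    ~gene,     ~chrom,  ~pos_base,  ~recurrent, ~oncokb, ~target,
    "KRAS",    "chr12", 25245000,   TRUE,       TRUE,    TRUE,
    "BRAF",    "chr7",  140753000,  TRUE,       TRUE,    TRUE,
    "TP53",    "chr17", 7675000,    TRUE,       FALSE,   TRUE,
    "FGFR3",   "chr4",  1801000,    TRUE,       FALSE,   FALSE,
    "EGFR",    "chr7",  55191000,   FALSE,      TRUE,    TRUE,
    "DUSP2",   "chr2",  96143000,   FALSE,      FALSE,   FALSE,
    "PABPC1",  "chr8",  100703000,  TRUE,       FALSE,   FALSE,
    "RYR2",    "chr1",  237042000,  FALSE,      FALSE,   FALSE,
    "ZFHX3",   "chr16", 72787000,   FALSE,      FALSE,   FALSE,
    "ATM",     "chr11", 108365000,  FALSE,      FALSE,   TRUE,
    "BRCA2",   "chr13", 32340000,   FALSE,      FALSE,   FALSE,
    "CYLD",    "chr16", 50776000,   TRUE,       FALSE,   FALSE,
    "DNAH5",   "chr5",  13700000,   FALSE,      FALSE,   FALSE,
    "TET2",    "chr4",  105234000,  FALSE,      FALSE,   FALSE,
    "RET",     "chr10", 43114000,   FALSE,      FALSE,   TRUE,
    "KMT2C",   "chr7",  152134000,  TRUE,       FALSE,   FALSE,
    "ARID1A",  "chr1",  26696000,   FALSE,      TRUE,    FALSE,
    "SF3B1",   "chr2",  197402000,  FALSE,      TRUE,    FALSE,
    "FAT4",    "chr4",  125316000,  FALSE,      FALSE,   FALSE,
    "LRP1B",   "chr2",  140231000,  FALSE,      FALSE,   FALSE,
    "NCOR2",   "chr12", 124324000,  FALSE,      FALSE,   FALSE,
    "SOX9",    "chr17", 72121000,   FALSE,      FALSE,   FALSE,
    "EP300",   "chr22", 41092000,   FALSE,      FALSE,   FALSE,
    "CDKN2A",  "chr9",  21968000,   FALSE,      TRUE,    TRUE,
    "ATR",     "chr3",  142449000,  FALSE,      FALSE,   TRUE)
}

#' Druggable-gene lists matching the synthetic panel
#' @return Named list with `oncokb` and `target` gene vectors.
#' @export
default_druggable_lists <- function() {
  pg <- panel_genes()
  list(oncokb = pg$gene[pg$oncokb], target = pg$gene[pg$target])
}

#' Simulate read counts at one or more loci
#'
#' Depth is drawn from an overdispersed (negative binomial) distribution
#' with the configured mean (zero depths are bumped to one read) and the
#' alternate-read count is binomial in the true VAF.
#'
#' @param true_vaf True variant allele fraction(s) in [0, 1].
#' @param mean_depth,depth_dispersion Negative-binomial mean and size.
#' @return Tibble `depth`, `alt_reads`, `vaf`.
#' @export
simulate_reads <- function(true_vaf, mean_depth = 267,
                           depth_dispersion = 12) {
  if (any(true_vaf < 0 | true_vaf > 1 | is.na(true_vaf))) {
    stop("true_vaf must be within [0,1]")
  }
  n <- length(true_vaf)
  depth <- stats::rnbinom(n, mu = mean_depth, size = depth_dispersion)
  depth[depth == 0] <- 1L
  alt <- stats::rbinom(n, depth, true_vaf)
  tibble::tibble(depth = as.integer(depth), alt_reads = as.integer(alt),
                 vaf = alt / depth)
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])

# Per-patient substream seeds drawn once from the master stream: patient
# i's seed depends only on (master seed, i), so increasing n_patients
# appends patients without reshuffling earlier ones.
patient_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2147483646L, n)
}

# Uniform censoring bound giving the target censored fraction for an
# exponential with rate lam: solve P(C < T) = target for C ~ U(0, cmax).
censoring_bound <- function(lam, target) {
  if (target <= 0) return(Inf)
  # P(censored) = P(C < T) = (1 - exp(-lam*cmax)) / (lam*cmax) for
  # C ~ U(0, cmax), T ~ Exp(lam); decreasing in cmax
  f <- function(cmax) (1 - exp(-lam * cmax)) / (lam * cmax) - target
  stats::uniroot(f, c(1e-9, 1e9))$root
}

#' Simulate one exponential survival group with uniform censoring
#'
#' @param n Number of subjects.
#' @param median_months True median survival; the exponential rate is
#'   log(2) / median.
#' @param censoring Target censored fraction (uniform censoring times).
#' @return Tibble `time`, `event`.
#' @export
simulate_survival_group <- function(n, median_months, censoring = 0.2) {
  lam <- log(2) / median_months
  t_ev <- stats::rexp(n, lam)
  if (censoring > 0) {
    cmax <- censoring_bound(lam, censoring)
    t_cs <- stats::runif(n, 0, cmax)
    tibble::tibble(time = pmin(t_ev, t_cs), event = t_ev <= t_cs)
  } else {
    tibble::tibble(time = t_ev, event = TRUE)
  }
}

#' Simulate two proportional-hazards survival groups
#'
#' Group `"ref"` is exponential at `median_ref`; group `"high"` has its
#' hazard multiplied by `hr`.
#'
#' @param n_per_arm Subjects per group.
#' @param median_ref Reference-group median (months).
#' @param hr True hazard ratio of the second group versus the first.
#' @param censoring Target censored fraction.
#' @return Tibble `time`, `event`, `group` (factor, levels ref/high).
#' @export
simulate_two_groups <- function(n_per_arm, median_ref, hr, censoring = 0.2) {
  ref <- simulate_survival_group(n_per_arm, median_ref, censoring)
  high <- simulate_survival_group(n_per_arm, median_ref / hr, censoring)
  tibble::tibble(time = c(ref$time, high$time),
                 event = c(ref$event, high$event),
                 group = factor(rep(c("ref", "high"), each = n_per_arm),
                                levels = c("ref", "high")))
}

rand_variant_identity <- function(pg_row) {
  pos <- pg_row$pos_base + sample.int(50000, 1)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, 1)
  alt <- sample(setdiff(bases, ref), 1)
  list(chrom = pg_row$chrom, pos = pos, ref = ref, alt = alt,
       gene = pg_row$gene,
       cdna = sprintf("c.%d%s>%s", sample.int(9000, 1), ref, alt))
}

draw_verdicts <- function(pathogenic, sens, miss_rate, max_pathogenic = NA) {
  # six verdicts; for non-pathogenic decoys max_pathogenic bounds the count
  v <- character(6)
  for (j in 1:6) {
    if (stats::runif(1) < miss_rate) { v[j] <- NA_character_; next }
    p <- if (pathogenic) sens else 0.08
    v[j] <- if (stats::runif(1) < p) "pathogenic" else "benign"
  }
  if (!is.na(max_pathogenic)) {
    idx <- which(!is.na(v) & v == "pathogenic")
    if (length(idx) > max_pathogenic) {
      v[idx[-seq_len(max_pathogenic)]] <- "benign"
    }
  }
  stats::setNames(as.list(v), predictor_cols())
}

#' Simulate a complete cohort with ground truth
#'
#' Per patient: draws an evolution pattern, allocates variants to trajectory
#' classes consistent with it (branching gets at least one acquired and one
#' lost variant, etc.), draws true CCFs, converts them to expected VAFs via
#' the purity-scaled diploid-heterozygous model, draws read counts, injects
#' decoy variants for every filter stage (plus one whitelisted KMT2C
#' c.1173C>A benign variant per cohort), generates CNV segments as Gaussian
#' log2 noise around true event shifts, clinical values, and survival times
#' exponential per true R-ISS group at the paired sample. A fixed seed gives
#' identical output.
#'
#' @param config A [simulation_config()].
#' @return List with `cohort` (an `mm_cohort`) and `truth` (list of tibbles
#'   `variants`, `patients`, `cnv`).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  pg <- panel_genes()
  regions <- default_region_defs()
  pat_seeds <- patient_seeds(config$seed, config$n_patients)
  whitelist_patient <- sample.int(config$n_patients, 1)

  variants <- list(); annotations <- list(); segments <- list()
  clinical <- list(); surv <- list()
  truth_var <- list(); truth_pat <- list(); truth_cnv <- list()

  for (i in seq_len(config$n_patients)) {
    set.seed(pat_seeds[i])
    pid <- sprintf("P%03d", i)
    purity <- runif_range(1, config$purity_range)
    pattern <- sample(names(config$pattern_mix), 1,
                      prob = config$pattern_mix)

    n_acq <- if (pattern %in% c("branching", "acquisition"))
      1L + stats::rpois(1, 0.8) else 0L
    n_lost <- if (pattern %in% c("branching", "loss"))
      1L + stats::rpois(1, 0.8) else 0L
    n_shared <- 1L + stats::rpois(1, config$shared_mean)

    cls <- c(rep("acquired", n_acq), rep("lost", n_lost),
             sample(names(config$shared_class_probs), n_shared,
                    replace = TRUE, prob = config$shared_class_probs))

    rows <- list()
    for (k in seq_along(cls)) {
      g <- pg[sample.int(nrow(pg), 1), ]
      id <- rand_variant_identity(g)
      ccf <- switch(cls[k],
        acquired = c(0, runif_range(1, config$ccf_present_range)),
        lost = c(runif_range(1, config$ccf_present_range), 0),
        stable = rep(runif_range(1, config$ccf_stable_range), 2),
        expanded = {
          c1 <- stats::runif(1, 0.15, 0.45)
          c(c1, min(c1 + runif_range(1, config$ccf_change_range), 0.98))
        },
        declined = {
          c2 <- stats::runif(1, 0.15, 0.45)
          c(min(c2 + runif_range(1, config$ccf_change_range), 0.98), c2)
        })
      rows[[k]] <- c(id, list(class = cls[k], ccf1 = ccf[1], ccf2 = ccf[2],
                              kind = "trajectory", pathogenic = TRUE,
                              recurrent = g$recurrent,
                              oncokb = g$oncokb, target = g$target))
    }

    # biallelic injection: override one stable shared variant to VAF 0.85+
    biallelic_idx <- NA_integer_
    stable_idx <- which(vapply(rows, function(r) r$class == "stable", TRUE))
    if (length(stable_idx) > 0 &&
        stats::runif(1) < config$biallelic_rate) {
      biallelic_idx <- stable_idx[1]
    }

    add_decoy <- function(kind, n) {
      out <- list()
      for (k in seq_len(n)) {
        g <- pg[sample.int(nrow(pg), 1), ]
        id <- rand_variant_identity(g)
        ccf <- switch(kind,
          contaminant = c(NA, NA),   # germline-like, VAF ~ 0.5 directly
          artifact = c(NA, NA),      # sub-threshold noise, VAF override
          passenger = rep(runif_range(1, c(0.3, 0.7)), 2),
          benign_reject = rep(runif_range(1, c(0.3, 0.7)), 2))
        out[[k]] <- c(id, list(class = "stable", ccf1 = ccf[1],
                               ccf2 = ccf[2], kind = kind,
                               pathogenic = kind %in% c("benign_reject"),
                               recurrent = FALSE,
                               oncokb = FALSE, target = FALSE))
      }
      out
    }
    rows <- c(rows,
              add_decoy("contaminant", stats::rpois(1, config$contaminant_mean)),
              add_decoy("artifact", stats::rpois(1, config$artifact_mean)),
              add_decoy("passenger", stats::rpois(1, config$passenger_mean)),
              add_decoy("benign_reject", stats::rpois(1, config$benign_mean)))

    if (i == whitelist_patient) {
      g <- pg[pg$gene == "KMT2C", ]
      rows[[length(rows) + 1]] <- list(
        chrom = g$chrom, pos = g$pos_base + 1173, ref = "C", alt = "A",
        gene = "KMT2C", cdna = "c.1173C>A", class = "stable",
        ccf1 = 0.5, ccf2 = 0.5, kind = "whitelisted",
        pathogenic = TRUE, recurrent = TRUE, oncokb = FALSE, target = FALSE)
    }

    # true VAFs
    for (k in seq_along(rows)) {
      r <- rows[[k]]
      tv <- switch(r$kind,
        contaminant = c(0.5, 0.5),
        artifact = stats::runif(2, 0.005, 0.045),
        c(purity * r$ccf1 / 2, purity * r$ccf2 / 2))
      if (!is.na(biallelic_idx) && k == biallelic_idx) {
        tv <- c(max(tv[1], 0.85), max(tv[2], 0.85))
      }
      rows[[k]]$vaf_true <- tv
    }

    # observations at both samples
    for (k in seq_along(rows)) {
      r <- rows[[k]]
      rd <- simulate_reads(r$vaf_true, config$mean_depth,
                           config$depth_dispersion)
      for (s in 1:2) {
        variants[[length(variants) + 1]] <- tibble::tibble(
          patient_id = pid, sample_index = s, chrom = r$chrom, pos = r$pos,
          ref = r$ref, alt = r$alt, gene = r$gene, cdna = r$cdna,
          depth = rd$depth[s], alt_reads = rd$alt_reads[s],
          vaf = rd$vaf[s])
      }

      # annotation
      pop_af <- rep(NA_real_, 3)
      if (r$kind == "contaminant") {
        which_db <- sample.int(3, sample(1:2, 1))
        pop_af[which_db] <- stats::runif(length(which_db), 0.01, 0.5)
      } else if (stats::runif(1) < 0.4) {
        pop_af[sample.int(3, 1)] <- stats::runif(1, 0, 0.005)
      }
      max_path <- if (r$kind == "passenger") 1 else NA
      verd <- draw_verdicts(r$pathogenic || r$kind == "trajectory" ||
                              r$kind == "whitelisted",
                            config$predictor_sensitivity,
                            config$predictor_missing_rate, max_path)
      acmg <- if (r$kind == "benign_reject") {
        sample(c("benign", "likely_benign"), 1)
      } else if (r$kind == "whitelisted") {
        "likely_benign"
      } else {
        sample(c("pathogenic", "likely_pathogenic", "vus"), 1,
               prob = c(0.3, 0.3, 0.4))
      }
      drg <- c(if (isTRUE(r$oncokb)) "oncokb", if (isTRUE(r$target)) "target")
      annotations[[length(annotations) + 1]] <- tibble::tibble(
        chrom = r$chrom, pos = r$pos, ref = r$ref, alt = r$alt,
        gene = r$gene,
        af_g1000 = pop_af[1], af_gnomad = pop_af[2], af_esp = pop_af[3],
        !!!verd,
        acmg_class = acmg,
        recurrent_mm_gene = isTRUE(r$recurrent) &&
          r$kind != "passenger",
        druggable_sources = if (length(drg) > 0)
          paste(drg, collapse = ",") else NA_character_)

      truth_var[[length(truth_var) + 1]] <- tibble::tibble(
        patient_id = pid, chrom = r$chrom, pos = r$pos, ref = r$ref,
        alt = r$alt, gene = r$gene, cdna = r$cdna, kind = r$kind,
        trajectory_class = if (r$kind %in% c("trajectory", "whitelisted"))
          r$class else NA_character_,
        ccf_first = r$ccf1, ccf_paired = r$ccf2,
        vaf_true_first = r$vaf_true[1], vaf_true_paired = r$vaf_true[2],
        biallelic = !is.na(biallelic_idx) && k == biallelic_idx)
    }

    # --- CNV truth and segments -----------------------------------------
    ev_first <- ev_paired <- stats::setNames(logical(5), CNV_EVENT_LABELS)
    del1p_sub <- sample(c("del1p_1p12", "del1p_1p22_1", "del1p_1p32_3"), 1)
    for (lab in CNV_EVENT_LABELS) {
      p1 <- config$cnv_prob_first[[lab]]
      ev_first[lab] <- stats::runif(1) < p1
      ev_paired[lab] <- if (ev_first[lab]) {
        stats::runif(1) >= config$cnv_prob_lost
      } else {
        stats::runif(1) < config$cnv_prob_acquired[[lab]]
      }
    }
    region_shift <- function(lab, sample_events) {
      if (lab %in% c("del1p_1p12", "del1p_1p22_1", "del1p_1p32_3")) {
        if (sample_events[["del1p"]] && lab == del1p_sub)
          config$event_log2_loss else 0
      } else if (lab == "gain1q21") {
        if (sample_events[["gain1q21"]]) config$event_log2_gain else 0
      } else {
        if (sample_events[[lab]]) config$event_log2_loss else 0
      }
    }
    for (s in 1:2) {
      evs <- if (s == 1) ev_first else ev_paired
      seg_rows <- list()
      emit <- function(chrom, start, end, shift = 0) {
        seg_rows[[length(seg_rows) + 1]] <<- tibble::tibble(
          patient_id = pid, sample_index = s, chrom = chrom,
          start = start, end = end,
          log2 = shift + stats::rnorm(1, 0, config$cnv_noise_sd),
          n_markers = as.integer(round((end - start) / 5e5)) + 1L)
      }
      # chromosomes carrying monitored regions: tile window + flanks
      for (chrom in c("chr1", "chr13", "chr14", "chr17")) {
        regs <- regions[regions$chrom == chrom, ]
        regs <- regs[order(regs$start), ]
        cursor <- 0
        for (j in seq_len(nrow(regs))) {
          if (regs$start[j] > cursor) emit(chrom, cursor, regs$start[j])
          emit(chrom, regs$start[j], regs$end[j],
               region_shift(regs$label[j], evs))
          cursor <- regs$end[j]
        }
        emit(chrom, cursor, 250e6)
      }
      # neutral coverage for variant loci on other chromosomes
      pos_by_chrom <- split(
        vapply(rows, function(r) r$pos, 0),
        vapply(rows, function(r) r$chrom, ""))
      for (chrom in setdiff(names(pos_by_chrom),
                            c("chr1", "chr13", "chr14", "chr17"))) {
        p <- pos_by_chrom[[chrom]]
        emit(chrom, max(0, min(p) - 1e6), max(p) + 1e6)
      }
      segments <- c(segments, seg_rows)
    }
    truth_cnv[[length(truth_cnv) + 1]] <- tibble::tibble(
      patient_id = pid, region = CNV_EVENT_LABELS,
      present_first = unname(ev_first), present_paired = unname(ev_paired))

    # --- clinical and survival ------------------------------------------
    fish_missing <- stats::runif(1) < 0.07
    t414 <- stats::runif(1) < 0.17
    t1416 <- stats::runif(1) < 0.03
    t1114 <- stats::runif(1) < 0.07
    igh_other <- stats::runif(1) < 0.27
    flag <- function(x) if (fish_missing) NA_character_ else
      if (x) "present" else "absent"

    clin_row <- function(s, role, label, b2m_meanlog) {
      miss <- stats::runif(2) < config$missing_clinical_rate
      albumin <- if (miss[1]) NA_real_ else
        stats::rlnorm(1, log(3.8), 0.12)
      b2m <- if (miss[2]) NA_real_ else stats::rlnorm(1, b2m_meanlog, 0.45)
      ldh <- if (stats::runif(1) < 0.05) NA_character_ else
        if (stats::runif(1) < (if (s == 1) 0.25 else 0.35)) "high" else "normal"
      del17p_here <- if (s == 1) ev_first[["del17p"]] else ev_paired[["del17p"]]
      tibble::tibble(
        patient_id = pid, sample_index = s, timepoint_label = label,
        role = role, purity = purity, albumin = albumin, b2m = b2m,
        ldh = ldh, ecog = sample(0:2, 1),
        fish_del17p = flag(del17p_here),
        fish_t_4_14 = flag(t414), fish_t_14_16 = flag(t1416),
        fish_t_11_14 = flag(t1114), fish_igh_other = flag(igh_other),
        response = NA_character_,
        refractory_pi = stats::runif(1) < 0.25,
        refractory_imid = stats::runif(1) < 0.25,
        refractory_alkylator = stats::runif(1) < 0.15)
    }
    row1 <- clin_row(1, "first", if (stats::runif(1) < 0.63) "Dx" else "PD",
                     log(4.0))
    row2 <- clin_row(2, "paired", "PD", log(4.5))
    resp_probs <- switch(pattern,
      loss = c(CR = 0.25, VGPR = 0.45, PR = 0.20, SD = 0.10, PD = 0.00),
      acquisition = c(CR = 0.00, VGPR = 0.05, PR = 0.55, SD = 0.25,
                      PD = 0.15),
      c(CR = 0.10, VGPR = 0.25, PR = 0.40, SD = 0.15, PD = 0.10))
    row2$response <- if (stats::runif(1) < 0.05) NA_character_ else
      sample(RESPONSE_LEVELS, 1, prob = resp_probs)
    clinical[[length(clinical) + 1]] <- row1
    clinical[[length(clinical) + 1]] <- row2

    # true R-ISS at the paired sample drives the survival group
    iss2 <- compute_iss(row2$albumin, row2$b2m)
    hr_ca <- ev_paired[["del17p"]] || t414 || t1416
    riss2 <- compute_riss(iss2, hr_ca, row2$ldh)
    group <- if (identical(riss2, "III")) "higher" else "lower"
    pfs <- simulate_survival_group(1, config$pfs_medians[[group]],
                                   config$censoring_rate)
    os2 <- simulate_survival_group(1, config$os2_medians[[group]],
                                   config$censoring_rate)
    gap <- stats::runif(1, 2, 12)   # months between first and paired sample
    surv[[length(surv) + 1]] <- tibble::tibble(
      patient_id = pid,
      pfs_months = pfs$time, pfs_event = pfs$event,
      os1_months = os2$time + gap, os1_event = os2$event,
      os2_months = os2$time, os2_event = os2$event)

    truth_pat[[length(truth_pat) + 1]] <- tibble::tibble(
      patient_id = pid, pattern = pattern, purity = purity,
      riss_paired_true = riss2, survival_group = group,
      n_acquired_true = n_acq, n_lost_true = n_lost,
      n_shared_true = n_shared)
  }

  annotations_tbl <- dplyr::distinct(
    dplyr::bind_rows(annotations),
    dplyr::across(dplyr::all_of(variant_key_cols())), .keep_all = TRUE)
  cohort <- new_cohort(variants = dplyr::bind_rows(variants),
                       annotations = annotations_tbl,
                       clinical = dplyr::bind_rows(clinical),
                       segments = dplyr::bind_rows(segments),
                       survival = dplyr::bind_rows(surv))
  truth <- list(variants = dplyr::bind_rows(truth_var),
                patients = dplyr::bind_rows(truth_pat),
                cnv = dplyr::bind_rows(truth_cnv))
  list(cohort = cohort, truth = truth)
}

#' Write ground-truth tables
#'
#' Writes `truth_variants.tsv`, `truth_patients.tsv` and `truth_cnv.tsv`,
#' keyed identically to the cohort outputs so accuracy can be scored by
#' joining.
#'
#' @param truth The `truth` element of [simulate_cohort()]'s result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
export_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_dot(truth$variants, file.path(dir, "truth_variants.tsv"))
  write_tsv_dot(truth$patients, file.path(dir, "truth_patients.tsv"))
  write_tsv_dot(truth$cnv, file.path(dir, "truth_cnv.tsv"))
  invisible(dir)
}
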