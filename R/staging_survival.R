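# ISS / R-ISS staging at both timepoints, restaging redistribution, and
# survival analysis of the resulting risk groups (Kaplan-Meier, log-rank,
# Cox proportional hazards), plus the evolution-pattern vs treatment
# response association.

STAGE_LEVELS <- c("I", "II", "III", "not_reported")

#' International Staging System (ISS)
#'
#' Stage I: beta-2-microglobulin < 3.5 mg/L and albumin >= 3.5 g/dL.
#' Stage III: beta-2-microglobulin >= 5.5 mg/L. Stage II otherwise.
#' A missing input gives `"not_reported"`.
#'
#' @param albumin_g_dl Serum albumin in g/dL; vectorized.
#' @param b2m_mg_l Serum beta-2-microglobulin in mg/L.
#' @return Character vector over `I`, `II`, `III`, `not_reported`.
#' @export
compute_iss <- function(albumin_g_dl, b2m_mg_l) {
  if (any(albumin_g_dl <= 0, na.rm = TRUE) ||
      any(b2m_mg_l <= 0, na.rm = TRUE)) {
    stop("albumin and beta-2-microglobulin must be positive")
  }
  n <- max(length(albumin_g_dl), length(b2m_mg_l))
  albumin_g_dl <- rep_len(albumin_g_dl, n)
  b2m_mg_l <- rep_len(b2m_mg_l, n)
  out <- rep("not_reported", n)
  known <- !is.na(albumin_g_dl) & !is.na(b2m_mg_l)
  out[known & b2m_mg_l >= 5.5] <- "III"
  out[known & b2m_mg_l < 3.5 & albumin_g_dl >= 3.5] <- "I"
  out[known & out == "not_reported"] <- "II"
  out
}

#' Revised ISS (R-ISS)
#'
#' R-ISS I: ISS I with no high-risk cytogenetic abnormality (del17p,
#' t(4;14) or t(14;16)) and normal LDH. R-ISS III: ISS III with a high-risk
#' abnormality or high LDH. R-ISS II otherwise. Missing cytogenetics or LDH
#' give `"not_reported"` unless the stage is decidable regardless (ISS II is
#' always R-ISS II; ISS I with a known high-risk abnormality or high LDH is
#' R-ISS II; ISS III with either risk factor known present is R-ISS III).
#'
#' @param iss Character vector from [compute_iss()].
#' @param high_risk_ca Logical (del17p or t(4;14) or t(14;16)); may be `NA`.
#' @param ldh `"normal"`, `"high"` or `NA`.
#' @return Character vector over `I`, `II`, `III`, `not_reported`.
#' @export
compute_riss <- function(iss, high_risk_ca, ldh) {
  n <- max(length(iss), length(high_risk_ca), length(ldh))
  iss <- rep_len(iss, n)
  high_risk_ca <- rep_len(high_risk_ca, n)
  ldh <- rep_len(ldh, n)
  ldh_high <- ifelse(is.na(ldh), NA, ldh == "high")
  risk <- dplyr::case_when(
    !is.na(high_risk_ca) & high_risk_ca ~ TRUE,
    !is.na(ldh_high) & ldh_high ~ TRUE,
    is.na(high_risk_ca) | is.na(ldh_high) ~ NA,
    TRUE ~ FALSE)
  dplyr::case_when(
    iss == "not_reported" ~ "not_reported",
    iss == "II" ~ "II",
    iss == "I" & !is.na(risk) & !risk ~ "I",
    iss == "I" & !is.na(risk) & risk ~ "II",
    iss == "III" & !is.na(risk) & risk ~ "III",
    iss == "III" & !is.na(risk) & !risk ~ "II",
    TRUE ~ "not_reported")
}

#' Stage every patient at both timepoints
#'
#' Computes ISS and R-ISS per patient at the first and the paired sample.
#' The high-risk cytogenetics flag combines the FISH del17p/t(4;14)/t(14;16)
#' flags with (optionally) the CNV del17p event call: `TRUE` if any is
#' present, `FALSE` if all are known absent, `NA` otherwise.
#'
#' @param cohort An `mm_cohort`.
#' @param cnv_events Optional tibble from [call_events_cohort()] whose
#'   `del17p` column supplements FISH.
#' @return Tibble `patient_id`, `timepoint` (`"first"`/`"paired"`), `iss`,
#'   `riss`.
#' @export
stage_cohort <- function(cohort, cnv_events = NULL) {
  pairs <- sample_pairs(cohort)
  long <- tidyr::pivot_longer(pairs, cols = c("first_index", "paired_index"),
                              names_to = "timepoint",
                              values_to = "sample_index")
  long$timepoint <- sub("_index$", "", long$timepoint)
  cl <- dplyr::inner_join(long, cohort$clinical,
                          by = c("patient_id", "sample_index"))
  if (!is.null(cnv_events)) {
    cl <- dplyr::left_join(
      cl, dplyr::select(cnv_events, "patient_id", "sample_index",
                        cnv_del17p = "del17p"),
      by = c("patient_id", "sample_index"))
  } else {
    cl$cnv_del17p <- NA
  }
  pres <- function(x) ifelse(is.na(x), NA, x == "present")
  f17 <- pres(cl$fish_del17p)
  f414 <- pres(cl$fish_t_4_14)
  f1416 <- pres(cl$fish_t_14_16)
  any3 <- function(a, b, c) {
    dplyr::case_when(
      (!is.na(a) & a) | (!is.na(b) & b) | (!is.na(c) & c) ~ TRUE,
      is.na(a) | is.na(b) | is.na(c) ~ NA,
      TRUE ~ FALSE)
  }
  del17p_any <- dplyr::case_when(
    (!is.na(f17) & f17) | (!is.na(cl$cnv_del17p) & cl$cnv_del17p) ~ TRUE,
    is.na(f17) & is.na(cl$cnv_del17p) ~ NA,
    TRUE ~ FALSE)
  high_risk <- any3(del17p_any, f414, f1416)
  iss <- compute_iss(cl$albumin, cl$b2m)
  riss <- compute_riss(iss, high_risk, cl$ldh)
  tibble::tibble(patient_id = cl$patient_id, timepoint = cl$timepoint,
                 iss = iss, riss = riss)
}

#' Restaging redistribution matrix
#'
#' Cross-tabulates each patient's stage at the first sample against the
#' stage at the paired sample, over the levels I, II, III, not_reported.
#'
#' @param staging Tibble from [stage_cohort()].
#' @param measure `"riss"` (default) or `"iss"`.
#' @return 4x4 integer matrix (rows = first, columns = paired) with
#'   marginals as attributes `first_counts` and `paired_counts`.
#' @export
restaging_matrix <- function(staging, measure = c("riss", "iss")) {
  measure <- match.arg(measure)
  if (nrow(staging) == 0) {
    m <- matrix(0L, 4, 4,
                dimnames = list(first = STAGE_LEVELS, paired = STAGE_LEVELS))
    attr(m, "first_counts") <- rowSums(m)
    attr(m, "paired_counts") <- colSums(m)
    return(m)
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(staging, "patient_id", "timepoint",
                  stage = dplyr::all_of(measure)),
    names_from = "timepoint", values_from = "stage")
  m <- table(factor(wide$first, levels = STAGE_LEVELS),
             factor(wide$paired, levels = STAGE_LEVELS))
  m <- matrix(as.integer(m), 4, 4,
              dimnames = list(first = STAGE_LEVELS, paired = STAGE_LEVELS))
  attr(m, "first_counts") <- rowSums(m)
  attr(m, "paired_counts") <- colSums(m)
  m
}

#' Kaplan-Meier, log-rank and Cox comparison of survival groups
#'
#' Estimates the per-group Kaplan-Meier curves (Greenwood variance,
#' log-transformed confidence intervals), defines each group's median as the
#' first time the estimate drops to 0.5 or below, computes the log-rank p
#' value, and fits a single-covariate Cox proportional-hazards model with
#' the Efron tie convention. The hazard ratio is reported for the second
#' group level versus the first, with a Wald 95% CI on the log scale.
#'
#' @param times Non-negative follow-up times (months).
#' @param events Logical (or 0/1) event indicators.
#' @param groups Group labels (coerced to factor; the first level is the
#'   reference).
#' @return List with `groups` (tibble: group, n, n_events, median_months),
#'   `km` (tibble of curve points: group, time, n_risk, survival, lower,
#'   upper), `p_logrank`, `hr`, `ci95` (length-2), `p_wald`. `hr` is `NA`
#'   when a group has zero events.
#' @export
survival_compare <- function(times, events, groups) {
  stopifnot(length(times) == length(events),
            length(times) == length(groups), all(times >= 0, na.rm = TRUE))
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need at least two groups")
  events <- as.integer(as.logical(events))

  fit <- survival::survfit(survival::Surv(times, events) ~ groups,
                           conf.type = "log")
  s <- summary(fit)
  km <- if (length(s$time) == 0) {
    tibble::tibble(group = character(), time = double(), n_risk = double(),
                   survival = double(), lower = double(), upper = double())
  } else {
    strata <- if (is.null(s$strata)) {
      rep(levels(groups)[1], length(s$time))
    } else {
      sub("^groups=", "", as.character(s$strata))
    }
    tibble::tibble(group = strata, time = s$time, n_risk = s$n.risk,
                   survival = s$surv, lower = s$lower, upper = s$upper)
  }

  med <- vapply(levels(groups), function(g) {
    pts <- km[km$group == g, ]
    hit <- which(pts$survival <= 0.5)
    if (length(hit) == 0) NA_real_ else pts$time[hit[1]]
  }, 0)
  grp_tab <- tibble::tibble(
    group = levels(groups),
    n = as.integer(table(groups)[levels(groups)]),
    n_events = vapply(levels(groups),
                      function(g) sum(events[groups == g]), 0L),
    median_months = med)

  p_logrank <- if (sum(events) == 0) {
    NA_real_
  } else {
    sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
    stats::pchisq(sd$chisq, df = nlevels(groups) - 1, lower.tail = FALSE)
  }

  if (any(grp_tab$n_events == 0)) {
    hr <- NA_real_; ci <- c(NA_real_, NA_real_); p_wald <- NA_real_
  } else {
    cox <- survival::coxph(survival::Surv(times, events) ~ groups,
                           ties = "efron")
    cf <- summary(cox)$coefficients[1, ]
    hr <- unname(exp(cf["coef"]))
    ci <- unname(exp(cf["coef"] + c(-1, 1) * stats::qnorm(0.975) *
                       cf["se(coef)"]))
    p_wald <- unname(cf["Pr(>|z|)"])
  }
  list(groups = grp_tab, km = km, p_logrank = p_logrank,
       hr = hr, ci95 = ci, p_wald = p_wald)
}

#' Kaplan-Meier median of a single group
#'
#' The first time at which the Kaplan-Meier estimate drops to 0.5 or below;
#' `NA` when the curve never reaches 0.5.
#'
#' @param times Non-negative follow-up times.
#' @param events Logical (or 0/1) event indicators.
#' @return Median time, or `NA`.
#' @export
km_median <- function(times, events) {
  fit <- survival::survfit(
    survival::Surv(times, as.integer(as.logical(events))) ~ 1)
  hit <- which(fit$surv <= 0.5)
  if (length(hit) == 0) NA_real_ else fit$time[hit[1]]
}

#' Two-sided Fisher exact p by hypergeometric enumeration
#'
#' Enumerates all 2x2 tables with the observed margins and sums the
#' hypergeometric probabilities of tables no more probable than the
#' observed one (with the conventional relative tolerance for probability
#' ties).
#'
#' @param tab 2x2 integer matrix.
#' @return p value in (0, 1]; `NA` for an all-zero table. A zero margin
#'   collapses the enumeration to a single table and gives p = 1.
#' @export
fisher_exact_p <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2, 2)), all(tab >= 0))
  if (sum(tab) == 0) return(NA_real_)
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  sum(d[d <= d[support == x] * (1 + 1e-7)])
}

#' Evolution pattern versus treatment response
#'
#' Restricts to patients whose pattern is `loss` or `acquisition` and whose
#' inter-sample response is known, dichotomizes the response at >= VGPR
#' (CR or VGPR versus PR/SD/PD), and tests the association with a two-sided
#' Fisher exact test computed by hypergeometric enumeration.
#'
#' @param patterns Tibble from [classify_patient_pattern()].
#' @param responses Tibble `patient_id`, `response` (IMWG category or `NA`).
#' @return List with `table` (2x2: pattern x response) and `p`.
#' @export
response_association <- function(patterns, responses) {
  df <- dplyr::inner_join(
    dplyr::filter(patterns, .data$pattern %in% c("loss", "acquisition")),
    responses, by = "patient_id")
  df <- dplyr::filter(df, !is.na(.data$response))
  good <- df$response %in% c("CR", "VGPR")
  tab <- matrix(c(sum(df$pattern == "loss" & good),
                  sum(df$pattern == "loss" & !good),
                  sum(df$pattern == "acquisition" & good),
                  sum(df$pattern == "acquisition" & !good)),
                nrow = 2, byrow = TRUE,
                dimnames = list(pattern = c("loss", "acquisition"),
                                response = c(">=VGPR", "<VGPR")))
  list(table = tab, p = fisher_exact_p(tab))
}
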