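# Independent lookup-table oracle for the published ISS / R-ISS rules,
# written as flat rule enumeration (distinct code path from the package).
iss_oracle <- function(albumin, b2m) {
  if (is.na(albumin) || is.na(b2m)) return("not_reported")
  if (b2m >= 5.5) return("III")
  if (b2m < 3.5 && albumin >= 3.5) return("I")
  "II"
}

riss_oracle <- function(iss, ca, ldh) {
  if (iss == "not_reported") return("not_reported")
  if (iss == "II") return("II")
  ldh_high <- if (is.na(ldh)) NA else ldh == "high"
  risk <- if (isTRUE(ca) || isTRUE(ldh_high)) TRUE
          else if (is.na(ca) || is.na(ldh_high)) NA
          else FALSE
  if (is.na(risk)) return("not_reported")
  if (iss == "I") return(if (risk) "II" else "I")
  if (risk) "III" else "II"
}

test_that("ISS and R-ISS agree with the lookup oracle over an exhaustive grid", {
  albs <- seq(2.0, 5.5, by = 0.5)
  b2ms <- 1:8
  cas <- c(TRUE, FALSE, NA)
  ldhs <- c("normal", "high", NA)
  for (a in albs) for (b in b2ms) {
    iss <- compute_iss(a, b)
    expect_identical(iss, iss_oracle(a, b))
    for (ca in cas) for (ldh in ldhs) {
      expect_identical(compute_riss(iss, ca, ldh),
                       riss_oracle(iss, ca, ldh))
    }
  }
  # spot cases at the rule boundaries
  expect_identical(compute_iss(4.0, 3.0), "I")
  expect_identical(compute_iss(3.0, 6.0), "III")
  expect_identical(compute_iss(2.9, 3.0), "II")   # low albumin blocks I
  expect_identical(compute_riss("I", FALSE, "normal"), "I")
  expect_identical(compute_riss("III", TRUE, "normal"), "III")
  expect_identical(compute_riss("II", TRUE, "high"), "II")
  # missing inputs propagate to not_reported unless decidable regardless
  expect_identical(compute_iss(NA, 4.0), "not_reported")
  expect_identical(compute_riss("I", NA, "normal"), "not_reported")
  expect_identical(compute_riss("I", TRUE, NA), "II")
  expect_identical(compute_riss("III", TRUE, NA), "III")
  expect_error(compute_iss(-1, 4), "positive")
})

test_that("the restaging matrix reproduces fixture marginals and totals", {
  first <- c(rep("I", 3), rep("II", 23), rep("III", 3), "not_reported")
  paired <- c(rep("I", 6), rep("II", 13), rep("III", 7),
              rep("not_reported", 4))
  set.seed(42)
  paired <- sample(paired)
  staging <- dplyr::bind_rows(
    tibble::tibble(patient_id = sprintf("P%02d", 1:30), timepoint = "first",
                   iss = "II", riss = first),
    tibble::tibble(patient_id = sprintf("P%02d", 1:30), timepoint = "paired",
                   iss = "II", riss = paired))
  m <- restaging_matrix(staging, "riss")
  expect_equal(sum(m), 30)
  expect_equal(unname(attr(m, "first_counts")), c(3, 23, 3, 1))
  expect_equal(unname(attr(m, "paired_counts")), c(6, 13, 7, 4))
  expect_equal(unname(rowSums(m)), c(3, 23, 3, 1))
  expect_equal(unname(colSums(m)), c(6, 13, 7, 4))

  # all-identical staging gives a diagonal matrix
  st2 <- staging
  st2$riss <- rep(first, 2)
  m2 <- restaging_matrix(st2, "riss")
  expect_equal(sum(diag(m2)), 30)

  m0 <- restaging_matrix(staging[0, ], "riss")
  expect_equal(sum(m0), 0)
})

test_that("KM medians recover the closed-form exponential median", {
  set.seed(501)
  g <- simulate_survival_group(5000, 12, censoring = 0.2)
  h <- simulate_survival_group(5000, 12, censoring = 0.2)
  sc <- survival_compare(c(g$time, h$time), c(g$event, h$event),
                         rep(c("a", "b"), each = 5000))
  # true median ln2/lambda = 12; tolerance band 11.4-12.6
  expect_true(all(sc$groups$median_months >= 11.4 &
                    sc$groups$median_months <= 12.6))
  # identical generating law: HR near 1
  expect_gt(sc$hr, 0.9)
  expect_lt(sc$hr, 1.1)
  expect_true(sc$ci95[1] <= sc$hr && sc$hr <= sc$ci95[2])
})

test_that("all-censored groups give undefined medians and HR", {
  times <- c(5, 6, 7, 8)
  events <- c(FALSE, FALSE, FALSE, FALSE)
  sc <- survival_compare(times, events, c("a", "a", "b", "b"))
  expect_true(all(is.na(sc$groups$median_months)))
  expect_true(is.na(sc$hr))
  expect_true(all(is.na(sc$ci95)))
})

test_that("Cox recovers the true log hazard ratio within 3 standard errors", {
  for (case in list(list(hr = 2, seed = 81), list(hr = 6.5, seed = 82))) {
    set.seed(case$seed)
    d <- simulate_two_groups(2000, 11, case$hr, censoring = 0.2)
    fit <- survival::coxph(survival::Surv(time, event) ~ group, data = d,
                           ties = "efron")
    se <- sqrt(diag(fit$var))[1]
    expect_lt(abs(unname(stats::coef(fit)[1]) - log(case$hr)), 3 * se)
    # package route agrees with the direct fit
    sc <- survival_compare(d$time, d$event, d$group)
    expect_equal(sc$hr, unname(exp(stats::coef(fit)[1])), tolerance = 1e-10)
  }
})

# choose()-based enumeration oracle, independent of dhyper
fisher_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  pr <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  obs <- pr[support == tab[1, 1]]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

test_that("Fisher p equals hypergeometric enumeration for every table with n <= 40", {
  worst <- 0
  for (m in 0:40) for (n in 0:(40 - m)) {
    if (m + n == 0) next
    for (k in 0:(m + n)) {
      support <- max(0, k - n):min(k, m)
      for (x in support) {
        tab <- matrix(c(x, m - x, k - x, n - (k - x)), 2, byrow = TRUE)
        worst <- max(worst, abs(fisher_exact_p(tab) - fisher_oracle(tab)))
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("Fisher p matches stats::fisher.test on random tables", {
  set.seed(321)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 5), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_p(tab), stats::fisher.test(tab)$p.value,
                 tolerance = 1e-12)
  }
  # worked examples
  expect_equal(fisher_exact_p(matrix(c(4, 3, 0, 11), 2, byrow = TRUE)),
               0.0114379085, tolerance = 1e-8)
  expect_equal(fisher_exact_p(matrix(c(0, 7, 0, 11), 2, byrow = TRUE)), 1.0)
  expect_equal(fisher_exact_p(matrix(c(7, 0, 0, 11), 2, byrow = TRUE)),
               1 / choose(18, 7), tolerance = 1e-12)
})

test_that("response association dichotomizes at >=VGPR over loss vs acquisition", {
  patterns <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:20),
    pattern = c(rep("loss", 7), rep("acquisition", 11), "branching",
                "stable"))
  responses <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:20),
    response = c("CR", "VGPR", "VGPR", "VGPR", "PR", "PR", "PR",
                 rep("PR", 6), rep("SD", 5), "CR", "VGPR"))
  ra <- response_association(patterns, responses)
  expect_equal(unname(ra$table[1, ]), c(4, 3))   # loss: 4 >=VGPR, 3 below
  expect_equal(unname(ra$table[2, ]), c(0, 11))
  expect_equal(ra$p, 0.0114379085, tolerance = 1e-8)
  # branching/stable patients and missing responses are excluded
  expect_equal(sum(ra$table), 18)
})
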