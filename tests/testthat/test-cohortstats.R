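SECT <- c("T", "IT", "IN", "N", "SN", "ST")

## Build a measurement-style cohort directly from generator truths (no
## rendering), for fast statistical-layer tests.
truthCohort <- function(n, seed = 100, ...) {
  p <- generativeParams(seed = seed, ...)
  co <- sampleCohort(p, n)
  co$gray_mean <- co$true_avg_gray
  for (s in SECT) {
    co[[paste0("gray_", s)]] <- co[[paste0("true_gray_", s)]]
    co[[paste0("thick_", s)]] <- co[[paste0("true_thick_", s)]]
  }
  co$thick_mean <- co$true_thick_mean
  co
}

test_that("ageGroupSummary reproduces the worked two-subject example", {
  co <- data.frame(age = c(25, 35), gray_mean = c(160, 170))
  for (s in SECT) co[[paste0("gray_", s)]] <- co$gray_mean
  co$thick_mean <- c(100, 110)
  for (s in SECT) co[[paste0("thick_", s)]] <- co$thick_mean
  tab <- ageGroupSummary(co)
  expect_equal(tab$n, c(1, 1, 0, 0, 0, 0, 2))
  expect_equal(tab$gray_mean_mean[tab$age_group == "18-29"], 160)
  expect_equal(tab$gray_mean_mean[tab$age_group == "30-39"], 170)
  expect_equal(tab$gray_mean_mean[tab$age_group == "Total"], 165)
  expect_true(is.na(tab$gray_mean_mean[3]))  # empty bin, no error
})

test_that("ageGroupSummary Total row equals whole-cohort moments", {
  co <- truthCohort(200, seed = 18)
  tab <- ageGroupSummary(co)
  tot <- tab[tab$age_group == "Total", ]
  expect_equal(tot$n, 200)
  expect_equal(tot$gray_mean_mean, mean(co$gray_mean), tolerance = 1e-10)
  expect_equal(tot$gray_mean_sd, sd(co$gray_mean), tolerance = 1e-10)
  expect_equal(tot$thick_N_mean, mean(co$thick_N), tolerance = 1e-10)
  # per-bin n sums to the total
  expect_equal(sum(tab$n[tab$age_group != "Total"]), 200)
  expect_error(ageGroupSummary(co, bins = c(30, 40)), "cover")
})

test_that("compareSectors: Bonferroni property, degeneracy, ordering invariance", {
  co <- truthCohort(60, seed = 41)
  res <- compareSectors(co)
  expect_equal(nrow(res), 15)
  ok <- !res$degenerate
  expect_true(all(res$p_adj[ok] >= res$p[ok]))
  expect_true(all(res$p_adj[ok] <= 1))
  expect_true(all(abs(res$p_adj[ok] - pmin(1, res$p[ok] * 15)) < 1e-12))
  # invariant to subject ordering
  res2 <- compareSectors(co[sample.int(60), ])
  expect_equal(res$mean_diff, res2$mean_diff, tolerance = 1e-12)
  expect_equal(res$p, res2$p, tolerance = 1e-12)

  # all sectors identical per eye -> degenerate, nothing significant
  flat <- co
  for (s in SECT) flat[[paste0("gray_", s)]] <- flat$gray_mean
  resFlat <- compareSectors(flat)
  expect_true(all(resFlat$degenerate))
  expect_true(all(is.na(resFlat$p_adj)))
  expect_false(attr(resFlat, "nasal_all_significant"))
})

test_that("nasal sector is significantly lowest in a generated cohort", {
  co <- truthCohort(397, seed = 52)
  # truth-level sector grays differ by constant offsets; add independent
  # per-sector measurement noise so the paired tests are non-degenerate
  set.seed(53)
  for (s in SECT)
    co[[paste0("gray_", s)]] <- co[[paste0("gray_", s)]] + rnorm(397, 0, 0.5)
  res <- compareSectors(co)
  expect_true(attr(res, "nasal_all_significant"))
  nasal <- res[res$sector1 == "N" | res$sector2 == "N", ]
  expect_true(all(nasal$p_adj < 0.001))
})

test_that("univariableScreen: exact case, oracle identity, constant covariate", {
  co <- truthCohort(100, seed = 61)
  co$gray_mean <- 2 * co$age          # outcome exactly 2*age
  res <- suppressWarnings(univariableScreen(co))  # perfect fit warns
  ageRow <- res[res$covariate == "age", ]
  expect_equal(ageRow$std_coef, 1, tolerance = 1e-10)
  expect_lt(ageRow$p, 1e-100)
  expect_true(ageRow$carry_forward)

  # standardized coefficient equals brute-force Pearson r
  co2 <- truthCohort(150, seed = 62)
  res2 <- univariableScreen(co2)
  for (v in c("age", "al", "rpe_gray", "imageq", "iop"))
    expect_equal(res2$std_coef[res2$covariate == v],
                 cor(co2[[v]], co2$gray_mean), tolerance = 1e-10)

  co2$iop <- 15                        # constant covariate
  res3 <- univariableScreen(co2)
  expect_false(res3$estimable[res3$covariate == "iop"])
  expect_false(res3$carry_forward[res3$covariate == "iop"])
  expect_true(all(res3$estimable[res3$covariate != "iop"]))
})

test_that("null covariates are carried forward at about the nominal rate", {
  hits <- 0
  for (r in 1:100) {
    co <- truthCohort(397, seed = 7000 + r)
    res <- univariableScreen(co)
    if (res$carry_forward[res$covariate == "iop"]) hits <- hits + 1
  }
  expect_lte(hits, 10)  # IOP has no true effect; expect ~5% false positives
})

test_that("multivariableFit: exact noise-free fit and rank-deficiency error", {
  co <- truthCohort(80, seed = 71)
  co$gray_mean <- 150 - 0.05 * co$age
  fit <- suppressWarnings(  # perfect fit warns in summary.lm
    multivariableFit(co, carryForward = "age", forced = character(0)))
  expect_equal(fit$slope[fit$covariate == "age"], -0.05, tolerance = 1e-10)
  expect_equal(attr(fit, "intercept"), 150, tolerance = 1e-8)
  expect_false(fit$included[fit$covariate == "iop"])
  expect_true(is.na(fit$slope[fit$covariate == "iop"]))

  # forced covariate enters even when not carried forward
  fit2 <- suppressWarnings(multivariableFit(co, carryForward = "age",
                                            forced = "al"))
  expect_true(all(fit2$included[fit2$covariate %in% c("age", "al")]))

  co$age2 <- co$age                   # duplicated covariate
  expect_error(multivariableFit(co, carryForward = c("age", "age2"),
                                forced = character(0),
                                candidates = c("age", "age2")),
               "rank deficient.*age2")
})

test_that("single-covariate multivariable fit matches the univariable screen", {
  co <- truthCohort(120, seed = 81)
  uni <- univariableScreen(co)
  fit <- multivariableFit(co, carryForward = "age", forced = character(0))
  expect_equal(fit$std_coef[fit$covariate == "age"],
               uni$std_coef[uni$covariate == "age"], tolerance = 1e-10)
  expect_equal(fit$slope[fit$covariate == "age"],
               uni$slope[uni$covariate == "age"], tolerance = 1e-10)
})

test_that("iccTwoObservers: identity, independence, and variance-ratio oracle", {
  set.seed(91)
  x <- rnorm(50, 100, 5)
  expect_equal(iccTwoObservers(x, x), 1)
  expect_error(iccTwoObservers(x, x[-1]), "equal length")
  expect_error(iccTwoObservers(1:2, 1:2), "fewer than 3")
  expect_error(iccTwoObservers(rep(1, 5), rep(1, 5)), "zero total variance")

  # no shared subject effect -> ICC near 0
  set.seed(92)
  vals <- replicate(40, iccTwoObservers(rnorm(100), rnorm(100)))
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(40))

  # subject SD 5, error SD 2.5 -> ICC = 25 / 31.25 = 0.8
  set.seed(93)
  vals <- replicate(40, {
    subj <- rnorm(100, 0, 5)
    iccTwoObservers(subj + rnorm(100, 0, 2.5), subj + rnorm(100, 0, 2.5))
  })
  expect_lt(abs(mean(vals) - 0.8), 3 * sd(vals) / sqrt(40))
})

test_that("analyzedSubset drops excluded records before any statistic", {
  co <- truthCohort(20, seed = 95)
  co$excluded <- NA_character_
  co$excluded[c(3, 9)] <- c("boundary_misidentification", "motion_artifact")
  kept <- analyzedSubset(co)
  expect_equal(nrow(kept), 18)
  tab <- ageGroupSummary(co)
  expect_equal(tab$n[tab$age_group == "Total"], 18)
})
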