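## Normative statistics layer: age-group summary tables, Bonferroni-
## corrected paired sector comparisons, univariable screening with
## carried-forward multivariable OLS (axial length forced), and the
## two-observer intraclass correlation.

.MEASURE_PARAMS <- c("gray_mean", paste0("gray_", .SECTORS),
                     "thick_mean", paste0("thick_", .SECTORS))

.DEFAULT_AGE_BINS <- c(18, 30, 40, 50, 60, 70, Inf)

#' Drop excluded records
#'
#' Removes rows whose `excluded` column carries a reason (boundary
#' misidentification or motion artifact); cohorts without the column pass
#' through unchanged.
#'
#' @param cohort merged cohort data.frame.
#' @return filtered data.frame.
#' @export
analyzedSubset <- function(cohort) {
  if (!"excluded" %in% names(cohort)) return(cohort)
  cohort[is.na(cohort$excluded) | cohort$excluded == "", , drop = FALSE]
}

#' Age-group normative summary table
#'
#' Mean and sample SD (n-1) of all grayscale and thickness parameters per
#' age group, plus a Total row over the whole cohort. Empty bins are
#' reported with `n = 0` and `NA` moments rather than raising an error.
#'
#' @param cohort merged cohort data.frame (covariates + measurement
#'   columns); excluded records are dropped first.
#' @param bins age bin edges; bin `i` is `[bins[i], bins[i+1])`.
#' @param params measurement columns to summarise.
#' @return data.frame with columns `age_group`, `n`, and `<param>_mean`,
#'   `<param>_sd` for every parameter.
#' @export
ageGroupSummary <- function(cohort, bins = .DEFAULT_AGE_BINS,
                            params = .MEASURE_PARAMS) {
  cohort <- analyzedSubset(cohort)
  if (any(cohort$age < bins[1]) || any(cohort$age >= bins[length(bins)] + 1))
    stop("age bins must cover all ages in the cohort")
  k <- length(bins) - 1
  labels <- vapply(seq_len(k), function(i) {
    if (is.infinite(bins[i + 1])) sprintf(">=%g", bins[i])
    else sprintf("%g-%g", bins[i], bins[i + 1] - 1)
  }, character(1))
  grp <- cut(cohort$age, breaks = bins, right = FALSE,
             include.lowest = TRUE, labels = labels)

  rowFor <- function(sub, label) {
    out <- data.frame(age_group = label, n = nrow(sub),
                      stringsAsFactors = FALSE)
    for (pm in params) {
      out[[paste0(pm, "_mean")]] <- if (nrow(sub) > 0) mean(sub[[pm]]) else NA_real_
      out[[paste0(pm, "_sd")]] <- if (nrow(sub) > 1) sd(sub[[pm]]) else NA_real_
    }
    out
  }
  rows <- lapply(seq_len(k), function(i)
    rowFor(cohort[!is.na(grp) & grp == labels[i], , drop = FALSE], labels[i]))
  rows[[k + 1]] <- rowFor(cohort, "Total")
  do.call(rbind, rows)
}

#' Bonferroni-corrected paired sector comparisons
#'
#' Paired t-tests on the within-eye differences between each of the 15
#' sector pairs of a measurement family, with Bonferroni adjustment over
#' the full family (`p_adj = min(1, 15 * p)`). Pairs with zero within-eye
#' variance are reported as degenerate with `NA` p-values. The attribute
#' `nasal_all_significant` records whether the nasal sector is
#' significantly lower than each of the five other sectors at
#' `p_adj < 0.001`.
#'
#' @param cohort merged cohort data.frame.
#' @param prefix measurement family, `"gray"` or `"thick"`.
#' @param alphaNasal adjusted significance level used for the nasal flag.
#' @return data.frame of the 15 pairwise comparisons.
#' @export
compareSectors <- function(cohort, prefix = "gray", alphaNasal = 0.001) {
  cohort <- analyzedSubset(cohort)
  if (nrow(cohort) < 2) stop("at least 2 subjects are required")
  pairs <- utils::combn(.SECTORS, 2)
  nfam <- ncol(pairs)
  res <- lapply(seq_len(nfam), function(i) {
    s1 <- pairs[1, i]; s2 <- pairs[2, i]
    x <- cohort[[paste0(prefix, "_", s1)]]
    y <- cohort[[paste0(prefix, "_", s2)]]
    d <- x - y
    degen <- sd(d) == 0
    if (degen) {
      tval <- NA_real_; pval <- NA_real_
    } else {
      tt <- t.test(x, y, paired = TRUE)
      tval <- unname(tt$statistic); pval <- tt$p.value
    }
    data.frame(sector1 = s1, sector2 = s2,
               mean1 = mean(x), mean2 = mean(y), mean_diff = mean(d),
               t = tval, df = length(d) - 1, p = pval,
               p_adj = if (degen) NA_real_ else min(1, pval * nfam),
               degenerate = degen, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  nasal <- res[res$sector1 == "N" | res$sector2 == "N", ]
  nasalLower <- ifelse(nasal$sector1 == "N", nasal$mean_diff < 0,
                       nasal$mean_diff > 0)
  attr(res, "nasal_all_significant") <-
    all(!nasal$degenerate & nasalLower & nasal$p_adj < alphaNasal)
  res
}

.DEFAULT_COVARIATES <- c("age", "sex", "se", "bcva", "al", "iop", "vf_md",
                         "thick_mean", "rpe_gray", "imageq")

#' Univariable regression screen
#'
#' One simple linear regression of the outcome on each covariate. The
#' standardized coefficient (slope times SD ratio) equals the Pearson
#' correlation in simple regression and is reported alongside the raw
#' slope and two-sided p-value; covariates with `p < alpha` are marked for
#' carry-forward into the multivariable model. Constant covariates are
#' flagged not estimable without affecting the rest.
#'
#' @param cohort merged cohort data.frame.
#' @param outcome outcome column (default `"gray_mean"`).
#' @param covariates covariate columns to screen.
#' @param alpha carry-forward significance level.
#' @return data.frame with one row per covariate: `slope`, `std_coef`,
#'   `p`, `carry_forward`, `estimable`, `n`.
#' @export
univariableScreen <- function(cohort, outcome = "gray_mean",
                              covariates = .DEFAULT_COVARIATES,
                              alpha = 0.05) {
  cohort <- analyzedSubset(cohort)
  y <- cohort[[outcome]]
  if (sd(y) == 0) stop("outcome has zero variance")
  res <- lapply(covariates, function(v) {
    x <- cohort[[v]]
    if (is.null(x)) stop(sprintf("covariate '%s' not found in cohort", v))
    if (sd(x) == 0)
      return(data.frame(covariate = v, n = length(x), slope = NA_real_,
                        std_coef = NA_real_, p = NA_real_,
                        carry_forward = FALSE, estimable = FALSE,
                        stringsAsFactors = FALSE))
    fit <- lm(y ~ x)
    sm <- summary(fit)$coefficients
    slope <- sm["x", "Estimate"]
    data.frame(covariate = v, n = length(x), slope = slope,
               std_coef = slope * sd(x) / sd(y), p = sm["x", "Pr(>|t|)"],
               carry_forward = sm["x", "Pr(>|t|)"] < alpha, estimable = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Multivariable OLS with forced covariates
#'
#' Ordinary least-squares fit of the outcome on the union of the
#' carried-forward and forced covariate sets (normative analyses commonly
#' force axial length into the model regardless of its univariable screen).
#' Slopes are unstandardized (outcome units per covariate unit);
#' covariates not entered are reported with `included = FALSE` and `NA`
#' estimates. A rank-deficient design raises an error naming the collinear
#' covariates.
#'
#' @param cohort merged cohort data.frame.
#' @param outcome outcome column.
#' @param carryForward covariates selected by [univariableScreen()].
#' @param forced covariates always entered (default `"al"`).
#' @param candidates the full covariate list reported (non-entered rows
#'   appear as not included).
#' @return data.frame with one row per candidate covariate plus attributes
#'   `intercept` and `n`.
#' @export
multivariableFit <- function(cohort, outcome = "gray_mean",
                             carryForward = character(),
                             forced = "al",
                             candidates = .DEFAULT_COVARIATES) {
  cohort <- analyzedSubset(cohort)
  vars <- unique(c(intersect(candidates, carryForward), forced))
  vars <- vars[vars %in% names(cohort)]
  if (!length(vars)) stop("no covariates to enter")
  X <- cbind(`(Intercept)` = 1, as.matrix(cohort[vars]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("design matrix is rank deficient; collinear covariates: %s",
                 paste(dropped, collapse = ", ")))
  }
  fml <- stats::as.formula(paste(outcome, "~", paste(vars, collapse = " + ")))
  fit <- lm(fml, data = cohort)
  sm <- summary(fit)$coefficients
  y <- cohort[[outcome]]
  res <- lapply(unique(c(candidates, vars)), function(v) {
    if (v %in% vars) {
      data.frame(covariate = v, included = TRUE,
                 slope = sm[v, "Estimate"],
                 se = sm[v, "Std. Error"],
                 std_coef = sm[v, "Estimate"] * sd(cohort[[v]]) / sd(y),
                 p = sm[v, "Pr(>|t|)"],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(covariate = v, included = FALSE, slope = NA_real_,
                 se = NA_real_, std_coef = NA_real_, p = NA_real_,
                 stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, res)
  attr(res, "intercept") <- unname(coef(fit)["(Intercept)"])
  attr(res, "n") <- nrow(cohort)
  attr(res, "fit") <- fit
  res
}

#' Two-observer intraclass correlation, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement
#' intraclass correlation of two paired observers, from the two-way ANOVA
#' mean squares. With n subjects and k = 2 observers:
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C} and \eqn{MS_E} are the subject (row),
#' observer (column) and residual mean squares.
#'
#' @param obs1,obs2 equal-length paired measurement vectors (n >= 3).
#' @return the ICC estimate (in \[-1, 1\]).
#' @export
iccTwoObservers <- function(obs1, obs2) {
  n <- length(obs1)
  if (length(obs2) != n) stop("observer vectors must have equal length")
  if (n < 3) stop("ICC is not estimable with fewer than 3 subjects")
  M <- cbind(obs1, obs2)
  if (var(as.vector(M)) == 0)
    stop("ICC is not estimable: zero total variance")
  k <- 2
  grand <- mean(M)
  rowM <- rowMeans(M); colM <- colMeans(M)
  SSR <- k * sum((rowM - grand)^2)
  SSC <- n * sum((colM - grand)^2)
  SST <- sum((M - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}
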