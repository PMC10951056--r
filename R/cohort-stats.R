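#' D'Agostino-Pearson omnibus normality test
#'
#' K^2 = Z1(skewness)^2 + Z2(kurtosis)^2, referred to a chi-square
#' distribution with 2 df. Z1 uses D'Agostino's (1970) Johnson-SU
#' transformation of sample skewness; Z2 uses the Anscombe-Glynn (1983)
#' cube-root transformation of sample kurtosis. Requires n >= 8.
#'
#' @param x numeric vector, n >= 8, non-constant.
#' @return list with `statistic` (K^2) and `p.value`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) stop("D'Agostino-Pearson omnibus test requires n >= 8",
                   call. = FALSE)
  if (stats::sd(x) == 0) stop("constant sample", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  g1 <- mean((x - m)^3) / m2^1.5
  b2 <- mean((x - m)^4) / m2^2

  # skewness component (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis component (Anscombe & Glynn 1983)
  e_b2 <- 3 * (n - 1) / (n + 1)
  var_b2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - e_b2) / sqrt(var_b2)
  sqrt_b1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrt_b1 * (2 / sqrt_b1 + sqrt(1 + 4 / sqrt_b1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p.value = stats::pchisq(k2, df = 2,
                                               lower.tail = FALSE))
}

#' Normality gate for two-group comparisons
#'
#' Parametric (t test) only if both groups pass (p > alpha) the
#' D'Agostino-Pearson omnibus test; groups smaller than 8 default to
#' nonparametric by rule, as do degenerate (constant) samples.
#'
#' @param sample_a,sample_b numeric vectors.
#' @param alpha gate significance level (default 0.05).
#' @return "parametric" or "nonparametric".
#' @export
normality_gate <- function(sample_a, sample_b, alpha = 0.05) {
  passes <- function(x) {
    if (length(x) < 8L || stats::sd(x) == 0) return(FALSE)
    dagostino_pearson(x)$p.value > alpha
  }
  if (passes(sample_a) && passes(sample_b)) "parametric" else "nonparametric"
}

iqr_linear <- function(x) stats::quantile(x, c(0.25, 0.75), type = 7,
                                          names = FALSE)

#' Two-group comparison with normality gating
#'
#' Runs [normality_gate()] and then either an unpaired two-sided t test
#' (equal variances) or a two-sided Mann-Whitney U test. The Mann-Whitney
#' branch uses the exact null distribution when min(n_a, n_b) <= 8 and
#' there are no ties, and the tie-corrected normal approximation (no
#' continuity correction) otherwise. Summaries are mean (sd) in the
#' parametric branch and median (IQR, quartiles by linear interpolation)
#' otherwise.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @param variable label carried into the result.
#' @return one-row data frame: variable, group summaries, test
#'   ("t" or "mann_whitney"), statistic, p.
#' @export
compare_groups <- function(sample_a, sample_b, variable = "x") {
  if (!length(sample_a) || !length(sample_b))
    stop("both groups must be non-empty", call. = FALSE)
  branch <- normality_gate(sample_a, sample_b)
  if (branch == "parametric") {
    ht <- stats::t.test(sample_a, sample_b, var.equal = TRUE)
    summ_a <- sprintf("%.3g (%.3g)", mean(sample_a), stats::sd(sample_a))
    summ_b <- sprintf("%.3g (%.3g)", mean(sample_b), stats::sd(sample_b))
    test <- "t"
  } else {
    ties <- anyDuplicated(c(sample_a, sample_b)) > 0L
    exact <- min(length(sample_a), length(sample_b)) <= 8L && !ties
    ht <- suppressWarnings(
      stats::wilcox.test(sample_a, sample_b, exact = exact,
                         correct = FALSE))
    qa <- iqr_linear(sample_a); qb <- iqr_linear(sample_b)
    summ_a <- sprintf("%.3g (%.3g-%.3g)", stats::median(sample_a), qa[1], qa[2])
    summ_b <- sprintf("%.3g (%.3g-%.3g)", stats::median(sample_b), qb[1], qb[2])
    test <- "mann_whitney"
  }
  data.frame(variable = variable, group_a = summ_a, group_b = summ_b,
             test = test, statistic = unname(ht$statistic),
             p = ht$p.value, stringsAsFactors = FALSE)
}

#' Pearson chi-square test on a 2x2 table
#'
#' chi^2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)), df = 1, with no
#' continuity correction; p from the chi-square survival function. A zero
#' row or column margin leaves the statistic undefined and is an error.
#'
#' @param a,b,c,d non-negative cell counts, rows = groups, columns =
#'   condition yes/no.
#' @return list with `counts` (2x2 matrix), `chi_square`, `df`, `p.value`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != floor(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  n <- a + b + c + d
  if (n < 1) stop("empty table", call. = FALSE)
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0))
    stop("zero margin: chi-square statistic undefined", call. = FALSE)
  x2 <- n * (a * d - b * c)^2 / prod(margins)
  list(counts = matrix(c(a, c, b, d), 2, 2), chi_square = x2, df = 1L,
       p.value = stats::pchisq(x2, df = 1, lower.tail = FALSE))
}

#' Spearman correlation with Fisher-z confidence interval
#'
#' rho on mid-ranks; two-sided p from the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)); 95 percent CI from the Fisher z
#' transform with standard error 1/sqrt(n - 3).
#'
#' @param x,y equal-length numeric vectors, n >= 4, neither constant.
#' @param conf_level confidence level (default 0.95).
#' @return list with `rho`, `p.value`, `conf_int` (length 2), `n`.
#' @export
spearman_with_ci <- function(x, y, conf_level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L || length(y) != n) stop("need n >= 4 paired values",
                                     call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rho undefined for a constant vector", call. = FALSE)
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  ci <- if (n > 3 && abs(rho) < 1) {
    z <- atanh(rho)
    zc <- stats::qnorm(1 - (1 - conf_level) / 2)
    tanh(z + c(-1, 1) * zc / sqrt(n - 3))
  } else c(rho, rho)
  list(rho = rho, p.value = p, conf_int = ci, n = n)
}

#' Percent difference of two summary values
#'
#' 100 * (a - b) / b, rounded to the nearest integer; the convention used
#' when reporting, e.g., that a median of 279 is 50 percent greater than a
#' median of 186.
#'
#' @param a,b numeric scalars, b != 0.
#' @return integer percent difference.
#' @export
percent_difference <- function(a, b) {
  if (b == 0) stop("reference value must be nonzero", call. = FALSE)
  round(100 * (a - b) / b)
}

#' Build the cohort comparison report
#'
#' Assembles the three two-group comparison tables (demographics and
#' baseline labs; six-month outcomes; podometrics and sclerosis indices),
#' the four threshold contingency analyses (low podocyte count, GSI > 1,
#' global sclerosis > 20 percent, FSGS lesions > 50 percent) and the
#' standard correlation panels.
#'
#' @param podometrics data frame of per-patient podometric results (rows
#'   from [compute_podometrics()]).
#' @param sclerosis data frame of per-patient sclerosis results (rows from
#'   [compute_sclerosis()]).
#' @param clinical list of [clinical_record()] objects (both timepoints).
#' @param labels data frame with columns patient_id, label ("responder" /
#'   "non_responder"), as from [classify_cohort()].
#' @return list of data frames: `table1` (baseline), `table2` (six-month),
#'   `table3` (podometrics), `thresholds` (4 contingency rows),
#'   `correlations`.
#' @export
build_report <- function(podometrics, sclerosis, clinical, labels) {
  if (!all(c("patient_id", "label") %in% names(labels)))
    stop("labels needs patient_id and label columns", call. = FALSE)
  pod <- merge(podometrics, labels, by = "patient_id")
  scl <- merge(sclerosis, labels, by = "patient_id")
  if (nrow(pod) != nrow(podometrics) || nrow(scl) != nrow(sclerosis))
    stop("label/patient mismatch between tables", call. = FALSE)
  resp <- function(df) df[df$label == "responder", , drop = FALSE]
  nonresp <- function(df) df[df$label == "non_responder", , drop = FALSE]
  if (!nrow(resp(pod)) || !nrow(nonresp(pod)))
    stop("both responder and non-responder groups are required",
         call. = FALSE)

  clin_df <- do.call(rbind, lapply(clinical, function(r)
    data.frame(patient_id = r$patient_id, timepoint = r$timepoint,
               age_years = r$age_years, sex = r$sex,
               scr_umol_l = r$scr_umol_l,
               proteinuria = tryCatch(proteinuria_g_per_day(r),
                                      error = function(e) NA_real_),
               egfr = tryCatch(egfr_ckd_epi(r$scr_umol_l, r$age_years, r$sex),
                               error = function(e) NA_real_),
               stringsAsFactors = FALSE)))
  clin_df <- merge(clin_df, labels, by = "patient_id")

  cmp_tp <- function(tp, var, name) {
    d <- clin_df[clin_df$timepoint == tp & is.finite(clin_df[[var]]), ]
    compare_groups(d[[var]][d$label == "responder"],
                   d[[var]][d$label == "non_responder"], name)
  }
  base_vars <- rbind(cmp_tp("biopsy", "age_years", "age_years"),
                     cmp_tp("biopsy", "proteinuria", "proteinuria_g24h"),
                     cmp_tp("biopsy", "scr_umol_l", "serum_creatinine"),
                     cmp_tp("biopsy", "egfr", "egfr"))
  # sex enters table 1 as a proportion
  base_sex <- clin_df[clin_df$timepoint == "biopsy", ]
  male_r <- sum(base_sex$sex == "male" & base_sex$label == "responder")
  male_nr <- sum(base_sex$sex == "male" & base_sex$label == "non_responder")
  n_r <- sum(base_sex$label == "responder")
  n_nr <- sum(base_sex$label == "non_responder")
  sex_p <- tryCatch(
    chi_square_2x2(male_nr, n_nr - male_nr, male_r, n_r - male_r)$p.value,
    error = function(e) NA_real_)
  table1 <- rbind(base_vars,
                  data.frame(variable = "sex_male",
                             group_a = sprintf("%d/%d", male_r, n_r),
                             group_b = sprintf("%d/%d", male_nr, n_nr),
                             test = "chi_square", statistic = NA_real_,
                             p = sex_p, stringsAsFactors = FALSE))
  table2 <- rbind(cmp_tp("month6", "proteinuria", "proteinuria_g24h"),
                  cmp_tp("month6", "scr_umol_l", "serum_creatinine"),
                  cmp_tp("month6", "egfr", "egfr"))

  pod_vars <- c("n_profiles", "mean_apparent_caliper", "estimated_true_caliper",
                "podocytes_per_tuft", "glomerular_volume", "podocyte_density",
                "snp_fraction", "nuclear_volume", "cytoplasmic_volume",
                "total_podocyte_volume", "nc_ratio", "vv_pod_glom")
  table3 <- do.call(rbind, lapply(pod_vars, function(v)
    compare_groups(pod[[v]][pod$label == "responder"],
                   pod[[v]][pod$label == "non_responder"], v)))
  table3 <- rbind(table3, do.call(rbind, lapply(
    c("gsi", "pct_global", "pct_fsgs"), function(v)
      compare_groups(scl[[v]][scl$label == "responder"],
                     scl[[v]][scl$label == "non_responder"], v))))

  thresholds <- threshold_contingencies(scl)
  correlations <- correlation_panels(pod, scl)
  list(table1 = table1, table2 = table2, table3 = table3,
       thresholds = thresholds, correlations = correlations)
}

threshold_contingencies <- function(scl) {
  flags <- c("low_podocyte", "gsi_gt_1", "global_gt_20", "fsgs_gt_50")
  do.call(rbind, lapply(flags, function(f) {
    a <- sum(scl[[f]] == 1 & scl$label == "non_responder")
    b <- sum(scl[[f]] == 0 & scl$label == "non_responder")
    c_ <- sum(scl[[f]] == 1 & scl$label == "responder")
    d <- sum(scl[[f]] == 0 & scl$label == "responder")
    res <- tryCatch(chi_square_2x2(a, b, c_, d), error = function(e) NULL)
    data.frame(flag = f, nonresponder_pos = a, nonresponder_neg = b,
               responder_pos = c_, responder_neg = d,
               chi_square = if (is.null(res)) NA_real_ else res$chi_square,
               p = if (is.null(res)) NA_real_ else res$p.value,
               stringsAsFactors = FALSE)
  }))
}

correlation_panels <- function(pod, scl) {
  both <- merge(pod, scl[, c("patient_id", "gsi")], by = "patient_id")
  panels <- list(
    c("glomerular_volume", "podocytes_per_tuft"),
    c("glomerular_volume", "podocyte_density"),
    c("podocytes_per_tuft", "total_podocyte_volume"),
    c("podocyte_density", "total_podocyte_volume"),
    c("gsi", "podocytes_per_tuft"),
    c("gsi", "podocyte_density"))
  do.call(rbind, lapply(panels, function(p) {
    r <- tryCatch(spearman_with_ci(both[[p[1]]], both[[p[2]]]),
                  error = function(e) NULL)
    data.frame(x = p[1], y = p[2],
               rho = if (is.null(r)) NA_real_ else r$rho,
               p = if (is.null(r)) NA_real_ else r$p.value,
               ci_lo = if (is.null(r)) NA_real_ else r$conf_int[1],
               ci_hi = if (is.null(r)) NA_real_ else r$conf_int[2],
               stringsAsFactors = FALSE)
  }))
}
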