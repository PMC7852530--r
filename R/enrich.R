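#' Case-versus-control enrichment statistics
#'
#' For each genomic feature, the case cohort contributes `a` DNVs with the
#' feature out of `n1` total, the control cohort `b` of `n2`. The enrichment
#' ratio is the ratio of proportions `R = (a/n1) / (b/n2)`; the printed
#' "odds ratio" column of the source analysis reproduces from its printed
#' counts under this formula, so it is the primary statistic here, with the
#' cross-product odds ratio available as a secondary output. Significance is
#' Pearson's chi-squared on the 2x2 table (optionally with Yates'
#' correction), Bonferroni-corrected over the 13 tested features. The
#' expected excess of disease-related DNVs is `E = a - a/R`, and under
#' uniform allocation of `k` excess variants among `T` patients the expected
#' number of patients carrying at least one is `T * (1 - (1 - 1/T)^k)`.
#'
#' @name enrich
NULL

#' Enrichment ratio (ratio of proportions)
#'
#' `R = (a/n1) / (b/n2)`. Undefined (`NA`) when `b = 0`; use
#' [enrichment_ratio_cc()] for a continuity-corrected alternative.
#'
#' @param a case DNVs with the feature
#' @param n1 total case DNVs
#' @param b control DNVs with the feature
#' @param n2 total control DNVs
#' @return numeric ratio (vectorized)
#' @export
enrichment_ratio <- function(a, n1, b, n2) {
  stopifnot(all(n1 > 0), all(n2 > 0), all(a >= 0 & a <= n1),
            all(b >= 0 & b <= n2))
  ifelse(b > 0, (a / n1) / (b / n2), NA_real_)
}

#' @rdname enrichment_ratio
#' @export
enrichment_ratio_cc <- function(a, n1, b, n2) {
  ((a + 0.5) / n1) / ((b + 0.5) / n2)
}

#' Cross-product odds ratio
#'
#' `(a / (n1 - a)) / (b / (n2 - b))` — the textbook 2x2 odds ratio, emitted
#' alongside the ratio of proportions for comparison.
#'
#' @inheritParams enrichment_ratio
#' @return numeric odds ratio (vectorized)
#' @export
odds_ratio <- function(a, n1, b, n2) {
  ifelse(b > 0 & a < n1 & b < n2,
         (a / (n1 - a)) / (b / (n2 - b)), NA_real_)
}

#' Pearson chi-squared test on a 2x2 feature table
#'
#' Tests equality of feature proportions between case and control cohorts on
#' the table `[[a, n1 - a], [b, n2 - b]]`, with 1 degree of freedom,
#' optionally with Yates' continuity correction.
#'
#' @inheritParams enrichment_ratio
#' @param yates apply Yates' continuity correction? (default `FALSE`)
#' @return list with `statistic` and `p`
#' @export
chi_squared <- function(a, n1, b, n2, yates = FALSE) {
  tab <- matrix(c(a, n1 - a, b, n2 - b), nrow = 2L, byrow = TRUE)
  if (any(tab < 0)) stop("negative cell count")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) stop("chi-squared undefined: expected cell is zero")
  res <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  list(statistic = unname(res$statistic), p = unname(res$p.value))
}

#' Bonferroni correction
#'
#' @param p p value(s) in `[0, 1]`
#' @param m number of tests (default 13, the number of tested features)
#' @return `min(1, m * p)`
#' @export
bonferroni <- function(p, m = 13) {
  if (m < 1) stop("m must be >= 1")
  stopifnot(all(p >= 0 & p <= 1))
  pmin(1, m * p)
}

#' Expected excess of disease-related DNVs
#'
#' `E = a - a / R`: the number of feature DNVs in the case cohort above the
#' count expected at the control rate.
#'
#' @param a observed case DNVs with the feature
#' @param R enrichment ratio (> 0)
#' @return list with `excess` (exact) and `excess_reported` (nearest
#'   integer)
#' @export
expected_excess <- function(a, R) {
  if (any(is.na(R)) || any(R <= 0)) stop("R must be positive")
  e <- a - a / R
  list(excess = e, excess_reported = round_half_up(e))
}

#' Patient occupancy expectation under uniform allocation
#'
#' If `k` excess DNVs fall uniformly at random among `T` patients, each
#' patient carries at least one with probability `1 - (1 - 1/T)^k`, and
#' `T` times that probability patients are expected to carry one.
#'
#' @param k number of excess DNVs (>= 0)
#' @param n_patients cohort size `T` (>= 1)
#' @return list with `probability`, `probability_reported` (2 decimals),
#'   `expected_patients`, `expected_patients_reported` (nearest integer)
#' @export
occupancy_expectation <- function(k, n_patients) {
  stopifnot(k >= 0, n_patients >= 1)
  p <- 1 - (1 - 1 / n_patients)^k
  list(probability = p,
       probability_reported = round_half_up(p, 2),
       expected_patients = n_patients * p,
       expected_patients_reported = round_half_up(n_patients * p))
}

#' Enrichment table from feature counts
#'
#' Computes one enrichment row per feature from case/control counts: case
#' and control percentages, ratio of proportions (and cross-product odds
#' ratio), chi-squared statistic and p value, Bonferroni-adjusted p,
#' significance at `alpha`, and expected excess. Features with zero control
#' count are emitted with an `NA` ratio sentinel (the continuity-corrected
#' ratio is always available).
#'
#' @param feature character vector of feature labels
#' @inheritParams enrichment_ratio
#' @inheritParams chi_squared
#' @param m number of tests for the Bonferroni correction
#' @param alpha significance level on the adjusted p (default 0.05)
#' @return a `data.frame`, one row per feature
#' @export
enrichment_from_counts <- function(feature, a, b, n1, n2, m = 13,
                                   alpha = 0.05, yates = FALSE) {
  stopifnot(length(feature) == length(a), length(a) == length(b))
  ratio <- enrichment_ratio(a, n1, b, n2)
  chi <- lapply(seq_along(a), function(i)
    tryCatch(chi_squared(a[i], n1, b[i], n2, yates = yates),
             error = function(e) list(statistic = NA_real_, p = NA_real_)))
  p <- vapply(chi, `[[`, numeric(1), "p")
  stat <- vapply(chi, `[[`, numeric(1), "statistic")
  p_adj <- rep(NA_real_, length(p))
  p_adj[!is.na(p)] <- bonferroni(p[!is.na(p)], m)
  excess <- ifelse(is.na(ratio) | ratio <= 0, NA_real_, a - a / ratio)
  data.frame(
    feature = feature,
    case_count = a, case_total = n1, case_pct = 100 * a / n1,
    control_count = b, control_total = n2, control_pct = 100 * b / n2,
    ratio = ratio,
    ratio_cc = enrichment_ratio_cc(a, n1, b, n2),
    odds_ratio = odds_ratio(a, n1, b, n2),
    chisq = stat, p = p, p_adj = p_adj,
    significant = !is.na(p_adj) & p_adj < alpha,
    excess = excess,
    excess_reported = ifelse(is.na(excess), NA_real_,
                             round_half_up(excess)),
    stringsAsFactors = FALSE)
}

#' Enrichment table from annotated cohorts
#'
#' Applies the GC exclusion filter symmetrically to both cohorts, counts the
#' 13 tested features (see [dnv_feature_matrix()]) and computes the
#' enrichment statistics.
#'
#' @param case_annot annotated case cohort (see [annotate_cohort()])
#' @param control_annot annotated control cohort
#' @param m number of tests for the Bonferroni correction (default 13)
#' @param alpha significance level (default 0.05)
#' @param yates use Yates' correction in the chi-squared tests?
#' @param apply_gc drop `gc_excluded` variants first? (default `TRUE`)
#' @return a `data.frame`, one row per feature
#' @export
enrichment_table <- function(case_annot, control_annot, m = 13, alpha = 0.05,
                             yates = FALSE, apply_gc = TRUE) {
  if (!is.data.frame(case_annot) || nrow(case_annot) == 0L)
    stop("empty case cohort")
  if (!is.data.frame(control_annot) || nrow(control_annot) == 0L)
    stop("empty control cohort")
  if (apply_gc) {
    case_annot <- case_annot[!case_annot$gc_excluded, , drop = FALSE]
    control_annot <- control_annot[!control_annot$gc_excluded, , drop = FALSE]
    if (nrow(case_annot) == 0L)
      stop("empty case cohort after GC filtering")
  }
  fm_case <- dnv_feature_matrix(case_annot)
  fm_ctrl <- dnv_feature_matrix(control_annot)
  enrichment_from_counts(colnames(fm_case),
                         a = colSums(fm_case), b = colSums(fm_ctrl),
                         n1 = nrow(case_annot), n2 = nrow(control_annot),
                         m = m, alpha = alpha, yates = yates)
}
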