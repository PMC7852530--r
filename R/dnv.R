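#' De novo variant candidate detection and filtering
#'
#' A de novo variant (DNV) is a Mendelian inconsistency: the child carries an
#' alternate allele observed in neither parental genotype. Candidates are the
#' canonical child-heterozygous / parents-homozygous-reference pattern; other
#' violation patterns (e.g. child homozygous alternate with both parents
#' homozygous reference) are almost always genotyping artefacts at ~30x
#' coverage and are flagged but not emitted as candidates by default.
#' Candidates then pass through three independent filters: a genotype
#' posterior quality threshold (Q20 on all three members), an allele-balance
#' window (30-70% of the child's reads supporting the alternate allele,
#' inclusive), and an optional externally supplied classifier score with a
#' 0.5 threshold.
#'
#' @name dnv_calling
NULL

#' Detect candidate de novo variants in one trio
#'
#' Scans trio genotype records (see [read_trio_vcf()]) for Mendelian
#' violations. A site is a violation when the child carries the alternate
#' allele and neither parent does. Violations where the child is `0/1` and
#' both parents `0/0` get status `"candidate"`; all other violation patterns
#' get status `"flagged"` (excluded downstream unless
#' `emit_flagged = TRUE`). Sites where the child carries the alternate allele
#' but a parental genotype is missing are skipped and counted in the
#' `"tally"` attribute of the result.
#'
#' @param records trio genotype record `data.frame` for one trio
#' @param child_id child sample identifier attached to the calls
#' @param emit_flagged also give non-canonical violation patterns status
#'   `"candidate"`? (default `FALSE`)
#' @return a `data.frame` of DNV calls (columns: variant fields, `child_id`,
#'   `ab` allele balance, genotype qualities, `status`), with an attribute
#'   `tally = c(candidate, flagged, missing)`
#' @export
detect_candidates <- function(records, child_id = NA_character_,
                              emit_flagged = FALSE) {
  gt_c <- normalize_gt(records$gt_child)
  gt_f <- normalize_gt(records$gt_father)
  gt_m <- normalize_gt(records$gt_mother)
  has_alt <- function(gt) !is.na(gt) & gt %in% c("0/1", "1/1")
  child_alt <- has_alt(gt_c)
  missing_par <- child_alt & (is.na(gt_f) | is.na(gt_m))
  violation <- child_alt & !missing_par & gt_f == "0/0" & gt_m == "0/0"
  candidate <- violation & gt_c == "0/1"
  flagged <- violation & !candidate

  keep <- violation
  calls <- records[keep, , drop = FALSE]
  tot <- calls$ad_child_ref + calls$ad_child_alt
  calls$ab <- ifelse(!is.na(tot) & tot > 0, calls$ad_child_alt / tot, NA_real_)
  calls$child_id <- child_id
  calls$status <- ifelse(candidate[keep] | emit_flagged, "candidate",
                         "flagged")
  rownames(calls) <- NULL
  attr(calls, "tally") <- c(candidate = sum(candidate),
                            flagged = sum(flagged),
                            missing = sum(missing_par))
  calls
}

#' Genotype posterior quality filter
#'
#' A call passes when the minimum genotype posterior quality over the three
#' trio members is at least `min_posterior` (phred scale; default Q20,
#' i.e. 99% posterior probability). Missing posteriors fail the filter.
#'
#' @param calls DNV call `data.frame`
#' @param min_posterior phred threshold (default 20)
#' @return `calls` with a logical `pass_quality` column
#' @export
filter_quality <- function(calls, min_posterior = 20) {
  mn <- pmin(calls$gq_child, calls$gq_father, calls$gq_mother)
  calls$pass_quality <- !is.na(mn) & mn >= min_posterior
  calls
}

#' Allele-balance filter
#'
#' The allele balance (AB) of a heterozygous call is the fraction of the
#' child's reads supporting the alternate allele. True germline
#' heterozygotes cluster near 0.5; calls outside `[low, high]` (default
#' 30-70%, bounds inclusive) are predominantly mosaic variants or sequencing
#' errors. Calls with zero total depth fail with reason `"zero_depth"`.
#'
#' @param calls DNV call `data.frame` with an `ab` column
#' @param low,high inclusive AB bounds (defaults 0.30 and 0.70)
#' @return `calls` with logical `pass_ab` and character `ab_reason` columns
#' @export
filter_allele_balance <- function(calls, low = 0.30, high = 0.70) {
  stopifnot(low >= 0, high <= 1, low <= high)
  tot <- calls$ad_child_ref + calls$ad_child_alt
  zero <- is.na(calls$ab) | (!is.na(tot) & tot == 0)
  calls$pass_ab <- !zero & calls$ab >= low & calls$ab <= high
  calls$ab_reason <- ifelse(zero, "zero_depth",
                            ifelse(calls$pass_ab, "pass", "out_of_range"))
  calls
}

#' External DNV score filter
#'
#' Machine-learned de novo classifiers (DNMFilter-style gradient boosting)
#' assign each candidate a score in `[0, 1]` correlated with the probability
#' of being a true DNV. The model itself is external to this package; its
#' scores enter as a table keyed by variant. Calls with a score pass when
#' `score >= threshold` (default 0.5); calls without a supplied score pass by
#' default (the hook is optional).
#'
#' @param calls DNV call `data.frame`
#' @param scores optional `data.frame` with columns chrom, pos, ref, alt,
#'   score
#' @param threshold score threshold (default 0.5)
#' @return `calls` with a logical `pass_score` column (and a `score` column)
#' @export
filter_score <- function(calls, scores = NULL, threshold = 0.5) {
  if (is.null(scores)) {
    calls$score <- NA_real_
    calls$pass_score <- TRUE
    return(calls)
  }
  stopifnot(all(c("chrom", "pos", "ref", "alt", "score") %in% names(scores)))
  if (any(is.na(scores$score)) ||
      any(scores$score < 0 | scores$score > 1))
    stop("DNV scores must lie in [0, 1]")
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  calls$score <- scores$score[match(key(calls), key(scores))]
  calls$pass_score <- is.na(calls$score) | calls$score >= threshold
  calls
}

#' Apply all DNV filters and mark accepted calls
#'
#' Runs the quality, allele-balance and score filters (their order is
#' irrelevant: each sets an independent flag) and marks as accepted the
#' candidate calls passing all three.
#'
#' @inheritParams filter_quality
#' @inheritParams filter_allele_balance
#' @inheritParams filter_score
#' @param ab_low,ab_high allele-balance bounds
#' @param score_threshold external-score threshold
#' @return `calls` with filter flag columns and a logical `accepted` column
#' @export
apply_dnv_filters <- function(calls, min_posterior = 20, ab_low = 0.30,
                              ab_high = 0.70, scores = NULL,
                              score_threshold = 0.5) {
  calls <- filter_quality(calls, min_posterior)
  calls <- filter_allele_balance(calls, ab_low, ab_high)
  calls <- filter_score(calls, scores, score_threshold)
  calls$accepted <- calls$status == "candidate" & calls$pass_quality &
    calls$pass_ab & calls$pass_score
  calls
}

#' Per-patient DNV count summary
#'
#' Counts accepted DNVs per child over a pedigree cohort (children with zero
#' calls included) and reports the mean (exact and rounded to the nearest
#' integer), range and total.
#'
#' @param calls DNV call `data.frame` with `child_id` (accepted calls only,
#'   or any table whose rows should be counted)
#' @param pedigree pedigree `data.frame` for the cohort
#' @return a list with `per_child` (named counts), `total`, `mean`,
#'   `mean_reported`, `min`, `max`
#' @export
per_patient_summary <- function(calls, pedigree) {
  if (!is.data.frame(pedigree) || nrow(pedigree) == 0L)
    stop("empty cohort: pedigree must contain at least one trio")
  children <- pedigree$child_id
  counts <- table(factor(calls$child_id, levels = children))
  counts <- setNames(as.integer(counts), children)
  list(per_child = counts,
       total = sum(counts),
       mean = mean(counts),
       mean_reported = round_half_up(mean(counts)),
       min = min(counts),
       max = max(counts))
}

#' Validation false-discovery rate
#'
#' Given a validation tally (number of calls with a successful orthogonal
#' assay, number confirmed de novo), the FDR is the failing fraction in
#' percent: `100 * (tested - confirmed) / tested`.
#'
#' @param tested number of calls with a successful assay (> 0)
#' @param confirmed number confirmed de novo (`<= tested`)
#' @return a list with `fdr` (exact percent) and `fdr_reported` (nearest
#'   integer percent)
#' @export
validation_fdr <- function(tested, confirmed) {
  if (length(tested) != 1L || is.na(tested) || tested <= 0)
    stop("tested must be a positive count")
  if (confirmed < 0 || confirmed > tested)
    stop("confirmed must lie in [0, tested]")
  fdr <- 100 * (tested - confirmed) / tested
  list(fdr = fdr, fdr_reported = round_half_up(fdr))
}
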