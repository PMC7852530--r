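#' Parent-of-origin phasing and parental-age regression
#'
#' The parental origin of a DNV is determined by read-backed phasing: a
#' sequencing read (or read pair) that carries the de novo allele and also
#' covers a nearby informative inherited SNV links the DNV to the parental
#' haplotype that donated the informative allele. An informative site is one
#' where the child is heterozygous and the parental genotypes admit exactly
#' one assignment of the child's alleles to parents. Origin is assigned only
#' on at least two concordant supporting reads with no opposing read (strict
#' conflict rule). De novo counts rise with the father's age at conception
#' because spermatogonial stem cells keep dividing after puberty; the age
#' effect is estimated by ordinary least squares.
#'
#' @name origin_age
NULL

#' Find informative SNVs near a DNV
#'
#' Scans trio records within `window` bp of the DNV for child-heterozygous
#' sites where the parental genotypes allow unambiguous assignment of each
#' child allele to one parent. For example father `1/1` / mother `0/0`
#' (child's alternate allele is paternal), or father `0/1` / mother `0/0`
#' with child `0/1` (the mother cannot have donated the alternate allele).
#' Sites where both parents are heterozygous, or that are themselves
#' Mendelian violations, are not informative.
#'
#' @param dnv one-row `data.frame` with chrom/pos (and the DNV excluded from
#'   candidates by position)
#' @param records trio genotype records for the same trio
#' @param window search window in bp around the DNV (default 500,
#'   approximately the read-pair span at a 350 bp insert)
#' @return `data.frame` of informative sites with columns chrom, pos, ref,
#'   alt, alt_parent, ref_parent
#' @export
find_informative_snvs <- function(dnv, records, window = 500) {
  stopifnot(nrow(dnv) == 1L)
  info <- informative_sites(records)
  near <- info$chrom == dnv$chrom & abs(info$pos - dnv$pos) <= window &
    info$pos != dnv$pos
  out <- info[near, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## vectorized informativeness over a whole trio record table
informative_sites <- function(records) {
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      alt_parent = character(0), ref_parent = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(records) == 0L) return(empty)
  gt_c <- normalize_gt(records$gt_child)
  gt_f <- normalize_gt(records$gt_father)
  gt_m <- normalize_gt(records$gt_mother)
  has0 <- function(gt) !is.na(gt) & gt %in% c("0/0", "0/1")
  has1 <- function(gt) !is.na(gt) & gt %in% c("0/1", "1/1")
  ## child must be het; consider the two assignments (alt from father + ref
  ## from mother) and the mirror; informative iff exactly one is consistent
  het <- !is.na(gt_c) & gt_c == "0/1"
  opt_pat <- het & has1(gt_f) & has0(gt_m)  # alt paternal, ref maternal
  opt_mat <- het & has1(gt_m) & has0(gt_f)  # alt maternal, ref paternal
  keep <- xor(opt_pat, opt_mat)
  if (!any(keep)) return(empty)
  data.frame(chrom = records$chrom[keep], pos = records$pos[keep],
             ref = records$ref[keep], alt = records$alt[keep],
             alt_parent = ifelse(opt_pat[keep], "father", "mother"),
             ref_parent = ifelse(opt_pat[keep], "mother", "father"),
             stringsAsFactors = FALSE)
}

#' Assign the parental origin of one DNV
#'
#' Each read that carries the DNV alternate allele and covers one or more
#' informative sites casts one vote: the parent that donated the observed
#' informative allele(s). Reads whose informative sites disagree internally
#' are discarded. Origin is the parent with at least `min_reads` votes
#' (default 2) provided the other parent has zero votes; any opposing vote
#' voids the assignment.
#'
#' @param dnv one-row DNV `data.frame` with chrom, pos, alt, child_id
#' @param informative informative-site table from [find_informative_snvs()]
#' @param evidence long-form read evidence (see [read_read_evidence()])
#' @param min_reads minimum concordant supporting reads (default 2)
#' @return a one-row `data.frame` with origin ("paternal", "maternal" or
#'   "unassigned"), per-parent read counts and number of sites used
#' @export
assign_origin <- function(dnv, informative, evidence, min_reads = 2) {
  stopifnot(nrow(dnv) == 1L)
  res <- data.frame(chrom = dnv$chrom, pos = dnv$pos,
                    child_id = dnv$child_id,
                    origin = "unassigned", paternal_reads = 0L,
                    maternal_reads = 0L, sites_used = 0L,
                    stringsAsFactors = FALSE)
  ev <- evidence[evidence$sample_id == dnv$child_id, , drop = FALSE]
  if (nrow(ev) == 0L || nrow(informative) == 0L) return(res)
  carriers <- unique(ev$read_id[ev$pos == dnv$pos & ev$allele == dnv$alt])
  if (length(carriers) == 0L) return(res)
  sub <- ev[ev$read_id %in% carriers & ev$pos != dnv$pos, , drop = FALSE]
  idx <- match(sub$pos, informative$pos)
  sub <- sub[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  parent <- ifelse(sub$allele == informative$alt[idx],
                   informative$alt_parent[idx],
                   ifelse(sub$allele == informative$ref[idx],
                          informative$ref_parent[idx], NA_character_))
  ok <- !is.na(parent)
  votes <- c(father = 0L, mother = 0L)
  sites <- unique(sub$pos[ok])
  for (p in split(parent[ok], sub$read_id[ok])) {
    ## a read with internally conflicting informative sites casts no vote
    if (length(unique(p)) != 1L) next
    votes[p[1L]] <- votes[p[1L]] + 1L
  }
  res$paternal_reads <- votes[["father"]]
  res$maternal_reads <- votes[["mother"]]
  res$sites_used <- length(sites)
  if (votes[["father"]] >= min_reads && votes[["mother"]] == 0L)
    res$origin <- "paternal"
  else if (votes[["mother"]] >= min_reads && votes[["father"]] == 0L)
    res$origin <- "maternal"
  res
}

#' Phase a cohort of DNVs
#'
#' Runs [find_informative_snvs()] and [assign_origin()] for every accepted
#' DNV of every trio.
#'
#' @param calls accepted DNV calls with `child_id`
#' @param records_by_child named list of trio record tables, keyed by child
#' @param evidence long-form read evidence for all children
#' @param window informative-site search window (default 500 bp)
#' @param min_reads minimum concordant reads (default 2)
#' @return a `data.frame`, one row per DNV, with origin and read counts
#' @export
phase_cohort <- function(calls, records_by_child, evidence, window = 500,
                         min_reads = 2) {
  ev_by_child <- split(evidence, evidence$sample_id)
  no_ev <- evidence[0L, , drop = FALSE]
  ## informativeness is a per-record property: compute it once per child
  info_by_child <- lapply(records_by_child, informative_sites)
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    dnv <- calls[i, , drop = FALSE]
    info <- info_by_child[[dnv$child_id]]
    if (is.null(info)) info <- informative_sites(empty_df(trio_record_proto))
    near <- info$chrom == dnv$chrom & abs(info$pos - dnv$pos) <= window &
      info$pos != dnv$pos
    ev <- ev_by_child[[dnv$child_id]]
    if (is.null(ev)) ev <- no_ev
    assign_origin(dnv, info[near, , drop = FALSE], ev, min_reads)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(chrom = character(0), pos = integer(0),
                      child_id = character(0), origin = character(0),
                      paternal_reads = integer(0),
                      maternal_reads = integer(0), sites_used = integer(0))
  res
}

#' Summarize parental origin over a phased cohort
#'
#' @param phased result of [phase_cohort()]
#' @return list with `paternal`, `maternal`, `unassigned` counts and the
#'   paternal:maternal `ratio` (`Inf` when no maternal DNV is assigned)
#' @export
origin_summary <- function(phased) {
  pat <- sum(phased$origin == "paternal")
  mat <- sum(phased$origin == "maternal")
  list(paternal = pat, maternal = mat,
       unassigned = sum(phased$origin == "unassigned"),
       ratio = if (mat == 0L) Inf else pat / mat)
}

#' Regress DNV counts on parental age at conception
#'
#' Ordinary least squares of per-child DNV counts on the father's age
#' (marginal fit: slope in DNVs per year, Pearson correlation `r` and its
#' t-test p value), and, when mother ages are supplied, on both parents'
#' ages (the conditional father slope given the mother's age).
#'
#' @param counts integer vector of per-child DNV counts
#' @param father_age,mother_age parental ages at conception (years);
#'   `mother_age` optional
#' @return list with `slope`, `intercept`, `r`, `p`,
#'   `conditional_slope`, `conditional_p` (the latter two `NA` without
#'   mother ages)
#' @export
age_regression <- function(counts, father_age, mother_age = NULL) {
  stopifnot(length(counts) == length(father_age))
  if (length(counts) < 3L)
    stop("at least 3 children with ages are required")
  if (stats::var(father_age) == 0)
    stop("degenerate design: father age is constant")
  fit <- stats::lm(counts ~ father_age)
  sm <- summary(fit)
  res <- list(slope = unname(stats::coef(fit)[2L]),
              intercept = unname(stats::coef(fit)[1L]),
              r = stats::cor(counts, father_age),
              p = sm$coefficients[2L, 4L],
              conditional_slope = NA_real_, conditional_p = NA_real_)
  if (!is.null(mother_age)) {
    stopifnot(length(mother_age) == length(counts))
    if (stats::var(mother_age) == 0)
      stop("degenerate design: mother age is constant")
    fit2 <- stats::lm(counts ~ father_age + mother_age)
    sm2 <- summary(fit2)
    res$conditional_slope <- unname(stats::coef(fit2)["father_age"])
    res$conditional_p <- sm2$coefficients["father_age", 4L]
  }
  res
}
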