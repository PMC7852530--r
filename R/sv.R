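#' De novo structural-variant consensus pipeline
#'
#' Germline SV callers do not call de novo events directly, so de novo SVs
#' are derived from per-sample germline calls by a four-stage filter tuned
#' for specificity: (1) consensus — keep child calls longer than 10 bp
#' detected by both callers (assembly-based and breakpoint-based callers
#' complement each other) at 50% reciprocal overlap; (2) parental
#' subtraction — drop candidates matching any same-type parental record at
#' the same overlap threshold, using both confident calls and low-confidence
#' candidate records; (3) annotation exclusion — drop candidates mostly
#' covered by blacklisted, low-mappability, segmental-duplication or repeat
#' tracks; (4) coverage similarity — drop candidates whose binned read-depth
#' profile over the interval plus flanks looks the same in the child and a
#' parent (a true de novo deletion drops the child's interior depth
#' relative to both parents). Every candidate keeps an audit trail naming
#' the first stage that removed it.
#'
#' @name sv_consensus
NULL

#' Reciprocal overlap of two intervals
#'
#' Returns `(overlap/len(x), overlap/len(y))`. Two intervals "match" at
#' threshold `theta` when both fractions are at least `theta` (inclusive).
#'
#' @param x,y one-row `data.frame`s (or named lists) with chrom, start, end
#'   (1-based closed)
#' @return numeric vector of two fractions
#' @export
reciprocal_overlap <- function(x, y) {
  lx <- x$end - x$start + 1
  ly <- y$end - y$start + 1
  if (lx <= 0 || ly <= 0) stop("zero-length interval")
  if (x$chrom != y$chrom) stop("intervals on different chromosomes")
  ov <- max(0, min(x$end, y$end) - max(x$start, y$start) + 1)
  c(ov / lx, ov / ly)
}

## vectorized RO for matched index pairs of two call tables
ro_pairs <- function(a, b, ia, ib) {
  ov <- pmax(0, pmin(a$end[ia], b$end[ib]) -
                pmax(a$start[ia], b$start[ib]) + 1)
  cbind(ov / (a$end[ia] - a$start[ia] + 1),
        ov / (b$end[ib] - b$start[ib] + 1))
}

#' Dual-caller consensus of SV calls
#'
#' Pairs same-type calls from two callers for the same child that exceed
#' `min_length` bp and match at reciprocal overlap `theta` (default 0.5,
#' inclusive). Pairing is greedy on the best reciprocal overlap (the
#' minimum of the two fractions), ties broken by smaller start coordinate;
#' each call is used at most once. The consensus interval is the caller-A
#' interval (breakpoint-precise callers make the better coordinate source).
#'
#' @param calls_a,calls_b SV call tables from the two callers
#' @param theta reciprocal-overlap threshold (default 0.5)
#' @param min_length minimum SV length, exclusive (default 10 bp)
#' @return list with `consensus` (caller-A rows plus `ro_a`, `ro_b`,
#'   `b_start`, `b_end`), `unmatched_a` and `unmatched_b`
#' @export
intersect_callers <- function(calls_a, calls_b, theta = 0.5,
                              min_length = 10) {
  a <- calls_a[calls_a$length > min_length, , drop = FALSE]
  b <- calls_b[calls_b$length > min_length, , drop = FALSE]
  empty_cons <- cbind(a[0, , drop = FALSE],
                      data.frame(ro_a = numeric(0), ro_b = numeric(0),
                                 b_start = integer(0), b_end = integer(0)))
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(list(consensus = empty_cons, unmatched_a = a, unmatched_b = b))
  gra <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start, a$end))
  grb <- GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start, b$end))
  hits <- GenomicRanges::findOverlaps(gra, grb)
  ia <- S4Vectors::queryHits(hits)
  ib <- S4Vectors::subjectHits(hits)
  same_type <- a$svtype[ia] == b$svtype[ib]
  ia <- ia[same_type]; ib <- ib[same_type]
  if (length(ia)) {
    ro <- ro_pairs(a, b, ia, ib)
    ok <- ro[, 1L] >= theta & ro[, 2L] >= theta
    ia <- ia[ok]; ib <- ib[ok]; ro <- ro[ok, , drop = FALSE]
  } else ro <- matrix(numeric(0), ncol = 2L)
  if (length(ia) == 0L)
    return(list(consensus = empty_cons, unmatched_a = a, unmatched_b = b))
  score <- pmin(ro[, 1L], ro[, 2L])
  ord <- order(-score, a$start[ia], b$start[ib])
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  pick <- integer(0)
  for (k in ord) {
    if (used_a[ia[k]] || used_b[ib[k]]) next
    used_a[ia[k]] <- TRUE; used_b[ib[k]] <- TRUE
    pick <- c(pick, k)
  }
  cons <- a[ia[pick], , drop = FALSE]
  cons$ro_a <- ro[pick, 1L]
  cons$ro_b <- ro[pick, 2L]
  cons$b_start <- b$start[ib[pick]]
  cons$b_end <- b$end[ib[pick]]
  rownames(cons) <- NULL
  list(consensus = cons,
       unmatched_a = a[!used_a, , drop = FALSE],
       unmatched_b = b[!used_b, , drop = FALSE])
}

#' Subtract parentally observed SVs
#'
#' A child candidate is flagged as inherited (fails) when any same-type
#' parental record — confident call or low-confidence candidate — matches
#' it at reciprocal overlap `theta`.
#'
#' @param candidates consensus candidate table
#' @param parental combined parental SV records (both callers, both
#'   parents, called and candidate status)
#' @param theta reciprocal-overlap threshold (default 0.5)
#' @return `candidates` with a logical `pass_parental` column
#' @export
subtract_parental <- function(candidates, parental, theta = 0.5) {
  if (nrow(candidates) == 0L) {
    candidates$pass_parental <- logical(0)
    return(candidates)
  }
  if (is.null(parental) || nrow(parental) == 0L) {
    candidates$pass_parental <- TRUE
    return(candidates)
  }
  grc <- GenomicRanges::GRanges(candidates$chrom,
                                IRanges::IRanges(candidates$start,
                                                 candidates$end))
  grp <- GenomicRanges::GRanges(parental$chrom,
                                IRanges::IRanges(parental$start,
                                                 parental$end))
  hits <- GenomicRanges::findOverlaps(grc, grp)
  ic <- S4Vectors::queryHits(hits); ip <- S4Vectors::subjectHits(hits)
  keep <- candidates$svtype[ic] == parental$svtype[ip]
  ic <- ic[keep]; ip <- ip[keep]
  matched <- logical(nrow(candidates))
  if (length(ic)) {
    ro <- ro_pairs(candidates, parental, ic, ip)
    hit <- ro[, 1L] >= theta & ro[, 2L] >= theta
    matched[unique(ic[hit])] <- TRUE
  }
  candidates$pass_parental <- !matched
  candidates
}

#' Exclude candidates in problematic annotation tracks
#'
#' A candidate fails when the fraction of its interval covered by any
#' single exclusion track (blacklist, low mappability, segmental
#' duplication, repeats) exceeds `phi` (default 0.5; with `phi = 0` any
#' overlap excludes).
#'
#' @param candidates candidate table
#' @param exclusion named list of `GRanges` exclusion tracks (or an
#'   [annotation_tracks()] object, whose `exclusion` field is used)
#' @param phi covered-fraction threshold, exclusive (default 0.5)
#' @return `candidates` with logical `pass_annotation` and numeric
#'   `exclusion_frac` columns
#' @export
annotation_exclusion <- function(candidates, exclusion, phi = 0.5) {
  if (is(exclusion, "AnnotationTrackSet")) exclusion <- exclusion$exclusion
  if (nrow(candidates) == 0L) {
    candidates$pass_annotation <- logical(0)
    candidates$exclusion_frac <- numeric(0)
    return(candidates)
  }
  grc <- GenomicRanges::GRanges(candidates$chrom,
                                IRanges::IRanges(candidates$start,
                                                 candidates$end))
  frac <- rep(0, nrow(candidates))
  for (track in exclusion) {
    if (length(track) == 0L) next
    red <- GenomicRanges::reduce(track)
    ov <- GenomicRanges::intersect(grc, red)
    if (length(ov) == 0L) next
    hits <- GenomicRanges::findOverlaps(grc, ov)
    cov <- tapply(GenomicRanges::width(ov)[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits), sum)
    idx <- as.integer(names(cov))
    frac[idx] <- pmax(frac[idx],
                      as.numeric(cov) / GenomicRanges::width(grc)[idx])
  }
  candidates$exclusion_frac <- frac
  candidates$pass_annotation <- frac <= phi
  candidates
}

## extract one sample's binned depth over [start - flank, end + flank]
profile_bins <- function(coverage, sample, chrom, start, end, flank) {
  sel <- coverage$sample == sample & coverage$chrom == chrom &
    coverage$bin_start >= start - flank & coverage$bin_start <= end + flank
  d <- coverage[sel, , drop = FALSE]
  d <- d[order(d$bin_start), , drop = FALSE]
  d
}

#' Coverage-similarity filter for de novo SV candidates
#'
#' Compares the binned read-depth profile of the child over the candidate
#' interval plus flanks with each parent's profile on the same bin grid
#' (Pearson correlation). A candidate fails (is removed) when the child's
#' profile is similar (correlation `>= rho`) to either parent — a true de
#' novo copy-number event changes the child's interior depth relative to
#' both parents, breaking the similarity. Constant profiles make the
#' correlation undefined; such candidates are kept with a warning.
#'
#' @param candidates candidate table with `sample` (the child)
#' @param coverage binned coverage table (see [read_coverage_tsv()])
#' @param father_id,mother_id parental sample identifiers
#' @param rho similarity threshold (default 0.9)
#' @param flank flank length in bp added on each side (default 1000)
#' @return `candidates` with `cor_father`, `cor_mother` and logical
#'   `pass_coverage` columns
#' @export
coverage_similarity_filter <- function(candidates, coverage, father_id,
                                       mother_id, rho = 0.9, flank = 1000) {
  n <- nrow(candidates)
  candidates$cor_father <- rep(NA_real_, n)
  candidates$cor_mother <- rep(NA_real_, n)
  candidates$pass_coverage <- rep(TRUE, n)
  if (n == 0L || is.null(coverage)) return(candidates)
  for (i in seq_len(n)) {
    ch <- profile_bins(coverage, candidates$sample[i], candidates$chrom[i],
                       candidates$start[i], candidates$end[i], flank)
    fa <- profile_bins(coverage, father_id, candidates$chrom[i],
                       candidates$start[i], candidates$end[i], flank)
    mo <- profile_bins(coverage, mother_id, candidates$chrom[i],
                       candidates$start[i], candidates$end[i], flank)
    if (nrow(ch) < 3L) next
    if (!identical(ch$bin_start, fa$bin_start) ||
        !identical(ch$bin_start, mo$bin_start))
      stop("coverage profiles are not on a common bin grid")
    sims <- vapply(list(fa, mo), function(par) {
      if (stats::sd(ch$depth) == 0 || stats::sd(par$depth) == 0)
        return(NA_real_)
      stats::cor(ch$depth, par$depth)
    }, numeric(1))
    candidates$cor_father[i] <- sims[1L]
    candidates$cor_mother[i] <- sims[2L]
    if (all(is.na(sims))) {
      warning("constant coverage profile: candidate kept (similarity ",
              "undefined) at ", candidates$chrom[i], ":",
              candidates$start[i])
      next
    }
    candidates$pass_coverage[i] <- !any(!is.na(sims) & sims >= rho)
  }
  candidates
}

#' Run the de novo SV pipeline
#'
#' Applies the four stages in order — dual-caller consensus, parental
#' subtraction, annotation exclusion, coverage similarity — and returns the
#' final de novo SVs together with an audit table covering every child call
#' from both callers, naming the first failing stage of each removed
#' candidate.
#'
#' @param child_a,child_b child call tables from the two callers
#' @param parental combined parental records (see [subtract_parental()])
#' @param exclusion exclusion tracks (see [annotation_exclusion()]); may be
#'   `NULL` to skip the stage
#' @param coverage binned coverage table; `NULL` skips the stage
#' @param father_id,mother_id parental sample identifiers for the coverage
#'   stage
#' @param theta reciprocal-overlap threshold (default 0.5)
#' @param phi exclusion-coverage threshold (default 0.5)
#' @param rho coverage-similarity threshold (default 0.9)
#' @param flank coverage flank in bp (default 1000)
#' @param min_length minimum SV length (default 10 bp, exclusive)
#' @return list with `final` (passing candidates with their filter trail)
#'   and `audit` (chrom, start, end, svtype, caller, stage_failed)
#' @export
run_sv_pipeline <- function(child_a, child_b, parental = NULL,
                            exclusion = NULL, coverage = NULL,
                            father_id = NULL, mother_id = NULL,
                            theta = 0.5, phi = 0.5, rho = 0.9,
                            flank = 1000, min_length = 10) {
  ic <- intersect_callers(child_a, child_b, theta, min_length)
  cands <- ic$consensus
  audit_cols <- c("chrom", "start", "end", "svtype", "caller")
  audit <- rbind(
    if (nrow(ic$unmatched_a)) cbind(ic$unmatched_a[, audit_cols],
                                    stage_failed = "consensus"),
    if (nrow(ic$unmatched_b)) cbind(ic$unmatched_b[, audit_cols],
                                    stage_failed = "consensus"))

  cands <- subtract_parental(cands, parental, theta)
  if (!is.null(exclusion)) {
    cands <- annotation_exclusion(cands, exclusion, phi)
  } else {
    cands$pass_annotation <- TRUE
    cands$exclusion_frac <- NA_real_
  }
  ## only candidates surviving earlier stages are judged by later ones
  eligible_cov <- cands$pass_parental & cands$pass_annotation
  if (!is.null(coverage) && any(eligible_cov)) {
    scored <- coverage_similarity_filter(
      cands[eligible_cov, , drop = FALSE], coverage, father_id, mother_id,
      rho, flank)
    cands$pass_coverage <- NA
    cands$cor_father <- NA_real_
    cands$cor_mother <- NA_real_
    cands[eligible_cov, c("pass_coverage", "cor_father", "cor_mother")] <-
      scored[, c("pass_coverage", "cor_father", "cor_mother")]
  } else {
    cands$pass_coverage <- TRUE
    cands$cor_father <- NA_real_
    cands$cor_mother <- NA_real_
  }
  stage <- rep("pass", nrow(cands))
  stage[!cands$pass_parental] <- "parental"
  stage[cands$pass_parental & !cands$pass_annotation] <- "annotation"
  stage[cands$pass_parental & cands$pass_annotation &
          !is.na(cands$pass_coverage) & !cands$pass_coverage] <- "coverage"
  cands$stage_failed <- stage
  audit <- rbind(audit,
                 cbind(cands[, audit_cols], stage_failed = stage))
  rownames(audit) <- NULL
  list(final = cands[stage == "pass", , drop = FALSE], audit = audit)
}

#' Describe the exonic effect of a structural variant
#'
#' For an SV overlapping exons of a gene model, returns a human-readable
#' effect string such as `"deletion of exons 3-7"` (using the exon ranks of
#' the most-affected gene), or `NA` when no exon is touched.
#'
#' @param sv one-row SV `data.frame` (chrom, start, end, svtype)
#' @param gene_model `GRanges` gene model with `label`, `gene` and
#'   `exon_rank` columns
#' @return a character scalar or `NA`
#' @export
sv_exon_annotation <- function(sv, gene_model) {
  stopifnot(nrow(sv) == 1L)
  exons <- gene_model[gene_model$label == "exon"]
  if (length(exons) == 0L) return(NA_character_)
  gr <- GenomicRanges::GRanges(sv$chrom, IRanges::IRanges(sv$start, sv$end))
  hit <- exons[IRanges::overlapsAny(exons, gr)]
  if (length(hit) == 0L) return(NA_character_)
  per_gene <- split(hit$exon_rank, hit$gene)
  gene <- names(per_gene)[which.max(lengths(per_gene))]
  ranks <- sort(unique(per_gene[[gene]]))
  noun <- c(DEL = "deletion", DUP = "duplication", INS = "insertion",
            INV = "inversion")[sv$svtype]
  if (is.na(noun)) noun <- "alteration"
  if (length(ranks) == 1L)
    sprintf("%s of exon %d (%s)", noun, ranks, gene)
  else
    sprintf("%s of exons %d-%d (%s)", noun, min(ranks), max(ranks), gene)
}
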