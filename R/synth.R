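#' Synthetic trio cohorts with ground truth
#'
#' Deterministic generators for every input the pipeline consumes:
#' annotation tracks with a reference sequence, trio cohorts with planted
#' DNVs (paternal-age-dependent counts, configurable per-feature enrichment
#' multipliers, read-level phasing evidence), a large control DNV set, and
#' dual-caller SV call sets with planted true de novo, inherited and
#' artefact events plus per-sample coverage profiles. Every planted event is
#' recorded in a ground-truth ledger together with its expected pipeline
#' fate, so tests can audit each stage against what was planted.
#'
#' Defaults emulate the cohort the package was designed around: 71 trios at
#' ~59 DNVs per child (Poisson around a mean linear in the father's age at
#' conception, slope 1.56 DNVs/year), an 80% paternal origin fraction
#' (~4:1), a 97,942-variant control set, and two discordant SV callers.
#'
#' @name synth
NULL

#' Configuration for the synthetic cohort generator
#'
#' All rates must be non-negative and all multipliers positive; a fixed
#' `seed` makes every generator output fully deterministic.
#'
#' @param seed integer random seed fixing the entire output
#' @param n_trios number of trios (default 71)
#' @param chrom_lengths named integer vector of chromosome lengths
#' @param n_genes genes placed across the genome
#' @param exons_per_gene inclusive range of exon counts per gene
#' @param exon_width,intron_width,utr5_width,utr3_width gene geometry (bp)
#' @param gene_gap_min minimum intergenic gap (bp)
#' @param promoter_halfwidth promoter chromatin state extends this many bp
#'   on each side of the TSS
#' @param enhancer_n,enhancer_width enhancer chromatin-state intervals
#' @param dhs_promoter_prob probability a promoter contains a DHS
#' @param dhs_width,dhs_background_n DHS geometry and background count
#' @param tfbs_rich_prob probability a DHS promoter gets a TFBS-rich focal
#'   cluster (>= 10 stacked sites)
#' @param tfbs_rich_range cluster size range for TFBS-rich promoters
#' @param tfbs_poor_max maximum scattered TFBS in other promoters
#' @param tfbs_width TFBS width (bp)
#' @param gc_tile_fraction fraction of 100 bp tiles made GC-rich
#' @param gc_promoter_tiles additional GC-rich tiles centred on promoters
#' @param difficult_promoter_n promoters declared "difficult"
#' @param blacklist_n,segdup_n,repeat_n exclusion-track interval counts
#' @param exclusion_width width range of exclusion intervals (bp)
#' @param make_reference emit a reference `DNAStringSet` whose tile GC
#'   content matches the GC track?
#' @param lambda0 baseline DNV rate at age zero (default 8.3, chosen so the
#'   cohort mean is ~59 at the default age range)
#' @param beta_father paternal-age slope in DNVs/year (default 1.56)
#' @param beta_mother maternal-age slope (default 0)
#' @param father_age_range integer range of father ages at conception
#' @param mother_age_offset_mean,mother_age_offset_sd father minus mother
#'   age distribution
#' @param multipliers named list of per-feature enrichment multipliers
#'   (names among promoter, enhancer, dhs, tfbs10, exon, utr5, upstream);
#'   unlisted features have multiplier 1
#' @param depth_mean mean sequencing depth (default 30)
#' @param gq_range range of genotype posterior qualities for good calls
#' @param gq_low_prob fraction of members with sub-Q20 posteriors
#' @param genotype_error probability a parent of a planted DNV is miscalled
#'   heterozygous (default 0: noise-free genotypes)
#' @param inherited_per_trio,homalt_violations_per_trio,missing_per_trio
#'   decoy record counts per trio
#' @param nssnv_exon_prob probability an exonic DNV is nonsynonymous
#' @param control_n control DNV set size (default 97942)
#' @param paternal_fraction fraction of DNVs of paternal origin (default
#'   0.8)
#' @param informative_prob probability a DNV has an informative SNV within
#'   the phasing window
#' @param phasing_window informative-site window (bp)
#' @param vote_probs named probabilities of 1..4 concordant supporting reads
#' @param sv_true_n,sv_inherited_n,sv_artifact_n,sv_single_caller_n,sv_excluded_n
#'   planted SV counts per category
#' @param sv_length_range SV length range (bp)
#' @param sv_jitter_frac breakpoint jitter of the second caller, as a
#'   fraction of SV length (must stay below the reciprocal-overlap
#'   threshold)
#' @param coverage_bin,coverage_flank,coverage_depth,coverage_noise_sd
#'   coverage-profile geometry and noise
#' @return a list of class `SyntheticCohortConfig`
#' @export
synth_config <- function(seed = 1L,
                         n_trios = 71L,
                         chrom_lengths = c(chr1 = 500000L, chr2 = 500000L),
                         n_genes = 24L,
                         exons_per_gene = c(4L, 8L),
                         exon_width = 150L, intron_width = 3000L,
                         utr5_width = 200L, utr3_width = 200L,
                         gene_gap_min = 2000L,
                         promoter_halfwidth = 300L,
                         enhancer_n = 40L, enhancer_width = 500L,
                         dhs_promoter_prob = 0.6,
                         dhs_width = 200L, dhs_background_n = 30L,
                         tfbs_rich_prob = 0.35,
                         tfbs_rich_range = c(10L, 15L),
                         tfbs_poor_max = 6L, tfbs_width = 150L,
                         gc_tile_fraction = 0.01,
                         gc_promoter_tiles = 3L,
                         difficult_promoter_n = 2L,
                         blacklist_n = 6L, segdup_n = 6L, repeat_n = 10L,
                         exclusion_width = c(2000L, 8000L),
                         make_reference = TRUE,
                         lambda0 = 8.3, beta_father = 1.56,
                         beta_mother = 0,
                         father_age_range = c(20L, 45L),
                         mother_age_offset_mean = 2.5,
                         mother_age_offset_sd = 3,
                         multipliers = list(),
                         depth_mean = 30, gq_range = c(20L, 99L),
                         gq_low_prob = 0.03, genotype_error = 0,
                         inherited_per_trio = 30L,
                         homalt_violations_per_trio = 2L,
                         missing_per_trio = 1L,
                         nssnv_exon_prob = 0.7,
                         control_n = 97942L,
                         paternal_fraction = 0.8,
                         informative_prob = 0.6,
                         phasing_window = 500L,
                         vote_probs = c(`1` = 0.15, `2` = 0.35, `3` = 0.30,
                                        `4` = 0.20),
                         sv_true_n = 5L, sv_inherited_n = 5L,
                         sv_artifact_n = 5L, sv_single_caller_n = 5L,
                         sv_excluded_n = 3L,
                         sv_length_range = c(500L, 5000L),
                         sv_jitter_frac = 0.1,
                         coverage_bin = 100L, coverage_flank = 1000L,
                         coverage_depth = 30, coverage_noise_sd = 1.5) {
  cfg <- as.list(environment())
  rates <- c(cfg$lambda0, cfg$beta_father, cfg$beta_mother,
             cfg$gq_low_prob, cfg$genotype_error, cfg$informative_prob,
             cfg$paternal_fraction, cfg$dhs_promoter_prob,
             cfg$tfbs_rich_prob, cfg$gc_tile_fraction, cfg$nssnv_exon_prob)
  if (any(rates < 0)) stop("all rates must be non-negative")
  if (cfg$paternal_fraction > 1 || cfg$informative_prob > 1)
    stop("probabilities must lie in [0, 1]")
  mult <- unlist(cfg$multipliers)
  if (length(mult) && any(mult <= 0)) stop("multipliers must be positive")
  known <- c("promoter", "enhancer", "dhs", "tfbs10", "exon", "utr5",
             "upstream")
  if (length(mult) && !all(names(mult) %in% known))
    stop("unknown multiplier feature(s): ",
         paste(setdiff(names(mult), known), collapse = ", "))
  structure(cfg, class = "SyntheticCohortConfig")
}

## sample one interval of `width` on the genome, uniformly by position;
## the result carries every chromosome as a seqlevel so combining is quiet
sample_interval <- function(chrom_lengths, width) {
  chrom <- sample(names(chrom_lengths), 1L,
                  prob = as.numeric(chrom_lengths))
  start <- sample.int(max(1L, chrom_lengths[[chrom]] - width), 1L)
  GenomicRanges::GRanges(factor(chrom, levels = names(chrom_lengths)),
                         IRanges::IRanges(start, start + width - 1L))
}

## sample n intervals avoiding overlap with `avoid` (best effort)
sample_intervals_avoiding <- function(n, chrom_lengths, width_range, avoid,
                                      max_tries = 50L) {
  out <- list()
  for (i in seq_len(n)) {
    w <- if (width_range[1L] == width_range[2L]) width_range[1L] else
      sample(seq.int(width_range[1L], width_range[2L]), 1L)
    for (t in seq_len(max_tries)) {
      gr <- sample_interval(chrom_lengths, w)
      if (!length(avoid) || !any(IRanges::overlapsAny(gr, avoid))) break
    }
    out[[i]] <- gr
    avoid <- suppressWarnings(c(avoid, gr))
  }
  if (!length(out))
    return(GenomicRanges::GRanges(
      seqnames = factor(levels = names(chrom_lengths)),
      ranges = IRanges::IRanges()))
  do.call(c, out)
}

#' Simulate annotation tracks and a reference sequence
#'
#' Places non-overlapping gene models (UTR5 - exons/introns - UTR3, random
#' strand) along the configured chromosomes, promoter chromatin states
#' around each TSS, enhancers in the remaining space, DHS preferentially
#' inside promoters, TFBS as focal stacked clusters (exercising the >= 10
#' threshold) plus scattered singles, GC-rich 100 bp tiles (some centred on
#' promoters so the GC filter has work to do), difficult promoters,
#' exclusion tracks for the SV pipeline, and optionally a reference
#' sequence whose per-tile GC content realizes the GC track.
#'
#' @param config a [synth_config()] object
#' @return an [annotation_tracks()] object (with `exclusion` and
#'   `reference` fields populated)
#' @export
simulate_tracks <- function(config) {
  stopifnot(is(config, "SyntheticCohortConfig"))
  set.seed(config$seed)
  cl <- config$chrom_lengths
  ## genes are laid out sequentially with random gaps; error when they
  ## cannot fit
  n_exons <- sample(seq.int(config$exons_per_gene[1L],
                            config$exons_per_gene[2L]),
                    config$n_genes, replace = TRUE)
  spans <- config$utr5_width + config$utr3_width +
    n_exons * config$exon_width + (n_exons - 1L) * config$intron_width
  per_chrom <- split(seq_len(config$n_genes),
                     rep(names(cl), length.out = config$n_genes))
  gm_rows <- list(); tss_rows <- list()
  for (chrom in names(per_chrom)) {
    idx <- per_chrom[[chrom]]
    need <- sum(spans[idx]) + (length(idx) + 1L) * config$gene_gap_min
    if (need > cl[[chrom]])
      stop("genome too small for requested features (need ", need,
           " bp on ", chrom, ", have ", cl[[chrom]], ")")
    slack <- cl[[chrom]] - sum(spans[idx]) -
      (length(idx) + 1L) * config$gene_gap_min
    extra <- if (length(idx)) {
      u <- sort(runif(length(idx)))
      round(diff(c(0, u)) * slack)
    } else integer(0)
    cursor <- config$gene_gap_min
    for (k in seq_along(idx)) {
      g <- idx[k]
      cursor <- cursor + extra[k]
      gene_start <- cursor
      strand <- sample(c("+", "-"), 1L)
      gene_id <- sprintf("GENE%03d", g)
      ## physical layout left -> right: UTRa, exon/intron alternation, UTRb
      widths <- c(config$utr5_width,
                  rep(c(config$exon_width, config$intron_width),
                      n_exons[g])[seq_len(2L * n_exons[g] - 1L)],
                  config$utr3_width)
      labels <- c("UTR5",
                  rep(c("exon", "intron"),
                      n_exons[g])[seq_len(2L * n_exons[g] - 1L)],
                  "UTR3")
      if (strand == "-") labels <- rev(labels)
      starts <- gene_start + cumsum(c(0L, widths[-length(widths)]))
      ends <- starts + widths - 1L
      ranks <- integer(length(labels))
      is_ex <- labels == "exon"
      ranks[is_ex] <- if (strand == "+") seq_len(sum(is_ex)) else
        rev(seq_len(sum(is_ex)))
      gm_rows[[length(gm_rows) + 1L]] <- data.frame(
        chrom = chrom, start = starts, end = ends, label = labels,
        gene = gene_id, exon_rank = ifelse(is_ex, ranks, NA_integer_),
        strand = strand, stringsAsFactors = FALSE)
      tss_pos <- if (strand == "+") gene_start else
        gene_start + sum(widths) - 1L
      tss_rows[[length(tss_rows) + 1L]] <- data.frame(
        chrom = chrom, pos = tss_pos, strand = strand, gene = gene_id,
        stringsAsFactors = FALSE)
      cursor <- cursor + sum(widths) + config$gene_gap_min
    }
  }
  gm <- do.call(rbind, gm_rows)
  gene_model <- GenomicRanges::GRanges(
    gm$chrom, IRanges::IRanges(gm$start, gm$end), strand = gm$strand,
    label = gm$label, gene = gm$gene, exon_rank = gm$exon_rank)
  ts <- do.call(rbind, tss_rows)
  tss <- GenomicRanges::GRanges(ts$chrom, IRanges::IRanges(ts$pos, ts$pos),
                                strand = ts$strand, gene = ts$gene)

  promoters <- GenomicRanges::trim(suppressWarnings(
    GenomicRanges::resize(GenomicRanges::granges(tss),
                          width = 2L * config$promoter_halfwidth + 1L,
                          fix = "center")))
  GenomicRanges::strand(promoters) <- "*"
  promoters$label <- "Promoter"
  promoters$gene <- tss$gene
  enhancers <- sample_intervals_avoiding(
    config$enhancer_n, cl, rep(config$enhancer_width, 2L), promoters)
  enhancers$label <- "Enhancer"
  enhancers$gene <- NA_character_
  chromatin <- c(promoters, enhancers)

  ## DHS: one per selected promoter (inside it), plus background sites
  has_dhs <- runif(length(promoters)) < config$dhs_promoter_prob
  dhs_list <- GenomicRanges::GRanges()
  if (any(has_dhs)) {
    p <- promoters[has_dhs]
    off <- vapply(GenomicRanges::width(p) - config$dhs_width,
                  function(m) sample.int(max(1L, m), 1L), integer(1))
    dhs_list <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(p),
      IRanges::IRanges(GenomicRanges::start(p) + off,
                       width = config$dhs_width))
  }
  dhs_bg <- sample_intervals_avoiding(
    config$dhs_background_n, cl, rep(config$dhs_width, 2L), promoters)
  dhs <- sort(c(dhs_list, GenomicRanges::granges(dhs_bg)))

  ## TFBS: focal stacked clusters in a subset of DHS promoters (all sites
  ## cover the focal base, so positional TFBS counts reach >= 10), plus
  ## scattered sites elsewhere
  tfbs_parts <- list()
  tw <- min(config$tfbs_width,
            max(10L, GenomicRanges::width(promoters)[1L] %/% 3L))
  dhs_prom_idx <- which(has_dhs)
  for (k in dhs_prom_idx) {
    p <- promoters[k]
    if (runif(1) < config$tfbs_rich_prob) {
      nsites <- sample(seq.int(config$tfbs_rich_range[1L],
                               config$tfbs_rich_range[2L]), 1L)
      focal <- GenomicRanges::start(p) +
        sample.int(GenomicRanges::width(p) - tw, 1L)
      offs <- sample.int(tw, nsites, replace = TRUE) - 1L
      tfbs_parts[[length(tfbs_parts) + 1L]] <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(p),
        IRanges::IRanges(focal - offs, width = tw))
    } else {
      nsites <- sample.int(config$tfbs_poor_max + 1L, 1L) - 1L
      if (nsites > 0L) {
        offs <- sample.int(GenomicRanges::width(p) - tw,
                           nsites, replace = TRUE)
        tfbs_parts[[length(tfbs_parts) + 1L]] <- GenomicRanges::GRanges(
          GenomicRanges::seqnames(p),
          IRanges::IRanges(GenomicRanges::start(p) + offs, width = tw))
      }
    }
  }
  tfbs_parts[[length(tfbs_parts) + 1L]] <- GenomicRanges::granges(
    sample_intervals_avoiding(50L, cl, rep(tw, 2L),
                              GenomicRanges::GRanges()))
  tfbs <- sort(suppressWarnings(do.call(c, tfbs_parts)))

  ## GC-rich 100 bp tiles on the tiling grid anchored at base 1
  gc_tiles <- list()
  for (chrom in names(cl)) {
    n_tiles <- cl[[chrom]] %/% 100L
    pick <- sample.int(n_tiles, max(0L, round(config$gc_tile_fraction *
                                                n_tiles)))
    gc_tiles[[chrom]] <- pick
  }
  prom_tiles <- head(which(has_dhs == FALSE), config$gc_promoter_tiles)
  for (k in prom_tiles) {
    p <- promoters[k]
    chrom <- as.character(GenomicRanges::seqnames(p))
    centre_tile <- (GenomicRanges::start(p) +
                      GenomicRanges::width(p) %/% 2L - 1L) %/% 100L + 1L
    gc_tiles[[chrom]] <- union(gc_tiles[[chrom]], centre_tile)
  }
  gc_high <- suppressWarnings(do.call(c, lapply(names(cl), function(chrom) {
    t <- sort(gc_tiles[[chrom]])
    if (!length(t)) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(chrom,
                           IRanges::IRanges((t - 1L) * 100L + 1L, t * 100L))
  })))

  difficult <- promoters[sample.int(length(promoters),
                                    config$difficult_promoter_n)]
  S4Vectors::mcols(difficult) <- NULL

  exclusion <- list(
    blacklist = sample_intervals_avoiding(config$blacklist_n, cl,
                                          config$exclusion_width,
                                          GenomicRanges::GRanges()),
    segdup = sample_intervals_avoiding(config$segdup_n, cl,
                                       config$exclusion_width,
                                       GenomicRanges::GRanges()),
    repeats = sample_intervals_avoiding(config$repeat_n, cl,
                                        config$exclusion_width,
                                        GenomicRanges::GRanges()))

  reference <- NULL
  if (config$make_reference) {
    reference <- Biostrings::DNAStringSet(vapply(names(cl), function(chrom) {
      n <- cl[[chrom]]
      bases <- sample(c("A", "T", "G", "C"), n, replace = TRUE,
                      prob = c(0.275, 0.275, 0.225, 0.225))
      for (t in gc_tiles[[chrom]]) {
        lo <- (t - 1L) * 100L + 1L
        hi <- min(t * 100L, n)
        w <- hi - lo + 1L
        tile <- sample(c("A", "T"), w, replace = TRUE)
        gc_pos <- sample.int(w, ceiling(0.85 * w))
        tile[gc_pos] <- sample(c("G", "C"), length(gc_pos), replace = TRUE)
        bases[lo:hi] <- tile
      }
      paste(bases, collapse = "")
    }, character(1)))
    names(reference) <- names(cl)
  }

  annotation_tracks(gene_model = gene_model, tss = tss,
                    chromatin = chromatin, dhs = dhs, tfbs = tfbs,
                    exclusion = exclusion,
                    difficult_promoters = difficult, gc_high = gc_high,
                    reference = reference)
}

## named list of feature GRanges used for multiplier-weighted placement
feature_regions <- function(tracks, upstream_window = 1000) {
  tf_cov <- GenomicRanges::coverage(tracks$tfbs)
  tf10 <- GenomicRanges::GRanges(IRanges::slice(tf_cov, lower = 10,
                                                rangesOnly = TRUE))
  list(promoter = tracks$chromatin[tracks$chromatin$label == "Promoter"],
       enhancer = tracks$chromatin[tracks$chromatin$label == "Enhancer"],
       dhs = tracks$dhs,
       tfbs10 = tf10,
       exon = tracks$gene_model[tracks$gene_model$label == "exon"],
       utr5 = tracks$gene_model[tracks$gene_model$label == "UTR5"],
       upstream = upstream_regions(tracks$tss, upstream_window))
}

#' Sample variant positions with per-feature enrichment multipliers
#'
#' Positions are drawn uniformly over the genome and accepted by rejection
#' sampling with weight equal to the product of the multipliers of the
#' features covering the position, giving exactly controllable relative
#' densities.
#'
#' @param n number of positions
#' @param tracks an [annotation_tracks()] object
#' @param multipliers named list of multipliers (see [synth_config()])
#' @param chrom_lengths named chromosome lengths
#' @param regions optional precomputed [feature_regions] list (internal
#'   optimization)
#' @return `data.frame` with chrom and pos columns
#' @export
sample_positions <- function(n, tracks, multipliers, chrom_lengths,
                             regions = NULL) {
  mult <- unlist(multipliers)
  mult <- mult[!is.na(mult) & mult != 1]
  if (is.null(regions))
    regions <- if (length(mult)) feature_regions(tracks) else list()
  wmax <- prod(pmax(mult, 1))
  got <- list(); total <- 0L
  while (total < n) {
    m <- max(1000L, ceiling((n - total) * wmax * 1.3))
    chrom <- sample(names(chrom_lengths), m, replace = TRUE,
                    prob = as.numeric(chrom_lengths))
    pos <- vapply(chrom_lengths[chrom], sample.int, integer(1), size = 1L)
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
    w <- rep(1, m)
    for (f in names(mult)) {
      hit <- IRanges::overlapsAny(gr, regions[[f]])
      w[hit] <- w[hit] * mult[[f]]
    }
    keep <- runif(m) < w / wmax
    got[[length(got) + 1L]] <- data.frame(chrom = chrom[keep],
                                          pos = pos[keep],
                                          stringsAsFactors = FALSE)
    total <- total + sum(keep)
  }
  res <- do.call(rbind, got)[seq_len(n), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## cache reference chromosomes as plain character scalars for fast
## positional lookup
reference_chars <- function(reference) {
  if (is.null(reference)) return(NULL)
  if (is.character(reference)) return(reference)
  setNames(as.character(reference), names(reference))
}

## draw ref/alt bases for positions; uses the reference sequence when there
## is one so planted records agree with it
draw_alleles <- function(pos_df, reference) {
  bases <- c("A", "C", "G", "T")
  n <- nrow(pos_df)
  ref_chars <- reference_chars(reference)
  if (!is.null(ref_chars)) {
    ref <- character(n)
    for (chrom in unique(pos_df$chrom)) {
      sel <- pos_df$chrom == chrom
      ref[sel] <- substring(ref_chars[[chrom]], pos_df$pos[sel],
                            pos_df$pos[sel])
    }
  } else {
    ref <- sample(bases, n, replace = TRUE)
  }
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  data.frame(ref = ref, alt = unname(alt), stringsAsFactors = FALSE)
}

## genotype-quality draw: mostly in gq_range, a small fraction below Q20
draw_gq <- function(n, config) {
  low <- runif(n) < config$gq_low_prob
  gq <- sample(seq.int(config$gq_range[1L], config$gq_range[2L]), n,
               replace = TRUE)
  gq[low] <- sample(5:19, sum(low), replace = TRUE)
  gq
}

## build one member's depth fields for a given genotype
member_depths <- function(gt, depth_mean) {
  dp <- pmax(1L, rpois(length(gt), depth_mean))
  alt <- integer(length(gt))
  het <- !is.na(gt) & gt == "0/1"
  hom <- !is.na(gt) & gt == "1/1"
  alt[het] <- rbinom(sum(het), dp[het], 0.5)
  alt[hom] <- dp[hom]
  data.frame(ref = dp - alt, alt = alt)
}

#' Simulate a trio cohort with planted DNVs
#'
#' For each trio, the DNV count is Poisson with mean
#' `lambda0 + beta_father * father_age + beta_mother * mother_age`; DNV
#' positions are drawn with the configured feature multipliers; genotypes,
#' allele depths (mean 30x, binomial allele balance), posterior qualities
#' and phasing read evidence are emitted consistent with the planted truth;
#' parental origin is Bernoulli with the configured paternal fraction.
#' Inherited heterozygous sites (phasing-informative among them),
#' child-homozygous-alternate violations and missing-genotype sites are
#' added as decoys. The ground-truth ledger records every planted DNV, its
#' feature memberships and its expected fate under the default filters.
#'
#' @param config a [synth_config()] object
#' @param tracks tracks from [simulate_tracks()]
#' @return list with `pedigree`, `records` (named list of per-trio record
#'   tables keyed by child id), `evidence` (long form) and `ledger`
#' @export
simulate_trio_cohort <- function(config, tracks) {
  stopifnot(is(config, "SyntheticCohortConfig"))
  set.seed(config$seed + 1L)
  n <- config$n_trios
  fam <- sprintf("FAM%03d", seq_len(n))
  ped <- data.frame(
    family_id = fam,
    child_id = sprintf("C%03d", seq_len(n)),
    father_id = sprintf("F%03d", seq_len(n)),
    mother_id = sprintf("M%03d", seq_len(n)),
    child_sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.85, 0.15)),
    father_age = sample(seq.int(config$father_age_range[1L],
                                config$father_age_range[2L]),
                        n, replace = TRUE),
    stringsAsFactors = FALSE)
  ped$mother_age <- pmax(18L, ped$father_age -
                           as.integer(round(rnorm(n,
                                                  config$mother_age_offset_mean,
                                                  config$mother_age_offset_sd))))
  lambda <- pmax(0, config$lambda0 + config$beta_father * ped$father_age +
                   config$beta_mother * ped$mother_age)
  counts <- rpois(n, lambda)

  records <- list(); evidence <- list(); ledger <- list()
  regions <- feature_regions(tracks)
  ref_chars <- reference_chars(tracks$reference)
  ## batch position draws for the whole cohort (one rejection-sampling run
  ## instead of one per trio)
  all_dnv <- if (sum(counts) > 0L)
    sample_positions(sum(counts), tracks, config$multipliers,
                     config$chrom_lengths, regions = regions)
  else data.frame(chrom = character(0), pos = integer(0))
  dnv_split <- split(all_dnv, factor(rep(seq_len(n), counts),
                                     levels = seq_len(n)))
  n_decoy <- config$inherited_per_trio +
    config$homalt_violations_per_trio + config$missing_per_trio
  all_decoy <- sample_positions(n * n_decoy, tracks, list(),
                                config$chrom_lengths, regions = regions)
  decoy_split <- split(all_decoy, rep(seq_len(n), each = n_decoy))
  for (i in seq_len(n)) {
    child <- ped$child_id[i]
    dnv_pos <- dnv_split[[i]]
    decoy_pos <- decoy_split[[i]]
    ## keep positions unique within the trio
    dnv_pos <- dnv_pos[!duplicated(paste(dnv_pos$chrom, dnv_pos$pos)), ,
                       drop = FALSE]
    k <- nrow(dnv_pos)
    al <- draw_alleles(dnv_pos, ref_chars)
    ch_d <- member_depths(rep("0/1", k), config$depth_mean)
    fa_d <- member_depths(rep("0/0", k), config$depth_mean)
    mo_d <- member_depths(rep("0/0", k), config$depth_mean)
    gq_c <- draw_gq(k, config); gq_f <- draw_gq(k, config)
    gq_m <- draw_gq(k, config)
    gt_f <- rep("0/0", k); gt_m <- rep("0/0", k)
    if (config$genotype_error > 0 && k > 0L) {
      err <- runif(k) < config$genotype_error
      which_par <- sample(c("f", "m"), k, replace = TRUE)
      gt_f[err & which_par == "f"] <- "0/1"
      gt_m[err & which_par == "m"] <- "0/1"
    }
    dnv_rec <- data.frame(
      chrom = dnv_pos$chrom, pos = dnv_pos$pos, ref = al$ref, alt = al$alt,
      var_class = "SNV",
      gt_child = "0/1", gt_father = gt_f, gt_mother = gt_m,
      ad_child_ref = ch_d$ref, ad_child_alt = ch_d$alt,
      ad_father_ref = fa_d$ref, ad_father_alt = fa_d$alt,
      ad_mother_ref = mo_d$ref, ad_mother_alt = mo_d$alt,
      gq_child = gq_c, gq_father = gq_f, gq_mother = gq_m,
      stringsAsFactors = FALSE)

    ## decoys: inherited het sites, hom-alt violations, missing genotypes
    n_inh <- config$inherited_per_trio
    inh_pos <- decoy_pos[seq_len(n_inh), , drop = FALSE]
    inh_al <- draw_alleles(inh_pos, ref_chars)
    inh_gts <- matrix(c("0/1", "0/1", "0/0",
                        "0/1", "0/0", "0/1",
                        "0/1", "1/1", "0/0",
                        "0/1", "0/0", "1/1",
                        "1/1", "0/1", "0/1",
                        "0/0", "0/1", "0/1"), ncol = 3L, byrow = TRUE)
    pick <- sample.int(nrow(inh_gts), n_inh, replace = TRUE)
    make_rec <- function(pos_df, al_df, gt3) {
      m <- nrow(pos_df)
      cd <- member_depths(gt3[, 1L], config$depth_mean)
      fd <- member_depths(gt3[, 2L], config$depth_mean)
      md <- member_depths(gt3[, 3L], config$depth_mean)
      data.frame(
        chrom = pos_df$chrom, pos = pos_df$pos, ref = al_df$ref,
        alt = al_df$alt, var_class = "SNV",
        gt_child = gt3[, 1L], gt_father = gt3[, 2L], gt_mother = gt3[, 3L],
        ad_child_ref = cd$ref, ad_child_alt = cd$alt,
        ad_father_ref = fd$ref, ad_father_alt = fd$alt,
        ad_mother_ref = md$ref, ad_mother_alt = md$alt,
        gq_child = draw_gq(m, config), gq_father = draw_gq(m, config),
        gq_mother = draw_gq(m, config), stringsAsFactors = FALSE)
    }
    inh_rec <- make_rec(inh_pos, inh_al, inh_gts[pick, , drop = FALSE])
    n_ha <- config$homalt_violations_per_trio
    ha_pos <- decoy_pos[n_inh + seq_len(n_ha), , drop = FALSE]
    ha_rec <- make_rec(
      ha_pos,
      draw_alleles(data.frame(chrom = character(n_ha), pos = integer(n_ha)),
                   NULL),
      matrix(rep(c("1/1", "0/0", "0/0"), n_ha), ncol = 3L, byrow = TRUE))
    n_mi <- config$missing_per_trio
    mi_pos <- decoy_pos[n_inh + n_ha + seq_len(n_mi), , drop = FALSE]
    mi_rec <- make_rec(
      mi_pos,
      draw_alleles(data.frame(chrom = character(n_mi), pos = integer(n_mi)),
                   NULL),
      matrix(rep(c("0/1", NA, "0/0"), n_mi), ncol = 3L, byrow = TRUE))

    ## parental origin and read-backed phasing evidence (vectorized; DNVs
    ## whose informative position collides with an existing record simply
    ## stay uninformative)
    origin <- ifelse(runif(k) < config$paternal_fraction,
                     "paternal", "maternal")
    informative <- runif(k) < config$informative_prob
    votes <- integer(k)
    inf_rec <- NULL
    ev <- NULL
    idx <- which(informative)
    if (length(idx)) {
      delta <- sample(c(-1L, 1L), length(idx), replace = TRUE) *
        sample(seq.int(30L, config$phasing_window - 50L), length(idx),
               replace = TRUE)
      ipos <- dnv_rec$pos[idx] + delta
      clen <- unname(unlist(config$chrom_lengths)[dnv_rec$chrom[idx]])
      used_pos <- c(dnv_rec$pos, inh_rec$pos, ha_rec$pos, mi_rec$pos)
      ok <- ipos >= 1L & ipos <= clen & !(ipos %in% used_pos) &
        !duplicated(paste(dnv_rec$chrom[idx], ipos))
      informative[idx[!ok]] <- FALSE
      idx <- idx[ok]; ipos <- ipos[ok]
      if (length(idx)) {
        ial <- draw_alleles(data.frame(chrom = dnv_rec$chrom[idx],
                                       pos = ipos,
                                       stringsAsFactors = FALSE), ref_chars)
        ## four unambiguous inherited patterns; alt_parent varies over them
        pats <- matrix(c("0/1", "1/1", "0/0",
                         "0/1", "0/1", "0/0",
                         "0/1", "0/0", "1/1",
                         "0/1", "0/0", "0/1"), ncol = 3L, byrow = TRUE)
        pat <- sample.int(4L, length(idx), replace = TRUE)
        alt_parent <- ifelse(pat <= 2L, "father", "mother")
        inf_rec <- make_rec(data.frame(chrom = dnv_rec$chrom[idx],
                                       pos = ipos,
                                       stringsAsFactors = FALSE),
                            ial, pats[pat, , drop = FALSE])
        nv <- as.integer(sample(names(config$vote_probs), length(idx),
                                replace = TRUE, prob = config$vote_probs))
        votes[idx] <- nv
        obs_allele <- ifelse((origin[idx] == "paternal") ==
                               (alt_parent == "father"), ial$alt, ial$ref)
        jr <- rep(seq_along(idx), nv)       # informative-site index per read
        rid <- sprintf("%s_d%d_r%d", child, idx[jr], sequence(nv))
        ev <- data.frame(
          read_id = c(rid, rid), sample_id = child,
          pos = c(dnv_rec$pos[idx][jr], ipos[jr]),
          allele = c(dnv_rec$alt[idx][jr], obs_allele[jr]),
          stringsAsFactors = FALSE)
      }
    }

    trio_rec <- rbind(dnv_rec, inh_rec, ha_rec, mi_rec, inf_rec)
    trio_rec <- trio_rec[order(trio_rec$chrom, trio_rec$pos), ,
                         drop = FALSE]
    rownames(trio_rec) <- NULL
    records[[child]] <- trio_rec
    evidence[[child]] <- ev

    if (k > 0L) {
      ab <- ch_d$alt / (ch_d$ref + ch_d$alt)
      gq_min <- pmin(gq_c, gq_f, gq_m)
      detectable <- gt_f == "0/0" & gt_m == "0/0"
      fate <- ifelse(!detectable, "undetected",
                     ifelse(gq_min < 20, "filtered_quality",
                            ifelse(ab < 0.30 | ab > 0.70, "filtered_ab",
                                   "accepted")))
      ledger[[child]] <- data.frame(
        child_id = child, chrom = dnv_rec$chrom, pos = dnv_rec$pos,
        ref = dnv_rec$ref, alt = dnv_rec$alt,
        origin = origin, informative = informative, votes = votes,
        expected_fate = fate, stringsAsFactors = FALSE)
    }
  }
  ev <- do.call(rbind, evidence)
  if (is.null(ev))
    ev <- data.frame(read_id = character(0), sample_id = character(0),
                     pos = integer(0), allele = character(0))
  led <- do.call(rbind, ledger)
  rownames(ev) <- NULL
  if (!is.null(led)) {
    ## feature memberships for the whole cohort in one pass
    gr <- GenomicRanges::GRanges(led$chrom,
                                 IRanges::IRanges(led$pos, led$pos))
    in_reg <- function(f) IRanges::overlapsAny(gr, regions[[f]])
    led$promoter <- in_reg("promoter")
    led$enhancer <- in_reg("enhancer")
    led$dhs <- in_reg("dhs")
    led$tfbs10 <- in_reg("tfbs10")
    led$exon <- in_reg("exon")
    led$utr5 <- in_reg("utr5")
    led$upstream <- in_reg("upstream")
    led$gc_excluded <- IRanges::overlapsAny(gr, tracks$gc_high) |
      IRanges::overlapsAny(gr, tracks$difficult_promoters)
    led$nssnv <- led$exon & runif(nrow(led)) < config$nssnv_exon_prob
    rownames(led) <- NULL
  }
  list(pedigree = ped, records = records, evidence = ev, ledger = led)
}

#' Simulate a control DNV set
#'
#' A large set of DNVs placed with baseline (multiplier 1) feature
#' densities, emulating a population control resource annotated with the
#' same tracks as the case cohort. The nonsynonymous flag is planted on
#' exonic variants at the same baseline rate as in the case generator.
#'
#' @param config a [synth_config()] object
#' @param tracks tracks from [simulate_tracks()]
#' @param n set size (default `config$control_n`)
#' @param multipliers feature multipliers (default none: baseline)
#' @return `data.frame` with chrom, pos, ref, alt and nssnv columns
#' @export
simulate_control_set <- function(config, tracks, n = config$control_n,
                                 multipliers = list()) {
  stopifnot(is(config, "SyntheticCohortConfig"))
  set.seed(config$seed + 2L)
  pos <- sample_positions(n, tracks, multipliers, config$chrom_lengths)
  al <- draw_alleles(pos, reference_chars(tracks$reference))
  gr <- GenomicRanges::GRanges(pos$chrom, IRanges::IRanges(pos$pos, pos$pos))
  exonic <- IRanges::overlapsAny(
    gr, tracks$gene_model[tracks$gene_model$label == "exon"])
  data.frame(chrom = pos$chrom, pos = pos$pos, ref = al$ref, alt = al$alt,
             nssnv = exonic & runif(n) < config$nssnv_exon_prob,
             stringsAsFactors = FALSE)
}

#' Simulate dual-caller SV data for one trio
#'
#' Plants five categories of child SVs: true de novo events (present in
#' both child call sets with breakpoint jitter below the reciprocal-overlap
#' threshold, absent from parents, carrier-specific coverage change),
#' inherited events (also present in a parental call set — half of them
#' only as low-confidence candidates), artefacts (trio-similar coverage
#' patterns), exclusion-region decoys (inside blacklist/repeat tracks), and
#' single-caller calls. Parents additionally carry private SVs that never
#' enter the child sets. Coverage is emitted genome-wide on a fixed bin
#' grid with heterozygous-deletion carriers at ~0.5x interior depth
#' (duplications ~1.5x).
#'
#' @param config a [synth_config()] object
#' @param tracks tracks from [simulate_tracks()] (exclusion tracks used)
#' @param child,father,mother sample identifiers
#' @return list with `callsets` (child A/B, father, mother), `coverage`
#'   (binned depth table) and `ledger` (planted events with category and
#'   expected first failing stage)
#' @export
simulate_sv_data <- function(config, tracks, child = "C001",
                             father = "F001", mother = "M001") {
  stopifnot(is(config, "SyntheticCohortConfig"))
  set.seed(config$seed + 3L)
  cl <- config$chrom_lengths
  excl_all <- GenomicRanges::reduce(
    do.call(c, unname(lapply(tracks$exclusion, GenomicRanges::granges))))
  pad <- config$coverage_flank + 2L * config$coverage_bin
  used <- excl_all

  place_clean <- function() {
    len <- sample(seq.int(config$sv_length_range[1L],
                          config$sv_length_range[2L]), 1L)
    for (t in 1:200) {
      gr <- sample_interval(cl, len)
      grp <- GenomicRanges::resize(gr, width = len + 2L * pad,
                                   fix = "center")
      grp <- GenomicRanges::trim(suppressWarnings(grp))
      if (!any(IRanges::overlapsAny(grp, used))) {
        used <<- c(used, grp)
        return(gr)
      }
    }
    stop("genome too small to place structural variants")
  }
  place_excluded <- function() {
    track <- tracks$exclusion[[sample.int(length(tracks$exclusion), 1L)]]
    host <- track[sample.int(length(track), 1L)]
    len <- min(sample(seq.int(config$sv_length_range[1L],
                              config$sv_length_range[2L]), 1L),
               GenomicRanges::width(host) - 2L)
    start <- GenomicRanges::start(host) +
      sample.int(max(1L, GenomicRanges::width(host) - len), 1L)
    GenomicRanges::GRanges(GenomicRanges::seqnames(host),
                           IRanges::IRanges(start, start + len - 1L))
  }

  jitter_call <- function(gr) {
    len <- GenomicRanges::width(gr)
    d1 <- sample.int(max(1L, round(config$sv_jitter_frac * len)), 1L) - 1L
    d2 <- sample.int(max(1L, round(config$sv_jitter_frac * len)), 1L) - 1L
    GenomicRanges::GRanges(
      GenomicRanges::seqnames(gr),
      IRanges::IRanges(GenomicRanges::start(gr) + d1 * sample(c(-1L, 1L), 1L),
                       GenomicRanges::end(gr) + d2 * sample(c(-1L, 1L), 1L)))
  }
  as_call <- function(gr, svtype, caller, sample_id, status = "called") {
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr),
               end = GenomicRanges::end(gr), svtype = svtype,
               length = GenomicRanges::width(gr), caller = caller,
               sample = sample_id, status = status,
               stringsAsFactors = FALSE)
  }
  draw_type <- function() sample(c("DEL", "DUP"), 1L, prob = c(0.8, 0.2))

  cats <- c(rep("true_denovo", config$sv_true_n),
            rep("inherited", config$sv_inherited_n),
            rep("artifact", config$sv_artifact_n),
            rep("excluded", config$sv_excluded_n),
            rep("single_caller", config$sv_single_caller_n))
  child_a <- list(); child_b <- list(); father_c <- list()
  mother_c <- list(); ledger <- list()
  cov_events <- list()  # sample, region, multiplier
  for (s in seq_along(cats)) {
    cat_s <- cats[s]
    svtype <- draw_type()
    gr <- if (cat_s == "excluded") place_excluded() else place_clean()
    mult <- if (svtype == "DEL") 0.5 else 1.5
    expected <- switch(cat_s,
                       true_denovo = "pass", inherited = "parental",
                       excluded = "annotation", artifact = "coverage",
                       single_caller = "consensus")
    if (cat_s == "single_caller") {
      child_a[[s]] <- as_call(gr, svtype, "callerA", child)
      cov_events[[length(cov_events) + 1L]] <-
        list(sample = child, gr = gr, mult = mult)
    } else {
      child_a[[s]] <- as_call(gr, svtype, "callerA", child)
      child_b[[s]] <- as_call(jitter_call(gr), svtype, "callerB", child)
      if (cat_s == "inherited") {
        parent <- sample(c(father, mother), 1L)
        status <- if (s %% 2L == 0L) "candidate" else "called"
        pc <- as_call(jitter_call(gr), svtype, "callerA", parent, status)
        if (parent == father) father_c[[s]] <- pc else mother_c[[s]] <- pc
        cov_events[[length(cov_events) + 1L]] <-
          list(sample = child, gr = gr, mult = mult)
        cov_events[[length(cov_events) + 1L]] <-
          list(sample = parent, gr = gr, mult = mult)
      } else if (cat_s == "artifact") {
        ## shared wiggle in all three samples: similar flanking coverage
        for (smp in c(child, father, mother))
          cov_events[[length(cov_events) + 1L]] <-
            list(sample = smp, gr = gr, mult = 0.6)
      } else {
        cov_events[[length(cov_events) + 1L]] <-
          list(sample = child, gr = gr, mult = mult)
      }
    }
    led_gr <- gr
    ledger[[s]] <- data.frame(
      sv_id = sprintf("SV%02d", s), category = cat_s,
      chrom = as.character(GenomicRanges::seqnames(led_gr)),
      start = GenomicRanges::start(led_gr),
      end = GenomicRanges::end(led_gr), svtype = svtype,
      expected_stage = expected, stringsAsFactors = FALSE)
  }
  ## parental private SVs (never in the child sets)
  for (p in c(father, mother)) {
    for (q in 1:3) {
      gr <- place_clean()
      ty <- draw_type()
      rec <- as_call(gr, ty, "callerA", p)
      if (p == father) father_c[[length(father_c) + 1L]] <- rec
      else mother_c[[length(mother_c) + 1L]] <- rec
      cov_events[[length(cov_events) + 1L]] <-
        list(sample = p, gr = gr, mult = if (ty == "DEL") 0.5 else 1.5)
    }
  }

  bind <- function(x) {
    x <- x[!vapply(x, is.null, TRUE)]
    if (!length(x)) empty_df(sv_call_proto) else
      do.call(rbind, x)
  }

  ## genome-wide binned coverage with planted dosage effects; the artefact
  ## wiggle is identical across samples by construction (same multiplier
  ## over the same bins), independent noise on top
  bins <- do.call(rbind, lapply(names(cl), function(chrom) {
    starts <- seq.int(1L, cl[[chrom]], by = config$coverage_bin)
    data.frame(chrom = chrom, bin_start = starts, stringsAsFactors = FALSE)
  }))
  samples <- c(child, father, mother)
  coverage <- do.call(rbind, lapply(samples, function(smp) {
    depth <- config$coverage_depth +
      rnorm(nrow(bins), 0, config$coverage_noise_sd)
    for (evn in cov_events) {
      if (evn$sample != smp) next
      sel <- bins$chrom == as.character(GenomicRanges::seqnames(evn$gr)) &
        bins$bin_start >= GenomicRanges::start(evn$gr) &
        bins$bin_start <= GenomicRanges::end(evn$gr)
      depth[sel] <- depth[sel] * evn$mult
    }
    data.frame(sample = smp, chrom = bins$chrom,
               bin_start = bins$bin_start, depth = depth,
               stringsAsFactors = FALSE)
  }))
  rownames(coverage) <- NULL

  list(callsets = list(child_a = bind(child_a), child_b = bind(child_b),
                       father = bind(father_c), mother = bind(mother_c)),
       coverage = coverage,
       ledger = do.call(rbind, ledger))
}

#' Write a simulated cohort to disk
#'
#' Emits exactly the formats the readers consume: one multi-sample VCF per
#' trio, a pedigree TSV, a read-evidence TSV and a JSON ground-truth
#' ledger.
#'
#' @param cohort result of [simulate_trio_cohort()]
#' @param dir output directory (created if needed)
#' @param chrom_lengths contig lengths for the VCF headers
#' @return the directory, invisibly
#' @export
write_cohort <- function(cohort, dir, chrom_lengths = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ped <- cohort$pedigree
  write_pedigree(ped, file.path(dir, "pedigree.tsv"))
  for (i in seq_len(nrow(ped))) {
    child <- ped$child_id[i]
    write_trio_vcf(cohort$records[[child]],
                   file.path(dir, paste0(ped$family_id[i], ".vcf")),
                   child, ped$father_id[i], ped$mother_id[i],
                   contigs = chrom_lengths)
  }
  write_read_evidence(cohort$evidence, file.path(dir, "evidence.tsv"))
  jsonlite::write_json(cohort$ledger, file.path(dir, "ledger.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
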