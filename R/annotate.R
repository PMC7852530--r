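#' Functional annotation of de novo variants
#'
#' Every DNV is assigned a gene-position class (RefSeq-style, with an
#' Annovar-like precedence order), a chromatin state (ChromHMM-style
#' B-lymphocyte segmentation: Promoter / Enhancer / Other), an open-chromatin
#' flag (DNase I hypersensitive sites), a count of overlapping transcription
#' factor binding sites (ENCODE ChIP-seq cluster style), and a GC-content
#' exclusion flag. The GC filter removes variants in 100 bp tiles with at
#' least 75% GC or in "difficult promoter" regions and is applied
#' symmetrically to case and control sets before enrichment testing, since
#' GC-rich regions have library-preparation-dependent coverage.
#'
#' @name annotate
NULL

#' Bundle annotation tracks
#'
#' Collects the interval tracks the annotator consumes into one object.
#'
#' @param gene_model `GRanges` with `mcols()` columns `label` (one of UTR5,
#'   UTR3, exon, intron), `gene`, and `exon_rank` for exons
#' @param tss stranded width-1 `GRanges` of transcription start sites with a
#'   `gene` column
#' @param chromatin `GRanges` of chromatin-state intervals, `label` in
#'   Promoter / Enhancer / Other (uncovered positions default to Other)
#' @param dhs `GRanges` of DNase I hypersensitive sites
#' @param tfbs `GRanges` of transcription factor binding sites (one range per
#'   factor-site)
#' @param exclusion named list of `GRanges` exclusion tracks (blacklist, low
#'   mappability, segmental duplications, repeats) used by the SV pipeline
#' @param difficult_promoters `GRanges` of promoters excluded by the GC
#'   filter
#' @param gc_high `GRanges` of 100 bp tiles with GC fraction >= 0.75
#' @param reference optional `DNAStringSet` named by chromosome
#' @return an object of class `AnnotationTrackSet`
#' @export
annotation_tracks <- function(gene_model = GenomicRanges::GRanges(),
                              tss = GenomicRanges::GRanges(),
                              chromatin = GenomicRanges::GRanges(),
                              dhs = GenomicRanges::GRanges(),
                              tfbs = GenomicRanges::GRanges(),
                              exclusion = list(),
                              difficult_promoters = GenomicRanges::GRanges(),
                              gc_high = GenomicRanges::GRanges(),
                              reference = NULL) {
  if (length(gene_model) &&
      !all(gene_model$label %in% c("UTR5", "UTR3", "exon", "intron")))
    stop("gene_model labels must be UTR5/UTR3/exon/intron")
  if (length(chromatin) &&
      !all(chromatin$label %in% c("Promoter", "Enhancer", "Other")))
    stop("chromatin labels must be Promoter/Enhancer/Other")
  structure(list(
    gene_model = sort(gene_model), tss = sort(tss),
    chromatin = sort(chromatin), dhs = sort(dhs), tfbs = sort(tfbs),
    exclusion = lapply(exclusion, sort),
    difficult_promoters = sort(difficult_promoters),
    gc_high = sort(gc_high), reference = reference),
    class = "AnnotationTrackSet")
}

#' @export
print.AnnotationTrackSet <- function(x, ...) {
  cat("AnnotationTrackSet:\n")
  for (nm in c("gene_model", "tss", "chromatin", "dhs", "tfbs",
               "difficult_promoters", "gc_high"))
    cat(sprintf("  %-20s %d intervals\n", nm, length(x[[nm]])))
  cat(sprintf("  %-20s %s\n", "exclusion",
              paste(names(x$exclusion), collapse = ", ")))
  cat(sprintf("  %-20s %s\n", "reference",
              if (is.null(x$reference)) "absent" else
                paste(length(x$reference), "sequence(s)")))
  invisible(x)
}

## strand-aware regions within `w` bp 5' of each TSS
upstream_regions <- function(tss, w) {
  if (length(tss) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::trim(
    suppressWarnings(GenomicRanges::promoters(tss, upstream = w,
                                              downstream = 0)))
}

## strand-aware regions within `w` bp 3' of each gene end
downstream_regions <- function(gene_model, w) {
  if (length(gene_model) == 0L) return(GenomicRanges::GRanges())
  spans <- unlist(range(GenomicRanges::split(gene_model, gene_model$gene)))
  GenomicRanges::trim(
    suppressWarnings(GenomicRanges::flank(spans, width = w, start = FALSE)))
}

#' Classify variant positions relative to gene models
#'
#' Assigns each position exactly one class with precedence
#' exon > UTR5 > UTR3 > upstream > downstream > intron > intergenic.
#' "Upstream" means within `upstream_window` bp 5' of a transcription start
#' site, respecting strand; "downstream" is the mirrored window 3' of the
#' gene end. Positions on chromosomes unknown to the gene model are
#' classified intergenic with a warning.
#'
#' @param pos width-1 `GRanges` or a `data.frame` with chrom/pos columns
#' @param tracks an [annotation_tracks()] object
#' @param upstream_window,downstream_window window sizes in bp (default 1000)
#' @return character vector of classes, one per position
#' @export
classify_gene_position <- function(pos, tracks, upstream_window = 1000,
                                   downstream_window = 1000) {
  pos <- as_positions(pos)
  gm <- tracks$gene_model
  known <- unique(c(GenomeInfoDb::seqlevels(gm),
                    GenomeInfoDb::seqlevels(tracks$tss)))
  if (length(pos) &&
      !all(as.character(GenomicRanges::seqnames(pos)) %in% known))
    warning("positions on chromosomes absent from the gene model ",
            "classified as intergenic")
  res <- rep("intergenic", length(pos))
  hit <- function(track) suppressWarnings(IRanges::overlapsAny(pos, track))
  ## assign lowest precedence first so later assignments override
  sel <- function(lbl) gm[gm$label == lbl]
  res[hit(sel("intron"))] <- "intron"
  res[hit(downstream_regions(gm, downstream_window))] <- "downstream"
  res[hit(upstream_regions(tracks$tss, upstream_window))] <- "upstream"
  res[hit(sel("UTR3"))] <- "UTR3"
  res[hit(sel("UTR5"))] <- "UTR5"
  res[hit(sel("exon"))] <- "exon"
  res
}

#' Chromatin state at variant positions
#'
#' Returns the label of the covering chromatin-state interval, or `"Other"`
#' for positions in gaps of the segmentation. Interval membership follows
#' range semantics: the first and last base of an interval belong to it.
#'
#' @inheritParams classify_gene_position
#' @return character vector of state labels
#' @export
chromatin_state <- function(pos, tracks) {
  pos <- as_positions(pos)
  res <- rep("Other", length(pos))
  ol <- suppressWarnings(
    GenomicRanges::findOverlaps(pos, tracks$chromatin, select = "first"))
  hit <- !is.na(ol)
  res[hit] <- tracks$chromatin$label[ol[hit]]
  res
}

#' Count transcription factor binding sites at positions
#'
#' The number of TFBS intervals overlapping each position. The enrichment
#' analysis thresholds this count at >= 10 ("TFBS-rich" positions).
#'
#' @inheritParams classify_gene_position
#' @return non-negative integer vector
#' @export
count_tfbs <- function(pos, tracks) {
  pos <- as_positions(pos)
  suppressWarnings(GenomicRanges::countOverlaps(pos, tracks$tfbs))
}

#' High-GC windows of a reference sequence
#'
#' Tiles each chromosome into non-overlapping windows anchored at position 1
#' and returns those whose GC fraction is at least `min_gc` (inclusive: a
#' 100 bp window with exactly 75 G/C bases is returned). A trailing partial
#' window uses its actual width as denominator.
#'
#' @param reference a `DNAStringSet` named by chromosome
#' @param window tile width in bp (default 100)
#' @param min_gc GC fraction threshold (default 0.75)
#' @return `GRanges` of high-GC tiles
#' @export
gc_high_windows <- function(reference, window = 100, min_gc = 0.75) {
  out <- lapply(names(reference), function(chr) {
    sq <- reference[[chr]]
    n <- length(sq)
    if (n == 0L) return(NULL)
    starts <- seq.int(1L, n, by = window)
    ends <- pmin(starts + window - 1L, n)
    v <- Biostrings::Views(sq, start = starts, end = ends)
    gc <- rowSums(Biostrings::letterFrequency(v, c("G", "C")))
    frac <- gc / (ends - starts + 1L)
    keep <- frac >= min_gc
    if (!any(keep)) return(NULL)
    GenomicRanges::GRanges(chr, IRanges::IRanges(starts[keep], ends[keep]))
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(GenomicRanges::GRanges())
  sort(suppressWarnings(do.call(c, out)))
}

#' GC-content exclusion filter
#'
#' A variant is excluded when it lies in a 100 bp tile with at least 75% GC
#' content or inside a difficult-promoter interval. The high-GC tiles come
#' from the track set, or are computed from `reference` when supplied.
#'
#' @inheritParams classify_gene_position
#' @param reference optional `DNAStringSet`; when given, high-GC tiles are
#'   recomputed from sequence and positions beyond the sequence end are an
#'   error
#' @param window,min_gc tiling parameters (see [gc_high_windows()])
#' @return logical vector: `TRUE` when the variant is excluded
#' @export
gc_filter <- function(pos, tracks, reference = NULL, window = 100,
                      min_gc = 0.75) {
  pos <- as_positions(pos)
  if (!is.null(reference)) {
    chr <- as.character(GenomicRanges::seqnames(pos))
    bad <- chr %in% names(reference) &
      GenomicRanges::start(pos) > vapply(chr, function(c.)
        if (c. %in% names(reference)) length(reference[[c.]]) else
          .Machine$integer.max, numeric(1))
    if (any(bad))
      stop("position beyond reference sequence end: ", chr[bad][1L], ":",
           GenomicRanges::start(pos)[bad][1L])
    gc_high <- gc_high_windows(reference, window, min_gc)
  } else {
    gc_high <- tracks$gc_high
  }
  suppressWarnings(IRanges::overlapsAny(pos, gc_high) |
                     IRanges::overlapsAny(pos, tracks$difficult_promoters))
}

#' Annotate a DNV cohort
#'
#' Composes the annotators over a table of variants (case DNVs or control
#' DNVs), adding gene-position class, chromatin state, DHS overlap, TFBS
#' count and `tfbs10` flag, and the GC exclusion flag. An existing `nssnv`
#' column (precomputed nonsynonymous status) is preserved; otherwise `NA`.
#'
#' @param calls `data.frame` with at least chrom and pos columns
#' @param tracks an [annotation_tracks()] object
#' @param upstream_window upstream window for gene-position classes
#' @param tfbs_min TFBS-rich threshold (default 10, inclusive)
#' @param reference optional `DNAStringSet` for the GC filter
#' @return `calls` with annotation columns appended
#' @export
annotate_cohort <- function(calls, tracks, upstream_window = 1000,
                            tfbs_min = 10, reference = NULL) {
  pos <- as_positions(calls)
  calls$gene_class <- classify_gene_position(pos, tracks, upstream_window)
  calls$chrom_state <- chromatin_state(pos, tracks)
  calls$dhs <- suppressWarnings(IRanges::overlapsAny(pos, tracks$dhs))
  calls$tfbs_count <- count_tfbs(pos, tracks)
  calls$tfbs10 <- calls$tfbs_count >= tfbs_min
  calls$gc_excluded <- gc_filter(pos, tracks, reference = reference)
  if (!("nssnv" %in% names(calls))) calls$nssnv <- NA
  calls
}

#' Feature membership matrix for enrichment testing
#'
#' Expands an annotated cohort into the 13 feature indicators tested in the
#' enrichment analysis: five gene-position classes, two chromatin states,
#' nonsynonymous status, TFBS-rich, open chromatin, and the three composite
#' promoter features.
#'
#' @param annot annotated cohort from [annotate_cohort()]
#' @return logical matrix with one column per feature
#' @export
dnv_feature_matrix <- function(annot) {
  nssnv <- !is.na(annot$nssnv) & annot$nssnv
  prom <- annot$chrom_state == "Promoter"
  cbind(
    "UTR5" = annot$gene_class == "UTR5",
    "Upstream of gene" = annot$gene_class == "upstream",
    "Exon" = annot$gene_class == "exon",
    "Intron" = annot$gene_class == "intron",
    "Intergenic region" = annot$gene_class == "intergenic",
    "Promoter" = prom,
    "Enhancer" = annot$chrom_state == "Enhancer",
    "nsSNV" = nssnv,
    "No of TFBS >= 10" = annot$tfbs10,
    "Promoter + TFBS >= 10" = prom & annot$tfbs10,
    "DHS" = annot$dhs,
    "Promoter + DHS" = prom & annot$dhs,
    "Promoter + DHS + TFBS >= 10" = prom & annot$dhs & annot$tfbs10)
}
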