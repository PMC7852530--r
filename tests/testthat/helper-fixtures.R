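## Hand-built deterministic fixtures shared across test files.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

gr <- function(chrom, start, end, ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), ...)
}

## Two-gene track set on one 100 kb chromosome:
##   GENE001 (+): TSS 1001; UTR5 1001-1200; exons 1-3 alternating with
##                introns; UTR3 2451-2650
##   GENE002 (-): span 20001-21650 mirrored; TSS 21650
## Promoters (chromatin) around each TSS, one enhancer, DHS inside the
## first promoter plus one background site, a 12-deep TFBS stack at 950 and
## a 9-deep stack at 30100, one difficult promoter, one high-GC tile.
tiny_tracks <- function() {
  gene1 <- rbind(
    data.frame(start = 1001, end = 1200, label = "UTR5", rank = NA),
    data.frame(start = 1201, end = 1350, label = "exon", rank = 1),
    data.frame(start = 1351, end = 1750, label = "intron", rank = NA),
    data.frame(start = 1751, end = 1900, label = "exon", rank = 2),
    data.frame(start = 1901, end = 2300, label = "intron", rank = NA),
    data.frame(start = 2301, end = 2450, label = "exon", rank = 3),
    data.frame(start = 2451, end = 2650, label = "UTR3", rank = NA))
  gene2 <- rbind(
    data.frame(start = 20001, end = 20200, label = "UTR3", rank = NA),
    data.frame(start = 20201, end = 20350, label = "exon", rank = 2),
    data.frame(start = 20351, end = 20750, label = "intron", rank = NA),
    data.frame(start = 20751, end = 20900, label = "exon", rank = 1),
    data.frame(start = 20901, end = 21650, label = "UTR5", rank = NA))
  gm <- rbind(cbind(gene1, gene = "GENE001", strand = "+"),
              cbind(gene2, gene = "GENE002", strand = "-"))
  gene_model <- gr("chr1", gm$start, gm$end, strand = gm$strand,
                   label = gm$label, gene = gm$gene, exon_rank = gm$rank)
  tss <- gr("chr1", c(1001, 21650), c(1001, 21650),
            strand = c("+", "-"), gene = c("GENE001", "GENE002"))
  chromatin <- gr("chr1", c(701, 21350, 5001), c(1300, 21950, 5500),
                  label = c("Promoter", "Promoter", "Enhancer"))
  dhs <- gr("chr1", c(901, 30001), c(1100, 30200))
  tfbs <- c(gr("chr1", 950 - (0:11), 950 - (0:11) + 14),
            gr("chr1", 30100 - (0:8), 30100 - (0:8) + 14),
            gr("chr1", 5100, 5114))
  annotation_tracks(
    gene_model = gene_model, tss = tss, chromatin = chromatin,
    dhs = dhs, tfbs = tfbs,
    exclusion = list(blacklist = gr("chr1", 60001, 62000),
                     repeats = gr("chr1", 70001, 71000)),
    difficult_promoters = gr("chr1", 40001, 40600),
    gc_high = gr("chr1", 50001, 50100))
}

## One trio genotype record with overridable fields.
make_rec <- function(chrom = "chr1", pos = 1000L, ref = "A", alt = "T",
                     gt_child = "0/1", gt_father = "0/0",
                     gt_mother = "0/0", ad_child = c(12L, 10L),
                     ad_father = c(30L, 0L), ad_mother = c(30L, 0L),
                     gq = c(50, 60, 55)) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             var_class = ifelse(nchar(ref) == 1 & nchar(alt) == 1,
                                "SNV", "INDEL"),
             gt_child = gt_child, gt_father = gt_father,
             gt_mother = gt_mother,
             ad_child_ref = ad_child[1], ad_child_alt = ad_child[2],
             ad_father_ref = ad_father[1], ad_father_alt = ad_father[2],
             ad_mother_ref = ad_mother[1], ad_mother_alt = ad_mother[2],
             gq_child = gq[1], gq_father = gq[2], gq_mother = gq[3],
             stringsAsFactors = FALSE)
}

## Small synthetic-cohort configuration for fast tests.
small_cfg <- function(seed = 1L, n_trios = 4L, ...) {
  synth_config(seed = seed, n_trios = n_trios, control_n = 1000L,
               chrom_lengths = c(chr1 = 300000L, chr2 = 300000L),
               n_genes = 12L, ...)
}

## One-row pedigree used by VCF reader tests.
tiny_ped <- function(child = "C001", father = "F001", mother = "M001") {
  data.frame(family_id = "FAM001", child_id = child, father_id = father,
             mother_id = mother, child_sex = "F", father_age = 32,
             mother_age = 30, stringsAsFactors = FALSE)
}

## Printed enrichment-table counts used by acceptance and rendering tests:
## feature label, case count (of 4157), control count (of 97942).
table1_counts <- function() {
  data.frame(
    feature = c("UTR5", "Upstream of gene", "Exon", "Intron",
                "Intergenic region", "Promoter", "Enhancer", "nsSNV",
                "No of TFBS >= 10", "Promoter + TFBS >= 10", "DHS",
                "Promoter + DHS", "Promoter + DHS + TFBS >= 10"),
    a = c(11, 32, 69, 1543, 2197, 87, 210, 51, 39, 21, 109, 46, 20),
    b = c(165, 536, 1535, 36426, 51674, 1442, 4724, 1122, 573, 254,
          2194, 599, 235),
    stringsAsFactors = FALSE)
}
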