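tr <- tiny_tracks()

pos_df <- function(pos) data.frame(chrom = "chr1", pos = pos)

test_that("gene-position classes follow the precedence convention", {
  expect_equal(
    classify_gene_position(pos_df(c(1250, 1100, 2500, 1500, 9000, 501)),
                           tr),
    c("exon", "UTR5", "UTR3", "intron", "intergenic", "upstream"))
})

test_that("upstream and downstream windows respect strand", {
  ## GENE002 is on the minus strand with TSS at 21650: its upstream window
  ## is 21651..22650, its downstream window 19001..20000
  expect_equal(classify_gene_position(pos_df(21700), tr), "upstream")
  expect_equal(classify_gene_position(pos_df(19500), tr), "downstream")
  ## GENE001 (+): upstream 1..1000, downstream 2651..3650
  expect_equal(classify_gene_position(pos_df(600), tr), "upstream")
  expect_equal(classify_gene_position(pos_df(3000), tr), "downstream")
  ## the window is configurable
  expect_equal(classify_gene_position(pos_df(600), tr,
                                      upstream_window = 100), "intergenic")
})

test_that("unknown chromosomes classify intergenic with a warning", {
  expect_warning(
    cls <- classify_gene_position(data.frame(chrom = "chrUn", pos = 100), tr),
    "intergenic")
  expect_equal(cls, "intergenic")
})

test_that("chromatin state covers interval ends and defaults to Other", {
  expect_equal(chromatin_state(pos_df(c(701, 1300, 1301, 5200, 9999)), tr),
               c("Promoter", "Promoter", "Other", "Enhancer", "Other"))
})

test_that("TFBS counts are positional and the rich flag is >= 10", {
  expect_equal(count_tfbs(pos_df(c(950, 30100, 80000)), tr), c(12L, 9L, 0L))
  ann <- annotate_cohort(pos_df(c(950, 30100)), tr)
  expect_equal(ann$tfbs10, c(TRUE, FALSE))
  empty <- annotation_tracks(gene_model = tr$gene_model, tss = tr$tss)
  expect_equal(count_tfbs(pos_df(950), empty), 0L)
})

test_that("GC filter excludes >= 75% tiles and difficult promoters", {
  ## chromosome of three 100 bp tiles: 50% GC, exactly 75% GC, 80% GC
  tile <- function(gc) paste(c(rep("G", gc), rep("A", 100 - gc)),
                             collapse = "")
  ref <- Biostrings::DNAStringSet(setNames(
    paste0(tile(50), tile(75), tile(80)), "chr9"))
  gw <- gc_high_windows(ref)
  expect_equal(GenomicRanges::start(gw), c(101L, 201L))

  tracks <- annotation_tracks(gc_high = gw)
  expect_equal(gc_filter(data.frame(chrom = "chr9", pos = c(50, 150, 250)),
                         tracks, reference = ref),
               c(FALSE, TRUE, TRUE))
  expect_error(gc_filter(data.frame(chrom = "chr9", pos = 350), tracks,
                         reference = ref), "beyond")

  ## difficult promoters are excluded regardless of GC
  expect_true(gc_filter(pos_df(40100), tr))
  expect_true(gc_filter(pos_df(50050), tr))
  expect_false(gc_filter(pos_df(45000), tr))
})

test_that("annotation matches the synthetic generator's ground-truth ledger", {
  cfg <- small_cfg(seed = 21)
  tracks <- simulate_tracks(cfg)
  co <- simulate_trio_cohort(cfg, tracks)
  led <- co$ledger
  ann <- annotate_cohort(led[, c("chrom", "pos")], tracks)
  expect_equal(ann$chrom_state == "Promoter", led$promoter)
  expect_equal(ann$chrom_state == "Enhancer", led$enhancer)
  expect_equal(ann$dhs, led$dhs)
  expect_equal(ann$tfbs10, led$tfbs10)
  expect_equal(ann$gc_excluded, led$gc_excluded)
  expect_equal(ann$gene_class == "exon", led$exon)
  expect_equal(ann$gene_class == "UTR5", led$utr5 & !led$exon)
})

test_that("gene-position classes partition any cohort", {
  cfg <- small_cfg(seed = 22)
  tracks <- simulate_tracks(cfg)
  ctl <- simulate_control_set(cfg, tracks, n = 500)
  ann <- annotate_cohort(ctl, tracks)
  expect_equal(sum(table(ann$gene_class)), nrow(ann))
  expect_true(all(ann$gene_class %in%
                    c("exon", "UTR5", "UTR3", "upstream", "downstream",
                      "intron", "intergenic")))
})

test_that("annotation is position-deterministic under permutation", {
  cfg <- small_cfg(seed = 23)
  tracks <- simulate_tracks(cfg)
  ctl <- simulate_control_set(cfg, tracks, n = 200)
  ann <- annotate_cohort(ctl, tracks)
  perm <- sample(nrow(ctl))
  ann_perm <- annotate_cohort(ctl[perm, ], tracks)
  rownames(ann_perm) <- NULL
  reord <- ann[perm, ]; rownames(reord) <- NULL
  expect_equal(ann_perm, reord)
})

test_that("the feature matrix encodes the 13 tested features", {
  ## 950 sits in the promoter, inside the DHS, under the 12-site TFBS
  ## stack; 2350 is in exon 3, outside the promoter state
  ann <- annotate_cohort(pos_df(c(950, 2350)), tr)
  ann$nssnv <- c(FALSE, TRUE)
  fm <- dnv_feature_matrix(ann)
  expect_equal(ncol(fm), 13L)
  expect_true(all(fm[1, c("Promoter", "DHS", "No of TFBS >= 10",
                          "Promoter + DHS",
                          "Promoter + DHS + TFBS >= 10")]))
  expect_true(fm[2, "Exon"] && fm[2, "nsSNV"] && !fm[2, "Promoter"])
})
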