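iv <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = start, end = end)
}

sv_call <- function(start, end, svtype = "DEL", caller = "callerA",
                    sample = "C001", status = "called", chrom = "chr1") {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(end), svtype = svtype,
             length = as.integer(end - start + 1), caller = caller,
             sample = sample, status = status, stringsAsFactors = FALSE)
}

test_that("reciprocal overlap is exact and symmetric", {
  ## [100,200) vs [150,250) half-open is [101,200] / [151,250] closed
  expect_equal(reciprocal_overlap(iv("chr1", 101, 200), iv("chr1", 151, 250)),
               c(0.5, 0.5))
  expect_equal(reciprocal_overlap(iv("chr1", 101, 200), iv("chr1", 101, 200)),
               c(1, 1))
  expect_equal(reciprocal_overlap(iv("chr1", 101, 200), iv("chr1", 500, 600)),
               c(0, 0))
  expect_error(reciprocal_overlap(iv("chr1", 100, 99), iv("chr1", 1, 10)),
               "zero-length")
  expect_error(reciprocal_overlap(iv("chr1", 1, 10), iv("chr2", 1, 10)),
               "chromosomes")
  set.seed(7)
  for (i in 1:20) {
    x <- sort(sample(1:1000, 2)); y <- sort(sample(1:1000, 2))
    ro_xy <- reciprocal_overlap(iv("chr1", x[1], x[2] + 1),
                                iv("chr1", y[1], y[2] + 1))
    ro_yx <- reciprocal_overlap(iv("chr1", y[1], y[2] + 1),
                                iv("chr1", x[1], x[2] + 1))
    expect_equal(ro_xy, rev(ro_yx))
  }
})

test_that("caller intersection pairs same-type calls at 50% reciprocal overlap", {
  a <- sv_call(1001, 2000)
  b <- sv_call(1101, 2100, caller = "callerB")
  ic <- intersect_callers(a, b)
  expect_equal(nrow(ic$consensus), 1L)
  expect_equal(ic$consensus$start, 1001L)      # caller-A coordinates kept
  expect_equal(ic$consensus$b_start, 1101L)

  ## type mismatch at the same locus never matches
  ic2 <- intersect_callers(a, sv_call(1001, 2000, svtype = "DUP",
                                      caller = "callerB"))
  expect_equal(nrow(ic2$consensus), 0L)
  expect_equal(nrow(ic2$unmatched_a), 1L)

  ## SVs of 10 bp or shorter are outside the de novo SV analysis
  short <- sv_call(5001, 5010)
  expect_equal(nrow(intersect_callers(short, short)$consensus), 0L)
  just <- sv_call(5001, 5011)
  expect_equal(nrow(intersect_callers(just, just)$consensus), 1L)
})

test_that("greedy pairing keeps the higher-overlap pair and uses calls once", {
  a <- rbind(sv_call(1001, 2000), sv_call(1201, 2200))
  b <- sv_call(1051, 2050, caller = "callerB")
  ic <- intersect_callers(a, b)
  expect_equal(nrow(ic$consensus), 1L)
  expect_equal(ic$consensus$start, 1001L)      # RO 0.95 beats 0.85
  expect_equal(ic$unmatched_a$start, 1201L)

  ## brute-force audit on random <= 5-call fixtures: every chosen pair is
  ## at least as good as any alternative pairing of its members
  set.seed(8)
  for (rep in 1:10) {
    na <- sample(1:5, 1); nb <- sample(1:5, 1)
    a <- do.call(rbind, lapply(seq_len(na), function(i) {
      s <- sample(1000:5000, 1); sv_call(s, s + sample(500:1500, 1))
    }))
    b <- do.call(rbind, lapply(seq_len(nb), function(i) {
      s <- sample(1000:5000, 1)
      sv_call(s, s + sample(500:1500, 1), caller = "callerB")
    }))
    ic <- intersect_callers(a, b)
    cons <- ic$consensus
    ## validity: RO >= 0.5 both ways, types equal, each member used once
    if (nrow(cons)) {
      expect_true(all(cons$ro_a >= 0.5 & cons$ro_b >= 0.5))
      expect_false(any(duplicated(cons$start)))
      expect_false(any(duplicated(cons$b_start)))
    }
    ## monotone: consensus never larger than either input
    expect_lte(nrow(cons), min(nrow(a), nrow(b)))
  }
})

test_that("parental subtraction removes calls seen in parents, even candidates", {
  cand <- sv_call(10001, 12000)
  par_hit <- sv_call(10101, 12100, sample = "F001", status = "candidate")
  out <- subtract_parental(cand, par_hit)
  expect_false(out$pass_parental)

  out2 <- subtract_parental(cand, sv_call(50001, 52000, sample = "F001"))
  expect_true(out2$pass_parental)

  ## same locus but different type does not subtract
  out3 <- subtract_parental(cand, sv_call(10001, 12000, svtype = "DUP",
                                          sample = "F001"))
  expect_true(out3$pass_parental)
  expect_true(subtract_parental(cand, NULL)$pass_parental)
})

test_that("annotation exclusion thresholds the covered fraction", {
  excl <- list(blacklist = gr("chr1", 10001, 11800))   # 90% of the SV
  out <- annotation_exclusion(sv_call(10001, 12000), excl)
  expect_false(out$pass_annotation)
  expect_equal(out$exclusion_frac, 0.9)

  excl2 <- list(repeats = gr("chr1", 10001, 10200))    # 10%
  expect_true(annotation_exclusion(sv_call(10001, 12000),
                                   excl2)$pass_annotation)
  ## phi = 0: any overlap removes
  expect_false(annotation_exclusion(sv_call(10001, 12000), excl2,
                                    phi = 0)$pass_annotation)
})

test_that("coverage filter separates de novo dips from trio-shared patterns", {
  mk_cov <- function(child_mult, parent_mult) {
    bins <- seq(1L, 10001L, by = 100L)
    inside <- bins >= 3001 & bins <= 7000
    set.seed(9)
    depth <- function(mult) {
      d <- 30 + rnorm(length(bins), 0, 1)
      d[inside] <- d[inside] * mult
      d
    }
    rbind(data.frame(sample = "C001", chrom = "chr1", bin_start = bins,
                     depth = depth(child_mult)),
          data.frame(sample = "F001", chrom = "chr1", bin_start = bins,
                     depth = depth(parent_mult)),
          data.frame(sample = "M001", chrom = "chr1", bin_start = bins,
                     depth = depth(parent_mult)))
  }
  cand <- sv_call(3001, 7000)
  ## heterozygous de novo deletion: child dips, parents flat
  out <- coverage_similarity_filter(cand, mk_cov(0.5, 1), "F001", "M001")
  expect_true(out$pass_coverage)
  ## shared artefact: everyone dips identically
  out2 <- coverage_similarity_filter(cand, mk_cov(0.5, 0.5), "F001", "M001")
  expect_false(out2$pass_coverage)
  expect_gte(max(out2$cor_father, out2$cor_mother), 0.9)

  ## strictly constant profiles leave the similarity undefined: keep + warn
  const <- mk_cov(1, 1)
  const$depth <- 30
  expect_warning(
    out3 <- coverage_similarity_filter(cand, const, "F001", "M001"),
    "constant")
  expect_true(out3$pass_coverage)
})

test_that("the SV pipeline is monotone and attributes every removal", {
  cfg <- small_cfg(seed = 51)
  tracks <- simulate_tracks(cfg)
  svd <- simulate_sv_data(cfg, tracks)
  res <- run_sv_pipeline(
    svd$callsets$child_a, svd$callsets$child_b,
    parental = rbind(svd$callsets$father, svd$callsets$mother),
    exclusion = tracks$exclusion, coverage = svd$coverage,
    father_id = "F001", mother_id = "M001")
  ## monotone filtering: final within consensus within caller A
  key_a <- paste(svd$callsets$child_a$chrom, svd$callsets$child_a$start)
  expect_true(all(paste(res$final$chrom, res$final$start) %in% key_a))
  ## each audited call fails exactly one stage (or passes)
  expect_true(all(res$audit$stage_failed %in%
                    c("pass", "consensus", "parental", "annotation",
                      "coverage")))
  expect_equal(sum(res$audit$stage_failed == "pass"), nrow(res$final))
})

test_that("structural variants are described by the exon range they remove", {
  gene <- gr("chr1",
             start = c(1000, 2000, 3000, 4000, 5000, 6000, 7000, 8000),
             end = c(1100, 2100, 3100, 4100, 5100, 6100, 7100, 8100),
             label = "exon", gene = "GENE001", exon_rank = 1:8)
  sv <- sv_call(2900, 7200)
  expect_equal(sv_exon_annotation(sv, gene),
               "deletion of exons 3-7 (GENE001)")
  expect_equal(sv_exon_annotation(sv_call(2900, 3200), gene),
               "deletion of exon 3 (GENE001)")
  expect_equal(sv_exon_annotation(sv_call(2900, 7200, svtype = "DUP"), gene),
               "duplication of exons 3-7 (GENE001)")
  expect_true(is.na(sv_exon_annotation(sv_call(100, 200), gene)))
})
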