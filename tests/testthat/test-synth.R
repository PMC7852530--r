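test_that("generators are fully deterministic under a fixed seed", {
  cfg <- small_cfg(seed = 61, n_trios = 3)
  t1 <- simulate_tracks(cfg); t2 <- simulate_tracks(cfg)
  expect_identical(t1$gene_model, t2$gene_model)
  expect_identical(t1$chromatin, t2$chromatin)
  expect_identical(t1$gc_high, t2$gc_high)
  expect_identical(as.character(t1$reference), as.character(t2$reference))
  c1 <- simulate_trio_cohort(cfg, t1)
  c2 <- simulate_trio_cohort(cfg, t2)
  expect_identical(c1$records, c2$records)
  expect_identical(c1$evidence, c2$evidence)
  expect_identical(c1$ledger, c2$ledger)
  expect_identical(simulate_control_set(cfg, t1, n = 300),
                   simulate_control_set(cfg, t2, n = 300))
  s1 <- simulate_sv_data(cfg, t1); s2 <- simulate_sv_data(cfg, t2)
  expect_identical(s1$callsets, s2$callsets)
  expect_identical(s1$coverage, s2$coverage)
})

test_that("track construction validates geometry", {
  cfg <- synth_config(seed = 1, chrom_lengths = c(chr1 = 1000L),
                      n_genes = 10L)
  expect_error(simulate_tracks(cfg), "genome too small")
  expect_error(synth_config(multipliers = list(promoter = -1)), "positive")
  expect_error(synth_config(multipliers = list(bogus = 2)), "unknown")
  expect_error(synth_config(paternal_fraction = 1.2), "\\[0, 1\\]")
})

test_that("every TSS has a promoter state and the GC track matches the sequence", {
  cfg <- small_cfg(seed = 62)
  tracks <- simulate_tracks(cfg)
  prom <- tracks$chromatin[tracks$chromatin$label == "Promoter"]
  expect_equal(length(prom), length(tracks$tss))
  expect_true(all(IRanges::overlapsAny(tracks$tss, prom)))
  ## the emitted reference realizes the GC-rich tiles exactly
  expect_identical(as.data.frame(gc_high_windows(tracks$reference)),
                   as.data.frame(tracks$gc_high))
})

test_that("cohort size and age structure follow the configured rates", {
  cfg <- small_cfg(seed = 63, n_trios = 50, lambda0 = 10, beta_father = 0,
                   informative_prob = 0)
  tracks <- simulate_tracks(cfg)
  co <- simulate_trio_cohort(cfg, tracks)
  expect_equal(nrow(co$pedigree), 50L)
  counts <- table(factor(co$ledger$child_id,
                         levels = co$pedigree$child_id))
  ## Poisson(10) mean over 50 trios: sampling error ~0.45
  expect_gt(mean(counts), 8.5)
  expect_lt(mean(counts), 11.5)
  expect_true(all(co$pedigree$father_age >= 20 &
                    co$pedigree$father_age <= 45))
  expect_true(all(co$pedigree$mother_age >= 18))
})

test_that("the control set has the requested size and baseline placement", {
  cfg <- small_cfg(seed = 64)
  tracks <- simulate_tracks(cfg)
  ctl <- simulate_control_set(cfg, tracks, n = 2000)
  expect_equal(nrow(ctl), 2000L)
  ## reference-consistent alleles
  ref <- tracks$reference
  idx <- sample(nrow(ctl), 50)
  bases <- vapply(idx, function(i)
    as.character(Biostrings::subseq(ref[[ctl$chrom[i]]], ctl$pos[i],
                                    ctl$pos[i])), character(1))
  expect_equal(bases, ctl$ref[idx])
  expect_true(all(ctl$alt != ctl$ref))
})

test_that("planted DNV fates audit against the pipeline exactly", {
  cfg <- small_cfg(seed = 65, n_trios = 6)
  tracks <- simulate_tracks(cfg)
  co <- simulate_trio_cohort(cfg, tracks)
  calls <- do.call(rbind, lapply(co$pedigree$child_id, function(ch)
    apply_dnv_filters(detect_candidates(co$records[[ch]], child_id = ch))))
  key <- function(d) paste(d$child_id, d$chrom, d$pos)
  led <- co$ledger
  m <- match(key(led), key(calls))
  fate <- ifelse(is.na(m), "undetected",
          ifelse(calls$accepted[m], "accepted",
          ifelse(!calls$pass_quality[m], "filtered_quality",
                 "filtered_ab")))
  expect_equal(fate, led$expected_fate)
  ## candidates are exactly the planted set (noise-free genotypes)
  cand <- calls[calls$status == "candidate", ]
  expect_true(setequal(key(cand), key(led)))
})

test_that("genotype errors make planted DNVs undetectable, as recorded", {
  cfg <- small_cfg(seed = 66, n_trios = 6, genotype_error = 0.3)
  tracks <- simulate_tracks(cfg)
  co <- simulate_trio_cohort(cfg, tracks)
  expect_gt(sum(co$ledger$expected_fate == "undetected"), 0)
  calls <- do.call(rbind, lapply(co$pedigree$child_id, function(ch) {
    out <- detect_candidates(co$records[[ch]], child_id = ch)
    out[out$status == "candidate", ]
  }))
  key <- function(d) paste(d$child_id, d$chrom, d$pos)
  led_det <- co$ledger[co$ledger$expected_fate != "undetected", ]
  expect_true(setequal(key(calls), key(led_det)))
})

test_that("SV simulation plants consensus-compatible true events", {
  cfg <- small_cfg(seed = 67)
  tracks <- simulate_tracks(cfg)
  svd <- simulate_sv_data(cfg, tracks)
  led <- svd$ledger
  true_sv <- led[led$category == "true_denovo", ]
  a <- svd$callsets$child_a
  b <- svd$callsets$child_b
  for (i in seq_len(nrow(true_sv))) {
    ia <- which(a$start == true_sv$start[i] & a$chrom == true_sv$chrom[i])
    expect_length(ia, 1L)
    ## the jittered caller-B twin still matches at 50% reciprocal overlap
    ib <- which(b$svtype == a$svtype[ia] & b$chrom == a$chrom[ia] &
                  abs(b$start - a$start[ia]) < a$length[ia])
    expect_length(ib, 1L)
    ro <- reciprocal_overlap(a[ia, ], b[ib, ])
    expect_true(all(ro >= 0.5))
  }
  ## single-caller decoys never appear in the caller-B set
  single <- led[led$category == "single_caller", ]
  expect_false(any(paste(single$chrom, single$start) %in%
                     paste(b$chrom, b$start)))
})

test_that("written cohorts read back identically through the io layer", {
  cfg <- small_cfg(seed = 68, n_trios = 2)
  tracks <- simulate_tracks(cfg)
  co <- simulate_trio_cohort(cfg, tracks)
  dir <- withr::local_tempdir()
  write_cohort(co, dir, chrom_lengths = cfg$chrom_lengths)
  ped <- read_pedigree(file.path(dir, "pedigree.tsv"))
  expect_equal(ped, co$pedigree)
  for (i in seq_len(nrow(ped))) {
    back <- read_trio_vcf(file.path(dir, paste0(ped$family_id[i], ".vcf")),
                          ped[i, ])
    orig <- co$records[[ped$child_id[i]]]
    orig <- orig[order(orig$chrom, orig$pos), ]
    rownames(orig) <- NULL
    expect_equal(back, orig)
  }
  ev <- read_read_evidence(file.path(dir, "evidence.tsv"))
  ev0 <- co$evidence[order(co$evidence$read_id, co$evidence$pos), ]
  rownames(ev0) <- NULL
  expect_equal(ev, ev0)
})
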