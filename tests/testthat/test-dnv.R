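test_that("candidate detection matches an exhaustive genotype-pattern oracle", {
  ## all 27 trio genotype combinations; the oracle classifies each from
  ## first principles on allele sets, independent of the implementation
  gts <- c("0/0", "0/1", "1/1")
  grid <- expand.grid(child = gts, father = gts, mother = gts,
                      stringsAsFactors = FALSE)
  recs <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    make_rec(pos = 1000L + i, gt_child = grid$child[i],
             gt_father = grid$father[i], gt_mother = grid$mother[i])))
  oracle <- vapply(seq_len(nrow(grid)), function(i) {
    child_has_alt <- grid$child[i] %in% c("0/1", "1/1")
    parents_lack_alt <- grid$father[i] == "0/0" && grid$mother[i] == "0/0"
    if (!child_has_alt || !parents_lack_alt) return("none")
    if (grid$child[i] == "0/1") "candidate" else "flagged"
  }, character(1))

  calls <- detect_candidates(recs, child_id = "C001")
  got <- setNames(rep("none", nrow(grid)), recs$pos)
  got[as.character(calls$pos)] <- calls$status
  expect_equal(unname(got), oracle)
  tally <- attr(calls, "tally")
  expect_equal(unname(tally["candidate"]), sum(oracle == "candidate"))
  expect_equal(unname(tally["flagged"]), sum(oracle == "flagged"))

  ## flagged patterns become candidates only when asked for
  calls2 <- detect_candidates(recs, child_id = "C001", emit_flagged = TRUE)
  expect_true(all(calls2$status == "candidate"))
})

test_that("sites with missing parental genotypes are skipped and tallied", {
  recs <- rbind(make_rec(pos = 1000L),
                make_rec(pos = 2000L, gt_father = NA),
                make_rec(pos = 3000L, gt_mother = "./."))
  calls <- detect_candidates(recs, child_id = "C001")
  expect_equal(calls$pos, 1000L)
  expect_equal(unname(attr(calls, "tally")["missing"]), 2L)
})

test_that("genotype posterior filter uses the trio minimum at Q20", {
  calls <- rbind(make_rec(gq = c(45, 60, 50)),
                 make_rec(gq = c(19, 60, 50)),
                 make_rec(gq = c(20, 21, 99)),
                 make_rec(gq = c(50, NA, 50)))
  out <- filter_quality(calls)
  expect_equal(out$pass_quality, c(TRUE, FALSE, TRUE, FALSE))
  expect_true(all(filter_quality(calls, min_posterior = 0)$pass_quality[1:3]))
})

test_that("allele-balance filter is inclusive at 30% and 70%", {
  calls <- rbind(make_rec(ad_child = c(12L, 10L)),   # 0.4545
                 make_rec(ad_child = c(28L, 2L)),    # 0.0667
                 make_rec(ad_child = c(7L, 3L)),     # exactly 0.30
                 make_rec(ad_child = c(3L, 7L)),     # exactly 0.70
                 make_rec(ad_child = c(0L, 0L)))     # no reads
  calls$ab <- with(calls, ifelse(ad_child_ref + ad_child_alt > 0,
                                 ad_child_alt / (ad_child_ref + ad_child_alt),
                                 NA_real_))
  out <- filter_allele_balance(calls)
  expect_equal(out$pass_ab, c(TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(out$ab_reason[5], "zero_depth")
  expect_equal(out$ab_reason[2], "out_of_range")
  expect_equal(round(out$ab[1], 4), 0.4545)
})

test_that("external score filter thresholds at 0.5 and passes unscored calls", {
  calls <- rbind(make_rec(pos = 1L), make_rec(pos = 2L), make_rec(pos = 3L))
  scores <- data.frame(chrom = "chr1", pos = c(1L, 2L), ref = "A",
                       alt = "T", score = c(0.93, 0.49),
                       stringsAsFactors = FALSE)
  out <- filter_score(calls, scores)
  expect_equal(out$pass_score, c(TRUE, FALSE, TRUE))
  expect_true(all(filter_score(calls, NULL)$pass_score))
  bad <- scores; bad$score[1] <- 1.2
  expect_error(filter_score(calls, bad), "\\[0, 1\\]")
})

test_that("filters are order-independent", {
  set.seed(42)
  calls <- do.call(rbind, lapply(1:50, function(i) {
    ad <- c(sample(0:30, 1), sample(0:30, 1))
    make_rec(pos = i, ad_child = ad,
             gq = sample(5:99, 3, replace = TRUE))
  }))
  calls$ab <- with(calls, ifelse(ad_child_ref + ad_child_alt > 0,
                                 ad_child_alt / (ad_child_ref + ad_child_alt),
                                 NA_real_))
  calls$status <- "candidate"
  scores <- data.frame(chrom = "chr1", pos = 1:50, ref = "A", alt = "T",
                       score = runif(50), stringsAsFactors = FALSE)
  filters <- list(
    q = function(x) filter_quality(x),
    ab = function(x) filter_allele_balance(x),
    s = function(x) filter_score(x, scores))
  accept <- function(x) x$pass_quality & x$pass_ab & x$pass_score
  ref_order <- accept(filters$s(filters$ab(filters$q(calls))))
  for (perm in list(c(1, 3, 2), c(2, 1, 3), c(3, 2, 1))) {
    out <- calls
    for (k in perm) out <- filters[[k]](out)
    expect_equal(accept(out), ref_order)
  }
})

test_that("per-patient summary reports rounded mean and range", {
  ped <- data.frame(family_id = paste0("F", 1:3),
                    child_id = c("A", "B", "C"),
                    father_id = paste0("fa", 1:3),
                    mother_id = paste0("mo", 1:3),
                    child_sex = "F", father_age = 30, mother_age = 28,
                    stringsAsFactors = FALSE)
  calls <- data.frame(child_id = c(rep("A", 40), rep("B", 91)))
  s <- per_patient_summary(calls, ped)
  expect_equal(s$total, 131L)
  expect_equal(s$min, 0L)   # child C has no calls but counts
  expect_equal(s$max, 91L)
  expect_equal(s$mean_reported, round_half_up(131 / 3))
  expect_error(per_patient_summary(calls, ped[0, ]), "empty cohort")
})

test_that("validation FDR is the failing fraction in percent", {
  expect_equal(validation_fdr(99, 98)$fdr_reported, 1)
  expect_equal(validation_fdr(71, 56)$fdr_reported, 21)
  expect_equal(validation_fdr(50, 50)$fdr_reported, 0)
  expect_equal(round(validation_fdr(71, 56)$fdr, 2), 21.13)
  expect_error(validation_fdr(0, 0), "positive")
  expect_error(validation_fdr(10, 11), "confirmed")
})
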