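## an informative site 120 bp from a DNV at 1000, with father 1/1 and
## mother 0/0: the alternate allele "G" marks the paternal haplotype
phase_fixture <- function() {
  recs <- rbind(
    make_rec(pos = 1000L),                                    # the DNV
    make_rec(pos = 1120L, ref = "A", alt = "G",
             gt_father = "1/1", gt_mother = "0/0",
             ad_father = c(0L, 30L)))
  dnv <- detect_candidates(recs, child_id = "C001")
  list(recs = recs, dnv = dnv[dnv$status == "candidate", ])
}

ev_row <- function(rid, pos, allele, sample = "C001") {
  data.frame(read_id = rid, sample_id = sample, pos = pos, allele = allele,
             stringsAsFactors = FALSE)
}

test_that("informative sites require exactly one consistent assignment", {
  dnv <- data.frame(chrom = "chr1", pos = 1000L)
  pattern <- function(f, m, child = "0/1") {
    recs <- make_rec(pos = 1150L, ref = "A", alt = "G", gt_child = child,
                     gt_father = f, gt_mother = m)
    find_informative_snvs(dnv, recs)
  }
  expect_equal(pattern("1/1", "0/0")$alt_parent, "father")
  expect_equal(pattern("0/1", "0/0")$alt_parent, "father")
  expect_equal(pattern("0/0", "1/1")$alt_parent, "mother")
  expect_equal(pattern("0/0", "0/1")$alt_parent, "mother")
  ## father 0/1, mother 1/1: the child's ref allele must be paternal, so
  ## the alt is maternal
  expect_equal(pattern("0/1", "1/1")$alt_parent, "mother")
  expect_equal(nrow(pattern("0/1", "0/1")), 0L)  # both het: ambiguous
  expect_equal(nrow(pattern("0/0", "0/0")), 0L)  # itself a violation
  expect_equal(nrow(pattern("1/1", "1/1")), 0L)  # child cannot be het
  expect_equal(nrow(pattern("1/1", "0/0", child = "0/0")), 0L)
  ## sites outside the window are not returned
  far <- make_rec(pos = 2000L, ref = "A", alt = "G", gt_father = "1/1",
                  gt_mother = "0/0")
  expect_equal(nrow(find_informative_snvs(dnv, far, window = 500)), 0L)
})

test_that("origin assignment follows the >=2-concordant-reads rule exactly", {
  fx <- phase_fixture()
  inf <- find_informative_snvs(fx$dnv, fx$recs)
  ## exhaustively enumerate vote patterns up to 4 reads per parent; the
  ## oracle is the stated rule: >= 2 votes for one parent and none for the
  ## other
  for (np in 0:4) for (nm in 0:4) {
    ev <- list()
    for (r in seq_len(np))
      ev[[length(ev) + 1L]] <- rbind(
        ev_row(sprintf("p%d", r), 1000L, "T"),
        ev_row(sprintf("p%d", r), 1120L, "G"))   # paternal allele
    for (r in seq_len(nm))
      ev[[length(ev) + 1L]] <- rbind(
        ev_row(sprintf("m%d", r), 1000L, "T"),
        ev_row(sprintf("m%d", r), 1120L, "A"))   # maternal allele
    evidence <- if (length(ev)) do.call(rbind, ev) else
      data.frame(read_id = character(0), sample_id = character(0),
                 pos = integer(0), allele = character(0))
    got <- assign_origin(fx$dnv, inf, evidence)
    want <- if (np >= 2 && nm == 0) "paternal" else
      if (nm >= 2 && np == 0) "maternal" else "unassigned"
    expect_equal(got$origin, want)
    expect_equal(got$paternal_reads, np)
    expect_equal(got$maternal_reads, nm)
  }
})

test_that("reads that skip the DNV or conflict internally cast no vote", {
  fx <- phase_fixture()
  inf <- find_informative_snvs(fx$dnv, fx$recs)
  ## read carries the reference allele at the DNV: not a carrier read
  ev <- rbind(ev_row("r1", 1000L, "A"), ev_row("r1", 1120L, "G"),
              ev_row("r2", 1000L, "T"), ev_row("r2", 1120L, "G"))
  got <- assign_origin(fx$dnv, inf, ev)
  expect_equal(got$paternal_reads, 1L)
  expect_equal(got$origin, "unassigned")

  ## two informative sites that disagree within one read
  recs2 <- rbind(fx$recs,
                 make_rec(pos = 900L, ref = "C", alt = "T",
                          gt_father = "0/0", gt_mother = "1/1",
                          ad_mother = c(0L, 30L)))
  inf2 <- find_informative_snvs(fx$dnv, recs2)
  ev2 <- rbind(ev_row("r1", 900L, "T"),    # maternal alt
               ev_row("r1", 1000L, "T"),
               ev_row("r1", 1120L, "G"))   # paternal alt: conflict
  got2 <- assign_origin(fx$dnv, inf2, ev2)
  expect_equal(got2$origin, "unassigned")
  expect_equal(got2$paternal_reads + got2$maternal_reads, 0L)
})

test_that("origin summary reports counts and the paternal:maternal ratio", {
  phased <- data.frame(origin = c(rep("paternal", 269),
                                  rep("maternal", 73),
                                  rep("unassigned", 10)))
  s <- origin_summary(phased)
  expect_equal(s$paternal, 269L)
  expect_equal(s$maternal, 73L)
  expect_equal(round(s$ratio, 2), 3.68)
  s0 <- origin_summary(data.frame(origin = "unassigned"))
  expect_equal(s0$paternal, 0L)
  expect_equal(s0$ratio, Inf)
})

test_that("phasing a synthetic cohort reproduces the planted origins exactly", {
  cfg <- small_cfg(seed = 41)
  tracks <- simulate_tracks(cfg)
  co <- simulate_trio_cohort(cfg, tracks)
  calls <- do.call(rbind, lapply(co$pedigree$child_id, function(ch)
    apply_dnv_filters(detect_candidates(co$records[[ch]], child_id = ch))))
  acc <- calls[calls$accepted, ]
  phased <- phase_cohort(acc, co$records, co$evidence)
  led <- co$ledger
  key <- function(d) paste(d$child_id, d$chrom, d$pos)
  m <- match(key(phased), key(led))
  assigned <- phased$origin != "unassigned"
  ## no disagreement with planted truth, ever
  expect_true(all(phased$origin[assigned] == led$origin[m][assigned]))
  ## assigned exactly when evidence permits: informative site + >= 2 reads
  expect_equal(assigned, led$informative[m] & led$votes[m] >= 2)
  ## and never on fewer than 2 concordant reads
  expect_true(all(pmax(phased$paternal_reads,
                       phased$maternal_reads)[assigned] >= 2))
})

test_that("age regression recovers exact linear relationships", {
  ages <- c(22, 28, 31, 35, 40, 44)
  ## an exactly linear relationship trips R's perfect-fit note in summary()
  fit <- suppressWarnings(age_regression(10 + 2 * ages, ages))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 10)
  expect_equal(fit$r, 1)
  set.seed(5)
  flat <- age_regression(rpois(30, 50), seq(20, 49))
  expect_lt(abs(flat$slope), 1)
  expect_gt(flat$p, 0.001)
  expect_error(age_regression(c(1, 2, 3), rep(30, 3)), "degenerate")
  expect_error(age_regression(c(1, 2), c(30, 40)), "at least 3")
})

test_that("marginal and conditional slopes agree on orthogonal designs", {
  father <- c(30, 40, 30, 40, 30, 40, 30, 40)
  mother <- c(20, 20, 30, 30, 20, 20, 30, 30)   # zero sample covariance
  expect_equal(stats::cov(father, mother), 0)
  set.seed(6)
  counts <- 5 + 1.5 * father + 0.4 * mother + rnorm(8, 0, 0.5)
  fit <- age_regression(counts, father, mother)
  expect_equal(fit$slope, fit$conditional_slope, tolerance = 1e-10)
})
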