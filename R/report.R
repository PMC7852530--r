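#' Pipeline orchestration and reporting
#'
#' Ties the stages together: a serializable configuration object whose
#' fingerprint is echoed into every report header, an end-to-end runner over
#' synthetic (or pre-loaded) inputs, and a renderer for the
#' enrichment-summary table.
#'
#' @name cli_report
NULL

#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with its domain checks:
#' genotype posterior (Q20), allele-balance window (30-70%), external DNV
#' score (0.5), GC-content cutoff (0.75 over 100 bp tiles), TFBS-rich cutoff
#' (10), Bonferroni test count (13), reciprocal overlap (0.5), exclusion
#' coverage (0.5) and coverage similarity (0.9), plus the seed.
#'
#' @param min_posterior phred genotype-posterior threshold
#' @param ab_low,ab_high inclusive allele-balance bounds
#' @param score_threshold external DNV score threshold
#' @param gc_min_gc,gc_window GC exclusion filter parameters
#' @param tfbs_min TFBS-rich cutoff
#' @param upstream_window upstream gene-position window (bp)
#' @param bonferroni_m number of tests corrected for
#' @param theta,phi,rho SV-pipeline thresholds (reciprocal overlap,
#'   exclusion coverage, coverage similarity)
#' @param phasing_window,min_phasing_reads phasing parameters
#' @param seed integer seed
#' @return a list of class `PipelineConfig`
#' @export
pipeline_config <- function(min_posterior = 20, ab_low = 0.30,
                            ab_high = 0.70, score_threshold = 0.5,
                            gc_min_gc = 0.75, gc_window = 100,
                            tfbs_min = 10, upstream_window = 1000,
                            bonferroni_m = 13, theta = 0.5, phi = 0.5,
                            rho = 0.9, phasing_window = 500,
                            min_phasing_reads = 2, seed = 1L) {
  stopifnot(min_posterior >= 0,
            ab_low >= 0, ab_high <= 1, ab_low <= ab_high,
            score_threshold >= 0, score_threshold <= 1,
            gc_min_gc >= 0, gc_min_gc <= 1, gc_window >= 1,
            tfbs_min >= 0, bonferroni_m >= 1,
            theta >= 0, theta <= 1, phi >= 0, phi <= 1,
            rho >= -1, rho <= 1, min_phasing_reads >= 1)
  structure(as.list(environment()), class = "PipelineConfig")
}

#' Fingerprint of a pipeline configuration
#'
#' @param config a [pipeline_config()] object
#' @return an 8-hex-digit hash of the serialized configuration
#' @export
config_hash <- function(config) {
  fnv1a_hash(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA))
}

#' Run the DNV analysis end to end on a synthetic cohort
#'
#' Generates tracks, a trio cohort and a control set from `synth`
#' parameters, then runs candidate detection, filtering, annotation, the GC
#' filter, the enrichment table, parent-of-origin phasing, the
#' parental-age regression and the de novo SV pipeline. Identical
#' configuration and seed give identical results.
#'
#' @param config a [pipeline_config()] object
#' @param synth a [synth_config()] object (its seed is taken from `config`
#'   unless the two already agree)
#' @param control_n control set size override (default from `synth`)
#' @param run_sv also simulate and run the SV pipeline? (default `TRUE`)
#' @param out_dir optional directory for TSV/markdown/JSON artifacts
#' @return list with `dnv_calls`, `summary`, `case_annot`, `enrichment`,
#'   `phased`, `origin`, `age_fit`, `sv` and `report` (markdown lines)
#' @export
run_pipeline <- function(config = pipeline_config(),
                         synth = synth_config(seed = config$seed),
                         control_n = synth$control_n, run_sv = TRUE,
                         out_dir = NULL) {
  tracks <- simulate_tracks(synth)
  cohort <- simulate_trio_cohort(synth, tracks)
  control <- simulate_control_set(synth, tracks, n = control_n)

  ped <- cohort$pedigree
  calls <- do.call(rbind, lapply(seq_len(nrow(ped)), function(i) {
    child <- ped$child_id[i]
    cand <- detect_candidates(cohort$records[[child]], child_id = child)
    apply_dnv_filters(cand, min_posterior = config$min_posterior,
                      ab_low = config$ab_low, ab_high = config$ab_high,
                      score_threshold = config$score_threshold)
  }))
  accepted <- calls[calls$accepted, , drop = FALSE]
  summary_counts <- per_patient_summary(accepted, ped)

  case_annot <- annotate_cohort(accepted, tracks,
                                upstream_window = config$upstream_window,
                                tfbs_min = config$tfbs_min)
  ## planted nonsynonymous status comes from the generator ledger
  if (!is.null(cohort$ledger)) {
    key <- function(d) paste(d$child_id, d$chrom, d$pos)
    m <- match(key(case_annot), key(cohort$ledger))
    case_annot$nssnv <- cohort$ledger$nssnv[m]
  }
  control_annot <- annotate_cohort(control, tracks,
                                   upstream_window = config$upstream_window,
                                   tfbs_min = config$tfbs_min)
  enr <- enrichment_table(case_annot, control_annot,
                          m = config$bonferroni_m)

  phased <- phase_cohort(accepted, cohort$records, cohort$evidence,
                         window = config$phasing_window,
                         min_reads = config$min_phasing_reads)
  origin <- origin_summary(phased)
  counts <- summary_counts$per_child[ped$child_id]
  age_fit <- age_regression(as.integer(counts), ped$father_age,
                            ped$mother_age)

  sv <- NULL
  if (run_sv) {
    svd <- simulate_sv_data(synth, tracks, child = ped$child_id[1L],
                            father = ped$father_id[1L],
                            mother = ped$mother_id[1L])
    sv <- run_sv_pipeline(svd$callsets$child_a, svd$callsets$child_b,
                          parental = rbind(svd$callsets$father,
                                           svd$callsets$mother),
                          exclusion = tracks$exclusion,
                          coverage = svd$coverage,
                          father_id = ped$father_id[1L],
                          mother_id = ped$mother_id[1L],
                          theta = config$theta, phi = config$phi,
                          rho = config$rho)
    sv$ledger <- svd$ledger
  }

  report <- c(
    sprintf("# De novo variant analysis report"),
    sprintf("config: %s  seed: %d", config_hash(config), config$seed),
    "",
    sprintf("Trios: %d; accepted DNVs: %d (mean %s per child, range %d-%d)",
            nrow(ped), summary_counts$total, summary_counts$mean_reported,
            summary_counts$min, summary_counts$max),
    sprintf("Parent of origin: %d paternal / %d maternal (ratio %.2f)",
            origin$paternal, origin$maternal, origin$ratio),
    sprintf("Paternal-age effect: %.2f DNVs/year (r = %.2f, p = %.2g)",
            age_fit$slope, age_fit$r, age_fit$p),
    "",
    render_table1(enr))
  if (!is.null(sv))
    report <- c(report, "",
                sprintf("De novo SVs passing all filters: %d of %d audited calls",
                        nrow(sv$final), nrow(sv$audit)))

  res <- list(dnv_calls = calls, summary = summary_counts,
              case_annot = case_annot, enrichment = enr, phased = phased,
              origin = origin, age_fit = age_fit, sv = sv, report = report)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write.table(calls, file.path(out_dir, "dnv_calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(enr, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(phased, file.path(out_dir, "phased.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(report, file.path(out_dir, "report.md"))
    jsonlite::write_json(
      list(config = unclass(config), summary = summary_counts,
           origin = origin, age = age_fit),
      file.path(out_dir, "results.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Render the enrichment table as markdown
#'
#' One row per feature: counts with percentages for both cohorts, the
#' enrichment ratio, the chi-squared p value with a Bonferroni significance
#' star, and the expected excess. Undefined ratios print as `NA`; an empty
#' result renders the header only.
#'
#' @param results `data.frame` from [enrichment_table()] or
#'   [enrichment_from_counts()]
#' @param digits decimals for ratios (default 2)
#' @return character vector of markdown lines
#' @export
render_table1 <- function(results, digits = 2) {
  hdr <- c(paste("| Feature | Case DNVs (%) | Control DNVs (%) | Ratio |",
                 "P value | Expected excess |"),
           "|---|---|---|---|---|---|")
  if (is.null(results) || nrow(results) == 0L) return(hdr)
  fmt_ratio <- ifelse(is.na(results$ratio), "NA",
                      sprintf("%.*f", digits, results$ratio))
  fmt_p <- ifelse(is.na(results$p), "NA",
                  paste0(signif(results$p, 2),
                         ifelse(results$significant, "*", "")))
  fmt_ex <- ifelse(is.na(results$excess_reported), "-",
                   sprintf("%d", as.integer(results$excess_reported)))
  rows <- sprintf("| %s | %d (%.2f%%) | %d (%.2f%%) | %s | %s | %s |",
                  results$feature, results$case_count, results$case_pct,
                  results$control_count, results$control_pct,
                  fmt_ratio, fmt_p, fmt_ex)
  c(hdr, rows)
}
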