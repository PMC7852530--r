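#' File input/output for trio de novo variant analysis
#'
#' Readers and writers for the formats the pipeline consumes: multi-sample
#' trio VCFs (GT/AD/GQ), BED annotation tracks, structural-variant VCFs,
#' pedigree tables with parental ages at conception, read-evidence tables for
#' parent-of-origin phasing, and binned coverage tables.
#'
#' Coordinate conventions: all in-memory intervals are `GRanges` (1-based,
#' closed); BED files (0-based half-open) are converted on import/export by
#' \pkg{rtracklayer}; VCF positions are 1-based natively. Structural-variant
#' lengths follow the HGVS convention: for a deletion of bases
#' `start..end` (1-based, both deleted) the length is `end - start + 1`,
#' which equals `END - POS` of a VCF record whose POS is the padding base.
#'
#' @name io_formats
NULL

trio_record_proto <- list(
  chrom = character, pos = integer, ref = character, alt = character,
  var_class = character,
  gt_child = character, gt_father = character, gt_mother = character,
  ad_child_ref = integer, ad_child_alt = integer,
  ad_father_ref = integer, ad_father_alt = integer,
  ad_mother_ref = integer, ad_mother_alt = integer,
  gq_child = numeric, gq_father = numeric, gq_mother = numeric
)

sv_call_proto <- list(
  chrom = character, start = integer, end = integer, svtype = character,
  length = integer, caller = character, sample = character, status = character
)

#' Read a pedigree table
#'
#' A pedigree is a tab-separated table with one row per trio and columns
#' `family_id`, `child_id`, `father_id`, `mother_id`, `child_sex`,
#' `father_age`, `mother_age`. Ages are the parental ages at conception of the
#' child, in years.
#'
#' @param path path to the TSV file
#' @return a `data.frame`, one row per trio
#' @export
read_pedigree <- function(path) {
  ped <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(family_id = "character",
                                   child_id = "character",
                                   father_id = "character",
                                   mother_id = "character",
                                   child_sex = "character"))
  validate_pedigree(ped)
  ped
}

#' @rdname read_pedigree
#' @param ped pedigree `data.frame`
#' @export
write_pedigree <- function(ped, path) {
  validate_pedigree(ped)
  write.table(ped, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_pedigree <- function(ped) {
  req <- c("family_id", "child_id", "father_id", "mother_id", "child_sex",
           "father_age", "mother_age")
  miss <- setdiff(req, names(ped))
  if (length(miss))
    stop("pedigree is missing columns: ", paste(miss, collapse = ", "))
  ids <- ped[, c("child_id", "father_id", "mother_id")]
  dup <- apply(ids, 1L, function(r) anyDuplicated(r) > 0L)
  if (any(dup))
    stop("child/father/mother ids must be distinct (row ",
         which(dup)[1L], ")")
  ages <- c(ped$father_age, ped$mother_age)
  if (any(!is.na(ages) & ages <= 0))
    stop("parental ages at conception must be positive")
  invisible(TRUE)
}

## extract one AD pair (ref, alt j) from whatever shape readVcf produced
ad_pair <- function(ad, i, j, alt_index) {
  v <- if (is.list(ad)) ad[[i, j]] else ad[i, j, ]
  v <- suppressWarnings(as.integer(v))
  if (length(v) < alt_index + 1L) return(c(NA_integer_, NA_integer_))
  c(v[1L], v[alt_index + 1L])
}

#' Read a trio VCF into genotype records
#'
#' Reads a multi-sample VCF and extracts, for the three members of one trio,
#' the genotype (GT), allele depths (AD) and genotype posterior quality (GQ,
#' phred scaled) at every site. Multiallelic sites are decomposed into one
#' biallelic record per alternate allele by default (alleles other than the
#' focal one are recoded to the reference index); set `multiallelic =
#' "skip"` to drop them instead. Genotypes that cannot be parsed cause the
#' site to be skipped with a warning; missing genotypes (`./.`) are kept as
#' `NA` and handled downstream.
#'
#' @param path path to a VCF (plain text or bgzipped)
#' @param pedigree a one-row pedigree `data.frame` naming the three samples
#' @param multiallelic `"split"` (default) or `"skip"`
#' @return a `data.frame` of trio genotype records (1-based VCF positions)
#' @export
read_trio_vcf <- function(path, pedigree, multiallelic = c("split", "skip")) {
  multiallelic <- match.arg(multiallelic)
  stopifnot(is.data.frame(pedigree), nrow(pedigree) == 1L)
  vcf <- VariantAnnotation::readVcf(path)
  need <- c(child = pedigree$child_id, father = pedigree$father_id,
            mother = pedigree$mother_id)
  absent <- need[!(need %in% colnames(vcf))]
  if (length(absent))
    stop("sample not found in VCF header: ", paste(absent, collapse = ", "))
  if (nrow(vcf) == 0L) return(empty_df(trio_record_proto))

  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  refs <- as.character(VariantAnnotation::ref(vcf))
  alts <- VariantAnnotation::alt(vcf)
  alts <- lapply(seq_along(alts), function(i) as.character(alts[[i]]))
  g <- VariantAnnotation::geno(vcf)
  gt <- g$GT[, need, drop = FALSE]
  ad <- if ("AD" %in% names(g)) g$AD[, need, drop = FALSE] else NULL
  gq <- if ("GQ" %in% names(g)) g$GQ[, need, drop = FALSE] else NULL

  out <- vector("list", nrow(vcf))
  n_skipped <- 0L
  for (i in seq_len(nrow(vcf))) {
    alt_i <- alts[[i]]
    alt_i <- alt_i[alt_i != "" & !is.na(alt_i)]
    if (length(alt_i) == 0L) next
    if (length(alt_i) > 1L && multiallelic == "skip") next
    ## symbolic / breakend alleles do not belong in the SNV/INDEL reader
    if (any(grepl("[<>\\[\\]]", alt_i))) next
    raw_gt <- gt[i, ]
    parsed <- lapply(strsplit(gsub("|", "/", raw_gt, fixed = TRUE), "/"),
                     function(p) suppressWarnings(
                       ifelse(p == ".", NA_integer_, as.integer(p))))
    bad <- vapply(parsed, function(p)
      length(p) != 2L || any(!is.na(p) & (p < 0L | p > length(alt_i))), TRUE)
    malformed <- vapply(raw_gt, function(x)
      !grepl("^([0-9]+|\\.)([/|]([0-9]+|\\.))?$", x), TRUE)
    if (any(bad | malformed)) { n_skipped <- n_skipped + 1L; next }
    rows <- lapply(seq_along(alt_i), function(j) {
      if (alt_i[j] == refs[i]) return(NULL)
      gts <- vapply(parsed, function(p) {
        if (any(is.na(p))) return(NA_character_)
        paste(sort(as.integer(p == j)), collapse = "/")
      }, character(1))
      ads <- if (is.null(ad)) matrix(NA_integer_, 2L, 3L) else
        vapply(seq_along(need), function(k) ad_pair(ad, i, k, j),
               integer(2))
      gqs <- if (is.null(gq)) rep(NA_real_, 3L) else
        suppressWarnings(as.numeric(gq[i, ]))
      data.frame(
        chrom = chrom[i], pos = pos[i], ref = refs[i], alt = alt_i[j],
        var_class = if (nchar(refs[i]) == 1L && nchar(alt_i[j]) == 1L)
          "SNV" else "INDEL",
        gt_child = gts[1L], gt_father = gts[2L], gt_mother = gts[3L],
        ad_child_ref = ads[1L, 1L], ad_child_alt = ads[2L, 1L],
        ad_father_ref = ads[1L, 2L], ad_father_alt = ads[2L, 2L],
        ad_mother_ref = ads[1L, 3L], ad_mother_alt = ads[2L, 3L],
        gq_child = gqs[1L], gq_father = gqs[2L], gq_mother = gqs[3L],
        stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, rows)
  }
  if (n_skipped > 0L)
    warning(n_skipped, " site(s) skipped due to malformed genotypes")
  res <- do.call(rbind, out)
  if (is.null(res)) res <- empty_df(trio_record_proto)
  rownames(res) <- NULL
  res
}

#' Write trio genotype records as a VCF
#'
#' Emits a minimal valid VCF 4.2 with GT/AD/GQ FORMAT fields for the three
#' trio members, sorted by chromosome and position. The inverse of
#' [read_trio_vcf()] for biallelic records.
#'
#' @param records trio record `data.frame` (see [read_trio_vcf()])
#' @param path output path
#' @param child_id,father_id,mother_id sample names for the three columns
#' @param contigs optional named integer vector of contig lengths
#' @return the path, invisibly
#' @export
write_trio_vcf <- function(records, path, child_id, father_id, mother_id,
                           contigs = NULL) {
  if (is.null(contigs)) {
    contigs <- tapply(records$pos, records$chrom, max)
    contigs <- setNames(as.integer(contigs) + 1000L, names(contigs))
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=",
           "\"Allelic depths for the ref and alt alleles\">"),
    paste0("##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=",
           "\"Genotype posterior quality (phred)\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", child_id, father_id, mother_id), collapse = "\t"))
  fmt_member <- function(gt, adr, ada, gq) {
    gt <- ifelse(is.na(gt), "./.", gt)
    ad <- ifelse(is.na(adr) | is.na(ada), ".", paste0(adr, ",", ada))
    gq <- ifelse(is.na(gq), ".", as.character(as.integer(gq)))
    paste(gt, ad, gq, sep = ":")
  }
  records <- records[order(records$chrom, records$pos), , drop = FALSE]
  body <- if (nrow(records) == 0L) character(0) else
    paste(records$chrom, records$pos, ".", records$ref, records$alt, ".",
          "PASS", ".", "GT:AD:GQ",
          fmt_member(records$gt_child, records$ad_child_ref,
                     records$ad_child_alt, records$gq_child),
          fmt_member(records$gt_father, records$ad_father_ref,
                     records$ad_father_alt, records$gq_father),
          fmt_member(records$gt_mother, records$ad_mother_ref,
                     records$ad_mother_alt, records$gq_mother),
          sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a BED annotation track
#'
#' Reads a BED3+ file into a sorted `GRanges`. BED files are 0-based
#' half-open; the returned ranges are 1-based closed per `GRanges`
#' convention. The name column (when present) is kept in `mcols()$name`;
#' otherwise `label` is used for all intervals.
#'
#' @param path path to the BED file
#' @param label track label used when the file has no name column
#' @return a sorted `GRanges` with a `name` metadata column
#' @export
read_bed_track <- function(path, label = NULL) {
  raw <- tryCatch(
    read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE),
    error = function(e) NULL)
  if (!is.null(raw) && nrow(raw) > 0L) {
    bad <- which(!(raw[[3L]] > raw[[2L]]))
    if (length(bad))
      stop("BED interval with end <= start at line ", bad[1L])
  }
  gr <- rtracklayer::import(path, format = "BED")
  if (!("name" %in% names(S4Vectors::mcols(gr))) ||
      all(is.na(gr$name))) {
    if (is.null(label)) label <- basename(path)
    gr$name <- label
  }
  S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)["name"]
  sort(gr)
}

#' Write a GRanges track as BED
#'
#' @param gr a `GRanges`; `mcols()$name` is written to the name column
#' @param path output path
#' @return the path, invisibly
#' @export
write_bed_track <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read structural-variant calls from a VCF
#'
#' Reads an SV VCF (Manta/FermiKit-shaped: symbolic ALT plus INFO
#' `SVTYPE`/`END`/`SVLEN`) into a table of calls. Only DEL, DUP, INS and INV
#' records are kept; breakends and records without resolvable END/SVLEN are
#' skipped with a warning. The affected interval is stored 1-based closed:
#' `start = POS + 1` (POS being the padding base) and `end = END`; the
#' canonical SV length is `abs(SVLEN)` when present, otherwise `END - POS`,
#' matching the HGVS deletion-length convention.
#'
#' @param path path to the SV VCF
#' @param caller_id identifier of the caller that produced the file
#' @param status `"auto"` (default: FILTER PASS -> "called", otherwise
#'   "candidate"), or a fixed value `"called"`/`"candidate"`
#' @param sample_id sample identifier; default: first sample column of the VCF
#' @return a `data.frame` of SV calls
#' @export
read_sv_vcf <- function(path, caller_id, status = "auto", sample_id = NULL) {
  vcf <- VariantAnnotation::readVcf(path)
  if (nrow(vcf) == 0L) return(empty_df(sv_call_proto))
  if (is.null(sample_id))
    sample_id <- if (ncol(vcf) > 0L) colnames(vcf)[1L] else NA_character_
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  inf <- VariantAnnotation::info(vcf)
  svtype <- if ("SVTYPE" %in% names(inf)) as.character(inf$SVTYPE)
            else rep(NA_character_, nrow(vcf))
  endv <- if ("END" %in% names(inf)) suppressWarnings(as.integer(inf$END))
          else rep(NA_integer_, nrow(vcf))
  svlen <- if ("SVLEN" %in% names(inf)) {
    vapply(seq_len(nrow(vcf)), function(i) {
      v <- inf$SVLEN[[i]]
      if (length(v) == 0L || all(is.na(v))) NA_integer_ else
        as.integer(v[1L])
    }, integer(1))
  } else rep(NA_integer_, nrow(vcf))
  altc <- vapply(seq_len(nrow(vcf)), function(i) {
    a <- VariantAnnotation::alt(vcf)[[i]]
    if (length(a)) as.character(a)[1L] else NA_character_
  }, character(1))
  ## fall back to parsing the symbolic ALT when SVTYPE is absent
  guess <- sub("^<([A-Z]+).*>$", "\\1", altc)
  svtype <- ifelse(is.na(svtype) & grepl("^<", altc), guess, svtype)
  filt <- VariantAnnotation::filt(vcf)

  keep_types <- c("DEL", "DUP", "INS", "INV")
  rows <- vector("list", nrow(vcf))
  n_skip <- 0L
  for (i in seq_len(nrow(vcf))) {
    ty <- svtype[i]
    if (is.na(ty) || !(ty %in% keep_types)) { n_skip <- n_skip + 1L; next }
    len <- svlen[i]
    en <- endv[i]
    if (is.na(len) && is.na(en)) { n_skip <- n_skip + 1L; next }
    if (is.na(len)) len <- en - pos[i]
    len <- abs(len)
    if (ty == "INS") {
      st <- pos[i]; en <- pos[i]
    } else {
      st <- pos[i] + 1L
      if (is.na(en)) en <- pos[i] + len
    }
    st_rec <- if (status == "auto") {
      if (!is.na(filt[i]) && filt[i] == "PASS") "called" else "candidate"
    } else status
    rows[[i]] <- data.frame(
      chrom = chrom[i], start = st, end = en, svtype = ty,
      length = as.integer(len), caller = caller_id, sample = sample_id,
      status = st_rec, stringsAsFactors = FALSE)
  }
  if (n_skip > 0L)
    warning(n_skip, " SV record(s) skipped (unsupported type or no END/SVLEN)")
  res <- do.call(rbind, rows)
  if (is.null(res)) res <- empty_df(sv_call_proto)
  rownames(res) <- NULL
  res
}

#' Write structural-variant calls as a VCF
#'
#' Inverse of [read_sv_vcf()]: POS is the padding base (`start - 1`), INFO
#' carries SVTYPE/END/SVLEN, FILTER encodes the call status (PASS for
#' "called", "Candidate" otherwise).
#'
#' @param calls SV call `data.frame` (see [read_sv_vcf()])
#' @param path output path
#' @param sample_id sample column name; default taken from the calls
#' @param contigs optional named integer vector of contig lengths
#' @return the path, invisibly
#' @export
write_sv_vcf <- function(calls, path, sample_id = NULL, contigs = NULL) {
  if (is.null(sample_id))
    sample_id <- if (nrow(calls)) calls$sample[1L] else "SAMPLE"
  if (is.null(contigs)) {
    contigs <- if (nrow(calls))
      setNames(as.integer(tapply(calls$end, calls$chrom, max)) + 10000L,
               sort(unique(calls$chrom)))
    else c(chr1 = 1000L)
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs)),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##ALT=<ID=INS,Description=\"Insertion\">",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "##FILTER=<ID=Candidate,Description=\"Low-confidence candidate call\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_id), collapse = "\t"))
  body <- if (nrow(calls) == 0L) character(0) else {
    calls <- calls[order(calls$chrom, calls$start), , drop = FALSE]
    pos <- ifelse(calls$svtype == "INS", calls$start, calls$start - 1L)
    svlen <- ifelse(calls$svtype == "DEL", -calls$length, calls$length)
    paste(calls$chrom, pos, ".", "N", paste0("<", calls$svtype, ">"), ".",
          ifelse(calls$status == "called", "PASS", "Candidate"),
          sprintf("SVTYPE=%s;END=%d;SVLEN=%d", calls$svtype, calls$end, svlen),
          "GT", "0/1", sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read phasing read evidence
#'
#' The canonical read-evidence dialect is a TSV with columns `read_id`,
#' `sample_id` and `obs`, where `obs` is a semicolon-separated list of
#' `pos:allele` pairs (1-based positions, strictly increasing within a
#' record) observed on one read or read pair. Returned in long form with one
#' row per (read, position).
#'
#' @param path path to the evidence TSV
#' @return a long `data.frame` with columns read_id, sample_id, pos, allele
#' @export
read_read_evidence <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("read_id", "sample_id", "obs") %in% names(tab)))
  if (nrow(tab) == 0L)
    return(data.frame(read_id = character(0), sample_id = character(0),
                      pos = integer(0), allele = character(0)))
  parts <- strsplit(tab$obs, ";", fixed = TRUE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    kv <- strsplit(parts[[i]], ":", fixed = TRUE)
    pos <- vapply(kv, function(p) as.integer(p[1L]), integer(1))
    allele <- vapply(kv, function(p) p[2L], character(1))
    if (any(diff(pos) <= 0L))
      stop("positions not strictly increasing in evidence record ",
           tab$read_id[i])
    data.frame(read_id = tab$read_id[i], sample_id = tab$sample_id[i],
               pos = pos, allele = allele, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @rdname read_read_evidence
#' @param evidence long-form evidence `data.frame`
#' @export
write_read_evidence <- function(evidence, path) {
  if (nrow(evidence) == 0L) {
    writeLines("read_id\tsample_id\tobs", path)
    return(invisible(path))
  }
  evidence <- evidence[order(evidence$read_id, evidence$pos), , drop = FALSE]
  obs <- vapply(split(evidence, evidence$read_id), function(d)
    paste(sprintf("%d:%s", d$pos, d$allele), collapse = ";"), character(1))
  samp <- vapply(split(evidence, evidence$read_id), function(d)
    d$sample_id[1L], character(1))
  tab <- data.frame(read_id = names(obs), sample_id = samp, obs = obs,
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a binned coverage table
#'
#' Coverage profiles are TSVs with columns `sample`, `chrom`, `bin_start`
#' (1-based first position of the bin) and `depth`, on a common bin grid for
#' all samples of a trio.
#'
#' @param path path to the TSV
#' @return a `data.frame`
#' @export
read_coverage_tsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "chrom", "bin_start", "depth") %in% names(tab)))
  tab
}

#' @rdname read_coverage_tsv
#' @param coverage coverage `data.frame`
#' @export
write_coverage_tsv <- function(coverage, path) {
  write.table(coverage, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
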