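#' @importFrom methods is
#' @importFrom stats cor lm pchisq rbinom rnorm rpois runif setNames
#' @importFrom utils read.table write.table head
NULL

#' Round half away from zero
#'
#' Reported integer quantities (mean DNVs per patient, validation FDR in
#' percent, expected excess counts, expected patient numbers) use conventional
#' "round half up" rounding rather than R's banker's rounding.
#'
#' @param x numeric vector
#' @param digits number of decimal places (default 0)
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## coerce a data.frame with chrom/pos columns (or a GRanges) to width-1 GRanges
as_positions <- function(x) {
  if (is(x, "GRanges")) return(x)
  stopifnot(is.data.frame(x), all(c("chrom", "pos") %in% names(x)))
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$pos, x$pos))
}

## zero-row data.frame with given column name -> class prototype mapping
empty_df <- function(proto) {
  as.data.frame(lapply(proto, function(f) f(0)), stringsAsFactors = FALSE)
}

## normalize a diploid GT string: "1|0" -> "0/1", "." or "./." -> NA
normalize_gt <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  parts <- strsplit(gt, "/", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) == 1L) p <- c(p, p)  # haploid records treated as homozygous
    if (length(p) != 2L || any(!grepl("^([0-9]+|\\.)$", p))) return(NA_character_)
    if (any(p == ".")) return(NA_character_)
    paste(sort(as.integer(p)), collapse = "/")
  }, character(1))
}

## tiny polynomial rolling hash over a character scalar; used for config
## fingerprints in report headers (no external digest dependency; exact in
## double arithmetic since intermediates stay below 2^53)
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
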