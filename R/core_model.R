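# Core domain arithmetic: heterozygote balance, homozygote noise, filter
# configurations. All genotype tables in this package are data.tables with
# columns chrom, pos, ref, alt, genotype, ref_count, alt_count, other_count,
# dp, gq; genotypes are one of "hom_ref", "het", "hom_alt", "missing".

GENOTYPES <- c("hom_ref", "het", "hom_alt", "missing")
CALLED_GENOTYPES <- c("hom_ref", "het", "hom_alt")
REASON_ORDER <- c("missing", "depth", "quality", "balance", "noise")
NUCLEOTIDES <- c("A", "C", "G", "T")

#' Heterozygote balance of a read-support observation
#'
#' The heterozygote balance (Hb) is the fraction of allele-informative reads
#' carrying the alternate allele, `alt / (ref + alt)`. Reads supporting
#' neither allele are excluded from the denominator. A constitutional
#' heterozygote is expected near 0.5; tissue-specific somatic variants
#' typically sit far below (alt fractions of roughly 5-20%), which is what
#' the Hb window filters exploit.
#'
#' @param ref_count integer vector, reads supporting the reference allele.
#' @param alt_count integer vector, reads supporting the alternate allele.
#' @return numeric vector of balances in `[0, 1]`.
#' @details Errors if any position has `ref_count + alt_count == 0`
#'   (the balance is undefined there and the genotype must be treated as
#'   unacceptable); the internal filter path maps that case to a rejection
#'   instead.
#' @examples
#' heterozygote_balance(15, 15)  # 0.5
#' heterozygote_balance(27, 3)   # 0.1
#' @export
heterozygote_balance <- function(ref_count, alt_count) {
  stopifnot(length(ref_count) == length(alt_count),
            all(ref_count >= 0), all(alt_count >= 0))
  denom <- ref_count + alt_count
  if (any(denom == 0)) {
    stop("heterozygote balance undefined: no reads support either allele")
  }
  alt_count / denom
}

# vectorised Hb that flags the undefined case as NA instead of erroring
hb_or_na <- function(ref_count, alt_count) {
  denom <- ref_count + alt_count
  out <- alt_count / denom
  out[denom == 0] <- NA_real_
  out
}

#' Noise fraction of a homozygous call
#'
#' For a homozygous genotype the noise is the fraction of reads that do NOT
#' support the called allele: `1 - called_allele_reads / dp`, where `dp`
#' counts all reads (`ref + alt + other`). It is the homozygote analogue of
#' the heterozygote balance and is used by the targeted-panel filter regime
#' (noise < 0.05 by default).
#'
#' @param genotype character vector, `"hom_ref"` or `"hom_alt"`.
#' @param ref_count,alt_count,other_count integer vectors of read support.
#' @return numeric vector of noise fractions in `[0, 1]`.
#' @examples
#' noise_fraction("hom_ref", 100, 0, 0)  # 0
#' noise_fraction("hom_alt", 2, 96, 2)   # 0.04
#' @export
noise_fraction <- function(genotype, ref_count, alt_count, other_count = 0L) {
  n <- length(genotype)
  other_count <- rep_len(other_count, n)
  if (any(!genotype %in% c("hom_ref", "hom_alt"))) {
    stop("noise fraction applies to homozygous calls only")
  }
  dp <- ref_count + alt_count + other_count
  if (any(dp == 0)) {
    stop("noise fraction undefined at zero depth")
  }
  called <- ifelse(genotype == "hom_ref", ref_count, alt_count)
  1 - called / dp
}

# NA-tolerant noise used by the filter path: NA for het/missing or dp == 0
noise_or_na <- function(genotype, ref_count, alt_count, other_count) {
  dp <- ref_count + alt_count + other_count
  called <- rep(NA_real_, length(genotype))
  called[genotype == "hom_ref"] <- ref_count[genotype == "hom_ref"]
  called[genotype == "hom_alt"] <- alt_count[genotype == "hom_alt"]
  out <- 1 - called / dp
  out[dp == 0] <- NA_real_
  out
}

#' Genotype acceptance configuration
#'
#' Bundles one acceptance regime: a depth floor, a genotype-quality floor, an
#' optional heterozygote-balance window applied to heterozygous calls, and an
#' optional noise ceiling applied to homozygous calls. Hb bounds are
#' inclusive (`hb_low <= Hb <= hb_high`); the noise test is strict
#' (`noise < noise_max`).
#'
#' @param dp_min integer, minimum read depth.
#' @param gq_min integer, minimum Phred-scaled genotype quality.
#' @param hb_low,hb_high optional Hb window bounds in `[0, 1]`; both `NA`
#'   disables the Hb filter.
#' @param noise_max optional noise ceiling in `[0, 1]`; `NA` disables the
#'   homozygote noise filter.
#' @param biallelic_only logical, restrict ingestion to biallelic SNVs.
#' @return an object of class `filter_config`.
#' @seealso [filter_preset()] for the two standard regimes.
#' @export
filter_config <- function(dp_min, gq_min, hb_low = NA_real_,
                          hb_high = NA_real_, noise_max = NA_real_,
                          biallelic_only = TRUE) {
  dp_min <- as.integer(dp_min)
  gq_min <- as.integer(gq_min)
  stopifnot(length(dp_min) == 1L, length(gq_min) == 1L,
            dp_min >= 0L, gq_min >= 0L)
  if (is.na(hb_low) != is.na(hb_high)) {
    stop("hb_low and hb_high must both be set or both be NA")
  }
  if (!is.na(hb_low)) {
    stopifnot(hb_low >= 0, hb_high <= 1, hb_low <= hb_high)
  }
  if (!is.na(noise_max)) {
    stopifnot(noise_max >= 0, noise_max <= 1)
  }
  structure(
    list(dp_min = dp_min, gq_min = gq_min,
         hb_low = as.numeric(hb_low), hb_high = as.numeric(hb_high),
         noise_max = as.numeric(noise_max),
         biallelic_only = isTRUE(biallelic_only)),
    class = "filter_config"
  )
}

#' Standard acceptance regimes
#'
#' Two named presets: `"shotgun"` (DP >= 8, GQ >= 10, Hb window 0.4-0.6 for
#' heterozygotes, no homozygote noise filter) for genome-wide shotgun data,
#' and `"targeted"` (DP >= 100, GQ >= 10, Hb 0.3-0.7, noise < 0.05) for
#' high-depth amplicon-panel confirmation.
#'
#' @param name `"shotgun"` or `"targeted"`.
#' @return a [filter_config()].
#' @export
filter_preset <- function(name = c("shotgun", "targeted")) {
  name <- match.arg(name)
  switch(name,
    shotgun  = filter_config(dp_min = 8L, gq_min = 10L,
                             hb_low = 0.4, hb_high = 0.6),
    targeted = filter_config(dp_min = 100L, gq_min = 10L,
                             hb_low = 0.3, hb_high = 0.7, noise_max = 0.05)
  )
}

#' @export
print.filter_config <- function(x, ...) {
  hb <- if (is.na(x$hb_low)) "none" else sprintf("[%g, %g]", x$hb_low, x$hb_high)
  noise <- if (is.na(x$noise_max)) "none" else sprintf("< %g", x$noise_max)
  cat("filter_config: DP >=", x$dp_min, "| GQ >=", x$gq_min,
      "| Hb window", hb, "| hom noise", noise,
      "| biallelic_only", x$biallelic_only, "\n")
  invisible(x)
}

#' Read or write a filter configuration as JSON
#'
#' The on-disk form uses keys `dp_min`, `gq_min`, `hb` (a two-element array
#' `[low, high]` or absent), `noise_max` (or absent) and `biallelic_only`.
#'
#' @param path file path.
#' @return `read_filter_config()` returns a [filter_config()];
#'   `write_filter_config()` returns `path` invisibly.
#' @export
read_filter_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  hb <- if (is.null(x$hb)) c(NA_real_, NA_real_) else as.numeric(x$hb)
  filter_config(
    dp_min = x$dp_min, gq_min = x$gq_min,
    hb_low = hb[1], hb_high = hb[2],
    noise_max = if (is.null(x$noise_max)) NA_real_ else x$noise_max,
    biallelic_only = if (is.null(x$biallelic_only)) TRUE else x$biallelic_only
  )
}

#' @rdname read_filter_config
#' @param config a [filter_config()].
#' @export
write_filter_config <- function(config, path) {
  stopifnot(inherits(config, "filter_config"))
  x <- list(dp_min = config$dp_min, gq_min = config$gq_min,
            biallelic_only = config$biallelic_only)
  if (!is.na(config$hb_low)) x$hb <- c(config$hb_low, config$hb_high)
  if (!is.na(config$noise_max)) x$noise_max <- config$noise_max
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# validate a calls table (shared by constructors and file readers)
validate_calls <- function(calls) {
  calls <- data.table::as.data.table(calls)
  needed <- c("chrom", "pos", "ref", "alt", "genotype",
              "ref_count", "alt_count", "other_count", "gq")
  missing_cols <- setdiff(needed, names(calls))
  if (length(missing_cols)) {
    stop("calls table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"dp" %in% names(calls)) {
    calls[, dp := ref_count + alt_count + other_count]
  }
  stopifnot(all(calls$pos >= 1L),
            all(calls$genotype %in% GENOTYPES),
            all(calls$ref_count >= 0L), all(calls$alt_count >= 0L),
            all(calls$other_count >= 0L), all(calls$gq >= 0L),
            all(calls$dp == calls$ref_count + calls$alt_count + calls$other_count))
  bad <- calls$ref == calls$alt |
    !calls$ref %in% NUCLEOTIDES | !calls$alt %in% NUCLEOTIDES
  if (any(bad)) stop("calls table contains non-SNV or degenerate alleles")
  if (anyDuplicated(calls, by = c("chrom", "pos"))) {
    stop("calls table has more than one record at a locus")
  }
  data.table::setkeyv(calls, c("chrom", "pos"))
  calls[]
}

#' Construct a per-replicate call set
#'
#' A `sample_calls` object holds all genotype calls of one sequencing
#' replicate of one sample: a keyed data.table of calls plus identifiers and
#' the contig lengths advertised by the source VCF header.
#'
#' @param calls data.frame with columns chrom, pos, ref, alt, genotype,
#'   ref_count, alt_count, other_count, gq (dp is derived if absent).
#' @param sample_id,replicate_id identifying strings.
#' @param contig_lengths named numeric vector of contig lengths (may be empty).
#' @param skipped named integer vector of ingestion skip counters.
#' @return an object of class `sample_calls`.
#' @export
sample_calls <- function(calls, sample_id, replicate_id,
                         contig_lengths = numeric(0),
                         skipped = c(multiallelic = 0L, non_snv = 0L,
                                     missing_format = 0L)) {
  structure(
    list(sample_id = as.character(sample_id),
         replicate_id = as.character(replicate_id),
         calls = validate_calls(calls),
         contig_lengths = contig_lengths,
         skipped = skipped),
    class = "sample_calls"
  )
}

#' @export
print.sample_calls <- function(x, ...) {
  cat(sprintf("sample_calls: %s / %s, %d loci (skipped: %s)\n",
              x$sample_id, x$replicate_id, nrow(x$calls),
              paste(names(x$skipped), x$skipped, sep = "=", collapse = ", ")))
  invisible(x)
}
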