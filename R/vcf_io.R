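# VCF ingestion and table output: the pipeline's only contact with on-disk
# formats. Reading is delegated to VariantAnnotation; records that cannot be
# represented (multiallelic, non-SNV, missing FORMAT fields) are skipped and
# counted rather than aborting the run — forensic VCFs are heterogeneous and
# silent truncation would be worse than logged loss.

#' Read one sample's genotype calls from a VCF file
#'
#' Ingests GT/AD/DP/GQ for the named sample into a [sample_calls()] object.
#' AD is authoritative for the ref/alt read counts; when DP exceeds
#' `sum(AD)` the excess is stored as `other_count` (reads supporting neither
#' allele), which the targeted-stage noise filter needs. Multiallelic
#' records, non-SNV alleles and records lacking any of AD/DP/GQ are skipped
#' with per-category counters kept in the returned object.
#'
#' @param path path to a VCFv4.x file with GT, AD, DP and GQ FORMAT fields.
#' @param sample sample name; may be omitted for single-sample VCFs.
#' @param replicate_id replicate label stored on the result (defaults to the
#'   file name).
#' @param biallelic_only skip records with more than one ALT allele
#'   (default TRUE; only biallelic SNVs are representable either way).
#' @return a [sample_calls()] object; `$skipped` holds the skip counters and
#'   `$contig_lengths` the header contig lengths.
#' @export
read_sample_calls <- function(path, sample = NULL, replicate_id = NULL,
                              biallelic_only = TRUE) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  vcf <- VariantAnnotation::readVcf(
    path,
    param = VariantAnnotation::ScanVcfParam(info = NA,
                                            geno = c("GT", "AD", "DP", "GQ"))
  )
  samples_avail <- colnames(vcf)
  if (is.null(sample)) {
    if (length(samples_avail) != 1L) {
      stop("VCF has ", length(samples_avail),
           " samples; name one of: ", paste(samples_avail, collapse = ", "))
    }
    sample <- samples_avail
  } else if (!sample %in% samples_avail) {
    stop("unknown sample '", sample, "' in ", path,
         " (available: ", paste(samples_avail, collapse = ", "), ")")
  }
  if (is.null(replicate_id)) replicate_id <- basename(path)

  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt_list)

  skipped <- c(multiallelic = 0L, non_snv = 0L, missing_format = 0L,
               duplicate = 0L)
  keep <- rep(TRUE, length(rr))

  multi <- n_alt != 1L
  skipped["multiallelic"] <- sum(multi)
  keep[multi] <- FALSE
  if (!biallelic_only && any(multi)) {
    # multiallelic records cannot be represented as a single biallelic SNV
    # call either way; they are always skipped, the flag only documents intent
    warning("biallelic_only = FALSE: multiallelic records are still skipped")
  }

  alt1 <- rep(NA_character_, length(rr))
  alt1[keep] <- as.character(unlist(alt_list[keep]))
  non_snv <- keep & (!ref %in% NUCLEOTIDES | !alt1 %in% NUCLEOTIDES |
                       nchar(ref) != 1L | is.na(alt1))
  skipped["non_snv"] <- sum(non_snv)
  keep[non_snv] <- FALSE

  g <- VariantAnnotation::geno(vcf)
  gt <- g$GT[, sample]
  dp <- g$DP[, sample]
  gq <- g$GQ[, sample]
  ad <- g$AD[, sample]
  if (!is.list(ad)) ad <- as.list(as.data.frame(t(ad)))  # array fallback
  ad_len <- lengths(ad)
  ad_ok <- ad_len == 2L
  ad_ok[ad_ok] <- !vapply(ad[ad_ok], anyNA, logical(1))
  bad_fmt <- keep & (is.na(dp) | is.na(gq) | !ad_ok)
  skipped["missing_format"] <- sum(bad_fmt)
  keep[bad_fmt] <- FALSE

  idx <- which(keep)
  dup <- duplicated(data.frame(chrom = chrom[idx], pos = pos[idx]))
  skipped["duplicate"] <- sum(dup)
  idx <- idx[!dup]

  ad_mat <- matrix(unlist(ad[idx], use.names = FALSE), ncol = 2L, byrow = TRUE)
  ref_count <- as.integer(ad_mat[, 1])
  alt_count <- as.integer(ad_mat[, 2])
  dp_i <- as.integer(dp[idx])
  other_count <- pmax(0L, dp_i - ref_count - alt_count)

  gt_i <- gsub("|", "/", gt[idx], fixed = TRUE)
  genotype <- rep("missing", length(idx))
  genotype[gt_i == "0/0"] <- "hom_ref"
  genotype[gt_i %in% c("0/1", "1/0")] <- "het"
  genotype[gt_i == "1/1"] <- "hom_alt"

  calls <- data.table::data.table(
    chrom = chrom[idx], pos = as.integer(pos[idx]),
    ref = ref[idx], alt = alt1[idx],
    genotype = genotype,
    ref_count = ref_count, alt_count = alt_count, other_count = other_count,
    gq = as.integer(gq[idx])
  )
  lens <- GenomeInfoDb::seqlengths(vcf)
  lens <- lens[!is.na(lens)]
  sample_calls(calls, sample_id = sample, replicate_id = replicate_id,
               contig_lengths = lens, skipped = skipped)
}

#' Write a call set to a single-sample VCF file
#'
#' Emits a minimal VCFv4.2 file with GT:AD:DP:GQ per record, contig header
#' lines taken from the object's `contig_lengths`, and records in
#' (chrom, pos) order. Round-trips exactly through [read_sample_calls()].
#'
#' @param callset a [sample_calls()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(callset, path) {
  stopifnot(inherits(callset, "sample_calls"))
  calls <- data.table::copy(callset$calls)
  data.table::setorder(calls, chrom, pos)
  gt_str <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
              missing = "./.")[calls$genotype]
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(callset$contig_lengths),
            as.integer(callset$contig_lengths)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Phred-scaled genotype quality\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", callset$sample_id, sep = "\t")
  )
  records <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\t.\t.\tGT:AD:DP:GQ\t%s:%d,%d:%d:%d",
    calls$chrom, calls$pos, calls$ref, calls$alt, gt_str,
    calls$ref_count, calls$alt_count,
    calls$ref_count + calls$alt_count + calls$other_count, calls$gq
  )
  con <- file(path, open = "wb")  # LF endings for byte-stable output
  on.exit(close(con))
  writeLines(c(header, records), con)
  invisible(path)
}

# canonical column order for the candidate/discordance table
candidate_fixed_cols <- c("chrom", "pos", "ref", "alt", "trace_genotype",
                          "reference_genotype", "pattern")

#' Write discordant loci to a tab-separated candidates file
#'
#' One row per discordant locus: position, alleles, the two consensus
#' genotypes, the discordance pattern, and per-sample per-replicate read
#' support, GQ and Hb. Rows are written in (chrom, pos) order regardless of
#' input order, so the output is canonical.
#'
#' @param records a discordance table from [find_discordances()] (possibly
#'   empty).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(records, path) {
  records <- data.table::as.data.table(records)
  if (!nrow(records) && !ncol(records)) {
    records <- data.table::setnames(
      data.table::as.data.table(lapply(candidate_fixed_cols, function(x) character(0))),
      candidate_fixed_cols)
  }
  missing_cols <- setdiff(candidate_fixed_cols, names(records))
  if (length(missing_cols)) {
    stop("candidate table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(records), candidate_fixed_cols)
  data.table::setcolorder(records, c(candidate_fixed_cols, extra))
  data.table::setorder(records, chrom, pos)
  data.table::fwrite(records, path, sep = "\t", eol = "\n")
  invisible(path)
}

#' Read a candidates file written by [write_candidates()]
#'
#' @param path candidates TSV path.
#' @return a data.table with at least chrom, pos, ref, alt.
#' @export
read_candidates <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  missing_cols <- setdiff(c("chrom", "pos", "ref", "alt"), names(dt))
  if (length(missing_cols)) {
    stop("candidates file lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  dt
}
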