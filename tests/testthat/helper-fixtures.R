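# Shared fixture builders. Everything is constructed in code — no binary or
# stored test data.

library(data.table)  # tests use data.table syntax on package-returned tables

# one-row call constructor with sane defaults
make_call <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                      genotype = "het", ref_count = 15L, alt_count = 15L,
                      other_count = 0L, gq = 50L) {
  data.table::data.table(chrom = chrom, pos = as.integer(pos), ref = ref,
                         alt = alt, genotype = genotype,
                         ref_count = as.integer(ref_count),
                         alt_count = as.integer(alt_count),
                         other_count = as.integer(other_count),
                         gq = as.integer(gq))
}

# build a sample_calls replicate from a data.frame of (partial) call specs
make_replicate <- function(calls, sample_id = "trace", replicate_id = "rep1") {
  twinsnv::sample_calls(calls, sample_id = sample_id,
                        replicate_id = replicate_id,
                        contig_lengths = c(chr1 = 1e6))
}

# a pair of identical high-quality replicates over the given calls
make_rep_pair <- function(calls, sample_id = "trace") {
  list(make_replicate(calls, sample_id, "rep1"),
       make_replicate(calls, sample_id, "rep2"))
}

# write VCF text lines (header + records) to a temp file
write_vcf_text <- function(records, samples = "S1",
                           contig = "##contig=<ID=chr1,length=1000000>") {
  path <- tempfile(fileext = ".vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    contig,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, records), path)
  path
}

# exact probability that a depth-d binomial(0.5) heterozygote lands inside an
# inclusive Hb window [lo, hi]; brute-force oracle, independent of the
# package's filter path
hb_window_prob <- function(d, lo, hi, p = 0.5) {
  k <- 0:d
  sum(stats::dbinom(k[k / d >= lo & k / d <= hi], d, p))
}

# independent re-derivation of the binomial-likelihood genotype caller used
# as the enumeration oracle: returns "hom_ref"/"het"/"hom_alt" for (k of n)
oracle_genotype <- function(k, n, e) {
  ll <- c(stats::dbinom(k, n, e / 3, log = TRUE),
          stats::dbinom(k, n, 0.5, log = TRUE),
          stats::dbinom(k, n, 1 - e, log = TRUE))
  c("hom_ref", "het", "hom_alt")[which.max(ll)]
}
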