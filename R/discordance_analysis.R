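# Cross-sample comparison: the comparison domain, discordance detection and
# classification, the heterozygote-balance stringency sweep, and breadth /
# mean-depth coverage summaries.

#' Loci eligible for trace-vs-reference comparison
#'
#' The comparison domain contains the loci with an accepted consensus
#' genotype in BOTH samples where at least one sample's genotype is not
#' hom_ref — i.e. a variant was identified in at least one sample.
#' Comparing hom_ref/hom_ref loci would be vacuous, and requiring the
#' variant in both samples would make hom-vs-het discordances impossible.
#'
#' @param trace,reference consensus tables from [consensus_genotypes()].
#' @return data.table of loci (chrom, pos, ref, alt) keyed by (chrom, pos).
#' @export
comparison_domain <- function(trace, reference) {
  m <- merge(trace[, .(chrom, pos, ref, alt, tg = genotype)],
             reference[, .(chrom, pos, ref, alt, rg = genotype)],
             by = c("chrom", "pos", "ref", "alt"))
  dom <- m[tg != "hom_ref" | rg != "hom_ref", .(chrom, pos, ref, alt)]
  data.table::setkeyv(dom, c("chrom", "pos"))
  dom[]
}

classify_pattern <- function(tg, rg) {
  data.table::fcase(
    tg == "het" & rg != "het", "het_vs_hom",
    tg != "het" & rg == "het", "hom_vs_het",
    default = "hom_vs_hom"
  )
}

#' Detect loci with discordant consensus genotypes
#'
#' Compares the trace and reference consensus genotypes over the comparison
#' domain and reports one record per locus where they differ, classified as
#' `hom_vs_het` (trace homozygous, reference heterozygous), `het_vs_hom`, or
#' `hom_vs_hom`. Per-sample per-replicate read support, GQ and Hb are
#' carried along as evidence, prefixed `trace_` / `reference_`. Output is in
#' (chrom, pos) order.
#'
#' @param trace,reference consensus tables from [consensus_genotypes()].
#' @param domain optional precomputed [comparison_domain()]; defaults to
#'   computing it from the two inputs.
#' @return data.table of discordant loci (possibly empty, schema preserved).
#' @export
find_discordances <- function(trace, reference,
                              domain = comparison_domain(trace, reference)) {
  key <- c("chrom", "pos", "ref", "alt")
  evid <- function(cons, prefix) {
    cols <- grep("^(ref|alt|other|gq|hb)_r[0-9]+$", names(cons), value = TRUE)
    out <- cons[, c(key, "genotype", cols), with = FALSE]
    data.table::setnames(out, c("genotype", cols),
                         paste0(prefix, "_", c("genotype", cols)))
    out
  }
  m <- merge(domain, evid(trace, "trace"), by = key)
  m <- merge(m, evid(reference, "reference"), by = key)
  disc <- m[trace_genotype != reference_genotype]
  disc[, pattern := classify_pattern(trace_genotype, reference_genotype)]
  data.table::setcolorder(disc, c(key, "trace_genotype",
                                  "reference_genotype", "pattern"))
  data.table::setorder(disc, chrom, pos)
  disc[]
}

#' Default heterozygote-balance sweep schemes
#'
#' The four standard stringency levels: no Hb filter, a broad window
#' (0.2-0.8), a medium window (0.4-0.6) and a narrow window (0.45-0.55).
#'
#' @return data.frame with columns label, hb_low, hb_high.
#' @export
default_sweep_schemes <- function() {
  data.frame(
    label = c("none", "0.2-0.8", "0.4-0.6", "0.45-0.55"),
    hb_low = c(NA, 0.2, 0.4, 0.45),
    hb_high = c(NA, 0.8, 0.6, 0.55)
  )
}

# "none" or "LO:HI" -> one scheme row
parse_scheme <- function(s) {
  s <- trimws(s)
  if (identical(tolower(s), "none")) {
    return(data.frame(label = "none", hb_low = NA_real_, hb_high = NA_real_))
  }
  parts <- strsplit(s, ":", fixed = TRUE)[[1]]
  lo <- suppressWarnings(as.numeric(parts[1]))
  hi <- suppressWarnings(as.numeric(parts[2]))
  if (length(parts) != 2L || is.na(lo) || is.na(hi) || lo > hi ||
      lo < 0 || hi > 1) {
    stop("malformed Hb scheme '", s, "' (expected LO:HI in [0,1] or 'none')")
  }
  data.frame(label = sprintf("%g-%g", lo, hi), hb_low = lo, hb_high = hi)
}

#' Heterozygote-balance stringency sweep
#'
#' Re-runs consensus building, comparison-domain construction and
#' discordance detection once per scheme, replacing only the Hb window of
#' the base configuration — depth and quality floors are held fixed. As the
#' window narrows, retained genotypes, compared loci and discordances can
#' only shrink (set inclusion), so the counts are non-increasing with
#' stringency.
#'
#' @param trace_reps,reference_reps lists of [sample_calls()] replicates.
#' @param schemes data.frame with columns label, hb_low, hb_high (default
#'   [default_sweep_schemes()]); labels must be unique.
#' @param config base [filter_config()] supplying dp_min/gq_min.
#' @return data.table with one row per scheme, in input order: label,
#'   hb_low, hb_high, retained_trace, retained_reference, retained_combined
#'   (counts of variant consensus genotypes), compared_loci,
#'   discordant_loci. The attribute `"discordances"` is a named list of the
#'   per-scheme discordance tables.
#' @export
hb_sweep <- function(trace_reps, reference_reps,
                     schemes = default_sweep_schemes(),
                     config = filter_preset("shotgun")) {
  schemes <- as.data.frame(schemes)
  if (!nrow(schemes)) stop("empty scheme list")
  if (anyDuplicated(schemes$label)) stop("sweep scheme labels must be unique")
  rows <- vector("list", nrow(schemes))
  disc_tabs <- vector("list", nrow(schemes))
  names(disc_tabs) <- schemes$label
  for (i in seq_len(nrow(schemes))) {
    cfg <- filter_config(config$dp_min, config$gq_min,
                         hb_low = schemes$hb_low[i],
                         hb_high = schemes$hb_high[i],
                         noise_max = config$noise_max,
                         biallelic_only = config$biallelic_only)
    tcons <- consensus_genotypes(trace_reps, cfg)
    rcons <- consensus_genotypes(reference_reps, cfg)
    dom <- comparison_domain(tcons, rcons)
    disc <- find_discordances(tcons, rcons, dom)
    rt <- sum(tcons$genotype != "hom_ref")
    rr <- sum(rcons$genotype != "hom_ref")
    rows[[i]] <- data.table::data.table(
      label = schemes$label[i],
      hb_low = schemes$hb_low[i], hb_high = schemes$hb_high[i],
      retained_trace = rt, retained_reference = rr,
      retained_combined = rt + rr,
      compared_loci = nrow(dom), discordant_loci = nrow(disc)
    )
    disc_tabs[[i]] <- disc
  }
  out <- data.table::rbindlist(rows)
  data.table::setattr(out, "discordances", disc_tabs)
  out[]
}

#' Breadth of coverage and mean depth over two replicates
#'
#' A position counts as covered when its depth reaches `dp_min` in BOTH
#' replicates of the sample. Breadth is covered positions divided by a
#' caller-supplied genome-size denominator (the VCF header contig total or,
#' failing that, 3.2e9 are the usual choices); mean depth averages the two
#' replicate depths over covered positions only.
#'
#' @param depth_rep1,depth_rep2 data.frames with columns `pos` (optionally
#'   `chrom`) and `depth`; positions absent from a table have depth 0.
#' @param dp_min depth threshold (default 8).
#' @param denominator positive genome-size normalizer.
#' @return list with covered_positions, denominator, breadth and mean_depth
#'   (`NA` when nothing is covered).
#' @export
coverage_summary <- function(depth_rep1, depth_rep2, dp_min = 8L,
                             denominator) {
  if (missing(denominator) || is.null(denominator) || denominator <= 0) {
    stop("coverage_summary needs a positive denominator")
  }
  norm <- function(x) {
    x <- data.table::as.data.table(x)
    if (!"chrom" %in% names(x)) x[, chrom := "genome"]
    stopifnot(all(c("pos", "depth") %in% names(x)))
    x[, .(chrom, pos, depth)]
  }
  m <- merge(norm(depth_rep1), norm(depth_rep2),
             by = c("chrom", "pos"), all = TRUE, suffixes = c("_1", "_2"))
  d1 <- data.table::fifelse(is.na(m$depth_1), 0, as.numeric(m$depth_1))
  d2 <- data.table::fifelse(is.na(m$depth_2), 0, as.numeric(m$depth_2))
  cov <- d1 >= dp_min & d2 >= dp_min
  covered <- sum(cov)
  list(
    covered_positions = covered,
    denominator = denominator,
    breadth = covered / denominator,
    mean_depth = if (covered > 0) mean((d1[cov] + d2[cov]) / 2) else NA_real_
  )
}
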