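# Seeded twin-pair read-count simulator. It states a small world with the
# three variant categories that matter for MZ-twin discrimination:
#   germline      — shared by both twins (the zygote's genome);
#   post_zygotic  — constitutional in ONE twin, alt fraction 0.5 in every
#                   tissue of that twin;
#   somatic       — tissue-specific, present in one SAMPLE only, with a
#                   skewed alt-read fraction (default Uniform(0.05, 0.20)).
# Read counts are Poisson depth with a three-way ref/alt/other draw that
# includes a uniform miscall model, and genotypes are re-called from the
# counts with a binomial-likelihood model so DP/GQ/Hb filters see realistic
# inputs. Everything is deterministic under the configured seed.

CHR1_LENGTH <- 248956422L  # GRCh38 chr1; the simulated world is one contig

#' Simulation configuration
#'
#' Defaults state the scenario the pipeline is designed for: a trace (blood)
#' and a reference (buccal) sample from monozygotic twins, sequenced in
#' duplicate at genome-typical depths (39.7x trace, 25.8x reference), with a
#' Poisson(14) expected count of twin-specific post-zygotic heterozygous
#' mutations per twin and tissue-specific somatic variants at alt-read
#' fractions of 5-20%.
#'
#' @param n_loci number of variant-capable positions simulated.
#' @param p_het,p_hom_alt germline genotype probabilities per locus
#'   (`p_hom_ref` is the remainder).
#' @param lambda_postzygotic expected twin-specific constitutional
#'   heterozygous mutations per twin (Poisson; default 14).
#' @param postzygotic_exact plant exactly `round(lambda_postzygotic)`
#'   mutations per twin instead of drawing a Poisson count — useful when a
#'   validation scenario calls for a fixed number of planted differences.
#' @param n_somatic tissue-specific somatic variants planted per sample.
#' @param somatic_fraction_low,somatic_fraction_high alt-read-fraction bounds
#'   for somatic variants (defaults 0.05, 0.20).
#' @param mean_depth_trace,mean_depth_reference Poisson mean depths.
#' @param error_rate per-read miscall probability.
#' @param n_replicates independent replicates per sample (>= 2).
#' @param panel_depth Poisson mean depth for targeted-panel simulation.
#' @param undesignable_rate fraction of candidate loci expected to be
#'   undesignable for an amplicon panel (default 11/28).
#' @param trace_twin,reference_twin which twin (1 or 2) each sample comes
#'   from; set both to the same twin to emulate a same-source trace.
#' @param seed integer seed fixing all randomness.
#' @return an object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_loci = 200000L,
                              p_het = 0.45, p_hom_alt = 0.25,
                              lambda_postzygotic = 14,
                              postzygotic_exact = FALSE,
                              n_somatic = 50L,
                              somatic_fraction_low = 0.05,
                              somatic_fraction_high = 0.20,
                              mean_depth_trace = 39.7,
                              mean_depth_reference = 25.8,
                              error_rate = 0.002,
                              n_replicates = 2L,
                              panel_depth = 500,
                              undesignable_rate = 11 / 28,
                              trace_twin = 1L, reference_twin = 2L,
                              seed = 1L) {
  cfg <- list(n_loci = as.integer(n_loci), p_het = p_het,
              p_hom_alt = p_hom_alt,
              lambda_postzygotic = lambda_postzygotic,
              postzygotic_exact = isTRUE(postzygotic_exact),
              n_somatic = as.integer(n_somatic),
              somatic_fraction_low = somatic_fraction_low,
              somatic_fraction_high = somatic_fraction_high,
              mean_depth_trace = mean_depth_trace,
              mean_depth_reference = mean_depth_reference,
              error_rate = error_rate,
              n_replicates = as.integer(n_replicates),
              panel_depth = panel_depth,
              undesignable_rate = undesignable_rate,
              trace_twin = as.integer(trace_twin),
              reference_twin = as.integer(reference_twin),
              seed = as.integer(seed))
  stopifnot(cfg$n_loci > 0L,
            cfg$p_het >= 0, cfg$p_hom_alt >= 0,
            cfg$p_het + cfg$p_hom_alt <= 1,
            cfg$lambda_postzygotic >= 0, cfg$n_somatic >= 0L,
            cfg$somatic_fraction_low >= 0,
            cfg$somatic_fraction_low <= cfg$somatic_fraction_high,
            cfg$somatic_fraction_high <= 1,
            cfg$mean_depth_trace > 0, cfg$mean_depth_reference > 0,
            cfg$error_rate >= 0, cfg$error_rate <= 1,
            cfg$n_replicates >= 2L, cfg$panel_depth > 0,
            cfg$undesignable_rate >= 0, cfg$undesignable_rate <= 1,
            cfg$trace_twin %in% 1:2, cfg$reference_twin %in% 1:2)
  structure(cfg, class = "simulation_config")
}

#' Draw replicate read support for given true alt fractions
#'
#' Depth is Poisson(`mean_depth`) (or fixed via `depth`); each read is then
#' assigned by a three-way draw with `p_alt = f(1-e) + (1-f)e/3`,
#' `p_other = 2e/3` and `p_ref = 1 - p_alt - p_other`, i.e. miscalls
#' distribute uniformly over the three non-true bases.
#'
#' @param f numeric vector of true alt-read fractions in `[0, 1]`.
#' @param mean_depth Poisson mean depth.
#' @param error_rate per-read miscall probability `e`.
#' @param depth optional fixed depth (recycled), overriding the Poisson draw.
#' @return data.table with columns ref_count, alt_count, other_count, dp.
#' @export
sample_read_support <- function(f, mean_depth, error_rate = 0, depth = NULL) {
  stopifnot(all(f >= 0 & f <= 1), error_rate >= 0, error_rate <= 1)
  n <- length(f)
  dp <- if (is.null(depth)) rpois(n, mean_depth) else
    as.integer(rep_len(depth, n))
  e <- error_rate
  p_alt <- f * (1 - e) + (1 - f) * e / 3
  p_other <- 2 * e / 3
  alt <- rbinom(n, dp, p_alt)
  q <- ifelse(p_alt >= 1, 0, p_other / (1 - p_alt))
  other <- rbinom(n, dp - alt, q)
  data.table::data.table(ref_count = as.integer(dp - alt - other),
                         alt_count = as.integer(alt),
                         other_count = as.integer(other),
                         dp = as.integer(dp))
}

#' Call genotypes and genotype qualities from read counts
#'
#' A deliberately simple stand-in for an upstream caller's model: the
#' likelihood of each diploid genotype is the binomial probability of
#' `alt_count` among the `ref_count + alt_count` allele-informative reads
#' with alt probability `e/3` (hom_ref), `0.5` (het) or `1 - e` (hom_alt).
#' The call is the argmax and `GQ = round(10 log10(L_best / L_second))`,
#' capped at 99. Zero allele-informative reads yield a missing genotype with
#' GQ 0.
#'
#' @param ref_count,alt_count integer vectors of allele-supporting reads.
#' @param error_rate per-read miscall probability used by the model.
#' @return data.table with columns genotype and gq.
#' @export
genotype_from_counts <- function(ref_count, alt_count, error_rate = 0.001) {
  n_reads <- ref_count + alt_count
  ll_hr <- dbinom(alt_count, n_reads, error_rate / 3, log = TRUE)
  ll_het <- dbinom(alt_count, n_reads, 0.5, log = TRUE)
  ll_ha <- dbinom(alt_count, n_reads, 1 - error_rate, log = TRUE)
  m <- cbind(ll_hr, ll_het, ll_ha)
  best <- max.col(m, ties.method = "first")
  best_ll <- m[cbind(seq_along(best), best)]
  second_ll <- data.table::fcase(
    best == 1L, pmax(ll_het, ll_ha),
    best == 2L, pmax(ll_hr, ll_ha),
    best == 3L, pmax(ll_hr, ll_het)
  )
  gq <- as.integer(pmin(99, pmax(0, round(10 * (best_ll - second_ll) / log(10)))))
  genotype <- c("hom_ref", "het", "hom_alt")[best]
  missing <- n_reads == 0L
  genotype[missing] <- "missing"
  gq[missing] <- 0L
  data.table::data.table(genotype = genotype, gq = gq)
}

# alt fraction implied by a constitutional diploid genotype
gt_to_fraction <- function(gt) {
  c(hom_ref = 0, het = 0.5, hom_alt = 1)[gt]
}

# realize one sample's replicates from its per-locus true alt fractions
realize_sample <- function(loci, f, sample_id, mean_depth, error_rate,
                           n_replicates, contig_lengths, depth = NULL) {
  lapply(seq_len(n_replicates), function(i) {
    sup <- sample_read_support(f, mean_depth, error_rate, depth = depth)
    gt <- genotype_from_counts(sup$ref_count, sup$alt_count, error_rate)
    calls <- data.table::data.table(
      chrom = loci$chrom, pos = loci$pos, ref = loci$ref, alt = loci$alt,
      genotype = gt$genotype,
      ref_count = sup$ref_count, alt_count = sup$alt_count,
      other_count = sup$other_count, gq = gt$gq
    )
    sample_calls(calls, sample_id = sample_id,
                 replicate_id = paste0("rep", i),
                 contig_lengths = contig_lengths)
  })
}

#' Simulate a monozygotic twin pair and its sequenced samples
#'
#' Draws germline genotypes shared by both twins, plants Poisson-distributed
#' twin-specific post-zygotic heterozygous mutations at hom_ref loci (alt
#' fraction 0.5 in every tissue of the carrier twin), plants tissue-specific
#' somatic variants in each SAMPLE at skewed alt fractions, and realizes
#' `n_replicates` independent read-count replicates per sample. The trace
#' sample comes from `trace_twin`, the reference from `reference_twin`.
#'
#' @param config a [simulation_config()].
#' @return an object of class `twin_simulation`: a list with `config`,
#'   `truth` (one row per locus: chrom, pos, ref, alt, category, twin1_gt,
#'   twin2_gt, sample, alt_fraction), `fractions` (true per-sample alt
#'   fractions used for read sampling), and `trace` / `reference` (lists of
#'   [sample_calls()] replicates).
#' @export
simulate_twin_pair <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_loci

  pos <- sort(sample.int(CHR1_LENGTH, n))
  ref_idx <- sample.int(4L, n, replace = TRUE)
  alt_idx <- (ref_idx - 1L + sample.int(3L, n, replace = TRUE)) %% 4L + 1L
  loci <- data.table::data.table(chrom = "chr1", pos = pos,
                                 ref = NUCLEOTIDES[ref_idx],
                                 alt = NUCLEOTIDES[alt_idx])

  p_hom_ref <- 1 - config$p_het - config$p_hom_alt
  germline <- sample(CALLED_GENOTYPES, n, replace = TRUE,
                     prob = c(p_hom_ref, config$p_het, config$p_hom_alt))
  twin1 <- twin2 <- germline
  category <- rep("germline", n)

  if (config$postzygotic_exact) {
    k1 <- k2 <- as.integer(round(config$lambda_postzygotic))
  } else {
    k1 <- rpois(1, config$lambda_postzygotic)
    k2 <- rpois(1, config$lambda_postzygotic)
  }
  hom_ref_pool <- which(germline == "hom_ref")
  if (k1 + k2 + 2L * config$n_somatic > length(hom_ref_pool)) {
    stop("not enough hom_ref loci to plant post-zygotic and somatic variants")
  }
  planted <- sample(hom_ref_pool, k1 + k2 + 2L * config$n_somatic)
  pz1 <- planted[seq_len(k1)]
  pz2 <- planted[k1 + seq_len(k2)]
  som_trace <- planted[k1 + k2 + seq_len(config$n_somatic)]
  som_ref <- planted[k1 + k2 + config$n_somatic + seq_len(config$n_somatic)]
  twin1[pz1] <- "het"
  twin2[pz2] <- "het"
  category[pz1] <- "post_zygotic_twin1"
  category[pz2] <- "post_zygotic_twin2"
  category[c(som_trace, som_ref)] <- "somatic"

  twin_gt <- cbind(twin1, twin2)
  f_trace <- unname(gt_to_fraction(twin_gt[, config$trace_twin]))
  f_reference <- unname(gt_to_fraction(twin_gt[, config$reference_twin]))
  f_trace[som_trace] <- runif(config$n_somatic,
                              config$somatic_fraction_low,
                              config$somatic_fraction_high)
  f_reference[som_ref] <- runif(config$n_somatic,
                                config$somatic_fraction_low,
                                config$somatic_fraction_high)

  somatic_sample <- rep(NA_character_, n)
  somatic_sample[som_trace] <- "trace"
  somatic_sample[som_ref] <- "reference"
  alt_fraction <- rep(NA_real_, n)
  alt_fraction[category %in% c("post_zygotic_twin1", "post_zygotic_twin2")] <- 0.5
  alt_fraction[som_trace] <- f_trace[som_trace]
  alt_fraction[som_ref] <- f_reference[som_ref]

  truth <- data.table::data.table(
    chrom = loci$chrom, pos = loci$pos, ref = loci$ref, alt = loci$alt,
    category = category, twin1_gt = twin1, twin2_gt = twin2,
    sample = somatic_sample, alt_fraction = alt_fraction
  )
  contig_lengths <- c(chr1 = CHR1_LENGTH)
  trace <- realize_sample(loci, f_trace, "trace", config$mean_depth_trace,
                          config$error_rate, config$n_replicates,
                          contig_lengths)
  reference <- realize_sample(loci, f_reference, "reference",
                              config$mean_depth_reference,
                              config$error_rate, config$n_replicates,
                              contig_lengths)
  structure(
    list(config = config, truth = truth,
         fractions = data.table::data.table(
           chrom = loci$chrom, pos = loci$pos,
           f_trace = f_trace, f_reference = f_reference),
         trace = trace, reference = reference),
    class = "twin_simulation"
  )
}

#' @export
print.twin_simulation <- function(x, ...) {
  cat(sprintf(
    "twin_simulation: %d loci, %d post-zygotic (twin1 %d / twin2 %d), %d somatic, %d replicates/sample, seed %d\n",
    x$config$n_loci,
    sum(x$truth$category %in% c("post_zygotic_twin1", "post_zygotic_twin2")),
    sum(x$truth$category == "post_zygotic_twin1"),
    sum(x$truth$category == "post_zygotic_twin2"),
    sum(x$truth$category == "somatic"),
    x$config$n_replicates, x$config$seed))
  invisible(x)
}

#' Simulate targeted-panel sequencing of selected loci
#'
#' Re-sequences the given loci in both samples at `panel_depth`, using the
#' same true alt fractions as the shotgun simulation — a post-zygotic
#' difference stays discordant at panel depth, a somatic variant keeps its
#' skewed fraction, and sampling noise is redrawn independently. Randomness
#' is derived deterministically from the simulation seed, so panel draws do
#' not perturb (and are not perturbed by) the shotgun draws.
#'
#' @param sim a [simulate_twin_pair()] result.
#' @param loci data.frame with chrom and pos (e.g. candidate + control loci).
#' @return list with elements `trace` and `reference`, each a list of
#'   [sample_calls()] replicates at panel depth.
#' @export
simulate_panel <- function(sim, loci) {
  stopifnot(inherits(sim, "twin_simulation"))
  loci <- data.table::as.data.table(loci)[, .(chrom, pos)]
  fr <- merge(loci, sim$fractions, by = c("chrom", "pos"), sort = TRUE)
  if (nrow(fr) < nrow(unique(loci))) {
    stop("simulate_panel: some requested loci were never simulated")
  }
  key <- merge(fr, sim$truth[, .(chrom, pos, ref, alt)],
               by = c("chrom", "pos"), sort = TRUE)
  cfg <- sim$config
  set.seed(cfg$seed + 97L)
  contig_lengths <- c(chr1 = CHR1_LENGTH)
  list(
    trace = realize_sample(key, key$f_trace, "trace", cfg$panel_depth,
                           cfg$error_rate, cfg$n_replicates, contig_lengths),
    reference = realize_sample(key, key$f_reference, "reference",
                               cfg$panel_depth, cfg$error_rate,
                               cfg$n_replicates, contig_lengths)
  )
}

#' Pick identity-SNP control loci from a simulation
#'
#' Controls emulate a standard human-identification SNP set: germline loci
#' where both twins carry the same variant genotype. Selection is
#' deterministic given the simulation seed.
#'
#' @param sim a [simulate_twin_pair()] result.
#' @param n number of control loci (default 54).
#' @return data.table with chrom, pos, ref, alt.
#' @export
select_control_loci <- function(sim, n = 54L) {
  stopifnot(inherits(sim, "twin_simulation"))
  pool <- sim$truth[category == "germline" & twin1_gt != "hom_ref" &
                      twin1_gt == twin2_gt]
  if (nrow(pool) < n) stop("fewer than ", n, " eligible control loci")
  set.seed(sim$config$seed + 193L)
  idx <- sort(sample.int(nrow(pool), n))
  pool[idx, .(chrom, pos, ref, alt)]
}

#' Sample an undesignable subset of candidate loci
#'
#' Emulates amplicon-panel design loss: each candidate is dropped
#' independently with probability `rate` (default the configured
#' undesignable rate, anchored at 11/28).
#'
#' @param candidates data.frame with chrom, pos, ref, alt.
#' @param rate drop probability per candidate.
#' @param seed integer seed.
#' @return logical vector, TRUE where the candidate is undesignable.
#' @export
sample_undesignable <- function(candidates, rate, seed) {
  set.seed(as.integer(seed) + 389L)
  runif(nrow(data.table::as.data.table(candidates))) < rate
}

#' Write a simulation to disk
#'
#' Emits `trace_rep<i>.vcf` and `reference_rep<i>.vcf` for every replicate,
#' `truth.tsv`, and `config.json` (an echo of the configuration). When
#' `panel_loci` is given, panel VCFs `panel_<sample>_rep<i>.vcf` are
#' generated via [simulate_panel()] as well. All VCFs round-trip through
#' [read_sample_calls()].
#'
#' @param sim a [simulate_twin_pair()] result.
#' @param out_dir output directory (created if needed).
#' @param panel_loci optional data.frame of loci to panel-sequence.
#' @return named character vector of the files written, invisibly.
#' @export
write_simulation <- function(sim, out_dir, panel_loci = NULL) {
  stopifnot(inherits(sim, "twin_simulation"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (s in c("trace", "reference")) {
    for (i in seq_along(sim[[s]])) {
      p <- file.path(out_dir, sprintf("%s_rep%d.vcf", s, i))
      write_vcf(sim[[s]][[i]], p)
      files[sprintf("%s_rep%d", s, i)] <- p
    }
  }
  truth_path <- file.path(out_dir, "truth.tsv")
  data.table::fwrite(sim$truth, truth_path, sep = "\t", eol = "\n")
  files["truth"] <- truth_path
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(sim$config), cfg_path, auto_unbox = TRUE,
                       digits = NA)
  files["config"] <- cfg_path
  if (!is.null(panel_loci)) {
    panel <- simulate_panel(sim, panel_loci)
    for (s in c("trace", "reference")) {
      for (i in seq_along(panel[[s]])) {
        p <- file.path(out_dir, sprintf("panel_%s_rep%d.vcf", s, i))
        write_vcf(panel[[s]][[i]], p)
        files[sprintf("panel_%s_rep%d", s, i)] <- p
      }
    }
  }
  invisible(files)
}
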