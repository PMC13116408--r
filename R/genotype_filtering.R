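# Per-replicate genotype acceptance and within-sample replicate-concordance
# consensus. A genotype enters any downstream comparison only if every
# replicate's call passes the active filter AND all replicates agree
# (both-must-pass reading: accepting single-replicate genotypes would inflate
# the comparison domain with calls the concordance requirement was designed
# to exclude).

NO_CONSENSUS_REASONS <- c("replicate_failed_filter", "replicate_discordant",
                          "insufficient_replicates")

#' Test genotype calls against an acceptance regime
#'
#' A call is accepted iff all of: the genotype is called (not missing);
#' `dp >= dp_min`; `gq >= gq_min`; for heterozygotes, the heterozygote
#' balance lies inside the configured window (inclusive); for homozygotes,
#' the noise is strictly below the configured ceiling. The rejection reason
#' is the first failed criterion in the fixed order
#' missing, depth, quality, balance, noise, so rejection statistics are
#' deterministic. A heterozygote with no allele-informative reads has an
#' undefined balance and is rejected with reason `balance`; a homozygote at
#' zero depth is rejected with reason `noise` when that filter is active.
#'
#' @param calls data.frame/data.table of calls (columns genotype, ref_count,
#'   alt_count, other_count, gq; dp derived if absent), or a [sample_calls()]
#'   object.
#' @param config a [filter_config()].
#' @return data.table with columns `accepted` (logical) and `reason`
#'   (character, `NA` for accepted calls), one row per input call.
#' @export
accept_genotype <- function(calls, config) {
  stopifnot(inherits(config, "filter_config"))
  if (inherits(calls, "sample_calls")) calls <- calls$calls
  calls <- data.table::as.data.table(calls)
  if (!"dp" %in% names(calls)) {
    calls <- data.table::copy(calls)
    calls[, dp := ref_count + alt_count + other_count]
  }
  n <- nrow(calls)
  reason <- rep(NA_character_, n)
  pick <- function(cond, code) {
    sel <- cond & is.na(reason)
    reason[sel] <<- code
  }
  pick(calls$genotype == "missing", "missing")
  pick(calls$dp < config$dp_min, "depth")
  pick(calls$gq < config$gq_min, "quality")
  if (!is.na(config$hb_low)) {
    hb <- hb_or_na(calls$ref_count, calls$alt_count)
    bad_hb <- calls$genotype == "het" &
      (is.na(hb) | hb < config$hb_low | hb > config$hb_high)
    pick(bad_hb, "balance")
  }
  if (!is.na(config$noise_max)) {
    noise <- noise_or_na(calls$genotype, calls$ref_count, calls$alt_count,
                         calls$other_count)
    bad_noise <- calls$genotype %in% c("hom_ref", "hom_alt") &
      (is.na(noise) | noise >= config$noise_max)
    pick(bad_noise, "noise")
  }
  data.table::data.table(accepted = is.na(reason), reason = reason)
}

#' Replicate-concordance consensus at a single locus
#'
#' Returns a consensus genotype iff every replicate call is individually
#' accepted under `config` and all called genotypes are identical; otherwise
#' a no-consensus result with a reason. This is the per-locus contract;
#' [consensus_genotypes()] applies it across whole call sets.
#'
#' @param calls data.frame of calls at one locus, one row per replicate
#'   (same chrom/pos/ref/alt on every row).
#' @param config a [filter_config()].
#' @return list with `consensus` (logical), and either `genotype`,
#'   `n_replicates` and `support` (the input rows) or `reason` (one of
#'   `replicate_failed_filter`, `replicate_discordant`,
#'   `insufficient_replicates`).
#' @export
replicate_consensus <- function(calls, config) {
  calls <- data.table::as.data.table(calls)
  if (nrow(calls) < 2L) {
    return(list(consensus = FALSE, reason = "insufficient_replicates"))
  }
  if (data.table::uniqueN(calls, by = c("chrom", "pos", "ref", "alt")) != 1L) {
    stop("replicate_consensus: calls span more than one locus")
  }
  acc <- accept_genotype(calls, config)
  if (!all(acc$accepted)) {
    return(list(consensus = FALSE, reason = "replicate_failed_filter"))
  }
  if (data.table::uniqueN(calls$genotype) != 1L) {
    return(list(consensus = FALSE, reason = "replicate_discordant"))
  }
  list(consensus = TRUE, genotype = calls$genotype[1],
       n_replicates = nrow(calls), support = calls)
}

#' Build consensus genotypes for one sample across its replicates
#'
#' Applies [accept_genotype()] to every replicate call set, then retains the
#' loci where all replicates carry an accepted, identical genotype. A locus
#' absent from any replicate counts as a missing call there and therefore
#' yields no consensus.
#'
#' @param replicates list (length >= 2) of [sample_calls()] objects for the
#'   same sample.
#' @param config a [filter_config()].
#' @return data.table keyed by (chrom, pos) with columns chrom, pos, ref,
#'   alt, genotype, n_replicates and per-replicate support columns
#'   `ref_r<i>`, `alt_r<i>`, `other_r<i>`, `gq_r<i>`, `hb_r<i>`. The
#'   attribute `"rejections"` tabulates no-consensus loci by reason and the
#'   attribute `"sample_id"` carries the sample name.
#' @export
consensus_genotypes <- function(replicates, config) {
  stopifnot(length(replicates) >= 2L,
            all(vapply(replicates, inherits, logical(1), "sample_calls")))
  n_rep <- length(replicates)
  wide <- NULL
  for (i in seq_len(n_rep)) {
    calls <- replicates[[i]]$calls
    acc <- accept_genotype(calls, config)
    part <- calls[, .(chrom, pos, ref, alt)]
    part[, paste0("gt_r", i) := calls$genotype]
    part[, paste0("acc_r", i) := acc$accepted]
    part[, paste0("ref_r", i) := calls$ref_count]
    part[, paste0("alt_r", i) := calls$alt_count]
    part[, paste0("other_r", i) := calls$other_count]
    part[, paste0("gq_r", i) := calls$gq]
    part[, paste0("hb_r", i) := hb_or_na(calls$ref_count, calls$alt_count)]
    wide <- if (is.null(wide)) part else
      merge(wide, part, by = c("chrom", "pos", "ref", "alt"), all = TRUE)
  }
  gt_cols <- paste0("gt_r", seq_len(n_rep))
  acc_cols <- paste0("acc_r", seq_len(n_rep))
  gt_mat <- as.matrix(wide[, gt_cols, with = FALSE])
  acc_mat <- as.matrix(wide[, acc_cols, with = FALSE])
  acc_sum <- rowSums(acc_mat)  # NA wherever a replicate lacks the locus
  all_acc <- !is.na(acc_sum) & acc_sum == n_rep
  same_gt <- !is.na(gt_mat[, 1]) &
    rowSums(gt_mat == gt_mat[, 1], na.rm = TRUE) == n_rep
  ok <- all_acc & same_gt

  reason <- rep(NA_character_, nrow(wide))
  reason[!all_acc] <- "replicate_failed_filter"
  reason[all_acc & !same_gt] <- "replicate_discordant"
  rejections <- table(reason[!ok])

  out <- wide[ok]
  out[, genotype := gt_mat[ok, 1]]
  out[, n_replicates := n_rep]
  out[, c(gt_cols, acc_cols) := NULL]
  data.table::setcolorder(out, c("chrom", "pos", "ref", "alt", "genotype",
                                 "n_replicates"))
  data.table::setkeyv(out, c("chrom", "pos"))
  data.table::setattr(out, "rejections", rejections)
  data.table::setattr(out, "sample_id", replicates[[1]]$sample_id)
  out[]
}
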