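# Targeted-panel confirmation stage: candidate loci from the shotgun
# comparison are re-genotyped at high depth under the stricter targeted
# filter regime and each receives a verdict; identity-SNP controls gate a
# run-quality flag but never influence the case outcome.

VERDICTS <- c("confirmed_discordant", "rejected_concordant", "inconclusive")

#' Construct a panel design
#'
#' The design partitions loci into targets (candidates carried into the
#' panel), dropped candidates (e.g. primer-undesignable positions) and
#' identity-SNP controls. Targets and dropped loci must be disjoint; all
#' loci are biallelic SNVs.
#'
#' @param targets,controls,dropped data.frames with columns chrom, pos, ref,
#'   alt (`dropped` may carry a `reason` column, default "undesignable").
#' @return an object of class `panel_design`.
#' @export
panel_design <- function(targets, controls = NULL, dropped = NULL) {
  norm <- function(x, reason = FALSE) {
    if (is.null(x) || !nrow(data.table::as.data.table(x))) {
      out <- data.table::data.table(chrom = character(0), pos = integer(0),
                                    ref = character(0), alt = character(0))
      if (reason) out[, reason := character(0)]
      return(out)
    }
    x <- data.table::as.data.table(x)
    stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(x)),
              all(x$ref %in% NUCLEOTIDES), all(x$alt %in% NUCLEOTIDES),
              all(x$ref != x$alt))
    cols <- c("chrom", "pos", "ref", "alt")
    out <- x[, cols, with = FALSE]
    if (reason) {
      out[, reason := if ("reason" %in% names(x)) x$reason else "undesignable"]
    }
    out
  }
  targets <- norm(targets)
  controls <- norm(controls)
  dropped <- norm(dropped, reason = TRUE)
  overlap <- merge(targets, dropped[, .(chrom, pos)], by = c("chrom", "pos"))
  if (nrow(overlap)) stop("panel design: targets and dropped loci overlap")
  structure(list(targets = targets, controls = controls, dropped = dropped),
            class = "panel_design")
}

#' Read or write a panel design as TSV
#'
#' Columns: chrom, pos, ref, alt, role (one of target/control/dropped) and
#' an optional reason for dropped loci.
#'
#' @param path file path.
#' @return `read_panel_design()` returns a [panel_design()];
#'   `write_panel_design()` returns `path` invisibly.
#' @export
read_panel_design <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  stopifnot(all(c("chrom", "pos", "ref", "alt", "role") %in% names(dt)))
  panel_design(targets = dt[role == "target"],
               controls = dt[role == "control"],
               dropped = dt[role == "dropped"])
}

#' @rdname read_panel_design
#' @param design a [panel_design()].
#' @export
write_panel_design <- function(design, path) {
  stopifnot(inherits(design, "panel_design"))
  blocks <- list(
    data.table::copy(design$targets)[, `:=`(role = "target", reason = NA_character_)],
    data.table::copy(design$controls)[, `:=`(role = "control", reason = NA_character_)],
    data.table::copy(design$dropped)[, role := "dropped"]
  )
  dt <- data.table::rbindlist(blocks, use.names = TRUE, fill = TRUE)
  data.table::setcolorder(dt, c("chrom", "pos", "ref", "alt", "role", "reason"))
  data.table::setorder(dt, chrom, pos)
  data.table::fwrite(dt, path, sep = "\t", eol = "\n")
  invisible(path)
}

#' Validate candidate loci against targeted-panel genotypes
#'
#' Rebuilds replicate-consensus genotypes per sample from the panel call
#' sets under the targeted filter regime and issues one verdict per
#' candidate and per control locus:
#' `confirmed_discordant` (accepted consensus in both samples, genotypes
#' differ), `rejected_concordant` (accepted identical genotypes), or
#' `inconclusive` (dropped from the panel, allele mismatch, not covered, or
#' no consensus in at least one sample — absence of evidence cannot confirm
#' a difference).
#'
#' @param candidates data.frame of candidate loci (chrom, pos, ref, alt).
#' @param trace_reps,reference_reps lists of panel [sample_calls()]
#'   replicates per sample.
#' @param design a [panel_design()].
#' @param config the targeted [filter_config()] (default
#'   `filter_preset("targeted")`).
#' @return data.table with one row per candidate/control locus: chrom, pos,
#'   ref, alt, role, verdict, trace_genotype, reference_genotype, reason.
#' @export
validate_candidates <- function(candidates, trace_reps, reference_reps,
                                design, config = filter_preset("targeted")) {
  stopifnot(inherits(design, "panel_design"))
  candidates <- data.table::as.data.table(candidates)[, .(chrom, pos, ref, alt)]
  tcons <- consensus_genotypes(trace_reps, config)
  rcons <- consensus_genotypes(reference_reps, config)

  judge_one <- function(locus, role) {
    key <- c("chrom", "pos")
    out <- data.table::data.table(
      chrom = locus$chrom, pos = locus$pos, ref = locus$ref, alt = locus$alt,
      role = role, verdict = "inconclusive",
      trace_genotype = NA_character_, reference_genotype = NA_character_,
      reason = NA_character_
    )
    if (role == "dropped" ||
        (role == "target" &&
         !nrow(merge(locus, design$targets, by = c(key, "ref", "alt"))))) {
      out$reason <- "not_in_panel"
      return(out)
    }
    tg <- tcons[locus, on = key]
    rg <- rcons[locus, on = key]
    # allele mismatch between the candidate and what the panel VCF carries
    mismatch <- function(x) !is.na(x$genotype) &&
      (x$ref != locus$ref || x$alt != locus$alt)
    if (mismatch(tg) || mismatch(rg)) {
      out$reason <- "allele_mismatch"
      return(out)
    }
    out$trace_genotype <- tg$genotype
    out$reference_genotype <- rg$genotype
    if (is.na(tg$genotype) && is.na(rg$genotype)) {
      out$reason <- "no_consensus_both"
    } else if (is.na(tg$genotype)) {
      out$reason <- "no_consensus_trace"
    } else if (is.na(rg$genotype)) {
      out$reason <- "no_consensus_reference"
    } else if (tg$genotype == rg$genotype) {
      out$verdict <- "rejected_concordant"
      out$reason <- "genotypes_identical"
    } else {
      out$verdict <- "confirmed_discordant"
      out$reason <- "genotypes_differ"
    }
    out
  }

  dropped_keys <- design$dropped[, .(chrom, pos)]
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    locus <- candidates[i]
    role <- if (nrow(merge(locus[, .(chrom, pos)], dropped_keys,
                           by = c("chrom", "pos")))) "dropped" else "target"
    judge_one(locus, role)
  })
  ctrl_rows <- lapply(seq_len(nrow(design$controls)), function(i) {
    judge_one(design$controls[i], "control")
  })
  out <- data.table::rbindlist(c(rows, ctrl_rows))
  data.table::setorder(out, role, chrom, pos)
  out[]
}

#' Case-level verdict from per-locus panel verdicts
#'
#' The case is `distinguishable` iff at least one target locus is
#' `confirmed_discordant`. Otherwise the outcome is
#' `no_detectable_difference`, with the explicit caveat that this cannot
#' separate a same-source trace from genetically identical twins. Controls
#' never influence the outcome, but any discordant control marks the run as
#' suspect.
#'
#' @param verdicts a table from [validate_candidates()].
#' @return an object of class `case_verdict`: outcome, per-class counts for
#'   target loci, control counts, run_quality (`"ok"`/`"suspect"`),
#'   zero_candidates flag and caveat string.
#' @export
case_verdict <- function(verdicts) {
  verdicts <- data.table::as.data.table(verdicts)
  if (nrow(verdicts) && "role" %in% names(verdicts)) {
    targets <- verdicts[role != "control"]
    controls <- verdicts[role == "control"]
  } else {
    targets <- controls <- data.table::data.table(verdict = character(0))
  }
  counts <- vapply(VERDICTS, function(v) sum(targets$verdict == v), integer(1))
  distinguishable <- counts[["confirmed_discordant"]] > 0L
  structure(list(
    outcome = if (distinguishable) "distinguishable" else "no_detectable_difference",
    counts = as.list(counts),
    n_candidates = nrow(targets),
    zero_candidates = nrow(targets) == 0L,
    control_counts = as.list(
      vapply(VERDICTS, function(v) sum(controls$verdict == v), integer(1))),
    run_quality = if (nrow(controls) &&
                      any(controls$verdict == "confirmed_discordant"))
      "suspect" else "ok",
    caveat = if (distinguishable) NA_character_ else
      paste("No SNV difference detected: either the trace and the reference",
            "share a source, or the twins are genetically identical for the",
            "applied methods.")
  ), class = "case_verdict")
}

#' @export
print.case_verdict <- function(x, ...) {
  cat("case verdict:", x$outcome, "\n")
  cat(sprintf("  candidates: %d (confirmed %d, rejected %d, inconclusive %d)\n",
              x$n_candidates, x$counts$confirmed_discordant,
              x$counts$rejected_concordant, x$counts$inconclusive))
  cat("  run quality:", x$run_quality, "\n")
  if (!is.na(x$caveat)) cat("  note:", x$caveat, "\n")
  invisible(x)
}
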