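# DNA-vs-RNA allele-fraction evidence of NMD-driven transcript loss.

#' Paired DNA/RNA allele counts for one heterozygous variant
#'
#' @param dna_alt,dna_ref alt/ref read counts from exome (DNA) data.
#' @param rna_alt,rna_ref alt/ref read counts from RNA-Seq.
#' @param sample_id optional label.
#' @return object of class `allele_counts`.
#' @export
allele_counts <- function(dna_alt, dna_ref, rna_alt, rna_ref,
                          sample_id = NA_character_) {
  x <- list(dna_alt = as.integer(dna_alt), dna_ref = as.integer(dna_ref),
            rna_alt = as.integer(rna_alt), rna_ref = as.integer(rna_ref),
            sample_id = as.character(sample_id))
  counts <- unlist(x[1:4])
  if (any(is.na(counts)) || any(counts < 0L)) {
    nmd_error("nmdscan_validation_error", "read counts must be >= 0")
  }
  if (x$dna_alt + x$dna_ref == 0L || x$rna_alt + x$rna_ref == 0L) {
    nmd_error("nmdscan_validation_error",
              "both DNA and RNA must have positive total depth")
  }
  structure(x, class = "allele_counts")
}

#' Variant allele fraction
#'
#' @param alt,ref read counts (vectorized).
#' @return `alt / (alt + ref)`.
#' @export
vaf <- function(alt, ref) {
  if (any(alt + ref <= 0)) {
    nmd_error("nmdscan_undefined_vaf", "VAF undefined at zero depth")
  }
  alt / (alt + ref)
}

odds <- function(p) p / (1 - p)

#' Assess allele-fraction evidence of NMD
#'
#' Formalizes the exome-vs-transcriptome comparison: the mutant allele of a
#' heterozygous PTC variant should be depleted from RNA-Seq reads if the
#' transcript is degraded. The RNA alt count is tested against the observed
#' DNA alt fraction with a two-sided exact binomial test, and the allelic
#' odds ratio
#' \deqn{\delta = \frac{vaf_{RNA}/(1-vaf_{RNA})}{vaf_{DNA}/(1-vaf_{DNA})}}
#' estimates the mutant transcript's relative retention (under a two-allele
#' model with equal DNA representation — a model assumption, not a
#' measurement).
#'
#' Verdicts: `consistent_with_decay` when the imbalance is significant
#' (`p < alpha`) and the estimated retention is below `ratio_threshold`;
#' `consistent_with_escape` when the retention estimate is at/above the
#' threshold, or when no significant imbalance is seen at informative RNA
#' depth (`>= min_depth` reads); `indeterminate` otherwise (no significant
#' imbalance, but too few RNA reads to mean anything).
#'
#' @param counts an [allele_counts].
#' @param alpha significance level for the exact test (default 0.05).
#' @param ratio_threshold retention fraction below which significant
#'   imbalance is called decay (default 0.25).
#' @param min_depth minimum RNA depth for a non-significant test to count as
#'   evidence of escape (default 20).
#' @return object of class `allele_evidence` with fields `vaf_dna`,
#'   `vaf_rna`, `allelic_ratio`, `p_value`, `verdict` plus the thresholds
#'   used.
#' @examples
#' assess_nmd(allele_counts(46, 54, 9, 91))   # consistent_with_decay
#' assess_nmd(allele_counts(56, 44, 32, 68))  # consistent_with_escape
#' @export
assess_nmd <- function(counts, alpha = 0.05, ratio_threshold = 0.25,
                       min_depth = 20L) {
  stopifnot(inherits(counts, "allele_counts"))
  vd <- vaf(counts$dna_alt, counts$dna_ref)
  vr <- vaf(counts$rna_alt, counts$rna_ref)
  if (vd %in% c(0, 1)) {
    nmd_error("nmdscan_degenerate_odds",
              sprintf("DNA VAF %.2f is not a heterozygous call; odds undefined", vd))
  }
  ratio <- odds(vr) / odds(vd)
  rna_total <- counts$rna_alt + counts$rna_ref
  p <- stats::binom.test(counts$rna_alt, rna_total, p = vd)$p.value

  verdict <- if (p < alpha && ratio < ratio_threshold) {
    "consistent_with_decay"
  } else if (ratio >= ratio_threshold ||
             (p >= alpha && rna_total >= min_depth)) {
    "consistent_with_escape"
  } else {
    "indeterminate"
  }
  structure(list(sample_id = counts$sample_id,
                 vaf_dna = vd, vaf_rna = vr,
                 allelic_ratio = ratio, p_value = p, verdict = verdict,
                 alpha = alpha, ratio_threshold = ratio_threshold,
                 min_depth = as.integer(min_depth)),
            class = "allele_evidence")
}

#' @export
print.allele_evidence <- function(x, ...) {
  cat(sprintf("allele_evidence%s\n",
              if (is.na(x$sample_id)) "" else paste0(" [", x$sample_id, "]")))
  cat(sprintf("  VAF: DNA %.3f, RNA %.3f; retention ratio %.3f; p = %.3g\n",
              x$vaf_dna, x$vaf_rna, x$allelic_ratio, x$p_value))
  cat(sprintf("  verdict: %s\n", x$verdict))
  invisible(x)
}

#' Read a DNA/RNA counts table
#'
#' Expects tab-separated columns `sample_id`, `variant_label`, `dna_alt`,
#' `dna_ref`, `rna_alt`, `rna_ref`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("dna_alt", "dna_ref", "rna_alt", "rna_ref")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    nmd_error("nmdscan_io_error",
              sprintf("counts TSV %s lacks column(s): %s", path,
                      paste(missing, collapse = ", ")))
  }
  df
}

#' Assess every row of a counts table
#'
#' @param df data.frame as returned by [read_counts_tsv].
#' @inheritParams assess_nmd
#' @return the input with columns `vaf_dna`, `vaf_rna`, `allelic_ratio`,
#'   `p_value`, `verdict` appended.
#' @export
assess_nmd_table <- function(df, alpha = 0.05, ratio_threshold = 0.25,
                             min_depth = 20L) {
  out <- lapply(seq_len(nrow(df)), function(i) {
    sid <- if ("sample_id" %in% names(df)) df$sample_id[i] else NA_character_
    ev <- assess_nmd(allele_counts(df$dna_alt[i], df$dna_ref[i],
                                   df$rna_alt[i], df$rna_ref[i], sid),
                     alpha = alpha, ratio_threshold = ratio_threshold,
                     min_depth = min_depth)
    data.frame(vaf_dna = ev$vaf_dna, vaf_rna = ev$vaf_rna,
               allelic_ratio = ev$allelic_ratio, p_value = ev$p_value,
               verdict = ev$verdict, stringsAsFactors = FALSE)
  })
  cbind(df, do.call(rbind, out))
}
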