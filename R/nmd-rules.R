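# The four positional NMD-escape rules, the trigger region they imply, and
# per-PTC classification.

#' NMD rule thresholds
#'
#' The four surveillance rules are positional: a PTC escapes decay when it
#' lies (1) in the last exon, (2) fewer than `junction_window_nt` (50-55 nt;
#' default the upper end, 55) upstream of the last exon-exon junction,
#' (3) in an exon longer than `long_exon_nt` (about 400 nt), or (4) within
#' `start_proximal_nt` (about 150 nt) of the start codon. `borderline_codons`
#' is the half-width (in codons) within which a trigger verdict at the edge
#' of the trigger region is flagged as borderline — decay there may be
#' incomplete.
#'
#' @param start_proximal_nt nt threshold from the start codon (default 150).
#' @param junction_window_nt escape window upstream of the last junction in
#'   nt (default 55, documented range 50-55).
#' @param long_exon_nt exon-length threshold in nt (default 400).
#' @param borderline_codons borderline flag half-width in codons (default 2).
#' @return object of class `nmd_config`.
#' @export
nmd_config <- function(start_proximal_nt = 150L, junction_window_nt = 55L,
                       long_exon_nt = 400L, borderline_codons = 2L) {
  cfg <- list(start_proximal_nt = as.integer(start_proximal_nt),
              junction_window_nt = as.integer(junction_window_nt),
              long_exon_nt = as.integer(long_exon_nt),
              borderline_codons = as.integer(borderline_codons))
  if (any(vapply(cfg, is.na, TRUE)) ||
      cfg$start_proximal_nt < 1L || cfg$junction_window_nt < 1L ||
      cfg$long_exon_nt < 1L || cfg$borderline_codons < 0L) {
    nmd_error("nmdscan_validation_error",
              "all thresholds must be positive (borderline width >= 0)")
  }
  structure(cfg, class = "nmd_config")
}

#' @export
print.nmd_config <- function(x, ...) {
  cat("nmd_config:\n")
  cat(sprintf("  start_proximal_nt   %d\n", x$start_proximal_nt))
  cat(sprintf("  junction_window_nt  %d\n", x$junction_window_nt))
  cat(sprintf("  long_exon_nt        %d\n", x$long_exon_nt))
  cat(sprintf("  borderline_codons   %d\n", x$borderline_codons))
  invisible(x)
}

# Codon bounds of the trigger region; canonical rule space is the codon
# index, nt bounds are primary and codons derived via floor(nt/3).
region_bounds <- function(t, cfg) {
  J <- last_junction_position(t)
  nt_lo <- cfg$start_proximal_nt + 1L
  nt_hi <- if (is.na(J)) NA_integer_ else J - cfg$junction_window_nt - 1L
  list(J = J, nt_lo = nt_lo, nt_hi = nt_hi,
       codon_lo = max(1L, nt_lo %/% 3L),
       codon_hi = if (is.na(nt_hi)) NA_integer_ else nt_hi %/% 3L)
}

# Does the codon's first nucleotide sit in a long exon that is not the last?
in_long_exon <- function(t, first_nt, cfg) {
  ex <- exon_of_cds_position(t, first_nt)
  ex$exon < length(t$exon_cds_lengths) & ex$exon_cds_length > cfg$long_exon_nt
}

#' Delineate a transcript's NMD-trigger region
#'
#' The region of the CDS in which a PTC is expected to trigger decay:
#' nucleotides `start_proximal_nt + 1` through
#' `last_junction - junction_window_nt - 1`, expressed also as codon bounds
#' `floor(nt/3)`. The region is empty for a single-exon transcript or when
#' the bounds cross. Codons inside the bounds whose exon (of the codon's
#' first nucleotide) exceeds `long_exon_nt` are carved out as
#' `excluded_intervals` (they escape by the long-exon rule).
#'
#' @param t a [transcript_model].
#' @param cfg an [nmd_config].
#' @return object of class `nmd_region` with fields `nt_lo`, `nt_hi`,
#'   `codon_lo`, `codon_hi`, `excluded_intervals` (list of `c(lo, hi)` codon
#'   pairs), `empty`, `transcript_id`, `config`.
#' @examples
#' t <- sod1_transcript()
#' trigger_region(t)  # nt 151-301, codons 50-100
#' @export
trigger_region <- function(t, cfg = nmd_config()) {
  stopifnot(inherits(t, "transcript_model"), inherits(cfg, "nmd_config"))
  b <- region_bounds(t, cfg)
  # emptiness is decided in codon space (the canonical rule space): at the
  # bounds the nt and codon intervals can disagree by up to 2 nt
  empty <- is.na(b$codon_hi) || b$codon_lo > b$codon_hi
  excl <- list()
  if (!empty) {
    codons <- b$codon_lo:b$codon_hi
    long <- in_long_exon(t, 3L * codons - 2L, cfg)
    if (any(long)) {
      r <- rle(long)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- which(r$values)
      excl <- lapply(keep, function(k) codons[c(starts[k], ends[k])])
    }
  }
  structure(list(
    nt_lo = if (empty) NA_integer_ else b$nt_lo,
    nt_hi = if (empty) NA_integer_ else b$nt_hi,
    codon_lo = if (empty) NA_integer_ else b$codon_lo,
    codon_hi = if (empty) NA_integer_ else b$codon_hi,
    excluded_intervals = excl,
    empty = empty,
    transcript_id = t$transcript_id,
    config = cfg), class = "nmd_region")
}

#' Render a trigger region as one line of text
#'
#' @param region an [nmd_region].
#' @return string such as `"trigger: codons 50-100 (nt 151-301)"`.
#' @export
format_region <- function(region) {
  stopifnot(inherits(region, "nmd_region"))
  if (region$empty) return("trigger: none")
  s <- sprintf("trigger: codons %d-%d (nt %d-%d)",
               region$codon_lo, region$codon_hi, region$nt_lo, region$nt_hi)
  if (length(region$excluded_intervals)) {
    ex <- vapply(region$excluded_intervals,
                 function(iv) sprintf("%d-%d", iv[1], iv[2]), "")
    s <- sprintf("%s excluding long-exon codons %s", s, paste(ex, collapse = ", "))
  }
  s
}

#' @export
print.nmd_region <- function(x, ...) {
  cat(sprintf("nmd_region [%s]\n  %s\n", x$transcript_id, format_region(x)))
  invisible(x)
}

#' Classify a premature termination codon against the NMD rules
#'
#' Evaluates the four escape rules in codon space. The PTC is anchored by
#' the first nucleotide of its stop codon in reference CDS coordinates (a
#' stop straddling the last junction is assigned by that first nucleotide).
#' `junction_proximal` is only reported when the last-exon rule does not
#' already apply. The verdict is `"escape"` when any rule fires, otherwise
#' `"trigger"`; a trigger within `borderline_codons` of either region bound
#' is flagged borderline (decay may be incomplete there).
#'
#' @param t a [transcript_model].
#' @param ptc a `ptc_call` from [find_ptc], or any list with `codon_index`
#'   and `cds_first_nt`.
#' @param cfg an [nmd_config].
#' @return object of class `nmd_call` with fields `status`, `rules_fired`,
#'   `borderline`, `ptc`.
#' @export
classify_ptc <- function(t, ptc, cfg = nmd_config()) {
  stopifnot(inherits(t, "transcript_model"))
  ci <- as.integer(ptc$codon_index)
  first_nt <- as.integer(ptc$cds_first_nt)
  if (ci >= n_codons(t)) {
    nmd_error("nmdscan_validation_error",
              sprintf("PTC codon %d is at/after the natural stop (codon %d)",
                      ci, n_codons(t)))
  }
  b <- region_bounds(t, cfg)
  rules <- character()
  last_exon <- is.na(b$J) || first_nt > b$J
  if (last_exon) rules <- c(rules, "last_exon")
  if (ci < b$codon_lo) rules <- c(rules, "start_proximal")
  if (!last_exon && !is.na(b$codon_hi) && ci > b$codon_hi) {
    rules <- c(rules, "junction_proximal")
  }
  if (in_long_exon(t, first_nt, cfg)) rules <- c(rules, "long_exon")

  status <- if (length(rules)) "escape" else "trigger"
  borderline <- status == "trigger" &&
    (ci - b$codon_lo <= cfg$borderline_codons ||
     b$codon_hi - ci <= cfg$borderline_codons)
  structure(list(status = status, rules_fired = rules,
                 borderline = borderline, ptc = ptc),
            class = "nmd_call")
}

#' @export
print.nmd_call <- function(x, ...) {
  cat(sprintf("nmd_call: %s%s%s\n", x$status,
              if (length(x$rules_fired))
                sprintf(" [%s]", paste(x$rules_fired, collapse = ", ")) else "",
              if (x$borderline) " (borderline)" else ""))
  invisible(x)
}
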