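#' Transcript model in CDS coordinates
#'
#' A `transcript_model` describes a single protein-coding transcript by its
#' CDS sequence and the CDS-overlapping length of each exon. All coordinates
#' are 1-based and inclusive in CDS space (HGVS c. convention: +1 is the A of
#' the ATG initiation codon); UTR exons and UTR lengths play no role. The
#' last CDS nucleotide of every non-terminal exon is an exon-exon junction;
#' the junction nucleotide belongs to the upstream exon.
#'
#' @param transcript_id accession-like label.
#' @param cds_sequence nucleotide string from the A of ATG through the
#'   natural stop codon (length a positive multiple of 3, first codon ATG,
#'   exactly one stop codon, at the end).
#' @param exon_cds_lengths integer vector of per-exon CDS-overlapping
#'   lengths, 5' to 3', summing to `nchar(cds_sequence)`. Exons with no CDS
#'   overlap are omitted.
#' @return object of class `transcript_model` with fields `transcript_id`,
#'   `cds_sequence`, `exon_cds_lengths` and the derived ascending junction
#'   list `exon_junctions_cds`.
#' @examples
#' t <- transcript_model("demo", "ATGAAACCCTAA", c(6, 6))
#' last_junction_position(t)
#' @export
transcript_model <- function(transcript_id, cds_sequence, exon_cds_lengths) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L)
  cds_sequence <- toupper(as.character(cds_sequence))
  exon_cds_lengths <- as.integer(exon_cds_lengths)
  L <- nchar(cds_sequence)

  if (!is_dna(cds_sequence) || L == 0L) {
    nmd_error("nmdscan_validation_error",
              sprintf("[%s] CDS sequence must be a non-empty A/C/G/T string",
                      transcript_id))
  }
  if (L %% 3L != 0L) {
    nmd_error("nmdscan_validation_error",
              sprintf("[%s] CDS length %d is not divisible by 3",
                      transcript_id, L))
  }
  codons <- codon_split(cds_sequence)
  n <- length(codons)
  if (codons[1L] != "ATG") {
    nmd_error("nmdscan_validation_error",
              sprintf("[%s] CDS does not begin with ATG (found %s)",
                      transcript_id, codons[1L]))
  }
  if (!codons[n] %in% STOP_CODONS) {
    nmd_error("nmdscan_validation_error",
              sprintf("[%s] CDS does not end with a stop codon (found %s)",
                      transcript_id, codons[n]))
  }
  internal <- which(codons[-n] %in% STOP_CODONS)
  if (length(internal) > 0L) {
    nmd_error("nmdscan_validation_error",
              sprintf("[%s] internal stop codon at codon index %d",
                      transcript_id, internal[1L]),
              codon_index = internal[1L])
  }
  if (length(exon_cds_lengths) == 0L || any(is.na(exon_cds_lengths)) ||
      any(exon_cds_lengths < 1L)) {
    nmd_error("nmdscan_validation_error",
              sprintf("[%s] exon CDS lengths must be positive integers",
                      transcript_id))
  }
  if (sum(exon_cds_lengths) != L) {
    nmd_error("nmdscan_validation_error",
              sprintf("[%s] exon CDS lengths sum to %d but CDS length is %d",
                      transcript_id, sum(exon_cds_lengths), L))
  }
  junctions <- cumsum(exon_cds_lengths)
  junctions <- junctions[-length(junctions)]

  structure(
    list(transcript_id = transcript_id,
         cds_sequence = cds_sequence,
         exon_cds_lengths = exon_cds_lengths,
         exon_junctions_cds = as.integer(junctions)),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  n <- nchar(x$cds_sequence) %/% 3L
  cat(sprintf("transcript_model %s\n", x$transcript_id))
  cat(sprintf("  CDS: %d nt, %d codons (%d aa + stop)\n",
              nchar(x$cds_sequence), n, n - 1L))
  cat(sprintf("  exons (CDS nt): %s\n",
              paste(x$exon_cds_lengths, collapse = ", ")))
  if (length(x$exon_junctions_cds)) {
    cat(sprintf("  junctions (CDS nt): %s\n",
                paste(x$exon_junctions_cds, collapse = ", ")))
  } else {
    cat("  single coding exon (no junctions)\n")
  }
  invisible(x)
}

#' Position of the last exon-exon junction
#'
#' The last CDS nucleotide of the penultimate exon, i.e. the junction the
#' 50-55 nt rule measures against. `NA` for a single-exon transcript.
#'
#' @param t a [transcript_model].
#' @return 1-based CDS position, or `NA_integer_` when there is no junction.
#' @export
last_junction_position <- function(t) {
  stopifnot(inherits(t, "transcript_model"))
  j <- t$exon_junctions_cds
  if (length(j) == 0L) NA_integer_ else j[length(j)]
}

#' Exon containing a CDS position
#'
#' Exon intervals are half-open on the junction partial sums,
#' `(prev_junction, this_junction]`, so a junction nucleotide belongs to the
#' upstream exon.
#'
#' @param t a [transcript_model].
#' @param p vector of 1-based CDS nucleotide positions.
#' @return data.frame with columns `position`, `exon` (1-based index) and
#'   `exon_cds_length`.
#' @export
exon_of_cds_position <- function(t, p) {
  stopifnot(inherits(t, "transcript_model"))
  p <- as.integer(p)
  L <- nchar(t$cds_sequence)
  if (any(is.na(p)) || any(p < 1L) || any(p > L)) {
    nmd_error("nmdscan_bounds_error",
              sprintf("[%s] CDS position out of range 1..%d",
                      t$transcript_id, L))
  }
  exon <- findInterval(p - 1L, t$exon_junctions_cds) + 1L
  data.frame(position = p, exon = exon,
             exon_cds_length = t$exon_cds_lengths[exon])
}

n_codons <- function(t) nchar(t$cds_sequence) %/% 3L
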