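# Applying coding edits to a CDS and locating the resulting PTC.

#' Apply a coding variant or transcript edit to a CDS
#'
#' Returns the mutant CDS sequence; the transcript itself is untouched.
#' Stated reference (or duplicated) bases are checked against the sequence
#' and a mismatch raises a condition of class `nmdscan_reference_mismatch`
#' naming the position and both alleles.
#'
#' @param t a [transcript_model].
#' @param v a [cds_variant] or [transcript_edit].
#' @return mutant CDS nucleotide string.
#' @export
apply_variant <- function(t, v) {
  stopifnot(inherits(t, "transcript_model"))
  seq <- t$cds_sequence
  L <- nchar(seq)

  if (inherits(v, "transcript_edit")) {
    if (v$insert_position >= L) {
      nmd_error("nmdscan_bounds_error",
                sprintf("insert position %d outside CDS 1..%d",
                        v$insert_position, L - 1L))
    }
    return(paste0(substr(seq, 1L, v$insert_position), v$inserted_sequence,
                  substr(seq, v$insert_position + 1L, L)))
  }
  stopifnot(inherits(v, "cds_variant"))
  if (v$end > L || (v$kind == "insertion" && v$end > L)) {
    nmd_error("nmdscan_bounds_error",
              sprintf("variant span %d..%d outside CDS 1..%d",
                      v$start, v$end, L))
  }
  check_ref <- function(span_start, span_end, stated) {
    found <- substr(seq, span_start, span_end)
    if (nzchar(stated) && found != stated) {
      nmd_error("nmdscan_reference_mismatch",
                sprintf("[%s] reference mismatch at c.%d..%d: expected '%s', found '%s'",
                        t$transcript_id, span_start, span_end, stated, found),
                position = span_start, expected = stated, found = found)
    }
    found
  }
  switch(v$kind,
    substitution = {
      check_ref(v$start, v$start, v$ref_allele)
      paste0(substr(seq, 1L, v$start - 1L), v$alt_allele,
             substr(seq, v$start + 1L, L))
    },
    deletion = {
      check_ref(v$start, v$end, v$ref_allele)
      paste0(substr(seq, 1L, v$start - 1L), substr(seq, v$end + 1L, L))
    },
    delins = {
      check_ref(v$start, v$end, v$ref_allele)
      paste0(substr(seq, 1L, v$start - 1L), v$alt_allele,
             substr(seq, v$end + 1L, L))
    },
    duplication = {
      span <- check_ref(v$start, v$end, v$ref_allele)
      paste0(substr(seq, 1L, v$end), span, substr(seq, v$end + 1L, L))
    },
    insertion = {
      paste0(substr(seq, 1L, v$start), v$alt_allele,
             substr(seq, v$start + 1L, L))
    })
}

# Project a mutant CDS position onto reference CDS coordinates by
# prefix/suffix alignment of the two sequences. Positions inside an inserted
# block map to the reference edit locus (capped at the replaced span).
project_to_reference <- function(ref, mut, m) {
  p <- common_prefix_len(ref, mut)
  sfx <- common_suffix_len(ref, mut, cap = min(nchar(ref), nchar(mut)) - p)
  diff <- nchar(mut) - nchar(ref)
  ref_block_len <- nchar(ref) - sfx - p
  if (m <= p) return(m)
  if (m > nchar(mut) - sfx) return(m - diff)
  p + min(m - p, max(ref_block_len, 1L))
}

#' Locate the premature termination codon in a mutant CDS
#'
#' Scans the mutant reading frame 5' to 3' for the first stop codon. When
#' that stop is the transcript's own terminator (reading frame preserved and
#' the stop maps to the reference stop codon position) there is no PTC and
#' `NULL` is returned. A mutant sequence with no stop codon at all is a
#' stop-loss, out of classification scope, and raises
#' `nmdscan_no_terminator`.
#'
#' `cds_first_nt`/`cds_last_nt` of the returned call are projected onto
#' reference CDS coordinates by subtracting the net length inserted 5' of
#' the stop, so downstream positional rules operate on the reference exon
#' structure; `codon_index` stays in the mutant frame (the catalogue
#' convention for "resulting PTC position").
#'
#' @param t a [transcript_model] (the reference).
#' @param mutant_cds mutant CDS sequence, starting with ATG.
#' @return object of class `ptc_call` with fields `codon_index`,
#'   `cds_first_nt`, `cds_last_nt`, `protein_hgvs`, `is_natural_stop`;
#'   or `NULL` when the first stop is the natural terminator.
#' @export
find_ptc <- function(t, mutant_cds) {
  stopifnot(inherits(t, "transcript_model"))
  mutant_cds <- toupper(mutant_cds)
  if (substr(mutant_cds, 1L, 3L) != "ATG") {
    nmd_error("nmdscan_validation_error", "mutant CDS does not start with ATG")
  }
  ref <- t$cds_sequence
  aa <- translate_cds(mutant_cds)
  stop_i <- which(aa == "*")
  if (length(stop_i) == 0L) {
    nmd_error("nmdscan_no_terminator",
              sprintf("[%s] mutant sequence contains no stop codon (stop-loss)",
                      t$transcript_id))
  }
  i <- stop_i[1L]
  m_first <- 3L * i - 2L
  diff <- nchar(mutant_cds) - nchar(ref)
  ref_first <- project_to_reference(ref, mutant_cds, m_first)
  if (diff %% 3L == 0L && ref_first == nchar(ref) - 2L) {
    return(NULL)  # natural terminator reached in frame: no PTC
  }
  ptc <- ptc_call(codon_index = i, cds_first_nt = ref_first)
  ptc$protein_hgvs <- protein_hgvs_of(ref, mutant_cds, ptc)
  ptc
}

ptc_call <- function(codon_index, cds_first_nt, protein_hgvs = NA_character_,
                     is_natural_stop = FALSE) {
  codon_index <- as.integer(codon_index)
  cds_first_nt <- as.integer(cds_first_nt)
  stopifnot(codon_index >= 1L, cds_first_nt >= 1L)
  structure(list(codon_index = codon_index,
                 cds_first_nt = cds_first_nt,
                 cds_last_nt = cds_first_nt + 2L,
                 protein_hgvs = protein_hgvs,
                 is_natural_stop = is_natural_stop),
            class = "ptc_call")
}

#' @export
print.ptc_call <- function(x, ...) {
  cat(sprintf("ptc_call: codon %d (ref CDS nt %d-%d)%s\n",
              x$codon_index, x$cds_first_nt, x$cds_last_nt,
              if (is.na(x$protein_hgvs)) "" else paste0(" ", x$protein_hgvs)))
  invisible(x)
}

#' Protein-level HGVS name of a premature stop
#'
#' Compares the translated mutant against the reference protein left to
#' right. If the first divergent residue is itself the stop the consequence
#' is written in nonsense form `p.Xaa{pos}*`; otherwise in frameshift form
#' `p.Xaa{pos}Yaafs*{N}` with `N = codon_index - pos + 1`. Three-letter
#' residue codes are emitted.
#'
#' @param ref_cds reference CDS string.
#' @param mutant_cds mutant CDS string.
#' @param ptc the [find_ptc] call for this mutant.
#' @return protein HGVS string.
#' @export
protein_hgvs_of <- function(ref_cds, mutant_cds, ptc) {
  stopifnot(inherits(ptc, "ptc_call"))
  ref_aa <- translate_cds(ref_cds)
  mut_aa <- translate_cds(mutant_cds)[seq_len(ptc$codon_index)]
  upto <- min(length(ref_aa), ptc$codon_index)
  div <- which(mut_aa[seq_len(upto)] != ref_aa[seq_len(upto)])
  if (length(div) == 0L) {
    nmd_error("nmdscan_validation_error",
              "mutant protein does not diverge from reference before the stop")
  }
  pos <- div[1L]
  if (mut_aa[pos] == "*") {
    sprintf("p.%s%d*", AA_1TO3[[ref_aa[pos]]], pos)
  } else {
    sprintf("p.%s%d%sfs*%d", AA_1TO3[[ref_aa[pos]]], pos,
            AA_1TO3[[mut_aa[pos]]], ptc$codon_index - pos + 1L)
  }
}
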