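# Independent re-derivations used as oracles. These deliberately avoid the
# package's own code paths: rules are recomputed from exon partial sums and
# the genetic code is a separate hand-typed lookup.

ORACLE_AA <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_translate <- function(seq) {
  n <- nchar(seq) %/% 3
  unname(ORACLE_AA[substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))])
}

# Escape/trigger status for every PTC codon of a transcript, re-derived from
# the exon partial sums. `codons` default: every possible PTC position.
# PTCs are anchored at the first nucleotide of the stop codon (3c - 2).
oracle_status_by_codon <- function(exon_lengths, cfg,
                                   codons = seq_len(sum(exon_lengths) %/% 3 - 1)) {
  psum <- cumsum(exon_lengths)
  n_ex <- length(exon_lengths)
  J <- if (n_ex > 1) psum[n_ex - 1] else NA_integer_
  first_nt <- 3 * codons - 2
  last_exon <- if (is.na(J)) rep(TRUE, length(codons)) else first_nt > J
  start_prox <- codons < max(1, (cfg$start_proximal_nt + 1) %/% 3)
  junc_prox <- if (is.na(J)) rep(FALSE, length(codons)) else {
    !last_exon & codons > (J - cfg$junction_window_nt - 1) %/% 3
  }
  exon_idx <- vapply(first_nt,
                     function(p) which(psum >= p)[1], 0)
  long <- exon_idx < n_ex & exon_lengths[exon_idx] > cfg$long_exon_nt
  ifelse(last_exon | start_prox | junc_prox | long, "escape", "trigger")
}

# Package-route status for every codon, via trigger_region (codon bounds
# minus long-exon exclusions).
region_status_by_codon <- function(t, cfg,
                                   codons = seq_len(nchar(t$cds_sequence) %/% 3 - 1)) {
  reg <- trigger_region(t, cfg)
  if (reg$empty) return(rep("escape", length(codons)))
  inside <- codons >= reg$codon_lo & codons <= reg$codon_hi
  for (iv in reg$excluded_intervals) {
    inside <- inside & !(codons >= iv[1] & codons <= iv[2])
  }
  ifelse(inside, "trigger", "escape")
}

classify_status <- function(t, codon, cfg = nmd_config()) {
  ptc <- list(codon_index = codon, cds_first_nt = 3 * codon - 2)
  classify_ptc(t, ptc, cfg)$status
}
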