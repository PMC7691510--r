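# Build GenBank / GFF3+FASTA renditions of a transcript_model with an
# invented genomic layout (short introns and flanks), for reader round-trips.

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

make_locus <- function(t, intron_len = 30, flank = 15, seed = 99) {
  set.seed(seed)
  rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
  lens <- t$exon_cds_lengths
  bounds <- cumsum(lens)
  exons <- substring(t$cds_sequence, c(1, head(bounds, -1) + 1), bounds)
  genome <- rand_dna(flank)
  starts <- ends <- integer(length(exons))
  for (i in seq_along(exons)) {
    starts[i] <- nchar(genome) + 1
    genome <- paste0(genome, exons[i])
    ends[i] <- nchar(genome)
    if (i < length(exons)) genome <- paste0(genome, rand_dna(intron_len))
  }
  genome <- paste0(genome, rand_dna(flank))
  list(genome = genome, starts = starts, ends = ends)
}

write_genbank_fixture <- function(t, path, minus = FALSE, ...) {
  loc <- make_locus(t, ...)
  genome <- loc$genome; starts <- loc$starts; ends <- loc$ends
  if (minus) {
    G <- nchar(genome)
    genome <- revcomp_chr(genome)
    new_starts <- G - rev(ends) + 1
    new_ends <- G - rev(starts) + 1
    starts <- new_starts; ends <- new_ends
  }
  join <- paste(sprintf("%d..%d", starts, ends), collapse = ",")
  locstr <- if (length(starts) > 1) sprintf("join(%s)", join) else join
  if (minus) locstr <- sprintf("complement(%s)", locstr)
  seq_lines <- character()
  s <- tolower(genome)
  for (off in seq(1, nchar(s), by = 60)) {
    chunk <- substr(s, off, min(off + 59, nchar(s)))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    seq_lines <- c(seq_lines,
                   sprintf("%9d %s", off, paste(blocks, collapse = " ")))
  }
  writeLines(c(
    sprintf("LOCUS       %s %d bp    DNA     linear   SYN 01-JAN-2020",
            t$transcript_id, nchar(genome)),
    "DEFINITION  synthetic locus for reader tests.",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(genome)),
    sprintf("     CDS             %s", locstr),
    "                     /codon_start=1",
    sprintf("                     /note=\"%s\"", t$transcript_id),
    "ORIGIN",
    seq_lines,
    "//"), path)
  path
}

write_gff3_fixture <- function(t, gff_path, fasta_path, minus = FALSE, ...) {
  loc <- make_locus(t, ...)
  genome <- loc$genome; starts <- loc$starts; ends <- loc$ends
  strand <- "+"
  if (minus) {
    G <- nchar(genome)
    genome <- revcomp_chr(genome)
    new_starts <- G - rev(ends) + 1
    new_ends <- G - rev(starts) + 1
    starts <- new_starts; ends <- new_ends
    strand <- "-"
  }
  lines <- c("##gff-version 3",
             sprintf("chrS\ttest\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s",
                     min(starts), max(ends), strand, t$transcript_id))
  for (i in seq_along(starts)) {
    lines <- c(lines,
               sprintf("chrS\ttest\tCDS\t%d\t%d\t.\t%s\t0\tID=cds%d;Parent=%s",
                       starts[i], ends[i], strand, i, t$transcript_id))
  }
  writeLines(lines, gff_path)
  writeLines(c(">chrS synthetic", genome), fasta_path)
  gff_path
}
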