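#' Load a transcript model from disk
#'
#' Reads a transcript's exon structure and CDS sequence from one of three
#' sources and converts it to CDS coordinates:
#'
#' * `"json"` — the package's native schema:
#'   `{"transcript_id", "cds_sequence", "exon_cds_lengths"}` (junctions are
#'   derived from the partial sums).
#' * `"genbank"` — a GenBank flat file whose `CDS` feature carries the exon
#'   structure as a `join(...)` location (optionally wrapped in
#'   `complement(...)`), with the nucleotide sequence in the `ORIGIN` block.
#' * `"gff3"` — a GFF3 annotation (CDS features, 1-based inclusive genomic
#'   coordinates) plus a genome FASTA given via `fasta=`. Minus-strand
#'   transcripts are reverse-complemented so the CDS is always the sense
#'   strand.
#'
#' @param path path to the transcript file.
#' @param format one of `"json"`, `"genbank"`, `"gff3"`.
#' @param fasta path to the genome FASTA (required for `"gff3"`).
#' @param transcript_id optional: select/rename the record. For GFF3 sources
#'   with several transcripts this picks the `Parent`/`transcript_id` to use.
#' @return a validated [transcript_model].
#' @export
load_transcript <- function(path, format = c("json", "genbank", "gff3"),
                            fasta = NULL, transcript_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    nmd_error("nmdscan_io_error", sprintf("file not found: %s", path))
  }
  switch(format,
         json = load_transcript_json(path),
         genbank = load_transcript_genbank(path, transcript_id),
         gff3 = load_transcript_gff3(path, fasta, transcript_id))
}

load_transcript_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("transcript_id", "cds_sequence", "exon_cds_lengths")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    nmd_error("nmdscan_io_error",
              sprintf("transcript JSON %s lacks field(s): %s",
                      path, paste(missing, collapse = ", ")))
  }
  transcript_model(x$transcript_id, x$cds_sequence,
                   unlist(x$exon_cds_lengths))
}

#' Write a transcript model to the native JSON schema
#'
#' @param t a [transcript_model].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transcript_json <- function(t, path) {
  stopifnot(inherits(t, "transcript_model"))
  jsonlite::write_json(
    list(transcript_id = t$transcript_id,
         cds_sequence = t$cds_sequence,
         exon_cds_lengths = t$exon_cds_lengths),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# Minimal GenBank flat-file reader: LOCUS name, the CDS feature location and
# the ORIGIN sequence are all that is needed. No pre-installed R package
# parses GenBank records, hence the hand-rolled reader.
load_transcript_genbank <- function(path, transcript_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  rec_id <- if (length(locus)) strsplit(trimws(locus[1]), "[[:space:]]+")[[1]][2]
            else basename(path)
  if (!is.null(transcript_id)) rec_id <- transcript_id

  # CDS feature location possibly continued over several lines
  cds_i <- grep("^ {5}CDS ", lines)
  if (length(cds_i) == 0L) {
    nmd_error("nmdscan_io_error",
              sprintf("record %s: no CDS feature found", rec_id))
  }
  if (length(cds_i) > 1L) {
    nmd_error("nmdscan_io_error",
              sprintf("record %s: ambiguous CDS (%d features)",
                      rec_id, length(cds_i)))
  }
  loc <- trimws(sub("^ {5}CDS +", "", lines[cds_i]))
  j <- cds_i + 1L
  while (j <= length(lines) && grepl("^ {21}[^/]", lines[j])) {
    loc <- paste0(loc, trimws(lines[j]))
    j <- j + 1L
  }

  minus <- grepl("^complement\\(", loc)
  inner <- gsub("^complement\\(|^join\\(|\\)+$", "", gsub("join\\(", "", loc))
  segs <- strsplit(inner, ",")[[1]]
  m <- regmatches(segs, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", trimws(segs)))
  if (any(lengths(m) != 3L)) {
    nmd_error("nmdscan_io_error",
              sprintf("record %s: cannot parse CDS location '%s'",
                      rec_id, loc))
  }
  starts <- as.integer(vapply(m, `[`, "", 2L))
  ends <- as.integer(vapply(m, `[`, "", 3L))

  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0L) {
    nmd_error("nmdscan_io_error",
              sprintf("record %s: no ORIGIN sequence block", rec_id))
  }
  seq_lines <- lines[(ori[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  genome <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  assemble_cds(rec_id, genome, starts, ends, minus)
}

load_transcript_gff3 <- function(path, fasta, transcript_id = NULL) {
  if (is.null(fasta)) {
    nmd_error("nmdscan_io_error", "gff3 format requires a genome FASTA")
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    nmd_error("nmdscan_io_error", "package 'rtracklayer' is required for GFF3")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  cds <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) {
    nmd_error("nmdscan_io_error",
              sprintf("%s: no CDS features found", path))
  }
  parent <- if ("Parent" %in% names(cds)) {
    vapply(cds$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_, "")
  } else rep(NA_character_, nrow(cds))
  if (!is.null(transcript_id)) {
    keep <- !is.na(parent) & parent == transcript_id
    if (!any(keep)) {
      nmd_error("nmdscan_io_error",
                sprintf("%s: no CDS features for transcript '%s'",
                        path, transcript_id))
    }
    cds <- cds[keep, , drop = FALSE]
    rec_id <- transcript_id
  } else {
    ids <- unique(parent[!is.na(parent)])
    if (length(ids) > 1L) {
      nmd_error("nmdscan_io_error",
                sprintf("%s: ambiguous CDS (transcripts: %s); pass transcript_id",
                        path, paste(ids, collapse = ", ")))
    }
    rec_id <- if (length(ids)) ids else tools::file_path_sans_ext(basename(path))
  }
  strand <- unique(as.character(cds$strand))
  if (length(strand) != 1L || !strand %in% c("+", "-")) {
    nmd_error("nmdscan_io_error",
              sprintf("%s: CDS features must share one explicit strand", path))
  }
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  chr <- unique(as.character(cds$seqnames))
  if (length(chr) != 1L || !chr %in% names(seqs)) {
    nmd_error("nmdscan_io_error",
              sprintf("%s: CDS sequence region '%s' not in FASTA",
                      path, paste(chr, collapse = ",")))
  }
  o <- order(cds$start)
  assemble_cds(rec_id, as.character(seqs[[chr]]),
               cds$start[o], cds$end[o], strand == "-")
}

# Splice genomic CDS segments (given in ascending genomic order) into a
# sense-strand transcript_model.
assemble_cds <- function(rec_id, genome, starts, ends, minus) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  if (any(starts < 1L) || any(ends > nchar(genome)) || any(ends < starts)) {
    nmd_error("nmdscan_io_error",
              sprintf("record %s: CDS segment outside sequence", rec_id))
  }
  pieces <- substring(genome, starts, ends)
  cds <- paste(pieces, collapse = "")
  lens <- ends - starts + 1L
  if (minus) {
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    lens <- rev(lens)
  }
  transcript_model(rec_id, cds, lens)
}
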