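# Internal helpers shared across modules.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' @importFrom Biostrings GENETIC_CODE
codon_split <- function(seq) {
  n <- nchar(seq) %/% 3L
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Translate a CDS codon-by-codon
#'
#' Returns one single-letter residue per codon ('*' for a stop). The input
#' need not terminate at a stop codon; trailing nucleotides that do not fill
#' a codon are ignored.
#'
#' @param seq nucleotide string (A/C/G/T), read 5'->3' in frame 0.
#' @return character vector of single-letter amino-acid codes.
#' @export
translate_cds <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  unname(Biostrings::GENETIC_CODE[codon_split(seq)])
}

nmd_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "nmdscan_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

is_dna <- function(x) grepl("^[ACGT]*$", x)

common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(substr(a, 1L, n), "")[[1]]
  bv <- strsplit(substr(b, 1L, n), "")[[1]]
  d <- which(av != bv)
  if (length(d) == 0L) n else d[1L] - 1L
}

common_suffix_len <- function(a, b, cap) {
  n <- min(nchar(a), nchar(b), cap)
  if (n == 0L) return(0L)
  av <- rev(strsplit(a, "")[[1]])[seq_len(n)]
  bv <- rev(strsplit(b, "")[[1]])[seq_len(n)]
  d <- which(av != bv)
  if (length(d) == 0L) n else d[1L] - 1L
}

# Run a block under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Deterministic child streams from one root seed (kept below 2^31).
child_seed <- function(root, offset) {
  ((as.numeric(root) %% 65536) * 31013 + offset * 7901) %% 2147483629 + 1
}
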