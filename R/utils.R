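# Small shared helpers. Sequences are handled as plain uppercase character
# strings on the protospacer strand; heavy lifting on standard formats goes
# through Biostrings/rtracklayer elsewhere.

BASES <- c("A", "C", "G", "T")

# channel order is fixed package-wide
CHANNELS <- c("A", "C", "G", "T", "CTCF", "DNase", "H3K4me3", "RRBS")
EPI_MARKS <- c("ctcf", "dnase", "h3k4me3", "rrbs")
GUIDE_LEN <- 23L
PROTO_LEN <- 20L

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA strings (A/C/G/T only).
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# split a single string into a character vector of bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

check_dna <- function(x, len = NULL, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single string", call. = FALSE)
  }
  if (!is.null(len) && nchar(x) != len) {
    stop(what, " must have length ", len, ", got ", nchar(x), call. = FALSE)
  }
  ch <- seq_chars(x)
  bad <- which(!ch %in% BASES)
  if (length(bad)) {
    stop(what, " contains non-ACGT character '", ch[bad[1]],
         "' at position ", bad[1], call. = FALSE)
  }
  invisible(x)
}

# protospacer Hamming distance over positions 1-20 (PAM excluded)
hamming20 <- function(a, b) {
  sum(seq_chars(substr(a, 1L, PROTO_LEN)) != seq_chars(substr(b, 1L, PROTO_LEN)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# seeded evaluation that restores the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == round(x) && x >= 0
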