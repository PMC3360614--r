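# Sequence string helpers. Coordinates everywhere in the package are 0-based,
# half-open; 1-based positions occur only inside the fragment-rule accessors,
# where they are converted immediately.

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and maps T to U. No validation is performed here.
#' @param x character vector of sequences.
#' @return character vector over the RNA alphabet.
#' @export
as_rna <- function(x) chartr("Tt", "UU", toupper(x))

#' Normalize a nucleotide string to the DNA alphabet
#'
#' Uppercases and maps U to T.
#' @param x character vector of sequences.
#' @return character vector over the DNA alphabet.
#' @export
as_dna <- function(x) chartr("Uu", "TT", toupper(x))

revcomp_dna <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

revcomp_rna <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::RNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# 0=A 1=C 2=G 3=U/T 4=other (N). Accepts both alphabets.
encode_seq <- function(x) {
  ch <- seq_chars(chartr("Tt", "UU", toupper(x)))
  code <- match(ch, c("A", "C", "G", "U"))
  code[is.na(code)] <- 5L
  as.integer(code - 1L)
}

check_alphabet <- function(x, alphabet = c("RNA", "DNA"), allow_n = TRUE,
                           what = "sequence") {
  alphabet <- match.arg(alphabet)
  letters_ok <- if (alphabet == "RNA") "ACGU" else "ACGT"
  if (allow_n) letters_ok <- paste0(letters_ok, "N")
  bad <- grepl(sprintf("[^%s]", letters_ok), x)
  if (any(bad)) {
    stop(sprintf("illegal %s character in %s: %s", alphabet, what,
                 paste(utils::head(x[bad], 3), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

gc_fraction <- function(x) {
  ch <- seq_chars(toupper(x))
  if (length(ch) == 0) return(NA_real_)
  mean(ch %in% c("G", "C"))
}

# round-half-up to `digits`
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
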