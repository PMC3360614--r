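# FASTA / TSV input-output and the two packaged catalogue fixtures.

#' Read a FASTA file of sequence records
#'
#' Sequences are uppercased and normalized to the requested alphabet
#' (`U -> T` for DNA, `T -> U` for RNA). Record ids are the first whitespace
#' token of each header and must be unique.
#'
#' @param path path to a FASTA file (wrapped or unwrapped).
#' @param alphabet `"DNA"` or `"RNA"`.
#' @param allow_n permit `N` characters (default `TRUE`; draft ESTs carry
#'   them, catalogue entries must not).
#' @return a tibble with columns `id`, `sequence`, `length`.
#' @export
read_fasta <- function(path, alphabet = c("DNA", "RNA"), allow_n = TRUE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("empty record id in ", path, call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- if (alphabet == "DNA") as_dna(as.character(set)) else as_rna(as.character(set))
  for (i in seq_along(seqs)) {
    tryCatch(check_alphabet(seqs[i], alphabet, allow_n = allow_n, what = ids[i]),
             error = function(e) stop(conditionMessage(e), call. = FALSE))
  }
  if (any(nchar(seqs) < 1)) stop("empty sequence in ", path, call. = FALSE)
  tibble(id = ids, sequence = unname(seqs), length = unname(nchar(seqs)))
}

#' Write sequence records to a FASTA file
#'
#' @param records tibble/data.frame with `id` and `sequence` columns (or a
#'   named character vector).
#' @param path output path.
#' @param width line-wrap width; `Inf` for unwrapped.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70) {
  if (is.character(records)) {
    records <- tibble(id = names(records), sequence = unname(records))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$sequence[i]
    if (is.finite(width) && nchar(s) > width) {
      starts <- seq(1, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
    } else {
      writeLines(s, con)
    }
  }
  invisible(path)
}

#' Load a mature-miRNA catalogue from TSV
#'
#' Expects columns `name` and `sequence` (RNA alphabet, 15-30 nt). The
#' packaged catalogue of 58 mature miRNAs is returned when `path` is omitted.
#' Duplicate names are preserved as printed in the source catalogue.
#'
#' @param path TSV path; default is the packaged fixture
#'   `table1_catalogue.tsv`.
#' @return tibble with columns `name`, `sequence`, `length`.
#' @export
load_catalogue <- function(path = NULL) {
  path <- path %||% system.file("extdata", "table1_catalogue.tsv",
                                package = "mirest", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "sequence") %in% names(tab))) {
    stop("catalogue TSV needs columns 'name' and 'sequence'", call. = FALSE)
  }
  if (nrow(tab) == 0) return(tibble(name = character(), sequence = character(),
                                    length = integer()))
  seqs <- as_rna(tab$sequence)
  for (i in seq_along(seqs)) {
    check_alphabet(seqs[i], "RNA", allow_n = FALSE, what = tab$name[i])
  }
  len <- nchar(seqs)
  bad <- len < 15 | len > 30
  if (any(bad)) {
    stop("catalogue entry length outside 15-30 nt: ",
         paste(tab$name[bad], collapse = ", "), call. = FALSE)
  }
  tibble(name = tab$name, sequence = seqs, length = len)
}

#' Load per-miRNA target counts from TSV
#'
#' Expects columns `mirna`, `n_targets` and optionally `n_class2` (defaults
#' to 0 when absent). The packaged fixture `table2_targets.tsv` holds the
#' 11-miRNA target-count catalogue.
#'
#' @param path TSV path; default is the packaged fixture.
#' @return tibble with columns `mirna`, `n_targets`, `n_class2`.
#' @export
load_target_counts <- function(path = NULL) {
  path <- path %||% system.file("extdata", "table2_targets.tsv",
                                package = "mirest", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) {
    return(tibble(mirna = character(), n_targets = integer(), n_class2 = integer()))
  }
  if (!all(c("mirna", "n_targets") %in% names(tab))) {
    stop("target-count TSV needs columns 'mirna' and 'n_targets'", call. = FALSE)
  }
  if (is.null(tab$n_class2)) tab$n_class2 <- 0L
  tab$n_class2[is.na(tab$n_class2)] <- 0L
  if (any(tab$n_targets < 0 | tab$n_class2 < 0)) {
    stop("negative target count", call. = FALSE)
  }
  if (any(tab$n_class2 > tab$n_targets)) {
    stop("class II count exceeds total for: ",
         paste(tab$mirna[tab$n_class2 > tab$n_targets], collapse = ", "),
         call. = FALSE)
  }
  tibble(mirna = tab$mirna, n_targets = as.integer(tab$n_targets),
         n_class2 = as.integer(tab$n_class2))
}
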