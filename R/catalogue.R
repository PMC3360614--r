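# Name-based family grouping and conservation statistics over mature miRNAs.
# A family is the set of miRNAs sharing the numeric identifier core
# (miR-33a/33b -> family "33"); variant letters and locus-copy suffixes
# collapse, and species prefixes are ignored.

#' Parse a miRNA name into its nomenclature components
#'
#' Accepts names of the form `<prefix>-miR-<digits>[letters][-digits]` (and
#' `let` cores, e.g. `bmo-let-7a`).
#'
#' @param name character vector of miRNA names.
#' @return tibble with columns `name`, `species_prefix`, `core`,
#'   `variant_letter` (`NA` if none), `copy_number` (`NA` if none).
#' @export
parse_name <- function(name) {
  pat <- "^([A-Za-z0-9]+)-(miR|let)-(\\d+)([a-z]*)(?:-(\\d+))?$"
  m <- regmatches(name, regexec(pat, name))
  bad <- vapply(m, length, integer(1)) == 0
  if (any(bad)) {
    stop("unparseable miRNA name: ", paste(name[bad], collapse = ", "),
         call. = FALSE)
  }
  tibble(
    name = name,
    species_prefix = vapply(m, `[`, character(1), 2),
    core = vapply(m, `[`, character(1), 4),
    variant_letter = ifelse(nzchar(vapply(m, `[`, character(1), 5)),
                            vapply(m, `[`, character(1), 5), NA_character_),
    copy_number = suppressWarnings(
      as.integer(vapply(m, `[`, character(1), 6)))
  )
}

#' Group mature miRNAs into nomenclature families
#'
#' One family per distinct numeric core; members are sorted by name. The
#' output partitions the input name multiset.
#'
#' @param mirnas tibble with a `name` column (e.g. [load_catalogue()]).
#' @return tibble with columns `family_key`, `n_members`, `members` (list
#'   column), sorted by numeric core.
#' @export
group_families <- function(mirnas) {
  if (is.null(mirnas) || nrow(mirnas) == 0) {
    return(tibble(family_key = character(), n_members = integer(),
                  members = list()))
  }
  parsed <- parse_name(mirnas$name)
  keys <- unique(parsed$core[order(as.integer(parsed$core))])
  out <- lapply(keys, function(k) {
    mem <- sort(parsed$name[parsed$core == k])
    tibble(family_key = k, n_members = length(mem), members = list(mem))
  })
  do.call(rbind, out)
}

#' Percent identity between two mature sequences
#'
#' Ungapped sliding comparison: the best overlap over all relative offsets
#' (including partial overhangs), scored as matches / length of the shorter
#' sequence, in percent to one decimal.
#'
#' @param a,b RNA sequences.
#' @return percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b) {
  a <- as_rna(a); b <- as_rna(b)
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence", call. = FALSE)
  ca <- seq_chars(a); cb <- seq_chars(b)
  la <- length(ca); lb <- length(cb)
  short <- min(la, lb)
  best <- 0L
  for (off in (-(lb - 1)):(la - 1)) {
    ia <- max(1, 1 + off):min(la, lb + off)
    ib <- ia - off
    matches <- sum(ca[ia] == cb[ib] & ca[ia] != "N")
    if (matches > best) best <- matches
  }
  round_half_up(100 * best / short, 1)
}

#' Export families as a two-column TSV
#'
#' @param families tibble from [group_families()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_families_tsv <- function(families, path) {
  flat <- do.call(rbind, lapply(seq_len(nrow(families)), function(i) {
    data.frame(family_key = families$family_key[i],
               member = families$members[[i]])
  }))
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
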