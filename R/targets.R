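# Target prediction: class I = canonical 7mer seed match (miRNA positions
# 2-8, Watson-Crick only) followed by a full-duplex free-energy filter;
# class II = hybridization of the miRNA 3' fragment (1-based positions 12 to
# x-2) against sliding 3'UTR windows. Both use the duplex threshold
# dG < -20 kcal/mol. Genes are counted once (best site), matching per-gene
# bookkeeping.

#' Seed fragment of a mature miRNA (positions 2-8)
#'
#' @param sequence mature RNA sequence, at least 8 nt.
#' @return the 7-nt seed (1-based positions 2-8).
#' @export
seed_fragment <- function(sequence) {
  sequence <- as_rna(sequence)
  if (nchar(sequence) < 8) stop("mature shorter than 8 nt has no seed", call. = FALSE)
  substr(sequence, 2, 8)
}

#' 3' fragment of a mature miRNA (positions 12 to x-2)
#'
#' Returns the 1-based inclusive positions 12 .. x-2 (`x` = mature length),
#' i.e. a fragment of length x-13.
#'
#' @param sequence mature RNA sequence, at least 14 nt.
#' @return the 3' fragment.
#' @export
fragment_12_to_xminus2 <- function(sequence) {
  sequence <- as_rna(sequence)
  x <- nchar(sequence)
  if (x < 14) stop("mature of length ", x, " yields an empty 3' fragment",
                   call. = FALSE)
  substr(sequence, 12, x - 2)
}

#' Intermolecular duplex minimum free energy
#'
#' Best hybridization of `a` (5'->3') against `b` (3'->5') allowing stacks,
#' bulges and internal loops from the packaged parameter table;
#' intramolecular pairs are excluded. A single initiation penalty is charged
#' per duplex. Returns 0 and no pairs when no stabilizing duplex exists.
#'
#' @param a,b RNA sequences (DNA accepted, transcribed).
#' @param params energy parameters from [energy_params()].
#' @return list with `dg` (kcal/mol) and `pairs` (two-column 0-based matrix:
#'   position in `a`, position in `b`).
#' @export
duplex_mfe <- function(a, b, params = energy_params()) {
  a <- as_rna(a); b <- as_rna(b)
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence", call. = FALSE)
  check_alphabet(a, "RNA", allow_n = TRUE, what = "duplex query")
  check_alphabet(b, "RNA", allow_n = TRUE, what = "duplex target")
  eb <- rev(encode_seq(b))
  res <- duplex_mfe_cpp(encode_seq(a), eb, params$stack, params$pair_ok,
                        params$bulge, params$internal, params$duplex_init,
                        params$max_interior)
  pairs <- res$pairs
  if (nrow(pairs) > 0) pairs[, 2] <- nchar(b) - 1L - pairs[, 2]
  list(dg = res$dg, pairs = pairs)
}

#' Find class I (seed-match) target sites in one 3'UTR
#'
#' Scans for exact reverse complements of the 7-nt seed (G.U not allowed in
#' the seed), then scores a window covering the full miRNA complement with
#' [duplex_mfe()] and keeps sites with `dg < threshold`.
#'
#' @param mirna one-row tibble (or list) with `name` and `sequence`.
#' @param utr one-row tibble (or list) with `gene_id` and `sequence` (sense
#'   mRNA orientation, RNA).
#' @param threshold duplex free-energy cutoff (default -20 kcal/mol).
#' @param params energy parameters.
#' @return tibble with `mirna_name`, `gene_id`, `site_start`, `site_end`
#'   (0-based half-open on the UTR), `dg`, `class` (`"I"`).
#' @export
find_class1_sites <- function(mirna, utr, threshold = -20,
                              params = energy_params()) {
  mseq <- as_rna(mirna$sequence[[1]])
  useq <- as_rna(utr$sequence[[1]])
  x <- nchar(mseq)
  L <- nchar(useq)
  empty <- tibble(mirna_name = character(), gene_id = character(),
                  site_start = integer(), site_end = integer(),
                  dg = numeric(), class = character())
  if (L < 7) return(empty)
  seed_rc <- revcomp_rna(seed_fragment(mseq))
  hits <- gregexpr(seed_rc, useq, fixed = TRUE)[[1]]
  if (hits[1] == -1) return(empty)
  rows <- list()
  for (p1 in as.integer(hits)) {
    p <- p1 - 1L  # 0-based start of the seed complement
    # miRNA position k (1-based) pairs UTR position p + 8 - k
    ws <- max(0L, p + 8L - x - 2L)
    we <- min(L, p + 8L + 2L)
    site <- substr(useq, ws + 1, we)
    dg <- duplex_mfe(mseq, site, params)$dg
    if (dg < threshold) {
      rows[[length(rows) + 1L]] <- tibble(
        mirna_name = mirna$name[[1]], gene_id = utr$gene_id[[1]],
        site_start = ws, site_end = as.integer(we), dg = dg, class = "I")
    }
  }
  if (length(rows) == 0) return(empty)
  do.call(rbind, rows)
}

#' Find class II (3'-fragment hybridization) targets across a 3'UTR set
#'
#' Hybridizes the miRNA 3' fragment against sliding UTR windows (window =
#' fragment length + 10 nt, step 1) and reports one result per gene (the
#' best site) when its duplex energy is below `threshold`.
#'
#' @param mirna one-row tibble (or list) with `name` and `sequence` (at
#'   least 14 nt so the fragment is non-empty).
#' @param utrs tibble of UTRs with `gene_id` and `sequence`.
#' @param threshold duplex free-energy cutoff (default -20 kcal/mol).
#' @param query `"fragment"` scans with the 3' fragment alone (positions 12
#'   to x-2); `"full_mirna"` scans with the whole mature, for the reading in
#'   which the fragment only selects candidates but the full molecule
#'   hybridizes.
#' @param params energy parameters.
#' @return tibble with `mirna_name`, `gene_id`, `site_start`, `site_end`,
#'   `dg`, `class` (`"II"`).
#' @export
find_class2_targets <- function(mirna, utrs, threshold = -20,
                                query = c("fragment", "full_mirna"),
                                params = energy_params()) {
  query <- match.arg(query)
  frag <- fragment_12_to_xminus2(mirna$sequence[[1]])
  if (query == "full_mirna") frag <- as_rna(mirna$sequence[[1]])
  empty <- tibble(mirna_name = character(), gene_id = character(),
                  site_start = integer(), site_end = integer(),
                  dg = numeric(), class = character())
  if (is.null(utrs) || nrow(utrs) == 0) return(empty)
  ef <- encode_seq(frag)
  wlen <- nchar(frag) + 10L
  rows <- list()
  for (g in seq_len(nrow(utrs))) {
    useq <- as_rna(utrs$sequence[g])
    res <- duplex_scan_cpp(ef, encode_seq(useq), wlen, params$stack,
                           params$pair_ok, params$bulge, params$internal,
                           params$duplex_init, params$max_interior)
    if (res$dg < threshold) {
      rows[[length(rows) + 1L]] <- tibble(
        mirna_name = mirna$name[[1]], gene_id = utrs$gene_id[g],
        site_start = as.integer(res$start),
        site_end = as.integer(res$start + res$window_len),
        dg = res$dg, class = "II")
    }
  }
  if (length(rows) == 0) return(empty)
  do.call(rbind, rows)
}

#' Summarize per-miRNA target counts
#'
#' @param rows tibble from [load_target_counts()].
#' @return list with `total`, `class1`, `class2` and the per-miRNA tibble.
#' @export
summarize_targets <- function(rows) {
  if (any(rows$n_class2 > rows$n_targets)) {
    stop("class II count exceeds total", call. = FALSE)
  }
  total <- sum(rows$n_targets)
  class2 <- sum(rows$n_class2)
  list(total = total, class2 = class2, class1 = total - class2,
       per_mirna = rows)
}

#' Transcription-factor ratio in percent
#'
#' `100 * n_tf / n_total`, half-up rounded to one decimal.
#'
#' @param n_tf transcription-factor target count.
#' @param n_total total target count (>= 1).
#' @return percent, one decimal.
#' @export
tf_ratio <- function(n_tf, n_total) {
  if (any(n_total < 1)) stop("zero denominator", call. = FALSE)
  if (any(n_tf > n_total)) stop("n_tf exceeds n_total", call. = FALSE)
  round_half_up(100 * n_tf / n_total, 1)
}
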