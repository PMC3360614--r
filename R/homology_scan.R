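# Stage 1-2 of the discovery pipeline: bounded-mismatch (Hamming) scan of
# ESTs against a reference set of mature miRNAs, and extraction of ~100 nt
# candidate precursor windows around each hit. No indels: a mature aligned
# with gaps is outside the model. All coordinates 0-based half-open on the
# EST forward strand.

#' Hamming distance between two equal-length sequences
#'
#' A position holding `N` in either sequence counts as a mismatch.
#'
#' @param a,b sequences of equal length (RNA or DNA; compared after
#'   normalization to a common alphabet).
#' @return integer mismatch count.
#' @export
count_mismatches <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences differ in length", call. = FALSE)
  ca <- seq_chars(as_rna(a))
  cb <- seq_chars(as_rna(b))
  sum(ca != cb | ca == "N" | cb == "N")
}

# collapse runs of mutually overlapping per-position hits (one reference, one
# strand) to the local minimum-mismatch hit; ties go to the leftmost position
reduce_overlaps <- function(pos, mm, width) {
  if (length(pos) == 0) return(integer(0))
  o <- order(pos)
  pos <- pos[o]; mm <- mm[o]
  keep <- integer(0)
  run_start <- 1L
  n <- length(pos)
  for (i in seq_len(n)) {
    last <- i == n || pos[i + 1] >= pos[i] + width
    if (last) {
      run <- run_start:i
      best <- run[which.min(mm[run])]  # which.min takes the first = leftmost
      keep <- c(keep, best)
      run_start <- i + 1L
    }
  }
  o[keep]
}

#' Scan one EST for homologs of reference mature miRNAs
#'
#' Slides every reference over both strands of the EST and reports windows
#' with at most `max_mm` mismatches. Overlapping hits of the same reference
#' on the same strand are reduced to the local-minimum-mismatch hit (ties:
#' leftmost); hits identical in coordinates and strand across references are
#' deduplicated keeping the lowest-mismatch reference.
#'
#' @param est a one-row tibble (or list) with `id` and `sequence` (DNA).
#' @param refs tibble of references with `name` and `sequence` (RNA).
#' @param max_mm maximum mismatches (default 5).
#' @param both_strands scan the reverse complement too (default `TRUE`).
#' @return tibble with columns `est_id`, `ref_name`, `start`, `end`,
#'   `strand`, `mismatches`.
#' @export
scan_est <- function(est, refs, max_mm = 5, both_strands = TRUE) {
  if (is.null(refs) || nrow(refs) == 0) stop("empty reference set", call. = FALSE)
  est_seq <- as_dna(est$sequence[[1]])
  est_id <- est$id[[1]]
  L <- nchar(est_seq)
  enc_fwd <- encode_seq(est_seq)
  enc_rev <- if (both_strands) encode_seq(revcomp_dna(est_seq)) else NULL

  out <- list()
  for (r in seq_len(nrow(refs))) {
    ref_enc <- encode_seq(refs$sequence[r])
    w <- length(ref_enc)
    if (w > L) next
    for (strand in if (both_strands) c("+", "-") else "+") {
      prof <- hamming_profile_cpp(if (strand == "+") enc_fwd else enc_rev, ref_enc)
      pos <- which(prof <= max_mm) - 1L
      if (length(pos) == 0) next
      mm <- prof[pos + 1L]
      keep <- reduce_overlaps(pos, mm, w)
      pos <- pos[keep]; mm <- mm[keep]
      start <- if (strand == "+") pos else L - pos - w
      out[[length(out) + 1L]] <- tibble(
        est_id = est_id, ref_name = refs$name[r],
        start = as.integer(start), end = as.integer(start + w),
        strand = strand, mismatches = as.integer(mm))
    }
  }
  if (length(out) == 0) {
    return(tibble(est_id = character(), ref_name = character(),
                  start = integer(), end = integer(), strand = character(),
                  mismatches = integer()))
  }
  hits <- do.call(rbind, out)
  # dedupe identical loci across references: keep min mismatches, then the
  # first reference in input order
  key <- paste(hits$start, hits$end, hits$strand)
  ord <- order(key, hits$mismatches, match(hits$ref_name, refs$name))
  hits <- hits[ord, ]
  hits <- hits[!duplicated(paste(hits$start, hits$end, hits$strand)), ]
  hits[order(hits$start, hits$end, hits$strand), ]
}

#' Scan a whole EST set
#'
#' @param ests tibble of ESTs (`id`, `sequence`).
#' @inheritParams scan_est
#' @return row-bound tibble of hits from [scan_est()].
#' @export
scan_ests <- function(ests, refs, max_mm = 5, both_strands = TRUE) {
  res <- lapply(seq_len(nrow(ests)), function(i) {
    scan_est(ests[i, ], refs, max_mm = max_mm, both_strands = both_strands)
  })
  do.call(rbind, res)
}

#' Extract candidate precursor windows around a homology hit
#'
#' Emits up to three windows of total length at most `window_len` placing the
#' mature region in the 5' arm, centered, and in the 3' arm, clipped at EST
#' boundaries. Windows shorter than mature length + 15 nt after clipping are
#' dropped; duplicates after clipping are collapsed. Minus-strand hits are
#' reverse-complemented so every window reads 5'->3' with the mature sense
#' sequence inside.
#'
#' @param est one-row tibble with `id`, `sequence` (DNA).
#' @param hit one-row tibble from [scan_est()].
#' @param window_len target window length (default 100).
#' @param flank_pad flank left outside the mature in the arm placements
#'   (default 5 nt).
#' @return tibble with `est_id`, `win_start`, `win_end` (EST forward
#'   coordinates), `strand`, `placement`, `arm_hint`, `sequence` (RNA,
#'   window orientation), `mature_offset`, `mature_len`, `ref_name`,
#'   `mismatches`.
#' @export
extract_windows <- function(est, hit, window_len = 100, flank_pad = 5) {
  est_seq <- as_dna(est$sequence[[1]])
  L <- nchar(est_seq)
  if (hit$start < 0 || hit$end > L || hit$start >= hit$end) {
    stop("hit lies outside the EST", call. = FALSE)
  }
  ml <- hit$end - hit$start
  minus <- identical(hit$strand, "-")
  # work in the strand-local frame: for minus hits, mirror onto the reverse
  # complement so placement arithmetic is identical for both strands
  seq_local <- if (minus) revcomp_dna(est_seq) else est_seq
  ms <- if (minus) L - hit$end else hit$start
  me <- ms + ml

  placements <- list(
    list(name = "5p", ws = ms - flank_pad),
    list(name = "center", ws = ms - (window_len - ml) %/% 2),
    list(name = "3p", ws = me + flank_pad - window_len)
  )
  rows <- list()
  for (p in placements) {
    ws <- max(0L, as.integer(p$ws))
    we <- min(L, ws + as.integer(window_len))
    ws <- max(0L, min(ws, ms))     # never clip into the mature region
    we <- max(we, me)
    if (we - ws < ml + 15) next
    win_seq <- as_rna(substr(seq_local, ws + 1, we))
    rows[[length(rows) + 1L]] <- tibble(
      est_id = est$id[[1]],
      win_start = if (minus) L - we else ws,
      win_end = if (minus) L - ws else we,
      strand = hit$strand,
      placement = p$name,
      arm_hint = switch(p$name, "5p" = "5p", "3p" = "3p", "unknown"),
      sequence = win_seq,
      mature_offset = ms - ws,
      mature_len = as.integer(ml),
      ref_name = hit$ref_name,
      mismatches = hit$mismatches)
  }
  if (length(rows) == 0) {
    return(tibble(est_id = character(), win_start = integer(),
                  win_end = integer(), strand = character(),
                  placement = character(), arm_hint = character(),
                  sequence = character(), mature_offset = integer(),
                  mature_len = integer(), ref_name = character(),
                  mismatches = integer()))
  }
  win <- do.call(rbind, rows)
  win[!duplicated(paste(win$win_start, win$win_end, win$strand)), ]
}

#' Export homology hits as BED6
#'
#' ESTs act as contigs; the score column carries the mismatch count.
#'
#' @param hits tibble from [scan_est()]/[scan_ests()].
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
export_hits_bed <- function(hits, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = hits$est_id,
    ranges = IRanges::IRanges(start = hits$start + 1L, end = hits$end),
    strand = hits$strand)
  S4Vectors::mcols(gr)$name <- hits$ref_name
  S4Vectors::mcols(gr)$score <- hits$mismatches
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
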