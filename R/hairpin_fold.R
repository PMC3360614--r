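# Stage 3: fold each candidate window into its best single-hairpin (rod-like,
# non-branching) structure under the packaged nearest-neighbor model, apply
# the precursor filter criteria, pick the lowest-energy precursor per hit,
# and detect same-EST miRNA clusters.
#
# The structure space is restricted to chains of nested pairs
# (i1,j1) > (i2,j2) > ... closed by a terminal loop of >= 3 nt; consecutive
# pairs are joined by a stack, a bulge or an internal loop (combined unpaired
# length <= max_interior). Exterior unpaired bases are free. This restriction
# matches the "classical stem-loop" requirement of pre-miRNA validation and
# keeps an exact enumeration oracle feasible.

fold_structure <- function(sequence, dg, pairs) {
  n <- nchar(sequence)
  db <- rep(".", n)
  loop_size <- NA_integer_
  if (nrow(pairs) > 0) {
    db[pairs[, 1] + 1L] <- "("
    db[pairs[, 2] + 1L] <- ")"
    inner <- pairs[nrow(pairs), ]
    loop_size <- as.integer(inner[2] - inner[1] - 1L)
  }
  structure(list(
    sequence = sequence,
    pairs = pairs,
    dot_bracket = paste(db, collapse = ""),
    mfe = dg,
    loop_size = loop_size,
    stem_pairs = nrow(pairs),
    gc_content = gc_fraction(sequence)
  ), class = "hairpin_structure")
}

#' @export
print.hairpin_structure <- function(x, ...) {
  cat(x$sequence, "\n", x$dot_bracket, "\n", sep = "")
  cat(sprintf("dG = %.2f kcal/mol, %d pairs, loop %s nt, GC %.2f\n",
              x$mfe, x$stem_pairs,
              ifelse(is.na(x$loop_size), "-", x$loop_size), x$gc_content))
  invisible(x)
}

#' Fold an RNA sequence into its best single-hairpin structure
#'
#' Dynamic program over all non-branching stem-loop structures under the
#' packaged nearest-neighbor model (Watson-Crick and G.U stacks, hairpin /
#' bulge / internal-loop length penalties). The open chain (no pairs) has
#' free energy 0 and is returned when no negative-energy hairpin exists.
#'
#' @param sequence RNA string (DNA accepted, transcribed); 5-400 nt.
#' @param params energy parameters from [energy_params()].
#' @return a `hairpin_structure`: list with `sequence`, `pairs` (0-based
#'   two-column matrix, outermost first), `dot_bracket`, `mfe` (kcal/mol),
#'   `loop_size`, `stem_pairs`, `gc_content`.
#' @export
fold_single_hairpin <- function(sequence, params = energy_params()) {
  sequence <- as_rna(sequence)
  check_alphabet(sequence, "RNA", allow_n = TRUE)
  n <- nchar(sequence)
  if (n < 5 || n > 400) stop("sequence length must be in 5..400 nt", call. = FALSE)
  res <- fold_hairpin_cpp(encode_seq(sequence), params$stack, params$pair_ok,
                          params$hairpin, params$bulge, params$internal,
                          params$max_interior)
  fold_structure(sequence, res$dg, res$pairs)
}

#' Score a given single-hairpin pair chain
#'
#' Recomputes the model free energy of an explicit chain of nested pairs
#' (outermost first) by summing its stack/loop terms plus the terminal-loop
#' penalty. Used by the enumeration oracle and by additivity checks.
#'
#' @param sequence RNA string.
#' @param pairs 0-based two-column matrix of nested pairs, outermost first.
#' @param params energy parameters.
#' @return free energy in kcal/mol (`Inf` if the chain is invalid under the
#'   model).
#' @export
score_hairpin_chain <- function(sequence, pairs, params = energy_params()) {
  if (is.null(pairs) || nrow(pairs) == 0) return(0)
  enc <- encode_seq(as_rna(sequence))
  total <- 0
  for (t in seq_len(nrow(pairs))) {
    i <- pairs[t, 1]; j <- pairs[t, 2]
    if (!params$pair_ok[enc[i + 1] + 1, enc[j + 1] + 1]) return(Inf)
    if (t > 1) {
      i0 <- pairs[t - 1, 1]; j0 <- pairs[t - 1, 2]
      g1 <- i - i0 - 1L; g2 <- j0 - j - 1L
      if (g1 < 0 || g2 < 0) return(Inf)
      if (g1 == 0 && g2 == 0) {
        total <- total + stack_energy(params, enc[i0 + 1], enc[j0 + 1],
                                      enc[i + 1], enc[j + 1])
      } else if (g1 + g2 > params$max_interior) {
        return(Inf)
      } else if (g1 == 0 || g2 == 0) {
        total <- total + params$bulge[g1 + g2]
      } else {
        total <- total + params$internal[g1 + g2]
      }
    }
  }
  inner <- pairs[nrow(pairs), ]
  loop <- inner[2] - inner[1] - 1L
  if (loop < 3) return(Inf)
  total + params$hairpin[loop]
}

#' Exhaustively enumerate single-hairpin structures (verification oracle)
#'
#' Generates every chain of nested pairs with terminal loop >= 3 nt and
#' scores each with [score_hairpin_chain()]; returns the minimum. Search
#' space is identical to [fold_single_hairpin()] by construction, but the
#' search is brute force, so the input is capped at `max_len`.
#'
#' @param sequence RNA string, at most `max_len` nt.
#' @param max_len enumeration cap (default 18).
#' @param params energy parameters.
#' @return list with `mfe` and `pairs` of the best structure (empty matrix,
#'   mfe 0 when no negative-energy hairpin exists).
#' @export
enumerate_structures <- function(sequence, max_len = 18,
                                 params = energy_params()) {
  sequence <- as_rna(sequence)
  n <- nchar(sequence)
  if (n == 0) stop("empty sequence", call. = FALSE)
  if (n > max_len) stop("sequence longer than max_len", call. = FALSE)
  check_alphabet(sequence, "RNA", allow_n = TRUE)
  enc <- encode_seq(sequence)
  ok <- function(i, j) {
    enc[i + 1] <= 3 && enc[j + 1] <= 3 && params$pair_ok[enc[i + 1] + 1, enc[j + 1] + 1]
  }
  candidate_pairs <- list()
  for (i in 0:(n - 1)) for (j in 0:(n - 1)) {
    if (j - i - 1 >= 3 && ok(i, j)) {
      candidate_pairs[[length(candidate_pairs) + 1L]] <- c(i, j)
    }
  }
  best <- list(mfe = 0, pairs = matrix(integer(0), 0, 2))
  recurse <- function(chain, i0, j0) {
    for (p in candidate_pairs) {
      if (p[1] <= i0 || p[2] >= j0) next
      new_chain <- rbind(chain, p)
      dg <- score_hairpin_chain(sequence, new_chain, params)
      if (is.finite(dg) && dg < best$mfe) best <<- list(mfe = dg, pairs = new_chain)
      if (p[2] - p[1] - 1 >= 5) recurse(new_chain, p[1], p[2])
    }
  }
  recurse(matrix(integer(0), 0, 2), -1L, n)
  best
}

# --- precursor filtering ----------------------------------------------------

criterion_names <- c("free_energy", "stem_loop", "mature_arm",
                     "mature_paired", "gc_content", "ch_ratio")

core_energy <- function(structure, mature_start, mature_end, params) {
  pairs <- structure$pairs
  if (nrow(pairs) == 0) return(0)
  touch <- (pairs[, 1] >= mature_start & pairs[, 1] < mature_end) |
    (pairs[, 2] >= mature_start & pairs[, 2] < mature_end)
  if (!any(touch)) return(0)
  outer <- which(touch)[1]
  score_hairpin_chain(structure$sequence,
                      pairs[outer:nrow(pairs), , drop = FALSE], params)
}

#' Apply the precursor filter criteria to a candidate window
#'
#' Evaluates, in order, recording every failure: (1) hairpin free energy
#' `mfe <= mfe_threshold` (default -20 kcal/mol); (2) a single stem-loop with
#' at least `min_stem` pairs; (3) the mature region confined to one arm,
#' overlapping the terminal loop by at most `max_loop_overlap` nt; (4) at
#' least `min_mature_paired` of mature positions paired; (5) window GC
#' content within `gc_bounds`; (6) `ch_ratio = core_mfe / mfe >=
#' min_ch_ratio`, where `core_mfe` is the energy of the stem-loop restricted
#' to the chain from the outermost pair touching the mature arm inward (the
#' package's own definitions of the core-energy criteria).
#'
#' @param window one-row tibble (or list) with `sequence`, `mature_offset`,
#'   `mature_len` (see [extract_windows()]).
#' @param config thresholds from [mirest_config()].
#' @param structure optional pre-computed [fold_single_hairpin()] result.
#' @param params energy parameters.
#' @return a `precursor_candidate` list: `window`, `structure`, `verdict`
#'   (`TRUE` iff no failures), `fail_reasons`, plus the derived statistics
#'   `core_mfe`, `ch_ratio`, `paired_fraction_mature`.
#' @export
evaluate_candidate <- function(window, config = mirest_config(),
                               structure = NULL, params = energy_params()) {
  seqc <- window$sequence[[1]]
  mo <- as.integer(window$mature_offset[[1]])
  ml <- as.integer(window$mature_len[[1]])
  stopifnot(mo >= 0, ml >= 1, mo + ml <= nchar(seqc))
  if (is.null(structure)) structure <- fold_single_hairpin(seqc, params)
  fails <- character(0)

  if (!(structure$mfe <= config$mfe_threshold)) fails <- c(fails, "free_energy")
  if (structure$stem_pairs < config$min_stem) fails <- c(fails, "stem_loop")

  pairs <- structure$pairs
  if (nrow(pairs) == 0) {
    fails <- c(fails, "mature_arm", "mature_paired", "ch_ratio")
    paired_frac <- 0; core_mfe <- 0; ch <- 0
  } else {
    inner <- pairs[nrow(pairs), ]
    loop_start <- inner[1] + 1L; loop_end <- inner[2]  # half-open loop interval
    m_start <- mo; m_end <- mo + ml
    overlap <- max(0, min(m_end, loop_end) - max(m_start, loop_start))
    crosses <- m_start < loop_start && m_end > loop_end
    if (crosses || overlap > config$max_loop_overlap) fails <- c(fails, "mature_arm")

    paired_pos <- c(pairs[, 1], pairs[, 2])
    paired_frac <- mean(seq(m_start, m_end - 1L) %in% paired_pos)
    if (paired_frac < config$min_mature_paired) fails <- c(fails, "mature_paired")

    core_mfe <- core_energy(structure, m_start, m_end, params)
    ch <- if (structure$mfe < 0) core_mfe / structure$mfe else 0
    if (ch < config$min_ch_ratio) fails <- c(fails, "ch_ratio")
  }

  gc <- structure$gc_content
  if (gc < config$gc_bounds[1] || gc > config$gc_bounds[2]) {
    fails <- c(fails, "gc_content")
  }
  fails <- criterion_names[criterion_names %in% fails]
  structure(list(window = window, structure = structure,
                 verdict = length(fails) == 0, fail_reasons = fails,
                 core_mfe = core_mfe, ch_ratio = ch,
                 paired_fraction_mature = paired_frac),
            class = "precursor_candidate")
}

#' Select the best-folding precursor among candidates for one hit
#'
#' Among passing candidates returns the one with minimum free energy; ties
#' break to the smaller window start. `NULL` when none passes.
#'
#' @param candidates list of `precursor_candidate` objects sharing one hit.
#' @return a `precursor_candidate` or `NULL`.
#' @export
select_best_precursor <- function(candidates) {
  if (length(candidates) == 0) return(NULL)
  passing <- Filter(function(c) isTRUE(c$verdict), candidates)
  if (length(passing) == 0) return(NULL)
  mfe <- vapply(passing, function(c) c$structure$mfe, numeric(1))
  ws <- vapply(passing, function(c) as.integer(c$window$win_start[[1]]), integer(1))
  passing[[order(mfe, ws)[1]]]
}

#' Detect clustered miRNAs on shared ESTs
#'
#' Groups accepted mature regions on the same EST and strand whose
#' consecutive gaps are at most `max_spacer` nt. Polycistronic precursors are
#' transcribed as one unit, so opposite-strand loci never cluster.
#'
#' @param accepted tibble with `est_id`, `strand`, `start`, `end`, `name`
#'   (mature coordinates on the EST forward strand).
#' @param max_spacer maximum spacer (default 1000 nt).
#' @return tibble with one row per cluster: `est_id`, `strand`,
#'   `member_names` (list column, coordinate order), `spacer_nt` (list
#'   column of consecutive gaps).
#' @export
detect_clusters <- function(accepted, max_spacer = 1000) {
  empty <- tibble(est_id = character(), strand = character(),
                  member_names = list(), spacer_nt = list())
  if (is.null(accepted) || nrow(accepted) < 2) return(empty)
  out <- list()
  for (key in unique(paste(accepted$est_id, accepted$strand))) {
    grp <- accepted[paste(accepted$est_id, accepted$strand) == key, ]
    if (nrow(grp) < 2) next
    grp <- grp[order(grp$start), ]
    gaps <- grp$start[-1] - grp$end[-nrow(grp)]
    starts_new <- c(TRUE, gaps > max_spacer)
    grp_chain <- cumsum(starts_new)
    for (cid in unique(grp_chain)) {
      members <- grp[grp_chain == cid, ]
      if (nrow(members) < 2) next
      sp <- members$start[-1] - members$end[-nrow(members)]
      out[[length(out) + 1L]] <- tibble(
        est_id = members$est_id[1], strand = members$strand[1],
        member_names = list(members$name),
        spacer_nt = list(as.integer(sp)))
    }
  }
  if (length(out) == 0) return(empty)
  do.call(rbind, out)
}

#' Export clusters as GFF3 features
#'
#' @param clusters tibble from [detect_clusters()].
#' @param accepted the accepted-hit tibble the clusters were derived from.
#' @param path output GFF3 path.
#' @return `path`, invisibly.
#' @export
export_clusters_gff3 <- function(clusters, accepted, path) {
  if (nrow(clusters) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  span <- t(vapply(seq_len(nrow(clusters)), function(i) {
    members <- clusters$member_names[[i]]
    sub <- accepted[accepted$est_id == clusters$est_id[i] &
                      accepted$name %in% members, ]
    c(min(sub$start) + 1L, max(sub$end))
  }, integer(2)))
  gr <- GenomicRanges::GRanges(
    seqnames = clusters$est_id,
    ranges = IRanges::IRanges(span[, 1], span[, 2]),
    strand = clusters$strand,
    type = "miRNA_cluster",
    ID = paste0("cluster_", seq_len(nrow(clusters))),
    members = vapply(clusters$member_names, paste, character(1),
                     collapse = ","))
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}
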