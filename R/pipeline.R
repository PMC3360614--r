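# Orchestration: discover -> fold/filter -> clusters, expression
# quantification, and target prediction, under a single configuration whose
# defaults are the published thresholds (max_mm = 5, ~100 nt windows,
# precursor dG <= -20 kcal/mol, duplex dG < -20 kcal/mol).

#' Pipeline configuration
#'
#' All thresholds of the pipeline in one place. Defaults reproduce the
#' published operating point; nothing threshold-like is hard-coded
#' elsewhere.
#'
#' @param max_mm maximum mismatches in the homology scan (default 5,
#'   inclusive).
#' @param window_len candidate precursor window length (default 100 nt).
#' @param mfe_threshold precursor hairpin free-energy cutoff, kcal/mol,
#'   pass iff `mfe <= mfe_threshold` (default -20).
#' @param duplex_threshold target-duplex cutoff, pass iff
#'   `dg < duplex_threshold` (default -20).
#' @param min_stem minimum stem pairs of a classical stem-loop (default 14).
#' @param max_loop_overlap maximum mature overlap with the terminal loop
#'   (default 4 nt).
#' @param min_mature_paired minimum paired fraction of the mature region
#'   (default 0.6).
#' @param gc_bounds admissible window GC range (default 0.20-0.80).
#' @param min_ch_ratio minimum core-energy ratio `core_mfe / mfe`
#'   (default 0.8).
#' @param max_spacer maximum spacer between clustered miRNAs (default
#'   1000 nt).
#' @param flank_pad arm-placement flank in window extraction (default 5 nt).
#' @param control_row control row name in intensity tables (default
#'   `"U6snRNA"`).
#' @param class_reference `"max"` or a sample column name used for
#'   fold-class calls.
#' @param class2_query `"fragment"` (default) or `"full_mirna"`: the query
#'   used in the class II hybridization scan.
#' @return a `mirest_config` list.
#' @export
mirest_config <- function(max_mm = 5, window_len = 100, mfe_threshold = -20,
                          duplex_threshold = -20, min_stem = 14,
                          max_loop_overlap = 4, min_mature_paired = 0.6,
                          gc_bounds = c(0.20, 0.80), min_ch_ratio = 0.8,
                          max_spacer = 1000, flank_pad = 5,
                          control_row = "U6snRNA", class_reference = "max",
                          class2_query = "fragment") {
  stopifnot(is.finite(mfe_threshold), is.finite(duplex_threshold),
            length(gc_bounds) == 2, gc_bounds[1] <= gc_bounds[2])
  structure(list(max_mm = max_mm, window_len = window_len,
                 mfe_threshold = mfe_threshold,
                 duplex_threshold = duplex_threshold, min_stem = min_stem,
                 max_loop_overlap = max_loop_overlap,
                 min_mature_paired = min_mature_paired, gc_bounds = gc_bounds,
                 min_ch_ratio = min_ch_ratio, max_spacer = max_spacer,
                 flank_pad = flank_pad, control_row = control_row,
                 class_reference = class_reference,
                 class2_query = class2_query),
            class = "mirest_config")
}

#' Run the discovery stage over an EST set
#'
#' Homology scan, window extraction, hairpin folding and filtering, best
#' precursor per hit, and cluster detection. Deterministic given inputs and
#' configuration.
#'
#' @param ests tibble of ESTs (`id`, `sequence` DNA).
#' @param refs tibble of reference matures (`name`, `sequence` RNA).
#' @param config a [mirest_config()].
#' @param params energy parameters.
#' @return list with `hits`, `accepted` (tibble: `name`, `est_id`,
#'   `win_start`, `win_end`, `start`, `end`, `strand`, `mfe`, `placement`,
#'   `mismatches`, `sequence`, `mature_sequence`), `clusters`, and
#'   `stage_counts` (`n_ests`, `n_ests_with_hits`, `n_hits`, `n_accepted`).
#' @export
run_discover <- function(ests, refs, config = mirest_config(),
                         params = energy_params()) {
  hits <- scan_ests(ests, refs, max_mm = config$max_mm)
  accepted_rows <- list()
  if (!is.null(hits) && nrow(hits) > 0) {
    for (h in seq_len(nrow(hits))) {
      hit <- hits[h, ]
      est <- ests[ests$id == hit$est_id, ]
      wins <- extract_windows(est, hit, window_len = config$window_len,
                              flank_pad = config$flank_pad)
      if (nrow(wins) == 0) next
      cands <- lapply(seq_len(nrow(wins)), function(w) {
        evaluate_candidate(wins[w, ], config = config, params = params)
      })
      best <- select_best_precursor(cands)
      if (is.null(best)) next
      w <- best$window
      mseq <- substr(w$sequence, w$mature_offset + 1,
                     w$mature_offset + w$mature_len)
      accepted_rows[[length(accepted_rows) + 1L]] <- tibble(
        name = paste0(hit$est_id, "|", hit$ref_name),
        est_id = hit$est_id, ref_name = hit$ref_name,
        win_start = w$win_start, win_end = w$win_end,
        start = hit$start, end = hit$end, strand = hit$strand,
        mfe = best$structure$mfe, placement = w$placement,
        mismatches = hit$mismatches, sequence = w$sequence,
        mature_sequence = mseq)
    }
  }
  accepted <- if (length(accepted_rows) > 0) do.call(rbind, accepted_rows) else
    tibble(name = character(), est_id = character(), ref_name = character(),
           win_start = integer(), win_end = integer(), start = integer(),
           end = integer(), strand = character(), mfe = numeric(),
           placement = character(), mismatches = integer(),
           sequence = character(), mature_sequence = character())
  clusters <- detect_clusters(accepted, max_spacer = config$max_spacer)
  list(hits = hits, accepted = accepted, clusters = clusters,
       stage_counts = c(n_ests = nrow(ests),
                        n_ests_with_hits = length(unique(hits$est_id)),
                        n_hits = if (is.null(hits)) 0L else nrow(hits),
                        n_accepted = nrow(accepted)))
}

#' Run the expression stage on an intensity table
#'
#' @param table intensity matrix (rows = miRNAs + control, cols = samples)
#'   or a TSV path.
#' @param config a [mirest_config()].
#' @return list with `expression` (the [relative_expression()] result),
#'   `class_counts` (named counts over all fold classes), and `clustering`
#'   (`NULL` with a warning when fewer than 2 miRNA rows).
#' @export
run_expression <- function(table, config = mirest_config()) {
  if (is.character(table)) {
    table <- as.matrix(read.delim(table, row.names = 1, check.names = FALSE))
  }
  em <- relative_expression(table, config = config)
  counts <- vapply(fold_class_labels, function(cl) count_classes(em, cl),
                   integer(1))
  clustering <- if (nrow(em$clamped) >= 2) cluster_rows(em) else {
    warning("fewer than 2 miRNA rows; clustering skipped")
    NULL
  }
  list(expression = em, class_counts = counts, clustering = clustering)
}

#' Run the target-prediction stage
#'
#' Class I seed-match sites plus class II fragment-hybridization targets for
#' every catalogue entry against a 3'UTR set, deduplicated per gene (best
#' site), plus a per-miRNA summary with a grand-total line.
#'
#' @param mirnas tibble with `name`, `sequence`.
#' @param utrs tibble with `gene_id`, `sequence`.
#' @param config a [mirest_config()].
#' @param params energy parameters.
#' @return list with `sites` (tibble of per-gene best sites, both classes)
#'   and `summary` (per-miRNA `n_targets`, `n_class2`, plus `total`,
#'   `class1`, `class2` grand totals).
#' @export
run_targets <- function(mirnas, utrs, config = mirest_config(),
                        params = energy_params()) {
  all_sites <- list()
  for (r in seq_len(nrow(mirnas))) {
    m <- mirnas[r, ]
    c1 <- list()
    for (g in seq_len(nrow(utrs))) {
      s <- find_class1_sites(m, utrs[g, ], threshold = config$duplex_threshold,
                             params = params)
      if (nrow(s) > 0) c1[[length(c1) + 1L]] <- s[which.min(s$dg), ]
    }
    c1 <- if (length(c1) > 0) do.call(rbind, c1) else NULL
    c2 <- if (nchar(m$sequence[[1]]) >= 14) {
      find_class2_targets(m, utrs, threshold = config$duplex_threshold,
                          query = config$class2_query, params = params)
    } else {
      NULL
    }
    sites <- rbind(c1, c2)
    if (!is.null(sites) && nrow(sites) > 0) {
      # one row per gene: class I takes precedence (a seed-anchored site is
      # the canonical call); remaining genes keep their class II site
      sites <- sites[order(match(sites$class, c("I", "II")), sites$dg), ]
      sites <- sites[!duplicated(sites$gene_id), ]
      all_sites[[length(all_sites) + 1L]] <- sites
    }
  }
  sites <- if (length(all_sites) > 0) do.call(rbind, all_sites) else
    tibble(mirna_name = character(), gene_id = character(),
           site_start = integer(), site_end = integer(), dg = numeric(),
           class = character())
  per <- lapply(seq_len(nrow(mirnas)), function(r) {
    sub <- sites[sites$mirna_name == mirnas$name[r], ]
    tibble(mirna = mirnas$name[r], n_targets = nrow(sub),
           n_class2 = sum(sub$class == "II"))
  })
  per <- do.call(rbind, per)
  summ <- summarize_targets(per)
  list(sites = sites, summary = summ)
}
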