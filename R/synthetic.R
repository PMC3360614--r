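# Synthetic-data generators with planted ground truth. These stand in for
# the study's unpublished EST libraries: every generator is a pure function
# of its parameters and seed, and the truth object is sufficient to score
# any pipeline output against what was planted.

random_seq <- function(n, gc = 0.42, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  bases <- if (alphabet == "DNA") c("A", "T", "G", "C") else c("A", "U", "G", "C")
  paste(sample(bases, n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

mutate_positions <- function(sequence, positions, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  bases <- if (alphabet == "RNA") c("A", "C", "G", "U") else c("A", "C", "G", "T")
  ch <- seq_chars(sequence)
  for (p in positions) {
    ch[p] <- sample(setdiff(bases, ch[p]), 1)
  }
  paste(ch, collapse = "")
}

# builds one ~precursor_len construct using the current RNG state
plant_precursor_impl <- function(mature, arm = c("5p", "3p"), mutations = 0,
                                 precursor_len = 100, config = mirest_config(),
                                 params = energy_params(), max_tries = 25) {
  arm <- match.arg(arm)
  mature <- as_rna(mature)
  x <- nchar(mature)
  if (x > 30) stop("mature longer than 30 nt", call. = FALSE)
  if (mutations > 10) stop("at most 10 mutations supported", call. = FALSE)
  mch <- seq_chars(mature)
  for (try in seq_len(max_tries)) {
    loop_len <- sample(8:12, 1)
    comp <- seq_chars(revcomp_rna(mature))
    # 2-4 G.U wobbles: where the mature holds G (partner C -> U) or U
    # (partner A -> G); the pair stays stackable so the stem survives
    wobble_ok <- which(mch %in% c("G", "U"))
    n_wob <- min(sample(2:4, 1), length(wobble_ok))
    if (n_wob > 0) {
      for (p in sample(wobble_ok, n_wob)) {
        q <- x - p + 1  # partner index in the complement arm
        comp[q] <- if (mch[p] == "G") "U" else "G"
      }
    }
    comp <- paste(comp, collapse = "")
    flank_total <- max(0, precursor_len - (2 * x + loop_len))
    f5 <- sample(0:flank_total, 1)
    f3 <- flank_total - f5
    loop_seq <- random_seq(loop_len, gc = 0.3, alphabet = "RNA")
    arms <- if (arm == "5p") c(mature, loop_seq, comp) else c(comp, loop_seq, mature)
    seqc <- paste0(random_seq(f5, alphabet = "RNA"), paste(arms, collapse = ""),
                   random_seq(f3, alphabet = "RNA"))
    mo <- if (arm == "5p") f5 else f5 + x + loop_len
    win <- list(sequence = seqc, mature_offset = mo, mature_len = x)
    cand <- evaluate_candidate(win, config = config, params = params)
    if (isTRUE(cand$verdict)) {
      if (mutations > 0) {
        pos <- mo + sample.int(x, mutations)
        seqc <- mutate_positions(seqc, pos, "RNA")
      }
      return(list(sequence = seqc, mature_offset = mo, mature_len = x,
                  arm = arm, loop_len = loop_len, mutations = mutations))
    }
  }
  stop("failed to build a filter-passing precursor for this mature after ",
       max_tries, " tries", call. = FALSE)
}

#' Build a synthetic precursor hairpin around a mature miRNA
#'
#' Constructs mature arm + random loop (8-12 nt) + reverse complement of the
#' mature carrying 2-4 planted G.U wobbles + random flanks to
#' `precursor_len` nt. The unmutated construct is self-checked to pass
#' [evaluate_candidate()] at the supplied thresholds (regenerated up to
#' `max_tries` times); `mutations` substitutions are then applied to the
#' mature copy for threshold testing.
#'
#' @param mature mature RNA sequence (<= 30 nt).
#' @param seed integer seed; the construct is a pure function of the
#'   arguments.
#' @param arm which arm carries the mature (`"5p"` or `"3p"`).
#' @param mutations substitutions applied to the planted mature copy
#'   (<= 10).
#' @param precursor_len construct length (default 100 nt).
#' @param config,params filter thresholds and energy parameters used in the
#'   self-check.
#' @param max_tries regeneration bound for the self-check.
#' @return list with `sequence` (RNA), `mature_offset`, `mature_len`, `arm`,
#'   `loop_len`, `mutations`.
#' @export
plant_precursor <- function(mature, seed, arm = c("5p", "3p"), mutations = 0,
                            precursor_len = 100, config = mirest_config(),
                            params = energy_params(), max_tries = 25) {
  withr::with_seed(seed, plant_precursor_impl(
    mature, arm = arm, mutations = mutations, precursor_len = precursor_len,
    config = config, params = params, max_tries = max_tries))
}

#' Generate a synthetic EST dataset with planted precursors
#'
#' Plants one precursor per selected reference mature inside random
#' background ESTs (lengths 300-900 nt, configurable GC) and adds decoy ESTs
#' of pure background.
#'
#' @param refs tibble of reference matures (`name`, `sequence`).
#' @param n_planted number of planted precursors (references sampled without
#'   replacement while possible).
#' @param n_decoys number of decoy ESTs.
#' @param seed integer seed.
#' @param decoy_len fixed decoy length, or `NULL` for random 300-900 nt.
#' @param gc background GC fraction (default 0.42, a typical lepidopteran
#'   transcript composition).
#' @param config,params passed to the precursor self-check.
#' @return list with `ests` (tibble `id`, `sequence`, `length`, `planted`)
#'   and `truth` (list with `planted_precursors` tibble — `est_id`,
#'   `win_start`, `win_end`, `mature_start`, `mature_end`, `name`, `arm` —
#'   `decoy_ids`, `seed`).
#' @export
generate_est_dataset <- function(refs, n_planted = 20, n_decoys = 200, seed = 1,
                                 decoy_len = NULL, gc = 0.42,
                                 config = mirest_config(),
                                 params = energy_params()) {
  stopifnot(n_planted >= 0, n_decoys >= 0)
  withr::with_seed(seed, {
    chosen <- if (n_planted > 0) {
      refs[sample(seq_len(nrow(refs)), n_planted,
                  replace = n_planted > nrow(refs)), ]
    } else {
      refs[0, ]
    }
    est_rows <- list()
    truth_rows <- list()
    for (i in seq_len(n_planted)) {
      pre <- plant_precursor_impl(chosen$sequence[i],
                                  arm = sample(c("5p", "3p"), 1),
                                  config = config, params = params)
      plen <- nchar(pre$sequence)
      est_len <- sample(300:900, 1)
      pos <- sample(0:(est_len - plen), 1)
      background <- random_seq(est_len, gc = gc, alphabet = "DNA")
      est_seq <- paste0(substr(background, 1, pos), as_dna(pre$sequence),
                        substr(background, pos + plen + 1, est_len))
      id <- sprintf("planted_%03d", i)
      est_rows[[i]] <- tibble(id = id, sequence = est_seq,
                              length = nchar(est_seq), planted = TRUE)
      truth_rows[[i]] <- tibble(
        est_id = id, win_start = pos, win_end = pos + plen,
        mature_start = pos + pre$mature_offset,
        mature_end = pos + pre$mature_offset + pre$mature_len,
        name = chosen$name[i], arm = pre$arm)
    }
    decoy_ids <- sprintf("decoy_%03d", seq_len(n_decoys))
    for (d in seq_len(n_decoys)) {
      dl <- if (is.null(decoy_len)) sample(300:900, 1) else decoy_len
      est_rows[[n_planted + d]] <- tibble(
        id = decoy_ids[d], sequence = random_seq(dl, gc = gc, alphabet = "DNA"),
        length = dl, planted = FALSE)
    }
    ests <- if (length(est_rows) > 0) do.call(rbind, est_rows) else
      tibble(id = character(), sequence = character(), length = integer(),
             planted = logical())
    truth <- list(
      planted_precursors = if (length(truth_rows) > 0) do.call(rbind, truth_rows)
        else tibble(est_id = character(), win_start = integer(),
                    win_end = integer(), mature_start = integer(),
                    mature_end = integer(), name = character(), arm = character()),
      decoy_ids = decoy_ids, seed = seed)
    list(ests = ests, truth = truth)
  })
}

#' Generate a synthetic 3'UTR set with planted target sites
#'
#' Random UTRs (200-1500 nt) carrying, per miRNA, `sites_per_mirna` planted
#' class I sites (the exact reverse complement of the full mature) and
#' optionally `class2_per_mirna` planted class II contexts (the reverse
#' complement of the 3' fragment). A planted class II site is only
#' detectable when a perfect fragment duplex clears the energy threshold;
#' the truth records that flag.
#'
#' @param mirnas tibble with `name`, `sequence`.
#' @param n_genes number of UTRs.
#' @param sites_per_mirna planted class I sites per miRNA.
#' @param seed integer seed.
#' @param class2_per_mirna planted class II contexts per miRNA (default 0).
#' @param gc background GC fraction.
#' @param threshold duplex energy threshold used for the detectability flag.
#' @param params energy parameters.
#' @return list with `utrs` (tibble `gene_id`, `sequence`) and `truth`
#'   (tibble `gene_id`, `mirna_name`, `site_start`, `site_end`, `class`,
#'   `detectable`).
#' @export
generate_utr_set <- function(mirnas, n_genes = 40, sites_per_mirna = 1,
                             seed = 1, class2_per_mirna = 0, gc = 0.42,
                             threshold = -20, params = energy_params()) {
  stopifnot(n_genes >= 0)
  withr::with_seed(seed, {
    gene_ids <- sprintf("gene_%03d", seq_len(n_genes))
    seqs <- vapply(seq_len(n_genes), function(i) {
      random_seq(sample(200:1500, 1), gc = gc, alphabet = "RNA")
    }, character(1))
    names(seqs) <- gene_ids
    truth_rows <- list()
    insert_site <- function(gene, insert, mirna_name, class, detectable) {
      L <- nchar(seqs[[gene]])
      w <- nchar(insert)
      pos <- sample(0:(L - w), 1)
      seqs[[gene]] <<- paste0(substr(seqs[[gene]], 1, pos), insert,
                              substr(seqs[[gene]], pos + w + 1, L))
      truth_rows[[length(truth_rows) + 1L]] <<- tibble(
        gene_id = gene, mirna_name = mirna_name, site_start = pos,
        site_end = pos + w, class = class, detectable = detectable)
    }
    for (r in seq_len(nrow(mirnas))) {
      mseq <- as_rna(mirnas$sequence[r])
      if (sites_per_mirna > 0 && n_genes > 0) {
        for (g in sample(gene_ids, min(sites_per_mirna, n_genes))) {
          insert_site(g, revcomp_rna(mseq), mirnas$name[r], "I", TRUE)
        }
      }
      if (class2_per_mirna > 0 && n_genes > 0 && nchar(mseq) >= 14) {
        frag <- fragment_12_to_xminus2(mseq)
        detectable <- duplex_mfe(frag, revcomp_rna(frag), params)$dg < threshold
        for (g in sample(gene_ids, min(class2_per_mirna, n_genes))) {
          insert_site(g, revcomp_rna(frag), mirnas$name[r], "II", detectable)
        }
      }
    }
    truth <- if (length(truth_rows) > 0) do.call(rbind, truth_rows) else
      tibble(gene_id = character(), mirna_name = character(),
             site_start = integer(), site_end = integer(), class = character(),
             detectable = logical())
    list(utrs = tibble(gene_id = gene_ids, sequence = unname(seqs[gene_ids])),
         truth = truth)
  })
}

class_representative_ratio <- c(high = 5, moderate = 0.5, very_low = 0.005,
                                intermediate = 1.5)

#' Generate a synthetic band-intensity table
#'
#' Control row constant at 1000 units; each miRNA value is its intended
#' fold-class representative ratio times the control, under multiplicative
#' lognormal noise of coefficient of variation `noise_cv`.
#'
#' @param classes named character vector: intended fold class per miRNA
#'   (`high`, `moderate`, `very_low` or `intermediate`).
#' @param samples sample labels (columns).
#' @param noise_cv lognormal coefficient of variation (0 = noiseless).
#' @param seed integer seed.
#' @param control_row control row name (default `"U6snRNA"`).
#' @param control_value control intensity (default 1000).
#' @return list with `table` (matrix incl. control row) and `truth` (the
#'   intended classes).
#' @export
generate_intensity_table <- function(classes, samples = paste0("S", 1:9),
                                     noise_cv = 0, seed = 1,
                                     control_row = "U6snRNA",
                                     control_value = 1000) {
  stopifnot(all(classes %in% names(class_representative_ratio)))
  withr::with_seed(seed, {
    n <- length(classes)
    k <- length(samples)
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- matrix(exp(rnorm(n * k, -sdlog^2 / 2, sdlog)), n, k)
    ratios <- class_representative_ratio[classes]
    values <- ratios * control_value * noise
    tab <- rbind(values, rep(control_value, k))
    rownames(tab) <- c(names(classes), control_row)
    colnames(tab) <- samples
    list(table = tab, truth = classes)
  })
}

#' Score pipeline output against planted truth
#'
#' A planted precursor counts as recovered when an accepted candidate window
#' overlaps its planted window by at least `min_overlap` of the planted
#' length (either strand); an accepted candidate is a true positive under
#' the same rule. Decoy false-accept is the fraction of decoy ESTs carrying
#' any accepted candidate. Homology-stage sensitivity uses the same overlap
#' rule on hits.
#'
#' @param accepted tibble of accepted precursors (needs `est_id`,
#'   `win_start`, `win_end`).
#' @param truth truth list from [generate_est_dataset()].
#' @param hits optional homology-hit tibble for stage-1 sensitivity.
#' @param min_overlap fractional overlap required (default 0.5).
#' @return list with `sensitivity`, `precision`, `decoy_false_accept`,
#'   `n_recovered`, `n_planted`, and `hit_sensitivity` when `hits` given.
#' @export
score_recovery <- function(accepted, truth, hits = NULL, min_overlap = 0.5) {
  planted <- truth$planted_precursors
  known <- c(planted$est_id, truth$decoy_ids)
  if (nrow(accepted) > 0 && !all(accepted$est_id %in% known)) {
    stop("accepted output names unknown EST ids", call. = FALSE)
  }
  overlaps <- function(est_id, s, e) {
    idx <- which(planted$est_id == est_id)
    if (length(idx) == 0) return(FALSE)
    ov <- pmin(e, planted$win_end[idx]) - pmax(s, planted$win_start[idx])
    any(ov >= min_overlap * (planted$win_end[idx] - planted$win_start[idx]))
  }
  recovered <- vapply(seq_len(nrow(planted)), function(i) {
    sub <- accepted[accepted$est_id == planted$est_id[i], ]
    if (nrow(sub) == 0) return(FALSE)
    ov <- pmin(sub$win_end, planted$win_end[i]) - pmax(sub$win_start, planted$win_start[i])
    any(ov >= min_overlap * (planted$win_end[i] - planted$win_start[i]))
  }, logical(1))
  tp <- if (nrow(accepted) > 0) {
    vapply(seq_len(nrow(accepted)), function(i) {
      overlaps(accepted$est_id[i], accepted$win_start[i], accepted$win_end[i])
    }, logical(1))
  } else {
    logical(0)
  }
  decoy_hit <- truth$decoy_ids %in% accepted$est_id
  out <- list(
    sensitivity = if (nrow(planted) > 0) mean(recovered) else NA_real_,
    precision = if (length(tp) > 0) mean(tp) else NA_real_,
    decoy_false_accept = if (length(truth$decoy_ids) > 0) mean(decoy_hit) else NA_real_,
    n_recovered = sum(recovered), n_planted = nrow(planted))
  if (!is.null(hits)) {
    hit_rec <- vapply(seq_len(nrow(planted)), function(i) {
      sub <- hits[hits$est_id == planted$est_id[i], ]
      if (nrow(sub) == 0) return(FALSE)
      ov <- pmin(sub$end, planted$mature_end[i]) - pmax(sub$start, planted$mature_start[i])
      any(ov > 0)
    }, logical(1))
    out$hit_sensitivity <- if (nrow(planted) > 0) mean(hit_rec) else NA_real_
  }
  out
}
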