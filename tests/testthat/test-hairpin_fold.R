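test_that("a pure GC stem folds to the hand-summed stack + loop energy", {
  # 10 GC pairs closed by a pentaloop: nine 5'GG/3'CC stacks at -3.26 each
  # plus the 5-nt hairpin penalty 5.7 from the packaged table
  s <- fold_single_hairpin("GGGGGGGGGGAAAAACCCCCCCCCC")
  expect_equal(s$mfe, 9 * -3.26 + 5.7, tolerance = 1e-9)
  expect_equal(s$stem_pairs, 10L)
  expect_equal(s$loop_size, 5L)
  expect_lte(s$mfe, -20)
  expect_equal(s$dot_bracket, "((((((((((.....))))))))))")
})

test_that("unpairable sequences return the open chain at zero energy", {
  s <- fold_single_hairpin(strrep("A", 20))
  expect_equal(s$mfe, 0)
  expect_equal(s$stem_pairs, 0L)
  expect_equal(s$dot_bracket, strrep(".", 20))
})

test_that("folding DP equals exhaustive enumeration on random short sequences", {
  withr::local_seed(201)
  for (i in 1:210) {
    n <- sample(8:16, 1)
    s <- rand_rna(n)
    expect_equal(fold_single_hairpin(s)$mfe, enumerate_structures(s)$mfe,
                 tolerance = 1e-9, label = s)
  }
})

test_that("enumerate_structures validates its input bounds", {
  expect_error(enumerate_structures(""), "empty")
  expect_error(enumerate_structures(strrep("G", 19)), "max_len")
  # too short for any stem of >= 1 pair with loop >= 3
  expect_equal(enumerate_structures("ACGU")$mfe, 0)
  expect_equal(enumerate_structures("GCGAAAGC")$mfe,
               fold_single_hairpin("GCGAAAGC")$mfe)
})

test_that("reported free energy is additive over the reported structure", {
  withr::local_seed(202)
  for (i in 1:25) {
    s <- rand_rna(sample(40:120, 1))
    st <- fold_single_hairpin(s)
    expect_equal(st$mfe, score_hairpin_chain(s, st$pairs), tolerance = 1e-9)
  }
})

test_that("extending a stem by a negative stack never raises the energy", {
  # grow a perfect helix pair by pair; each added GC stack is negative
  for (k in 5:12) {
    inner <- fold_single_hairpin(paste0(strrep("G", k), "AAAAA", strrep("C", k)))$mfe
    outer <- fold_single_hairpin(paste0(strrep("G", k + 1), "AAAAA", strrep("C", k + 1)))$mfe
    expect_lte(outer, inner)
  }
})

test_that("candidate filtering applies the published thresholds in order", {
  # 20xA window: no structure -> free energy and stem-loop both fail
  win <- list(sequence = strrep("A", 20), mature_offset = 0L, mature_len = 18L)
  cand <- evaluate_candidate(win)
  expect_false(cand$verdict)
  expect_true(all(c("free_energy", "stem_loop") %in% cand$fail_reasons))

  # short GC stem with a planted 12-nt mature in the 5' arm: fails only the
  # 14-pair stem requirement under defaults, passes once min_stem is relaxed
  win2 <- list(sequence = "GGGGGGGGGGAAAAACCCCCCCCCC",
               mature_offset = 0L, mature_len = 12L)
  strict <- evaluate_candidate(win2)
  expect_false(strict$verdict)
  expect_equal(strict$fail_reasons, "stem_loop")
  relaxed <- evaluate_candidate(win2, config = mirest_config(min_stem = 8))
  expect_true(relaxed$verdict)
  expect_equal(relaxed$fail_reasons, character(0))
  # a 20-nt mature in this 25-nt window necessarily crosses the terminal loop
  win3 <- list(sequence = "GGGGGGGGGGAAAAACCCCCCCCCC",
               mature_offset = 0L, mature_len = 20L)
  expect_true("mature_arm" %in% evaluate_candidate(win3)$fail_reasons)

  # a realistic self-checked construct passes all six criteria
  pre <- plant_precursor("GUGCAUUUGUAGUUGCAUUGCA", seed = 5, arm = "5p")
  cand3 <- evaluate_candidate(list(sequence = pre$sequence,
                                   mature_offset = pre$mature_offset,
                                   mature_len = pre$mature_len))
  expect_true(cand3$verdict)
  expect_gte(cand3$paired_fraction_mature, 0.6)
  expect_gte(cand3$ch_ratio, 0.8)
})

test_that("the free-energy threshold boundary is strict at -20", {
  pre <- plant_precursor("GUGCAUUUGUAGUUGCAUUGCA", seed = 6, arm = "5p")
  win <- list(sequence = pre$sequence, mature_offset = pre$mature_offset,
              mature_len = pre$mature_len)
  st <- fold_single_hairpin(pre$sequence)
  # push the threshold just past this structure's energy: only free_energy
  # flips from pass to fail
  eps <- 0.05
  pass <- evaluate_candidate(win, config = mirest_config(mfe_threshold = st$mfe + eps))
  fail <- evaluate_candidate(win, config = mirest_config(mfe_threshold = st$mfe - eps))
  expect_true(pass$verdict)
  expect_false(fail$verdict)
  expect_equal(fail$fail_reasons, "free_energy")
})

test_that("relaxing any threshold never shrinks the passing set", {
  withr::local_seed(203)
  cat58 <- load_catalogue()
  wins <- list()
  for (i in 1:12) {
    m <- cat58$sequence[sample(58, 1)]
    pre <- plant_precursor(m, seed = 300 + i, mutations = sample(0:6, 1))
    wins[[i]] <- list(sequence = pre$sequence,
                      mature_offset = pre$mature_offset,
                      mature_len = pre$mature_len)
  }
  strict <- mirest_config()
  relaxed <- mirest_config(mfe_threshold = -15, min_stem = 10,
                           max_loop_overlap = 6, min_mature_paired = 0.4,
                           gc_bounds = c(0.1, 0.9), min_ch_ratio = 0.6)
  for (w in wins) {
    v1 <- evaluate_candidate(w, config = strict)$verdict
    v2 <- evaluate_candidate(w, config = relaxed)$verdict
    expect_true(!v1 || v2)  # pass under strict implies pass under relaxed
  }
})

test_that("select_best_precursor picks the lowest energy, leftmost on ties", {
  mk <- function(mfe, ws, verdict = TRUE) {
    structure(list(window = list(win_start = ws),
                   structure = list(mfe = mfe),
                   verdict = verdict, fail_reasons = character(0)),
              class = "precursor_candidate")
  }
  best <- select_best_precursor(list(mk(-25, 10), mk(-31, 50), mk(-22, 5)))
  expect_equal(best$structure$mfe, -31)
  expect_null(select_best_precursor(list(mk(-25, 10, FALSE), mk(-31, 50, FALSE))))
  tie <- select_best_precursor(list(mk(-25, 40), mk(-25, 10)))
  expect_equal(tie$window$win_start, 10)
  expect_null(select_best_precursor(list()))
})

test_that("same-EST accepted matures cluster with the printed 126-nt spacer", {
  accepted <- tibble::tibble(
    est_id = c("e1", "e1"), strand = c("+", "+"),
    start = c(10L, 156L), end = c(30L, 176L),
    name = c("sli-miR-3329", "sli-miR-1814a"))
  cl <- detect_clusters(accepted)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$spacer_nt[[1]], 126L)
  expect_equal(cl$member_names[[1]], c("sli-miR-3329", "sli-miR-1814a"))

  # single mature: no cluster; opposite strands: no cluster
  expect_equal(nrow(detect_clusters(accepted[1, ])), 0L)
  mixed <- accepted; mixed$strand <- c("+", "-")
  expect_equal(nrow(detect_clusters(mixed)), 0L)
  # spacer beyond the limit: no cluster
  far <- accepted; far$start[2] <- 1200L; far$end[2] <- 1220L
  expect_equal(nrow(detect_clusters(far, max_spacer = 1000)), 0L)
})
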