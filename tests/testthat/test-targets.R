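test_that("seed and 3' fragments follow the positional rules", {
  expect_equal(seed_fragment("UGACAGUGUGGACAGGUGGC"), "GACAGUG")   # miR-34
  expect_equal(seed_fragment("UCGACGAACAACUAUAAGGG"), "CGACGAA")   # miR-184
  expect_error(seed_fragment("UGACAGU"), "seed")

  # x = 22: 1-based positions 12..20, length 9 (indexed by hand)
  expect_equal(fragment_12_to_xminus2("GUGCAUUUGUAGUUGCAUUGCA"), "GUUGCAUUG")
  # x = 17: positions 12..15, length 4 (indexed by hand: A12 C13 U14 C15)
  expect_equal(fragment_12_to_xminus2("UGACGAGAUGCACUCAU"), "ACUC")
  expect_equal(nchar(fragment_12_to_xminus2("UGACGAGAUGCACUCAU")), 17 - 13)
  expect_error(fragment_12_to_xminus2(strrep("A", 13)), "empty")
})

test_that("perfect-complement duplexes sum the packaged stack terms", {
  p <- energy_params()
  d <- duplex_mfe("GGGGG", "CCCCC")
  expect_equal(d$dg, 4 * -3.26 + p$duplex_init, tolerance = 1e-9)
  expect_equal(nrow(d$pairs), 5L)
  expect_equal(duplex_mfe("AAAA", "AAAA")$dg, 0)
  expect_equal(nrow(duplex_mfe("AAAA", "AAAA")$pairs), 0L)
})

test_that("duplex DP equals the exhaustive intermolecular oracle on short pairs", {
  withr::local_seed(601)
  for (i in 1:30) {
    a <- rand_rna(sample(4:9, 1))
    b <- rand_rna(sample(4:9, 1))
    expect_equal(duplex_mfe(a, b)$dg, oracle_duplex_mfe(a, b),
                 tolerance = 1e-9, label = paste(a, b))
  }
})

test_that("duplex energy is strand-swap symmetric and monotone under extension", {
  withr::local_seed(602)
  for (i in 1:10) {
    a <- rand_rna(sample(6:12, 1)); b <- rand_rna(sample(6:12, 1))
    expect_equal(duplex_mfe(a, b)$dg, duplex_mfe(b, a)$dg, tolerance = 1e-9)
  }
  # extending complementarity never raises the energy
  m <- "GUGCAUUUGUAGUUGCAUUGCA"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::RNAString(m)))
  prev <- 0
  for (k in c(6, 10, 14, 18, 22)) {
    dg <- duplex_mfe(substr(m, 1, k),
                     substr(rc, nchar(rc) - k + 1, nchar(rc)))$dg
    expect_lte(dg, prev + 1e-9)
    prev <- dg
  }
})

test_that("class I sites need both the seed 7mer and a strong full duplex", {
  withr::local_seed(603)
  m <- tibble::tibble(name = "sli-miR-34", sequence = "UGACAGUGUGGACAGGUGGC")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::RNAString(m$sequence)))
  utr <- tibble::tibble(gene_id = "g1",
                        sequence = paste0(rand_rna(80), rc, rand_rna(80)))
  sites <- find_class1_sites(m, utr)
  expect_equal(nrow(sites), 1L)
  expect_lt(sites$dg, -20)
  expect_equal(sites$class, "I")
  # the site window contains the planted complement
  expect_lte(sites$site_start, 80)
  expect_gte(sites$site_end, 80 + nchar(rc))

  # poly-A UTR: no seed, no sites
  expect_equal(nrow(find_class1_sites(m, tibble::tibble(
    gene_id = "g2", sequence = strrep("A", 200)))), 0L)

  # seed match present but pairing beyond the seed destroyed -> rejected
  seed_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::RNAString(seed_fragment(m$sequence))))
  weak <- tibble::tibble(gene_id = "g3",
                         sequence = paste0(strrep("A", 80), seed_rc, strrep("A", 80)))
  expect_equal(nrow(find_class1_sites(m, weak)), 0L)
})

test_that("class II targets: planted strong fragments found, weak fragments cannot reach -20", {
  withr::local_seed(604)
  # GC-rich long mature -> 12-nt fragment whose perfect duplex clears -20
  m <- tibble::tibble(name = "sli-miR-3242",
                      sequence = "CACGCGGGCGGGCGUAUCGCGUUGGA")
  frag <- fragment_12_to_xminus2(m$sequence)
  expect_lt(duplex_mfe(frag, as.character(Biostrings::reverseComplement(
    Biostrings::RNAString(frag))))$dg, -20)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::RNAString(frag)))
  utrs <- tibble::tibble(
    gene_id = c("hit", "bg"),
    sequence = c(paste0(rand_rna(150), rc, rand_rna(150)), rand_rna(300)))
  res <- find_class2_targets(m, utrs)
  expect_true("hit" %in% res$gene_id)
  expect_true(all(res$dg < -20))
  expect_true(all(res$class == "II"))
  # one row per gene (best site only)
  expect_equal(anyDuplicated(res$gene_id), 0L)

  # a 4-nt fragment (x = 17) has at most 3 stack terms: cannot reach -20
  m2 <- tibble::tibble(name = "sli-miR-279b", sequence = "UGACGAGAUGCACUCAU")
  f2 <- fragment_12_to_xminus2(m2$sequence)
  expect_equal(nchar(f2), 4L)
  best3 <- 3 * min(energy_params()$stack[is.finite(energy_params()$stack)])
  expect_gt(best3 + energy_params()$duplex_init, -20)
  res2 <- find_class2_targets(m2, tibble::tibble(gene_id = "g",
                                                 sequence = rand_rna(500)))
  expect_equal(nrow(res2), 0L)
  # empty UTR list
  expect_equal(nrow(find_class2_targets(m, utrs[0, ])), 0L)
})

test_that("class II gene set is invariant to UTR input order", {
  withr::local_seed(605)
  m <- tibble::tibble(name = "m", sequence = "CACGCGGGCGGGCGUAUCGCGUUGGA")
  frag_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::RNAString(fragment_12_to_xminus2(m$sequence))))
  utrs <- tibble::tibble(
    gene_id = sprintf("g%d", 1:6),
    sequence = c(paste0(rand_rna(100), frag_rc, rand_rna(100)),
                 rand_rna(400), rand_rna(350),
                 paste0(rand_rna(50), frag_rc, rand_rna(250)),
                 rand_rna(300), rand_rna(450)))
  r1 <- find_class2_targets(m, utrs)
  r2 <- find_class2_targets(m, utrs[6:1, ])
  expect_setequal(r1$gene_id, r2$gene_id)
})

test_that("target bookkeeping reproduces the fixture totals and conserves counts", {
  counts <- load_target_counts()
  s <- summarize_targets(counts)
  expect_equal(s$total, 211L)
  expect_equal(s$class2, 22L)
  expect_equal(s$class1, 189L)
  expect_equal(s$class1 + s$class2, s$total)
  empty <- summarize_targets(load_target_counts(
    withr::local_tempfile(lines = "mirna\tn_targets\tn_class2", fileext = ".tsv")))
  expect_equal(empty$total, 0L)
})

test_that("tf_ratio reproduces the published percentages with half-up rounding", {
  expect_equal(tf_ratio(869, 12046), 7.2)
  expect_equal(tf_ratio(606, 9721), 6.2)
  expect_equal(tf_ratio(19, 38), 50.0)
  expect_equal(tf_ratio(2316, 30484), 7.6)
  expect_equal(tf_ratio(1, 16), 6.3)  # 6.25 rounds half-up
  expect_error(tf_ratio(1, 0), "denominator")
})
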