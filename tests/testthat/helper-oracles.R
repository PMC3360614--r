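# Independent brute-force oracles used to verify the dynamic programs and
# the clustering. These deliberately share no code path with the package
# implementations beyond the packaged parameter tables.

rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                              collapse = "")
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

str_rev <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")

# exhaustive intermolecular duplex minimum over all antiparallel monotone
# pairings; inputs capped at ~9 nt each
oracle_duplex_mfe <- function(a, b, params = energy_params()) {
  ea <- mirest:::encode_seq(as_rna(a))
  eb <- rev(mirest:::encode_seq(as_rna(b)))
  n <- length(ea); m <- length(eb)
  best <- 0
  score <- function(ch) {
    tot <- params$duplex_init
    for (t in seq_len(nrow(ch))) {
      if (t == 1) next
      g1 <- ch[t, 1] - ch[t - 1, 1] - 1
      g2 <- ch[t, 2] - ch[t - 1, 2] - 1
      if (g1 + g2 > params$max_interior) return(Inf)
      if (g1 == 0 && g2 == 0) {
        tot <- tot + mirest:::stack_energy(params, ea[ch[t - 1, 1]], eb[ch[t - 1, 2]],
                                           ea[ch[t, 1]], eb[ch[t, 2]])
      } else if (g1 == 0 || g2 == 0) {
        tot <- tot + params$bulge[g1 + g2]
      } else {
        tot <- tot + params$internal[g1 + g2]
      }
    }
    tot
  }
  rec <- function(ch, i0, j0) {
    if (i0 >= n || j0 >= m) return()
    for (i in (i0 + 1):n) {
      for (j in (j0 + 1):m) {
        if (ea[i] > 3 || eb[j] > 3 || !params$pair_ok[ea[i] + 1, eb[j] + 1]) next
        ch2 <- rbind(ch, c(i, j))
        sc <- score(ch2)
        if (is.finite(sc) && sc < best) best <<- sc
        rec(ch2, i, j)
      }
    }
  }
  rec(matrix(integer(0), 0, 2), 0, 0)
  best
}

# naive per-position homology recount: substring comparison at every offset
# and strand, then the same local-minimum reduction rule restated directly
oracle_scan <- function(est_seq, ref_rna, max_mm) {
  ref <- as_dna(ref_rna)
  w <- nchar(ref)
  hits <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") est_seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(est_seq)))
    L <- nchar(s)
    if (w > L) next
    pos <- c(); mm <- c()
    for (p in 0:(L - w)) {
      sub <- substr(s, p + 1, p + w)
      d <- sum(strsplit(sub, "")[[1]] != strsplit(ref, "")[[1]] |
                 strsplit(sub, "")[[1]] == "N")
      if (d <= max_mm) { pos <- c(pos, p); mm <- c(mm, d) }
    }
    if (length(pos) == 0) next
    # reduce overlapping runs to leftmost minimum
    keep_pos <- c(); keep_mm <- c()
    i <- 1
    while (i <= length(pos)) {
      j <- i
      while (j < length(pos) && pos[j + 1] < pos[j] + w) j <- j + 1
      run <- i:j
      b <- run[which.min(mm[run])]
      keep_pos <- c(keep_pos, pos[b]); keep_mm <- c(keep_mm, mm[b])
      i <- j + 1
    }
    start <- if (strand == "+") keep_pos else L - keep_pos - w
    hits[[strand]] <- data.frame(start = start, end = start + w,
                                 strand = strand, mismatches = keep_mm)
  }
  if (length(hits) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, out$strand), ]
}

# hand-rolled O(n^3) average-linkage agglomeration on a distance matrix,
# returning the cophenetic distance matrix
oracle_average_linkage_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  labels <- rownames(d)
  members <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  coph <- matrix(0, n, n, dimnames = list(labels, labels))
  dd <- d
  diag(dd) <- Inf
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    best <- c(NA, NA); bd <- Inf
    for (a in idx) for (b in idx) {
      if (a < b && dd[a, b] < bd) { bd <- dd[a, b]; best <- c(a, b) }
    }
    a <- best[1]; b <- best[2]
    for (x in members[[a]]) for (y in members[[b]]) {
      coph[x, y] <- bd; coph[y, x] <- bd
    }
    # average-linkage update, sizes weighted
    na_ <- length(members[[a]]); nb_ <- length(members[[b]])
    for (c_ in idx) {
      if (c_ == a || c_ == b) next
      dd[a, c_] <- dd[c_, a] <- (na_ * dd[a, c_] + nb_ * dd[b, c_]) / (na_ + nb_)
    }
    members[[a]] <- c(members[[a]], members[[b]])
    active[b] <- FALSE
    dd[b, ] <- Inf; dd[, b] <- Inf
  }
  coph
}
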