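test_that("core k-mer ranking counts every substring window", {
  r <- rank_core_kmers(c("GAATATTC", "AGAACTTC"), 3, top = 20)
  cnt <- function(core) r$count[r$core == core]
  expect_equal(cnt("GAA"), 2)
  expect_equal(cnt("TTC"), 2)
  expect_equal(cnt("TAT"), 1)
  # repeated windows within one 8-mer each count
  r2 <- rank_core_kmers("AAAAAAAA", 3)
  expect_equal(r2$count[r2$core == "AAA"], 6)
  # ties broken lexicographically, cut-off ties reported
  r3 <- rank_core_kmers(c("GAATATTC", "AGAACTTC"), 3, top = 2)
  expect_equal(r3$core, c("GAA", "TTC"))  # both count 2, GAA < TTC
  expect_equal(nrow(r3), 2)
  expect_type(attr(r3, "tied_at_cutoff"), "character")
  # empty input
  r0 <- rank_core_kmers(character(0), 3)
  expect_equal(nrow(r0), 0)
  expect_error(rank_core_kmers("GAATATTC", 8), "< 8")
})

test_that("8-mer selection keeps carriers of top cores (union by default)", {
  enriched <- c("GAATATTC", "CCCCCCCC", "AGAACTTC")
  r3 <- rank_core_kmers(c("GAATATTC", "AGAACTTC"), 3, top = 1)  # GAA only
  r4 <- rank_core_kmers("TTTTTTTT", 4, top = 1)                 # TTTT only
  sel <- select_step1_motifs(enriched, r3, r4)
  expect_setequal(sel, c("GAATATTC", "AGAACTTC"))  # carry GAA, lack TTTT
  expect_length(select_step1_motifs(enriched, r3, r4, mode = "intersection"), 0)
  expect_length(select_step1_motifs(character(0), r3, r4), 0)
})

test_that("mapping merges occurrences sharing >= 1 base into maximal regions", {
  ps <- ps_from_seqs("CCGAATATTCTCC", "g1")
  regions <- map_and_merge(c("GAATATTC", "AATATTCT"), ps)
  expect_equal(nrow(regions), 1)
  expect_equal(regions$sequence, "GAATATTCT")
  expect_equal(regions$end - regions$start, 9)
  expect_equal(nrow(regions$contributing[[1]]), 2)

  # single occurrence yields the motif itself
  ps1 <- ps_from_seqs("CCCCGAATATTCCCCC", "g1")
  r1 <- map_and_merge("GAATATTC", ps1)
  expect_equal(r1$sequence, "GAATATTC")

  # same motif on two promoters -> two regions
  ps2 <- ps_from_seqs(c("AAGAATATTCAA", "TTGAATATTCTT"), c("g1", "g2"))
  expect_equal(nrow(map_and_merge("GAATATTC", ps2)), 2)
})

test_that("merged regions are disjoint and cover every occurrence exactly once", {
  set.seed(43)
  motifs <- c("GAATATTC", "AATATTCT", "TTCTGAAT")
  for (rep in 1:5) {
    seq <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    # splice in overlapping motif copies
    for (at in sample(1:280, 4)) substr(seq, at, at + 7) <- motifs[sample(3, 1)]
    ps <- ps_from_seqs(seq, "g1")
    regions <- map_and_merge(motifs, ps)
    if (nrow(regions) == 0) next
    expect_true(all(regions$start[-1] >= head(regions$end, -1)))  # disjoint
    for (i in seq_len(nrow(regions))) {
      occ <- regions$contributing[[i]]
      # every contributing motif matches the promoter at its offset ...
      for (j in seq_len(nrow(occ))) {
        expect_equal(substr(seq, occ$offset[j] + 1, occ$offset[j] + 8),
                     occ$motif[j])
      }
      # ... and lies inside exactly this region
      expect_true(all(occ$offset >= regions$start[i] &
                        occ$offset + 8 <= regions$end[i]))
    }
    # total occurrences across regions equal brute-force match count
    n_occ <- sum(vapply(motifs, function(m) count_occurrences(seq, m), 0L))
    expect_equal(sum(vapply(regions$contributing, nrow, 0L)), n_occ)
  }
})

test_that("PSSM stacking, trimming and information content behave as specified", {
  # single region -> one-hot columns
  p1 <- build_pssm(data.frame(sequence = "GAAT"))
  expect_equal(unname(p1$freq["G", 1]), 1)
  expect_equal(unname(colSums(p1$freq)), rep(1, 4), tolerance = 1e-9)
  expect_equal(unname(p1$ic), rep(2, 4))
  expect_equal(p1$consensus, "GAAT")

  # half/half column
  p2 <- build_pssm(data.frame(sequence = c("GAAT", "GAAA")))
  expect_equal(unname(p2$freq["A", 4]), 0.5)
  expect_equal(unname(p2$freq["T", 4]), 0.5)
  expect_equal(unname(p2$ic[4]), 1)

  # all-identical regions -> 2 bits everywhere
  p3 <- build_pssm(data.frame(sequence = rep("ACGT", 5)))
  expect_equal(unname(p3$ic), rep(2, 4))

  # anchored stacking: regions share the GAA core at different offsets;
  # the left flank column is covered by 1/3 regions (< 50%) and trimmed
  p4 <- build_pssm(data.frame(sequence = c("GAATATTC", "GAATATTC", "CGAATATT")),
                   anchor_core = "GAA")
  expect_equal(p4$consensus, "GAATATTC")
  expect_equal(unname(colSums(p4$freq)), rep(1, 8), tolerance = 1e-9)
  expect_true(all(p4$ic >= 0 & p4$ic <= 2 + 1e-12))

  expect_error(build_pssm(data.frame(sequence = character(0))), "no regions")
})

test_that("palindrome classification distinguishes full, flank and none", {
  expect_equal(classify_palindrome("GAATATTC"), "full")
  expect_equal(classify_palindrome("GAACCTTC"), "flank_3")
  expect_equal(classify_palindrome("AAAAAAAA"), "none")
  expect_error(classify_palindrome("ACGT"), "length-8")
  expect_error(classify_palindrome("GAATATTN"), "ACGT")

  # exactly 256 of the 65,536 8-mers are full reverse-complement palindromes
  all8 <- enumerate_kmers(8, 8)
  classes <- vapply(all8, classify_palindrome, "")
  expect_equal(sum(classes == "full"), 256)

  # exactly 16 8-mers match GAANNTTC; all classify full or flank_3
  hse <- all8[grepl("^GAA..TTC$", all8)]
  expect_length(hse, 16)
  expect_true(all(classes[hse] %in% c("full", "flank_3")))
  # the swapped-core variant TTCnnGAA keeps the outer rc pairing
  # (rc of GAA is TTC), so it classifies flank_3 unless the spacer
  # happens to self-complement
  expect_equal(classify_palindrome("TTCAAGAA"), "flank_3")
  expect_equal(classify_palindrome("TTCATGAA"), "full")
})

test_that("TSS-distance profile bins region midpoints by upstream distance", {
  ps <- ps_from_seqs(strrep("A", 1000), "g1")
  regions <- data.frame(promoter_id = "g1_p1",
                        start = c(950, 955), end = c(958, 963),
                        sequence = "AAAAAAAA")
  prof <- tss_distance_profile(regions, ps)
  expect_equal(nrow(prof), 10)
  expect_equal(prof$count[1], 2)       # offsets ~954/959 -> ~46/41 bp upstream
  expect_equal(sum(prof$count), 2)

  # empty region list -> all-zero histogram
  prof0 <- tss_distance_profile(regions[0, ], ps)
  expect_true(all(prof0$count == 0))

  # uniform placement is not rejected as non-uniform (chi-square at 0.01)
  set.seed(53)
  n <- 1000
  starts <- sample(0:992, n, replace = TRUE)
  regs <- data.frame(promoter_id = "g1_p1", start = starts, end = starts + 8,
                     sequence = "AAAAAAAA")
  prof_u <- tss_distance_profile(regs, ps)
  chi <- suppressWarnings(chisq.test(prof_u$count))
  expect_gt(chi$p.value, 0.01)
})

test_that("MEME minimal output carries the letter-probability matrices", {
  p <- build_pssm(data.frame(sequence = c("GAAT", "GAAA")))
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(list(hse_like = p), path)
  lines <- readLines(path)
  expect_true("MEME version 4" %in% lines)
  expect_true(any(grepl("^MOTIF hse_like$", lines)))
  expect_true(any(grepl("alength= 4 w= 4 nsites= 2", lines)))
  mat_line <- lines[grep("letter-probability", lines) + 4]
  expect_equal(scan(text = mat_line, quiet = TRUE), c(0.5, 0, 0, 0.5))
})
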