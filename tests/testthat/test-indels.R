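test_that("breakpoint microhomology follows the max-of-both-sides rule", {
  # deleted TAGC, right flank starts TAGT: 3 bp prefix homology
  expect_equal(max_microhomology("TAGC", "GGGGG", "TAGTAAA"), 3)
  # no homology on either side
  expect_equal(max_microhomology("A", "GGGG", "CCCC"), 0)
  # full-length suffix match is capped at len - 1 (repeat territory)
  expect_equal(max_microhomology("AT", "CCAT", "GGGG"), 1)
  expect_error(max_microhomology("", "AA", "AA"), "empty")
})

test_that("tandem copy counting scans both directions", {
  # deletion of CA inside ...CACACA...: deleted copy plus two neighbours
  expect_equal(tandem_copies("CA", "GGCACA", "CAGG"), 4)
  expect_equal(tandem_copies("CA", "GGGG", "CACATT"), 3)
  expect_equal(tandem_copies("T", "GGA", "GCC"), 1)
  expect_equal(tandem_copies("AGG", "TTTTT", "AGGTCC"), 2)
  expect_error(tandem_copies("", "A", "A"), "empty")
})

test_that("classification precedence is repeat > microhomology > none", {
  # 1 bp deletion of A inside AAA: repeat
  g <- Biostrings::DNAStringSet(c(chr1 = "GGCGTAAACGTACGGCGCGT"))
  rec <- data.frame(sample = "s", chrom = "chr1", pos = 5L, ref = "TA",
                    alt = "T", kind = "DEL", stringsAsFactors = FALSE)
  call <- classify_deletion(rec, g)
  expect_equal(call$context_class, "repeat")
  expect_gte(call$tandem_copies, 2)
  # 4 bp deletion with 2 bp breakpoint homology, no tandem copy
  #            pos 5, deleted ACGT (6..9), right flank starts AC
  g2 <- Biostrings::DNAStringSet(c(chr1 = "GGGTGACGTACTTGGCATGG"))
  rec2 <- data.frame(sample = "s", chrom = "chr1", pos = 5L, ref = "GACGT",
                     alt = "G", kind = "DEL", stringsAsFactors = FALSE)
  call2 <- classify_deletion(rec2, g2)
  expect_equal(call2$context_class, "microhomology")
  expect_equal(call2$mh_length, 2L)
  expect_equal(call2$tandem_copies, 1L)
  # unique context
  g3 <- Biostrings::DNAStringSet(c(chr1 = "AATTGGCCGAGTCCAATTGG"))
  rec3 <- data.frame(sample = "s", chrom = "chr1", pos = 9L, ref = "GAGT",
                     alt = "G", kind = "DEL", stringsAsFactors = FALSE)
  call3 <- classify_deletion(rec3, g3)
  expect_equal(call3$context_class, "none")
  expect_equal(call3$mh_length, 0L)
  expect_equal(call3$tandem_copies, 1L)
})

test_that("classification is independent of indel placement in a tract", {
  g <- Biostrings::DNAStringSet(c(chr1 = "GGTTACACACACGTTACGGATT"))
  # deleting any AC unit of the tract gives the identical call
  calls <- lapply(c(5L, 7L, 9L), function(p) {
    rec <- data.frame(sample = "s", chrom = "chr1", pos = p,
                      ref = paste0(substr(as.character(g[[1]]), p, p), "CA"),
                      alt = substr(as.character(g[[1]]), p, p),
                      kind = "DEL", stringsAsFactors = FALSE)
    classify_deletion(rec, g)
  })
  for (i in 2:3) expect_equal(calls[[i]], calls[[1]])
  expect_equal(calls[[1]]$context_class, "repeat")
})

test_that("classifier agrees with the brute-force string oracle", {
  set.seed(101)
  n_ok <- 0
  for (i in 1:1500) {
    L <- sample(1:6, 1)
    left <- rand_dna(sample(L:(6 * L), 1) + 3)
    right <- rand_dna(sample(L:(6 * L), 1) + 3)
    deleted <- rand_dna(L)
    expect_equal(max_microhomology(deleted, left, right),
                 oracle_mh(deleted, left, right))
    expect_equal(tandem_copies(deleted, left, right),
                 oracle_tandem(deleted, left, right))
    n_ok <- n_ok + 1
  }
  expect_equal(n_ok, 1500)
})

test_that("ID-83 channels follow the PCAWG scheme", {
  expect_equal(length(id83_channels()), 83)
  expect_equal(anyDuplicated(id83_channels()), 0)
  # del T from a TTTT homopolymer: 4-long homopolymer channel (3 extra)
  g <- Biostrings::DNAStringSet(c(chr1 = "GGCGATTTTCAGCGCGGGAA"))
  rec <- data.frame(sample = "s", chrom = "chr1", pos = 5L, ref = "AT",
                    alt = "A", kind = "DEL", stringsAsFactors = FALSE)
  expect_equal(classify_indel_id83(rec, g), "1:Del:T:3")
  # del of G (purine) is reported as its pyrimidine partner C
  rec_g <- data.frame(sample = "s", chrom = "chr1", pos = 15L, ref = "CG",
                      alt = "C", kind = "DEL", stringsAsFactors = FALSE)
  expect_match(classify_indel_id83(rec_g, g), "^1:Del:C:")
  # ins C next to no C: insertion into a 0-length run
  g2 <- Biostrings::DNAStringSet(c(chr1 = "GGATATATGGATTTAAGG"))
  rec2 <- data.frame(sample = "s", chrom = "chr1", pos = 10L, ref = "G",
                     alt = "GC", kind = "INS", stringsAsFactors = FALSE)
  expect_equal(classify_indel_id83(rec2, g2), "1:Ins:C:0")
  # del ACGT with 2 bp microhomology, no tandem copy
  g3 <- Biostrings::DNAStringSet(c(chr1 = "GGGTGACGTACTTGGCATGG"))
  rec3 <- data.frame(sample = "s", chrom = "chr1", pos = 5L, ref = "GACGT",
                     alt = "G", kind = "DEL", stringsAsFactors = FALSE)
  expect_equal(classify_indel_id83(rec3, g3), "4:Del:M:2")
  # >= 2 bp insertion with one pre-existing copy
  rec4 <- data.frame(sample = "s", chrom = "chr1", pos = 4L, ref = "T",
                     alt = "TAT", kind = "INS", stringsAsFactors = FALSE)
  expect_match(classify_indel_id83(rec4, g2), "^2:Ins:R:")
  expect_error(classify_indel_id83(
    data.frame(sample = "s", chrom = "chr1", pos = 3, ref = "A", alt = "T",
               kind = "SNV"), g2), "SNV")
})

test_that("catalog-level indel classification conserves counts", {
  sim <- simulate_genome_with_indels(12000, n_events = 15, seed = 33)
  res <- classify_indels(sim$catalog, sim$genome)
  expect_equal(sum(res$id83), 15)
  expect_equal(nrow(res$deletions), 15)
  expect_equal(res$n_long, 0)
})

test_that("deletion size ECDF uses the lower-midpoint median", {
  expect_equal(deletion_size_ecdf(c(1, 1, 1))$median, 1)
  e <- deletion_size_ecdf(c(1, 2, 4, 8))
  expect_equal(e$ecdf(2), 0.5)
  expect_equal(e$median, 2)           # lower of the two central values
  expect_equal(deletion_size_ecdf(c(2, 4, 4, 6))$median, 4)
  expect_error(deletion_size_ecdf(numeric(0)), "no deletions")
})
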