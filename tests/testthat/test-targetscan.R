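test_that("target_space_pattern reverse-complements into DNA space", {
  expect_equal(target_space_pattern("ACG"), "CGT")
  expect_equal(target_space_pattern("A.G"), "C.T")
  # double application returns the U->T transliterated original
  expect_equal(target_space_pattern(target_space_pattern("ACGU")), "ACGT")
  expect_equal(target_space_pattern(target_space_pattern("A..G")), "A..G")
  # data-frame input maps the motif column and keeps the rest
  p <- tibble::tibble(motif = c("ACG", "UU.A"), support = c(3L, 2L))
  tp <- target_space_pattern(p)
  expect_equal(tp$motif, c("CGT", "T.AA"))
  expect_equal(tp$support, p$support)
})

test_that("target-space mapping preserves the density constraint", {
  set.seed(33)
  seqs <- vapply(rep(16, 10), random_rna, character(1))
  pats <- discover_patterns(seqs, L = 2, W = 3, min_support = 2)
  skip_if(nrow(pats) == 0)
  mapped <- chartr("T", "U", target_space_pattern(pats$motif))
  expect_true(all(is_valid_pattern(mapped, L = 2, W = 3)))
})

test_that("apply_allele substitutes exactly one base and validates input", {
  utr <- tibble::tibble(transcript_id = "tx1", sequence = "AAGAA")
  snp <- tibble::tibble(rsid = "rs1", utr_offset = 2L,
                        allele1 = "G", allele2 = "A")
  out <- apply_allele(utr, snp, "A")
  expect_equal(out$sequence, "AAAAA")
  expect_equal(utr$sequence, "AAGAA") # input unmodified
  # in-sequence allele is the identity case
  expect_equal(apply_allele(utr, snp, "G")$sequence, "AAGAA")
  expect_error(apply_allele(utr, snp, "T"), class = "mirsnp_param_error")
  bad <- tibble::tibble(rsid = "rs1", utr_offset = 9L,
                        allele1 = "G", allele2 = "A")
  expect_error(apply_allele(utr, bad, "G"), class = "mirsnp_param_error")
  # a biallelic SNP yields exactly two allelic sequences
  seqs <- vapply(c(snp$allele1, snp$allele2),
                 function(a) apply_allele(utr, snp, a)$sequence, character(1))
  expect_equal(length(unique(seqs)), 2L)
})

test_that("scan_hits reports every overlapping match and respects N", {
  h <- scan_hits("TTTCGTTTT", "CGT")
  expect_equal(as.data.frame(h),
               data.frame(motif = "CGT", start = 3L, end = 6L))
  h2 <- scan_hits("TTTT", "T.T")
  expect_equal(h2$start, c(0L, 1L))
  expect_equal(nrow(scan_hits("ACGTACGT", character(0))), 0L)
  # N in the sequence matches neither a literal nor the wildcard
  expect_equal(nrow(scan_hits("ACNTA", "C.T")), 0L)
  # motifs themselves may not contain N
  expect_error(scan_hits("ACNTA", "CNT"), class = "mirsnp_param_error")
})

test_that("scan_hits equals the naive overlapping-match oracle", {
  set.seed(55)
  for (rep in 1:40) {
    seq <- random_dna(sample(20:60, 1))
    motifs <- unique(vapply(1:4, function(i) {
      m <- random_dna(sample(3:6, 1))
      if (runif(1) < 0.5 && nchar(m) > 2) substr(m, 2, 2) <- "."
      m
    }, character(1)))
    got <- scan_hits(seq, motifs)
    want <- oracle_scan(seq, motifs)
    expect_equal(as.data.frame(got), as.data.frame(want), info = seq)
  }
})

test_that("call_islands matches the frozen window examples", {
  mk_hits <- function(starts, len = 7L) {
    tibble::tibble(motif = strrep("A", len), start = as.integer(starts),
                   end = as.integer(starts + len))
  }
  isl <- call_islands(mk_hits(c(10, 12, 14, 16, 18)), 100, window = 25,
                      min_island_hits = 5)
  expect_equal(nrow(isl), 1L)
  expect_equal(isl$start, 10L)
  expect_equal(isl$end, 25L) # last hit start 18 + motif length 7
  expect_equal(isl$hit_count, 5L)

  expect_equal(nrow(call_islands(mk_hits(5), 100, 25, 2)), 0L)

  two <- call_islands(mk_hits(c(10, 12, 14, 16, 18,
                                510, 512, 514, 516, 518)), 1000, 25, 5)
  expect_equal(nrow(two), 2L)
  expect_true(two$end[1] <= two$start[2]) # disjoint after merging
})

test_that("call_islands equals the all-spans brute-force oracle", {
  set.seed(66)
  for (rep in 1:60) {
    n_hits <- sample(0:50, 1)
    utr_len <- 300L
    len <- sample(4:8, 1)
    starts <- sort(sample(0:(utr_len - len), n_hits, replace = TRUE))
    hits <- tibble::tibble(motif = strrep("C", len), start = as.integer(starts),
                           end = as.integer(starts + len))
    window <- sample(c(10L, 25L), 1)
    mih <- sample(2:6, 1)
    got <- call_islands(hits, utr_len, window, mih)
    want <- oracle_islands(hits, utr_len, window, mih)
    expect_equal(as.data.frame(got[, c("start", "end", "hit_count")]),
                 as.data.frame(want),
                 info = sprintf("rep %d (n=%d w=%d m=%d)", rep, n_hits,
                                window, mih))
  }
})

test_that("islands are flagged when they overlap the SNP offset", {
  hits <- tibble::tibble(motif = "AAAA", start = c(10L, 12L, 14L),
                         end = c(14L, 16L, 18L))
  isl <- call_islands(hits, 100, window = 25, min_island_hits = 3,
                      snp_offset = 15L)
  expect_true(isl$overlaps_snp)
  isl2 <- call_islands(hits, 100, window = 25, min_island_hits = 3,
                       snp_offset = 40L)
  expect_false(isl2$overlaps_snp)
  expect_error(call_islands(hits, 100, window = 0, min_island_hits = 3),
               class = "mirsnp_param_error")
})

test_that("substitution is local: hits far from the SNP are allele-invariant", {
  set.seed(77)
  for (rep in 1:10) {
    utr <- tibble::tibble(transcript_id = "tx", sequence = random_dna(300))
    off <- sample(50:250, 1)
    ref <- substr(utr$sequence, off + 1, off + 1)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    snp <- tibble::tibble(rsid = "rs", utr_offset = off,
                          allele1 = ref, allele2 = alt)
    motifs <- vapply(1:5, function(i) random_dna(5), character(1))
    h1 <- scan_hits(apply_allele(utr, snp, ref)$sequence, motifs)
    h2 <- scan_hits(apply_allele(utr, snp, alt)$sequence, motifs)
    max_len <- max(nchar(motifs))
    far1 <- h1[h1$end <= off - max_len | h1$start >= off + max_len, ]
    far2 <- h2[h2$end <= off - max_len | h2$start >= off + max_len, ]
    expect_equal(as.data.frame(far1), as.data.frame(far2))
  }
})

test_that("islands serialize to BED with rsid|allele names", {
  isl <- tibble::tibble(start = 10L, end = 40L, hit_count = 6L,
                        transcript_id = "tx1", rsid = "rs1", allele = "A")
  f <- withr::local_tempfile(fileext = ".bed")
  write_islands_bed(isl, f)
  expect_equal(readLines(f), "tx1\t10\t40\trs1|A\t6")
})
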