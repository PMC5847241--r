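test_that("discover_patterns matches the frozen toy-corpus expectations", {
  # shared 3-mer across all three sequences
  p <- discover_patterns(c("ACGUACG", "ACGUUCG", "ACGAACG"),
                         L = 3, W = 3, min_support = 3)
  expect_true("ACG" %in% p$motif)
  expect_equal(p$support[p$motif == "ACG"], 3L)

  # support cannot reach 2 in a one-sequence corpus
  expect_equal(nrow(discover_patterns("ACGUACGU", L = 3, W = 3,
                                      min_support = 2)), 0L)

  # maximality: the full shared sequence is reported, its substrings are not
  p <- discover_patterns(c("AAAA", "AAAA"), L = 2, W = 2, min_support = 2)
  expect_equal(p$motif, "AAAA")
  expect_equal(p$support, 2L)
})

test_that("discover_patterns validates its parameters", {
  expect_error(discover_patterns(c("ACGU", "ACGU"), L = 5, W = 4),
               class = "mirsnp_param_error")
  expect_error(discover_patterns(c("ACGU", "ACGU"), L = 2, W = 3,
                                 min_support = 1),
               class = "mirsnp_param_error")
})

test_that("pattern_support counts sequences, not occurrences", {
  expect_equal(pattern_support("A.G", c("AAG", "ACG", "AUU")), 2L)
  expect_equal(pattern_support("ACGUACGUA", c("ACG", "UUU")), 0L)
  expect_equal(pattern_support("ACGU", c("ACGU", "UUUU")), 1L)
  # two matches in one sequence still count once
  expect_equal(pattern_support("AA", "AAAA"), 1L)
})

test_that("discover_patterns equals the brute-force enumerator on small corpora", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(2:5, 1)
    seqs <- vapply(sample(4:8, n, TRUE), random_rna, character(1))
    L <- sample(2:3, 1); W <- L + sample(0:2, 1)
    ms <- 2L
    got <- discover_patterns(seqs, L = L, W = W, min_support = ms)
    want <- oracle_patterns(seqs, L = L, W = W, min_support = ms)
    got <- got[order(got$motif, method = "radix"), c("motif", "support")]
    expect_equal(as.data.frame(got), as.data.frame(want),
                 info = paste("corpus:", paste(seqs, collapse = ",")))
  }
})

test_that("support is monotone under specialization and extension", {
  set.seed(7)
  seqs <- vapply(rep(15, 12), random_rna, character(1))
  pats <- discover_patterns(seqs, L = 2, W = 3, min_support = 2)
  for (i in seq_len(min(nrow(pats), 40))) {
    m <- pats$motif[i]
    # any single wildcard -> literal specialization cannot gain support
    wpos <- which(strsplit(m, "", fixed = TRUE)[[1]] == ".")
    for (w in utils::head(wpos, 2)) {
      for (b in c("A", "C")) {
        spec <- m
        substr(spec, w, w) <- b
        expect_lte(pattern_support(spec, seqs), pats$support[i])
      }
    }
    # extension cannot gain support
    expect_lte(pattern_support(paste0(m, "A"), seqs), pats$support[i])
    expect_lte(pattern_support(paste0("A", m), seqs), pats$support[i])
  }
})

test_that("pattern discovery is deterministic", {
  set.seed(42)
  seqs <- vapply(rep(18, 20), random_rna, character(1))
  a <- discover_patterns(seqs, min_support = 3)
  b <- discover_patterns(seqs, min_support = 3)
  expect_identical(a, b)
})

test_that("a planted motif is recovered (possibly inside a longer maximal pattern)", {
  set.seed(9)
  for (rep in 1:5) {
    motif <- random_rna(7)
    corpus <- gen_mirna_corpus(n_mirnas = 25, planted_motif = motif,
                               carrier_fraction = 0.6, seed = 100 + rep)
    pats <- discover_patterns(corpus, min_support = 10)
    expect_true(any(grepl(motif, pats$motif, fixed = TRUE) |
                      vapply(pats$motif, function(m)
                        grepl(m, motif), logical(1))),
                info = motif)
  }
})

test_that("fit_background matches closed-form smoothed counts", {
  bg <- suppressWarnings(fit_background("AAAA", order = 0))
  expect_equal(unname(bg$trans["*", "A"]), (4 + 1) / (4 + 4))
  expect_equal(unname(rowSums(bg$trans)), rep(1, nrow(bg$trans)),
               tolerance = 1e-9)

  # unseen contexts under pure smoothing are uniform
  bg2 <- suppressWarnings(fit_background("ACGU", order = 2))
  expect_equal(unname(bg2$trans["UU", ]), rep(0.25, 4), tolerance = 1e-12)
  expect_equal(unname(rowSums(bg2$trans)), rep(1, nrow(bg2$trans)),
               tolerance = 1e-9)

  # law of large numbers on a uniform corpus
  set.seed(3)
  big <- vapply(rep(50, 200), random_rna, character(1))
  bg3 <- fit_background(big, order = 0)
  expect_equal(unname(bg3$trans["*", ]), rep(0.25, 4), tolerance = 0.02)

  expect_error(fit_background(character(0), order = 0),
               class = "mirsnp_param_error")
  expect_error(suppressWarnings(fit_background("ACGU", order = 3)),
               class = "mirsnp_param_error")
})

test_that("keep_significant retains planted, over-represented patterns and drops null ones", {
  set.seed(21)
  motif <- "GUCACGG"
  hits <- 0L
  for (s in 1:10) {
    corpus <- gen_mirna_corpus(n_mirnas = 40, planted_motif = motif,
                               carrier_fraction = 0.9, seed = 300 + s)
    pats <- discover_patterns(corpus, min_support = 30)
    bg <- fit_background(corpus, order = 2)
    # Monte Carlo oracle for the expected support of the planted motif
    lens <- nchar(corpus$sequence)
    null_support <- replicate(200, {
      null <- vapply(lens, random_rna, character(1))
      sum(grepl(motif, null))
    })
    expect_lt(mean(null_support), 0.05 * nrow(corpus)) # rare under the null
    sig <- keep_significant(pats, bg, corpus, min_log_odds = 1)
    carried <- any(vapply(sig$motif, function(m)
      grepl(m, motif) || grepl(motif, m, fixed = TRUE), logical(1)))
    hits <- hits + carried
  }
  expect_equal(hits, 10L)
})

test_that("keep_significant drops patterns at their background expectation", {
  set.seed(5)
  corpus <- vapply(rep(20, 60), random_rna, character(1))
  pats <- discover_patterns(corpus, min_support = 2)
  bg <- fit_background(corpus, order = 0)
  sig <- keep_significant(pats, bg, corpus, min_log_odds = log(2))
  # single-base patterns match essentially every sequence under the null
  expect_false(any(nchar(sig$motif) == 1L))
  # observed == expected implies log-odds 0, dropped for any threshold > 0
  expect_true(all(sig$log_odds >= log(2)))

  empty <- keep_significant(pats[0, ], bg, corpus)
  expect_equal(nrow(empty), 0L)
})

test_that("Monte Carlo and inclusion-bound significance agree on clear cases", {
  set.seed(8)
  motif <- "CCAUGGA"
  corpus <- gen_mirna_corpus(n_mirnas = 30, planted_motif = motif,
                             carrier_fraction = 0.8, seed = 77)
  pats <- discover_patterns(corpus, min_support = 20)
  bg <- fit_background(corpus, order = 1)
  a <- keep_significant(pats, bg, corpus, method = "inclusion")
  b <- keep_significant(pats, bg, corpus, method = "mc", n_null = 50, seed = 2)
  planted_in <- function(x) any(vapply(x$motif, function(m)
    grepl(m, motif) || grepl(motif, m, fixed = TRUE), logical(1)))
  expect_true(planted_in(a))
  expect_true(planted_in(b))
})
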