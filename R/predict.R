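# Per-SNP orchestration: substitute each allele, scan, call islands, rank
# miRNAs, and classify the SNP by allele-differential predicted binding.

#' Classify a SNP from its per-allele best binding scores
#'
#' An allele with no qualifying alignment contributes score 0. Verdicts:
#' `"equal"` (both alleles qualify, score difference <= `epsilon`),
#' `"stronger:<allele>"` (one allele exceeds the other by more than
#' `epsilon`), `"island_no_alignment"` (an island overlaps the SNP but no
#' miRNA qualifies for either allele), `"no_island"` (no island overlaps the
#' SNP in either allelic context).
#'
#' @param best_a,best_b Best qualifying score for each allele (`NA` = no
#'   qualifying alignment).
#' @param epsilon Equal-binding margin (score units), >= 0.
#' @param allele_a,allele_b Allele labels used in the `stronger:` verdict.
#' @param any_island Whether any island overlapped the SNP in at least one
#'   allelic context.
#' @return Verdict string.
#' @export
classify <- function(best_a, best_b, epsilon = 0.5,
                     allele_a = "A", allele_b = "B", any_island = TRUE) {
  if (epsilon < 0) mirsnp_param_error("epsilon must be >= 0")
  if (!any_island) return("no_island")
  if (is.na(best_a) && is.na(best_b)) return("island_no_alignment")
  a <- if (is.na(best_a)) 0 else best_a
  b <- if (is.na(best_b)) 0 else best_b
  if (abs(a - b) <= epsilon) return("equal")
  if (a > b) paste0("stronger:", allele_a) else paste0("stronger:", allele_b)
}

# Evaluate one allelic context: scan, call islands, keep SNP-overlapping
# islands, rank miRNAs, return the best qualifying alignment.
evaluate_allele <- function(utr, snp, allele, target_patterns, corpus, config) {
  autr <- apply_allele(utr, snp, allele)
  hits <- scan_hits(autr$sequence, target_patterns)
  islands <- call_islands(hits, nchar(autr$sequence),
                          window = config$window,
                          min_island_hits = config$min_island_hits,
                          snp_offset = autr$snp_offset)
  overl <- islands[which(islands$overlaps_snp), , drop = FALSE]
  best <- NULL
  if (nrow(overl) > 0L) {
    utr_len <- nchar(autr$sequence)
    for (i in seq_len(nrow(overl))) {
      st <- overl$start[i]; en <- overl$end[i]
      # guarantee the aligner's minimum context on very short islands
      if (en - st < 8L) {
        pad <- 8L - (en - st)
        st <- max(0L, st - pad %/% 2L - pad %% 2L)
        en <- min(utr_len, max(en + pad %/% 2L, st + 8L))
      }
      island_seq <- substr(autr$sequence, st + 1L, en)
      ranked <- rank_mirnas(corpus, island_seq, config$duplex)
      if (nrow(ranked) > 0L) {
        top <- ranked[1L, ]
        if (is.null(best) || top$score > best$score) {
          best <- dplyr::mutate(top, island_start = st + top$island_start,
                                island_end = st + top$island_end)
        }
      }
    }
  }
  list(
    allele = allele,
    n_islands = nrow(islands),
    has_island = nrow(overl) > 0L,
    islands = islands,
    best = best
  )
}

#' Predict the allele-differential miRNA binding verdict for one SNP
#'
#' Runs both allelic contexts of the host UTR through hit scanning, island
#' calling (only islands overlapping the SNP are allele-compared), and
#' duplex ranking, then classifies the SNP.
#'
#' @param utr One-row UTR tibble (`transcript_id`, `gene`, `sequence`).
#' @param snp One-row SNP tibble (`rsid`, `utr_offset`, `allele1`,
#'   `allele2`).
#' @param patterns Significant patterns already mapped to target space
#'   ([target_space_pattern()]).
#' @param corpus miRNA corpus tibble.
#' @param config A [mirsnp_config()] object.
#' @return A one-row tibble: `rsid, gene, alleles, mirnas, allele_scores,
#'   verdict, delta, score_allele1, score_allele2, mirna_allele1,
#'   mirna_allele2`.
#' @export
predict_mirsnp <- function(utr, snp, patterns, corpus, config = mirsnp_config()) {
  if (!is.null(utr$transcript_id) && !is.null(snp$transcript_id) &&
      utr$transcript_id[[1]] != snp$transcript_id[[1]]) {
    mirsnp_param_error(sprintf("SNP %s is not on UTR %s", snp$rsid[[1]],
                               utr$transcript_id[[1]]))
  }
  alleles <- c(snp$allele1[[1]], snp$allele2[[1]])
  evals <- lapply(alleles, function(a) {
    evaluate_allele(utr, snp, a, patterns, corpus, config)
  })
  best_scores <- vapply(evals, function(ev) {
    if (is.null(ev$best)) NA_real_ else ev$best$score
  }, numeric(1))
  best_mirnas <- vapply(evals, function(ev) {
    if (is.null(ev$best)) NA_character_ else ev$best$mirna_id
  }, character(1))
  any_island <- any(vapply(evals, function(ev) ev$has_island, logical(1)))
  verdict <- classify(best_scores[1], best_scores[2], epsilon = config$epsilon,
                      allele_a = alleles[1], allele_b = alleles[2],
                      any_island = any_island)
  scores0 <- ifelse(is.na(best_scores), 0, best_scores)
  mirna_set <- sort(unique(best_mirnas[!is.na(best_mirnas)]), method = "radix")
  allele_scores <- paste(sprintf("%s=%g", alleles, scores0), collapse = ";")
  tibble(
    rsid = snp$rsid[[1]],
    gene = if ("gene" %in% names(utr)) utr$gene[[1]] else NA_character_,
    alleles = paste(alleles, collapse = "/"),
    mirnas = paste(mirna_set, collapse = ","),
    allele_scores = allele_scores,
    verdict = verdict,
    delta = abs(scores0[1] - scores0[2]),
    score_allele1 = scores0[1], score_allele2 = scores0[2],
    mirna_allele1 = best_mirnas[1], mirna_allele2 = best_mirnas[2]
  )
}

#' Run the full MirSNP prediction pipeline
#'
#' Reads the three inputs (or accepts in-memory tibbles), discovers and
#' filters significant patterns from the miRNA corpus, maps them to target
#' space, and classifies every retained SNP. Deterministic given config (and
#' seed, when the Monte Carlo significance method is selected).
#'
#' @param mirna_fasta miRNA corpus: FASTA path or tibble (`mirna_id`,
#'   `sequence`).
#' @param utr_fasta 3'UTRs: FASTA path or tibble (`transcript_id`, `gene`,
#'   `sequence`).
#' @param snp_table SNPs: TSV path (see [read_snp_table()]) or tibble.
#' @param config A [mirsnp_config()] object.
#' @param report Optional path; when given, the TSV report is written there
#'   via [write_mirsnp_report()].
#' @return A `mirsnp_result`: the calls tibble (one row per retained SNP)
#'   with attributes `patterns` (significant target-space patterns),
#'   `config`, and `summary`.
#' @export
run_pipeline <- function(mirna_fasta, utr_fasta, snp_table,
                         config = mirsnp_config(), report = NULL) {
  corpus <- if (is.data.frame(mirna_fasta)) {
    as_mirna_corpus(mirna_fasta)
  } else {
    x <- read_fasta(mirna_fasta, alphabet = "rna")
    tibble(mirna_id = x$id, sequence = x$sequence)
  }
  utrs <- if (is.data.frame(utr_fasta)) {
    as_tibble(utr_fasta)
  } else {
    x <- read_fasta(utr_fasta, alphabet = "dna")
    tibble(transcript_id = x$id, gene = x$id, sequence = x$sequence)
  }
  if (!"gene" %in% names(utrs)) utrs$gene <- utrs$transcript_id
  n_snps_in <- NA_integer_
  snps <- if (is.data.frame(snp_table)) {
    n_snps_in <- nrow(snp_table)
    s <- as_tibble(snp_table)
    s[!is.na(s$maf) & s$maf >= config$maf_min, , drop = FALSE]
  } else {
    s <- read_snp_table(snp_table, format = "tsv", maf_min = config$maf_min,
                        utrs = utrs)
    s
  }

  min_support <- config$min_support %||%
    max(2L, as.integer(ceiling(0.01 * nrow(corpus))))
  pats <- discover_patterns(corpus, L = config$L, W = config$W,
                            min_support = min_support)
  bg <- fit_background(corpus, order = config$markov_order)
  sig <- keep_significant(pats, bg, corpus,
                          min_log_odds = config$min_log_odds,
                          method = config$significance_method,
                          n_null = config$n_null, seed = config$seed)
  tpats <- target_space_pattern(sig)

  calls <- purrr::map(seq_len(nrow(snps)), function(i) {
    snp <- snps[i, ]
    utr <- utrs[utrs$transcript_id == snp$transcript_id, , drop = FALSE]
    if (nrow(utr) == 0L) {
      warn(sprintf("SNP %s: host UTR %s not found; skipped",
                   snp$rsid, snp$transcript_id))
      return(NULL)
    }
    predict_mirsnp(utr[1L, ], snp, tpats, corpus, config)
  })
  calls <- dplyr::bind_rows(calls)
  if (nrow(calls) == 0L) {
    calls <- tibble(
      rsid = character(), gene = character(), alleles = character(),
      mirnas = character(), allele_scores = character(),
      verdict = character(), delta = numeric(),
      score_allele1 = numeric(), score_allele2 = numeric(),
      mirna_allele1 = character(), mirna_allele2 = character()
    )
  }
  calls <- calls[order(calls$rsid, method = "radix"), ]

  verdict_class <- sub(":.*$", "", calls$verdict)
  summary <- tibble(
    n_mirnas = nrow(corpus),
    n_patterns = nrow(pats),
    n_significant = nrow(sig),
    n_snps_in = if (is.na(n_snps_in)) nrow(snps) else n_snps_in,
    n_snps_evaluated = nrow(calls),
    n_equal = sum(verdict_class == "equal"),
    n_stronger = sum(verdict_class == "stronger"),
    n_island_no_alignment = sum(verdict_class == "island_no_alignment"),
    n_no_island = sum(verdict_class == "no_island")
  )
  inform(sprintf(
    "mirsnp pipeline: %d patterns (%d significant); %d SNP(s): %d stronger, %d equal, %d island_no_alignment, %d no_island",
    summary$n_patterns, summary$n_significant, summary$n_snps_evaluated,
    summary$n_stronger, summary$n_equal, summary$n_island_no_alignment,
    summary$n_no_island
  ))
  out <- structure(calls, class = c("mirsnp_result", class(calls)),
                   patterns = tpats, config = config, summary = summary)
  if (!is.null(report)) write_mirsnp_report(out, report)
  out
}

#' @export
print.mirsnp_result <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf(
    "<mirsnp_result> %d SNP call(s) [%d stronger, %d equal, %d island_no_alignment, %d no_island]; %d significant pattern(s)\n",
    s$n_snps_evaluated, s$n_stronger, s$n_equal, s$n_island_no_alignment,
    s$n_no_island, s$n_significant
  ))
  NextMethod()
}
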