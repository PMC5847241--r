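# miRNA:island heteroduplex scoring by local antiparallel complementarity
# alignment (Watson-Crick + G:U wobble, affine gaps).

#' Duplex alignment scoring parameters
#'
#' @param match_wc Score for a Watson-Crick pair (A:U/T, C:G); default +5.
#' @param match_gu Score for a G:U wobble pair; default +1.
#' @param mismatch Mismatch score; default -3.
#' @param gap_open Cost of the first base of a gap; default -8. A gap of
#'   length k costs `gap_open + (k - 1) * gap_extend`.
#' @param gap_extend Per-base gap extension cost; default -2.
#' @param seed_min_pairs Minimum paired seed positions for a qualifying
#'   alignment; default 6. The seed is miRNA positions 2-8 (1-based from the
#'   5' end).
#' @param min_report_score Minimum qualifying alignment score; default 40.
#' @param wobble_in_seed Whether G:U wobble pairs count towards
#'   `seed_min_pairs`; default TRUE.
#' @return A `duplex_params` list.
#' @export
duplex_params <- function(match_wc = 5, match_gu = 1, mismatch = -3,
                          gap_open = -8, gap_extend = -2,
                          seed_min_pairs = 6L, min_report_score = 40,
                          wobble_in_seed = TRUE) {
  if (!(match_wc > match_gu && match_gu > 0 && 0 > mismatch)) {
    mirsnp_param_error("require match_wc > match_gu > 0 > mismatch")
  }
  if (!(gap_open <= gap_extend && gap_extend < 0)) {
    mirsnp_param_error("require gap_open <= gap_extend < 0")
  }
  structure(
    list(match_wc = match_wc, match_gu = match_gu, mismatch = mismatch,
         gap_open = gap_open, gap_extend = gap_extend,
         seed_min_pairs = as.integer(seed_min_pairs),
         min_report_score = min_report_score,
         wobble_in_seed = isTRUE(wobble_in_seed)),
    class = "duplex_params"
  )
}

#' Align a miRNA against a target-island sequence
#'
#' Optimal local antiparallel complementarity alignment (miRNA 5'->3'
#' against the island 3'->5') under affine gap scoring. A:U/T and C:G score
#' `match_wc`, G:U/T wobble scores `match_gu`. A best score of 0 or less is
#' reported as score 0 with no paired positions (local alignment floor).
#'
#' @param mirna miRNA sequence (RNA or DNA letters), or a one-row corpus
#'   tibble with `mirna_id`, `sequence`.
#' @param island_seq Island sequence (DNA or RNA letters; both give
#'   identical scores), length >= 8.
#' @param params A [duplex_params()] object.
#' @return A one-row tibble: `mirna_id, score, seed_pairs, n_pairs,
#'   qualifies, mirna_start, mirna_end, island_start, island_end, cigar,
#'   pairs` where `pairs` is a list-column tibble
#'   (`mirna_pos, island_pos, type`) of paired positions (0-based; type
#'   `"WC"` or `"GU"`), strictly increasing on the miRNA and strictly
#'   decreasing on the island. Alignment coordinates are 0-based half-open.
#' @export
align_duplex <- function(mirna, island_seq, params = duplex_params()) {
  mirna_id <- NA_character_
  if (is.data.frame(mirna)) {
    mirna_id <- mirna$mirna_id[[1]]
    mirna <- mirna$sequence[[1]]
  }
  if (nchar(island_seq) < 8L) {
    mirsnp_param_error("island sequence must be at least 8 nt")
  }
  mir_dna <- chartr("U", "T", toupper(mirna))
  isl_dna <- chartr("U", "T", toupper(island_seq))
  n_isl <- nchar(isl_dna)
  res <- duplex_align_cpp(mir_dna, stringi::stri_reverse(isl_dna),
                          params$match_wc, params$match_gu, params$mismatch,
                          params$gap_open, params$gap_extend)
  score <- res$score
  op <- res$col_op
  type <- res$col_type
  pair_cols <- which(op == 0L & type %in% c(0L, 1L))
  pairs <- tibble(
    mirna_pos = res$col_mirna[pair_cols] - 1L,
    island_pos = n_isl - res$col_island[pair_cols],
    type = c("WC", "GU")[type[pair_cols] + 1L]
  )
  seed_types <- if (params$wobble_in_seed) c("WC", "GU") else "WC"
  seed_pairs <- sum(pairs$mirna_pos >= 1L & pairs$mirna_pos <= 7L &
                      pairs$type %in% seed_types)
  qualifies <- score >= params$min_report_score &&
    seed_pairs >= params$seed_min_pairs && score > 0
  if (length(op) > 0L) {
    mcols <- res$col_mirna[op != 1L]
    icols <- res$col_island[op != 2L]
    mirna_start <- min(mcols) - 1L
    mirna_end <- max(mcols)
    island_start <- n_isl - max(icols)
    island_end <- n_isl - min(icols) + 1L
    aligned_sym <- c("M", "W", "X")[pmax(type, 0L) + 1L]
    sym <- ifelse(op == 1L, "D", ifelse(op == 2L, "I", aligned_sym))
    r <- rle(sym)
    cigar <- paste0(r$lengths, r$values, collapse = "")
  } else {
    mirna_start <- mirna_end <- island_start <- island_end <- NA_integer_
    cigar <- ""
  }
  tibble(
    mirna_id = mirna_id, score = score,
    seed_pairs = as.integer(seed_pairs),
    n_pairs = nrow(pairs), qualifies = qualifies,
    mirna_start = mirna_start, mirna_end = mirna_end,
    island_start = island_start, island_end = island_end,
    cigar = cigar, pairs = list(pairs)
  )
}

#' Rank corpus miRNAs against one target island
#'
#' Aligns every corpus miRNA to the island sequence and returns the
#' qualifying alignments (score >= `min_report_score` and seed pairing >=
#' `seed_min_pairs`), sorted by score (desc) then `mirna_id`; an empty
#' tibble when no miRNA qualifies.
#'
#' @param corpus miRNA corpus (tibble with `mirna_id`, `sequence`).
#' @param island_seq Island sequence (DNA), length >= 8.
#' @param params A [duplex_params()] object.
#' @return Tibble of qualifying alignments (see [align_duplex()]).
#' @export
rank_mirnas <- function(corpus, island_seq, params = duplex_params()) {
  cp <- as_mirna_corpus(corpus)
  res <- purrr::map(seq_len(nrow(cp)), function(i) {
    align_duplex(cp[i, ], island_seq, params)
  })
  out <- dplyr::bind_rows(res)
  out <- out[out$qualifies, , drop = FALSE]
  out[order(-out$score, out$mirna_id, method = "radix"), ]
}
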