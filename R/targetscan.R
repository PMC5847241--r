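# Mapping patterns into 3'UTR (DNA) space and calling target islands.
#
# Patterns are discovered in miRNA (RNA) space; a target site is the reverse
# complement of (part of) the miRNA, so patterns are reverse-complemented
# and transliterated U -> T before scanning UTRs. UTR coordinates are
# 0-based, half-open.

#' Map a pattern motif into target (UTR/DNA) space
#'
#' Reverse-complements the motif (A<->U/T, C<->G) and transliterates to the
#' DNA alphabet; the wildcard `.` maps to itself. The (L,W) density
#' constraint is preserved (reversal is literal-mask symmetric).
#'
#' @param p A motif string over `{A,C,G,U,.}`, or a pattern tibble with a
#'   `motif` column (all other columns are carried through).
#' @return The target-space motif(s) over `{A,C,G,T,.}`, same type as input.
#' @export
target_space_pattern <- function(p) {
  if (is.data.frame(p)) {
    p$motif <- target_space_pattern(p$motif)
    return(p)
  }
  stringi::stri_reverse(chartr("ACGUT", "TGCAA", p))
}

#' Substitute a SNP allele into a 3'UTR sequence
#'
#' @param utr One UTR record: a one-row tibble (or list) with
#'   `transcript_id` and `sequence` (DNA, sense strand).
#' @param snp One SNP record: a one-row tibble (or list) with `rsid`,
#'   `utr_offset` (0-based), `allele1`, `allele2`.
#' @param allele The allele to apply; must be one of the SNP's two alleles.
#' @return A one-row tibble `transcript_id, rsid, allele, snp_offset,
#'   sequence` with the allele substituted at `snp_offset`. The input is
#'   unmodified; the sequence differs from the input at exactly the SNP
#'   offset (or nowhere, when `allele` is the in-sequence allele).
#' @export
apply_allele <- function(utr, snp, allele) {
  seq <- utr$sequence[[1]]
  off <- as.integer(snp$utr_offset[[1]])
  if (!allele %in% c(snp$allele1[[1]], snp$allele2[[1]])) {
    mirsnp_param_error(sprintf(
      "allele %s is not one of %s/%s for %s",
      allele, snp$allele1[[1]], snp$allele2[[1]], snp$rsid[[1]]
    ))
  }
  if (off < 0L || off >= nchar(seq)) {
    mirsnp_param_error(sprintf(
      "SNP offset %d outside UTR %s (length %d)",
      off, utr$transcript_id[[1]], nchar(seq)
    ))
  }
  substr(seq, off + 1L, off + 1L) <- allele
  tibble(
    transcript_id = utr$transcript_id[[1]],
    rsid = snp$rsid[[1]],
    allele = allele,
    snp_offset = off,
    sequence = seq
  )
}

#' Scan a sequence for all (overlapping) pattern hits
#'
#' Every position where a target-space motif matches is reported, for every
#' motif; overlapping matches are found. The wildcard `.` matches any of
#' `{A,C,G,T}`; the ambiguity code `N` in the sequence matches nothing.
#'
#' @param sequence A DNA string (an allelic UTR sequence), or a one-row
#'   tibble with a `sequence` column.
#' @param motifs Character vector of target-space motifs (or a pattern
#'   tibble with a `motif` column).
#' @return A tibble `motif, start, end` (0-based, half-open), sorted by
#'   `start` then `motif`.
#' @export
scan_hits <- function(sequence, motifs) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[[1]]
  if (is.data.frame(motifs)) motifs <- motifs$motif
  if (length(motifs) == 0L) {
    return(tibble(motif = character(), start = integer(), end = integer()))
  }
  bad <- stringi::stri_detect_regex(motifs, "[^ACGT.]")
  if (any(bad)) {
    mirsnp_param_error(sprintf(
      "target-space motifs must be over {A,C,G,T,.}: %s",
      paste(utils::head(motifs[bad], 3), collapse = ", ")
    ))
  }
  res <- purrr::map(motifs, function(m) {
    rx <- paste0("(?=", gsub(".", "[ACGT]", m, fixed = TRUE), ")")
    loc <- stringi::stri_locate_all_regex(sequence, rx)[[1]]
    if (all(is.na(loc[, 1L]))) return(NULL)
    starts <- loc[, 1L] - 1L
    tibble(motif = m, start = as.integer(starts),
           end = as.integer(starts + nchar(m)))
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) {
    return(tibble(motif = character(), start = integer(), end = integer()))
  }
  out[order(out$start, out$motif, method = "radix"), ]
}

#' Call target islands from pattern hits
#'
#' A target island is a hit-dense interval: whenever at least
#' `min_island_hits` hit start positions fall within some span of `window`
#' consecutive positions, those hits seed an island spanning from the first
#' hit's start to the last member hit's end; overlapping islands are merged,
#' so islands within one allelic UTR are disjoint. Hit counts report all
#' hits whose start lies inside the island.
#'
#' @param hits Hit tibble from [scan_hits()].
#' @param utr_len Length of the scanned sequence (bounds check only).
#' @param window Window span in nt, default 25.
#' @param min_island_hits Minimum hit starts per window, default 5.
#' @param snp_offset Optional 0-based SNP offset used to flag
#'   `overlaps_snp` (`start <= snp_offset < end`).
#' @return A tibble `start, end, hit_count, overlaps_snp` sorted by `start`.
#' @export
call_islands <- function(hits, utr_len, window = 25L, min_island_hits = 5L,
                         snp_offset = NULL) {
  window <- as.integer(window)
  min_island_hits <- as.integer(min_island_hits)
  if (window < 1L || min_island_hits < 1L) {
    mirsnp_param_error("window and min_island_hits must be >= 1")
  }
  empty <- tibble(start = integer(), end = integer(), hit_count = integer(),
                  overlaps_snp = logical())
  if (nrow(hits) < min_island_hits) return(empty)
  hits <- hits[order(hits$start, hits$end, method = "radix"), ]
  s <- hits$start
  e <- hits$end
  m <- min_island_hits
  nh <- length(s)
  qual <- which(s[seq_len(nh - m + 1L) + m - 1L] - s[seq_len(nh - m + 1L)] <= window - 1L)
  if (length(qual) == 0L) return(empty)
  iv_start <- s[qual]
  iv_end <- vapply(qual, function(i) max(e[i:(i + m - 1L)]), integer(1))
  # merge overlapping seed intervals
  ord <- order(iv_start, iv_end)
  iv_start <- iv_start[ord]; iv_end <- iv_end[ord]
  ms <- iv_start[1L]; me <- iv_end[1L]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(iv_start)[-1L]) {
    if (iv_start[i] < me) {
      me <- max(me, iv_end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- iv_start[i]; me <- iv_end[i]
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  hit_count <- vapply(seq_along(out_s), function(i) {
    sum(s >= out_s[i] & s < out_e[i])
  }, integer(1))
  overlaps <- if (is.null(snp_offset)) {
    rep(NA, length(out_s))
  } else {
    out_s <= snp_offset & snp_offset < out_e
  }
  tibble(start = out_s, end = pmin(out_e, as.integer(utr_len)),
         hit_count = hit_count, overlaps_snp = overlaps)
}

#' Write target islands as BED
#'
#' Transcript-relative coordinates, 0-based half-open; `name` is
#' `rsid|allele` and `score` the island hit count.
#'
#' @param islands Island tibble with at least `start`, `end`, `hit_count`,
#'   plus `transcript_id`, `rsid`, `allele` columns.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_islands_bed <- function(islands, path) {
  lines <- sprintf("%s\t%d\t%d\t%s|%s\t%d",
                   islands$transcript_id, islands$start, islands$end,
                   islands$rsid, islands$allele, islands$hit_count)
  writeLines(lines, path)
  invisible(path)
}
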