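# (L,W) pattern discovery over a mature-miRNA corpus.
#
# A pattern is a motif over {A,C,G,U,'.'} ('.' = single-base wildcard) that
# starts and ends with a literal and satisfies the (L,W) density constraint:
# every window of W consecutive motif positions contains >= L literals
# (vacuous for motifs shorter than W). Support counts corpus sequences with
# at least one match, not occurrences. discover_patterns() returns exactly
# the maximal patterns: those that cannot be extended (prefix/suffix) or
# specialized (wildcard -> literal) without losing support.

pattern_literal_count <- function(motif) {
  nchar(motif) - stringi::stri_count_fixed(motif, ".")
}

# Density validity of a literal mask under the (L,W) rule.
valid_lw_mask <- function(mask, L, W) {
  n <- length(mask)
  if (n == 0L || !mask[1L] || !mask[n]) return(FALSE)
  if (n < W) return(TRUE)
  cs <- cumsum(mask)
  win <- cs[W:n] - c(0L, cs[seq_len(n - W)])
  all(win >= L)
}

#' Validate a wildcard pattern motif
#'
#' @param motif Motif string over `{A,C,G,U,.}`.
#' @param L,W Density parameters: every window of `W` consecutive positions
#'   must contain at least `L` literals (windows only exist for motifs of
#'   length `>= W`); the motif must start and end with a literal.
#' @return Logical.
#' @export
is_valid_pattern <- function(motif, L = 4L, W = 6L) {
  vapply(motif, function(m) {
    if (stringi::stri_detect_regex(m, "[^ACGU.]")) return(FALSE)
    mask <- strsplit(m, "", fixed = TRUE)[[1]] != "."
    valid_lw_mask(mask, L, W)
  }, logical(1), USE.NAMES = FALSE)
}

#' Count supporting sequences for a motif
#'
#' Support is the number of corpus sequences containing at least one match
#' of the motif; the wildcard `.` matches any single base. Multiple matches
#' within one sequence count once.
#'
#' @param motif Motif string over `{A,C,G,U,.}`.
#' @param corpus miRNA corpus (tibble with `mirna_id`, `sequence`, or a
#'   character vector of RNA sequences).
#' @return Integer support count.
#' @export
pattern_support <- function(motif, corpus) {
  cp <- as_mirna_corpus(corpus)
  if (stringi::stri_detect_regex(motif, "[^ACGU.]")) {
    mirsnp_param_error(sprintf("invalid motif: %s", motif))
  }
  sum(stringi::stri_detect_regex(cp$sequence, motif))
}

#' Discover maximal (L,W) patterns in a miRNA corpus
#'
#' Teiresias-style de-novo enumeration: depth-first extension of motifs
#' (literal start, rightward extension by 0..W-1 wildcards plus a literal)
#' with support-based pruning, followed by a maximality filter. A pattern is
#' reported iff its support is at least `min_support` and no extension or
#' wildcard specialization retains the same support. Subtrees whose motif
#' has a wildcard position that is base-uniform across all occurrences are
#' pruned (every pattern there is subsumed by the literal specialization
#' with identical occurrences).
#'
#' @param corpus miRNA corpus (tibble or character vector).
#' @param L,W Density parameters (`2 <= L <= W`), defaults 4 and 6.
#' @param min_support Minimum number of supporting sequences; default
#'   `max(2, ceiling(0.01 * corpus size))`.
#' @return A tibble `motif, support, literal_count, log_odds` sorted by
#'   support (desc), literal count (desc), motif (lexicographic, C locale);
#'   `log_odds` is `NA` until [keep_significant()] is applied.
#' @export
discover_patterns <- function(corpus, L = 4L, W = 6L, min_support = NULL) {
  cp <- as_mirna_corpus(corpus)
  seqs <- cp$sequence
  n <- length(seqs)
  if (is.null(min_support)) min_support <- max(2L, as.integer(ceiling(0.01 * n)))
  L <- as.integer(L); W <- as.integer(W); min_support <- as.integer(min_support)
  if (L < 2L || L > W) {
    mirsnp_param_error("require 2 <= L <= W")
  }
  if (min_support < 2L) {
    mirsnp_param_error("min_support must be >= 2")
  }

  M <- seq_char_matrix(seqs)
  ncol_m <- ncol(M)

  res_env <- new.env(parent = emptyenv())
  res_env$motif <- vector("list", 256L)
  res_env$support <- vector("list", 256L)
  res_env$k <- 0L

  record <- function(motif, support) {
    k <- res_env$k + 1L
    if (k > length(res_env$motif)) {
      length(res_env$motif) <- 2L * k
      length(res_env$support) <- 2L * k
    }
    res_env$motif[[k]] <- motif
    res_env$support[[k]] <- support
    res_env$k <- k
  }

  # occ_seq/occ_pos: occurrence list (sequence index, 1-based start).
  # wmask: logical literal mask of the motif.
  extend <- function(motif, wmask, occ_seq, occ_pos) {
    len <- length(wmask)
    # closedness prune: a wildcard uniform across occurrences means every
    # pattern in this subtree is subsumed with identical support
    wpos <- which(!wmask)
    for (w in wpos) {
      b <- M[cbind(occ_seq, occ_pos + w - 1L)]
      if (length(unique(b)) == 1L) return(invisible(NULL))
    }
    record(motif, length(unique(occ_seq)))
    max_next <- ncol_m - len
    for (k in 0L:min(W - 1L, max_next - 1L)) {
      newcol <- occ_pos + len + k
      ok <- newcol <= ncol_m
      if (!any(ok)) break
      chars <- rep(NA_character_, length(occ_seq))
      chars[ok] <- M[cbind(occ_seq[ok], newcol[ok])]
      new_mask <- c(wmask, rep(FALSE, k), TRUE)
      if (!valid_lw_mask(new_mask, L, W)) next
      for (b in RNA_BASES) {
        sel <- which(!is.na(chars) & chars == b)
        if (length(sel) == 0L) next
        os <- occ_seq[sel]
        if (length(unique(os)) < min_support) next
        extend(paste0(motif, strrep(".", k), b), new_mask, os, occ_pos[sel])
      }
    }
    invisible(NULL)
  }

  for (b in RNA_BASES) {
    idx <- which(M == b, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    os <- idx[, 1L]
    if (length(unique(os)) < min_support) next
    ord <- order(os, idx[, 2L])
    extend(b, TRUE, os[ord], idx[ord, 2L])
  }

  k <- res_env$k
  if (k == 0L) {
    return(tibble(motif = character(), support = integer(),
                  literal_count = integer(), log_odds = numeric()))
  }
  motifs <- unlist(res_env$motif[seq_len(k)])
  support <- unlist(res_env$support[seq_len(k)])
  lit <- pattern_literal_count(motifs)
  lens <- nchar(motifs)

  # maximality: drop P if some Q with equal support subsumes it (P obtainable
  # from Q by trimming/wildcarding); Q subsumes P iff regex P matches Q
  keep <- rep(TRUE, length(motifs))
  for (s in unique(support)) {
    g <- which(support == s)
    if (length(g) < 2L) next
    gl <- lens[g]; glit <- lit[g]; gm <- motifs[g]
    for (ii in seq_along(g)) {
      cand <- gm[gl > gl[ii] | (gl == gl[ii] & glit > glit[ii])]
      if (length(cand) == 0L) next
      if (any(stringi::stri_detect_regex(cand, gm[ii]))) keep[g[ii]] <- FALSE
    }
  }
  motifs <- motifs[keep]; support <- support[keep]; lit <- lit[keep]
  ord <- order(-support, -lit, motifs, method = "radix")
  tibble(motif = motifs[ord], support = as.integer(support[ord]),
         literal_count = as.integer(lit[ord]), log_odds = NA_real_)
}

#' Fit a Markov background model to a miRNA corpus
#'
#' Maximum-likelihood transition probabilities with add-one smoothing over
#' the RNA alphabet. The initial (context) distribution is the smoothed
#' empirical frequency of order-grams.
#'
#' @param corpus miRNA corpus.
#' @param order Markov order, one of 0, 1, 2.
#' @return A `mirsnp_background` object with elements `order`, `contexts`,
#'   `trans` (contexts x 4 matrix of probabilities, rows sum to 1), `init`
#'   (context distribution) and `trained_on`.
#' @export
fit_background <- function(corpus, order = 2L) {
  cp <- as_mirna_corpus(corpus)
  order <- as.integer(order)
  if (!order %in% 0:2) {
    mirsnp_param_error("order must be 0, 1 or 2")
  }
  seqs <- cp$sequence
  total <- sum(nchar(seqs))
  if (total <= 4^(order + 1)) {
    warn(sprintf("corpus length %d is small for a Markov model of order %d", total, order))
  }
  contexts <- if (order == 0L) {
    "*"
  } else {
    do.call(paste0, expand.grid(rep(list(RNA_BASES), order))[, order:1, drop = FALSE])
  }
  contexts <- sort(contexts, method = "radix")
  counts <- matrix(0, nrow = length(contexts), ncol = 4L,
                   dimnames = list(contexts, RNA_BASES))
  ctx_counts <- setNames(rep(0, length(contexts)), contexts)
  for (s in seqs) {
    len <- nchar(s)
    if (len <= order) next
    pos <- seq.int(order + 1L, len)
    b <- substring(s, pos, pos)
    ctx <- if (order == 0L) rep("*", length(pos)) else substring(s, pos - order, pos - 1L)
    t <- table(ctx, b)
    counts[rownames(t), colnames(t)] <- counts[rownames(t), colnames(t)] + t
    tc <- table(ctx)
    ctx_counts[names(tc)] <- ctx_counts[names(tc)] + tc
  }
  trans <- (counts + 1) / (rowSums(counts) + 4)
  init <- (ctx_counts + 1) / sum(ctx_counts + 1)
  structure(
    list(order = order, contexts = contexts, trans = trans, init = init,
         trained_on = sprintf("%d sequences, %d nt", length(seqs), total)),
    class = "mirsnp_background"
  )
}

#' @export
print.mirsnp_background <- function(x, ...) {
  cat(sprintf("<mirsnp_background> order %d Markov model (%s)\n",
              x$order, x$trained_on))
  invisible(x)
}

# Probability that `motif` matches a fixed window of a background sequence.
# Forward pass over Markov contexts; wildcards admit all four bases.
motif_match_prob <- function(motif, model) {
  chars <- strsplit(motif, "", fixed = TRUE)[[1]]
  ord <- model$order
  # distribution over contexts; advance one motif position at a time,
  # restricting emissions at literal positions
  dist <- model$init
  for (ch in chars) {
    new_dist <- setNames(rep(0, length(model$contexts)), model$contexts)
    bases <- if (ch == ".") RNA_BASES else ch
    for (b in bases) {
      step <- dist * model$trans[, b]
      if (ord == 0L) {
        new_ctx <- "*"
        new_dist[new_ctx] <- new_dist[new_ctx] + sum(step)
      } else {
        nc <- paste0(substring(names(dist), 2L, ord), b)
        agg <- tapply(step, nc, sum)
        new_dist[names(agg)] <- new_dist[names(agg)] + agg
      }
    }
    dist <- new_dist
  }
  sum(dist)
}

# Expected number of supporting sequences under the background model, by the
# position-wise inclusion bound (per-sequence match probability capped at 1).
expected_support_inclusion <- function(motif, model, seq_lengths) {
  k <- nchar(motif)
  p_pos <- motif_match_prob(motif, model)
  n_windows <- pmax(seq_lengths - k + 1L, 0L)
  sum(pmin(1, n_windows * p_pos))
}

# Simulate one corpus from the background model.
simulate_corpus <- function(model, seq_lengths) {
  ord <- model$order
  vapply(seq_lengths, function(len) {
    if (len == 0L) return("")
    ctx <- sample(model$contexts, 1L, prob = model$init)
    out <- character(len)
    start <- strsplit(ctx, "", fixed = TRUE)[[1]]
    take <- min(ord, len)
    if (take > 0L) out[seq_len(take)] <- start[seq_len(take)]
    if (len > ord) {
      for (i in seq.int(ord + 1L, len)) {
        b <- sample(RNA_BASES, 1L, prob = model$trans[if (ord == 0L) 1L else ctx, ])
        out[i] <- b
        if (ord > 0L) ctx <- paste0(substring(ctx, 2L, ord), b)
      }
    }
    paste(out, collapse = "")
  }, character(1))
}

#' Filter patterns by significance against a background model
#'
#' Each pattern's `log_odds = log(observed support / expected support)`
#' where expected support under the background model is computed either by
#' the position-wise inclusion bound (default; exact per-position match
#' probability, union-bounded per sequence) or by Monte Carlo over `n_null`
#' simulated corpora with the observed sequence lengths.
#'
#' @param patterns Pattern tibble from [discover_patterns()].
#' @param model Background model from [fit_background()].
#' @param corpus The corpus the patterns were discovered in (supplies the
#'   per-sequence lengths, and the simulation template for `method = "mc"`).
#' @param min_log_odds Retention threshold, default `log(2)`.
#' @param method `"inclusion"` or `"mc"`.
#' @param n_null Number of Monte Carlo null corpora (`method = "mc"`).
#' @param seed Seed for the Monte Carlo null (`method = "mc"`).
#' @return The retained patterns with `log_odds` filled in, original order.
#' @export
keep_significant <- function(patterns, model, corpus, min_log_odds = log(2),
                             method = c("inclusion", "mc"), n_null = 1000L,
                             seed = 1L) {
  method <- match.arg(method)
  if (nrow(patterns) == 0L) {
    patterns$log_odds <- numeric(0)
    return(patterns)
  }
  cp <- as_mirna_corpus(corpus)
  lens <- nchar(cp$sequence)
  if (method == "inclusion") {
    expected <- vapply(patterns$motif, expected_support_inclusion,
                       numeric(1), model = model, seq_lengths = lens,
                       USE.NAMES = FALSE)
  } else {
    hits <- numeric(nrow(patterns))
    with_substream(seed, "keep_significant_mc", {
      for (r in seq_len(n_null)) {
        null_seqs <- simulate_corpus(model, lens)
        for (i in seq_len(nrow(patterns))) {
          hits[i] <- hits[i] +
            sum(stringi::stri_detect_regex(null_seqs, patterns$motif[i]))
        }
      }
    })
    # half-count pseudo-observation keeps log odds finite for unseen motifs
    expected <- (hits + 0.5) / n_null
  }
  expected <- pmax(expected, .Machine$double.xmin)
  patterns$log_odds <- log(patterns$support / expected)
  patterns[patterns$log_odds >= min_log_odds, , drop = FALSE]
}
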