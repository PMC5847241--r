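# Independent oracles used to validate the package's algorithms on small
# instances. Each oracle is deliberately implemented by a different route
# than the code it checks (exhaustive enumeration, closed forms, or
# recurrences), never by calling the implementation.

# ---- pattern discovery oracle: enumerate every wildcard motif obtainable
# from a corpus substring by masking internal positions, filter by the
# (L,W) rule and support, then keep the maximal ones -----------------------

oracle_lw_valid <- function(motif, L, W) {
  mask <- strsplit(motif, "", fixed = TRUE)[[1]] != "."
  n <- length(mask)
  if (!mask[1] || !mask[n]) return(FALSE)
  if (n >= W) {
    for (st in seq_len(n - W + 1L)) {
      if (sum(mask[st:(st + W - 1L)]) < L) return(FALSE)
    }
  }
  TRUE
}

oracle_patterns <- function(seqs, L, W, min_support) {
  cands <- character(0)
  for (s in seqs) {
    n <- nchar(s)
    for (i in seq_len(n)) {
      for (j in i:n) {
        sub <- strsplit(substr(s, i, j), "", fixed = TRUE)[[1]]
        len <- j - i + 1L
        internal <- max(len - 2L, 0L)
        for (mask in 0:(2^internal - 1L)) {
          ch <- sub
          if (internal > 0L) {
            for (b in seq_len(internal)) {
              if (bitwAnd(mask, bitwShiftL(1L, b - 1L)) != 0L) ch[b + 1L] <- "."
            }
          }
          cands <- c(cands, paste(ch, collapse = ""))
        }
      }
    }
  }
  cands <- unique(cands)
  cands <- cands[vapply(cands, oracle_lw_valid, logical(1), L = L, W = W)]
  if (length(cands) == 0L) {
    return(tibble::tibble(motif = character(), support = integer()))
  }
  sup <- vapply(cands, function(m) {
    sum(vapply(seqs, function(s) grepl(m, s), logical(1)))
  }, numeric(1))
  keep <- sup >= min_support
  cands <- cands[keep]; sup <- sup[keep]
  maximal <- rep(TRUE, length(cands))
  for (i in seq_along(cands)) {
    for (j in seq_along(cands)) {
      if (i != j && sup[j] == sup[i] && grepl(cands[i], cands[j], fixed = FALSE)) {
        maximal[i] <- FALSE
        break
      }
    }
  }
  out <- tibble::tibble(motif = cands[maximal], support = as.integer(sup[maximal]))
  out[order(out$motif, method = "radix"), ]
}

# ---- scan oracle: naive position-by-position matching --------------------

oracle_scan <- function(seq, motifs) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  out <- list()
  for (m in motifs) {
    mc <- strsplit(m, "", fixed = TRUE)[[1]]
    k <- length(mc)
    if (k > length(chars)) next
    for (st in 0:(length(chars) - k)) {
      okay <- TRUE
      for (q in seq_len(k)) {
        c0 <- chars[st + q]
        if (mc[q] == ".") {
          if (!c0 %in% c("A", "C", "G", "T")) { okay <- FALSE; break }
        } else if (c0 != mc[q]) { okay <- FALSE; break }
      }
      if (okay) {
        out[[length(out) + 1L]] <- tibble::tibble(motif = m, start = st,
                                                  end = st + k)
      }
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble::tibble(motif = character(), start = integer(),
                          end = integer()))
  }
  res$start <- as.integer(res$start); res$end <- as.integer(res$end)
  res[order(res$start, res$motif, method = "radix"), ]
}

# ---- island oracle: test every possible window span ----------------------

oracle_islands <- function(hits, utr_len, window, min_hits) {
  if (nrow(hits) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(),
                          hit_count = integer()))
  }
  ivs <- list()
  for (x in 0:max(utr_len - 1L, 0L)) {
    memb <- which(hits$start >= x & hits$start <= x + window - 1L)
    if (length(memb) >= min_hits) {
      ivs[[length(ivs) + 1L]] <- c(min(hits$start[memb]), max(hits$end[memb]))
    }
  }
  if (length(ivs) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(),
                          hit_count = integer()))
  }
  iv <- unique(do.call(rbind, ivs))
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  merged <- list(iv[1, ])
  if (nrow(iv) > 1L) {
    for (r in 2:nrow(iv)) {
      last <- merged[[length(merged)]]
      if (iv[r, 1] < last[2]) {
        merged[[length(merged)]] <- c(last[1], max(last[2], iv[r, 2]))
      } else {
        merged[[length(merged) + 1L]] <- iv[r, ]
      }
    }
  }
  m <- do.call(rbind, merged)
  tibble::tibble(
    start = as.integer(m[, 1]),
    end = pmin(as.integer(m[, 2]), as.integer(utr_len)),
    hit_count = vapply(seq_len(nrow(m)), function(i) {
      sum(hits$start >= m[i, 1] & hits$start < m[i, 2])
    }, integer(1))
  )
}

# ---- duplex oracle: exhaustive chaining over paired positions ------------
# Enumerates monotone antiparallel pairings (via DP over chains of WC/GU
# pairs) with the optimal closed-form inter-pair fill: m mismatch columns
# plus single insertion/deletion runs; gap(k) = open + (k-1)*ext. Local
# alignment: flanks are free, empty pairing scores 0.

oracle_duplex_score <- function(mirna, island, params = duplex_params()) {
  a <- strsplit(chartr("U", "T", toupper(mirna)), "", fixed = TRUE)[[1]]
  b <- rev(strsplit(chartr("U", "T", toupper(island)), "", fixed = TRUE)[[1]])
  pair_sc <- function(x, y) {
    wc <- (x == "A" && y == "T") || (x == "T" && y == "A") ||
      (x == "C" && y == "G") || (x == "G" && y == "C")
    gu <- (x == "G" && y == "T") || (x == "T" && y == "G")
    if (wc) params$match_wc else if (gu) params$match_gu else NA_real_
  }
  gap <- function(k) if (k == 0L) 0 else params$gap_open + (k - 1L) * params$gap_extend
  fill <- function(di, dj) {
    best <- -Inf
    for (m in 0:min(di, dj)) {
      best <- max(best, m * params$mismatch + gap(di - m) + gap(dj - m))
    }
    best
  }
  n <- length(a); mm <- length(b)
  f <- matrix(-Inf, n, mm)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(mm)) {
      s <- pair_sc(a[i], b[j])
      if (is.na(s)) next
      prev <- 0
      if (i > 1L && j > 1L) {
        for (i2 in seq_len(i - 1L)) {
          for (j2 in seq_len(j - 1L)) {
            if (is.finite(f[i2, j2])) {
              prev <- max(prev, f[i2, j2] + fill(i - i2 - 1L, j - j2 - 1L))
            }
          }
        }
      }
      f[i, j] <- prev + s
      best <- max(best, f[i, j])
    }
  }
  best
}

# ---- Mendelian trio oracle: enumerate transmissible genotype sets --------

oracle_trio_consistent <- function(child, father, mother, universe = c("A", "B")) {
  if (any(is.na(child))) return(TRUE)
  f_opts <- if (any(is.na(father))) universe else father
  m_opts <- if (any(is.na(mother))) universe else mother
  combos <- expand.grid(f = f_opts, m = m_opts, stringsAsFactors = FALSE)
  target <- paste(sort(child), collapse = "")
  any(vapply(seq_len(nrow(combos)), function(r) {
    paste(sort(c(combos$f[r], combos$m[r])), collapse = "") == target
  }, logical(1)))
}

# ---- HWE oracle: Wigginton-style recurrence over heterozygote counts -----

oracle_hwe_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0L) return(1)
  na <- 2L * n_aa + n_ab
  nb <- 2L * n - na
  hets <- seq.int(na %% 2L, min(na, nb), by = 2L)
  # unnormalized probabilities by the ratio recurrence
  # P(h+2)/P(h) = (na-h)(nb-h) / ((h+2)(h+1)) * ... for the conditional
  # distribution given allele counts
  p <- numeric(length(hets))
  p[1] <- 1
  if (length(hets) > 1L) {
    for (k in 2:length(hets)) {
      h <- hets[k - 1L]
      aa <- (na - h) / 2 # homozygote counts at heterozygote count h
      bb <- (nb - h) / 2
      p[k] <- p[k - 1L] * (4 * aa * bb) / ((h + 2) * (h + 1))
    }
  }
  p <- p / sum(p)
  obs <- p[match(n_ab, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

# ---- misc helpers --------------------------------------------------------

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
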