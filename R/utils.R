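# Internal helpers shared across modules. All coordinates are 0-based,
# half-open; conversion to/from 1-based happens only at file-format
# boundaries (VCF, FASTA substring extraction).

RNA_BASES <- c("A", "C", "G", "U")
DNA_BASES <- c("A", "C", "G", "T")

# DNA complement used when mapping miRNA-space patterns into UTR (DNA) space.
DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

mirsnp_input_error <- function(msg, class = NULL) {
  abort(msg, class = c(class, "mirsnp_input_error"))
}

mirsnp_param_error <- function(msg) {
  abort(msg, class = c("mirsnp_param_error", "mirsnp_input_error"))
}

# Split sequences into a padded character matrix (rows = sequences) for fast
# indexed base lookup during pattern discovery.
seq_char_matrix <- function(seqs) {
  n <- length(seqs)
  lens <- nchar(seqs)
  m <- matrix(NA_character_, nrow = n, ncol = max(lens, 1L))
  for (i in seq_len(n)) {
    m[i, seq_len(lens[i])] <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
  }
  m
}

# Reverse complement of a DNA string (no wildcards).
revcomp_dna <- function(x) {
  stringi::stri_reverse(chartr("ACGT", "TGCA", x))
}

# miRNA (RNA) -> the exact DNA reverse complement a perfect target site has.
site_for_mirna <- function(mirna_rna) {
  revcomp_dna(chartr("U", "T", mirna_rna))
}

# Derive a reproducible substream seed from (seed, label) so that adding a
# generator never perturbs existing fixtures. Kept below 2^31.
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

with_substream <- function(seed, label, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, label))
  force(code)
}

random_seq <- function(len, bases = DNA_BASES) {
  paste(sample(bases, len, replace = TRUE), collapse = "")
}

# Coerce a miRNA corpus argument (tibble with mirna_id/sequence, named
# character vector, or bare character vector) to a canonical tibble.
as_mirna_corpus <- function(corpus) {
  if (is.data.frame(corpus)) {
    stopifnot(all(c("mirna_id", "sequence") %in% names(corpus)))
    out <- as_tibble(corpus[, c("mirna_id", "sequence")])
  } else if (is.character(corpus)) {
    ids <- names(corpus) %||% paste0("mir_", seq_along(corpus))
    if (is.null(names(corpus))) {
      ids <- paste0("mir_", seq_along(corpus))
    }
    out <- tibble(mirna_id = ids, sequence = unname(corpus))
  } else {
    mirsnp_param_error("corpus must be a data frame or character vector")
  }
  if (nrow(out) == 0L) {
    mirsnp_param_error("corpus is empty")
  }
  out$sequence <- vapply(out$sequence, normalize_rna, character(1), USE.NAMES = FALSE)
  out
}
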