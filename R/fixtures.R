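# Seeded synthetic-fixture generators. All generators are pure functions of
# (parameters, seed); labelled RNG substreams keep outputs stable when new
# generators are added. Sequences are synthetic stand-ins for the real
# corpora (mirbase miRNAs, AceView 3'UTRs, dbSNP variants, array pedigrees):
# they emulate the statistical structure each stage consumes, nothing more.

#' Generate a synthetic mature-miRNA corpus
#'
#' i.i.d. uniform-base RNA sequences; an optional motif is planted at a
#' random position in a `carrier_fraction` of them (the first
#' `round(carrier_fraction * n)` sequences after seeded shuffling).
#'
#' @param n_mirnas Corpus size.
#' @param mirna_len Length range (integer vector, sampled uniformly).
#' @param planted_motif Optional RNA motif(s) to embed.
#' @param carrier_fraction Fraction of sequences carrying the motif.
#' @param seed Mandatory seed.
#' @param fasta Optional path: write the corpus as FASTA.
#' @return Tibble `mirna_id, sequence` (RNA).
#' @export
gen_mirna_corpus <- function(n_mirnas = 50L, mirna_len = 20:22,
                             planted_motif = NULL, carrier_fraction = 0,
                             seed, fasta = NULL) {
  stopifnot(!missing(seed))
  corpus <- with_substream(seed, "gen_mirna_corpus", {
    lens <- sample(rep(mirna_len, length.out = max(n_mirnas, length(mirna_len))),
                   n_mirnas, replace = TRUE)
    seqs <- vapply(lens, random_seq, character(1), bases = RNA_BASES)
    if (!is.null(planted_motif) && carrier_fraction > 0) {
      motifs <- normalize_rna(planted_motif)
      n_carriers <- round(carrier_fraction * n_mirnas)
      carriers <- sample(n_mirnas, n_carriers)
      for (i in seq_along(carriers)) {
        j <- carriers[i]
        m <- motifs[((i - 1L) %% length(motifs)) + 1L]
        k <- nchar(m)
        if (k <= lens[j]) {
          at <- sample(lens[j] - k + 1L, 1L)
          substr(seqs[j], at, at + k - 1L) <- m
        }
      }
    }
    tibble(mirna_id = sprintf("syn-miR-%03d", seq_len(n_mirnas)),
           sequence = seqs)
  })
  if (!is.null(fasta)) write_fasta(tibble(id = corpus$mirna_id,
                                          sequence = corpus$sequence), fasta)
  corpus
}

# Pick a DNA base for a UTR position facing miRNA base `m` (DNA letters)
# that forms no pair with it: excludes the Watson-Crick complement and the
# G:T wobble partner. Deterministic (first eligible of A,C,G,T).
nonpairing_base <- function(m, exclude = character(0)) {
  bad <- c(DNA_COMPLEMENT[[m]],
           if (m == "G") "T", if (m == "T") "G",
           exclude)
  setdiff(DNA_BASES, bad)[1]
}

# Flank base for a sequence position adjacent to a planted fragment of
# miRNA `mir` (DNA letters) at miRNA position `next_pos`: must differ from
# the miRNA's own base there (so patterns cannot extend across the flank
# with full support) and must not pair with the complement the target site
# carries there (so duplex alignments cannot extend either).
flank_base <- function(mir, next_pos) {
  if (next_pos < 1L || next_pos > nchar(mir)) return(NULL)
  m <- substr(mir, next_pos, next_pos)
  site_base <- DNA_COMPLEMENT[[m]]
  bad <- c(m, if (site_base == "T") "G", if (site_base == "G") "T")
  setdiff(DNA_BASES, bad)[1]
}

#' Generate SNP-bearing UTRs with planted miRNA target sites
#'
#' Each planted site is the exact DNA reverse complement of its miRNA,
#' embedded at the stated offset of the stated UTR; the SNP sits at
#' `snp_offset_within_site` with the in-sequence allele intact and the
#' disrupting allele breaking one Watson-Crick pair (auto-chosen as a
#' mismatch, neither complement nor wobble, unless given). MAF values are
#' drawn uniformly from [0.03, 0.5].
#'
#' @param corpus miRNA corpus tibble.
#' @param planted_sites Tibble with columns `mirna` (corpus row index),
#'   `utr` (UTR index), `offset` (0-based site start),
#'   `snp_offset_within_site` (0-based within the site) and optionally
#'   `disrupting_allele`.
#' @param n_utrs,utr_len UTR count and length.
#' @param seed Mandatory seed.
#' @param utr_fasta,snp_tsv Optional output paths.
#' @return A list with tibbles `utrs` (`transcript_id, gene, sequence`) and
#'   `snps` (SNP TSV schema).
#' @export
gen_snp_utrs <- function(corpus, planted_sites = NULL, n_utrs = 5L,
                         utr_len = 200L, seed, utr_fasta = NULL,
                         snp_tsv = NULL) {
  stopifnot(!missing(seed))
  out <- with_substream(seed, "gen_snp_utrs", {
    utr_seqs <- vapply(rep(utr_len, n_utrs), random_seq, character(1),
                       bases = DNA_BASES)
    ids <- sprintf("utr%02d", seq_len(n_utrs))
    snps <- list()
    if (!is.null(planted_sites) && nrow(planted_sites) > 0L) {
      for (r in seq_len(nrow(planted_sites))) {
        ps <- planted_sites[r, ]
        mir <- corpus$sequence[[ps$mirna]]
        site <- site_for_mirna(mir)
        k <- nchar(site)
        u <- ps$utr
        stopifnot(ps$offset + k <= utr_len)
        substr(utr_seqs[u], ps$offset + 1L, ps$offset + k) <- site
        so <- ps$snp_offset_within_site
        in_seq <- substr(site, so + 1L, so + 1L)
        mir_dna <- chartr("U", "T", mir)
        mir_base <- substr(mir_dna, k - so, k - so) # pairs the SNP position
        disrupting <- if ("disrupting_allele" %in% names(ps) &&
                          !is.na(ps$disrupting_allele)) {
          ps$disrupting_allele
        } else {
          nonpairing_base(mir_base, exclude = in_seq)
        }
        snps[[r]] <- tibble(
          rsid = sprintf("rs_fix_%03d", r),
          transcript_id = ids[u],
          utr_offset = as.integer(ps$offset + so),
          allele1 = in_seq, allele2 = disrupting,
          maf = round(runif(1, 0.03, 0.5), 3)
        )
      }
    } else {
      # no planted sites: SNPs at random offsets, alt allele random non-ref
      for (r in seq_len(n_utrs)) {
        off <- sample(utr_len, 1L) - 1L
        ref <- substr(utr_seqs[r], off + 1L, off + 1L)
        alt <- sample(setdiff(DNA_BASES, ref), 1L)
        snps[[r]] <- tibble(
          rsid = sprintf("rs_fix_%03d", r), transcript_id = ids[r],
          utr_offset = off, allele1 = ref, allele2 = alt,
          maf = round(runif(1, 0.03, 0.5), 3)
        )
      }
    }
    list(
      utrs = tibble(transcript_id = ids, gene = toupper(ids),
                    sequence = utr_seqs),
      snps = dplyr::bind_rows(snps)
    )
  })
  if (!is.null(utr_fasta)) {
    write_fasta(tibble(id = out$utrs$transcript_id,
                       sequence = out$utrs$sequence), utr_fasta)
  }
  if (!is.null(snp_tsv)) readr::write_tsv(out$snps, snp_tsv, progress = FALSE)
  out
}

# Tiling 7-mers of a planted miRNA: the corpus carries each tile in several
# members (a synthetic "family"), so pattern discovery recovers motifs that
# tile the planted target site densely enough for island calling.
mirna_tiles <- function(mirna, tile_offsets, tile_len = 7L) {
  vapply(tile_offsets, function(o) substr(mirna, o + 1L, o + tile_len),
         character(1))
}

#' Generate a seeded planted-MirSNP fixture
#'
#' One planted miRNA whose exact reverse complement is embedded in a UTR; a
#' SNP in the site's seed-pairing region whose alternate allele breaks one
#' Watson-Crick pair. The corpus contains the planted miRNA, a "family" of
#' carriers each bearing one 7-nt tile of it (so discovered patterns tile
#' the site), and unrelated random miRNAs. Running [run_pipeline()] with the
#' fixture's `config` names the intact allele as stronger and top-ranks the
#' planted miRNA.
#'
#' @param seed Mandatory seed.
#' @param mirna_len Planted miRNA length, default 20.
#' @param tile_offsets Tile start offsets in the planted miRNA.
#' @param carriers_per_tile Corpus members carrying each tile, default 6.
#' @param n_random Unrelated random corpus members, default 5.
#' @param utr_len,site_offset UTR length and site placement.
#' @param snp_mirna_pos 0-based miRNA position (within the seed, 1-7) whose
#'   pairing the SNP alters; default 5.
#' @return List: `corpus`, `utrs`, `snps`, `config` (a [mirsnp_config()]
#'   with `min_support = carriers_per_tile`), `truth` (planted miRNA id,
#'   intact/disrupting alleles, site interval).
#' @export
gen_mirsnp_fixture <- function(seed, mirna_len = 20L,
                               tile_offsets = c(0L, 3L, 6L, 9L, 13L),
                               carriers_per_tile = 6L, n_random = 5L,
                               utr_len = 200L, site_offset = 90L,
                               snp_mirna_pos = 5L) {
  stopifnot(!missing(seed))
  with_substream(seed, "gen_mirsnp_fixture", {
    target <- random_seq(mirna_len, RNA_BASES)
    tiles <- mirna_tiles(target, tile_offsets)
    carriers <- character(0)
    for (tl in tiles) {
      for (j in seq_len(carriers_per_tile)) {
        s <- random_seq(mirna_len, RNA_BASES)
        at <- sample(mirna_len - nchar(tl) + 1L, 1L)
        substr(s, at, at + nchar(tl) - 1L) <- tl
        carriers <- c(carriers, s)
      }
    }
    randoms <- vapply(rep(mirna_len, n_random), random_seq, character(1),
                      bases = RNA_BASES)
    corpus <- tibble(
      mirna_id = c("syn-miR-target",
                   sprintf("syn-miR-fam-%03d", seq_along(carriers)),
                   sprintf("syn-miR-rnd-%03d", seq_along(randoms))),
      sequence = c(target, carriers, randoms)
    )

    utr <- random_seq(utr_len, DNA_BASES)
    site <- site_for_mirna(target)
    substr(utr, site_offset + 1L, site_offset + mirna_len) <- site
    snp_site_offset <- mirna_len - 1L - snp_mirna_pos
    utr_offset <- site_offset + snp_site_offset
    in_seq <- substr(utr, utr_offset + 1L, utr_offset + 1L)
    mir_base <- substr(chartr("U", "T", target), snp_mirna_pos + 1L,
                       snp_mirna_pos + 1L)
    disrupting <- nonpairing_base(mir_base, exclude = in_seq)
    utrs <- tibble(transcript_id = "utr01", gene = "SYNGENE1", sequence = utr)
    snps <- tibble(rsid = "rs_fix_001", transcript_id = "utr01",
                   utr_offset = as.integer(utr_offset),
                   allele1 = in_seq, allele2 = disrupting,
                   maf = round(runif(1, 0.03, 0.5), 3))
    list(
      corpus = corpus, utrs = utrs, snps = snps,
      config = mirsnp_config(min_support = carriers_per_tile),
      truth = list(mirna_id = "syn-miR-target", intact_allele = in_seq,
                   disrupting_allele = disrupting,
                   site = c(site_offset, site_offset + mirna_len),
                   snp_offset = utr_offset)
    )
  })
}

# Cap the number of U bases in a sequence's seed region (positions 2-8,
# 1-based) so that filler sequence cannot seed-pair a poly-A stretch; excess
# U's become C's. Used by the deterministic five-SNP fixture.
cap_seed_u <- function(seq, max_u = 4L) {
  seed <- strsplit(substr(seq, 2L, 8L), "", fixed = TRUE)[[1]]
  upos <- which(seed == "U")
  if (length(upos) > max_u) {
    for (i in upos[-seq_len(max_u)]) {
      substr(seq, 1L + i, 1L + i) <- "C"
    }
  }
  seq
}

# Embed a tile in a fresh carrier with extension-breaking flanks (see
# flank_base); used by the deterministic five-SNP fixture.
make_carrier <- function(tile_rna, mir_rna, tile_start0, at0, len = 20L) {
  s <- random_seq(len, RNA_BASES)
  k <- nchar(tile_rna)
  substr(s, at0 + 1L, at0 + k) <- tile_rna
  mir_dna <- chartr("U", "T", mir_rna)
  lf <- flank_base(mir_dna, tile_start0)       # miRNA base before the tile
  rf <- flank_base(mir_dna, tile_start0 + k + 1L) # miRNA base after the tile
  if (!is.null(lf) && at0 >= 1L) substr(s, at0, at0) <- chartr("T", "U", lf)
  if (!is.null(rf) && at0 + k < len) {
    substr(s, at0 + k + 1L, at0 + k + 1L) <- chartr("T", "U", rf)
  }
  s
}

#' The deterministic five-SNP demonstration fixture
#'
#' A constructed corpus/UTR/SNP set whose pipeline output has the shape of a
#' five-MirSNP report: three SNPs where one allele ablates pairing of a
#' planted target site (verdicts `stronger:A`, `stronger:C`, `stronger:C`),
#' one SNP inside a planted site at a position where both alleles mismatch
#' the miRNA equally (verdict `equal`), and one SNP inside a decoy pattern
#' island assembled from fragments of a miRNA absent from the corpus, where
#' no miRNA yields a qualifying alignment (verdict `island_no_alignment`).
#'
#' The decoy island is a single 7-nt region matched by five distinct planted
#' patterns (nested fragments of a 7-mer absent as a full site from any
#' corpus miRNA's seed-compatible register, each with its own carrier set so
#' all five stay maximal). An island that short is padded to the aligner's
#' 8-nt minimum, so no alignment can reach both the 40-score threshold
#' (which would need 8 Watson-Crick pairs) and 6 seed pairs inside it:
#' the island-without-alignment verdict holds by construction. All
#' sequences are synthetic; rsids/genes are illustrative labels.
#'
#' @return List: `corpus`, `utrs`, `snps`, `config`, `truth` (expected
#'   verdict per rsid).
#' @export
gen_five_mirsnp_fixture <- function() {
  target <- "CGAGCUACUGACAUCGUAGC" # fixed: pos1=G, pos3=G, pos5=U, pos12=A
  decoy7 <- "ACGGUCA"              # fixed 7-mer; position 3 = G
  k <- nchar(target)
  tile_offsets <- c(0L, 1L, 2L, 3L, 8L, 10L, 12L, 13L)
  carriers_per_tile <- 6L

  with_substream(20090101L, "gen_five_mirsnp_fixture", {
    carriers <- character(0)
    tiles <- mirna_tiles(target, tile_offsets)
    for (t in seq_along(tiles)) {
      for (j in seq_len(carriers_per_tile)) {
        # tiles sit in the carrier 3' half so a carrier's own seed region
        # (positions 2-8) cannot pair a planted fragment
        at0 <- 9L + ((t + j) %% 4L)
        carriers <- c(carriers,
                      make_carrier(tiles[t], target, tile_offsets[t], at0, 21L))
      }
    }
    # nested decoy fragments: distinct supports keep each fragment maximal,
    # and all five match inside the same 7-nt target region
    dfrags <- c(decoy7,                 # ACGGUCA
                substr(decoy7, 1L, 6L), # ACGGUC
                substr(decoy7, 2L, 7L), # CGGUCA
                substr(decoy7, 1L, 5L), # ACGGU
                substr(decoy7, 3L, 7L)) # GGUCA
    for (t in seq_along(dfrags)) {
      for (j in seq_len(carriers_per_tile)) {
        s <- random_seq(21L, RNA_BASES)
        at0 <- 9L + ((t + j) %% 4L)
        kf <- nchar(dfrags[t])
        substr(s, at0 + 1L, at0 + kf) <- dfrags[t]
        carriers <- c(carriers, s)
      }
    }
    carriers <- vapply(carriers, cap_seed_u, character(1), USE.NAMES = FALSE)
    randoms <- vapply(rep(21L, 8L), random_seq, character(1),
                      bases = RNA_BASES)
    randoms <- vapply(randoms, cap_seed_u, character(1), USE.NAMES = FALSE)
    corpus <- tibble(
      mirna_id = c("syn-miR-616",
                   sprintf("syn-miR-fam-%03d", seq_along(carriers)),
                   sprintf("syn-miR-rnd-%03d", seq_along(randoms))),
      sequence = c(target, carriers, randoms)
    )

    # five UTRs; sites at offset 60 of 150-nt UTRs
    site_offset <- 60L
    utr_ids <- sprintf("utr%02d", 1:5)
    genes <- c("SYN-H3F3B", "SYN-BAIAP2", "SYN-LOC2839", "SYN-CHMP6",
               "SYN-TBC1D16")
    utr_seqs <- vapply(rep(150L, 5L), random_seq, character(1),
                       bases = DNA_BASES)
    site_t <- site_for_mirna(target)
    site_d <- site_for_mirna(decoy7) # "TGACCGT"

    put_site <- function(seq, site) {
      substr(seq, site_offset + 1L, site_offset + k) <- site
      seq
    }
    # SNP descriptor: miRNA position p -> site offset k-1-p
    snp_at <- function(rsid, utr, p, allele1, allele2) {
      tibble(rsid = rsid, transcript_id = utr,
             utr_offset = as.integer(site_offset + k - 1L - p),
             allele1 = allele1, allele2 = allele2, maf = 0.2)
    }

    # rs1060120-like: equal — both alleles mismatch target pos 12 (A)
    u1 <- put_site(utr_seqs[1], site_t)
    substr(u1, site_offset + k - 12L, site_offset + k - 12L) <- "A"
    # rs4969391-like: stronger A — intact A pairs U at pos 5; alt G wobbles
    u2 <- put_site(utr_seqs[2], site_t)
    # rs7211218-like: stronger C — intact C pairs G at pos 3; alt A mismatches
    u3 <- put_site(utr_seqs[3], site_t)
    # rs1128687-like: stronger C — intact C pairs G at pos 1; alt T wobbles
    u4 <- put_site(utr_seqs[4], site_t)
    # rs1663196-like: island without alignment — the 7-nt decoy region,
    # matched by five planted fragment patterns but by no full-length miRNA.
    # A poly-A moat (>= 25 nt each side) keeps the island from merging with
    # hits elsewhere and offers no pairing partners beyond the 7-mer itself.
    u5 <- utr_seqs[5]
    substr(u5, 36L, 95L) <- strrep("A", 60L)
    substr(u5, site_offset + 2L, site_offset + 1L + nchar(site_d)) <- site_d

    utrs <- tibble(transcript_id = utr_ids, gene = genes,
                   sequence = c(u1, u2, u3, u4, u5))
    snps <- dplyr::bind_rows(
      snp_at("rs1060120", "utr01", 12L, "A", "G"),
      snp_at("rs4969391", "utr02", 5L, "A", "G"),
      snp_at("rs7211218", "utr03", 3L, "C", "A"),
      snp_at("rs1128687", "utr04", 1L, "C", "T"),
      # decoy site offset 3 holds "C" (= site_d[4]); the alt T kills the
      # fragment hits, leaving the island only in the in-sequence context
      tibble(rsid = "rs1663196", transcript_id = "utr05",
             utr_offset = as.integer(site_offset + 4L),
             allele1 = "C", allele2 = "T", maf = 0.2)
    )
    list(
      corpus = corpus, utrs = utrs, snps = snps,
      config = mirsnp_config(min_support = carriers_per_tile),
      truth = tibble(
        rsid = c("rs1060120", "rs4969391", "rs7211218", "rs1128687",
                 "rs1663196"),
        verdict = c("equal", "stronger:A", "stronger:C", "stronger:C",
                    "island_no_alignment")
      )
    )
  })
}

#' Generate a synthetic pedigree with injected Mendelian errors
#'
#' Nuclear families (two founders, `n_children` children). Founder
#' genotypes are drawn from Hardy-Weinberg proportions with per-SNP allele
#' frequencies; children by Mendelian transmission. Child genotypes are then
#' flipped to Mendelian-inconsistent values at `mendel_error_rate` (per
#' child-SNP; trios whose parental pair admits every genotype, e.g. AB x AB,
#' are skipped) and genotypes masked to missing at `missing_rate`. The
#' injected-error ground truth is returned alongside.
#'
#' @param n_families,n_children Pedigree shape.
#' @param n_snps Number of biallelic SNPs (alleles A/B).
#' @param mendel_error_rate,missing_rate Injection rates in [0, 1].
#' @param seed Mandatory seed.
#' @param ped_path Optional path: write as PED.
#' @return List: `pedigree` (a `pedigree_genotypes`), `truth` (tibble
#'   `snp_id, family_id, child_id, original, injected`), `allele_freq`.
#' @export
gen_pedigree <- function(n_families = 30L, n_children = 2L, n_snps = 20L,
                         mendel_error_rate = 0, missing_rate = 0, seed,
                         ped_path = NULL) {
  stopifnot(!missing(seed))
  out <- with_substream(seed, "gen_pedigree", {
    snp_ids <- sprintf("SNP%03d", seq_len(n_snps))
    freq <- setNames(round(runif(n_snps, 0.2, 0.8), 3), snp_ids)
    ind <- list(); gen <- list(); truth <- list()
    draw_allele <- function(p) ifelse(runif(1) < p, "A", "B")
    for (f in seq_len(n_families)) {
      fam <- sprintf("F%03d", f)
      fid <- sprintf("%s-father", fam)
      mid <- sprintf("%s-mother", fam)
      kids <- sprintf("%s-child%d", fam, seq_len(n_children))
      ind[[f]] <- tibble(
        family_id = fam,
        individual_id = c(fid, mid, kids),
        father_id = c("0", "0", rep(fid, n_children)),
        mother_id = c("0", "0", rep(mid, n_children)),
        sex = c("1", "2", rep("0", n_children))
      )
      for (s in snp_ids) {
        p <- freq[[s]]
        fg <- sort(c(draw_allele(p), draw_allele(p)))
        mg <- sort(c(draw_allele(p), draw_allele(p)))
        rows <- list(tibble(individual_id = fid, snp_id = s,
                            a1 = fg[1], a2 = fg[2]),
                     tibble(individual_id = mid, snp_id = s,
                            a1 = mg[1], a2 = mg[2]))
        for (kk in seq_along(kids)) {
          cg <- sort(c(sample(fg, 1L), sample(mg, 1L)))
          if (mendel_error_rate > 0 && runif(1) < mendel_error_rate) {
            possible <- unique(vapply(
              seq_len(4L),
              function(i) paste(sort(c(fg[(i - 1L) %/% 2L + 1L],
                                       mg[(i - 1L) %% 2L + 1L])),
                                collapse = ""),
              character(1)
            ))
            all_gt <- c("AA", "AB", "BB")
            bad <- setdiff(all_gt, possible)
            if (length(bad) > 0L) {
              inj <- bad[sample.int(length(bad), 1L)]
              truth[[length(truth) + 1L]] <- tibble(
                snp_id = s, family_id = fam, child_id = kids[kk],
                original = paste(cg, collapse = ""), injected = inj
              )
              cg <- strsplit(inj, "", fixed = TRUE)[[1]]
            }
          }
          rows[[length(rows) + 1L]] <- tibble(individual_id = kids[kk],
                                              snp_id = s, a1 = cg[1],
                                              a2 = cg[2])
        }
        gen[[length(gen) + 1L]] <- dplyr::bind_rows(rows)
      }
    }
    genotypes <- dplyr::bind_rows(gen)
    if (missing_rate > 0) {
      mask <- runif(nrow(genotypes)) < missing_rate
      genotypes$a1[mask] <- NA_character_
      genotypes$a2[mask] <- NA_character_
    }
    list(
      pedigree = new_pedigree(dplyr::bind_rows(ind), genotypes),
      truth = if (length(truth) > 0L) dplyr::bind_rows(truth) else
        tibble(snp_id = character(), family_id = character(),
               child_id = character(), original = character(),
               injected = character()),
      allele_freq = freq
    )
  })
  if (!is.null(ped_path)) write_ped(out$pedigree, ped_path)
  out
}
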