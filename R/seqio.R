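#' Normalize an RNA sequence
#'
#' Uppercases and maps T to U. Idempotent and length-preserving. Any
#' character outside `{A,C,G,T,U}` (case-insensitive) is an error.
#'
#' @param seq Character vector of sequences.
#' @return Character vector of normalized RNA sequences over `{A,C,G,U}`.
#' @examples
#' normalize_rna("acgt") # "ACGU"
#' @export
normalize_rna <- function(seq) {
  out <- chartr("T", "U", toupper(seq))
  bad <- stringi::stri_detect_regex(out, "[^ACGU]")
  if (any(bad, na.rm = TRUE)) {
    mirsnp_input_error(
      sprintf(
        "illegal character in RNA sequence: %s",
        paste(utils::head(seq[which(bad)], 3), collapse = ", ")
      ),
      class = "mirsnp_alphabet_error"
    )
  }
  out
}

#' Normalize a DNA sequence
#'
#' Uppercases and maps U to T. `N` is tolerated (it never matches a pattern
#' literal downstream); other characters are an error.
#'
#' @param seq Character vector of sequences.
#' @return Character vector over `{A,C,G,T,N}`.
#' @export
normalize_dna <- function(seq) {
  out <- chartr("U", "T", toupper(seq))
  bad <- stringi::stri_detect_regex(out, "[^ACGTN]")
  if (any(bad, na.rm = TRUE)) {
    mirsnp_input_error(
      sprintf(
        "illegal character in DNA sequence: %s",
        paste(utils::head(seq[which(bad)], 3), collapse = ", ")
      ),
      class = "mirsnp_alphabet_error"
    )
  }
  out
}

#' Read a FASTA file into a tibble
#'
#' Sequences are uppercased; with `alphabet = "rna"` T is mapped to U (and
#' the strict `{A,C,G,U}` alphabet enforced), with `alphabet = "dna"` U is
#' mapped to T and `N` is tolerated. Record order is preserved. Duplicate
#' IDs are kept, with a warning.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"dna"` or `"rna"`.
#' @return A tibble with columns `id`, `sequence`.
#' @export
read_fasta <- function(path, alphabet = c("dna", "rna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) {
    mirsnp_input_error(sprintf("FASTA file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) == 0L) {
    return(tibble(id = character(), sequence = character()))
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    mirsnp_input_error(
      sprintf("malformed FASTA: sequence before header at line %d of %s",
              nonblank[1], path),
      class = "mirsnp_parse_error"
    )
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  if (anyDuplicated(ids)) {
    warn(sprintf(
      "duplicate FASTA ids in %s: %s", path,
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  seqs <- tryCatch(
    if (alphabet == "rna") normalize_rna(seqs) else normalize_dna(seqs),
    mirsnp_alphabet_error = function(e) {
      bad <- if (alphabet == "rna") {
        stringi::stri_detect_regex(chartr("T", "U", toupper(seqs)), "[^ACGU]")
      } else {
        stringi::stri_detect_regex(chartr("U", "T", toupper(seqs)), "[^ACGTN]")
      }
      mirsnp_input_error(
        sprintf("illegal character after normalization in record(s): %s",
                paste(ids[which(bad)], collapse = ", ")),
        class = "mirsnp_alphabet_error"
      )
    }
  )
  tibble(id = unname(ids), sequence = unname(seqs))
}

#' Write sequences to FASTA
#'
#' @param x A tibble with columns `id` and `sequence` (or the first two
#'   columns are used), e.g. the output of [read_fasta()] or
#'   [gen_mirna_corpus()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(x, path) {
  stopifnot(is.data.frame(x))
  id_col <- if ("id" %in% names(x)) "id" else names(x)[1]
  seq_col <- if ("sequence" %in% names(x)) "sequence" else names(x)[2]
  set <- Biostrings::BStringSet(setNames(x[[seq_col]], x[[id_col]]))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a SNP table and apply the minor-allele-frequency filter
#'
#' The primary format is a 6-column TSV with header
#' `rsid, transcript_id, utr_offset, allele1, allele2, maf`, where
#' `utr_offset` is the 0-based position of the SNP in its host 3'UTR
#' sequence. A VCF can be supplied instead together with a transcript
#' `mapping` (columns `transcript_id`, `chrom`, `utr_start` giving the
#' 1-based genomic position of UTR offset 0, plus-strand); 1-based VCF `POS`
#' is converted to the 0-based UTR offset at this boundary only.
#'
#' Only biallelic single-base records with `maf >= maf_min` are retained
#' (the threshold is inclusive). Records whose offset falls outside the host
#' UTR (when `utrs` is supplied) are skipped with a warning, as are records
#' where neither allele matches the in-sequence base.
#'
#' @param path Path to the SNP table.
#' @param format `"tsv"` or `"vcf"`.
#' @param maf_min Minimum minor allele frequency (inclusive), default 0.03.
#' @param utrs Optional UTR tibble (`transcript_id`, `sequence`) used to
#'   validate offsets and in-sequence alleles.
#' @param mapping Transcript mapping tibble, required for `format = "vcf"`.
#' @return A tibble with columns `rsid`, `transcript_id`, `utr_offset`,
#'   `allele1`, `allele2`, `maf`.
#' @export
read_snp_table <- function(path, format = c("tsv", "vcf"), maf_min = 0.03,
                           utrs = NULL, mapping = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    snps <- readr::read_tsv(
      path, show_col_types = FALSE, progress = FALSE,
      col_types = readr::cols(
        rsid = readr::col_character(),
        transcript_id = readr::col_character(),
        utr_offset = readr::col_integer(),
        allele1 = readr::col_character(),
        allele2 = readr::col_character(),
        maf = readr::col_double()
      )
    )
    need <- c("rsid", "transcript_id", "utr_offset", "allele1", "allele2", "maf")
    if (!all(need %in% names(snps))) {
      mirsnp_input_error(sprintf(
        "SNP TSV must have columns: %s", paste(need, collapse = ", ")
      ))
    }
    snps <- dplyr::select(snps, dplyr::all_of(need))
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      mirsnp_input_error("reading VCF requires the vcfR package")
    }
    if (is.null(mapping)) {
      mirsnp_param_error("format = 'vcf' requires a transcript `mapping`")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    info <- vcfR::getINFO(v)
    maf <- suppressWarnings(as.numeric(
      stringi::stri_match_first_regex(info, "(?:^|;)(?:MAF|AF)=([0-9.eE+-]+)")[, 2]
    ))
    snps <- tibble(
      rsid = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
      allele1 = fix$REF, allele2 = fix$ALT, maf = maf
    )
    snps <- dplyr::inner_join(snps, as_tibble(mapping), by = "chrom")
    snps <- dplyr::mutate(snps, utr_offset = .data$pos - .data$utr_start)
    snps <- dplyr::select(
      snps, "rsid", "transcript_id", "utr_offset", "allele1", "allele2", "maf"
    )
  }
  snps <- as_tibble(snps)
  n0 <- nrow(snps)

  multi <- nchar(snps$allele1) != 1L | nchar(snps$allele2) != 1L |
    stringi::stri_detect_fixed(snps$allele2, ",") |
    snps$allele1 == snps$allele2
  if (any(multi)) {
    warn(sprintf("skipping %d non-biallelic SNP record(s): %s", sum(multi),
                 paste(utils::head(snps$rsid[multi], 5), collapse = ", ")))
    snps <- snps[!multi, , drop = FALSE]
  }

  if (!is.null(utrs)) {
    utr_len <- setNames(nchar(utrs$sequence), utrs$transcript_id)
    len <- utr_len[snps$transcript_id]
    out_of_range <- is.na(len) | snps$utr_offset < 0L | snps$utr_offset >= len
    if (any(out_of_range)) {
      warn(sprintf("skipping %d SNP(s) with offset outside host UTR: %s",
                   sum(out_of_range),
                   paste(utils::head(snps$rsid[out_of_range], 5), collapse = ", ")))
      snps <- snps[!out_of_range, , drop = FALSE]
    }
    if (nrow(snps) > 0L) {
      base <- substr(
        setNames(utrs$sequence, utrs$transcript_id)[snps$transcript_id],
        snps$utr_offset + 1L, snps$utr_offset + 1L
      )
      mismatch <- base != snps$allele1 & base != snps$allele2
      if (any(mismatch)) {
        warn(sprintf(
          "skipping %d SNP(s) where neither allele matches the UTR base: %s",
          sum(mismatch),
          paste(utils::head(snps$rsid[mismatch], 5), collapse = ", ")
        ))
        snps <- snps[!mismatch, , drop = FALSE]
      }
    }
  }

  keep <- !is.na(snps$maf) & snps$maf >= maf_min
  inform(sprintf("SNP MAF filter (maf >= %g): %d of %d retained, %d dropped",
                 maf_min, sum(keep), n0, nrow(snps) - sum(keep)))
  snps[keep, , drop = FALSE]
}

#' Write the per-SNP MirSNP report
#'
#' Tab-separated, one row per call, deterministic row order (by `rsid`),
#' with header `rsid, gene, alleles, mirnas, allele_scores, verdict`.
#'
#' @param calls A tibble of MirSNP calls ([predict_mirsnp()] rows or
#'   [run_pipeline()] output).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mirsnp_report <- function(calls, path) {
  cols <- c("rsid", "gene", "alleles", "mirnas", "allele_scores", "verdict")
  if (nrow(calls) == 0L) {
    out <- tibble(
      rsid = character(), gene = character(), alleles = character(),
      mirnas = character(), allele_scores = character(), verdict = character()
    )
  } else {
    out <- calls[order(calls$rsid, method = "radix"), cols]
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a PED-style pedigree + genotype file
#'
#' Whitespace-separated, five leading columns (`family_id`, `individual_id`,
#' `father_id`, `mother_id`, `sex`) followed by two allele columns per SNP,
#' `0` meaning missing. Parent id `0` marks a founder.
#'
#' @param path Path to the PED file.
#' @param snp_ids Optional character vector of SNP ids (defaults to
#'   `SNP1..SNPk`).
#' @return A `pedigree_genotypes` object: a list with tibbles `individuals`
#'   (`family_id`, `individual_id`, `father_id`, `mother_id`, `sex`) and
#'   `genotypes` (`individual_id`, `snp_id`, `a1`, `a2`; `NA` = missing).
#' @export
read_ped <- function(path, snp_ids = NULL) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 5L || (ncol(raw) - 5L) %% 2L != 0L) {
    mirsnp_input_error(
      "PED file must have 5 leading columns plus two allele columns per SNP",
      class = "mirsnp_parse_error"
    )
  }
  k <- (ncol(raw) - 5L) %/% 2L
  if (is.null(snp_ids)) snp_ids <- paste0("SNP", seq_len(k))
  if (length(snp_ids) != k) {
    mirsnp_param_error("length(snp_ids) does not match the number of SNPs in the PED file")
  }
  individuals <- tibble(
    family_id = raw[[1]], individual_id = raw[[2]],
    father_id = raw[[3]], mother_id = raw[[4]], sex = raw[[5]]
  )
  geno_list <- vector("list", k)
  for (j in seq_len(k)) {
    a1 <- raw[[5L + 2L * j - 1L]]
    a2 <- raw[[5L + 2L * j]]
    a1[a1 == "0"] <- NA_character_
    a2[a2 == "0"] <- NA_character_
    # half-missing genotypes are treated as missing
    miss <- is.na(a1) | is.na(a2)
    a1[miss] <- NA_character_
    a2[miss] <- NA_character_
    geno_list[[j]] <- tibble(
      individual_id = individuals$individual_id,
      snp_id = snp_ids[j], a1 = a1, a2 = a2
    )
  }
  new_pedigree(individuals, dplyr::bind_rows(geno_list))
}

#' Construct a pedigree_genotypes object
#'
#' Validates that every non-founder parent id resolves to an individual in
#' the same family.
#'
#' @param individuals Tibble with `family_id`, `individual_id`, `father_id`,
#'   `mother_id`, and optionally `sex`.
#' @param genotypes Long tibble with `individual_id`, `snp_id`, `a1`, `a2`.
#' @return A `pedigree_genotypes` object.
#' @export
new_pedigree <- function(individuals, genotypes) {
  individuals <- as_tibble(individuals)
  if (!"sex" %in% names(individuals)) individuals$sex <- "0"
  genotypes <- as_tibble(genotypes)
  key <- paste(individuals$family_id, individuals$individual_id)
  for (col in c("father_id", "mother_id")) {
    p <- individuals[[col]]
    unresolved <- !is.na(p) & p != "0" &
      !(paste(individuals$family_id, p) %in% key)
    if (any(unresolved)) {
      mirsnp_input_error(sprintf(
        "unresolvable %s for individual(s): %s", col,
        paste(utils::head(individuals$individual_id[unresolved], 5), collapse = ", ")
      ), class = "mirsnp_pedigree_error")
    }
  }
  structure(list(individuals = individuals, genotypes = genotypes),
            class = "pedigree_genotypes")
}

#' @export
print.pedigree_genotypes <- function(x, ...) {
  n_snp <- length(unique(x$genotypes$snp_id))
  cat(sprintf("<pedigree_genotypes> %d individuals in %d families, %d SNPs\n",
              nrow(x$individuals), length(unique(x$individuals$family_id)),
              n_snp))
  invisible(x)
}

#' Write a pedigree_genotypes object to a PED-style file
#'
#' @param ped A `pedigree_genotypes` object.
#' @param path Output path.
#' @param snp_ids SNP order for the allele columns (default: sorted unique
#'   SNP ids in the genotype table).
#' @return Invisibly, `path`.
#' @export
write_ped <- function(ped, path, snp_ids = NULL) {
  stopifnot(inherits(ped, "pedigree_genotypes"))
  if (is.null(snp_ids)) {
    snp_ids <- sort(unique(ped$genotypes$snp_id), method = "radix")
  }
  g <- ped$genotypes
  g$a1[is.na(g$a1)] <- "0"
  g$a2[is.na(g$a2)] <- "0"
  wide <- tidyr::pivot_wider(
    g, id_cols = "individual_id", names_from = "snp_id",
    values_from = c("a1", "a2"), names_glue = "{snp_id}__{.value}"
  )
  ord <- as.vector(rbind(paste0(snp_ids, "__a1"), paste0(snp_ids, "__a2")))
  ind <- ped$individuals
  out <- dplyr::left_join(ind, wide, by = "individual_id")
  m <- as.matrix(out[, ord, drop = FALSE])
  m[is.na(m)] <- "0"
  lines <- paste(
    out$family_id, out$individual_id, out$father_id, out$mother_id, out$sex,
    apply(m, 1L, paste, collapse = " ")
  )
  writeLines(lines, path)
  invisible(path)
}
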