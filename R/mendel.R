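# Pedigree genotype cleaning: per-SNP completion / monomorphism /
# Mendelian-error-rate / Hardy-Weinberg filters, and identification +
# removal of trio genotypes causing Mendelian errors.

#' QC thresholds for the genotype-cleaning stage
#'
#' @param min_completion Minimum per-SNP completion rate, default 0.98
#'   (SNPs with completion < 0.98 are dropped).
#' @param mendel_error_rate_max Maximum tolerated per-SNP Mendelian error
#'   rate (error trios / genotyped trios), default 0.01 (SNPs with a rate
#'   > 0.01 are dropped).
#' @param hwe_p_min Minimum exact Hardy-Weinberg p-value among founders,
#'   default 0.001 (SNPs with p <= 0.001 are dropped).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_completion = 0.98, mendel_error_rate_max = 0.01,
                          hwe_p_min = 0.001) {
  vals <- c(min_completion, mendel_error_rate_max, hwe_p_min)
  if (any(vals <= 0 | vals >= 1)) {
    mirsnp_param_error("all QC thresholds must lie in (0, 1)")
  }
  structure(list(min_completion = min_completion,
                 mendel_error_rate_max = mendel_error_rate_max,
                 hwe_p_min = hwe_p_min),
            class = "qc_thresholds")
}

snp_genotypes <- function(ped, snp_id) {
  g <- ped$genotypes
  g[g$snp_id == snp_id, , drop = FALSE]
}

#' Per-SNP genotype completion rate
#'
#' @param geno Genotype tibble for one SNP (`a1`, `a2`; `NA` = missing).
#' @return Fraction of non-missing genotypes.
#' @export
completion_rate <- function(geno) {
  if (nrow(geno) == 0L) mirsnp_param_error("no genotypes")
  mean(!is.na(geno$a1) & !is.na(geno$a2))
}

#' Is a SNP monomorphic?
#'
#' TRUE iff at most one distinct allele is observed among non-missing
#' genotypes (an all-missing SNP is monomorphic by this definition).
#'
#' @param geno Genotype tibble for one SNP (`a1`, `a2`).
#' @return Logical.
#' @export
is_monomorphic <- function(geno) {
  alleles <- unique(c(geno$a1, geno$a2))
  length(alleles[!is.na(alleles)]) <= 1L
}

# Is the (child, father, mother) genotype combination Mendelian-consistent?
# A missing parent may transmit any allele of the SNP's allele universe; a
# missing child genotype is never an error.
trio_consistent <- function(child, father, mother, allele_universe) {
  if (any(is.na(child))) return(TRUE)
  f <- if (any(is.na(father))) allele_universe else father
  m <- if (any(is.na(mother))) allele_universe else mother
  for (fa in unique(f)) {
    for (ma in unique(m)) {
      if (identical(sort(c(fa, ma)), sort(child))) return(TRUE)
    }
  }
  FALSE
}

#' Find trio genotype combinations causing Mendelian errors
#'
#' Every child-father-mother trio (children with at least one genotyped,
#' resolvable parent; single-parent trios use single-parent rules, the
#' missing parent being allowed to transmit any allele) whose genotypes are
#' jointly impossible under biallelic autosomal inheritance is reported.
#'
#' @param ped A `pedigree_genotypes` object.
#' @param snp_id SNP id(s) to scan; default all SNPs in the pedigree.
#' @return A tibble `snp_id, family_id, child_id, father_id, mother_id,
#'   child_gt, father_gt, mother_gt` (genotypes as `"A/B"`, `NA` when
#'   missing).
#' @export
find_mendel_errors <- function(ped, snp_id = NULL) {
  stopifnot(inherits(ped, "pedigree_genotypes"))
  ind <- ped$individuals
  if (is.null(snp_id)) {
    snp_id <- sort(unique(ped$genotypes$snp_id), method = "radix")
  }
  children <- ind[(!is.na(ind$father_id) & ind$father_id != "0") |
                    (!is.na(ind$mother_id) & ind$mother_id != "0"), ,
                  drop = FALSE]
  out <- list()
  fmt <- function(a1, a2) {
    ifelse(is.na(a1), NA_character_, paste0(pmin(a1, a2), "/", pmax(a1, a2)))
  }
  for (s in snp_id) {
    g <- snp_genotypes(ped, s)
    gmap1 <- setNames(g$a1, g$individual_id)
    gmap2 <- setNames(g$a2, g$individual_id)
    universe <- sort(unique(c(g$a1, g$a2)))
    universe <- universe[!is.na(universe)]
    if (length(universe) == 0L) next
    for (r in seq_len(nrow(children))) {
      cid <- children$individual_id[r]
      fid <- children$father_id[r]
      mid <- children$mother_id[r]
      child <- c(gmap1[cid], gmap2[cid])
      father <- if (is.na(fid) || fid == "0") c(NA, NA) else c(gmap1[fid], gmap2[fid])
      mother <- if (is.na(mid) || mid == "0") c(NA, NA) else c(gmap1[mid], gmap2[mid])
      if (!trio_consistent(unname(child), unname(father), unname(mother), universe)) {
        out[[length(out) + 1L]] <- tibble(
          snp_id = s, family_id = children$family_id[r], child_id = cid,
          father_id = fid, mother_id = mid,
          child_gt = fmt(child[1], child[2]),
          father_gt = fmt(father[1], father[2]),
          mother_gt = fmt(mother[1], mother[2])
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble(snp_id = character(), family_id = character(),
                  child_id = character(), father_id = character(),
                  mother_id = character(), child_gt = character(),
                  father_gt = character(), mother_gt = character()))
  }
  dplyr::bind_rows(out)
}

#' Remove genotypes causing Mendelian errors
#'
#' For each error trio, sets the member genotypes at that SNP to missing.
#' The default policy blanks all three trio members (child, father, mother);
#' `policy = "child"` blanks only the child. Re-running
#' [find_mendel_errors()] on the result returns no errors for the default
#' policy; the operation is idempotent.
#'
#' @param ped A `pedigree_genotypes` object.
#' @param errors Error tibble from [find_mendel_errors()] on this pedigree.
#' @param policy `"trio"` (default) or `"child"`.
#' @return A list: `pedigree` (cleaned), `n_removed` (genotypes set to
#'   missing, counting each previously non-missing genotype once).
#' @export
remove_error_genotypes <- function(ped, errors, policy = c("trio", "child")) {
  policy <- match.arg(policy)
  stopifnot(inherits(ped, "pedigree_genotypes"))
  g <- ped$genotypes
  if (nrow(errors) == 0L) {
    return(list(pedigree = ped, n_removed = 0L))
  }
  targets <- if (policy == "trio") {
    dplyr::bind_rows(
      tibble(snp_id = errors$snp_id, individual_id = errors$child_id),
      tibble(snp_id = errors$snp_id, individual_id = errors$father_id),
      tibble(snp_id = errors$snp_id, individual_id = errors$mother_id)
    )
  } else {
    tibble(snp_id = errors$snp_id, individual_id = errors$child_id)
  }
  targets <- dplyr::distinct(targets[!is.na(targets$individual_id) &
                                       targets$individual_id != "0", ])
  key_g <- paste(g$snp_id, g$individual_id)
  key_t <- paste(targets$snp_id, targets$individual_id)
  hit <- key_g %in% key_t
  n_removed <- sum(hit & !is.na(g$a1))
  g$a1[hit] <- NA_character_
  g$a2[hit] <- NA_character_
  list(pedigree = new_pedigree(ped$individuals, g),
       n_removed = as.integer(n_removed))
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditional on the allele counts: the p-value sums
#' the probabilities of all heterozygote counts whose conditional
#' probability does not exceed that of the observed table.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (typically among founders).
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) {
    mirsnp_param_error("genotype counts must be non-negative")
  }
  n <- n_aa + n_ab + n_bb
  if (n == 0L) return(1)
  na <- 2L * n_aa + n_ab # count of the A allele
  # possible heterozygote counts share the parity of na
  hets <- seq.int(na %% 2L, min(na, 2L * n - na), by = 2L)
  logp <- vapply(hets, function(h) {
    aa <- (na - h) %/% 2L
    bb <- n - aa - h
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2) + lfactorial(na) + lfactorial(2L * n - na) -
      lfactorial(2L * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_ab, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

founder_ids <- function(ped) {
  ind <- ped$individuals
  ind$individual_id[(is.na(ind$father_id) | ind$father_id == "0") &
                      (is.na(ind$mother_id) | ind$mother_id == "0")]
}

# Count genotyped child-father-mother trios for one SNP (child genotype
# non-missing and at least one resolvable parent).
genotyped_trios <- function(ped, snp_id) {
  ind <- ped$individuals
  g <- snp_genotypes(ped, snp_id)
  called <- setNames(!is.na(g$a1), g$individual_id)
  children <- ind[(!is.na(ind$father_id) & ind$father_id != "0") |
                    (!is.na(ind$mother_id) & ind$mother_id != "0"), ,
                  drop = FALSE]
  sum(called[children$individual_id], na.rm = TRUE)
}

#' Run the full genotype-cleaning pipeline
#'
#' Filters are applied in order: completion rate, monomorphism, Mendelian
#' error rate, exact Hardy-Weinberg (founders only); genotype-level
#' Mendelian-error removal is then applied to the surviving SNPs.
#'
#' @param ped A `pedigree_genotypes` object.
#' @param thresholds A [qc_thresholds()] object.
#' @param removal_policy Passed to [remove_error_genotypes()].
#' @return A `mirsnp_qc` object: list with `snp_summary` (per-SNP tibble:
#'   `snp_id, completion, monomorphic, mendel_rate, hwe_p, action`),
#'   `kept_snps`, `drop_counts` (per-filter), `n_genotypes_removed`,
#'   `cleaned` (cleaned `pedigree_genotypes` restricted to kept SNPs), and
#'   `final_completion`.
#' @export
qc_pipeline <- function(ped, thresholds = qc_thresholds(),
                        removal_policy = c("trio", "child")) {
  removal_policy <- match.arg(removal_policy)
  stopifnot(inherits(ped, "pedigree_genotypes"))
  snp_ids <- sort(unique(ped$genotypes$snp_id), method = "radix")
  founders <- founder_ids(ped)

  rows <- purrr::map(snp_ids, function(s) {
    g <- snp_genotypes(ped, s)
    comp <- completion_rate(g)
    mono <- is_monomorphic(g)
    action <- NA_character_
    mendel_rate <- NA_real_
    hwe_p <- NA_real_
    if (comp < thresholds$min_completion) {
      action <- "drop:completion"
    } else if (mono) {
      action <- "drop:monomorphic"
    } else {
      n_err <- nrow(find_mendel_errors(ped, s))
      n_trio <- genotyped_trios(ped, s)
      mendel_rate <- if (n_trio > 0L) n_err / n_trio else 0
      if (mendel_rate > thresholds$mendel_error_rate_max) {
        action <- "drop:mendel"
      } else {
        gf <- g[g$individual_id %in% founders & !is.na(g$a1), , drop = FALSE]
        alleles <- sort(unique(c(gf$a1, gf$a2)))
        if (length(alleles) <= 1L) {
          hwe_p <- 1
        } else {
          a <- alleles[1L]
          n_aa <- sum(gf$a1 == a & gf$a2 == a)
          n_ab <- sum((gf$a1 == a) != (gf$a2 == a))
          n_bb <- sum(gf$a1 != a & gf$a2 != a)
          hwe_p <- hwe_exact_p(n_aa, n_ab, n_bb)
        }
        action <- if (hwe_p <= thresholds$hwe_p_min) "drop:hwe" else "keep"
      }
    }
    tibble(snp_id = s, completion = comp, monomorphic = mono,
           mendel_rate = mendel_rate, hwe_p = hwe_p, action = action)
  })
  snp_summary <- dplyr::bind_rows(rows)
  kept <- snp_summary$snp_id[snp_summary$action == "keep"]

  kept_ped <- new_pedigree(
    ped$individuals,
    ped$genotypes[ped$genotypes$snp_id %in% kept, , drop = FALSE]
  )
  errors <- find_mendel_errors(kept_ped)
  cleaned <- remove_error_genotypes(kept_ped, errors, policy = removal_policy)

  final_completion <- if (nrow(cleaned$pedigree$genotypes) > 0L) {
    completion_rate(cleaned$pedigree$genotypes)
  } else {
    NA_real_
  }
  drop_counts <- c(
    completion = sum(snp_summary$action == "drop:completion"),
    monomorphic = sum(snp_summary$action == "drop:monomorphic"),
    mendel = sum(snp_summary$action == "drop:mendel"),
    hwe = sum(snp_summary$action == "drop:hwe")
  )
  inform(sprintf(
    "qc: %d SNPs in, dropped %d (completion) + %d (monomorphic) + %d (mendel) + %d (hwe); removed %d genotype(s) in %d error trio(s); final completion %.4f",
    length(snp_ids), drop_counts[["completion"]], drop_counts[["monomorphic"]],
    drop_counts[["mendel"]], drop_counts[["hwe"]], cleaned$n_removed,
    nrow(errors), final_completion
  ))
  structure(
    list(snp_summary = snp_summary, kept_snps = kept,
         drop_counts = drop_counts, errors = errors,
         n_genotypes_removed = cleaned$n_removed,
         cleaned = cleaned$pedigree, final_completion = final_completion,
         thresholds = thresholds),
    class = "mirsnp_qc"
  )
}

#' @export
print.mirsnp_qc <- function(x, ...) {
  cat(sprintf(
    "<mirsnp_qc> %d SNPs: kept %d; drops: %d completion, %d monomorphic, %d mendel, %d hwe; %d genotypes removed; final completion %.4f\n",
    nrow(x$snp_summary), length(x$kept_snps), x$drop_counts[["completion"]],
    x$drop_counts[["monomorphic"]], x$drop_counts[["mendel"]],
    x$drop_counts[["hwe"]], x$n_genotypes_removed, x$final_completion
  ))
  invisible(x)
}
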