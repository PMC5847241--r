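# broom-style tidiers and ggplot2 autoplot methods for the two result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a MirSNP result
#'
#' One row per (SNP, allele) with the allele's best qualifying score.
#'
#' @param x A `mirsnp_result` from [run_pipeline()].
#' @param ... Unused.
#' @return A tibble `rsid, gene, allele, score, mirna, verdict`.
#' @method tidy mirsnp_result
#' @export
tidy.mirsnp_result <- function(x, ...) {
  calls <- as_tibble(x)
  if (nrow(calls) == 0L) {
    return(tibble(rsid = character(), gene = character(),
                  allele = character(), score = numeric(),
                  mirna = character(), verdict = character()))
  }
  long <- tidyr::separate_rows(
    dplyr::transmute(calls, rsid = .data$rsid, gene = .data$gene,
                     verdict = .data$verdict,
                     allele_scores = .data$allele_scores),
    "allele_scores", sep = ";"
  )
  parts <- stringi::stri_split_fixed(long$allele_scores, "=", simplify = TRUE)
  long$allele <- parts[, 1]
  long$score <- as.numeric(parts[, 2])
  long$allele_scores <- NULL
  mirna_map <- dplyr::bind_rows(
    tibble(rsid = calls$rsid,
           allele = stringi::stri_split_fixed(calls$alleles, "/",
                                              simplify = TRUE)[, 1],
           mirna = calls$mirna_allele1),
    tibble(rsid = calls$rsid,
           allele = stringi::stri_split_fixed(calls$alleles, "/",
                                              simplify = TRUE)[, 2],
           mirna = calls$mirna_allele2)
  )
  dplyr::left_join(long, mirna_map, by = c("rsid", "allele"))[
    , c("rsid", "gene", "allele", "score", "mirna", "verdict")]
}

#' One-row summary of a MirSNP result
#'
#' @param x A `mirsnp_result`.
#' @param ... Unused.
#' @return The pipeline summary tibble (pattern and verdict counts).
#' @method glance mirsnp_result
#' @export
glance.mirsnp_result <- function(x, ...) {
  attr(x, "summary")
}

#' Per-allele binding-score plot for a MirSNP result
#'
#' @param object A `mirsnp_result`.
#' @param ... Unused.
#' @return A ggplot: best qualifying score per allele, one facet row of
#'   points per SNP, coloured by verdict class.
#' @method autoplot mirsnp_result
#' @export
autoplot.mirsnp_result <- function(object, ...) {
  d <- tidy(object)
  d$verdict_class <- sub(":.*$", "", d$verdict)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score, y = .data$rsid)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$rsid), colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$verdict_class),
                        size = 2.5) +
    ggplot2::geom_text(ggplot2::aes(label = .data$allele), vjust = -0.9,
                       size = 3) +
    ggplot2::labs(x = "best qualifying duplex score", y = NULL,
                  colour = "verdict") +
    ggplot2::theme_minimal()
}

#' Tidy a QC result
#'
#' @param x A `mirsnp_qc` from [qc_pipeline()].
#' @param ... Unused.
#' @return The per-SNP summary tibble.
#' @method tidy mirsnp_qc
#' @export
tidy.mirsnp_qc <- function(x, ...) {
  x$snp_summary
}

#' One-row summary of a QC result
#'
#' @param x A `mirsnp_qc`.
#' @param ... Unused.
#' @return A one-row tibble with drop counts, genotype removals and the
#'   final completion rate.
#' @method glance mirsnp_qc
#' @export
glance.mirsnp_qc <- function(x, ...) {
  tibble(
    n_snps = nrow(x$snp_summary),
    n_kept = length(x$kept_snps),
    dropped_completion = x$drop_counts[["completion"]],
    dropped_monomorphic = x$drop_counts[["monomorphic"]],
    dropped_mendel = x$drop_counts[["mendel"]],
    dropped_hwe = x$drop_counts[["hwe"]],
    n_genotypes_removed = x$n_genotypes_removed,
    final_completion = x$final_completion
  )
}

#' QC action bar chart
#'
#' @param object A `mirsnp_qc`.
#' @param ... Unused.
#' @return A ggplot of per-SNP QC outcomes.
#' @method autoplot mirsnp_qc
#' @export
autoplot.mirsnp_qc <- function(object, ...) {
  d <- object$snp_summary
  ggplot2::ggplot(d, ggplot2::aes(x = .data$action)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "SNPs") +
    ggplot2::theme_minimal()
}
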