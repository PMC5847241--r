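geno_tbl <- function(...) {
  gts <- list(...)
  tibble::tibble(
    individual_id = paste0("i", seq_along(gts)),
    snp_id = "S1",
    a1 = vapply(gts, function(g) if (is.na(g[1])) NA_character_ else g[1],
                character(1)),
    a2 = vapply(gts, function(g) if (is.na(g[1])) NA_character_ else g[2],
                character(1))
  )
}

trio_ped <- function(father, mother, child) {
  ind <- tibble::tibble(
    family_id = "F1",
    individual_id = c("dad", "mom", "kid"),
    father_id = c("0", "0", "dad"),
    mother_id = c("0", "0", "mom"),
    sex = c("1", "2", "0")
  )
  g <- tibble::tibble(
    individual_id = rep(c("dad", "mom", "kid"), each = 1),
    snp_id = "S1",
    a1 = c(father[1], mother[1], child[1]),
    a2 = c(father[2], mother[2], child[2])
  )
  new_pedigree(ind, g)
}

test_that("completion_rate and is_monomorphic follow their definitions", {
  g <- geno_tbl(c("A", "A"))
  g99 <- dplyr::bind_rows(replicate(99, g, simplify = FALSE),
                          geno_tbl(NA))
  expect_equal(completion_rate(g99), 0.99)
  expect_gte(completion_rate(g99), 0.98)
  g97 <- dplyr::bind_rows(replicate(97, g, simplify = FALSE),
                          replicate(3, geno_tbl(NA), simplify = FALSE))
  expect_equal(completion_rate(g97), 0.97)
  expect_lt(completion_rate(g97), 0.98)
  expect_equal(completion_rate(geno_tbl(NA, NA)), 0)
  expect_error(completion_rate(geno_tbl()), class = "mirsnp_param_error")

  expect_true(is_monomorphic(geno_tbl(c("A", "A"), c("A", "A"))))
  expect_false(is_monomorphic(geno_tbl(c("A", "A"), c("A", "B"))))
  expect_true(is_monomorphic(geno_tbl(NA, NA))) # degenerate all-missing case
})

test_that("find_mendel_errors flags the canonical impossible trios", {
  # B cannot be transmitted by AA x AA
  e1 <- find_mendel_errors(trio_ped(c("A", "A"), c("A", "A"), c("A", "B")))
  expect_equal(nrow(e1), 1L)
  expect_equal(e1$child_id, "kid")
  # AA x BB forces an AB child
  e2 <- find_mendel_errors(trio_ped(c("A", "A"), c("B", "B"), c("A", "A")))
  expect_equal(nrow(e2), 1L)
  # a missing parent marginalizes: AB child is possible
  e3 <- find_mendel_errors(trio_ped(c("A", "A"), c(NA, NA), c("A", "B")))
  expect_equal(nrow(e3), 0L)
  # ... but a BB child still cannot get B from an AA father
  e4 <- find_mendel_errors(trio_ped(c("A", "A"), c(NA, NA), c("B", "B")))
  expect_equal(nrow(e4), 1L)
})

test_that("trio calls agree with exhaustive enumeration over all genotype combos", {
  gts <- list(c("A", "A"), c("A", "B"), c("B", "B"), c(NA, NA))
  for (f in gts) for (m in gts) for (c0 in gts) {
    ped <- trio_ped(f, m, c0)
    got <- nrow(find_mendel_errors(ped)) > 0L
    # universe: alleles observed at the SNP (as the implementation defines)
    universe <- unique(stats::na.omit(c(f, m, c0)))
    if (length(universe) == 0L) universe <- c("A", "B")
    want <- !oracle_trio_consistent(c0, f, m, universe)
    expect_equal(got, want,
                 info = paste(paste(f, collapse = ""), paste(m, collapse = ""),
                              paste(c0, collapse = "")))
  }
})

test_that("remove_error_genotypes blanks trios, reaches a fixed point, is idempotent", {
  ped <- trio_ped(c("A", "A"), c("A", "A"), c("A", "B"))
  errors <- find_mendel_errors(ped)
  out <- remove_error_genotypes(ped, errors)
  expect_equal(out$n_removed, 3L)
  expect_equal(nrow(find_mendel_errors(out$pedigree)), 0L)
  # idempotent
  again <- remove_error_genotypes(out$pedigree,
                                  find_mendel_errors(out$pedigree))
  expect_equal(again$n_removed, 0L)
  expect_equal(again$pedigree$genotypes, out$pedigree$genotypes)
  # child-only policy also clears the error
  out2 <- remove_error_genotypes(ped, errors, policy = "child")
  expect_equal(out2$n_removed, 1L)
  expect_equal(nrow(find_mendel_errors(out2$pedigree)), 0L)
  # no errors -> pedigree unchanged
  clean <- trio_ped(c("A", "B"), c("A", "B"), c("A", "A"))
  noop <- remove_error_genotypes(clean, find_mendel_errors(clean))
  expect_equal(noop$n_removed, 0L)
  expect_equal(noop$pedigree$genotypes, clean$genotypes)
})

test_that("a shared individual across two error trios is removed once", {
  ind <- tibble::tibble(
    family_id = "F1",
    individual_id = c("dad", "mom", "kid1", "kid2"),
    father_id = c("0", "0", "dad", "dad"),
    mother_id = c("0", "0", "mom", "mom"),
    sex = "0"
  )
  g <- tibble::tibble(
    individual_id = c("dad", "mom", "kid1", "kid2"),
    snp_id = "S1",
    a1 = c("A", "A", "B", "B"),
    a2 = c("A", "A", "B", "B")
  )
  ped <- new_pedigree(ind, g)
  errors <- find_mendel_errors(ped)
  expect_equal(nrow(errors), 2L)
  out <- remove_error_genotypes(ped, errors)
  expect_equal(out$n_removed, 4L) # dad+mom counted once, both kids
  expect_equal(nrow(find_mendel_errors(out$pedigree)), 0L)
})

test_that("hwe_exact_p matches the frozen examples", {
  expect_gt(hwe_exact_p(25, 50, 25), 0.5) # perfect HWE proportions
  expect_lt(hwe_exact_p(50, 0, 50), 0.001) # total heterozygote deficit
  expect_equal(hwe_exact_p(10, 0, 0), 1) # monomorphic: a single table
  expect_error(hwe_exact_p(-1, 0, 0), class = "mirsnp_param_error")
})

test_that("hwe_exact_p matches the recurrence oracle to 1e-9", {
  set.seed(88)
  cases <- list(c(25, 50, 25), c(50, 0, 50), c(3, 1, 10), c(0, 5, 0),
                c(60, 70, 70), c(1, 0, 1))
  for (r in 1:30) {
    n <- sample(5:200, 1)
    aa <- sample(0:n, 1); ab <- sample(0:(n - aa), 1); bb <- n - aa - ab
    cases[[length(cases) + 1L]] <- c(aa, ab, bb)
  }
  for (cs in cases) {
    expect_equal(hwe_exact_p(cs[1], cs[2], cs[3]),
                 oracle_hwe_p(cs[1], cs[2], cs[3]),
                 tolerance = 1e-9, info = paste(cs, collapse = ","))
  }
})

test_that("qc_pipeline drops each engineered bad SNP in its own category", {
  fix <- gen_pedigree(n_families = 40, n_children = 2, n_snps = 6,
                      mendel_error_rate = 0, missing_rate = 0, seed = 17)
  ped <- fix$pedigree
  g <- ped$genotypes
  n_ind <- nrow(ped$individuals)
  # SNP001: poor completion (10% missing)
  idx <- which(g$snp_id == "SNP001")
  drop_idx <- idx[seq_len(ceiling(0.1 * n_ind))]
  g$a1[drop_idx] <- NA; g$a2[drop_idx] <- NA
  # SNP002: monomorphic
  idx <- which(g$snp_id == "SNP002")
  g$a1[idx] <- "A"; g$a2[idx] <- "A"
  # SNP003: >1% Mendelian error rate — corrupt several children under AAxAA
  idx3 <- which(g$snp_id == "SNP003")
  g$a1[idx3] <- "A"; g$a2[idx3] <- "A"
  kids <- grep("child", g$individual_id[idx3])
  flip <- idx3[kids[1:5]]
  g$a1[flip] <- "B"; g$a2[flip] <- "B"
  # keep SNP003 polymorphic among founders so it reaches the Mendel filter
  dads <- idx3[grep("father", g$individual_id[idx3])[1:2]]
  g$a1[dads] <- "B"
  ped2 <- new_pedigree(ped$individuals, g)
  qc <- suppressMessages(qc_pipeline(ped2))
  s <- qc$snp_summary
  expect_equal(s$action[s$snp_id == "SNP001"], "drop:completion")
  expect_equal(s$action[s$snp_id == "SNP002"], "drop:monomorphic")
  expect_equal(s$action[s$snp_id == "SNP003"], "drop:mendel")
  expect_true(all(s$action[s$snp_id %in% c("SNP004", "SNP005", "SNP006")]
                  == "keep"))
  # cleaned output carries no residual Mendelian errors
  expect_equal(nrow(find_mendel_errors(qc$cleaned)), 0L)
})

test_that("qc_pipeline on an error-free pedigree changes nothing", {
  fix <- gen_pedigree(n_families = 25, n_children = 2, n_snps = 5,
                      mendel_error_rate = 0, missing_rate = 0, seed = 23)
  qc <- suppressMessages(qc_pipeline(fix$pedigree))
  expect_equal(qc$n_genotypes_removed, 0L)
  expect_equal(qc$drop_counts[["completion"]], 0L)
  expect_equal(qc$final_completion, 1)
  kept_geno <- qc$cleaned$genotypes
  orig <- fix$pedigree$genotypes[fix$pedigree$genotypes$snp_id %in%
                                   qc$kept_snps, ]
  expect_equal(dplyr::arrange(kept_geno, individual_id, snp_id),
               dplyr::arrange(orig, individual_id, snp_id))
  # extreme thresholds: nothing can fail a 0+eps completion bar
  qc2 <- suppressMessages(qc_pipeline(fix$pedigree,
                                      qc_thresholds(min_completion = 1e-6)))
  expect_equal(qc2$drop_counts[["completion"]], 0L)
})

test_that("injected Mendelian errors are detected with full sensitivity when parents are typed", {
  fix <- gen_pedigree(n_families = 40, n_children = 2, n_snps = 10,
                      mendel_error_rate = 0.05, missing_rate = 0, seed = 29)
  expect_gt(nrow(fix$truth), 0)
  errors <- find_mendel_errors(fix$pedigree)
  got <- paste(errors$snp_id, errors$child_id)
  want <- paste(fix$truth$snp_id, fix$truth$child_id)
  expect_true(all(want %in% got))
  # QC glance/tidy accessors
  qc <- suppressMessages(qc_pipeline(fix$pedigree))
  expect_equal(nrow(tidy(qc)), 10L)
  expect_s3_class(autoplot(qc), "ggplot")
  expect_equal(glance(qc)$n_snps, 10L)
})
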