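test_that("per-genome counts follow the halving rule", {
  d <- matrix(c(2L, 1L, 0L, 1L), nrow = 4, ncol = 1)
  colnames(d) <- "acc1"
  pol <- make_pol(d)
  cats <- make_categories(pol, rep("deleterious", 4))
  prof <- per_genome_counts(pol, cats)
  expect_equal(prof$deleterious, 2.0)  # 1 hom + 2 het/2
  expect_true(is.na(prof$del_neutr_ratio))  # zero neutral denominator
  # all-ancestral genome: zero counts, both ratios undefined
  pol0 <- make_pol(matrix(0L, 4, 1))
  prof0 <- per_genome_counts(pol0, cats)
  expect_equal(prof0$deleterious, 0)
  expect_true(is.na(prof0$nonsyn_syn_ratio) && is.na(prof0$del_neutr_ratio))
})

test_that("counts equal brute-force enumeration and are additive across categories", {
  set.seed(9)
  for (r in 1:5) {
    d <- random_dosage(50, 10)
    cats_vec <- sample(load_categories(), 50, replace = TRUE)
    pol <- make_pol(d)
    prof <- per_genome_counts(pol, make_categories(pol, cats_vec))
    oracle <- oracle_counts(d, cats_vec)
    for (k in seq_along(oracle)) {
      o <- oracle[[k]]
      row <- prof[prof$accession == o$accession, ]
      for (cl in setdiff(names(o), "accession"))
        expect_equal(row[[cl]], o[[cl]])
    }
    # additivity: category counts sum to the class-blind total
    blind <- colSums(d == 2) + 0.5 * colSums(d == 1)
    total <- rowSums(as.matrix(prof[, load_categories(), with = FALSE]))
    expect_equal(unname(total), unname(blind))
  }
})

test_that("ratios are consistent with their definitions", {
  d <- rbind(matrix(2L, 4, 3), matrix(1L, 2, 3), matrix(2L, 2, 3))
  pol <- make_pol(d)
  cats <- make_categories(pol, c(rep("synonymous", 4),
                                 rep("neutral-nonsynonymous", 2),
                                 rep("deleterious", 2)))
  prof <- per_genome_counts(pol, cats)
  expect_equal(prof$nonsyn_syn_ratio, rep((1 + 2) / 4, 3))
  expect_equal(prof$del_neutr_ratio, rep(2 / 1, 3))
})

test_that("compare_populations separates forced groups with letters", {
  # n = 5 per group: with only 3 values per group the Bonferroni-adjusted
  # Dunn p for a fully separated pair is 0.05-0.11, i.e., never significant
  vals <- c(rep(1, 5), rep(9, 5), rep(9, 5))
  pops <- rep(c("A", "B", "C"), each = 5)
  res <- compare_populations(vals, pops)
  expect_lt(res$kruskal_p, 0.05)
  lt <- res$letters
  expect_equal(unname(lt["A"]) == unname(lt["B"]), FALSE)
  expect_equal(unname(lt["B"]), unname(lt["C"]))  # B and C share a letter
})

test_that("Dunn test matches an independent implementation", {
  set.seed(4)
  vals <- round(rnorm(30), 1)  # rounding makes ties
  pops <- rep(c("A", "B", "C"), each = 10)
  mine <- dunn_test(vals, pops)
  ref <- oracle_dunn(vals, pops)
  for (k in seq_len(nrow(ref))) {
    row <- mine[mine$group1 == ref$group1[k] & mine$group2 == ref$group2[k], ]
    expect_equal(row$z, ref$z[k], tolerance = 1e-8)
    expect_equal(row$p_raw, ref$p_raw[k], tolerance = 1e-8)
  }
})

test_that("populations with < 2 accessions are excluded with a warning", {
  vals <- c(1, 2, 3, 4, 10)
  pops <- c("A", "A", "B", "B", "C")
  expect_warning(res <- compare_populations(vals, pops), "excluded")
  expect_false("C" %in% names(res$letters))
})

test_that("SFS bins are left-open right-closed over (0, 1]", {
  # 10 diploids: dosage sums give exact frequencies
  d <- matrix(0L, nrow = 3, ncol = 10)
  d[1, 1] <- 1L            # DAF 0.05 -> bin (0, 0.1]
  d[2, ] <- 2L             # DAF 1.0  -> bin (0.9, 1]
  # site 3 stays DAF 0 -> excluded
  pol <- make_pol(d)
  cats <- make_categories(pol, rep("deleterious", 3))
  res <- sfs_and_adaf(pol, cats)
  sp <- res$spectra[res$spectra$class == "deleterious", ]
  expect_equal(sp$count[sp$bin == 1], 1L)
  expect_equal(sp$count[sp$bin == 10], 1L)
  expect_equal(sum(sp$count), 2L)  # DAF-0 site excluded
})

test_that("identical DAF lists give KS statistic 0 and verdict D~N", {
  d <- rbind(matrix(1L, 4, 10), matrix(1L, 4, 10))
  pol <- make_pol(d)
  cats <- make_categories(pol, c(rep("deleterious", 4),
                                 rep("neutral-nonsynonymous", 4)))
  res <- sfs_and_adaf(pol, cats)
  expect_equal(res$summary$ks_stat, 0)
  expect_equal(res$summary$verdict, "D~N")
  # empty class -> undefined
  cats2 <- make_categories(pol, rep("neutral-nonsynonymous", 8))
  res2 <- sfs_and_adaf(pol, cats2)
  expect_equal(res2$summary$verdict, "undefined")
})

test_that("private alleles equal brute-force set algebra", {
  set.seed(13)
  for (r in 1:5) {
    n_sites <- 30
    d <- random_dosage(n_sites, 9, probs = c(0.75, 0.15, 0.10))
    pops <- rep(c("A", "B", "C"), each = 3)
    pol <- make_pol(d, populations = pops)
    cls <- sample(c("deleterious", "neutral-nonsynonymous"), n_sites,
                  replace = TRUE)
    res <- private_alleles(pol, make_categories(pol, cls))
    # brute force
    for (i in seq_len(n_sites)) {
      freqs <- sapply(c("A", "B", "C"), function(p)
        sum(d[i, pops == p]) > 0)
      expected_private <- if (sum(freqs) == 1) names(freqs)[freqs] else NA
      got <- res$private_sites[res$private_sites$pos == pol$sites$pos[i], ]
      if (is.na(expected_private)) {
        expect_equal(nrow(got), 0)
      } else {
        expect_equal(got$private_to, expected_private)
      }
    }
  }
})

test_that("a site segregating in two populations is private to neither", {
  d <- matrix(0L, 1, 6)
  d[1, c(1, 4)] <- 1L
  pol <- make_pol(d, populations = rep(c("A", "B"), each = 3))
  res <- private_alleles(pol, make_categories(pol, "deleterious"))
  expect_equal(nrow(res$private_sites), 0)
})

test_that("genotype frequencies sum to one and match direct computation", {
  d <- matrix(c(2L, 2L, 1L, 0L), nrow = 1)
  pol <- make_pol(d)
  gf <- genotype_frequency_table(pol)
  expect_equal(gf$freq_hom_derived, 0.5)
  expect_equal(gf$freq_het, 0.25)
  expect_equal(gf$freq_hom_ancestral, 0.25)
  # monomorphic ancestral population
  gf0 <- genotype_frequency_table(make_pol(matrix(0L, 1, 4)))
  expect_equal(gf0$freq_hom_ancestral, 1)
  # normalization on random data
  set.seed(5)
  pol2 <- make_pol(random_dosage(40, 8),
                   populations = rep(c("A", "B"), each = 4))
  gf2 <- genotype_frequency_table(pol2)
  expect_true(all(abs(gf2$freq_hom_derived + gf2$freq_het +
                        gf2$freq_hom_ancestral - 1) < 1e-12))
})
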