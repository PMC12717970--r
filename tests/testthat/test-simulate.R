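test_that("sim_config validates proportions, rates and demography", {
  expect_error(sim_config(category_proportions = c(
    "non-coding" = 0.5, "synonymous" = 0.5, "neutral-nonsynonymous" = 0.1,
    "deleterious" = 0.1)), "sum to 1")
  expect_error(sim_config(mut_rate = 1.5), "mut_rate")
  expect_error(sim_config(sel_coeff = 0.1), "sel_coeff")
  expect_error(sim_config(populations = list(
    pop_spec("A", N = 10, n_sampled = 11))), "n_sampled")
  expect_error(sim_config(populations = list(
    pop_spec("A", N = 10), pop_spec("B", N = 10))), "root")
  expect_error(pop_spec("A", N = 1), "N must be")
})

test_that("simulation is bit-identical under the same config and seed", {
  cfg <- sim_config(seed = 5, n_sites = 300, n_gens = 60,
                    populations = list(pop_spec("P", N = 40, n_sampled = 8)))
  s1 <- simulate_populations(cfg)
  s2 <- simulate_populations(cfg)
  expect_identical(s1, s2)
  # and the emitted VCF is byte-identical
  p1 <- tempfile(); p2 <- tempfile()
  set.seed(99); write_sim_vcf(s1, p1)
  set.seed(99); write_sim_vcf(s2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("outgroup is homozygous ancestral so polarization is the identity on truth", {
  cfg <- sim_config(seed = 21, n_sites = 400, n_gens = 80,
                    ref_is_derived_frac = 0.3, missing_rate = 0,
                    populations = list(pop_spec("P", N = 50, n_sampled = 10)))
  sim <- simulate_populations(cfg)
  d <- sim_dosage(sim)
  expect_true(all(d[, "OUTGROUP"] == 0))
  vp <- tempfile(fileext = ".vcf"); ap <- tempfile()
  write_sim_vcf(sim, vp)
  write_assignment(sim$accessions, "OUTGROUP", ap)
  pol <- polarize(filter_sites(read_vcf(vp)), read_assignment(ap))
  expect_true(all(pol$sites$polarization_status == "ok"))
  truth_idx <- match(paste(pol$sites$chrom, pol$sites$pos),
                     paste(sim$sites$chrom, sim$sites$pos))
  ing <- setdiff(colnames(d), "OUTGROUP")
  expect_equal(unname(pol$dosage[, ing]), unname(d[truth_idx, ing]))
  # a substantial fraction of sites was REF-flipped, so this exercised both
  # polarization directions
  expect_gt(sum(pol$sites$ref != pol$sites$ancestral), 50)
})

test_that("extinction reports the failing generation", {
  cfg <- sim_config(seed = 1, n_sites = 50, n_gens = 10, sel_coeff = -1,
                    init_freq = 1, mut_rate = 0,
                    category_proportions = c(
                      "non-coding" = 0, "synonymous" = 0,
                      "neutral-nonsynonymous" = 0, "deleterious" = 1),
                    populations = list(pop_spec("P", N = 10, n_sampled = 2)))
  expect_error(simulate_populations(cfg), "extinct.*generation 1")
})

test_that("neutral single-population drift keeps mean DAF near the initial frequency", {
  # s = 0 everywhere, no bottleneck: across replicate sites the mean DAF
  # stays within 3 standard errors of the initialised frequency
  cfg <- sim_config(seed = 31, n_sites = 200, n_gens = 50, sel_coeff = 0,
                    mut_rate = 0, init_freq = 0.3,
                    populations = list(pop_spec("P", N = 100, n_sampled = 40)))
  sim <- simulate_populations(cfg)
  daf <- rowMeans(sim$populations$P) / 2
  se <- sd(daf) / sqrt(length(daf))
  expect_lt(abs(mean(daf) - 0.3), 3 * se)
})

test_that("purifying selection lowers deleterious DAF, matching an independent single-site simulator", {
  reps <- 10
  wins_pkg <- wins_oracle <- 0
  for (r in seq_len(reps)) {
    cfg <- sim_config(seed = 100 + r, n_sites = 400, n_gens = 150,
                      sel_coeff = -0.05, dominance = 0.5, mut_rate = 0,
                      init_freq = 0.2,
                      category_proportions = c(
                        "non-coding" = 0, "synonymous" = 0,
                        "neutral-nonsynonymous" = 0.5, "deleterious" = 0.5),
                      populations = list(pop_spec("P", N = 100,
                                                  n_sampled = 50)))
    sim <- simulate_populations(cfg)
    daf <- rowMeans(sim$populations$P) / 2
    del <- sim$sites$category == "deleterious"
    if (mean(daf[del]) < mean(daf[!del])) wins_pkg <- wins_pkg + 1
    q_del <- mean(replicate(200, oracle_wf_single_site(100, -0.05, 0.5,
                                                       0.2, 150)))
    q_neu <- mean(replicate(200, oracle_wf_single_site(100, 0, 0.5,
                                                       0.2, 150)))
    if (q_del < q_neu) wins_oracle <- wins_oracle + 1
  }
  expect_gte(wins_pkg, 9)
  expect_gte(wins_oracle, 9)  # the oracle agrees on the expected direction
})

test_that("annotation tables decode to truth and swap exactly floor(m*n) labels", {
  cfg <- sim_config(seed = 8, n_sites = 500, n_gens = 40,
                    populations = list(pop_spec("P", N = 30, n_sampled = 6)))
  sim <- simulate_populations(cfg)
  ann0 <- emit_annotation_tables(sim, miscls_rate = 0)
  pol_like <- sim$sites[, .(chrom, pos)]
  dec0 <- suppressMessages(
    classify_sites(ann0$sift, ann0$provean, pol_like))
  expect_equal(dec0$category, sim$sites$category)

  # deleterious sites carry a deleterious-class label and score < -2.5
  del <- sim$sites$category == "deleterious"
  key <- paste(sim$sites$chrom, sim$sites$pos)
  sk <- paste(ann0$sift$chrom, ann0$sift$pos)
  lab <- ann0$sift$label[match(key[del], sk)]
  expect_true(all(lab %in% c("DELETERIOUS",
                             "DELETERIOUS (*WARNING! Low confidence)")))
  pk <- paste(ann0$provean$chrom, ann0$provean$pos)
  sc <- ann0$provean$score[match(key[del], pk)]
  expect_true(all(sc < -2.5))

  # misclassification swaps exactly floor(m * n_nonsyn) decoded classes
  n_nonsyn <- sum(sim$sites$category %in%
                    c("deleterious", "neutral-nonsynonymous"))
  ann1 <- emit_annotation_tables(sim, miscls_rate = 0.1)
  dec1 <- suppressMessages(
    classify_sites(ann1$sift, ann1$provean, pol_like))
  expect_equal(sum(dec1$category != sim$sites$category),
               floor(0.1 * n_nonsyn))
})

test_that("gene models are contiguous with the required feature grammar", {
  set.seed(3)
  gm <- generate_gene_models(12, n_chrom = 3, chrom_length = 1e6)
  genes <- gm[gm$type == "gene", ]
  expect_equal(nrow(genes), 12)
  for (g in genes$ID) {
    f <- gm[!is.na(gm$Parent) & gm$Parent == g, ]
    expect_equal(f$type[1], "five_prime_UTR")
    expect_equal(f$type[nrow(f)], "three_prime_UTR")
    n_ex <- sum(f$type == "exon")
    expect_gte(n_ex, 1)
    expect_equal(sum(f$type == "intron"), n_ex - 1)  # 2 exons -> 1 intron
    expect_equal(f$start[-1], f$end[-nrow(f)] + 1)   # contiguous
    expect_equal(range(c(f$start, f$end)),
                 unname(unlist(genes[genes$ID == g, c("start", "end")])))
  }
  # genes never overlap
  set.seed(3)
  for (cc in unique(genes$seqid)) {
    gsub <- genes[genes$seqid == cc, ]
    gsub <- gsub[order(gsub$start), ]
    if (nrow(gsub) > 1)
      expect_true(all(gsub$start[-1] > gsub$end[-nrow(gsub)]))
  }
  # GFF3 round trip
  p <- tempfile(fileext = ".gff3")
  write_gene_models(gm, p)
  back <- read_gene_models(p)
  expect_equal(back$start, gm$start)
  expect_equal(back$type, gm$type)
})

test_that("genetic map generation and interpolation are linear where expected", {
  set.seed(5)
  map <- generate_genetic_map(n_markers = 8, cm_per_mb = 2, n_chrom = 2,
                              chrom_length = 1e6)
  wins <- data.table::data.table(
    chrom = rep(c("chr01", "chr02"), each = 5),
    start = rep(seq(1, 9e5, by = 2e5), 2))
  wins[, end := start + 2e5 - 1]
  out <- interpolate_recombination(map, wins)
  expect_equal(out$recomb_rate, rep(2, 10), tolerance = 1e-9)
  # two-marker map: exact linear interpolation between and beyond markers
  map2 <- data.table::data.table(chrom = "chr01",
                                 bp = c(1, 1000001), cM = c(0, 2))
  w2 <- data.table::data.table(chrom = "chr01",
                               start = c(1, 200001, 1200001),
                               end = c(200000, 400000, 1400000))
  out2 <- interpolate_recombination(map2, w2)
  expect_equal(out2$recomb_rate, rep(2, 3), tolerance = 1e-9)
  # non-monotone map rejected
  bad <- data.table::data.table(chrom = "chr01", bp = c(1, 10, 5),
                                cM = c(0, 1, 2))
  expect_error(interpolate_recombination(bad, w2), "monotone")
})

test_that("neutral equilibrium SFS is monotone over the first bins (coarse 1/i shape)", {
  # scaled-down: N = 50 diploids run 10N generations under mutation only
  reps <- 20
  ok <- 0
  for (r in seq_len(reps)) {
    cfg <- sim_config(seed = 600 + r, n_sites = 2000, n_gens = 500,
                      sel_coeff = 0, mut_rate = 2e-4, init_freq = 0,
                      category_proportions = c(
                        "non-coding" = 1, "synonymous" = 0,
                        "neutral-nonsynonymous" = 0, "deleterious" = 0),
                      populations = list(pop_spec("P", N = 50,
                                                  n_sampled = 40)))
    sim <- simulate_populations(cfg)
    daf <- rowMeans(sim$populations$P) / 2
    daf <- daf[daf > 0]
    cnt <- tabulate(cut(daf, seq(0, 1, 0.1)), nbins = 10)
    if (all(diff(cnt[1:5]) <= 0)) ok <- ok + 1
  }
  expect_gte(ok / reps, 0.8)
})
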