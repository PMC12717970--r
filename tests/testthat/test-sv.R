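mk_calls <- function(...) {
  rows <- list(...)
  data.table::rbindlist(lapply(rows, function(r)
    data.table::data.table(accession = r[["acc"]] %||% "A1",
                           caller = r[["caller"]],
                           chrom = r[["chrom"]] %||% "chr01",
                           start = as.integer(r[["start"]]),
                           end = as.integer(r[["end"]]),
                           chrom2 = r[["chrom2"]] %||% NA_character_,
                           type = r[["type"]] %||% "DEL")))
}

test_that("SV VCF parsing: spans, INS exclusion, SVLEN fallback, missing SVTYPE", {
  tf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"l\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "ACC01"), collapse = "\t"),
    "chr01\t1000\ta\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=1500\tGT\t0/1",
    "chr01\t2000\tb\tN\t<INS>\t.\tPASS\tSVTYPE=INS;END=2001\tGT\t0/1",
    "chr01\t3000\tc\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;SVLEN=-470\tGT\t0/1",
    "chr01\t4000\td\tN\t<DUP>\t.\tPASS\tEND=4600\tGT\t0/1"), tf)
  mani <- data.frame(accession = "ACC01", caller = "callerA", path = tf)
  expect_warning(
    expect_message(calls <- read_caller_vcfs(mani), "insertion"),
    "SVTYPE")
  expect_equal(nrow(calls), 2)            # INS and no-SVTYPE dropped
  expect_equal(calls$end[calls$start == 1000], 1500)
  expect_equal(calls$end[calls$start == 3000], 3470)  # END = start + |SVLEN|
})

test_that("per-accession consensus applies the 2-of-3, size and type rules", {
  calls <- mk_calls(
    list(caller = "callerA", start = 1000, end = 1500),
    list(caller = "callerB", start = 1050, end = 1540),   # merges: d=50, r=0.98
    list(caller = "callerA", start = 5000, end = 5400),
    list(caller = "callerB", start = 5000, end = 5400, type = "DUP"),
    list(caller = "callerA", start = 9000, end = 9020),
    list(caller = "callerB", start = 9000, end = 9020))   # 21 bp: too small
  cons <- consensus_per_accession(calls)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$start, 1025L)  # median of member starts
  expect_equal(cons$n_callers, 2L)
  # the DEL/DUP pair at 5000 must not merge (type mismatch), neither
  # reaches two callers; the 21-bp cluster is dropped by size
})

test_that("cross-accession collapsing keeps the 100 bp / 90% rule", {
  cons <- data.table::rbindlist(list(
    data.table::data.table(accession = c("A1", "A2", "A3"), chrom = "chr01",
                           start = 1000L, end = 2000L, chrom2 = NA_character_,
                           type = "DEL", n_callers = 2L, callers = "x,y"),
    data.table::data.table(accession = "A4", chrom = "chr01",
                           start = 1150L, end = 2150L, chrom2 = NA_character_,
                           type = "DEL", n_callers = 2L, callers = "x,y")))
  cat_ <- collapse_across_accessions(cons)
  expect_equal(nrow(cat_), 2)  # 150 bp apart: two catalogue entries
  expect_equal(sort(cat_$n_accessions), c(1L, 3L))
  expect_equal(cat_$carriers[cat_$n_accessions == 3], "A1,A2,A3")
  # collapsing an already-collapsed catalogue is the identity
  again <- collapse_across_accessions(
    cbind(cat_[, .(chrom, start, end, chrom2, type)],
          accession = cat_$carriers, n_callers = 2L, callers = "x,y"))
  expect_equal(nrow(again), nrow(cat_))
  expect_equal(again$start, cat_$start)
})

test_that("clustering equals the brute-force transitive closure on random trials", {
  set.seed(77)
  for (r in 1:20) {
    dt <- random_sv_calls(50)
    ids <- tomload:::sv_cluster_ids(dt)
    expect_true(same_partition(partition_sets(ids), oracle_sv_partition(dt)))
  }
})

test_that("consensus and collapse are invariant to input order", {
  set.seed(78)
  fix <- generate_sv_fixtures(n_accessions = 3, carrier_freq = 0.7,
                              dropout = 0, fp_per_caller = 2)
  calls <- fix$calls[, .(accession, caller, chrom, start, end, chrom2, type)]
  c1 <- collapse_across_accessions(consensus_per_accession(calls))
  c2 <- collapse_across_accessions(
    consensus_per_accession(calls[sample.int(nrow(calls))]))
  expect_equal(c1, c2)
})

test_that("planted fixtures are recovered exactly and false positives never survive", {
  set.seed(80)
  fix <- generate_sv_fixtures(n_per_type = c(DEL = 10, DUP = 5, INV = 5,
                                             TRA = 5),
                              n_accessions = 4, carrier_freq = 0.6,
                              jitter_sd = 10, dropout = 0, fp_per_caller = 4)
  calls <- fix$calls[, .(accession, caller, chrom, start, end, chrom2, type)]
  cat_ <- collapse_across_accessions(consensus_per_accession(calls))
  expect_equal(nrow(cat_), nrow(fix$truth))
  # every catalogue entry sits within jitter range of one truth SV
  for (i in seq_len(nrow(cat_))) {
    hit <- fix$truth[chrom == cat_$chrom[i] & type == cat_$type[i] &
                       abs(start - cat_$start[i]) <= 40]
    expect_equal(nrow(hit), 1)
    expect_equal(sort(strsplit(cat_$carriers[i], ",")[[1]]),
                 sort(sprintf("ACC%02d",
                              as.integer(strsplit(hit$carriers, ",")[[1]]))))
  }
})

test_that("one caller lost to dropout still yields the 2-of-3 consensus", {
  set.seed(81)
  fix <- generate_sv_fixtures(n_per_type = c(DEL = 20), n_accessions = 1,
                              jitter_sd = 5, dropout = 0)
  calls <- fix$calls[, .(accession, caller, chrom, start, end, chrom2, type)]
  # remove exactly one caller per truth SV (cycling through callers)
  drop_rows <- integer(0)
  for (k in seq_len(nrow(fix$truth))) {
    rows <- which(fix$calls$truth_id == fix$truth$sv_id[k])
    drop_rows <- c(drop_rows, rows[(k %% 3) + 1])
  }
  cons <- consensus_per_accession(calls[-drop_rows])
  expect_equal(nrow(cons), 20)
  expect_true(all(cons$n_callers == 2))
})

test_that("MAF filter and outgroup polarization of SVs", {
  accs <- c(sprintf("A%03d", 1:200), "OUT")
  cat_ <- data.table::data.table(
    sv_id = c("s1", "s2", "s3"), chrom = "chr01",
    start = c(1000L, 5000L, 9000L), end = c(2000L, 6000L, 9900L),
    chrom2 = NA_character_, type = "DEL",
    n_accessions = c(1L, 30L, 150L),
    carriers = c("A001",
                 paste(sprintf("A%03d", 1:30), collapse = ","),
                 paste(c(sprintf("A%03d", 1:150), "OUT"), collapse = ",")))
  out <- sv_filter_and_polarize(cat_, accs, "OUT", min_maf = 0.01)
  expect_false("s1" %in% out$sv_id)   # 1/200 = 0.005 < 0.01
  expect_equal(out[sv_id == "s2", derived_state], "presence")
  expect_equal(out[sv_id == "s3", derived_state], "absence")
})

test_that("genic and feature overlap counts with size adjustment", {
  gm <- data.table::data.table(
    seqid = "chr01",
    type = c("gene", "five_prime_UTR", "exon", "intron", "exon",
             "three_prime_UTR"),
    start = c(1000L, 1000L, 1100L, 1600L, 2600L, 3100L),
    end = c(3200L, 1099L, 1599L, 2599L, 3099L, 3200L),
    strand = "+", ID = c("g1", paste0("g1.f", 1:5)),
    Parent = c(NA, rep("g1", 5)))
  cat_ <- data.table::data.table(
    sv_id = c("s1", "s2"), chrom = "chr01",
    start = c(1700L, 50000L), end = c(1800L, 50100L),
    chrom2 = NA_character_, type = "DEL")
  res <- genic_feature_overlap(cat_, gm, genome_bp = 1e6)
  expect_equal(res$genic[region == "genic", n_sv], 1L)       # intron DEL
  expect_equal(res$genic[region == "non-genic", n_sv], 1L)
  expect_equal(res$features[feature == "intron", n_sv], 1L)
  expect_equal(res$features[feature == "exon", n_sv], 0L)
  # adjusted counts are raw / (class Mb): 10 in 1 Mb vs 10 in 4 Mb
  expect_equal(res$genic$sv_per_mb,
               res$genic$n_sv / (res$genic$total_bp / 1e6))
  # overlapping gene models are rejected
  gm_bad <- rbind(gm, data.table::data.table(
    seqid = "chr01", type = "gene", start = 2000L, end = 2500L,
    strand = "+", ID = "g2", Parent = NA_character_))
  expect_error(genic_feature_overlap(cat_, gm_bad), "overlap")
})

test_that("load inside vs outside SV genes: no-SV edge case and brute force", {
  gm <- data.table::rbindlist(lapply(1:5, function(g)
    data.table::data.table(
      seqid = "chr01", type = "gene", start = g * 10000L,
      end = g * 10000L + 2000L, strand = "+",
      ID = sprintf("g%d", g), Parent = NA_character_)))
  # SNPs: 2 per gene (one del, one neutral), all dosage 2
  pos <- as.integer(unlist(lapply(1:5, function(g)
    c(g * 10000L + 10L, g * 10000L + 20L))))
  d <- matrix(2L, nrow = 10, ncol = 4)
  pol <- make_pol(d, pos = pos)
  cats <- make_categories(pol, rep(c("deleterious", "neutral-nonsynonymous"),
                                   5))
  # no SVs: all genes outside, inside undefined
  empty_cat <- data.table::data.table(sv_id = character(), chrom = character(),
                                      start = integer(), end = integer(),
                                      chrom2 = character(), type = character())
  res0 <- load_in_sv_vs_outside(empty_cat, pol, cats, gm)
  expect_true(all(is.na(res0$per_accession$ratio_inside)))
  expect_equal(res0$per_accession$ratio_outside, rep(1, 4))
  # SV over genes 1-2: inside ratio from genes 1-2, outside from 3-5
  cat_ <- data.table::data.table(sv_id = "s1", chrom = "chr01",
                                 start = 9000L, end = 23000L,
                                 chrom2 = NA_character_, type = "DUP")
  res1 <- load_in_sv_vs_outside(cat_, pol, cats, gm)
  expect_equal(res1$per_accession$ratio_inside, rep(1, 4))
  expect_equal(res1$per_accession$ratio_outside, rep(1, 4))
})

test_that("long-read concordance: identity, disjoint and planted 70%", {
  set.seed(90)
  svs <- data.table::data.table(
    chrom = "chr01", start = seq(1000L, 10000L, by = 1000L),
    end = seq(1400L, 10400L, by = 1000L), chrom2 = NA_character_,
    type = "DEL")
  expect_equal(longread_concordance(svs, svs)$fraction, 1.0)
  far <- data.table::copy(svs)[, chrom := "chr02"]
  expect_equal(longread_concordance(svs, far)$fraction, 0.0)
  # planted 70%: 7 of 10 matched within 100 bp, 3 displaced far away
  long <- data.table::copy(svs)
  long[8:10, `:=`(start = start + 5000L, end = end + 5000L)]
  long[1:7, `:=`(start = start + sample(-30:30, 7),
                 end = end + sample(-30:30, 7))]
  expect_equal(longread_concordance(svs, long)$fraction, 0.70)
  # empty short set undefined
  expect_true(is.na(longread_concordance(svs[0], long)$fraction))
})
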