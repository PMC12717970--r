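# Fixture builders used across the test files. Everything is constructed in
# code; no binary fixtures.

# genotype_matrix from a dosage matrix (sites x accessions)
make_gm <- function(dosage, chrom = NULL, pos = NULL, ref = "A", alt = "G") {
  n <- nrow(dosage)
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("S%02d", seq_len(ncol(dosage)))
  sites <- data.table::data.table(
    chrom = chrom %||% rep("chr01", n),
    pos = pos %||% (seq_len(n) * 10L),
    ref = rep(ref, length.out = n), alt = rep(alt, length.out = n),
    site_id = paste0("v", seq_len(n)),
    multiallelic = FALSE, indel = FALSE)
  tomload:::new_genotype_matrix(dosage, sites, colnames(dosage))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# assignment table with outgroup attribute
make_assignment <- function(accessions, populations, outgroup) {
  dt <- data.table::data.table(accession = accessions,
                               population = populations)
  data.table::setattr(dt, "outgroup", outgroup)
  dt
}

# polarized_sites straight from a derived-dosage matrix: appends an
# all-ancestral outgroup column and polarizes (REF = ancestral everywhere,
# so derived dosage equals the input dosage)
make_pol <- function(dosage, populations = NULL, chrom = NULL, pos = NULL) {
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("S%02d", seq_len(ncol(dosage)))
  populations <- populations %||% rep("P1", ncol(dosage))
  full <- cbind(dosage, OUT = 0L)
  gm <- make_gm(full, chrom = chrom, pos = pos)
  asn <- make_assignment(colnames(full), c(populations, "OUT"), "OUT")
  polarize(gm, asn)
}

# category table aligned to a polarized object
make_categories <- function(pol, categories) {
  data.table::data.table(chrom = pol$sites$chrom, pos = pol$sites$pos,
                         category = categories,
                         sift_label = NA_character_,
                         provean_score = NA_real_)
}

# random dosage matrix
random_dosage <- function(n_sites, n_acc, p_missing = 0,
                          probs = c(0.5, 0.3, 0.2)) {
  d <- matrix(sample(0:2, n_sites * n_acc, replace = TRUE, prob = probs),
              nrow = n_sites)
  if (p_missing > 0)
    d[runif(length(d)) < p_missing] <- NA_integer_
  colnames(d) <- sprintf("S%02d", seq_len(n_acc))
  d
}

# write a small VCF from raw text lines (header built here)
write_test_vcf <- function(body_lines, samples, path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr01>", "##contig=<ID=chr02>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body_lines), path)
  path
}

# random SV call table for clustering tests: calls concentrated so that
# chains and ties actually occur
random_sv_calls <- function(n = 50, n_chrom = 2, span = 4000,
                            types = c("DEL", "DUP", "INV", "TRA")) {
  type <- sample(types, n, replace = TRUE)
  chrom <- sprintf("chr%02d", sample.int(n_chrom, n, replace = TRUE))
  start <- sample.int(span, n, replace = TRUE)
  len <- sample(30:500, n, replace = TRUE)
  chrom2 <- ifelse(type == "TRA",
                   sprintf("chr%02d", sample.int(n_chrom, n, replace = TRUE)),
                   NA_character_)
  end <- ifelse(type == "TRA", sample.int(span, n, replace = TRUE),
                start + len - 1L)
  data.table::data.table(
    accession = sample(sprintf("ACC%02d", 1:4), n, replace = TRUE),
    caller = sample(c("callerA", "callerB", "callerC"), n, replace = TRUE),
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    chrom2 = chrom2, type = type)
}
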