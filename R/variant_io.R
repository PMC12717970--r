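## VCF ingestion, accession/site filtering, imputation and polarization.
##
## Genotypes travel as a sites x accessions integer dosage matrix in
## {0, 1, 2, NA} counting ALT copies (unphased; phase is never used).
## Coordinates are 1-based as in VCF; windowing converts to half-open
## intervals internally.

new_genotype_matrix <- function(dosage, sites, accessions, imputed = NULL) {
  stopifnot(nrow(dosage) == nrow(sites), ncol(dosage) == length(accessions))
  structure(list(dosage = dosage, sites = sites, accessions = accessions,
                 imputed = imputed),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d accessions (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

## GT strings -> ALT dosage; anything not made of alleles in {0, 1, .}
## separated by / or | is NA (multiallelic GTs and malformed strings alike)
gt_to_dosage <- function(gt) {
  g <- gsub("\\|", "/", gt)
  map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  d <- unname(map[g])
  dim(d) <- dim(gt)
  dimnames(d) <- dimnames(gt)
  d
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Records are preserved in file order. Multiallelic and indel records are
#' retained but flagged for [filter_sites()]; GT strings that cannot be
#' parsed as diploid 0/1 genotypes (including multiallelic calls) become
#' missing, with a warning giving the count of malformed entries.
#'
#' @param path Path to a VCF (v4.x) with a GT FORMAT field.
#' @return A `genotype_matrix`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stopf("cannot read VCF: %s", path)
  vcf <- VariantAnnotation::readVcf(path)
  if (ncol(vcf) == 0) stopf("VCF has no samples: %s", path)
  if (anyDuplicated(colnames(vcf)))
    stopf("duplicate sample names in VCF: %s", path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stopf("VCF has no GT field: %s", path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt_list)
  ul <- as.character(BiocGenerics::unlist(alt_list))
  ends <- cumsum(n_alt)
  alt_chr <- character(length(n_alt))
  single <- n_alt == 1
  alt_chr[single] <- ul[ends[single]]
  for (i in which(n_alt > 1))
    alt_chr[i] <- paste(ul[(ends[i] - n_alt[i] + 1):ends[i]], collapse = ",")
  ref_chr <- as.character(VariantAnnotation::ref(vcf))
  sites <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = ref_chr, alt = alt_chr,
    site_id = names(rr) %||% paste0("v", seq_along(rr)),
    multiallelic = n_alt > 1,
    indel = nchar(ref_chr) != 1 |
      vapply(strsplit(alt_chr, ","), function(a) any(nchar(a) != 1), TRUE))
  dos <- gt_to_dosage(gt)
  ## distinguish genuinely missing ./. from malformed entries for the log
  ok_missing <- gsub("\\|", "/", gt) %in% c("./.", ".")
  n_bad <- sum(is.na(dos) & !ok_missing & !sites$multiallelic)
  if (n_bad > 0)
    warnf("%d malformed GT entries set to missing", n_bad)
  new_genotype_matrix(dos, sites, colnames(gt))
}

#' Write a genotype matrix as VCF v4.2
#' @param gm A `genotype_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2", "##source=tomload"), con)
  for (cc in unique(gm$sites$chrom))
    writeLines(sprintf("##contig=<ID=%s>", cc), con)
  writeLines(
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">", con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$accessions), collapse = "\t"), con)
  gt <- matrix("./.", nrow = nrow(gm$dosage), ncol = ncol(gm$dosage))
  idx <- !is.na(gm$dosage)
  gt[idx] <- c("0/0", "0/1", "1/1")[gm$dosage[idx] + 1L]
  body <- cbind(gm$sites$chrom, gm$sites$pos, gm$sites$site_id, gm$sites$ref,
                gm$sites$alt, ".", ".", ".", "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

subset_sites <- function(gm, keep) {
  new_genotype_matrix(gm$dosage[keep, , drop = FALSE],
                      gm$sites[keep], gm$accessions,
                      if (!is.null(gm$imputed)) gm$imputed[keep, , drop = FALSE])
}

#' Remove accessions with excessive missing data
#'
#' Accessions whose missing-genotype fraction is strictly greater than
#' `max_missing` are dropped (an accession at exactly the threshold is
#' retained). The site set is unchanged.
#'
#' @param gm A `genotype_matrix`.
#' @param max_missing Missingness threshold in \[0,1\]; default 0.25.
#' @return Filtered `genotype_matrix`; removals are reported via `message()`.
#' @export
filter_accessions <- function(gm, max_missing = 0.25) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  frac <- colMeans(is.na(gm$dosage))
  drop <- frac > max_missing
  if (all(drop)) stopf("all accessions exceed %.0f%% missing data",
                       100 * max_missing)
  if (any(drop))
    message(sprintf("filter_accessions: removed %d accession(s): %s",
                    sum(drop), paste(gm$accessions[drop], collapse = ", ")))
  new_genotype_matrix(gm$dosage[, !drop, drop = FALSE], gm$sites,
                      gm$accessions[!drop],
                      if (!is.null(gm$imputed)) gm$imputed[, !drop, drop = FALSE])
}

#' Keep biallelic SNP records only
#'
#' Removes indels (REF or any ALT allele longer than one base) and
#' multiallelic records; for duplicated (chrom, pos) keys the first record
#' is kept and the rest are dropped with a message.
#'
#' @param gm A `genotype_matrix`.
#' @return Filtered `genotype_matrix`.
#' @export
filter_sites <- function(gm) {
  keep <- !gm$sites$indel & !gm$sites$multiallelic
  key <- site_key(gm$sites$chrom, gm$sites$pos)
  dup <- duplicated(key)
  if (any(dup & keep))
    message(sprintf("filter_sites: dropped %d duplicate position record(s)",
                    sum(dup & keep)))
  keep <- keep & !dup
  if (!any(keep)) stopf("no sites left after SNP filtering")
  n_rm <- sum(!keep)
  if (n_rm > 0)
    message(sprintf("filter_sites: removed %d non-SNP/duplicate record(s)",
                    n_rm))
  subset_sites(gm, keep)
}

#' Impute missing genotypes by per-site mode
#'
#' A deliberately simple, deterministic stand-in for LD-based imputation:
#' each missing call is replaced by the modal dosage at its site, ties
#' resolved toward the lower dosage. Imputed cells are flagged in the
#' `imputed` matrix of the result.
#'
#' @param gm A `genotype_matrix`.
#' @return `genotype_matrix` with no missing values.
#' @export
impute_missing <- function(gm) {
  dos <- gm$dosage
  imputed <- is.na(dos)
  need <- which(rowSums(imputed) > 0)
  for (i in need) {
    row <- dos[i, ]
    obs <- row[!is.na(row)]
    if (length(obs) == 0)
      stopf("site %s:%d has no observed genotypes; cannot impute",
            gm$sites$chrom[i], gm$sites$pos[i])
    tab <- tabulate(obs + 1L, nbins = 3L)
    mode_d <- which.max(tab) - 1L   # which.max returns first max: lower wins
    dos[i, is.na(row)] <- mode_d
  }
  new_genotype_matrix(dos, gm$sites, gm$accessions, imputed)
}

#' Polarize alleles against the outgroup accession
#'
#' The allele carried homozygously by the outgroup is taken as ancestral and
#' the other allele as derived. Sites where the outgroup call is missing or
#' heterozygous (or the record is multiallelic) are retained with a
#' diagnostic status and their derived dosages set to missing, which
#' excludes them from every downstream count and spectrum.
#'
#' @param gm A `genotype_matrix` (biallelic SNPs; run [filter_sites()] first).
#' @param assignment Population assignment `data.table` from
#'   [read_assignment()] (attribute `outgroup` set), or any data.frame with
#'   accession/population columns plus an `outgroup` attribute.
#' @return A `polarized_sites` object: `sites` gains ancestral/derived/status
#'   columns; `dosage` becomes the derived-allele dosage.
#' @export
polarize <- function(gm, assignment) {
  outgroup <- attr(assignment, "outgroup")
  if (is.null(outgroup)) stopf("assignment carries no outgroup attribute")
  if (!outgroup %in% gm$accessions)
    stopf("outgroup accession '%s' absent from genotype matrix", outgroup)
  og <- gm$dosage[, outgroup]
  status <- rep("ok", nrow(gm$sites))
  status[is.na(og)] <- "outgroup_missing"
  status[!is.na(og) & og == 1] <- "outgroup_het"
  status[gm$sites$multiallelic] <- "outgroup_third_allele"
  flip <- !is.na(og) & og == 2 & status == "ok"

  sites <- data.table::copy(gm$sites)
  sites[, ancestral := ifelse(status == "ok",
                              ifelse(flip, alt, ref), NA_character_)]
  sites[, derived := ifelse(status == "ok",
                            ifelse(flip, ref, alt), NA_character_)]
  sites[, polarization_status := status]

  dos <- gm$dosage
  dos[flip, ] <- 2L - dos[flip, , drop = FALSE]
  dos[status != "ok", ] <- NA_integer_

  structure(list(sites = sites, dosage = dos, accessions = gm$accessions,
                 outgroup = outgroup,
                 assignment = data.table::as.data.table(assignment)),
            class = "polarized_sites")
}

#' @export
print.polarized_sites <- function(x, ...) {
  cat(sprintf("polarized_sites: %d sites (%d ok) x %d accessions\n",
              nrow(x$sites), sum(x$sites$polarization_status == "ok"),
              length(x$accessions)))
  invisible(x)
}

## accession columns that belong to study populations (outgroup excluded)
ingroup_accessions <- function(pol) {
  setdiff(pol$accessions, pol$outgroup)
}

subset_polarized <- function(pol, keep) {
  structure(list(sites = pol$sites[keep],
                 dosage = pol$dosage[keep, , drop = FALSE],
                 accessions = pol$accessions, outgroup = pol$outgroup,
                 assignment = pol$assignment),
            class = "polarized_sites")
}

#' Minor-allele-frequency filter
#'
#' Removes sites whose minor-allele frequency, computed over non-missing
#' dosages of the non-outgroup accessions, is strictly below `min_maf`
#' (a site at exactly the threshold is retained). Monomorphic sites have
#' MAF 0 and are removed for any positive threshold.
#'
#' @param x A `polarized_sites` or `genotype_matrix`.
#' @param min_maf Threshold in \[0, 0.5\].
#' @return Object of the same class with low-MAF sites removed.
#' @export
maf_filter <- function(x, min_maf = 0.001) {
  stopifnot(min_maf >= 0, min_maf <= 0.5)
  if (min_maf == 0) return(x)
  if (inherits(x, "polarized_sites")) {
    cols <- ingroup_accessions(x)
    f <- daf_vector(x$dosage[, cols, drop = FALSE])
    maf <- pmin(f, 1 - f)
    keep <- !is.na(maf) & maf >= min_maf
    ## non-ok sites carry NA dosage; keep them (they are already excluded
    ## from counts) so their status bookkeeping survives
    keep <- keep | x$sites$polarization_status != "ok"
    subset_polarized(x, keep)
  } else if (inherits(x, "genotype_matrix")) {
    f <- daf_vector(x$dosage)
    maf <- pmin(f, 1 - f)
    keep <- !is.na(maf) & maf >= min_maf
    subset_sites(x, keep)
  } else stopf("maf_filter: unsupported input class")
}
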