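## Internal helpers shared across modules.

#' Functional categories used throughout the package
#'
#' The four mutually exclusive site categories: `non-coding`, `synonymous`,
#' `neutral-nonsynonymous` and `deleterious` (nonsynonymous and predicted
#' damaging by both annotation sources).
#'
#' @return Character vector of the four category labels, in canonical order.
#' @export
load_categories <- function() {
  c("non-coding", "synonymous", "neutral-nonsynonymous", "deleterious")
}

site_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## deterministic integer allocation of n items to proportions p
## (largest-remainder method; sizes are exact, not multinomial draws)
allocate_counts <- function(n, p) {
  stopifnot(abs(sum(p) - 1) < 1e-9)
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    take <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

## derived-allele frequency per site within one set of accession columns;
## dosage is a sites x accessions matrix in {0,1,2,NA}
daf_vector <- function(dosage) {
  n_called <- rowSums(!is.na(dosage))
  ifelse(n_called > 0, rowSums(dosage, na.rm = TRUE) / (2 * n_called), NA_real_)
}

## write a data.frame/data.table as TSV with optional '#' provenance header
write_tsv <- function(x, path, header_lines = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
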