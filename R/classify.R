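## Functional classification of polarized sites from SIFT-style and
## PROVEAN-style annotation tables.
##
## The decision rule: a nonsynonymous site is deleterious only when BOTH
## sources agree - the SIFT-style label is in the deleterious class
## ("DELETERIOUS" or any label containing "Low confidence") AND the
## PROVEAN-style score is strictly below -2.5. Nonsynonymous sites failing
## either arm are neutral-nonsynonymous; SIFT-synonymous sites are
## synonymous; sites absent from the SIFT table are non-coding.

PROVEAN_DELETERIOUS_CUTOFF <- -2.5

sift_is_deleterious_label <- function(label) {
  !is.na(label) & (label == "DELETERIOUS" |
                     grepl("low confidence", label, ignore.case = TRUE))
}

#' Read a SIFT-style annotation table
#'
#' Expected TSV columns: `chrom`, `pos`, and at least `substitution_type`
#' (SYNONYMOUS/NONSYNONYMOUS) and `label`; `ref`/`alt`/`region_type` are
#' carried through when present. Sites may appear at most once.
#'
#' @param path TSV path.
#' @return `data.table` keyed by chrom, pos.
#' @export
read_sift_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  req <- c("chrom", "pos", "substitution_type", "label")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stopf("SIFT table %s lacks column(s): %s", path, paste(miss, collapse = ", "))
  bad <- which(!dt$substitution_type %in% c("SYNONYMOUS", "NONSYNONYMOUS"))
  if (length(bad))
    stopf("SIFT table %s: malformed substitution_type at line %d", path,
          bad[1] + 1L)
  if (anyDuplicated(dt[, .(chrom, pos)]))
    stopf("SIFT table %s: duplicate site keys", path)
  data.table::setkey(dt, chrom, pos)
  dt
}

#' Read a PROVEAN-style score table
#'
#' Expected TSV columns: `chrom`, `pos`, `score` (numeric).
#'
#' @param path TSV path.
#' @return `data.table` keyed by chrom, pos.
#' @export
read_provean_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  req <- c("chrom", "pos", "score")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stopf("PROVEAN table %s lacks column(s): %s", path,
          paste(miss, collapse = ", "))
  if (!is.numeric(dt$score)) {
    bad <- which(is.na(suppressWarnings(as.numeric(dt$score))))
    stopf("PROVEAN table %s: non-numeric score at line %d", path,
          if (length(bad)) bad[1] + 1L else NA_integer_)
  }
  if (anyDuplicated(dt[, .(chrom, pos)]))
    stopf("PROVEAN table %s: duplicate site keys", path)
  data.table::setkey(dt, chrom, pos)
  dt
}

#' Assign every polarized site to a functional category
#'
#' Applies the two-source intersection rule described above to all sites of
#' a [polarize()] result (or any table with chrom/pos columns). Sites absent
#' from the SIFT table are non-coding (count reported); nonsynonymous sites
#' lacking a PROVEAN score cannot satisfy the "both sources" requirement and
#' are neutral-nonsynonymous (count reported). A PROVEAN score attached to a
#' non-nonsynonymous site is ignored with a warning. The score boundary is
#' strict: exactly -2.5 is NOT deleterious.
#'
#' @param sift `data.table` from [read_sift_table()] (or same columns).
#' @param provean `data.table` from [read_provean_table()].
#' @param polarized A `polarized_sites` object, or a data.frame with
#'   chrom/pos columns.
#' @return `data.table(chrom, pos, category, sift_label, provean_score)`,
#'   one row per input site, in input order.
#' @export
classify_sites <- function(sift, provean, polarized) {
  st <- if (inherits(polarized, "polarized_sites")) polarized$sites
        else data.table::as.data.table(polarized)
  out <- data.table::data.table(chrom = st$chrom, pos = st$pos)
  sift <- data.table::as.data.table(sift)
  provean <- data.table::as.data.table(provean)
  out[, sift_sub := sift[out, on = c("chrom", "pos"), x.substitution_type]]
  out[, sift_label := sift[out, on = c("chrom", "pos"), x.label]]
  out[, provean_score := provean[out, on = c("chrom", "pos"), x.score]]

  n_unannotated <- sum(is.na(out$sift_sub))
  if (n_unannotated > 0)
    message(sprintf(
      "classify_sites: %d site(s) absent from the SIFT table -> non-coding",
      n_unannotated))
  n_orphan_score <- sum(!is.na(out$provean_score) &
                          (is.na(out$sift_sub) | out$sift_sub != "NONSYNONYMOUS"))
  if (n_orphan_score > 0)
    warnf("%d PROVEAN score(s) attached to non-nonsynonymous sites; ignored",
          n_orphan_score)

  nonsyn <- !is.na(out$sift_sub) & out$sift_sub == "NONSYNONYMOUS"
  n_noscore <- sum(nonsyn & is.na(out$provean_score))
  if (n_noscore > 0)
    message(sprintf(
      "classify_sites: %d nonsynonymous site(s) without PROVEAN score -> neutral",
      n_noscore))
  deleterious <- nonsyn & sift_is_deleterious_label(out$sift_label) &
    !is.na(out$provean_score) &
    out$provean_score < PROVEAN_DELETERIOUS_CUTOFF

  out[, category := data.table::fifelse(
    deleterious, "deleterious",
    data.table::fifelse(nonsyn, "neutral-nonsynonymous",
      data.table::fifelse(!is.na(sift_sub) & sift_sub == "SYNONYMOUS",
                          "synonymous", "non-coding")))]
  tab <- table(factor(out$category, levels = load_categories()))
  message(sprintf("classify_sites: %s",
                  paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                        collapse = ", ")))
  out[, sift_sub := NULL]
  out[]
}
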