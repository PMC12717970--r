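## Structural-variant consensus, collapsing, filtering, polarization and
## gene-feature overlap.
##
## Merging criterion (the SURVIVOR-style rule): two calls of the same type
## on the same chromosome are linked when their start positions are within
## `max_dist` bp and their length ratio min/max is at least `min_overlap`;
## translocations (TRA) instead require both breakpoints within `max_dist`
## and matching partner chromosomes, with no length criterion. Clusters are
## single-linkage (transitive closure of links); the representative
## coordinates are the member-wise medians.

sv_length <- function(dt) {
  ifelse(dt$type == "TRA", NA_integer_, dt$end - dt$start + 1L)
}

## single-linkage clustering of SV calls; returns integer cluster ids
## aligned with the input rows
sv_cluster_ids <- function(dt, max_dist = 100, min_overlap = 0.9) {
  n <- nrow(dt)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <<- rj }
  grp_key <- paste(dt$type, dt$chrom,
                   ifelse(dt$type == "TRA", as.character(dt$chrom2), ""))
  len <- sv_length(dt)
  for (idx in split(seq_len(n), grp_key)) {
    o <- idx[order(dt$start[idx])]
    for (a in seq_along(o)) {
      i <- o[a]
      b <- a - 1L
      while (b >= 1L) {
        j <- o[b]
        if (dt$start[i] - dt$start[j] > max_dist) break
        linked <- if (dt$type[i] == "TRA") {
          abs(dt$end[i] - dt$end[j]) <= max_dist
        } else {
          min(len[i], len[j]) / max(len[i], len[j]) >= min_overlap
        }
        if (linked) unite(i, j)
        b <- b - 1L
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots))
}

#' Read per-accession, per-caller SV VCFs
#'
#' Accepts a manifest `data.table(accession, caller, path)`. Records need an
#' SVTYPE INFO key (otherwise skipped with a warning); the end coordinate
#' comes from END, or from `start + |SVLEN|` when only SVLEN is present.
#' Insertions are dropped with a logged count; BND records are normalised to
#' TRA breakpoint pairs using the breakend ALT syntax. Duplicate calls
#' (identical span and type within one caller) are deduplicated.
#'
#' @param manifest `data.frame` with columns accession, caller, path.
#' @return `data.table`: accession, caller, chrom, start, end, chrom2, type.
#' @export
read_caller_vcfs <- function(manifest) {
  manifest <- data.table::as.data.table(manifest)
  stopifnot(all(c("accession", "caller", "path") %in% names(manifest)))
  out <- list()
  n_ins <- 0L
  for (i in seq_len(nrow(manifest))) {
    vcf <- VariantAnnotation::readVcf(manifest$path[i])
    if (nrow(vcf) == 0) next
    info <- VariantAnnotation::info(vcf)
    rr <- SummarizedExperiment::rowRanges(vcf)
    chrom <- as.character(GenomicRanges::seqnames(rr))
    start <- GenomicRanges::start(rr)
    svtype <- if ("SVTYPE" %in% names(info)) as.character(info$SVTYPE)
              else rep(NA_character_, length(rr))
    endv <- if ("END" %in% names(info)) suppressWarnings(as.integer(info$END))
            else rep(NA_integer_, length(rr))
    svlen <- if ("SVLEN" %in% names(info)) {
      sl <- info$SVLEN
      if (is.list(sl) || methods::is(sl, "List"))
        vapply(as.list(sl), function(v) if (length(v)) as.integer(v[[1]])
               else NA_integer_, 1L)
      else as.integer(sl)
    } else rep(NA_integer_, length(rr))
    chrom2 <- if ("CHR2" %in% names(info)) as.character(info$CHR2)
              else rep(NA_character_, length(rr))

    skip_no_type <- is.na(svtype)
    if (any(skip_no_type))
      warnf("%s: %d record(s) without SVTYPE skipped", manifest$path[i],
            sum(skip_no_type))
    ins <- !is.na(svtype) & svtype == "INS"
    n_ins <- n_ins + sum(ins)

    ## BND -> TRA breakpoint pairs via breakend ALT syntax
    is_bnd <- !is.na(svtype) & svtype == "BND"
    if (any(is_bnd)) {
      altc <- vapply(as.list(VariantAnnotation::alt(vcf)), function(a)
        if (length(a)) as.character(a[[1]]) else "", "")
      mt <- regmatches(altc, regexpr("[][]([^:]+):([0-9]+)[][]", altc))
      mate_chrom <- sub("^[][]([^:]+):.*$", "\\1", mt)
      mate_pos <- as.integer(sub("^.*:([0-9]+)[][]$", "\\1", mt))
      k <- which(is_bnd)
      chrom2[k] <- mate_chrom[seq_along(k)]
      endv[k] <- mate_pos[seq_along(k)]
      svtype[k] <- "TRA"
    }
    endv <- ifelse(is.na(endv) & !is.na(svlen), start + abs(svlen), endv)

    keep <- !skip_no_type & !ins & svtype %in% c("DEL", "DUP", "INV", "TRA") &
      !is.na(endv)
    if (!any(keep)) next
    out[[length(out) + 1]] <- data.table::data.table(
      accession = manifest$accession[i], caller = manifest$caller[i],
      chrom = chrom[keep], start = start[keep], end = endv[keep],
      chrom2 = chrom2[keep], type = svtype[keep])
  }
  if (n_ins > 0)
    message(sprintf("read_caller_vcfs: dropped %d insertion record(s)", n_ins))
  calls <- data.table::rbindlist(out)
  if (nrow(calls)) {
    calls <- unique(calls,
                    by = c("accession", "caller", "chrom", "start", "end",
                           "chrom2", "type"))
    data.table::setorder(calls, accession, caller, chrom, start, end, type,
                         na.last = TRUE)
  }
  calls[]
}

cluster_representative <- function(dt, ids) {
  memb <- data.table::data.table(dt, .cluster = ids)
  memb[, .(
    chrom = chrom[1],
    start = as.integer(round(median(start))),
    end = as.integer(round(median(end))),
    chrom2 = chrom2[1], type = type[1],
    n_callers = data.table::uniqueN(caller),
    callers = paste(sort(unique(caller)), collapse = ","),
    n_members = .N), by = .cluster]
}

#' Two-of-three caller consensus within one accession
#'
#' Clusters one accession's calls from all callers and keeps clusters
#' supported by at least `min_callers` distinct callers whose representative
#' span is at least `min_size` bp (translocations have no size criterion).
#'
#' @param calls `data.table` from [read_caller_vcfs()] (one or more
#'   accessions; consensus is computed per accession).
#' @param max_dist Maximum start-position distance for merging (bp).
#' @param min_overlap Minimum length ratio min/max for merging.
#' @param min_size Minimum representative SV length (bp).
#' @param min_callers Minimum number of distinct supporting callers.
#' @return `data.table`: accession, chrom, start, end, chrom2, type,
#'   n_callers, callers.
#' @export
consensus_per_accession <- function(calls, max_dist = 100, min_overlap = 0.9,
                                    min_size = 30, min_callers = 2) {
  calls <- data.table::as.data.table(calls)
  out <- list()
  for (acc in unique(calls$accession)) {
    cc <- calls[accession == acc]
    data.table::setorder(cc, chrom, start, end, type, caller, na.last = TRUE)
    ids <- sv_cluster_ids(cc, max_dist, min_overlap)
    rep_ <- cluster_representative(cc, ids)
    rep_ <- rep_[n_callers >= min_callers]
    rep_ <- rep_[type == "TRA" | (end - start + 1L) >= min_size]
    if (nrow(rep_)) {
      rep_[, accession := acc]
      out[[length(out) + 1]] <- rep_[, .(accession, chrom, start, end,
                                         chrom2, type, n_callers, callers)]
    }
  }
  res <- data.table::rbindlist(out)
  if (nrow(res))
    data.table::setorder(res, chrom, start, end, type, accession,
                         na.last = TRUE)
  res[]
}

#' Collapse per-accession consensus SVs into a population catalogue
#'
#' Applies the same merging rule across accessions; each catalogue entry
#' carries a presence/absence genotype per accession (SV genotypes are
#' carrier flags, not diploid dosages).
#'
#' @param consensus `data.table` from [consensus_per_accession()].
#' @inheritParams consensus_per_accession
#' @return `data.table`: sv_id, chrom, start, end, chrom2, type,
#'   n_accessions, carriers (comma-joined accession names).
#' @export
collapse_across_accessions <- function(consensus, max_dist = 100,
                                       min_overlap = 0.9) {
  cc <- data.table::as.data.table(consensus)
  if (nrow(cc) == 0)
    return(data.table::data.table(sv_id = character(), chrom = character(),
                                  start = integer(), end = integer(),
                                  chrom2 = character(), type = character(),
                                  n_accessions = integer(),
                                  carriers = character()))
  data.table::setorder(cc, chrom, start, end, type, accession, na.last = TRUE)
  ids <- sv_cluster_ids(cc, max_dist, min_overlap)
  memb <- data.table::data.table(cc, .cluster = ids)
  cat_ <- memb[, .(
    chrom = chrom[1],
    start = as.integer(round(median(start))),
    end = as.integer(round(median(end))),
    chrom2 = chrom2[1], type = type[1],
    n_accessions = data.table::uniqueN(accession),
    carriers = paste(sort(unique(accession)), collapse = ",")),
    by = .cluster]
  data.table::setorder(cat_, chrom, start, end, type, na.last = TRUE)
  cat_[, sv_id := sprintf("CSV%05d", .I)]
  cat_[, .cluster := NULL]
  data.table::setcolorder(cat_, "sv_id")
  cat_[]
}

#' Frequency filter and outgroup polarization of the SV catalogue
#'
#' The presence-allele frequency of each SV is its carrier count over all
#' non-outgroup accessions; entries with minor allele frequency strictly
#' below `min_maf` are dropped. The derived state is whichever state the
#' outgroup does not show: if the outgroup carries the SV, absence is
#' derived; otherwise presence is derived.
#'
#' @param catalogue From [collapse_across_accessions()].
#' @param accessions Character vector of all genotyped accessions
#'   (including the outgroup).
#' @param outgroup Outgroup accession name.
#' @param min_maf MAF threshold (default 0.01).
#' @return Catalogue with `freq`, `maf` and `derived_state` columns.
#' @export
sv_filter_and_polarize <- function(catalogue, accessions, outgroup,
                                   min_maf = 0.01) {
  cat_ <- data.table::as.data.table(catalogue)
  if (!outgroup %in% accessions)
    stopf("outgroup '%s' not among accessions", outgroup)
  ing <- setdiff(accessions, outgroup)
  carr <- strsplit(cat_$carriers, ",", fixed = TRUE)
  n_carr <- vapply(carr, function(x) length(intersect(x, ing)), 1L)
  cat_[, freq := n_carr / length(ing)]
  cat_[, maf := pmin(freq, 1 - freq)]
  cat_[, derived_state := ifelse(
    vapply(carr, function(x) outgroup %in% x, TRUE), "absence", "presence")]
  cat_[maf >= min_maf]
}

sv_granges <- function(cat_) {
  ## TRA contributes both breakpoints as 1-bp ranges; others their span
  non_tra <- cat_[cat_$type != "TRA"]
  tra <- cat_[cat_$type == "TRA"]
  grs <- list()
  if (nrow(non_tra))
    grs[[1]] <- GenomicRanges::GRanges(
      non_tra$chrom, IRanges::IRanges(non_tra$start, non_tra$end),
      sv_id = non_tra$sv_id)
  if (nrow(tra)) {
    grs[[length(grs) + 1]] <- GenomicRanges::GRanges(
      tra$chrom, IRanges::IRanges(tra$start, width = 1), sv_id = tra$sv_id)
    grs[[length(grs) + 1]] <- GenomicRanges::GRanges(
      tra$chrom2, IRanges::IRanges(tra$end, width = 1), sv_id = tra$sv_id)
  }
  if (length(grs) == 0) return(GenomicRanges::GRanges())
  do.call(c, grs)
}

#' Genic / non-genic and per-feature SV overlap
#'
#' An SV is genic when its span overlaps any gene body by at least 1 bp
#' (translocations are attributed through each breakpoint). Feature counts
#' attribute each SV to every feature class it overlaps; adjusted counts
#' divide by the total bp of the class per Mb.
#'
#' @param catalogue SV catalogue table (needs sv_id, chrom, start, end,
#'   chrom2, type).
#' @param gene_models Long-form gene-model table from
#'   [generate_gene_models()] / [read_gene_models()].
#' @param genome_bp Total genome size in bp; default: sum over chromosomes
#'   of the largest coordinate seen in the gene models or catalogue.
#' @return List: `genic` (region, n_sv, total_bp, sv_per_mb) and
#'   `features` (feature, n_sv, total_bp, sv_per_mb).
#' @export
genic_feature_overlap <- function(catalogue, gene_models, genome_bp = NULL) {
  cat_ <- data.table::as.data.table(catalogue)
  gm <- data.table::as.data.table(gene_models)
  genes <- gm[type == "gene"]
  gene_gr <- GenomicRanges::GRanges(genes$seqid,
                                    IRanges::IRanges(genes$start, genes$end))
  if (any(GenomicRanges::countOverlaps(gene_gr, gene_gr) > 1))
    stopf("gene models overlap; the fixture guarantees disjoint genes")
  sv_gr <- sv_granges(cat_)
  genic_ids <- unique(sv_gr$sv_id[
    GenomicRanges::countOverlaps(sv_gr, gene_gr) > 0])
  n_sv <- length(unique(cat_$sv_id))
  genic_bp <- sum(genes$end - genes$start + 1)
  if (is.null(genome_bp)) {
    ext <- rbind(gm[, .(chrom = seqid, end)],
                 cat_[, .(chrom, end = pmax(start, end))])
    genome_bp <- sum(ext[, .(m = max(end)), by = chrom]$m)
  }
  nongenic_bp <- genome_bp - genic_bp
  genic <- data.table::data.table(
    region = c("genic", "non-genic"),
    n_sv = c(length(genic_ids), n_sv - length(genic_ids)),
    total_bp = c(genic_bp, nongenic_bp))
  genic[, sv_per_mb := n_sv / (total_bp / 1e6)]

  feats <- c("five_prime_UTR", "exon", "intron", "three_prime_UTR")
  frows <- lapply(feats, function(f) {
    ff <- gm[type == f]
    if (nrow(ff) == 0)
      return(data.table::data.table(feature = f, n_sv = 0L, total_bp = 0))
    fgr <- GenomicRanges::GRanges(ff$seqid, IRanges::IRanges(ff$start, ff$end))
    hit <- unique(sv_gr$sv_id[GenomicRanges::countOverlaps(sv_gr, fgr) > 0])
    data.table::data.table(feature = f, n_sv = length(hit),
                           total_bp = sum(ff$end - ff$start + 1))
  })
  features <- data.table::rbindlist(frows)
  features[, sv_per_mb := ifelse(total_bp > 0, n_sv / (total_bp / 1e6),
                                 NA_real_)]
  list(genic = genic[], features = features[])
}

#' Relative load inside vs outside SV-overlapped genes
#'
#' Genes are partitioned into SV-overlapped and SV-free (any overlap with
#' any catalogue SV, population-agnostic); SNPs are attributed to genes by
#' position. For each accession the deleterious / neutral-nonsynonymous
#' ratio is computed over the SNPs of each gene partition, and a two-sample
#' Welch t-test compares the two ratio distributions within each
#' population.
#'
#' @param catalogue SV catalogue table.
#' @param pol A `polarized_sites` object.
#' @param categories Classification from [classify_sites()].
#' @param gene_models Long-form gene-model table.
#' @param assignment Assignment table (defaults to the one in `pol`).
#' @return List: `per_accession` (accession, population, ratio_inside,
#'   ratio_outside), `ttest` (population, mean_inside, mean_outside, t_p,
#'   comparison flag).
#' @export
load_in_sv_vs_outside <- function(catalogue, pol, categories, gene_models,
                                  assignment = NULL) {
  assignment <- data.table::as.data.table(assignment %||% pol$assignment)
  gm <- data.table::as.data.table(gene_models)
  genes <- gm[type == "gene"]
  gene_gr <- GenomicRanges::GRanges(genes$seqid,
                                    IRanges::IRanges(genes$start, genes$end))
  sv_gr <- sv_granges(data.table::as.data.table(catalogue))
  sv_gene <- rep(FALSE, length(gene_gr))
  if (length(sv_gr))
    sv_gene <- GenomicRanges::countOverlaps(gene_gr, sv_gr) > 0

  cat_vec <- align_categories(pol, categories)
  ok <- pol$sites$polarization_status == "ok"
  snp_gr <- GenomicRanges::GRanges(pol$sites$chrom,
                                   IRanges::IRanges(pol$sites$pos, width = 1))
  hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr, select = "first")
  in_sv_gene <- !is.na(hits) & sv_gene[ifelse(is.na(hits), 1L, hits)]
  in_free_gene <- !is.na(hits) & !in_sv_gene

  accs <- ingroup_accessions(pol)
  ratio_over <- function(region_mask) {
    del <- which(ok & region_mask & !is.na(cat_vec) & cat_vec == "deleterious")
    neu <- which(ok & region_mask & !is.na(cat_vec) &
                   cat_vec == "neutral-nonsynonymous")
    dc <- half_count(pol$dosage[del, accs, drop = FALSE])
    nc <- half_count(pol$dosage[neu, accs, drop = FALSE])
    ifelse(nc > 0, dc / nc, NA_real_)
  }
  ri <- ratio_over(in_sv_gene)
  ro <- ratio_over(in_free_gene)
  per_acc <- data.table::data.table(accession = accs,
                                    ratio_inside = ri, ratio_outside = ro)
  per_acc[, population := assignment[per_acc, on = "accession", x.population]]
  tt <- per_acc[, {
    ok_i <- sum(!is.na(ratio_inside)) >= 2
    ok_o <- sum(!is.na(ratio_outside)) >= 2
    p <- if (ok_i && ok_o &&
             isTRUE(sd(c(ratio_inside, ratio_outside), na.rm = TRUE) > 0))
      t.test(ratio_inside, ratio_outside)$p.value else NA_real_
    .(mean_inside = mean(ratio_inside, na.rm = TRUE),
      mean_outside = mean(ratio_outside, na.rm = TRUE),
      t_p = p,
      comparison = if (!any(sv_gene) || all(sv_gene)) "undefined" else "ok")
  }, by = population]
  list(per_accession = per_acc[], ttest = tt[])
}

#' Short-read vs long-read SV concordance
#'
#' Greedy one-to-one matching: a short-read SV is matched when a same-type
#' long-read SV (same chromosome, and same partner chromosome for TRA) has
#' both breakpoints within `max_dist` bp; candidate pairs are consumed in
#' order of increasing total breakpoint distance.
#'
#' @param short,long SV tables (chrom, start, end, chrom2, type) for one
#'   sample from the two technologies.
#' @param max_dist Breakpoint tolerance in bp (default 100).
#' @return List: `fraction` (matched / n short; NA when `short` is empty),
#'   `n_short`, `n_matched`, `matches` (indices into both tables).
#' @export
longread_concordance <- function(short, long, max_dist = 100) {
  short <- data.table::as.data.table(short)
  long <- data.table::as.data.table(long)
  if (nrow(short) == 0)
    return(list(fraction = NA_real_, n_short = 0L, n_matched = 0L,
                matches = data.table::data.table()))
  cand <- list()
  for (i in seq_len(nrow(short))) {
    for (j in seq_len(nrow(long))) {
      if (short$type[i] != long$type[j]) next
      if (short$chrom[i] != long$chrom[j]) next
      if (short$type[i] == "TRA" &&
          !identical(short$chrom2[i], long$chrom2[j])) next
      ds <- abs(short$start[i] - long$start[j])
      de <- abs(short$end[i] - long$end[j])
      if (ds <= max_dist && de <= max_dist)
        cand[[length(cand) + 1]] <- data.table::data.table(
          short_idx = i, long_idx = j, dist = ds + de)
    }
  }
  if (length(cand) == 0)
    return(list(fraction = 0, n_short = nrow(short), n_matched = 0L,
                matches = data.table::data.table()))
  cand <- data.table::rbindlist(cand)
  data.table::setorder(cand, dist, short_idx, long_idx)
  used_s <- logical(nrow(short)); used_l <- logical(nrow(long))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    si <- cand$short_idx[k]; lj <- cand$long_idx[k]
    if (!used_s[si] && !used_l[lj]) {
      keep[k] <- TRUE; used_s[si] <- TRUE; used_l[lj] <- TRUE
    }
  }
  matches <- cand[keep]
  list(fraction = nrow(matches) / nrow(short), n_short = nrow(short),
       n_matched = nrow(matches), matches = matches)
}
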