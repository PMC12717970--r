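## Per-genome mutational-load measures, population comparisons,
## site-frequency spectra, private alleles and genotype-frequency tables.

## align a classification table to the site order of a polarized object
align_categories <- function(pol, categories) {
  cats <- data.table::as.data.table(categories)
  key <- data.table::data.table(chrom = pol$sites$chrom, pos = pol$sites$pos)
  cats[key, on = c("chrom", "pos"), x.category]
}

## halved-heterozygote derived count per accession for one dosage matrix
half_count <- function(dosage) {
  colSums(dosage == 2, na.rm = TRUE) + 0.5 * colSums(dosage == 1, na.rm = TRUE)
}

#' Per-genome derived-allele counts and load ratios
#'
#' For every accession, counts sites carrying derived alleles in each
#' functional category, with heterozygous sites counted one half
#' (hom-derived + 0.5 x het). Two ratio statistics follow:
#' `nonsyn_syn_ratio` = (neutral-nonsynonymous + deleterious) / synonymous,
#' and `del_neutr_ratio` (the relative mutational load) =
#' deleterious / neutral-nonsynonymous. Ratios with a zero denominator are
#' `NA`. Only sites with polarization status `ok` contribute; the outgroup
#' is excluded.
#'
#' @param pol A `polarized_sites` object.
#' @param categories Classification table from [classify_sites()].
#' @param assignment Optional assignment table (defaults to the one stored
#'   in `pol`).
#' @return `data.table`: accession, population, one count column per
#'   category, plus the two ratios.
#' @export
per_genome_counts <- function(pol, categories, assignment = NULL) {
  assignment <- data.table::as.data.table(assignment %||% pol$assignment)
  accs <- ingroup_accessions(pol)
  if (!all(accs %in% assignment$accession))
    stopf("accession(s) without population assignment: %s",
          paste(setdiff(accs, assignment$accession), collapse = ", "))
  cat_vec <- align_categories(pol, categories)
  ok <- pol$sites$polarization_status == "ok"
  res <- data.table::data.table(accession = accs)
  for (cl in load_categories()) {
    idx <- which(ok & !is.na(cat_vec) & cat_vec == cl)
    data.table::set(res, j = cl, value = if (length(idx))
      half_count(pol$dosage[idx, accs, drop = FALSE]) else 0)
  }
  nonsyn <- res[["neutral-nonsynonymous"]] + res[["deleterious"]]
  res[, nonsyn_syn_ratio :=
        ifelse(res[["synonymous"]] > 0, nonsyn / res[["synonymous"]], NA_real_)]
  res[, del_neutr_ratio :=
        ifelse(res[["neutral-nonsynonymous"]] > 0,
               res[["deleterious"]] / res[["neutral-nonsynonymous"]], NA_real_)]
  res[, population := assignment[res, on = "accession", x.population]]
  data.table::setcolorder(res, c("accession", "population"))
  res[]
}

#' Dunn's rank-based pairwise post-hoc test
#'
#' Pairwise z-statistics on mean ranks with tie correction, after a
#' Kruskal-Wallis omnibus. Two-sided p-values; the adjusted column applies
#' Bonferroni over the number of pairs.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector (coerced to factor).
#' @return `data.table`: group1, group2, z, p_raw, p_adj.
#' @export
dunn_test <- function(values, groups) {
  keep <- !is.na(values)
  values <- values[keep]
  groups <- factor(groups[keep])
  n <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_rank <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  g <- levels(groups)
  pairs <- utils::combn(g, 2)
  m <- ncol(pairs)
  z <- p_raw <- numeric(m)
  for (k in seq_len(m)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / n_g[i] + 1 / n_g[j]))
    z[k] <- (mean_rank[i] - mean_rank[j]) / se
    p_raw[k] <- 2 * pnorm(-abs(z[k]))
  }
  data.table::data.table(group1 = pairs[1, ], group2 = pairs[2, ],
                         z = z, p_raw = p_raw,
                         p_adj = pmin(1, p_raw * m))
}

## compact letter display by insert-and-absorb over a significance matrix
## sig[i, j] TRUE means groups i and j differ significantly
letter_groups <- function(sig, order_by = NULL) {
  g <- rownames(sig)
  ord <- if (is.null(order_by)) g else g[order(-order_by)]
  sets <- list(ord)
  for (i in g) for (j in g) {
    if (i < j && isTRUE(sig[i, j])) {
      new_sets <- list()
      for (s in sets) {
        if (all(c(i, j) %in% s)) {
          new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
        } else new_sets <- c(new_sets, list(s))
      }
      ## absorb sets fully contained in another
      keep <- rep(TRUE, length(new_sets))
      for (a in seq_along(new_sets)) for (b in seq_along(new_sets)) {
        if (a != b && keep[a] && keep[b] &&
            all(new_sets[[a]] %in% new_sets[[b]]) &&
            length(new_sets[[a]]) < length(new_sets[[b]]))
          keep[a] <- FALSE
      }
      new_sets <- new_sets[keep]
      sets <- unique(new_sets)
    }
  }
  ## order letter sets by the best-ranked member so 'a' is the top group
  first_pos <- vapply(sets, function(s) min(match(s, ord)), 1)
  sets <- sets[order(first_pos)]
  out <- setNames(rep("", length(g)), g)
  for (k in seq_along(sets))
    for (p in sets[[k]]) out[p] <- paste0(out[p], letters[k])
  out[ord]
}

#' Compare a per-accession statistic between populations
#'
#' Kruskal-Wallis omnibus test followed by Dunn's pairwise comparisons with
#' Bonferroni adjustment, summarised as a compact letter display:
#' populations sharing a letter are not significantly different.
#'
#' @param values Numeric vector, one value per accession.
#' @param populations Population label per value.
#' @param alpha Significance level (applied to adjusted p-values).
#' @return List: `kruskal_p`, `dunn` (pairwise table), `letters`,
#'   `n` (accessions per population used).
#' @export
compare_populations <- function(values, populations, alpha = 0.05) {
  keep <- !is.na(values)
  values <- values[keep]; populations <- as.character(populations[keep])
  cnt <- table(populations)
  small <- names(cnt)[cnt < 2]
  if (length(small)) {
    warnf("population(s) with < 2 accessions excluded: %s",
          paste(small, collapse = ", "))
    keep <- !populations %in% small
    values <- values[keep]; populations <- populations[keep]
  }
  if (length(unique(populations)) < 2)
    stopf("need >= 2 populations with >= 2 accessions each")
  kw <- kruskal.test(values, factor(populations))
  dunn <- dunn_test(values, populations)
  g <- sort(unique(populations))
  sig <- matrix(FALSE, length(g), length(g), dimnames = list(g, g))
  for (k in seq_len(nrow(dunn))) {
    s <- dunn$p_adj[k] < alpha
    sig[dunn$group1[k], dunn$group2[k]] <- s
    sig[dunn$group2[k], dunn$group1[k]] <- s
  }
  med <- tapply(values, populations, mean)[g]
  list(kruskal_p = unname(kw$p.value), dunn = dunn,
       letters = letter_groups(sig, order_by = med),
       n = table(populations))
}

## per-population derived-allele frequencies for a set of site rows
pop_daf <- function(pol, assignment, rows = NULL) {
  assignment <- data.table::as.data.table(assignment)
  pops <- setdiff(unique(assignment$population),
                  assignment$population[assignment$accession == pol$outgroup])
  rows <- rows %||% seq_len(nrow(pol$sites))
  out <- sapply(pops, function(p) {
    accs <- intersect(assignment$accession[assignment$population == p],
                      ingroup_accessions(pol))
    daf_vector(pol$dosage[rows, accs, drop = FALSE])
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = length(rows),
                                       dimnames = list(NULL, pops))
  out
}

#' Site-frequency spectra and mean derived-allele frequency per population
#'
#' For each population and each of the deleterious and neutral-nonsynonymous
#' classes: derived-allele frequencies over non-missing dosages, binned into
#' ten left-open intervals over (0, 1] (a DAF of exactly 1 falls in
#' (0.9, 1]); sites with DAF 0 in a population are excluded from that
#' population's spectrum. ADAF is the mean DAF over segregating sites of the
#' class (fixed-derived sites included). A two-sample Kolmogorov-Smirnov
#' test compares the two DAF lists; the verdict is `D<N` / `D>N` when the
#' test is significant at `alpha` (sign of the ADAF difference), `D~N`
#' otherwise, and `undefined` when either class has no segregating sites.
#'
#' @param pol A `polarized_sites` object.
#' @param categories Classification from [classify_sites()].
#' @param assignment Assignment table (defaults to the one in `pol`).
#' @param alpha Significance level for the KS verdict.
#' @return List: `spectra` (data.table population, class, bin, bin_low,
#'   bin_high, count), `summary` (population, n_del, n_neutral, adaf_del,
#'   adaf_neutral, ks_stat, ks_p, verdict), `daf` (long table of per-site
#'   DAF for the two classes).
#' @export
sfs_and_adaf <- function(pol, categories, assignment = NULL, alpha = 0.05) {
  assignment <- data.table::as.data.table(assignment %||% pol$assignment)
  cat_vec <- align_categories(pol, categories)
  ok <- pol$sites$polarization_status == "ok"
  classes <- c(deleterious = "deleterious",
               neutral = "neutral-nonsynonymous")
  daf_all <- pop_daf(pol, assignment)
  pops <- colnames(daf_all)
  breaks <- seq(0, 1, by = 0.1)
  spectra <- list(); summ <- list(); daf_long <- list()
  for (p in pops) {
    lists <- list()
    for (cl in names(classes)) {
      rows <- which(ok & !is.na(cat_vec) & cat_vec == classes[[cl]])
      d <- daf_all[rows, p]
      d <- d[!is.na(d) & d > 0]
      lists[[cl]] <- d
      bin <- cut(d, breaks = breaks, include.lowest = FALSE, right = TRUE)
      cnt <- tabulate(bin, nbins = 10)
      spectra[[length(spectra) + 1]] <- data.table::data.table(
        population = p, class = classes[[cl]], bin = seq_len(10),
        bin_low = breaks[-11], bin_high = breaks[-1], count = cnt)
      if (length(d))
        daf_long[[length(daf_long) + 1]] <- data.table::data.table(
          population = p, class = classes[[cl]], daf = d)
    }
    if (length(lists$deleterious) == 0 || length(lists$neutral) == 0) {
      verdict <- "undefined"; ks_stat <- NA_real_; ks_p <- NA_real_
    } else {
      ks <- suppressWarnings(ks.test(lists$deleterious, lists$neutral))
      ks_stat <- unname(ks$statistic); ks_p <- unname(ks$p.value)
      d_adaf <- mean(lists$deleterious) - mean(lists$neutral)
      verdict <- if (ks_p < alpha && d_adaf < 0) "D<N"
                 else if (ks_p < alpha && d_adaf > 0) "D>N"
                 else "D~N"
    }
    summ[[length(summ) + 1]] <- data.table::data.table(
      population = p,
      n_del = length(lists$deleterious), n_neutral = length(lists$neutral),
      adaf_del = if (length(lists$deleterious)) mean(lists$deleterious) else NA_real_,
      adaf_neutral = if (length(lists$neutral)) mean(lists$neutral) else NA_real_,
      ks_stat = ks_stat, ks_p = ks_p, verdict = verdict)
  }
  list(spectra = data.table::rbindlist(spectra),
       summary = data.table::rbindlist(summ),
       daf = data.table::rbindlist(daf_long))
}

#' Private-allele accounting
#'
#' A site is private to a population when its derived-allele frequency is
#' positive there and exactly zero in every other population (the outgroup
#' is not a population). Reports, for the deleterious and
#' neutral-nonsynonymous classes: the private site sets; per-accession
#' private/total proportions (halved-heterozygote weighting), computed both
#' over the sites the accession itself carries and over the sites
#' segregating in its population; per-population mean DAF of private vs
#' shared sites; and a per-population Welch t-test comparing per-accession
#' private vs shared del/neutral ratios.
#'
#' @inheritParams sfs_and_adaf
#' @return List: `private_sites`, `per_accession`, `per_population`,
#'   `ttest`.
#' @export
private_alleles <- function(pol, categories, assignment = NULL) {
  assignment <- data.table::as.data.table(assignment %||% pol$assignment)
  cat_vec <- align_categories(pol, categories)
  ok <- pol$sites$polarization_status == "ok"
  daf_all <- pop_daf(pol, assignment)
  pops <- colnames(daf_all)
  if (length(pops) < 2) stopf("private alleles need >= 2 populations")
  classes <- c("deleterious", "neutral-nonsynonymous")

  seg <- !is.na(daf_all) & daf_all > 0
  n_seg_pops <- rowSums(seg)
  private_pop <- rep(NA_character_, nrow(seg))
  one <- which(n_seg_pops == 1)
  private_pop[one] <- pops[max.col(seg[one, , drop = FALSE])]

  private_sites <- data.table::data.table(
    chrom = pol$sites$chrom, pos = pol$sites$pos, class = cat_vec,
    private_to = private_pop)[ok & class %in% classes & !is.na(private_to)]

  per_acc <- list(); per_pop <- list()
  acc_tbl <- assignment[accession %in% ingroup_accessions(pol)]
  for (cl in classes) {
    rows_cl <- which(ok & !is.na(cat_vec) & cat_vec == cl)
    for (p in pops) {
      accs <- intersect(acc_tbl$accession[acc_tbl$population == p],
                        pol$accessions)
      rows_priv <- rows_cl[!is.na(private_pop[rows_cl]) &
                             private_pop[rows_cl] == p]
      rows_seg <- rows_cl[seg[rows_cl, p]]
      rows_shared <- setdiff(rows_seg, rows_priv)
      cnt_priv <- half_count(pol$dosage[rows_priv, accs, drop = FALSE])
      cnt_all_carried <- half_count(pol$dosage[rows_cl, accs, drop = FALSE])
      per_acc[[length(per_acc) + 1]] <- data.table::data.table(
        accession = accs, population = p, class = cl,
        n_private = cnt_priv, n_all_carried = cnt_all_carried,
        prop_private_carried = ifelse(cnt_all_carried > 0,
                                      cnt_priv / cnt_all_carried, NA_real_),
        n_segregating_pop = length(rows_seg),
        n_private_pop = length(rows_priv),
        prop_private_pop = if (length(rows_seg) > 0)
          length(rows_priv) / length(rows_seg) else NA_real_)
      per_pop[[length(per_pop) + 1]] <- data.table::data.table(
        population = p, class = cl,
        n_private = length(rows_priv), n_shared = length(rows_shared),
        mean_daf_private = if (length(rows_priv))
          mean(daf_all[rows_priv, p]) else NA_real_,
        mean_daf_shared = if (length(rows_shared))
          mean(daf_all[rows_shared, p]) else NA_real_)
    }
  }
  per_acc <- data.table::rbindlist(per_acc)
  per_pop <- data.table::rbindlist(per_pop)

  ## per accession: del/neutral ratio among private vs among shared sites
  ttest <- list()
  for (p in pops) {
    accs <- acc_tbl$accession[acc_tbl$population == p]
    ratio_of <- function(rows_by_class) {
      del <- half_count(pol$dosage[rows_by_class$deleterious, accs,
                                   drop = FALSE])
      neu <- half_count(pol$dosage[rows_by_class$`neutral-nonsynonymous`, accs,
                                   drop = FALSE])
      ifelse(neu > 0, del / neu, NA_real_)
    }
    rows_priv <- lapply(setNames(classes, classes), function(cl)
      which(ok & !is.na(cat_vec) & cat_vec == cl &
              !is.na(private_pop) & private_pop == p))
    rows_shared <- lapply(setNames(classes, classes), function(cl)
      setdiff(which(ok & !is.na(cat_vec) & cat_vec == cl & seg[, p]),
              rows_priv[[cl]]))
    rp <- ratio_of(rows_priv); rs <- ratio_of(rows_shared)
    tt_p <- if (sum(!is.na(rp)) >= 2 && sum(!is.na(rs)) >= 2 &&
                isTRUE(sd(c(rp, rs), na.rm = TRUE) > 0))
      t.test(rp, rs)$p.value else NA_real_
    ttest[[length(ttest) + 1]] <- data.table::data.table(
      population = p, mean_ratio_private = mean(rp, na.rm = TRUE),
      mean_ratio_shared = mean(rs, na.rm = TRUE), t_p = tt_p)
  }
  list(private_sites = private_sites, per_accession = per_acc,
       per_population = per_pop, ttest = data.table::rbindlist(ttest))
}

#' Per-site, per-population genotype frequencies
#'
#' Frequencies of homozygous-derived, heterozygous and homozygous-ancestral
#' genotypes over the non-missing accessions of each population, for a
#' chosen subset of sites (typically all deleterious sites).
#'
#' @param pol A `polarized_sites` object.
#' @param assignment Assignment table (defaults to the one in `pol`).
#' @param site_rows Integer or logical index into the site table; default
#'   all polarization-ok sites.
#' @return `data.table`: chrom, pos, site_id, population, freq_hom_derived,
#'   freq_het, freq_hom_ancestral, n_called. Frequencies sum to 1.
#' @export
genotype_frequency_table <- function(pol, assignment = NULL, site_rows = NULL) {
  assignment <- data.table::as.data.table(assignment %||% pol$assignment)
  rows <- site_rows %||% which(pol$sites$polarization_status == "ok")
  if (is.logical(rows)) rows <- which(rows)
  pops <- setdiff(unique(assignment$population),
                  assignment$population[assignment$accession == pol$outgroup])
  out <- list()
  for (p in pops) {
    accs <- intersect(assignment$accession[assignment$population == p],
                      ingroup_accessions(pol))
    d <- pol$dosage[rows, accs, drop = FALSE]
    n <- rowSums(!is.na(d))
    out[[length(out) + 1]] <- data.table::data.table(
      chrom = pol$sites$chrom[rows], pos = pol$sites$pos[rows],
      site_id = pol$sites$site_id[rows], population = p,
      freq_hom_derived = ifelse(n > 0, rowSums(d == 2, na.rm = TRUE) / n, NA_real_),
      freq_het = ifelse(n > 0, rowSums(d == 1, na.rm = TRUE) / n, NA_real_),
      freq_hom_ancestral = ifelse(n > 0, rowSums(d == 0, na.rm = TRUE) / n, NA_real_),
      n_called = n)
  }
  data.table::rbindlist(out)
}
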