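## Windowed population statistics: nucleotide diversity, Tajima's D,
## per-window relative load, recombination-rate interpolation and the
## high/low partition test relating load to genomic correlates.
##
## Windows are anchored at position 1 of every chromosome and tile it
## without overlap; the final partial window is retained and flagged.
## Window coordinates are reported 1-based inclusive (start, end).

## extract (dosage, sites, accessions) from either container
dosage_parts <- function(x) {
  if (inherits(x, "polarized_sites"))
    list(dosage = x$dosage, sites = x$sites,
         accessions = ingroup_accessions(x), assignment = x$assignment)
  else if (inherits(x, "genotype_matrix"))
    list(dosage = x$dosage, sites = x$sites, accessions = x$accessions,
         assignment = NULL)
  else stopf("expected polarized_sites or genotype_matrix")
}

window_of <- function(pos, width) as.integer((pos - 1) %/% width)

## per-site pi: 2 j (n - j) / (n (n - 1)) with j alt/derived allele count
## over n non-missing allele calls (expected heterozygosity without
## replacement; equals the mean pairwise difference among the n haplotypes)
site_pi <- function(dosage) {
  j <- rowSums(dosage, na.rm = TRUE)
  n <- 2 * rowSums(!is.na(dosage))
  ifelse(n >= 2, 2 * j * (n - j) / (n * (n - 1)), NA_real_)
}

pop_columns <- function(parts, assignment, population) {
  intersect(assignment$accession[assignment$population == population],
            parts$accessions)
}

#' Windowed nucleotide diversity
#'
#' Per population and fixed-width window, the sum of per-site pi divided by
#' the window width in bp. Positions without a genotyped record count as
#' invariant (the standard VCF-based estimator; a documented downward bias
#' where missingness is structured). Windows with no called site get
#' pi = 0 and a flag.
#'
#' @param x A `polarized_sites` or `genotype_matrix`.
#' @param assignment Assignment table (accession, population); outgroup
#'   rows are ignored if present.
#' @param width Window width in bp (default 10 kb).
#' @return `data.table`: chrom, start, end, population, n_sites, pi,
#'   no_data flag.
#' @export
windowed_pi <- function(x, assignment = NULL, width = 1e4) {
  parts <- dosage_parts(x)
  assignment <- data.table::as.data.table(assignment %||% parts$assignment)
  pops <- setdiff(unique(assignment$population[
    assignment$accession %in% parts$accessions]), character(0))
  grid <- window_grid(parts$sites, width)
  out <- list()
  for (p in pops) {
    cols <- pop_columns(parts, assignment, p)
    if (length(cols) == 0) next
    ps <- site_pi(parts$dosage[, cols, drop = FALSE])
    dt <- data.table::data.table(chrom = parts$sites$chrom,
                                 win = window_of(parts$sites$pos, width),
                                 pi_site = ps)
    agg <- dt[, .(pi_sum = sum(pi_site, na.rm = TRUE),
                  n_sites = sum(!is.na(pi_site))), by = .(chrom, win)]
    res <- merge(grid, agg, by = c("chrom", "win"), all.x = TRUE)
    res[is.na(n_sites), `:=`(pi_sum = 0, n_sites = 0L)]
    res[, `:=`(population = p, pi = pi_sum / width,
               no_data = n_sites == 0L)]
    out[[length(out) + 1]] <- res[, .(chrom, start, end, population,
                                      n_sites, pi, no_data)]
  }
  data.table::rbindlist(out)
}

## tiling windows covering every site position
window_grid <- function(sites, width) {
  ext <- data.table::as.data.table(sites)[, .(max_pos = max(pos)), by = chrom]
  grid <- ext[, .(win = 0:window_of(max_pos, width)), by = chrom]
  grid[, `:=`(start = win * as.integer(width) + 1L,
              end = (win + 1L) * as.integer(width))]
  grid
}

tajima_constants <- function(n) {
  # n = number of sequences (haplotypes)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed Tajima's D
#'
#' Standard formulation: D = (pi_sum - S/a1) / sqrt(e1 S + e2 S (S-1)),
#' where S counts sites segregating within the population in the window and
#' the harmonic-number constants use n = 2 x the minimum per-site number of
#' non-missing diploids in the window (a conservative, deterministic choice
#' under missingness). D is undefined (NA) when S = 0 or n < 4.
#'
#' @inheritParams windowed_pi
#' @return `data.table`: chrom, start, end, population, S, n_haplotypes,
#'   tajima_d.
#' @export
windowed_tajimas_d <- function(x, assignment = NULL, width = 1e4) {
  parts <- dosage_parts(x)
  assignment <- data.table::as.data.table(assignment %||% parts$assignment)
  pops <- unique(assignment$population[
    assignment$accession %in% parts$accessions])
  grid <- window_grid(parts$sites, width)
  out <- list()
  for (p in pops) {
    cols <- pop_columns(parts, assignment, p)
    if (length(cols) == 0) next
    d <- parts$dosage[, cols, drop = FALSE]
    j <- rowSums(d, na.rm = TRUE)
    n_dip <- rowSums(!is.na(d))
    n_hap <- 2 * n_dip
    seg <- !is.na(j) & n_hap > 0 & j > 0 & j < n_hap
    dt <- data.table::data.table(
      chrom = parts$sites$chrom, win = window_of(parts$sites$pos, width),
      pi_site = site_pi(d), seg = seg, n_dip = n_dip)
    dt <- dt[n_dip > 0]
    agg <- dt[, .(pi_sum = sum(pi_site, na.rm = TRUE), S = sum(seg),
                  n_min = 2L * min(n_dip)), by = .(chrom, win)]
    agg[, tajima_d := {
      vapply(seq_len(.N), function(k) {
        S <- S[k]; n <- n_min[k]
        if (S == 0 || n < 4) return(NA_real_)
        cst <- tajima_constants(n)
        den <- sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
        if (den == 0) return(NA_real_)
        (pi_sum[k] - S / cst$a1) / den
      }, 1)
    }]
    res <- merge(grid, agg, by = c("chrom", "win"), all.x = TRUE)
    res[is.na(S), S := 0L]
    res[, population := p]
    out[[length(out) + 1]] <- res[, .(chrom, start, end, population, S,
                                      n_haplotypes = n_min,
                                      tajima_d)]
  }
  data.table::rbindlist(out)
}

#' Per-window relative mutational load
#'
#' For each accession and window: deleterious count / neutral-nonsynonymous
#' count (halved-heterozygote weighting), undefined when the accession has
#' no neutral-nonsynonymous derived alleles in the window. The population
#' mean is taken over defined values only.
#'
#' @param pol A `polarized_sites` object.
#' @param categories Classification from [classify_sites()].
#' @param assignment Assignment table (defaults to the one in `pol`).
#' @param width Window width in bp (default 100 kb).
#' @return List: `per_accession` (chrom, start, end, accession, population,
#'   del, neutral, ratio), `per_population` (population means over defined
#'   ratios).
#' @export
window_relative_load <- function(pol, categories, assignment = NULL,
                                 width = 1e5) {
  assignment <- data.table::as.data.table(assignment %||% pol$assignment)
  cat_vec <- align_categories(pol, categories)
  ok <- pol$sites$polarization_status == "ok"
  accs <- ingroup_accessions(pol)
  grid <- window_grid(pol$sites, width)
  win <- window_of(pol$sites$pos, width)
  key <- paste(pol$sites$chrom, win)
  ukey <- paste(grid$chrom, grid$win)
  del_rows <- which(ok & !is.na(cat_vec) & cat_vec == "deleterious")
  neu_rows <- which(ok & !is.na(cat_vec) & cat_vec == "neutral-nonsynonymous")
  count_by_window <- function(rows) {
    ## windows x accessions matrix of halved counts
    m <- matrix(0, nrow = nrow(grid), ncol = length(accs),
                dimnames = list(ukey, accs))
    if (length(rows)) {
      d <- pol$dosage[rows, accs, drop = FALSE]
      w <- (d == 2) + 0.5 * (d == 1)
      w[is.na(w)] <- 0
      agg <- rowsum(w, group = key[rows])
      m[rownames(agg), ] <- agg
    }
    m
  }
  del_m <- count_by_window(del_rows)
  neu_m <- count_by_window(neu_rows)
  ratio <- ifelse(neu_m > 0, del_m / neu_m, NA_real_)
  per_acc <- data.table::data.table(
    chrom = rep(grid$chrom, times = length(accs)),
    start = rep(grid$start, times = length(accs)),
    end = rep(grid$end, times = length(accs)),
    accession = rep(accs, each = nrow(grid)),
    del = as.vector(del_m), neutral = as.vector(neu_m),
    ratio = as.vector(ratio))
  per_acc[, population := assignment[per_acc, on = "accession", x.population]]
  per_pop <- per_acc[!is.na(ratio),
                     .(mean_ratio = mean(ratio), n_defined = .N),
                     by = .(chrom, start, end, population)]
  list(per_accession = per_acc[], per_population = per_pop[])
}

#' Interpolate recombination rate onto windows
#'
#' Builds a piecewise-linear genetic-position function cM(bp) per chromosome
#' from a marker map and reports, for each window,
#' (cM(end) - cM(start)) / Mb. Windows beyond the terminal markers use the
#' nearest segment's slope (linear extrapolation).
#'
#' @param map `data.table(chrom, bp, cM)`, markers strictly increasing in
#'   both columns within each chromosome.
#' @param windows `data.table(chrom, start, end)` (1-based inclusive).
#' @return `windows` with a `recomb_rate` column (cM/Mb).
#' @export
interpolate_recombination <- function(map, windows) {
  map <- data.table::as.data.table(map)
  windows <- data.table::as.data.table(windows)
  bad <- map[, .(bad = is.unsorted(bp, strictly = TRUE) ||
                   is.unsorted(cM, strictly = FALSE)), by = chrom][bad == TRUE]
  if (nrow(bad))
    stopf("genetic map not monotone on chromosome(s): %s",
          paste(bad$chrom, collapse = ", "))
  cm_at <- function(chr, q) {
    mk <- map[chrom == chr]
    if (nrow(mk) < 2) stopf("need >= 2 markers on %s", chr)
    i <- findInterval(q, mk$bp)
    i <- pmin(pmax(i, 1L), nrow(mk) - 1L)  # clamp: terminal segments extend
    slope <- (mk$cM[i + 1] - mk$cM[i]) / (mk$bp[i + 1] - mk$bp[i])
    mk$cM[i] + (q - mk$bp[i]) * slope
  }
  windows[, recomb_rate := {
    cms <- cm_at(.BY$chrom, start)
    cme <- cm_at(.BY$chrom, end)
    (cme - cms) / ((end - start) / 1e6)
  }, by = chrom]
  windows[]
}

#' Read a per-window sweep-statistic table
#'
#' SweeD-grid style TSV with columns `chrom`, `pos` (grid position) and
#' `likelihood`; the statistic is mapped onto windows by position, taking
#' the maximum over grid points falling in each window.
#'
#' @param path TSV path.
#' @param windows `data.table(chrom, start, end)`.
#' @return `windows` with a `sweep_stat` column (NA where no grid point).
#' @export
attach_sweep_stat <- function(path, windows) {
  sw <- data.table::fread(path, sep = "\t", header = TRUE)
  req <- c("chrom", "pos", "likelihood")
  if (!all(req %in% names(sw)))
    stopf("sweep table %s lacks column(s): %s", path,
          paste(setdiff(req, names(sw)), collapse = ", "))
  windows <- data.table::as.data.table(windows)
  sw[, start := pos]; sw[, end := pos]
  data.table::setkey(windows, chrom, start, end)
  ov <- data.table::foverlaps(sw, windows,
                              by.x = c("chrom", "start", "end"), nomatch = NULL)
  agg <- ov[, .(sweep_stat = max(likelihood)), by = .(chrom, start, end)]
  merge(windows, agg, by = c("chrom", "start", "end"), all.x = TRUE)
}

#' High/low partition test of load against a window statistic
#'
#' Windows are ranked by the statistic and split at the median: the top 50%
#' form the high group, ties at the cut go to the low group, and an odd
#' window count gives the low group the extra window. A two-sample Wilcoxon
#' rank-sum test then compares the load values pooled across windows within
#' each group. Load values may be per-accession (several per window, the
#' primary output) and a per-window-mean variant is reported alongside.
#'
#' @param stat `data.table(window, stat)`: one statistic value per window id.
#' @param load `data.table(window, load)`: one or more load values per
#'   window (e.g., per accession).
#' @param alpha Significance level for the s/n verdict.
#' @return List: `mean_low`, `mean_high`, `p`, `verdict` ("s"/"n"),
#'   `high_windows`, `low_windows`, and `p_window_means` for the per-window
#'   mean variant.
#' @export
high_low_partition_test <- function(stat, load, alpha = 0.05) {
  st <- data.table::as.data.table(stat)
  ld <- data.table::as.data.table(load)
  sv <- st[["stat"]]; sw <- st[["window"]]
  lv <- ld[["load"]]; lw <- ld[["window"]]
  keep <- !is.na(sv) & sw %in% unique(lw[!is.na(lv)])
  sv <- sv[keep]; sw <- sw[keep]
  n <- length(sv)
  if (n < 4) stopf("need >= 4 windows with defined statistic and load")
  if (length(unique(sv)) == 1) {
    warnf("all windows tied on the statistic; verdict 'n'")
    return(list(mean_low = NA_real_, mean_high = NA_real_, p = NA_real_,
                verdict = "n", high_windows = character(0),
                low_windows = sw, p_window_means = NA_real_))
  }
  nh <- n %/% 2L
  ord <- order(-sv, sw)
  cutval <- sv[ord[nh]]
  if (nh < n && sv[ord[nh + 1L]] == cutval) {
    high <- sw[sv > cutval]   # ties at the cut go low
  } else {
    high <- sw[ord[seq_len(nh)]]
  }
  low <- setdiff(sw, high)
  lv_high <- lv[lw %in% high & !is.na(lv)]
  lv_low <- lv[lw %in% low & !is.na(lv)]
  if (length(lv_high) == 0 || length(lv_low) == 0)
    stopf("empty high or low load group")
  wt <- suppressWarnings(wilcox.test(lv_low, lv_high))
  mh <- ld[, .(m = mean(load, na.rm = TRUE)), by = window]
  wt2 <- suppressWarnings(
    wilcox.test(mh$m[mh$window %in% low], mh$m[mh$window %in% high]))
  list(mean_low = mean(lv_low), mean_high = mean(lv_high),
       p = unname(wt$p.value),
       verdict = if (!is.na(wt$p.value) && wt$p.value < alpha) "s" else "n",
       high_windows = high, low_windows = low,
       p_window_means = unname(wt2$p.value))
}
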