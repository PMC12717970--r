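## End-to-end orchestration: one config object (or JSON file) drives
## simulate -> io -> classify -> load statistics -> windows -> SV -> report,
## writing every output table with a provenance header. Identical config +
## seed gives byte-identical tables.

#' Pipeline configuration
#'
#' Either a `simulate` block (a [sim_config()]) or a set of input paths must
#' be provided. Thresholds default to the published analysis settings:
#' accession missingness 0.25, site MAF 0.001, PROVEAN cutoff -2.5, SV
#' minimum size 30 bp, merge distance 100 bp, length-ratio 0.9, SV MAF 0.01,
#' diversity windows 10 kb, correlate windows 100 kb, alpha 0.05 with
#' Bonferroni adjustment.
#'
#' @param simulate A [sim_config()] block, or `NULL` when `inputs` given.
#' @param inputs Named list of paths: vcf, assignment, sift, provean,
#'   gene_models, genetic_map, sweep_table (optional), sv_manifest
#'   (optional data.frame accession/caller/path).
#' @param outdir Output directory.
#' @param seed Integer seed for every stochastic step.
#' @param thresholds Named list overriding individual defaults.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, inputs = NULL,
                            outdir = "tomload_out", seed = 1L,
                            thresholds = list()) {
  def <- list(max_missing = 0.25, min_maf = 0.001, provean_cutoff = -2.5,
              sv_min_size = 30, sv_max_dist = 100, sv_min_overlap = 0.9,
              sv_min_maf = 0.01, pi_window = 1e4, load_window = 1e5,
              alpha = 0.05)
  unknown <- setdiff(names(thresholds), names(def))
  if (length(unknown))
    stopf("unknown threshold(s): %s", paste(unknown, collapse = ", "))
  def[names(thresholds)] <- thresholds
  if (is.null(simulate) && is.null(inputs))
    stopf("pipeline_config: either a simulate block or inputs must be given")
  if (!is.null(simulate) && !inherits(simulate, "sim_config"))
    stopf("simulate block must be a sim_config object")
  if (!is.null(inputs)) {
    req <- c("vcf", "assignment", "sift", "provean")
    miss <- setdiff(req, names(inputs))
    if (length(miss))
      stopf("inputs lack required path(s): %s", paste(miss, collapse = ", "))
  }
  structure(list(simulate = simulate, inputs = inputs, outdir = outdir,
                 seed = as.integer(seed), thresholds = def),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(
    rapply(unclass(config), unclass, how = "replace"), tf,
    auto_unbox = TRUE, digits = NA, force = TRUE, null = "null")
  unname(tools::md5sum(tf))
}

provenance <- function(config) {
  c(sprintf("tomload %s", as.character(utils::packageVersion("tomload"))),
    sprintf("seed=%d", config$seed),
    sprintf("config_md5=%s", config_hash(config)),
    sprintf("thresholds: %s",
            paste(sprintf("%s=%g", names(config$thresholds),
                          unlist(config$thresholds)), collapse = " ")))
}

run_stage <- function(name, outdir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

simulate_inputs <- function(config, dir) {
  sim <- simulate_populations(config$simulate)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(vcf = file.path(dir, "genotypes.vcf"),
                assignment = file.path(dir, "assignment.tsv"),
                gene_models = file.path(dir, "genes.gff3"),
                genetic_map = file.path(dir, "genetic_map.tsv"),
                sweep_table = file.path(dir, "sweep.tsv"))
  write_sim_vcf(sim, paths$vcf)
  write_assignment(sim$accessions, "OUTGROUP", paths$assignment)
  ann <- emit_annotation_tables(sim, miscls_rate = 0, dir = dir)
  paths$sift <- ann$paths[["sift"]]
  paths$provean <- ann$paths[["provean"]]
  gm <- generate_gene_models(40, n_chrom = sim$config$n_chrom,
                             chrom_length = sim$config$chrom_length)
  write_gene_models(gm, paths$gene_models)
  map <- generate_genetic_map(n_markers = 12, cm_per_mb = 2,
                              n_chrom = sim$config$n_chrom,
                              chrom_length = sim$config$chrom_length)
  write_tsv(map, paths$genetic_map)
  ## synthetic sweep grid: exponential likelihoods on a regular grid
  grid_pos <- seq(1, sim$config$chrom_length, by = 5e4)
  sweep <- data.table::rbindlist(lapply(unique(sim$sites$chrom), function(cc)
    data.table::data.table(chrom = cc, pos = as.integer(grid_pos),
                           likelihood = stats::rexp(length(grid_pos)))))
  write_tsv(sweep, paths$sweep_table)
  fix <- generate_sv_fixtures(
    n_per_type = c(DEL = 12, DUP = 6, INV = 6, TRA = 4),
    n_accessions = sum(sim$accessions$population != "OUTGROUP"),
    carrier_freq = 0.4, jitter_sd = 10, dropout = 0.05, fp_per_caller = 2,
    n_chrom = sim$config$n_chrom, chrom_length = sim$config$chrom_length)
  manifest <- write_sv_fixture_vcfs(fix, file.path(dir, "sv"))
  ## SV accession names follow the simulated accessions
  accs <- sim$accessions$accession[sim$accessions$population != "OUTGROUP"]
  manifest[, accession := accs[match(accession, sprintf("ACC%02d",
                                                        seq_along(accs)))]]
  paths$sv_manifest <- manifest
  list(paths = paths, sim = sim)
}

#' Run the full pipeline
#'
#' Executes all stages in dependency order and writes the report bundle to
#' `config$outdir`: load profiles, population comparison statistics,
#' site-frequency spectra, private alleles, genotype frequencies, window
#' statistics, load-correlate partitions, and the SV catalogue with its
#' overlap and load comparisons. Each table carries a provenance header
#' (package version, seed, config hash, thresholds).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(outdir, "FAILED"))
  th <- config$thresholds
  hdr <- provenance(config)
  set.seed(config$seed)

  paths <- config$inputs
  if (!is.null(config$simulate)) {
    siminp <- run_stage("simulate", outdir,
                        simulate_inputs(config, file.path(outdir, "inputs")))
    paths <- siminp$paths
  }

  pol <- run_stage("io", outdir, {
    gm <- read_vcf(paths$vcf)
    assignment <- read_assignment(paths$assignment)
    gm <- filter_accessions(gm, th$max_missing)
    gm <- filter_sites(gm)
    gm <- impute_missing(gm)
    p <- polarize(gm, assignment)
    maf_filter(p, th$min_maf)
  })
  assignment <- pol$assignment

  categories <- run_stage("classify", outdir, {
    sift <- read_sift_table(paths$sift)
    provean <- read_provean_table(paths$provean)
    classify_sites(sift, provean, pol)
  })

  out <- list()
  run_stage("load_statistics", outdir, {
    profiles <- per_genome_counts(pol, categories)
    out$load_profiles <- write_tsv(profiles,
                                    file.path(outdir, "load_profiles.tsv"), hdr)
    cmp <- list(
      del_neutr_ratio = tryCatch(
        compare_populations(profiles$del_neutr_ratio, profiles$population,
                            th$alpha), error = function(e) NULL),
      nonsyn_syn_ratio = tryCatch(
        compare_populations(profiles$nonsyn_syn_ratio, profiles$population,
                            th$alpha), error = function(e) NULL))
    sfs <- sfs_and_adaf(pol, categories, alpha = th$alpha)
    out$sfs <- write_tsv(sfs$spectra, file.path(outdir, "sfs.tsv"), hdr)
    out$sfs_summary <- write_tsv(sfs$summary,
                                  file.path(outdir, "sfs_summary.tsv"), hdr)
    priv <- private_alleles(pol, categories)
    out$private_alleles <- write_tsv(priv$per_accession,
                                      file.path(outdir, "private_alleles.tsv"),
                                      hdr)
    del_rows <- which(pol$sites$polarization_status == "ok" &
                        align_categories(pol, categories) == "deleterious")
    gf <- genotype_frequency_table(pol, site_rows = del_rows)
    out$genotype_frequencies <- write_tsv(
      gf, file.path(outdir, "genotype_frequencies.tsv"), hdr)
    stats <- list(
      kruskal_dunn = lapply(cmp, function(x) if (is.null(x)) NULL else list(
        kruskal_p = x$kruskal_p, letters = as.list(x$letters),
        dunn = as.data.frame(x$dunn))),
      private_ttest = as.data.frame(priv$ttest),
      sfs_summary = as.data.frame(sfs$summary))
    out$stats <- file.path(outdir, "stats.json")
    jsonlite::write_json(stats, out$stats, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  })

  run_stage("windows", outdir, {
    pi10 <- windowed_pi(pol, width = th$pi_window)
    d10 <- windowed_tajimas_d(pol, width = th$pi_window)
    wstats <- merge(pi10, d10[, .(chrom, start, end, population, S, tajima_d)],
                    by = c("chrom", "start", "end", "population"))
    out$window_stats <- write_tsv(wstats,
                                   file.path(outdir, "window_stats.tsv"), hdr)

    pi100 <- windowed_pi(pol, width = th$load_window)
    wrl <- window_relative_load(pol, categories, width = th$load_window)
    wins <- unique(pi100[, .(chrom, start, end)])
    if (!is.null(paths$genetic_map)) {
      map <- data.table::fread(paths$genetic_map)
      wins <- interpolate_recombination(map, wins)
    }
    if (!is.null(paths$sweep_table))
      wins <- attach_sweep_stat(paths$sweep_table, wins)
    rows <- list()
    for (p in unique(pi100$population)) {
      loads <- wrl$per_accession[population == p & !is.na(ratio)]
      loads[, window := paste(chrom, start)]
      stat_tbls <- list(
        pi = pi100[population == p,
                   .(window = paste(chrom, start), stat = pi)])
      if ("recomb_rate" %in% names(wins))
        stat_tbls$recomb <- wins[, .(window = paste(chrom, start),
                                     stat = recomb_rate)]
      if ("sweep_stat" %in% names(wins))
        stat_tbls$sweep <- wins[, .(window = paste(chrom, start),
                                    stat = sweep_stat)]
      for (sname in names(stat_tbls)) {
        hl <- tryCatch(
          high_low_partition_test(stat_tbls[[sname]],
                                  loads[, .(window, load = ratio)], th$alpha),
          error = function(e) NULL)
        if (!is.null(hl))
          rows[[length(rows) + 1]] <- data.table::data.table(
            population = p, statistic = sname, mean_low = hl$mean_low,
            mean_high = hl$mean_high, p = hl$p, verdict = hl$verdict)
      }
    }
    out$load_correlates <- write_tsv(
      data.table::rbindlist(rows),
      file.path(outdir, "load_correlates.tsv"), hdr)
  })

  if (!is.null(paths$sv_manifest)) {
    run_stage("sv", outdir, {
      calls <- read_caller_vcfs(paths$sv_manifest)
      cons <- consensus_per_accession(calls, th$sv_max_dist,
                                      th$sv_min_overlap, th$sv_min_size)
      cat_ <- collapse_across_accessions(cons, th$sv_max_dist,
                                         th$sv_min_overlap)
      cat_ <- sv_filter_and_polarize(cat_, pol$accessions, pol$outgroup,
                                     th$sv_min_maf)
      out$sv_catalogue <- write_tsv(cat_,
                                     file.path(outdir, "sv_catalogue.tsv"),
                                     hdr)
      if (!is.null(paths$gene_models)) {
        gmod <- read_gene_models(paths$gene_models)
        ov <- genic_feature_overlap(cat_, gmod)
        out$sv_overlap <- write_tsv(
          rbind(ov$genic[, .(class = region, n_sv, total_bp, sv_per_mb)],
                ov$features[, .(class = feature, n_sv, total_bp, sv_per_mb)]),
          file.path(outdir, "sv_overlap.tsv"), hdr)
        lio <- load_in_sv_vs_outside(cat_, pol, categories, gmod)
        out$sv_load <- write_tsv(lio$per_accession,
                                  file.path(outdir, "sv_load.tsv"), hdr)
      }
    })
  }
  invisible(out)
}

#' Read a pipeline configuration from JSON
#'
#' The JSON mirrors [pipeline_config()]: top-level `outdir`, `seed`,
#' `thresholds`, and either `inputs` (paths) or `simulate` (fields of
#' [sim_config()]; `populations` as a list of [pop_spec()] field sets).
#'
#' @param path JSON file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  simulate <- NULL
  if (!is.null(js$simulate)) {
    sb <- js$simulate
    pops <- NULL
    if (!is.null(sb$populations)) {
      pops <- lapply(seq_len(nrow(sb$populations)), function(i) {
        row <- as.list(sb$populations[i, ])
        do.call(pop_spec, row[!vapply(row, function(v)
          is.null(v) || (length(v) == 1 && is.na(v)), TRUE)])
      })
      sb$populations <- NULL
    }
    cp <- sb$category_proportions
    if (!is.null(cp)) sb$category_proportions <- unlist(cp)
    simulate <- do.call(sim_config, c(sb, list(populations = pops)))
  }
  pipeline_config(simulate = simulate, inputs = js$inputs,
                  outdir = js$outdir %||% "tomload_out",
                  seed = js$seed %||% 1L,
                  thresholds = as.list(js$thresholds %||% list()))
}
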