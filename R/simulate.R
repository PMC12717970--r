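## Forward Wright-Fisher simulation of a domestication history.
##
## The generator exists so that every downstream operation of the package can
## be exercised on data whose truth is known: category labels, ancestral
## states, demography and selection are all chosen by the caller, and the
## outgroup is emitted homozygous ancestral at every site so polarization is
## the identity on truth.

#' Define one simulated population
#'
#' Populations form a tree: the root has `source = NULL` and exists from
#' generation 0; a descendant is founded at `split_gen` by sampling its
#' founders with replacement from the source population at that generation
#' (a serial-founder model of domestication).
#'
#' @param name Population label.
#' @param N Diploid population size (used for all generations unless `epochs`
#'   is given).
#' @param selfing Probability an offspring is produced by self-fertilisation.
#' @param n_sampled Number of accessions sampled at the final generation.
#' @param source Name of the source population, or `NULL` for the root.
#' @param split_gen Generation (global clock) at which this population is
#'   founded from `source`; 0 for the root.
#' @param epochs Optional `data.frame(start_gen, N)` of piecewise-constant
#'   population sizes (global clock); rows must be ordered and start at or
#'   before `split_gen`. Use this to encode bottlenecks or expansions.
#' @param sample_gen Generation at which accessions are sampled; default the
#'   final generation. An earlier value takes a snapshot (e.g., a
#'   pre-bottleneck sample of a lineage, via a zero-drift child split at the
#'   same generation).
#' @return A `pop_spec` list.
#' @export
pop_spec <- function(name, N, selfing = 0, n_sampled = 10, source = NULL,
                     split_gen = 0, epochs = NULL, sample_gen = NULL) {
  if (is.null(epochs)) epochs <- data.frame(start_gen = split_gen, N = N)
  stopifnot(is.data.frame(epochs), all(c("start_gen", "N") %in% names(epochs)))
  epochs$start_gen <- as.integer(epochs$start_gen)
  epochs$N <- as.integer(epochs$N)
  if (any(diff(epochs$start_gen) <= 0))
    stopf("epochs for population '%s' must be strictly ordered", name)
  if (any(epochs$N < 2)) stopf("population '%s': epoch N must be >= 2", name)
  if (!is.null(selfing) && (selfing < 0 || selfing > 1))
    stopf("selfing rate must be in [0,1]")
  structure(list(name = name, source = source, split_gen = as.integer(split_gen),
                 epochs = epochs, selfing = selfing,
                 n_sampled = as.integer(n_sampled),
                 sample_gen = if (is.null(sample_gen)) NULL
                              else as.integer(sample_gen)),
            class = "pop_spec")
}

#' Simulation configuration
#'
#' Defaults encode the stated world the rest of the package is tested
#' against: a wild, outcrossing ancestor of size 200 from which a
#' semi-domesticated population splits through a bottleneck with elevated
#' selfing, followed by a second, stronger bottleneck into a highly selfing
#' domesticate. Deleterious sites carry a multiplicative fitness cost with
#' genotype factors \{1, 1+hs, 1+s\}.
#'
#' @param seed Integer seed; the same config + seed gives bit-identical output.
#' @param n_sites Number of simulated biallelic sites.
#' @param n_chrom Number of freely assorting chromosomes the sites are spread
#'   over (one crossover per chromosome per meiosis at probability `xo_prob`).
#' @param chrom_length Length of each chromosome in bp (positions are drawn
#'   uniformly without replacement).
#' @param category_proportions Named fractions over the four categories of
#'   [load_categories()]; must sum to 1.
#' @param sel_coeff Selection coefficient s (<= 0) applied to the deleterious
#'   category; all other categories are neutral.
#' @param dominance Dominance coefficient h in \[0,1\].
#' @param mut_rate Per-site, per-gamete, per-generation probability of a
#'   0 -> 1 (ancestral -> derived) mutation; no back-mutation.
#' @param init_freq Initial derived-allele frequency of every site in the
#'   root founders (standing variation; set 0 to start from a clean slate).
#' @param xo_prob Probability of one within-chromosome crossover per meiosis.
#' @param ref_is_derived_frac Fraction of sites written to VCF with the
#'   derived allele as REF, so that polarization against the outgroup is
#'   exercised in both directions.
#' @param missing_rate Fraction of genotype calls masked to missing when the
#'   VCF is written (never applied to the outgroup).
#' @param n_gens Total number of generations simulated (global clock).
#' @param populations List of [pop_spec()] objects; default is the three-stage
#'   domestication preset described above.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(seed = 1L,
                       n_sites = 2000L,
                       n_chrom = 10L,
                       chrom_length = 1e6,
                       category_proportions = c(
                         "non-coding" = 0.5, "synonymous" = 0.2,
                         "neutral-nonsynonymous" = 0.2, "deleterious" = 0.1),
                       sel_coeff = -0.05,
                       dominance = 0.5,
                       mut_rate = 1e-4,
                       init_freq = 0.1,
                       xo_prob = 1,
                       ref_is_derived_frac = 0.1,
                       missing_rate = 0,
                       n_gens = 300L,
                       populations = NULL) {
  if (is.null(populations)) {
    populations <- list(
      pop_spec("WILD", N = 200, selfing = 0.1, n_sampled = 15),
      pop_spec("SEMIDOM", N = 60, selfing = 0.7, n_sampled = 15,
               source = "WILD", split_gen = 100L),
      pop_spec("DOM", N = 20, selfing = 0.95, n_sampled = 15,
               source = "SEMIDOM", split_gen = 200L)
    )
  }
  cfg <- structure(list(
    seed = as.integer(seed), n_sites = as.integer(n_sites),
    n_chrom = as.integer(n_chrom), chrom_length = chrom_length,
    category_proportions = category_proportions,
    sel_coeff = sel_coeff, dominance = dominance, mut_rate = mut_rate,
    init_freq = init_freq, xo_prob = xo_prob,
    ref_is_derived_frac = ref_is_derived_frac, missing_rate = missing_rate,
    n_gens = as.integer(n_gens), populations = populations),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  p <- cfg$category_proportions
  if (!setequal(names(p), load_categories()))
    stopf("category_proportions must be named by: %s",
          paste(load_categories(), collapse = ", "))
  if (abs(sum(p) - 1) > 1e-9)
    stopf("category_proportions must sum to 1 (got %.12f)", sum(p))
  if (any(p < 0)) stopf("category_proportions must be non-negative")
  for (r in c("mut_rate", "init_freq", "xo_prob", "ref_is_derived_frac",
              "missing_rate", "dominance")) {
    v <- cfg[[r]]
    if (v < 0 || v > 1) stopf("%s must be in [0,1] (got %g)", r, v)
  }
  if (cfg$sel_coeff > 0 || cfg$sel_coeff < -1)
    stopf("sel_coeff must be in [-1, 0]")
  nm <- vapply(cfg$populations, `[[`, "", "name")
  if (anyDuplicated(nm)) stopf("duplicate population names")
  roots <- vapply(cfg$populations, function(p) is.null(p$source), TRUE)
  if (sum(roots) != 1) stopf("exactly one root population required")
  for (pp in cfg$populations) {
    if (!is.null(pp$source) && !pp$source %in% nm)
      stopf("population '%s': unknown source '%s'", pp$name, pp$source)
    sg <- pp$sample_gen %||% cfg$n_gens
    N_at_sample <- epoch_N_at(pp$epochs, sg)
    if (pp$n_sampled > N_at_sample)
      stopf("population '%s': n_sampled (%d) exceeds N (%d) at sampling",
            pp$name, pp$n_sampled, N_at_sample)
    if (sg > cfg$n_gens)
      stopf("population '%s': sample_gen beyond n_gens", pp$name)
  }
  invisible(cfg)
}

## population size at global generation g under a pop's epoch schedule
epoch_N_at <- function(epochs, g) {
  i <- findInterval(g, epochs$start_gen)
  epochs$N[max(i, 1L)]
}

## N per generation for gens (from, to]  (size of the generation *produced*)
epoch_N_vector <- function(epochs, from, to) {
  if (to <= from) return(integer(0))
  vapply((from + 1L):to, function(g) epoch_N_at(epochs, g), 1L)
}

#' Run the forward simulation
#'
#' Simulates the configured population tree forward in time and samples
#' accessions from every population at the final generation. The outgroup is
#' a single pseudo-accession homozygous ancestral at every site.
#'
#' @param config A [sim_config()] object.
#' @return A `wf_simulation` list with elements `sites` (a `data.table` of
#'   site_id, chrom, pos, ref, alt, ancestral, derived, category),
#'   `populations` (named list of derived-allele dosage matrices,
#'   sites x accessions), `accessions` (data.table accession/population,
#'   outgroup included) and `config`.
#' @export
simulate_populations <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  L <- config$n_sites

  ## --- site table -------------------------------------------------------
  n_cat <- allocate_counts(L, config$category_proportions[load_categories()])
  category <- sample(rep(load_categories(), times = n_cat))
  per_chrom <- allocate_counts(L, rep(1 / config$n_chrom, config$n_chrom))
  chrom <- rep(sprintf("chr%02d", seq_len(config$n_chrom)), times = per_chrom)
  pos <- unlist(lapply(per_chrom, function(k)
    sort(sample.int(config$chrom_length, k))), use.names = FALSE)
  bases <- c("A", "C", "G", "T")
  ancestral <- sample(bases, L, replace = TRUE)
  derived <- vapply(ancestral, function(b) sample(setdiff(bases, b), 1), "")
  flip <- runif(L) < config$ref_is_derived_frac
  sites <- data.table::data.table(
    site_id = paste0("s", seq_len(L)), chrom = chrom, pos = pos,
    ancestral = ancestral, derived = derived,
    ref = ifelse(flip, derived, ancestral),
    alt = ifelse(flip, ancestral, derived),
    category = category)

  del_idx0 <- which(category == "deleterious") - 1L  # 0-based for C++
  chrom_id <- as.integer(factor(chrom, levels = unique(chrom)))

  ## --- population tree --------------------------------------------------
  pops <- config$populations
  names(pops) <- vapply(pops, `[[`, "", "name")
  children <- lapply(pops, function(p)
    Filter(function(q) identical(q$source, p$name), pops))
  root <- pops[[which(vapply(pops, function(p) is.null(p$source), TRUE))]]

  N0 <- epoch_N_at(root$epochs, 0L)
  founders <- matrix(as.raw(rbinom(2L * N0 * L, 1L,
                                   rep(config$init_freq, each = 2L * N0))),
                     nrow = 2L * N0, ncol = L)

  sampled <- list()
  run_branch <- function(pop, haps, from_gen) {
    kids <- children[[pop$name]]
    sample_gen <- pop$sample_gen %||% config$n_gens
    take_sample <- function(haps) {
      picks <- sort(sample.int(nrow(haps) / 2L, pop$n_sampled))
      dos <- matrix(0L, nrow = L, ncol = pop$n_sampled)
      for (j in seq_along(picks)) {
        i <- picks[j]
        dos[, j] <- as.integer(haps[2L * i - 1L, ]) +
          as.integer(haps[2L * i, ])
      }
      colnames(dos) <- sprintf("%s_%02d", pop$name, seq_len(pop$n_sampled))
      sampled[[pop$name]] <<- dos
    }
    if (sample_gen <= from_gen) take_sample(haps)
    split_gens <- vapply(kids, `[[`, 1L, "split_gen")
    checkpoints <- sort(unique(c(split_gens[split_gens > from_gen],
                                 sample_gen[sample_gen > from_gen],
                                 config$n_gens)))
    for (cp in checkpoints) {
      Nvec <- epoch_N_vector(pop$epochs, from_gen, cp)
      if (length(Nvec)) {
        res <- wf_run_cpp(haps, Nvec, del_idx0,
                          config$sel_coeff, config$dominance, pop$selfing,
                          config$mut_rate, chrom_id, config$xo_prob)
        haps <- res$haps
      }
      from_gen <- cp
      if (cp == sample_gen) take_sample(haps)
      for (kid in kids) {
        if (kid$split_gen == cp) {
          Nk <- epoch_N_at(kid$epochs, cp)
          picks <- sample.int(nrow(haps) / 2L, Nk, replace = TRUE)
          rows <- as.vector(rbind(2L * picks - 1L, 2L * picks))
          run_branch(kid, haps[rows, , drop = FALSE], cp)
        }
      }
    }
    invisible(NULL)
  }
  run_branch(root, founders, 0L)
  sampled <- sampled[names(pops)]  # config order

  accessions <- data.table::rbindlist(lapply(names(sampled), function(nm)
    data.table::data.table(accession = colnames(sampled[[nm]]),
                           population = nm)))
  accessions <- rbind(accessions,
                      data.table::data.table(accession = "OUTGROUP",
                                             population = "OUTGROUP"))

  structure(list(sites = sites, populations = sampled,
                 accessions = accessions, config = config),
            class = "wf_simulation")
}

#' @export
print.wf_simulation <- function(x, ...) {
  cat("Forward Wright-Fisher simulation\n")
  cat(sprintf("  %d sites on %d chromosomes; categories: %s\n",
              nrow(x$sites), x$config$n_chrom,
              paste(sprintf("%s=%d", names(table(x$sites$category)),
                            as.integer(table(x$sites$category))),
                    collapse = ", ")))
  for (nm in names(x$populations))
    cat(sprintf("  population %s: %d accessions\n", nm,
                ncol(x$populations[[nm]])))
  invisible(x)
}

#' Combined derived-allele dosage matrix of a simulation
#'
#' @param sim A `wf_simulation`.
#' @param include_outgroup Append the all-ancestral outgroup column.
#' @return Integer matrix, sites x accessions, counting derived alleles.
#' @export
sim_dosage <- function(sim, include_outgroup = TRUE) {
  m <- do.call(cbind, sim$populations)
  if (include_outgroup)
    m <- cbind(m, OUTGROUP = rep(0L, nrow(m)))
  m
}
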