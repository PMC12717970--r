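## Emission of simulated data in the standard on-disk formats consumed by
## the analysis side of the package: multi-sample VCF, SIFT-style and
## PROVEAN-style annotation TSVs, GFF3 gene models, a genetic map, and mock
## three-caller SV call sets.

#' Write a simulation as a multi-sample VCF (v4.2, GT only)
#'
#' REF/ALT follow the site table: for most sites REF is the ancestral base,
#' but a configured fraction is written with the derived allele as REF, so
#' that downstream polarization must genuinely consult the outgroup. The
#' outgroup sample is homozygous ancestral everywhere. Missing genotypes are
#' injected at rate `missing_rate` (non-outgroup samples only).
#'
#' @param sim A `wf_simulation` from [simulate_populations()].
#' @param path Output file path.
#' @param missing_rate Overrides `sim$config$missing_rate` if not `NULL`.
#' @return `path`, invisibly.
#' @export
write_sim_vcf <- function(sim, path, missing_rate = NULL) {
  missing_rate <- missing_rate %||% sim$config$missing_rate
  st <- sim$sites
  dderived <- sim_dosage(sim, include_outgroup = TRUE)
  ## convert derived dosage -> ALT dosage given REF orientation
  flip <- st$ref != st$ancestral
  dalt <- dderived
  dalt[flip, ] <- 2L - dalt[flip, , drop = FALSE]
  if (missing_rate > 0) {
    smp <- which(colnames(dalt) != "OUTGROUP")
    mask <- matrix(runif(nrow(dalt) * length(smp)) < missing_rate,
                   nrow = nrow(dalt))
    dalt[, smp][mask] <- NA_integer_
  }
  gt <- matrix("./.", nrow = nrow(dalt), ncol = ncol(dalt))
  gt[!is.na(dalt)] <- c("0/0", "0/1", "1/1")[dalt[!is.na(dalt)] + 1L]

  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines("##source=tomload_simulate", con)
  for (cc in unique(st$chrom))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", cc,
                       as.integer(sim$config$chrom_length)), con)
  writeLines(
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">", con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(dalt)), collapse = "\t"), con)
  body <- cbind(st$chrom, st$pos, st$site_id, st$ref, st$alt, ".", ".", ".",
                "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Write / read a population-assignment table
#'
#' Two-column TSV (accession, population) with a `#outgroup=<accession>`
#' header line flagging the single outgroup accession.
#'
#' @param assignment `data.frame` with columns accession, population.
#' @param outgroup Accession name of the outgroup.
#' @param path File path.
#' @return `path` (write) / a `data.table` with attribute `outgroup` (read).
#' @export
write_assignment <- function(assignment, outgroup, path) {
  if (!outgroup %in% assignment$accession)
    stopf("outgroup '%s' not among accessions", outgroup)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("#outgroup=%s", outgroup), con)
  writeLines("accession\tpopulation", con)
  writeLines(paste(assignment$accession, assignment$population, sep = "\t"),
             con)
  invisible(path)
}

#' @rdname write_assignment
#' @export
read_assignment <- function(path) {
  lines <- readLines(path)
  og_line <- grep("^#outgroup=", lines, value = TRUE)
  if (length(og_line) != 1)
    stopf("assignment file must carry exactly one '#outgroup=' header line")
  outgroup <- sub("^#outgroup=", "", og_line)
  dt <- data.table::fread(text = lines[!startsWith(lines, "#")], sep = "\t",
                          header = TRUE, colClasses = "character")
  if (!all(c("accession", "population") %in% names(dt)))
    stopf("assignment table needs columns: accession, population")
  if (anyDuplicated(dt$accession)) stopf("duplicate accession in assignment")
  if (!outgroup %in% dt$accession)
    stopf("outgroup '%s' absent from assignment table", outgroup)
  data.table::setattr(dt, "outgroup", outgroup)
  dt
}

#' Emit SIFT-style and PROVEAN-style annotation tables
#'
#' Coding sites (synonymous + nonsynonymous) appear in the SIFT-style table;
#' nonsynonymous sites additionally receive a PROVEAN-style score. With
#' `miscls_rate = 0` the tables decode back to the true categories exactly
#' under the intersection rule (deleterious label and score < -2.5 together);
#' with rate m, exactly `floor(m * n_nonsynonymous)` nonsynonymous sites are
#' emitted with the opposite deleterious/neutral annotation. Scores are drawn
#' uniform on (-6, -2.6) for the deleterious class and (-2.4, 2) otherwise:
#' only the decision rule's inputs matter, not score realism.
#'
#' @param sim A `wf_simulation`, or a site `data.table` with columns
#'   chrom, pos, ancestral, derived, category.
#' @param miscls_rate Misclassification rate in \[0, 1).
#' @param dir Optional directory; if given, `sift.tsv` and `provean.tsv`
#'   are written there.
#' @return List with `sift`, `provean` (data.tables) and the file `paths`.
#' @export
emit_annotation_tables <- function(sim, miscls_rate = 0, dir = NULL) {
  stopifnot(miscls_rate >= 0, miscls_rate < 1)
  st <- if (inherits(sim, "wf_simulation")) sim$sites else data.table::as.data.table(sim)
  nonsyn <- which(st$category %in% c("neutral-nonsynonymous", "deleterious"))
  emitted_del <- st$category == "deleterious"
  n_swap <- floor(miscls_rate * length(nonsyn))
  if (n_swap > 0) {
    swap <- sample(nonsyn, n_swap)
    emitted_del[swap] <- !emitted_del[swap]
  }

  coding <- st$category != "non-coding"
  lab <- rep(".", nrow(st))
  lab[emitted_del] <- sample(
    c("DELETERIOUS", "DELETERIOUS (*WARNING! Low confidence)"),
    sum(emitted_del), replace = TRUE, prob = c(0.8, 0.2))
  lab[st$category != "non-coding" & !emitted_del &
        st$category != "synonymous"] <- "TOLERATED"
  subst <- ifelse(st$category == "synonymous", "SYNONYMOUS", "NONSYNONYMOUS")
  sift <- data.table::data.table(
    chrom = st$chrom, pos = st$pos, ref = st$ancestral, alt = st$derived,
    region_type = "CDS", substitution_type = subst,
    label = lab)[coding]

  pv_idx <- nonsyn
  score <- numeric(length(pv_idx))
  is_del <- emitted_del[pv_idx]
  score[is_del] <- runif(sum(is_del), -6, -2.6)
  score[!is_del] <- runif(sum(!is_del), -2.4, 2)
  provean <- data.table::data.table(
    chrom = st$chrom[pv_idx], pos = st$pos[pv_idx], score = score)
  data.table::setorder(provean, chrom, pos)

  paths <- NULL
  if (!is.null(dir)) {
    paths <- c(sift = file.path(dir, "sift.tsv"),
               provean = file.path(dir, "provean.tsv"))
    write_tsv(sift, paths[["sift"]])
    write_tsv(provean, paths[["provean"]])
  }
  list(sift = sift, provean = provean, paths = paths)
}

#' Generate synthetic gene models
#'
#' Each gene is a contiguous run of 5'UTR, alternating exons and introns
#' (>= 1 exon), and 3'UTR; genes never overlap. Feature sizes are drawn
#' uniformly from the configured ranges.
#'
#' @param n_genes Number of genes.
#' @param n_chrom,chrom_length Chromosome layout (genes are placed round-robin).
#' @param sizes Named list of `c(min, max)` bp ranges for `utr5`, `exon`,
#'   `intron`, `utr3`, plus `max_exons` and `intergenic` spacing range.
#' @return A `data.table` in GFF3-like long form (seqid, type, start, end,
#'   strand, ID, Parent) with one `gene` row plus its feature rows per gene.
#' @export
generate_gene_models <- function(n_genes, n_chrom = 10, chrom_length = 1e6,
                                 sizes = list(utr5 = c(50, 300),
                                              exon = c(100, 1000),
                                              intron = c(50, 2000),
                                              utr3 = c(50, 300),
                                              max_exons = 4,
                                              intergenic = c(500, 5000))) {
  rng <- function(r) sample(seq.int(r[1], r[2]), 1)
  cursor <- rep(1L, n_chrom)
  rows <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    cc <- ((g - 1) %% n_chrom) + 1
    start <- cursor[cc] + rng(sizes$intergenic)
    n_ex <- sample(seq_len(sizes$max_exons), 1)
    widths <- c(utr5 = rng(sizes$utr5))
    for (e in seq_len(n_ex)) {
      widths <- c(widths, setNames(rng(sizes$exon), paste0("exon", e)))
      if (e < n_ex)
        widths <- c(widths, setNames(rng(sizes$intron), paste0("intron", e)))
    }
    widths <- c(widths, utr3 = rng(sizes$utr3))
    ends <- start - 1 + cumsum(widths)
    starts <- c(start, head(ends, -1) + 1)
    if (tail(ends, 1) > chrom_length)
      stopf("gene %d does not fit on chromosome %d: infeasible geometry", g, cc)
    type <- c("five_prime_UTR",
              rep(c("exon", "intron"), length.out = 2 * n_ex - 1),
              "three_prime_UTR")
    gid <- sprintf("gene%04d", g)
    rows[[g]] <- data.table::data.table(
      seqid = sprintf("chr%02d", cc),
      type = c("gene", type),
      start = c(start, starts), end = c(tail(ends, 1), unname(ends)),
      strand = "+",
      ID = c(gid, sprintf("%s.f%d", gid, seq_along(type))),
      Parent = c(NA_character_, rep(gid, length(type))))
    cursor[cc] <- tail(ends, 1)
  }
  data.table::rbindlist(rows)
}

#' Write / read gene models as GFF3
#' @param models `data.table` from [generate_gene_models()].
#' @param path File path.
#' @return `path` (write); a `data.table` in the same long form (read).
#' @export
write_gene_models <- function(models, path) {
  attr_col <- ifelse(is.na(models$Parent),
                     sprintf("ID=%s", models$ID),
                     sprintf("ID=%s;Parent=%s", models$ID, models$Parent))
  lines <- paste(models$seqid, "tomload", models$type, models$start,
                 models$end, ".", models$strand, ".", attr_col, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  dt <- data.table::data.table(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(gr$type),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    ID = gr$ID,
    Parent = vapply(as.list(gr$Parent), function(p)
      if (length(p)) p[[1]] else NA_character_, ""))
  dt
}

#' Generate a synthetic genetic map
#'
#' Markers strictly increasing in both bp and cM; by default the map is
#' linear at `cm_per_mb`, with optional positive jitter on the cM increments
#' (monotonicity preserved by construction).
#'
#' @param n_markers Markers per chromosome.
#' @param cm_per_mb Slope in cM/Mb (scalar, or vector of length `n_chrom`).
#' @param n_chrom,chrom_length Chromosome layout.
#' @param jitter Fractional jitter on increments (0 = exactly linear).
#' @return `data.table(chrom, bp, cM)`.
#' @export
generate_genetic_map <- function(n_markers = 20, cm_per_mb = 2, n_chrom = 10,
                                 chrom_length = 1e6, jitter = 0) {
  cm_per_mb <- rep(cm_per_mb, length.out = n_chrom)
  out <- lapply(seq_len(n_chrom), function(cc) {
    bp <- sort(sample.int(chrom_length, n_markers))
    bp[1] <- 1L
    inc <- diff(bp) / 1e6 * cm_per_mb[cc]
    if (jitter > 0)
      inc <- inc * pmax(1e-6, 1 + runif(length(inc), -jitter, jitter))
    data.table::data.table(chrom = sprintf("chr%02d", cc), bp = bp,
                           cM = c(0, cumsum(inc)))
  })
  data.table::rbindlist(out)
}

#' Generate mock three-caller structural-variant call sets
#'
#' Plants a truth set of DEL/DUP/INV/TRA variants, assigns carrier accessions,
#' and emits per-accession, per-caller call sets with breakpoint jitter,
#' per-caller dropout and per-caller unique false positives. False positives
#' are placed away from every truth SV so they can never join a truth
#' cluster; jitter must stay below `max_dist / 3` so replicate calls of one
#' truth SV always remain mergeable.
#'
#' @param n_per_type Named counts of truth SVs, names among DEL, DUP, INV, TRA.
#' @param n_accessions Number of (non-outgroup) accessions.
#' @param carrier_freq Probability each accession carries each truth SV
#'   (accession 1 is forced to carry everything so single-accession fixtures
#'   are complete). May be a vector, one value per accession.
#' @param jitter_sd Breakpoint jitter SD in bp (must be <= 100/3).
#' @param dropout Per-caller probability a carried truth SV is missed.
#' @param fp_per_caller False positives unique to each caller, per accession.
#' @param n_chrom,chrom_length Genome layout.
#' @param len_range Truth SV length range in bp. The lower bound must be
#'   large enough that jittered replicate calls keep a length ratio of at
#'   least 0.9: with jitter truncated at +/- 50 bp, lengths of two replicate
#'   calls differ by at most 200 bp, so the default 3000 bp floor leaves a
#'   worst-case ratio of 0.935.
#' @return List: `truth` (sv_id, chrom, start, end, chrom2, type, carriers),
#'   `calls` (data.table: accession, caller, chrom, start, end, chrom2, type,
#'   truth_id — NA for false positives).
#' @export
generate_sv_fixtures <- function(n_per_type = c(DEL = 10, DUP = 5, INV = 5,
                                                TRA = 5),
                                 n_accessions = 1, carrier_freq = 1,
                                 jitter_sd = 10, dropout = 0,
                                 fp_per_caller = 0,
                                 n_chrom = 5, chrom_length = 1e7,
                                 len_range = c(3000, 8000)) {
  stopifnot(all(names(n_per_type) %in% c("DEL", "DUP", "INV", "TRA")))
  if (jitter_sd > 100 / 3)
    stopf("jitter_sd must be <= 100/3 so truth replicates stay mergeable")
  carrier_freq <- rep(carrier_freq, length.out = n_accessions)
  chroms <- sprintf("chr%02d", seq_len(n_chrom))
  n_truth <- sum(n_per_type)
  ## lay truth SVs on a coarse grid so same-chromosome neighbours are far
  ## apart (>> max_dist + max length): clusters are unambiguous by design
  slot_w <- max(len_range[2] * 2, 20000)
  n_slots <- floor(chrom_length / slot_w)
  if (n_truth > n_chrom * n_slots) stopf("too many truth SVs for the genome")
  slot_ids <- sample.int(n_chrom * n_slots, n_truth)
  sv_chrom <- chroms[((slot_ids - 1) %/% n_slots) + 1]
  sv_start <- ((slot_ids - 1) %% n_slots) * slot_w +
    sample.int(slot_w %/% 4, n_truth, replace = TRUE)
  type <- rep(names(n_per_type), times = n_per_type)
  len <- sample(seq.int(len_range[1], len_range[2]), n_truth, replace = TRUE)
  is_tra <- type == "TRA"
  sv_end <- sv_start + len - 1L
  chrom2 <- rep(NA_character_, n_truth)
  if (any(is_tra)) {
    ## TRA: second breakpoint on another chromosome, also slotted
    chrom2[is_tra] <- sample(chroms, sum(is_tra), replace = TRUE)
    sv_end[is_tra] <- sample.int(chrom_length - 1000L, sum(is_tra))
  }
  carriers <- lapply(seq_len(n_truth), function(i) {
    cs <- which(runif(n_accessions) < carrier_freq)
    sort(unique(c(1L, cs)))
  })
  truth <- data.table::data.table(
    sv_id = sprintf("sv%04d", seq_len(n_truth)), chrom = sv_chrom,
    start = as.integer(sv_start), end = as.integer(sv_end),
    chrom2 = chrom2, type = type,
    carriers = vapply(carriers, function(x) paste(x, collapse = ","), ""))

  accs <- sprintf("ACC%02d", seq_len(n_accessions))
  callers <- c("callerA", "callerB", "callerC")
  ## false positives each get their own unused genome slot, so no false
  ## positive can ever cluster with truth or with another false positive
  n_fp_total <- n_accessions * length(callers) * fp_per_caller
  free_slots <- setdiff(seq_len(n_chrom * n_slots), slot_ids)
  if (n_fp_total > length(free_slots))
    stopf("not enough genome slots for %d false positives", n_fp_total)
  fp_slots <- if (n_fp_total) sample(free_slots, n_fp_total) else integer(0)
  fp_cursor <- 0L
  out <- list()
  for (a in seq_len(n_accessions)) {
    for (k in seq_along(callers)) {
      carried <- which(vapply(carriers, function(x) a %in% x, TRUE))
      keep <- carried[runif(length(carried)) >= dropout]
      if (length(keep)) {
        ## jitter truncated at +/- 50 bp: any two replicate calls of one
        ## truth SV then sit within the 100 bp merge distance by design
        jit <- function(n) as.integer(pmin(50, pmax(-50,
          round(rnorm(n, 0, jitter_sd)))))
        js <- jit(length(keep))
        je <- jit(length(keep))
        out[[length(out) + 1]] <- data.table::data.table(
          accession = accs[a], caller = callers[k],
          chrom = truth$chrom[keep],
          start = pmax(1L, truth$start[keep] + js),
          end = truth$end[keep] + je,
          chrom2 = truth$chrom2[keep], type = truth$type[keep],
          truth_id = truth$sv_id[keep])
      }
      if (fp_per_caller > 0) {
        sl <- fp_slots[fp_cursor + seq_len(fp_per_caller)]
        fp_cursor <- fp_cursor + fp_per_caller
        fp_type <- sample(names(n_per_type), fp_per_caller, replace = TRUE)
        fp_chrom <- chroms[((sl - 1) %/% n_slots) + 1]
        fp_start <- ((sl - 1) %% n_slots) * slot_w +
          sample.int(slot_w %/% 4, fp_per_caller, replace = TRUE)
        fp_len <- sample(seq.int(len_range[1], len_range[2]), fp_per_caller,
                         replace = TRUE)
        fp_end <- as.integer(fp_start + fp_len - 1L)
        fp_chrom2 <- rep(NA_character_, fp_per_caller)
        fp_chrom2[fp_type == "TRA"] <- sample(chroms, sum(fp_type == "TRA"),
                                              replace = TRUE)
        out[[length(out) + 1]] <- data.table::data.table(
          accession = accs[a], caller = callers[k], chrom = fp_chrom,
          start = as.integer(fp_start), end = fp_end, chrom2 = fp_chrom2,
          type = fp_type, truth_id = NA_character_)
      }
    }
  }
  calls <- data.table::rbindlist(out)
  data.table::setorder(calls, accession, caller, chrom, start)
  list(truth = truth, calls = calls)
}

#' Write one caller's calls for one accession as an SV VCF
#'
#' Minimal VCF v4.2 with SVTYPE, END, SVLEN and (for TRA) CHR2 INFO keys and
#' a single sample genotyped 0/1.
#'
#' @param calls `data.table` with chrom, start, end, chrom2, type.
#' @param accession Sample name.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(calls, accession, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=tomload_sv_fixture",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"Mate chromosome\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", accession), collapse = "\t")), con)
  if (nrow(calls)) {
    info <- ifelse(
      calls$type == "TRA",
      sprintf("SVTYPE=TRA;CHR2=%s;END=%d", calls$chrom2, calls$end),
      sprintf("SVTYPE=%s;END=%d;SVLEN=%d", calls$type, calls$end,
              calls$end - calls$start + 1L))
    writeLines(paste(calls$chrom, calls$start,
                     sprintf("sv_%06d", seq_len(nrow(calls))), "N",
                     sprintf("<%s>", calls$type), ".", "PASS", info, "GT",
                     "0/1", sep = "\t"), con)
  }
  invisible(path)
}

#' Write a full SV fixture to per-accession, per-caller VCFs
#' @param fix Result of [generate_sv_fixtures()].
#' @param dir Output directory (created if needed).
#' @return `data.table(accession, caller, path)`.
#' @export
write_sv_fixture_vcfs <- function(fix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  combos <- unique(fix$calls[, .(accession, caller)])
  combos[, path := file.path(dir, sprintf("%s_%s.vcf", accession, caller))]
  for (i in seq_len(nrow(combos))) {
    cc <- fix$calls[accession == combos$accession[i] &
                      caller == combos$caller[i]]
    write_sv_vcf(cc, combos$accession[i], combos$path[i])
  }
  write_tsv(fix$truth, file.path(dir, "truth_svs.tsv"))
  combos
}
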