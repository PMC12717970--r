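# Independent oracles: deliberately naive implementations, structured
# differently from the package code, used to freeze expected values.

# mean pairwise haplotype difference per site, summed over sites, / width.
# Expands each diploid dosage into two haplotypes and compares all pairs.
oracle_pi <- function(dosage, width) {
  total <- 0
  for (i in seq_len(nrow(dosage))) {
    row <- dosage[i, ]
    row <- row[!is.na(row)]
    haps <- unlist(lapply(row, function(d) switch(as.character(d),
                                                  "0" = c(0, 0),
                                                  "1" = c(0, 1),
                                                  "2" = c(1, 1))))
    n <- length(haps)
    if (n < 2) next
    diffs <- 0; pairs <- 0
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      diffs <- diffs + as.integer(haps[a] != haps[b])
      pairs <- pairs + 1
    }
    total <- total + diffs / pairs
  }
  total / width
}

# Tajima's D from scratch for complete data: j = derived counts per site,
# n = haplotypes. Written against the textbook definitions.
oracle_tajimas_d <- function(j, n) {
  seg <- j > 0 & j < n
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  theta_pi <- sum(sapply(j[seg], function(k) k * (n - k))) / choose(n, 2)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (theta_pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Dunn pairwise z / p from first principles (rank sums, tie correction)
oracle_dunn <- function(values, groups) {
  groups <- as.character(groups)
  N <- length(values)
  rk <- rank(values)
  tie_term <- 0
  for (v in unique(values)) {
    t <- sum(values == v)
    tie_term <- tie_term + (t^3 - t)
  }
  tie_term <- tie_term / (12 * (N - 1))
  gs <- sort(unique(groups))
  res <- list()
  for (a in seq_along(gs)) for (b in seq_along(gs)) {
    if (a >= b) next
    ga <- gs[a]; gb <- gs[b]
    na <- sum(groups == ga); nb <- sum(groups == gb)
    za <- mean(rk[groups == ga]) - mean(rk[groups == gb])
    sigma <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / na + 1 / nb))
    z <- za / sigma
    res[[length(res) + 1]] <- data.frame(group1 = ga, group2 = gb, z = z,
                                         p_raw = 2 * (1 - pnorm(abs(z))))
  }
  do.call(rbind, res)
}

# brute-force per-genome category counts by explicit genotype enumeration
oracle_counts <- function(dosage, categories) {
  out <- list()
  for (acc in colnames(dosage)) {
    row <- list(accession = acc)
    for (cl in unique(categories)) {
      cnt <- 0
      for (i in which(categories == cl)) {
        d <- dosage[i, acc]
        if (is.na(d)) next
        if (d == 2) cnt <- cnt + 1
        if (d == 1) cnt <- cnt + 0.5
      }
      row[[cl]] <- cnt
    }
    out[[length(out) + 1]] <- row
  }
  out
}

# brute-force single-linkage clustering of SV calls: full adjacency matrix
# + transitive closure; returns a list of member-index sets
oracle_sv_partition <- function(dt, max_dist = 100, min_overlap = 0.9) {
  n <- nrow(dt)
  adj <- matrix(FALSE, n, n)
  len <- ifelse(dt$type == "TRA", NA_integer_, dt$end - dt$start + 1L)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (dt$type[i] != dt$type[j] || dt$chrom[i] != dt$chrom[j]) next
    if (dt$type[i] == "TRA") {
      if (!identical(dt$chrom2[i], dt$chrom2[j])) next
      adj[i, j] <- abs(dt$start[i] - dt$start[j]) <= max_dist &&
        abs(dt$end[i] - dt$end[j]) <= max_dist
    } else {
      adj[i, j] <- abs(dt$start[i] - dt$start[j]) <= max_dist &&
        min(len[i], len[j]) / max(len[i], len[j]) >= min_overlap
    }
  }
  diag(adj) <- TRUE
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  unique(apply(adj, 1, function(r) sort(which(r)), simplify = FALSE))
}

# canonical form of a clustering for set comparison
partition_sets <- function(ids) {
  unname(lapply(split(seq_along(ids), ids), sort))
}
same_partition <- function(a, b) {
  setequal(lapply(a, paste, collapse = ","), lapply(b, paste, collapse = ","))
}

# independent single-site Wright-Fisher simulator (frequency dynamics only):
# deterministic selection step + binomial drift, no linkage
oracle_wf_single_site <- function(N, s, h, q0, gens) {
  q <- q0
  for (g in seq_len(gens)) {
    w_bar <- q^2 * (1 + s) + 2 * q * (1 - q) * (1 + h * s) + (1 - q)^2
    q <- (q^2 * (1 + s) + q * (1 - q) * (1 + h * s)) / w_bar
    q <- rbinom(1, 2 * N, q) / (2 * N)
    if (q == 0 || q == 1) break
  }
  q
}
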