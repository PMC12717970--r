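#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Forward Wright-Fisher engine over diploid individuals.
//
// Haplotypes are stored flat as int8: individual i, haplotype a (0/1), site l
// lives at index (2*i + a) * L + l.  Alleles are 0 (ancestral) / 1 (derived).
// Fitness is multiplicative across deleterious sites with genotype factors
// {1, 1+hs, 1+s}; selection acts on parents (fitness-weighted sampling),
// selfing replaces the second parent draw with the first at the configured
// probability.  Recombination: chromosomes assort freely; within a chromosome
// a single crossover at a uniform site boundary occurs with probability
// xo_prob per meiosis.  Mutation is one-way 0 -> 1 (infinite-sites flavour,
// recurrent at the same site allowed but without back-mutation).
//
// All randomness flows through R's RNG so that set.seed() in R gives
// bit-identical trajectories.

static inline int sample_parent(const std::vector<double> &cumw) {
  const double u = unif_rand() * cumw.back();
  // binary search for first cumw[i] >= u
  int lo = 0, hi = (int)cumw.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cumw[mid] >= u) hi = mid; else lo = mid + 1;
  }
  return lo;
}

static void make_gamete(const int8_t *hapA, const int8_t *hapB,
                        int8_t *dest, const std::vector<int> &chrom_start,
                        double xo_prob, int L) {
  const int nchrom = (int)chrom_start.size() - 1;
  for (int c = 0; c < nchrom; ++c) {
    const int cs = chrom_start[c], ce = chrom_start[c + 1];
    const int clen = ce - cs;
    const int8_t *first = (unif_rand() < 0.5) ? hapA : hapB;
    const int8_t *second = (first == hapA) ? hapB : hapA;
    if (clen > 1 && unif_rand() < xo_prob) {
      // crossover after site cs + k, k in 1..clen-1
      int k = 1 + (int)(unif_rand() * (clen - 1));
      if (k >= clen) k = clen - 1;
      std::memcpy(dest + cs, first + cs, k);
      std::memcpy(dest + cs + k, second + cs + k, clen - k);
    } else {
      std::memcpy(dest + cs, first + cs, clen);
    }
  }
}

// [[Rcpp::export]]
List wf_run_cpp(RawMatrix founder_haps,
                IntegerVector N_per_gen, IntegerVector del_sites0,
                double s, double h, double selfing, double mut_rate,
                IntegerVector chrom_id, double xo_prob) {
  // founder_haps: (2*N0) x L raw matrix, rows are haplotypes of individuals
  // 0..N0-1 in order (ind0 hapA, ind0 hapB, ind1 hapA, ...)
  const int L = founder_haps.ncol();
  const int N0 = founder_haps.nrow() / 2;
  const int G = N_per_gen.size();

  int Nmax = N0;
  for (int g = 0; g < G; ++g) if (N_per_gen[g] > Nmax) Nmax = N_per_gen[g];

  // chromosome block boundaries from chrom_id (must be grouped)
  std::vector<int> chrom_start;
  chrom_start.push_back(0);
  for (int l = 1; l < L; ++l)
    if (chrom_id[l] != chrom_id[l - 1]) chrom_start.push_back(l);
  chrom_start.push_back(L);

  std::vector<int8_t> cur((size_t)2 * Nmax * L), nxt((size_t)2 * Nmax * L);
  for (int r = 0; r < 2 * N0; ++r)
    for (int l = 0; l < L; ++l)
      cur[(size_t)r * L + l] = (int8_t)founder_haps(r, l);

  const int ndel = del_sites0.size();
  std::vector<int> del(ndel);
  for (int i = 0; i < ndel; ++i) del[i] = del_sites0[i];

  const double f_het = 1.0 + h * s, f_hom = 1.0 + s;
  int Ncur = N0;
  std::vector<double> cumw(Nmax);

  for (int g = 0; g < G; ++g) {
    // fitness of current generation
    double tot = 0.0;
    for (int i = 0; i < Ncur; ++i) {
      const int8_t *ha = cur.data() + (size_t)(2 * i) * L;
      const int8_t *hb = cur.data() + (size_t)(2 * i + 1) * L;
      int nhet = 0, nhom = 0;
      for (int k = 0; k < ndel; ++k) {
        const int d = ha[del[k]] + hb[del[k]];
        if (d == 1) ++nhet; else if (d == 2) ++nhom;
      }
      double w = 1.0;
      if (nhet) w *= std::pow(f_het, nhet);
      if (nhom) w *= std::pow(f_hom, nhom);
      tot += w;
      cumw[i] = tot;
    }
    if (!(tot > 0.0))
      stop("population extinct (all fitness zero) at generation %d", g + 1);

    const int Nnext = N_per_gen[g];
    for (int j = 0; j < Nnext; ++j) {
      const int p1 = sample_parent(cumw);
      const int p2 = (unif_rand() < selfing) ? p1 : sample_parent(cumw);
      make_gamete(cur.data() + (size_t)(2 * p1) * L,
                  cur.data() + (size_t)(2 * p1 + 1) * L,
                  nxt.data() + (size_t)(2 * j) * L, chrom_start, xo_prob, L);
      make_gamete(cur.data() + (size_t)(2 * p2) * L,
                  cur.data() + (size_t)(2 * p2 + 1) * L,
                  nxt.data() + (size_t)(2 * j + 1) * L, chrom_start, xo_prob, L);
    }
    if (mut_rate > 0) {
      const double ncells = 2.0 * Nnext * (double)L;
      const int nmut = (int)R::rbinom(ncells, mut_rate);
      for (int m = 0; m < nmut; ++m) {
        size_t cell = (size_t)(unif_rand() * ncells);
        if (cell >= (size_t)ncells) cell = (size_t)ncells - 1;
        nxt[cell] = 1;
      }
    }
    cur.swap(nxt);
    Ncur = Nnext;
  }

  RawMatrix out(2 * Ncur, L);
  for (int r = 0; r < 2 * Ncur; ++r)
    for (int l = 0; l < L; ++l)
      out(r, l) = (Rbyte)cur[(size_t)r * L + l];
  return List::create(_["haps"] = out, _["N"] = Ncur);
}
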