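#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Structured-coalescent SNP simulator.
//
// Simulates, for each locus independently, the genealogy of the sampled
// gene copies under a continuous-time structured coalescent: within deme
// d with k_d active lineages, pairs coalesce at rate choose(k_d, 2)/twoN
// per generation; a lineage in deme d migrates (backwards in time) to
// deme j at rate mig(d, j). One mutation is then placed uniformly at
// random on the genealogy's branches (infinite sites, conditioned on the
// locus segregating), and every gene copy below the mutated branch
// carries the derived allele.
//
// deme0: 0-based deme index of each sampled gene copy (length 2n for n
// diploids). mig: d x d backward migration rate matrix, zero diagonal.
// twoN: gene copies per deme (2N). Returns a (2n) x n_loci 0/1 matrix.
// [[Rcpp::export]]
IntegerMatrix coalescent_snps(IntegerVector deme0, NumericMatrix mig,
                              double twoN, int n_loci) {
  const int k = deme0.size();
  const int d = mig.nrow();
  if (k < 2) stop("need at least two gene copies");
  if (mig.ncol() != d) stop("migration matrix must be square");
  std::vector<double> out_rate(d, 0.0);
  for (int a = 0; a < d; ++a)
    for (int b = 0; b < d; ++b)
      if (a != b) out_rate[a] += mig(a, b);

  IntegerMatrix alleles(k, n_loci);
  const int n_nodes = 2 * k - 1;
  std::vector<double> birth(n_nodes), blen(n_nodes);
  std::vector<int> child1(n_nodes), child2(n_nodes);
  std::vector<std::vector<int>> pool(d);

  for (int loc = 0; loc < n_loci; ++loc) {
    for (int a = 0; a < d; ++a) pool[a].clear();
    for (int i = 0; i < k; ++i) pool[deme0[i]].push_back(i);
    std::fill(child1.begin(), child1.end(), -1);
    std::fill(child2.begin(), child2.end(), -1);
    std::fill(blen.begin(), blen.end(), 0.0);
    std::fill(birth.begin(), birth.end(), 0.0);

    int active = k, next_node = k;
    double t = 0.0;
    long events = 0;
    while (active > 1) {
      if (++events > 50000000L)
        stop("coalescent did not complete; is the migration graph connected?");
      double total = 0.0;
      for (int a = 0; a < d; ++a) {
        double ka = (double)pool[a].size();
        total += ka * (ka - 1.0) / (2.0 * twoN) + ka * out_rate[a];
      }
      if (total <= 0.0)
        stop("all lineages isolated: migration graph is disconnected");
      t += R::exp_rand() / total;
      double u = unif_rand() * total;
      int ev_deme = -1;
      bool is_coal = false;
      for (int a = 0; a < d; ++a) {
        double ka = (double)pool[a].size();
        double rc = ka * (ka - 1.0) / (2.0 * twoN);
        if (u < rc) { ev_deme = a; is_coal = true; break; }
        u -= rc;
        double rm = ka * out_rate[a];
        if (u < rm) { ev_deme = a; is_coal = false; break; }
        u -= rm;
      }
      if (ev_deme < 0) ev_deme = d - 1;  // guard against rounding
      std::vector<int>& p = pool[ev_deme];
      if (is_coal && p.size() >= 2) {
        int i1 = (int)(unif_rand() * p.size());
        int i2 = (int)(unif_rand() * (p.size() - 1));
        if (i2 >= i1) ++i2;
        int c1 = p[i1], c2 = p[i2];
        blen[c1] = t - birth[c1];
        blen[c2] = t - birth[c2];
        int nn = next_node++;
        birth[nn] = t;
        child1[nn] = c1;
        child2[nn] = c2;
        // replace the two children by the parent (swap-pop the larger idx)
        int hi = std::max(i1, i2), lo = std::min(i1, i2);
        p[hi] = p.back(); p.pop_back();
        p[lo] = nn;
        --active;
      } else if (!is_coal && !p.empty()) {
        int il = (int)(unif_rand() * p.size());
        int lin = p[il];
        double v = unif_rand() * out_rate[ev_deme];
        int dest = -1;
        for (int b = 0; b < d; ++b) {
          if (b == ev_deme) continue;
          if (v < mig(ev_deme, b)) { dest = b; break; }
          v -= mig(ev_deme, b);
        }
        if (dest < 0) continue;  // rounding; redraw next iteration
        p[il] = p.back(); p.pop_back();
        pool[dest].push_back(lin);
      }
    }

    // place one mutation uniformly on the branches (root excluded)
    int root = next_node - 1;
    double total_len = 0.0;
    for (int i = 0; i < root; ++i) total_len += blen[i];
    double x = unif_rand() * total_len;
    int mut = root - 1;
    for (int i = 0; i < root; ++i) {
      if (x < blen[i]) { mut = i; break; }
      x -= blen[i];
    }
    // derived allele for every leaf below the mutated branch
    std::vector<int> stack;
    stack.push_back(mut);
    while (!stack.empty()) {
      int nd = stack.back(); stack.pop_back();
      if (nd < k) alleles(nd, loc) = 1;
      else {
        stack.push_back(child1[nd]);
        stack.push_back(child2[nd]);
      }
    }
  }
  return alleles;
}
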