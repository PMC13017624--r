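// Event loop of the birth-death / diversity-dependent Gillespie simulator.
// Uses R's RNG (so set.seed() governs reproducibility) and returns the
// lineage table; tree assembly happens in R. Each lineage is one edge:
// born at a branching event (or the crown), ended by speciation (two
// children), extinction, or the present.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_bdd_gillespie(int model, double lambda0, double mu0, double K,
                       double crown_age, int max_alive) {
  std::vector<int> parent = {0, 0};
  std::vector<double> t_birth = {0.0, 0.0};
  std::vector<double> t_end = {-1.0, -1.0};
  std::vector<int> n_children = {0, 0};
  std::vector<int> dead_idx;
  std::vector<int> alive = {0, 1};   // 0-based lineage ids
  double t = 0.0;
  bool oversize = false;
  while (true) {
    int n = (int)alive.size();
    if (n == 0) break;
    double lam = lambda0;
    if (model == 1) {
      lam = lambda0 - (lambda0 - mu0) * n / K;
      if (lam < 0) lam = 0;
    }
    double total = n * (lam + mu0);
    if (total <= 0) break;
    t += R::rexp(1.0 / total);
    if (t >= crown_age) break;
    int k = (int)(unif_rand() * n);
    if (k >= n) k = n - 1;
    int j = alive[k];
    if (unif_rand() < lam / (lam + mu0)) {
      int c1 = (int)parent.size(), c2 = c1 + 1;
      t_end[j] = t; n_children[j] = 2;
      parent.push_back(j + 1); parent.push_back(j + 1);  // 1-based for R
      t_birth.push_back(t); t_birth.push_back(t);
      t_end.push_back(-1.0); t_end.push_back(-1.0);
      n_children.push_back(0); n_children.push_back(0);
      alive[k] = c1;
      alive.push_back(c2);
      if ((int)alive.size() > max_alive) { oversize = true; break; }
    } else {
      t_end[j] = t;
      dead_idx.push_back(j);
      alive[k] = alive.back();
      alive.pop_back();
    }
  }
  int L = (int)parent.size();
  LogicalVector dead(L, false);
  for (int j : dead_idx) dead[j] = true;
  for (int j : alive) t_end[j] = crown_age;
  // fix 1-based parent for the two crown lineages (parent 0 = crown)
  IntegerVector par(L);
  for (int i = 0; i < L; ++i) par[i] = (i < 2) ? 0 : parent[i];
  return List::create(Named("parent") = par,
                      Named("t_birth") = NumericVector(t_birth.begin(), t_birth.end()),
                      Named("t_end") = NumericVector(t_end.begin(), t_end.end()),
                      Named("n_children") = IntegerVector(n_children.begin(), n_children.end()),
                      Named("dead") = dead,
                      Named("oversize") = oversize);
}
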