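// Minimum-free-energy RNA secondary structure prediction.
//
// Nearest-neighbor model: stacking energies for the canonical pair stacks
// plus hairpin/bulge/internal length penalties and an affine multiloop
// term; no dangles, no coaxial stacking, no special tetraloops.  All
// energies are integer deci-kcal/mol so the dynamic program and the
// exhaustive enumeration oracle compare exactly.
//
// Structures are fully nested (no pseudoknots), minimum hairpin loop 3,
// lonely pairs allowed, pairs restricted to {AU, UA, GC, CG, GU, UG}.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <string>

using namespace Rcpp;

static const int INF = 100000000;
static const int MIN_HP = 3;

struct EnergyModel {
  int stack[6][6];       // [outer pair][inner pair], deci-kcal
  std::vector<int> hairpin, bulge, internal_; // indexed by loop size
  int ml_a, ml_b, ml_c;  // multiloop closing / per-branch / per-unpaired
  int lncoef;            // deci-kcal per ln-unit for long-loop extrapolation
  int maxloop;           // interior/bulge size cap in the DP

  int loop_tab(const std::vector<int>& tab, int size) const {
    int m = (int)tab.size() - 1;
    if (size <= m) return tab[size];
    return tab[m] + (int)std::lround(lncoef * std::log((double)size / m));
  }
  int hp(int size) const {
    if (size < MIN_HP) return INF;
    return loop_tab(hairpin, size);
  }
  int bl(int size) const { return loop_tab(bulge, size); }
  int il(int size) const { return loop_tab(internal_, size); }
};

// base codes: A=0 C=1 G=2 U=3, other=-1
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'U': return 3;
    default: return -1;
  }
}

// pair types: AU=0 CG=1 GC=2 UA=3 GU=4 UG=5, else -1
static inline int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 1 && b == 2) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 3 && b == 0) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

static EnergyModel model_from_list(const List& par) {
  EnergyModel em;
  IntegerMatrix st = par["stack"];
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) em.stack[i][j] = st(i, j);
  IntegerVector hp = par["hairpin"], bl = par["bulge"], il = par["internal"];
  em.hairpin.assign(hp.begin(), hp.end());
  em.bulge.assign(bl.begin(), bl.end());
  em.internal_.assign(il.begin(), il.end());
  em.ml_a = as<int>(par["ml_a"]);
  em.ml_b = as<int>(par["ml_b"]);
  em.ml_c = as<int>(par["ml_c"]);
  em.lncoef = as<int>(par["lncoef"]);
  em.maxloop = as<int>(par["maxloop"]);
  return em;
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  return v;
}

// two-pair loop energy: stack / bulge / internal, by unpaired side sizes
static inline int two_loop_energy(const EnergyModel& em,
                                  const std::vector<int>& x,
                                  int i, int j, int k, int l) {
  int n1 = k - i - 1, n2 = j - l - 1;
  if (n1 == 0 && n2 == 0) {
    int p1 = pair_type(x[i], x[j]), p2 = pair_type(x[k], x[l]);
    return em.stack[p1][p2];
  }
  if (n1 == 0 || n2 == 0) return em.bl(n1 + n2);
  return em.il(n1 + n2);
}

// ---- standalone structure scorer (shared by energy_of and the oracle) ----

// pairs: partner index per position, -1 if unpaired (0-based)
static int score_structure(const EnergyModel& em, const std::vector<int>& x,
                           const std::vector<int>& pr) {
  int n = (int)x.size();
  long long total = 0;
  for (int i = 0; i < n; ++i) {
    int j = pr[i];
    if (j <= i) continue;  // visit each pair once, from its 5' side
    // children: pairs directly interior to (i,j)
    int nb = 0, unp = 0, k1 = -1, l1 = -1;
    int p = i + 1;
    while (p < j) {
      if (pr[p] > p) {
        if (nb == 0) { k1 = p; l1 = pr[p]; }
        ++nb;
        p = pr[p] + 1;
      } else {
        ++unp;
        ++p;
      }
    }
    if (nb == 0) {
      total += em.hp(j - i - 1);
    } else if (nb == 1) {
      total += two_loop_energy(em, x, i, j, k1, l1);
    } else {
      total += em.ml_a + em.ml_b * (nb + 1) + em.ml_c * unp;
    }
  }
  return (int)total;
}

// [[Rcpp::export(name = ".energy_pairs_cpp")]]
int energy_pairs_cpp(std::string seq, IntegerVector pairs, List par) {
  EnergyModel em = model_from_list(par);
  std::vector<int> x = encode(seq);
  std::vector<int> pr(pairs.begin(), pairs.end());
  return score_structure(em, x, pr);
}

// ---- Zuker-style dynamic program with traceback ----

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(std::string seq, List par) {
  EnergyModel em = model_from_list(par);
  std::vector<int> x = encode(seq);
  int n = (int)seq.size();
  if (n < 1) stop("empty sequence");

  std::vector<std::vector<int> > V(n, std::vector<int>(n, INF));
  std::vector<std::vector<int> > M1(n, std::vector<int>(n, INF));
  std::vector<std::vector<int> > ML(n, std::vector<int>(n, INF));

  for (int d = MIN_HP + 1; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      // V(i,j): i paired with j
      if (pair_type(x[i], x[j]) >= 0) {
        int best = em.hp(j - i - 1);
        // interior (stack/bulge/internal), loop size capped
        for (int k = i + 1; k <= j - 2 && (k - i - 1) <= em.maxloop; ++k) {
          int rem = em.maxloop - (k - i - 1);
          int lmin = j - 1 - rem; if (lmin < k + MIN_HP + 1) lmin = k + MIN_HP + 1;
          for (int l = j - 1; l >= lmin; --l) {
            if (V[k][l] >= INF) continue;
            if (k == i + 1 && l == j - 1 && pair_type(x[k], x[l]) < 0) continue;
            int e = two_loop_energy(em, x, i, j, k, l) + V[k][l];
            if (e < best) best = e;
          }
        }
        // multiloop: a + b + ML(i+1,k-1) + M1(k,j-1), >= 2 branches
        for (int k = i + 2; k <= j - 2; ++k) {
          if (ML[i + 1][k - 1] >= INF || M1[k][j - 1] >= INF) continue;
          int e = em.ml_a + em.ml_b + ML[i + 1][k - 1] + M1[k][j - 1];
          if (e < best) best = e;
        }
        V[i][j] = best;
      }
      // M1(i,j): multiloop segment, exactly one branch starting at i
      {
        int best = INF;
        if (j - 1 >= i && M1[i][j - 1] < INF) best = M1[i][j - 1] + em.ml_c;
        if (V[i][j] < INF && V[i][j] + em.ml_b < best) best = V[i][j] + em.ml_b;
        M1[i][j] = best;
      }
      // ML(i,j): multiloop segment, >= 1 branch
      {
        int best = M1[i][j];
        if (i + 1 <= j && ML[i + 1][j] < INF && ML[i + 1][j] + em.ml_c < best)
          best = ML[i + 1][j] + em.ml_c;
        for (int k = i + 1; k <= j; ++k) {
          if (ML[i][k - 1] >= INF || M1[k][j] >= INF) continue;
          int e = ML[i][k - 1] + M1[k][j];
          if (e < best) best = e;
        }
        ML[i][j] = best;
      }
    }
  }

  // exterior: W(i) = min energy of suffix [i, n)
  std::vector<int> W(n + 1, 0);
  for (int i = n - 1; i >= 0; --i) {
    int best = W[i + 1];
    for (int j = i + MIN_HP + 1; j < n; ++j) {
      if (V[i][j] >= INF) continue;
      int e = V[i][j] + W[j + 1];
      if (e < best) best = e;
    }
    W[i] = best;
  }

  // traceback: deterministic, preferring a paired leftmost position
  std::vector<int> pr(n, -1);
  struct Item { char t; int i, j; };
  std::vector<Item> st;
  st.push_back(Item{'W', 0, 0});
  while (!st.empty()) {
    Item it = st.back(); st.pop_back();
    if (it.t == 'W') {
      int i = it.i;
      if (i >= n) continue;
      bool done = false;
      for (int j = i + MIN_HP + 1; j < n && !done; ++j) {
        if (V[i][j] < INF && V[i][j] + W[j + 1] == W[i]) {
          st.push_back(Item{'V', i, j});
          st.push_back(Item{'W', j + 1, 0});
          done = true;
        }
      }
      if (!done) st.push_back(Item{'W', i + 1, 0});  // i unpaired
    } else if (it.t == 'V') {
      int i = it.i, j = it.j;
      pr[i] = j; pr[j] = i;
      bool done = false;
      for (int k = i + 1; k <= j - 2 && (k - i - 1) <= em.maxloop && !done; ++k) {
        int rem = em.maxloop - (k - i - 1);
        int lmin = j - 1 - rem; if (lmin < k + MIN_HP + 1) lmin = k + MIN_HP + 1;
        for (int l = j - 1; l >= lmin && !done; --l) {
          if (V[k][l] >= INF) continue;
          if (two_loop_energy(em, x, i, j, k, l) + V[k][l] == V[i][j]) {
            st.push_back(Item{'V', k, l});
            done = true;
          }
        }
      }
      for (int k = i + 2; k <= j - 2 && !done; ++k) {
        if (ML[i + 1][k - 1] >= INF || M1[k][j - 1] >= INF) continue;
        if (em.ml_a + em.ml_b + ML[i + 1][k - 1] + M1[k][j - 1] == V[i][j]) {
          st.push_back(Item{'M', i + 1, k - 1});
          st.push_back(Item{'1', k, j - 1});
          done = true;
        }
      }
      // else: hairpin, nothing to push
    } else if (it.t == '1') {
      int i = it.i, j = it.j;
      if (V[i][j] < INF && V[i][j] + em.ml_b == M1[i][j]) {
        st.push_back(Item{'V', i, j});
      } else {
        st.push_back(Item{'1', i, j - 1});  // j unpaired
      }
    } else {  // 'M'
      int i = it.i, j = it.j;
      if (M1[i][j] == ML[i][j]) {
        st.push_back(Item{'1', i, j});
        continue;
      }
      bool done = false;
      for (int k = i + 1; k <= j && !done; ++k) {
        if (ML[i][k - 1] >= INF || M1[k][j] >= INF) continue;
        if (ML[i][k - 1] + M1[k][j] == ML[i][j]) {
          st.push_back(Item{'M', i, k - 1});
          st.push_back(Item{'1', k, j});
          done = true;
        }
      }
      if (!done) st.push_back(Item{'M', i + 1, j});  // i unpaired
    }
  }

  std::string db(n, '.');
  for (int i = 0; i < n; ++i) {
    if (pr[i] > i) { db[i] = '('; db[pr[i]] = ')'; }
  }
  // self-check: traced structure reproduces the DP energy
  int check = score_structure(em, x, pr);
  if (check != W[0]) stop("internal error: traceback energy mismatch");

  IntegerVector pairs(pr.begin(), pr.end());
  return List::create(_["dotbracket"] = db, _["mfe_deci"] = W[0],
                      _["pairs"] = pairs);
}

// ---- exhaustive enumeration oracle (test support) ----
//
// Enumerates every valid nested structure and scores it with the same
// standalone scorer; independent of the dynamic program above.

struct EnumCtx {
  const EnergyModel* em;
  const std::vector<int>* x;
  std::vector<int> pr;
  std::vector<std::pair<int,int> > todo;
  int best;
  long long count;
};

static void enum_rec(EnumCtx& c) {
  if (c.todo.empty()) {
    int e = score_structure(*c.em, *c.x, c.pr);
    if (e < c.best) c.best = e;
    ++c.count;
    return;
  }
  std::pair<int,int> iv = c.todo.back();
  c.todo.pop_back();
  int i = iv.first, j = iv.second;  // half-open [i, j)
  if (i >= j) {
    enum_rec(c);
  } else {
    // i unpaired
    c.todo.push_back(std::make_pair(i + 1, j));
    enum_rec(c);
    c.todo.pop_back();
    // i paired with k
    for (int k = i + MIN_HP + 1; k < j; ++k) {
      if (pair_type((*c.x)[i], (*c.x)[k]) < 0) continue;
      c.pr[i] = k; c.pr[k] = i;
      c.todo.push_back(std::make_pair(k + 1, j));
      c.todo.push_back(std::make_pair(i + 1, k));
      enum_rec(c);
      c.todo.pop_back();
      c.todo.pop_back();
      c.pr[i] = -1; c.pr[k] = -1;
    }
  }
  c.todo.push_back(iv);
}

// [[Rcpp::export(name = ".enumerate_mfe_cpp")]]
List enumerate_mfe_cpp(std::string seq, List par) {
  EnergyModel em = model_from_list(par);
  std::vector<int> x = encode(seq);
  int n = (int)x.size();
  if (n > 40) stop("enumeration oracle limited to <= 40 nt");
  EnumCtx c;
  c.em = &em; c.x = &x;
  c.pr.assign(n, -1);
  c.best = 0;  // open chain
  c.count = 0;
  c.todo.push_back(std::make_pair(0, n));
  enum_rec(c);
  return List::create(_["mfe_deci"] = c.best,
                      _["n_structures"] = (double)c.count);
}
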