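#include <Rcpp.h>
using namespace Rcpp;

// Individual-based community dynamics. Sites hold 0 (empty) or a species
// id in 1..S. All randomness goes through R's RNG so set.seed() in R
// makes runs bit-reproducible.

static inline int unif_index(int n) {
  // uniform integer in 0..n-1 (n >= 1)
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// uniformly chosen index of a site whose occupancy flag matches `want`
// (rejection sampling; occupancy is dense in practice). Returns -1 when
// no such site exists.
static int pick_site(const std::vector<int>& sites, bool want_occupied,
                     int n_occupied) {
  int I = sites.size();
  int avail = want_occupied ? n_occupied : I - n_occupied;
  if (avail == 0) return -1;
  if (avail > I / 8) {
    for (;;) {
      int s = unif_index(I);
      if ((sites[s] > 0) == want_occupied) return s;
    }
  }
  // sparse case: enumerate
  int r = unif_index(avail);
  for (int s = 0; s < I; ++s) {
    if ((sites[s] > 0) == want_occupied && r-- == 0) return s;
  }
  return -1; // unreachable
}

// Self-organized instability dynamics. Per timestep: (1) immigration of
// each species into one empty site with its migration probability;
// (2) I interaction/growth events: random occupied site a (species i)
// meets random other site b; empty b is colonised with prob growth_prob,
// occupied b (species j) is resolved by the net pairwise effect
// delta = A[i,j] - A[j,i] (positive: i displaces j at b with prob
// min(1, delta); negative: j displaces i at a with prob min(1, -delta));
// (3) extinction: every occupied site is vacated with prob
// extinction_prob.
// [[Rcpp::export]]
List soi_dynamics_cpp(IntegerVector sites0, NumericMatrix A,
                      NumericVector migration, double growth_prob,
                      double extinction_prob, int timesteps,
                      bool trajectory) {
  int I = sites0.size();
  int S = A.nrow();
  std::vector<int> sites(sites0.begin(), sites0.end());
  int n_occ = 0;
  for (int s = 0; s < I; ++s) if (sites[s] > 0) ++n_occ;

  IntegerMatrix traj(trajectory ? timesteps : 0, trajectory ? S : 0);

  for (int t = 0; t < timesteps; ++t) {
    // (1) immigration
    for (int sp = 1; sp <= S; ++sp) {
      if (n_occ < I && unif_rand() < migration[sp - 1]) {
        int b = pick_site(sites, false, n_occ);
        sites[b] = sp;
        ++n_occ;
      }
    }
    // (2) interaction / growth events
    for (int ev = 0; ev < I; ++ev) {
      if (n_occ == 0) break;
      int a = pick_site(sites, true, n_occ);
      int b = unif_index(I - 1);
      if (b >= a) ++b; // uniform over sites != a
      int i = sites[a];
      if (sites[b] == 0) {
        if (unif_rand() < growth_prob) {
          sites[b] = i;
          ++n_occ;
        }
      } else {
        int j = sites[b];
        if (j != i) {
          double delta = A(i - 1, j - 1) - A(j - 1, i - 1);
          if (delta > 0) {
            if (unif_rand() < std::min(1.0, delta)) sites[b] = i;
          } else if (delta < 0) {
            if (unif_rand() < std::min(1.0, -delta)) sites[a] = j;
          }
        }
      }
    }
    // (3) extinction
    if (extinction_prob > 0) {
      for (int s = 0; s < I; ++s) {
        if (sites[s] > 0 && unif_rand() < extinction_prob) {
          sites[s] = 0;
          --n_occ;
        }
      }
    }
    if (trajectory) {
      for (int s = 0; s < I; ++s) if (sites[s] > 0) traj(t, sites[s] - 1)++;
    }
  }

  IntegerVector abundance(S);
  IntegerVector final_sites(I);
  for (int s = 0; s < I; ++s) {
    final_sites[s] = sites[s];
    if (sites[s] > 0) abundance[sites[s] - 1]++;
  }
  List out = List::create(_["abundance"] = abundance,
                          _["sites"] = final_sites);
  if (trajectory) out["trajectory"] = traj;
  return out;
}

// Zero-sum neutral (Hubbell) dynamics: per timestep, d uniformly chosen
// individuals die and are each immediately replaced, by an immigrant with
// probability mbar = mean(migration) (species drawn proportional to the
// migration probabilities) or else by the offspring of a uniformly chosen
// other local individual. Occupancy stays at I throughout.
// [[Rcpp::export]]
List hubbell_dynamics_cpp(IntegerVector sites0, NumericVector migration,
                          int deaths_per_step, int timesteps,
                          bool trajectory) {
  int I = sites0.size();
  int S = migration.size();
  std::vector<int> sites(sites0.begin(), sites0.end());

  double mig_total = 0.0, mbar = 0.0;
  std::vector<double> cum(S, 0.0);
  for (int sp = 0; sp < S; ++sp) {
    mig_total += migration[sp];
    cum[sp] = mig_total;
  }
  mbar = mig_total / S;

  IntegerMatrix traj(trajectory ? timesteps : 0, trajectory ? S : 0);

  for (int t = 0; t < timesteps; ++t) {
    for (int d = 0; d < deaths_per_step; ++d) {
      int a = unif_index(I);
      if (mig_total > 0 && unif_rand() < mbar) {
        double u = unif_rand() * mig_total;
        int sp = (int)(std::lower_bound(cum.begin(), cum.end(), u) -
                       cum.begin());
        if (sp >= S) sp = S - 1;
        sites[a] = sp + 1;
      } else {
        int b = unif_index(I - 1);
        if (b >= a) ++b; // a surviving (other) individual
        sites[a] = sites[b];
      }
    }
    if (trajectory) {
      for (int s = 0; s < I; ++s) traj(t, sites[s] - 1)++;
    }
  }

  IntegerVector abundance(S);
  IntegerVector final_sites(I);
  for (int s = 0; s < I; ++s) {
    final_sites[s] = sites[s];
    abundance[sites[s] - 1]++;
  }
  List out = List::create(_["abundance"] = abundance,
                          _["sites"] = final_sites);
  if (trajectory) out["trajectory"] = traj;
  return out;
}
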