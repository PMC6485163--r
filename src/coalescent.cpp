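// Structured-coalescent simulator for fragmented genomes.
//
// Each fragment is an independent non-recombining coalescent replicate under
// a demography of populations with constant diploid sizes, timed rootward
// merges ("splits", viewed forward in time), instantaneous introgression
// pulses, and continuous migration among coexisting populations. Mutations
// are laid down on branches under the infinite-sites model at rate mu per bp
// per generation; sites are polarized by construction (the ancestral state
// is the root state).
//
// Uses R's RNG throughout so results are reproducible via set.seed().

#include <Rcpp.h>
#include <vector>
#include <set>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Branch {
  uint64_t mask;
  double len;
};

struct Discrete {
  double time;
  int kind;  // 0 = split (move all), 1 = pulse (move each w.p. prop)
  int from;  // population losing lineages (split child / pulse dest)
  int to;    // population receiving lineages (split parent / pulse source)
  double prop;
};

}  // namespace

// [[Rcpp::export]]
List sim_fragments_cpp(NumericVector pop_ne,
                       IntegerVector sample_pop,     // per diploid, 0-based
                       NumericVector sample_time,    // generations
                       NumericVector ev_time,        // discrete events, sorted
                       IntegerVector ev_kind,
                       IntegerVector ev_from,
                       IntegerVector ev_to,
                       NumericVector ev_prop,
                       IntegerVector mig_from,       // forward-time source
                       IntegerVector mig_to,         // forward-time dest
                       NumericVector mig_rate,
                       NumericVector frag_len,
                       double mu) {
  const int npop = pop_ne.size();
  const int nind = sample_pop.size();
  const int nlin_total = 2 * nind;
  const int nev = ev_time.size();
  const int nmig = mig_rate.size();
  const int nfrag = frag_len.size();
  if (nind < 1) stop("no samples");
  if (nind > 31) stop("at most 31 diploid samples supported");

  // sample introduction order by time
  std::vector<int> sord(nind);
  for (int i = 0; i < nind; ++i) sord[i] = i;
  std::stable_sort(sord.begin(), sord.end(), [&](int a, int b) {
    return sample_time[a] < sample_time[b];
  });

  std::vector<int> out_frag;
  std::vector<int> out_pos;
  std::vector<std::vector<int>> out_dos(nind);

  std::vector<int> lin_pop;
  std::vector<uint64_t> lin_mask;
  std::vector<double> lin_birth;
  std::vector<Branch> branches;
  std::vector<char> merged(npop);
  std::vector<int> npl(npop);  // lineages per population

  for (int f = 0; f < nfrag; ++f) {
    const double L = frag_len[f];
    lin_pop.clear(); lin_mask.clear(); lin_birth.clear();
    branches.clear();
    std::fill(merged.begin(), merged.end(), 0);
    std::fill(npl.begin(), npl.end(), 0);

    int next_sample = 0;  // index into sord
    int next_ev = 0;
    double t = 0.0;

    auto introduce = [&](int ind) {
      for (int h = 0; h < 2; ++h) {
        lin_pop.push_back(sample_pop[ind]);
        lin_mask.push_back(uint64_t(1) << (2 * ind + h));
        lin_birth.push_back(sample_time[ind]);
        npl[sample_pop[ind]]++;
      }
    };
    // introduce all samples at time 0 (or earliest)
    while (next_sample < nind && sample_time[sord[next_sample]] <= 0.0) {
      introduce(sord[next_sample]);
      ++next_sample;
    }

    auto remove_lineage = [&](int i) {
      npl[lin_pop[i]]--;
      lin_pop[i] = lin_pop.back(); lin_pop.pop_back();
      lin_mask[i] = lin_mask.back(); lin_mask.pop_back();
      lin_birth[i] = lin_birth.back(); lin_birth.pop_back();
    };

    int pending = nind - next_sample;
    while ((int)lin_pop.size() + 2 * pending > 1) {
      // next discrete time
      double t_disc = R_PosInf;
      if (next_ev < nev) t_disc = ev_time[next_ev];
      if (pending > 0)
        t_disc = std::min(t_disc, sample_time[sord[next_sample]]);

      // total continuous rate
      double rate = 0.0;
      for (int p = 0; p < npop; ++p) {
        if (npl[p] >= 2)
          rate += npl[p] * (npl[p] - 1.0) / (4.0 * pop_ne[p]);
      }
      for (int m = 0; m < nmig; ++m) {
        if (!merged[mig_from[m]] && !merged[mig_to[m]])
          rate += npl[mig_to[m]] * mig_rate[m];
      }

      double t_cont = R_PosInf;
      if (rate > 0.0) t_cont = t + exp_rand() / rate;

      if (t_cont < t_disc) {
        t = t_cont;
        double u = unif_rand() * rate;
        bool done = false;
        for (int p = 0; p < npop && !done; ++p) {
          if (npl[p] < 2) continue;
          double r = npl[p] * (npl[p] - 1.0) / (4.0 * pop_ne[p]);
          if (u < r) {
            // coalesce a random pair in p
            int k = npl[p];
            int a = (int)(unif_rand() * k); if (a >= k) a = k - 1;
            int b = (int)(unif_rand() * (k - 1)); if (b >= k - 1) b = k - 2;
            if (b >= a) ++b;
            // map a,b (indices among lineages in p) to global indices
            int ia = -1, ib = -1, seen = 0;
            for (int i = 0; i < (int)lin_pop.size(); ++i) {
              if (lin_pop[i] == p) {
                if (seen == a) ia = i;
                if (seen == b) ib = i;
                ++seen;
              }
            }
            branches.push_back({lin_mask[ia], t - lin_birth[ia]});
            branches.push_back({lin_mask[ib], t - lin_birth[ib]});
            uint64_t m2 = lin_mask[ia] | lin_mask[ib];
            if (ia < ib) std::swap(ia, ib);  // remove higher index first
            remove_lineage(ia);
            remove_lineage(ib);
            lin_pop.push_back(p);
            lin_mask.push_back(m2);
            lin_birth.push_back(t);
            npl[p]++;
            done = true;
          } else u -= r;
        }
        if (!done) {
          for (int m = 0; m < nmig && !done; ++m) {
            if (merged[mig_from[m]] || merged[mig_to[m]]) continue;
            double r = npl[mig_to[m]] * mig_rate[m];
            if (u < r) {
              int k = npl[mig_to[m]];
              int a = (int)(unif_rand() * k); if (a >= k) a = k - 1;
              int seen = 0;
              for (int i = 0; i < (int)lin_pop.size(); ++i) {
                if (lin_pop[i] == mig_to[m]) {
                  if (seen == a) {
                    npl[lin_pop[i]]--;
                    lin_pop[i] = mig_from[m];
                    npl[mig_from[m]]++;
                    break;
                  }
                  ++seen;
                }
              }
              done = true;
            } else u -= r;
          }
        }
        if (!done) stop("internal: rate walk failed");
      } else {
        if (!R_FINITE(t_disc)) stop("internal: no events left but >1 lineage");
        t = t_disc;
        // apply all discrete items at exactly this time: samples first
        while (pending > 0 && sample_time[sord[next_sample]] <= t) {
          introduce(sord[next_sample]);
          ++next_sample; --pending;
        }
        while (next_ev < nev && ev_time[next_ev] <= t) {
          const int kind = ev_kind[next_ev];
          const int from = ev_from[next_ev];
          const int to = ev_to[next_ev];
          if (kind == 0) {  // split: move everything, close population
            for (int i = 0; i < (int)lin_pop.size(); ++i) {
              if (lin_pop[i] == from) {
                npl[from]--; lin_pop[i] = to; npl[to]++;
              }
            }
            merged[from] = 1;
          } else {  // pulse
            const double pr = ev_prop[next_ev];
            if (pr > 0) {
              for (int i = 0; i < (int)lin_pop.size(); ++i) {
                if (lin_pop[i] == from && unif_rand() < pr) {
                  npl[from]--; lin_pop[i] = to; npl[to]++;
                }
              }
            }
          }
          ++next_ev;
        }
      }
    }

    // mutations
    std::set<int> used;
    for (const Branch& br : branches) {
      int nm = (int)R::rpois(mu * L * br.len);
      for (int m = 0; m < nm; ++m) {
        int pos;
        int tries = 0;
        do {
          pos = (int)(unif_rand() * L);
          if (pos >= (int)L) pos = (int)L - 1;
        } while (used.count(pos) && ++tries < 100);
        if (used.count(pos)) continue;  // fragment saturated
        used.insert(pos);
        out_frag.push_back(f + 1);
        out_pos.push_back(pos);
        for (int i = 0; i < nind; ++i) {
          int d = (int)((br.mask >> (2 * i)) & 1) +
                  (int)((br.mask >> (2 * i + 1)) & 1);
          out_dos[i].push_back(d);
        }
      }
    }
  }

  const int nsite = out_frag.size();
  IntegerMatrix geno(nsite, nind);
  for (int i = 0; i < nind; ++i)
    for (int s = 0; s < nsite; ++s) geno(s, i) = out_dos[i][s];

  return List::create(_["frag"] = wrap(out_frag),
                      _["pos"] = wrap(out_pos),
                      _["geno"] = geno);
}
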