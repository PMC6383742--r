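// Forward Wright-Fisher simulator with recombination, infinite-sites
// mutation, a population split, recent unidirectional migration, optional
// positive selection on donor-derived alleles, and donor-ancestry tract
// tracking.  All randomness goes through R's RNG so runs are reproducible
// under set.seed().
//
// Haplotypes store sorted derived-mutation positions (continuous in [0, L))
// and, during the migration phase, sorted disjoint donor-origin tracts.
// Mutations fixed within a closed population are periodically moved to a
// per-population "fixed background" and merged back into every haplotype
// when contact (migration) begins; globally fixed burn-in mutations are
// dropped outright (they would be monomorphic in any sample).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <utility>
using namespace Rcpp;

typedef std::pair<double, double> Tract;

struct Hap {
  std::vector<double> mut;
  std::vector<Tract> donor;
};

typedef std::vector<Hap> Pop;  // 2N haplotypes; individual i = 2i, 2i+1

static inline int runif_int(int n) {
  int j = (int)(unif_rand() * n);
  return j >= n ? n - 1 : j;
}

// Poisson by inversion; adequate for the small per-meiosis rates used here.
static inline int rpois_small(double lambda) {
  const double limit = std::exp(-lambda);
  double p = 1.0;
  int k = -1;
  do { ++k; p *= unif_rand(); } while (p > limit);
  return k;
}

static void meiosis(const Hap& a, const Hap& b, Hap& child, double L,
                    double rec_hap, double mu_hap, bool track,
                    std::vector<double>& cuts) {
  child.mut.clear();
  child.donor.clear();
  int k = rpois_small(rec_hap);
  cuts.clear();
  for (int i = 0; i < k; ++i) cuts.push_back(unif_rand() * L);
  std::sort(cuts.begin(), cuts.end());
  bool useA = unif_rand() < 0.5;
  double seg_start = 0.0;
  size_t ci = 0;
  size_t ia = 0, ib = 0;    // monotone cursors into the parents' mutations
  size_t ta = 0, tb = 0;    // and into their donor-tract lists
  for (;;) {
    const double seg_end = (ci < cuts.size()) ? cuts[ci] : L;
    const Hap& src = useA ? a : b;
    size_t& cur = useA ? ia : ib;
    if (seg_end > seg_start) {
      const std::vector<double>& mv = src.mut;
      while (cur < mv.size() && mv[cur] < seg_start) ++cur;
      while (cur < mv.size() && mv[cur] < seg_end) {
        child.mut.push_back(mv[cur]);
        ++cur;
      }
      if (track && !src.donor.empty()) {
        size_t& tcur = useA ? ta : tb;
        const std::vector<Tract>& tv = src.donor;
        while (tcur < tv.size() && tv[tcur].second <= seg_start) ++tcur;
        for (size_t t = tcur; t < tv.size() && tv[t].first < seg_end; ++t) {
          double s = std::max(tv[t].first, seg_start);
          double e = std::min(tv[t].second, seg_end);
          if (e <= s) continue;
          if (!child.donor.empty() && child.donor.back().second >= s)
            child.donor.back().second =
              std::max(child.donor.back().second, e);
          else
            child.donor.push_back(Tract(s, e));
        }
      }
    }
    if (ci >= cuts.size()) break;
    seg_start = seg_end;
    useA = !useA;
    ++ci;
  }
  int nm = rpois_small(mu_hap);
  for (int i = 0; i < nm; ++i) {
    double p = unif_rand() * L;
    std::vector<double>::iterator it =
      std::lower_bound(child.mut.begin(), child.mut.end(), p);
    if (it == child.mut.end() || *it != p) child.mut.insert(it, p);
  }
}

// Remove mutations fixed in every haplotype of `pop`; append them to
// `store` (or discard when store is NULL).
static void purge_fixed(Pop& pop, std::vector<double>* store,
                        std::vector<double>& buf1, std::vector<double>& buf2) {
  if (pop.empty()) return;
  std::vector<double> fixed = pop[0].mut;
  for (size_t h = 1; h < pop.size() && !fixed.empty(); ++h) {
    buf1.clear();
    std::set_intersection(fixed.begin(), fixed.end(),
                          pop[h].mut.begin(), pop[h].mut.end(),
                          std::back_inserter(buf1));
    fixed.swap(buf1);
  }
  if (fixed.empty()) return;
  for (size_t h = 0; h < pop.size(); ++h) {
    buf2.clear();
    std::set_difference(pop[h].mut.begin(), pop[h].mut.end(),
                        fixed.begin(), fixed.end(),
                        std::back_inserter(buf2));
    pop[h].mut.swap(buf2);
  }
  if (store)
    store->insert(store->end(), fixed.begin(), fixed.end());
}

// One generation of `N_child` diploids written into dst.  Parents come
// from `mig_src` (both parents) with probability m, else from `self`.
// When `fit_cum` is non-null, self-parents are drawn proportional to
// fitness; migrant parents are always drawn uniformly.
static void next_gen(const Pop& self, const Pop* mig_src, double m,
                     const std::vector<double>* fit_cum, Pop& dst,
                     int N_child, double L, double rec_hap, double mu_hap,
                     bool track, std::vector<double>& cuts) {
  const int N_self = (int)(self.size() / 2);
  dst.resize(2 * (size_t)N_child);
  for (int i = 0; i < N_child; ++i) {
    const Pop* src = &self;
    bool migrant = false;
    if (mig_src && m > 0.0 && unif_rand() < m) {
      src = mig_src;
      migrant = true;
    }
    const int N_src = (int)(src->size() / 2);
    for (int g = 0; g < 2; ++g) {
      int par;
      if (!migrant && fit_cum) {
        const double u = unif_rand() * fit_cum->back();
        par = (int)(std::lower_bound(fit_cum->begin(), fit_cum->end(), u) -
                    fit_cum->begin());
        if (par >= N_self) par = N_self - 1;
      } else {
        par = runif_int(N_src);
      }
      meiosis((*src)[2 * par], (*src)[2 * par + 1], dst[2 * i + g], L,
              rec_hap, mu_hap, track, cuts);
    }
  }
}

static int count_matches(const std::vector<double>& a,
                         const std::vector<double>& b) {
  int n = 0;
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) ++i;
    else if (b[j] < a[i]) ++j;
    else { ++n; ++i; ++j; }
  }
  return n;
}

static void sample_indices(int N, int n, std::vector<int>& out) {
  std::vector<int> pool(N);
  for (int i = 0; i < N; ++i) pool[i] = i;
  out.clear();
  for (int i = 0; i < n; ++i) {
    int j = i + runif_int(N - i);
    std::swap(pool[i], pool[j]);
    out.push_back(pool[i]);
  }
  std::sort(out.begin(), out.end());
}

// [[Rcpp::export(name = ".forward_sim_cpp")]]
List forward_sim_cpp(double L, double mu_hap, double rec_hap,
                     int N1, int N2, int N0,
                     int burn_gens, int div_gens, int mig_gens,
                     double m, double s, double benefit_frac,
                     int ns0, int ns1, int ns2, int purge_every,
                     int init_sfs, int anc_gens) {
  Pop p1(2 * (size_t)N1), p1b, p2, p2b, p0, p0b;
  std::vector<double> cuts, buf1, buf2;
  std::vector<double> fixed1, fixed2;

  if (init_sfs) {
    // seed P1 with standing variation drawn from the neutral site
    // frequency spectrum (P(count = i) proportional to 1/i); linkage
    // equilibrates during the subsequent forward generations
    const int n_hap = 2 * N1;
    std::vector<double> cum(n_hap - 1);
    double a = 0.0;
    for (int i = 1; i < n_hap; ++i) {
      a += 1.0 / i;
      cum[i - 1] = a;
    }
    const double theta = 4.0 * N1 * mu_hap;  // mu_hap is the genome rate
    const int S0 = (int) R::rpois(theta * a);
    std::vector<int> pool(n_hap);
    for (int i = 0; i < n_hap; ++i) pool[i] = i;
    for (int sidx = 0; sidx < S0; ++sidx) {
      const double pos = unif_rand() * L;
      const double u = unif_rand() * a;
      const int c = (int)(std::lower_bound(cum.begin(), cum.end(), u) -
                          cum.begin()) + 1;
      for (int i = 0; i < c; ++i) {
        int j = i + runif_int(n_hap - i);
        std::swap(pool[i], pool[j]);
        p1[pool[i]].mut.push_back(pos);
      }
    }
    for (int h = 0; h < n_hap; ++h)
      std::sort(p1[h].mut.begin(), p1[h].mut.end());
  }

  // burn-in: P1 alone; globally fixed mutations are dropped
  for (int g = 0; g < burn_gens; ++g) {
    next_gen(p1, NULL, 0.0, NULL, p1b, N1, L, rec_hap, mu_hap, false, cuts);
    p1.swap(p1b);
    if ((g + 1) % purge_every == 0) purge_fixed(p1, NULL, buf1, buf2);
  }
  purge_fixed(p1, NULL, buf1, buf2);

  // split: P2's founding generation drawn from P1
  next_gen(p1, NULL, 0.0, NULL, p2, N2, L, rec_hap, mu_hap, false, cuts);
  // The ancestor-proxy P0 splits from P1 `anc_gens` generations before
  // sampling; any part of that predating the migration phase falls inside
  // the divergence phase.  P0 and P1 share the P1 fixed background, so
  // their joint fixed sites must stay in the haplotype lists once P0
  // exists: stop moving P1 fixations aside from that point on.
  const int pre_mig = std::max(0, anc_gens - mig_gens);
  const int p0_at = div_gens - std::min(pre_mig, div_gens);
  bool p0_alive = false;
  for (int g = 0; g < div_gens; ++g) {
    if (!p0_alive && g == p0_at) {
      std::sort(fixed1.begin(), fixed1.end());
      for (size_t h = 0; h < p1.size(); ++h) {
        buf1.clear();
        std::merge(p1[h].mut.begin(), p1[h].mut.end(),
                   fixed1.begin(), fixed1.end(), std::back_inserter(buf1));
        p1[h].mut.swap(buf1);
      }
      fixed1.clear();
      next_gen(p1, NULL, 0.0, NULL, p0, N0, L, rec_hap, mu_hap, false,
               cuts);
      p0_alive = true;
    }
    next_gen(p1, NULL, 0.0, NULL, p1b, N1, L, rec_hap, mu_hap, false, cuts);
    next_gen(p2, NULL, 0.0, NULL, p2b, N2, L, rec_hap, mu_hap, false, cuts);
    p1.swap(p1b);
    p2.swap(p2b);
    if (p0_alive) {
      next_gen(p0, NULL, 0.0, NULL, p0b, N0, L, rec_hap, mu_hap, false,
               cuts);
      p0.swap(p0b);
    }
    if ((g + 1) % purge_every == 0) {
      if (!p0_alive) purge_fixed(p1, &fixed1, buf1, buf2);
      purge_fixed(p2, &fixed2, buf1, buf2);
    }
  }

  // restore fixed backgrounds before contact
  std::sort(fixed1.begin(), fixed1.end());
  std::sort(fixed2.begin(), fixed2.end());
  if (!fixed1.empty())
    for (size_t h = 0; h < p1.size(); ++h) {
      buf1.clear();
      std::merge(p1[h].mut.begin(), p1[h].mut.end(),
                 fixed1.begin(), fixed1.end(), std::back_inserter(buf1));
      p1[h].mut.swap(buf1);
    }
  for (size_t h = 0; h < p2.size(); ++h) {
    buf1.clear();
    std::merge(p2[h].mut.begin(), p2[h].mut.end(),
               fixed2.begin(), fixed2.end(), std::back_inserter(buf1));
    p2[h].mut.swap(buf1);
  }

  // label ancestry: everything in P2 is donor material from here on
  for (size_t h = 0; h < p2.size(); ++h) {
    p2[h].donor.clear();
    p2[h].donor.push_back(Tract(0.0, L));
  }

  // designate beneficial donor alleles: donor-private polymorphic sites
  std::vector<double> benefit;
  if (s > 0.0 && benefit_frac > 0.0) {
    std::vector<double> donor_all;
    for (size_t h = 0; h < p2.size(); ++h)
      donor_all.insert(donor_all.end(), p2[h].mut.begin(), p2[h].mut.end());
    std::sort(donor_all.begin(), donor_all.end());
    donor_all.erase(std::unique(donor_all.begin(), donor_all.end()),
                    donor_all.end());
    // donor-private: absent from every P1 haplotype
    std::vector<double> p1_all;
    for (size_t h = 0; h < p1.size(); ++h)
      p1_all.insert(p1_all.end(), p1[h].mut.begin(), p1[h].mut.end());
    std::sort(p1_all.begin(), p1_all.end());
    p1_all.erase(std::unique(p1_all.begin(), p1_all.end()), p1_all.end());
    std::vector<double> priv;
    std::set_difference(donor_all.begin(), donor_all.end(),
                        p1_all.begin(), p1_all.end(),
                        std::back_inserter(priv));
    int nb = (int)(benefit_frac * priv.size() + 0.5);
    if (nb < 1) nb = 1;
    if (nb > (int)priv.size()) nb = (int)priv.size();
    for (int i = 0; i < nb && !priv.empty(); ++i) {
      int j = i + runif_int((int)priv.size() - i);
      std::swap(priv[i], priv[j]);
      benefit.push_back(priv[i]);
    }
    std::sort(benefit.begin(), benefit.end());
  }

  // if it has not already split during divergence, the ancestor-proxy
  // population P0 splits from P1 at migration start
  if (!p0_alive)
    next_gen(p1, NULL, 0.0, NULL, p0, N0, L, rec_hap, mu_hap, true, cuts);

  // migration phase
  std::vector<double> fit_cum(N1);
  for (int g = 0; g < mig_gens; ++g) {
    const std::vector<double>* fit = NULL;
    if (!benefit.empty()) {
      double acc = 0.0;
      for (int i = 0; i < N1; ++i) {
        int copies = count_matches(p1[2 * i].mut, benefit) +
                     count_matches(p1[2 * i + 1].mut, benefit);
        acc += std::pow(1.0 + s, copies);
        fit_cum[i] = acc;
      }
      fit = &fit_cum;
    }
    next_gen(p1, &p2, m, fit, p1b, N1, L, rec_hap, mu_hap, true, cuts);
    next_gen(p2, NULL, 0.0, NULL, p2b, N2, L, rec_hap, mu_hap, true, cuts);
    next_gen(p0, NULL, 0.0, NULL, p0b, N0, L, rec_hap, mu_hap, true, cuts);
    p1.swap(p1b);
    p2.swap(p2b);
    p0.swap(p0b);
  }

  // sample diploids
  std::vector<int> s0, s1, s2;
  sample_indices(N0, ns0, s0);
  sample_indices(N1, ns1, s1);
  sample_indices(N2, ns2, s2);

  std::vector<const Hap*> haps;
  for (size_t i = 0; i < s0.size(); ++i) {
    haps.push_back(&p0[2 * s0[i]]);
    haps.push_back(&p0[2 * s0[i] + 1]);
  }
  const size_t rec_first = haps.size();
  for (size_t i = 0; i < s1.size(); ++i) {
    haps.push_back(&p1[2 * s1[i]]);
    haps.push_back(&p1[2 * s1[i] + 1]);
  }
  const size_t rec_last = haps.size();  // one past
  for (size_t i = 0; i < s2.size(); ++i) {
    haps.push_back(&p2[2 * s2[i]]);
    haps.push_back(&p2[2 * s2[i] + 1]);
  }
  const int H = (int)haps.size();

  // segregating sites among the sampled haplotypes
  std::vector<double> all;
  for (int h = 0; h < H; ++h)
    all.insert(all.end(), haps[h]->mut.begin(), haps[h]->mut.end());
  std::sort(all.begin(), all.end());
  std::vector<double> sites;
  std::vector<int> freq;
  for (size_t i = 0; i < all.size();) {
    size_t j = i;
    while (j < all.size() && all[j] == all[i]) ++j;
    if ((int)(j - i) < H) {  // not fixed in the sample
      sites.push_back(all[i]);
      freq.push_back((int)(j - i));
    }
    i = j;
  }
  const int S = (int)sites.size();

  IntegerMatrix alleles(H, S);
  for (int h = 0; h < H; ++h) {
    const std::vector<double>& mv = haps[h]->mut;
    size_t i = 0, j = 0;
    while (i < mv.size() && j < sites.size()) {
      if (mv[i] < sites[j]) ++i;
      else if (sites[j] < mv[i]) ++j;
      else { alleles(h, (int)j) = 1; ++i; ++j; }
    }
  }

  // donor-origin truth tracts of the sampled recipient haplotypes
  std::vector<int> t_hap;
  std::vector<double> t_start, t_end;
  double donor_bp = 0.0;
  for (size_t h = rec_first; h < rec_last; ++h) {
    const std::vector<Tract>& d = haps[h]->donor;
    for (size_t t = 0; t < d.size(); ++t) {
      t_hap.push_back((int)(h - rec_first) + 1);
      t_start.push_back(d[t].first);
      t_end.push_back(d[t].second);
      donor_bp += d[t].second - d[t].first;
    }
  }
  const double true_fraction =
    100.0 * donor_bp / ((double)(rec_last - rec_first) * L);

  return List::create(
    _["positions"] = NumericVector(sites.begin(), sites.end()),
    _["alleles"] = alleles,
    _["tract_hap"] = IntegerVector(t_hap.begin(), t_hap.end()),
    _["tract_start"] = NumericVector(t_start.begin(), t_start.end()),
    _["tract_end"] = NumericVector(t_end.begin(), t_end.end()),
    _["true_donor_fraction"] = true_fraction,
    _["benefit_positions"] = NumericVector(benefit.begin(), benefit.end()),
    _["n_sampled"] = IntegerVector::create(ns0, ns1, ns2));
}
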