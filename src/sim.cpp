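// Forward simulator of a recurrent-selection breeding program.
//
// Haplotypes inside the program loop are ancestry-segment lists over the
// four root haplotypes of the current cross; full marker vectors are only
// instantiated for lines that are kept. Crossovers follow a Poisson /
// no-interference model (Haldane). All randomness comes from R's RNG so
// set.seed() on the R side is reproducible.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// ---- segment representation --------------------------------------------

struct Seg { double end; int src; };
typedef std::vector<Seg> Hap; // covers (0, L], sorted by end

static Hap whole(double L, int src) {
  Hap h(1);
  h[0].end = L; h[0].src = src;
  return h;
}

// one gamete from a pair of segment haplotypes on one chromosome
static Hap gamete_seg(const Hap &h1, const Hap &h2, double L) {
  int k = (int) R::rpois(L / 100.0); // cM -> Morgans
  std::vector<double> cuts(k);
  for (int i = 0; i < k; ++i) cuts[i] = R::unif_rand() * L;
  std::sort(cuts.begin(), cuts.end());
  cuts.push_back(L);
  int strand = (R::unif_rand() < 0.5) ? 0 : 1;
  Hap out;
  double a = 0.0;
  size_t i1 = 0, i2 = 0;
  for (size_t c = 0; c < cuts.size(); ++c) {
    double b = cuts[c];
    if (b > a) {
      const Hap &h = strand == 0 ? h1 : h2;
      size_t &ii = strand == 0 ? i1 : i2;
      // advance to first segment ending beyond a
      while (ii < h.size() && h[ii].end <= a) ++ii;
      size_t j = ii;
      double lo = a;
      while (lo < b && j < h.size()) {
        double hi = std::min(h[j].end, b);
        if (!out.empty() && out.back().src == h[j].src) out.back().end = hi;
        else { Seg s; s.end = hi; s.src = h[j].src; out.push_back(s); }
        lo = hi;
        if (h[j].end <= b) ++j;
      }
      a = b;
    }
    strand = 1 - strand;
  }
  if (out.empty()) out = whole(L, h1.empty() ? 0 : h1[0].src);
  out.back().end = L;
  return out;
}

static int src_at(const Hap &h, double pos) {
  // first segment with end >= pos  (positions are > 0)
  size_t lo = 0, hi = h.size() - 1;
  while (lo < hi) {
    size_t mid = (lo + hi) / 2;
    if (h[mid].end < pos) lo = mid + 1; else hi = mid;
  }
  return h[lo].src;
}

// ---- per-chromosome genome views ---------------------------------------

struct GenomeView {
  std::vector<double> len;                 // chromosome lengths, cM
  std::vector<std::vector<int> > midx;     // marker indices per chromosome
  std::vector<std::vector<double> > mpos;  // marker cM per chromosome
};

static GenomeView make_view(const IntegerVector &chrom, const NumericVector &cm,
                            const NumericVector &chrom_len) {
  GenomeView g;
  int nc = chrom_len.size();
  g.len.assign(chrom_len.begin(), chrom_len.end());
  g.midx.resize(nc); g.mpos.resize(nc);
  for (int j = 0; j < chrom.size(); ++j) {
    g.midx[chrom[j]].push_back(j);
    g.mpos[chrom[j]].push_back(cm[j]);
  }
  return g;
}

// a diploid individual as segment haplotypes over all chromosomes
struct SegInd { std::vector<Hap> h1, h2; };

static SegInd f6_ril(const std::vector<Hap> &p1, const std::vector<Hap> &p2,
                     const GenomeView &g) {
  // p1/p2 are the two gamete haplotypes of the F1; self to F2 then 4 SSD
  size_t nc = g.len.size();
  SegInd ind;
  ind.h1.resize(nc); ind.h2.resize(nc);
  for (size_t c = 0; c < nc; ++c) {
    Hap a = gamete_seg(p1[c], p2[c], g.len[c]);
    Hap b = gamete_seg(p1[c], p2[c], g.len[c]);
    for (int s = 0; s < 4; ++s) { // F2 -> F6
      Hap na = gamete_seg(a, b, g.len[c]);
      Hap nb = gamete_seg(a, b, g.len[c]);
      a = na; b = nb;
    }
    ind.h1[c] = a; ind.h2[c] = b;
  }
  return ind;
}

// allele of a segment haplotype at marker j given the 4 root haplotypes
static inline int root_allele(const std::vector<const unsigned char*> &roots,
                              int src, int j) {
  return roots[src][j];
}

// instantiate full 0/1 haplotype vectors for one individual
static void instantiate(const SegInd &ind, const GenomeView &g,
                        const std::vector<const unsigned char*> &roots,
                        unsigned char *out1, unsigned char *out2) {
  for (size_t c = 0; c < g.len.size(); ++c) {
    const std::vector<int> &mi = g.midx[c];
    const std::vector<double> &mp = g.mpos[c];
    for (int hap = 0; hap < 2; ++hap) {
      const Hap &h = hap == 0 ? ind.h1[c] : ind.h2[c];
      unsigned char *out = hap == 0 ? out1 : out2;
      size_t si = 0;
      for (size_t k = 0; k < mi.size(); ++k) {
        while (si < h.size() && h[si].end < mp[k]) ++si;
        out[mi[k]] = (unsigned char) root_allele(roots, h[si].src, mi[k]);
      }
    }
  }
}

// ---- exposed dense helpers (used by meiosis() / derive_rils() in R) ----

// [[Rcpp::export(name = ".cpp_meiosis")]]
IntegerVector cpp_meiosis(IntegerVector hapA, IntegerVector hapB,
                          IntegerVector chrom, NumericVector cm,
                          NumericVector chrom_len) {
  GenomeView g = make_view(chrom, cm, chrom_len);
  int m = hapA.size();
  IntegerVector out(m);
  for (size_t c = 0; c < g.len.size(); ++c) {
    Hap h1 = whole(g.len[c], 0), h2 = whole(g.len[c], 1);
    Hap gam = gamete_seg(h1, h2, g.len[c]);
    const std::vector<int> &mi = g.midx[c];
    const std::vector<double> &mp = g.mpos[c];
    size_t si = 0;
    for (size_t k = 0; k < mi.size(); ++k) {
      while (si < gam.size() && gam[si].end < mp[k]) ++si;
      out[mi[k]] = gam[si].src == 0 ? hapA[mi[k]] : hapB[mi[k]];
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_derive_rils")]]
IntegerMatrix cpp_derive_rils(IntegerVector hap1, IntegerVector hap2,
                              int n_rils, IntegerVector chrom,
                              NumericVector cm, NumericVector chrom_len) {
  GenomeView g = make_view(chrom, cm, chrom_len);
  int m = hap1.size();
  std::vector<unsigned char> r0(m), r1(m);
  for (int j = 0; j < m; ++j) { r0[j] = hap1[j]; r1[j] = hap2[j]; }
  std::vector<const unsigned char*> roots(2);
  roots[0] = r0.data(); roots[1] = r1.data();
  size_t nc = g.len.size();
  std::vector<Hap> p1(nc), p2(nc);
  for (size_t c = 0; c < nc; ++c) {
    p1[c] = whole(g.len[c], 0);
    p2[c] = whole(g.len[c], 1);
  }
  IntegerMatrix out(n_rils, m);
  std::vector<unsigned char> o1(m), o2(m);
  for (int r = 0; r < n_rils; ++r) {
    SegInd ind = f6_ril(p1, p2, g);
    instantiate(ind, g, roots, o1.data(), o2.data());
    for (int j = 0; j < m; ++j) out(r, j) = o1[j] + o2[j];
  }
  return out;
}

// ---- full breeding program ---------------------------------------------

struct Line { std::vector<unsigned char> h1, h2; double pheno; };

// sample k of n without replacement using R's RNG
static std::vector<int> sample_wor(int n, int k) {
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  for (int i = 0; i < k; ++i) {
    int j = i + (int) (R::unif_rand() * (n - i));
    if (j >= n) j = n - 1;
    std::swap(idx[i], idx[j]);
  }
  idx.resize(k);
  return idx;
}

// [[Rcpp::export(name = ".cpp_run_program")]]
List cpp_run_program(IntegerMatrix founder_haps, // n_f x m, 0/1
                     IntegerVector chrom, NumericVector cm,
                     NumericVector chrom_len,
                     IntegerVector qtl_index,   // 0-based marker indices
                     NumericVector qtl_effect,  // scaled allele effects
                     double residual_sd,
                     bool selection,
                     int total_generations, int burnin,
                     int n_crosses, int rils_per_cross, int keep_per_cross,
                     int varieties_per_gen,
                     int pool_min_back, int pool_max_back) {
  GenomeView g = make_view(chrom, cm, chrom_len);
  int m = founder_haps.ncol();
  int n_f = founder_haps.nrow();
  int nq = qtl_index.size();
  size_t nc = g.len.size();

  // founders as lines (inbred: h1 == h2)
  std::vector<std::vector<Line> > gens; // gens[t] = kept lines of generation t+1
  std::vector<Line> founders(n_f);
  for (int i = 0; i < n_f; ++i) {
    founders[i].h1.resize(m);
    for (int j = 0; j < m; ++j) founders[i].h1[j] = (unsigned char) founder_haps(i, j);
    founders[i].h2 = founders[i].h1;
    founders[i].pheno = NA_REAL;
  }

  // QTL lookup per chromosome: (chrom, pos, marker index, effect)
  std::vector<std::vector<int> > qmk(nc);
  std::vector<std::vector<double> > qpos(nc), qeff(nc);
  for (int q = 0; q < nq; ++q) {
    int j = qtl_index[q];
    qmk[chrom[j]].push_back(j);
    qpos[chrom[j]].push_back(cm[j]);
    qeff[chrom[j]].push_back(qtl_effect[q]);
  }

  int kept_total = n_crosses * keep_per_cross;
  int n_panel_gens = total_generations - burnin;
  IntegerMatrix panel(n_panel_gens * varieties_per_gen, m);
  NumericVector panel_pheno(n_panel_gens * varieties_per_gen);
  NumericVector panel_gv(n_panel_gens * varieties_per_gen);
  IntegerVector panel_year(n_panel_gens * varieties_per_gen);
  int panel_row = 0;

  std::vector<double> cand_ph(rils_per_cross), cand_gv(rils_per_cross);
  std::vector<SegInd> cand(rils_per_cross);

  for (int t = 1; t <= total_generations; ++t) {
    // parent pool
    std::vector<Line*> pool;
    if (t <= pool_max_back) {
      for (int i = 0; i < n_f; ++i) pool.push_back(&founders[i]);
    } else {
      for (int back = pool_min_back; back <= pool_max_back; ++back) {
        int tg = t - back; // generation index (1-based)
        if (tg >= 1) {
          std::vector<Line> &L = gens[tg - 1];
          for (size_t i = 0; i < L.size(); ++i) pool.push_back(&L[i]);
        }
      }
    }
    int need = 2 * n_crosses;
    std::vector<int> pick = sample_wor((int) pool.size(), need);

    std::vector<Line> newgen;
    newgen.reserve(kept_total);
    for (int cx = 0; cx < n_crosses; ++cx) {
      Line *pa = pool[pick[2 * cx]];
      Line *pb = pool[pick[2 * cx + 1]];
      std::vector<const unsigned char*> roots(4);
      roots[0] = pa->h1.data(); roots[1] = pa->h2.data();
      roots[2] = pb->h1.data(); roots[3] = pb->h2.data();
      // F1 gametes: one from each parent (parents may be residually het)
      for (int r = 0; r < rils_per_cross; ++r) {
        std::vector<Hap> f1a(nc), f1b(nc);
        for (size_t c = 0; c < nc; ++c) {
          Hap pa1 = whole(g.len[c], 0), pa2 = whole(g.len[c], 1);
          Hap pb1 = whole(g.len[c], 2), pb2 = whole(g.len[c], 3);
          f1a[c] = gamete_seg(pa1, pa2, g.len[c]);
          f1b[c] = gamete_seg(pb1, pb2, g.len[c]);
        }
        cand[r] = f6_ril(f1a, f1b, g);
        // genetic value from QTL genotypes only
        double gv = 0.0;
        for (size_t c = 0; c < nc; ++c) {
          for (size_t q = 0; q < qmk[c].size(); ++q) {
            int j = qmk[c][q];
            int a1 = root_allele(roots, src_at(cand[r].h1[c], qpos[c][q]), j);
            int a2 = root_allele(roots, src_at(cand[r].h2[c], qpos[c][q]), j);
            gv += 0.5 * (a1 + a2) * qeff[c][q];
          }
        }
        cand_gv[r] = gv;
        cand_ph[r] = gv + R::norm_rand() * residual_sd;
      }
      // choose kept RILs
      std::vector<int> kept;
      if (selection) {
        std::vector<int> ordidx(rils_per_cross);
        for (int r = 0; r < rils_per_cross; ++r) ordidx[r] = r;
        std::partial_sort(ordidx.begin(), ordidx.begin() + keep_per_cross,
                          ordidx.end(), [&](int a, int b) {
                            return cand_ph[a] > cand_ph[b];
                          });
        kept.assign(ordidx.begin(), ordidx.begin() + keep_per_cross);
      } else {
        kept = sample_wor(rils_per_cross, keep_per_cross);
      }
      for (size_t ki = 0; ki < kept.size(); ++ki) {
        Line ln;
        ln.h1.resize(m); ln.h2.resize(m);
        instantiate(cand[kept[ki]], g, roots, ln.h1.data(), ln.h2.data());
        ln.pheno = cand_ph[kept[ki]];
        newgen.push_back(ln);
      }
    }
    gens.push_back(newgen);
    // free generations no longer needed as parents
    int oldest_needed = t + 1 - pool_max_back; // 1-based generation index
    for (int tg = 1; tg < oldest_needed; ++tg)
      if (!gens[tg - 1].empty() && tg <= t - pool_max_back)
        std::vector<Line>().swap(gens[tg - 1]);

    if (t > burnin) {
      std::vector<int> take = sample_wor((int) newgen.size(), varieties_per_gen);
      for (int vi = 0; vi < varieties_per_gen; ++vi) {
        Line &ln = newgen[take[vi]];
        for (int j = 0; j < m; ++j) panel(panel_row, j) = ln.h1[j] + ln.h2[j];
        double gv = 0.0;
        for (size_t c = 0; c < nc; ++c)
          for (size_t q = 0; q < qmk[c].size(); ++q) {
            int j = qmk[c][q];
            gv += 0.5 * (ln.h1[j] + ln.h2[j]) * qeff[c][q];
          }
        panel_gv[panel_row] = gv;
        panel_pheno[panel_row] = ln.pheno;
        panel_year[panel_row] = t - burnin;
        ++panel_row;
      }
    }
  }
  return List::create(_["genotypes"] = panel,
                      _["year"] = panel_year,
                      _["phenotype"] = panel_pheno,
                      _["genetic_value"] = panel_gv);
}
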