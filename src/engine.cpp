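#include <Rcpp.h>
#include <vector>
#include <cstdlib>
using namespace Rcpp;

// Genotypes are integer-encoded bitstrings: locus 0 is the leftmost character
// of the bitstring and occupies bit (L-1), i.e. the integer encoding is
// big-endian on the bitstring ("1100" -> 12). Empty lattice cells hold -1.
//
// All randomness comes from R's RNG (unif_rand), so a run is reproducible
// from set.seed() alone. Draw order within one update is fixed:
//   1. focal cell (1 draw)
//   2. occupied focal: survival check (1 draw)
//      empty focal:   first-parent pick (1 draw if any candidate),
//                     rare-global coin (1 draw, only when rareGlobalProb > 0),
//                     mate pick (1 draw local; >=1 draws global, rejection on
//                     the first parent's cell), centers redraw (as global),
//                     donor coin (1 draw), L-1 crossover draws (only r > 0),
//                     L mutation draws (only mu > 0).

static inline int bit_at(int g, int L, int locus) {
  return (g >> (L - 1 - locus)) & 1;
}

static std::vector<std::pair<int, int> > vn_offsets(int radius) {
  std::vector<std::pair<int, int> > off;
  for (int dr = -radius; dr <= radius; ++dr)
    for (int dc = -radius; dc <= radius; ++dc) {
      if (dr == 0 && dc == 0) continue;
      if (std::abs(dr) + std::abs(dc) <= radius)
        off.push_back(std::make_pair(dr, dc));
    }
  return off;
}

static inline int runif_int(int k) {  // uniform on 0..k-1
  int v = (int)(unif_rand() * k);
  return v >= k ? k - 1 : v;
}

// positions are 0-based, column-major: pos = col * n + row
static void neighbor_positions(int n, int pos, const std::vector<std::pair<int, int> >& off,
                               bool toroidal, std::vector<int>& out) {
  out.clear();
  int row = pos % n, col = pos / n;
  for (size_t i = 0; i < off.size(); ++i) {
    int rr = row + off[i].first, cc = col + off[i].second;
    if (toroidal) {
      rr = ((rr % n) + n) % n;
      cc = ((cc % n) + n) % n;
    } else if (rr < 0 || rr >= n || cc < 0 || cc >= n) {
      continue;
    }
    out.push_back(cc * n + rr);
  }
}

// uniform among occupied neighbors; -1 if none. `exclude` (-1 = none) is
// skipped (a cell cannot be its own mate).
static int pick_local(const std::vector<int>& lat, int n, int pos,
                      const std::vector<std::pair<int, int> >& off, bool toroidal,
                      int exclude, std::vector<int>& nbuf, std::vector<int>& cbuf) {
  neighbor_positions(n, pos, off, toroidal, nbuf);
  cbuf.clear();
  for (size_t i = 0; i < nbuf.size(); ++i)
    if (lat[nbuf[i]] >= 0 && nbuf[i] != exclude) cbuf.push_back(nbuf[i]);
  if (cbuf.empty()) return -1;
  return cbuf[runif_int((int)cbuf.size())];
}

// uniform among all occupied cells, excluding `exclude` (-1 = none)
static int pick_global(const std::vector<int>& occ, int exclude) {
  if (occ.empty()) return -1;
  if (exclude < 0) return occ[runif_int((int)occ.size())];
  if ((int)occ.size() == 1) return -1;
  int p;
  do {
    p = occ[runif_int((int)occ.size())];
  } while (p == exclude);
  return p;
}

static int recombine_one(int g1, int g2, int L, double r) {
  int donor = (unif_rand() < 0.5) ? 0 : 1;
  int rec = 0;
  for (int i = 0; i < L; ++i) {
    int src = donor ? g2 : g1;
    rec |= bit_at(src, L, i) << (L - 1 - i);
    if (i < L - 1 && r > 0 && unif_rand() < r) donor = 1 - donor;
  }
  return rec;
}

static int mutate_one(int g, int L, double mu) {
  if (mu <= 0) return g;
  for (int i = 0; i < L; ++i)
    if (unif_rand() < mu) g ^= 1 << (L - 1 - i);
  return g;
}

// [[Rcpp::export]]
IntegerVector cpp_neighborhood(int n, int pos, int mode, int radius, bool toroidal) {
  std::vector<int> out;
  if (mode == 1) {  // global: the entire lattice minus the focal point
    out.reserve(n * n - 1);
    for (int p = 0; p < n * n; ++p)
      if (p != pos) out.push_back(p);
  } else {
    std::vector<std::pair<int, int> > off = vn_offsets(radius);
    neighbor_positions(n, pos, off, toroidal, out);
  }
  return wrap(out);
}

// [[Rcpp::export]]
IntegerVector cpp_select_parent(IntegerVector lat, int n, int pos, int mode,
                                int radius, bool toroidal, int exclude, int ndraw) {
  std::vector<int> latv = as<std::vector<int> >(lat);
  std::vector<int> occ, nbuf, cbuf;
  for (int p = 0; p < (int)latv.size(); ++p)
    if (latv[p] >= 0 && p != pos) occ.push_back(p);
  std::vector<std::pair<int, int> > off = vn_offsets(radius);
  IntegerVector res(ndraw);
  for (int d = 0; d < ndraw; ++d)
    res[d] = (mode == 1) ? pick_global(occ, exclude)
                         : pick_local(latv, n, pos, off, toroidal, exclude, nbuf, cbuf);
  return res;
}

// [[Rcpp::export]]
IntegerVector cpp_select_mate(IntegerVector lat, int n, int L, int p1, int mode,
                              int radius, bool toroidal, double rare_global_prob,
                              int centers_genotype, double centers_threshold,
                              int ndraw) {
  std::vector<int> latv = as<std::vector<int> >(lat);
  int G = 1 << L;
  std::vector<int> occ, counts(G, 0), nbuf, cbuf;
  for (int p = 0; p < (int)latv.size(); ++p)
    if (latv[p] >= 0) {
      occ.push_back(p);
      counts[latv[p]]++;
    }
  std::vector<std::pair<int, int> > off = vn_offsets(radius);
  int g1 = latv[p1];
  IntegerVector res(ndraw);
  for (int d = 0; d < ndraw; ++d) {
    int m_mode = mode;
    if (rare_global_prob > 0 && unif_rand() < rare_global_prob) m_mode = 1;
    int p2 = (m_mode == 1) ? pick_global(occ, p1)
                           : pick_local(latv, n, p1, off, toroidal, p1, nbuf, cbuf);
    if (p2 >= 0 && centers_genotype >= 0 && g1 == centers_genotype &&
        latv[p2] == centers_genotype &&
        (double)counts[centers_genotype] < centers_threshold * (double)occ.size()) {
      p2 = pick_global(occ, p1);
    }
    res[d] = p2;
  }
  return res;
}

// [[Rcpp::export]]
IntegerVector cpp_recombine(int g1, int g2, int L, double r, int ndraw) {
  IntegerVector res(ndraw);
  for (int d = 0; d < ndraw; ++d) res[d] = recombine_one(g1, g2, L, r);
  return res;
}

// [[Rcpp::export]]
IntegerVector cpp_mutate(int g, int L, double mu, int ndraw) {
  IntegerVector res(ndraw);
  for (int d = 0; d < ndraw; ++d) res[d] = mutate_one(g, L, mu);
  return res;
}

// Full run. record_mode: 0 none, 1 novel births (offspring differs from a
// parent), 2 all births and deaths. stop_genotype/tracked_genotype/-
// centers_genotype: -1 disables. n_updates_override >= 0 runs exactly that
// many updates (used by the single-step wrapper); otherwise max_epochs * n^2.
// [[Rcpp::export]]
List cpp_run(IntegerVector init_lat, int n, int L, NumericVector surv,
             double mu, double r, int disp_mode, int disp_radius, int mate_mode,
             int mate_radius, bool toroidal, double rare_global_prob,
             int centers_genotype, double centers_threshold, int stop_genotype,
             double stop_frequency, int max_epochs, double n_updates_override,
             int record_mode, int snapshot_every, int tracked_genotype) {
  const int n2 = n * n, G = 1 << L;
  std::vector<int> lat = as<std::vector<int> >(init_lat);
  std::vector<int> pos_of(n2, -1), counts(G, 0), occ;
  occ.reserve(n2);
  for (int p = 0; p < n2; ++p)
    if (lat[p] >= 0) {
      pos_of[p] = (int)occ.size();
      occ.push_back(p);
      counts[lat[p]]++;
    }

  std::vector<std::pair<int, int> > disp_off = vn_offsets(disp_radius);
  std::vector<std::pair<int, int> > mate_off = vn_offsets(mate_radius);
  std::vector<int> nbuf, cbuf;

  std::vector<int> counts_log;                    // per-epoch genotype counts
  std::vector<double> trans_upd;                  // 0-count transitions
  std::vector<int> trans_g, trans_type;           // type: 0 appear, 1 extinct
  std::vector<double> b_upd;                      // birth records
  std::vector<int> b_focal, b_p1, b_p2, b_g1, b_g2, b_rec, b_off;
  std::vector<double> d_upd;                      // death records
  std::vector<int> d_pos, d_g;
  List snapshots;
  std::vector<int> snapshot_epochs;
  double rec_creations = 0, mut_creations = 0;

  for (int g = 0; g < G; ++g)
    if (counts[g] > 0) {
      trans_upd.push_back(-1);  // present at initialization
      trans_g.push_back(g);
      trans_type.push_back(0);
    }
  for (int g = 0; g < G; ++g) counts_log.push_back(counts[g]);

  long long total_updates = (n_updates_override >= 0)
                                ? (long long)n_updates_override
                                : (long long)max_epochs * (long long)n2;
  long long upd = 0;
  int epochs_done = 0, stop_reason = 0;

  while (upd < total_updates) {
    int focal = runif_int(n2);
    int g = lat[focal];
    if (g >= 0) {
      if (unif_rand() >= surv[g]) {  // dies with probability 1 - s_G
        int idx = pos_of[focal];
        int last = occ.back();
        occ[idx] = last;
        pos_of[last] = idx;
        occ.pop_back();
        pos_of[focal] = -1;
        lat[focal] = -1;
        counts[g]--;
        if (record_mode == 2) {
          d_upd.push_back((double)upd);
          d_pos.push_back(focal);
          d_g.push_back(g);
        }
        if (counts[g] == 0) {
          trans_upd.push_back((double)upd);
          trans_g.push_back(g);
          trans_type.push_back(1);
        }
      }
    } else {
      // birth attempt
      int p1 = (disp_mode == 1)
                   ? pick_global(occ, -1)
                   : pick_local(lat, n, focal, disp_off, toroidal, -1, nbuf, cbuf);
      if (p1 >= 0) {
        int m_mode = mate_mode;
        if (rare_global_prob > 0 && unif_rand() < rare_global_prob) m_mode = 1;
        int p2 = (m_mode == 1)
                     ? pick_global(occ, p1)
                     : pick_local(lat, n, p1, mate_off, toroidal, p1, nbuf, cbuf);
        if (p2 >= 0) {
          int g1 = lat[p1], g2 = lat[p2];
          if (centers_genotype >= 0 && g1 == centers_genotype &&
              g2 == centers_genotype &&
              (double)counts[centers_genotype] <
                  centers_threshold * (double)occ.size()) {
            int p2b = pick_global(occ, p1);
            if (p2b >= 0) {
              p2 = p2b;
              g2 = lat[p2];
            } else {
              p2 = -1;  // first parent is the sole organism: no mate
            }
          }
          if (p2 >= 0) {
            int rec = recombine_one(g1, g2, L, r);
            int off = mutate_one(rec, L, mu);
            lat[focal] = off;
            pos_of[focal] = (int)occ.size();
            occ.push_back(focal);
            counts[off]++;
            if (counts[off] == 1) {
              trans_upd.push_back((double)upd);
              trans_g.push_back(off);
              trans_type.push_back(0);
            }
            if (tracked_genotype >= 0 && off == tracked_genotype &&
                g1 != tracked_genotype && g2 != tracked_genotype) {
              if (rec == tracked_genotype) rec_creations += 1;
              else mut_creations += 1;
            }
            if (record_mode == 2 ||
                (record_mode == 1 && (off != g1 || off != g2))) {
              b_upd.push_back((double)upd);
              b_focal.push_back(focal);
              b_p1.push_back(p1);
              b_p2.push_back(p2);
              b_g1.push_back(g1);
              b_g2.push_back(g2);
              b_rec.push_back(rec);
              b_off.push_back(off);
            }
          }
        }
      }
    }
    ++upd;
    if (upd % n2 == 0) {
      ++epochs_done;
      for (int gg = 0; gg < G; ++gg) counts_log.push_back(counts[gg]);
      if (snapshot_every > 0 && epochs_done % snapshot_every == 0) {
        snapshots.push_back(wrap(lat));
        snapshot_epochs.push_back(epochs_done);
      }
      if (occ.empty()) {
        stop_reason = 2;
        break;
      }
      if (stop_genotype >= 0 && counts[stop_genotype] > 0 &&
          (double)counts[stop_genotype] >=
              stop_frequency * (double)occ.size()) {
        stop_reason = 1;
        break;
      }
    }
  }

  int nrows = (int)counts_log.size() / G;
  IntegerMatrix cmat(nrows, G);
  for (int i = 0; i < nrows; ++i)
    for (int gg = 0; gg < G; ++gg) cmat(i, gg) = counts_log[(size_t)i * G + gg];

  return List::create(
      _["lattice"] = wrap(lat), _["epochs"] = epochs_done,
      _["updates"] = (double)upd, _["stop_reason"] = stop_reason,
      _["counts"] = cmat, _["trans_update"] = wrap(trans_upd),
      _["trans_genotype"] = wrap(trans_g), _["trans_type"] = wrap(trans_type),
      _["birth_update"] = wrap(b_upd), _["birth_focal"] = wrap(b_focal),
      _["birth_p1"] = wrap(b_p1), _["birth_p2"] = wrap(b_p2),
      _["birth_g1"] = wrap(b_g1), _["birth_g2"] = wrap(b_g2),
      _["birth_rec"] = wrap(b_rec), _["birth_off"] = wrap(b_off),
      _["death_update"] = wrap(d_upd), _["death_pos"] = wrap(d_pos),
      _["death_genotype"] = wrap(d_g), _["rec_creations"] = rec_creations,
      _["mut_creations"] = mut_creations, _["snapshots"] = snapshots,
      _["snapshot_epochs"] = wrap(snapshot_epochs));
}
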