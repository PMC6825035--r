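// Dynamic Metropolis Monte Carlo engine for enzyme-mediated fibril
// degradation.  The lattice layout (columns, stagger, gaps) is built on the
// R side; this file owns the hot loops: surface re-scans, the removal
// cascade for disconnected fragments, and the per-step enzyme dynamics.
//
// Conventions: all site/column/chain ids are 1-based (matching R); state
// arrays are indexed with id-1.  bond_up[s-1] == true means the bond between
// site s and the site directly above it (same chain, i+1) is cleaved.
// The R random number generator supplies all randomness, so set.seed()
// makes every run reproducible.

#include <Rcpp.h>
#include <vector>
#include <deque>
#include <cmath>

using namespace Rcpp;

namespace {

struct Lat {
  int ncol, nz, nsites, nchains, spc, gap;
  IntegerVector sc_, sz_, si_, sch_, sat_, dn_;  // keep SEXPs protected
  const int *site_col, *site_z, *site_i, *site_chain, *site_at, *dir_nbr;
  std::vector<char> removed, bond_up, gelatin, surface;
};

struct Epar {
  double e_well, e_c_gela, e_g_colla, e_g_gela;
  int well_i;
  int cleave_mode;  // 0 = cleave from the well site (sever bond below),
                    // 1 = cleave from the site below (sever bond above)
  int cleave_i;     // competent axial index for collagenase
};

inline int satf(const Lat &L, int col, int z) {
  if (z < 1 || z > L.nz) return 0;
  return L.site_at[(col - 1) * L.nz + (z - 1)];
}

// A lateral face toward column col2 at axial position z is blocked when an
// intact site sits there, or when z is a gap interior whose two flanking
// sites in col2 are intact.
bool face_blocked(const Lat &L, int col2, int z) {
  int s = satf(L, col2, z);
  if (s) return !L.removed[s - 1];
  int below = 0, above = 0;
  for (int k = 1; k <= L.gap && !below; k++) below = satf(L, col2, z - k);
  for (int k = 1; k <= L.gap && !above; k++) above = satf(L, col2, z + k);
  if (below && above)
    return !L.removed[below - 1] && !L.removed[above - 1];
  return false;
}

bool site_surface(const Lat &L, int s) {
  if (L.removed[s - 1]) return false;
  int col = L.site_col[s - 1], z = L.site_z[s - 1];
  int blocked = 0;
  for (int d = 0; d < 6; d++) {
    int c2 = L.dir_nbr[(col - 1) * 6 + d];
    if (c2 && face_blocked(L, c2, z)) blocked++;
  }
  return blocked < 6;
}

void recompute_surface(Lat &L) {
  for (int s = 1; s <= L.nsites; s++)
    L.surface[s - 1] = site_surface(L, s) ? 1 : 0;
}

// site flanks a cleaved bond (above or below)
inline bool flanked(const Lat &L, int s) {
  int i = L.site_i[s - 1];
  if (i < L.spc && L.bond_up[s - 1]) return true;
  if (i > 1 && L.bond_up[s - 2]) return true;
  return false;
}

inline double site_energy(const Lat &L, const Epar &E, int kind, int s) {
  int ch = L.site_chain[s - 1];
  if (L.gelatin[ch - 1]) return kind == 0 ? E.e_c_gela : E.e_g_gela;
  if (kind == 0) return (L.site_i[s - 1] == E.well_i) ? E.e_well : 0.0;
  return E.e_g_colla;
}

Lat load_lattice(const List &lat) {
  Lat L;
  L.ncol = as<int>(lat["n_columns"]);
  L.nz = as<int>(lat["n_z"]);
  L.nsites = as<int>(lat["n_sites"]);
  L.nchains = as<int>(lat["n_chains"]);
  List g = lat["geometry"];
  L.spc = as<int>(g["sites_per_chain"]);
  L.gap = as<int>(g["gap_length"]);
  L.sc_ = lat["site_col"]; L.sz_ = lat["site_z"]; L.si_ = lat["site_i"];
  L.sch_ = lat["site_chain"]; L.sat_ = lat["site_at"];
  L.dn_ = lat["dir_nbr"];
  L.site_col = INTEGER(L.sc_); L.site_z = INTEGER(L.sz_);
  L.site_i = INTEGER(L.si_); L.site_chain = INTEGER(L.sch_);
  L.site_at = INTEGER(L.sat_); L.dir_nbr = INTEGER(L.dn_);
  LogicalVector rm = lat["removed"], bu = lat["bond_up"],
                ge = lat["gelatin"];
  L.removed.assign(rm.begin(), rm.end());
  L.bond_up.assign(bu.begin(), bu.end());
  L.gelatin.assign(ge.begin(), ge.end());
  L.surface.assign(L.nsites, 0);
  if (lat.containsElementNamed("is_surface")) {
    LogicalVector su = lat["is_surface"];
    if (su.size() == L.nsites) L.surface.assign(su.begin(), su.end());
  }
  return L;
}

// Removal cascade over maximal runs of bond-connected intact sites.
//
// Rule (a): a single-site run whose two flanking positions are cleaved
// bonds or chain ends is disconnected and removed immediately (this is the
// double-cut produced by gelatinase activity).
//
// Rule (b): a larger run is removed only when it is vertically isolated by
// *occupancy* - the column positions directly below its bottom site and
// above its top site are vacant or removed - and it touches fewer than two
// intact beads laterally.  A cleaved bond alone does not detach a fragment:
// the unbonded neighbour above/below still holds it in place, so removal
// is driven by gelatinase double-cuts and spreads from the resulting
// vacancies.  Removals re-enqueue the laterally and vertically adjacent
// chains until a fixed point.
void cascade(Lat &L, std::deque<int> &q, std::vector<int> &removed_now) {
  std::vector<char> inq(L.nchains + 1, 0);
  for (int c : q) inq[c] = 1;
  auto enqueue = [&](int ch) {
    if (ch >= 1 && !inq[ch]) { q.push_back(ch); inq[ch] = 1; }
  };
  while (!q.empty()) {
    int c = q.front(); q.pop_front(); inq[c] = 0;
    int first = (c - 1) * L.spc + 1;
    bool chain_changed = false;
    int i = 1;
    while (i <= L.spc) {
      int s = first + i - 1;
      if (L.removed[s - 1]) { i++; continue; }
      int j = i;
      while (j < L.spc) {
        int sj = first + j - 1;
        if (L.bond_up[sj - 1]) break;   // bond (j -> j+1) cleaved
        if (L.removed[sj]) break;       // site j+1 removed
        j++;
      }
      int s_i = first + i - 1, s_j = first + j - 1;
      bool rm = false;
      bool below_free = (i == 1) || L.bond_up[s_i - 2];
      bool above_free = (j == L.spc) || L.bond_up[s_j - 1];
      if (j == i && below_free && above_free) {
        rm = true;  // rule (a)
      } else {
        int col = L.site_col[s_i - 1];
        int zb = L.site_z[s_i - 1] - 1, zt = L.site_z[s_j - 1] + 1;
        int tb = satf(L, col, zb), tt = satf(L, col, zt);
        bool iso_below = (tb == 0) || L.removed[tb - 1];
        bool iso_above = (tt == 0) || L.removed[tt - 1];
        if (iso_below && iso_above) {
          int attach = 0;
          for (int k = i; k <= j && attach < 2; k++) {
            int sk = first + k - 1;
            int z = L.site_z[sk - 1];
            for (int d = 0; d < 6 && attach < 2; d++) {
              int c2 = L.dir_nbr[(col - 1) * 6 + d];
              if (!c2) continue;
              int t = satf(L, c2, z);
              if (t && !L.removed[t - 1]) attach++;
            }
          }
          rm = attach < 2;  // rule (b)
        }
      }
      if (rm) {
        chain_changed = true;
        for (int k = i; k <= j; k++) {
          int sk = first + k - 1;
          L.removed[sk - 1] = 1;
          removed_now.push_back(sk);
        }
        int col = L.site_col[s_i - 1];
        // vertical neighbours in the column may now be isolated
        int tb = satf(L, col, L.site_z[s_i - 1] - 1);
        int tt = satf(L, col, L.site_z[s_j - 1] + 1);
        if (tb && !L.removed[tb - 1]) enqueue(L.site_chain[tb - 1]);
        if (tt && !L.removed[tt - 1]) enqueue(L.site_chain[tt - 1]);
        for (int k = i; k <= j; k++) {
          int sk = first + k - 1;
          int z = L.site_z[sk - 1];
          for (int d = 0; d < 6; d++) {
            int c2 = L.dir_nbr[(col - 1) * 6 + d];
            if (!c2) continue;
            int t = satf(L, c2, z);
            if (t && !L.removed[t - 1]) enqueue(L.site_chain[t - 1]);
          }
        }
      }
      i = j + 1;
    }
    if (chain_changed) enqueue(c);  // earlier runs may be isolated now
  }
}

}  // namespace

// [[Rcpp::export]]
LogicalVector cpp_recompute_surface(List lat) {
  Lat L = load_lattice(lat);
  recompute_surface(L);
  return LogicalVector(L.surface.begin(), L.surface.end());
}

// [[Rcpp::export]]
List cpp_remove_disconnected(List lat, IntegerVector chains) {
  Lat L = load_lattice(lat);
  std::deque<int> q;
  if (chains.size() == 0) {
    for (int c = 1; c <= L.nchains; c++) q.push_back(c);
  } else {
    for (int c : chains) q.push_back(c);
  }
  std::vector<int> removed_now;
  cascade(L, q, removed_now);
  recompute_surface(L);
  return List::create(
      _["removed"] = LogicalVector(L.removed.begin(), L.removed.end()),
      _["removed_now"] = IntegerVector(removed_now.begin(), removed_now.end()),
      _["is_surface"] = LogicalVector(L.surface.begin(), L.surface.end()));
}

// Simulated waiting times for an enzyme held in its cleavage-competent
// position: per selected step, a cleave is attempted with probability
// p_cleave and succeeds with probability p_succ; dt_attempt seconds elapse
// per step (single enzyme).
// [[Rcpp::export]]
NumericVector cpp_waiting_times(int n_events, double p_cleave, double p_succ,
                                double dt_attempt) {
  NumericVector out(n_events);
  for (int e = 0; e < n_events; e++) {
    double t = 0.0;
    for (;;) {
      t += dt_attempt;
      if (unif_rand() < p_cleave && unif_rand() < p_succ) break;
    }
    out[e] = t;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_mc_run(List lat, IntegerVector enz_site, IntegerVector enz_kind,
                List energy, List kin, List ctrl) {
  Lat L = load_lattice(lat);
  bool have_surface = false;
  for (int s = 0; s < L.nsites; s++) if (L.surface[s]) { have_surface = true; break; }
  if (!have_surface) recompute_surface(L);

  Epar E;
  E.e_well = as<double>(energy["e_well"]);
  E.well_i = as<int>(energy["well_index"]);
  E.e_c_gela = as<double>(energy["e_collagenase_gelatin"]);
  E.e_g_colla = as<double>(energy["e_gelatinase_collagen"]);
  E.e_g_gela = as<double>(energy["e_gelatinase_gelatin"]);
  E.cleave_mode = as<std::string>(energy["cleave_mode"]) == "well" ? 0 : 1;
  E.cleave_i = as<int>(energy["cleave_index"]);

  double p_vert = as<double>(kin["p_vertical"]);
  double p_horiz = as<double>(kin["p_horizontal"]);
  double p_cleave = as<double>(kin["p_cleave_attempt"]);
  double p_succ = as<double>(kin["p_cleave_success"]);
  double dt_attempt = as<double>(kin["dt_attempt"]);
  bool cleave_enabled = as<bool>(kin["cleave_enabled"]);

  long long max_steps = (long long)as<double>(ctrl["max_steps"]);
  int target_removed = as<int>(ctrl["target_removed"]);
  double max_time = as<double>(ctrl["max_time"]);
  bool record_moves = as<bool>(ctrl["record_moves"]);
  long long snap_every = (long long)as<double>(ctrl["snapshot_every"]);
  double t0 = as<double>(ctrl["time0"]);
  long long step0 = (long long)as<double>(ctrl["step0"]);

  int n_enz = enz_site.size();
  if (n_enz == 0) stop("no enzymes in the system");
  std::vector<int> esite(enz_site.begin(), enz_site.end());
  std::vector<int> ekind(enz_kind.begin(), enz_kind.end());
  std::vector<int> occ(L.nsites + 1, 0);
  for (int e = 0; e < n_enz; e++) occ[esite[e]] = e + 1;

  double dt_step = dt_attempt / n_enz;
  double time = t0;
  long long step = 0;
  int removed_cnt = 0;
  for (int s = 0; s < L.nsites; s++) removed_cnt += L.removed[s];
  long long n_cleaves_prior = 0;
  for (int s = 0; s < L.nsites; s++) n_cleaves_prior += L.bond_up[s];

  // event log: 1 move, 2 cleave, 3 removal, 4 relocation
  std::vector<double> ev_step, ev_time;
  std::vector<int> ev_type, ev_enz, ev_site;

  // time-in-state occupancy tally (per enzyme, per axial index i)
  NumericMatrix occ_cnt(L.spc, n_enz);
  std::vector<int> last_i(n_enz);
  std::vector<long long> last_step(n_enz, 0);
  for (int e = 0; e < n_enz; e++) last_i[e] = L.site_i[esite[e] - 1];
  // snapshots
  std::vector<double> sn_time;
  std::vector<int> sn_removed, sn_z;

  long long acc_moves = 0, blk_moves = 0, rej_moves = 0;
  long long cl_attempts = 0, cl_success = 0;

  auto tally = [&](int e) {
    occ_cnt(last_i[e] - 1, e) += (double)(step - last_step[e]);
    last_step[e] = step;
  };
  auto snapshot = [&]() {
    sn_time.push_back(time);
    sn_removed.push_back(removed_cnt);
    for (int e = 0; e < n_enz; e++) sn_z.push_back(L.site_z[esite[e] - 1]);
  };
  if (snap_every > 0) snapshot();

  while (step < max_steps) {
    if (target_removed >= 0 && removed_cnt >= target_removed) break;
    if (max_time >= 0 && time >= max_time) break;
    step++;
    time += dt_step;
    int e = (int)(unif_rand() * n_enz);
    if (e >= n_enz) e = n_enz - 1;
    int s = esite[e];
    int kind = ekind[e];
    double u = unif_rand();
    if (u < p_vert + p_horiz) {
      // displacement attempt
      int target = 0;
      if (u < p_vert) {
        int dir = unif_rand() < 0.5 ? 1 : -1;
        int col = L.site_col[s - 1], z = L.site_z[s - 1];
        for (int k = 1; k <= L.gap + 1; k++) {
          int t = satf(L, col, z + dir * k);
          if (t) { target = t; break; }
        }
      } else {
        int d = (int)(unif_rand() * 6.0);
        if (d >= 6) d = 5;
        int col = L.site_col[s - 1], z = L.site_z[s - 1];
        int c2 = L.dir_nbr[(col - 1) * 6 + d];
        if (c2) target = satf(L, c2, z);
      }
      bool blocked = (target == 0) || L.removed[target - 1] ||
                     occ[target] != 0 || !L.surface[target - 1] ||
                     (kind == 0 && flanked(L, target));
      if (blocked) {
        blk_moves++;
      } else {
        double dE = site_energy(L, E, kind, target) -
                    site_energy(L, E, kind, s);
        if (dE <= 0.0 || unif_rand() < std::exp(-dE)) {
          occ[s] = 0; occ[target] = e + 1;
          tally(e);
          esite[e] = target;
          last_i[e] = L.site_i[target - 1];
          acc_moves++;
          if (record_moves) {
            ev_step.push_back((double)(step0 + step));
            ev_time.push_back(time);
            ev_type.push_back(1); ev_enz.push_back(e + 1);
            ev_site.push_back(target);
          }
        } else {
          rej_moves++;
        }
      }
    } else if (cleave_enabled) {
      cl_attempts++;
      int i = L.site_i[s - 1];
      int chain = L.site_chain[s - 1];
      bool competent = false;
      int bond_site = 0;  // site whose bond_up gets severed
      if (kind == 0) {
        if (!L.gelatin[chain - 1]) {
          if (E.cleave_mode == 0 && i == E.cleave_i && i > 1 &&
              !L.removed[s - 2] && !L.bond_up[s - 2]) {
            competent = true; bond_site = s - 1;
          } else if (E.cleave_mode == 1 && i == E.cleave_i && i < L.spc &&
                     !L.removed[s] && !L.bond_up[s - 1]) {
            competent = true; bond_site = s;
          }
        }
      } else {
        if (L.gelatin[chain - 1] && i < L.spc && !L.bond_up[s - 1] &&
            !L.removed[s]) {
          competent = true; bond_site = s;
        }
      }
      if (competent && unif_rand() < p_succ) {
        cl_success++;
        L.bond_up[bond_site - 1] = 1;
        L.gelatin[chain - 1] = 1;
        ev_step.push_back((double)(step0 + step));
        ev_time.push_back(time);
        ev_type.push_back(2); ev_enz.push_back(e + 1); ev_site.push_back(s);
        // removal cascade
        std::deque<int> q; q.push_back(chain);
        std::vector<int> removed_now;
        cascade(L, q, removed_now);
        if (!removed_now.empty()) {
          removed_cnt += (int)removed_now.size();
          for (int sk : removed_now) {
            ev_step.push_back((double)(step0 + step));
            ev_time.push_back(time);
            ev_type.push_back(3); ev_enz.push_back(0); ev_site.push_back(sk);
          }
          recompute_surface(L);
          // relocate displaced enzymes to random empty surface sites
          for (int sk : removed_now) {
            int de = occ[sk];
            if (de == 0) continue;
            occ[sk] = 0;
            std::vector<int> cand;
            cand.reserve(256);
            for (int t = 1; t <= L.nsites; t++) {
              if (!L.surface[t - 1] || occ[t] != 0) continue;
              if (ekind[de - 1] == 0 && flanked(L, t)) continue;
              cand.push_back(t);
            }
            if (cand.empty()) {
              for (int t = 1; t <= L.nsites; t++)
                if (L.surface[t - 1] && occ[t] == 0) cand.push_back(t);
            }
            if (cand.empty()) stop("no surface sites left to relocate enzyme");
            int pick = (int)(unif_rand() * cand.size());
            if (pick >= (int)cand.size()) pick = (int)cand.size() - 1;
            int t = cand[pick];
            occ[t] = de;
            tally(de - 1);
            esite[de - 1] = t;
            last_i[de - 1] = L.site_i[t - 1];
            ev_step.push_back((double)(step0 + step));
            ev_time.push_back(time);
            ev_type.push_back(4); ev_enz.push_back(de); ev_site.push_back(t);
          }
        } else {
          // cleave alone can change which faces are exposed? no: bonds do
          // not enter the surface rule, only removals do.
        }
      }
    }
    if (snap_every > 0 && step % snap_every == 0) snapshot();
  }
  for (int e = 0; e < n_enz; e++) tally(e);
  if (snap_every > 0 && (sn_time.empty() || sn_time.back() < time)) snapshot();

  long long n_cleaves = 0;
  for (int s = 0; s < L.nsites; s++) n_cleaves += L.bond_up[s];

  return List::create(
      _["removed"] = LogicalVector(L.removed.begin(), L.removed.end()),
      _["bond_up"] = LogicalVector(L.bond_up.begin(), L.bond_up.end()),
      _["gelatin"] = LogicalVector(L.gelatin.begin(), L.gelatin.end()),
      _["is_surface"] = LogicalVector(L.surface.begin(), L.surface.end()),
      _["enz_site"] = IntegerVector(esite.begin(), esite.end()),
      _["steps"] = (double)step,
      _["time"] = time,
      _["removed_count"] = removed_cnt,
      _["n_cleaved_bonds"] = (double)n_cleaves,
      _["event_step"] = NumericVector(ev_step.begin(), ev_step.end()),
      _["event_time"] = NumericVector(ev_time.begin(), ev_time.end()),
      _["event_type"] = IntegerVector(ev_type.begin(), ev_type.end()),
      _["event_enzyme"] = IntegerVector(ev_enz.begin(), ev_enz.end()),
      _["event_site"] = IntegerVector(ev_site.begin(), ev_site.end()),
      _["occupancy"] = occ_cnt,
      _["snap_time"] = NumericVector(sn_time.begin(), sn_time.end()),
      _["snap_removed"] = IntegerVector(sn_removed.begin(), sn_removed.end()),
      _["snap_z"] = IntegerVector(sn_z.begin(), sn_z.end()),
      _["counters"] = NumericVector::create(
          _["accepted_moves"] = (double)acc_moves,
          _["blocked_moves"] = (double)blk_moves,
          _["rejected_moves"] = (double)rej_moves,
          _["cleave_attempts"] = (double)cl_attempts,
          _["cleave_successes"] = (double)cl_success));
}
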