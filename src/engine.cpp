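// Continuous-time event engine for one parasitoid generation.
//
// Hosts sit in patches; each foraging female cycles through search ->
// patch visit (encounters/ovipositions) -> recovery. Host fate resolves
// at min(maturation, earliest qualifying egg completion). All waiting
// times are exponential, so the whole generation is a race of competing
// memoryless clocks processed in (time, sequence) order from a binary
// heap; stale heap entries are skipped via per-actor version counters.
// R's RNG is used throughout, so set.seed() in R makes runs bit
// reproducible.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <unordered_set>
#include <cmath>

using namespace Rcpp;

namespace {

enum Kind { PATCH_FOUND, ENCOUNTER, ABANDON, RECOVERY_DONE, HOST_RESOLUTION };
enum Phase { SEARCHING, IN_PATCH, RECOVERING };
enum Fate { UNRESOLVED = 0, SURVIVED = 1, KILLED_REP = 2, KILLED_NONREP = 3 };

struct Ev {
  double t;
  long seq;
  int kind;
  int actor;
  long version;
};

struct EvLater {
  // min-heap on (time, sequence); sequence is the deterministic tie-break
  bool operator()(const Ev& a, const Ev& b) const {
    if (a.t != b.t) return a.t > b.t;
    return a.seq > b.seq;
  }
};

inline int unif_index(int n) {
  // uniform integer in [0, n)
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

} // namespace

// [[Rcpp::export(name = ".sim_generation_cpp")]]
List sim_generation_cpp(IntegerVector host_species, IntegerVector host_patch,
                        NumericVector host_maturation,
                        NumericVector par_q, IntegerVector par_S,
                        int n_patches, IntegerVector patch_species,
                        double tau_s, double tau_a, double tau_e, double tau_r,
                        NumericVector tau_dP, int scenario,
                        bool matured_encounterable) {
  const int H = host_species.size();
  const int P = par_q.size();
  if (host_patch.size() != H || host_maturation.size() != H)
    stop("host vectors must have equal length");
  if (par_S.size() != P) stop("parasitoid vectors must have equal length");
  if (tau_dP.size() != 3) stop("tau_dP must have length 3");
  if (scenario != 1 && scenario != 2) stop("scenario must be 1 or 2");

  // ---- host state -------------------------------------------------------
  std::vector<int> fate(H, UNRESOLVED);
  std::vector<double> bestT(H, R_PosInf);     // earliest qualifying completion
  std::vector<char> best_comp(H, 0);
  std::vector<double> best_q(H, 0.0);
  std::vector<int> best_S(H, 0);
  std::vector<char> attacked(H, 0);           // received >= 1 egg
  std::vector<long> host_version(H, 0);
  std::vector<int> host_pos(H, -1);           // position in its patch pool

  // ---- patch state ------------------------------------------------------
  std::vector<std::vector<int> > patch_hosts(n_patches);
  std::vector<std::vector<int> > patch_paras(n_patches);
  for (int h = 0; h < H; ++h) {
    int pt = host_patch[h] - 1;
    if (pt < 0 || pt >= n_patches) stop("host patch id out of range");
    host_pos[h] = (int)patch_hosts[pt].size();
    patch_hosts[pt].push_back(h);
  }

  // ---- parasitoid state -------------------------------------------------
  std::vector<int> phase(P, SEARCHING);
  std::vector<int> cur_patch(P, -1);
  std::vector<int> par_pos(P, -1);            // position in patch_paras
  std::vector<double> last_enc(P, 0.0);       // abandon-clock anchor
  std::vector<int> investment(P, 0);
  std::vector<long> par_version(P, 0);
  std::vector<std::unordered_set<int> > seen(P);

  // ---- outputs ----------------------------------------------------------
  std::vector<double> off_q;                  // deciding parents of emerged
  std::vector<int> off_S;                     //   offspring (pre-mutation)
  IntegerVector eggs_laid(2);

  // ---- event queue ------------------------------------------------------
  std::priority_queue<Ev, std::vector<Ev>, EvLater> pq;
  long seq = 0;
  int unresolved = H;

  // every host carries one pending resolution event
  for (int h = 0; h < H; ++h)
    pq.push(Ev{host_maturation[h], seq++, HOST_RESOLUTION, h, 0});
  // every parasitoid starts searching
  for (int i = 0; i < P; ++i)
    pq.push(Ev{R::rexp(tau_s), seq++, PATCH_FOUND, i, ++par_version[i]});

  // schedule the next within-patch event for parasitoid i at time t:
  // the earlier of the next host encounter (rate m/tau_e, memoryless, so
  // redrawing after any change in the pool size m is exact) and the
  // abandonment deadline tau_a after the last encounter (patch entry if
  // none yet).
  auto schedule_in_patch = [&](int i, double t) {
    int pt = cur_patch[i];
    int m = (int)patch_hosts[pt].size();
    double t_ab = last_enc[i] + tau_a;
    long v = ++par_version[i];
    if (m > 0) {
      double t_enc = t + R::rexp(tau_e / m);
      if (t_enc < t_ab) {
        pq.push(Ev{t_enc, seq++, ENCOUNTER, i, v});
        return;
      }
    }
    pq.push(Ev{t_ab, seq++, ABANDON, i, v});
  };

  auto leave_patch = [&](int i, double t) {
    int pt = cur_patch[i];
    // swap-remove from the patch's parasitoid list
    int pos = par_pos[i];
    std::vector<int>& pl = patch_paras[pt];
    int moved = pl.back();
    pl[pos] = moved;
    par_pos[moved] = pos;
    pl.pop_back();
    par_pos[i] = -1;
    cur_patch[i] = -1;
    phase[i] = RECOVERING;
    int k = investment[i];
    double rec = (k > 0) ? R::rgamma((double)k, tau_r) : 0.0;
    pq.push(Ev{t + rec, seq++, RECOVERY_DONE, i, ++par_version[i]});
  };

  while (unresolved > 0 && !pq.empty()) {
    Ev ev = pq.top();
    pq.pop();
    const double t = ev.t;

    if (ev.kind == HOST_RESOLUTION) {
      int h = ev.actor;
      if (ev.version != host_version[h]) continue; // stale
      if (bestT[h] < host_maturation[h]) {
        // a qualifying egg completed development first: the host dies now
        fate[h] = best_comp[h] ? KILLED_REP : KILLED_NONREP;
        if (best_comp[h]) {
          off_q.push_back(best_q[h]);
          off_S.push_back(best_S[h]);
        }
        int pt = host_patch[h] - 1;
        std::vector<int>& hl = patch_hosts[pt];
        int pos = host_pos[h];
        int moved = hl.back();
        hl[pos] = moved;
        host_pos[moved] = pos;
        hl.pop_back();
        host_pos[h] = -1;
        --unresolved;
        // the encounterable pool shrank: redraw pending within-patch
        // events of every female currently foraging in this patch
        for (size_t j = 0; j < patch_paras[pt].size(); ++j)
          schedule_in_patch(patch_paras[pt][j], t);
      } else {
        // matured before any qualifying egg: survives, all eggs inviable
        fate[h] = SURVIVED;
        --unresolved;
        if (!matured_encounterable) {
          // alternative host-pool reading: a matured host leaves the
          // encounterable pool immediately
          int pt = host_patch[h] - 1;
          std::vector<int>& hl = patch_hosts[pt];
          int pos = host_pos[h];
          int moved = hl.back();
          hl[pos] = moved;
          host_pos[moved] = pos;
          hl.pop_back();
          host_pos[h] = -1;
          for (size_t j = 0; j < patch_paras[pt].size(); ++j)
            schedule_in_patch(patch_paras[pt][j], t);
        }
      }
      continue;
    }

    int i = ev.actor;
    if (ev.version != par_version[i]) continue; // stale

    switch (ev.kind) {
    case PATCH_FOUND: {
      int pt = unif_index(n_patches);
      double rej = (patch_species[pt] == 1) ? std::max(0.0, -par_q[i])
                                            : std::max(0.0, par_q[i]);
      if (rej > 0.0 && unif_rand() < rej) {
        // rejection costs only search time; no visit state is touched
        pq.push(Ev{t + R::rexp(tau_s), seq++, PATCH_FOUND, i,
                   ++par_version[i]});
      } else {
        phase[i] = IN_PATCH;
        cur_patch[i] = pt;
        par_pos[i] = (int)patch_paras[pt].size();
        patch_paras[pt].push_back(i);
        seen[i].clear();
        investment[i] = 0;
        last_enc[i] = t; // abandon clock anchored at entry
        schedule_in_patch(i, t);
      }
      break;
    }
    case ENCOUNTER: {
      int pt = cur_patch[i];
      std::vector<int>& hl = patch_hosts[pt];
      int m = (int)hl.size();
      if (m == 0) { // cannot happen (pool changes bump the version)
        schedule_in_patch(i, t);
        break;
      }
      int h = hl[unif_index(m)];
      if (seen[i].count(h)) {
        // second encounter with the same individual this visit: no
        // further oviposition, leave and recover
        leave_patch(i, t);
      } else {
        seen[i].insert(h);
        if (fate[h] == UNRESOLVED && t < host_maturation[h]) {
          // oviposition: investment is paid whether or not the egg is
          // compatible -- the mother cannot tell
          ++investment[i];
          ++eggs_laid[host_species[h] - 1];
          attacked[h] = 1;
          int Sm = par_S[i];
          bool comp = (Sm == host_species[h]) || (Sm == 3);
          bool qual = (scenario == 2) || comp;
          double Tc = t + R::rexp(tau_dP[Sm - 1]);
          if (qual && Tc < bestT[h]) {
            bestT[h] = Tc;
            best_comp[h] = comp ? 1 : 0;
            best_q[h] = par_q[i];
            best_S[h] = Sm;
            if (Tc < host_maturation[h])
              pq.push(Ev{Tc, seq++, HOST_RESOLUTION, h, ++host_version[h]});
          }
        }
        last_enc[i] = t;
        schedule_in_patch(i, t);
      }
      break;
    }
    case ABANDON:
      leave_patch(i, t);
      break;
    case RECOVERY_DONE:
      phase[i] = SEARCHING;
      pq.push(Ev{t + R::rexp(tau_s), seq++, PATCH_FOUND, i,
                 ++par_version[i]});
      break;
    default:
      stop("unknown event kind");
    }
  }

  if (unresolved > 0)
    stop("event queue underflow with vulnerable hosts remaining");

  return List::create(
    _["fate"] = IntegerVector(fate.begin(), fate.end()),
    _["off_parent_q"] = NumericVector(off_q.begin(), off_q.end()),
    _["off_parent_S"] = IntegerVector(off_S.begin(), off_S.end()),
    _["eggs_laid"] = eggs_laid,
    _["attacked"] = IntegerVector(attacked.begin(), attacked.end()));
}
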