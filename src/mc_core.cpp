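// Dynamically triangulated Metropolis Monte-Carlo membrane engine.
//
// Fixed-topology closed triangulated surface: vertex moves (uniform in a
// sphere of radius `step`) and bond flips (3N random attempts per sweep)
// with hard tether constraints dmin <= |bond| <= dmax. Energy
// W = Wb + Wd + WF: discrete Helfrich bending (cotangent Laplace operator
// with barycentric dual areas, Gaussian term omitted for fixed topology),
// nearest-neighbour nanodomain attraction (-w per pair within r0,
// boundary inclusive, 3D Euclidean distance), and the active-force
// pseudo-energy -F sum n_i . x_i over nanodomain vertices. Energy changes
// are evaluated incrementally over the affected vertex set and audited
// against full recomputation.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <array>
#include <cmath>

using namespace Rcpp;

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double a, double b, double c) : x(a), y(b), z(c) {}
  V3 operator-(const V3& o) const { return V3(x - o.x, y - o.y, z - o.z); }
  V3 operator+(const V3& o) const { return V3(x + o.x, y + o.y, z + o.z); }
  V3 operator*(double s) const { return V3(x * s, y * s, z * s); }
};
static inline double dot(const V3& a, const V3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline V3 cross(const V3& a, const V3& b) {
  return V3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
            a.x * b.y - a.y * b.x);
}
static inline double norm(const V3& a) { return std::sqrt(dot(a, a)); }

class MCMembrane {
public:
  int n;                                    // vertices
  std::vector<V3> x;
  std::vector<std::array<int, 3> > tri;     // oriented outward
  std::vector<std::vector<int> > vtri;      // vertex -> incident triangles
  std::vector<std::vector<int> > adj;       // vertex -> neighbours
  std::vector<std::array<int, 2> > edges;   // undirected edge list
  std::vector<std::array<int, 2> > etri;    // edge -> incident triangles
  std::unordered_map<long long, int> eid;   // edge key -> edge index
  std::vector<char> dom;                    // nanodomain flag
  std::vector<int> domlist;                 // indices of nanodomains
  std::vector<int> dompos;                  // vertex -> index in domlist (-1)
  long acc_swap, try_swap_n;
  double swap_rate;                         // swap attempts per vertex/sweep
  double kappa, c0, w, r0, Fact, kT, dmin, dmax, step;
  double Wb, Wd, WF;
  std::vector<double> wb_v, wf_v;
  long acc_move, try_move, acc_flip, try_flip;
  double max_drift;

  long long ekey(int a, int b) const {
    int lo = a < b ? a : b, hi = a < b ? b : a;
    return (long long)lo * (long long)n + hi;
  }

  MCMembrane(NumericMatrix Vm, IntegerMatrix Tm, LogicalVector domains,
             double kappa_, double c0_, double w_, double r0_,
             double F_, double kT_, double dmin_, double dmax_,
             double step_)
    : kappa(kappa_), c0(c0_), w(w_), r0(r0_), Fact(F_), kT(kT_),
      dmin(dmin_), dmax(dmax_), step(step_),
      acc_move(0), try_move(0), acc_flip(0), try_flip(0), max_drift(0),
      acc_swap(0), try_swap_n(0), swap_rate(0) {
    n = Vm.nrow();
    x.resize(n);
    for (int i = 0; i < n; ++i) x[i] = V3(Vm(i, 0), Vm(i, 1), Vm(i, 2));
    int m = Tm.nrow();
    tri.resize(m);
    vtri.assign(n, std::vector<int>());
    adj.assign(n, std::vector<int>());
    for (int t = 0; t < m; ++t) {
      tri[t][0] = Tm(t, 0); tri[t][1] = Tm(t, 1); tri[t][2] = Tm(t, 2);
      for (int k = 0; k < 3; ++k) vtri[tri[t][k]].push_back(t);
    }
    // edges from triangles
    for (int t = 0; t < m; ++t) {
      for (int k = 0; k < 3; ++k) {
        int a = tri[t][k], b = tri[t][(k + 1) % 3];
        long long key = ekey(a, b);
        auto it = eid.find(key);
        if (it == eid.end()) {
          int id = edges.size();
          eid[key] = id;
          std::array<int, 2> e = {{a < b ? a : b, a < b ? b : a}};
          edges.push_back(e);
          std::array<int, 2> et = {{t, -1}};
          etri.push_back(et);
          adj[a].push_back(b);
          adj[b].push_back(a);
        } else {
          etri[it->second][1] = t;
        }
      }
    }
    dom.assign(n, 0);
    dompos.assign(n, -1);
    for (int i = 0; i < n; ++i)
      if (domains[i]) {
        dom[i] = 1;
        dompos[i] = domlist.size();
        domlist.push_back(i);
      }
    wb_v.assign(n, 0.0);
    wf_v.assign(n, 0.0);
    full_recompute();
  }

  double cvert(int i) const { return dom[i] ? c0 : 0.0; }

  V3 vertex_normal(int i) const {
    V3 nrm;
    for (size_t k = 0; k < vtri[i].size(); ++k) {
      const std::array<int, 3>& T = tri[vtri[i][k]];
      V3 fn = cross(x[T[1]] - x[T[0]], x[T[2]] - x[T[0]]); // 2*area*unit
      nrm = nrm + fn;
    }
    double nn = norm(nrm);
    if (nn < 1e-300) return V3(0, 0, 0);
    return nrm * (1.0 / nn);
  }

  // per-vertex bending energy: (kappa/2)(2H - c)^2 A_i, cotangent operator
  double bending_at(int i) const {
    double area = 0.0;
    V3 lap;                                // sum w_ij (x_i - x_j)
    for (size_t k = 0; k < vtri[i].size(); ++k) {
      const std::array<int, 3>& T = tri[vtri[i][k]];
      // order so that T[p] == i
      int p = (T[0] == i) ? 0 : (T[1] == i ? 1 : 2);
      int j = T[(p + 1) % 3], l = T[(p + 2) % 3];
      V3 e_ij = x[j] - x[i], e_il = x[l] - x[i], e_jl = x[l] - x[j];
      V3 cr = cross(e_ij, e_il);
      double a2 = norm(cr);                // 2 * area
      if (a2 < 1e-14) continue;
      area += a2 / 6.0;                    // barycentric: area/3
      // angle at l is opposite edge (i,j); at j opposite (i,l)
      double cot_l = dot(x[i] - x[l], x[j] - x[l]) / a2;
      double cot_j = dot(x[i] - x[j], x[l] - x[j]) / a2;
      lap = lap + (x[i] - x[j]) * cot_l + (x[i] - x[l]) * cot_j;
    }
    if (area < 1e-14) return 0.0;
    V3 Kv = lap * (0.5 / area);            // mean curvature vector, |Kv| = 2H
    double twoH = norm(Kv);
    V3 nrm = vertex_normal(i);
    if (dot(Kv, nrm) < 0) twoH = -twoH;    // signed: positive for sphere
    double mis = twoH - cvert(i);
    return 0.5 * kappa * mis * mis * area;
  }

  double wf_at(int i) const {
    if (!dom[i] || Fact == 0.0) return 0.0;
    return -Fact * dot(vertex_normal(i), x[i]);
  }

  // direct-attraction pairs involving vertex i (i must be a domain)
  double wd_pairs(int i) const {
    if (!dom[i] || w == 0.0) return 0.0;
    double e = 0.0;
    for (size_t k = 0; k < domlist.size(); ++k) {
      int j = domlist[k];
      if (j == i) continue;
      if (norm(x[i] - x[j]) <= r0) e -= w;
    }
    return e;
  }

  double full_Wb() {
    double s = 0.0;
    for (int i = 0; i < n; ++i) { wb_v[i] = bending_at(i); s += wb_v[i]; }
    return s;
  }
  double full_Wd() const {
    if (w == 0.0) return 0.0;
    double s = 0.0;
    for (size_t a = 0; a < domlist.size(); ++a)
      for (size_t b = a + 1; b < domlist.size(); ++b)
        if (norm(x[domlist[a]] - x[domlist[b]]) <= r0) s -= w;
    return s;
  }
  double full_WF() {
    double s = 0.0;
    for (int i = 0; i < n; ++i) { wf_v[i] = wf_at(i); s += wf_v[i]; }
    return s;
  }
  void full_recompute() { Wb = full_Wb(); Wd = full_Wd(); WF = full_WF(); }

  // ---- vertex move -------------------------------------------------------
  bool try_vertex_move(int i) {
    ++try_move;
    // uniform in sphere of radius step
    double dx, dy, dz;
    do {
      dx = (2.0 * R::unif_rand() - 1.0) * step;
      dy = (2.0 * R::unif_rand() - 1.0) * step;
      dz = (2.0 * R::unif_rand() - 1.0) * step;
    } while (dx * dx + dy * dy + dz * dz > step * step);
    V3 xnew = x[i] + V3(dx, dy, dz);
    // tether constraints
    for (size_t k = 0; k < adj[i].size(); ++k) {
      double d = norm(xnew - x[adj[i][k]]);
      if (d < dmin || d > dmax) return false;
    }
    // triangle degeneracy / inversion
    for (size_t k = 0; k < vtri[i].size(); ++k) {
      const std::array<int, 3>& T = tri[vtri[i][k]];
      V3 p0 = (T[0] == i) ? xnew : x[T[0]];
      V3 p1 = (T[1] == i) ? xnew : x[T[1]];
      V3 p2 = (T[2] == i) ? xnew : x[T[2]];
      V3 nn = cross(p1 - p0, p2 - p0);
      if (norm(nn) < 1e-12) return false;
      V3 no = cross(x[T[1]] - x[T[0]], x[T[2]] - x[T[0]]);
      if (dot(nn, no) <= 0) return false;
    }
    // affected set: i and neighbours
    std::vector<int> aff;
    aff.push_back(i);
    for (size_t k = 0; k < adj[i].size(); ++k) aff.push_back(adj[i][k]);
    double old_b = 0.0, old_f = 0.0;
    for (size_t k = 0; k < aff.size(); ++k) {
      old_b += wb_v[aff[k]];
      old_f += wf_v[aff[k]];
    }
    double old_d = wd_pairs(i);
    V3 xold = x[i];
    x[i] = xnew;
    double new_b = 0.0, new_f = 0.0;
    std::vector<double> nb(aff.size()), nf(aff.size());
    for (size_t k = 0; k < aff.size(); ++k) {
      nb[k] = bending_at(aff[k]); new_b += nb[k];
      nf[k] = wf_at(aff[k]);      new_f += nf[k];
    }
    double new_d = wd_pairs(i);
    double dW = (new_b - old_b) + (new_f - old_f) + (new_d - old_d);
    if (dW <= 0.0 || R::unif_rand() < std::exp(-dW / kT)) {
      for (size_t k = 0; k < aff.size(); ++k) {
        wb_v[aff[k]] = nb[k];
        wf_v[aff[k]] = nf[k];
      }
      Wb += new_b - old_b; WF += new_f - old_f; Wd += new_d - old_d;
      ++acc_move;
      return true;
    }
    x[i] = xold;
    return false;
  }

  // ---- bond flip ---------------------------------------------------------
  bool try_bond_flip(int e) {
    ++try_flip;
    int a = edges[e][0], b = edges[e][1];
    int t1 = etri[e][0], t2 = etri[e][1];
    // orient t1 as (p, q, c) with edge p->q, {p,q} = {a,b}
    std::array<int, 3> T1 = tri[t1], T2 = tri[t2];
    int p = -1, q = -1, c = -1, d = -1;
    for (int k = 0; k < 3; ++k) {
      int u = T1[k], vtx = T1[(k + 1) % 3];
      if ((u == a && vtx == b) || (u == b && vtx == a)) {
        p = u; q = vtx; c = T1[(k + 2) % 3];
        break;
      }
    }
    for (int k = 0; k < 3; ++k)
      if (T2[k] != a && T2[k] != b) { d = T2[k]; break; }
    if (p < 0 || d < 0) return false;      // should not happen
    // manifold / validity checks
    if ((int)adj[p].size() <= 3 || (int)adj[q].size() <= 3) return false;
    for (size_t k = 0; k < adj[c].size(); ++k)
      if (adj[c][k] == d) return false;    // edge c-d already exists
    double dcd = norm(x[c] - x[d]);
    if (dcd < dmin || dcd > dmax) return false;
    // new triangles t1' = (c,p,d), t2' = (d,q,c): reject degenerate
    V3 n1 = cross(x[p] - x[c], x[d] - x[c]);
    V3 n2 = cross(x[q] - x[d], x[c] - x[d]);
    if (norm(n1) < 1e-12 || norm(n2) < 1e-12) return false;
    int vset[4] = {p, q, c, d};
    double old_b = 0.0, old_f = 0.0;
    for (int k = 0; k < 4; ++k) {
      old_b += wb_v[vset[k]];
      old_f += wf_v[vset[k]];
    }
    apply_flip(e, t1, t2, p, q, c, d);
    double new_b = 0.0, new_f = 0.0;
    double nb[4], nf[4];
    for (int k = 0; k < 4; ++k) {
      nb[k] = bending_at(vset[k]); new_b += nb[k];
      nf[k] = wf_at(vset[k]);      new_f += nf[k];
    }
    double dW = (new_b - old_b) + (new_f - old_f);
    if (dW <= 0.0 || R::unif_rand() < std::exp(-dW / kT)) {
      for (int k = 0; k < 4; ++k) {
        wb_v[vset[k]] = nb[k];
        wf_v[vset[k]] = nf[k];
      }
      Wb += new_b - old_b; WF += new_f - old_f;
      ++acc_flip;
      return true;
    }
    // undo: after the flip, edge e is (c,d); the triangle holding the
    // directed edge c->d is t2 (third vertex q) and t1 holds d->c
    // (third vertex p), so the inverse flip swaps the triangle-id roles
    apply_flip(e, t2, t1, c, d, q, p);
    return false;
  }

  // flip edge e = (p,q) with t1 = (p,q,c), t2 = (q,p,d)
  // into (c,d) with t1' = (c,p,d), t2' = (d,q,c)
  void apply_flip(int e, int t1, int t2, int p, int q, int c, int d) {
    // adjacency
    erase_val(adj[p], q); erase_val(adj[q], p);
    adj[c].push_back(d); adj[d].push_back(c);
    // edge record
    eid.erase(ekey(p, q));
    edges[e][0] = c < d ? c : d;
    edges[e][1] = c < d ? d : c;
    eid[ekey(c, d)] = e;
    // boundary-edge triangle references:
    // (p,d): t2 -> t1 ; (q,c): t1 -> t2
    int e_pd = eid[ekey(p, d)];
    replace_tri_ref(e_pd, t2, t1);
    int e_qc = eid[ekey(q, c)];
    replace_tri_ref(e_qc, t1, t2);
    // triangles
    tri[t1][0] = c; tri[t1][1] = p; tri[t1][2] = d;
    tri[t2][0] = d; tri[t2][1] = q; tri[t2][2] = c;
    // vertex-triangle incidence
    erase_val(vtri[p], t2); erase_val(vtri[q], t1);
    vtri[c].push_back(t2); vtri[d].push_back(t1);
  }

  static void erase_val(std::vector<int>& v, int val) {
    for (size_t k = 0; k < v.size(); ++k)
      if (v[k] == val) { v[k] = v.back(); v.pop_back(); return; }
  }
  void replace_tri_ref(int e, int told, int tnew) {
    if (etri[e][0] == told) etri[e][0] = tnew;
    else if (etri[e][1] == told) etri[e][1] = tnew;
  }

  // ---- nanodomain swap move (attribute exchange along a bond) ------------
  bool try_swap_move(int e) {
    int a = edges[e][0], b = edges[e][1];
    if (dom[a] == dom[b]) return false;
    ++try_swap_n;
    if (!dom[a]) std::swap(a, b);          // a is the domain vertex
    // curvature estimates do not change; only the spontaneous-curvature
    // assignment, the pair energies and the force term move
    double old_b = wb_v[a] + wb_v[b];
    double old_f = wf_v[a] + wf_v[b];
    double old_d = wd_pairs(a);
    toggle_pair(a, b);
    double nb_a = bending_at(a), nb_b = bending_at(b);
    double nf_a = wf_at(a), nf_b = wf_at(b);
    double new_d = wd_pairs(b);
    double dW = (nb_a + nb_b - old_b) + (nf_a + nf_b - old_f) +
      (new_d - old_d);
    if (dW <= 0.0 || R::unif_rand() < std::exp(-dW / kT)) {
      wb_v[a] = nb_a; wb_v[b] = nb_b;
      wf_v[a] = nf_a; wf_v[b] = nf_b;
      Wb += nb_a + nb_b - old_b;
      WF += nf_a + nf_b - old_f;
      Wd += new_d - old_d;
      ++acc_swap;
      return true;
    }
    toggle_pair(b, a);
    return false;
  }

  // move the domain attribute from vertex a (domain) to vertex b
  void toggle_pair(int a, int b) {
    dom[a] = 0; dom[b] = 1;
    int k = dompos[a];
    domlist[k] = b;
    dompos[b] = k; dompos[a] = -1;
  }

  // ---- sweeps ------------------------------------------------------------
  void recenter() {
    // enclosed-volume centroid via the divergence theorem
    double V = 0.0; V3 cen;
    for (size_t t = 0; t < tri.size(); ++t) {
      const V3 &p1 = x[tri[t][0]], &p2 = x[tri[t][1]], &p3 = x[tri[t][2]];
      double vt = dot(p1, cross(p2, p3)) / 6.0;
      V += vt;
      cen = cen + (p1 + p2 + p3) * (vt / 4.0);
    }
    if (std::fabs(V) < 1e-12) return;
    cen = cen * (1.0 / V);
    for (int i = 0; i < n; ++i) x[i] = x[i] - cen;
    if (Fact != 0.0) WF = full_WF();       // translation shifts WF
  }

  void sweep(bool do_recenter) {
    if (do_recenter && Fact != 0.0) recenter();
    for (int i = 0; i < n; ++i) try_vertex_move(i);
    int m3 = 3 * n;
    int ne = edges.size();
    for (int k = 0; k < m3; ++k) {
      int e = (int)std::floor(R::unif_rand() * ne);
      if (e >= ne) e = ne - 1;
      try_bond_flip(e);
    }
    if (swap_rate > 0 && !domlist.empty()) {
      int nswap = (int)std::ceil(swap_rate * n);
      for (int k = 0; k < nswap; ++k) {
        int e = (int)std::floor(R::unif_rand() * ne);
        if (e >= ne) e = ne - 1;
        try_swap_move(e);
      }
    }
  }

  double audit() {
    double ob = Wb, od = Wd, of = WF;
    full_recompute();
    double scale = std::fabs(Wb) + std::fabs(Wd) + std::fabs(WF) + 1.0;
    double drift = (std::fabs(Wb - ob) + std::fabs(Wd - od) +
                    std::fabs(WF - of)) / scale;
    if (drift > max_drift) max_drift = drift;
    return drift;
  }

  // ---- validity ----------------------------------------------------------
  List check() const {
    int m = tri.size(), ne = edges.size();
    bool bonds_ok = true;
    double bl_min = 1e300, bl_max = 0.0;
    for (int e = 0; e < ne; ++e) {
      double d = norm(x[edges[e][0]] - x[edges[e][1]]);
      if (d < bl_min) bl_min = d;
      if (d > bl_max) bl_max = d;
      if (d < dmin - 1e-12 || d > dmax + 1e-12) bonds_ok = false;
    }
    int euler = n - ne + m;
    bool manifold = true;
    for (int e = 0; e < ne; ++e)
      if (etri[e][0] < 0 || etri[e][1] < 0) manifold = false;
    // every edge in exactly two triangles, consistent incidence
    int mindeg = n > 0 ? (int)adj[0].size() : 0;
    for (int i = 0; i < n; ++i)
      if ((int)adj[i].size() < mindeg) mindeg = adj[i].size();
    return List::create(_["bonds_ok"] = bonds_ok, _["bl_min"] = bl_min,
                        _["bl_max"] = bl_max, _["euler"] = euler,
                        _["manifold"] = manifold, _["min_degree"] = mindeg,
                        _["n_vertices"] = n, _["n_edges"] = ne,
                        _["n_triangles"] = m);
  }
};

typedef Rcpp::XPtr<MCMembrane> MCPtr;

// [[Rcpp::export]]
SEXP ms_state_new(NumericMatrix V, IntegerMatrix T, LogicalVector domains,
                  double kappa, double c0, double w, double r0, double F,
                  double kT, double dmin, double dmax, double step,
                  double swap_rate = 0) {
  MCMembrane* m = new MCMembrane(V, T, domains, kappa, c0, w, r0, F, kT,
                                 dmin, dmax, step);
  m->swap_rate = swap_rate;
  return MCPtr(m, true);
}

// [[Rcpp::export]]
List ms_sweep(SEXP ptr, int n_sweeps, int recenter_every = 1,
              int audit_every = 100, int check_every = 0) {
  MCPtr m(ptr);
  double drift = 0.0;
  for (int s = 0; s < n_sweeps; ++s) {
    bool rec = recenter_every > 0 && (s % recenter_every == 0);
    m->sweep(rec);
    if (audit_every > 0 && ((s + 1) % audit_every == 0)) {
      double d = m->audit();
      if (d > drift) drift = d;
    }
    if (check_every > 0 && ((s + 1) % check_every == 0)) {
      List ck = m->check();
      if (!as<bool>(ck["bonds_ok"]) || as<int>(ck["euler"]) != 2 ||
          !as<bool>(ck["manifold"]))
        stop("mesh invariant breached after sweep %d", s + 1);
    }
  }
  return List::create(
    _["acc_move"] = (double)m->acc_move / std::max(1L, m->try_move),
    _["acc_flip"] = (double)m->acc_flip / std::max(1L, m->try_flip),
    _["acc_swap"] = (double)m->acc_swap / std::max(1L, m->try_swap_n),
    _["drift"] = drift, _["max_drift"] = m->max_drift,
    _["W"] = m->Wb + m->Wd + m->WF, _["Wb"] = m->Wb, _["Wd"] = m->Wd,
    _["WF"] = m->WF);
}

// [[Rcpp::export]]
List ms_get(SEXP ptr) {
  MCPtr m(ptr);
  int n = m->n, mt = m->tri.size(), ne = m->edges.size();
  NumericMatrix V(n, 3);
  for (int i = 0; i < n; ++i) {
    V(i, 0) = m->x[i].x; V(i, 1) = m->x[i].y; V(i, 2) = m->x[i].z;
  }
  IntegerMatrix T(mt, 3), E(ne, 2);
  for (int t = 0; t < mt; ++t)
    for (int k = 0; k < 3; ++k) T(t, k) = m->tri[t][k] + 1;
  for (int e = 0; e < ne; ++e) {
    E(e, 0) = m->edges[e][0] + 1; E(e, 1) = m->edges[e][1] + 1;
  }
  LogicalVector dm(n);
  for (int i = 0; i < n; ++i) dm[i] = m->dom[i] != 0;
  return List::create(_["vertices"] = V, _["triangles"] = T,
                      _["edges"] = E, _["domains"] = dm,
                      _["Wb"] = m->Wb, _["Wd"] = m->Wd, _["WF"] = m->WF);
}

// [[Rcpp::export]]
List ms_energies(SEXP ptr) {
  MCPtr m(ptr);
  double Wb = 0.0;
  for (int i = 0; i < m->n; ++i) Wb += m->bending_at(i);
  double Wd = m->full_Wd();
  double WF = 0.0;
  for (int i = 0; i < m->n; ++i) WF += m->wf_at(i);
  return List::create(_["Wb"] = Wb, _["Wd"] = Wd, _["WF"] = WF,
                      _["W"] = Wb + Wd + WF);
}

// [[Rcpp::export]]
List ms_check(SEXP ptr) {
  MCPtr m(ptr);
  return m->check();
}

// [[Rcpp::export]]
NumericVector ms_vertex_normals(SEXP ptr) {
  MCPtr m(ptr);
  NumericVector out(3 * m->n);
  for (int i = 0; i < m->n; ++i) {
    V3 nr = m->vertex_normal(i);
    out[i] = nr.x; out[m->n + i] = nr.y; out[2 * m->n + i] = nr.z;
  }
  out.attr("dim") = IntegerVector::create(m->n, 3);
  return out;
}

// acceptance-rule check: fraction of accepted trials at fixed dW
// [[Rcpp::export]]
double ms_metropolis_rate(double dW, double kT, int n_trials) {
  int acc = 0;
  for (int k = 0; k < n_trials; ++k)
    if (dW <= 0.0 || R::unif_rand() < std::exp(-dW / kT)) ++acc;
  return (double)acc / n_trials;
}

// 1-DOF harmonic-potential Metropolis sampler (Boltzmann check):
// U(x) = 0.5 * k * x^2, same acceptance rule as the membrane engine
// [[Rcpp::export]]
NumericVector ms_harmonic_chain(int n_samples, double kconst, double kT,
                                double step, int thin = 10) {
  NumericVector out(n_samples);
  double xx = 0.0;
  for (int s = 0; s < n_samples; ++s) {
    for (int t = 0; t < thin; ++t) {
      double xn = xx + (2.0 * R::unif_rand() - 1.0) * step;
      double dW = 0.5 * kconst * (xn * xn - xx * xx);
      if (dW <= 0.0 || R::unif_rand() < std::exp(-dW / kT)) xx = xn;
    }
    out[s] = xx;
  }
  return out;
}
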