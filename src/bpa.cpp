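#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <deque>
#include <map>
#include <set>
#include <vector>

using namespace Rcpp;

// Ball-pivoting surface reconstruction.
//
// A ball of radius r is seeded on a triangle whose circumscribing ball is
// empty, then pivots around front edges: rotating about an edge it settles on
// the first point where the empty-ball property holds again, emitting one
// triangle per pivot. Multiple radii are processed in ascending order; edges
// left on the boundary by a small ball re-enter the front for the next
// radius, which fills holes in regions of sparser sampling.

namespace {

struct Vec {
  double x, y, z;
};

inline Vec vsub(const Vec& a, const Vec& b) { Vec r = {a.x - b.x, a.y - b.y, a.z - b.z}; return r; }
inline Vec vadd(const Vec& a, const Vec& b) { Vec r = {a.x + b.x, a.y + b.y, a.z + b.z}; return r; }
inline Vec vscale(const Vec& a, double s) { Vec r = {a.x * s, a.y * s, a.z * s}; return r; }
inline double vdot(const Vec& a, const Vec& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec vcross(const Vec& a, const Vec& b) {
  Vec r = {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
  return r;
}
inline double vnorm2(const Vec& a) { return vdot(a, a); }
inline double vnorm(const Vec& a) { return std::sqrt(vnorm2(a)); }

struct FrontEdge {
  int a, b, opp;
  Vec center;
};

class BPA {
public:
  BPA(const NumericMatrix& pts, const NumericMatrix& normals)
      : n_(pts.nrow()), used_(pts.nrow(), false), seedCursor_(0) {
    P_.resize(n_);
    N_.resize(n_);
    for (int i = 0; i < n_; ++i) {
      P_[i].x = pts(i, 0); P_[i].y = pts(i, 1); P_[i].z = pts(i, 2);
      N_[i].x = normals(i, 0); N_[i].y = normals(i, 1); N_[i].z = normals(i, 2);
    }
  }

  void run(double r) {
    r_ = r;
    reseedBoundary();
    for (;;) {
      processFront();
      if (!findSeed()) break;
    }
  }

  IntegerMatrix triangles() const {
    IntegerMatrix out((int)tris_.size() / 3, 3);
    for (int t = 0; t < out.nrow(); ++t)
      for (int j = 0; j < 3; ++j) out(t, j) = tris_[3 * t + j] + 1;
    return out;
  }

private:
  int n_;
  double r_;
  std::vector<Vec> P_, N_;
  std::vector<bool> used_;
  std::vector<int> tris_;
  std::map<long long, int> edgeCount_;
  std::map<long long, int> edgeThird_;  // a triangle vertex opposite the edge
  std::set<long long> triSeen_;
  std::deque<FrontEdge> front_;
  int seedCursor_;

  long long ekey(int a, int b) const {
    if (a > b) std::swap(a, b);
    return (long long)a * n_ + b;
  }
  long long tkey(int a, int b, int c) const {
    int v[3] = {a, b, c};
    std::sort(v, v + 3);
    return ((long long)v[0] * n_ + v[1]) * n_ + v[2];
  }

  // Center of the radius-r ball resting on triangle (a, b, c) on the side
  // `sign` of the triangle normal. Returns false if the circumradius
  // exceeds r or the triangle is degenerate.
  bool ballCenter(int a, int b, int c, int sign, Vec& out) const {
    Vec A = P_[a], B = P_[b], C = P_[c];
    Vec ab = vsub(B, A), ac = vsub(C, A);
    Vec nrm = vcross(ab, ac);
    double n2 = vnorm2(nrm);
    if (n2 < 1e-24) return false;
    // circumcenter in barycentric form
    double d1 = vnorm2(ab), d2 = vnorm2(ac);
    Vec t = vadd(vscale(vcross(nrm, ab), d2), vscale(vcross(ac, nrm), d1));
    Vec circ = vadd(A, vscale(t, 0.5 / n2));
    double R2 = vnorm2(vsub(circ, A));
    double h2 = r_ * r_ - R2;
    if (h2 < 0) return false;
    Vec unit = vscale(nrm, 1.0 / std::sqrt(n2));
    out = vadd(circ, vscale(unit, sign * std::sqrt(h2)));
    return true;
  }

  bool ballEmpty(const Vec& c, int a, int b, int x) const {
    double lim = r_ * r_ * (1.0 - 1e-9) - 1e-12;
    for (int i = 0; i < n_; ++i) {
      if (i == a || i == b || i == x) continue;
      if (vnorm2(vsub(P_[i], c)) < lim) return false;
    }
    return true;
  }

  void addTriangle(int a, int b, int x, const Vec& center) {
    tris_.push_back(a); tris_.push_back(b); tris_.push_back(x);
    triSeen_.insert(tkey(a, b, x));
    used_[a] = used_[b] = used_[x] = true;
    int opp[3] = {x, a, b};
    int ea[3] = {a, b, x}, eb[3] = {b, x, a};
    for (int j = 0; j < 3; ++j) {
      long long k = ekey(ea[j], eb[j]);
      edgeCount_[k] += 1;
      edgeThird_[k] = opp[j];
    }
    // new front edges (the pivot edge itself is now interior or was a seed)
    maybePush(x, b, a, center);
    maybePush(a, x, b, center);
  }

  void maybePush(int a, int b, int opp, const Vec& center) {
    if (edgeCount_[ekey(a, b)] == 1) {
      FrontEdge e = {a, b, opp, center};
      front_.push_back(e);
    }
  }

  bool pivot(const FrontEdge& e, int& bestX, Vec& bestCenter) const {
    Vec A = P_[e.a], B = P_[e.b];
    Vec m = vscale(vadd(A, B), 0.5);
    Vec axis = vsub(B, A);
    double alen = vnorm(axis);
    if (alen < 1e-12) return false;
    axis = vscale(axis, 1.0 / alen);
    Vec u = vsub(e.center, m);
    u = vsub(u, vscale(axis, vdot(u, axis)));
    if (vnorm(u) < 1e-12) return false;
    // rotation sense: the center should initially move away from the
    // previous triangle's interior
    Vec w = vsub(m, P_[e.opp]);
    w = vsub(w, vscale(axis, vdot(w, axis)));
    double sense = vdot(vcross(axis, u), w);
    Vec rotAxis = sense >= 0 ? axis : vscale(axis, -1.0);

    double lim2 = 4.0 * r_ * r_;
    double bestTheta = R_PosInf;
    bestX = -1;
    for (int x = 0; x < n_; ++x) {
      if (x == e.a || x == e.b || x == e.opp) continue;
      if (vnorm2(vsub(P_[x], m)) > lim2) continue;
      std::map<long long, int>::const_iterator it;
      it = edgeCount_.find(ekey(e.a, x));
      if (it != edgeCount_.end() && it->second >= 2) continue;
      it = edgeCount_.find(ekey(e.b, x));
      if (it != edgeCount_.end() && it->second >= 2) continue;
      if (triSeen_.count(tkey(e.a, e.b, x))) continue;
      for (int sign = -1; sign <= 1; sign += 2) {
        Vec c;
        if (!ballCenter(e.a, e.b, x, sign, c)) continue;
        Vec v = vsub(c, m);
        v = vsub(v, vscale(rotAxis, vdot(v, rotAxis)));
        if (vnorm(v) < 1e-12) continue;
        double theta = std::atan2(vdot(rotAxis, vcross(u, v)), vdot(u, v));
        if (theta < 1e-9) theta += 2.0 * M_PI;
        if (theta < bestTheta && ballEmpty(c, e.a, e.b, x)) {
          bestTheta = theta;
          bestX = x;
          bestCenter = c;
        }
      }
    }
    return bestX >= 0;
  }

  void processFront() {
    while (!front_.empty()) {
      FrontEdge e = front_.front();
      front_.pop_front();
      std::map<long long, int>::const_iterator it = edgeCount_.find(ekey(e.a, e.b));
      if (it == edgeCount_.end() || it->second != 1) continue;  // stale
      int x;
      Vec c;
      if (pivot(e, x, c)) addTriangle(e.a, e.b, x, c);
    }
  }

  bool findSeed() {
    double lim2 = 4.0 * r_ * r_;
    for (int scan = 0; scan < n_; ++scan) {
      int p = (seedCursor_ + scan) % n_;
      if (used_[p]) continue;
      std::vector<std::pair<double, int> > cand;
      for (int q = 0; q < n_; ++q) {
        if (q == p) continue;
        double d2 = vnorm2(vsub(P_[q], P_[p]));
        if (d2 <= lim2) cand.push_back(std::make_pair(d2, q));
      }
      std::sort(cand.begin(), cand.end());
      int nc = (int)cand.size();
      for (int i = 0; i < nc; ++i) {
        for (int j = i + 1; j < nc; ++j) {
          int q1 = cand[i].second, q2 = cand[j].second;
          if (triSeen_.count(tkey(p, q1, q2))) continue;
          // outward side by vertex-normal consensus
          Vec nsum = vadd(vadd(N_[p], N_[q1]), N_[q2]);
          Vec tn = vcross(vsub(P_[q1], P_[p]), vsub(P_[q2], P_[p]));
          int a = p, b = q1, c = q2;
          if (vdot(tn, nsum) < 0) std::swap(b, c);
          Vec center;
          if (!ballCenter(a, b, c, +1, center)) continue;
          if (!ballEmpty(center, a, b, c)) continue;
          addTriangle(a, b, c, center);
          // the seed triangle leaves all three edges on the front
          maybePush(b, a, c, center);
          seedCursor_ = p;
          processFront();
          return true;
        }
      }
    }
    return false;
  }

  // boundary edges of the existing mesh re-enter the front at a new radius
  void reseedBoundary() {
    front_.clear();
    for (std::map<long long, int>::const_iterator it = edgeCount_.begin();
         it != edgeCount_.end(); ++it) {
      if (it->second != 1) continue;
      int a = (int)(it->first / n_);
      int b = (int)(it->first % n_);
      int opp = edgeThird_[it->first];
      for (int sign = -1; sign <= 1; sign += 2) {
        Vec c;
        if (ballCenter(a, b, opp, sign, c) && ballEmpty(c, a, b, opp)) {
          FrontEdge e = {a, b, opp, c};
          front_.push_back(e);
          break;
        }
      }
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".bpa_cpp")]]
IntegerMatrix bpa_cpp(NumericMatrix pts, NumericMatrix normals, NumericVector radii) {
  if (pts.nrow() != normals.nrow()) stop("points and normals disagree in length");
  BPA bpa(pts, normals);
  NumericVector r = clone(radii).sort();
  for (int i = 0; i < r.size(); ++i) bpa.run(r[i]);
  return bpa.triangles();
}
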