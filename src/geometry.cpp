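#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Convex polygon helpers for rotated-rectangle overlap. Quads arrive as
// length-8 rows (x1,y1,...,x4,y4) in consistent winding order.

struct Pt { double x, y; };

static double poly_area(const std::vector<Pt>& p) {
  const int n = p.size();
  if (n < 3) return 0.0;
  double a = 0.0;
  for (int i = 0; i < n; ++i) {
    const Pt& u = p[i];
    const Pt& v = p[(i + 1) % n];
    a += u.x * v.y - v.x * u.y;
  }
  return std::fabs(a) * 0.5;
}

// Sutherland-Hodgman: clip subject polygon by each directed edge of a convex
// clip polygon. Points on the "inside" half-plane (consistent with the clip
// polygon's winding) are kept.
static std::vector<Pt> clip_convex(std::vector<Pt> subject,
                                   const std::vector<Pt>& clip) {
  const int m = clip.size();
  // orientation sign of the clip polygon
  double orient = 0.0;
  for (int i = 0; i < m; ++i) {
    const Pt& u = clip[i];
    const Pt& v = clip[(i + 1) % m];
    orient += u.x * v.y - v.x * u.y;
  }
  const double sgn = orient >= 0 ? 1.0 : -1.0;
  for (int i = 0; i < m && !subject.empty(); ++i) {
    const Pt a = clip[i];
    const Pt b = clip[(i + 1) % m];
    std::vector<Pt> out;
    out.reserve(subject.size() + 4);
    const int n = subject.size();
    for (int j = 0; j < n; ++j) {
      const Pt p = subject[j];
      const Pt q = subject[(j + 1) % n];
      const double dp = sgn * ((b.x - a.x) * (p.y - a.y) - (b.y - a.y) * (p.x - a.x));
      const double dq = sgn * ((b.x - a.x) * (q.y - a.y) - (b.y - a.y) * (q.x - a.x));
      if (dp >= 0) {
        out.push_back(p);
        if (dq < 0) {
          const double t = dp / (dp - dq);
          out.push_back({p.x + t * (q.x - p.x), p.y + t * (q.y - p.y)});
        }
      } else if (dq >= 0) {
        const double t = dp / (dp - dq);
        out.push_back({p.x + t * (q.x - p.x), p.y + t * (q.y - p.y)});
      }
    }
    subject = out;
  }
  return subject;
}

static std::vector<Pt> row_to_quad(const NumericMatrix& m, int i) {
  std::vector<Pt> q(4);
  for (int v = 0; v < 4; ++v) q[v] = {m(i, 2 * v), m(i, 2 * v + 1)};
  return q;
}

// [[Rcpp::export]]
NumericVector cpp_quad_iou(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow();
  if (b.nrow() != n) stop("quad matrices must have equal row counts");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    std::vector<Pt> qa = row_to_quad(a, i), qb = row_to_quad(b, i);
    const double aa = poly_area(qa), ab = poly_area(qb);
    const std::vector<Pt> inter = clip_convex(qa, qb);
    const double ai = poly_area(inter);
    const double un = aa + ab - ai;
    out[i] = un > 0 ? std::min(1.0, std::max(0.0, ai / un)) : 0.0;
  }
  return out;
}

// Intersection of one convex polygon (nx2 matrix) with a convex clip quad.
// [[Rcpp::export]]
NumericMatrix cpp_clip_poly(NumericMatrix poly, NumericMatrix clip) {
  std::vector<Pt> subject(poly.nrow()), cl(clip.nrow());
  for (int i = 0; i < poly.nrow(); ++i) subject[i] = {poly(i, 0), poly(i, 1)};
  for (int i = 0; i < clip.nrow(); ++i) cl[i] = {clip(i, 0), clip(i, 1)};
  std::vector<Pt> res = clip_convex(subject, cl);
  NumericMatrix out(res.size(), 2);
  for (size_t i = 0; i < res.size(); ++i) {
    out(i, 0) = res[i].x;
    out(i, 1) = res[i].y;
  }
  return out;
}

static inline bool in_quad(const std::vector<Pt>& q, double sgn, double x, double y) {
  for (int i = 0; i < 4; ++i) {
    const Pt& a = q[i];
    const Pt& b = q[(i + 1) % 4];
    if (sgn * ((b.x - a.x) * (y - a.y) - (b.y - a.y) * (x - a.x)) < 0) return false;
  }
  return true;
}

static double quad_orient(const std::vector<Pt>& q) {
  double o = 0.0;
  for (int i = 0; i < 4; ++i) {
    o += q[i].x * q[(i + 1) % 4].y - q[(i + 1) % 4].x * q[i].y;
  }
  return o >= 0 ? 1.0 : -1.0;
}

// Brute-force IoU estimate from a dense point grid over the joint bounding
// box; algorithmically independent of the clipping route (cross-check only).
// [[Rcpp::export]]
double cpp_raster_iou(NumericVector a, NumericVector b, double npts) {
  std::vector<Pt> qa(4), qb(4);
  for (int v = 0; v < 4; ++v) {
    qa[v] = {a[2 * v], a[2 * v + 1]};
    qb[v] = {b[2 * v], b[2 * v + 1]};
  }
  double xmin = qa[0].x, xmax = qa[0].x, ymin = qa[0].y, ymax = qa[0].y;
  for (int v = 0; v < 4; ++v) {
    xmin = std::min({xmin, qa[v].x, qb[v].x});
    xmax = std::max({xmax, qa[v].x, qb[v].x});
    ymin = std::min({ymin, qa[v].y, qb[v].y});
    ymax = std::max({ymax, qa[v].y, qb[v].y});
  }
  const double w = xmax - xmin, h = ymax - ymin;
  if (w <= 0 || h <= 0) return 0.0;
  const double step = std::sqrt(w * h / npts);
  const int nx = std::max(1, (int)(w / step));
  const int ny = std::max(1, (int)(h / step));
  const double sa = quad_orient(qa), sb = quad_orient(qb);
  long long ia = 0, ib = 0, iboth = 0;
  for (int i = 0; i < nx; ++i) {
    const double x = xmin + (i + 0.5) * w / nx;
    for (int j = 0; j < ny; ++j) {
      const double y = ymin + (j + 0.5) * h / ny;
      const bool na = in_quad(qa, sa, x, y);
      const bool nb = in_quad(qb, sb, x, y);
      ia += na;
      ib += nb;
      iboth += (na && nb);
    }
  }
  const long long un = ia + ib - iboth;
  return un > 0 ? (double)iboth / (double)un : 0.0;
}
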