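#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Uniform spatial hash over 3-D points supporting incremental insertion and
// nearest-neighbour queries with a small exclusion list. Cell size should be
// of the order of the expected nearest-neighbour distance.
struct NodeGrid {
  double cell;
  std::unordered_map<long long, std::vector<int> > cells;  // 1-based ids
  std::vector<double> x, y, z;                             // id - 1 indexed

  explicit NodeGrid(double c) : cell(c) {}

  long long key(int ix, int iy, int iz) const {
    return ((long long)(ix + 1048576) << 42) |
           ((long long)(iy + 1048576) << 21) |
           (long long)(iz + 1048576);
  }
  int cidx(double v) const { return (int)std::floor(v / cell); }

  void insert(int id, double px, double py, double pz) {
    if ((int)x.size() < id) { x.resize(id); y.resize(id); z.resize(id); }
    x[id - 1] = px; y[id - 1] = py; z[id - 1] = pz;
    cells[key(cidx(px), cidx(py), cidx(pz))].push_back(id);
  }

  // nearest id (1-based, 0 if none) within max_ring Chebyshev cell rings,
  // skipping up to three excluded ids
  int nearest(double qx, double qy, double qz, const int *excl,
              double &best_d2) const {
    int cx = cidx(qx), cy = cidx(qy), cz = cidx(qz);
    int best = 0;
    best_d2 = R_PosInf;
    const int max_ring = 8;
    for (int r = 0; r <= max_ring; ++r) {
      for (int ix = cx - r; ix <= cx + r; ++ix)
        for (int iy = cy - r; iy <= cy + r; ++iy)
          for (int iz = cz - r; iz <= cz + r; ++iz) {
            if (std::max(std::abs(ix - cx),
                         std::max(std::abs(iy - cy), std::abs(iz - cz))) != r)
              continue;
            std::unordered_map<long long, std::vector<int> >::const_iterator
              it = cells.find(key(ix, iy, iz));
            if (it == cells.end()) continue;
            for (size_t m = 0; m < it->second.size(); ++m) {
              int id = it->second[m];
              if (id == excl[0] || id == excl[1] || id == excl[2]) continue;
              double dx = x[id - 1] - qx, dy = y[id - 1] - qy,
                     dz = z[id - 1] - qz;
              double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 < best_d2) { best_d2 = d2; best = id; }
            }
          }
      if (best && best_d2 <= (double)r * cell * (double)r * cell) break;
    }
    return best;
  }
};

// [[Rcpp::export]]
SEXP cpp_grid_new(double cell) {
  XPtr<NodeGrid> p(new NodeGrid(cell), true);
  return p;
}

// [[Rcpp::export]]
void cpp_grid_insert(SEXP gp, int id, NumericVector pt) {
  XPtr<NodeGrid> g(gp);
  g->insert(id, pt[0], pt[1], pt[2]);
}

// Nearest row of pts (n x 3) to query point q; rows with skip[i] == true are
// ignored. Returns 1-based index (0 if none) and squared distance.
// [[Rcpp::export]]
List cpp_nn1(NumericVector q, NumericMatrix pts, LogicalVector skip) {
  const int n = pts.nrow();
  int best = -1;
  double bestd = R_PosInf;
  const bool use_skip = skip.size() == n;
  for (int i = 0; i < n; ++i) {
    if (use_skip && skip[i]) continue;
    double dx = pts(i, 0) - q[0];
    double dy = pts(i, 1) - q[1];
    double dz = pts(i, 2) - q[2];
    double d = dx * dx + dy * dy + dz * dz;
    if (d < bestd) { bestd = d; best = i; }
  }
  return List::create(_["index"] = best + 1, _["dist2"] = bestd);
}

// Nearest row of pts for each row of queries (m x 3). Returns 1-based indices.
// [[Rcpp::export]]
IntegerVector cpp_nn_batch(NumericMatrix queries, NumericMatrix pts) {
  const int m = queries.nrow(), n = pts.nrow();
  IntegerVector out(m);
  for (int j = 0; j < m; ++j) {
    double qx = queries(j, 0), qy = queries(j, 1), qz = queries(j, 2);
    int best = -1;
    double bestd = R_PosInf;
    for (int i = 0; i < n; ++i) {
      double dx = pts(i, 0) - qx, dy = pts(i, 1) - qy, dz = pts(i, 2) - qz;
      double d = dx * dx + dy * dy + dz * dz;
      if (d < bestd) { bestd = d; best = i; }
    }
    out[j] = best + 1;
  }
  return out;
}

// Indices (1-based) of rows of pts within radius r of q.
// [[Rcpp::export]]
IntegerVector cpp_within_radius(NumericVector q, NumericMatrix pts, double r) {
  const int n = pts.nrow();
  const double r2 = r * r;
  std::vector<int> hits;
  for (int i = 0; i < n; ++i) {
    double dx = pts(i, 0) - q[0];
    double dy = pts(i, 1) - q[1];
    double dz = pts(i, 2) - q[2];
    if (dx * dx + dy * dy + dz * dz <= r2) hits.push_back(i + 1);
  }
  return wrap(hits);
}

// Moeller-Trumbore ray/triangle intersection over a triangle soup.
// v0, v1, v2 are (ntri x 3); returns parameter t (>= 0) per triangle or Inf.
// [[Rcpp::export]]
NumericVector cpp_ray_tris(NumericVector orig, NumericVector dir,
                           NumericMatrix v0, NumericMatrix v1,
                           NumericMatrix v2) {
  const int n = v0.nrow();
  NumericVector out(n, R_PosInf);
  const double eps = 1e-9;
  for (int i = 0; i < n; ++i) {
    double e1x = v1(i, 0) - v0(i, 0), e1y = v1(i, 1) - v0(i, 1), e1z = v1(i, 2) - v0(i, 2);
    double e2x = v2(i, 0) - v0(i, 0), e2y = v2(i, 1) - v0(i, 1), e2z = v2(i, 2) - v0(i, 2);
    double px = dir[1] * e2z - dir[2] * e2y;
    double py = dir[2] * e2x - dir[0] * e2z;
    double pz = dir[0] * e2y - dir[1] * e2x;
    double det = e1x * px + e1y * py + e1z * pz;
    if (std::fabs(det) < eps) continue;
    double inv = 1.0 / det;
    double tx = orig[0] - v0(i, 0), ty = orig[1] - v0(i, 1), tz = orig[2] - v0(i, 2);
    double u = (tx * px + ty * py + tz * pz) * inv;
    if (u < -1e-9 || u > 1 + 1e-9) continue;
    double qx = ty * e1z - tz * e1y;
    double qy = tz * e1x - tx * e1z;
    double qz = tx * e1y - ty * e1x;
    double v = (dir[0] * qx + dir[1] * qy + dir[2] * qz) * inv;
    if (v < -1e-9 || u + v > 1 + 1e-9) continue;
    double t = (e2x * qx + e2y * qy + e2z * qz) * inv;
    if (t >= 0) out[i] = t;
  }
  return out;
}

// Walk one growth branch in sub-steps of `res`, re-projecting onto the
// sub-endocardial surface and testing for collisions against the existing
// network. Appends nodes into the preallocated matrix `nodes` (by
// reference; caller guarantees capacity n_nodes + n_sub) and marks
// coverage flags in place. Returns the new node count, the segment list
// (from/to pairs, 1-based), the final direction, and the termination
// mode: 0 = tip alive, 1 = truncated at the band edge, 2 = collided and
// merged, 3 = collided but the target's parent cap forbade merging.
// [[Rcpp::export]]
List cpp_walk_branch(int start_id, NumericVector start_pos,
                     NumericVector d_rot_in, int n_sub, double res,
                     double rfac, bool collide,
                     NumericMatrix surf_pts, NumericMatrix surf_nrm,
                     NumericMatrix nodes, int n_nodes,
                     IntegerVector parent_ct, int child_ct_start,
                     double edge_length, double mu,
                     LogicalVector covered, SEXP grid_ptr) {
  XPtr<NodeGrid> grid(grid_ptr);
  const int ns = surf_pts.nrow();
  double pos[3] = {start_pos[0], start_pos[1], start_pos[2]};
  double d_rot[3] = {d_rot_in[0], d_rot_in[1], d_rot_in[2]};
  double d_last[3] = {d_rot[0], d_rot[1], d_rot[2]};
  int recent[3] = {start_id, -1, -1};
  int cur = start_id;
  int added = 0, term = 0, merge_target = 0;
  std::vector<int> seg_from, seg_to;
  const double mu2 = mu * mu;

  for (int s = 0; s < n_sub; ++s) {
    // local surface frame at pos
    int qi = -1; double qd = R_PosInf;
    for (int i = 0; i < ns; ++i) {
      double dx = surf_pts(i, 0) - pos[0], dy = surf_pts(i, 1) - pos[1],
             dz = surf_pts(i, 2) - pos[2];
      double d = dx * dx + dy * dy + dz * dz;
      if (d < qd) { qd = d; qi = i; }
    }
    double nx = surf_nrm(qi, 0), ny = surf_nrm(qi, 1), nz = surf_nrm(qi, 2);
    // project branch direction onto the tangent plane
    double dot = d_rot[0] * nx + d_rot[1] * ny + d_rot[2] * nz;
    double dr[3] = {d_rot[0] - dot * nx, d_rot[1] - dot * ny,
                    d_rot[2] - dot * nz};
    double nrm = std::sqrt(dr[0] * dr[0] + dr[1] * dr[1] + dr[2] * dr[2]);
    if (nrm < 1e-9) { dr[0] = d_rot[0]; dr[1] = d_rot[1]; dr[2] = d_rot[2];
      nrm = std::sqrt(dr[0]*dr[0] + dr[1]*dr[1] + dr[2]*dr[2]); }
    dr[0] /= nrm; dr[1] /= nrm; dr[2] /= nrm;
    double d[3] = {dr[0], dr[1], dr[2]};
    if (rfac > 0 && n_nodes + added > 1) {
      double bd = R_PosInf;
      int bid = grid->nearest(pos[0], pos[1], pos[2], recent, bd);
      int bi = bid - 1;
      if (bid > 0 && bd > 1e-12) {
        double rx = pos[0] - nodes(bi, 0), ry = pos[1] - nodes(bi, 1),
               rz = pos[2] - nodes(bi, 2);
        double rn = std::sqrt(bd);
        d[0] = (1 - rfac) * dr[0] + rfac * rx / rn;
        d[1] = (1 - rfac) * dr[1] + rfac * ry / rn;
        d[2] = (1 - rfac) * dr[2] + rfac * rz / rn;
        double dn = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
        if (dn < 1e-9) { d[0] = dr[0]; d[1] = dr[1]; d[2] = dr[2]; }
        else { d[0] /= dn; d[1] /= dn; d[2] /= dn; }
      }
    }
    double cand[3] = {pos[0] + res * d[0], pos[1] + res * d[1],
                      pos[2] + res * d[2]};
    // re-project the candidate onto the surface
    int ci = -1; double cd = R_PosInf;
    for (int i = 0; i < ns; ++i) {
      double dx = surf_pts(i, 0) - cand[0], dy = surf_pts(i, 1) - cand[1],
             dz = surf_pts(i, 2) - cand[2];
      double dd = dx * dx + dy * dy + dz * dz;
      if (dd < cd) { cd = dd; ci = i; }
    }
    double cnx = surf_nrm(ci, 0), cny = surf_nrm(ci, 1), cnz = surf_nrm(ci, 2);
    double offx = cand[0] - surf_pts(ci, 0), offy = cand[1] - surf_pts(ci, 1),
           offz = cand[2] - surf_pts(ci, 2);
    double offn = offx * cnx + offy * cny + offz * cnz;
    cand[0] -= offn * cnx; cand[1] -= offn * cny; cand[2] -= offn * cnz;
    double resid0 = std::sqrt(cd);
    double dqx = cand[0] - surf_pts(ci, 0), dqy = cand[1] - surf_pts(ci, 1),
           dqz = cand[2] - surf_pts(ci, 2);
    double resid = std::sqrt(dqx * dqx + dqy * dqy + dqz * dqz);
    if (resid > 0.9 * edge_length || resid0 > 0.9 * edge_length) {
      term = 1; break;   // leaving the sub-endocardial band: truncate
    }
    if (collide) {
      double bd = R_PosInf;
      int bid = grid->nearest(cand[0], cand[1], cand[2], recent, bd);
      if (bid > 0 && std::sqrt(bd) < 0.5 * res) {
        if (parent_ct[bid - 1] < 2) { term = 2; merge_target = bid; }
        else term = 3;
        break;
      }
    }
    // append the accepted sub-step node
    int nid = n_nodes + added;    // 0-based row
    nodes(nid, 0) = cand[0]; nodes(nid, 1) = cand[1]; nodes(nid, 2) = cand[2];
    added++;
    grid->insert(nid + 1, cand[0], cand[1], cand[2]);
    seg_from.push_back(cur); seg_to.push_back(nid + 1);
    // coverage update
    for (int i = 0; i < covered.size(); ++i) {
      if (covered[i]) continue;
      double dx = surf_pts(i, 0) - cand[0], dy = surf_pts(i, 1) - cand[1],
             dz = surf_pts(i, 2) - cand[2];
      if (dx * dx + dy * dy + dz * dz <= mu2) covered[i] = true;
    }
    double stepn = std::sqrt((cand[0] - pos[0]) * (cand[0] - pos[0]) +
                             (cand[1] - pos[1]) * (cand[1] - pos[1]) +
                             (cand[2] - pos[2]) * (cand[2] - pos[2]));
    if (stepn > 1e-9) {
      d_last[0] = (cand[0] - pos[0]) / stepn;
      d_last[1] = (cand[1] - pos[1]) / stepn;
      d_last[2] = (cand[2] - pos[2]) / stepn;
    }
    pos[0] = cand[0]; pos[1] = cand[1]; pos[2] = cand[2];
    recent[2] = recent[1]; recent[1] = recent[0]; recent[0] = nid + 1;
    cur = nid + 1;
  }
  return List::create(_["added"] = added,
                      _["seg_from"] = wrap(seg_from),
                      _["seg_to"] = wrap(seg_to),
                      _["tip_id"] = cur,
                      _["tip_dir"] = NumericVector::create(d_last[0], d_last[1],
                                                           d_last[2]),
                      _["term"] = term,
                      _["merge_target"] = merge_target);
}

// First-hit parameter per ray: for each row of `orig`/`dir`, the minimum
// Moeller-Trumbore intersection parameter over the triangle soup, ignoring
// hits with t < tmin. Returns Inf where no triangle is hit.
// [[Rcpp::export]]
NumericVector cpp_ray_first(NumericMatrix orig, NumericMatrix dir,
                            NumericMatrix v0, NumericMatrix v1,
                            NumericMatrix v2, double tmin) {
  const int nr = orig.nrow(), nt = v0.nrow();
  NumericVector out(nr, R_PosInf);
  const double eps = 1e-9;
  for (int j = 0; j < nr; ++j) {
    double ox = orig(j, 0), oy = orig(j, 1), oz = orig(j, 2);
    double dx = dir(j, 0), dy = dir(j, 1), dz = dir(j, 2);
    double best = R_PosInf;
    for (int i = 0; i < nt; ++i) {
      double e1x = v1(i, 0) - v0(i, 0), e1y = v1(i, 1) - v0(i, 1),
             e1z = v1(i, 2) - v0(i, 2);
      double e2x = v2(i, 0) - v0(i, 0), e2y = v2(i, 1) - v0(i, 1),
             e2z = v2(i, 2) - v0(i, 2);
      double px = dy * e2z - dz * e2y;
      double py = dz * e2x - dx * e2z;
      double pz = dx * e2y - dy * e2x;
      double det = e1x * px + e1y * py + e1z * pz;
      if (std::fabs(det) < eps) continue;
      double inv = 1.0 / det;
      double tx = ox - v0(i, 0), ty = oy - v0(i, 1), tz = oz - v0(i, 2);
      double u = (tx * px + ty * py + tz * pz) * inv;
      if (u < -1e-9 || u > 1 + 1e-9) continue;
      double qx = ty * e1z - tz * e1y;
      double qy = tz * e1x - tx * e1z;
      double qz = tx * e1y - ty * e1x;
      double v = (dx * qx + dy * qy + dz * qz) * inv;
      if (v < -1e-9 || u + v > 1 + 1e-9) continue;
      double t = (e2x * qx + e2y * qy + e2z * qz) * inv;
      if (t >= tmin && t < best) best = t;
    }
    out[j] = best;
  }
  return out;
}

// Update coverage flags: mark rows of pts within radius r of q as covered.
// Modifies `covered` in place (logical vector of length nrow(pts)).
// [[Rcpp::export]]
void cpp_cover_update(NumericVector q, NumericMatrix pts, double r,
                      LogicalVector covered) {
  const int n = pts.nrow();
  const double r2 = r * r;
  for (int i = 0; i < n; ++i) {
    if (covered[i]) continue;
    double dx = pts(i, 0) - q[0];
    double dy = pts(i, 1) - q[1];
    double dz = pts(i, 2) - q[2];
    if (dx * dx + dy * dy + dz * dz <= r2) covered[i] = true;
  }
}
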