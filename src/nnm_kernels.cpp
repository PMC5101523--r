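#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pair displacement with optional minimum-image convention per dimension.
// coords are column-major n x d; box has length d (entries <= 0 mean open).
static inline double pair_dist(const double* x, int n, int d, int i, int j,
                               const double* box, bool has_box, double* dx) {
  double r2 = 0.0;
  for (int c = 0; c < d; ++c) {
    double del = x[i + (size_t)c * n] - x[j + (size_t)c * n];
    if (has_box && box[c] > 0.0) del -= box[c] * std::round(del / box[c]);
    dx[c] = del;
    r2 += del * del;
  }
  return std::sqrt(r2);
}

static inline double edge_energy(double r, double r0, double k2, double k4) {
  double s = r - r0;
  double s2 = s * s;
  return 0.5 * k2 * s2 + 0.25 * k4 * s2 * s2;
}

static void compute_forces(const double* x, int n, int d,
                           const int* ei, const int* ej, const double* r0,
                           int ne, double k2, double k4,
                           const double* box, bool has_box, double* f) {
  std::fill(f, f + (size_t)n * d, 0.0);
  double dx[3];
  for (int e = 0; e < ne; ++e) {
    int i = ei[e] - 1, j = ej[e] - 1;
    double r = pair_dist(x, n, d, i, j, box, has_box, dx);
    if (r <= 0.0) continue;
    double s = r - r0[e];
    double dVdr = k2 * s + k4 * s * s * s;
    double g = dVdr / r;
    for (int c = 0; c < d; ++c) {
      double fc = g * dx[c];
      f[i + (size_t)c * n] -= fc;
      f[j + (size_t)c * n] += fc;
    }
  }
}

// [[Rcpp::export]]
double nnm_potential_cpp(NumericMatrix coords, IntegerVector ei, IntegerVector ej,
                         NumericVector r0, double k2, double k4, NumericVector box) {
  int n = coords.nrow(), d = coords.ncol(), ne = ei.size();
  bool has_box = box.size() == d;
  double dx[3], v = 0.0;
  for (int e = 0; e < ne; ++e) {
    double r = pair_dist(REAL(coords), n, d, ei[e] - 1, ej[e] - 1,
                         has_box ? REAL(box) : nullptr, has_box, dx);
    v += edge_energy(r, r0[e], k2, k4);
  }
  return v;
}

// [[Rcpp::export]]
NumericMatrix nnm_forces_cpp(NumericMatrix coords, IntegerVector ei, IntegerVector ej,
                             NumericVector r0, double k2, double k4, NumericVector box) {
  int n = coords.nrow(), d = coords.ncol();
  bool has_box = box.size() == d;
  NumericMatrix f(n, d);
  compute_forces(REAL(coords), n, d, INTEGER(ei), INTEGER(ej), REAL(r0), ei.size(),
                 k2, k4, has_box ? REAL(box) : nullptr, has_box, REAL(f));
  return f;
}

// Per-node total energy: kinetic plus half of each incident edge's potential.
static void node_energies_one(const double* x, const double* v, const double* m,
                              int n, int d, const int* ei, const int* ej,
                              const double* r0, int ne, double k2, double k4,
                              const double* box, bool has_box, double* en) {
  for (int i = 0; i < n; ++i) {
    double ke = 0.0;
    for (int c = 0; c < d; ++c) {
      double vc = v[i + (size_t)c * n];
      ke += vc * vc;
    }
    en[i] = 0.5 * m[i] * ke;
  }
  double dx[3];
  for (int e = 0; e < ne; ++e) {
    int i = ei[e] - 1, j = ej[e] - 1;
    double r = pair_dist(x, n, d, i, j, box, has_box, dx);
    double half = 0.5 * edge_energy(r, r0[e], k2, k4);
    en[i] += half;
    en[j] += half;
  }
}

// [[Rcpp::export]]
NumericVector nnm_node_energies_cpp(NumericMatrix coords, NumericMatrix vel,
                                    NumericVector mass, IntegerVector ei,
                                    IntegerVector ej, NumericVector r0,
                                    double k2, double k4, NumericVector box) {
  int n = coords.nrow(), d = coords.ncol();
  bool has_box = box.size() == d;
  NumericVector en(n);
  node_energies_one(REAL(coords), REAL(vel), REAL(mass), n, d, INTEGER(ei),
                    INTEGER(ej), REAL(r0), ei.size(), k2, k4,
                    has_box ? REAL(box) : nullptr, has_box, REAL(en));
  return en;
}

// Microcanonical velocity-Verlet integrator.
//
// Sparse output: full state (positions, velocities, per-node energies) every
// `stride` steps; designated probe coordinates and the summed energy of an
// optional node group every step.  Aborts early if the total energy drifts by
// more than `max_drift` (fraction of the initial total; <= 0 disables).
// [[Rcpp::export]]
List nnm_verlet_cpp(NumericMatrix x0, NumericMatrix v0, NumericVector mass,
                    IntegerVector ei, IntegerVector ej, NumericVector r0,
                    double k2, double k4, NumericVector box,
                    double dt, int n_steps, int stride,
                    IntegerVector probe_nodes, IntegerVector energy_group,
                    double max_drift) {
  int n = x0.nrow(), d = x0.ncol(), ne = ei.size();
  bool has_box = box.size() == d;
  const double* boxp = has_box ? REAL(box) : nullptr;
  const double* m = REAL(mass);
  int np = probe_nodes.size(), ng = energy_group.size();

  std::vector<double> x(REAL(x0), REAL(x0) + (size_t)n * d);
  std::vector<double> v(REAL(v0), REAL(v0) + (size_t)n * d);
  std::vector<double> f((size_t)n * d), en(n);

  int n_frames = n_steps / stride + 1;
  NumericVector pos((size_t)n_frames * n * d), velout((size_t)n_frames * n * d);
  NumericMatrix node_en(n_frames, n);
  NumericVector total_en(n_frames), frame_step(n_frames);
  NumericMatrix probe(np > 0 ? n_steps + 1 : 0, np * d);
  NumericVector group_en(ng > 0 ? n_steps + 1 : 0);

  compute_forces(x.data(), n, d, INTEGER(ei), INTEGER(ej), REAL(r0), ne, k2, k4,
                 boxp, has_box, f.data());

  double e_init = 0.0;
  int frame = 0, aborted_at = -1;

  auto record_frame = [&](int step) {
    for (int c = 0; c < d; ++c)
      for (int i = 0; i < n; ++i) {
        pos[frame + (size_t)n_frames * (i + (size_t)n * c)] = x[i + (size_t)c * n];
        velout[frame + (size_t)n_frames * (i + (size_t)n * c)] = v[i + (size_t)c * n];
      }
    node_energies_one(x.data(), v.data(), m, n, d, INTEGER(ei), INTEGER(ej),
                      REAL(r0), ne, k2, k4, boxp, has_box, en.data());
    double tot = 0.0;
    for (int i = 0; i < n; ++i) {
      node_en(frame, i) = en[i];
      tot += en[i];
    }
    total_en[frame] = tot;
    frame_step[frame] = step;
    ++frame;
    return tot;
  };

  auto record_dense = [&](int step) {
    if (np > 0)
      for (int p = 0; p < np; ++p)
        for (int c = 0; c < d; ++c)
          probe(step, p + np * c) = x[(probe_nodes[p] - 1) + (size_t)c * n];
    if (ng > 0) {
      node_energies_one(x.data(), v.data(), m, n, d, INTEGER(ei), INTEGER(ej),
                        REAL(r0), ne, k2, k4, boxp, has_box, en.data());
      double g = 0.0;
      for (int k = 0; k < ng; ++k) g += en[energy_group[k] - 1];
      group_en[step] = g;
    }
  };

  e_init = record_frame(0);
  record_dense(0);

  for (int step = 1; step <= n_steps; ++step) {
    for (int c = 0; c < d; ++c)
      for (int i = 0; i < n; ++i) {
        size_t k = i + (size_t)c * n;
        v[k] += 0.5 * dt * f[k] / m[i];
        x[k] += dt * v[k];
      }
    compute_forces(x.data(), n, d, INTEGER(ei), INTEGER(ej), REAL(r0), ne, k2, k4,
                   boxp, has_box, f.data());
    for (int c = 0; c < d; ++c)
      for (int i = 0; i < n; ++i) {
        size_t k = i + (size_t)c * n;
        v[k] += 0.5 * dt * f[k] / m[i];
      }
    record_dense(step);
    if (step % stride == 0) {
      double tot = record_frame(step);
      if (max_drift > 0.0 && e_init > 0.0 &&
          std::abs(tot - e_init) > max_drift * e_init) {
        aborted_at = step;
        break;
      }
    }
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  pos.attr("dim") = IntegerVector::create(n_frames, n, d);
  velout.attr("dim") = IntegerVector::create(n_frames, n, d);

  return List::create(
      _["frame_step"] = head(frame_step, frame), _["positions"] = pos,
      _["velocities"] = velout, _["node_energy"] = node_en,
      _["total_energy"] = head(total_en, frame), _["probe"] = probe,
      _["group_energy"] = group_en, _["n_frames"] = frame,
      _["aborted_at"] = aborted_at);
}
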