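#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// All state matrices arrive column-major from R; copy to row-major for
// cache-friendly pairwise scans. Indices returned to R are 1-based.

static std::vector<double> row_major(const NumericMatrix& m) {
  const int n = m.nrow(), d = m.ncol();
  std::vector<double> out((size_t)n * d);
  for (int j = 0; j < d; ++j)
    for (int i = 0; i < n; ++i)
      out[(size_t)i * d + j] = m(i, j);
  return out;
}

static inline double pt_dist(const double* a, const double* b, int d, bool maxnorm) {
  if (maxnorm) {
    double m = 0.0;
    for (int c = 0; c < d; ++c) {
      double v = std::fabs(a[c] - b[c]);
      if (v > m) m = v;
    }
    return m;
  }
  double s = 0.0;
  for (int c = 0; c < d; ++c) {
    double v = a[c] - b[c];
    s += v * v;
  }
  return std::sqrt(s);
}

// Exact fixed-radius neighbor lists with Theiler exclusion.
// [[Rcpp::export]]
List nn_radius_cpp(NumericMatrix states, double eps, int theiler, bool maxnorm) {
  const int n = states.nrow(), d = states.ncol();
  std::vector<double> X = row_major(states);
  std::vector< std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + theiler + 1; j < n; ++j) {
      double dist = pt_dist(&X[(size_t)i * d], &X[(size_t)j * d], d, maxnorm);
      if (dist <= eps) {
        nb[i].push_back(j + 1);
        nb[j].push_back(i + 1);
      }
    }
  }
  List out(n);
  for (int i = 0; i < n; ++i) {
    std::sort(nb[i].begin(), nb[i].end());
    out[i] = IntegerVector(nb[i].begin(), nb[i].end());
  }
  return out;
}

// Exact k-nearest neighbors (indices + distances), Theiler exclusion.
// Fewer than k admissible points -> NA padding.
// [[Rcpp::export]]
List nn_knn_cpp(NumericMatrix states, int k, int theiler, bool maxnorm) {
  const int n = states.nrow(), d = states.ncol();
  std::vector<double> X = row_major(states);
  IntegerMatrix idx(n, k);
  NumericMatrix dst(n, k);
  std::vector< std::pair<double, int> > cand;
  cand.reserve(n);
  for (int i = 0; i < n; ++i) {
    cand.clear();
    for (int j = 0; j < n; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      cand.push_back(std::make_pair(
        pt_dist(&X[(size_t)i * d], &X[(size_t)j * d], d, maxnorm), j + 1));
    }
    int m = std::min((int)cand.size(), k);
    std::partial_sort(cand.begin(), cand.begin() + m, cand.end());
    for (int q = 0; q < k; ++q) {
      if (q < m) { idx(i, q) = cand[q].second; dst(i, q) = cand[q].first; }
      else { idx(i, q) = NA_INTEGER; dst(i, q) = NA_REAL; }
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dst);
}

// Kennel false-nearest-neighbor counts. emb has d+1 columns: column 0 is the
// extra coordinate gained at dimension d+1, columns 1..d are the dim-d state.
// Distances at or below dist_floor are duplicates up to rounding (exactly
// periodic signals produce them); the ratio test is meaningless there, so
// such a neighbor is false only if the extra coordinate separates the pair
// by more than the floor.
// [[Rcpp::export]]
NumericVector fnn_cpp(NumericMatrix emb, double Rtol, double AtolSD,
                      int theiler, bool maxnorm, double dist_floor) {
  const int n = emb.nrow(), dd = emb.ncol(), d = dd - 1;
  std::vector<double> X = row_major(emb);
  double nvalid = 0.0, nfalse = 0.0;
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int jbest = -1;
    for (int j = 0; j < n; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      double dist = pt_dist(&X[(size_t)i * dd + 1], &X[(size_t)j * dd + 1], d, maxnorm);
      if (dist < best) { best = dist; jbest = j; }
    }
    if (jbest < 0) continue;
    nvalid += 1.0;
    double extra = std::fabs(X[(size_t)i * dd] - X[(size_t)jbest * dd]);
    bool isfalse;
    if (best > dist_floor) {
      double dd1 = maxnorm ? std::max(best, extra)
                           : std::sqrt(best * best + extra * extra);
      isfalse = (extra / best > Rtol) || (dd1 > AtolSD);
    } else {
      isfalse = (extra > dist_floor);
    }
    if (isfalse) nfalse += 1.0;
  }
  return NumericVector::create(nvalid, nfalse);
}

// Grassberger-Procaccia pair counts over a sorted epsilon grid.
// Returns cumulative counts (pairs with dist <= eps) and admissible pair count.
// [[Rcpp::export]]
List corr_sum_cpp(NumericMatrix states, NumericVector eps_sorted,
                  int theiler, bool maxnorm) {
  const int n = states.nrow(), d = states.ncol(), ne = eps_sorted.size();
  std::vector<double> X = row_major(states);
  std::vector<double> eps(eps_sorted.begin(), eps_sorted.end());
  std::vector<double> bucket(ne, 0.0);
  double npairs = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + theiler + 1; j < n; ++j) {
      npairs += 1.0;
      double dist = pt_dist(&X[(size_t)i * d], &X[(size_t)j * d], d, maxnorm);
      std::vector<double>::iterator it =
        std::lower_bound(eps.begin(), eps.end(), dist);
      if (it != eps.end()) bucket[it - eps.begin()] += 1.0;
    }
  }
  NumericVector counts(ne);
  double acc = 0.0;
  for (int e = 0; e < ne; ++e) { acc += bucket[e]; counts[e] = acc; }
  return List::create(_["counts"] = counts, _["npairs"] = npairs);
}

// Divergence curves for the largest Lyapunov exponent.
// kantz: delta(dt) = < ln( mean_{j in U_eps(i)} dist(x_{i+dt}, x_{j+dt}) ) >_i
// rosenstein: delta(dt) = < ln dist(x_{i+dt}, x_{nn(i)+dt}) >_i
// When scalar_dist is true, the distance after dt steps is measured on the
// newest (scalar) coordinate only, so the divergence is not smeared over the
// embedding window; the neighbor search always uses the full state.
// [[Rcpp::export]]
List lyap_cpp(NumericMatrix states, bool kantz, double eps, int iters,
              int theiler, bool maxnorm, bool scalar_dist) {
  const int n = states.nrow(), d = states.ncol();
  std::vector<double> X = row_major(states);
  const int nref = n - iters;
  std::vector<double> sums(iters + 1, 0.0);
  std::vector<double> cnts(iters + 1, 0.0);
  int used = 0;
  std::vector<int> nb;
  for (int i = 0; i < nref; ++i) {
    nb.clear();
    if (kantz) {
      for (int j = 0; j < nref; ++j) {
        if (std::abs(i - j) <= theiler) continue;
        if (pt_dist(&X[(size_t)i * d], &X[(size_t)j * d], d, maxnorm) <= eps)
          nb.push_back(j);
      }
    } else {
      double best = R_PosInf;
      int jbest = -1;
      for (int j = 0; j < nref; ++j) {
        if (std::abs(i - j) <= theiler) continue;
        double dist = pt_dist(&X[(size_t)i * d], &X[(size_t)j * d], d, maxnorm);
        if (dist < best) { best = dist; jbest = j; }
      }
      if (jbest >= 0) nb.push_back(jbest);
    }
    if (nb.empty()) continue;
    ++used;
    for (int dt = 0; dt <= iters; ++dt) {
      double acc = 0.0;
      for (size_t q = 0; q < nb.size(); ++q) {
        if (scalar_dist)
          acc += std::fabs(X[(size_t)(i + dt) * d + (d - 1)] -
                           X[(size_t)(nb[q] + dt) * d + (d - 1)]);
        else
          acc += pt_dist(&X[(size_t)(i + dt) * d], &X[(size_t)(nb[q] + dt) * d],
                         d, maxnorm);
      }
      acc /= (double)nb.size();
      if (acc > 0.0) { sums[dt] += std::log(acc); cnts[dt] += 1.0; }
    }
  }
  NumericVector delta(iters + 1);
  for (int dt = 0; dt <= iters; ++dt)
    delta[dt] = cnts[dt] > 0 ? sums[dt] / cnts[dt] : NA_REAL;
  return List::create(_["delta"] = delta, _["n_ref"] = used);
}

// Ragwitz local-constant predictor RMSPE over a (dim, tau) grid.
// Prediction of x[t+h] = mean over the k nearest neighbors' successors.
// States follow the backward convention: a state's index is its last sample.
// [[Rcpp::export]]
NumericMatrix ragwitz_cpp(NumericVector x, IntegerVector dims, IntegerVector taus,
                          int k, int horizon, int theiler) {
  const int n = x.size();
  NumericMatrix rmspe(dims.size(), taus.size());
  std::vector< std::pair<double, int> > cand;
  for (int di = 0; di < dims.size(); ++di) {
    int d = dims[di];
    for (int ti = 0; ti < taus.size(); ++ti) {
      int tau = taus[ti];
      int t0 = (d - 1) * tau;              // first valid state end index
      int tmaxq = n - 1 - horizon;         // last query with a target
      if (t0 > tmaxq) { rmspe(di, ti) = NA_REAL; continue; }
      double err = 0.0;
      int nq = 0;
      for (int t = t0; t <= tmaxq; ++t) {
        cand.clear();
        for (int s = t0; s <= tmaxq; ++s) {
          if (std::abs(t - s) <= theiler) continue;
          double dist = 0.0;
          for (int c = 0; c < d; ++c) {
            double v = std::fabs(x[t - c * tau] - x[s - c * tau]);
            if (v > dist) dist = v;
          }
          cand.push_back(std::make_pair(dist, s));
        }
        if (cand.empty()) continue;
        int m = std::min((int)cand.size(), k);
        std::partial_sort(cand.begin(), cand.begin() + m, cand.end());
        double pred = 0.0;
        for (int q = 0; q < m; ++q) pred += x[cand[q].second + horizon];
        pred /= (double)m;
        double e = pred - x[t + horizon];
        err += e * e;
        ++nq;
      }
      rmspe(di, ti) = nq > 0 ? std::sqrt(err / nq) : NA_REAL;
    }
  }
  return rmspe;
}

// Fixed-radius local-constant prediction of the next scalar at the given
// horizon for selected query states (1-based row indices). Empty
// neighborhoods are skipped and counted.
// [[Rcpp::export]]
List predict_radius_cpp(NumericMatrix states, NumericVector x, int dim, int tau,
                        double eps, int horizon, IntegerVector queries,
                        int theiler, bool maxnorm) {
  const int n = states.nrow(), d = states.ncol();
  std::vector<double> X = row_major(states);
  const int off = (dim - 1) * tau;         // state row r ends at sample r+off
  const int nmax = x.size();
  NumericVector pred(queries.size(), NA_REAL);
  NumericVector truth(queries.size(), NA_REAL);
  int skipped = 0;
  double err = 0.0;
  int nq = 0;
  for (int qi = 0; qi < queries.size(); ++qi) {
    int i = queries[qi] - 1;
    if (i + off + horizon >= nmax) { ++skipped; continue; }
    double acc = 0.0;
    int cnt = 0;
    for (int j = 0; j < n; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      if (j + off + horizon >= nmax) continue;
      if (pt_dist(&X[(size_t)i * d], &X[(size_t)j * d], d, maxnorm) <= eps) {
        acc += x[j + off + horizon];
        ++cnt;
      }
    }
    if (cnt == 0) { ++skipped; continue; }
    pred[qi] = acc / cnt;
    truth[qi] = x[i + off + horizon];
    double e = pred[qi] - truth[qi];
    err += e * e;
    ++nq;
  }
  double rmspe = nq > 0 ? std::sqrt(err / nq) : NA_REAL;
  return List::create(_["pred"] = pred, _["truth"] = truth,
                      _["rmspe"] = rmspe, _["n_skipped"] = skipped);
}

// Recurrence-time and recurrence-amplitude extraction per reference column,
// scanned forward in time, over a grid of absolute radii. A recurrence time is
// the length of a run of non-recurrent samples between leaving and re-entering
// the eps-neighborhood of the reference state; samples within the Theiler
// window belong to the initial sojourn. Amplitude bookkeeping tracks
// per-coordinate extremes over the excursion (including the bounding
// recurrent samples) and records the box diameter (exact for the maximum
// norm). Returns, per epsilon, counts R(T) and diameter sums for
// T in [tmin, tmax].
// [[Rcpp::export]]
List rectimes_cpp(NumericMatrix states, NumericVector eps_vec, int tmin,
                  int tmax, int theiler, bool maxnorm) {
  const int n = states.nrow(), d = states.ncol(), ne = eps_vec.size();
  std::vector<double> X = row_major(states);
  const int tlen = tmax - tmin + 1;
  NumericMatrix counts(tlen, ne);
  NumericMatrix ampsum(tlen, ne);
  std::vector<double> dist(n, 0.0);
  std::vector<double> lo(d), hi(d);
  for (int i = 0; i < n - 1; ++i) {
    const double* xi = &X[(size_t)i * d];
    int jstart = i + theiler + 1;
    if (jstart >= n) continue;
    for (int j = jstart; j < n; ++j)
      dist[j] = pt_dist(xi, &X[(size_t)j * d], d, maxnorm);
    for (int e = 0; e < ne; ++e) {
      double eps = eps_vec[e];
      int state = 0;                        // 0 = sojourn, 1 = excursion
      int gap = 0;
      for (int j = jstart; j < n; ++j) {
        bool rec = dist[j] <= eps;
        if (state == 0) {
          if (!rec) {
            state = 1;
            gap = 1;
            const double* prev = (j - 1 >= jstart) ? &X[(size_t)(j - 1) * d] : xi;
            for (int c = 0; c < d; ++c) {
              lo[c] = std::min(prev[c], X[(size_t)j * d + c]);
              hi[c] = std::max(prev[c], X[(size_t)j * d + c]);
            }
          }
        } else {
          const double* xj = &X[(size_t)j * d];
          for (int c = 0; c < d; ++c) {
            if (xj[c] < lo[c]) lo[c] = xj[c];
            if (xj[c] > hi[c]) hi[c] = xj[c];
          }
          if (rec) {
            if (gap >= tmin && gap <= tmax) {
              double diam;
              if (maxnorm) {
                diam = 0.0;
                for (int c = 0; c < d; ++c) diam = std::max(diam, hi[c] - lo[c]);
              } else {
                diam = 0.0;
                for (int c = 0; c < d; ++c) {
                  double v = hi[c] - lo[c];
                  diam += v * v;
                }
                diam = std::sqrt(diam);
              }
              counts(gap - tmin, e) += 1.0;
              ampsum(gap - tmin, e) += diam;
            }
            state = 0;
          } else {
            ++gap;
          }
        }
      }
    }
  }
  return List::create(_["counts"] = counts, _["ampsum"] = ampsum);
}

// Kozachenko-Leonenko support: distance to the k-th nearest neighbor
// (self excluded) for each point.
// [[Rcpp::export]]
NumericVector knn_dist_cpp(NumericMatrix X_, int k, bool maxnorm) {
  const int n = X_.nrow(), d = X_.ncol();
  std::vector<double> X = row_major(X_);
  NumericVector out(n);
  std::vector<double> dd(n);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      dd[m++] = pt_dist(&X[(size_t)i * d], &X[(size_t)j * d], d, maxnorm);
    }
    std::nth_element(dd.begin(), dd.begin() + (k - 1), dd.begin() + m);
    out[i] = dd[k - 1];
  }
  return out;
}

// Kraskov-Stoegbauer-Grassberger (algorithm 1) marginal counts between two
// variable blocks A (n x da) and B (n x db): for each point, the strict count
// of points whose block-wise max-norm distance is below the k-th nearest
// joint-space (max-norm) distance.
// [[Rcpp::export]]
List ksg_counts_cpp(NumericMatrix A_, NumericMatrix B_, int k) {
  const int n = A_.nrow();
  const int da = A_.ncol(), db = B_.ncol();
  std::vector<double> A = row_major(A_);
  std::vector<double> B = row_major(B_);
  NumericVector epsk(n);
  std::vector<double> dd(n);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dj = std::max(
        pt_dist(&A[(size_t)i * da], &A[(size_t)j * da], da, true),
        pt_dist(&B[(size_t)i * db], &B[(size_t)j * db], db, true));
      dd[m++] = dj;
    }
    std::nth_element(dd.begin(), dd.begin() + (k - 1), dd.begin() + m);
    epsk[i] = dd[k - 1];
  }
  IntegerVector nA(n), nB(n);
  for (int i = 0; i < n; ++i) {
    int ca = 0, cb = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (pt_dist(&A[(size_t)i * da], &A[(size_t)j * da], da, true) < epsk[i]) ++ca;
      if (pt_dist(&B[(size_t)i * db], &B[(size_t)j * db], db, true) < epsk[i]) ++cb;
    }
    nA[i] = ca;
    nB[i] = cb;
  }
  return List::create(_["eps"] = epsk, _["nx"] = nA, _["ny"] = nB);
}
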