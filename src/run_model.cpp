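#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Weighted pick by cumulative-sum inversion over the distance kernel
// w_k = max(|focal - cand_k|, floor)^(-gamma).  Consumes exactly one
// uniform draw.  Accumulation is plain double addition so that pure-R
// oracles looping the same way see bit-identical cut points.
static int pick_biased(double focal, const double *cand, const int *idx,
                       int n_cand, double gamma, double floor_d) {
  std::vector<double> w(n_cand);
  double total = 0.0;
  for (int k = 0; k < n_cand; ++k) {
    double d = std::fabs(focal - cand[idx ? idx[k] : k]);
    if (d < floor_d) d = floor_d;
    w[k] = std::pow(d, -gamma);
    total += w[k];
  }
  double cut = unif_rand() * total;
  double acc = 0.0;
  for (int k = 0; k < n_cand; ++k) {
    acc += w[k];
    if (cut < acc) return k;
  }
  return n_cand - 1; // guard against terminal rounding
}

// Gap-threshold cluster labels: sort opinions, start a new cluster when a
// consecutive gap strictly exceeds gap_threshold; labels are canonical
// (ascending cluster mean), so label-vector equality is partition equality.
static void cluster_labels(const std::vector<double> &x, double gap,
                           std::vector<int> &labels,
                           std::vector<int> &ord) {
  int n = (int)x.size();
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&x](int a, int b) { return x[a] < x[b]; });
  int c = 0;
  labels[ord[0]] = 0;
  for (int i = 1; i < n; ++i) {
    if (x[ord[i]] - x[ord[i - 1]] > gap) ++c;
    labels[ord[i]] = c;
  }
}

// [[Rcpp::export(name = ".run_model_cpp")]]
List run_model_cpp(NumericVector opinions0,
                   NumericVector epsilon,
                   bool heterogeneous,
                   double gamma,
                   double mu,
                   double p_m,
                   NumericVector media,
                   Nullable<List> adjacency,
                   double distance_floor,
                   double max_iterations,
                   int stop_kind,           // 0 cluster_equilibrium, 1 max_change
                   int check_stride,
                   int patience,
                   double change_threshold,
                   double gap_threshold,
                   int snapshot_stride) {
  const int n = opinions0.size();
  const int m = media.size();
  std::vector<double> x(opinions0.begin(), opinions0.end());
  std::vector<double> eps(n);
  if (heterogeneous) {
    for (int i = 0; i < n; ++i) eps[i] = epsilon[i];
  } else {
    for (int i = 0; i < n; ++i) eps[i] = epsilon[0];
  }
  const bool mean_field = adjacency.isNull();
  std::vector<std::vector<int>> adj;
  if (!mean_field) {
    List al(adjacency);
    adj.resize(n);
    for (int i = 0; i < n; ++i) {
      IntegerVector nb = al[i];
      adj[i].assign(nb.begin(), nb.end()); // 0-based
    }
  }
  // mean-field neighbour index buffer (all k != i)
  std::vector<int> mf_idx(std::max(n - 1, 0));

  const bool media_active = (p_m > 0.0) && (m >= 1);

  std::vector<int> labels(n), prev_labels(n), ord(n);
  bool have_prev = false;
  int identical_checks = 0;
  long long below_count = 0;

  std::vector<double> snap_times;
  std::vector<std::vector<double>> snaps;

  long long cap = (long long)max_iterations;
  long long t = 0;
  std::string stop_reason = "iteration_cap";
  bool converged = false;

  while (t < cap) {
    // (1) target agent, uniform
    int i = (int)(unif_rand() * n);
    if (i >= n) i = n - 1;

    // (2) peer among i's neighbours, kernel-weighted
    int j;
    if (mean_field) {
      int p = 0;
      for (int k = 0; k < n; ++k)
        if (k != i) mf_idx[p++] = k;
      int pick = pick_biased(x[i], x.data(), mf_idx.data(), n - 1,
                             gamma, distance_floor);
      j = mf_idx[pick];
    } else {
      const std::vector<int> &nb = adj[i];
      if (nb.empty())
        stop("agent %d has no neighbours", i + 1);
      int pick = pick_biased(x[i], x.data(), nb.data(), (int)nb.size(),
                             gamma, distance_floor);
      j = nb[pick];
    }

    // (3) pair update (rule in force)
    double xi = x[i], xj = x[j];
    double d = std::fabs(xi - xj);
    double step_change = 0.0;
    if (heterogeneous) {
      if (d < eps[i]) x[i] = xi + mu * (xj - xi);
      if (d < eps[j]) x[j] = xj + mu * (xi - xj);
    } else {
      if (d <= eps[i]) {
        x[i] = xi + mu * (xj - xi);
        x[j] = xj + mu * (xi - xj);
      }
    }
    step_change = std::max(std::fabs(x[i] - xi), std::fabs(x[j] - xj));

    // (4) media interaction of the target agent with probability p_m
    if (media_active) {
      double u = unif_rand();
      if (u < p_m) {
        int mk = pick_biased(x[i], REAL(media), nullptr, m,
                             gamma, distance_floor);
        double xm = media[mk];
        double dm = std::fabs(x[i] - xm);
        bool gate = heterogeneous ? (dm < eps[i]) : (dm <= eps[i]);
        if (gate) {
          double before = x[i];
          x[i] = x[i] + mu * (xm - x[i]);
          step_change = std::max(step_change, std::fabs(x[i] - before));
        }
      }
    }

    ++t;

    if (snapshot_stride > 0 && (t % snapshot_stride == 0)) {
      snap_times.push_back((double)t);
      snaps.push_back(x);
    }

    // (5) stopping rules
    if (stop_kind == 0) {
      if (t % check_stride == 0) {
        cluster_labels(x, gap_threshold, labels, ord);
        if (have_prev && labels == prev_labels)
          ++identical_checks;
        else
          identical_checks = 1;
        prev_labels = labels;
        have_prev = true;
        if (identical_checks >= patience) {
          stop_reason = "equilibrium";
          converged = true;
          break;
        }
      }
    } else {
      if (step_change < change_threshold)
        ++below_count;
      else
        below_count = 0;
      if (below_count >= patience) {
        stop_reason = "max_change";
        converged = true;
        break;
      }
    }
  }

  List snapshots = R_NilValue;
  if (snapshot_stride > 0) {
    int ns = (int)snaps.size();
    List sl(ns);
    NumericVector st(ns);
    for (int s = 0; s < ns; ++s) {
      st[s] = snap_times[s];
      sl[s] = NumericVector(snaps[s].begin(), snaps[s].end());
    }
    snapshots = List::create(_["time"] = st, _["opinions"] = sl);
  }

  return List::create(
      _["opinions"] = NumericVector(x.begin(), x.end()),
      _["iterations"] = (double)t,
      _["stop_reason"] = stop_reason,
      _["converged"] = converged,
      _["snapshots"] = snapshots);
}
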