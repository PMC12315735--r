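#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Stamp one experiment's modeled-activation (MA) map: at every voxel the
// maximum per-focus Gaussian stencil value (non-additive max rule).
// foci: F x 3 integer matrix of 0-based voxel indices (may lie outside the
// grid; their stencil is clipped at the bounds). offsets: K x 3 integer
// voxel offsets of the truncated stencil, values: the K stencil values.
// [[Rcpp::export]]
NumericVector ma_map_cpp(IntegerVector dim, IntegerMatrix foci,
                         IntegerMatrix offsets, NumericVector values) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(nx * ny * nz);
  const int F = foci.nrow(), K = offsets.nrow();
  for (int f = 0; f < F; ++f) {
    const int fx = foci(f, 0), fy = foci(f, 1), fz = foci(f, 2);
    for (int k = 0; k < K; ++k) {
      const int x = fx + offsets(k, 0);
      if (x < 0 || x >= nx) continue;
      const int y = fy + offsets(k, 1);
      if (y < 0 || y >= ny) continue;
      const int z = fz + offsets(k, 2);
      if (z < 0 || z >= nz) continue;
      const R_xlen_t idx = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      if (values[k] > out[idx]) out[idx] = values[k];
    }
  }
  return out;
}

// Full ALE map for a list of experiments: ALE = 1 - prod_i (1 - MA_i).
// foci_list[i]: 0-based voxel index matrix of experiment i;
// stencil_list[i]: list(offsets = K x 3 int, values = numeric K).
// Experiments are combined in list order.
// [[Rcpp::export]]
NumericVector ale_map_cpp(IntegerVector dim, List foci_list, List stencil_list) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t V = (R_xlen_t)nx * ny * nz;
  NumericVector acc(V, 1.0);
  std::vector<double> ma(V);
  const int E = foci_list.size();
  for (int e = 0; e < E; ++e) {
    std::fill(ma.begin(), ma.end(), 0.0);
    IntegerMatrix foci = foci_list[e];
    List st = stencil_list[e];
    IntegerMatrix offsets = st["offsets"];
    NumericVector values = st["values"];
    const int F = foci.nrow(), K = offsets.nrow();
    for (int f = 0; f < F; ++f) {
      const int fx = foci(f, 0), fy = foci(f, 1), fz = foci(f, 2);
      for (int k = 0; k < K; ++k) {
        const int x = fx + offsets(k, 0);
        if (x < 0 || x >= nx) continue;
        const int y = fy + offsets(k, 1);
        if (y < 0 || y >= ny) continue;
        const int z = fz + offsets(k, 2);
        if (z < 0 || z >= nz) continue;
        const R_xlen_t idx = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        if (values[k] > ma[idx]) ma[idx] = values[k];
      }
    }
    for (R_xlen_t v = 0; v < V; ++v) acc[v] *= (1.0 - ma[v]);
  }
  for (R_xlen_t v = 0; v < V; ++v) acc[v] = 1.0 - acc[v];
  return acc;
}

// 26-connected component labelling of a logical volume. Labels are assigned
// in order of first encounter along the linear (column-major) scan, starting
// at 1; background is 0.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t V = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(V, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;
  for (R_xlen_t s = 0; s < V; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++next_label;
    labels[s] = next_label;
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int cx = cur % nx;
      const int cy = (cur / nx) % ny;
      const int cz = cur / ((R_xlen_t)nx * ny);
      for (int dz = -1; dz <= 1; ++dz) {
        const int z = cz + dz;
        if (z < 0 || z >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int y = cy + dy;
          if (y < 0 || y >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            const int x = cx + dx;
            if (x < 0 || x >= nx) continue;
            const R_xlen_t nb = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
            if (mask[nb] && labels[nb] == 0) {
              labels[nb] = next_label;
              stack.push_back(nb);
            }
          }
        }
      }
    }
  }
  return labels;
}

// Maximum 26-connected cluster size of a logical volume (0 if empty).
// [[Rcpp::export]]
int max_cluster_size_cpp(LogicalVector mask, IntegerVector dim) {
  IntegerVector labels = label_components_cpp(mask, dim);
  int nlab = 0;
  for (R_xlen_t i = 0; i < labels.size(); ++i)
    if (labels[i] > nlab) nlab = labels[i];
  if (nlab == 0) return 0;
  std::vector<int> sizes(nlab, 0);
  for (R_xlen_t i = 0; i < labels.size(); ++i)
    if (labels[i] > 0) ++sizes[labels[i] - 1];
  int mx = 0;
  for (int j = 0; j < nlab; ++j) if (sizes[j] > mx) mx = sizes[j];
  return mx;
}

// One step of the non-linear histogram combination for the analytic ALE null:
// deposit, for every pair of occupied bins (a from the accumulated null, m
// from the next experiment's MA histogram), the probability mass product at
// the nearest bin of 1 - (1 - a)(1 - m). Bin i represents ALE value i * bw;
// nearest-bin deposition keeps the combined null unbiased (flooring would
// shift it down by up to one bin per combination step). m_idx are 0-based
// occupied bin indices of the experiment's histogram.
// [[Rcpp::export]]
NumericVector combine_null_cpp(NumericVector a_probs, IntegerVector m_idx,
                               NumericVector m_probs, double bw) {
  const int B = a_probs.size();
  NumericVector out(B);
  for (int i = 0; i < B; ++i) {
    const double pa = a_probs[i];
    if (pa == 0.0) continue;
    const double ai = i * bw;
    for (int j = 0; j < m_idx.size(); ++j) {
      const double mj = m_idx[j] * bw;
      const double val = 1.0 - (1.0 - ai) * (1.0 - mj);
      int k = (int)std::floor(val / bw + 0.5);
      if (k >= B) k = B - 1;
      out[k] += pa * m_probs[j];
    }
  }
  return out;
}

// Permutation null of maximum cluster sizes for cluster-level FWE. Every
// focus is relocated to a uniformly random in-mask voxel; positions holds,
// per permutation (row), 0-based row indices into mask_vox for all foci of
// all experiments laid out consecutively (experiment e owns n_foci[e] of
// them). The ALE map of each permutation is thresholded at ale >= cutoff
// within the mask and the maximum 26-connected cluster size is recorded.
// [[Rcpp::export]]
IntegerVector cfwe_null_sizes_cpp(IntegerVector dim, IntegerMatrix mask_vox,
                                  IntegerMatrix positions,
                                  IntegerVector n_foci, List stencil_list,
                                  double cutoff, LogicalVector mask) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t V = (R_xlen_t)nx * ny * nz;
  const int E = n_foci.size();
  const int n_perm = positions.nrow();
  std::vector<double> acc(V), ma(V);
  std::vector<int> labels(V);
  std::vector<R_xlen_t> stack;
  // unpack stencils once
  std::vector<IntegerMatrix> offs(E);
  std::vector<NumericVector> vals(E);
  for (int e = 0; e < E; ++e) {
    List st = stencil_list[e];
    offs[e] = as<IntegerMatrix>(st["offsets"]);
    vals[e] = as<NumericVector>(st["values"]);
  }
  IntegerVector out(n_perm);
  for (int p = 0; p < n_perm; ++p) {
    std::fill(acc.begin(), acc.end(), 1.0);
    int col = 0;
    for (int e = 0; e < E; ++e) {
      std::fill(ma.begin(), ma.end(), 0.0);
      const IntegerMatrix& of = offs[e];
      const NumericVector& va = vals[e];
      const int K = of.nrow();
      for (int f = 0; f < n_foci[e]; ++f, ++col) {
        const int row = positions(p, col);
        const int fx = mask_vox(row, 0), fy = mask_vox(row, 1),
                  fz = mask_vox(row, 2);
        for (int k = 0; k < K; ++k) {
          const int x = fx + of(k, 0);
          if (x < 0 || x >= nx) continue;
          const int y = fy + of(k, 1);
          if (y < 0 || y >= ny) continue;
          const int z = fz + of(k, 2);
          if (z < 0 || z >= nz) continue;
          const R_xlen_t idx = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
          if (va[k] > ma[idx]) ma[idx] = va[k];
        }
      }
      for (R_xlen_t v = 0; v < V; ++v) acc[v] *= (1.0 - ma[v]);
    }
    // threshold (ALE = 1 - acc) and find the max 26-connected cluster
    std::fill(labels.begin(), labels.end(), 0);
    int best = 0;
    for (R_xlen_t s = 0; s < V; ++s) {
      if (labels[s] != 0 || !mask[s] || 1.0 - acc[s] < cutoff) continue;
      int size = 0;
      labels[s] = 1;
      stack.push_back(s);
      while (!stack.empty()) {
        const R_xlen_t cur = stack.back();
        stack.pop_back();
        ++size;
        const int cx = cur % nx;
        const int cy = (cur / nx) % ny;
        const int cz = cur / ((R_xlen_t)nx * ny);
        for (int dz = -1; dz <= 1; ++dz) {
          const int z = cz + dz;
          if (z < 0 || z >= nz) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            const int y = cy + dy;
            if (y < 0 || y >= ny) continue;
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              const int x = cx + dx;
              if (x < 0 || x >= nx) continue;
              const R_xlen_t nb = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
              if (labels[nb] == 0 && mask[nb] && 1.0 - acc[nb] >= cutoff) {
                labels[nb] = 1;
                stack.push_back(nb);
              }
            }
          }
        }
      }
      if (size > best) best = size;
    }
    out[p] = best;
  }
  return out;
}

// Voxel-wise ALE difference between two groups of experiments, computed from
// the matrix Q of per-experiment (1 - MA) columns:
// diff = prod_{e in B} Q[, e] - prod_{e in A} Q[, e]  ( = ALE_A - ALE_B ).
// idx_a / idx_b: 0-based column indices; products accumulate in index order.
// [[Rcpp::export]]
NumericVector group_diff_cpp(NumericMatrix Q, IntegerVector idx_a,
                             IntegerVector idx_b) {
  const R_xlen_t V = Q.nrow();
  NumericVector pa(V, 1.0), pb(V, 1.0);
  for (int j = 0; j < idx_a.size(); ++j) {
    NumericMatrix::Column col = Q(_, idx_a[j]);
    for (R_xlen_t v = 0; v < V; ++v) pa[v] *= col[v];
  }
  for (int j = 0; j < idx_b.size(); ++j) {
    NumericMatrix::Column col = Q(_, idx_b[j]);
    for (R_xlen_t v = 0; v < V; ++v) pb[v] *= col[v];
  }
  NumericVector out(V);
  for (R_xlen_t v = 0; v < V; ++v) out[v] = pb[v] - pa[v];
  return out;
}

// Pool-shuffle-split permutation counts for the meta-analytic contrast.
// Q: V x E matrix of (1 - MA) for the pooled experiments. splits: n_perm x nA
// matrix; row p holds the 0-based pooled column indices forming pseudo-group A
// in permutation p (the complement forms pseudo-group B). Returns, per voxel,
// the number of permutations whose pseudo ALE difference is >= obs_diff.
// [[Rcpp::export]]
IntegerVector contrast_perm_counts_cpp(NumericMatrix Q, IntegerMatrix splits,
                                       NumericVector obs_diff) {
  const R_xlen_t V = Q.nrow();
  const int E = Q.ncol();
  const int n_perm = splits.nrow(), nA = splits.ncol();
  IntegerVector counts(V, 0);
  std::vector<double> pa(V), pb(V);
  std::vector<bool> in_a(E);
  for (int p = 0; p < n_perm; ++p) {
    std::fill(pa.begin(), pa.end(), 1.0);
    std::fill(pb.begin(), pb.end(), 1.0);
    std::fill(in_a.begin(), in_a.end(), false);
    for (int j = 0; j < nA; ++j) in_a[splits(p, j)] = true;
    for (int e = 0; e < E; ++e) {
      NumericMatrix::Column col = Q(_, e);
      if (in_a[e]) {
        for (R_xlen_t v = 0; v < V; ++v) pa[v] *= col[v];
      } else {
        for (R_xlen_t v = 0; v < V; ++v) pb[v] *= col[v];
      }
    }
    for (R_xlen_t v = 0; v < V; ++v)
      if (pb[v] - pa[v] >= obs_diff[v]) ++counts[v];
  }
  return counts;
}
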