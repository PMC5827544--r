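// Energy/mass transfer scatter-gather kernels.
//
// All three layouts evaluate the identical contribution arithmetic
//   w = ((w1 * w2) * w3) * E_T
// per (record, overlap voxel) pair, where the per-axis factor is the base
// weight w0 or its complement 1 - w0 depending on which member of the
// overlap ensemble is addressed; only the accumulation order differs:
//   push    -- records in ascending source-voxel order, 8-voxel scatter each
//              (fixed pattern order: base, +x, +y, +xy, +z, +xz, +yz, +xyz);
//   pull    -- reference voxels in ascending order, gathering from records
//              keyed to the 27-neighbourhood (ascending key, then source);
//   unified -- reference voxels ascending, gathering from records keyed to
//              the 8 base-corner predecessors with branch-free w0/w+ factors.
// The pull/unified gathers compute every reference voxel independently, so
// the result is bitwise identical for any z-slab decomposition and the
// per-voxel accumulation is race-free by construction.
//
// Accumulation is templated on the arithmetic type: double (default) or
// float (to study the reordering deviations of a single-precision
// implementation).

#include <Rcpp.h>
#include <vector>
#include <cstdint>

using namespace Rcpp;

static const double DEQ = 1.0 / 127.0;

template <typename Real>
static NumericVector to_numeric(const std::vector<Real>& acc) {
  NumericVector out(acc.size());
  for (size_t i = 0; i < acc.size(); ++i) out[i] = (double)acc[i];
  return out;
}

// Per-axis base weight from a dequantized offset: base voxel is the nearest
// voxel when dx >= 0, its lower neighbour when dx < 0.
template <typename Real>
static inline void axis_base_weight(double dxq, Real& w0, int& boff) {
  if (dxq < 0) { w0 = (Real)(-dxq); boff = -1; }
  else         { w0 = (Real)(1.0 - dxq); boff = 0; }
}

template <typename Real>
static NumericVector map_push_impl(const IntegerVector& target_index,
                                   const IntegerMatrix& dXb,
                                   const IntegerVector& is_used,
                                   const NumericVector& et,
                                   const IntegerVector& ref_shape) {
  const int s1 = ref_shape[0], s2 = ref_shape[1], s3 = ref_shape[2];
  const R_xlen_t n = target_index.size();
  std::vector<Real> acc((size_t)s1 * s2 * s3, (Real)0);

  for (R_xlen_t k = 0; k < n; ++k) {
    if (!is_used[k]) continue;
    const int64_t t = target_index[k];
    const int ni = (int)(t % s1);
    const int nj = (int)((t / s1) % s2);
    const int nk = (int)(t / ((int64_t)s1 * s2));
    Real w0[3];
    int boff[3];
    for (int a = 0; a < 3; ++a)
      axis_base_weight<Real>(dXb(k, a) * DEQ, w0[a], boff[a]);
    const int bi = ni + boff[0], bj = nj + boff[1], bk = nk + boff[2];
    const int64_t base = bi + (int64_t)s1 * (bj + (int64_t)s2 * bk);
    const Real e = (Real)et[k];
    // fixed traversal pattern: base, +x, +y, +xy, +z, +xz, +yz, +xyz
    for (int o3 = 0; o3 < 2; ++o3)
      for (int o2 = 0; o2 < 2; ++o2)
        for (int o1 = 0; o1 < 2; ++o1) {
          const Real w1 = o1 ? (Real)1 - w0[0] : w0[0];
          const Real w2 = o2 ? (Real)1 - w0[1] : w0[1];
          const Real w3 = o3 ? (Real)1 - w0[2] : w0[2];
          const int64_t idx = base + o1 + (int64_t)s1 * (o2 + (int64_t)s2 * o3);
          acc[(size_t)idx] += ((w1 * w2) * w3) * e;
        }
  }
  return to_numeric(acc);
}

// [[Rcpp::export]]
NumericVector map_push_cpp(IntegerVector target_index, IntegerMatrix dXb,
                           IntegerVector is_used, NumericVector et,
                           IntegerVector ref_shape, bool single_precision) {
  if (single_precision)
    return map_push_impl<float>(target_index, dXb, is_used, et, ref_shape);
  return map_push_impl<double>(target_index, dXb, is_used, et, ref_shape);
}

// Gather for the pull layout: records keyed by their nearest reference
// voxel; voxel v collects from keys u in its 27-neighbourhood. The per-axis
// weight of v in a record's ensemble is w0 at the base corner, 1 - w0 one
// step up, and 0 elsewhere.
template <typename Real>
static NumericVector map_pull_impl(const IntegerVector& ranges,
                                   const IntegerVector& source_index,
                                   const IntegerMatrix& dXb,
                                   const NumericVector& et_image,
                                   const IntegerVector& ref_shape,
                                   const int n_slabs) {
  const int s1 = ref_shape[0], s2 = ref_shape[1], s3 = ref_shape[2];
  std::vector<Real> acc((size_t)s1 * s2 * s3, (Real)0);

  for (int slab = 0; slab < n_slabs; ++slab) {
    const int z0 = (int)(((int64_t)slab * s3) / n_slabs);
    const int z1 = (int)(((int64_t)(slab + 1) * s3) / n_slabs);
    for (int vk = z0; vk < z1; ++vk)
      for (int vj = 0; vj < s2; ++vj)
        for (int vi = 0; vi < s1; ++vi) {
          Real sum = (Real)0;
          for (int dk = -1; dk <= 1; ++dk) {
            const int uk = vk + dk;
            if (uk < 0 || uk >= s3) continue;
            for (int dj = -1; dj <= 1; ++dj) {
              const int uj = vj + dj;
              if (uj < 0 || uj >= s2) continue;
              for (int di = -1; di <= 1; ++di) {
                const int ui = vi + di;
                if (ui < 0 || ui >= s1) continue;
                const int64_t u = ui + (int64_t)s1 * (uj + (int64_t)s2 * uk);
                const int r0 = ranges[(size_t)u], r1 = ranges[(size_t)u + 1];
                for (int r = r0; r < r1; ++r) {
                  Real w = (Real)1;
                  bool hit = true;
                  for (int a = 0; a < 3; ++a) {
                    Real w0; int boff;
                    axis_base_weight<Real>(dXb(r, a) * DEQ, w0, boff);
                    const int du = (a == 0) ? di : (a == 1) ? dj : dk;
                    const int rel = -du - boff;  // v - base along axis a
                    if (rel == 0) w *= w0;
                    else if (rel == 1) w *= (Real)1 - w0;
                    else { hit = false; break; }
                  }
                  if (hit)
                    sum += w * (Real)et_image[source_index[r]];
                }
              }
            }
          }
          acc[(size_t)(vi + (int64_t)s1 * (vj + (int64_t)s2 * vk))] = sum;
        }
  }
  return to_numeric(acc);
}

// [[Rcpp::export]]
NumericVector map_pull_cpp(IntegerVector ranges, IntegerVector source_index,
                           IntegerMatrix dXb, NumericVector et_image,
                           IntegerVector ref_shape, int n_slabs,
                           bool single_precision) {
  if (n_slabs < 1 || n_slabs > ref_shape[2])
    stop("n_slabs must be between 1 and the reference z-extent");
  if (single_precision)
    return map_pull_impl<float>(ranges, source_index, dXb, et_image,
                                ref_shape, n_slabs);
  return map_pull_impl<double>(ranges, source_index, dXb, et_image,
                               ref_shape, n_slabs);
}

// Gather for the unified layout: records keyed by the minimum-index corner
// of their overlap ensemble; voxel v collects from the 8 predecessor keys
// u = v - {0,1}^3 with branch-free factors w0 / (1 - w0).
template <typename Real>
static NumericVector map_unified_impl(const IntegerVector& ranges,
                                      const IntegerVector& source_index,
                                      const IntegerMatrix& wb,
                                      const NumericVector& et_image,
                                      const IntegerVector& ref_shape,
                                      const int n_slabs) {
  const int s1 = ref_shape[0], s2 = ref_shape[1], s3 = ref_shape[2];
  std::vector<Real> acc((size_t)s1 * s2 * s3, (Real)0);

  for (int slab = 0; slab < n_slabs; ++slab) {
    const int z0 = (int)(((int64_t)slab * s3) / n_slabs);
    const int z1 = (int)(((int64_t)(slab + 1) * s3) / n_slabs);
    for (int vk = z0; vk < z1; ++vk)
      for (int vj = 0; vj < s2; ++vj)
        for (int vi = 0; vi < s1; ++vi) {
          Real sum = (Real)0;
          for (int dk = -1; dk <= 0; ++dk) {
            const int uk = vk + dk;
            if (uk < 0 || uk >= s3) continue;
            for (int dj = -1; dj <= 0; ++dj) {
              const int uj = vj + dj;
              if (uj < 0 || uj >= s2) continue;
              for (int di = -1; di <= 0; ++di) {
                const int ui = vi + di;
                if (ui < 0 || ui >= s1) continue;
                const int64_t u = ui + (int64_t)s1 * (uj + (int64_t)s2 * uk);
                const int r0 = ranges[(size_t)u], r1 = ranges[(size_t)u + 1];
                for (int r = r0; r < r1; ++r) {
                  const Real w0x = (Real)(wb(r, 0) * DEQ);
                  const Real w0y = (Real)(wb(r, 1) * DEQ);
                  const Real w0z = (Real)(wb(r, 2) * DEQ);
                  const Real w1 = di ? (Real)1 - w0x : w0x;
                  const Real w2 = dj ? (Real)1 - w0y : w0y;
                  const Real w3 = dk ? (Real)1 - w0z : w0z;
                  sum += ((w1 * w2) * w3) * (Real)et_image[source_index[r]];
                }
              }
            }
          }
          acc[(size_t)(vi + (int64_t)s1 * (vj + (int64_t)s2 * vk))] = sum;
        }
  }
  return to_numeric(acc);
}

// [[Rcpp::export]]
NumericVector map_unified_cpp(IntegerVector ranges, IntegerVector source_index,
                              IntegerMatrix wb, NumericVector et_image,
                              IntegerVector ref_shape, int n_slabs,
                              bool single_precision) {
  if (n_slabs < 1 || n_slabs > ref_shape[2])
    stop("n_slabs must be between 1 and the reference z-extent");
  if (single_precision)
    return map_unified_impl<float>(ranges, source_index, wb, et_image,
                                   ref_shape, n_slabs);
  return map_unified_impl<double>(ranges, source_index, wb, et_image,
                                  ref_shape, n_slabs);
}

// Direct dose mapping baseline: scatter weight * dose and weight with the
// same trilinear overlap weights as EMT, then form the weighted mean per
// reference voxel.
// [[Rcpp::export]]
List map_ddm_cpp(IntegerVector target_index, IntegerMatrix dXb,
                 IntegerVector is_used, NumericVector dose_rec,
                 IntegerVector ref_shape) {
  const int s1 = ref_shape[0], s2 = ref_shape[1], s3 = ref_shape[2];
  const R_xlen_t n = target_index.size();
  std::vector<double> num((size_t)s1 * s2 * s3, 0.0);
  std::vector<double> den((size_t)s1 * s2 * s3, 0.0);

  for (R_xlen_t k = 0; k < n; ++k) {
    if (!is_used[k]) continue;
    const int64_t t = target_index[k];
    const int ni = (int)(t % s1);
    const int nj = (int)((t / s1) % s2);
    const int nk = (int)(t / ((int64_t)s1 * s2));
    double w0[3];
    int boff[3];
    for (int a = 0; a < 3; ++a)
      axis_base_weight<double>(dXb(k, a) * DEQ, w0[a], boff[a]);
    const int64_t base = (ni + boff[0]) +
      (int64_t)s1 * ((nj + boff[1]) + (int64_t)s2 * (nk + boff[2]));
    const double d = dose_rec[k];
    for (int o3 = 0; o3 < 2; ++o3)
      for (int o2 = 0; o2 < 2; ++o2)
        for (int o1 = 0; o1 < 2; ++o1) {
          const double w1 = o1 ? 1.0 - w0[0] : w0[0];
          const double w2 = o2 ? 1.0 - w0[1] : w0[1];
          const double w3 = o3 ? 1.0 - w0[2] : w0[2];
          const double w = (w1 * w2) * w3;
          const int64_t idx = base + o1 + (int64_t)s1 * (o2 + (int64_t)s2 * o3);
          num[(size_t)idx] += w * d;
          den[(size_t)idx] += w;
        }
  }
  NumericVector dose(num.size());
  for (size_t i = 0; i < num.size(); ++i)
    dose[i] = den[i] > 0.0 ? num[i] / den[i] : 0.0;
  return List::create(_["dose"] = dose, _["weight"] = to_numeric(den));
}
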