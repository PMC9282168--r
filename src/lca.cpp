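#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

// Locally competitive algorithm over a sequence of input vectors.
//
// For each column I_t of `input`, runs `n_inner` forward-Euler steps of
//   tau * du/dt = -u + A' I_t - (A'A - 1) s,   s = max(u - beta, 0),
// with u carried over between columns (the membrane state persists across
// trajectory steps).  When `learn` is true, after the inner iterations the
// dictionary receives one Hebbian update
//   A <- A + eta (I_t - A s) s',
// is clipped at zero and column-renormalized to unit Euclidean norm.
// Zero columns (possible after input inactivation) are left zero.
//
// Returns the (possibly updated) dictionary, the final membrane state, the
// final rates, the per-step squared reconstruction error ||I - A s||^2, and
// (optionally) the full rate matrix S (n_cells x n_steps).
// [[Rcpp::export]]
List lca_run_cpp(arma::mat A, const arma::mat& input, arma::vec u,
                 double tau, double beta, double dt, int n_inner,
                 double eta, bool learn, bool keep_s) {
  const uword n_in = A.n_rows, n_cells = A.n_cols, n_t = input.n_cols;
  if (input.n_rows != n_in)
    stop("input has %d rows but the dictionary expects %d", input.n_rows, n_in);
  if (u.n_elem != n_cells)
    stop("membrane state has length %d but there are %d cells", u.n_elem, n_cells);
  const double a = dt / tau;
  mat S;
  if (keep_s) S.set_size(n_cells, n_t);
  vec s(n_cells, fill::zeros), b(n_cells), As(n_in), lat(n_cells),
      resid(n_in), err(n_t);
  for (uword t = 0; t < n_t; ++t) {
    b = A.t() * input.col(t);
    for (int k = 0; k < n_inner; ++k) {
      s = clamp(u - beta, 0.0, datum::inf);
      As = A * s;
      lat = A.t() * As - s;  // (A'A - 1) s without materializing A'A
      u += a * (-u + b - lat);
    }
    if (!u.is_finite())
      stop("LCA dynamics diverged (non-finite membrane potential at step %d)",
           t + 1);
    s = clamp(u - beta, 0.0, datum::inf);
    if (keep_s) S.col(t) = s;
    resid = input.col(t) - A * s;
    err(t) = dot(resid, resid);
    if (learn) {
      A += eta * resid * s.t();
      A.clamp(0.0, datum::inf);
      rowvec nrm = sqrt(sum(square(A), 0));
      nrm.replace(0.0, 1.0);  // keep all-zero columns at zero
      A.each_row() /= nrm;
    }
  }
  List out = List::create(_["A"] = A, _["u"] = u, _["s"] = s, _["err"] = err);
  if (keep_s) out["S"] = S;
  return out;
}

// Spatiotemporal firing rate of one grid cell at many (position, time,
// heading) samples.  Field centers live on a triangular lattice with basis
// a1 = lambda (cos th, sin th), a2 = lambda (cos(th+60), sin(th+60)) shifted
// by `offset`; the nearest vertex is found by rounding in lattice
// coordinates and scanning the 3x3 neighbourhood.  Per-field amplitudes are
// looked up in `amp` (row i - imin + 1, col j - jmin + 1 for lattice index
// (i, j)); vertices outside the enumerated window carry no field.  Within
// radius R of a field center the rate is
//   alpha_c exp(-ln5 d^2/R^2) * exp(k_phi (cos(2 pi F t - phi) - 1)),
// where the phase phi falls linearly with the projected distance along the
// current running direction across the chord through the field.
// [[Rcpp::export]]
arma::vec grid_rates_cpp(double spacing, double orient_rad,
                         double ox, double oy,
                         const arma::mat& amp, int imin, int jmin,
                         double kphi, double phi0_deg, double dphi_deg,
                         double freq, double radius,
                         const arma::vec& x, const arma::vec& y,
                         const arma::vec& tt,
                         const arma::vec& hx, const arma::vec& hy,
                         bool spatial_only) {
  const uword n = x.n_elem;
  vec out(n, fill::zeros);
  const double a1x = spacing * std::cos(orient_rad);
  const double a1y = spacing * std::sin(orient_rad);
  const double a2x = spacing * std::cos(orient_rad + datum::pi / 3.0);
  const double a2y = spacing * std::sin(orient_rad + datum::pi / 3.0);
  const double det = a1x * a2y - a1y * a2x;
  const double R2 = radius * radius;
  const double ln5 = std::log(5.0);
  const double deg2rad = datum::pi / 180.0;
  const int ni = amp.n_rows, nj = amp.n_cols;
  for (uword q = 0; q < n; ++q) {
    const double px = x(q) - ox, py = y(q) - oy;
    const double f1 = (px * a2y - py * a2x) / det;
    const double f2 = (-px * a1y + py * a1x) / det;
    const int i0 = (int)std::lround(f1), j0 = (int)std::lround(f2);
    double best = datum::inf, cx = 0, cy = 0;
    int bi = 0, bj = 0;
    for (int di = -1; di <= 1; ++di) {
      for (int dj = -1; dj <= 1; ++dj) {
        const int i = i0 + di, j = j0 + dj;
        const double vx = ox + i * a1x + j * a2x;
        const double vy = oy + i * a1y + j * a2y;
        const double d2 = (x(q) - vx) * (x(q) - vx) + (y(q) - vy) * (y(q) - vy);
        if (d2 < best) { best = d2; cx = vx; cy = vy; bi = i; bj = j; }
      }
    }
    if (best >= R2) continue;
    const int ii = bi - imin, jj = bj - jmin;
    if (ii < 0 || ii >= ni || jj < 0 || jj >= nj) continue;
    const double alpha = amp(ii, jj);
    if (!std::isfinite(alpha)) continue;
    double rate = alpha * std::exp(-ln5 * best / R2);
    if (!spatial_only && kphi != 0.0) {
      const double dxp = x(q) - cx, dyp = y(q) - cy;
      const double d = dxp * hx(q) + dyp * hy(q);
      const double c = -dxp * hy(q) + dyp * hx(q);
      const double Rp = std::sqrt(std::max(R2 - c * c, 1e-300));
      const double phi =
          (phi0_deg - dphi_deg * (d + Rp) / (2.0 * Rp)) * deg2rad;
      rate *= std::exp(kphi * (std::cos(2.0 * datum::pi * freq * tt(q) - phi)
                               - 1.0));
    }
    out(q) = rate;
  }
  return out;
}
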