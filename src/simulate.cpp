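#include <Rcpp.h>
using namespace Rcpp;

// Linear-scattering forward model for one transmit event.
// All inputs in SI units (m, s, Hz). Positions are (x, z) rows.
// Transmit arrival at a scatterer is the first arrival over the transmit
// aperture: min over elements of (element delay + element->scatterer
// travel time), a first-arrival approximation of the diverging wavefront.
// Each contribution is weighted by the transmit apodization and the
// soft cosine directivity of both the first-arriving transmit element and
// the receiving element, so that single-element transmit/receive traces
// obey acoustic reciprocity.
// [[Rcpp::export]]
NumericMatrix sim_channels_cpp(NumericMatrix scat_pos, NumericVector scat_amp,
                               NumericMatrix tx_pos, NumericMatrix tx_norm,
                               NumericVector tx_delay, NumericVector tx_apod,
                               NumericMatrix rx_pos, NumericMatrix rx_norm,
                               double fs, double t0, int n_samp,
                               double c, double f0, double sigma_t,
                               double dir_power) {
  const int ns = scat_pos.nrow();
  const int nt = tx_pos.nrow();
  const int nr = rx_pos.nrow();
  NumericMatrix out(n_samp, nr);
  const double support = 4.0 * sigma_t;
  const double two_pi_f0 = 2.0 * M_PI * f0;

  for (int s = 0; s < ns; ++s) {
    const double px = scat_pos(s, 0), pz = scat_pos(s, 1);
    const double amp = scat_amp[s];
    if (amp == 0.0) continue;
    // first arrival over the transmit aperture
    double t_tx = R_PosInf; int i_best = -1;
    for (int i = 0; i < nt; ++i) {
      const double dx = px - tx_pos(i, 0), dz = pz - tx_pos(i, 1);
      const double t = tx_delay[i] + std::sqrt(dx * dx + dz * dz) / c;
      if (t < t_tx) { t_tx = t; i_best = i; }
    }
    // directivity of the first-arriving transmit element
    double dxb = px - tx_pos(i_best, 0), dzb = pz - tx_pos(i_best, 1);
    double db = std::sqrt(dxb * dxb + dzb * dzb);
    double ct = (dxb * tx_norm(i_best, 0) + dzb * tx_norm(i_best, 1)) / db;
    if (ct <= 0.0) continue;
    const double w_tx = amp * tx_apod[i_best] *
      (dir_power == 1.0 ? ct : std::pow(ct, dir_power));

    for (int j = 0; j < nr; ++j) {
      const double dx = px - rx_pos(j, 0), dz = pz - rx_pos(j, 1);
      const double d = std::sqrt(dx * dx + dz * dz);
      const double cr = (dx * rx_norm(j, 0) + dz * rx_norm(j, 1)) / d;
      if (cr <= 0.0) continue;
      const double w = w_tx * (dir_power == 1.0 ? cr : std::pow(cr, dir_power));
      const double t_arr = t_tx + d / c;
      int n_lo = (int)std::ceil(((t_arr - support) - t0) * fs);
      int n_hi = (int)std::floor(((t_arr + support) - t0) * fs);
      if (n_lo < 0) n_lo = 0;
      if (n_hi > n_samp - 1) n_hi = n_samp - 1;
      for (int n = n_lo; n <= n_hi; ++n) {
        const double tau = t0 + n / fs - t_arr;
        out(n, j) += w * std::exp(-tau * tau / (2.0 * sigma_t * sigma_t)) *
          std::cos(two_pi_f0 * tau);
      }
    }
  }
  return out;
}
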