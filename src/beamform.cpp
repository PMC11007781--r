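#include <Rcpp.h>
using namespace Rcpp;

// Delay-and-sum beamforming of complex baseband (IQ) channel data onto an
// arbitrary set of image nodes. All inputs SI (m, s, Hz).
//
// Per node p and receive element e: total delay tau = tau_tx(p) + |p-e|/c,
// with the virtual-source transmit model tau_tx(p) = |p - vs|/c - t_vs0
// (t_vs0 re-references to the firing of the first element, matching the
// delay normalization of the transmit event). The baseband sample at tau
// is linearly interpolated and rotated back to carrier phase by
// exp(+i 2 pi f0 tau), so the output is the analytic (carrier-preserving)
// signal at the node. Contributions are restricted to an acceptance cone
// around each element normal; delays outside the recorded window
// contribute zero.
// [[Rcpp::export]]
ComplexVector das_cpp(ComplexMatrix iq, NumericMatrix rx_pos,
                      NumericMatrix rx_norm, NumericVector vs,
                      double t_vs0, NumericMatrix nodes,
                      double fs, double t0, double c, double f0,
                      double max_angle_deg) {
  const int n_samp = iq.nrow();
  const int nr = iq.ncol();
  const int nn = nodes.nrow();
  ComplexVector out(nn);
  const double cos_max = std::cos(max_angle_deg * M_PI / 180.0);
  const double two_pi_f0 = 2.0 * M_PI * f0;

  for (int k = 0; k < nn; ++k) {
    const double px = nodes(k, 0), pz = nodes(k, 1);
    const double dvx = px - vs[0], dvz = pz - vs[1];
    const double tau_tx = std::sqrt(dvx * dvx + dvz * dvz) / c - t_vs0;
    double acc_re = 0.0, acc_im = 0.0;
    for (int j = 0; j < nr; ++j) {
      const double dx = px - rx_pos(j, 0), dz = pz - rx_pos(j, 1);
      const double d = std::sqrt(dx * dx + dz * dz);
      if (d <= 0.0) continue;
      const double ca = (dx * rx_norm(j, 0) + dz * rx_norm(j, 1)) / d;
      if (ca < cos_max) continue;
      const double tau = tau_tx + d / c;
      const double sidx = (tau - t0) * fs;
      const int i0 = (int)std::floor(sidx);
      if (i0 < 0 || i0 >= n_samp - 1) continue;
      const double frac = sidx - i0;
      const Rcomplex a = iq(i0, j), b = iq(i0 + 1, j);
      const double vre = a.r + frac * (b.r - a.r);
      const double vim = a.i + frac * (b.i - a.i);
      const double ph = two_pi_f0 * tau;
      const double cp = std::cos(ph), sp = std::sin(ph);
      acc_re += vre * cp - vim * sp;
      acc_im += vre * sp + vim * cp;
    }
    out[k].r = acc_re;
    out[k].i = acc_im;
  }
  return out;
}
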