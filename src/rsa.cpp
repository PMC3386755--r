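#include <Rcpp.h>
using namespace Rcpp;

// Random-sequential-adsorption inner loop on the unrolled cylinder surface.
//
// Candidate positions are uniform on the surface, the orientation is drawn
// with probability proportional to its hydrophobic contact area, and a
// candidate is accepted iff its rectangular footprint overlaps no previously
// accepted one (arc coordinate periodic, axial boundaries hard). Stops after
// `stop_after_failures` consecutive rejections.
//
// Two modes:
//  * fixed: `orient` is a k x 4 matrix (contact_area, radial, ax, arc) used
//    for every attempt;
//  * jitter (`ranges` a 3 x 2 matrix of edge_a/edge_b/thickness ranges):
//    each attempt draws its own prism dimensions and rebuilds the 5-mode
//    orientation table with the strip-contact construction
//    (w = 2*sqrt(2*r*cutoff), contact area proportional to the mode's
//    effective face length).
//
// Uses R's RNG so results are reproducible under set.seed().

// [[Rcpp::export(name = ".rsa_engine")]]
List rsa_engine(double tube_length, double period,
                int stop_after_failures,
                NumericMatrix orient,
                bool jitter,
                NumericMatrix ranges,
                double radius, double cutoff) {
  std::vector<double> zc, zh, sc, sh, rad;
  std::vector<int> oid;
  int fails = 0;
  long attempts = 0;
  const double half_period = period / 2.0;

  // fixed-mode cumulative orientation weights
  int k = orient.nrow();
  std::vector<double> cum(k);
  if (!jitter) {
    double tot = 0.0;
    for (int i = 0; i < k; ++i) { tot += orient(i, 0); cum[i] = tot; }
    for (int i = 0; i < k; ++i) cum[i] /= tot;
  }

  double face[5], radial[5], axf[5], arcf[5];

  while (fails < stop_after_failures) {
    ++attempts;
    double ax, arc, rext;
    int kidx;
    if (jitter) {
      double ea = R::runif(ranges(0, 0), ranges(0, 1));
      double eb = R::runif(ranges(1, 0), ranges(1, 1));
      double th = R::runif(ranges(2, 0), ranges(2, 1));
      face[0] = eb;       radial[0] = th; axf[0] = eb; arcf[0] = ea;
      face[1] = th;       radial[1] = eb; axf[1] = th; arcf[1] = ea;
      face[2] = eb / 2.0; radial[2] = ea; axf[2] = eb; arcf[2] = th;
      face[3] = ea / 2.0; radial[3] = eb; axf[3] = ea; arcf[3] = th;
      face[4] = th / 2.0; radial[4] = eb; axf[4] = th; arcf[4] = th;
      double tot = 0.0;
      for (int i = 0; i < 5; ++i) tot += face[i];
      double u = R::runif(0.0, 1.0) * tot, acc = 0.0;
      kidx = 4;
      for (int i = 0; i < 5; ++i) {
        acc += face[i];
        if (u <= acc) { kidx = i; break; }
      }
      ax = axf[kidx]; arc = arcf[kidx]; rext = radial[kidx];
    } else {
      double u = R::runif(0.0, 1.0);
      kidx = k - 1;
      for (int i = 0; i < k; ++i) {
        if (u <= cum[i]) { kidx = i; break; }
      }
      rext = orient(kidx, 1); ax = orient(kidx, 2); arc = orient(kidx, 3);
    }

    double z = R::runif(ax / 2.0, tube_length - ax / 2.0);
    double s = R::runif(0.0, period);

    bool ok = true;
    const size_t n = zc.size();
    const double zhn = ax / 2.0, shn = arc / 2.0;
    for (size_t i = 0; i < n; ++i) {
      if (std::fabs(z - zc[i]) >= zhn + zh[i]) continue;
      // wrap into [0, period): s, sc are in [0, period) so one step suffices
      double d = s - sc[i] + half_period;
      if (d < 0) d += period;
      else if (d >= period) d -= period;
      d = std::fabs(d - half_period);
      if (d < shn + sh[i]) { ok = false; break; }
    }
    if (ok) {
      zc.push_back(z); zh.push_back(zhn);
      sc.push_back(s); sh.push_back(shn);
      rad.push_back(rext); oid.push_back(kidx + 1);
      fails = 0;
    } else {
      ++fails;
    }
  }

  const size_t n = zc.size();
  NumericMatrix out(n, 6);
  for (size_t i = 0; i < n; ++i) {
    out(i, 0) = zc[i];
    out(i, 1) = sc[i];
    out(i, 2) = oid[i];
    out(i, 3) = rad[i];
    out(i, 4) = 2.0 * zh[i];
    out(i, 5) = 2.0 * sh[i];
  }
  return List::create(_["placements"] = out,
                      _["attempts"] = (double)attempts,
                      _["fails"] = fails);
}
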