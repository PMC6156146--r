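#include <Rcpp.h>
using namespace Rcpp;

// Persistent random walk on the pixel grid: unit steps with Gaussian
// heading changes, confined to `ok`. On collision the heading is
// re-drawn up to 12 times; an unresolvable collision ends the walk.
// Draws from R's RNG stream so (config, seed) stays bit-reproducible.
// [[Rcpp::export(name = ".walkCpp")]]
List walkCpp(IntegerVector start, int nSteps, LogicalMatrix ok,
             double turnSd) {
  int nr = ok.nrow(), nc = ok.ncol();
  IntegerVector rows(nSteps + 1), cols(nSteps + 1);
  double pr = start[0], pc = start[1];
  rows[0] = start[0]; cols[0] = start[1];
  double theta = R::runif(0, 2 * M_PI);
  int taken = 0;
  for (int s = 0; s < nSteps; s++) {
    bool placed = false;
    double th = theta + R::rnorm(0, turnSd);
    for (int t = 0; t < 12; t++) {
      double cr = pr + cos(th), cc = pc + sin(th);
      int ir = (int) ::round(cr), ic = (int) ::round(cc);
      if (ir >= 1 && ir <= nr && ic >= 1 && ic <= nc && ok(ir - 1, ic - 1)) {
        pr = cr; pc = cc; theta = th;
        taken++;
        rows[taken] = ir; cols[taken] = ic;
        placed = true;
        break;
      }
      th += R::runif(-1, 1) * M_PI;
    }
    if (!placed) break;
  }
  return List::create(_["rows"] = rows[Range(0, taken)],
                      _["cols"] = cols[Range(0, taken)],
                      _["steps"] = taken);
}
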