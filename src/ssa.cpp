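#include <Rcpp.h>

// Exact (Gillespie) stochastic simulation of the two-state gene-expression
// model: promoter activation/inactivation, transcription from the active
// state, transcript degradation (rate 1 per transcript), translation and
// protein degradation. Each cell starts at (repressed, 0 transcripts,
// 0 proteins) and is sampled at `duration` (time in transcript lifetimes).
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
Rcpp::IntegerMatrix ssa_telegraph_cpp(int n_cells, double duration,
                                      double kappa_a, double kappa_r,
                                      double kappa_t_plus,
                                      double kappa_p_plus,
                                      double kappa_p_minus) {
  Rcpp::IntegerMatrix out(n_cells, 2);
  for (int c = 0; c < n_cells; ++c) {
    double t = 0.0;
    int g = 0;
    long T = 0, P = 0;
    for (;;) {
      double a1 = g ? kappa_r : kappa_a;          // gene switch
      double a2 = g ? kappa_t_plus : 0.0;         // transcription
      double a3 = (double)T;                      // transcript decay
      double a4 = kappa_p_plus * (double)T;       // translation
      double a5 = kappa_p_minus * (double)P;      // protein decay
      double atot = a1 + a2 + a3 + a4 + a5;
      t += R::rexp(1.0 / atot);
      if (t > duration) break;
      double u = R::runif(0.0, atot);
      if (u < a1) g = 1 - g;
      else if (u < a1 + a2) ++T;
      else if (u < a1 + a2 + a3) --T;
      else if (u < a1 + a2 + a3 + a4) ++P;
      else --P;
    }
    out(c, 0) = (int)T;
    out(c, 1) = (int)P;
  }
  return out;
}
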