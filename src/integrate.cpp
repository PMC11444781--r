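#include <Rcpp.h>
using namespace Rcpp;

// Explicit-Euler integration of the SIRS metapopulation model on a lattice
// whose mobility flows are maximum-entropy softmax distributions over the
// five reachable destinations (self + von Neumann neighbours, all at unit
// cost).  Flows are treated as fast variables: they are recomputed from the
// instantaneous benefit field b_j = (P_j - I_j) / P_j at the start of every
// step.  `nbr` is an M x 5 matrix of 1-based destination indices; each
// column is a permutation of 1..M (torus shift), which makes the
// scatter-accumulation of inflows race-free.
//
// When `sis` is true the recovered compartment is bypassed entirely:
// recovering mass returns to S within the same step (the zeta -> infinity
// limit), and R stays identically zero.
//
// Negative undershoot smaller than `tol_frac * P_i` is clamped to zero
// (round-off); anything larger aborts with a stability error.

// [[Rcpp::export]]
List euler_lattice(NumericVector P, NumericVector S0, NumericVector I0,
                   NumericVector R0, IntegerMatrix nbr, double beta,
                   double gamma, double zeta, double alpha_I, double alpha_S,
                   double dt, int n_steps, bool sis, int snapshot_every,
                   double tol_frac) {
  const int M = P.size();
  const int K = nbr.ncol();
  std::vector<double> S(S0.begin(), S0.end());
  std::vector<double> I(I0.begin(), I0.end());
  std::vector<double> R(R0.begin(), R0.end());
  std::vector<double> b(M), eS(M), eI(M), FS(M), FI(M), mix(M), inc(M);
  std::vector<double> phiS((size_t)M * K), phiI((size_t)M * K);
  List snaps;

  for (int t = 0; t < n_steps; t++) {
    // benefit field and a global exponent shift (cancels in the row-wise
    // normalisation; keeps exp() in range for |alpha| well beyond 700)
    double mS = -1e300, mI = -1e300;
    for (int i = 0; i < M; i++) {
      b[i] = (P[i] - I[i]) / P[i];
      double vS = alpha_S * b[i];
      double vI = alpha_I * b[i];
      if (vS > mS) mS = vS;
      if (vI > mI) mI = vI;
    }
    for (int i = 0; i < M; i++) {
      eS[i] = std::exp(alpha_S * b[i] - mS);
      eI[i] = std::exp(alpha_I * b[i] - mI);
    }

    // flows (softmax over reachable destinations; the unit cost term is a
    // constant per row and cancels) and inflow accumulators
    std::fill(FS.begin(), FS.end(), 0.0);
    std::fill(FI.begin(), FI.end(), 0.0);
    for (int i = 0; i < M; i++) {
      double zS = 0.0, zI = 0.0;
      for (int s = 0; s < K; s++) {
        int j = nbr(i, s) - 1;
        zS += eS[j];
        zI += eI[j];
      }
      for (int s = 0; s < K; s++) {
        int j = nbr(i, s) - 1;
        double pS = eS[j] / zS, pI = eI[j] / zI;
        phiS[(size_t)i * K + s] = pS;
        phiI[(size_t)i * K + s] = pI;
        FS[j] += S[i] * pS;
        FI[j] += I[i] * pI;
      }
    }

    // mixing populations N^_j = FS_j + FI_j > 0 (self-flow is positive)
    for (int j = 0; j < M; j++) {
      double Nhat = FS[j] + FI[j];
      if (!(Nhat > 0.0))
        stop("mixing population is non-positive at location %d", j + 1);
      mix[j] = FI[j] / Nhat;
    }
    for (int i = 0; i < M; i++) {
      double acc = 0.0;
      for (int s = 0; s < K; s++) {
        int j = nbr(i, s) - 1;
        acc += phiS[(size_t)i * K + s] * mix[j];
      }
      inc[i] = beta * S[i] * acc;
    }

    for (int i = 0; i < M; i++) {
      double dS, dI, dR;
      if (sis) {
        dS = -inc[i] + gamma * I[i];
        dI = inc[i] - gamma * I[i];
        dR = 0.0;
      } else {
        dS = -inc[i] + zeta * R[i];
        dI = inc[i] - gamma * I[i];
        dR = gamma * I[i] - zeta * R[i];
      }
      S[i] += dt * dS;
      I[i] += dt * dI;
      R[i] += dt * dR;
      double lim = -tol_frac * P[i];
      if (S[i] < lim || I[i] < lim || R[i] < lim)
        stop("compartment undershoot beyond tolerance at step %d; reduce dt",
             t + 1);
      if (S[i] < 0) S[i] = 0;
      if (I[i] < 0) I[i] = 0;
      if (R[i] < 0) R[i] = 0;
    }

    if (snapshot_every > 0 && ((t + 1) % snapshot_every == 0)) {
      snaps.push_back(NumericVector(I.begin(), I.end()));
    }
  }

  return List::create(_["S"] = NumericVector(S.begin(), S.end()),
                      _["I"] = NumericVector(I.begin(), I.end()),
                      _["R"] = NumericVector(R.begin(), R.end()),
                      _["snapshots"] = snaps);
}
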