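#include <Rcpp.h>
using namespace Rcpp;

// Profile-HMM scoring in natural-log space, glocal path set
// (Begin -> M1..MK -> End with insert/delete detours).
//
// State layout: k = 0..K. M_0 is Begin, "M_{K+1}" is End.
// Transition matrices (rows k = 0..K, natural log):
//   tM[k] = { M_k -> M_{k+1}, M_k -> I_k, M_k -> D_{k+1} }
//   tI[k] = { I_k -> M_{k+1}, I_k -> I_k, I_k -> D_{k+1} }
//   tD[k] = { D_k -> M_{k+1}, D_k -> I_k, D_k -> D_{k+1} }
// Emissions: logMat (K x A) for M_1..M_K, logIns ((K+1) x A) for I_0..I_K.
// seq: 0-based alphabet codes; -1 marks an unknown residue whose emission
// cancels against the null model (log-odds contribution zero).
//
// forward = true gives log P(seq | model); false gives the Viterbi log-prob.
// [[Rcpp::export(rng = false)]]
double phmm_logprob(NumericMatrix logMat, NumericMatrix logIns,
                    NumericMatrix tM, NumericMatrix tI, NumericMatrix tD,
                    IntegerVector seq, bool forward) {
  const int K = logMat.nrow();
  const int L = seq.size();
  const double NEG = -1e300;

  auto comb = [&](double a, double b, double c) {
    if (forward) {
      double m = std::max(a, std::max(b, c));
      if (m <= NEG / 2) return NEG;
      return m + std::log(std::exp(a - m) + std::exp(b - m) + std::exp(c - m));
    }
    return std::max(a, std::max(b, c));
  };

  std::vector<double> M(K + 1, NEG), I(K + 1, NEG), D(K + 1, NEG);
  std::vector<double> nM(K + 1), nI(K + 1), nD(K + 1);

  // i = 0: Begin occupied, deletes reachable without emitting
  M[0] = 0.0;
  for (int k = 1; k <= K; ++k)
    D[k] = comb(M[k - 1] + tM(k - 1, 2), I[k - 1] + tI(k - 1, 2),
                D[k - 1] + tD(k - 1, 2));

  for (int i = 1; i <= L; ++i) {
    const int s = seq[i - 1];
    for (int k = 0; k <= K; ++k) { nM[k] = NEG; nI[k] = NEG; nD[k] = NEG; }
    for (int k = 1; k <= K; ++k) {
      double e = (s >= 0) ? logMat(k - 1, s) : 0.0;
      nM[k] = e + comb(M[k - 1] + tM(k - 1, 0), I[k - 1] + tI(k - 1, 0),
                       D[k - 1] + tD(k - 1, 0));
    }
    for (int k = 0; k <= K; ++k) {
      double e = (s >= 0) ? logIns(k, s) : 0.0;
      nI[k] = e + comb(M[k] + tM(k, 1), I[k] + tI(k, 1), D[k] + tD(k, 1));
    }
    for (int k = 1; k <= K; ++k)
      nD[k] = comb(nM[k - 1] + tM(k - 1, 2), nI[k - 1] + tI(k - 1, 2),
                   nD[k - 1] + tD(k - 1, 2));
    M = nM; I = nI; D = nD;
  }

  return comb(M[K] + tM(K, 0), I[K] + tI(K, 0), D[K] + tD(K, 0));
}
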