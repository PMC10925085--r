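#include <Rcpp.h>
using namespace Rcpp;

// Population-count update of the balanced all-to-all E/I network of
// stochastic non-leaky integrate-and-fire neurons.  Because synaptic
// weights are uniform within each class and the leak is zero, the
// membrane potential after one step is identical across all neurons that
// did not just fire, so the per-step update reduces to two binomial draws
// (one per class) over the non-refractory pools.  Subsampled observers are
// coupled to the population by hypergeometric draws, stratified by class.

static inline double firing_prob(double nE, double nI,
                                 double J, double g, double Gamma) {
  double V = J * nE - g * J * nI;
  double p = Gamma * V;
  if (p < 0.0) p = 0.0;
  if (p > 1.0) p = 1.0;
  return p;
}

// [[Rcpp::export]]
List sim_counts_cpp(int steps, double NE, double NI,
                    double J, double g, double Gamma, double lambda,
                    NumericVector ME, NumericVector MI,
                    bool drive_refractory_immune,
                    double nE0, double nI0,
                    NumericVector sE0, NumericVector sI0) {
  int nf = ME.size();
  IntegerVector nE_out(steps), nI_out(steps), ndrive_out(steps);
  List sampled(nf);
  std::vector<IntegerVector> scount(nf);
  for (int q = 0; q < nf; ++q) {
    scount[q] = IntegerVector(steps);
  }

  double nE = nE0, nI = nI0;
  std::vector<double> sE(nf), sI(nf);
  for (int q = 0; q < nf; ++q) { sE[q] = sE0[q]; sI[q] = sI0[q]; }

  for (int t = 0; t < steps; ++t) {
    double poolE = NE - nE;
    double poolI = NI - nI;
    double pm = firing_prob(nE, nI, J, g, Gamma);

    // external drive fires non-refractory neurons directly; membrane rule
    // applies to the remainder (exact decomposition of the independent-OR)
    double dE = R::rbinom(poolE, lambda);
    double dI = R::rbinom(poolI, lambda);
    double mE = R::rbinom(poolE - dE, pm);
    double mI = R::rbinom(poolI - dI, pm);
    double dR = 0.0;
    if (!drive_refractory_immune) {
      dR = R::rbinom(nE + nI, lambda); // drive may re-excite refractory cells
    }
    double nE_new = dE + mE;
    double nI_new = dI + mI;
    if (!drive_refractory_immune && dR > 0) {
      // split refractory re-excitations proportionally between classes
      double dRE = R::rhyper(nE, nI, dR);
      nE_new += dRE;
      nI_new += dR - dRE;
    }

    // coupled subsampled observers: sampled fired counts are hypergeometric
    // draws of the fired neurons within the sampled non-refractory pool
    for (int q = 0; q < nf; ++q) {
      double availE = ME[q] - sE[q];
      double availI = MI[q] - sI[q];
      double sEn = (poolE > 0) ? R::rhyper(nE_new, poolE - nE_new, availE) : 0.0;
      double sIn = (poolI > 0) ? R::rhyper(nI_new, poolI - nI_new, availI) : 0.0;
      sE[q] = sEn;
      sI[q] = sIn;
      scount[q][t] = (int)(sEn + sIn);
    }

    nE = nE_new;
    nI = nI_new;
    nE_out[t] = (int)nE;
    nI_out[t] = (int)nI;
    ndrive_out[t] = (int)(dE + dI + dR);
  }

  for (int q = 0; q < nf; ++q) sampled[q] = scount[q];
  return List::create(_["nE"] = nE_out, _["nI"] = nI_out,
                      _["n_drive"] = ndrive_out, _["sampled"] = sampled);
}

// Per-neuron raster for a tracked subset of M = ME + MI neurons.  Global
// population counts evolve as in sim_counts_cpp; the tracked subset's fired
// counts are hypergeometric draws coupled to the population, and individual
// spikes are allocated uniformly at random among the tracked non-refractory
// neurons of each class (all of which share the same firing probability).
// [[Rcpp::export]]
List sim_raster_cpp(int steps, double NE, double NI,
                    double J, double g, double Gamma, double lambda,
                    int ME, int MI) {
  IntegerVector nE_out(steps), nI_out(steps), ndrive_out(steps);
  IntegerVector scount_out(steps);
  std::vector<int> ev_neuron, ev_t;

  double nE = 0.0, nI = 0.0;
  int M = ME + MI;
  std::vector<char> refr(M, 0);     // tracked neuron fired at previous step
  std::vector<int> availE, availI;
  availE.reserve(ME); availI.reserve(MI);

  for (int t = 0; t < steps; ++t) {
    double poolE = NE - nE;
    double poolI = NI - nI;
    double pm = firing_prob(nE, nI, J, g, Gamma);

    double dE = R::rbinom(poolE, lambda);
    double dI = R::rbinom(poolI, lambda);
    double mE = R::rbinom(poolE - dE, pm);
    double mI = R::rbinom(poolI - dI, pm);
    double nE_new = dE + mE;
    double nI_new = dI + mI;

    availE.clear(); availI.clear();
    for (int i = 0; i < ME; ++i) if (!refr[i]) availE.push_back(i);
    for (int i = ME; i < M; ++i) if (!refr[i]) availI.push_back(i);

    int sEn = (poolE > 0) ? (int)R::rhyper(nE_new, poolE - nE_new,
                                           (double)availE.size()) : 0;
    int sIn = (poolI > 0) ? (int)R::rhyper(nI_new, poolI - nI_new,
                                           (double)availI.size()) : 0;

    std::fill(refr.begin(), refr.end(), 0);
    // partial Fisher-Yates: choose sEn tracked E spikes uniformly
    int nAE = (int)availE.size();
    for (int s = 0; s < sEn; ++s) {
      int j = s + (int)(unif_rand() * (nAE - s));
      if (j >= nAE) j = nAE - 1;
      std::swap(availE[s], availE[j]);
      refr[availE[s]] = 1;
      ev_neuron.push_back(availE[s] + 1);  // 1-based ids, E first
      ev_t.push_back(t + 1);
    }
    int nAI = (int)availI.size();
    for (int s = 0; s < sIn; ++s) {
      int j = s + (int)(unif_rand() * (nAI - s));
      if (j >= nAI) j = nAI - 1;
      std::swap(availI[s], availI[j]);
      refr[availI[s]] = 1;
      ev_neuron.push_back(availI[s] + 1);
      ev_t.push_back(t + 1);
    }

    nE = nE_new;
    nI = nI_new;
    nE_out[t] = (int)nE;
    nI_out[t] = (int)nI;
    ndrive_out[t] = (int)(dE + dI);
    scount_out[t] = sEn + sIn;
  }

  return List::create(_["nE"] = nE_out, _["nI"] = nI_out,
                      _["n_drive"] = ndrive_out,
                      _["sampled_count"] = scount_out,
                      _["neuron"] = wrap(ev_neuron),
                      _["t"] = wrap(ev_t));
}
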