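// Event-driven recall engine for the digital coincidence-detector backend.
//
// Events are processed in (time, sequence) order.  A post-synaptic spike
// (injected initiation spike or a neuron firing) retriggers every axon
// module whose input address matches; retriggering restarts the module's
// ramp and cancels pre-synaptic emissions still pending from the previous
// trigger (tracked with a per-module generation counter).  A pre-synaptic
// arrival sets its synapse line's coincidence timer to t + window; the
// neuron fires when at least `threshold` lines hold unexpired timers and
// the neuron is outside its refractory period.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <random>
using namespace Rcpp;

namespace {

struct Ev {
  double t;
  long long seq;
  int kind;       // 0 = post-synaptic spike (trigger axons), 1 = pre-synaptic arrival
  int neuron;
  int line;
  int module;     // scheduling module for kind 1 (-1 for injected noise)
  long long gen;  // module trigger generation (-1 = never cancelled)
};

struct EvOrder {
  bool operator()(const Ev& a, const Ev& b) const {
    if (a.t != b.t) return a.t > b.t;
    return a.seq > b.seq;
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_recall_digital(IntegerVector mod_nout,
                        IntegerMatrix mod_out,
                        NumericMatrix mod_delay,
                        IntegerVector addr_ptr,
                        IntegerVector addr_mod,
                        int n_neurons,
                        int n_lines,
                        int threshold,
                        double window,
                        double refractory,
                        NumericVector init_t,
                        IntegerVector init_neuron,
                        NumericVector noise_t,
                        IntegerVector noise_neuron,
                        IntegerVector noise_line,
                        double t_end,
                        int max_emitted,
                        double jitter,
                        double spurious_p,
                        int seed) {
  const int n_mod = mod_nout.size();
  std::vector<long long> mod_gen(n_mod, 0);
  std::vector<double> timer((size_t)n_neurons * n_lines, -1e300);
  std::vector<double> refr_until(n_neurons, -1e300);

  std::mt19937_64 rng((unsigned long long)seed);
  std::uniform_real_distribution<double> U(0.0, 1.0);

  std::priority_queue<Ev, std::vector<Ev>, EvOrder> q;
  long long seq = 0;
  for (int i = 0; i < init_t.size(); ++i)
    q.push({init_t[i], seq++, 0, init_neuron[i], -1, -1, -1});
  for (int i = 0; i < noise_t.size(); ++i)
    q.push({noise_t[i], seq++, 1, noise_neuron[i], noise_line[i], -1, -1});

  std::vector<double> em_t;
  std::vector<int> em_n;
  bool all_firing = false;
  long long n_events = 0;

  auto trigger = [&](int addr, double t) {
    for (int p = addr_ptr[addr]; p < addr_ptr[addr + 1]; ++p) {
      const int m = addr_mod[p];
      const long long g = ++mod_gen[m];
      const int no = mod_nout[m];
      for (int j = 0; j < no; ++j) {
        double te = t + mod_delay(m, j);
        if (jitter > 0) te += (2.0 * U(rng) - 1.0) * jitter;
        q.push({te, seq++, 1, mod_out(m, j), j, m, g});
        if (spurious_p > 0 && U(rng) < spurious_p) {
          // parasitic coupling: a neighbouring delay path of the same
          // module emits as well
          int j2 = (int)(U(rng) * no);
          if (j2 >= no) j2 = no - 1;
          double te2 = t + mod_delay(m, j2);
          if (jitter > 0) te2 += (2.0 * U(rng) - 1.0) * jitter;
          q.push({te2, seq++, 1, mod_out(m, j2), j2, m, g});
        }
      }
    }
  };

  while (!q.empty()) {
    Ev e = q.top();
    q.pop();
    if (e.t > t_end) break;
    ++n_events;
    if (e.kind == 0) {
      trigger(e.neuron, e.t);
      continue;
    }
    if (e.gen >= 0 && mod_gen[e.module] != e.gen) continue;  // ramp restarted
    const int n = e.neuron;
    timer[(size_t)n * n_lines + e.line] = e.t + window;
    if (e.t < refr_until[n]) continue;
    int cnt = 0;
    for (int l = 0; l < n_lines; ++l)
      if (timer[(size_t)n * n_lines + l] > e.t) ++cnt;
    if (cnt >= threshold) {
      for (int l = 0; l < n_lines; ++l) timer[(size_t)n * n_lines + l] = -1e300;
      refr_until[n] = e.t + refractory;
      em_t.push_back(e.t);
      em_n.push_back(n);
      if ((int)em_t.size() > max_emitted) {
        all_firing = true;
        break;
      }
      trigger(n, e.t);
    }
  }

  return List::create(_["time_ms"] = em_t, _["neuron"] = em_n,
                      _["all_firing"] = all_firing,
                      _["n_events"] = (double)n_events);
}
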