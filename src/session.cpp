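#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Categories are coded 1 = color, 2 = shape, 3 = number, 4 = other (no-match
// key). Stimulus attributes are stored as key-card positions: a card with
// color code c matches the key card at position c on the color dimension,
// and likewise for shape and number; the number attribute IS its position
// (key card p shows p objects). A valid stimulus has three pairwise distinct
// attribute positions, so the fourth position matches on no dimension.

struct Stim {
  int n, c, s;
};

// uniform integer on 1..n from R's RNG stream
static inline int sample_int(int n) {
  int k = (int)(unif_rand() * n) + 1;
  return k > n ? n : k;
}

static Stim gen_stim(const Stim *prev) {
  for (;;) {
    int n = sample_int(4), c = sample_int(4), s = sample_int(4);
    if (n == c || n == s || c == s) continue;
    if (prev && prev->n == n && prev->c == c && prev->s == s) continue;
    Stim st = {n, c, s};
    return st;
  }
}

// shift an error probability on the log-odds scale by d per elapsed trial
static inline double drift_prob(double p, double d, int t) {
  if (d == 0.0 || p <= 0.0 || p >= 1.0) return p;
  double lo = std::log(p / (1.0 - p)) + d * (double)(t - 1);
  return 1.0 / (1.0 + std::exp(-lo));
}

static inline int other_of_two(int a, int excl) {
  // uniform draw from the two categories in {1,2,3} different from excl;
  // a is the draw index 1 or 2
  int k = 0;
  for (int cat = 1; cat <= 3; ++cat) {
    if (cat == excl && excl >= 1 && excl <= 3) continue;
    if (++k == a) return cat;
  }
  return 3; // unreachable for valid input
}

// param columns: p_persev, p_setloss, p_inferr, p_other,
// loc_switch, loc_repeat, loc_inference,
// scale_switch, scale_repeat, scale_inference, drift_rt, drift_logodds
// [[Rcpp::export]]
List cpp_simulate_cohort(NumericMatrix params, int n_practice_switches,
                         int n_experimental_switches, int max_total_trials,
                         IntegerVector run_length_support) {
  RNGScope scope;
  int n_agents = params.nrow();
  int ns = run_length_support.size();

  std::vector<int> v_agent, v_block, v_trial, v_num, v_col, v_shp,
      v_prev, v_resp, v_appl, v_fb;
  std::vector<double> v_rt;
  size_t cap = (size_t)n_agents * 200u;
  v_agent.reserve(cap); v_rt.reserve(cap);

  for (int a = 0; a < n_agents; ++a) {
    double p_persev = params(a, 0), p_setloss = params(a, 1);
    double p_inferr = params(a, 2), p_other = params(a, 3);
    double loc[3] = {params(a, 4), params(a, 5), params(a, 6)};
    double scl[3] = {params(a, 7), params(a, 8), params(a, 9)};
    double d_rt = params(a, 10), d_lo = params(a, 11);

    int total = 0;  // session trial counter (practice + experimental)
    for (int block = 0; block < 2; ++block) {
      int target_switches =
          block == 0 ? n_practice_switches : n_experimental_switches;
      int prevailing = sample_int(3);
      int run_target = run_length_support[sample_int(ns) - 1];
      int run_correct = 0, switches = 0;
      int prev_appl = 0, prev2_appl = 0, prev_fb = -1, prev2_fb = -1;
      Stim prev_stim = {0, 0, 0};
      int ti = 0;

      while (switches < target_switches && total < max_total_trials) {
        ++ti;
        ++total;
        Stim st = gen_stim(ti == 1 ? (const Stim *)0 : &prev_stim);

        // trial context: 0 start, 1 repeat, 2 switch, 3 inference.
        // Inference requires the preceding trial to be a switch trial on
        // which a genuine category (not the no-match key) was switched to
        // and again answered with negative feedback.
        int ctx;
        if (ti == 1)
          ctx = 0;
        else if (prev_fb == 1)
          ctx = 1;
        else {
          ctx = 2;
          if (ti >= 3 && prev2_fb == 0 && prev_appl != prev2_appl &&
              prev_appl >= 1 && prev_appl <= 3 && prev2_appl >= 1 &&
              prev2_appl <= 3)
            ctx = 3;
        }

        double pp = drift_prob(p_persev, d_lo, total);
        double psl = drift_prob(p_setloss, d_lo, total);
        double pin = drift_prob(p_inferr, d_lo, total);

        int cat;
        if (ctx == 0) {
          cat = sample_int(3);
        } else if (ctx == 1) {
          // repeat context: previously applied category == prevailing
          if (unif_rand() < psl) {
            if (unif_rand() < p_other)
              cat = 4;
            else
              cat = other_of_two(sample_int(2), prev_appl);
          } else
            cat = prev_appl;
        } else if (ctx == 2) {
          if (prev_appl >= 1 && prev_appl <= 3 && unif_rand() < pp) {
            cat = prev_appl;
          } else if (unif_rand() < p_other) {
            cat = 4;
          } else if (prev_appl >= 1 && prev_appl <= 3) {
            cat = other_of_two(sample_int(2), prev_appl);
          } else {
            cat = sample_int(3);
          }
        } else {
          // inference context: prevailing is the third category, the two
          // predecessors applied the two disconfirmed ones
          if (unif_rand() < pp)
            cat = prev_appl;
          else if (unif_rand() < pin) {
            if (unif_rand() < p_other)
              cat = 4;
            else
              cat = prev2_appl;
          } else
            cat = prevailing;
        }

        int resp;
        if (cat == 1) resp = st.c;
        else if (cat == 2) resp = st.s;
        else if (cat == 3) resp = st.n;
        else resp = 10 - st.n - st.c - st.s;

        int fb = (cat == prevailing) ? 1 : 0;
        int rt_type = (ctx == 2) ? 0 : (ctx == 3 ? 2 : 1);
        double rt = std::exp(
            norm_rand() * scl[rt_type] +
            loc[rt_type] + d_rt * (double)(total - 1));

        v_agent.push_back(a + 1);
        v_block.push_back(block);
        v_trial.push_back(ti);
        v_num.push_back(st.n);
        v_col.push_back(st.c);
        v_shp.push_back(st.s);
        v_prev.push_back(prevailing);
        v_resp.push_back(resp);
        v_appl.push_back(cat);
        v_fb.push_back(fb);
        v_rt.push_back(rt);

        if (fb == 1) {
          ++run_correct;
          if (run_correct == run_target) {
            ++switches;
            if (switches < target_switches) {
              prevailing = other_of_two(sample_int(2), prevailing);
              run_target = run_length_support[sample_int(ns) - 1];
              run_correct = 0;
            }
          }
        }
        prev2_appl = prev_appl;
        prev2_fb = prev_fb;
        prev_appl = cat;
        prev_fb = fb;
        prev_stim = st;
      }
      if (total >= max_total_trials) break;
    }
  }

  return List::create(
      _["agent"] = wrap(v_agent), _["block"] = wrap(v_block),
      _["trial_index"] = wrap(v_trial), _["stim_number"] = wrap(v_num),
      _["stim_color_pos"] = wrap(v_col), _["stim_shape_pos"] = wrap(v_shp),
      _["prevailing"] = wrap(v_prev), _["response"] = wrap(v_resp),
      _["applied"] = wrap(v_appl), _["feedback"] = wrap(v_fb),
      _["rt_ms"] = wrap(v_rt));
}
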