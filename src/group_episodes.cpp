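#include <Rcpp.h>
using namespace Rcpp;

// Greedy left-to-right grouping of pregnancy-related claims into episodes.
// Input rows must be sorted by (woman, day). `outcome_type` codes the
// outcome evidence carried by each claim: 0 none, 1 live birth, 2
// stillbirth, 3 spontaneous abortion, 4 induced abortion. A new episode
// opens when the current claim is at least `gap_live` days after the open
// episode's most recent live-birth record, at least `gap_loss` days after
// its most recent stillbirth/abortion record, or (no outcome record yet)
// more than `max_span` days after the episode's first claim.
//
// [[Rcpp::export]]
IntegerVector group_episodes_cpp(IntegerVector woman, IntegerVector day,
                                 IntegerVector outcome_type,
                                 int gap_live, int gap_loss, int max_span) {
  R_xlen_t n = woman.size();
  IntegerVector ep(n);
  if (n == 0) return ep;
  int cur = 0, cur_woman = 0, ep_start = 0, out_day = 0, out_type = 0;
  bool have_woman = false;
  for (R_xlen_t i = 0; i < n; i++) {
    bool new_woman = !have_woman || woman[i] != cur_woman;
    if (!new_woman && day[i] < day[i - 1])
      stop("claims must be sorted by service date within woman");
    bool split = false;
    if (!new_woman) {
      if (out_type > 0) {
        int gap = (out_type == 1) ? gap_live : gap_loss;
        if (day[i] - out_day >= gap) split = true;
      } else if (day[i] - ep_start > max_span) {
        split = true;
      }
    }
    if (new_woman) {
      cur = 1; cur_woman = woman[i]; have_woman = true;
      ep_start = day[i]; out_type = 0;
    } else if (split) {
      cur += 1; ep_start = day[i]; out_type = 0;
    }
    if (outcome_type[i] > 0) { out_type = outcome_type[i]; out_day = day[i]; }
    ep[i] = cur;
  }
  return ep;
}
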