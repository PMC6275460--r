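#include <Rcpp.h>
#include <set>

using namespace Rcpp;

// Order-statistic window holding the current W (or truncated) values as two
// multisets: `low` keeps the ceil(n/2) smallest values, `high` the rest, so
// the median is read off the boundary in O(1) and insert/erase cost O(log W).
class MedianWindow {
  std::multiset<double> low, high;

  void rebalance() {
    while (low.size() > high.size() + 1) {
      high.insert(*low.rbegin());
      low.erase(std::prev(low.end()));
    }
    while (low.size() < high.size()) {
      low.insert(*high.begin());
      high.erase(high.begin());
    }
  }

public:
  void insert(double v) {
    if (low.empty() || v <= *low.rbegin()) low.insert(v); else high.insert(v);
    rebalance();
  }

  void erase(double v) {
    std::multiset<double>::iterator it = low.find(v);
    if (it != low.end()) {
      low.erase(it);
    } else {
      it = high.find(v);
      if (it == high.end()) stop("internal error: value not in window");
      high.erase(it);
    }
    rebalance();
  }

  // Middle order statistic; even counts (truncated edge windows) average the
  // two central values, matching the naive sorted-window definition.
  double median() const {
    std::size_t n = low.size() + high.size();
    if (n % 2 == 1) return *low.rbegin();
    return (*low.rbegin() + *high.begin()) / 2.0;
  }
};

inline int wrap_index(int i, int n) {
  int r = i % n;
  return r < 0 ? r + n : r;
}

// [[Rcpp::export]]
NumericVector rolling_median_cpp(NumericVector x, int W, bool circular) {
  const int n = x.size();
  if (n < 1) stop("empty series");
  if (W < 1 || W % 2 == 0) stop("W must be a positive odd integer");
  if (circular && W > n) stop("W must not exceed the series length on circular tracks");
  const int V = (W - 1) / 2;
  NumericVector out(n);
  MedianWindow win;

  if (circular) {
    for (int i = -V; i <= V; ++i) win.insert(x[wrap_index(i, n)]);
    out[0] = win.median();
    for (int b = 1; b < n; ++b) {
      win.erase(x[wrap_index(b - V - 1, n)]);
      win.insert(x[wrap_index(b + V, n)]);
      out[b] = win.median();
    }
  } else {
    const int top = std::min(V, n - 1);
    for (int i = 0; i <= top; ++i) win.insert(x[i]);
    out[0] = win.median();
    for (int b = 1; b < n; ++b) {
      const int add = b + V, rem = b - V - 1;
      if (add < n) win.insert(x[add]);
      if (rem >= 0) win.erase(x[rem]);
      out[b] = win.median();
    }
  }
  return out;
}
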