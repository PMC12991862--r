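#include <Rcpp.h>
using namespace Rcpp;

// Events are pre-encoded in R as numeric matrix rows (see encode_course()):
//   col 0: type (1 diagnosis, 2 surgery, 3 radiotherapy, 4 systemic)
//   diagnosis:    1 uicc, 2 ecog, 3 age group, 4 histology, 5 grading
//   surgery:      1 group, 2 residual, 3 complications bitmask (-1 missing)
//   radiotherapy: 1 application bitmask (-1 missing/unrelated), 2 region
//                 (0 breast, 1 thorax), 3 temporal
//   systemic:     1 therapy type index (0-based into the 14x14 matrix,
//                 13 = MI), 2 temporal
// -1 encodes a missing or unrelated value, which always has distance 1.

static const int NCOL = 6;

static inline double ord_dist(double a, double b, double scale) {
  if (a < 0 || b < 0) return 1.0;
  return std::abs(a - b) / scale;
}

static inline double cat_dist(double a, double b) {
  if (a < 0 || b < 0) return 1.0;
  return (a == b) ? 0.0 : 1.0;
}

static inline double jaccard_mask(double a, double b) {
  if (a < 0 || b < 0) return 1.0;
  unsigned int ua = (unsigned int) a, ub = (unsigned int) b;
  unsigned int uni = ua | ub;
  if (uni == 0u) return 0.0;  // two documented-empty sets agree
  unsigned int in = ua & ub;
  int cu = 0, ci = 0;
  for (; uni; uni >>= 1) cu += uni & 1u;
  for (; in; in >>= 1) ci += in & 1u;
  return 1.0 - (double) ci / (double) cu;
}

static inline double region_dist(double a, double b) {
  if (a < 0 || b < 0) return 1.0;
  if (a == b) return 0.0;
  return 0.5;  // breast vs thorax
}

struct Weights {
  double d_uicc, d_ecog, d_age, d_hist, d_grad;
  double s_type, s_temp;
  double su_proc, su_res, su_comp;
  double r_target, r_app, r_temp;
};

static Weights make_weights(List weights) {
  NumericVector d = weights["diagnosis"], s = weights["systemic"],
                su = weights["surgery"], r = weights["radiotherapy"];
  Weights w;
  w.d_uicc = d["uicc"]; w.d_ecog = d["ecog"]; w.d_age = d["age_group"];
  w.d_hist = d["histology"]; w.d_grad = d["grading"];
  w.s_type = s["type"]; w.s_temp = s["temporal"];
  w.su_proc = su["procedure"]; w.su_res = su["residual"]; w.su_comp = su["complications"];
  w.r_target = r["target"]; w.r_app = r["application"]; w.r_temp = r["temporal"];
  return w;
}

// a, b are contiguous NCOL-element event rows
static double event_dist(const double* a, const double* b,
                         const Weights& w, const NumericMatrix& tmat) {
  int ta = (int) a[0], tb = (int) b[0];
  if (ta != tb) return 1.0;
  switch (ta) {
  case 1:
    return w.d_uicc * ord_dist(a[1], b[1], 4.0)
         + w.d_ecog * ord_dist(a[2], b[2], 4.0)
         + w.d_age  * cat_dist(a[3], b[3])
         + w.d_hist * cat_dist(a[4], b[4])
         + w.d_grad * ord_dist(a[5], b[5], 8.0);
  case 2:
    return w.su_proc * cat_dist(a[1], b[1])
         + w.su_res  * ord_dist(a[2], b[2], 3.0)
         + w.su_comp * jaccard_mask(a[3], b[3]);
  case 3:
    return w.r_app    * jaccard_mask(a[1], b[1])
         + w.r_target * region_dist(a[2], b[2])
         + w.r_temp   * cat_dist(a[3], b[3]);
  case 4: {
    int ia = a[1] < 0 ? 13 : (int) a[1];
    int ib = b[1] < 0 ? 13 : (int) b[1];
    return w.s_type * tmat(ia, ib)
         + w.s_temp * cat_dist(a[2], b[2]);
  }
  }
  return 1.0;
}

// Copy an R (column-major) event matrix into row-major contiguous storage.
static std::vector<double> to_rows(const NumericMatrix& A) {
  int na = A.nrow();
  std::vector<double> out((size_t) na * NCOL);
  for (int i = 0; i < na; ++i)
    for (int c = 0; c < NCOL; ++c)
      out[(size_t) i * NCOL + c] = A(i, c);
  return out;
}

// Length-normalized Levenshtein DP: insertion/deletion cost 1, substitution
// cost the event-level distance; result divided by max sequence length.
static double course_dist(const std::vector<double>& A, int na,
                          const std::vector<double>& B, int nb,
                          const Weights& w, const NumericMatrix& tmat,
                          std::vector<double>& prev, std::vector<double>& cur) {
  if (na == 0 && nb == 0) return 0.0;
  if (na == 0 || nb == 0) return 1.0;  // |na - nb| / max(na, nb) = 1
  prev.resize(nb + 1); cur.resize(nb + 1);
  for (int j = 0; j <= nb; ++j) prev[j] = j;
  for (int i = 1; i <= na; ++i) {
    cur[0] = i;
    const double* arow = A.data() + (size_t)(i - 1) * NCOL;
    for (int j = 1; j <= nb; ++j) {
      double sub = prev[j - 1] + event_dist(arow, B.data() + (size_t)(j - 1) * NCOL, w, tmat);
      double del = prev[j] + 1.0;
      double ins = cur[j - 1] + 1.0;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[nb] / (double) std::max(na, nb);
}

// [[Rcpp::export]]
double cpp_course_distance(NumericMatrix a, NumericMatrix b,
                           NumericMatrix tmat, List weights) {
  Weights w = make_weights(weights);
  std::vector<double> ra = to_rows(a), rb = to_rows(b), p, c;
  return course_dist(ra, a.nrow(), rb, b.nrow(), w, tmat, p, c);
}

// [[Rcpp::export]]
NumericMatrix cpp_pairwise_course_distance(List courses, NumericMatrix tmat,
                                           List weights) {
  int n = courses.size();
  Weights w = make_weights(weights);
  std::vector<std::vector<double> > enc(n);
  std::vector<int> len(n);
  for (int i = 0; i < n; ++i) {
    NumericMatrix m = as<NumericMatrix>(courses[i]);
    enc[i] = to_rows(m);
    len[i] = m.nrow();
  }
  NumericMatrix out(n, n);
  std::vector<double> p, c;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = course_dist(enc[i], len[i], enc[j], len[j], w, tmat, p, c);
      out(i, j) = d;
      out(j, i) = d;
    }
    if ((i & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
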