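// Numerical core: CIE L*a*b* <-> sRGB conversion, CIEDE2000, conformation
// scoring, simulated annealing and the random-sampling baseline.
//
// All random numbers come from R's RNG (unif_rand via RNGScope), so every
// entry point is reproducible under set.seed() on the R side.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double PI_ = 3.14159265358979323846;

// ---------------------------------------------------------------------------
// sRGB <-> XYZ <-> L*a*b*
//
// Forward matrix: linear sRGB -> XYZ (IEC 61966-2-1, D65, 2 deg observer).
// The D65 white point is taken as the image of (1,1,1) under this matrix and
// the inverse is computed analytically from the same matrix, so the
// round-trip and the white point are exact at floating-point resolution.
// ---------------------------------------------------------------------------

static const double M_FWD[3][3] = {
    {0.4124564, 0.3575761, 0.1804375},
    {0.2126729, 0.7151522, 0.0721750},
    {0.0193339, 0.1191920, 0.9503041}
};

struct XyzInv {
    double m[3][3];
    double white[3]; // Xn, Yn, Zn = row sums of M_FWD
    XyzInv() {
        double det = 0.0;
        for (int i = 0; i < 3; ++i)
            det += M_FWD[0][i] * (M_FWD[1][(i + 1) % 3] * M_FWD[2][(i + 2) % 3] -
                                  M_FWD[1][(i + 2) % 3] * M_FWD[2][(i + 1) % 3]);
        for (int i = 0; i < 3; ++i) {
            for (int j = 0; j < 3; ++j) {
                m[i][j] = (M_FWD[(j + 1) % 3][(i + 1) % 3] * M_FWD[(j + 2) % 3][(i + 2) % 3] -
                           M_FWD[(j + 1) % 3][(i + 2) % 3] * M_FWD[(j + 2) % 3][(i + 1) % 3]) / det;
            }
        }
        for (int i = 0; i < 3; ++i)
            white[i] = M_FWD[i][0] + M_FWD[i][1] + M_FWD[i][2];
    }
};
static const XyzInv XYZ_INV;

static const double GAMUT_TOL = 1e-9;   // tolerance on pre-clamp linear channels
static const double EPS_CBRT = 216.0 / 24389.0;  // (6/29)^3
static const double KAPPA = 24389.0 / 27.0;

static inline double lab_finv(double t) {
    double t3 = t * t * t;
    return (t3 > EPS_CBRT) ? t3 : (116.0 * t - 16.0) / KAPPA;
}

static inline double lab_f(double t) {
    return (t > EPS_CBRT) ? std::cbrt(t) : (KAPPA * t + 16.0) / 116.0;
}

static inline double srgb_encode(double c) {
    return (c <= 0.0031308) ? 12.92 * c
                            : 1.055 * std::pow(c, 1.0 / 2.4) - 0.055;
}

static inline double srgb_decode(double c) {
    return (c <= 0.04045) ? c / 12.92
                          : std::pow((c + 0.055) / 1.055, 2.4);
}

// Lab -> sRGB; returns true iff in gamut. rgb[] is filled (clamped) either way.
static bool lab2rgb_one(double L, double a, double b, double rgb[3]) {
    double fy = (L + 16.0) / 116.0;
    double fx = fy + a / 500.0;
    double fz = fy - b / 200.0;
    double xyz[3] = {
        lab_finv(fx) * XYZ_INV.white[0],
        lab_finv(fy) * XYZ_INV.white[1],
        lab_finv(fz) * XYZ_INV.white[2]
    };
    bool in_gamut = true;
    for (int i = 0; i < 3; ++i) {
        double lin = XYZ_INV.m[i][0] * xyz[0] + XYZ_INV.m[i][1] * xyz[1] +
                     XYZ_INV.m[i][2] * xyz[2];
        if (lin < -GAMUT_TOL || lin > 1.0 + GAMUT_TOL) in_gamut = false;
        if (lin < 0.0) lin = 0.0;
        if (lin > 1.0) lin = 1.0;
        rgb[i] = srgb_encode(lin);
    }
    return in_gamut;
}

static void rgb2lab_one(double r, double g, double b, double lab[3]) {
    double lin[3] = { srgb_decode(r), srgb_decode(g), srgb_decode(b) };
    double xyz[3];
    for (int i = 0; i < 3; ++i)
        xyz[i] = M_FWD[i][0] * lin[0] + M_FWD[i][1] * lin[1] + M_FWD[i][2] * lin[2];
    double fx = lab_f(xyz[0] / XYZ_INV.white[0]);
    double fy = lab_f(xyz[1] / XYZ_INV.white[1]);
    double fz = lab_f(xyz[2] / XYZ_INV.white[2]);
    lab[0] = 116.0 * fy - 16.0;
    lab[1] = 500.0 * (fx - fy);
    lab[2] = 200.0 * (fy - fz);
}

// ---------------------------------------------------------------------------
// Color difference metrics
// ---------------------------------------------------------------------------

// CIEDE2000 (kL = kC = kH = 1), hue arithmetic in degrees.
static double ciede2000_one(double L1, double a1, double b1,
                            double L2, double a2, double b2) {
    const double POW25_7 = 6103515625.0; // 25^7
    double C1 = std::sqrt(a1 * a1 + b1 * b1);
    double C2 = std::sqrt(a2 * a2 + b2 * b2);
    double Cbar = 0.5 * (C1 + C2);
    double Cbar7 = std::pow(Cbar, 7);
    double G = 0.5 * (1.0 - std::sqrt(Cbar7 / (Cbar7 + POW25_7)));
    double ap1 = (1.0 + G) * a1, ap2 = (1.0 + G) * a2;
    double Cp1 = std::sqrt(ap1 * ap1 + b1 * b1);
    double Cp2 = std::sqrt(ap2 * ap2 + b2 * b2);
    double hp1 = 0.0, hp2 = 0.0;
    if (!(ap1 == 0.0 && b1 == 0.0)) {
        hp1 = std::atan2(b1, ap1) * 180.0 / PI_;
        if (hp1 < 0.0) hp1 += 360.0;
    }
    if (!(ap2 == 0.0 && b2 == 0.0)) {
        hp2 = std::atan2(b2, ap2) * 180.0 / PI_;
        if (hp2 < 0.0) hp2 += 360.0;
    }
    double dLp = L2 - L1;
    double dCp = Cp2 - Cp1;
    double dhp = 0.0;
    if (Cp1 * Cp2 != 0.0) {
        dhp = hp2 - hp1;
        if (dhp > 180.0) dhp -= 360.0;
        else if (dhp < -180.0) dhp += 360.0;
    }
    double dHp = 2.0 * std::sqrt(Cp1 * Cp2) * std::sin(dhp * PI_ / 360.0);
    double Lbar = 0.5 * (L1 + L2);
    double Cpbar = 0.5 * (Cp1 + Cp2);
    double hpbar;
    if (Cp1 * Cp2 == 0.0) {
        hpbar = hp1 + hp2;
    } else {
        double sum = hp1 + hp2;
        if (std::fabs(hp1 - hp2) <= 180.0) hpbar = 0.5 * sum;
        else if (sum < 360.0) hpbar = 0.5 * (sum + 360.0);
        else hpbar = 0.5 * (sum - 360.0);
    }
    double rad = PI_ / 180.0;
    double T = 1.0 - 0.17 * std::cos((hpbar - 30.0) * rad)
                   + 0.24 * std::cos(2.0 * hpbar * rad)
                   + 0.32 * std::cos((3.0 * hpbar + 6.0) * rad)
                   - 0.20 * std::cos((4.0 * hpbar - 63.0) * rad);
    double dTheta = 30.0 * std::exp(-std::pow((hpbar - 275.0) / 25.0, 2));
    double Cpbar7 = std::pow(Cpbar, 7);
    double RC = 2.0 * std::sqrt(Cpbar7 / (Cpbar7 + POW25_7));
    double Lm50 = (Lbar - 50.0) * (Lbar - 50.0);
    double SL = 1.0 + 0.015 * Lm50 / std::sqrt(20.0 + Lm50);
    double SC = 1.0 + 0.045 * Cpbar;
    double SH = 1.0 + 0.015 * Cpbar * T;
    double RT = -std::sin(2.0 * dTheta * rad) * RC;
    double tL = dLp / SL, tC = dCp / SC, tH = dHp / SH;
    return std::sqrt(tL * tL + tC * tC + tH * tH + RT * tC * tH);
}

static inline double euclid_one(double L1, double a1, double b1,
                                double L2, double a2, double b2) {
    double dL = L1 - L2, da = a1 - a2, db = b1 - b2;
    return std::sqrt(dL * dL + da * da + db * db);
}

// metric codes: 0 = CIEDE2000, 1 = Euclidean
static inline double metric_one(int metric, const double* c1, const double* c2) {
    return metric == 0 ? ciede2000_one(c1[0], c1[1], c1[2], c2[0], c2[1], c2[2])
                       : euclid_one(c1[0], c1[1], c1[2], c2[0], c2[1], c2[2]);
}

// ---------------------------------------------------------------------------
// Subspace membership and sampling
// ---------------------------------------------------------------------------

struct Subspace {
    double lmin, lmax, amin, amax, bmin, bmax;
    bool gamut;
};

static Subspace as_subspace(const NumericVector& bounds, bool gamut) {
    Subspace s;
    s.lmin = bounds[0]; s.lmax = bounds[1];
    s.amin = bounds[2]; s.amax = bounds[3];
    s.bmin = bounds[4]; s.bmax = bounds[5];
    s.gamut = gamut;
    return s;
}

static bool member_one(const Subspace& s, double L, double a, double b) {
    if (L < s.lmin || L > s.lmax || a < s.amin || a > s.amax ||
        b < s.bmin || b > s.bmax) return false;
    if (s.gamut) {
        double rgb[3];
        return lab2rgb_one(L, a, b, rgb);
    }
    return true;
}

// Rejection sampling over the bounding box; a*/b* boxes default to [-128,128]
// where unbounded, L* to [0,100].
static void sample_one(const Subspace& s, double out[3], int max_reject) {
    double llo = std::max(s.lmin, 0.0),    lhi = std::min(s.lmax, 100.0);
    double alo = std::max(s.amin, -128.0), ahi = std::min(s.amax, 128.0);
    double blo = std::max(s.bmin, -128.0), bhi = std::min(s.bmax, 128.0);
    if (!(llo <= lhi && alo <= ahi && blo <= bhi))
        stop("color subspace has an empty bounding box");
    for (int k = 0; k < max_reject; ++k) {
        double L = llo + unif_rand() * (lhi - llo);
        double a = alo + unif_rand() * (ahi - alo);
        double b = blo + unif_rand() * (bhi - blo);
        if (member_one(s, L, a, b)) {
            out[0] = L; out[1] = a; out[2] = b;
            return;
        }
    }
    stop("rejection budget exhausted: color subspace appears to be empty");
}

// ---------------------------------------------------------------------------
// Scoring
//
// dvec holds the strict lower triangle of D in column-major pair order
// (j < i, column j fastest), the same order R's lower.tri() extraction uses.
// Returns +Inf for a degenerate (all colors identical) conformation.
// ---------------------------------------------------------------------------

static double score_conf(const std::vector<double>& lab, int N,
                         const double* dvec, double fc, int metric,
                         std::vector<double>& cbuf) {
    int n = N * (N - 1) / 2;
    double sumC = 0.0;
    int k = 0;
    for (int j = 0; j < N - 1; ++j) {
        for (int i = j + 1; i < N; ++i, ++k) {
            double c = metric_one(metric, &lab[3 * i], &lab[3 * j]);
            cbuf[k] = c;
            sumC += c;
        }
    }
    if (sumC <= 0.0) return R_PosInf;
    double fs = n / sumC;
    double sh = 0.0;
    for (k = 0; k < n; ++k) {
        double d = fs * cbuf[k] - dvec[k];
        sh += d * d;
    }
    double sc = fc * n / sumC; // fc / <C>
    return sh + sc;
}

// ---------------------------------------------------------------------------
// Exported entry points
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_lab_to_rgb(NumericMatrix lab) {
    int n = lab.nrow();
    NumericMatrix rgb(n, 3);
    LogicalVector ok(n);
    double buf[3];
    for (int i = 0; i < n; ++i) {
        ok[i] = lab2rgb_one(lab(i, 0), lab(i, 1), lab(i, 2), buf);
        rgb(i, 0) = buf[0]; rgb(i, 1) = buf[1]; rgb(i, 2) = buf[2];
    }
    return List::create(_["rgb"] = rgb, _["in_gamut"] = ok);
}

// [[Rcpp::export]]
NumericMatrix cpp_rgb_to_lab(NumericMatrix rgb) {
    int n = rgb.nrow();
    NumericMatrix lab(n, 3);
    double buf[3];
    for (int i = 0; i < n; ++i) {
        rgb2lab_one(rgb(i, 0), rgb(i, 1), rgb(i, 2), buf);
        lab(i, 0) = buf[0]; lab(i, 1) = buf[1]; lab(i, 2) = buf[2];
    }
    return lab;
}

// [[Rcpp::export]]
NumericVector cpp_color_diff(NumericMatrix lab1, NumericMatrix lab2, int metric) {
    int n = lab1.nrow();
    NumericVector out(n);
    for (int i = 0; i < n; ++i) {
        double c1[3] = { lab1(i, 0), lab1(i, 1), lab1(i, 2) };
        double c2[3] = { lab2(i, 0), lab2(i, 1), lab2(i, 2) };
        out[i] = metric_one(metric, c1, c2);
    }
    return out;
}

// Strict-lower-triangle pairwise differences in column-major pair order.
// [[Rcpp::export]]
NumericVector cpp_pairwise_diff(NumericMatrix lab, int metric) {
    int N = lab.nrow();
    NumericVector out(N * (N - 1) / 2);
    int k = 0;
    for (int j = 0; j < N - 1; ++j) {
        for (int i = j + 1; i < N; ++i, ++k) {
            double ci[3] = { lab(i, 0), lab(i, 1), lab(i, 2) };
            double cj[3] = { lab(j, 0), lab(j, 1), lab(j, 2) };
            out[k] = metric_one(metric, ci, cj);
        }
    }
    return out;
}

// [[Rcpp::export]]
LogicalVector cpp_in_subspace(NumericMatrix lab, NumericVector bounds, bool gamut) {
    Subspace s = as_subspace(bounds, gamut);
    int n = lab.nrow();
    LogicalVector out(n);
    for (int i = 0; i < n; ++i)
        out[i] = member_one(s, lab(i, 0), lab(i, 1), lab(i, 2));
    return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_subspace(int n, NumericVector bounds, bool gamut,
                                  int max_reject) {
    Subspace s = as_subspace(bounds, gamut);
    NumericMatrix out(n, 3);
    double buf[3];
    for (int i = 0; i < n; ++i) {
        sample_one(s, buf, max_reject);
        out(i, 0) = buf[0]; out(i, 1) = buf[1]; out(i, 2) = buf[2];
    }
    return out;
}

// Simulated annealing run. Uses R's RNG; seed with set.seed() on the R side.
// [[Rcpp::export]]
List cpp_run_sa(NumericVector dvec, int N, NumericVector bounds, bool gamut,
                int n_steps, double beta0, double tau, double step0,
                double step_tau, double fc, int metric, bool global_moves,
                int max_reject) {
    Subspace s = as_subspace(bounds, gamut);
    int n = N * (N - 1) / 2;
    if ((int)dvec.size() != n) stop("distance vector length does not match alphabet size");
    std::vector<double> cur(3 * N), prop(3 * N), cbuf(n);

    double buf[3];
    for (int i = 0; i < N; ++i) {
        sample_one(s, buf, max_reject);
        cur[3 * i] = buf[0]; cur[3 * i + 1] = buf[1]; cur[3 * i + 2] = buf[2];
    }
    double cur_score = score_conf(cur, N, dvec.begin(), fc, metric, cbuf);
    std::vector<double> best = cur;
    double best_score = cur_score;
    double worst_score = cur_score;

    NumericVector trajectory(n_steps);
    LogicalVector accepted(n_steps);

    for (int t = 0; t < n_steps; ++t) {
        double beta = beta0 * std::exp((double)t / tau);
        double step = step0 * std::exp(-(double)t / step_tau);
        prop = cur;
        if (global_moves) {
            for (int i = 0; i < N; ++i) {
                double L = prop[3 * i]     + (2.0 * unif_rand() - 1.0) * step;
                double a = prop[3 * i + 1] + (2.0 * unif_rand() - 1.0) * step;
                double b = prop[3 * i + 2] + (2.0 * unif_rand() - 1.0) * step;
                if (member_one(s, L, a, b)) { // per-color rejection
                    prop[3 * i] = L; prop[3 * i + 1] = a; prop[3 * i + 2] = b;
                }
            }
        } else {
            int i = (int)(unif_rand() * N);
            if (i == N) i = N - 1;
            double L = prop[3 * i]     + (2.0 * unif_rand() - 1.0) * step;
            double a = prop[3 * i + 1] + (2.0 * unif_rand() - 1.0) * step;
            double b = prop[3 * i + 2] + (2.0 * unif_rand() - 1.0) * step;
            if (member_one(s, L, a, b)) {
                prop[3 * i] = L; prop[3 * i + 1] = a; prop[3 * i + 2] = b;
            }
        }
        double new_score = score_conf(prop, N, dvec.begin(), fc, metric, cbuf);
        double delta = new_score - cur_score;
        bool acc;
        if (delta <= 0.0) {
            acc = true;
        } else if (!R_FINITE(new_score)) {
            acc = false;
        } else {
            acc = unif_rand() < std::exp(-beta * delta);
        }
        if (acc) {
            cur = prop;
            cur_score = new_score;
        }
        if (cur_score < best_score) {
            best = cur;
            best_score = cur_score;
        }
        if (cur_score > worst_score) worst_score = cur_score;
        trajectory[t] = cur_score;
        accepted[t] = acc;
    }

    NumericMatrix best_mat(N, 3);
    for (int i = 0; i < N; ++i) {
        best_mat(i, 0) = best[3 * i];
        best_mat(i, 1) = best[3 * i + 1];
        best_mat(i, 2) = best[3 * i + 2];
    }
    return List::create(_["best"] = best_mat,
                        _["best_score"] = best_score,
                        _["worst_score"] = worst_score,
                        _["trajectory"] = trajectory,
                        _["accepted"] = accepted);
}

// Random-sampling baseline: scores of independent uniform conformations.
// [[Rcpp::export]]
NumericVector cpp_random_baseline(NumericVector dvec, int N, NumericVector bounds,
                                  bool gamut, int n_samples, double fc,
                                  int metric, int max_reject) {
    Subspace s = as_subspace(bounds, gamut);
    int n = N * (N - 1) / 2;
    if ((int)dvec.size() != n) stop("distance vector length does not match alphabet size");
    std::vector<double> lab(3 * N), cbuf(n);
    NumericVector scores(n_samples);
    double buf[3];
    for (int k = 0; k < n_samples; ++k) {
        for (int i = 0; i < N; ++i) {
            sample_one(s, buf, max_reject);
            lab[3 * i] = buf[0]; lab[3 * i + 1] = buf[1]; lab[3 * i + 2] = buf[2];
        }
        scores[k] = score_conf(lab, N, dvec.begin(), fc, metric, cbuf);
    }
    return scores;
}
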