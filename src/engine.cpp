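// Single-precision training engine.
//
// The R level walks the layer graph tensor-by-tensor in double precision
// (the reference path, see R/engine.R). Training runs orders of magnitude
// more layer calls, so this engine interprets the same graph entirely in
// C++ with float activations and parameters -- the customary precision
// for CNN optimization -- using persistent per-slot buffers (no per-step
// allocation churn) and batched im2col + sgemm for all convolutions.
// One cpp_engine_step call performs forward, loss, backward and the SGDM
// update for a mini-batch; parameters live inside the engine between
// steps and are exported back to R as doubles when training finishes.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <random>
#ifdef __GLIBC__
#include <malloc.h>
#endif
using namespace Rcpp;

// Large GEMM temporaries of identical sizes are allocated every step;
// keep glibc from serving them with mmap/munmap (page-fault churn) so
// the free list recycles them instead.
static void tune_allocator() {
#ifdef __GLIBC__
  static bool done = false;
  if (!done) {
    mallopt(M_MMAP_THRESHOLD, 256 * 1024 * 1024);
    mallopt(M_TRIM_THRESHOLD, 256 * 1024 * 1024);
    done = true;
  }
#endif
}

enum LayerKind { L_CONV = 1, L_DECONV, L_BN, L_RELU, L_POOL, L_DROP, L_CONCAT };

struct LayerDef {
  int kind = 0;
  std::vector<int> in;   // input slot(s)
  int out = -1;          // output slot
  int k = 0, stride = 0, pad = 0;
  int inCh = 0, outCh = 0;
  double ratio = 0.0;    // dropout
  // spatial geometry, filled at first step for the batch size in use
  int Hin = 0, Win = 0, Hout = 0, Wout = 0;
};

struct ParamSet {
  arma::fvec W, b, gamma, beta, rmean, rvar;
  arma::fvec Wprev, bprev, gprev, beprev;   // previous step (momentum)
};

struct Engine {
  std::vector<LayerDef> layers;
  std::vector<ParamSet> params;       // parallel to layers (unused slots empty)
  int side = 0;
  int logitsSlot = 0;
  int nSlots = 0;
  float lr = 1e-3f, mom = 0.9f, bnmom = 0.1f, eps = 1e-5f;
  bool geomReady = false;
  int batchN = 0;
  // per-slot activation and gradient buffers (flat, (H,W,C,N) layout)
  std::vector<arma::fvec> act, dact;
  std::vector<int> actH, actW, actC;
  // per-layer caches
  std::vector<arma::fmat> cols;          // conv patch matrices
  std::vector<std::vector<int>> poolIdx;
  std::vector<arma::fvec> bnMean, bnInvstd, dropMask;
  std::mt19937 rng;
};

template <typename eT>
static void im2colT_f(const eT* x, int H, int W, int C,
                      int k, int s, int p, int Ho, int Wo,
                      arma::Mat<eT>& colsT, size_t rowOff) {
  for (int c = 0; c < C; ++c) {
    const eT* xc = x + (size_t)H * W * c;
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * kw + k * k * c;
        eT* col = colsT.colptr(r) + rowOff;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * s - p + kw;
          eT* dst = col + (size_t)Ho * wo;
          if (wi < 0 || wi >= W) { std::fill(dst, dst + Ho, eT(0)); continue; }
          const eT* xcol = xc + (size_t)H * wi;
          int ho0 = 0, hi = -p + kh;
          while (hi < 0) { hi += s; ++ho0; }
          int ho1 = ho0 + (H - 1 - hi) / s + 1;
          if (ho1 > Ho) ho1 = Ho;
          std::fill(dst, dst + ho0, eT(0));
          if (s == 1) std::copy(xcol + hi, xcol + hi + (ho1 - ho0), dst + ho0);
          else for (int ho = ho0; ho < ho1; ++ho, hi += s) dst[ho] = xcol[hi];
          std::fill(dst + ho1, dst + Ho, eT(0));
        }
      }
  }
}

template <typename eT>
static void col2imT_f(const arma::Mat<eT>& colsT, int H, int W, int C,
                      int k, int s, int p, int Ho, int Wo,
                      eT* x, size_t rowOff) {
  for (int c = 0; c < C; ++c) {
    eT* xc = x + (size_t)H * W * c;
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * kw + k * k * c;
        const eT* col = colsT.colptr(r) + rowOff;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * s - p + kw;
          if (wi < 0 || wi >= W) continue;
          eT* xcol = xc + (size_t)H * wi;
          const eT* src = col + (size_t)Ho * wo;
          int ho = 0, hi = -p + kh;
          while (hi < 0) { hi += s; ++ho; }
          for (; ho < Ho && hi < H; ++ho, hi += s) xcol[hi] += src[ho];
        }
      }
  }
}

static void gather_rows_f(const float* x, int HW, int C, int N, arma::fmat& Xb) {
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      std::copy(x + (size_t)HW * (c + (size_t)C * n),
                x + (size_t)HW * (c + (size_t)C * n) + HW,
                Xb.colptr(c) + (size_t)HW * n);
}

static void scatter_rows_f(const arma::fmat& Yb, int HW, int C, int N,
                           const float* bias, float* y, bool accumulate) {
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const float* src = Yb.colptr(c) + (size_t)HW * n;
      float* dst = y + (size_t)HW * (c + (size_t)C * n);
      if (accumulate) for (int i = 0; i < HW; ++i) dst[i] += src[i];
      else if (bias) { const float b = bias[c]; for (int i = 0; i < HW; ++i) dst[i] = src[i] + b; }
      else std::copy(src, src + HW, dst);
    }
}

// mirror (k,k,Cin,Cout) -> (k*k*Cout x Cin)
static arma::fmat mirror_f(const arma::fvec& w, int k, int Cin, int Cout) {
  arma::fmat Vm(k * k * Cout, Cin);
  const float* wp = w.memptr();
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int kw = 0; kw < k; ++kw)
        for (int kh = 0; kh < k; ++kh)
          Vm(kh + k * kw + k * k * co, ci) =
            wp[kh + k * (kw + k * (ci + (size_t)Cin * co))];
  return Vm;
}

static arma::fvec asF(const NumericVector& v) {
  arma::fvec out(v.size());
  for (R_xlen_t i = 0; i < v.size(); ++i) out[i] = (float)v[i];
  return out;
}

// desc: list(layers = list(list(kind, in, out, k, stride, pad, inCh, outCh,
//       ratio)), nSlots, side, logitsSlot); pars: per-layer list (may be
//       NULL) with W, b or gamma, beta, rmean, rvar
// [[Rcpp::export]]
SEXP cpp_engine_create(List desc, List pars, double lr, double momentum,
                       double bnMomentum, double eps) {
  tune_allocator();
  Engine* E = new Engine();
  E->side = as<int>(desc["side"]);
  E->nSlots = as<int>(desc["nSlots"]);
  E->logitsSlot = as<int>(desc["logitsSlot"]);
  E->lr = (float)lr; E->mom = (float)momentum;
  E->bnmom = (float)bnMomentum; E->eps = (float)eps;
  List ls = desc["layers"];
  const int L = ls.size();
  E->layers.resize(L);
  E->params.resize(L);
  E->cols.resize(L);
  E->poolIdx.resize(L);
  E->bnMean.resize(L); E->bnInvstd.resize(L); E->dropMask.resize(L);
  for (int i = 0; i < L; ++i) {
    List ld = ls[i];
    LayerDef& d = E->layers[i];
    d.kind = as<int>(ld["kind"]);
    d.in = as<std::vector<int>>(ld["in"]);
    d.out = as<int>(ld["out"]);
    d.k = as<int>(ld["k"]); d.stride = as<int>(ld["stride"]);
    d.pad = as<int>(ld["pad"]);
    d.inCh = as<int>(ld["inCh"]); d.outCh = as<int>(ld["outCh"]);
    d.ratio = as<double>(ld["ratio"]);
    SEXP pv = pars[i];
    if (pv != R_NilValue) {
      List p(pv);
      ParamSet& ps = E->params[i];
      if (p.containsElementNamed("W")) {
        ps.W = asF(p["W"]); ps.b = asF(p["b"]);
        ps.Wprev = ps.W; ps.bprev = ps.b;
      }
      if (p.containsElementNamed("gamma")) {
        ps.gamma = asF(p["gamma"]); ps.beta = asF(p["beta"]);
        ps.rmean = asF(p["rmean"]); ps.rvar = asF(p["rvar"]);
        ps.gprev = ps.gamma; ps.beprev = ps.beta;
      }
    }
  }
  E->act.resize(E->nSlots); E->dact.resize(E->nSlots);
  E->actH.resize(E->nSlots); E->actW.resize(E->nSlots); E->actC.resize(E->nSlots);
  return XPtr<Engine>(E, true);
}

static void ensure(arma::fvec& v, size_t n) { if (v.n_elem != n) v.set_size(n); }

static void sgdm_update(arma::fvec& th, arma::fvec& prev, const arma::fvec& g,
                        float lr, float mom) {
  arma::fvec cur = th;
  th = th - lr * g + mom * (th - prev);
  prev = std::move(cur);
}

// one mini-batch step: forward, cross-entropy, backward, SGDM update.
// x: (side, side, 1, N) doubles; tgt: (side, side, N) doubles in {0,1};
// dropSeed seeds the dropout masks. Returns the mini-batch loss.
// [[Rcpp::export]]
double cpp_engine_step(SEXP eng, NumericVector x, NumericVector tgt,
                       int dropSeed) {
  XPtr<Engine> E(eng);
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], N = xd[3];
  const int L = (int)E->layers.size();
  E->batchN = N;
  E->rng.seed((unsigned)dropSeed);

  // slot 0 = input
  ensure(E->act[0], (size_t)H * W * N);
  for (size_t i = 0; i < (size_t)H * W * N; ++i) E->act[0][i] = (float)x[i];
  E->actH[0] = H; E->actW[0] = W; E->actC[0] = 1;

  // ---- forward ----
  for (int li = 0; li < L; ++li) {
    LayerDef& d = E->layers[li];
    ParamSet& ps = E->params[li];
    const int s0 = d.in[0];
    const int Hi = E->actH[s0], Wi = E->actW[s0], Ci = E->actC[s0];
    float* xin = E->act[s0].memptr();
    switch (d.kind) {
    case L_CONV: {
      const int Ho = (Hi + 2 * d.pad - d.k) / d.stride + 1;
      const int Wo = (Wi + 2 * d.pad - d.k) / d.stride + 1;
      const size_t HoWo = (size_t)Ho * Wo;
      arma::fmat& colsT = E->cols[li];
      if (colsT.n_rows != HoWo * N || colsT.n_cols != (size_t)d.k * d.k * Ci)
        colsT.set_size(HoWo * N, (size_t)d.k * d.k * Ci);
      for (int n = 0; n < N; ++n)
        im2colT_f<float>(xin + (size_t)Hi * Wi * Ci * n, Hi, Wi, Ci,
                         d.k, d.stride, d.pad, Ho, Wo, colsT, HoWo * n);
      arma::fmat Wm(ps.W.memptr(), d.k * d.k * Ci, d.outCh, false, true);
      arma::fmat Yb = colsT * Wm;
      ensure(E->act[d.out], HoWo * d.outCh * N);
      scatter_rows_f(Yb, (int)HoWo, d.outCh, N, ps.b.memptr(),
                     E->act[d.out].memptr(), false);
      E->actH[d.out] = Ho; E->actW[d.out] = Wo; E->actC[d.out] = d.outCh;
      break;
    }
    case L_DECONV: {
      const int Ho = (Hi - 1) * d.stride - 2 * d.pad + d.k;
      const int Wo = (Wi - 1) * d.stride - 2 * d.pad + d.k;
      const size_t HW = (size_t)Hi * Wi;
      arma::fmat Vm = mirror_f(ps.W, d.k, Ci, d.outCh);
      arma::fmat Xb(HW * N, Ci);
      gather_rows_f(xin, (int)HW, Ci, N, Xb);
      arma::fmat dcolsT = Xb * Vm.t();
      ensure(E->act[d.out], (size_t)Ho * Wo * d.outCh * N);
      E->act[d.out].zeros();
      float* yp = E->act[d.out].memptr();
      for (int n = 0; n < N; ++n) {
        float* yn = yp + (size_t)Ho * Wo * d.outCh * n;
        col2imT_f<float>(dcolsT, Ho, Wo, d.outCh, d.k, d.stride, d.pad,
                         Hi, Wi, yn, HW * n);
        for (int co = 0; co < d.outCh; ++co) {
          float* yc = yn + (size_t)Ho * Wo * co;
          const float b = ps.b[co];
          for (size_t i = 0; i < (size_t)Ho * Wo; ++i) yc[i] += b;
        }
      }
      E->actH[d.out] = Ho; E->actW[d.out] = Wo; E->actC[d.out] = d.outCh;
      break;
    }
    case L_BN: {
      const size_t HW = (size_t)Hi * Wi;
      const double m = (double)HW * N;
      ensure(E->act[d.out], HW * Ci * N);
      ensure(E->bnMean[li], Ci); ensure(E->bnInvstd[li], Ci);
      float* yp = E->act[d.out].memptr();
      for (int c = 0; c < Ci; ++c) {
        double s = 0, s2 = 0;
        for (int n = 0; n < N; ++n) {
          const float* xc = xin + HW * (c + (size_t)Ci * n);
          for (size_t i = 0; i < HW; ++i) { s += xc[i]; s2 += (double)xc[i] * xc[i]; }
        }
        const double mu = s / m;
        double v = s2 / m - mu * mu; if (v < 0) v = 0;
        const float is = (float)(1.0 / std::sqrt(v + E->eps));
        E->bnMean[li][c] = (float)mu; E->bnInvstd[li][c] = is;
        ps.rmean[c] = (1.0f - E->bnmom) * ps.rmean[c] + E->bnmom * (float)mu;
        ps.rvar[c] = (1.0f - E->bnmom) * ps.rvar[c] + E->bnmom * (float)v;
        const float a = ps.gamma[c] * is, b0 = ps.beta[c] - a * (float)mu;
        for (int n = 0; n < N; ++n) {
          const float* xc = xin + HW * (c + (size_t)Ci * n);
          float* yc = yp + HW * (c + (size_t)Ci * n);
          for (size_t i = 0; i < HW; ++i) yc[i] = a * xc[i] + b0;
        }
      }
      E->actH[d.out] = Hi; E->actW[d.out] = Wi; E->actC[d.out] = Ci;
      break;
    }
    case L_RELU: {
      const size_t n = (size_t)Hi * Wi * Ci * N;
      ensure(E->act[d.out], n);
      float* yp = E->act[d.out].memptr();
      for (size_t i = 0; i < n; ++i) yp[i] = xin[i] > 0 ? xin[i] : 0.0f;
      E->actH[d.out] = Hi; E->actW[d.out] = Wi; E->actC[d.out] = Ci;
      break;
    }
    case L_POOL: {
      const int Ho = (d.stride == 2) ? Hi / 2 : Hi;
      const int Wo = (d.stride == 2) ? Wi / 2 : Wi;
      ensure(E->act[d.out], (size_t)Ho * Wo * Ci * N);
      E->poolIdx[li].resize((size_t)Ho * Wo * Ci * N);
      float* yp = E->act[d.out].memptr();
      int* ip = E->poolIdx[li].data();
      for (int n = 0; n < N; ++n)
        for (int c = 0; c < Ci; ++c) {
          const size_t base = (size_t)Hi * Wi * (c + (size_t)Ci * n);
          const size_t obase = (size_t)Ho * Wo * (c + (size_t)Ci * n);
          for (int wo = 0; wo < Wo; ++wo)
            for (int ho = 0; ho < Ho; ++ho) {
              const int h0 = ho * d.stride, w0 = wo * d.stride;
              float best = -1e30f; size_t besti = 0;
              for (int dw = 0; dw < 2; ++dw) {
                const int wi2 = w0 + dw; if (wi2 >= Wi) continue;
                for (int dh = 0; dh < 2; ++dh) {
                  const int hi2 = h0 + dh; if (hi2 >= Hi) continue;
                  const size_t xi = base + hi2 + (size_t)Hi * wi2;
                  if (xin[xi] > best) { best = xin[xi]; besti = xi; }
                }
              }
              const size_t oi = obase + ho + (size_t)Ho * wo;
              yp[oi] = best; ip[oi] = (int)besti;
            }
        }
      E->actH[d.out] = Ho; E->actW[d.out] = Wo; E->actC[d.out] = Ci;
      break;
    }
    case L_DROP: {
      const size_t n = (size_t)Hi * Wi * Ci * N;
      ensure(E->act[d.out], n);
      ensure(E->dropMask[li], n);
      const float keep = 1.0f - (float)d.ratio;
      std::uniform_real_distribution<float> U(0.0f, 1.0f);
      float* mk = E->dropMask[li].memptr();
      float* yp = E->act[d.out].memptr();
      for (size_t i = 0; i < n; ++i) {
        mk[i] = (U(E->rng) < keep) ? 1.0f / keep : 0.0f;
        yp[i] = xin[i] * mk[i];
      }
      E->actH[d.out] = Hi; E->actW[d.out] = Wi; E->actC[d.out] = Ci;
      break;
    }
    case L_CONCAT: {
      int Ct = 0;
      for (int s : d.in) Ct += E->actC[s];
      const size_t HW = (size_t)Hi * Wi;
      ensure(E->act[d.out], HW * Ct * N);
      float* yp = E->act[d.out].memptr();
      for (int n = 0; n < N; ++n) {
        size_t at = 0;
        for (int s : d.in) {
          const int c = E->actC[s];
          std::copy(E->act[s].memptr() + HW * c * n,
                    E->act[s].memptr() + HW * c * (n + 1),
                    yp + HW * (at + (size_t)Ct * n));
          at += c;
        }
      }
      E->actH[d.out] = Hi; E->actW[d.out] = Wi; E->actC[d.out] = Ct;
      break;
    }
    default: stop("engine: unknown layer kind");
    }
  }

  // ---- softmax + cross-entropy on the logits slot (2 channels) ----
  const int ls = E->logitsSlot;
  const int Ho = E->actH[ls], Wo = E->actW[ls];
  const size_t HW = (size_t)Ho * Wo;
  const double npix = (double)HW * N;
  const float* lg = E->act[ls].memptr();
  for (int s = 0; s < E->nSlots; ++s) {
    ensure(E->dact[s], E->act[s].n_elem);
    E->dact[s].zeros();
  }
  float* dlg = E->dact[ls].memptr();
  double loss = 0.0;
  for (int n = 0; n < N; ++n) {
    const float* a = lg + HW * (0 + 2 * (size_t)n);
    const float* b = lg + HW * (1 + 2 * (size_t)n);
    float* da = dlg + HW * (0 + 2 * (size_t)n);
    float* db = dlg + HW * (1 + 2 * (size_t)n);
    const double* tg = tgt.begin() + HW * (size_t)n;
    for (size_t i = 0; i < HW; ++i) {
      const float mx = a[i] > b[i] ? a[i] : b[i];
      const double ea = std::exp((double)(a[i] - mx));
      const double eb = std::exp((double)(b[i] - mx));
      const double Z = ea + eb;
      const double p1 = eb / Z, p0 = ea / Z;
      const double t = tg[i];
      loss -= t * std::log(p1 + 1e-12) + (1 - t) * std::log(p0 + 1e-12);
      da[i] = (float)((p0 - (1 - t)) / npix);
      db[i] = (float)((p1 - t) / npix);
    }
  }
  loss /= npix;
  if (!std::isfinite(loss)) return loss;

  // ---- backward + SGDM (reverse layer order) ----
  for (int li = L - 1; li >= 0; --li) {
    LayerDef& d = E->layers[li];
    ParamSet& ps = E->params[li];
    const int s0 = d.in[0];
    const int Hi = E->actH[s0], Wi = E->actW[s0], Ci = E->actC[s0];
    const float* xin = E->act[s0].memptr();
    const float* dy = E->dact[d.out].memptr();
    float* dx = E->dact[s0].memptr();
    switch (d.kind) {
    case L_CONV: {
      const int Ho2 = E->actH[d.out], Wo2 = E->actW[d.out];
      const size_t HoWo = (size_t)Ho2 * Wo2;
      arma::fmat& colsT = E->cols[li];   // cached from forward
      arma::fmat Dyb(HoWo * N, d.outCh);
      gather_rows_f(dy, (int)HoWo, d.outCh, N, Dyb);
      arma::fmat Wm(ps.W.memptr(), d.k * d.k * Ci, d.outCh, false, true);
      arma::fmat dWm = colsT.t() * Dyb;
      arma::fvec dW(dWm.memptr(), dWm.n_elem);          // same layout as W
      arma::fvec dB(d.outCh);
      for (int co = 0; co < d.outCh; ++co) dB[co] = arma::accu(Dyb.col(co));
      if (s0 != 0) {                     // input-layer gradient unused
        arma::fmat dcolsT = Dyb * Wm.t();
        for (int n = 0; n < N; ++n)
          col2imT_f<float>(dcolsT, Hi, Wi, Ci, d.k, d.stride, d.pad,
                           Ho2, Wo2, dx + (size_t)Hi * Wi * Ci * n, HoWo * n);
      }
      sgdm_update(ps.W, ps.Wprev, dW, E->lr, E->mom);
      sgdm_update(ps.b, ps.bprev, dB, E->lr, E->mom);
      break;
    }
    case L_DECONV: {
      const int Ho2 = E->actH[d.out], Wo2 = E->actW[d.out];
      const size_t HW2 = (size_t)Hi * Wi;
      arma::fmat Vm = mirror_f(ps.W, d.k, Ci, d.outCh);
      arma::fmat colsT(HW2 * N, (size_t)d.k * d.k * d.outCh);
      for (int n = 0; n < N; ++n)
        im2colT_f<float>(dy + (size_t)Ho2 * Wo2 * d.outCh * n, Ho2, Wo2,
                         d.outCh, d.k, d.stride, d.pad, Hi, Wi, colsT, HW2 * n);
      arma::fmat dXb = colsT * Vm;
      scatter_rows_f(dXb, (int)HW2, Ci, N, nullptr, dx, true);
      arma::fmat Xb(HW2 * N, Ci);
      gather_rows_f(xin, (int)HW2, Ci, N, Xb);
      arma::fmat dVm = colsT.t() * Xb;
      // permute into W layout (k,k,Cin,Cout)
      arma::fvec dW(ps.W.n_elem);
      for (int co = 0; co < d.outCh; ++co)
        for (int ci = 0; ci < Ci; ++ci)
          for (int kw = 0; kw < d.k; ++kw)
            for (int kh = 0; kh < d.k; ++kh)
              dW[kh + d.k * (kw + d.k * (ci + (size_t)Ci * co))] =
                dVm(kh + d.k * kw + d.k * d.k * co, ci);
      arma::fvec dB(d.outCh);
      for (int co = 0; co < d.outCh; ++co) {
        double acc = 0;
        for (int n = 0; n < N; ++n) {
          const float* dyc = dy + (size_t)Ho2 * Wo2 * (co + (size_t)d.outCh * n);
          for (size_t i = 0; i < (size_t)Ho2 * Wo2; ++i) acc += dyc[i];
        }
        dB[co] = (float)acc;
      }
      sgdm_update(ps.W, ps.Wprev, dW, E->lr, E->mom);
      sgdm_update(ps.b, ps.bprev, dB, E->lr, E->mom);
      break;
    }
    case L_BN: {
      const size_t HW2 = (size_t)Hi * Wi;
      const double m = (double)HW2 * N;
      arma::fvec dG(Ci), dBt(Ci);
      for (int c = 0; c < Ci; ++c) {
        const float mu = E->bnMean[li][c], is = E->bnInvstd[li][c];
        double sdy = 0, sdyx = 0;
        for (int n = 0; n < N; ++n) {
          const float* xc = xin + HW2 * (c + (size_t)Ci * n);
          const float* dyc = dy + HW2 * (c + (size_t)Ci * n);
          for (size_t i = 0; i < HW2; ++i) {
            sdy += dyc[i];
            sdyx += (double)dyc[i] * (xc[i] - mu) * is;
          }
        }
        dG[c] = (float)sdyx; dBt[c] = (float)sdy;
        const float g = ps.gamma[c] * is / (float)m;
        const float fsdy = (float)sdy, fsdyx = (float)sdyx;
        for (int n = 0; n < N; ++n) {
          const float* xc = xin + HW2 * (c + (size_t)Ci * n);
          const float* dyc = dy + HW2 * (c + (size_t)Ci * n);
          float* dxc = dx + HW2 * (c + (size_t)Ci * n);
          for (size_t i = 0; i < HW2; ++i) {
            const float xhat = (xc[i] - mu) * is;
            dxc[i] += g * ((float)m * dyc[i] - fsdy - xhat * fsdyx);
          }
        }
      }
      sgdm_update(ps.gamma, ps.gprev, dG, E->lr, E->mom);
      sgdm_update(ps.beta, ps.beprev, dBt, E->lr, E->mom);
      break;
    }
    case L_RELU: {
      const size_t n = (size_t)Hi * Wi * Ci * N;
      for (size_t i = 0; i < n; ++i) if (xin[i] > 0) dx[i] += dy[i];
      break;
    }
    case L_POOL: {
      const int* ip = E->poolIdx[li].data();
      const size_t m2 = E->act[d.out].n_elem;
      for (size_t i = 0; i < m2; ++i) dx[ip[i]] += dy[i];
      break;
    }
    case L_DROP: {
      const float* mk = E->dropMask[li].memptr();
      const size_t n = E->act[d.out].n_elem;
      for (size_t i = 0; i < n; ++i) dx[i] += dy[i] * mk[i];
      break;
    }
    case L_CONCAT: {
      const size_t HW2 = (size_t)Hi * Wi;
      const int Ct = E->actC[d.out];
      for (int n = 0; n < N; ++n) {
        size_t at = 0;
        for (int s : d.in) {
          const int c = E->actC[s];
          float* dd = E->dact[s].memptr() + HW2 * c * n;
          const float* sy = dy + HW2 * (at + (size_t)Ct * n);
          for (size_t i = 0; i < HW2 * c; ++i) dd[i] += sy[i];
          at += c;
        }
      }
      break;
    }
    }
  }
  return loss;
}

// export trained parameters back to R (doubles), per layer index
// [[Rcpp::export]]
List cpp_engine_params(SEXP eng) {
  XPtr<Engine> E(eng);
  const int L = (int)E->layers.size();
  List out(L);
  for (int i = 0; i < L; ++i) {
    ParamSet& ps = E->params[i];
    if (ps.W.n_elem) {
      out[i] = List::create(_["W"] = NumericVector(ps.W.begin(), ps.W.end()),
                            _["b"] = NumericVector(ps.b.begin(), ps.b.end()));
    } else if (ps.gamma.n_elem) {
      out[i] = List::create(
        _["gamma"] = NumericVector(ps.gamma.begin(), ps.gamma.end()),
        _["beta"] = NumericVector(ps.beta.begin(), ps.beta.end()),
        _["rmean"] = NumericVector(ps.rmean.begin(), ps.rmean.end()),
        _["rvar"] = NumericVector(ps.rvar.begin(), ps.rvar.end()));
    } else {
      out[i] = R_NilValue;
    }
  }
  return out;
}
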