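#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Convolutional motion encoder: maps one standardized projection image to
// nine motion-basis coefficients. Six 3x3 stride-2 convolutions (channels
// 2,4,8,16,32,32), each followed by batch normalization and ReLU, then a
// flatten and one linear layer with nine outputs.
//
// Activations use [n][c][h][w] layout (w fastest). Parameters arrive as a
// flat list: for each conv layer W (3x3xCinxCout), b, gamma, beta; then the
// linear W (K x 9) and b (9). Batch statistics are computed here in training
// mode and returned so the caller can maintain running averages.

static const double BN_EPS = 1e-5;

struct LayerCache {
  std::vector<double> conv;   // pre-BN
  std::vector<double> xhat;   // normalized
  std::vector<double> act;    // post-ReLU
  std::vector<double> mean, var;
  int C, H, W;
};

static inline int conv_out(int n) { return (n - 1) / 2 + 1; }

static void conv_forward(const std::vector<double>& in, int n, int Cin,
                         int H, int W, const double* wt, const double* b,
                         int Cout, std::vector<double>& out, int& Ho,
                         int& Wo) {
  Ho = conv_out(H); Wo = conv_out(W);
  out.assign((size_t)n * Cout * Ho * Wo, 0.0);
  for (int ni = 0; ni < n; ++ni)
    for (int co = 0; co < Cout; ++co) {
      double* op = out.data() + ((size_t)ni * Cout + co) * Ho * Wo;
      for (int ho = 0; ho < Ho; ++ho)
        for (int wo = 0; wo < Wo; ++wo) {
          double s = b[co];
          for (int ci = 0; ci < Cin; ++ci) {
            const double* ip = in.data() + ((size_t)ni * Cin + ci) * H * W;
            for (int kh = 0; kh < 3; ++kh) {
              int h = ho * 2 - 1 + kh;
              if (h < 0 || h >= H) continue;
              for (int kw = 0; kw < 3; ++kw) {
                int w2 = wo * 2 - 1 + kw;
                if (w2 < 0 || w2 >= W) continue;
                s += wt[kh + 3 * (kw + 3 * (ci + (size_t)Cin * co))] *
                     ip[(size_t)h * W + w2];
              }
            }
          }
          op[(size_t)ho * Wo + wo] = s;
        }
    }
}

static void conv_backward(const std::vector<double>& in, int n, int Cin,
                          int H, int W, const double* wt, int Cout,
                          const std::vector<double>& dout, int Ho, int Wo,
                          std::vector<double>& din, double* dwt, double* db) {
  din.assign(in.size(), 0.0);
  for (int ni = 0; ni < n; ++ni)
    for (int co = 0; co < Cout; ++co) {
      const double* dop = dout.data() + ((size_t)ni * Cout + co) * Ho * Wo;
      for (int ho = 0; ho < Ho; ++ho)
        for (int wo = 0; wo < Wo; ++wo) {
          double g = dop[(size_t)ho * Wo + wo];
          if (g == 0.0) continue;
          db[co] += g;
          for (int ci = 0; ci < Cin; ++ci) {
            const double* ip = in.data() + ((size_t)ni * Cin + ci) * H * W;
            double* dip = din.data() + ((size_t)ni * Cin + ci) * H * W;
            for (int kh = 0; kh < 3; ++kh) {
              int h = ho * 2 - 1 + kh;
              if (h < 0 || h >= H) continue;
              for (int kw = 0; kw < 3; ++kw) {
                int w2 = wo * 2 - 1 + kw;
                if (w2 < 0 || w2 >= W) continue;
                size_t widx = kh + 3 * (kw + 3 * (ci + (size_t)Cin * co));
                dwt[widx] += g * ip[(size_t)h * W + w2];
                dip[(size_t)h * W + w2] += g * wt[widx];
              }
            }
          }
        }
    }
}

static void encoder_run(const NumericVector& input, int H, int W, int n,
                        const List& params, const IntegerVector& channels,
                        bool training, const List& running,
                        std::vector<LayerCache>& caches,
                        std::vector<double>& flat, NumericMatrix& out) {
  const int L = channels.size();
  // input (H, W, n) column-major -> [n][1][h][w]
  std::vector<double> act((size_t)n * H * W);
  for (int ni = 0; ni < n; ++ni)
    for (int h = 0; h < H; ++h)
      for (int w = 0; w < W; ++w)
        act[((size_t)ni * H + h) * W + w] =
            input[h + (size_t)H * (w + (size_t)W * ni)];
  int Cin = 1, Hc = H, Wc = W;
  caches.resize(L);
  for (int l = 0; l < L; ++l) {
    int Cout = channels[l];
    NumericVector Wt = params[4 * l], Bb = params[4 * l + 1];
    NumericVector Ga = params[4 * l + 2], Be = params[4 * l + 3];
    LayerCache& c = caches[l];
    int Ho, Wo;
    conv_forward(act, n, Cin, Hc, Wc, Wt.begin(), Bb.begin(), Cout, c.conv,
                 Ho, Wo);
    c.C = Cout; c.H = Ho; c.W = Wo;
    size_t plane = (size_t)Ho * Wo;
    size_t per_ch = (size_t)n * plane;
    c.mean.assign(Cout, 0.0);
    c.var.assign(Cout, 0.0);
    if (training) {
      for (int co = 0; co < Cout; ++co) {
        double s = 0, s2 = 0;
        for (int ni = 0; ni < n; ++ni) {
          const double* p = c.conv.data() + ((size_t)ni * Cout + co) * plane;
          for (size_t i = 0; i < plane; ++i) { s += p[i]; s2 += p[i] * p[i]; }
        }
        double m = s / per_ch;
        c.mean[co] = m;
        c.var[co] = s2 / per_ch - m * m;
        if (c.var[co] < 0) c.var[co] = 0;
      }
    } else {
      NumericVector rm = as<List>(running[l])["mean"];
      NumericVector rv = as<List>(running[l])["var"];
      for (int co = 0; co < Cout; ++co) { c.mean[co] = rm[co]; c.var[co] = rv[co]; }
    }
    c.xhat.resize(c.conv.size());
    c.act.resize(c.conv.size());
    for (int co = 0; co < Cout; ++co) {
      double inv = 1.0 / std::sqrt(c.var[co] + BN_EPS);
      double g = Ga[co], be = Be[co], m = c.mean[co];
      for (int ni = 0; ni < n; ++ni) {
        size_t off = ((size_t)ni * Cout + co) * plane;
        for (size_t i = 0; i < plane; ++i) {
          double xh = (c.conv[off + i] - m) * inv;
          c.xhat[off + i] = xh;
          double y = g * xh + be;
          c.act[off + i] = y > 0 ? y : 0.0;
        }
      }
    }
    act = c.act;
    Cin = Cout; Hc = Ho; Wc = Wo;
  }
  flat = act;  // [n][C][h][w], K = C*h*w per sample
  const size_t K = (size_t)Cin * Hc * Wc;
  NumericMatrix Wfc = params[4 * L];
  NumericVector bfc = params[4 * L + 1];
  if ((size_t)Wfc.nrow() != K)
    stop("encoder: linear layer expects %d inputs, got %d", Wfc.nrow(), (int)K);
  out = NumericMatrix(n, 9);
  for (int ni = 0; ni < n; ++ni)
    for (int j = 0; j < 9; ++j) {
      double s = bfc[j];
      const double* fp = flat.data() + (size_t)ni * K;
      for (size_t k = 0; k < K; ++k) s += Wfc(k, j) * fp[k];
      out(ni, j) = s;
    }
}

// [[Rcpp::export]]
List cpp_encoder_forward(NumericVector input, IntegerVector hw, int n,
                         List params, IntegerVector channels, bool training,
                         List running) {
  std::vector<LayerCache> caches;
  std::vector<double> flat;
  NumericMatrix out;
  encoder_run(input, hw[0], hw[1], n, params, channels, training, running,
              caches, flat, out);
  List stats(channels.size());
  for (int l = 0; l < channels.size(); ++l) {
    stats[l] = List::create(_["mean"] = NumericVector(caches[l].mean.begin(),
                                                      caches[l].mean.end()),
                            _["var"] = NumericVector(caches[l].var.begin(),
                                                     caches[l].var.end()));
  }
  return List::create(_["coeffs"] = out, _["batch_stats"] = stats);
}

// Forward + backward in one call (training mode batch statistics).
// upstream: n x 9 gradient of the loss w.r.t. the coefficients.
// [[Rcpp::export]]
List cpp_encoder_fwdbwd(NumericVector input, IntegerVector hw, int n,
                        List params, IntegerVector channels,
                        NumericMatrix upstream) {
  const int L = channels.size();
  std::vector<LayerCache> caches;
  std::vector<double> flat;
  NumericMatrix out;
  List dummy;
  encoder_run(input, hw[0], hw[1], n, params, channels, true, dummy, caches,
              flat, out);
  List grads(4 * L + 2);
  // linear backward
  const LayerCache& last = caches[L - 1];
  const size_t K = (size_t)last.C * last.H * last.W;
  NumericMatrix Wfc = params[4 * L];
  NumericMatrix dWfc(K, 9);
  NumericVector dbfc(9);
  std::vector<double> dflat((size_t)n * K, 0.0);
  for (int ni = 0; ni < n; ++ni)
    for (int j = 0; j < 9; ++j) {
      double g = upstream(ni, j);
      if (g == 0.0) continue;
      dbfc[j] += g;
      const double* fp = flat.data() + (size_t)ni * K;
      for (size_t k = 0; k < K; ++k) {
        dWfc(k, j) += g * fp[k];
        dflat[(size_t)ni * K + k] += g * Wfc(k, j);
      }
    }
  grads[4 * L] = dWfc;
  grads[4 * L + 1] = dbfc;
  std::vector<double> dact = dflat;  // gradient at post-ReLU of last layer
  for (int l = L - 1; l >= 0; --l) {
    const LayerCache& c = caches[l];
    NumericVector Wt = params[4 * l];
    NumericVector Ga = params[4 * l + 2];
    size_t plane = (size_t)c.H * c.W;
    size_t per_ch = (size_t)n * plane;
    // ReLU backward
    std::vector<double> dy(c.conv.size());
    for (size_t i = 0; i < dy.size(); ++i)
      dy[i] = c.act[i] > 0 ? dact[i] : 0.0;
    // BN backward
    NumericVector dGa(c.C), dBe(c.C);
    std::vector<double> dconv(c.conv.size());
    for (int co = 0; co < c.C; ++co) {
      double sum_dy = 0, sum_dyxh = 0;
      for (int ni = 0; ni < n; ++ni) {
        size_t off = ((size_t)ni * c.C + co) * plane;
        for (size_t i = 0; i < plane; ++i) {
          sum_dy += dy[off + i];
          sum_dyxh += dy[off + i] * c.xhat[off + i];
        }
      }
      dBe[co] = sum_dy;
      dGa[co] = sum_dyxh;
      double inv = 1.0 / std::sqrt(c.var[co] + BN_EPS);
      double g = Ga[co];
      double m_dy = sum_dy / per_ch, m_dyxh = sum_dyxh / per_ch;
      for (int ni = 0; ni < n; ++ni) {
        size_t off = ((size_t)ni * c.C + co) * plane;
        for (size_t i = 0; i < plane; ++i)
          dconv[off + i] = g * inv *
              (dy[off + i] - m_dy - c.xhat[off + i] * m_dyxh);
      }
    }
    grads[4 * l + 2] = dGa;
    grads[4 * l + 3] = dBe;
    // conv backward
    int Cin = l == 0 ? 1 : channels[l - 1];
    int Hin, Win;
    std::vector<double> in_act;
    if (l == 0) {
      Hin = hw[0]; Win = hw[1];
      in_act.resize((size_t)n * Hin * Win);
      for (int ni = 0; ni < n; ++ni)
        for (int h = 0; h < Hin; ++h)
          for (int w = 0; w < Win; ++w)
            in_act[((size_t)ni * Hin + h) * Win + w] =
                input[h + (size_t)Hin * (w + (size_t)Win * ni)];
    } else {
      Hin = caches[l - 1].H; Win = caches[l - 1].W;
      in_act = caches[l - 1].act;
    }
    NumericVector dWt((size_t)9 * Cin * c.C);
    NumericVector db(c.C);
    std::vector<double> din;
    conv_backward(in_act, n, Cin, Hin, Win, Wt.begin(), c.C, dconv, c.H, c.W,
                  din, dWt.begin(), db.begin());
    dWt.attr("dim") = IntegerVector::create(3, 3, Cin, c.C);
    grads[4 * l] = dWt;
    grads[4 * l + 1] = db;
    dact = din;
  }
  List stats(L);
  for (int l = 0; l < L; ++l)
    stats[l] = List::create(_["mean"] = NumericVector(caches[l].mean.begin(),
                                                      caches[l].mean.end()),
                            _["var"] = NumericVector(caches[l].var.begin(),
                                                     caches[l].var.end()));
  return List::create(_["coeffs"] = out, _["grads"] = grads,
                      _["batch_stats"] = stats);
}
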