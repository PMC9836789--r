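// Minimal CNN graph engine: float32 tensors, im2col+GEMM convolutions,
// spatial batch norm, max/avg pooling, channel concat, elementwise add,
// generalized-mean (GeM) global pooling, dense layer, softmax cross-entropy,
// Adam, and gradient capture at arbitrary nodes (Grad-CAM).
//
// Layout: a feature map of one sample is an (H*W x C) float matrix with
// pixel index p = y + H*x (column-major, identical to R's array flattening),
// a batch is an fcube (H*W, C, N). Conv weights are (k*k*cin x cout) with
// row index dy + k*dx + k*k*c; R initialises them as flat matrices so only
// the engine needs this ordering to be self-consistent.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct Tens {
  int H = 0, W = 0, C = 0, N = 0;
  arma::fcube a;  // (H*W, C, N)
  void alloc(int H_, int W_, int C_, int N_) {
    H = H_; W = W_; C = C_; N = N_;
    a.set_size((size_t)H * W, C, N);
  }
};

struct Adam {
  arma::fmat m, v;
  bool init = false;
  void step(arma::fmat& w, const arma::fmat& g, double lr, double t) {
    if (!init) { m.zeros(w.n_rows, w.n_cols); v.zeros(w.n_rows, w.n_cols); init = true; }
    const double b1 = 0.9, b2 = 0.999;
    m = (float)b1 * m + (float)(1 - b1) * g;
    v = (float)b2 * v + (float)(1 - b2) * (g % g);
    double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
    w -= (float)(lr / c1) * (m / (arma::sqrt(v / (float)c2) + 1e-8f));
  }
};

struct Node {
  std::string name, op;
  std::vector<int> in;
  int H = 0, W = 0, C = 0;           // output shape
  int k = 0, stride = 1, pad = 0;    // conv/pool geometry
  int cin = 0, cout = 0;
  bool bias = true;
  double gem_p = 4.0; float gem_eps = 1e-6f;
  float bn_eps = 1e-5f, bn_mom = 0.1f;

  arma::fmat Wt, dW;                 // conv/dense weights
  arma::fvec b, db;                  // bias
  arma::fvec gamma, beta, dgamma, dbeta, run_mean, run_var;  // batch norm
  Adam aW, ab, ag, abt;

  Tens out, grad;
  arma::fvec bn_mean, bn_invstd;
  arma::Cube<arma::uword> mp_idx;    // argmax cache (maxpool / gem p=Inf)
  arma::fmat colbuf, dXbuf;          // reused conv work buffers
};

static void im2col(arma::fmat& col, const arma::fmat& X, int H, int W, int k,
                   int s, int pad, int Ho, int Wo) {
  int Cin = X.n_cols;
  col.set_size((size_t)Ho * Wo, (size_t)k * k * Cin);
  col.zeros();
  for (int c = 0; c < Cin; ++c) {
    const float* xc = X.colptr(c);
    for (int dx = 0; dx < k; ++dx)
      for (int dy = 0; dy < k; ++dy) {
        float* cc = col.colptr((size_t)c * k * k + (size_t)dx * k + dy);
        if (s == 1) {  // contiguous vertical runs: block copies
          int yo0 = std::max(0, pad - dy);
          int yo1 = std::min(Ho - 1, H - 1 + pad - dy);
          if (yo1 < yo0) continue;
          size_t len = (size_t)(yo1 - yo0 + 1);
          for (int xo = 0; xo < Wo; ++xo) {
            int xi = xo - pad + dx;
            if (xi < 0 || xi >= W) continue;
            std::memcpy(cc + yo0 + (size_t)Ho * xo,
                        xc + (yo0 - pad + dy) + (size_t)H * xi,
                        len * sizeof(float));
          }
        } else {
          for (int xo = 0; xo < Wo; ++xo) {
            int xi = xo * s - pad + dx;
            if (xi < 0 || xi >= W) continue;
            for (int yo = 0; yo < Ho; ++yo) {
              int yi = yo * s - pad + dy;
              if (yi < 0 || yi >= H) continue;
              cc[yo + (size_t)Ho * xo] = xc[yi + (size_t)H * xi];
            }
          }
        }
      }
  }
}

static bool convIsPointwise(int k, int s, int pad) {
  return k == 1 && s == 1 && pad == 0;
}

static void col2im_add(arma::fmat& dX, const arma::fmat& dcol, int H, int W,
                       int k, int s, int pad, int Ho, int Wo) {
  int Cin = dX.n_cols;
  for (int c = 0; c < Cin; ++c) {
    float* xc = dX.colptr(c);
    for (int dx = 0; dx < k; ++dx)
      for (int dy = 0; dy < k; ++dy) {
        const float* cc = dcol.colptr((size_t)c * k * k + (size_t)dx * k + dy);
        if (s == 1) {
          int yo0 = std::max(0, pad - dy);
          int yo1 = std::min(Ho - 1, H - 1 + pad - dy);
          if (yo1 < yo0) continue;
          int len = yo1 - yo0 + 1;
          for (int xo = 0; xo < Wo; ++xo) {
            int xi = xo - pad + dx;
            if (xi < 0 || xi >= W) continue;
            float* xdst = xc + (yo0 - pad + dy) + (size_t)H * xi;
            const float* csrc = cc + yo0 + (size_t)Ho * xo;
            for (int i = 0; i < len; ++i) xdst[i] += csrc[i];
          }
        } else {
          for (int xo = 0; xo < Wo; ++xo) {
            int xi = xo * s - pad + dx;
            if (xi < 0 || xi >= W) continue;
            for (int yo = 0; yo < Ho; ++yo) {
              int yi = yo * s - pad + dy;
              if (yi < 0 || yi >= H) continue;
              xc[yi + (size_t)H * xi] += cc[yo + (size_t)Ho * xo];
            }
          }
        }
      }
  }
}

class Network {
 public:
  std::vector<Node> nodes;
  int inH = 0, inW = 0, inC = 0;
  double adam_t = 0;

  int find(const std::string& nm) const {
    for (size_t i = 0; i < nodes.size(); ++i)
      if (nodes[i].name == nm) return (int)i;
    stop("unknown node: " + nm);
    return -1;
  }

  void build(List spec) {
    IntegerVector ins = spec["input"];
    inH = ins[0]; inW = ins[1]; inC = ins[2];
    List nl = spec["nodes"];
    for (int i = 0; i < nl.size(); ++i) {
      List nd = nl[i];
      Node n;
      n.name = as<std::string>(nd["name"]);
      n.op = as<std::string>(nd["op"]);
      if (nd.containsElementNamed("inputs")) {
        CharacterVector iv = nd["inputs"];
        for (int j = 0; j < iv.size(); ++j) {
          int idx = find(as<std::string>(iv[j]));
          if (idx >= (int)nodes.size()) stop("inputs must precede node " + n.name);
          n.in.push_back(idx);
        }
      }
      auto geti = [&](const char* f, int d) {
        return nd.containsElementNamed(f) ? as<int>(nd[f]) : d; };
      auto getd = [&](const char* f, double d) {
        return nd.containsElementNamed(f) ? as<double>(nd[f]) : d; };

      if (n.op == "input") {
        n.H = inH; n.W = inW; n.C = inC;
      } else if (n.op == "conv") {
        const Node& p = nodes[n.in[0]];
        n.k = geti("k", 3); n.stride = geti("stride", 1); n.pad = geti("pad", 0);
        n.cin = p.C; n.cout = geti("cout", p.C);
        n.bias = nd.containsElementNamed("bias") ? as<bool>(nd["bias"]) : true;
        n.H = (p.H + 2 * n.pad - n.k) / n.stride + 1;
        n.W = (p.W + 2 * n.pad - n.k) / n.stride + 1;
        if (n.H < 1 || n.W < 1 || p.H + 2 * n.pad < n.k)
          stop("conv '" + n.name + "': kernel exceeds padded input");
        n.C = n.cout;
        n.Wt.zeros((size_t)n.k * n.k * n.cin, n.cout);
        if (n.bias) n.b.zeros(n.cout);
      } else if (n.op == "maxpool" || n.op == "avgpool") {
        const Node& p = nodes[n.in[0]];
        n.k = geti("k", 2); n.stride = geti("stride", n.k); n.pad = geti("pad", 0);
        n.H = (p.H + 2 * n.pad - n.k) / n.stride + 1;
        n.W = (p.W + 2 * n.pad - n.k) / n.stride + 1;
        if (n.H < 1 || n.W < 1) stop("pool '" + n.name + "': window exceeds input");
        n.C = p.C;
      } else if (n.op == "bn") {
        const Node& p = nodes[n.in[0]];
        n.H = p.H; n.W = p.W; n.C = p.C;
        n.gamma.ones(n.C); n.beta.zeros(n.C);
        n.run_mean.zeros(n.C); n.run_var.ones(n.C);
      } else if (n.op == "relu") {
        const Node& p = nodes[n.in[0]];
        n.H = p.H; n.W = p.W; n.C = p.C;
      } else if (n.op == "concat") {
        const Node& p0 = nodes[n.in[0]];
        n.H = p0.H; n.W = p0.W; n.C = 0;
        for (int idx : n.in) {
          if (nodes[idx].H != n.H || nodes[idx].W != n.W)
            stop("concat '" + n.name + "': spatial shape mismatch");
          n.C += nodes[idx].C;
        }
      } else if (n.op == "add") {
        const Node& p0 = nodes[n.in[0]], &p1 = nodes[n.in[1]];
        if (p0.H != p1.H || p0.W != p1.W || p0.C != p1.C)
          stop("add '" + n.name + "': shape mismatch");
        n.H = p0.H; n.W = p0.W; n.C = p0.C;
      } else if (n.op == "gem") {
        const Node& p = nodes[n.in[0]];
        n.gem_p = getd("p", 4.0);
        n.gem_eps = (float)getd("eps", 1e-6);
        if (!std::isinf(n.gem_p) && n.gem_p < 1.0)
          stop("gem '" + n.name + "': p must be >= 1");
        n.H = 1; n.W = 1; n.C = p.C;
      } else if (n.op == "dense") {
        const Node& p = nodes[n.in[0]];
        if (p.H != 1 || p.W != 1) stop("dense '" + n.name + "': input must be pooled");
        n.cin = p.C; n.cout = geti("cout", 7);
        n.H = 1; n.W = 1; n.C = n.cout;
        n.Wt.zeros(n.cin, n.cout);
        n.b.zeros(n.cout);
      } else {
        stop("unknown op: " + n.op);
      }
      nodes.push_back(std::move(n));
    }
  }

  double nParams() const {
    double s = 0;
    for (const Node& n : nodes) {
      s += n.Wt.n_elem + n.b.n_elem + n.gamma.n_elem + n.beta.n_elem;
    }
    return s;
  }

  void forward(const arma::fcube& x, bool training, int upto = -1) {
    int N = x.n_slices;
    int last = upto < 0 ? (int)nodes.size() - 1 : upto;
    for (int i = 0; i <= last; ++i) {
      Node& n = nodes[i];
      if (n.op == "input") {
        n.out.alloc(inH, inW, inC, N);
        n.out.a = x;
        continue;
      }
      const Tens& A = nodes[n.in[0]].out;
      n.out.alloc(n.H, n.W, n.C, N);
      if (n.op == "conv") {
        bool pw = convIsPointwise(n.k, n.stride, n.pad);
        for (int s = 0; s < N; ++s) {
          if (pw) {
            n.out.a.slice(s) = A.a.slice(s) * n.Wt;
          } else {
            im2col(n.colbuf, A.a.slice(s), A.H, A.W, n.k, n.stride, n.pad, n.H, n.W);
            n.out.a.slice(s) = n.colbuf * n.Wt;
          }
          if (n.bias) n.out.a.slice(s).each_row() += n.b.t();
        }
      } else if (n.op == "maxpool") {
        n.mp_idx.set_size((size_t)n.H * n.W, n.C, N);
        for (int s = 0; s < N; ++s) {
          const arma::fmat& X = A.a.slice(s);
          arma::fmat& Y = n.out.a.slice(s);
          for (int c = 0; c < n.C; ++c) {
            const float* xc = X.colptr(c);
            float* yc = Y.colptr(c);
            for (int xo = 0; xo < n.W; ++xo)
              for (int yo = 0; yo < n.H; ++yo) {
                float best = -std::numeric_limits<float>::infinity();
                arma::uword bi = 0;
                for (int dx = 0; dx < n.k; ++dx) {
                  int xi = xo * n.stride - n.pad + dx;
                  if (xi < 0 || xi >= A.W) continue;
                  for (int dy = 0; dy < n.k; ++dy) {
                    int yi = yo * n.stride - n.pad + dy;
                    if (yi < 0 || yi >= A.H) continue;
                    float v = xc[yi + (size_t)A.H * xi];
                    if (v > best) { best = v; bi = yi + (size_t)A.H * xi; }
                  }
                }
                yc[yo + (size_t)n.H * xo] = best;
                n.mp_idx(yo + (size_t)n.H * xo, c, s) = bi;
              }
          }
        }
      } else if (n.op == "avgpool") {
        for (int s = 0; s < N; ++s) {
          const arma::fmat& X = A.a.slice(s);
          arma::fmat& Y = n.out.a.slice(s);
          for (int c = 0; c < n.C; ++c) {
            const float* xc = X.colptr(c);
            float* yc = Y.colptr(c);
            for (int xo = 0; xo < n.W; ++xo)
              for (int yo = 0; yo < n.H; ++yo) {
                float acc = 0; int cnt = 0;
                for (int dx = 0; dx < n.k; ++dx) {
                  int xi = xo * n.stride - n.pad + dx;
                  if (xi < 0 || xi >= A.W) continue;
                  for (int dy = 0; dy < n.k; ++dy) {
                    int yi = yo * n.stride - n.pad + dy;
                    if (yi < 0 || yi >= A.H) continue;
                    acc += xc[yi + (size_t)A.H * xi]; ++cnt;
                  }
                }
                yc[yo + (size_t)n.H * xo] = cnt ? acc / cnt : 0.0f;
              }
          }
        }
      } else if (n.op == "bn") {
        size_t M = (size_t)A.H * A.W * N;
        if (training) {
          n.bn_mean.set_size(n.C); n.bn_invstd.set_size(n.C);
          for (int c = 0; c < n.C; ++c) {
            double mu = 0, ss = 0;
            for (int s = 0; s < N; ++s) {
              const float* xc = A.a.slice(s).colptr(c);
              for (size_t p = 0; p < (size_t)A.H * A.W; ++p) { mu += xc[p]; ss += (double)xc[p] * xc[p]; }
            }
            mu /= M;
            double var = ss / M - mu * mu;
            if (var < 0) var = 0;
            n.bn_mean[c] = (float)mu;
            n.bn_invstd[c] = (float)(1.0 / std::sqrt(var + n.bn_eps));
            n.run_mean[c] = (1.0f - n.bn_mom) * n.run_mean[c] + n.bn_mom * (float)mu;
            n.run_var[c] = (1.0f - n.bn_mom) * n.run_var[c] + n.bn_mom * (float)var;
          }
        } else {
          n.bn_mean = n.run_mean;
          n.bn_invstd = 1.0f / arma::sqrt(n.run_var + n.bn_eps);
        }
        for (int s = 0; s < N; ++s)
          for (int c = 0; c < n.C; ++c)
            n.out.a.slice(s).col(c) =
              (A.a.slice(s).col(c) - n.bn_mean[c]) * (n.bn_invstd[c] * n.gamma[c]) + n.beta[c];
      } else if (n.op == "relu") {
        n.out.a = arma::clamp(A.a, 0.0f, std::numeric_limits<float>::max());
      } else if (n.op == "concat") {
        for (int s = 0; s < N; ++s) {
          size_t off = 0;
          for (int idx : n.in) {
            const Tens& B = nodes[idx].out;
            n.out.a.slice(s).cols(off, off + B.C - 1) = B.a.slice(s);
            off += B.C;
          }
        }
      } else if (n.op == "add") {
        n.out.a = nodes[n.in[0]].out.a + nodes[n.in[1]].out.a;
      } else if (n.op == "gem") {
        size_t HW = (size_t)A.H * A.W;
        if (std::isinf(n.gem_p)) {
          n.mp_idx.set_size(1, n.C, N);
          for (int s = 0; s < N; ++s)
            for (int c = 0; c < n.C; ++c) {
              arma::uword bi;
              n.out.a.slice(s)(0, c) = A.a.slice(s).col(c).max(bi);
              n.mp_idx(0, c, s) = bi;
            }
        } else {
          float p = (float)n.gem_p;
          for (int s = 0; s < N; ++s)
            for (int c = 0; c < n.C; ++c) {
              const float* xc = A.a.slice(s).colptr(c);
              double acc = 0;
              for (size_t q = 0; q < HW; ++q)
                acc += std::pow((double)xc[q] + n.gem_eps, p);
              n.out.a.slice(s)(0, c) = (float)std::pow(acc / HW, 1.0 / p);
            }
        }
      } else if (n.op == "dense") {
        for (int s = 0; s < N; ++s)
          n.out.a.slice(s) = A.a.slice(s) * n.Wt + n.b.t();
      }
    }
  }

  // Backward from a gradient placed at node `from` (default: last). When
  // param_grads is false only input gradients are propagated (Grad-CAM).
  void backward(bool param_grads = true, int from = -1) {
    int start = from < 0 ? (int)nodes.size() - 1 : from;
    int N = nodes[0].out.N;
    for (int i = 0; i <= start; ++i) {
      Node& n = nodes[i];
      if (i < start) n.grad.a.reset();  // gradients are allocated lazily
      if (param_grads) {
        if (n.Wt.n_elem) { n.dW.zeros(n.Wt.n_rows, n.Wt.n_cols); if (n.bias || n.op == "dense") n.db.zeros(n.b.n_elem); }
        if (n.gamma.n_elem) { n.dgamma.zeros(n.C); n.dbeta.zeros(n.C); }
      }
    }
    auto ensureGrad = [&](Node& P) {
      if (P.grad.a.n_elem == 0) { P.grad.alloc(P.H, P.W, P.C, N); P.grad.a.zeros(); }
    };
    for (int i = start; i >= 0; --i) {
      Node& n = nodes[i];
      if (n.op == "input") continue;
      if (n.grad.a.n_elem == 0) continue;  // node not on the path to `from`
      Node& P = nodes[n.in[0]];
      ensureGrad(P);
      for (size_t j = 1; j < n.in.size(); ++j) ensureGrad(nodes[n.in[j]]);
      const arma::fcube& G = n.grad.a;
      if (n.op == "conv") {
        bool pw = convIsPointwise(n.k, n.stride, n.pad);
        for (int s = 0; s < N; ++s) {
          if (pw) {
            if (param_grads) {
              n.dW += P.out.a.slice(s).t() * G.slice(s);
              if (n.bias) n.db += arma::sum(G.slice(s), 0).t();
            }
            P.grad.a.slice(s) += G.slice(s) * n.Wt.t();
            continue;
          }
          if (param_grads) {
            im2col(n.colbuf, P.out.a.slice(s), P.H, P.W, n.k, n.stride, n.pad, n.H, n.W);
            n.dW += n.colbuf.t() * G.slice(s);
            if (n.bias) n.db += arma::sum(G.slice(s), 0).t();
          }
          arma::fmat dcol = G.slice(s) * n.Wt.t();
          n.dXbuf.set_size(P.grad.a.slice(s).n_rows, P.C);
          n.dXbuf.zeros();
          col2im_add(n.dXbuf, dcol, P.H, P.W, n.k, n.stride, n.pad, n.H, n.W);
          P.grad.a.slice(s) += n.dXbuf;
        }
      } else if (n.op == "maxpool") {
        for (int s = 0; s < N; ++s)
          for (int c = 0; c < n.C; ++c) {
            const float* gc = G.slice(s).colptr(c);
            float* pc = P.grad.a.slice(s).colptr(c);
            for (size_t q = 0; q < (size_t)n.H * n.W; ++q)
              pc[n.mp_idx(q, c, s)] += gc[q];
          }
      } else if (n.op == "avgpool") {
        for (int s = 0; s < N; ++s) {
          const arma::fmat& Gs = G.slice(s);
          arma::fmat& Pg = P.grad.a.slice(s);
          for (int c = 0; c < n.C; ++c) {
            const float* gc = Gs.colptr(c);
            float* pc = Pg.colptr(c);
            for (int xo = 0; xo < n.W; ++xo)
              for (int yo = 0; yo < n.H; ++yo) {
                int cnt = 0;
                for (int dx = 0; dx < n.k; ++dx) {
                  int xi = xo * n.stride - n.pad + dx;
                  if (xi < 0 || xi >= P.W) continue;
                  for (int dy = 0; dy < n.k; ++dy) {
                    int yi = yo * n.stride - n.pad + dy;
                    if (yi >= 0 && yi < P.H) ++cnt;
                  }
                }
                float g = gc[yo + (size_t)n.H * xo] / cnt;
                for (int dx = 0; dx < n.k; ++dx) {
                  int xi = xo * n.stride - n.pad + dx;
                  if (xi < 0 || xi >= P.W) continue;
                  for (int dy = 0; dy < n.k; ++dy) {
                    int yi = yo * n.stride - n.pad + dy;
                    if (yi < 0 || yi >= P.H) continue;
                    pc[yi + (size_t)P.H * xi] += g;
                  }
                }
              }
          }
        }
      } else if (n.op == "bn") {
        size_t M = (size_t)n.H * n.W * N;
        for (int c = 0; c < n.C; ++c) {
          double sum_dy = 0, sum_dy_xhat = 0;
          for (int s = 0; s < N; ++s) {
            const float* gc = G.slice(s).colptr(c);
            const float* xc = P.out.a.slice(s).colptr(c);
            for (size_t q = 0; q < (size_t)n.H * n.W; ++q) {
              float xhat = (xc[q] - n.bn_mean[c]) * n.bn_invstd[c];
              sum_dy += gc[q];
              sum_dy_xhat += (double)gc[q] * xhat;
            }
          }
          if (param_grads) { n.dbeta[c] = (float)sum_dy; n.dgamma[c] = (float)sum_dy_xhat; }
          float k1 = n.gamma[c] * n.bn_invstd[c];
          float mdy = (float)(sum_dy / M), mdyx = (float)(sum_dy_xhat / M);
          for (int s = 0; s < N; ++s) {
            const float* gc = G.slice(s).colptr(c);
            const float* xc = P.out.a.slice(s).colptr(c);
            float* pc = P.grad.a.slice(s).colptr(c);
            for (size_t q = 0; q < (size_t)n.H * n.W; ++q) {
              float xhat = (xc[q] - n.bn_mean[c]) * n.bn_invstd[c];
              pc[q] += k1 * (gc[q] - mdy - xhat * mdyx);
            }
          }
        }
      } else if (n.op == "relu") {
        P.grad.a += G % arma::conv_to<arma::fcube>::from(n.out.a > 0.0f);
      } else if (n.op == "concat") {
        for (int s = 0; s < N; ++s) {
          size_t off = 0;
          for (int idx : n.in) {
            Node& B = nodes[idx];
            B.grad.a.slice(s) += G.slice(s).cols(off, off + B.C - 1);
            off += B.C;
          }
        }
      } else if (n.op == "add") {
        nodes[n.in[0]].grad.a += G;
        nodes[n.in[1]].grad.a += G;
      } else if (n.op == "gem") {
        size_t HW = (size_t)P.H * P.W;
        if (std::isinf(n.gem_p)) {
          for (int s = 0; s < N; ++s)
            for (int c = 0; c < n.C; ++c)
              P.grad.a.slice(s)(n.mp_idx(0, c, s), c) += G.slice(s)(0, c);
        } else {
          float p = (float)n.gem_p;
          for (int s = 0; s < N; ++s)
            for (int c = 0; c < n.C; ++c) {
              float y = n.out.a.slice(s)(0, c);
              float g = G.slice(s)(0, c);
              const float* xc = P.out.a.slice(s).colptr(c);
              float* pc = P.grad.a.slice(s).colptr(c);
              // dy/dx = (1/HW) * y^(1-p) * (x+eps)^(p-1)
              float yp = std::pow(y, 1.0f - p);
              for (size_t q = 0; q < HW; ++q)
                pc[q] += g * yp * std::pow(xc[q] + n.gem_eps, p - 1.0f) / HW;
            }
        }
      } else if (n.op == "dense") {
        for (int s = 0; s < N; ++s) {
          if (param_grads) {
            n.dW += P.out.a.slice(s).t() * G.slice(s);
            n.db += G.slice(s).row(0).t();
          }
          P.grad.a.slice(s) += G.slice(s) * n.Wt.t();
        }
      }
      if (param_grads) {  // this node's output gradient is now fully consumed
        n.grad.a.reset();
        n.mp_idx.reset();
      }
    }
  }

  void adamStep(double lr) {
    adam_t += 1;
    for (Node& n : nodes) {
      if (n.Wt.n_elem) n.aW.step(n.Wt, n.dW, lr, adam_t);
      if (n.b.n_elem) { arma::fmat bm(n.b), bg(n.db); n.ab.step(bm, bg, lr, adam_t); n.b = bm.col(0); }
      if (n.gamma.n_elem) {
        arma::fmat gm(n.gamma), gg(n.dgamma); n.ag.step(gm, gg, lr, adam_t); n.gamma = gm.col(0);
        arma::fmat bm(n.beta), bg(n.dbeta); n.abt.step(bm, bg, lr, adam_t); n.beta = bm.col(0);
      }
    }
  }
};

static arma::fcube r2cube(NumericVector x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  size_t HW = (size_t)d[0] * d[1];
  arma::fcube a(HW, d[2], d[3]);
  const double* p = x.begin();
  float* q = a.memptr();
  for (size_t i = 0; i < a.n_elem; ++i) q[i] = (float)p[i];
  return a;
}

static NumericVector cube2r(const Tens& t) {
  NumericVector out((size_t)t.H * t.W * t.C * t.N);
  const float* q = t.a.memptr();
  for (size_t i = 0; i < out.size(); ++i) out[i] = q[i];
  out.attr("dim") = IntegerVector::create(t.H, t.W, t.C, t.N);
  return out;
}

// [[Rcpp::export]]
SEXP eng_build(List spec) {
  XPtr<Network> p(new Network(), true);
  p->build(spec);
  return p;
}

// [[Rcpp::export]]
double eng_nparams(SEXP xp) { return XPtr<Network>(xp)->nParams(); }

// [[Rcpp::export]]
List eng_shapes(SEXP xp) {
  XPtr<Network> net(xp);
  List out(net->nodes.size());
  CharacterVector nm(net->nodes.size());
  for (size_t i = 0; i < net->nodes.size(); ++i) {
    const Node& n = net->nodes[i];
    out[i] = IntegerVector::create(n.H, n.W, n.C);
    nm[i] = n.name;
  }
  out.attr("names") = nm;
  return out;
}

// [[Rcpp::export]]
void eng_set_weights(SEXP xp, List w) {
  XPtr<Network> net(xp);
  CharacterVector nm = w.names();
  for (int i = 0; i < w.size(); ++i) {
    Node& n = net->nodes[net->find(as<std::string>(nm[i]))];
    List e = w[i];
    if (e.containsElementNamed("W")) {
      NumericMatrix Wm = e["W"];
      if ((size_t)Wm.nrow() != n.Wt.n_rows || (size_t)Wm.ncol() != n.Wt.n_cols)
        stop("weight shape mismatch at node " + n.name);
      for (size_t j = 0; j < n.Wt.n_elem; ++j) n.Wt[j] = (float)Wm[j];
    }
    if (e.containsElementNamed("b")) {
      NumericVector bv = e["b"];
      if ((size_t)bv.size() != n.b.n_elem)
        stop("bias length mismatch at node " + n.name);
      for (int j = 0; j < bv.size(); ++j) n.b[j] = (float)bv[j];
    }
    if (e.containsElementNamed("gamma")) {
      NumericVector g = e["gamma"], bt = e["beta"], rm = e["run_mean"], rv = e["run_var"];
      if ((size_t)g.size() != n.gamma.n_elem)
        stop("batch-norm length mismatch at node " + n.name);
      for (int j = 0; j < g.size(); ++j) {
        n.gamma[j] = (float)g[j]; n.beta[j] = (float)bt[j];
        n.run_mean[j] = (float)rm[j]; n.run_var[j] = (float)rv[j];
      }
    }
  }
}

// [[Rcpp::export]]
List eng_get_weights(SEXP xp) {
  XPtr<Network> net(xp);
  std::vector<std::string> nms;
  std::vector<List> els;
  for (const Node& n : net->nodes) {
    List e;
    if (n.Wt.n_elem) {
      NumericMatrix Wm(n.Wt.n_rows, n.Wt.n_cols);
      for (size_t j = 0; j < n.Wt.n_elem; ++j) Wm[j] = n.Wt[j];
      e["W"] = Wm;
      if (n.b.n_elem) {
        NumericVector bv(n.b.n_elem);
        for (size_t j = 0; j < n.b.n_elem; ++j) bv[j] = n.b[j];
        e["b"] = bv;
      }
    }
    if (n.gamma.n_elem) {
      e["gamma"] = NumericVector(n.gamma.begin(), n.gamma.end());
      e["beta"] = NumericVector(n.beta.begin(), n.beta.end());
      e["run_mean"] = NumericVector(n.run_mean.begin(), n.run_mean.end());
      e["run_var"] = NumericVector(n.run_var.begin(), n.run_var.end());
    }
    if (e.size()) { nms.push_back(n.name); els.push_back(e); }
  }
  List out(els.size());
  CharacterVector on(els.size());
  for (size_t i = 0; i < els.size(); ++i) { out[i] = els[i]; on[i] = nms[i]; }
  out.attr("names") = on;
  return out;
}

// [[Rcpp::export]]
NumericVector eng_forward(SEXP xp, NumericVector x, bool training = false) {
  XPtr<Network> net(xp);
  arma::fcube a = r2cube(x);
  if ((int)a.n_rows != net->inH * net->inW || (int)a.n_cols != net->inC)
    stop("input shape mismatch: expected " + std::to_string(net->inH) + "x" +
         std::to_string(net->inW) + "x" + std::to_string(net->inC));
  net->forward(a, training);
  return cube2r(net->nodes.back().out);
}

// [[Rcpp::export]]
NumericVector eng_node_output(SEXP xp, std::string name) {
  XPtr<Network> net(xp);
  return cube2r(net->nodes[net->find(name)].out);
}

// [[Rcpp::export]]
List eng_train_step(SEXP xp, NumericVector x, IntegerVector labels, double lr) {
  XPtr<Network> net(xp);
  arma::fcube a = r2cube(x);
  int N = a.n_slices;
  net->forward(a, true);
  Node& last = net->nodes.back();
  int C = last.C;
  arma::fmat P(N, C), dL(N, C);
  double loss = 0;
  for (int s = 0; s < N; ++s) {
    arma::frowvec z = last.out.a.slice(s).row(0);
    z -= z.max();
    arma::frowvec e = arma::exp(z);
    arma::frowvec pr = e / arma::accu(e);
    P.row(s) = pr;
    int y = labels[s];
    if (y < 0 || y >= C) stop("label out of range");
    loss += -std::log(std::max(pr[y], 1e-12f));
  }
  loss /= N;
  if (!std::isfinite(loss)) stop("divergence: non-finite loss");
  last.grad.alloc(1, 1, C, N);
  for (int s = 0; s < N; ++s) {
    arma::frowvec g = P.row(s);
    g[labels[s]] -= 1.0f;
    last.grad.a.slice(s).row(0) = g / N;
  }
  net->backward(true);
  net->adamStep(lr);
  NumericMatrix Pr(N, C);
  for (int s = 0; s < N; ++s) for (int c = 0; c < C; ++c) Pr(s, c) = P(s, c);
  return List::create(_["loss"] = loss, _["probs"] = Pr);
}

// Recompute batch-norm running statistics from one batch: a training-mode
// forward with momentum forced to `mom`, leaving weights untouched. Calling
// with mom = 1/b for batches b = 1..B accumulates the exact mean of the
// per-batch statistics over a whole set.
// [[Rcpp::export]]
void eng_calibrate_bn(SEXP xp, NumericVector x, double mom = 1.0) {
  XPtr<Network> net(xp);
  std::vector<float> moms;
  for (Node& n : net->nodes) { moms.push_back(n.bn_mom); n.bn_mom = (float)mom; }
  arma::fcube a = r2cube(x);
  net->forward(a, true);
  for (size_t i = 0; i < net->nodes.size(); ++i) net->nodes[i].bn_mom = moms[i];
}

// Training-mode loss and parameter gradients without an optimizer step
// (used by finite-difference gradient tests).
// [[Rcpp::export]]
List eng_loss_grads(SEXP xp, NumericVector x, IntegerVector labels) {
  XPtr<Network> net(xp);
  arma::fcube a = r2cube(x);
  int N = a.n_slices;
  net->forward(a, true);
  Node& last = net->nodes.back();
  int C = last.C;
  double loss = 0;
  arma::fmat P(N, C);
  for (int s = 0; s < N; ++s) {
    arma::frowvec z = last.out.a.slice(s).row(0);
    z -= z.max();
    arma::frowvec e = arma::exp(z);
    P.row(s) = e / arma::accu(e);
    loss += -std::log(std::max(P(s, labels[s]), 1e-12f));
  }
  loss /= N;
  last.grad.alloc(1, 1, C, N);
  for (int s = 0; s < N; ++s) {
    arma::frowvec g = P.row(s);
    g[labels[s]] -= 1.0f;
    last.grad.a.slice(s).row(0) = g / N;
  }
  net->backward(true);
  std::vector<std::string> nms;
  std::vector<List> els;
  for (const Node& n : net->nodes) {
    List e;
    if (n.dW.n_elem) {
      NumericMatrix Wm(n.dW.n_rows, n.dW.n_cols);
      for (size_t j = 0; j < n.dW.n_elem; ++j) Wm[j] = n.dW[j];
      e["dW"] = Wm;
      if (n.db.n_elem) e["db"] = NumericVector(n.db.begin(), n.db.end());
    }
    if (n.dgamma.n_elem) {
      e["dgamma"] = NumericVector(n.dgamma.begin(), n.dgamma.end());
      e["dbeta"] = NumericVector(n.dbeta.begin(), n.dbeta.end());
    }
    if (e.size()) { nms.push_back(n.name); els.push_back(e); }
  }
  List g(els.size());
  CharacterVector gn(els.size());
  for (size_t i = 0; i < els.size(); ++i) { g[i] = els[i]; gn[i] = nms[i]; }
  g.attr("names") = gn;
  return List::create(_["loss"] = loss, _["grads"] = g);
}

// Loss and probabilities without a parameter update (validation).
// [[Rcpp::export]]
List eng_eval(SEXP xp, NumericVector x, IntegerVector labels) {
  XPtr<Network> net(xp);
  arma::fcube a = r2cube(x);
  int N = a.n_slices;
  net->forward(a, false);
  Node& last = net->nodes.back();
  int C = last.C;
  NumericMatrix Pr(N, C);
  double loss = 0;
  for (int s = 0; s < N; ++s) {
    arma::frowvec z = last.out.a.slice(s).row(0);
    z -= z.max();
    arma::frowvec e = arma::exp(z);
    arma::frowvec pr = e / arma::accu(e);
    for (int c = 0; c < C; ++c) Pr(s, c) = pr[c];
    if (labels.size() == N)
      loss += -std::log(std::max(pr[labels[s]], 1e-12f));
  }
  return List::create(_["loss"] = labels.size() == N ? loss / N : NA_REAL,
                      _["probs"] = Pr);
}

// Gradient of the target-class logit w.r.t. a named node's activations,
// combined Grad-CAM style: w_c = spatial mean of the gradient, map =
// ReLU(sum_c w_c * A_c), returned at the node's spatial resolution.
// [[Rcpp::export]]
NumericMatrix eng_gradcam(SEXP xp, NumericVector x, int cls, std::string node) {
  XPtr<Network> net(xp);
  arma::fcube a = r2cube(x);
  if (a.n_slices != 1) stop("gradcam takes a single image");
  net->forward(a, false);
  Node& last = net->nodes.back();
  if (cls < 0 || cls >= last.C) stop("class index out of range");
  last.grad.alloc(1, 1, last.C, 1);
  last.grad.a.zeros();
  last.grad.a.slice(0)(0, cls) = 1.0f;
  net->backward(false);
  Node& t = net->nodes[net->find(node)];
  if (t.H < 2 || t.W < 2) stop("gradcam target must be a spatial (convolutional) node");
  const arma::fmat& A = t.out.a.slice(0);
  const arma::fmat& G = t.grad.a.slice(0);
  arma::frowvec w = arma::mean(G, 0);
  arma::fvec cam = A * w.t();
  cam = arma::clamp(cam, 0.0f, std::numeric_limits<float>::max());
  NumericMatrix out(t.H, t.W);
  for (size_t i = 0; i < cam.n_elem; ++i) out[i] = cam[i];
  return out;
}
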