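// Reverse-mode autodiff on dense matrices, sized for the small regression
// networks this package trains on phylogeny encodings. A Tape records the
// forward computation; backward() accumulates gradients node by node.
// Gradients are validated against numerical differentiation in the test
// suite, so every op keeps its adjoint next to its forward rule.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

enum Op {
  LEAF, MATMUL, MATMUL_TN, ADD, ADD_BIAS, SUB, MUL, GELU, SIGMOID, TANH_,
  SOFTMAX_ROWS, CONCAT_COLS, CONCAT_ROWS, COLMEANS, ROWSUMS, DIVROWS,
  BATCHNORM, SPMM, HUBER, LINK_LOSS_SP, LINK_LOSS_DN, ENTROPY_LOSS, SCALE,
  SCALE_ROWS, SLICE_COLS, SHIFT, ADDSCALED, LSTM_CELL
};

struct Node {
  mat val;
  mat grad;
  int op = LEAF;
  std::vector<int> in;
  vec aux;          // op-specific scalars
  mat extra;        // op-specific cache (BN xhat, masks, slices ...)
  mat extra2;
  bool need = false;
};

struct Tape {
  std::vector<Node> nodes;
  std::vector<sp_mat> spconst;   // sparse constants referenced by index

  int push(Node n) {
    for (int i : n.in) n.need = n.need || nodes[i].need;
    nodes.push_back(std::move(n));
    return (int)nodes.size() - 1;
  }
  int leaf(const mat& v, bool need) {
    Node n; n.val = v; n.need = need; return push(std::move(n));
  }
  const mat& v(int i) const { return nodes[i].val; }

  int matmul(int a, int b) {
    Node n; n.op = MATMUL; n.in = {a, b}; n.val = v(a) * v(b);
    return push(std::move(n));
  }
  int matmul_tn(int a, int b) { // a' * b
    Node n; n.op = MATMUL_TN; n.in = {a, b}; n.val = v(a).t() * v(b);
    return push(std::move(n));
  }
  int add(int a, int b) {
    Node n; n.op = ADD; n.in = {a, b}; n.val = v(a) + v(b);
    return push(std::move(n));
  }
  int addscaled(int a, int b, double c) { // a + c*b
    Node n; n.op = ADDSCALED; n.in = {a, b}; n.aux = {c};
    n.val = v(a) + c * v(b);
    return push(std::move(n));
  }
  int add_bias(int a, int b) { // b is 1 x k
    Node n; n.op = ADD_BIAS; n.in = {a, b};
    n.val = v(a).each_row() + v(b).row(0);
    return push(std::move(n));
  }
  int sub(int a, int b) {
    Node n; n.op = SUB; n.in = {a, b}; n.val = v(a) - v(b);
    return push(std::move(n));
  }
  int mul(int a, int b) {
    Node n; n.op = MUL; n.in = {a, b}; n.val = v(a) % v(b);
    return push(std::move(n));
  }
  int gelu(int a) {
    Node n; n.op = GELU; n.in = {a};
    n.val = v(a) % normcdf(v(a));
    return push(std::move(n));
  }
  int sigmoid(int a) {
    Node n; n.op = SIGMOID; n.in = {a};
    n.val = 1.0 / (1.0 + exp(-v(a)));
    return push(std::move(n));
  }
  int tanh_(int a) {
    Node n; n.op = TANH_; n.in = {a}; n.val = tanh(v(a));
    return push(std::move(n));
  }
  int softmax_rows(int a) {
    Node n; n.op = SOFTMAX_ROWS; n.in = {a};
    mat z = v(a).each_col() - max(v(a), 1);
    z = exp(z);
    n.val = z.each_col() / sum(z, 1);
    return push(std::move(n));
  }
  int concat_cols(const std::vector<int>& xs) {
    Node n; n.op = CONCAT_COLS; n.in = xs;
    uword k = 0, r = v(xs[0]).n_rows;
    for (int x : xs) k += v(x).n_cols;
    n.val.set_size(r, k);
    uword at = 0;
    for (int x : xs) { n.val.cols(at, at + v(x).n_cols - 1) = v(x); at += v(x).n_cols; }
    return push(std::move(n));
  }
  int concat_rows(const std::vector<int>& xs) {
    Node n; n.op = CONCAT_ROWS; n.in = xs;
    uword r = 0, k = v(xs[0]).n_cols;
    for (int x : xs) r += v(x).n_rows;
    n.val.set_size(r, k);
    uword at = 0;
    for (int x : xs) { n.val.rows(at, at + v(x).n_rows - 1) = v(x); at += v(x).n_rows; }
    return push(std::move(n));
  }
  int colmeans(int a) {
    Node n; n.op = COLMEANS; n.in = {a}; n.val = mean(v(a), 0);
    return push(std::move(n));
  }
  int rowsums(int a) {
    Node n; n.op = ROWSUMS; n.in = {a}; n.val = sum(v(a), 1);
    return push(std::move(n));
  }
  int divrows(int a, int r) { // divide each row i of a by r(i)
    Node n; n.op = DIVROWS; n.in = {a, r};
    n.val = v(a).each_col() / v(r).col(0);
    return push(std::move(n));
  }
  int shift(int a, double c) {
    Node n; n.op = SHIFT; n.in = {a}; n.val = v(a) + c;
    return push(std::move(n));
  }
  int scale(int a, double c) {
    Node n; n.op = SCALE; n.in = {a}; n.aux = {c}; n.val = c * v(a);
    return push(std::move(n));
  }
  int scale_rows(int a, const vec& m) { // constant row mask/scale
    Node n; n.op = SCALE_ROWS; n.in = {a}; n.extra = m;
    n.val = v(a).each_col() % m;
    return push(std::move(n));
  }
  int slice_cols(int a, uword from, uword to) {
    Node n; n.op = SLICE_COLS; n.in = {a};
    n.aux = {(double)from, (double)to, (double)v(a).n_cols};
    n.val = v(a).cols(from, to);
    return push(std::move(n));
  }
  // Batch normalisation over rows. training: batch statistics (population
  // variance), xhat cached for backward; else: supplied running statistics.
  int batchnorm(int x, int g, int b, const rowvec& rm, const rowvec& rv,
                bool training, double eps) {
    Node n; n.op = BATCHNORM; n.in = {x, g, b};
    rowvec mu, va;
    if (training) {
      mu = mean(v(x), 0);
      va = mean(square(v(x).each_row() - mu), 0);
    } else { mu = rm; va = rv; }
    rowvec invstd = 1.0 / sqrt(va + eps);
    mat xhat = (v(x).each_row() - mu).each_row() % invstd;
    n.val = (xhat.each_row() % v(g).row(0)).each_row() + v(b).row(0);
    n.extra = xhat;
    n.extra2 = join_cols(mat(invstd), mat(mu), mat(va));
    n.aux = {training ? 1.0 : 0.0};
    return push(std::move(n));
  }
  int spmm(int spidx, int x) { // constant sparse (spidx) times x
    Node n; n.op = SPMM; n.in = {x};
    n.aux = {(double)spidx};
    n.val = spconst[spidx] * v(x);
    return push(std::move(n));
  }
  int huber(int pred, int target, double delta) {
    Node n; n.op = HUBER; n.in = {pred, target};
    mat e = v(pred) - v(target);
    mat a = abs(e);
    mat l = 0.5 * square(a);
    uvec big = find(a > delta);
    l.elem(big) = delta * (a.elem(big) - 0.5 * delta);
    n.val = mat(1, 1, fill::value(accu(l) / e.n_elem));
    n.aux = {delta};
    n.extra = e;
    return push(std::move(n));
  }
  // || A - S S' ||_F / n_entries for sparse constant A (the reference
  // DiffPool scaling; the expanded form keeps everything
  // O(nnz * c + N * c^2) without materialising S S').
  int link_loss_sp(int s, int spidx, double norm) {
    Node n; n.op = LINK_LOSS_SP; n.in = {s};
    const sp_mat& A = spconst[spidx];
    const mat& S = v(s);
    mat StS = S.t() * S;
    double aa = 0.0;
    for (sp_mat::const_iterator it = A.begin(); it != A.end(); ++it)
      aa += (*it) * (*it);
    mat AS = A * S;
    double f2 = std::max(aa - 2.0 * accu(S % AS) + accu(square(StS)), 0.0);
    n.val = mat(1, 1, fill::value(std::sqrt(f2) / norm));
    n.aux = {(double)spidx, norm, std::sqrt(f2)};
    return push(std::move(n));
  }
  int link_loss_dn(int s, int a, double norm) { // dense A is itself a node
    Node n; n.op = LINK_LOSS_DN; n.in = {s, a};
    const mat& S = v(s); const mat& A = v(a);
    mat R = A - S * S.t();
    n.val = mat(1, 1, fill::value(std::sqrt(accu(square(R))) / norm));
    n.aux = {norm};
    n.extra = R;
    return push(std::move(n));
  }
  // Fused masked LSTM cell. Inputs: x (B x in), h_prev, c_prev (B x h),
  // Wx (in x 4h), Wh (h x 4h), b (1 x 4h); gate order i, f, g, o. Rows with
  // mask 0 (finished sequences) carry their state through unchanged, so
  // padding cannot influence the output. Value is [h_out | c_out] (B x 2h).
  int lstm_cell(int x, int h_prev, int c_prev, int Wx, int Wh, int b,
                const vec& m) {
    Node n; n.op = LSTM_CELL; n.in = {x, h_prev, c_prev, Wx, Wh, b};
    uword h = v(Wh).n_rows;
    mat Z = v(x) * v(Wx) + v(h_prev) * v(Wh);
    Z.each_row() += v(b).row(0);
    mat gi = 1.0 / (1.0 + exp(-Z.cols(0, h - 1)));
    mat gf = 1.0 / (1.0 + exp(-Z.cols(h, 2 * h - 1)));
    mat gg = tanh(Z.cols(2 * h, 3 * h - 1));
    mat go = 1.0 / (1.0 + exp(-Z.cols(3 * h, 4 * h - 1)));
    mat cnew = gf % v(c_prev) + gi % gg;
    mat tc = tanh(cnew);
    mat hnew = go % tc;
    mat hout = (hnew.each_col() % m) + (v(h_prev).each_col() % (1.0 - m));
    mat cout = (cnew.each_col() % m) + (v(c_prev).each_col() % (1.0 - m));
    n.val = join_rows(hout, cout);
    n.extra = join_rows(gi, gf, gg, go);   // B x 4h gate cache
    n.extra2 = tc;                         // B x h
    n.aux = vec(m);
    return push(std::move(n));
  }

  int entropy_loss(int s) { // mean over rows of -sum_c S log S
    Node n; n.op = ENTROPY_LOSS; n.in = {s};
    const double eps = 1e-12;
    n.val = mat(1, 1, fill::value(accu(-v(s) % log(v(s) + eps)) / v(s).n_rows));
    return push(std::move(n));
  }

  void backward(int out) {
    for (auto& n : nodes) n.grad.zeros(n.val.n_rows, n.val.n_cols);
    nodes[out].grad.ones(nodes[out].val.n_rows, nodes[out].val.n_cols);
    for (int i = out; i >= 0; --i) {
      Node& n = nodes[i];
      if (!n.need || n.op == LEAF) continue;
      const mat& G = n.grad;
      switch (n.op) {
      case MATMUL: {
        if (nodes[n.in[0]].need) nodes[n.in[0]].grad += G * v(n.in[1]).t();
        if (nodes[n.in[1]].need) nodes[n.in[1]].grad += v(n.in[0]).t() * G;
        break; }
      case MATMUL_TN: {
        if (nodes[n.in[0]].need) nodes[n.in[0]].grad += v(n.in[1]) * G.t();
        if (nodes[n.in[1]].need) nodes[n.in[1]].grad += v(n.in[0]) * G;
        break; }
      case ADD:
        if (nodes[n.in[0]].need) nodes[n.in[0]].grad += G;
        if (nodes[n.in[1]].need) nodes[n.in[1]].grad += G;
        break;
      case ADDSCALED:
        if (nodes[n.in[0]].need) nodes[n.in[0]].grad += G;
        if (nodes[n.in[1]].need) nodes[n.in[1]].grad += n.aux[0] * G;
        break;
      case ADD_BIAS:
        if (nodes[n.in[0]].need) nodes[n.in[0]].grad += G;
        if (nodes[n.in[1]].need) nodes[n.in[1]].grad += sum(G, 0);
        break;
      case SUB:
        if (nodes[n.in[0]].need) nodes[n.in[0]].grad += G;
        if (nodes[n.in[1]].need) nodes[n.in[1]].grad -= G;
        break;
      case MUL:
        if (nodes[n.in[0]].need) nodes[n.in[0]].grad += G % v(n.in[1]);
        if (nodes[n.in[1]].need) nodes[n.in[1]].grad += G % v(n.in[0]);
        break;
      case GELU: {
        const mat& x = v(n.in[0]);
        nodes[n.in[0]].grad += G % (normcdf(x) + x % normpdf(x));
        break; }
      case SIGMOID:
        nodes[n.in[0]].grad += G % (n.val % (1.0 - n.val));
        break;
      case TANH_:
        nodes[n.in[0]].grad += G % (1.0 - square(n.val));
        break;
      case SOFTMAX_ROWS: {
        mat gs = G % n.val;
        nodes[n.in[0]].grad += gs - (n.val.each_col() % sum(gs, 1));
        break; }
      case CONCAT_COLS: {
        uword at = 0;
        for (int x : n.in) {
          uword k = v(x).n_cols;
          if (nodes[x].need) nodes[x].grad += G.cols(at, at + k - 1);
          at += k;
        }
        break; }
      case CONCAT_ROWS: {
        uword at = 0;
        for (int x : n.in) {
          uword r = v(x).n_rows;
          if (nodes[x].need) nodes[x].grad += G.rows(at, at + r - 1);
          at += r;
        }
        break; }
      case COLMEANS: {
        mat& gx = nodes[n.in[0]].grad;
        gx.each_row() += G.row(0) / (double)gx.n_rows;
        break; }
      case ROWSUMS:
        nodes[n.in[0]].grad.each_col() += G.col(0);
        break;
      case DIVROWS: {
        const vec r = v(n.in[1]).col(0);
        if (nodes[n.in[0]].need)
          nodes[n.in[0]].grad += G.each_col() / r;
        if (nodes[n.in[1]].need)
          nodes[n.in[1]].grad -= sum(G % n.val, 1) / r;
        break; }
      case SHIFT:
        nodes[n.in[0]].grad += G;
        break;
      case SCALE:
        nodes[n.in[0]].grad += n.aux[0] * G;
        break;
      case SCALE_ROWS:
        nodes[n.in[0]].grad += G.each_col() % n.extra.col(0);
        break;
      case SLICE_COLS: {
        uword from = (uword)n.aux[0], to = (uword)n.aux[1];
        nodes[n.in[0]].grad.cols(from, to) += G;
        break; }
      case BATCHNORM: {
        const mat& xhat = n.extra;
        rowvec invstd = n.extra2.row(0);
        const rowvec gam = v(n.in[1]).row(0);
        bool training = n.aux[0] > 0.5;
        if (nodes[n.in[1]].need) nodes[n.in[1]].grad += sum(G % xhat, 0);
        if (nodes[n.in[2]].need) nodes[n.in[2]].grad += sum(G, 0);
        if (nodes[n.in[0]].need) {
          mat dxhat = G.each_row() % gam;
          if (training) {
            double m = (double)xhat.n_rows;
            rowvec s1 = sum(dxhat, 0), s2 = sum(dxhat % xhat, 0);
            mat dx = (dxhat * m - (xhat.each_row() % s2));
            dx.each_row() -= s1;
            dx.each_row() %= invstd / m;
            nodes[n.in[0]].grad += dx;
          } else {
            nodes[n.in[0]].grad += dxhat.each_row() % invstd;
          }
        }
        break; }
      case SPMM:
        nodes[n.in[0]].grad += spconst[(uword)n.aux[0]].t() * G;
        break;
      case HUBER: {
        double delta = n.aux[0], g = G(0, 0);
        nodes[n.in[0]].grad += clamp(n.extra, -delta, delta) *
                               (g / (double)n.extra.n_elem);
        break; }
      case LINK_LOSS_SP: {
        const sp_mat& A = spconst[(uword)n.aux[0]];
        const mat& S = v(n.in[0]);
        double fro = std::max(n.aux[2], 1e-12);
        double g = G(0, 0) / (n.aux[1] * 2.0 * fro);
        nodes[n.in[0]].grad += g * (-2.0 * (A * S + A.t() * S) +
                                    4.0 * S * (S.t() * S));
        break; }
      case LINK_LOSS_DN: {
        const mat& S = v(n.in[0]);
        double fro = std::max(n.val(0, 0) * n.aux[0], 1e-12);
        double g = G(0, 0) / (n.aux[0] * 2.0 * fro);
        if (nodes[n.in[0]].need)
          nodes[n.in[0]].grad += g * (-2.0 * (n.extra + n.extra.t()) * S);
        if (nodes[n.in[1]].need)
          nodes[n.in[1]].grad += (2.0 * g) * n.extra;
        break; }
      case LSTM_CELL: {
        uword h = v(n.in[4]).n_rows;
        const vec& m = n.aux;
        mat Gh = G.cols(0, h - 1);
        mat Gc = G.cols(h, 2 * h - 1);
        mat gi = n.extra.cols(0, h - 1);
        mat gf = n.extra.cols(h, 2 * h - 1);
        mat gg = n.extra.cols(2 * h, 3 * h - 1);
        mat go = n.extra.cols(3 * h, 4 * h - 1);
        const mat& tc = n.extra2;
        mat dh_prev = Gh.each_col() % (1.0 - m);
        mat dc_prev = Gc.each_col() % (1.0 - m);
        mat dhnew = Gh.each_col() % m;
        mat dcnew = Gc.each_col() % m;
        mat dgo = dhnew % tc;
        dcnew += dhnew % go % (1.0 - square(tc));
        mat dgf = dcnew % v(n.in[2]);
        dc_prev += dcnew % gf;
        mat dgi = dcnew % gg;
        mat dgg = dcnew % gi;
        mat dZ = join_rows(dgi % gi % (1.0 - gi), dgf % gf % (1.0 - gf),
                           dgg % (1.0 - square(gg)), dgo % go % (1.0 - go));
        if (nodes[n.in[0]].need) nodes[n.in[0]].grad += dZ * v(n.in[3]).t();
        if (nodes[n.in[1]].need) nodes[n.in[1]].grad += dh_prev + dZ * v(n.in[4]).t();
        if (nodes[n.in[2]].need) nodes[n.in[2]].grad += dc_prev;
        if (nodes[n.in[3]].need) nodes[n.in[3]].grad += v(n.in[0]).t() * dZ;
        if (nodes[n.in[4]].need) nodes[n.in[4]].grad += v(n.in[1]).t() * dZ;
        if (nodes[n.in[5]].need) nodes[n.in[5]].grad += sum(dZ, 0);
        break; }
      case ENTROPY_LOSS: {
        const double eps = 1e-12;
        const mat& S = v(n.in[0]);
        double g = G(0, 0) / S.n_rows;
        nodes[n.in[0]].grad += g * (-(log(S + eps) + S / (S + eps)));
        break; }
      default: break;
      }
    }
  }
};

// ---------------------------------------------------------------------------
// helpers for moving parameters between R lists and the tape

static mat as_mat(SEXP s) { return Rcpp::as<mat>(s); }

struct ParamSet {
  std::vector<std::string> names;
  std::vector<int> ids;
  Tape* tp;
  void load(Tape& t, const List& params) {
    tp = &t;
    Rcpp::CharacterVector nm = params.names();
    for (int i = 0; i < params.size(); ++i) {
      names.push_back(Rcpp::as<std::string>(nm[i]));
      ids.push_back(t.leaf(as_mat(params[i]), true));
    }
  }
  int operator[](const std::string& k) const {
    for (size_t i = 0; i < names.size(); ++i)
      if (names[i] == k) return ids[i];
    Rcpp::stop("missing parameter: " + k);
  }
  List grads() const {
    List out(names.size());
    out.names() = Rcpp::wrap(names);
    for (size_t i = 0; i < names.size(); ++i)
      out[i] = Rcpp::wrap(tp->nodes[ids[i]].grad);
    return out;
  }
};

// ---------------------------------------------------------------------------
// DNN: five (linear -> batchnorm -> GELU) blocks on 54 summary statistics,
// all block outputs concatenated into a single linear readout.

struct BnIo {
  std::vector<rowvec> rm, rv;    // running stats in
  std::vector<rowvec> bm, bv;    // batch stats out
};

static int dnn_features(Tape& t, ParamSet& P, int X, const List& bn, bool training,
                        BnIo& bnio) {
  std::vector<int> feats;
  int h = X;
  for (int k = 1; k <= 5; ++k) {
    std::string s = std::to_string(k);
    int lin = t.add_bias(t.matmul(h, P["W" + s]), P["b" + s]);
    rowvec rm = Rcpp::as<rowvec>(bn["rm" + s]);
    rowvec rv = Rcpp::as<rowvec>(bn["rv" + s]);
    int bnn = t.batchnorm(lin, P["g" + s], P["be" + s], rm, rv, training, 1e-5);
    bnio.bm.push_back(t.nodes[bnn].extra2.row(1));
    bnio.bv.push_back(t.nodes[bnn].extra2.row(2));
    h = t.gelu(bnn);
    feats.push_back(h);
  }
  return t.concat_cols(feats);
}

// average per-layer batch statistics over the graphs of a batch (stride =
// number of normalisation layers per graph)
static BnIo bn_collapse(const BnIo& bnio, int stride) {
  BnIo out;
  int n = (int)bnio.bm.size() / stride;
  for (int l = 0; l < stride; ++l) {
    rowvec m = bnio.bm[l], v = bnio.bv[l];
    for (int g = 1; g < n; ++g) {
      m += bnio.bm[g * stride + l];
      v += bnio.bv[g * stride + l];
    }
    out.bm.push_back(m / n);
    out.bv.push_back(v / n);
  }
  return out;
}

static List bn_out(const BnIo& bnio) {
  List bm(bnio.bm.size()), bv(bnio.bv.size());
  for (size_t i = 0; i < bnio.bm.size(); ++i) {
    bm[i] = Rcpp::wrap(bnio.bm[i]);
    bv[i] = Rcpp::wrap(bnio.bv[i]);
  }
  return List::create(Named("mean") = bm, Named("var") = bv);
}

// [[Rcpp::export]]
List cpp_dnn_pass(List params, arma::mat X, Rcpp::Nullable<Rcpp::NumericMatrix> Y,
                  List bn, bool training, double huber_delta,
                  bool want_grads, bool want_features) {
  Tape t;
  ParamSet P; P.load(t, params);
  int x = t.leaf(X, false);
  BnIo bnio;
  int C = dnn_features(t, P, x, bn, training, bnio);
  int pred = t.add_bias(t.matmul(C, P["Wr"]), P["br"]);
  List out;
  out["pred"] = Rcpp::wrap(t.v(pred));
  if (want_features) out["features"] = Rcpp::wrap(t.v(C));
  if (Y.isNotNull()) {
    int y = t.leaf(Rcpp::as<mat>(Y.get()), false);
    int loss = t.huber(pred, y, huber_delta);
    out["loss"] = t.v(loss)(0, 0);
    if (want_grads) { t.backward(loss); out["grads"] = P.grads(); }
  }
  if (training) out["bn_batch"] = bn_out(bnio);
  return out;
}

// ---------------------------------------------------------------------------
// LSTM: five stacked recurrent layers over branching-time sequences
// (padded; masking freezes finished sequences so padding cannot affect the
// output), final hidden state -> linear+GELU -> linear readout.

static int lstm_features(Tape& t, ParamSet& P, const mat& X, const ivec& lens) {
  uword B = X.n_rows, T = X.n_cols;
  const int n_layers = 5;
  uword hdim = t.v(P["Wh1"]).n_rows;
  std::vector<int> hs(n_layers), cs(n_layers);
  int zero = t.leaf(mat(B, hdim, fill::zeros), false);
  for (int l = 0; l < n_layers; ++l) { hs[l] = zero; cs[l] = zero; }
  std::vector<int> wx(n_layers), wh(n_layers), bl(n_layers);
  for (int l = 0; l < n_layers; ++l) {
    std::string s = std::to_string(l + 1);
    wx[l] = P["Wx" + s]; wh[l] = P["Wh" + s]; bl[l] = P["bl" + s];
  }
  for (uword step = 0; step < T; ++step) {
    vec m(B);
    for (uword b = 0; b < B; ++b) m(b) = (int)step < lens(b) ? 1.0 : 0.0;
    if (accu(m) == 0) break;
    int inp = t.leaf(X.col(step), false);
    for (int l = 0; l < n_layers; ++l) {
      int cell = t.lstm_cell(inp, hs[l], cs[l], wx[l], wh[l], bl[l], m);
      hs[l] = t.slice_cols(cell, 0, hdim - 1);
      cs[l] = t.slice_cols(cell, hdim, 2 * hdim - 1);
      inp = hs[l];
    }
  }
  return t.gelu(t.add_bias(t.matmul(hs[n_layers - 1], P["Wf"]), P["bf"]));
}

// [[Rcpp::export]]
List cpp_lstm_pass(List params, arma::mat X, arma::ivec lens,
                   Rcpp::Nullable<Rcpp::NumericMatrix> Y, double huber_delta,
                   bool want_grads, bool want_features) {
  Tape t;
  ParamSet P; P.load(t, params);
  int F = lstm_features(t, P, X, lens);
  int pred = t.add_bias(t.matmul(F, P["Wr"]), P["br"]);
  List out;
  out["pred"] = Rcpp::wrap(t.v(pred));
  if (want_features) out["features"] = Rcpp::wrap(t.v(F));
  if (Y.isNotNull()) {
    int y = t.leaf(Rcpp::as<mat>(Y.get()), false);
    int loss = t.huber(pred, y, huber_delta);
    out["loss"] = t.v(loss)(0, 0);
    if (want_grads) { t.backward(loss); out["grads"] = P.grads(); }
  }
  return out;
}

// ---------------------------------------------------------------------------
// GNN: five GraphSAGE modules (two mean-aggregator operators each, outputs
// concatenated within a module), two DiffPool coarsenings with
// link-prediction and assignment-entropy auxiliary losses, global mean
// pooling, two-layer readout. Graphs are processed one by one inside a
// shared tape; batch statistics for the normalisation layers are taken over
// the nodes of each graph.

struct GnnAux { std::vector<int> aux_losses; };

// one SAGE operator on a sparse-aggregated level
static int sage_op_sp(Tape& t, ParamSet& P, const std::string& id, int X,
                      int spidx, const List& bn, bool training, BnIo& bnio) {
  int agg = t.spmm(spidx, X);
  int lin = t.add_bias(t.add(t.matmul(X, P["Ws" + id]),
                             t.matmul(agg, P["Wn" + id])), P["bb" + id]);
  rowvec rm = Rcpp::as<rowvec>(bn["rm" + id]);
  rowvec rv = Rcpp::as<rowvec>(bn["rv" + id]);
  // graph-wise normalisation: statistics over this graph's nodes in both
  // training and inference (keeps train/eval behaviour identical on graphs
  // of very different sizes); rm/rv only monitor.
  int bnn = t.batchnorm(lin, P["gg" + id], P["ee" + id], rm, rv, true, 1e-5);
  bnio.bm.push_back(t.nodes[bnn].extra2.row(1));
  bnio.bv.push_back(t.nodes[bnn].extra2.row(2));
  return t.gelu(bnn);
}

// one SAGE operator on a dense (pooled) level: adjacency is a tape node,
// aggregation is row-normalised A X
static int sage_op_dn(Tape& t, ParamSet& P, const std::string& id, int X,
                      int A, int rs, const List& bn, bool training, BnIo& bnio) {
  int agg = t.divrows(t.matmul(A, X), rs);
  int lin = t.add_bias(t.add(t.matmul(X, P["Ws" + id]),
                             t.matmul(agg, P["Wn" + id])), P["bb" + id]);
  rowvec rm = Rcpp::as<rowvec>(bn["rm" + id]);
  rowvec rv = Rcpp::as<rowvec>(bn["rv" + id]);
  int bnn = t.batchnorm(lin, P["gg" + id], P["ee" + id], rm, rv, true, 1e-5);
  bnio.bm.push_back(t.nodes[bnn].extra2.row(1));
  bnio.bv.push_back(t.nodes[bnn].extra2.row(2));
  return t.gelu(bnn);
}

static int sage_module_sp(Tape& t, ParamSet& P, const std::string& mid, int X,
                          int spidx, const List& bn, bool training, BnIo& bnio) {
  int h1 = sage_op_sp(t, P, mid + "a", X, spidx, bn, training, bnio);
  int h2 = sage_op_sp(t, P, mid + "b", h1, spidx, bn, training, bnio);
  return t.concat_cols({h1, h2});
}

static int sage_module_dn(Tape& t, ParamSet& P, const std::string& mid, int X,
                          int A, int rs, const List& bn, bool training, BnIo& bnio) {
  int h1 = sage_op_dn(t, P, mid + "a", X, A, rs, bn, training, bnio);
  int h2 = sage_op_dn(t, P, mid + "b", h1, A, rs, bn, training, bnio);
  return t.concat_cols({h1, h2});
}

// Build symmetric adjacency and its row-normalised version from a 2 x m
// edge index (1-based node ids).
static void build_adj(const imat& ei, uword N, sp_mat& A, sp_mat& An) {
  uword m = ei.n_cols;
  umat loc(2, 2 * m);
  vec vals(2 * m, fill::ones);
  for (uword e = 0; e < m; ++e) {
    loc(0, 2 * e) = ei(0, e) - 1; loc(1, 2 * e) = ei(1, e) - 1;
    loc(0, 2 * e + 1) = ei(1, e) - 1; loc(1, 2 * e + 1) = ei(0, e) - 1;
  }
  A = sp_mat(loc, vals, N, N);
  vec deg(N, fill::zeros);
  for (uword e = 0; e < 2 * m; ++e) deg(loc(0, e)) += 1.0;
  vec nv(2 * m);
  for (uword e = 0; e < 2 * m; ++e) nv(e) = 1.0 / deg(loc(0, e));
  An = sp_mat(loc, nv, N, N);
}

// forward for one graph; returns the pooled 1 x 2w feature node and pushes
// auxiliary losses
static int gnn_graph(Tape& t, ParamSet& P, const mat& X, const imat& ei,
                     const List& bn, bool training, BnIo& bnio, GnnAux& aux) {
  uword N = X.n_rows;
  sp_mat A, An;
  build_adj(ei, N, A, An);
  t.spconst.push_back(A);
  int ia = (int)t.spconst.size() - 1;
  t.spconst.push_back(An);
  int ian = (int)t.spconst.size() - 1;
  int x = t.leaf(X, false);
  // level 1 (sparse)
  int emb1 = sage_module_sp(t, P, "m1", x, ian, bn, training, bnio);
  int pool1 = sage_module_sp(t, P, "m2", x, ian, bn, training, bnio);
  int S1 = t.softmax_rows(t.add_bias(t.matmul(pool1, P["Wp1"]), P["bp1"]));
  aux.aux_losses.push_back(t.link_loss_sp(S1, ia, (double)N * (double)N));
  aux.aux_losses.push_back(t.entropy_loss(S1));
  int X2 = t.matmul_tn(S1, emb1);               // c1 x 2w
  int A2 = t.matmul_tn(S1, t.spmm(ia, S1));     // c1 x c1
  int rs2 = t.shift(t.rowsums(A2), 1e-8);
  // level 2 (dense)
  int emb2 = sage_module_dn(t, P, "m3", X2, A2, rs2, bn, training, bnio);
  int pool2 = sage_module_dn(t, P, "m4", X2, A2, rs2, bn, training, bnio);
  int S2 = t.softmax_rows(t.add_bias(t.matmul(pool2, P["Wp2"]), P["bp2"]));
  double c1 = (double)t.v(S2).n_rows;
  aux.aux_losses.push_back(t.link_loss_dn(S2, A2, c1 * c1));
  aux.aux_losses.push_back(t.entropy_loss(S2));
  int X3 = t.matmul_tn(S2, emb2);               // c2 x 2w
  int A3 = t.matmul_tn(S2, t.matmul(A2, S2));   // c2 x c2
  int rs3 = t.shift(t.rowsums(A3), 1e-8);
  int emb3 = sage_module_dn(t, P, "m5", X3, A3, rs3, bn, training, bnio);
  return t.colmeans(emb3);                      // 1 x 2w
}

static int gnn_batch(Tape& t, ParamSet& P, const List& graphs, const List& bn,
                     bool training, BnIo& bnio, GnnAux& aux,
                     std::vector<int>& pooled_nodes) {
  for (int i = 0; i < graphs.size(); ++i) {
    List g = graphs[i];
    mat X = as_mat(g["node_features"]);
    imat ei = Rcpp::as<imat>(g["edge_index"]);
    pooled_nodes.push_back(gnn_graph(t, P, X, ei, bn, training, bnio, aux));
  }
  return t.concat_rows(pooled_nodes);
}

// [[Rcpp::export]]
List cpp_gnn_pass(List params, List graphs, Rcpp::Nullable<Rcpp::NumericMatrix> Y,
                  List bn, bool training, double huber_delta, double aux_weight,
                  bool want_grads, bool want_features) {
  Tape t;
  t.nodes.reserve(graphs.size() * 120 + 64);
  ParamSet P; P.load(t, params);
  BnIo bnio; GnnAux aux;
  std::vector<int> pooled;
  int feat = gnn_batch(t, P, graphs, bn, training, bnio, aux, pooled);
  int r1 = t.gelu(t.add_bias(t.matmul(feat, P["Wr1"]), P["br1"]));
  int pred = t.add_bias(t.matmul(r1, P["Wr2"]), P["br2"]);
  List out;
  out["pred"] = Rcpp::wrap(t.v(pred));
  if (want_features) out["features"] = Rcpp::wrap(t.v(feat));
  if (Y.isNotNull()) {
    int y = t.leaf(Rcpp::as<mat>(Y.get()), false);
    int loss = t.huber(pred, y, huber_delta);
    double aux_val = 0.0;
    if (aux_weight > 0.0) {
      int s = aux.aux_losses[0];
      for (size_t i = 1; i < aux.aux_losses.size(); ++i)
        s = t.add(s, aux.aux_losses[i]);
      for (int a : aux.aux_losses) aux_val += t.v(a)(0, 0);
      loss = t.addscaled(loss, s, aux_weight / graphs.size());
      aux_val *= aux_weight / graphs.size();
    }
    out["loss"] = t.v(loss)(0, 0);
    out["huber"] = t.v(loss)(0, 0) - aux_val;
    if (want_grads) { t.backward(loss); out["grads"] = P.grads(); }
  }
  if (training) out["bn_batch"] = bn_out(bn_collapse(bnio, 10));
  return out;
}

// ---------------------------------------------------------------------------
// Stacking: the three base networks without their readouts feed a linear
// meta-learner; everything trains jointly through one tape.

// [[Rcpp::export]]
List cpp_stack_pass(List dnn_params, List lstm_params, List gnn_params,
                    List meta_params,
                    arma::mat Xss, arma::mat Xbt, arma::ivec lens, List graphs,
                    Rcpp::Nullable<Rcpp::NumericMatrix> Y,
                    List bn_dnn, List bn_gnn, bool training,
                    double huber_delta, double aux_weight, bool want_grads) {
  Tape t;
  ParamSet Pd; Pd.load(t, dnn_params);
  ParamSet Pl; Pl.load(t, lstm_params);
  ParamSet Pg; Pg.load(t, gnn_params);
  ParamSet Pm; Pm.load(t, meta_params);
  BnIo bn_d, bn_g; GnnAux aux;
  int xss = t.leaf(Xss, false);
  int fd = dnn_features(t, Pd, xss, bn_dnn, training, bn_d);
  int fl = lstm_features(t, Pl, Xbt, lens);
  std::vector<int> pooled;
  int fg = gnn_batch(t, Pg, graphs, bn_gnn, training, bn_g, aux, pooled);
  int F = t.concat_cols({fg, fd, fl});
  int pred = t.add_bias(t.matmul(F, Pm["Wm"]), Pm["bm"]);
  List out;
  out["pred"] = Rcpp::wrap(t.v(pred));
  if (Y.isNotNull()) {
    int y = t.leaf(Rcpp::as<mat>(Y.get()), false);
    int loss = t.huber(pred, y, huber_delta);
    if (aux_weight > 0.0) {
      int s = aux.aux_losses[0];
      for (size_t i = 1; i < aux.aux_losses.size(); ++i)
        s = t.add(s, aux.aux_losses[i]);
      loss = t.addscaled(loss, s, aux_weight / graphs.size());
    }
    out["loss"] = t.v(loss)(0, 0);
    if (want_grads) {
      t.backward(loss);
      out["grads"] = List::create(
        Named("dnn") = Pd.grads(), Named("lstm") = Pl.grads(),
        Named("gnn") = Pg.grads(), Named("meta") = Pm.grads());
    }
  }
  if (training) {
    out["bn_batch_dnn"] = bn_out(bn_d);
    out["bn_batch_gnn"] = bn_out(bn_collapse(bn_g, 10));
  }
  return out;
}
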