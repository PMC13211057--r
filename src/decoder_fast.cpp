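// Single-precision training fast path for the hybrid CNN-Transformer
// decoder. Mirrors the R reference implementation layer for layer (same
// formulas, same parameter names); used by train_model(backend = "fast").
// Gradient agreement between the two paths is asserted in the test suite.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct DecCfg {
  uword C, T, K1, F1, K2, F2, pool, L, H, dmodel, dk, ffn, ncls;
  uword T1, P1, T2, Tseq;
  float dropout;
};

struct DecParams {
  fmat conv1_w; fvec conv1_b; fvec bn1_g, bn1_b;
  fmat conv2_w; fvec conv2_b; fvec bn2_g, bn2_b;
  std::vector<fmat> wq, wk, wv, wo, w1, w2;
  std::vector<fvec> bq, bk, bv, bo, b1, b2;
  std::vector<fvec> ln1_g, ln1_b, ln2_g, ln2_b;
  fmat head_w; fvec head_b;
};

struct BnState { fvec m1, v1, m2, v2; };

fmat as_f(const Rcpp::List& l, const char* nm) {
  return conv_to<fmat>::from(Rcpp::as<mat>(l[nm]));
}
fvec as_fv(const Rcpp::List& l, const char* nm) {
  return conv_to<fvec>::from(Rcpp::as<vec>(l[nm]));
}

DecParams load_params(const Rcpp::List& pl, uword L) {
  DecParams p;
  p.conv1_w = as_f(pl, "conv1.w"); p.conv1_b = as_fv(pl, "conv1.b");
  p.bn1_g = as_fv(pl, "bn1.gamma"); p.bn1_b = as_fv(pl, "bn1.beta");
  p.conv2_w = as_f(pl, "conv2.w"); p.conv2_b = as_fv(pl, "conv2.b");
  p.bn2_g = as_fv(pl, "bn2.gamma"); p.bn2_b = as_fv(pl, "bn2.beta");
  for (uword l = 1; l <= L; ++l) {
    std::string pre = "enc" + std::to_string(l) + ".";
    p.wq.push_back(as_f(pl, (pre + "wq").c_str()));
    p.wk.push_back(as_f(pl, (pre + "wk").c_str()));
    p.wv.push_back(as_f(pl, (pre + "wv").c_str()));
    p.wo.push_back(as_f(pl, (pre + "wo").c_str()));
    p.bq.push_back(as_fv(pl, (pre + "bq").c_str()));
    p.bk.push_back(as_fv(pl, (pre + "bk").c_str()));
    p.bv.push_back(as_fv(pl, (pre + "bv").c_str()));
    p.bo.push_back(as_fv(pl, (pre + "bo").c_str()));
    p.w1.push_back(as_f(pl, (pre + "ffn.w1").c_str()));
    p.b1.push_back(as_fv(pl, (pre + "ffn.b1").c_str()));
    p.w2.push_back(as_f(pl, (pre + "ffn.w2").c_str()));
    p.b2.push_back(as_fv(pl, (pre + "ffn.b2").c_str()));
    p.ln1_g.push_back(as_fv(pl, (pre + "ln1.gamma").c_str()));
    p.ln1_b.push_back(as_fv(pl, (pre + "ln1.beta").c_str()));
    p.ln2_g.push_back(as_fv(pl, (pre + "ln2.gamma").c_str()));
    p.ln2_b.push_back(as_fv(pl, (pre + "ln2.beta").c_str()));
  }
  p.head_w = as_f(pl, "head.w"); p.head_b = as_fv(pl, "head.b");
  return p;
}

void flatten(const DecParams& p, std::vector<fmat*>& out) {
  DecParams& q = const_cast<DecParams&>(p);
  out.clear();
  out.push_back(&q.conv1_w); out.push_back(&q.conv2_w);
  for (size_t l = 0; l < q.wq.size(); ++l) {
    out.push_back(&q.wq[l]); out.push_back(&q.wk[l]); out.push_back(&q.wv[l]);
    out.push_back(&q.wo[l]); out.push_back(&q.w1[l]); out.push_back(&q.w2[l]);
  }
  out.push_back(&q.head_w);
}

void flatten_v(const DecParams& p, std::vector<fvec*>& out) {
  DecParams& q = const_cast<DecParams&>(p);
  out.clear();
  out.push_back(&q.conv1_b); out.push_back(&q.bn1_g); out.push_back(&q.bn1_b);
  out.push_back(&q.conv2_b); out.push_back(&q.bn2_g); out.push_back(&q.bn2_b);
  for (size_t l = 0; l < q.wq.size(); ++l) {
    out.push_back(&q.bq[l]); out.push_back(&q.bk[l]); out.push_back(&q.bv[l]);
    out.push_back(&q.bo[l]); out.push_back(&q.b1[l]); out.push_back(&q.b2[l]);
    out.push_back(&q.ln1_g[l]); out.push_back(&q.ln1_b[l]);
    out.push_back(&q.ln2_g[l]); out.push_back(&q.ln2_b[l]);
  }
  out.push_back(&q.head_b);
}

void im2col_f(const fmat& x, uword K, fmat& col) {
  const uword C = x.n_rows, T_out = x.n_cols - K + 1;
  for (uword k = 0; k < K; ++k)
    col.rows(k * C, k * C + C - 1) = x.cols(k, k + T_out - 1);
}

void conv_fwd(const fcube& x, const fmat& w, const fvec& b, fcube& y,
              uword K) {
  const uword C = x.n_rows, T_out = x.n_cols - K + 1, N = x.n_slices;
  y.set_size(w.n_rows, T_out, N);
  fmat col(C * K, T_out);
  for (uword n = 0; n < N; ++n) {
    im2col_f(x.slice(n), K, col);
    y.slice(n) = w * col;
    y.slice(n).each_col() += b;
  }
}

void conv_bwd(const fcube& x, const fmat& w, const fcube& dy, fcube* dx,
              fmat& dw, fvec& db, uword K) {
  const uword C = x.n_rows, T_out = dy.n_cols, N = x.n_slices;
  dw.zeros(w.n_rows, w.n_cols);
  db.zeros(w.n_rows);
  if (dx) dx->zeros(size(x));
  fmat col(C * K, T_out);
  for (uword n = 0; n < N; ++n) {
    im2col_f(x.slice(n), K, col);
    dw += dy.slice(n) * col.t();
    db += sum(dy.slice(n), 1);
    if (dx) {
      fmat dcol = w.t() * dy.slice(n);
      for (uword k = 0; k < K; ++k)
        dx->slice(n).cols(k, k + T_out - 1) += dcol.rows(k * C, k * C + C - 1);
    }
  }
}

struct BnCache { fmat xhat; fvec inv, gamma; bool training; };

void bn_fwd(fcube& x, const fvec& g, const fvec& b, fvec& rm, fvec& rv,
            bool training, BnCache& ca, float momentum = 0.1f,
            float eps = 1e-5f) {
  const uword C = x.n_rows, M = x.n_cols * x.n_slices;
  fmat xm(x.memptr(), C, M, false, true);
  fvec mu, v;
  if (training) {
    mu = mean(xm, 1);
    v = mean(square(xm), 1) - square(mu);
    rm = (1 - momentum) * rm + momentum * mu;
    rv = (1 - momentum) * rv + momentum * v * ((float)M / std::max<uword>(M - 1, 1));
  } else { mu = rm; v = rv; }
  ca.inv = 1.0f / sqrt(v + eps);
  ca.gamma = g;
  ca.training = training;
  xm.each_col() -= mu;
  xm.each_col() %= ca.inv;
  ca.xhat = xm;  // copy
  xm.each_col() %= g;
  xm.each_col() += b;
}

void bn_bwd(const BnCache& ca, fcube& dy, fvec& dg, fvec& dbv) {
  const uword C = dy.n_rows, M = dy.n_cols * dy.n_slices;
  fmat dym(dy.memptr(), C, M, false, true);
  dg = sum(dym % ca.xhat, 1);
  dbv = sum(dym, 1);
  if (ca.training) {
    dym.each_col() %= ca.gamma;
    fvec mh = mean(dym, 1);
    fvec mxh = mean(dym % ca.xhat, 1);
    dym.each_col() -= mh;
    dym -= ca.xhat.each_col() % mxh;
    dym.each_col() %= ca.inv;
  } else {
    dym.each_col() %= ca.gamma % ca.inv;
  }
}

void elu_fwd(fcube& x) {
  float* v = x.memptr();
  for (uword i = 0; i < x.n_elem; ++i)
    if (v[i] < 0) v[i] = std::expm1(v[i]);
}

// dy *= elu'(x) given y = elu(x)
void elu_bwd(const fcube& y, fcube& dy) {
  const float* yv = y.memptr();
  float* dv = dy.memptr();
  for (uword i = 0; i < y.n_elem; ++i)
    if (yv[i] < 0) dv[i] *= (yv[i] + 1.0f);
}

void pool_fwd(const fcube& x, uword p, fcube& y, Cube<uword>& idx) {
  const uword C = x.n_rows, T_out = x.n_cols / p, N = x.n_slices;
  y.set_size(C, T_out, N); idx.set_size(C, T_out, N);
  for (uword n = 0; n < N; ++n)
    for (uword t = 0; t < T_out; ++t)
      for (uword c = 0; c < C; ++c) {
        uword best = 0; float bv = x(c, t * p, n);
        for (uword j = 1; j < p; ++j) {
          float vv = x(c, t * p + j, n);
          if (vv > bv) { bv = vv; best = j; }
        }
        y(c, t, n) = bv; idx(c, t, n) = best;
      }
}

void pool_bwd(const fcube& dy, const Cube<uword>& idx, uword p, uword T_in,
              fcube& dx) {
  const uword C = dy.n_rows, T_out = dy.n_cols, N = dy.n_slices;
  dx.zeros(C, T_in, N);
  for (uword n = 0; n < N; ++n)
    for (uword t = 0; t < T_out; ++t)
      for (uword c = 0; c < C; ++c)
        dx(c, t * p + idx(c, t, n), n) += dy(c, t, n);
}

struct LnCache { fmat zhat; fvec inv; fvec gamma; };

fmat ln_fwd(const fmat& z, const fvec& g, const fvec& b, LnCache& ca,
            float eps = 1e-5f) {
  fvec mu = mean(z, 1);
  fmat zc = z;
  zc.each_col() -= mu;
  ca.inv = 1.0f / sqrt(mean(square(zc), 1) + eps);
  zc.each_col() %= ca.inv;
  ca.zhat = zc;
  ca.gamma = g;
  zc.each_row() %= g.t();
  zc.each_row() += b.t();
  return zc;
}

fmat ln_bwd(const LnCache& ca, const fmat& dy, fvec& dg, fvec& db) {
  dg = sum(dy % ca.zhat, 0).t();
  db = sum(dy, 0).t();
  fmat dzh = dy;
  dzh.each_row() %= ca.gamma.t();
  fvec mh = mean(dzh, 1);
  fvec mxh = mean(dzh % ca.zhat, 1);
  fmat dz = dzh;
  dz.each_col() -= mh;
  dz -= ca.zhat.each_col() % mxh;
  dz.each_col() %= ca.inv;
  return dz;
}

struct RngDropout {
  std::mt19937 gen;
  std::uniform_real_distribution<float> un{0.0f, 1.0f};
  float p;
  bool active;
  fmat mask(uword r, uword c) {
    fmat m(r, c);
    const float scale = 1.0f / (1.0f - p);
    for (uword j = 0; j < c; ++j)
      for (uword i = 0; i < r; ++i)
        m(i, j) = un(gen) >= p ? scale : 0.0f;
    return m;
  }
};

struct EncCache {
  fmat z_in, Q, K, V, O, do1_mask, ln1_out, f1, r1_mask_in, do2_mask;
  std::vector<fmat> A, Ad, Amask;
  LnCache ln1, ln2;
};

struct FwdCache {
  fcube x, e1y, m1, e2y, m2;
  Cube<uword> i1, i2;
  BnCache bn1, bn2;
  fmat z0, pooled;
  std::vector<EncCache> enc;
  fmat logits;
};

// full training/eval forward; returns logits (N x ncls)
fmat forward(const DecCfg& cfg, const DecParams& p, BnState& st,
             const fcube& xb, bool training, RngDropout& rng,
             FwdCache* ca) {
  const uword N = xb.n_slices;
  fcube c1, m1, c2, m2;
  BnCache bc1, bc2;
  Cube<uword> i1, i2;
  conv_fwd(xb, p.conv1_w, p.conv1_b, c1, cfg.K1);
  bn_fwd(c1, p.bn1_g, p.bn1_b, st.m1, st.v1, training, bc1);
  elu_fwd(c1);
  if (ca) ca->e1y = c1;
  pool_fwd(c1, cfg.pool, m1, i1);
  conv_fwd(m1, p.conv2_w, p.conv2_b, c2, cfg.K2);
  if (ca) ca->m1 = m1;
  bn_fwd(c2, p.bn2_g, p.bn2_b, st.m2, st.v2, training, bc2);
  elu_fwd(c2);
  if (ca) ca->e2y = c2;
  pool_fwd(c2, cfg.pool, m2, i2);

  // tokens: rows t-within-n
  fmat z(cfg.Tseq * N, cfg.dmodel);
  for (uword n = 0; n < N; ++n)
    z.rows(n * cfg.Tseq, (n + 1) * cfg.Tseq - 1) = m2.slice(n).t();

  if (ca) {
    ca->m2 = m2; ca->i1 = i1; ca->i2 = i2; ca->bn1 = bc1; ca->bn2 = bc2;
    ca->z0 = z; ca->enc.resize(cfg.L);
  }

  const float sdk = std::sqrt((float)cfg.dk);
  for (uword l = 0; l < cfg.L; ++l) {
    EncCache ec;
    ec.z_in = z;
    ec.Q = z * p.wq[l]; ec.Q.each_row() += p.bq[l].t();
    ec.K = z * p.wk[l]; ec.K.each_row() += p.bk[l].t();
    ec.V = z * p.wv[l]; ec.V.each_row() += p.bv[l].t();
    ec.O.set_size(z.n_rows, cfg.dmodel);
    for (uword n = 0; n < N; ++n) {
      const uword r0 = n * cfg.Tseq;
      for (uword h = 0; h < cfg.H; ++h) {
        const uword c0 = h * cfg.dk;
        fmat Qh = ec.Q.submat(r0, c0, r0 + cfg.Tseq - 1, c0 + cfg.dk - 1);
        fmat Kh = ec.K.submat(r0, c0, r0 + cfg.Tseq - 1, c0 + cfg.dk - 1);
        fmat Vh = ec.V.submat(r0, c0, r0 + cfg.Tseq - 1, c0 + cfg.dk - 1);
        fmat S = Qh * Kh.t() / sdk;
        S.each_col() -= max(S, 1);
        fmat A = exp(S);
        A.each_col() /= sum(A, 1);
        fmat Ad = A;
        fmat msk;
        if (training && cfg.dropout > 0) {
          msk = rng.mask(A.n_rows, A.n_cols);
          Ad %= msk;
        }
        ec.O.submat(r0, c0, r0 + cfg.Tseq - 1, c0 + cfg.dk - 1) = Ad * Vh;
        if (ca) { ec.A.push_back(A); ec.Ad.push_back(Ad); ec.Amask.push_back(msk); }
      }
    }
    fmat mh = ec.O * p.wo[l]; mh.each_row() += p.bo[l].t();
    if (training && cfg.dropout > 0) {
      ec.do1_mask = rng.mask(mh.n_rows, mh.n_cols);
      mh %= ec.do1_mask;
    }
    fmat z1 = ln_fwd(z + mh, p.ln1_g[l], p.ln1_b[l], ec.ln1);
    ec.ln1_out = z1;
    fmat f1 = z1 * p.w1[l]; f1.each_row() += p.b1[l].t();
    ec.r1_mask_in = conv_to<fmat>::from(f1 > 0);
    f1 %= ec.r1_mask_in;
    ec.f1 = f1;
    fmat f2 = f1 * p.w2[l]; f2.each_row() += p.b2[l].t();
    if (training && cfg.dropout > 0) {
      ec.do2_mask = rng.mask(f2.n_rows, f2.n_cols);
      f2 %= ec.do2_mask;
    }
    z = ln_fwd(z1 + f2, p.ln2_g[l], p.ln2_b[l], ec.ln2);
    if (ca) ca->enc[l] = std::move(ec);
  }

  fmat pooled(N, cfg.dmodel);
  for (uword n = 0; n < N; ++n)
    pooled.row(n) = mean(z.rows(n * cfg.Tseq, (n + 1) * cfg.Tseq - 1), 0);
  fmat logits = pooled * p.head_w;
  logits.each_row() += p.head_b.t();
  if (ca) { ca->pooled = pooled; ca->x = xb; ca->logits = logits; }
  return logits;
}

// backward pass; fills gradient structure (same layout as params)
float backward(const DecCfg& cfg, const DecParams& p, const FwdCache& ca,
               const ivec& y, DecParams& g) {
  const uword N = ca.x.n_slices;
  // softmax CE
  fmat pr = ca.logits;
  pr.each_col() -= max(pr, 1);
  pr = exp(pr);
  pr.each_col() /= sum(pr, 1);
  double loss = 0;
  for (uword n = 0; n < N; ++n)
    loss -= std::log(std::max(pr(n, (uword)y[n] - 1), 1e-12f));
  loss /= N;
  fmat dlog = pr;
  for (uword n = 0; n < N; ++n) dlog(n, (uword)y[n] - 1) -= 1.0f;
  dlog /= (float)N;

  g.head_w = ca.pooled.t() * dlog;
  g.head_b = sum(dlog, 0).t();
  fmat dpooled = dlog * p.head_w.t();

  fmat dz(cfg.Tseq * N, cfg.dmodel);
  for (uword n = 0; n < N; ++n)
    dz.rows(n * cfg.Tseq, (n + 1) * cfg.Tseq - 1) =
      repmat(dpooled.row(n) / (float)cfg.Tseq, cfg.Tseq, 1);

  g.wq.resize(cfg.L); g.wk.resize(cfg.L); g.wv.resize(cfg.L);
  g.wo.resize(cfg.L); g.w1.resize(cfg.L); g.w2.resize(cfg.L);
  g.bq.resize(cfg.L); g.bk.resize(cfg.L); g.bv.resize(cfg.L);
  g.bo.resize(cfg.L); g.b1.resize(cfg.L); g.b2.resize(cfg.L);
  g.ln1_g.resize(cfg.L); g.ln1_b.resize(cfg.L);
  g.ln2_g.resize(cfg.L); g.ln2_b.resize(cfg.L);

  const float sdk = std::sqrt((float)cfg.dk);
  for (sword li = cfg.L - 1; li >= 0; --li) {
    const uword l = (uword)li;
    const EncCache& ec = ca.enc[l];
    fmat dres2 = ln_bwd(ec.ln2, dz, g.ln2_g[l], g.ln2_b[l]);
    fmat df2 = dres2;
    if (ec.do2_mask.n_elem) df2 %= ec.do2_mask;
    g.w2[l] = ec.f1.t() * df2;
    g.b2[l] = sum(df2, 0).t();
    fmat df1 = df2 * p.w2[l].t();
    df1 %= ec.r1_mask_in;
    g.w1[l] = ec.ln1_out.t() * df1;
    g.b1[l] = sum(df1, 0).t();
    fmat dln1 = dres2 + df1 * p.w1[l].t();
    fmat dres1 = ln_bwd(ec.ln1, dln1, g.ln1_g[l], g.ln1_b[l]);
    fmat dmh = dres1;
    if (ec.do1_mask.n_elem) dmh %= ec.do1_mask;
    g.wo[l] = ec.O.t() * dmh;
    g.bo[l] = sum(dmh, 0).t();
    fmat dO = dmh * p.wo[l].t();
    fmat dQ(size(dO), fill::zeros), dK(size(dO), fill::zeros),
        dV(size(dO), fill::zeros);
    for (uword n = 0; n < N; ++n) {
      const uword r0 = n * cfg.Tseq;
      for (uword h = 0; h < cfg.H; ++h) {
        const uword c0 = h * cfg.dk;
        const fmat& A = ec.A[n * cfg.H + h];
        const fmat& Ad = ec.Ad[n * cfg.H + h];
        const fmat& msk = ec.Amask[n * cfg.H + h];
        fmat dOh = dO.submat(r0, c0, r0 + cfg.Tseq - 1, c0 + cfg.dk - 1);
        fmat Vh = ec.V.submat(r0, c0, r0 + cfg.Tseq - 1, c0 + cfg.dk - 1);
        fmat dAd = dOh * Vh.t();
        dV.submat(r0, c0, r0 + cfg.Tseq - 1, c0 + cfg.dk - 1) = Ad.t() * dOh;
        fmat dA = msk.n_elem ? fmat(dAd % msk) : dAd;
        fmat dS = dA;
        dS.each_col() -= sum(dA % A, 1);
        dS %= A;
        dS /= sdk;
        fmat Qh = ec.Q.submat(r0, c0, r0 + cfg.Tseq - 1, c0 + cfg.dk - 1);
        fmat Kh = ec.K.submat(r0, c0, r0 + cfg.Tseq - 1, c0 + cfg.dk - 1);
        dQ.submat(r0, c0, r0 + cfg.Tseq - 1, c0 + cfg.dk - 1) = dS * Kh;
        dK.submat(r0, c0, r0 + cfg.Tseq - 1, c0 + cfg.dk - 1) = dS.t() * Qh;
      }
    }
    g.wq[l] = ec.z_in.t() * dQ; g.bq[l] = sum(dQ, 0).t();
    g.wk[l] = ec.z_in.t() * dK; g.bk[l] = sum(dK, 0).t();
    g.wv[l] = ec.z_in.t() * dV; g.bv[l] = sum(dV, 0).t();
    dz = dres1 + dQ * p.wq[l].t() + dK * p.wk[l].t() + dV * p.wv[l].t();
  }

  fcube dfeat(cfg.dmodel, cfg.Tseq, N);
  for (uword n = 0; n < N; ++n)
    dfeat.slice(n) = dz.rows(n * cfg.Tseq, (n + 1) * cfg.Tseq - 1).t();

  fcube dp2, dp1, dc2;
  pool_bwd(dfeat, ca.i2, cfg.pool, cfg.T2, dp2);
  elu_bwd(ca.e2y, dp2);
  bn_bwd(ca.bn2, dp2, g.bn2_g, g.bn2_b);
  conv_bwd(ca.m1, p.conv2_w, dp2, &dc2, g.conv2_w, g.conv2_b, cfg.K2);
  pool_bwd(dc2, ca.i1, cfg.pool, cfg.T1, dp1);
  elu_bwd(ca.e1y, dp1);
  bn_bwd(ca.bn1, dp1, g.bn1_g, g.bn1_b);
  conv_bwd(ca.x, p.conv1_w, dp1, nullptr, g.conv1_w, g.conv1_b, cfg.K1);
  return (float)loss;
}

DecCfg make_cfg(const Rcpp::List& cfgl) {
  DecCfg c;
  c.C = cfgl["in_channels"]; c.T = cfgl["input_samples"];
  c.K1 = cfgl["conv1_kernel"]; c.F1 = cfgl["conv1_out"];
  c.K2 = cfgl["conv2_kernel"]; c.F2 = cfgl["conv2_out"];
  c.pool = cfgl["pool"]; c.L = cfgl["encoder_layers"];
  c.H = cfgl["attention_heads"]; c.dmodel = cfgl["d_model"];
  c.ffn = cfgl["ffn_dim"]; c.ncls = cfgl["n_classes"];
  c.dk = c.dmodel / c.H;
  c.T1 = c.T - c.K1 + 1; c.P1 = c.T1 / c.pool;
  c.T2 = c.P1 - c.K2 + 1; c.Tseq = c.T2 / c.pool;
  c.dropout = (float)Rcpp::as<double>(cfgl["dropout"]);
  return c;
}

Rcpp::List params_out(const DecParams& p, uword L) {
  const uword n = 8 + L * 16 + 2;
  Rcpp::List out(n);
  Rcpp::CharacterVector nm(n);
  uword i = 0;
  auto put_m = [&](const std::string& name, const fmat& w) {
    nm[i] = name; out[i] = conv_to<mat>::from(w); ++i;
  };
  auto put_v = [&](const std::string& name, const fvec& w) {
    nm[i] = name; out[i] = conv_to<vec>::from(w); ++i;
  };
  put_m("conv1.w", p.conv1_w); put_v("conv1.b", p.conv1_b);
  put_v("bn1.gamma", p.bn1_g); put_v("bn1.beta", p.bn1_b);
  put_m("conv2.w", p.conv2_w); put_v("conv2.b", p.conv2_b);
  put_v("bn2.gamma", p.bn2_g); put_v("bn2.beta", p.bn2_b);
  for (uword l = 0; l < L; ++l) {
    std::string pre = "enc" + std::to_string(l + 1) + ".";
    put_m(pre + "wq", p.wq[l]); put_v(pre + "bq", p.bq[l]);
    put_m(pre + "wk", p.wk[l]); put_v(pre + "bk", p.bk[l]);
    put_m(pre + "wv", p.wv[l]); put_v(pre + "bv", p.bv[l]);
    put_m(pre + "wo", p.wo[l]); put_v(pre + "bo", p.bo[l]);
    put_v(pre + "ln1.gamma", p.ln1_g[l]); put_v(pre + "ln1.beta", p.ln1_b[l]);
    put_m(pre + "ffn.w1", p.w1[l]); put_v(pre + "ffn.b1", p.b1[l]);
    put_m(pre + "ffn.w2", p.w2[l]); put_v(pre + "ffn.b2", p.b2[l]);
    put_v(pre + "ln2.gamma", p.ln2_g[l]); put_v(pre + "ln2.beta", p.ln2_b[l]);
  }
  put_m("head.w", p.head_w); put_v("head.b", p.head_b);
  out.attr("names") = nm;
  return out;
}

}  // namespace

// Train the decoder with Adam + early stopping, entirely in single
// precision. Returns best-epoch parameters, BN running stats and history.
// [[Rcpp::export]]
Rcpp::List cpp_train_eegdecoder(const Rcpp::List& params,
                                const Rcpp::List& cfgl,
                                const arma::cube& xtr,
                                const arma::ivec& ytr,
                                const arma::cube& xval,
                                const arma::ivec& yval,
                                const Rcpp::List& state,
                                double lr, double weight_decay,
                                int batch_size, int max_epochs,
                                int patience, int seed) {
  DecCfg cfg = make_cfg(cfgl);
  DecParams p = load_params(params, cfg.L);
  BnState st{as_fv(state, "bn1.mean"), as_fv(state, "bn1.var"),
             as_fv(state, "bn2.mean"), as_fv(state, "bn2.var")};
  fcube Xtr = conv_to<fcube>::from(xtr);
  fcube Xva = conv_to<fcube>::from(xval);
  const uword Ntr = Xtr.n_slices, Nva = Xva.n_slices;

  // Adam state
  DecParams m = p, v = p, best = p;
  std::vector<fmat*> pm, mm, vm, bm;
  std::vector<fvec*> pv, mv, vv, bv;
  flatten(p, pm); flatten(m, mm); flatten(v, vm);
  flatten_v(p, pv); flatten_v(m, mv); flatten_v(v, vv);
  for (auto* w : mm) w->zeros();
  for (auto* w : vm) w->zeros();
  for (auto* w : mv) w->zeros();
  for (auto* w : vv) w->zeros();

  std::mt19937 shuffler((unsigned)seed);
  RngDropout rng;
  rng.gen.seed((unsigned)seed + 777u);
  rng.p = cfg.dropout;

  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  long tstep = 0;
  double best_acc = -1;
  int best_epoch = 0, wait = 0;
  BnState best_st = st;
  std::vector<double> h_loss, h_acc;

  std::vector<uword> ord(Ntr);
  for (uword i = 0; i < Ntr; ++i) ord[i] = i;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(ord.begin(), ord.end(), shuffler);
    double tot = 0;
    for (uword s = 0; s < Ntr; s += (uword)batch_size) {
      const uword e = std::min(s + (uword)batch_size, Ntr);
      fcube xb(cfg.C, cfg.T, e - s);
      ivec yb(e - s);
      for (uword i = s; i < e; ++i) {
        xb.slice(i - s) = Xtr.slice(ord[i]);
        yb[i - s] = ytr[ord[i]];
      }
      FwdCache ca;
      forward(cfg, p, st, xb, true, rng, &ca);
      DecParams g;
      float loss = backward(cfg, p, ca, yb, g);
      tot += loss * (e - s);
      // Adam
      ++tstep;
      const float bc1 = 1 - std::pow(b1, (float)tstep);
      const float bc2 = 1 - std::pow(b2, (float)tstep);
      std::vector<fmat*> gm; flatten(g, gm);
      std::vector<fvec*> gv; flatten_v(g, gv);
      for (size_t i = 0; i < pm.size(); ++i) {
        fmat gr = *gm[i] + (float)weight_decay * (*pm[i]);
        *mm[i] = b1 * (*mm[i]) + (1 - b1) * gr;
        *vm[i] = b2 * (*vm[i]) + (1 - b2) * square(gr);
        *pm[i] -= (float)lr * ((*mm[i]) / bc1) / (sqrt((*vm[i]) / bc2) + eps);
      }
      for (size_t i = 0; i < pv.size(); ++i) {
        fvec gr = *gv[i] + (float)weight_decay * (*pv[i]);
        *mv[i] = b1 * (*mv[i]) + (1 - b1) * gr;
        *vv[i] = b2 * (*vv[i]) + (1 - b2) * square(gr);
        *pv[i] -= (float)lr * ((*mv[i]) / bc1) / (sqrt((*vv[i]) / bc2) + eps);
      }
    }
    // validation accuracy, eval mode
    uword ok = 0;
    for (uword s = 0; s < Nva; s += 64) {
      const uword e = std::min(s + (uword)64, Nva);
      fcube xb = Xva.slices(s, e - 1);
      fmat lg = forward(cfg, p, st, xb, false, rng, nullptr);
      for (uword n = 0; n < lg.n_rows; ++n)
        if (lg.row(n).index_max() == (uword)(yval[s + n] - 1)) ++ok;
    }
    double acc = (double)ok / Nva;
    h_loss.push_back(tot / Ntr);
    h_acc.push_back(acc);
    if (acc > best_acc + 1e-12) {
      best_acc = acc; best_epoch = epoch; best = p; best_st = st; wait = 0;
    } else if (++wait >= patience) break;
    Rcpp::checkUserInterrupt();
  }

  Rcpp::List stout;
  stout["bn1.mean"] = conv_to<vec>::from(best_st.m1);
  stout["bn1.var"] = conv_to<vec>::from(best_st.v1);
  stout["bn2.mean"] = conv_to<vec>::from(best_st.m2);
  stout["bn2.var"] = conv_to<vec>::from(best_st.v2);
  return Rcpp::List::create(
      Rcpp::Named("params") = params_out(best, cfg.L),
      Rcpp::Named("state") = stout,
      Rcpp::Named("train_loss") = h_loss,
      Rcpp::Named("val_accuracy") = h_acc,
      Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("best_val_accuracy") = best_acc);
}

// Debug/validation entry: single-batch loss and gradients without dropout,
// used to assert agreement with the R reference implementation.
// [[Rcpp::export]]
Rcpp::List cpp_decoder_grads(const Rcpp::List& params, const Rcpp::List& cfgl,
                             const arma::cube& x, const arma::ivec& y,
                             const Rcpp::List& state, bool training) {
  DecCfg cfg = make_cfg(cfgl);
  cfg.dropout = 0.0f;
  DecParams p = load_params(params, cfg.L);
  BnState st{as_fv(state, "bn1.mean"), as_fv(state, "bn1.var"),
             as_fv(state, "bn2.mean"), as_fv(state, "bn2.var")};
  fcube xb = conv_to<fcube>::from(x);
  RngDropout rng; rng.p = 0;
  FwdCache ca;
  forward(cfg, p, st, xb, training, rng, &ca);
  DecParams g;
  float loss = backward(cfg, p, ca, y, g);
  return Rcpp::List::create(Rcpp::Named("loss") = (double)loss,
                            Rcpp::Named("grads") = params_out(g, cfg.L),
                            Rcpp::Named("logits") = conv_to<mat>::from(ca.logits));
}
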