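// Small U-Net: forward, backprop and prediction.
//
// Feature maps are arma::cube (rows, cols, channels); convolutions are 3x3
// zero-padded "same", realised as im2col + matrix product so BLAS carries
// the arithmetic. Weight layout for a 3x3 conv is (9 * C_in) x C_out with
// the 9 kernel taps ordered row-major over (dr, dc) in {-1,0,1}^2 and the
// input channel varying slowest; biases are length-C_out row vectors.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col3(const cube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  mat M(H * (size_t)W, 9 * (size_t)C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& S = X.slice(c);
    int k = 0;
    for (int dr = -1; dr <= 1; ++dr) {
      for (int dc = -1; dc <= 1; ++dc, ++k) {
        const int r0 = std::max(0, -dr), r1 = H - 1 - std::max(0, dr);
        const int c0 = std::max(0, -dc), c1 = W - 1 - std::max(0, dc);
        const size_t col = (size_t)c * 9 + k;
        for (int cc = c0; cc <= c1; ++cc)
          for (int r = r0; r <= r1; ++r)
            M(r + (size_t)cc * H, col) = S(r + dr, cc + dc);
      }
    }
  }
  return M;
}

static cube col2im3(const mat& dM, int H, int W, int C) {
  cube dX(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& S = dX.slice(c);
    int k = 0;
    for (int dr = -1; dr <= 1; ++dr) {
      for (int dc = -1; dc <= 1; ++dc, ++k) {
        const int r0 = std::max(0, -dr), r1 = H - 1 - std::max(0, dr);
        const int c0 = std::max(0, -dc), c1 = W - 1 - std::max(0, dc);
        const size_t col = (size_t)c * 9 + k;
        for (int cc = c0; cc <= c1; ++cc)
          for (int r = r0; r <= r1; ++r)
            S(r + dr, cc + dc) += dM(r + (size_t)cc * H, col);
      }
    }
  }
  return dX;
}

static cube mat2cube(const mat& Y, int H, int W) {
  cube out(H, W, Y.n_cols);
  for (size_t j = 0; j < Y.n_cols; ++j)
    out.slice(j) = reshape(Y.col(j), H, W);
  return out;
}

static mat cube2mat(const cube& X) {
  mat M(X.n_rows * X.n_cols, X.n_slices);
  for (size_t j = 0; j < X.n_slices; ++j)
    M.col(j) = vectorise(X.slice(j));
  return M;
}

static cube conv3_fwd(const cube& X, const mat& W, const rowvec& b, mat& Mcache) {
  Mcache = im2col3(X);
  mat Y = Mcache * W;
  Y.each_row() += b;
  return mat2cube(Y, X.n_rows, X.n_cols);
}

// dY cube -> (dW, db, dX); Mcache is im2col of the forward input
static cube conv3_bwd(const cube& dY, const mat& Mcache, const mat& W,
                      int Hin, int Win, int Cin, mat& dW, rowvec& db) {
  mat dYm = cube2mat(dY);
  dW = Mcache.t() * dYm;
  db = sum(dYm, 0);
  return col2im3(dYm * W.t(), Hin, Win, Cin);
}

static cube relu(const cube& Z) {
  cube A = Z;
  A.transform([](double v) { return v > 0.0 ? v : 0.0; });
  return A;
}

// 1/0 mask of positive entries, for ReLU backprop
static cube gtz(const cube& Z) {
  cube M = Z;
  M.transform([](double v) { return v > 0.0 ? 1.0 : 0.0; });
  return M;
}

static cube maxpool2(const cube& X, ucube& idx) {
  const int H = X.n_rows / 2, W = X.n_cols / 2, C = X.n_slices;
  cube out(H, W, C);
  idx.set_size(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double best = X(2 * i, 2 * j, c);
        uword bk = 0;
        const int di[4] = {0, 1, 0, 1}, dj[4] = {0, 0, 1, 1};
        for (int k = 1; k < 4; ++k) {
          double v = X(2 * i + di[k], 2 * j + dj[k], c);
          if (v > best) { best = v; bk = k; }
        }
        out(i, j, c) = best;
        idx(i, j, c) = bk;
      }
  return out;
}

static cube maxpool2_bwd(const cube& dP, const ucube& idx, int Hin, int Win) {
  cube dX(Hin, Win, dP.n_slices, fill::zeros);
  const int di[4] = {0, 1, 0, 1}, dj[4] = {0, 0, 1, 1};
  for (size_t c = 0; c < dP.n_slices; ++c)
    for (size_t j = 0; j < dP.n_cols; ++j)
      for (size_t i = 0; i < dP.n_rows; ++i) {
        uword k = idx(i, j, c);
        dX(2 * i + di[k], 2 * j + dj[k], c) += dP(i, j, c);
      }
  return dX;
}

static cube upsample2(const cube& X) {
  cube out(2 * X.n_rows, 2 * X.n_cols, X.n_slices);
  for (size_t c = 0; c < X.n_slices; ++c)
    for (size_t j = 0; j < X.n_cols; ++j)
      for (size_t i = 0; i < X.n_rows; ++i) {
        double v = X(i, j, c);
        out(2 * i, 2 * j, c) = v;
        out(2 * i + 1, 2 * j, c) = v;
        out(2 * i, 2 * j + 1, c) = v;
        out(2 * i + 1, 2 * j + 1, c) = v;
      }
  return out;
}

static cube upsample2_bwd(const cube& dU) {
  cube dX(dU.n_rows / 2, dU.n_cols / 2, dU.n_slices);
  for (size_t c = 0; c < dU.n_slices; ++c)
    for (size_t j = 0; j < dX.n_cols; ++j)
      for (size_t i = 0; i < dX.n_rows; ++i)
        dX(i, j, c) = dU(2 * i, 2 * j, c) + dU(2 * i + 1, 2 * j, c) +
                      dU(2 * i, 2 * j + 1, c) + dU(2 * i + 1, 2 * j + 1, c);
  return dX;
}

// One full pass. params: named list in canonical order (see R side).
// x: H x W x C input; y: H x W binary target (ignored unless want_loss).
// [[Rcpp::export]]
Rcpp::List unet_pass_cpp(Rcpp::List params, int n_enc, arma::ivec filters,
                         arma::cube x, arma::mat y,
                         bool want_loss, bool want_grad) {
  const int H = x.n_rows, W = x.n_cols;

  std::vector<mat> eW1(n_enc), eW2(n_enc), dW1v(n_enc), dW2v(n_enc);
  std::vector<rowvec> eb1(n_enc), eb2(n_enc), db1v(n_enc), db2v(n_enc);
  int p = 0;
  for (int i = 0; i < n_enc; ++i) {
    eW1[i] = Rcpp::as<mat>(params[p++]); eb1[i] = Rcpp::as<rowvec>(params[p++]);
    eW2[i] = Rcpp::as<mat>(params[p++]); eb2[i] = Rcpp::as<rowvec>(params[p++]);
  }
  for (int i = n_enc - 2; i >= 0; --i) {
    dW1v[i] = Rcpp::as<mat>(params[p++]); db1v[i] = Rcpp::as<rowvec>(params[p++]);
    dW2v[i] = Rcpp::as<mat>(params[p++]); db2v[i] = Rcpp::as<rowvec>(params[p++]);
  }
  mat outW = Rcpp::as<mat>(params[p++]);
  double outb = Rcpp::as<double>(params[p++]);

  // ---- forward: encoder
  std::vector<cube> encIn(n_enc), encZ1(n_enc), encA1(n_enc), encZ2(n_enc),
      encOut(n_enc);
  std::vector<mat> encM1(n_enc), encM2(n_enc);
  std::vector<ucube> poolIdx(std::max(n_enc - 1, 0));
  cube cur = x;
  for (int i = 0; i < n_enc; ++i) {
    encIn[i] = cur;
    encZ1[i] = conv3_fwd(cur, eW1[i], eb1[i], encM1[i]);
    encA1[i] = relu(encZ1[i]);
    encZ2[i] = conv3_fwd(encA1[i], eW2[i], eb2[i], encM2[i]);
    encOut[i] = relu(encZ2[i]);
    if (i < n_enc - 1) cur = maxpool2(encOut[i], poolIdx[i]);
  }

  // ---- forward: decoder
  std::vector<cube> decIn(n_enc), decZ1(n_enc), decA1(n_enc), decZ2(n_enc),
      decOut(n_enc);
  std::vector<mat> decM1(n_enc), decM2(n_enc);
  cube d = encOut[n_enc - 1];
  for (int i = n_enc - 2; i >= 0; --i) {
    cube up = upsample2(d);
    decIn[i] = join_slices(encOut[i], up);
    decZ1[i] = conv3_fwd(decIn[i], dW1v[i], db1v[i], decM1[i]);
    decA1[i] = relu(decZ1[i]);
    decZ2[i] = conv3_fwd(decA1[i], dW2v[i], db2v[i], decM2[i]);
    decOut[i] = relu(decZ2[i]);
    d = decOut[i];
  }

  // ---- output head: 1x1 conv + sigmoid
  mat Mo = cube2mat(d);                       // (H*W) x F1
  vec zv = Mo * outW + outb;                  // logits
  mat z = reshape(zv, H, W);
  mat prob = 1.0 / (1.0 + exp(-z));

  Rcpp::List res;
  res["prob"] = prob;
  if (!want_loss) return res;

  // summed binary cross-entropy, numerically stable in the logit
  mat zpos = z; zpos.transform([](double v) { return v > 0.0 ? v : 0.0; });
  mat l = zpos - y % z + log(1.0 + exp(-abs(z)));
  res["loss"] = accu(l);
  if (!want_grad) return res;

  // ---- backward
  Rcpp::List grads(params.size());

  mat dz = prob - y;
  vec dzv = vectorise(dz);
  mat g_outW = Mo.t() * dzv;
  double g_outb = accu(dzv);
  cube dd = mat2cube(dzv * outW.t(), H, W);

  std::vector<cube> dEnc(n_enc);
  for (int i = 0; i < n_enc; ++i)
    dEnc[i] = cube(encOut[i].n_rows, encOut[i].n_cols, encOut[i].n_slices,
                   fill::zeros);

  std::vector<mat> g_dW1(n_enc), g_dW2(n_enc);
  std::vector<rowvec> g_db1(n_enc), g_db2(n_enc);

  // decoder backward, shallowest level first (reverse of data flow)
  for (int i = 0; i <= n_enc - 2; ++i) {
    const int Fi = filters[i], Fip = decIn[i].n_slices - Fi;
    cube dZ2 = dd % gtz(decZ2[i]);
    cube dA1 = conv3_bwd(dZ2, decM2[i], dW2v[i], decA1[i].n_rows,
                         decA1[i].n_cols, decA1[i].n_slices, g_dW2[i], g_db2[i]);
    cube dZ1 = dA1 % gtz(decZ1[i]);
    cube dCat = conv3_bwd(dZ1, decM1[i], dW1v[i], decIn[i].n_rows,
                          decIn[i].n_cols, decIn[i].n_slices, g_dW1[i], g_db1[i]);
    dEnc[i] += dCat.slices(0, Fi - 1);
    cube dUpIn = upsample2_bwd(dCat.slices(Fi, Fi + Fip - 1));
    if (i == n_enc - 2) dEnc[n_enc - 1] += dUpIn; else dd = dUpIn;
    if (i < n_enc - 2) { /* dd flows to the next-deeper decoder level */ }
  }
  if (n_enc == 1) dEnc[0] += dd;  // degenerate single-level net (unused: n_enc >= 2)

  std::vector<mat> g_eW1(n_enc), g_eW2(n_enc);
  std::vector<rowvec> g_eb1(n_enc), g_eb2(n_enc);

  for (int i = n_enc - 1; i >= 0; --i) {
    cube dZ2 = dEnc[i] % gtz(encZ2[i]);
    cube dA1 = conv3_bwd(dZ2, encM2[i], eW2[i], encA1[i].n_rows,
                         encA1[i].n_cols, encA1[i].n_slices, g_eW2[i], g_eb2[i]);
    cube dZ1 = dA1 % gtz(encZ1[i]);
    cube dX = conv3_bwd(dZ1, encM1[i], eW1[i], encIn[i].n_rows,
                        encIn[i].n_cols, encIn[i].n_slices, g_eW1[i], g_eb1[i]);
    if (i > 0)
      dEnc[i - 1] += maxpool2_bwd(dX, poolIdx[i - 1], encOut[i - 1].n_rows,
                                  encOut[i - 1].n_cols);
  }

  p = 0;
  for (int i = 0; i < n_enc; ++i) {
    grads[p++] = g_eW1[i]; grads[p++] = g_eb1[i];
    grads[p++] = g_eW2[i]; grads[p++] = g_eb2[i];
  }
  for (int i = n_enc - 2; i >= 0; --i) {
    grads[p++] = g_dW1[i]; grads[p++] = g_db1[i];
    grads[p++] = g_dW2[i]; grads[p++] = g_db2[i];
  }
  grads[p++] = g_outW;
  grads[p++] = Rcpp::wrap(g_outb);
  res["grads"] = grads;
  return res;
}
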