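// Li & Stephens copying-model kernels.
//
// All transition structure is the uniform-copying kernel
//   T(z -> z') = (1 - p) * 1{z == z'} + p / K,
// with per-interval switch probability p = 1 - exp(-rho/K),
// rho = 4 * Ne * (genetic distance in Morgans).  This kernel is a
// semigroup in rho, which is what makes inserting untyped sites as
// missing-observation columns exact without running them through the
// forward pass.
//
// Emission: P(obs a | template allele h) = 1 - lambda if h == a, else
// lambda; missing observations emit 1 for every state.
//
// All sampling uses R's RNG (unif_rand) so set.seed() governs results.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double emit1(int h, int a, double lambda) {
  return (h == a) ? (1.0 - lambda) : lambda;
}

// Haploid forward-backward over typed sites.
// obs: length M, entries 0/1 or NA; templ: M x K matrix of 0/1.
// p_switch: length M-1.  Works in K-contiguous (state-major) buffers so
// every per-site pass is sequential in memory.  Returns
//   alphaT: K x M scaled forward messages (each column sums to 1),
//   bsT:    K x M normalized emission-weighted backward messages
//           bs_j = e_j * beta_j / sum (what untyped-site imputation
//           consumes for the right flank),
//   p1_typed: per-site posterior allele-1 probability
//           lambda + (1-2*lambda) * sum_z gamma_z 1{h_z = 1},
//   loglik, and (if want_gamma) the M x K smoothed state posterior.
// [[Rcpp::export(name = ".haploid_fb_cpp")]]
List haploid_fb_cpp(IntegerVector obs, IntegerMatrix templ,
                    NumericVector p_switch, double lambda,
                    bool want_gamma) {
  const int M = templ.nrow(), K = templ.ncol();
  if (obs.size() != M) stop("observation length does not match template sites");
  if (M > 1 && p_switch.size() != M - 1)
    stop("p_switch must have length (sites - 1)");
  NumericMatrix alphaT(K, M), bsT(K, M);
  NumericVector p1_typed(M);
  double loglik = 0.0;
  std::vector<double> e(K), beta(K), gam(K);

  auto load_emission = [&](int j) {
    if (IntegerVector::is_na(obs[j])) {
      std::fill(e.begin(), e.end(), 1.0);
    } else {
      const int a = obs[j];
      for (int z = 0; z < K; ++z) e[z] = emit1(templ(j, z), a, lambda);
    }
  };

  // forward
  load_emission(0);
  {
    double c = 0.0;
    double *ac = &alphaT(0, 0);
    for (int z = 0; z < K; ++z) { ac[z] = e[z] / K; c += ac[z]; }
    if (c <= 0.0) stop("zero forward likelihood at site 1");
    for (int z = 0; z < K; ++z) ac[z] /= c;
    loglik += std::log(c);
  }
  for (int j = 1; j < M; ++j) {
    const double p = p_switch[j - 1], a = 1.0 - p, b = p / K;
    load_emission(j);
    const double *pr = &alphaT(0, j - 1);
    double *ac = &alphaT(0, j);
    double c = 0.0;
    for (int z = 0; z < K; ++z) {
      ac[z] = (a * pr[z] + b) * e[z];  // previous column sums to 1
      c += ac[z];
    }
    if (c <= 0.0) stop("zero forward likelihood at site " + std::to_string(j + 1));
    for (int z = 0; z < K; ++z) ac[z] /= c;
    loglik += std::log(c);
  }

  NumericMatrix gamma = want_gamma ? NumericMatrix(M, K) : NumericMatrix(0, 0);
  // backward, fused with the per-site posterior summaries
  for (int j = M - 1; j >= 0; --j) {
    if (j == M - 1) {
      std::fill(beta.begin(), beta.end(), 1.0);
    } else {
      const double p = p_switch[j], a = 1.0 - p, b = p / K;
      const double *bn = &bsT(0, j + 1);  // already normalized to sum 1
      for (int z = 0; z < K; ++z) beta[z] = a * bn[z] + b;
    }
    load_emission(j);
    double s = 0.0;
    double *bc = &bsT(0, j);
    for (int z = 0; z < K; ++z) { bc[z] = e[z] * beta[z]; s += bc[z]; }
    if (s <= 0.0) stop("zero backward likelihood at site " + std::to_string(j + 1));
    for (int z = 0; z < K; ++z) bc[z] /= s;
    const double *ac = &alphaT(0, j);
    double gs = 0.0, g1 = 0.0;
    for (int z = 0; z < K; ++z) {
      gam[z] = ac[z] * beta[z];
      gs += gam[z];
      if (templ(j, z) == 1) g1 += gam[z];
    }
    p1_typed[j] = lambda + (1.0 - 2.0 * lambda) * g1 / gs;
    if (want_gamma)
      for (int z = 0; z < K; ++z) gamma(j, z) = gam[z] / gs;
  }

  return List::create(_["alphaT"] = alphaT, _["bsT"] = bsT,
                      _["p1_typed"] = p1_typed, _["loglik"] = loglik,
                      _["gamma"] = gamma);
}

// Analytic allele-1 probabilities at untyped sites.
// For an untyped site u between typed sites j and j+1 the state
// posterior is prop to (T_left^T alpha_j) * (T_right bs_{j+1}),
// bs_j = normalized e_j * beta_j, where T_left/T_right use the switch
// probabilities of the two sub-intervals.  Both factors are affine in
// the messages (a*msg + b*1), so the posterior expectation of the
// template allele reduces to four dot products per site:
//   num(u) = a*c*<alpha_j . bs_{j+1}, h_u> + a*d*<alpha_j, h_u>
//          + b*c*<bs_{j+1}, h_u> + b*d*<1, h_u>
//   den    = a*c*<alpha_j, bs_{j+1}> + a*d + b*c + b*d*K
// computed per untyped site from the flanking messages transposed to
// K-contiguous layout, streaming the (haplotypes x untyped sites)
// allele matrix once in memory order.
// left_idx is 1-based; 0 = before the first typed site, M = after the
// last; templ_untyped_t is haplotypes x untyped sites (the transpose of
// the site-major panel) and sel holds 1-based haplotype rows.
// [[Rcpp::export(name = ".impute_untyped_cpp")]]
NumericVector impute_untyped_cpp(NumericMatrix alphaT, NumericMatrix bsT,
                                 IntegerMatrix templ_untyped_t,
                                 IntegerVector sel,
                                 IntegerVector left_idx,
                                 NumericVector p_left, NumericVector p_right,
                                 double lambda) {
  const int K = alphaT.nrow(), M = alphaT.ncol();
  const int U = templ_untyped_t.ncol(), Hfull = templ_untyped_t.nrow();
  if (sel.size() != K) stop("template selection does not match state count");
  // <alpha_j, bs_{j+1}> per interior interval
  std::vector<double> dots(M > 1 ? M - 1 : 0, 0.0);
  for (int j = 0; j + 1 < M; ++j) {
    const double *ac = &alphaT(0, j);
    const double *bc = &bsT(0, j + 1);
    double d = 0.0;
    for (int z = 0; z < K; ++z) d += ac[z] * bc[z];
    dots[j] = d;
  }
  std::vector<int> sidx(K);
  for (int z = 0; z < K; ++z) {
    sidx[z] = sel[z] - 1;
    if (sidx[z] < 0 || sidx[z] >= Hfull)
      stop("template selection index out of range");
  }
  NumericVector out(U);
  for (int u = 0; u < U; ++u) {
    const int j = left_idx[u];
    if (j < 0 || j > M) stop("left flanking index out of range");
    double ca, cb, cc, cd;
    if (j >= 1) { ca = 1.0 - p_left[u]; cb = p_left[u] / K; }
    else { ca = 0.0; cb = 1.0 / K; }
    if (j <= M - 1) { cc = 1.0 - p_right[u]; cd = p_right[u] / K; }
    else { cc = 0.0; cd = 1.0; }
    const int jl = (j >= 1) ? j - 1 : 0;
    const int jr = (j <= M - 1) ? j : M - 1;
    const double *aj = &alphaT(0, jl);
    const double *bj = &bsT(0, jr);
    const int *col = &templ_untyped_t(0, u);
    double sa = 0.0, sb = 0.0, sab = 0.0, sn = 0.0;
    for (int z = 0; z < K; ++z) {
      const double m = (double)col[sidx[z]];  // branchless 0/1 mask
      const double av = aj[z], bv = bj[z];
      sa += m * av; sb += m * bv; sab += m * av * bv; sn += m;
    }
    const double dab = (j >= 1 && j <= M - 1) ? dots[j - 1] : 0.0;
    const double num = ca * cc * sab + ca * cd * sa + cb * cc * sb +
      cb * cd * sn;
    const double den = ca * cc * dab + ca * cd + cb * cc + cb * cd * K;
    out[u] = lambda + (1.0 - 2.0 * lambda) * num / den;
  }
  return out;
}

// Diploid forward filter / backward sampler over ordered template pairs.
// Ordered pairs with symmetric emissions are marginally equivalent to
// the unordered k^2/2 parameterization and map naturally onto k x k
// arrays.  geno: length M with entries 0/1/2 or NA.
// Returns genotype-consistent haplotypes h1, h2.
// [[Rcpp::export(name = ".diploid_sample_cpp")]]
List diploid_sample_cpp(IntegerVector geno, IntegerMatrix templ,
                        NumericVector p_switch, double lambda) {
  const int M = templ.nrow(), K = templ.ncol();
  if (geno.size() != M) stop("genotype length does not match template sites");
  if (M > 1 && p_switch.size() != M - 1)
    stop("p_switch must have length (sites - 1)");
  const int KK = K * K;
  std::vector<double> F((size_t)M * KK);
  std::vector<double> rowsum(K), colsum(K), w(KK);
  // per-site emission is separable in the two haplotypes:
  // g=0 -> e0(u)e0(v), g=2 -> e1(u)e1(v), g=1 -> e1(u)e0(v)+e0(u)e1(v)
  std::vector<double> x0(K), x1(K);
  auto load_site = [&](int j) {
    for (int u = 0; u < K; ++u) {
      const int h = templ(j, u);
      x0[u] = emit1(h, 0, lambda);
      x1[u] = emit1(h, 1, lambda);
    }
  };
  // emission weight at site j for the ordered pair (u, v), given the
  // precomputed per-haplotype emission rows x0/x1
  enum { EM_MISS, EM_HOM0, EM_HOM2, EM_HET };
  auto site_mode = [&](int j) {
    if (IntegerVector::is_na(geno[j])) return (int)EM_MISS;
    return geno[j] == 0 ? (int)EM_HOM0 : (geno[j] == 2 ? (int)EM_HOM2
                                                       : (int)EM_HET);
  };

  // forward; rows are stored unnormalized with per-site sums in csum,
  // and the 1/csum scale is folded into the next step's coefficients
  std::vector<double> csum(M);
  {
    double *cur = &F[0];
    const int mode = site_mode(0);
    if (mode != EM_MISS) load_site(0);
    double c = 0.0;
    for (int u = 0; u < K; ++u) {
      double *cu = cur + (size_t)u * K;
      for (int v = 0; v < K; ++v) {
        double e = 1.0;
        if (mode == EM_HOM0) e = x0[u] * x0[v];
        else if (mode == EM_HOM2) e = x1[u] * x1[v];
        else if (mode == EM_HET) e = x1[u] * x0[v] + x0[u] * x1[v];
        cu[v] = e;
        c += e;
      }
    }
    if (c <= 0.0) stop("zero diploid forward likelihood at site 1");
    csum[0] = c;
  }
  for (int j = 1; j < M; ++j) {
    const double p = p_switch[j - 1], a = 1.0 - p, b = p / K;
    double *prev = &F[(size_t)(j - 1) * KK], *cur = &F[(size_t)j * KK];
    std::fill(colsum.begin(), colsum.end(), 0.0);
    for (int u = 0; u < K; ++u) {
      const double *pr = prev + (size_t)u * K;
      double rs = 0.0;
      for (int v = 0; v < K; ++v) { rs += pr[v]; colsum[v] += pr[v]; }
      rowsum[u] = rs;
    }
    const double s = 1.0 / csum[j - 1];  // prev normalizer
    const double aas = a * a * s, abs_ = a * b * s, bb = b * b;
    for (int v = 0; v < K; ++v) colsum[v] *= abs_;
    const int mode = site_mode(j);
    if (mode != EM_MISS) load_site(j);
    double c = 0.0;
    for (int u = 0; u < K; ++u) {
      const double *pr = prev + (size_t)u * K;
      double *cu = cur + (size_t)u * K;
      const double ru = abs_ * rowsum[u] + bb;
      const double u0 = x0[u], u1 = x1[u];
      if (mode == EM_MISS) {
        for (int v = 0; v < K; ++v) {
          cu[v] = aas * pr[v] + ru + colsum[v];
          c += cu[v];
        }
      } else if (mode == EM_HOM0) {
        for (int v = 0; v < K; ++v) {
          cu[v] = (aas * pr[v] + ru + colsum[v]) * (u0 * x0[v]);
          c += cu[v];
        }
      } else if (mode == EM_HOM2) {
        for (int v = 0; v < K; ++v) {
          cu[v] = (aas * pr[v] + ru + colsum[v]) * (u1 * x1[v]);
          c += cu[v];
        }
      } else {
        for (int v = 0; v < K; ++v) {
          cu[v] = (aas * pr[v] + ru + colsum[v]) *
            (u1 * x0[v] + u0 * x1[v]);
          c += cu[v];
        }
      }
    }
    if (c <= 0.0) stop("zero diploid forward likelihood at site " + std::to_string(j + 1));
    csum[j] = c;
  }

  // backward sampling of the state-pair path
  std::vector<int> zu(M), zv(M);
  auto sample_from = [&](const std::vector<double> &wt, double tot) {
    double r = unif_rand() * tot, cum = 0.0;
    for (int i = 0; i < KK; ++i) { cum += wt[i]; if (r <= cum) return i; }
    return KK - 1;
  };
  {
    double *last = &F[(size_t)(M - 1) * KK];
    std::copy(last, last + KK, w.begin());
    int i = sample_from(w, csum[M - 1]);
    zu[M - 1] = i / K; zv[M - 1] = i % K;
  }
  for (int j = M - 2; j >= 0; --j) {
    const double p = p_switch[j], a = 1.0 - p, b = p / K;
    double *cur = &F[(size_t)j * KK];
    const int un = zu[j + 1], vn = zv[j + 1];
    double tot = 0.0;
    for (int u = 0; u < K; ++u) {
      const double tu = (u == un ? a + b : b);
      for (int v = 0; v < K; ++v) {
        const double tv = (v == vn ? a + b : b);
        const size_t i = (size_t)u * K + v;
        w[i] = cur[i] * tu * tv;
        tot += w[i];
      }
    }
    int i = sample_from(w, tot);
    zu[j] = i / K; zv[j] = i % K;
  }

  // per-site allele assignment, genotype-consistent
  IntegerVector h1(M), h2(M);
  for (int j = 0; j < M; ++j) {
    const int hu = templ(j, zu[j]), hv = templ(j, zv[j]);
    if (IntegerVector::is_na(geno[j])) {
      h1[j] = (unif_rand() < (hu == 1 ? 1.0 - lambda : lambda)) ? 1 : 0;
      h2[j] = (unif_rand() < (hv == 1 ? 1.0 - lambda : lambda)) ? 1 : 0;
    } else if (geno[j] == 0) {
      h1[j] = 0; h2[j] = 0;
    } else if (geno[j] == 2) {
      h1[j] = 1; h2[j] = 1;
    } else {
      const double w10 = emit1(hu, 1, lambda) * emit1(hv, 0, lambda);
      const double w01 = emit1(hu, 0, lambda) * emit1(hv, 1, lambda);
      if (unif_rand() < w10 / (w10 + w01)) { h1[j] = 1; h2[j] = 0; }
      else { h1[j] = 0; h2[j] = 1; }
    }
  }
  return List::create(_["h1"] = h1, _["h2"] = h2);
}

// Hamming distances from one query haplotype to every panel column,
// restricted to masked sites.
// [[Rcpp::export(name = ".hamming_query_cpp")]]
IntegerVector hamming_query_cpp(IntegerMatrix panel, IntegerVector query,
                                LogicalVector use) {
  const int M = panel.nrow(), H = panel.ncol();
  if (query.size() != M || use.size() != M)
    stop("query/mask length does not match panel sites");
  IntegerVector out(H);
  for (int h = 0; h < H; ++h) {
    int d = 0;
    for (int j = 0; j < M; ++j)
      if (use[j] && panel(j, h) != query[j]) ++d;
    out[h] = d;
  }
  return out;
}
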