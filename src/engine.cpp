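#include <Rcpp.h>
using namespace Rcpp;

// Column layout of the population matrix (see R/genome.R, pop_columns()).
// All state is numeric so the whole population lives in one matrix.
enum PopCol {
  DEME = 0, SEX,
  ZF0_MAT, SFM_MAT, ZF0FR_MAT, SFMFR_MAT,
  ZF0_PAT, SFM_PAT, ZF0FR_PAT, SFMFR_PAT,
  Y_MAT, ZMY_MAT, ZMYFR_MAT,
  Y_PAT, ZMY_PAT, ZMYFR_PAT,
  A_MAT, ZMA_MAT, ZMAFR_MAT,
  A_PAT, ZMA_PAT, ZMAFR_PAT,
  N_POP_COL
};

// Gamete matrix layout (see R/genome.R, gamete_columns()).
enum GamCol {
  G_ZF0 = 0, G_SFM, G_ZF0FR, G_SFMFR,
  G_Y, G_ZMY, G_ZMYFR,
  G_A, G_ZMA, G_ZMAFR,
  N_GAM_COL
};

// Sex phenotype codes shared with R: 0 undeveloped, 1 female, 2 male,
// 3 intersex.

// One allelic trait passes through mutation at gamete formation. A frozen
// (null-mutated) trait is absorbing: it stays 0 and consumes no randomness.
static inline void mutate_one(double &value, double &frozen,
                              double lo, double hi,
                              double p_mut, double p_null, double sigma) {
  if (frozen != 0.0) {
    value = 0.0;
    return;
  }
  if (p_mut <= 0.0) return;
  if (unif_rand() < p_mut) {
    if (p_null > 0.0 && unif_rand() < p_null) {
      value = 0.0;
      frozen = 1.0;
    } else {
      value += norm_rand() * sigma;
      if (value < lo) value = lo;
      if (value > hi) value = hi;
    }
  }
}

// Write one gamete of parent r into the maternal or paternal allele slots
// of offspring row orow. Transmission, mutation and de novo M_A activation
// follow the same model as cpp_make_gametes().
static void gamete_into(const NumericMatrix &pop, int r,
                        NumericMatrix &off, int orow, bool maternal_side,
                        double p_mut, double p_null, double sigma,
                        double mu_d, double z_m_init) {
  const int ZF0 = maternal_side ? ZF0_MAT : ZF0_PAT;
  const int SFM = maternal_side ? SFM_MAT : SFM_PAT;
  const int ZF0FR = maternal_side ? ZF0FR_MAT : ZF0FR_PAT;
  const int SFMFR = maternal_side ? SFMFR_MAT : SFMFR_PAT;
  const int Y = maternal_side ? Y_MAT : Y_PAT;
  const int ZMY = maternal_side ? ZMY_MAT : ZMY_PAT;
  const int ZMYFR = maternal_side ? ZMYFR_MAT : ZMYFR_PAT;
  const int A = maternal_side ? A_MAT : A_PAT;
  const int ZMA = maternal_side ? ZMA_MAT : ZMA_PAT;
  const int ZMAFR = maternal_side ? ZMAFR_MAT : ZMAFR_PAT;

  bool mat = unif_rand() < 0.5;
  double zf0 = pop(r, mat ? ZF0_MAT : ZF0_PAT);
  double sfm = pop(r, mat ? SFM_MAT : SFM_PAT);
  double zf0fr = pop(r, mat ? ZF0FR_MAT : ZF0FR_PAT);
  double sfmfr = pop(r, mat ? SFMFR_MAT : SFMFR_PAT);
  mutate_one(zf0, zf0fr, 0.0, R_PosInf, p_mut, p_null, sigma);
  mutate_one(sfm, sfmfr, 0.0, 1.0, p_mut, p_null, sigma);
  off(orow, ZF0) = zf0; off(orow, SFM) = sfm;
  off(orow, ZF0FR) = zf0fr; off(orow, SFMFR) = sfmfr;

  mat = unif_rand() < 0.5;
  double y = pop(r, mat ? Y_MAT : Y_PAT);
  double zmy = pop(r, mat ? ZMY_MAT : ZMY_PAT);
  double zmyfr = pop(r, mat ? ZMYFR_MAT : ZMYFR_PAT);
  if (y != 0.0) {
    mutate_one(zmy, zmyfr, 0.0, R_PosInf, p_mut, p_null, sigma);
  } else {
    zmy = 0.0; zmyfr = 0.0;
  }
  off(orow, Y) = y; off(orow, ZMY) = zmy; off(orow, ZMYFR) = zmyfr;

  mat = unif_rand() < 0.5;
  double a = pop(r, mat ? A_MAT : A_PAT);
  double zma = pop(r, mat ? ZMA_MAT : ZMA_PAT);
  double zmafr = pop(r, mat ? ZMAFR_MAT : ZMAFR_PAT);
  if (a != 0.0) {
    mutate_one(zma, zmafr, 0.0, R_PosInf, p_mut, p_null, sigma);
  } else {
    zma = 0.0; zmafr = 0.0;
  }
  // de novo activation: fires when the transmitted slot carries no
  // expressed allele; a decayed (null) allele can be overwritten by a
  // fresh one, an expressed lineage cannot
  if (zma <= 0.0 && mu_d > 0.0 && unif_rand() < mu_d) {
    a = 1.0; zma = z_m_init; zmafr = 0.0;
  }
  off(orow, A) = a; off(orow, ZMA) = zma; off(orow, ZMAFR) = zmafr;
}

// One full life-cycle iteration (reproduction, development, viability
// selection, dispersal, density regulation) fused into a single pass.
// Behaviourally equivalent to composing the R-level operations; used by
// run_simulation(engine = "cpp") to keep long runs fast. Mating-success
// weighting (sa_on_mating) is not handled here; run_simulation() falls
// back to the R composition in that case.
// [[Rcpp::export]]
NumericMatrix cpp_step_generation(NumericMatrix pop, int n_demes, int B,
                                  int K, NumericVector temps,
                                  double p_mut, double p_null, double sigma,
                                  double mu_d, double z_m_init,
                                  double theta_f, double theta_m,
                                  double beta, double sigma_eps,
                                  double s_yy, double s_a, double d) {
  int n = pop.nrow();
  std::vector< std::vector<int> > fem(n_demes), mal(n_demes);
  for (int r = 0; r < n; r++) {
    int dm = (int) pop(r, DEME);
    int sx = (int) pop(r, SEX);
    if (sx == 1) fem[dm].push_back(r);
    else if (sx == 2) mal[dm].push_back(r);
  }
  int n_ok = 0;
  for (int dm = 0; dm < n_demes; dm++) {
    if (!fem[dm].empty() && !mal[dm].empty()) n_ok++;
  }
  int tot = n_ok * B;
  NumericMatrix off(tot, N_POP_COL);
  int row = 0;
  for (int dm = 0; dm < n_demes; dm++) {
    int nf = fem[dm].size(), nm = mal[dm].size();
    if (nf == 0 || nm == 0) continue;
    for (int b = 0; b < B; b++) {
      int mo = fem[dm][(int)(unif_rand() * nf)];
      int fa = mal[dm][(int)(unif_rand() * nm)];
      gamete_into(pop, mo, off, row, true,
                  p_mut, p_null, sigma, mu_d, z_m_init);
      gamete_into(pop, fa, off, row, false,
                  p_mut, p_null, sigma, mu_d, z_m_init);
      off(row, DEME) = dm;
      off(row, SEX) = 0;
      row++;
    }
  }
  // development, viability selection, dispersal
  std::vector< std::vector<int> > pool(n_demes);
  for (int r = 0; r < tot; r++) {
    int dm = (int) off(r, DEME);
    double zm = off(r, Y_MAT) * off(r, ZMY_MAT) +
                off(r, Y_PAT) * off(r, ZMY_PAT) +
                off(r, A_MAT) * off(r, ZMA_MAT) +
                off(r, A_PAT) * off(r, ZMA_PAT);
    double zf_hat = 0.0;
    for (int al = 0; al < 2; al++) {
      double zf0 = off(r, al == 0 ? ZF0_MAT : ZF0_PAT);
      double sfm = off(r, al == 0 ? SFM_MAT : SFM_PAT);
      double eps = (sigma_eps > 0.0) ? norm_rand() * sigma_eps : 0.0;
      double amount = zf0 * (1.0 + beta * temps[dm]) + eps;
      if (amount < 0.0) amount = 0.0;
      double keep = 1.0 - sfm * zm;
      if (keep < 0.0) keep = 0.0;
      zf_hat += amount * keep;
    }
    int sx = (zf_hat > theta_f) ? 1 : ((zf_hat < theta_m) ? 2 : 3);
    off(r, SEX) = sx;
    int ny = (off(r, Y_MAT) != 0.0) + (off(r, Y_PAT) != 0.0);
    double w = (ny == 2) ? s_yy : 1.0;
    if (ny >= 1) {
      if (sx == 2) w *= (1.0 + s_a);
      else if (sx == 1) w *= (1.0 - s_a);
    }
    if (w < 0.0) w = 0.0;
    // soft selection: survival is relative to the largest attainable
    // factor (1 + s_a), so the male advantage is not capped away
    double p = w / (1.0 + s_a);
    if (p < 1.0 && unif_rand() >= p) continue; // did not survive
    int nd = dm;
    if (d > 0.0 && unif_rand() < d) {
      if (dm == 0) nd = 1;
      else if (dm == n_demes - 1) nd = dm - 1;
      else nd = (unif_rand() < 0.5) ? dm - 1 : dm + 1;
    }
    off(r, DEME) = nd;
    pool[nd].push_back(r);
  }
  // density regulation: uniform sampling without replacement above K
  std::vector<int> kept;
  kept.reserve(std::min(tot, n_demes * K));
  for (int dm = 0; dm < n_demes; dm++) {
    std::vector<int> &p = pool[dm];
    int m = p.size();
    if (m > K) {
      for (int i = 0; i < K; i++) {
        int j = i + (int)(unif_rand() * (m - i));
        std::swap(p[i], p[j]);
      }
      m = K;
    }
    for (int i = 0; i < m; i++) kept.push_back(p[i]);
  }
  NumericMatrix out(kept.size(), N_POP_COL);
  for (size_t i = 0; i < kept.size(); i++) {
    for (int c = 0; c < N_POP_COL; c++) out(i, c) = off(kept[i], c);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_mutate_traits(NumericVector value, NumericVector frozen,
                       double lo, double hi,
                       double p_mut, double p_null, double sigma) {
  int n = value.size();
  NumericVector v = clone(value);
  NumericVector f = clone(frozen);
  for (int i = 0; i < n; i++) {
    mutate_one(v[i], f[i], lo, hi, p_mut, p_null, sigma);
  }
  return List::create(_["value"] = v, _["frozen"] = f);
}

// Meiosis for a set of parents. Each gamete takes one allele per locus
// (free recombination between the three loci), mutates the transmitted
// evolvable traits, and may gain a de novo autosomal M allele when the
// transmitted autosomal slot is empty.
// [[Rcpp::export]]
NumericMatrix cpp_make_gametes(NumericMatrix pop, IntegerVector parent_row,
                               double p_mut, double p_null, double sigma,
                               double mu_d, double z_m_init) {
  int n = parent_row.size();
  NumericMatrix g(n, N_GAM_COL);
  for (int i = 0; i < n; i++) {
    int r = parent_row[i] - 1;
    // F locus
    bool mat = unif_rand() < 0.5;
    double zf0 = pop(r, mat ? ZF0_MAT : ZF0_PAT);
    double sfm = pop(r, mat ? SFM_MAT : SFM_PAT);
    double zf0fr = pop(r, mat ? ZF0FR_MAT : ZF0FR_PAT);
    double sfmfr = pop(r, mat ? SFMFR_MAT : SFMFR_PAT);
    mutate_one(zf0, zf0fr, 0.0, R_PosInf, p_mut, p_null, sigma);
    mutate_one(sfm, sfmfr, 0.0, 1.0, p_mut, p_null, sigma);
    g(i, G_ZF0) = zf0; g(i, G_SFM) = sfm;
    g(i, G_ZF0FR) = zf0fr; g(i, G_SFMFR) = sfmfr;
    // sex-chromosome slot (X or Y carrying the M_Y locus)
    mat = unif_rand() < 0.5;
    double y = pop(r, mat ? Y_MAT : Y_PAT);
    double zmy = pop(r, mat ? ZMY_MAT : ZMY_PAT);
    double zmyfr = pop(r, mat ? ZMYFR_MAT : ZMYFR_PAT);
    if (y != 0.0) {
      mutate_one(zmy, zmyfr, 0.0, R_PosInf, p_mut, p_null, sigma);
    } else {
      zmy = 0.0; zmyfr = 0.0;
    }
    g(i, G_Y) = y; g(i, G_ZMY) = zmy; g(i, G_ZMYFR) = zmyfr;
    // autosomal M slot
    mat = unif_rand() < 0.5;
    double a = pop(r, mat ? A_MAT : A_PAT);
    double zma = pop(r, mat ? ZMA_MAT : ZMA_PAT);
    double zmafr = pop(r, mat ? ZMAFR_MAT : ZMAFR_PAT);
    if (a != 0.0) {
      mutate_one(zma, zmafr, 0.0, R_PosInf, p_mut, p_null, sigma);
    } else {
      zma = 0.0; zmafr = 0.0;
    }
    // de novo activation when no expressed allele was transmitted; a
    // decayed (null) allele is overwritten, an expressed one never is
    if (zma <= 0.0 && mu_d > 0.0 && unif_rand() < mu_d) {
      a = 1.0; zma = z_m_init; zmafr = 0.0;
    }
    g(i, G_A) = a; g(i, G_ZMA) = zma; g(i, G_ZMAFR) = zmafr;
  }
  return g;
}

// Threshold sex determination. Net expression of each F allele is
// (zf0 * (1 + beta * T) + eps) * (1 - sfm * zM), with each factor floored
// at zero; the two allelic values are summed and compared to the two
// thresholds. One independent noise draw per F allele.
// [[Rcpp::export]]
IntegerVector cpp_determine_sex(NumericMatrix pop, NumericVector temp,
                                double theta_f, double theta_m,
                                double beta, double sigma_eps) {
  int n = pop.nrow();
  IntegerVector sex(n);
  for (int i = 0; i < n; i++) {
    double zm = pop(i, Y_MAT) * pop(i, ZMY_MAT) +
                pop(i, Y_PAT) * pop(i, ZMY_PAT) +
                pop(i, A_MAT) * pop(i, ZMA_MAT) +
                pop(i, A_PAT) * pop(i, ZMA_PAT);
    double zf_hat = 0.0;
    for (int al = 0; al < 2; al++) {
      double zf0 = pop(i, al == 0 ? ZF0_MAT : ZF0_PAT);
      double sfm = pop(i, al == 0 ? SFM_MAT : SFM_PAT);
      double eps = (sigma_eps > 0.0) ? norm_rand() * sigma_eps : 0.0;
      double amount = zf0 * (1.0 + beta * temp[i]) + eps;
      if (amount < 0.0) amount = 0.0;
      double keep = 1.0 - sfm * zm;
      if (keep < 0.0) keep = 0.0;
      zf_hat += amount * keep;
    }
    if (zf_hat > theta_f) sex[i] = 1;
    else if (zf_hat < theta_m) sex[i] = 2;
    else sex[i] = 3;
  }
  return sex;
}

// Multiplicative Y-chromosomal fitness factor: YY homozygotes are scaled
// by s_yy; Y carriers additionally get (1 + s_a) as males and (1 - s_a)
// as females. Intersexes only experience the YY viability cost.
// [[Rcpp::export]]
NumericVector cpp_fitness_factor(NumericMatrix pop,
                                 double s_yy, double s_a) {
  int n = pop.nrow();
  NumericVector w(n);
  for (int i = 0; i < n; i++) {
    int ny = (pop(i, Y_MAT) != 0.0) + (pop(i, Y_PAT) != 0.0);
    double f = (ny == 2) ? s_yy : 1.0;
    int sex = (int) pop(i, SEX);
    if (ny >= 1) {
      if (sex == 2) f *= (1.0 + s_a);
      else if (sex == 1) f *= (1.0 - s_a);
    }
    if (f < 0.0) f = 0.0;
    w[i] = f;
  }
  return w;
}
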