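#include <Rcpp.h>
using namespace Rcpp;

// Decomposable toy Hamiltonian: a bead-chain solute (harmonic bonds +
// truncated Lennard-Jones between non-bonded beads) in a Lennard-Jones
// solvent bath, cubic periodic box, minimum-image convention. Energies are
// kept decomposed into solute-solute (epp), solute-solvent (epw) and
// solvent-solvent (eww) so the solute-tempering machinery can scale them.

struct ToyParams {
  double box, bond_k, bond_r0, eps, sigma2, rc2, move_size;
  int dim;
  bool periodic;
};

static ToyParams read_params(const List& p) {
  ToyParams tp;
  tp.box = as<double>(p["box_length"]);
  tp.bond_k = as<double>(p["bond_k"]);
  tp.bond_r0 = as<double>(p["bond_r0"]);
  tp.eps = as<double>(p["lj_epsilon"]);
  double s = as<double>(p["lj_sigma"]);
  tp.sigma2 = s * s;
  double rc = as<double>(p["lj_cutoff"]);
  tp.rc2 = rc * rc;
  tp.move_size = as<double>(p["move_size"]);
  tp.dim = as<int>(p["dim"]);
  tp.periodic = as<bool>(p["periodic"]);
  return tp;
}

static inline double dist2(const double* a, const double* b,
                           const ToyParams& tp) {
  double d2 = 0.0;
  for (int k = 0; k < 3; ++k) {
    double d = a[k] - b[k];
    if (tp.periodic) d -= tp.box * std::round(d / tp.box);
    d2 += d * d;
  }
  return d2;
}

// truncated (unshifted) LJ
static inline double lj(double r2, const ToyParams& tp) {
  if (r2 >= tp.rc2) return 0.0;
  if (r2 < 1e-12) return R_PosInf;
  double sr2 = tp.sigma2 / r2;
  double sr6 = sr2 * sr2 * sr2;
  return 4.0 * tp.eps * (sr6 * sr6 - sr6);
}

static inline double bond(double r2, const ToyParams& tp) {
  double d = std::sqrt(r2) - tp.bond_r0;
  return 0.5 * tp.bond_k * d * d;
}

// row pointer helpers: coordinates are stored as n x 3 matrices
static inline void get_row(const NumericMatrix& m, int i, double* out) {
  out[0] = m(i, 0); out[1] = m(i, 1); out[2] = m(i, 2);
}

// [[Rcpp::export]]
NumericVector cpp_toy_energy(NumericMatrix solute, NumericMatrix solvent,
                             List params) {
  ToyParams tp = read_params(params);
  int ns = solute.nrow(), nw = solvent.nrow();
  double epp = 0.0, epw = 0.0, eww = 0.0;
  double a[3], b[3];
  for (int i = 0; i < ns; ++i) {
    get_row(solute, i, a);
    for (int j = i + 1; j < ns; ++j) {
      get_row(solute, j, b);
      double r2 = dist2(a, b, tp);
      if (j == i + 1) epp += bond(r2, tp);
      else epp += lj(r2, tp);
    }
    for (int j = 0; j < nw; ++j) {
      get_row(solvent, j, b);
      epw += lj(dist2(a, b, tp), tp);
    }
  }
  for (int i = 0; i < nw; ++i) {
    get_row(solvent, i, a);
    for (int j = i + 1; j < nw; ++j) {
      get_row(solvent, j, b);
      eww += lj(dist2(a, b, tp), tp);
    }
  }
  return NumericVector::create(_["epp"] = epp, _["epw"] = epw,
                               _["eww"] = eww);
}

// interaction of one solute bead with the rest of the system
static void solute_bead_energy(const double* pos, int i,
                               const NumericMatrix& solute,
                               const NumericMatrix& solvent,
                               const ToyParams& tp,
                               double* epp, double* epw) {
  int ns = solute.nrow(), nw = solvent.nrow();
  double b[3];
  *epp = 0.0; *epw = 0.0;
  for (int j = 0; j < ns; ++j) {
    if (j == i) continue;
    get_row(solute, j, b);
    double r2 = dist2(pos, b, tp);
    if (j == i - 1 || j == i + 1) *epp += bond(r2, tp);
    else *epp += lj(r2, tp);
  }
  for (int j = 0; j < nw; ++j) {
    get_row(solvent, j, b);
    *epw += lj(dist2(pos, b, tp), tp);
  }
}

static void solvent_bead_energy(const double* pos, int i,
                                const NumericMatrix& solute,
                                const NumericMatrix& solvent,
                                const ToyParams& tp,
                                double* epw, double* eww) {
  int ns = solute.nrow(), nw = solvent.nrow();
  double b[3];
  *epw = 0.0; *eww = 0.0;
  for (int j = 0; j < ns; ++j) {
    get_row(solute, j, b);
    *epw += lj(dist2(pos, b, tp), tp);
  }
  for (int j = 0; j < nw; ++j) {
    if (j == i) continue;
    get_row(solvent, j, b);
    *eww += lj(dist2(pos, b, tp), tp);
  }
}

// Metropolis sweeps under the deformed potential
// lambda*epp + lambda^pw_exponent*epw + eww. Solute moves see the scaled
// epp and epw terms; solvent moves see the scaled epw plus unscaled eww.
// Uses R's RNG so set.seed() in R controls all randomness.
// [[Rcpp::export]]
List cpp_toy_sweep(NumericMatrix solute, NumericMatrix solvent,
                   NumericVector decomp, List params, double lambda,
                   double beta, int n_sweeps, double pw_exponent) {
  ToyParams tp = read_params(params);
  NumericMatrix sol = clone(solute);
  NumericMatrix wat = clone(solvent);
  double epp = decomp["epp"], epw = decomp["epw"], eww = decomp["eww"];
  double lam_pw = std::pow(lambda, pw_exponent);
  int ns = sol.nrow(), nw = wat.nrow();
  long accepted = 0, attempted = 0;
  double oldp[3], newp[3];

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int i = 0; i < ns; ++i) {
      get_row(sol, i, oldp);
      for (int k = 0; k < 3; ++k) newp[k] = oldp[k];
      for (int k = 0; k < tp.dim; ++k)
        newp[k] += R::runif(-tp.move_size, tp.move_size);
      double epp0, epw0, epp1, epw1;
      solute_bead_energy(oldp, i, sol, wat, tp, &epp0, &epw0);
      solute_bead_energy(newp, i, sol, wat, tp, &epp1, &epw1);
      double ddef = lambda * (epp1 - epp0) + lam_pw * (epw1 - epw0);
      ++attempted;
      if (ddef <= 0.0 || R::runif(0.0, 1.0) < std::exp(-beta * ddef)) {
        for (int k = 0; k < 3; ++k) sol(i, k) = newp[k];
        epp += epp1 - epp0;
        epw += epw1 - epw0;
        ++accepted;
      }
    }
    for (int i = 0; i < nw; ++i) {
      get_row(wat, i, oldp);
      for (int k = 0; k < 3; ++k) newp[k] = oldp[k];
      for (int k = 0; k < tp.dim; ++k)
        newp[k] += R::runif(-tp.move_size, tp.move_size);
      double epw0, eww0, epw1, eww1;
      solvent_bead_energy(oldp, i, sol, wat, tp, &epw0, &eww0);
      solvent_bead_energy(newp, i, sol, wat, tp, &epw1, &eww1);
      double ddef = lam_pw * (epw1 - epw0) + (eww1 - eww0);
      ++attempted;
      if (ddef <= 0.0 || R::runif(0.0, 1.0) < std::exp(-beta * ddef)) {
        for (int k = 0; k < 3; ++k) wat(i, k) = newp[k];
        epw += epw1 - epw0;
        eww += eww1 - eww0;
        ++accepted;
      }
    }
    if (!(std::isfinite(epp) && std::isfinite(epw) && std::isfinite(eww)))
      stop("non-finite energy during propagation (sweep %d)", sweep + 1);
  }

  double acc = attempted > 0 ? (double)accepted / (double)attempted : 1.0;
  return List::create(
    _["solute"] = sol, _["solvent"] = wat,
    _["decomp"] = NumericVector::create(_["epp"] = epp, _["epw"] = epw,
                                        _["eww"] = eww),
    _["acceptance"] = acc);
}
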