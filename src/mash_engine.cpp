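// MASH trajectory engine for Frenkel-exciton models.
//
// Internal units: energies/frequencies in rad/ps (wavenumbers multiplied by
// 2*pi*c upstream in R), time in ps, unit masses.  Nuclear coordinates are
// mass-scaled; each of the N sites owns M bath modes, stored contiguously as
// index j + M*n.  The electronic wavefunction is propagated exactly in the
// diabatic (site) representation by the exponential of the instantaneous
// potential matrix, evaluated in its adiabatic eigenbasis; the nuclei follow
// velocity Verlet on the active adiabat, which is the eigenstate with the
// largest instantaneous population.  Hops are deterministic: whenever the
// population ordering changes, the crossing is located by bisection and the
// momentum is rescaled (or reversed, if the kinetic energy along the
// rescaling direction is insufficient) along the direction
// v_j = Re(c_a^* c_b) d^j_ab built from the nonadiabatic coupling.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// Cyclic Jacobi eigensolver for small dense symmetric matrices (N <= 8 in
// practice).  A is destroyed; eigenvalues land in V ascending with the
// matching eigenvectors in the columns of U.  Much faster than a general
// LAPACK call at this size because it runs in fixed preallocated storage.
inline void jacobi_eig_sym(const int N, double* A, double* U, double* V) {
  for (int i = 0; i < N * N; ++i) U[i] = 0.0;
  for (int i = 0; i < N; ++i) U[i + N * i] = 1.0;
  double fro = 0.0;
  for (int i = 0; i < N * N; ++i) fro += A[i] * A[i];
  const double tol2 = 1e-24 * (fro + 1e-300);
  for (int sweep = 0; sweep < 50; ++sweep) {
    double off2 = 0.0;
    for (int p = 0; p < N; ++p)
      for (int q = p + 1; q < N; ++q) off2 += A[p + N * q] * A[p + N * q];
    if (2.0 * off2 < tol2) break;
    for (int p = 0; p < N - 1; ++p) {
      for (int q = p + 1; q < N; ++q) {
        const double apq = A[p + N * q];
        if (apq == 0.0) continue;
        const double theta = (A[q + N * q] - A[p + N * p]) / (2.0 * apq);
        const double t = (theta >= 0 ? 1.0 : -1.0) /
          (std::abs(theta) + std::sqrt(theta * theta + 1.0));
        const double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
        for (int k = 0; k < N; ++k) {   // rotate rows/cols p and q of A
          const double akp = A[k + N * p], akq = A[k + N * q];
          A[k + N * p] = c * akp - s * akq;
          A[k + N * q] = s * akp + c * akq;
        }
        for (int k = 0; k < N; ++k) {
          const double apk = A[p + N * k], aqk = A[q + N * k];
          A[p + N * k] = c * apk - s * aqk;
          A[q + N * k] = s * apk + c * aqk;
        }
        for (int k = 0; k < N; ++k) {   // accumulate the transform
          const double ukp = U[k + N * p], ukq = U[k + N * q];
          U[k + N * p] = c * ukp - s * ukq;
          U[k + N * q] = s * ukp + c * ukq;
        }
      }
    }
  }
  // ascending eigenvalue order (insertion sort, N is tiny)
  int idx[8];
  for (int i = 0; i < N; ++i) { V[i] = A[i + N * i]; idx[i] = i; }
  for (int i = 1; i < N; ++i) {
    const double v = V[i]; const int id = idx[i];
    int j = i - 1;
    while (j >= 0 && V[j] > v) { V[j + 1] = V[j]; idx[j + 1] = idx[j]; --j; }
    V[j + 1] = v; idx[j + 1] = id;
  }
  double tmp[64];
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < N; ++k) tmp[k + N * i] = U[k + N * idx[i]];
  for (int i = 0; i < N * N; ++i) U[i] = tmp[i];
}

struct Diag {
  long n_hops = 0, n_frustrated = 0, n_event_overflow = 0, n_dropped = 0;
  double max_norm_err = 0.0;
  double max_seg_drift_rate = 0.0;   // |dE|/dt between hops, units of kT/ps
  double max_hop_err = 0.0;          // |dE| across accepted hops, units of kT
};

class MashEngine {
public:
  int N, M, nd;
  vec eps;         // N, rad/ps (current disorder realization)
  mat Jc;          // N x N, rad/ps
  vec om, om2, cj; // M, rad/ps
  double kT;       // rad/ps
  double dt;

  // state
  vec q, p;        // nd = M*N
  cx_vec c;        // N, diabatic amplitudes
  int active = 0;
  mat U;           // N x N adiabatic transform at current q (columns = adiabats)
  vec V;           // N electronic eigenvalues (rad/ps), ascending
  int amax = 0;    // argmax adiabatic population at end of last step

  // workspace
  vec Wdiag, padv;
  cx_vec cad;
  vec F0, F1;
  mat Wm;
  // saved state for bisection
  vec q_s, p_s; cx_vec c_s; mat U_s; vec V_s; int active_s, amax_s;

  Diag* dg = nullptr;
  double Eseg = 0.0, tseg = 0.0; // segment reference energy and elapsed time

  MashEngine(int N_, int M_) : N(N_), M(M_), nd(N_ * M_),
    eps(N_), Jc(N_, N_), om(M_), om2(M_), cj(M_),
    q(nd), p(nd), c(N_), U(N_, N_), V(N_),
    Wdiag(N_), padv(N_), cad(N_), F0(nd), F1(nd), Wm(N_, N_),
    q_s(nd), p_s(nd), c_s(N_), U_s(N_, N_), V_s(N_) {
    if (N > 8) Rcpp::stop("engine supports at most 8 electronic states");
  }

  // electronic (diabatic) potential matrix eigen-decomposition at current q
  void electronic_eigen() {
    const double* cjp = cj.memptr();
    for (int n = 0; n < N; ++n) {
      double s = eps(n);
      const double* qn = q.memptr() + (size_t)M * n;
      for (int j = 0; j < M; ++j) s += cjp[j] * qn[j];
      Wdiag(n) = s;
    }
    if (N == 2) {
      const double a = Wdiag(0), b = Wdiag(1), J = Jc(0, 1);
      const double h = 0.5 * (a + b), d = 0.5 * (a - b);
      const double r = std::sqrt(d * d + J * J);
      V(0) = h - r; V(1) = h + r;
      // eigenvector of lower state: angle th with tan(2 th) = J/d handling
      double ux, uy;
      if (r < 1e-300) { ux = 1.0; uy = 0.0; }
      else {
        // lower eigenvector satisfies (d - (-r)) ux + J uy = 0 form; build robustly
        double t = V(0) - b;  // = d - r - ? ; use (W - V0) null vector
        // (a - V0) x + J y = 0 -> y = -(a - V0)/J x when J != 0
        if (std::abs(J) > 1e-14 * (std::abs(d) + std::abs(J))) {
          ux = J; uy = V(0) - a;
        } else if (d <= 0) { ux = 1.0; uy = 0.0; }
        else { ux = 0.0; uy = 1.0; }
        (void)t;
        double nrm = std::sqrt(ux * ux + uy * uy);
        ux /= nrm; uy /= nrm;
      }
      U(0, 0) = ux; U(1, 0) = uy;
      U(0, 1) = -uy; U(1, 1) = ux;
    } else {
      std::memcpy(Wm.memptr(), Jc.memptr(), sizeof(double) * N * N);
      for (int n = 0; n < N; ++n) Wm(n, n) = Wdiag(n);
      jacobi_eig_sym(N, Wm.memptr(), U.memptr(), V.memptr());
    }
  }

  // advance diabatic amplitudes by exp(-i W h) using current U, V
  void electronic_step(double h) {
    for (int a = 0; a < N; ++a) {
      std::complex<double> s(0.0, 0.0);
      for (int n = 0; n < N; ++n) s += U(n, a) * c(n);
      cad(a) = s * std::polar(1.0, -V(a) * h);
    }
    for (int n = 0; n < N; ++n) {
      std::complex<double> s(0.0, 0.0);
      for (int a = 0; a < N; ++a) s += U(n, a) * cad(a);
      c(n) = s;
    }
  }

  void force(vec& F) {
    const double* o2 = om2.memptr();
    const double* cjp = cj.memptr();
    for (int n = 0; n < N; ++n) {
      const double w = U(n, active) * U(n, active);
      const double* qn = q.memptr() + (size_t)M * n;
      double* Fn = F.memptr() + (size_t)M * n;
      for (int j = 0; j < M; ++j) Fn[j] = -o2[j] * qn[j] - cjp[j] * w;
    }
  }

  // one velocity-Verlet step of size h with split electronic propagation;
  // no hop logic here.  Assumes U, V current for the present q.
  void step_once(double h) {
    electronic_step(0.5 * h);
    force(F0);
    const double h2 = 0.5 * h * h;
    double* qp = q.memptr(); double* pp = p.memptr();
    const double* f0 = F0.memptr();
    for (int k = 0; k < nd; ++k) qp[k] += pp[k] * h + f0[k] * h2;
    electronic_eigen();
    force(F1);
    const double hh = 0.5 * h;
    const double* f1 = F1.memptr();
    for (int k = 0; k < nd; ++k) pp[k] += (f0[k] + f1[k]) * hh;
    electronic_step(0.5 * h);
  }

  int argmax_pop() {
    int ib = 0; double best = -1.0;
    for (int a = 0; a < N; ++a) {
      std::complex<double> s(0.0, 0.0);
      for (int n = 0; n < N; ++n) s += U(n, a) * c(n);
      double pa = std::norm(s);
      if (pa > best) { best = pa; ib = a; }
    }
    return ib;
  }

  double energy() const {
    double E = V(active);
    const double* pp = p.memptr();
    const double* o2 = om2.memptr();
    for (int k = 0; k < nd; ++k) E += 0.5 * pp[k] * pp[k];
    for (int n = 0; n < N; ++n) {
      const double* qn = q.memptr() + (size_t)M * n;
      for (int j = 0; j < M; ++j) E += 0.5 * o2[j] * qn[j] * qn[j];
    }
    return E;
  }

  void save_state() { q_s = q; p_s = p; c_s = c; U_s = U; V_s = V; active_s = active; amax_s = amax; }
  void restore_state() { q = q_s; p = p_s; c = c_s; U = U_s; V = V_s; active = active_s; amax = amax_s; }

  // attempt a hop from the current active state to adiabat b at the current
  // phase-space point; returns true if accepted
  bool attempt_hop(int b) {
    const int a = active;
    const double gap = V(b) - V(a);
    // adiabatic coefficients
    std::complex<double> ca(0, 0), cb(0, 0);
    for (int n = 0; n < N; ++n) { ca += U(n, a) * c(n); cb += U(n, b) * c(n); }
    const double bil = (std::conj(ca) * cb).real();
    // direction v_j = Re(c_a^* c_b) d^j_ab with d^j_ab = cj U(n,a) U(n,b)/(V_b - V_a);
    // d is parallel to the per-site pattern U(n,a)U(n,b) cj(j); the scalar
    // prefactors only set the sign, which cancels.  Fall back to bare d when
    // the coefficient bilinear vanishes.
    double vnorm2 = 0.0;
    static thread_local std::vector<double> vdir;
    vdir.assign(nd, 0.0);
    double denom = gap;
    if (std::abs(denom) < 1e-8) denom = (denom >= 0 ? 1e-8 : -1e-8);
    for (int n = 0; n < N; ++n) {
      const double site = U(n, a) * U(n, b) / denom;
      double* vn = vdir.data() + (size_t)M * n;
      for (int j = 0; j < M; ++j) { vn[j] = cj(j) * site; }
    }
    double scal = (std::abs(bil) > 1e-14) ? bil : 1.0;
    for (int k = 0; k < nd; ++k) { vdir[k] *= scal; vnorm2 += vdir[k] * vdir[k]; }
    if (vnorm2 < 1e-300) {
      // vanishing coupling: a genuine diabatic crossing (degenerate at the
      // crossing point).  Relabel freely when the residual gap is tiny so
      // the trajectory keeps following its diabat; otherwise keep surface.
      if (std::abs(gap) < 1e-4 * kT) { active = b; if (dg) ++dg->n_hops; return true; }
      return false;
    }
    const double vn1 = std::sqrt(vnorm2);
    double pv = 0.0;
    for (int k = 0; k < nd; ++k) pv += p(k) * vdir[k];
    pv /= vn1;
    if (0.5 * pv * pv >= gap) {
      const double pvnew = (pv >= 0 ? 1.0 : -1.0) * std::sqrt(pv * pv - 2.0 * gap);
      const double dpv = pvnew - pv;
      for (int k = 0; k < nd; ++k) p(k) += dpv * vdir[k] / vn1;
      active = b;
      if (dg) ++dg->n_hops;
      return true;
    } else {
      const double dpv = -2.0 * pv;
      for (int k = 0; k < nd; ++k) p(k) += dpv * vdir[k] / vn1;
      if (dg) ++dg->n_frustrated;
      return false;
    }
  }

  // full step of size dt with deterministic hop detection: whenever the
  // population ordering changes to a state other than the active one, the
  // crossing time is located by bisection (tolerance 1e-4 dt) and the hop is
  // attempted there; the remainder of the step is then integrated, allowing
  // further events (capped).
  void step_with_hops() {
    double remaining = dt;
    int events = 0;
    while (remaining > 1e-12 * dt) {
      save_state();
      step_once(remaining);
      int b = argmax_pop();
      if (b == active || b == amax_s || events >= 8) {
        if (events >= 8 && b != active && b != amax_s && dg) ++dg->n_event_overflow;
        amax = b;
        tseg += remaining;
        return;
      }
      // bisection for the crossing point inside (0, remaining]
      double lo = 0.0, hi = remaining;
      const double tol = 1e-4 * dt;
      while (hi - lo > tol) {
        const double mid = 0.5 * (lo + hi);
        restore_state();
        step_once(mid);
        if (argmax_pop() == amax_s) lo = mid; else hi = mid;
      }
      restore_state();
      step_once(hi);
      tseg += hi;
      check_drift();
      int bnew = argmax_pop();
      if (bnew != active) {
        const double Eb = energy();
        const bool acc = attempt_hop(bnew);
        const double Ea = energy();
        if (dg) {
          const double err = std::abs(Ea - Eb) / kT;
          if (acc && err > dg->max_hop_err) dg->max_hop_err = err;
        }
        if (acc) { Eseg = Ea; tseg = 0.0; }
      }
      amax = argmax_pop();
      remaining -= hi;
      ++events;
    }
  }

  // secular drift of the conserved energy over the current inter-hop
  // segment, normalized per unit time; evaluated at recording points (the
  // instantaneous error of a symplectic step is a bounded oscillation)
  void check_drift() {
    if (dg && tseg > 0.05) {
      const double rate = std::abs(energy() - Eseg) / kT / tseg;
      if (rate > dg->max_seg_drift_rate) dg->max_seg_drift_rate = rate;
    }
  }

  void start_segments() { Eseg = energy(); tseg = 0.0; }
};

// ---- electronic initial-condition sampling -------------------------------

cx_vec sample_sphere(int N, std::mt19937_64& rng) {
  std::normal_distribution<double> nrm(0.0, 1.0);
  cx_vec cv(N);
  double s = 0.0;
  for (int n = 0; n < N; ++n) {
    const double x = nrm(rng), y = nrm(rng);
    cv(n) = std::complex<double>(x, y);
    s += x * x + y * y;
  }
  return cv / std::sqrt(s);
}

int argmax_abs2(const cx_vec& cv) {
  int ib = 0; double best = -1.0;
  for (uword n = 0; n < cv.n_elem; ++n) {
    const double v = std::norm(cv(n));
    if (v > best) { best = v; ib = (int)n; }
  }
  return ib;
}

} // namespace

// [[Rcpp::export(name = ".mash_ensemble_cpp")]]
Rcpp::List mash_ensemble_cpp(
    const arma::vec& eps_mean, const arma::vec& eps_sigma, const arma::mat& Jc,
    const arma::vec& omega, const arma::vec& coupling, double kT, double dt,
    int n_steps, int record_every, int n_traj, int n_batch,
    int init_state, int init_basis,  // basis: 0 site, 1 exciton
    int scheme,                      // 0 cap, 1 focused, 2 equivariant, 3 original
    double alpha_N, double beta_N, double a_N, double b_N,
    int seed) {

  const int N = (int)eps_mean.n_elem, M = (int)omega.n_elem;
  if (scheme == 3 && N != 2) Rcpp::stop("original MASH requires 2 states");
  MashEngine eng(N, M);
  eng.Jc = Jc; eng.om = omega; eng.om2 = square(omega); eng.cj = coupling;
  eng.kT = kT; eng.dt = dt;

  const int n_rec = n_steps / record_every + 1;
  cube acc_site(n_rec, N, n_batch, fill::zeros);
  cube acc_exc(n_rec, N, n_batch, fill::zeros);
  vec batch_n(n_batch, fill::zeros);
  Diag dg;
  eng.dg = &dg;

  mat traj_site(n_rec, N), traj_exc(n_rec, N);
  mat Uexc(N, N); vec Eexc(N); mat Hs(N, N);
  const bool disorder = any(eps_sigma > 0);

  // exciton basis for the mean model (used when there is no disorder)
  Hs = Jc; Hs.diag() = eps_mean;
  eig_sym(Eexc, Uexc, Hs);

  for (int tr = 0; tr < n_traj; ++tr) {
    std::seed_seq ss{seed, 7919, tr};
    std::mt19937_64 rng(ss);
    std::normal_distribution<double> nrm(0.0, 1.0);
    std::uniform_real_distribution<double> unif(0.0, 1.0);

    // static disorder: per-trajectory site energies and exciton basis
    if (disorder) {
      for (int n = 0; n < N; ++n) eng.eps(n) = eps_mean(n) + eps_sigma(n) * nrm(rng);
      Hs = Jc; Hs.diag() = eng.eps;
      eig_sym(Eexc, Uexc, Hs);
    } else {
      eng.eps = eps_mean;
    }

    // nuclear Boltzmann sampling of the uncoupled bath
    for (int n = 0; n < N; ++n) {
      double* qn = eng.q.memptr() + (size_t)M * n;
      double* pn = eng.p.memptr() + (size_t)M * n;
      for (int j = 0; j < M; ++j) {
        qn[j] = std::sqrt(kT) / omega(j) * nrm(rng);
        pn[j] = std::sqrt(kT) * nrm(rng);
      }
    }

    // electronic sampling in the requested basis
    cx_vec cb;
    double w0 = 1.0;
    if (scheme == 0) {           // cap: rejection
      do { cb = sample_sphere(N, rng); } while (argmax_abs2(cb) != init_state);
    } else if (scheme == 1) {    // focused: fixed moduli, uniform phases
      cb.set_size(N);
      const double ri = std::sqrt((1.0 - beta_N) / alpha_N);
      const double rj = std::sqrt(-beta_N / alpha_N);
      for (int n = 0; n < N; ++n)
        cb(n) = std::polar(n == init_state ? ri : rj, 2.0 * M_PI * unif(rng));
    } else {                     // equivariant or original: uniform sphere
      cb = sample_sphere(N, rng);
      if (scheme == 2) w0 = N * (a_N * std::norm(cb(init_state)) + b_N);
    }
    if (init_basis == 1) eng.c = cx_vec(Uexc * cb); else eng.c = cb;

    eng.electronic_eigen();
    if (scheme == 3) {
      // original two-state MASH: weight from the adiabatic decomposition of
      // the initial projector at q0 (populations via sgn, coherences via the
      // 3 S_alpha quasi-probability factors)
      vec b0(N, fill::zeros);
      if (init_basis == 1) b0 = Uexc.col(init_state); else b0(init_state) = 1.0;
      const double u1 = dot(eng.U.col(0), b0), u2 = dot(eng.U.col(1), b0);
      std::complex<double> c1(0, 0), c2(0, 0);
      for (int n = 0; n < N; ++n) { c1 += eng.U(n, 0) * eng.c(n); c2 += eng.U(n, 1) * eng.c(n); }
      // signed quasiprobability: the population sector carries the linear
      // weight 2 S_z (negative on the wrong hemisphere), the coherence
      // sector the linear weight 3 S_x/y; populations are later measured by
      // the state indicator and coherences by |S_z|-damped bilinears
      const double Sz = std::norm(c1) - std::norm(c2);
      const double rz = u1 * u1 - u2 * u2;
      const double r12 = u1 * u2;
      w0 = 1.0 + rz * 2.0 * Sz + 12.0 * r12 * (std::conj(c1) * c2).real();
    }
    eng.active = eng.argmax_pop();
    eng.amax = eng.active;
    eng.start_segments();

    // integrate and record
    bool ok = true;
    for (int irec = 0, istep = 0; irec < n_rec; ++irec) {
      // record observables
      if (scheme == 3) {
        std::complex<double> c1(0, 0), c2(0, 0);
        for (int n = 0; n < N; ++n) { c1 += eng.U(n, 0) * eng.c(n); c2 += eng.U(n, 1) * eng.c(n); }
        const double pop1 = std::norm(c1), pop2 = std::norm(c2);
        const int th = (pop1 >= pop2) ? 0 : 1;
        const double W = std::abs(4.0 * std::max(pop1, pop2) - 2.0);
        const double coh = (std::conj(c1) * c2).real();
        for (int n = 0; n < N; ++n) {
          const double u1 = eng.U(n, 0), u2 = eng.U(n, 1);
          traj_site(irec, n) = (th == 0 ? u1 * u1 : u2 * u2) + (4.0 / 3.0) * W * 2.0 * u1 * u2 * coh;
        }
        for (int m = 0; m < N; ++m) {
          const double u1 = dot(eng.U.col(0), Uexc.col(m));
          const double u2 = dot(eng.U.col(1), Uexc.col(m));
          traj_exc(irec, m) = (th == 0 ? u1 * u1 : u2 * u2) + (4.0 / 3.0) * W * 2.0 * u1 * u2 * coh;
        }
      } else {
        for (int n = 0; n < N; ++n)
          traj_site(irec, n) = alpha_N * std::norm(eng.c(n)) + beta_N;
        for (int m = 0; m < N; ++m) {
          std::complex<double> s(0, 0);
          for (int n = 0; n < N; ++n) s += Uexc(n, m) * eng.c(n);
          traj_exc(irec, m) = alpha_N * std::norm(s) + beta_N;
        }
      }
      if (irec == n_rec - 1) break;
      for (int k = 0; k < record_every; ++k, ++istep) eng.step_with_hops();
      eng.check_drift();
      const double nrm2 = std::abs(norm(eng.c) - 1.0);
      if (nrm2 > dg.max_norm_err) dg.max_norm_err = nrm2;
      if (!eng.c.is_finite() || !eng.q.is_finite() || !std::isfinite(eng.energy())) {
        ok = false; break;
      }
    }
    if (!ok) { ++dg.n_dropped; continue; }
    const int ib = tr % n_batch;
    acc_site.slice(ib) += w0 * traj_site;
    acc_exc.slice(ib) += w0 * traj_exc;
    batch_n(ib) += 1.0;
  }

  return Rcpp::List::create(
    Rcpp::Named("acc_site") = acc_site,
    Rcpp::Named("acc_exc") = acc_exc,
    Rcpp::Named("batch_n") = batch_n,
    Rcpp::Named("n_hops") = (double)dg.n_hops,
    Rcpp::Named("n_frustrated") = (double)dg.n_frustrated,
    Rcpp::Named("n_event_overflow") = (double)dg.n_event_overflow,
    Rcpp::Named("n_dropped") = (double)dg.n_dropped,
    Rcpp::Named("max_norm_err") = dg.max_norm_err,
    Rcpp::Named("max_seg_drift_rate") = dg.max_seg_drift_rate,
    Rcpp::Named("max_hop_err") = dg.max_hop_err);
}

// Single-trajectory debugging interface: deterministic integration from an
// explicit phase-space point; returns the final state and conservation
// diagnostics.  Same engine as the ensemble driver.
// [[Rcpp::export(name = ".mash_trajectory_cpp")]]
Rcpp::List mash_trajectory_cpp(
    const arma::vec& eps, const arma::mat& Jc,
    const arma::vec& omega, const arma::vec& coupling, double kT, double dt,
    int n_steps, const arma::vec& q0, const arma::vec& p0,
    const arma::cx_vec& c0, int active0) {  // active0 = -1 means argmax

  const int N = (int)eps.n_elem, M = (int)omega.n_elem;
  MashEngine eng(N, M);
  eng.eps = eps; eng.Jc = Jc; eng.om = omega; eng.om2 = square(omega);
  eng.cj = coupling; eng.kT = kT; eng.dt = dt;
  eng.q = q0; eng.p = p0; eng.c = c0 / norm(c0);
  Diag dg; eng.dg = &dg;
  eng.electronic_eigen();
  eng.active = (active0 >= 0) ? active0 : eng.argmax_pop();
  eng.amax = eng.argmax_pop();
  eng.start_segments();
  const double E0 = eng.energy();

  double max_norm_err = 0.0;
  for (int k = 0; k < n_steps; ++k) {
    eng.step_with_hops();
    if (k % 100 == 99) eng.check_drift();
    const double ne = std::abs(norm(eng.c) - 1.0);
    if (ne > max_norm_err) max_norm_err = ne;
  }
  eng.check_drift();
  return Rcpp::List::create(
    Rcpp::Named("q") = eng.q, Rcpp::Named("p") = eng.p,
    Rcpp::Named("c") = eng.c, Rcpp::Named("active") = eng.active + 1,
    Rcpp::Named("energy0") = E0, Rcpp::Named("energy") = eng.energy(),
    Rcpp::Named("adiabatic_energies") = eng.V,
    Rcpp::Named("n_hops") = (double)dg.n_hops,
    Rcpp::Named("n_frustrated") = (double)dg.n_frustrated,
    Rcpp::Named("max_norm_err") = max_norm_err,
    Rcpp::Named("max_seg_drift_rate") = dg.max_seg_drift_rate,
    Rcpp::Named("max_hop_err") = dg.max_hop_err);
}
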