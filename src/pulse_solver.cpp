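// Implicit 1D pulse-wave stepper for a branching arterial tree.
//
// Discretization: backward Euler in time on a staggered grid (pressures at
// nodes, flows at faces). Within each time step the nonlinear coefficients
// (area, area compliance, convective flux, junction dynamic-pressure
// offsets, friction denominator) are converged by Picard iteration, so the
// committed state satisfies the fully implicit equations to the requested
// residual tolerance.
//
// Per Picard pass each segment's interior pressure system is tridiagonal;
// it is condensed to an affine relation between the two boundary-node
// pressures and the boundary in/outflows (three tridiagonal solves per
// segment). Junction flow balance, the prescribed inlet flow, and the WK3
// terminal relations then close a small dense system over the boundary
// nodes, solved monolithically every pass.
//
// Units are SI throughout: Pa, m, m^3/s, kg/m^3, Pa s.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct WallLaw {
  double a1, b1, PmaxC, Pwidth, Pref; // pressures in Pa
};

inline double area_of_p(double P, double Aref, double Dref, const WallLaw& w) {
  const double at1 = std::atan((P - w.PmaxC) / w.Pwidth);
  const double at0 = std::atan((w.Pref - w.PmaxC) / w.Pwidth);
  return Aref * std::exp(w.a1 * Dref * (P - w.Pref) +
                         w.b1 * Dref * w.Pwidth * (at1 - at0));
}

inline double distens_of_p(double P, double Dref, const WallLaw& w) {
  const double x = (P - w.PmaxC) / w.Pwidth;
  return (w.a1 + w.b1 / (1.0 + x * x)) * Dref;
}

// Thomas algorithm; overwrites nothing, returns solution of the tridiagonal
// system with sub-diagonal a (a[0] unused), diagonal b, super-diagonal c
// (c[n-1] unused) for possibly several right-hand sides stacked in columns.
void thomas(const arma::vec& a, const arma::vec& b, const arma::vec& c,
            arma::mat& rhs) {
  const arma::uword n = b.n_elem;
  arma::vec cp(n);
  cp[0] = c[0] / b[0];
  rhs.row(0) /= b[0];
  for (arma::uword i = 1; i < n; ++i) {
    const double m = b[i] - a[i] * cp[i - 1];
    cp[i] = c[i] / m;
    rhs.row(i) = (rhs.row(i) - a[i] * rhs.row(i - 1)) / m;
  }
  for (arma::uword i = n - 1; i-- > 0;) {
    rhs.row(i) -= cp[i] * rhs.row(i + 1);
  }
}

} // namespace

// [[Rcpp::export(name = ".pulse_solver_cpp")]]
List pulse_solver_cpp(List net, NumericVector inlet_flow, double dt, int nt,
                      int n_cycles, List wall, List blood, List ctrl,
                      Nullable<List> init_state) {
  // ---- unpack network -------------------------------------------------
  const IntegerVector nn = net["n_nodes"];        // nodes per segment
  const IntegerVector noff = net["node_offset"];  // 0-based node offsets
  const NumericVector dzv = net["dz"];            // axial step per segment (m)
  const NumericVector Aref = net["Aref"];         // per node (m^2)
  const NumericVector Dref = net["Dref"];         // per node (1/Pa)
  const IntegerVector bnd_prox = net["bnd_prox"]; // boundary id per segment
  const IntegerVector bnd_dist = net["bnd_dist"];
  const IntegerVector bnd_type = net["bnd_type"]; // 0 inlet, 1 junction, 2 terminal
  const NumericVector tR1 = net["term_R1"];       // per boundary node (Pa s/m^3)
  const NumericVector tR2 = net["term_R2"];
  const NumericVector tC = net["term_C"];         // m^3/Pa
  const NumericVector tPout = net["term_Pout"];   // Pa

  const int nseg = nn.size();
  const int nbnd = bnd_type.size();
  int nnode = 0, nface = 0;
  std::vector<int> foff(nseg);
  for (int s = 0; s < nseg; ++s) {
    foff[s] = nface;
    nnode += nn[s];
    nface += nn[s] - 1;
  }

  const WallLaw w{as<double>(wall["a1"]), as<double>(wall["b1"]),
                  as<double>(wall["PmaxC"]), as<double>(wall["Pwidth"]),
                  as<double>(wall["Pref"])};
  const double rho = as<double>(blood["rho"]);
  const double mu = as<double>(blood["mu"]);
  const double zeta = as<double>(blood["zeta"]);
  const double kf = 2.0 * (zeta + 2.0) * M_PI * mu / rho; // friction coef (m^2/s)

  const double tol = as<double>(ctrl["picard_tol"]);   // relative, on P and Q
  const int maxit = as<int>(ctrl["picard_maxit"]);
  const bool debug = ctrl.containsElementNamed("debug") && as<bool>(ctrl["debug"]);

  // ---- state ----------------------------------------------------------
  arma::vec P(nnode), Qf(nface, arma::fill::zeros);
  arma::vec Qin(nseg, arma::fill::zeros), Qout(nseg, arma::fill::zeros);
  arma::vec Pc(nbnd, arma::fill::zeros);
  if (init_state.isNotNull()) {
    List st(init_state);
    P = as<arma::vec>(st["P"]);
    Qf = as<arma::vec>(st["Qf"]);
    Qin = as<arma::vec>(st["Qin"]);
    Qout = as<arma::vec>(st["Qout"]);
    Pc = as<arma::vec>(st["Pc"]);
  } else {
    P.fill(w.Pref);
    for (int b = 0; b < nbnd; ++b) {
      if (bnd_type[b] == 2) {
        const double RT = tR1[b] + tR2[b];
        Pc[b] = tPout[b] + (w.Pref - tPout[b]) * tR2[b] / RT;
      }
    }
  }

  // recording buffers (last cycle) and previous-cycle pressures
  arma::mat Prec(nnode, nt), Qrec(nnode, nt), Arec(nnode, nt);
  arma::mat Pcyc(nnode, nt, arma::fill::zeros), Pprev(nnode, nt, arma::fill::zeros);
  arma::vec cyc_metric(n_cycles, arma::fill::value(NA_REAL));
  arma::vec term_vol(nbnd, arma::fill::zeros); // outflow volume, last cycle
  double inflow_vol = 0.0;                     // inflow volume, last cycle

  // Picard work vectors
  arma::vec A(nnode), CA(nnode);
  arma::vec g(nface), beta(nface);
  arma::vec Pit(nnode), Qfit(Qf), Qinit(Qin), Qoutit(Qout), Pcit(Pc);
  Pit = P;
  // condensed per-segment coefficients
  arma::mat qi(nseg, 3), qo(nseg, 3); // columns: const, coef P1', coef Pn'
  std::vector<arma::mat> X(nseg);     // interior solutions [x0 x1 xn]

  arma::mat M(nbnd, nbnd);
  arma::vec rhs(nbnd), y(nbnd);

  const int nsteps = nt * n_cycles;
  if (inlet_flow.size() < nsteps)
    stop("inlet flow vector shorter than nt * n_cycles");

  for (int step = 0; step < nsteps; ++step) {
    const double Qin_t = inlet_flow[step];
    // Picard initial guess: previous committed state
    Pit = P; Qfit = Qf; Qinit = Qin; Qoutit = Qout; Pcit = Pc;

    bool converged = false;
    double relax = 1.0, dP_prev = std::numeric_limits<double>::infinity();
    double dP_last = dP_prev;
    for (int it = 0; it < maxit; ++it) {
      // coefficients at current iterate
      for (int i = 0; i < nnode; ++i) {
        A[i] = area_of_p(Pit[i], Aref[i], Dref[i], w);
        CA[i] = distens_of_p(Pit[i], Dref[i], w) * A[i];
      }

      for (int s = 0; s < nseg; ++s) {
        const int n = nn[s], o = noff[s], fo = foff[s];
        const double dz = dzv[s];
        // convective flux F = Q^2/A at nodes (node flow = face average,
        // boundary rows use the boundary in/outflows)
        // faces
        for (int j = 0; j < n - 1; ++j) {
          const double Abar = 0.5 * (A[o + j] + A[o + j + 1]);
          const double alpha = 1.0 / (1.0 / dt + kf / Abar);
          double Fl, Fr;
          {
            const double Ql = (j == 0) ? Qinit[s] : 0.5 * (Qfit[fo + j - 1] + Qfit[fo + j]);
            const double Qr = (j == n - 2) ? Qoutit[s] : 0.5 * (Qfit[fo + j] + Qfit[fo + j + 1]);
            Fl = Ql * Ql / A[o + j];
            Fr = Qr * Qr / A[o + j + 1];
          }
          const double conv = (Fr - Fl) / dz;
          g[fo + j] = alpha * (Qf[fo + j] / dt - conv);
          beta[fo + j] = alpha * Abar / (rho * dz);
        }
        // interior tridiagonal (nodes 1..n-2 local), three right-hand sides
        const int ni = n - 2;
        arma::vec ta(ni), tb(ni), tc(ni);
        arma::mat tr(ni, 3, arma::fill::zeros);
        for (int k = 0; k < ni; ++k) {
          const int i = k + 1; // local node
          const double cap = CA[o + i] * dz / dt;
          ta[k] = -beta[fo + i - 1];
          tb[k] = cap + beta[fo + i - 1] + beta[fo + i];
          tc[k] = -beta[fo + i];
          tr(k, 0) = cap * P[o + i] - (g[fo + i] - g[fo + i - 1]);
        }
        tr(0, 1) = beta[fo];          // response to P1'
        tr(ni - 1, 2) = beta[fo + n - 2]; // response to Pn'
        thomas(ta, tb, tc, tr);
        X[s] = tr;
        // boundary flow condensation
        const double cap0 = CA[o] * (dz / 2.0) / dt;
        const double capn = CA[o + n - 1] * (dz / 2.0) / dt;
        // Qin = cap0*(P1'-P1_old) + g0 - beta0*(X1' - P1')
        qi(s, 0) = -cap0 * P[o] + g[fo] - beta[fo] * tr(0, 0);
        qi(s, 1) = cap0 + beta[fo] * (1.0 - tr(0, 1));
        qi(s, 2) = -beta[fo] * tr(0, 2);
        // Qout = g_{n-2} - beta_{n-2}*(Pn' - X_{n-2}') - capn*(Pn'-Pn_old)
        qo(s, 0) = g[fo + n - 2] + beta[fo + n - 2] * tr(ni - 1, 0) + capn * P[o + n - 1];
        qo(s, 1) = beta[fo + n - 2] * tr(ni - 1, 1);
        qo(s, 2) = -beta[fo + n - 2] * (1.0 - tr(ni - 1, 2)) - capn;
      }

      // dynamic-pressure offsets at junction-attached segment ends (lagged)
      arma::vec offp(nseg, arma::fill::zeros), offd(nseg, arma::fill::zeros);
      for (int s = 0; s < nseg; ++s) {
        const int o = noff[s], n = nn[s];
        if (bnd_type[bnd_prox[s]] == 1) {
          const double u = Qinit[s] / A[o];
          offp[s] = 0.5 * rho * u * u;
        }
        if (bnd_type[bnd_dist[s]] == 1) {
          const double u = Qoutit[s] / A[o + n - 1];
          offd[s] = 0.5 * rho * u * u;
        }
      }

      // assemble boundary system
      M.zeros(); rhs.zeros();
      auto add_flow = [&](int row, double sgn, int s, const arma::mat& q) {
        const int bp = bnd_prox[s], bd = bnd_dist[s];
        M(row, bp) += sgn * q(s, 1);
        M(row, bd) += sgn * q(s, 2);
        rhs[row] -= sgn * (q(s, 0) - q(s, 1) * offp[s] - q(s, 2) * offd[s]);
      };
      for (int s = 0; s < nseg; ++s) {
        const int bp = bnd_prox[s], bd = bnd_dist[s];
        if (bnd_type[bp] == 0) { // inlet: Qin = prescribed
          add_flow(bp, 1.0, s, qi);
          rhs[bp] += Qin_t;
        } else { // junction: child takes -Qin
          add_flow(bp, -1.0, s, qi);
        }
        if (bnd_type[bd] == 1) { // junction: parent contributes +Qout
          add_flow(bd, 1.0, s, qo);
        } else { // terminal WK3: Pn' - k*Qout - c0 = 0
          const double den = tC[bd] / dt + 1.0 / tR2[bd];
          const double k = tR1[bd] + 1.0 / den;
          const double c0 = (tC[bd] * Pc[bd] / dt + tPout[bd] / tR2[bd]) / den;
          M(bd, bd) += 1.0;
          add_flow(bd, -k, s, qo);
          rhs[bd] += c0;
        }
      }
      if (!arma::solve(y, M, rhs, arma::solve_opts::no_approx))
        stop("boundary system solve failed at step %d", step + 1);

      // back-substitution
      double dP_max = 0.0, dQ_max = 0.0, Q_scale = 1e-9;
      arma::vec Pnew(nnode), Qfnew(nface);
      arma::vec Qin_new(nseg), Qout_new(nseg), Pc_new(Pcit);
      for (int s = 0; s < nseg; ++s) {
        const int n = nn[s], o = noff[s], fo = foff[s];
        const double P1 = y[bnd_prox[s]] - offp[s];
        const double Pn = y[bnd_dist[s]] - offd[s];
        Pnew[o] = P1;
        Pnew[o + n - 1] = Pn;
        const arma::mat& tr = X[s];
        for (int k = 0; k < n - 2; ++k)
          Pnew[o + k + 1] = tr(k, 0) + tr(k, 1) * P1 + tr(k, 2) * Pn;
        for (int j = 0; j < n - 1; ++j)
          Qfnew[fo + j] = g[fo + j] - beta[fo + j] * (Pnew[o + j + 1] - Pnew[o + j]);
        Qin_new[s] = qi(s, 0) + qi(s, 1) * P1 + qi(s, 2) * Pn;
        Qout_new[s] = qo(s, 0) + qo(s, 1) * P1 + qo(s, 2) * Pn;
        const int bd = bnd_dist[s];
        if (bnd_type[bd] == 2) {
          const double den = tC[bd] / dt + 1.0 / tR2[bd];
          Pc_new[bd] = (tC[bd] * Pc[bd] / dt + Qout_new[s] + tPout[bd] / tR2[bd]) / den;
        }
      }
      for (int i = 0; i < nnode; ++i)
        dP_max = std::max(dP_max, std::abs(Pnew[i] - Pit[i]));
      for (int j = 0; j < nface; ++j) {
        Q_scale = std::max(Q_scale, std::abs(Qfnew[j]));
        dQ_max = std::max(dQ_max, std::abs(Qfnew[j] - Qfit[j]));
      }
      if (debug)
        Rcout << "step " << step + 1 << " it " << it + 1 << " dP " << dP_max
              << " dQ/Q " << dQ_max / Q_scale << " relax " << relax << "\n";
      // under-relax when the fixed point oscillates instead of contracting
      if (dP_max > 0.7 * dP_prev) relax = std::max(0.3, relax * 0.7);
      dP_prev = dP_max;
      Pit = (1.0 - relax) * Pit + relax * Pnew;
      Qfit = (1.0 - relax) * Qfit + relax * Qfnew;
      Qinit = (1.0 - relax) * Qinit + relax * Qin_new;
      Qoutit = (1.0 - relax) * Qoutit + relax * Qout_new;
      Pcit = Pc_new;
      if (!Pit.is_finite())
        stop("solver diverged (non-finite pressure) at step %d", step + 1);
      dP_last = dP_max;
      if (dP_max / w.Pref < tol && dQ_max / Q_scale < tol) {
        converged = true;
        break;
      }
    }
    // accept an iterate stalled at its round-off floor provided it is
    // within two orders of the requested tolerance
    if (!converged && !(dP_last / w.Pref < 100.0 * tol))
      stop("implicit step failed to converge at step %d (dP = %g Pa)",
           step + 1, dP_last);

    // commit
    P = Pit; Qf = Qfit; Qin = Qinit; Qout = Qoutit; Pc = Pcit;

    const int k_in_cycle = step % nt;
    const int cycle = step / nt;
    Pcyc.col(k_in_cycle) = P;
    if (cycle == n_cycles - 1) { // record reporting cycle
      Prec.col(k_in_cycle) = P;
      for (int s = 0; s < nseg; ++s) {
        const int n = nn[s], o = noff[s], fo = foff[s];
        Qrec(o, k_in_cycle) = Qin[s];
        Qrec(o + n - 1, k_in_cycle) = Qout[s];
        for (int i = 1; i < n - 1; ++i)
          Qrec(o + i, k_in_cycle) = 0.5 * (Qf[fo + i - 1] + Qf[fo + i]);
        const int bd = bnd_dist[s];
        if (bnd_type[bd] == 2) term_vol[bd] += Qout[s] * dt;
      }
      for (int i = 0; i < nnode; ++i)
        Arec(i, k_in_cycle) = area_of_p(P[i], Aref[i], Dref[i], w);
      inflow_vol += Qin_t * dt;
    }
    if (k_in_cycle == nt - 1) { // end of a cycle: periodicity metric
      if (cycle > 0) {
        double m = 0.0;
        for (int i = 0; i < nnode; ++i) {
          const arma::rowvec cur = Pcyc.row(i), prev = Pprev.row(i);
          const double num = arma::abs(cur - prev).max();
          double den = cur.max() - cur.min();
          if (den < 1.0) den = std::max(std::abs(arma::mean(cur)), 1.0);
          m = std::max(m, num / den);
        }
        cyc_metric[cycle] = m;
      }
      Pprev = Pcyc;
    }
  }

  return List::create(
      _["P"] = Prec, _["Q"] = Qrec, _["A"] = Arec,
      _["cycle_metric"] = cyc_metric,
      _["inflow_volume"] = inflow_vol,
      _["terminal_volume"] = term_vol,
      _["state"] = List::create(_["P"] = P, _["Qf"] = Qf, _["Qin"] = Qin,
                                _["Qout"] = Qout, _["Pc"] = Pc));
}
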