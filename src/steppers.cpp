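// Euler-Maruyama ensemble steppers for the pCF10 and toy networks.
//
// Cells advance with the extracellular inhibitor frozen, then the
// environment advances from the updated ensemble (first-order Lie
// splitting). In shared mode one I_ext is driven by the ensemble-average
// exchange (the population balance coupling); in private mode each cell
// drives its own copy (the isolated single-cell model), including the
// chemical-Langevin noise of the exchange channels when the inhibitor
// species is unmasked. Wiener increments are drawn per cell and species
// from R's RNG so runs are reproducible under set.seed().
//
// Negative excursions are clipped to zero after each step and counted.

#include <Rcpp.h>
using namespace Rcpp;

static const double NA_CONST = 6.02214076e23;

// parameter vector layout for pcf10 (see .pcf10_par_vector in R/):
// 0:K11 1:K12 2:K13 3:K14 4:K15 5:K16 6:K17 7:K18 8:K19 9:K26 10:K28
// 11:K35 12:K38 13:K39 14:K41 15:K42 16:K43 17:K45 18:K46 19:K48 20:K49
// 21:mu 22:n 23:phi 24:Vcell

// [[Rcpp::export(name = ".pcf10_advance_cpp")]]
List pcf10_advance(NumericMatrix X, IntegerVector k, double I_ext_shared,
                   NumericVector I_ext_private, double C_ext,
                   NumericVector p, int linear_variant, LogicalVector mask,
                   double dt, int n_steps, bool shared_env, bool divide,
                   bool within_class) {
  const int N = X.ncol();
  NumericMatrix x = clone(X);
  NumericVector Ip = clone(I_ext_private);
  double Ie = I_ext_shared;

  const double K11 = p[0], K12 = p[1], K13 = p[2], K14 = p[3], K15 = p[4],
               K16 = p[5], K17 = p[6], K18 = p[7], K19 = p[8], K26 = p[9],
               K28 = p[10], K35 = p[11], K38 = p[12], K39 = p[13],
               K41 = p[14], K42 = p[15], K43 = p[16], K45 = p[17],
               K46 = p[18], K48 = p[19], K49 = p[20], mu = p[21],
               nbind = p[22], phi = p[23], Vcell = p[24];
  const double omega = 1e-9 * NA_CONST * Vcell; // molecules per nM
  const double vol_ratio = phi / (1.0 - phi);
  const double sdt = std::sqrt(dt);

  long clipped = 0, divisions = 0;
  const bool noisy[6] = {mask[0] != 0, mask[1] != 0, mask[2] != 0,
                         mask[3] != 0, mask[4] != 0, mask[5] != 0};

  for (int step = 0; step < n_steps; ++step) {
    double secr_sum = 0.0;
    for (int i = 0; i < N; ++i) {
      const double env_I = shared_env ? Ie : Ip[i];
      double QS = x(0, i), QL = x(1, i), A = x(2, i), Ii = x(3, i),
             Ci = x(4, i), B = x(5, i);
      // transcription block
      double f;
      if (Ii <= 0.0) {
        f = 0.0;
      } else {
        f = 1.0 / (1.0 + K38 * std::pow(Ci / Ii, nbind));
      }
      const double b = K35 * A / (1.0 + K35 * A);
      const double TQ = k[i] * (K11 * f + K12 * (1.0 - f));
      const double TA = k[i] * (K13 * f + K14 * (1.0 - f));
      const double prodB =
          linear_variant ? K15 * QL
                         : K17 + K19 / (1.0 + std::exp(-K39 * (QL - K18)));

      double drift[6] = {TQ * b - (K41 + mu) * QS,
                         TQ * (1.0 - b) - (K42 + mu) * QL,
                         TA - TQ * b - (K43 + mu) * A,
                         K26 * env_I - (K46 + mu) * Ii,
                         K28 * C_ext - (K48 + mu) * Ci,
                         prodB - (K49 + mu) * B};
      double rates[6] = {TQ * b + K41 * QS,
                         TQ * (1.0 - b) + K42 * QL,
                         TA + TQ * b + K43 * A,
                         K26 * env_I + K46 * Ii,
                         K28 * C_ext + K48 * Ci,
                         prodB + K49 * B};
      for (int s = 0; s < 6; ++s) {
        double xi = x(s, i) + drift[s] * dt;
        if (noisy[s]) {
          xi += std::sqrt(rates[s] / omega) * sdt * R::norm_rand();
        }
        if (xi < 0.0) {
          xi = 0.0;
          ++clipped;
        }
        x(s, i) = xi;
      }
      const double secr = K16 * (x(0, i) + x(1, i));
      if (shared_env) {
        secr_sum += secr;
      } else {
        // private environment: own stochastic exchange only
        double dI = vol_ratio * (secr - K26 * Ip[i]) - (K45 + mu) * Ip[i];
        double Inew = Ip[i] + dI * dt;
        if (noisy[3]) { // peptide noise extends to the exchange channels
          const double omega_ext = omega * (1.0 - phi) / phi;
          const double rate =
              vol_ratio * (secr + K26 * Ip[i]) + K45 * Ip[i];
          Inew += std::sqrt(rate / omega_ext) * sdt * R::norm_rand();
        }
        if (Inew < 0.0) {
          Inew = 0.0;
          ++clipped;
        }
        Ip[i] = Inew;
      }
    }
    if (shared_env) {
      // empirical ensemble mean stands in for the expectation integral
      // (grouped exactly like the private-environment update so the two
      // couplings are bitwise identical for one cell)
      double dI = vol_ratio * (secr_sum / N - K26 * Ie) - (K45 + mu) * Ie;
      Ie += dI * dt;
      if (Ie < 0.0) {
        Ie = 0.0;
        ++clipped;
      }
    }
    if (divide) {
      const double pdiv = mu * dt;
      for (int i = 0; i < N; ++i) {
        if (R::unif_rand() < pdiv) {
          // daughters inherit the parent state and copy number exactly;
          // one cell is discarded (constant-number MC). Victim scope
          // "within_class" preserves the copy-number marginal that the
          // population balance fixes; "uniform" is the plain Moran scheme.
          int victim;
          do {
            victim = (int)std::floor(R::unif_rand() * N);
            if (victim >= N) victim = N - 1;
          } while (within_class && k[victim] != k[i]);
          for (int s = 0; s < 6; ++s) x(s, victim) = x(s, i);
          k[victim] = k[i];
          if (!shared_env) Ip[victim] = Ip[i];
          ++divisions;
        }
      }
    }
  }
  return List::create(_["x"] = x, _["k"] = k, _["I_ext"] = Ie,
                      _["I_ext_private"] = Ip, _["clipped"] = clipped,
                      _["divisions"] = divisions);
}

// toy parameter layout: 0:k1 1:kdS 2:kp 3:kdX 4:ku 5:kdI 6:ki 7:mu
// 8:Vcell 9:theta_p 10:theta_i 11:gamma 12:phi

// [[Rcpp::export(name = ".toy_advance_cpp")]]
List toy_advance(NumericMatrix X, NumericVector P, double I_ext_shared,
                 NumericVector I_ext_private, double precursor,
                 NumericVector p, LogicalVector mask, double dt, int n_steps,
                 bool shared_env, bool divide, bool within_class) {
  const int N = X.ncol();
  NumericMatrix x = clone(X);
  NumericVector Pc = clone(P);
  NumericVector Ip = clone(I_ext_private);
  double Ie = I_ext_shared;

  const double k1 = p[0], kdS = p[1], kp = p[2], kdX = p[3], ku = p[4],
               kdI = p[5], ki = p[6], mu = p[7], Vcell = p[8],
               thp = p[9], thi = p[10], gamma = p[11], phi = p[12];
  const double omega = Vcell / 1e-15; // molecules per arb.u./volume
  const double sdt = std::sqrt(dt);
  long clipped = 0, divisions = 0;
  const bool noisy[3] = {mask[0] != 0, mask[1] != 0, mask[2] != 0};

  for (int step = 0; step < n_steps; ++step) {
    double hi_sum = 0.0;
    for (int i = 0; i < N; ++i) {
      const double env_I = shared_env ? Ie : Ip[i];
      const double S = x(0, i), I = x(1, i), Xp = x(2, i);
      const bool on = S > I;
      const double hp = on ? thp : 1.0;
      const double hi = on ? thi : 1.0;
      const double genS = k1 * Pc[i] * precursor;
      const double upt = ku * env_I;

      // annihilation (gamma S I, stiff) is split off and integrated exactly
      // below; the Euler-Maruyama substep carries the remaining channels
      double drift[3] = {genS - (kdS + mu) * S, upt - (kdI + mu) * I,
                         kp * hp - (kdX + mu) * Xp};
      double rates[3] = {genS + kdS * S, upt + kdI * I,
                         kp * hp + kdX * Xp};
      for (int s = 0; s < 3; ++s) {
        double xi = x(s, i) + drift[s] * dt;
        if (noisy[s]) {
          xi += std::sqrt(rates[s] / omega) * sdt * R::norm_rand();
        }
        if (xi < 0.0) {
          xi = 0.0;
          ++clipped;
        }
        x(s, i) = xi;
      }
      // exact solution of dS/dt = dI/dt = -gamma S I over dt
      {
        const double a = x(0, i), b = x(1, i);
        const double m0 = std::min(a, b), M0 = std::max(a, b);
        const double d = M0 - m0;
        double m1;
        if (m0 <= 0.0) {
          m1 = 0.0;
        } else if (d <= 1e-12) {
          m1 = m0 / (1.0 + gamma * m0 * dt);
        } else if (gamma * d * dt > 700.0) {
          m1 = 0.0;
        } else {
          const double E = std::exp(-gamma * d * dt);
          m1 = d * m0 * E / (M0 - m0 * E);
        }
        if (a >= b) {
          x(0, i) = m1 + d;
          x(1, i) = m1;
        } else {
          x(0, i) = m1;
          x(1, i) = m1 + d;
        }
      }
      const double hinew = (x(0, i) > x(1, i)) ? thi : 1.0;
      if (shared_env) {
        hi_sum += hinew;
      } else {
        double dI = phi * (ki * hinew - ku * Ip[i]);
        double Inew = Ip[i] + dI * dt;
        if (Inew < 0.0) {
          Inew = 0.0;
          ++clipped;
        }
        Ip[i] = Inew;
      }
    }
    if (shared_env) {
      double dI = phi * (ki * (hi_sum / N) - ku * Ie);
      Ie += dI * dt;
      if (Ie < 0.0) {
        Ie = 0.0;
        ++clipped;
      }
    }
    if (divide) {
      const double pdiv = mu * dt;
      for (int i = 0; i < N; ++i) {
        if (R::unif_rand() < pdiv) {
          int victim;
          do {
            victim = (int)std::floor(R::unif_rand() * N);
            if (victim >= N) victim = N - 1;
          } while (within_class && Pc[victim] != Pc[i]);
          for (int s = 0; s < 3; ++s) x(s, victim) = x(s, i);
          Pc[victim] = Pc[i];
          if (!shared_env) Ip[victim] = Ip[i];
          ++divisions;
        }
      }
    }
  }
  return List::create(_["x"] = x, _["P"] = Pc, _["I_ext"] = Ie,
                      _["I_ext_private"] = Ip, _["clipped"] = clipped,
                      _["divisions"] = divisions);
}
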