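// Joint likelihood templates for statistical population reconstruction:
//   model_code 1 -- two-age-class small-game model (HT/AA x RE/FE families)
//   model_code 2 -- two-season wild-turkey model with known removals
// The Laplace approximation over the annual random effects is supplied by
// TMB; the templates only define the joint negative log-likelihood.
#include <TMB.hpp>

// Binomial log-pmf with continuous (Horvitz-Thompson or estimated) size.
// The size is softly clamped to at least x + 1 with a quadratic penalty so
// that optimizers exploring N < x recover instead of hitting NaN.
template <class Type>
Type dbinom_cont(Type x, Type n, Type p) {
  Type lo = x + Type(1);
  Type pen = CppAD::CondExpGt(n, lo, Type(0), (lo - n) * (lo - n));
  Type nc = CppAD::CondExpGt(n, lo, n, lo);
  return lgamma(nc + Type(1)) - lgamma(x + Type(1)) -
         lgamma(nc - x + Type(1)) + x * log(p) +
         (nc - x) * log(Type(1) - p) - pen;
}

template <class Type>
Type objective_function<Type>::operator()() {
  DATA_INTEGER(model_code);
  Type nll = Type(0);

  if (model_code == 1) {
    // ---- small-game model -------------------------------------------------
    DATA_VECTOR(xJ);      // juvenile harvest, length Y
    DATA_VECTOR(xA);      // adult harvest, length Y
    DATA_VECTOR(f);       // hunter effort, length Y
    DATA_IVECTOR(tel_year);  // 1-based year index of telemetry records
    DATA_VECTOR(tel_m);      // tagged at risk
    DATA_VECTOR(tel_y);      // tagged harvested
    DATA_VECTOR(Ntot);    // annual total abundances (HT plug-in for CE)
    DATA_UPDATE(Ntot);    // refreshed between EM iterations without retaping
    DATA_INTEGER(aa_mode);   // 1: entry abundances are parameters (AA)
    DATA_INTEGER(use_ce);    // 1: include catch-effort auxiliary
    DATA_INTEGER(re_s);      // 1: survival random effects active
    DATA_INTEGER(re_c);      // 1: vulnerability random effects active

    PARAMETER(logit_s);
    PARAMETER(log_c);
    PARAMETER(log_sigma_s);
    PARAMETER(log_sigma_c);
    PARAMETER_VECTOR(delta);  // length Y
    PARAMETER_VECTOR(nu);     // length Y
    PARAMETER_VECTOR(logN);   // length Y+1 (AA only; mapped off for HT)

    int Y = xJ.size();
    vector<Type> s(Y), P(Y);
    for (int i = 0; i < Y; i++) {
      s(i) = invlogit(logit_s + delta(i));
      P(i) = Type(1) - exp(-exp(log_c) * f(i) * exp(nu(i)));
    }
    // Cohort entry abundances: free parameters for the AA family, or the
    // Horvitz-Thompson estimator at the current parameter values (entry-cell
    // harvest scaled by that cell's harvest probability) for the HT family.
    vector<Type> N(Y + 1);
    for (int j = 0; j <= Y; j++) {
      if (aa_mode == 1) {
        N(j) = exp(logN(j));
      } else {
        N(j) = (j == 0) ? xA(0) / P(0) : xJ(j - 1) / P(j - 1);
      }
    }

    // Cohort recursion: expected harvest in each observable cell, adult
    // cells pooling additively, and pre-harvest total abundance per year.
    vector<Type> EJ(Y), EA(Y), TotN(Y);
    EJ.setZero(); EA.setZero(); TotN.setZero();
    for (int j = 0; j <= Y; j++) {
      int e = (j == 0) ? 0 : j - 1;  // entry year (0-based)
      Type alive = N(j);
      for (int t = e; t < Y; t++) {
        TotN(t) += alive;
        Type Eht = alive * P(t);
        if (j > 0 && t == e) EJ(t) += Eht; else EA(t) += Eht;
        alive *= (Type(1) - P(t)) * s(t);
        if (j == Y) break;  // final-year juvenile cohort: single cell
      }
    }

    // Conditional multinomial over all 2Y cells.
    Type Esum = EJ.sum() + EA.sum();
    Type Tobs = xJ.sum() + xA.sum();
    Type ll = lgamma(Tobs + Type(1));
    for (int i = 0; i < Y; i++) {
      if (asDouble(xJ(i)) > 0) {
        ll += xJ(i) * log(EJ(i) / Esum) - lgamma(xJ(i) + Type(1));
      }
      if (asDouble(xA(i)) > 0) {
        ll += xA(i) * log(EA(i) / Esum) - lgamma(xA(i) + Type(1));
      }
    }
    // Edge cohorts: initial pooled adults and final-year juveniles.
    ll += dbinom_cont(xA(0), N(0), P(0));
    ll += dbinom_cont(xJ(Y - 1), N(Y), P(Y - 1));

    // Radiotelemetry (single shared vulnerability => pooled class).
    for (int k = 0; k < tel_year.size(); k++) {
      ll += dbinom(tel_y(k), tel_m(k), P(tel_year(k) - 1), true);
    }

    // Auxiliary catch-effort likelihood.
    if (use_ce == 1) {
      for (int i = 0; i < Y; i++) {
        Type Ni = aa_mode == 1 ? TotN(i) : Ntot(i);
        ll += dbinom_cont(xJ(i) + xA(i), Ni, P(i));
      }
    }

    // Random-effects penalty.
    if (re_s == 1) {
      for (int i = 0; i < Y; i++) {
        ll += dnorm(delta(i), Type(0), exp(log_sigma_s), true);
      }
    }
    if (re_c == 1) {
      for (int i = 0; i < Y; i++) {
        ll += dnorm(nu(i), Type(0), exp(log_sigma_c), true);
      }
    }

    // Annual total abundance for reporting: HT per-cell estimator, or the
    // model-propagated pre-harvest total for AA models.
    vector<Type> Nann(Y);
    for (int i = 0; i < Y; i++) {
      Nann(i) = aa_mode == 1 ? TotN(i) : (xJ(i) + xA(i)) / P(i);
    }
    ADREPORT(Nann);
    REPORT(EJ); REPORT(EA); REPORT(TotN); REPORT(P); REPORT(s);
    nll = -ll;

  } else {
    // ---- two-season turkey model ------------------------------------------
    DATA_VECTOR(xJ);       // spring permitted harvest, juveniles
    DATA_VECTOR(xA);       // spring permitted harvest, adults
    DATA_VECTOR(f);        // spring hunter effort
    DATA_VECTOR(RA_fall);  // fall harvest (known removal), adults
    DATA_IVECTOR(telt_year);
    DATA_VECTOR(telt_mJ); DATA_VECTOR(telt_yJ);
    DATA_VECTOR(telt_mA); DATA_VECTOR(telt_yA);
    DATA_INTEGER(re_cJ); DATA_INTEGER(re_cA); DATA_INTEGER(re_s);
    DATA_SCALAR(w_summer);  // 22/46
    DATA_SCALAR(w_winter);  // 24/46
    DATA_SCALAR(f_mean);    // mean spring effort, for reported rates

    PARAMETER_VECTOR(log_cv);  // (log c_J, log c_A); tie via map for 1-c
    PARAMETER(logit_s);
    PARAMETER_VECTOR(log_sig);  // (sigma_cJ, sigma_cA, sigma_s)
    PARAMETER_VECTOR(nu2);      // (nu_J_1..Y, nu_A_1..Y)
    PARAMETER_VECTOR(dlt);      // survival effects, length Y

    int Y = xJ.size();
    vector<Type> PJ(Y), PA(Y), s(Y), Javail(Y), Aavail(Y);
    for (int i = 0; i < Y; i++) {
      PJ(i) = Type(1) - exp(-exp(log_cv(0)) * f(i) * exp(nu2(i)));
      PA(i) = Type(1) - exp(-exp(log_cv(1)) * f(i) * exp(nu2(Y + i)));
      s(i) = invlogit(logit_s + dlt(i));
      // availabilities at the spring harvest: Horvitz-Thompson estimates at
      // the current parameter values
      Javail(i) = xJ(i) / PJ(i);
      Aavail(i) = xA(i) / PA(i);
    }

    // Expected spring harvest: juveniles (and first-year adults) anchored at
    // the availabilities; later adult cells predicted through the
    // within-year chain: spring survivors of both classes -> 22-week summer
    // survival -> fall adult harvest (known removal) -> 24-week winter
    // survival -> available adults next spring.  Spring NPR removals occur
    // before the permitted harvest, so the HT availabilities are already net
    // of them; they re-enter only in the abundance totals.
    // Juvenile cohorts are anchored at entry by their Horvitz-Thompson
    // availability; the adult pool starts at its first-year HT availability
    // and is then propagated forward through the chain, so natural survival
    // is identified by the cumulative adult dynamics.
    vector<Type> EJ(Y), EA(Y);
    for (int i = 0; i < Y; i++) EJ(i) = Javail(i) * PJ(i);
    Type Apool = Aavail(0);
    EA(0) = Apool * PA(0);
    for (int i = 0; i < Y - 1; i++) {
      Type Apred = (Javail(i) * (Type(1) - PJ(i)) +
                    Apool * (Type(1) - PA(i))) * pow(s(i), w_summer);
      Apred -= RA_fall(i);
      nll += CppAD::CondExpGt(Apred, Type(1), Type(0),
                              (Type(1) - Apred) * (Type(1) - Apred));
      Apred = CppAD::CondExpGt(Apred, Type(1), Apred, Type(1));
      Apred *= pow(s(i), w_winter);
      Apool = Apred;
      EA(i + 1) = Apool * PA(i + 1);
    }

    Type Esum = EJ.sum() + EA.sum();
    Type Tobs = xJ.sum() + xA.sum();
    Type ll = lgamma(Tobs + Type(1));
    for (int i = 0; i < Y; i++) {
      if (asDouble(xJ(i)) > 0) {
        ll += xJ(i) * log(EJ(i) / Esum) - lgamma(xJ(i) + Type(1));
      }
      if (asDouble(xA(i)) > 0) {
        ll += xA(i) * log(EA(i) / Esum) - lgamma(xA(i) + Type(1));
      }
    }
    ll += dbinom_cont(xA(0), Aavail(0), PA(0));
    ll += dbinom_cont(xJ(Y - 1), Javail(Y - 1), PJ(Y - 1));

    for (int k = 0; k < telt_year.size(); k++) {
      int i = telt_year(k) - 1;
      ll += dbinom(telt_yJ(k), telt_mJ(k), PJ(i), true);
      ll += dbinom(telt_yA(k), telt_mA(k), PA(i), true);
    }

    if (re_cJ == 1) {
      for (int i = 0; i < Y; i++) {
        ll += dnorm(nu2(i), Type(0), exp(log_sig(0)), true);
      }
    }
    if (re_cA == 1) {
      for (int i = 0; i < Y; i++) {
        ll += dnorm(nu2(Y + i), Type(0), exp(log_sig(1)), true);
      }
    }
    if (re_s == 1) {
      for (int i = 0; i < Y; i++) {
        ll += dnorm(dlt(i), Type(0), exp(log_sig(2)), true);
      }
    }

    // Spring Horvitz-Thompson abundance (removals added as constants in R).
    vector<Type> NhtJ(Y), Nht(Y);
    for (int i = 0; i < Y; i++) {
      NhtJ(i) = xJ(i) / PJ(i);
      Nht(i) = NhtJ(i) + xA(i) / PA(i);
    }
    Type P_juv_mean = Type(1) - exp(-exp(log_cv(0)) * f_mean);
    Type P_adult_mean = Type(1) - exp(-exp(log_cv(1)) * f_mean);
    Type s_annual = invlogit(logit_s);
    ADREPORT(Nht); ADREPORT(NhtJ);
    ADREPORT(P_juv_mean); ADREPORT(P_adult_mean); ADREPORT(s_annual);
    REPORT(EJ); REPORT(EA); REPORT(PJ); REPORT(PA); REPORT(s);
    nll += -ll;
  }
  return nll;
}
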