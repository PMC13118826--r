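# Shared fixtures: small materials built in code, independent of the
# bundled library so library defects cannot mask construction defects.

mk_drug <- function(delta = 23.8, rho = 1.37, tg = 62, mm = 494.0) {
  material_record("drugA", "drug", delta_total = delta,
                  true_density = rho, tg = tg, molar_mass = mm)
}

mk_polymer <- function(delta = 22.2, rho = 1.18, tg = 145,
                       name = "polyB") {
  material_record(name, "polymer", delta_total = delta,
                  true_density = rho, tg = tg)
}

# Independent brute-force chi oracle: every quantity converted to base SI
# units explicitly, no shared code with flory_huggins_chi().
chi_oracle_si <- function(delta_drug_mpa_sqrt, delta_poly_mpa_sqrt,
                          molar_mass_g, density_g_cm3, temp_k) {
  pa_sqrt <- sqrt(1e6)                           # MPa^1/2 -> Pa^1/2
  dd_pa <- (delta_drug_mpa_sqrt - delta_poly_mpa_sqrt) * pa_sqrt
  vd_m3 <- (molar_mass_g / 1000) / (density_g_cm3 * 1000)  # kg / (kg/m^3)
  vd_m3 * dd_pa^2 / (8.314 * temp_k)
}

# Independent f2 oracle written straight from the defining formula.
f2_oracle <- function(r, t) {
  50 * log10(100 / sqrt(1 + mean((r - t)^2)))
}

# Analytic AUC of the Bateman curve from 0 to tend.
bateman_auc <- function(ka, ke, scale, tend) {
  scale * ka / (ka - ke) *
    ((1 - exp(-ke * tend)) / ke - (1 - exp(-ka * tend)) / ka)
}
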