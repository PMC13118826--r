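#' Solubility parameter difference between drug and polymer
#'
#' \eqn{\Delta\delta = |\delta_{drug} - \delta_{polymer}|}. A small
#' difference in total solubility parameter indicates similar cohesive
#' energy density and hence a high probability of miscibility.
#'
#' @param drug,polymer [material_record()]s carrying `delta_total`
#'   (directly or derived from Hansen components).
#' @return Delta-delta in MPa^1/2 (non-negative, symmetric in arguments).
#' @examples
#' lib <- material_library()
#' delta_delta(get_material(lib, "GLB"), get_material(lib, "PVP K25")) # 1.6
#' @export
delta_delta <- function(drug, polymer) {
  for (m in list(drug, polymer)) {
    stopifnot(inherits(m, "material_record"))
    if (is.null(m$delta_total) || !is.finite(m$delta_total)) {
      stop("material '", m$name, "' has no usable delta_total")
    }
  }
  abs(drug$delta_total - polymer$delta_total)
}

#' Flory--Huggins interaction parameter from solubility parameters
#'
#' \eqn{\chi = V_d (\Delta\delta)^2 / (R T)} with the drug's molar volume
#' \eqn{V_d} (cm^3/mol, from molar mass and true density), R = 8.314
#' J mol^-1 K^-1 and T in kelvin. Units cancel exactly: \eqn{V_d} in
#' m^3/mol is the cm^3 value times 1e-6 and \eqn{(\Delta\delta)^2} in J/m^3
#' is the MPa value times 1e6, so the numeric product of the cm^3 and MPa
#' quantities over RT is already dimensionless.
#'
#' Low chi means favourable mixing free energy; chi above 0.5 signals
#' limited miscibility and a tendency toward phase separation.
#'
#' @inheritParams delta_delta
#' @param temperature Absolute temperature in kelvin (default 298).
#' @return chi, dimensionless and non-negative; 0 exactly when the two
#'   solubility parameters coincide.
#' @examples
#' lib <- material_library()
#' flory_huggins_chi(get_material(lib, "GLB"),
#'                   get_material(lib, "PVP K25")) # 0.373
#' @export
flory_huggins_chi <- function(drug, polymer, temperature = 298) {
  if (!is.finite(temperature) || temperature <= 0) {
    stop("temperature must be > 0 kelvin")
  }
  if (!is.finite(drug$molar_mass)) {
    stop("molar_mass is missing for drug '", drug$name,
         "'; it is required to form the molar volume in chi")
  }
  dd <- delta_delta(drug, polymer)
  vd <- molar_volume(drug$molar_mass, drug$true_density)
  # (cm^3/mol * 1e-6) * (MPa * 1e6 J/m^3) / (J/mol/K * K)
  vd * dd^2 / (.R_GAS * temperature)
}

#' Classify a solubility-parameter difference
#'
#' Differences below 7.0 MPa^1/2 point to a high probability of
#' miscibility; above 10.0 MPa^1/2, immiscibility. The band between is
#' "partially miscible", and exact boundary values fall in that band (the
#' thresholds are stated as strict inequalities).
#'
#' @param dd Delta-delta in MPa^1/2, non-negative.
#' @return One of `"miscible"`, `"partially_miscible"`, `"immiscible"`.
#' @export
classify_delta <- function(dd) {
  if (!is.finite(dd) || dd < 0) stop("delta_delta must be >= 0")
  if (dd < 7) "miscible" else if (dd > 10) "immiscible" else "partially_miscible"
}

#' Classify a Flory--Huggins interaction parameter
#'
#' chi above 0.5 reflects limited miscibility; at or below 0.5 the
#' interaction is classed favourable (the criterion is "chi > 0.5", so the
#' boundary value itself is favourable).
#'
#' @param chi Dimensionless, non-negative.
#' @return `"favourable"` or `"limited"`.
#' @export
classify_chi <- function(chi) {
  if (!is.finite(chi) || chi < 0) stop("chi must be >= 0")
  if (chi > 0.5) "limited" else "favourable"
}

#' Full miscibility assessment for one drug--polymer pair
#'
#' Combines [delta_delta()], [flory_huggins_chi()] and both
#' classifications into one record — one row of a miscibility screening
#' table.
#'
#' @inheritParams flory_huggins_chi
#' @return An object of class `miscibility_assessment` with fields `pair`,
#'   `delta_delta`, `chi`, `temperature`, `delta_class`, `chi_class`.
#' @examples
#' lib <- material_library()
#' assess_pair(get_material(lib, "GLB"), get_material(lib, "SOL"))
#' @export
assess_pair <- function(drug, polymer, temperature = 298) {
  dd <- delta_delta(drug, polymer)
  chi <- flory_huggins_chi(drug, polymer, temperature)
  structure(
    list(pair = c(drug = drug$name, polymer = polymer$name),
         delta_delta = dd, chi = chi, temperature = temperature,
         delta_class = classify_delta(dd), chi_class = classify_chi(chi)),
    class = "miscibility_assessment"
  )
}

#' @export
print.miscibility_assessment <- function(x, ...) {
  cat(sprintf("<miscibility_assessment> %s / %s at %g K\n",
              x$pair[["drug"]], x$pair[["polymer"]], x$temperature))
  cat(sprintf("  delta-delta %.4g MPa^1/2 (%s)\n",
              x$delta_delta, x$delta_class))
  cat(sprintf("  chi         %.4g (%s)\n", x$chi, x$chi_class))
  invisible(x)
}

#' Miscibility screen of one drug against several polymers
#'
#' @param library A `material_library`.
#' @param drug Name of the drug record.
#' @param polymers Polymer names; defaults to every record with role
#'   `"polymer"`.
#' @inheritParams flory_huggins_chi
#' @return A data frame with one row per pair: polymer, density,
#'   delta_delta, chi, delta_class, chi_class.
#' @export
screen_polymers <- function(library, drug, polymers = NULL,
                            temperature = 298) {
  d <- get_material(library, drug)
  if (is.null(polymers)) {
    polymers <- names(library)[vapply(library, `[[`, character(1), "role") ==
                                 "polymer"]
  }
  rows <- lapply(polymers, function(p) {
    a <- assess_pair(d, get_material(library, p), temperature)
    data.frame(polymer = p,
               true_density = get_material(library, p)$true_density,
               delta_delta = a$delta_delta, chi = a$chi,
               delta_class = a$delta_class, chi_class = a$chi_class,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
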