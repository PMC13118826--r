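#' Simha--Boyer constant for a binary amorphous mixture
#'
#' \eqn{K = \rho_1 T_{g1} / (\rho_2 T_{g2})}, where subscript 1 is the
#' component with the lower glass-transition temperature and subscript 2
#' the one with the higher. The rule rests on the observation that the
#' jump in thermal expansion coefficient at Tg is similar across amorphous
#' materials, so K can be approximated from density and Tg alone.
#'
#' `scale` controls the scale on which the temperatures enter the ratio.
#' `"celsius"` reproduces the convention under which the literature
#' constants for this system were evaluated; `"kelvin"` is the
#' thermodynamically conventional alternative and yields different numbers
#' (see the package vignette).
#'
#' @param component1 [material_record()] of the lower-Tg component.
#' @param component2 [material_record()] of the higher-Tg component.
#' @param scale `"celsius"` or `"kelvin"`.
#' @return K, dimensionless and positive.
#' @examples
#' lib <- material_library()
#' simha_boyer_k(get_material(lib, "GLB"), get_material(lib, "PVP K25"))
#' @export
simha_boyer_k <- function(component1, component2,
                          scale = c("celsius", "kelvin")) {
  scale <- match.arg(scale)
  stopifnot(inherits(component1, "material_record"),
            inherits(component2, "material_record"))
  tg1 <- material_tg(component1, scale)
  tg2 <- material_tg(component2, scale)
  if (tg1 > tg2) {
    stop("component1 must be the lower-Tg component (",
         component1$name, " has Tg ", tg1, " > ", component2$name,
         " Tg ", tg2, " on the ", scale, " scale)")
  }
  if (tg1 <= 0 || tg2 <= 0) {
    stop("glass-transition temperatures must be positive on the chosen ",
         "scale ('", scale, "'); got ", tg1, " and ", tg2)
  }
  component1$true_density * tg1 / (component2$true_density * tg2)
}

#' Gordon--Taylor glass-transition prediction for a drug--polymer mixture
#'
#' Predicts the single Tg of an ideally mixed binary amorphous system,
#' \deqn{T_g = \frac{W_1 T_{g1} + K W_2 T_{g2}}{W_1 + K W_2},}
#' with component 1 the lower-Tg component, weights the dry-mass
#' fractions, and K from [simha_boyer_k()] unless overridden. The
#' prediction always lies between the two pure-component Tg values and
#' reproduces them exactly at the endpoints.
#'
#' @param drug,polymer [material_record()]s; which is component 1 is
#'   resolved internally by comparing Tg.
#' @param w_drug Drug weight fraction in \[0, 1\].
#' @param scale `"celsius"` (the mode under which the reference
#'   predictions for this system reproduce) or `"kelvin"`. In kelvin mode
#'   both the Simha--Boyer ratio and the mixing rule are evaluated in
#'   kelvin and the result converted back to Celsius.
#' @param k Optional K override (e.g. the Fox-equation value
#'   \eqn{T_{g1}/T_{g2}} in kelvin); default is the Simha--Boyer value on
#'   the chosen scale.
#' @return An object of class `gordon_taylor_prediction` with fields
#'   `pair`, `w_drug`, `k`, `tg_predicted` (degrees Celsius),
#'   `scale_mode`.
#' @examples
#' lib <- material_library()
#' gordon_taylor_tg(get_material(lib, "GLB"),
#'                  get_material(lib, "PVP K25"), w_drug = 0.10)
#' @export
gordon_taylor_tg <- function(drug, polymer, w_drug,
                             scale = c("celsius", "kelvin"), k = NULL) {
  scale <- match.arg(scale)
  stopifnot(inherits(drug, "material_record"),
            inherits(polymer, "material_record"))
  if (!is.finite(w_drug) || w_drug < 0 || w_drug > 1) {
    stop("w_drug must be a weight fraction in [0, 1]")
  }
  tg_drug <- material_tg(drug, scale)
  tg_poly <- material_tg(polymer, scale)
  if (tg_drug <= tg_poly) {
    c1 <- drug; c2 <- polymer; w1 <- w_drug
  } else {
    c1 <- polymer; c2 <- drug; w1 <- 1 - w_drug
  }
  if (is.null(k)) k <- simha_boyer_k(c1, c2, scale)
  if (!is.finite(k) || k <= 0) stop("k must be positive")
  tg1 <- material_tg(c1, scale)
  tg2 <- material_tg(c2, scale)
  w2 <- 1 - w1
  tg <- (w1 * tg1 + k * w2 * tg2) / (w1 + k * w2)
  if (scale == "kelvin") tg <- tg - 273.15
  structure(
    list(pair = c(drug = drug$name, polymer = polymer$name),
         w_drug = w_drug, k = k, tg_predicted = tg,
         scale_mode = scale),
    class = "gordon_taylor_prediction"
  )
}

#' @export
print.gordon_taylor_prediction <- function(x, ...) {
  cat(sprintf("<gordon_taylor_prediction> %s in %s, w_drug = %.3g\n",
              x$pair[["drug"]], x$pair[["polymer"]], x$w_drug))
  cat(sprintf("  K = %.4f (%s mode); predicted Tg = %.2f degC\n",
              x$k, x$scale_mode, x$tg_predicted))
  invisible(x)
}

#' Compare a predicted Tg with an experimental value
#'
#' Agreement between the Gordon--Taylor prediction and the DSC-measured Tg
#' of the processed mixture is taken as evidence of a homogeneous,
#' single-phase glassy solution; the default closeness threshold is
#' 4 degrees Celsius.
#'
#' @param prediction A [gordon_taylor_tg()] result, or a numeric predicted
#'   Tg in degrees Celsius.
#' @param tg_experimental Experimental Tg, same scale (degrees Celsius).
#' @param threshold Closeness threshold in degrees Celsius (default 4).
#' @return An object of class `tg_comparison` with `tg_predicted`,
#'   `tg_experimental`, `delta_tg` (experimental minus predicted) and
#'   `single_phase_consistent`.
#' @export
compare_tg <- function(prediction, tg_experimental, threshold = 4) {
  tg_pred <- if (inherits(prediction, "gordon_taylor_prediction")) {
    prediction$tg_predicted
  } else if (is.numeric(prediction) && length(prediction) == 1L) {
    prediction
  } else {
    stop("prediction must be a gordon_taylor_prediction or a single number")
  }
  if (!is.finite(tg_experimental)) {
    stop("tg_experimental must be a finite number (degrees Celsius)")
  }
  if (!is.finite(threshold) || threshold <= 0) {
    stop("threshold must be positive")
  }
  dtg <- tg_experimental - tg_pred
  structure(
    list(tg_predicted = tg_pred, tg_experimental = tg_experimental,
         delta_tg = dtg, threshold = threshold,
         single_phase_consistent = abs(dtg) <= threshold),
    class = "tg_comparison"
  )
}

#' @export
print.tg_comparison <- function(x, ...) {
  cat(sprintf(
    "<tg_comparison> predicted %.2f, experimental %.2f, delta %+.2f degC\n",
    x$tg_predicted, x$tg_experimental, x$delta_tg))
  cat(sprintf("  single-phase consistent (|delta| <= %g): %s\n",
              x$threshold, x$single_phase_consistent))
  invisible(x)
}
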