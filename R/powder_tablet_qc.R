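#' Powder density pair (bulk and tapped)
#'
#' @param bulk,tapped Bulk and tapped density, g/mL. Vectors are treated
#'   as replicate measurements and summarised by their means (stored with
#'   standard deviations).
#' @return An object of class `powder_densities`.
#' @export
powder_densities <- function(bulk, tapped) {
  if (any(!is.finite(bulk)) || any(!is.finite(tapped))) {
    stop("densities must be finite numbers")
  }
  if (any(bulk <= 0)) stop("bulk density must be > 0")
  mb <- mean(bulk); mt <- mean(tapped)
  if (mb > mt) {
    stop("bulk density (", mb, ") exceeds tapped density (", mt,
         "): physically impossible — tapping can only consolidate")
  }
  structure(
    list(bulk_density = mb, tapped_density = mt,
         bulk_sd = if (length(bulk) > 1) sd(bulk) else NA_real_,
         tapped_sd = if (length(tapped) > 1) sd(tapped) else NA_real_,
         n = max(length(bulk), length(tapped))),
    class = "powder_densities"
  )
}

#' Carr's (compressibility) index
#'
#' \eqn{CI = (\rho_t - \rho_b)/\rho_t \times 100}: the percentage volume
#' reduction on tapping. Higher values mean a more compressible, poorer
#' flowing powder. Scale-invariant in the densities.
#'
#' @param bulk Bulk density (g/mL), or a [powder_densities()] object (in
#'   which case `tapped` is ignored).
#' @param tapped Tapped density, g/mL.
#' @return Carr's index in percent, within \[0, 100).
#' @examples
#' carrs_index(0.49, 0.60) # 18.3
#' @export
carrs_index <- function(bulk, tapped = NULL) {
  if (inherits(bulk, "powder_densities")) {
    d <- bulk
  } else {
    d <- powder_densities(bulk, tapped)
  }
  (d$tapped_density - d$bulk_density) / d$tapped_density * 100
}

#' USP <1174> flow classification from Carr's index
#'
#' Bands: excellent (CI <= 10), good (10, 15\], fair (15, 20\], passable
#' (20, 25\], poor (25, 31\], very poor (31, 37\], extremely poor (> 37).
#' The published band edges leave small gaps (e.g. 10--11, 37--38); the
#' implementation closes them with contiguous half-open intervals so every
#' non-negative CI has exactly one class.
#'
#' @param ci Carr's index, percent, >= 0.
#' @return One of `"excellent"`, `"good"`, `"fair"`, `"passable"`,
#'   `"poor"`, `"very_poor"`, `"extremely_poor"`.
#' @examples
#' classify_flow(18.3) # "fair"
#' @export
classify_flow <- function(ci) {
  if (!is.finite(ci) || ci < 0) stop("Carr's index must be >= 0")
  if (ci <= 10) "excellent"
  else if (ci <= 15) "good"
  else if (ci <= 20) "fair"
  else if (ci <= 25) "passable"
  else if (ci <= 31) "poor"
  else if (ci <= 37) "very_poor"
  else "extremely_poor"
}

#' Tablet batch acceptance check
#'
#' Immediate-release acceptance rules for this platform: friability
#' strictly below 0.5%, disintegration strictly below 60 s (close to the
#' reference product), and drug content within 90--110% of label claim
#' (inclusive).
#'
#' @param friability Percent weight loss, >= 0.
#' @param disintegration_s Disintegration time in seconds, >= 0.
#' @param content_pct Assayed drug content, percent of label.
#' @param limits Named list overriding the defaults `friability_max`
#'   (0.5), `disintegration_max_s` (60), `content_range` (c(90, 110)).
#' @return An object of class `tablet_qc` containing a per-criterion data
#'   frame (`criteria`) and an overall `pass` flag.
#' @examples
#' tablet_acceptance(friability = 0.46, disintegration_s = 20,
#'                   content_pct = 98.3)
#' @export
tablet_acceptance <- function(friability, disintegration_s, content_pct,
                              limits = list()) {
  vals <- c(friability, disintegration_s, content_pct)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all quality values must be finite and non-negative")
  }
  lim <- modifyList(list(friability_max = 0.5, disintegration_max_s = 60,
                         content_range = c(90, 110)), limits)
  criteria <- data.frame(
    criterion = c("friability", "disintegration", "content"),
    value = c(friability, disintegration_s, content_pct),
    limit = c(sprintf("< %g %%", lim$friability_max),
              sprintf("< %g s", lim$disintegration_max_s),
              sprintf("[%g, %g] %%", lim$content_range[1],
                      lim$content_range[2])),
    pass = c(friability < lim$friability_max,
             disintegration_s < lim$disintegration_max_s,
             content_pct >= lim$content_range[1] &
               content_pct <= lim$content_range[2]),
    stringsAsFactors = FALSE
  )
  structure(list(criteria = criteria, pass = all(criteria$pass)),
            class = "tablet_qc")
}

#' @export
print.tablet_qc <- function(x, ...) {
  cat("<tablet_qc>", if (x$pass) "PASS" else "FAIL", "\n")
  print(x$criteria, row.names = FALSE)
  invisible(x)
}
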