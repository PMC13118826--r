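#' Total (Hildebrand) solubility parameter from Hansen components
#'
#' Combines the dispersion, polar and hydrogen-bonding contributions into
#' the total solubility parameter,
#' \eqn{\delta_t = \sqrt{\delta_d^2 + \delta_p^2 + \delta_h^2}}.
#'
#' @param delta_d,delta_p,delta_h Hansen components, MPa^1/2. Must be
#'   non-negative; vectors recycle in the usual way.
#' @return Total solubility parameter in MPa^1/2. Always at least as large
#'   as the largest single component.
#' @examples
#' total_solubility_parameter(3, 4, 12) # 13
#' @export
total_solubility_parameter <- function(delta_d, delta_p, delta_h) {
  comps <- c(delta_d, delta_p, delta_h)
  if (any(!is.finite(comps))) {
    stop("Hansen components must be finite numbers")
  }
  if (any(comps < 0)) {
    stop("Hansen components must be non-negative (solubility parameters ",
         "are square roots of cohesive energy densities)")
  }
  sqrt(delta_d^2 + delta_p^2 + delta_h^2)
}

#' Molar volume from molar mass and true density
#'
#' @param molar_mass g/mol, > 0.
#' @param true_density g/cm^3, > 0.
#' @return Molar volume in cm^3/mol.
#' @examples
#' molar_volume(494.0, 1.37) # glibenclamide, ~360.6 cm^3/mol
#' @export
molar_volume <- function(molar_mass, true_density) {
  if (!is.finite(molar_mass) || molar_mass <= 0) {
    stop("molar_mass must be a positive number (g/mol)")
  }
  if (!is.finite(true_density) || true_density <= 0) {
    stop("true_density must be a positive number (g/cm^3)")
  }
  molar_mass / true_density
}

#' Material record for a drug or polymer
#'
#' Bundles the thermophysical constants the screening chain needs: total
#' and/or component Hansen solubility parameters, amorphous true density,
#' glass-transition temperature with an explicit scale, and (for the drug,
#' when the Flory--Huggins parameter is wanted) the molar mass.
#'
#' At least one of `delta_total` or the full (`delta_d`, `delta_p`,
#' `delta_h`) triple must be supplied. When both are given they must agree
#' within 0.05 MPa^1/2 under [total_solubility_parameter()].
#'
#' @param name Identifier, unique within a library.
#' @param role `"drug"` or `"polymer"`.
#' @param delta_total Total solubility parameter, MPa^1/2.
#' @param delta_d,delta_p,delta_h Hansen components, MPa^1/2.
#' @param true_density Amorphous true density, g/cm^3 (> 0).
#' @param tg Glass-transition temperature on the scale given by `tg_scale`.
#' @param tg_scale `"celsius"` (default, the convention in which literature
#'   Tg values are quoted) or `"kelvin"`.
#' @param molar_mass g/mol; required only when chi is to be computed with
#'   this material as the drug.
#' @return An object of class `material_record`.
#' @examples
#' glb <- material_record("GLB", "drug", delta_total = 23.8,
#'                        true_density = 1.37, tg = 62, molar_mass = 494.0)
#' glb
#' @export
material_record <- function(name, role = c("drug", "polymer"),
                            delta_total = NULL,
                            delta_d = NULL, delta_p = NULL, delta_h = NULL,
                            true_density, tg,
                            tg_scale = c("celsius", "kelvin"),
                            molar_mass = NULL) {
  role <- match.arg(role)
  tg_scale <- match.arg(tg_scale)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("name must be a single non-empty string")
  }
  if (!is.finite(true_density) || true_density <= 0) {
    stop("true_density must be > 0 (g/cm^3) for material '", name, "'")
  }
  if (!is.finite(tg)) stop("tg must be a finite number for '", name, "'")
  if (tg_scale == "kelvin" && tg <= 0) {
    stop("tg on the kelvin scale must be positive for '", name, "'")
  }
  comps <- list(delta_d, delta_p, delta_h)
  have_comps <- all(vapply(comps, function(x) !is.null(x) && is.finite(x),
                           logical(1)))
  if (is.null(delta_total) && !have_comps) {
    stop("material '", name, "' needs delta_total or the full ",
         "(delta_d, delta_p, delta_h) triple")
  }
  if (have_comps) {
    from_comps <- total_solubility_parameter(delta_d, delta_p, delta_h)
    if (is.null(delta_total)) {
      delta_total <- from_comps
    } else if (abs(delta_total - from_comps) > 0.05) {
      stop("delta_total (", delta_total, ") disagrees with the Hansen ",
           "components (", round(from_comps, 3),
           ") by more than 0.05 MPa^1/2 for '", name, "'")
    }
  }
  if (!is.null(molar_mass) && (!is.finite(molar_mass) || molar_mass <= 0)) {
    stop("molar_mass must be > 0 (g/mol) for '", name, "'")
  }
  structure(
    list(name = name, role = role,
         delta_total = delta_total,
         delta_d = if (have_comps) delta_d else NA_real_,
         delta_p = if (have_comps) delta_p else NA_real_,
         delta_h = if (have_comps) delta_h else NA_real_,
         true_density = true_density,
         tg = tg, tg_scale = tg_scale,
         molar_mass = if (is.null(molar_mass)) NA_real_ else molar_mass),
    class = "material_record"
  )
}

#' @export
print.material_record <- function(x, ...) {
  cat(sprintf("<material_record> %s (%s)\n", x$name, x$role))
  cat(sprintf("  delta_t %.4g MPa^1/2 | rho %.4g g/cm^3 | Tg %.4g %s\n",
              x$delta_total, x$true_density, x$tg,
              if (x$tg_scale == "celsius") "degC" else "K"))
  if (is.finite(x$molar_mass)) {
    cat(sprintf("  molar mass %.4g g/mol (Vm %.4g cm^3/mol)\n",
                x$molar_mass, x$molar_mass / x$true_density))
  }
  invisible(x)
}

#' Glass-transition temperature of a material on a chosen scale
#'
#' @param record A [material_record()].
#' @param scale `"celsius"` or `"kelvin"`.
#' @return Tg on the requested scale.
#' @export
material_tg <- function(record, scale = c("celsius", "kelvin")) {
  scale <- match.arg(scale)
  stopifnot(inherits(record, "material_record"))
  if (record$tg_scale == scale) return(record$tg)
  if (scale == "kelvin") record$tg + 273.15 else record$tg - 273.15
}

#' Read a materials table from delimited text
#'
#' Expects tab-delimited text with a header row and columns `name`, `role`,
#' `delta_total`, `delta_d`, `delta_p`, `delta_h`, `density`, `tg`,
#' `tg_scale`, `molar_mass`. Empty cells mean "not supplied". Every row is
#' validated through [material_record()].
#'
#' @param path Path to the file.
#' @return A `material_library`: a named list of [material_record()]s.
#' @seealso [material_library()] for the bundled constants.
#' @export
read_materials <- function(path) {
  if (!file.exists(path)) stop("materials file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("name", "role", "density", "tg")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    stop("materials file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  grab <- function(row, col) {
    if (!col %in% names(tab)) return(NULL)
    v <- row[[col]]
    if (is.na(v)) NULL else as.numeric(v)
  }
  recs <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    material_record(
      name = row$name, role = row$role,
      delta_total = grab(row, "delta_total"),
      delta_d = grab(row, "delta_d"), delta_p = grab(row, "delta_p"),
      delta_h = grab(row, "delta_h"),
      true_density = as.numeric(row$density), tg = as.numeric(row$tg),
      tg_scale = if ("tg_scale" %in% names(tab) && !is.na(row$tg_scale))
        row$tg_scale else "celsius",
      molar_mass = grab(row, "molar_mass")
    )
  })
  names(recs) <- vapply(recs, `[[`, character(1), "name")
  if (anyDuplicated(names(recs))) {
    stop("duplicate material names in ", path, ": ",
         paste(unique(names(recs)[duplicated(names(recs))]), collapse = ", "))
  }
  structure(recs, class = "material_library")
}

#' Bundled material parameter library
#'
#' Literature constants for glibenclamide (GLB) and the three carriers
#' studied alongside it: PVP K25, PVP VA64 (Kollidon VA64) and Soluplus
#' (SOL). Totals are literature Hansen parameters in MPa^1/2; densities are
#' amorphous true densities in g/cm^3; Tg values are in degrees Celsius.
#' The GLB molar mass (494.0 g/mol) is the standard chemical constant and
#' feeds the molar volume used by [flory_huggins_chi()].
#'
#' @return A `material_library` with entries `GLB`, `PVP K25`, `PVP VA64`
#'   and `SOL`. Values are identical on every call.
#' @examples
#' lib <- material_library()
#' get_material(lib, "GLB")
#' @export
material_library <- function() {
  path <- system.file("extdata", "materials.tsv", package = "asdtools",
                      mustWork = TRUE)
  read_materials(path)
}

#' Look up a material by name
#'
#' @param library A `material_library` (see [material_library()],
#'   [read_materials()]).
#' @param name Material name.
#' @return The [material_record()].
#' @export
get_material <- function(library, name) {
  stopifnot(inherits(library, "material_library"))
  if (!name %in% names(library)) {
    stop("material '", name, "' not found; available: ",
         paste(names(library), collapse = ", "))
  }
  library[[name]]
}

#' @export
print.material_library <- function(x, ...) {
  cat(sprintf("<material_library> %d materials\n", length(x)))
  for (m in x) {
    cat(sprintf("  %-10s %-7s delta_t %.4g  rho %.4g  Tg %.4g %s\n",
                m$name, m$role, m$delta_total, m$true_density, m$tg,
                if (m$tg_scale == "celsius") "degC" else "K"))
  }
  invisible(x)
}
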