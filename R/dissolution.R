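#' Dissolution profile container
#'
#' A cumulative dissolution curve for one formulation: strictly increasing
#' sampling times (minutes) and cumulative percent dissolved at each time.
#' An optional replicate matrix (times x vessels) carries the per-vessel
#' data behind the mean curve; when supplied, its row means must match
#' `dissolved` to within 1e-9.
#'
#' @param formulation Formulation label.
#' @param times Sampling times in minutes, strictly increasing, >= 0.
#' @param dissolved Cumulative percent dissolved, same length; values in
#'   \[0, 110\] (a little assay overshoot above 100 is tolerated).
#' @param replicates Optional numeric matrix, `length(times)` rows, one
#'   column per vessel.
#' @return An object of class `dissolution_profile`.
#' @export
dissolution_profile <- function(formulation, times, dissolved,
                                replicates = NULL) {
  if (length(times) != length(dissolved)) {
    stop("times and dissolved must have the same length")
  }
  if (any(!is.finite(times)) || any(!is.finite(dissolved))) {
    stop("times and dissolved must be finite")
  }
  if (any(times < 0) || is.unsorted(times, strictly = TRUE)) {
    stop("times must be non-negative and strictly increasing")
  }
  if (any(dissolved < 0 | dissolved > 110)) {
    stop("dissolved values must lie in [0, 110] percent")
  }
  if (!is.null(replicates)) {
    replicates <- as.matrix(replicates)
    if (nrow(replicates) != length(times)) {
      stop("replicates must have one row per time point")
    }
    if (max(abs(rowMeans(replicates) - dissolved)) > 1e-9) {
      stop("replicate row means disagree with the stored mean curve")
    }
  }
  structure(
    list(formulation = formulation, times = as.numeric(times),
         dissolved = as.numeric(dissolved), replicates = replicates,
         n_vessels = if (is.null(replicates)) NA_integer_ else
           ncol(replicates)),
    class = "dissolution_profile"
  )
}

#' @export
print.dissolution_profile <- function(x, ...) {
  cat(sprintf("<dissolution_profile> %s (%d points%s)\n", x$formulation,
              length(x$times),
              if (is.na(x$n_vessels)) "" else
                sprintf(", %d vessels", x$n_vessels)))
  print(data.frame(time_min = x$times, pct_dissolved = x$dissolved),
        row.names = FALSE)
  invisible(x)
}

#' Read dissolution profiles from long-format delimited text
#'
#' Expects tab-delimited text with header columns `formulation`,
#' `time_min`, `pct_dissolved` and optionally `vessel`. With a vessel
#' column, per-vessel curves are stored as replicates and the mean curve is
#' computed; without it each row is taken as the (mean) curve directly.
#'
#' @param path Path to the file.
#' @return A named list of [dissolution_profile()]s, one per formulation.
#' @export
read_dissolution <- function(path) {
  if (!file.exists(path)) stop("dissolution file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("formulation", "time_min", "pct_dissolved")
  if (!all(needed %in% names(tab))) {
    stop("dissolution file must have columns: ",
         paste(needed, collapse = ", "))
  }
  out <- lapply(split(tab, tab$formulation), function(d) {
    if ("vessel" %in% names(d) && length(unique(d$vessel)) > 1) {
      times <- sort(unique(d$time_min))
      vessels <- sort(unique(d$vessel))
      mat <- sapply(vessels, function(v) {
        dv <- d[d$vessel == v, ]
        dv$pct_dissolved[order(dv$time_min)]
      })
      dissolution_profile(d$formulation[1], times, rowMeans(mat),
                          replicates = mat)
    } else {
      d <- d[order(d$time_min), ]
      dissolution_profile(d$formulation[1], d$time_min, d$pct_dissolved)
    }
  })
  out
}

#' Write dissolution profiles to long-format delimited text
#'
#' Inverse of [read_dissolution()]; per-vessel replicates are written when
#' present.
#'
#' @param profiles A `dissolution_profile` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dissolution <- function(profiles, path) {
  if (inherits(profiles, "dissolution_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    if (!is.null(p$replicates)) {
      do.call(rbind, lapply(seq_len(ncol(p$replicates)), function(v) {
        data.frame(formulation = p$formulation, time_min = p$times,
                   pct_dissolved = p$replicates[, v], vessel = v)
      }))
    } else {
      data.frame(formulation = p$formulation, time_min = p$times,
                 pct_dissolved = p$dissolved)
    }
  })
  tab <- do.call(rbind, lapply(rows, function(r) {
    if (!"vessel" %in% names(r)) r$vessel <- NA_integer_
    r
  }))
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Similarity factor f2 between two dissolution profiles
#'
#' \deqn{f_2 = 50 \log_{10}\!\left(100\,\big[1 + \tfrac1n \sum_t (R_t -
#' T_t)^2\big]^{-1/2}\right)}
#' over the n shared time points. Identical profiles give exactly 100; the
#' value falls as the curves separate, and the regulatory similarity
#' threshold is f2 > 50 (an average point-wise difference of about 10%).
#'
#' The two profiles must share the same time grid; no interpolation is
#' performed (regulatory practice compares at common points). Optionally
#' the conventional truncation can be switched on so that at most one
#' point after both profiles exceed 85% dissolved enters the sum; it is
#' off by default.
#'
#' @param reference,test [dissolution_profile()]s on the same grid.
#' @param truncate_85 If `TRUE`, drop points after the first at which both
#'   profiles are >= 85% dissolved.
#' @return f2, dimensionless; symmetric in its arguments.
#' @examples
#' a <- dissolution_profile("A", c(10, 20, 30), c(40, 70, 90))
#' b <- dissolution_profile("B", c(10, 20, 30), c(30, 60, 80))
#' f2_similarity(a, b) # uniform 10% offset -> ~49.89
#' @export
f2_similarity <- function(reference, test, truncate_85 = FALSE) {
  stopifnot(inherits(reference, "dissolution_profile"),
            inherits(test, "dissolution_profile"))
  if (length(reference$times) != length(test$times) ||
      any(reference$times != test$times)) {
    stop("profiles are on different time grids; f2 requires common ",
         "sampling points (no interpolation is performed)")
  }
  r <- reference$dissolved
  t_ <- test$dissolved
  if (truncate_85) {
    over <- which(r >= 85 & t_ >= 85)
    if (length(over)) {
      keep <- seq_len(min(over[1], length(r)))
      r <- r[keep]; t_ <- t_[keep]
    }
  }
  n <- length(r)
  if (n < 1) stop("at least one shared time point is required")
  50 * log10(100 * (1 + sum((r - t_)^2) / n)^(-0.5))
}

# Linear interpolation of a cumulative curve at time t, with the implicit
# (0, 0) origin; beyond the last sample the last value is carried forward.
.dissolved_at <- function(profile, t) {
  times <- profile$times
  diss <- profile$dissolved
  if (times[1] > 0) {
    times <- c(0, times)
    diss <- c(0, diss)
  }
  approx(times, diss, xout = t, rule = 2)$y
}

#' Regulatory similarity decision for two dissolution profiles
#'
#' Implements the two-branch rule used for immediate-release comparisons:
#' if both profiles dissolve more than `cutoff` percent (default 85%) at
#' or before `t_rapid` minutes (default 15), they are very rapidly
#' dissolving and accepted as similar without an f2 computation (the f2
#' statistic loses discrimination there). Otherwise f2 is computed and the
#' profiles are similar iff f2 > 50.
#'
#' The 15-minute check linearly interpolates the cumulative curves
#' (anchored at the origin) when 15 min is not a sampling point; that is
#' the only interpolation in the module.
#'
#' @inheritParams f2_similarity
#' @param t_rapid Rapid-dissolution time point, minutes.
#' @param cutoff Rapid-dissolution cutoff, percent.
#' @return An object of class `similarity_decision` with fields `rule`
#'   (`"rapid_dissolution_exemption"` or `"f2_test"`), `f2` (NA under the
#'   exemption) and `similar`.
#' @export
similarity_decision <- function(reference, test, t_rapid = 15,
                                cutoff = 85, truncate_85 = FALSE) {
  r15 <- .dissolved_at(reference, t_rapid)
  t15 <- .dissolved_at(test, t_rapid)
  if (r15 > cutoff && t15 > cutoff) {
    out <- list(rule = "rapid_dissolution_exemption", f2 = NA_real_,
                similar = TRUE,
                detail = sprintf(
                  "both profiles > %g%% dissolved at %g min (%.1f / %.1f)",
                  cutoff, t_rapid, r15, t15))
  } else {
    f2 <- f2_similarity(reference, test, truncate_85 = truncate_85)
    out <- list(rule = "f2_test", f2 = f2, similar = f2 > 50,
                detail = sprintf("f2 = %.1f vs threshold 50", f2))
  }
  structure(out, class = "similarity_decision")
}

#' @export
print.similarity_decision <- function(x, ...) {
  cat("<similarity_decision>", if (x$similar) "SIMILAR" else "NOT similar",
      sprintf("(%s)\n  %s\n", x$rule, x$detail))
  invisible(x)
}

.KINETIC_MODELS <- c("zero_order", "first_order", "higuchi",
                     "hixson_crowell")

.kinetic_units <- c(zero_order = "%/min", first_order = "1/min",
                    higuchi = "%/min^0.5",
                    hixson_crowell = "%^(1/3)/min")

#' Fit one release-kinetics model to a dissolution profile
#'
#' Ordinary least squares on the model's standard linearisation:
#' \describe{
#'   \item{zero_order}{Q vs t; k in %/min.}
#'   \item{first_order}{ln(100 - Q) vs t; k = -slope, reported positive,
#'     in 1/min (natural log; divide by 2.303 for the log10 variant).}
#'   \item{higuchi}{Q vs sqrt(t); k in %/min^0.5. Strict Higuchi theory
#'     forces a zero intercept; the default fit leaves it free, and
#'     `through_origin = TRUE` imposes it.}
#'   \item{hixson_crowell}{100^(1/3) - (100 - Q)^(1/3) vs t; k in
#'     %^(1/3)/min.}
#' }
#' Goodness of fit is the R^2 of the linearised regression. For the
#' first-order and Hixson--Crowell transforms, points at or above 99.95%
#' dissolved are dropped with a warning (nothing remains to take the
#' log/cube root of); at least 3 usable points are required.
#'
#' @param profile A [dissolution_profile()].
#' @param model One of `"zero_order"`, `"first_order"`, `"higuchi"`,
#'   `"hixson_crowell"`.
#' @param through_origin Force a zero intercept (zero-order and Higuchi
#'   only).
#' @return An object of class `kinetic_fit`: `model`, `rate_constant`,
#'   `units`, `intercept`, `r_squared`, `n_points`.
#' @examples
#' p <- dissolution_profile("z", c(10, 20, 30, 45, 60),
#'                          2 * c(10, 20, 30, 45, 60))
#' fit_kinetic_model(p, "zero_order") # k = 2, R^2 = 1
#' @export
fit_kinetic_model <- function(profile, model = .KINETIC_MODELS,
                              through_origin = FALSE) {
  stopifnot(inherits(profile, "dissolution_profile"))
  model <- match.arg(model)
  t <- profile$times
  q <- profile$dissolved
  if (model %in% c("first_order", "hixson_crowell")) {
    usable <- q < 99.95
    if (!all(usable)) {
      warning(sum(!usable), " point(s) at >= 99.95% dissolved excluded ",
              "from the ", model, " fit (no drug remaining to transform)")
      t <- t[usable]; q <- q[usable]
    }
  }
  if (length(t) < 3) {
    stop("fewer than 3 usable points for the ", model, " fit")
  }
  xy <- switch(model,
    zero_order = list(x = t, y = q),
    first_order = list(x = t, y = log(100 - pmin(q, 100 - 1e-12))),
    higuchi = list(x = sqrt(t), y = q),
    hixson_crowell = list(x = t, y = 100^(1 / 3) - (100 - pmin(q, 100))^(1 / 3))
  )
  origin <- through_origin && model %in% c("zero_order", "higuchi")
  fit <- if (origin) lm(y ~ x + 0, data = xy) else lm(y ~ x, data = xy)
  cf <- coef(fit)
  slope <- cf[["x"]]
  intercept <- if ("(Intercept)" %in% names(cf)) cf[["(Intercept)"]] else 0
  k <- if (model == "first_order") -slope else slope
  # R^2 computed directly (lm's own convention: uncentered total SS for a
  # through-origin fit); avoids summary.lm's perfect-fit warning on exact
  # synthetic data
  ss_res <- sum(fit$residuals^2)
  ss_tot <- if (origin) sum(xy$y^2) else sum((xy$y - mean(xy$y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    list(model = model, rate_constant = k,
         units = .kinetic_units[[model]],
         intercept = intercept,
         r_squared = r2,
         n_points = length(t)),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> %s: k = %.5g %s, intercept %.4g, R^2 = %.4f (n = %d)\n",
              x$model, x$rate_constant, x$units, x$intercept,
              x$r_squared, x$n_points))
  invisible(x)
}

#' Fit all release-kinetics models and pick the best by R^2
#'
#' Fits the zero-order, first-order, Higuchi and Hixson--Crowell
#' linearisations and ranks them by the coefficient of determination of
#' the linearised fit. On an exact R^2 tie the fixed model order above
#' decides, with a warning.
#'
#' @inheritParams fit_kinetic_model
#' @return An object of class `kinetic_selection`: a ranked data frame
#'   `table` (model, rate_constant, units, intercept, r_squared) and the
#'   name of the `best` model.
#' @export
select_model <- function(profile, through_origin = FALSE) {
  fits <- lapply(.KINETIC_MODELS, function(m) {
    fit_kinetic_model(profile, m, through_origin = through_origin)
  })
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(model = f$model, rate_constant = f$rate_constant,
               units = f$units, intercept = f$intercept,
               r_squared = f$r_squared, stringsAsFactors = FALSE)
  }))
  best_r2 <- max(tab$r_squared)
  top <- which(abs(tab$r_squared - best_r2) == 0)
  if (length(top) > 1) {
    warning("exact R^2 tie between models ",
            paste(tab$model[top], collapse = ", "),
            "; keeping the first in the fixed model order")
  }
  # stable sort: ties stay in the fixed model order
  tab <- tab[order(-tab$r_squared), ]
  rownames(tab) <- NULL
  structure(list(table = tab, best = tab$model[1],
                 formulation = profile$formulation),
            class = "kinetic_selection")
}

#' @export
print.kinetic_selection <- function(x, ...) {
  cat(sprintf("<kinetic_selection> %s: best model = %s\n",
              x$formulation, x$best))
  print(x$table, row.names = FALSE)
  invisible(x)
}
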