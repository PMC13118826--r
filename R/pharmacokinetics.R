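#' Plasma concentration--time profile for one subject
#'
#' @param group Treatment group label.
#' @param subject Subject identifier.
#' @param times Sampling times in hours, strictly increasing, >= 0.
#' @param concentrations Plasma concentrations in ug/mL, non-negative,
#'   same length as `times`.
#' @return An object of class `plasma_profile`.
#' @export
plasma_profile <- function(group, subject, times, concentrations) {
  if (length(times) != length(concentrations)) {
    stop("times and concentrations must have the same length")
  }
  if (any(!is.finite(times)) || any(!is.finite(concentrations))) {
    stop("times and concentrations must be finite")
  }
  if (any(times < 0) || is.unsorted(times, strictly = TRUE)) {
    stop("times must be non-negative and strictly increasing")
  }
  if (any(concentrations < 0)) {
    stop("concentrations must be non-negative")
  }
  structure(
    list(group = group, subject = subject, times = as.numeric(times),
         concentrations = as.numeric(concentrations)),
    class = "plasma_profile"
  )
}

#' Read plasma profiles from long-format delimited text
#'
#' Expects tab-delimited text with header columns `group`, `subject`,
#' `time_h`, `conc_ug_ml`.
#'
#' @param path Path to the file.
#' @return A list of [plasma_profile()]s, one per (group, subject).
#' @export
read_plasma <- function(path) {
  if (!file.exists(path)) stop("plasma file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("group", "subject", "time_h", "conc_ug_ml")
  if (!all(needed %in% names(tab))) {
    stop("plasma file must have columns: ", paste(needed, collapse = ", "))
  }
  key <- interaction(tab$group, tab$subject, drop = TRUE)
  unname(lapply(split(tab, key), function(d) {
    d <- d[order(d$time_h), ]
    plasma_profile(d$group[1], d$subject[1], d$time_h, d$conc_ug_ml)
  }))
}

#' Write plasma profiles to long-format delimited text
#'
#' @param profiles A `plasma_profile` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plasma <- function(profiles, path) {
  if (inherits(profiles, "plasma_profile")) profiles <- list(profiles)
  tab <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(group = p$group, subject = p$subject, time_h = p$times,
               conc_ug_ml = p$concentrations)
  }))
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Non-compartmental analysis of one plasma profile
#'
#' Cmax and Tmax are read directly from the observations (ties on the
#' maximum broken by the earliest time). AUC from time zero to the last
#' sample is the linear trapezoid over the observed curve, with the point
#' (0, 0) prepended when the first sample is later than t = 0 (an oral
#' dose starts at zero plasma concentration).
#'
#' @param profile A [plasma_profile()] with at least 2 points.
#' @param loq Optional lower limit of quantification (ug/mL);
#'   concentrations below it are set to 0 before analysis. Default off.
#' @return An object of class `nca_result`: `cmax` (ug/mL), `tmax` (h),
#'   `auc_0_t` (ug h/mL), plus the group/subject labels and `t_last`.
#' @examples
#' p <- plasma_profile("g", 1, c(0, 1, 2), c(0, 2, 0))
#' nca(p) # Cmax 2 at Tmax 1, AUC 2 (triangle)
#' @export
nca <- function(profile, loq = NULL) {
  stopifnot(inherits(profile, "plasma_profile"))
  if (length(profile$times) < 2) {
    stop("at least 2 sampling points are required for NCA")
  }
  conc <- profile$concentrations
  if (!is.null(loq)) {
    if (!is.finite(loq) || loq < 0) stop("loq must be >= 0")
    conc[conc < loq] <- 0
  }
  times <- profile$times
  cmax <- max(conc)
  tmax <- times[which.max(conc)] # which.max -> earliest tie
  if (times[1] > 0) {
    times <- c(0, times)
    conc <- c(0, conc)
  }
  auc <- pracma::trapz(times, conc)
  structure(
    list(group = profile$group, subject = profile$subject,
         cmax = cmax, tmax = tmax, auc_0_t = auc,
         t_last = max(times)),
    class = "nca_result"
  )
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf(
    "<nca_result> %s / subject %s: Cmax %.4g ug/mL at Tmax %g h, AUC0-%g %.4g ug.h/mL\n",
    x$group, x$subject, x$cmax, x$tmax, x$t_last, x$auc_0_t))
  invisible(x)
}

#' Group summary of NCA parameters
#'
#' Runs [nca()] per subject, then reports arithmetic mean and sample
#' standard deviation of Cmax, Tmax and AUC over the group.
#'
#' @param profiles List of [plasma_profile()]s for one group (>= 1
#'   subject).
#' @inheritParams nca
#' @return An object of class `group_pk`: `group`, `n`, a `summary` data
#'   frame (parameter, mean, sd) and the per-subject `nca` table.
#' @export
group_summary <- function(profiles, loq = NULL) {
  if (inherits(profiles, "plasma_profile")) profiles <- list(profiles)
  if (length(profiles) < 1) stop("at least one subject is required")
  res <- lapply(profiles, nca, loq = loq)
  groups <- unique(vapply(res, `[[`, character(1), "group"))
  if (length(groups) > 1) {
    stop("profiles span several groups (", paste(groups, collapse = ", "),
         "); summarise one group at a time")
  }
  per_subject <- do.call(rbind, lapply(res, function(r) {
    data.frame(subject = r$subject, cmax = r$cmax, tmax = r$tmax,
               auc_0_t = r$auc_0_t, stringsAsFactors = FALSE)
  }))
  n <- nrow(per_subject)
  smry <- data.frame(
    parameter = c("cmax", "tmax", "auc_0_t"),
    mean = c(mean(per_subject$cmax), mean(per_subject$tmax),
             mean(per_subject$auc_0_t)),
    sd = if (n > 1) c(sd(per_subject$cmax), sd(per_subject$tmax),
                      sd(per_subject$auc_0_t)) else rep(NA_real_, 3),
    stringsAsFactors = FALSE
  )
  structure(list(group = groups, n = n, summary = smry,
                 nca = per_subject),
            class = "group_pk")
}

#' @export
print.group_pk <- function(x, ...) {
  cat(sprintf("<group_pk> %s (n = %d)\n", x$group, x$n))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

.group_mean <- function(x, parameter) {
  if (inherits(x, "group_pk")) {
    x$summary$mean[x$summary$parameter == parameter]
  } else if (is.numeric(x) && length(x) == 1L) {
    x
  } else {
    stop("expected a group_pk object or a single numeric group-mean value")
  }
}

#' Relative bioavailability from group-mean AUCs
#'
#' \eqn{F\% = 100 \times \overline{AUC}_{test} / \overline{AUC}_{ref}},
#' computed from the group mean AUC values (not per-subject ratios).
#'
#' @param test,reference [group_summary()] results, or bare numeric
#'   group-mean AUC values (ug h/mL).
#' @return An object of class `relative_bioavailability` with `f_percent`
#'   and the two group labels.
#' @examples
#' relative_bioavailability(11.28, 4.58) # 246.3%
#' @export
relative_bioavailability <- function(test, reference) {
  auc_t <- .group_mean(test, "auc_0_t")
  auc_r <- .group_mean(reference, "auc_0_t")
  if (!is.finite(auc_r) || auc_r <= 0) {
    stop("reference mean AUC must be > 0")
  }
  if (!is.finite(auc_t) || auc_t < 0) stop("test mean AUC must be >= 0")
  structure(
    list(f_percent = 100 * auc_t / auc_r,
         test = if (inherits(test, "group_pk")) test$group else "test",
         reference = if (inherits(reference, "group_pk"))
           reference$group else "reference"),
    class = "relative_bioavailability"
  )
}

#' @export
print.relative_bioavailability <- function(x, ...) {
  cat(sprintf("<relative_bioavailability> %s vs %s: F%% = %.1f\n",
              x$test, x$reference, x$f_percent))
  invisible(x)
}

#' One-way ANOVA across treatment groups
#'
#' Classical fixed-effects one-way analysis of variance (between/within
#' mean-square ratio on k - 1 and N - k degrees of freedom, via
#' [stats::aov()]) for a PK parameter measured per subject in two or more
#' groups. Significance is declared at p < 0.05.
#'
#' When the within-group variance is exactly zero but the group means
#' differ, the F ratio is unbounded; the result reports `F = Inf`,
#' `p = 0` and sets a `degenerate` flag rather than failing.
#'
#' @param values Numeric vector of per-subject parameter values.
#' @param groups Group labels, same length; at least 2 groups with at
#'   least 2 subjects each.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `pk_anova`: `f`, `df` (numerator,
#'   denominator), `p_value`, `significant`, `degenerate`.
#' @export
pk_anova <- function(values, groups, alpha = 0.05) {
  if (length(values) != length(groups)) {
    stop("values and groups must have the same length")
  }
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("at least 2 groups are required")
  if (any(table(groups) < 2)) {
    stop("every group needs at least 2 subjects")
  }
  fit <- aov(values ~ groups)
  tab <- anova(fit)
  ssw <- tab[["Sum Sq"]][2]
  ssb <- tab[["Sum Sq"]][1]
  # numerical zero relative to the scale of the data
  tol <- 1e-12 * max(1, sum(values^2))
  degenerate <- FALSE
  if (ssw <= tol) {
    if (ssb > tol) {
      f <- Inf; p <- 0; degenerate <- TRUE
    } else {
      f <- 0; p <- 1 # all observations identical
    }
  } else {
    f <- tab[["F value"]][1]
    p <- tab[["Pr(>F)"]][1]
  }
  structure(
    list(f = f, df = c(tab$Df[1], tab$Df[2]), p_value = p,
         significant = p < alpha, degenerate = degenerate,
         alpha = alpha),
    class = "pk_anova"
  )
}

#' @export
print.pk_anova <- function(x, ...) {
  cat(sprintf("<pk_anova> F(%d, %d) = %.4g, p = %.4g (%ssignificant at %g)%s\n",
              x$df[1], x$df[2], x$f, x$p_value,
              if (x$significant) "" else "not ", x$alpha,
              if (x$degenerate) " [zero within-group variance]" else ""))
  invisible(x)
}
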