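#' Closed-form cumulative release curves
#'
#' Evaluates the noise-free cumulative percent dissolved for one of the
#' four kinetic models at the given times:
#' zero order \eqn{Q = k t}; first order \eqn{Q = 100 (1 - e^{-k t})};
#' Higuchi \eqn{Q = k \sqrt t}; Hixson--Crowell
#' \eqn{Q = 100 - (100^{1/3} - k t)^3} (capped at 100 once the cube root
#' is exhausted). All curves are clipped to \[0, 100\].
#'
#' @param model One of `"zero_order"`, `"first_order"`, `"higuchi"`,
#'   `"hixson_crowell"`.
#' @param k Positive rate constant in the model's units (%/min; 1/min;
#'   %/min^0.5; %^(1/3)/min).
#' @param times Times in minutes.
#' @return Cumulative percent dissolved at each time.
#' @export
predict_release <- function(model = .KINETIC_MODELS, k, times) {
  model <- match.arg(model)
  if (!is.finite(k) || k <= 0) stop("rate constant must be positive")
  if (any(times < 0)) stop("times must be non-negative")
  q <- switch(model,
    zero_order = k * times,
    first_order = 100 * (1 - exp(-k * times)),
    higuchi = k * sqrt(times),
    hixson_crowell = 100 - (pmax(100^(1 / 3) - k * times, 0))^3
  )
  pmin(pmax(q, 0), 100)
}

# Derive independent sub-stream seeds from one study seed; kept < 2^31.
.stream_seed <- function(seed, stream) {
  (as.integer(seed) %% 100000L) * 10000L + as.integer(stream)
}

#' Simulation settings for a dissolution profile
#'
#' @param model Kinetic model generating the curve.
#' @param k Rate constant (model units).
#' @param times Sampling grid in minutes; default the standard 6-point
#'   immediate-release grid 10/20/30/45/60/120.
#' @param noise_sd SD of the additive Gaussian vessel noise, in percent
#'   dissolved (>= 0).
#' @param n_vessels Number of vessels (>= 1).
#' @param seed Integer seed; equal seeds give bit-identical output.
#' @param formulation Label for the simulated profile.
#' @return An object of class `dissolution_sim_spec`.
#' @export
dissolution_sim_spec <- function(model = .KINETIC_MODELS, k,
                                 times = c(10, 20, 30, 45, 60, 120),
                                 noise_sd = 0, n_vessels = 1, seed = 1,
                                 formulation = NULL) {
  model <- match.arg(model)
  if (!is.finite(k) || k <= 0) stop("rate constant must be positive")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_vessels < 1) stop("n_vessels must be >= 1")
  structure(
    list(model = model, k = k, times = times, noise_sd = noise_sd,
         n_vessels = as.integer(n_vessels), seed = as.integer(seed),
         formulation = if (is.null(formulation))
           paste0("sim_", model) else formulation),
    class = "dissolution_sim_spec"
  )
}

#' Simulate a dissolution profile
#'
#' Evaluates the spec's kinetic model on the grid, adds independent
#' Gaussian noise per vessel and time point, clips each vessel curve to
#' \[0, 100\], and returns the vessel-mean profile with the per-vessel
#' matrix attached. Fully determined by the spec's seed.
#'
#' @param spec A [dissolution_sim_spec()].
#' @return A [dissolution_profile()].
#' @examples
#' simulate_dissolution(dissolution_sim_spec("first_order", k = 0.03))
#' @export
simulate_dissolution <- function(spec) {
  stopifnot(inherits(spec, "dissolution_sim_spec"))
  clean <- predict_release(spec$model, spec$k, spec$times)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  mat <- sapply(seq_len(spec$n_vessels), function(v) {
    pmin(pmax(clean + rnorm(length(clean), 0, spec$noise_sd), 0), 100)
  })
  mat <- matrix(mat, nrow = length(spec$times))
  dissolution_profile(spec$formulation, spec$times, rowMeans(mat),
                      replicates = mat)
}

# Save/restore the global RNG state so seeded simulation helpers do not
# disturb a caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Bateman one-compartment oral-absorption curve
#'
#' \deqn{C(t) = S \frac{k_a}{k_a - k_e} (e^{-k_e t} - e^{-k_a t})}
#' with absorption rate `ka`, elimination rate `ke` (1/h, `ka != ke`) and
#' scale `S = F D / V` (ug/mL). The analytic time of maximum is
#' \eqn{t_{max} = \ln(k_a/k_e) / (k_a - k_e)}.
#'
#' @param times Hours.
#' @param ka,ke Absorption and elimination rate constants, 1/h, positive
#'   and distinct (the confluent `ka == ke` limit is not implemented;
#'   perturb one of them).
#' @param scale FD/V in ug/mL.
#' @return Concentrations in ug/mL, non-negative.
#' @export
bateman <- function(times, ka, ke, scale = 1) {
  if (!is.finite(ka) || !is.finite(ke) || ka <= 0 || ke <= 0) {
    stop("ka and ke must be positive rates (1/h)")
  }
  if (ka == ke) {
    stop("ka == ke is degenerate for the two-exponential form; ",
         "perturb one rate")
  }
  if (scale <= 0) stop("scale (FD/V) must be positive")
  pmax(scale * ka / (ka - ke) * (exp(-ke * times) - exp(-ka * times)), 0)
}

#' Simulation settings for a plasma cohort
#'
#' One treatment group of subjects following the Bateman one-compartment
#' oral-absorption model, with lognormal between-subject variability
#' applied multiplicatively and independently to `ka`, `ke` and the scale.
#'
#' @param ka,ke Typical absorption/elimination rates, 1/h.
#' @param scale Typical FD/V, ug/mL.
#' @param times Sampling grid in hours; default the standard rat grid
#'   0.25/0.5/1/2/4/8/12/24.
#' @param n_subjects Number of subjects (>= 1).
#' @param cv Between-subject coefficient of variation of the lognormal
#'   perturbations (e.g. 0.1 for 10%); >= 0.
#' @param seed Integer seed.
#' @param group Group label.
#' @return An object of class `pk_sim_spec`.
#' @export
pk_sim_spec <- function(ka = 1.5, ke = 0.2, scale = 1,
                        times = c(0.25, 0.5, 1, 2, 4, 8, 12, 24),
                        n_subjects = 5, cv = 0.1, seed = 1,
                        group = "sim") {
  if (!is.finite(ka) || !is.finite(ke) || ka <= 0 || ke <= 0) {
    stop("ka and ke must be positive")
  }
  if (ka == ke) stop("ka must differ from ke")
  if (scale <= 0) stop("scale must be positive")
  if (!is.finite(cv) || cv < 0) stop("cv must be >= 0")
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  structure(
    list(ka = ka, ke = ke, scale = scale, times = times,
         n_subjects = as.integer(n_subjects), cv = cv,
         seed = as.integer(seed), group = group),
    class = "pk_sim_spec"
  )
}

#' Simulate a plasma cohort
#'
#' Draws per-subject parameters as the typical values times independent
#' lognormal factors with the spec's CV (sdlog = sqrt(log(1 + CV^2)),
#' meanlog chosen so the multiplicative factor has mean 1), then evaluates
#' [bateman()] on the grid. Fully determined by the spec's seed.
#'
#' @param spec A [pk_sim_spec()].
#' @return A list of [plasma_profile()]s, one per subject.
#' @export
simulate_plasma <- function(spec) {
  stopifnot(inherits(spec, "pk_sim_spec"))
  sdlog <- sqrt(log(1 + spec$cv^2))
  meanlog <- -sdlog^2 / 2
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  lapply(seq_len(spec$n_subjects), function(s) {
    fac <- exp(rnorm(3, meanlog, sdlog))
    ka_s <- spec$ka * fac[1]
    ke_s <- spec$ke * fac[2]
    if (ka_s == ke_s) ka_s <- ka_s * (1 + 1e-9) # measure-zero guard
    plasma_profile(spec$group, s, spec$times,
                   bateman(spec$times, ka_s, ke_s, spec$scale * fac[3]))
  })
}

#' Generate a complete synthetic formulation study
#'
#' Builds the full data bundle the analysis chain consumes: four
#' dissolution arms (one slow Higuchi arm emulating a conventional
#' reference tablet, one moderate Higuchi arm emulating a
#' biphasic-release matrix, and two fast first-order arms emulating
#' immediate-release glassy-solution tablets) and four plasma cohorts
#' whose group-mean exposure ratios against the first (reference) group
#' are set by `auc_ratios`.
#'
#' Sub-streams (each arm, each cohort) get seeds derived from the single
#' study seed, so the bundle is reproducible component-wise.
#'
#' @param seed Integer study seed.
#' @param auc_ratios Named numeric vector of target group-mean AUC ratios
#'   relative to the first (reference) group, applied through the Bateman
#'   scale (AUC is linear in FD/V).
#' @param n_subjects Subjects per cohort.
#' @param cv Between-subject CV of the cohorts.
#' @param noise_sd Vessel noise SD of the dissolution arms, percent.
#' @param n_vessels Vessels per dissolution arm.
#' @return A list with `dissolution` (named list of
#'   [dissolution_profile()]s) and `plasma` (named list of cohorts, each a
#'   list of [plasma_profile()]s).
#' @export
make_study <- function(seed = 1,
                       auc_ratios = c(reference = 1, test_low = 0.95,
                                      test_mid = 1.25, test_high = 2.5),
                       n_subjects = 5, cv = 0.1,
                       noise_sd = 2, n_vessels = 6) {
  arms <- list(
    slow = dissolution_sim_spec("higuchi", k = 4.5,
                                noise_sd = noise_sd, n_vessels = n_vessels,
                                seed = .stream_seed(seed, 1),
                                formulation = "slow"),
    moderate = dissolution_sim_spec("higuchi", k = 9,
                                    noise_sd = noise_sd,
                                    n_vessels = n_vessels,
                                    seed = .stream_seed(seed, 2),
                                    formulation = "moderate"),
    fast_a = dissolution_sim_spec("first_order", k = 0.25,
                                  noise_sd = noise_sd,
                                  n_vessels = n_vessels,
                                  seed = .stream_seed(seed, 3),
                                  formulation = "fast_a"),
    fast_b = dissolution_sim_spec("first_order", k = 0.35,
                                  noise_sd = noise_sd,
                                  n_vessels = n_vessels,
                                  seed = .stream_seed(seed, 4),
                                  formulation = "fast_b")
  )
  dissolution <- lapply(arms, simulate_dissolution)
  plasma <- lapply(seq_along(auc_ratios), function(i) {
    simulate_plasma(pk_sim_spec(
      ka = 1.5, ke = 0.2, scale = auc_ratios[[i]],
      n_subjects = n_subjects, cv = cv,
      seed = .stream_seed(seed, 10 + i),
      group = names(auc_ratios)[i]
    ))
  })
  names(plasma) <- names(auc_ratios)
  list(dissolution = dissolution, plasma = plasma)
}
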