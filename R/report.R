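#' Configuration for a full formulation report
#'
#' Collects paths, names and thresholds for [run_full_report()]. Only the
#' material library is mandatory (it defaults to the bundled constants);
#' sections whose inputs are absent are skipped with a warning rather than
#' aborting, because formulation programmes are naturally staged.
#'
#' @param materials Path to a materials table ([read_materials()] format)
#'   or `NULL` for the bundled [material_library()].
#' @param drug Drug name in the library.
#' @param polymers Polymer names; default all polymers in the library.
#' @param w_drug Drug weight fraction for the Tg prediction.
#' @param temperature Kelvin, for the Flory--Huggins parameter.
#' @param tg_scale Scale mode for the Gordon--Taylor prediction.
#' @param experimental_tg Optional named numeric vector of experimental Tg
#'   values (degrees Celsius), names matching polymer names.
#' @param densities Optional data frame (or path to a tab-delimited file)
#'   with columns `formulation`, `bulk`, `tapped` for the flow section.
#' @param tablet_qc Optional data frame (or path) with columns
#'   `formulation`, `friability`, `disintegration_s`, `content_pct`.
#' @param dissolution Optional path to a [read_dissolution()] file.
#' @param dissolution_reference Formulation name used as the f2 reference.
#' @param plasma Optional path to a [read_plasma()] file.
#' @param plasma_reference Group name used as the F% reference.
#' @param tg_threshold Single-phase closeness threshold, degrees Celsius.
#' @param seed Seed recorded in the report (all randomness in a report run
#'   derives from it; the report itself is deterministic given inputs).
#' @return An object of class `run_config`.
#' @export
run_config <- function(materials = NULL, drug = "GLB", polymers = NULL,
                       w_drug = 0.10, temperature = 298,
                       tg_scale = "celsius", experimental_tg = NULL,
                       densities = NULL, tablet_qc = NULL,
                       dissolution = NULL, dissolution_reference = NULL,
                       plasma = NULL, plasma_reference = NULL,
                       tg_threshold = 4, seed = 1) {
  if (!is.finite(w_drug) || w_drug < 0 || w_drug > 1) {
    stop("w_drug must lie in [0, 1]")
  }
  if (!is.finite(temperature) || temperature <= 0) {
    stop("temperature must be > 0 K")
  }
  if (!is.finite(tg_threshold) || tg_threshold <= 0) {
    stop("tg_threshold must be positive")
  }
  for (p in c(materials, dissolution, plasma)) {
    if (is.character(p) && !file.exists(p)) {
      stop("input file not found: ", p)
    }
  }
  structure(
    list(materials = materials, drug = drug, polymers = polymers,
         w_drug = w_drug, temperature = temperature, tg_scale = tg_scale,
         experimental_tg = experimental_tg, densities = densities,
         tablet_qc = tablet_qc, dissolution = dissolution,
         dissolution_reference = dissolution_reference,
         plasma = plasma, plasma_reference = plasma_reference,
         tg_threshold = tg_threshold, seed = as.integer(seed)),
    class = "run_config"
  )
}

.load_table <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) read.delim(x, stringsAsFactors = FALSE) else x
}

#' Run the full formulation report
#'
#' Executes every pipeline stage whose inputs are available, in the order
#' of a formulation programme: miscibility screening, glass-transition
#' prediction, powder flow, tablet quality, dissolution similarity and
#' kinetics, pharmacokinetics. Missing optional inputs skip their section
#' with a warning. The returned object (and the JSON written by
#' [write_report()]) contains every number in the printed rendering.
#'
#' @param config A [run_config()].
#' @return An object of class `formulation_report`: a named list of
#'   section results plus the config echo.
#' @examples
#' rep <- run_full_report(run_config())
#' names(rep$sections)
#' @export
run_full_report <- function(config) {
  stopifnot(inherits(config, "run_config"))
  lib <- if (is.null(config$materials)) material_library() else
    read_materials(config$materials)
  drug <- get_material(lib, config$drug)
  polymers <- config$polymers
  if (is.null(polymers)) {
    polymers <- names(lib)[vapply(lib, `[[`, character(1), "role") ==
                             "polymer"]
  }
  sections <- list()

  sections$miscibility <- screen_polymers(lib, config$drug, polymers,
                                          config$temperature)

  sections$glass_transition <- do.call(rbind, lapply(polymers, function(p) {
    pred <- gordon_taylor_tg(drug, get_material(lib, p), config$w_drug,
                             scale = config$tg_scale)
    row <- data.frame(polymer = p, w_drug = config$w_drug, k = pred$k,
                      tg_predicted = pred$tg_predicted,
                      stringsAsFactors = FALSE)
    if (!is.null(config$experimental_tg)) {
      if (p %in% names(config$experimental_tg)) {
        cmp <- compare_tg(pred, config$experimental_tg[[p]],
                          config$tg_threshold)
        row$tg_experimental <- cmp$tg_experimental
        row$delta_tg <- cmp$delta_tg
        row$single_phase <- cmp$single_phase_consistent
      } else {
        row$tg_experimental <- NA_real_
        row$delta_tg <- NA_real_
        row$single_phase <- NA
      }
    }
    row
  }))

  dens <- .load_table(config$densities)
  if (is.null(dens)) {
    warning("no powder densities supplied; flow section skipped")
  } else {
    sections$flow <- do.call(rbind, lapply(seq_len(nrow(dens)), function(i) {
      ci <- carrs_index(dens$bulk[i], dens$tapped[i])
      data.frame(formulation = dens$formulation[i],
                 bulk = dens$bulk[i], tapped = dens$tapped[i],
                 carrs_index = ci, flow_class = classify_flow(ci),
                 stringsAsFactors = FALSE)
    }))
  }

  qc <- .load_table(config$tablet_qc)
  if (is.null(qc)) {
    warning("no tablet QC data supplied; tablet section skipped")
  } else {
    sections$tablet_qc <- do.call(rbind, lapply(seq_len(nrow(qc)), function(i) {
      res <- tablet_acceptance(qc$friability[i], qc$disintegration_s[i],
                               qc$content_pct[i])
      data.frame(formulation = qc$formulation[i],
                 friability = qc$friability[i],
                 disintegration_s = qc$disintegration_s[i],
                 content_pct = qc$content_pct[i], pass = res$pass,
                 stringsAsFactors = FALSE)
    }))
  }

  if (is.null(config$dissolution)) {
    warning("no dissolution file supplied; dissolution section skipped")
  } else {
    profs <- read_dissolution(config$dissolution)
    ref_name <- config$dissolution_reference
    if (is.null(ref_name)) ref_name <- names(profs)[1]
    if (!ref_name %in% names(profs)) {
      stop("dissolution reference '", ref_name, "' not among profiles: ",
           paste(names(profs), collapse = ", "))
    }
    tests <- setdiff(names(profs), ref_name)
    similarity <- do.call(rbind, lapply(tests, function(nm) {
      d <- similarity_decision(profs[[ref_name]], profs[[nm]])
      data.frame(reference = ref_name, test = nm, rule = d$rule,
                 f2 = d$f2, similar = d$similar, stringsAsFactors = FALSE)
    }))
    kinetics <- do.call(rbind, lapply(names(profs), function(nm) {
      sel <- suppressWarnings(select_model(profs[[nm]]))
      cbind(formulation = nm, sel$table)
    }))
    best <- vapply(names(profs), function(nm) {
      suppressWarnings(select_model(profs[[nm]]))$best
    }, character(1))
    sections$dissolution <- list(similarity = similarity,
                                 kinetics = kinetics,
                                 best_model = best)
  }

  if (is.null(config$plasma)) {
    warning("no plasma file supplied; pharmacokinetics section skipped")
  } else {
    profs <- read_plasma(config$plasma)
    groups <- unique(vapply(profs, `[[`, character(1), "group"))
    ref_group <- config$plasma_reference
    if (is.null(ref_group)) ref_group <- groups[1]
    if (!ref_group %in% groups) {
      stop("plasma reference group '", ref_group, "' not among groups: ",
           paste(groups, collapse = ", "))
    }
    gpk <- lapply(groups, function(g) {
      group_summary(Filter(function(p) p$group == g, profs))
    })
    names(gpk) <- groups
    summary_tab <- do.call(rbind, lapply(groups, function(g) {
      s <- gpk[[g]]$summary
      data.frame(group = g, n = gpk[[g]]$n,
                 cmax_mean = s$mean[s$parameter == "cmax"],
                 cmax_sd = s$sd[s$parameter == "cmax"],
                 tmax_mean = s$mean[s$parameter == "tmax"],
                 auc_mean = s$mean[s$parameter == "auc_0_t"],
                 auc_sd = s$sd[s$parameter == "auc_0_t"],
                 stringsAsFactors = FALSE)
    }))
    summary_tab$f_percent <- vapply(groups, function(g) {
      relative_bioavailability(gpk[[g]], gpk[[ref_group]])$f_percent
    }, numeric(1))
    auc_values <- unlist(lapply(gpk, function(g) g$nca$auc_0_t))
    auc_groups <- unlist(lapply(gpk, function(g) rep(g$group, g$n)))
    anova_res <- pk_anova(auc_values, auc_groups)
    sections$pharmacokinetics <- list(
      summary = summary_tab, reference = ref_group,
      anova_auc = list(f = anova_res$f, df = anova_res$df,
                       p_value = anova_res$p_value,
                       significant = anova_res$significant))
  }

  structure(list(config = config[!vapply(config, is.null, logical(1))],
                 sections = sections),
            class = "formulation_report")
}

#' Write a formulation report to JSON (and optionally text)
#'
#' The JSON carries every numeric value at full precision; the text
#' rendering of [print.formulation_report()] applies display rounding
#' only.
#'
#' @param report A [run_full_report()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly. Identical reports produce byte-identical
#'   files.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "formulation_report"))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null",
                       force = TRUE)
  invisible(path)
}

#' @export
print.formulation_report <- function(x, ...) {
  cat("==== Formulation report ====\n")
  s <- x$sections
  if (!is.null(s$miscibility)) {
    cat("\n-- Miscibility screening (drug:", x$config$drug, ") --\n")
    tab <- s$miscibility
    tab$delta_delta <- round(tab$delta_delta, 2)
    tab$chi <- signif(tab$chi, 3)
    print(tab, row.names = FALSE)
  }
  if (!is.null(s$glass_transition)) {
    cat("\n-- Gordon-Taylor Tg prediction (w_drug =",
        x$config$w_drug, ") --\n")
    tab <- s$glass_transition
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], round, 2)
    print(tab, row.names = FALSE)
  }
  if (!is.null(s$flow)) {
    cat("\n-- Powder flow --\n")
    tab <- s$flow
    tab$carrs_index <- round(tab$carrs_index, 1)
    print(tab, row.names = FALSE)
  }
  if (!is.null(s$tablet_qc)) {
    cat("\n-- Tablet QC --\n")
    print(s$tablet_qc, row.names = FALSE)
  }
  if (!is.null(s$dissolution)) {
    cat("\n-- Dissolution similarity --\n")
    tab <- s$dissolution$similarity
    tab$f2 <- round(tab$f2, 1)
    print(tab, row.names = FALSE)
    cat("\n-- Release kinetics (best model per formulation) --\n")
    print(data.frame(formulation = names(s$dissolution$best_model),
                     best_model = unname(s$dissolution$best_model)),
          row.names = FALSE)
  }
  if (!is.null(s$pharmacokinetics)) {
    cat("\n-- Pharmacokinetics (reference:",
        s$pharmacokinetics$reference, ") --\n")
    tab <- s$pharmacokinetics$summary
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], function(v) signif(v, 4))
    print(tab, row.names = FALSE)
    a <- s$pharmacokinetics$anova_auc
    cat(sprintf("  AUC one-way ANOVA: F(%d, %d) = %.3g, p = %.3g\n",
                a$df[1], a$df[2], a$f, a$p_value))
  }
  invisible(x)
}
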