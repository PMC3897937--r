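# End-to-end orchestration: simulate synthetic sections, measure them,
# simulate the randomised cohort, analyse it blinded-then-unblinded, and
# render a results report. Every random stage receives a seed derived
# deterministically from the master seed, so a run is reproducible
# byte-for-byte from its config.

#' Pipeline run configuration
#'
#' @param seed master seed; each stage derives its own stream from it.
#' @param out_dir run directory (named after the seed by default, so reruns
#'   are diffable).
#' @param stages character subset of
#'   `c("images", "measure", "cohort", "analyze", "report")`.
#' @param n_images number of synthetic sections to render.
#' @param scenario effect scenario for [effect_spec()].
#' @param n_per_letter,attrition_rate cohort size and biopsy-loss settings.
#' @param threshold_method automatic threshold method (only `"otsu"`).
#' @param tilt_tol_deg orientation tolerance for the adequacy screen.
#' @param welch,holm,alpha statistical options for [route_and_compare()].
#' @return a `run_config` list; round-trips losslessly through YAML with
#'   [write_run_config()] / [read_run_config()].
#' @export
run_config <- function(seed = 1L,
                       out_dir = file.path("runs", paste0("seed-", seed)),
                       stages = c("images", "measure", "cohort", "analyze", "report"),
                       n_images = 4,
                       scenario = "paper",
                       n_per_letter = 13,
                       attrition_rate = 14 / 52,
                       threshold_method = "otsu",
                       tilt_tol_deg = 30,
                       welch = FALSE, holm = FALSE, alpha = 0.05) {
  if (length(stages)) {
    stages <- match.arg(stages, several.ok = TRUE)
  } else {
    stages <- character(0)
  }
  if (threshold_method != "otsu") abort("only threshold_method = 'otsu' is available")
  structure(list(
    seed = as.integer(seed), out_dir = out_dir, stages = stages,
    n_images = as.integer(n_images), scenario = scenario,
    n_per_letter = as.integer(n_per_letter), attrition_rate = attrition_rate,
    threshold_method = threshold_method, tilt_tol_deg = tilt_tol_deg,
    welch = welch, holm = holm, alpha = alpha
  ), class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

stage_seed <- function(config, k) config$seed * 101L + k

#' Run the full pipeline
#'
#' Executes the configured stages in order and writes all artifacts under
#' `config$out_dir`: synthetic images + sidecars + `manifest.csv`,
#' `morphometry.csv`, `cohort.csv` + `code_map.json` (the manufacturer's
#' sealed envelope), `results.csv`, a CONSORT-style `consort.csv`
#' (randomised and analyzable counts per arm) and `report.md`. Identical
#' config + seed give byte-identical outputs. A log of seeds, thresholds
#' and exclusion decisions is written to `run.log`.
#'
#' @param config a [run_config()].
#' @return the run directory path, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("master seed: %d", config$seed))
  if (!length(config$stages)) {
    warn("all stages disabled; nothing to do")
    return(invisible(config$out_dir))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  if ("images" %in% config$stages) {
    stage("images", {
      s0 <- stage_seed(config, 1L)
      heights <- seq(200, 350, length.out = max(1, config$n_images))
      specs <- lapply(seq_len(config$n_images), function(i) {
        mucosa_spec(villus_height_um = heights[i], seed = s0 + i)
      })
      manifest <- render_batch(specs, file.path(config$out_dir, "images"))
      log_lines <- c(log_lines, sprintf("images: %d rendered, seed %d",
                                         nrow(manifest), s0))
    })
  }

  if ("measure" %in% config$stages) {
    stage("measure", {
      morpho <- measure_batch(file.path(config$out_dir, "images"),
                              tilt_tol_deg = config$tilt_tol_deg)
      readr::write_csv(morpho, file.path(config$out_dir, "morphometry.csv"))
      log_lines <- c(log_lines,
        sprintf("measure: %d sections, thresholds [%s], %d excluded as inadequate",
                nrow(morpho),
                paste(round(morpho$threshold[!is.na(morpho$threshold)], 1), collapse = ", "),
                sum(!morpho$adequate)))
    })
  }

  sim <- NULL
  if ("cohort" %in% config$stages) {
    stage("cohort", {
      spec <- effect_spec(scenario = config$scenario,
                          n_per_letter = config$n_per_letter,
                          attrition_rate = config$attrition_rate,
                          seed = stage_seed(config, 2L))
      sim <- simulate_cohort(spec)
      readr::write_csv(tibble::as_tibble(sim$cohort),
                       file.path(config$out_dir, "cohort.csv"))
      # the manufacturer's sealed envelope, persisted for the unblind step
      jsonlite::write_json(as.list(attr(sim$code_map, "env")$map),
                           file.path(config$out_dir, "code_map.json"),
                           auto_unbox = TRUE)
      log_lines <- c(log_lines, sprintf("cohort: seed %d, %d records",
                                         stage_seed(config, 2L), nrow(sim$cohort)))
    })
  }

  if ("analyze" %in% config$stages) {
    stage("analyze", {
      if (is.null(sim)) abort("analyze requires the cohort stage")
      locked <- lock_cohort(sim$cohort)
      unblinded <- unblind(locked, sim$code_map)
      log_lines <- c(log_lines, "analyze: database locked, then unblinded")

      res_pre <- route_and_compare(unblinded, timepoint = "pre",
                                   alpha = config$alpha, welch = config$welch,
                                   holm = config$holm)
      n_post <- sum(unblinded$timepoint == "post" & unblinded$adequate)
      res <- if (n_post >= 8) {
        res_post <- route_and_compare(unblinded, timepoint = "post",
                                      alpha = config$alpha, welch = config$welch,
                                      holm = config$holm)
        out <- tryCatch(select_conservative(res_pre, res_post),
                        error = function(e) res_pre)
        log_lines <- c(log_lines,
          sprintf("analyze: conservative dataset = %s", attr(out, "dataset") %||% "pre"))
        out
      } else {
        res_pre
      }
      readr::write_csv(tibble::as_tibble(res), file.path(config$out_dir, "results.csv"))

      consort <- consort_table(unblinded)
      readr::write_csv(consort, file.path(config$out_dir, "consort.csv"))
      log_lines <- c(log_lines,
        sprintf("analyze: analyzable %s",
                paste(sprintf("%s %d/%d", consort$arm, consort$analyzable,
                              consort$randomised), collapse = ", ")))
    })
  }

  if ("report" %in% config$stages) {
    stage("report", {
      res_path <- file.path(config$out_dir, "results.csv")
      if (!file.exists(res_path)) abort("report requires results.csv from the analyze stage")
      results <- readr::read_csv(res_path, show_col_types = FALSE)
      writeLines(render_report(results), file.path(config$out_dir, "report.md"))
    })
  }

  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  invisible(config$out_dir)
}

#' CONSORT-style attrition table
#'
#' Randomised versus analyzable (adequate pre-vaccination biopsy) counts per
#' arm.
#' @param cohort an unblinded `villi_cohort`.
#' @export
consort_table <- function(cohort) {
  if (!"arm" %in% names(cohort)) abort("consort_table needs an unblinded cohort")
  dat <- as.data.frame(cohort)
  pre <- dat[dat$timepoint == "pre", , drop = FALSE]
  pre |>
    dplyr::group_by(arm = .data$arm) |>
    dplyr::summarise(randomised = dplyr::n(),
                     analyzable = sum(.data$adequate), .groups = "drop")
}

#' Render a results report as markdown text
#'
#' One paragraph per stratum and variable with group statistics, percent
#' difference, estimate, 95% CI, test name and p-value, following the
#' rounding conventions of the trial literature (estimates to one decimal,
#' p to one significant figure below 0.01).
#'
#' @param results results table as produced by [route_and_compare()] (or
#'   read back from `results.csv`).
#' @return character vector of markdown lines.
#' @export
render_report <- function(results) {
  needed <- c("stratum", "variable", "test", "estimate", "ci_low", "ci_high",
              "p_value", "group1_stat", "group2_stat")
  missing <- setdiff(needed, names(results))
  if (length(missing)) {
    abort(sprintf("results table is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (nrow(results) == 0) return("No comparisons available.")
  units <- c(VH = "\u03bcm", CD = "\u03bcm", VW = "\u03bcm",
             VP = "\u03bcm/100 \u03bcm", VA = "\u03bcm\u00b2/100 \u03bcm")
  lines <- c("# Morphometry results", "")
  for (stratum in unique(results$stratum)) {
    lines <- c(lines, sprintf("## HIV %s patients", stratum), "")
    sub <- results[results$stratum == stratum, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      r <- sub[i, ]
      u <- units[[r$variable]] %||% ""
      kind <- if (identical(r$test, "Kruskal-Wallis")) "median" else "mean"
      pct <- percent_difference(r$group1_stat, r$group2_stat)
      dir <- if (pct >= 0) "greater" else "lower"
      ci_txt <- if (is.na(r$ci_low)) "" else {
        sprintf(" [95%% confidence interval %s \u2013 %s %s]",
                fmt_um(r$ci_low), fmt_um(r$ci_high), u)
      }
      lines <- c(lines, sprintf(
        "%s %s was %s%% %s with MM (%s v. %s %s; %s difference %s %s%s; P = %s, %s).",
        kind, r$variable, fmt_um(abs(pct)), dir,
        fmt_um(r$group1_stat), fmt_um(r$group2_stat), u,
        kind, fmt_um(r$estimate), u, ci_txt,
        format_p(r$p_value), r$test), "")
    }
  }
  lines
}
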