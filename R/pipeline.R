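#' Run configuration for the analysis pipeline
#'
#' Bundles everything one end-to-end run needs: which stages to execute,
#' demographic parameters (or a preset name), GLMM and scaling settings,
#' input paths (for externally supplied data), the output directory and the
#' global seed. Per-stage seeds are fanned out deterministically from the
#' global seed.
#'
#' @param stages Character vector from `c("predict", "simulate",
#'   "subgroups", "glmm", "thresholds")`, or `"all"`.
#' @param params A [demographic_params()] object (ignored when `preset`
#'   given).
#' @param preset `"community"` or `"subgroup"` ([ngogo_preset()]).
#' @param glmm A [glmm_config()].
#' @param scaling A [scaling_params()].
#' @param outdir Output directory.
#' @param seed Global integer seed (< 2^28 so fanned-out seeds stay well
#'   below 2^31).
#' @param inputs Optional named list of input paths (`relatedness`,
#'   `metadata`, `association`) for runs on external data; when absent the
#'   `simulate` stage provides them.
#' @param simulate_args Arguments forwarded to [make_study_dataset()]
#'   (`n_years`, `noise_sd`, `subgroup_spec`, `burn_in`).
#' @param min_periods Observation minimum for [simple_ratio_index()].
#' @param figures Emit ggplot figures (PNG) alongside the tables.
#' @return A list of class `run_config`.
#' @export
run_config <- function(stages = "all", params = NULL, preset = NULL,
                       glmm = glmm_config(), scaling = scaling_params(),
                       outdir = "kinconflict_run", seed = 1L,
                       inputs = list(), simulate_args = list(n_years = 8),
                       min_periods = 20, figures = TRUE) {
  all_stages <- c("predict", "simulate", "subgroups", "glmm", "thresholds")
  if (identical(stages, "all")) stages <- all_stages
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  if (!is.null(preset)) params <- ngogo_preset(preset)
  if (is.null(params)) stop("provide either params or preset", call. = FALSE)
  stopifnot(seed == as.integer(seed), abs(seed) < 2^28)
  for (nm in names(inputs)) {
    if (!file.exists(inputs[[nm]])) {
      stop(sprintf("input path for '%s' does not exist: %s", nm, inputs[[nm]]),
           call. = FALSE)
    }
  }
  structure(list(stages = stages, params = params, preset = preset,
                 glmm = glmm, scaling = scaling, outdir = outdir,
                 seed = as.integer(seed), inputs = inputs,
                 simulate_args = simulate_args, min_periods = min_periods,
                 figures = figures),
            class = "run_config")
}

stage_seed <- function(config, stage) {
  idx <- match(stage, c("predict", "simulate", "subgroups", "glmm", "thresholds"))
  config$seed + 1000L * idx
}

#' Execute the pipeline
#'
#' Runs the selected stages in dependency order -- `predict` (analytic
#' kinship profile), `simulate` (synthetic study dataset), `subgroups`
#' (annual simple-ratio matrices and Newman partitions), `glmm` (dyadic
#' means and beta-GLMM fits at community and, where a partition exists,
#' subgroup scale) and `thresholds` (inclusive-fitness curves from the
#' fitted trajectories) -- writing tidy CSV/JSON outputs, optional figures
#' and a run manifest. Stages that need an upstream artifact fail with a
#' message naming the stage to run first.
#'
#' @param config A [run_config()].
#' @return The manifest (also written to `manifest.json`), invisibly
#'   carrying the in-memory stage results as attribute `"results"`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outdir, ...)
  manifest <- list(package_version = as.character(utils::packageVersion("kinconflict")),
                   seed = config$seed, stages = config$stages,
                   params = unclass(config$params),
                   generation_time = config$scaling$generation_time,
                   stage_seeds = sapply(config$stages, function(s) stage_seed(config, s)),
                   outputs = list())
  results <- list()

  if ("predict" %in% config$stages) {
    prof <- predict_kinship_dynamics(config$params)
    write_kinship_profile(prof, out("predicted_kinship.csv"))
    manifest$outputs$predict <- "predicted_kinship.csv"
    results$profile <- prof
    if (config$figures) {
      ggplot2::ggsave(out("fig_predicted_kinship.png"),
                      plot_kinship(prof), width = 6, height = 4, dpi = 150)
    }
  }

  if ("simulate" %in% config$stages) {
    args <- c(list(params = config$params, seed = stage_seed(config, "simulate")),
              config$simulate_args)
    ds <- do.call(make_study_dataset, args)
    write_study_dataset(ds, out("synthetic_data"))
    manifest$outputs$simulate <- "synthetic_data/"
    results$dataset <- ds
  }

  get_input <- function(kind, file, reader, needed_by) {
    if (!is.null(config$inputs[[kind]])) return(reader(config$inputs[[kind]]))
    p <- out("synthetic_data", file)
    if (!file.exists(p)) {
      stop(sprintf("stage '%s' needs %s data; run the 'simulate' stage first or point inputs$%s at a file",
                   needed_by, kind, kind), call. = FALSE)
    }
    reader(p)
  }

  if ("subgroups" %in% config$stages) {
    assoc <- get_input("association", "association.csv", read_association, "subgroups")
    meta <- get_input("metadata", "metadata.csv", read_metadata, "subgroups")
    sg <- assign_annual_subgroups(assoc, meta, min_periods = config$min_periods)
    utils::write.csv(sg$table, out("subgroup_partition.csv"), row.names = FALSE)
    jsonlite::write_json(
      lapply(sg$partitions, function(p) c(list(modularity_q = p$modularity_q), p$summary["n_retained"])),
      out("subgroup_summary.json"), auto_unbox = TRUE, digits = NA)
    manifest$outputs$subgroups <- c("subgroup_partition.csv", "subgroup_summary.json")
    results$subgroups <- sg
  }

  if ("glmm" %in% config$stages) {
    pairs <- get_input("relatedness", "relatedness.tsv", read_relatedness_pairs, "glmm")
    meta <- get_input("metadata", "metadata.csv", read_metadata, "glmm")
    cfg <- config$glmm
    cfg$seed <- stage_seed(config, "glmm")
    fits <- list()
    tab_c <- build_dyadic_means(pairs, meta, offset = cfg$offset)
    utils::write.csv(tab_c, out("dyadic_means_community.csv"), row.names = FALSE)
    fits$community <- fit_beta_glmm(tab_c, cfg)
    part <- if (!is.null(results$subgroups)) results$subgroups$table
      else if (file.exists(out("subgroup_partition.csv"))) utils::read.csv(out("subgroup_partition.csv"))
      else NULL
    if (!is.null(part)) {
      tab_s <- build_dyadic_means(pairs, meta, partition = part, offset = cfg$offset)
      utils::write.csv(tab_s, out("dyadic_means_subgroup.csv"), row.names = FALSE)
      fits$subgroup <- fit_beta_glmm(tab_s, cfg)
    }
    for (nm in names(fits)) {
      f <- fits[[nm]]
      utils::write.csv(cbind(draw = seq_len(nrow(f$draws)), as.data.frame(f$draws)),
                       out(sprintf("glmm_%s_draws.csv", nm)), row.names = FALSE)
      jsonlite::write_json(list(summary = f$summary, per_year = f$summary_per_year,
                                converged = f$converged),
                           out(sprintf("glmm_%s_summary.json", nm)),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      ages <- seq(13, 65, by = 1)
      traj <- rbind(posterior_trajectory(f, ages, "F"),
                    posterior_trajectory(f, ages, "M"))
      utils::write.csv(traj, out(sprintf("glmm_%s_trajectory.csv", nm)), row.names = FALSE)
      if (config$figures) {
        ggplot2::ggsave(out(sprintf("fig_glmm_%s.png", nm)), plot_trajectory(traj),
                        width = 6, height = 4, dpi = 150)
      }
    }
    manifest$outputs$glmm <- names(fits)
    results$fits <- fits
  }

  if ("thresholds" %in% config$stages) {
    if (is.null(results$fits)) {
      stop("stage 'thresholds' needs fitted relatedness trajectories; run the 'glmm' stage first",
           call. = FALSE)
    }
    curves <- list()
    for (nm in names(results$fits)) {
      traj <- trajectory_from_glmm(results$fits[[nm]])
      crv <- selection_thresholds(traj, config$params, config$scaling,
                                  ages = seq(13, 65, by = 0.5))
      write_threshold_curve(crv, out(sprintf("thresholds_%s.csv", nm)),
                            out(sprintf("switch_age_%s.json", nm)))
      curves[[nm]] <- crv
      if (config$figures) {
        ggplot2::ggsave(out(sprintf("fig_thresholds_%s.png", nm)),
                        plot_thresholds(crv), width = 6, height = 4, dpi = 150)
      }
    }
    manifest$outputs$thresholds <- names(curves)
    results$thresholds <- curves
  }

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(structure(manifest, results = results))
}

#' Figures for kinship profiles, fitted trajectories and threshold curves
#'
#' Small ggplot2 helpers in the style of the analysis figures: relatedness
#' against female age by target sex (with credible bands where available)
#' and the selection-threshold curve with harm/help shading and dashed
#' guides at ages 13, 40 and 65.
#'
#' @param profile A `relatedness_profile`.
#' @return A ggplot object.
#' @export
plot_kinship <- function(profile) {
  long <- rbind(
    data.frame(age_years = profile$age_years, relatedness = profile$r_to_females,
               target_sex = "to females"),
    data.frame(age_years = profile$age_years, relatedness = profile$r_to_males,
               target_sex = "to males"))
  ggplot2::ggplot(long, ggplot2::aes(x = age_years, y = relatedness,
                                     colour = target_sex)) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::geom_vline(xintercept = c(13, 40, 65), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_colour_manual(values = c("to females" = "#7b3294",
                                            "to males" = "#e66101")) +
    ggplot2::labs(x = "female age (years)", y = "expected mean relatedness",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_kinship
#' @param trajectory Data frame from [posterior_trajectory()] (both sexes
#'   row-bound).
#' @export
plot_trajectory <- function(trajectory) {
  ggplot2::ggplot(trajectory,
                  ggplot2::aes(x = age_years, y = mean,
                               colour = target_sex, fill = target_sex)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lower, ymax = upper),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::geom_vline(xintercept = c(13, 40, 65), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(F = "#7b3294", M = "#e66101"),
                                 aesthetics = c("colour", "fill")) +
    ggplot2::labs(x = "female age (years)", y = "mean relatedness (89% CI)",
                  colour = "target sex", fill = "target sex") +
    ggplot2::theme_minimal()
}

#' @rdname plot_kinship
#' @param curve A `selection_threshold_curve`.
#' @export
plot_thresholds <- function(curve) {
  df <- as.data.frame(curve)
  ggplot2::ggplot(df, ggplot2::aes(x = age_years, y = threshold)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmin(threshold, 0), ymax = 0),
                         fill = "#67a9cf", alpha = 0.4) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = 0, ymax = pmax(threshold, 0)),
                         fill = "#ef8a62", alpha = 0.4) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey30") +
    ggplot2::geom_vline(xintercept = c(13, 40, 65), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "female age (years)",
                  y = "critical cost/benefit ratio",
                  subtitle = "harming favoured between the curve and 0 (blue); helping favoured between 0 and the curve (orange)") +
    ggplot2::theme_minimal()
}
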