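#' Demographic parameters for the kinship-dynamics model
#'
#' Bundles the seven life-history parameters of the local-relatedness
#' recursion -- group composition, sex-specific dispersal and replacement
#' rates, and the proportion of offspring sired locally -- together with the
#' time grid (number of age classes and timestep length) and the calendar age
#' at which females are considered reproductively mature.
#'
#' @param n_females Number of reproductively mature females in the group
#'   (`nf`, >= 2 so that a "mean relatedness to other females" exists).
#' @param n_males Number of reproductively mature males (`nm`, >= 1).
#' @param disp_f,disp_m Female / male dispersal rates: the probability that a
#'   new recruit of that sex is an immigrant rather than locally born.
#'   Fractions in \[0, 1\].
#' @param repl_f,repl_m Per-timestep replacement probabilities: each breeder
#'   of that sex dies and is replaced with this probability each timestep.
#'   Fractions in (0, 1).
#' @param local_mating Proportion `m` of offspring fathered by males of the
#'   local group; the remainder are sired by outside (unrelated) males.
#' @param n_steps Number of age classes `K` on the reporting grid.
#' @param step_years Length of one timestep in years.
#' @param maturity_age_f Calendar age (years) mapped to age class 1.
#'
#' @return An object of class `demographic_params` (a validated named list).
#' @seealso [ngogo_preset()] for the two shipped parameterizations,
#'   [predict_kinship_dynamics()] for the model they feed.
#' @export
#' @examples
#' p <- demographic_params(n_females = 66, n_males = 44, disp_f = 0.5,
#'                         disp_m = 0, repl_f = 0.076, repl_m = 0.076,
#'                         local_mating = 1)
#' age_class_to_years(1, p)
demographic_params <- function(n_females, n_males, disp_f, disp_m,
                               repl_f, repl_m, local_mating,
                               n_steps = 30L, step_years = 2.5,
                               maturity_age_f = 13) {
  p <- list(
    n_females = as.integer(n_females), n_males = as.integer(n_males),
    disp_f = disp_f, disp_m = disp_m,
    repl_f = repl_f, repl_m = repl_m,
    local_mating = local_mating,
    n_steps = as.integer(n_steps), step_years = step_years,
    maturity_age_f = maturity_age_f
  )
  validate_demographic_params(p)
  structure(p, class = "demographic_params")
}

validate_demographic_params <- function(p) {
  chk <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
  chk(p$n_females >= 2, "n_females must be >= 2 (mean to *other* females needs at least one other female)")
  chk(p$n_males >= 1, "n_males must be >= 1")
  for (f in c("disp_f", "disp_m", "local_mating")) {
    chk(is.numeric(p[[f]]) && length(p[[f]]) == 1 && p[[f]] >= 0 && p[[f]] <= 1,
        sprintf("%s must be a fraction in [0, 1]", f))
  }
  for (f in c("repl_f", "repl_m")) {
    chk(is.numeric(p[[f]]) && length(p[[f]]) == 1 && p[[f]] > 0 && p[[f]] < 1,
        sprintf("%s must be a fraction in (0, 1)", f))
  }
  chk(p$n_steps >= 1, "n_steps must be >= 1")
  chk(p$step_years > 0, "step_years must be > 0")
  chk(p$maturity_age_f >= 0, "maturity_age_f must be >= 0")
  invisible(p)
}

#' Shipped Ngogo parameterizations
#'
#' Two preset parameter sets for the Ngogo chimpanzee community: the whole
#' community of reproductively mature members (66 females, 44 males, 50%
#' female dispersal, male philopatry, fully local mating) and the typical
#' mixed-sex association subgroup (18 females, 12 males, 90% female and 10%
#' male dispersal). Both use 30 age classes of 2.5 years and a per-timestep
#' replacement probability of 0.076 for each sex (2.5 years divided by a mean
#' lifespan of 32.8 years).
#'
#' @param scale `"community"` or `"subgroup"`.
#' @return A [demographic_params()] object.
#' @export
ngogo_preset <- function(scale = c("community", "subgroup")) {
  scale <- match.arg(scale)
  if (scale == "community") {
    demographic_params(n_females = 66, n_males = 44, disp_f = 0.5, disp_m = 0,
                       repl_f = 0.076, repl_m = 0.076, local_mating = 1)
  } else {
    demographic_params(n_females = 18, n_males = 12, disp_f = 0.9, disp_m = 0.1,
                       repl_f = 0.076, repl_m = 0.076, local_mating = 1)
  }
}

#' Convert between age classes and calendar years
#'
#' Class 1 corresponds to a newly mature female (`maturity_age_f` years) and
#' each subsequent class adds `step_years`. The inverse returns a fractional
#' class, suitable for linear interpolation of a profile.
#'
#' @param x Age class (may be fractional, in \[1, n_steps\]).
#' @param age Calendar age in years (>= `maturity_age_f`).
#' @param params A [demographic_params()] object.
#' @return Years, or a fractional age class.
#' @export
age_class_to_years <- function(x, params) {
  if (any(x < 1 | x > params$n_steps)) {
    stop(sprintf("age class must lie in [1, %d]", params$n_steps), call. = FALSE)
  }
  params$maturity_age_f + (x - 1) * params$step_years
}

#' @rdname age_class_to_years
#' @export
years_to_age_class <- function(age, params) {
  if (any(age < params$maturity_age_f)) {
    stop(sprintf("age %s is below female maturity (%s years)",
                 format(min(age)), format(params$maturity_age_f)), call. = FALSE)
  }
  (age - params$maturity_age_f) / params$step_years + 1
}

#' Read / write demographic parameters as a YAML config block
#'
#' The config names every `demographic_params` field; unknown fields are an
#' error so typos do not silently fall back to defaults.
#'
#' @param path Path to a YAML file whose top level (or whose `params` block)
#'   names the fields of [demographic_params()], or contains
#'   `preset: ngogo_community` / `preset: ngogo_subgroup`.
#' @return A [demographic_params()] object.
#' @export
params_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$params)) cfg <- cfg$params
  if (!is.null(cfg$preset)) {
    return(ngogo_preset(sub("^ngogo_", "", cfg$preset)))
  }
  known <- names(formals(demographic_params))
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    stop("unknown parameter field(s) in config: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(demographic_params, cfg)
}

#' @rdname params_from_config
#' @param params A [demographic_params()] object to serialize.
#' @export
params_to_config <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @export
print.demographic_params <- function(x, ...) {
  cat("Demographic parameters\n")
  cat(sprintf("  group: %d females, %d males\n", x$n_females, x$n_males))
  cat(sprintf("  dispersal: df = %.3g, dm = %.3g; local mating m = %.3g\n",
              x$disp_f, x$disp_m, x$local_mating))
  cat(sprintf("  replacement/step: uf = %.3g, um = %.3g\n", x$repl_f, x$repl_m))
  cat(sprintf("  grid: %d classes of %.3g y, class 1 at %.3g y\n",
              x$n_steps, x$step_years, x$maturity_age_f))
  invisible(x)
}
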