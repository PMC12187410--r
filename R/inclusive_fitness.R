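#' Generation-time scaling
#'
#' The inclusive-fitness model measures age in units of mean generation time
#' (mean parental age), so observed ages are divided by it: scaled age 1 is
#' one generation.
#'
#' @param generation_time Mean generation time in years (> 0), default 25.
#' @return A list of class `scaling_params`.
#' @export
scaling_params <- function(generation_time = 25) {
  stopifnot(generation_time > 0)
  structure(list(generation_time = generation_time), class = "scaling_params")
}

#' @rdname scaling_params
#' @param age Age(s) in years (>= 0).
#' @param scaling A `scaling_params` object.
#' @export
#' @examples
#' scale_age(25, scaling_params(25)) # 1
scale_age <- function(age, scaling = scaling_params()) {
  if (any(age < 0)) stop("age must be >= 0", call. = FALSE)
  age / scaling$generation_time
}

#' Relatedness trajectory objects
#'
#' A trajectory packages two evaluators -- age in years to expected mean
#' relatedness to other female breeders and to male breeders -- together with
#' its provenance and valid age range. Constructors exist for the analytic
#' prediction, a fitted GLMM's posterior-mean curve, and a logit-linear
#' reconstruction from two printed endpoints per sex.
#'
#' @param fn_females,fn_males Vectorized functions of age (years).
#' @param age_range Length-2 numeric range over which the evaluators are
#'   defined.
#' @param provenance One of `"analytic"`, `"glmm-posterior-mean"`,
#'   `"reconstructed-from-endpoints"`, or free text.
#' @return An object of class `relatedness_trajectory`.
#' @export
relatedness_trajectory <- function(fn_females, fn_males, age_range,
                                   provenance = "custom") {
  stopifnot(is.function(fn_females), is.function(fn_males),
            length(age_range) == 2, age_range[1] < age_range[2])
  structure(list(fn_females = fn_females, fn_males = fn_males,
                 age_range = age_range, provenance = provenance),
            class = "relatedness_trajectory")
}

eval_trajectory <- function(traj, ages) {
  if (any(ages < traj$age_range[1] - 1e-9 | ages > traj$age_range[2] + 1e-9)) {
    stop(sprintf("trajectory (%s) is undefined outside ages [%g, %g]",
                 traj$provenance, traj$age_range[1], traj$age_range[2]),
         call. = FALSE)
  }
  rf <- traj$fn_females(ages)
  rm_ <- traj$fn_males(ages)
  if (any(rf < 0 | rf > 1 | rm_ < 0 | rm_ > 1)) {
    stop("trajectory returned relatedness outside [0, 1]", call. = FALSE)
  }
  list(rf = rf, rm = rm_)
}

#' @rdname relatedness_trajectory
#' @param profile A `relatedness_profile` from [predict_kinship_dynamics()].
#' @export
trajectory_from_profile <- function(profile) {
  rng <- range(profile$age_years)
  relatedness_trajectory(
    fn_females = function(a) stats::approx(profile$age_years, profile$r_to_females, xout = a)$y,
    fn_males = function(a) stats::approx(profile$age_years, profile$r_to_males, xout = a)$y,
    age_range = rng, provenance = "analytic")
}

#' @rdname relatedness_trajectory
#' @param fit A `beta_glmm_fit`; the posterior-mean curve is used.
#' @export
trajectory_from_glmm <- function(fit) {
  guard <- fit$config$age_guard
  mk <- function(sex) {
    force(sex)
    function(a) posterior_trajectory(fit, a, sex = sex)$mean
  }
  relatedness_trajectory(fn_females = mk("F"), fn_males = mk("M"),
                         age_range = guard,
                         provenance = "glmm-posterior-mean")
}

#' Logit-linear trajectory through printed endpoints
#'
#' For each target sex, the unique curve that is linear in age on the logit
#' scale and passes through the two given endpoint values -- the natural
#' reconstruction when only a model's fitted values at the youngest and
#' oldest ages are available, and consistent with a linear-age logit-link
#' fit.
#'
#' @param r13_f,r65_f Relatedness to other females at the first and last age.
#' @param r13_m,r65_m Same, to males. All in (0, 1).
#' @param age_range Ages (years) of the two endpoints, default `c(13, 65)`.
#' @return A `relatedness_trajectory`.
#' @export
#' @examples
#' tr <- reconstruct_trajectory_from_endpoints(0.015, 0.014, 0.018, 0.037)
#' tr$fn_males(c(13, 65))
reconstruct_trajectory_from_endpoints <- function(r13_f, r65_f, r13_m, r65_m,
                                                  age_range = c(13, 65)) {
  vals <- c(r13_f, r65_f, r13_m, r65_m)
  if (any(vals <= 0 | vals >= 1)) {
    stop("endpoint relatedness values must lie strictly in (0, 1)", call. = FALSE)
  }
  mk <- function(v1, v2) {
    l1 <- stats::qlogis(v1); l2 <- stats::qlogis(v2)
    a1 <- age_range[1]; a2 <- age_range[2]
    function(a) stats::plogis(l1 + (a - a1) / (a2 - a1) * (l2 - l1))
  }
  relatedness_trajectory(fn_females = mk(r13_f, r65_f),
                         fn_males = mk(r13_m, r65_m),
                         age_range = age_range,
                         provenance = "reconstructed-from-endpoints")
}

#' Expected relatedness of a focal female to a beneficiary's offspring
#'
#' The benefit `b` of a helpful act is spread uniformly over all other group
#' members of both sexes; each beneficiary's marginal offspring has the
#' beneficiary as one parent and a local co-parent drawn uniformly from the
#' opposite sex (excluding the focal). Isolated here so alternative
#' beneficiary conventions can be swapped in and tested.
#'
#' @param rf,rm Focal relatedness to a random other female / to a random
#'   male.
#' @param n_females,n_males Group composition.
#' @return Mean relatedness of the focal to a random beneficiary offspring.
#' @export
beneficiary_offspring_relatedness <- function(rf, rm, n_females, n_males) {
  n_oth <- n_females + n_males - 1
  (( n_females - 1) * (0.5 * rf + 0.5 * rm) +
     n_males * (0.5 * rm + 0.5 * rf)) / n_oth
}

# Inclusive-fitness value components at one age, given focal relatedness
# (rf, rm) and demographic parameters. Competition for breeding vacancies is
# island-model: an offspring of sex s stays to compete locally w.p.
# (1 - d_s), in which case it displaces a local-pool candidate (itself local
# w.p. 1 - d_s), while dispersers displace non-relatives; sexes are weighted
# by replacement flux times Fisherian class reproductive value
# (nf * vf = nm * vm), which reduces to weights u_f : u_m.
threshold_components <- function(rf, rm, params) {
  p <- params
  abar <- (p$repl_f * (1 - p$disp_f)^2 + p$repl_m * (1 - p$disp_m)^2) /
    (p$repl_f + p$repl_m)
  r_ben <- beneficiary_offspring_relatedness(rf, rm, p$n_females, p$n_males)
  # random local offspring (the displaced competitor): mother uniform over
  # all local females including the focal, father uniform over local males
  r_pool <- 0.5 * (1 / p$n_females + (1 - 1 / p$n_females) * rf) + 0.5 * rm
  r_own <- 0.5 + 0.5 * rm
  list(abar = abar, r_ben = r_ben, r_pool = r_pool, r_own = r_own,
       numerator = r_ben - abar * r_pool,
       denominator = r_own - abar * r_pool)
}

#' Age-specific critical cost/benefit ratio for social actions
#'
#' For each age, the critical ratio `c/b` at which the inclusive-fitness
#' effect of a female's social act changes sign. The act costs the focal `c`
#' offspring and changes the offspring production of the other group members
#' by `b` in total; offspring compete for breeding vacancies (immigrant slot
#' shares `disp_f`/`disp_m`, replacement fluxes `repl_f`/`repl_m`), so part
#' of any extra offspring's success comes at the expense of local kin. A
#' positive threshold means helping is favoured for `0 < c/b < threshold`; a
#' negative threshold means harming is favoured for `threshold < c/b < 0`.
#' Given the trajectory, the threshold does not involve the local-mating
#' rate.
#'
#' @param traj A `relatedness_trajectory`.
#' @param params A [demographic_params()] object.
#' @param scaling A [scaling_params()] object (used to report scaled ages).
#' @param ages Age grid (years); defaults to 0.5-year steps over the
#'   trajectory's range intersected with 13--75.
#' @return An object of class `selection_threshold_curve`: data frame
#'   `age_years`, `age_scaled`, `threshold`, `favoured_action` (`"help"`,
#'   `"harm"` or `"neither"`).
#' @export
selection_thresholds <- function(traj, params, scaling = scaling_params(),
                                 ages = NULL) {
  validate_demographic_params(params)
  if (is.null(ages)) {
    lo <- max(13, traj$age_range[1])
    hi <- min(75, traj$age_range[2])
    ages <- seq(lo, hi, by = 0.5)
  }
  r <- eval_trajectory(traj, ages)
  comp <- threshold_components(r$rf, r$rm, params)
  thr <- comp$numerator / comp$denominator
  tol <- 1e-12
  favoured <- ifelse(thr > tol, "help", ifelse(thr < -tol, "harm", "neither"))
  structure(data.frame(age_years = ages,
                       age_scaled = scale_age(ages, scaling),
                       threshold = thr, favoured_action = favoured),
            class = c("selection_threshold_curve", "data.frame"),
            params = params, scaling = scaling,
            provenance = traj$provenance)
}

#' Age at which the favoured social action switches from harming to helping
#'
#' The smallest age at which the threshold crosses from non-positive to
#' positive, linearly interpolated between grid points. With no sign change
#' the single prevailing regime is reported instead.
#'
#' @param curve A `selection_threshold_curve` on a grid of >= 2 ages.
#' @return The switch age in years, or `NA` with attribute `regime`
#'   (`"help throughout"` / `"harm throughout"`) when the threshold never
#'   changes sign. Multiple crossings return the first with a warning.
#' @export
find_switch_age <- function(curve) {
  stopifnot(nrow(curve) >= 2)
  thr <- curve$threshold
  up <- which(thr[-length(thr)] <= 0 & thr[-1] > 0)
  if (!length(up)) {
    regime <- if (all(thr > 0)) "help throughout"
      else if (all(thr <= 0)) "harm throughout"
      else "no upward crossing"
    return(structure(NA_real_, regime = regime))
  }
  if (length(up) > 1) {
    warning(sprintf("%d upward threshold crossings; returning the first", length(up)))
  }
  i <- up[1]
  a1 <- curve$age_years[i]; a2 <- curve$age_years[i + 1]
  t1 <- thr[i]; t2 <- thr[i + 1]
  if (t1 == 0) return(a1)
  a1 + (0 - t1) / (t2 - t1) * (a2 - a1)
}

#' Direct inclusive-fitness accounting in a realized pedigree population
#'
#' Brute-force counterpart of [selection_thresholds()] for the sign check:
#' given one realized population state and a focal female, the act's
#' offspring increments are weighted by realized pedigree relatedness to the
#' focal, with vacancy competition evaluated through the recruitment
#' lottery's parent-draw probabilities (and the island-model dispersal
#' escape) on the same realized matrix. Positive values mean the act raises
#' the focal's inclusive fitness.
#'
#' @param pop A `pedigree_population`.
#' @param focal_id Id of the focal female.
#' @param cost,benefit Offspring increments `c` (to the focal, lost) and `b`
#'   (to the rest of the group, spread uniformly).
#' @param params A [demographic_params()] object.
#' @return The inclusive-fitness effect (arbitrary positive scale).
#' @export
ibm_act_effect <- function(pop, focal_id, cost, benefit, params) {
  mem <- pop$members
  R <- pop$relmatrix
  k <- match(focal_id, mem$id)
  if (is.na(k) || mem$sex[k] != "F") stop("focal_id must be a current female member", call. = FALSE)
  fpos <- which(mem$sex == "F")
  mpos <- which(mem$sex == "M")
  row <- R[k, ]
  rm_real <- mean(row[mpos])
  # own offspring: focal is the mother, father a random local male
  r_own <- 0.5 + 0.5 * rm_real
  # beneficiary offspring: each other member one parent, local co-parent
  # drawn from the opposite sex excluding the focal
  oth_f <- setdiff(fpos, k)
  rf_oth <- if (length(oth_f)) mean(row[oth_f]) else 0
  r_ben_f <- 0.5 * row[oth_f] + 0.5 * rm_real            # female beneficiaries
  r_ben_m <- 0.5 * row[mpos] + 0.5 * rf_oth              # male beneficiaries
  r_ben <- mean(c(r_ben_f, r_ben_m))
  # displaced local-pool candidate: mother uniform over all females
  # (including the focal, whose self-relatedness is 1), father uniform males
  r_pool <- 0.5 * ((1 + sum(row[oth_f])) / length(fpos)) + 0.5 * rm_real
  comp <- list(
    abar = (params$repl_f * (1 - params$disp_f)^2 +
              params$repl_m * (1 - params$disp_m)^2) /
      (params$repl_f + params$repl_m))
  (-cost * r_own + benefit * r_ben) - comp$abar * (benefit - cost) * r_pool
}

#' Write a selection-threshold curve and its switch age
#'
#' @param curve A `selection_threshold_curve`.
#' @param csv_path Output CSV (`age_years, age_scaled, threshold,
#'   favoured_action`).
#' @param json_path Optional JSON with the switch age / regime.
#' @export
write_threshold_curve <- function(curve, csv_path, json_path = NULL) {
  utils::write.csv(as.data.frame(curve), csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    sw <- find_switch_age(curve)
    jsonlite::write_json(
      list(switch_age_years = if (is.na(sw)) NULL else as.numeric(sw),
           regime = if (is.na(sw)) attr(sw, "regime") else "harm then help",
           provenance = attr(curve, "provenance")),
      json_path, auto_unbox = TRUE, null = "null", digits = NA)
  }
  invisible(csv_path)
}
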