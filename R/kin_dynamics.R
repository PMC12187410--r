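#' Relatedness of a new recruit to a reference individual
#'
#' Additive-relationship propagation on an outbred pedigree: a locally born
#' recruit is related to any reference individual by half the mother's plus
#' half the father's relatedness to that individual. An absent father means
#' the offspring was sired by an (unrelated) extra-group male; an immigrant
#' recruit has both parents absent and is unrelated to everyone.
#'
#' @param r_ref_mother Relatedness of the reference individual to the
#'   recruit's mother, in \[0, 1\], or `NA` if the recruit is an immigrant.
#' @param r_ref_father Relatedness to the father, in \[0, 1\], or `NA` for an
#'   outside sire. Default `NA`.
#' @return The recruit's relatedness to the reference individual.
#' @export
#' @examples
#' recruit_relatedness(1, NA)    # reference is the mother, outside sire: 0.5
#' recruit_relatedness(NA, NA)   # immigrant recruit: 0
#' recruit_relatedness(0.3, 0.1) # 0.2
recruit_relatedness <- function(r_ref_mother, r_ref_father = NA_real_) {
  if (is.null(r_ref_mother)) r_ref_mother <- NA_real_
  if (is.null(r_ref_father)) r_ref_father <- NA_real_
  vals <- c(r_ref_mother, r_ref_father)
  bad <- !is.na(vals) & (vals < 0 | vals > 1)
  if (any(bad)) {
    stop("relatedness values must lie in [0, 1]; got ",
         paste(vals[bad], collapse = ", "), call. = FALSE)
  }
  m <- ifelse(is.na(r_ref_mother), 0, r_ref_mother)
  f <- ifelse(is.na(r_ref_father), 0, r_ref_father)
  0.5 * m + 0.5 * f
}

# One application of the stationary-relatedness map.
#
# State is the expected pairwise relatedness between two random *distinct*
# breeders of the indicated sexes (rho_ff, rho_fm, rho_mm). Each breeder dies
# w.p. u_sex per step; a vacancy is filled by an immigrant w.p. d_sex, else by
# a natal recruit with a uniformly random local mother and, w.p. m, a
# uniformly random local father (else an outside sire). Parents are drawn from
# the population as it stood at the start of the step.
stationary_map <- function(rho, p) {
  nf <- p$n_females; nm <- p$n_males
  uf <- p$repl_f; um <- p$repl_m
  df <- p$disp_f; dm <- p$disp_m; m <- p$local_mating
  # expected relatedness of a uniformly drawn parent to a random same-sex
  # member (includes the 1/n chance the draw *is* that member)
  Sff <- 1 / nf + (1 - 1 / nf) * rho[["rho_ff"]]
  Smm <- 1 / nm + (1 - 1 / nm) * rho[["rho_mm"]]
  cF <- 0.5 * Sff + 0.5 * m * rho[["rho_fm"]]        # natal recruit -> surviving female
  cM <- 0.5 * rho[["rho_fm"]] + 0.5 * m * Smm        # natal recruit -> surviving male
  B <- 0.25 * Sff + 0.5 * m * rho[["rho_fm"]] + 0.25 * m^2 * Smm # two same-step natal recruits
  c(
    rho_ff = (1 - uf)^2 * rho[["rho_ff"]] +
      2 * uf * (1 - uf) * (1 - df) * cF + uf^2 * (1 - df)^2 * B,
    rho_fm = (1 - uf) * (1 - um) * rho[["rho_fm"]] +
      uf * (1 - um) * (1 - df) * cM + um * (1 - uf) * (1 - dm) * cF +
      uf * um * (1 - df) * (1 - dm) * B,
    rho_mm = (1 - um)^2 * rho[["rho_mm"]] +
      2 * um * (1 - um) * (1 - dm) * cM + um^2 * (1 - dm)^2 * B
  )
}

#' Stationary group-level relatedness
#'
#' Fixed point of the expected-relatedness recursion induced by the
#' replacement process: the long-run mean pairwise relatedness between two
#' random distinct breeders, by sex pair. Solved by damped fixed-point
#' iteration.
#'
#' @param params A [demographic_params()] object.
#' @param tol Convergence tolerance on the maximum absolute residual of one
#'   recursion step.
#' @param max_iter Iteration cap.
#' @param damping Damping factor in \[0, 1): each iterate is
#'   `(1 - damping) * map(x) + damping * x`.
#' @return An object of class `group_relatedness`: a list with `rho_ff`,
#'   `rho_fm`, `rho_mm`, the final `residual` and the iteration count.
#' @export
stationary_group_relatedness <- function(params, tol = 1e-12, max_iter = 1e5,
                                         damping = 0.5) {
  validate_demographic_params(params)
  # the map is affine in rho, so the exact fixed point solves (I - A) x = b;
  # use it as the start and let the damped iteration certify the residual
  # (replacement rates near 0 contract too slowly to iterate from scratch)
  b0 <- stationary_map(c(rho_ff = 0, rho_fm = 0, rho_mm = 0), params)
  A <- vapply(1:3, function(i) {
    e <- c(rho_ff = 0, rho_fm = 0, rho_mm = 0)
    e[i] <- 1
    stationary_map(e, params) - b0
  }, numeric(3))
  rho <- tryCatch(
    stats::setNames(solve(diag(3) - A, b0), c("rho_ff", "rho_fm", "rho_mm")),
    error = function(e) c(rho_ff = 0, rho_fm = 0, rho_mm = 0))
  rho <- pmin(pmax(rho, 0), 1)
  res <- Inf
  for (it in seq_len(max_iter)) {
    nxt <- stationary_map(rho, params)
    res <- max(abs(nxt - rho))
    rho <- (1 - damping) * nxt + damping * rho
    if (res < tol) break
  }
  if (res >= tol) {
    stop(sprintf("stationary relatedness did not converge in %d iterations (last residual %.3g)",
                 as.integer(max_iter), res), call. = FALSE)
  }
  structure(list(rho_ff = unname(rho[["rho_ff"]]), rho_fm = unname(rho[["rho_fm"]]),
                 rho_mm = unname(rho[["rho_mm"]]), residual = res, iterations = it),
            class = "group_relatedness")
}

#' @export
print.group_relatedness <- function(x, ...) {
  cat(sprintf("Stationary group relatedness: rho_ff = %.5f, rho_fm = %.5f, rho_mm = %.5f\n",
              x$rho_ff, x$rho_fm, x$rho_mm))
  cat(sprintf("  (converged in %d iterations, residual %.2g)\n", x$iterations, x$residual))
  invisible(x)
}

# Expected relatedness trajectory of a focal female from birth, on the model
# timestep grid. Index i corresponds to (i - 1) * step_years years after her
# entry into the group. At entry she is an immigrant (unrelated) w.p. disp_f,
# else locally born with parents drawn from the group at the start of her
# entry step; afterwards her own mortality is *not* applied (the profile
# conditions on her survival) while every other member is replaced at the
# stationary background rates. Her relatedness to a slot only changes when
# that slot's occupant is replaced; a replacement is related to her through
# the parent draw, which may pick the focal herself as mother (prob 1/nf).
kinship_curve_from_birth <- function(params, n_internal) {
  p <- params
  rho <- stationary_group_relatedness(p)
  nf <- p$n_females; nm <- p$n_males
  uf <- p$repl_f; um <- p$repl_m
  df <- p$disp_f; dm <- p$disp_m; m <- p$local_mating
  Sff <- 1 / nf + (1 - 1 / nf) * rho$rho_ff
  Smm <- 1 / nm + (1 - 1 / nm) * rho$rho_mm
  cF <- 0.5 * Sff + 0.5 * m * rho$rho_fm
  cM <- 0.5 * rho$rho_fm + 0.5 * m * Smm
  B <- 0.25 * Sff + 0.5 * m * rho$rho_fm + 0.25 * m^2 * Smm
  rf <- rm <- numeric(n_internal)
  # entry state: another slot of the target sex holds a survivor w.p. (1 - u)
  # or a same-step recruit (itself immigrant w.p. d)
  rf[1] <- (1 - df) * ((1 - uf) * cF + uf * (1 - df) * B)
  rm[1] <- (1 - df) * ((1 - um) * cM + um * (1 - dm) * B)
  for (i in seq_len(n_internal - 1)) {
    inner <- 0.5 * (1 / nf + (1 - 1 / nf) * rf[i]) + 0.5 * m * rm[i]
    rf[i + 1] <- (1 - uf) * rf[i] + uf * (1 - df) * inner
    rm[i + 1] <- (1 - um) * rm[i] + um * (1 - dm) * inner
  }
  list(age_from_birth = (seq_len(n_internal) - 1) * p$step_years,
       rf = rf, rm = rm, stationary = rho)
}

#' Predicted age-specific local relatedness of females
#'
#' Analytic expectation of a female's mean relatedness to the other female
#' breeders and to the male breeders of her group at each age class,
#' conditional on her survival. The recursion is propagated from her entry
#' into the group (the dispersal lottery: immigrant with probability
#' `disp_f`, else locally born) at the stationary group background, with her
#' age counted from birth; the reported grid maps class 1 to
#' `maturity_age_f` calendar years so that, e.g., a newly mature (13-year-old)
#' female's values reflect the replacements that accumulated since her birth.
#'
#' @param params A [demographic_params()] object.
#' @return An object of class `relatedness_profile`: a data frame with columns
#'   `age_class`, `age_years`, `r_to_females`, `r_to_males`, carrying the
#'   internal birth-grid curve and the stationary background as attributes.
#' @export
#' @examples
#' prof <- predict_kinship_dynamics(ngogo_preset("community"))
#' head(prof, 3)
#' relatedness_at_age(prof, 65, "M")
predict_kinship_dynamics <- function(params) {
  validate_demographic_params(params)
  ages <- age_class_to_years(seq_len(params$n_steps), params)
  n_internal <- ceiling(max(ages) / params$step_years) + 2L
  curve <- kinship_curve_from_birth(params, n_internal)
  prof <- data.frame(
    age_class = seq_len(params$n_steps),
    age_years = ages,
    r_to_females = stats::approx(curve$age_from_birth, curve$rf, xout = ages)$y,
    r_to_males = stats::approx(curve$age_from_birth, curve$rm, xout = ages)$y
  )
  structure(prof, class = c("relatedness_profile", "data.frame"),
            params = params, internal = curve, stationary = curve$stationary)
}

#' Evaluate a relatedness profile at arbitrary calendar ages
#'
#' Linear interpolation between adjacent age classes, as used for reporting
#' values at ages that fall between classes (e.g. age 65 on a 2.5-year grid).
#'
#' @param profile A `relatedness_profile` from [predict_kinship_dynamics()]
#'   or [empirical_age_profile()].
#' @param age Calendar ages in years, within the profile's range.
#' @param sex `"F"` for relatedness to other females, `"M"` to males.
#' @return Interpolated expected relatedness values.
#' @export
relatedness_at_age <- function(profile, age, sex = c("M", "F")) {
  sex <- match.arg(sex)
  col <- if (sex == "M") "r_to_males" else "r_to_females"
  if (any(age < min(profile$age_years) | age > max(profile$age_years))) {
    stop("age outside the profile's age range", call. = FALSE)
  }
  stats::approx(profile$age_years, profile[[col]], xout = age)$y
}

#' Write a relatedness profile as tidy CSV
#'
#' Long format with one row per age class and target sex:
#' `age_class, age_years, target_sex, expected_relatedness`.
#'
#' @param profile A `relatedness_profile`.
#' @param path Output CSV path.
#' @export
write_kinship_profile <- function(profile, path) {
  long <- rbind(
    data.frame(age_class = profile$age_class, age_years = profile$age_years,
               target_sex = "F", expected_relatedness = profile$r_to_females),
    data.frame(age_class = profile$age_class, age_years = profile$age_years,
               target_sex = "M", expected_relatedness = profile$r_to_males)
  )
  long <- long[order(long$age_class, long$target_sex), ]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
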