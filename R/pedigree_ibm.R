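#' Create an individual-based pedigree population
#'
#' Initializes a group of `n_females + n_males` breeders with an
#' additive-relationship matrix. Founders are mutually unrelated
#' (off-diagonal 0, diagonal 1); relatedness structure then builds up through
#' [ibm_step()] replacements.
#'
#' @param params A [demographic_params()] object.
#' @return An object of class `pedigree_population`: a list with `members`
#'   (data frame: `id`, `sex`, `origin`, `mother_id`, `father_id`,
#'   `age_steps`), `relmatrix`, `step_index` and an internal id counter.
#' @export
pedigree_population <- function(params) {
  validate_demographic_params(params)
  n <- params$n_females + params$n_males
  ids <- c(sprintf("F%03d", seq_len(params$n_females)),
           sprintf("M%03d", seq_len(params$n_males)))
  members <- data.frame(
    id = ids,
    sex = rep(c("F", "M"), c(params$n_females, params$n_males)),
    origin = "founder",
    mother_id = NA_character_, father_id = NA_character_,
    age_steps = 0L,
    stringsAsFactors = FALSE
  )
  R <- diag(1, n)
  dimnames(R) <- list(ids, ids)
  structure(list(members = members, relmatrix = R, step_index = 0L,
                 next_id = 1L, params = params),
            class = "pedigree_population")
}

#' Advance the pedigree population by one timestep
#'
#' Each member dies independently with its sex's replacement probability;
#' every vacancy is refilled keeping sex counts constant. A recruit is an
#' immigrant (unrelated to everyone) with probability `disp_sex`, else
#' locally born with a uniformly random mother drawn from the females present
#' at the *start* of the step and, with probability `local_mating`, a
#' uniformly random local father (else an unrelated outside sire). Recruit
#' relatedness follows the additive rule `r(new, j) = (r(mo, j) + r(fa, j))/2`
#' with an absent parent contributing zero; same-step recruits are related
#' through their parents. Survivors' entries are untouched and their ages
#' increment.
#'
#' @param pop A `pedigree_population`.
#' @param params A [demographic_params()] object.
#' @param exempt Character vector of member ids protected from death (used to
#'   condition an age profile on focal survival).
#' @param forced_deaths Ids that die this step regardless of the mortality
#'   draw.
#' @return The updated population; the recruits of the step are attached as
#'   attribute `"recruits"` (data frame `id`, `replaces`, `sex`, `origin`).
#' @export
ibm_step <- function(pop, params, exempt = character(0),
                     forced_deaths = character(0)) {
  mem <- pop$members
  R0 <- pop$relmatrix
  n <- nrow(mem)
  u <- ifelse(mem$sex == "F", params$repl_f, params$repl_m)
  dies <- stats::runif(n) < u
  dies[mem$id %in% exempt] <- FALSE
  dies[mem$id %in% forced_deaths] <- TRUE
  dead_pos <- which(dies)

  f_pos <- which(mem$sex == "F")
  m_pos <- which(mem$sex == "M")

  nrec <- length(dead_pos)
  rec_id <- rec_origin <- character(nrec)
  rec_mother <- rec_father <- integer(nrec)
  rowvecs <- vector("list", nrec)
  for (i in seq_len(nrec)) {
    k <- dead_pos[i]
    d <- if (mem$sex[k] == "F") params$disp_f else params$disp_m
    rec_id[i] <- sprintf("I%05d", pop$next_id)
    pop$next_id <- pop$next_id + 1L
    if (stats::runif(1) < d) {
      rec_mother[i] <- NA_integer_; rec_father[i] <- NA_integer_
      rec_origin[i] <- "immigrant"
      rowvecs[[i]] <- numeric(n)
    } else {
      mo <- if (length(f_pos) == 1) f_pos else sample(f_pos, 1)
      fa <- if (stats::runif(1) < params$local_mating) {
        if (length(m_pos) == 1) m_pos else sample(m_pos, 1)
      } else NA_integer_
      rec_mother[i] <- mo; rec_father[i] <- fa
      rec_origin[i] <- "natal"
      rv <- 0.5 * R0[mo, ]
      if (!is.na(fa)) rv <- rv + 0.5 * R0[fa, ]
      rowvecs[[i]] <- rv
    }
  }
  recruits <- data.frame(pos = dead_pos, id = rec_id,
                         replaces = mem$id[dead_pos],
                         sex = mem$sex[dead_pos], origin = rec_origin,
                         mother = rec_mother, father = rec_father,
                         stringsAsFactors = FALSE)

  Rn <- R0
  mem$age_steps <- mem$age_steps + 1L
  if (nrow(recruits)) {
    for (i in seq_len(nrow(recruits))) {
      k <- recruits$pos[i]
      rv <- rowvecs[[i]]
      Rn[k, ] <- rv
      Rn[, k] <- rv
    }
    # recruit-recruit entries go through the parents, not the dead occupants
    if (nrow(recruits) > 1) {
      for (i in seq_len(nrow(recruits) - 1)) {
        for (j in seq(i + 1, nrow(recruits))) {
          ki <- recruits$pos[i]; kj <- recruits$pos[j]
          rv <- rowvecs[[i]]
          mo_j <- recruits$mother[j]; fa_j <- recruits$father[j]
          val <- 0
          if (!is.na(mo_j)) val <- val + 0.5 * rv[mo_j]
          if (!is.na(fa_j)) val <- val + 0.5 * rv[fa_j]
          if (recruits$origin[i] == "immigrant") val <- 0
          Rn[ki, kj] <- Rn[kj, ki] <- val
        }
      }
    }
    for (i in seq_len(nrow(recruits))) {
      k <- recruits$pos[i]
      Rn[k, k] <- 1
      mem$id[k] <- recruits$id[i]
      mem$sex[k] <- recruits$sex[i]
      mem$origin[k] <- recruits$origin[i]
      mem$mother_id[k] <- if (is.na(recruits$mother[i])) NA_character_ else pop$members$id[recruits$mother[i]]
      mem$father_id[k] <- if (is.na(recruits$father[i])) NA_character_ else pop$members$id[recruits$father[i]]
      mem$age_steps[k] <- 0L
    }
    dimnames(Rn) <- list(mem$id, mem$id)
  }

  pop$members <- mem
  pop$relmatrix <- Rn
  pop$step_index <- pop$step_index + 1L
  attr(pop, "recruits") <- recruits[, c("id", "replaces", "sex", "origin")]
  pop
}

# mean off-diagonal relatedness by sex pair for one population state
group_mean_relatedness <- function(pop) {
  R <- pop$relmatrix
  f <- pop$members$sex == "F"
  m <- !f
  off_mean <- function(S) {
    n <- nrow(S)
    if (n < 2) return(NA_real_)
    (sum(S) - sum(diag(S))) / (n * (n - 1))
  }
  c(rho_ff = off_mean(R[f, f, drop = FALSE]),
    rho_fm = mean(R[f, m, drop = FALSE]),
    rho_mm = off_mean(R[m, m, drop = FALSE]))
}

#' Monte Carlo estimate of the stationary group relatedness
#'
#' Runs independent replicate simulations to a stationary state and averages
#' the realized mean pairwise relatedness by sex pair; the brute-force oracle
#' for [stationary_group_relatedness()].
#'
#' @param params A [demographic_params()] object.
#' @param n_replicates Number of independent replicates (>= 2).
#' @param burn_in Steps run before the snapshot is taken.
#' @param seed Integer seed; all randomness flows from it.
#' @return A data frame with one row per sex pair: `mean` and Monte Carlo
#'   standard error `se` across replicates.
#' @export
ibm_group_relatedness <- function(params, n_replicates = 100, burn_in = 200,
                                  seed = 1) {
  stopifnot(n_replicates >= 2)
  set.seed(seed)
  snaps <- matrix(NA_real_, n_replicates, 3,
                  dimnames = list(NULL, c("rho_ff", "rho_fm", "rho_mm")))
  for (r in seq_len(n_replicates)) {
    pop <- pedigree_population(params)
    for (b in seq_len(burn_in)) pop <- ibm_step(pop, params)
    snaps[r, ] <- group_mean_relatedness(pop)
  }
  data.frame(pair = colnames(snaps),
             mean = colMeans(snaps),
             se = apply(snaps, 2, stats::sd) / sqrt(n_replicates),
             row.names = NULL)
}

#' Empirical age profile of focal-female relatedness
#'
#' The simulation analogue of [predict_kinship_dynamics()]: in each replicate
#' the group is equilibrated, one randomly chosen female is then replaced and
#' her successor -- drawn through the ordinary recruitment lottery -- becomes
#' the focal. She is exempted from death thereafter (the profile conditions
#' on focal survival) while the rest of the group turns over, and her mean
#' relatedness to the other females and to the males is recorded at every
#' timestep since her entry. Replicate curves are interpolated onto the
#' calendar age-class grid and averaged.
#'
#' @param params A [demographic_params()] object.
#' @param n_replicates Number of replicates (>= 2).
#' @param burn_in Equilibration steps before the focal is recruited. A
#'   warning is raised if the group mean relatedness still drifts by more
#'   than three standard errors over the last quarter of the burn-in.
#' @param seed Integer seed.
#' @return A `relatedness_profile` data frame (`age_class`, `age_years`,
#'   `r_to_females`, `r_to_males`) with Monte Carlo standard errors `se_f`,
#'   `se_m`; per-replicate curves on the internal birth grid are attached as
#'   attributes.
#' @export
empirical_age_profile <- function(params, n_replicates = 200, burn_in = 200,
                                  seed = 1) {
  stopifnot(n_replicates >= 2)
  set.seed(seed)
  ages <- age_class_to_years(seq_len(params$n_steps), params)
  n_internal <- ceiling(max(ages) / params$step_years) + 2L
  rf_cal <- rm_cal <- matrix(NA_real_, n_replicates, params$n_steps)
  drift <- numeric(n_replicates)
  birth_grid <- (seq_len(n_internal) - 1) * params$step_years
  rf_int_acc <- rm_int_acc <- matrix(NA_real_, n_replicates, n_internal)
  for (r in seq_len(n_replicates)) {
    pop <- pedigree_population(params)
    every <- 5L
    trace <- numeric(0)
    for (b in seq_len(burn_in)) {
      pop <- ibm_step(pop, params)
      if (b %% every == 0) {
        trace <- c(trace, mean(group_mean_relatedness(pop), na.rm = TRUE))
      }
    }
    nt <- length(trace)
    q <- max(2L, nt %/% 4L)
    last <- trace[seq(nt - q + 1, nt)]
    prev <- trace[seq(nt - 2 * q + 1, nt - q)]
    drift[r] <- abs(mean(last) - mean(prev)) /
      max(stats::sd(last) / sqrt(q), .Machine$double.eps)
    # recruit the focal by replacing one uniformly chosen female
    victim <- sample(pop$members$id[pop$members$sex == "F"], 1)
    pop <- ibm_step(pop, params, forced_deaths = victim)
    rec <- attr(pop, "recruits")
    focal <- rec$id[rec$replaces == victim]
    rf_int <- rm_int <- numeric(n_internal)
    for (i in seq_len(n_internal)) {
      if (i > 1) pop <- ibm_step(pop, params, exempt = focal)
      kpos <- match(focal, pop$members$id)
      row <- pop$relmatrix[kpos, ]
      sexes <- pop$members$sex
      rf_int[i] <- mean(row[sexes == "F" & pop$members$id != focal])
      rm_int[i] <- mean(row[sexes == "M"])
    }
    rf_int_acc[r, ] <- rf_int
    rm_int_acc[r, ] <- rm_int
    rf_cal[r, ] <- stats::approx(birth_grid, rf_int, xout = ages)$y
    rm_cal[r, ] <- stats::approx(birth_grid, rm_int, xout = ages)$y
  }
  if (mean(drift) > 3) {
    warning(sprintf(
      "group mean relatedness still drifting after burn-in (mean drift %.1f SE); consider a longer burn_in",
      mean(drift)))
  }
  prof <- data.frame(
    age_class = seq_len(params$n_steps),
    age_years = ages,
    r_to_females = colMeans(rf_cal),
    r_to_males = colMeans(rm_cal),
    se_f = apply(rf_cal, 2, stats::sd) / sqrt(n_replicates),
    se_m = apply(rm_cal, 2, stats::sd) / sqrt(n_replicates)
  )
  structure(prof, class = c("relatedness_profile", "data.frame"),
            params = params,
            internal = list(age_from_birth = birth_grid,
                            rf = colMeans(rf_int_acc), rm = colMeans(rm_int_acc),
                            se_rf = apply(rf_int_acc, 2, stats::sd) / sqrt(n_replicates),
                            se_rm = apply(rm_int_acc, 2, stats::sd) / sqrt(n_replicates)),
            n_replicates = n_replicates)
}
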