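test_that("age scaling divides by the generation time", {
  sc <- scaling_params(25)
  expect_equal(scale_age(25, sc), 1)
  expect_equal(scale_age(40, sc), 1.6)
  expect_equal(scale_age(13, sc), 0.52)
  expect_error(scale_age(-1, sc), ">= 0")
  expect_error(scaling_params(0))
})

test_that("endpoint reconstruction is exact, monotone and flat when flat", {
  tr <- reconstruct_trajectory_from_endpoints(0.015, 0.014, 0.018, 0.037)
  expect_equal(tr$fn_males(c(13, 65)), c(0.018, 0.037), tolerance = 1e-12)
  expect_equal(tr$fn_females(c(13, 65)), c(0.015, 0.014), tolerance = 1e-12)
  mid <- tr$fn_males(39)
  expect_true(mid > 0.018 && mid < 0.037)
  flat <- reconstruct_trajectory_from_endpoints(0.02, 0.02, 0.05, 0.05)
  expect_equal(flat$fn_males(seq(13, 65, 7)), rep(0.05, 8))
  expect_error(reconstruct_trajectory_from_endpoints(0, 0.1, 0.1, 0.1), "strictly")
})

test_that("threshold sign semantics separate help and harm regimes", {
  p <- ngogo_preset("subgroup")
  # high relatedness to everyone: helping favoured (threshold > 0)
  hi <- relatedness_trajectory(function(a) rep(0.2, length(a)),
                               function(a) rep(0.4, length(a)), c(13, 75))
  ch <- selection_thresholds(hi, p)
  expect_true(all(ch$threshold > 0))
  expect_true(all(ch$favoured_action == "help"))
  # zero relatedness to all others: helping never favoured
  zero <- relatedness_trajectory(function(a) rep(0, length(a)),
                                 function(a) rep(0, length(a)), c(13, 75))
  cz <- selection_thresholds(zero, p)
  expect_true(all(cz$threshold <= 0))
  expect_false(any(cz$favoured_action == "help"))
  # trajectory evaluation outside its domain errors
  short <- relatedness_trajectory(function(a) rep(0.01, length(a)),
                                  function(a) rep(0.01, length(a)), c(13, 40))
  expect_error(selection_thresholds(short, p, ages = c(30, 50)), "undefined")
})

test_that("the threshold does not involve the local-mating rate", {
  tr <- reconstruct_trajectory_from_endpoints(0.015, 0.014, 0.018, 0.037)
  p1 <- ngogo_preset("subgroup")
  p5 <- p1; p5$local_mating <- 0.5
  c1 <- selection_thresholds(tr, p1)
  c5 <- selection_thresholds(tr, p5)
  expect_identical(c1$threshold, c5$threshold)
})

test_that("raising relatedness to males never lowers the threshold", {
  p <- ngogo_preset("subgroup")
  rf <- function(a) rep(0.014, length(a))
  base <- selection_thresholds(
    relatedness_trajectory(rf, function(a) rep(0.02, length(a)), c(13, 75)), p)
  up <- selection_thresholds(
    relatedness_trajectory(rf, function(a) rep(0.03, length(a)), c(13, 75)), p)
  expect_true(all(up$threshold > base$threshold))
})

test_that("switch-age detection interpolates crossings and names pure regimes", {
  p <- ngogo_preset("subgroup")
  sc <- scaling_params(25)
  grid <- seq(13, 65, 0.5)
  # constructed linear threshold crossing at exactly 40 years
  curve <- structure(data.frame(age_years = grid, age_scaled = grid / 25,
                                threshold = grid / 25 - 1.6,
                                favoured_action = ifelse(grid > 40, "help", "harm")),
                     class = c("selection_threshold_curve", "data.frame"))
  expect_equal(find_switch_age(curve), 40)
  allpos <- curve; allpos$threshold <- abs(allpos$threshold) + 0.01
  sw <- find_switch_age(allpos)
  expect_true(is.na(sw))
  expect_equal(attr(sw, "regime"), "help throughout")
  # sin(age/4) has upward zero crossings at 8*pi*k: the first is returned
  wob <- curve; wob$threshold <- sin(grid / 4)
  expect_warning(first <- find_switch_age(wob), "crossings")
  expect_equal(first, 8 * pi, tolerance = 0.01)
})

test_that("threshold CSV and switch JSON round-trip", {
  tr <- reconstruct_trajectory_from_endpoints(0.015, 0.014, 0.018, 0.037)
  crv <- selection_thresholds(tr, ngogo_preset("subgroup"))
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_threshold_curve(crv, csv, js)
  back <- read.csv(csv)
  expect_named(back, c("age_years", "age_scaled", "threshold", "favoured_action"))
  sw <- jsonlite::read_json(js)
  expect_equal(sw$regime, "harm then help")
  expect_equal(sw$switch_age_years, as.numeric(find_switch_age(crv)), tolerance = 1e-9)
})

test_that("realized-pedigree inclusive-fitness accounting matches the analytic regimes", {
  # single equilibrated subgroup-preset community; states sampled along the
  # chain; naturally old / young females provide the age conditioning
  p <- ngogo_preset("subgroup")
  ana <- predict_kinship_dynamics(p)
  traj <- trajectory_from_profile(ana)
  crv <- selection_thresholds(traj, p, ages = seq(13, 85, 0.5))
  t_young <- crv$threshold[crv$age_years == 15]
  old_age <- 80
  t_old <- crv$threshold[crv$age_years == old_age]
  expect_lt(t_young, 0)
  expect_gt(t_old, 0)
  set.seed(19)
  pop <- pedigree_population(p)
  for (b in 1:200) pop <- ibm_step(pop, p)
  eff_old <- eff_young <- numeric(0)
  old_steps <- (old_age - 13) / p$step_years + 5.2   # model steps since birth
  for (s in 1:800) {
    pop <- ibm_step(pop, p)
    mem <- pop$members
    old_f <- mem$id[mem$sex == "F" & mem$age_steps >= old_steps]
    yng_f <- mem$id[mem$sex == "F" & mem$age_steps <= 1]
    if (length(old_f)) {
      eff_old <- c(eff_old, vapply(old_f, function(id) {
        ibm_act_effect(pop, id, cost = t_old / 10, benefit = 1, p)
      }, numeric(1)))
    }
    if (length(yng_f)) {
      eff_young <- c(eff_young, vapply(yng_f, function(id) {
        ibm_act_effect(pop, id, cost = -t_young / 10, benefit = -1, p)
      }, numeric(1)))
    }
  }
  expect_gt(length(eff_old), 500)
  expect_gt(length(eff_young), 500)
  # helping pays for old females at c/b inside the predicted help region
  expect_gt(mean(eff_old), 0)
  # harming pays for young females at c/b inside the predicted harm region
  expect_gt(mean(eff_young), 0)
})
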