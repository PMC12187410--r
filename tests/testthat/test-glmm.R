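test_that("dyadic means average the right dyads and apply the offset", {
  tab <- build_dyadic_means(toy_pairs(), toy_metadata(), offset = 1e-5)
  fa_m <- tab[tab$female_id == "fa" & tab$target_sex == "M", ]
  expect_equal(fa_m$mean_relatedness, mean(c(0, 0.5)) + 1e-5)
  expect_equal(fa_m$n_dyads, 2)
  fa_f <- tab[tab$female_id == "fa" & tab$target_sex == "F", ]
  expect_equal(fa_f$mean_relatedness, 0.25 + 1e-5)
  expect_equal(nrow(tab), 4)  # two females x two target sexes
  expect_true(all(tab$scale == "community"))
})

test_that("dyadic means respect maturity, missing dyads and metadata coverage", {
  meta <- toy_metadata()
  meta$age_years[meta$id == "mb"] <- 5        # immature male drops out
  tab <- build_dyadic_means(toy_pairs(), meta)
  expect_equal(tab$n_dyads[tab$female_id == "fa" & tab$target_sex == "M"], 1)
  # a female whose only potential targets are missing is dropped with a note
  pairs2 <- toy_pairs()[1, ]                  # only the fa-fb dyad known
  expect_message(tab2 <- build_dyadic_means(pairs2, toy_metadata()), "dropped")
  expect_true(all(tab2$target_sex == "F"))
  expect_error(build_dyadic_means(toy_pairs(), toy_metadata()[-3, ]), "ma")
})

test_that("subgroup-scale tables restrict dyads to the female's retained subgroup", {
  part <- data.frame(id = c("fa", "fb", "ma", "mb"), year = 1L,
                     subgroup = c(1, 2, 1, 2), excluded = FALSE)
  tab <- suppressMessages(build_dyadic_means(toy_pairs(), toy_metadata(), partition = part))
  expect_true(all(tab$scale == "subgroup"))
  # fa's subgroup holds only ma -> single male dyad, no female row
  fa <- tab[tab$female_id == "fa", ]
  expect_equal(nrow(fa), 1)
  expect_equal(fa$mean_relatedness, 0 + 1e-5)
})

test_that("noiseless synthetic data reproduce pedigree means exactly", {
  p <- small_params(n_females = 6, n_males = 4)
  ds <- make_study_dataset(p, n_years = 2, noise_sd = 0, seed = 5, burn_in = 30)
  tab <- suppressMessages(
    build_dyadic_means(ds$relatedness_pairs, ds$metadata, offset = 1e-5))
  # cross-check one cell against the truth matrix of its year block
  row <- tab[1, ]
  blk <- ds$truth$year_block[row$year]
  R <- ds$truth$relmatrix_by_block[[blk]]
  resid <- ds$metadata[ds$metadata$year == row$year & ds$metadata$resident, ]
  mature <- resid[ifelse(resid$sex == "F", resid$age_years >= 13,
                         resid$age_years >= 10.5), ]
  targets <- setdiff(mature$id[mature$sex == row$target_sex], row$female_id)
  targets <- intersect(targets, rownames(R))
  expect_equal(row$mean_relatedness,
               mean(R[row$female_id, targets]) + 1e-5)
})

test_that("prior-predictive draws recover the stated priors", {
  pr <- prior_predictive_glmm(glmm_config(seed = 4), n_draws = 4000)
  expect_lt(abs(mean(pr$a) - (-2)), 0.1)
  expect_lt(abs(mean(pr$bA)), 0.1)
  expect_lt(abs(stats::median(pr$phi) - 100), 15)
  expect_true(all(pr$sigma_f > 0))
})

test_that("the fit rejects malformed tables", {
  tab <- simulate_glmm_table(n_females = 5, n_years = 1, seed = 1)
  bad <- tab; bad$mean_relatedness[1] <- 0
  expect_error(fit_beta_glmm(bad), "offset")
  one_sex <- tab[tab$target_sex == "M", ]
  expect_error(fit_beta_glmm(one_sex), "target sexes")
  one_female <- tab[tab$female_id == tab$female_id[1], ]
  expect_error(fit_beta_glmm(one_female), "2 females")
})

test_that("the GLMM recovers a planted positive male-age slope and is row-order invariant", {
  tab <- simulate_glmm_table(n_females = 25, n_years = 4,
                             coefs = list(a = -4, bA = 0.25, bS = 0.2, bI = 0.25),
                             sigma_f = 0.25, phi = 300, seed = 17)
  cfg <- test_glmm_config(adapt = 200, warmup = 200, draws = 500)
  fit <- suppressWarnings(fit_beta_glmm(tab, cfg))
  # posterior probability that relatedness to males increases with age
  p_pos <- mean(fit$draws[, "bA"] + fit$draws[, "bI"] > 0)
  expect_gt(p_pos, 0.95)
  # identical fit after shuffling rows (internal sort + seeded sampler)
  set.seed(1)
  fit2 <- suppressWarnings(fit_beta_glmm(tab[sample(nrow(tab)), ], cfg))
  expect_equal(fit$summary, fit2$summary)
  # per-year slope reporting is the standardized slope over age_scale
  expect_equal(fit$summary_per_year$mean[1],
               mean(fit$draws[, "bA"]) / cfg$age_scale)
})

test_that("posterior trajectories honour the link, the offset and the guard", {
  cfg <- glmm_config(offset = 1e-3)
  draws <- cbind(a = rnorm(500, -2, 0.1), bA = 0, bS = 0, bI = 0,
                 sigma_f = 0.2, phi = 100)
  fake <- structure(list(draws = draws, config = cfg), class = "beta_glmm_fit")
  tr <- posterior_trajectory(fake, ages = c(13, 40, 65), sex = "F")
  # zero slopes: flat curve equal to inverse-logit intercept summaries
  expect_equal(tr$mean, rep(mean(plogis(draws[, "a"])) - 1e-3, 3))
  expect_lt(diff(range(tr$mean)), 1e-12)
  expect_true(all(tr$lower <= tr$mean & tr$mean <= tr$upper))
  expect_error(posterior_trajectory(fake, ages = 80, sex = "F"), "guard")
  # monotone link: almost-surely-positive slopes give an increasing male curve
  draws2 <- cbind(a = rnorm(500, -4, 0.05), bA = abs(rnorm(500, 0.3, 0.05)),
                  bS = 0, bI = abs(rnorm(500, 0.2, 0.05)), sigma_f = 0.1, phi = 100)
  fake2 <- structure(list(draws = draws2, config = glmm_config()), class = "beta_glmm_fit")
  tr2 <- posterior_trajectory(fake2, ages = seq(13, 65, 5), sex = "M")
  expect_true(all(diff(tr2$mean) > 0))
})

test_that("doubling the sampling leaves posterior means within Monte Carlo error", {
  tab <- simulate_glmm_table(n_females = 15, n_years = 3, seed = 23)
  f1 <- suppressWarnings(fit_beta_glmm(tab, test_glmm_config(draws = 400, warmup = 200, adapt = 200, seed = 7)))
  f2 <- suppressWarnings(fit_beta_glmm(tab, test_glmm_config(draws = 800, warmup = 200, adapt = 200, seed = 8)))
  for (par in c("a", "bA", "bS", "bI")) {
    i1 <- which(f1$summary$parameter == par)
    mcse1 <- f1$summary$sd[i1] / sqrt(f1$summary$n_eff[i1])
    i2 <- which(f2$summary$parameter == par)
    mcse2 <- f2$summary$sd[i2] / sqrt(f2$summary$n_eff[i2])
    expect_lt(abs(f1$summary$mean[i1] - f2$summary$mean[i2]),
              3 * sqrt(mcse1^2 + mcse2^2))
  }
})
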