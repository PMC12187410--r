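# Shared fixtures: small demographic parameter sets and hand-built tables.

small_params <- function(...) {
  args <- utils::modifyList(
    list(n_females = 12, n_males = 8, disp_f = 0.5, disp_m = 0,
         repl_f = 0.1, repl_m = 0.1, local_mating = 1, n_steps = 10),
    list(...))
  do.call(demographic_params, args)
}

# tiny relatedness-pairs + metadata pair for build_dyadic_means tests:
# one year, two females (fa, fb), two males (ma, mb)
toy_pairs <- function() {
  data.frame(
    ida = c("fa", "fa", "fa", "fb", "fb", "ma"),
    idb = c("fb", "ma", "mb", "ma", "mb", "mb"),
    rab = c(0.25, 0.0, 0.5, 0.125, 0.0625, 0.5),
    stringsAsFactors = FALSE)
}

toy_metadata <- function() {
  data.frame(
    id = c("fa", "fb", "ma", "mb"),
    sex = c("F", "F", "M", "M"),
    year = 1L,
    age_years = c(20, 30, 15, 25),
    resident = TRUE,
    stringsAsFactors = FALSE)
}

# reduced MCMC settings for test fits
test_glmm_config <- function(...) {
  args <- utils::modifyList(
    list(adapt = 300L, warmup = 300L, draws = 800L, chains = 2L, seed = 99L),
    list(...))
  do.call(glmm_config, args)
}

expect_symmetric_unit_diag <- function(R) {
  expect_true(isSymmetric(unname(R)))
  expect_equal(unname(diag(R)), rep(1, nrow(R)))
  expect_true(all(R >= 0 & R <= 1))
}
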