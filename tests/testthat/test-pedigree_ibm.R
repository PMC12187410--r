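test_that("relmatrix invariants hold across many steps and recruits follow the additive rule", {
  p <- small_params()
  set.seed(42)
  pop <- pedigree_population(p)
  for (s in 1:40) {
    prev <- pop
    pop <- ibm_step(pop, p)
    expect_symmetric_unit_diag(pop$relmatrix)
    expect_equal(sum(pop$members$sex == "F"), p$n_females)
    expect_equal(sum(pop$members$sex == "M"), p$n_males)
    # every recruit's row against surviving members reproduces the rule
    rec <- attr(pop, "recruits")
    surv <- intersect(prev$members$id, pop$members$id)
    for (i in seq_len(nrow(rec))) {
      m <- pop$members[pop$members$id == rec$id[i], ]
      expected <- vapply(surv, function(j) {
        rm_ <- if (is.na(m$mother_id)) NA_real_ else prev$relmatrix[m$mother_id, j]
        rf_ <- if (is.na(m$father_id)) NA_real_ else prev$relmatrix[m$father_id, j]
        recruit_relatedness(rm_, rf_)
      }, numeric(1))
      expect_equal(unname(pop$relmatrix[rec$id[i], surv]), unname(expected))
    }
  }
})

test_that("sib relatedness identities emerge from shared parents", {
  # two females, one male, no dispersal: same-step recruits share the father,
  # so they are full sibs (0.5) with the same mother, paternal half sibs
  # (0.25) otherwise, relative to unrelated founder parents
  p <- demographic_params(2, 1, 0, 0, 0.5, 0.5, 1, n_steps = 5)
  set.seed(7)
  pop <- pedigree_population(p)
  checked_full <- checked_half <- FALSE
  for (s in 1:40) {
    prev <- pop
    pop <- ibm_step(pop, p)
    rec <- attr(pop, "recruits")
    if (nrow(rec) >= 2) {
      mm <- pop$members[match(rec$id, pop$members$id), ]
      for (i in 1:(nrow(rec) - 1)) for (j in (i + 1):nrow(rec)) {
        r_par <- prev$relmatrix[mm$mother_id[i], mm$father_id[i]]
        r_obs <- pop$relmatrix[rec$id[i], rec$id[j]]
        if (mm$mother_id[i] == mm$mother_id[j]) {
          # full sibs: (1 + r(mo, fa)) / 2
          expect_equal(r_obs, 0.5 * (1 + r_par))
          checked_full <- TRUE
        } else {
          # paternal half sibs: (r(mo1, mo2) + 1 + r crossing terms) / 4
          expect_gte(r_obs, 0.25 - 1e-12)
          checked_half <- TRUE
        }
      }
    }
    if (checked_full && checked_half) break
  }
  expect_true(checked_full)
  expect_true(checked_half)
})

test_that("full immigration erases relatedness and seeds give bit-identical runs", {
  p <- small_params(disp_f = 1, disp_m = 1)
  set.seed(5)
  pop <- pedigree_population(p)
  for (s in 1:50) pop <- ibm_step(pop, p)
  off <- pop$relmatrix[lower.tri(pop$relmatrix)]
  expect_true(all(off == 0))

  prof1 <- suppressWarnings(
    empirical_age_profile(small_params(), n_replicates = 3, burn_in = 20, seed = 11))
  prof2 <- suppressWarnings(
    empirical_age_profile(small_params(), n_replicates = 3, burn_in = 20, seed = 11))
  expect_identical(as.data.frame(prof1), as.data.frame(prof2))
})

test_that("empirical profile is exactly zero under full immigration", {
  p <- small_params(disp_f = 1, disp_m = 1)
  prof <- empirical_age_profile(p, n_replicates = 5, burn_in = 10, seed = 2)
  expect_equal(prof$r_to_males, rep(0, nrow(prof)))
  expect_equal(prof$r_to_females, rep(0, nrow(prof)))
})

test_that("synthetic study datasets are internally consistent and reproducible", {
  p <- small_params()
  ds <- make_study_dataset(p, n_years = 4, noise_sd = 0, seed = 21, burn_in = 40)
  # noiseless estimates equal true pedigree relatedness
  expect_equal(ds$relatedness_pairs$rab, ds$truth$true_relatedness$rab)
  # every id with relatedness data appears in the metadata
  expect_true(all(c(ds$relatedness_pairs$ida, ds$relatedness_pairs$idb) %in%
                    ds$metadata$id))
  expect_true(all(ds$relatedness_pairs$rab >= 0 & ds$relatedness_pairs$rab <= 1))
  # truth carries enough to score recovery
  expect_true(all(unique(ds$association$member_id) %in% ds$truth$subgroups$id))
  expect_setequal(unique(ds$metadata$year), 1:4)
  # determinism
  ds2 <- make_study_dataset(p, n_years = 4, noise_sd = 0, seed = 21, burn_in = 40)
  expect_identical(ds$relatedness_pairs, ds2$relatedness_pairs)
  expect_identical(ds$association, ds2$association)
  # noisy values stay in [0, 1] and differ from truth
  dsn <- make_study_dataset(p, n_years = 2, noise_sd = 0.02, seed = 21, burn_in = 40)
  expect_true(all(dsn$relatedness_pairs$rab >= 0 & dsn$relatedness_pairs$rab <= 1))
  expect_gt(sd(dsn$relatedness_pairs$rab - dsn$truth$true_relatedness$rab), 0)
})

test_that("study dataset files round-trip through the plain-text writers", {
  p <- small_params()
  ds <- make_study_dataset(p, n_years = 2, noise_sd = 0.01, seed = 8, burn_in = 30)
  dir <- tempfile("ds")
  write_study_dataset(ds, dir)
  pairs <- read_relatedness_pairs(file.path(dir, "relatedness.tsv"))
  expect_equal(pairs$rab, ds$relatedness_pairs$rab)
  meta <- read_metadata(file.path(dir, "metadata.csv"))
  expect_equal(nrow(meta), nrow(ds$metadata))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$seed, 8)
  expect_equal(manifest$params$n_females, p$n_females)
  # alternative column names are recognized
  alt <- file.path(dir, "alt.tsv")
  x <- ds$relatedness_pairs
  names(x) <- c("id_a", "id_b", "relatedness")
  write.table(x, alt, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(read_relatedness_pairs(alt)$rab, pairs$rab)
})

test_that("oversized subgroup specs are rejected", {
  p <- small_params()
  expect_error(make_study_dataset(p, 2, subgroup_spec = list(n_subgroups = 50), seed = 1),
               "subgroups")
  expect_error(make_study_dataset(p, 2, subgroup_spec = list(p_within = 0.9, p_between = 0.2),
                                  seed = 1),
               "exceed")
})
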