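#' Generate a synthetic study dataset
#'
#' Emulates the shape of a multi-year field study of a fission-fusion
#' community: a dyadic pairwise-relatedness table (one estimate per dyad, as
#' produced by genomic relatedness estimators), per-individual annual
#' metadata (sex, age, residency), and focal-follow association records with
#' planted subgroup structure. The community is simulated with
#' [ibm_step()] so the emitted relatedness estimates are true pedigree values
#' plus optional truncated-Gaussian estimation noise; the `truth` element
#' retains everything needed to score recovery (generating parameters, true
#' relatedness matrices, true subgroup labels).
#'
#' Study years are mapped onto simulation timesteps (one step spans
#' `step_years` years); an individual is resident in every year of the step
#' block it is present for, mirroring a >= 6-month residency rule. Females
#' enter the mature population at 13 years, males at 10.5; founder ages add a
#' geometric number of elapsed timesteps so the age distribution is
#' stationary.
#'
#' @param params A [demographic_params()] object.
#' @param n_years Number of study years (>= 1).
#' @param noise_sd Standard deviation of the Gaussian estimation noise added
#'   to true relatedness, truncated to \[0, 1\]. 0 emits exact pedigree
#'   values.
#' @param subgroup_spec List: `n_subgroups` (planted blocks), `p_within` /
#'   `p_between` (per-period probability that an individual attends its own /
#'   a given other subgroup's party), `periods_per_year` (sampling periods
#'   per study year), `drop_years` (years with no association data, e.g. a
#'   field gap).
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param burn_in Equilibration steps before the study window opens.
#' @return An object of class `study_dataset`: list with `relatedness_pairs`
#'   (`ida`, `idb`, `rab`), `metadata` (long: `id`, `sex`, `year`,
#'   `age_years`, `resident`), `association` (`focal_id`, `period_id`,
#'   `member_id`, `year`), and `truth`.
#' @export
make_study_dataset <- function(params, n_years, noise_sd = 0.02,
                               subgroup_spec = list(), seed = 1,
                               burn_in = 150) {
  stopifnot(n_years >= 1, noise_sd >= 0)
  sg <- utils::modifyList(list(n_subgroups = 3L, p_within = 0.4,
                               p_between = 0.05, periods_per_year = 60L,
                               drop_years = integer(0)), subgroup_spec)
  n_total <- params$n_females + params$n_males
  if (sg$n_subgroups > n_total) {
    stop(sprintf("subgroup_spec asks for %d subgroups but the population only has %d members",
                 sg$n_subgroups, n_total), call. = FALSE)
  }
  if (sg$p_within + (sg$n_subgroups - 1) * sg$p_between > 1) {
    stop("subgroup_spec attendance probabilities exceed 1", call. = FALSE)
  }
  set.seed(seed)

  pop <- pedigree_population(params)
  for (b in seq_len(burn_in)) pop <- ibm_step(pop, params)

  # study blocks: block k covers years ((k-1)*step, k*step]
  year_block <- floor((seq_len(n_years) - 0.5) / params$step_years) + 1L
  n_blocks <- max(year_block)
  states <- vector("list", n_blocks)
  states[[1]] <- pop
  if (n_blocks > 1) {
    for (k in seq(2, n_blocks)) {
      pop <- ibm_step(pop, params)
      states[[k]] <- pop
    }
  }

  entry_age <- function(sex) ifelse(sex == "F", 13, 10.5)
  first_state <- states[[1]]$members
  age_at_year1 <- stats::setNames(
    entry_age(first_state$sex) +
      stats::rgeom(nrow(first_state),
                   ifelse(first_state$sex == "F", params$repl_f, params$repl_m)) *
      params$step_years,
    first_state$id)

  # subgroup labels: block-1 members split evenly at random; later recruits
  # inherit a uniformly random label (labels persist across years)
  labels <- stats::setNames(
    sample(rep_len(seq_len(sg$n_subgroups), n_total)), first_state$id)

  first_year <- stats::setNames(rep(1L, n_total), first_state$id)
  for (k in seq_len(n_blocks)[-1]) {
    newcomers <- setdiff(states[[k]]$members$id, names(first_year))
    if (length(newcomers)) {
      yr <- min(which(year_block == k))
      first_year[newcomers] <- yr
      labels[newcomers] <- sample.int(sg$n_subgroups, length(newcomers),
                                      replace = TRUE)
    }
  }

  all_ids <- names(first_year)
  sex_of <- stats::setNames(rep(NA_character_, length(all_ids)), all_ids)
  for (k in seq_len(n_blocks)) {
    sex_of[states[[k]]$members$id] <- states[[k]]$members$sex
  }

  meta <- do.call(rbind, lapply(seq_len(n_years), function(y) {
    st <- states[[year_block[y]]]$members
    resident <- all_ids %in% st$id
    age <- ifelse(all_ids %in% names(age_at_year1),
                  age_at_year1[all_ids] + (y - 1),
                  entry_age(sex_of[all_ids]) + (y - first_year[all_ids]))
    data.frame(id = all_ids, sex = unname(sex_of[all_ids]), year = y,
               age_years = unname(age), resident = resident,
               stringsAsFactors = FALSE)
  }))
  rownames(meta) <- NULL

  # dyads co-resident in at least one block; estimate from the latest
  # co-resident state (one estimate per dyad, like a genomic estimator)
  pair_env <- new.env(parent = emptyenv())
  for (k in seq_len(n_blocks)) {
    ids <- states[[k]]$members$id
    R <- states[[k]]$relmatrix
    cmb <- utils::combn(sort(ids), 2)
    for (j in seq_len(ncol(cmb))) {
      key <- paste(cmb[1, j], cmb[2, j], sep = "\r")
      assign(key, R[cmb[1, j], cmb[2, j]], envir = pair_env)
    }
  }
  keys <- sort(ls(pair_env))
  true_r <- vapply(keys, function(k) get(k, envir = pair_env), numeric(1))
  est <- if (noise_sd > 0) {
    pmin(1, pmax(0, true_r + stats::rnorm(length(true_r), 0, noise_sd)))
  } else true_r
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  pairs <- data.frame(ida = parts[, 1], idb = parts[, 2], rab = unname(est),
                      stringsAsFactors = FALSE)

  assoc_years <- setdiff(seq_len(n_years), sg$drop_years)
  assoc <- do.call(rbind, lapply(assoc_years, function(y) {
    st <- states[[year_block[y]]]$members
    res <- st$id
    out <- vector("list", sg$periods_per_year)
    for (p in seq_len(sg$periods_per_year)) {
      # each resident attends its own subgroup's party w.p. p_within, a given
      # other party w.p. p_between, else goes unobserved this period
      pr <- matrix(sg$p_between, length(res), sg$n_subgroups)
      pr[cbind(seq_along(res), labels[res])] <- sg$p_within
      pick <- apply(pr, 1, function(row) {
        u <- stats::runif(1)
        cs <- cumsum(row)
        w <- which(u < cs)
        if (length(w)) w[1] else NA_integer_
      })
      pid <- sprintf("y%02d_p%04d", y, p)
      parties <- split(res[!is.na(pick)], pick[!is.na(pick)])
      out[[p]] <- do.call(rbind, lapply(parties, function(mm) {
        data.frame(focal_id = mm[1], period_id = pid, member_id = mm,
                   year = y, stringsAsFactors = FALSE)
      }))
    }
    do.call(rbind, out)
  }))
  rownames(assoc) <- NULL

  truth <- list(params = params, seed = seed, noise_sd = noise_sd,
                subgroup_spec = sg,
                relmatrix_by_block = lapply(states, function(s) s$relmatrix),
                year_block = year_block,
                true_relatedness = data.frame(ida = parts[, 1], idb = parts[, 2],
                                              rab = unname(true_r),
                                              stringsAsFactors = FALSE),
                subgroups = data.frame(id = names(labels),
                                       subgroup = unname(labels),
                                       stringsAsFactors = FALSE))
  structure(list(relatedness_pairs = pairs, metadata = meta,
                 association = assoc, truth = truth),
            class = "study_dataset")
}

#' Write / read a study dataset as plain-text files
#'
#' `write_study_dataset()` emits `relatedness.tsv` (dyadic, ngsRelate-style
#' columns `ida`, `idb`, `rab`), `metadata.csv`, `association.csv` and a
#' `manifest.json` capturing the generating parameters and seed. The read
#' helpers accept the same formats from any source, mapping common
#' alternative column names (`id_a`/`id_b`, `relatedness`) onto the expected
#' ones.
#'
#' @param dataset A `study_dataset`.
#' @param dir Output directory (created if needed).
#' @return `write_study_dataset()` returns `dir` invisibly; readers return
#'   data frames.
#' @export
write_study_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(dataset$relatedness_pairs, file.path(dir, "relatedness.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(dataset$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$association, file.path(dir, "association.csv"),
                   row.names = FALSE)
  tr <- dataset$truth
  manifest <- list(
    generator = "make_study_dataset",
    package_version = as.character(utils::packageVersion("kinconflict")),
    seed = tr$seed, noise_sd = tr$noise_sd,
    params = unclass(tr$params), subgroup_spec = tr$subgroup_spec,
    n_years = max(dataset$metadata$year),
    files = c("relatedness.tsv", "metadata.csv", "association.csv"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_study_dataset
#' @param path Path of the file to read.
#' @export
read_relatedness_pairs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  names(df) <- nm
  ren <- c(id_a = "ida", id_b = "idb", a = "ida", b = "idb",
           relatedness = "rab", rel = "rab")
  for (i in seq_along(ren)) {
    if (names(ren)[i] %in% nm && !(ren[i] %in% nm)) {
      names(df)[names(df) == names(ren)[i]] <- ren[i]
    }
  }
  need <- c("ida", "idb", "rab")
  if (!all(need %in% names(df))) {
    stop("relatedness table must have columns ida, idb, rab (or recognized synonyms)",
         call. = FALSE)
  }
  df[need]
}

#' @rdname write_study_dataset
#' @export
read_metadata <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname write_study_dataset
#' @export
read_association <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
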