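#' Annual simple-ratio association matrix
#'
#' Builds the dyadic simple-ratio index (SRI) from long-format focal-follow
#' records. A party is the set of individuals recorded with one focal in one
#' sampling period; an individual is "observed" in a period if it appears in
#' any party of that period. For a dyad (A, B),
#' `SRI = x / (x + yA + yB + yAB)` where, over the year's periods, `x` counts
#' periods with A and B in the same party, `yA` / `yB` periods where only one
#' of them was observed, and `yAB` periods where both were observed but never
#' shared a party. No chain-rule correction is applied.
#'
#' @param records Data frame with columns `focal_id`, `period_id`,
#'   `member_id` (and optionally `year`).
#' @param year Study-year label; if `records` has a `year` column the records
#'   are filtered to it.
#' @param min_periods Individuals observed in fewer periods than this over
#'   the year are excluded from the matrix (with a message).
#' @return An object of class `association_matrix`: the symmetric index
#'   matrix (values in \[0, 1\], diagonal `NA`) with attributes `ids` and
#'   `year`.
#' @export
#' @examples
#' rec <- data.frame(focal_id = "a", period_id = rep(1:4, each = 2),
#'                   member_id = c("a", "b", "a", "b", "a", "c", "a", "c"))
#' simple_ratio_index(rec, year = 2010, min_periods = 1)
simple_ratio_index <- function(records, year = NULL, min_periods = 20) {
  need <- c("focal_id", "period_id", "member_id")
  if (!all(need %in% names(records))) {
    stop("records must have columns focal_id, period_id, member_id", call. = FALSE)
  }
  if (!is.null(year) && "year" %in% names(records)) {
    records <- records[records$year == year, ]
  }
  if (!nrow(records)) stop("no association records for this year", call. = FALSE)

  records$party <- paste(records$period_id, records$focal_id, sep = "\r")
  # periods each individual was observed in
  obs <- tapply(records$period_id, records$member_id,
                function(p) unique(as.character(p)))
  n_obs <- vapply(obs, length, integer(1))
  keep <- names(n_obs)[n_obs >= min_periods]
  dropped <- setdiff(names(n_obs), keep)
  if (length(dropped)) {
    message(sprintf("simple_ratio_index: dropping %d individual(s) with < %d observation periods%s",
                    length(dropped), min_periods,
                    if (!is.null(year)) sprintf(" in year %s", year) else ""))
  }
  if (length(keep) < 2) stop("fewer than two individuals meet the observation minimum", call. = FALSE)
  keep <- sort(keep)
  n <- length(keep)

  # periods where each dyad shared a party
  parties <- split(as.character(records$member_id), records$party)
  period_of_party <- vapply(strsplit(names(parties), "\r", fixed = TRUE),
                            `[`, character(1), 1)
  together <- new.env(parent = emptyenv())
  for (g in seq_along(parties)) {
    mm <- sort(unique(intersect(parties[[g]], keep)))
    if (length(mm) < 2) next
    cmb <- utils::combn(mm, 2)
    for (j in seq_len(ncol(cmb))) {
      key <- paste(cmb[1, j], cmb[2, j], sep = "\r")
      cur <- if (exists(key, envir = together)) get(key, envir = together) else character(0)
      assign(key, union(cur, period_of_party[g]), envir = together)
    }
  }

  M <- matrix(NA_real_, n, n, dimnames = list(keep, keep))
  never <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      A <- keep[i]; B <- keep[j]
      key <- paste(A, B, sep = "\r")
      tog <- if (exists(key, envir = together)) get(key, envir = together) else character(0)
      x <- length(tog)
      both <- intersect(obs[[A]], obs[[B]])
      yAB <- length(setdiff(both, tog))
      yA <- length(setdiff(obs[[A]], both))
      yB <- length(setdiff(obs[[B]], both))
      denom <- x + yA + yB + yAB
      val <- if (denom == 0) 0 else x / denom
      if (x == 0) never <- c(never, paste(A, B, sep = "-"))
      M[i, j] <- M[j, i] <- val
    }
  }
  if (length(never)) {
    message(sprintf("simple_ratio_index: %d dyad(s) never co-observed in the same party (index 0)",
                    length(never)))
  }
  structure(M, class = c("association_matrix", class(M)),
            ids = keep, year = year)
}

#' Partition an association matrix into subgroups by Newman modularity
#'
#' Weighted-graph modularity maximization by leading-eigenvector recursive
#' bisection (the SOCPROG approach), with
#' `Q = sum_c (e_cc - a_c^2)` computed on edge-weight fractions. Degenerate
#' inputs (all-zero matrix, or no split with positive `Q`) return a single
#' cluster with `Q = 0`. The procedure is deterministic given the matrix.
#'
#' @param matrix An `association_matrix` (or any symmetric non-negative
#'   matrix with dimnames) over at least two individuals.
#' @return An object of class `subgroup_partition`: list with `membership`
#'   (named integer vector), `modularity_q`, `n_subgroups`, `year`.
#' @export
newman_partition <- function(matrix) {
  M <- unclass(matrix)
  if (nrow(M) < 2) stop("need at least two individuals to partition", call. = FALSE)
  if (is.null(rownames(M))) {
    rownames(M) <- colnames(M) <- paste0("v", seq_len(nrow(M)))
  }
  M[is.na(M)] <- 0
  diag(M) <- 0
  if (any(M < 0)) stop("association indices must be non-negative", call. = FALSE)
  if (max(M) == 0) {
    membership <- stats::setNames(rep(1L, nrow(M)), rownames(M))
    return(structure(list(membership = membership, modularity_q = 0,
                          n_subgroups = 1L, year = attr(matrix, "year")),
                     class = "subgroup_partition"))
  }
  g <- igraph::graph_from_adjacency_matrix(M, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  cl <- igraph::cluster_leading_eigen(g, weights = igraph::E(g)$weight)
  membership <- igraph::membership(cl)
  q <- weighted_modularity(M, membership)
  if (q <= 0) {
    membership[] <- 1L
    q <- 0
  }
  membership <- stats::setNames(as.integer(factor(membership)), rownames(M))
  structure(list(membership = membership, modularity_q = q,
                 n_subgroups = length(unique(membership)),
                 year = attr(matrix, "year")),
            class = "subgroup_partition")
}

# Q = sum_c (e_cc - a_c^2) on edge-weight fractions of a symmetric matrix
weighted_modularity <- function(M, membership) {
  M[is.na(M)] <- 0
  diag(M) <- 0
  W <- sum(M)
  if (W == 0) return(0)
  groups <- unique(membership)
  q <- 0
  for (gr in groups) {
    inside <- membership == gr
    e_cc <- sum(M[inside, inside, drop = FALSE]) / W
    a_c <- sum(M[inside, , drop = FALSE]) / W
    q <- q + e_cc - a_c^2
  }
  q
}

#' @export
print.subgroup_partition <- function(x, ...) {
  cat(sprintf("Subgroup partition (%d subgroup(s), Q = %.3f%s)\n",
              x$n_subgroups, x$modularity_q,
              if (!is.null(x$year)) sprintf(", year %s", x$year) else ""))
  print(table(subgroup = x$membership))
  invisible(x)
}

#' Flag single-sex subgroups for exclusion
#'
#' Kinship dynamics at the subgroup scale are only meaningful where females
#' can compete or cooperate with members of both sexes, so subgroups that
#' contain no female or no male are flagged excluded. The returned partition
#' carries a summary of the retained subgroups (count, sizes, proportion of
#' females).
#'
#' @param partition A `subgroup_partition`.
#' @param metadata Data frame mapping `id` to `sex` (extra columns ignored;
#'   one row per id suffices).
#' @return The partition with added elements `excluded` (named logical by
#'   id), `mixed_sex` (logical by subgroup) and `summary`.
#' @export
mixed_sex_filter <- function(partition, metadata) {
  ids <- names(partition$membership)
  sex_map <- metadata$sex[match(ids, metadata$id)]
  if (anyNA(sex_map)) {
    stop("missing sex for id(s): ",
         paste(ids[is.na(sex_map)], collapse = ", "), call. = FALSE)
  }
  groups <- sort(unique(partition$membership))
  mixed <- vapply(groups, function(gr) {
    s <- sex_map[partition$membership == gr]
    any(s == "F") && any(s == "M")
  }, logical(1))
  names(mixed) <- groups
  excluded <- !mixed[as.character(partition$membership)]
  names(excluded) <- ids
  retained <- groups[mixed]
  sizes <- vapply(retained, function(gr) sum(partition$membership == gr), integer(1))
  propf <- vapply(retained, function(gr) {
    mean(sex_map[partition$membership == gr] == "F")
  }, numeric(1))
  partition$excluded <- excluded
  partition$mixed_sex <- mixed
  partition$summary <- list(
    n_retained = length(retained),
    n_excluded = sum(!mixed),
    sizes = sizes,
    mean_size = if (length(sizes)) mean(sizes) else NA_real_,
    prop_female = propf,
    mean_prop_female = if (length(propf)) mean(propf) else NA_real_)
  partition
}

#' Annual subgroup assignment across a multi-year association table
#'
#' Convenience wrapper running [simple_ratio_index()], [newman_partition()]
#' and [mixed_sex_filter()] for every year with association records; years
#' without records are skipped (with a message), mirroring field seasons with
#' no association data.
#'
#' @param association Long-format records with a `year` column.
#' @param metadata Data frame mapping `id` to `sex`.
#' @param years Years to attempt; defaults to all years in `association`.
#' @param min_periods Passed to [simple_ratio_index()].
#' @return A list: `partitions` (per year), and `table` -- a data frame
#'   `id`, `year`, `subgroup`, `excluded`.
#' @export
assign_annual_subgroups <- function(association, metadata, years = NULL,
                                    min_periods = 20) {
  if (is.null(years)) years <- sort(unique(association$year))
  partitions <- list()
  rows <- list()
  for (y in years) {
    rec <- association[association$year == y, ]
    if (!nrow(rec)) {
      message(sprintf("no association records for year %s; skipping", y))
      next
    }
    M <- simple_ratio_index(rec, year = y, min_periods = min_periods)
    part <- mixed_sex_filter(newman_partition(M), metadata)
    partitions[[as.character(y)]] <- part
    rows[[as.character(y)]] <- data.frame(
      id = names(part$membership), year = y,
      subgroup = unname(part$membership),
      excluded = unname(part$excluded), stringsAsFactors = FALSE)
  }
  list(partitions = partitions, table = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}
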