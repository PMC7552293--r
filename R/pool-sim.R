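# Simulator of the two-stage pooled screen: individuals are randomly
# partitioned into pools of size a; each pool costs one reaction; any pool
# whose members do not all share one genotype is re-examined one reaction
# per member. The assay is error-free by default.

#' Randomly partition individuals into pools
#'
#' A seeded random permutation of the IDs is chunked into consecutive groups
#' of `a`; the remainder (if `a` does not divide the cohort) forms a final
#' smaller pool.
#'
#' @param ids character or integer vector of individual identifiers.
#' @param a pool size (>= 1).
#' @param seed integer RNG seed.
#' @return list of class `pool_plan`: `assignments` (list of ID vectors),
#'   `a`, and `group` (integer pool index per input ID, in input order).
#' @export
make_pools <- function(ids, a, seed = 1) {
  if (length(ids) == 0) stop_input("ids must be non-empty")
  if (a < 1 || a != as.integer(a)) stop_input("pool size a must be >= 1")
  perm <- with_rng(seed, sample(length(ids)))
  grp_of_pos <- ceiling(seq_along(ids) / a)          # pool index by permuted slot
  group <- integer(length(ids))
  group[perm] <- grp_of_pos
  structure(list(assignments = split(ids[perm], grp_of_pos),
                 a = as.integer(a), group = group),
            class = "pool_plan")
}

#' Run the two-stage screen on a genotyped population
#'
#' First stage: one reaction per pool. A pool is uniform iff all its members
#' share one genotype, in which case every member receives that call from
#' the pool reaction alone. Otherwise every member of the pool is retested
#' individually (one reaction each) and called from its retest. The assay is
#' error-free, so calls always equal true genotypes; an optional per-pool
#' false-negative rate models a mixed pool read as uniform (members then
#' called at the pool's majority genotype).
#'
#' @param population data.frame with columns `id` and `genotype` (0/1/2).
#' @param plan a [make_pools()] plan over exactly the population's IDs.
#' @param fn_rate per-pool probability that a mixed pool is missed
#'   (default 0: perfectly sensitive heteroduplex detection).
#' @param seed RNG seed, used only when `fn_rate > 0`.
#' @return list of class `screen_outcome`: `pool_tests`, `retests`,
#'   `total_reactions`, `genotype_calls` (named vector), `mixed_pools`.
#' @export
screen_pools <- function(population, plan, fn_rate = 0, seed = 1) {
  stopifnot(inherits(plan, "pool_plan"))
  if (!all(c("id", "genotype") %in% names(population))) {
    stop_input("population must have columns id and genotype")
  }
  planned <- unlist(plan$assignments, use.names = FALSE)
  pos <- match(planned, population$id)
  g <- population$genotype[pos]
  bad <- is.na(pos) | is.na(g)
  if (any(bad)) {
    stop_input("no genotype for individual(s): %s",
               paste(utils::head(planned[bad], 5), collapse = ", "))
  }
  sizes <- lengths(plan$assignments)
  grp <- rep.int(seq_along(sizes), sizes)
  first <- g[match(seq_along(sizes), grp)]
  truly_mixed <- rowsum(as.integer(g != first[grp]), grp)[, 1] > 0
  mixed <- truly_mixed
  if (fn_rate > 0) {
    missed <- with_rng(seed, stats::runif(length(mixed)) < fn_rate)
    mixed <- mixed & !missed
  }
  calls <- g
  # a mixed pool read as uniform (false negative) mis-calls its members at
  # the pool's majority genotype; with fn_rate = 0 this branch never runs
  for (i in which(truly_mixed & !mixed)) {
    members <- grp == i
    tab <- tabulate(g[members] + 1L, nbins = 3L)
    calls[members] <- which.max(tab) - 1L
  }
  pool_tests <- length(sizes)
  retests <- sum(sizes[mixed])
  calls_by_id <- stats::setNames(calls[order(pos)],
                                 population$id[sort(pos)])
  structure(list(pool_tests = pool_tests,
                 retests = retests,
                 total_reactions = pool_tests + retests,
                 genotype_calls = calls_by_id,
                 mixed_pools = which(mixed)),
            class = "screen_outcome")
}

#' Empirical reaction-count curve over pool sizes
#'
#' Monte-Carlo counterpart of [design_curve()]: for each pool size the
#' population is repeatedly re-pooled (fresh seeds) and screened, and the
#' realized total reaction counts are summarized next to the analytic
#' expectation.
#'
#' @param population data.frame with `id` and `genotype`.
#' @param a_min,a_max inclusive pool-size range.
#' @param replicates number of seeded replicates per pool size.
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param p_expected positive frequency used for the analytic prediction
#'   column; defaults to the population's realized carrier frequency.
#' @return data.frame: `a`, `mean_reactions`, `sd_reactions`, `predicted`.
#' @export
empirical_curve <- function(population, a_min, a_max, replicates = 100,
                            seed = 1, p_expected = NULL) {
  if (a_min < 1 || a_min > a_max) stop_input("invalid pool-size range")
  if (replicates < 1) stop_input("replicates must be >= 1")
  if (is.null(p_expected)) p_expected <- mean(population$genotype > 0)
  a_seq <- seq.int(a_min, a_max)
  seeds <- matrix(derive_seeds(seed, length(a_seq) * replicates),
                  nrow = length(a_seq))
  res <- lapply(seq_along(a_seq), function(i) {
    totals <- vapply(seq_len(replicates), function(r) {
      plan <- make_pools(population$id, a_seq[i], seed = seeds[i, r])
      screen_pools(population, plan)$total_reactions
    }, numeric(1))
    data.frame(a = a_seq[i],
               mean_reactions = mean(totals),
               sd_reactions = stats::sd(totals),
               predicted = expected_reactions(nrow(population), p_expected,
                                              a_seq[i])$n_expected)
  })
  do.call(rbind, res)
}
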