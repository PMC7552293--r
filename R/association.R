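# Genotype-trait association for a low-frequency deletion: per-sex,
# per-trait comparison of wild-type vs deletion carriers. Trait
# distributions are screened for normality with a Kolmogorov-Smirnov test;
# the group comparison is the Mann-Whitney U test, exact when the smaller
# arm permits, otherwise a tie-corrected normal approximation with
# continuity correction.

# Survival function of the Kolmogorov distribution,
# Q(t) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 t^2).
kolmogorov_sf <- function(t) {
  if (t < 0.05) return(1)
  k <- 1:100
  min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))))
}

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS statistic of the data against a normal distribution with
#' sample-estimated mean and SD. The default p-value uses the asymptotic
#' Kolmogorov distribution (the common statistics-package default when
#' parameters are estimated); because estimation makes that p-value
#' conservative, a Lilliefors Monte-Carlo p-value is available.
#'
#' @param values numeric sample (n >= 4, non-constant).
#' @param lilliefors if `TRUE`, also compute a Monte-Carlo Lilliefors
#'   p-value (`mc_draws` seeded normal samples re-estimating parameters).
#' @param mc_draws,seed Monte-Carlo settings for the Lilliefors p-value.
#' @return list: `ks_stat`, `p_value` (asymptotic), `n`, and
#'   `p_lilliefors` when requested.
#' @export
ks_normality <- function(values, lilliefors = FALSE, mc_draws = 1e4,
                         seed = 1) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 4) stop_input("need at least 4 observations, got %d", n)
  s <- stats::sd(values)
  if (s == 0) stop_input("sample is constant; normality screen undefined")
  stat_of <- function(x) {
    z <- sort((x - mean(x)) / stats::sd(x))
    F <- stats::pnorm(z)
    i <- seq_along(z)
    max(i / length(z) - F, F - (i - 1) / length(z))
  }
  D <- stat_of(values)
  out <- list(ks_stat = D, p_value = kolmogorov_sf(sqrt(n) * D), n = n)
  if (lilliefors) {
    null_D <- with_rng(seed, vapply(seq_len(mc_draws), function(i) {
      stat_of(stats::rnorm(n))
    }, numeric(1)))
    out$p_lilliefors <- (sum(null_D >= D) + 1) / (mc_draws + 1)
  }
  out
}

# Cache of exact Mann-Whitney null distributions keyed by "m,n".
.mw_cache <- new.env(parent = emptyenv())

# Exact null distribution of U for tie-free samples of sizes m and n:
# counts c(u; m, n) satisfy c(u; m, n) = c(u - n; m - 1, n) + c(u; m, n - 1)
# (the largest observation belongs to one arm or the other), which is an
# exact tally of all choose(m + n, m) rank assignments.
mw_exact_probs <- function(m, n) {
  key <- paste(m, n, sep = ",")
  if (!is.null(.mw_cache[[key]])) return(.mw_cache[[key]])
  umax <- m * n
  # counts[k + 1, u + 1] = c(u; k, np), built up over np = 0..n;
  # at np = 0 every arm size has the point mass c(0) = 1
  counts <- matrix(0, nrow = m + 1, ncol = umax + 1)
  counts[, 1] <- 1
  for (np in seq_len(n)) {
    # ascending k: counts[k, ] is already at np, counts[k + 1, ] still at np - 1
    for (k in 1:m) {
      shifted <- c(rep(0, np), counts[k, seq_len(umax + 1 - np)])
      counts[k + 1, ] <- counts[k + 1, ] + shifted
    }
  }
  probs <- counts[m + 1, ] / choose(m + n, m)
  .mw_cache[[key]] <- probs
  probs
}

#' Mann-Whitney U test of two trait arms
#'
#' `U` counts pairwise wins of the first arm via midranks. Mode `"exact"`
#' evaluates the full null permutation distribution of `U` (valid only
#' without ties); mode `"approx"` uses the tie-corrected normal
#' approximation with continuity correction. The default `"auto"` picks
#' exact when the smaller arm has at most `exact_limit` observations and the
#' pooled data are tie-free.
#'
#' @param values_wild,values_del numeric trait values of the wild-type and
#'   deletion-carrier arms.
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @param exact_limit largest minor-arm size for automatic exact mode.
#' @return list of class `mw_result`: `U` (first arm), `U_del`, `z`
#'   (tie-corrected deviate), `p_value` (two-sided), `method`, `n_wild`,
#'   `n_del`, means and standard errors per arm.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4), mode = "exact")$p_value # 1/3
#' @export
mann_whitney <- function(values_wild, values_del,
                         mode = c("auto", "exact", "approx"),
                         exact_limit = 10) {
  mode <- match.arg(mode)
  x <- values_wild[!is.na(values_wild)]
  y <- values_del[!is.na(values_del)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop_input("both genotype arms must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled) # midranks
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  ties <- any(duplicated(pooled))
  if (mode == "auto") {
    mode <- if (!ties && min(n1, n2) <= exact_limit) "exact" else "approx"
  }
  if (mode == "exact" && ties) {
    stop_input("exact mode requires tie-free data; use mode = 'approx'")
  }
  # tie-corrected normal deviate reported in both modes
  N <- n1 + n2
  tie_tab <- table(pooled)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  mu <- n1 * n2 / 2
  z <- if (sigma2 > 0) {
    (U1 - mu - sign(U1 - mu) * 0.5) / sqrt(sigma2)
  } else 0
  if (mode == "exact") {
    m <- min(n1, n2)
    probs <- mw_exact_probs(m, max(n1, n2))
    u_small <- if (n1 <= n2) U1 else U2 # U of the smaller arm
    lower <- sum(probs[seq_len(u_small + 1)])
    upper <- sum(probs[seq.int(u_small + 1, length(probs))])
    p <- min(1, 2 * min(lower, upper))
  } else {
    p <- if (sigma2 > 0) 2 * stats::pnorm(-abs(z)) else 1
  }
  structure(list(U = U1, U_del = U2, z = z, p_value = p,
                 method = mode, n_wild = n1, n_del = n2,
                 mean_wild = mean(x), se_wild = stats::sd(x) / sqrt(n1),
                 mean_del = mean(y), se_del = stats::sd(y) / sqrt(n2)),
            class = "mw_result")
}

#' Per-sex, per-trait association table
#'
#' Joins trait and genotype tables on individual ID, splits each trait into
#' wild-type (genotype 0) and deletion-carrier (genotype >= 1) arms within
#' each sex stratum, and runs [mann_whitney()] per (sex, trait) cell. Arm
#' summaries are arithmetic mean and standard error.
#'
#' @param traits data.frame with `id`, `sex`, and one column per trait.
#' @param genotypes data.frame with `id` and `genotype` (0/1/2); if `traits`
#'   already has a `genotype` column, `genotypes` may be `NULL`.
#' @param trait_names trait columns to test (default: all numeric columns
#'   other than `genotype`).
#' @param stratify_by_sex split into `ram`/`ewe` strata (default `TRUE`).
#' @param alpha significance level for the `significant` flag.
#' @param ... passed to [mann_whitney()].
#' @return data.frame, one row per (sex, trait): `sex`, `trait`, `n_wild`,
#'   `mean_wild`, `se_wild`, `n_del`, `mean_del`, `se_del`, `U`, `p_value`,
#'   `significant`.
#' @export
association_table <- function(traits, genotypes = NULL, trait_names = NULL,
                              stratify_by_sex = TRUE, alpha = 0.05, ...) {
  if (!is.null(genotypes)) {
    if (!all(c("id", "genotype") %in% names(genotypes))) {
      stop_input("genotypes must have columns id and genotype")
    }
    matched <- match(traits$id, genotypes$id)
    if (anyNA(matched)) {
      warning(sum(is.na(matched)), " trait record(s) without a genotype dropped")
    }
    traits <- traits[!is.na(matched), , drop = FALSE]
    traits$genotype <- genotypes$genotype[matched[!is.na(matched)]]
  }
  if (!("genotype" %in% names(traits))) {
    stop_input("no genotype column and no genotype table given")
  }
  if (is.null(trait_names)) {
    trait_names <- setdiff(names(traits)[vapply(traits, is.numeric, logical(1))],
                           "genotype")
  }
  missing_tr <- setdiff(trait_names, names(traits))
  if (length(missing_tr)) {
    stop_input("trait column(s) missing: %s", paste(missing_tr, collapse = ", "))
  }
  strata <- if (stratify_by_sex) split(traits, traits$sex) else list(all = traits)
  rows <- list()
  for (sx in names(strata)) {
    d <- strata[[sx]]
    carrier <- d$genotype >= 1
    for (tr in trait_names) {
      res <- mann_whitney(d[[tr]][!carrier], d[[tr]][carrier], ...)
      rows[[length(rows) + 1]] <- data.frame(
        sex = sx, trait = tr,
        n_wild = res$n_wild, mean_wild = res$mean_wild, se_wild = res$se_wild,
        n_del = res$n_del, mean_del = res$mean_del, se_del = res$se_del,
        U = res$U, p_value = res$p_value,
        significant = res$p_value < alpha,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
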