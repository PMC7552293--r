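# Normality screening and Mann-Whitney association: hand-computed KS
# statistics, enumeration oracle for exact p-values, agreement with the
# stats-package reference, calibration under the null, and power ordering.

test_that("KS statistic equals the hand-computed sup-distance", {
  # {0, 0, 0, 1}: fitted mean 0.25, SD 0.5; jumps at z = -0.5 and z = 1.5
  v <- c(0, 0, 0, 1)
  z <- sort((v - mean(v)) / stats::sd(v))
  i <- 1:4
  by_hand <- max(pmax(i / 4 - stats::pnorm(z), stats::pnorm(z) - (i - 1) / 4))
  res <- ks_normality(v)
  expect_equal(res$ks_stat, by_hand)

  # near-perfect normal fit: quantiles at plotting positions
  q <- stats::qnorm(((1:100) - 0.5) / 100)
  expect_lt(ks_normality(q)$ks_stat, 0.01)

  expect_error(ks_normality(rep(1, 10)), "constant")
  expect_error(ks_normality(c(1, 2, 3)), "at least 4")
})

test_that("KS statistic and asymptotic p agree with the stats reference", {
  for (s in 1:5) {
    v <- withr::with_seed(s, stats::rlnorm(80))
    res <- ks_normality(v)
    ref <- suppressWarnings(stats::ks.test(v, "pnorm", mean(v), stats::sd(v),
                                           exact = FALSE))
    expect_equal(res$ks_stat, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-6)
  }
})

test_that("Lilliefors Monte-Carlo p agrees with the nortest reference", {
  v <- withr::with_seed(4, stats::rlnorm(60))
  res <- ks_normality(v, lilliefors = TRUE, mc_draws = 4000, seed = 2)
  ref <- nortest::lillie.test(v)
  # both reject clearly for a log-normal sample of this size
  expect_lt(res$p_lilliefors, 0.01)
  expect_lt(ref$p.value, 0.01)
  # and agree loosely on a normal sample, where p is non-extreme
  v2 <- withr::with_seed(5, stats::rnorm(60))
  res2 <- ks_normality(v2, lilliefors = TRUE, mc_draws = 4000, seed = 2)
  ref2 <- nortest::lillie.test(v2)
  expect_lt(abs(res2$p_lilliefors - ref2$p.value), 0.1)
})

# Brute-force oracle: enumerate every assignment of pooled ranks to arm 1.
enumerate_mw <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  U_all <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p <- min(1, 2 * min(mean(U_all <= U_obs), mean(U_all >= U_obs)))
  list(U = U_obs, p = p)
}

test_that("exact Mann-Whitney p-values match full enumeration for all small tie-free inputs", {
  res <- mann_whitney(c(1, 2), c(3, 4), mode = "exact")
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 2 / 6)

  for (s in 1:40) {
    sizes <- withr::with_seed(s, sample(2:8, 2))
    n1 <- sizes[1]; n2 <- min(sizes[2], 10 - n1)
    if (n2 < 1) n2 <- 1
    v <- withr::with_seed(s + 100, sample(seq_len(50), n1 + n2)) # tie-free
    x <- v[seq_len(n1)]; y <- v[n1 + seq_len(n2)]
    res <- mann_whitney(x, y, mode = "exact")
    oracle <- enumerate_mw(x, y)
    expect_equal(res$U, oracle$U)
    expect_equal(res$p_value, oracle$p, tolerance = 1e-12)
  }
})

test_that("U statistics are complementary and agree with wilcox.test", {
  for (s in 1:10) {
    x <- withr::with_seed(s, stats::rnorm(12))
    y <- withr::with_seed(s + 50, stats::rnorm(7, 0.5))
    res <- mann_whitney(x, y)
    expect_equal(res$U + res$U_del, 12 * 7)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(res$U, unname(ref$statistic))
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  }
  # midrank ties: U1 + U2 = n1 n2 still holds; approx p matches wilcox.test
  x <- c(1, 2, 2, 3, 5, 5)
  y <- c(2, 3, 3, 4)
  res <- mann_whitney(x, y, mode = "approx")
  expect_equal(res$U + res$U_del, length(x) * length(y))
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("normal approximation converges to the exact p at moderate sizes", {
  diffs <- vapply(1:50, function(s) {
    v <- withr::with_seed(s, sample(seq_len(200), 40)) # tie-free
    x <- v[1:20]; y <- v[21:40]
    abs(mann_whitney(x, y, mode = "exact")$p_value -
          mann_whitney(x, y, mode = "approx")$p_value)
  }, numeric(1))
  expect_lt(max(diffs), 0.02)
})

test_that("identical arms give U = n1 n2 / 2 and p near 1", {
  v <- c(3.2, 5.1, 7.8, 9.0)
  res <- mann_whitney(v, v)
  expect_equal(res$U, length(v)^2 / 2)
  expect_gt(res$p_value, 0.95)
  expect_error(mann_whitney(numeric(0), v), "non-empty")
})

test_that("association table has one row per sex-trait cell with correct arm sizes", {
  pop <- generate_population(
    population_spec(c(TS = 907), maf = 0.007,
                    sex_counts = list(TS = c(458, 449))), seed = 31)
  traits <- generate_traits(pop, trait_spec(), seed = 32)
  tab <- association_table(traits)
  expect_equal(nrow(tab), 16) # 8 traits x 2 sexes
  expect_setequal(unique(tab$sex), c("ram", "ewe"))
  n_ram <- sum(pop$sex == "ram")
  expect_true(all(tab$n_wild[tab$sex == "ram"] +
                    tab$n_del[tab$sex == "ram"] == n_ram))
  expect_true(all(tab$U >= 0 & tab$U <= tab$n_wild * tab$n_del))

  # genotype join path and mismatch warning
  geno <- pop[, c("id", "genotype")]
  tr2 <- traits[, setdiff(names(traits), "genotype")]
  tab2 <- association_table(tr2, geno)
  expect_equal(tab2$p_value, tab$p_value)
  tr3 <- tr2
  tr3$id[1] <- "missing_id"
  expect_warning(association_table(tr3, geno), "without a genotype")
  expect_error(association_table(tr2, geno, trait_names = "nope"), "missing")
})

test_that("type-I error is calibrated and power responds to a real carrier effect", {
  # null: zero effect, Tan-ram-like arms (449 wild, 9 carriers)
  reps <- 1000
  null_p <- vapply(seq_len(reps), function(s) {
    tr <- tan_like_traits(n_wild = 449, n_del = 9, effect = 0, seed = s)
    mann_whitney(tr$BL[tr$genotype == 0], tr$BL[tr$genotype == 1])$p_value
  }, numeric(1))
  rate <- mean(null_p < 0.05)
  mc_se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rate - 0.05), 3 * mc_se)

  # alternative: -3.6 cm shift on body length at SE-matched noise
  alt_p <- vapply(seq_len(300), function(s) {
    tr <- tan_like_traits(n_wild = 449, n_del = 9, effect = -3.6,
                          seed = s + 2000)
    mann_whitney(tr$BL[tr$genotype == 0], tr$BL[tr$genotype == 1])$p_value
  }, numeric(1))
  expect_gt(mean(alt_p < 0.05), rate)
})
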