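# EM haplotype estimation and LD classification: grid-search likelihood
# oracle, margin preservation, monotone likelihood, parameter recovery, and
# the strength rule.

# Independent oracle: maximize the multinomial likelihood of the 3x3
# genotype table over p_AB on a fine grid, with allele frequencies fixed at
# their observed values (the constrained MLE the EM solves).
grid_ld_oracle <- function(tab, step = 1e-4) {
  n <- sum(tab)
  p_A <- sum(tab * matrix(0:2, 3, 3)) / (2 * n)
  p_B <- sum(tab * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
  lo <- max(0, p_A + p_B - 1)
  hi <- min(p_A, p_B)
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, function(p_ab) {
    h <- c(p_ab, p_A - p_ab, p_B - p_ab, 1 - p_A - p_B + p_ab)
    if (any(h < -1e-12)) return(-Inf)
    h <- pmax(h, 0)
    P <- matrix(0, 3, 3)
    hap_a <- c(1, 1, 0, 0); hap_b <- c(1, 0, 1, 0)
    for (i in 1:4) for (j in 1:4) {
      P[hap_a[i] + hap_a[j] + 1, hap_b[i] + hap_b[j] + 1] <-
        P[hap_a[i] + hap_a[j] + 1, hap_b[i] + hap_b[j] + 1] + h[i] * h[j]
    }
    sum(tab[tab > 0] * log(P[tab > 0]))
  }, numeric(1))
  grid[which.max(ll)]
}

table_to_genotypes <- function(tab) {
  idx <- which(tab > 0, arr.ind = TRUE)
  g1 <- rep(idx[, 1] - 1L, tab[tab > 0])
  g2 <- rep(idx[, 2] - 1L, tab[tab > 0])
  list(g1 = g1, g2 = g2)
}

test_that("EM haplotype frequencies match the grid-search likelihood oracle", {
  # deterministic 3x3 table with double heterozygotes
  tab <- matrix(c(5, 3, 1,
                  2, 4, 1,
                  1, 2, 1), 3, 3, byrow = TRUE)
  g <- table_to_genotypes(tab)
  res <- em_haplotypes(g$g1, g$g2)
  expect_lt(abs(res$hap_freqs[["AB"]] - grid_ld_oracle(tab)), 1e-3)

  # random small tables across seeds
  for (s in 1:25) {
    tab <- withr::with_seed(s, matrix(stats::rpois(9, 2), 3, 3))
    n <- sum(tab)
    if (n < 4) next
    g <- table_to_genotypes(tab)
    res <- tryCatch(em_haplotypes(g$g1, g$g2), error = function(e) NULL)
    if (is.null(res)) next # monomorphic draw: LD undefined
    expect_lt(abs(res$hap_freqs[["AB"]] - grid_ld_oracle(tab)), 1e-3)
  }
})

test_that("EM preserves allele-frequency margins and keeps frequencies on the simplex", {
  for (s in 1:10) {
    tl <- generate_two_locus(two_locus_spec(0.3, 0.15, 0.4, 300), seed = s)
    res <- em_haplotypes(tl$locus1, tl$locus2)
    h <- res$hap_freqs
    expect_lt(abs(sum(h) - 1), 1e-9)
    expect_true(all(h >= -1e-12))
    expect_lt(abs((h[["AB"]] + h[["Ab"]]) - res$p_A), 1e-9)
    expect_lt(abs((h[["AB"]] + h[["aB"]]) - res$p_B), 1e-9)
    expect_true(abs(res$d_prime) <= 1 + 1e-9)
    expect_true(res$r2 >= 0 && res$r2 <= 1 + 1e-9)
  }
})

test_that("EM log-likelihood is nondecreasing along the iteration path", {
  # re-run EM manually, tracking the likelihood at each step
  tl <- generate_two_locus(two_locus_spec(0.4, 0.25, 0.6, 200), seed = 3)
  tab <- table(factor(tl$locus1, 0:2), factor(tl$locus2, 0:2))
  n <- sum(tab)
  p_A <- sum(tab * matrix(0:2, 3, 3)) / (2 * n)
  p_B <- sum(tab * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
  fixed <- c(2 * tab[3, 3] + tab[3, 2] + tab[2, 3],
             2 * tab[3, 1] + tab[3, 2] + tab[2, 1],
             2 * tab[1, 3] + tab[1, 2] + tab[2, 3],
             2 * tab[1, 1] + tab[1, 2] + tab[2, 1])
  n_dh <- tab[2, 2]
  hap_a <- c(1, 1, 0, 0); hap_b <- c(1, 0, 1, 0)
  ll_of <- function(h) {
    P <- matrix(0, 3, 3)
    for (i in 1:4) for (j in 1:4) {
      P[hap_a[i] + hap_a[j] + 1, hap_b[i] + hap_b[j] + 1] <-
        P[hap_a[i] + hap_a[j] + 1, hap_b[i] + hap_b[j] + 1] + h[i] * h[j]
    }
    sum(tab[tab > 0] * log(P[tab > 0]))
  }
  h <- c(p_A * p_B, p_A * (1 - p_B), (1 - p_A) * p_B, (1 - p_A) * (1 - p_B))
  lls <- ll_of(h)
  for (it in 1:50) {
    w <- h[1] * h[4] / (h[1] * h[4] + h[2] * h[3])
    h <- (fixed + n_dh * c(w, 1 - w, 1 - w, w)) / (2 * n)
    lls <- c(lls, ll_of(h))
  }
  expect_true(all(diff(lls) >= -1e-10))
})

test_that("generator D' in {0, 0.5, 1} is recovered within 0.05 at n = 1e4", {
  for (dp in c(0, 0.5, 1)) {
    tl <- generate_two_locus(two_locus_spec(0.3, 0.3, dp, 1e4),
                             seed = 17 + round(10 * dp))
    res <- em_haplotypes(tl$locus1, tl$locus2)
    expect_lt(abs(res$d_prime - dp), 0.05)
  }
  # equilibrium also means r2 near 0
  tl0 <- generate_two_locus(two_locus_spec(0.3, 0.3, 0, 1e4), seed = 5)
  expect_lt(em_haplotypes(tl0$locus1, tl0$locus2)$r2, 0.01)
})

test_that("LD strength classification follows the published rule", {
  expect_equal(classify_ld(list(d_prime = 1, r2 = 1)), "complete")
  expect_equal(classify_ld(list(d_prime = 0.9, r2 = 0.5)), "strong")
  expect_equal(classify_ld(list(d_prime = 0.4, r2 = 0.05)), "weak")
  # open boundary assigned to weak
  expect_equal(classify_ld(list(d_prime = 0.8, r2 = 0.33)), "weak")
  expect_error(classify_ld(list(d_prime = NaN, r2 = 0.2)), "finite")

  # perfect coupling without phase ambiguity
  g1 <- rep(c(0L, 2L), each = 50)
  res <- em_haplotypes(g1, g1)
  expect_equal(res$d_prime, 1)
  expect_equal(res$r2, 1)
  expect_equal(res$strength, "complete")
})

test_that("pairwise LD reports one row per pair and flags undefined pairs", {
  tl <- generate_two_locus(two_locus_spec(0.2, 0.3, 0.5, 100), seed = 8)
  records <- data.frame(l1 = tl$locus1, l2 = tl$locus2, l3 = 0L)
  out <- pairwise_ld(records)
  expect_equal(nrow(out), 3)
  defined <- out$locus1 == "l1" & out$locus2 == "l2"
  expect_true(all(is.na(out$r2[!defined])))
  expect_true(all(grepl("monomorphic", out$note[!defined])))
  expect_false(anyNA(out$r2[defined]))

  # duplicated locus paired with itself: complete self-LD
  res_self <- pairwise_ld(data.frame(a = tl$locus1, b = tl$locus1))
  expect_equal(res_self$Dprime, 1)
  expect_equal(res_self$r2, 1)
  expect_equal(res_self$strength, "complete")
})

test_that("a low-frequency focal locus against common partners shows weak LD at n = 276", {
  # majority verdict over seeds, mirroring the weak-LD finding for a rare
  # deletion paired with moderately common partner loci
  verdicts <- vapply(1:15, function(s) {
    tl <- generate_two_locus(two_locus_spec(0.012, 0.05, 0.3, 276), seed = s)
    res <- tryCatch(em_haplotypes(tl$locus1, tl$locus2),
                    error = function(e) NULL)
    if (is.null(res)) NA_character_ else res$strength
  }, character(1))
  verdicts <- verdicts[!is.na(verdicts)]
  expect_gt(mean(verdicts == "weak"), 0.5)
})
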