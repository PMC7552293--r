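# Two-locus linkage disequilibrium from unphased genotypes: EM estimation
# of the four haplotype frequencies (the double heterozygote is the only
# phase-ambiguous class), then D, Lewontin's D', r^2, and the strength
# classification used for low-frequency indel studies.

# Genotype-class probabilities implied by haplotype frequencies
# h = (AB, Ab, aB, ab); returns a 3x3 matrix indexed by copies of the minor
# allele at locus 1 (rows 0..2) and locus 2 (cols 0..2).
geno_probs_from_haps <- function(h) {
  hap_a <- c(1, 1, 0, 0) # copies of minor allele A per haplotype
  hap_b <- c(1, 0, 1, 0)
  P <- matrix(0, 3, 3)
  for (i in 1:4) {
    for (j in 1:4) {
      P[hap_a[i] + hap_a[j] + 1, hap_b[i] + hap_b[j] + 1] <-
        P[hap_a[i] + hap_a[j] + 1, hap_b[i] + hap_b[j] + 1] + h[i] * h[j]
    }
  }
  P
}

# 3x3 genotype count table from paired 0/1/2 codes.
genotype_cross_table <- function(g1, g2) {
  keep <- !is.na(g1) & !is.na(g2)
  table(factor(g1[keep], levels = 0:2), factor(g2[keep], levels = 0:2))
}

#' EM estimation of two-locus haplotype frequencies and LD statistics
#'
#' Maximum-likelihood haplotype frequencies for a pair of biallelic loci
#' genotyped without phase. All genotype classes except the double
#' heterozygote determine their two haplotypes; the double heterozygotes are
#' split between the coupling (AB/ab) and repulsion (Ab/aB) phases in the
#' E-step in proportion to their current probabilities. Initialization is at
#' linkage equilibrium and the log-likelihood is monotone nondecreasing.
#'
#' @param g1,g2 integer vectors, copies of the minor allele (0/1/2) at each
#'   locus, one entry per individual.
#' @param tol convergence tolerance on the log-likelihood increment.
#' @param max_iter iteration cap; non-convergence is flagged, not hidden.
#' @return list of class `ld_result`: `hap_freqs` (AB, Ab, aB, ab), `p_A`,
#'   `p_B`, `D`, `d_max`, `d_prime` (reported as `|D'|`), `r2`, `strength`,
#'   `loglik`, `iterations`, `converged`, `n`.
#' @export
em_haplotypes <- function(g1, g2, tol = 1e-8, max_iter = 1000) {
  tab <- genotype_cross_table(g1, g2)
  n <- sum(tab)
  if (n < 1) stop_input("no complete two-locus genotypes")
  p_A <- sum(tab * matrix(0:2, 3, 3)) / (2 * n)
  p_B <- sum(tab * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
  if (p_A %in% c(0, 1)) stop_input("LD undefined: locus 1 is monomorphic")
  if (p_B %in% c(0, 1)) stop_input("LD undefined: locus 2 is monomorphic")

  # haplotype counts fixed by unambiguous classes; coded (AB, Ab, aB, ab)
  fixed <- c(
    AB = 2 * tab[3, 3] + tab[3, 2] + tab[2, 3],
    Ab = 2 * tab[3, 1] + tab[3, 2] + tab[2, 1],
    aB = 2 * tab[1, 3] + tab[1, 2] + tab[2, 3],
    ab = 2 * tab[1, 1] + tab[1, 2] + tab[2, 1]
  )
  n_dh <- tab[2, 2] # double heterozygotes: AB/ab or Ab/aB

  h <- c(p_A * p_B, p_A * (1 - p_B), (1 - p_A) * p_B, (1 - p_A) * (1 - p_B))
  loglik_of <- function(h) {
    P <- geno_probs_from_haps(h)
    sum(tab[tab > 0] * log(P[tab > 0]))
  }
  ll <- loglik_of(h)
  iter <- 0
  converged <- TRUE
  repeat {
    iter <- iter + 1
    coupling <- h[1] * h[4]
    repulsion <- h[2] * h[3]
    w <- if (coupling + repulsion > 0) coupling / (coupling + repulsion) else 0.5
    new_counts <- fixed + n_dh * c(w, 1 - w, 1 - w, w)
    h_new <- new_counts / (2 * n)
    ll_new <- loglik_of(h_new)
    done <- abs(ll_new - ll) < tol
    h <- h_new
    ll <- ll_new
    if (done) break
    if (iter >= max_iter) {
      converged <- FALSE
      warning("EM did not converge within ", max_iter, " iterations")
      break
    }
  }
  names(h) <- c("AB", "Ab", "aB", "ab")
  D <- h[["AB"]] - p_A * p_B
  d_max <- if (D >= 0) {
    min(p_A * (1 - p_B), (1 - p_A) * p_B)
  } else {
    min(p_A * p_B, (1 - p_A) * (1 - p_B))
  }
  d_prime <- if (d_max > 0) abs(D) / d_max else 0
  r2 <- D^2 / (p_A * (1 - p_A) * p_B * (1 - p_B))
  res <- structure(list(hap_freqs = h, p_A = p_A, p_B = p_B,
                        D = D, d_max = d_max, d_prime = d_prime, r2 = r2,
                        strength = NA_character_, loglik = ll,
                        iterations = iter, converged = converged, n = n),
                   class = "ld_result")
  res$strength <- classify_ld(res)
  res
}

#' Classify linkage-disequilibrium strength
#'
#' `complete` iff \eqn{D' = 1} and \eqn{r^2 = 1} (within `1e-9`); otherwise
#' `strong` iff \eqn{r^2 > 0.33} (ancestral LD disrupted but strong LD
#' remains) and `weak` iff \eqn{r^2 \le 0.33}. The published inequalities
#' are strict, leaving the boundary \eqn{r^2 = 0.33} open; it is assigned to
#' `weak`.
#'
#' @param result an `ld_result`, or a list with `d_prime` and `r2`.
#' @return one of `"complete"`, `"strong"`, `"weak"`.
#' @export
classify_ld <- function(result) {
  d_prime <- result$d_prime
  r2 <- result$r2
  if (!is.finite(d_prime) || !is.finite(r2)) {
    stop_input("d_prime and r2 must be finite")
  }
  if (abs(d_prime - 1) < 1e-9 && abs(r2 - 1) < 1e-9) return("complete")
  if (r2 > 0.33) return("strong")
  "weak"
}

#' Pairwise LD over all locus pairs of a genotype table
#'
#' @param records data.frame of per-individual genotype codes (0/1/2); one
#'   column per locus.
#' @param loci character vector of locus column names (default: all numeric
#'   columns).
#' @param ... passed to [em_haplotypes()].
#' @return data.frame with one row per unordered pair: `locus1`, `locus2`,
#'   `n`, `D`, `Dprime`, `r2`, `strength`, `iterations`, `note` (error
#'   message for undefined pairs, which are reported, not dropped).
#' @export
pairwise_ld <- function(records, loci = NULL, ...) {
  if (is.null(loci)) {
    loci <- names(records)[vapply(records, is.numeric, logical(1))]
  }
  if (length(loci) < 2) stop_input("need at least two loci")
  pairs <- utils::combn(loci, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    l1 <- pairs[1, k]; l2 <- pairs[2, k]
    res <- tryCatch(em_haplotypes(records[[l1]], records[[l2]], ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(locus1 = l1, locus2 = l2, n = NA_integer_, D = NA_real_,
                 Dprime = NA_real_, r2 = NA_real_, strength = NA_character_,
                 iterations = NA_integer_, note = conditionMessage(res),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(locus1 = l1, locus2 = l2, n = res$n, D = res$D,
                 Dprime = res$d_prime, r2 = res$r2, strength = res$strength,
                 iterations = res$iterations, note = "",
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf(
    "Two-locus LD (n = %d): D = %.4f, D' = %.3f, r2 = %.3f -> %s LD\n",
    x$n, x$D, x$d_prime, x$r2, x$strength))
  cat("Haplotype frequencies:",
      paste(sprintf("%s = %.4f", names(x$hap_freqs), x$hap_freqs),
            collapse = ", "), "\n")
  cat(sprintf("EM: %d iterations, loglik %.4f%s\n", x$iterations, x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}
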