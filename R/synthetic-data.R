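# Synthetic-data generators: Hardy-Weinberg multi-breed populations,
# non-normal growth traits with a carrier effect, and two-locus genotypes
# with controllable linkage disequilibrium. Every generator is a pure
# function of its spec and seed.

GENOTYPE_LEVELS <- c("II", "ID", "DD")

#' Specify a multi-breed population
#'
#' @param breed_sizes named integer vector: individuals per breed.
#' @param maf deletion-allele frequency per breed, in `[0, 0.5]`; recycled or
#'   named to match `breed_sizes`.
#' @param sex_counts optional named list `breed -> c(ram, ewe)`; breeds not
#'   listed get sexes drawn Bernoulli(0.5).
#' @return a `population_spec` list.
#' @examples
#' population_spec(c(TS = 907, LXBH = 629), maf = c(TS = 0.007, LXBH = 0.011))
#' @export
population_spec <- function(breed_sizes, maf, sex_counts = NULL) {
  if (is.null(names(breed_sizes)) || any(!nzchar(names(breed_sizes)))) {
    stop_input("breed_sizes must be a named vector of per-breed counts")
  }
  if (any(breed_sizes < 1)) {
    stop_input("every breed count must be >= 1 (offending: %s)",
               paste(names(breed_sizes)[breed_sizes < 1], collapse = ", "))
  }
  if (length(maf) == 1 && is.null(names(maf))) {
    maf <- stats::setNames(rep(maf, length(breed_sizes)), names(breed_sizes))
  }
  if (is.null(names(maf))) {
    names(maf) <- names(breed_sizes)
  }
  maf <- maf[names(breed_sizes)]
  bad <- is.na(maf) | maf < 0 | maf > 0.5
  if (any(bad)) {
    stop_input("maf must lie in [0, 0.5] for every breed (offending: %s)",
               paste(names(breed_sizes)[bad], collapse = ", "))
  }
  structure(list(breed_sizes = breed_sizes, maf = maf,
                 sex_counts = sex_counts),
            class = "population_spec")
}

#' Generate a diploid population under Hardy-Weinberg equilibrium
#'
#' Genotypes at a biallelic deletion locus are drawn `II`/`ID`/`DD` with
#' probabilities \eqn{(1-p)^2, 2p(1-p), p^2} at each breed's deletion-allele
#' frequency \eqn{p}. Deterministic given the seed.
#'
#' @param spec a [population_spec()].
#' @param seed integer RNG seed.
#' @return data.frame with columns `id`, `breed`, `sex` (`ram`/`ewe`),
#'   `genotype` (0/1/2 copies of the deletion allele).
#' @export
generate_population <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "population_spec"))
  with_rng(seed, {
    rows <- lapply(names(spec$breed_sizes), function(b) {
      n <- spec$breed_sizes[[b]]
      p <- spec$maf[[b]]
      g <- sample(0:2, n, replace = TRUE,
                  prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
      sc <- spec$sex_counts[[b]]
      sex <- if (!is.null(sc)) {
        if (sum(sc) != n) {
          stop_input("sex_counts for breed %s sum to %d, not %d", b, sum(sc), n)
        }
        sample(rep(c("ram", "ewe"), times = sc))
      } else {
        sample(c("ram", "ewe"), n, replace = TRUE)
      }
      data.frame(breed = b, sex = sex, genotype = g,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- cbind(id = sprintf("%s_%04d", out$breed,
                              stats::ave(seq_len(nrow(out)), out$breed,
                                         FUN = seq_along)),
                 out)
    rownames(out) <- NULL
    out
  })
}

# Default growth-trait panel for a Tan-sheep-like population. Locations are
# adult body-measurement means; scales are per-animal standard deviations
# consistent with standard errors of ~0.03-0.21 at arm sizes near 450.
default_trait_panel <- function() {
  data.frame(
    trait = c("BW", "BH", "BL", "HHC", "PG", "CD", "CW", "CC"),
    unit  = c("kg", rep("cm", 7)),
    location = c(33.71, 65.04, 64.85, 62.52, 78.78, 26.54, 20.74, 8.14),
    scale    = c(2.33, 3.18, 4.45, 2.97, 4.03, 2.33, 1.91, 0.64),
    stringsAsFactors = FALSE
  )
}

#' Specify a growth-trait panel
#'
#' @param panel data.frame with columns `trait`, `location`, `scale`
#'   (per-animal SD, same units as the trait); defaults to an eight-trait
#'   body-measurement panel (BW, BH, BL, HHC, PG, CD, CW, CC).
#' @param genotype_effect named numeric: additive shift applied to deletion
#'   carriers, per trait (traits not named get 0).
#' @param noise_family one of `"skewed"` (shifted log-normal, the default,
#'   since livestock growth data typically fail normality), `"heavy-tailed"`
#'   (scaled t with 3 df) or `"normal"`.
#' @return a `trait_spec` list.
#' @export
trait_spec <- function(panel = default_trait_panel(),
                       genotype_effect = numeric(),
                       noise_family = c("skewed", "heavy-tailed", "normal")) {
  noise_family <- match.arg(noise_family)
  stopifnot(all(c("trait", "location", "scale") %in% names(panel)))
  if (anyDuplicated(panel$trait)) stop_input("trait labels must be unique")
  if (any(panel$scale <= 0)) stop_input("trait scale must be > 0")
  unknown <- setdiff(names(genotype_effect), panel$trait)
  if (length(unknown)) {
    stop_input("genotype_effect names not in panel: %s",
               paste(unknown, collapse = ", "))
  }
  eff <- stats::setNames(rep(0, nrow(panel)), panel$trait)
  eff[names(genotype_effect)] <- genotype_effect
  structure(list(panel = panel, genotype_effect = eff,
                 noise_family = noise_family),
            class = "trait_spec")
}

# Standardized (mean 0, SD 1) noise draws from the chosen family.
draw_noise <- function(n, family) {
  switch(family,
    "skewed" = {
      # shifted log-normal, sdlog 0.8: skewness ~3, standardized analytically
      s <- 0.8
      (exp(s * stats::rnorm(n)) - exp(s^2 / 2)) /
        sqrt((exp(s^2) - 1) * exp(s^2))
    },
    "heavy-tailed" = stats::rt(n, df = 3) / sqrt(3),
    "normal" = stats::rnorm(n),
    stop_input("unknown noise_family: %s", family)
  )
}

#' Generate growth traits for a genotyped population
#'
#' Each trait value is `location + genotype_effect * carrier + scale * noise`,
#' where carriers are individuals with at least one deletion allele (dominant
#' coding: heterozygotes are shifted, and deletion homozygotes are effectively
#' absent at the low frequencies modelled).
#'
#' @param genotypes data.frame from [generate_population()] (columns `id`,
#'   `sex`, `genotype` required).
#' @param spec a [trait_spec()].
#' @param seed integer RNG seed.
#' @return data.frame: one row per individual; columns `id`, `breed`, `sex`,
#'   `genotype`, then one column per trait.
#' @export
generate_traits <- function(genotypes, spec = trait_spec(), seed = 1) {
  stopifnot(inherits(spec, "trait_spec"))
  need <- c("id", "sex", "genotype")
  if (!all(need %in% names(genotypes))) {
    stop_input("genotypes must have columns %s", paste(need, collapse = ", "))
  }
  if (any(is.na(genotypes$genotype))) {
    stop_input("every individual must have a genotype")
  }
  n <- nrow(genotypes)
  carrier <- as.numeric(genotypes$genotype >= 1)
  out <- genotypes[, intersect(c("id", "breed", "sex", "genotype"),
                               names(genotypes)), drop = FALSE]
  with_rng(seed, {
    for (k in seq_len(nrow(spec$panel))) {
      tr <- spec$panel$trait[k]
      out[[tr]] <- spec$panel$location[k] +
        spec$genotype_effect[[tr]] * carrier +
        spec$panel$scale[k] * draw_noise(n, spec$noise_family)
    }
  })
  rownames(out) <- NULL
  out
}

#' Specify a two-locus genotype sample with target linkage disequilibrium
#'
#' Haplotype frequencies are constructed as \eqn{p_{AB} = p_A p_B + D} with
#' \eqn{D = D' \cdot D_{max}} and \eqn{D_{max} = \min(p_A(1-p_B),
#' (1-p_A)p_B)} (positive coupling of the two minor alleles).
#'
#' @param p_A,p_B minor-allele frequencies at the two loci, in `(0, 1)`.
#' @param d_prime target `|D'|`, in `[0, 1]`.
#' @param n number of diploid individuals.
#' @return a `two_locus_spec` list with the implied haplotype frequencies.
#' @export
two_locus_spec <- function(p_A, p_B, d_prime, n) {
  if (p_A <= 0 || p_A >= 1 || p_B <= 0 || p_B >= 1) {
    stop_input("allele frequencies must lie in (0, 1); got p_A=%g, p_B=%g",
               p_A, p_B)
  }
  if (d_prime < 0 || d_prime > 1) {
    stop_input("d_prime must lie in [0, 1] (feasible bound for positive D: D_max = %g)",
               min(p_A * (1 - p_B), (1 - p_A) * p_B))
  }
  if (n < 1) stop_input("n must be >= 1")
  d_max <- min(p_A * (1 - p_B), (1 - p_A) * p_B)
  D <- d_prime * d_max
  hap <- c(AB = p_A * p_B + D,
           Ab = p_A * (1 - p_B) - D,
           aB = (1 - p_A) * p_B - D,
           ab = (1 - p_A) * (1 - p_B) + D)
  structure(list(p_A = p_A, p_B = p_B, d_prime = d_prime, n = n,
                 hap_freqs = hap),
            class = "two_locus_spec")
}

#' Generate unphased two-locus genotypes
#'
#' Individuals are formed by pairing two haplotypes drawn independently from
#' the spec's haplotype distribution; phase is then discarded.
#'
#' @param spec a [two_locus_spec()].
#' @param seed integer RNG seed.
#' @return data.frame with columns `id`, `locus1`, `locus2` (0/1/2 copies of
#'   the minor allele at each locus).
#' @export
generate_two_locus <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "two_locus_spec"))
  with_rng(seed, {
    # haplotypes coded by (copies of A, copies of B) in {0,1} each
    idx <- sample.int(4, 2 * spec$n, replace = TRUE, prob = spec$hap_freqs)
    a <- c(1, 1, 0, 0)[idx] # AB, Ab, aB, ab
    b <- c(1, 0, 1, 0)[idx]
    g1 <- a[seq_len(spec$n)] + a[spec$n + seq_len(spec$n)]
    g2 <- b[seq_len(spec$n)] + b[spec$n + seq_len(spec$n)]
    data.frame(id = sprintf("ind_%05d", seq_len(spec$n)),
               locus1 = g1, locus2 = g2, stringsAsFactors = FALSE)
  })
}
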