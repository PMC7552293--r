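# Per-breed genetic parameters of a biallelic locus: genotype and allele
# frequencies, MAF, and the Nei diversity panel Ho = sum(p_i^2),
# He = 1 - Ho, Ne = 1/Ho.

#' Locus statistics from genotype counts
#'
#' Allele frequencies are counted from the genotypes; homozygosity,
#' heterozygosity and the effective allele number use the expected
#' (allele-frequency based) definitions \eqn{Ho = p^2 + q^2},
#' \eqn{He = 1 - Ho}, \eqn{Ne = 1/Ho}.
#'
#' @param n_II,n_ID,n_DD genotype counts (wild-type homozygote,
#'   heterozygote, deletion homozygote).
#' @param breed optional breed label carried through to the output.
#' @return one-row data.frame: `breed`, `size`, `gf_wild`, `gf_del`
#'   (genotypic frequencies; deletion genotype = carriers), `af_wild`,
#'   `af_del`, `Ho`, `He`, `Ne`, `MAF`, at full precision.
#' @examples
#' locus_stats(894, 13, 0, breed = "TS") # af_del 0.00717, He 0.0142, Ne 1.014
#' @export
locus_stats <- function(n_II, n_ID, n_DD, breed = NA_character_) {
  counts <- c(n_II, n_ID, n_DD)
  if (any(counts < 0)) stop_input("genotype counts must be nonnegative")
  n <- sum(counts)
  if (n < 1) stop_input("need at least one genotyped individual")
  p_del <- (n_ID + 2 * n_DD) / (2 * n)
  p_wild <- 1 - p_del
  ho <- p_wild^2 + p_del^2
  data.frame(breed = breed,
             size = as.integer(n),
             gf_wild = n_II / n,
             gf_del = (n_ID + n_DD) / n,
             af_wild = p_wild,
             af_del = p_del,
             Ho = ho,
             He = 1 - ho,
             Ne = 1 / ho,
             MAF = min(p_del, p_wild),
             stringsAsFactors = FALSE)
}

#' Per-breed locus statistics from individual genotype records
#'
#' @param records data.frame with columns `breed` and `genotype`
#'   (0/1/2 copies of the deletion allele).
#' @param rounded if `TRUE` (default), report at 3 decimals (half-up), the
#'   conventional published precision; full precision otherwise.
#' @return data.frame with one [locus_stats()] row per breed, in order of
#'   first appearance.
#' @export
breed_table <- function(records, rounded = TRUE) {
  if (!all(c("breed", "genotype") %in% names(records))) {
    stop_input("records must have columns breed and genotype")
  }
  bad <- which(!(records$genotype %in% 0:2))
  if (length(bad)) {
    stop_input("unknown genotype code in record(s) %s",
               paste(utils::head(bad, 5), collapse = ", "))
  }
  breeds <- unique(records$breed)
  rows <- lapply(breeds, function(b) {
    g <- records$genotype[records$breed == b]
    locus_stats(sum(g == 0), sum(g == 1), sum(g == 2), breed = b)
  })
  out <- do.call(rbind, rows)
  if (rounded) {
    num <- setdiff(names(out), c("breed", "size"))
    out[num] <- lapply(out[num], round_half_up, digits = 3)
  }
  rownames(out) <- NULL
  out
}

#' Hardy-Weinberg exact test (optional diagnostic)
#'
#' Exact two-sided test for a biallelic locus, conditioning on the observed
#' allele counts and summing the probabilities of all heterozygote counts no
#' more probable than the observed one.
#'
#' @inheritParams locus_stats
#' @return list with `p_value` and the observed/expected heterozygote count.
#' @export
hwe_exact_test <- function(n_II, n_ID, n_DD) {
  n <- n_II + n_ID + n_DD
  n_del <- n_ID + 2 * n_DD # minor-allele copies (folding irrelevant by symmetry)
  if (n < 1) stop_input("empty sample")
  n_rare <- min(n_del, 2 * n - n_del)
  hets <- seq.int(n_rare %% 2, n_rare, by = 2)
  # P(n_ID = h | allele counts), Levene/Haldane conditional distribution
  logp <- lgamma(n + 1) - lgamma((n_rare - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma(n - (n_rare + hets) / 2 + 1) + hets * log(2) +
    lgamma(n_rare + 1) + lgamma(2 * n - n_rare + 1) - lgamma(2 * n + 1)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_ID, hets)]
  if (is.na(p_obs)) stop_input("inconsistent genotype counts")
  list(p_value = min(1, sum(pr[pr <= p_obs + 1e-12])),
       het_observed = n_ID,
       het_expected = n_rare * (2 * n - n_rare) / (2 * n - 1))
}
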