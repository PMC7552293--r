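# Shared fixtures built in code.

# Published per-breed genotype counts for the 8-bp deletion locus
# (wild-type homozygotes / heterozygotes; no deletion homozygote was
# observed in any breed).
breed_counts_fixture <- function() {
  data.frame(
    breed = c("TS", "LXBH", "STHS", "LFTS", "HS", "SS", "AUW"),
    n_II = c(894, 615, 187, 48, 201, 48, 326),
    n_ID = c(13, 14, 3, 1, 0, 0, 0),
    n_DD = 0L,
    stringsAsFactors = FALSE
  )
}

# Expand genotype counts into per-individual records.
records_from_counts <- function(counts) {
  do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    n <- c(counts$n_II[i], counts$n_ID[i], counts$n_DD[i])
    data.frame(breed = counts$breed[i],
               genotype = rep(0:2, times = n),
               stringsAsFactors = FALSE)
  }))
}

# Tiny Tan-sheep-like cohort for association tests: n_wild/n_del arm sizes
# per sex, continuous traits, optional carrier shift on one trait.
tan_like_traits <- function(n_wild = 449, n_del = 9, effect = 0, sd = 4.45,
                            seed = 1, noise_family = "skewed") {
  n <- n_wild + n_del
  pop <- data.frame(id = sprintf("t%04d", seq_len(n)),
                    breed = "TS", sex = "ram",
                    genotype = rep(c(0L, 1L), c(n_wild, n_del)))
  panel <- data.frame(trait = "BL", unit = "cm", location = 64.85, scale = sd)
  spec <- trait_spec(panel, genotype_effect = c(BL = effect),
                     noise_family = noise_family)
  generate_traits(pop, spec, seed = seed)
}
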