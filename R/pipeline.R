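# End-to-end workflow driver: pilot MAF -> design curve -> simulated
# two-stage screen -> per-breed locus statistics -> two-locus LD ->
# genotype-trait association. Outputs are a pure function of
# (config, seed); logs are line-oriented JSON without timestamps so that
# identical runs are byte-identical.

#' Default demo configuration
#'
#' A multi-breed cohort mirroring a seven-breed low-frequency-deletion
#' survey: breed sizes 907/629/190/49/201/48/326, deletion-allele
#' frequencies of 0.007-0.011 in four breeds and 0 in three, a 50-animal
#' pilot, pool sizes 3-20, a 276-animal two-locus LD subsample, and an
#' eight-trait association panel on the first breed with carrier effects on
#' body length, chest depth and chest width.
#'
#' @return nested configuration list (the same shape as a YAML config file).
#' @export
default_config <- function() {
  list(
    seed = 20200821,
    population = list(
      breed_sizes = list(TS = 907, LXBH = 629, STHS = 190, LFTS = 49,
                         HS = 201, SS = 48, AUW = 326),
      maf = list(TS = 0.007, LXBH = 0.011, STHS = 0.008, LFTS = 0.010,
                 HS = 0, SS = 0, AUW = 0),
      sex_counts = list(TS = c(458, 449))
    ),
    design = list(n_pilot = 50, a_min = 3, a_max = 20),
    ld = list(breed = "TS", n = 276, partner_maf = c(0.05, 0.08),
              d_prime = 0.3),
    association = list(breed = "TS",
                       genotype_effect = list(BL = -3.6, CD = -1.9, CW = 1.7),
                       noise_family = "skewed", alpha = 0.05)
  )
}

read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_config()
  # merge one level of stage sections, replacing their entries wholesale so
  # that a user-supplied breed list is not deep-merged into the default one
  for (k in names(config)) {
    if (is.list(base[[k]]) && is.list(config[[k]])) {
      for (k2 in names(config[[k]])) base[[k]][[k2]] <- config[[k]][[k2]]
    } else {
      base[[k]] <- config[[k]]
    }
  }
  base
}

#' Run the full pooled-screen analysis pipeline
#'
#' Stages: (1) generate the multi-breed population; (2) pilot-genotype a
#' random subsample and estimate the MAF; (3) compute the expected-reaction
#' design curve and pick the optimal pool size; (4) simulate the two-stage
#' pooled screen at that pool size; (5) per-breed locus statistics from the
#' called genotypes; (6) two-locus LD on a subsample against two synthetic
#' partner loci; (7) per-sex trait association. Any stage failure aborts
#' with the stage name; outputs written before the failure are preserved.
#'
#' @param config a config list, a YAML file path, or `NULL` for
#'   [default_config()].
#' @param out_dir output directory (created if needed).
#' @param seed overrides the config seed when given.
#' @return (invisibly) the output directory; writes `population.csv`,
#'   `curve.tsv`, `screen.json`, `table1.tsv`, `ld.tsv`, `table2.tsv`,
#'   `run.json` (stamps) and `log.jsonl`.
#' @export
run_pipeline <- function(config = NULL, out_dir = "sheeppool_run",
                         seed = NULL) {
  cfg <- read_config(if (is.null(config)) list() else config)
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.jsonl")
  if (file.exists(log_path)) file.remove(log_path)
  log_stage <- function(stage, ...) {
    rec <- c(list(stage = stage), list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
        sep = "", file = log_path, append = TRUE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      log_stage(stage, status = "failed", error = conditionMessage(e))
      stop_input("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
    })
  }
  seeds <- derive_seeds(cfg$seed, 6)

  # 1. population
  pop <- run_stage("population", {
    spec <- population_spec(unlist(cfg$population$breed_sizes),
                            unlist(cfg$population$maf),
                            cfg$population$sex_counts)
    p <- generate_population(spec, seed = seeds[1])
    write_genotype_csv(p, file.path(out_dir, "population.csv"))
    p
  })
  log_stage("population", status = "ok", n = nrow(pop),
            carriers = sum(pop$genotype > 0))

  # 2. pilot MAF
  pilot <- run_stage("pilot", {
    idx <- with_rng(seeds[2], sample(nrow(pop), cfg$design$n_pilot))
    g <- pop$genotype[idx]
    estimate_pilot_maf(c(sum(g == 0), sum(g == 1), sum(g == 2)))
  })
  # a monomorphic pilot cannot distinguish p = 0 from p < 1/(2 n_pilot);
  # the design uses the pilot's resolution as a floor
  p_design <- max(pilot$maf_hat, 1 / (2 * pilot$n_pilot))
  log_stage("pilot", status = "ok", n_pilot = pilot$n_pilot,
            maf_hat = pilot$maf_hat, p_design = p_design)

  # 3. design curve
  curve <- run_stage("design", {
    cv <- design_curve(nrow(pop), p_design, cfg$design$a_min, cfg$design$a_max)
    out <- as.data.frame(cv)
    out$n_expected <- round(out$n_expected, 1)
    write_tsv(out, file.path(out_dir, "curve.tsv"))
    cv
  })
  a_opt <- curve$a[curve$is_optimum]
  log_stage("design", status = "ok", a_optimum = a_opt,
            n_expected = round(curve$n_expected[curve$is_optimum], 1))

  # 4. simulated two-stage screen
  outcome <- run_stage("screen", {
    plan <- make_pools(pop$id, a_opt, seed = seeds[3])
    oc <- screen_pools(pop, plan)
    jsonlite::write_json(
      list(a = a_opt, pool_tests = oc$pool_tests, retests = oc$retests,
           total_reactions = oc$total_reactions,
           mixed_pools = oc$mixed_pools,
           pools = lapply(plan$assignments, as.character)),
      file.path(out_dir, "screen.json"), auto_unbox = TRUE, digits = NA)
    oc
  })
  log_stage("screen", status = "ok",
            total_reactions = outcome$total_reactions,
            calls_correct = all(outcome$genotype_calls[pop$id] == pop$genotype))

  # 5. per-breed locus statistics from the *called* genotypes
  tab1 <- run_stage("popgen", {
    called <- pop
    called$genotype <- unname(outcome$genotype_calls[pop$id])
    t1 <- breed_table(called)
    write_tsv(t1, file.path(out_dir, "table1.tsv"))
    t1
  })
  log_stage("popgen", status = "ok", breeds = nrow(tab1))

  # 6. two-locus LD on a subsample vs two synthetic partner loci
  ld_tab <- run_stage("ld", {
    sub <- pop[pop$breed == cfg$ld$breed, ][seq_len(cfg$ld$n), ]
    maf1 <- max(mean(sub$genotype) / 2, 1 / (2 * nrow(sub)))
    ld_seeds <- derive_seeds(seeds[4], length(cfg$ld$partner_maf))
    geno <- data.frame(id = sub$id, focal = sub$genotype)
    for (k in seq_along(cfg$ld$partner_maf)) {
      tl <- generate_two_locus(
        two_locus_spec(maf1, cfg$ld$partner_maf[k], cfg$ld$d_prime,
                       nrow(sub)),
        seed = ld_seeds[k])
      geno[[paste0("partner", k)]] <- tl$locus2
    }
    lt <- pairwise_ld(geno[, -1])
    write_tsv(lt, file.path(out_dir, "ld.tsv"))
    lt
  })
  log_stage("ld", status = "ok", pairs = nrow(ld_tab))

  # 7. trait association
  tab2 <- run_stage("association", {
    sub <- pop[pop$breed == cfg$association$breed, ]
    tspec <- trait_spec(
      genotype_effect = unlist(cfg$association$genotype_effect),
      noise_family = cfg$association$noise_family)
    traits <- generate_traits(sub, tspec, seed = seeds[5])
    t2 <- association_table(traits, alpha = cfg$association$alpha)
    write_tsv(t2, file.path(out_dir, "table2.tsv"))
    t2
  })
  log_stage("association", status = "ok", rows = nrow(tab2),
            significant = sum(tab2$significant))

  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(package = "sheeppool",
         version = as.character(utils::packageVersion("sheeppool")),
         seed = cfg$seed, config_hash = fnv1a32(cfg_json), config = cfg),
    file.path(out_dir, "run.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
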