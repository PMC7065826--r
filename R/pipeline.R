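#' Load and validate a pipeline run configuration
#'
#' The configuration is a structured key-value file (YAML) or an
#' equivalent list.  Top-level keys: `out_dir`, `seed` (master seed,
#' mandatory), `trait`, `simulate` (fields of [sim_config()]; QTLs as a
#' list of `{chromosome, position_cM, effect, segregating}`), `chain`
#' (fields of [mcmc_control()]), `priors` (fields of [scan_priors()]),
#' `permutation` (`n_perm`, `level`, `chain_shrink`), `cv` (`k`) and
#' `ideotype` (`p_min`, `n_genotypes`, `n_ideotypes`).  Every stage
#' derives its own seed as `seed + stage index`, so stages are
#' reproducible when rerun independently.
#'
#' @param config Path to a YAML file or a list.
#' @return Validated configuration list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config must set a master seed")
  if (is.null(config$out_dir)) stop("config must set out_dir")
  config$seed <- as.integer(config$seed)
  if (is.null(config$trait)) config$trait <- "trait"
  structure(config, class = "run_config")
}

# Fixed stage order; stage seed = master seed + position in this vector.
pipeline_stages <- c("simulate", "prep", "map", "scan", "permute", "call",
                     "cv", "ideotype")

stage_seed <- function(cfg, stage) {
  cfg$seed + match(stage, pipeline_stages)
}

artifact_path <- function(cfg, name) file.path(cfg$out_dir, name)

require_artifact <- function(cfg, name, stage) {
  p <- artifact_path(cfg, name)
  if (!file.exists(p)) {
    stop("missing artifact '", name, "': run stage '", stage, "' first")
  }
  p
}

config_sim <- function(cfg) {
  s <- cfg$simulate
  if (is.null(s)) s <- list()
  qtls <- lapply(s$qtls, function(q) {
    qtl_spec(q$chromosome, q$position_cM, q$effect, unlist(q$segregating))
  })
  args <- s[setdiff(names(s), "qtls")]
  if (!is.null(args$chromosomes)) args$chromosomes <- unlist(args$chromosomes)
  if (!is.null(args$env_effects)) args$env_effects <- unlist(args$env_effects)
  if (!is.null(args$family_means)) args$family_means <- unlist(args$family_means)
  args$qtls <- qtls
  args$seed <- stage_seed(cfg, "simulate")
  do.call(sim_config, args)
}

config_control <- function(cfg, stage) {
  args <- if (is.null(cfg$chain)) list() else cfg$chain
  args$seed <- stage_seed(cfg, stage)
  do.call(mcmc_control, args)
}

config_priors <- function(cfg) {
  do.call(scan_priors, if (is.null(cfg$priors)) list() else cfg$priors)
}

# Read the genotype/phenotype artifacts back and impute interval genotypes.
load_interval_genotypes <- function(cfg, stage) {
  gt <- read_genotypes(require_artifact(cfg, "genotypes.csv", "simulate"))
  grid <- interval_grid(gt$map)
  list(table = gt, grid = grid,
       genotypes = impute_interval_genotypes(gt, grid))
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages `simulate` (synthetic data), `prep`
#' (season adjustment), `map` (interval grid + imputation summary),
#' `scan` (Bayesian QTL scan), `permute` (intensity threshold), `call`
#' (QTL report + BED), `cv` (cross-validation) and `ideotype`
#' (region definition, ideotype ladder, genotype simulation,
#' prediction); `"all"` chains them in order.  Each stage writes its
#' artifacts under `out_dir` and a deterministic run manifest
#' (`manifest.yaml`) records seeds, settings and artifact checksums, so
#' two runs with equal configuration are byte-identical.
#'
#' @param config A [run_config()], list or YAML path.
#' @param stages Character vector of stages, or `"all"`.
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config, stages = "all") {
  cfg <- run_config(config)
  if (identical(stages, "all")) stages <- pipeline_stages
  unknown <- setdiff(stages, pipeline_stages)
  if (length(unknown)) stop("unknown stage: ", unknown[1])
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  arts <- list()

  for (stage in pipeline_stages[pipeline_stages %in% stages]) {
    if (stage == "simulate") {
      sc <- config_sim(cfg)
      dat <- simulate_dataset(sc, trait = cfg$trait)
      fam <- rep(names(dat$genotypes), vapply(dat$genotypes, ncol, integer(1)))
      geno <- do.call(cbind, dat$genotypes)
      names(fam) <- colnames(geno)
      gt <- genotype_table(dat$map, geno, fam)
      arts$genotypes <- write_genotypes(gt, artifact_path(cfg, "genotypes.csv"))
      arts$phenotypes <- write_phenotypes(dat$phenotypes,
                                          artifact_path(cfg, "phenotypes.csv"))
      arts$map <- write_map(dat$map, artifact_path(cfg, "map.csv"))
    } else if (stage == "prep") {
      ph <- read_phenotypes(require_artifact(cfg, "phenotypes.csv", "simulate"))
      adj <- adjust_for_environment(ph, cfg$trait)
      arts$adjusted <- write_adjusted(adj, artifact_path(cfg, "adjusted.csv"))
    } else if (stage == "map") {
      ig <- load_interval_genotypes(cfg, stage)
      utils::write.csv(as.data.frame(ig$grid),
                       artifact_path(cfg, "interval_grid.csv"),
                       row.names = FALSE, quote = FALSE)
      arts$grid <- artifact_path(cfg, "interval_grid.csv")
    } else if (stage == "scan") {
      adj <- read_adjusted(require_artifact(cfg, "adjusted.csv", "prep"))
      ig <- load_interval_genotypes(cfg, stage)
      scan <- mfqtl_scan(adj, ig$genotypes, priors = config_priors(cfg),
                         control = config_control(cfg, "scan"))
      arts$field <- write_posterior_field(scan$field,
                                          artifact_path(cfg, "posterior_field.tsv"))
      saveRDS(scan, artifact_path(cfg, "scan.rds"))
    } else if (stage == "permute") {
      adj <- read_adjusted(require_artifact(cfg, "adjusted.csv", "prep"))
      ig <- load_interval_genotypes(cfg, stage)
      pm <- cfg$permutation
      th <- permutation_threshold(
        adj, ig$genotypes,
        n_perm = if (is.null(pm$n_perm)) 100 else pm$n_perm,
        level = if (is.null(pm$level)) 0.05 else pm$level,
        priors = config_priors(cfg),
        control = config_control(cfg, "permute"),
        chain_shrink = if (is.null(pm$chain_shrink)) 4 else pm$chain_shrink)
      yaml::write_yaml(list(threshold = th$threshold, level = th$level,
                            n_perm = th$n_perm, chain_shrink = th$chain_shrink,
                            maxima = th$maxima),
                       artifact_path(cfg, "threshold.yaml"))
      arts$threshold <- artifact_path(cfg, "threshold.yaml")
    } else if (stage == "call") {
      scan <- readRDS(require_artifact(cfg, "scan.rds", "scan"))
      th <- yaml::read_yaml(require_artifact(cfg, "threshold.yaml", "permute"))
      report <- call_qtls(scan, th$threshold, trait = cfg$trait)
      arts$report <- write_qtl_report(report,
                                      artifact_path(cfg, "qtl_report.tsv"),
                                      families = scan$families)
    } else if (stage == "cv") {
      adj <- read_adjusted(require_artifact(cfg, "adjusted.csv", "prep"))
      ig <- load_interval_genotypes(cfg, stage)
      k <- if (is.null(cfg$cv$k)) 6 else cfg$cv$k
      cv <- crossvalidate(adj, ig$genotypes, k = k,
                          seed = stage_seed(cfg, "cv"),
                          priors = config_priors(cfg),
                          control = config_control(cfg, "cv"))
      tab <- data.frame(t(c(cv$fold_r, mean = cv$mean, sd = cv$sd)))
      names(tab) <- c(paste0("cv", seq_along(cv$fold_r)), "mean", "sd")
      tab <- data.frame(trait = cfg$trait, tab)
      utils::write.table(tab, artifact_path(cfg, "cv.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      arts$cv <- artifact_path(cfg, "cv.tsv")
    } else if (stage == "ideotype") {
      scan <- readRDS(require_artifact(cfg, "scan.rds", "scan"))
      io <- cfg$ideotype
      p_min <- if (is.null(io$p_min)) 0.01 else io$p_min
      n_g <- if (is.null(io$n_genotypes)) 500 else io$n_genotypes
      regions <- define_regions(scan, p_min = p_min)
      if (!nrow(regions)) {
        warning("no QTL regions above p_min; ideotype stage writes empty output")
        arts$ideotypes <- artifact_path(cfg, "ideotype_predictions.csv")
        utils::write.csv(data.frame(), arts$ideotypes, row.names = FALSE)
        next
      }
      regions$trait <- cfg$trait
      regions$favorable <- ifelse(regions$effect >= 0, "B", "A")
      regions$contribution <- vapply(regions$intervals, function(iv) {
        qtl_contribution(scan, iv)
      }, numeric(1))
      spec <- build_ideotypes(regions,
                              n_ideotypes = if (is.null(io$n_ideotypes)) 1 else io$n_ideotypes,
                              release_trait = cfg$trait, keep_trait = cfg$trait)
      gens <- lapply(seq_len(ncol(spec$genotype)), function(i) {
        generate_genotypes(spec, scan$grid, n = n_g,
                           seed = stage_seed(cfg, "ideotype") + i, ideotype = i)
      })
      names(gens) <- colnames(spec$genotype)
      preds <- predict_ideotype_phenotypes(gens, stats::setNames(list(scan), cfg$trait))
      arts$ideotypes <- artifact_path(cfg, "ideotype_predictions.csv")
      utils::write.csv(preds, arts$ideotypes, row.names = FALSE, quote = FALSE)
    }
  }

  files <- sort(setdiff(list.files(cfg$out_dir), c("manifest.yaml", "scan.rds")))
  manifest <- list(seed = cfg$seed, trait = cfg$trait,
                   stages = stages,
                   checksums = as.list(tools::md5sum(file.path(cfg$out_dir, files))))
  names(manifest$checksums) <- files
  yaml::write_yaml(manifest, artifact_path(cfg, "manifest.yaml"))
  invisible(arts)
}
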