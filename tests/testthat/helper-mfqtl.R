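# Build a complete small multifamily dataset (genotype table, interval
# grid, imputed genotypes, adjusted phenotypes) for tests.
make_dataset <- function(chromosomes = c(C1 = 100, C2 = 100, C3 = 100),
                         marker_spacing_cM = 5, qtls = list(),
                         n_families = 3, lines_per_family = 188,
                         resid_sd = 0.5, family_means = NULL,
                         env_effects = c(env1 = 0, env2 = 0),
                         missing_rate = 0, seed = 1, trait = "trait") {
  if (is.null(family_means)) family_means <- seq_len(n_families)
  cfg <- sim_config(n_families = n_families,
                    lines_per_family = lines_per_family,
                    chromosomes = chromosomes,
                    marker_spacing_cM = marker_spacing_cM, qtls = qtls,
                    env_effects = env_effects, resid_sd = resid_sd,
                    family_means = family_means,
                    missing_rate = missing_rate, seed = seed)
  dat <- simulate_dataset(cfg, trait = trait)
  fam <- rep(names(dat$genotypes), vapply(dat$genotypes, ncol, integer(1)))
  geno <- do.call(cbind, dat$genotypes)
  names(fam) <- colnames(geno)
  gt <- genotype_table(dat$map, geno, fam)
  grid <- interval_grid(gt$map)
  ig <- impute_interval_genotypes(gt, grid)
  adj <- adjust_for_environment(dat$phenotypes, trait)
  list(config = cfg, map = dat$map, table = gt, grid = grid, genotypes = ig,
       phenotypes = dat$phenotypes, adjusted = adj,
       genetic_values = dat$genetic_values)
}

# Minimal hand-built scan-like object for testing downstream operations
# (call_qtls, predict, regions) without running MCMC.
fake_scan <- function(field, y, u_soft, families = "F1",
                      family = NULL, mu = NULL) {
  if (is.null(family)) family <- rep(families[1], length(y))
  names(family) <- names(y)
  if (is.null(mu)) {
    mu <- matrix(rep(tapply(y, family, mean)[families], each = 2),
                 nrow = 2, dimnames = list(NULL, families))
  }
  grid <- data.frame(interval = field$interval, chromosome = field$chromosome,
                     start = field$mid - 0.5, end = field$mid + 0.5,
                     mid = field$mid)
  class(grid) <- c("interval_grid", "data.frame")
  intensity <- vapply(unique(field$chromosome), function(ch) {
    sum(field$p[field$chromosome == ch])
  }, numeric(1))
  structure(list(field = field, intensity = intensity,
                 samples = list(N = c(1, 1), mu = mu, sigma2 = c(1, 1)),
                 grid = grid, families = families,
                 data = list(y = y, family = family, u_soft = u_soft),
                 n_samples = 2),
            class = "mfqtl_scan")
}

# Posterior-field data frame skeleton on a single chromosome.
make_field <- function(p, chromosome = "C1", effect = 0, families = "F1",
                       seg = 1) {
  f <- data.frame(interval = seq_along(p), chromosome = chromosome,
                  mid = seq_along(p) - 0.5, p = p,
                  effect = rep_len(effect, length(p)),
                  stringsAsFactors = FALSE)
  for (fm in families) f[[paste0("seg_prob_", fm)]] <- rep_len(seg, length(p))
  class(f) <- c("posterior_field", "data.frame")
  f
}
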