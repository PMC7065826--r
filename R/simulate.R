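#' Specify a simulated QTL
#'
#' @param chromosome Chromosome name (must exist in the simulated map).
#' @param position_cM Position in cM.
#' @param effect Additive effect `a` of the common-parent allele, in trait
#'   units (DH lines are homozygous, so genotype values are `+a` or `-a`).
#' @param segregating Logical (or 0/1) vector, one entry per family: does
#'   this QTL segregate in that family?
#' @return An object of class `qtl_spec`.
#' @export
qtl_spec <- function(chromosome, position_cM, effect, segregating) {
  if (!is.finite(effect)) stop("QTL effect must be finite")
  if (position_cM < 0) stop("QTL position must be >= 0")
  segregating <- as.integer(as.logical(segregating))
  structure(list(chromosome = as.character(chromosome),
                 position_cM = position_cM, effect = effect,
                 segregating = segregating),
            class = "qtl_spec")
}

#' Default chromosome lengths for the simulated wheat genome
#'
#' The 21 hexaploid wheat chromosomes at joint-map scale (~3,950 cM
#' genome-wide), used as the simulator's default.
#'
#' @return Named numeric vector of lengths in cM.
#' @export
default_wheat_chromosomes <- function() {
  c(`1A` = 166.1, `2A` = 182.0, `3A` = 186.4, `4A` = 153.3, `5A` = 258.9,
    `6A` = 110.0, `7A` = 289.1, `1B` = 160.8, `2B` = 153.4, `3B` = 151.7,
    `4B` = 162.8, `5B` = 205.3, `6B` = 153.7, `7B` = 198.2, `1D` = 199.2,
    `2D` = 220.0, `3D` = 185.1, `4D` = 178.4, `5D` = 316.8, `6D` = 136.7,
    `7D` = 276.4)
}

#' Configure the multifamily DH simulator
#'
#' Defaults emulate the study system assumed throughout the package:
#' three DH families of 188 lines sharing one common parent, 21 wheat
#' chromosomes, markers every 5 cM (roughly 800 genome-wide), one
#' unreplicated plot per line and season, Gaussian residuals.
#'
#' @param n_families Number of DH families sharing the common parent.
#' @param lines_per_family Lines per family.
#' @param chromosomes Named numeric vector of chromosome lengths (cM).
#' @param marker_spacing_cM Regular marker spacing (cM), > 0.
#' @param qtls List of [qtl_spec()] objects (each `segregating` vector must
#'   have `n_families` entries, positions on declared chromosomes).
#' @param env_effects Named numeric vector of additive environment
#'   (cropping-season) shifts, trait units.
#' @param resid_sd Residual standard deviation, trait units.
#' @param family_means Numeric vector of family means, trait units.
#' @param missing_rate Fraction of phenotype records set missing, in `[0, 1)`.
#' @param seed Integer seed used by the simulation operations.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_families = 3, lines_per_family = 188,
                       chromosomes = default_wheat_chromosomes(),
                       marker_spacing_cM = 5, qtls = list(),
                       env_effects = c(env1 = 0, env2 = 0),
                       resid_sd = 1, family_means = rep(0, n_families),
                       missing_rate = 0, seed = 1L) {
  if (n_families < 1 || lines_per_family < 1) stop("need >= 1 family and >= 1 line")
  if (marker_spacing_cM <= 0) stop("marker spacing must be positive")
  if (any(chromosomes <= 0) || is.null(names(chromosomes))) {
    stop("chromosome lengths must be named and positive")
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (resid_sd < 0) stop("resid_sd must be >= 0")
  if (length(family_means) != n_families) stop("need one family mean per family")
  for (q in qtls) {
    if (!inherits(q, "qtl_spec")) stop("qtls must be a list of qtl_spec objects")
    if (!q$chromosome %in% names(chromosomes)) {
      stop("QTL on undeclared chromosome: ", q$chromosome)
    }
    if (q$position_cM > chromosomes[[q$chromosome]]) {
      stop("QTL position beyond chromosome end: ", q$chromosome)
    }
    if (length(q$segregating) != n_families) {
      stop("each QTL needs one segregation flag per family")
    }
  }
  structure(list(n_families = n_families, lines_per_family = lines_per_family,
                 chromosomes = chromosomes,
                 marker_spacing_cM = marker_spacing_cM, qtls = qtls,
                 env_effects = env_effects, resid_sd = resid_sd,
                 family_means = family_means, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a regular-spacing genetic map
#'
#' Places markers at regular spacing along each configured chromosome,
#' with synthetic physical (Mb) positions monotone in cM.
#'
#' @param config A [sim_config()].
#' @return A [as_genetic_map()] data frame.
#' @export
simulate_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sp <- config$marker_spacing_cM
  pieces <- lapply(names(config$chromosomes), function(chr) {
    len <- config$chromosomes[[chr]]
    pos <- seq(0, len, by = sp)
    if (pos[length(pos)] < len) pos <- c(pos, len)
    data.frame(marker = sprintf("%s_%07.2f", chr, pos), chromosome = chr,
               cM = pos, Mb = pos * 2, stringsAsFactors = FALSE)
  })
  as_genetic_map(do.call(rbind, pieces))
}

#' Simulate doubled haploid genotypes along a map
#'
#' Each DH line is one meiotic product of the F1, doubled: per chromosome
#' the first marker allele is Bernoulli(0.5) and a recombination occurs in
#' each marker gap independently (no interference) with probability given
#' by the inverse Kosambi function of the cM gap.  Codes are +1 for the
#' common-parent allele and -1 for the alternative allele.
#'
#' @param map A `genetic_map`.
#' @param n_lines Number of lines (> 0).
#' @param seed Integer seed, or NULL to use the current RNG state.
#' @param missing_rate Fraction of genotype calls set to NA.
#' @param line_prefix Prefix for generated line ids.
#' @return A markers x lines integer matrix (+1/-1/NA) with marker row
#'   names, carrying the map as attribute `"map"`.
#' @export
simulate_dh_genotypes <- function(map, n_lines, seed = NULL, missing_rate = 0,
                                  line_prefix = "L") {
  if (n_lines <= 0) stop("n_lines must be positive")
  if (!nrow(map)) stop("map has no markers")
  if (!is.null(seed)) set.seed(seed)
  chrs <- unique(map$chromosome)
  geno <- matrix(NA_integer_, nrow = nrow(map), ncol = n_lines,
                 dimnames = list(map$marker,
                                 sprintf("%s%04d", line_prefix, seq_len(n_lines))))
  for (chr in chrs) {
    idx <- which(map$chromosome == chr)
    pos <- map$cM[idx]
    first <- sample(c(1L, -1L), n_lines, replace = TRUE)
    if (length(idx) == 1L) {
      geno[idx, ] <- first
      next
    }
    r <- inverse_kosambi(diff(pos))
    # switch matrix: n_gaps x n_lines; allele_k = first * prod_{j<k}(1-2*sw_j)
    sw <- matrix(stats::rbinom(length(r) * n_lines, 1L, rep(r, n_lines)),
                 nrow = length(r))
    flip <- apply(1L - 2L * sw, 2, cumprod)
    flip <- matrix(flip, nrow = length(r))
    geno[idx, ] <- rbind(first, sweep(flip, 2, first, `*`))
  }
  storage.mode(geno) <- "integer"
  if (missing_rate > 0) {
    drop <- stats::runif(length(geno)) < missing_rate
    geno[drop] <- NA_integer_
  }
  attr(geno, "map") <- map
  geno
}

# Resolve each configured QTL to the nearest mapped marker on its chromosome.
resolve_qtl_markers <- function(map, qtls) {
  vapply(qtls, function(q) {
    idx <- which(map$chromosome == q$chromosome)
    if (!length(idx)) stop("no markers on chromosome ", q$chromosome)
    idx[which.min(abs(map$cM[idx] - q$position_cM))]
  }, integer(1))
}

#' Simulate multi-environment plot phenotypes for multifamily DH genotypes
#'
#' Per plot: `value = mu_i + sum_l s_il * u_ijl * a_l + env_effect +
#' N(0, resid_sd^2)`, where `u` is the line's genotype at the marker
#' nearest the QTL, and `s_il` switches the QTL off in families where it
#' does not segregate.  Missing observations are injected uniformly at
#' random at `config$missing_rate`.
#'
#' @param genotypes List of per-family genotype matrices (as produced by
#'   [simulate_dh_genotypes()], all on the same map), in family order.
#' @param config A [sim_config()].
#' @param environments Character vector of environment labels; each must be
#'   named in `config$env_effects`.
#' @param seed Integer seed, or NULL.
#' @param trait Trait label for the output records.
#' @return A long data frame `(line_id, family, environment, rep, trait,
#'   value)` with one plot per line x environment, plus the per-line true
#'   genetic values as attribute `"genetic_values"`.
#' @export
simulate_phenotypes <- function(genotypes, config, environments = names(config$env_effects),
                                seed = NULL, trait = "trait") {
  stopifnot(inherits(config, "sim_config"))
  if (!is.list(genotypes)) genotypes <- list(genotypes)
  if (length(genotypes) != config$n_families) {
    stop("need one genotype matrix per family")
  }
  unknown <- setdiff(environments, names(config$env_effects))
  if (length(unknown)) stop("unknown environment label: ", unknown[1])
  if (!is.null(seed)) set.seed(seed)
  map <- attr(genotypes[[1]], "map")
  qidx <- if (length(config$qtls)) resolve_qtl_markers(map, config$qtls) else integer(0)
  fams <- if (!is.null(names(genotypes))) names(genotypes) else
    sprintf("F%d", seq_along(genotypes))
  recs <- list(); gvals <- list()
  for (i in seq_along(genotypes)) {
    g <- genotypes[[i]]
    n <- ncol(g)
    gen <- rep(0, n)
    for (k in seq_along(qidx)) {
      q <- config$qtls[[k]]
      if (q$segregating[i] == 0L) next
      u <- g[qidx[k], ]
      u[is.na(u)] <- 0          # mean-impute the rare missing call
      gen <- gen + u * q$effect
    }
    gvals[[i]] <- data.frame(line_id = colnames(g), family = fams[i],
                             genetic_value = config$family_means[i] + gen,
                             stringsAsFactors = FALSE)
    for (env in environments) {
      val <- config$family_means[i] + gen + config$env_effects[[env]] +
        stats::rnorm(n, 0, config$resid_sd)
      recs[[length(recs) + 1L]] <- data.frame(
        line_id = colnames(g), family = fams[i], environment = env,
        rep = 1L, trait = trait, value = val, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  if (config$missing_rate > 0) {
    out$value[stats::runif(nrow(out)) < config$missing_rate] <- NA_real_
  }
  attr(out, "genetic_values") <- do.call(rbind, gvals)
  out
}

#' Simulate a complete multifamily DH dataset
#'
#' Convenience wrapper chaining [simulate_map()], per-family
#' [simulate_dh_genotypes()] and [simulate_phenotypes()] under one seed.
#'
#' @param config A [sim_config()].
#' @param trait Trait label.
#' @param genotype_missing_rate Fraction of genotype calls set missing.
#' @return List with `map`, `genotypes` (per-family list), `phenotypes`
#'   (long plot table) and `genetic_values`.
#' @export
simulate_dataset <- function(config, trait = "trait", genotype_missing_rate = 0) {
  map <- simulate_map(config)
  set.seed(config$seed)
  genotypes <- lapply(seq_len(config$n_families), function(i) {
    simulate_dh_genotypes(map, config$lines_per_family, seed = NULL,
                          missing_rate = genotype_missing_rate,
                          line_prefix = sprintf("F%d_", i))
  })
  names(genotypes) <- sprintf("F%d", seq_len(config$n_families))
  ph <- simulate_phenotypes(genotypes, config, seed = NULL, trait = trait)
  list(map = map, genotypes = genotypes, phenotypes = ph,
       genetic_values = attr(ph, "genetic_values"))
}
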