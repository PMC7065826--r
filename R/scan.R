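#' Priors for the multifamily Bayesian QTL model
#'
#' The phenotype model for line `j` of family `i` is
#' `y_ij = mu_i + sum_l s_il u_ijl a_l + e_ij`, with a variable number of
#' QTLs `N` on the 1-cM interval grid.  Priors: `N ~ Poisson(lambda)`
#' truncated at `n_max` (positions uniform over unoccupied intervals, at
#' most one QTL per interval); effects `a_l ~ N(0, sigma_a2)`;
#' segregation indicators `s_il ~ Bernoulli(pi_s)` independently;
#' `sigma_e^2` has the improper scale prior `1/sigma^2`.
#'
#' @param lambda Prior mean number of QTLs.
#' @param n_max Hard cap on the number of QTLs in the model.
#' @param sigma_a2 Prior effect variance; default (`NULL`) the phenotypic
#'   variance of the trait being scanned.
#' @param pi_s Prior segregation probability per family; `pi_s = 1`
#'   fixes every indicator at 1, reducing the model to standard Bayesian
#'   interval mapping over the pooled families.
#' @return List of class `scan_priors`.
#' @export
scan_priors <- function(lambda = 2, n_max = 20, sigma_a2 = NULL, pi_s = 0.5) {
  stopifnot(lambda > 0, n_max >= 1, pi_s > 0, pi_s <= 1)
  structure(list(lambda = lambda, n_max = n_max, sigma_a2 = sigma_a2,
                 pi_s = pi_s), class = "scan_priors")
}

#' MCMC chain settings
#'
#' @param iterations Total sweeps.
#' @param burn_in Discarded initial sweeps (must be < `iterations`).
#' @param thin Keep every `thin`-th post-burn-in sweep.
#' @param seed Integer seed (mandatory for reproducible runs).
#' @param genotype Which imputed interval genotype feeds the sampler:
#'   `"hard"` (maximum-probability call, the model's `u in {-1, +1}`) or
#'   `"soft"` (the expectation).
#' @return List of class `mcmc_control`.
#' @export
mcmc_control <- function(iterations = 20000, burn_in = 2000, thin = 10,
                         seed = 1L, genotype = c("hard", "soft")) {
  if (burn_in >= iterations) stop("burn_in must be smaller than iterations")
  if (thin < 1) stop("thin must be >= 1")
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), genotype = match.arg(genotype)),
            class = "mcmc_control")
}

# Birth-proposal probability at model size N (death is 1 - p).
birth_prob <- function(N, n_max) {
  if (N == 0L) 1 else if (N >= n_max) 0 else 0.5
}

#' Multifamily Bayesian QTL scan
#'
#' Fits the variable-dimension multifamily QTL model by MCMC over the
#' whole-genome 1-cM interval grid.  Each sweep performs Gibbs updates of
#' family means, QTL effects, per-family segregation indicators and the
#' residual variance; a reversible-jump birth/death move that proposes a
#' QTL in a uniformly chosen unoccupied interval (effect and segregation
#' drawn from their priors, so the acceptance ratio reduces to the
#' likelihood ratio times the model-size prior and proposal terms); and a
#' position move of a random QTL to a random unoccupied interval.  The
#' per-interval posterior probability of QTL existence `p_l` is the
#' relative frequency of retained samples in which interval `l` is
#' occupied.
#'
#' @param adjusted Adjusted phenotypes for one trait: a data frame
#'   `(line_id, family, value)` (see [adjust_for_environment()]) or a
#'   numeric vector named by line id (then `family` is taken from
#'   `genotypes`).
#' @param genotypes An [impute_interval_genotypes()] result on the grid to
#'   scan.
#' @param priors A [scan_priors()].
#' @param control An [mcmc_control()].
#' @return Object of class `mfqtl_scan`: list with `field` (per-interval
#'   posterior data frame: `interval, chromosome, mid, p, effect`,
#'   `seg_prob_<family>` columns), `intensity` (per-chromosome sums of
#'   `p`), `samples` (`N`, `mu`, `sigma2` draws), `grid`, `priors`,
#'   `control` and the training data.
#' @export
mfqtl_scan <- function(adjusted, genotypes, priors = scan_priors(),
                       control = mcmc_control()) {
  stopifnot(inherits(genotypes, "interval_genotypes"))
  if (is.data.frame(adjusted)) {
    y <- stats::setNames(adjusted$value, adjusted$line_id)
    fam <- stats::setNames(as.character(adjusted$family), adjusted$line_id)
  } else {
    y <- adjusted
    fam <- genotypes$family[names(y)]
  }
  if (any(!is.finite(y))) stop("adjusted phenotypes must be finite")
  ids <- intersect(names(y), rownames(genotypes$u))
  if (length(ids) < 3) stop("fewer than 3 lines shared by phenotypes and genotypes")
  y <- y[ids]; fam <- fam[ids]
  U <- if (control$genotype == "hard") genotypes$hard[ids, , drop = FALSE]
       else genotypes$u[ids, , drop = FALSE]
  grid <- genotypes$grid
  m <- nrow(grid)
  fams <- unique(fam)
  nf <- length(fams)
  fi <- match(fam, fams)
  n <- length(y)
  fam_rows <- lapply(seq_len(nf), function(i) which(fi == i))
  n_i <- lengths(fam_rows)

  sigma_a2 <- if (is.null(priors$sigma_a2)) stats::var(y) else priors$sigma_a2
  lambda <- priors$lambda; n_max <- min(priors$n_max, m); pi_s <- priors$pi_s
  logit_pi <- if (pi_s >= 1) Inf else log(pi_s / (1 - pi_s))

  set.seed(control$seed)
  # initial state: empty model
  occ <- integer(0); a <- numeric(0); s <- matrix(0L, nf, 0)
  mu <- vapply(fam_rows, function(rw) mean(y[rw]), numeric(1))
  sig2 <- stats::var(y)
  if (!is.finite(sig2) || sig2 <= 0) sig2 <- 1
  r <- y - mu[fi]

  qtl_col <- function(k) s[fi, k] * U[, occ[k]] * a[k]

  n_keep <- (control$iterations - control$burn_in) %/% control$thin
  occ_count <- numeric(m); a_sum <- numeric(m)
  seg_sum <- matrix(0, nf, m)
  N_draw <- integer(n_keep); sig2_draw <- numeric(n_keep)
  mu_draw <- matrix(NA_real_, n_keep, nf, dimnames = list(NULL, fams))
  kept <- 0L

  for (it in seq_len(control$iterations)) {
    ## family means
    rf <- r + mu[fi]
    for (i in seq_len(nf)) {
      rw <- fam_rows[[i]]
      mu[i] <- stats::rnorm(1, mean(rf[rw]), sqrt(sig2 / n_i[i]))
    }
    r <- rf - mu[fi]

    ## per-QTL updates: segregation indicators, then effect
    N <- length(occ)
    if (N > 0) for (k in sample.int(N)) {
      r <- r + qtl_col(k)                       # residual without QTL k
      uk <- U[, occ[k]]
      for (i in seq_len(nf)) {
        rw <- fam_rows[[i]]
        d1 <- r[rw] - uk[rw] * a[k]
        logit <- logit_pi + 0.5 / sig2 * (sum(r[rw]^2) - sum(d1^2))
        s[i, k] <- as.integer(stats::runif(1) < stats::plogis(logit))
      }
      x <- s[fi, k] * uk
      xx <- sum(x^2)
      if (xx == 0) {
        a[k] <- stats::rnorm(1, 0, sqrt(sigma_a2))
      } else {
        v <- 1 / (xx / sig2 + 1 / sigma_a2)
        a[k] <- stats::rnorm(1, v * sum(x * r) / sig2, sqrt(v))
      }
      r <- r - x * a[k]
    }

    ## residual variance (improper 1/sigma^2 prior)
    sig2 <- sum(r^2) / stats::rchisq(1, df = n)

    ## reversible-jump birth / death
    N <- length(occ)
    pb <- birth_prob(N, n_max)
    if (stats::runif(1) < pb) {                 # birth
      free <- if (N) setdiff(seq_len(m), occ) else seq_len(m)
      l_new <- free[sample.int(length(free), 1)]
      a_new <- stats::rnorm(1, 0, sqrt(sigma_a2))
      s_new <- as.integer(stats::runif(nf) < pi_s)
      w <- s_new[fi] * U[, l_new] * a_new
      logA <- -0.5 / sig2 * (sum((r - w)^2) - sum(r^2)) +
        log(lambda) - log(N + 1) +
        log(1 - birth_prob(N + 1L, n_max)) - log(pb)
      if (log(stats::runif(1)) < logA) {
        occ <- c(occ, l_new); a <- c(a, a_new); s <- cbind(s, s_new)
        r <- r - w
      }
    } else if (N > 0) {                         # death
      k <- sample.int(N, 1)
      w <- qtl_col(k)
      logA <- -0.5 / sig2 * (sum((r + w)^2) - sum(r^2)) +
        log(N) - log(lambda) +
        log(birth_prob(N - 1L, n_max)) - log(1 - pb)
      if (log(stats::runif(1)) < logA) {
        occ <- occ[-k]; a <- a[-k]; s <- s[, -k, drop = FALSE]
        r <- r + w
      }
    }

    ## position moves
    N <- length(occ)
    if (N > 0) for (k in sample.int(N)) {
      free <- setdiff(seq_len(m), occ)
      if (!length(free)) break
      l_new <- free[sample.int(length(free), 1)]
      w_old <- qtl_col(k)
      w_new <- s[fi, k] * U[, l_new] * a[k]
      r_new <- r + w_old - w_new
      logA <- -0.5 / sig2 * (sum(r_new^2) - sum(r^2))
      if (log(stats::runif(1)) < logA) {
        occ[k] <- l_new
        r <- r_new
      }
    }

    ## record
    if (it > control$burn_in && (it - control$burn_in) %% control$thin == 0 &&
        kept < n_keep) {
      kept <- kept + 1L
      if (length(occ)) {
        occ_count[occ] <- occ_count[occ] + 1
        a_sum[occ] <- a_sum[occ] + a
        seg_sum[, occ] <- seg_sum[, occ] + s
      }
      N_draw[kept] <- length(occ)
      sig2_draw[kept] <- sig2
      mu_draw[kept, ] <- mu
    }
  }

  p <- occ_count / kept
  eff <- ifelse(occ_count > 0, a_sum / pmax(occ_count, 1), 0)
  seg <- sweep(seg_sum, 2, pmax(occ_count, 1), `/`)
  field <- data.frame(interval = grid$interval, chromosome = grid$chromosome,
                      mid = grid$mid, p = p, effect = eff,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nf)) field[[paste0("seg_prob_", fams[i])]] <- seg[i, ]
  class(field) <- c("posterior_field", "data.frame")
  intensity <- vapply(unique(grid$chromosome), function(chr) {
    sum(p[grid$chromosome == chr])
  }, numeric(1))

  structure(list(field = field, intensity = intensity,
                 samples = list(N = N_draw, mu = mu_draw, sigma2 = sig2_draw),
                 grid = grid, priors = priors, control = control,
                 families = fams,
                 data = list(y = y, family = fam, u_soft = genotypes$u[ids, , drop = FALSE]),
                 sigma_a2 = sigma_a2, n_samples = kept,
                 call = match.call()),
            class = "mfqtl_scan")
}

#' QTL intensity of a chromosome
#'
#' The sum of per-interval posterior probabilities of QTL existence over a
#' chromosome: the expected number of QTLs residing there.
#'
#' @param field A `posterior_field` (or an `mfqtl_scan`).
#' @param chromosome Chromosome name.
#' @return Numeric intensity.
#' @export
qtl_intensity <- function(field, chromosome) {
  if (inherits(field, "mfqtl_scan")) field <- field$field
  if (!chromosome %in% field$chromosome) stop("unknown chromosome: ", chromosome)
  sum(field$p[field$chromosome == chromosome])
}

#' Genome-wide intensity threshold from permutation maxima
#'
#' Returns the `ceiling(level * n)`-th highest of the recorded maxima
#' (the 5th highest of 100 at the 5% level).
#'
#' @param maxima Per-permutation maximum chromosome intensities.
#' @param level Genome-wide significance level.
#' @return The threshold value.
#' @export
threshold_from_maxima <- function(maxima, level = 0.05) {
  n <- length(maxima)
  if (level * n < 1) stop("level * n_perm must be >= 1")
  k <- ceiling(level * n)
  sort(maxima, decreasing = TRUE)[k]
}

#' Permutation threshold for QTL intensity
#'
#' Shuffles adjusted phenotypes across lines within each family (so the
#' family means are preserved under the no-QTL null), reruns the scan for
#' each permutation, and takes the `ceiling(level * n_perm)`-th highest
#' maximum chromosome intensity as the genome-wide threshold.
#'
#' @inheritParams mfqtl_scan
#' @param n_perm Number of permutations (>= 20).
#' @param level Genome-wide significance level.
#' @param chain_shrink Divisor applied to `iterations`/`burn_in` for the
#'   permutation reruns (full-length chains for every permutation dominate
#'   runtime; shrunken chains are flagged in the result).
#' @return List of class `permutation_threshold`: `threshold`, `maxima`,
#'   `level`, `n_perm`, `chain_shrink`.
#' @export
permutation_threshold <- function(adjusted, genotypes, n_perm = 100,
                                  level = 0.05, priors = scan_priors(),
                                  control = mcmc_control(),
                                  chain_shrink = 4) {
  if (n_perm < 20) stop("n_perm must be >= 20")
  if (level * n_perm < 1) stop("level * n_perm must be >= 1")
  if (is.data.frame(adjusted)) {
    y <- stats::setNames(adjusted$value, adjusted$line_id)
    fam <- stats::setNames(as.character(adjusted$family), adjusted$line_id)
  } else {
    y <- adjusted
    fam <- genotypes$family[names(y)]
  }
  sub <- mcmc_control(iterations = max(200L, control$iterations %/% chain_shrink),
                      burn_in = max(50L, control$burn_in %/% chain_shrink),
                      thin = control$thin, seed = control$seed,
                      genotype = control$genotype)
  set.seed(control$seed)
  perm_seeds <- sample.int(.Machine$integer.max, n_perm)
  maxima <- vapply(seq_len(n_perm), function(b) {
    set.seed(perm_seeds[b])
    yp <- y
    for (f in unique(fam)) {
      idx <- which(fam == f)
      yp[idx] <- y[idx][sample.int(length(idx))]
    }
    ctl <- sub; ctl$seed <- perm_seeds[b]
    sc <- mfqtl_scan(yp, genotypes, priors = priors, control = ctl)
    max(sc$intensity)
  }, numeric(1))
  structure(list(threshold = threshold_from_maxima(maxima, level),
                 maxima = maxima, level = level, n_perm = n_perm,
                 chain_shrink = chain_shrink),
            class = "permutation_threshold")
}

#' @export
print.permutation_threshold <- function(x, ...) {
  cat(sprintf("Permutation threshold (%d permutations, %.0f%% level): %.4g\n",
              x$n_perm, 100 * x$level, x$threshold))
  if (x$chain_shrink != 1) {
    cat("  (permutation chains shortened by factor", x$chain_shrink, ")\n")
  }
  invisible(x)
}

# Weighted summaries of a posterior field over a set of interval rows.
region_summary <- function(field, rows, fams, vary, var_u) {
  p <- field$p[rows]
  W <- sum(p)
  segcols <- paste0("seg_prob_", fams)
  seg <- vapply(segcols, function(cl) sum(p * field[[cl]][rows]) / W, numeric(1))
  sbar <- rowMeans(as.matrix(field[rows, segcols, drop = FALSE]))
  contr <- sum(p * sbar * field$effect[rows]^2 * var_u[rows]) / vary
  list(position = sum(p * field$mid[rows]) / W,
       effect = sum(p * field$effect[rows]) / W,
       intensity = W, seg = seg, contribution = contr)
}

#' Call significant QTLs from a scan
#'
#' A chromosome carries a QTL when its intensity exceeds the threshold;
#' when the intensity exceeds twice the threshold, two QTLs are assumed
#' and the chromosome is split at the interior interval of minimum
#' posterior probability such that the summed probabilities on each side
#' still exceed the threshold (falling back to a single QTL, with a
#' warning, if no such boundary exists).  Per region, position and effect
#' are posterior-probability-weighted averages, segregation probabilities
#' are occupancy-weighted per-family frequencies, and the contribution is
#' the region's share of phenotypic variance (see [qtl_contribution()]).
#'
#' @param scan An [mfqtl_scan()] result.
#' @param threshold Positive intensity threshold (see
#'   [permutation_threshold()]).
#' @param trait Trait label for the report.
#' @return Data frame of class `qtl_report` (possibly zero rows).
#' @export
call_qtls <- function(scan, threshold, trait = "trait") {
  stopifnot(inherits(scan, "mfqtl_scan"), threshold > 0)
  field <- scan$field
  fams <- scan$families
  vary <- stats::var(scan$data$y)
  var_u <- apply(scan$data$u_soft, 2, stats::var)
  rows_out <- list()
  for (chr in unique(field$chromosome)) {
    rows <- which(field$chromosome == chr)
    W <- sum(field$p[rows])
    if (W <= threshold) next
    groups <- list(rows)
    if (W > 2 * threshold && length(rows) > 2) {
      p <- field$p[rows]
      csum <- cumsum(p)
      interior <- 2:(length(rows) - 1)
      ok <- interior[csum[interior - 1] > threshold &
                     (W - csum[interior]) > threshold]
      if (length(ok)) {
        j <- ok[which.min(p[ok])]
        groups <- list(rows[seq_len(j - 1)], rows[(j + 1):length(rows)])
      } else {
        warning("chromosome ", chr, ": intensity > 2x threshold but no valid ",
                "boundary; reporting a single QTL")
      }
    }
    for (g in groups) {
      # summaries are taken over the contiguous p > 0.01 region containing
      # the posterior mode, so diffuse low-probability occupancy elsewhere
      # on the chromosome does not dilute position/effect estimates
      sub <- field[g, , drop = FALSE]
      rg <- define_regions(sub, p_min = 0.01)
      core <- g
      if (nrow(rg)) {
        peak <- sub$interval[which.max(sub$p)]
        hit <- vapply(rg$intervals, function(iv) peak %in% iv, logical(1))
        if (any(hit)) {
          core <- g[match(rg$intervals[[which(hit)[1]]], sub$interval)]
        }
      }
      sm <- region_summary(field, core, fams, vary, var_u)
      rec <- data.frame(trait = trait, chromosome = chr,
                        position_cM = sm$position,
                        intensity = sum(field$p[g]),
                        stringsAsFactors = FALSE)
      for (i in seq_along(fams)) rec[[paste0("seg_prob_", fams[i])]] <- sm$seg[i]
      rec$contribution <- sm$contribution
      rec$effect <- sm$effect
      rec$start_cM <- field$mid[core[1]] - 0.5
      rec$end_cM <- field$mid[core[length(core)]] + 0.5
      rows_out[[length(rows_out) + 1L]] <- rec
    }
  }
  rep_df <- if (length(rows_out)) do.call(rbind, rows_out) else
    data.frame(trait = character(0), chromosome = character(0),
               position_cM = numeric(0), intensity = numeric(0),
               contribution = numeric(0), effect = numeric(0))
  rownames(rep_df) <- NULL
  class(rep_df) <- c("qtl_report", "data.frame")
  attr(rep_df, "threshold") <- threshold
  rep_df
}

#' Fraction of phenotypic variance attributed to a QTL region
#'
#' Defined here as
#' `sum over the region of p_l * sbar_l * effect_l^2 * Var(u_l)` divided
#' by the variance of the adjusted phenotype, where `sbar_l` is the
#' across-family mean segregation frequency and `Var(u_l)` the empirical
#' variance of the interval genotype.  This is this package's explicit
#' operational definition of a QTL's "contribution".
#'
#' @param scan An [mfqtl_scan()].
#' @param intervals Genome-wide interval indices of the region.
#' @return The contribution (fraction).
#' @export
qtl_contribution <- function(scan, intervals) {
  stopifnot(inherits(scan, "mfqtl_scan"))
  vary <- stats::var(scan$data$y)
  if (vary == 0) stop("zero phenotypic variance")
  var_u <- apply(scan$data$u_soft, 2, stats::var)
  rows <- match(intervals, scan$field$interval)
  sm <- region_summary(scan$field, rows, scan$families, vary, var_u)
  sm$contribution
}
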