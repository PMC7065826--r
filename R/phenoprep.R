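#' Remove cropping-season (environment) effects from plot phenotypes
#'
#' Fits the additive two-way least-squares model
#' `value = line + environment` (no interaction) jointly over all lines,
#' with a sum-to-zero constraint on environment effects, subtracts the
#' estimated environment effect from every plot value, and averages the
#' corrected values over each line's observations.
#'
#' @param plots Long plot table `(line_id, family, environment, rep,
#'   trait, value)`.
#' @param trait Trait to adjust (must be present in `plots`).
#' @param per_family Adjust each family separately instead of jointly
#'   (default FALSE: one joint fit across all lines).
#' @return Data frame `(line_id, family, trait, value)` of class
#'   `adjusted_phenotypes`, one row per line, with the estimated
#'   environment effects as attribute `"env_effects"`.
#' @export
adjust_for_environment <- function(plots, trait, per_family = FALSE) {
  if (!trait %in% plots$trait) stop("trait not present in plot table: ", trait)
  d <- plots[plots$trait == trait & !is.na(plots$value), , drop = FALSE]
  all_lines <- unique(plots$line_id[plots$trait == trait])
  lost <- setdiff(all_lines, d$line_id)
  if (length(lost)) {
    warning(length(lost), " line(s) with zero observations excluded")
  }
  if (!nrow(d)) stop("no observed values for trait ", trait)

  adjust_block <- function(d) {
    envs <- sort(unique(d$environment))
    if (length(envs) == 1L) {
      eff <- stats::setNames(0, envs)
    } else {
      env <- factor(d$environment, levels = envs)
      line <- factor(d$line_id)
      X <- stats::model.matrix(~ 0 + line)
      E <- stats::model.matrix(~ env, contrasts.arg = list(env = "contr.sum"))[, -1, drop = FALSE]
      fit <- stats::lm.fit(cbind(X, E), d$value)
      ecf <- fit$coefficients[(ncol(X) + 1):(ncol(X) + ncol(E))]
      ecf[is.na(ecf)] <- 0
      eff <- stats::setNames(c(ecf, -sum(ecf)), envs)
    }
    corrected <- d$value - eff[d$environment]
    val <- tapply(corrected, d$line_id, mean)
    fam <- d$family[!duplicated(d$line_id)]
    names(fam) <- d$line_id[!duplicated(d$line_id)]
    out <- data.frame(line_id = names(val), family = unname(fam[names(val)]),
                      trait = trait, value = as.numeric(val),
                      stringsAsFactors = FALSE)
    attr(out, "env_effects") <- eff
    out
  }

  if (per_family) {
    parts <- lapply(split(d, d$family), adjust_block)
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    attr(out, "env_effects") <- lapply(parts, attr, "env_effects")
  } else {
    out <- adjust_block(d)
  }
  class(out) <- c("adjusted_phenotypes", "data.frame")
  out
}

#' Realized kinship from marker genotypes
#'
#' `K = W W' / m` with `W` the lines x markers matrix coded +1/-1 and `m`
#' the number of markers; missing codes are mean-imputed per marker, and
#' all-missing markers are dropped with a warning.  For fully genotyped
#' inbred lines the diagonal equals 1.
#'
#' @param genotypes A [genotype_table()] or a markers x lines code matrix.
#' @return Symmetric lines x lines relatedness matrix.
#' @export
realized_kinship <- function(genotypes) {
  g <- if (inherits(genotypes, "genotype_table")) genotypes$geno else genotypes
  if (is.null(dim(g)) || ncol(g) < 2 || nrow(g) < 1) {
    stop("need >= 2 lines and >= 1 marker")
  }
  W <- t(g)                                   # lines x markers
  all_na <- colSums(!is.na(W)) == 0
  if (any(all_na)) {
    warning("dropping ", sum(all_na), " all-missing marker(s)")
    W <- W[, !all_na, drop = FALSE]
  }
  if (!ncol(W)) stop("no scored markers left")
  mu <- colMeans(W, na.rm = TRUE)
  idx <- which(is.na(W), arr.ind = TRUE)
  if (nrow(idx)) W[idx] <- mu[idx[, 2]]
  K <- tcrossprod(W) / ncol(W)
  (K + t(K)) / 2
}

# REML profile log-likelihood machinery for y = Xb + g + e with
# g ~ N(0, va*K) on lines and e ~ N(0, ve*I) on observations.
# Observations map to lines through Z; V = ve * (lambda * ZKZ' + I).
reml_profile <- function(y, M_eig, x, lambda) {
  d <- M_eig$values
  yt <- crossprod(M_eig$vectors, y)
  xt <- crossprod(M_eig$vectors, x)
  n <- length(y)
  vapply(lambda, function(l) {
    w <- l * d + 1
    xx <- sum(xt^2 / w)
    b <- sum(xt * yt / w) / xx
    S <- sum((yt - xt * b)^2 / w)
    ve <- S / (n - 1)
    -0.5 * ((n - 1) * log(ve) + sum(log(w)) + log(xx) + (n - 1))
  }, numeric(1))
}

#' Marker-based heritability by REML
#'
#' Fits the single-genetic-variance-component mixed model
#' `y = mu + g + e`, `g ~ N(0, va K)`, `e ~ N(0, ve I)`, by REML using one
#' eigendecomposition of the (observation-level) relatedness matrix, and
#' reports `h2 = va / (va + ve)` with a 95% profile-likelihood interval.
#' `values` may be line-level (one record per line) or plot-level with
#' replicates; in the latter case pass the line of each observation in
#' `lines`.
#'
#' @param values Numeric phenotype vector.  If `lines` is NULL its names
#'   must be line ids present in `kinship`.
#' @param kinship Positive semi-definite relatedness matrix with line ids
#'   as dimnames (see [realized_kinship()]).
#' @param lines Optional character vector, same length as `values`,
#'   giving the line of each observation.
#' @param psd_tol Tolerance on negative kinship eigenvalues.
#' @return List of class `heritability_estimate` with `va`, `ve`, `h2`,
#'   `conf_int` (95%), `lambda` and `n`.
#' @export
marker_heritability <- function(values, kinship, lines = NULL, psd_tol = 1e-6) {
  if (is.null(lines)) lines <- names(values)
  if (is.null(lines)) stop("values must be named by line id, or supply `lines`")
  keep <- !is.na(values) & lines %in% rownames(kinship)
  values <- values[keep]; lines <- lines[keep]
  if (length(unique(lines)) < 3) stop("need >= 3 lines")
  K <- kinship[unique(lines), unique(lines)]
  ek <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ek) < -psd_tol * max(abs(ek))) {
    stop("kinship matrix is not positive semi-definite")
  }
  Z <- outer(lines, unique(lines), `==`) * 1
  M <- Z %*% K %*% t(Z)
  M_eig <- eigen((M + t(M)) / 2, symmetric = TRUE)
  x <- rep(1, length(values))

  h2_grid <- seq(1e-4, 1 - 1e-4, length.out = 501)
  lam_grid <- h2_grid / (1 - h2_grid)
  ll <- reml_profile(values, M_eig, x, lam_grid)
  i0 <- which.max(ll)
  opt <- stats::optimize(function(h) {
    reml_profile(values, M_eig, x, h / (1 - h))
  }, lower = h2_grid[max(1, i0 - 1)], upper = h2_grid[min(length(h2_grid), i0 + 1)],
  maximum = TRUE, tol = 1e-8)
  h2 <- opt$maximum
  llmax <- opt$objective
  lambda <- h2 / (1 - h2)

  d <- M_eig$values
  yt <- crossprod(M_eig$vectors, values)
  xt <- crossprod(M_eig$vectors, x)
  w <- lambda * d + 1
  xx <- sum(xt^2 / w)
  b <- sum(xt * yt / w) / xx
  ve <- sum((yt - xt * b)^2 / w) / (length(values) - 1)
  va <- lambda * ve

  cut <- llmax - stats::qchisq(0.95, 1) / 2
  inside <- h2_grid[ll >= cut]
  conf_int <- if (length(inside)) {
    c(max(0, min(inside, h2)), min(1, max(inside, h2)))
  } else c(h2, h2)

  structure(list(va = va, ve = ve, h2 = h2, conf_int = conf_int,
                 lambda = lambda, mean = b, n = length(values),
                 n_lines = length(unique(lines))),
            class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("Marker-based heritability: h2 = %.3f (95%% CI %.3f - %.3f)\n",
              x$h2, x$conf_int[1], x$conf_int[2]))
  cat(sprintf("  va = %.4g, ve = %.4g, %d observations on %d lines\n",
              x$va, x$ve, x$n, x$n_lines))
  invisible(x)
}

#' Pairwise trait correlations with significance tests
#'
#' Pearson correlations on pairwise-complete observations with two-sided
#' t-test p-values; a Holm-adjusted p matrix is reported alongside the raw
#' one, and the significance flag uses the raw p at the requested level.
#'
#' @param adjusted Adjusted phenotype data frame `(line_id, family, trait,
#'   value)` covering >= 2 traits.
#' @param traits Traits to include (default: all present).
#' @param families `"all"` (default) or a subset of family labels.
#' @param level Significance level for the flag matrix.
#' @return List of class `trait_correlations` with matrices `r`, `p`,
#'   `p_holm`, `n`, `significant`.
#' @export
trait_correlations <- function(adjusted, traits = NULL, families = "all",
                               level = 0.05) {
  d <- adjusted
  if (!identical(families, "all")) d <- d[d$family %in% families, , drop = FALSE]
  if (is.null(traits)) traits <- unique(d$trait)
  if (length(traits) < 2) stop("need >= 2 traits")
  wide <- stats::reshape(d[d$trait %in% traits, c("line_id", "trait", "value")],
                         idvar = "line_id", timevar = "trait", direction = "wide")
  colnames(wide) <- sub("^value\\.", "", colnames(wide))
  wide <- wide[, c("line_id", traits), drop = FALSE]
  k <- length(traits)
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      x <- wide[[traits[i]]]; y <- wide[[traits[j]]]
      ok <- !is.na(x) & !is.na(y)
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      if (sum(ok) < 3) stop("fewer than 3 complete pairs for ",
                            traits[i], " vs ", traits[j])
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        warning("constant trait in pair ", traits[i], " vs ", traits[j],
                "; correlation undefined")
        next
      }
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  up <- upper.tri(p)
  ph <- p
  ph[up] <- stats::p.adjust(p[up], method = "holm")
  ph[lower.tri(ph)] <- t(ph)[lower.tri(ph)]
  structure(list(r = r, p = p, p_holm = ph, n = nmat,
                 significant = p < level),
            class = "trait_correlations")
}

#' @export
print.trait_correlations <- function(x, digits = 3, ...) {
  cat("Pearson trait correlations (pairwise complete):\n")
  print(round(x$r, digits))
  invisible(x)
}
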