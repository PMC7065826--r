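#' @export
print.mfqtl_scan <- function(x, ...) {
  cat("Multifamily Bayesian QTL scan\n")
  cat(sprintf("  %d lines in %d families, %d intervals on %d chromosomes\n",
              length(x$data$y), length(x$families), nrow(x$grid),
              length(unique(x$grid$chromosome))))
  cat(sprintf("  %d retained samples; posterior mean N = %.2f, sigma_e^2 = %.3g\n",
              x$n_samples, mean(x$samples$N), mean(x$samples$sigma2)))
  top <- sort(x$intensity, decreasing = TRUE)
  top <- top[top > 0.05]
  if (length(top)) {
    cat("  Leading chromosome intensities:\n")
    print(round(utils::head(top, 8), 3))
  }
  invisible(x)
}

#' Summarize a multifamily QTL scan
#'
#' @param object An [mfqtl_scan()] result.
#' @param threshold Optional intensity threshold; when given, significant
#'   QTLs are called with [call_qtls()].
#' @param trait Trait label for the call table.
#' @param ... Unused.
#' @return A `summary.mfqtl_scan` list: posterior means of `N`,
#'   `sigma_e^2` and family means, the per-chromosome intensity table,
#'   and (when a threshold was given) the QTL report.
#' @export
summary.mfqtl_scan <- function(object, threshold = NULL, trait = "trait", ...) {
  out <- list(
    n_qtl = mean(object$samples$N),
    sigma2 = mean(object$samples$sigma2),
    family_means = colMeans(object$samples$mu),
    intensity = object$intensity,
    threshold = threshold,
    calls = if (!is.null(threshold)) call_qtls(object, threshold, trait = trait)
  )
  class(out) <- "summary.mfqtl_scan"
  out
}

#' @export
print.summary.mfqtl_scan <- function(x, ...) {
  cat(sprintf("Posterior mean number of QTLs: %.2f; residual variance: %.3g\n",
              x$n_qtl, x$sigma2))
  cat("Family means:\n"); print(round(x$family_means, 3))
  cat("Chromosome QTL intensities:\n")
  print(round(x$intensity, 3))
  if (!is.null(x$calls)) {
    cat(sprintf("QTLs called at threshold %.3g:\n", x$threshold))
    print(x$calls)
  }
  invisible(x)
}

#' Extract the prediction-model coefficients of a scan
#'
#' @param object An [mfqtl_scan()].
#' @param ... Unused.
#' @return List with `family_means` (posterior means), `grand_mean`
#'   (size-weighted), and `effects`: the per-interval
#'   posterior-probability-weighted marker effects `p_l * a_hat_l` used by
#'   the prediction equation.
#' @export
coef.mfqtl_scan <- function(object, ...) {
  mu <- colMeans(object$samples$mu)
  n_i <- table(object$data$family)[names(mu)]
  list(family_means = mu,
       grand_mean = sum(mu * as.numeric(n_i)) / sum(n_i),
       effects = stats::setNames(object$field$p * object$field$effect,
                                 object$field$interval))
}

#' Predict phenotypes from a fitted scan
#'
#' The posterior-weighted prediction
#' `yhat_i = mu_hat + sum_l p_l u_il a_hat_l`, using the family-specific
#' intercept when a line's family is known (and matches a training
#' family) and the grand mean otherwise.  Expected (soft) interval
#' genotypes are used.
#'
#' @param object An [mfqtl_scan()].
#' @param newdata An [impute_interval_genotypes()] object on the same
#'   grid, or a lines x m matrix of interval genotype expectations;
#'   default: the training lines.
#' @param family Optional per-line family labels (named or positional);
#'   taken from `newdata` when it is an `interval_genotypes`.
#' @param use_family_means Use family-specific intercepts where known
#'   (default TRUE; FALSE forces the grand mean).
#' @param ... Unused.
#' @return Named numeric vector of predicted trait values.
#' @export
predict.mfqtl_scan <- function(object, newdata = NULL, family = NULL,
                               use_family_means = TRUE, ...) {
  if (is.null(newdata)) {
    Unew <- object$data$u_soft
    if (is.null(family)) family <- object$data$family
  } else if (inherits(newdata, "interval_genotypes")) {
    Unew <- newdata$u
    if (is.null(family)) family <- newdata$family
  } else {
    Unew <- as.matrix(newdata)
  }
  if (ncol(Unew) != nrow(object$grid)) {
    stop("interval grid mismatch: model has ", nrow(object$grid),
         " intervals, newdata has ", ncol(Unew))
  }
  cf <- coef.mfqtl_scan(object)
  icpt <- rep(cf$grand_mean, nrow(Unew))
  if (use_family_means && !is.null(family)) {
    known <- family %in% names(cf$family_means)
    icpt[known] <- cf$family_means[family[known]]
  }
  drop(icpt + Unew %*% cf$effects)
}

#' @export
fitted.mfqtl_scan <- function(object, ...) {
  predict.mfqtl_scan(object)
}

#' @export
residuals.mfqtl_scan <- function(object, ...) {
  object$data$y - fitted.mfqtl_scan(object)
}

#' Simulate phenotypes from the posterior predictive of a fitted scan
#'
#' Draws `fitted + N(0, posterior mean sigma_e^2)` vectors for the
#' training lines.
#'
#' @param object An [mfqtl_scan()].
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns.
#' @export
simulate.mfqtl_scan <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted.mfqtl_scan(object)
  sd <- sqrt(mean(object$samples$sigma2))
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0, sd)))
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- names(mu)
  out
}

#' Plot the posterior QTL-probability profile of a scan
#'
#' Per-interval posterior probabilities along the genome, chromosomes
#' concatenated and separated by vertical lines; an optional intensity
#' threshold is not drawn (intensity is a per-chromosome sum, not a
#' per-interval quantity) but chromosome intensities are printed along
#' the top axis when `annotate = TRUE`.
#'
#' @param x An [mfqtl_scan()].
#' @param annotate Print per-chromosome intensities above the panel.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mfqtl_scan <- function(x, annotate = TRUE, ...) {
  f <- x$field
  chrs <- unique(f$chromosome)
  offs <- c(0, cumsum(vapply(chrs, function(ch) max(f$mid[f$chromosome == ch]) + 5,
                             numeric(1))))
  xs <- f$mid + offs[match(f$chromosome, chrs)]
  graphics::plot(xs, f$p, type = "h", xlab = "genome position (cM, concatenated)",
                 ylab = "posterior QTL probability", ylim = c(0, max(f$p, 0.1)),
                 ...)
  graphics::abline(v = offs[-1] - 2.5, col = "grey70", lty = 3)
  if (annotate) {
    mids <- (offs[-length(offs)] + offs[-1]) / 2
    graphics::mtext(sprintf("%s\n%.2f", chrs, x$intensity[chrs]), side = 3,
                    at = mids, cex = 0.5, line = 0.2)
  }
  invisible(x)
}
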