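#' Random k-fold partition of lines
#'
#' Shuffles the ids under the given seed and deals them into `k`
#' near-equal groups (sizes differ by at most one); every id lands in
#' exactly one validation fold.
#'
#' @param ids Character vector of line ids.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold assignments (1..k) named by id.
#' @export
cv_partition <- function(ids, k, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  if (k > length(ids)) stop("more folds than lines")
  set.seed(seed)
  shuffled <- sample(ids)
  fold <- rep(seq_len(k), length.out = length(ids))
  fold <- sort(fold)                       # near-equal block sizes
  stats::setNames(fold, shuffled)[ids]
}

#' k-fold cross-validation of the posterior-weighted prediction model
#'
#' For each fold, refits the Bayesian scan on the remaining folds and
#' predicts the held-out lines with [predict.mfqtl_scan()]; reports the
#' per-fold Pearson correlation between predicted and observed adjusted
#' values, with mean and SD.
#'
#' @inheritParams mfqtl_scan
#' @param k Number of folds (default 6).
#' @param seed Seed for the partition (per-fold chains derive their seeds
#'   from `control$seed`).
#' @return List of class `mfqtl_cv`: `fold_r`, `mean`, `sd`, `folds`
#'   (assignments), `predictions` (data frame with observed and predicted
#'   values per line).
#' @export
crossvalidate <- function(adjusted, genotypes, k = 6, seed = 1L,
                          priors = scan_priors(), control = mcmc_control()) {
  if (is.data.frame(adjusted)) {
    y <- stats::setNames(adjusted$value, adjusted$line_id)
    fam <- stats::setNames(as.character(adjusted$family), adjusted$line_id)
  } else {
    y <- adjusted
    fam <- genotypes$family[names(y)]
  }
  ids <- intersect(names(y), rownames(genotypes$u))
  y <- y[ids]; fam <- fam[ids]
  folds <- cv_partition(ids, k, seed = seed)
  if (min(table(folds)) < 3) stop("a fold has fewer than 3 lines")
  preds <- rep(NA_real_, length(ids)); names(preds) <- ids
  fold_r <- numeric(k)
  for (f in seq_len(k)) {
    test <- ids[folds == f]
    train <- ids[folds != f]
    ctl <- control; ctl$seed <- control$seed + f
    sc <- mfqtl_scan(y[train], genotypes, priors = priors, control = ctl)
    ph <- predict.mfqtl_scan(sc, newdata = genotypes$u[test, , drop = FALSE],
                             family = fam[test])
    preds[test] <- ph
    fold_r[f] <- stats::cor(ph, y[test])
  }
  structure(list(fold_r = fold_r, mean = mean(fold_r), sd = stats::sd(fold_r),
                 folds = folds,
                 predictions = data.frame(line_id = ids, family = fam,
                                          observed = unname(y),
                                          predicted = unname(preds),
                                          fold = unname(folds),
                                          stringsAsFactors = FALSE)),
            class = "mfqtl_cv")
}

#' @export
print.mfqtl_cv <- function(x, ...) {
  cat("k-fold cross-validated prediction accuracy (Pearson r):\n")
  print(round(stats::setNames(x$fold_r, paste0("cv", seq_along(x$fold_r))), 3))
  cat(sprintf("mean = %.3f, SD = %.3f\n", x$mean, x$sd))
  invisible(x)
}
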