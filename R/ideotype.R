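#' Define QTL regions from a posterior field
#'
#' A QTL region is a maximal run of 1-cM intervals with posterior
#' probability above `p_min`, extended by absorbing any run of
#' sub-threshold intervals that is flanked on both sides (within the same
#' chromosome) by such runs; absorption merges the flanking runs into one
#' region.
#'
#' @param field A `posterior_field` (or [mfqtl_scan()]).
#' @param p_min Probability threshold (default 0.01).
#' @return Data frame of class `qtl_regions` with columns `region`,
#'   `chromosome`, `start_cM`, `end_cM`, `p_mass`, `effect` (probability-
#'   weighted mean) and a list column `intervals` of member interval
#'   indices.
#' @export
define_regions <- function(field, p_min = 0.01) {
  if (inherits(field, "mfqtl_scan")) field <- field$field
  out <- list()
  for (chr in unique(field$chromosome)) {
    rows <- which(field$chromosome == chr)
    above <- field$p[rows] > p_min
    if (!any(above)) next
    rl <- rle(above)
    ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1
    # absorb interior FALSE runs (flanked by TRUE runs on both sides)
    keep <- rl$values
    interior_gap <- which(!rl$values & seq_along(rl$values) > 1 &
                          seq_along(rl$values) < length(rl$values))
    keep[interior_gap] <- TRUE
    # merge consecutive kept runs into regions
    reg_id <- 0
    i <- 1
    while (i <= length(rl$values)) {
      if (!keep[i]) { i <- i + 1; next }
      j <- i
      while (j + 1 <= length(rl$values) && keep[j + 1]) j <- j + 1
      reg_id <- reg_id + 1
      iv <- rows[starts[i]:ends[j]]
      p <- field$p[iv]
      out[[length(out) + 1L]] <- data.frame(
        chromosome = chr,
        start_cM = field$mid[iv[1]] - 0.5,
        end_cM = field$mid[iv[length(iv)]] + 0.5,
        p_mass = sum(p),
        effect = if (sum(p) > 0) sum(p * field$effect[iv]) / sum(p) else 0,
        stringsAsFactors = FALSE)
      out[[length(out)]]$intervals <- I(list(field$interval[iv]))
      i <- j + 1
    }
  }
  if (!length(out)) {
    res <- data.frame(region = integer(0), chromosome = character(0),
                      start_cM = numeric(0), end_cM = numeric(0),
                      p_mass = numeric(0), effect = numeric(0))
    res$intervals <- I(list())
  } else {
    res <- do.call(rbind, out)
    res <- data.frame(region = seq_len(nrow(res)), res, stringsAsFactors = FALSE)
    rownames(res) <- NULL
  }
  class(res) <- c("qtl_regions", "data.frame")
  res
}

#' Build a ladder of ideotypes over fixed QTL regions
#'
#' Ideotype 1 fixes the favorable allele in every region.  Ideotypes
#' `2..n` successively unconstrain the regions that carry only the
#' release trait (by default the flour-a*-type trait), in ascending order
#' of their contribution; regions carrying the keep trait (flour-yield
#' type) stay fixed in every ideotype.  Ties in contribution break by
#' region order.
#'
#' @param regions Data frame with one row per region and columns
#'   `region`, `chromosome`, `start_cM`, `end_cM`, `trait`
#'   (`;`-separated when a region carries QTLs of several traits),
#'   `favorable` (`"A"` donor allele / `"B"` common-parent allele) and
#'   `contribution`.
#' @param n_ideotypes Number of ideotypes (at most 1 + number of
#'   releasable regions).
#' @param release_trait Trait whose single-trait regions are released.
#' @param keep_trait Trait whose regions are never released.
#' @return Object of class `ideotype_spec`: list with `regions` and
#'   `genotype`, a regions x ideotypes character matrix over
#'   `{"A", "B", "-"}`.
#' @export
build_ideotypes <- function(regions, n_ideotypes = NULL,
                            release_trait = "Fla", keep_trait = "FlYd") {
  req <- c("region", "trait", "favorable", "contribution")
  if (!all(req %in% names(regions))) {
    stop("regions need columns: ", paste(req, collapse = ", "))
  }
  traits <- strsplit(as.character(regions$trait), ";")
  has_keep <- vapply(traits, function(t) keep_trait %in% trimws(t), logical(1))
  has_rel <- vapply(traits, function(t) release_trait %in% trimws(t), logical(1))
  releasable <- which(has_rel & !has_keep)
  if (is.null(n_ideotypes)) n_ideotypes <- 1 + length(releasable)
  if (n_ideotypes > 1 + length(releasable)) {
    stop("n_ideotypes may not exceed 1 + number of releasable regions (",
         1 + length(releasable), ")")
  }
  ord <- releasable[order(regions$contribution[releasable], releasable)]
  geno <- matrix(regions$favorable, nrow = nrow(regions), ncol = n_ideotypes,
                 dimnames = list(regions$region,
                                 paste0("ideotype_", seq_len(n_ideotypes))))
  for (t in seq_len(n_ideotypes)[-1]) {
    released <- ord[seq_len(t - 1)]
    geno[released, t] <- "-"
  }
  structure(list(regions = regions, genotype = geno,
                 release_order = regions$region[ord]),
            class = "ideotype_spec")
}

#' @export
print.ideotype_spec <- function(x, ...) {
  cat("Ideotype ladder:", ncol(x$genotype), "ideotypes over",
      nrow(x$regions), "QTL regions\n")
  print(cbind(x$regions[, c("region", "chromosome", "trait")], x$genotype))
  invisible(x)
}

# Fixed-interval vector (length m; NA = unconstrained, +1 = B, -1 = A) for
# one column of an ideotype ladder on a grid.
ideotype_fixed_vector <- function(spec, ideotype, grid) {
  stopifnot(inherits(spec, "ideotype_spec"))
  g <- spec$genotype[, ideotype]
  fixed <- rep(NA_real_, nrow(grid))
  for (i in seq_len(nrow(spec$regions))) {
    if (g[i] == "-") next
    rg <- spec$regions[i, ]
    rows <- which(grid$chromosome == rg$chromosome &
                  grid$mid >= rg$start_cM & grid$mid <= rg$end_cM)
    val <- if (g[i] == "B") 1 else -1
    if (any(!is.na(fixed[rows]) & fixed[rows] != val)) {
      stop("overlapping fixed regions with conflicting alleles")
    }
    fixed[rows] <- val
  }
  fixed
}

#' Generate random genotypes consistent with fixed regions
#'
#' Samples whole-genome interval genotypes from the no-interference
#' Markov chain along each chromosome (per-gap recombination fractions
#' from the inverse Kosambi function of interval midpoint spacing),
#' conditioned exactly on all fixed intervals by backward-filtering /
#' forward-sampling (a Markov bridge between consecutive fixed blocks;
#' chromosomes without fixed intervals start from Bernoulli(0.5)).  Fixed
#' intervals match the requested allele in every sample; inside a fixed
#' block no recombination occurs.
#'
#' @param fixed Numeric vector, one entry per grid interval: `+1` (fix
#'   common-parent allele B), `-1` (fix donor allele A) or `NA` (free).
#'   Alternatively an [build_ideotypes()] spec together with `ideotype`.
#' @param grid The [interval_grid()].
#' @param n Number of genotypes.
#' @param seed Integer seed.
#' @param ideotype Column of the ideotype spec to use when `fixed` is an
#'   `ideotype_spec`.
#' @return An n x m matrix of interval genotypes in -1/+1.
#' @export
generate_genotypes <- function(fixed, grid, n, seed = NULL, ideotype = 1) {
  if (inherits(fixed, "ideotype_spec")) {
    fixed <- ideotype_fixed_vector(fixed, ideotype, grid)
  }
  stopifnot(length(fixed) == nrow(grid), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(NA_real_, nrow = n, ncol = nrow(grid))
  for (chr in unique(grid$chromosome)) {
    gi <- which(grid$chromosome == chr)
    J <- length(gi)
    fx <- fixed[gi]
    r <- if (J > 1) inverse_kosambi(diff(grid$mid[gi])) else numeric(0)
    # backward pass: next fixed index and phase-retention product to it
    nf <- rep(NA_integer_, J); C <- rep(NA_real_, J)
    for (t in J:1) {
      if (!is.na(fx[t])) { nf[t] <- t; C[t] <- 1 }
      else if (t < J && !is.na(nf[t + 1])) {
        nf[t] <- nf[t + 1]; C[t] <- (1 - 2 * r[t]) * C[t + 1]
      }
    }
    x <- matrix(NA_real_, n, J)
    for (t in seq_len(J)) {
      if (!is.na(fx[t])) {
        if (t > 1) {
          # feasibility: transition from previous state must be possible
          p_tr <- ifelse(x[, t - 1] == fx[t], 1 - r[t - 1], r[t - 1])
          if (any(p_tr == 0)) {
            stop("infeasible fixed blocks: opposite alleles with zero ",
                 "recombination on chromosome ", chr)
          }
        }
        x[, t] <- fx[t]
        next
      }
      # forward weight from previous interval (0.5/0.5 at chromosome start)
      if (t == 1) {
        wp <- rep(0.5, n); wm <- rep(0.5, n)
      } else {
        wp <- ifelse(x[, t - 1] == 1, 1 - r[t - 1], r[t - 1])
        wm <- 1 - wp
      }
      # backward weight to the next fixed interval, if any
      if (!is.na(nf[t])) {
        v <- fx[nf[t]]
        wp <- wp * (1 + v * C[t]) / 2
        wm <- wm * (1 - v * C[t]) / 2
      }
      tot <- wp + wm
      if (any(tot == 0)) {
        stop("infeasible fixed blocks: opposite alleles with zero ",
             "recombination on chromosome ", chr)
      }
      x[, t] <- ifelse(stats::runif(n) < wp / tot, 1, -1)
    }
    X[, gi] <- x
  }
  rownames(X) <- sprintf("g%04d", seq_len(n))
  X
}

#' Predict phenotypes of simulated ideotype genotypes
#'
#' Applies the posterior-weighted prediction equation of one fitted scan
#' per trait to every generated genotype, and appends the common parent's
#' own predicted values (the all-B genotype) as a reference row per
#' ideotype.
#'
#' @param genotypes A named list of genotype matrices (one per ideotype,
#'   from [generate_genotypes()]), or a single matrix.
#' @param models Named list of [mfqtl_scan()] fits (or objects accepted by
#'   [predict.mfqtl_scan()]), one per trait, all on the same grid.
#' @param reference Append the all-common-parent genotype (default TRUE).
#' @return Long data frame `(ideotype, genotype_id, trait, value)`.
#' @export
predict_ideotype_phenotypes <- function(genotypes, models, reference = TRUE) {
  if (!is.list(genotypes)) genotypes <- list(ideotype_1 = genotypes)
  if (is.null(names(models))) stop("models must be a named list (one per trait)")
  m <- nrow(models[[1]]$grid)
  out <- list()
  for (ideo in names(genotypes)) {
    G <- genotypes[[ideo]]
    if (ncol(G) != m) stop("interval grid mismatch for ideotype ", ideo)
    if (reference) {
      G <- rbind(G, common_parent = rep(1, m))
    }
    for (tr in names(models)) {
      ph <- predict.mfqtl_scan(models[[tr]], newdata = G,
                               use_family_means = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        ideotype = ideo, genotype_id = rownames(G), trait = tr,
        value = unname(ph), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
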