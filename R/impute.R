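# Conditional probability that a DH line carries the common-parent allele
# at a locus between flanking codes gL, gR, given recombination fractions
# rL, rR to the locus (two-step Markov chain, no interference).
dh_flank_prob <- function(gL, gR, rL, rR) {
  rLR <- rf_compose(rL, rR)
  num <- ifelse(gL == 1, 1 - rL, rL) * ifelse(gR == 1, 1 - rR, rR)
  den <- ifelse(gL == gR, 1 - rLR, rLR)
  num / den
}

#' Impute per-interval genotypes for every line
#'
#' For each 1-cM interval midpoint, computes the expected coded genotype
#' `u in [-1, 1]` given the line's nearest scored flanking markers via the
#' no-interference Markov chain (`u = 2 P(Q) - 1`); beyond the terminal
#' scored marker the single-flank rule `u = g (1 - 2 r)` applies.  An
#' interval containing a scored marker takes that marker's observed code.
#' Lines with no scored marker on a chromosome get `u = 0` on all its
#' intervals (with a warning): such lines carry no information there.
#'
#' @param table A [genotype_table()].
#' @param grid An [interval_grid()] covering the table's chromosomes.
#' @return Object of class `interval_genotypes`: list with `u` (lines x m
#'   expected codes), `hard` (lines x m calls in -1/+1, ties to +1),
#'   `grid`, `family` (named per-line).
#' @export
impute_interval_genotypes <- function(table, grid) {
  stopifnot(inherits(table, "genotype_table"), inherits(grid, "interval_grid"))
  m <- nrow(grid)
  lines <- colnames(table$geno)
  u <- matrix(0, nrow = length(lines), ncol = m,
              dimnames = list(lines, paste0("iv", grid$interval)))
  map <- table$map
  warned <- FALSE
  for (chr in unique(grid$chromosome)) {
    gi <- which(grid$chromosome == chr)
    mids <- grid$mid[gi]
    starts <- grid$start[gi]
    mk <- which(map$chromosome == chr)
    pos_all <- map$cM[mk]
    for (j in seq_along(lines)) {
      codes <- table$geno[mk, j]
      sc <- !is.na(codes)
      if (!any(sc)) { warned <- TRUE; next }      # u stays 0
      p <- pos_all[sc]; g <- codes[sc]
      iL <- findInterval(mids, p)
      iR <- iL + 1L
      has_L <- iL >= 1L
      has_R <- iR <= length(p)
      uu <- numeric(length(mids))
      b <- has_L & has_R
      if (any(b)) {
        rL <- inverse_kosambi(mids[b] - p[iL[b]])
        rR <- inverse_kosambi(p[iR[b]] - mids[b])
        uu[b] <- 2 * dh_flank_prob(g[iL[b]], g[iR[b]], rL, rR) - 1
      }
      b <- has_L & !has_R
      if (any(b)) {
        uu[b] <- g[iL[b]] * (1 - 2 * inverse_kosambi(mids[b] - p[iL[b]]))
      }
      b <- !has_L & has_R
      if (any(b)) {
        uu[b] <- g[iR[b]] * (1 - 2 * inverse_kosambi(p[iR[b]] - mids[b]))
      }
      # intervals containing a scored marker take the observed code
      mk_int <- findInterval(p, starts)
      for (t in seq_along(p)) {
        ii <- mk_int[t]
        if (ii >= 1 && ii <= length(mids)) {
          prev <- abs(mids[ii] - p[mk_int == ii])
          if (abs(mids[ii] - p[t]) == min(prev)) uu[ii] <- g[t]
        }
      }
      u[j, gi] <- uu
    }
  }
  if (warned) warning("some line(s) had no scored marker on a chromosome; ",
                      "their intervals there were set to 0")
  hard <- ifelse(u >= 0, 1, -1)
  structure(list(u = u, hard = hard, grid = grid,
                 family = table$family[lines]),
            class = "interval_genotypes")
}

#' @export
print.interval_genotypes <- function(x, ...) {
  cat("Imputed interval genotypes:", nrow(x$u), "lines x", ncol(x$u),
      "intervals on", length(unique(x$grid$chromosome)), "chromosomes\n")
  invisible(x)
}
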