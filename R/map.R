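#' Construct or validate a genetic map table
#'
#' A genetic map is a data frame with one row per marker and columns
#' `marker`, `chromosome`, `cM` and (optionally) `Mb`.  Markers must be
#' unique and cM positions non-decreasing within each chromosome after
#' sorting.
#'
#' @param x A data frame with at least columns `marker`, `chromosome`, `cM`.
#' @return A validated, chromosome/cM-sorted data frame of class
#'   `c("genetic_map", "data.frame")`.
#' @export
as_genetic_map <- function(x) {
  x <- as.data.frame(x)
  req <- c("marker", "chromosome", "cM")
  if (!all(req %in% names(x))) {
    stop("a genetic map needs columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(x$marker)) {
    dup <- x$marker[duplicated(x$marker)][1]
    stop("duplicate marker id: ", dup)
  }
  if (any(!is.finite(x$cM)) || any(x$cM < 0)) stop("cM positions must be finite and >= 0")
  x$chromosome <- as.character(x$chromosome)
  chrs <- unique(x$chromosome)
  x <- x[order(match(x$chromosome, chrs), x$cM), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("genetic_map", "data.frame")
  x
}

#' Lay out a whole-genome grid of 1-cM intervals
#'
#' Partitions each chromosome into contiguous half-open intervals
#' `[start, end)` of the requested width (default 1 cM), anchored at 0 cM;
#' the final interval on a chromosome may be shorter.  The grid carries a
#' genome-wide interval index `l = 1..m` concatenating chromosomes in the
#' order given.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in cM,
#'   or a `genetic_map` (lengths taken as the last marker position per
#'   chromosome).
#' @param width Interval width in cM (default 1).
#' @return A data frame of class `interval_grid` with columns
#'   `interval`, `chromosome`, `start`, `end`, `mid`.
#' @export
interval_grid <- function(chrom_lengths, width = 1) {
  if (inherits(chrom_lengths, "genetic_map") || is.data.frame(chrom_lengths)) {
    map <- chrom_lengths
    chrom_lengths <- tapply(map$cM, factor(map$chromosome, unique(map$chromosome)), max)
    chrom_lengths <- stats::setNames(as.numeric(chrom_lengths),
                                     names(chrom_lengths))
  }
  if (width <= 0) stop("interval width must be positive")
  if (is.null(names(chrom_lengths)) || any(chrom_lengths <= 0)) {
    stop("chromosome lengths must be named and positive")
  }
  pieces <- lapply(names(chrom_lengths), function(chr) {
    len <- chrom_lengths[[chr]]
    starts <- seq(0, len, by = width)
    if (starts[length(starts)] >= len) starts <- starts[-length(starts)]
    ends <- pmin(starts + width, len)
    data.frame(chromosome = chr, start = starts, end = ends,
               mid = (starts + ends) / 2, stringsAsFactors = FALSE)
  })
  g <- do.call(rbind, pieces)
  g <- data.frame(interval = seq_len(nrow(g)), g, stringsAsFactors = FALSE)
  attr(g, "chrom_lengths") <- chrom_lengths
  class(g) <- c("interval_grid", "data.frame")
  g
}

#' Estimate the recombination fraction between two markers in DH lines
#'
#' For doubled haploids each line is a single (doubled) gamete, so the
#' recombination fraction between two markers is simply the fraction of
#' jointly scored lines with discordant parental codes.
#'
#' @param col_a,col_b Genotype codes (+1/-1, NA allowed) for the two
#'   markers across the same lines.
#' @return The estimate, with attributes `n` (lines jointly scored) and
#'   `unlinked` (TRUE when the estimate exceeds 0.5).
#' @export
estimate_rf_dh <- function(col_a, col_b) {
  keep <- !is.na(col_a) & !is.na(col_b)
  n <- sum(keep)
  if (n == 0L) stop("no lines jointly scored at both markers")
  rec <- sum(col_a[keep] != col_b[keep])
  r <- rec / n
  attr(r, "n") <- n
  attr(r, "recombinants") <- rec
  attr(r, "unlinked") <- r > 0.5
  r
}

#' Recalculate a joint genetic map across DH families from physical order
#'
#' Markers are ordered by physical (Mb) position per chromosome; for each
#' adjacent pair, per-family recombinant and informative line counts are
#' pooled (count-weighted, the maximum-likelihood estimate under a shared
#' recombination fraction) over the families in which both markers
#' segregate, and pooled fractions are accumulated into cM with the
#' Kosambi function.
#'
#' @param genotypes List of per-family genotype matrices (markers x lines,
#'   codes +1/-1/NA) whose row names are marker ids.  A family missing a
#'   marker simply contributes nothing at gaps involving it.
#' @param physical Data frame with columns `marker`, `chromosome`, `Mb`
#'   defining the physical order.
#' @param max_rf Cap applied to a pooled adjacent fraction at or above 0.5
#'   (with a warning); default 0.49.
#' @return A `genetic_map` with recalculated `cM` and the input `Mb`.
#' @export
build_joint_map <- function(genotypes, physical, max_rf = 0.49) {
  if (!is.list(genotypes) || !length(genotypes)) stop("need >= 1 family genotype matrix")
  req <- c("marker", "chromosome", "Mb")
  if (!all(req %in% names(physical))) {
    stop("physical order needs columns: ", paste(req, collapse = ", "))
  }
  physical$chromosome <- as.character(physical$chromosome)
  chrs <- unique(physical$chromosome)
  physical <- physical[order(match(physical$chromosome, chrs), physical$Mb), , drop = FALSE]

  seg_in <- vapply(physical$marker, function(mk) {
    any(vapply(genotypes, function(g) {
      mk %in% rownames(g) && length(unique(stats::na.omit(g[mk, ]))) > 1
    }, logical(1)))
  }, logical(1))
  if (any(!seg_in)) {
    warning("dropping ", sum(!seg_in), " marker(s) segregating in no family")
    physical <- physical[seg_in, , drop = FALSE]
  }
  if (!nrow(physical)) stop("no marker segregates in any family")

  out <- lapply(split(physical, factor(physical$chromosome, unique(physical$chromosome))),
                function(ph) {
    cm <- numeric(nrow(ph))
    if (nrow(ph) > 1) {
      for (i in seq_len(nrow(ph) - 1)) {
        rec <- 0L; tot <- 0L
        for (g in genotypes) {
          a <- ph$marker[i]; b <- ph$marker[i + 1]
          if (!(a %in% rownames(g)) || !(b %in% rownames(g))) next
          ca <- g[a, ]; cb <- g[b, ]
          if (length(unique(stats::na.omit(ca))) < 2 ||
              length(unique(stats::na.omit(cb))) < 2) next
          keep <- !is.na(ca) & !is.na(cb)
          rec <- rec + sum(ca[keep] != cb[keep])
          tot <- tot + sum(keep)
        }
        r <- if (tot > 0) rec / tot else 0
        if (r >= 0.5) {
          warning("adjacent pooled rf >= 0.5 between ", ph$marker[i], " and ",
                  ph$marker[i + 1], "; capped at ", max_rf)
          r <- max_rf
        }
        cm[i + 1] <- cm[i] + kosambi_cM(r)
      }
    }
    data.frame(marker = ph$marker, chromosome = ph$chromosome,
               cM = cm, Mb = ph$Mb, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  as_genetic_map(out)
}
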