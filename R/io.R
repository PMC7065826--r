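#' Assemble a multifamily genotype table
#'
#' The package's central genotype container: a marker map, a markers x
#' lines code matrix (+1 = common-parent allele "B", -1 = alternative
#' allele "A", NA = missing), and a line -> family assignment.
#'
#' @param map A [as_genetic_map()] table (columns marker, chromosome, cM,
#'   optional Mb).
#' @param geno Markers x lines matrix coded +1/-1/NA; row names must match
#'   `map$marker`, column names are line ids.
#' @param family Named character vector mapping every line id to a family.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(map, geno, family) {
  map <- as_genetic_map(map)
  if (!identical(rownames(geno), map$marker)) {
    geno <- geno[map$marker, , drop = FALSE]
  }
  if (is.null(colnames(geno))) stop("genotype matrix needs line ids as column names")
  if (!all(colnames(geno) %in% names(family))) {
    stop("every line must be assigned to exactly one family")
  }
  bad <- !(geno %in% c(-1, 1) | is.na(geno))
  if (any(bad)) stop("genotype codes must be +1, -1 or NA")
  storage.mode(geno) <- "integer"
  structure(list(map = map, geno = geno,
                 family = family[colnames(geno)]),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("Multifamily DH genotype table:", nrow(x$geno), "markers x",
      ncol(x$geno), "lines in", length(unique(x$family)), "families\n")
  cat("Chromosomes:", paste(unique(x$map$chromosome), collapse = " "), "\n")
  invisible(x)
}

#' Split a genotype table into per-family code matrices
#'
#' @param table A `genotype_table`.
#' @return Named list of markers x lines matrices, one per family.
#' @export
split_by_family <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  fams <- unique(table$family)
  out <- lapply(fams, function(f) {
    table$geno[, table$family == f, drop = FALSE]
  })
  names(out) <- fams
  for (i in seq_along(out)) attr(out[[i]], "map") <- table$map
  out
}

#' Read and write genotype tables
#'
#' The on-disk dialect is a plain CSV: a header row
#' `marker,chromosome,cM,Mb,<line ids...>`, then a mandatory family row
#' whose marker field is `_family_` and whose line cells name each line's
#' family, then one row per marker with cells in `{A, B, NA}` (B = the
#' common-parent allele).
#'
#' @param path File path.
#' @return `read_genotypes`: a [genotype_table()].
#' @export
read_genotypes <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         na.strings = NULL)
  meta_cols <- c("marker", "chromosome", "cM", "Mb")
  if (!all(c("marker", "chromosome", "cM") %in% names(raw))) {
    stop("genotype file must start with columns marker, chromosome, cM[, Mb]")
  }
  famrow <- which(raw$marker == "_family_")
  if (length(famrow) != 1L) stop("genotype file needs exactly one _family_ row")
  line_ids <- setdiff(names(raw), meta_cols)
  if (!length(line_ids)) stop("no line columns found")
  family <- stats::setNames(as.character(raw[famrow, line_ids]), line_ids)
  if (any(is.na(family) | family == "")) stop("every line needs a family in the _family_ row")
  body <- raw[-famrow, , drop = FALSE]
  if (anyDuplicated(body$marker)) {
    stop("duplicate marker id: ", body$marker[duplicated(body$marker)][1])
  }
  cM <- suppressWarnings(as.numeric(body$cM))
  if (any(is.na(cM))) stop("non-numeric cM at row ", which(is.na(cM))[1])
  for (chr in unique(body$chromosome)) {
    p <- cM[body$chromosome == chr]
    if (is.unsorted(p)) stop("cM positions not non-decreasing on chromosome ", chr)
  }
  map <- data.frame(marker = body$marker, chromosome = body$chromosome,
                    cM = cM, stringsAsFactors = FALSE)
  if ("Mb" %in% names(body)) {
    mb <- suppressWarnings(as.numeric(body$Mb))
    if (!all(is.na(mb))) map$Mb <- mb
  }
  cells <- as.matrix(body[, line_ids, drop = FALSE])
  ok <- matrix(cells %in% c("A", "B", "NA", ""), nrow(cells))
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop("unknown genotype code '", cells[bad[1], bad[2]], "' at marker ",
         body$marker[bad[1]], ", line ", line_ids[bad[2]])
  }
  geno <- matrix(NA_integer_, nrow(cells), ncol(cells),
                 dimnames = list(body$marker, line_ids))
  geno[cells == "B"] <- 1L
  geno[cells == "A"] <- -1L
  genotype_table(map, geno, family)
}

#' @rdname read_genotypes
#' @param table A [genotype_table()].
#' @export
write_genotypes <- function(table, path) {
  stopifnot(inherits(table, "genotype_table"))
  cells <- matrix("NA", nrow(table$geno), ncol(table$geno))
  cells[table$geno == 1L] <- "B"
  cells[table$geno == -1L] <- "A"
  has_mb <- "Mb" %in% names(table$map)
  meta <- data.frame(marker = table$map$marker, chromosome = table$map$chromosome,
                     cM = table$map$cM, stringsAsFactors = FALSE)
  if (has_mb) meta$Mb <- table$map$Mb
  famrow <- c("_family_", "", "", if (has_mb) "", unname(table$family))
  out <- cbind(meta, as.data.frame(cells, stringsAsFactors = FALSE))
  names(out) <- c(names(meta), colnames(table$geno))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = ","), con)
  writeLines(paste(famrow, collapse = ","), con)
  utils::write.table(out, con, sep = ",", col.names = FALSE, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read and write long phenotype plot tables
#'
#' Columns: `line_id, family, environment, rep, trait, value`; at most one
#' record per (line, environment, trait, rep); values numeric or NA.
#'
#' @param path File path.
#' @return `read_phenotypes`: a validated data frame.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("line_id", "family", "environment", "rep", "trait", "value")
  if (!all(req %in% names(ph))) {
    stop("phenotype file needs columns: ", paste(req, collapse = ", "))
  }
  key <- paste(ph$line_id, ph$environment, ph$trait, ph$rep)
  if (anyDuplicated(key)) {
    stop("duplicate phenotype record: ", key[duplicated(key)][1])
  }
  if (!is.numeric(ph$value)) stop("phenotype values must be numeric")
  if (any(is.infinite(ph$value))) stop("phenotype values must be finite or NA")
  ph
}

#' @rdname read_phenotypes
#' @param phenotypes Long plot data frame as documented above.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read and write marker map CSVs (marker, chromosome, cM[, Mb])
#' @param path File path.
#' @return `read_map`: a `genetic_map`.
#' @export
read_map <- function(path) {
  as_genetic_map(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_map
#' @param map A `genetic_map`.
#' @export
write_map <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and read a QTL report
#'
#' TSV with columns `trait, chromosome, position_cM, intensity,
#' seg_prob_<family>..., contribution, effect`.  An empty report writes a
#' header-only file.
#'
#' @param reports Data frame of called QTLs (may have zero rows).
#' @param path File path.
#' @param families Family names used for the `seg_prob_` columns when the
#'   report has zero rows and none can be inferred.
#' @export
write_qtl_report <- function(reports, path, families = character(0)) {
  if (is.null(reports) || !nrow(reports)) {
    cols <- c("trait", "chromosome", "position_cM", "intensity",
              paste0("seg_prob_", families), "contribution", "effect")
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  utils::write.table(reports, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_qtl_report
#' @export
read_qtl_report <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Export physical QTL regions as BED
#'
#' BED is 0-based half-open on base-pair coordinates; megabase positions
#' are converted with `floor(Mb * 1e6)`.
#'
#' @param regions Data frame with columns `chromosome`, `start_Mb`,
#'   `end_Mb` and optionally `name`.
#' @param path File path.
#' @export
write_regions_bed <- function(regions, path) {
  if (!all(c("chromosome", "start_Mb", "end_Mb") %in% names(regions))) {
    stop("BED export needs chromosome, start_Mb and end_Mb columns")
  }
  if (any(is.na(regions$start_Mb) | is.na(regions$end_Mb))) {
    stop("BED export refused: region(s) without Mb coordinates")
  }
  bed <- data.frame(chrom = regions$chromosome,
                    start = floor(regions$start_Mb * 1e6),
                    end = floor(regions$end_Mb * 1e6),
                    name = if ("name" %in% names(regions)) regions$name else ".",
                    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write and read a per-interval posterior field
#'
#' @param field A `posterior_field` data frame (see [mfqtl_scan()]).
#' @param path File path.
#' @export
write_posterior_field <- function(field, path) {
  utils::write.table(as.data.frame(field), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_posterior_field
#' @export
read_posterior_field <- function(path) {
  f <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(f) <- c("posterior_field", "data.frame")
  f
}

#' Read and write adjusted (season-corrected) per-line phenotypes
#' @param path File path.
#' @export
read_adjusted <- function(path) {
  a <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("line_id", "family", "trait", "value")
  if (!all(req %in% names(a))) {
    stop("adjusted phenotype file needs columns: ", paste(req, collapse = ", "))
  }
  a
}

#' @rdname read_adjusted
#' @param adjusted Data frame `(line_id, family, trait, value)`.
#' @export
write_adjusted <- function(adjusted, path) {
  utils::write.csv(adjusted, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
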