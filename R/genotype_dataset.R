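#' Diploid multilocus genotype dataset
#'
#' The common currency of all statistics in the package: a set of diploid
#' individuals typed at codominant loci (microsatellites), with per-individual
#' metadata (reef, region, coordinates, sex).
#'
#' Alleles are stored as an integer matrix with two columns per locus
#' (`<locus>.1`, `<locus>.2`); allele values are positive integer state labels
#' (e.g. repeat numbers). Missing genotypes are `NA` in both columns of a
#' locus: a genotype is either fully called or fully missing.
#'
#' @param alleles integer matrix `n x 2L` (two adjacent columns per locus),
#'   positive integers or `NA`.
#' @param locus_names character vector of length `L`.
#' @param individual_ids unique character vector of length `n`.
#' @param reef_id character vector: sampling reef of each individual.
#' @param region_id optional character vector: geographic region of each reef.
#' @param x_km,y_km optional numeric coordinates in km.
#' @param sex optional, one of `"male"`, `"female"`, `"unknown"`.
#'
#' @return an object of class `genotype_dataset`: a list with elements
#'   `alleles` (integer matrix), `loci` (character) and `ind` (data.frame of
#'   metadata, one row per individual).
#' @export
genotype_dataset <- function(alleles, locus_names, individual_ids,
                             reef_id, region_id = NULL,
                             x_km = NULL, y_km = NULL, sex = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  n <- nrow(alleles)
  if (ncol(alleles) %% 2L != 0L)
    stop("allele matrix must have two columns per locus")
  L <- ncol(alleles) %/% 2L
  if (length(locus_names) != L)
    stop("expected ", L, " locus names, got ", length(locus_names))
  if (anyDuplicated(locus_names))
    stop("duplicated locus names")
  if (length(individual_ids) != n)
    stop("individual_ids length does not match allele matrix")
  if (anyDuplicated(individual_ids))
    stop("individual ids must be unique")
  if (length(reef_id) != n)
    stop("reef_id must be given for every individual")

  ok_val <- is.na(alleles) | alleles >= 1L
  if (!all(ok_val))
    stop("allele values must be positive integers or NA")
  # both gene copies of a locus missing together or called together
  for (l in seq_len(L)) {
    m1 <- is.na(alleles[, 2L * l - 1L])
    m2 <- is.na(alleles[, 2L * l])
    if (any(m1 != m2))
      stop("half-missing genotype at locus ", locus_names[l],
           " (individual ", individual_ids[which(m1 != m2)[1L]], ")")
  }

  if (is.null(sex)) sex <- rep("unknown", n)
  if (n > 0L) {
    sex <- match.arg(as.character(sex), c("male", "female", "unknown"),
                     several.ok = TRUE)
    if (length(sex) == 1L) sex <- rep(sex, n)
  }

  ind <- data.frame(
    individual_id = as.character(individual_ids),
    reef_id = as.character(reef_id),
    region_id = if (is.null(region_id)) rep(NA_character_, n) else as.character(region_id),
    x_km = if (is.null(x_km)) rep(NA_real_, n) else as.numeric(x_km),
    y_km = if (is.null(y_km)) rep(NA_real_, n) else as.numeric(y_km),
    sex = sex,
    stringsAsFactors = FALSE
  )
  colnames(alleles) <- paste(rep(locus_names, each = 2L), 1:2, sep = ".")
  rownames(alleles) <- ind$individual_id
  structure(list(alleles = alleles, loci = as.character(locus_names), ind = ind),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$alleles), "individuals x",
      length(x$loci), "loci\n")
  cat("  reefs:  ", length(unique(x$ind$reef_id)), "\n")
  rg <- unique(x$ind$region_id)
  if (!all(is.na(rg))) cat("  regions:", length(rg), "\n")
  miss <- mean(is.na(x$alleles))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) {
  c(nrow(x$alleles), length(x$loci))
}

#' Subset a genotype dataset by individuals and/or loci
#'
#' @param x a `genotype_dataset`.
#' @param individuals logical, integer or character index over individuals.
#' @param loci logical, integer or character index over loci.
#' @return a `genotype_dataset`.
#' @export
subset_genotypes <- function(x, individuals = NULL, loci = NULL) {
  stopifnot(inherits(x, "genotype_dataset"))
  ii <- seq_len(nrow(x$alleles))
  if (!is.null(individuals)) {
    if (is.character(individuals))
      individuals <- match(individuals, x$ind$individual_id)
    ii <- ii[individuals]
  }
  ll <- seq_along(x$loci)
  if (!is.null(loci)) {
    if (is.character(loci)) loci <- match(loci, x$loci)
    ll <- ll[loci]
  }
  cols <- as.vector(rbind(2L * ll - 1L, 2L * ll))
  genotype_dataset(x$alleles[ii, cols, drop = FALSE], x$loci[ll],
                   x$ind$individual_id[ii], x$ind$reef_id[ii],
                   x$ind$region_id[ii], x$ind$x_km[ii], x$ind$y_km[ii],
                   x$ind$sex[ii])
}

#' Combine genotype datasets typed at the same loci
#'
#' Stacks individuals; ids must stay unique across the inputs.
#'
#' @param ... `genotype_dataset` objects with identical loci.
#' @return a `genotype_dataset`.
#' @export
rbind_genotypes <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) >= 1L, all(vapply(xs, inherits, TRUE, "genotype_dataset")))
  loci <- xs[[1L]]$loci
  for (x in xs) if (!identical(x$loci, loci)) stop("loci differ between datasets")
  ind <- do.call(rbind, lapply(xs, `[[`, "ind"))
  genotype_dataset(do.call(rbind, lapply(xs, `[[`, "alleles")), loci,
                   ind$individual_id, ind$reef_id, ind$region_id,
                   ind$x_km, ind$y_km, ind$sex)
}

#' Extract the two allele columns of one locus
#' @noRd
.locus_cols <- function(x, l) {
  x$alleles[, c(2L * l - 1L, 2L * l), drop = FALSE]
}

#' Resolve a grouping specification to a factor over individuals
#'
#' `grouping` may be `"reef"`, `"region"`, a metadata column name, or a vector
#' of length n.
#' @noRd
.resolve_grouping <- function(x, grouping) {
  if (length(grouping) == 1L && is.character(grouping)) {
    g <- switch(grouping,
                reef = x$ind$reef_id,
                region = x$ind$region_id,
                x$ind[[grouping]])
    if (is.null(g)) stop("unknown grouping: ", grouping)
  } else {
    if (length(grouping) != nrow(x$alleles))
      stop("grouping vector length does not match individuals")
    g <- grouping
  }
  if (anyNA(g)) stop("grouping contains missing labels")
  factor(g, levels = unique(g))
}
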