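#' Read a genepop file
#'
#' Parses genepop 4.x text files with 2- or 3-digit allele coding. Each "Pop"
#' block becomes one reef; the reef label is taken from the identifier of the
#' first individual in the block (the token before the comma), which is the
#' common convention for genepop exports. Alleles coded `00`/`000` are mapped
#' to missing (`NA`).
#'
#' Coordinates, region and sex cannot travel inside a genepop file; use
#' [read_metadata_csv()] and [attach_metadata()] for the sidecar table.
#'
#' @param path path to a genepop text file.
#' @return a [genotype_dataset()].
#' @seealso [write_genepop()]
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) < 3L)
    stop("genepop parse error at line 1: file too short for a header")
  lines <- lines[nonblank]
  lineno <- nonblank  # original line numbers for error messages

  # line 1: title; then locus names until first "Pop"
  pop_idx <- which(toupper(trimws(lines)) == "POP")
  if (length(pop_idx) == 0L)
    stop("genepop parse error: no 'Pop' line found")
  if (pop_idx[1L] < 3L)
    stop("genepop parse error at line ", lineno[pop_idx[1L]],
         ": no locus names before first 'Pop'")
  locus_lines <- lines[2:(pop_idx[1L] - 1L)]
  # locus names may be one per line or comma-separated on one line
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[loci != ""]
  L <- length(loci)

  ids <- character(0); reefs <- character(0)
  allele_rows <- list()
  width <- NA_integer_
  block <- 0L
  cur_reef <- NA_character_
  for (k in seq_along(lines)) {
    if (k == 1L || k < pop_idx[1L]) next
    ln <- lines[k]
    if (toupper(trimws(ln)) == "POP") {
      block <- block + 1L
      cur_reef <- NA_character_
      next
    }
    parts <- strsplit(ln, ",")[[1L]]
    if (length(parts) < 2L)
      stop("genepop parse error at line ", lineno[k],
           ": expected '<id> , <genotypes>'")
    id <- trimws(parts[1L])
    gts <- strsplit(trimws(paste(parts[-1L], collapse = ",")), "[[:space:]]+")[[1L]]
    gts <- gts[gts != ""]
    if (length(gts) != L)
      stop("genepop parse error at line ", lineno[k], ": expected ", L,
           " genotypes, found ", length(gts))
    w <- unique(nchar(gts))
    if (length(w) != 1L || !(w %in% c(4L, 6L)))
      stop("genepop parse error at line ", lineno[k],
           ": mixed or invalid allele coding widths (", paste(w, collapse = "/"), ")")
    w <- w %/% 2L
    if (is.na(width)) width <- w
    if (w != width)
      stop("genepop parse error at line ", lineno[k],
           ": allele coding width ", w, " differs from earlier width ", width)
    if (any(grepl("[^0-9]", gts)))
      stop("genepop parse error at line ", lineno[k], ": non-numeric genotype")
    a1 <- as.integer(substr(gts, 1L, width))
    a2 <- as.integer(substr(gts, width + 1L, 2L * width))
    a1[a1 == 0L] <- NA_integer_
    a2[a2 == 0L] <- NA_integer_
    half <- xor(is.na(a1), is.na(a2))
    if (any(half))
      stop("genepop parse error at line ", lineno[k],
           ": half-missing genotype at locus ", loci[which(half)[1L]])
    if (is.na(cur_reef)) cur_reef <- id
    ids <- c(ids, id)
    reefs <- c(reefs, cur_reef)
    allele_rows[[length(allele_rows) + 1L]] <- as.vector(rbind(a1, a2))
  }
  if (length(allele_rows) == 0L)
    stop("genepop parse error: no genotype rows")
  if (anyDuplicated(ids)) {
    # ids repeated across pops (common when the pop label is reused): make unique
    ids <- make.unique(ids, sep = "_")
  }
  alleles <- do.call(rbind, allele_rows)
  genotype_dataset(alleles, loci, ids, reefs)
}

#' Write a genepop file
#'
#' Populations are emitted grouped by `reef_id` in order of first appearance;
#' output is deterministic (byte-identical for identical datasets). The allele
#' coding width (2 or 3 digits) is chosen from the largest allele value;
#' values that do not fit 3 digits are an error, never truncated.
#'
#' @param dataset a [genotype_dataset()].
#' @param path output file path.
#' @param title header line content.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(dataset, path, title = "reefconn genepop export") {
  stopifnot(inherits(dataset, "genotype_dataset"))
  n <- nrow(dataset$alleles)
  if (n == 0L || length(dataset$loci) == 0L)
    stop("refusing to write an empty genotype dataset")
  amax <- suppressWarnings(max(dataset$alleles, na.rm = TRUE))
  if (!is.finite(amax)) amax <- 1L
  width <- if (amax <= 99L) 2L else if (amax <= 999L) 3L else
    stop("allele value ", amax, " exceeds 3-digit genepop coding")
  fmt <- function(a) {
    a[is.na(a)] <- 0L
    formatC(a, width = width, flag = "0")
  }
  out <- c(title, dataset$loci)
  reefs <- unique(dataset$ind$reef_id)
  L <- length(dataset$loci)
  for (r in reefs) {
    out <- c(out, "Pop")
    for (i in which(dataset$ind$reef_id == r)) {
      row <- dataset$alleles[i, ]
      gt <- paste0(fmt(row[seq(1L, 2L * L, 2L)]), fmt(row[seq(2L, 2L * L, 2L)]))
      out <- c(out, paste0(dataset$ind$individual_id[i], " ,  ",
                           paste(gt, collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read the sidecar metadata table
#'
#' CSV with columns `individual_id`, `reef_id`, `region_id`, `x_km`, `y_km`,
#' `sex`; the canonical channel for information genepop cannot carry.
#'
#' @param path CSV path.
#' @return a data.frame.
#' @export
read_metadata_csv <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "reef_id")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop("metadata is missing required column(s): ", paste(miss, collapse = ", "))
  for (col in c("region_id", "sex")) if (is.null(md[[col]])) md[[col]] <- NA_character_
  for (col in c("x_km", "y_km")) if (is.null(md[[col]])) md[[col]] <- NA_real_
  md$sex[is.na(md$sex)] <- "unknown"
  md
}

#' Attach sidecar metadata to a genotype dataset
#'
#' @param dataset a [genotype_dataset()].
#' @param metadata data.frame as returned by [read_metadata_csv()].
#' @return the dataset with metadata columns filled in.
#' @export
attach_metadata <- function(dataset, metadata) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  i <- match(dataset$ind$individual_id, metadata$individual_id)
  if (anyNA(i))
    stop("individuals missing from metadata: ",
         paste(dataset$ind$individual_id[is.na(i)], collapse = ", "))
  md <- metadata[i, ]
  genotype_dataset(dataset$alleles, dataset$loci, dataset$ind$individual_id,
                   md$reef_id, md$region_id, md$x_km, md$y_km, md$sex)
}

#' Write the sidecar metadata table
#' @param dataset a [genotype_dataset()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_metadata_csv <- function(dataset, path) {
  utils::write.csv(dataset$ind, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
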