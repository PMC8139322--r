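#' Gene-family presence/absence matrix
#'
#' The central container of the package: an integer matrix of gene-copy
#' counts with gene families as rows and genomes as columns, plus an
#' optional per-genome metadata table (niche of isolation, species
#' assignment).  A value of 0 means the family is absent from the genome;
#' values >= 2 record in-paralogs.
#'
#' @param counts integer matrix, rows = families, columns = genomes.
#'   Must have unique row and column names.
#' @param metadata optional `data.frame` with a `genome` column matching
#'   `colnames(counts)` and, typically, `niche` (e.g. `"marine"`/`"land"`)
#'   and `species` columns.
#' @return an object of class `pa_matrix`: a list with elements `counts`
#'   and `metadata`.
#' @examples
#' m <- matrix(c(1, 1, 1, 0, 1, 1, 1, 0, 0), nrow = 3,
#'             dimnames = list(c("f1", "f2", "f3"), c("g1", "g2", "g3")))
#' pa <- pa_matrix(m)
#' pa
#' @export
pa_matrix <- function(counts, metadata = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have family row names and genome column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate family ids in `counts`")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate genome ids in `counts`")
  if (any(counts < 0)) stop("negative copy numbers are not allowed")
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (!"genome" %in% names(metadata))
      stop("`metadata` must have a `genome` column")
    missing <- setdiff(colnames(counts), metadata$genome)
    if (length(missing))
      stop("metadata missing genomes: ", paste(missing, collapse = ", "))
    metadata <- metadata[match(colnames(counts), metadata$genome), ,
                         drop = FALSE]
    rownames(metadata) <- NULL
  }
  structure(list(counts = counts, metadata = metadata),
            class = "pa_matrix")
}

#' @export
print.pa_matrix <- function(x, ...) {
  occ <- occupancy(x)
  n <- ncol(x$counts)
  cat(sprintf("pa_matrix: %d gene families x %d genomes\n",
              nrow(x$counts), n))
  cat(sprintf("  core (all %d genomes): %d;  single-genome: %d\n",
              n, sum(occ == n), sum(occ == 1)))
  if (!is.null(x$metadata) && "niche" %in% names(x$metadata)) {
    tab <- table(x$metadata$niche)
    cat("  niches: ",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
dim.pa_matrix <- function(x) dim(x$counts)

#' Number of genomes in which each family occurs
#'
#' @param x a [pa_matrix()]
#' @return named integer vector over families
#' @export
occupancy <- function(x) {
  stopifnot(inherits(x, "pa_matrix"))
  rowSums(x$counts > 0L)
}

#' Genome ids of a presence/absence matrix
#' @param x a [pa_matrix()]
#' @export
genome_ids <- function(x) colnames(x$counts)

#' Family ids of a presence/absence matrix
#' @param x a [pa_matrix()]
#' @export
family_ids <- function(x) rownames(x$counts)
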