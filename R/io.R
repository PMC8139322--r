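#' Write a presence/absence matrix
#'
#' Two dialects: `"binary-tsv"` writes a families-by-genomes 0/1 table
#' (copy number collapsed to presence) with a leading `family` column;
#' `"roary-csv"` writes a Roary-style `gene_presence_absence.csv` with
#' `Gene` and `Annotation` columns followed by one column per genome
#' holding comma-separated member gene ids (copy number preserved as
#' the member count).
#'
#' @param matrix a [pa_matrix()]
#' @param path output file
#' @param dialect `"binary-tsv"` or `"roary-csv"`
#' @return `path`, invisibly
#' @export
write_presence_absence <- function(matrix, path,
                                   dialect = c("binary-tsv", "roary-csv")) {
  dialect <- match.arg(dialect)
  counts <- matrix$counts
  if (dialect == "binary-tsv") {
    df <- data.frame(family = rownames(counts),
                     (counts > 0L) * 1L, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    cells <- t(vapply(seq_len(nrow(counts)), function(i) {
      vapply(seq_len(ncol(counts)), function(j) {
        k <- counts[i, j]
        if (k == 0L) "" else
          paste(sprintf("%s_%s_%d", rownames(counts)[i],
                        colnames(counts)[j], seq_len(k)),
                collapse = ",")
      }, "")
    }, character(ncol(counts))))
    df <- data.frame(Gene = rownames(counts), Annotation = "",
                     cells, check.names = FALSE)
    names(df)[-(1:2)] <- colnames(counts)
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a presence/absence matrix
#'
#' Counterpart of [write_presence_absence()].  In the Roary dialect a
#' non-empty cell marks presence and the comma-separated member count
#' gives the copy number.  Ragged rows and duplicate family or genome
#' ids are rejected with the offending line number.
#'
#' @param path input file
#' @param dialect `"binary-tsv"` or `"roary-csv"`
#' @param metadata optional genome metadata `data.frame` attached to
#'   the result
#' @return a [pa_matrix()]
#' @export
read_presence_absence <- function(path,
                                  dialect = c("binary-tsv", "roary-csv"),
                                  metadata = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "binary-tsv") {
    lines <- readLines(path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (length(unique(nf)) != 1)
      stop("ragged row at line ", which(nf != nf[1])[1], " of ", path)
    header <- fields[[1]]
    if (header[1] != "family")
      stop("expected leading 'family' column in ", path)
    genomes <- header[-1]
    if (anyDuplicated(genomes)) stop("duplicate genome ids in header")
    fams <- vapply(fields[-1], `[[`, "", 1L)
    dup <- anyDuplicated(fams)
    if (dup) stop("duplicate family id at line ", dup + 1L)
    vals <- do.call(rbind, lapply(fields[-1],
                                  function(f) as.integer(f[-1])))
    dimnames(vals) <- list(fams, genomes)
    pa_matrix(vals, metadata)
  } else {
    df <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
    if (!"Gene" %in% names(df)) stop("no 'Gene' column in ", path)
    dup <- anyDuplicated(df$Gene)
    if (dup) stop("duplicate family id at line ", dup + 1L)
    meta_cols <- intersect(c("Gene", "Annotation",
                             "Non-unique Gene name", "No. isolates"),
                           names(df))
    genomes <- setdiff(names(df), meta_cols)
    vals <- vapply(genomes, function(g) {
      cell <- df[[g]]
      ifelse(is.na(cell) | cell == "", 0L,
             lengths(strsplit(as.character(cell), ",", fixed = TRUE)))
    }, integer(nrow(df)))
    vals <- matrix(vals, nrow = nrow(df),
                   dimnames = list(df$Gene, genomes))
    pa_matrix(vals, metadata)
  }
}

#' Read or write a genome metadata table
#'
#' Tab-separated with columns `genome`, `niche` and optionally
#' `species`.
#'
#' @param path file path
#' @return `read_metadata()`: a `data.frame`
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"genome" %in% names(df)) stop("metadata needs a `genome` column")
  df
}

#' @param metadata the table to write
#' @rdname read_metadata
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read or write a family-to-COG-category table
#'
#' Tab-separated, columns `family` and `category` (single COG letters
#' or `"unknown"`).
#'
#' @param path file path
#' @export
read_cog_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("family", "category") %in% names(df)))
    stop("COG table needs `family` and `category` columns")
  df
}

#' @param cog_table the table to write
#' @rdname read_cog_table
#' @export
write_cog_table <- function(cog_table, path) {
  utils::write.table(cog_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read or write a square ANI (or distance) matrix as TSV
#'
#' Row and column names are genome ids; the first column holds the row
#' names.
#'
#' @param path file path
#' @export
read_ani_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop("ANI matrix in ", path, " is not square")
  m
}

#' @param m the matrix to write
#' @rdname read_ani_matrix
#' @export
write_ani_matrix <- function(m, path) {
  df <- data.frame(genome = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write simulation ground truth as JSON
#'
#' Stores the per-family class labels, planted niche-family ids, niche
#' and species assignments, per-genome gene counts and the generating
#' tree (as a newick string).
#'
#' @param truth a `sim_truth` from [simulate_gene_content()]
#' @param path output file
#' @export
write_truth_json <- function(truth, path) {
  obj <- list(classes = as.list(truth$classes),
              planted = truth$planted,
              niche = as.list(truth$niche),
              species = as.list(truth$species),
              genes_per_genome = as.list(truth$genes_per_genome),
              tree = ape::write.tree(truth$tree))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(classes = unlist(obj$classes),
                 planted = lapply(obj$planted, as.character),
                 niche = unlist(obj$niche),
                 species = unlist(obj$species),
                 genes_per_genome = unlist(obj$genes_per_genome),
                 tree = ape::read.tree(text = obj$tree)),
            class = "sim_truth")
}

#' Export a rarefaction profile and its curve fits as JSON
#'
#' The JSON embeds the seed and a configuration hash alongside the mean
#' trajectories, partition counts and fitted parameters, so every
#' artifact records its provenance.
#'
#' @param profile a `pan_profile` from [rarefaction()]
#' @param path output file
#' @param part optional [partition()] to embed
#' @param fits optional named list of `curve_fit` objects
#' @export
write_profile_json <- function(profile, path, part = NULL, fits = NULL) {
  obj <- list(seed = profile$seed,
              n_permutations = profile$n_permutations,
              config_hash = config_hash(list(profile$seed,
                                             profile$n_permutations,
                                             length(profile$n))),
              n = profile$n,
              pan_mean = unname(profile$pan_mean),
              core_mean = unname(profile$core_mean),
              new_mean = unname(profile$new_mean))
  if (!is.null(part))
    obj$partition <- list(counts = as.list(part$counts),
                          fractions = as.list(part$fractions))
  if (!is.null(fits))
    obj$fits <- lapply(fits, function(f)
      list(model = f$model, params = as.list(f$params),
           r_squared = f$r_squared, converged = f$converged,
           open = f$open))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
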