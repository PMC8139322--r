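#' MinHash sketch of a genome
#'
#' Bottom-s MinHash over the canonical (strand-minimal) k-mers of a
#' nucleotide sequence: every k-mer is replaced by the lexicographic
#' minimum of itself and its reverse complement, hashed with a seeded
#' 64-bit FNV-1a hash, and the `s` smallest distinct hash values are
#' kept.  Identical defaults to Mash (k = 21, s = 1000).  A genome and
#' its reverse complement produce identical sketches.
#'
#' @param x a nucleotide sequence: a character scalar, a
#'   [Biostrings::DNAString]/[Biostrings::DNAStringSet] (contigs are
#'   sketched jointly), or a path to a FASTA file
#' @param k k-mer length
#' @param s sketch size; `Inf` keeps every distinct k-mer hash, giving
#'   the exact k-mer set in hash space
#' @param seed hash seed (fixed by default so sketches are comparable
#'   across runs)
#' @param genome_id label stored in the sketch
#' @return a `sketch`: list with `genome`, `k`, `s`, `hashes` (sorted
#'   ascending, distinct)
#' @export
sketch_genome <- function(x, k = 21, s = 1000, seed = 42,
                          genome_id = NULL) {
  seqs <- as_dna_strings(x, genome_id)
  if (is.null(genome_id)) genome_id <- seqs$id
  if (all(nchar(seqs$seq) < k))
    stop("sequence shorter than k = ", k)
  hashes <- sort(unique(unlist(
    lapply(seqs$seq, function(sq) .sketch_cpp(sq, as.integer(k), 0L,
                                              as.double(seed))))))
  if (is.finite(s) && length(hashes) > s) hashes <- hashes[seq_len(s)]
  structure(list(genome = genome_id, k = as.integer(k), s = s,
                 hashes = hashes),
            class = "sketch")
}

as_dna_strings <- function(x, genome_id) {
  if (inherits(x, "DNAStringSet"))
    return(list(seq = as.character(x), id = genome_id %||% "genome"))
  if (inherits(x, "DNAString"))
    return(list(seq = as.character(x), id = genome_id %||% "genome"))
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    set <- Biostrings::readDNAStringSet(x)
    id <- genome_id %||% sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(x))
    return(list(seq = as.character(set), id = id))
  }
  if (is.character(x))
    return(list(seq = toupper(x), id = genome_id %||% "genome"))
  stop("cannot interpret `x` as a nucleotide sequence")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mash distance between two sketches
#'
#' The Jaccard index of the two k-mer sets is estimated from the merged
#' sketch (the `s` smallest hashes of the union; the fraction of those
#' present in both sketches estimates Jaccard), and converted to a
#' mutation-rate estimate `d = -(1/k) * log(2j / (1 + j))`.  A zero
#' Jaccard estimate gives the capped distance 1.
#'
#' @param sk1,sk2 sketches from [sketch_genome()]; `k` must match
#' @return a single distance in `[0, 1]`
#' @examples
#' a <- sketch_genome(paste(sample(c("A","C","G","T"), 300, TRUE),
#'                          collapse = ""), k = 11, s = 50)
#' mash_distance(a, a)  # 0
#' @export
mash_distance <- function(sk1, sk2) {
  stopifnot(inherits(sk1, "sketch"), inherits(sk2, "sketch"))
  if (sk1$k != sk2$k)
    stop("sketches have different k (", sk1$k, " vs ", sk2$k, ")")
  s <- min(sk1$s, sk2$s)
  merged <- sort(unique(c(sk1$hashes, sk2$hashes)))
  if (is.finite(s) && length(merged) > s) merged <- merged[seq_len(s)]
  shared <- sum(merged %in% sk1$hashes & merged %in% sk2$hashes)
  j <- shared / length(merged)
  if (j <= 0) return(1)
  min(1, -(1 / sk1$k) * log(2 * j / (1 + j)))
}

#' All-pairs Mash distance matrix
#'
#' @param sketches named list of [sketch_genome()] sketches
#' @return a `distance_matrix` (kind `"mash"`)
#' @export
mash_distance_matrix <- function(sketches) {
  ids <- vapply(sketches, function(s) s$genome, "")
  n <- length(sketches)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      m[i, j] <- m[j, i] <- mash_distance(sketches[[i]], sketches[[j]])
  new_distance_matrix(m, "mash")
}

new_distance_matrix <- function(m, kind) {
  structure(list(matrix = m, kind = kind), class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix [%s]: %d genomes\n", x$kind,
              nrow(x$matrix)))
  invisible(x)
}

check_ani <- function(ani) {
  if (inherits(ani, "distance_matrix")) ani <- ani$matrix
  if (!is.matrix(ani) || nrow(ani) != ncol(ani))
    stop("ANI matrix must be square")
  if (is.null(rownames(ani))) stop("ANI matrix needs genome dimnames")
  if (!isTRUE(all.equal(ani, t(ani), tolerance = 1e-6,
                        check.attributes = FALSE)))
    stop("ANI matrix must be symmetric")
  ani
}

#' Pearson-correlation matrix of ANI profiles
#'
#' Correlates each pair of genomes' full ANI profiles (matrix rows,
#' self-entries set to 100), the similarity display used for species
#' delineation heatmaps.
#'
#' @param ani square symmetric ANI matrix (percent identities) with
#'   genome dimnames
#' @return a `distance_matrix` of kind `"pearson-corr"` (a similarity:
#'   unit diagonal)
#' @export
ani_correlation <- function(ani) {
  ani <- check_ani(ani)
  diag(ani) <- 100
  cc <- stats::cor(t(ani))
  new_distance_matrix(cc, "pearson-corr")
}

#' ANI species delineation
#'
#' Genomes are joined whenever their ANI meets `threshold` (by
#' convention 95%, corresponding to the classical 70% DDH species
#' boundary), and species are the connected components of that graph.
#' Component membership is transitive: chains A-B, B-C above threshold
#' place A and C in one species even if A-C falls below it.
#'
#' @param ani square symmetric ANI matrix with genome dimnames
#' @param threshold minimum ANI (percent) for conspecificity
#' @return a `species_assignment`: named vector `species` (genome ->
#'   `"sp1"`, `"sp2"`, ... numbered by first appearance in matrix
#'   order), plus `threshold`
#' @export
ani_species <- function(ani, threshold = 95) {
  ani <- check_ani(ani)
  g <- rownames(ani)
  adj <- ani >= threshold
  diag(adj) <- TRUE
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
  memb <- comp$membership
  # renumber components by order of first appearance
  lev <- unique(memb)
  sp <- stats::setNames(paste0("sp", match(memb, lev)), g)
  structure(list(species = sp, threshold = threshold),
            class = "species_assignment")
}

#' @export
print.species_assignment <- function(x, ...) {
  tab <- table(x$species)
  cat(sprintf("species_assignment (ANI >= %g%%): %d species\n",
              x$threshold, length(tab)))
  print(tab)
  invisible(x)
}

#' Hierarchical clustering dendrogram of a genome distance matrix
#'
#' Average-linkage (UPGMA) by default.  Similarity matrices (ANI,
#' Pearson correlation) are converted to distances first (`100 - ANI`,
#' `1 - r`).  Deterministic: ties are resolved by `hclust`'s ordering of
#' the input labels.
#'
#' @param x a `distance_matrix`, or a plain symmetric matrix treated as
#'   distances
#' @param linkage linkage method passed to [stats::hclust()]
#' @return a rooted `phylo` dendrogram
#' @export
hierarchical_tree <- function(x, linkage = "average") {
  if (inherits(x, "distance_matrix")) {
    m <- switch(x$kind,
                ani = 100 - x$matrix,
                `pearson-corr` = 1 - x$matrix,
                x$matrix)
  } else m <- x
  if (any(is.na(m))) stop("distance matrix contains NA")
  diag(m) <- 0
  hc <- stats::hclust(stats::as.dist(m), method = linkage)
  ape::as.phylo(hc)
}

#' Neighbor-joining tree of a genome distance matrix
#'
#' @param x a `distance_matrix` or symmetric distance matrix with >= 3
#'   genomes
#' @return an unrooted `phylo`; negative branch lengths (a known NJ
#'   artifact) are clamped to zero with a warning
#' @export
nj_tree <- function(x) {
  m <- if (inherits(x, "distance_matrix")) x$matrix else x
  if (nrow(m) < 3) stop("need >= 3 genomes for a neighbor-joining tree")
  tr <- ape::nj(stats::as.dist(m))
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Approximate ANI from Mash distances
#'
#' The k-mer approximation `ANI ~ 100 * (1 - d)` applied elementwise to
#' a Mash distance matrix.  This is an approximation to alignment-based
#' ANI and is labelled as such in the result kind (`"ani"`); use a
#' BLAST/MUMmer ANI matrix when one is available.
#'
#' @param mash a `distance_matrix` of kind `"mash"`
#' @return a `distance_matrix` of kind `"ani"` (percent identities)
#' @export
kmer_ani <- function(mash) {
  stopifnot(inherits(mash, "distance_matrix"), mash$kind == "mash")
  m <- 100 * (1 - mash$matrix)
  diag(m) <- 100
  new_distance_matrix(m, "ani")
}
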