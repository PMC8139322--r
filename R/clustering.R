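#' Parameters of the ortholog clustering regime
#'
#' The clustering regime used throughout the package: a similarity hit
#' requires at least `identity_min` identity over the aligned columns
#' *and* at least `coverage_min` of *each* sequence covered by the
#' alignment span ("match cut-off" read as per-sequence coverage).
#' `score_min` is a raw alignment-score floor standing in for a
#' database-size-dependent E-value cut-off; it is deterministic and
#' independent of the number of sequences searched.
#'
#' @param identity_min minimum identity over aligned columns, default 0.5
#' @param coverage_min minimum aligned fraction of each sequence,
#'   default 0.5
#' @param score_min minimum raw alignment score (BLOSUM62, affine gaps)
#' @param prefilter skip pairs sharing no 4-mer before aligning; a pure
#'   speed device, validated against unfiltered clustering in the tests
#' @return a `cluster_params` list
#' @export
cluster_params <- function(identity_min = 0.5, coverage_min = 0.5,
                           score_min = 0, prefilter = TRUE) {
  if (identity_min <= 0 || identity_min > 1)
    stop("`identity_min` must be in (0, 1]")
  if (coverage_min <= 0 || coverage_min > 1)
    stop("`coverage_min` must be in (0, 1]")
  structure(list(identity_min = identity_min, coverage_min = coverage_min,
                 score_min = score_min, prefilter = isTRUE(prefilter)),
            class = "cluster_params")
}

AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

check_protein <- function(s, what) {
  if (!nzchar(s)) stop(what, " is an empty sequence")
  bad <- setdiff(strsplit(toupper(s), "")[[1]], AA_ALPHABET20)
  if (length(bad))
    stop(what, " contains non-amino-acid characters: ",
         paste(unique(bad), collapse = ""))
  invisible(TRUE)
}

align_overlap <- function(a, b) {
  Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                Biostrings::AAString(b),
                                type = "overlap",
                                substitutionMatrix = "BLOSUM62",
                                gapOpening = 11, gapExtension = 1)
}

#' Score one protein pair against the clustering thresholds
#'
#' Aligns two proteins with an ends-free ("overlap") BLOSUM62 alignment
#' (gap open 11, extend 1), computes identity over the aligned columns
#' (end gaps excluded by the alignment type) and the aligned span as a
#' fraction of each full sequence, and returns a hit only when identity,
#' both coverages and the raw score pass `params`.
#'
#' @param a,b protein sequences (character scalars, 20-letter alphabet)
#' @param params a [cluster_params()]
#' @return a one-row `data.frame` (`identity`, `coverage_a`,
#'   `coverage_b`, `score`) or `NULL` when the pair fails the thresholds
#' @examples
#' pairwise_similarity("MKVLATTT", "MKVLATTT", cluster_params())
#' @export
pairwise_similarity <- function(a, b, params = cluster_params()) {
  check_protein(a, "`a`"); check_protein(b, "`b`")
  aln <- align_overlap(a, b)
  hit <- hit_from_alignment(aln, nchar(a), nchar(b))
  if (passes(hit, params)) hit else NULL
}

hit_from_alignment <- function(aln, len_a, len_b) {
  ncols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  span_a <- Biostrings::end(Biostrings::pattern(aln)) -
    Biostrings::start(Biostrings::pattern(aln)) + 1L
  span_b <- Biostrings::end(Biostrings::subject(aln)) -
    Biostrings::start(Biostrings::subject(aln)) + 1L
  data.frame(identity = Biostrings::nmatch(aln) / ncols,
             coverage_a = span_a / len_a,
             coverage_b = span_b / len_b,
             score = Biostrings::score(aln))
}

passes <- function(hit, params) {
  hit$identity >= params$identity_min &
    pmin(hit$coverage_a, hit$coverage_b) >= params$coverage_min &
    hit$score >= params$score_min
}

shares_kmer <- function(a, b, k = 4L) {
  if (nchar(a) < k || nchar(b) < k) return(TRUE)  # never prefilter short
  ka <- substring(a, seq_len(nchar(a) - k + 1L), k:nchar(a))
  kb <- substring(b, seq_len(nchar(b) - k + 1L), k:nchar(b))
  any(ka %in% kb)
}

#' Build ortholog gene families from proteomes
#'
#' All-against-all ends-free alignment of the input proteins, a hit
#' graph restricted to inter-genome *bidirectional best hits* (two genes
#' that are each other's highest-scoring match between their genomes;
#' ties kept) plus intra-genome hits passing the thresholds
#' (in-paralogs), and families as the connected components of that
#' graph.  Every input gene lands in exactly one family; genes with no
#' edges form singleton families.  Family ids are assigned in
#' lexicographic order of each component's smallest (genome, gene) pair,
#' so the labelling is reproducible.
#'
#' @param proteomes named list genome -> [Biostrings::AAStringSet] (or
#'   named character vector) with names `<genome>|<gene>` or plain gene
#'   ids
#' @param params a [cluster_params()]
#' @return list with `families` (list of `gene_family` objects: `id`,
#'   `members` = genome -> gene ids, `copy_number`) and `matrix` (a
#'   [pa_matrix()] of copy numbers)
#' @export
build_families <- function(proteomes, params = cluster_params()) {
  if (length(proteomes) < 2) stop("need proteomes for >= 2 genomes")
  if (is.null(names(proteomes))) stop("`proteomes` must be named by genome")
  seqs <- character(0); gene_genome <- character(0)
  for (g in names(proteomes)) {
    p <- proteomes[[g]]
    s <- as.character(p)
    if (is.null(names(s))) names(s) <- names(p)
    if (!length(s)) stop("empty proteome for genome '", g, "'")
    if (is.null(names(s)))
      names(s) <- sprintf("%s|g%03d", g, seq_along(s))
    seqs <- c(seqs, s)
    gene_genome <- c(gene_genome, rep(g, length(s)))
  }
  names(gene_genome) <- names(seqs)
  if (anyDuplicated(names(seqs))) stop("duplicate gene ids across proteomes")

  hits <- all_vs_all_hits(seqs, gene_genome, params)
  edges <- bbh_edges(hits, gene_genome)
  families_from_edges(names(seqs), gene_genome, edges)
}

# upper-triangle hits passing params; returns data.frame(a, b, score).
# All patterns for one subject are aligned in a single vectorised
# pairwiseAlignment call.
all_vs_all_hits <- function(seqs, gene_genome, params) {
  ids <- names(seqs)
  n <- length(ids)
  aaset <- Biostrings::AAStringSet(seqs)
  out <- vector("list", n)
  for (j in 2:n) {
    idx <- seq_len(j - 1L)
    if (params$prefilter)
      idx <- idx[vapply(idx, function(i) shares_kmer(seqs[i], seqs[j]),
                        TRUE)]
    if (!length(idx)) next
    aln <- Biostrings::pairwiseAlignment(
      aaset[idx], Biostrings::AAString(seqs[[j]]), type = "overlap",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
    ncols <- nchar(as.character(Biostrings::alignedPattern(aln)))
    span_a <- Biostrings::end(Biostrings::pattern(aln)) -
      Biostrings::start(Biostrings::pattern(aln)) + 1L
    span_b <- Biostrings::end(Biostrings::subject(aln)) -
      Biostrings::start(Biostrings::subject(aln)) + 1L
    hit <- data.frame(identity = Biostrings::nmatch(aln) / ncols,
                      coverage_a = span_a / nchar(seqs[idx]),
                      coverage_b = span_b / nchar(seqs[[j]]),
                      score = Biostrings::score(aln))
    ok <- passes(hit, params)
    if (any(ok))
      out[[j]] <- data.frame(a = ids[idx][ok], b = ids[j],
                             score = hit$score[ok])
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(a = character(0), b = character(0),
                      score = numeric(0)))
  do.call(rbind, out)
}

# inter-genome BBH (ties kept) + intra-genome hits
bbh_edges <- function(hits, gene_genome) {
  if (!nrow(hits)) return(hits[, c("a", "b")])
  ga <- gene_genome[hits$a]; gb <- gene_genome[hits$b]
  intra <- hits[ga == gb, c("a", "b")]
  inter <- hits[ga != gb, , drop = FALSE]
  if (nrow(inter)) {
    # duplicate each hit in both directions: query gene -> target genome
    dir <- rbind(data.frame(q = inter$a, t = inter$b, score = inter$score),
                 data.frame(q = inter$b, t = inter$a, score = inter$score))
    dir$tg <- gene_genome[dir$t]
    key <- paste(dir$q, dir$tg)
    best <- stats::ave(dir$score, key, FUN = max)
    dir <- dir[dir$score >= best - 1e-9, ]
    fwd <- paste(dir$q, dir$t)
    rev <- paste(dir$t, dir$q)
    keep <- fwd %in% rev
    bbh <- dir[keep & dir$q < dir$t, c("q", "t")]
    names(bbh) <- c("a", "b")
  } else {
    bbh <- inter[, c("a", "b")]
  }
  rbind(intra, bbh)
}

families_from_edges <- function(genes, gene_genome, edges) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = genes)
  comp <- igraph::components(g)$membership[genes]
  # reproducible family order: by smallest (genome, gene) member
  keyfun <- function(members)
    min(paste(gene_genome[members], members))
  groups <- split(genes, comp)
  ord <- order(vapply(groups, keyfun, ""))
  groups <- groups[ord]
  fam_ids <- sprintf("F%05d", seq_along(groups))
  genomes <- sort(unique(gene_genome))
  counts <- matrix(0L, length(groups), length(genomes),
                   dimnames = list(fam_ids, genomes))
  families <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    members <- split(groups[[i]], gene_genome[groups[[i]]])
    cn <- lengths(members)
    counts[i, names(cn)] <- as.integer(cn)
    families[[i]] <- structure(list(id = fam_ids[i], members = members,
                                    copy_number = cn),
                               class = "gene_family")
  }
  names(families) <- fam_ids
  list(families = families, matrix = pa_matrix(counts))
}

#' Single-copy core families
#'
#' Families present in every genome of `genome_list` with exactly one
#' gene copy per genome -- the input for core-gene phylogenetics.
#'
#' @param families `families` element of [build_families()] output
#' @param genome_list genome ids the core must span
#' @return subset of `families`
#' @export
single_copy_core <- function(families, genome_list) {
  keep <- vapply(families, function(f) {
    all(genome_list %in% names(f$copy_number)) &&
      all(f$copy_number[genome_list] == 1L)
  }, TRUE)
  families[keep]
}

#' Distance tree from concatenated single-copy core families
#'
#' For each genome pair, the p-distance (mean per-site mismatch over the
#' non-gap columns of global pairwise alignments) is averaged across the
#' single-copy core families, and a neighbor-joining tree is built from
#' the resulting matrix.  This is a fast distance-based stand-in for a
#' maximum-likelihood core-gene phylogeny.
#'
#' @param families single-copy core families ([single_copy_core()])
#' @param proteomes named list genome -> sequences as in
#'   [build_families()]
#' @return an unrooted `phylo`
#' @export
concat_distance_tree <- function(families, proteomes) {
  genomes <- names(proteomes)
  if (length(genomes) < 3) stop("need >= 3 genomes for a tree")
  if (!length(families)) stop("no single-copy core families")
  seqs <- unlist(lapply(proteomes, as.character))
  names(seqs) <- unlist(lapply(proteomes, names))
  n <- length(genomes)
  d <- matrix(0, n, n, dimnames = list(genomes, genomes))
  tot <- matrix(0, n, n); mis <- matrix(0, n, n)
  for (f in families) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      sa <- seqs[f$members[[genomes[i]]][1]]
      sb <- seqs[f$members[[genomes[j]]][1]]
      pd <- p_distance(sa, sb)
      mis[i, j] <- mis[i, j] + pd["mismatch"]
      tot[i, j] <- tot[i, j] + pd["sites"]
    }
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- if (tot[i, j] > 0) mis[i, j] / tot[i, j] else 0
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# mismatches and compared sites over the non-gap columns of a global
# alignment
p_distance <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                       Biostrings::AAString(b),
                                       type = "global",
                                       substitutionMatrix = "BLOSUM62",
                                       gapOpening = 11, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ok <- pa != "-" & pb != "-"
  c(mismatch = sum(pa[ok] != pb[ok]), sites = sum(ok))
}
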