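#' COG functional categories used by the simulator
#'
#' The 23 single-letter COG categories commonly observed in bacterial
#' genomes (the rare eukaryote-leaning categories A and B are excluded)
#' plus the pseudo-category `"unknown"` for unannotated families.
#'
#' @return character vector of length 24
#' @export
cog_categories <- function() {
  c("J", "K", "L",                          # information storage
    "D", "V", "T", "M", "N", "U", "O",     # cellular processes
    "W", "Y", "Z",
    "C", "G", "E", "F", "H", "I", "P", "Q", # metabolism
    "R", "S",                               # poorly characterized
    "unknown")
}

#' Default COG category weights
#'
#' A plausible bacterial category distribution: about a quarter of
#' families unannotated, general-function/unknown-function (R, S) and
#' the large metabolic and regulatory categories (E, G, K, P) most
#' frequent among the rest.  Used when [sim_config()] is not given an
#' explicit weight vector.
#'
#' @return named numeric vector over [cog_categories()], summing to 1
#' @export
default_cog_weights <- function() {
  w <- c(J = 5, K = 8, L = 4,
         D = 1.2, V = 2, T = 3, M = 6, N = 1.5, U = 1.5, O = 3,
         W = 0.3, Y = 0.2, Z = 0.3,
         C = 5, G = 6, E = 9, F = 2.5, H = 3.5, I = 3, P = 5, Q = 2.5,
         R = 10, S = 8, unknown = 25)
  w <- w[cog_categories()]
  w / sum(w)
}

#' Configuration for the synthetic pan-genome simulator
#'
#' Collects all parameters of the generative model: a clade of
#' `n_genomes` genomes related by a random tree, with a fixed core
#' genome, accessory families gained once on a branch (infinitely-many-
#' genes style) and lost independently along descendant branches, an
#' optional set of planted niche-specific families, and COG labels drawn
#' from a category distribution.
#'
#' The defaults emulate the genome statistics of a ~50-strain
#' *Bacillus pumilus*-group clade: 52 genomes, a 2,370-family core, and
#' gain/loss rates calibrated so that genomes carry about 3,700 gene
#' families each (see the methods vignette for the calibration).
#'
#' @param n_genomes number of genomes (>= 2)
#' @param core_size number of families present in every genome
#' @param accessory_pool cap on the number of distinct accessory
#'   families; `Inf` (default) leaves gains uncapped
#' @param gain_rate expected gene-family gains per unit branch length
#' @param loss_rate per-family loss rate per unit branch length below
#'   the gain point
#' @param tree_shape `"random-coalescent"` or `"balanced"`
#' @param marine_fraction fraction of genomes labelled `"marine"`; the
#'   remainder are `"land"`
#' @param niche_mode `"clustered"` assigns contiguous blocks of the
#'   tree's tip order to the same niche (marine isolates cluster
#'   together); `"shuffled"` randomizes labels as a null model
#' @param niche_labels optional named character vector genome -> niche
#'   overriding the automatic assignment; must cover all genomes
#' @param planted_niche_families named count vector
#'   `c(marine = ..., land = ...)` of niche-specific families to plant
#' @param planted_presence_fraction fraction of the focal niche's
#'   genomes carrying each planted family (families are absent from the
#'   contrasting niche by construction)
#' @param cog_weights named probability vector over [cog_categories()]
#' @param n_species number of species labels, assigned to monophyletic
#'   groups of the simulated tree
#' @param seed root seed; all stage-level streams are derived from it
#' @return a `sim_config` list
#' @seealso [simulate_pangenome()], [calibrate_gain_rate()]
#' @export
sim_config <- function(n_genomes = 52,
                       core_size = 2370,
                       accessory_pool = Inf,
                       gain_rate = 1045,
                       loss_rate = 0.3,
                       tree_shape = c("random-coalescent", "balanced"),
                       marine_fraction = 20 / 52,
                       niche_mode = c("clustered", "shuffled"),
                       niche_labels = NULL,
                       planted_niche_families = c(marine = 0, land = 0),
                       planted_presence_fraction = 0.5,
                       cog_weights = default_cog_weights(),
                       n_species = 3,
                       seed = 1) {
  tree_shape <- match.arg(tree_shape)
  niche_mode <- match.arg(niche_mode)
  if (n_genomes < 2) stop("`n_genomes` must be >= 2")
  if (core_size < 0) stop("`core_size` must be >= 0")
  if (gain_rate < 0 || loss_rate < 0) stop("rates must be >= 0")
  if (abs(sum(cog_weights) - 1) > 1e-8)
    stop("`cog_weights` must sum to 1")
  if (!all(cog_categories() %in% names(cog_weights)))
    stop("`cog_weights` must be named over cog_categories()")
  if (marine_fraction < 0 || marine_fraction > 1)
    stop("`marine_fraction` must be in [0, 1]")
  p <- planted_niche_families
  if (!all(c("marine", "land") %in% names(p)))
    stop("`planted_niche_families` needs `marine` and `land` entries")
  if (planted_presence_fraction <= 0 || planted_presence_fraction > 1)
    stop("`planted_presence_fraction` must be in (0, 1]")
  structure(list(n_genomes = as.integer(n_genomes),
                 core_size = as.integer(core_size),
                 accessory_pool = accessory_pool,
                 gain_rate = gain_rate, loss_rate = loss_rate,
                 tree_shape = tree_shape,
                 marine_fraction = marine_fraction,
                 niche_mode = niche_mode,
                 niche_labels = niche_labels,
                 planted_niche_families = p,
                 planted_presence_fraction = planted_presence_fraction,
                 cog_weights = cog_weights,
                 n_species = as.integer(n_species),
                 seed = seed),
            class = "sim_config")
}

genome_labels <- function(n) sprintf("G%02d", seq_len(n))

#' Simulate a genome phylogeny
#'
#' @param n_genomes number of leaves (>= 2)
#' @param shape `"random-coalescent"` (a Kingman coalescent via
#'   [ape::rcoal()]) or `"balanced"` (a maximally balanced topology with
#'   uniform random branch lengths)
#' @param seed integer seed; the tree is reproducible from it
#' @return a rooted binary `phylo` with positive branch lengths and tips
#'   `G01 ... Gnn`
#' @export
simulate_tree <- function(n_genomes,
                          shape = c("random-coalescent", "balanced"),
                          seed = 1) {
  shape <- match.arg(shape)
  if (n_genomes < 2) stop("`n_genomes` must be >= 2")
  labels <- genome_labels(n_genomes)
  with_seed(derive_seed(seed, "tree"), {
    if (shape == "random-coalescent") {
      tr <- ape::rcoal(n_genomes, tip.label = labels)
    } else {
      nwk <- paste0(balanced_newick(labels), ";")
      tr <- ape::read.tree(text = nwk)
      tr$edge.length <- stats::runif(nrow(tr$edge), 0.5, 1.5) / n_genomes
    }
    tr
  })
}

balanced_newick <- function(labels) {
  n <- length(labels)
  if (n == 1) return(labels)
  k <- ceiling(n / 2)
  paste0("(", balanced_newick(labels[seq_len(k)]), ",",
         balanced_newick(labels[(k + 1):n]), ")")
}

# niche assignment: contiguous blocks of the tree's tip order (marine
# isolates form clades) or a random shuffle as a null.
assign_niches <- function(tree, config) {
  if (!is.null(config$niche_labels)) {
    lab <- config$niche_labels
    missing <- setdiff(tree$tip.label, names(lab))
    if (length(missing))
      stop("`niche_labels` does not cover genomes: ",
           paste(missing, collapse = ", "))
    return(lab[tree$tip.label])
  }
  n <- length(tree$tip.label)
  n_marine <- round(config$marine_fraction * n)
  tr <- ape::reorder.phylo(tree, "cladewise")
  ord <- tr$tip.label[tr$edge[tr$edge[, 2] <= n, 2]]
  niche <- stats::setNames(rep("land", n), ord)
  if (n_marine > 0) niche[seq_len(n_marine)] <- "marine"
  if (config$niche_mode == "shuffled")
    names(niche) <- sample(names(niche))
  niche[tree$tip.label]
}

# species labels: average-linkage clusters of the cophenetic distance,
# cut at n_species groups (monophyletic on ultrametric trees).
species_from_tree <- function(tree, n_species) {
  n <- length(tree$tip.label)
  k <- min(n_species, n)
  if (k <= 1) return(stats::setNames(rep("S1", n), tree$tip.label))
  d <- stats::as.dist(ape::cophenetic.phylo(tree))
  cl <- stats::cutree(stats::hclust(d, method = "average"), k = k)
  stats::setNames(paste0("S", cl), names(cl))[tree$tip.label]
}

#' Simulate gene content on a phylogeny
#'
#' Core families are present in every genome.  Accessory families arise
#' once, at a uniform position on a random branch (gains are Poisson
#' with rate `gain_rate` per unit length), and are subsequently lost
#' along descendant branches at rate `loss_rate`; a loss removes the
#' family from the whole subtree below it.  Planted niche-specific
#' families are inserted into a fixed fraction of one niche's genomes
#' and kept absent from the other niche.
#'
#' @param tree a `phylo` as returned by [simulate_tree()]
#' @param config a [sim_config()]; its `seed` drives this stage
#' @return list with elements `matrix` (a [pa_matrix()] with niche and
#'   species metadata) and `truth` (a `sim_truth` list: per-family class
#'   labels `core`/`dispensable`/`unique`, planted family ids per niche,
#'   the generating tree, per-genome gene counts, and the niche and
#'   species assignments)
#' @export
simulate_gene_content <- function(tree, config) {
  stopifnot(inherits(config, "sim_config"))
  genomes <- tree$tip.label
  n <- length(genomes)
  niche <- assign_niches(tree, config)
  if (!all(niche %in% c("marine", "land")))
    stop("niche labels must be 'marine' or 'land'")
  species <- species_from_tree(tree, config$n_species)

  with_seed(derive_seed(config$seed, "content"), {
    fam_rows <- list()
    # core: all genomes
    if (config$core_size > 0) {
      core_ids <- sprintf("C%04d", seq_len(config$core_size))
      fam_rows$core <- matrix(1L, config$core_size, n,
                              dimnames = list(core_ids, genomes))
    }
    # accessory: single gain, exponential loss below
    acc <- simulate_accessory(tree, config$gain_rate, config$loss_rate,
                              config$accessory_pool)
    if (nrow(acc)) {
      rownames(acc) <- sprintf("A%05d", seq_len(nrow(acc)))
      colnames(acc) <- genomes
      fam_rows$accessory <- acc
    }
    # planted niche-specific families
    planted <- list(marine = character(0), land = character(0))
    for (nich in c("marine", "land")) {
      np <- config$planted_niche_families[[nich]]
      if (np < 1) next
      focal <- genomes[niche == nich]
      if (!length(focal))
        stop("cannot plant ", nich, " families: no ", nich, " genomes")
      m <- max(1L, ceiling(config$planted_presence_fraction * length(focal)))
      ids <- sprintf("%s%04d", toupper(substr(nich, 1, 1)), seq_len(np))
      block <- matrix(0L, np, n, dimnames = list(ids, genomes))
      for (i in seq_len(np))
        block[i, sample(focal, m)] <- 1L
      planted[[nich]] <- ids
      fam_rows[[paste0("planted_", nich)]] <- block
    }
    counts <- do.call(rbind, fam_rows)
    if (is.null(counts))
      stop("simulation produced no families; increase core_size or gain_rate")
    occ <- rowSums(counts > 0L)
    keep <- occ > 0L
    counts <- counts[keep, , drop = FALSE]
    occ <- occ[keep]
    classes <- ifelse(occ == n, "core",
                      ifelse(occ == 1L & n > 1L, "unique", "dispensable"))
    names(classes) <- rownames(counts)
    meta <- data.frame(genome = genomes, niche = unname(niche[genomes]),
                       species = unname(species[genomes]),
                       stringsAsFactors = FALSE)
    mat <- pa_matrix(counts, meta)
    truth <- structure(list(classes = classes, planted = planted,
                            tree = tree,
                            genes_per_genome = colSums(counts),
                            niche = niche, species = species),
                       class = "sim_truth")
    list(matrix = mat, truth = truth)
  })
}

# presence matrix (families x leaves) of the gained accessory families.
simulate_accessory <- function(tree, gain_rate, loss_rate, pool = Inf) {
  n <- length(tree$tip.label)
  edge <- tree$edge
  len <- tree$edge.length
  children <- split(seq_len(nrow(edge)), edge[, 1])  # node -> child edges
  rows <- list()
  for (e in seq_len(nrow(edge))) {
    ngain <- stats::rpois(1L, gain_rate * len[e])
    if (!ngain) next
    for (g in seq_len(ngain)) {
      u <- stats::runif(1, 0, len[e])   # gain position from the top
      pres <- rep(0L, n)
      # survive the remainder of the gain edge, then descend
      if (stats::runif(1) < exp(-loss_rate * (len[e] - u)))
        pres <- descend_presence(edge[e, 2], edge, len, children,
                                 loss_rate, n, pres)
      rows[[length(rows) + 1L]] <- pres
    }
  }
  if (length(rows) > pool) rows <- rows[seq_len(pool)]
  if (!length(rows)) return(matrix(0L, 0, n))
  do.call(rbind, rows)
}

descend_presence <- function(node, edge, len, children, loss_rate, n, pres) {
  if (node <= n) { pres[node] <- 1L; return(pres) }
  for (e in children[[as.character(node)]]) {
    if (stats::runif(1) < exp(-loss_rate * len[e]))
      pres <- descend_presence(edge[e, 2], edge, len, children,
                               loss_rate, n, pres)
  }
  pres
}

#' Simulate a full synthetic pan-genome
#'
#' Convenience wrapper: [simulate_tree()] then [simulate_gene_content()]
#' then [emit_cog_labels()], all driven by the config's root seed.
#'
#' @param config a [sim_config()]
#' @return list with `matrix`, `truth`, `tree`, `cog` (family ->
#'   category table) and `config`
#' @examples
#' sim <- simulate_pangenome(sim_config(n_genomes = 8, core_size = 50,
#'                                      gain_rate = 120, seed = 7))
#' sim$matrix
#' @export
simulate_pangenome <- function(config = sim_config()) {
  tree <- simulate_tree(config$n_genomes, config$tree_shape, config$seed)
  gc <- simulate_gene_content(tree, config)
  cog <- emit_cog_labels(gc$matrix, config$cog_weights, seed = config$seed)
  list(matrix = gc$matrix, truth = gc$truth, tree = tree, cog = cog,
       config = config)
}

#' Calibrate the gain rate against a target genome size
#'
#' Mean gene families per genome scale linearly in `gain_rate` for fixed
#' tree law and `loss_rate` (each gained family contributes
#' independently).  A pilot simulation measures accessory families per
#' genome per unit gain rate, and the rate is rescaled to hit the
#' target.
#'
#' @param config a [sim_config()] whose `gain_rate` seeds the pilot
#' @param target_mean_genes desired mean gene families per genome
#' @param n_rep pilot replicates (different derived seeds)
#' @return calibrated gain rate (numeric)
#' @export
calibrate_gain_rate <- function(config, target_mean_genes, n_rep = 5) {
  stopifnot(target_mean_genes > config$core_size)
  acc <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0("calibrate", r))
    sim <- simulate_pangenome(cfg)
    acc[r] <- mean(sim$truth$genes_per_genome) - cfg$core_size
  }
  per_unit <- mean(acc) / config$gain_rate
  (target_mean_genes - config$core_size) / per_unit
}

#' Emit synthetic proteomes for a presence/absence matrix
#'
#' Each family gets a random ancestral protein (uniform residues, length
#' uniform on 100--400 aa); every member is an independently
#' point-mutated copy such that the expected *pairwise* identity between
#' members equals `identity_within_family`.  Ancestors of different
#' families are independent random sequences, so inter-family identity
#' stays far below common clustering thresholds.  Gene ids are
#' `<family>.<copy>` and FASTA headers are `<genome>|<gene>`.
#'
#' @param matrix a [pa_matrix()]
#' @param identity_within_family expected pairwise identity within a
#'   family, in (0.5, 1]; values <= 0.5 are allowed but warn, because
#'   such families will fragment under a 50% clustering threshold
#' @param seed integer seed
#' @param dir optional directory; if given, one `<genome>.faa` protein
#'   FASTA per genome is written there
#' @param length_range ancestral sequence length range (aa)
#' @return named list genome -> [Biostrings::AAStringSet], invisibly if
#'   `dir` is given
#' @export
emit_proteomes <- function(matrix, identity_within_family = 0.9,
                           seed = 1, dir = NULL,
                           length_range = c(100L, 400L)) {
  stopifnot(inherits(matrix, "pa_matrix"))
  p <- identity_within_family
  if (p <= 0 || p > 1)
    stop("`identity_within_family` must be in (0, 1]")
  if (p <= 0.5)
    warning("identity_within_family <= 0.5: families will fragment under ",
            "the default 50% clustering threshold")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  # per-member mutation rate m such that pairwise identity
  # (1-m)^2 + m^2/19 equals p (two independent branches from the
  # ancestor, 1/19 chance of convergent substitution)
  m <- (2 - sqrt(4 - 4 * (20 / 19) * (1 - p))) / (2 * 20 / 19)
  counts <- matrix$counts
  genomes <- colnames(counts)
  with_seed(derive_seed(seed, "proteomes"), {
    fam_len <- sample(length_range[1]:length_range[2], nrow(counts),
                      replace = TRUE)
    ancestors <- lapply(fam_len, function(L) sample(aa, L, replace = TRUE))
    names(ancestors) <- rownames(counts)
    out <- stats::setNames(vector("list", length(genomes)), genomes)
    for (g in genomes) {
      present <- which(counts[, g] > 0L)
      seqs <- character(0)
      for (f in present) {
        anc <- ancestors[[f]]
        for (k in seq_len(counts[f, g])) {
          s <- anc
          hit <- stats::runif(length(s)) < m
          if (any(hit))
            s[hit] <- vapply(s[hit],
                             function(r) sample(setdiff(aa, r), 1L), "")
          gene <- sprintf("%s.%d", rownames(counts)[f], k)
          seqs[paste0(g, "|", gene)] <- paste(s, collapse = "")
        }
      }
      out[[g]] <- Biostrings::AAStringSet(seqs)
    }
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      for (g in genomes)
        Biostrings::writeXStringSet(out[[g]],
                                    file.path(dir, paste0(g, ".faa")))
      return(invisible(out))
    }
    out
  })
}

#' Draw COG category labels for gene families
#'
#' Each family receives exactly one category from `weights` (a
#' distribution over [cog_categories()], including `"unknown"`).  An
#' optional skew multiplies the weight of selected categories for a
#' stated set of families -- typically the planted niche-specific
#' families -- before renormalisation, planting a functional enrichment
#' signal of known strength.
#'
#' @param matrix a [pa_matrix()]
#' @param weights named probability vector over [cog_categories()]
#' @param skew optional list with elements `families` (ids), `categories`
#'   (letters) and `factor` (multiplier > 0)
#' @param seed integer seed
#' @return `data.frame(family, category)`
#' @export
emit_cog_labels <- function(matrix, weights = default_cog_weights(),
                            skew = NULL, seed = 1) {
  stopifnot(inherits(matrix, "pa_matrix"))
  if (abs(sum(weights) - 1) > 1e-8) stop("`weights` must sum to 1")
  cats <- names(weights)
  fams <- rownames(matrix$counts)
  with_seed(derive_seed(seed, "cog"), {
    lab <- sample(cats, length(fams), replace = TRUE, prob = weights)
    names(lab) <- fams
    if (!is.null(skew)) {
      stopifnot(all(c("families", "categories", "factor") %in% names(skew)),
                skew$factor > 0)
      w2 <- weights
      w2[skew$categories] <- w2[skew$categories] * skew$factor
      w2 <- w2 / sum(w2)
      tgt <- intersect(skew$families, fams)
      lab[tgt] <- sample(cats, length(tgt), replace = TRUE, prob = w2)
    }
    data.frame(family = fams, category = unname(lab),
               stringsAsFactors = FALSE)
  })
}

#' Simulate an ANI matrix consistent with species labels
#'
#' Average nucleotide identities are drawn uniformly from `within` for
#' same-species pairs and from `between` for cross-species pairs, with
#' 100 on the diagonal; the matrix is symmetric.  This stands in for a
#' BLAST/MUMmer ANI computation, which the package consumes but does not
#' perform.
#'
#' @param species named character vector genome -> species
#' @param within,between ANI ranges (percent) for same-species and
#'   cross-species pairs
#' @param seed integer seed
#' @return symmetric numeric matrix with genome dimnames
#' @export
simulate_ani <- function(species, within = c(96, 99.5),
                         between = c(86, 91), seed = 1) {
  g <- names(species)
  n <- length(g)
  with_seed(derive_seed(seed, "ani"), {
    m <- matrix(100, n, n, dimnames = list(g, g))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      rng <- if (species[i] == species[j]) within else between
      m[i, j] <- m[j, i] <- stats::runif(1, rng[1], rng[2])
    }
    m
  })
}
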