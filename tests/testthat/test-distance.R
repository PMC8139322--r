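random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

revcomp_chr <- function(s)
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")

mutate_dna <- function(s, rate, seed) {
  set.seed(seed)
  v <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  v[hit] <- vapply(v[hit],
                   function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                   "")
  paste(v, collapse = "")
}

sketch_of <- function(hashes, k = 21, s = Inf) {
  structure(list(genome = "x", k = k, s = s,
                 hashes = sort(unique(hashes))), class = "sketch")
}

test_that("sketches are canonical, capped and deterministic", {
  g <- random_dna(500, 1)
  sk_f <- sketch_genome(g, k = 15, s = 100, genome_id = "f")
  sk_r <- sketch_genome(revcomp_chr(g), k = 15, s = 100, genome_id = "r")
  expect_identical(sk_f$hashes, sk_r$hashes)
  expect_lte(length(sk_f$hashes), 100)
  expect_identical(sk_f$hashes,
                   sketch_genome(g, k = 15, s = 100)$hashes)

  # s >= number of distinct k-mers: sketch is the full k-mer hash set
  full <- sketch_genome(g, k = 15, s = Inf)
  expect_equal(length(full$hashes),
               length(oracle_canonical_kmers(g, 15)))
  big_s <- sketch_genome(g, k = 15, s = 10000)
  expect_identical(big_s$hashes, full$hashes)

  expect_error(sketch_genome("ACGT", k = 21), "shorter than k")
})

test_that("the sketch Jaccard estimator is unbiased against exact k-mer sets", {
  a <- random_dna(2000, 11)
  b <- mutate_dna(a, 0.03, 12)
  k <- 16
  j_exact <- oracle_jaccard(a, b, k)
  ests <- vapply(1:200, function(sd) {
    sa <- sketch_genome(a, k = k, s = 100, seed = sd)
    sb <- sketch_genome(b, k = k, s = 100, seed = sd)
    merged <- sort(unique(c(sa$hashes, sb$hashes)))[1:100]
    sum(merged %in% sa$hashes & merged %in% sb$hashes) / 100
  }, 0)
  se <- sqrt(j_exact * (1 - j_exact) / 100) / sqrt(200)
  expect_lt(abs(mean(ests) - j_exact), 2 * se + 1e-9)
})

test_that("mash distance follows the closed form and premetric axioms", {
  g <- random_dna(800, 5)
  sk <- sketch_genome(g, k = 21, s = 200)
  expect_equal(mash_distance(sk, sk), 0)

  # exact Jaccard 1/3 at k = 21: d = ln(2)/21
  s1 <- sketch_of(c(1, 2, 3, 4))
  s2 <- sketch_of(c(3, 4, 5, 6))
  expect_equal(mash_distance(s1, s2), log(2) / 21, tolerance = 1e-12)

  # disjoint sets: capped at 1
  expect_equal(mash_distance(sketch_of(1:4), sketch_of(11:14)), 1)

  # symmetry and non-negativity on random sketches
  for (sd in 1:5) {
    a <- sketch_genome(random_dna(600, sd), k = 15, s = 50)
    b <- sketch_genome(random_dna(600, sd + 50), k = 15, s = 50)
    expect_gte(mash_distance(a, b), 0)
    expect_equal(mash_distance(a, b), mash_distance(b, a))
  }

  expect_error(mash_distance(sketch_of(1:3, k = 15), sketch_of(1:3, k = 21)),
               "different k")
})

test_that("ANI profile correlation ranks within-species pairs first", {
  ani <- matrix(c(100, 98, 89, 89,
                  98, 100, 89, 89,
                  89, 89, 100, 98,
                  89, 89, 98, 100), 4, byrow = TRUE,
                dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  cc <- ani_correlation(ani)
  expect_equal(cc$kind, "pearson-corr")
  expect_gt(cc$matrix["g1", "g2"], cc$matrix["g1", "g3"])
  expect_lt(cc$matrix["g1", "g3"], 0)   # anti-correlated blocks

  # genomes with identical ANI profiles correlate perfectly
  ani5 <- rbind(ani, g5 = ani["g1", ])
  ani5 <- cbind(ani5, g5 = c(ani["g1", ], 100))
  ani5["g1", "g5"] <- ani5["g5", "g1"] <- 100
  cc5 <- ani_correlation(ani5)
  expect_equal(unname(cc5$matrix["g1", "g5"]), 1, tolerance = 1e-12)

  expect_error(ani_correlation(ani[, 1:3]), "square")
})

test_that("ANI species components obey threshold and ordering invariance", {
  blocks <- matrix(89, 6, 6, dimnames = list(sprintf("g%d", 1:6),
                                             sprintf("g%d", 1:6)))
  blocks[1:3, 1:3] <- 98; blocks[4:6, 4:6] <- 98; diag(blocks) <- 100
  sp <- ani_species(blocks, 95)
  expect_length(unique(sp$species), 2)
  expect_length(unique(sp$species[1:3]), 1)

  one <- matrix(98, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(one) <- 100
  expect_length(unique(ani_species(one)$species), 1)

  # transitive chain: A-B 96, B-C 96, A-C 90 -> one species
  chain <- matrix(c(100, 96, 90, 96, 100, 96, 90, 96, 100), 3,
                  dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  expect_length(unique(ani_species(chain, 95)$species), 1)

  # genome order invariance
  ord <- c(5, 2, 6, 1, 3, 4)
  sp2 <- ani_species(blocks[ord, ord], 95)
  same <- function(a) outer(a, a, "==")
  expect_equal(unname(same(sp2$species[rownames(blocks)])),
               unname(same(sp$species)))

  # raising the threshold never merges clusters
  n_cl <- vapply(c(88, 92, 95, 99), function(th)
    length(unique(ani_species(blocks, th)$species)), 0L)
  expect_true(all(diff(n_cl) >= 0))
})

test_that("species calls on simulated ANI recover the simulated species", {
  sim <- small_sim(6, n_genomes = 9, n_species = 3)
  ani <- simulate_ani(sim$truth$species, within = c(96, 99),
                      between = c(86, 91), seed = 8)
  sp <- ani_species(ani, 95)
  same <- function(a) outer(a, a, "==")
  expect_equal(unname(same(sp$species)),
               unname(same(sim$truth$species[names(sp$species)])))
})

test_that("hierarchical clustering reproduces UPGMA geometry", {
  d3 <- matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3,
               dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  tr <- hierarchical_tree(d3)
  parts <- ape::prop.part(tr)
  tips <- lapply(parts, function(p) sort(attr(parts, "labels")[p]))
  expect_true(any(vapply(tips, identical, TRUE, c("A", "B"))))

  # ultrametric 4-leaf matrix: merge heights are half the distances
  d4 <- matrix(c(0, 2, 6, 6,
                 2, 0, 6, 6,
                 6, 6, 0, 4,
                 6, 6, 4, 0), 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr4 <- hierarchical_tree(d4)
  expect_equal(ape::Ntip(tr4), 4)
  # each leaf sits at half its pairwise distance from the merge point,
  # so tip-to-tip path lengths reproduce the ultrametric matrix
  cop <- ape::cophenetic.phylo(tr4)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(cop, d4, ignore_attr = TRUE)

  # label permutation leaves the topology unchanged
  ord <- c(3, 1, 4, 2)
  tr4p <- hierarchical_tree(d4[ord, ord])
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr4),
                                         ape::unroot(tr4p))), 0)

  dna <- d4; dna[1, 2] <- NA
  expect_error(hierarchical_tree(dna), "NA")
})

test_that("neighbor joining recovers additive metrics", {
  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
               dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  tr <- nj_tree(d3)
  bl <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                        tr$tip.label)
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 1, 3))

  # additive 4-taxon metric: ((A,B),(C,D)) with internal branch 1
  d4 <- matrix(c(0, 2, 5, 5,
                 2, 0, 5, 5,
                 5, 5, 0, 2,
                 5, 5, 2, 0), 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr4 <- nj_tree(d4)
  parts <- ape::prop.part(tr4)
  tips <- lapply(parts, function(p) sort(attr(parts, "labels")[p]))
  expect_true(any(vapply(tips, identical, TRUE, c("A", "B"))) ||
                any(vapply(tips, identical, TRUE, c("C", "D"))))

  # equidistant points: star-like, zero internal branches after clamping
  ds <- matrix(2, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(ds) <- 0
  trs <- suppressWarnings(nj_tree(ds))
  internal <- trs$edge[, 2] > ape::Ntip(trs)
  expect_true(all(abs(trs$edge.length[internal]) < 1e-9))

  expect_error(nj_tree(d3[1:2, 1:2]), ">= 3")
})

test_that("mash distance matrices feed the tree builders end to end", {
  base <- random_dna(1500, 33)
  g <- list(A = base,
            B = mutate_dna(base, 0.01, 34),
            C = mutate_dna(base, 0.01, 35),
            D = mutate_dna(base, 0.15, 36))
  sks <- lapply(names(g), function(nm)
    sketch_genome(g[[nm]], k = 15, s = 200, genome_id = nm))
  dm <- mash_distance_matrix(sks)
  expect_true(isSymmetric(dm$matrix))
  expect_true(all(diag(dm$matrix) == 0))
  # the diverged genome is farthest from everything
  expect_gt(min(dm$matrix["D", c("A", "B", "C")]),
            max(dm$matrix["A", c("B", "C")]))
  ani <- kmer_ani(dm)
  expect_equal(ani$kind, "ani")
  sp <- ani_species(ani$matrix, 95)
  expect_length(unique(sp$species[c("A", "B", "C")]), 1)
  expect_false(sp$species["D"] == sp$species["A"])
  tr <- nj_tree(dm)
  expect_equal(ape::Ntip(tr), 4)
})
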