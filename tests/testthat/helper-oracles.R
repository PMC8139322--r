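# Independent oracles used by the tests.  These deliberately avoid the
# package's own code paths: the aligner is a plain-R Gotoh DP, Jaccard
# is computed from literal k-mer strings, Fisher p by hypergeometric
# enumeration, and rarefaction means by exhaustive enumeration of
# genome orderings.

# ends-free (overlap) affine-gap alignment oracle, BLOSUM62, gap
# open 11 / extend 1 (a gap of length L costs 11 + L).  Returns score,
# identity over aligned columns and per-sequence coverage.
oracle_align <- function(a, b, open = 11, ext = 1) {
  sm <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    as.matrix(e$BLOSUM62)
  })
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  B <- matrix(0, n + 1, m + 1)   # best of the three states
  B[1, ] <- 0; B[, 1] <- 0       # free end gaps
  for (i in 1:n) for (j in 1:m) {
    M[i + 1, j + 1] <- sm[av[i], bv[j]] + B[i, j]
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
    B[i + 1, j + 1] <- max(M[i + 1, j + 1], X[i + 1, j + 1],
                           Y[i + 1, j + 1])
  }
  # best cell on the last row or column
  ends <- rbind(cbind(n + 1, 1:(m + 1)), cbind(1:n, m + 1))
  sc <- B[ends]
  best <- ends[which.max(sc), ]
  score <- max(sc)
  # traceback for identity/coverage
  i <- best[1]; j <- best[2]
  matches <- cols <- 0
  i_end <- i - 1; j_end <- j - 1
  state <- c("M", "X", "Y")[which.max(c(M[i, j], X[i, j], Y[i, j]))]
  while (i > 1 && j > 1) {
    cols <- cols + 1
    if (state == "M") {
      if (av[i - 1] == bv[j - 1]) matches <- matches + 1
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      if (max(prev) <= 0 && B[i - 1, j - 1] == 0) { i <- i - 1; j <- j - 1; break }
      state <- c("M", "X", "Y")[which.max(prev)]
      i <- i - 1; j <- j - 1
    } else if (state == "X") {
      from_m <- M[i - 1, j] - open - ext
      state <- if (X[i, j] == from_m ||
                   from_m >= X[i - 1, j] - ext) "M" else "X"
      i <- i - 1
    } else {
      from_m <- M[i, j - 1] - open - ext
      state <- if (Y[i, j] == from_m ||
                   from_m >= Y[i, j - 1] - ext) "M" else "Y"
      j <- j - 1
    }
  }
  list(score = score, identity = matches / cols,
       coverage_a = (i_end - (i - 1)) / n,
       coverage_b = (j_end - (j - 1)) / m)
}

# exact canonical k-mer set of a nucleotide sequence
oracle_canonical_kmers <- function(s, k) {
  s <- toupper(s)
  revcomp <- function(x)
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]),
          collapse = "")
  km <- substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
  km <- km[!grepl("[^ACGT]", km)]
  unique(vapply(km, function(x) {
    rc <- revcomp(x)
    if (x <= rc) x else rc
  }, "", USE.NAMES = FALSE))
}

oracle_jaccard <- function(s1, s2, k) {
  a <- oracle_canonical_kmers(s1, k); b <- oracle_canonical_kmers(s2, k)
  length(intersect(a, b)) / length(union(a, b))
}

# two-sided Fisher p for the 2x2 table rbind(c(a_in, b_in),
# c(a_out, b_out)) by summing all hypergeometric outcomes with
# probability <= the observed one
oracle_fisher2 <- function(a_in, a_out, b_in, b_out) {
  na <- a_in + a_out; nb <- b_in + b_out; k <- a_in + b_in
  support <- max(0, k - nb):min(k, na)
  probs <- stats::dhyper(support, na, nb, k)
  p_obs <- stats::dhyper(a_in, na, nb, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# all permutations of a vector (for exhaustive rarefaction)
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(all_perms(v[-i]), function(p) c(v[i], p))))
}

# exhaustive mean pan/core/new trajectories over every genome ordering
oracle_rarefaction_mean <- function(pres) {
  N <- ncol(pres)
  ps <- all_perms(seq_len(N))
  pan <- core <- new <- matrix(0, length(ps), N)
  for (r in seq_along(ps)) {
    ord <- ps[[r]]
    cum_any <- cum_all <- pres[, ord[1]]
    pan[r, 1] <- sum(cum_any); core[r, 1] <- sum(cum_all)
    new[r, 1] <- pan[r, 1]
    for (i in seq_len(N - 1) + 1) {
      cum_any <- cum_any | pres[, ord[i]]
      cum_all <- cum_all & pres[, ord[i]]
      pan[r, i] <- sum(cum_any); core[r, i] <- sum(cum_all)
      new[r, i] <- pan[r, i] - pan[r, i - 1]
    }
  }
  list(pan = colMeans(pan), core = colMeans(core), new = colMeans(new))
}

# brute-force family construction: transitive closure over ALL gene
# pairs passing the thresholds under the oracle aligner
oracle_families <- function(seqs, identity_min = 0.5, coverage_min = 0.5,
                            score_min = 0) {
  ids <- names(seqs)
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    al <- oracle_align(seqs[[i]], seqs[[j]])
    if (al$identity >= identity_min &&
        min(al$coverage_a, al$coverage_b) >= coverage_min &&
        al$score >= score_min) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  split(ids, comp)
}

# small simulated pan-genome used across tests
small_sim <- function(seed = 1, n_genomes = 6, core = 20, gain = 60,
                      loss = 0.5, ...) {
  simulate_pangenome(sim_config(n_genomes = n_genomes, core_size = core,
                                gain_rate = gain, loss_rate = loss,
                                seed = seed, ...))
}

# compare two clusterings as set-of-sets
as_partition <- function(groups) {
  unname(sort(vapply(groups, function(g) paste(sort(g), collapse = "+"),
                     "")))
}
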