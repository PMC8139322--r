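test_that("group-shared dispensable families respect both conditions", {
  m <- matrix(c(1, 1, 1, 1,    # f1 core
                1, 1, 1, 0,    # f2 dispensable, all of group m1+m2+l1
                1, 1, 0, 0,    # f3 dispensable, all marine
                1, 0, 0, 0),   # f4 unique
              4, byrow = TRUE,
              dimnames = list(paste0("f", 1:4),
                              c("m1", "m2", "l1", "l2")))
  pa <- pa_matrix(m)
  part <- partition(pa)
  got <- shared_dispensable(pa, part, c("m1", "m2"))
  expect_setequal(got, c("f2", "f3"))     # core f1 excluded, f4 unique
  expect_error(shared_dispensable(pa, part, character(0)), "empty")
  expect_error(shared_dispensable(pa, part, "nope"), "unknown")

  # planted all-marine accessory families are recovered exactly
  cfg <- sim_config(n_genomes = 12, core_size = 30, gain_rate = 0,
                    marine_fraction = 0.5,
                    planted_niche_families = c(marine = 50, land = 0),
                    planted_presence_fraction = 1.0, seed = 21)
  sim <- simulate_pangenome(cfg)
  marine <- names(sim$truth$niche)[sim$truth$niche == "marine"]
  part <- partition(sim$matrix)
  got <- shared_dispensable(sim$matrix, part, marine)
  expect_setequal(got, sim$truth$planted$marine)
  expect_length(got, 50)
})

test_that("the one-third presence rule is applied with ceiling and background cap", {
  genomes <- c(paste0("m", 1:3), paste0("l", 1:3))
  m <- matrix(0L, 3, 6, dimnames = list(paste0("f", 1:3), genomes))
  m["f1", "m1"] <- 1L                      # 1 of 3 marine, no land
  m["f2", c("m1", "m2", "l1")] <- 1L       # background violation
  m["f3", c("m1", "m2")] <- 1L             # 2 of 3 marine, clean
  pa <- pa_matrix(m)
  rule <- niche_rule(1 / 3, 0)
  got <- niche_specific(pa, paste0("m", 1:3), paste0("l", 1:3), rule)
  expect_setequal(got, c("f1", "f3"))      # ceil(3/3) = 1 genome suffices

  expect_error(niche_specific(pa, c("m1", "l1"), c("l1", "l2")),
               "overlap")
  expect_error(niche_specific(pa, character(0), "l1"), "empty")
})

test_that("niche-specific calls match a brute-force double loop", {
  set.seed(42)
  for (rep in 1:3) {
    m <- matrix(rbinom(400, 1, 0.35), 40, 10,
                dimnames = list(sprintf("f%02d", 1:40),
                                sprintf("g%02d", 1:10)))
    pa <- pa_matrix(m)
    focal <- sprintf("g%02d", 1:4)
    bg <- sprintf("g%02d", 5:10)
    rule <- niche_rule(1 / 3, 0)
    got <- niche_specific(pa, focal, bg, rule)
    brute <- character(0)
    for (f in rownames(m)) {
      nf <- 0; nb <- 0
      for (g in focal) if (m[f, g] > 0) nf <- nf + 1
      for (g in bg) if (m[f, g] > 0) nb <- nb + 1
      if (nf >= ceiling(length(focal) / 3) && nb == 0)
        brute <- c(brute, f)
    }
    expect_setequal(got, brute)
  }
})

test_that("tightening the presence fraction never adds families", {
  sim <- small_sim(23, n_genomes = 10, core = 10, gain = 60)
  meta <- sim$matrix$metadata
  focal <- meta$genome[meta$niche == "marine"]
  bg <- meta$genome[meta$niche == "land"]
  sizes <- vapply(c(0.2, 1 / 3, 0.5, 0.8, 1), function(fr)
    length(niche_specific(sim$matrix, focal, bg, niche_rule(fr, 0))), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("planted niche signal is recovered exactly under the rule", {
  cfg <- sim_config(n_genomes = 15, core_size = 40, gain_rate = 0,
                    marine_fraction = 0.4,
                    planted_niche_families = c(marine = 12, land = 9),
                    planted_presence_fraction = 0.5, seed = 31)
  sim <- simulate_pangenome(cfg)
  niche <- sim$truth$niche
  marine <- names(niche)[niche == "marine"]
  land <- names(niche)[niche == "land"]
  rule <- niche_rule(1 / 3, 0)
  expect_setequal(niche_specific(sim$matrix, marine, land, rule),
                  sim$truth$planted$marine)
  expect_setequal(niche_specific(sim$matrix, land, marine, rule),
                  sim$truth$planted$land)
})

test_that("Fisher enrichment agrees with hypergeometric enumeration", {
  # 2x2 [[2,0],[0,2]]: two-sided p = 1/3
  cog <- data.frame(family = c("a1", "a2", "b1", "b2"),
                    category = c("J", "J", "S", "S"))
  res <- cog_enrichment(c("a1", "a2"), c("b1", "b2"), cog)
  expect_equal(res$p[res$category == "J"], 1 / 3, tolerance = 1e-12)

  # identical composition: all p = 1
  cog2 <- data.frame(family = c("a1", "a2", "b1", "b2"),
                     category = c("J", "K", "J", "K"))
  res2 <- cog_enrichment(c("a1", "a2"), c("b1", "b2"), cog2)
  expect_true(all(res2$p == 1))

  # random 2x2 tables with margins <= 30: p equals the enumeration
  set.seed(13)
  for (rep in 1:25) {
    na <- sample(1:15, 1); nb <- sample(1:15, 1)
    a_in <- sample(0:na, 1); b_in <- sample(0:nb, 1)
    fams_a <- sprintf("a%02d", seq_len(na))
    fams_b <- sprintf("b%02d", seq_len(nb))
    cog <- data.frame(
      family = c(fams_a, fams_b),
      category = c(rep(c("K", "S"), c(a_in, na - a_in)),
                   rep(c("K", "S"), c(b_in, nb - b_in))))
    res <- cog_enrichment(fams_a, fams_b, cog)
    if (a_in + b_in == 0) {
      expect_false("K" %in% res$category)  # category absent, nothing to test
    } else {
      expect_equal(res$p[res$category == "K"],
                   oracle_fisher2(a_in, na - a_in, b_in, nb - b_in),
                   tolerance = 1e-9)
    }
  }

  expect_error(cog_enrichment(character(0), character(0), cog), "empty")
})

test_that("a planted two-fold category skew is detected with high power", {
  # power check: 2x weight on K in set A, 1,000 families per set; the
  # expected K fractions (0.129 vs 0.069) give a ~4.5-sigma separation,
  # so nearly every replicate should flag K at alpha = 0.05
  w <- default_cog_weights()
  w2 <- w; w2["K"] <- w2["K"] * 2; w2 <- w2 / sum(w2)
  hits <- 0
  set.seed(55)
  for (r in 1:100) {
    fams_a <- sprintf("a%04d", 1:1000)
    fams_b <- sprintf("b%04d", 1:1000)
    cog <- data.frame(
      family = c(fams_a, fams_b),
      category = c(sample(names(w2), 1000, TRUE, prob = w2),
                   sample(names(w), 1000, TRUE, prob = w)))
    res <- cog_enrichment(fams_a, fams_b, cog)
    if (res$significant[res$category == "K"]) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("the enrichment null holds: flag rate tracks alpha under shuffling", {
  # random splits of a common family pool emulate shuffled niche labels;
  # categories with pooled counts >= 200 keep the exact test's
  # discreteness negligible
  w <- default_cog_weights()
  set.seed(7)
  n_tests <- 0; n_flag <- 0
  for (r in 1:60) {
    N <- 10000
    fams <- sprintf("f%05d", 1:N)
    cog <- data.frame(family = fams,
                      category = sample(names(w), N, TRUE, prob = w))
    idx <- sample(N, N / 2)
    res <- cog_enrichment(fams[idx], fams[-idx], cog, alpha = 0.05)
    ok <- (res$a_in + res$b_in) >= 200
    n_tests <- n_tests + sum(ok)
    n_flag <- n_flag + sum(res$significant[ok])
  }
  rate <- n_flag / n_tests
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_tests))
})

test_that("Benjamini-Hochberg correction is applied when requested", {
  set.seed(3)
  fams <- sprintf("f%04d", 1:400)
  cog <- data.frame(family = fams,
                    category = sample(cog_categories(), 400, TRUE))
  res_raw <- cog_enrichment(fams[1:200], fams[201:400], cog)
  res_bh <- cog_enrichment(fams[1:200], fams[201:400], cog,
                           correction = "BH")
  expect_equal(res_bh$p_adj,
               stats::p.adjust(res_bh$p, "BH"))
  expect_true(all(res_bh$p_adj >= res_raw$p_adj - 1e-12))
})

test_that("the per-species niche report recovers planted structure", {
  cfg <- sim_config(n_genomes = 16, core_size = 40, gain_rate = 0,
                    marine_fraction = 0.5, n_species = 1,
                    planted_niche_families = c(marine = 10, land = 7),
                    planted_presence_fraction = 0.5, seed = 17)
  sim <- simulate_pangenome(cfg)
  rep <- niche_report(sim$matrix, partition(sim$matrix), sim$cog)
  expect_equal(nrow(rep$summary), 1)
  expect_equal(rep$summary$status, "ok")
  expect_equal(rep$summary$marine_specific, 10)
  expect_equal(rep$summary$land_specific, 7)
  sp <- rep$species[[1]]
  expect_setequal(sp$marine_specific, sim$truth$planted$marine)
  expect_s3_class(sp$enrichment, "data.frame")

  # a species with a single-niche membership is reported, not tested
  meta <- sim$matrix$metadata
  meta$species <- ifelse(meta$niche == "marine", "Sm", "Sl")
  m2 <- pa_matrix(sim$matrix$counts, meta)
  rep2 <- niche_report(m2, partition(m2), sim$cog)
  expect_true(all(rep2$summary$status == "insufficient contrast"))

  # determinism: identical inputs give identical reports
  rep3 <- niche_report(sim$matrix, partition(sim$matrix), sim$cog)
  expect_identical(rep$summary, rep3$summary)
  expect_identical(rep$species, rep3$species)
})
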