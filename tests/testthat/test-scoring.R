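uniform_pwm <- pwm(matrix(0.25, 6, 4), "uni")

test_that("crm_score handles the degenerate and closed-form cases", {
  # uniform PWM vs uniform background: log-odds identically 0, no hits
  expect_equal(crm_score("ACGTACGTACGT", uniform_pwm), 0)
  # single consensus match scores sum_j log2(p_max/0.25)
  m <- matrix(0.04, 4, 4); m[cbind(1:4, c(1, 2, 3, 4))] <- 0.88
  p <- pwm(m, "acgt")
  expect_equal(crm_score("ACGT", p), 4 * log2(0.88 / 0.25))
  # the reverse complement scores the same (strand symmetry)
  expect_equal(crm_score("ACGT", p), crm_score("ACGT", pwm_revcomp(p)))
  # sequence shorter than motif, or all N -> 0
  expect_equal(crm_score("AC", p), 0)
  expect_equal(crm_score("NNNNNNNN", p), 0)
  expect_error(crm_score("ACXT", p), "invalid character")
})

test_that("crm_score sums non-overlapping positive hits only", {
  m <- matrix(0.04, 4, 4); m[cbind(1:4, c(1, 2, 3, 4))] <- 0.88
  p <- pwm(m, "acgt")
  one <- 4 * log2(0.88 / 0.25)
  # two well-separated consensus sites add up
  expect_equal(crm_score("ACGTTTTTTTACGT", p), 2 * one)
  # overlapping placements cannot both count
  expect_lt(crm_score("ACGACGT", p), 2 * one)
})

test_that("crm_score equals the exhaustive oracle on random small inputs", {
  set.seed(202)
  for (i in 1:120) {
    L <- sample(3:8, 1)
    p <- random_informative_pwm(sprintf("m%d", i), len = L,
                                dominant = stats::runif(1, 0.5, 0.95))
    n <- sample(L:80, 1)
    s <- random_seq(n)
    # plant a site half the time so positive hits are common
    if (i %% 2 == 0 && n >= L) {
      at <- sample(n - L + 1, 1)
      substr(s, at, at + L - 1) <- pwm_consensus(p)
    }
    expect_equal(crm_score(s, p), oracle_crm_score(s, p), tolerance = 1e-12)
  }
})

test_that("the memoized oracle agrees with power-set enumeration on tiny inputs", {
  set.seed(301)
  for (i in 1:15) {
    p <- random_informative_pwm(sprintf("t%d", i), len = 4, dominant = 0.7)
    s <- random_seq(20)
    expect_equal(oracle_crm_score(s, p), oracle_crm_powerset(s, p),
                 tolerance = 1e-12)
  }
})

test_that("score_motif_over_regions distinguishes absent orthologs from zero", {
  crrs <- rs("chr1", c(0, 30), c(20, 60), ids = c("r1", "r2"))
  p <- random_informative_pwm("m", len = 6)
  g1 <- paste(rep("A", 100), collapse = "")
  genomes <- list(
    base = list(sequences = c(chr1 = g1), regions = NULL),
    g2 = list(sequences = c(chrX = g1),
              regions = data.frame(region_id = "r1", chrom = "chrX",
                                   start = 0L, end = 20L,
                                   stringsAsFactors = FALSE)))
  sm <- score_motif_over_regions(crrs, genomes, p)
  expect_false(anyNA(sm[, "base"]))
  expect_false(is.na(sm["r1", "g2"]))
  expect_true(is.na(sm["r2", "g2"]))  # no ortholog: absent, not 0
  bad <- list(base = list(sequences = c(chr1 = substr(g1, 1, 10)),
                          regions = NULL))
  expect_error(score_motif_over_regions(crrs, bad, p), "bounds")
})

test_that("planted regions outscore unplanted background regions", {
  sizes <- c(chr1 = 20000L)
  gen <- make_genome(5, sizes, gc = 0.5)
  crrs <- rs("chr1", seq(0, 19800, by = 200), seq(150, 19950, by = 200),
             ids = sprintf("r%03d", 1:100))
  set.seed(55)
  p <- random_informative_pwm("m", len = 8)
  planted <- crrs$region_id[1:30]
  pl <- plant_motif(gen, crrs, p, planted, sites_per_region = 2,
                    strength = 0.2, seed = 6)
  sc <- score_motif_over_regions(
    crrs, list(base = list(sequences = pl$genome, regions = NULL)), p)[, 1]
  w <- stats::wilcox.test(sc[planted], sc[setdiff(names(sc), planted)],
                          alternative = "greater")
  expect_lt(w$p.value, 1e-6)
  expect_gt(min(sc[planted]), stats::quantile(sc[setdiff(names(sc), planted)],
                                              0.95))
})

test_that("track peak scoring takes the per-region maximum signal", {
  crrs <- rs("chr1", c(0, 1000, 2000), c(500, 1500, 2500),
             ids = c("a", "b", "c"))
  peaks <- rs("chr1", c(100, 300, 1499, 5000), c(200, 400, 1600, 5100),
              ids = paste0("p", 1:4), score = c(3.2, 7.1, 2.0, 9.9))
  sc <- score_track_peaks(crrs, peaks)
  expect_equal(unname(sc), c(7.1, 2.0, 0))  # 1-bp overlap counts; no peak -> 0
  neg <- rs("chr1", 0, 50, ids = "n", score = -1)
  expect_warning(score_track_peaks(crrs, neg), "negative")
})

test_that("coverage scoring supports max and mean aggregation", {
  crrs <- rs("chr1", c(0, 10), c(10, 20), ids = c("a", "b"))
  cov <- list(chr1 = c(rep(2, 10), rep(c(1, 9), c(5, 5))))
  expect_equal(unname(score_track_coverage(crrs, cov, "max")), c(2, 9))
  expect_equal(unname(score_track_coverage(crrs, cov, "mean")), c(2, 5))
  off <- rs("chr9", 0, 10, ids = "x")
  expect_warning(sc <- score_track_coverage(off, cov), "chromosome")
  expect_equal(unname(sc), 0)
})

test_that("scores_to_ranking is a deterministic permutation with seeded ties", {
  ids <- c("a", "b", "c")
  r <- scores_to_ranking(stats::setNames(c(5, 3, 9), ids), "f", 1)
  expect_equal(r$order, c("c", "a", "b"))
  expect_equal(unname(r$ranks[r$order]), 1:3)
  # all-equal scores: same seed reproduces, different seeds differ w.h.p.
  eq <- stats::setNames(rep(1, 50), sprintf("r%02d", 1:50))
  p1 <- scores_to_ranking(eq, "f", 7)$order
  expect_identical(p1, scores_to_ranking(eq, "f", 7)$order)
  differs <- vapply(1:20, function(s)
    !identical(p1, scores_to_ranking(eq, "f", 100 + s)$order), TRUE)
  expect_gt(mean(differs), 0.9)
  # absent scores rank after all present scores
  withna <- stats::setNames(c(2, NA, 1, NA), c("a", "b", "c", "d"))
  rk <- scores_to_ranking(withna, "f", 1)$ranks
  expect_true(all(rk[c("b", "d")] > rk[c("a", "c")]))
})

test_that("order-statistic aggregation matches closed forms and Monte Carlo", {
  expect_equal(aggregate_rankings(0.3), 0.3)
  expect_equal(aggregate_rankings(c(1, 1, 1)), 1.0)
  expect_equal(aggregate_rankings(c(0.5, 0.5)), 0.25)  # P(max <= .5)
  expect_error(aggregate_rankings(c(0.5, 0)), "ratios")
  expect_error(aggregate_rankings(c(0.5, 1.1)), "ratios")
  set.seed(77)
  for (N in c(2, 3, 5)) {
    for (rep in 1:3) {
      r <- stats::runif(N, 0.05, 1)
      q <- aggregate_rankings(r)
      mc <- mc_order_stat(r, n_draws = 2e5)
      expect_lt(abs(q - mc$p), 3 * mc$se + 1e-9)
    }
  }
})

test_that("aggregation is monotone and idempotent on identical rankings", {
  set.seed(8)
  r <- sort(stats::runif(4, 0.1, 0.9))
  q0 <- aggregate_rankings(r)
  for (k in 1:4) {
    r2 <- r; r2[k] <- r2[k] * 0.5
    expect_lte(aggregate_rankings(r2), q0 + 1e-12)
  }
  # N identical copies of one ranking reproduce its order
  ids <- sprintf("r%02d", 1:30)
  set.seed(9)
  sc <- stats::setNames(stats::runif(30), ids)
  base_order <- scores_to_ranking(sc, "f", 1)$order
  ranks <- scores_to_ranking(sc, "f", 1)$ranks
  q <- vapply(ids, function(i)
    aggregate_rankings(rep(ranks[[i]] / 30, 3)), 0)
  expect_equal(names(sort(q)), base_order)
})

test_that("ranking databases are permutations and round-trip through disk", {
  crrs <- rs("chr1", seq(0, 990, 10), seq(10, 1000, 10),
             ids = sprintf("r%03d", 1:100))
  set.seed(3)
  sets <- list(f1 = stats::setNames(stats::rnorm(100), crrs$region_id),
               f2 = stats::setNames(stats::rnorm(100), crrs$region_id),
               f3 = stats::setNames(rep(1, 100), crrs$region_id))
  db <- build_ranking_database(crrs, sets, seed = 11, db_label = "user",
                               feature_type = "track")
  for (f in rownames(db$ranks))
    expect_setequal(unname(db$ranks[f, ]), 1:100)
  pre <- withr::local_tempfile()
  save_ranking_db(db, pre)
  db2 <- load_ranking_db(pre, crrs)
  expect_identical(db2$ranks, db$ranks)
  expect_identical(db2$seed, db$seed)
  other <- rs("chr1", 0, 10, ids = "zzz")
  expect_error(load_ranking_db(pre, other), "does not match")
  expect_error(build_ranking_database(crrs, stats::setNames(sets, NULL), 1),
               "named")
})
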