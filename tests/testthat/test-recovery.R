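test_that("threshold_rank reproduces the published database cutoffs exactly", {
  expect_identical(threshold_rank(1223024, 0.005), 6115L)
  expect_identical(threshold_rank(938376, 0.005), 4692L)
  expect_identical(threshold_rank(136353, 0.01), 1364L)
  expect_identical(threshold_rank(100, 0.001), 1L)  # clamped to >= 1
  expect_error(threshold_rank(100, 0), "fraction")
  expect_error(threshold_rank(100, 1.5), "fraction")
})

mk_ranks <- function(perm, ids = sprintf("r%02d", seq_along(perm))) {
  stats::setNames(perm, ids)
}

test_that("recovery_curve counts foreground regions per rank prefix", {
  ranks <- mk_ranks(1:10)
  rc <- recovery_curve(ranks, c("r02", "r05"), 5)
  expect_equal(rc$rc, c(0, 1, 1, 1, 2))
  expect_equal(recovery_curve(ranks, names(ranks), 10)$rc, 1:10)
  expect_equal(recovery_curve(ranks, c("r09", "r10"), 5)$rc, rep(0, 5))
  expect_error(recovery_curve(ranks, "nope", 5), "absent")
})

test_that("auc_recovery implements the normalized step integral", {
  ranks <- mk_ranks(1:10)
  # F=2 at ranks 1 and 6, window 10: (5*0.5 + 5*1.0)/10
  rc <- recovery_curve(ranks, c("r01", "r06"), 10)
  expect_equal(auc_recovery(rc, 10), 0.75)
  # single foreground at rank 1 -> 1.0 for any window
  expect_equal(auc_recovery(recovery_curve(ranks, "r01", 10), 4), 1.0)
  # nothing in the window -> 0
  expect_equal(auc_recovery(recovery_curve(ranks, "r10", 5), 5), 0.0)
})

test_that("NES uses the population sd and is location-invariant", {
  a <- c(f1 = 0.9, f2 = 0.1, f3 = 0.1, f4 = 0.1)
  sc <- nes_scores(a)
  expect_equal(sc$nes[1], 0.6 / sqrt(0.12))
  expect_equal(mean(sc$nes), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(sc$nes^2)), 1, tolerance = 1e-12)
  expect_equal(nes_scores(a + 0.05)$nes, sc$nes)
  expect_equal(nes_scores(c(f1 = 0.3, f2 = 0.3))$nes, c(0, 0))
  expect_error(nes_scores(c(f1 = 0.3)), "2 features")
})

test_that("mean_sd_curves does pointwise population statistics", {
  c1 <- structure(list(rc = c(0, 2), F = 2), class = "recovery_curve")
  c2 <- structure(list(rc = c(2, 2), F = 2), class = "recovery_curve")
  ms <- mean_sd_curves(list(c1, c2))
  expect_equal(ms$mean, c(1, 2))
  expect_equal(ms$sd, c(1, 0))
  expect_equal(mean_sd_curves(list(c1, c1))$sd, c(0, 0))
  c3 <- structure(list(rc = c(0, 1, 2), F = 2), class = "recovery_curve")
  expect_error(mean_sd_curves(list(c1, c3)), "length")
})

test_that("leading_edge takes the first argmax of rc - (mean + 2 sd)", {
  ranks <- mk_ranks(1:10)
  curve <- structure(list(rc = c(0, 1, 4, 4), F = 4),
                     class = "recovery_curve")
  le <- leading_edge(curve, mean_curve = c(1, 1, 1, 2),
                     sd_curve = c(0, 0, 0, 0), t_le = 4,
                     ranks = ranks, foreground_ids = c("r01", "r02", "r03"))
  expect_equal(le$le_rank, 3L)  # diff series -1, 0, 3, 2
  expect_setequal(le$target_ids, c("r01", "r02", "r03"))
  expect_true(le$positive)
  # everywhere below mean + 2 sd: still reported, flagged non-positive
  le2 <- leading_edge(curve, mean_curve = c(5, 5, 5, 5),
                      sd_curve = rep(0, 4), t_le = 4, ranks = ranks,
                      foreground_ids = "r10")
  expect_false(le2$positive)
  expect_equal(le2$le_rank, 3L)  # first argmax of (-5, -4, -1, -1)
})

test_that("recovery pipeline matches the brute-force oracle to 1e-12", {
  set.seed(606)
  n <- 1000; nf <- 20
  crrs <- rs("chr1", seq(0, by = 10, length.out = n),
             seq(10, by = 10, length.out = n),
             ids = sprintf("r%04d", seq_len(n)))
  sets <- stats::setNames(lapply(seq_len(nf), function(i)
    stats::setNames(stats::rnorm(n), crrs$region_id)),
    sprintf("f%02d", seq_len(nf)))
  db <- build_ranking_database(crrs, sets, seed = 5, db_label = "user",
                               feature_type = "track")
  fg <- sample(crrs$region_id, 40)
  t_auc <- threshold_rank(n, 0.02)
  rep <- run_enrichment(db, fg, auc_fraction = 0.02, nes_threshold = -Inf)
  want <- oracle_recovery_pipeline(db$ranks, fg, t_auc, t_auc)
  got <- rep$all_scores
  expect_equal(stats::setNames(got$auc, got$feature_id), want$aucs,
               tolerance = 1e-12)
  expect_equal(stats::setNames(got$nes, got$feature_id), want$nes,
               tolerance = 1e-12)
  d <- rep$details$user
  expect_equal(d$mean_sd$mean, want$mean_c, tolerance = 1e-12)
  expect_equal(d$mean_sd$sd, want$sd_c, tolerance = 1e-12)
  expect_equal(vapply(rownames(db$ranks), function(f)
    d$leading_edges[[f]]$le_rank, 1L),
    stats::setNames(want$le_rank, rownames(db$ranks)))
  # NES set has mean 0 and population SD 1 by construction
  expect_equal(mean(got$nes), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(got$nes^2)), 1, tolerance = 1e-12)
})

test_that("AUC is monotone under promoting a foreground region", {
  ranks <- mk_ranks(1:50)
  fg <- c("r10", "r30")
  base <- auc_recovery(recovery_curve(ranks, fg, 20), 20)
  # promote r30 to rank 2: swap ranks of r02 and r30
  promoted <- ranks; promoted["r30"] <- 2L; promoted["r02"] <- 30L
  expect_gt(auc_recovery(recovery_curve(promoted, fg, 20), 20), base)
})

test_that("NES values are invariant to feature order in the database", {
  set.seed(12)
  n <- 200
  crrs <- rs("chr1", seq(0, by = 5, length.out = n),
             seq(5, by = 5, length.out = n), ids = sprintf("r%03d", 1:n))
  sets <- stats::setNames(lapply(1:6, function(i)
    stats::setNames(stats::rnorm(n), crrs$region_id)), paste0("f", 1:6))
  fg <- sample(crrs$region_id, 20)
  db1 <- build_ranking_database(crrs, sets, 3, "user", "track")
  db2 <- build_ranking_database(crrs, rev(sets), 3, "user", "track")
  r1 <- run_enrichment(db1, fg, 0.05, -Inf)$all_scores
  r2 <- run_enrichment(db2, fg, 0.05, -Inf)$all_scores
  expect_equal(stats::setNames(r1$nes, r1$feature_id)[r2$feature_id],
               stats::setNames(r2$nes, r2$feature_id))
})

test_that("quick mode restricts motifs and raises the threshold to 4", {
  set.seed(21)
  n <- 300
  crrs <- rs("chr1", seq(0, by = 5, length.out = n),
             seq(5, by = 5, length.out = n), ids = sprintf("r%03d", 1:n))
  fg <- crrs$region_id[1:20]
  # f_hot concentrates the foreground at the top; decoys are random
  sets <- c(list(f_hot = stats::setNames(-match(crrs$region_id,
                                                c(fg, crrs$region_id)),
                                         crrs$region_id)),
            stats::setNames(lapply(1:11, function(i)
              stats::setNames(stats::rnorm(n), crrs$region_id)),
              paste0("dec", 1:11)))
  db <- build_ranking_database(crrs, sets, 4, "motifs", "motif")
  full <- run_enrichment(db, fg, 0.1, 3.0)
  expect_true("f_hot" %in% full$table$feature_id)
  quick <- run_enrichment(db, fg, 0.1, 3.0, quick = TRUE,
                          quick_subset = names(sets))
  expect_equal(quick$params$nes_threshold, 4.0)
  expect_true(all(quick$table$nes > 4.0))
  sub <- run_enrichment(db, fg, 0.1, 3.0, quick = TRUE,
                        quick_subset = c("f_hot", paste0("dec", 1:5)))
  expect_true(all(sub$table$feature_id %in% c("f_hot", paste0("dec", 1:5))))
  expect_error(run_enrichment(db, fg, 0.1, 3.0, quick = TRUE), "subset")
})

test_that("combine_features reproduces and interpolates rankings", {
  set.seed(31)
  n <- 200
  crrs <- rs("chr1", seq(0, by = 5, length.out = n),
             seq(5, by = 5, length.out = n), ids = sprintf("r%03d", 1:n))
  fg <- crrs$region_id[seq(1, 40, 2)]
  strong <- stats::setNames(-match(crrs$region_id, crrs$region_id) +
                              stats::rnorm(n, 0, 0.01), crrs$region_id)
  random1 <- stats::setNames(stats::rnorm(n), crrs$region_id)
  db <- build_ranking_database(crrs, list(s = strong, r = random1,
                                          s2 = strong), 9, "user", "track")
  # combining two identical rankings preserves the order
  comb_same <- combine_features(db, c("s", "s2"))
  expect_equal(comb_same$order, names(sort(feature_ranks(db, "s"))))
  # strong + random: foreground AUC lands between the two singletons'
  t_auc <- threshold_rank(n, 0.1)
  auc_of <- function(ranks) auc_recovery(recovery_curve(ranks, fg, t_auc),
                                         t_auc)
  a_s <- auc_of(feature_ranks(db, "s"))
  a_r <- auc_of(feature_ranks(db, "r"))
  a_c <- auc_of(combine_features(db, c("s", "r"))$ranks)
  expect_true(a_c <= max(a_s, a_r) + 1e-9 && a_c >= min(a_s, a_r) - 1e-9)
  expect_error(combine_features(db, "s"), "two features")
  expect_error(combine_features(db, c("s", "nope")), "unknown")
})
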