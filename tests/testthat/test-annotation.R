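test_that("ssd_distance is a symmetric pre-metric with orientation handling", {
  set.seed(41)
  pwms <- lapply(1:6, function(i)
    random_informative_pwm(paste0("m", i), len = sample(5:9, 1)))
  for (p in pwms) {
    expect_equal(ssd_distance(p, p), 0)
    expect_equal(ssd_distance(p, pwm_revcomp(p)), 0)
  }
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(ssd_distance(pwms[[i]], pwms[[j]]),
                 ssd_distance(pwms[[j]], pwms[[i]]), tolerance = 1e-12)
  }
})

test_that("ssd_distance equals exhaustive offset/orientation enumeration", {
  # independent re-enumeration with padded matrices
  brute_ssd <- function(a, b) {
    pad <- function(m, bg, left, right) {
      bgrows <- function(k) matrix(rep(bg, each = k), nrow = k, ncol = 4)
      rbind(bgrows(left), m, bgrows(right))
    }
    best <- Inf
    for (bb in list(b, pwm_revcomp(b))) {
      la <- nrow(a$matrix); lb <- nrow(bb$matrix)
      for (s in (-(lb - 1)):(la - 1)) {
        lo <- min(0, s); hi <- max(la, s + lb)
        span <- hi - lo
        # a sits at offset -lo, b at s - lo; each motif is padded with its
        # own background, so an absent column is compared against the
        # other motif's background distribution
        A <- pad(a$matrix, a$background, -lo, span - la + lo)
        B <- pad(bb$matrix, bb$background, s - lo, span - (s - lo) - lb)
        best <- min(best, mean(rowSums((A - B)^2)))
      }
    }
    best
  }
  set.seed(43)
  for (k in 1:10) {
    a <- random_informative_pwm("a", len = sample(4:8, 1))
    b <- random_informative_pwm("b", len = sample(4:8, 1))
    expect_equal(ssd_distance(a, b), brute_ssd(a, b), tolerance = 1e-12)
  }
})

test_that("cluster_motifs recovers two well-separated synthetic families", {
  set.seed(47)
  base1 <- random_informative_pwm("fam1", len = 8, dominant = 0.9)
  base2 <- random_informative_pwm("fam2", len = 8, dominant = 0.9)
  jitter_pwm <- function(p, id) {
    m <- p$matrix + matrix(stats::runif(length(p$matrix), 0, 0.03),
                           nrow = nrow(p$matrix))
    pwm(m / rowSums(m), id)
  }
  fam <- c(lapply(1:4, function(i) jitter_pwm(base1, paste0("a", i))),
           lapply(1:4, function(i) jitter_pwm(base2, paste0("b", i))))
  names(fam) <- vapply(fam, `[[`, "", "motif_id")
  nes <- stats::setNames(c(5, 4, 3.5, 3.2, 6, 4.5, 3.3, 3.1), names(fam))
  cl <- cluster_motifs(fam, nes)
  expect_equal(length(unique(cl$cluster_id)), 2)
  a_cl <- unique(cl$cluster_id[grepl("^a", cl$motif_id)])
  b_cl <- unique(cl$cluster_id[grepl("^b", cl$motif_id)])
  expect_length(a_cl, 1); expect_length(b_cl, 1)
  expect_false(a_cl == b_cl)
  # family containing the best NES (b: 6) is cluster rank 1
  expect_equal(unique(cl$cluster_rank[cl$cluster_id == b_cl]), 1L)
  # member ranks follow NES within each cluster
  expect_equal(cl$motif_id[cl$cluster_rank == 1 & cl$within_rank == 1], "b1")
})

test_that("cluster_motifs handles singletons and exact duplicates", {
  p <- random_informative_pwm("solo", len = 6)
  cl <- cluster_motifs(list(solo = p), c(solo = 4))
  expect_equal(cl$cluster_rank, 1L)
  dup <- list(d1 = p, d2 = p,
              far = random_informative_pwm("far", len = 6, dominant = 0.95))
  cl <- cluster_motifs(dup, c(d1 = 5, d2 = 4, far = 3))
  expect_equal(cl$cluster_id[cl$motif_id == "d1"],
               cl$cluster_id[cl$motif_id == "d2"])
  # partition: every motif in exactly one cluster
  expect_setequal(cl$motif_id, names(dup))
  expect_equal(anyDuplicated(cl$motif_id), 0L)
})

m2t <- data.frame(
  motif_id = c("m1", "m1", "m1", "m2", "m2"),
  tf = c("FLI1", "ERG", "FLI1", "GATA1", "TAL1"),
  evidence = c("direct", "orthology", "similarity", "similarity", "direct"),
  species = c("hsa", "mmu", "hsa", "hsa", "hsa"),
  score = c(NA, 0.9, 0.5, 0.8, NA), stringsAsFactors = FALSE)

test_that("motif2tf lookup filters, orders and deduplicates by evidence", {
  out <- motif2tf_lookup("m1", m2t)
  expect_equal(out$tf, c("FLI1", "ERG"))
  expect_equal(out$evidence[out$tf == "FLI1"], "direct")  # best evidence kept
  out <- motif2tf_lookup("m2", m2t, evidence = c("direct", "orthology"))
  expect_equal(out$tf, "TAL1")  # similarity-only TF excluded
  expect_equal(nrow(motif2tf_lookup("mX", m2t)), 0)
  out <- motif2tf_lookup("m1", m2t, species = "mmu")
  expect_equal(out$tf, "ERG")
})

test_that("read_motif2tf validates evidence categories", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("motif_id\ttf\tevidence\tspecies\tscore",
               "m1\tFLI1\tdirect\thsa\t1"), f)
  tab <- read_motif2tf(f)
  expect_s3_class(tab, "motif2tf_table")
  writeLines(c("motif_id\ttf\tevidence\tspecies\tscore",
               "m1\tFLI1\tguesswork\thsa\t1"), f)
  expect_error(read_motif2tf(f), "evidence")
})

test_that("closest_genes assigns by midpoint-to-TSS distance with tie rule", {
  ann <- data.frame(gene = c("B", "A", "C"), chrom = c("chr1", "chr1", "chr2"),
                    strand = "+", tss = c(1000L, 3000L, 50L),
                    stringsAsFactors = FALSE)
  class(ann) <- c("gene_annotation", "data.frame")
  targets <- rs(c("chr1", "chr1", "chr3"), c(800, 1900, 0),
                c(1000, 2100, 100), ids = c("t1", "t2", "t3"))
  out <- closest_genes(targets, ann)
  expect_equal(out$gene, c("B", "A", NA))  # t2 equidistant -> "A" wins
  expect_equal(out$distance, c(100, 1000, NA))
  # invariant to annotation row order
  out2 <- closest_genes(targets, ann[c(2, 3, 1), ])
  expect_equal(out, out2)
})

test_that("compare_reports classifies common and distinct motifs", {
  ra <- data.frame(feature_id = c("m1", "m2"), nes = c(5, 4),
                   stringsAsFactors = FALSE)
  rb <- data.frame(feature_id = c("m2", "m3"), nes = c(3.5, 6),
                   stringsAsFactors = FALSE)
  cmp <- compare_reports(ra, rb)
  expect_equal(cmp$status[cmp$feature_id == "m2"], "common")
  expect_equal(cmp$status[cmp$feature_id == "m1"], "a_only")
  expect_equal(cmp$status[cmp$feature_id == "m3"], "b_only")
  expect_equal(cmp$nes_b[cmp$feature_id == "m2"], 3.5)
  ident <- compare_reports(ra, ra)
  expect_true(all(ident$status == "common"))
  disj <- compare_reports(ra, data.frame(feature_id = "mX", nes = 1))
  expect_false(any(disj$status == "common"))
})

test_that("cluster-level comparison matches clusters sharing any member", {
  ra <- data.frame(feature_id = c("m1", "m2"), nes = c(5, 4))
  rb <- data.frame(feature_id = c("m2", "m3"), nes = c(3.5, 6))
  ca <- data.frame(motif_id = c("m1", "m2"), cluster_id = c(1L, 1L))
  cb <- data.frame(motif_id = c("m2", "m3"), cluster_id = c(7L, 8L))
  cmp <- compare_reports(ra, rb, ca, cb)
  cc <- attr(cmp, "cluster_common")
  expect_true(cc["1", "7"])    # shared member m2
  expect_false(cc["1", "8"])   # different member motifs only
})
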