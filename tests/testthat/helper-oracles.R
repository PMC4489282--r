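# Independent brute-force oracles. These deliberately use per-base masks,
# character loops and naive recursion -- separate code paths from the
# package implementations they check.

rs <- function(chrom, start, end, ids = NULL, score = NULL, tag = "toy") {
  region_set(chrom, start, end, region_id = ids, score = score,
             genome_tag = tag)
}

# union-of-intersections overlap fraction by counting bases one at a time
oracle_overlap_fraction <- function(q, others) {
  covered <- 0L
  for (b in q$start:(q$end - 1L)) {
    hit <- FALSE
    for (i in seq_len(nrow(others))) {
      if (others$chrom[i] == q$chrom && b >= others$start[i] &&
          b < others$end[i]) { hit <- TRUE; break }
    }
    if (hit) covered <- covered + 1L
  }
  covered / (q$end - q$start)
}

mask_from <- function(sets, ch, n) {
  m <- logical(n)
  for (x in sets) for (i in seq_len(nrow(x))) {
    if (x$chrom[i] == ch) {
      a <- x$start[i] + 1L; b <- min(x$end[i], n)
      if (a <= b) m[a:b] <- TRUE
    }
  }
  m
}

runs_of <- function(mask) {
  r <- rle(mask)
  e <- cumsum(r$lengths)
  s <- e - r$lengths  # 0-based starts
  cbind(start = s[r$values], end = e[r$values])
}

# full CRR construction by per-base mask-and-segment, with 1-bp-alternating
# extension (left first), independent of the interval-tree implementation
oracle_build_crrs <- function(feature_sets, insulators, exons, config,
                              chrom_sizes) {
  out <- NULL
  for (ch in names(chrom_sizes)) {
    n <- chrom_sizes[[ch]]
    feat <- mask_from(feature_sets, ch, n)
    ins <- mask_from(list(insulators), ch, n)
    exn <- mask_from(list(exons), ch, n)
    forb <- ins | exn
    pieces <- NULL
    segs <- runs_of(feat)
    for (k in seq_len(nrow(segs))) {
      s <- segs[k, 1]; e <- segs[k, 2]
      idx <- (s + 1L):e
      if (mean(ins[idx]) >= config$insulator_fraction) next
      if (mean(exn[idx]) >= config$exon_fraction) next
      sub <- runs_of(!forb[idx])
      if (!nrow(sub)) next
      sub <- sub + s
      sub <- sub[sub[, 2] - sub[, 1] >= config$min_size, , drop = FALSE]
      if (nrow(sub)) pieces <- rbind(pieces, sub)
    }
    if (is.null(pieces)) next
    for (k in seq_len(nrow(pieces))) {
      a <- pieces[k, 1]; b <- pieces[k, 2]
      side <- 0L  # 0 = try left first
      while (b - a < config$target_size) {
        can_l <- a > 0 && !forb[a]        # base a-1 (0-based) = index a
        can_r <- b < n && !forb[b + 1L]   # base b (0-based) = index b+1
        if (!can_l && !can_r) break
        if (side == 0L) {
          if (can_l) a <- a - 1L else b <- b + 1L
        } else {
          if (can_r) b <- b + 1L else a <- a - 1L
        }
        side <- 1L - side
      }
      out <- rbind(out, data.frame(chrom = ch, start = a, end = b,
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_region_layout <- function(seed, chrom_sizes, n_feat = 25, n_ins = 6,
                                 n_ex = 6) {
  set.seed(seed)
  pick <- function(n, wmin, wmax, prefix) {
    ch <- sample(names(chrom_sizes), n, replace = TRUE)
    w <- sample(wmin:wmax, n, replace = TRUE)
    s <- vapply(seq_len(n), function(i)
      sample.int(chrom_sizes[[ch[i]]] - w[i], 1) - 1L, 1L)
    rs(ch, s, s + w, ids = sprintf("%s_%03d", prefix, seq_len(n)))
  }
  list(features = list(pick(n_feat, 40, 900, "fa"),
                       pick(n_feat, 40, 900, "fb")),
       insulators = pick(n_ins, 100, 500, "ins"),
       exons = pick(n_ex, 80, 400, "ex"))
}

# naive CRM scorer: character-loop window scores + memoized recursion over
# the positive-hit list (explores every non-overlapping subset)
oracle_crm_score <- function(seq, p) {
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- nrow(p$matrix)
  n <- length(chars)
  if (n < L) return(0)
  one <- function(M, bg, b, j) {
    if (b == "N") return(0)
    log2(M[j, b] / bg[match(b, c("A", "C", "G", "T"))])
  }
  rc <- pwm_revcomp(p)
  w <- numeric(n - L + 1)
  for (pos in seq_len(n - L + 1)) {
    f <- 0; r <- 0
    for (j in seq_len(L)) {
      b <- chars[pos + j - 1]
      f <- f + one(p$matrix, p$background, b, j)
      r <- r + one(rc$matrix, rc$background, b, j)
    }
    w[pos] <- max(f, r)
  }
  hits <- which(w > 0)
  if (!length(hits)) return(0)
  memo <- rep(NA_real_, length(hits) + 1)
  rec <- function(k) {
    if (k > length(hits)) return(0)
    if (!is.na(memo[k])) return(memo[k])
    best <- rec(k + 1)
    nxt <- k + 1
    while (nxt <= length(hits) && hits[nxt] < hits[k] + L) nxt <- nxt + 1
    best <- max(best, w[hits[k]] + rec(nxt))
    memo[k] <<- best
    best
  }
  rec(1)
}

# power-set enumerator over positive hits (for small hit counts only);
# validates the recursion above
oracle_crm_powerset <- function(seq, p) {
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- nrow(p$matrix)
  n <- length(chars)
  if (n < L) return(0)
  rc <- pwm_revcomp(p)
  one <- function(M, bg, b, j) {
    if (b == "N") return(0)
    log2(M[j, b] / bg[match(b, c("A", "C", "G", "T"))])
  }
  w <- vapply(seq_len(n - L + 1), function(pos) {
    f <- sum(vapply(seq_len(L), function(j)
      one(p$matrix, p$background, chars[pos + j - 1], j), 0))
    r <- sum(vapply(seq_len(L), function(j)
      one(rc$matrix, rc$background, chars[pos + j - 1], j), 0))
    max(f, r)
  }, 0)
  hits <- which(w > 0)
  if (!length(hits)) return(0)
  stopifnot(length(hits) <= 16)
  best <- 0
  for (mask in 0:(2^length(hits) - 1)) {
    sel <- hits[bitwAnd(mask, 2^(seq_along(hits) - 1)) > 0]
    if (length(sel) > 1 && any(diff(sel) < L)) next
    best <- max(best, sum(w[sel]))
  }
  best
}

# Monte-Carlo estimate of the order-statistic joint probability via a
# sorting network (vectorised exact row sort for N <= 5)
row_sort_small <- function(U) {
  nets <- list(`1` = list(), `2` = list(c(1, 2)),
               `3` = list(c(1, 2), c(2, 3), c(1, 2)),
               `4` = list(c(1, 2), c(3, 4), c(1, 3), c(2, 4), c(2, 3)),
               `5` = list(c(1, 2), c(4, 5), c(3, 5), c(3, 4), c(1, 4),
                          c(1, 3), c(2, 5), c(2, 4), c(2, 3)))
  for (e in nets[[as.character(ncol(U))]]) {
    a <- pmin(U[, e[1]], U[, e[2]])
    b <- pmax(U[, e[1]], U[, e[2]])
    U[, e[1]] <- a; U[, e[2]] <- b
  }
  U
}

mc_order_stat <- function(ratios, n_draws = 1e6) {
  N <- length(ratios)
  r <- sort(ratios)
  U <- row_sort_small(matrix(stats::runif(n_draws * N), ncol = N))
  ok <- rep(TRUE, n_draws)
  for (k in seq_len(N)) ok <- ok & (U[, k] <= r[k])
  p <- mean(ok)
  list(p = p, se = sqrt(p * (1 - p) / n_draws))
}

# from-scratch recovery pipeline on a rank matrix (loops, no shared code)
oracle_recovery_pipeline <- function(ranks_m, fg, t_auc, t_le) {
  nf <- nrow(ranks_m)
  t_curve <- max(t_auc, t_le)
  F <- length(fg)
  rc <- matrix(0, nf, t_curve, dimnames = list(rownames(ranks_m), NULL))
  for (f in seq_len(nf)) for (x in seq_len(t_curve))
    rc[f, x] <- sum(ranks_m[f, fg] <= x)
  aucs <- numeric(nf)
  for (f in seq_len(nf)) aucs[f] <- sum(rc[f, seq_len(t_auc)] / F) / t_auc
  mu <- sum(aucs) / nf
  sig <- sqrt(sum((aucs - mu)^2) / nf)
  nes <- if (sig > 0) (aucs - mu) / sig else rep(0, nf)
  mean_c <- numeric(t_curve); sd_c <- numeric(t_curve)
  for (x in seq_len(t_curve)) {
    mean_c[x] <- sum(rc[, x]) / nf
    sd_c[x] <- sqrt(sum((rc[, x] - mean_c[x])^2) / nf)
  }
  le_rank <- integer(nf)
  for (f in seq_len(nf)) {
    best <- -Inf; bx <- 1L
    for (x in seq_len(t_le)) {
      d <- rc[f, x] - (mean_c[x] + 2 * sd_c[x])
      if (d > best) { best <- d; bx <- x }
    }
    le_rank[f] <- bx
  }
  list(rc = rc, aucs = stats::setNames(aucs, rownames(ranks_m)),
       nes = stats::setNames(nes, rownames(ranks_m)),
       mean_c = mean_c, sd_c = sd_c, le_rank = le_rank)
}

random_informative_pwm <- function(id, len = 8, dominant = 0.85) {
  m <- matrix((1 - dominant) / 3, len, 4)
  for (j in seq_len(len)) m[j, sample.int(4, 1)] <- dominant
  pwm(m, id)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

covered_by <- function(x, others) {
  vapply(seq_len(nrow(x)), function(i) overlap_fraction(x[i, ], others), 0)
}

merge2 <- function(a, b) {
  rs(c(a$chrom, b$chrom), c(a$start, b$start), c(a$end, b$end),
     ids = c(a$region_id, b$region_id))
}
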