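#' Scoring and ranking of CRRs
#'
#' The offline half of the method: every CRR is scored for every feature
#' (motif or experimental track), scores are converted into one total
#' ordering of the whole CRR universe per feature, and per-genome motif
#' rankings are aggregated across genomes with order statistics.
#' @name scoring
NULL

# ---- CRM scorer -----------------------------------------------------------

#' Cis-regulatory-module score of a sequence for one PWM
#'
#' The score is the maximum, over every set of mutually non-overlapping
#' motif placements on either strand, of the summed placement scores, where
#' a placement at window `w` contributes
#' `sum_j log2(p_motif(base_j) / p_background(base_j))` and only placements
#' with a positive contribution count. `N` bases contribute log-odds 0
#' (background-equal). A sequence shorter than the motif scores 0.
#'
#' The optimum is found by dynamic programming over window start positions;
#' with equal-length windows this is exact.
#'
#' @param sequence nucleotide string over A, C, G, T, N (case-insensitive).
#' @param pwm a [pwm()].
#' @return Non-negative CRM score in log2-odds units.
#' @export
crm_score <- function(sequence, pwm) {
  w <- crm_hit_scores(sequence, pwm)
  if (is.null(w)) return(0)
  L <- pwm_length(pwm)
  n <- length(w$best) + L - 1L  # sequence length
  # best[i+1] = optimal score using the first i bases
  best <- numeric(n + 1L)
  hit <- w$best
  for (i in seq_len(n)) {
    b <- best[i]
    if (i >= L && hit[i - L + 1L] > 0) {
      cand <- best[i - L + 1L] + hit[i - L + 1L]
      if (cand > b) b <- cand
    }
    best[i + 1L] <- b
  }
  best[n + 1L]
}

#' Per-window best-strand log-odds scores
#'
#' Returns NULL when the sequence is shorter than the motif; otherwise a
#' list with `fwd`, `rev` (per-start-position window scores) and `best`
#' (elementwise max). Window p on `rev` is a hit of the motif on the minus
#' strand covering the same bases.
#' @noRd
crm_hit_scores <- function(sequence, pwm) {
  s <- toupper(as.character(sequence))
  si <- match(strsplit(s, "", fixed = TRUE)[[1]], c(DNA, "N"))
  if (anyNA(si)) stop("invalid character in sequence")
  L <- pwm_length(pwm)
  n <- length(si)
  if (n < L) return(NULL)
  lo <- cbind(log2(pwm$matrix) - rep(log2(pwm$background), each = L), 0)
  rc <- pwm_revcomp(pwm)
  lor <- cbind(log2(rc$matrix) - rep(log2(rc$background), each = L), 0)
  P <- n - L + 1L
  pos <- outer(seq_len(L) - 1L, seq_len(P), "+")  # L x P window indices
  ridx <- rep(seq_len(L), P)
  bidx <- si[as.vector(pos)]
  fwd <- colSums(matrix(lo[cbind(ridx, bidx)], nrow = L))
  rev <- colSums(matrix(lor[cbind(ridx, bidx)], nrow = L))
  list(fwd = fwd, rev = rev, best = pmax(fwd, rev))
}

#' Score one motif over all CRRs, per genome
#'
#' For the base genome every CRR is scored on its own coordinates; for each
#' additional genome an orthology table maps CRR ids to coordinates there,
#' and CRRs without an ortholog get an absent (`NA`) score — absence is not
#' zero, it is imputed as uninformative at aggregation time.
#'
#' @param crrs the CRR `region_set`.
#' @param genomes named list; each element is a list with `sequences` (a
#'   named character vector or `Biostrings::DNAStringSet`, one entry per
#'   chromosome) and optionally `regions`, a data.frame with columns
#'   `region_id, chrom, start, end` giving the orthologous coordinates
#'   (omit or set `NULL` for the base genome, which uses `crrs` directly).
#' @param pwm a [pwm()].
#' @return Numeric matrix: regions x genomes, `NA` for missing orthologs.
#' @export
score_motif_over_regions <- function(crrs, genomes, pwm) {
  stopifnot(length(genomes) >= 1, !is.null(names(genomes)))
  out <- matrix(NA_real_, nrow = nrow(crrs), ncol = length(genomes),
                dimnames = list(crrs$region_id, names(genomes)))
  for (g in names(genomes)) {
    seqs <- genomes[[g]]$sequences
    if (inherits(seqs, "DNAStringSet")) seqs <- as.character(seqs)
    reg <- genomes[[g]]$regions
    if (is.null(reg)) {
      reg <- data.frame(region_id = crrs$region_id, chrom = crrs$chrom,
                        start = crrs$start, end = crrs$end,
                        stringsAsFactors = FALSE)
    }
    idx <- match(reg$region_id, crrs$region_id)
    if (anyNA(idx)) stop("orthology table names unknown region ids")
    for (k in seq_len(nrow(reg))) {
      chr <- reg$chrom[k]
      if (!chr %in% names(seqs))
        stop("chromosome ", chr, " absent from genome ", g)
      if (reg$start[k] < 0 || reg$end[k] > nchar(seqs[[chr]]))
        stop("region ", reg$region_id[k], " outside sequence bounds in ", g)
      sub <- substr(seqs[[chr]], reg$start[k] + 1L, reg$end[k])
      out[idx[k], g] <- crm_score(sub, pwm)
    }
  }
  out
}

# ---- track scoring --------------------------------------------------------

#' Score CRRs by a peak track
#'
#' Per CRR, the maximum signal value among peaks intersecting it by at
#' least 1 bp; CRRs hit by no peak score 0.
#'
#' @param crrs CRR `region_set`.
#' @param scored_peaks `region_set` carrying a `score` column (e.g. from
#'   `read_bed(..., with_score = TRUE, score_col = 7)` for narrowPeak
#'   signalValue).
#' @return Named numeric score vector over the CRR ids.
#' @export
score_track_peaks <- function(crrs, scored_peaks) {
  if (is.null(scored_peaks$score)) stop("peaks carry no score column")
  if (any(scored_peaks$score < 0))
    warning("negative signalValue in peak track; kept as-is")
  out <- stats::setNames(numeric(nrow(crrs)), crrs$region_id)
  if (!nrow(scored_peaks)) return(out)
  h <- harmonized(as_granges(crrs), as_granges(scored_peaks))
  hits <- GenomicRanges::findOverlaps(h$a, h$b)
  if (length(hits)) {
    mx <- tapply(scored_peaks$score[S4Vectors::subjectHits(hits)],
                 S4Vectors::queryHits(hits), max)
    out[as.integer(names(mx))] <- as.numeric(mx)
  }
  out
}

#' Score CRRs by a per-base coverage signal
#'
#' @param crrs CRR `region_set`.
#' @param coverage named list of numeric vectors, one per chromosome;
#'   element `i` of a vector is the signal on 0-based position `i - 1`.
#' @param aggregate `"max"` (default) or `"mean"` over the region's bases.
#' @return Named numeric score vector; regions on chromosomes absent from
#'   `coverage` score 0 with a warning.
#' @export
score_track_coverage <- function(crrs, coverage,
                                 aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  f <- if (aggregate == "max") max else mean
  out <- stats::setNames(numeric(nrow(crrs)), crrs$region_id)
  missing_chr <- setdiff(unique(crrs$chrom), names(coverage))
  if (length(missing_chr))
    warning("no coverage for chromosome(s): ",
            paste(missing_chr, collapse = ", "))
  for (i in seq_len(nrow(crrs))) {
    cv <- coverage[[crrs$chrom[i]]]
    if (is.null(cv)) next
    out[i] <- f(cv[(crrs$start[i] + 1L):min(crrs$end[i], length(cv))])
  }
  out
}

# ---- ranking --------------------------------------------------------------

#' Deterministic integer seed derived from a run seed and a feature id
#' @noRd
derive_seed <- function(seed, feature_id) {
  h <- 0
  for (k in utf8ToInt(feature_id)) h <- (h * 31 + k) %% 2147483629
  as.integer((as.numeric(seed) + h) %% 2147483629)
}

#' Evaluate an expression under a temporary RNG state
#' @noRd
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

#' Convert a score vector into a full ranking
#'
#' Descending-score order over the whole CRR universe; ties are broken by a
#' pseudo-random shuffle seeded deterministically by `(seed, feature_id)`
#' so reruns reproduce the permutation exactly. Absent (`NA`) scores rank
#' after all present scores, shuffled among themselves.
#'
#' @param scores named numeric vector, one slot per CRR (`NA` = absent).
#' @param feature_id feature identifier.
#' @param seed integer run seed.
#' @param feature_type `"motif"`, `"track"` or `"combined"`.
#' @return A `feature_ranking`: list with `feature_id`, `feature_type`,
#'   `order` (region ids, rank 1 first) and `ranks` (named integer vector).
#' @export
scores_to_ranking <- function(scores, feature_id, seed,
                              feature_type = c("motif", "track", "combined")) {
  feature_type <- match.arg(feature_type)
  if (is.null(names(scores))) stop("scores must be named by region id")
  n <- length(scores)
  tb <- with_seed(derive_seed(seed, feature_id), sample.int(n))
  key <- ifelse(is.na(scores), -Inf, scores)
  ord <- order(-key, tb)
  ranks <- integer(n)
  ranks[ord] <- seq_len(n)
  structure(list(feature_id = feature_id, feature_type = feature_type,
                 order = names(scores)[ord],
                 ranks = stats::setNames(ranks, names(scores))),
            class = "feature_ranking")
}

# ---- order-statistic aggregation ------------------------------------------

#' Aggregate per-genome rank ratios with order statistics
#'
#' Given rank ratios `r_1..r_N` in (0, 1] for one region across N genomes
#' (missing genomes imputed as 1.0 beforehand), returns the joint
#' cumulative probability Q that N independent uniform(0,1) order
#' statistics fall componentwise below the sorted ratios, computed by the
#' standard recursion `Q = N! * V_N` with
#' `V_k = sum_{i=1..k} (-1)^(i-1) V_{k-i} r_(N-k+1)^i / i!`, `V_0 = 1`.
#' Smaller Q = more consistently top-ranked across genomes.
#'
#' @param ratios numeric vector of rank ratios in (0, 1].
#' @return Q in (0, 1].
#' @export
aggregate_rankings <- function(ratios) {
  if (!length(ratios)) stop("need at least one ratio")
  if (any(ratios <= 0 | ratios > 1)) stop("ratios must lie in (0, 1]")
  if (all(ratios == 1)) return(1)  # certain event, exact
  r <- sort(ratios)
  N <- length(r)
  V <- numeric(N + 1L)
  V[1L] <- 1
  for (k in seq_len(N)) {
    i <- seq_len(k)
    V[k + 1L] <- sum((-1)^(i - 1) * V[k - i + 1L] * r[N - k + 1L]^i /
                       factorial(i))
  }
  factorial(N) * V[N + 1L]
}

#' Aggregate a per-genome score matrix into one score ranking per motif
#'
#' Scores are ranked within each genome (ties seeded per genome), converted
#' to rank ratios, missing orthologs imputed at ratio 1.0, and combined
#' region-wise with [aggregate_rankings()]; the final motif ranking is by
#' ascending Q.
#'
#' @param score_matrix regions x genomes matrix from
#'   [score_motif_over_regions()].
#' @param feature_id motif id (used for tie-break seeding).
#' @param seed integer run seed.
#' @return Named numeric vector of -Q values (larger = better), suitable
#'   for [scores_to_ranking()] / [build_ranking_database()].
#' @export
aggregate_genome_scores <- function(score_matrix, feature_id, seed) {
  n <- nrow(score_matrix)
  ids <- rownames(score_matrix)
  ratios <- matrix(1, nrow = n, ncol = ncol(score_matrix))
  for (g in seq_len(ncol(score_matrix))) {
    s <- score_matrix[, g]
    rk <- scores_to_ranking(stats::setNames(s, ids),
                            paste0(feature_id, "@", colnames(score_matrix)[g]),
                            seed)$ranks
    ratios[, g] <- rk / n
    ratios[is.na(s), g] <- 1  # missing ortholog: uninformative
  }
  q <- apply(ratios, 1, aggregate_rankings)
  stats::setNames(-q, ids)
}

# ---- ranking database -----------------------------------------------------

#' Build a ranking database
#'
#' One full ranking per feature over a common CRR universe, stored as an
#' integer rank matrix (features x regions, entry = rank of the region for
#' that feature, 1 = strongest).
#'
#' @param crrs CRR `region_set` (the region universe).
#' @param score_sets named list of named numeric score vectors (one per
#'   feature; motifs after cross-genome aggregation, i.e. -Q).
#' @param seed integer run seed for tie-breaking.
#' @param db_label one of `"motifs"`, `"open_chromatin"`, `"histone"`,
#'   `"tf_chipseq"`, `"user"`.
#' @param feature_type type recorded for every feature in this database.
#' @return A `ranking_db`: list with `crr_ids`, `ranks` matrix,
#'   `feature_type`, `db_label`, `seed`, `checksum` (of the CRR universe).
#' @export
build_ranking_database <- function(crrs, score_sets, seed,
                                   db_label = "user",
                                   feature_type = "motif") {
  stopifnot(db_label %in% c("motifs", "open_chromatin", "histone",
                            "tf_chipseq", "user"))
  fids <- names(score_sets)
  if (is.null(fids) || anyDuplicated(fids))
    stop("score_sets must be uniquely named by feature_id")
  n <- nrow(crrs)
  ranks <- matrix(NA_integer_, nrow = length(fids), ncol = n,
                  dimnames = list(fids, crrs$region_id))
  for (f in fids) {
    s <- score_sets[[f]]
    if (length(s) != n) stop("score vector length mismatch for ", f)
    s <- s[crrs$region_id]
    ranks[f, ] <- scores_to_ranking(s, f, seed, feature_type)$ranks
  }
  structure(list(crr_ids = crrs$region_id, ranks = ranks,
                 feature_type = feature_type, db_label = db_label,
                 seed = as.integer(seed),
                 checksum = id_checksum(crrs$region_id)),
            class = "ranking_db")
}

#' @export
print.ranking_db <- function(x, ...) {
  cat(sprintf("ranking_db '%s': %d features x %d regions (seed %d)\n",
              x$db_label, nrow(x$ranks), length(x$crr_ids), x$seed))
  invisible(x)
}

#' Ranks of all regions for one feature
#' @param db a `ranking_db`.
#' @param feature_id feature identifier.
#' @return Named integer vector of ranks (1 = strongest).
#' @export
feature_ranks <- function(db, feature_id) {
  if (!feature_id %in% rownames(db$ranks))
    stop("unknown feature_id: ", feature_id)
  db$ranks[feature_id, ]
}

#' Polynomial rolling checksum of the region-id universe
#' @noRd
id_checksum <- function(ids) {
  h <- 0
  for (k in utf8ToInt(paste(ids, collapse = "\n")))
    h <- (h * 31 + k) %% 2147483629
  sprintf("%d:%d", length(ids), h)
}

#' Persist / load a ranking database
#'
#' The rank matrix is written as a TSV (features x regions, integer ranks)
#' next to a JSON sidecar holding the label, seed, feature types and CRR
#' checksum. Save then load round-trips bit-exactly.
#'
#' @param db a `ranking_db`.
#' @param prefix file prefix; writes `<prefix>.ranks.tsv` and
#'   `<prefix>.meta.json`.
#' @export
save_ranking_db <- function(db, prefix) {
  tsv <- paste0(prefix, ".ranks.tsv")
  con <- file(tsv, "wb")
  writeLines(c(paste(c("feature_id", colnames(db$ranks)), collapse = "\t"),
               vapply(rownames(db$ranks), function(f)
                 paste(c(f, db$ranks[f, ]), collapse = "\t"), "")), con)
  close(con)
  meta <- list(db_label = db$db_label, seed = db$seed,
               feature_type = db$feature_type, checksum = db$checksum,
               n_features = nrow(db$ranks), n_regions = ncol(db$ranks))
  jsonlite::write_json(meta, paste0(prefix, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(prefix)
}

#' @rdname save_ranking_db
#' @param prefix file prefix used at save time.
#' @param crrs optional CRR `region_set`; when supplied, its id universe is
#'   checked against the stored checksum and a mismatch is an error.
#' @export
load_ranking_db <- function(prefix, crrs = NULL) {
  tab <- utils::read.table(paste0(prefix, ".ranks.tsv"), header = TRUE,
                           sep = "\t", row.names = 1, check.names = FALSE,
                           stringsAsFactors = FALSE)
  ranks <- as.matrix(tab)
  storage.mode(ranks) <- "integer"
  meta <- jsonlite::read_json(paste0(prefix, ".meta.json"),
                              simplifyVector = TRUE)
  db <- structure(list(crr_ids = colnames(ranks), ranks = ranks,
                       feature_type = meta$feature_type,
                       db_label = meta$db_label,
                       seed = as.integer(meta$seed),
                       checksum = meta$checksum),
                  class = "ranking_db")
  if (!is.null(crrs) && id_checksum(crrs$region_id) != db$checksum)
    stop("ranking database does not match the supplied CRR universe")
  db
}
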