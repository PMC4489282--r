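#' Ranking-and-recovery enrichment analysis
#'
#' The online half of the method: walk down each feature's ranking of the
#' CRR universe, count how fast the foreground (the user's mapped regions)
#' is recovered, summarise the top of the curve as an AUC, z-normalise the
#' AUCs within each database to NES, and take the leading edge of the
#' curve as the predicted direct target regions.
#' @name recovery
NULL

#' Rank cutoff for a top fraction of the database
#'
#' `round(total * fraction)` with half-away-from-zero rounding, clamped to
#' at least 1. With the published database sizes this reproduces the
#' tool's printed defaults: 0.5% of 1,223,024 human CRRs = 6115, 0.5% of
#' 938,376 mouse CRRs = 4692, 1% of 136,353 fly CRRs = 1364.
#'
#' @param total number of CRRs in the database.
#' @param fraction top fraction in (0, 1].
#' @return Integer rank cutoff.
#' @export
threshold_rank <- function(total, fraction) {
  stopifnot(total >= 1)
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  max(1L, as.integer(floor(total * fraction + 0.5)))
}

#' Cumulative recovery curve of a foreground along one ranking
#'
#' @param ranks named integer rank vector for one feature (from
#'   [feature_ranks()] or a `feature_ranking$ranks`).
#' @param foreground_ids character vector of foreground region ids.
#' @param t_curve curve length (number of top ranks evaluated).
#' @return A `recovery_curve`: list with `rc` (rc\[x\] = number of
#'   foreground regions at rank <= x), `fg_ranks`, `F` (foreground size).
#' @export
recovery_curve <- function(ranks, foreground_ids, t_curve) {
  if (inherits(ranks, "feature_ranking")) ranks <- ranks$ranks
  if (!length(foreground_ids)) stop("empty foreground")
  miss <- setdiff(foreground_ids, names(ranks))
  if (length(miss))
    stop("foreground id absent from ranking universe: ", miss[1])
  stopifnot(t_curve >= 1, t_curve <= length(ranks))
  fr <- sort(unname(ranks[foreground_ids]))
  rc <- cumsum(tabulate(fr[fr <= t_curve], nbins = t_curve))
  structure(list(rc = rc, fg_ranks = fr, F = length(foreground_ids)),
            class = "recovery_curve")
}

#' Area under the top of a recovery curve
#'
#' Mean normalised recovery over the top window: a unit-width step
#' integral of rc(x)/F over x = 1..t_auc, divided by t_auc, so the value
#' lies in \[0, 1\] (1 = whole foreground at the very top).
#'
#' @param curve a [recovery_curve()].
#' @param t_auc rank cutoff (see [threshold_rank()]); at most the curve
#'   length.
#' @return AUC in \[0, 1\].
#' @export
auc_recovery <- function(curve, t_auc) {
  stopifnot(t_auc >= 1, t_auc <= length(curve$rc))
  if (curve$F == 0) stop("empty foreground")
  mean(curve$rc[seq_len(t_auc)]) / curve$F
}

#' Normalised enrichment scores for a database of AUCs
#'
#' `NES = (AUC - mu) / sigma` where `mu` and `sigma` are the mean and
#' population standard deviation of the AUCs of all features in the
#' database. When `sigma` is 0 every NES is 0.
#'
#' @param aucs named numeric vector, one AUC per feature (>= 2 features).
#' @return data.frame with columns `feature_id`, `auc`, `nes`, `mu`,
#'   `sigma`.
#' @export
nes_scores <- function(aucs) {
  if (length(aucs) < 2) stop("need at least 2 features to normalise")
  mu <- mean(aucs)
  sigma <- sqrt(mean((aucs - mu)^2))  # population sd: reproducible NES
  nes <- if (sigma > 0) (aucs - mu) / sigma else rep(0, length(aucs))
  data.frame(feature_id = names(aucs), auc = unname(aucs),
             nes = unname(nes), mu = mu, sigma = sigma,
             stringsAsFactors = FALSE)
}

#' Pointwise mean and standard deviation of a set of recovery curves
#'
#' @param curves list of [recovery_curve()]s of equal length and equal
#'   foreground size.
#' @return List with `mean` and `sd` (population) numeric vectors.
#' @export
mean_sd_curves <- function(curves) {
  lens <- vapply(curves, function(c) length(c$rc), 1L)
  if (length(unique(lens)) != 1) stop("curve length mismatch")
  if (length(unique(vapply(curves, function(c) as.numeric(c$F), 0))) != 1)
    stop("foreground size mismatch")
  m <- do.call(rbind, lapply(curves, `[[`, "rc"))
  mu <- colMeans(m)
  list(mean = mu, sd = sqrt(colMeans(m^2) - mu^2))
}

#' Leading edge of a recovery curve
#'
#' The rank position at which the curve most exceeds the database-average
#' recovery plus two standard deviations; the foreground members within
#' that prefix are the predicted direct target regions.
#'
#' @param curve a [recovery_curve()] (its `fg_ranks` must carry names or
#'   the ids are recovered via `foreground_ids`).
#' @param mean_curve,sd_curve database mean/sd curves from
#'   [mean_sd_curves()].
#' @param t_le search window (<= curve length).
#' @param ranks the feature's named rank vector (to resolve target ids).
#' @param foreground_ids foreground region ids.
#' @return A `leading_edge`: list with `le_rank`, `target_ids`, `positive`
#'   (whether the maximal difference is > 0) and `max_diff`.
#' @export
leading_edge <- function(curve, mean_curve, sd_curve, t_le,
                         ranks, foreground_ids) {
  stopifnot(t_le >= 1, t_le <= length(curve$rc))
  d <- curve$rc[seq_len(t_le)] -
    (mean_curve[seq_len(t_le)] + 2 * sd_curve[seq_len(t_le)])
  x_star <- which.max(d)  # first index on ties
  fg_rank <- ranks[foreground_ids]
  structure(list(le_rank = as.integer(x_star),
                 target_ids = foreground_ids[fg_rank <= x_star],
                 positive = d[x_star] > 0,
                 max_diff = unname(d[x_star])),
            class = "leading_edge")
}

#' Run the full enrichment analysis
#'
#' For each ranking database: recovery curves for every feature, AUCs over
#' the top `auc_fraction` of the ranking, NES normalisation within the
#' database, and a leading edge per feature. Features with NES above the
#' threshold are reported, sorted by NES (descending) within each
#' database. Quick mode restricts the motif databases to a designated
#' subset collection and raises the NES threshold to 4.0.
#'
#' @param databases a `ranking_db` or list of them.
#' @param foreground character vector of foreground CRR ids (or a
#'   `foreground_set` from the input mapper).
#' @param auc_fraction top fraction of the ranking integrated by the AUC
#'   (default 0.005, the tool's genome-scale default; small toy universes
#'   need a larger fraction for the top window to hold more than a couple
#'   of ranks).
#' @param nes_threshold report features with NES strictly above this
#'   (default 3.0).
#' @param quick logical; use `quick_subset` and threshold 4.0.
#' @param quick_subset character vector of motif ids forming the quick
#'   collection (required when `quick = TRUE` for motif databases).
#' @param t_le leading-edge search window; default = the AUC cutoff.
#' @return An `enrichment_report`: list with `table` (one row per enriched
#'   feature), `details` (per-feature curves and leading edges),
#'   `all_scores` (every feature's AUC/NES) and `params`.
#' @export
run_enrichment <- function(databases, foreground, auc_fraction = 0.005,
                           nes_threshold = 3.0, quick = FALSE,
                           quick_subset = NULL, t_le = NULL) {
  if (inherits(databases, "ranking_db")) databases <- list(databases)
  if (inherits(foreground, "foreground_set")) foreground <- foreground$crr_ids
  foreground <- unique(as.character(foreground))
  if (!length(foreground)) stop("foreground is empty after mapping")
  if (quick) nes_threshold <- max(nes_threshold, 4.0)
  rows <- list(); details <- list(); all_scores <- list()
  for (db in databases) {
    ranks_m <- db$ranks
    if (quick && db$feature_type == "motif") {
      if (is.null(quick_subset)) stop("quick mode needs a quick_subset")
      keep <- intersect(rownames(ranks_m), quick_subset)
      if (length(keep) < 2) stop("quick subset leaves < 2 motifs")
      ranks_m <- ranks_m[keep, , drop = FALSE]
    }
    n <- ncol(ranks_m)
    t_auc <- threshold_rank(n, auc_fraction)
    t_le_db <- if (is.null(t_le)) t_auc else min(t_le, n)
    t_curve <- max(t_auc, t_le_db)
    miss <- setdiff(foreground, db$crr_ids)
    if (length(miss))
      stop("foreground id absent from database universe: ", miss[1])
    curves <- lapply(rownames(ranks_m), function(f)
      recovery_curve(stats::setNames(ranks_m[f, ], colnames(ranks_m)),
                     foreground, t_curve))
    names(curves) <- rownames(ranks_m)
    aucs <- vapply(curves, auc_recovery, 0, t_auc = t_auc)
    sc <- nes_scores(aucs)
    msd <- mean_sd_curves(curves)
    les <- lapply(rownames(ranks_m), function(f)
      leading_edge(curves[[f]], msd$mean, msd$sd, t_le_db,
                   stats::setNames(ranks_m[f, ], colnames(ranks_m)),
                   foreground))
    names(les) <- rownames(ranks_m)
    sc$db_label <- db$db_label
    sc$feature_type <- db$feature_type
    all_scores[[length(all_scores) + 1L]] <- sc
    hit <- sc[sc$nes > nes_threshold, , drop = FALSE]
    hit <- hit[order(-hit$nes), , drop = FALSE]
    if (nrow(hit)) {
      hit$le_rank <- vapply(hit$feature_id, function(f)
        les[[f]]$le_rank, 1L)
      hit$n_targets <- vapply(hit$feature_id, function(f)
        length(les[[f]]$target_ids), 1L)
      hit$targets <- lapply(hit$feature_id, function(f) les[[f]]$target_ids)
      rows[[length(rows) + 1L]] <- hit
    }
    details[[db$db_label]] <- list(curves = curves, mean_sd = msd,
                                   leading_edges = les, t_auc = t_auc,
                                   t_le = t_le_db)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature_id = character(), auc = numeric(), nes = numeric(),
               mu = numeric(), sigma = numeric(), db_label = character(),
               feature_type = character(), le_rank = integer(),
               n_targets = integer(), stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab,
                 all_scores = do.call(rbind, all_scores),
                 details = details,
                 foreground = foreground,
                 params = list(auc_fraction = auc_fraction,
                               nes_threshold = nes_threshold,
                               quick = quick,
                               t_le = t_le,
                               seeds = vapply(databases, `[[`, 1L, "seed"),
                               checksums = vapply(databases, `[[`, "",
                                                  "checksum"))),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf("enrichment_report: %d enriched feature(s), foreground %d, NES > %.1f\n",
              nrow(x$table), length(x$foreground), x$params$nes_threshold))
  if (nrow(x$table))
    print.data.frame(x$table[, c("feature_id", "feature_type", "db_label",
                                 "nes", "auc", "le_rank", "n_targets")],
                     digits = 4)
  invisible(x)
}

#' Combine several features into one new ranking
#'
#' Rank ratios of the selected features are aggregated region-wise with
#' [aggregate_rankings()] and regions are re-ranked by ascending combined
#' Q; the result can be fed back into [recovery_curve()] or a new
#' database.
#'
#' @param db a `ranking_db`.
#' @param feature_ids at least two feature ids present in `db`.
#' @param seed integer seed for tie-breaking (default: the database seed).
#' @return A `feature_ranking` with `feature_type = "combined"`.
#' @export
combine_features <- function(db, feature_ids, seed = db$seed) {
  if (length(feature_ids) < 2) stop("need at least two features to combine")
  miss <- setdiff(feature_ids, rownames(db$ranks))
  if (length(miss)) stop("unknown feature_id: ", miss[1])
  n <- ncol(db$ranks)
  ratios <- db$ranks[feature_ids, , drop = FALSE] / n
  q <- apply(ratios, 2, aggregate_rankings)
  scores_to_ranking(stats::setNames(-q, colnames(db$ranks)),
                    paste(feature_ids, collapse = "+"), seed,
                    feature_type = "combined")
}

#' Plot a recovery curve against the database mean
#'
#' @param curve a [recovery_curve()].
#' @param mean_curve,sd_curve optional database mean/sd curves.
#' @param le optional `leading_edge` to mark.
#' @param main plot title.
#' @export
plot_recovery <- function(curve, mean_curve = NULL, sd_curve = NULL,
                          le = NULL, main = "recovery curve") {
  x <- seq_along(curve$rc)
  graphics::plot(x, curve$rc, type = "s", xlab = "rank",
                 ylab = "foreground regions recovered", main = main)
  if (!is.null(mean_curve)) {
    graphics::lines(x, mean_curve[x], lty = 2)
    if (!is.null(sd_curve))
      graphics::lines(x, mean_curve[x] + 2 * sd_curve[x], lty = 3)
  }
  if (!is.null(le)) graphics::abline(v = le$le_rank, col = 2)
  invisible(NULL)
}
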