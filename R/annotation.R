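#' Post-enrichment interpretation
#'
#' Enriched motifs are linked to candidate transcription factors through
#' an evidence-typed motif-TF table, grouped into clusters of similar
#' motifs (SSD distance, Calinski-Harabasz model selection), and target
#' regions are assigned their closest gene. Two analyses can be compared
#' to find commonly or distinctively enriched motifs.
#' @name annotation
NULL

ssd_cols <- function(a, b) colSums((a - b)^2)

#' Sum-of-squared-distances dissimilarity between two PWMs
#'
#' Minimum over all ungapped offsets and both orientations (the reverse
#' complement of the second motif is also tried) of the mean
#' per-aligned-column sum of squared probability differences; columns of
#' the alignment span covered by only one motif are compared against the
#' other motif's background distribution, so length mismatches are
#' penalised proportionally. Symmetric, and 0 for identical motifs or a
#' motif against its own reverse complement.
#'
#' @param a,b `pwm` objects.
#' @return Non-negative dissimilarity.
#' @export
ssd_distance <- function(a, b) {
  best <- Inf
  for (bb in list(b, pwm_revcomp(b))) {
    ma <- t(a$matrix); mb <- t(bb$matrix)  # 4 x L
    la <- ncol(ma); lb <- ncol(mb)
    bg_a <- a$background; bg_b <- bb$background
    for (s in (-(lb - 1L)):(la - 1L)) {
      # a occupies columns 1..la, b occupies s+1..s+lb of the span
      span <- c(min(1L, s + 1L), max(la, s + lb))
      total <- 0
      for (col in span[1]:span[2]) {
        in_a <- col >= 1 && col <= la
        in_b <- col - s >= 1 && col - s <= lb
        if (in_a && in_b) {
          v <- sum((ma[, col] - mb[, col - s])^2)
        } else if (in_a) {
          v <- sum((ma[, col] - bg_b)^2)
        } else {
          v <- sum((mb[, col - s] - bg_a)^2)
        }
        total <- total + v
      }
      d <- total / (span[2] - span[1] + 1)
      if (d < best) best <- d
    }
  }
  best
}

#' Calinski-Harabasz index from a distance matrix
#'
#' Within/between sums of squares are recovered from pairwise squared
#' distances (W = sum over clusters of the mean pairwise squared distance
#' within the cluster / 2 per element), which agrees with the centroid
#' formulation in Euclidean space.
#' @noRd
ch_index <- function(D2, labels) {
  n <- length(labels)
  k <- length(unique(labels))
  if (k < 2 || k >= n) return(NA_real_)
  TT <- sum(D2) / (2 * n)
  W <- 0
  for (cl in unique(labels)) {
    i <- which(labels == cl)
    if (length(i) > 1) W <- W + sum(D2[i, i]) / (2 * length(i))
  }
  B <- TT - W
  if (W <= 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

#' Cluster enriched motifs by similarity
#'
#' Average-linkage hierarchical clustering on the [ssd_distance()] matrix;
#' the number of clusters maximises the Calinski-Harabasz index over
#' k = 2..min(10, n - 1, number of distinct motifs), falling back to a
#' single cluster for n <= 2 or when no split yields a finite index.
#' Clusters are ranked by their best member's NES and members are ranked
#' within their cluster by NES, mirroring the "cluster rank (member rank)"
#' labels of the report.
#'
#' @param pwms named list of `pwm` objects (the enriched motifs).
#' @param nes named numeric NES vector over the same motif ids.
#' @return data.frame with columns `motif_id`, `cluster_id`,
#'   `cluster_rank`, `within_rank`, `nes`; every motif appears exactly
#'   once.
#' @export
cluster_motifs <- function(pwms, nes) {
  ids <- names(pwms)
  stopifnot(!is.null(ids), all(ids %in% names(nes)))
  n <- length(ids)
  if (n == 1) {
    return(data.frame(motif_id = ids, cluster_id = 1L, cluster_rank = 1L,
                      within_rank = 1L, nes = unname(nes[ids]),
                      stringsAsFactors = FALSE))
  }
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- ssd_distance(pwms[[i]], pwms[[j]])
  }
  # distinct motifs under the zero-distance equivalence
  n_distinct <- length(unique(apply(D < 1e-12, 1, function(r)
    paste(which(r), collapse = ","))))
  labels <- rep(1L, n)
  kmax <- min(10L, n - 1L, n_distinct)
  if (n > 2 && kmax >= 2) {
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    D2 <- D^2
    ch <- vapply(2:kmax, function(k)
      ch_index(D2, stats::cutree(hc, k = k)), 0)
    if (any(is.finite(ch)))
      labels <- stats::cutree(hc, k = (2:kmax)[which.max(ch)])
  } else if (n == 2 && D[1, 2] > 1e-12) {
    labels <- c(1L, 2L)
  }
  best_nes <- tapply(nes[ids], labels, max)
  cl_rank <- stats::setNames(rank(-best_nes, ties.method = "first"),
                             names(best_nes))
  out <- data.frame(motif_id = ids, cluster_id = as.integer(labels),
                    cluster_rank = as.integer(cl_rank[as.character(labels)]),
                    nes = unname(nes[ids]), stringsAsFactors = FALSE)
  out$within_rank <- stats::ave(-out$nes, out$cluster_id,
                                FUN = function(x) rank(x, ties.method = "first"))
  out$within_rank <- as.integer(out$within_rank)
  out[order(out$cluster_rank, out$within_rank),
      c("motif_id", "cluster_id", "cluster_rank", "within_rank", "nes")]
}

#' Read a motif-to-TF evidence table
#'
#' TSV with columns `motif_id, tf, evidence, species, score`; `evidence`
#' must be one of `direct`, `orthology`, `similarity`.
#'
#' @param path file path.
#' @return data.frame of class `motif2tf_table`.
#' @export
read_motif2tf <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("motif_id", "tf", "evidence", "species") %in% names(tab)))
  bad <- setdiff(unique(tab$evidence), c("direct", "orthology", "similarity"))
  if (length(bad)) stop("unknown evidence type: ", bad[1])
  if (!"score" %in% names(tab)) tab$score <- NA_real_
  class(tab) <- c("motif2tf_table", "data.frame")
  tab
}

#' Candidate transcription factors for a motif
#'
#' TFs whose edges pass the evidence and species filters, ordered
#' direct > orthology > similarity (then by score, then symbol) and
#' deduplicated keeping the best evidence.
#'
#' @param motif_id motif identifier.
#' @param table a [read_motif2tf()] table (or equivalent data.frame).
#' @param evidence evidence categories to allow.
#' @param species optional species labels to allow (NULL = all).
#' @return data.frame with columns `tf`, `evidence`, `species`, `score`;
#'   empty for an unknown motif.
#' @export
motif2tf_lookup <- function(motif_id, table,
                            evidence = c("direct", "orthology", "similarity"),
                            species = NULL) {
  sub <- table[table$motif_id == motif_id & table$evidence %in% evidence, ,
               drop = FALSE]
  if (!is.null(species)) sub <- sub[sub$species %in% species, , drop = FALSE]
  if (!nrow(sub))
    return(data.frame(tf = character(), evidence = character(),
                      species = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  prio <- match(sub$evidence, c("direct", "orthology", "similarity"))
  sub <- sub[order(prio, -ifelse(is.na(sub$score), -Inf, sub$score), sub$tf), ,
             drop = FALSE]
  sub <- sub[!duplicated(sub$tf), , drop = FALSE]
  rownames(sub) <- NULL
  sub[, c("tf", "evidence", "species", "score")]
}

#' Closest gene per target region
#'
#' Each target is assigned the gene minimising the distance from the
#' target midpoint to the TSS on the same chromosome; ties go to the
#' lexicographically smallest symbol, and targets on chromosomes without
#' genes stay unassigned (`NA`).
#'
#' @param targets `region_set` of target regions.
#' @param annotation a `gene_annotation`.
#' @return data.frame with columns `region_id`, `gene`, `distance`.
#' @export
closest_genes <- function(targets, annotation) {
  ann <- annotation[order(annotation$gene), , drop = FALSE]  # tie rule
  out <- data.frame(region_id = targets$region_id, gene = NA_character_,
                    distance = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(targets))) {
    g <- ann[ann$chrom == targets$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    mid <- floor((targets$start[i] + targets$end[i]) / 2)
    d <- abs(mid - g$tss)
    j <- which.min(d)  # first = lexicographically smallest on ties
    out$gene[i] <- g$gene[j]
    out$distance[i] <- d[j]
  }
  out
}

#' Compare two enrichment reports
#'
#' Motifs (tracks are matched by exact id as well) are classified as
#' `common`, `a_only` or `b_only`; when cluster assignments are supplied,
#' clusters sharing any member motif are additionally matched at cluster
#' level.
#'
#' @param a,b `enrichment_report` objects (or data.frames with
#'   `feature_id` and `nes` columns).
#' @param clusters_a,clusters_b optional [cluster_motifs()] outputs for
#'   the two reports.
#' @return data.frame with columns `feature_id`, `cluster_id_a`,
#'   `cluster_id_b`, `nes_a`, `nes_b`, `status`, plus an attribute
#'   `cluster_common` (logical matrix of cluster-level sharing) when
#'   clusters are given.
#' @export
compare_reports <- function(a, b, clusters_a = NULL, clusters_b = NULL) {
  ta <- if (inherits(a, "enrichment_report")) a$table else a
  tb <- if (inherits(b, "enrichment_report")) b$table else b
  ids <- union(ta$feature_id, tb$feature_id)
  nes_a <- ta$nes[match(ids, ta$feature_id)]
  nes_b <- tb$nes[match(ids, tb$feature_id)]
  status <- ifelse(!is.na(nes_a) & !is.na(nes_b), "common",
                   ifelse(!is.na(nes_a), "a_only", "b_only"))
  out <- data.frame(feature_id = ids,
                    cluster_id_a = if (is.null(clusters_a)) NA_integer_ else
                      clusters_a$cluster_id[match(ids, clusters_a$motif_id)],
                    cluster_id_b = if (is.null(clusters_b)) NA_integer_ else
                      clusters_b$cluster_id[match(ids, clusters_b$motif_id)],
                    nes_a = nes_a, nes_b = nes_b, status = status,
                    stringsAsFactors = FALSE)
  if (!is.null(clusters_a) && !is.null(clusters_b)) {
    ca <- unique(clusters_a$cluster_id); cb <- unique(clusters_b$cluster_id)
    m <- matrix(FALSE, length(ca), length(cb), dimnames = list(ca, cb))
    for (i in ca) for (j in cb) {
      m[as.character(i), as.character(j)] <- length(intersect(
        clusters_a$motif_id[clusters_a$cluster_id == i],
        clusters_b$motif_id[clusters_b$cluster_id == j])) > 0
    }
    attr(out, "cluster_common") <- m
  }
  out
}
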