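#' Report, BED, and SIF writers
#'
#' Deterministic writers for the analysis outputs: the enrichment report
#' table (with "cluster rank (member rank)" labels for motifs), per-feature
#' target-region BED files, and a Simple Interaction File linking enriched
#' features, target regions and their closest genes for network viewers.
#' @name reporting
NULL

#' Write the enrichment report as TSV
#'
#' One row per enriched feature, sorted as in the report (NES descending
#' within each database). Motif rows get cluster / within-cluster ranks and
#' a `rank_label` of the form `"1 (2)"` (cluster rank, member rank) when a
#' clustering is supplied. All run parameters and seeds go to a JSON
#' metadata sidecar (`<path>.meta.json`) so reruns are fully reproducible.
#'
#' @param report an `enrichment_report` from [run_enrichment()].
#' @param path output TSV path.
#' @param clusters optional [cluster_motifs()] output for the enriched
#'   motifs.
#' @param tf_table optional [read_motif2tf()] table; adds a
#'   `candidate_tfs` column (comma-separated, best-evidence order).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, clusters = NULL, tf_table = NULL) {
  tab <- report$table
  cols <- c("rank_label", "cluster_rank", "within_rank", "feature_id",
            "feature_type", "db_label", "nes", "auc", "candidate_tfs",
            "le_rank", "n_targets", "target_ids")
  if (nrow(tab)) {
    if (!is.null(clusters)) {
      i <- match(tab$feature_id, clusters$motif_id)
      tab$cluster_rank <- clusters$cluster_rank[i]
      tab$within_rank <- clusters$within_rank[i]
    } else {
      tab$cluster_rank <- NA_integer_
      tab$within_rank <- NA_integer_
    }
    tab$rank_label <- ifelse(is.na(tab$cluster_rank), "",
                             sprintf("%d (%d)", tab$cluster_rank,
                                     tab$within_rank))
    tab$candidate_tfs <- if (is.null(tf_table)) "" else
      vapply(tab$feature_id, function(f)
        paste(motif2tf_lookup(f, tf_table)$tf, collapse = ","), "")
    tab$target_ids <- vapply(tab$targets, paste, "", collapse = ",")
    tab$nes <- sprintf("%.6f", tab$nes)
    tab$auc <- sprintf("%.6f", tab$auc)
    out <- tab[, cols]
  } else {
    out <- as.data.frame(stats::setNames(
      replicate(length(cols), character(0), simplify = FALSE), cols))
  }
  con <- file(path, "wb")
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(out))
    writeLines(do.call(sprintf, c(list(
      paste(rep("%s", length(cols)), collapse = "\t")),
      lapply(out, as.character))), con)
  close(con)
  meta <- report$params
  meta$foreground_size <- length(report$foreground)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Write leading-edge target regions as BED6
#'
#' Targets in genomic order; name = region_id, score = 1000 scaled down by
#' rank order of the target within the leading edge, strand ".". An
#' optional UCSC custom-track header can be prepended.
#'
#' @param le a `leading_edge` (from [leading_edge()] or
#'   `report$details[[db]]$leading_edges[[feature]]`).
#' @param crrs the CRR `region_set` the target ids resolve in.
#' @param path output BED path.
#' @param track_name when non-NULL, prepend
#'   `track name="<track_name>"` as the first line.
#' @return `path`, invisibly; an empty leading edge writes an empty file
#'   with a warning.
#' @export
write_target_bed <- function(le, crrs, path, track_name = NULL) {
  ids <- le$target_ids
  miss <- setdiff(ids, crrs$region_id)
  if (length(miss)) stop("target id not in CRR set: ", miss[1])
  if (!length(ids)) warning("empty leading edge; writing empty BED")
  sub <- crrs[match(ids, crrs$region_id), , drop = FALSE]
  ord <- order(sub$chrom, sub$start)
  sub <- sub[ord, , drop = FALSE]
  score <- if (nrow(sub)) round(1000 * rev(seq_len(nrow(sub))) / nrow(sub))
           else numeric()
  tl <- if (is.null(track_name)) NULL else
    sprintf('track name="%s"', track_name)
  write_bed(sub, path, bed6 = TRUE, score_from = score, track_line = tl)
  invisible(path)
}

#' Export the result network as a Simple Interaction File
#'
#' Whitespace-delimited SIF with two relations: one line
#' `feature_id targets region_id` per (enriched feature, leading-edge
#' region) pair and one line `region_id nearest gene` per region with an
#' assigned closest gene.
#'
#' @param report an `enrichment_report`.
#' @param gene_assignments optional [closest_genes()] output for the union
#'   of target regions.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(report, gene_assignments = NULL, path) {
  lines <- character()
  tab <- report$table
  for (i in seq_len(nrow(tab))) {
    for (t in tab$targets[[i]])
      lines <- c(lines, paste(tab$feature_id[i], "targets", t))
  }
  if (!is.null(gene_assignments)) {
    ga <- gene_assignments[!is.na(gene_assignments$gene), , drop = FALSE]
    lines <- c(lines, paste(ga$region_id, "nearest", ga$gene))
  }
  con <- file(path, "wb")
  writeLines(lines, con)
  close(con)
  invisible(path)
}

#' Parse a SIF file back into an edge table
#' @param path SIF file.
#' @return data.frame with columns `source`, `relation`, `target`.
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\\s+")
  if (any(lengths(parts) != 3)) stop("malformed SIF line")
  data.frame(source = vapply(parts, `[`, "", 1),
             relation = vapply(parts, `[`, "", 2),
             target = vapply(parts, `[`, "", 3),
             stringsAsFactors = FALSE)
}
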