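#' Candidate-regulatory-region (CRR) database construction
#'
#' Heterogeneous regulatory feature sets (open chromatin, TF and histone
#' ChIP peaks, ...) are merged into contiguous intervals, intervals
#' dominated by insulators or coding exons are removed, remaining intervals
#' are split around the excluded elements, size-filtered, and finally grown
#' toward a target size in directions that avoid insulators and exons.
#' @name crr_builder
NULL

#' CRR build configuration
#'
#' @param insulator_fraction drop a region when at least this fraction of it
#'   is covered by insulator elements (default 0.2).
#' @param exon_fraction drop a region when at least this fraction of it is
#'   covered by coding exons (default 0.8).
#' @param min_size regions and split fragments shorter than this many bp are
#'   removed (default 30).
#' @param target_size regions shorter than this are extended toward it where
#'   insulators/exons and chromosome bounds allow (default 1000).
#' @return A list of class `crr_config`.
#' @export
crr_config <- function(insulator_fraction = 0.2, exon_fraction = 0.8,
                       min_size = 30L, target_size = 1000L) {
  stopifnot(insulator_fraction >= 0, insulator_fraction <= 1,
            exon_fraction >= 0, exon_fraction <= 1,
            min_size < target_size, min_size >= 1)
  structure(list(insulator_fraction = insulator_fraction,
                 exon_fraction = exon_fraction,
                 min_size = as.integer(min_size),
                 target_size = as.integer(target_size)),
            class = "crr_config")
}

#' Merge feature region sets into contiguous intervals
#'
#' Union of all intervals with overlapping or book-ended (touching)
#' intervals coalesced; output sorted by (chrom, start) with fresh ids.
#'
#' @param feature_sets list of `region_set` objects sharing one genome tag.
#' @return A `region_set` of disjoint, sorted intervals.
#' @export
merge_feature_sets <- function(feature_sets) {
  stopifnot(is.list(feature_sets))
  if (!length(feature_sets))
    return(region_set(character(), integer(), integer()))
  tags <- unique(vapply(feature_sets, genome_tag, ""))
  if (length(tags) > 1)
    stop("mixed genome_tag: ", paste(tags, collapse = ", "))
  df <- do.call(rbind, lapply(feature_sets, function(x)
    data.frame(chrom = x$chrom, start = x$start, end = x$end,
               stringsAsFactors = FALSE)))
  all <- GenomicRanges::GRanges(df$chrom,
                                IRanges::IRanges(df$start + 1L, df$end))
  red <- GenomicRanges::reduce(GenomicRanges::sort(all))  # merges book-ended
  granges_to_region_set(red, genome_tag = tags)
}

ins_exon_fractions <- function(regions, insulators, exons) {
  w <- region_widths(regions)
  list(ins = covered_widths(regions, insulators) / w,
       ex = covered_widths(regions, exons) / w)
}

#' Remove and split regions around insulators and coding exons
#'
#' Three steps: (1) drop regions whose insulator-covered fraction is at
#' least `insulator_fraction` or whose exon-covered fraction is at least
#' `exon_fraction`; (2) regions that still intersect an insulator or exon
#' are cut at the excluded-interval boundaries, keeping only fragments with
#' no excluded base; (3) fragments (and untouched regions) shorter than
#' `min_size` are dropped.
#'
#' @param merged a `region_set` (normally the output of
#'   [merge_feature_sets()]).
#' @param insulators,exons `region_set`s of elements to exclude.
#' @param config a [crr_config()].
#' @return A `region_set`; ids are regenerated from coordinates.
#' @export
apply_exclusions <- function(merged, insulators, exons, config = crr_config()) {
  if (!nrow(merged)) return(merged)
  fr <- ins_exon_fractions(merged, insulators, exons)
  keep <- fr$ins < config$insulator_fraction & fr$ex < config$exon_fraction
  kept <- merged[keep, , drop = FALSE]
  if (!nrow(kept))
    return(region_set(character(), integer(), integer(),
                      genome_tag = genome_tag(merged)))
  forb <- forbidden_union(insulators, exons)
  pieces <- if (nrow(forb)) {
    # per-region subtraction keeps fragments attributable to their source
    # region even if the input set is not disjoint
    h <- harmonized(as_granges(kept),
                    GenomicRanges::reduce(as_granges(forb)))
    kgr <- h$a; fgr <- h$b
    res <- lapply(seq_along(kgr), function(i)
      GenomicRanges::setdiff(kgr[i], fgr))
    do.call(c, unname(res))
  } else {
    as_granges(kept)
  }
  pieces <- pieces[GenomicRanges::width(pieces) >= config$min_size]
  pieces <- GenomicRanges::sort(pieces)
  granges_to_region_set(pieces, genome_tag = genome_tag(merged))
}

forbidden_union <- function(insulators, exons) {
  ril <- list(insulators, exons)
  ril <- ril[vapply(ril, nrow, 1L) > 0]
  if (!length(ril)) return(region_set(character(), integer(), integer()))
  merge_feature_sets(lapply(ril, function(x) {
    attr(x, "genome_tag") <- "forbidden"
    x
  }))
}

#' Extend short regions toward the target size
#'
#' Regions shorter than `target_size` are grown toward it: symmetrically
#' when both flanks are free, one-sided into the free flank when the other
#' is blocked by an insulator/exon or a chromosome bound, and each side up
#' to its own limit when both are partially blocked (an odd deficit puts
#' the extra base on the left flank). Regions already at or above the
#' target are unchanged; no output base overlaps `forbidden`.
#'
#' @param regions exclusion-filtered `region_set`.
#' @param forbidden `region_set` union of insulators and exons.
#' @param config a [crr_config()].
#' @param chrom_sizes optional named integer vector bounding growth on the
#'   right of each chromosome (left bound is always 0).
#' @return A `region_set` with the same region order and ids.
#' @export
extend_to_target <- function(regions, forbidden, config = crr_config(),
                             chrom_sizes = NULL) {
  if (!nrow(regions)) return(regions)
  fgr <- GenomicRanges::reduce(as_granges(forbidden))
  fchrom <- as.character(GenomicRanges::seqnames(fgr))
  fstart0 <- GenomicRanges::start(fgr) - 1L
  fend0 <- GenomicRanges::end(fgr)
  start <- regions$start
  end <- regions$end
  for (i in seq_len(nrow(regions))) {
    d <- config$target_size - (end[i] - start[i])
    if (d <= 0) next
    on_chr <- fchrom == regions$chrom[i]
    left_bound <- 0L
    le <- fend0[on_chr & fend0 <= start[i]]
    if (length(le)) left_bound <- max(le)
    right_bound <- if (!is.null(chrom_sizes) &&
                       regions$chrom[i] %in% names(chrom_sizes))
      as.integer(chrom_sizes[[regions$chrom[i]]]) else .Machine$integer.max
    rs <- fstart0[on_chr & fstart0 >= end[i]]
    if (length(rs)) right_bound <- min(right_bound, min(rs))
    free_left <- start[i] - left_bound
    free_right <- right_bound - end[i]
    l <- min(free_left, ceiling(d / 2))
    r <- min(free_right, d - l)
    l <- min(free_left, d - r)
    start[i] <- start[i] - l
    end[i] <- end[i] + r
  }
  region_set(regions$chrom, start, end, region_id = regions$region_id,
             genome_tag = genome_tag(regions))
}

#' Build the CRR database
#'
#' Composition of [merge_feature_sets()], [apply_exclusions()] and
#' [extend_to_target()]. Output is sorted by (chrom, start) and regions get
#' sequential ids `crr_00001 ...`; per-stage region counts are attached as
#' the `build_log` attribute.
#'
#' @inheritParams apply_exclusions
#' @inheritParams extend_to_target
#' @param feature_sets list of `region_set`s of regulatory features.
#' @return A `region_set` of CRRs (regions may overlap after extension;
#'   they are never re-merged).
#' @export
build_crr_database <- function(feature_sets, insulators, exons,
                               config = crr_config(), chrom_sizes = NULL) {
  merged <- merge_feature_sets(feature_sets)
  cleaned <- apply_exclusions(merged, insulators, exons, config)
  forb <- forbidden_union(insulators, exons)
  extended <- extend_to_target(cleaned, forb, config, chrom_sizes)
  ord <- order(extended$chrom, extended$start, extended$end)
  extended <- extended[ord, , drop = FALSE]
  out <- region_set(extended$chrom, extended$start, extended$end,
                    region_id = sprintf("crr_%05d", seq_len(nrow(extended))),
                    genome_tag = genome_tag(extended))
  attr(out, "build_log") <- list(merged = nrow(merged),
                                 after_exclusion = nrow(cleaned),
                                 final = nrow(out))
  out
}
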