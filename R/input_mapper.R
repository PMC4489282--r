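#' Mapping user input onto the CRR universe
#'
#' User input is either a set of genomic regions/peaks or a list of gene
#' symbols; both are converted into a foreground subset of CRR ids, the
#' query of the enrichment analysis.
#' @name input_mapper
NULL

#' Gene search-space specification
#'
#' @param mode `"around_tss"` (a window of `upstream_bp` + `downstream_bp`
#'   centred on the TSS, strand-aware) or `"upstream_plus_introns"` (the
#'   strand-aware upstream window plus all intron intervals). Defaults of
#'   the published tool: 20 kb around the TSS for human/mouse (here split
#'   +/-10 kb), 5 kb upstream plus introns for fly.
#' @param upstream_bp,downstream_bp window extents in bp (>= 0).
#' @return A list of class `gene_window_spec`.
#' @export
gene_window_spec <- function(mode = c("around_tss", "upstream_plus_introns"),
                             upstream_bp = 10000L, downstream_bp = 10000L) {
  mode <- match.arg(mode)
  stopifnot(upstream_bp >= 0, downstream_bp >= 0)
  structure(list(mode = mode, upstream_bp = as.integer(upstream_bp),
                 downstream_bp = as.integer(downstream_bp)),
            class = "gene_window_spec")
}

new_foreground_set <- function(crr_ids, provenance, unmapped, report = NULL) {
  structure(list(crr_ids = crr_ids, provenance = provenance,
                 unmapped = unmapped, report = report),
            class = "foreground_set")
}

#' @export
print.foreground_set <- function(x, ...) {
  cat(sprintf("foreground_set: %d CRRs (%d input item(s) unmapped)\n",
              length(x$crr_ids), length(x$unmapped)))
  invisible(x)
}

#' Map input regions/peaks to CRRs
#'
#' A CRR enters the foreground when at least `min_fraction` of its length
#' is covered by the union of the input regions (the published default is
#' 0.4). The result carries a per-pair overlap report and, per CRR, the
#' provenance list of every input peak intersecting it.
#'
#' @param input_regions `region_set` of user peaks/regions.
#' @param crrs the CRR `region_set`.
#' @param min_fraction inclusion threshold in \[0, 1\].
#' @return A `foreground_set` with elements `crr_ids`, `provenance` (named
#'   list of contributing input ids per CRR), `unmapped` (input ids that
#'   hit no CRR) and `report` (data.frame: input item, CRR id, overlap bp,
#'   fraction of the CRR covered by all input).
#' @export
map_regions_to_crrs <- function(input_regions, crrs, min_fraction = 0.4) {
  if (min_fraction < 0 || min_fraction > 1)
    stop("min_fraction must lie in [0, 1]")
  if (!identical(genome_tag(input_regions), genome_tag(crrs)))
    stop("input regions and CRRs carry different genome tags")
  cov <- covered_widths(crrs, input_regions)
  frac <- cov / region_widths(crrs)
  included <- crrs$region_id[frac >= min_fraction]
  h <- harmonized(as_granges(crrs), as_granges(input_regions))
  hits <- GenomicRanges::findOverlaps(h$a, h$b)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  pi_w <- if (length(hits))
    GenomicRanges::width(GenomicRanges::pintersect(
      h$a[qh], h$b[sh])) else integer()
  report <- data.frame(input_id = input_regions$region_id[sh],
                       crr_id = crrs$region_id[qh],
                       overlap_bp = pi_w,
                       crr_fraction = frac[qh],
                       included = crrs$region_id[qh] %in% included,
                       stringsAsFactors = FALSE)
  prov <- split(report$input_id[report$included], report$crr_id[report$included])
  prov <- prov[included[included %in% names(prov)]]
  unmapped <- setdiff(input_regions$region_id, report$input_id)
  new_foreground_set(included, prov, unmapped, report)
}

#' Strand-aware gene search space
#'
#' For `around_tss` on the + strand the space is
#' `[tss - upstream_bp, tss + downstream_bp)`; on the - strand it is the
#' exact mirror image about the TSS base. For `upstream_plus_introns` the
#' space is the strand-aware upstream window plus every intron interval.
#' Coordinates are clamped at 0.
#' @noRd
gene_space <- function(entry, window) {
  up <- window$upstream_bp; down <- window$downstream_bp
  tss <- entry$tss
  if (window$mode == "around_tss") {
    iv <- if (entry$strand == "+")
      c(tss - up, tss + down) else c(tss - down + 1L, tss + up + 1L)
    ivs <- matrix(iv, ncol = 2)
  } else {
    iv <- if (entry$strand == "+")
      c(tss - up, tss) else c(tss + 1L, tss + 1L + up)
    ivs <- rbind(matrix(iv, ncol = 2), entry$introns[[1]])
  }
  ivs[, 1] <- pmax(ivs[, 1], 0L)
  ivs[ivs[, 2] > ivs[, 1], , drop = FALSE]
}

#' Map gene symbols to CRRs
#'
#' Each gene contributes a search space (see [gene_window_spec()]); a CRR
#' enters the foreground when it intersects any gene's space by >= 1 bp
#' (the fraction-of-overlap threshold applies to region input only). Gene
#' symbols are matched case-sensitively after whitespace stripping; genes
#' absent from the annotation are reported in `unmapped`.
#'
#' @param genes character vector of gene symbols.
#' @param annotation a `gene_annotation` from [read_gene_annotation()].
#' @param window a [gene_window_spec()].
#' @param crrs the CRR `region_set`.
#' @return A `foreground_set`; `provenance` lists the contributing genes
#'   per CRR.
#' @export
map_genes_to_crrs <- function(genes, annotation, window, crrs) {
  genes <- trimws(genes)
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop("empty gene list")
  if (window$mode == "upstream_plus_introns" &&
      !"introns" %in% names(annotation))
    stop("annotation lacks introns required for upstream_plus_introns")
  known <- genes[genes %in% annotation$gene]
  unmapped <- setdiff(genes, known)
  spaces <- list(); space_gene <- character()
  for (g in known) {
    e <- annotation[annotation$gene == g, , drop = FALSE]
    ivs <- gene_space(e, window)
    if (nrow(ivs)) {
      spaces[[length(spaces) + 1L]] <-
        data.frame(chrom = e$chrom, start = ivs[, 1], end = ivs[, 2],
                   gene = g, stringsAsFactors = FALSE)
    }
  }
  if (!length(spaces)) stop("no gene could be mapped; unmapped: ",
                            paste(unmapped, collapse = ", "))
  sp <- do.call(rbind, spaces)
  spr <- region_set(sp$chrom, sp$start, sp$end,
                    region_id = sprintf("space_%d", seq_len(nrow(sp))),
                    genome_tag = genome_tag(crrs))
  h <- harmonized(as_granges(crrs), as_granges(spr))
  hits <- GenomicRanges::findOverlaps(h$a, h$b)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  if (!length(qh)) stop("no gene could be mapped to any CRR")
  included <- unique(crrs$region_id[qh])
  included <- crrs$region_id[crrs$region_id %in% included]  # universe order
  prov <- lapply(split(sp$gene[sh], crrs$region_id[qh]), unique)
  prov <- prov[included]
  report <- data.frame(input_id = sp$gene[sh],
                       crr_id = crrs$region_id[qh],
                       stringsAsFactors = FALSE)
  report <- unique(report)
  new_foreground_set(included, prov, unmapped, report)
}
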