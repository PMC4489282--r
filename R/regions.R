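#' Region containers and interval arithmetic
#'
#' All coordinates in this package are 0-based half-open (BED convention):
#' a region covers bases `start .. end-1` and has length `end - start`.
#' Chromosome names are opaque strings ("chr1" != "1"); no aliasing is done.
#' @name regions
NULL

#' Construct a region set
#'
#' The basic container used throughout: an ordered collection of genomic
#' intervals with unique string identifiers, tagged with a genome build label.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive.
#' @param end integer vector, 0-based exclusive; must satisfy `start < end`.
#' @param region_id unique identifiers; auto-generated as `chrom:start-end`
#'   (made unique with a numeric suffix) when `NULL`.
#' @param score optional numeric per-region score (e.g. narrowPeak signalValue).
#' @param genome_tag genome build label; region sets from different builds
#'   never mix.
#' @return An object of class `region_set`: a data.frame with columns
#'   `chrom`, `start`, `end`, `region_id` (and `score` if given).
#' @export
region_set <- function(chrom, start, end, region_id = NULL, score = NULL,
                       genome_tag = "genome") {
  start <- as.integer(start)
  end <- as.integer(end)
  n <- max(length(start), length(end), length(chrom))
  if (n > 0 && length(chrom) %in% c(1L, n)) {
    chrom <- rep_len(as.character(chrom), n)
  } else {
    chrom <- as.character(chrom)
  }
  stopifnot(length(chrom) == n, length(start) == n, length(end) == n)
  if (n > 0) {
    if (any(start < 0)) stop("negative start coordinate")
    bad <- which(start >= end)
    if (length(bad)) stop("start >= end for region ", bad[1])
  }
  if (is.null(region_id)) {
    region_id <- make.unique(sprintf("%s:%d-%d", chrom, start, end), sep = "_")
  } else {
    region_id <- as.character(region_id)
    if (anyDuplicated(region_id))
      stop("duplicate region_id: ", region_id[duplicated(region_id)][1])
  }
  df <- data.frame(chrom = chrom, start = start, end = end,
                   region_id = region_id, stringsAsFactors = FALSE)
  if (!is.null(score)) df$score <- as.numeric(score)
  structure(df, class = c("region_set", "data.frame"), genome_tag = genome_tag)
}

#' @export
`[.region_set` <- function(x, ...) {
  tag <- attr(x, "genome_tag")
  out <- NextMethod()
  if (is.data.frame(out)) {
    class(out) <- c("region_set", "data.frame")
    attr(out, "genome_tag") <- tag
    rownames(out) <- NULL
  }
  out
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set: %d regions on genome '%s'\n",
              nrow(x), attr(x, "genome_tag")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

genome_tag <- function(x) attr(x, "genome_tag")

region_widths <- function(x) x$end - x$start

#' Convert a region set to GRanges (1-based closed) and back
#' @noRd
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    region_id = x$region_id
  )
}

# put two GRanges on the union of their seqlevels so range operations do
# not warn about disjoint chromosome sets
harmonized <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a = a, b = b)
}

granges_to_region_set <- function(gr, genome_tag = "genome", region_id = NULL) {
  region_set(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    region_id = region_id,
    genome_tag = genome_tag
  )
}

#' Read a BED / narrowPeak file
#'
#' Accepts BED3/BED6 and ENCODE narrowPeak/broadPeak. Coordinates are kept
#' as written (BED is already 0-based half-open). Lines starting with
#' `track`, `browser` or `#` are skipped.
#'
#' @param path file path.
#' @param with_score if `TRUE`, a numeric score is extracted per region.
#' @param score_col column holding the score when `with_score` (5 for BED
#'   score, 7 for narrowPeak/broadPeak signalValue).
#' @param genome_tag genome build label to stamp on the result.
#' @return A `region_set`; region ids come from the name column (column 4)
#'   when present and non-".", otherwise `chrom:start-end`.
#' @export
read_bed <- function(path, with_score = FALSE, score_col = 5L,
                     genome_tag = "genome") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(region_set(character(), integer(), integer(),
                                        genome_tag = genome_tag))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3))
    stop("malformed line ", lineno[which(ncol < 3)[1]], ": fewer than 3 columns")
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed line ", lineno[bad[1]], ": non-numeric coordinates")
  bad <- which(start >= end)
  if (length(bad))
    stop("start >= end at line ", lineno[bad[1]])
  name <- rep(NA_character_, length(lines))
  has4 <- ncol >= 4L
  name[has4] <- vapply(fields[has4], `[`, "", 4L)
  name[name %in% c(".", "")] <- NA_character_
  ids <- ifelse(is.na(name), sprintf("%s:%d-%d", chrom, start, end), name)
  if (any(is.na(name))) ids <- make.unique(ids, sep = "_")
  if (anyDuplicated(ids))
    stop("duplicate region name: ", ids[duplicated(ids)][1])
  score <- NULL
  if (with_score) {
    short <- which(ncol < score_col)
    if (length(short))
      stop("missing score column ", score_col, " at line ", lineno[short[1]])
    score <- suppressWarnings(as.numeric(vapply(fields, `[`, "", score_col)))
    bad <- which(is.na(score))
    if (length(bad))
      stop("non-numeric score at line ", lineno[bad[1]])
  }
  region_set(chrom, start, end, region_id = ids, score = score,
             genome_tag = genome_tag)
}

#' Write a region set as BED
#'
#' Tab-separated, no header; BED6 when `bed6 = TRUE` (name = region_id,
#' score column from `score_from`, strand ".").
#'
#' @param x a `region_set`.
#' @param path output file.
#' @param bed6 write six columns instead of four.
#' @param score_from numeric vector of scores for column 5 (recycled 0).
#' @param track_line optional UCSC custom-track header line to prepend.
#' @export
write_bed <- function(x, path, bed6 = FALSE, score_from = NULL,
                      track_line = NULL) {
  con <- file(path, "wb")  # binary mode: deterministic \n on every platform
  on.exit(close(con))
  if (!is.null(track_line)) writeLines(track_line, con)
  if (!nrow(x)) return(invisible(path))
  if (bed6) {
    sc <- if (is.null(score_from)) rep(0, nrow(x)) else score_from
    lines <- sprintf("%s\t%d\t%d\t%s\t%s\t.", x$chrom, x$start, x$end,
                     x$region_id, format(sc, trim = TRUE, scientific = FALSE))
  } else {
    lines <- sprintf("%s\t%d\t%d\t%s", x$chrom, x$start, x$end, x$region_id)
  }
  writeLines(lines, con)
  invisible(path)
}

#' Read gene annotation
#'
#' Two dialects: `tss_table`, a TSV with header columns
#' `gene, chrom, strand, tss` (tss 0-based); and `gtf_lite`, a minimal GTF
#' whose `exon` lines (1-based inclusive, `gene_id` attribute required) are
#' collapsed to a union-exon model per gene: the TSS is the 5'-most position
#' respecting strand and introns are the gaps between consecutive union exons.
#'
#' @param path file path.
#' @param dialect `"tss_table"` or `"gtf_lite"`.
#' @return A data.frame of class `gene_annotation` with columns `gene`,
#'   `chrom`, `strand`, `tss` and a list-column `introns` (each element a
#'   two-column matrix of 0-based half-open intervals).
#' @export
read_gene_annotation <- function(path, dialect = c("tss_table", "gtf_lite")) {
  dialect <- match.arg(dialect)
  if (dialect == "tss_table") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    stopifnot(all(c("gene", "chrom", "strand", "tss") %in% names(tab)))
    if (anyDuplicated(tab$gene))
      stop("duplicate gene: ", tab$gene[duplicated(tab$gene)][1])
    if (!all(tab$strand %in% c("+", "-")))
      stop("unknown strand: ", setdiff(tab$strand, c("+", "-"))[1])
    ann <- data.frame(gene = tab$gene, chrom = tab$chrom, strand = tab$strand,
                      tss = as.integer(tab$tss), stringsAsFactors = FALSE)
    ann$introns <- replicate(nrow(ann),
                             matrix(integer(), ncol = 2,
                                    dimnames = list(NULL, c("start", "end"))),
                             simplify = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    type <- vapply(fields, `[`, "", 3L)
    ex <- fields[type == "exon"]
    if (!length(ex)) stop("no exon lines in GTF")
    gid <- vapply(ex, function(f) {
      m <- regmatches(f[9], regexec('gene_id[ =]+"?([^";]+)"?', f[9]))[[1]]
      if (length(m) < 2) stop("exon line without gene_id attribute")
      m[2]
    }, "")
    chrom <- vapply(ex, `[`, "", 1L)
    start <- as.integer(vapply(ex, `[`, "", 4L)) - 1L  # GTF 1-based -> 0-based
    end <- as.integer(vapply(ex, `[`, "", 5L))
    strand <- vapply(ex, `[`, "", 7L)
    if (!all(strand %in% c("+", "-"))) stop("unknown strand in GTF")
    genes <- unique(gid)
    rows <- lapply(genes, function(g) {
      i <- which(gid == g)
      if (length(unique(chrom[i])) > 1 || length(unique(strand[i])) > 1)
        stop("gene ", g, " spans chromosomes or strands")
      ir <- IRanges::reduce(IRanges::IRanges(start[i] + 1L, end[i]))
      es <- IRanges::start(ir) - 1L
      ee <- IRanges::end(ir)
      tss <- if (strand[i][1] == "+") min(es) else max(ee) - 1L
      introns <- if (length(es) > 1) {
        cbind(start = ee[-length(ee)], end = es[-1])
      } else {
        matrix(integer(), ncol = 2, dimnames = list(NULL, c("start", "end")))
      }
      list(gene = g, chrom = chrom[i][1], strand = strand[i][1],
           tss = tss, introns = introns)
    })
    ann <- data.frame(gene = vapply(rows, `[[`, "", "gene"),
                      chrom = vapply(rows, `[[`, "", "chrom"),
                      strand = vapply(rows, `[[`, "", "strand"),
                      tss = vapply(rows, function(r) as.integer(r$tss), 1L),
                      stringsAsFactors = FALSE)
    ann$introns <- lapply(rows, `[[`, "introns")
  }
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Write a TSS-table gene annotation
#' @param ann a `gene_annotation` (introns are not representable and dropped).
#' @param path output TSV.
#' @export
write_tss_table <- function(ann, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("gene\tchrom\tstrand\ttss",
               sprintf("%s\t%s\t%s\t%d", ann$gene, ann$chrom, ann$strand,
                       ann$tss)), con)
  invisible(path)
}

#' Fraction of a query region covered by a region set
#'
#' The length of the union of intersections of `query` with all regions in
#' `others`, divided by the query length. Invariant to the order and
#' fragmentation of `others`.
#'
#' @param query a single-row `region_set` or a list/vector with `chrom`,
#'   `start`, `end`.
#' @param others a `region_set`.
#' @return Fraction in \[0, 1\]; 0 when nothing overlaps.
#' @export
overlap_fraction <- function(query, others) {
  if (inherits(query, "region_set")) {
    stopifnot(nrow(query) == 1)
    q <- query
  } else {
    q <- region_set(query$chrom, query$start, query$end)
  }
  covered_widths(q, others) / (q$end - q$start)
}

#' Per-region covered base counts (union of intersections), vectorized
#' @noRd
covered_widths <- function(queries, others) {
  if (!nrow(others) || !nrow(queries)) return(numeric(nrow(queries)))
  h <- harmonized(as_granges(queries),
                  GenomicRanges::reduce(as_granges(others)))
  qgr <- h$a; red <- h$b
  hits <- GenomicRanges::findOverlaps(qgr, red)
  if (!length(hits)) return(numeric(nrow(queries)))
  pi <- GenomicRanges::pintersect(qgr[S4Vectors::queryHits(hits)],
                                  red[S4Vectors::subjectHits(hits)])
  w <- tapply(GenomicRanges::width(pi), S4Vectors::queryHits(hits), sum)
  out <- numeric(nrow(queries))
  out[as.integer(names(w))] <- as.numeric(w)
  out
}
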