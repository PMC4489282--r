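#' Position weight matrices
#'
#' A PWM is an L x 4 matrix of per-position nucleotide probabilities over
#' (A, C, G, T) with an associated background distribution. Count matrices
#' (Cluster-Buster text format, JASPAR-style) are converted to
#' probabilities with a pseudocount.
#' @name pwm
NULL

DNA <- c("A", "C", "G", "T")

#' Construct a PWM
#'
#' @param matrix numeric L x 4 matrix of probabilities, columns (A,C,G,T);
#'   each row must sum to 1 (tolerance 1e-9) with all entries > 0.
#' @param motif_id identifier string.
#' @param background length-4 background probabilities (default uniform).
#' @return An object of class `pwm`.
#' @export
pwm <- function(matrix, motif_id, background = rep(0.25, 4)) {
  matrix <- as.matrix(matrix)
  stopifnot(ncol(matrix) == 4, nrow(matrix) >= 1,
            length(background) == 4)
  if (any(matrix <= 0)) stop("PWM entries must be > 0 (apply a pseudocount)")
  if (any(abs(rowSums(matrix) - 1) > 1e-9))
    stop("PWM rows must sum to 1")
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  colnames(matrix) <- DNA
  structure(list(motif_id = as.character(motif_id), matrix = matrix,
                 background = as.numeric(background)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s' (%d bp), consensus %s\n", x$motif_id,
              nrow(x$matrix), pwm_consensus(x)))
  invisible(x)
}

#' Convert a count matrix to a PWM
#'
#' @param counts L x 4 non-negative count matrix, columns (A,C,G,T).
#' @param motif_id identifier.
#' @param pseudocount added to every cell before normalisation (default
#'   0.001, enough to keep log-odds finite without distorting informative
#'   positions).
#' @param background background distribution.
#' @return A `pwm`.
#' @export
pwm_from_counts <- function(counts, motif_id, pseudocount = 0.001,
                            background = rep(0.25, 4)) {
  counts <- as.matrix(counts) + pseudocount
  pwm(counts / rowSums(counts), motif_id, background)
}

#' Motif length in bp
#' @param x a `pwm`.
#' @export
pwm_length <- function(x) nrow(x$matrix)

#' Reverse complement of a PWM
#' @param x a `pwm`.
#' @return A `pwm` describing the same motif on the opposite strand.
#' @export
pwm_revcomp <- function(x) {
  m <- x$matrix[rev(seq_len(nrow(x$matrix))), c(4, 3, 2, 1), drop = FALSE]
  colnames(m) <- DNA
  pwm(m, x$motif_id, x$background[c(4, 3, 2, 1)])
}

#' Consensus sequence of a PWM
#' @param x a `pwm`.
#' @export
pwm_consensus <- function(x) {
  paste(DNA[apply(x$matrix, 1, which.max)], collapse = "")
}

#' Read a PWM collection
#'
#' Supports the Cluster-Buster text format (`>name` followed by rows of
#' four counts A C G T) and JASPAR-style matrices (`>ID name` followed by
#' four rows `A [ n1 n2 ... ]`, one per base).
#'
#' @param path file path.
#' @param format `"clusterbuster"` or `"jaspar"`.
#' @param pseudocount,background passed to [pwm_from_counts()].
#' @return Named list of `pwm` objects.
#' @export
read_pwms <- function(path, format = c("clusterbuster", "jaspar"),
                      pseudocount = 0.001, background = rep(0.25, 4)) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no motif records in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- list()
  for (k in seq_along(starts)) {
    header <- sub("^>\\s*", "", lines[starts[k]])
    id <- strsplit(trimws(header), "\\s+")[[1]][1]
    body <- lines[(starts[k] + 1L):ends[k]]
    if (format == "clusterbuster") {
      rows <- lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
      if (any(lengths(rows) != 4)) stop("malformed count row in motif ", id)
      counts <- do.call(rbind, rows)
    } else {
      if (length(body) != 4) stop("JASPAR motif ", id, " needs 4 base rows")
      base <- toupper(substr(trimws(body), 1, 1))
      vals <- lapply(body, function(l) {
        l <- gsub("[][]", " ", sub("^\\s*[ACGTacgt]", "", l))
        as.numeric(strsplit(trimws(l), "\\s+")[[1]])
      })
      if (length(unique(lengths(vals))) != 1)
        stop("ragged JASPAR matrix for motif ", id)
      counts <- t(do.call(rbind, vals)[match(DNA, base), , drop = FALSE])
    }
    if (id %in% names(out)) stop("duplicate motif_id: ", id)
    out[[id]] <- pwm_from_counts(counts, id, pseudocount, background)
  }
  out
}

#' Write PWMs in Cluster-Buster text format
#'
#' Probabilities are written scaled to counts out of 100 (sufficient for a
#' lossless round-trip at the precision used by the fixture generator).
#'
#' @param pwms named list of `pwm` objects.
#' @param path output file.
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$motif_id), con)
    writeLines(apply(p$matrix, 1, function(r)
      paste(format(r, trim = TRUE, scientific = FALSE, digits = 10),
            collapse = "\t")), con)
  }
  invisible(path)
}
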