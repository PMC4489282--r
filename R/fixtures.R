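#' Deterministic synthetic fixtures
#'
#' Generates toy genomes, regulatory feature tracks, PWMs with planted
#' binding sites, scored peak tracks and gene annotations so that every
#' pipeline stage can be exercised end-to-end without any download. All
#' randomness flows from one integer seed; regenerating with the same seed
#' reproduces every file byte-identically.
#'
#' The generator emulates: an i.i.d. background genome (no Markov
#' structure, so PWM log-odds are exactly calibrated to the generator
#' composition), peak-like regulatory features on a loose grid,
#' insulator/exon elements that trigger the exclusion rules, a motif
#' planted at near-consensus strength into a known subset of CRRs, and a
#' peak track with elevated signal on the same subset. It does not emulate
#' chromatin-domain structure, realistic peak shapes or sequence
#' conservation across genomes.
#' @name synthetic_fixtures
NULL

#' Generate an i.i.d. random genome
#'
#' @param seed integer seed.
#' @param chrom_sizes named integer vector of chromosome lengths (>= 1 kb).
#' @param gc GC fraction in (0, 1); P(G) = P(C) = gc/2.
#' @return Named character vector, one sequence per chromosome.
#' @export
make_genome <- function(seed, chrom_sizes, gc = 0.5) {
  stopifnot(all(chrom_sizes >= 1000), gc > 0, gc < 1,
            !is.null(names(chrom_sizes)))
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  with_seed(seed, {
    out <- vapply(names(chrom_sizes), function(ch)
      paste(sample(DNA, chrom_sizes[[ch]], replace = TRUE, prob = p),
            collapse = ""), "")
    out
  })
}

#' Sample one site from a PWM at a given temperature
#'
#' `strength` is a sampling temperature: per position, bases are drawn
#' with probability proportional to `p^(1/strength)`; the zero-temperature
#' limit (`strength = 0`) returns the consensus.
#' @noRd
sample_site <- function(pwm, strength) {
  m <- pwm$matrix
  if (strength <= 0) return(pwm_consensus(pwm))
  paste(apply(m, 1, function(row) {
    w <- row^(1 / strength)
    sample(DNA, 1, prob = w / sum(w))
  }), collapse = "")
}

#' Plant motif instances into target regions of a genome
#'
#' Writes `sites_per_region` sampled motif instances (random strand) into
#' each target region at recorded, non-overlapping positions; all other
#' sequence is untouched.
#'
#' @param genome named character vector (from [make_genome()]).
#' @param crrs `region_set` the target ids resolve in.
#' @param pwm the motif to plant.
#' @param target_region_ids ids of the regions receiving sites.
#' @param sites_per_region sites per region (0 = genome unchanged).
#' @param strength sampling temperature (see details; 0 = consensus).
#' @param seed integer seed.
#' @return List with `genome` (modified) and `truth` (data.frame:
#'   region_id, pos (0-based genome position), strand, site).
#' @export
plant_motif <- function(genome, crrs, pwm, target_region_ids,
                        sites_per_region = 2L, strength = 0.25, seed = 1L) {
  L <- pwm_length(pwm)
  idx <- match(target_region_ids, crrs$region_id)
  if (anyNA(idx)) stop("unknown target region id")
  truth <- list()
  if (sites_per_region >= 1) with_seed(seed, {
    for (i in idx) {
      w <- crrs$end[i] - crrs$start[i]
      if (w < L * sites_per_region)
        stop("region ", crrs$region_id[i], " too short for ",
             sites_per_region, " site(s)")
      # one site per equal slot, jittered, so sites never overlap
      slot <- w %/% sites_per_region
      for (s in seq_len(sites_per_region)) {
        off <- (s - 1L) * slot + sample.int(slot - L + 1L, 1) - 1L
        pos <- crrs$start[i] + off
        site <- sample_site(pwm, strength)
        strand <- sample(c("+", "-"), 1)
        ins <- if (strand == "+") site else
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(site)))
        chr <- crrs$chrom[i]
        substr(genome[[chr]], pos + 1L, pos + L) <- ins
        truth[[length(truth) + 1L]] <-
          data.frame(region_id = crrs$region_id[i], pos = pos,
                     strand = strand, site = site, stringsAsFactors = FALSE)
      }
    }
  })
  list(genome = genome,
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(region_id = character(), pos = integer(),
                    strand = character(), site = character(),
                    stringsAsFactors = FALSE))
}

#' Generate a scored peak track over the CRRs
#'
#' One peak per CRR (the CRR interval itself) with a Gaussian-noised
#' score: mean `signal_high` on the enriched regions, `signal_low`
#' elsewhere; scores are clamped at 0 so downstream signalValue handling
#' never sees negative values.
#'
#' @param crrs CRR `region_set`.
#' @param enriched_region_ids ids drawing from the high-signal
#'   distribution (may be empty).
#' @param signal_high,signal_low means with `signal_high > signal_low >= 0`.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return A `region_set` with a `score` column (ids `peak_<crr id>`).
#' @export
make_track <- function(crrs, enriched_region_ids, signal_high = 10,
                       signal_low = 1, noise_sd = 1, seed = 1L) {
  stopifnot(signal_high > signal_low, signal_low >= 0)
  mu <- ifelse(crrs$region_id %in% enriched_region_ids, signal_high,
               signal_low)
  sc <- with_seed(seed, pmax(0, stats::rnorm(nrow(crrs), mu, noise_sd)))
  region_set(crrs$chrom, crrs$start, crrs$end,
             region_id = paste0("peak_", crrs$region_id), score = sc,
             genome_tag = genome_tag(crrs))
}

#' Random informative PWM
#' @noRd
random_pwm <- function(motif_id, len = 8L, dominant = 0.85) {
  m <- matrix((1 - dominant) / 3, nrow = len, ncol = 4)
  for (j in seq_len(len)) m[j, sample.int(4, 1)] <- dominant
  pwm(m, motif_id)
}

#' Build a complete synthetic test case
#'
#' The bundle contains a genome, regulatory feature tracks, insulator and
#' exon tracks, the CRR database built from them by the real builder, a
#' motif collection with one motif planted into most of a known foreground
#' subset, twenty scored peak tracks (one enriched on that subset), a gene
#' annotation whose TSSs sit at the foreground CRR midpoints, region-mode
#' and gene-mode foreground inputs, and a truth record sufficient to score
#' any leading edge for precision/recall.
#'
#' Scales: `tiny` = 2 chromosomes x 50 kb, ~190 CRRs (target size 400 bp),
#' 20 motifs, 20 tracks, 30 foreground regions with the motif planted in 24
#' (80%) of them; `small` = 2 x 250 kb with ~950 CRRs and a 100-region
#' foreground.
#'
#' @param seed integer seed; every file the bundle writes is byte-identical
#'   per seed.
#' @param scale `"tiny"` or `"small"`.
#' @return A `fixture_bundle` list; see fields in the implementation and
#'   `truth` for ground truth (planted motif/track/regions, foreground).
#' @export
make_case <- function(seed, scale = c("tiny", "small")) {
  scale <- match.arg(scale)
  chr_len <- if (scale == "tiny") 50000L else 250000L
  n_fg <- if (scale == "tiny") 30L else 100L
  chrom_sizes <- c(chr1 = chr_len, chr2 = chr_len)
  slot <- 500L
  config <- crr_config(min_size = 30L, target_size = 400L)
  genome <- make_genome(seed, chrom_sizes, gc = 0.5)

  layout <- with_seed(seed + 1L, {
    feats <- list(f1 = list(), f2 = list(), f3 = list())
    ins <- list(); ex <- list()
    for (ch in names(chrom_sizes)) {
      nslot <- chrom_sizes[[ch]] %/% slot
      for (k in seq_len(nslot - 1L)) {
        if (stats::runif(1) > 0.92) next
        w <- sample(150:300, 1)
        c0 <- k * slot + sample(-80:80, 1)
        set <- sample(3, 1)
        feats[[set]][[length(feats[[set]]) + 1L]] <-
          c(ch, max(0L, c0 - w %/% 2L), c0 + w %/% 2L)
      }
      for (k in sample(seq_len(nslot - 1L), max(3L, nslot %/% 12L))) {
        w <- sample(150:250, 1)
        c0 <- k * slot + sample(-150:150, 1)
        ins[[length(ins) + 1L]] <- c(ch, max(0L, c0 - w %/% 2L), c0 + w %/% 2L)
      }
      for (k in sample(seq_len(nslot - 1L), max(3L, nslot %/% 10L))) {
        w <- sample(100:200, 1)
        c0 <- k * slot + sample(-150:150, 1)
        ex[[length(ex) + 1L]] <- c(ch, max(0L, c0 - w %/% 2L), c0 + w %/% 2L)
      }
    }
    list(feats = feats, ins = ins, ex = ex)
  })
  to_rs <- function(rows, prefix) {
    if (!length(rows)) return(region_set(character(), integer(), integer(),
                                         genome_tag = "toy"))
    m <- do.call(rbind, rows)
    region_set(m[, 1], as.integer(m[, 2]), as.integer(m[, 3]),
               region_id = sprintf("%s_%04d", prefix, seq_len(nrow(m))),
               genome_tag = "toy")
  }
  feature_sets <- list(to_rs(layout$feats$f1, "f1"),
                       to_rs(layout$feats$f2, "f2"),
                       to_rs(layout$feats$f3, "f3"))
  insulators <- to_rs(layout$ins, "ins")
  exons <- to_rs(layout$ex, "ex")
  crrs <- build_crr_database(feature_sets, insulators, exons, config,
                             chrom_sizes)

  # foreground: evenly spread CRRs, big enough to hold 2 planted sites
  eligible <- which(region_widths(crrs) >= 80)
  fg_idx <- eligible[round(seq(1, length(eligible), length.out = n_fg))]
  fg_ids <- crrs$region_id[fg_idx]
  n_plant <- ceiling(0.8 * n_fg)
  planted_ids <- with_seed(seed + 2L, sort(sample(fg_ids, n_plant)))

  pwms <- with_seed(seed + 3L, {
    ps <- lapply(seq_len(20L), function(i)
      random_pwm(sprintf("motif_%02d", i), len = 8L))
    stats::setNames(ps, vapply(ps, `[[`, "", "motif_id"))
  })
  planted_motif <- "motif_01"
  pl <- plant_motif(genome, crrs, pwms[[planted_motif]], planted_ids,
                    sites_per_region = 2L, strength = 0.25,
                    seed = seed + 4L)
  genome <- pl$genome

  # 20 tracks: the z-score of one outlier among n values is bounded by
  # sqrt(n - 1), so a track database must hold well over 10 features for
  # an NES > 3 call to be reachable at all
  n_tracks <- 20L
  enriched_track <- "track_01"
  tracks <- stats::setNames(lapply(seq_len(n_tracks), function(i)
    make_track(crrs, if (i == 1) fg_ids else character(),
               signal_high = 10, signal_low = 1, noise_sd = 1,
               seed = seed + 10L + i)),
    sprintf("track_%02d", seq_len(n_tracks)))

  # genes: TSS at each foreground CRR midpoint (so gene windows of
  # +/-300 bp stay inside their CRR), plus decoy genes elsewhere
  bg_idx <- setdiff(seq_len(nrow(crrs)), fg_idx)
  bg_pick <- bg_idx[round(seq(1, length(bg_idx), length.out = 10L))]
  gi <- c(fg_idx, bg_pick)
  mids <- (crrs$start[gi] + crrs$end[gi]) %/% 2L
  ann <- data.frame(gene = sprintf("g%03d", seq_along(gi)),
                    chrom = crrs$chrom[gi],
                    strand = rep(c("+", "-"), length.out = length(gi)),
                    tss = mids, stringsAsFactors = FALSE)
  ann$introns <- lapply(seq_along(gi), function(k)
    cbind(start = mids[k] + 40L, end = mids[k] + 120L))
  class(ann) <- c("gene_annotation", "data.frame")
  fg_genes <- ann$gene[seq_along(fg_idx)]

  # region-mode input: peaks covering the central 80% of each fg CRR
  pk_s <- crrs$start[fg_idx] + ceiling(region_widths(crrs)[fg_idx] * 0.1)
  pk_e <- crrs$end[fg_idx] - floor(region_widths(crrs)[fg_idx] * 0.1)
  input_peaks <- region_set(crrs$chrom[fg_idx], pk_s, pk_e,
                            region_id = sprintf("inpk_%03d",
                                                seq_along(fg_idx)),
                            genome_tag = "toy")

  structure(list(
    seed = as.integer(seed), scale = scale, chrom_sizes = chrom_sizes,
    genome = genome, feature_sets = feature_sets, insulators = insulators,
    exons = exons, config = config, crrs = crrs, pwms = pwms,
    tracks = tracks, annotation = ann, input_peaks = input_peaks,
    fg_genes = fg_genes,
    gene_window = gene_window_spec("around_tss", 300L, 300L),
    params = list(auc_fraction = 0.1, nes_threshold = 3.0,
                  min_fraction = 0.4),
    truth = list(planted_motif = planted_motif,
                 enriched_track = enriched_track,
                 planted_region_ids = planted_ids,
                 plant_sites = pl$truth,
                 foreground_ids = fg_ids)
  ), class = "fixture_bundle")
}

#' Run the full pipeline on a fixture bundle
#'
#' Offline half: score every motif on the bundle genome (single genome;
#' the order-statistic aggregation degenerates to the identity) and every
#' track by peak signal, then build one motif and one track ranking
#' database. Online half: map the region-mode input to the CRRs and run
#' the recovery analysis with the bundle's parameters.
#'
#' @param bundle a [make_case()] bundle.
#' @param mode `"regions"` (map the input peaks) or `"genes"` (map the
#'   foreground gene list).
#' @return List with `report` (an `enrichment_report`), `databases`,
#'   `foreground` and the `bundle` parameters used.
#' @export
analyze_case <- function(bundle, mode = c("regions", "genes")) {
  mode <- match.arg(mode)
  genomes <- list(base = list(sequences = bundle$genome, regions = NULL))
  motif_scores <- lapply(bundle$pwms, function(p) {
    sm <- score_motif_over_regions(bundle$crrs, genomes, p)
    aggregate_genome_scores(sm, p$motif_id, bundle$seed)
  })
  track_scores <- lapply(bundle$tracks, function(t)
    score_track_peaks(bundle$crrs, t))
  db_motifs <- build_ranking_database(bundle$crrs, motif_scores,
                                      seed = bundle$seed,
                                      db_label = "motifs",
                                      feature_type = "motif")
  db_tracks <- build_ranking_database(bundle$crrs, track_scores,
                                      seed = bundle$seed,
                                      db_label = "open_chromatin",
                                      feature_type = "track")
  fg <- if (mode == "regions") {
    map_regions_to_crrs(bundle$input_peaks, bundle$crrs,
                        min_fraction = bundle$params$min_fraction)
  } else {
    map_genes_to_crrs(bundle$fg_genes, bundle$annotation,
                      bundle$gene_window, bundle$crrs)
  }
  # leading-edge window: twice the AUC cutoff, so the target search is not
  # clipped below the size of a realistic foreground on a toy universe
  t_le <- 2L * threshold_rank(nrow(bundle$crrs),
                              bundle$params$auc_fraction)
  report <- run_enrichment(list(db_motifs, db_tracks), fg,
                           auc_fraction = bundle$params$auc_fraction,
                           nes_threshold = bundle$params$nes_threshold,
                           t_le = t_le)
  list(report = report, databases = list(motifs = db_motifs,
                                         tracks = db_tracks),
       foreground = fg, params = bundle$params)
}

#' Write a fixture bundle to disk
#'
#' Emits genome FASTA, feature/insulator/exon BEDs, the CRR BED, the PWM
#' collection (Cluster-Buster text format), scored track BEDs (score in
#' column 5), the TSS-table gene annotation, the region-mode input BED,
#' the gene list, and `truth.json`. Regenerating a bundle from the same
#' seed and writing it again reproduces every file byte-identically.
#'
#' @param bundle a [make_case()] bundle.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_case <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  con <- file(fa, "wb")
  for (ch in names(bundle$genome)) {
    writeLines(paste0(">", ch), con)
    s <- bundle$genome[[ch]]
    writeLines(substring(s, seq(1, nchar(s), 70),
                         pmin(seq(70, nchar(s) + 69, 70), nchar(s))), con)
  }
  close(con)
  for (i in seq_along(bundle$feature_sets))
    write_bed(bundle$feature_sets[[i]],
              file.path(dir, sprintf("features_%d.bed", i)))
  write_bed(bundle$insulators, file.path(dir, "insulators.bed"))
  write_bed(bundle$exons, file.path(dir, "exons.bed"))
  write_bed(bundle$crrs, file.path(dir, "crrs.bed"))
  write_pwms(bundle$pwms, file.path(dir, "motifs.cb"))
  for (tn in names(bundle$tracks)) {
    t <- bundle$tracks[[tn]]
    con <- file(file.path(dir, paste0(tn, ".bed")), "wb")
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s", t$chrom, t$start, t$end,
                       t$region_id,
                       sprintf("%.6f", t$score)), con)
    close(con)
  }
  write_tss_table(bundle$annotation, file.path(dir, "genes.tsv"))
  write_bed(bundle$input_peaks, file.path(dir, "input_peaks.bed"))
  con <- file(file.path(dir, "input_genes.txt"), "wb")
  writeLines(bundle$fg_genes, con)
  close(con)
  jsonlite::write_json(
    list(seed = bundle$seed, scale = bundle$scale,
         planted_motif = bundle$truth$planted_motif,
         enriched_track = bundle$truth$enriched_track,
         planted_region_ids = bundle$truth$planted_region_ids,
         foreground_ids = bundle$truth$foreground_ids,
         plant_sites = bundle$truth$plant_sites),
    file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(dir)
}
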