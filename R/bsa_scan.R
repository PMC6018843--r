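# Sliding-window pooled-allele-frequency scan and dual-bulk region calling.
#
# Coordinate conventions: marker and variant positions are 1-based on
# input; window and region intervals are 0-based half-open internally and
# in all BED/bedGraph output. Conversion happens only at the I/O boundary.

#' Variant filter configuration
#'
#' Thresholds applied to pooled variant counts before scanning: minimum
#' read coverage 10, minimum variant (donor) read count 3 and minimum
#' variant frequency 35%.
#'
#' @param min_coverage Minimum total read coverage (default 10).
#' @param min_variant_reads Minimum donor-allele read count (default 3).
#' @param min_variant_frequency Minimum donor-allele read fraction
#'   (default 0.35).
#' @return List of class `variant_filter_config`.
#' @export
variant_filter_config <- function(min_coverage = 10, min_variant_reads = 3,
                                  min_variant_frequency = 0.35) {
  if (min_coverage < 0 || min_variant_reads < 0)
    stop("count thresholds must be >= 0", call. = FALSE)
  if (min_variant_frequency < 0 || min_variant_frequency > 1)
    stop("min_variant_frequency must be in [0, 1]", call. = FALSE)
  structure(list(min_coverage = min_coverage,
                 min_variant_reads = min_variant_reads,
                 min_variant_frequency = min_variant_frequency),
            class = "variant_filter_config")
}

#' Window configuration for the sliding scan
#'
#' Defaults reproduce a 1-Mbp window advanced by 500 kb (each pair of
#' adjacent windows overlapping by half a window).
#'
#' @param window_length Window length in bp (default 1e6).
#' @param step Window step in bp, `0 < step <= window_length`
#'   (default 5e5).
#' @param min_snps_per_window Minimum markers for a window mean to be
#'   defined (default 1).
#' @return List of class `window_config`.
#' @export
window_config <- function(window_length = 1e6, step = 5e5,
                          min_snps_per_window = 1) {
  if (step <= 0 || step > window_length)
    stop("need 0 < step <= window_length", call. = FALSE)
  if (min_snps_per_window < 1)
    stop("min_snps_per_window must be >= 1", call. = FALSE)
  structure(list(window_length = window_length, step = step,
                 min_snps_per_window = min_snps_per_window),
            class = "window_config")
}

#' Filter pooled variant counts
#'
#' Retains a variant iff `total_reads >= min_coverage` AND
#' `donor_reads >= min_variant_reads` AND
#' `donor_reads / total_reads >= min_variant_frequency`. When the table
#' carries an `is_indel` column and `snps_only = TRUE` (the default),
#' indels are dropped before the threshold filters.
#'
#' @param counts `data.frame` with columns `chrom`, `pos`, `donor_reads`,
#'   `total_reads` (optionally `marker`, `bulk`, `is_indel`).
#' @param cfg A [variant_filter_config()].
#' @param snps_only Drop records flagged as indels (default `TRUE`).
#' @return The retained rows, with a `filter_report` attribute: named
#'   integer vector of input/removed-per-criterion/retained counts
#'   (records failing several criteria are attributed to the first failed
#'   one, in the order indel, coverage, variant reads, frequency).
#' @export
filter_pooled_variants <- function(counts, cfg = variant_filter_config(),
                                   snps_only = TRUE) {
  stopifnot(is.data.frame(counts),
            all(c("chrom", "pos", "donor_reads", "total_reads") %in%
                  names(counts)))
  if (any(counts$donor_reads < 0) ||
      any(counts$donor_reads > counts$total_reads))
    stop("need 0 <= donor_reads <= total_reads", call. = FALSE)
  n_in <- nrow(counts)
  indel <- if (snps_only && "is_indel" %in% names(counts))
    counts$is_indel %in% TRUE else rep(FALSE, n_in)
  low_cov <- counts$total_reads < cfg$min_coverage
  low_reads <- counts$donor_reads < cfg$min_variant_reads
  freq <- ifelse(counts$total_reads > 0,
                 counts$donor_reads / counts$total_reads, 0)
  low_freq <- freq < cfg$min_variant_frequency
  drop_reason <- ifelse(indel, "indel",
                 ifelse(low_cov, "coverage",
                 ifelse(low_reads, "variant_reads",
                 ifelse(low_freq, "frequency", "retained"))))
  out <- counts[drop_reason == "retained", , drop = FALSE]
  rownames(out) <- NULL
  report <- c(input = n_in,
              removed_indel = sum(drop_reason == "indel"),
              removed_coverage = sum(drop_reason == "coverage"),
              removed_variant_reads = sum(drop_reason == "variant_reads"),
              removed_frequency = sum(drop_reason == "frequency"),
              retained = nrow(out))
  attr(out, "filter_report") <- report
  out
}

#' Donor-allele frequency of a pool from genotype codes
#'
#' Mean of the non-missing codes (donor = 1, het = 0.5, recurrent = 0) of
#' the pooled individuals at one marker; missing codes are excluded, never
#' imputed.
#'
#' @param codes Numeric vector of genotype codes for one marker across the
#'   pooled individuals.
#' @return The pool frequency in `[0, 1]`, or `NA` (with a warning) when
#'   every code is missing.
#' @export
pool_frequency_from_genotypes <- function(codes) {
  if (any(!is.na(codes) & !codes %in% c(0, 0.5, 1)))
    stop("genotype codes must be 0, 0.5, 1 or NA", call. = FALSE)
  if (all(is.na(codes))) {
    warning("all genotype codes missing; frequency undefined", call. = FALSE)
    return(NA_real_)
  }
  mean(codes, na.rm = TRUE)
}

#' Donor-allele frequency of a pool from read counts
#'
#' @param donor_reads,total_reads Count vectors, recycled as usual.
#' @return `donor_reads / total_reads`; `NA` (with one warning) where
#'   `total_reads == 0`.
#' @export
pool_frequency_from_reads <- function(donor_reads, total_reads) {
  if (any(donor_reads < 0) || any(total_reads < 0) ||
      any(donor_reads > total_reads))
    stop("need 0 <= donor_reads <= total_reads", call. = FALSE)
  zero <- total_reads == 0
  if (any(zero))
    warning(sprintf("%d marker(s) with zero coverage; frequency undefined",
                    sum(zero)), call. = FALSE)
  ifelse(zero, NA_real_, donor_reads / total_reads)
}

#' Per-marker pool frequencies of a set of pooled individuals
#'
#' Array-genotyping analogue of a sequenced bulk: the pool frequency at
#' every marker is the mean genotype code over the pooled individuals
#' (see [pool_frequency_from_genotypes()]).
#'
#' @param gm A [genotype_matrix()].
#' @param individuals Ids of the pooled individuals (default: all).
#' @return `data.frame` with `marker`, `chrom`, `pos`, `freq`, `n_used`.
#' @export
array_pool_frequencies <- function(gm, individuals = gm$individuals) {
  stopifnot(inherits(gm, "genotype_matrix"))
  missing_ids <- setdiff(individuals, gm$individuals)
  if (length(missing_ids) > 0)
    stop(sprintf("unknown individual id(s): %s",
                 paste(utils::head(missing_ids, 3), collapse = ", ")),
         call. = FALSE)
  sub <- gm$codes[individuals, , drop = FALSE]
  n_used <- colSums(!is.na(sub))
  freq <- ifelse(n_used > 0, colMeans(sub, na.rm = TRUE), NA_real_)
  if (any(n_used == 0))
    warning(sprintf("%d marker(s) with no non-missing codes excluded from scans",
                    sum(n_used == 0)), call. = FALSE)
  data.frame(marker = gm$markers$marker, chrom = gm$markers$chrom,
             pos = gm$markers$pos, freq = as.numeric(freq),
             n_used = as.integer(n_used), row.names = NULL,
             stringsAsFactors = FALSE)
}

# Window membership by arithmetic on the grid: marker at 0-based offset x
# lies in windows k with k*step <= x < k*step + L.
.window_index_range <- function(x, step, window_length, n_windows) {
  k_max <- pmin(floor(x / step), n_windows - 1)
  k_min <- pmax(floor((x - window_length) / step) + 1, 0)
  list(k_min = k_min, k_max = k_max)
}

#' Sliding-window mean donor-allele frequency for one chromosome
#'
#' Windows are anchored at offset 0 and advanced by `step`; the trailing
#' partial window is emitted. A marker at 1-based position `p` belongs to
#' every window whose 0-based half-open interval `[start, start +
#' window_length)` contains `p - 1`; each window's value is the unweighted
#' mean of its member marker frequencies. Windows with fewer than
#' `min_snps_per_window` markers (or only `NA` frequencies) carry an
#' undefined (`NA`) mean.
#'
#' @param pos 1-based marker positions within `[1, chrom_length]`.
#' @param freq Per-marker donor-allele frequencies in `[0, 1]` (`NA`
#'   markers are ignored).
#' @param chrom_length Chromosome length in bp.
#' @param cfg A [window_config()].
#' @param chrom Chromosome label stored in the output.
#' @return `data.frame` of class `window_track` with columns `chrom`,
#'   `start`, `end` (0-based half-open), `freq`, `n_snps`; window geometry
#'   kept in attributes `window_length` and `step`.
#' @export
sliding_window_frequency <- function(pos, freq, chrom_length,
                                     cfg = window_config(), chrom = "chr") {
  stopifnot(inherits(cfg, "window_config"), length(pos) == length(freq))
  if (any(pos < 1))
    stop("marker positions must be >= 1", call. = FALSE)
  if (any(pos > chrom_length))
    stop(sprintf("marker at position %d beyond chromosome end (%d bp)",
                 max(pos), as.integer(chrom_length)), call. = FALSE)
  keep <- !is.na(freq)
  pos <- pos[keep]; freq <- freq[keep]
  if (any(freq < 0 | freq > 1))
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  starts <- seq(0, max(chrom_length - 1, 0), by = cfg$step)
  nw <- length(starts)
  n_snps <- integer(nw)
  sums <- numeric(nw)
  if (length(pos) > 0) {
    x <- pos - 1  # to 0-based offsets
    rng <- .window_index_range(x, cfg$step, cfg$window_length, nw)
    for (i in seq_along(x)) {
      ks <- seq.int(rng$k_min[i], rng$k_max[i]) + 1L
      n_snps[ks] <- n_snps[ks] + 1L
      sums[ks] <- sums[ks] + freq[i]
    }
  }
  mean_freq <- ifelse(n_snps >= cfg$min_snps_per_window & n_snps > 0,
                      sums / n_snps, NA_real_)
  track <- data.frame(chrom = chrom, start = starts,
                      end = pmin(starts + cfg$window_length, chrom_length),
                      freq = mean_freq, n_snps = as.integer(n_snps),
                      stringsAsFactors = FALSE)
  attr(track, "window_length") <- cfg$window_length
  attr(track, "step") <- cfg$step
  class(track) <- c("window_track", "data.frame")
  track
}

#' Genome-wide window scan over per-marker frequencies
#'
#' Applies [sliding_window_frequency()] to every chromosome of a genome
#' and binds the tracks. Marker input order is irrelevant.
#'
#' @param freqs `data.frame` with columns `chrom`, `pos`, `freq` (e.g.
#'   from [array_pool_frequencies()] or read-count frequencies).
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp;
#'   every chromosome named here gets a track, even without markers.
#' @param cfg A [window_config()].
#' @return A `window_track` spanning all chromosomes, ordered by
#'   chromosome name then window start.
#' @export
window_scan <- function(freqs, chrom_lengths, cfg = window_config()) {
  stopifnot(is.data.frame(freqs),
            all(c("chrom", "pos", "freq") %in% names(freqs)))
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == ""))
    stop("chrom_lengths must be a named vector", call. = FALSE)
  stray <- setdiff(unique(freqs$chrom), names(chrom_lengths))
  if (length(stray) > 0)
    stop(sprintf("markers on unknown chromosome(s): %s",
                 paste(stray, collapse = ", ")), call. = FALSE)
  tracks <- lapply(sort(names(chrom_lengths)), function(cn) {
    sel <- freqs$chrom == cn
    sliding_window_frequency(freqs$pos[sel], freqs$freq[sel],
                             chrom_lengths[[cn]], cfg, chrom = cn)
  })
  out <- do.call(rbind, tracks)
  attr(out, "window_length") <- cfg$window_length
  attr(out, "step") <- cfg$step
  class(out) <- c("window_track", "data.frame")
  rownames(out) <- NULL
  out
}

.check_same_grid <- function(a, b) {
  if (nrow(a) != nrow(b) || !all(a$chrom == b$chrom) ||
      !all(a$start == b$start) || !all(a$end == b$end))
    stop("window tracks are on different grids", call. = FALSE)
}

# Merge runs of >= min_consecutive consecutive qualifying windows into
# regions; undefined windows never qualify and break runs. Regions span
# the first window's start to the last window's end (overlapping windows
# fuse). freq_list: named list of per-window frequency vectors whose
# per-region means are reported.
.merge_qualifying_windows <- function(grid, qualifies, freq_list,
                                      min_consecutive, evidence) {
  out <- list()
  for (cn in unique(grid$chrom)) {
    sel <- which(grid$chrom == cn)
    q <- qualifies[sel]
    r <- rle(q)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1
    for (j in seq_along(r$values)) {
      if (!isTRUE(r$values[j]) || r$lengths[j] < min_consecutive) next
      idx <- sel[starts_i[j]:ends_i[j]]
      row <- data.frame(chrom = cn,
                        start = grid$start[idx[1]],
                        end = grid$end[idx[length(idx)]],
                        n_windows = length(idx),
                        evidence = evidence,
                        stringsAsFactors = FALSE)
      for (nm in names(freq_list))
        row[[paste0("mean_freq_", nm)]] <- mean(freq_list[[nm]][idx])
      out[[length(out) + 1]] <- row
    }
  }
  if (length(out) == 0) {
    res <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_windows = integer(),
                      evidence = character(), stringsAsFactors = FALSE)
    for (nm in names(freq_list)) res[[paste0("mean_freq_", nm)]] <- numeric()
  } else {
    res <- do.call(rbind, out)
    res <- res[order(res$chrom, res$start), , drop = FALSE]
    rownames(res) <- NULL
  }
  class(res) <- c("candidate_regions", "data.frame")
  res
}

#' Call candidate regions from a recessive and a segregating bulk
#'
#' A window qualifies when the recessive (mutant-fixed) bulk has a donor
#' allele frequency at or above `high_threshold` ("1 or close to 1") while
#' the segregating bulk sits inside `segregating_band` (around the 0.5
#' expected of selfed progeny of a heterozygous parent). Runs of at least
#' `min_consecutive` consecutive qualifying windows merge into one region.
#' Requiring the segregating pool near 0.5 guards against regions where
#' donor alleles merely drifted to fixation during line development.
#'
#' @param recessive_track,segregating_track `window_track`s on the same
#'   grid (same chromosomes, starts and ends).
#' @param high_threshold Minimum recessive-bulk frequency (default 0.9).
#' @param segregating_band Length-2 inclusive band for the segregating
#'   bulk (default `c(0.35, 0.65)`).
#' @param min_consecutive Minimum run of qualifying windows (default 2).
#' @return `candidate_regions` data.frame: `chrom`, `start`, `end`
#'   (0-based half-open, window-aligned), `n_windows`, `evidence`
#'   (`"MBS"`), `mean_freq_recessive`, `mean_freq_segregating`.
#' @export
call_candidate_regions <- function(recessive_track, segregating_track,
                                   high_threshold = 0.9,
                                   segregating_band = c(0.35, 0.65),
                                   min_consecutive = 2) {
  .check_same_grid(recessive_track, segregating_track)
  stopifnot(length(segregating_band) == 2,
            segregating_band[1] <= segregating_band[2])
  q <- !is.na(recessive_track$freq) & !is.na(segregating_track$freq) &
    recessive_track$freq >= high_threshold &
    segregating_track$freq >= segregating_band[1] &
    segregating_track$freq <= segregating_band[2]
  .merge_qualifying_windows(recessive_track, q,
                            list(recessive = recessive_track$freq,
                                 segregating = segregating_track$freq),
                            min_consecutive, evidence = "MBS")
}

#' Call candidate regions from array-genotyped reduced- and normal-fuzz pools
#'
#' A window qualifies when the reduced-fuzz pool frequency is at or above
#' `high_threshold` (fuzzless lines homozygous donor, near-fuzzless ones
#' possibly heterozygous) and the normal-fuzz pool frequency is strictly
#' below `normal_max` (those lines heterozygous or without donor alleles).
#'
#' @param reduced_fuzz_track,normal_fuzz_track `window_track`s on the same
#'   grid.
#' @param high_threshold Minimum reduced-fuzz pool frequency (default 0.9).
#' @param normal_max Exclusive upper bound for the normal-fuzz pool
#'   (default 0.5).
#' @param min_consecutive Minimum run of qualifying windows (default 2).
#' @return `candidate_regions` data.frame with `evidence = "array"` and
#'   per-region `mean_freq_reduced` / `mean_freq_normal`.
#' @export
call_array_candidates <- function(reduced_fuzz_track, normal_fuzz_track,
                                  high_threshold = 0.9, normal_max = 0.5,
                                  min_consecutive = 2) {
  .check_same_grid(reduced_fuzz_track, normal_fuzz_track)
  q <- !is.na(reduced_fuzz_track$freq) & !is.na(normal_fuzz_track$freq) &
    reduced_fuzz_track$freq >= high_threshold &
    normal_fuzz_track$freq < normal_max
  .merge_qualifying_windows(reduced_fuzz_track, q,
                            list(reduced = reduced_fuzz_track$freq,
                                 normal = normal_fuzz_track$freq),
                            min_consecutive, evidence = "array")
}

.regions_to_granges <- function(r) {
  GenomicRanges::GRanges(r$chrom,
                         IRanges::IRanges(start = r$start + 1, end = r$end))
}

#' Intersect two candidate-region sets
#'
#' Overlapping region pairs yield their interval intersection with
#' `evidence = "both"`; regions without a counterpart in the other set are
#' retained with their single-source evidence label. A locus found by both
#' the sequencing-bulk and the array route is the strongest candidate.
#'
#' @param a,b `candidate_regions` data.frames (same coordinate system,
#'   0-based half-open).
#' @return `candidate_regions` data.frame with columns `chrom`, `start`,
#'   `end`, `evidence`, sorted by `(chrom, start)`.
#' @export
intersect_region_sets <- function(a, b) {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), evidence = character(),
                      stringsAsFactors = FALSE)
  pieces <- list(empty)
  if (nrow(a) > 0 && nrow(b) > 0) {
    ga <- .regions_to_granges(a)
    gb <- .regions_to_granges(b)
    # the two sets may legitimately cover different chromosomes
    hits <- suppressWarnings(GenomicRanges::findOverlaps(ga, gb))
    if (length(hits) > 0) {
      inter <- GenomicRanges::pintersect(
        ga[S4Vectors::queryHits(hits)], gb[S4Vectors::subjectHits(hits)])
      pieces[[length(pieces) + 1]] <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(inter)),
        start = GenomicRanges::start(inter) - 1,
        end = GenomicRanges::end(inter),
        evidence = "both", stringsAsFactors = FALSE)
    }
    solo_a <- setdiff(seq_len(nrow(a)), S4Vectors::queryHits(hits))
    solo_b <- setdiff(seq_len(nrow(b)), S4Vectors::subjectHits(hits))
  } else {
    solo_a <- seq_len(nrow(a))
    solo_b <- seq_len(nrow(b))
  }
  if (length(solo_a) > 0)
    pieces[[length(pieces) + 1]] <- data.frame(
      chrom = a$chrom[solo_a], start = a$start[solo_a], end = a$end[solo_a],
      evidence = a$evidence[solo_a], stringsAsFactors = FALSE)
  if (length(solo_b) > 0)
    pieces[[length(pieces) + 1]] <- data.frame(
      chrom = b$chrom[solo_b], start = b$start[solo_b], end = b$end[solo_b],
      evidence = b$evidence[solo_b], stringsAsFactors = FALSE)
  out <- do.call(rbind, pieces)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_regions", "data.frame")
  out
}
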