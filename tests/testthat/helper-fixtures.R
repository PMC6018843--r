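# Small reusable fixtures, all built in code.

# Two-chromosome toy genome: 5 Mb each, marker every 500 kb.
tiny_genome <- function(n_chrom = 2, chrom_length = 5e6,
                        marker_spacing = 5e5, cm_per_mb = 1) {
  sim_genome(n_chrom, chrom_length, marker_spacing, cm_per_mb)
}

# One fully penetrant required-recessive locus on the first chromosome.
single_locus_model <- function(genome = tiny_genome(), ...) {
  causal_model(data.frame(locus = "L1",
                          chrom = genome$markers$chrom[1],
                          pos = genome$chrom_lengths[[1]] / 2,
                          role = "required_recessive", effect = 0,
                          stringsAsFactors = FALSE), ...)
}

# Hand-built window grid (one chromosome) for region-calling tests:
# start offsets 0, 5e5, ... with 1 Mb windows.
toy_track <- function(freqs, chrom = "D12", step = 5e5, win = 1e6) {
  n <- length(freqs)
  starts <- (seq_len(n) - 1) * step
  tr <- data.frame(chrom = chrom, start = starts, end = starts + win,
                   freq = freqs,
                   n_snps = ifelse(is.na(freqs), 0L, 5L),
                   stringsAsFactors = FALSE)
  attr(tr, "window_length") <- win
  attr(tr, "step") <- step
  class(tr) <- c("window_track", "data.frame")
  tr
}

# Brute-force window oracle: literal per-window membership scan.
brute_force_windows <- function(pos, freq, chrom_length, window_length,
                                step, min_snps = 1) {
  starts <- seq(0, max(chrom_length - 1, 0), by = step)
  keep <- !is.na(freq)
  pos <- pos[keep]; freq <- freq[keep]
  res <- lapply(starts, function(s) {
    inside <- (pos - 1) >= s & (pos - 1) < s + window_length
    n <- sum(inside)
    list(n = n, mean = if (n >= min_snps && n > 0) mean(freq[inside])
                       else NA_real_)
  })
  data.frame(start = starts,
             n_snps = vapply(res, function(r) r$n, numeric(1)),
             freq = vapply(res, function(r) r$mean, numeric(1)))
}

# Genotype groups object without going through a genotype matrix.
make_groups <- function(donor, het, recurrent, marker_id = "m1") {
  structure(list(donor = donor, het = het, recurrent = recurrent,
                 marker_id = marker_id, n_excluded = 0L),
            class = "genotype_groups")
}
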