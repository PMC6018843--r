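# End-to-end orchestration: simulate -> pool -> filter -> frequency ->
# windows -> regions -> intersect, plus the segregation and association
# summaries, writing every intermediate artifact to a run directory.

#' Default run configuration
#'
#' Flat key set collecting every stage's tunables at its documented
#' default. Values here drive [run_pipeline()] and are validated by
#' [validate_config()] before any stage runs.
#'
#' @param ... Overrides as `key = value` pairs.
#' @return Named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    # genome / simulator
    n_chrom = 26, chrom_length = 60e6, marker_spacing = 250e3, cm_per_mb = 1,
    f2_n = 169, n_backcrosses = 4, n_selfs = 5,
    n_fuzzless_lines = 6, n_segregating_lines = 4, progeny_per_line = 10,
    recessive_bulk_size = 15, segregating_bulk_size = 24,
    depth = 30, error_rate = 0,
    baseline_fuzz = 11, noise_sd = 1.5, penetrance = 1,
    # phenotype classes
    cutoff_fuzzless = 1.5, cutoff_intermediate = 6,
    # variant filter
    min_coverage = 10, min_variant_reads = 3, min_variant_frequency = 0.35,
    # windows
    window_length = 1e6, step = 5e5, min_snps_per_window = 1,
    # region calling
    high_threshold = 0.9, segregating_band_low = 0.35,
    segregating_band_high = 0.65, normal_max = 0.5, min_consecutive = 2,
    # segregation / association
    k_range_max = 4, alpha = 0.05, min_group_size = 3,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0)
    stop(sprintf("unknown configuration key(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  cfg[names(over)] <- over
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Validate a run configuration
#'
#' Checks every key against its stage's constraints; called by
#' [run_pipeline()] before any stage executes.
#'
#' @param cfg A [default_config()] list.
#' @return `cfg`, invisibly, or an error naming the offending key.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, key, why) if (!ok)
    stop(sprintf("invalid configuration '%s': %s", key, why), call. = FALSE)
  chk(cfg$step > 0 && cfg$step <= cfg$window_length, "step",
      "need 0 < step <= window_length")
  chk(cfg$min_snps_per_window >= 1, "min_snps_per_window", "must be >= 1")
  chk(cfg$min_coverage >= 0 && cfg$min_variant_reads >= 0,
      "min_coverage/min_variant_reads", "must be >= 0")
  chk(cfg$min_variant_frequency >= 0 && cfg$min_variant_frequency <= 1,
      "min_variant_frequency", "must be in [0, 1]")
  chk(cfg$high_threshold > 0 && cfg$high_threshold <= 1, "high_threshold",
      "must be in (0, 1]")
  chk(cfg$segregating_band_low <= cfg$segregating_band_high,
      "segregating_band", "low bound exceeds high bound")
  chk(cfg$min_consecutive >= 1, "min_consecutive", "must be >= 1")
  chk(cfg$cutoff_fuzzless < cfg$cutoff_intermediate, "cutoff_fuzzless",
      "class cut-offs must increase")
  chk(cfg$penetrance > 0 && cfg$penetrance <= 1, "penetrance",
      "must be in (0, 1]")
  chk(cfg$error_rate >= 0 && cfg$error_rate < 0.5, "error_rate",
      "must be in [0, 0.5)")
  chk(cfg$depth > 0, "depth", "must be > 0")
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha", "must be in (0, 1)")
  chk(all(unlist(cfg[c("f2_n", "n_backcrosses", "n_selfs",
                       "n_fuzzless_lines", "n_segregating_lines",
                       "progeny_per_line", "recessive_bulk_size",
                       "segregating_bulk_size")]) >= 1),
      "population sizes", "must be >= 1")
  invisible(cfg)
}

#' Score recovery of planted causal loci by called regions
#'
#' @param regions `candidate_regions` (0-based half-open).
#' @param loci `data.frame` with `chrom` and `pos` (1-based) of planted
#'   loci, e.g. `model$loci`.
#' @return List: `recovered` (named logical per locus), `n_recovered`,
#'   and `n_offtarget` (regions on chromosomes without any planted
#'   locus).
#' @export
score_recovery <- function(regions, loci) {
  hit <- vapply(seq_len(nrow(loci)), function(i) {
    any(regions$chrom == loci$chrom[i] &
          regions$start <= loci$pos[i] - 1 & regions$end > loci$pos[i] - 1)
  }, logical(1))
  names(hit) <- if ("locus" %in% names(loci)) loci$locus else
    paste0(loci$chrom, ":", loci$pos)
  list(recovered = hit, n_recovered = sum(hit),
       n_offtarget = sum(!regions$chrom %in% loci$chrom))
}

.log_line <- function(con, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  writeLines(msg, con)
  message(msg)
}

#' Run the full mapping workflow on a simulated study
#'
#' Executes the published workflow end to end on a seeded simulation:
#' F2 segregation analysis and model selection; NIL development and
#' bulk construction; pooled-count simulation; variant filtering;
#' per-marker frequencies; sliding-window tracks for both bulks;
#' dual-bulk candidate-region calling; an array-style pool scan of
#' reduced- vs normal-fuzz individuals; intersection of the two region
#' sets; and single-marker association at the causal markers. Every
#' intermediate artifact is written to `out_dir` along with a
#' machine-readable `summary.json` and a parameter-echo log.
#'
#' @param cfg A [default_config()] (validated before any stage runs).
#' @param out_dir Run directory (created if needed).
#' @param model Optional [causal_model()]; default [ps_causal_model()]
#'   with the configured baseline, noise and penetrance.
#' @return Invisibly, a list with the main results: `segregation`,
#'   `association`, `regions_mbs`, `regions_array`, `regions_combined`,
#'   `recovery`, `out_dir`.
#' @export
run_pipeline <- function(cfg = default_config(), out_dir, model = NULL) {
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(log_con))
  .log_line(log_con, "fuzzmap ", as.character(utils::packageVersion("fuzzmap")),
            " | R ", getRversion())
  .log_line(log_con, "config: ",
            paste(names(cfg), unlist(cfg), sep = "=", collapse = " "))
  set.seed(cfg$seed)
  cutoffs <- c(fuzzless = cfg$cutoff_fuzzless,
               intermediate = cfg$cutoff_intermediate)
  genome <- sim_genome(cfg$n_chrom, cfg$chrom_length, cfg$marker_spacing,
                       cfg$cm_per_mb)
  if (is.null(model))
    model <- ps_causal_model(baseline_fuzz = cfg$baseline_fuzz,
                             noise_sd = cfg$noise_sd,
                             penetrance = cfg$penetrance)

  # --- F2: segregation and association ---------------------------------
  .log_line(log_con, "stage f2: simulating F2 of ", cfg$f2_n)
  f2 <- simulate_f2(genome, model, n = cfg$f2_n, cutoffs = cutoffs)
  write_genotypes(f2$genotypes, file.path(out_dir, "f2_genotypes.tsv"))
  utils::write.table(f2$phenotypes, file.path(out_dir, "f2_phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  n_mutant <- sum(f2$phenotypes$fuzz_class == "fuzzless", na.rm = TRUE)
  seg <- select_model(n_mutant, cfg$f2_n, k_range = seq_len(cfg$k_range_max))
  utils::write.table(seg$table, file.path(out_dir, "segregation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .log_line(log_con, "stage segregate: ", n_mutant, " fuzzless of ",
            cfg$f2_n, "; best k=", seg$best_k)
  assoc <- association_scan(f2$genotypes, f2$phenotypes,
                            marker_ids = unname(f2$causal_markers),
                            alpha = cfg$alpha,
                            min_group_size = cfg$min_group_size)
  utils::write.table(assoc, file.path(out_dir, "association.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- NILs, bulks, pooled counts --------------------------------------
  .log_line(log_con, "stage nil: developing lines and progeny")
  nil <- simulate_nil_lines(genome, model,
                            n_backcrosses = cfg$n_backcrosses,
                            n_selfs = cfg$n_selfs,
                            n_fuzzless_lines = cfg$n_fuzzless_lines,
                            n_segregating_lines = cfg$n_segregating_lines,
                            progeny_per_line = cfg$progeny_per_line,
                            cutoffs = cutoffs)
  rec_ids <- build_bulk(nil, "recessive_bulk", cfg$recessive_bulk_size)
  seg_ids <- build_bulk(nil, "segregating_bulk", cfg$segregating_bulk_size)
  counts <- list(
    recessive = simulate_pool_counts(nil$genotypes, rec_ids,
                                     depth = cfg$depth,
                                     error_rate = cfg$error_rate),
    segregating = simulate_pool_counts(nil$genotypes, seg_ids,
                                       depth = cfg$depth,
                                       error_rate = cfg$error_rate))
  for (b in names(counts)) {
    counts[[b]]$bulk <- b
    utils::write.table(counts[[b]],
                       file.path(out_dir, paste0("counts_", b, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- filter -> frequency -> windows -> regions -----------------------
  fcfg <- variant_filter_config(cfg$min_coverage, cfg$min_variant_reads,
                                cfg$min_variant_frequency)
  wcfg <- window_config(cfg$window_length, cfg$step, cfg$min_snps_per_window)
  tracks <- lapply(counts, function(d) {
    filt <- filter_pooled_variants(d, fcfg)
    rep <- attr(filt, "filter_report")
    .log_line(log_con, "stage filter: ", rep[["retained"]], "/",
              rep[["input"]], " variants retained")
    filt$freq <- pool_frequency_from_reads(filt$donor_reads,
                                           filt$total_reads)
    window_scan(filt[, c("chrom", "pos", "freq")], genome$chrom_lengths,
                wcfg)
  })
  write_window_track(tracks$recessive,
                     file.path(out_dir, "track_recessive.tsv"))
  write_window_track(tracks$segregating,
                     file.path(out_dir, "track_segregating.tsv"))
  regions_mbs <- call_candidate_regions(
    tracks$recessive, tracks$segregating,
    high_threshold = cfg$high_threshold,
    segregating_band = c(cfg$segregating_band_low,
                         cfg$segregating_band_high),
    min_consecutive = cfg$min_consecutive)
  .log_line(log_con, "stage call-regions: ", nrow(regions_mbs),
            " MBS region(s)")

  # --- array-style pool scan -------------------------------------------
  reduced_ids <- nil$phenotypes$individual[
    nil$phenotypes$fuzz_class %in% c("fuzzless", "intermediate")]
  normal_ids <- nil$phenotypes$individual[
    nil$phenotypes$fuzz_class == "normal"]
  regions_array <- regions_mbs[0, ]
  if (length(reduced_ids) >= 2 && length(normal_ids) >= 2) {
    tr_red <- window_scan(array_pool_frequencies(nil$genotypes, reduced_ids),
                          genome$chrom_lengths, wcfg)
    tr_nrm <- window_scan(array_pool_frequencies(nil$genotypes, normal_ids),
                          genome$chrom_lengths, wcfg)
    regions_array <- call_array_candidates(
      tr_red, tr_nrm, high_threshold = cfg$high_threshold,
      normal_max = cfg$normal_max, min_consecutive = cfg$min_consecutive)
  } else {
    .log_line(log_con, "stage array: too few normal-fuzz individuals; skipped")
  }
  combined <- intersect_region_sets(regions_mbs, regions_array)
  write_regions_bed(regions_mbs, file.path(out_dir, "regions_mbs.bed"))
  write_regions_bed(regions_array, file.path(out_dir, "regions_array.bed"))
  write_regions_bed(combined, file.path(out_dir, "regions_combined.bed"))

  # --- truth + summary -------------------------------------------------
  truth <- data.frame(chrom = model$loci$chrom,
                      start = model$loci$pos - 1, end = model$loci$pos,
                      evidence = model$loci$locus, stringsAsFactors = FALSE)
  write_regions_bed(truth, file.path(out_dir, "truth_loci.bed"))
  recovery <- score_recovery(regions_mbs, model$loci)
  .log_line(log_con, "recovery: ", recovery$n_recovered, "/",
            nrow(model$loci), " loci; ", recovery$n_offtarget,
            " off-target region(s)")
  summary <- list(
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("fuzzmap")),
    config = cfg[order(names(cfg))],
    segregation = list(n_mutant = n_mutant, n_total = cfg$f2_n,
                       best_k = seg$best_k, table = seg$table),
    association = assoc,
    regions_mbs = as.data.frame(regions_mbs),
    regions_array = as.data.frame(regions_array),
    regions_combined = as.data.frame(combined),
    recovery = list(recovered = as.list(recovery$recovered),
                    n_recovered = recovery$n_recovered,
                    n_offtarget = recovery$n_offtarget))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .log_line(log_con, "done")
  invisible(list(segregation = seg, association = assoc,
                 regions_mbs = regions_mbs, regions_array = regions_array,
                 regions_combined = combined, recovery = recovery,
                 out_dir = out_dir))
}
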