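# Homoeolog expression bookkeeping for a duplicated regulator in an
# allotetraploid, and the two-threshold dosage model mapping its
# expression at two developmental timepoints to a seed fibre phenotype.

#' At-homoeolog expression by subtraction
#'
#' When no homoeolog-specific assay exists for the At copy, its expression
#' is taken as total minus the Dt-specific measurement. Small negative
#' differences (Dt exceeding total by at most `tolerance * total`) are
#' treated as measurement noise and clamped to zero with a warning; larger
#' excesses indicate incompatible measurements and raise an error.
#'
#' @param total Total expression of both homoeologs (relative units, >= 0).
#' @param dt Dt-homoeolog expression (same units, >= 0). Recycled
#'   pairwise with `total`.
#' @param tolerance Allowed relative excess of `dt` over `total`
#'   (default 0.05).
#' @return `total - dt`, clamped to 0 where within tolerance.
#' @export
at_by_subtraction <- function(total, dt, tolerance = 0.05) {
  if (any(!is.finite(total)) || any(!is.finite(dt)))
    stop("expression values must be finite", call. = FALSE)
  if (any(total < 0) || any(dt < 0))
    stop("expression values must be >= 0", call. = FALSE)
  diff <- total - dt
  bad <- dt > total * (1 + tolerance)
  if (any(bad))
    stop(sprintf("Dt expression exceeds total by more than %.0f%% at %d point(s): inconsistent measurements",
                 100 * tolerance, sum(bad)), call. = FALSE)
  clamp <- diff < 0
  if (any(clamp)) {
    warning(sprintf("%d point(s) with Dt slightly above total clamped to 0",
                    sum(clamp)), call. = FALSE)
    diff[clamp] <- 0
  }
  diff
}

#' Per-timepoint At/Dt expression shares
#'
#' @param total,dt Expression per timepoint as in [at_by_subtraction()].
#' @param tolerance Passed to [at_by_subtraction()].
#' @return `data.frame` with columns `at_share`, `dt_share` summing to 1
#'   per timepoint; both `NA` where `total == 0`.
#' @export
homoeolog_proportions <- function(total, dt, tolerance = 0.05) {
  at <- at_by_subtraction(total, dt, tolerance)
  dt_eff <- total - at  # clamped dt, so shares always sum to 1
  undef <- total == 0
  data.frame(at_share = ifelse(undef, NA_real_, at / total),
             dt_share = ifelse(undef, NA_real_, dt_eff / total))
}

#' Dosage thresholds of the fibre phenotype model
#'
#' `threshold1` gates fuzz: Dt-homoeolog expression at ~3 days
#' post-anthesis (dpa), when fuzz fibres initiate. `threshold2` gates
#' lint: total expression at ~0 dpa, when lint fibres initiate. The
#' thresholds are relative-expression values in the units of the input
#' data; biology fixes only their ordering role, not their magnitude, so
#' both are user parameters.
#'
#' @param threshold1 Fuzz gate (Dt at ~3 dpa), > 0.
#' @param threshold2 Lint gate (total at ~0 dpa), > 0.
#' @return List of class `dosage_thresholds`.
#' @export
dosage_thresholds <- function(threshold1, threshold2) {
  if (!is.finite(threshold1) || !is.finite(threshold2) ||
      threshold1 <= 0 || threshold2 <= 0)
    stop("thresholds must be finite and > 0", call. = FALSE)
  structure(list(threshold1 = threshold1, threshold2 = threshold2),
            class = "dosage_thresholds")
}

#' Two-threshold dosage classification of seed fibre phenotype
#'
#' Total expression below `threshold2` at ~0 dpa means no lint initiates:
#' the seed is `fibreless`. Otherwise, Dt expression below `threshold1` at
#' ~3 dpa means no fuzz initiates: `fuzzless_linted`. Otherwise
#' `fuzzy_linted`. The fourth logical combination (lintless but fuzzy)
#' is never emitted: genotypes expressing enough Dt at ~3 dpa for fuzz
#' also express enough total at ~0 dpa for lint, and no lintless-fuzzy
#' mutant has ever been observed.
#'
#' @param total_at_0dpa Total expression at ~0 dpa (>= 0); vectorized.
#' @param dt_at_3dpa Dt-homoeolog expression at ~3 dpa (>= 0).
#' @param th A [dosage_thresholds()] object.
#' @return Factor with ordered levels
#'   `fibreless < fuzzless_linted < fuzzy_linted`.
#' @export
dosage_classify <- function(total_at_0dpa, dt_at_3dpa, th) {
  stopifnot(inherits(th, "dosage_thresholds"))
  if (any(!is.finite(total_at_0dpa)) || any(!is.finite(dt_at_3dpa)))
    stop("expression inputs must be finite", call. = FALSE)
  if (any(total_at_0dpa < 0) || any(dt_at_3dpa < 0))
    stop("expression inputs must be >= 0", call. = FALSE)
  cls <- ifelse(total_at_0dpa < th$threshold2, "fibreless",
         ifelse(dt_at_3dpa < th$threshold1, "fuzzless_linted",
                "fuzzy_linted"))
  factor(cls, levels = c("fibreless", "fuzzless_linted", "fuzzy_linted"),
         ordered = TRUE)
}

#' Convert qPCR Ct values to relative quantities
#'
#' Reference-normalized relative quantity `2^(ct_ref - ct_target)`,
#' assuming perfect doubling per cycle. Per-primer efficiency correction
#' is deliberately not applied.
#'
#' @param ct_target Ct of the target amplicon.
#' @param ct_ref Ct of the reference gene in the same sample.
#' @return Relative expression quantity.
#' @export
ct_to_relative <- function(ct_target, ct_ref) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_ref)))
    stop("Ct values must be finite", call. = FALSE)
  2^(ct_ref - ct_target)
}

#' Summarize replicate expression measurements
#'
#' Means and standard errors of `total` and `dt` per genotype and
#' timepoint, for tables read by [read_expression()].
#'
#' @param expr `data.frame` with columns `genotype`, `dpa`, `total`, `dt`
#'   (replicate rows).
#' @return `data.frame` with one row per `(genotype, dpa)`: `n`,
#'   `total_mean`, `total_se`, `dt_mean`, `dt_se`.
#' @export
summarize_expression <- function(expr) {
  stopifnot(is.data.frame(expr),
            all(c("genotype", "dpa", "total", "dt") %in% names(expr)))
  key <- interaction(expr$genotype, expr$dpa, drop = TRUE)
  rows <- lapply(split(expr, key), function(d) {
    n <- nrow(d)
    se <- function(v) if (n > 1) stats::sd(v) / sqrt(n) else NA_real_
    data.frame(genotype = d$genotype[1], dpa = d$dpa[1], n = n,
               total_mean = mean(d$total), total_se = se(d$total),
               dt_mean = mean(d$dt), dt_se = se(d$dt),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$genotype, out$dpa), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify genotypes from an expression time course
#'
#' Summarizes replicates, extracts per-genotype total expression at the
#' timepoint closest to 0 dpa and Dt expression at the timepoint closest
#' to 3 dpa, and applies [dosage_classify()].
#'
#' @param expr Replicate expression table (`genotype`, `dpa`, `total`,
#'   `dt`).
#' @param th A [dosage_thresholds()].
#' @param lint_dpa,fuzz_dpa Target timepoints for the two gates
#'   (defaults 0 and 3 dpa).
#' @return `data.frame` with `genotype`, `total_at_0dpa`, `dt_at_3dpa`,
#'   `class`.
#' @export
dosage_classify_profiles <- function(expr, th, lint_dpa = 0, fuzz_dpa = 3) {
  summ <- summarize_expression(expr)
  rows <- lapply(split(summ, summ$genotype), function(d) {
    i0 <- which.min(abs(d$dpa - lint_dpa))
    i3 <- which.min(abs(d$dpa - fuzz_dpa))
    data.frame(genotype = d$genotype[1],
               total_at_0dpa = d$total_mean[i0],
               dt_at_3dpa = d$dt_mean[i3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$class <- dosage_classify(out$total_at_0dpa, out$dt_at_3dpa, th)
  rownames(out) <- NULL
  out
}
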