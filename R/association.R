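# Single-marker association of genotype classes with fuzz percentage, and
# classification of each locus as suppressor / enhancer / additive-major.

#' Partition phenotype values by genotype class at one marker
#'
#' Splits individuals into donor-homozygous (code 1), heterozygous (0.5)
#' and recurrent-homozygous (0) groups at the given marker and collects
#' their quantitative phenotype values. Individuals with a missing
#' genotype or missing phenotype are excluded and counted.
#'
#' @param gm A [genotype_matrix()].
#' @param marker_id Marker to group on.
#' @param phenos A [phenotype_table()] (matched to `gm` by individual id).
#' @param trait Phenotype column to use (default `"fuzz_pct"`).
#' @return List of class `genotype_groups` with numeric vectors `donor`,
#'   `het`, `recurrent`, plus `marker_id` and `n_excluded`.
#' @export
group_phenotype_by_genotype <- function(gm, marker_id, phenos,
                                        trait = "fuzz_pct") {
  stopifnot(inherits(gm, "genotype_matrix"), is.data.frame(phenos))
  if (!marker_id %in% gm$markers$marker)
    stop(sprintf("marker '%s' not in genotype matrix", marker_id),
         call. = FALSE)
  if (!trait %in% names(phenos))
    stop(sprintf("phenotype column '%s' not found", trait), call. = FALSE)
  codes <- gm$codes[, marker_id]
  pheno_val <- phenos[[trait]][match(gm$individuals, phenos$individual)]
  unmatched <- sum(!gm$individuals %in% phenos$individual)
  if (unmatched > 0)
    warning(sprintf("%d individual(s) without phenotype record excluded",
                    unmatched), call. = FALSE)
  usable <- !is.na(codes) & !is.na(pheno_val)
  if (!any(usable))
    stop("no individual with both genotype and phenotype at this marker",
         call. = FALSE)
  structure(list(donor = pheno_val[usable & codes == 1],
                 het = pheno_val[usable & codes == 0.5],
                 recurrent = pheno_val[usable & codes == 0],
                 marker_id = marker_id,
                 n_excluded = sum(!usable)),
            class = "genotype_groups")
}

# Two-sided two-sample t, pooled variance by default (Welch optional).
# Returns c(t, p) or c(NA, NA) when a group is below min_group_size or the
# statistic is undefined (zero pooled variance with equal means gives t=0).
.contrast_t <- function(x, y, min_group_size, welch) {
  if (length(x) < min_group_size || length(y) < min_group_size)
    return(c(t = NA_real_, p = NA_real_))
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(c(t = 0, p = 1))
    return(c(t = ifelse(mean(x) > mean(y), Inf, -Inf), p = 0))
  }
  tt <- stats::t.test(x, y, var.equal = !welch)
  c(t = unname(tt$statistic), p = tt$p.value)
}

#' Marker-trait association test across genotype classes
#'
#' Compares mean phenotype between genotype classes with two-sided
#' two-sample Student's t-tests (pooled variance; Welch's correction
#' available via `welch = TRUE`): donor-homozygote vs
#' recurrent-homozygote, heterozygote vs each homozygote. Contrasts with a
#' group below `min_group_size` are reported as untestable (`NA`), not
#' errors.
#'
#' @param groups A `genotype_groups` object from
#'   [group_phenotype_by_genotype()].
#' @param min_group_size Minimum observations per group for a contrast to
#'   be tested (default 3).
#' @param welch Use Welch's unequal-variance t instead of pooled variance
#'   (default `FALSE`).
#' @return List of class `association_result`: `marker_id`, `group_means`,
#'   `group_sizes` (each named donor/het/recurrent), `contrasts` (a
#'   `data.frame` with `contrast`, `t`, `p`, `sig05`, `sig01`).
#' @export
marker_trait_test <- function(groups, min_group_size = 3, welch = FALSE) {
  stopifnot(inherits(groups, "genotype_groups"))
  g <- groups[c("donor", "het", "recurrent")]
  means <- vapply(g, function(v) if (length(v)) mean(v) else NA_real_,
                  numeric(1))
  sizes <- vapply(g, length, integer(1))
  cons <- rbind(
    donor_vs_recurrent = .contrast_t(g$donor, g$recurrent, min_group_size, welch),
    het_vs_donor = .contrast_t(g$het, g$donor, min_group_size, welch),
    het_vs_recurrent = .contrast_t(g$het, g$recurrent, min_group_size, welch))
  contrasts <- data.frame(contrast = rownames(cons),
                          t = unname(cons[, "t"]), p = unname(cons[, "p"]),
                          sig05 = !is.na(cons[, "p"]) & cons[, "p"] < 0.05,
                          sig01 = !is.na(cons[, "p"]) & cons[, "p"] < 0.01,
                          row.names = NULL, stringsAsFactors = FALSE)
  structure(list(marker_id = groups$marker_id, group_means = means,
                 group_sizes = sizes, contrasts = contrasts),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("association at %s: means donor=%.2f het=%.2f recurrent=%.2f (n=%d/%d/%d)\n",
              x$marker_id, x$group_means["donor"], x$group_means["het"],
              x$group_means["recurrent"], x$group_sizes["donor"],
              x$group_sizes["het"], x$group_sizes["recurrent"]))
  print(x$contrasts)
  invisible(x)
}

#' Classify the effect of a locus on the quantitative trait
#'
#' Based on the homozygote contrast: the donor allele is a `suppressor`
#' when donor homozygotes have a significantly lower trait mean than
#' recurrent homozygotes, an `enhancer` when significantly higher.
#' `additive_major` additionally requires the heterozygote mean to lie
#' strictly between the homozygote means with the heterozygote
#' significantly different from both homozygote classes. `none` when the
#' homozygote contrast is untestable or not significant.
#'
#' @param res An `association_result` from [marker_trait_test()].
#' @param alpha Significance level (default 0.05).
#' @return Single character: `"suppressor"`, `"enhancer"`,
#'   `"additive_major"` or `"none"`. When the homozygote contrast is
#'   untestable the result carries a `reason` attribute.
#' @export
classify_locus_effect <- function(res, alpha = 0.05) {
  stopifnot(inherits(res, "association_result"))
  ct <- res$contrasts
  p_hom <- ct$p[ct$contrast == "donor_vs_recurrent"]
  if (is.na(p_hom))
    return(structure("none", reason = "homozygote contrast untestable"))
  if (p_hom >= alpha) return("none")
  m <- res$group_means
  direction <- if (m["donor"] < m["recurrent"]) "suppressor" else "enhancer"
  p_hd <- ct$p[ct$contrast == "het_vs_donor"]
  p_hr <- ct$p[ct$contrast == "het_vs_recurrent"]
  het_between <- !is.na(m["het"]) &&
    m["het"] > min(m["donor"], m["recurrent"]) &&
    m["het"] < max(m["donor"], m["recurrent"])
  het_distinct <- !is.na(p_hd) && !is.na(p_hr) && p_hd < alpha && p_hr < alpha
  if (het_between && het_distinct) return("additive_major")
  direction
}

#' Association scan over several markers
#'
#' Convenience wrapper running [group_phenotype_by_genotype()],
#' [marker_trait_test()] and [classify_locus_effect()] per marker.
#'
#' @param gm A [genotype_matrix()].
#' @param phenos A [phenotype_table()].
#' @param marker_ids Markers to test (default: all in `gm`).
#' @param alpha Significance level for the effect call.
#' @param min_group_size,welch Passed to [marker_trait_test()].
#' @return `data.frame` with one row per marker: group means and sizes,
#'   t and p for each contrast, and `effect_call`.
#' @export
association_scan <- function(gm, phenos, marker_ids = gm$markers$marker,
                             alpha = 0.05, min_group_size = 3,
                             welch = FALSE) {
  rows <- lapply(marker_ids, function(mid) {
    res <- marker_trait_test(
      group_phenotype_by_genotype(gm, mid, phenos),
      min_group_size = min_group_size, welch = welch)
    ct <- res$contrasts
    data.frame(marker = mid,
               mean_donor = res$group_means["donor"],
               mean_het = res$group_means["het"],
               mean_recurrent = res$group_means["recurrent"],
               n_donor = res$group_sizes["donor"],
               n_het = res$group_sizes["het"],
               n_recurrent = res$group_sizes["recurrent"],
               t_hom = ct$t[1], p_hom = ct$p[1],
               t_het_donor = ct$t[2], p_het_donor = ct$p[2],
               t_het_recurrent = ct$t[3], p_het_recurrent = ct$p[3],
               effect_call = as.character(classify_locus_effect(res, alpha)),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
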