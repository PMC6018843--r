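#' Expected mutant fraction under a k-recessive-gene model
#'
#' In an F2 (selfed F1), a phenotype requiring homozygosity of the donor
#' allele at `k` unlinked recessive loci is expected in `(1/4)^k` of
#' plants, i.e. a `(4^k - 1):1` ratio of non-mutant to mutant. `k = 2`
#' gives the 15:1 ratio, `k = 3` the 63:1 ratio.
#'
#' @param k Integer number of unlinked required recessive loci, `k >= 1`.
#' @return Expected mutant fraction `(1/4)^k`.
#' @export
expected_mutant_fraction <- function(k) {
  if (length(k) != 1 || !is.finite(k) || k < 1 || k != round(k))
    stop("invalid input 'k': must be a single integer >= 1", call. = FALSE)
  (1 / 4)^k
}

#' Two-class Pearson chi-square test of a k-recessive-gene ratio
#'
#' Tests observed mutant (e.g. fuzzless) vs non-mutant counts in an F2
#' against the `(4^k - 1):1` expectation with the uncorrected Pearson
#' statistic on the two classes (1 degree of freedom, upper-tail p). No
#' Yates continuity correction is applied.
#'
#' @param n_mutant Number of mutant-phenotype plants (or F2:F3 families
#'   scored mutant).
#' @param n_total Total number of plants/families.
#' @param k Number of required recessive loci, see
#'   [expected_mutant_fraction()].
#' @return `data.frame` of class `segregation_result` with columns `k`,
#'   `ratio` (non-mutant:mutant, e.g. `"63:1"`), `n_total`, `n_mutant`,
#'   `expected_mutant`, `chi_square`, `df`, `p_value`.
#' @examples
#' ratio_chisq(3, 169, k = 3) # chi^2 = 0.0497, p = 0.8236
#' @export
ratio_chisq <- function(n_mutant, n_total, k) {
  if (length(n_mutant) != 1 || length(n_total) != 1 ||
      !is.finite(n_mutant) || !is.finite(n_total) ||
      n_mutant != round(n_mutant) || n_total != round(n_total))
    stop("counts must be single integers", call. = FALSE)
  if (n_total < 1 || n_mutant < 0 || n_mutant > n_total)
    stop("invalid counts: need 0 <= n_mutant <= n_total, n_total >= 1",
         call. = FALSE)
  q <- expected_mutant_fraction(k)
  e_mut <- n_total * q
  e_non <- n_total * (1 - q)
  chi <- (n_mutant - e_mut)^2 / e_mut + ((n_total - n_mutant) - e_non)^2 / e_non
  res <- data.frame(k = as.integer(k),
                    ratio = sprintf("%d:1", 4L^as.integer(k) - 1L),
                    n_total = as.integer(n_total),
                    n_mutant = as.integer(n_mutant),
                    expected_mutant = e_mut,
                    chi_square = chi,
                    df = 1L,
                    p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  class(res) <- c("segregation_result", "data.frame")
  res
}

#' Select the best-fitting k-recessive-gene segregation model
#'
#' Runs [ratio_chisq()] for every `k` in `k_range` and reports the model
#' with the largest goodness-of-fit p-value; ties break toward smaller `k`
#' (the more parsimonious model).
#'
#' @param n_mutant,n_total Observed counts as in [ratio_chisq()].
#' @param k_range Integer vector of candidate locus counts (default 1:4).
#' @return List with `table` (one [ratio_chisq()] row per k, ordered by k)
#'   and `best_k`.
#' @examples
#' select_model(3, 169, k_range = 1:4)$best_k # 3
#' @export
select_model <- function(n_mutant, n_total, k_range = 1:4) {
  if (length(k_range) < 1)
    stop("k_range must be non-empty", call. = FALSE)
  k_range <- sort(unique(as.integer(k_range)))
  tab <- do.call(rbind, lapply(k_range, function(k)
    ratio_chisq(n_mutant, n_total, k)))
  class(tab) <- c("segregation_result", "data.frame")
  # which.max returns the first (smallest-k) maximizer on the sorted table
  list(table = tab, best_k = tab$k[which.max(tab$p_value)])
}
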