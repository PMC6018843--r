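#' fuzzmap: bulk segregant mapping of recessive seed-fuzz traits
#'
#' Tools for dissecting a recessive, multilocus seed-fuzz trait in an
#' interspecific cotton cross: Mendelian segregation-model selection,
#' pooled-bulk allele-frequency scanning with overlapping sliding windows,
#' dual-bulk candidate-region calling, single-marker association of
#' genotype classes with fuzz percentage, a two-threshold homoeolog
#' expression dosage classifier, and a seeded population simulator that
#' emulates the F2 and backcross/NIL designs the analysis assumes.
#'
#' @keywords internal
#' @aliases fuzzmap-package
"_PACKAGE"

# Internal allele coding used throughout: donor-parent homozygote = 1,
# heterozygote = 0.5, recurrent-parent homozygote = 0, missing = NA.
.VALID_CODES <- c(0, 0.5, 1)

#' Fuzz percentage of a seed sample
#'
#' The quantitative fuzz phenotype: the weight fraction of short seed-coat
#' fibres (fuzz) removed by delinting, expressed as a percentage of the
#' ginned-seed weight, `100 * (ginned - delinted) / ginned`. Both weights
#' must be taken at the same moisture equilibrium.
#'
#' @param ginned_weight Weight of ginned (linted then fuzz-bearing) seeds;
#'   any mass unit, must be positive.
#' @param delinted_weight Weight of the same seeds after delinting; same
#'   unit, must lie in `[0, ginned_weight]`. Vectors recycle as usual.
#' @return Numeric vector of fuzz percentages in `[0, 100]`.
#' @examples
#' fuzz_percentage(12.0, 10.8) # 10
#' @export
fuzz_percentage <- function(ginned_weight, delinted_weight) {
  if (!is.numeric(ginned_weight) || !is.numeric(delinted_weight))
    stop("weights must be numeric", call. = FALSE)
  if (any(!is.finite(ginned_weight)) || any(!is.finite(delinted_weight)))
    stop("weights must be finite", call. = FALSE)
  if (any(ginned_weight <= 0))
    stop("invalid input 'ginned_weight': must be > 0", call. = FALSE)
  if (any(delinted_weight < 0))
    stop("invalid input 'delinted_weight': must be >= 0", call. = FALSE)
  if (any(delinted_weight > ginned_weight))
    stop("invalid input 'delinted_weight': exceeds ginned_weight", call. = FALSE)
  100 * (ginned_weight - delinted_weight) / ginned_weight
}

#' Encode a parental-origin genotype call as a numeric dose
#'
#' Donor-parent homozygotes are coded 1, heterozygotes 0.5 and
#' recurrent-parent homozygotes 0; missing calls become `NA`. The code is
#' the donor-allele dosage halved, so the mean code of a pool is its
#' donor-allele frequency.
#'
#' @param call Character vector of calls. Accepted tokens (case-insensitive):
#'   `"AA"`/`"donor"`/`"donor/donor"` for donor homozygotes,
#'   `"AB"`/`"het"`/`"heterozygous"`/`"donor/recurrent"` for heterozygotes,
#'   `"BB"`/`"recurrent"`/`"recurrent/recurrent"` for recurrent homozygotes,
#'   and `"NA"`/`""`/`NA` for missing.
#' @param context Optional label (marker/individual) used in error messages.
#' @return Numeric vector with values in `{0, 0.5, 1, NA}`.
#' @seealso [decode_genotype()]
#' @export
encode_genotype <- function(call, context = NULL) {
  tok <- tolower(trimws(as.character(call)))
  out <- rep(NA_real_, length(tok))
  donor <- c("aa", "donor", "donor/donor", "1")
  het <- c("ab", "ba", "het", "heterozygous", "donor/recurrent",
           "recurrent/donor", "0.5")
  rec <- c("bb", "recurrent", "recurrent/recurrent", "0")
  miss <- c("na", "", ".", "nn")
  out[tok %in% donor] <- 1
  out[tok %in% het] <- 0.5
  out[tok %in% rec] <- 0
  bad <- !(tok %in% c(donor, het, rec, miss)) & !is.na(call)
  if (any(bad)) {
    where <- if (is.null(context)) "" else paste0(" at ", context[bad][1])
    stop(sprintf("unrecognized genotype call '%s'%s",
                 as.character(call)[bad][1], where), call. = FALSE)
  }
  out
}

#' Decode a numeric genotype code back to a call token
#'
#' Inverse of [encode_genotype()] on the three valid codes.
#'
#' @param code Numeric vector with values in `{0, 0.5, 1, NA}`.
#' @return Character vector in `{"AA", "AB", "BB", NA}`.
#' @export
decode_genotype <- function(code) {
  if (any(!is.na(code) & !code %in% .VALID_CODES))
    stop("genotype codes must be 0, 0.5, 1 or NA", call. = FALSE)
  out <- rep(NA_character_, length(code))
  out[!is.na(code) & code == 1] <- "AA"
  out[!is.na(code) & code == 0.5] <- "AB"
  out[!is.na(code) & code == 0] <- "BB"
  out
}

#' Default fuzz-class cut-offs
#'
#' Seeds are classed `fuzzless` below the lower cut-off, `intermediate`
#' below the upper cut-off and `normal` otherwise. The defaults (1.5% and
#' 6%) sit between the near-zero fuzz of fuzzless donor-type seeds and the
#' 10--12% typical of normal-fuzz upland cultivars; visual class boundaries
#' are not a measured quantity, so both are configuration.
#'
#' @return Named numeric vector `c(fuzzless = 1.5, intermediate = 6)`.
#' @export
default_fuzz_cutoffs <- function() c(fuzzless = 1.5, intermediate = 6)

#' Classify a fuzz percentage into a visual fuzz class
#'
#' @param fp Fuzz percentage(s) in `[0, 100]`.
#' @param cutoffs Length-2 numeric `(lower, upper)`, see
#'   [default_fuzz_cutoffs()]. Must be strictly increasing.
#' @return Factor with ordered levels `fuzzless < intermediate < normal`.
#' @export
classify_fuzz <- function(fp, cutoffs = default_fuzz_cutoffs()) {
  if (length(cutoffs) != 2 || !cutoffs[1] < cutoffs[2])
    stop("cutoffs must be two increasing values", call. = FALSE)
  if (any(!is.na(fp) & (fp < 0 | fp > 100)))
    stop("invalid input 'fp': fuzz percentage outside [0, 100]", call. = FALSE)
  cls <- ifelse(is.na(fp), NA_character_,
         ifelse(fp < cutoffs[1], "fuzzless",
         ifelse(fp < cutoffs[2], "intermediate", "normal")))
  factor(cls, levels = c("fuzzless", "intermediate", "normal"), ordered = TRUE)
}

#' Build a marker map
#'
#' @param marker Character marker ids (unique).
#' @param chrom Chromosome labels.
#' @param pos 1-based physical positions in base pairs (strictly positive;
#'   `(chrom, pos)` pairs must be unique).
#' @return A `data.frame` with columns `marker`, `chrom`, `pos`, sorted by
#'   `(chrom, pos)`, of class `marker_map`.
#' @export
marker_map <- function(marker, chrom, pos) {
  marker <- as.character(marker)
  chrom <- as.character(chrom)
  pos <- as.numeric(pos)
  if (length(marker) != length(chrom) || length(marker) != length(pos))
    stop("marker, chrom and pos must have equal length", call. = FALSE)
  if (any(!is.finite(pos)) || any(pos <= 0) || any(pos != round(pos)))
    stop("positions must be positive integers (1-based bp)", call. = FALSE)
  if (anyDuplicated(marker))
    stop("duplicated marker ids", call. = FALSE)
  if (anyDuplicated(paste(chrom, pos)))
    stop("duplicated (chrom, pos) pairs", call. = FALSE)
  mm <- data.frame(marker = marker, chrom = chrom, pos = pos,
                   stringsAsFactors = FALSE)
  mm <- mm[order(mm$chrom, mm$pos), , drop = FALSE]
  rownames(mm) <- NULL
  class(mm) <- c("marker_map", "data.frame")
  mm
}

#' Assemble a genotype matrix
#'
#' Container pairing a [marker_map()] with an individuals-by-markers matrix
#' of numeric codes (donor = 1, het = 0.5, recurrent = 0, `NA` missing).
#'
#' @param markers A `marker_map`.
#' @param codes Numeric matrix, rows = individuals, columns = markers in
#'   map order; values in `{0, 0.5, 1, NA}`.
#' @param individuals Character ids, one per row of `codes`.
#' @return A list of class `genotype_matrix` with elements `markers`,
#'   `individuals` and `codes` (dimnames set from both id sets).
#' @export
genotype_matrix <- function(markers, codes, individuals) {
  stopifnot(inherits(markers, "marker_map"))
  codes <- as.matrix(codes)
  individuals <- as.character(individuals)
  if (nrow(codes) != length(individuals))
    stop("row count of codes does not match individual ids", call. = FALSE)
  if (ncol(codes) != nrow(markers))
    stop("column count of codes does not match marker map", call. = FALSE)
  if (any(!is.na(codes) & !codes %in% .VALID_CODES))
    stop("genotype codes must be 0, 0.5, 1 or NA", call. = FALSE)
  if (anyDuplicated(individuals))
    stop("duplicated individual ids", call. = FALSE)
  dimnames(codes) <- list(individuals, markers$marker)
  structure(list(markers = markers, individuals = individuals, codes = codes),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d markers on %d chromosome(s)\n",
              length(x$individuals), nrow(x$markers),
              length(unique(x$markers$chrom))))
  cat(sprintf("  missing codes: %d (%.2f%%)\n", sum(is.na(x$codes)),
              100 * mean(is.na(x$codes))))
  invisible(x)
}

#' Build a phenotype table
#'
#' @param individual Character ids.
#' @param fuzz_pct Fuzz percentage in `[0, 100]` (may be `NA`).
#' @param lint_pct Lint percentage or `NA`.
#' @param fuzz_class Optional character/factor class; when `NULL` it is
#'   derived from `fuzz_pct` via [classify_fuzz()].
#' @param tufted Optional logical flag (micropylar tuft present) or `NA`.
#' @param cutoffs Class cut-offs used when deriving `fuzz_class`.
#' @return `data.frame` of class `phenotype_table` with columns
#'   `individual`, `fuzz_pct`, `lint_pct`, `fuzz_class`, `tufted`.
#' @export
phenotype_table <- function(individual, fuzz_pct, lint_pct = NA,
                            fuzz_class = NULL, tufted = NA,
                            cutoffs = default_fuzz_cutoffs()) {
  individual <- as.character(individual)
  n <- length(individual)
  fuzz_pct <- rep_len(as.numeric(fuzz_pct), n)
  if (any(!is.na(fuzz_pct) & (fuzz_pct < 0 | fuzz_pct > 100)))
    stop("invalid input 'fuzz_pct': outside [0, 100]", call. = FALSE)
  if (is.null(fuzz_class)) {
    fuzz_class <- classify_fuzz(fuzz_pct, cutoffs)
  } else {
    fuzz_class <- factor(as.character(fuzz_class),
                         levels = c("fuzzless", "intermediate", "normal"),
                         ordered = TRUE)
  }
  pt <- data.frame(individual = individual,
                   fuzz_pct = fuzz_pct,
                   lint_pct = rep_len(as.numeric(lint_pct), n),
                   fuzz_class = fuzz_class,
                   tufted = rep_len(as.logical(tufted), n),
                   stringsAsFactors = FALSE)
  class(pt) <- c("phenotype_table", "data.frame")
  pt
}

#' Percentage tabulation of genotype-class counts
#'
#' Tabulates counts per genotype class (e.g. homoeoallele combinations in
#' an F2) into percentages of the population total, the layout used to
#' summarize fuzz/tuft classes by genotype class.
#'
#' @param counts Named integer vector (or a column of counts) per class.
#' @param total Population size; defaults to `sum(counts)` but can be given
#'   explicitly when the rows tabulate a subset of phenotype columns.
#' @param digits Decimal places for the reported percentage (default 2;
#'   internal computation is full precision).
#' @return `data.frame` with columns `class`, `n`, `pct`.
#' @examples
#' class_percentages(c(fibreless = 5, fuzzless = 11), total = 92)
#' @export
class_percentages <- function(counts, total = sum(counts), digits = 2) {
  if (any(counts < 0) || total <= 0 || sum(counts) > total)
    stop("invalid counts/total", call. = FALSE)
  data.frame(class = if (is.null(names(counts))) as.character(seq_along(counts))
                     else names(counts),
             n = as.integer(counts),
             pct = round(100 * counts / total, digits),
             row.names = NULL, stringsAsFactors = FALSE)
}
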