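# Readers and writers for the package's plain-text interchange formats.
# Marker/variant positions are 1-based in all input files; window and
# region intervals are 0-based half-open in bedGraph/BED output.

#' Read a genotype TSV
#'
#' Expected layout: header `marker chrom pos <ind1> <ind2> ...`, one row
#' per marker, genotype cells in `{AA, AB, BB, NA}` with `A` the donor
#' parent allele. Calls are encoded via [encode_genotype()].
#'
#' @param path File path.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = "character", check.names = FALSE)
  if (ncol(d) < 4 || !all(c("marker", "chrom", "pos") %in% names(d)[1:3]))
    stop("genotype file must start with columns marker, chrom, pos",
         call. = FALSE)
  mm <- marker_map(d$marker, d$chrom, as.numeric(d$pos))
  ind <- names(d)[-(1:3)]
  codes <- matrix(NA_real_, nrow = length(ind), ncol = nrow(mm),
                  dimnames = list(ind, mm$marker))
  for (j in seq_along(ind)) {
    enc <- encode_genotype(d[[ind[j]]],
                           context = paste0(d$marker, "/", ind[j]))
    codes[j, d$marker] <- enc
  }
  genotype_matrix(mm, codes, ind)
}

#' Write a genotype TSV
#'
#' Inverse of [read_genotypes()].
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  # markers x individuals character matrix of call tokens
  calls <- matrix(decode_genotype(as.vector(t(gm$codes))),
                  nrow = ncol(gm$codes))
  d <- data.frame(marker = gm$markers$marker, chrom = gm$markers$chrom,
                  pos = format(gm$markers$pos, scientific = FALSE,
                               trim = TRUE),
                  calls, check.names = FALSE, stringsAsFactors = FALSE)
  names(d)[-(1:3)] <- gm$individuals
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a phenotype TSV
#'
#' Expected header: `individual fuzz_pct lint_pct fuzz_class tufted`;
#' `NA` allowed everywhere except `individual`. A missing `fuzz_class`
#' column (or `NA` cells) is derived from `fuzz_pct`.
#'
#' @param path File path.
#' @param cutoffs Class cut-offs used when deriving classes.
#' @return A [phenotype_table()].
#' @export
read_phenotypes <- function(path, cutoffs = default_fuzz_cutoffs()) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!"individual" %in% names(d))
    stop("phenotype file must have an 'individual' column", call. = FALSE)
  if (any(is.na(d$individual)) || any(d$individual == ""))
    stop("individual ids must be present on every row", call. = FALSE)
  cls <- if ("fuzz_class" %in% names(d)) d$fuzz_class else NULL
  if (!is.null(cls) && all(is.na(cls))) cls <- NULL
  phenotype_table(d$individual,
                  fuzz_pct = if ("fuzz_pct" %in% names(d)) d$fuzz_pct else NA,
                  lint_pct = if ("lint_pct" %in% names(d)) d$lint_pct else NA,
                  fuzz_class = cls,
                  tufted = if ("tufted" %in% names(d)) d$tufted else NA,
                  cutoffs = cutoffs)
}

#' Read a replicate expression TSV
#'
#' Expected header: `genotype dpa total dt`, one row per biological
#' replicate. `dt` must not exceed `total` by more than the subtraction
#' tolerance (checked downstream).
#'
#' @param path File path.
#' @return `data.frame` with those four columns.
#' @export
read_expression <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("genotype", "dpa", "total", "dt")
  if (!all(need %in% names(d)))
    stop("expression file must have columns genotype, dpa, total, dt",
         call. = FALSE)
  if (any(!is.finite(d$total)) || any(!is.finite(d$dt)) ||
      any(d$total < 0) || any(d$dt < 0))
    stop("expression values must be finite and >= 0", call. = FALSE)
  d[need]
}

#' Read pooled variant counts (minimal VCF or TSV)
#'
#' TSV layout: `chrom pos donor_reads total_reads bulk` (1-based
#' positions). VCF: one sample per bulk with an `AD` (allele depth)
#' FORMAT field; the donor allele is ALT by default (variants called
#' against the recurrent-parent reference), flip with
#' `donor_allele = "ref"`. Records with more than one ALT allele are
#' rejected; records where REF or ALT is longer than one base are flagged
#' as indels (`is_indel`), which the default variant filter drops.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param donor_allele Which VCF allele is the donor's: `"alt"` (default)
#'   or `"ref"`.
#' @return Named list of per-bulk `data.frame`s with columns `marker`,
#'   `chrom`, `pos`, `donor_reads`, `total_reads`, `is_indel`.
#' @export
read_variants <- function(path, format = c("auto", "vcf", "tsv"),
                          donor_allele = c("alt", "ref")) {
  format <- match.arg(format)
  donor_allele <- match.arg(donor_allele)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  if (format == "tsv") {
    d <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "donor_reads", "total_reads", "bulk")
    if (!all(need %in% names(d)))
      stop("variant TSV must have columns chrom, pos, donor_reads, total_reads, bulk",
           call. = FALSE)
    if (any(d$donor_reads < 0) || any(d$donor_reads > d$total_reads))
      stop("need 0 <= donor_reads <= total_reads", call. = FALSE)
    d$marker <- paste0(d$chrom, "_", d$pos)
    d$is_indel <- FALSE
    return(lapply(split(d, d$bulk), function(x) {
      x <- x[order(x$chrom, x$pos),
             c("marker", "chrom", "pos", "donor_reads", "total_reads",
               "is_indel")]
      rownames(x) <- NULL
      x
    }))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(v@gt) == 0 || ncol(v@gt) < 2)
    stop("VCF must carry at least one sample (bulk)", call. = FALSE)
  if (!any(grepl("AD", v@gt[, "FORMAT"])))
    stop("VCF FORMAT lacks the AD (allele depth) field", call. = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  if (any(grepl(",", alt)))
    stop(sprintf("multiallelic record at %s:%s not supported",
                 fix[which(grepl(",", alt))[1], "CHROM"],
                 fix[which(grepl(",", alt))[1], "POS"]), call. = FALSE)
  is_indel <- nchar(ref) != 1 | nchar(alt) != 1
  bulks <- colnames(ad)
  out <- lapply(bulks, function(b) {
    parts <- strsplit(ad[, b], ",", fixed = TRUE)
    bad <- vapply(parts, function(p) length(p) != 2 || anyNA(suppressWarnings(
      as.integer(p))), logical(1))
    if (any(bad))
      stop(sprintf("missing or malformed AD for sample %s at %s:%s",
                   b, fix[which(bad)[1], "CHROM"], fix[which(bad)[1], "POS"]),
           call. = FALSE)
    ref_d <- vapply(parts, function(p) as.integer(p[1]), integer(1))
    alt_d <- vapply(parts, function(p) as.integer(p[2]), integer(1))
    donor <- if (donor_allele == "alt") alt_d else ref_d
    d <- data.frame(marker = paste0(fix[, "CHROM"], "_", fix[, "POS"]),
                    chrom = fix[, "CHROM"],
                    pos = as.numeric(fix[, "POS"]),
                    donor_reads = donor,
                    total_reads = ref_d + alt_d,
                    is_indel = is_indel,
                    stringsAsFactors = FALSE)
    d <- d[order(d$chrom, d$pos), ]
    rownames(d) <- NULL
    d
  })
  names(out) <- bulks
  out
}

#' Write a window track as bedGraph-style TSV
#'
#' Columns `chrom start end freq n_snps`, 0-based half-open intervals,
#' undefined frequencies written as `NA`.
#'
#' @param track A `window_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_window_track <- function(track, path) {
  stopifnot(inherits(track, "window_track"))
  d <- data.frame(chrom = track$chrom,
                  start = format(track$start, scientific = FALSE, trim = TRUE),
                  end = format(track$end, scientific = FALSE, trim = TRUE),
                  freq = ifelse(is.na(track$freq), "NA",
                                formatC(track$freq, digits = 6,
                                        format = "g")),
                  n_snps = track$n_snps, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Write candidate regions as BED
#'
#' BED5 (`chrom start end name score`), 0-based half-open. The name
#' encodes the evidence source and a per-file index
#' (e.g. `MBS_1`, `both_2`); the score is 0. Unsorted input is sorted
#' with a warning. `write -> read -> write` is byte-identical.
#'
#' @param regions A `candidate_regions` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  stopifnot(is.data.frame(regions))
  if (nrow(regions) > 0) {
    ord <- order(regions$chrom, regions$start, regions$end)
    if (!identical(ord, seq_len(nrow(regions)))) {
      warning("regions were unsorted; sorting before writing", call. = FALSE)
      regions <- regions[ord, , drop = FALSE]
    }
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tname\tscore", con)
  if (nrow(regions) > 0) {
    name <- paste0(regions$evidence, "_", seq_len(nrow(regions)))
    writeLines(sprintf("%s\t%s\t%s\t%s\t0", regions$chrom,
                       .format_bp(regions$start), .format_bp(regions$end),
                       name), con)
  }
  invisible(path)
}

#' Read a candidate-region BED written by [write_regions_bed()]
#'
#' @param path File path.
#' @return `candidate_regions` data.frame with columns `chrom`, `start`,
#'   `end`, `evidence`.
#' @export
read_regions_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), evidence = character(),
                      stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) < 4))
      stop("malformed BED line", call. = FALSE)
    out <- data.frame(
      chrom = vapply(parts, `[`, "", 1),
      start = as.numeric(vapply(parts, `[`, "", 2)),
      end = as.numeric(vapply(parts, `[`, "", 3)),
      evidence = sub("_[0-9]+$", "", vapply(parts, `[`, "", 4)),
      stringsAsFactors = FALSE)
  }
  class(out) <- c("candidate_regions", "data.frame")
  out
}
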