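# Seeded simulator of the genetic designs the analysis assumes: an
# interspecific F2, and backcross-derived near-isogenic lines (NILs) whose
# selfed progeny supply the recessive and segregating sequencing bulks.
# Haplotypes are 0/1 vectors (1 = donor-parent allele) over the marker
# map; meiosis uses a Haldane map (Poisson crossovers, uniform positions,
# no interference) at a constant cM/Mb rate.

#' Simulated genome
#'
#' A set of chromosomes with a regular marker grid and a constant
#' physical-to-genetic map rate. Defaults emulate an allotetraploid cotton
#' frame: 26 chromosomes (A01-A13, D01-D13) of 60 Mb with one marker per
#' 250 kb (6240 markers, the order of magnitude of a polymorphic SNP-array
#' set).
#'
#' @param n_chrom Number of chromosomes (default 26).
#' @param chrom_length Chromosome length in bp (default 60e6; scalar or
#'   one per chromosome).
#' @param marker_spacing Regular marker spacing in bp (default 250e3).
#' @param cm_per_mb Map rate in centiMorgan per megabase (default 1).
#' @return List of class `sim_genome`: `chrom_lengths` (named), `markers`
#'   (a [marker_map()]), `cm_per_mb`, and a per-chromosome marker index.
#' @export
sim_genome <- function(n_chrom = 26, chrom_length = 60e6,
                       marker_spacing = 250e3, cm_per_mb = 1) {
  if (n_chrom < 1 || any(chrom_length <= 0) || marker_spacing <= 0 ||
      cm_per_mb <= 0)
    stop("genome dimensions must be positive", call. = FALSE)
  labels <- if (n_chrom <= 26) {
    c(sprintf("A%02d", 1:13), sprintf("D%02d", 1:13))[seq_len(n_chrom)]
  } else sprintf("C%03d", seq_len(n_chrom))
  lens <- rep_len(chrom_length, n_chrom)
  names(lens) <- labels
  pos_list <- lapply(labels, function(cn)
    seq(marker_spacing, lens[[cn]], by = marker_spacing))
  mm <- marker_map(
    marker = unlist(lapply(seq_along(labels), function(i)
      paste0(labels[i], "_", format(pos_list[[i]], scientific = FALSE,
                                    trim = TRUE)))),
    chrom = rep(labels, lengths(pos_list)),
    pos = unlist(pos_list))
  structure(list(chrom_lengths = lens, markers = mm, cm_per_mb = cm_per_mb,
                 chrom_index = split(seq_len(nrow(mm)), mm$chrom)),
            class = "sim_genome")
}

#' Causal model of the fuzz phenotype
#'
#' Loci have one of three roles. `required_recessive` loci gate the
#' near-zero mutant phenotype: an individual homozygous donor at every
#' required locus (and passing a penetrance draw) is fuzzless, with
#' residual fuzz drawn as `|N(residual_mean, residual_sd)|`. Outside that
#' gate, fuzz is `baseline_fuzz` plus per-donor-copy `effect` contributions
#' of `required_recessive` and `additive_major` loci, plus the `effect` of
#' each `enhancer` locus when donor-homozygous, plus `N(0, noise_sd)`,
#' truncated to `[0, 100]`.
#'
#' @param loci `data.frame` with columns `locus`, `chrom`, `pos`, `role`
#'   (one of `required_recessive`, `additive_major`, `enhancer`), `effect`
#'   (fuzz-percentage points; per donor copy for required/additive roles,
#'   per donor-homozygous genotype for enhancers).
#' @param baseline_fuzz Mean fuzz percentage without donor alleles
#'   (default 11, a normal-fuzz cultivar).
#' @param noise_sd Phenotype noise standard deviation (default 1.5).
#' @param penetrance Probability that the full required-recessive genotype
#'   expresses the fuzzless phenotype (default 1).
#' @param residual_mean,residual_sd Parameters of the half-normal residual
#'   fuzz of fuzzless individuals (defaults 0.7 and 0.4, near the low end
#'   of fuzz measured on fuzzless-donor accessions).
#' @return List of class `causal_model`.
#' @export
causal_model <- function(loci, baseline_fuzz = 11, noise_sd = 1.5,
                         penetrance = 1, residual_mean = 0.7,
                         residual_sd = 0.4) {
  stopifnot(is.data.frame(loci),
            all(c("locus", "chrom", "pos", "role", "effect") %in% names(loci)))
  if (!all(loci$role %in% c("required_recessive", "additive_major",
                            "enhancer")))
    stop("unknown locus role", call. = FALSE)
  if (any(!is.finite(loci$effect)))
    stop("locus effects must be finite", call. = FALSE)
  if (penetrance <= 0 || penetrance > 1)
    stop("penetrance must be in (0, 1]", call. = FALSE)
  if (baseline_fuzz < 0 || baseline_fuzz > 100)
    stop("baseline_fuzz must be in [0, 100]", call. = FALSE)
  structure(list(loci = loci, baseline_fuzz = baseline_fuzz,
                 noise_sd = noise_sd, penetrance = penetrance,
                 residual_mean = residual_mean, residual_sd = residual_sd),
            class = "causal_model")
}

#' Default five-locus causal model of the donor fuzzless trait
#'
#' Three required recessive loci (III-V), of which locus V carries a major
#' additive per-copy effect; one enhancer locus (I) whose donor allele
#' increases fuzz; and one non-required additive modifier (II). Five loci
#' on five different chromosomes, matching the multilocus architecture the
#' package is designed to dissect: a three-recessive-gene segregation
#' expectation (63:1), an additive major locus with intermediate
#' heterozygotes, an enhancer, and weaker modifiers.
#'
#' @param ... Overrides passed to [causal_model()].
#' @return A [causal_model()].
#' @export
ps_causal_model <- function(...) {
  loci <- data.frame(
    locus = c("locus_I", "locus_II", "locus_III", "locus_IV", "locus_V"),
    chrom = c("A08", "A10", "D07", "D11", "D12"),
    pos = c(30e6, 30e6, 30e6, 30e6, 30e6),
    role = c("enhancer", "additive_major", "required_recessive",
             "required_recessive", "required_recessive"),
    effect = c(3, -1.5, 0, 0, -2.5),
    stringsAsFactors = FALSE)
  causal_model(loci, ...)
}

# --- haplotype plumbing ------------------------------------------------

.founder <- function(genome, allele) {
  h <- rep(as.numeric(allele), nrow(genome$markers))
  list(h1 = h, h2 = h)
}

.gamete_chrom <- function(h1, h2, pos, len_bp, len_morgan) {
  n_xo <- stats::rpois(1, len_morgan)
  start <- sample.int(2L, 1L)
  if (n_xo == 0) {
    return(if (start == 1L) h1 else h2)
  }
  xo <- sort(stats::runif(n_xo, 0, len_bp))
  seg <- findInterval(pos, xo)
  use_h1 <- ((seg + start) %% 2L) == 1L
  ifelse(use_h1, h1, h2)
}

#' Simulate one gamete of an individual
#'
#' Meiosis under the Haldane model: per chromosome, the crossover count is
#' Poisson with mean equal to the chromosome's genetic length in Morgans
#' (`length_bp * cm_per_mb / 1e8`), crossover positions are uniform, and
#' there is no interference. Chromosomes assort independently.
#'
#' @param parent List with haplotype vectors `h1` and `h2` over the
#'   genome's markers.
#' @param genome A [sim_genome()].
#' @return Numeric haplotype vector (one allele per marker).
#' @export
simulate_gamete <- function(parent, genome) {
  stopifnot(inherits(genome, "sim_genome"))
  nm <- nrow(genome$markers)
  if (length(parent$h1) != nm || length(parent$h2) != nm)
    stop("parental haplotypes must cover all markers", call. = FALSE)
  g <- numeric(nm)
  for (cn in names(genome$chrom_lengths)) {
    idx <- genome$chrom_index[[cn]]
    len_bp <- genome$chrom_lengths[[cn]]
    len_morgan <- len_bp * genome$cm_per_mb / 1e6 / 100
    g[idx] <- .gamete_chrom(parent$h1[idx], parent$h2[idx],
                            genome$markers$pos[idx], len_bp, len_morgan)
  }
  g
}

.cross <- function(p1, p2, genome) {
  list(h1 = simulate_gamete(p1, genome), h2 = simulate_gamete(p2, genome))
}

.codes_of <- function(ind) (ind$h1 + ind$h2) / 2

.causal_marker_ids <- function(genome, model) {
  key <- paste(model$loci$chrom, model$loci$pos)
  idx <- match(key, paste(genome$markers$chrom, genome$markers$pos))
  if (any(is.na(idx)))
    stop("causal loci must lie on simulated marker positions", call. = FALSE)
  stats::setNames(genome$markers$marker[idx], model$loci$locus)
}

#' Phenotypes from causal genotype codes
#'
#' Applies the [causal_model()] phenotype rule to a matrix of genotype
#' codes at the causal loci (individuals in rows, loci in model order).
#'
#' @param causal_codes Numeric matrix (or vector for one individual) of
#'   codes in `{0, 0.5, 1}` at the causal loci.
#' @param model A [causal_model()].
#' @param ids Individual ids (default `ind1..indN`).
#' @param cutoffs Fuzz-class cut-offs for the derived class.
#' @return A [phenotype_table()].
#' @export
phenotype_from_genotype <- function(causal_codes, model,
                                    ids = NULL,
                                    cutoffs = default_fuzz_cutoffs()) {
  stopifnot(inherits(model, "causal_model"))
  if (is.null(dim(causal_codes)))
    causal_codes <- matrix(causal_codes, nrow = 1)
  if (ncol(causal_codes) != nrow(model$loci))
    stop("causal_codes columns must match model loci", call. = FALSE)
  if (any(is.na(causal_codes)))
    stop("genotypes must be defined at all causal loci", call. = FALSE)
  n <- nrow(causal_codes)
  if (is.null(ids)) ids <- paste0("ind", seq_len(n))
  role <- model$loci$role
  eff <- model$loci$effect
  req <- role == "required_recessive"
  percopy <- role %in% c("required_recessive", "additive_major")
  # without any required locus there is no epistatic gate to satisfy
  gate <- if (any(req)) {
    rowSums(causal_codes[, req, drop = FALSE] == 1) == sum(req)
  } else rep(FALSE, n)
  gate <- gate & stats::runif(n) <= model$penetrance
  residual <- abs(stats::rnorm(n, model$residual_mean, model$residual_sd))
  copies <- 2 * causal_codes
  dose_eff <- as.numeric(copies[, percopy, drop = FALSE] %*% eff[percopy])
  enh_eff <- if (any(role == "enhancer")) {
    as.numeric((causal_codes[, role == "enhancer", drop = FALSE] == 1) %*%
                 eff[role == "enhancer"])
  } else 0
  quant <- model$baseline_fuzz + dose_eff + enh_eff +
    stats::rnorm(n, 0, model$noise_sd)
  fuzz <- ifelse(gate, residual, quant)
  fuzz <- pmin(pmax(fuzz, 0), 100)
  phenotype_table(ids, fuzz, cutoffs = cutoffs)
}

.population <- function(inds, genome, model, ids, meta = NULL,
                        cutoffs = default_fuzz_cutoffs()) {
  codes <- do.call(rbind, lapply(inds, .codes_of))
  gm <- genotype_matrix(genome$markers, codes, ids)
  causal_ids <- .causal_marker_ids(genome, model)
  phenos <- phenotype_from_genotype(gm$codes[, causal_ids, drop = FALSE],
                                    model, ids = ids, cutoffs = cutoffs)
  structure(list(genotypes = gm, phenotypes = phenos, meta = meta,
                 causal_markers = causal_ids, genome = genome,
                 model = model),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("sim_population: %d individuals, %d markers, %d causal loci\n",
              length(x$genotypes$individuals), nrow(x$genotypes$markers),
              length(x$causal_markers)))
  print(table(x$phenotypes$fuzz_class))
  invisible(x)
}

#' Simulate an F2 population
#'
#' Selfs the F1 of a donor x recurrent cross: each F2 plant is the union
#' of two independent F1 gametes. Phenotypes follow the causal model.
#'
#' @param genome A [sim_genome()].
#' @param model A [causal_model()]; its loci must sit on marker positions.
#' @param n Population size (default 169).
#' @param seed Optional integer seed for reproducibility.
#' @param cutoffs Fuzz-class cut-offs.
#' @return A `sim_population`: list with `genotypes`
#'   (a [genotype_matrix()]), `phenotypes` (a [phenotype_table()]),
#'   `causal_markers` (named marker ids), `genome`, `model`.
#' @export
simulate_f2 <- function(genome, model, n = 169, seed = NULL,
                        cutoffs = default_fuzz_cutoffs()) {
  if (!is.null(seed)) set.seed(seed)
  if (n < 1) stop("population size must be >= 1", call. = FALSE)
  f1 <- list(h1 = .founder(genome, 1)$h1, h2 = .founder(genome, 0)$h1)
  inds <- lapply(seq_len(n), function(i) .cross(f1, f1, genome))
  .population(inds, genome, model, paste0("F2_", seq_len(n)),
              cutoffs = cutoffs)
}

# Draw gametes from `parent` until one carries the donor allele at every
# causal marker index; used for marker-assisted backcrossing.
.gamete_with_donor <- function(parent, genome, causal_idx, max_tries) {
  for (i in seq_len(max_tries)) {
    g <- simulate_gamete(parent, genome)
    if (all(g[causal_idx] == 1)) return(g)
  }
  stop(sprintf("no gamete carrying all donor alleles in %d tries", max_tries),
       call. = FALSE)
}

# One backcross-then-self line. type "fuzzless": selfing fixes the donor
# allele at every causal locus (one additional homozygous locus required
# per generation, never losing a donor allele). type "segregating":
# selfing retains heterozygosity at every causal locus.
.develop_line <- function(genome, causal_idx, n_backcrosses, n_selfs, type,
                          max_tries) {
  donor <- .founder(genome, 1)
  recurrent <- .founder(genome, 0)
  carrier <- .cross(donor, recurrent, genome)
  for (b in seq_len(n_backcrosses)) {
    g <- .gamete_with_donor(carrier, genome, causal_idx, max_tries)
    carrier <- list(h1 = g, h2 = simulate_gamete(recurrent, genome))
  }
  cur <- carrier
  for (s in seq_len(n_selfs)) {
    cc <- .codes_of(cur)[causal_idx]
    if (type == "fuzzless" && all(cc == 1)) {
      cur <- .cross(cur, cur, genome)
      next
    }
    target_hom <- if (type == "fuzzless") sum(cc == 1) + 1L else NA
    found <- FALSE
    for (i in seq_len(max_tries)) {
      off <- .cross(cur, cur, genome)
      oc <- .codes_of(off)[causal_idx]
      ok <- if (type == "fuzzless") {
        all(oc >= 0.5) && sum(oc == 1) >= min(target_hom, length(causal_idx))
      } else {
        all(oc == 0.5)
      }
      if (ok) { cur <- off; found <- TRUE; break }
    }
    if (!found)
      stop(sprintf("line development failed: no acceptable %s offspring in %d tries",
                   type, max_tries), call. = FALSE)
  }
  if (type == "fuzzless" && !all(.codes_of(cur)[causal_idx] == 1))
    stop("fuzzless line not fixed at all causal loci after selfing",
         call. = FALSE)
  cur
}

#' Simulate NIL lines and their selfed progeny
#'
#' Develops near-isogenic lines by `n_backcrosses` backcrosses to the
#' recurrent parent with marker-assisted retention of at least one donor
#' allele at every causal locus, followed by `n_selfs` selfing
#' generations. Fuzzless lines are driven to homozygosity for the donor
#' allele at every causal locus; segregating lines are kept heterozygous
#' at every causal locus. Each line then contributes `progeny_per_line`
#' unselected selfed progeny; these progeny populations are what the
#' sequencing bulks are drawn from.
#'
#' Marker-assisted retention stands in for the phenotypic selection used
#' in real line development; it is reproducible and yields the same
#' endpoint (homozygous-donor vs segregating causal loci in a
#' recurrent-parent background).
#'
#' @param genome A [sim_genome()].
#' @param model A [causal_model()].
#' @param n_backcrosses Backcross generations (default 4).
#' @param n_selfs Selfing generations after backcrossing (default 5).
#' @param n_fuzzless_lines,n_segregating_lines Number of independent lines
#'   of each type (defaults 6 and 4).
#' @param progeny_per_line Selfed progeny per line (default 10).
#' @param max_tries Retry bound for each marker-assisted selection step
#'   (default 1000).
#' @param seed Optional integer seed.
#' @param cutoffs Fuzz-class cut-offs.
#' @return A `sim_population` over all progeny, with `meta` columns
#'   `individual`, `line`, `line_type` (`"fuzzless"`/`"segregating"`).
#' @export
simulate_nil_lines <- function(genome, model, n_backcrosses = 4,
                               n_selfs = 5, n_fuzzless_lines = 6,
                               n_segregating_lines = 4,
                               progeny_per_line = 10, max_tries = 1000,
                               seed = NULL,
                               cutoffs = default_fuzz_cutoffs()) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(genome, "sim_genome"), inherits(model, "causal_model"))
  causal_idx <- match(.causal_marker_ids(genome, model),
                      genome$markers$marker)
  types <- c(rep("fuzzless", n_fuzzless_lines),
             rep("segregating", n_segregating_lines))
  line_names <- c(sprintf("FLN%d", seq_len(n_fuzzless_lines)),
                  sprintf("SEG%d", seq_len(n_segregating_lines)))
  inds <- list()
  ids <- character()
  meta <- list()
  for (li in seq_along(types)) {
    nil <- .develop_line(genome, causal_idx, n_backcrosses, n_selfs,
                         types[li], max_tries)
    for (p in seq_len(progeny_per_line)) {
      off <- .cross(nil, nil, genome)
      id <- sprintf("%s_p%02d", line_names[li], p)
      inds[[length(inds) + 1]] <- off
      ids <- c(ids, id)
      meta[[length(meta) + 1]] <- data.frame(
        individual = id, line = line_names[li], line_type = types[li],
        stringsAsFactors = FALSE)
    }
  }
  .population(inds, genome, model, ids, meta = do.call(rbind, meta),
              cutoffs = cutoffs)
}

#' Draw a sequencing bulk from a simulated population
#'
#' `recessive_bulk` samples only fuzzless-class individuals (all of which,
#' under full penetrance, are homozygous donor at every required locus).
#' `segregating_bulk` samples progeny of parents heterozygous at the
#' causal loci regardless of phenotype: in a NIL population these are the
#' progeny of segregating lines; in an F2 every plant qualifies (the F1
#' parent is heterozygous everywhere).
#'
#' @param pop A `sim_population` from [simulate_f2()] or
#'   [simulate_nil_lines()].
#' @param design `"recessive_bulk"` or `"segregating_bulk"`.
#' @param size Bulk size; defaults mirror a 15-member recessive and a
#'   24-member segregating bulk.
#' @return Character vector of sampled individual ids.
#' @export
build_bulk <- function(pop, design = c("recessive_bulk", "segregating_bulk"),
                       size = NULL) {
  design <- match.arg(design)
  stopifnot(inherits(pop, "sim_population"))
  if (is.null(size)) size <- if (design == "recessive_bulk") 15 else 24
  eligible <- if (design == "recessive_bulk") {
    pop$phenotypes$individual[!is.na(pop$phenotypes$fuzz_class) &
                                pop$phenotypes$fuzz_class == "fuzzless"]
  } else if (!is.null(pop$meta) && "line_type" %in% names(pop$meta)) {
    pop$meta$individual[pop$meta$line_type == "segregating"]
  } else {
    pop$phenotypes$individual
  }
  if (length(eligible) < size)
    stop(sprintf("cannot build %s of size %d: only %d eligible individual(s)",
                 design, size, length(eligible)), call. = FALSE)
  sample(eligible, size)
}

#' Simulate pooled sequencing counts for a bulk
#'
#' Per marker, total coverage is Poisson(`depth`) and donor reads are
#' binomial with success probability `p * (1 - error_rate) + (1 - p) *
#' error_rate`, where `p` is the bulk's mean genotype code (its true
#' donor-allele frequency). Markers where every bulk member is missing
#' yield `NA` frequency and zero reads.
#'
#' @param gm A [genotype_matrix()].
#' @param individuals Ids of the bulk members.
#' @param depth Mean read coverage (default 30).
#' @param error_rate Per-read allele error rate in `[0, 0.5)` (default 0).
#' @param seed Optional integer seed.
#' @return `data.frame` with `marker`, `chrom`, `pos`, `donor_reads`,
#'   `total_reads`.
#' @export
simulate_pool_counts <- function(gm, individuals, depth = 30,
                                 error_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(gm, "genotype_matrix"))
  if (depth <= 0) stop("depth must be > 0", call. = FALSE)
  if (error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must be in [0, 0.5)", call. = FALSE)
  freqs <- array_pool_frequencies(gm, individuals)
  nm <- nrow(freqs)
  cov <- stats::rpois(nm, depth)
  p_read <- freqs$freq * (1 - error_rate) + (1 - freqs$freq) * error_rate
  donor <- integer(nm)
  ok <- !is.na(p_read) & cov > 0
  donor[ok] <- stats::rbinom(sum(ok), cov[ok], p_read[ok])
  cov[is.na(p_read)] <- 0L
  data.frame(marker = freqs$marker, chrom = freqs$chrom, pos = freqs$pos,
             donor_reads = as.integer(donor), total_reads = as.integer(cov),
             stringsAsFactors = FALSE)
}
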