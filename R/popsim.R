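#' Simulate a structured multi-population SNP cohort
#'
#' Balding-Nichols model: each SNP draws an ancestral allele frequency
#' `p ~ Uniform(ancestral_maf_range)`; each population then draws its own
#' frequency from `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` with `F = fst`,
#' so per-population frequencies scatter around `p` with variance
#' `p (1 - p) F`. Genotypes are `Binomial(ploidy, pop frequency)` and SNPs
#' are independent (no linkage disequilibrium) — the regime DAPC expects
#' after LD pruning. Missing calls are masked uniformly at `missing_rate`.
#'
#' Defaults mirror a miniature malaria-parasite-style job: 4 populations,
#' 50 samples each, 1000 SNPs, FST 0.1, diploid (set `ploidy = 1` for
#' haploid parasites).
#'
#' @param n_populations number of populations (>= 1; >= 2 for any supervised
#'   use).
#' @param samples_per_population samples per population (scalar or
#'   per-population vector).
#' @param n_snps number of biallelic SNPs.
#' @param fst differentiation parameter, strictly inside (0, 1).
#' @param ancestral_maf_range interval within (0, 0.5] for the ancestral
#'   allele frequency draw.
#' @param ploidy 1 or 2 (or higher; dosages are binomial counts).
#' @param missing_rate per-call missingness probability in `[0, 1)`.
#' @param seed RNG seed; the whole cohort is reproducible from it.
#' @return Object of class `simulated_cohort`: `genotypes`
#'   ([genotype_matrix()]), `true_labels` ([sample_labels()], populations
#'   `pop_1 ...`), `pop_freqs` (populations x SNPs allele-frequency matrix),
#'   `spec` (the arguments, for provenance).
#' @examples
#' cohort <- simulate_cohort(n_populations = 2, samples_per_population = 10,
#'                           n_snps = 50, seed = 42)
#' cohort$genotypes
#' @export
simulate_cohort <- function(n_populations = 4L, samples_per_population = 50L,
                            n_snps = 1000L, fst = 0.1,
                            ancestral_maf_range = c(0.05, 0.5), ploidy = 2L,
                            missing_rate = 0, seed = 1L) {
  n_populations <- as.integer(n_populations)
  n_snps <- as.integer(n_snps)
  ploidy <- as.integer(ploidy)
  if (n_populations < 1L || n_snps < 1L || ploidy < 1L) {
    stop("counts must be positive")
  }
  if (!(fst > 0 && fst < 1)) stop("fst must lie strictly inside (0, 1)")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  lo <- ancestral_maf_range[1]; hi <- ancestral_maf_range[2]
  if (!(lo > 0 && hi <= 0.5 && lo <= hi)) {
    stop("ancestral_maf_range must be an interval within (0, 0.5]")
  }
  sizes <- rep_len(as.integer(samples_per_population), n_populations)
  if (any(sizes < 1L)) stop("samples_per_population must be positive")
  n <- sum(sizes)
  pop_of <- rep.int(seq_len(n_populations), sizes)

  sim <- withr::with_seed(as.integer(seed), {
    p_anc <- stats::runif(n_snps, lo, hi)
    shape <- (1 - fst) / fst
    pf <- matrix(stats::rbeta(n_populations * n_snps,
                              rep(p_anc * shape, each = n_populations),
                              rep((1 - p_anc) * shape, each = n_populations)),
                 nrow = n_populations)
    # numerical guard: Beta draws can underflow to exactly 0/1; keep them valid
    d <- matrix(stats::rbinom(n * n_snps, ploidy, pf[pop_of, ]), nrow = n)
    mask <- if (missing_rate > 0) {
      which(matrix(stats::runif(n * n_snps) < missing_rate, nrow = n),
            arr.ind = TRUE)
    } else NULL
    list(p_anc = p_anc, pf = pf, d = d, mask = mask)
  })
  d <- sim$d
  if (!is.null(sim$mask)) d[sim$mask] <- 0L  # masked entries hold no dosage
  ids <- sprintf("pop%d_ind%03d", pop_of,
                 unlist(lapply(sizes, seq_len)))
  vids <- sprintf("1:%d:A:T", seq_len(n_snps))
  G <- genotype_matrix(d, sample_ids = ids, variant_ids = vids,
                       missing_mask = sim$mask, ploidy = ploidy)
  structure(
    list(genotypes = G,
         true_labels = sample_labels(ids, sprintf("pop_%d", pop_of)),
         pop_freqs = sim$pf,
         ancestral_freqs = sim$p_anc,
         spec = list(n_populations = n_populations,
                     samples_per_population = sizes, n_snps = n_snps,
                     fst = fst, ancestral_maf_range = c(lo, hi),
                     ploidy = ploidy, missing_rate = missing_rate,
                     seed = as.integer(seed))),
    class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("<simulated_cohort> %d populations x %s samples, %d SNPs, FST %.3g, ploidy %d\n",
              x$spec$n_populations,
              paste(unique(x$spec$samples_per_population), collapse = "/"),
              x$spec$n_snps, x$spec$fst, x$spec$ploidy))
  invisible(x)
}

#' Write a simulated cohort (or genotype matrix) as VCF
#'
#' Emits a valid VCF 4.2 with GT-only FORMAT fields. Diploid dosages map to
#' `0/0`, `0/1`, `1/1`; haploid to `0` / `1`; missing calls to `./.` (or `.`
#' for haploids). Simulation provenance is recorded in the header. A `.gz`
#' suffix triggers gzip compression.
#'
#' @param cohort a `simulated_cohort` or a [genotype_matrix()].
#' @param path output path (`.vcf` or `.vcf.gz`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(cohort, path) {
  G <- if (inherits(cohort, "simulated_cohort")) cohort$genotypes else cohort
  stopifnot(inherits(G, "genotype_matrix"))
  if (!G$ploidy %in% c(1L, 2L)) stop("VCF writing supports ploidy 1 or 2")
  d <- as.matrix(G$dosages)
  d[as.matrix(G$missing_mask)] <- NA_integer_
  gt_codes <- if (G$ploidy == 2L) c("0/0", "0/1", "1/1") else c("0", "1")
  miss_code <- if (G$ploidy == 2L) "./." else "."
  parts <- strsplit(G$variant_ids, ":", fixed = TRUE)
  full <- lengths(parts) == 4L
  chrom <- ifelse(full, vapply(parts, `[`, "", 1), "1")
  pos <- ifelse(full, vapply(parts, `[`, "", 2), as.character(seq_along(parts)))
  ref <- ifelse(full, vapply(parts, `[`, "", 3), "A")
  alt <- ifelse(full, vapply(parts, `[`, "", 4), "T")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=dapcr",
    if (inherits(cohort, "simulated_cohort")) {
      sprintf("##dapcr_simulation=%s",
              jsonlite::toJSON(cohort$spec, auto_unbox = TRUE))
    },
    sprintf("##contig=<ID=%s>", unique(chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", G$sample_ids), collapse = "\t"))
  gt <- matrix(miss_code, nrow = nrow(d), ncol = ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gt_codes[d[ok] + 1L]
  body <- vapply(seq_len(ncol(d)), function(j) {
    paste(c(chrom[j], pos[j], G$variant_ids[j], ref[j], alt[j], ".", "PASS",
            ".", "GT", gt[, j]), collapse = "\t")
  }, character(1))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con), add = TRUE)
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Hudson-style FST estimate from a labelled cohort
#'
#' For each SNP and each pair of populations, computes the Hudson estimator
#' numerator `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' denominator `p1(1-p2) + p2(1-p1)`, where `p` are sample allele frequencies
#' and `n` allele counts over observed calls. Per-SNP values sum numerators
#' and denominators over pairs; the mean estimate is the ratio of sums over
#' SNPs and pairs (the recommended ratio-of-averages form, robust to
#' low-frequency SNPs). SNPs with zero total denominator (monomorphic) are
#' skipped with a reported count.
#'
#' @param cohort a `simulated_cohort`, or a [genotype_matrix()] when `labels`
#'   is supplied.
#' @param labels population labels (ignored for a `simulated_cohort`).
#' @return list with `mean` (overall FST), `per_snp` (named vector, `NA` for
#'   skipped SNPs), `n_skipped`.
#' @export
estimate_fst <- function(cohort, labels = NULL) {
  if (inherits(cohort, "simulated_cohort")) {
    G <- cohort$genotypes
    y <- cohort$true_labels$label
  } else {
    G <- cohort
    stopifnot(inherits(G, "genotype_matrix"))
    if (is.null(labels)) stop("labels are required for a plain genotype matrix")
    y <- resolve_labels(labels, G$sample_ids)
  }
  pops <- sort(unique(y))
  if (length(pops) < 2L) stop("FST needs at least two populations")
  m <- ncol(G$dosages)
  ac <- matrix(0, length(pops), m)  # alt allele counts
  an <- matrix(0, length(pops), m)  # observed allele totals
  for (i in seq_along(pops)) {
    rows <- which(y == pops[i])
    ac[i, ] <- as.numeric(Matrix::colSums(G$dosages[rows, , drop = FALSE]))
    an[i, ] <- G$ploidy *
      (length(rows) - as.numeric(Matrix::colSums(G$missing_mask[rows, , drop = FALSE])))
  }
  p <- ac / an
  num <- den <- numeric(m)
  for (i in seq_len(length(pops) - 1L)) {
    for (j in seq(i + 1L, length(pops))) {
      p1 <- p[i, ]; p2 <- p[j, ]
      n1 <- an[i, ]; n2 <- an[j, ]
      num <- num + (p1 - p2)^2 - p1 * (1 - p1) / pmax(n1 - 1, 1) -
        p2 * (1 - p2) / pmax(n2 - 1, 1)
      den <- den + p1 * (1 - p2) + p2 * (1 - p1)
    }
  }
  usable <- is.finite(num) & is.finite(den) & den > 0
  per_snp <- rep(NA_real_, m)
  per_snp[usable] <- num[usable] / den[usable]
  names(per_snp) <- G$variant_ids
  n_skipped <- sum(!usable)
  if (n_skipped > 0L) {
    message(sprintf("estimate_fst: skipped %d monomorphic/unusable SNP(s)", n_skipped))
  }
  list(mean = sum(num[usable]) / sum(den[usable]), per_snp = per_snp,
       n_skipped = n_skipped)
}
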