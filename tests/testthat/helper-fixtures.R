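# Shared fixtures, all built in code at test time.

# small default cohort used across modules
tiny_cohort <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_populations = 3L, samples_per_population = 12L, n_snps = 120L,
         fst = 0.15, missing_rate = 0, seed = seed),
    list(...))
  do.call(simulate_cohort, args)
}

# hand-written 3-sample VCF covering the GT encoding corner cases
write_hand_vcf <- function(path, extra_records = character(0)) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("1", "100", "v1", "A", "T", ".", "PASS", ".", "GT:DP",
          "0/0:9", "0/1:8", "1/1:7", sep = "\t"),
    paste("1", "200", "v2", "C", "G", ".", "PASS", ".", "GT:DP",
          "0|1:5", "./.:1", "./1:2", sep = "\t"),
    extra_records)
  writeLines(lines, path)
  path
}

# gaussian blob scores with known group structure
blob_scores <- function(k = 3, n_per = 20, r = 5, sep = 10, sd = 0.5, seed = 1) {
  withr::with_seed(seed, {
    centers <- matrix(rnorm(k * r), k, r) * sep
    S <- do.call(rbind, lapply(seq_len(k), function(c_) {
      sweep(matrix(rnorm(n_per * r, sd = sd), n_per, r), 2, centers[c_, ], "+")
    }))
    rownames(S) <- sprintf("s%03d", seq_len(k * n_per))
    list(scores = S, labels = rep(sprintf("grp%d", seq_len(k)), each = n_per))
  })
}

# best one-to-one matching agreement between cluster assignments and truth
matched_agreement <- function(assignments, truth) {
  a <- as.integer(factor(assignments))
  b <- as.integer(factor(truth))
  ka <- max(a); kb <- max(b)
  tab <- table(factor(a, levels = seq_len(ka)), factor(b, levels = seq_len(kb)))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }), recursive = FALSE)
  }
  stopifnot(ka <= 6)  # brute-force matching only for small k
  best <- 0
  for (p in perms(seq_len(max(ka, kb)))) {
    hit <- sum(vapply(seq_len(ka), function(i) {
      j <- p[i]
      if (j <= kb) tab[i, j] else 0
    }, numeric(1)))
    best <- max(best, hit)
  }
  best / length(truth)
}
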