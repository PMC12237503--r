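#' Encode VCF GT calls as alternate-allele dosages
#'
#' Counts alternate alleles in a GT string (phased `|` or unphased `/`
#' separators). Any `.` allele makes the whole call missing — half-calls such
#' as `./1` are ambiguous dosages and are treated as missing. Allele indices
#' above `max_allele` (multiallelic residue) also yield missing, never a
#' miscoded dosage.
#'
#' @param gt character vector of GT fields, e.g. `"0/1"`, `"1|1"`, `"."`.
#' @param ploidy expected maximum dosage; calls with more alleles than
#'   `ploidy` are rejected.
#' @param max_allele largest allele index counted as alternate (1 for
#'   biallelic sites).
#' @return integer vector of dosages with `NA` for missing calls.
#' @examples
#' encode_genotype(c("0/0", "0|1", "1/1", "./.", "./1"))
#' encode_genotype("1", ploidy = 1)
#' @export
encode_genotype <- function(gt, ploidy = 2L, max_allele = 1L) {
  gt <- as.character(gt)
  ux <- unique(gt)
  enc1 <- function(g) {
    al <- strsplit(g, "[/|]", perl = TRUE)[[1]]
    if (length(al) == 0L || length(al) > ploidy) {
      stop(sprintf("GT call '%s' incompatible with ploidy %d", g, ploidy))
    }
    if (any(al == ".")) return(NA_integer_)
    ai <- suppressWarnings(as.integer(al))
    if (anyNA(ai)) stop(sprintf("malformed GT call '%s'", g))
    if (any(ai > max_allele)) return(NA_integer_)
    sum(ai > 0L)
  }
  code <- vapply(ux, enc1, integer(1))
  unname(code[match(gt, ux)])
}

#' Read a VCF into a sparse dosage matrix
#'
#' Streams the file chunk-wise (`chunk_size` variant records at a time) so peak
#' memory is proportional to one chunk plus the sparse accumulator, and builds
#' a [genotype_matrix()] of alternate-allele dosages from the GT field. Plain
#' and gzip/BGZF-compressed files are supported. The result is independent of
#' `chunk_size`.
#'
#' Multiallelic records are handled per `multiallelic`: `"drop"` (default)
#' removes them with a reported count; `"split"` expands each ALT allele into
#' a biallelic pseudo-variant whose dosage counts that allele only.
#'
#' @param path VCF or VCF.gz file path.
#' @param chunk_size number of variant records parsed per chunk (>= 1).
#' @param ploidy `NULL` to infer from the first non-missing call, or an
#'   explicit integer.
#' @param multiallelic policy for records with more than one ALT allele.
#' @return a [genotype_matrix()]; sample ids come from the `#CHROM` header
#'   line, variant ids are `chrom:pos:ref:alt`.
#' @export
read_vcf <- function(path, chunk_size = 10000L, ploidy = NULL,
                     multiallelic = c("drop", "split")) {
  multiallelic <- match.arg(multiallelic)
  chunk_size <- as.integer(chunk_size)
  if (is.na(chunk_size) || chunk_size < 1L) stop("chunk_size must be >= 1")
  if (!file.exists(path)) stop("cannot read VCF: file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con), add = TRUE)

  samples <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("not a VCF: no #CHROM header line in ", path)
    if (startsWith(line, "##")) next
    if (startsWith(line, "#CHROM")) {
      fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(fields) < 10L) stop("VCF has no sample columns")
      samples <- fields[-seq_len(9L)]
      break
    }
    stop("malformed VCF header in ", path)
  }
  n <- length(samples)

  acc_i <- list(); acc_j <- list(); acc_x <- list()
  mis_i <- list(); mis_j <- list()
  variant_ids <- character(0)
  n_multi_dropped <- 0L
  ploidy_seen <- ploidy
  jbase <- 0L

  repeat {
    lines <- readLines(con, n = chunk_size)
    if (length(lines) == 0L) break
    for (line in lines) {
      if (!nzchar(line) || startsWith(line, "#")) next
      f <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(f) != n + 9L) {
        stop(sprintf("VCF record with %d fields, expected %d", length(f), n + 9L))
      }
      alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
      multi <- length(alts) > 1L
      if (multi && multiallelic == "drop") {
        n_multi_dropped <- n_multi_dropped + 1L
        next
      }
      fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
      gt_pos <- match("GT", fmt)
      if (is.na(gt_pos)) stop("VCF record lacks GT in FORMAT at ", f[1], ":", f[2])
      cells <- f[-seq_len(9L)]
      gt <- if (length(fmt) == 1L) cells else {
        vapply(strsplit(cells, ":", fixed = TRUE),
               function(z) z[[gt_pos]], character(1))
      }
      if (is.null(ploidy_seen)) {
        first_called <- gt[!grepl(".", gt, fixed = TRUE)]
        ploidy_seen <- if (length(first_called)) {
          length(strsplit(first_called[[1]], "[/|]")[[1]])
        } else 2L
      }
      for (a in seq_along(alts)) {
        # for split records, dosage counts allele index a only
        d <- encode_allele_count(gt, a, ploidy_seen)
        jbase <- jbase + 1L
        variant_ids[jbase] <- paste(f[1], f[2], f[4], alts[a], sep = ":")
        nz <- which(!is.na(d) & d > 0L)
        ms <- which(is.na(d))
        if (length(nz)) {
          acc_i[[length(acc_i) + 1L]] <- nz
          acc_j[[length(acc_j) + 1L]] <- rep.int(jbase, length(nz))
          acc_x[[length(acc_x) + 1L]] <- d[nz]
        }
        if (length(ms)) {
          mis_i[[length(mis_i) + 1L]] <- ms
          mis_j[[length(mis_j) + 1L]] <- rep.int(jbase, length(ms))
        }
      }
    }
  }
  if (n_multi_dropped > 0L) {
    message(sprintf("read_vcf: dropped %d multiallelic record(s)", n_multi_dropped))
  }
  if (jbase == 0L) stop("empty input: VCF contains no usable variant records")
  D <- Matrix::sparseMatrix(i = unlist(acc_i), j = unlist(acc_j),
                            x = as.numeric(unlist(acc_x)),
                            dims = c(n, jbase))
  M <- Matrix::sparseMatrix(i = as.integer(unlist(mis_i)),
                            j = as.integer(unlist(mis_j)),
                            dims = c(n, jbase))
  genotype_matrix(D, sample_ids = samples, variant_ids = variant_ids,
                  missing_mask = M, ploidy = ploidy_seen %||% 2L)
}

# Dosage of allele index `a` in a vector of GT strings; NA for any call
# containing ".".
encode_allele_count <- function(gt, a, ploidy) {
  ux <- unique(gt)
  enc1 <- function(g) {
    al <- strsplit(g, "[/|]", perl = TRUE)[[1]]
    if (length(al) == 0L || length(al) > ploidy) {
      stop(sprintf("GT call '%s' incompatible with ploidy %d", g, ploidy))
    }
    if (any(al == ".")) return(NA_integer_)
    ai <- suppressWarnings(as.integer(al))
    if (anyNA(ai)) stop(sprintf("malformed GT call '%s'", g))
    sum(ai == a)
  }
  code <- vapply(ux, enc1, integer(1))
  unname(code[match(gt, ux)])
}

#' Read a PLINK 1 binary BED/BIM/FAM trio
#'
#' Decodes the SNP-major PLINK bit encoding (magic bytes `6c 1b 01`; per
#' sample two bits: `00` = homozygous A1, `01` = missing, `10` = heterozygous,
#' `11` = homozygous A2). Dosage is the count of the A1 allele, so a trio
#' written with A1 = ALT round-trips with [read_vcf()].
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim`, `.fam` must all exist.
#' @param ploidy dosage upper bound recorded on the matrix (PLINK stores
#'   diploid codes; haploid data coded as homozygotes may be read with
#'   `ploidy = 2`).
#' @return a [genotype_matrix()]; sample ids from FAM column 2, variant ids
#'   from BIM column 2.
#' @export
read_bed <- function(prefix, ploidy = 2L) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  missing_f <- paths[!file.exists(paths)]
  if (length(missing_f)) stop("missing PLINK file(s): ", paste(missing_f, collapse = ", "))
  fam <- utils::read.table(paths[3], header = FALSE, colClasses = "character")
  bim <- utils::read.table(paths[2], header = FALSE, colClasses = "character")
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paths[1], what = "raw", n = file.size(paths[1]))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK BED file (bad magic bytes)")
  }
  if (raw[3] != as.raw(0x01)) stop("only SNP-major BED files are supported")
  bpv <- ceiling(n / 4)
  if (length(raw) != 3L + bpv * m) {
    stop(sprintf("BED payload size %d does not match BIM/FAM dimensions (%d variants x %d samples)",
                 length(raw) - 3L, m, n))
  }
  bits <- as.integer(rawToBits(raw[-(1:3)]))
  codes <- bits[seq(1L, length(bits), by = 2L)] + 2L * bits[seq(2L, length(bits), by = 2L)]
  codes <- matrix(codes, nrow = 4L * bpv)[seq_len(n), , drop = FALSE]
  # code -> dosage of A1: 00->2, 10->1, 11->0, 01->missing
  dosage_of <- c(2L, NA_integer_, 1L, 0L)
  d <- matrix(dosage_of[codes + 1L], nrow = n)
  nz <- which(!is.na(d) & d > 0L, arr.ind = TRUE)
  ms <- which(is.na(d), arr.ind = TRUE)
  D <- Matrix::sparseMatrix(i = nz[, 1], j = nz[, 2],
                            x = as.numeric(d[nz]), dims = c(n, m))
  genotype_matrix(D, sample_ids = fam[[2]], variant_ids = bim[[2]],
                  missing_mask = ms, ploidy = ploidy)
}

#' Write a PLINK 1 binary BED/BIM/FAM trio
#'
#' Inverse of [read_bed()]: A1 is the alternate allele (dosage counted), A2
#' the reference. Variant ids of the form `chrom:pos:ref:alt` populate the
#' BIM positions and alleles; other ids get placeholder coordinates.
#'
#' @param G a [genotype_matrix()] with diploid-compatible dosages (0, 1, 2).
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(G, prefix) {
  stopifnot(inherits(G, "genotype_matrix"))
  d <- as.matrix(G$dosages)
  d[as.matrix(G$missing_mask)] <- NA_integer_
  if (any(d > 2, na.rm = TRUE)) stop("PLINK BED supports dosages 0..2 only")
  n <- nrow(d); m <- ncol(d)
  # dosage -> code: 2->00, 1->10, 0->11, NA->01
  code_of <- function(x) {
    out <- integer(length(x))
    out[is.na(x)] <- 1L
    out[!is.na(x) & x == 2] <- 0L
    out[!is.na(x) & x == 1] <- 2L
    out[!is.na(x) & x == 0] <- 3L
    out
  }
  bpv <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  for (j in seq_len(m)) {
    codes <- c(code_of(d[, j]), rep.int(0L, 4L * bpv - n))
    bits <- rbind(codes %% 2L, codes %/% 2L)
    writeBin(packBits(as.raw(as.integer(bits)), type = "raw"), con)
  }
  parts <- strsplit(G$variant_ids, ":", fixed = TRUE)
  ok <- lengths(parts) == 4L
  chrom <- vapply(parts, function(z) if (length(z) == 4L) z[1] else "0", character(1))
  pos <- mapply(function(z, i) if (length(z) == 4L) z[2] else as.character(i),
                parts, seq_len(m))
  ref <- vapply(parts, function(z) if (length(z) == 4L) z[3] else "N", character(1))
  alt <- vapply(parts, function(z) if (length(z) == 4L) z[4] else "N", character(1))
  if (!all(ok)) message("write_plink: ", sum(!ok), " variant id(s) lack chrom:pos:ref:alt form")
  utils::write.table(
    data.frame(chrom, G$variant_ids, 0L, pos, alt, ref),
    paste0(prefix, ".bim"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(G$sample_ids, G$sample_ids, 0L, 0L, 0L, -9L),
    paste0(prefix, ".fam"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Impute missing genotype calls
#'
#' `"mean"` replaces each missing entry with the variant's mean dosage over
#' observed calls (preserves allele frequency; the standard choice before
#' genotype PCA); `"zero"` sets missing entries to the reference dosage 0.
#' Either way the missing mask is emptied. Variants whose calls are all
#' missing cannot be mean-imputed and are dropped with a warning.
#'
#' @param G a [genotype_matrix()]
#' @param strategy `"mean"` or `"zero"`.
#' @return a [genotype_matrix()] with an empty missing mask; non-missing
#'   entries are unchanged.
#' @export
impute_missing <- function(G, strategy = c("mean", "zero")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(G, "genotype_matrix"))
  if (n_missing(G) == 0L) return(G)
  empty <- NULL
  D <- G$dosages
  if (strategy == "mean") {
    n_obs <- nrow(D) - Matrix::colSums(G$missing_mask)
    empty <- which(n_obs == 0)
    mu <- as.numeric(Matrix::colSums(D)) / pmax(n_obs, 1)
    idx <- Matrix::which(G$missing_mask, arr.ind = TRUE)
    fill <- Matrix::sparseMatrix(i = idx[, 1], j = idx[, 2], x = mu[idx[, 2]],
                                 dims = dim(D))
    D <- D + fill
  }
  if (length(empty)) {
    warning(sprintf("impute_missing: dropped %d variant(s) with all calls missing",
                    length(empty)))
    keep <- setdiff(seq_len(ncol(D)), empty)
    return(genotype_matrix(D[, keep, drop = FALSE], sample_ids = G$sample_ids,
                           variant_ids = G$variant_ids[keep], ploidy = G$ploidy))
  }
  genotype_matrix(D, sample_ids = G$sample_ids, variant_ids = G$variant_ids,
                  ploidy = G$ploidy)
}

#' Filter variants by minor allele frequency
#'
#' Retains variants with `min(p, 1 - p) >= min_maf`, where `p` is the
#' alternate-allele frequency over observed calls. Column order is preserved
#' and the operation is idempotent. Apply before imputation so frequencies
#' reflect observed calls only.
#'
#' @param G a [genotype_matrix()]
#' @param min_maf threshold in `[0, 0.5]`.
#' @return a filtered [genotype_matrix()] (possibly with zero variants).
#' @export
filter_maf <- function(G, min_maf) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (!is.numeric(min_maf) || length(min_maf) != 1L || min_maf < 0 || min_maf > 0.5) {
    stop("min_maf must be a single value in [0, 0.5]")
  }
  if (min_maf == 0) return(G)
  p <- alt_allele_freq(G)
  maf <- pmin(p, 1 - p)
  keep <- which(!is.na(maf) & maf >= min_maf)
  G[, keep]
}
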