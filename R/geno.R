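#' Genotype matrix container
#'
#' Holds an individuals-by-markers allele-dosage matrix together with sample
#' grouping (e.g. generation number or registration year), an optional marker
#' map and the identity of the counted allele per marker.  Dosages are diploid
#' counts of the counted allele: 0, 1 or 2 (fractional values appear only
#' after mean imputation, see [impute_missing()]).
#'
#' @param dosages numeric matrix, rows = samples, columns = markers, with
#'   dimnames giving unique sample and marker ids.  Non-missing entries must
#'   lie in \[0, 2\].
#' @param group optional per-sample labels (generation, year, population).
#' @param map optional data frame with columns `marker`, `chr`, `pos`
#'   covering every marker, in the same order as the columns of `dosages`.
#' @param counted_allele,other_allele optional per-marker allele identifiers
#'   (e.g. REF/ALT bases from a VCF); `counted_allele` is the allele whose
#'   copies are counted by the dosage.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosages, group = NULL, map = NULL,
                        counted_allele = NULL, other_allele = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("S", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("M", seq_len(ncol(dosages)))
  if (anyDuplicated(rownames(dosages)))
    stop("sample ids must be unique")
  if (anyDuplicated(colnames(dosages)))
    stop("marker ids must be unique")
  rng <- range(dosages, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    stop("dosages must lie in [0, 2]; got range [",
         rng[1], ", ", rng[2], "]. {-1,0,1}-coded input must be recoded.")
  if (!is.null(group)) {
    stopifnot(length(group) == nrow(dosages))
    group <- as.vector(group)
  }
  if (!is.null(map)) {
    map <- validate_map(map, colnames(dosages))
  }
  if (!is.null(counted_allele))
    stopifnot(length(counted_allele) == ncol(dosages))
  if (!is.null(other_allele))
    stopifnot(length(other_allele) == ncol(dosages))
  structure(list(dosages = dosages, group = group, map = map,
                 counted_allele = counted_allele,
                 other_allele = other_allele),
            class = "geno_matrix")
}

# trusted construction for matrices built in code (skips validation scans)
new_geno_matrix <- function(dosages, group = NULL, map = NULL,
                            counted_allele = NULL, other_allele = NULL) {
  structure(list(dosages = dosages, group = group, map = map,
                 counted_allele = counted_allele,
                 other_allele = other_allele),
            class = "geno_matrix")
}

validate_map <- function(map, markers = NULL) {
  map <- as.data.frame(map)
  need <- c("marker", "chr", "pos")
  if (!all(need %in% names(map)))
    stop("map must have columns marker, chr, pos")
  map$marker <- as.character(map$marker)
  map$pos <- as.numeric(map$pos)
  if (anyDuplicated(map$marker))
    stop("map markers must be unique")
  if (!is.null(markers)) {
    if (!setequal(map$marker, markers))
      stop("map must cover exactly the genotyped markers")
    map <- map[match(markers, map$marker), , drop = FALSE]
    rownames(map) <- NULL
  }
  map
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$dosages), "samples x", ncol(x$dosages),
      "markers\n")
  if (!is.null(x$group)) {
    tb <- table(x$group)
    cat("groups:", paste0(names(tb), " (n=", tb, ")", collapse = ", "), "\n")
  }
  nmis <- sum(is.na(x$dosages))
  if (nmis > 0) cat("missing dosages:", nmis, "\n")
  if (!is.null(x$map))
    cat("map:", length(unique(x$map$chr)), "chromosome(s)\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix
#'
#' @param x a [geno_matrix()].
#' @param i,j sample and marker indices (any form accepted by matrix
#'   subsetting).
#' @param ... ignored.
#' @return A `geno_matrix` restricted to the selected samples/markers.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosages))
  if (missing(j)) j <- seq_len(ncol(x$dosages))
  jj <- seq_len(ncol(x$dosages))
  names(jj) <- colnames(x$dosages)
  j <- jj[j]
  geno_matrix(x$dosages[i, j, drop = FALSE],
              group = if (!is.null(x$group)) x$group[i],
              map = if (!is.null(x$map)) x$map[j, , drop = FALSE],
              counted_allele = if (!is.null(x$counted_allele)) x$counted_allele[j],
              other_allele = if (!is.null(x$other_allele)) x$other_allele[j])
}

#' Read a genotype matrix
#'
#' Supported formats:
#' \describe{
#'   \item{`delimited`}{comma- or tab-separated; first column sample id,
#'     header row of marker ids; entries 0/1/2, missing coded `NA` or empty.}
#'   \item{`vcf`}{VCF 4.x via the vcfR package.  Only biallelic SNP records
#'     are retained (multi-allelic records are skipped with a message);
#'     dosage counts ALT alleles; phased and unphased genotypes are treated
#'     identically.  The map is taken from CHROM/POS.}
#'   \item{`plink_raw`}{the PLINK `--recode A` additive dosage export; the
#'     counted allele is recovered from the `_A` column-name suffix.}
#' }
#'
#' @param path file path.
#' @param format one of `"delimited"`, `"vcf"`, `"plink_raw"`.
#' @param sep field separator for `delimited` (guessed from the header line
#'   when `NULL`).
#' @param group optional per-sample group labels (recycled checks apply), or
#'   a function of the sample-id vector returning labels.
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("delimited", "vcf", "plink_raw"),
                           sep = NULL, group = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  g <- switch(format,
    delimited = read_genotypes_delim(path, sep),
    vcf = read_genotypes_vcf(path),
    plink_raw = read_genotypes_plink_raw(path))
  if (!is.null(group)) {
    if (is.function(group)) group <- group(rownames(g$dosages))
    stopifnot(length(group) == nrow(g$dosages))
    g$group <- as.vector(group)
  }
  g
}

read_genotypes_delim <- function(path, sep = NULL) {
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   na.strings = c("NA", ""), stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("parse error: need sample-id column plus markers")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  bad <- which(!is.na(m) & !(m %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("parse error in ", path, " at data line ", bad[1, 1],
         " (marker ", colnames(m)[bad[1, 2]],
         "): dosage must be 0, 1, 2 or missing")
  }
  rownames(m) <- ids
  geno_matrix(m)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  nskip <- sum(!bi)
  if (nskip > 0) {
    message("skipped ", nskip, " non-biallelic VCF record(s)")
    v <- v[bi, ]
  }
  if (nrow(v@fix) == 0) stop("no biallelic records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  # count ALT alleles; treat '|' and '/' identically
  dos <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean %in% c("0/0")] <- 0
  dos[clean %in% c("0/1", "1/0")] <- 1
  dos[clean %in% c("1/1")] <- 2
  fix <- v@fix
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  rownames(dos) <- ids
  map <- data.frame(marker = ids, chr = fix[, "CHROM"],
                    pos = as.numeric(fix[, "POS"]),
                    stringsAsFactors = FALSE)
  geno_matrix(t(dos), map = map,
              counted_allele = unname(fix[, "ALT"]),
              other_allele = unname(fix[, "REF"]))
}

read_genotypes_plink_raw <- function(path) {
  df <- read.table(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(meta %in% names(df)))
    stop("parse error: not a PLINK .raw file (missing header columns)")
  snps <- setdiff(names(df), meta)
  m <- as.matrix(df[, snps, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df$IID)
  counted <- sub("^.*_([^_]+)$", "\\1", snps)
  colnames(m) <- sub("_[^_]+$", "", snps)
  geno_matrix(m, counted_allele = counted)
}

#' Write a genotype matrix as a delimited file
#'
#' Inverse of `read_genotypes(format = "delimited")`: first column `sample`,
#' header row of marker ids, missing written as `NA`.
#'
#' @param g a [geno_matrix()].
#' @param path output path.
#' @param sep field separator.
#' @export
write_genotypes <- function(g, path, sep = ",") {
  df <- data.frame(sample = rownames(g$dosages), g$dosages,
                   check.names = FALSE)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits an uncompressed VCF 4.2 file with GT-only genotype fields.
#' Heterozygotes are written unphased (`0/1`); dosages must be integral.
#' Requires a marker map; REF/OTHER alleles default to A/B placeholders when
#' the object carries none.
#'
#' @param g a [geno_matrix()] with a map and integral dosages.
#' @param path output path.
#' @export
write_vcf <- function(g, path) {
  if (is.null(g$map)) stop("write_vcf needs a marker map")
  d <- g$dosages
  if (any(!is.na(d) & d != round(d)))
    stop("write_vcf needs integral dosages (write before imputation)")
  alt <- if (!is.null(g$counted_allele)) g$counted_allele else
    rep("B", ncol(d))
  ref <- if (!is.null(g$other_allele)) g$other_allele else
    rep("A", ncol(d))
  gt <- matrix("./.", nrow = ncol(d), ncol = nrow(d))
  codes <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  ok <- !is.na(t(d))
  gt[ok] <- codes[as.character(t(d)[ok])]
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(d)), collapse = "\t"))
  body <- cbind(as.character(g$map$chr),
                format(g$map$pos, scientific = FALSE, trim = TRUE),
                g$map$marker, ref, alt, ".", ".", ".", "GT", gt)
  writeLines(c(lines, apply(body, 1, paste, collapse = "\t")), path)
  invisible(path)
}

#' Read a marker map
#'
#' Delimited file with columns `marker`, `chr`, `pos` (positions in bp or cM
#' as declared by the producing pipeline; stored as given).
#'
#' @param path file path.
#' @param sep separator (guessed when `NULL`).
#' @return data frame with columns marker, chr, pos.
#' @export
read_map <- function(path, sep = NULL) {
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  validate_map(read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE))
}

#' Read a phenotype table
#'
#' Delimited file with a sample-id column (`sample` or first column) and one
#' numeric column per trait; extra columns (year, environment, covariates)
#' are kept.  Samples may be a subset of the genotyped samples: effects can
#' be estimated on the phenotyped subset only (the "modern phenotypes"
#' design).
#'
#' @param path file path.
#' @param sep separator (guessed when `NULL`).
#' @return data frame with character column `sample` first.
#' @export
read_phenotypes <- function(path, sep = NULL) {
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  idcol <- if ("sample" %in% names(df)) "sample" else names(df)[1]
  df$sample <- as.character(df[[idcol]])
  if (anyDuplicated(df$sample))
    stop("at most one phenotype row per sample")
  df[, c("sample", setdiff(names(df), "sample")), drop = FALSE]
}

#' Mean-impute missing dosages
#'
#' Replaces each missing dosage by the marker's mean dosage over non-missing
#' samples (twice the counted-allele frequency).  Non-missing values are
#' unchanged.  Frequency computations ([allele_frequencies()]) use
#' non-missing calls only and do not need imputation; imputation is for
#' effect estimation and LD computation.
#'
#' @param g a [geno_matrix()].
#' @return A `geno_matrix` with no missing values.
#' @export
impute_missing <- function(g) {
  d <- g$dosages
  if (!anyNA(d)) return(g)
  mu <- colMeans(d, na.rm = TRUE)
  dead <- !is.finite(mu)
  if (any(dead))
    stop("fully missing marker(s): ",
         paste(head(colnames(d)[dead], 10), collapse = ", "))
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- mu[idx[, 2]]
  g$dosages <- d
  g
}

#' Align effect and frequency-change vectors
#'
#' Matches a set of allele-substitution effects and a set of per-marker
#' frequency changes by marker id, reorients markers whose counted allele
#' differs between the two (flipping the sign of both \eqn{\alpha} and
#' \eqn{\Delta} leaves the test statistic unchanged), and drops markers
#' present in only one input (with a message).
#'
#' @param effects a [fit_rrblup()]/[fit_bayesc()] result, or a data frame
#'   with columns `marker`, `alpha` (optionally `counted_allele`,
#'   `other_allele`).
#' @param change a [frequency_change()] result, or a data frame with columns
#'   `marker`, `delta` (optionally `counted_allele`, `other_allele`).
#' @return list with components `marker`, `alpha`, `delta`, `n_dropped`.
#' @export
align_effects_and_change <- function(effects, change) {
  ef <- as_effect_frame(effects)
  ch <- as_change_frame(change)
  common <- intersect(ef$marker, ch$marker)
  if (length(common) == 0) stop("no markers shared by effects and change")
  n_dropped <- (nrow(ef) - length(common)) + (nrow(ch) - length(common))
  if (n_dropped > 0)
    message("dropped ", n_dropped,
            " marker(s) present in only one of effects/change")
  ef <- ef[match(common, ef$marker), ]
  ch <- ch[match(common, ch$marker), ]
  delta <- ch$delta
  if (!is.null(ef$counted_allele) && !is.null(ch$counted_allele)) {
    same <- is.na(ef$counted_allele) | is.na(ch$counted_allele) |
      ef$counted_allele == ch$counted_allele
    flip <- !same & !is.na(ch$other_allele) &
      ef$counted_allele == ch$other_allele
    bad <- !same & !flip
    if (any(bad))
      stop("conflicting counted alleles with no way to flip: ",
           paste(head(common[bad], 10), collapse = ", "))
    delta[flip] <- -delta[flip]
  }
  list(marker = common, alpha = ef$alpha, delta = delta,
       n_dropped = n_dropped)
}

as_effect_frame <- function(effects) {
  if (inherits(effects, "marker_effects")) {
    data.frame(marker = effects$marker, alpha = effects$alpha,
               counted_allele = effects$counted_allele %||%
                 rep(NA_character_, length(effects$marker)),
               other_allele = effects$other_allele %||%
                 rep(NA_character_, length(effects$marker)),
               stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(effects)
    stopifnot(all(c("marker", "alpha") %in% names(df)))
    df$marker <- as.character(df$marker)
    df
  }
}

as_change_frame <- function(change) {
  df <- as.data.frame(change)
  stopifnot(all(c("marker", "delta") %in% names(df)))
  df$marker <- as.character(df$marker)
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
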