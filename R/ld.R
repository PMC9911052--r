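#' Pairwise r-squared within a marker window
#'
#' Squared Pearson correlation of dosage vectors for all marker pairs within
#' a sliding window of `max_win_snp` markers on one chromosome, with the
#' inter-marker distance of each pair.  Monomorphic markers carry no LD
#' information and are skipped (with a message).
#'
#' @param g a [geno_matrix()] (imputed; missing dosages are mean-imputed on
#'   the fly).
#' @param map marker map (defaults to the map carried by `g`).
#' @param chrom chromosome id.
#' @param max_win_snp window size in markers.
#' @return data frame with columns `marker1`, `marker2`, `dist`, `r2`.
#' @export
pairwise_r2 <- function(g, map = NULL, chrom, max_win_snp = 100) {
  map <- map %||% g$map
  if (is.null(map)) stop("pairwise_r2 needs a marker map")
  map <- validate_map(map, colnames(g$dosages))
  keep <- map$chr == chrom
  if (sum(keep) < 2) stop("chromosome ", chrom, " has <2 markers")
  d <- impute_missing(g[, which(keep)])$dosages
  pos <- map$pos[keep]
  o <- order(pos)
  d <- d[, o, drop = FALSE]
  pos <- pos[o]
  sds <- apply(d, 2, sd)
  poly <- sds > 0
  nmono <- sum(!poly)
  if (nmono > 0) message("skipped ", nmono, " monomorphic marker(s)")
  if (sum(poly) < 2) {
    warning("all markers monomorphic on chromosome ", chrom)
    return(data.frame(marker1 = character(), marker2 = character(),
                      dist = numeric(), r2 = numeric()))
  }
  d <- d[, poly, drop = FALSE]
  pos <- pos[poly]
  mc <- ncol(d)
  s <- scale(d)           # columns standardized; cor = crossprod/(n-1)
  n <- nrow(d)
  out <- vector("list", min(max_win_snp, mc - 1))
  for (off in seq_len(min(max_win_snp, mc - 1))) {
    a <- seq_len(mc - off)
    b <- a + off
    r <- colSums(s[, a, drop = FALSE] * s[, b, drop = FALSE]) / (n - 1)
    out[[off]] <- data.frame(marker1 = colnames(d)[a],
                             marker2 = colnames(d)[b],
                             dist = pos[b] - pos[a],
                             r2 = r^2,
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Effective marker number from the decay of LD with distance
#'
#' For each chromosome, pairwise r-squared values within a `max_win_snp`
#' window are binned by inter-marker distance (bin width = 1/`n_bins` of the
#' chromosome span), the binned means are smoothed by a monotone
#' non-increasing (isotonic) fit, and the independence distance `d_star` is
#' the first bin midpoint at which the smoothed mean falls below `max_r2`.
#' The chromosome contributes `ceiling(span / d_star)` independent segments
#' (at least 1); the genome-wide effective marker number is the sum over
#' chromosomes.  When LD never decays below `max_r2` the chromosome counts
#' as a single segment (with a warning).
#'
#' @param g a [geno_matrix()].
#' @param map marker map (defaults to the map carried by `g`).
#' @param max_win_snp window size in markers for the r-squared computation.
#' @param max_chr optional cap on the number of chromosomes analysed (the
#'   first `max_chr` in map order); segment counts then cover only those.
#' @param max_r2 LD threshold defining independence; the default 0.03 is of
#'   the order of the chance r-squared (about 1/n) at a few hundred samples,
#'   plus margin.
#' @param n_bins number of distance bins per chromosome.
#' @return An object of class `ld_summary` with per-chromosome decay tables,
#'   segment counts and the genome-wide `m_eff`.
#' @export
ld_decay <- function(g, map = NULL, max_win_snp = 100, max_chr = NULL,
                     max_r2 = 0.03, n_bins = 100) {
  stopifnot(max_r2 > 0, max_r2 < 1)
  map <- map %||% g$map
  if (is.null(map)) stop("ld_decay needs a marker map")
  map <- validate_map(map, colnames(g$dosages))
  chroms <- unique(map$chr)
  if (!is.null(max_chr)) chroms <- chroms[seq_len(min(max_chr, length(chroms)))]
  per <- vector("list", length(chroms))
  decay <- vector("list", length(chroms))
  for (k in seq_along(chroms)) {
    cc <- chroms[k]
    pos <- map$pos[map$chr == cc]
    span <- max(pos) - min(pos)
    pr <- suppressMessages(pairwise_r2(g, map, cc, max_win_snp))
    if (nrow(pr) == 0 || span <= 0) {
      per[[k]] <- data.frame(chr = cc, d_star = NA_real_, span = span,
                             segments = 1)
      next
    }
    width <- span / n_bins
    bin <- pmin(floor(pr$dist / width), n_bins - 1)
    mids <- (sort(unique(bin)) + 0.5) * width
    mr2 <- tapply(pr$r2, bin, mean)
    # monotone non-increasing smoothing of the decay curve
    iso <- isoreg(seq_along(mr2), -as.vector(mr2))
    sm <- -iso$yf
    below <- which(sm < max_r2)
    if (length(below) == 0) {
      warning("LD never decays below max_r2 on chromosome ", cc,
              "; counting 1 segment")
      d_star <- NA_real_
      segments <- 1
    } else {
      d_star <- mids[below[1]]
      segments <- max(1, ceiling(span / d_star))
    }
    per[[k]] <- data.frame(chr = cc, d_star = d_star, span = span,
                           segments = segments)
    decay[[k]] <- data.frame(chr = cc, bin_distance = mids,
                             mean_r2 = as.vector(mr2), smoothed_r2 = sm)
  }
  per <- do.call(rbind, per)
  structure(list(per_chrom = per,
                 decay = do.call(rbind, decay),
                 m_eff = sum(per$segments),
                 m = ncol(g$dosages),
                 params = list(max_win_snp = max_win_snp, max_r2 = max_r2,
                               n_bins = n_bins),
                 method = "ld_decay"),
            class = "ld_summary")
}

#' Effective marker number by eigenvalue decomposition (simpleM)
#'
#' Per chromosome, the marker correlation matrix is eigen-decomposed and the
#' effective number of independent tests is the smallest number of leading
#' eigenvalues whose sum reaches `var_fraction` of the total; the genome-wide
#' value is the sum over chromosomes.  Chromosomes longer than `block_size`
#' markers are processed in contiguous blocks of at most `block_size` markers
#' whose counts are summed, so the method stays feasible at large marker
#' counts.  Monomorphic markers carry a degenerate correlation and are
#' excluded.
#'
#' @param g a [geno_matrix()] (missing dosages mean-imputed on the fly).
#' @param map marker map (defaults to the map carried by `g`; when absent,
#'   all markers are treated as one chromosome).
#' @param var_fraction fraction of total eigenvalue mass to capture
#'   (default 0.995).
#' @param block_size maximum markers per eigen-decomposition block.
#' @return An object of class `ld_summary` with per-chromosome counts and
#'   the genome-wide `m_eff`.
#' @export
simple_m <- function(g, map = NULL, var_fraction = 0.995, block_size = 2000) {
  stopifnot(var_fraction > 0, var_fraction <= 1)
  map <- map %||% g$map
  d <- impute_missing(g)$dosages
  if (is.null(map)) {
    chr <- rep("1", ncol(d))
  } else {
    map <- validate_map(map, colnames(d))
    chr <- as.character(map$chr)
  }
  chroms <- unique(chr)
  segs <- numeric(length(chroms))
  for (k in seq_along(chroms)) {
    cols <- which(chr == chroms[k])
    if (!is.null(map)) cols <- cols[order(map$pos[cols])]
    dc <- d[, cols, drop = FALSE]
    poly <- apply(dc, 2, sd) > 0
    dc <- dc[, poly, drop = FALSE]
    if (ncol(dc) == 0) stop("no polymorphic markers on chromosome ",
                            chroms[k])
    starts <- seq(1, ncol(dc), by = block_size)
    segs[k] <- sum(vapply(starts, function(s) {
      blk <- dc[, s:min(s + block_size - 1, ncol(dc)), drop = FALSE]
      meff_from_correlation(fast_cor(blk), var_fraction)
    }, numeric(1)))
  }
  per <- data.frame(chr = chroms, segments = segs)
  structure(list(per_chrom = per, decay = NULL,
                 m_eff = sum(per$segments), m = ncol(d),
                 params = list(var_fraction = var_fraction,
                               block_size = block_size),
                 method = "simpleM"),
            class = "ld_summary")
}

# column-correlation via BLAS crossprod (columns known polymorphic)
fast_cor <- function(x) {
  xc <- sweep(x, 2, colMeans(x))
  C <- crossprod(xc)
  s <- sqrt(diag(C))
  C / tcrossprod(s)
}

#' Effective test number of a correlation matrix
#'
#' The simpleM reduction applied to an explicit correlation matrix: the
#' smallest k such that the k largest eigenvalues sum to at least
#' `var_fraction` of the total eigenvalue mass.
#'
#' @param R symmetric correlation matrix.
#' @param var_fraction fraction of eigenvalue mass to capture.
#' @return integer effective number of tests (between 1 and `ncol(R)`).
#' @export
meff_from_correlation <- function(R, var_fraction = 0.995) {
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  tot <- sum(ev)
  if (tot <= 0) stop("degenerate correlation matrix")
  k <- which(cumsum(ev) / tot >= var_fraction - 1e-12)[1]
  max(1L, as.integer(k))
}

#' @export
print.ld_summary <- function(x, ...) {
  cat("Effective marker number (", x$method, "): M_eff = ", x$m_eff,
      " of m = ", x$m, " markers\n", sep = "")
  print(x$per_chrom, row.names = FALSE)
  invisible(x)
}

#' Write per-chromosome LD decay and M_eff summary
#'
#' @param x an `ld_summary` from [ld_decay()] or [simple_m()].
#' @param path output path for the decay table (`<path>` gets the table,
#'   `<path>.meff` the one-line summary).
#' @export
write_ld_summary <- function(x, path) {
  if (!is.null(x$decay))
    write.table(x$decay, path, sep = "\t", row.names = FALSE, quote = FALSE)
  else
    write.table(x$per_chrom, path, sep = "\t", row.names = FALSE,
                quote = FALSE)
  writeLines(paste0("m_eff\t", x$m_eff), paste0(path, ".meff"))
  invisible(path)
}
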