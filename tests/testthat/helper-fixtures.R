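# Small in-code fixtures shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# genotype matrix with given dosage columns (markers as list of vectors)
make_geno <- function(..., group = NULL, map = NULL) {
  cols <- list(...)
  d <- do.call(cbind, cols)
  cn <- names(cols)
  if (is.null(cn) || any(cn == "")) cn <- paste0("M", seq_along(cols))
  colnames(d) <- cn
  rownames(d) <- paste0("S", seq_len(nrow(d)))
  polyadapt::geno_matrix(d, group = group, map = map)
}

# random biallelic genotype matrix: independent markers, HWE at uniform freqs
random_geno <- function(n, m, group = NULL, seed = NULL,
                        freq = NULL, map = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- freq %||% runif(m, 0.1, 0.9)
  d <- sapply(seq_len(m), function(j) rbinom(n, 2, p[j]))
  dimnames(d) <- list(paste0("S", seq_len(n)), paste0("M", seq_len(m)))
  polyadapt::geno_matrix(d, group = group, map = map)
}

# one-chromosome map at evenly spaced positions
even_map <- function(markers, chr = "1", span = 100) {
  data.frame(marker = markers, chr = chr,
             pos = seq(0, span, length.out = length(markers)),
             stringsAsFactors = FALSE)
}

# tiny simulated study (fast): used where a full desk-scale run is overkill
tiny_config <- function(...) {
  polyadapt::desk_scale_config(n_chrom = 3, m = 150, n = 80, n_hist = 20,
                               n_gen = 6, n_qtl = 30, ...)
}
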