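#' Counted-allele frequencies within a sample group
#'
#' Per marker, frequency = (sum of non-missing dosages) / (2 x number of
#' non-missing calls); individuals are weighted equally.  Markers with no
#' non-missing call in the group get `NA`.
#'
#' @param g a [geno_matrix()] with group labels (unless `group` is `NULL`
#'   and the whole matrix is used).
#' @param group a group label selecting samples, or `NULL` for all samples.
#' @return named numeric vector of frequencies in \[0, 1\].
#' @export
allele_frequencies <- function(g, group = NULL) {
  d <- g$dosages
  if (!is.null(group)) {
    if (is.null(g$group)) stop("geno_matrix has no group labels")
    keep <- g$group == group
    if (!any(keep)) stop("group '", group, "' selects no samples")
    d <- d[keep, , drop = FALSE]
  }
  n_called <- colSums(!is.na(d))
  f <- colSums(d, na.rm = TRUE) / (2 * n_called)
  f[n_called == 0] <- NA_real_
  f
}

#' Allele-frequency change between two time points
#'
#' Computes \eqn{\Delta_j = f_{late,j} - f_{early,j}} for every marker, so a
#' positive test statistic means selection moved trait-increasing alleles up
#' in frequency.  Markers with a missing frequency in either group are
#' flagged `NA` (and excluded downstream, with a message here).
#'
#' @param g a [geno_matrix()] with group labels.
#' @param early,late group labels of the early and late samples (must
#'   differ).
#' @return A data frame of class `freq_change` with columns `marker`,
#'   `freq_early`, `freq_late`, `delta`, `n_early`, `n_late`; the
#'   counted-allele annotation of `g`, if any, is carried in columns
#'   `counted_allele`/`other_allele`.
#' @export
frequency_change <- function(g, early, late) {
  if (identical(early, late))
    stop("early and late groups must differ (degenerate contrast)")
  if (is.null(g$group)) stop("geno_matrix has no group labels")
  fe <- allele_frequencies(g, early)
  fl <- allele_frequencies(g, late)
  ne <- colSums(!is.na(g$dosages[g$group == early, , drop = FALSE]))
  nl <- colSums(!is.na(g$dosages[g$group == late, , drop = FALSE]))
  delta <- fl - fe
  nmiss <- sum(is.na(delta))
  if (nmiss > 0)
    message(nmiss, " marker(s) with missing frequency flagged NA")
  out <- data.frame(marker = colnames(g$dosages),
                    freq_early = unname(fe), freq_late = unname(fl),
                    delta = unname(delta),
                    n_early = unname(ne), n_late = unname(nl),
                    stringsAsFactors = FALSE)
  if (!is.null(g$counted_allele)) out$counted_allele <- g$counted_allele
  if (!is.null(g$other_allele)) out$other_allele <- g$other_allele
  class(out) <- c("freq_change", "data.frame")
  out
}

#' Write a frequency-change table
#'
#' Delimited `(marker, freq_early, freq_late, delta)` table consumable by
#' [ghat_test()] and by the two-vector entry point.
#'
#' @param x a [frequency_change()] result.
#' @param path output path.
#' @param sep separator.
#' @export
write_freq_change <- function(x, path, sep = "\t") {
  write.table(as.data.frame(x), path, sep = sep, row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
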