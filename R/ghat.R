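#' The composite selection statistic
#'
#' \eqn{\hat{G} = \sum_j \Delta_j \alpha_j}: the sum over markers of the
#' allele-frequency change times the allele-substitution effect, both
#' oriented to the same counted allele.  Pairs with a missing entry are
#' excluded.
#'
#' @param alpha numeric vector of allele-substitution effects.
#' @param delta numeric vector of frequency changes, same length and marker
#'   order as `alpha`.
#' @return scalar statistic in trait units.
#' @export
ghat_statistic <- function(alpha, delta) {
  if (length(alpha) != length(delta))
    stop("alpha and delta must have equal length")
  if (length(alpha) == 0) stop("empty input")
  ok <- !is.na(alpha) & !is.na(delta)
  if (!any(ok)) stop("all entries missing")
  sum(alpha[ok] * delta[ok])
}

#' Test for selection on a polygenic trait
#'
#' Computes the composite statistic \eqn{\hat{G} = \sum_j \Delta_j \alpha_j}
#' and evaluates it against a permutation null built by repeatedly permuting
#' the effect vector against the fixed frequency-change vector.  Because
#' markers in linkage disequilibrium are not independent observations, the
#' permutation null (which treats them as exchangeable) understates the true
#' drift variance; three ways of handling this are provided:
#' \describe{
#'   \item{`scale`}{(default) the permutation standard deviation is inflated
#'     by \eqn{\sqrt{m / m_{eff}}}, where `num_eff` \eqn{= m_{eff}} is the
#'     effective number of independent genome segments from [simple_m()] or
#'     [ld_decay()]; the p-value is the two-sided normal tail of the scaled
#'     z-score.}
#'   \item{`trim`}{markers are thinned deterministically to every
#'     `blocksize`-th marker (in map order) before testing, so the retained
#'     markers are approximately independent; the unscaled permutation
#'     normal approximation is applied to the thinned vectors.}
#'   \item{`naive`}{the unscaled permutation normal approximation on all
#'     markers; valid only when markers are independent.}
#' }
#' For `naive` and `trim` an exact empirical p-value
#' \eqn{(r+1)/(\mathrm{perms}+1)} is also reported; the `scale` correction
#' is defined on a variance, so its p-value is necessarily the normal
#' approximation.
#'
#' @param effects effect input: a numeric vector of \eqn{\alpha_j}, or a
#'   [fit_rrblup()]/[fit_bayesc()] result (aligned to `change` by marker id
#'   via [align_effects_and_change()]).
#' @param change change input: a numeric vector of \eqn{\Delta_j}, or a
#'   [frequency_change()] result.
#' @param method `"scale"`, `"trim"` or `"naive"`.
#' @param perms number of permutations (at least 100).
#' @param num_eff effective number of independent markers (required for
#'   `scale`; an `ld_summary` object is accepted).
#' @param blocksize thinning interval for `trim`.
#' @param level confidence level of the reported interval.
#' @param sig_level significance level used for the direction call.
#' @param seed optional integer seed; the permutation stream is restored
#'   afterwards, and the seed is recorded in the result.
#' @return An object of class `ghat`: see [print.ghat()]; fields include
#'   `ghat_obs`, `p_value`, `empirical_p`, `null_mean`, `null_sd`, `m`,
#'   `num_eff`, `direction`, `ci`.
#' @examples
#' set.seed(1)
#' a <- rnorm(500); d <- rnorm(500, sd = 0.05)
#' ghat_test(a, d, method = "naive", perms = 200, seed = 7)
#' @export
ghat_test <- function(effects, change, method = c("scale", "trim", "naive"),
                      perms = 1000, num_eff = NULL, blocksize = NULL,
                      level = 0.95, sig_level = 0.05, seed = NULL) {
  method <- match.arg(method)
  if (perms < 100) stop("perms must be at least 100")
  if (is.numeric(effects) && is.numeric(change)) {
    if (length(effects) != length(change))
      stop("alpha and delta must have equal length")
    alpha <- as.numeric(effects)
    delta <- as.numeric(change)
  } else {
    al <- align_effects_and_change(effects, change)
    alpha <- al$alpha
    delta <- al$delta
  }
  ok <- !is.na(alpha) & !is.na(delta)
  n_excl <- sum(!ok)
  if (!any(ok)) stop("all entries missing")
  if (n_excl > 0)
    message("excluded ", n_excl, " marker(s) with missing alpha or delta")
  alpha <- alpha[ok]
  delta <- delta[ok]
  m <- length(alpha)
  if (inherits(num_eff, "ld_summary")) num_eff <- num_eff$m_eff
  if (method == "scale") {
    if (is.null(num_eff)) stop("method 'scale' requires num_eff")
    if (num_eff < 1 || num_eff > m)
      stop("num_eff must lie in [1, m = ", m, "]")
  }
  if (method == "trim") {
    if (is.null(blocksize)) stop("method 'trim' requires blocksize")
    if (blocksize < 1 || blocksize > m)
      stop("blocksize must lie in [1, m = ", m, "]")
    keep <- seq(1, m, by = blocksize)
    alpha <- alpha[keep]
    delta <- delta[keep]
    m_used <- length(alpha)
  } else {
    m_used <- m
  }

  obs <- sum(alpha * delta)
  null_stats <- with_seed(seed, {
    vapply(seq_len(perms),
           function(i) sum(delta * alpha[sample.int(m_used)]),
           numeric(1))
  })
  null_mean <- mean(null_stats)
  null_sd <- sd(null_stats)

  inflation <- if (method == "scale") sqrt(m / num_eff) else 1
  if (!is.finite(null_sd) || null_sd == 0) {
    warning("degenerate permutation null (sd = 0); p set to 1")
    p <- 1
    z <- 0
  } else {
    z <- (obs - null_mean) / (null_sd * inflation)
    p <- min(1, 2 * pnorm(-abs(z)))
    p <- max(p, .Machine$double.xmin)
  }
  emp_p <- if (method %in% c("naive", "trim") && null_sd > 0) {
    (sum(abs(null_stats - null_mean) >= abs(obs - null_mean)) + 1) /
      (perms + 1)
  } else NA_real_

  ci <- if (p >= 1 || obs == 0) c(-Inf, Inf) else
    ci_from_pvalue(obs, p, level)
  direction <- if (p < sig_level && obs > 0) "positive"
    else if (p < sig_level && obs < 0) "negative" else "none"

  structure(list(ghat_obs = obs, p_value = p, empirical_p = emp_p,
                 method = method, perms = perms, m = m, m_used = m_used,
                 num_eff = if (method == "scale") num_eff else NA,
                 blocksize = if (method == "trim") blocksize else NA,
                 null_mean = null_mean, null_sd = null_sd, z = z,
                 direction = direction, sig_level = sig_level,
                 level = level, ci_low = ci[1], ci_high = ci[2],
                 null_stats = null_stats, seed = seed,
                 call = match.call()),
            class = "ghat")
}

#' Confidence interval back-calculated from a p-value
#'
#' Recovers a standard error from a two-sided p-value and the point estimate
#' (\eqn{SE = |est| / z} with \eqn{z = |\Phi^{-1}(p/2)|}) and forms a normal
#' confidence interval around the estimate.  Undefined when the estimate is
#' zero or the p-value is 1; the interval is then flagged infinite, with a
#' warning.
#'
#' @param estimate point estimate.
#' @param p two-sided p-value in (0, 1).
#' @param level confidence level.
#' @return numeric vector `c(low, high)`.
#' @export
ci_from_pvalue <- function(estimate, p, level = 0.95) {
  stopifnot(is.finite(estimate), level > 0, level < 1)
  if (p >= 1 || estimate == 0) {
    warning("standard error undefined (p >= 1 or estimate 0); ",
            "returning infinite interval")
    return(c(-Inf, Inf))
  }
  if (p <= 0) stop("p must be in (0, 1)")
  z <- abs(qnorm(p / 2))
  se <- abs(estimate) / z
  half <- qnorm(1 - (1 - level) / 2) * se
  c(estimate - half, estimate + half)
}

#' @export
print.ghat <- function(x, ...) {
  cat("Ghat test for polygenic selection\n")
  cat(sprintf("  Ghat = %.6g  (m = %d markers", x$ghat_obs, x$m))
  if (x$method == "scale")
    cat(sprintf(", m_eff = %.4g", x$num_eff))
  if (x$method == "trim")
    cat(sprintf(", thinned to %d (blocksize %d)", x$m_used, x$blocksize))
  cat(")\n")
  cat(sprintf("  method = %s, perms = %d\n", x$method, x$perms))
  cat(sprintf("  p-value = %.4g  direction: %s (at alpha = %g)\n",
              x$p_value, x$direction, x$sig_level))
  cat(sprintf("  %g%% CI: [%.6g, %.6g]\n", 100 * x$level, x$ci_low,
              x$ci_high))
  invisible(x)
}

#' @export
summary.ghat <- function(object, ...) {
  out <- object
  class(out) <- c("summary.ghat", "ghat")
  out
}

#' @export
print.summary.ghat <- function(x, ...) {
  print.ghat(x)
  cat(sprintf("  permutation null: mean = %.6g, sd = %.6g, z = %.4g\n",
              x$null_mean, x$null_sd, x$z))
  if (!is.na(x$empirical_p))
    cat(sprintf("  empirical p (rank-based): %.4g\n", x$empirical_p))
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' @export
confint.ghat <- function(object, parm, level = 0.95, ...) {
  ci <- ci_from_pvalue(object$ghat_obs, object$p_value, level)
  out <- matrix(ci, nrow = 1,
                dimnames = list("ghat", sprintf("%g %%",
                  100 * c((1 - level) / 2, 1 - (1 - level) / 2))))
  out
}

#' Plot a test result against its permutation null
#'
#' Histogram of the permuted statistics with the observed statistic marked.
#'
#' @param x a [ghat_test()] result.
#' @param ... passed to [graphics::hist()].
#' @export
plot.ghat <- function(x, ...) {
  h <- hist(x$null_stats, breaks = 30, col = "grey85", border = "grey60",
            main = "Permutation null vs observed Ghat",
            xlab = "Ghat under permutation",
            xlim = range(c(x$null_stats, x$ghat_obs)), ...)
  abline(v = x$ghat_obs, col = "firebrick", lwd = 2)
  legend("topright", bty = "n",
         legend = sprintf("observed = %.3g, p = %.3g", x$ghat_obs,
                          x$p_value))
  invisible(h)
}

#' Write a test result as a one-row table plus JSON sidecar
#'
#' @param x a [ghat_test()] result.
#' @param path output path for the delimited row; `<path>.json` receives the
#'   full result (requires jsonlite).
#' @export
write_ghat_result <- function(x, path) {
  row <- data.frame(ghat = x$ghat_obs, p_value = x$p_value,
                    method = x$method, perms = x$perms, m = x$m,
                    num_eff = x$num_eff, blocksize = x$blocksize,
                    null_mean = x$null_mean, null_sd = x$null_sd,
                    direction = x$direction,
                    ci_low = x$ci_low, ci_high = x$ci_high,
                    seed = if (is.null(x$seed)) NA else x$seed)
  write.table(row, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    full <- x[setdiff(names(x), c("null_stats", "call"))]
    full$seed <- if (is.null(x$seed)) NA else x$seed
    jsonlite::write_json(full, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

# Evaluate expr with a temporary RNG state seeded by `seed` (NULL = use the
# ambient stream and leave it advanced, as base R simulation functions do).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
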