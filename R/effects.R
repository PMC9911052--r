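#' Marker effects by ridge-regression BLUP (REML)
#'
#' Fits the whole-genome regression \eqn{y = X\beta + Zu + e} with
#' \eqn{u \sim N(0, I\sigma^2_u)} and \eqn{e \sim N(0, I\sigma^2_e)}, where
#' `Z` holds column-centred allele dosages, so each element of `u` is the
#' allele-substitution effect of one marker in trait units per allele copy.
#' Variance components are estimated by REML: the fixed part is absorbed by
#' orthogonal projection, the genotype cross-product is eigen-decomposed
#' once, and the restricted likelihood is maximised by a single 1-D search
#' over the variance ratio \eqn{\lambda = \sigma^2_e / \sigma^2_u} (this is
#' exact, not an EM iteration).  Effects are the BLUP
#' \eqn{\hat{u} = (Z'Z + \lambda I)^{-1} Z' \tilde{y}} at the REML
#' \eqn{\lambda}.
#'
#' Only phenotyped samples enter the fit; the returned object predicts over
#' any genotype matrix (see [predict.marker_effects()]), which supports the
#' design where phenotypes exist only for a modern subset while frequency
#' change uses the full time span.
#'
#' @param g a [geno_matrix()]; missing dosages are mean-imputed before
#'   estimation.
#' @param pheno a data frame from [read_phenotypes()] (column `sample` plus
#'   trait columns), or a named numeric vector of phenotypes.
#' @param trait trait column name (ignored for a vector `pheno`).
#' @param covariates optional character vector of `pheno` columns entering
#'   the fixed part alongside the intercept.
#' @param lambda optional fixed variance ratio; skips REML and returns the
#'   plain ridge solution at that ratio.
#' @param max_markers explicit guard on the marker count: the solver holds
#'   an m-by-m cross-product, so m beyond this limit stops with an error
#'   rather than exhausting memory.  Raise it deliberately on large-memory
#'   machines.
#' @return An object of class `marker_effects` with fields `marker`,
#'   `alpha` (named vector), `method = "rrblup"`, variance components
#'   `varcomp`, fixed-effect estimates `beta`, column `centers`, and the
#'   counted-allele annotation of `g`.
#' @export
fit_rrblup <- function(g, pheno, trait = NULL, covariates = NULL,
                       lambda = NULL, max_markers = 20000) {
  if (ncol(g$dosages) > max_markers)
    stop("m = ", ncol(g$dosages), " markers exceeds max_markers = ",
         max_markers, "; raise the limit explicitly if memory allows")
  dat <- match_pheno(g, pheno, trait, covariates)
  y <- dat$y
  n <- length(y)
  if (n < 2) stop("need at least 2 phenotyped, genotyped samples")
  Z <- dat$Z
  centers <- colMeans(Z)
  Zc <- sweep(Z, 2, centers)
  X <- dat$X
  qx <- qr(X)
  p <- qx$rank
  Q <- qr.Q(qx)[, seq_len(p), drop = FALSE]
  ystar <- y - Q %*% crossprod(Q, y)
  Zstar <- Zc - Q %*% crossprod(Q, Zc)
  m <- ncol(Zstar)
  df <- n - p

  if (df < 1 || var(as.vector(ystar)) < .Machine$double.eps * 100) {
    warning("trait has no residual variance; all effects set to 0")
    alpha <- rep(0, m)
    vc <- list(sigma2_u = 0, sigma2_e = 0, lambda = Inf)
  } else {
    C <- crossprod(Zstar)
    b <- crossprod(Zstar, ystar)
    ee <- eigen(C, symmetric = TRUE)
    d2 <- pmax(ee$values, 0)
    tol <- max(d2) * 1e-10
    r <- sum(d2 > tol)
    vb <- crossprod(ee$vectors, b)
    w2 <- numeric(m)
    w2[seq_len(r)] <- vb[seq_len(r)]^2 / d2[seq_len(r)]
    q <- max(sum(ystar^2) - sum(w2[seq_len(r)]), 0)
    if (is.null(lambda)) {
      negll <- function(t) {
        delta <- exp(t)
        su2 <- (sum(w2[seq_len(r)] / (d2[seq_len(r)] + delta)) + q / delta) /
          df
        df * log(su2) + sum(log(d2[seq_len(r)] + delta)) +
          (df - r) * log(delta)
      }
      opt <- optimize(negll, c(log(1e-8), log(1e8)), tol = 1e-10)
      lambda <- exp(opt$minimum)
      sigma2_u <- (sum(w2[seq_len(r)] / (d2[seq_len(r)] + lambda)) +
                     q / lambda) / df
      vc <- list(sigma2_u = sigma2_u, sigma2_e = lambda * sigma2_u,
                 lambda = lambda)
    } else {
      vc <- list(sigma2_u = NA_real_, sigma2_e = NA_real_, lambda = lambda)
    }
    alpha <- as.vector(ee$vectors %*% (vb / (d2 + lambda)))
  }
  beta <- qr.coef(qx, as.vector(y - Zc %*% alpha))
  new_marker_effects(marker = colnames(Z), alpha = alpha, method = "rrblup",
                     g = g, centers = centers, beta = beta, varcomp = vc,
                     n = n, trait = dat$trait)
}

#' Marker effects by BayesC
#'
#' Gibbs sampler for the whole-genome regression in which a fixed prior
#' fraction `pi` of markers has exactly zero effect and the remainder share
#' a common effect variance (spike-and-slab with a point mass at zero).
#' Priors on the effect and residual variances are scaled inverse
#' chi-squared with `nu` degrees of freedom and data-derived scales (half
#' the phenotypic variance apportioned to each side).  The returned effect
#' is the posterior-mean allele-substitution effect per marker (zeros
#' included), with per-marker posterior inclusion probabilities.
#'
#' @inheritParams fit_rrblup
#' @param pi prior fraction of zero-effect markers in \[0, 1\]; `pi = 1`
#'   short-circuits to all-zero effects.
#' @param iters,burnin Gibbs chain length and burn-in (`iters > burnin`).
#' @param seed optional integer seed (recorded in the result).
#' @param nu prior degrees of freedom for both variance components.
#' @return An object of class `marker_effects` with `method = "bayesc"`,
#'   posterior means in `varcomp`, `inclusion_prob`, and the sampler
#'   settings in `hyper`.
#' @export
fit_bayesc <- function(g, pheno, trait = NULL, covariates = NULL,
                       pi = 0.95, iters = 10000, burnin = 2000,
                       seed = NULL, nu = 4) {
  stopifnot(pi >= 0, pi <= 1, iters > burnin, burnin >= 0)
  dat <- match_pheno(g, pheno, trait, covariates)
  y <- dat$y
  n <- length(y)
  if (n < 2) stop("need at least 2 phenotyped, genotyped samples")
  Z <- dat$Z
  centers <- colMeans(Z)
  Zc <- sweep(Z, 2, centers)
  X <- dat$X
  qx <- qr(X)
  Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  ystar <- as.vector(y - Q %*% crossprod(Q, y))
  Zstar <- Zc - Q %*% crossprod(Q, Zc)
  m <- ncol(Zstar)
  hyper <- list(pi = pi, iters = iters, burnin = burnin, nu = nu,
                seed = seed)
  if (pi >= 1) {
    fit <- list(alpha = rep(0, m), inclusion = rep(0, m),
                s2a = 0, s2e = var(ystar), mu = 0)
  } else {
    vy <- var(ystar)
    czz <- colSums(Zstar^2)
    s_a <- (0.5 * vy * n) / (max((1 - pi) * m, 1) * max(mean(czz), 1e-8))
    s_e <- 0.5 * vy
    fit <- with_seed(seed, bayesc_gibbs(Zstar, ystar, pi, as.integer(iters),
                                        as.integer(burnin), nu, s_a, s_e))
  }
  beta <- qr.coef(qx, as.vector(y - Zc %*% fit$alpha))
  vc <- list(sigma2_alpha = fit$s2a, sigma2_e = fit$s2e, pi = pi)
  new_marker_effects(marker = colnames(Z), alpha = as.vector(fit$alpha),
                     method = "bayesc", g = g, centers = centers,
                     beta = beta, varcomp = vc, n = n, trait = dat$trait,
                     inclusion_prob = as.vector(fit$inclusion),
                     hyper = hyper)
}

# Match phenotypes to genotyped samples and build y, Z, X.
match_pheno <- function(g, pheno, trait, covariates) {
  if (is.numeric(pheno) && !is.null(names(pheno))) {
    pheno <- data.frame(sample = names(pheno), .y = unname(pheno),
                        stringsAsFactors = FALSE)
    trait <- ".y"
  }
  pheno <- as.data.frame(pheno)
  if (!"sample" %in% names(pheno))
    stop("pheno must have a 'sample' column (or be a named vector)")
  if (is.null(trait)) stop("trait must be named")
  if (!trait %in% names(pheno)) stop("trait '", trait, "' not in pheno")
  keep <- pheno$sample %in% rownames(g$dosages) & !is.na(pheno[[trait]])
  pheno <- pheno[keep, , drop = FALSE]
  if (nrow(pheno) == 0)
    stop("no overlap between phenotyped and genotyped samples")
  Z <- impute_missing(g)$dosages[pheno$sample, , drop = FALSE]
  X <- matrix(1, nrow(Z), 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates)) {
    form <- stats::reformulate(covariates)
    miss <- setdiff(all.vars(form), names(pheno))
    if (length(miss)) stop("covariate(s) not in pheno: ",
                           paste(miss, collapse = ", "))
    X <- stats::model.matrix(form, data = pheno)
  }
  list(y = as.numeric(pheno[[trait]]), Z = Z, X = X, trait = trait)
}

new_marker_effects <- function(marker, alpha, method, g, centers, beta,
                               varcomp, n, trait, inclusion_prob = NULL,
                               hyper = NULL) {
  names(alpha) <- marker
  structure(list(marker = marker, alpha = alpha, method = method,
                 counted_allele = g$counted_allele,
                 other_allele = g$other_allele,
                 centers = centers, beta = beta, varcomp = varcomp,
                 inclusion_prob = inclusion_prob, hyper = hyper,
                 n = n, trait = trait),
            class = "marker_effects")
}

#' @export
print.marker_effects <- function(x, ...) {
  cat("marker_effects (", x$method, "): ", length(x$alpha), " markers, ",
      x$n, " phenotyped samples, trait '", x$trait, "'\n", sep = "")
  if (x$method == "rrblup")
    cat(sprintf("  REML: sigma2_u = %.4g, sigma2_e = %.4g, lambda = %.4g\n",
                x$varcomp$sigma2_u, x$varcomp$sigma2_e, x$varcomp$lambda))
  else
    cat(sprintf(
      "  posterior: sigma2_alpha = %.4g, sigma2_e = %.4g, pi = %.2f\n",
      x$varcomp$sigma2_alpha, x$varcomp$sigma2_e, x$varcomp$pi))
  cat("  effect range: [", sprintf("%.4g", min(x$alpha)), ", ",
      sprintf("%.4g", max(x$alpha)), "]\n", sep = "")
  invisible(x)
}

#' @export
coef.marker_effects <- function(object, ...) object$alpha

#' Predict genetic values from estimated marker effects
#'
#' Returns \eqn{\hat{g}_i = \beta_0 + \sum_j (z_{ij} - \bar{z}_j)
#' \hat{\alpha}_j} for each sample of a genotype matrix, using the column
#' centres stored at fit time.  Covariate effects are not added (prediction
#' targets the genetic merit plus intercept).
#'
#' @param object a `marker_effects` fit.
#' @param newdata a [geno_matrix()] covering the fitted markers.
#' @param ... ignored.
#' @return named numeric vector of predictions.
#' @export
predict.marker_effects <- function(object, newdata, ...) {
  d <- impute_missing(newdata)$dosages
  if (!all(object$marker %in% colnames(d)))
    stop("newdata lacks fitted markers")
  d <- d[, object$marker, drop = FALSE]
  Zc <- sweep(d, 2, object$centers)
  mu <- if ("(Intercept)" %in% names(object$beta))
    object$beta[["(Intercept)"]] else object$beta[[1]]
  drop(mu + Zc %*% object$alpha)
}

#' Write an effect table
#'
#' Delimited `(marker, alpha[, inclusion_prob])` table.
#'
#' @param x a `marker_effects` fit.
#' @param path output path.
#' @param sep separator.
#' @export
write_effects <- function(x, path, sep = "\t") {
  df <- data.frame(marker = x$marker, alpha = unname(x$alpha))
  if (!is.null(x$inclusion_prob)) df$inclusion_prob <- x$inclusion_prob
  if (!is.null(x$counted_allele)) df$counted_allele <- x$counted_allele
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a two-column effects (or change) table
#'
#' Reads delimited `(marker, value)` tables as written by [write_effects()]
#' or [write_freq_change()]; the value column is located by name.
#'
#' @param path file path.
#' @param value column holding the values (`"alpha"` for effects,
#'   `"delta"` for changes).
#' @param sep separator (guessed when `NULL`).
#' @return data frame with at least columns `marker` and `value`.
#' @export
read_marker_table <- function(path, value = "alpha", sep = NULL) {
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  if (!"marker" %in% names(df)) names(df)[1] <- "marker"
  if (!value %in% names(df)) {
    num <- which(vapply(df, is.numeric, logical(1)))[1]
    names(df)[num] <- value
  }
  df$marker <- as.character(df$marker)
  df
}
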