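#' Simulation configuration
#'
#' Parameters of the forward-in-time study design: a historical drift-only
#' phase (random mating, no selection) followed by 20 generations of
#' breeding in which a selected population (truncation selection on
#' phenotype) is compared against an unselected control sharing the same
#' founders.  Defaults mirror a livestock-style design: 30 chromosomes of
#' 100 cM, 100 historical generations, n = 400 individuals per generation,
#' h2 = 0.5, 150 QTL and ~10,000 markers.
#'
#' Candidate loci are placed uniformly along the genome and drift through
#' the historical phase; markers are then ascertained uniformly among loci
#' with minor-allele frequency at least `maf_min` (mimicking array design),
#' and QTL are drawn from the remaining eligible loci, so QTL and marker
#' positions are disjoint.  QTL effects are standard normal, rescaled so the
#' additive variance in the founder sample hits the `h2` target (phenotypic
#' variance 1 at generation 0).
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_len chromosome length in cM (Haldane mapping: crossovers are
#'   Poisson with mean `chrom_len`/100 per meiosis).
#' @param n_hist historical drift generations.
#' @param n_gen breeding generations.
#' @param n individuals per generation (also the historical population
#'   size).
#' @param h2 narrow-sense heritability at generation 0, in (0, 1\].
#' @param n_qtl number of QTL.
#' @param m number of markers.
#' @param selected_fraction fraction of individuals (top of the phenotype
#'   distribution) used as parents under truncation selection.
#' @param maf_min marker/QTL ascertainment threshold on founder MAF.
#' @param candidate_factor candidate loci simulated per locus ultimately
#'   kept (head-room for ascertainment).
#' @param max_retries founder resampling attempts when ascertainment fails.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 30, chrom_len = 100, n_hist = 100,
                       n_gen = 20, n = 400, h2 = 0.5, n_qtl = 150,
                       m = 10020, selected_fraction = 0.2, maf_min = 0.05,
                       candidate_factor = 1.6, max_retries = 5) {
  stopifnot(h2 > 0, h2 <= 1, selected_fraction > 0, selected_fraction <= 1,
            n >= 2, n_qtl >= 1, m >= 1, n_chrom >= 1, chrom_len > 0,
            n_hist >= 0, n_gen >= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Desk-scale simulation preset
#'
#' A reduced genome used throughout the package's own power and calibration
#' studies: 5 chromosomes of 100 cM, 1,000 markers, 150 QTL, n = 200 per
#' generation, h2 = 0.5.  Chosen so that a full simulate-estimate-test
#' replicate runs in a couple of seconds, making replicated power studies
#' practical on a single core; the methods vignette discusses what this
#' scale does and does not probe.
#'
#' @param ... overrides passed to [sim_config()].
#' @return list of class `sim_config`.
#' @export
desk_scale_config <- function(...) {
  args <- list(n_chrom = 5, m = 1000, n = 200)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

#' Simulate a founder population
#'
#' Draws initial allele frequencies uniform on (0, 1), samples founder
#' haplotypes, runs `n_hist` generations of random-mating drift with
#' recombination, then ascertains markers and QTL (founder MAF at least
#' `maf_min`) and draws QTL effects scaled to the `h2` target.  Monomorphic
#' loci arising from drift are retained among candidates but never
#' ascertained.  If too few loci remain eligible (or the QTL variance is
#' degenerate) the founder simulation is resampled, with a warning, up to
#' `max_retries` times.
#'
#' @param cfg a [sim_config()].
#' @return An object of class `founder_pop` holding haplotypes, the locus
#'   table, marker/QTL assignments, QTL effects and the residual SD.
#' @export
simulate_founders <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  for (try in seq_len(cfg$max_retries)) {
    pop <- founders_once(cfg)
    if (!is.null(pop)) return(pop)
    warning("founder ascertainment failed (attempt ", try,
            "); resampling founders")
  }
  stop("could not ascertain ", cfg$m, " markers and ", cfg$n_qtl,
       " QTL at MAF >= ", cfg$maf_min, " after ", cfg$max_retries,
       " attempts")
}

founders_once <- function(cfg) {
  n_cand <- ceiling((cfg$m + cfg$n_qtl) * cfg$candidate_factor)
  # allocate candidates to chromosomes as evenly as possible
  per <- rep(n_cand %/% cfg$n_chrom, cfg$n_chrom)
  extra <- n_cand %% cfg$n_chrom
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1
  chr <- rep(seq_len(cfg$n_chrom), per)
  pos <- unlist(lapply(per, function(k) sort(runif(k, 0, cfg$chrom_len))))
  geno_map <- list(
    pos = pos + (chr - 1) * cfg$chrom_len,   # global coordinate for C code
    chr_start = as.integer(cumsum(c(0, per[-cfg$n_chrom]))),
    chr_end = as.integer(cumsum(per)),
    chr_lo = (seq_len(cfg$n_chrom) - 1) * cfg$chrom_len,
    chr_len = rep(cfg$chrom_len, cfg$n_chrom))

  p0 <- runif(n_cand)
  # loci x haplotypes layout (columns 2i-1, 2i are individual i)
  hap <- matrix(rbinom(2 * cfg$n * n_cand, 1, rep(p0, times = 2 * cfg$n)),
                nrow = n_cand, ncol = 2 * cfg$n)
  parents <- seq_len(cfg$n) - 1L
  for (g in seq_len(cfg$n_hist)) {
    hap <- wf_generation(hap, parents, cfg$n, geno_map$pos,
                         geno_map$chr_start, geno_map$chr_end,
                         geno_map$chr_lo, geno_map$chr_len)
  }
  freq <- rowMeans(hap)
  eligible <- which(pmin(freq, 1 - freq) >= cfg$maf_min)
  if (length(eligible) < cfg$m + cfg$n_qtl) return(NULL)
  pick <- sample(eligible, cfg$m + cfg$n_qtl)
  qtl_idx <- sort(pick[seq_len(cfg$n_qtl)])
  marker_idx <- sort(pick[-seq_len(cfg$n_qtl)])

  eff <- rnorm(cfg$n_qtl)
  bv <- hap_dosages(hap[qtl_idx, , drop = FALSE]) %*% eff
  vb <- var(as.vector(bv))
  if (vb <= 0) return(NULL)
  eff <- eff * sqrt(cfg$h2 / vb)
  sigma_e <- sqrt(1 - cfg$h2)

  structure(list(hap = hap, chr = chr, pos = pos, init_freq = p0,
                 geno_map = geno_map, qtl_idx = qtl_idx,
                 marker_idx = marker_idx, qtl_eff = eff,
                 sigma_e = sigma_e, cfg = cfg),
            class = "founder_pop")
}

#' @export
print.founder_pop <- function(x, ...) {
  cat("founder_pop:", x$cfg$n, "diploids,", length(x$pos),
      "candidate loci on", x$cfg$n_chrom, "chromosomes\n")
  cat("  ascertained:", length(x$marker_idx), "markers,",
      length(x$qtl_idx), "QTL\n")
  invisible(x)
}

#' Evolve a founder population for the breeding phase
#'
#' Each generation, individuals are phenotyped (true breeding value from the
#' QTL plus normal noise calibrated to the configured h2 at generation 0);
#' parents are either all individuals (`selection = "none"`, random mating)
#' or the top `selected_fraction` by phenotype (`"truncation"`), and the
#' next generation of constant size `n` is produced by recombinant gametes.
#' Generation 0 is the founder sample itself; all generations are recorded.
#'
#' @param pop a [simulate_founders()] result.
#' @param cfg optional [sim_config()] override (defaults to the one inside
#'   `pop`).
#' @param selection `"none"` or `"truncation"`.
#' @return An object of class `sim_study`: `geno` (a [geno_matrix()] of all
#'   generations' marker dosages with `group` = generation and a cM map),
#'   `pheno` (sample, generation, phenotype, bv), `qtl` truth table,
#'   `selection`, `cfg`.
#' @export
evolve <- function(pop, cfg = NULL, selection = c("none", "truncation")) {
  stopifnot(inherits(pop, "founder_pop"))
  selection <- match.arg(selection)
  cfg <- cfg %||% pop$cfg
  n <- cfg$n
  if (selection == "truncation" && floor(cfg$selected_fraction * n) < 2)
    stop("selected_fraction leaves fewer than 2 parents")
  gm <- pop$geno_map
  mk <- pop$marker_idx
  marker_ids <- sprintf("M%05d", seq_along(mk))
  map <- data.frame(marker = marker_ids, chr = pop$chr[mk],
                    pos = pop$pos[mk], stringsAsFactors = FALSE)

  n_rec <- cfg$n_gen + 1
  dos_list <- vector("list", n_rec)
  qtl_list <- vector("list", n_rec)
  ph_list <- vector("list", n_rec)
  hap <- pop$hap
  for (gen in 0:cfg$n_gen) {
    qd <- hap_dosages(hap[pop$qtl_idx, , drop = FALSE])
    bv <- as.vector(qd %*% pop$qtl_eff)
    phen <- bv + if (pop$sigma_e > 0) rnorm(n, 0, pop$sigma_e) else 0
    ids <- sprintf("G%02d_I%04d", gen, seq_len(n))
    d <- hap_dosages(hap[mk, , drop = FALSE])
    dimnames(d) <- list(ids, marker_ids)
    dos_list[[gen + 1]] <- d
    dimnames(qd) <- list(ids, sprintf("Q%04d", seq_along(pop$qtl_idx)))
    qtl_list[[gen + 1]] <- qd
    ph_list[[gen + 1]] <- data.frame(sample = ids, generation = gen,
                                     phenotype = phen, bv = bv,
                                     stringsAsFactors = FALSE)
    if (gen == cfg$n_gen) break
    parents <- if (selection == "none") seq_len(n) - 1L else
      sort(order(phen, decreasing = TRUE)[seq_len(floor(
        cfg$selected_fraction * n))]) - 1L
    hap <- wf_generation(hap, parents, n, gm$pos, gm$chr_start, gm$chr_end,
                         gm$chr_lo, gm$chr_len)
  }
  pheno <- do.call(rbind, ph_list)
  geno <- new_geno_matrix(do.call(rbind, dos_list),
                          group = pheno$generation, map = map)
  qtl_geno <- new_geno_matrix(do.call(rbind, qtl_list),
                              group = pheno$generation)
  qtl <- data.frame(qtl = colnames(qtl_geno$dosages),
                    chr = pop$chr[pop$qtl_idx], pos = pop$pos[pop$qtl_idx],
                    effect = pop$qtl_eff)
  structure(list(geno = geno, pheno = pheno, qtl = qtl,
                 qtl_geno = qtl_geno, selection = selection, cfg = cfg),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("sim_study (selection:", x$selection, ")\n")
  cat("  generations 0..", x$cfg$n_gen, ", n = ", x$cfg$n,
      " per generation\n", sep = "")
  cat("  markers:", ncol(x$geno$dosages), " QTL:", nrow(x$qtl),
      " h2:", x$cfg$h2, "\n")
  invisible(x)
}

#' Simulate a seed-paired selected/unselected study
#'
#' Runs the historical phase once, then evolves two populations from the
#' identical founder state and identical RNG stream: population A under
#' random mating and population B under truncation selection.  Their
#' generation-0 genotypes are bit-identical; they diverge only through the
#' action of selection.
#'
#' @param cfg a [sim_config()].
#' @param seed optional integer seed governing the whole study.
#' @return list of class `paired_study` with components `A` (unselected)
#'   and `B` (selected), both [evolve()] results.
#' @export
simulate_study <- function(cfg = desk_scale_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pop <- simulate_founders(cfg)
  s2 <- sample.int(.Machine$integer.max - 1, 1)
  A <- with_seed(s2, evolve(pop, cfg, "none"))
  B <- with_seed(s2, evolve(pop, cfg, "truncation"))
  structure(list(A = A, B = B, cfg = cfg, seed = seed),
            class = "paired_study")
}

#' Run the full test on a simulated study
#'
#' The analysis applied to every simulated population: estimate marker
#' effects from the genotypes and phenotypes of all recorded generations,
#' compute the allele-frequency change between generations `early` and
#' `late`, estimate the effective marker number, and run the
#' scale-corrected permutation test.
#'
#' @param study a [evolve()] result (one population).
#' @param estimator `"rrblup"` or `"bayesc"`.
#' @param early,late generation labels contrasted for frequency change.
#' @param ld_method `"simpleM"` or `"ld_decay"` for the effective marker
#'   number.
#' @param perms permutations for the test.
#' @param seed optional seed for the permutation stream.
#' @param covariates fixed effects absorbed before marker estimation.  The
#'   default absorbs per-generation means: with an intercept-only fit, each
#'   generation's mean phenotype noise loads onto between-generation marker
#'   frequency differences in the estimated effects, and the frequency
#'   change being tested is exactly such a between-generation contrast --
#'   the resulting effect/change coupling inflates the null.  Generation
#'   fixed effects remove it.
#' @param bayesc_args list of extra arguments for [fit_bayesc()].
#' @return A [ghat_test()] result.
#' @export
test_selection <- function(study, estimator = c("rrblup", "bayesc"),
                           early = 15, late = 20,
                           ld_method = c("simpleM", "ld_decay"),
                           perms = 1000, seed = NULL,
                           covariates = "factor(generation)",
                           bayesc_args = list()) {
  estimator <- match.arg(estimator)
  ld_method <- match.arg(ld_method)
  g <- study$geno
  fit <- if (estimator == "rrblup") {
    fit_rrblup(g, study$pheno, trait = "phenotype",
               covariates = covariates)
  } else {
    do.call(fit_bayesc, c(list(g = g, pheno = study$pheno,
                               trait = "phenotype",
                               covariates = covariates), bayesc_args))
  }
  ch <- frequency_change(g, early, late)
  meff <- if (ld_method == "simpleM") simple_m(g) else ld_decay(g)
  ghat_test(fit, ch, method = "scale", perms = perms, num_eff = meff,
            seed = seed)
}

#' Replicated power/calibration sweep
#'
#' The parameter-sweep harness: for each level of the swept parameter and
#' each replicate, simulates a seed-paired selected/unselected study,
#' analyses both populations with [test_selection()] and records the test
#' outcomes.  `summary()` reports, per level and population, the fraction
#' of replicates significant at `alpha` (power for the selected population,
#' type-I error for the unselected one).
#'
#' @param param which parameter to sweep: `"sample_size"` (n),
#'   `"heritability"` (h2), `"n_qtl"`, or `"marker_density"` (m).
#' @param levels numeric vector of levels for the swept parameter.
#' @param reps replicates per level.
#' @param base baseline [sim_config()] supplying the constant parameters.
#' @param estimator `"rrblup"` or `"bayesc"`.
#' @param perms permutations per test.
#' @param alpha significance level used in the summary.
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param ... passed to [test_selection()].
#' @return A data frame of class `ghat_sweep` with columns `param`,
#'   `level`, `rep`, `pop`, `ghat`, `p`, `m_eff`; failed replicates are
#'   dropped with a message and counted in `attr(, "n_failed")`.
#' @export
run_sweep <- function(param = c("sample_size", "heritability", "n_qtl",
                                "marker_density"),
                      levels, reps, base = desk_scale_config(),
                      estimator = "rrblup", perms = 1000, alpha = 0.01,
                      seed = 1, ...) {
  param <- match.arg(param)
  field <- c(sample_size = "n", heritability = "h2", n_qtl = "n_qtl",
             marker_density = "m")[[param]]
  stopifnot(reps >= 1, length(levels) >= 1)
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1,
                             length(levels) * reps),
                  nrow = length(levels))
  rows <- list()
  n_failed <- 0
  for (li in seq_along(levels)) {
    args <- unclass(base)
    args[[field]] <- levels[li]
    cfg <- do.call(sim_config, args[names(formals(sim_config))])
    for (ri in seq_len(reps)) {
      res <- tryCatch({
        study <- simulate_study(cfg, seed = seeds[li, ri])
        lapply(study[c("A", "B")], function(s)
          test_selection(s, estimator = estimator, perms = perms,
                         seed = seeds[li, ri], ...))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        n_failed <- n_failed + 1
        message("replicate dropped (level ", levels[li], ", rep ", ri,
                "): ", conditionMessage(res))
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        param = param, level = levels[li], rep = ri,
        pop = c("A_unselected", "B_selected"),
        ghat = vapply(res, `[[`, numeric(1), "ghat_obs"),
        p = vapply(res, `[[`, numeric(1), "p_value"),
        m_eff = vapply(res, `[[`, numeric(1), "num_eff"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("ghat_sweep", "data.frame"),
            alpha = alpha, n_failed = n_failed, seed = seed)
}

#' @export
summary.ghat_sweep <- function(object, alpha = attr(object, "alpha"), ...) {
  sp <- split(object, list(object$level, object$pop), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(param = d$param[1], level = d$level[1], pop = d$pop[1],
               n = nrow(d), reject = mean(d$p < alpha),
               nonreject = mean(d$p >= alpha))
  }))
  out <- out[order(out$pop, out$level), ]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "n_failed") <- attr(object, "n_failed")
  out
}

#' @export
print.ghat_sweep <- function(x, ...) {
  cat("ghat_sweep:", x$param[1], "sweep,",
      length(unique(x$level)), "level(s),",
      max(x$rep), "replicate(s); alpha =", attr(x, "alpha"), "\n")
  print(summary(x), row.names = FALSE)
  if (attr(x, "n_failed") > 0)
    cat("dropped replicates:", attr(x, "n_failed"), "\n")
  invisible(x)
}

#' Write a simulated study to files
#'
#' Per-generation genotypes in the delimited format, a VCF export of the
#' whole matrix, the marker map, phenotypes/breeding values and the QTL
#' truth table.
#'
#' @param study a [evolve()] result.
#' @param dir output directory (created if needed).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- study$geno
  for (gen in unique(g$group)) {
    write_genotypes(g[g$group == gen, ],
                    file.path(dir, sprintf("genotypes_gen%02d.csv", gen)))
  }
  write_vcf(g, file.path(dir, "genotypes.vcf"))
  write.table(g$map, file.path(dir, "map.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(study$pheno, file.path(dir, "phenotypes.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(study$qtl, file.path(dir, "qtl_truth.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}
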