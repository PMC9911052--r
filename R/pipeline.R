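#' Read a flat key-value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment; values are kept as
#' strings and coerced where the pipeline expects numbers.  Command-line
#' flags of the bundled `polyadapt` script override file values.
#'
#' @param path file path.
#' @return named list of character values.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3
  if (any(bad)) stop("cannot parse config line: ", lines[bad][1])
  vals <- lapply(kv, function(x) trimws(gsub('^"|"$', "", x[3])))
  names(vals) <- vapply(kv, `[`, character(1), 2)
  vals
}

#' Run the full selection-test pipeline
#'
#' Executes the four analysis steps on file inputs: read genotypes (and map
#' and phenotypes), mean-impute missing dosages, estimate marker effects on
#' the configured phenotype subset, compute the allele-frequency change
#' between the configured (default earliest vs latest) groups, estimate the
#' effective marker number, and run the permutation test.  All artifacts
#' (effects, frequency-change and LD tables, a one-row result plus JSON
#' sidecar, a log with per-stage timing, and an echo of the configuration)
#' are written to the output directory.
#'
#' Configuration keys (strings; defaults in parentheses):
#' `genotypes`, `format` (delimited), `map`, `phenotypes`, `trait`,
#' `covariates` (comma-separated), `mode` (all_phenotypes |
#' modern_phenotypes), `modern_groups` (comma-separated group labels whose
#' samples keep their phenotypes in modern mode), `estimator` (rrblup |
#' bayesc), `pi` (0.95), `iters` (10000), `burnin` (2000), `ld_method`
#' (simpleM | ld_decay), `var_fraction` (0.995), `max_r2` (0.03),
#' `max_win_snp` (100), `method` (scale | trim | naive), `perms` (1000),
#' `blocksize`, `level` (0.95), `early`, `late`, `group_column` (phenotype
#' column holding the group label of each sample), `seed`, `out_dir`
#' (required).
#'
#' @param config a named list (as from [read_run_config()]) or a path to a
#'   config file.
#' @return The [ghat_test()] result, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- read_run_config(config)
  cfg <- function(key, default = NULL) {
    if (!is.null(config[[key]])) config[[key]] else default
  }
  out_dir <- cfg("out_dir")
  if (is.null(out_dir)) stop("config key 'out_dir' is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "run.log")
  logcon <- file(logfile, open = "wt")
  on.exit(close(logcon), add = TRUE)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    writeLines(msg, logcon)
    message(msg)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
    say(sprintf("stage %-12s done in %.2fs", name,
                proc.time()[["elapsed"]] - t0))
    res
  }
  seed <- as.integer(cfg("seed", 1))
  set.seed(seed)

  # provenance record
  prov <- c(sprintf("polyadapt %s",
                    as.character(utils::packageVersion("polyadapt"))),
            sprintf("R %s", getRversion()),
            sprintf("seed = %d", seed),
            vapply(names(config), function(k)
              paste0(k, " = ", config[[k]]), character(1)))
  writeLines(prov, file.path(out_dir, "config_echo.txt"))

  g <- stage("read", {
    gg <- read_genotypes(cfg("genotypes"), format = cfg("format",
                                                        "delimited"))
    if (!is.null(cfg("map"))) gg$map <- validate_map(read_map(cfg("map")),
                                                     colnames(gg$dosages))
    gg
  })
  pheno <- stage("phenotypes", read_phenotypes(cfg("phenotypes")))
  grpcol <- cfg("group_column", "group")
  if (!grpcol %in% names(pheno))
    stop("phenotype table lacks group column '", grpcol, "'")
  g$group <- pheno[[grpcol]][match(rownames(g$dosages), pheno$sample)]

  g <- stage("impute", impute_missing(g))

  mode <- cfg("mode", "all_phenotypes")
  fit_pheno <- pheno
  if (mode == "modern_phenotypes") {
    keep_groups <- trimws(strsplit(cfg("modern_groups", ""), ",")[[1]])
    if (length(keep_groups) == 0)
      stop("modern_phenotypes mode needs 'modern_groups'")
    fit_pheno <- pheno[as.character(pheno[[grpcol]]) %in% keep_groups, ]
    say("modern-phenotype mode: ", nrow(fit_pheno), " of ", nrow(pheno),
        " samples keep phenotypes")
  }
  covs <- cfg("covariates")
  if (!is.null(covs)) covs <- trimws(strsplit(covs, ",")[[1]])

  estimator <- cfg("estimator", "rrblup")
  fit <- stage("effects", {
    if (estimator == "rrblup")
      fit_rrblup(g, fit_pheno, trait = cfg("trait"), covariates = covs)
    else
      fit_bayesc(g, fit_pheno, trait = cfg("trait"), covariates = covs,
                 pi = as.numeric(cfg("pi", 0.95)),
                 iters = as.integer(cfg("iters", 10000)),
                 burnin = as.integer(cfg("burnin", 2000)), seed = seed)
  })
  write_effects(fit, file.path(out_dir, "effects.tsv"))

  groups <- unique(g$group[!is.na(g$group)])
  ord <- order(suppressWarnings(as.numeric(groups)), groups)
  early <- cfg("early", as.character(groups[ord][1]))
  late <- cfg("late", as.character(groups[ord][length(groups)]))
  ch <- stage("freq_change",
              frequency_change(g, type_match(g$group, early),
                               type_match(g$group, late)))
  write_freq_change(ch, file.path(out_dir, "freq_change.tsv"))

  ld_method <- cfg("ld_method", "simpleM")
  meff <- stage("m_eff", {
    if (ld_method == "simpleM")
      simple_m(g, var_fraction = as.numeric(cfg("var_fraction", 0.995)))
    else
      ld_decay(g, max_win_snp = as.integer(cfg("max_win_snp", 100)),
               max_r2 = as.numeric(cfg("max_r2", 0.03)))
  })
  write_ld_summary(meff, file.path(out_dir, "ld_summary.tsv"))

  res <- stage("test", {
    bs <- cfg("blocksize")
    ghat_test(fit, ch, method = cfg("method", "scale"),
              perms = as.integer(cfg("perms", 1000)), num_eff = meff,
              blocksize = if (!is.null(bs)) as.integer(bs),
              level = as.numeric(cfg("level", 0.95)), seed = seed)
  })
  write_ghat_result(res, file.path(out_dir, "result.tsv"))
  say(sprintf("Ghat = %.6g, p = %.4g, direction = %s", res$ghat_obs,
              res$p_value, res$direction))
  invisible(res)
}

# coerce a label to the storage type of the group vector
type_match <- function(group, label) {
  if (is.numeric(group)) as.numeric(label) else label
}
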