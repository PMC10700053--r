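# Record, surface and report I/O, run configuration, and the command-line
# entry point.

recordColumns <- c("replicate_id", "seed", "x1", "x2", "x3", "g", "f", "m")

#' Read and write simulation record tables
#'
#' Records are stored as CSV with header
#' `replicate_id, seed, x1, x2, x3, g, f, m`; values round-trip at full
#' double precision. A file without the `m` column is accepted and `m` is
#' recomputed from `g`, `f` and the supplied [TargetSpec-class]. Malformed
#' rows are reported with their line numbers.
#'
#' @param path CSV file path.
#' @param target [TargetSpec-class] used to recompute a missing `m`.
#' @return `readRecords`: record data.frame. `writeRecords`: the path,
#'   invisibly.
#' @export
readRecords <- function(path, target = TargetSpec()) {
  if (!file.exists(path)) stop("record file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, sep = ",")
  need <- setdiff(recordColumns, "m")
  missing <- setdiff(need, names(dt))
  if (length(missing))
    stop("record file lacks required column(s): ",
         paste(missing, collapse = ", "),
         " (expected header: ", paste(recordColumns, collapse = ", "), ")")
  unknown <- setdiff(names(dt), recordColumns)
  if (length(unknown))
    stop("record file has unexpected column(s): ",
         paste(unknown, collapse = ", "))
  rec <- as.data.frame(dt)
  for (cn in intersect(recordColumns, names(rec))) {
    bad <- which(!is.finite(as.numeric(rec[[cn]])))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at data line(s) %s",
                   cn, paste(head(bad + 1L, 5), collapse = ", ")))
  }
  if (!"m" %in% names(rec))
    rec$m <- compositeTarget(rec$g, rec$f, target)
  rec[, recordColumns]
}

#' @rdname readRecords
#' @param rec record data.frame with the standard columns.
#' @export
writeRecords <- function(rec, path) {
  miss <- setdiff(setdiff(recordColumns, "m"), names(rec))
  if (length(miss))
    stop("records lack column(s): ", paste(miss, collapse = ", "))
  if (!"m" %in% names(rec)) rec$m <- compositeTarget(rec$g, rec$f)
  data.table::fwrite(rec[, recordColumns], path)
  invisible(path)
}

#' Read and write smoothed surfaces
#'
#' Surfaces are exported as CSV with columns
#' `x2, x3, g_hat, f_hat, m_hat, weight_mass, missing_flag`.
#'
#' @param surface a [KernelSurface-class].
#' @param path CSV file path.
#' @return `writeSurface`: the path, invisibly; `readSurface`: a
#'   [KernelSurface-class] (bandwidth metadata is not stored in the file
#'   and comes back as the default).
#' @export
writeSurface <- function(surface, path) {
  data.table::fwrite(surfaceTable(surface), path)
  invisible(path)
}

#' @rdname writeSurface
#' @export
readSurface <- function(path) {
  dt <- as.data.frame(data.table::fread(path, header = TRUE, sep = ","))
  need <- c("x2", "x3", "g_hat", "f_hat", "m_hat", "weight_mass",
            "missing_flag")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("surface file lacks column(s): ", paste(miss, collapse = ", "))
  new("KernelSurface", grid = data.frame(x2 = dt$x2, x3 = dt$x3),
      gHat = dt$g_hat, fHat = dt$f_hat, mHat = dt$m_hat,
      massG = as.numeric(dt$weight_mass), massF = rep(NA_real_, nrow(dt)),
      missing = as.logical(dt$missing_flag), bandwidths = Bandwidths(),
      method = "file")
}

# ---- run configuration ----------------------------------------------------

configDefaults <- function() {
  list(
    budget = list(total = 1e7, cost_cow = 4000, cost_bull = 3000),
    bounds = list(x2 = c(100L, 700L), x3 = c(3L, 30L)),
    target = list(weight = 50, horizon_weights = NULL),
    scheme = list(years = 15L, heritability = 0.3, additive_variance = 1,
                  founder_cows = NULL, founder_bulls = NULL,
                  dam_replacement = 0.25),
    smoothing = list(h0 = c(30, 1), f_divisor = 3, cv = FALSE),
    optimizer = list(n_sims = c(2000, 1500, 500), padding = 0.5,
                     factor = 0.5, tolerance = 1, max_iterations = 3L,
                     min_separation = 3, n_maxima_keep = 3L,
                     grid_step = c(1L, 1L)),
    evaluation = list(n_boot = 100L, subsample_size = NULL,
                      sizes = c(1000L, 10000L, 20000L, 60000L), n_rep = 50L),
    seed = 1L,
    out_dir = "."
  )
}

mergeConfig <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", full)
    if (is.list(defaults[[key]]) && !is.null(user[[key]])) {
      if (!is.list(user[[key]]))
        stop("configuration key must be a block: ", full)
      defaults[[key]] <- mergeConfig(defaults[[key]], user[[key]], c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration file, fills in the documented
#' defaults (10M budget at 4,000/3,000 housing costs, bounds 100-700 and
#' 3-30, inbreeding weight 50, initial bandwidths (30, 1) with the f
#' divisor 3 and halving schedule), validates every block, and rejects
#' unknown keys naming the offending key path. An empty file yields the
#' full default configuration.
#'
#' @param path file path (`.yaml`/`.yml`/`.json`); `NULL` for pure defaults.
#' @return a validated [RunConfig-class].
#' @export
loadConfig <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (is.null(user)) user <- list()
  }
  cfg <- mergeConfig(configDefaults(), user)
  bad <- function(key, why) stop(sprintf("invalid configuration: %s (%s)", key, why))

  if (length(cfg$bounds$x2) != 2L) bad("bounds.x2", "need a 2-integer range")
  if (length(cfg$bounds$x3) != 2L) bad("bounds.x3", "need a 2-integer range")
  if (any(cfg$smoothing$h0 <= 0)) bad("smoothing.h0", "bandwidths must be positive")
  if (cfg$smoothing$f_divisor <= 0) bad("smoothing.f_divisor", "must be positive")
  if (cfg$optimizer$factor <= 0 || cfg$optimizer$factor >= 1)
    bad("optimizer.factor", "must lie in (0, 1)")
  if (cfg$target$weight < 0) bad("target.weight", "must be non-negative")

  hw <- if (is.null(cfg$target$horizon_weights)) numeric(0) else {
    v <- unlist(cfg$target$horizon_weights)
    stats::setNames(as.numeric(v), names(v))
  }
  h0 <- cfg$smoothing$h0
  names(h0) <- if (length(h0) == 2) c("x2", "x3") else c("x1", "x2", "x3")[seq_along(h0)]

  budget <- BudgetModel(cfg$budget$total, cfg$budget$cost_cow, cfg$budget$cost_bull)
  bounds <- ParameterBounds(cfg$bounds$x2[1], cfg$bounds$x2[2],
                            cfg$bounds$x3[1], cfg$bounds$x3[2])
  target <- TargetSpec(cfg$target$weight, hw)
  scheme <- SchemeConfig(cfg$scheme$years, cfg$scheme$heritability,
                         cfg$scheme$additive_variance,
                         founderCows = if (is.null(cfg$scheme$founder_cows)) NA
                                       else cfg$scheme$founder_cows,
                         founderBulls = if (is.null(cfg$scheme$founder_bulls)) NA
                                        else cfg$scheme$founder_bulls,
                         damReplacement = cfg$scheme$dam_replacement)
  new("RunConfig", budget = budget, bounds = bounds, target = target,
      scheme = scheme,
      smoothing = list(h0 = Bandwidths(h0, fScale = 1 / cfg$smoothing$f_divisor),
                       cv = isTRUE(cfg$smoothing$cv)),
      optimizer = cfg$optimizer, evaluation = cfg$evaluation,
      seed = as.numeric(cfg$seed), outDir = as.character(cfg$out_dir))
}

#' Serialize an optimization report to JSON
#'
#' Per-iteration box, bandwidths, simulation count, optimum and the
#' convergence outcome, as structured text.
#'
#' @param report an [OptimizationReport-class].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeReport <- function(report, path) {
  its <- lapply(iterations(report), function(s) list(
    index = s$index,
    box = list(x2 = x2Range(s$box), x3 = x3Range(s$box)),
    bandwidths = list(g = as.list(hValues(s$bandwidths, "g")),
                      f = as.list(hValues(s$bandwidths, "f"))),
    n_new_simulations = s$nNew,
    optimum = list(par = as.list(s$optimum$par), value = s$optimum$value),
    local_maxima = s$maxima))
  out <- list(iterations = its,
              optimum = list(par = as.list(optimum(report)$par),
                             value = optimum(report)$value),
              converged = report@converged, reason = report@reason)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# Reproducibility manifest: config fingerprint, seed, versions.
writeManifest <- function(cfg, seed, path) {
  dump <- utils::capture.output(utils::str(cfg, max.level = 3))
  out <- list(config_hash = contentHash(dump), seed = seed,
              package_version = as.character(utils::packageVersion("breedoptim")),
              r_version = R.version.string,
              timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# ---- command-line interface ----------------------------------------------

cliUsage <- function() {
  paste(
    "usage: breedoptim <command> [options]",
    "",
    "commands:",
    "  simulate  --n <count> [--config <path>] [--seed <int>] --out <dir>",
    "            simulate records for sampled designs",
    "  smooth    --records <csv> [--config <path>] --out <dir>",
    "            smooth records into a target surface",
    "  optimize  --surface <csv> --out <dir>",
    "            brute-force argmax of an existing surface file",
    "  pipeline  [--config <path>] [--seed <int>] --out <dir>",
    "            full iterative optimization (synthetic objective unless a",
    "            scheme block is configured and --simulator is given)",
    "  evaluate  [--config <path>] [--seed <int>] --out <dir>",
    "            bootstrap comparison of smoothing methods",
    sep = "\n")
}

cliOptions <- function(args) {
  opts <- list(); i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (key %in% c("simulator")) { opts[[key]] <- TRUE; i <- i + 1L; next }
    if (i == length(args)) stop("missing value for --", key)
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

#' Command-line entry point
#'
#' In-process implementation of the `breedoptim` command line (see
#' `inst/cli/breedoptim.R` for the Rscript wrapper). Returns the exit code:
#' 0 success, 1 validation error, 2 runtime error. Every run writes a
#' `manifest.json` (config hash, seed, versions) next to its outputs.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit code, invisibly.
#' @export
cliMain <- function(args) {
  if (!length(args) || args[1] %in% c("-h", "--help", "help")) {
    message(cliUsage())
    return(invisible(0L))
  }
  cmd <- args[1]
  code <- tryCatch({
    opts <- cliOptions(args[-1])
    if (is.null(opts$out)) stop("--out is required")
    cfg <- loadConfig(opts$config)
    seed <- if (!is.null(opts$seed)) as.integer(opts$seed) else cfg@seed
    dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
    writeManifest(cfg, seed, file.path(opts$out, "manifest.json"))
    h0 <- cfg@smoothing$h0
    op <- cfg@optimizer

    if (cmd == "simulate") {
      n <- as.integer(opts$n)
      if (is.na(n) || n < 1) stop("--n must be a positive integer")
      params <- sampleParametrizations(n, cfg@bounds, cfg@budget, seed = seed)
      rec <- simulateRecords(params, cfg@scheme, cfg@target, seed = seed)
      writeRecords(rec, file.path(opts$out, "records.csv"))
    } else if (cmd == "smooth") {
      if (is.null(opts$records)) stop("--records is required")
      rec <- readRecords(opts$records, cfg@target)
      grid <- enumerateGrid(cfg@bounds, cfg@budget,
                            stepX2 = op$grid_step[1], stepX3 = op$grid_step[2])
      surf <- smoothSurface(rec, grid, h0, cfg@target)
      writeSurface(surf, file.path(opts$out, "surface.csv"))
    } else if (cmd == "optimize") {
      if (is.null(opts$surface)) stop("--surface is required")
      surf <- readSurface(opts$surface)
      opt <- bruteForceArgmax(surf)
      jsonlite::write_json(list(par = as.list(opt$par), value = opt$value),
                           file.path(opts$out, "optimum.json"),
                           auto_unbox = TRUE, digits = NA)
    } else if (cmd == "pipeline") {
      objective <- if (isTRUE(opts$simulator)) {
        objectiveFunction(cfg@scheme, cfg@target)
      } else objectiveFunction(quadraticObjective())
      report <- runPipeline(objective, cfg@bounds, cfg@budget, cfg@target,
                            h0 = h0, nSims = op$n_sims, factor = op$factor,
                            paddingFraction = op$padding,
                            tolerance = op$tolerance,
                            maxIterations = op$max_iterations,
                            minSeparation = op$min_separation,
                            nMaximaKeep = op$n_maxima_keep,
                            gridStep = op$grid_step, seed = seed)
      writeReport(report, file.path(opts$out, "report.json"))
      writeRecords(records(report), file.path(opts$out, "records.csv"))
    } else if (cmd == "evaluate") {
      ev <- cfg@evaluation
      obj <- quadraticObjective()
      n <- if (is.null(ev$subsample_size)) 2000L else 2L * ev$subsample_size
      rec <- generateSyntheticRecords(obj, n, cfg@bounds, cfg@budget,
                                      cfg@target, seed = seed)
      cmpr <- bootstrapCompare(rec, nBoot = ev$n_boot,
                               subsampleSize = if (is.null(ev$subsample_size))
                                 n %/% 2L else ev$subsample_size,
                               grid = enumerateGrid(cfg@bounds, cfg@budget,
                                                    stepX2 = 5L),
                               bandwidths = h0, target = cfg@target,
                               seed = seed)
      jsonlite::write_json(cmpr@summary, file.path(opts$out, "comparison.json"),
                           dataframe = "rows", digits = NA)
    } else {
      stop("unknown command: ", cmd)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    validation <- grepl("unknown|required|invalid|lacks|must be|not found",
                        conditionMessage(e))
    if (validation) 1L else 2L
  })
  invisible(code)
}
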