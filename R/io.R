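CONFIG_OPS <- c("simulate", "reduce", "fixedpoints", "basins", "scan",
                "branches", "survey")

#' Load a run configuration
#'
#' Reads a JSON (canonical) or YAML run configuration with the shape
#' \preformatted{
#' {
#'   "model":  "chemostat" | "elv",
#'   "params": { ...chemostat_params or elv_params fields... },
#'   "operation": { "name": "simulate" | "reduce" | "fixedpoints" |
#'                  "basins" | "scan" | "branches" | "survey", ...options },
#'   "seed": 0, "out_dir": "results"   // optional
#' }}
#' Unknown keys anywhere in the schema are rejected with a field-level
#' message; the parameter block is validated before anything runs.
#'
#' @param path Path to a \code{.json}, \code{.yaml} or \code{.yml} file.
#' @return A \code{run_config}: list with \code{model}, \code{params}
#'   (validated parameter object), \code{operation} (name + options),
#'   \code{seed}, \code{out_dir}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path)
  raw <- if (grepl("\\.(yaml|yml)$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  known_top <- c("model", "params", "operation", "seed", "out_dir")
  extra <- setdiff(names(raw), known_top)
  if (length(extra))
    stop("load_config: unknown top-level key(s): ",
         paste(extra, collapse = ", "),
         " (allowed: ", paste(known_top, collapse = ", "), ")")
  if (is.null(raw$model) || !raw$model %in% c("chemostat", "elv"))
    stop("load_config: 'model' must be \"chemostat\" or \"elv\"")
  if (is.null(raw$params) || !is.list(raw$params))
    stop("load_config: 'params' block is required")
  ctor <- if (raw$model == "chemostat") chemostat_params else elv_params
  allowed <- names(formals(ctor))
  extra <- setdiff(names(raw$params), allowed)
  if (length(extra))
    stop("load_config: unknown field(s) in params: ",
         paste(extra, collapse = ", "))
  params <- do.call(ctor, raw$params)
  op <- raw$operation
  if (is.null(op)) op <- list(name = "fixedpoints")
  if (is.null(op$name) || !op$name %in% CONFIG_OPS)
    stop("load_config: operation$name must be one of: ",
         paste(CONFIG_OPS, collapse = ", "))
  structure(list(model = raw$model, params = params, operation = op,
                 seed = if (is.null(raw$seed)) 0L else as.integer(raw$seed),
                 out_dir = if (is.null(raw$out_dir)) "." else raw$out_dir),
            class = "run_config")
}

#' Write a parameter object as a JSON config
#'
#' Numbers are serialised at full precision so that
#' params -> file -> params round-trips exactly.
#'
#' @param params A [chemostat_params()] or [elv_params()] object.
#' @param path Output path (\code{.json}).
#' @param operation Optional operation block to embed.
#' @return The path, invisibly.
#' @export
write_config <- function(params, path, operation = NULL) {
  model <- if (inherits(params, "chemostat_params")) "chemostat"
  else if (inherits(params, "elv_params")) "elv"
  else stop("write_config: unknown parameter class")
  cfg <- list(model = model, params = unclass(params))
  if (!is.null(operation)) cfg$operation <- operation
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Execute a run configuration and write its outputs
#'
#' Dispatches the configured operation to the corresponding package
#' function, writes the per-operation outputs (CSV/TSV/JSON) into
#' \code{dir}, and writes \code{manifest.json} echoing the configuration,
#' the seed, the package version and the files produced.
#'
#' @param cfg A \code{run_config} from [load_config()].
#' @param dir Output directory (created if missing); defaults to the
#'   config's \code{out_dir}.
#' @return The manifest list, invisibly.
#' @export
run_config_operation <- function(cfg, dir = cfg$out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  op <- cfg$operation
  opt <- function(nm, default) if (is.null(op[[nm]])) default else op[[nm]]
  files <- character(0)
  results <- list()

  if (op$name == "simulate") {
    init <- as.numeric(opt("init",
                           if (cfg$model == "chemostat")
                             c(10, 10, cfg$params$s0_in, cfg$params$s1_in,
                               cfg$params$s2_in)
                           else c(10, 10)))
    tr <- simulate_model(cfg$model, cfg$params, init,
                         t_end = opt("t_end", NULL),
                         n_out = opt("n_out", 201L))
    f <- file.path(dir, "trajectory.csv")
    write_trajectory_csv(tr, f); files <- f
    oc <- suppressWarnings(classify_outcome(tr))
    results$outcome <- list(survives1 = oc$survives1,
                            survives2 = oc$survives2,
                            converged = oc$converged,
                            final_state = as.numeric(oc$final_state))
  } else if (op$name == "reduce") {
    if (cfg$model != "chemostat")
      stop("run_config_operation: 'reduce' needs a chemostat config")
    mode <- opt("mode", "leading_order")
    lv <- reduce_to_lv(cfg$params, mode = mode)
    f1 <- file.path(dir, "elv_params.json")
    write_config(lv, f1)
    rep <- bistability_conditions_chemostat(cfg$params)
    f2 <- file.path(dir, "condition_report.json")
    jsonlite::write_json(unclass(rep), f2, auto_unbox = TRUE, digits = NA)
    files <- c(f1, f2)
    results$elv_params <- unclass(lv)
  } else if (op$name == "fixedpoints") {
    fps <- if (cfg$model == "elv") elv_fixed_points(cfg$params)
    else chemostat_fixed_points(cfg$params, seed = cfg$seed)
    tab <- fixed_points_table(fps)
    f <- file.path(dir, "fixed_points.tsv")
    utils::write.table(tab, f, sep = "\t", row.names = FALSE, quote = FALSE)
    files <- f
    results$n_fixed_points <- nrow(tab)
  } else if (op$name == "basins") {
    if (cfg$model != "elv")
      stop("run_config_operation: 'basins' needs an elv config")
    bm <- basin_map(cfg$params, grid = opt("grid", NULL),
                    t_end = opt("t_end", 400))
    files <- write_basin_map(bm, file.path(dir, "basins"))
    results$n_attractors <- length(bm$attractors)
  } else if (op$name == "scan") {
    rm_ <- scan_2d(cfg$model, op$axis1, op$axis2, cfg$params)
    files <- write_regime_map(rm_, file.path(dir, "scan"))
    results$counts <- as.list(rm_$counts)
  } else if (op$name == "branches") {
    if (cfg$model != "elv")
      stop("run_config_operation: 'branches' needs an elv config")
    bd <- branch_trace_1d(cfg$params,
                          as.numeric(opt("r_range", c(0.01, 0.06))),
                          n = opt("n", 121L))
    f1 <- file.path(dir, "branches.tsv")
    utils::write.table(bd$branches, f1, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    f2 <- file.path(dir, "bifurcations.json")
    jsonlite::write_json(bd$bifurcations, f2, auto_unbox = TRUE, digits = NA)
    files <- c(f1, f2)
    results$bifurcations <- bd$bifurcations
  } else if (op$name == "survey") {
    if (cfg$model != "chemostat")
      stop("run_config_operation: 'survey' needs a chemostat config")
    spec <- sampling_spec(n = opt("n", 1000L), seed = cfg$seed,
                          constrained = opt("constrained", FALSE),
                          ranges = opt("ranges", list()))
    sr <- survey_fraction(spec)
    f <- file.path(dir, "survey.json")
    jsonlite::write_json(list(n = sr$n, n_bistable = sr$n_bistable,
                              fraction = sr$fraction, ci = sr$ci,
                              n_indeterminate = sr$n_indeterminate,
                              constrained = spec$constrained),
                         f, auto_unbox = TRUE, digits = NA)
    files <- f
    results$fraction <- sr$fraction
  }

  manifest <- list(operation = op, model = cfg$model,
                   params = unclass(cfg$params), seed = cfg$seed,
                   package_version = as.character(
                     utils::packageVersion("mutucomp")),
                   files = basename(files), results = results)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
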