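#' Read a run configuration file
#'
#' Plain-text `key = value` format with `[section]` headers.  Recognised
#' sections and keys:
#' \preformatted{
#' [learning]      beta, lambda, gamma, epsilon, theta
#' [architecture]  n_regular, n_memory, n_q, init_low, init_high
#' [run]           task, mode, seed, n_networks, max_trials, shaping,
#'                 pro_only, out
#' }
#' Missing keys take the reference defaults (see [learning_params()] and
#' [architecture_spec()]); the tag persistence is always recomputed from
#' `lambda` and `gamma`.  Unknown sections or keys and out-of-range values
#' are rejected with a descriptive error.
#'
#' @param path path to the configuration file.
#' @return list of class `augment_config` with `params`, `arch_opts`, `run`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- ""
  kv <- list(learning = list(), architecture = list(), run = list())
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (!section %in% names(kv))
        stop("unknown config section '[", section, "]'")
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (!nzchar(section)) stop("key outside any [section]: ", ln)
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      kv[[section]][[key]] <- val
    } else stop("cannot parse config line: ", ln)
  }
  num <- function(sec, key, default) {
    v <- kv[[sec]][[key]]
    if (is.null(v)) return(default)
    x <- suppressWarnings(as.numeric(v))
    if (is.na(x)) stop("config key '", key, "' is not numeric: ", v)
    x
  }
  flag <- function(sec, key, default) {
    v <- kv[[sec]][[key]]
    if (is.null(v)) return(default)
    tolower(v) %in% c("true", "1", "yes")
  }
  known <- list(
    learning = c("beta", "lambda", "gamma", "epsilon", "theta"),
    architecture = c("n_regular", "n_memory", "n_q", "init_low", "init_high"),
    run = c("task", "mode", "seed", "n_networks", "max_trials", "shaping",
            "pro_only", "out"))
  for (sec in names(known)) {
    bad <- setdiff(names(kv[[sec]]), known[[sec]])
    if (length(bad))
      stop("unknown config key", if (length(bad) > 1) "s", " in [", sec,
           "]: ", paste(bad, collapse = ", "))
  }
  params <- learning_params(
    beta = num("learning", "beta", 0.15),
    lambda = num("learning", "lambda", 0.20),
    gamma = num("learning", "gamma", 0.90),
    epsilon = num("learning", "epsilon", 0.025),
    theta = num("learning", "theta", 2.5))
  arch_opts <- list(
    n_regular = as.integer(num("architecture", "n_regular", 3)),
    n_memory = as.integer(num("architecture", "n_memory", 4)),
    n_q = as.integer(num("architecture", "n_q", 3)),
    init_low = num("architecture", "init_low", -0.25),
    init_high = num("architecture", "init_high", 0.25))
  if (arch_opts$init_low >= arch_opts$init_high)
    stop("init_low must be smaller than init_high")
  run <- list(
    task = if (is.null(kv$run$task)) "saccade" else kv$run$task,
    mode = kv$run$mode,
    seed = as.integer(num("run", "seed", 1)),
    n_networks = as.integer(num("run", "n_networks", 100)),
    max_trials = as.integer(num("run", "max_trials", 25000)),
    shaping = flag("run", "shaping", TRUE),
    pro_only = flag("run", "pro_only", FALSE),
    out = kv$run$out)
  if (!run$task %in% c("saccade", "category", "classification",
                       "vibrotactile"))
    stop("unknown task '", run$task, "'")
  structure(list(params = params, arch_opts = arch_opts, run = run),
            class = "augment_config")
}

#' Execute a configured experiment
#'
#' Convenience driver: builds the architecture for the task's input
#' dimension, trains the configured number of networks and, if `run$out`
#' is set, writes the result files.
#'
#' @param config an `augment_config` from [load_config()].
#' @return the [run_experiment()] result, invisibly if written to disk.
#' @export
run_config <- function(config) {
  r <- config$run
  extra <- list()
  if (r$task == "vibrotactile" && !is.null(r$mode)) extra$mode <- r$mode
  if (r$task == "saccade" && isTRUE(r$pro_only)) extra$pro_only <- TRUE
  env0 <- make_env(r$task, seed = 0L)
  arch <- do.call(architecture_spec,
                  c(list(n_inst = env_n_inputs(env0$ptr)), config$arch_opts))
  args <- c(list(task = r$task, n_networks = r$n_networks, seed = r$seed,
                 max_trials = r$max_trials, params = config$params),
            if (r$task != "classification")
              c(list(arch = arch, shaping = r$shaping), extra))
  res <- do.call(run_experiment, args)
  if (!is.null(r$out)) {
    write_results(res, r$out, config = config)
    return(invisible(res))
  }
  res
}

#' Write experiment results to a directory
#'
#' Writes `summary.txt` (key: value lines), `networks.tsv` (per-network
#' convergence table) and, when available, a `config.txt` snapshot that
#' reproduces the run.
#'
#' @param result an `augment_experiment` from [run_experiment()].
#' @param dir output directory (created if missing).
#' @param config optional `augment_config` to snapshot.
#' @return invisibly, the paths written.
#' @export
write_results <- function(result, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- result$summary
  sfile <- file.path(dir, "summary.txt")
  writeLines(c(
    paste0("task: ", s$task),
    paste0("n_networks: ", s$n_networks),
    paste0("n_converged: ", s$n_converged),
    paste0("fraction_converged: ", format(s$fraction_converged, digits = 6)),
    paste0("fraction_ci_low: ", format(s$fraction_ci[1], digits = 6)),
    paste0("fraction_ci_high: ", format(s$fraction_ci[2], digits = 6)),
    paste0("median_trials: ", s$median_trials),
    paste0("median_fix: ", s$median_fix),
    paste0("median_go: ", s$median_go),
    paste0("master_seed: ", result$seed)), sfile)
  nfile <- file.path(dir, "networks.tsv")
  utils::write.table(result$networks, nfile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(sfile, nfile)
  if (!is.null(config)) {
    cfile <- file.path(dir, "config.txt")
    p <- config$params
    a <- config$arch_opts
    r <- config$run
    writeLines(c(
      "[learning]",
      sprintf("beta = %g", p$beta), sprintf("lambda = %g", p$lambda),
      sprintf("gamma = %g", p$gamma), sprintf("epsilon = %g", p$epsilon),
      sprintf("theta = %g", p$theta),
      "[architecture]",
      sprintf("n_regular = %d", a$n_regular),
      sprintf("n_memory = %d", a$n_memory),
      sprintf("n_q = %d", a$n_q),
      sprintf("init_low = %g", a$init_low),
      sprintf("init_high = %g", a$init_high),
      "[run]",
      sprintf("task = %s", r$task),
      if (!is.null(r$mode)) sprintf("mode = %s", r$mode),
      sprintf("seed = %d", r$seed),
      sprintf("n_networks = %d", r$n_networks),
      sprintf("max_trials = %d", r$max_trials),
      sprintf("shaping = %s", tolower(r$shaping)),
      sprintf("pro_only = %s", tolower(r$pro_only))), cfile)
    paths <- c(paths, cfile)
  }
  invisible(paths)
}

#' Read back a results summary
#' @param dir directory written by [write_results()].
#' @return named list of the summary fields.
#' @export
read_results <- function(dir) {
  lines <- readLines(file.path(dir, "summary.txt"))
  keys <- sub(":.*$", "", lines)
  vals <- trimws(sub("^[^:]*:", "", lines))
  out <- as.list(vals)
  names(out) <- keys
  for (k in setdiff(keys, "task")) {
    v <- suppressWarnings(as.numeric(out[[k]]))
    if (!is.na(v)) out[[k]] <- v
  }
  nets <- utils::read.delim(file.path(dir, "networks.tsv"))
  for (k in c("trials", "fix", "go"))
    if (k %in% names(nets)) nets[[k]] <- as.integer(nets[[k]])
  out$networks <- nets
  out
}
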