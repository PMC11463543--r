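#' Run configuration
#'
#' Bundle of the pipeline-wide thresholds and bookkeeping: the log2
#' fold-change cutoff and q-value cutoff used for enrichment calls, the ipTM
#' cutoff used by the motif screen, the RNG seed, named input/output paths
#' and stage toggles.
#'
#' @param lfc_cutoff log2 fold-change cutoff for an enrichment call
#'   (log2 units, must be > 0). Default 1.0.
#' @param q_cutoff BH-adjusted q-value cutoff, in (0, 1). Default 0.01.
#' @param iptm_cutoff ipTM screening cutoff, in (0, 1); a peptide passes
#'   only with a score strictly above it. Default 0.6.
#' @param rng_seed integer seed for all stochastic stages.
#' @param paths named character vector or list of input/output paths.
#' @param stages named logical vector of stage toggles.
#' @return an object of class \code{run_config}.
#' @export
run_config <- function(lfc_cutoff = 1.0, q_cutoff = 0.01, iptm_cutoff = 0.6,
                       rng_seed = 1L, paths = list(), stages = list()) {
  if (!is.numeric(lfc_cutoff) || length(lfc_cutoff) != 1L || lfc_cutoff <= 0)
    stop("lfc_cutoff must be a single positive number")
  if (!is.numeric(q_cutoff) || q_cutoff <= 0 || q_cutoff >= 1)
    stop("q_cutoff must lie strictly between 0 and 1")
  if (!is.numeric(iptm_cutoff) || iptm_cutoff <= 0 || iptm_cutoff >= 1)
    stop("iptm_cutoff must lie strictly between 0 and 1")
  structure(list(
    lfc_cutoff = as.numeric(lfc_cutoff),
    q_cutoff = as.numeric(q_cutoff),
    iptm_cutoff = as.numeric(iptm_cutoff),
    rng_seed = as.integer(rng_seed),
    paths = as.list(paths),
    stages = as.list(stages)
  ), class = "run_config")
}

#' Write a run configuration as a flat key/value text file
#'
#' One `key = value` pair per line; paths and stage toggles are written with
#' `path.` / `stage.` prefixes. The format round-trips losslessly through
#' [read_run_config()].
#'
#' @param cfg a \code{run_config}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  num <- function(x) format(x, digits = 17, scientific = FALSE)
  lines <- c(
    paste0("lfc_cutoff = ", num(cfg$lfc_cutoff)),
    paste0("q_cutoff = ", num(cfg$q_cutoff)),
    paste0("iptm_cutoff = ", num(cfg$iptm_cutoff)),
    paste0("rng_seed = ", cfg$rng_seed)
  )
  if (length(cfg$paths))
    lines <- c(lines, paste0("path.", names(cfg$paths), " = ",
                             unlist(cfg$paths)))
  if (length(cfg$stages))
    lines <- c(lines, paste0("stage.", names(cfg$stages), " = ",
                             ifelse(unlist(cfg$stages), "true", "false")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key/value run configuration
#'
#' @param path config file written by [write_run_config()].
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^\\s*([^=]+?)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  pick <- function(k) vals[match(k, keys)]
  is_path <- startsWith(keys, "path.")
  is_stage <- startsWith(keys, "stage.")
  paths <- as.list(vals[is_path])
  names(paths) <- sub("^path\\.", "", keys[is_path])
  stages <- as.list(vals[is_stage] == "true")
  names(stages) <- sub("^stage\\.", "", keys[is_stage])
  run_config(
    lfc_cutoff = as.numeric(pick("lfc_cutoff")),
    q_cutoff = as.numeric(pick("q_cutoff")),
    iptm_cutoff = as.numeric(pick("iptm_cutoff")),
    rng_seed = as.integer(pick("rng_seed")),
    paths = paths, stages = stages
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config: lfc_cutoff =", x$lfc_cutoff,
      "| q_cutoff =", x$q_cutoff,
      "| iptm_cutoff =", x$iptm_cutoff,
      "| seed =", x$rng_seed, "\n")
  invisible(x)
}

# stage-tagged logging to stderr
log_stage <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

# deterministic substream seed derived from a base seed and a stream name,
# kept below 2^31 so it is a valid R integer seed
substream_seed <- function(seed, name) {
  m <- 2147483629
  h <- 17
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% m
  as.integer((abs(as.numeric(seed)) %% m * 131 + h) %% m)
}

# evaluate expr under a named substream of the base seed, restoring RNG state
with_substream <- function(seed, name, expr) {
  withr::with_seed(substream_seed(seed, name), expr)
}
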