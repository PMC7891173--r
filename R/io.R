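# Readers and writers: TSV trajectory/summary tables ('.' decimal, tab
# delimiter, header row, bit-exact re-writable), JSON/YAML config parsing with
# strict key validation, and run manifests with file checksums.

.scenario_keys <- c("mating", "p", "q", "s1", "s2", "p_t", "q_t", "s1_t", "s2_t")

.read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML config requires the 'yaml' package; use JSON instead", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Parse and validate a scenario or simulation config file
#'
#' Reads a JSON (or YAML) file and returns a validated [scenario_params()] or
#' [sim_config()] object. A file whose keys all belong to the deterministic
#' scenario schema (`mating`, `p`, `q`, `s1`, `s2`, per-year series) is
#' parsed as a scenario; a file using simulator keys (`n_breeding`,
#' `years`, `rho`, ...) is parsed as a simulation config. Unknown keys are
#' rejected by name.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return A `scenario_params` or `sim_config` object.
#' @export
parse_config <- function(path) {
  lst <- .read_config_file(path)
  if (!is.list(lst) || is.null(names(lst)) || any(names(lst) == "")) {
    stop("config must be a mapping of named keys", call. = FALSE)
  }
  keys <- names(lst)
  sim_keys <- names(formals(sim_config))
  if (all(keys %in% .scenario_keys)) {
    for (k in c("p", "q", "s1")) {
      if (is.null(lst[[k]])) {
        stop("scenario config is missing required key '", k, "'", call. = FALSE)
      }
    }
    if (is.null(lst$mating)) lst$mating <- "uncontrolled"
    do.call(scenario_params, lst)
  } else if (all(keys %in% sim_keys)) {
    do.call(sim_config, lst)
  } else {
    bad <- setdiff(keys, union(.scenario_keys, sim_keys))
    stop("config contains unknown key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
}

#' Write a config object back to JSON
#'
#' Configs written by the tool re-parse to equal objects
#' (round-trip property).
#'
#' @param config a `scenario_params` or `sim_config` object.
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  lst <- unclass(config)
  if (inherits(config, "scenario_params")) {
    lst <- c(lst[c("mating", "p", "q", "s1")],
             if (!is.null(config$s2)) list(s2 = config$s2),
             Filter(Negate(is.null),
                    stats::setNames(config$series,
                                    paste0(names(config$series), "_t"))))
  }
  jsonlite::write_json(Filter(Negate(is.null), lst), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a trajectory as TSV with a JSON scenario sidecar
#'
#' Columns `year`, `B`, `P`, `dB`, `dP`, `D`; tab-delimited, `'.'` decimal,
#' header row. The scenario parameters are echoed to `<path>.json`.
#'
#' @param trajectory a `bee_trajectory` from [iterate_gene_flow()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "bee_trajectory"))
  utils::write.table(as.data.frame(trajectory)[c("year", "B", "P", "dB", "dP", "D")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_config(attr(trajectory, "params"), paste0(path, ".json"))
  invisible(path)
}

#' Write per-replicate simulation summaries as TSV
#'
#' @param sim a `bee_sim` from [simulate_breeding()].
#' @param path output TSV path (all replicates, long format).
#' @return `path`, invisibly.
#' @export
write_sim_summary <- function(sim, path) {
  stopifnot(inherits(sim, "bee_sim"))
  utils::write.table(sim$summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a run manifest with output checksums
#'
#' Records the package version, timestamp, seed(s), a config echo and an
#' inventory of the produced files with MD5 checksums; re-running with the
#' manifest's seed and config reproduces identical checksums.
#'
#' @param files character vector of produced files.
#' @param seed the seed(s) used.
#' @param config the config object used (echoed into the manifest).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(files, seed, config, path) {
  inv <- lapply(files, function(f) {
    list(file = basename(f), md5 = unname(tools::md5sum(f)))
  })
  manifest <- list(
    tool = "beeflow",
    version = as.character(utils::packageVersion("beeflow")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = Filter(Negate(is.null), unclass(config)),
    outputs = inv
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
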