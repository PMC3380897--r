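#' Load a network configuration from a JSON file
#'
#' The file mirrors [network_config()] field-for-field; absent keys fall
#' back to the published defaults.  `conductances` may name any subset of
#' the 12 couplings.  Values outside the printed plausible ranges produce
#' warnings, unknown keys a hard error.  An empty file (or `{}`) yields the
#' full default preset.
#'
#' @param path JSON file path
#' @return a `tg_config`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  obj <- if (nchar(trimws(txt)) == 0) list() else
    jsonlite::fromJSON(txt, simplifyVector = TRUE)
  known <- c("n_ex", "n_inf", "n_ins", "conductances", "connectivity", "p",
             "background", "dt", "duration", "warmup", "record_dt", "seed",
             "conductance_scaling", "mg_conc", "synaptic_delay",
             "neuron_ex", "neuron_in", "kinetics", "stimulus")
  bad <- setdiff(names(obj), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  args <- obj[setdiff(names(obj), c("conductances", "stimulus", "neuron_ex",
                                    "neuron_in", "kinetics"))]
  if (!is.null(obj$conductances)) args$conductances <- unlist(obj$conductances)
  if (!is.null(obj$synaptic_delay)) args$synaptic_delay <- unlist(obj$synaptic_delay)
  if (!is.null(obj$neuron_ex)) args$neuron_ex <- do.call(neuron_params, obj$neuron_ex)
  if (!is.null(obj$neuron_in)) args$neuron_in <- do.call(neuron_params, obj$neuron_in)
  cfg <- do.call(network_config, args)
  validate_config(cfg, warn_ranges = TRUE)
  attr(cfg, "stimulus") <- if (!is.null(obj$stimulus))
    do.call(stimulus_protocol, obj$stimulus) else NULL
  cfg
}

#' Save a configuration as JSON
#'
#' Round-trips through [load_config()]: `load_config(save_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param config a `tg_config`
#' @param path output file
#' @param stimulus optional [stimulus_protocol()] stored alongside
#' @return `path`, invisibly
#' @export
save_config <- function(config, path, stimulus = NULL) {
  stopifnot(inherits(config, "tg_config"))
  obj <- list(n_ex = config$n_ex, n_inf = config$n_inf, n_ins = config$n_ins,
              conductances = as.list(config$conductances),
              connectivity = config$connectivity, p = config$p,
              background = config$background,
              neuron_ex = unclass(config$neuron_ex),
              neuron_in = unclass(config$neuron_in),
              conductance_scaling = config$conductance_scaling,
              mg_conc = config$mg_conc,
              synaptic_delay = as.list(config$synaptic_delay),
              dt = config$dt,
              duration = config$duration, warmup = config$warmup,
              record_dt = config$record_dt, seed = config$seed)
  if (!is.null(stimulus)) obj$stimulus <- unclass(stimulus)[c("amplitude",
                                                              "onset",
                                                              "duration")]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# stable content hash of an arbitrary R object (via its serialized JSON)
tg_config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  save_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Write simulation results to a directory
#'
#' Writes spikes as TSV (`neuron_id`, `population`, `time_ms`; times with 3
#' decimals), the LFP and EX traces as TSV with a time axis, and a JSON run
#' manifest carrying the configuration snapshot, seed, package version and
#' content hashes of every file, sufficient to re-run bit-identically.
#'
#' @param sim a `tg_sim`
#' @param dir output directory (created if missing)
#' @return named vector of written file paths, invisibly
#' @export
write_results <- function(sim, dir) {
  stopifnot(inherits(sim, "tg_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(spikes = file.path(dir, "spikes.tsv"),
             lfp = file.path(dir, "lfp.tsv"),
             v_ex = file.path(dir, "v_ex.tsv"),
             manifest = file.path(dir, "manifest.json"))
  sp <- sim$spikes
  sp$time <- sprintf("%.3f", sp$time)
  names(sp) <- c("neuron_id", "population", "time_ms")
  write.table(sp, paths[["spikes"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(time_ms = sprintf("%.3f", sim$time),
                         lfp_mv = sim$lfp),
              paths[["lfp"]], sep = "\t", quote = FALSE, row.names = FALSE)
  vex <- as.data.frame(sim$v_ex)
  names(vex) <- paste0("ex", seq_len(ncol(vex)))
  write.table(cbind(time_ms = sprintf("%.3f", sim$time), vex),
              paths[["v_ex"]], sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    package = "thetagamma",
    version = as.character(packageVersion("thetagamma")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = sim$config$seed,
    config_hash = tg_config_hash(sim$config),
    config = jsonlite::fromJSON(paste(readLines(save_config(
      sim$config, tempfile(fileext = ".json"), sim$stimulus)),
      collapse = "\n")),
    stimulus = unclass(sim$stimulus)[c("amplitude", "onset", "duration")],
    files = lapply(paths[setdiff(names(paths), "manifest")], function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read spikes written by [write_results()]
#'
#' @param dir results directory
#' @return data.frame with `neuron`, `population`, `time`
#' @export
read_spikes <- function(dir) {
  sp <- read.table(file.path(dir, "spikes.tsv"), header = TRUE, sep = "\t",
                   colClasses = c("integer", "character", "numeric"))
  names(sp) <- c("neuron", "population", "time")
  sp
}

#' Re-run a simulation from a manifest
#'
#' @param manifest_path path to a `manifest.json` from [write_results()]
#' @return a `tg_sim`
#' @export
rerun_from_manifest <- function(manifest_path) {
  man <- jsonlite::fromJSON(manifest_path)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(man$config, tmp, auto_unbox = TRUE, digits = NA)
  cfg <- load_config(tmp)
  stim <- attr(cfg, "stimulus")
  if (is.null(stim)) stim <- stimulus_protocol()
  run_simulation(build_network(cfg), stim)
}

#' Write an experiment table as TSV
#'
#' @param table a `tg_experiment_table` (or any data.frame)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_experiment_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
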