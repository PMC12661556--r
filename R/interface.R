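# Configuration and trajectory-log I/O. Configs are a single YAML dialect;
# logs are plain delimited text with a commented YAML header, so every run
# is reconstructible from (config, seed) and logs survive any text tooling.

run_config_defaults <- function() {
  list(
    method = "sst2",
    seed = 1L,
    start_rung = NULL,
    initial_weights = NULL,
    ladder = list(t_min = 280, t_max = 540, t_ref = 300, n_rungs = 10L,
                  n_below_ref = NULL),
    integrator = list(timestep = 0.01, friction = 1.0),
    schedule = list(exchange_interval = 20L, n_segments = 1000L,
                    weight_update = "averaged",
                    weight_refresh_interval = 500L,
                    burn_in_fraction = 0.10),
    system = list(d_solute = 10L, d_solvent = 0L, potential = "harmonic",
                  k_solute = 1, k_solvent = 1, barrier = 0,
                  well_separation = 2, coupling = 0),
    flags = list(omega_exclusion = FALSE, monitor_variant = "radical")
  )
}

merge_config <- function(defaults, given, path = character()) {
  for (key in names(given)) {
    if (!key %in% names(defaults)) {
      stop("unrecognized option: ", paste(c(path, key), collapse = "."))
    }
    if (is.null(given[[key]])) next   # null means "use the default"
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]], given[[key]],
                                      c(path, key))
    } else {
      defaults[[key]] <- given[[key]]
    }
  }
  defaults
}

#' Assemble and validate a run configuration
#'
#' All knobs of a tempering run in one validated object: method, ladder
#' bounds, integrator settings, exchange/weight schedule, toy-system spec
#' and flags. Unspecified keys take the documented defaults (friction 1,
#' timestep 0.01, exchange every 20 steps, 10% burn-in, averaged weight
#' updates). Unknown keys are rejected.
#'
#' @param ... Named top-level keys (`method`, `seed`, `start_rung`,
#'   `initial_weights`) or named blocks (`ladder`, `integrator`, `schedule`,
#'   `system`, `flags`) given as lists; see [run_config_defaults] in the
#'   source for the full key set.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- merge_config(run_config_defaults(), list(...))
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (!cfg$method %in% c("st", "sst1", "sst2")) {
    stop("method: must be one of st, sst1, sst2")
  }
  lb <- cfg$ladder
  if (!(lb$t_min > 0)) stop("t_min: must be > 0")
  if (lb$t_ref < lb$t_min) stop("t_ref: must be >= t_min")
  if (lb$t_ref > lb$t_max) stop("t_ref: must be <= t_max")
  if (lb$n_rungs < 2) stop("n_rungs: must be >= 2")
  if (cfg$integrator$timestep <= 0) stop("timestep: must be > 0")
  if (cfg$integrator$friction <= 0) stop("friction: must be > 0")
  sc <- cfg$schedule
  if (sc$exchange_interval < 1) stop("exchange_interval: must be >= 1")
  if (sc$n_segments < 0) stop("n_segments: must be >= 0")
  if (!sc$weight_update %in% c("on_the_fly", "averaged", "fixed")) {
    stop("weight_update: must be one of on_the_fly, averaged, fixed")
  }
  if (sc$burn_in_fraction < 0 || sc$burn_in_fraction >= 1) {
    stop("burn_in_fraction: must be in [0, 1)")
  }
  if (!cfg$flags$monitor_variant %in% c("radical", "printed")) {
    stop("monitor_variant: must be radical or printed")
  }
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration file
#'
#' @param path File path of a YAML run configuration.
#' @return [parse_config()] returns a validated `run_config`;
#'   [write_config()] returns `path` invisibly.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  given <- yaml::read_yaml(path)
  cfg <- merge_config(run_config_defaults(), given)
  validate_run_config(cfg)
}

#' @rdname parse_config
#' @param cfg A `run_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  writeLines(yaml::as.yaml(unclass(cfg), precision = 15), path)
  invisible(path)
}

#' Build the toy system and ladder of a configuration and run it
#'
#' @param cfg A `run_config`.
#' @return A `trajectory_log`; see [run_tempering()].
#' @export
run_from_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  system <- do.call(toy_system, cfg$system)
  lb <- cfg$ladder
  ladder <- build_ladder(lb$t_min, lb$t_max, lb$t_ref, lb$n_rungs,
                         lb$n_below_ref)
  run_tempering(system, ladder, cfg)
}

fmt_full <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write / read a trajectory log
#'
#' Logs are tab-separated text: a commented header carrying the YAML config
#' echo, seed, unit system and weight-table history, followed by one row
#' per exchange attempt. Floats are written at full (17 significant digit)
#' precision so the round trip is lossless.
#'
#' @param log A `trajectory_log` from [run_tempering()].
#' @param path Output file path.
#' @return [write_log()] returns `path` invisibly; [read_log()] returns the
#'   reconstructed `trajectory_log`.
#' @export
write_log <- function(log, path) {
  stopifnot(inherits(log, "trajectory_log"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- log$header
  writeLines(c(
    "# soltemper trajectory log v1",
    paste0("# version: ", hdr$version),
    paste0("# unit_system: ", hdr$unit_system),
    paste0("# seed: ", hdr$seed),
    "# config:",
    paste0("#   ", strsplit(yaml::as.yaml(unclass(hdr$config), precision = 15),
                            "\n")[[1]])
  ), con)
  wh <- log$weights_history
  if (!is.null(wh) && nrow(wh) > 0) {
    for (i in seq_len(nrow(wh))) {
      writeLines(paste0("# weights ", rownames(wh)[i], ": ",
                        paste(fmt_full(wh[i, ]), collapse = " ")), con)
    }
  }
  rec <- log$records
  writeLines(paste(names(rec), collapse = "\t"), con)
  if (nrow(rec) > 0) {
    cols <- lapply(rec, function(col) {
      if (is.numeric(col)) fmt_full(col) else as.character(col)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' @rdname write_log
#' @param expect_unit Unit system the caller works in; a log written in a
#'   different unit system is refused.
#' @export
read_log <- function(path, expect_unit = "reduced") {
  lines <- readLines(path)
  if (length(lines) == 0 || lines[1] != "# soltemper trajectory log v1") {
    stop("corrupt log: missing header")
  }
  is_comment <- startsWith(lines, "#")
  n_hdr <- which(!is_comment)[1]
  if (is.na(n_hdr)) stop("corrupt log: no column header")
  hdr_lines <- lines[seq_len(n_hdr - 1)]

  get_field <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), hdr_lines, value = TRUE)
    sub(paste0("^# ", key, ": "), "", ln[1])
  }
  unit_system <- get_field("unit_system")
  if (!identical(unit_system, expect_unit)) stop("unit mismatch")
  seed <- as.integer(get_field("seed"))
  version <- get_field("version")

  cfg_start <- which(hdr_lines == "# config:")[1]
  cfg_lines <- character(0)
  if (!is.na(cfg_start)) {
    j <- cfg_start + 1
    while (j <= length(hdr_lines) && startsWith(hdr_lines[j], "#   ")) {
      cfg_lines <- c(cfg_lines, substring(hdr_lines[j], 5))
      j <- j + 1
    }
  }
  cfg <- validate_run_config(merge_config(run_config_defaults(),
                                          yaml::yaml.load(paste(cfg_lines, collapse = "\n"))))

  w_lines <- grep("^# weights ", hdr_lines, value = TRUE)
  wh <- NULL
  if (length(w_lines) > 0) {
    labels <- sub("^# weights ([^:]+): .*$", "\\1", w_lines)
    vals <- lapply(strsplit(sub("^# weights [^:]+: ", "", w_lines), " "),
                   as.numeric)
    wh <- do.call(rbind, vals)
    rownames(wh) <- labels
  }

  col_names <- strsplit(lines[n_hdr], "\t")[[1]]
  data_lines <- lines[-seq_len(n_hdr)]
  data_lines <- data_lines[nzchar(data_lines)]
  if (length(data_lines) > 0) {
    nfields <- lengths(strsplit(data_lines, "\t", fixed = TRUE))
    bad <- which(nfields != length(col_names))
    if (length(bad) > 0) {
      stop("corrupt log: truncated at record ", bad[1],
           "; last good record: ", bad[1] - 1L)
    }
  }
  rec <- if (length(data_lines) > 0) {
    utils::read.table(text = data_lines, sep = "\t", header = FALSE,
                      col.names = col_names, colClasses = NA)
  } else {
    as.data.frame(stats::setNames(
      replicate(length(col_names), numeric(0), simplify = FALSE), col_names))
  }
  if ("accepted" %in% names(rec)) rec$accepted <- as.logical(rec$accepted)

  lb <- cfg$ladder
  ladder <- build_ladder(lb$t_min, lb$t_max, lb$t_ref, lb$n_rungs,
                         lb$n_below_ref)
  structure(
    list(header = list(config = cfg, ladder = ladder, seed = seed,
                       unit_system = unit_system, version = version),
         records = rec,
         weights_history = wh,
         final = NULL),
    class = "trajectory_log"
  )
}

#' @export
print.trajectory_log <- function(x, ...) {
  cat(sprintf(
    "Tempering trajectory: %d exchange attempts, method %s, seed %s\n",
    nrow(x$records), x$header$config$method, x$header$seed))
  if (nrow(x$records) > 0) {
    cat(sprintf("  overall acceptance %.3f, rungs visited %d/%d\n",
                mean(x$records$accepted),
                length(unique(x$records$rung_index)),
                x$header$ladder$n_rungs))
  }
  invisible(x)
}
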