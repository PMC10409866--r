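# On-disk formats: UTF-8, tab-separated, '.' decimal, header row;
# intensities at fixed 1e-6 precision so fixtures are bit-stable.
SCHEMA_VERSION <- "1.0"

#' Write / read a trace set as a directory of tables
#'
#' One tab-separated table per molecule (`frame`, `donor`, `acceptor`)
#' plus a YAML manifest (`manifest.yaml`) with the acquisition
#' parameters, seeds, schema version and per-molecule ground truth.
#' Intensities are written at 1e-6 precision and round-trip bit-stably
#' at that precision. Readers reject manifests with an unknown major
#' schema version.
#'
#' @param ts a `trace_set` from [generate_dataset].
#' @param dir output directory (created if needed).
#' @return `write_trace_set` returns `dir` invisibly; `read_trace_set`
#'   returns a `trace_set` (traces carry `dt` and `molecule_id`; the
#'   manifest data frame carries replicate and ground truth).
#' @export
write_trace_set <- function(ts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cam <- ts$params$cam
  files <- character(length(ts$traces))
  for (i in seq_along(ts$traces)) {
    tr <- ts$traces[[i]]
    id <- attr(tr, "molecule_id")
    files[i] <- paste0(id, ".tsv")
    df <- data.frame(frame = tr$frame,
                     donor = sprintf("%.6f", tr$donor),
                     acceptor = sprintf("%.6f", tr$acceptor))
    utils::write.table(df, file.path(dir, files[i]), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  man <- ts$manifest
  manifest <- list(
    schema_version = SCHEMA_VERSION,
    frame_rate = cam$frame_rate,
    bleed_through = cam$bleed_through,
    window = cam$window,
    k_photobleach = cam$k_photobleach,
    scenario = ts$params$scenario,
    protocol = ts$params$protocol,
    rateset_label = ts$params$rates$label,
    master_seed = ts$params$seed,
    n_replicates = ts$params$n_replicates,
    molecules = lapply(seq_len(nrow(man)), function(i) list(
      id = man$molecule_id[i], file = files[i],
      replicate = man$replicate[i], seed = man$seed[i],
      class = man$class[i],
      bleach_time = if (is.finite(man$bleach_time[i]))
        man$bleach_time[i] else "Inf",
      bleach_mode = man$bleach_mode[i])))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"),
                   precision = 15L)
  invisible(dir)
}

#' @rdname write_trace_set
#' @export
read_trace_set <- function(dir) {
  mf <- file.path(dir, "manifest.yaml")
  if (!file.exists(mf)) stop("no manifest.yaml in ", dir)
  manifest <- yaml::read_yaml(mf)
  major <- sub("\\..*$", "", as.character(manifest$schema_version))
  if (!identical(major, sub("\\..*$", "", SCHEMA_VERSION)))
    stop("unsupported trace-set schema version: ",
         manifest$schema_version)
  dt <- 1 / manifest$frame_rate
  mols <- manifest$molecules
  missing_files <- vapply(mols, function(m)
    !file.exists(file.path(dir, m$file)), logical(1))
  if (any(missing_files))
    stop("manifest/trace mismatch, missing table(s) for: ",
         paste(vapply(mols[missing_files], `[[`, "", "id"),
               collapse = ", "))
  traces <- lapply(mols, function(m) {
    df <- utils::read.table(file.path(dir, m$file), header = TRUE,
                            sep = "\t")
    structure(df, dt = dt, molecule_id = m$id,
              class = c("intensity_trace", "data.frame"))
  })
  man <- do.call(rbind, lapply(mols, function(m) data.frame(
    molecule_id = m$id, replicate = m$replicate, seed = m$seed,
    class = m$class,
    bleach_time = suppressWarnings(as.numeric(m$bleach_time)),
    bleach_mode = m$bleach_mode)))
  structure(list(traces = traces, manifest = man,
                 params = list(cam = camera_model(
                   frame_rate = manifest$frame_rate,
                   bleed_through = manifest$bleed_through,
                   window = manifest$window,
                   k_photobleach = manifest$k_photobleach),
                   scenario = manifest$scenario,
                   protocol = manifest$protocol,
                   seed = manifest$master_seed,
                   n_replicates = manifest$n_replicates)),
            class = "trace_set")
}

#' Write a state trajectory as a three-column table
#'
#' @param traj a `state_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(as.data.frame(traj), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write idealized traces as a delimited table
#'
#' One row per dwell: molecule id, fitted mean and width, assigned level
#' (if any), start and end time.
#'
#' @param itraces list of `idealized_trace` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_idealized <- function(itraces, path) {
  rows <- lapply(itraces, function(it) {
    if (is.null(it)) return(NULL)
    s <- it$segments
    data.frame(molecule_id = it$molecule_id %||% NA_character_,
               state = s$state, mu = s$mu, sigma = s$sigma,
               level = if (!is.null(s$level)) s$level else NA_character_,
               t_start = s$t_start, t_end = s$t_end)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Analysis configuration
#'
#' Collects every tunable of the trace-analysis chain with its default.
#' Fully serializable: `read_run_config(write_run_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param beta donor bleed-through coefficient.
#' @param k_photobleach photobleaching rate (s^-1).
#' @param window observation window T (s).
#' @param max_states maximum HMM state count; `NULL` (default) means
#'   one more than the number of declared FRET levels (the extra state
#'   accommodates camera-integration boundary frames).
#' @param detection_threshold FRET level counted as "signal appeared".
#' @param min_frames consecutive frames above threshold for detection /
#'   resolved-phase rule.
#' @param anticorr_threshold QC frame-difference correlation threshold.
#' @param bin_frames dwell histogram bin width in frames.
#' @param min_dwells minimum dwells for a decay fit.
#' @param levels named FRET levels used for dwell assignment.
#' @param seed master seed for any stochastic analysis step.
#' @return A `run_config` list.
#' @export
analysis_config <- function(beta = 0.13, k_photobleach = 0.03, window = 33,
                            max_states = NULL, detection_threshold = 0.125,
                            min_frames = 2L, anticorr_threshold = -0.1,
                            bin_frames = 2L, min_dwells = 20L,
                            levels = c(dark = 0, high = 0.9,
                                       classical = 0.8, hybrid = 0.6),
                            seed = 1L) {
  structure(list(beta = beta, k_photobleach = k_photobleach,
                 window = window,
                 max_states = if (is.null(max_states)) length(levels) + 1L
                              else as.integer(max_states),
                 detection_threshold = detection_threshold,
                 min_frames = as.integer(min_frames),
                 anticorr_threshold = anticorr_threshold,
                 bin_frames = as.integer(bin_frames),
                 min_dwells = as.integer(min_dwells),
                 levels = levels, seed = as.integer(seed),
                 schema_version = SCHEMA_VERSION),
            class = "run_config")
}

#' @rdname analysis_config
#' @param config a `run_config`.
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  out <- unclass(config)
  out$levels <- as.list(out$levels)
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' @rdname analysis_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  major <- sub("\\..*$", "", as.character(raw$schema_version))
  if (!identical(major, sub("\\..*$", "", SCHEMA_VERSION)))
    stop("unsupported config schema version: ", raw$schema_version)
  raw$levels <- unlist(raw$levels)
  raw$schema_version <- NULL
  do.call(analysis_config, raw)
}
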