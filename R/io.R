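#' Retinotopic ROI registry
#'
#' The 15 retinotopically defined regions of interest and the two
#' feature-selective aggregate regions: the color map (hV4, VO1, VO2) and
#' the motion map (TO1, TO2). The aggregates are disjoint.
#'
#' @return List with `rois` (character, length 15) and `aggregates`
#'   (named list `color`, `motion`).
#' @export
roi_registry <- function() {
  list(rois = c("V1", "V2", "V3", "V3AB", "hV4", "LO1", "LO2", "VO1", "VO2",
                "TO1", "TO2", "IPS0", "IPS1", "IPS2", "IPS3"),
       aggregates = list(color = c("hV4", "VO1", "VO2"),
                         motion = c("TO1", "TO2")))
}

# "# key: value" provenance lines echoed into every output file
provenance_header <- function(config, seed = NULL) {
  vals <- unclass(config)
  vals <- vals[order(names(vals))]
  lines <- vapply(names(vals), function(k)
    sprintf("# %s: %s", k, paste(format(vals[[k]]), collapse = " ")),
    character(1))
  if (!is.null(seed)) lines <- c(sprintf("# master_seed: %d", seed), lines)
  unname(lines)
}

write_table_with_header <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_table_with_header <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path)
  hdr <- grep("^#", lines)
  meta <- character()
  if (length(hdr)) {
    kv <- sub("^#\\s*", "", lines[hdr])
    keys <- sub(":.*$", "", kv)
    vals <- sub("^[^:]*:\\s*", "", kv)
    meta <- stats::setNames(vals, keys)
  }
  body <- lines[setdiff(seq_along(lines), hdr)]
  if (!length(body)) stop("file has a header but no table: ", path)
  df <- utils::read.table(text = body, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  attr(df, "meta") <- meta
  df
}

#' Write a voxel timeseries run to tab-separated text
#'
#' One run of TR x voxel BOLD data, with `# key: value` header lines
#' carrying the TR, run identifier, and any provenance lines (seed, config
#' echo), then a header row of voxel ids.
#'
#' @param bold TR x voxel numeric matrix (column names = voxel ids).
#' @param path Output path.
#' @param tr Repetition time, seconds.
#' @param run Run identifier.
#' @param provenance Extra `# key: value` lines to echo.
#' @return The path, invisibly.
#' @export
write_timeseries <- function(bold, path, tr, run = 1L,
                             provenance = character()) {
  bold <- as.matrix(bold)
  if (is.null(colnames(bold)))
    colnames(bold) <- paste0("v", seq_len(ncol(bold)))
  hdr <- c(sprintf("# tr: %s", format(tr)),
           sprintf("# run: %s", format(run)),
           sprintf("# n_tr: %d", nrow(bold)),
           provenance)
  write_table_with_header(as.data.frame(bold), path, hdr)
}

#' Read a voxel timeseries run
#'
#' Parses the tab-separated dialect written by [write_timeseries()],
#' validating the header metadata, cell values, and (optionally) the voxel
#' set.
#'
#' @param path File path.
#' @param expected_tr If given, error when the file's TR differs.
#' @param expected_voxels If given, error when any voxel column is missing.
#' @return TR x voxel numeric matrix with attributes `tr` and `run`.
#' @export
read_timeseries <- function(path, expected_tr = NULL,
                            expected_voxels = NULL) {
  df <- read_table_with_header(path)
  meta <- attr(df, "meta")
  if (!"tr" %in% names(meta))
    stop("malformed timeseries header: missing '# tr:' line in ", path)
  tr <- as.numeric(meta[["tr"]])
  if (!is.finite(tr)) stop("malformed TR in header of ", path)
  if (!is.null(expected_tr) && abs(tr - expected_tr) > 1e-9)
    stop(sprintf("TR mismatch in %s: file %g, expected %g",
                 path, tr, expected_tr))
  M <- as.matrix(df)
  if (!is.numeric(M) || anyNA(M) || any(!is.finite(M)))
    stop("timeseries contains missing or non-finite cells: ", path)
  if (!is.null(expected_voxels)) {
    miss <- setdiff(expected_voxels, colnames(M))
    if (length(miss))
      stop("voxel column(s) missing from ", path, ": ",
           paste(miss, collapse = ", "))
  }
  attr(M, "tr") <- tr
  attr(M, "run") <- if ("run" %in% names(meta)) meta[["run"]] else NA
  attr(M, "meta") <- meta
  M
}

#' Convert a task schedule to an events table
#'
#' Emits a BIDS-events-style tab-separated dialect (columns `onset`,
#' `duration`, `trial_type`, `stim_angle_deg`, `stim_ecc_deg`, `coherence`,
#' `response`, `correct`) from an attention or mapping schedule.
#'
#' @param schedule Output of [make_attention_schedule()] or
#'   [make_mapping_schedule()].
#' @return Events data frame.
#' @export
events_from_schedule <- function(schedule) {
  if ("condition" %in% names(schedule)) {
    data.frame(onset = schedule$onset_s,
               duration = schedule$cue_dur_s + schedule$blank_s +
                 schedule$stim_dur_s,
               trial_type = schedule$condition,
               stim_angle_deg = schedule$stim_angle_deg,
               stim_ecc_deg = schedule$stim_ecc_deg,
               coherence = NA_real_, response = NA_character_,
               correct = NA, stringsAsFactors = FALSE)
  } else {
    ecc <- sqrt(schedule$x^2 + schedule$y^2)
    data.frame(onset = schedule$onset_s, duration = schedule$stim_dur_s,
               trial_type = ifelse(schedule$target, "mapping_target",
                                   "mapping"),
               stim_angle_deg = atan2(schedule$y, schedule$x) * 180 / pi,
               stim_ecc_deg = ecc,
               coherence = NA_real_, response = NA_character_,
               correct = NA, stringsAsFactors = FALSE)
  }
}

#' Write / read an events table
#'
#' @param events Events data frame (see [events_from_schedule()]).
#' @param path File path.
#' @param provenance Extra `# key: value` lines to echo.
#' @return `write_events`: the path, invisibly. `read_events`: the events
#'   data frame with the parsed header in `attr(, "meta")`.
#' @export
write_events <- function(events, path, provenance = character()) {
  write_table_with_header(events, path, provenance)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  read_table_with_header(path)
}

#' Write / read voxel metadata
#'
#' Tab-separated voxel metadata: receptive-field parameters, ROI, and
#' variance explained.
#'
#' @param voxels Voxel metadata data frame (see [synth_voxels()]).
#' @param path File path.
#' @param provenance Extra `# key: value` lines to echo.
#' @return `write_voxel_meta`: the path, invisibly. `read_voxel_meta`: the
#'   metadata data frame.
#' @export
write_voxel_meta <- function(voxels, path, provenance = character()) {
  write_table_with_header(voxels, path, provenance)
}

#' @rdname write_voxel_meta
#' @export
read_voxel_meta <- function(path) {
  read_table_with_header(path)
}

#' Write / read a plain-text configuration
#'
#' `key: value` lines, one per parameter; the same representation is echoed
#' as `#`-prefixed header lines into every result file for provenance.
#'
#' @param config A [sim_config()] (or named list).
#' @param path File path.
#' @param extra Named extra entries (e.g. the master seed).
#' @return `write_config`: the path, invisibly. `read_config`: a named
#'   character vector of entries.
#' @export
write_config <- function(config, path, extra = NULL) {
  vals <- c(unclass(config), as.list(extra))
  writeLines(vapply(names(vals), function(k)
    sprintf("%s: %s", k, paste(format(vals[[k]]), collapse = " ")),
    character(1)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  keys <- sub(":.*$", "", lines)
  vals <- sub("^[^:]*:\\s*", "", lines)
  stats::setNames(vals, keys)
}
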