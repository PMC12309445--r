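#' Session bundle: all units and trial events of one animal-session
#'
#' A `session_bundle` is the atomic analysis input: a unit table, a named
#' list of spike-time vectors (seconds from session start), a trial/event
#' table, and session metadata. Construct one directly from in-memory data,
#' read one from the three-file plain-text layout with
#' [read_session_bundle()], or simulate one with [simulate_session()].
#'
#' @param units data.frame with columns `unit_id`, `animal_id`, `group`
#'   (`control`/`stress`), `session` (`day1`/`day15`), `area`
#'   (`dmPFC`/`VTA`) and `waveform_ms` (NA allowed; required for VTA cell
#'   typing only).
#' @param spikes named list of strictly ascending, non-negative numeric
#'   vectors of spike times (s), one per `unit_id`.
#' @param trials data.frame with columns `trial_id`, `cue_type` (`DSplus`/
#'   `DSminus`), `cue_onset_s`, `lever_onset_s` (= cue + 3 s),
#'   `press_time_s` (NA on omissions) and `omission` (logical).
#' @param metadata list with at least `animal_id`, `group`, `session`.
#' @param validate run [validate_session_bundle()] (default TRUE).
#' @return An object of class `session_bundle`.
#' @export
session_bundle <- function(units, spikes, trials, metadata = list(),
                           validate = TRUE) {
  units <- as.data.frame(units, stringsAsFactors = FALSE)
  trials <- as.data.frame(trials, stringsAsFactors = FALSE)
  if (is.null(units$waveform_ms)) units$waveform_ms <- NA_real_
  missing_spk <- setdiff(units$unit_id, names(spikes))
  if (length(missing_spk)) {
    warning("no spikes for unit(s): ", paste(missing_spk, collapse = ", "),
            "; using empty spike trains")
    for (u in missing_spk) spikes[[u]] <- numeric(0)
  }
  b <- structure(
    list(units = units, spikes = spikes[units$unit_id], trials = trials,
         metadata = metadata),
    class = "session_bundle"
  )
  if (validate) validate_session_bundle(b)
  b
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf(
    "<session_bundle> %s / %s / %s: %d units, %d trials (%d DS+, %d DS-)\n",
    x$metadata$animal_id %||% "?", x$metadata$group %||% "?",
    x$metadata$session %||% "?", nrow(x$units), nrow(x$trials),
    sum(x$trials$cue_type == "DSplus"), sum(x$trials$cue_type == "DSminus")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a session bundle
#'
#' Checks every structural invariant of the data model: required columns,
#' strictly ascending non-negative spike times, strictly ascending cue
#' onsets, the 3 s tone-to-lever latency, press times absent on omissions,
#' at most 50 trials per cue type with at least one trial of each, positive
#' waveform durations where present, and unit/session metadata consistency.
#'
#' @param bundle a [session_bundle()].
#' @return The bundle, invisibly; stops with an informative error otherwise.
#' @export
validate_session_bundle <- function(bundle) {
  u <- bundle$units; tr <- bundle$trials
  need_u <- c("unit_id", "animal_id", "group", "session", "area")
  miss <- setdiff(need_u, names(u))
  if (length(miss)) stop("units table missing column(s): ",
                         paste(miss, collapse = ", "))
  need_t <- c("trial_id", "cue_type", "cue_onset_s", "lever_onset_s",
              "press_time_s", "omission")
  miss <- setdiff(need_t, names(tr))
  if (length(miss)) stop("trials table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(u$unit_id)) stop("duplicated unit_id in units table")
  if (!all(u$group %in% c("control", "stress")))
    stop("group must be 'control' or 'stress'")
  if (!all(u$session %in% c("day1", "day15")))
    stop("session must be 'day1' or 'day15'")
  if (!all(u$area %in% c("dmPFC", "VTA")))
    stop("area must be 'dmPFC' or 'VTA'")
  wf <- u$waveform_ms
  if (!is.null(wf) && any(!is.na(wf) & wf <= 0))
    stop("waveform_ms must be > 0 when present")
  if (!is.null(bundle$metadata$animal_id) &&
      !all(u$animal_id == bundle$metadata$animal_id))
    stop("all units must share the bundle's animal_id")
  for (uid in u$unit_id) {
    st <- bundle$spikes[[uid]]
    if (length(st)) {
      if (any(st < 0)) stop("negative spike times for unit ", uid)
      if (any(diff(st) <= 0))
        stop("spike times not strictly ascending for unit ", uid)
    }
  }
  if (!all(tr$cue_type %in% c("DSplus", "DSminus")))
    stop("cue_type must be 'DSplus' or 'DSminus'")
  if (any(diff(tr$cue_onset_s) <= 0))
    stop("cue onsets must be strictly ascending")
  if (any(abs(tr$lever_onset_s - tr$cue_onset_s - 3) > 1e-6))
    stop("lever_onset_s must equal cue_onset_s + 3.0 s")
  if (any(tr$omission & !is.na(tr$press_time_s)))
    stop("omission trials must have no press_time_s")
  n_cue <- table(factor(tr$cue_type, levels = c("DSplus", "DSminus")))
  if (any(n_cue > 50)) stop("more than 50 trials of one cue type")
  if (any(n_cue < 1)) stop("at least 1 trial per cue type is required")
  invisible(bundle)
}

# map between in-memory cue codes and the file dialect
.cue_to_file <- c(DSplus = "DS+", DSminus = "DS-")
.cue_from_file <- c("DS+" = "DSplus", "DS-" = "DSminus")

.read_tsv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop("file ", basename(path), " missing required column(s): ",
         paste(miss, collapse = ", "))
  d
}

#' Read a session bundle from the three-file plain-text layout
#'
#' Files are UTF-8 tab-separated values with a header row; times are seconds
#' as decimal numbers. `spikes_file` has columns `unit_id`, `spike_time_s`;
#' `units_file` has `unit_id`, `animal_id`, `group`, `session`, `area`,
#' `waveform_ms` (empty allowed); `events_file` has `trial_id`, `cue_type`
#' (`DS+`/`DS-`), `cue_onset_s`, `lever_onset_s`, `press_time_s` (empty
#' allowed), `omission` (0/1).
#'
#' @param spikes_file,units_file,events_file file paths.
#' @return A validated [session_bundle()].
#' @seealso [write_session_bundle()] for the inverse.
#' @export
read_session_bundle <- function(spikes_file, units_file, events_file) {
  spk <- .read_tsv(spikes_file, c("unit_id", "spike_time_s"))
  uni <- .read_tsv(units_file, c("unit_id", "animal_id", "group", "session",
                                 "area", "waveform_ms"))
  ev <- .read_tsv(events_file, c("trial_id", "cue_type", "cue_onset_s",
                                 "lever_onset_s", "press_time_s", "omission"))
  if (!all(ev$cue_type %in% names(.cue_from_file)))
    stop("events cue_type must be 'DS+' or 'DS-'")
  ev$cue_type <- unname(.cue_from_file[ev$cue_type])
  ev$omission <- as.logical(ev$omission)
  spikes <- split(spk$spike_time_s, factor(spk$unit_id, levels = uni$unit_id))
  spikes <- lapply(spikes, function(x) sort(as.numeric(x)))
  # keep only units that actually have spike rows so the constructor can
  # warn about (and backfill) units missing from the spikes file
  spikes <- spikes[intersect(uni$unit_id, unique(spk$unit_id))]
  meta <- list(animal_id = uni$animal_id[1], group = uni$group[1],
               session = uni$session[1])
  session_bundle(uni, spikes, ev, metadata = meta)
}

#' Write a session bundle to the three-file plain-text layout
#'
#' @param bundle a [session_bundle()].
#' @param dir output directory (created if needed).
#' @param digits decimal places for times (default 6; round-trips to 1e-6 s).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_session_bundle <- function(bundle, dir, digits = 6) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) ifelse(is.na(x), NA, sprintf(paste0("%.", digits, "f"), x))
  u <- bundle$units
  spk <- data.frame(
    unit_id = rep(u$unit_id, lengths(bundle$spikes[u$unit_id])),
    spike_time_s = fmt(unlist(bundle$spikes[u$unit_id], use.names = FALSE)),
    stringsAsFactors = FALSE)
  tr <- bundle$trials
  ev <- data.frame(trial_id = tr$trial_id,
                   cue_type = unname(.cue_to_file[tr$cue_type]),
                   cue_onset_s = fmt(tr$cue_onset_s),
                   lever_onset_s = fmt(tr$lever_onset_s),
                   press_time_s = fmt(tr$press_time_s),
                   omission = as.integer(tr$omission),
                   stringsAsFactors = FALSE)
  uo <- u[, c("unit_id", "animal_id", "group", "session", "area", "waveform_ms")]
  paths <- c(spikes = file.path(dir, "spikes.tsv"),
             units = file.path(dir, "units.tsv"),
             events = file.path(dir, "events.tsv"))
  utils::write.table(spk, paths["spikes"], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(uo, paths["units"], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(ev, paths["events"], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(paths)
}

#' Write result tables and a run manifest
#'
#' Writes one tab-separated file per named table plus `manifest.json`
#' recording the file list, MD5 hashes, the seed and a hash of the analysis
#' configuration, so a run can be traced and compared byte-for-byte.
#'
#' @param tables non-empty named list of data.frames.
#' @param out_dir output directory (created if needed).
#' @param config optional [analysis_config()] snapshot to hash.
#' @param seed optional master seed to record.
#' @return The manifest, invisibly (list with `files`, `md5`, `seed`,
#'   `config_hash`).
#' @export
write_results <- function(tables, out_dir, config = NULL, seed = NULL) {
  if (!length(tables) || is.null(names(tables)) || any(names(tables) == ""))
    stop("'tables' must be a non-empty named list of data.frames")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  files <- character(0)
  for (nm in names(tables)) {
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tables[[nm]], path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    files[nm] <- path
  }
  cfg_hash <- NA_character_
  if (!is.null(config)) {
    tmp <- tempfile()
    on.exit(unlink(tmp), add = TRUE)
    writeLines(deparse(config), tmp)
    cfg_hash <- unname(tools::md5sum(tmp))
  }
  manifest <- list(files = basename(unname(files)),
                   md5 = unname(tools::md5sum(unname(files))),
                   seed = seed, config_hash = cfg_hash,
                   package_version = as.character(utils::packageVersion("cuephys")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
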