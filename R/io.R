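# On-disk cohort layout
# <dir>/manifest.json
# <dir>/<subject>/eda.csv     time_s, eda_uS           (1 comment header line)
# <dir>/<subject>/nirs.csv    time_s, oxyHb_au, deoxyHb_au
# <dir>/<subject>/events.tsv  onset_s, offset_s, pressure_kPa, label
# <dir>/<subject>/vas.json    per-epoch raw VAS + anchor
# All times in seconds, pressures in kPa, conductance in uS; epochs are
# half-open [onset_s, offset_s).

units_comment <- "# times in seconds; conductance in uS; pressures in kPa; epochs half-open [onset_s, offset_s)"

write_table_with_units <- function(df, path, sep) {
  writeLines(units_comment, path)
  data.table::fwrite(df, path, sep = sep, append = TRUE, col.names = TRUE)
}

read_table_with_units <- function(path, sep) {
  first <- readLines(path, n = 1L)
  skip <- if (startsWith(first, "#")) 1L else 0L
  as.data.frame(data.table::fread(path, sep = sep, skip = skip,
                                  header = TRUE))
}

#' Write a simulated cohort to disk
#'
#' One subdirectory per subject (`eda.csv`, `nirs.csv` when present,
#' `events.tsv`, `vas.json`) plus a cohort-level `manifest.json` recording
#' the design, the per-subject profiles and the derived seeds, so the
#' cohort is fully reproducible from `(design, seed)`.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir target directory; must not already contain a manifest
#'   (collision protection).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "cuff_cohort"))
    stopf("parameter_error", "cohort must be a cuff_cohort")
  if (file.exists(file.path(dir, "manifest.json")))
    stopf("io_error", "output collision: %s already holds a cohort", dir)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    sd <- file.path(dir, s$profile$subject_id)
    dir.create(sd, showWarnings = FALSE)
    write_table_with_units(
      data.frame(time_s = s$eda$time_s, eda_uS = s$eda$eda_uS),
      file.path(sd, "eda.csv"), sep = ",")
    if (!is.null(s$nirs))
      write_table_with_units(
        data.frame(time_s = s$nirs$time_s, oxyHb_au = s$nirs$oxyHb_au,
                   deoxyHb_au = s$nirs$deoxyHb_au),
        file.path(sd, "nirs.csv"), sep = ",")
    ep <- s$schedule$epochs
    write_table_with_units(
      data.frame(onset_s = ep$onset_s, offset_s = ep$onset_s + ep$duration_s,
                 pressure_kPa = ep$pressure_kPa, label = ep$label),
      file.path(sd, "events.tsv"), sep = "\t")
    jsonlite::write_json(
      list(anchor = s$vas$anchor,
           ratings = s$vas$ratings),
      file.path(sd, "vas.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE)
  }
  d <- cohort$design
  manifest <- list(
    generator = "cuffcomfort",
    version = as.character(packageVersion("cuffcomfort")),
    seed = cohort$seed,
    design = list(
      n_subjects = d$n_subjects, epoch_duration_s = d$epoch_duration_s,
      pressures_kPa = d$pressures_kPa, randomize_order = d$randomize_order,
      with_nirs = d$with_nirs, rest_s = d$rest_s, lead_in_s = d$lead_in_s,
      sim_config = unclass(d$sim_config)
    ),
    subjects = lapply(cohort$subjects, function(s)
      list(subject_id = s$profile$subject_id, seed = s$seed,
           profile = unclass(s$profile)))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# internal: validate an events table, naming offending rows
validate_events <- function(ev, path) {
  need <- c("onset_s", "offset_s", "pressure_kPa", "label")
  if (!all(need %in% names(ev)))
    stopf("io_error", "%s: expected columns %s", path,
          paste(need, collapse = ", "))
  bad <- which(ev$offset_s <= ev$onset_s)
  if (length(bad))
    stopf("io_error", "%s: non-positive epoch duration in row(s) %s",
          path, paste(bad, collapse = ", "))
  ord <- order(ev$onset_s)
  eo <- ev[ord, ]
  if (nrow(eo) > 1) {
    ovl <- which(eo$offset_s[-nrow(eo)] > eo$onset_s[-1] + 1e-9)
    if (length(ovl))
      stopf("io_error", "%s: overlapping epochs in row(s) %s",
            path, paste(sort(ord[c(ovl, ovl + 1L)]), collapse = ", "))
  }
  ev
}

#' Read a cohort from disk
#'
#' Loads and validates a cohort directory written by [write_cohort()] (or
#' assembled by hand in the same layout). Each channel is checked on load:
#' sampling uniformity for the CSV traces, schema and epoch overlap for the
#' events TSV (errors name the offending rows), and anchor positivity for
#' the VAS JSON.
#'
#' @param dir cohort directory containing `manifest.json` or per-subject
#'   subdirectories.
#' @return a `cuff_cohort` (profiles populated from the manifest when
#'   available).
#' @export
read_cohort <- function(dir) {
  if (!dir.exists(dir))
    stopf("io_error", "cohort directory %s does not exist", dir)
  manifest_path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  subdirs <- list.dirs(dir, recursive = FALSE)
  subdirs <- subdirs[file.exists(file.path(subdirs, "eda.csv"))]
  if (!length(subdirs))
    stopf("io_error", "no subject directories with eda.csv under %s", dir)

  subjects <- lapply(subdirs, function(sd) {
    sid <- basename(sd)
    eda_df <- read_table_with_units(file.path(sd, "eda.csv"), ",")
    if (!all(c("time_s", "eda_uS") %in% names(eda_df)))
      stopf("io_error", "%s/eda.csv: expected columns time_s, eda_uS", sd)
    eda <- tryCatch(eda_recording(eda_df$time_s, eda_df$eda_uS),
                    cuffcomfort_error = function(e)
                      stopf("io_error", "%s/eda.csv: %s", sd, conditionMessage(e)))
    nirs <- NULL
    npath <- file.path(sd, "nirs.csv")
    if (file.exists(npath)) {
      nd <- read_table_with_units(npath, ",")
      if (!all(c("time_s", "oxyHb_au", "deoxyHb_au") %in% names(nd)))
        stopf("io_error", "%s: expected columns time_s, oxyHb_au, deoxyHb_au",
              npath)
      nirs <- tryCatch(nirs_recording(nd$time_s, nd$oxyHb_au, nd$deoxyHb_au),
                       cuffcomfort_error = function(e)
                         stopf("io_error", "%s: %s", npath, conditionMessage(e)))
    }
    epath <- file.path(sd, "events.tsv")
    if (!file.exists(epath))
      stopf("io_error", "missing channel file %s", epath)
    ev <- validate_events(read_table_with_units(epath, "\t"), epath)
    anchor_rows <- ev$label == "anchor"
    schedule <- stimulus_schedule(
      data.frame(onset_s = ev$onset_s, duration_s = ev$offset_s - ev$onset_s,
                 pressure_kPa = ev$pressure_kPa, label = ev$label),
      anchor_pressure_kPa = if (any(anchor_rows))
        ev$pressure_kPa[anchor_rows][1] else 60,
      span_s = max(eda$time_s))
    vpath <- file.path(sd, "vas.json")
    if (!file.exists(vpath))
      stopf("io_error", "missing channel file %s", vpath)
    vj <- jsonlite::read_json(vpath, simplifyVector = TRUE)
    if (is.null(vj$anchor$vas_raw) || vj$anchor$vas_raw <= 0)
      stopf("io_error", "%s: anchor rating missing or non-positive", vpath)
    vas <- structure(list(ratings = as.data.frame(vj$ratings),
                          anchor = as.list(vj$anchor)), class = "vas_record")
    profile <- subject_profile(subject_id = sid)
    if (!is.null(manifest$subjects)) {
      ms <- manifest$subjects
      hit <- which(ms$subject_id == sid)
      if (length(hit) == 1) {
        pr <- as.list(ms$profile[hit, , drop = TRUE])
        pr$subject_id <- sid
        profile <- do.call(subject_profile, pr)
      }
    }
    list(profile = profile, schedule = schedule, eda = eda, nirs = nirs,
         vas = vas, seed = NA_integer_)
  })

  design <- if (!is.null(manifest$design)) {
    dm <- manifest$design
    cohort_design(n_subjects = length(subjects),
                  epoch_duration_s = dm$epoch_duration_s,
                  pressures_kPa = dm$pressures_kPa,
                  randomize_order = isTRUE(dm$randomize_order),
                  with_nirs = isTRUE(dm$with_nirs),
                  sim_config = do.call(sim_config, as.list(dm$sim_config)),
                  rest_s = dm$rest_s, lead_in_s = dm$lead_in_s)
  } else {
    pe <- pressure_epochs(subjects[[1]]$schedule)
    cohort_design(n_subjects = length(subjects),
                  epoch_duration_s = pe$duration_s[1],
                  pressures_kPa = sort(unique(pe$pressure_kPa)),
                  with_nirs = !is.null(subjects[[1]]$nirs))
  }
  structure(list(design = design,
                 seed = if (!is.null(manifest$seed)) manifest$seed else NA,
                 subjects = subjects),
            class = "cuff_cohort")
}
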