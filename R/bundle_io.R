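# On-disk layout of a recording bundle:
#   <dir>/<cell_id>/meta.json            structured metadata
#   <dir>/<cell_id>/sweep_<k>.csv        columns time_ms,recorded,command[,light]
# Samples are written with 17 significant digits so the text round-trip is
# bit-exact for doubles.

fmt_num <- function(x) sprintf("%.17g", x)

serialize_segments <- function(segments) {
  lapply(segments, function(s) s[!vapply(s, function(v) is.na(v)[1], TRUE)])
}

deserialize_segments <- function(lst) {
  lapply(lst, function(s) {
    stim_segment(kind = s$kind, t_start = s$t_start, t_end = s$t_end,
                 amp_start = s$amp_start,
                 amp_end = if (is.null(s$amp_end)) s$amp_start else s$amp_end,
                 period = s$period %||% NA_real_,
                 pulse_width = s$pulse_width %||% NA_real_,
                 pulse_amp = s$pulse_amp %||% NA_real_)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a recording bundle to disk
#'
#' One directory per cell: a `meta.json` metadata document plus one
#' `sweep_<k>.csv` table per sweep (`time_ms,recorded,command`, plus a
#' `light` column for optogenetic sweeps). The layout is plain text,
#' diff-able and lossless: [read_bundle] reproduces the samples bit-exactly.
#'
#' @param recording a [new_recording] object
#' @param path parent directory; the bundle is written to `path/<cell_id>`
#' @return the bundle directory, invisibly
#' @export
write_bundle <- function(recording, path) {
  stopifnot(inherits(recording, "recording"))
  dir <- file.path(path, recording$cell_id)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  k <- 0L
  sweep_meta <- list()
  for (fam in names(recording$sweeps)) {
    for (sw in recording$sweeps[[fam]]) {
      k <- k + 1L
      dt <- 1000 / sw$sampling_rate
      tm <- (seq_along(sw$recorded) - 1) * dt
      cols <- c("time_ms", "recorded", "command")
      lines <- paste(fmt_num(tm), fmt_num(sw$recorded), fmt_num(sw$command),
                     sep = ",")
      if (!is.null(sw$light)) {
        cols <- c(cols, "light")
        lines <- paste(lines, fmt_num(sw$light), sep = ",")
      }
      writeLines(c(paste(cols, collapse = ","), lines),
                 file.path(dir, sprintf("sweep_%d.csv", k)))
      sweep_meta[[k]] <- list(
        file = sprintf("sweep_%d.csv", k),
        family = fam,
        sweep_index = sw$sweep_index,
        sampling_rate = sw$sampling_rate,
        clamp_mode = sw$clamp_mode,
        amp = sw$amp,
        stim_on = sw$stim_on,
        stim_off = sw$stim_off,
        segments = serialize_segments(sw$segments))
    }
  }

  meta <- list(cell_id = recording$cell_id, group = recording$group,
               species = recording$species, diameter = recording$diameter,
               provenance = recording$provenance, sweeps = sweep_meta)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}

read_sweep_csv <- function(file) {
  tab <- utils::read.csv(file, colClasses = "numeric")
  if (!all(c("time_ms", "recorded", "command") %in% names(tab)))
    stop("sweep table must have columns time_ms, recorded, command: ", file)
  if (anyNA(tab$recorded) || anyNA(tab$command))
    stop("missing samples in ", file)
  tab
}

#' Read a recording bundle
#'
#' Inverse of [write_bundle]; validates the metadata document and sweep
#' tables and reassembles the [new_recording].
#'
#' @param path the bundle directory (`.../cell_id`)
#' @return a `recording`
#' @export
read_bundle <- function(path) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file)) stop("no meta.json under ", path)
  meta <- jsonlite::read_json(meta_file, simplifyVector = FALSE)
  for (field in c("cell_id", "group", "species", "diameter"))
    if (is.null(meta[[field]])) stop("bundle metadata missing field: ", field)

  sweeps <- list()
  for (sm in meta$sweeps) {
    for (field in c("sampling_rate", "clamp_mode", "family"))
      if (is.null(sm[[field]])) stop("sweep metadata missing field: ", field)
    tab <- read_sweep_csv(file.path(path, sm$file))
    sw <- new_sweep(sweep_index = sm$sweep_index,
                    recorded = tab$recorded, command = tab$command,
                    sampling_rate = sm$sampling_rate,
                    clamp_mode = sm$clamp_mode,
                    segments = deserialize_segments(sm$segments),
                    amp = sm$amp %||% NA_real_,
                    stim_on = sm$stim_on %||% NA_real_,
                    stim_off = sm$stim_off %||% NA_real_,
                    light = tab$light)
    sweeps[[sm$family]] <- c(sweeps[[sm$family]], list(sw))
  }

  new_recording(cell_id = meta$cell_id, group = meta$group,
                species = meta$species, diameter = meta$diameter,
                sweeps = sweeps,
                provenance = lapply(meta$provenance, identity))
}
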