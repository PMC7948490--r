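# File I/O: transients as two-column CSV with a JSON metadata sidecar,
# secondary-plot and ATPase tables as CSV, results as JSON. CSV dialect:
# comma separator, header row, '.' decimal, UTF-8; units in column names.

#' Write a transient to CSV with a JSON sidecar
#'
#' The CSV holds \code{time_s, signal_au}; experiment kind, conditions and
#' signal convention go to \code{<path>.json}.
#'
#' @param trans a \code{\link{transient}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_transient <- function(trans, path) {
  stopifnot(inherits(trans, "transient"))
  write.csv(data.frame(time_s = trans$t, signal_au = trans$signal),
            path, row.names = FALSE)
  meta <- list(experiment_kind = trans$experiment_kind,
               conditions = unclass(trans$conditions),
               signal_convention = trans$signal_convention)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a transient written by \code{\link{write_transient}}
#'
#' @param path CSV path; the sidecar \code{<path>.json} is read when
#'   present.
#' @return A \code{\link{transient}}.
#' @export
read_transient <- function(path) {
  tab <- read.csv(path)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    transient(tab$time_s, tab$signal_au, meta$experiment_kind,
              do.call(ligand_conditions, as.list(meta$conditions)),
              meta$signal_convention)
  } else {
    transient(tab$time_s, tab$signal_au, "atp_dissociation")
  }
}

#' Write a secondary-plot or ATPase table to CSV
#'
#' @param tab data.frame (units encoded in column names, e.g.
#'   \code{actin_uM}, \code{rate_per_s}).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_kinetic_table <- function(tab, path) {
  write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' Read a kinetic table CSV
#' @param path CSV path.
#' @return data.frame.
#' @export
read_kinetic_table <- function(path) read.csv(path)

# provenance block stamped into machine outputs
.provenance <- function(config = list(), seed = NULL) {
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA)
  hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  list(package = "myo1ckin",
       version = as.character(packageVersion("myo1ckin")),
       config_md5 = hash,
       seed = seed,
       timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
}
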