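## Reading and writing trajectory and summary tables.
##
## On-disk format: comma-separated UTF-8 text with a mandatory header row
##   sample_id,condition,particle_id,frame,t_s,x_um,y_um
## Coordinates are in micrometers and time in seconds everywhere; unit
## conversion is the caller's job. Lines starting with '#' before the header
## are metadata comments (seed, configuration hash) and are ignored on read.

#' Read a trajectory table
#'
#' Reads and validates a comma-delimited trajectory table (columns
#' `sample_id, condition, particle_id, frame, t_s, x_um, y_um`). Rows are
#' sorted by (sample_id, condition, particle_id, t_s). Validation rejects
#' malformed headers, missing coordinates, duplicate (particle, time) rows,
#' and non-uniform time steps (e.g. a dropped frame), naming the offending
#' particle.
#'
#' @param path file path.
#' @return a [TrackingExperiment-class].
#' @export
readTrajectories <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  head_lines <- readLines(path, n = 50L)
  skip <- 0L
  while (skip < length(head_lines) && startsWith(head_lines[skip + 1L], "#"))
    skip <- skip + 1L
  if (skip >= length(head_lines))
    stop("no header row found in ", path)
  header <- strsplit(head_lines[skip + 1L], ",", fixed = TRUE)[[1L]]
  if (!identical(header, .TRAJ_COLS))
    stop("malformed header in ", path, ": expected '",
         paste(.TRAJ_COLS, collapse = ","), "' but found '",
         paste(header, collapse = ","), "'")
  df <- as.data.frame(data.table::fread(
    path, skip = skip, header = TRUE, sep = ",",
    colClasses = list(character = c("sample_id", "condition", "particle_id"),
                      integer = "frame",
                      numeric = c("t_s", "x_um", "y_um"))))
  bad <- which(!stats::complete.cases(df[c("t_s", "x_um", "y_um")]))
  if (length(bad))
    stop("missing coordinate or time at data row ", bad[1L], " of ", path)
  TrackingExperiment(df)
}

#' Write a trajectory table
#'
#' Writes a [TrackingExperiment-class] as plain comma-delimited text with
#' deterministic row and column order. Optional metadata (seed,
#' configuration hash) is recorded in '#' comment lines above the header.
#'
#' @param experiment a `TrackingExperiment`.
#' @param path output file path.
#' @param meta optional named character vector written as `# name: value`
#'   comment lines.
#' @return `invisible(path)`.
#' @export
writeTrajectories <- function(experiment, path, meta = NULL) {
  stopifnot(is(experiment, "TrackingExperiment"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(meta))
    writeLines(sprintf("# %s: %s", names(meta), as.character(meta)), con)
  df <- trajectoryData(experiment)
  writeLines(paste(.TRAJ_COLS, collapse = ","), con)
  if (nrow(df)) {
    num <- function(v) formatC(v, format = "g", digits = 12)
    writeLines(paste(df$sample_id, df$condition, df$particle_id, df$frame,
                     num(df$t_s), num(df$x_um), num(df$y_um), sep = ","),
               con)
  }
  invisible(path)
}

#' Write a per-particle summary table
#'
#' Writes the per-particle summary produced by [particleSummaries()] as
#' comma-delimited text with columns `sample_id, condition, particle_id,
#' deff_1s_um2_s, alpha, immobile` (immobile coded 0/1).
#'
#' @param summaries data.frame from [particleSummaries()].
#' @param path output file path.
#' @param meta optional named character vector of comment metadata.
#' @return `invisible(path)`.
#' @export
writeParticleSummaries <- function(summaries, path, meta = NULL) {
  cols <- c("sample_id", "condition", "particle_id", "deff_1s_um2_s",
            "alpha", "immobile")
  stopifnot(all(cols %in% colnames(summaries)))
  out <- summaries[cols]
  out$immobile <- as.integer(out$immobile)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(meta))
    writeLines(sprintf("# %s: %s", names(meta), as.character(meta)), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-particle summary table
#'
#' @param path file path written by [writeParticleSummaries()].
#' @return data.frame with `immobile` as logical.
#' @export
readParticleSummaries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  head_lines <- readLines(path, n = 50L)
  skip <- 0L
  while (skip < length(head_lines) && startsWith(head_lines[skip + 1L], "#"))
    skip <- skip + 1L
  df <- as.data.frame(data.table::fread(path, skip = skip, header = TRUE,
                                        sep = ","))
  cols <- c("sample_id", "condition", "particle_id", "deff_1s_um2_s",
            "alpha", "immobile")
  if (!all(cols %in% colnames(df)))
    stop("malformed summary table: expected columns ",
         paste(cols, collapse = ", "))
  df$immobile <- as.logical(df$immobile)
  df
}
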