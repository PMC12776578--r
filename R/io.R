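# Plain-text readers and writers.  CSV dialect: comma separator, period
# decimal, UTF-8, mandatory header.  Numeric columns are written with 17
# significant digits so that write -> read round-trips are lossless.

.check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema error in '", path, "': missing column(s) ",
         paste(missing, collapse = ", "))
}

.write_csv17 <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
}

#' Read dielectric spectra from a long-form CSV
#'
#' Required columns: \code{sample}, \code{temperature_K},
#' \code{frequency_Hz}, \code{eps_real}, \code{eps_imag}.  One spectrum is
#' built per (sample, temperature) group; frequencies must be strictly
#' increasing within each group.
#'
#' @param path CSV file path.
#' @return list of [dielectric_spectrum()] objects.
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  .check_columns(df, c("sample", "temperature_K", "frequency_Hz",
                       "eps_real", "eps_imag"), path)
  groups <- split(seq_len(nrow(df)),
                  list(df$sample, df$temperature_K), drop = TRUE)
  lapply(unname(groups), function(rows) {
    sub <- df[rows, ]
    bad <- which(diff(sub$frequency_Hz) <= 0)
    if (length(bad))
      stop("data error in '", path, "': non-monotone frequency at row ",
           rows[bad[1L] + 1L])
    dielectric_spectrum(sub$temperature_K[1L], sub$frequency_Hz,
                        sub$eps_real, sub$eps_imag,
                        sample = as.character(sub$sample[1L]))
  })
}

#' Write dielectric spectra to a long-form CSV
#'
#' @param spectra list of [dielectric_spectrum()] objects (or one).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  if (inherits(spectra, "dielectric_spectrum")) spectra <- list(spectra)
  df <- do.call(rbind, lapply(spectra, function(sp)
    data.frame(sample = sp$meta$sample, temperature_K = sp$temperature,
               frequency_Hz = sp$freq, eps_real = sp$eps_real,
               eps_imag = sp$eps_imag)))
  .write_csv17(df, path)
  invisible(path)
}

#' Read DSC thermograms from a CSV
#'
#' Required columns: \code{sample}, \code{channel}, \code{temperature_C},
#' \code{heat_flow}.  One trace per (sample, channel) group.  Scan
#' metadata (rate, sign convention) is not stored in the CSV and is
#' supplied as arguments.
#'
#' @param path CSV file path.
#' @param scan_rate scan rate applied to every trace, degC/min.
#' @param exo_up sign convention applied to every trace.
#' @return list of [thermogram()] objects.
#' @export
read_thermogram_csv <- function(path, scan_rate = 10, exo_up = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  .check_columns(df, c("sample", "channel", "temperature_C", "heat_flow"),
                 path)
  groups <- split(seq_len(nrow(df)), list(df$sample, df$channel),
                  drop = TRUE)
  lapply(unname(groups), function(rows) {
    sub <- df[rows, ]
    thermogram(sub$temperature_C, sub$heat_flow,
               channel = as.character(sub$channel[1L]),
               scan_rate = scan_rate, exo_up = exo_up,
               sample = as.character(sub$sample[1L]))
  })
}

#' Write DSC thermograms to a CSV
#'
#' @param traces list of [thermogram()] objects (or one).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_thermogram_csv <- function(traces, path) {
  if (inherits(traces, "thermogram")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, function(tr)
    data.frame(sample = tr$sample, channel = tr$channel,
               temperature_C = tr$temperature, heat_flow = tr$heat_flow)))
  .write_csv17(df, path)
  invisible(path)
}

#' Read radial growth tracks from a CSV
#'
#' Required columns: \code{direction}, \code{time_s}, \code{radius_um}.
#'
#' @param path CSV file path.
#' @return list of [growth_track()] objects, one per direction.
#' @export
read_growth_tracks_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  .check_columns(df, c("direction", "time_s", "radius_um"), path)
  lapply(split(df, df$direction), function(sub)
    growth_track(sub$direction[1L], sub$time_s, sub$radius_um))
}

#' Write a relaxation map to CSV
#'
#' Columns \code{process}, \code{T_K}, \code{tau_s}, \code{delta_eps}.
#'
#' @param map a [track_modes()] relaxation map.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_relaxation_map_csv <- function(map, path) {
  stopifnot(inherits(map, "relaxation_map"))
  .write_csv17(map$points, path)
  invisible(path)
}

#' Write an analysis report (or any result list) as JSON
#'
#' Full-precision JSON via \pkg{jsonlite}; S3 analysis objects are
#' unclassed to plain lists.  Function-valued fields are dropped.
#'
#' @param results named list of results.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(results, path) {
  strip <- function(x) {
    if (is.function(x)) return(NULL)
    if (is.list(x)) {
      x <- lapply(x, strip)
      x[!vapply(x, is.null, logical(1))]
    } else x
  }
  jsonlite::write_json(strip(unclass(results)), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Serialize / restore generator ground truth
#'
#' @param truth a \code{ground_truth} object from any generator.
#' @param path JSON path.
#' @return \code{write_ground_truth}: \code{path} invisibly;
#'   \code{read_ground_truth}: the restored list (class
#'   \code{ground_truth}).
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  write_report(truth, path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE),
            class = "ground_truth")
}
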