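# Persistence: labeled volumes as raw arrays with a JSON sidecar, and
# detection records as delimited text.

#' Write a labeled volume as a raw array with a JSON sidecar
#'
#' The label grid is written as little-endian 32-bit integers in R array
#' (column-major) order to `<path>.bin`; dimensions, voxel size, origin
#' and medium names go to `<path>.json`.
#'
#' @param volume A `tissue_volume` (voxelized, not homogeneous).
#' @param path Output path stem (without extension).
#' @return Invisibly, the sidecar path.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "tissue_volume"))
  if (length(volume$labels) == 1)
    stop("homogeneous volumes are parametric; nothing to persist")
  con <- file(paste0(path, ".bin"), "wb")
  writeBin(as.integer(volume$labels), con, size = 4L, endian = "little")
  close(con)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(kind = "ppgmc_tissue_volume", dims = dim(volume$labels),
         voxel_mm = volume$voxel_mm, origin_mm = volume$origin,
         media_names = volume$media_names, dtype = "int32_le",
         order = "column_major",
         package_version = as.character(utils::packageVersion("ppgmc"))),
    sidecar, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a labeled volume written by [write_volume()]
#'
#' @param path Path stem used at write time.
#' @return A `tissue_volume`.
#' @export
read_volume <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$kind, "ppgmc_tissue_volume"))
    stop("not a ppgmc volume sidecar")
  dims <- as.integer(meta$dims)
  con <- file(paste0(path, ".bin"), "rb")
  labels <- readBin(con, "integer", n = prod(dims), size = 4L,
                    endian = "little")
  close(con)
  if (length(labels) != prod(dims)) stop("truncated label array")
  dim(labels) <- dims
  structure(list(labels = labels, voxel_mm = meta$voxel_mm,
                 origin = meta$origin_mm, media_names = meta$media_names),
            class = "tissue_volume")
}

#' Export detection records as delimited text
#'
#' Tab-separated columns: detector, weight, total_l, exit_x, exit_y, and
#' one partial-pathlength column per medium; a `#` header line carries
#' wavelength, seed and package version.
#'
#' @param result An `mc_result`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_records <- function(result, path) {
  stopifnot(inherits(result, "mc_result"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ppgmc=%s wavelength_nm=%g seed=%d launched=%g",
                     utils::packageVersion("ppgmc"), result$wavelength_nm,
                     result$seed, result$launched), con)
  utils::write.table(as.data.frame(result$records), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
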