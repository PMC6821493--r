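# File interchange: volumes as multi-page TIFF with a JSON sidecar carrying
# the physical spacing, annotations and membrane traces as CSV, pattern
# calls and frequency tables as TSV, enrichment regions as JSON.

#' Write / read a 3D volume as multi-page TIFF
#'
#' Pages are z slices; intensities are stored as 32-bit float after scaling
#' into \[0, 1\] (the scale is recorded in the JSON sidecar together with
#' the voxel spacing, so round-trips restore the original values).
#'
#' @param volume 3D array indexed \[x, y, z\].
#' @param path output `.tif` path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @param spacing voxel spacing in um.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, spacing = c(0.34, 0.34, 1)) {
  dm <- dim(volume)
  stopifnot(length(dm) == 3)
  hi <- max(volume, 1e-12)
  pages <- lapply(seq_len(dm[3]), function(k) t(volume[, , k]) / hi)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(spacing_um = spacing, intensity_scale = hi, dim = dm),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_volume
#' @return for `read_volume`: list with `volume`, `spacing`, `axes`.
#' @export
read_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vol <- array(0, meta$dim)
  for (k in seq_along(pages)) vol[, , k] <- t(pages[[k]])
  vol <- vol * meta$intensity_scale
  sp <- as.numeric(meta$spacing_um)
  dm <- dim(vol)
  axes <- list(
    x = (seq_len(dm[1]) - 0.5) * sp[1],
    y = (seq_len(dm[2]) - 0.5) * sp[2],
    z = (seq_len(dm[3]) - 0.5) * sp[3]
  )
  list(volume = vol, spacing = sp, axes = axes)
}

#' Write / read two-point synapse annotations
#'
#' CSV with columns `cell_id`, `coupling_frame`, `cx`, `cy`, `cz` (interface
#' centre, um) and `rx`, `ry`, `rz` (cell rear, um).
#'
#' @param annotations named list of [synapse_annotation()] objects.
#' @param path CSV path.
#' @return `path` invisibly; for the reader, a named list of annotations.
#' @export
write_annotations <- function(annotations, path) {
  rows <- lapply(names(annotations), function(id) {
    a <- annotations[[id]]
    data.frame(
      cell_id = id, coupling_frame = a$coupling_frame,
      cx = a$interface_center[1], cy = a$interface_center[2],
      cz = a$interface_center[3],
      rx = a$cell_rear[1], ry = a$cell_rear[2], rz = a$cell_rear[3]
    )
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  d <- read.csv(path)
  out <- lapply(seq_len(nrow(d)), function(i) {
    synapse_annotation(d$coupling_frame[i],
                       c(d$cx[i], d$cy[i], d$cz[i]),
                       c(d$rx[i], d$ry[i], d$rz[i]))
  })
  names(out) <- d$cell_id
  out
}

#' Write / read a membrane trace as CSV
#'
#' Columns `x_um`, `y_um`; the two interface endpoints are stored in an
#' accompanying `paste0(path, ".json")`.
#'
#' @param trace a [membrane_trace()].
#' @param path CSV path.
#' @return `path` invisibly; for the reader, a `membrane_trace`.
#' @export
write_membrane_trace <- function(trace, path) {
  stopifnot(inherits(trace, "membrane_trace"))
  write.csv(
    data.frame(x_um = trace$points$x, y_um = trace$points$y),
    path, row.names = FALSE
  )
  jsonlite::write_json(
    list(endpoints_um = trace$endpoints),
    paste0(path, ".json"), digits = NA
  )
  invisible(path)
}

#' @rdname write_membrane_trace
#' @export
read_membrane_trace <- function(path) {
  d <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  membrane_trace(d$x_um, d$y_um, endpoints = meta$endpoints_um)
}

#' Write pattern calls or frequency tables as TSV
#'
#' @param x data frame (pattern calls or a `frequency_table`).
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read an enrichment region as JSON
#'
#' @param region a [compute_enrichment_region()] result.
#' @param path JSON path.
#' @return `path` invisibly; for the reader, an `enrichment_region`.
#' @export
write_enrichment_region <- function(region, path) {
  stopifnot(inherits(region, "enrichment_region"))
  jsonlite::write_json(
    list(indices = region$indices, n_voxels = region$n_voxels),
    path, digits = NA
  )
  invisible(path)
}

#' @rdname write_enrichment_region
#' @export
read_enrichment_region <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(indices = as.integer(meta$indices),
         n_voxels = as.integer(meta$n_voxels),
         mean_distribution = NULL),
    class = "enrichment_region"
  )
}
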