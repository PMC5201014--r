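#' Multi-channel 3D voxel stack
#'
#' In-memory container for a confocal stack: one non-negative 3D array per
#' channel (array dims are x, y, z), physical voxel size in um and an origin.
#' Voxel `[i, j, k]` has its center at
#' `origin + ((i, j, k) - 0.5) * voxel_size`. Channel names double as roles
#' (`npc`, `nucleolus`, `spb`).
#'
#' @param channels named list of 3D numeric arrays with identical dims.
#' @param voxel_size length-3 `c(dx, dy, dz)` in um, all > 0.
#' @param origin length-3 physical position of the stack corner (um).
#' @return an object of class `voxel_stack`.
#' @export
voxel_stack <- function(channels, voxel_size, origin = c(0, 0, 0)) {
  stopifnot(is.list(channels), length(channels) >= 1, !is.null(names(channels)),
            length(voxel_size) == 3, all(voxel_size > 0), length(origin) == 3)
  dims <- dim(channels[[1]])
  stopifnot(length(dims) == 3)
  for (ch in channels) {
    stopifnot(identical(dim(ch), dims), all(ch >= 0))
  }
  structure(list(channels = channels, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin), dims = dims),
            class = "voxel_stack")
}

#' @export
print.voxel_stack <- function(x, ...) {
  cat("<voxel_stack>", paste(x$dims, collapse = " x "), "voxels,",
      paste(signif(x$voxel_size, 3), collapse = " x "), "um/voxel\n")
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

# physical coordinates of voxel centers along each axis
stack_axes <- function(stack) {
  lapply(1:3, function(d) {
    stack$origin[d] + (seq_len(stack$dims[d]) - 0.5) * stack$voxel_size[d]
  })
}

#' Write a voxel stack to TIFF files plus a JSON sidecar
#'
#' One multi-page (z) 32-bit float TIFF per channel, intensities scaled to
#' `[0, 1]`; the sidecar (`<prefix>_meta.json`) records voxel size, origin,
#' per-channel intensity scale and channel roles so that [read_stack()]
#' restores the stack exactly.
#'
#' @param stack a [voxel_stack()].
#' @param prefix output path prefix; files are `<prefix>_<channel>.tif`.
#' @return the sidecar path, invisibly.
#' @export
write_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "voxel_stack"))
  scales <- vapply(stack$channels, function(ch) max(ch, 1e-12), 0)
  for (ch in names(stack$channels)) {
    arr <- stack$channels[[ch]] / scales[[ch]]
    pages <- lapply(seq_len(stack$dims[3]), function(k) arr[, , k])
    tiff::writeTIFF(pages, sprintf("%s_%s.tif", prefix, ch),
                    bits.per.sample = 32L)
  }
  meta <- list(voxel_size = stack$voxel_size, origin = stack$origin,
               dims = stack$dims, channels = names(stack$channels),
               scales = as.list(scales))
  path <- sprintf("%s_meta.json", prefix)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a voxel stack written by [write_stack()]
#'
#' @param prefix path prefix used when writing.
#' @param voxel_size optional length-3 override of the sidecar voxel size
#'   (explicit configuration wins over file metadata).
#' @return a [voxel_stack()].
#' @export
read_stack <- function(prefix, voxel_size = NULL) {
  meta <- jsonlite::read_json(sprintf("%s_meta.json", prefix),
                              simplifyVector = TRUE)
  dims <- as.integer(meta$dims)
  channels <- list()
  for (ch in meta$channels) {
    pages <- tiff::readTIFF(sprintf("%s_%s.tif", prefix, ch), all = TRUE)
    arr <- array(0, dims)
    for (k in seq_len(dims[3])) arr[, , k] <- pages[[k]]
    channels[[ch]] <- arr * meta$scales[[ch]]
  }
  voxel_stack(channels, voxel_size %||% as.numeric(meta$voxel_size),
              origin = as.numeric(meta$origin))
}
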