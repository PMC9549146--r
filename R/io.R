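#' Write / read gamma power traces as text containers
#'
#' The trial x timepoint matrix goes to a headerless TSV; the time axis,
#' per-trial conditions and contact metadata go to a JSON sidecar next to it
#' (`<path>.json`).
#'
#' @param g A [gpt()] object.
#' @param path TSV path for the matrix.
#' @return `read_gpt()` returns a [gpt()]; `write_gpt()` the path, invisibly.
#' @export
write_gpt <- function(g, path) {
  stopifnot(inherits(g, "gpt"))
  utils::write.table(g$values, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  sidecar <- list(time_s = g$time_s, conditions = g$conditions)
  if (!is.null(g$contact)) sidecar$contact <- as.list(g$contact)
  write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gpt
#' @export
read_gpt <- function(path) {
  values <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(values) <- NULL
  side <- read_json(paste0(path, ".json"), simplifyVector = TRUE)
  contact <- if (!is.null(side$contact)) as_tibble(side$contact) else NULL
  gpt(values, side$time_s, side$conditions, contact)
}

#' Write / read a label volume as text
#'
#' Voxels are stored long-format (`i`, `j`, `k` 0-based, `code`) in a TSV
#' with a JSON sidecar holding the dimensions, voxel size and code-to-name
#' map.
#'
#' @param volume A [label_volume()].
#' @param path TSV path.
#' @return `read_label_volume()` returns a [label_volume()].
#' @export
write_label_volume <- function(volume, path) {
  dims <- dim(volume$voxels)
  idx <- which(volume$voxels != 0, arr.ind = TRUE)
  readr::write_tsv(
    tibble(i = idx[, 1] - 1L, j = idx[, 2] - 1L, k = idx[, 3] - 1L,
           code = volume$voxels[idx]),
    path)
  write_json(list(dim = dims, voxel_size_mm = volume$voxel_size_mm,
                  code_to_name = as.list(volume$code_to_name)),
             paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path) {
  side <- read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  vox <- array(0L, dim = side$dim)
  vox[cbind(tab$i + 1L, tab$j + 1L, tab$k + 1L)] <- as.integer(tab$code)
  label_volume(vox, unlist(side$code_to_name), side$voxel_size_mm)
}
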