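#' Electrode-contact tables
#'
#' A contact table is the spatial backbone of every analysis in this package:
#' one row per depth-electrode contact, with the subject it belongs to, its 3D
#' coordinates on a common brain template (mm), its anatomical structure name
#' (Desikan-Killiany vocabulary) and the hemisphere. All subjects' coordinates
#' must share one template frame.
#'
#' @param x A data frame with columns `subject`, `contact`, `x`, `y`, `z`,
#'   `label`, `hemisphere` (`"LH"` or `"RH"`).
#' @return A validated tibble (class unchanged) in the canonical column order.
#' @examples
#' tbl <- contact_table(tibble::tibble(
#'   subject = "S1", contact = c("A1", "A2"),
#'   x = c(-30, -33.5), y = 0, z = 0,
#'   label = "INSULA", hemisphere = "LH"
#' ))
#' @export
contact_table <- function(x) {
  cols <- c("subject", "contact", "x", "y", "z", "label", "hemisphere")
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols)) {
    abort(paste0("contact table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- as_tibble(x)[cols]
  if (!all(is.finite(x$x) & is.finite(x$y) & is.finite(x$z))) {
    abort("contact coordinates must be finite")
  }
  if (any(!nzchar(x$label) | is.na(x$label))) {
    abort("every contact needs a non-empty anatomical label")
  }
  if (!all(x$hemisphere %in% c("LH", "RH"))) {
    abort("hemisphere must be 'LH' or 'RH'")
  }
  if (anyDuplicated(x[c("subject", "contact")])) {
    abort("(subject, contact) pairs must be unique within a cohort")
  }
  x
}

#' Read or write an electrodes TSV
#'
#' Tab-separated, UTF-8, header required, columns `subject`, `contact`,
#' `x`, `y`, `z`, `label`, `hemisphere`.
#'
#' @param path File path.
#' @return `read_electrodes()` returns a validated contact tibble.
#' @export
read_electrodes <- function(path) {
  contact_table(readr::read_tsv(path, show_col_types = FALSE))
}

#' @param contacts A contact table.
#' @rdname read_electrodes
#' @export
write_electrodes <- function(contacts, path) {
  readr::write_tsv(contact_table(contacts), path)
  invisible(path)
}

#' Anatomical label volumes
#'
#' A small wrapper around a 3D integer array of atlas label codes, with the
#' code-to-name mapping and voxel size. Code 0 is reserved for "unknown".
#' Voxel indices are 0-based, matching the usual neuroimaging convention.
#'
#' @param voxels 3D integer array of label codes.
#' @param code_to_name Named character vector mapping code (as name) to
#'   structure name; code 0 need not be listed.
#' @param voxel_size_mm Length-3 voxel size in mm (default 1 mm isotropic).
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(voxels, code_to_name, voxel_size_mm = c(1, 1, 1)) {
  stopifnot(length(dim(voxels)) == 3, length(voxel_size_mm) == 3)
  codes <- sort(unique(as.vector(voxels)))
  named <- as.integer(names(code_to_name))
  missing_codes <- setdiff(codes, c(0L, named))
  if (length(missing_codes)) {
    abort(paste0("label codes with no name: ",
                 paste(missing_codes, collapse = ", ")))
  }
  structure(
    list(voxels = voxels, code_to_name = code_to_name,
         voxel_size_mm = as.numeric(voxel_size_mm)),
    class = "label_volume"
  )
}

#' Assign an anatomical label by 3x3x3 majority vote
#'
#' Labels a contact with the structure whose code occurs most often among the
#' (at most 27) voxels of a 3x3x3 cube centered on the contact's voxel. The
#' cube is clipped at volume edges. This guards against mislabeling contacts
#' that sit on the border of two structures or in noisy voxels. Ties are broken
#' deterministically in favor of the smallest label code; "unknown" (code 0)
#' never wins a tie against a named label and is returned only when the whole
#' cube is unknown.
#'
#' @param voxel_index Length-3 integer voxel index, 0-based.
#' @param volume A [label_volume()].
#' @return A structure name, or `"unknown"`.
#' @export
assign_anatomical_label <- function(voxel_index, volume) {
  stopifnot(inherits(volume, "label_volume"), length(voxel_index) == 3)
  dims <- dim(volume$voxels)
  idx1 <- as.integer(voxel_index) + 1L  # to 1-based
  if (any(idx1 < 1L) || any(idx1 > dims)) {
    abort(paste0("voxel index (", paste(voxel_index, collapse = ", "),
                 ") is outside the label volume"))
  }
  rng <- function(i) max(1L, idx1[i] - 1L):min(dims[i], idx1[i] + 1L)
  cube <- volume$voxels[rng(1), rng(2), rng(3), drop = FALSE]
  counts <- table(as.vector(cube))
  codes <- as.integer(names(counts))
  named <- codes != 0L
  if (!any(named)) {
    return("unknown")
  }
  counts <- counts[named]
  codes <- codes[named]
  # which.max on a count vector ordered by increasing code = smallest-code tie win
  ord <- order(codes)
  win <- codes[ord][which.max(counts[ord])]
  unname(volume$code_to_name[as.character(win)])
}

#' Label every contact of a table from a label volume
#'
#' Convenience wrapper mapping [assign_anatomical_label()] over contacts whose
#' template coordinates are converted to voxel indices with a given origin.
#'
#' @param contacts Contact table (its `label` column is replaced).
#' @param volume A [label_volume()].
#' @param origin_mm Template-space coordinate of voxel (0, 0, 0).
#' @return The contact table with refreshed `label`.
#' @export
relabel_contacts <- function(contacts, volume, origin_mm = c(0, 0, 0)) {
  contacts <- contact_table(contacts)
  vs <- volume$voxel_size_mm
  labels <- pmap(list(contacts$x, contacts$y, contacts$z), function(x, y, z) {
    idx <- round((c(x, y, z) - origin_mm) / vs)
    assign_anatomical_label(idx, volume)
  })
  contacts$label <- unlist(labels)
  contacts
}

#' Build searchlight neighborhoods over sparse contacts
#'
#' For each contact (the center), collects all contacts of the *same subject*
#' within `radius_mm` Euclidean distance — regardless of whether they sit on
#' the same depth electrode. The ball is closed (distance equal to the radius
#' is included), so every neighborhood contains its own center and membership
#' is symmetric. Neighborhoods never cross subjects because trials are only
#' aligned within a subject.
#'
#' @param contacts A contact table.
#' @param radius_mm Searchlight radius in mm (default 25).
#' @return A tibble with one row per center contact: `subject`, `contact`,
#'   `label`, `hemisphere`, `n_members`, and a list-column `members` of member
#'   contact ids (including the center).
#' @export
build_neighborhoods <- function(contacts, radius_mm = 25) {
  contacts <- contact_table(contacts)
  if (nrow(contacts) == 0) abort("contact table is empty")
  if (!is.numeric(radius_mm) || radius_mm <= 0) abort("radius_mm must be > 0")
  out <- contacts %>%
    group_by(.data$subject) %>%
    dplyr::group_modify(function(df, key) {
      xyz <- as.matrix(df[c("x", "y", "z")])
      d <- as.matrix(stats::dist(xyz))
      members <- lapply(seq_len(nrow(df)), function(i) {
        df$contact[d[i, ] <= radius_mm]
      })
      tibble(
        contact = df$contact, label = df$label, hemisphere = df$hemisphere,
        n_members = lengths(members), members = members
      )
    }) %>%
    ungroup()
  attr(out, "radius_mm") <- radius_mm
  out
}

#' Summarise electrode coverage per structure and hemisphere
#'
#' Counts implanted contacts per (hemisphere, structure); per-hemisphere totals
#' are attached as the attribute `"totals"` and always equal the sum of the
#' per-structure counts.
#'
#' @param contacts A contact table.
#' @return A tibble `hemisphere`, `structure`, `n_contacts`, sorted by
#'   structure then hemisphere, with a `totals` attribute tibble
#'   (`hemisphere`, `n_contacts`).
#' @export
coverage_summary <- function(contacts) {
  contacts <- contact_table(contacts)
  by_structure <- contacts %>%
    count(.data$hemisphere, structure = .data$label, name = "n_contacts") %>%
    arrange(.data$structure, .data$hemisphere)
  totals <- by_structure %>%
    group_by(.data$hemisphere) %>%
    summarise(n_contacts = sum(.data$n_contacts), .groups = "drop")
  attr(by_structure, "totals") <- totals
  by_structure
}
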