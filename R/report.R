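# Report writers: JSON provenance report, TSV cavity table, and a
# pseudo-atom PDB of cavity voxel centres for visualisation.

#' Write a JSON report for a cavity detection
#'
#' The report carries full provenance: parameters, grid metadata (origin,
#' spacing, node counts), stage voxel counts, and the per-cavity table
#' (id, voxel count, volume, centre). Field order is fixed, so two runs on
#' identical input differ only in the `timestamp` field.
#'
#' @param det A `cavity_detection`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_detection_report <- function(det, path) {
  stopifnot(inherits(det, "cavity_detection"))
  report <- list(
    tool = "gausscavity",
    version = as.character(utils::packageVersion("gausscavity")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    molecule = det$label,
    params = det$params,
    grid = list(origin = det$grid$origin, spacing = det$grid$spacing,
                node_counts = det$grid$node_counts,
                voxel_counts = det$grid$voxel_counts),
    n_intermediate_voxels = det$n_intermediate,
    n_cavity_voxels = det$n_cavity_voxels,
    n_cavities = nrow(det$cavities),
    n_rejected = nrow(det$rejected),
    cavities = det$cavities,
    rejected = det$rejected
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write the cavity table of a detection as TSV
#'
#' Columns: `id`, `n_voxels`, `volume` (cubic Angstrom) and the cavity
#' centre `x`, `y`, `z` (Angstrom).
#'
#' @param det A `cavity_detection`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cavity_tsv <- function(det, path) {
  stopifnot(inherits(det, "cavity_detection"))
  utils::write.table(det$cavities, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write cavity voxels as a pseudo-atom PDB
#'
#' One HETATM pseudo-atom per cavity voxel centre, with the cavity id in
#' the residue-number column, so cavities can be inspected in any molecular
#' viewer alongside the protein.
#'
#' @param det A `cavity_detection`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_voxel_pdb <- function(det, path) {
  stopifnot(inherits(det, "cavity_detection"))
  lines <- character(0)
  serial <- 0L
  for (id in seq_along(det$cluster_voxels)) {
    ctr <- voxel_center(det$grid, det$cluster_voxels[[id]])
    for (r in seq_len(nrow(ctr))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "HETATM%5d  CAV CAV %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        serial %% 100000L, "A", id %% 9999L,
        ctr[r, 1], ctr[r, 2], ctr[r, 3], 1, 0
      ))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
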