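# Field post-processing: element scalar fields, region-wise peak
# extraction with singularity exclusion near fiber attachments, VTK-family
# export and summary tables.
#
# Peaks are element-level quantities (volume-weighted averages of the
# quadrature-point values), deliberately not nodal extrapolations: at the
# point attachments of the fiber network the continuum solution is
# singular and nodal peaks would be pure mesh artifacts.

#' Element scalar fields for one solver state
#'
#' Volume-weighted element averages of Von Mises stress and
#' largest-magnitude principal strain at the quadrature points.
#'
#' @param model A \code{discrete_model}.
#' @param state A solver state.
#' @return List with \code{time}, \code{von_mises} (Pa),
#'   \code{principal_strain_magnitude} (dimensionless) and
#'   \code{fiber_force} (N).
#' @export
element_fields <- function(model, state) {
  fl <- frame_fields(model, state)
  list(time = state$t, von_mises = fl$vm,
       principal_strain_magnitude = fl$ps,
       fiber_force = state$fiber_force)
}

#' Elements adjacent to fiber attachment points
#'
#' The one-ring exclusion set: every tetrahedron sharing at least one node
#' with any fiber anchor node. Used to separate the singular,
#' frequency-independent attachment-point values from the physically
#' meaningful field peaks distal to the attachments.
#'
#' @param mesh A \code{cs_mesh}.
#' @return Integer element indices (empty for a fiber-free mesh).
#' @export
attachment_exclusion_set <- function(mesh) {
  anchors <- c(mesh$node_sets$sf_foot_anchors,
               mesh$node_sets$sf_nucleus_anchors)
  if (!length(anchors)) return(integer(0))
  hit <- matrix(mesh$tet10 %in% anchors, nrow = nrow(mesh$tet10))
  which(rowSums(hit) > 0)
}

#' Region-wise field peak over a solution series
#'
#' Maximum of the chosen element scalar over all recorded frames and all
#' elements of the region, optionally ignoring the attachment one-ring.
#'
#' @param series A \code{solution_series}.
#' @param region \code{"cytoplasm"} or \code{"nucleus"}.
#' @param quantity \code{"stress"} (Von Mises, Pa) or \code{"strain"}
#'   (principal-strain magnitude, dimensionless).
#' @param policy \code{"none"} or \code{"exclude_attachment_ring"}.
#' @return A one-row data frame (a peak record): region, quantity,
#'   peak_value, element, frame_time, exclusion_policy.
#' @export
region_peak <- function(series, region = c("cytoplasm", "nucleus"),
                        quantity = c("stress", "strain"),
                        policy = c("none", "exclude_attachment_ring")) {
  region <- match.arg(region)
  quantity <- match.arg(quantity)
  policy <- match.arg(policy)
  rid <- match(region, region_names)
  keep <- which(series$region == rid)
  if (!length(keep)) stopf("region '%s' is empty in this mesh", region)
  if (policy == "exclude_attachment_ring")
    keep <- setdiff(keep, attachment_exclusion_set(series$mesh))
  if (!length(keep)) stopf("exclusion policy removed every element of '%s'",
                           region)
  F <- if (quantity == "stress") series$vm else series$ps
  sub <- F[keep, , drop = FALSE]
  idx <- arrayInd(which.max(sub), dim(sub))
  data.frame(region = region, quantity = quantity,
             peak_value = sub[idx[1], idx[2]],
             element = keep[idx[1]],
             frame_time = series$times[idx[2]],
             exclusion_policy = policy,
             stringsAsFactors = FALSE)
}

#' Scenario summary table
#'
#' One row per scenario x region x quantity with the peak value (stress in
#' Pa, strain in microstrain) and its ratio against the same family's 1 Hz
#' run.
#'
#' @param results List of \code{solution_series} (or a list of lists with
#'   elements \code{series}); names or spec labels identify scenarios.
#' @param policy Peak exclusion policy; defaults to the attachment-ring
#'   exclusion whenever a series has fibers.
#' @return A data frame with columns scenario, frequency_hz, region,
#'   quantity, peak, frame_time_s, excluded_policy, ratio_vs_1hz.
#' @export
summary_table <- function(results, policy = NULL) {
  if (!length(results)) stopf("summary_table needs at least one result")
  rows <- list()
  for (series in results) {
    lab <- series$spec$label
    freq <- series$spec$loading$frequency
    pol <- policy %||% if (!is.null(series$fiber_force))
      "exclude_attachment_ring" else "none"
    for (region in region_names) for (quantity in c("stress", "strain")) {
      pk <- region_peak(series, region, quantity, pol)
      val <- if (quantity == "strain") pk$peak_value * 1e6 else pk$peak_value
      rows[[length(rows) + 1L]] <-
        data.frame(scenario = lab, frequency_hz = freq, region = region,
                   quantity = quantity, peak = val,
                   frame_time_s = pk$frame_time, excluded_policy = pol,
                   stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  fam <- sub("_[0-9]+Hz$", "", tab$scenario)
  tab$ratio_vs_1hz <- NA_real_
  for (i in seq_len(nrow(tab))) {
    ref <- which(fam == fam[i] & tab$frequency_hz == 1 &
                   tab$region == tab$region[i] &
                   tab$quantity == tab$quantity[i])
    if (length(ref) == 1 && tab$peak[ref] > 0)
      tab$ratio_vs_1hz[i] <- tab$peak[i] / tab$peak[ref]
  }
  tab
}

# ---- VTK-family export ---------------------------------------------------

vtu_da <- function(name, x, ncomp = 1, type = "Float64") {
  vals <- paste(format(x, digits = 17, scientific = TRUE, trim = TRUE),
                collapse = " ")
  sprintf('<DataArray type="%s" Name="%s" NumberOfComponents="%d" format="ascii">\n%s\n</DataArray>',
          type, name, ncomp, vals)
}

write_vtu_frame <- function(series, k, path) {
  mesh <- series$mesh
  npts <- nrow(mesh$nodes)
  ntet <- nrow(mesh$tet10)
  ntru <- if (is.null(mesh$tru3)) 0L else nrow(mesh$tru3)
  ncell <- ntet + ntru
  conn <- as.vector(t(mesh$tet10)) - 1L
  offs <- seq_len(ntet) * 10L
  types <- rep(24L, ntet)                     # VTK_QUADRATIC_TETRA
  if (ntru) {
    conn <- c(conn, as.vector(t(mesh$tru3[, c(1, 3, 2), drop = FALSE])) - 1L)
    offs <- c(offs, ntet * 10L + seq_len(ntru) * 3L)
    types <- c(types, rep(21L, ntru))         # VTK_QUADRATIC_EDGE
  }
  u <- if (!is.null(series$U)) matrix(series$U[, k], ncol = 3, byrow = TRUE)
       else matrix(0, npts, 3)
  vmc <- c(series$vm[, k], rep(0, ntru))
  psc <- c(series$ps[, k], rep(0, ntru))
  regc <- c(series$region, rep(0L, ntru))
  xml <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    '<UnstructuredGrid>',
    sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', npts, ncell),
    '<Points>', vtu_da("Points", as.vector(t(mesh$nodes)), 3), '</Points>',
    '<Cells>',
    vtu_da("connectivity", conn, 1, "Int64"),
    vtu_da("offsets", offs, 1, "Int64"),
    vtu_da("types", types, 1, "UInt8"),
    '</Cells>',
    '<PointData>',
    vtu_da("Displacement", as.vector(t(u)), 3),
    '</PointData>',
    '<CellData>',
    vtu_da("VonMises_Pa", vmc), vtu_da("PrincStrain", psc),
    vtu_da("Region", regc, 1, "Int32"),
    '</CellData>',
    '</Piece>', '</UnstructuredGrid>', '</VTKFile>')
  writeLines(xml, path)
}

#' Export a solution series to VTK files
#'
#' Writes one ascii VTU file per recorded frame (quadratic tetrahedra, plus
#' quadratic edge cells for fibers) carrying \code{Displacement},
#' \code{VonMises_Pa} and \code{PrincStrain}, and a PVD collection file
#' indexing them by simulation time. Coordinates are in micrometres
#' (displacements in metres, matching the stored solution).
#'
#' @param series A non-empty \code{solution_series}.
#' @param path Output base path; files are written as
#'   \code{<path>_NNNN.vtu} and \code{<path>.pvd}.
#' @return Invisibly, the written file names.
#' @export
export_vtk <- function(series, path) {
  if (!inherits(series, "solution_series") || length(series$times) == 0)
    stopf("export_vtk needs a non-empty solution_series")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  nf <- length(series$times)
  files <- sprintf("%s_%04d.vtu", path, seq_len(nf) - 1L)
  for (k in seq_len(nf)) write_vtu_frame(series, k, files[k])
  pvd <- c('<?xml version="1.0"?>',
           '<VTKFile type="Collection" version="0.1">', '<Collection>',
           sprintf('<DataSet timestep="%.10g" file="%s"/>',
                   series$times, basename(files)),
           '</Collection>', '</VTKFile>')
  pvd_file <- paste0(path, ".pvd")
  writeLines(pvd, pvd_file)
  invisible(c(files, pvd_file))
}

#' Read back an ascii VTU file written by \code{\link{export_vtk}}
#'
#' @param file Path to a \code{.vtu} file.
#' @return List with \code{points}, \code{connectivity} (1-based, list of
#'   cells), \code{types}, \code{point_data}, \code{cell_data}.
#' @export
read_vtu <- function(file) {
  doc <- xml2::read_xml(file)
  num <- function(node) as.numeric(strsplit(trimws(xml2::xml_text(node)),
                                            "\\s+")[[1]])
  das <- xml2::xml_find_all(doc, ".//DataArray")
  nm <- xml2::xml_attr(das, "Name")
  get <- function(name) num(das[[match(name, nm)]])
  pts <- matrix(get("Points"), ncol = 3, byrow = TRUE)
  conn <- get("connectivity") + 1
  offs <- get("offsets")
  cells <- mapply(function(a, b) conn[a:b], c(1, utils::head(offs, -1) + 1), offs,
                  SIMPLIFY = FALSE)
  point_data <- list(Displacement = matrix(get("Displacement"), ncol = 3,
                                           byrow = TRUE))
  cell_data <- list(VonMises_Pa = get("VonMises_Pa"),
                    PrincStrain = get("PrincStrain"),
                    Region = get("Region"))
  list(points = pts, connectivity = cells, types = get("types"),
       point_data = point_data, cell_data = cell_data)
}

#' Persist / restore a solution series
#'
#' Native serialized container for a \code{solution_series} (frames, field
#' arrays, fiber forces and the scenario echo); use
#' \code{\link{export_vtk}} for interchange with visualization tools.
#'
#' @param series A \code{solution_series}.
#' @param path File path.
#' @return \code{load_series} returns the restored series.
#' @export
save_series <- function(series, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(series, path)
  invisible(path)
}

#' @rdname save_series
#' @export
load_series <- function(path) readRDS(path)
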