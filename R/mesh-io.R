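# Mesh and field import/export: Gmsh 2.2 ASCII (.msh) and VTK
# unstructured-grid XML (.vtu), tetrahedral cells only. Electrode
# assignments travel as tagged surface triangles (.msh physical tags) or
# a cell-data array `electrode_id` (.vtu).

#' Write a mesh to disk
#'
#' Supported formats (chosen by extension): Gmsh 2.2 ASCII `.msh`
#' (tetrahedra plus electrode triangles tagged by electrode id) and VTK
#' unstructured `.vtu` (tetrahedra and electrode triangles with an
#' `electrode_id` cell-data array; volume cells carry id 0).
#'
#' @param mesh an `eit_mesh`.
#' @param path output path ending in `.msh` or `.vtu`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stop_if(!inherits(mesh, "eit_mesh"), "need an eit_mesh")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         msh = write_msh(mesh, path),
         vtu = write_vtu_mesh(mesh, path),
         stop_if(TRUE, "unsupported mesh format: .", ext))
  invisible(path)
}

#' Read a mesh from disk
#'
#' Only tetrahedral volume cells are supported; any other volume cell
#' type is rejected. Electrode triangles are matched back to boundary
#' faces; if the file carries no electrode metadata, a warning is issued
#' and electrodes are left unset.
#'
#' @param path `.msh` or `.vtu` file.
#' @param spec optional [cylinder_spec()] to attach to the mesh.
#' @return an `eit_mesh`.
#' @export
read_mesh <- function(path, spec = NULL) {
  stop_if(!file.exists(path), "no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  parsed <- switch(ext,
                   msh = read_msh(path),
                   vtu = read_vtu_mesh(path),
                   stop_if(TRUE, "unsupported mesh format: .", ext))
  mesh_from_parts(parsed$nodes, parsed$tets, parsed$tri, parsed$tri_id, spec)
}

mesh_from_parts <- function(nodes, tets, tri, tri_id, spec) {
  geo <- tet_geometry(nodes, tets)
  flip <- geo$det < 0
  if (any(flip)) {
    tmp <- tets[flip, 3L]; tets[flip, 3L] <- tets[flip, 4L]; tets[flip, 4L] <- tmp
    geo <- tet_geometry(nodes, tets)
  }
  bf <- boundary_faces_of(tets)
  mesh <- structure(list(
    nodes = nodes, tets = tets,
    boundary_faces = bf$faces, face_owner = bf$owner,
    electrode_faces = NULL,
    element_centroids = geo$centroids, element_volumes = geo$volume,
    n_elements = nrow(tets), spec = spec
  ), class = "eit_mesh")
  if (is.null(tri) || length(tri_id) == 0L || all(tri_id == 0)) {
    warning("no electrode metadata in mesh file; electrodes unset")
    mesh$mesh_hash <- fingerprint(list(nodes, tets))
    return(mesh)
  }
  key <- paste(bf$faces[, 1L], bf$faces[, 2L], bf$faces[, 3L])
  tri_sorted <- t(apply(tri, 1L, sort))
  idx <- match(paste(tri_sorted[, 1L], tri_sorted[, 2L], tri_sorted[, 3L]), key)
  keep <- !is.na(idx) & tri_id > 0
  ids <- sort(unique(tri_id[keep]))
  mesh$electrode_faces <- lapply(seq_len(max(ids)), function(l)
    idx[keep & tri_id == l])
  mesh$mesh_hash <- fingerprint(list(nodes, tets, mesh$electrode_faces))
  mesh
}

electrode_triangles <- function(mesh) {
  if (is.null(mesh$electrode_faces)) {
    return(list(tri = matrix(0L, 0L, 3L), id = integer(0)))
  }
  tri <- do.call(rbind, lapply(seq_along(mesh$electrode_faces), function(l)
    mesh$boundary_faces[mesh$electrode_faces[[l]], , drop = FALSE]))
  id <- unlist(lapply(seq_along(mesh$electrode_faces), function(l)
    rep.int(l, length(mesh$electrode_faces[[l]]))))
  list(tri = tri, id = id)
}

write_msh <- function(mesh, path) {
  et <- electrode_triangles(mesh)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(nrow(mesh$nodes))), con)
  writeLines(sprintf("%d %.17g %.17g %.17g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1L], mesh$nodes[, 2L], mesh$nodes[, 3L]), con)
  writeLines(c("$EndNodes", "$Elements",
               as.character(nrow(et$tri) + nrow(mesh$tets))), con)
  k <- 0L
  if (nrow(et$tri) > 0L) {
    writeLines(sprintf("%d 2 2 %d %d %d %d %d",
                       seq_len(nrow(et$tri)), et$id, et$id,
                       et$tri[, 1L], et$tri[, 2L], et$tri[, 3L]), con)
    k <- nrow(et$tri)
  }
  writeLines(sprintf("%d 4 2 0 0 %d %d %d %d",
                     k + seq_len(nrow(mesh$tets)),
                     mesh$tets[, 1L], mesh$tets[, 2L],
                     mesh$tets[, 3L], mesh$tets[, 4L]), con)
  writeLines("$EndElements", con)
}

read_msh <- function(path) {
  lines <- readLines(path)
  sect <- function(tag) {
    i0 <- which(lines == paste0("$", tag)) + 1L
    i1 <- which(lines == paste0("$End", tag)) - 1L
    stop_if(length(i0) != 1L || length(i1) != 1L, "malformed .msh: ", tag)
    lines[i0:i1]
  }
  nl <- sect("Nodes")
  n <- as.integer(nl[1L])
  nd <- do.call(rbind, lapply(strsplit(nl[1L + seq_len(n)], "\\s+"), as.numeric))
  nodes <- nd[order(nd[, 1L]), 2:4, drop = FALSE]
  el <- sect("Elements")
  ne <- as.integer(el[1L])
  rows <- strsplit(el[1L + seq_len(ne)], "\\s+")
  tets <- list(); tri <- list(); tri_id <- integer(0)
  for (r in rows) {
    v <- as.integer(r)
    type <- v[2L]; ntags <- v[3L]
    conn <- v[(4L + ntags):length(v)]
    if (type == 4L) {
      tets[[length(tets) + 1L]] <- conn
    } else if (type == 2L) {
      tri[[length(tri) + 1L]] <- conn
      tri_id <- c(tri_id, if (ntags >= 1L) v[4L] else 0L)
    } else {
      stop_if(TRUE, "unsupported cell type in .msh (only tetrahedra ",
              "and electrode triangles): type ", type)
    }
  }
  stop_if(length(tets) == 0L, "no tetrahedral cells in .msh")
  list(nodes = nodes, tets = do.call(rbind, tets),
       tri = if (length(tri)) do.call(rbind, tri) else NULL, tri_id = tri_id)
}

vtu_header <- function() {
  paste0("<?xml version=\"1.0\"?>\n",
         "<VTKFile type=\"UnstructuredGrid\" version=\"0.1\" ",
         "byte_order=\"LittleEndian\">\n")
}

write_vtu_cells <- function(con, nodes, cells, celltypes, celldata) {
  npts <- nrow(nodes); ncell <- length(cells)
  cat(vtu_header(), file = con)
  cat(sprintf("<UnstructuredGrid>\n<Piece NumberOfPoints=\"%d\" NumberOfCells=\"%d\">\n",
              npts, ncell), file = con)
  cat("<Points>\n<DataArray type=\"Float64\" NumberOfComponents=\"3\" format=\"ascii\">\n",
      file = con)
  cat(sprintf("%.17g %.17g %.17g", nodes[, 1L], nodes[, 2L], nodes[, 3L]),
      sep = "\n", file = con)
  cat("</DataArray>\n</Points>\n<Cells>\n", file = con)
  cat("<DataArray type=\"Int64\" Name=\"connectivity\" format=\"ascii\">\n", file = con)
  cat(vapply(cells, function(cl) paste(cl - 1L, collapse = " "), ""),
      sep = "\n", file = con)
  cat("</DataArray>\n<DataArray type=\"Int64\" Name=\"offsets\" format=\"ascii\">\n",
      file = con)
  cat(cumsum(vapply(cells, length, 1L)), sep = "\n", file = con)
  cat("</DataArray>\n<DataArray type=\"UInt8\" Name=\"types\" format=\"ascii\">\n",
      file = con)
  cat(celltypes, sep = "\n", file = con)
  cat("</DataArray>\n</Cells>\n", file = con)
  if (length(celldata)) {
    cat("<CellData>\n", file = con)
    for (nm in names(celldata)) {
      x <- celldata[[nm]]
      type <- if (is.integer(x)) "Int64" else "Float64"
      fmtd <- if (is.integer(x)) as.character(x) else sprintf("%.17g", x)
      cat(sprintf("<DataArray type=\"%s\" Name=\"%s\" format=\"ascii\">\n",
                  type, nm), file = con)
      cat(fmtd, sep = "\n", file = con)
      cat("</DataArray>\n", file = con)
    }
    cat("</CellData>\n", file = con)
  }
  cat("</Piece>\n</UnstructuredGrid>\n</VTKFile>\n", file = con)
}

write_vtu_mesh <- function(mesh, path) {
  et <- electrode_triangles(mesh)
  cells <- c(lapply(seq_len(nrow(mesh$tets)), function(i) mesh$tets[i, ]),
             lapply(seq_len(nrow(et$tri)), function(i) et$tri[i, ]))
  types <- c(rep(10L, nrow(mesh$tets)), rep(5L, nrow(et$tri)))
  eid <- c(rep(0L, nrow(mesh$tets)), as.integer(et$id))
  con <- file(path, "w"); on.exit(close(con))
  write_vtu_cells(con, mesh$nodes, cells, types,
                  list(electrode_id = eid))
}

read_vtu_mesh <- function(path) {
  stop_if(!requireNamespace("xml2", quietly = TRUE), "xml2 is required")
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  num <- function(xp) {
    nd <- xml2::xml_find_first(piece, xp)
    stop_if(is.na(nd) || inherits(nd, "xml_missing"), "malformed .vtu: ", xp)
    scan(text = xml2::xml_text(nd), quiet = TRUE)
  }
  pts <- matrix(num(".//Points/DataArray"), ncol = 3L, byrow = TRUE)
  conn <- as.integer(num(".//Cells/DataArray[@Name='connectivity']")) + 1L
  offs <- as.integer(num(".//Cells/DataArray[@Name='offsets']"))
  types <- as.integer(num(".//Cells/DataArray[@Name='types']"))
  eid_nd <- xml2::xml_find_first(piece, ".//CellData/DataArray[@Name='electrode_id']")
  eid <- if (inherits(eid_nd, "xml_missing")) rep(0L, length(types)) else
    as.integer(scan(text = xml2::xml_text(eid_nd), quiet = TRUE))
  starts <- c(1L, head(offs, -1L) + 1L)
  tets <- list(); tri <- list(); tri_id <- integer(0)
  for (i in seq_along(types)) {
    cl <- conn[starts[i]:offs[i]]
    if (types[i] == 10L) {
      tets[[length(tets) + 1L]] <- cl
    } else if (types[i] == 5L) {
      tri[[length(tri) + 1L]] <- cl
      tri_id <- c(tri_id, eid[i])
    } else {
      stop_if(TRUE, "unsupported cell type in .vtu (only tetrahedra and ",
              "triangles): VTK type ", types[i])
    }
  }
  stop_if(length(tets) == 0L, "no tetrahedral cells in .vtu")
  list(nodes = pts, tets = do.call(rbind, tets),
       tri = if (length(tri)) do.call(rbind, tri) else NULL, tri_id = tri_id)
}

#' Export a conductivity field as a VTK unstructured grid
#'
#' Writes the mesh's tetrahedra with the per-element scalar
#' `sigma_S_per_m`; values survive a write/read round trip to at least
#' 1e-12 relative.
#'
#' @param field an `eit_field` bound to `mesh`.
#' @param mesh an `eit_mesh`.
#' @param path output `.vtu` path.
#' @return `path`, invisibly.
#' @export
export_vtk <- function(field, mesh, path) {
  check_binding(field, mesh)
  cells <- lapply(seq_len(nrow(mesh$tets)), function(i) mesh$tets[i, ])
  con <- file(path, "w"); on.exit(close(con))
  write_vtu_cells(con, mesh$nodes, cells, rep(10L, nrow(mesh$tets)),
                  list(sigma_S_per_m = field$values))
  invisible(path)
}

#' Read back an exported conductivity field
#'
#' @param path a `.vtu` written by [export_vtk()].
#' @param mesh the `eit_mesh` the field belongs to.
#' @return an `eit_field`.
#' @export
import_vtk_field <- function(path, mesh) {
  stop_if(!requireNamespace("xml2", quietly = TRUE), "xml2 is required")
  doc <- xml2::read_xml(path)
  nd <- xml2::xml_find_first(doc, ".//CellData/DataArray[@Name='sigma_S_per_m']")
  stop_if(inherits(nd, "xml_missing"), "no sigma_S_per_m array in file")
  vals <- scan(text = xml2::xml_text(nd), quiet = TRUE)
  conductivity_field(vals, mesh)
}
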