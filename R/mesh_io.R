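# Mesh file formats: ASCII VTU (read/write) and Gmsh MSH 4.1 (read).
#
# VTU files written here carry the tetrahedra (VTK cell type 10) plus the
# tagged boundary triangles (type 5) with a `surface_tag` cell array
# (0 = volume, 1 = endocardium, 2 = epicardium, 3 = base), so facet tags
# round-trip exactly.  Nodal fields (e.g. the transmural coordinate, pressure
# snapshots) are written as PointData.

surface_tag_codes <- c(endocardium = 1L, epicardium = 2L, base = 3L)

#' Write a wall mesh (and optional nodal fields) to ASCII VTU
#'
#' @param mesh a `wall_mesh`.
#' @param path output `.vtu` path.
#' @param point_data named list of per-node numeric vectors to include; the
#'   transmural coordinate is added automatically as `"lambda"` when present.
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, path, point_data = list()) {
  stopifnot(inherits(mesh, "wall_mesh"))
  if (!is.null(mesh$transmural) && is.null(point_data[["lambda"]])) {
    point_data[["lambda"]] <- mesh$transmural
  }
  np <- nrow(mesh$nodes)
  conn <- c(t(mesh$tets) - 1L, t(mesh$facets) - 1L)
  sizes <- c(rep(4L, nrow(mesh$tets)), rep(3L, nrow(mesh$facets)))
  offsets <- cumsum(sizes)
  types <- c(rep(10L, nrow(mesh$tets)), rep(5L, nrow(mesh$facets)))
  tags <- c(rep(0L, nrow(mesh$tets)),
            unname(surface_tag_codes[mesh$facet_tags]))
  num <- function(x, digits = 10) paste(formatC(x, format = "g", digits = digits),
                                        collapse = " ")
  da <- function(name, x, type = "Float64", ncomp = NULL) {
    comp <- if (is.null(ncomp)) "" else sprintf(' NumberOfComponents="%d"', ncomp)
    sprintf('<DataArray type="%s" Name="%s"%s format="ascii">\n%s\n</DataArray>',
            type, name, comp,
            if (type == "Float64") num(x) else paste(as.integer(x), collapse = " "))
  }
  pd <- paste(vapply(names(point_data), function(nm) {
    da(nm, as.numeric(point_data[[nm]]))
  }, character(1)), collapse = "\n")
  xml <- paste0(
    '<?xml version="1.0"?>\n',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">\n',
    '<UnstructuredGrid>\n',
    sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">\n', np, length(types)),
    '<Points>\n', da("Points", t(mesh$nodes), ncomp = 3), '\n</Points>\n',
    '<Cells>\n',
    da("connectivity", conn, type = "Int64"), "\n",
    da("offsets", offsets, type = "Int64"), "\n",
    da("types", types, type = "Int64"), "\n",
    '</Cells>\n',
    '<CellData>\n', da("surface_tag", tags, type = "Int64"), '\n</CellData>\n',
    if (nzchar(pd)) paste0("<PointData>\n", pd, "\n</PointData>\n") else "",
    '</Piece>\n</UnstructuredGrid>\n</VTKFile>\n'
  )
  writeLines(xml, path)
  invisible(path)
}

vtu_array <- function(piece, name) {
  nodeset <- xml2::xml_find_all(piece, ".//DataArray")
  nm <- vapply(nodeset, function(n) xml2::xml_attr(n, "Name"), character(1))
  hit <- which(nm == name)
  if (length(hit) == 0) return(NULL)
  txt <- xml2::xml_text(nodeset[[hit[1]]])
  as.numeric(strsplit(trimws(txt), "\\s+")[[1]])
}

#' Read a wall mesh from a VTU or Gmsh MSH file
#'
#' VTU files must contain tetrahedral cells; boundary surface tags are taken
#' from triangle cells with a `surface_tag` cell array (as written by
#' [write_vtu()]).  MSH 4.1 files must carry physical surface names
#' `endocardium`, `epicardium`, `base` on the boundary triangles.
#' Coordinates are interpreted in mm.
#'
#' @param path mesh file path (`.vtu` or `.msh`).
#' @param format `"vtu"`, `"msh"`, or `"auto"` (from the extension).
#' @return a `wall_mesh` with the transmural coordinate recomputed.
#' @export
read_wall_mesh <- function(path, format = c("auto", "vtu", "msh")) {
  format <- match.arg(format)
  if (!file.exists(path)) rlang::abort(paste0("mesh file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.msh$", path, ignore.case = TRUE)) "msh" else "vtu"
  }
  mesh <- if (format == "vtu") read_vtu_mesh(path) else read_msh_mesh(path)
  mesh$transmural <- compute_transmural_coordinate(mesh)
  mesh
}

read_vtu_mesh <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  pts <- vtu_array(xml2::xml_find_first(piece, ".//Points"), "Points")
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  cells <- xml2::xml_find_first(piece, ".//Cells")
  conn <- as.integer(vtu_array(cells, "connectivity")) + 1L
  offsets <- as.integer(vtu_array(cells, "offsets"))
  types <- as.integer(vtu_array(cells, "types"))
  bad <- setdiff(unique(types), c(5L, 10L))
  if (length(bad) > 0) {
    rlang::abort(paste0("unsupported VTK cell type(s): ", paste(bad, collapse = ", "),
                        " (only tetrahedra and boundary triangles are supported)"))
  }
  starts <- c(1L, utils::head(offsets, -1) + 1L)
  tag_arr <- vtu_array(piece, "surface_tag")
  tets <- list(); facets <- list(); ftags <- character()
  code2tag <- stats::setNames(names(surface_tag_codes), surface_tag_codes)
  for (c_i in seq_along(types)) {
    ids <- conn[starts[c_i]:offsets[c_i]]
    if (types[c_i] == 10L) {
      tets[[length(tets) + 1]] <- ids
    } else {
      facets[[length(facets) + 1]] <- ids
      code <- if (is.null(tag_arr)) NA else as.integer(tag_arr[c_i])
      ftags <- c(ftags, ifelse(is.na(code) || code == 0, NA, code2tag[as.character(code)]))
    }
  }
  if (length(tets) == 0) rlang::abort("VTU file contains no tetrahedral cells")
  tets <- do.call(rbind, tets)
  if (length(facets) == 0 || anyNA(ftags)) {
    rlang::abort("VTU file lacks tagged boundary triangles (surface_tag cell data)")
  }
  facets <- do.call(rbind, facets)
  found <- unique(ftags)
  missing <- setdiff(names(surface_tag_codes), found)
  if (length(missing) > 0) {
    rlang::abort(paste0("missing surface tag(s): ", paste(missing, collapse = ", "),
                        "; found: ", paste(found, collapse = ", ")))
  }
  new_wall_mesh(nodes, tets, facets, ftags)
}

read_msh_mesh <- function(path) {
  lines <- readLines(path)
  sec <- function(name) {
    a <- which(lines == paste0("$", name)); b <- which(lines == paste0("$End", name))
    if (length(a) == 0 || length(b) == 0) return(NULL)
    lines[(a + 1):(b - 1)]
  }
  ver <- strsplit(trimws(sec("MeshFormat")[1]), "\\s+")[[1]]
  if (!startsWith(ver[1], "4")) rlang::abort("only MSH format 4.x is supported")
  # physical names -> surface tag names
  phys <- sec("PhysicalNames")
  phys_map <- character()
  if (!is.null(phys)) {
    n <- as.integer(phys[1])
    for (k in seq_len(n)) {
      f <- strsplit(trimws(phys[k + 1]), "\\s+")[[1]]
      phys_map[f[2]] <- gsub('"', "", paste(f[-(1:2)], collapse = " "))
    }
  }
  # entities: map (dim=2) entity tag -> physical tag
  ent <- sec("Entities")
  surf_phys <- character()
  if (!is.null(ent)) {
    counts <- as.integer(strsplit(trimws(ent[1]), "\\s+")[[1]])
    row <- 2 + counts[1] + counts[2]            # skip points and curves
    for (k in seq_len(counts[3])) {
      f <- as.numeric(strsplit(trimws(ent[row]), "\\s+")[[1]])
      npt <- as.integer(f[8])
      if (npt > 0) surf_phys[as.character(as.integer(f[1]))] <- as.character(as.integer(f[9]))
      row <- row + 1
    }
  }
  # nodes
  nl <- sec("Nodes")
  hdr <- as.integer(strsplit(trimws(nl[1]), "\\s+")[[1]])
  nblocks <- hdr[1]
  row <- 2
  ids <- integer(); coords <- list()
  for (b in seq_len(nblocks)) {
    bh <- as.integer(strsplit(trimws(nl[row]), "\\s+")[[1]])
    nn <- bh[4]; row <- row + 1
    if (nn > 0) {
      bid <- as.integer(nl[row:(row + nn - 1)]); row <- row + nn
      cc <- do.call(rbind, lapply(nl[row:(row + nn - 1)], function(s) {
        as.numeric(strsplit(trimws(s), "\\s+")[[1]])[1:3]
      }))
      row <- row + nn
      ids <- c(ids, bid); coords[[b]] <- cc
    }
  }
  coords <- do.call(rbind, coords)
  remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
  # elements
  el <- sec("Elements")
  hdr <- as.integer(strsplit(trimws(el[1]), "\\s+")[[1]])
  nblocks <- hdr[1]; row <- 2
  tets <- list(); facets <- list(); ftags <- character()
  for (b in seq_len(nblocks)) {
    bh <- as.integer(strsplit(trimws(el[row]), "\\s+")[[1]])
    dim <- bh[1]; etag <- bh[2]; etype <- bh[3]; ne <- bh[4]
    row <- row + 1
    if (ne == 0) next
    rows <- el[row:(row + ne - 1)]; row <- row + ne
    parse <- function(s) as.integer(strsplit(trimws(s), "\\s+")[[1]])[-1]
    if (etype == 4L) {
      tets[[length(tets) + 1]] <- do.call(rbind, lapply(rows, parse))
    } else if (etype == 2L) {
      ptag <- surf_phys[as.character(etag)]
      nm <- if (!is.na(ptag)) phys_map[ptag] else NA_character_
      facets[[length(facets) + 1]] <- do.call(rbind, lapply(rows, parse))
      ftags <- c(ftags, rep(nm, ne))
    } else if (dim == 3L) {
      rlang::abort(paste0("unsupported volume element type ", etype,
                          " (only tetrahedra are supported)"))
    }
  }
  if (length(tets) == 0) rlang::abort("MSH file contains no tetrahedra")
  tets <- apply(do.call(rbind, tets), c(1, 2), function(i) remap[i])
  facets <- apply(do.call(rbind, facets), c(1, 2), function(i) remap[i])
  ftags[is.na(ftags)] <- "untagged"
  found <- unique(ftags)
  missing <- setdiff(names(surface_tag_codes), found)
  if (length(missing) > 0) {
    rlang::abort(paste0("missing surface tag(s): ", paste(missing, collapse = ", "),
                        "; found: ", paste(found, collapse = ", ")))
  }
  keep <- ftags %in% names(surface_tag_codes)
  new_wall_mesh(coords, tets, facets[keep, , drop = FALSE], ftags[keep])
}
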