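#' Read a Gmsh MSH (ASCII v2.2) tetrahedral mesh
#'
#' Supports the MSH 2.2 ASCII dialect. Physical volume groups become region
#' labels; point elements (type 15) carrying a physical name become node
#' sets, the conventional Gmsh encoding for named node selections. Elements
#' whose physical tag has no name are labelled `"unassigned"` with a
#' warning. Elements are reoriented to positive signed volume on read.
#'
#' @param path path to a `.msh` file.
#' @return a [tet4_mesh()].
#' @seealso [write_msh()]
#' @export
read_msh <- function(path) {
  lines <- readLines(path)
  section <- function(name) {
    beg <- match(paste0("$", name), lines)
    end <- match(paste0("$End", name), lines)
    if (is.na(beg) || is.na(end)) return(NULL)
    lines[(beg + 1L):(end - 1L)]
  }

  fmt <- section("MeshFormat")
  if (is.null(fmt)) stop("not a Gmsh MSH file (no $MeshFormat): ", path)
  ver <- strsplit(trimws(fmt[1L]), "\\s+")[[1L]][1L]
  if (!startsWith(ver, "2."))
    stop("unsupported MSH version ", ver, " (need ASCII v2.x)")

  phys <- list()
  pn <- section("PhysicalNames")
  if (!is.null(pn) && length(pn) > 1L) {
    for (ln in pn[-1L]) {
      m <- regmatches(ln, regexec('^\\s*(\\d+)\\s+(\\d+)\\s+"(.*)"', ln))[[1L]]
      if (length(m) == 4L)
        phys[[paste(m[2L], m[3L])]] <- list(dim = as.integer(m[2L]),
                                            tag = as.integer(m[3L]),
                                            name = m[4L])
    }
  }
  phys_dim <- vapply(phys, function(p) p$dim, integer(1))
  phys_tag <- vapply(phys, function(p) p$tag, integer(1))
  phys_name <- vapply(phys, function(p) p$name, character(1))

  nsec <- section("Nodes")
  if (is.null(nsec)) stop("MSH file has no $Nodes section")
  nn <- as.integer(nsec[1L])
  ntab <- matrix(scan(text = nsec[-1L], quiet = TRUE), ncol = 4L, byrow = TRUE)
  if (nrow(ntab) != nn) stop("node count mismatch in $Nodes")
  # ids may be non-contiguous; map to 1..n in file order
  id_map <- integer(max(ntab[, 1L]))
  id_map[as.integer(ntab[, 1L])] <- seq_len(nn)
  nodes <- ntab[, 2:4, drop = FALSE]

  esec <- section("Elements")
  if (is.null(esec)) stop("MSH file has no $Elements section")
  ne <- as.integer(esec[1L])
  elines <- esec[-1L]
  if (length(elines) != ne) stop("element count mismatch in $Elements")

  lookup_name <- function(dim, tag) {
    hit <- which(phys_dim == dim & phys_tag == tag)
    if (length(hit)) phys_name[hit[1L]] else NA_character_
  }

  tets <- vector("list", ne)
  tet_region <- character(ne)
  node_sets <- list()
  nt <- 0L
  unknown <- character(0)
  for (ln in elines) {
    v <- as.integer(strsplit(trimws(ln), "\\s+")[[1L]])
    type <- v[2L]; ntags <- v[3L]
    tags <- if (ntags > 0L) v[4L:(3L + ntags)] else integer(0)
    conn <- v[(4L + ntags):length(v)]
    if (type == 4L) {
      nt <- nt + 1L
      tets[[nt]] <- id_map[conn]
      nm <- if (length(tags)) lookup_name(3L, tags[1L]) else NA_character_
      if (is.na(nm)) {
        unknown <- c(unknown, as.character(if (length(tags)) tags[1L] else -1L))
        nm <- "unassigned"
      }
      tet_region[nt] <- nm
    } else if (type == 15L) {
      nm <- if (length(tags)) lookup_name(0L, tags[1L]) else NA_character_
      if (!is.na(nm))
        node_sets[[nm]] <- c(node_sets[[nm]], id_map[conn[1L]])
    } # other element types (surface triangles etc.) are ignored
  }
  if (nt == 0L)
    stop("MSH file contains no 4-node tetrahedral elements: ", path)
  if (length(unknown))
    warning("physical tag(s) without a name: ",
            paste(unique(unknown), collapse = ", "),
            "; elements labelled 'unassigned'")

  tet4_mesh(nodes, do.call(rbind, tets[seq_len(nt)]),
            tet_region[seq_len(nt)], node_sets)
}

#' Write a mesh as Gmsh MSH ASCII v2.2
#'
#' Regions are written as physical volume groups and node sets as type-15
#' point elements carrying a physical name, so [read_msh()] round-trips
#' regions and node sets exactly.
#'
#' @param mesh a [tet4_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msh <- function(mesh, path) {
  stopifnot(inherits(mesh, "tet4_mesh"))
  regions <- sort(unique(mesh$region))
  region_tag <- stats::setNames(seq_along(regions), regions)
  set_names <- names(mesh$node_sets)
  set_tag <- stats::setNames(100L + seq_along(set_names), set_names)

  out <- c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
           "$PhysicalNames", length(regions) + length(set_names),
           sprintf('3 %d "%s"', region_tag, regions),
           if (length(set_names)) sprintf('0 %d "%s"', set_tag, set_names),
           "$EndPhysicalNames",
           "$Nodes", nrow(mesh$nodes),
           sprintf("%d %.17g %.17g %.17g", seq_len(nrow(mesh$nodes)),
                   mesh$nodes[, 1L], mesh$nodes[, 2L], mesh$nodes[, 3L]),
           "$EndNodes")

  pts <- character(0)
  eid <- 0L
  for (nm in set_names) {
    idx <- mesh$node_sets[[nm]]
    pts <- c(pts, sprintf("%d 15 2 %d %d %d", eid + seq_along(idx),
                          set_tag[[nm]], set_tag[[nm]], idx))
    eid <- eid + length(idx)
  }
  el <- mesh$elements
  tet_lines <- sprintf("%d 4 2 %d %d %d %d %d %d",
                       eid + seq_len(nrow(el)),
                       region_tag[mesh$region], region_tag[mesh$region],
                       el[, 1L], el[, 2L], el[, 3L], el[, 4L])
  out <- c(out, "$Elements", eid + nrow(el), pts, tet_lines, "$EndElements")
  writeLines(out, path)
  invisible(path)
}

#' Export per-node fields as a legacy VTK unstructured grid
#'
#' Writes the mesh plus named nodal fields (scalars or 3-vectors, e.g. the
#' real part of a complex displacement field at a chosen phase) as VTK
#' legacy ASCII, readable by ParaView and similar tools. Values are written
#' with 17 significant digits so a re-read reproduces them to better than
#' 1e-12 relative.
#'
#' @param mesh a [tet4_mesh()].
#' @param fields named list; each entry a numeric vector of length
#'   `n_nodes(mesh)` or a matrix with that many rows and 3 columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [read_vtk_fields()]
#' @export
write_fields_vtk <- function(mesh, fields, path) {
  stopifnot(inherits(mesh, "tet4_mesh"))
  if (length(fields) && is.null(names(fields)))
    stop("`fields` must be a named list")
  n <- n_nodes(mesh)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    len <- if (is.matrix(f)) nrow(f) else length(f)
    if (len != n)
      stop("field '", nm, "' has ", len, " entries; mesh has ", n, " nodes")
  }
  el <- mesh$elements
  out <- c("# vtk DataFile Version 3.0",
           "vibroskull nodal fields",
           "ASCII",
           "DATASET UNSTRUCTURED_GRID",
           sprintf("POINTS %d double", n),
           sprintf("%.17g %.17g %.17g",
                   mesh$nodes[, 1L], mesh$nodes[, 2L], mesh$nodes[, 3L]),
           sprintf("CELLS %d %d", nrow(el), 5L * nrow(el)),
           sprintf("4 %d %d %d %d", el[, 1L] - 1L, el[, 2L] - 1L,
                   el[, 3L] - 1L, el[, 4L] - 1L),
           sprintf("CELL_TYPES %d", nrow(el)),
           rep("10", nrow(el)),
           sprintf("CELL_DATA %d", nrow(el)),
           "SCALARS region_id int 1",
           "LOOKUP_TABLE default",
           as.character(as.integer(factor(mesh$region))))
  if (length(fields)) {
    out <- c(out, sprintf("POINT_DATA %d", n))
    for (nm in names(fields)) {
      f <- fields[[nm]]
      if (is.matrix(f)) {
        out <- c(out, sprintf("VECTORS %s double", nm),
                 sprintf("%.17g %.17g %.17g", f[, 1L], f[, 2L], f[, 3L]))
      } else {
        out <- c(out, sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default", sprintf("%.17g", f))
      }
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read back points and nodal fields from a legacy VTK file
#'
#' Minimal reader for the files produced by [write_fields_vtk()]; intended
#' for round-trip verification.
#'
#' @param path a VTK legacy ASCII file.
#' @return list with `points` (n x 3 matrix) and `fields` (named list).
#' @export
read_vtk_fields <- function(path) {
  lines <- readLines(path)
  i_pts <- grep("^POINTS ", lines)[1L]
  if (is.na(i_pts)) stop("no POINTS section in ", path)
  n <- as.integer(strsplit(lines[i_pts], "\\s+")[[1L]][2L])
  pts <- matrix(scan(text = lines[i_pts + seq_len(n)], quiet = TRUE),
                ncol = 3L, byrow = TRUE)
  fields <- list()
  i_pd <- grep("^POINT_DATA ", lines)
  if (length(i_pd)) {
    i <- i_pd[1L] + 1L
    while (i <= length(lines)) {
      ln <- lines[i]
      if (startsWith(ln, "VECTORS ")) {
        nm <- strsplit(ln, "\\s+")[[1L]][2L]
        fields[[nm]] <- matrix(scan(text = lines[i + seq_len(n)], quiet = TRUE),
                               ncol = 3L, byrow = TRUE)
        i <- i + n + 1L
      } else if (startsWith(ln, "SCALARS ")) {
        nm <- strsplit(ln, "\\s+")[[1L]][2L]
        fields[[nm]] <- scan(text = lines[i + 1L + seq_len(n)], quiet = TRUE)
        i <- i + n + 2L
      } else i <- i + 1L
    }
  }
  list(points = pts, fields = fields)
}
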