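#' Linear-tetrahedron volume mesh
#'
#' `tet4_mesh()` builds the package's core mesh object: node coordinates in
#' metres, four-node tetrahedral elements, one region label per element
#' (e.g. `"bone"`, `"polyurethane"`), and named node sets used to place
#' loads and response probes (`"stim_site"`, `"ipsi_cochlea"`, ...).
#'
#' Elements are brought to canonical orientation on construction: any
#' element listed with negative signed volume has its last two nodes
#' swapped so that all signed volumes are positive. Node and element
#' indices are 1-based throughout.
#'
#' @param nodes numeric matrix, one row per node, columns x/y/z in metres.
#' @param elements integer matrix, one row per element, four node indices.
#' @param region character vector, one region label per element.
#' @param node_sets named list of integer vectors of node indices.
#' @return an object of class `tet4_mesh` with fields `nodes`, `elements`,
#'   `region`, `node_sets`.
#' @examples
#' m <- tet4_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'                matrix(1:4, 1), region = "bone")
#' element_volumes(m) # 1/6
#' @export
tet4_mesh <- function(nodes, elements, region, node_sets = list()) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  if (ncol(nodes) != 3L) stop("`nodes` must have 3 columns (x, y, z)")
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  if (ncol(elements) != 4L) stop("`elements` must have 4 columns")
  n <- nrow(nodes)
  if (any(elements < 1L) || any(elements > n))
    stop("element node indices out of range 1..", n)
  if (length(region) == 1L) region <- rep(region, nrow(elements))
  if (length(region) != nrow(elements))
    stop("`region` must have one label per element")
  region <- as.character(region)
  if (!is.list(node_sets) || (length(node_sets) && is.null(names(node_sets))))
    stop("`node_sets` must be a named list")
  for (nm in names(node_sets)) {
    idx <- as.integer(node_sets[[nm]])
    if (any(idx < 1L) || any(idx > n))
      stop("node set '", nm, "' references nodes outside 1..", n)
    node_sets[[nm]] <- idx
  }

  v <- tet_signed_volumes(nodes, elements)
  neg <- which(v < 0)
  if (length(neg)) {
    elements[neg, 3:4] <- elements[neg, 4:3]
    v[neg] <- -v[neg]
  }
  scale <- max(abs(v))
  if (scale == 0 || any(v <= 1e-12 * scale))
    stop("degenerate (zero-volume) element present")

  structure(
    list(nodes = nodes, elements = elements, region = region,
         node_sets = node_sets),
    class = "tet4_mesh")
}

#' Signed volumes of tetrahedra
#'
#' @param nodes node coordinate matrix.
#' @param elements element connectivity matrix.
#' @return numeric vector of signed volumes (m^3).
#' @keywords internal
tet_signed_volumes <- function(nodes, elements) {
  a <- nodes[elements[, 1L], , drop = FALSE]
  b <- nodes[elements[, 2L], , drop = FALSE] - a
  c_ <- nodes[elements[, 3L], , drop = FALSE] - a
  d <- nodes[elements[, 4L], , drop = FALSE] - a
  (b[, 1L] * (c_[, 2L] * d[, 3L] - c_[, 3L] * d[, 2L]) -
   b[, 2L] * (c_[, 1L] * d[, 3L] - c_[, 3L] * d[, 1L]) +
   b[, 3L] * (c_[, 1L] * d[, 2L] - c_[, 2L] * d[, 1L])) / 6
}

#' Element volumes of a mesh
#'
#' @param mesh a [tet4_mesh()].
#' @return numeric vector of (positive) element volumes in m^3.
#' @export
element_volumes <- function(mesh) {
  stopifnot(inherits(mesh, "tet4_mesh"))
  tet_signed_volumes(mesh$nodes, mesh$elements)
}

#' Total volume of a mesh region
#'
#' @param mesh a [tet4_mesh()].
#' @param region region label, or `"all"` for the whole mesh.
#' @return volume in m^3.
#' @export
region_volume <- function(mesh, region = "all") {
  v <- element_volumes(mesh)
  if (identical(region, "all")) return(sum(v))
  if (!region %in% mesh$region) stop("unknown region '", region, "'")
  sum(v[mesh$region == region])
}

#' Number of nodes / elements
#' @param mesh a [tet4_mesh()].
#' @return integer count.
#' @export
n_nodes <- function(mesh) nrow(mesh$nodes)

#' @rdname n_nodes
#' @export
n_elements <- function(mesh) nrow(mesh$elements)

#' @export
print.tet4_mesh <- function(x, ...) {
  cat("<tet4_mesh> ", n_nodes(x), " nodes, ", n_elements(x), " tet4 elements\n",
      sep = "")
  tab <- table(x$region)
  cat("  regions: ",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n", sep = "")
  if (length(x$node_sets))
    cat("  node sets: ",
        paste(sprintf("%s (%d)", names(x$node_sets),
                      lengths(x$node_sets)), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

# All (unordered) triangular faces of every element; used for watertightness
# checks: an interior face appears exactly twice, a boundary face once.
tet_face_keys <- function(mesh) {
  el <- mesh$elements
  f <- rbind(el[, c(1, 2, 3)], el[, c(1, 2, 4)],
             el[, c(1, 3, 4)], el[, c(2, 3, 4)])
  f <- t(apply(f, 1L, sort))
  paste(f[, 1L], f[, 2L], f[, 3L], sep = "-")
}
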