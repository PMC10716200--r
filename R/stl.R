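# STL surface-mesh input/output. Both the ASCII ("solid ... facet normal
# ...") and the binary layout (80-byte header, uint32 facet count, then 50
# bytes per facet: normal, three vertices as float32, uint16 attribute) are
# supported. Vertices are stored to single precision, the format's native
# resolution.

#' Write a surface mesh to an STL file
#'
#' Native quadrilateral meshes are triangulated (two triangles per quad)
#' before writing; imported triangle meshes are written as-is. Facet
#' normals are recomputed from vertex winding.
#'
#' @param mesh A `surface_mesh`.
#' @param file Output path.
#' @param binary Write binary STL (default) or ASCII.
#' @return `file`, invisibly.
#' @export
write_stl <- function(mesh, file, binary = TRUE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  tris <- mesh_triangles(mesh)
  nd <- mesh$nodes
  n <- nrow(tris)
  normals <- t(vapply(seq_len(n), function(k) {
    f <- tris[k, ]
    nrm <- crossprod3(nd[f[2], ] - nd[f[1], ], nd[f[3], ] - nd[f[1], ])
    len <- sqrt(sum(nrm^2))
    if (len > 0) nrm / len else c(0, 0, 0)
  }, numeric(3)))
  if (binary) {
    con <- file(file, "wb")
    on.exit(close(con))
    header <- charToRaw(formatC("helixvessel binary STL", width = -80))
    length(header) <- 80L
    header[is.na(header)] <- as.raw(0)
    writeBin(header, con)
    writeBin(as.integer(n), con, size = 4L, endian = "little")
    for (k in seq_len(n)) {
      f <- tris[k, ]
      writeBin(as.numeric(c(normals[k, ], t(nd[f, ]))), con,
               size = 4L, endian = "little")
      writeBin(0L, con, size = 2L, endian = "little")
    }
  } else {
    con <- file(file, "w")
    on.exit(close(con))
    writeLines("solid helixvessel", con)
    for (k in seq_len(n)) {
      f <- tris[k, ]
      writeLines(sprintf("  facet normal %.8e %.8e %.8e",
                         normals[k, 1], normals[k, 2], normals[k, 3]), con)
      writeLines("    outer loop", con)
      for (v in f) {
        writeLines(sprintf("      vertex %.8e %.8e %.8e",
                           nd[v, 1], nd[v, 2], nd[v, 3]), con)
      }
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
    writeLines("endsolid helixvessel", con)
  }
  invisible(file)
}

#' Read an STL file as an external surface mesh
#'
#' Detects binary vs ASCII STL automatically. Imported meshes are flagged
#' `external = TRUE`: they carry triangles and vertex coordinates but no
#' cylindrical (z, phi) parameterization, so they are usable for geometry
#' statistics (bounding boxes, areas) but not for the structured-shell
#' solver. Vertices are welded exactly (identical single-precision
#' coordinates collapse to one node).
#'
#' @param file Path to an ASCII or binary STL file.
#' @return A `surface_mesh` with fields `nodes`, `tris`, `external = TRUE`.
#' @export
read_stl <- function(file) {
  if (!file.exists(file)) stop("read_stl: no such file: ", file, call. = FALSE)
  size <- file.info(file)$size
  if (size < 15) stop("read_stl: malformed STL (file too short, ", size,
                      " bytes)", call. = FALSE)
  con <- file(file, "rb")
  head84 <- readBin(con, "raw", n = min(84, size))
  close(con)
  is_binary <- FALSE
  if (size >= 84) {
    n_facets <- readBin(head84[81:84], "integer", size = 4L, endian = "little")
    if (!is.na(n_facets) && n_facets >= 0 && size == 84 + 50 * n_facets)
      is_binary <- TRUE
  }
  if (is_binary) read_stl_binary(file) else read_stl_ascii(file)
}

read_stl_binary <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  n <- readBin(con, "integer", size = 4L, endian = "little")
  verts <- matrix(NA_real_, nrow = 3L * n, ncol = 3L)
  for (k in seq_len(n)) {
    rec <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
    if (length(rec) < 12L) {
      stop("read_stl: malformed binary STL, truncated at byte offset ",
           84 + 50 * (k - 1), call. = FALSE)
    }
    verts[(3 * k - 2):(3 * k), ] <- matrix(rec[4:12], nrow = 3L, byrow = TRUE)
    readBin(con, "integer", n = 1L, size = 2L, endian = "little")
  }
  weld_triangles(verts, n)
}

read_stl_ascii <- function(file) {
  lines <- readLines(file, warn = FALSE)
  if (!grepl("^\\s*solid", lines[1]))
    stop("read_stl: malformed STL (neither valid binary layout nor ASCII ",
         "'solid' header at byte offset 0)", call. = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop("read_stl: malformed ASCII STL (vertex count ", length(vl),
         " not a multiple of 3)", call. = FALSE)
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4]))
  verts <- do.call(rbind, nums)
  if (anyNA(verts)) stop("read_stl: malformed ASCII STL (non-numeric vertex)",
                         call. = FALSE)
  weld_triangles(verts, nrow(verts) / 3L)
}

weld_triangles <- function(verts, n_tri) {
  key <- apply(verts, 1L, function(v) paste(v, collapse = "_"))
  uk <- !duplicated(key)
  nodes <- verts[uk, , drop = FALSE]
  map <- match(key, key[uk])
  tris <- matrix(map, ncol = 3L, byrow = TRUE)
  colnames(nodes) <- c("x", "y", "z")
  structure(list(nodes = nodes, tris = tris, external = TRUE,
                 n_facets = n_tri),
            class = "surface_mesh")
}

#' Bounding box of a surface mesh
#'
#' @param mesh A `surface_mesh` (native or imported).
#' @return A 2 x 3 matrix with rows `min`, `max` over x, y, z (mm).
#' @export
mesh_bbox <- function(mesh) {
  nd <- mesh$nodes
  rbind(min = apply(nd, 2, min), max = apply(nd, 2, max))
}
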