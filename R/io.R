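# File formats: ASCII PLY with per-face patch labels (the label-carrying
# format), read-only OFF and ASCII STL for interoperability, CSV wall
# fields and station profiles.

fmt17 <- function(x) sprintf("%.17g", x)

#' Write a surface mesh
#'
#' PLY (ASCII) carries the triangulation plus per-face integer patch
#' labels; STL and OFF drop the labels (with a warning).
#'
#' @param g A `duct_geometry` or surface list with `vertices`,
#'   `triangles` and optionally `patch_labels`.
#' @param path Output file; format chosen by extension (`.ply`, `.off`,
#'   `.stl`).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(g, path) {
  s <- as_surface(g)
  labels <- if (inherits(g, "duct_geometry")) g$patch_labels
            else g$patch_labels %||% NULL
  ext <- tolower(tools::file_ext(path))
  v <- s$vertices
  tr <- s$triangles
  if (ext == "ply") {
    has_lab <- !is.null(labels)
    header <- c("ply", "format ascii 1.0",
                "comment written by noseflow",
                sprintf("element vertex %d", nrow(v)),
                "property double x", "property double y", "property double z",
                sprintf("element face %d", nrow(tr)),
                "property list uchar int vertex_indices",
                if (has_lab) "property int patch",
                "end_header")
    vlines <- paste(fmt17(v[, 1]), fmt17(v[, 2]), fmt17(v[, 3]))
    flines <- paste(3, tr[, 1] - 1L, tr[, 2] - 1L, tr[, 3] - 1L)
    if (has_lab) flines <- paste(flines, labels)
    writeLines(c(header, vlines, flines), path)
  } else if (ext == "off") {
    if (!is.null(labels))
      warning("OFF output drops patch labels")
    writeLines(c("OFF",
                 sprintf("%d %d 0", nrow(v), nrow(tr)),
                 paste(fmt17(v[, 1]), fmt17(v[, 2]), fmt17(v[, 3])),
                 paste(3, tr[, 1] - 1L, tr[, 2] - 1L, tr[, 3] - 1L)),
               path)
  } else if (ext == "stl") {
    if (!is.null(labels))
      warning("STL output drops patch labels")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid noseflow", con)
    for (t in seq_len(nrow(tr))) {
      p <- v[tr[t, ], , drop = FALSE]
      n <- c((p[2, 2] - p[1, 2]) * (p[3, 3] - p[1, 3]) -
               (p[2, 3] - p[1, 3]) * (p[3, 2] - p[1, 2]),
             (p[2, 3] - p[1, 3]) * (p[3, 1] - p[1, 1]) -
               (p[2, 1] - p[1, 1]) * (p[3, 3] - p[1, 3]),
             (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
               (p[2, 2] - p[1, 2]) * (p[3, 1] - p[1, 1]))
      nn <- sqrt(sum(n^2))
      if (nn > 0) n <- n / nn
      writeLines(c(sprintf("facet normal %s %s %s",
                           fmt17(n[1]), fmt17(n[2]), fmt17(n[3])),
                   "  outer loop",
                   sprintf("    vertex %s %s %s",
                           fmt17(p[, 1]), fmt17(p[, 2]), fmt17(p[, 3])),
                   "  endloop", "endfacet"), con)
    }
    writeLines("endsolid noseflow", con)
  } else {
    stop("unsupported mesh format: .", ext)
  }
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || trimws(lines[1]) != "ply")
    stop("not a PLY file: ", path)
  end <- which(trimws(lines) == "end_header")[1]
  if (is.na(end)) stop("PLY header without end_header: ", path)
  header <- trimws(lines[2:(end - 1)])
  fmt <- grep("^format ", header, value = TRUE)
  if (!grepl("ascii", fmt))
    stop("only ASCII PLY is supported (", path, " is ", fmt, ")")
  elems <- list()
  cur <- NULL
  for (h in header) {
    tok <- strsplit(h, "\\s+")[[1]]
    if (tok[1] == "element") {
      cur <- tok[2]
      elems[[cur]] <- list(n = as.integer(tok[3]), props = character(0))
    } else if (tok[1] == "property" && !is.null(cur)) {
      elems[[cur]]$props <- c(elems[[cur]]$props, tok[length(tok)])
    }
  }
  if (is.null(elems$vertex) || is.null(elems$face))
    stop("PLY file must contain vertex and face elements: ", path)
  nv <- elems$vertex$n
  nf <- elems$face$n
  body <- lines[(end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf)
    stop("PLY body truncated at line ", end + length(body) + 1, ": ", path)
  vprops <- elems$vertex$props
  xyz_idx <- match(c("x", "y", "z"), vprops)
  if (any(is.na(xyz_idx))) stop("PLY vertex element lacks x/y/z: ", path)
  vdat <- utils::read.table(text = body[seq_len(nv)])
  vertices <- as.matrix(vdat[, xyz_idx])
  dimnames(vertices) <- NULL
  fdat <- utils::read.table(text = body[nv + seq_len(nf)])
  if (any(fdat[, 1] != 3))
    stop("non-triangular face in PLY file: ", path)
  triangles <- as.matrix(fdat[, 2:4]) + 1L
  dimnames(triangles) <- NULL
  storage.mode(triangles) <- "integer"
  patch <- NULL
  fprops <- setdiff(elems$face$props, "vertex_indices")
  if ("patch" %in% fprops && ncol(fdat) >= 5)
    patch <- as.integer(fdat[, 5])
  list(vertices = vertices, triangles = triangles, patch_labels = patch)
}

read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", trimws(lines))]
  if (trimws(lines[1]) != "OFF") stop("not an OFF file: ", path)
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- counts[1]
  nf <- counts[2]
  vertices <- as.matrix(utils::read.table(text = lines[2 + seq_len(nv)]))
  dimnames(vertices) <- NULL
  fdat <- utils::read.table(text = lines[2 + nv + seq_len(nf)])
  if (any(fdat[, 1] != 3)) stop("non-triangular face in OFF file: ", path)
  triangles <- as.matrix(fdat[, 2:4]) + 1L
  dimnames(triangles) <- NULL
  storage.mode(triangles) <- "integer"
  list(vertices = vertices, triangles = triangles, patch_labels = NULL)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^\\s*solid", lines[1]))
    stop("only ASCII STL is supported: ", path)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop("malformed ASCII STL (vertex count ", length(vl), "): ", path)
  coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(t)
    as.numeric(t[2:4])))
  key <- paste(coords[, 1], coords[, 2], coords[, 3])
  uk <- !duplicated(key)
  vertices <- coords[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  triangles <- matrix(idx, ncol = 3, byrow = TRUE)
  storage.mode(triangles) <- "integer"
  list(vertices = vertices, triangles = triangles, patch_labels = NULL)
}

#' Read a surface mesh
#'
#' Auto-detects ASCII PLY, OFF and ASCII STL.  PLY files may carry
#' per-face integer patch labels (property `patch`); STL/OFF meshes load
#' without labels or station structure (a warning is issued) and support
#' field mapping, distances and surface histograms, but not the flow
#' proxy.
#'
#' @param path Input file.
#' @return A list of class `surface_mesh` with `vertices` (mm),
#'   `triangles` (1-based) and `patch_labels` (or `NULL`).
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- trimws(readLines(path, n = 1, warn = FALSE))
  out <- if (grepl("^ply", first)) read_ply(path)
    else if (grepl("^OFF", first)) read_off(path)
    else if (grepl("^solid", first)) read_stl_ascii(path)
    else stop("unsupported mesh format (expected PLY/OFF/ASCII STL): ", path)
  if (is.null(out$patch_labels))
    warning("mesh ", basename(path),
            " carries no patch labels; flow proxy unavailable unless ",
            "profiles are supplied separately")
  if (nrow(out$vertices) < 3 || nrow(out$triangles) < 1)
    stop("degenerate mesh (", nrow(out$vertices), " vertices, ",
         nrow(out$triangles), " triangles): ", path)
  structure(out, class = "surface_mesh")
}

#' Write / read a wall field as CSV
#'
#' Plain CSV with columns `vertex_id` (1-based) and `value`, written with
#' 17 significant digits so round-trips are exact.
#'
#' @param field A `wall_field` or numeric vector.
#' @param path File path.
#' @return `write_field`: `path` invisibly; `read_field`: a numeric
#'   vector of values ordered by `vertex_id`.
#' @export
write_field <- function(field, path) {
  v <- field_values(field)
  writeLines(c("vertex_id,value",
               paste(seq_along(v), fmt17(v), sep = ",")), path)
  invisible(path)
}

#' @rdname write_field
#' @param n_vertices Optional expected vertex count; a mismatch is an
#'   error.
#' @export
read_field <- function(path, n_vertices = NULL) {
  d <- utils::read.csv(path, colClasses = c("integer", "character"))
  if (!identical(names(d), c("vertex_id", "value")))
    stop("field CSV must have columns vertex_id,value; got: ",
         paste(names(d), collapse = ","), " in ", path)
  vals <- suppressWarnings(as.numeric(d$value))
  if (any(!is.finite(vals)))
    stop("non-finite field values at rows ",
         paste(utils::head(which(!is.finite(vals)), 5), collapse = ", "),
         " in ", path)
  if (!is.null(n_vertices) && nrow(d) != n_vertices)
    stop("field length ", nrow(d), " does not match mesh vertex count ",
         n_vertices, ": ", path)
  vals[order(d$vertex_id)]
}

#' Write / read station profiles as CSV
#'
#' Columns `side`, `station`, `s`, `area_mm2`, `perimeter_mm` plus the
#' semi-axes, ring centers and arc length needed to re-drive the flow
#' proxy.
#'
#' @param g A `duct_geometry`.
#' @param path File path.
#' @return `write_profiles`: `path` invisibly; `read_profiles`: a named
#'   list of per-side profile data.frames.
#' @export
write_profiles <- function(g, path) {
  tabs <- lapply(c("left", "right"), function(side)
    cbind(side = side, g$profiles[[side]]))
  d <- do.call(rbind, tabs)
  utils::write.csv(format(d, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  d <- utils::read.csv(path)
  need <- c("side", "station", "s", "area_mm2", "perimeter_mm")
  if (!all(need %in% names(d)))
    stop("profiles CSV must contain columns ",
         paste(need, collapse = ", "), ": ", path)
  split(d[setdiff(names(d), "side")], d$side)
}
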