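# Minimal STL (ASCII + binary) and PLY (ASCII) surface-mesh I/O.
# No mesh-I/O package ships with this stack, and the formats are simple
# enough that a small reader/writer keeps the dependency surface flat.

#' Load a segmented tumor surface mesh from an STL or PLY file
#'
#' Reads the triangle soup, merges coincident vertices, enforces a closed and
#' consistently oriented surface (outward orientation is restored by sign of
#' the enclosed volume), and normalizes units to metres. Files written in
#' millimetres (the common convention for anatomical surface exports) are
#' detected by a bounding-box heuristic: an extent above 0.3 in file units is
#' taken to be millimetres.
#'
#' @param path STL (ASCII or binary) or PLY (ASCII) file.
#' @param units `"auto"` (bounding-box heuristic), `"m"` or `"mm"`.
#' @return an `mwa_mesh` in metres.
#' @export
load_tumor_mesh <- function(path, units = c("auto", "m", "mm")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty mesh file: ", path)
  ext <- tolower(tools::file_ext(path))
  raw_mesh <- switch(ext,
                     stl = read_stl(path),
                     ply = read_ply(path),
                     stop("unsupported mesh format: .", ext,
                          " (expected .stl or .ply)"))
  v <- raw_mesh$vertices
  f <- raw_mesh$faces
  # merge coincident vertices (STL repeats them per facet)
  key <- paste(signif(v[, 1], 10), signif(v[, 2], 10), signif(v[, 3], 10))
  idx <- match(key, unique(key))
  v <- v[!duplicated(key), , drop = FALSE]
  f <- matrix(idx[f], ncol = 3)
  # drop degenerate faces
  ok <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  f <- f[ok, , drop = FALSE]
  scale <- switch(units, m = 1, mm = 1e-3, auto = {
    extent <- max(apply(v, 2, max) - apply(v, 2, min))
    if (extent > 0.3) 1e-3 else 1
  })
  mesh <- new_tumor_mesh(v * scale, f, provenance = path)
  assert_watertight(mesh)
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

#' Write a tumor mesh to STL (ASCII) or PLY (ASCII)
#'
#' Output is deterministic (fixed number formatting), so identical meshes
#' produce byte-identical files.
#'
#' @param mesh an `mwa_mesh`.
#' @param path output path; format chosen by extension (.stl or .ply).
#' @param units `"m"` or `"mm"` for the written coordinates.
#' @return `path`, invisibly.
#' @export
write_tumor_mesh <- function(mesh, path, units = c("mm", "m")) {
  units <- match.arg(units)
  scale <- if (units == "mm") 1e3 else 1
  v <- mesh$vertices * scale
  f <- mesh$faces
  ext <- tolower(tools::file_ext(path))
  con <- file(path, "wb") # binary mode: fixed \n newlines on all platforms
  on.exit(close(con))
  if (ext == "stl") {
    a <- v[f[, 1], , drop = FALSE]
    b <- v[f[, 2], , drop = FALSE]
    c_ <- v[f[, 3], , drop = FALSE]
    n <- cbind((b[, 2] - a[, 2]) * (c_[, 3] - a[, 3]) - (b[, 3] - a[, 3]) * (c_[, 2] - a[, 2]),
               (b[, 3] - a[, 3]) * (c_[, 1] - a[, 1]) - (b[, 1] - a[, 1]) * (c_[, 3] - a[, 3]),
               (b[, 1] - a[, 1]) * (c_[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (c_[, 1] - a[, 1]))
    len <- sqrt(rowSums(n^2))
    len[len == 0] <- 1
    n <- n / len
    fmt3 <- function(m) sprintf("%.9e %.9e %.9e", m[, 1], m[, 2], m[, 3])
    lines <- c("solid mwaplan",
               as.vector(rbind(
                 sprintf("  facet normal %s", fmt3(n)),
                 "    outer loop",
                 sprintf("      vertex %s", fmt3(a)),
                 sprintf("      vertex %s", fmt3(b)),
                 sprintf("      vertex %s", fmt3(c_)),
                 "    endloop",
                 "  endfacet")),
               "endsolid mwaplan")
    writeLines(lines, con)
  } else if (ext == "ply") {
    header <- c("ply", "format ascii 1.0",
                sprintf("element vertex %d", nrow(v)),
                "property double x", "property double y", "property double z",
                sprintf("element face %d", nrow(f)),
                "property list uchar int vertex_indices", "end_header")
    writeLines(c(header,
                 sprintf("%.9e %.9e %.9e", v[, 1], v[, 2], v[, 3]),
                 sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)),
               con)
  } else {
    stop("unsupported mesh format: .", ext)
  }
  invisible(path)
}

read_stl <- function(path) {
  # binary STL: 80-byte header, uint32 facet count, 50 bytes per facet
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 80)
  is_binary <- FALSE
  if (sz >= 84) {
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (!is.na(ntri) && ntri > 0 && sz == 84 + 50 * ntri) is_binary <- TRUE
  }
  if (is_binary) {
    tri <- matrix(0, ntri * 3, 3)
    for (t in seq_len(ntri)) {
      rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
      readBin(con, "raw", 2)
      tri[(t - 1) * 3 + 1:3, ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    }
  } else {
    close(con)
    on.exit()
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (!length(vl)) stop("no vertices found in STL file: ", path)
    nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
      as.numeric(x[2:4])))
    tri <- nums
  }
  if (nrow(tri) %% 3 != 0) stop("malformed STL: vertex count not divisible by 3")
  nf <- nrow(tri) / 3
  list(vertices = tri,
       faces = matrix(seq_len(nrow(tri)), nf, 3, byrow = TRUE))
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1]) != "ply") stop("not a PLY file: ", path)
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("malformed PLY: no end_header")
  header <- trimws(lines[seq_len(end)])
  if (!any(grepl("^format ascii", header))) {
    stop("only ASCII PLY is supported")
  }
  nv <- as.integer(sub("^element vertex\\s+", "",
                       grep("^element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub("^element face\\s+", "",
                       grep("^element face", header, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("malformed PLY header")
  body <- lines[(end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  vparts <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  v <- do.call(rbind, lapply(vparts, function(x) as.numeric(x[1:3])))
  fparts <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  f <- do.call(rbind, lapply(fparts, function(x) {
    n <- as.integer(x[1])
    if (n != 3) stop("only triangulated PLY faces are supported")
    as.integer(x[2:4]) + 1L
  }))
  list(vertices = v, faces = f)
}
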