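#' @useDynLib mwaplan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# run code under a fixed RNG seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

new_tumor_mesh <- function(vertices, faces, provenance, seed = NA_integer_) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 3,
            is.matrix(faces), ncol(faces) == 3)
  structure(list(vertices = vertices, faces = faces,
                 provenance = provenance, seed = seed),
            class = "mwa_mesh")
}

#' @export
print.mwa_mesh <- function(x, ...) {
  bb <- mesh_bbox(x)
  cat(sprintf("<mwa_mesh> %d vertices, %d faces (%s)\n",
              nrow(x$vertices), nrow(x$faces), x$provenance))
  cat(sprintf("  bbox %.2f x %.2f x %.2f mm, volume %.3f cm^3\n",
              1e3 * diff(bb[, 1]), 1e3 * diff(bb[, 2]), 1e3 * diff(bb[, 3]),
              1e6 * mesh_volume(x)))
  invisible(x)
}

#' Axis-aligned bounding box of a mesh
#' @param mesh an `mwa_mesh`.
#' @return 2x3 matrix (rows min/max, columns x/y/z), metres.
#' @export
mesh_bbox <- function(mesh) {
  rbind(apply(mesh$vertices, 2, min), apply(mesh$vertices, 2, max))
}

#' Enclosed volume of a closed triangulated surface
#'
#' Signed tetrahedron sum (divergence theorem); positive for an outward
#' oriented closed surface.
#' @param mesh an `mwa_mesh`.
#' @return volume in m^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cross <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
                 b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
                 b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(rowSums(a * cross)) / 6
}

#' Volume centroid of a closed triangulated surface
#' @param mesh an `mwa_mesh`.
#' @return length-3 numeric, metres.
#' @export
mesh_centroid <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cross <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
                 b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
                 b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  w <- rowSums(a * cross) # 6 * signed tetra volume
  vol6 <- sum(w)
  cent <- colSums((a + b + c_) / 4 * w) / vol6
  as.numeric(cent)
}

# edge-pairing watertightness check; returns NULL or a defect description
mesh_defect <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) < 4) return("too few faces to bound a volume")
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  if (any(cnt != 2)) {
    n_open <- sum(cnt == 1)
    n_nonman <- sum(cnt > 2)
    if (n_open > 0) return(sprintf("open surface: %d boundary edges", n_open))
    return(sprintf("non-manifold surface: %d edges shared by >2 faces", n_nonman))
  }
  # consistent orientation: each undirected edge must appear once per direction
  dir_key <- paste(e[, 1], e[, 2])
  if (any(table(dir_key) != 1)) {
    return("inconsistently oriented faces")
  }
  NULL
}

assert_watertight <- function(mesh) {
  d <- mesh_defect(mesh)
  if (!is.null(d)) stop("mesh is not a closed oriented surface: ", d)
  invisible(mesh)
}

# unit icosphere: subdivided icosahedron, vertices on the unit sphere
icosphere <- function(subdivisions = 4) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    edge_id <- new.env(hash = TRUE)
    verts <- list(v)
    next_id <- nv
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- edge_id[[key]]
      if (!is.null(id)) return(id)
      m <- (v[i, ] + v[j, ])
      m <- m / sqrt(sum(m^2))
      next_id <<- next_id + 1
      verts[[length(verts) + 1]] <<- m
      edge_id[[key]] <- next_id
      next_id
    }
    nf <- matrix(0L, nrow(f) * 4, 3)
    for (t in seq_len(nrow(f))) {
      i <- f[t, 1]; j <- f[t, 2]; k <- f[t, 3]
      a <- midpoint(i, j); b <- midpoint(j, k); c_ <- midpoint(k, i)
      nf[(t - 1) * 4 + 1, ] <- c(i, a, c_)
      nf[(t - 1) * 4 + 2, ] <- c(j, b, a)
      nf[(t - 1) * 4 + 3, ] <- c(k, c_, b)
      nf[(t - 1) * 4 + 4, ] <- c(a, b, c_)
    }
    v <- do.call(rbind, c(list(v), verts[-1]))
    f <- nf
  }
  list(vertices = v, faces = f)
}

# real low-order spherical harmonic basis (l = 2, 3) evaluated at unit vectors
sh_basis <- function(u) {
  x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
  cbind(
    x * y, y * z, x * z, x^2 - y^2, 3 * z^2 - 1,
    z * (5 * z^2 - 3), x * (5 * z^2 - 1), y * (5 * z^2 - 1),
    z * (x^2 - y^2), x * y * z, x * (x^2 - 3 * y^2), y * (3 * x^2 - y^2))
}

#' Generate a synthetic tumor surface phantom
#'
#' Builds a closed triangulated surface emulating one of the two study
#' tumors from the 3D-IRCADb-01 liver database via their published bounding
#' boxes (preset `"ircad-1.07"`: 1.74 x 1.53 x 2.10 cm; `"ircad-1.03"`:
#' 1.78 x 1.97 x 2.27 cm), or an arbitrary ellipsoid from explicit semi-axes.
#' With `perturbation_amplitude = 0` the result is an exact triangulated
#' ellipsoid; a positive amplitude applies a smooth, low-order
#' spherical-harmonic radial modulation (seed-reproducible) standing in for
#' the irregular shape of a real segmented tumor, after which the mesh is
#' rescaled per axis so its bounding box still matches the requested box.
#'
#' @param preset `"ircad-1.07"` or `"ircad-1.03"`; ignored when `semi_axes`
#'   is given.
#' @param semi_axes optional explicit semi-axes (m), length 3.
#' @param perturbation_amplitude relative radial modulation amplitude, in
#'   \[0, 0.3\].
#' @param seed integer RNG seed for the modulation coefficients.
#' @param subdivisions icosphere subdivision level (4 gives 2562 vertices).
#' @return an `mwa_mesh` (vertices in metres, centred at the origin).
#' @export
generate_tumor_phantom <- function(preset = c("ircad-1.07", "ircad-1.03"),
                                   semi_axes = NULL,
                                   perturbation_amplitude = 0,
                                   seed = 0L,
                                   subdivisions = 4) {
  if (perturbation_amplitude < 0 || perturbation_amplitude > 0.3) {
    stop("perturbation_amplitude must be in [0, 0.3]")
  }
  if (is.null(semi_axes)) {
    if (is.character(preset) && length(preset) == 1 &&
        !preset %in% c("ircad-1.07", "ircad-1.03")) {
      stop("unknown phantom preset: ", preset)
    }
    preset <- match.arg(preset)
    box_cm <- switch(preset,
                     "ircad-1.07" = c(1.74, 1.53, 2.10),
                     "ircad-1.03" = c(1.78, 1.97, 2.27))
    semi_axes <- box_cm * 1e-2 / 2
    provenance <- paste0("phantom:", preset)
  } else {
    stopifnot(length(semi_axes) == 3, all(semi_axes > 0))
    provenance <- "phantom:custom"
  }
  ico <- icosphere(subdivisions)
  u <- ico$vertices
  radial <- rep(1, nrow(u))
  if (perturbation_amplitude > 0) {
    basis <- sh_basis(u)
    coef <- with_seed(seed, stats::rnorm(ncol(basis)))
    g <- drop(basis %*% coef)
    g <- g / max(abs(g))
    radial <- 1 + perturbation_amplitude * g
  }
  v <- u * radial
  v <- sweep(v, 2, semi_axes, "*")
  # restore the requested axis-aligned bounding box exactly, centred at 0
  vmin <- apply(v, 2, min)
  vmax <- apply(v, 2, max)
  v <- sweep(v, 2, 2 * semi_axes / (vmax - vmin), "*")
  vmin <- apply(v, 2, min)
  vmax <- apply(v, 2, max)
  v <- sweep(v, 2, (vmin + vmax) / 2, "-")
  mesh <- new_tumor_mesh(v, ico$faces, provenance, as.integer(seed))
  assert_watertight(mesh)
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}
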