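# Stack IO: image stacks with acquisition geometry, TIFF reading/writing,
# and surface-mesh export of label volumes.

#' Acquisition geometry of a slice-and-view stack
#'
#' Bundles the voxel geometry of a FIB/SEM slice-and-view acquisition: the
#' in-plane pixel sizes, the thickness of material removed per slicing step,
#' and the angle between the SEM optical axis and the normal of the cut face.
#' Pixel sizes refer to physical sample-plane distance per pixel of the
#' raster they accompany; after [correct_view_angle()] the vertical pixel
#' size is updated so physical heights are preserved.
#'
#' @param pixel_size_x,pixel_size_y In-plane pixel size in nm/pixel.
#' @param slice_thickness Material removed per slicing step, nm.
#' @param view_angle Angle in degrees between SEM axis and cut-face normal;
#'   must satisfy `0 <= view_angle < 90`. A corrected stack has 0.
#' @return An object of class `voxel_geometry`.
#' @examples
#' voxel_geometry()  # the defaults mirror a typical acquisition
#' @export
voxel_geometry <- function(pixel_size_x = 6.3, pixel_size_y = 6.3,
                           slice_thickness = 40, view_angle = 0) {
  if (!all(is.finite(c(pixel_size_x, pixel_size_y, slice_thickness, view_angle)))) {
    stop("geometry values must be finite")
  }
  if (pixel_size_x <= 0 || pixel_size_y <= 0 || slice_thickness <= 0) {
    stop("all geometry lengths must be strictly positive")
  }
  if (view_angle < 0 || view_angle >= 90) {
    stop("view_angle must satisfy 0 <= view_angle < 90 degrees")
  }
  structure(list(pixel_size_x = pixel_size_x, pixel_size_y = pixel_size_y,
                 slice_thickness = slice_thickness, view_angle = view_angle),
            class = "voxel_geometry")
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf("voxel geometry: %.3g x %.3g x %.3g nm, view angle %.3g deg\n",
              x$pixel_size_x, x$pixel_size_y, x$slice_thickness, x$view_angle))
  invisible(x)
}

#' Voxel volume in cubic nanometres
#' @param geometry A [voxel_geometry()].
#' @return Scalar, nm^3 per voxel.
#' @export
voxel_volume_nm3 <- function(geometry) {
  geometry$pixel_size_x * geometry$pixel_size_y * geometry$slice_thickness
}

#' Construct an image stack
#'
#' An ordered set of 2D grayscale intensity slices with attached voxel
#' geometry. Slice index is the slicing axis: slice `k+1` lies one
#' `slice_thickness` deeper into the sample than slice `k` (that depth has
#' been consumed by the ion beam). Within a slice, row 1 is the image top.
#'
#' @param slices List of numeric matrices, all of identical dimension, with
#'   finite non-negative intensities.
#' @param geometry A [voxel_geometry()].
#' @param provenance Free-text metadata carried along unchanged.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(slices, geometry = voxel_geometry(), provenance = "") {
  if (length(slices) < 1) stop("an image stack needs at least one slice")
  d <- dim(slices[[1]])
  for (s in slices) {
    if (!is.matrix(s) || !identical(dim(s), d)) {
      stop("all slices must be matrices of identical dimension")
    }
    if (!all(is.finite(s))) stop("slice intensities must be finite")
  }
  stopifnot(inherits(geometry, "voxel_geometry"))
  structure(list(slices = slices, geometry = geometry, provenance = provenance),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("image stack: %d slices of %d x %d px\n", length(x$slices), d[1], d[2]))
  print(x$geometry)
  invisible(x)
}

#' @export
dim.image_stack <- function(x) c(dim(x$slices[[1]]), length(x$slices))

#' Convert an image stack to a 3D array (row, col, slice)
#' @param stack An [image_stack()].
#' @return Numeric array of dimension `nrow x ncol x nslice`.
#' @export
stack_array <- function(stack) slices_to_array(stack$slices)

# numeric-aware ordering of file names: sorts by the last number embedded in
# the base name, so s2.tif < s10.tif regardless of lexicographic order
order_numbered <- function(files) {
  base <- tools::file_path_sans_ext(basename(files))
  num <- suppressWarnings(as.numeric(gsub(".*?(\\d+)\\D*$", "\\1", base)))
  ord <- order(is.na(num), num, base)
  files[ord]
}

#' Read an image stack from TIFF
#'
#' Accepts either a multi-page TIFF file or a directory of numbered
#' single-page TIFFs (sorted numerically by the number embedded in each file
#' name, so `s2.tif` precedes `s10.tif`). Intensities are returned as stored
#' by [tiff::readTIFF()] (unit-scaled); processing downstream works on real
#' values and re-normalizes to background units, so the raw scale is
#' immaterial.
#'
#' @param path A TIFF file or a directory containing `.tif`/`.tiff` files.
#' @param geometry A [voxel_geometry()] attached unchanged.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, geometry = voxel_geometry()) {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0) stop("no TIFF images found in ", path)
    files <- order_numbered(files)
    slices <- lapply(files, function(f) {
      im <- tiff::readTIFF(f, all = FALSE)
      if (length(dim(im)) == 3) im <- im[, , 1]
      im
    })
    prov <- paste0("directory:", path)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) == 0) stop("no readable pages in ", path)
    slices <- lapply(pages, function(im) if (length(dim(im)) == 3) im[, , 1] else im)
    prov <- paste0("file:", path)
  }
  d <- dim(slices[[1]])
  if (!all(vapply(slices, function(s) identical(dim(s), d), logical(1)))) {
    stop("inconsistent slice shapes in ", path)
  }
  image_stack(slices, geometry, provenance = prov)
}

#' Write an image stack to a multi-page TIFF
#'
#' Samples are stored with 32 bits, i.e. on a uniform grid over [0, 1], so
#' intensities are divided by a scale that brings the maximum into range.
#' Integer rasters are placed exactly on the sample grid (scale
#' `2^32 - 1`), so they survive a round trip without any quantization (up
#' to the returned scale); continuous data round-trip to about 2e-10. The
#' absolute scale is immaterial downstream: processing renormalizes to
#' background units.
#'
#' @param stack An [image_stack()].
#' @param path Output file name.
#' @return The scale divisor applied (1 for continuous data already in
#'   `[0, 1]`), invisibly.
#' @export
write_stack <- function(stack, path) {
  mx <- max(vapply(stack$slices, max, numeric(1)), 0)
  mn <- min(vapply(stack$slices, min, numeric(1)), 0)
  if (mn < 0) stop("TIFF export requires non-negative intensities")
  grid <- 2^32 - 1
  integral <- all(vapply(stack$slices, function(x) all(x == round(x)), logical(1)))
  s <- if (integral && mx <= grid) grid else if (mx > 1) 2^ceiling(log2(mx)) else 1
  slices <- if (s == 1) stack$slices else lapply(stack$slices, function(x) x / s)
  tiff::writeTIFF(slices, path, bits.per.sample = 32L)
  invisible(s)
}

#' Read acquisition geometry from a YAML or JSON config file
#'
#' Recognized keys: `pixel_size_x_nm`, `pixel_size_y_nm`,
#' `slice_thickness_nm`, `view_angle_deg`. Missing keys fall back to the
#' [voxel_geometry()] defaults.
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A [voxel_geometry()].
#' @export
read_geometry <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  def <- voxel_geometry()
  voxel_geometry(
    pixel_size_x = cfg$pixel_size_x_nm %||% def$pixel_size_x,
    pixel_size_y = cfg$pixel_size_y_nm %||% def$pixel_size_y,
    slice_thickness = cfg$slice_thickness_nm %||% def$slice_thickness,
    view_angle = cfg$view_angle_deg %||% def$view_angle
  )
}

# ---------------------------------------------------------------------------
# Surface meshes.
#
# Label volumes are meshed by extracting exposed voxel faces and merging
# coplanar runs into maximal rectangles (greedy), which keeps flat regions to
# a handful of triangles: a solid axis-aligned box reduces to 12. Triangles
# are consistently wound with outward normals, so the signed volume of the
# mesh equals the voxel volume of the label exactly.

# map rectangle corners in the two transverse axes to 3D, winding so that the
# cross product points along +axis (cyclic: x->(y,z), y->(z,x), z->(x,y))
mesh_rects_for_axis <- function(mask, axis) {
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  quads <- list()
  # voxel occupies [i-1, i] along each axis (in voxel units)
  shift <- c(0L, 0L, 0L)
  shift[axis] <- 1L
  core <- list(2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1))
  here <- pad[core[[1]], core[[2]], core[[3]], drop = FALSE]
  nb_pos <- pad[core[[1]] + shift[1], core[[2]] + shift[2], core[[3]] + shift[3], drop = FALSE]
  nb_neg <- pad[core[[1]] - shift[1], core[[2]] - shift[2], core[[3]] - shift[3], drop = FALSE]
  for (sign in c(1L, -1L)) {
    faces <- here & !(if (sign > 0) nb_pos else nb_neg)
    if (!any(faces)) next
    # collapse the face axis: one logical matrix per plane position
    perm <- c(axis, setdiff(1:3, axis))
    fp <- aperm(faces, perm)
    for (i in seq_len(dim(fp)[1])) {
      m <- fp[i, , , drop = TRUE]
      dim(m) <- dim(fp)[2:3]
      if (!any(m)) next
      plane <- if (sign > 0) i else i - 1L  # face coordinate along `axis`
      rects <- greedy_rectangles(m)
      for (r in seq_len(nrow(rects))) {
        quads[[length(quads) + 1L]] <- c(axis, sign, plane, rects[r, ])
      }
    }
  }
  quads
}

# greedy decomposition of a logical matrix into maximal rectangles;
# returns matrix with columns u0, u1, v0, v1 (half-open, in cell units)
greedy_rectangles <- function(m) {
  rem <- m  # true and not yet covered
  nr <- nrow(m)
  nc <- ncol(m)
  out <- vector("list", 0)
  for (ii in which(m)) {
    if (!rem[ii]) next
    u <- ((ii - 1L) %% nr) + 1L
    v <- ((ii - 1L) %/% nr) + 1L
    u1 <- u
    while (u1 < nr && rem[u1 + 1L, v]) u1 <- u1 + 1L
    v1 <- v
    while (v1 < nc && all(rem[u:u1, v1 + 1L])) v1 <- v1 + 1L
    rem[u:u1, v:v1] <- FALSE
    out[[length(out) + 1L]] <- c(u - 1L, u1, v - 1L, v1)
  }
  matrix(unlist(out), ncol = 4, byrow = TRUE)
}

# build triangle soup (n x 9 matrix: v1 v2 v3 as xyz) in nm
mesh_triangles <- function(mask, geometry) {
  scale <- c(geometry$pixel_size_y, geometry$pixel_size_x, geometry$slice_thickness)
  tris <- list()
  # axes of the volume are (row=y, col=x, slice=z); meshing runs in index
  # space, vertices are scaled to nm at the end with x=col, y=row, z=slice
  cyc <- list(`1` = c(2, 3), `2` = c(3, 1), `3` = c(1, 2))
  for (axis in 1:3) {
    quads <- mesh_rects_for_axis(mask, axis)
    tra <- cyc[[axis]]
    for (q in quads) {
      sign <- q[2]; plane <- q[3]
      u0 <- q[4]; u1 <- q[5]; v0 <- q[6]; v1 <- q[7]
      p <- function(u, v) {
        xyz <- numeric(3)
        xyz[axis] <- plane
        xyz[tra[1]] <- u
        xyz[tra[2]] <- v
        xyz * scale
      }
      a <- p(u0, v0); b <- p(u1, v0); cc <- p(u1, v1); dd <- p(u0, v1)
      if (sign > 0) {
        tris[[length(tris) + 1L]] <- c(a, b, cc)
        tris[[length(tris) + 1L]] <- c(a, cc, dd)
      } else {
        tris[[length(tris) + 1L]] <- c(a, cc, b)
        tris[[length(tris) + 1L]] <- c(a, dd, cc)
      }
    }
  }
  do.call(rbind, tris)
}

# signed volume of a closed triangle soup via the divergence theorem
mesh_volume <- function(tris) {
  a <- tris[, 1:3, drop = FALSE]
  b <- tris[, 4:6, drop = FALSE]
  cc <- tris[, 7:9, drop = FALSE]
  det3 <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
    a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
    a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  sum(det3) / 6
}

write_stl <- function(tris, path, name = "label") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  for (i in seq_len(nrow(tris))) {
    a <- tris[i, 1:3]; b <- tris[i, 4:6]; cc <- tris[i, 7:9]
    n <- c((b[2] - a[2]) * (cc[3] - a[3]) - (b[3] - a[3]) * (cc[2] - a[2]),
           (b[3] - a[3]) * (cc[1] - a[1]) - (b[1] - a[1]) * (cc[3] - a[3]),
           (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1]))
    nn <- sqrt(sum(n^2))
    if (nn > 0) n <- n / nn
    writeLines(c(sprintf("  facet normal %g %g %g", n[1], n[2], n[3]),
                 "    outer loop",
                 sprintf("      vertex %g %g %g", a[1], a[2], a[3]),
                 sprintf("      vertex %g %g %g", b[1], b[2], b[3]),
                 sprintf("      vertex %g %g %g", cc[1], cc[2], cc[3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", name), con)
}

write_ply <- function(tris, path) {
  nf <- nrow(tris)
  verts <- rbind(tris[, 1:3], tris[, 4:6], tris[, 7:9])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", 3L * nf),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nf),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%g %g %g", verts[, 1], verts[, 2], verts[, 3]), con)
  idx <- seq_len(nf) - 1L
  writeLines(sprintf("3 %d %d %d", idx, idx + nf, idx + 2L * nf), con)
}

#' Export label surfaces as triangulated meshes
#'
#' Extracts a closed triangulated isosurface for each label of a 3D label
#' volume (voxel-face extraction with greedy rectangle merging) and writes it
#' as ASCII STL or PLY, with vertex coordinates in nanometres via the voxel
#' geometry. The signed volume enclosed by each mesh equals the labelled
#' voxel volume exactly.
#'
#' @param labels 3D integer array (row, col, slice); 0 is background.
#' @param geometry A [voxel_geometry()].
#' @param path Output file name; one file per label is written, with the
#'   label id appended before the extension when several labels are present.
#' @param format `"stl"` or `"ply"`; default inferred from the extension.
#' @return Data frame with one row per label: id, triangle count, enclosed
#'   volume (nm^3), and file written.
#' @export
export_surface_mesh <- function(labels, geometry, path, format = NULL) {
  ids <- sort(unique(as.integer(labels[labels > 0])))
  if (length(ids) == 0) stop("label volume is empty: nothing to mesh")
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("stl", "ply")) ext else "stl"
  }
  out <- data.frame(label = ids, triangles = 0L, volume_nm3 = 0, file = "",
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    f <- if (length(ids) == 1) path else {
      sub(sprintf("\\.%s$", format), sprintf("_label%d.%s", ids[i], format),
          path, ignore.case = TRUE)
    }
    tris <- mesh_triangles(labels == ids[i], geometry)
    if (format == "stl") write_stl(tris, f, name = sprintf("label%d", ids[i]))
    else write_ply(tris, f)
    out$triangles[i] <- nrow(tris)
    out$volume_nm3[i] <- mesh_volume(tris)
    out$file[i] <- f
  }
  out
}
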