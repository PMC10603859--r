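# Readers/writers: NIfTI volumes and the project contour text format.

#' Write a volume to NIfTI
#'
#' Voxel spacing is stored in the pixdim fields and the origin in the sform
#' (code 2); the round trip preserves voxels bit-exactly and spacing/origin
#' to well below 1e-6 mm.
#'
#' @param vol a `volume3d`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!grepl("\\.nii(\\.gz)?$", path))
    stop("volume files must end in .nii or .nii.gz")
  a <- vol$voxels
  attr(a, "pixdim") <- vol$spacing
  img <- RNifti::asNifti(a)
  m <- diag(c(vol$spacing, 1))
  m[1:3, 4] <- vol$origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path a `.nii` / `.nii.gz` file written by [write_volume()] (or any
#'   NIfTI volume with sane pixdim/sform).
#' @return a `volume3d`.
#' @export
read_volume <- function(path) {
  if (!grepl("\\.nii(\\.gz)?$", path))
    stop("volume files must end in .nii or .nii.gz")
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  x <- RNifti::xform(img, useQuaternionFirst = FALSE)
  origin <- x[1:3, 4]
  vox <- as.array(img)
  vox <- array(as.numeric(vox), dim = dim(vox)) # drop NIfTI attributes
  if (!all(is.finite(vox))) stop("volume contains non-finite intensities")
  if (any(sp <= 0)) stop("voxel spacing must be strictly positive")
  structure(list(voxels = vox, spacing = as.numeric(sp[1:3]),
                 origin = as.numeric(origin)),
            class = "volume3d")
}

#' Write a contour stack to the project text format
#'
#' One file per volume: a header block with the bifurcation position and
#' ISD, then per-slice polygon blocks with (z, vessel, boundary kind) and
#' `x y` vertex rows in mm.
#'
#' @param stack a [contour_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_contours <- function(stack, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# caroseg contour stack v1",
               sprintf("bifurcation_z %.8f", stack$bifurcation_z),
               sprintf("isd %.8f", stack$isd)), con)
  for (s in stack$slices) {
    for (kind in c("mab", "lib")) {
      cont <- s[[kind]]
      if (is.null(cont)) next
      writeLines(sprintf("contour z %.8f vessel %s kind %s n %d",
                         s$z, cont$vessel, cont$kind, nrow(cont$points)), con)
      writeLines(sprintf("%.8f %.8f", cont$points[, 1L], cont$points[, 2L]),
                 con)
    }
  }
  invisible(path)
}

#' Read a contour stack from the project text format
#'
#' Validates polygons (simplicity, orientation, vertex count) and the
#' LIB-inside-MAB invariant on every slice.
#'
#' @param path file written by [write_contours()].
#' @return a [contour_stack()].
#' @export
read_contours <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  hdr <- strsplit(lines[1:2], " +")
  if (hdr[[1L]][1L] != "bifurcation_z" || hdr[[2L]][1L] != "isd")
    stop("malformed contour file header")
  bifurcation_z <- as.numeric(hdr[[1L]][2L])
  isd <- as.numeric(hdr[[2L]][2L])
  i <- 3L
  slices <- list()
  while (i <= length(lines)) {
    f <- strsplit(lines[i], " +")[[1L]]
    if (f[1L] != "contour") stop("malformed contour block at line ", i)
    z <- as.numeric(f[3L]); vessel <- f[5L]; kind <- f[7L]
    n <- as.integer(f[9L])
    pts <- do.call(rbind, lapply(lines[(i + 1L):(i + n)], function(l)
      as.numeric(strsplit(l, " +")[[1L]])))
    cont <- contour(pts, z = z, kind = kind, vessel = vessel,
                    validate = TRUE)
    key <- sprintf("%.6f", z)
    if (is.null(slices[[key]])) slices[[key]] <- list(z = z)
    slices[[key]][[tolower(kind)]] <- cont
    i <- i + n + 1L
  }
  contour_stack(unname(slices), bifurcation_z, isd, check = TRUE)
}
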