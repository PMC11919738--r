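#' Read a density map in MRC/CCP4 format
#'
#' Minimal reader for modes 0 (int8), 1 (int16) and 2 (float32). The voxel
#' size is derived from the header cell dimensions divided by the sampling
#' grid; axis order is normalized to (x, y, z) using the header axis-map
#' fields. Little-endian files as written by the mainstream EM packages.
#'
#' @param path MRC file path.
#' @return List with `data` (3D numeric array, x fastest), `voxel_A`
#'   (length-3, Å) and `origin_A`.
#' @export
read_density_map <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("no such file: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_num <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]
  mode <- hdr_int[4]
  if (any(c(nx, ny, nz) <= 0) || any(c(nx, ny, nz) > 1e5)) {
    abort(sprintf("malformed MRC header: grid size (%d, %d, %d)",
                  nx, ny, nz),
          class = "vippgeom_format_error")
  }
  if (!mode %in% c(0L, 1L, 2L)) {
    abort(sprintf("malformed MRC header: unsupported mode %d", mode),
          class = "vippgeom_format_error")
  }
  mx <- hdr_int[8]; my <- hdr_int[9]; mz <- hdr_int[10]
  if (any(c(mx, my, mz) <= 0)) {
    abort("malformed MRC header: sampling (mx, my, mz) must be positive",
          class = "vippgeom_format_error")
  }
  cella <- hdr_num[11:13]
  voxel <- cella / c(mx, my, mz)
  if (any(!is.finite(voxel)) || any(voxel <= 0)) {
    abort("malformed MRC header: cell dimensions (cella) must be positive",
          class = "vippgeom_format_error")
  }
  mapc <- hdr_int[17]; mapr <- hdr_int[18]; maps <- hdr_int[19]
  axis_map <- c(mapc, mapr, maps)
  if (!setequal(axis_map, 1:3)) axis_map <- 1:3
  origin <- hdr_num[50:52]
  nsymbt <- hdr_int[24]
  seek(con, 1024 + max(0, nsymbt))
  n_vox <- nx * ny * nz
  data <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n_vox, size = 1, signed = TRUE,
                  endian = "little"),
    "1" = readBin(con, "integer", n = n_vox, size = 2, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "numeric", n = n_vox, size = 4, endian = "little")
  )
  if (length(data) < n_vox) {
    abort(sprintf(
      "truncated MRC file: expected %d voxels, read %d", n_vox,
      length(data)),
      class = "vippgeom_format_error")
  }
  vol <- array(as.numeric(data), dim = c(nx, ny, nz))
  if (!identical(as.integer(axis_map), 1:3)) {
    # file axes (fast, medium, slow) carry crystallographic axes axis_map;
    # permute so that array axis i is crystallographic axis i. The voxel
    # size is already per crystallographic axis (cella / m).
    vol <- aperm(vol, order(axis_map))
  }
  list(data = vol, voxel_A = voxel, origin_A = origin)
}

#' Write a density map in MRC format (mode 2, float32)
#'
#' @param map3d List with `data` (3D array) and `voxel_A` (scalar or
#'   length-3 Å voxel size), as produced by [synthetic_lattice_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_density_map <- function(map3d, path) {
  stopifnot(is.list(map3d), !is.null(map3d$data), !is.null(map3d$voxel_A))
  vol <- map3d$data
  stopifnot(length(dim(vol)) == 3)
  voxel <- rep(map3d$voxel_A, length.out = 3)
  d <- dim(vol)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4,
                             endian = "little")
  wi(d)                  # nx ny nz
  wi(2L)                 # mode 2: float32
  wi(c(0L, 0L, 0L))      # nxstart
  wi(d)                  # mx my mz
  wf(d * voxel)          # cella
  wf(c(90, 90, 90))      # cellb
  wi(1:3)                # mapc mapr maps
  wf(c(min(vol), max(vol), mean(vol)))
  wi(1L)                 # ispg
  wi(0L)                 # nsymbt
  wi(rep(0L, 25))        # extra
  wf(c(0, 0, 0))         # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con) # little-endian stamp
  wf(sd(as.numeric(vol)))
  wi(0L)                 # nlabl
  writeBin(raw(800), con) # labels
  wf(as.numeric(vol))
  invisible(path)
}
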