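# Density-volume I/O. NIfTI (.nii / .nii.gz) goes through RNifti; MetaImage
# (.mha, single-file, uncompressed, local data) is read and written directly
# since no installed package handles the format. Density is stored as a
# single-channel float field in mg HA/cm^3 with mandatory spacing metadata.

vol_ext <- function(path) {
  p <- tolower(path)
  if (endsWith(p, ".nii.gz") || endsWith(p, ".nii")) ".nii"
  else if (endsWith(p, ".mha")) ".mha"
  else ""
}

#' Read a density volume into a simulation lattice
#'
#' @param path Path to a `.nii`, `.nii.gz` or `.mha` volume.
#' @param voxel_size Expected voxel size in micrometres. If the file's spacing
#'   differs, a warning is issued and the file's spacing wins.
#' @return A [sim_lattice()].
#' @export
read_volume <- function(path, voxel_size = 10.5) {
  ext <- vol_ext(path)
  if (ext == ".nii") {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    sp <- RNifti::pixdim(img) * 1000 # NIfTI spacing is mm
  } else if (ext == ".mha") {
    m <- read_mha(path)
    arr <- m$data
    sp <- m$spacing * 1000 # stored in mm
  } else {
    stop("unsupported volume format: ", path)
  }
  if (length(dim(arr)) != 3) stop("expected a 3D volume, got ", length(dim(arr)), "D")
  if (length(sp) < 3 || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0)) {
    stop("volume is missing spacing metadata")
  }
  if (max(abs(sp[1:3] - voxel_size)) > 1e-6 * voxel_size) {
    warning(sprintf(
      "file spacing (%.4g um) differs from configured voxel size (%.4g um); using file spacing",
      sp[1], voxel_size
    ))
    voxel_size <- sp[1]
  }
  sim_lattice(dim(arr), voxel_size = voxel_size, mineral = arr)
}

#' Write a lattice's density field to a volume file
#'
#' @param lattice A [sim_lattice()].
#' @param path Output path (`.nii`, `.nii.gz` or `.mha`).
#' @param field Which field to export (`"mineral"`, `"osteoid"`, or any
#'   numeric lattice field).
#' @return `path`, invisibly.
#' @export
write_volume <- function(lattice, path, field = "mineral") {
  stopifnot(inherits(lattice, "sim_lattice"))
  arr <- lattice[[field]]
  if (is.null(arr)) stop("no such lattice field: ", field)
  arr <- array(as.numeric(arr), lattice$dims)
  sp_mm <- lattice$voxel_size / 1000
  ext <- vol_ext(path)
  if (ext == ".nii") {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(sp_mm, sp_mm, sp_mm)
    RNifti::writeNifti(img, path)
  } else if (ext == ".mha") {
    write_mha(arr, path, spacing = rep(sp_mm, 3))
  } else {
    stop("unsupported volume format: ", path)
  }
  invisible(path)
}

# minimal MetaImage writer: ASCII header + little-endian float64 raw block
write_mha <- function(arr, path, spacing) {
  dims <- dim(arr)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    "ObjectType = Image\n",
    "NDims = 3\n",
    "BinaryData = True\n",
    "BinaryDataByteOrderMSB = False\n",
    "DimSize = ", paste(dims, collapse = " "), "\n",
    "ElementSpacing = ", paste(format(spacing, digits = 10), collapse = " "), "\n",
    "ElementType = MET_DOUBLE\n",
    "ElementDataFile = LOCAL\n"
  )
  writeChar(hdr, con, eos = NULL)
  writeBin(as.numeric(arr), con, size = 8, endian = "little")
  invisible(path)
}

read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    line <- ""
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0) stop("unexpected end of MetaImage header")
      if (ch == "\n") break
      line <- paste0(line, ch)
    }
    hdr <- c(hdr, line)
    if (grepl("^ElementDataFile", line)) break
  }
  kv <- strsplit(hdr, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  get <- function(k) vals[match(k, keys)]
  if (!identical(get("NDims"), "3")) stop("expected a 3D MetaImage volume")
  dims <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing"), "\\s+")[[1]])
  if (any(is.na(spacing))) stop("MetaImage volume missing ElementSpacing")
  type <- get("ElementType")
  n <- prod(dims)
  data <- switch(type,
    MET_DOUBLE = readBin(con, "numeric", n, size = 8, endian = "little"),
    MET_FLOAT = readBin(con, "numeric", n, size = 4, endian = "little"),
    stop("unsupported MetaImage element type: ", type)
  )
  if (length(data) != n) stop("truncated MetaImage data block")
  list(data = array(data, dims), spacing = spacing)
}
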