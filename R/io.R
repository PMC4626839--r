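#' Read / write masks and scalar volumes (NIfTI, MetaImage)
#'
#' Masks and CT-like volumes round-trip through NIfTI (`.nii`, `.nii.gz`)
#' or MetaImage (`.mha`, `.mhd` + `.raw`), preserving shape, spacing, origin
#' and values exactly. NIfTI goes through RNifti; MetaImage is read and
#' written directly (uncompressed, little-endian; masks as `MET_UCHAR`,
#' scalar volumes as `MET_DOUBLE`).
#'
#' @param x a [voxel_mask()] or [ct_volume()].
#' @param path file path with a recognized extension.
#' @return `read_mask()` a `voxel_mask`; `read_volume()` a `ct_volume`;
#'   the writers return `path` invisibly.
#' @export
write_mask <- function(x, path) {
  stopifnot(inherits(x, "voxel_mask"))
  write_any(array(as.double(x$occupancy), dim = dim(x$occupancy)),
            x$spacing, x$origin, path, raw_type = "uchar")
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  v <- read_any(path)
  voxel_mask(v$data > 0.5, v$spacing, v$origin)
}

#' @rdname write_mask
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "ct_volume"))
  write_any(x$intensity, x$spacing, x$origin, path, raw_type = "double")
}

#' @rdname write_mask
#' @export
read_volume <- function(path) {
  v <- read_any(path)
  ct_volume(v$data, v$spacing, v$origin)
}

file_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
  else if (grepl("\\.mha$", path)) "mha"
  else if (grepl("\\.mhd$", path)) "mhd"
  else stop("unrecognized volume format: ", path,
            " (supported: .nii, .nii.gz, .mha, .mhd)")
}

write_any <- function(data, spacing, origin, path, raw_type) {
  switch(file_format(path),
         nifti = write_nifti_vol(data, spacing, origin, path),
         mha = write_meta(data, spacing, origin, path, local = TRUE,
                          raw_type = raw_type),
         mhd = write_meta(data, spacing, origin, path, local = FALSE,
                          raw_type = raw_type))
  invisible(path)
}

read_any <- function(path) {
  switch(file_format(path),
         nifti = read_nifti_vol(path),
         read_meta(path))
}

write_nifti_vol <- function(data, spacing, origin, path) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- spacing
  m <- diag(4)
  diag(m)[1:3] <- spacing
  m[1:3, 4] <- origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
}

read_nifti_vol <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  if (is.na(sp[1]) || any(sp <= 0)) stop("volume ", path, " has no spacing")
  list(data = array(as.numeric(img), dim = dim(img)[1:3]),
       spacing = as.numeric(sp), origin = as.numeric(xf[1:3, 4]))
}

meta_types <- list(uchar = list(name = "MET_UCHAR", size = 1L, what = "integer"),
                   short = list(name = "MET_SHORT", size = 2L, what = "integer"),
                   float = list(name = "MET_FLOAT", size = 4L, what = "numeric"),
                   double = list(name = "MET_DOUBLE", size = 8L, what = "numeric"))

write_meta <- function(data, spacing, origin, path, local, raw_type) {
  tp <- meta_types[[raw_type]]
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(dim(data), collapse = " ")),
           paste("ElementSpacing =", paste(format(spacing, digits = 17), collapse = " ")),
           paste("Offset =", paste(format(origin, digits = 17), collapse = " ")),
           paste("ElementType =", tp$name))
  if (local) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c(hdr, "ElementDataFile = LOCAL"), con)
    write_raw(con, data, raw_type, tp)
  } else {
    raw_name <- sub("\\.mhd$", ".raw", basename(path))
    writeLines(c(hdr, paste("ElementDataFile =", raw_name)), path)
    con <- file(file.path(dirname(path), raw_name), "wb")
    on.exit(close(con))
    write_raw(con, data, raw_type, tp)
  }
}

write_raw <- function(con, data, raw_type, tp) {
  v <- as.vector(data)
  if (tp$what == "integer") v <- as.integer(round(v))
  writeBin(v, con, size = tp$size, endian = "little")
}

read_meta <- function(path) {
  # header is ASCII key = value lines; for .mha the raw block follows LOCAL
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- read_ascii_line(con)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed MetaImage header line: ", line)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  if (is.null(hdr$ElementSpacing)) stop("MetaImage ", path, " has no ElementSpacing")
  spacing <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  tp_name <- hdr$ElementType
  tp <- NULL
  for (t in meta_types) if (t$name == tp_name) tp <- t
  if (is.null(tp)) stop("unsupported MetaImage ElementType: ", tp_name)
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    v <- readBin(con, what = tp$what, n = n, size = tp$size, endian = "little")
  } else {
    rcon <- file(file.path(dirname(path), hdr$ElementDataFile), "rb")
    on.exit(close(rcon), add = TRUE)
    v <- readBin(rcon, what = tp$what, n = n, size = tp$size, endian = "little")
  }
  if (length(v) != n) stop("truncated MetaImage data in ", path)
  list(data = array(as.numeric(v), dim = dims), spacing = spacing,
       origin = origin)
}

read_ascii_line <- function(con) {
  out <- raw(0)
  repeat {
    ch <- readBin(con, "raw", n = 1)
    if (length(ch) == 0 || ch == as.raw(10L)) break
    out <- c(out, ch)
  }
  rawToChar(out)
}

#' Write the NIfTI outputs of a segmentation
#'
#' Writes the label volume and the cavity mask of a [extract_cavity()]
#' result next to each other.
#'
#' @param seg a `segmentation_result`.
#' @param labels_path,cavity_path output paths (NIfTI or MetaImage).
#' @return invisibly, the two paths.
#' @export
write_segmentation <- function(seg, labels_path, cavity_path) {
  stopifnot(inherits(seg, "segmentation_result"))
  sp <- seg$cavity$spacing; og <- seg$cavity$origin
  write_any(array(as.double(seg$labels), dim = dim(seg$labels)), sp, og,
            labels_path, raw_type = "uchar")
  write_mask(seg$cavity, cavity_path)
  invisible(c(labels_path, cavity_path))
}
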