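# Minimal DICOM series reader.
#
# Supports uncompressed single-frame files in implicit or explicit VR little
# endian, which covers the axial MR series this package targets. Only the
# tags needed to assemble a 3D volume are interpreted; everything else is
# skipped structurally. No installed R package reads DICOM, hence this
# hand-written reader.

dcm_tag <- function(group, elem) sprintf("%04X,%04X", group, elem)

read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140) stop("not a DICOM file: ", path)
  explicit <- TRUE
  pos <- 1L
  if (rawToChar(raw[129:132]) == "DICM") pos <- 133L else
    stop("not a DICOM file (missing DICM marker): ", path)
  tags <- list()
  ts <- NULL
  n <- length(raw)
  while (pos + 7L <= n) {
    group <- readBin(raw[pos:(pos + 1)], "integer", size = 2, endian = "little", signed = FALSE)
    elem  <- readBin(raw[(pos + 2):(pos + 3)], "integer", size = 2, endian = "little", signed = FALSE)
    pos <- pos + 4L
    exp_here <- explicit || group == 2L   # file meta group is always explicit
    if (exp_here) {
      vr <- rawToChar(raw[pos:(pos + 1)])
      if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
        len <- readBin(raw[(pos + 4):(pos + 7)], "integer", size = 4, endian = "little")
        pos <- pos + 8L
      } else {
        len <- readBin(raw[(pos + 2):(pos + 3)], "integer", size = 2, endian = "little", signed = FALSE)
        pos <- pos + 4L
      }
    } else {
      vr <- NA_character_
      len <- readBin(raw[pos:(pos + 3)], "integer", size = 4, endian = "little")
      pos <- pos + 4L
    }
    if (len < 0) stop("undefined-length DICOM element not supported (", dcm_tag(group, elem), ") in ", path)
    if (pos + len - 1L > n) stop("truncated DICOM element in ", path)
    val <- raw[seq.int(pos, length.out = len)]
    pos <- pos + len
    key <- dcm_tag(group, elem)
    tags[[key]] <- list(vr = vr, bytes = val)
    if (key == "0002,0010") {
      ts <- sub("\\s+$", "", rawToChar(val[val != as.raw(0)]))
      if (ts == "1.2.840.10008.1.2") explicit <- FALSE
      else if (ts != "1.2.840.10008.1.2.1")
        stop("unsupported DICOM transfer syntax ", ts, " (only uncompressed little endian)")
    }
    if (key == "7FE0,0010") break
  }
  tags
}

dcm_str <- function(tags, key) {
  el <- tags[[key]]
  if (is.null(el)) return(NULL)
  sub("\\s+$", "", rawToChar(el$bytes[el$bytes != as.raw(0)]))
}

dcm_num <- function(tags, key) {
  s <- dcm_str(tags, key)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_us <- function(tags, key) {
  el <- tags[[key]]
  if (is.null(el)) return(NULL)
  readBin(el$bytes, "integer", size = 2, endian = "little", signed = FALSE)
}

read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) stop("no DICOM files found in ", dir)
  slices <- lapply(files, read_dicom_file)

  rows <- vapply(slices, function(t) dcm_us(t, "0028,0010"), integer(1))
  cols <- vapply(slices, function(t) dcm_us(t, "0028,0011"), integer(1))
  if (length(unique(rows)) != 1L || length(unique(cols)) != 1L)
    stop("DICOM series rejected: slice matrix size varies within ", dir)

  thick <- lapply(slices, function(t) dcm_num(t, "0018,0050"))
  thick <- unlist(thick[!vapply(thick, is.null, logical(1))])
  if (length(thick) && diff(range(thick)) > 0.01)
    stop("DICOM series rejected: slice thickness varies (",
         paste(sort(unique(round(thick, 2))), collapse = "/"), " mm); ",
         "only constant-slice-thickness series are supported")

  ipp <- lapply(slices, function(t) dcm_num(t, "0020,0032"))
  if (all(!vapply(ipp, is.null, logical(1)))) {
    z <- vapply(ipp, function(p) p[3], numeric(1))
    ord <- order(z)
  } else {
    inst <- vapply(slices, function(t) {
      v <- dcm_num(t, "0020,0013"); if (is.null(v)) NA_real_ else v[1]
    }, numeric(1))
    ord <- order(inst)
    z <- NULL
  }
  slices <- slices[ord]
  if (!is.null(z)) {
    z <- sort(z)
    if (length(z) > 1) {
      gaps <- diff(z)
      if (diff(range(gaps)) > 0.01)
        stop("DICOM series rejected: slice spacing varies (",
             paste(sort(unique(round(gaps, 2))), collapse = "/"), " mm)")
      dz <- mean(gaps)
    } else dz <- if (length(thick)) thick[1] else 1
  } else dz <- if (length(thick)) thick[1] else 1

  ps <- dcm_num(slices[[1]], "0028,0030")   # (row spacing, column spacing)
  if (is.null(ps)) ps <- c(1, 1)
  bits <- dcm_us(slices[[1]], "0028,0100")
  if (is.null(bits)) bits <- 16L
  signed <- identical(dcm_us(slices[[1]], "0028,0103"), 1L)
  slope <- dcm_num(slices[[1]], "0028,1053"); if (is.null(slope)) slope <- 1
  inter <- dcm_num(slices[[1]], "0028,1052"); if (is.null(inter)) inter <- 0

  nx <- cols[1]; ny <- rows[1]; nz <- length(slices)
  arr <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    px <- slices[[k]][["7FE0,0010"]]
    if (is.null(px)) stop("DICOM file without pixel data in ", dir)
    v <- readBin(px$bytes, "integer", n = nx * ny, size = bits / 8,
                 endian = "little", signed = if (bits == 8) TRUE else signed)
    if (bits == 8 && !signed) v <- (v + 256L) %% 256L
    arr[, , k] <- matrix(v, nrow = nx)   # pixel rows are contiguous: x fastest
  }
  arr <- arr * slope + inter
  volume_image(arr, spacing_mm = c(ps[2], ps[1], dz))
}
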