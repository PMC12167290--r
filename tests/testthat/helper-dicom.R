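# minimal explicit-VR little-endian DICOM writer for test fixtures
# (files are generated at test time; nothing binary is stored in the repo)

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_elem_str <- function(group, elem, vr, value) {
  v <- charToRaw(value)
  # UI values are null-padded, other strings space-padded, to even length
  if (length(v) %% 2 == 1) v <- c(v, if (vr == "UI") as.raw(0) else charToRaw(" "))
  c(u16(group), u16(elem), charToRaw(vr), u16(length(v)), v)
}

dcm_elem_us <- function(group, elem, value) {
  c(u16(group), u16(elem), charToRaw("US"), u16(2L), u16(value))
}

dcm_elem_ow <- function(group, elem, raw_data) {
  c(u16(group), u16(elem), charToRaw("OW"), as.raw(c(0, 0)), u32(length(raw_data)), raw_data)
}

write_test_dicom_slice <- function(path, slice_mat, spacing_xy, thickness, z_mm, instance) {
  px <- writeBin(as.integer(round(slice_mat)), raw(), size = 2, endian = "little")
  body <- c(
    dcm_elem_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
    dcm_elem_str(0x0018, 0x0050, "DS", format(thickness)),
    dcm_elem_str(0x0020, 0x0013, "IS", format(instance)),
    dcm_elem_str(0x0020, 0x0032, "DS", sprintf("0\\0\\%g", z_mm)),
    dcm_elem_us(0x0028, 0x0010, ncol(slice_mat)),                # Rows (y)
    dcm_elem_us(0x0028, 0x0011, nrow(slice_mat)),                # Columns (x)
    dcm_elem_str(0x0028, 0x0030, "DS", sprintf("%g\\%g", spacing_xy[2], spacing_xy[1])),
    dcm_elem_us(0x0028, 0x0100, 16L),                            # BitsAllocated
    dcm_elem_us(0x0028, 0x0103, 0L),                             # PixelRepresentation
    dcm_elem_ow(0x7FE0, 0x0010, px)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), body), con)
  invisible(path)
}

# arr: integer array (X, Y, Z) with values in [0, 65535]
write_test_dicom_series <- function(dir, arr, spacing = c(0.6, 0.6, 4.5),
                                    thicknesses = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nz <- dim(arr)[3]
  if (is.null(thicknesses)) thicknesses <- rep(spacing[3], nz)
  for (k in seq_len(nz)) {
    write_test_dicom_slice(file.path(dir, sprintf("slice%03d.dcm", k)),
                           arr[, , k], spacing[1:2], thicknesses[k],
                           z_mm = (k - 1) * spacing[3], instance = k)
  }
  invisible(dir)
}
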