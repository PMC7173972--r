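#' Registered 3-D voxel stack
#'
#' Container for a registered confocal stack: a 3-D intensity array whose
#' first axis is the left-right (x) axis of the brain, with per-axis voxel
#' size in micrometres.
#'
#' @param intensities 3-D numeric array, non-negative.
#' @param voxel_size Length-3 positive numeric, micrometres per voxel
#'   along (x, y, z).
#'
#' @return An object of class `voxel_stack`.
#' @export
voxel_stack <- function(intensities, voxel_size = c(1, 1, 1)) {
  stopifnot(is.array(intensities), length(dim(intensities)) == 3L)
  if (any(intensities < 0))
    stop("intensities must be non-negative", call. = FALSE)
  stopifnot(is.numeric(voxel_size), length(voxel_size) == 3L,
            all(voxel_size > 0))
  structure(list(intensities = intensities,
                 voxel_size = as.numeric(voxel_size)),
            class = "voxel_stack")
}

#' @export
print.voxel_stack <- function(x, ...) {
  cat("voxel_stack:", paste(dim(x$intensities), collapse = " x "),
      "voxels,", paste(signif(x$voxel_size, 4), collapse = " x "),
      "um/voxel\n")
  invisible(x)
}

flip_x <- function(a) a[dim(a)[1]:1, , , drop = FALSE]

#' Bilaterally symmetric mirror average of registered stacks
#'
#' Averages one or more registered stacks together with their left-right
#' mirror images: every output voxel is the mean, over all stacks and
#' their x-flipped copies, of the intensity at that voxel. The result is
#' exactly symmetric under an x-flip and the operation is idempotent.
#'
#' @param stacks A [voxel_stack()] or list of them; all must share shape
#'   and voxel size.
#'
#' @return A [voxel_stack()], bilaterally symmetric along x.
#' @export
mirror_average <- function(stacks) {
  if (inherits(stacks, "voxel_stack")) stacks <- list(stacks)
  stopifnot(length(stacks) >= 1,
            all(vapply(stacks, inherits, logical(1), "voxel_stack")))
  d <- dim(stacks[[1]]$intensities)
  vs <- stacks[[1]]$voxel_size
  for (s in stacks) {
    if (!identical(dim(s$intensities), d))
      stop("stack shapes differ; register stacks before averaging",
           call. = FALSE)
    if (!isTRUE(all.equal(s$voxel_size, vs)))
      stop("stack voxel sizes differ", call. = FALSE)
  }
  acc <- array(0, dim = d)
  for (s in stacks)
    acc <- acc + (s$intensities + flip_x(s$intensities))
  voxel_stack(acc / (2 * length(stacks)), vs)
}

#' Threshold-based structure volume
#'
#' Counts voxels at or above an intensity threshold (within an optional
#' region mask) and converts the count to a volume using the voxel size.
#' The threshold is applied on the stack's native intensity scale; the
#' default 800 corresponds to the standard setting on 12/16-bit stacks.
#'
#' @param stack A [voxel_stack()].
#' @param threshold Intensity threshold (inclusive, `>=`).
#' @param mask Optional logical array of the stack's shape restricting
#'   the count to a segmented region.
#'
#' @return List with `voxels` (count) and `volume_um3`.
#' @export
threshold_volume <- function(stack, threshold = 800, mask = NULL) {
  stopifnot(inherits(stack, "voxel_stack"))
  sel <- stack$intensities >= threshold
  if (!is.null(mask)) {
    stopifnot(is.logical(mask),
              identical(dim(mask), dim(stack$intensities)))
    if (!any(mask))
      warning("empty mask: volume is zero by construction",
              call. = FALSE)
    sel <- sel & mask
  }
  voxels <- sum(sel)
  list(voxels = voxels, volume_um3 = voxels * prod(stack$voxel_size))
}

#' Volume report over labeled structures
#'
#' Applies [threshold_volume()] to each labeled region of a segmentation
#' mask (an integer label array; 0 = background).
#'
#' @param stack A [voxel_stack()].
#' @param labels Integer array of the stack's shape; positive labels name
#'   structures.
#' @param threshold Intensity threshold.
#' @param sample Sample identifier carried into the report.
#'
#' @return Data frame `sample,structure,threshold,voxels,volume_um3`.
#' @export
volume_report <- function(stack, labels, threshold = 800,
                          sample = "sample1") {
  stopifnot(identical(dim(labels), dim(stack$intensities)))
  structs <- sort(unique(labels[labels > 0]))
  out <- lapply(structs, function(lb) {
    v <- threshold_volume(stack, threshold, mask = labels == lb)
    data.frame(sample = sample, structure = lb, threshold = threshold,
               voxels = v$voxels, volume_um3 = v$volume_um3,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

nrrd_type_map <- list(
  "unsigned char" = list(what = "integer", size = 1L, signed = FALSE),
  "uchar" = list(what = "integer", size = 1L, signed = FALSE),
  "uint8" = list(what = "integer", size = 1L, signed = FALSE),
  "short" = list(what = "integer", size = 2L, signed = TRUE),
  "int16" = list(what = "integer", size = 2L, signed = TRUE),
  "unsigned short" = list(what = "integer", size = 2L, signed = FALSE),
  "ushort" = list(what = "integer", size = 2L, signed = FALSE),
  "uint16" = list(what = "integer", size = 2L, signed = FALSE),
  "int" = list(what = "integer", size = 4L, signed = TRUE),
  "int32" = list(what = "integer", size = 4L, signed = TRUE),
  "unsigned int" = list(what = "integer", size = 4L, signed = FALSE),
  "uint32" = list(what = "integer", size = 4L, signed = FALSE),
  "float" = list(what = "numeric", size = 4L, signed = TRUE),
  "double" = list(what = "numeric", size = 8L, signed = TRUE))

#' Read a 3-D NRRD stack
#'
#' Minimal reader for detached-free NRRD files (magic `NRRD0001`-`0005`):
#' 3-D data, `raw` (little-endian) or `ascii`/`text` encodings, voxel
#' size from `spacings` or a diagonal `space directions` field. The NRRD
#' convention (first axis fastest) matches R's column-major arrays, so
#' axis order is preserved as stored; a non-diagonal `space directions`
#' or a permuted axis layout is refused explicitly rather than silently
#' transposed.
#'
#' @param path NRRD file path.
#' @return A [voxel_stack()].
#' @export
read_nrrd <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  nl <- which(bytes == as.raw(10L))
  # header ends at the first blank line
  hdr_end <- NA_integer_
  prev <- 0L
  for (p in nl) {
    line_len <- p - prev - 1L
    if (line_len == 0L || (line_len == 1L && bytes[prev + 1L] ==
                           as.raw(13L))) { hdr_end <- p; break }
    prev <- p
  }
  if (is.na(hdr_end))
    stop("malformed NRRD: no end-of-header blank line", call. = FALSE)
  hdr_txt <- rawToChar(bytes[seq_len(hdr_end - 1L)])
  lines <- strsplit(gsub("\r", "", hdr_txt), "\n", fixed = TRUE)[[1]]
  if (!grepl("^NRRD000[1-5]$", lines[1]))
    stop("malformed NRRD: bad magic '", lines[1], "'", call. = FALSE)
  fields <- list()
  for (ln in lines[-1]) {
    if (grepl("^#", ln) || !nzchar(ln)) next
    kv <- regmatches(ln, regexec("^([^:]+):=?\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3L)
      stop("malformed NRRD header line: ", ln, call. = FALSE)
    fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  need <- c("dimension", "sizes", "type", "encoding")
  miss <- setdiff(need, names(fields))
  if (length(miss))
    stop("malformed NRRD: missing field(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (as.integer(fields$dimension) != 3L)
    stop("only 3-D NRRD stacks are supported (dimension = ",
         fields$dimension, ")", call. = FALSE)
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  stopifnot(length(sizes) == 3L, all(sizes >= 1L))
  voxel <- c(1, 1, 1)
  if (!is.null(fields$spacings)) {
    voxel <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)",
                                fields[["space directions"]]))[[1]]
    if (length(vecs) != 3L)
      stop("malformed NRRD: space directions must give 3 vectors",
           call. = FALSE)
    mat <- vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3))
    if (any(abs(mat[col(mat) != row(mat)]) > 1e-12))
      stop("non-axis-aligned space directions: refusing to reorder axes ",
           "silently", call. = FALSE)
    voxel <- abs(diag(mat))
  }
  if (!is.null(fields$space) && is.null(fields[["space directions"]])) {
    # a named space without directions leaves axis order ambiguous
    stop("NRRD declares a space but no space directions; axis order is ",
         "ambiguous", call. = FALSE)
  }
  enc <- tolower(fields$encoding)
  data_raw <- if (hdr_end < length(bytes))
    bytes[(hdr_end + 1L):length(bytes)] else raw(0)
  n_vox <- prod(sizes)
  if (enc %in% c("ascii", "text", "txt")) {
    vals <- scan(text = rawToChar(data_raw), quiet = TRUE)
  } else if (enc == "raw") {
    tp <- nrrd_type_map[[tolower(fields$type)]]
    if (is.null(tp))
      stop("unsupported NRRD type: ", fields$type, call. = FALSE)
    endian <- tolower(fields$endian %||% "little")
    if (tp$size > 1L && endian != "little")
      stop("only little-endian raw NRRD is supported", call. = FALSE)
    if (length(data_raw) < n_vox * tp$size)
      stop("malformed NRRD: data shorter than sizes imply", call. = FALSE)
    vals <- readBin(data_raw, tp$what, n = n_vox, size = tp$size,
                    signed = if (tp$size >= 4L) TRUE else tp$signed,
                    endian = "little")
  } else {
    stop("unsupported NRRD encoding: ", fields$encoding, call. = FALSE)
  }
  if (length(vals) < n_vox)
    stop("malformed NRRD: expected ", n_vox, " values, found ",
         length(vals), call. = FALSE)
  voxel_stack(array(as.numeric(vals[seq_len(n_vox)]), dim = sizes), voxel)
}

#' Write a 3-D NRRD stack
#'
#' Writes a [voxel_stack()] as NRRD0004 with `spacings` metadata.
#' Integer-valued stacks fitting 16 bits are stored as `unsigned short`,
#' anything else as `double`. `encoding = "ascii"` produces a purely
#' textual file; `"raw"` writes little-endian binary.
#'
#' @param stack A [voxel_stack()].
#' @param path Output path.
#' @param encoding `"raw"` or `"ascii"`.
#' @return The path, invisibly.
#' @export
write_nrrd <- function(stack, path, encoding = c("raw", "ascii")) {
  encoding <- match.arg(encoding)
  stopifnot(inherits(stack, "voxel_stack"))
  v <- stack$intensities
  integral <- all(v == round(v)) && max(v) <= 65535
  type <- if (integral) "unsigned short" else "double"
  hdr <- c("NRRD0004",
           "# generated by flydyad",
           paste0("type: ", type),
           "dimension: 3",
           paste0("sizes: ", paste(dim(v), collapse = " ")),
           paste0("spacings: ", paste(format(stack$voxel_size,
                                             digits = 17),
                                      collapse = " ")),
           paste0("encoding: ", encoding),
           if (encoding == "raw") "endian: little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, ""), con, sep = "\n")
  if (encoding == "ascii") {
    writeLines(paste(format(as.vector(v), digits = 17, trim = TRUE,
                            scientific = FALSE),
                     collapse = " "), con, sep = "\n")
  } else if (integral) {
    iv <- as.integer(v)
    # pack uint16 little-endian by hand; writeBin(size = 2) is signed-only
    writeBin(as.raw(rbind(iv %% 256L, iv %/% 256L)), con)
  } else {
    writeBin(as.numeric(v), con, size = 8L, endian = "little")
  }
  invisible(path)
}
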