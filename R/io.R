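# File input/output: TIFF micrographs and label masks, MRC mode-2
# micrographs, FASTA sequences, and per-vesicle CSV tables.

#' Read a micrograph from TIFF
#'
#' Grayscale TIFF (any bit depth readable by the tiff package);
#' intensities are returned on the stored 0..1 scale multiplied by
#' `scale` (default 65535, i.e. 16-bit counts).
#'
#' @param path TIFF file.
#' @param pixel_size_nm physical pixel size (TIFF carries none).
#' @param scale multiplier applied to the 0..1 values returned by
#'   [tiff::readTIFF()].
#' @param ... passed to [micrograph()] (`source_id`, `modality`).
#' @return a [micrograph()].
#' @export
read_micrograph_tiff <- function(path, pixel_size_nm, scale = 65535, ...) {
  img <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(img)) == 3) img <- img[, , 1]  # drop extra channels
  micrograph(img * scale, pixel_size_nm = pixel_size_nm, ...)
}

#' Write a micrograph (or plain matrix) as 16-bit grayscale TIFF
#'
#' Intensities are divided by `scale` and clipped to 0..1 before
#' writing.
#'
#' @param x a [micrograph()] or numeric matrix.
#' @param path output file.
#' @param scale full-scale intensity mapped to 65535 counts.
#' @export
write_micrograph_tiff <- function(x, path, scale = 65535) {
  img <- if (inherits(x, "micrograph")) x$pixels else x
  img <- pmin(pmax(img / scale, 0), 1)
  tiff::writeTIFF(img, path, bits.per.sample = 16)
  invisible(path)
}

#' Read / write an integer label mask as 16-bit TIFF
#'
#' Labels are stored as counts (label / 65535 in the file), so up to
#' 65535 objects per mask round-trip exactly.
#'
#' @param path TIFF file.
#' @return integer matrix of labels.
#' @export
read_label_mask_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix(as.integer(round(img * 65535)), nrow(img), ncol(img))
}

#' @rdname read_label_mask_tiff
#' @param labels integer label matrix (values 0..65535).
#' @export
write_label_mask_tiff <- function(labels, path) {
  stopifnot(is.matrix(labels), all(labels >= 0), all(labels <= 65535))
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' Read an MRC mode-2 micrograph
#'
#' Minimal reader for the MRC2014 format restricted to mode 2 (32-bit
#' float), the mode electron micrographs are distributed in. The pixel
#' size is taken from the header cell dimensions (`cella.x / nx`, in
#' angstrom, converted to nm) unless overridden.
#'
#' @param path MRC file.
#' @param pixel_size_nm override for the header pixel size (nm/px).
#' @param ... passed to [micrograph()].
#' @return a [micrograph()]; only the first section of a stack is read.
#' @export
read_micrograph_mrc <- function(path, pixel_size_nm = NULL, ...) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]; mode <- hdr_int[4]
  if (mode != 2) stop("only MRC mode 2 (32-bit float) is supported, got mode ",
                      mode)
  # words 11-13: cell dimensions in angstrom
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  if (is.null(pixel_size_nm)) {
    if (cella[1] <= 0) stop("MRC header has no cell size; supply pixel_size_nm")
    pixel_size_nm <- cella[1] / nx / 10  # angstrom -> nm
  }
  seek(con, 1024)  # data starts after the fixed 1024-byte header
  dat <- readBin(con, "numeric", n = nx * ny, size = 4, endian = "little")
  # MRC stores rows of x varying fastest; map to a rows x cols matrix
  img <- t(matrix(dat, nx, ny))
  micrograph(img, pixel_size_nm = pixel_size_nm, ...)
}

#' Write a micrograph as MRC mode 2
#'
#' @param x a [micrograph()] or numeric matrix.
#' @param path output file.
#' @param pixel_size_nm pixel size recorded in the header (taken from
#'   the micrograph when omitted).
#' @export
write_micrograph_mrc <- function(x, path, pixel_size_nm = NULL) {
  img <- if (inherits(x, "micrograph")) x$pixels else x
  if (is.null(pixel_size_nm)) {
    pixel_size_nm <- if (inherits(x, "micrograph")) x$pixel_size_nm else 1
  }
  nx <- ncol(img); ny <- nrow(img)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(nx, ny, 1L, 2L, 0L, 0L, 0L, nx, ny, 1L)), con,
           size = 4, endian = "little")
  writeBin(c(nx * pixel_size_nm * 10, ny * pixel_size_nm * 10, 10), con,
           size = 4, endian = "little")  # cell in angstrom
  writeBin(c(90, 90, 90), con, size = 4, endian = "little")
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4, endian = "little")
  writeBin(c(min(img), max(img), mean(img)), con, size = 4, endian = "little")
  # pad the rest of the 1024-byte header
  writeBin(raw(1024 - 4 * (10 + 3 + 3 + 3 + 3)), con)
  writeBin(as.numeric(t(img)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta_sequences <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write protein sequences to FASTA
#'
#' @param sequences named character vector.
#' @param path output file.
#' @export
write_fasta_sequences <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a topology annotation from TSV
#'
#' Expects columns `sequence_id`, `kind` (`TM`/`inside`/`outside`),
#' `start`, `end`; returns one [topology_annotation()] per sequence id.
#'
#' @param path TSV file.
#' @return named list of [topology_annotation()] objects.
#' @export
read_topology_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sequence_id", "kind", "start", "end") %in% names(tab)))
  ids <- unique(tab$sequence_id)
  out <- lapply(ids, function(id) {
    topology_annotation(tab[tab$sequence_id == id,
                            c("kind", "start", "end"), drop = FALSE],
                        sequence_id = id)
  })
  names(out) <- ids
  out
}

#' Write per-vesicle metrics to CSV
#'
#' @param metrics data.frame from [classify_morphology()].
#' @param path output CSV.
#' @export
write_metrics_csv <- function(metrics, path) {
  cols <- c("source_id", "label", "area_nm2", "eq_diameter_nm",
            "feret_max_nm", "feret_min_nm", "roundness",
            "morphology_class", "touches_border")
  utils::write.csv(metrics[, intersect(cols, names(metrics)), drop = FALSE],
                   path, row.names = FALSE)
  invisible(path)
}
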