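#' Write an imaging MS dataset to imzML
#'
#' Writes a minimal continuous-mode imzML pair (`.imzML` XML plus `.ibd`
#' binary, 64-bit floats). Internal 0-based pixel coordinates are converted to
#' imzML's 1-based convention on output.
#'
#' @param dataset an `msi_dataset`.
#' @param path output path ending in `.imzML`; the `.ibd` file is written
#'   alongside.
#' @return `path`, invisibly.
#' @export
write_imzml <- function(dataset, path) {
  validate_msi_dataset(dataset)
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd_path, path)) ibd_path <- paste0(path, ".ibd")

  uuid <- as.raw(rep_len(c(as.integer(charToRaw(dataset$dataset_id)), 0L), 16L))
  con <- file(ibd_path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(uuid, con)
  n_mz <- length(dataset$mz)
  mz_offset <- 16
  writeBin(as.double(dataset$mz), con, size = 8, endian = "little")
  int_offsets <- mz_offset + 8 * n_mz + 8 * n_mz * (seq_len(nrow(dataset$coords)) - 1)
  for (i in seq_len(nrow(dataset$coords)))
    writeBin(as.double(dataset$intensities[i, ]), con, size = 8,
             endian = "little")

  spec_xml <- vapply(seq_len(nrow(dataset$coords)), function(i) {
    paste0(
      '  <spectrum index="', i - 1L, '" id="spectrum=', i, '">\n',
      '   <scanList count="1"><scan>\n',
      '    <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="',
      dataset$coords[i, "x"] + 1L, '"/>\n',
      '    <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="',
      dataset$coords[i, "y"] + 1L, '"/>\n',
      '   </scan></scanList>\n',
      '   <binaryDataArrayList count="2">\n',
      '    <binaryDataArray encodedLength="0">\n',
      '     <referenceableParamGroupRef ref="mzArray"/>\n',
      '     <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="',
      n_mz, '"/>\n',
      '     <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="',
      mz_offset, '"/>\n',
      '     <binary/>\n    </binaryDataArray>\n',
      '    <binaryDataArray encodedLength="0">\n',
      '     <referenceableParamGroupRef ref="intensityArray"/>\n',
      '     <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="',
      n_mz, '"/>\n',
      '     <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="',
      format(int_offsets[i], scientific = FALSE), '"/>\n',
      '     <binary/>\n    </binaryDataArray>\n',
      '   </binaryDataArrayList>\n  </spectrum>\n')
  }, character(1))

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
    ' <fileDescription><fileContent>\n',
    '  <cvParam cvRef="IMS" accession="IMS:1000030" name="continuous"/>\n',
    ' </fileContent></fileDescription>\n',
    ' <referenceableParamGroupList count="2">\n',
    '  <referenceableParamGroup id="mzArray">\n',
    '   <cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>\n',
    '   <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>\n',
    '  </referenceableParamGroup>\n',
    '  <referenceableParamGroup id="intensityArray">\n',
    '   <cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>\n',
    '   <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>\n',
    '  </referenceableParamGroup>\n',
    ' </referenceableParamGroupList>\n',
    ' <run id="', dataset$dataset_id, '">\n',
    ' <spectrumList count="', nrow(dataset$coords), '">\n',
    paste0(spec_xml, collapse = ""),
    ' </spectrumList>\n </run>\n</mzML>\n')
  writeLines(xml, path)
  invisible(path)
}

imzml_cv <- function(node, accession) {
  xml2::xml_attr(
    xml2::xml_find_first(node, paste0(".//cvParam[@accession='", accession,
                                      "']")), "value")
}

#' Read an imzML imaging MS dataset
#'
#' Supports continuous-mode files (shared m/z axis) and processed-mode files,
#' whose per-spectrum axes are resampled by linear interpolation onto the
#' union of all axes. Only 64-bit float arrays are supported.
#'
#' @param path path to the `.imzML` file; the `.ibd` file must sit alongside.
#' @param dataset_id optional id; defaults to the file stem.
#' @return An `msi_dataset`.
#' @export
read_imzml <- function(path, dataset_id = NULL) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed imzML (not parseable XML): ",
                                           conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (!file.exists(ibd_path)) stop("missing .ibd binary file: ", ibd_path)
  if (is.null(dataset_id))
    dataset_id <- sub("\\.imzML$", "", basename(path), ignore.case = TRUE)

  mode_cont <- length(xml2::xml_find_all(
    doc, "//cvParam[@accession='IMS:1000030']")) > 0
  mode_proc <- length(xml2::xml_find_all(
    doc, "//cvParam[@accession='IMS:1000031']")) > 0
  if (!mode_cont && !mode_proc)
    stop("malformed imzML: fileContent lacks a continuous/processed cvParam")

  spectra <- xml2::xml_find_all(doc, "//spectrum")
  if (length(spectra) == 0L)
    stop("empty imzML dataset: no spectrum elements")

  ibd <- file(ibd_path, "rb")
  on.exit(close(ibd), add = TRUE)

  read_array <- function(bda) {
    off <- as.numeric(imzml_cv(bda, "IMS:1000102"))
    len <- as.integer(imzml_cv(bda, "IMS:1000103"))
    if (is.na(off) || is.na(len))
      stop("malformed imzML: binaryDataArray lacks external offset/length")
    seek(ibd, where = off, origin = "start")
    readBin(ibd, "double", n = len, size = 8, endian = "little")
  }

  pixels <- matrix(0L, length(spectra), 2,
                   dimnames = list(NULL, c("x", "y")))
  mzs <- vector("list", length(spectra))
  ints <- vector("list", length(spectra))
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    px <- as.integer(imzml_cv(sp, "IMS:1000050"))
    py <- as.integer(imzml_cv(sp, "IMS:1000051"))
    if (is.na(px) || is.na(py))
      stop("malformed imzML: spectrum ", i, " lacks position x/y cvParams")
    pixels[i, ] <- c(px - 1L, py - 1L)
    bdas <- xml2::xml_find_all(sp, ".//binaryDataArray")
    if (length(bdas) < 2L)
      stop("malformed imzML: spectrum ", i, " lacks two binaryDataArrays")
    refs <- vapply(bdas, function(b) {
      r <- xml2::xml_attr(
        xml2::xml_find_first(b, ".//referenceableParamGroupRef"), "ref")
      if (is.na(r)) {
        if (!is.na(imzml_cv(b, "MS:1000514"))) r <- "mzArray"
        else if (!is.na(imzml_cv(b, "MS:1000515"))) r <- "intensityArray"
        else r <- ""
      }
      r
    }, character(1))
    i_mz <- grep("mz", refs, ignore.case = TRUE)[1]
    i_int <- grep("intensit", refs, ignore.case = TRUE)[1]
    if (is.na(i_mz) || is.na(i_int))
      stop("malformed imzML: cannot identify m/z vs intensity array in spectrum ",
           i)
    mzs[[i]] <- read_array(bdas[[i_mz]])
    ints[[i]] <- read_array(bdas[[i_int]])
  }

  if (mode_cont) {
    axis <- mzs[[1]]
    mat <- do.call(rbind, ints)
  } else {
    axis <- sort(unique(unlist(mzs)))
    mat <- t(vapply(seq_along(spectra), function(i) {
      if (length(mzs[[i]]) == 1L)
        ifelse(axis == mzs[[i]], ints[[i]], 0)
      else
        stats::approx(mzs[[i]], ints[[i]], xout = axis, method = "linear",
                      yleft = 0, yright = 0)$y
    }, numeric(length(axis))))
  }
  msi_dataset(pixels, axis, mat, dataset_id = dataset_id)
}

#' Write a reduced dataset to the interchange TSV format
#'
#' Plain tab-separated text: commented header lines carry the dataset id,
#' normalization state and the feature m/z panel; data columns are `x`, `y`,
#' per-pixel provenance, then one intensity column per feature.
#'
#' @param data a `reduced_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reduced <- function(data, path) {
  validate_reduced_dataset(data)
  hdr <- c(
    "# msiagree reduced dataset v1",
    paste0("# dataset_id: ", data$dataset_id),
    paste0("# normalization: ", data$normalization),
    paste0("# feature_mz: ",
           paste(format(data$features$mz, digits = 15, trim = TRUE,
                        scientific = FALSE), collapse = "\t")),
    paste0("# feature_window_ppm: ",
           paste(format(data$features$window_ppm, digits = 15, trim = TRUE),
                 collapse = "\t")))
  df <- data.frame(x = data$coords[, "x"], y = data$coords[, "y"],
                   data$provenance, data$matrix, check.names = FALSE)
  names(df)[8:ncol(df)] <- paste0("f", seq_len(ncol(data$matrix)))
  writeLines(hdr, path)
  data.table::fwrite(df, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a reduced dataset from the interchange TSV format
#'
#' @param path file written by [write_reduced()].
#' @return A `reduced_dataset`.
#' @export
read_reduced <- function(path) {
  hdr <- grep("^#", readLines(path, n = 20L), value = TRUE)
  take <- function(key) {
    line <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(line) != 1L)
      stop("reduced-dataset format error: missing header '", key, "' in ",
           path)
    sub(paste0("^# ", key, ": "), "", line)
  }
  dataset_id <- take("dataset_id")
  normalization <- take("normalization")
  fmz <- as.numeric(strsplit(take("feature_mz"), "\t")[[1]])
  fwin <- as.numeric(strsplit(take("feature_window_ppm"), "\t")[[1]])
  df <- data.table::fread(path, sep = "\t", skip = length(hdr),
                          header = TRUE, data.table = FALSE)
  need <- c("x", "y", "source_id", "source_x", "source_y",
            "offset_x", "offset_y")
  if (!all(need %in% names(df)))
    stop("reduced-dataset format error: missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "))
  fcols <- setdiff(names(df), need)
  if (length(fcols) != length(fmz))
    stop("reduced-dataset format error: header lists ", length(fmz),
         " features but file has ", length(fcols), " feature columns")
  reduced_dataset(df[, c("x", "y")], fmz, as.matrix(df[, fcols, drop = FALSE]),
                  feature_window_ppm = fwin, normalization = normalization,
                  provenance = df[, need[3:7]], dataset_id = dataset_id)
}

#' Render per-pixel values as an image matrix
#'
#' Places a pixel-indexed vector onto its (row = y, column = x) grid;
#' off-tissue grid cells are `NA`.
#'
#' @param coords pixel coordinate matrix (0-based x, y).
#' @param values numeric vector, one value per pixel.
#' @return A numeric matrix covering the coordinate bounding box.
#' @export
as_image_matrix <- function(coords, values) {
  coords <- as_coords(coords)
  stopifnot(length(values) == nrow(coords))
  nx <- max(coords[, "x"]) + 1L
  ny <- max(coords[, "y"]) + 1L
  img <- matrix(NA_real_, ny, nx)
  img[cbind(coords[, "y"] + 1L, coords[, "x"] + 1L)] <- values
  img
}

#' Export an image matrix as a CSV grid (NaN off tissue)
#' @param coords,values as in [as_image_matrix()].
#' @param path output CSV path.
#' @export
write_image_csv <- function(coords, values, path) {
  img <- as_image_matrix(coords, values)
  img[is.na(img)] <- NaN
  utils::write.table(img, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
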