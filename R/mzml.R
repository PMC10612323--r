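#' @title Minimal centroided mzML reader/writer
#'
#' @description Lightweight mzML support sufficient for centroided MS1 data:
#' one `<spectrum>` per scan with base64-encoded m/z and intensity arrays.
#' Profile-mode spectra are rejected because every downstream metric assumes
#' one centroid per ion per scan.
#'
#' @name mzml-io
#' @keywords internal
NULL

.MS_CV <- list(
  centroid   = "MS:1000127",
  profile    = "MS:1000128",
  scan_start = "MS:1000016",
  mz_array   = "MS:1000514",
  int_array  = "MS:1000515",
  float64    = "MS:1000523",
  float32    = "MS:1000521",
  zlib       = "MS:1000574",
  no_comp    = "MS:1000576"
)

#' Read centroided scans from an mzML file
#'
#' Parses a centroided mzML file into a `data.frame` of scan points with one
#' row per centroid, sorted by retention time then m/z. Scan times are
#' converted to seconds regardless of the unit declared in the file.
#'
#' @param path Path to a centroided mzML file.
#' @return A `data.frame` with columns `rt` (seconds), `mz` (Th) and
#'   `intensity`, sorted by `(rt, mz)`. The distinct sorted `rt` values are
#'   the file's scan times (see [scan_times()]). Zero scans yield a zero-row
#'   data frame.
#' @export
#' @examples
#' sc <- data.frame(rt = c(1, 1, 2), mz = c(100, 200, 100.1),
#'                  intensity = c(5, 9, 7))
#' f <- tempfile(fileext = ".mzML")
#' write_mzml(sc, f)
#' read_scans(f)
read_scans <- function(path) {
  if (!file.exists(path)) stop("cannot read mzML file: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("unreadable mzML file '", path,
                                           "': ", conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  spectra <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  if (length(spectra) == 0L) {
    return(data.frame(rt = numeric(0), mz = numeric(0),
                      intensity = numeric(0)))
  }
  pieces <- lapply(spectra, .parse_spectrum, path = path)
  out <- do.call(rbind, pieces)
  out <- out[order(out$rt, out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.spectrum_has_cv <- function(node, accession) {
  length(xml2::xml_find_first(
    node, sprintf(".//cvParam[@accession='%s']", accession))) > 0 &&
    !inherits(xml2::xml_find_first(
      node, sprintf(".//cvParam[@accession='%s']", accession)),
      "xml_missing")
}

.parse_spectrum <- function(sp, path) {
  if (.spectrum_has_cv(sp, .MS_CV$profile)) {
    stop("mzML file '", path, "' contains profile-mode spectra; ",
         "peakgrader requires centroided data (re-run msConvert with ",
         "peak picking / centroiding enabled)")
  }
  rt_node <- xml2::xml_find_first(
    sp, sprintf(".//scan/cvParam[@accession='%s']", .MS_CV$scan_start))
  if (inherits(rt_node, "xml_missing")) {
    stop("spectrum without a scan start time in '", path, "'")
  }
  rt <- as.numeric(xml2::xml_attr(rt_node, "value"))
  unit <- xml2::xml_attr(rt_node, "unitName")
  if (!is.na(unit) && grepl("minute", unit, ignore.case = TRUE)) {
    rt <- rt * 60
  }
  arrays <- xml2::xml_find_all(sp, ".//binaryDataArray")
  mz <- int <- numeric(0)
  for (arr in arrays) {
    vals <- .decode_binary_array(arr, path)
    if (.spectrum_has_cv(arr, .MS_CV$mz_array)) mz <- vals
    if (.spectrum_has_cv(arr, .MS_CV$int_array)) int <- vals
  }
  if (length(mz) != length(int)) {
    stop("m/z and intensity arrays differ in length in '", path, "'")
  }
  if (length(mz) == 0L) {
    return(data.frame(rt = numeric(0), mz = numeric(0),
                      intensity = numeric(0)))
  }
  data.frame(rt = rep(rt, length(mz)), mz = mz, intensity = int)
}

.decode_binary_array <- function(arr, path) {
  b64 <- xml2::xml_text(xml2::xml_find_first(arr, ".//binary"))
  b64 <- gsub("[[:space:]]", "", b64)
  if (!nzchar(b64)) return(numeric(0))
  raw_bytes <- jsonlite::base64_dec(b64)
  if (.spectrum_has_cv(arr, .MS_CV$zlib)) {
    raw_bytes <- memDecompress(raw_bytes, type = "gzip")
  }
  size <- if (.spectrum_has_cv(arr, .MS_CV$float32)) 4L else 8L
  readBin(raw_bytes, what = "double", n = length(raw_bytes) %/% size,
          size = size, endian = "little")
}

#' Distinct acquisition times of a scan-point table
#'
#' @param scans A scan-point `data.frame` as returned by [read_scans()].
#' @return Sorted unique retention times (seconds).
#' @export
scan_times <- function(scans) {
  sort(unique(scans$rt))
}

#' Write scan points to a centroided mzML file
#'
#' Inverse of [read_scans()]: groups points by retention time into spectra
#' and writes uncompressed 64-bit float arrays so the round trip is
#' bit-exact.
#'
#' @param scans `data.frame` with columns `rt`, `mz`, `intensity`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(scans, path) {
  stopifnot(is.data.frame(scans),
            all(c("rt", "mz", "intensity") %in% names(scans)))
  scans <- scans[order(scans$rt, scans$mz), , drop = FALSE]
  rts <- unique(scans$rt)
  enc <- function(x) {
    jsonlite::base64_enc(writeBin(as.double(x), raw(), size = 8L,
                                  endian = "little"))
  }
  spectra <- vapply(seq_along(rts), function(i) {
    pts <- scans[scans$rt == rts[i], , drop = FALSE]
    mz_b64 <- enc(pts$mz)
    int_b64 <- enc(pts$intensity)
    paste0(
      sprintf('<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
              i - 1L, i, nrow(pts)),
      '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>',
      '<scanList count="1"><scan>',
      sprintf(paste0('<cvParam cvRef="MS" accession="MS:1000016" ',
                     'name="scan start time" value="%.12g" ',
                     'unitCvRef="UO" unitAccession="UO:0000010" ',
                     'unitName="second"/>'), rts[i]),
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      sprintf('<binaryDataArray encodedLength="%d">', nchar(mz_b64)),
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>',
      sprintf('<binary>%s</binary></binaryDataArray>', mz_b64),
      sprintf('<binaryDataArray encodedLength="%d">', nchar(int_b64)),
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>',
      sprintf('<binary>%s</binary></binaryDataArray>', int_b64),
      '</binaryDataArrayList></spectrum>'
    )
  }, character(1))
  xml <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<run id="run1"><spectrumList count="', length(rts), '">',
    paste0(spectra, collapse = ""),
    '</spectrumList></run></mzML>'
  )
  writeLines(xml, path)
  invisible(path)
}
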