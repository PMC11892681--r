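# Minimal imzML 1.1 writer/reader (processed mode written; processed and
# continuous dialects read). m/z arrays are stored as 64-bit floats and
# intensities as 32-bit floats in the external .ibd file, linked to the XML
# by a shared UUID, following the imzML convention. Coordinates are 1-based
# on disk and 0-based in memory.

.IMZML_NS <- "http://psi.hupo.org/ms/mzml"

.deterministic_uuid <- function(seed) {
  bytes <- with_seed(seed, as.integer(floor(runif(16, 0, 256))))
  # RFC 4122 version-4 variant bits
  bytes[7] <- bitwOr(bitwAnd(bytes[7], 15L), 64L)
  bytes[9] <- bitwOr(bitwAnd(bytes[9], 63L), 128L)
  hx <- sprintf("%02x", bytes)
  sprintf("%s-%s-%s-%s-%s", paste(hx[1:4], collapse = ""),
          paste(hx[5:6], collapse = ""), paste(hx[7:8], collapse = ""),
          paste(hx[9:10], collapse = ""), paste(hx[11:16], collapse = ""))
}

#' Write an MSI dataset as imzML 1.1 (processed mode)
#'
#' Writes `<path>.imzML` and `<path>.ibd`. Zero-intensity points are
#' preserved. The UUID linking the two files is derived deterministically
#' from the dataset metadata so identical datasets yield identical files.
#'
#' @param dataset an [msi_dataset()]
#' @param path output path without extension (or ending in .imzML)
#' @return invisibly, the .imzML path
#' @export
write_imzml <- function(dataset, path) {
  stopifnot(inherits(dataset, "msi_dataset"))
  for (s in dataset$spectra)
    if (any(!is.finite(s$intensity)) || any(!is.finite(s$mz)))
      stopf("non-finite values cannot be serialised to imzML")
  path <- sub("\\.imzML$", "", path, ignore.case = TRUE)
  xml_path <- paste0(path, ".imzML")
  ibd_path <- paste0(path, ".ibd")
  uuid <- .deterministic_uuid(derive_seed(1L, "uuid", dataset$tissue_id,
                                          dataset$experiment_id, dataset$arm,
                                          nrow(dataset$coords)))

  con <- file(ibd_path, "wb")
  on.exit(close(con), add = TRUE)
  uuid_bytes <- as.raw(strtoi(substring(gsub("-", "", uuid),
                                        seq(1, 31, 2), seq(2, 32, 2)), 16L))
  writeBin(uuid_bytes, con)
  offset <- 16
  n <- length(dataset$spectra)
  mz_off <- int_off <- mz_len <- int_len <- numeric(n)
  for (i in seq_len(n)) {
    s <- dataset$spectra[[i]]
    mz_off[i] <- offset; mz_len[i] <- length(s$mz)
    writeBin(as.numeric(s$mz), con, size = 8, endian = "little")
    offset <- offset + 8 * length(s$mz)
    int_off[i] <- offset; int_len[i] <- length(s$intensity)
    writeBin(as.numeric(s$intensity), con, size = 4, endian = "little")
    offset <- offset + 4 * length(s$intensity)
  }

  xs <- dataset$coords$x + 1L
  ys <- dataset$coords$y + 1L
  spec_xml <- sprintf(paste0(
    '      <spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">\n',
    '        <scanList count="1">\n',
    '          <scan>\n',
    '            <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>\n',
    '            <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>\n',
    '          </scan>\n',
    '        </scanList>\n',
    '        <binaryDataArrayList count="2">\n',
    '          <binaryDataArray encodedLength="0">\n',
    '            <referenceableParamGroupRef ref="mzArray"/>\n',
    '            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n',
    '            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>\n',
    '            <binary/>\n',
    '          </binaryDataArray>\n',
    '          <binaryDataArray encodedLength="0">\n',
    '            <referenceableParamGroupRef ref="intensityArray"/>\n',
    '            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n',
    '            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>\n',
    '            <binary/>\n',
    '          </binaryDataArray>\n',
    '        </binaryDataArrayList>\n',
    '      </spectrum>'),
    seq_len(n) - 1L, seq_len(n), mz_len, xs, ys,
    mz_len, mz_off, int_len, int_off)

  header <- sprintf(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="%s" version="1.1">\n',
    '  <cvList count="2">\n',
    '    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>\n',
    '    <cv id="IMS" fullName="Imaging MS Ontology" URI="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>\n',
    '  </cvList>\n',
    '  <fileDescription>\n',
    '    <fileContent>\n',
    '      <cvParam cvRef="IMS" accession="IMS:1000031" name="processed" value=""/>\n',
    '      <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>\n',
    '      <userParam name="tissue_id" value="%s"/>\n',
    '      <userParam name="experiment_id" value="%s"/>\n',
    '      <userParam name="arm" value="%s"/>\n',
    '      <userParam name="polarity" value="%s"/>\n',
    '      <userParam name="modality" value="%s"/>\n',
    '      <userParam name="pixel_pitch_um" value="%.6g"/>\n',
    '      <userParam name="mass_range_low" value="%.9g"/>\n',
    '      <userParam name="mass_range_high" value="%.9g"/>\n',
    '    </fileContent>\n',
    '  </fileDescription>\n',
    '  <referenceableParamGroupList count="2">\n',
    '    <referenceableParamGroup id="mzArray">\n',
    '      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>\n',
    '      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n',
    '      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>\n',
    '    </referenceableParamGroup>\n',
    '    <referenceableParamGroup id="intensityArray">\n',
    '      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>\n',
    '      <cvParam cvRef="MS" accession="MS:1000521" name="32-bit float" value=""/>\n',
    '      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>\n',
    '    </referenceableParamGroup>\n',
    '  </referenceableParamGroupList>\n',
    '  <softwareList count="1">\n',
    '    <software id="msipd" version="0.1.0"/>\n',
    '  </softwareList>\n',
    '  <scanSettingsList count="1">\n',
    '    <scanSettings id="scan1">\n',
    '      <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>\n',
    '      <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>\n',
    '    </scanSettings>\n',
    '  </scanSettingsList>\n',
    '  <instrumentConfigurationList count="1">\n',
    '    <instrumentConfiguration id="IC1"/>\n',
    '  </instrumentConfigurationList>\n',
    '  <dataProcessingList count="1">\n',
    '    <dataProcessing id="export">\n',
    '      <processingMethod order="1" softwareRef="msipd">\n',
    '        <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>\n',
    '      </processingMethod>\n',
    '    </dataProcessing>\n',
    '  </dataProcessingList>\n',
    '  <run id="run1" defaultInstrumentConfigurationRef="IC1">\n',
    '    <spectrumList count="%d">'),
    .IMZML_NS, uuid, dataset$tissue_id, dataset$experiment_id, dataset$arm,
    dataset$polarity, dataset$modality, dataset$pixel_pitch,
    dataset$mass_range[1], dataset$mass_range[2],
    max(xs), max(ys), n)

  writeLines(c(header, spec_xml,
               '    </spectrumList>', '  </run>', '</mzML>'), xml_path)
  invisible(xml_path)
}

#' Read an imzML file pair into an MSI dataset
#'
#' Accepts both processed and continuous imzML dialects with external binary
#' data. Coordinates are remapped from the 1-based convention on disk to
#' 0-based in memory. Offsets beyond the .ibd size raise an error naming the
#' offending pixel.
#'
#' @param path path to the .imzML file (the .ibd must sit beside it)
#' @return an [msi_dataset()]
#' @export
read_imzml <- function(path) {
  if (!file.exists(path)) stopf("imzML file not found: %s", path)
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd_path, path)) ibd_path <- paste0(path, ".ibd")
  if (!file.exists(ibd_path)) stopf("missing .ibd companion for %s", path)
  doc <- xml2::read_xml(path)
  ns <- c(d = .IMZML_NS)

  up <- function(name, default = NA_character_) {
    node <- xml2::xml_find_first(doc, sprintf(".//d:userParam[@name='%s']", name), ns)
    if (inherits(node, "xml_missing")) default else xml2::xml_attr(node, "value")
  }
  uuid_node <- xml2::xml_find_first(
    doc, ".//d:cvParam[@accession='IMS:1000080']", ns)
  ibd_size <- file.info(ibd_path)$size
  ibd <- file(ibd_path, "rb")
  on.exit(close(ibd), add = TRUE)
  if (!inherits(uuid_node, "xml_missing")) {
    xml_uuid <- tolower(gsub("[{}-]", "", xml2::xml_attr(uuid_node, "value")))
    ibd_uuid <- paste(sprintf("%02x", as.integer(readBin(ibd, "raw", 16))),
                      collapse = "")
    if (nzchar(xml_uuid) && xml_uuid != ibd_uuid)
      stopf("UUID mismatch between imzML (%s) and ibd (%s)", xml_uuid, ibd_uuid)
  }

  specs <- xml2::xml_find_all(doc, ".//d:spectrum", ns)
  if (!length(specs)) stopf("imzML contains no spectra: %s", path)
  get_attr <- function(nodes, xpath) {
    as.numeric(xml2::xml_attr(xml2::xml_find_first(nodes, xpath, ns), "value"))
  }
  xs <- get_attr(specs, ".//d:cvParam[@accession='IMS:1000050']")
  ys <- get_attr(specs, ".//d:cvParam[@accession='IMS:1000051']")
  if (any(is.na(xs)) || any(is.na(ys))) stopf("missing pixel positions in %s", path)

  arrays <- lapply(seq_along(specs), function(i) {
    bda <- xml2::xml_find_all(specs[[i]], ".//d:binaryDataArray", ns)
    info <- lapply(bda, function(b) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(b, ".//d:referenceableParamGroupRef", ns), "ref")
      is_mz <- if (!is.na(ref)) grepl("mz", ref, ignore.case = TRUE) else
        !inherits(xml2::xml_find_first(b, ".//d:cvParam[@accession='MS:1000514']", ns),
                  "xml_missing")
      len <- as.numeric(xml2::xml_attr(
        xml2::xml_find_first(b, ".//d:cvParam[@accession='IMS:1000103']", ns), "value"))
      off <- as.numeric(xml2::xml_attr(
        xml2::xml_find_first(b, ".//d:cvParam[@accession='IMS:1000102']", ns), "value"))
      list(is_mz = is_mz, len = len, off = off)
    })
    mz_i <- which(vapply(info, `[[`, logical(1), "is_mz"))[1]
    int_i <- setdiff(seq_along(info), mz_i)[1]
    if (is.na(mz_i) || is.na(int_i))
      stopf("pixel %d: cannot identify m/z and intensity arrays", i)
    mzin <- info[[mz_i]]; inin <- info[[int_i]]
    if (mzin$off + 8 * mzin$len > ibd_size || inin$off + 4 * inin$len > ibd_size)
      stopf("pixel %d: binary offset beyond .ibd size (corrupt file?)", i)
    seek(ibd, mzin$off)
    mz <- readBin(ibd, "double", n = mzin$len, size = 8, endian = "little")
    seek(ibd, inin$off)
    inten <- readBin(ibd, "double", n = inin$len, size = 4, endian = "little")
    new_spectrum(mz, pmax(inten, 0))
  })

  mr_lo <- suppressWarnings(as.numeric(up("mass_range_low")))
  mr_hi <- suppressWarnings(as.numeric(up("mass_range_high")))
  msi_dataset(
    coords = data.frame(x = as.integer(xs) - 1L, y = as.integer(ys) - 1L),
    spectra = arrays,
    pixel_pitch = suppressWarnings(as.numeric(up("pixel_pitch_um", "50"))),
    polarity = up("polarity", "negative"),
    modality = up("modality", "MALDI"),
    tissue_id = up("tissue_id", tools::file_path_sans_ext(basename(path))),
    experiment_id = up("experiment_id", "exp"),
    arm = up("arm", "unknown"),
    mass_range = if (is.finite(mr_lo) && is.finite(mr_hi)) c(mr_lo, mr_hi) else NULL
  )
}
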