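# toy spectrum with explicit peaks
toy_spectrum <- function(mz, intensity, pre = NA_real_) {
  centroid_spectrum(mz, intensity, precursor_mz = pre)
}

# minimal valid mzML written from code (64-bit float, no compression)
write_test_mzml <- function(path, scans) {
  b64 <- function(x) {
    jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8,
                                  endian = "little"))
  }
  spec <- function(idx, sc) {
    sprintf(paste0(
      '<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">\n',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="2"/>\n',
      '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>\n',
      '<precursorList count="1"><precursor><selectedIonList count="1"><selectedIon>\n',
      '<cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%f"/>\n',
      '</selectedIon></selectedIonList><activation/></precursor></precursorList>\n',
      '<binaryDataArrayList count="2">\n',
      '<binaryDataArray encodedLength="%d">\n',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>\n',
      '<binary>%s</binary></binaryDataArray>\n',
      '<binaryDataArray encodedLength="%d">\n',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>\n',
      '<binary>%s</binary></binaryDataArray>\n',
      '</binaryDataArrayList></spectrum>'),
      idx, idx + 1L, length(sc$mz), sc$pre,
      nchar(b64(sc$mz)), b64(sc$mz),
      nchar(b64(sc$intensity)), b64(sc$intensity))
  }
  body <- paste(vapply(seq_along(scans), function(i) {
    spec(i - 1L, scans[[i]])
  }, character(1)), collapse = "\n")
  xml <- paste0('<?xml version="1.0" encoding="utf-8"?>\n',
                '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
                '<cvList count="1"><cv id="MS" fullName="PSI-MS" URI="x"/></cvList>\n',
                '<fileDescription><fileContent>\n',
                '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>\n',
                '</fileContent></fileDescription>\n',
                '<run id="run1">\n<spectrumList count="', length(scans),
                '" defaultDataProcessingRef="dp">\n', body,
                '\n</spectrumList></run></mzML>')
  writeLines(xml, path)
  invisible(path)
}

# tiny synthetic m/z + CCS reference table
test_ccs_reference <- function() {
  data.frame(
    name = c("PC 34:1", "PC 36:4", "SM 34:1;O2", "PE 34:2", "TG 52:3"),
    adduct = "[M+H]+",
    mz = c(760.5851, 782.5694, 703.5749, 714.5068, 857.7542),
    ccs = c(289.1, 293.4, 284.7, 277.9, 321.5),
    source = "predicted",
    stringsAsFactors = FALSE)
}
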