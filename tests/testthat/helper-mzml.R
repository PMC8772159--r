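# Minimal centroided mzML writer for fixtures (uncompressed 64-bit little-
# endian arrays). Only what mzR needs to hand back scans: not a general
# exporter.

mzml_b64 <- function(x) {
  raw <- writeBin(as.numeric(x), raw(), size = 8, endian = "little")
  gsub("\n", "", jsonlite::base64_enc(raw))
}

mzml_spectrum <- function(i, rt, mz, inten) {
  sprintf(paste0(
    '<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
    '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>',
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
    '<scanList count="1"><cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>',
    '<scan><cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%f" unitName="second" unitCvRef="UO" unitAccession="UO:0000010"/></scan></scanList>',
    '<binaryDataArrayList count="2">',
    '<binaryDataArray encodedLength="%d"><cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
    '<binary>%s</binary></binaryDataArray>',
    '<binaryDataArray encodedLength="%d"><cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
    '<binary>%s</binary></binaryDataArray>',
    '</binaryDataArrayList></spectrum>'),
    i, i + 1, length(mz), rt,
    nchar(mzml_b64(mz)), mzml_b64(mz),
    nchar(mzml_b64(inten)), mzml_b64(inten))
}

# scans: list of list(rt=, mz=, intensity=)
write_test_mzml <- function(scans, path) {
  body <- paste0(vapply(seq_along(scans), function(i) {
    s <- scans[[i]]
    mzml_spectrum(i - 1, s$rt, s$mz, s$intensity)
  }, character(1)), collapse = "")
  xml <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<cvList count="2">',
    '<cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="UO" URI="http://ontologies.berkeleybop.org/uo.obo"/></cvList>',
    '<fileDescription><fileContent><cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/></fileContent></fileDescription>',
    '<softwareList count="1"><software id="sw" version="0"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value=""/></software></softwareList>',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="ic"/></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="dp"><processingMethod order="1" softwareRef="sw">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/></processingMethod></dataProcessing></dataProcessingList>',
    '<run id="r" defaultInstrumentConfigurationRef="ic">',
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="dp">%s</spectrumList>',
            length(scans), body),
    '</run></mzML>')
  writeLines(xml, path)
  path
}
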