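# Minimal uncompressed mzML writer used only to create read fixtures.
# 64-bit little-endian doubles, base64, no compression; one MS1 spectrum
# per element of `spectra` (list of list(rt_sec, mz, intensity)).
write_minimal_mzml <- function(path, spectra, centroided = TRUE) {
  b64 <- function(x)
    jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8,
                                  endian = "little"))
  mode_param <- if (centroided)
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>'
  else
    '<cvParam cvRef="MS" accession="MS:1000128" name="profile spectrum" value=""/>'

  spec_xml <- vapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    mzb <- b64(s$mz); inb <- b64(s$intensity)
    paste0(
      '<spectrum index="', i - 1L, '" id="scan=', i,
      '" defaultArrayLength="', length(s$mz), '">\n',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>\n',
      mode_param, "\n",
      '<scanList count="1"><scan>',
      '<cvParam cvRef="MS" accession="MS:1000016" name="scan start time" ',
      'value="', s$rt_sec, '" unitCvRef="UO" unitAccession="UO:0000010" ',
      'unitName="second"/></scan></scanList>\n',
      '<binaryDataArrayList count="2">\n',
      '<binaryDataArray encodedLength="', nchar(mzb), '">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>',
      '<binary>', mzb, '</binary></binaryDataArray>\n',
      '<binaryDataArray encodedLength="', nchar(inb), '">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>',
      '<binary>', inb, '</binary></binaryDataArray>\n',
      '</binaryDataArrayList></spectrum>'
    )
  }, "")

  xml <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="2">\n',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>\n',
    '<cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>\n',
    '</cvList>\n',
    '<fileDescription><fileContent>\n',
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>\n',
    mode_param, "\n",
    '</fileContent></fileDescription>\n',
    '<softwareList count="1"><software id="sim" version="1.0">',
    '<cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="sim"/>',
    '</software></softwareList>\n',
    '<instrumentConfigurationList count="1">',
    '<instrumentConfiguration id="IC1">',
    '<cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/>',
    '</instrumentConfiguration></instrumentConfigurationList>\n',
    '<dataProcessingList count="1"><dataProcessing id="dp1">',
    '<processingMethod order="1" softwareRef="sim">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
    '</processingMethod></dataProcessing></dataProcessingList>\n',
    '<run id="run1" defaultInstrumentConfigurationRef="IC1">\n',
    '<spectrumList count="', length(spectra),
    '" defaultDataProcessingRef="dp1">\n',
    paste(spec_xml, collapse = "\n"), "\n",
    '</spectrumList></run></mzML>\n'
  )
  writeLines(xml, path)
  invisible(path)
}
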