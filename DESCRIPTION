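Package: sheetbuild
Title: Rapid Model Building of Beta-Sheets in Electron-Density Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Locates beta-strands in moderate-resolution (2.5-4 Angstrom)
    electron-density maps as nearly parallel tubes of density, determines
    strand register and direction from the 6.7 Angstrom periodic pattern of
    carbonyl-O and C-beta density, places idealized strands and assembles
    them into a non-overlapping beta-sheet model. Includes map (CCP4/MRC)
    and model (PDB) input/output, a synthetic fixture generator that
    computes model density for idealized sheets at a stated resolution,
    and evaluation metrics (residue recall/precision, main-chain RMSD,
    masked map-model correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
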