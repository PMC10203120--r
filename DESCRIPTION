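Package: SliceLink
Title: Slice-Wise Watershed Segmentation with Cross-Slice Linking for 3D
    Cell Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-automatic 3D instance segmentation for volumetric cell
    images such as electron-microscopy stacks. Converts per-slice
    cell/non-cell predictions into 2D instance labels with a
    distance-transform seeded watershed (h-maxima seeds), links instances
    across slices by the overlap coefficient, and provides a proofreading
    toolkit -- merge, delete, 2D and 3D division, division with
    relinking, cell insertion, sorting by volume and small-object
    removal -- over efficient slice-wise and volumetric label stores with
    bounded undo/redo, autosave/resume, and TIFF stack import/export. A
    synthetic phantom generator with known ground truth and
    segmentation-error scoring supports benchmarking against a 3D
    watershed baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, data.table, tiff, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), EBImage, jsonlite, optparse, igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
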