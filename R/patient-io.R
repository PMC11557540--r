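# Patient case serialization: a directory holding mesh.vtk (with cellularity,
# ktrans and tumour mask as cell data) and patient.json (pt, PSA series,
# follow-up observations, seed).

#' Save / load a patient case
#'
#' `savePatient` writes `mesh.vtk` (cell data: cellularity, ktrans_per_day,
#' tumour_mask) and `patient.json` into a directory; `loadPatient` restores
#' the [PatientCase-class].
#'
#' @param patient a [PatientCase-class].
#' @param dir directory (created if missing).
#' @return the directory (`savePatient`) or a [PatientCase-class]
#'   (`loadPatient`).
#' @export
savePatient <- function(patient, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeVTKMesh(patient@mesh, file.path(dir, "mesh.vtk"),
               fields = list(cellularity = patient@cellularity,
                             ktrans_per_day = patient@ktrans,
                             tumour_mask = as.numeric(patient@tumourMask)))
  meta <- list(pt = patient@pt,
               psa = list(dates = patient@psaDates, values = patient@psaValues),
               followUp = patient@followUp, seed = patient@seed)
  jsonlite::write_json(meta, file.path(dir, "patient.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' @rdname savePatient
#' @export
loadPatient <- function(dir) {
  vtk <- readVTKMesh(file.path(dir, "mesh.vtk"))
  meta <- jsonlite::read_json(file.path(dir, "patient.json"),
                              simplifyVector = TRUE)
  fu <- as.data.frame(meta$followUp)
  if (!nrow(fu))
    fu <- data.frame(date = numeric(0), prostateVolume = numeric(0),
                     tumourVolume = numeric(0), prostateCellularity = numeric(0),
                     tumourCellularity = numeric(0))
  new("PatientCase", mesh = vtk$mesh,
      tumourMask = vtk$fields$tumour_mask > 0,
      cellularity = vtk$fields$cellularity,
      ktrans = vtk$fields$ktrans_per_day,
      pt = meta$pt, psaDates = as.numeric(meta$psa$dates),
      psaValues = as.numeric(meta$psa$values), followUp = fu,
      seed = if (is.null(meta$seed)) NA_real_ else as.numeric(meta$seed))
}
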