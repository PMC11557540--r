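# Imaging biomarkers -> model initial condition. ADC maps give cellularity
# (linear inverse relation between the free-water ADC and the standardized
# minimum); cellularity plus the biopsy tumour burden partitions the tissue
# into tumour-cell, healthy-cell and stroma densities; KTrans maps are
# converted to per-day extravasation rates.

#' Cellularity from an ADC map or field
#'
#' cellularity = (ADCw - ADC) / (ADCw - ADCmin), clipped to [0, 1]. Free
#' water diffuses fastest, so cellularity decreases monotonically with ADC;
#' the minimum ADC is standardized to 0 for comparability across patients
#' and follow-ups, which is why clipping is needed for ADC > ADCw.
#'
#' @param adc a [VoxelMap-class] (mm^2/s) or numeric per-element field.
#' @param ADCw free-water ADC (default 3e-3 mm^2/s).
#' @param ADCmin standardized minimum ADC (default 0).
#' @return object of the same shape as `adc`, values in [0, 1].
#' @examples
#' cellularityFromADC(c(3e-3, 0, 1.5e-3))
#' @export
cellularityFromADC <- function(adc, ADCw = 3e-3, ADCmin = 0) {
  if (ADCw <= ADCmin || ADCmin < 0)
    stop("require ADCw > ADCmin >= 0")
  f <- function(x) pmin(pmax((ADCw - x) / (ADCw - ADCmin), 0), 1)
  if (is(adc, "VoxelMap")) {
    out <- adc
    out@data[] <- f(adc@data)
    out@units <- ""
    return(out)
  }
  f(adc)
}

#' Initial constituent densities from cellularity and tumour burden
#'
#' In tumour elements, the biopsy burden fraction `pt` splits the cellularity
#' between tumour and healthy cells, each scaled by its own carrying capacity;
#' outside the lesion the cellularity is all healthy cells. The space not
#' occupied by cells is stroma.
#'
#' @param cellularity numeric per element, in [0, 1].
#' @param mask logical (or 0/1) per element; TRUE inside the lesion.
#' @param pt tumour burden fraction in [0, 1] (single scalar per patient).
#' @param caps a [CarryingCapacities-class].
#' @return list of per-element densities rhoT, rhoH (cells/mm^3) and rhoS
#'   (g/mm^3).
#' @examples
#' initDensities(0.6, TRUE, 0.02, carryingCapacities())
#' @export
initDensities <- function(cellularity, mask, pt, caps = carryingCapacities()) {
  if (pt < 0 || pt > 1) stop("pt must lie in [0, 1]")
  if (any(cellularity < 0 | cellularity > 1))
    stop("cellularity must lie in [0, 1]")
  mask <- mask > 0
  rhoT <- ifelse(mask, cellularity * pt * caps@rhoCT, 0)
  rhoH <- ifelse(mask, cellularity * (1 - pt) * caps@rhoCH,
                 cellularity * caps@rhoCH)
  rhoS <- (1 - cellularity) * caps@rhoCS
  list(rhoT = rhoT, rhoH = rhoH, rhoS = rhoS)
}

#' Prepare a KTrans field in per-day units
#'
#' Samples the map at element centroids (trilinear) if given a
#' [VoxelMap-class] and converts to 1/day. Negative values (fit artefacts)
#' are clipped to zero with a warning; an all-zero field (avascular prostate)
#' also warns.
#'
#' @param ktrans a [VoxelMap-class] or numeric per-element field.
#' @param mesh a [TetMesh-class]; required when `ktrans` is a map.
#' @param unit unit of the input values: "per_min" (DCE convention,
#'   multiplied by 1440), "per_day" (no conversion) or "per_s" (x 86400).
#' @return per-element extravasation rates (1/day).
#' @export
prepareKTrans <- function(ktrans, mesh = NULL, unit = c("per_min", "per_day", "per_s")) {
  unit <- match.arg(unit)
  if (is(ktrans, "VoxelMap")) {
    if (is.null(mesh)) stop("a mesh is required to sample a KTrans map")
    field <- interpolateToMesh(ktrans, mesh, method = "trilinear")
  } else field <- ktrans
  nneg <- sum(field < 0)
  if (nneg) {
    warning(nneg, " negative KTrans value(s) clipped to 0")
    field <- pmax(field, 0)
  }
  field <- field * switch(unit, per_min = 1440, per_day = 1, per_s = 86400)
  if (all(field == 0))
    warning("KTrans field is identically zero (avascular prostate)")
  field
}
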