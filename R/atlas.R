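#' Atlas region labels and disorder panels
#'
#' Canonical label sets used throughout the package: the 34 bilateral
#' Desikan-Killiany cortical regions (hemispheres combined), the 7
#' subcortical structures, the 3 global measures (total cortical surface
#' area, mean cortical thickness, intracranial volume), the 13-disorder
#' neuropsychiatric panel used for PRS association scans, and the
#' 8-disorder subset with published case-control brain maps.
#'
#' @return character vector of labels.
#' @examples
#' length(dkCorticalRegions())  # 34
#' asegSubcorticalRegions()
#' @export
dkCorticalRegions <- function() c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
  "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
  "lateralorbitofrontal", "lingual", "medialorbitofrontal", "middletemporal",
  "paracentral", "parahippocampal", "parsopercularis", "parsorbitalis",
  "parstriangularis", "pericalcarine", "postcentral", "posteriorcingulate",
  "precentral", "precuneus", "rostralanteriorcingulate",
  "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
  "superiortemporal", "supramarginal", "temporalpole", "transversetemporal")

#' @rdname dkCorticalRegions
#' @export
asegSubcorticalRegions <- function() c(
  "thalamus", "caudate", "putamen", "pallidum", "hippocampus", "amygdala",
  "accumbens")

#' @rdname dkCorticalRegions
#' @export
globalMeasureNames <- function() c(
  "total_surface_area", "mean_thickness", "ICV")

#' @rdname dkCorticalRegions
#' @export
disorderPanel <- function() c(
  "ADHD", "ASD", "BPD", "MDD", "OCD", "PTSD", "SZ", "TS", "AD", "ALS",
  "EP", "FTD", "PD")

#' @rdname dkCorticalRegions
#' @export
mappedDisorders <- function() c(
  "ADHD", "ASD", "BPD", "EP", "MDD", "OCD", "SZ", "PD")

# Global measure paired with each regional modality.
matchingGlobal <- function(modality) {
  switch(modality,
         SA = "total_surface_area",
         CT = "mean_thickness",
         subcortical = "ICV",
         stop(sprintf("no matching global measure for modality '%s'",
                      modality), call. = FALSE))
}
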