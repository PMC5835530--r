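#' Default ROI panel labels
#'
#' The 58 FreeSurfer-style cortical and subcortical region labels used as the
#' default predictor panel: 8 subcortical structures per hemisphere plus 21
#' Desikan-Killiany cortical parcels per hemisphere.  Cohort generation,
#' selection and connectivity reporting use this ordering throughout.
#'
#' @return Character vector of length 58.
#' @examples
#' head(default_roi_labels())
#' @export
default_roi_labels <- function() {
  c(
    "Left-Cerebellum-Cortex", "Left-Thalamus-Proper", "Left-Caudate",
    "Left-Putamen", "Left-Pallidum", "Left-Hippocampus", "Left-Amygdala",
    "Left-Accumbens-area",
    "ctx-lh-caudalanteriorcingulate", "ctx-lh-caudalmiddlefrontal",
    "ctx-lh-cuneus", "ctx-lh-entorhinal", "ctx-lh-inferiorparietal",
    "ctx-lh-inferiortemporal", "ctx-lh-lateralorbitofrontal",
    "ctx-lh-medialorbitofrontal", "ctx-lh-middletemporal",
    "ctx-lh-parahippocampal", "ctx-lh-paracentral", "ctx-lh-postcentral",
    "ctx-lh-posteriorcingulate", "ctx-lh-precentral", "ctx-lh-precuneus",
    "ctx-lh-rostralanteriorcingulate", "ctx-lh-rostralmiddlefrontal",
    "ctx-lh-superiorfrontal", "ctx-lh-superiorparietal",
    "ctx-lh-superiortemporal", "ctx-lh-insula",
    "Right-Cerebellum-Cortex", "Right-Thalamus-Proper", "Right-Caudate",
    "Right-Putamen", "Right-Pallidum", "Right-Hippocampus", "Right-Amygdala",
    "Right-Accumbens-area",
    "ctx-rh-caudalanteriorcingulate", "ctx-rh-caudalmiddlefrontal",
    "ctx-rh-cuneus", "ctx-rh-entorhinal", "ctx-rh-inferiorparietal",
    "ctx-rh-inferiortemporal", "ctx-rh-lateralorbitofrontal",
    "ctx-rh-medialorbitofrontal", "ctx-rh-middletemporal",
    "ctx-rh-parahippocampal", "ctx-rh-paracentral", "ctx-rh-postcentral",
    "ctx-rh-posteriorcingulate", "ctx-rh-precentral", "ctx-rh-precuneus",
    "ctx-rh-rostralanteriorcingulate", "ctx-rh-rostralmiddlefrontal",
    "ctx-rh-superiorfrontal", "ctx-rh-superiorparietal",
    "ctx-rh-superiortemporal", "ctx-rh-insula"
  )
}
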