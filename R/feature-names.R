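#' Feature and region rosters
#'
#' Frozen name lists for the Desikan-Killiany-based feature space: 22
#' subcortical/ventricular/callosal volumes (SV), 68 cortical thicknesses
#' (CT), brain parenchymal volume (BPV), 5 diffusion summaries (MS), and the
#' 82 connectome node labels (84-region atlas minus the two cerebellar
#' cortices). Column order is frozen so feature tables are column-stable
#' across runs.
#'
#' @name feature_names
NULL

# 34 cortical parcels per hemisphere (Desikan-Killiany)
.dk_cortical <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
  "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
  "lateralorbitofrontal", "lingual", "medialorbitofrontal", "middletemporal",
  "paracentral", "parahippocampal", "parsopercularis", "parsorbitalis",
  "parstriangularis", "pericalcarine", "postcentral", "posteriorcingulate",
  "precentral", "precuneus", "rostralanteriorcingulate",
  "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
  "superiortemporal", "supramarginal", "temporalpole", "transversetemporal"
)

.deep_gm <- c("Thalamus", "Caudate", "Putamen", "Pallidum", "Hippocampus",
              "Amygdala", "Accumbens-area")

#' @rdname feature_names
#' @return `sv_feature_names()`: character vector of the 22 volumetric
#'   feature names.
#' @export
sv_feature_names <- function() {
  c(paste0("Left-", .deep_gm), paste0("Right-", .deep_gm),
    "Left-Lateral-Ventricle", "Right-Lateral-Ventricle", "3rd-Ventricle",
    "CC_Posterior", "CC_Mid_Posterior", "CC_Central", "CC_Mid_Anterior",
    "CC_Anterior")
}

#' @rdname feature_names
#' @return `ct_feature_names()`: character vector of the 68 cortical
#'   thickness feature names (`ctx-lh-*`, `ctx-rh-*`).
#' @export
ct_feature_names <- function() {
  c(paste0("ctx-lh-", .dk_cortical), paste0("ctx-rh-", .dk_cortical))
}

#' @rdname feature_names
#' @return `mo_feature_names()`: the 91 morphometric feature names
#'   (22 SV + 68 CT + BPV).
#' @export
mo_feature_names <- function() {
  c(sv_feature_names(), ct_feature_names(), "BPV")
}

#' @rdname feature_names
#' @return `ms_feature_names()`: the 5 microstructural feature names.
#' @export
ms_feature_names <- function() {
  c("wholebrain-FA", "wholebrain-MD", "Left-Hippocampus-MD",
    "Right-Hippocampus-MD", "skeleton-FA")
}

#' @rdname feature_names
#' @return `connectome_labels()`: the 82 region labels used as connectome
#'   nodes (68 cortical parcels + 14 deep grey-matter structures).
#' @export
connectome_labels <- function() {
  c(ct_feature_names(), paste0("Left-", .deep_gm), paste0("Right-", .deep_gm))
}

.gt_nodal_metrics <- c("CC", "DC", "EC", "CClo", "BC", "NS", "PR")

.gt_global_metrics <- c(
  "density", "modularity", "assortativity", "transitivity",
  "global_efficiency", "CPL", "diameter", "SW", "DegEnt", "SpecRad",
  "avgDeg", "avgCC", "avgBC", "avgEC", "avgCClo", "avgNS", "avgPR"
)

#' @rdname feature_names
#' @param labels node labels of the graph (defaults to the 82-region roster)
#' @return `gt_feature_names()`: the frozen graph-metric feature name order,
#'   `"<metric>_<region>"` for the 7 nodal metrics then the 17 globals.
#' @export
gt_feature_names <- function(labels = connectome_labels()) {
  nodal <- as.vector(vapply(.gt_nodal_metrics,
                            function(m) paste0(m, "_", labels),
                            character(length(labels))))
  c(nodal, .gt_global_metrics)
}

#' Classify a feature name into its feature set
#'
#' Maps each column name of an assembled feature table to one of the tagged
#' sets: `MO-SV`, `MO-CT`, `MO-other`, `MS`, `GT-local`, `GT-global`,
#' `ABETA`. Names are resolved against the frozen rosters, so tags survive
#' any reordering or subsetting of columns.
#'
#' @param features character vector of feature names
#' @return tibble with columns `feature` and `set`
#' @export
feature_dictionary <- function(features) {
  gt_local <- gt_feature_names()[seq_len(7 * 82)]
  set <- dplyr::case_when(
    features %in% sv_feature_names() ~ "MO-SV",
    features %in% ct_feature_names() ~ "MO-CT",
    features == "BPV" ~ "MO-other",
    features %in% ms_feature_names() ~ "MS",
    features %in% gt_local ~ "GT-local",
    features %in% .gt_global_metrics ~ "GT-global",
    features == "abeta_status" ~ "ABETA",
    TRUE ~ NA_character_
  )
  tibble::tibble(feature = features, set = set)
}
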