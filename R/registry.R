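#' Region registry for the 70-region Desikan-based tau-PET vocabulary
#'
#' Builds the region vocabulary used throughout the pipeline: the 34 bilateral
#' cortical regions of the Desikan atlas plus the two amygdalae (70 regions in
#' total), each tagged with its hemisphere, its Braak stage and whether it
#' belongs to the temporal meta-ROI. The hippocampus (Braak II) is excluded
#' because of known off-target binding of the flortaucipir tracer in the
#' choroid plexus; the Braak precedence chain used downstream is therefore
#' I < III < IV < V < VI.
#'
#' The default stage map follows the flortaucipir staging scheme used in the
#' in-vivo staging literature (Braak I = entorhinal; III = parahippocampal,
#' fusiform, lingual, amygdala; IV = limbic/temporal; V = association
#' neocortex; VI = primary sensorimotor/visual). A different assignment can be
#' supplied as a JSON file mapping base region name to stage label.
#'
#' @param stage_map Optional path to a JSON file mapping base region names
#'   (e.g. \code{"entorhinal"}) to stage labels in
#'   \code{c("I","III","IV","V","VI","none")}. Unmapped regions get
#'   \code{"none"}.
#' @return A data.frame of class \code{region_registry} with columns
#'   \code{region_id}, \code{base_region}, \code{hemisphere},
#'   \code{braak_stage}, \code{in_meta_roi}; one row per region, 70 rows.
#' @examples
#' reg <- region_registry()
#' nrow(reg)                      # 70
#' table(reg$braak_stage)
#' sum(reg$in_meta_roi)           # 12
#' @export
region_registry <- function(stage_map = NULL) {
  cortical <- c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal", "middletemporal",
    "paracentral", "parahippocampal", "parsopercularis", "parsorbitalis",
    "parstriangularis", "pericalcarine", "postcentral", "posteriorcingulate",
    "precentral", "precuneus", "rostralanteriorcingulate",
    "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
    "superiortemporal", "supramarginal", "temporalpole", "transversetemporal")
  stopifnot(length(cortical) == 34L)
  base <- c(cortical, "amygdala")

  stages <- default_stage_map()
  if (!is.null(stage_map)) {
    user <- jsonlite::read_json(stage_map, simplifyVector = TRUE)
    bad <- setdiff(names(user), base)
    if (length(bad))
      stop("stage map names unknown regions: ", paste(bad, collapse = ", "))
    ok <- c("I", "III", "IV", "V", "VI", "none")
    if (!all(unlist(user) %in% ok))
      stop("stage labels must be one of ", paste(ok, collapse = ", "))
    stages[names(user)] <- unlist(user)
  }

  meta_roi <- c("entorhinal", "parahippocampal", "inferiortemporal",
                "middletemporal", "fusiform", "amygdala")

  reg <- data.frame(
    base_region = rep(base, each = 2L),
    hemisphere  = rep(c("left", "right"), times = length(base)),
    stringsAsFactors = FALSE)
  reg$region_id   <- paste(reg$base_region, reg$hemisphere, sep = "_")
  reg$braak_stage <- unname(stages[reg$base_region])
  reg$braak_stage[is.na(reg$braak_stage)] <- "none"
  reg$in_meta_roi <- reg$base_region %in% meta_roi
  reg <- reg[, c("region_id", "base_region", "hemisphere", "braak_stage",
                 "in_meta_roi")]
  stopifnot(nrow(reg) == 70L, !anyDuplicated(reg$region_id))
  class(reg) <- c("region_registry", "data.frame")
  reg
}

# flortaucipir in-vivo staging scheme (hippocampus/Braak II excluded)
default_stage_map <- function() {
  c(entorhinal = "I",
    parahippocampal = "III", fusiform = "III", lingual = "III",
    amygdala = "III",
    middletemporal = "IV", caudalanteriorcingulate = "IV",
    rostralanteriorcingulate = "IV", posteriorcingulate = "IV",
    isthmuscingulate = "IV", insula = "IV", inferiortemporal = "IV",
    temporalpole = "IV",
    superiorfrontal = "V", lateralorbitofrontal = "V",
    medialorbitofrontal = "V", frontalpole = "V", caudalmiddlefrontal = "V",
    rostralmiddlefrontal = "V", parsopercularis = "V", parsorbitalis = "V",
    parstriangularis = "V", lateraloccipital = "V", supramarginal = "V",
    inferiorparietal = "V", superiortemporal = "V", superiorparietal = "V",
    precuneus = "V", bankssts = "V", transversetemporal = "V",
    pericalcarine = "VI", postcentral = "VI", cuneus = "VI",
    precentral = "VI", paracentral = "VI")
}

#' Braak stage labels in precedence order
#'
#' Stage II (hippocampus) is excluded from the analysis chain, so the
#' precedence used for conformance is I < III < IV < V < VI.
#' @return Character vector \code{c("I","III","IV","V","VI")}.
#' @export
braak_stage_order <- function() c("I", "III", "IV", "V", "VI")

#' Normalize region identifiers to the registry dialect
#'
#' Accepts FreeSurfer-style names (\code{"ctx-lh-entorhinal"},
#' \code{"ctx_rh_fusiform"}, \code{"Left-Amygdala"}) and plain names
#' (\code{"entorhinal_left"}, \code{"ENTORHINAL_LH"}) and maps them onto the
#' canonical \code{<base>_<left|right>} identifiers. Unrecognized names are
#' returned unchanged (the caller validates against the registry).
#'
#' @param x Character vector of region names.
#' @return Character vector of canonical region ids.
#' @export
normalize_region_id <- function(x) {
  y <- tolower(trimws(x))
  y <- gsub("-", "_", y, fixed = TRUE)
  y <- sub("^ctx_", "", y)
  # leading hemisphere markers: lh_foo, left_foo
  y <- sub("^(lh|left)_(.+)$", "\\2_left", y)
  y <- sub("^(rh|right)_(.+)$", "\\2_right", y)
  # trailing abbreviations: foo_lh, foo_l
  y <- sub("_(lh|l)$", "_left", y)
  y <- sub("_(rh|r)$", "_right", y)
  y
}

#' Member regions of a Braak stage or the temporal meta-ROI
#'
#' @param registry A \code{region_registry}.
#' @param stage One of \code{"I"}, \code{"III"}, \code{"IV"}, \code{"V"},
#'   \code{"VI"}, or \code{"meta_roi"}.
#' @return Character vector of region ids.
#' @export
stage_members <- function(registry, stage) {
  if (identical(stage, "meta_roi"))
    return(registry$region_id[registry$in_meta_roi])
  if (!stage %in% braak_stage_order())
    stop("unknown stage: ", stage)
  registry$region_id[registry$braak_stage == stage]
}
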