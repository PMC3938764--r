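# Feature catalogs: 29 instantaneous per-CMAC features and 88 single-cell
# features (87 organizational + Instantaneous Cell Speed). Class vocabulary:
# Cell Dynamics, Cell Morphology, CMAC Dynamics, CMAC Intensity,
# CMAC Localization, CMAC Morphology, Colocalization.

#' Instantaneous CMAC feature catalog
#'
#' Manifest of the 29 features computed per CMAC per frame: morphology (area,
#' axes, form factor), dynamics (displacement, sliding speed, lifetime and
#' per-frame changes), background-corrected channel intensities
#' (EGFP-Paxillin marks CMACs, RubyRed-LifeAct marks F-actin), localization
#' relative to the parent cell, and intra-CMAC channel colocalization.
#'
#' @return A data frame with columns \code{name}, \code{class}, \code{units}
#'   and \code{description}, one row per CMAC feature (29 rows).
#' @seealso [cell_feature_catalog()]
#' @export
#' @examples
#' nrow(cmac_feature_catalog())  # 29
cmac_feature_catalog <- function() {
  def <- function(name, class, units, description)
    data.frame(name = name, class = class, units = units,
               description = description, stringsAsFactors = FALSE)
  rbind(
    def("CMAC Area", "CMAC Morphology", "um2", "Segmented CMAC area"),
    def("CMAC Major Axis", "CMAC Morphology", "um", "Fitted-ellipse major axis"),
    def("CMAC Minor Axis", "CMAC Morphology", "um", "Fitted-ellipse minor axis"),
    def("CMAC Axis Ratio", "CMAC Morphology", "ratio", "Major/minor axis ratio"),
    def("CMAC Eccentricity", "CMAC Morphology", "ratio",
        "Ellipse eccentricity sqrt(1 - (minor/major)^2)"),
    def("CMAC Form Factor", "CMAC Morphology", "ratio",
        "4*Area / (pi * Major * Minor); 1 for a perfect ellipse"),
    def("CMAC Displacement", "CMAC Dynamics", "um",
        "Centroid displacement since previous frame"),
    def("CMAC Sliding Speed", "CMAC Dynamics", "um/min",
        "Displacement divided by the frame interval"),
    def("CMAC Cumulative Displacement", "CMAC Dynamics", "um",
        "Path length travelled since CMAC birth"),
    def("CMAC Lifetime to Date", "CMAC Dynamics", "min",
        "Time elapsed since first observation of this CMAC"),
    def("CMAC Lifetime", "CMAC Dynamics", "min",
        "Total observed lifetime of the CMAC track; missing when censored"),
    def("CMAC Age Fraction", "CMAC Dynamics", "ratio",
        "Lifetime to date divided by total lifetime"),
    def("Change in CMAC Total EGFP-Paxillin Intensity", "CMAC Dynamics", "a.u.",
        "Net change in corrected total EGFP-Paxillin vs previous frame"),
    def("Change in CMAC Total RubyRed-LifeAct Intensity", "CMAC Dynamics", "a.u.",
        "Net change in corrected total RubyRed-LifeAct vs previous frame"),
    def("Change in CMAC Area", "CMAC Dynamics", "um2",
        "Net change in area vs previous frame"),
    def("CMAC Mean EGFP-Paxillin Intensity", "CMAC Intensity", "a.u.",
        "Background-corrected mean EGFP-Paxillin intensity"),
    def("CMAC Total EGFP-Paxillin Intensity", "CMAC Intensity", "a.u.",
        "Corrected mean EGFP-Paxillin intensity times area"),
    def("CMAC Mean RubyRed-LifeAct Intensity", "CMAC Intensity", "a.u.",
        "Background-corrected mean RubyRed-LifeAct intensity"),
    def("CMAC Total RubyRed-LifeAct Intensity", "CMAC Intensity", "a.u.",
        "Corrected mean RubyRed-LifeAct intensity times area"),
    def("CMAC Raw Mean EGFP-Paxillin Intensity", "CMAC Intensity", "a.u.",
        "Mean EGFP-Paxillin pixel intensity before background correction"),
    def("CMAC Raw Mean RubyRed-LifeAct Intensity", "CMAC Intensity", "a.u.",
        "Mean RubyRed-LifeAct pixel intensity before background correction"),
    def("CMAC EGFP-Paxillin Background Intensity", "CMAC Intensity", "a.u.",
        "Local background estimate, EGFP-Paxillin channel (1 um annulus)"),
    def("CMAC RubyRed-LifeAct Background Intensity", "CMAC Intensity", "a.u.",
        "Local background estimate, RubyRed-LifeAct channel (1 um annulus)"),
    def("CMAC Paxillin-LifeAct Mean Intensity Ratio", "CMAC Intensity", "ratio",
        "Corrected mean EGFP-Paxillin over corrected mean RubyRed-LifeAct"),
    def("CMAC Paxillin-LifeAct Total Intensity Ratio", "CMAC Intensity", "ratio",
        "Corrected total EGFP-Paxillin over corrected total RubyRed-LifeAct"),
    def("Standardized CMAC Distance to Cell Edge", "CMAC Localization", "ratio",
        "d_edge / (d_edge + d_center): 0 at the cell edge, 1 at the center of area"),
    def("CMAC Distance to Cell Edge", "CMAC Localization", "um",
        "Distance from CMAC centroid to the nearest cell boundary point"),
    def("CMAC Distance to Cell Center", "CMAC Localization", "um",
        "Distance from CMAC centroid to the cell center of area"),
    def("EGFP-Paxillin - RubyRed-LifeAct Colocalization per CMAC",
        "Colocalization", "r",
        "Pearson correlation of paired per-pixel channel intensities within the CMAC")
  )
}

# Base CMAC features crossed with the per-cell aggregators to complete the
# single-cell manifest (16 bases x 5 aggregators = 80 aggregated features).
.aggregation_bases <- function() {
  c("CMAC Area", "CMAC Axis Ratio", "CMAC Form Factor",
    "CMAC Displacement", "CMAC Sliding Speed", "CMAC Lifetime",
    "Change in CMAC Total EGFP-Paxillin Intensity",
    "Change in CMAC Total RubyRed-LifeAct Intensity",
    "CMAC Mean EGFP-Paxillin Intensity",
    "CMAC Total EGFP-Paxillin Intensity",
    "CMAC Mean RubyRed-LifeAct Intensity",
    "CMAC Total RubyRed-LifeAct Intensity",
    "CMAC Paxillin-LifeAct Mean Intensity Ratio",
    "Standardized CMAC Distance to Cell Edge",
    "CMAC Distance to Cell Center",
    "EGFP-Paxillin - RubyRed-LifeAct Colocalization per CMAC")
}

.aggregators <- function() c("Mean", "Median", "Sum", "SD", "IDR")

#' Single-cell feature catalog
#'
#' Manifest of the 88 per-cell per-frame features: 6 cell-morphology
#' features, Number of CMACs per Cell, 80 aggregations of instantaneous CMAC
#' features over each cell's CMAC population (Mean, Median, Sum, SD and IDR,
#' the interdecile range q90 - q10, of 16 base CMAC features), and the single
#' behavioral feature, Instantaneous Cell Speed. The 87 non-speed features
#' are the organizational features.
#'
#' @return A data frame with columns \code{name}, \code{class},
#'   \code{scale} (\code{"cell"} or \code{"cmac_population"}),
#'   \code{aggregator}, \code{base} (the aggregated CMAC feature, \code{NA}
#'   for cell-scale features), \code{role} (\code{"organizational"} or
#'   \code{"behavioral"}) and \code{units}; 88 rows.
#' @export
#' @examples
#' cat88 <- cell_feature_catalog()
#' table(cat88$role)  # 87 organizational, 1 behavioral
cell_feature_catalog <- function() {
  cmac <- cmac_feature_catalog()
  cellrow <- function(name, class, units)
    data.frame(name = name, class = class, scale = "cell",
               aggregator = NA_character_, base = NA_character_,
               role = "organizational", units = units,
               stringsAsFactors = FALSE)
  cell_scale <- rbind(
    cellrow("Cell Area", "Cell Morphology", "um2"),
    cellrow("Cell Perimeter", "Cell Morphology", "um"),
    cellrow("Cell Compactness", "Cell Morphology", "ratio"),
    cellrow("Cell Major Axis", "Cell Morphology", "um"),
    cellrow("Cell Minor Axis", "Cell Morphology", "um"),
    cellrow("Cell Aspect Ratio", "Cell Morphology", "ratio"),
    cellrow("Number of CMACs per Cell", "CMAC Dynamics", "count")
  )
  bases <- .aggregation_bases()
  aggs <- .aggregators()
  agg_rows <- do.call(rbind, lapply(bases, function(b) {
    cls <- cmac$class[match(b, cmac$name)]
    u <- cmac$units[match(b, cmac$name)]
    data.frame(name = sprintf("%s [%s] per Cell", aggs, b),
               class = cls, scale = "cmac_population", aggregator = aggs,
               base = b, role = "organizational", units = u,
               stringsAsFactors = FALSE)
  }))
  ics <- data.frame(name = "Instantaneous Cell Speed", class = "Cell Dynamics",
                    scale = "cell", aggregator = NA_character_,
                    base = NA_character_, role = "behavioral",
                    units = "um/min", stringsAsFactors = FALSE)
  out <- rbind(cell_scale, agg_rows, ics)
  rownames(out) <- NULL
  out
}

#' Names of the organizational features
#'
#' @return Character vector of the 87 organizational feature names.
#' @export
organizational_features <- function() {
  cat88 <- cell_feature_catalog()
  cat88$name[cat88$role == "organizational"]
}

#' Write the feature manifests as YAML
#'
#' Serializes both catalogs to a single YAML manifest, the interchange form
#' used by the pipeline configuration.
#'
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog_yaml <- function(path) {
  obj <- list(cell_features = cell_feature_catalog(),
              cmac_features = cmac_feature_catalog())
  obj <- lapply(obj, function(d) lapply(seq_len(nrow(d)),
                                        function(i) as.list(d[i, ])))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a YAML feature manifest
#'
#' @param path Manifest path as written by [write_catalog_yaml()].
#' @return List with data frames `cell_features` and `cmac_features`.
#' @export
read_catalog_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  lapply(obj, function(rows)
    do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE))))
}
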