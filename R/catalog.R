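#' The 120-feature radiomic catalog
#'
#' Radiomic pipelines for CT lymph-node analysis extract 120 quantitative
#' descriptors per segmented lesion, grouped into eight classes: first-order
#' intensity statistics, 3D shape, 2D shape, and five texture-matrix families
#' (GLCM, GLRLM, GLSZM, NGTDM, GLDM). This function returns the canonical
#' catalog: one row per feature with its name, class and index.
#'
#' Canonical order is classes in the order
#' `first_order, shape_3d, shape_2d, glcm, glrlm, glszm, ngtdm, gldm`,
#' features alphabetical within each class, so that feature indices are
#' reproducible across runs and machines.
#'
#' @return A `data.frame` with columns `name` (unique feature identifier,
#'   `<extractor class tag>_<feature>`), `feature_class` (factor with the
#'   eight class levels) and `index` (1..120).
#' @examples
#' cat120 <- feature_catalog()
#' nrow(cat120)              # 120
#' table(cat120$feature_class)
#' @export
feature_catalog <- function() {
  classes <- list(
    first_order = c(
      "10Percentile", "90Percentile", "Energy", "Entropy",
      "InterquartileRange", "Kurtosis", "Maximum", "Mean",
      "MeanAbsoluteDeviation", "Median", "Minimum", "Range",
      "RobustMeanAbsoluteDeviation", "RootMeanSquared", "Skewness",
      "StandardDeviation", "TotalEnergy", "Uniformity", "Variance"
    ),
    shape_3d = c(
      "Compactness1", "Compactness2", "Elongation", "Flatness",
      "LeastAxisLength", "MajorAxisLength", "Maximum2DDiameterColumn",
      "Maximum2DDiameterRow", "Maximum2DDiameterSlice", "Maximum3DDiameter",
      "MeshVolume", "MinorAxisLength", "Sphericity", "SurfaceArea",
      "SurfaceVolumeRatio", "VoxelVolume"
    ),
    shape_2d = c(
      "Elongation", "MajorAxisLength", "MaximumDiameter", "MeshSurface",
      "MinorAxisLength", "Perimeter", "PerimeterSurfaceRatio",
      "PixelSurface", "SphericalDisproportion", "Sphericity"
    ),
    glcm = c(
      "Autocorrelation", "ClusterProminence", "ClusterShade",
      "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
      "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn", "Idn",
      "Imc1", "Imc2", "InverseVariance", "JointAverage", "JointEnergy",
      "JointEntropy", "MCC", "MaximumProbability", "SumAverage",
      "SumEntropy", "SumSquares"
    ),
    glrlm = c(
      "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
      "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
      "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
      "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
      "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
      "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
      "ShortRunLowGrayLevelEmphasis"
    ),
    glszm = c(
      "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
      "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
      "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
      "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
      "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
      "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
      "ZoneEntropy", "ZonePercentage", "ZoneVariance"
    ),
    ngtdm = c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength"),
    gldm = c(
      "DependenceEntropy", "DependenceNonUniformity",
      "DependenceNonUniformityNormalized", "DependenceVariance",
      "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
      "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
      "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
      "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
      "SmallDependenceLowGrayLevelEmphasis"
    )
  )
  tags <- c(
    first_order = "firstorder", shape_3d = "shape", shape_2d = "shape2D",
    glcm = "glcm", glrlm = "glrlm", glszm = "glszm", ngtdm = "ngtdm",
    gldm = "gldm"
  )
  rows <- lapply(names(classes), function(cl) {
    nm <- sort(classes[[cl]])
    data.frame(
      name = paste0("original_", tags[[cl]], "_", nm),
      feature_class = cl,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$feature_class <- factor(out$feature_class, levels = names(classes))
  out$index <- seq_len(nrow(out))
  rownames(out) <- NULL
  stopifnot(nrow(out) == 120L, !anyDuplicated(out$name))
  out
}

#' Class cardinalities of the radiomic catalog
#'
#' @return Named integer vector of per-class feature counts in canonical
#'   class order; sums to 120.
#' @export
catalog_class_counts <- function() {
  cat120 <- feature_catalog()
  vapply(split(cat120$name, cat120$feature_class), length, integer(1))
}

# Coarse Type grouping used in selection-frequency reports:
# shape / intensity / texture.
catalog_type_group <- function(feature_class) {
  cl <- as.character(feature_class)
  ifelse(cl %in% c("shape_3d", "shape_2d"), "shape",
    ifelse(cl == "first_order", "intensity", "texture")
  )
}
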