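#' Count model parameters
#'
#' @param object A model object.
#' @return Exact integer-valued parameter count.
#' @export
setGeneric("countParameters", function(object) standardGeneric("countParameters"))

#' Extract a backbone feature map
#'
#' @param object A feature extractor.
#' @param images Image array (batch or single image).
#' @export
setGeneric("featureMap", function(object, images) standardGeneric("featureMap"))

#' Node-feature matrix accessor
#'
#' @param object An object holding graph-node features.
#' @export
setGeneric("nodeValues", function(object) standardGeneric("nodeValues"))

#' @rdname nodeValues
#' @export
setMethod("nodeValues", "NodeFeatures", function(object) object@values)

#' Normalized adjacency accessor
#'
#' @param object A [NormalizedAdjacency-class].
#' @export
setGeneric("adjacencyMatrix", function(object) standardGeneric("adjacencyMatrix"))

#' @rdname adjacencyMatrix
#' @export
setMethod("adjacencyMatrix", "NormalizedAdjacency", function(object) object@ahat)

#' Confusion-matrix counts accessor
#'
#' @param object A [ConfusionMatrix-class].
#' @export
setGeneric("confusionCounts", function(object) standardGeneric("confusionCounts"))

#' @rdname confusionCounts
#' @export
setMethod("confusionCounts", "ConfusionMatrix", function(object) object@counts)

setMethod("show", "Backbone", function(object) {
  cat("Backbone '", object@name, "': C = ", object@channels,
      ", parameters = ", format(countParameters(object), big.mark = ","),
      if (object@includeTop) " (with classification top)" else "", "\n",
      sep = "")
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec: ", object@nClasses, " classes x ",
      object@imagesPerClass, " images, ", object@imageSize, "px, noise sd ",
      signif(object@noiseSd, 3), ", seed ", object@seed, "\n", sep = "")
})

setMethod("show", "DatasetIndex", function(object) {
  cat("DatasetIndex: ", nrow(object@records), " images in ",
      length(object@classNames), " classes\n", sep = "")
  if (length(object@skipped))
    cat("  skipped (unreadable): ", length(object@skipped), "\n", sep = "")
})

setMethod("show", "SplitPlan", function(object) {
  cat("SplitPlan: ", length(object@trainIds), " train / ",
      length(object@testIds), " test (seed ", object@seed, ")\n", sep = "")
  if (length(object@folds))
    cat("  ", length(object@folds), " stratified folds over the training pool\n",
        sep = "")
})

setMethod("show", "NormalizedAdjacency", function(object) {
  cat("NormalizedAdjacency: ", nrow(object@ahat), " nodes, ",
      object@topology, " topology\n", sep = "")
})

setMethod("show", "NodeFeatures", function(object) {
  cat("NodeFeatures: P = ", nrow(object@values), " nodes x C = ",
      ncol(object@values), " channels\n", sep = "")
})

setMethod("show", "PNDNet", function(object) {
  cfg <- object@config
  cat("PNDNet: backbone '", object@backbone@name, "', ",
      nrow(object@adjacency@ahat), " graph nodes, ",
      length(object@gcn), " GCN layer(s), ", cfg$numClasses, " classes\n",
      sep = "")
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (rows = truth):\n")
  m <- object@counts
  dimnames(m) <- list(object@classNames, object@classNames)
  print(m)
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: top-1 %.4f, top-3 %.4f, macro F1 %.4f\n",
              object@top1, object@top3, object@macro[["f1"]]))
})
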