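#' @import methods
NULL

#' Backbone feature extractor
#'
#' Wraps a convolutional architecture as a feature extractor: either one of
#' the four registered standard networks (encoded layer by layer, used for
#' exact parameter accounting and shape-checked feature extraction), or the
#' tiny three-block test backbone whose forward and backward passes drive
#' training.
#'
#' @slot name Architecture name.
#' @slot layers Layer graph (empty for the tiny backbone).
#' @slot params Materialized weights.
#' @slot channels Output channel width C of the final feature map.
#' @slot featureLayer Identifier of the final convolutional layer.
#' @slot includeTop Whether the ImageNet classification head is attached.
#' @slot seed Seed used for weight initialization.
#' @export
setClass("Backbone", representation(
  name = "character", layers = "list", params = "list",
  channels = "integer", featureLayer = "character",
  includeTop = "logical", seed = "integer"
))

setValidity("Backbone", function(object) {
  if (length(object@channels) != 1L || object@channels <= 0L)
    return("channels must be a positive integer")
  TRUE
})

#' Synthetic leaf-image dataset specification
#'
#' Parameters of the deterministic synthetic image generator.  Each class is
#' rendered as an elliptical "leaf" with a class-specific base hue carrying a
#' class-specific count and colour of lesion blobs on a textured background,
#' plus additive Gaussian pixel noise, so that classes are separable by simple
#' colour statistics while still exercising every pipeline stage.
#'
#' @slot nClasses Number of classes (>= 2).
#' @slot imagesPerClass Images generated per class.
#' @slot imageSize Square image side in pixels (>= 64).
#' @slot noiseSd Additive Gaussian pixel noise standard deviation on the
#'   \[0, 1\] intensity scale (default 8/255).
#' @slot seed Integer seed; identical spec + seed gives bit-identical images.
#' @export
setClass("SyntheticSpec", representation(
  nClasses = "integer", imagesPerClass = "integer", imageSize = "integer",
  noiseSd = "numeric", seed = "integer"
))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@nClasses < 2L) msg <- c(msg, "nClasses must be >= 2")
  if (object@imagesPerClass < 1L) msg <- c(msg, "imagesPerClass must be >= 1")
  if (object@imageSize < 64L) msg <- c(msg, "imageSize must be >= 64")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Index of a class-per-folder image dataset
#'
#' @slot records data.frame with columns `path` and `classId` (0-based dense
#'   class identifiers).
#' @slot classNames Ordered class labels (lexicographic over folder names).
#' @slot skipped Paths that could not be read, reported rather than silently
#'   dropped.
#' @export
setClass("DatasetIndex", representation(
  records = "data.frame", classNames = "character", skipped = "character"
))

setValidity("DatasetIndex", function(object) {
  if (!all(c("path", "classId") %in% names(object@records)))
    return("records must have 'path' and 'classId' columns")
  ids <- object@records$classId
  if (length(ids) && (min(ids) < 0L || max(ids) >= length(object@classNames)))
    return("classId out of range")
  TRUE
})

#' Train/test split and cross-validation plan
#'
#' Index sets (1-based into the records of the [DatasetIndex-class] the plan
#' was built from) for a stratified hold-out split, optionally refined into k
#' stratified cross-validation folds over the training pool.  The test set is
#' identical across folds and the fold validation sets partition the training
#' pool exactly.
#'
#' @slot trainIds,testIds Disjoint index vectors.
#' @slot folds List of `list(train, val)` index pairs (possibly empty).
#' @slot labels Class id per index, retained for stratification.
#' @slot seed Seed the plan was drawn with, recorded for exact replay.
#' @export
setClass("SplitPlan", representation(
  trainIds = "integer", testIds = "integer", folds = "list",
  labels = "integer", seed = "integer"
))

setValidity("SplitPlan", function(object) {
  if (length(intersect(object@trainIds, object@testIds)))
    return("train and test ids must be disjoint")
  for (f in object@folds) {
    if (!setequal(union(f$train, f$val), object@trainIds) ||
        length(intersect(f$train, f$val)))
      return("each fold must partition the training pool")
  }
  TRUE
})

#' Region pooling and spatial pyramid configuration
#'
#' @slot upsampleSize Target (square) spatial size H the backbone map is
#'   bilinearly upsampled to.
#' @slot grid Region grid side g; the map is cut into g*g non-overlapping
#'   tiles, each averaged to one channel vector.
#' @slot levels Two pyramid bin resolutions `c(i, j)`; the node count is
#'   P = i^2 + j^2.
#' @slot poolMode `"average"` or `"max"` pyramid pooling.
#' @export
setClass("RegionConfig", representation(
  upsampleSize = "integer", grid = "integer", levels = "integer",
  poolMode = "character"
))

setValidity("RegionConfig", function(object) {
  msg <- character()
  if (object@upsampleSize %% object@grid != 0L)
    msg <- c(msg, "upsampleSize must be divisible by grid")
  if (length(object@levels) != 2L || any(object@levels < 1L))
    msg <- c(msg, "levels must be two integers >= 1")
  if (any(object@levels > object@grid))
    msg <- c(msg, "pyramid levels cannot exceed the region grid")
  if (!object@poolMode %in% c("average", "max"))
    msg <- c(msg, "poolMode must be 'average' or 'max'")
  if (length(msg)) msg else TRUE
})

#' Graph-node feature matrix
#'
#' The P x C matrix of spatial-pyramid-pooled region descriptors that forms
#' the input G^(0) (and the output) of the graph convolutional module.
#'
#' @slot values Numeric P x C matrix, finite.
#' @export
setClass("NodeFeatures", representation(values = "matrix"))

setValidity("NodeFeatures", function(object) {
  if (!all(is.finite(object@values))) return("node features must be finite")
  TRUE
})

#' Symmetrically normalized adjacency
#'
#' Holds the binary adjacency A of the node graph together with its
#' renormalized propagation operator
#' \eqn{\hat{A} = \tilde{D}^{-1/2}(A + I)\tilde{D}^{-1/2}}.  For the complete
#' graph used by the network every entry of \eqn{\hat{A}} equals 1/P.
#'
#' @slot ahat Normalized P x P operator.
#' @slot a Binary adjacency without self-loops.
#' @slot topology Topology name (`"complete"`, or test topologies).
#' @export
setClass("NormalizedAdjacency", representation(
  ahat = "matrix", a = "matrix", topology = "character"
))

setValidity("NormalizedAdjacency", function(object) {
  if (!isSymmetric(unname(object@ahat), tol = 1e-12))
    return("normalized adjacency must be symmetric")
  if (any(object@ahat < -1e-12)) return("entries must be nonnegative")
  TRUE
})

#' Assembled network
#'
#' The full model: tiny (or other) backbone, the precomputed linear operator
#' taking a flattened backbone map to node features (upsample -> region grid
#' -> spatial pyramid), the graph convolutional parameters, and the
#' layer-normalized dropout + softmax head.
#'
#' @slot config Model configuration list (see [modelConfig()]).
#' @slot backbone A [Backbone-class].
#' @slot pipeline Sparse P x (hw) matrix mapping flattened feature maps to
#'   node features (identity-like variants under ablation switches).
#' @slot adjacency A [NormalizedAdjacency-class].
#' @slot gcn List of per-layer `list(W, b)` graph-convolution weights.
#' @slot head List with layer/batch-norm parameters and the dense softmax
#'   layer weights.
#' @slot seed Initialization seed.
#' @export
setClass("PNDNet", representation(
  config = "list", backbone = "Backbone", pipeline = "ANY",
  adjacency = "NormalizedAdjacency", gcn = "list", head = "list",
  seed = "integer"
))

#' Confusion matrix
#'
#' @slot counts Y x Y integer matrix; rows are true classes, columns
#'   predicted.
#' @slot classNames Class labels.
#' @export
setClass("ConfusionMatrix", representation(
  counts = "matrix", classNames = "character"
))

setValidity("ConfusionMatrix", function(object) {
  if (nrow(object@counts) != ncol(object@counts))
    return("counts must be square")
  if (any(object@counts < 0)) return("counts must be nonnegative")
  TRUE
})

#' Classification metrics report
#'
#' @slot top1,top3 Top-k accuracies as fractions in \[0, 1\].
#' @slot perClass data.frame of per-class precision, recall and F1.
#' @slot macro Named numeric vector of unweighted means of the per-class
#'   precision, recall and F1.
#' @slot confusion A [ConfusionMatrix-class].
#' @export
setClass("MetricsReport", representation(
  top1 = "numeric", top3 = "numeric", perClass = "data.frame",
  macro = "numeric", confusion = "ConfusionMatrix"
))

setValidity("MetricsReport", function(object) {
  if (object@top3 < object@top1 - 1e-12)
    return("top3 accuracy cannot be below top1")
  TRUE
})
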