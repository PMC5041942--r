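# Accessor generics. Slot access from user code is discouraged; these are
# the supported surface.

#' Accessors for mirXtalk containers
#'
#' @param object an ExpressionMatrix, GeneSetCollection, PPINetwork,
#'   MirnaPathwayNetwork or CrosstalkNetwork.
#' @return \code{exprValues}: the numeric matrix. \code{featureKind}: the
#'   feature kind string. \code{featureIds}/\code{sampleIds}: identifier
#'   vectors. \code{geneSets}: named list of gene sets.
#'   \code{setDescriptions}: named descriptions. \code{ppiEdges} /
#'   \code{networkEdges} / \code{scoredPairs}: edge data.frames.
#'   \code{networkNodes}: node attribute data.frame.
#' @name accessors
#' @aliases exprValues featureKind featureIds sampleIds geneSets
#'   setDescriptions ppiEdges networkEdges networkNodes scoredPairs
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("featureKind", function(object) standardGeneric("featureKind"))
#' @rdname accessors
#' @export
setGeneric("featureIds", function(object) standardGeneric("featureIds"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("geneSets", function(object) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setGeneric("setDescriptions",
           function(object) standardGeneric("setDescriptions"))
#' @rdname accessors
#' @export
setGeneric("ppiEdges", function(object) standardGeneric("ppiEdges"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setGeneric("scoredPairs", function(object) standardGeneric("scoredPairs"))

#' @rdname accessors
setMethod("exprValues", "ExpressionMatrix", function(object) object@assay)
#' @rdname accessors
setMethod("featureKind", "ExpressionMatrix",
          function(object) object@featureKind)
#' @rdname accessors
setMethod("featureIds", "ExpressionMatrix",
          function(object) rownames(object@assay))
#' @rdname accessors
setMethod("sampleIds", "ExpressionMatrix",
          function(object) colnames(object@assay))

#' @rdname accessors
setMethod("geneSets", "GeneSetCollection", function(object) object@sets)
#' @rdname accessors
setMethod("setDescriptions", "GeneSetCollection",
          function(object) object@description)

#' @rdname accessors
setMethod("ppiEdges", "PPINetwork", function(object) object@edges)

#' @rdname accessors
setMethod("networkEdges", "MirnaPathwayNetwork",
          function(object) object@edges)
#' @rdname accessors
setMethod("networkNodes", "MirnaPathwayNetwork", function(object) {
  mir <- data.frame(
    node_id = names(object@mirnaDirection), side = "miRNA",
    direction = unname(object@mirnaDirection), grade = NA_character_,
    stringsAsFactors = FALSE)
  pw <- data.frame(
    node_id = names(object@pathwayGrade), side = "pathway",
    direction = unname(object@pathwayDirection[names(object@pathwayGrade)]),
    grade = unname(object@pathwayGrade), stringsAsFactors = FALSE)
  rbind(mir, pw)
})

#' @rdname accessors
setMethod("networkEdges", "CrosstalkNetwork", function(object) object@edges)
#' @rdname accessors
setMethod("scoredPairs", "CrosstalkNetwork", function(object) object@pairs)
#' @rdname accessors
setMethod("networkNodes", "CrosstalkNetwork", function(object) object@nodes)
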