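# Central S4 containers. Every class carries a validity method so malformed
# objects fail at construction, not deep inside a pipeline stage.

#' ExpressionMatrix: a feature-by-sample log-scale expression matrix
#'
#' Thin container for a numeric feature x sample matrix together with the
#' kind of feature it holds (\code{"miRNA"} or \code{"gene"}). Expression is
#' assumed already normalized and log-transformed upstream; duplicate probes
#' must have been collapsed (see [readExpressionMatrix()], which averages
#' them).
#'
#' @slot assay numeric matrix, features in rows, samples in columns; row and
#'   column names are the unique feature and sample identifiers.
#' @slot featureKind character scalar, \code{"miRNA"} or \code{"gene"}.
#'
#' @seealso [ExpressionMatrix()], [exprValues()], [featureKind()]
#' @aliases ExpressionMatrix-class
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix",
  representation(assay = "matrix", featureKind = "character"))

setValidity("ExpressionMatrix", function(object) {
  msg <- character(0)
  a <- object@assay
  if (!is.numeric(a))
    msg <- c(msg, "assay must be a numeric matrix")
  if (is.null(rownames(a)) || is.null(colnames(a)))
    msg <- c(msg, "assay must have feature (row) and sample (column) names")
  else {
    if (anyDuplicated(rownames(a)))
      msg <- c(msg, "duplicate feature identifiers")
    if (anyDuplicated(colnames(a)))
      msg <- c(msg, "duplicate sample identifiers")
  }
  if (anyNA(a))
    msg <- c(msg, "assay contains missing values")
  if (length(object@featureKind) != 1L ||
      !object@featureKind %in% c("miRNA", "gene"))
    msg <- c(msg, "featureKind must be \"miRNA\" or \"gene\"")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix with unique row (feature) and column
#'   (sample) names; log-scale expression.
#' @param featureKind \code{"miRNA"} or \code{"gene"}.
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'   dimnames = list(c("miR1", "miR2"), c("S1", "S2", "S3")))
#' ExpressionMatrix(m, "miRNA")
#' @export
ExpressionMatrix <- function(values, featureKind = c("gene", "miRNA")) {
  featureKind <- match.arg(featureKind)
  new("ExpressionMatrix", assay = as.matrix(values), featureKind = featureKind)
}

#' GeneSetCollection: named pathway gene sets
#'
#' Pathway membership as read from a GMT file: a named list of character
#' vectors of gene identifiers plus a parallel description per set.
#'
#' @slot sets named list of character vectors (deduplicated, nonempty).
#' @slot description named character vector, one description per set.
#' @aliases GeneSetCollection-class
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
  representation(sets = "list", description = "character"))

setValidity("GeneSetCollection", function(object) {
  msg <- character(0)
  s <- object@sets
  if (is.null(names(s)) || anyDuplicated(names(s)))
    msg <- c(msg, "sets must have unique names")
  if (!all(vapply(s, function(x) is.character(x) && length(x) > 0L,
                  logical(1))))
    msg <- c(msg, "each set must be a nonempty character vector")
  if (any(vapply(s, anyDuplicated, integer(1)) > 0L))
    msg <- c(msg, "set membership must be deduplicated")
  if (length(object@description) != length(s) ||
      !identical(names(object@description), names(s)))
    msg <- c(msg, "description must parallel the sets")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of gene identifiers.
#' @param description optional named character vector of set descriptions;
#'   defaults to empty strings.
#' @return A [GeneSetCollection-class] object.
#' @export
GeneSetCollection <- function(sets, description = NULL) {
  sets <- lapply(sets, function(x) unique(as.character(x)))
  if (is.null(description))
    description <- setNames(rep("", length(sets)), names(sets))
  new("GeneSetCollection", sets = sets,
      description = description[names(sets)])
}

#' PPINetwork: a simple protein-protein interaction graph
#'
#' Undirected simple graph over gene identifiers, stored as a deduplicated
#' edge table with an optional 0-1000 confidence score per edge (the STRING
#' combined-score convention; the reader applies a >= 900 cutoff by
#' default).
#'
#' @slot edges data.frame with columns \code{gene_a}, \code{gene_b} and
#'   optionally \code{score}; no self-loops, each unordered pair once.
#' @aliases PPINetwork-class
#' @exportClass PPINetwork
setClass("PPINetwork", representation(edges = "data.frame"))

setValidity("PPINetwork", function(object) {
  msg <- character(0)
  e <- object@edges
  if (!all(c("gene_a", "gene_b") %in% names(e)))
    msg <- c(msg, "edges needs gene_a and gene_b columns")
  else {
    if (any(e$gene_a == e$gene_b))
      msg <- c(msg, "self-loops are not allowed")
    key <- paste(pmin(e$gene_a, e$gene_b), pmax(e$gene_a, e$gene_b))
    if (anyDuplicated(key))
      msg <- c(msg, "parallel edges are not allowed")
  }
  if ("score" %in% names(e) &&
      (any(e$score < 0) || any(e$score > 1000)))
    msg <- c(msg, "scores must lie in [0, 1000]")
  if (length(msg)) msg else TRUE
})

#' Construct a PPINetwork
#'
#' Edges are canonicalized to unordered pairs; duplicates collapse to the
#' maximum score.
#'
#' @param edges data.frame with columns \code{gene_a}, \code{gene_b} and
#'   optionally \code{score}.
#' @return A [PPINetwork-class] object.
#' @export
PPINetwork <- function(edges) {
  edges <- as.data.frame(edges)
  if (nrow(edges)) {
    a <- pmin(edges$gene_a, edges$gene_b)
    b <- pmax(edges$gene_a, edges$gene_b)
    edges$gene_a <- a
    edges$gene_b <- b
    edges <- edges[edges$gene_a != edges$gene_b, , drop = FALSE]
    if ("score" %in% names(edges)) {
      o <- order(edges$gene_a, edges$gene_b, -edges$score)
      edges <- edges[o, , drop = FALSE]
    } else {
      edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
    }
    edges <- edges[!duplicated(paste(edges$gene_a, edges$gene_b)), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  }
  new("PPINetwork", edges = edges)
}

#' MirnaPathwayNetwork: the bipartite miRNA-pathway crosstalk network
#'
#' Bipartite network connecting a miRNA to a pathway when the miRNA's
#' inversely correlated target genes are significantly enriched in the
#' pathway (cumulative hypergeometric p below the edge threshold) in at
#' least one grade contrast.
#'
#' @slot edges data.frame with columns \code{mirna_id}, \code{pathway_id},
#'   \code{contrast} and \code{p}; one row per significant
#'   (miRNA, pathway, contrast) relationship.
#' @slot mirnaDirection named character: per-miRNA regulation direction
#'   (\code{"up"}/\code{"down"}; \code{"mixed"} when contrasts disagree).
#' @slot pathwayGrade named character: \code{"III"}, \code{"IV"} or
#'   \code{"both"}, derived from which contrasts contribute edges.
#' @slot pathwayDirection named character: majority direction of the target
#'   genes enriching the pathway (\code{"up"}, \code{"down"} or
#'   \code{"mixed"}).
#' @aliases MirnaPathwayNetwork-class
#' @exportClass MirnaPathwayNetwork
setClass("MirnaPathwayNetwork",
  representation(edges = "data.frame", mirnaDirection = "character",
                 pathwayGrade = "character",
                 pathwayDirection = "character"))

setValidity("MirnaPathwayNetwork", function(object) {
  msg <- character(0)
  e <- object@edges
  need <- c("mirna_id", "pathway_id", "contrast", "p")
  if (!all(need %in% names(e)))
    msg <- c(msg, paste("edges needs columns:", paste(need, collapse = ", ")))
  else if (nrow(e) &&
           anyDuplicated(paste(e$mirna_id, e$pathway_id, e$contrast)))
    msg <- c(msg, "duplicate (miRNA, pathway, contrast) edges")
  if (length(msg)) msg else TRUE
})

#' CrosstalkNetwork: the pathway-pathway crosstalk network
#'
#' Pathway nodes with grade/direction attributes; the \code{pairs} slot
#' keeps every scored pathway pair (crosstalk weight, number of qualifying
#' PPI edges, permutation p), the \code{edges} slot the subset below the
#' significance threshold.
#'
#' @slot pairs data.frame: \code{pathway_i}, \code{pathway_j},
#'   \code{weight}, \code{n_edges}, \code{perm_p} for all scored pairs.
#' @slot edges data.frame: the significant subset of \code{pairs}.
#' @slot nodes data.frame: \code{pathway_id}, \code{grade},
#'   \code{direction}.
#' @slot nPermutations integer, permutation rounds per pair.
#' @aliases CrosstalkNetwork-class
#' @exportClass CrosstalkNetwork
setClass("CrosstalkNetwork",
  representation(pairs = "data.frame", edges = "data.frame",
                 nodes = "data.frame", nPermutations = "integer"))

setValidity("CrosstalkNetwork", function(object) {
  msg <- character(0)
  need <- c("pathway_i", "pathway_j", "weight", "n_edges", "perm_p")
  for (slotname in c("pairs", "edges")) {
    e <- slot(object, slotname)
    if (!all(need %in% names(e)))
      msg <- c(msg, paste(slotname, "needs columns:",
                          paste(need, collapse = ", ")))
  }
  p <- object@pairs
  if (all(need %in% names(p)) && nrow(p)) {
    if (any(p$weight < 0)) msg <- c(msg, "weights must be nonnegative")
    if (any(p$perm_p <= 0 | p$perm_p > 1))
      msg <- c(msg, "perm_p must lie in (0, 1]")
    if (any(p$pathway_i == p$pathway_j))
      msg <- c(msg, "self-pairs are not allowed")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix (%s): %d features x %d samples\n",
              object@featureKind, nrow(object@assay), ncol(object@assay)))
})

setMethod("show", "GeneSetCollection", function(object) {
  sizes <- lengths(object@sets)
  cat(sprintf("GeneSetCollection: %d sets, %d distinct genes\n",
              length(object@sets), length(unique(unlist(object@sets)))))
  if (length(sizes))
    cat(sprintf("  set sizes: %d-%d (median %g)\n",
                min(sizes), max(sizes), stats::median(sizes)))
})

setMethod("show", "PPINetwork", function(object) {
  e <- object@edges
  cat(sprintf("PPINetwork: %d edges over %d genes%s\n", nrow(e),
              length(unique(c(e$gene_a, e$gene_b))),
              if ("score" %in% names(e)) " (scored)" else ""))
})

setMethod("show", "MirnaPathwayNetwork", function(object) {
  e <- object@edges
  cat(sprintf(
    "MirnaPathwayNetwork: %d miRNAs, %d pathways, %d edge records\n",
    length(unique(e$mirna_id)), length(unique(e$pathway_id)), nrow(e)))
})

setMethod("show", "CrosstalkNetwork", function(object) {
  cat(sprintf(
    "CrosstalkNetwork: %d pathways, %d significant / %d scored pairs (B = %d)\n",
    nrow(object@nodes), nrow(object@edges), nrow(object@pairs),
    object@nPermutations))
})
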