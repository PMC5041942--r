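# Readers and writers for the five pipeline inputs plus network exports.
# All readers are strict: they either return a validated object or stop
# with a message naming the offending file (and line/cell where it helps).

stopIfMissing <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
}

#' Read a feature-by-sample expression matrix
#'
#' Reads a tab-separated matrix (header row of sample identifiers, first
#' column of feature identifiers, log-scale values). Rows sharing a feature
#' identifier are collapsed by arithmetic mean, the standard treatment of
#' multiple probes mapping to one miRNA or gene. Missing values are
#' rejected unless \code{impute = "rowmean"}, which replaces each NA with
#' its row mean.
#'
#' @param path file path.
#' @param featureKind \code{"miRNA"} or \code{"gene"}.
#' @param impute \code{"none"} (reject NAs, default) or \code{"rowmean"}.
#' @return An [ExpressionMatrix-class].
#' @export
readExpressionMatrix <- function(path, featureKind = c("gene", "miRNA"),
                                 impute = c("none", "rowmean")) {
  featureKind <- match.arg(featureKind)
  impute <- match.arg(impute)
  stopIfMissing(path)
  if (file.size(path) == 0L)
    stop("empty expression file: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1L)
    stop("ragged rows in ", path, ": rows have ",
         paste(unique(nf), collapse = ", "), " fields", call. = FALSE)
  tab <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L)
    stop("expression file needs a feature column and >= 1 sample: ", path,
         call. = FALSE)
  ids <- tab[[1L]]
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals),
                                dimnames = dimnames(vals)))
  bad <- which(is.na(num) & !(is.na(vals) | toupper(vals) %in% c("NA", "")))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(num))
    stop(sprintf("non-numeric value %s at data row %d, column '%s' of %s",
                 dQuote(vals[bad[1L]]), rc[1L],
                 colnames(num)[rc[2L]], path), call. = FALSE)
  }
  rownames(num) <- ids
  if (anyDuplicated(ids)) {
    # duplicate probes for one feature: average their expression values
    num <- rowsum(num, group = ids, reorder = FALSE) /
      as.vector(table(factor(ids, levels = unique(ids))))
    rownames(num) <- unique(ids)
  }
  if (anyNA(num)) {
    if (impute == "none")
      stop("missing values in ", path,
           " (set impute = \"rowmean\" to impute)", call. = FALSE)
    rm <- rowMeans(num, na.rm = TRUE)
    idx <- which(is.na(num), arr.ind = TRUE)
    num[idx] <- rm[idx[, 1L]]
    if (anyNA(num))
      stop("rows with all values missing in ", path, call. = FALSE)
  }
  ExpressionMatrix(num, featureKind)
}

#' Write an expression matrix
#'
#' @param object an [ExpressionMatrix-class].
#' @param path output path (tab-separated; first column \code{feature_id}).
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(object, path) {
  df <- data.frame(feature_id = featureIds(object),
                   exprValues(object), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Tab-separated with header; columns \code{sample_id}, \code{grade}
#' (II/III/IV) and optionally \code{time_months} (nonnegative) and
#' \code{event} (0/1).
#'
#' @param path file path.
#' @return data.frame with columns \code{sample_id}, \code{grade},
#'   \code{time_months}, \code{event} (the last two NA when absent).
#' @export
readSampleAnnotation <- function(path) {
  stopIfMissing(path)
  tab <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE)
  if (!all(c("sample_id", "grade") %in% names(tab)))
    stop("annotation needs sample_id and grade columns: ", path,
         call. = FALSE)
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample_id in ", path, call. = FALSE)
  if (!all(tab$grade %in% c("II", "III", "IV")))
    stop("grade must be II, III or IV in ", path, call. = FALSE)
  if (is.null(tab$time_months)) tab$time_months <- NA_real_
  if (is.null(tab$event)) tab$event <- NA_integer_
  if (any(!is.na(tab$time_months) & tab$time_months < 0))
    stop("negative survival time in ", path, call. = FALSE)
  if (any(!is.na(tab$event) & !tab$event %in% c(0L, 1L)))
    stop("event must be 0/1 in ", path, call. = FALSE)
  tab[c("sample_id", "grade", "time_months", "event")]
}

#' @rdname readSampleAnnotation
#' @param annotation data.frame as returned by [readSampleAnnotation()].
#' @export
writeSampleAnnotation <- function(annotation, path) {
  write.table(annotation, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a miRNA-target pair list
#'
#' Two tab-separated columns (\code{mirna_id}, \code{gene_id}), with or
#' without header; duplicates removed.
#'
#' @param path file path.
#' @return data.frame with columns \code{mirna_id}, \code{gene_id}.
#' @export
readTargetPairs <- function(path) {
  stopIfMissing(path)
  tab <- read.delim(path, header = FALSE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("target pair file needs two columns: ", path, call. = FALSE)
  if (identical(tolower(tab[1L, 1L]), "mirna_id"))
    tab <- tab[-1L, , drop = FALSE]
  out <- data.frame(mirna_id = as.character(tab[[1L]]),
                    gene_id = as.character(tab[[2L]]),
                    stringsAsFactors = FALSE)
  out <- out[out$mirna_id != out$gene_id, , drop = FALSE]
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' @rdname readTargetPairs
#' @param pairs data.frame with columns \code{mirna_id}, \code{gene_id}.
#' @export
writeTargetPairs <- function(pairs, path) {
  write.table(pairs[c("mirna_id", "gene_id")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein-protein interaction edge list
#'
#' Two or three tab-separated columns: \code{gene_a}, \code{gene_b} and an
#' optional integer confidence \code{score} (0-1000, the STRING
#' combined-score scale). When scores are present, edges below
#' \code{minScore} are dropped; the default 900 keeps only high-confidence
#' interactions. Self-loops are dropped with a warning; unordered
#' duplicates collapse to their best score.
#'
#' @param path file path.
#' @param minScore minimum combined score, applied only when a score
#'   column is present. Default 900.
#' @return A [PPINetwork-class].
#' @export
readPPI <- function(path, minScore = 900) {
  stopIfMissing(path)
  tab <- read.delim(path, header = FALSE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("PPI file needs >= 2 columns: ", path, call. = FALSE)
  if (identical(tolower(tab[1L, 1L]), "gene_a"))
    tab <- tab[-1L, , drop = FALSE]
  edges <- data.frame(gene_a = as.character(tab[[1L]]),
                      gene_b = as.character(tab[[2L]]),
                      stringsAsFactors = FALSE)
  if (ncol(tab) >= 3L) {
    edges$score <- suppressWarnings(as.numeric(tab[[3L]]))
    if (anyNA(edges$score))
      stop("non-numeric score in ", path, call. = FALSE)
    edges <- edges[edges$score >= minScore, , drop = FALSE]
  }
  loops <- edges$gene_a == edges$gene_b
  if (any(loops)) {
    warning(sum(loops), " self-loop row(s) dropped from ", path)
    edges <- edges[!loops, , drop = FALSE]
  }
  PPINetwork(edges)
}

#' @rdname readPPI
#' @param network a [PPINetwork-class].
#' @export
writePPI <- function(network, path) {
  write.table(ppiEdges(network), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: set id, description, then tab-separated members.
#' Lines with fewer than three fields are format errors (reported with
#' their line number); members are deduplicated.
#'
#' @param path file path.
#' @return A [GeneSetCollection-class].
#' @export
readGMT <- function(path) {
  stopIfMissing(path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("GMT line %d of %s has fewer than 3 fields", short[1L],
                 path), call. = FALSE)
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate set ids in ", path, call. = FALSE)
  desc <- setNames(vapply(fields, `[[`, character(1), 2L), ids)
  sets <- setNames(lapply(fields, function(f) unique(f[-(1:2)])), ids)
  GeneSetCollection(sets, desc)
}

#' @rdname readGMT
#' @param collection a [GeneSetCollection-class].
#' @export
writeGMT <- function(collection, path) {
  sets <- geneSets(collection)
  desc <- setDescriptions(collection)
  lines <- vapply(names(sets), function(id) {
    paste(c(id, desc[[id]], sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export a network as GraphML
#'
#' Converts a [PPINetwork-class], [MirnaPathwayNetwork-class] or
#' [CrosstalkNetwork-class] to igraph and writes GraphML for inspection in
#' standard graph viewers. Node attributes (side, direction, grade) are
#' carried along where defined.
#'
#' @param network the network object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
exportGraphML <- function(network, path) {
  g <- asIgraph(network)
  write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Convert a mirXtalk network to igraph
#'
#' @param network a [PPINetwork-class], [MirnaPathwayNetwork-class] or
#'   [CrosstalkNetwork-class].
#' @return an igraph graph.
#' @export
asIgraph <- function(network) {
  if (is(network, "PPINetwork")) {
    e <- ppiEdges(network)
    if (!nrow(e)) return(make_empty_graph(directed = FALSE))
    return(graph_from_data_frame(e, directed = FALSE))
  }
  if (is(network, "MirnaPathwayNetwork")) {
    e <- networkEdges(network)
    nodes <- networkNodes(network)
    el <- unique(e[c("mirna_id", "pathway_id")])
    return(graph_from_data_frame(el, directed = FALSE, vertices = nodes))
  }
  if (is(network, "CrosstalkNetwork")) {
    e <- networkEdges(network)
    nodes <- networkNodes(network)
    return(graph_from_data_frame(
      e[c("pathway_i", "pathway_j", "weight", "n_edges", "perm_p")],
      directed = FALSE, vertices = nodes))
  }
  stop("unsupported network class: ", class(network)[1L], call. = FALSE)
}
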