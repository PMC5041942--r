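# Staged pipeline driver: chains the analysis in study order over a
# shared configuration, writing tab-separated tables plus a manifest per
# stage. Stage outputs are pure functions of (inputs, config, seed).

#' Pipeline configuration
#'
#' Collects the thresholds of the whole workflow: FDR level for
#' differential calling, inverse-correlation cutoff and p bound for
#' signature pairs, enrichment edge threshold, permutation count and
#' significance threshold for pathway crosstalk, clique size, hub
#' fraction and PPI score cutoff, plus the seed governing every random
#' step.
#'
#' @param outDir output directory; stage outputs and manifests land here.
#' @param inputs optional named list of input file paths
#'   (\code{mirna_expression}, \code{gene_expression},
#'   \code{sample_annotation}, \code{target_pairs}, \code{ppi_edges},
#'   \code{pathways}); unnamed inputs default to the files the
#'   \code{simulate} stage writes into \code{outDir}.
#' @param alpha FDR threshold for differential calling (default 0.05).
#' @param corCutoff inverse-correlation cutoff (default -0.4).
#' @param corPMax correlation p bound (default 0.05).
#' @param enrichThreshold miRNA-pathway edge p threshold (default 0.05).
#' @param tail hypergeometric tail convention (\code{"ge"}/\code{"gt"}).
#' @param permutations crosstalk permutation rounds B (default 1000; the
#'   full-scale analysis convention is 1e6).
#' @param crosstalkThreshold crosstalk permutation-p threshold (0.05).
#' @param cliqueK clique-percolation k (default 3).
#' @param hubFraction hub degree fraction (default 0.15).
#' @param ppiMinScore PPI combined-score cutoff (default 900).
#' @param sampleSet correlation sample policy, see
#'   [selectSignaturePairs()].
#' @param seed integer seed for every stochastic step.
#' @param synth optional [syntheticConfig()] for the \code{simulate}
#'   stage; defaults to \code{syntheticConfig(seed = seed)}.
#' @return list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(outDir, inputs = list(), alpha = 0.05,
                           corCutoff = -0.4, corPMax = 0.05,
                           enrichThreshold = 0.05,
                           tail = c("ge", "gt"), permutations = 1000L,
                           crosstalkThreshold = 0.05, cliqueK = 3L,
                           hubFraction = 0.15, ppiMinScore = 900,
                           sampleSet = c("contrast", "all"), seed = 1L,
                           synth = NULL) {
  tail <- match.arg(tail)
  sampleSet <- match.arg(sampleSet)
  for (thr in c(alpha, corPMax, enrichThreshold, crosstalkThreshold))
    if (thr < 0 || thr > 1)
      stop("thresholds must lie in [0, 1]", call. = FALSE)
  if (permutations < 1L) stop("permutations must be >= 1", call. = FALSE)
  if (cliqueK < 3L) stop("cliqueK must be >= 3", call. = FALSE)
  structure(list(outDir = outDir, inputs = inputs, alpha = alpha,
                 corCutoff = corCutoff, corPMax = corPMax,
                 enrichThreshold = enrichThreshold, tail = tail,
                 permutations = as.integer(permutations),
                 crosstalkThreshold = crosstalkThreshold,
                 cliqueK = as.integer(cliqueK),
                 hubFraction = hubFraction, ppiMinScore = ppiMinScore,
                 sampleSet = sampleSet, seed = as.integer(seed),
                 synth = synth),
            class = "PipelineConfig")
}

pipelineStages <- c("simulate", "diff", "pairs", "mirpath", "crosstalk",
                    "modules", "survive")

inputPath <- function(config, name, producedBy = "simulate") {
  p <- config$inputs[[name]]
  if (is.null(p))
    p <- file.path(config$outDir, paste0(name, switch(name,
      pathways = ".gmt", ".tsv")))
  if (!file.exists(p))
    stop("missing input '", name, "' (", p, "); run stage '", producedBy,
         "' first or supply the path in config$inputs", call. = FALSE)
  p
}

stageOutput <- function(config, file, producedBy) {
  p <- file.path(config$outDir, file)
  if (!file.exists(p))
    stop("missing intermediate '", file, "'; run stage '", producedBy,
         "' first", call. = FALSE)
  p
}

writeTSV <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

writeManifest <- function(config, stage, inputFiles) {
  cfg <- unclass(config)
  cfg$synth <- if (is.null(cfg$synth)) NULL else unclass(cfg$synth)
  inputFiles <- inputFiles[file.exists(inputFiles)]
  manifest <- list(
    stage = stage,
    package = "mirXtalk",
    version = as.character(packageVersion("mirXtalk")),
    seed = config$seed,
    config = cfg[setdiff(names(cfg), c("outDir", "inputs"))],
    inputs = as.list(setNames(unname(md5sum(inputFiles)),
                              basename(inputFiles))))
  yaml::write_yaml(manifest,
                   file.path(config$outDir,
                             sprintf("manifest_%s.yaml", stage)))
}

#' Run the analysis pipeline
#'
#' Executes one stage or the whole chain in study order:
#' \code{simulate} (write synthetic inputs), \code{diff} (grade-contrast
#' differential calling for miRNAs and genes), \code{pairs} (signature
#' miRNA-target pairs), \code{mirpath} (bipartite miRNA-pathway network
#' and hub miRNAs), \code{crosstalk} (pathway crosstalk network with
#' permutation significance), \code{modules} (maximal bicliques and
#' k-clique-percolation communities), \code{survive} (core-module
#' survival stratification in gene, miRNA and combined modes). Each
#' stage writes tab-separated tables plus a \code{manifest_<stage>.yaml}
#' recording configuration, seed and input checksums. With identical
#' configuration and seed, all outputs are byte-identical across runs.
#'
#' @param stage one of \code{"all"} or a stage name.
#' @param config a [pipelineConfig()].
#' @return invisibly, the output directory.
#' @export
runPipeline <- function(stage = "all", config) {
  stopifnot(inherits(config, "PipelineConfig"))
  stage <- match.arg(stage, c("all", pipelineStages))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  stages <- if (stage == "all") pipelineStages else stage
  for (s in stages)
    switch(s,
           simulate = stageSimulate(config),
           diff = stageDiff(config),
           pairs = stagePairs(config),
           mirpath = stageMirpath(config),
           crosstalk = stageCrosstalk(config),
           modules = stageModules(config),
           survive = stageSurvive(config))
  invisible(config$outDir)
}

stageSimulate <- function(config) {
  synth <- if (is.null(config$synth)) syntheticConfig(seed = config$seed)
           else config$synth
  data <- simulateCrosstalkData(synth)
  writeSyntheticDataset(data, config$outDir)
  writeManifest(config, "simulate", character(0))
}

readPipelineInputs <- function(config, what) {
  out <- list()
  if ("mirna" %in% what)
    out$mirnaExpr <- readExpressionMatrix(
      inputPath(config, "mirna_expression"), "miRNA")
  if ("gene" %in% what)
    out$geneExpr <- readExpressionMatrix(
      inputPath(config, "gene_expression"), "gene")
  if ("annotation" %in% what)
    out$annotation <- readSampleAnnotation(
      inputPath(config, "sample_annotation"))
  if ("targets" %in% what)
    out$targetPairs <- readTargetPairs(inputPath(config, "target_pairs"))
  if ("ppi" %in% what)
    out$ppi <- readPPI(inputPath(config, "ppi_edges"),
                       minScore = config$ppiMinScore)
  if ("gmt" %in% what)
    out$geneSets <- readGMT(inputPath(config, "pathways"))
  out
}

stageDiff <- function(config) {
  inp <- readPipelineInputs(config, c("mirna", "gene", "annotation"))
  res <- do.call(rbind, lapply(c("III_vs_II", "IV_vs_II"), function(ctr) {
    rbind(callDifferential(inp$mirnaExpr, inp$annotation, ctr,
                           alpha = config$alpha),
          callDifferential(inp$geneExpr, inp$annotation, ctr,
                           alpha = config$alpha))
  }))
  writeTSV(res, file.path(config$outDir, "differential_results.tsv"))
  writeManifest(config, "diff",
                vapply(c("mirna_expression", "gene_expression",
                         "sample_annotation"),
                       function(n) inputPath(config, n), character(1)))
}

readDifferential <- function(config) {
  read.delim(stageOutput(config, "differential_results.tsv", "diff"),
             stringsAsFactors = FALSE)
}

stagePairs <- function(config) {
  inp <- readPipelineInputs(config,
                            c("mirna", "gene", "annotation", "targets"))
  diff <- readDifferential(config)
  pairs <- selectSignaturePairs(
    diff[diff$kind == "miRNA", ], diff[diff$kind == "gene", ],
    inp$targetPairs, inp$mirnaExpr, inp$geneExpr, inp$annotation,
    cutoff = config$corCutoff, pMax = config$corPMax,
    sampleSet = config$sampleSet)
  writeTSV(pairs, file.path(config$outDir, "signature_pairs.tsv"))
  writeManifest(config, "pairs",
                stageOutput(config, "differential_results.tsv", "diff"))
}

readSignaturePairs <- function(config) {
  read.delim(stageOutput(config, "signature_pairs.tsv", "pairs"),
             stringsAsFactors = FALSE)
}

stageMirpath <- function(config) {
  inp <- readPipelineInputs(config, c("gene", "gmt"))
  pairs <- readSignaturePairs(config)
  universe <- intersect(featureIds(inp$geneExpr),
                        unique(unlist(geneSets(inp$geneSets))))
  net <- buildMirnaPathwayNetwork(pairs, inp$geneSets, universe,
                                  threshold = config$enrichThreshold,
                                  tail = config$tail)
  writeTSV(networkEdges(net),
           file.path(config$outDir, "mirna_pathway_edges.tsv"))
  writeTSV(networkNodes(net),
           file.path(config$outDir, "mirna_pathway_nodes.tsv"))
  hubs <- findHubs(net, fraction = config$hubFraction)
  writeTSV(data.frame(mirna_id = hubs, stringsAsFactors = FALSE),
           file.path(config$outDir, "hub_mirnas.tsv"))
  exportGraphML(net,
                file.path(config$outDir, "mirna_pathway_network.graphml"))
  writeManifest(config, "mirpath",
                stageOutput(config, "signature_pairs.tsv", "pairs"))
}

readMirpathNetwork <- function(config) {
  edges <- read.delim(stageOutput(config, "mirna_pathway_edges.tsv",
                                  "mirpath"), stringsAsFactors = FALSE)
  nodes <- read.delim(stageOutput(config, "mirna_pathway_nodes.tsv",
                                  "mirpath"), stringsAsFactors = FALSE)
  list(edges = edges, nodes = nodes)
}

stageCrosstalk <- function(config) {
  inp <- readPipelineInputs(config, c("gene", "gmt", "ppi"))
  net <- readMirpathNetwork(config)
  diff <- readDifferential(config)
  pw <- sort(unique(net$edges$pathway_id))
  if (length(pw) < 2L)
    stop("fewer than 2 pathways in the miRNA-pathway network; ",
         "crosstalk undefined", call. = FALSE)
  sets <- geneSets(inp$geneSets)[pw]
  pwNodes <- net$nodes[net$nodes$side == "pathway", , drop = FALSE]
  grade <- setNames(pwNodes$grade, pwNodes$node_id)
  direction <- setNames(pwNodes$direction, pwNodes$node_id)
  ct <- buildCrosstalkNetwork(
    GeneSetCollection(sets), inp$ppi, inp$geneExpr,
    diff[diff$kind == "gene", ], B = config$permutations,
    threshold = config$crosstalkThreshold, seed = config$seed,
    nodeGrade = grade, nodeDirection = direction)
  writeTSV(scoredPairs(ct),
           file.path(config$outDir, "crosstalk_pairs.tsv"))
  writeTSV(networkEdges(ct),
           file.path(config$outDir, "crosstalk_edges.tsv"))
  writeTSV(networkNodes(ct),
           file.path(config$outDir, "crosstalk_nodes.tsv"))
  exportGraphML(ct, file.path(config$outDir,
                              "crosstalk_network.graphml"))
  writeManifest(config, "crosstalk",
                c(stageOutput(config, "mirna_pathway_edges.tsv",
                              "mirpath"),
                  stageOutput(config, "differential_results.tsv",
                              "diff")))
}

readCrosstalk <- function(config) {
  list(edges = read.delim(stageOutput(config, "crosstalk_edges.tsv",
                                      "crosstalk"),
                          stringsAsFactors = FALSE),
       nodes = read.delim(stageOutput(config, "crosstalk_nodes.tsv",
                                      "crosstalk"),
                          stringsAsFactors = FALSE))
}

stageModules <- function(config) {
  net <- readMirpathNetwork(config)
  bic <- maximalBicliques(net$edges[c("mirna_id", "pathway_id")])
  bicTab <- if (length(bic)) do.call(rbind, lapply(bic, function(m) {
    data.frame(module_id = m$id,
               side = rep(c("miRNA", "pathway"),
                          c(length(m$mirnas), length(m$pathways))),
               member_id = c(m$mirnas, m$pathways),
               stringsAsFactors = FALSE)
  })) else data.frame(module_id = character(0), side = character(0),
                      member_id = character(0))
  writeTSV(bicTab, file.path(config$outDir, "biclique_modules.tsv"))
  ct <- readCrosstalk(config)
  comms <- if (nrow(ct$edges))
    cliquePercolation(ct$edges[c("pathway_i", "pathway_j")],
                      k = config$cliqueK) else list()
  commTab <- if (length(comms)) do.call(rbind, lapply(
    seq_along(comms), function(i)
      data.frame(community_id = sprintf("CC%03d", i),
                 pathway_id = comms[[i]], stringsAsFactors = FALSE)))
    else data.frame(community_id = character(0),
                    pathway_id = character(0))
  writeTSV(commTab, file.path(config$outDir, "clique_communities.tsv"))
  writeManifest(config, "modules",
                c(stageOutput(config, "mirna_pathway_edges.tsv",
                              "mirpath"),
                  stageOutput(config, "crosstalk_edges.tsv",
                              "crosstalk")))
}

stageSurvive <- function(config) {
  inp <- readPipelineInputs(config, c("mirna", "gene", "annotation",
                                      "gmt"))
  net <- readMirpathNetwork(config)
  ct <- readCrosstalk(config)
  pairs <- readSignaturePairs(config)
  if (nrow(ct$edges)) {
    deg <- sort(table(c(ct$edges$pathway_i, ct$edges$pathway_j)),
                decreasing = TRUE)
    anchor <- sort(names(deg)[deg == max(deg)])[1L]
    ctNet <- new("CrosstalkNetwork",
                 pairs = ct$edges, edges = ct$edges,
                 nodes = data.frame(pathway_id = ct$nodes$pathway_id,
                                    grade = ct$nodes$grade,
                                    direction = ct$nodes$direction,
                                    stringsAsFactors = FALSE),
                 nPermutations = config$permutations)
    core <- extractCoreModule(ctNet, anchor, k = config$cliqueK)
    corePw <- core$nodes
  } else {
    # degenerate crosstalk network: fall back to the full pathway set of
    # the miRNA-pathway network
    corePw <- sort(unique(net$edges$pathway_id))
  }
  coreGenes <- unique(unlist(geneSets(inp$geneSets)[
    intersect(corePw, names(geneSets(inp$geneSets)))]))
  sigGenes <- intersect(unique(pairs$gene_id), coreGenes)
  sigMirnas <- sort(unique(net$edges$mirna_id[net$edges$pathway_id %in%
                                                corePw]))
  summaries <- list()
  for (mode in c("combined", "gene", "mirna")) {
    st <- stratifyAndTest(inp$mirnaExpr, inp$geneExpr, inp$annotation,
                          signatureGenes = sigGenes,
                          signatureMirnas = sigMirnas, mode = mode,
                          seed = config$seed)
    if (mode == "combined") {
      writeTSV(st$table,
               file.path(config$outDir, "survival_groups.tsv"))
      kmTab <- do.call(rbind, lapply(names(st$curves), function(g) {
        k <- st$curves[[g]]
        data.frame(group = g, time_months = k$event_times,
                   survival = k$survival, at_risk = k$at_risk,
                   n_event = k$n_event, stringsAsFactors = FALSE)
      }))
      writeTSV(kmTab, file.path(config$outDir, "km_curves.tsv"))
    }
    summaries[[mode]] <- data.frame(
      mode = mode,
      n_short = sum(st$table$group == "short"),
      n_long = sum(st$table$group == "long"),
      median_short = st$curves$short$median,
      median_long = st$curves$long$median,
      chisq = st$chisq, p = st$p, stringsAsFactors = FALSE)
  }
  writeTSV(do.call(rbind, summaries),
           file.path(config$outDir, "survival_summary.tsv"))
  writeManifest(config, "survive",
                c(stageOutput(config, "crosstalk_edges.tsv", "crosstalk"),
                  stageOutput(config, "signature_pairs.tsv", "pairs")))
}
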