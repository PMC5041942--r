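# Synthetic data with planted structure: the ground truth every downstream
# stage is validated against. The generator emulates a graded-tumor study
# with matched miRNA/mRNA profiles: planted grade-contrast differential
# features, negative miRNA-target coupling, target sets concentrated in
# pathways, pathway pairs with dense inter-pathway PPI wiring among
# differential genes, and survival times tied to a planted expression
# factor.

#' Configuration for the synthetic dataset generator
#'
#' Defaults describe the emulated study design: 63/33/64 samples in grades
#' II/III/IV, log-scale expression, a mean shift of 2 expression units for
#' planted differential features, miRNA-target coupling slope -0.8 with
#' residual standard deviation 0.5, 25 pathways of 40 genes, baseline PPI
#' density 0.03 with planted crosstalk pairs wired at 5x baseline, and a
#' planted hazard ratio of 3 between risk groups with ~20% censoring.
#'
#' @param nSamplesPerGrade integer triple: samples in grades II, III, IV.
#' @param nMirnas,nGenes numbers of miRNA and gene features.
#' @param nDiffMirnas,nDiffGenes planted differential feature counts
#'   (shifted in both grade-III and grade-IV contrasts).
#' @param effectSize mean shift (log-scale expression units) of planted
#'   differential features in grades III/IV versus II.
#' @param couplingBeta negative regression slope linking a planted target
#'   gene to its miRNA's expression.
#' @param noiseSd residual standard deviation of the coupling model.
#' @param nPathways,pathwaySize gene-set geometry.
#' @param nPlantedCrosstalkPairs pathway pairs given dense inter-pathway
#'   PPI edges among planted differential genes.
#' @param baselinePpiDensity probability of a background PPI edge between
#'   any two genes.
#' @param crosstalkDensityMultiplier planted inter-pathway edge density as
#'   a multiple of \code{baselinePpiDensity} (>= 5).
#' @param hazardRatio planted hazard ratio of the high-risk group.
#' @param censoringRate target fraction of censored samples in \[0, 1).
#' @param baselineMedianMonths median survival of the low-risk group.
#' @param targetsPerMirna planted target genes per differential miRNA.
#' @param decoysPerPlanted decoy (non-planted) predicted pairs per planted
#'   pair, drawn from non-differential features.
#' @param factorEffect loading of the planted risk factor on planted
#'   differential features (separation between risk groups, in expression
#'   units). The default (3) makes the risk factor the dominant variance
#'   axis of the signature features, so two-group clustering can recover
#'   the risk groups, as the stratification design requires.
#' @param allowPathwayOverlap allow \code{nPathways * pathwaySize} to
#'   exceed \code{nGenes} by sampling pathway fill genes with overlap.
#' @param seed integer random seed; identical configurations with the same
#'   seed reproduce the dataset exactly.
#' @return A validated list of class \code{"SyntheticConfig"}.
#' @seealso [simulateCrosstalkData()]
#' @export
syntheticConfig <- function(nSamplesPerGrade = c(63L, 33L, 64L),
                            nMirnas = 150L, nGenes = 1200L,
                            nDiffMirnas = 40L, nDiffGenes = 300L,
                            effectSize = 2, couplingBeta = -0.8,
                            noiseSd = 0.5,
                            nPathways = 25L, pathwaySize = 40L,
                            nPlantedCrosstalkPairs = 5L,
                            baselinePpiDensity = 0.03,
                            crosstalkDensityMultiplier = 5,
                            hazardRatio = 3, censoringRate = 0.2,
                            baselineMedianMonths = 28,
                            targetsPerMirna = 4L, decoysPerPlanted = 2L,
                            factorEffect = 3,
                            allowPathwayOverlap = FALSE, seed = 1L) {
  cfg <- list(nSamplesPerGrade = as.integer(nSamplesPerGrade),
              nMirnas = as.integer(nMirnas), nGenes = as.integer(nGenes),
              nDiffMirnas = as.integer(nDiffMirnas),
              nDiffGenes = as.integer(nDiffGenes),
              effectSize = effectSize, couplingBeta = couplingBeta,
              noiseSd = noiseSd, nPathways = as.integer(nPathways),
              pathwaySize = as.integer(pathwaySize),
              nPlantedCrosstalkPairs = as.integer(nPlantedCrosstalkPairs),
              baselinePpiDensity = baselinePpiDensity,
              crosstalkDensityMultiplier = crosstalkDensityMultiplier,
              hazardRatio = hazardRatio, censoringRate = censoringRate,
              baselineMedianMonths = baselineMedianMonths,
              targetsPerMirna = as.integer(targetsPerMirna),
              decoysPerPlanted = as.integer(decoysPerPlanted),
              factorEffect = factorEffect,
              allowPathwayOverlap = isTRUE(allowPathwayOverlap),
              seed = as.integer(seed))
  if (length(cfg$nSamplesPerGrade) != 3L || any(cfg$nSamplesPerGrade < 2L))
    stop("nSamplesPerGrade must be three counts, each >= 2", call. = FALSE)
  if (cfg$nDiffMirnas > cfg$nMirnas)
    stop("nDiffMirnas exceeds nMirnas", call. = FALSE)
  if (cfg$nDiffGenes > cfg$nGenes)
    stop("nDiffGenes exceeds nGenes", call. = FALSE)
  if (cfg$couplingBeta >= 0)
    stop("couplingBeta must be negative", call. = FALSE)
  if (cfg$noiseSd <= 0) stop("noiseSd must be positive", call. = FALSE)
  if (cfg$censoringRate < 0 || cfg$censoringRate >= 1)
    stop("censoringRate must lie in [0, 1)", call. = FALSE)
  if (cfg$nDiffMirnas * cfg$targetsPerMirna > cfg$nDiffGenes)
    stop("nDiffGenes too small for nDiffMirnas * targetsPerMirna planted ",
         "target genes", call. = FALSE)
  if (!cfg$allowPathwayOverlap &&
      cfg$nPathways * cfg$pathwaySize > cfg$nGenes)
    stop("nPathways * pathwaySize exceeds nGenes; set ",
         "allowPathwayOverlap = TRUE to permit overlapping sets",
         call. = FALSE)
  if (cfg$nPlantedCrosstalkPairs > choose(cfg$nPathways, 2))
    stop("more planted crosstalk pairs than pathway pairs", call. = FALSE)
  if (cfg$crosstalkDensityMultiplier < 5)
    stop("crosstalkDensityMultiplier must be >= 5", call. = FALSE)
  if (cfg$hazardRatio <= 0) stop("hazardRatio must be > 0", call. = FALSE)
  class(cfg) <- "SyntheticConfig"
  cfg
}

# map linear indices 1..choose(n,2) to unordered pairs (i<j), enumerated
# (1,2),(1,3),...,(2,3),...
pairFromIndex <- function(k, n) {
  ends <- cumsum(seq(n - 1L, 1L))
  i <- findInterval(k - 0.5, c(0, ends))
  j <- k - c(0, ends)[i] + i
  cbind(i, j)
}

# uniform horizon giving the target expected censoring fraction under
# exponential event times: P(censored) = (1 - exp(-l*h)) / (l*h)
censoringHorizon <- function(rates, targetRate) {
  if (targetRate <= 0) return(Inf)
  f <- function(h) mean((1 - exp(-rates * h)) / (rates * h)) - targetRate
  uniroot(f, lower = 1e-6, upper = 1e6, tol = 1e-9)$root
}

#' Generate a synthetic crosstalk dataset with planted ground truth
#'
#' Draws the five pipeline inputs from the model described in
#' [syntheticConfig()]:
#' \itemize{
#'   \item planted differential miRNAs get a mean shift of
#'     \code{+/- effectSize} in grades III and IV versus II (half up, half
#'     down), plus a risk-factor loading;
#'   \item each planted miRNA regulates \code{targetsPerMirna} target
#'     genes via \code{gene = baseline + couplingBeta * (miRNA - miRNA
#'     baseline) + N(0, noiseSd)}, so targets shift opposite to their
#'     miRNA; remaining planted differential genes get direct shifts;
#'   \item each planted miRNA's targets land in one pathway, the planted
#'     enrichment; pathways are filled to size with non-differential
#'     genes;
#'   \item the PPI graph has background density
#'     \code{baselinePpiDensity}; the planted crosstalk pairs -- the
#'     leading clique edges over a small core pathway set -- additionally
#'     connect their differential genes at
#'     \code{crosstalkDensityMultiplier} times that density;
#'   \item survival is exponential with rate multiplied by
#'     \code{hazardRatio} in the high-risk group (a coin-flip label whose
#'     expression factor loads on planted features), censored uniformly on
#'     a horizon calibrated to \code{censoringRate}.
#' }
#'
#' @param config a [syntheticConfig()] object.
#' @return A list with elements \code{mirnaExpr}, \code{geneExpr}
#'   ([ExpressionMatrix-class]), \code{annotation} (data.frame),
#'   \code{targetPairs} (data.frame), \code{ppi} ([PPINetwork-class]),
#'   \code{geneSets} ([GeneSetCollection-class]) and \code{truth}, the
#'   ground-truth list (planted differential features with directions,
#'   planted pairs, per-miRNA planted pathways, planted crosstalk pairs,
#'   per-sample risk groups).
#' @examples
#' cfg <- syntheticConfig(nSamplesPerGrade = c(10, 10, 10), nMirnas = 20,
#'   nGenes = 120, nDiffMirnas = 6, nDiffGenes = 30, nPathways = 5,
#'   pathwaySize = 20, seed = 1)
#' d <- simulateCrosstalkData(cfg)
#' d$mirnaExpr
#' @export
simulateCrosstalkData <- function(config = syntheticConfig()) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed)
  nS <- sum(config$nSamplesPerGrade)
  grade <- rep(c("II", "III", "IV"), config$nSamplesPerGrade)
  sampleId <- sprintf("S%03d", seq_len(nS))
  mirId <- sprintf("miR-%03d", seq_len(config$nMirnas))
  geneId <- sprintf("G%04d", seq_len(config$nGenes))

  # planted differential features and directions
  diffMir <- sample(mirId, config$nDiffMirnas)
  mirDir <- setNames(rep(c(1, -1), length.out = config$nDiffMirnas),
                     diffMir)
  nCoupled <- config$nDiffMirnas * config$targetsPerMirna
  diffGene <- sample(geneId, config$nDiffGenes)
  coupledGene <- diffGene[seq_len(nCoupled)]
  directGene <- diffGene[-seq_len(nCoupled)]
  targetOf <- rep(diffMir, each = config$targetsPerMirna)
  geneDir <- c(setNames(-mirDir[targetOf], coupledGene),
               setNames(rep(c(1, -1), length.out = length(directGene)),
                        directGene))

  # risk factor: coin-flip groups, expression loading on planted features
  risk <- sample(c(0L, 1L), nS, replace = TRUE)
  fac <- (risk - 0.5) * config$factorEffect
  shifted <- as.numeric(grade != "II")

  # miRNA expression
  baseM <- setNames(rnorm(config$nMirnas, 7, 1), mirId)
  M <- matrix(rnorm(config$nMirnas * nS), config$nMirnas, nS,
              dimnames = list(mirId, sampleId))
  M <- M + baseM
  M[diffMir, ] <- M[diffMir, ] +
    outer(mirDir[diffMir] * config$effectSize, shifted) +
    matrix(fac, length(diffMir), nS, byrow = TRUE)

  # gene expression
  baseG <- setNames(rnorm(config$nGenes, 8, 1), geneId)
  G <- matrix(rnorm(config$nGenes * nS), config$nGenes, nS,
              dimnames = list(geneId, sampleId))
  G <- G + baseG
  # coupled targets: residual noise is noiseSd, signal comes through the miRNA
  G[coupledGene, ] <- baseG[coupledGene] +
    config$couplingBeta * (M[targetOf, , drop = FALSE] - baseM[targetOf]) +
    matrix(rnorm(length(coupledGene) * nS, 0, config$noiseSd),
           length(coupledGene), nS)
  if (length(directGene))
    G[directGene, ] <- G[directGene, ] +
      outer(geneDir[directGene] * config$effectSize, shifted) +
      matrix(fac, length(directGene), nS, byrow = TRUE)
  M <- round(M, 6)
  G <- round(G, 6)

  # predicted target pairs: planted plus uniform decoys among
  # non-differential features (true negatives for the correlation filter)
  planted <- data.frame(mirna_id = targetOf, gene_id = coupledGene,
                        stringsAsFactors = FALSE)
  nDecoy <- config$decoysPerPlanted * nrow(planted)
  otherMir <- setdiff(mirId, diffMir)
  otherGene <- setdiff(geneId, diffGene)
  decoy <- unique(data.frame(
    mirna_id = sample(otherMir, nDecoy, replace = TRUE),
    gene_id = sample(otherGene, nDecoy, replace = TRUE),
    stringsAsFactors = FALSE))
  targetPairs <- rbind(cbind(planted, planted = TRUE),
                       cbind(decoy, planted = FALSE))
  rownames(targetPairs) <- NULL

  # pathways: each planted miRNA's targets land in one pathway; direct
  # differential genes spread evenly; fill with non-differential genes
  pwId <- sprintf("PW%03d", seq_len(config$nPathways))
  mirPathway <- setNames(
    pwId[((seq_len(config$nDiffMirnas) - 1L) %% config$nPathways) + 1L],
    diffMir)
  members <- setNames(vector("list", config$nPathways), pwId)
  for (i in seq_along(diffMir))
    members[[mirPathway[[i]]]] <-
      c(members[[mirPathway[[i]]]],
        coupledGene[targetOf == diffMir[[i]]])
  for (g in directGene) {
    at <- which.min(lengths(members))
    members[[at]] <- c(members[[at]], g)
  }
  if (any(lengths(members) > config$pathwaySize))
    stop("pathwaySize too small to hold the planted differential genes",
         call. = FALSE)
  fillNeeded <- config$pathwaySize - lengths(members)
  if (!config$allowPathwayOverlap) {
    pool <- sample(otherGene, sum(fillNeeded))
    at <- rep(seq_len(config$nPathways), fillNeeded)
    fills <- split(pool, factor(at, levels = seq_len(config$nPathways)))
  } else {
    fills <- lapply(fillNeeded, function(k) sample(otherGene, k))
  }
  for (i in seq_len(config$nPathways))
    members[[i]] <- c(members[[i]], fills[[i]])
  geneSets <- GeneSetCollection(
    members, setNames(sprintf("synthetic pathway %d",
                              seq_len(config$nPathways)), pwId))

  # PPI: background Bernoulli graph plus dense planted inter-pathway wiring
  nPairs <- choose(config$nGenes, 2)
  nBg <- rbinom(1L, nPairs, config$baselinePpiDensity)
  bg <- pairFromIndex(sort(sample.int(nPairs, nBg)), config$nGenes)
  edges <- data.frame(gene_a = geneId[bg[, 1L]], gene_b = geneId[bg[, 2L]],
                      stringsAsFactors = FALSE)
  ctPairs <- data.frame(pathway_i = character(0), pathway_j = character(0))
  corePathways <- character(0)
  if (config$nPlantedCrosstalkPairs > 0L) {
    # plant the pairs as the leading edges of a clique over a small "core"
    # pathway set, the dense crosstalk module downstream stages look for
    nCore <- 2L
    while (choose(nCore, 2) < config$nPlantedCrosstalkPairs)
      nCore <- nCore + 1L
    corePathways <- sort(sample(pwId, nCore))
    pp <- t(combn(corePathways, 2L))[seq_len(config$nPlantedCrosstalkPairs),
                                     , drop = FALSE]
    ctPairs <- data.frame(pathway_i = pp[, 1L], pathway_j = pp[, 2L],
                          stringsAsFactors = FALSE)
    dens <- config$crosstalkDensityMultiplier * config$baselinePpiDensity
    for (r in seq_len(nrow(ctPairs))) {
      di <- intersect(members[[ctPairs$pathway_i[r]]], diffGene)
      dj <- intersect(members[[ctPairs$pathway_j[r]]], diffGene)
      combos <- expand.grid(gene_a = di, gene_b = dj,
                            stringsAsFactors = FALSE)
      combos <- combos[combos$gene_a != combos$gene_b, , drop = FALSE]
      keep <- runif(nrow(combos)) < dens
      edges <- rbind(edges, combos[keep, , drop = FALSE])
    }
  }
  edges$score <- sample(900:1000, nrow(edges), replace = TRUE)
  ppi <- PPINetwork(edges)

  # survival: exponential hazards by risk group, uniform censoring
  rates <- log(2) / config$baselineMedianMonths *
    config$hazardRatio^risk
  tEvent <- rexp(nS, rates)
  horizon <- censoringHorizon(log(2) / config$baselineMedianMonths *
                                config$hazardRatio^c(0, 1),
                              config$censoringRate)
  cens <- if (is.finite(horizon)) runif(nS, 0, horizon) else rep(Inf, nS)
  annotation <- data.frame(
    sample_id = sampleId, grade = grade,
    time_months = round(pmin(tEvent, cens), 4),
    event = as.integer(tEvent <= cens), stringsAsFactors = FALSE)

  truth <- list(
    config = config,
    diffMirnas = data.frame(mirna_id = diffMir,
                            direction = ifelse(mirDir > 0, "up", "down"),
                            stringsAsFactors = FALSE),
    diffGenes = data.frame(
      gene_id = c(coupledGene, directGene),
      direction = ifelse(geneDir[c(coupledGene, directGene)] > 0,
                         "up", "down"),
      role = rep(c("coupled", "direct"),
                 c(length(coupledGene), length(directGene))),
      stringsAsFactors = FALSE),
    pairs = planted,
    mirnaPathway = data.frame(mirna_id = names(mirPathway),
                              pathway_id = unname(mirPathway),
                              stringsAsFactors = FALSE),
    crosstalkPairs = ctPairs,
    corePathways = corePathways,
    riskGroups = data.frame(sample_id = sampleId, risk_group = risk,
                            stringsAsFactors = FALSE))

  list(mirnaExpr = ExpressionMatrix(M, "miRNA"),
       geneExpr = ExpressionMatrix(G, "gene"),
       annotation = annotation,
       targetPairs = targetPairs,
       ppi = ppi,
       geneSets = geneSets,
       truth = truth)
}

#' Write a synthetic dataset to a directory
#'
#' Writes the five pipeline input files (tab-separated expression
#' matrices, sample annotation, target pairs, PPI edge list, GMT gene
#' sets) plus the ground truth as structured YAML. With a fixed
#' configuration and seed the files are byte-identical across runs.
#'
#' @param data a list from [simulateCrosstalkData()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the file paths, invisibly.
#' @export
writeSyntheticDataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    mirna_expression = file.path(dir, "mirna_expression.tsv"),
    gene_expression = file.path(dir, "gene_expression.tsv"),
    sample_annotation = file.path(dir, "sample_annotation.tsv"),
    target_pairs = file.path(dir, "target_pairs.tsv"),
    ppi_edges = file.path(dir, "ppi_edges.tsv"),
    pathways = file.path(dir, "pathways.gmt"),
    ground_truth = file.path(dir, "ground_truth.yaml"))
  writeExpressionMatrix(data$mirnaExpr, paths[["mirna_expression"]])
  writeExpressionMatrix(data$geneExpr, paths[["gene_expression"]])
  writeSampleAnnotation(data$annotation, paths[["sample_annotation"]])
  writeTargetPairs(data$targetPairs, paths[["target_pairs"]])
  writePPI(data$ppi, paths[["ppi_edges"]])
  writeGMT(data$geneSets, paths[["pathways"]])
  truth <- data$truth
  truth$config <- unclass(truth$config)
  asPlainList <- function(x) {
    if (is.data.frame(x)) as.list(x)
    else if (is.list(x)) lapply(x, asPlainList)
    else x
  }
  yaml::write_yaml(asPlainList(truth), paths[["ground_truth"]])
  invisible(paths)
}
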