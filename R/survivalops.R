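# Module-based survival stratification: two-group K-means on signature
# expression, Kaplan-Meier curves per group, log-rank separation test,
# and the within-grade complete-linkage heatmap ordering.

#' Two-group K-means clustering of samples
#'
#' Partitions samples into k = 2 groups minimizing within-cluster sum of
#' squares over \code{nRestarts} seeded initializations. Features are
#' standardized (zero mean, unit variance) first so miRNAs and genes
#' contribute on a common scale; zero-variance features are dropped.
#'
#' @param featureMatrix numeric sample x feature matrix.
#' @param seed random seed, default 1.
#' @param nRestarts K-means restarts, default 10.
#' @return integer vector of group labels (1/2), named by sample.
#' @export
twoGroupCluster <- function(featureMatrix, seed = 1L, nRestarts = 10L) {
  m <- as.matrix(featureMatrix)
  if (nrow(m) < 2L) stop("need >= 2 samples", call. = FALSE)
  sds <- apply(m, 2L, sd)
  m <- m[, sds > 0, drop = FALSE]
  if (!ncol(m) || all(dist(m) == 0))
    stop("all samples identical: clustering degenerate", call. = FALSE)
  m <- scale(m)
  set.seed(seed)
  km <- kmeans(m, centers = 2L, nstart = nRestarts)
  setNames(km$cluster, rownames(featureMatrix))
}

#' Kaplan-Meier product-limit estimate
#'
#' Product-limit estimator of the survival function (computed with
#' \code{survival::survfit}); censored subjects leave the risk set
#' without producing a step. The median is the smallest time t with
#' S(t) <= 0.5, undefined (NA) when the curve never drops that far.
#'
#' @param times nonnegative survival times.
#' @param events 0/1 event indicators.
#' @return object of class \code{"KMCurve"}: list with
#'   \code{event_times} (distinct times with >= 1 event), \code{survival}
#'   (the step values), \code{at_risk}, \code{n_event}, \code{median},
#'   \code{n}, and \code{fit} (the underlying survfit object).
#' @export
kmFit <- function(times, events) {
  if (!length(times)) stop("empty input", call. = FALSE)
  if (any(times < 0)) stop("negative times", call. = FALSE)
  if (!all(events %in% c(0, 1))) stop("events must be 0/1", call. = FALSE)
  fit <- survfit(Surv(times, events) ~ 1)
  keep <- fit$n.event > 0
  surv <- fit$surv[keep]
  tt <- fit$time[keep]
  med <- if (any(surv <= 0.5)) min(tt[surv <= 0.5]) else NA_real_
  structure(list(event_times = tt, survival = surv,
                 at_risk = fit$n.risk[keep], n_event = fit$n.event[keep],
                 median = med, n = length(times), fit = fit),
            class = "KMCurve")
}

#' @export
print.KMCurve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d event times, median = %s\n",
              x$n, length(x$event_times),
              if (is.na(x$median)) "not reached" else
                format(x$median, digits = 4)))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic over the pooled risk sets, 1 df chi-square
#' p-value (via \code{survival::survdiff}). With no events in either
#' group the statistic is undefined; it is reported as 0 with p = 1 and
#' a warning.
#'
#' @param timesA,eventsA,timesB,eventsB survival times and 0/1 event
#'   indicators of the two groups.
#' @return list with elements \code{chisq} and \code{p}.
#' @export
logrankTest <- function(timesA, eventsA, timesB, eventsB) {
  if (!length(timesA) || !length(timesB))
    stop("both groups must be nonempty", call. = FALSE)
  if (sum(eventsA) + sum(eventsB) == 0) {
    warning("no events in either group; log-rank undefined, p = 1")
    return(list(chisq = 0, p = 1))
  }
  time <- c(timesA, timesB)
  event <- c(eventsA, eventsB)
  group <- rep(c("A", "B"), c(length(timesA), length(timesB)))
  sd <- survdiff(Surv(time, event) ~ group)
  list(chisq = unname(sd$chisq),
       p = pchisq(unname(sd$chisq), df = 1, lower.tail = FALSE))
}

#' Stratify patients by signature expression and test survival separation
#'
#' Builds the signature feature matrix (genes, miRNAs, or both,
#' per-feature standardized), splits the annotated samples into two
#' groups by K-means, labels the group with the smaller Kaplan-Meier
#' median survival \code{"short"} (a never-reached median counts as
#' infinite), and tests the separation by log-rank.
#'
#' @param mirnaExpr,geneExpr [ExpressionMatrix-class] objects.
#' @param annotation sample annotation with \code{time_months} and
#'   \code{event}; samples lacking survival data are dropped (>= 4 must
#'   remain).
#' @param signatureGenes,signatureMirnas identifier vectors; the mode
#'   decides which are used.
#' @param mode \code{"combined"} (default), \code{"gene"} or
#'   \code{"mirna"}.
#' @param seed,nRestarts passed to [twoGroupCluster()].
#' @return list with elements \code{table} (data.frame \code{sample_id},
#'   \code{group}, \code{time_months}, \code{event}), \code{curves}
#'   (KMCurve list \code{short}/\code{long}), \code{chisq}, \code{p}.
#' @export
stratifyAndTest <- function(mirnaExpr, geneExpr, annotation,
                            signatureGenes = character(0),
                            signatureMirnas = character(0),
                            mode = c("combined", "gene", "mirna"),
                            seed = 1L, nRestarts = 10L) {
  mode <- match.arg(mode)
  ann <- annotation[!is.na(annotation$time_months) &
                      !is.na(annotation$event), , drop = FALSE]
  keep <- intersect(intersect(ann$sample_id, sampleIds(mirnaExpr)),
                    sampleIds(geneExpr))
  ann <- ann[ann$sample_id %in% keep, , drop = FALSE]
  if (nrow(ann) < 4L)
    stop("need >= 4 samples with survival data", call. = FALSE)
  parts <- list()
  if (mode %in% c("combined", "gene")) {
    sg <- intersect(signatureGenes, featureIds(geneExpr))
    if (length(sg))
      parts$gene <- exprValues(geneExpr)[sg, ann$sample_id, drop = FALSE]
  }
  if (mode %in% c("combined", "mirna")) {
    sm <- intersect(signatureMirnas, featureIds(mirnaExpr))
    if (length(sm))
      parts$mirna <- exprValues(mirnaExpr)[sm, ann$sample_id,
                                           drop = FALSE]
  }
  if (!length(parts))
    stop("empty signature for mode = ", dQuote(mode), call. = FALSE)
  fm <- t(do.call(rbind, parts))
  cl <- twoGroupCluster(fm, seed = seed, nRestarts = nRestarts)
  km <- lapply(1:2, function(g)
    kmFit(ann$time_months[cl == g], ann$event[cl == g]))
  med <- vapply(km, function(k) if (is.na(k$median)) Inf else k$median,
                numeric(1))
  shortGrp <- which.min(med)   # ties: lower-index group is "short"
  group <- ifelse(cl == shortGrp, "short", "long")
  curves <- list(short = km[[shortGrp]], long = km[[3L - shortGrp]])
  lr <- logrankTest(ann$time_months[group == "short"],
                    ann$event[group == "short"],
                    ann$time_months[group == "long"],
                    ann$event[group == "long"])
  list(table = data.frame(sample_id = ann$sample_id, group = group,
                          time_months = ann$time_months,
                          event = ann$event, stringsAsFactors = FALSE,
                          row.names = NULL),
       curves = curves, chisq = lr$chisq, p = lr$p)
}

#' Heatmap ordering: within-grade sample clustering, global feature clustering
#'
#' Orders samples by complete-linkage hierarchical clustering (Euclidean
#' distance) run separately within each grade, keeping grades contiguous
#' in II, III, IV order; features are ordered by complete-linkage
#' clustering across all samples.
#'
#' @param exprMatrix an [ExpressionMatrix-class].
#' @param annotation sample annotation data.frame.
#' @return list with character vectors \code{sampleOrder} and
#'   \code{featureOrder}.
#' @export
heatmapOrder <- function(exprMatrix, annotation) {
  m <- exprValues(exprMatrix)
  gr <- annotation$grade[match(colnames(m), annotation$sample_id)]
  sampleOrder <- unlist(lapply(c("II", "III", "IV"), function(g) {
    cols <- colnames(m)[which(gr == g)]
    if (length(cols) < 2L) return(cols)
    hc <- hclust(dist(t(m[, cols, drop = FALSE])), method = "complete")
    cols[hc$order]
  }), use.names = FALSE)
  featureOrder <- if (nrow(m) < 2L) rownames(m) else
    rownames(m)[hclust(dist(m), method = "complete")$order]
  list(sampleOrder = sampleOrder, featureOrder = featureOrder)
}
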