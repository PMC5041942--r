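# Grade-contrast differential calling: unpaired t test of grade III or IV
# samples against grade II controls, Benjamini-Hochberg FDR within each
# (feature kind, contrast) family.

#' Unpaired two-sample t test for a single feature
#'
#' Pooled-variance Student's t by default (the convention for
#' grade-contrast calling here); Welch's unequal-variance variant behind a
#' flag. Two-sided p. A feature that is constant and equal in both groups
#' has an undefined statistic and is reported as \code{t = 0, p = 1} with
#' a warning rather than dropped, which keeps the feature universe stable
#' for downstream enrichment.
#'
#' @param caseValues,controlValues numeric vectors, each of length >= 2.
#' @param variant \code{"student"} (pooled variance, default) or
#'   \code{"welch"}.
#' @return list with elements \code{t} and \code{p}.
#' @examples
#' tTestFeature(c(1, 2, 3), c(1, 2, 3))   # t = 0, p = 1
#' @export
tTestFeature <- function(caseValues, controlValues,
                         variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(caseValues) < 2L || length(controlValues) < 2L)
    stop("each group needs >= 2 values", call. = FALSE)
  r <- rowTTest(matrix(c(caseValues, controlValues), nrow = 1),
                seq_along(caseValues),
                length(caseValues) + seq_along(controlValues), variant)
  list(t = r$t, p = r$p)
}

# vectorized unpaired t test over matrix rows; returns t, p, means
rowTTest <- function(mat, idxCase, idxControl,
                     variant = c("student", "welch")) {
  variant <- match.arg(variant)
  n1 <- length(idxCase)
  n2 <- length(idxControl)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs >= 2 samples", call. = FALSE)
  x <- mat[, idxCase, drop = FALSE]
  y <- mat[, idxControl, drop = FALSE]
  m1 <- rowMeans(x)
  m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  if (variant == "student") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, nrow(mat))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  degenerate <- se == 0 & m1 == m2
  if (any(degenerate)) {
    warning(sum(degenerate),
            " feature(s) constant and equal in both groups; reported ",
            "with t = 0, p = 1")
    t[degenerate] <- 0
  }
  p <- pmax(2 * pt(-abs(t), df), .Machine$double.xmin)
  p[degenerate] <- 1
  list(t = t, p = p, meanCase = m1, meanControl = m2)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjusted p-values: step-up \code{p * m / rank},
#' clipped at 1, enforced monotone in p rank, returned in input order.
#'
#' @param pValues numeric vector of p-values in \[0, 1\].
#' @return adjusted values, same order as the input.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bhAdjust <- function(pValues) {
  if (!is.numeric(pValues) || anyNA(pValues) ||
      any(pValues < 0 | pValues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pValues, method = "BH")
}

#' Call differential features for a grade contrast
#'
#' Tests every feature of an expression matrix for differential expression
#' between the contrast's case grade (III or IV) and grade II controls
#' using the unpaired t test, adjusts p-values by Benjamini-Hochberg
#' within this (feature kind, contrast) family, and flags features with
#' FDR below \code{alpha} (default 5%). Direction is \code{"up"} when the
#' case-grade mean exceeds the control mean.
#'
#' @param exprMatrix an [ExpressionMatrix-class].
#' @param annotation sample annotation data.frame (columns
#'   \code{sample_id}, \code{grade}); every matrix sample must be
#'   annotated.
#' @param contrast \code{"III_vs_II"} or \code{"IV_vs_II"}.
#' @param alpha FDR threshold, default 0.05.
#' @param variant t-test variant, see [tTestFeature()].
#' @return data.frame with columns \code{feature_id}, \code{kind},
#'   \code{contrast}, \code{t}, \code{p}, \code{fdr}, \code{direction},
#'   \code{significant}.
#' @export
callDifferential <- function(exprMatrix, annotation,
                             contrast = c("III_vs_II", "IV_vs_II"),
                             alpha = 0.05,
                             variant = c("student", "welch")) {
  contrast <- match.arg(contrast)
  variant <- match.arg(variant)
  caseGrade <- sub("_vs_II", "", contrast)
  mat <- exprValues(exprMatrix)
  gr <- annotation$grade[match(colnames(mat), annotation$sample_id)]
  if (anyNA(gr))
    stop("samples missing from annotation: ",
         paste(head(colnames(mat)[is.na(gr)]), collapse = ", "),
         call. = FALSE)
  idxCase <- which(gr == caseGrade)
  idxControl <- which(gr == "II")
  if (length(idxCase) < 2L || length(idxControl) < 2L)
    stop("contrast ", contrast, " needs >= 2 samples in grades ",
         caseGrade, " and II", call. = FALSE)
  r <- rowTTest(mat, idxCase, idxControl, variant)
  fdr <- bhAdjust(r$p)
  data.frame(
    feature_id = rownames(mat), kind = featureKind(exprMatrix),
    contrast = contrast, t = r$t, p = r$p, fdr = fdr,
    direction = ifelse(r$meanCase > r$meanControl, "up", "down"),
    significant = fdr < alpha, stringsAsFactors = FALSE,
    row.names = NULL)
}
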