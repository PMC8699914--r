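#' Discordance between two call matrices, stratified by provenance and allele
#'
#' The primary error metric: the fraction of compared cells where the two
#' panels disagree. Cells missing in either panel are excluded from the
#' comparison. Strata:
#' \itemize{
#'   \item by cell provenance (\code{RAW_CALLED}: called by the upstream
#'     caller; \code{HB_CALLED}: first called by block consensus;
#'     \code{COMPLETED}: first called by downstream completion), when a
#'     provenance matrix is supplied;
#'   \item by the comparison panel's allele (\code{REF}/\code{ALT}), since
#'     allele-calling asymmetries live on the truth side.
#' }
#' A stratum with no comparable cells is reported as \code{NA}, not zero.
#'
#' @param imputed,comparison call matrices (0/1/\code{NA}) of identical
#'   dimension (shared markers).
#' @param provenance optional character matrix of the same shape.
#' @return list with \code{overall}, \code{byClass}, \code{byAllele}
#'   (fractions), \code{imputationAccuracy}, and \code{nCells} (compared
#'   cells per stratum).
#' @export
discordanceReport <- function(imputed, comparison, provenance = NULL) {
  stopifnot(identical(dim(imputed), dim(comparison)))
  cmp <- !is.na(imputed) & !is.na(comparison)
  disc <- cmp & (imputed != comparison)
  rate <- function(mask) {
    n <- sum(cmp & mask)
    if (n == 0L) NA_real_ else sum(disc & mask) / n
  }
  full <- matrix(TRUE, nrow(imputed), ncol(imputed))
  byClass <- byClassN <- NULL
  if (!is.null(provenance)) {
    stopifnot(identical(dim(provenance), dim(imputed)))
    cls <- c("RAW_CALLED", "HB_CALLED", "COMPLETED")
    byClass <- vapply(cls, function(k) rate(provenance == k), numeric(1))
    byClassN <- vapply(cls, function(k) sum(cmp & provenance == k),
                       integer(1))
  }
  byAllele <- c(REF = rate(!is.na(comparison) & comparison == 0L),
                ALT = rate(!is.na(comparison) & comparison == 1L))
  acc <- tryCatch(imputationAccuracy(imputed, comparison),
                  error = function(e) NA_real_)
  list(overall = rate(full),
       byClass = byClass,
       byAllele = byAllele,
       imputationAccuracy = acc,
       nCells = list(overall = sum(cmp), byClass = byClassN,
                     byAllele = c(REF = sum(cmp & comparison == 0L),
                                  ALT = sum(cmp & comparison == 1L))))
}

#' Imputation accuracy: mean per-marker genotype correlation
#'
#' For every marker polymorphic in the comparison panel, the Pearson
#' correlation between the 0/1 codes of the two panels over cells called in
#' both; the mean over markers is returned. A marker where either vector is
#' constant contributes 0. Averaging per marker (rather than pooling all
#' cells) gives rare variants the same weight as common ones, which is why
#' this metric penalizes rare-variant errors heavily.
#'
#' @param imputed,comparison call matrices (0/1/\code{NA}) of identical
#'   dimension.
#' @return a single number in \[-1, 1\].
#' @export
imputationAccuracy <- function(imputed, comparison) {
  stopifnot(identical(dim(imputed), dim(comparison)))
  poly <- which(rowSums(comparison == 0L, na.rm = TRUE) > 0 &
                  rowSums(comparison == 1L, na.rm = TRUE) > 0)
  if (length(poly) < 1L)
    stop("no marker is polymorphic in the comparison panel")
  r <- vapply(poly, function(m) {
    ok <- !is.na(imputed[m, ]) & !is.na(comparison[m, ])
    x <- imputed[m, ok]; y <- comparison[m, ok]
    if (length(x) < 2L || sd(x) == 0 || sd(y) == 0) return(0)
    cor(x, y)
  }, numeric(1))
  mean(r)
}

#' Allele-frequency spectrum of a complete panel
#'
#' Per-marker ALT-allele frequencies binned into the supplied edges
#' (left-closed bins, the last bin closed on both sides).
#'
#' @param callsMat complete call matrix (no \code{NA}).
#' @param binEdges increasing bin edges spanning \[0, 1\].
#' @return list with \code{counts}, \code{binEdges}, \code{freq}
#'   (per-marker frequencies) and \code{nonFixed} (count of markers with
#'   frequency strictly between 0 and 1).
#' @export
afSpectrum <- function(callsMat, binEdges = seq(0, 1, by = 0.05)) {
  if (anyNA(callsMat)) stop("panel must be complete (no missing calls)")
  freq <- rowMeans(callsMat == 1L)
  counts <- graphics::hist(freq, breaks = binEdges, right = FALSE,
                           include.lowest = TRUE, plot = FALSE)$counts
  list(counts = counts, binEdges = binEdges, freq = freq,
       nonFixed = sum(freq > 0 & freq < 1))
}

#' Recall and false-positive share of flagged cells
#'
#' Compares predicted against true flag matrices cell-by-cell:
#' recall = |pred AND true| / |true|; false-positive share =
#' |pred AND NOT true| / |pred| (the share of predictions that are wrong).
#' Undefined quantities (empty truth or empty prediction) are \code{NA}.
#'
#' @param predFlags,trueFlags logical matrices of identical dimension.
#' @return list with \code{recall}, \code{falsePositiveShare},
#'   \code{nPred}, \code{nTrue}.
#' @export
cnvMetrics <- function(predFlags, trueFlags) {
  stopifnot(identical(dim(predFlags), dim(trueFlags)))
  nTrue <- sum(trueFlags)
  nPred <- sum(predFlags)
  list(recall = if (nTrue == 0L) NA_real_ else
         sum(predFlags & trueFlags) / nTrue,
       falsePositiveShare = if (nPred == 0L) NA_real_ else
         sum(predFlags & !trueFlags) / nPred,
       nPred = nPred, nTrue = nTrue)
}

#' Single-marker association scan
#'
#' Per marker, the two-sided p-value of the slope in a simple linear
#' regression of the phenotype on the 0/1 allele code — a minimal
#' association test to make region classification testable end-to-end,
#' not a replacement for a mixed-model GWAS. Monomorphic markers get
#' p = 1; zero phenotypic variance yields all p = 1 with a warning. No
#' multiple-testing correction is applied; sweep the significance
#' threshold externally.
#'
#' @param callsMat complete call matrix (markers x lines).
#' @param phenotype numeric vector, one value per line.
#' @return numeric vector of p-values, one per marker.
#' @export
singleMarkerScan <- function(callsMat, phenotype) {
  stopifnot(ncol(callsMat) == length(phenotype))
  if (anyNA(callsMat)) stop("panel must be complete (no missing calls)")
  n <- length(phenotype)
  if (var(phenotype) == 0) {
    warning("phenotype has zero variance; all p-values set to 1")
    return(rep(1, nrow(callsMat)))
  }
  yc <- phenotype - mean(phenotype)
  xc <- callsMat - rowMeans(callsMat)
  num <- as.numeric(xc %*% yc)
  den <- sqrt(rowSums(xc^2) * sum(yc^2))
  p <- rep(1, nrow(callsMat))
  ok <- den > 0
  r <- pmin(pmax(num[ok] / den[ok], -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p[ok] <- 2 * pt(abs(tt), df = n - 2, lower.tail = FALSE)
  p
}

#' Join significant markers into regions and classify against true QTLs
#'
#' Significant markers (p strictly below the threshold) on the same
#' chromosome chain into one region while consecutive significant markers
#' are at most \code{joinDistBp} apart. A region is a true positive iff
#' some QTL lies within \code{hitDistBp} of the region's bp interval (a
#' QTL inside the interval has distance 0). For every QTL hit by at least
#' one true-positive region, the distance from that region's peak (the
#' smallest p-value; tie: the first such marker) to the QTL is reported —
#' the fine-mapping statistic.
#'
#' @param pvalues numeric vector of per-marker p-values.
#' @param positions bp positions, sorted within chromosome.
#' @param qtlPos bp positions of the true QTLs.
#' @param params list from \code{\link{gwasEvalParams}}.
#' @param chrom optional chromosome label per marker (default: one
#'   chromosome).
#' @param qtlChrom optional chromosome label per QTL.
#' @return list with \code{nRegions}, \code{nTruePositive}, \code{tpShare}
#'   (\code{NA} when no region), \code{qtlPeakDistance} (named by QTL
#'   index, only for hit QTLs) and \code{regions} (a \code{data.frame}).
#' @export
gwasRegionClassification <- function(pvalues, positions, qtlPos,
                                     params = gwasEvalParams(),
                                     chrom = NULL, qtlChrom = NULL) {
  stopifnot(length(pvalues) == length(positions))
  if (is.null(chrom)) chrom <- rep("chr1", length(pvalues))
  if (is.null(qtlChrom)) qtlChrom <- rep("chr1", length(qtlPos))
  regions <- list()
  for (ch in unique(chrom)) {
    i <- which(chrom == ch & pvalues < params$pThreshold)
    if (!length(i)) next
    p <- positions[i]
    newReg <- c(TRUE, diff(p) > params$joinDistBp)
    grp <- cumsum(newReg)
    for (g in unique(grp)) {
      j <- i[grp == g]
      peak <- j[which.min(pvalues[j])]
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = ch, startBp = min(positions[j]), endBp = max(positions[j]),
        peakBp = positions[peak], peakP = pvalues[peak],
        nMarkers = length(j), stringsAsFactors = FALSE)
    }
  }
  if (!length(regions))
    return(list(nRegions = 0L, nTruePositive = 0L, tpShare = NA_real_,
                qtlPeakDistance = numeric(0),
                regions = data.frame()))
  reg <- do.call(rbind, regions)
  qtlDist <- function(q, r)  # distance from QTL q to region interval r
    if (qtlPos[q] >= reg$startBp[r] && qtlPos[q] <= reg$endBp[r]) 0 else
      min(abs(qtlPos[q] - reg$startBp[r]), abs(qtlPos[q] - reg$endBp[r]))
  tp <- logical(nrow(reg))
  peakDist <- setNames(rep(NA_real_, length(qtlPos)),
                       seq_along(qtlPos))
  for (r in seq_len(nrow(reg))) {
    for (q in seq_along(qtlPos)) {
      if (qtlChrom[q] != reg$chrom[r]) next
      if (qtlDist(q, r) <= params$hitDistBp) {
        tp[r] <- TRUE
        d <- abs(reg$peakBp[r] - qtlPos[q])
        if (is.na(peakDist[q]) || d < peakDist[q]) peakDist[q] <- d
      }
    }
  }
  reg$truePositive <- tp
  list(nRegions = nrow(reg), nTruePositive = sum(tp),
       tpShare = sum(tp) / nrow(reg),
       qtlPeakDistance = peakDist[!is.na(peakDist)],
       regions = reg)
}
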