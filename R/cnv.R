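#' Nadaraya-Watson kernel smoothing of a depth track
#'
#' Smooths per-marker values along the genome with a Gaussian kernel in
#' physical distance:
#' \deqn{\hat v(x_j) = \frac{\sum_i K((x_j - x_i)/h)\, v_i}{\sum_i K((x_j - x_i)/h)},
#'   \qquad K(u) = e^{-u^2/2},}
#' with \code{bandwidthBp} as the kernel standard deviation \eqn{h}.
#' Gaps (\code{NA}, cells covered by no block) are excluded from both sums;
#' smoothing never crosses chromosome boundaries and is evaluated at marker
#' positions only. A chromosome whose values are all gaps stays all-gap,
#' with a warning.
#'
#' @param values numeric vector or matrix (markers x tracks), \code{NA} for
#'   gaps.
#' @param positions bp coordinates, strictly increasing within a chromosome.
#' @param bandwidthBp Gaussian kernel standard deviation in bp.
#' @param chrom optional chromosome label per marker (default: one
#'   chromosome).
#' @return smoothed values, same shape as \code{values}.
#' @examples
#' smoothTrack(c(0, 1, 0), c(1, 250001, 500001), 250000)
#' @export
smoothTrack <- function(values, positions, bandwidthBp = 250000,
                        chrom = NULL) {
  vec <- is.null(dim(values))
  V <- if (vec) matrix(values, ncol = 1) else as.matrix(values)
  stopifnot(length(positions) == nrow(V), bandwidthBp > 0)
  if (is.null(chrom)) chrom <- rep("chr1", nrow(V))
  out <- V
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    p <- positions[i]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within a chromosome")
    W <- exp(-(outer(p, p, "-") / bandwidthBp)^2 / 2)
    Vi <- V[i, , drop = FALSE]
    has <- !is.na(Vi)
    if (!any(has)) {
      warning("all values are gaps on chromosome ", ch)
      next
    }
    num <- W %*% ifelse(has, Vi, 0)
    den <- W %*% (has * 1)
    S <- num / den
    S[den == 0] <- NA_real_  # track all-gap on this chromosome
    out[i, ] <- S
  }
  if (vec) out[, 1] else out
}

#' Population-average raw read-depth per marker
#'
#' Total raw reads across all haplotypes divided by the number of
#' haplotypes — unweighted, straight from the panel's read counts. This is
#' the reference track the individual block-weighted depth is compared to
#' for CNV classification; smooth it with \code{\link{smoothTrack}} where
#' the individual tracks are smoothed.
#'
#' @param panel a \code{\link{HaplotypePanel}}.
#' @return numeric vector, one value per marker.
#' @examples
#' populationAverageDepth(toyExample()$panel)[4]  # 0.4: 2 reads / 5 haplotypes
#' @export
populationAverageDepth <- function(panel) {
  tot <- refReads(panel) + altReads(panel)
  rowSums(tot) / ncol(tot)
}

#' Classify copy-number state from depth ratios
#'
#' Per cell, the ratio of the individual (block-weighted, optionally
#' smoothed) depth to the population-average depth is thresholded: strictly
#' above \code{dupRatio} is a duplication (\code{DUP}), strictly below
#' \code{delRatio} a deletion (\code{DEL}), in between \code{NONE}. Cells
#' with no depth estimate, or where the population average is zero, are
#' \code{NO_CALL}. Maximal runs of consecutive same-label markers on a
#' chromosome (runs are broken by \code{NO_CALL} and \code{NONE}) merge into
#' one call, with the ratio averaged over the run.
#'
#' With \code{standardize = TRUE} the individual track is first divided by
#' its haplotype's genome-wide mean and the population track by its own
#' mean, so that only relative depth differences drive the classification.
#'
#' @param indiv numeric matrix (markers x haplotypes) of individual depth,
#'   \code{NA} for gaps.
#' @param pop numeric vector of population-average depth per marker.
#' @param markers marker annotation with \code{chrom} and \code{pos}
#'   columns.
#' @param params list from \code{\link{cnvParams}}.
#' @return list with \code{labels} (character matrix in
#'   \{\code{DUP}, \code{DEL}, \code{NONE}, \code{NO_CALL}\}) and
#'   \code{calls} (\code{data.frame}: \code{haplotype}, \code{chrom},
#'   \code{startBp}, \code{endBp} 1-based inclusive, \code{kind},
#'   \code{meanRatio}, \code{nMarkers}).
#' @export
classifyCnv <- function(indiv, pop, markers, params = cnvParams()) {
  indiv <- as.matrix(indiv)
  stopifnot(length(pop) == nrow(indiv), nrow(markers) == nrow(indiv))
  if (is.null(colnames(indiv)))
    colnames(indiv) <- sprintf("H%d", seq_len(ncol(indiv)))
  if (params$standardize) {
    hm <- colMeans(indiv, na.rm = TRUE)
    if (any(hm == 0, na.rm = TRUE))
      stop("cannot standardize: a haplotype has zero mean depth")
    indiv <- sweep(indiv, 2, hm, "/")
    pm <- mean(pop)
    if (pm > 0) pop <- pop / pm
  }
  ratio <- sweep(indiv, 1, pop, "/")
  labels <- matrix("NONE", nrow(indiv), ncol(indiv),
                   dimnames = dimnames(indiv))
  labels[which(ratio > params$dupRatio)] <- "DUP"
  labels[which(ratio < params$delRatio)] <- "DEL"
  zeroPop <- is.na(indiv) | pop <= 0
  if (any(pop == 0 & rowSums(!is.na(indiv)) > 0))
    warning("population depth is zero at some markers; cells set to NO_CALL")
  labels[zeroPop] <- "NO_CALL"
  res <- list()
  for (h in colnames(labels)) {
    for (ch in unique(markers$chrom)) {
      i <- which(markers$chrom == ch)
      lab <- labels[i, h]
      r <- rle(lab)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values %in% c("DUP", "DEL"))) {
        ii <- i[starts[k]:ends[k]]
        res[[length(res) + 1L]] <- data.frame(
          haplotype = h, chrom = ch,
          startBp = markers$pos[ii[1L]],
          endBp = markers$pos[ii[length(ii)]],
          kind = r$values[k],
          meanRatio = mean(ratio[ii, h]),
          nMarkers = length(ii),
          stringsAsFactors = FALSE)
      }
    }
  }
  callsDf <- if (length(res))
    `row.names<-`(do.call(rbind, res), NULL) else
    data.frame(haplotype = character(), chrom = character(),
               startBp = integer(), endBp = integer(), kind = character(),
               meanRatio = numeric(), nMarkers = integer(),
               stringsAsFactors = FALSE)
  list(labels = labels, calls = callsDf)
}

#' Encode CNV calls as binary pseudo-markers
#'
#' One pseudo-marker per distinct (chrom, startBp, endBp, kind) event; each
#' haplotype is coded 1 if it carries an overlapping call of the same kind
#' on that chromosome, 0 otherwise. Pseudo-markers are appended after the
#' last real marker of their chromosome, flagged \code{isSnp = FALSE}, with
#' zero read counts and allele labels \code{N} / \code{<DUP>} or
#' \code{<DEL>}.
#'
#' @param cnvCalls \code{data.frame} as returned in the \code{calls}
#'   component of \code{\link{classifyCnv}}.
#' @param panel the \code{\link{HaplotypePanel}} to append to.
#' @return a new \code{HaplotypePanel}; unchanged if \code{cnvCalls} is
#'   empty.
#' @export
cnvBinaryMarkers <- function(cnvCalls, panel) {
  if (nrow(cnvCalls) == 0L) return(panel)
  ev <- unique(cnvCalls[, c("chrom", "startBp", "endBp", "kind")])
  ev <- ev[order(ev$chrom, ev$startBp, ev$endBp, ev$kind), , drop = FALSE]
  haps <- haplotypeIds(panel)
  codes <- matrix(0L, nrow(ev), length(haps),
                  dimnames = list(NULL, haps))
  for (j in seq_len(nrow(ev))) {
    hit <- cnvCalls$chrom == ev$chrom[j] & cnvCalls$kind == ev$kind[j] &
      cnvCalls$startBp <= ev$endBp[j] & cnvCalls$endBp >= ev$startBp[j]
    codes[j, unique(cnvCalls$haplotype[hit])] <- 1L
  }
  info <- markerInfo(panel)
  newInfo <- data.frame(
    chrom = ev$chrom, pos = ev$startBp, end = ev$endBp,
    ref = "N", alt = paste0("<", ev$kind, ">"),
    markerId = sprintf("%s_%d_%d_%s", ev$chrom, ev$startBp, ev$endBp,
                       ev$kind),
    isSnp = FALSE, stringsAsFactors = FALSE)
  # interleave: pseudo-markers follow the last real marker of their chromosome
  ord <- order(match(c(info$chrom, newInfo$chrom), unique(info$chrom)),
               c(rep(0L, nrow(info)), rep(1L, nrow(newInfo))))
  allInfo <- rbind(info[, names(newInfo)], newInfo)[ord, , drop = FALSE]
  allCalls <- rbind(calls(panel), codes)[ord, , drop = FALSE]
  allRef <- rbind(refReads(panel),
                  matrix(0L, nrow(ev), length(haps)))[ord, , drop = FALSE]
  allAlt <- rbind(altReads(panel),
                  matrix(0L, nrow(ev), length(haps)))[ord, , drop = FALSE]
  HaplotypePanel(allCalls, allRef, allAlt, allInfo, haplotypeIds = haps)
}

#' Flag markers with high standardized smoothed depth
#'
#' Each haplotype's smoothed track is divided by its genome-wide mean over
#' estimated cells; cells strictly above \code{threshold} are flagged. Cells
#' with no depth estimate are never flagged.
#'
#' @param smoothed numeric matrix (markers x haplotypes) of smoothed depth,
#'   \code{NA} for gaps.
#' @param threshold standardized depth cutoff (default 1.5).
#' @return logical matrix of the same shape.
#' @export
highDepthFlags <- function(smoothed, threshold = 1.5) {
  smoothed <- as.matrix(smoothed)
  hm <- colMeans(smoothed, na.rm = TRUE)
  std <- sweep(smoothed, 2, hm, "/")
  flags <- std > threshold
  flags[is.na(flags)] <- FALSE
  flags
}
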