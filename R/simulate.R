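#' Configuration of the doubled-haploid population simulator
#'
#' The generator emulates the study design the calling step is aimed at: a
#' panel of fully homozygous doubled-haploid (DH) lines derived from a
#' diverse founder population, whole-genome sequenced at very low depth.
#' Each line is a mosaic of founder haplotypes with long shared segments
#' (the source of local IBD that haplotype blocks detect); sequencing is
#' per-marker Poisson read sampling with a per-read miscall probability;
#' copy-number events scale the local Poisson mean for carrier lines.
#'
#' @param nFounders number of founder haplotypes.
#' @param nLines number of DH lines.
#' @param nMarkers markers per chromosome.
#' @param nChrom number of chromosomes.
#' @param chromLengthBp chromosome length in bp.
#' @param expectedCrossovers Poisson mean of crossovers per line per
#'   chromosome.
#' @param mafLow,mafHigh bounds of the uniform founder ALT-allele frequency
#'   per marker.
#' @param meanDepth expected reads per cell (0.5 = 0.5X sequencing).
#' @param errorRate per-read probability of reporting the wrong allele.
#' @param cnvEvents list of events, each a list with \code{chrom},
#'   \code{startBp}, \code{endBp}, \code{kind} (\code{"DUP"}/\code{"DEL"}),
#'   \code{multiplier} (local depth scale for carriers) and
#'   \code{carrierFrac} (each line carries the event independently with
#'   this probability).
#' @param seed integer seed; the whole simulation is deterministic given
#'   the config.
#' @return a validated named list of class \code{SimConfig}.
#' @export
simConfig <- function(nFounders = 10, nLines = 200, nMarkers = 2000,
                      nChrom = 1, chromLengthBp = 2e8,
                      expectedCrossovers = 1, mafLow = 0.1, mafHigh = 0.9,
                      meanDepth = 0.5, errorRate = 0.01,
                      cnvEvents = list(), seed = 1L) {
  stopifnot(nFounders >= 2, nLines >= 1, nMarkers >= 1, nChrom >= 1,
            chromLengthBp >= nMarkers, expectedCrossovers >= 0,
            mafLow >= 0, mafHigh <= 1, mafLow <= mafHigh,
            meanDepth > 0, errorRate >= 0, errorRate < 0.5,
            abs(seed) < 2^31 - 2)
  structure(list(nFounders = as.integer(nFounders),
                 nLines = as.integer(nLines),
                 nMarkers = as.integer(nMarkers),
                 nChrom = as.integer(nChrom),
                 chromLengthBp = chromLengthBp,
                 expectedCrossovers = expectedCrossovers,
                 mafLow = mafLow, mafHigh = mafHigh,
                 meanDepth = meanDepth, errorRate = errorRate,
                 cnvEvents = cnvEvents, seed = as.integer(seed)),
            class = "SimConfig")
}

#' Simulate a doubled-haploid population with known truth
#'
#' Founder haplotypes are drawn independently per marker with ALT
#' frequency uniform on \[\code{mafLow}, \code{mafHigh}\]; marker positions
#' are uniform (sorted, distinct) on \[1, \code{chromLengthBp}\]; each line
#' is a founder mosaic with a Poisson number of uniformly placed
#' crossovers. CNV events from the config are injected afterwards via
#' \code{\link{injectCnvs}}.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return a \code{TruthSet}: list with \code{calls} (complete truth
#'   matrix, markers x lines), \code{markers} (annotation), \code{segments}
#'   (founder mosaic: line, chrom, startM, endM 0-based half-open,
#'   founder), \code{founders} (markers x founders matrix),
#'   \code{multiplier} (true per-cell depth multiplier), \code{carriers}
#'   (event x line logical matrix), \code{cfg}.
#' @export
simulatePopulation <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  lines <- sprintf("L%03d", seq_len(cfg$nLines))
  founderIds <- sprintf("F%02d", seq_len(cfg$nFounders))
  markerList <- list(); founderList <- list(); callList <- list()
  segs <- list()
  for (c_i in seq_len(cfg$nChrom)) {
    ch <- paste0("chr", c_i)
    pos <- sort(sample.int(cfg$chromLengthBp, cfg$nMarkers))
    freq <- runif(cfg$nMarkers, cfg$mafLow, cfg$mafHigh)
    fnd <- matrix(rbinom(cfg$nMarkers * cfg$nFounders, 1L, freq),
                  cfg$nMarkers, cfg$nFounders,
                  dimnames = list(NULL, founderIds))
    cl <- matrix(NA_integer_, cfg$nMarkers, cfg$nLines,
                 dimnames = list(NULL, lines))
    for (l in seq_len(cfg$nLines)) {
      nCross <- rpois(1L, cfg$expectedCrossovers)
      bp <- sort(runif(nCross, 1, cfg$chromLengthBp))
      bounds <- c(0, bp, cfg$chromLengthBp + 1)
      fids <- sample.int(cfg$nFounders, nCross + 1L, replace = TRUE)
      for (s in seq_len(nCross + 1L)) {
        inSeg <- which(pos >= bounds[s] & pos < bounds[s + 1L])
        if (!length(inSeg)) next
        cl[inSeg, l] <- fnd[inSeg, fids[s]]
        segs[[length(segs) + 1L]] <- data.frame(
          line = lines[l], chrom = ch,
          startM = min(inSeg) - 1L, endM = max(inSeg),
          founder = founderIds[fids[s]], stringsAsFactors = FALSE)
      }
    }
    markerList[[c_i]] <- data.frame(chrom = ch, pos = pos, ref = "A",
                                    alt = "T", stringsAsFactors = FALSE)
    founderList[[c_i]] <- fnd
    callList[[c_i]] <- cl
  }
  truth <- list(
    calls = do.call(rbind, callList),
    markers = do.call(rbind, markerList),
    founders = do.call(rbind, founderList),
    segments = do.call(rbind, segs),
    multiplier = matrix(1, cfg$nChrom * cfg$nMarkers, cfg$nLines,
                        dimnames = list(NULL, lines)),
    carriers = NULL,
    cfg = cfg)
  class(truth) <- "TruthSet"
  if (length(cfg$cnvEvents))
    truth <- injectCnvs(truth, cfg$cnvEvents)
  truth
}

#' Inject copy-number events into a truth set
#'
#' Each event assigns its depth multiplier (e.g. 2.0 for a duplication,
#' 0-0.3 for a deletion) over its bp region to a random carrier subset of
#' lines: every line carries the event independently with probability
#' \code{carrierFrac}. Overlapping events on the same line are an error
#' (keeps the test geometry simple).
#'
#' @param truth a \code{TruthSet} from \code{\link{simulatePopulation}}.
#' @param events list of event lists (see \code{\link{simConfig}}).
#' @param seed optional seed; default: continue from the current RNG state
#'   (\code{simulatePopulation} applies config events under the config
#'   seed).
#' @return the updated \code{TruthSet} with \code{multiplier} and
#'   \code{carriers} filled.
#' @export
injectCnvs <- function(truth, events, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nLines <- ncol(truth$multiplier)
  carriers <- matrix(FALSE, length(events), nLines,
                     dimnames = list(NULL, colnames(truth$multiplier)))
  touched <- matrix(FALSE, nrow(truth$multiplier), nLines)
  for (e in seq_along(events)) {
    ev <- events[[e]]
    stopifnot(all(c("chrom", "startBp", "endBp", "kind", "multiplier",
                    "carrierFrac") %in% names(ev)))
    if (ev$startBp < 1 || ev$endBp > truth$cfg$chromLengthBp)
      stop("event region outside chromosome bounds")
    rows <- which(truth$markers$chrom == ev$chrom &
                    truth$markers$pos >= ev$startBp &
                    truth$markers$pos <= ev$endBp)
    carry <- rbinom(nLines, 1L, ev$carrierFrac) == 1L
    carriers[e, ] <- carry
    if (any(touched[rows, carry]))
      stop("overlapping CNV events on the same line are not supported")
    touched[rows, carry] <- TRUE
    truth$multiplier[rows, carry] <- ev$multiplier
  }
  truth$carriers <- carriers
  truth$events <- events
  truth
}

#' Sample low-depth sequencing reads from a truth set
#'
#' Per cell, the total read count is Poisson with mean
#' \code{meanDepth} x local CNV multiplier; each read reports the true
#' allele with probability 1 - \code{errorRate} and the other allele
#' otherwise. The raw call is the majority allele among the cell's reads;
#' zero reads or an exact tie leave the cell missing — a simple surrogate
#' for the upstream variant caller, which the block-based step is agnostic
#' to.
#'
#' @param truth a \code{TruthSet}.
#' @param cfg the \code{\link{simConfig}} (defaults to the truth's own).
#' @return a \code{\link{HaplotypePanel}} of raw calls and read counts.
#' @export
sampleReads <- function(truth, cfg = truth$cfg) {
  set.seed(cfg$seed + 1L)
  n <- length(truth$calls)
  reads <- matrix(rpois(n, cfg$meanDepth * truth$multiplier),
                  nrow(truth$calls), ncol(truth$calls))
  wrong <- matrix(rbinom(n, reads, cfg$errorRate),
                  nrow(reads), ncol(reads))
  right <- reads - wrong
  isAlt <- truth$calls == 1L
  ar <- ifelse(isAlt, right, wrong)
  rr <- ifelse(isAlt, wrong, right)
  cl <- matrix(NA_integer_, nrow(reads), ncol(reads))
  cl[which(ar > rr)] <- 1L
  cl[which(rr > ar)] <- 0L
  HaplotypePanel(cl, rr, ar, truth$markers,
                 haplotypeIds = colnames(truth$calls))
}

#' Simulate a quantitative trait from the truth matrix
#'
#' QTL positions are drawn among markers with minor allele frequency of at
#' least 0.1; all QTLs receive the same allele-substitution effect (+1 per
#' ALT allele, 0/1 haploid coding). Environmental noise variance is set so
#' that the genetic share of phenotypic variance equals \code{h2} in
#' expectation.
#'
#' @param truth a \code{TruthSet}.
#' @param nQtl number of QTLs (default 10).
#' @param h2 trait heritability (default 0.5).
#' @param seed seed for QTL placement and noise (default derived from the
#'   config seed so the end-to-end simulation is deterministic).
#' @param minMaf minimum minor allele frequency of eligible markers.
#' @return list with \code{phenotype}, \code{genetic} (true genetic
#'   values), \code{qtlRows} (marker row indices), \code{qtlChrom},
#'   \code{qtlPos} (bp), \code{effects}, \code{h2}.
#' @export
simulateTrait <- function(truth, nQtl = 10, h2 = 0.5,
                          seed = truth$cfg$seed + 2L, minMaf = 0.1) {
  stopifnot(h2 > 0, h2 <= 1)
  set.seed(seed)
  freq <- rowMeans(truth$calls)
  eligible <- which(pmin(freq, 1 - freq) >= minMaf)
  if (length(eligible) < nQtl)
    stop("fewer than ", nQtl, " markers with MAF >= ", minMaf)
  qtl <- sort(sample(eligible, nQtl))
  effects <- rep(1, nQtl)
  g <- as.numeric(effects %*% truth$calls[qtl, , drop = FALSE])
  if (h2 < 1) {
    varE <- var(g) * (1 - h2) / h2
    y <- g + rnorm(length(g), 0, sqrt(varE))
  } else y <- g
  list(phenotype = y, genetic = g, qtlRows = qtl,
       qtlChrom = truth$markers$chrom[qtl],
       qtlPos = truth$markers$pos[qtl],
       effects = effects, h2 = h2)
}
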