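# Fixtures built in code and brute-force oracles used across test files.

# Random panel: calls 0/1/NA; every called cell gets >= 0 reads of the
# called allele plus occasional opposite-allele reads; some calls carry
# zero reads (asserted by the "file" only).
randomPanel <- function(nMarkers = 30, nHaps = 6, seed = 1,
                        missingFrac = 0.3, chrom = "chr1") {
  set.seed(seed)
  haps <- sprintf("H%d", seq_len(nHaps))
  cl <- matrix(sample(c(0L, 1L), nMarkers * nHaps, replace = TRUE),
               nMarkers, nHaps, dimnames = list(NULL, haps))
  cl[matrix(runif(nMarkers * nHaps) < missingFrac, nMarkers)] <- NA
  rr <- matrix(0L, nMarkers, nHaps, dimnames = list(NULL, haps))
  ar <- matrix(0L, nMarkers, nHaps, dimnames = list(NULL, haps))
  nr <- matrix(rpois(nMarkers * nHaps, 1.2), nMarkers, nHaps)
  rr[which(cl == 0L)] <- nr[which(cl == 0L)]
  ar[which(cl == 1L)] <- nr[which(cl == 1L)]
  # sprinkle a minority read on some read-backed ALT cells (keeps raw
  # calls consistent with their own read majority, as a caller would)
  extra <- which(!is.na(cl) & cl == 1L & nr >= 2L &
                   runif(nMarkers * nHaps) < 0.1)
  rr[extra] <- rr[extra] + 1L
  markers <- data.frame(chrom = chrom,
                        pos = sort(sample.int(nMarkers * 1000L, nMarkers)),
                        ref = "A", alt = "T")
  HaplotypePanel(cl, rr, ar, markers, haplotypeIds = haps)
}

randomLibrary <- function(nHaps = 6, nMarkers = 30, nBlocks = 4, seed = 1,
                          chrom = "chr1") {
  set.seed(seed)
  haps <- sprintf("H%d", seq_len(nHaps))
  startM <- integer(0); endM <- integer(0); members <- list()
  for (b in seq_len(nBlocks)) {
    s <- sample.int(nMarkers, 1L) - 1L
    e <- min(nMarkers, s + sample(2:max(3, nMarkers %/% 2), 1L))
    m <- sort(sample(haps, sample(2:nHaps, 1L)))
    startM <- c(startM, s); endM <- c(endM, e)
    members <- c(members, list(m))
  }
  BlockLibrary(blockId = sprintf("b%d", seq_len(nBlocks)),
               chrom = rep(chrom, nBlocks),
               startM = startM, endM = endM, members = members)
}

# Brute-force neighbor lookup straight from the definition.
bruteNeighbors <- function(lib, h, m, chrom = "chr1") {
  bl <- blocks(lib)
  out <- character(0)
  for (i in seq_len(nrow(bl)))
    if (bl$chrom[i] == chrom && bl$startM[i] <= m && bl$endM[i] > m &&
        h %in% bl$members[[i]])
      out <- union(out, bl$members[[i]])
  setdiff(out, h)
}

# Cell-by-cell weighted merge oracle.
bruteMerge <- function(panel, lib, selfWeight = 5) {
  R <- refReads(panel); A <- altReads(panel)
  haps <- haplotypeIds(panel)
  info <- markerInfo(panel)
  wR <- selfWeight * R; wA <- selfWeight * A
  nN <- 0 * R; cov <- R == -1
  for (m in seq_len(nrow(R))) {
    for (h in seq_along(haps)) {
      nb <- bruteNeighbors(lib, haps[h], info$chromIndex[m], info$chrom[m])
      for (g in nb) {
        wR[m, h] <- wR[m, h] + R[m, g]
        wA[m, h] <- wA[m, h] + A[m, g]
      }
      nN[m, h] <- length(nb)
      bl <- blocks(lib)
      cov[m, h] <- any(vapply(seq_len(nrow(bl)), function(i)
        bl$chrom[i] == info$chrom[m] &&
          bl$startM[i] <= info$chromIndex[m] &&
          bl$endM[i] > info$chromIndex[m] &&
          haps[h] %in% bl$members[[i]], logical(1)))
    }
  }
  list(wRef = wR, wAlt = wA, nNeighbors = nN, covered = cov)
}

# Double-loop Nadaraya-Watson oracle.
bruteSmooth <- function(v, pos, h) {
  out <- rep(NA_real_, length(v))
  for (j in seq_along(v)) {
    num <- 0; den <- 0
    for (i in seq_along(v)) {
      if (is.na(v[i])) next
      w <- exp(-((pos[j] - pos[i]) / h)^2 / 2)
      num <- num + w * v[i]; den <- den + w
    }
    if (den > 0) out[j] <- num / den
  }
  out
}

# Group-by-window-string block-finder oracle (single chromosome).
bruteFinder <- function(mat, windowSize, minMembers, extend) {
  k <- nrow(mat)
  starts <- seq(0L, k - 1L, by = windowSize)
  raw <- list()
  for (s in starts) {
    e <- min(s + windowSize, k)
    key <- apply(mat[(s + 1L):e, , drop = FALSE], 2, paste, collapse = "")
    for (g in split(colnames(mat), key)) {
      if (length(g) < minMembers) next
      raw[[length(raw) + 1L]] <- list(startM = s, endM = e,
                                      members = sort(g))
    }
  }
  if (extend) {
    merged <- list()
    for (b in raw) {
      id <- paste(b$members, collapse = ",")
      prev <- merged[[id]]
      if (!is.null(prev) && prev[[length(prev)]]$endM == b$startM) {
        prev[[length(prev)]]$endM <- b$endM
        merged[[id]] <- prev
      } else merged[[id]] <- c(prev, list(b))
    }
    raw <- do.call(c, unname(merged))
  }
  if (!length(raw))
    return(data.frame(startM = integer(), endM = integer(),
                      key = character()))
  df <- do.call(rbind, lapply(raw, function(b)
    data.frame(startM = b$startM, endM = b$endM,
               key = paste(b$members, collapse = ","))))
  df[order(df$startM, df$key), , drop = FALSE]
}

# Interval-chaining oracle for GWAS regions (single chromosome).
bruteRegions <- function(p, pos, thr, joinDist) {
  sig <- which(p < thr)
  if (!length(sig)) return(data.frame())
  out <- list()
  cur <- sig[1]
  for (i in sig[-1]) {
    if (pos[i] - pos[cur[length(cur)]] <= joinDist) cur <- c(cur, i)
    else { out[[length(out) + 1L]] <- cur; cur <- i }
  }
  out[[length(out) + 1L]] <- cur
  do.call(rbind, lapply(out, function(j)
    data.frame(startBp = min(pos[j]), endBp = max(pos[j]))))
}

# Shared benchmark population (small): built once per test run.
benchSim <- function(seed = 42, nLines = 60, nMarkers = 400,
                     meanDepth = 0.5, errorRate = 0.01,
                     cnvEvents = list()) {
  cfg <- simConfig(nFounders = 6, nLines = nLines, nMarkers = nMarkers,
                   chromLengthBp = 4e7, expectedCrossovers = 1,
                   meanDepth = meanDepth, errorRate = errorRate,
                   cnvEvents = cnvEvents, seed = seed)
  truth <- simulatePopulation(cfg)
  panel <- sampleReads(truth, cfg)
  lib <- findBlocksWindowed(truth$calls, truth$markers)
  list(cfg = cfg, truth = truth, panel = panel, lib = lib)
}
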