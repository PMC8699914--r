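toy <- toyExample()

test_that("read merging weights own reads by the self-weight", {
  s <- mergeReads(toy$panel, toy$library)
  # own ALT read x5 vs one neighbor REF read
  expect_equal(unname(wAlt(s)[5, "H1"]), 5)
  expect_equal(unname(wRef(s)[5, "H1"]), 1)
  # own cell missing: neighbors only
  expect_equal(unname(wAlt(s)[1, "H1"]), 2)
  expect_equal(unname(wRef(s)[1, "H1"]), 0)
  # uncovered cell with no reads
  lib1 <- BlockLibrary("a", "chr1", 0L, 10L, list(c("H1", "H2")))
  s2 <- mergeReads(toy$panel, lib1)
  expect_equal(unname(wRef(s2)[1, "H5"]) + unname(wAlt(s2)[1, "H5"]), 0)
  expect_false(covered(s2)[1, "H5"])
  # weighted haplotype count: self-weight + #neighbors when covered
  expect_equal(unname(wHaps(s)[4, "H1"]), 7)
  expect_equal(unname(wHaps(s)[4, "H4"]), 6)
})

test_that("merging matches a cell-by-cell brute-force oracle", {
  for (seed in 1:4) {
    panel <- randomPanel(nMarkers = 40, nHaps = 7, seed = seed)
    lib <- randomLibrary(nHaps = 7, nMarkers = 40, nBlocks = 5,
                         seed = seed + 10)
    s <- mergeReads(panel, lib)
    want <- bruteMerge(panel, lib, selfWeight = 5)
    expect_equal(wRef(s), want$wRef)
    expect_equal(wAlt(s), want$wAlt)
    expect_equal(unname(wHaps(s)), unname(5 + want$nNeighbors))
    expect_equal(unname(covered(s)), unname(want$covered))
    # conservation: weighted total = selfWeight*own + sum of neighbor reads
    tot <- refReads(panel) + altReads(panel)
    expect_equal(wRef(s) + wAlt(s),
                 5 * tot + (want$wRef - 5 * refReads(panel)) +
                   (want$wAlt - 5 * altReads(panel)))
  }
})

test_that("consensus calling applies the at-least-80% share rule", {
  mk <- function(wr, wa) {
    new("WeightedSupport", wRef = matrix(wr), wAlt = matrix(wa),
        nNeighbors = matrix(2L), coveredCells = matrix(TRUE),
        selfWeight = 5, markers = data.frame(chrom = "chr1", pos = 1))
  }
  expect_equal(callFromSupport(mk(1, 5))[1], 1L)   # 5/6 >= 0.8
  expect_equal(callFromSupport(mk(5, 1))[1], 0L)   # own reads dominate
  expect_true(is.na(callFromSupport(mk(1, 1))[1])) # 50/50
  expect_equal(callFromSupport(mk(1, 4))[1], 1L)   # exactly 0.8 counts
  expect_true(is.na(callFromSupport(mk(1.01, 4))[1]))  # just below
  expect_true(is.na(callFromSupport(mk(0, 0))[1]))     # no reads, no call
})

test_that("toy consensus calls at SNP 5 are ALT / REF / missing", {
  cl <- callFromSupport(mergeReads(toy$panel, toy$library))
  expect_equal(unname(cl[5, c("H1", "H2")]), c(1L, 0L))
  expect_true(is.na(cl[5, "H3"]))
})

test_that("finalize inserts raw calls, allows overwrite, never erases", {
  raw <- toy$panel
  hb <- matrix(NA_integer_, 10, 5, dimnames = dimnames(calls(raw)))
  hb[1, "H1"] <- 1L     # newly called
  hb[5, "H2"] <- 1L     # overwrites the raw REF call
  fin <- finalizeCalls(hb, raw)
  expect_equal(unname(fin$calls[1, "H1"]), 1L)
  expect_equal(fin$provenance[1, "H1"], "HB_CALLED")
  expect_equal(unname(fin$calls[5, "H2"]), 1L)       # overwritten
  expect_equal(fin$provenance[5, "H2"], "RAW_CALLED") # provenance kept
  expect_equal(unname(fin$calls[1, "H2"]), 1L)       # raw call re-inserted
  expect_equal(fin$provenance[2, "H1"], "MISSING")
  # no called cell ever becomes missing
  expect_true(all(!is.na(fin$calls[!is.na(calls(raw))])))
})

test_that("estimated depths reproduce the worked example at SNP 4", {
  d <- depthMatrix(estimateDepth(mergeReads(toy$panel, toy$library)))
  expect_equal(unname(d[4, ]), c(2 / 7, 6 / 7, 6 / 7, 0, 0),
               tolerance = 1e-12)
  # gaps exactly where no block covers the cell (H5 on SNPs 6-10)
  expect_true(all(is.na(d[6:10, "H5"])))
  expect_false(anyNA(d[1:5, ]))
})

test_that("marker filters use the pre-filter overall mean and strict bounds", {
  dep <- matrix(c(1.0, 0.4, 1.6), 3, 4)  # per-marker means 1.0/0.4/1.6
  cl <- matrix(0L, 3, 4)
  dt <- new("DepthTrack", depth = dep, hapMeans = colMeans(dep),
            markers = data.frame(chrom = "chr1", pos = 1:3))
  flt <- filterMarkers(cl, dt)
  expect_equal(flt$keep, c(1L, 3L))
  expect_equal(flt$dropLog$reason, "LOW_DEPTH")
  # missingness: strictly more than 50% drops; exactly 50% is retained
  cl2 <- matrix(0L, 2, 10)
  cl2[1, 1:6] <- NA  # 60%
  cl2[2, 1:5] <- NA  # 50%
  dt2 <- new("DepthTrack", depth = matrix(1, 2, 10), hapMeans = rep(1, 10),
             markers = data.frame(chrom = "chr1", pos = 1:2))
  flt2 <- filterMarkers(cl2, dt2)
  expect_equal(flt2$keep, 2L)
  expect_equal(flt2$dropLog$reason, "HIGH_MISSING")
  expect_error(filterMarkers(cl2[1, , drop = FALSE],
                             new("DepthTrack",
                                 depth = matrix(1, 1, 10),
                                 hapMeans = rep(1, 10),
                                 markers = data.frame(chrom = "chr1",
                                                      pos = 1))),
               "all markers")
})

test_that("naive completion fills by neighbor majority then population", {
  lib <- BlockLibrary("a", "chr1", 0L, 3L,
                      list(c("H1", "H2", "H3", "H4", "H5")))
  cl <- matrix(NA_integer_, 3, 6,
               dimnames = list(NULL, sprintf("H%d", 1:6)))
  cl[1, 2:5] <- c(1L, 1L, 1L, 0L)       # 3 ALT vs 1 REF neighbors for H1
  cl[2, 2:3] <- c(1L, 0L)               # neighbor tie for H1
  cl[2, 6] <- 1L                        # population: 2 ALT vs 1 REF
  # marker 3 entirely missing
  expect_warning(res <- naiveComplete(cl, lib), "population-wide")
  expect_equal(unname(res$calls[1, "H1"]), 1L)   # neighbor majority
  expect_equal(unname(res$calls[2, "H1"]), 1L)   # tie -> population majority
  expect_equal(unname(res$calls[2, "H6"]), 1L)   # H6 uncovered -> population
  expect_equal(unname(res$calls[3, ]), rep(0L, 6))  # all-missing -> REF
  expect_false(anyNA(res$calls))
  expect_true(all(res$completed[is.na(cl)]))
  # population tie breaks toward REF
  cl2 <- matrix(c(0L, 1L, NA), 1, 3)
  res2 <- naiveComplete(cl2, BlockLibrary())
  expect_equal(unname(res2$calls[1, 3]), 0L)
})

test_that("the composed step reproduces the toy end-to-end", {
  # the sparse toy would not survive the missingness filter; disable the
  # quality filters to inspect the calling stages themselves
  res <- runHBStep(toy$panel, toy$library,
                   hbParams(minDepthFrac = 0, maxMissing = 1),
                   complete = FALSE)
  expect_equal(res$summary$markersDropped, 0L)
  cl <- calls(res$panel)
  expect_equal(unname(cl[5, c("H1", "H2")]), c(1L, 0L))
  expect_true(is.na(cl[5, "H3"]))
  expect_equal(unname(cl[1, 1:3]), c(1L, 1L, 1L))
  expect_lte(res$summary$postMissing, res$summary$preMissing)
  d <- depthMatrix(res$depth)
  expect_equal(unname(d[4, ]), c(2 / 7, 6 / 7, 6 / 7, 0, 0))
})

test_that("an empty library degenerates to the raw panel", {
  panel <- randomPanel(nMarkers = 40, nHaps = 8, seed = 6,
                       missingFrac = 0.25)
  res <- runHBStep(panel, BlockLibrary(), complete = FALSE)
  keep <- setdiff(seq_len(nrow(panel)), res$dropLog$row)
  expect_equal(calls(res$panel), calls(panel)[keep, ])
  expect_true(all(is.na(depthMatrix(res$depth))))
})

test_that("missingness never increases through the block step", {
  b <- benchSim(seed = 5, nLines = 50, nMarkers = 300)
  res <- runHBStep(b$panel, b$lib, complete = FALSE)
  expect_lte(res$summary$postMissing, res$summary$preMissing)
})

test_that("homogeneous blocks leave existing calls unchanged", {
  # every member of every block has identical, fully read-backed calls
  set.seed(8)
  cl <- matrix(rep(rbinom(30, 1, 0.5), 4), 30, 4)
  storage.mode(cl) <- "integer"
  colnames(cl) <- sprintf("H%d", 1:4)
  rr <- (cl == 0L) * 1L; ar <- (cl == 1L) * 1L
  panel <- HaplotypePanel(cl, rr, ar,
                          data.frame(chrom = "chr1", pos = 1:30 * 10L,
                                     ref = "A", alt = "T"))
  lib <- BlockLibrary("a", "chr1", 0L, 30L, list(colnames(cl)))
  res <- runHBStep(panel, lib, complete = FALSE)
  expect_equal(res$summary$markersDropped, 0L)
  expect_equal(calls(res$panel), calls(panel))
})

test_that("a huge self-weight makes cells follow their own reads", {
  panel <- randomPanel(nMarkers = 30, nHaps = 6, seed = 2)
  lib <- randomLibrary(nHaps = 6, nMarkers = 30, nBlocks = 4, seed = 3)
  s <- mergeReads(panel, lib, hbParams(selfWeight = 1e6))
  cl <- callFromSupport(s, hbParams(selfWeight = 1e6))
  rr <- refReads(panel); ar <- altReads(panel)
  # unanimous own reads always yield the own allele, whatever the block says
  unan <- which((rr > 0) != (ar > 0))
  expect_equal(cl[unan], ifelse(ar[unan] > 0, 1L, 0L))
  # no called cell with own reads ever contradicts its own majority
  own <- which(rr + ar > 0 & rr != ar & !is.na(cl))
  expect_equal(cl[own], ifelse(ar[own] > rr[own], 1L, 0L))
})

test_that("raising the share threshold never yields more consensus calls", {
  panel <- randomPanel(nMarkers = 50, nHaps = 8, seed = 4)
  lib <- randomLibrary(nHaps = 8, nMarkers = 50, nBlocks = 6, seed = 5)
  s <- mergeReads(panel, lib)
  nCalled <- vapply(c(0.6, 0.7, 0.8, 0.9, 1.0), function(th)
    sum(!is.na(callFromSupport(s, hbParams(minShare = th)))), numeric(1))
  expect_true(all(diff(nCalled) <= 0))
})

test_that("overwriting a raw call needs 4x opposition at self-weight 5", {
  # one own REF read (weighted 5): ALT is called iff neighbor ALT >= 4*5
  mkPanel <- function(nbAltReads) {
    n <- 2 + 1
    cl <- matrix(NA_integer_, 1, n, dimnames = list(NULL, c("H1", "N1", "N2")))
    rr <- ar <- matrix(0L, 1, n, dimnames = dimnames(cl))
    cl[1, "H1"] <- 0L; rr[1, "H1"] <- 1L
    cl[1, c("N1", "N2")] <- 1L
    ar[1, "N1"] <- ceiling(nbAltReads / 2)
    ar[1, "N2"] <- floor(nbAltReads / 2)
    HaplotypePanel(cl, rr, ar, data.frame(chrom = "chr1", pos = 100L,
                                          ref = "A", alt = "T"))
  }
  lib <- BlockLibrary("a", "chr1", 0L, 1L, list(c("H1", "N1", "N2")))
  for (nb in c(19, 20, 21)) {
    panel <- mkPanel(nb)
    res <- runHBStep(panel, lib, complete = FALSE)
    got <- unname(calls(res$panel)[1, "H1"])
    if (nb >= 20) expect_equal(got, 1L) else expect_equal(got, 0L)
  }
})
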