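#' BlockLibrary: a library of haplotype blocks
#'
#' A haplotype block is a marker interval together with the set of haplotypes
#' whose sequences over that interval are identical, indicating local
#' group-wise identity-by-descent. Blocks may overlap both in markers and in
#' members; all queries take unions over covering blocks.
#'
#' Marker coordinates are 0-based half-open indices into the panel's SNP
#' marker list *for that chromosome* (the \code{chromIndex} column of
#' \code{\link{markerInfo}}). On-disk interchange (\code{\link{readBlockLibrary}})
#' uses 1-based inclusive indices.
#'
#' @param blockId character vector of block identifiers.
#' @param chrom character vector of chromosome labels.
#' @param startM,endM integer vectors; 0-based half-open marker interval.
#' @param members list of character vectors of haplotype identifiers.
#' @param x a \code{BlockLibrary}.
#'
#' @return \code{BlockLibrary()} returns a validated object; \code{blocks()}
#'   a \code{data.frame} (one row per block, \code{members} a list column);
#'   \code{length()} the number of blocks.
#'
#' @examples
#' lib <- toyExample()$library
#' blocks(lib)
#' blockNeighbors(lib, "H1", 3)
#'
#' @aliases blocks
#' @export
setClass("BlockLibrary", representation(
  blockId = "character",
  chrom = "character",
  startM = "integer",
  endM = "integer",
  members = "list"))

.validBlockLibrary <- function(object) {
  n <- length(object@blockId)
  if (length(object@chrom) != n || length(object@startM) != n ||
      length(object@endM) != n || length(object@members) != n)
    return("all slots must have one entry per block")
  if (n == 0L) return(TRUE)
  msg <- character()
  if (any(object@startM < 0L)) msg <- c(msg, "startM must be >= 0")
  if (any(object@startM >= object@endM))
    msg <- c(msg, "startM must be < endM (0-based half-open)")
  if (any(!vapply(object@members, function(m)
    is.character(m) && length(m) > 0L && !anyDuplicated(m), logical(1))))
    msg <- c(msg, "each block needs a non-empty, duplicate-free member set")
  if (anyDuplicated(object@blockId)) msg <- c(msg, "blockId must be unique")
  if (length(msg)) msg else TRUE
}

setValidity("BlockLibrary", .validBlockLibrary)

#' @rdname BlockLibrary-class
#' @export
BlockLibrary <- function(blockId = character(), chrom = character(),
                         startM = integer(), endM = integer(),
                         members = list()) {
  new("BlockLibrary", blockId = as.character(blockId),
      chrom = as.character(chrom), startM = as.integer(startM),
      endM = as.integer(endM), members = members)
}

#' @rdname BlockLibrary-class
#' @export
setMethod("blocks", "BlockLibrary", function(x)
  data.frame(blockId = x@blockId, chrom = x@chrom, startM = x@startM,
             endM = x@endM, members = I(x@members),
             stringsAsFactors = FALSE, row.names = NULL))

#' @rdname BlockLibrary-class
#' @export
setMethod("length", "BlockLibrary", function(x) length(x@blockId))

setMethod("show", "BlockLibrary", function(object) {
  cat(sprintf("BlockLibrary: %d block(s) on %d chromosome(s), %d haplotype(s)\n",
              length(object), length(unique(object@chrom)),
              length(unique(unlist(object@members)))))
  invisible(NULL)
})

#' Validate a block library against a panel
#'
#' Checks that every block member is a haplotype of the panel and every block
#' interval lies within the panel's SNP marker range for its chromosome.
#'
#' @param lib a \code{\link{BlockLibrary}}.
#' @param panel a \code{\link{HaplotypePanel}}.
#' @return \code{TRUE} invisibly; otherwise an error listing offenders.
#' @export
validateLibrary <- function(lib, panel) {
  haps <- haplotypeIds(panel)
  bad <- setdiff(unique(unlist(lib@members)), haps)
  if (length(bad))
    stop("block members absent from panel: ", paste(bad, collapse = ", "))
  info <- markerInfo(panel)
  nPer <- table(info$chrom[info$isSnp])
  for (i in seq_along(lib@blockId)) {
    ch <- lib@chrom[i]
    k <- if (ch %in% names(nPer)) as.integer(nPer[[ch]]) else 0L
    if (lib@endM[i] > k)
      stop(sprintf("block %s exceeds the %d SNP markers of chromosome %s",
                   lib@blockId[i], k, ch))
  }
  invisible(TRUE)
}

# Decompose a chromosome's marker index range [0, nMarkers) into maximal
# segments on which the set of covering blocks is constant. Returns a list of
# list(start, end, blockIdx).
.blockSegments <- function(lib, chrom, nMarkers) {
  idx <- which(lib@chrom == chrom & lib@startM < nMarkers)
  cuts <- sort(unique(c(0L, nMarkers,
                        pmin(lib@startM[idx], nMarkers),
                        pmin(lib@endM[idx], nMarkers))))
  out <- vector("list", length(cuts) - 1L)
  for (s in seq_len(length(cuts) - 1L)) {
    a <- cuts[s]; b <- cuts[s + 1L]
    out[[s]] <- list(start = a, end = b,
                     blockIdx = idx[lib@startM[idx] <= a & lib@endM[idx] >= b])
  }
  out
}

# Neighbor indicator matrix (haps x haps, diagonal FALSE) and coverage vector
# for a set of blocks, in the coordinate system of `haps`.
.neighborMatrix <- function(lib, blockIdx, haps) {
  n <- length(haps)
  M <- matrix(FALSE, n, n, dimnames = list(haps, haps))
  for (b in blockIdx) {
    i <- match(lib@members[[b]], haps)
    if (anyNA(i))
      stop("block members absent from panel: ",
           paste(lib@members[[b]][is.na(i)], collapse = ", "))
    M[i, i] <- TRUE
  }
  cov <- diag(M)
  diag(M) <- FALSE
  list(neighbors = M, covered = cov)
}
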