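#' Local identity-by-descent neighbors of a haplotype
#'
#' Returns the union of the members of every block that contains haplotype
#' \code{h} and covers marker index \code{m}, minus \code{h} itself. These
#' are the haplotypes whose reads are pooled with \code{h}'s at that marker.
#'
#' @param lib a \code{\link{BlockLibrary}}.
#' @param h haplotype identifier; must occur in at least one block of the
#'   library (its universe).
#' @param m 0-based marker index within \code{chrom}.
#' @param chrom chromosome label; defaults to the library's single
#'   chromosome.
#' @return character vector of neighbor identifiers (possibly empty).
#' @examples
#' lib <- toyExample()$library
#' blockNeighbors(lib, "H1", 3)  # red block -> H2, H3
#' blockNeighbors(lib, "H4", 6)  # blue block -> H1, H2, H3
#' @export
blockNeighbors <- function(lib, h, m, chrom = NULL) {
  universe <- unique(unlist(lib@members))
  if (length(universe) && !(h %in% universe))
    stop("unknown haplotype: ", h)
  if (is.null(chrom)) {
    chs <- unique(lib@chrom)
    if (length(chs) > 1L)
      stop("library spans several chromosomes; supply `chrom`")
    chrom <- if (length(chs)) chs else NA_character_
  }
  hit <- which(lib@chrom == chrom & lib@startM <= m & lib@endM > m &
                 vapply(lib@members, function(mm) h %in% mm, logical(1)))
  setdiff(unique(as.character(unlist(lib@members[hit]))), h)
}

#' Fraction of panel cells covered by the block library
#'
#' A (marker, haplotype) cell is covered when at least one block contains the
#' haplotype and spans the marker. Uncovered cells are the gaps of the
#' read-depth estimation.
#'
#' @param lib a \code{\link{BlockLibrary}}, validated against \code{panel}.
#' @param panel a \code{\link{HaplotypePanel}}.
#' @return a single number in \[0, 1\].
#' @examples
#' toy <- toyExample()
#' coverageFraction(toy$library, toy$panel)  # 45 of 50 cells
#' @export
coverageFraction <- function(lib, panel) {
  validateLibrary(lib, panel)
  info <- markerInfo(panel)
  haps <- haplotypeIds(panel)
  snp <- which(info$isSnp)
  if (!length(snp) || !length(haps)) return(0)
  covered <- 0L
  for (ch in unique(info$chrom[snp])) {
    k <- sum(info$chrom[snp] == ch)
    for (seg in .blockSegments(lib, ch, k)) {
      if (!length(seg$blockIdx)) next
      nm <- .neighborMatrix(lib, seg$blockIdx, haps)
      covered <- covered + (seg$end - seg$start) * sum(nm$covered)
    }
  }
  covered / (length(snp) * length(haps))
}

#' Window-based haplotype-block finder
#'
#' A deliberately simple block finder for complete (no-missing) genotype
#' matrices, standing in for a full adaptive haplotype-library algorithm:
#' markers are partitioned into consecutive windows of \code{windowSize};
#' within each window, haplotypes with exactly identical call sequences are
#' grouped; groups reaching \code{minMembers} become blocks; with
#' \code{extend = TRUE}, blocks in adjacent windows with identical member
#' sets are merged into one longer block. Blocks never span chromosome
#' boundaries. Output ordering and block identifiers are deterministic
#' (sorted by chromosome, start, member set), so repeated runs are
#' byte-identical.
#'
#' @param mat complete call matrix, markers x haplotypes (0/1, no \code{NA});
#'   typically an externally imputed auxiliary panel or array data.
#' @param markers optional marker annotation \code{data.frame} with a
#'   \code{chrom} column (one row per row of \code{mat}); default one
#'   chromosome \code{"chr1"}.
#' @param params list from \code{\link{finderParams}}.
#' @return a \code{\link{BlockLibrary}}.
#' @examples
#' m <- cbind(matrix(0, 40, 3), matrix(1, 40, 3))
#' colnames(m) <- sprintf("H%d", 1:6)
#' findBlocksWindowed(m)  # two blocks spanning all 40 markers
#' @export
findBlocksWindowed <- function(mat, markers = NULL, params = finderParams()) {
  mat <- as.matrix(mat)
  if (anyNA(mat))
    stop("the call matrix contains missing cells; complete the panel first ",
         "(e.g. naiveComplete or external imputation)")
  if (is.null(colnames(mat)))
    colnames(mat) <- sprintf("H%d", seq_len(ncol(mat)))
  if (is.null(markers))
    markers <- data.frame(chrom = rep("chr1", nrow(mat)))
  stopifnot(nrow(markers) == nrow(mat))
  ws <- params$windowSize
  rows <- list()
  for (ch in unique(markers$chrom)) {
    i <- which(markers$chrom == ch)
    k <- length(i)
    starts <- seq(0L, k - 1L, by = ws)
    prev <- list()  # open blocks from the previous window, keyed by members
    for (s in starts) {
      e <- min(s + ws, k)
      key <- apply(mat[i[(s + 1L):e], , drop = FALSE], 2, paste, collapse = "")
      grp <- split(colnames(mat), key)
      grp <- grp[vapply(grp, length, integer(1)) >= params$minMembers]
      cur <- list()
      for (g in grp) {
        g <- sort(g)
        id <- paste(g, collapse = ",")
        if (params$extend && !is.null(prev[[id]])) {
          blk <- prev[[id]]
          blk$endM <- e
          cur[[id]] <- blk
        } else {
          cur[[id]] <- list(chrom = ch, startM = s, endM = e, members = g)
        }
      }
      # blocks not continued into this window are finalized
      rows <- c(rows,
                if (params$extend) prev[setdiff(names(prev), names(cur))]
                else prev)
      prev <- cur
    }
    rows <- c(rows, prev)
  }
  if (!length(rows))
    return(BlockLibrary())
  df <- data.frame(
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    startM = vapply(rows, `[[`, integer(1), "startM"),
    endM = vapply(rows, `[[`, integer(1), "endM"),
    key = vapply(rows, function(r) paste(r$members, collapse = ","),
                 character(1)),
    stringsAsFactors = FALSE)
  o <- order(df$chrom, df$startM, df$key)
  BlockLibrary(blockId = sprintf("B%04d", seq_along(o)),
               chrom = df$chrom[o], startM = df$startM[o], endM = df$endM[o],
               members = lapply(rows[o], `[[`, "members"))
}

#' @rdname findBlocksWindowed
#' @param windowSize window length in markers.
#' @param minMembers minimum number of haplotypes sharing a window sequence
#'   for the group to become a block (the block frequency floor).
#' @param extend merge blocks of adjacent windows with identical member sets.
#' @export
finderParams <- function(windowSize = 20, minMembers = 3, extend = TRUE) {
  stopifnot(windowSize >= 1, minMembers >= 2)
  list(windowSize = as.integer(windowSize),
       minMembers = as.integer(minMembers), extend = isTRUE(extend))
}
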