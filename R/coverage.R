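# Strand-specific coverage, alignment-start and alignment-end tracks.
# These are the C(i), S(i), E(i) quantities the MRN boundary algorithm
# operates on. Coordinates are 1-based closed throughout the package.

#' Construct a coverage track
#'
#' A coverage track stores, for one chromosome and strand, the per-position
#' read coverage \code{C}, the number of alignments whose first covered base
#' is the position (\code{S}) and the number whose last covered base is the
#' position (\code{E}). \code{origin} is the 1-based genomic coordinate of the
#' first element of the vectors.
#'
#' For contiguous (ungapped) alignments the three vectors are linked by the
#' conservation identity \eqn{C(i) = \sum_{j \le i} S(j) - \sum_{j < i} E(j)}:
#' reads enter at their start and leave after their end.
#'
#' @param chrom Chromosome name.
#' @param strand \code{"+"} or \code{"-"}.
#' @param origin 1-based genomic position of the first vector element.
#' @param C,S,E Integer vectors of equal length.
#' @return An object of class \code{"coverage_track"}.
#' @export
coverage_track <- function(chrom, strand, origin, C, S, E) {
  stopifnot(length(C) == length(S), length(C) == length(E))
  if (any(C < 0) || any(S < 0) || any(E < 0)) {
    stop("coverage track values must be non-negative")
  }
  structure(
    list(chrom = chrom, strand = strand, origin = as.integer(origin),
         C = as.integer(C), S = as.integer(S), E = as.integer(E)),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track %s(%s) [%d, %d]: %d alignments, max C = %d\n",
              x$chrom, x$strand, x$origin, x$origin + length(x$C) - 1L,
              sum(x$S), if (length(x$C)) max(x$C) else 0L))
  invisible(x)
}

#' Build a coverage track from alignments
#'
#' Computes \code{C}, \code{S} and \code{E} for one chromosome and strand.
#' Coverage is computed by interval stabbing (via \code{IRanges::coverage}) on
#' the aligned segments; N cigar operations (and, when \code{drop_deletions}
#' is \code{TRUE}, deletions) create coverage gaps, while \code{S}/\code{E}
#' always count the first/last covered base of the whole alignment.
#'
#' @param aln Either a \code{data.frame} with columns \code{start}, \code{end}
#'   (1-based closed; \code{chrom}/\code{strand} columns optional and filtered
#'   on when present) or a \code{GAlignments} object.
#' @param chrom Chromosome to build the track for.
#' @param strand Strand to build the track for.
#' @param drop_deletions Treat D cigar operations as coverage gaps
#'   (default \code{TRUE}).
#' @return A \code{\link{coverage_track}}. Empty input gives a zero-length
#'   track with \code{origin = 1}.
#' @export
build_coverage <- function(aln, chrom, strand, drop_deletions = TRUE) {
  if (methods::is(aln, "GAlignments")) {
    keep <- as.character(GenomicAlignments::seqnames(aln)) == chrom &
      as.character(BiocGenerics::strand(aln)) == strand
    aln <- aln[keep]
    if (length(aln) == 0L) {
      return(coverage_track(chrom, strand, 1L, integer(0), integer(0), integer(0)))
    }
    starts <- BiocGenerics::start(aln)
    ends <- BiocGenerics::end(aln)
    segs <- unlist(GenomicAlignments::grglist(aln, drop.D.ranges = drop_deletions))
    seg_ir <- IRanges::IRanges(BiocGenerics::start(segs), BiocGenerics::end(segs))
  } else {
    aln <- as.data.frame(aln)
    if ("chrom" %in% names(aln)) aln <- aln[aln$chrom == chrom, , drop = FALSE]
    if ("strand" %in% names(aln)) aln <- aln[aln$strand == strand, , drop = FALSE]
    if (nrow(aln) == 0L) {
      return(coverage_track(chrom, strand, 1L, integer(0), integer(0), integer(0)))
    }
    bad <- aln$end < aln$start | aln$start < 1
    if (any(bad)) {
      warning(sum(bad), " malformed alignment record(s) skipped")
      aln <- aln[!bad, , drop = FALSE]
    }
    starts <- aln$start
    ends <- aln$end
    seg_ir <- IRanges::IRanges(starts, ends)
  }
  origin <- min(starts)
  len <- max(ends) - origin + 1L
  S <- tabulate(starts - origin + 1L, nbins = len)
  E <- tabulate(ends - origin + 1L, nbins = len)
  covrle <- IRanges::coverage(IRanges::shift(seg_ir, 1L - origin), width = len)
  coverage_track(chrom, strand, origin, as.integer(covrle), S, E)
}

#' Build coverage tracks for all chromosome/strand combinations in a BAM file
#'
#' @param x Path to a coordinate-sorted BAM file (a SAM path is converted on
#'   the fly), or a \code{GAlignments} object.
#' @param chroms Optional character vector restricting the chromosomes.
#' @param min_mapq Optional minimum mapping quality (default: no filter).
#' @param drop_deletions Passed to \code{\link{build_coverage}}.
#' @return A named list of \code{\link{coverage_track}} objects, keyed
#'   \code{"chrom:strand"}, of class \code{"coverage_track_list"}.
#' @export
coverage_tracks <- function(x, chroms = NULL, min_mapq = NULL,
                            drop_deletions = TRUE) {
  galn <- if (methods::is(x, "GAlignments")) x else read_alignments(x, min_mapq)
  combos <- unique(data.frame(
    chrom = as.character(GenomicAlignments::seqnames(galn)),
    strand = as.character(BiocGenerics::strand(galn)),
    stringsAsFactors = FALSE
  ))
  if (!is.null(chroms)) combos <- combos[combos$chrom %in% chroms, , drop = FALSE]
  combos <- combos[order(combos$chrom, combos$strand), , drop = FALSE]
  out <- vector("list", nrow(combos))
  names(out) <- paste0(combos$chrom, ":", combos$strand)
  for (i in seq_len(nrow(combos))) {
    out[[i]] <- build_coverage(galn, combos$chrom[i], combos$strand[i],
                               drop_deletions = drop_deletions)
  }
  structure(out, class = "coverage_track_list")
}

#' Read a BAM (or SAM) file into a GAlignments object
#'
#' SAM input is converted to BAM in a temporary location first. Unmapped
#' reads are never returned.
#'
#' @param path BAM or SAM file path.
#' @param min_mapq Optional minimum mapping quality.
#' @return A \code{GAlignments} object.
#' @export
read_alignments <- function(path, min_mapq = NULL) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = TRUE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    mapqFilter = if (is.null(min_mapq)) NA_integer_ else as.integer(min_mapq)
  )
  GenomicAlignments::readGAlignments(path, param = param)
}

#' Slice one per-position vector of a coverage track
#'
#' Returns the \code{[from, to]} genomic slice of the \code{C}, \code{S} or
#' \code{E} vector, zero-padded outside the stored range.
#'
#' @param track A \code{\link{coverage_track}}.
#' @param what One of \code{"C"}, \code{"S"}, \code{"E"}.
#' @param from,to Genomic positions (1-based closed).
#' @return Integer vector of length \code{to - from + 1}.
#' @export
track_slice <- function(track, what, from, to) {
  v <- track[[what]]
  idx <- (from:to) - track$origin + 1L
  out <- integer(length(idx))
  ok <- idx >= 1L & idx <= length(v)
  out[ok] <- v[idx[ok]]
  out
}

#' @noRd
get_track <- function(tracks, chrom, strand) {
  tr <- tracks[[paste0(chrom, ":", strand)]]
  if (is.null(tr)) stop("no coverage track for ", chrom, "(", strand, ")")
  tr
}

#' Export one component of a coverage track as bedGraph
#'
#' Writes the \code{C}, \code{S} or \code{E} vector of a track as a bedGraph
#' file (0-based half-open intervals) for genome-browser inspection.
#'
#' @param track A \code{\link{coverage_track}}.
#' @param path Output file path.
#' @param what One of \code{"C"}, \code{"S"}, \code{"E"}.
#' @return Invisibly, the output path.
#' @export
export_bedgraph <- function(track, path, what = c("C", "S", "E")) {
  what <- match.arg(what)
  v <- track[[what]]
  r <- S4Vectors::Rle(v)
  ends <- cumsum(S4Vectors::runLength(r))
  starts <- c(0L, ends[-length(ends)])
  val <- S4Vectors::runValue(r)
  keep <- val != 0L
  df <- data.frame(chrom = track$chrom,
                   start = starts[keep] + track$origin - 1L,
                   end = ends[keep] + track$origin - 1L,
                   value = val[keep])
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
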