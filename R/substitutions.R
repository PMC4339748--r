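# Per-position substitution profiles in transcript orientation.
#
# The observable the whole method rests on is the relative substitution
# frequency x = y/z at a genomic position: y reads showing a given base
# substitution out of z aligned reads. Profiles are strand-specific and
# expressed in transcript orientation, i.e. for minus-strand alignments both
# the reference and the read base are complemented, so "TC" always denotes
# the 4SU crosslink transition regardless of the transcribed strand.

#' Build a per-position substitution profile from a BAM file
#'
#' Runs a strand- and nucleotide-aware pileup and tabulates, for every covered
#' position, the aligned-read coverage \code{z} (matches plus mismatches;
#' insertions, deletions and clipped bases are excluded) and the count
#' \code{y} of every observed substitution type in transcript orientation.
#' Positions whose reference base is ambiguous (N) are excluded entirely.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file (SAM accepted).
#' @param genome Reference genome (see \code{\link{load_genome}}).
#' @param min_base_quality Minimum base quality for a read base to enter the
#'   pileup (default 0: no filter, as upstream filtering is assumed).
#' @param min_mapq Optional minimum mapping quality.
#' @param max_depth Pileup depth cap (default 1e6).
#' @return An object of class \code{"substitution_profile"}: a list with
#'   \itemize{
#'     \item \code{coverage}: \code{data.table} of all covered positions with
#'       columns \code{chrom}, \code{strand}, \code{pos}, \code{z};
#'     \item \code{mismatches}: \code{data.table} with columns \code{chrom},
#'       \code{strand}, \code{pos}, \code{subst} (transcript-oriented code
#'       such as \code{"TC"}) and \code{y}.
#'   }
#' @export
substitution_profile <- function(bam, genome, min_base_quality = 0L,
                                 min_mapq = NULL, max_depth = 1e6L) {
  genome <- load_genome(genome)
  if (grepl("\\.sam$", bam, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(bam, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
  }
  pparam <- Rsamtools::PileupParam(
    max_depth = as.integer(max_depth),
    min_base_quality = as.integer(min_base_quality),
    min_mapq = if (is.null(min_mapq)) 0L else as.integer(min_mapq),
    min_nucleotide_depth = 1L,
    distinguish_strands = TRUE,
    distinguish_nucleotides = TRUE,
    include_deletions = FALSE,
    include_insertions = FALSE
  )
  pu <- Rsamtools::pileup(bam, pileupParam = pparam)
  pu <- data.table::as.data.table(pu)
  data.table::setnames(pu, "seqnames", "chrom")
  pu[, `:=`(chrom = as.character(chrom), strand = as.character(strand),
            nucleotide = as.character(nucleotide))]
  pu <- pu[nucleotide %in% BASES]

  # reference base at every pileup position
  pu[, ref := {
    chars <- chrom_chars(genome, .BY$chrom)
    chars[pos]
  }, by = "chrom"]
  pu <- pu[ref %in% BASES]  # drop ambiguous reference positions

  # transcript orientation: complement both bases on the minus strand
  minus <- pu$strand == "-"
  pu[, ref_t := ref]
  pu[, read_t := nucleotide]
  pu[minus, `:=`(ref_t = unname(COMPLEMENT[ref]),
                 read_t = unname(COMPLEMENT[nucleotide]))]

  coverage <- pu[, .(z = sum(count)), by = .(chrom, strand, pos)]
  mism <- pu[read_t != ref_t,
             .(chrom, strand, pos, subst = paste0(ref_t, read_t), y = count)]
  data.table::setkey(coverage, chrom, strand, pos)
  data.table::setkey(mism, chrom, strand, pos)
  structure(list(coverage = coverage, mismatches = mism),
            class = "substitution_profile")
}

#' @export
print.substitution_profile <- function(x, ...) {
  cat(sprintf(
    "substitution_profile: %d covered positions, %d mismatch records (%s)\n",
    nrow(x$coverage), nrow(x$mismatches),
    paste(unique(x$coverage$chrom), collapse = ", ")))
  invisible(x)
}

#' Extract transition sites from a substitution profile
#'
#' Returns one site per position carrying at least one substitution of the
#' requested type(s) at coverage \code{z >= min_cov}, with its relative
#' substitution frequency \code{x = y/z}. With several types (e.g. the 11
#' non-target types pooled as the non-experimental background), one site is
#' returned per (position, type) pair.
#'
#' @param profile A \code{\link{substitution_profile}}.
#' @param subst Character vector of transcript-oriented substitution codes
#'   (default \code{"TC"}, the 4SU transition; use \code{"GA"} for 6SG).
#' @param min_cov Minimum coverage \code{z} (default 20, the model-fitting
#'   coverage requirement).
#' @return A \code{data.frame} with columns \code{chrom}, \code{strand},
#'   \code{pos}, \code{subst}, \code{y}, \code{z}, \code{x}, ordered by
#'   position.
#' @export
extract_sites <- function(profile, subst = "TC", min_cov = 20L) {
  stopifnot(inherits(profile, "substitution_profile"), min_cov >= 1)
  m <- profile$mismatches[subst, on = "subst", nomatch = NULL]
  if (nrow(m) == 0L) {
    return(data.frame(chrom = character(0), strand = character(0),
                      pos = integer(0), subst = character(0),
                      y = integer(0), z = integer(0), x = numeric(0)))
  }
  m <- profile$coverage[m, on = c("chrom", "strand", "pos")]
  m <- m[z >= min_cov]
  out <- as.data.frame(m[, .(chrom, strand, pos, subst, y, z, x = y / z)])
  out[order(out$chrom, out$strand, out$pos, out$subst), , drop = FALSE]
}

#' Background (non-target) transition sites
#'
#' Pools all substitution types other than the target type; these cannot be
#' crosslink-induced and estimate the non-experimental RSF component.
#'
#' @inheritParams extract_sites
#' @param target The experimentally induced type to exclude (default
#'   \code{"TC"}).
#' @return As \code{\link{extract_sites}}.
#' @export
background_sites <- function(profile, target = "TC", min_cov = 20L) {
  extract_sites(profile, setdiff(all_subst_codes(), target), min_cov)
}
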