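# Seeded synthetic PAR-CLIP / RNA-Seq simulator with known truth.
#
# The simulator emulates the data-generating structure the model assumes:
# strand-specific transcribed regions at modest uniform coverage; rectangular
# read pile-ups over protein binding sites; crosslink-induced T->C
# transitions (transcript orientation) with a per-site probability drawn
# from a signal RSF range; homozygous SNPs (alternate allele in every read of
# both libraries); shared "artifact" positions reproducing systematic
# sequencing errors, RNA editing and mismapping-like substitutions in both
# libraries at a position-specific rate; and independent uniform sequencing
# errors. Reads are emitted pre-aligned (perfect placement) as sorted,
# indexed BAM, since alignment is upstream of this package.

#' Simulate a random reference genome
#'
#' @param n_chroms Number of chromosomes (default 1).
#' @param length Chromosome length in bp (>= 1000; default 3e5).
#' @param gc GC content in [0, 1] (default 0.4).
#' @param seed RNG seed.
#' @param path Optional FASTA output path (an index is written alongside).
#' @return A \code{DNAStringSet}; chromosomes are named \code{chr1, ...}.
#' @export
simulate_genome <- function(n_chroms = 1L, length = 3e5, gc = 0.4,
                            seed = NULL, path = NULL) {
  stopifnot(length >= 1000, gc >= 0, gc <= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(seq_len(n_chroms), function(i) {
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- paste0("chr", seq_len(n_chroms))
  if (!is.null(path)) {
    Biostrings::writeXStringSet(genome, path)
    Rsamtools::indexFa(path)
  }
  genome
}

#' Define the ground truth of a simulated PAR-CLIP experiment
#'
#' Lays out strand-alternating transcribed regions on the genome, places
#' disjoint binding sites inside them (each with a crosslink transition
#' probability drawn from \code{signal_range}), and plants homozygous SNPs
#' and shared artifact positions in transcribed sequence away from the sites.
#'
#' @param genome A \code{DNAStringSet} (see \code{\link{simulate_genome}}).
#' @param n_sites Number of binding sites (default 200).
#' @param site_width Binding-site width in bp (default 30).
#' @param signal_range Range of per-site crosslink transition probabilities
#'   (default \code{c(0.25, 0.6)}).
#' @param n_snps Number of homozygous SNPs (default 20).
#' @param n_artifacts Number of shared artifact positions (default 500).
#' @param artifact_low,artifact_high Rate ranges of the low-rate (systematic
#'   sequencing error) and high-rate (editing / mismapping-like) artifact
#'   classes; defaults \code{c(0.01, 0.12)} and \code{c(0.12, 0.95)}.
#' @param artifact_high_frac Fraction of artifacts in the high-rate class
#'   (default 0.4).
#' @param error_rate Independent per-base sequencing error probability
#'   (default 0.002).
#' @param site_depth Reads per binding site (default 50).
#' @param background_coverage Coverage of transcribed regions in the PAR-CLIP
#'   library (default 25).
#' @param rnaseq_coverage Coverage of transcribed regions in the RNA-Seq
#'   library (default 30).
#' @param read_length Read length in bp (default 36; must be >=
#'   \code{site_width}).
#' @param tx_length,tx_gap Transcript length and inter-transcript gap
#'   (defaults 1000 and 200).
#' @param seed RNG seed for the layout.
#' @return A list of class \code{"sim_truth"} with elements \code{genome},
#'   \code{transcripts}, \code{sites}, \code{snps}, \code{artifacts} and the
#'   scalar parameters.
#' @export
simulate_truth <- function(genome, n_sites = 200L, site_width = 30L,
                           signal_range = c(0.25, 0.6), n_snps = 20L,
                           n_artifacts = 500L,
                           artifact_low = c(0.01, 0.12),
                           artifact_high = c(0.12, 0.95),
                           artifact_high_frac = 0.4,
                           error_rate = 0.002, site_depth = 50L,
                           background_coverage = 25, rnaseq_coverage = 30,
                           read_length = 36L, tx_length = 1000L,
                           tx_gap = 200L, seed = NULL) {
  stopifnot(read_length >= site_width)
  if (!is.null(seed)) set.seed(seed)
  lens <- setNames(BiocGenerics::width(genome), names(genome))

  # strand-alternating transcripts tiled over each chromosome
  tx <- do.call(rbind, lapply(names(genome), function(chrom) {
    starts <- seq(1L, lens[[chrom]] - tx_length, by = tx_length + tx_gap)
    data.frame(chrom = chrom, start = starts,
               end = starts + tx_length - 1L,
               strand = rep(c("+", "-"), length.out = length(starts)))
  }))
  if (nrow(tx) < n_sites) {
    stop("genome too small: ", nrow(tx), " transcripts for ", n_sites,
         " sites; increase genome length")
  }

  # one site per transcript, placed away from transcript edges
  site_tx <- sort(sample(nrow(tx), n_sites))
  margin <- 150L
  off <- sample(margin:(tx_length - margin - site_width), n_sites,
                replace = TRUE)
  sites <- data.frame(
    chrom = tx$chrom[site_tx], strand = tx$strand[site_tx],
    start = tx$start[site_tx] + off,
    p = runif(n_sites, signal_range[1], signal_range[2])
  )
  sites$end <- sites$start + site_width - 1L
  sites <- sites[, c("chrom", "strand", "start", "end", "p")]

  # candidate positions for SNPs/artifacts: transcribed, >= 50 bp from sites
  forbidden <- lapply(names(genome), function(chrom) {
    s <- sites[sites$chrom == chrom, ]
    ir <- IRanges::IRanges(s$start - 50L, s$end + 50L)
    IRanges::reduce(ir)
  })
  names(forbidden) <- names(genome)
  cand <- do.call(rbind, lapply(seq_len(nrow(tx)), function(i) {
    pos <- (tx$start[i] + 20L):(tx$end[i] - 20L)
    bad <- IRanges::overlapsAny(IRanges::IRanges(pos, pos),
                                forbidden[[tx$chrom[i]]])
    if (all(bad)) return(NULL)
    data.frame(chrom = tx$chrom[i], strand = tx$strand[i], pos = pos[!bad])
  }))
  pick <- sample(nrow(cand), n_snps + n_artifacts)
  snp_rows <- cand[pick[seq_len(n_snps)], , drop = FALSE]
  art_rows <- cand[pick[n_snps + seq_len(n_artifacts)], , drop = FALSE]

  ref_at <- function(rows) {
    vapply(seq_len(nrow(rows)), function(i) {
      chrom_chars(genome, rows$chrom[i])[rows$pos[i]]
    }, character(1))
  }
  alt_uniform <- function(ref) {
    vapply(ref, function(r) sample(setdiff(BASES, r), 1L), character(1))
  }
  # transition-biased alternate allele (transitions ~4x transversions),
  # matching the substitution spectrum of systematic errors and editing
  TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
  alt_biased <- function(ref) {
    vapply(ref, function(r) {
      alts <- setdiff(BASES, r)
      w <- ifelse(alts == TRANSITION[[r]], 4, 1)
      sample(alts, 1L, prob = w)
    }, character(1))
  }

  snps <- data.frame(chrom = snp_rows$chrom, pos = snp_rows$pos,
                     ref = ref_at(snp_rows))
  snps$alt <- alt_uniform(snps$ref)
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]

  n_hi <- round(n_artifacts * artifact_high_frac)
  rate <- c(runif(n_artifacts - n_hi, artifact_low[1], artifact_low[2]),
            runif(n_hi, artifact_high[1], artifact_high[2]))
  artifacts <- data.frame(chrom = art_rows$chrom, pos = art_rows$pos,
                          ref = ref_at(art_rows),
                          rate = rate[sample.int(n_artifacts)])
  artifacts$alt <- alt_biased(artifacts$ref)
  artifacts <- artifacts[order(artifacts$chrom, artifacts$pos), , drop = FALSE]
  rownames(sites) <- rownames(snps) <- rownames(artifacts) <- NULL

  structure(
    list(genome = genome, transcripts = tx, sites = sites, snps = snps,
         artifacts = artifacts, error_rate = error_rate,
         site_depth = as.integer(site_depth),
         background_coverage = background_coverage,
         rnaseq_coverage = rnaseq_coverage,
         read_length = as.integer(read_length),
         signal_range = signal_range),
    class = "sim_truth"
  )
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "sim_truth: %d chrom(s), %d transcripts, %d sites (p in [%.2f, %.2f]), %d SNPs, %d artifacts\n",
    length(x$genome), nrow(x$transcripts), nrow(x$sites),
    x$signal_range[1], x$signal_range[2], nrow(x$snps), nrow(x$artifacts)))
  invisible(x)
}

# Generate the read table (start positions + strand) for one library.
#' @noRd
sim_read_layout <- function(truth, coverage, with_sites) {
  L <- truth$read_length
  tx <- truth$transcripts
  reads <- vector("list", nrow(tx) + if (with_sites) nrow(truth$sites) else 0L)
  for (i in seq_len(nrow(tx))) {
    span <- tx$end[i] - L + 1L - tx$start[i] + 1L
    n_reads <- round(coverage * span / L)
    if (n_reads > 0) {
      reads[[i]] <- data.frame(
        chrom = tx$chrom[i], strand = tx$strand[i],
        start = tx$start[i] + sample.int(span, n_reads, replace = TRUE) - 1L)
    }
  }
  if (with_sites) {
    s <- truth$sites
    w <- s$end - s$start + 1L
    for (j in seq_len(nrow(s))) {
      # offsets keep the whole site inside the read: rectangular pile-up
      offs <- sample.int(L - w[j] + 1L, truth$site_depth, replace = TRUE) - 1L
      reads[[nrow(tx) + j]] <- data.frame(
        chrom = s$chrom[j], strand = s$strand[j], start = s$start[j] - offs)
    }
  }
  out <- do.call(rbind, reads)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Build read sequences (forward-genomic orientation) with planted events.
#' @noRd
sim_read_seqs <- function(truth, reads, crosslink) {
  L <- truth$read_length
  genome <- truth$genome
  n <- nrow(reads)
  seqs <- character(n)
  for (chrom in unique(reads$chrom)) {
    chars <- chrom_chars(genome, chrom)
    sel <- which(reads$chrom == chrom)
    starts <- reads$start[sel]  # sorted within chromosome
    idx <- outer(starts, 0:(L - 1L), "+")
    m <- matrix(chars[idx], nrow = length(sel))

    # rows of reads covering genomic position p (starts are sorted)
    rows_at <- function(p) {
      lo <- findInterval(p - L, starts) + 1L
      hi <- findInterval(p, starts)
      if (hi < lo) integer(0) else lo:hi
    }
    # SNPs: alternate allele in every read
    snps <- truth$snps[truth$snps$chrom == chrom, ]
    for (k in seq_len(nrow(snps))) {
      rows <- rows_at(snps$pos[k])
      if (length(rows)) m[cbind(rows, snps$pos[k] - starts[rows] + 1L)] <- snps$alt[k]
    }
    # shared artifacts: alternate base at the position-specific rate
    arts <- truth$artifacts[truth$artifacts$chrom == chrom, ]
    for (k in seq_len(nrow(arts))) {
      rows <- rows_at(arts$pos[k])
      if (length(rows)) {
        hit <- rows[runif(length(rows)) < arts$rate[k]]
        if (length(hit)) m[cbind(hit, arts$pos[k] - starts[hit] + 1L)] <- arts$alt[k]
      }
    }
    # crosslink-induced transitions: every read over a site converts its
    # crosslinkable bases (transcript T; genomic T on +, A on -) with the
    # site's probability
    if (crosslink) {
      st <- truth$sites[truth$sites$chrom == chrom, ]
      strand_of <- reads$strand[sel]
      for (k in seq_len(nrow(st))) {
        conv_from <- if (st$strand[k] == "+") "T" else "A"
        conv_to <- if (st$strand[k] == "+") "C" else "G"
        for (p in st$start[k]:st$end[k]) {
          if (chars[p] != conv_from) next
          rows <- rows_at(p)
          rows <- rows[strand_of[rows] == st$strand[k]]
          if (length(rows)) {
            hit <- rows[runif(length(rows)) < st$p[k]]
            if (length(hit)) m[cbind(hit, p - starts[hit] + 1L)] <- conv_to
          }
        }
      }
    }
    # independent sequencing errors, uniform over the three other bases
    err <- which(runif(length(m)) < truth$error_rate)
    if (length(err)) {
      cur <- m[err]
      shift <- sample.int(3L, length(err), replace = TRUE)
      m[err] <- BASES[(match(cur, BASES) - 1L + shift) %% 4L + 1L]
    }
    seqs[sel] <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  seqs
}

# Write reads as SAM text and convert to sorted, indexed BAM.
#' @noRd
write_reads_bam <- function(truth, reads, seqs, path) {
  L <- truth$read_length
  lens <- setNames(BiocGenerics::width(truth$genome), names(truth$genome))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens))
  flag <- ifelse(reads$strand == "+", 0L, 16L)
  qual <- strrep("I", L)
  body <- sprintf("r%07d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s",
                  seq_len(nrow(reads)), flag, reads$chrom, reads$start, L,
                  seqs, qual)
  sam <- sub("\\.bam$", ".sam", path)
  writeLines(c(hdr, body), sam)
  bam <- Rsamtools::asBam(sam, sub("\\.bam$", "", path), overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

#' Simulate an aligned PAR-CLIP library
#'
#' Emits background reads over every transcript plus a rectangular pile-up of
#' \code{site_depth} reads over every binding site; applies SNPs, shared
#' artifacts, crosslink conversions and independent sequencing errors; and
#' writes a coordinate-sorted, indexed BAM. A truth table of the planted
#' sites is written alongside as TSV.
#'
#' @param truth A \code{\link{simulate_truth}} object.
#' @param path Output BAM path.
#' @param seed RNG seed for read sampling.
#' @return List with elements \code{bam} (path), \code{truth_tsv} (path of
#'   the site truth table) and \code{n_reads}.
#' @export
simulate_parclip <- function(truth, path, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!is.null(seed)) set.seed(seed)
  reads <- sim_read_layout(truth, truth$background_coverage, with_sites = TRUE)
  seqs <- sim_read_seqs(truth, reads, crosslink = TRUE)
  bam <- write_reads_bam(truth, reads, seqs, path)
  tsv <- paste0(sub("\\.bam$", "", path), "_sites.tsv")
  write.table(truth$sites, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  list(bam = bam, truth_tsv = tsv, n_reads = nrow(reads))
}

#' Simulate a matched total RNA-Seq library
#'
#' Same genome, transcripts, SNPs, artifacts and error model as the PAR-CLIP
#' simulation, but no crosslink-induced conversions and no site pile-ups:
#' uniform coverage over all transcribed regions.
#'
#' @inheritParams simulate_parclip
#' @return List with \code{bam} and \code{n_reads}.
#' @export
simulate_rnaseq <- function(truth, path, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!is.null(seed)) set.seed(seed)
  reads <- sim_read_layout(truth, truth$rnaseq_coverage, with_sites = FALSE)
  seqs <- sim_read_seqs(truth, reads, crosslink = FALSE)
  bam <- write_reads_bam(truth, reads, seqs, path)
  list(bam = bam, n_reads = nrow(reads))
}
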