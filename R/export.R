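# Export of clusters/hcTs, cluster sequence extraction, and miRNA
# seed-enrichment analysis against a dinucleotide-shuffled background.

#' Export clusters as BED6 or TSV
#'
#' BED output is 0-based half-open with the score column
#' \code{min(1000, round(100 * rel_log_odds))} clamped to [0, 1000] (0 for
#' clusters without crosslinkable bases). TSV output keeps 1-based closed
#' coordinates and the full score columns; a write/read round trip
#' reproduces the coordinates exactly.
#'
#' @param clusters \code{GRanges} from \code{\link{call_clusters}}.
#' @param path Output file path.
#' @param format \code{"BED"} or \code{"TSV"}.
#' @param allow_empty Permit writing a file for an empty cluster set
#'   (header-only for TSV, empty for BED).
#' @return Invisibly, the path.
#' @export
export_clusters <- function(clusters, path, format = c("BED", "TSV"),
                            allow_empty = FALSE) {
  format <- match.arg(format)
  if (length(clusters) == 0L && !allow_empty) {
    stop("no clusters to export (use allow_empty = TRUE for a header-only file)")
  }
  mc <- S4Vectors::mcols(clusters)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(clusters)),
    start = BiocGenerics::start(clusters),
    end = BiocGenerics::end(clusters),
    strand = as.character(BiocGenerics::strand(clusters)),
    n_hcT = mc$n_hcT %||% rep(NA_integer_, length(clusters)),
    rel_log_odds = mc$rel_log_odds %||% rep(NA_real_, length(clusters)),
    width = BiocGenerics::width(clusters)
  )
  if (format == "BED") {
    score <- ifelse(is.na(df$rel_log_odds), 0,
                    pmin(1000, pmax(0, round(100 * df$rel_log_odds))))
    bed <- data.frame(chrom = df$chrom, start = df$start - 1L, end = df$end,
                      name = sprintf("cluster_%05d", seq_len(nrow(df))),
                      score = as.integer(score), strand = df$strand)
    write.table(bed, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Export high-confidence transitions as BED6
#'
#' One line per hcT (0-based half-open single positions), name \code{"y/z"}
#' and score \code{min(1000, round(posterior2 * 1000))}.
#'
#' @param hcts Scored hcTs from \code{\link{classify_hct}}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
export_sites <- function(hcts, path) {
  bed <- data.frame(
    chrom = hcts$chrom, start = hcts$pos - 1L, end = hcts$pos,
    name = paste0(hcts$y, "/", hcts$z),
    score = as.integer(pmin(1000, round(hcts$posterior2 * 1000))),
    strand = hcts$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read clusters from a TSV written by \code{\link{export_clusters}}
#'
#' @param path TSV path.
#' @return A \code{GRanges} with \code{n_hcT} and \code{rel_log_odds}.
#' @export
read_clusters <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$n_hcT <- df$n_hcT
  S4Vectors::mcols(gr)$rel_log_odds <- df$rel_log_odds
  gr
}

#' Extract cluster sequences
#'
#' Returns the transcript-oriented sequence of every cluster:
#' minus-strand clusters are reverse-complemented. Soft-masked (lowercase)
#' genome bases are uppercased. Record ids follow
#' \code{chrom:start-end(strand)}.
#'
#' @param clusters \code{GRanges} of clusters.
#' @param genome Reference genome (see \code{\link{load_genome}}).
#' @param path Optional FASTA output path.
#' @return A \code{DNAStringSet} (invisibly if \code{path} is given).
#' @export
cluster_sequences <- function(clusters, genome, path = NULL) {
  genome <- load_genome(genome)
  chroms <- as.character(GenomicRanges::seqnames(clusters))
  starts <- BiocGenerics::start(clusters)
  ends <- BiocGenerics::end(clusters)
  strands <- as.character(BiocGenerics::strand(clusters))
  lens <- setNames(BiocGenerics::width(genome), names(genome))
  if (any(!(chroms %in% names(genome)))) {
    stop("cluster chromosome absent from genome")
  }
  if (any(ends > lens[chroms]) || any(starts < 1L)) {
    stop("cluster interval beyond chromosome end")
  }
  seqs <- Biostrings::DNAStringSet(vapply(seq_along(clusters), function(i) {
    toupper(as.character(
      Biostrings::subseq(genome[[chroms[i]]], starts[i], ends[i])))
  }, character(1)))
  minus <- strands == "-"
  if (any(minus)) seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  names(seqs) <- sprintf("%s:%d-%d(%s)", chroms, starts, ends, strands)
  if (!is.null(path)) {
    Biostrings::writeXStringSet(seqs, path)
    return(invisible(seqs))
  }
  seqs
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Returns a random sequence with exactly the same dinucleotide multiset as
#' the input (and hence the same mononucleotide composition apart from the
#' unchanged terminal vertices), using a randomized Eulerian-path walk
#' (Hierholzer's algorithm on the dinucleotide transition multigraph).
#' Deterministic under a fixed seed.
#'
#' @param seq A character scalar (or \code{DNAString}) of length >= 3.
#' @param seed Optional RNG seed.
#' @return A shuffled character scalar.
#' @export
dinucleotide_shuffle <- function(seq, seed = NULL) {
  s <- toupper(as.character(seq))
  if (nchar(s) < 3L) stop("sequence too short to shuffle (need >= 3 bases)")
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  edges_from <- chars[-n]
  edges_to <- chars[-1]
  if (length(unique(paste0(edges_from, edges_to))) < 2L) {
    warning("sequence has fewer than 2 distinct dinucleotide transitions; ",
            "returned unchanged")
    return(s)
  }
  verts <- unique(chars)
  adj <- lapply(setNames(verts, verts), function(v) {
    out <- edges_to[edges_from == v]
    if (length(out) > 1L) out[sample.int(length(out))] else out
  })
  nxt <- lapply(adj, function(x) 1L)  # next unused edge index per vertex
  # Hierholzer from the original start vertex: the multigraph of a sequence
  # always admits an Eulerian path from its first to its last character.
  stack <- chars[1]
  path <- character(0)
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    i <- nxt[[v]]
    if (i <= length(adj[[v]])) {
      nxt[[v]] <- i + 1L
      stack <- c(stack, adj[[v]][i])
    } else {
      path <- c(path, v)
      stack <- stack[-length(stack)]
    }
  }
  paste(rev(path), collapse = "")
}

#' miRNA seed enrichment in cluster sequences
#'
#' For each miRNA, counts occurrences of the reverse complement of its seed
#' (positions 2-8) in the cluster sequences, normalized per kilobase of
#' cluster sequence, and compares with the mean per-kb count obtained from
#' dinucleotide-shuffled copies of the miRNA (same seed positions taken from
#' each shuffle).
#'
#' @param cluster_seqs \code{DNAStringSet} from
#'   \code{\link{cluster_sequences}}.
#' @param mirnas Named character vector or \code{DNAStringSet} of miRNA
#'   sequences (each >= 8 nt; shorter ones are skipped with a warning). U is
#'   converted to T.
#' @param n_shuffles Number of shuffled background samples (default 10000).
#' @param seed Optional RNG seed.
#' @return A \code{data.frame} with one row per miRNA: \code{mirna},
#'   \code{seed}, \code{observed} (matches/kb), \code{background} (mean
#'   matches/kb over shuffles), \code{enrichment}.
#' @export
seed_enrichment <- function(cluster_seqs, mirnas, n_shuffles = 10000L,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- names(mirnas)
  mir <- toupper(chartr("U", "T", as.character(mirnas)))
  names(mir) <- ids
  if (is.null(names(mir))) names(mir) <- paste0("mirna_", seq_along(mir))
  short <- nchar(mir) < 8L
  if (any(short)) {
    warning(sum(short), " miRNA(s) shorter than 8 nt skipped: ",
            paste(names(mir)[short], collapse = ", "))
    mir <- mir[!short]
  }
  total_kb <- sum(BiocGenerics::width(cluster_seqs)) / 1000
  # all 7-mer counts of the cluster set at once; overlapping occurrences count
  k7 <- colSums(Biostrings::oligonucleotideFrequency(cluster_seqs, width = 7))
  count_per_kb <- function(seed7) {
    target <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(seed7)))
    unname(k7[target]) / total_kb
  }
  rows <- lapply(names(mir), function(id) {
    m <- mir[[id]]
    seed7 <- substr(m, 2, 8)
    observed <- count_per_kb(seed7)
    bg <- vapply(seq_len(n_shuffles), function(b) {
      count_per_kb(substr(dinucleotide_shuffle(m), 2, 8))
    }, numeric(1))
    background <- mean(bg)
    data.frame(mirna = id, seed = seed7, observed = observed,
               background = background,
               enrichment = if (background > 0) observed / background else
                 ifelse(observed > 0, Inf, NA_real_))
  })
  do.call(rbind, rows)
}
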