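# Experimentally based FDR estimation from matched RNA-Seq.
#
# RNA-Seq from the same cells carries the same SNPs and systematic
# substitution artifacts but no crosslink-induced transitions. A PAR-CLIP
# transition that is equally observed in RNA-Seq is therefore likely a false
# positive, which yields conservative, data-driven FDR bounds without any
# parametric null.

# RNA-Seq target-type evidence (y, z) at given transcript-oriented positions.
# When the RNA-Seq library is unstranded both strands are pooled; the
# opposite-strand profile stores the same genomic event under the
# complementary substitution code.
#' @noRd
rnaseq_evidence <- function(positions, rnaseq, subst, stranded = TRUE) {
  stopifnot(inherits(rnaseq, "substitution_profile"))
  code <- subst
  code_opp <- comp_pair(subst)
  q <- data.table::as.data.table(positions[, c("chrom", "strand", "pos")])
  cov <- rnaseq$coverage
  mism <- rnaseq$mismatches
  same_cov <- cov[q, on = c("chrom", "strand", "pos")]
  z <- ifelse(is.na(same_cov$z), 0L, same_cov$z)
  m_t <- mism[mism$subst == code][q, on = c("chrom", "strand", "pos")]
  y <- ifelse(is.na(m_t$y), 0L, m_t$y)
  if (!stranded) {
    q2 <- data.table::copy(q)
    q2[, strand := ifelse(strand == "+", "-", "+")]
    opp_cov <- cov[q2, on = c("chrom", "strand", "pos")]
    z <- z + ifelse(is.na(opp_cov$z), 0L, opp_cov$z)
    m_o <- mism[mism$subst == code_opp][q2, on = c("chrom", "strand", "pos")]
    y <- y + ifelse(is.na(m_o$y), 0L, m_o$y)
  }
  data.frame(z = z, y = y)
}

#' Site-level FDR bounds over RSF bins
#'
#' Considers the positions \eqn{\mathcal G} with coverage of at least
#' \code{min_cov} in both the PAR-CLIP and RNA-Seq profile and at least one
#' target transition in PAR-CLIP. The RSF interval (0, 1] is partitioned into
#' \code{n_bins} equal bins; within each bin the members
#' \eqn{\mathcal P \subseteq \mathcal G} are the positions whose PAR-CLIP RSF
#' falls into the bin. The conservative upper bound counts as false positives
#' all members with any target transition in RNA-Seq
#' (\eqn{|\mathcal U| / |\mathcal P|}), the lower bound only those whose
#' RNA-Seq RSF falls into the same bin (\eqn{|\mathcal L| / |\mathcal P|}).
#'
#' @param parclip,rnaseq \code{\link{substitution_profile}} objects on the
#'   same reference.
#' @param subst Target transition type (default \code{"TC"}).
#' @param min_cov Minimum coverage in both profiles (default 20).
#' @param n_bins Number of equal RSF bins (default 10).
#' @param stranded Is the RNA-Seq library stranded? When \code{FALSE} both
#'   strands are pooled at each position (default \code{TRUE}).
#' @return A \code{data.frame} of class \code{"fdr_table"} (mode
#'   \code{"site"}) with one row per non-empty bin: \code{bin_lo},
#'   \code{bin_hi}, \code{n_P}, \code{n_U}, \code{n_L}, \code{upper},
#'   \code{lower}.
#' @export
site_fdr <- function(parclip, rnaseq, subst = "TC", min_cov = 20L,
                     n_bins = 10L, stranded = TRUE) {
  g <- extract_sites(parclip, subst = subst, min_cov = min_cov)
  if (nrow(g) > 0) {
    ev <- rnaseq_evidence(g, rnaseq, subst, stranded)
    g$z_rna <- ev$z
    g$y_rna <- ev$y
    g <- g[g$z_rna >= min_cov, , drop = FALSE]
  }
  if (nrow(g) == 0L) {
    stop("profiles do not overlap at required coverage: no position has ",
         "coverage >= ", min_cov, " in both data sets with a PAR-CLIP transition")
  }
  g$x_rna <- g$y_rna / g$z_rna
  breaks <- seq(0, 1, length.out = n_bins + 1)
  g$bin <- pmin(pmax(ceiling(g$x * n_bins), 1L), n_bins)
  rows <- lapply(seq_len(n_bins), function(b) {
    p <- g[g$bin == b, , drop = FALSE]
    if (nrow(p) == 0L) return(NULL)
    in_bin_rna <- p$y_rna > 0 & p$x_rna > breaks[b] & p$x_rna <= breaks[b + 1]
    data.frame(bin_lo = breaks[b], bin_hi = breaks[b + 1],
               n_P = nrow(p), n_U = sum(p$y_rna > 0), n_L = sum(in_bin_rna),
               upper = sum(p$y_rna > 0) / nrow(p),
               lower = sum(in_bin_rna) / nrow(p))
  })
  out <- do.call(rbind, rows)
  attr(out, "mode") <- "site"
  class(out) <- c("fdr_table", class(out))
  out
}

#' Cluster-level FDR estimates for top-ranked clusters
#'
#' Clusters are ranked by decreasing relative log-odds (the order returned by
#' \code{\link{call_clusters}}, preserved here by a stable sort). For each
#' requested \code{top_n}, a cluster counts as a conservative false positive
#' if at least one member hcT shows an RNA-Seq RSF inside the
#' PAR-CLIP-specific support \code{[a, b]}, and as a relaxed false positive
#' if it has RNA-Seq-covered members and every one of them does. Member hcTs
#' without RNA-Seq coverage contribute no evidence.
#'
#' @param clusters \code{GRanges} from \code{\link{call_clusters}}.
#' @param rnaseq A \code{\link{substitution_profile}} of the matched RNA-Seq.
#' @param support RSF support \code{c(a, b)} from the fitted model (see
#'   \code{\link{rsf_support}} or the attribute of \code{\link{classify_hct}}).
#' @param top_n Integer vector of ranking depths (default
#'   \code{c(75, 125, 250)}).
#' @param subst Target transition type (default \code{"TC"}).
#' @param min_cov Minimum RNA-Seq coverage for a member hcT to provide
#'   evidence (default 1).
#' @param stranded See \code{\link{site_fdr}}.
#' @return A \code{data.frame} of class \code{"fdr_table"} (mode
#'   \code{"cluster"}) with columns \code{top_n}, \code{n_fp_conservative},
#'   \code{n_fp_relaxed}, \code{conservative}, \code{relaxed}.
#' @export
cluster_fdr <- function(clusters, rnaseq, support, top_n = c(75L, 125L, 250L),
                        subst = "TC", min_cov = 1L, stranded = TRUE) {
  stopifnot(length(support) == 2, support[1] <= support[2])
  nc <- length(clusters)
  if (any(top_n > nc)) {
    warning("top_n truncated to the number of clusters (", nc, ")")
    top_n <- pmin(top_n, nc)
  }
  top_n <- sort(unique(top_n))
  rlo <- S4Vectors::mcols(clusters)$rel_log_odds
  ord <- order(is.na(rlo), -ifelse(is.na(rlo), 0, rlo), method = "radix")
  clusters <- clusters[ord]

  pos_list <- S4Vectors::mcols(clusters)$hcT_pos
  q <- data.frame(
    chrom = rep(as.character(GenomicRanges::seqnames(clusters)),
                lengths(pos_list)),
    strand = rep(as.character(BiocGenerics::strand(clusters)),
                 lengths(pos_list)),
    pos = unlist(pos_list, use.names = FALSE),
    cluster = rep(seq_along(clusters), lengths(pos_list))
  )
  if (nrow(q) > 0) {
    ev <- rnaseq_evidence(q, rnaseq, subst, stranded)
    covered <- ev$z >= min_cov
    x_rna <- ifelse(covered, ev$y / pmax(ev$z, 1L), NA_real_)
    in_support <- covered & x_rna >= support[1] & x_rna <= support[2]
    fp_cons_by_cl <- tapply(in_support, q$cluster, any)
    all_in <- tapply(seq_len(nrow(q)), q$cluster, function(ii) {
      cov_ii <- covered[ii]
      any(cov_ii) && all(in_support[ii][cov_ii])
    })
    fp_cons <- logical(length(clusters))
    fp_cons[as.integer(names(fp_cons_by_cl))] <- fp_cons_by_cl
    fp_rel <- logical(length(clusters))
    fp_rel[as.integer(names(all_in))] <- all_in
  } else {
    fp_cons <- fp_rel <- logical(length(clusters))
  }
  out <- do.call(rbind, lapply(top_n, function(n) {
    data.frame(top_n = n,
               n_fp_conservative = sum(fp_cons[seq_len(n)]),
               n_fp_relaxed = sum(fp_rel[seq_len(n)]),
               conservative = mean(fp_cons[seq_len(n)]),
               relaxed = mean(fp_rel[seq_len(n)]))
  }))
  attr(out, "mode") <- "cluster"
  class(out) <- c("fdr_table", class(out))
  out
}

#' Write an FDR table as TSV
#'
#' @param x An \code{"fdr_table"} from \code{\link{site_fdr}} or
#'   \code{\link{cluster_fdr}}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_fdr_table <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
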