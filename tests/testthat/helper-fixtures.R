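# Shared fixtures: in-code SAM/BAM builders, hand-rolled profile objects and
# the brute-force rank/selection oracle used to validate the MRN caller.

suppressPackageStartupMessages({
  library(Biostrings)
})

# Write alignment records as SAM and convert to a sorted, indexed BAM.
# `records` is a data.frame with columns chrom, pos (1-based), strand
# ("+"/"-"), seq; cigar defaults to full-length match.
make_bam <- function(records, chrom_lens, cigar = NULL) {
  records <- records[order(records$chrom, records$pos), , drop = FALSE]
  if (is.null(cigar)) cigar <- paste0(nchar(records$seq), "M")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lens),
                   as.integer(chrom_lens)))
  body <- sprintf("r%04d\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t%s",
                  seq_len(nrow(records)),
                  ifelse(records$strand == "+", 0L, 16L),
                  records$chrom, records$pos, cigar, records$seq,
                  strrep("I", nchar(records$seq)))
  sam <- tempfile(fileext = ".sam")
  writeLines(c(hdr, body), sam)
  Rsamtools::asBam(sam, tempfile(), overwrite = TRUE, indexDestination = TRUE)
}

# Assemble a substitution_profile object directly from per-position tables.
make_profile <- function(coverage, mismatches = NULL) {
  if (is.null(mismatches)) {
    mismatches <- data.frame(chrom = character(0), strand = character(0),
                             pos = integer(0), subst = character(0),
                             y = integer(0))
  }
  structure(list(coverage = data.table::as.data.table(coverage),
                 mismatches = data.table::as.data.table(mismatches)),
            class = "substitution_profile")
}

# Assemble an rsf_mixture object from explicit grid densities.
make_mixture <- function(grid, f1, f2, lambda) {
  f1 <- f1 / clipSiteR:::trapz(grid, f1)
  f2 <- f2 / clipSiteR:::trapz(grid, f2)
  structure(list(grid = grid, f1 = f1, f2 = f2, fhat = NULL,
                 lambda = lambda, grid_step = grid[2] - grid[1],
                 bandwidth = 0, n_target = NA, n_background = NA),
            class = "rsf_mixture")
}

# --- brute-force MRN oracle ------------------------------------------------
# Quadratic-time re-derivation of the rank vectors and the optimal candidate,
# written independently of the package implementation.

oracle_rank <- function(cand) {
  us <- unique(cand[, c("start", "n_s")])
  ue <- unique(cand[, c("end", "n_e")])
  r_s <- integer(nrow(cand))
  r_e <- integer(nrow(cand))
  r_w <- integer(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r_s[i] <- sum(us$n_s > cand$n_s[i] |
                    (us$n_s == cand$n_s[i] & us$start < cand$start[i]))
    r_e[i] <- sum(ue$n_e > cand$n_e[i] |
                    (ue$n_e == cand$n_e[i] & ue$end > cand$end[i]))
    r_w[i] <- sum(cand$width < cand$width[i])
  }
  cand$r_s <- r_s
  cand$r_e <- r_e
  cand$r_w <- r_w
  cand$norm2 <- r_s^2 + r_e^2 + r_w^2
  cand
}

oracle_select <- function(cand) {
  best <- 1L
  for (i in seq_len(nrow(cand))[-1]) {
    better <- FALSE
    if (cand$norm2[i] < cand$norm2[best]) better <- TRUE
    else if (cand$norm2[i] == cand$norm2[best]) {
      if (cand$width[i] < cand$width[best]) better <- TRUE
      else if (cand$width[i] == cand$width[best] &&
               cand$start[i] < cand$start[best]) better <- TRUE
    }
    if (better) best <- i
  }
  cand[best, , drop = FALSE]
}

# Random coverage track for MRN property tests: random S/E fluctuation
# profile over a short window, coverage kept positive throughout.
random_track <- function(len = 60L, base_cov = 5L) {
  S <- rbinom(len, 8, 0.25)
  E <- rbinom(len, 8, 0.25)
  C <- pmax(base_cov + cumsum(S) - c(0L, cumsum(E)[-len]), 1L)
  coverage_track("chrT", "+", 1L, C, S, E)
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

dinuc_counts <- function(s) {
  ch <- strsplit(s, "")[[1]]
  table(paste0(ch[-length(ch)], ch[-1]))
}
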