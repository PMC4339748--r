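# Mini-Rank Norm (MRN) cluster-boundary identification.
#
# Around each high-confidence transition (hcT), candidate cluster boundaries
# are the positions inside the surrounding non-zero coverage window whose
# alignment-start (upstream) or alignment-end (downstream) counts clear a
# background threshold. Each candidate (start k, end l) is summarized by the
# rank vector (r_s, r_e, r_w) of its boundary signals and width; the expected
# coverage of an RBP binding site is a sharply peaked rectangle, i.e. the
# ideal rank vector O = (0, 0, 0). The candidate closest to O in euclidean
# norm wins; ties prefer the shortest cluster, then the 5'-most start.

#' MRN configuration
#'
#' @param N Number of hcTs sampled for noise estimation (default 1000).
#' @param n Half-window around sampled hcTs for noise estimation (default 25).
#' @param threshold \code{"local"} (window-specific, from the fitted noise
#'   model) or \code{"global"} (one threshold from \code{m1}/\code{m2}).
#' @param m1 Minimum-coverage requirement at hcTs, used by the global
#'   threshold (default 20).
#' @param m2 Mode of the coverage distribution at hcTs; when \code{NULL} it is
#'   computed from the data where needed.
#' @param seed RNG seed for the noise-estimation subsample.
#' @return A list of class \code{"mrn_config"}.
#' @export
mrn_config <- function(N = 1000L, n = 25L, threshold = c("local", "global"),
                       m1 = 20L, m2 = NULL, seed = NULL) {
  stopifnot(N >= 1, n >= 1)
  structure(list(N = as.integer(N), n = as.integer(n),
                 threshold = match.arg(threshold),
                 m1 = m1, m2 = m2, seed = seed),
            class = "mrn_config")
}

#' Largest non-zero coverage window containing a position
#'
#' @param track A \code{\link{coverage_track}}.
#' @param pos Genomic position with \code{C(pos) > 0}.
#' @return Genomic interval \code{c(from, to)} of the maximal run of
#'   consecutive positions with positive coverage containing \code{pos}.
#' @export
nonzero_window <- function(track, pos) {
  i <- pos - track$origin + 1L
  if (i < 1L || i > length(track$C) || track$C[i] == 0L) {
    stop("hcT outside covered region: C(", pos, ") = 0 on ",
         track$chrom, "(", track$strand, ")")
  }
  pos_nz <- track$C > 0L
  left <- i
  while (left > 1L && pos_nz[left - 1L]) left <- left - 1L
  right <- i
  n <- length(pos_nz)
  while (right < n && pos_nz[right + 1L]) right <- right + 1L
  c(track$origin + left - 1L, track$origin + right - 1L)
}

# --- noise model -----------------------------------------------------------

#' Two-component Gaussian mixture fit by EM (unequal variances)
#'
#' Used to separate noisy coverage fluctuations (component 1) from sharp,
#' binding-driven jumps (component 2) in the normalized fluctuation data.
#' Initialization uses the 25th/75th percentiles; log-likelihood tolerance
#' 1e-8, at most \code{max_iter} iterations, variance floor 1e-6.
#'
#' @param x Numeric data (normalized non-zero coverage fluctuations).
#' @param max_iter Maximum EM iterations (default 500).
#' @return List with \code{mu1}, \code{sd1}, \code{mu2}, \code{sd2},
#'   \code{w1}, \code{loglik}, \code{iterations}, \code{responsibility2}
#'   (per observation). Component 1 has the smaller mean.
#' @export
em_gauss2 <- function(x, max_iter = 500L) {
  n <- length(x)
  if (n < 10L) stop("insufficient fluctuation data (need >= 10 points)")
  mu <- as.numeric(quantile(x, c(0.25, 0.75)))
  if (mu[2] - mu[1] < 1e-6) {
    # quantile init collapses when one value dominates; fall back to the
    # data range
    mu <- min(x) + c(0.25, 0.75) * (max(x) - min(x))
  }
  s <- rep(max(sd(x) / 2, 1e-3), 2)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  it <- 0L
  repeat {
    it <- it + 1L
    d1 <- w[1] * dnorm(x, mu[1], s[1])
    d2 <- w[2] * dnorm(x, mu[2], s[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r2 <- d2 / tot
    ll <- sum(log(tot))
    if (!is.finite(ll)) stop("EM non-convergence: log-likelihood diverged")
    if (abs(ll - ll_old) < 1e-8 || it >= max_iter) break
    ll_old <- ll
    n2 <- sum(r2)
    n1 <- n - n2
    if (n1 < 1e-8 || n2 < 1e-8) break  # weight collapse; flagged below
    mu[1] <- sum((1 - r2) * x) / n1
    mu[2] <- sum(r2 * x) / n2
    s[1] <- sqrt(max(sum((1 - r2) * (x - mu[1])^2) / n1, 1e-6))
    s[2] <- sqrt(max(sum(r2 * (x - mu[2])^2) / n2, 1e-6))
    w <- c(n1, n2) / n
  }
  if (it >= max_iter && abs(ll - ll_old) >= 1e-8) {
    stop("EM non-convergence after ", max_iter, " iterations (loglik delta ",
         format(abs(ll - ll_old)), ")")
  }
  if (mu[2] < mu[1]) {  # order components by mean
    mu <- rev(mu); s <- rev(s); w <- rev(w); r2 <- 1 - r2
  }
  if (min(w) < 0.01 || (mu[2] - mu[1]) < 1e-3) {
    stop("degenerate Gaussian mixture: fluctuation data do not separate ",
         "into noise and signal components")
  }
  list(mu1 = mu[1], sd1 = s[1], mu2 = mu[2], sd2 = s[2], w1 = w[1],
       loglik = ll, iterations = it, responsibility2 = r2)
}

#' Estimate the coverage-fluctuation noise model
#'
#' Samples up to \code{N} hcTs (without replacement), collects the
#' alignment-start and alignment-end counts in windows of half-width \code{n}
#' around each, normalizes each window by its largest fluctuation, and fits a
#' two-component Gaussian mixture to the pooled non-zero values \eqn{D^+}.
#' The crossover coefficient is
#' \eqn{c = \min\{x \in D^+ : p(k=2|x) \ge p(k=1|x)\}}: the smallest observed
#' normalized fluctuation already attributed to the signal component.
#'
#' @param tracks A \code{\link{coverage_tracks}} list.
#' @param hcts hcT sites (a \code{data.frame} with \code{chrom},
#'   \code{strand}, \code{pos}).
#' @param cfg An \code{\link{mrn_config}}.
#' @return List of class \code{"mrn_noise"} with the mixture parameters and
#'   crossover coefficient \code{c}.
#' @export
estimate_noise <- function(tracks, hcts, cfg = mrn_config()) {
  stopifnot(nrow(hcts) >= 1)
  idx <- seq_len(nrow(hcts))
  if (nrow(hcts) > cfg$N) {
    if (!is.null(cfg$seed)) set.seed(cfg$seed)
    idx <- sort(sample(idx, cfg$N))
  }
  dplus <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    h <- hcts[idx[j], ]
    tr <- get_track(tracks, h$chrom, h$strand)
    from <- h$pos - cfg$n
    to <- h$pos + cfg$n
    sv <- track_slice(tr, "S", from, to)
    ev <- track_slice(tr, "E", from, to)
    m <- max(sv, ev)
    if (m > 0L) {
      v <- c(sv, ev) / m
      dplus[[j]] <- v[v > 0]
    }
  }
  dplus <- unlist(dplus)
  if (length(dplus) < 10L) stop("insufficient fluctuation data")
  fit <- em_gauss2(dplus)
  cross <- dplus[fit$responsibility2 >= 0.5]
  if (length(cross) == 0L) {
    stop("degenerate Gaussian mixture: no fluctuation attributed to signal")
  }
  structure(list(mu1 = fit$mu1, sd1 = fit$sd1, mu2 = fit$mu2, sd2 = fit$sd2,
                 w1 = fit$w1, c = min(cross), n_points = length(dplus),
                 iterations = fit$iterations),
            class = "mrn_noise")
}

#' @export
print.mrn_noise <- function(x, ...) {
  cat(sprintf(
    "mrn_noise: c = %.3f | k=1 N(%.3f, %.3f) w=%.2f | k=2 N(%.3f, %.3f) | %d points\n",
    x$c, x$mu1, x$sd1, x$w1, x$mu2, x$sd2, x$n_points))
  invisible(x)
}

#' Window-specific boundary thresholds from a noise model
#'
#' Scales the crossover coefficient by each side's dynamic range within the
#' window: \eqn{\delta_s = \lceil c \cdot \max S(w) \rceil},
#' \eqn{\delta_e = \lceil c \cdot \max E(w) \rceil}, both clamped to at
#' least 1.
#'
#' @param noise An \code{\link{estimate_noise}} fit.
#' @param track A \code{\link{coverage_track}}.
#' @param w Window \code{c(from, to)}.
#' @return \code{c(delta_s, delta_e)}.
#' @export
local_threshold <- function(noise, track, w) {
  sv <- track_slice(track, "S", w[1], w[2])
  ev <- track_slice(track, "E", w[1], w[2])
  c(max(1, ceiling(noise$c * max(sv))), max(1, ceiling(noise$c * max(ev))))
}

#' Global boundary threshold
#'
#' \eqn{\delta = \lfloor 0.1 \cdot \max(m_1, m_2) \rfloor}, clamped to at
#' least 1, where \eqn{m_1} is the minimum-coverage requirement at hcTs and
#' \eqn{m_2} the mode of the coverage distribution at hcTs.
#'
#' @param m1,m2 Non-negative scalars.
#' @return Integer threshold.
#' @export
global_threshold <- function(m1, m2) {
  stopifnot(m1 >= 0, m2 >= 0)
  max(1L, as.integer(floor(0.1 * max(m1, m2))))
}

# --- candidate enumeration, ranking, selection -----------------------------

#' Enumerate candidate cluster boundaries around an hcT
#'
#' Candidate starts are positions \code{<= pos} in the window whose
#' alignment-start count reaches \code{delta_s}; candidate ends are positions
#' \code{>= pos} whose alignment-end count reaches \code{delta_e}. If a side
#' has no qualifying position, the window edge is used as the sole boundary
#' on that side, so every hcT yields at least one candidate.
#'
#' @param track A \code{\link{coverage_track}}.
#' @param pos hcT position (must lie in \code{w}).
#' @param w Window \code{c(from, to)}.
#' @param delta_s,delta_e Integer thresholds for the start/end side.
#' @return \code{data.frame} with one row per candidate: \code{start},
#'   \code{end}, \code{n_s}, \code{n_e}, \code{width}.
#' @export
enumerate_candidates <- function(track, pos, w, delta_s, delta_e) {
  stopifnot(pos >= w[1], pos <= w[2])
  sv <- track_slice(track, "S", w[1], pos)
  ev <- track_slice(track, "E", pos, w[2])
  starts <- w[1] - 1L + which(sv >= delta_s)
  ends <- pos - 1L + which(ev >= delta_e)
  if (length(starts) == 0L) starts <- w[1]
  if (length(ends) == 0L) ends <- w[2]
  cand <- expand.grid(start = starts, end = ends, KEEP.OUT.ATTRS = FALSE)
  cand$n_s <- sv[cand$start - w[1] + 1L]
  cand$n_e <- ev[cand$end - pos + 1L]
  cand$width <- cand$end - cand$start + 1L
  cand
}

#' Attach rank vectors to candidate clusters
#'
#' \code{r_s} ranks the distinct start positions by decreasing
#' alignment-start count (ties resolved 5'\eqn{\to}3'); \code{r_e} ranks the
#' distinct end positions by decreasing alignment-end count (ties
#' 3'\eqn{\to}5'); \code{r_w} ranks candidate widths increasingly, ties
#' sharing the minimum rank. All ranks are 0-based so the ideal rectangle
#' peak is \code{(0, 0, 0)}.
#'
#' @param cand Candidates from \code{\link{enumerate_candidates}}.
#' @return \code{cand} with added columns \code{r_s}, \code{r_e}, \code{r_w}
#'   and \code{norm2} (squared euclidean norm of the rank vector).
#' @export
rank_candidates <- function(cand) {
  stopifnot(nrow(cand) >= 1)
  us <- unique(cand[, c("start", "n_s")])
  us <- us[order(-us$n_s, us$start), , drop = FALSE]
  r_s <- setNames(seq_len(nrow(us)) - 1L, us$start)
  ue <- unique(cand[, c("end", "n_e")])
  ue <- ue[order(-ue$n_e, -ue$end), , drop = FALSE]
  r_e <- setNames(seq_len(nrow(ue)) - 1L, ue$end)
  cand$r_s <- unname(r_s[as.character(cand$start)])
  cand$r_e <- unname(r_e[as.character(cand$end)])
  cand$r_w <- rank(cand$width, ties.method = "min") - 1L
  cand$norm2 <- cand$r_s^2 + cand$r_e^2 + cand$r_w^2
  cand
}

#' Select the optimal candidate cluster
#'
#' Minimizes the euclidean norm of the rank vector; among equal norms the
#' shortest cluster wins, and among equal widths the 5'-most start.
#'
#' @param cand Ranked candidates from \code{\link{rank_candidates}}.
#' @return The single winning row of \code{cand}.
#' @export
select_optimal <- function(cand) {
  stopifnot(!is.null(cand$norm2))
  cand[order(cand$norm2, cand$width, cand$start)[1L], , drop = FALSE]
}

# --- cluster calling -------------------------------------------------------

#' Call binding-site clusters with the MRN algorithm
#'
#' For every hcT: take the enclosing non-zero coverage window, derive the
#' boundary thresholds (local noise-model-based or global), enumerate and
#' rank candidate boundaries, and keep the optimal candidate. hcTs selecting
#' the identical interval are merged into one cluster. Each cluster is scored
#' by its relative log-odds: the sum of member hcT log-odds divided by the
#' number of crosslinkable bases (T in transcript orientation) in the cluster
#' sequence.
#'
#' @param tracks A \code{\link{coverage_tracks}} list.
#' @param hcts Scored hcTs from \code{\link{classify_hct}} (must carry
#'   \code{log_odds}).
#' @param genome Reference genome (see \code{\link{load_genome}}).
#' @param cfg An \code{\link{mrn_config}}.
#' @param noise Optional precomputed \code{\link{estimate_noise}} fit; when
#'   \code{NULL} and \code{cfg$threshold == "local"} it is estimated here.
#' @param crosslink_base Base susceptible to crosslinking in transcript
#'   orientation (default \code{"T"}; use \code{"G"} for 6SG chemistry).
#' @return A \code{GRanges} of clusters sorted by decreasing relative
#'   log-odds (clusters without crosslinkable bases last, flagged by
#'   \code{rel_log_odds = NA}), with metadata columns \code{n_hcT},
#'   \code{rel_log_odds}, \code{n_crosslinkable}, \code{hcT_pos} (an
#'   \code{IntegerList}) and \code{sum_log_odds}.
#' @export
call_clusters <- function(tracks, hcts, genome, cfg = mrn_config(),
                          noise = NULL, crosslink_base = "T") {
  if (nrow(hcts) == 0L) {
    return(GenomicRanges::GRanges(
      n_hcT = integer(0), rel_log_odds = numeric(0),
      n_crosslinkable = integer(0),
      hcT_pos = IRanges::IntegerList(),
      sum_log_odds = numeric(0)))
  }
  if (is.null(hcts$log_odds)) stop("hcts must carry log_odds (classify_hct)")
  genome <- load_genome(genome)
  if (cfg$threshold == "local" && is.null(noise)) {
    noise <- estimate_noise(tracks, hcts, cfg)
  }
  if (cfg$threshold == "global") {
    m2 <- cfg$m2
    if (is.null(m2)) {
      zt <- table(hcts$z)
      m2 <- as.numeric(names(zt)[which.max(zt)])
    }
    delta_global <- global_threshold(cfg$m1, m2)
  }
  n <- nrow(hcts)
  res_start <- integer(n)
  res_end <- integer(n)
  for (i in seq_len(n)) {
    h <- hcts[i, ]
    tr <- get_track(tracks, h$chrom, h$strand)
    w <- nonzero_window(tr, h$pos)
    if (cfg$threshold == "local") {
      d <- local_threshold(noise, tr, w)
    } else {
      d <- c(delta_global, delta_global)
    }
    cand <- rank_candidates(enumerate_candidates(tr, h$pos, w, d[1], d[2]))
    best <- select_optimal(cand)
    res_start[i] <- best$start
    res_end[i] <- best$end
  }
  key <- paste(hcts$chrom, hcts$strand, res_start, res_end, sep = ":")
  grp <- split(seq_len(n), key)
  cl <- data.frame(
    chrom = vapply(grp, function(ii) hcts$chrom[ii[1]], character(1)),
    strand = vapply(grp, function(ii) hcts$strand[ii[1]], character(1)),
    start = vapply(grp, function(ii) res_start[ii[1]], integer(1)),
    end = vapply(grp, function(ii) res_end[ii[1]], integer(1)),
    n_hcT = lengths(grp),
    sum_log_odds = vapply(grp, function(ii) sum(hcts$log_odds[ii]), numeric(1)),
    row.names = NULL
  )
  hct_pos <- IRanges::IntegerList(lapply(grp, function(ii) sort(hcts$pos[ii])))

  # crosslinkable bases: count of T in the transcript-oriented sequence,
  # i.e. T on + clusters and A (genomic forward) on - clusters
  n_xl <- integer(nrow(cl))
  for (i in seq_len(nrow(cl))) {
    sq <- Biostrings::subseq(genome[[cl$chrom[i]]], cl$start[i], cl$end[i])
    base <- if (cl$strand[i] == "+") crosslink_base else
      unname(COMPLEMENT[crosslink_base])
    n_xl[i] <- Biostrings::countPattern(base, sq)
  }
  cl$n_crosslinkable <- n_xl
  cl$rel_log_odds <- ifelse(n_xl > 0, cl$sum_log_odds / n_xl, NA_real_)

  ord <- order(is.na(cl$rel_log_odds), -ifelse(is.na(cl$rel_log_odds), 0,
                                               cl$rel_log_odds),
               cl$chrom, cl$start)
  cl <- cl[ord, , drop = FALSE]
  hct_pos <- hct_pos[ord]
  gr <- GenomicRanges::GRanges(
    seqnames = cl$chrom,
    ranges = IRanges::IRanges(cl$start, cl$end),
    strand = cl$strand
  )
  S4Vectors::mcols(gr)$n_hcT <- cl$n_hcT
  S4Vectors::mcols(gr)$rel_log_odds <- cl$rel_log_odds
  S4Vectors::mcols(gr)$n_crosslinkable <- cl$n_crosslinkable
  S4Vectors::mcols(gr)$hcT_pos <- unname(hct_pos)
  S4Vectors::mcols(gr)$sum_log_odds <- cl$sum_log_odds
  names(gr) <- NULL
  gr
}
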