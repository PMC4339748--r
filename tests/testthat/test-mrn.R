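# Mini-Rank Norm: windows, noise model, thresholds, candidate ranking,
# optimal selection and cluster calling.

test_that("nonzero_window extracts the maximal positive-coverage run", {
  tr <- coverage_track("c", "+", 1L, C = c(0, 1, 2, 2, 1, 0),
                       S = rep(0, 6), E = rep(0, 6))
  expect_equal(nonzero_window(tr, 3), c(2, 5))
  expect_error(nonzero_window(tr, 1), "outside covered region")

  tr_all <- coverage_track("c", "+", 10L, C = rep(2, 5), S = rep(0, 5),
                           E = rep(0, 5))
  expect_equal(nonzero_window(tr_all, 12), c(10, 14))

  tr_single <- coverage_track("c", "+", 1L, C = c(0, 1, 0), S = rep(0, 3),
                              E = rep(0, 3))
  expect_equal(nonzero_window(tr_single, 2), c(2, 2))
})

test_that("the Gaussian-mixture EM separates noise from sharp jumps", {
  # planted 50/50 mixture: noise N(0.05, 0.01), jumps N(0.8, 0.1)
  cs <- numeric(5)
  for (s in 1:5) {
    set.seed(100 + s)
    x <- c(rnorm(1000, 0.05, 0.01), rnorm(1000, 0.8, 0.1))
    x <- x[x > 0 & x <= 1]
    fit <- em_gauss2(x)
    expect_lt(abs(fit$mu1 - 0.05), 0.02)
    expect_lt(abs(fit$mu2 - 0.8), 0.05)
    cs[s] <- min(x[fit$responsibility2 >= 0.5])
  }
  # the crossover coefficient is the smallest observed value attributed to
  # the jump component; for these parameters that is the lower tail of
  # N(0.8, 0.1) over 1000 draws (expected minimum ~ 0.8 - 3.2 * 0.1), and
  # it is seed-stable
  expect_true(all(cs >= 0.35 & cs <= 0.6))
  expect_lt(max(cs) - min(cs), 0.1)

  # independent oracle: mclust on the same data
  suppressPackageStartupMessages(library(mclust))
  set.seed(101)
  x <- c(rnorm(1000, 0.05, 0.01), rnorm(1000, 0.8, 0.1))
  x <- x[x > 0 & x <= 1]
  fit <- em_gauss2(x)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_lt(abs(fit$mu1 - min(mc$parameters$mean)), 0.01)
  expect_lt(abs(fit$mu2 - max(mc$parameters$mean)), 0.01)

  # a single tight Gaussian cannot be decomposed
  set.seed(102)
  expect_error(em_gauss2(rnorm(2000, 0.5, 0.001)), "degenerate")
  expect_error(em_gauss2(rnorm(5, 0.5, 0.1)), "insufficient")
})

test_that("estimate_noise pools window fluctuations and finds the crossover", {
  set.seed(9)
  # track with sharp pile-up boundaries (counts ~ 40) over a noisy floor
  len <- 4000L
  S <- rbinom(len, 2, 0.05)
  E <- rbinom(len, 2, 0.05)
  peaks <- seq(100L, len - 100L, by = 200L)
  S[peaks] <- S[peaks] + 40L
  E[peaks + 30L] <- E[peaks + 30L] + 40L
  C <- pmax(cumsum(S) - c(0L, cumsum(E)[-len]), 1L)
  tracks <- structure(list("chrN:+" = coverage_track("chrN", "+", 1L, C, S, E)),
                      class = "coverage_track_list")
  hcts <- data.frame(chrom = "chrN", strand = "+", pos = peaks + 15L)
  noise <- estimate_noise(tracks, hcts, mrn_config(N = 10, seed = 3))
  expect_s3_class(noise, "mrn_noise")
  # normalized floor fluctuations sit at ~1/40, jumps at 1
  expect_lt(noise$mu1, 0.2)
  expect_gt(noise$mu2, 0.5)
  expect_true(noise$c > 0.05 && noise$c <= 1)

  # |T| <= N uses every hcT deterministically (no resampling)
  n1 <- estimate_noise(tracks, hcts, mrn_config(N = 1000))
  n2 <- estimate_noise(tracks, hcts, mrn_config(N = 1000))
  expect_identical(n1$c, n2$c)
  expect_identical(n1$n_points, n2$n_points)
})

test_that("local and global thresholds follow their formulas", {
  tr <- coverage_track("c", "+", 1L,
                       C = rep(5, 10),
                       S = c(10, 0, 0, 2, 0, 0, 0, 0, 0, 0),
                       E = c(0, 0, 0, 0, 0, 3, 0, 0, 20, 0))
  noise <- structure(list(c = 0.3), class = "mrn_noise")
  expect_equal(local_threshold(noise, tr, c(1, 10)), c(3, 6))
  # c -> 1 keeps only the sharpest jump per side
  noise1 <- structure(list(c = 1), class = "mrn_noise")
  expect_equal(local_threshold(noise1, tr, c(1, 10)), c(10, 20))
  # c * max < 1 clamps to 1
  noise_small <- structure(list(c = 0.01), class = "mrn_noise")
  expect_equal(local_threshold(noise_small, tr, c(1, 10)), c(1, 1))

  expect_equal(global_threshold(20, 47), 4L)
  expect_equal(global_threshold(100, 20), 10L)
  expect_equal(global_threshold(5, 5), 1L)  # floor(0.5) clamped to 1
})

test_that("candidate enumeration matches the worked example and falls back", {
  tr <- coverage_track("c", "+", 1L,
                       C = rep(5, 10),
                       S = c(5, 0, 0, 3, 0, 0, 0, 0, 0, 0),
                       E = c(0, 0, 0, 0, 0, 2, 0, 0, 4, 0))
  cand <- enumerate_candidates(tr, 5, c(1, 10), 2, 2)
  expect_equal(nrow(cand), 4L)
  expect_setequal(cand$width, c(6L, 9L, 3L, 6L))
  expect_setequal(unique(cand$start), c(1L, 4L))
  expect_setequal(unique(cand$end), c(6L, 9L))

  # thresholds above all fluctuations: whole window as the only candidate
  cand_fb <- enumerate_candidates(tr, 5, c(1, 10), 99, 99)
  expect_equal(nrow(cand_fb), 1L)
  expect_equal(c(cand_fb$start, cand_fb$end), c(1L, 10L))

  # hcT that is itself a qualifying start and end gives a width-1 candidate
  tr2 <- coverage_track("c", "+", 1L, C = rep(3, 5),
                        S = c(0, 0, 4, 0, 0), E = c(0, 0, 4, 0, 0))
  cand1 <- enumerate_candidates(tr2, 3, c(1, 5), 2, 2)
  expect_true(any(cand1$width == 1L & cand1$start == 3L & cand1$end == 3L))
})

test_that("rank vectors reproduce the hand-enumerated example", {
  tr <- coverage_track("c", "+", 1L,
                       C = rep(5, 10),
                       S = c(5, 0, 0, 3, 0, 0, 0, 0, 0, 0),
                       E = c(0, 0, 0, 0, 0, 2, 0, 0, 4, 0))
  cand <- rank_candidates(enumerate_candidates(tr, 5, c(1, 10), 2, 2))
  get <- function(s, e) cand[cand$start == s & cand$end == e, ]
  expect_equal(unlist(get(1, 6)[, c("r_s", "r_e", "r_w")], use.names = FALSE),
               c(0L, 1L, 1L))
  expect_equal(unlist(get(1, 9)[, c("r_s", "r_e", "r_w")], use.names = FALSE),
               c(0L, 0L, 3L))
  expect_equal(unlist(get(4, 6)[, c("r_s", "r_e", "r_w")], use.names = FALSE),
               c(1L, 1L, 0L))
  expect_equal(unlist(get(4, 9)[, c("r_s", "r_e", "r_w")], use.names = FALSE),
               c(1L, 0L, 1L))
  # norm ties {2, 2, 2} resolve to the shortest candidate [4, 6]
  best <- select_optimal(cand)
  expect_equal(c(best$start, best$end), c(4L, 6L))

  # single candidate is the identity rank vector
  single <- rank_candidates(data.frame(start = 5L, end = 9L, n_s = 1L,
                                       n_e = 1L, width = 5L))
  expect_equal(unlist(single[, c("r_s", "r_e", "r_w")], use.names = FALSE),
               c(0L, 0L, 0L))

  # start-count ties are ranked 5'->3'
  tie <- rank_candidates(data.frame(start = c(2L, 7L), end = 10L,
                                    n_s = c(4L, 4L), n_e = 1L,
                                    width = c(9L, 4L)))
  expect_equal(tie$r_s[tie$start == 2L], 0L)
  expect_equal(tie$r_s[tie$start == 7L], 1L)
})

test_that("a perfect rank vector always wins and (0,2,0) loses to (0,1,0)", {
  cand <- data.frame(start = c(1L, 3L, 5L), end = c(20L, 18L, 15L),
                     n_s = c(9L, 5L, 2L), n_e = c(2L, 5L, 9L),
                     width = c(20L, 16L, 11L))
  r <- rank_candidates(cand)
  zero <- r[r$r_s == 0 & r$r_e == 0 & r$r_w == 0, ]
  if (nrow(zero) == 1L) expect_equal(select_optimal(r)$start, zero$start)
  expect_lt(sum(c(0, 1, 0)^2), sum(c(0, 2, 0)^2))
})

test_that("select_optimal agrees exactly with the brute-force oracle", {
  set.seed(77)
  for (i in 1:500) {
    tr <- random_track(sample(20:60, 1))
    pos <- sample(5:(length(tr$C) - 5), 1)
    w <- nonzero_window(tr, pos)
    d_s <- sample(1:3, 1)
    d_e <- sample(1:3, 1)
    cand <- enumerate_candidates(tr, pos, w, d_s, d_e)
    got_rank <- rank_candidates(cand)
    want_rank <- oracle_rank(cand)
    expect_identical(got_rank$r_s, want_rank$r_s)
    expect_identical(got_rank$r_e, want_rank$r_e)
    expect_identical(got_rank$r_w, as.integer(want_rank$r_w))
    got <- select_optimal(got_rank)
    want <- oracle_select(want_rank)
    expect_identical(c(got$start, got$end), c(want$start, want$end))
  }
})

test_that("cluster calling merges identical intervals and keeps hcTs assigned", {
  set.seed(5)
  # rectangular pile-up: 30 reads over [50, 85] on a low background
  reads <- data.frame(start = c(rep(50L, 30L), sample(1:150, 20L)),
                      stringsAsFactors = FALSE)
  reads$end <- reads$start + 35L
  tr <- build_coverage(reads, "chrM", "+")
  tracks <- structure(list("chrM:+" = tr), class = "coverage_track_list")
  genome <- Biostrings::DNAStringSet(c(chrM = random_dna(300)))
  grid <- seq(0.001, 1, 0.001)
  m <- make_mixture(grid, dnorm(grid, 0.05, 0.03), dnorm(grid, 0.4, 0.1), 0.4)
  hcts <- data.frame(chrom = "chrM", strand = "+", pos = c(60L, 70L),
                     subst = "TC", y = c(12L, 14L), z = c(30L, 30L))
  hcts$x <- hcts$y / hcts$z
  hcts$posterior2 <- posterior_counts(m, hcts$y, hcts$z)[, "p2"]
  hcts$log_odds <- log_odds_counts(m, hcts$y, hcts$z)

  cl <- call_clusters(tracks, hcts, genome,
                      mrn_config(threshold = "global", m1 = 20, m2 = 30))
  # both hcTs under the same rectangle merge into one cluster
  expect_equal(length(cl), 1L)
  expect_equal(S4Vectors::mcols(cl)$n_hcT, 2L)
  expect_equal(sort(unlist(S4Vectors::mcols(cl)$hcT_pos)), c(60L, 70L),
               ignore_attr = TRUE)
  d <- as.data.frame(cl)
  expect_true(d$start <= 60L && d$end >= 70L)
  # relative log-odds normalizes by the T count of the cluster sequence
  sq <- as.character(Biostrings::subseq(genome[["chrM"]], d$start, d$end))
  nT <- sum(strsplit(sq, "")[[1]] == "T")
  expect_equal(S4Vectors::mcols(cl)$rel_log_odds,
               sum(hcts$log_odds) / nT)

  # empty hcT set gives an empty result
  cl0 <- call_clusters(tracks, hcts[0, ], genome)
  expect_equal(length(cl0), 0L)
})

test_that("two peaks separated by a deep valley become two clusters", {
  set.seed(6)
  reads <- data.frame(start = c(rep(100L, 40L), rep(160L, 40L),
                                sample(80:200, 10L, replace = TRUE)))
  reads$end <- reads$start + 35L
  tr <- build_coverage(reads, "chrV", "+")
  tracks <- structure(list("chrV:+" = tr), class = "coverage_track_list")
  genome <- Biostrings::DNAStringSet(c(chrV = random_dna(400)))
  grid <- seq(0.001, 1, 0.001)
  m <- make_mixture(grid, dnorm(grid, 0.05, 0.03), dnorm(grid, 0.4, 0.1), 0.4)
  hcts <- data.frame(chrom = "chrV", strand = "+", pos = c(115L, 175L),
                     subst = "TC", y = c(15L, 15L), z = c(40L, 40L))
  hcts$x <- hcts$y / hcts$z
  hcts$posterior2 <- posterior_counts(m, hcts$y, hcts$z)[, "p2"]
  hcts$log_odds <- log_odds_counts(m, hcts$y, hcts$z)
  cl <- call_clusters(tracks, hcts, genome,
                      mrn_config(threshold = "global", m1 = 40, m2 = 40))
  expect_equal(length(cl), 2L)
  d <- as.data.frame(cl)
  d <- d[order(d$start), ]
  expect_true(d$end[1] < d$start[2])
})

test_that("cluster calling is deterministic for a fixed seed", {
  set.seed(8)
  reads <- data.frame(start = sample(1:400, 300, replace = TRUE))
  reads$end <- reads$start + 35L
  tr <- build_coverage(reads, "chrD", "+")
  tracks <- structure(list("chrD:+" = tr), class = "coverage_track_list")
  genome <- Biostrings::DNAStringSet(c(chrD = random_dna(600)))
  grid <- seq(0.001, 1, 0.001)
  m <- make_mixture(grid, dnorm(grid, 0.05, 0.03), dnorm(grid, 0.4, 0.1), 0.4)
  pos <- sort(sample(50:350, 40))
  hcts <- data.frame(chrom = "chrD", strand = "+", pos = pos, subst = "TC",
                     y = 12L, z = 30L, x = 0.4)
  hcts <- hcts[track_slice(tr, "C", 1, 600)[pos] > 0, ]
  hcts$posterior2 <- posterior_counts(m, hcts$y, hcts$z)[, "p2"]
  hcts$log_odds <- log_odds_counts(m, hcts$y, hcts$z)
  cl1 <- call_clusters(tracks, hcts, genome, mrn_config(N = 20, seed = 42))
  cl2 <- call_clusters(tracks, hcts, genome, mrn_config(N = 20, seed = 42))
  expect_identical(as.data.frame(cl1), as.data.frame(cl2))
  # every hcT in covered sequence is assigned to exactly one cluster
  expect_equal(sum(S4Vectors::mcols(cl1)$n_hcT), nrow(hcts))
  all_pos <- unlist(S4Vectors::mcols(cl1)$hcT_pos)
  expect_equal(sort(all_pos), hcts$pos, ignore_attr = TRUE)
})
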