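toy_pwm <- function(consensus = "ACAGGAAGTG", p = 0.94) {
  L <- nchar(consensus)
  m <- matrix((1 - p) / 3, 4, L,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  idx <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  m[cbind(idx, seq_len(L))] <- p
  pwm(m, name = "toy")
}

test_that("the consensus scores maximally at position 1 on both strands", {
  x <- toy_pwm()
  hits <- scan_pwm("ACAGGAAGTG", x, threshold = 0.99 * pwm_max_score(x))
  expect_equal(hits$pos, 1)
  expect_equal(hits$strand, "+")
  expect_equal(hits$score, pwm_max_score(x), tolerance = 1e-10)
  rc <- scan_pwm("CACTTCCTGT", x, threshold = 0.99 * pwm_max_score(x))
  expect_equal(rc$strand, "-")
  expect_equal(rc$score, hits$score)
})

test_that("scanning is shift-equivariant and skips N windows", {
  x <- toy_pwm()
  thr <- 0.8 * pwm_max_score(x)
  s <- "TTTTACAGGAAGTGTTTT"
  h1 <- scan_pwm(s, x, thr)
  h2 <- scan_pwm(paste0("GGGGG", s), x, thr)
  expect_equal(h2$pos, h1$pos + 5)
  hN <- scan_pwm("TTTTACAGGANGTGTTTT", x, thr)
  expect_equal(nrow(hN), 0)
  expect_error(scan_pwm("ACGTX", x), "A/C/G/T/N")
})

test_that("PWM hit enumeration matches the brute-force scan", {
  x <- toy_pwm("GGAA", p = 0.7)
  for (s in 1:500) {
    set.seed(s)
    seq <- paste(sample(c("A", "C", "G", "T", "N"), 60, TRUE,
                        prob = c(0.24, 0.24, 0.25, 0.25, 0.02)),
                 collapse = "")
    thr <- runif(1, 0.2, 0.9) * pwm_max_score(x)
    got <- scan_pwm(seq, x, thr)
    want <- bf_pwm_hits(seq, x$matrix, x$background, thr)
    want <- want[order(want$pos, want$strand), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got$pos, want$pos)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-10)
  }
})

test_that("13 sites inside 300 bp form one cluster with count 13", {
  pos <- 2000 + 23 * (0:12)
  cl <- motif_cluster(pos, region_length = 5000, min_sites = 3,
                      n_shuffle = 200, seed = 1)
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(cl$clusters$n_sites, 13)
  expect_equal(cl$max_count, 13L)
  expect_lte(cl$p_value, 0.05)
})

test_that("hits spaced 400 bp apart form no cluster", {
  cl <- motif_cluster(seq(1, 4001, by = 400), region_length = 5000,
                      min_sites = 2, n_shuffle = 100, seed = 1)
  expect_equal(nrow(cl$clusters), 0)
})

test_that("window count statistic matches the sliding-window maximum", {
  for (s in 1:200) {
    set.seed(s)
    pos <- sort(sample(1:3000, sample(2:40, 1)))
    w <- sample(c(50, 300, 500), 1)
    cl <- motif_cluster(pos, region_length = 3000, window = w,
                        min_sites = 2, n_shuffle = 0)
    expect_equal(cl$max_count, bf_max_window_count(pos, w))
  }
})

test_that("cluster p-values are roughly uniform under Poisson placement", {
  set.seed(99)
  hits <- replicate(150, sort(sample(1:20000, 25)), simplify = FALSE)
  ps <- vapply(hits, function(p)
    motif_cluster(p, region_length = 20000, n_shuffle = 99)$p_value, 1)
  rate <- mean(ps <= 0.05)
  expect_gte(rate, 0.0)
  expect_lte(rate, 0.12)
})

enr_fixture <- function(seed, at_ends) {
  set.seed(seed)
  st <- round(seq(5000, 9.5e5, length.out = 150))
  tr <- data.frame(chrom = "chr1", start = st, end = st + 4000)
  if (at_ends) {
    pos <- c(tr$start, tr$end) + sample(-500:500, 300, TRUE)
  } else {
    pos <- sample(1e6, 400)
  }
  peaks <- data.frame(chrom = "chr1", start = pmax(1, pos - 100),
                      end = pos + 100)
  list(tr = tr, peaks = peaks, sizes = c(chr1 = 1e6))
}

test_that("end enrichment is calibrated under uniform peak placement", {
  fx <- enr_fixture(3, at_ends = FALSE)
  r <- end_enrichment(fx$tr, fx$peaks, fx$sizes, n_random = 400, seed = 10)
  expect_gt(r$ratio, 0.8)
  expect_lt(r$ratio, 1.2)
  expect_gt(r$p_value, 0.05)
})

test_that("peaks planted at every end give the minimal empirical p", {
  fx <- enr_fixture(4, at_ends = TRUE)
  r <- end_enrichment(fx$tr, fx$peaks, fx$sizes, n_random = 200, seed = 11)
  expect_equal(r$observed_rate, 1)
  expect_equal(r$p_value, 1 / 201)  # +1-corrected minimum
  expect_equal(r$ratio, 1 / r$null_rate)  # at its maximum for the fixture
})

test_that("degenerate enrichment inputs are handled", {
  fx <- enr_fixture(5, at_ends = FALSE)
  expect_error(end_enrichment(fx$tr, fx$peaks, fx$sizes, n_random = 50),
               "n_random")
  empty <- fx$peaks[0, ]
  expect_message(r <- end_enrichment(fx$tr, empty, fx$sizes,
                                     n_random = 100), "no peaks")
  expect_true(is.na(r$ratio))
})
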