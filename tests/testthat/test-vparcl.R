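pileup_with <- function(ref, depth, c_at = integer(0), c_count = 0L) {
  L <- segment_lengths(ref)[[1]]
  seg <- names(ref$segments)[1]
  M <- matrix(0L, L, 6L, dimnames = list(NULL, c("A", "C", "G", "T", "N", "depth")))
  depth <- rep_len(depth, L)
  refc <- strsplit(ref$segments[[seg]], "")[[1]]
  M[cbind(seq_len(L), match(refc, c("A", "C", "G", "T", "N")))] <- depth
  M[, "depth"] <- as.integer(depth)
  for (pos in c_at) {
    M[pos, "C"] <- as.integer(c_count)
    M[pos, refc[pos]] <- M[pos, refc[pos]] - as.integer(c_count)
  }
  structure(stats::setNames(list(M), seg), class = "pileup_matrix")
}

test_that("transition rates count C at reference-T positions, with masking", {
  ref <- toy_reference(120)
  tp <- t_positions(ref, "SEG")
  pu <- pileup_with(ref, 10L, c_at = tp[3], c_count = 3L)
  tt <- transition_rates(pu, ref, min_depth = 1L)
  expect_equal(nrow(tt), length(tp))
  expect_equal(tt$rate[tt$pos == tp[3]], 0.3)
  expect_true(all(tt$rate[tt$pos != tp[3]] == 0))

  # depth 999 is masked at the default threshold of 1000
  pu999 <- pileup_with(ref, 999L)
  tt999 <- transition_rates(pu999, ref)
  expect_true(all(tt999$masked))
  expect_true(all(is.na(tt999$rate)))
  pu1000 <- pileup_with(ref, 1000L)
  expect_false(any(transition_rates(pu1000, ref)$masked))

  # an error-free run has rate exactly 0 everywhere unmasked
  set.seed(71)
  ref2 <- toy_reference(400)
  prof <- structure(list(SEG = rep(0.5, 400)), class = "exposure_profile",
                    temperature = 50)
  pa <- library_params(n_fragments = 3000L)
  fr <- simulate_fragments(ref2, prof, NULL, pa, "CL-")
  mol <- dedup_molecules(truth_molecules(fr, pa))
  tt0 <- transition_rates(build_pileup(mol, ref2), ref2, min_depth = 50L)
  expect_true(all(tt0$rate[!tt0$masked] == 0))
})

test_that("signal track arithmetic and masking", {
  ref <- toy_reference(120)
  tp <- t_positions(ref, "SEG")
  n <- length(tp)
  mk <- function(rate, depth = 2000L, masked_at = integer(0)) {
    d <- rep(depth, n); d[match(masked_at, tp)] <- 10L
    tab <- data.frame(segment = "SEG", pos = tp, depth = d,
                      c_count = as.integer(round(rate * d)),
                      rate = ifelse(d < 1000L, NA_real_, rate),
                      masked = d < 1000L, stringsAsFactors = FALSE)
    structure(tab, class = c("transition_table", "data.frame"),
              min_depth = 1000L)
  }
  s1 <- vparcl_signal(mk(0.05), mk(0.05), pseudo = 0)
  expect_equal(unique(s1$signal), 1)

  s2 <- vparcl_signal(mk(0.3), mk(0.1), pseudo = 0)
  expect_equal(unique(s2$signal), 3)

  # pseudocount keeps a zero control finite
  s3 <- vparcl_signal(mk(0.01), mk(0), pseudo = 0.001)
  expect_equal(unique(s3$signal), (0.01 + 0.001) / 0.001)
  expect_true(all(is.finite(s3$signal)))

  # default pseudocount is 1/min_depth
  s3b <- vparcl_signal(mk(0.01), mk(0))
  expect_equal(unique(s3b$signal), (0.01 + 1e-3) / 1e-3)

  # a position masked in any replicate of any condition is masked overall
  s4 <- vparcl_signal(list(mk(0.3), mk(0.3, masked_at = tp[2])),
                      list(mk(0.1)))
  expect_true(s4$masked[2])
  expect_true(is.na(s4$signal[2]))
  expect_false(any(s4$masked[-2]))

  # replicate averaging is mean of per-replicate rates
  s5 <- vparcl_signal(list(mk(0.2), mk(0.4)), mk(0.1), pseudo = 0)
  expect_equal(unique(s5$signal), 0.3 / 0.1)

  expect_error(vparcl_signal(list(), mk(0.1)), "at least one replicate")
})

test_that("KS statistic matches brute-force ECDF enumeration", {
  expect_equal(ks_compare(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))$D, 0)
  ks <- ks_compare(c(0.1, 0.2), c(0.9, 1.0))
  expect_equal(ks$D, 1)

  set.seed(72)
  for (rep in 1:8) {
    n <- sample(5:100, 1); m <- sample(5:100, 1)
    x <- round(runif(n), sample(c(1, 2, 6), 1))  # coarse rounding forces ties
    y <- round(runif(m) + runif(1, -0.2, 0.2), 2)
    ks <- ks_compare(x, y)
    expect_equal(ks$D, oracle_ks_D(x, y))
  }
  # agreement with stats::ks.test on tie-free data
  set.seed(73)
  x <- rnorm(40); y <- rnorm(35, 0.5)
  ks <- ks_compare(x, y)
  ref <- suppressWarnings(stats::ks.test(x, y))
  expect_equal(ks$D, unname(ref$statistic))
  expect_equal(ks$p_value, ref$p.value, tolerance = 1e-8)

  expect_error(ks_compare(0.1, c(0.2, 0.3)), "at least 2")
})

test_that("signal correlations handle self, negation and noise", {
  set.seed(74)
  x <- runif(200)
  self <- correlate_signals(x, x)
  expect_equal(self$coefficient, 1)

  neg <- correlate_signals(x, -(x - mean(x)))
  expect_equal(neg$coefficient, -1)

  a <- rnorm(1000); b <- rnorm(1000)
  ind <- correlate_signals(a, b)
  expect_lt(abs(ind$coefficient), 0.1)
  expect_gt(ind$p_value, 1e-4)

  const <- correlate_signals(rep(1, 100), runif(100))
  expect_true(const$undefined)
  expect_true(is.na(const$coefficient))

  # NA positions are excluded pairwise
  x2 <- x; x2[1:50] <- NA
  expect_equal(correlate_signals(x2, x)$n, 150L)
  expect_error(correlate_signals(c(1, NA, NA), c(1, 2, 3)), "at least 3")
})

test_that("signal thresholding reports the achieved quantile", {
  mk_track <- function(sig) {
    structure(data.frame(segment = "S", pos = seq_along(sig), r_plus = 0.1,
                         r_minus = 0.1, signal = sig, masked = is.na(sig),
                         stringsAsFactors = FALSE),
              class = c("signal_track", "data.frame"), min_depth = 1000L,
              pseudo = 1e-3)
  }
  flat <- threshold_signals(mk_track(rep(1, 8)), cutoff = 1.5)
  expect_equal(nrow(flat$positions), 0L)
  expect_equal(flat$quantile_pct, 100)

  some <- threshold_signals(mk_track(c(1, 1, 1, 2)), cutoff = 1.5)
  expect_equal(nrow(some$positions), 1L)
  expect_equal(some$pct_above, 25)
  expect_equal(some$quantile_pct, 75)
  expect_equal(some$positions$pos, 4L)

  # masked positions never contribute
  masked <- threshold_signals(mk_track(c(NA, 9, 1, 1)), cutoff = 1.5)
  expect_equal(masked$n_unmasked, 3L)
  expect_equal(masked$pct_above, 100 / 3)
})
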