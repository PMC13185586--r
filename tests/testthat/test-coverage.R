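fake_pileup <- function(depths) {
  out <- lapply(depths, function(d) {
    M <- matrix(0L, length(d), 6L,
                dimnames = list(NULL, c("A", "C", "G", "T", "N", "depth")))
    M[, "depth"] <- as.integer(d)
    M[, "A"] <- as.integer(d)
    M
  })
  structure(out, class = "pileup_matrix")
}

test_that("ratiometric normalization", {
  cp <- normalize_coverage(fake_pileup(list(S = c(10, 30, 60))))
  expect_equal(cp$pct$S, c(10, 30, 60))

  cp2 <- normalize_coverage(fake_pileup(list(S = rep(7, 100))))
  expect_equal(cp2$pct$S, rep(1, 100))

  d <- numeric(50); d[20] <- 33
  cp3 <- normalize_coverage(fake_pileup(list(S = d)))
  expect_equal(cp3$pct$S[20], 100)
  expect_equal(sum(cp3$pct$S), 100)

  expect_warning(cp4 <- normalize_coverage(fake_pileup(list(S = numeric(10)))),
                 "zero total depth")
  expect_equal(sum(cp4$pct$S), 0)
})

test_that("priming-site profiles tally deduplicated anchors", {
  ref <- toy_reference(300)
  mol <- data.frame(segment = "SEG", anchor = c(100L, 100L, 100L, 200L, 200L))
  pp <- call_priming_sites(mol, ref)
  expect_equal(pp$count$SEG[100], 3L)
  expect_equal(pp$pct$SEG[100], 60)
  expect_equal(pp$pct$SEG[200], 40)

  pp1 <- call_priming_sites(data.frame(segment = "SEG", anchor = 42L), ref)
  expect_equal(pp1$pct$SEG[42], 100)

  # molecules lacking an anchor are skipped
  ppna <- call_priming_sites(data.frame(segment = "SEG",
                                        anchor = c(10L, NA)), ref)
  expect_equal(sum(ppna$count$SEG), 1L)
})

test_that("window statistics reproduce the published length percentages", {
  # RNA1 is 3107 nt, RNA2 1400 nt in the bipartite nodavirus genome
  ref <- fhv_like_reference(seed = 1)
  uniform <- normalize_coverage(fake_pileup(list(RNA1 = rep(1, 3107),
                                                 RNA2 = rep(1, 1400))))
  expect_equal(window_stats(uniform, "RNA1:26-75")$pct_of_length, 1.6)
  expect_equal(window_stats(uniform, "RNA1:151-250")$pct_of_length, 3.2)
  expect_equal(window_stats(uniform, "RNA1:2901-3050")$pct_of_length, 4.8)
  expect_equal(window_stats(uniform, "RNA2:26-100")$pct_of_length, 5.4)
  expect_equal(window_stats(uniform, "RNA2:276-375")$pct_of_length, 7.1)
  expect_equal(window_stats(uniform, "RNA2:1251-1350")$pct_of_length, 7.1)

  # under uniform coverage, share of coverage equals share of length
  ws <- window_stats(uniform, "RNA1:26-75")
  expect_equal(ws$pct_of_coverage, 100 * 50 / 3107)

  whole <- window_stats(uniform, "RNA1:1-3107")
  expect_equal(whole$pct_of_length, 100)
  expect_equal(whole$pct_of_coverage, 100)

  expect_error(window_stats(uniform, "RNA2:1390-1500"), "outside segment")
})

test_that("moving averages use centered shrinking windows", {
  expect_equal(moving_average(rep(3.5, 40), 7), rep(3.5, 40))
  x <- numeric(100); x[50] <- 1
  sm <- moving_average(x, 5)
  expect_equal(sm[48:52], rep(0.2, 5))
  expect_equal(sum(sm != 0), 5L)
  expect_equal(moving_average(x, 1), x)
  # edges shrink: first value averages only positions 1..3 for window 5
  y <- c(6, 0, 0, 0, 0, 0)
  expect_equal(moving_average(y, 5)[1], 2)
  expect_warning(glob <- moving_average(1:4, 9), "wider than")
  expect_equal(glob, rep(2.5, 4))
})

test_that("trend classification follows the rank-correlation rules", {
  inc <- classify_trend(fake_series(1:10), "S:1-10")
  expect_equal(inc$class, "increasing")
  expect_equal(inc$rho, 1)

  dec <- classify_trend(fake_series(10:1), "S:1-10")
  expect_equal(dec$class, "decreasing")

  # flat and below the uniform expectation (10 % of length here)
  flat <- classify_trend(fake_series(rep(5, 10) + c(0.2, -0.2)), "S:1-10")
  expect_equal(flat$class, "flat_low")

  # alternating high series: rank correlation weak, range large
  fluc <- classify_trend(fake_series(rep(c(20, 60), 5)), "S:1-10")
  expect_equal(fluc$class, "fluctuating")

  # monotone but nearly flat high series: not directional, not low
  shallow <- classify_trend(fake_series(seq(50, 54, length.out = 10)), "S:1-10")
  expect_equal(shallow$class, "fluctuating")

  expect_error(classify_trend(fake_series(c(1, 2, 3), temps = c(50, 55, 60)),
                              "S:1-10"),
               "at least 4 temperatures")
})

test_that("region fold change and its undefined flag", {
  s <- fake_series(c(2, 6.2, rep(3, 8)))
  fc <- region_fold_change(s, "S:1-10", 50, 52.5)
  expect_equal(fc$ratio, 3.1)
  expect_false(fc$undefined)

  same <- region_fold_change(fake_series(rep(4, 10)), "S:1-10", 50, 75)
  expect_equal(same$ratio, 1)

  z <- fake_series(c(0, rep(5, 9)))
  fz <- region_fold_change(z, "S:1-10", 50, 55)
  expect_true(fz$undefined)
  expect_true(is.na(fz$ratio))
  expect_error(region_fold_change(s, "S:1-10", 50, 51), "not present")
})

test_that("bedGraph export converts coordinates and merges runs", {
  ref <- toy_reference(100)
  v <- numeric(100); v[1] <- 2; v[50:60] <- 1.5
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(list(SEG = v), path)
  lines <- readLines(path)
  # 1-based position 1 becomes the interval [0, 1)
  expect_equal(lines[1], "SEG\t0\t1\t2")
  # contiguous equal values merge into one interval
  expect_true("SEG\t49\t60\t1.5" %in% lines)
  back <- read_bedgraph(path, ref)
  expect_equal(back$SEG, v)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_track_tsv(list(SEG = v), tsv)
  expect_equal(read_track_tsv(tsv, ref)$SEG, v)
})

test_that("normalization conservation holds on simulated runs", {
  set.seed(61)
  ref <- random_genome(c(S1 = 700L, S2 = 400L))
  bm <- barrier_model(data.frame(segment = "S1", start = 100, end = 300,
                                 b = 0.1, a = 0.7, t50 = 58, k = 2),
                      default_exposure = 0.08)
  pa <- library_params(n_fragments = 5000L)
  for (temp in c(50, 65)) {
    prof <- exposure_at_temperature(bm, ref, temp)
    fr <- simulate_fragments(ref, prof, NULL, pa, "CL-")
    mol <- dedup_molecules(truth_molecules(fr, pa))
    cp <- normalize_coverage(build_pileup(mol, ref))
    for (seg in names(cp$pct)) {
      expect_equal(sum(cp$pct[[seg]]), 100, tolerance = 1e-6)
    }
    pp <- call_priming_sites(mol, ref)
    for (seg in names(pp$pct)) {
      expect_equal(sum(pp$pct[[seg]]), 100, tolerance = 1e-6)
    }
  }
})
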