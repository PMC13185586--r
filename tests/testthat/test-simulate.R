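test_that("anchors are confined to priming-competent positions", {
  set.seed(101)
  ref <- toy_reference(800)
  e <- numeric(800); e[500:600] <- 1
  prof <- structure(list(SEG = e), class = "exposure_profile", temperature = 50)
  fr <- simulate_fragments(ref, prof, NULL,
                           library_params(n_fragments = 1000L), "CL-")
  # hexamer window [p+1, p+6] must overlap the exposed stretch
  expect_true(all(fr$p >= 494 & fr$p <= 600))
  expect_true(all(fr$t >= 1 & fr$t <= fr$p))
  expect_true(all(fr$p + 6 <= 800))
  expect_true(all(nchar(fr$umi) == 12))
})

test_that("all-zero exposure is an explicit error", {
  ref <- toy_reference(200)
  prof <- structure(list(SEG = numeric(200)), class = "exposure_profile",
                    temperature = 50)
  expect_error(simulate_fragments(ref, prof, NULL, library_params(), "CL-"),
               "no priming-competent positions")
})

test_that("fragment lengths follow the truncated geometric law", {
  set.seed(202)
  ref <- toy_reference(2000)
  prof <- structure(list(SEG = rep(0.5, 2000)), class = "exposure_profile",
                    temperature = 50)
  pa <- library_params(n_fragments = 50000L, p_term = 1 / 6, min_len = 20L)
  fr <- simulate_fragments(ref, prof, NULL, pa, "CL-")
  anchors <- 20:1994  # uniform exposure: every valid anchor equally likely
  expected <- oracle_truncated_geom_mean(anchors, 20L, 1 / 6)
  expect_lt(abs(mean(fr$length) - expected) / expected, 0.02)
  expect_true(all(fr$length >= pmin(20L, fr$p)))
  expect_true(all(fr$t == fr$p - fr$length + 1L))
})

test_that("anchor density tracks the hexamer-window mean exposure", {
  set.seed(303)
  ref <- toy_reference(1000)
  e <- 0.1 + 0.8 * (sin(seq(0, 6 * pi, length.out = 1000)) + 1) / 2
  prof <- structure(list(SEG = e), class = "exposure_profile", temperature = 50)
  pa <- library_params(n_fragments = 100000L)
  fr <- simulate_fragments(ref, prof, NULL, pa, "CL-")
  w <- priming_weights(prof, min_len = pa$min_len)$SEG
  counts <- tabulate(fr$p, 1000)
  # chi-square goodness of fit on 20 position bins over the valid range
  valid <- which(w > 0)
  bins <- cut(valid, 20)
  obs <- tapply(counts[valid], bins, sum)
  expp <- tapply(w[valid], bins, sum) / sum(w[valid]) * sum(obs)
  chi2 <- sum((obs - expp)^2 / expp)
  expect_lt(chi2, qchisq(0.99, df = 19))
})

test_that("conversions occur only where the chemistry allows them", {
  set.seed(404)
  ref <- toy_reference(600)
  prof <- structure(list(SEG = rep(0.4, 600)), class = "exposure_profile",
                    temperature = 50)
  tp <- t_positions(ref, "SEG")
  sites <- data.frame(segment = "SEG", pos = tp[tp > 100 & tp < 200][1:5],
                      p_xl = 0.5)
  pa <- library_params(n_fragments = 4000L)

  # CL- with p_bg = 0: no conversion source at all
  xl0 <- crosslink_profile(ref, sites, p_bg = 0)
  fr_minus <- simulate_fragments(ref, prof, xl0, pa, "CL-")
  expect_equal(nrow(attr(fr_minus, "conversions")), 0L)

  # CL+: conversions only at the designated sites, only on covering fragments
  fr_plus <- simulate_fragments(ref, prof, xl0, pa, "CL+")
  conv <- attr(fr_plus, "conversions")
  expect_gt(nrow(conv), 0)
  expect_true(all(conv$pos %in% sites$pos))
  i <- match(conv$frag_id, fr_plus$frag_id)
  expect_true(all(conv$pos >= fr_plus$t[i] & conv$pos <= fr_plus$p[i]))

  # empirical conversion frequency at sites ~ p_xl within binomial error
  pos1 <- sites$pos[1]
  covering <- fr_plus$t <= pos1 & fr_plus$p >= pos1
  n_cov <- sum(covering)
  n_conv <- sum(conv$pos == pos1)
  se <- sqrt(0.5 * 0.5 / n_cov)
  expect_lt(abs(n_conv / n_cov - 0.5), 4 * se)

  # non-T position rejected outright
  not_t <- setdiff(1:600, tp)[50]
  expect_error(crosslink_profile(ref, data.frame(segment = "SEG", pos = not_t,
                                                 p_xl = 0.5)),
               "not a reference T")
})

test_that("PCR duplication preserves molecules and keys", {
  set.seed(505)
  ref <- toy_reference(500)
  prof <- structure(list(SEG = rep(0.3, 500)), class = "exposure_profile",
                    temperature = 50)
  pa1 <- library_params(n_fragments = 100L, dup_mean = 1)
  fr <- simulate_fragments(ref, prof, NULL, pa1, "CL-")

  # degenerate d = 1: identity
  out1 <- apply_pcr_duplication(fr, pa1)
  expect_equal(nrow(out1), 100L)
  expect_equal(out1$umi, fr$umi)

  # fixed factor 3: exact multiplication, 100 distinct (position, UMI) keys
  pa3 <- library_params(n_fragments = 100L, dup_mean = 3, dup_model = "fixed")
  out3 <- apply_pcr_duplication(fr, pa3)
  expect_equal(nrow(out3), 300L)
  expect_equal(oracle_dedup_count(out3$segment, out3$p, out3$umi), 100L)

  # Poisson(mean 2) + 1 factors: distinct-key count equals input count
  pap <- library_params(n_fragments = 100L, dup_mean = 3, dup_model = "poisson1")
  outp <- apply_pcr_duplication(fr, pap)
  expect_gte(nrow(outp), 100L)
  expect_equal(oracle_dedup_count(outp$segment, outp$p, outp$umi), 100L)

  expect_error(library_params(dup_mean = 0.5), ">= 1")
})

test_that("read pairs are rendered with the documented geometry", {
  ref <- toy_reference(200)
  pa <- library_params(n_fragments = 1L, min_len = 10L, max_read_len = 75L)
  fr <- data.frame(frag_id = 1L, segment = "SEG", t = 10L, p = 40L,
                   length = 31L, umi = strrep("A", 12), condition = "CL-",
                   stringsAsFactors = FALSE)
  attr(fr, "conversions") <- data.frame(frag_id = integer(), segment = character(),
                                        pos = integer())
  pair <- render_read_pairs(fr, ref, pa)
  seg <- ref$segments[["SEG"]]
  frag <- substr(seg, 10, 40)
  # R1: UMI then sense sequence from t
  expect_equal(pair$r1, paste0(strrep("A", 12), frag))
  # R2: after the 7-nt prefix, the reverse complement of [t, p];
  # the first retained base maps to p
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(frag)))
  expect_equal(substring(pair$r2, 8), rc)
  expect_equal(substr(pair$r2, 8, 8),
               chartr("ACGT", "TGCA", substr(seg, 40, 40)))
  # prefix bases 1..6 are the reverse complement of the hexamer window
  hex <- substr(seg, 41, 46)
  expect_equal(substr(pair$r2, 1, 6),
               as.character(Biostrings::reverseComplement(Biostrings::DNAString(hex))))

  # converted U appears as C on R1 at offset (pos - t) + 12 + 1
  tp <- t_positions(ref, "SEG")
  upos <- tp[tp >= 12 & tp <= 38][1]
  attr(fr, "conversions") <- data.frame(frag_id = 1L, segment = "SEG", pos = upos)
  pair2 <- render_read_pairs(fr, ref, pa)
  expect_equal(substr(pair2$r1, upos - 10 + 12 + 1, upos - 10 + 12 + 1), "C")

  # length cap: a 200-nt fragment yields a 75-nt R1 (12 UMI + 63 genomic)
  ref2 <- toy_reference(400)
  fr3 <- data.frame(frag_id = 1L, segment = "SEG", t = 51L, p = 250L,
                    length = 200L, umi = strrep("G", 12), condition = "CL-",
                    stringsAsFactors = FALSE)
  pair3 <- render_read_pairs(fr3, ref2, pa)
  expect_equal(nchar(pair3$r1), 75L)
  expect_equal(nchar(pair3$r2), 75L)

  # fragments below min_len must never reach rendering
  fr4 <- fr3; fr4$length <- 5L
  expect_error(render_read_pairs(fr4, ref2, pa), "min_len")
})

test_that("write_run round-trips and is deterministic", {
  ref <- toy_reference(300)
  prof <- structure(list(SEG = rep(0.5, 300)), class = "exposure_profile",
                    temperature = 55)
  pa <- library_params(n_fragments = 10L)
  run_once <- function(dir) {
    set.seed(42)
    fr <- simulate_fragments(ref, prof, NULL, pa, "CL-")
    write_run(fr, ref, pa, dir, profile = prof, seed = 42)
    fr
  }
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  fr <- run_once(d1); run_once(d2)

  pairs <- parse_fastq_pair(file.path(d1, "reads_R1.fastq.gz"),
                            file.path(d1, "reads_R2.fastq.gz"))
  expect_equal(nrow(pairs), 10L)
  expect_equal(pairs$name, sprintf("sim%08d", 1:10))

  truth <- read_truth(d1)
  expect_equal(truth$fragments$t, fr$t)
  expect_equal(truth$fragments$umi, fr$umi)
  expect_equal(truth$manifest$seed, 42L)

  expect_identical(readLines(file.path(d1, "truth_fragments.tsv")),
                   readLines(file.path(d2, "truth_fragments.tsv")))
})
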