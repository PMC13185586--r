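# Independent brute-force oracles and tiny fixture builders.
# These deliberately avoid the package's own code paths.

# deterministic toy reference: repeating motif, unambiguous
toy_reference <- function(len = 200L, id = "SEG") {
  motif <- "ACGTTGCAATCGGCTA"
  seq <- substr(strrep(motif, ceiling(len / nchar(motif))), 1L, len)
  genome_reference(stats::setNames(seq, id))
}

# brute-force per-column pileup from explicit read placements
# reads: data.frame(segment, start, seq) -- seq laid on the sense strand
oracle_pileup <- function(reads, seg_lengths) {
  bases <- c("A", "C", "G", "T", "N")
  out <- lapply(names(seg_lengths), function(seg) {
    L <- seg_lengths[[seg]]
    M <- matrix(0L, L, 6L, dimnames = list(NULL, c(bases, "depth")))
    d <- reads[reads$segment == seg, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      chars <- strsplit(d$seq[i], "")[[1]]
      for (j in seq_along(chars)) {
        pos <- d$start[i] + j - 1L
        M[pos, chars[j]] <- M[pos, chars[j]] + 1L
        M[pos, "depth"] <- M[pos, "depth"] + 1L
      }
    }
    M
  })
  names(out) <- names(seg_lengths)
  out
}

# brute-force distinct-key count
oracle_dedup_count <- function(segment, anchor, umi) {
  length(unique(paste(segment, anchor, umi, sep = "|")))
}

# brute-force two-sample KS statistic by direct ECDF evaluation
oracle_ks_D <- function(x, y) {
  pts <- c(x, y)
  d <- 0
  for (v in pts) {
    fx <- sum(x <= v) / length(x)
    fy <- sum(y <= v) / length(y)
    d <- max(d, abs(fx - fy))
  }
  d
}

# brute-force best ungapped placement over all offsets and both strands
oracle_best_alignment <- function(insert, ref) {
  best <- list(mm = Inf)
  ichars <- strsplit(insert, "")[[1]]
  n <- length(ichars)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- paste(rev(unname(comp[ichars])), collapse = "")
  for (seg in names(ref$segments)) {
    chars <- strsplit(ref$segments[[seg]], "")[[1]]
    L <- length(chars)
    for (strand in c("+", "-")) {
      q <- strsplit(if (strand == "+") insert else rc, "")[[1]]
      for (s in seq_len(L - n + 1L)) {
        mm <- sum(q != chars[s:(s + n - 1L)])
        if (mm < best$mm) {
          best <- list(mm = mm, segment = seg, start = s, end = s + n - 1L,
                       strand = strand)
        }
      }
    }
  }
  best
}

# closed-form mean fragment length: L = min(min_len + G, p), G ~ Geom(p_term)
# (number of failures), averaged over the anchor distribution
oracle_truncated_geom_mean <- function(anchors, min_len, p_term) {
  q <- 1 - p_term
  per_anchor <- vapply(anchors, function(p) {
    if (p <= min_len) return(as.numeric(p))
    j <- seq_len(p - min_len)
    min_len + sum(q^j)
  }, numeric(1))
  mean(per_anchor)
}

# build a coverage_profile whose window [1, w] on a length-L segment has
# exactly `window_pct` percent of coverage (rest spread uniformly)
make_fake_profile <- function(window_pct, w = 10L, L = 100L, seg = "S",
                              temperature = NA_real_) {
  pct <- rep((100 - window_pct) / (L - w), L)
  pct[seq_len(w)] <- window_pct / w
  structure(list(depth = stats::setNames(list(rep(1, L)), seg),
                 pct = stats::setNames(list(pct), seg),
                 label = "fake", temperature = temperature),
            class = "coverage_profile")
}

fake_series <- function(window_pcts, temps = default_temperature_grid(),
                        w = 10L, L = 100L) {
  temperature_series(temps, lapply(window_pcts, make_fake_profile, w = w, L = L))
}
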