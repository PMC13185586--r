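#' Per-U transition rates from a pileup
#'
#' At every reference-T position (genomic U) with deduplicated depth at
#' or above `min_depth`, the U-to-C transition rate is the sense-strand
#' C count divided by depth. Positions below the threshold are flagged
#' masked (rate `NA`), never silently zero. Non-T reference positions
#' (including `N`) are excluded entirely.
#'
#' @param pileup a [build_pileup()] result built from deduplicated
#'   molecules.
#' @param ref the matching [genome_reference()].
#' @param min_depth depth mask threshold (default 1000 deduplicated
#'   molecules, the conventional quality floor for transition calling).
#' @param label,condition,replicate sample annotations.
#' @return object of class `transition_table`: data.frame with columns
#'   `segment`, `pos`, `depth`, `c_count`, `rate`, `masked`; attribute
#'   `min_depth`.
#' @export
transition_rates <- function(pileup, ref, min_depth = 1000L, label = "sample",
                             condition = NA_character_, replicate = NA_integer_) {
  stopifnot(inherits(pileup, "pileup_matrix"), inherits(ref, "genome_reference"))
  if (!identical(names(pileup), names(ref$segments)) ||
      !all(vapply(pileup, nrow, integer(1)) == ref$lengths)) {
    stop("pileup does not match reference segment lengths")
  }
  out <- do.call(rbind, lapply(names(pileup), function(seg) {
    tp <- t_positions(ref, seg)
    depth <- pileup[[seg]][tp, "depth"]
    cc <- pileup[[seg]][tp, "C"]
    masked <- depth < min_depth
    data.frame(segment = seg, pos = tp, depth = as.integer(depth),
               c_count = as.integer(cc),
               rate = ifelse(masked, NA_real_, cc / pmax(depth, 1L)),
               masked = masked, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, class = c("transition_table", "data.frame"),
            min_depth = as.integer(min_depth), label = label,
            condition = condition, replicate = replicate)
}

check_same_positions <- function(tables) {
  key0 <- paste(tables[[1]]$segment, tables[[1]]$pos)
  for (tb in tables[-1]) {
    if (!identical(paste(tb$segment, tb$pos), key0)) {
      stop("transition tables cover different positions")
    }
  }
  key0
}

#' Crosslink fold-change signal track
#'
#' Averages per-replicate transition rates position-wise within each
#' condition, then forms the fold change
#' `(mean r_plus + pseudo) / (mean r_minus + pseudo)`. A position is
#' masked whenever any contributing replicate (either condition) is
#' depth-masked there, so sub-threshold observations never leak into the
#' signal. The default pseudocount is `1 / min_depth` (a one-read
#' equivalent), keeping zero control rates finite on the scale set by
#' the depth mask.
#'
#' @param plus,minus lists of [transition_rates()] tables (>= 1 replicate
#'   each) over identical positions.
#' @param pseudo pseudocount; default `1 / min_depth`.
#' @return object of class `signal_track`: data.frame with `segment`,
#'   `pos`, `r_plus`, `r_minus`, `signal`, `masked`.
#' @export
vparcl_signal <- function(plus, minus, pseudo = NULL) {
  if (inherits(plus, "transition_table")) plus <- list(plus)
  if (inherits(minus, "transition_table")) minus <- list(minus)
  if (!length(plus) || !length(minus)) {
    stop("need at least one replicate per condition")
  }
  check_same_positions(c(plus, minus))
  min_depth <- attr(plus[[1]], "min_depth")
  if (is.null(pseudo)) pseudo <- 1 / min_depth
  rate_mat <- function(tabs) do.call(cbind, lapply(tabs, `[[`, "rate"))
  mask_mat <- function(tabs) do.call(cbind, lapply(tabs, `[[`, "masked"))
  rp <- rowMeans(rate_mat(plus))
  rm_ <- rowMeans(rate_mat(minus))
  masked <- rowSums(mask_mat(plus)) > 0 | rowSums(mask_mat(minus)) > 0
  signal <- ifelse(masked, NA_real_, (rp + pseudo) / (rm_ + pseudo))
  if (all(masked)) warning("all positions masked; empty signal track")
  out <- data.frame(segment = plus[[1]]$segment, pos = plus[[1]]$pos,
                    r_plus = ifelse(masked, NA_real_, rp),
                    r_minus = ifelse(masked, NA_real_, rm_),
                    signal = signal, masked = masked,
                    stringsAsFactors = FALSE)
  structure(out, class = c("signal_track", "data.frame"),
            min_depth = min_depth, pseudo = pseudo)
}

ks_asymptotic_p <- function(d, n, m) {
  lambda <- sqrt(n * m / (n + m)) * d
  if (lambda == 0) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

#' Two-sample Kolmogorov-Smirnov comparison of transition rates
#'
#' `D` is the maximal absolute gap between the two empirical
#' distribution functions, computed over the pooled support (ties
#' handled by evaluating both ECDFs at every pooled value). The p-value
#' uses the exact conditional distribution (`stats::psmirnov`, which
#' accommodates ties) for small samples (`n * m <= 10000`) and the
#' asymptotic Kolmogorov series otherwise.
#'
#' @param plus_rates,minus_rates numeric vectors of per-position mean
#'   rates (NAs dropped); at least 2 values each.
#' @return list with `D`, `p_value`, `n`, `m`, `exact`.
#' @export
ks_compare <- function(plus_rates, minus_rates) {
  x <- plus_rates[!is.na(plus_rates)]
  y <- minus_rates[!is.na(minus_rates)]
  n <- length(x); m <- length(y)
  if (n < 2L || m < 2L) stop("need at least 2 unmasked positions per condition")
  pooled <- sort(unique(c(x, y)))
  fx <- vapply(pooled, function(q) mean(x <= q), numeric(1))
  fy <- vapply(pooled, function(q) mean(y <= q), numeric(1))
  d <- max(abs(fx - fy))
  exact <- n * m <= 10000
  p <- if (exact) {
    stats::psmirnov(d, sizes = c(n, m), z = c(x, y), two.sided = TRUE,
                    exact = TRUE, lower.tail = FALSE)
  } else {
    ks_asymptotic_p(d, n, m)
  }
  list(D = d, p_value = p, n = n, m = m, exact = exact)
}

#' Correlate two signal tracks
#'
#' Pearson or Spearman correlation over the intersection of unmasked
#' positions, with the usual t-distribution p-value for the coefficient
#' (for simple correlation this equals the one-way ANOVA F-test p).
#' Constant tracks yield a flagged undefined result rather than NaN.
#'
#' @param track_a,track_b numeric vectors (NA = masked), same length, or
#'   `signal_track` objects over identical positions.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `coefficient`, `p_value`, `n`, `method`,
#'   `undefined`.
#' @export
correlate_signals <- function(track_a, track_b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (inherits(track_a, "signal_track")) track_a <- track_a$signal
  if (inherits(track_b, "signal_track")) track_b <- track_b$signal
  if (length(track_a) != length(track_b)) stop("tracks differ in length")
  ok <- !is.na(track_a) & !is.na(track_b)
  n <- sum(ok)
  if (n < 3L) stop("need at least 3 shared unmasked positions")
  a <- track_a[ok]; b <- track_b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(list(coefficient = NA_real_, p_value = NA_real_, n = n,
                method = method, undefined = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(a, b, method = method, exact = FALSE))
  list(coefficient = unname(ct$estimate), p_value = ct$p.value, n = n,
       method = method, undefined = FALSE)
}

#' Threshold a signal track
#'
#' Returns the unmasked positions whose signal exceeds `cutoff`,
#' together with where the cutoff sits in the empirical signal
#' distribution: `quantile_pct` is the percent of unmasked signals at or
#' below the cutoff, `pct_above` the percent above it.
#'
#' @param track a [vparcl_signal()] track.
#' @param cutoff signal cutoff (default 1.5).
#' @return list with `positions` (data.frame `segment`, `pos`, `signal`),
#'   `cutoff`, `quantile_pct`, `pct_above`, `n_unmasked`.
#' @export
threshold_signals <- function(track, cutoff = 1.5) {
  stopifnot(inherits(track, "signal_track"))
  un <- track[!track$masked, , drop = FALSE]
  if (!nrow(un)) stop("signal track has no unmasked positions")
  hit <- un[un$signal > cutoff, c("segment", "pos", "signal")]
  rownames(hit) <- NULL
  list(positions = hit, cutoff = cutoff,
       quantile_pct = 100 * mean(un$signal <= cutoff),
       pct_above = 100 * mean(un$signal > cutoff),
       n_unmasked = nrow(un))
}

#' Write a signal track as TSV (and optionally bedGraph)
#'
#' @param track a [vparcl_signal()] track.
#' @param path TSV output path.
#' @param bedgraph_path optional bedGraph output of the signal column
#'   (masked positions written as 0).
#' @param ref reference (required for bedGraph output).
#' @return `path` invisibly.
#' @export
write_signal_track <- function(track, path, bedgraph_path = NULL, ref = NULL) {
  utils::write.table(as.data.frame(track), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(bedgraph_path)) {
    if (is.null(ref)) stop("ref required for bedGraph export")
    tracks <- lapply(names(ref$segments), function(seg) {
      v <- numeric(ref$lengths[[seg]])
      d <- track[track$segment == seg & !track$masked, , drop = FALSE]
      v[d$pos] <- d$signal
      v
    })
    names(tracks) <- names(ref$segments)
    write_bedgraph(tracks, bedgraph_path)
  }
  invisible(path)
}
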