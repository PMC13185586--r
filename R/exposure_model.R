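#' Region-wise logistic temperature-response model of RNA exposure
#'
#' Each genomic region that responds to disassembly temperature is given a
#' logistic accessibility curve
#' \deqn{e(T) = b + a / (1 + \exp(-(T - T_{50}) / k))}
#' where `b` is the baseline exposure at low temperature, `a` the amplitude
#' (`b + a <= 1`), `T50` the midpoint ("energy barrier") temperature in
#' degrees Celsius and `k` the steepness in degrees. Positions not covered
#' by any region receive `default_exposure` at every temperature.
#' Overlapping regions are resolved by taking the position-wise maximum.
#'
#' @param regions data.frame with columns `segment`, `start`, `end`, `b`,
#'   `a`, `t50`, `k` (one row per responsive region). May have zero rows.
#' @param default_exposure accessibility of unlisted positions, in `[0, 1]`.
#' @return object of class `barrier_model`.
#' @export
barrier_model <- function(regions = NULL, default_exposure = 0.05) {
  if (is.null(regions)) {
    regions <- data.frame(segment = character(), start = integer(), end = integer(),
                          b = numeric(), a = numeric(), t50 = numeric(), k = numeric())
  }
  need <- c("segment", "start", "end", "b", "a", "t50", "k")
  if (!all(need %in% names(regions))) {
    stop("barrier_model regions need columns: ", paste(need, collapse = ", "))
  }
  if (nrow(regions)) {
    if (any(regions$b < 0 | regions$b > 1)) stop("baseline b must lie in [0, 1]")
    if (any(regions$a < 0 | regions$a + regions$b > 1)) {
      stop("amplitude a must lie in [0, 1 - b]")
    }
    if (any(regions$k <= 0)) stop("steepness k must be positive")
    if (any(regions$start < 1 | regions$end < regions$start)) {
      stop("invalid region bounds in barrier model")
    }
  }
  if (default_exposure < 0 || default_exposure > 1) {
    stop("default_exposure must lie in [0, 1]")
  }
  structure(list(regions = regions, default_exposure = default_exposure),
            class = "barrier_model")
}

logistic_exposure <- function(b, a, t50, k, temp) {
  b + a / (1 + exp(-(temp - t50) / k))
}

#' Per-position exposure profile at a fixed temperature
#'
#' Evaluates a [barrier_model()] over a reference at temperature `temp`,
#' producing one accessibility vector per segment (values in `[0, 1]`).
#'
#' @param model a `barrier_model`.
#' @param ref a [genome_reference()].
#' @param temp treatment temperature in degrees Celsius.
#' @return object of class `exposure_profile`: named list of numeric
#'   vectors (one per segment), with attribute `temperature`.
#' @export
exposure_at_temperature <- function(model, ref, temp) {
  stopifnot(inherits(model, "barrier_model"), inherits(ref, "genome_reference"))
  if (!is.finite(temp)) stop("temperature must be finite")
  regions <- model$regions
  if (nrow(regions)) {
    unknown <- !regions$segment %in% names(ref$segments)
    if (any(unknown)) {
      stop("barrier model region on unknown segment '",
           regions$segment[which(unknown)[1]], "'")
    }
    over <- regions$end > ref$lengths[regions$segment]
    if (any(over)) {
      i <- which(over)[1]
      stop(sprintf("barrier model region %s:%d-%d outside segment bounds (length %d)",
                   regions$segment[i], regions$start[i], regions$end[i],
                   ref$lengths[[regions$segment[i]]]))
    }
  }
  prof <- lapply(names(ref$segments), function(seg) {
    e <- rep(model$default_exposure, ref$lengths[[seg]])
    rows <- which(regions$segment == seg)
    for (i in rows) {
      val <- logistic_exposure(regions$b[i], regions$a[i], regions$t50[i],
                               regions$k[i], temp)
      idx <- regions$start[i]:regions$end[i]
      e[idx] <- pmax(e[idx], val)
    }
    e
  })
  names(prof) <- names(ref$segments)
  structure(prof, class = "exposure_profile", temperature = temp)
}

#' Expected priming density implied by an exposure profile
#'
#' The hexamer primer anneals over the window `[p + 1, p + 6]` downstream
#' of the anchor `p` (genome sense), so the probability that a fragment
#' anchors at `p` is proportional to the mean exposure over that window.
#' Anchors must leave room for the hexamer (`p + 6 <= L`) and for a
#' minimum-length extension (`p >= min_len`).
#'
#' @param profile an [exposure_at_temperature()] result.
#' @param min_len minimum fragment length (anchors below it get weight 0).
#' @return named list of per-position weight vectors (unnormalised; zero
#'   where no priming can occur). Same lengths as the profile.
#' @export
priming_weights <- function(profile, min_len = 20L) {
  stopifnot(inherits(profile, "exposure_profile"))
  out <- lapply(profile, function(e) {
    L <- length(e)
    w <- numeric(L)
    if (L >= 7L) {
      # mean exposure over [p+1, p+6] for p in 1..(L-6), via cumulative sums
      cs <- c(0, cumsum(e))
      p <- seq_len(L - 6L)
      w[p] <- (cs[p + 7L] - cs[p + 1L]) / 6
    }
    if (min_len > 1L) w[seq_len(min(L, min_len - 1L))] <- 0
    w
  })
  names(out) <- names(profile)
  out
}
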