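#' Ratiometric coverage profile from a pileup
#'
#' Normalises per-position depth to percent of the segment's total depth
#' ("ratiometric" normalisation), segment-wise. A segment with zero total
#' depth yields all-zero percents with a warning.
#'
#' @param pileup a [build_pileup()] result.
#' @param label sample label carried in the profile.
#' @param temperature optional treatment temperature tag.
#' @return object of class `coverage_profile`: list with `depth` and
#'   `pct` (named lists of per-position numeric vectors), `label`,
#'   `temperature`.
#' @export
normalize_coverage <- function(pileup, label = "sample", temperature = NA_real_) {
  stopifnot(inherits(pileup, "pileup_matrix"))
  depth <- lapply(pileup, function(M) as.numeric(M[, "depth"]))
  pct <- lapply(names(depth), function(seg) {
    tot <- sum(depth[[seg]])
    if (tot == 0) {
      warning("segment ", seg, " has zero total depth; percents set to 0")
      return(numeric(length(depth[[seg]])))
    }
    100 * depth[[seg]] / tot
  })
  names(pct) <- names(depth)
  structure(list(depth = depth, pct = pct, label = label,
                 temperature = temperature),
            class = "coverage_profile")
}

#' Priming-site profile from deduplicated molecules
#'
#' Tallies, per position, the number of retained molecules whose trimmed
#' R2 5'-most genomic coordinate (the priming anchor, i.e. the position
#' immediately upstream of the hexamer annealing window on the genome
#' sense) falls there, and normalises to percent of the segment total.
#'
#' @param molecules deduplicated molecule table with `segment` and
#'   `anchor` columns.
#' @param ref a [genome_reference()].
#' @param label,temperature carried through as in [normalize_coverage()].
#' @return object of class `priming_profile`: list with `count` and
#'   `pct` per segment, plus `label`, `temperature`.
#' @export
call_priming_sites <- function(molecules, ref, label = "sample",
                               temperature = NA_real_) {
  stopifnot(inherits(ref, "genome_reference"))
  count <- lapply(names(ref$segments), function(seg) {
    rows <- molecules$segment == seg & !is.na(molecules$anchor)
    tabulate(molecules$anchor[rows], ref$lengths[[seg]])
  })
  names(count) <- names(ref$segments)
  pct <- lapply(count, function(x) {
    tot <- sum(x)
    if (tot == 0) numeric(length(x)) else 100 * x / tot
  })
  structure(list(count = count, pct = pct, label = label,
                 temperature = temperature),
            class = "priming_profile")
}

profile_pct <- function(profile, segment) {
  if (!segment %in% names(profile$pct)) {
    stop("profile has no segment '", segment, "'")
  }
  profile$pct[[segment]]
}

#' Window enrichment statistics
#'
#' For a region, reports what percent of the segment's length it spans
#' (one-decimal precision, matching how such windows are conventionally
#' quoted) and what percent of the segment's total coverage (or priming
#' sites) it collects.
#'
#' @param profile a `coverage_profile` or `priming_profile`.
#' @param reg a [region()] (or string accepted by [parse_region()]).
#' @return list with `region`, `pct_of_length` (rounded to one decimal)
#'   and `pct_of_coverage` (full precision).
#' @export
window_stats <- function(profile, reg) {
  if (is.character(reg)) reg <- parse_region(reg)
  stopifnot(inherits(reg, "region"))
  pct <- profile_pct(profile, reg$segment)
  L <- length(pct)
  if (reg$end > L) {
    stop(sprintf("region %s:%d-%d outside segment (length %d)",
                 reg$segment, reg$start, reg$end, L))
  }
  list(region = reg,
       pct_of_length = round(100 * reg$width / L, 1),
       pct_of_coverage = sum(pct[reg$start:reg$end]),
       label = profile$label)
}

#' Centered moving average with shrinking edge windows
#'
#' Means are taken over `[i - floor((w-1)/2), i + ceiling((w-1)/2)]`
#' truncated at the segment edges (no padding, no wrap-around), so the
#' output has the same length as the input. A window wider than the
#' track collapses to the global mean, with a warning.
#'
#' @param x numeric track.
#' @param window_nt window width in nucleotides (>= 1).
#' @return smoothed numeric vector, same length as `x`.
#' @export
moving_average <- function(x, window_nt) {
  window_nt <- as.integer(window_nt)
  if (window_nt < 1L) stop("window_nt must be >= 1")
  L <- length(x)
  if (window_nt == 1L || L == 0L) return(as.numeric(x))
  if (window_nt > L) {
    warning("window (", window_nt, ") wider than track (", L,
            "); returning the global mean")
    return(rep(mean(x), L))
  }
  left <- (window_nt - 1L) %/% 2L
  right <- window_nt - 1L - left
  cs <- c(0, cumsum(x))
  i <- seq_len(L)
  lo <- pmax.int(i - left, 1L)
  hi <- pmin.int(i + right, L)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Temperature series of coverage (and optional priming) profiles
#'
#' @param temperatures strictly increasing numeric vector (degrees C).
#' @param coverage list of `coverage_profile`, one per temperature.
#' @param priming optional list of `priming_profile`, one per temperature.
#' @return object of class `temperature_series`.
#' @export
temperature_series <- function(temperatures, coverage, priming = NULL) {
  if (length(temperatures) != length(coverage)) {
    stop("one coverage profile per temperature required")
  }
  if (is.unsorted(temperatures, strictly = TRUE)) {
    stop("temperatures must be strictly increasing")
  }
  structure(list(temperatures = as.numeric(temperatures), coverage = coverage,
                 priming = priming),
            class = "temperature_series")
}

#' The disassembly temperature grid used throughout
#'
#' 50 C (untreated particle) through the 2.5 C-step series to 67.5 C,
#' plus the 70 C ("eluted") and 75 C ("puff") end points.
#' @return numeric vector of 10 temperatures.
#' @export
default_temperature_grid <- function() {
  c(50, 52.5, 55, 57.5, 60, 62.5, 65, 67.5, 70, 75)
}

series_window_pcts <- function(series, reg) {
  vapply(series$coverage, function(pr) window_stats(pr, reg)$pct_of_coverage,
         numeric(1))
}

#' Classify a region's coverage trend across the temperature series
#'
#' Computes the region's percent-of-coverage at every temperature and
#' classifies it as one of `increasing`, `decreasing`, `flat_low` or
#' `fluctuating`. Directional classes require both a strong Spearman
#' rank correlation with temperature (`|rho| >= rho_threshold`) and a
#' relative dynamic range `(max - min) / max >= range_threshold`;
#' `flat_low` requires a small dynamic range and a mean below the
#' uniform expectation (the region's percent of segment length);
#' everything else is `fluctuating`.
#'
#' @param series a [temperature_series()] (>= 4 temperatures).
#' @param reg a [region()] or region string.
#' @param rho_threshold Spearman threshold for directional classes.
#' @param range_threshold relative dynamic-range threshold.
#' @return list with `class` plus the supporting statistics (`rho`,
#'   `dynamic_range`, `mean_pct`, `pct_of_length`, `pcts`).
#' @export
classify_trend <- function(series, reg, rho_threshold = 0.7,
                           range_threshold = 0.25) {
  stopifnot(inherits(series, "temperature_series"))
  if (length(series$temperatures) < 4L) {
    stop("trend classification needs at least 4 temperatures")
  }
  if (is.character(reg)) reg <- parse_region(reg)
  pcts <- series_window_pcts(series, reg)
  ws <- window_stats(series$coverage[[1]], reg)
  rho <- if (stats::sd(pcts) == 0) 0 else {
    stats::cor(pcts, series$temperatures, method = "spearman")
  }
  rng <- if (max(pcts) == 0) 0 else (max(pcts) - min(pcts)) / max(pcts)
  cls <- if (rho >= rho_threshold && rng >= range_threshold) {
    "increasing"
  } else if (rho <= -rho_threshold && rng >= range_threshold) {
    "decreasing"
  } else if (rng < range_threshold && mean(pcts) < ws$pct_of_length) {
    "flat_low"
  } else {
    "fluctuating"
  }
  list(class = cls, rho = rho, dynamic_range = rng, mean_pct = mean(pcts),
       pct_of_length = ws$pct_of_length, pcts = pcts,
       temperatures = series$temperatures)
}

#' Coverage fold change of a region between two temperatures
#'
#' @param series a [temperature_series()].
#' @param reg region or region string.
#' @param t_from,t_to temperatures present in the series.
#' @return list with `ratio` (NA when undefined), `undefined` flag and
#'   the two percent values.
#' @export
region_fold_change <- function(series, reg, t_from, t_to) {
  stopifnot(inherits(series, "temperature_series"))
  i_from <- match(t_from, series$temperatures)
  i_to <- match(t_to, series$temperatures)
  if (is.na(i_from) || is.na(i_to)) stop("temperature not present in series")
  if (is.character(reg)) reg <- parse_region(reg)
  pcts <- series_window_pcts(series, reg)
  if (pcts[i_from] == 0) {
    return(list(ratio = NA_real_, undefined = TRUE,
                pct_from = pcts[i_from], pct_to = pcts[i_to]))
  }
  list(ratio = pcts[i_to] / pcts[i_from], undefined = FALSE,
       pct_from = pcts[i_from], pct_to = pcts[i_to])
}

#' Write / read per-position tracks
#'
#' `write_bedgraph()` converts the internal 1-based inclusive positions
#' to bedGraph's 0-based half-open intervals and merges runs of equal
#' values; `read_bedgraph()` inverts that. `write_track_tsv()` keeps
#' 1-based positions for human use.
#'
#' @param tracks named list of per-position numeric vectors (per segment).
#' @param path output path.
#' @return `path` invisibly (writers); named list of numeric vectors
#'   (`read_bedgraph`).
#' @export
write_bedgraph <- function(tracks, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (seg in names(tracks)) {
    v <- tracks[[seg]]
    if (!length(v)) next
    r <- rle(v)
    end1 <- cumsum(r$lengths)          # 1-based inclusive run ends
    start0 <- c(0L, end1[-length(end1)])  # 0-based half-open starts
    writeLines(sprintf("%s\t%d\t%d\t%.15g", seg, start0, end1, r$values), con)
  }
  invisible(path)
}

#' @rdname write_bedgraph
#' @param ref a [genome_reference()] giving segment lengths.
#' @export
read_bedgraph <- function(path, ref) {
  df <- utils::read.table(path, sep = "\t",
                          col.names = c("segment", "start0", "end0", "value"),
                          stringsAsFactors = FALSE)
  out <- lapply(names(ref$segments), function(seg) {
    v <- numeric(ref$lengths[[seg]])
    d <- df[df$segment == seg, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      v[(d$start0[i] + 1L):d$end0[i]] <- d$value[i]
    }
    v
  })
  names(out) <- names(ref$segments)
  out
}

#' @rdname write_bedgraph
#' @export
write_track_tsv <- function(tracks, path) {
  df <- data.frame(segment = rep(names(tracks), lengths(tracks)),
                   pos = unlist(lapply(tracks, seq_along), use.names = FALSE),
                   value = unlist(tracks, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_track_tsv <- function(path, ref) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(names(ref$segments), function(seg) {
    v <- numeric(ref$lengths[[seg]])
    d <- df[df$segment == seg, , drop = FALSE]
    v[d$pos] <- d$value
    v
  })
  names(out) <- names(ref$segments)
  out
}

#' Export coverage / priming tracks for a profile
#'
#' Writes a bedGraph (0-based half-open) and a TSV (1-based) of the
#' percent track of each profile into `out_dir`.
#'
#' @param profiles named list of `coverage_profile` / `priming_profile`.
#' @param out_dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
export_tracks <- function(profiles, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", out_dir)
  paths <- list()
  for (nm in names(profiles)) {
    tryCatch({
      bg <- file.path(out_dir, paste0(nm, ".pct.bedgraph"))
      tsv <- file.path(out_dir, paste0(nm, ".pct.tsv"))
      write_bedgraph(profiles[[nm]]$pct, bg)
      write_track_tsv(profiles[[nm]]$pct, tsv)
      paths[[nm]] <- c(bedgraph = bg, tsv = tsv)
    }, error = function(e) {
      stop("failed exporting tracks for '", nm, "' to '", out_dir, "': ",
           conditionMessage(e))
    })
  }
  invisible(paths)
}
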