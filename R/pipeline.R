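#' Validated end-to-end run configuration
#'
#' Collects everything a reproducible run needs: the reference (or a
#' seed to synthesise one), the exposure barrier model, library
#' parameters, the treatment temperature grid, the crosslink experiment
#' block, analysis regions, thresholds and the master seed. Validation
#' happens here, before any computation.
#'
#' @param ref a [genome_reference()]; default is the two-segment
#'   nodavirus-like synthetic reference.
#' @param barrier a [barrier_model()].
#' @param params a [library_params()].
#' @param temperatures treatment grid (strictly increasing; default the
#'   standard disassembly grid).
#' @param xl a [crosslink_profile()] for the crosslink block (or NULL to
#'   skip it).
#' @param vparcl list with `temperature`, `replicates`, `n_fragments`
#'   for the crosslink experiment (defaults: 50 C, 4 replicates, the
#'   library default fragment count).
#' @param regions character vector of analysis regions
#'   (`"SEGMENT:START-END"`).
#' @param min_depth depth mask for transition calling.
#' @param signal_cutoff crosslink signal cutoff.
#' @param rho_threshold,range_threshold trend-classifier thresholds.
#' @param coverage_window,priming_window smoothing windows (nt).
#' @param route `"truth"` (fast, error-free molecule route) or
#'   `"reads"` (render, parse, align).
#' @param seed master RNG seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(ref = NULL, barrier = barrier_model(),
                       params = library_params(), temperatures = default_temperature_grid(),
                       xl = NULL, vparcl = list(), regions = character(),
                       min_depth = 1000L, signal_cutoff = 1.5,
                       rho_threshold = 0.7, range_threshold = 0.25,
                       coverage_window = 50L, priming_window = 15L,
                       route = c("truth", "reads"), seed = 1L) {
  route <- match.arg(route)
  if (is.null(ref)) ref <- fhv_like_reference(seed = seed)
  stopifnot(inherits(ref, "genome_reference"), inherits(barrier, "barrier_model"),
            inherits(params, "library_params"))
  if (is.unsorted(temperatures, strictly = TRUE)) {
    stop("temperatures must be strictly increasing")
  }
  # validate barrier regions and analysis regions against the reference now
  exposure_at_temperature(barrier, ref, temperatures[1])
  parsed_regions <- lapply(regions, parse_region, ref = ref)
  if (!is.null(xl)) stopifnot(inherits(xl, "crosslink_profile"))
  vp <- utils::modifyList(list(temperature = 50, replicates = 4L,
                               n_fragments = params$n_fragments), vparcl)
  structure(list(ref = ref, barrier = barrier, params = params,
                 temperatures = as.numeric(temperatures), xl = xl, vparcl = vp,
                 regions = regions, parsed_regions = parsed_regions,
                 min_depth = as.integer(min_depth), signal_cutoff = signal_cutoff,
                 rho_threshold = rho_threshold, range_threshold = range_threshold,
                 coverage_window = as.integer(coverage_window),
                 priming_window = as.integer(priming_window),
                 route = route, seed = as.integer(seed)),
            class = "run_config")
}

# one simulate -> process -> dedup -> pileup pass; each stage gets its
# own derived seed so the truth and reads routes draw identical fragments
simulate_and_process <- function(config, profile, xl, condition, n_fragments,
                                 label, index = NULL, out_dir = NULL,
                                 stage_seed = NULL) {
  if (!is.null(stage_seed)) set.seed(stage_seed)
  params <- config$params
  params$n_fragments <- as.integer(n_fragments)
  frags <- simulate_fragments(config$ref, profile, xl, params, condition)
  if (config$route == "reads") {
    frags <- apply_pcr_duplication(frags, params)
    if (!is.null(out_dir)) {
      paths <- write_run(frags, config$ref, params, file.path(out_dir, label),
                         profile = profile, seed = config$seed)
      mol <- process_run(paths$r1, paths$r2, config$ref, index = index)
    } else {
      pairs <- render_read_pairs(frags, config$ref, params)
      pairs_df <- data.frame(name = pairs$name, seq1 = pairs$r1, qual1 = "",
                             seq2 = pairs$r2, qual2 = "", stringsAsFactors = FALSE)
      attr(pairs_df, "counts") <- c(parsed = nrow(pairs_df), malformed = 0L)
      mol <- process_run(ref = config$ref, pairs = pairs_df, index = index)
    }
  } else {
    frags <- apply_pcr_duplication(frags, params)
    mol <- truth_molecules(frags, params)
  }
  retained <- dedup_molecules(mol)
  list(molecules = retained, pileup = build_pileup(retained, config$ref),
       counts = c(attr(mol, "counts"),
                  retained = unname(attr(retained, "counts")["retained"])),
       label = label)
}

#' Run the full pipeline: simulate, process, analyse, integrate
#'
#' Executes the exposure temperature series (one library per
#' temperature), the crosslink experiment (CL+ and CL- replicates at the
#' crosslink block's temperature), per-region window statistics and
#' trend classes, the crosslink signal track with its condition tests,
#' and the priming-versus-signal anti-correlation. Fully deterministic
#' given the config seed.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory for intermediates (reads route
#'   writes FASTQ runs there).
#' @return object of class `report_bundle`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  n_stages <- length(config$temperatures) + 2L * config$vparcl$replicates
  stage_seeds <- sample.int(.Machine$integer.max, n_stages)
  next_seed <- local({ i <- 0L; function() { i <<- i + 1L; stage_seeds[i] } })
  index <- if (config$route == "reads") kmer_index(config$ref) else NULL
  stage <- "exposure-series"
  bundle <- tryCatch({
    covs <- list(); prims <- list(); counters <- list()
    for (i in seq_along(config$temperatures)) {
      temp <- config$temperatures[i]
      profile <- exposure_at_temperature(config$barrier, config$ref, temp)
      label <- sprintf("T%g", temp)
      res <- simulate_and_process(config, profile, xl = NULL, condition = "CL-",
                                  n_fragments = config$params$n_fragments,
                                  label = label, index = index, out_dir = out_dir,
                                  stage_seed = next_seed())
      covs[[i]] <- normalize_coverage(res$pileup, label = label, temperature = temp)
      prims[[i]] <- call_priming_sites(res$molecules, config$ref, label = label,
                                       temperature = temp)
      counters[[label]] <- res$counts
    }
    series <- temperature_series(config$temperatures, covs, prims)

    stage <- "window-stats"
    window_tab <- NULL
    trend_tab <- NULL
    for (rg in config$regions) {
      pcts <- vapply(covs, function(pr) window_stats(pr, rg)$pct_of_coverage,
                     numeric(1))
      ws1 <- window_stats(covs[[1]], rg)
      window_tab <- rbind(window_tab, data.frame(
        region = rg, temperature = config$temperatures,
        pct_of_length = ws1$pct_of_length, pct_of_coverage = pcts))
      tr <- classify_trend(series, rg, config$rho_threshold, config$range_threshold)
      trend_tab <- rbind(trend_tab, data.frame(
        region = rg, class = tr$class, rho = tr$rho,
        dynamic_range = tr$dynamic_range, mean_pct = tr$mean_pct,
        pct_of_length = tr$pct_of_length))
    }

    stage <- "crosslink"
    vparcl_out <- NULL
    if (!is.null(config$xl)) {
      vp <- config$vparcl
      profile <- exposure_at_temperature(config$barrier, config$ref, vp$temperature)
      tabs <- list(`CL+` = list(), `CL-` = list())
      for (condition in c("CL+", "CL-")) {
        for (r in seq_len(vp$replicates)) {
          label <- sprintf("%s_rep%d", condition, r)
          res <- simulate_and_process(config, profile, config$xl, condition,
                                      vp$n_fragments, label, index = index,
                                      out_dir = out_dir,
                                      stage_seed = next_seed())
          tabs[[condition]][[r]] <- transition_rates(res$pileup, config$ref,
                                                     config$min_depth,
                                                     label = label,
                                                     condition = condition,
                                                     replicate = r)
          counters[[label]] <- res$counts
        }
      }
      signal <- vparcl_signal(tabs[["CL+"]], tabs[["CL-"]])
      mean_rate <- function(tabs_cond) {
        rowMeans(do.call(cbind, lapply(tabs_cond, `[[`, "rate")))
      }
      rp <- mean_rate(tabs[["CL+"]]); rm_ <- mean_rate(tabs[["CL-"]])
      ks <- lapply(names(config$ref$segments), function(seg) {
        sel <- tabs[["CL+"]][[1]]$segment == seg
        if (sum(!is.na(rp[sel])) >= 2 && sum(!is.na(rm_[sel])) >= 2) {
          ks_compare(rp[sel], rm_[sel])
        }
      })
      names(ks) <- names(config$ref$segments)
      thr <- threshold_signals(signal, config$signal_cutoff)
      vparcl_out <- list(tables = tabs, signal = signal, ks = ks, threshold = thr)
    }

    stage <- "integration"
    integration <- NULL
    if (!is.null(vparcl_out)) {
      i_wt <- match(config$vparcl$temperature, config$temperatures)
      if (!is.na(i_wt)) {
        integration <- lapply(names(config$ref$segments), function(seg) {
          tryCatch(correlate_priming_vs_signal(prims[[i_wt]], vparcl_out$signal,
                                               seg, config$priming_window),
                   error = function(e) NULL)
        })
        names(integration) <- names(config$ref$segments)
      }
    }

    structure(list(series = series, window_stats = window_tab,
                   trends = trend_tab, vparcl = vparcl_out,
                   integration = integration, counters = counters,
                   config = config),
              class = "report_bundle")
  }, error = function(e) {
    if (!is.null(out_dir)) {
      ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
      if (ok) {
        jsonlite::write_json(list(failed_stage = stage,
                                  error = conditionMessage(e)),
                             file.path(out_dir, "partial_manifest.json"),
                             auto_unbox = TRUE)
      }
    }
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e))
  })
  bundle
}

#' Priming-density versus crosslink-signal correlation
#'
#' Smooths the priming percent track with a centered moving average
#' (15 nt by default) and correlates it, by Spearman rank correlation,
#' with the crosslink signal over that segment's unmasked positions.
#' A negative coefficient means exposure-driven priming concentrates
#' where RNA-capsid contacts are absent.
#'
#' @param priming a [call_priming_sites()] profile.
#' @param signal a [vparcl_signal()] track.
#' @param segment segment id shared by both tracks.
#' @param window_nt smoothing window for the priming track.
#' @return a [correlate_signals()] result (Spearman).
#' @export
correlate_priming_vs_signal <- function(priming, signal, segment,
                                        window_nt = 15L) {
  stopifnot(inherits(priming, "priming_profile"), inherits(signal, "signal_track"))
  pct <- profile_pct(priming, segment)
  smoothed <- moving_average(pct, window_nt)
  d <- signal[signal$segment == segment & !signal$masked, , drop = FALSE]
  if (nrow(d) < 3L) stop("signal track has fewer than 3 unmasked positions on ", segment)
  if (nrow(d) < 100L) {
    warning("fewer than 100 unmasked signal positions on ", segment)
  }
  correlate_signals(smoothed[d$pos], d$signal, method = "spearman")
}

#' Write the report bundle to disk
#'
#' Always writes TSV tables and a JSON summary; every number in the
#' summary is recomputed from the bundle's stored intermediates.
#'
#' @param bundle a [run_pipeline()] result.
#' @param out_dir output directory.
#' @param formats subset of `c("tsv", "json")`.
#' @return named list of written paths, invisibly.
#' @export
generate_report <- function(bundle, out_dir, formats = c("tsv", "json")) {
  stopifnot(inherits(bundle, "report_bundle"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stop("cannot create report directory: ", out_dir)
  paths <- list()
  if ("tsv" %in% formats) {
    if (!is.null(bundle$window_stats)) {
      paths$window_stats <- file.path(out_dir, "window_stats.tsv")
      utils::write.table(bundle$window_stats, paths$window_stats, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    if (!is.null(bundle$trends)) {
      paths$trends <- file.path(out_dir, "trend_classes.tsv")
      utils::write.table(bundle$trends, paths$trends, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    if (!is.null(bundle$vparcl)) {
      paths$signal <- file.path(out_dir, "vparcl_signal.tsv")
      write_signal_track(bundle$vparcl$signal, paths$signal,
                         bedgraph_path = file.path(out_dir, "vparcl_signal.bedgraph"),
                         ref = bundle$config$ref)
    }
    covs <- stats::setNames(bundle$series$coverage,
                            sprintf("coverage_%s", vapply(bundle$series$coverage,
                                                          `[[`, "", "label")))
    paths$tracks <- export_tracks(covs, file.path(out_dir, "tracks"))
  }
  if ("json" %in% formats) {
    summ <- list(
      n_temperatures = length(bundle$series$temperatures),
      temperatures = bundle$series$temperatures,
      regions = bundle$config$regions,
      trends = bundle$trends,
      ks = if (!is.null(bundle$vparcl)) {
        lapply(bundle$vparcl$ks, function(k) if (!is.null(k)) k[c("D", "p_value", "n", "m")])
      },
      threshold = if (!is.null(bundle$vparcl)) {
        bundle$vparcl$threshold[c("cutoff", "quantile_pct", "pct_above", "n_unmasked")]
      },
      integration = lapply(bundle$integration, function(x) {
        if (!is.null(x)) x[c("coefficient", "p_value", "n", "method")]
      }),
      counters = bundle$counters,
      seed = bundle$config$seed
    )
    paths$summary <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summ, paths$summary, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
  }
  invisible(paths)
}
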