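#' Library-preparation parameters for the particle-templated simulator
#'
#' Encodes the ClickSeq chemistry knobs: number of primed cDNA fragments,
#' per-nucleotide azido-termination probability (1/6 at the 1:5
#' terminator:extender molar ratio, assuming no polymerase discrimination),
#' minimum usable fragment length, read-length cap, UMI length (12N) and
#' the 7-nt R2 prefix (hexamer + 1 buffer base), PCR duplication model and
#' uniform sequencing-error rate.
#'
#' @param n_fragments number of primed molecules to simulate.
#' @param p_term azido termination probability per extended nucleotide.
#' @param az_bias polymerase terminator incorporation bias multiplier
#'   applied to `p_term` (1 = unbiased).
#' @param min_len minimum fragment length; shorter molecules are never
#'   rendered into reads.
#' @param max_read_len read length cap for both mates.
#' @param umi_len UMI length on R1 (12 unless overridden).
#' @param r2_prefix_len non-genomic R2 prefix removed before mapping
#'   (6 hexamer bases + 1 buffer).
#' @param dup_mean mean PCR duplication factor `d >= 1`.
#' @param dup_model `"poisson1"` (factor `1 + Poisson(d - 1)`) or
#'   `"fixed"` (constant integer factor).
#' @param p_err uniform per-base sequencing error rate, in `[0, 0.1]`.
#' @return object of class `library_params`.
#' @export
library_params <- function(n_fragments = 10000L,
                           p_term = 1 / 6,
                           az_bias = 1,
                           min_len = 20L,
                           max_read_len = 75L,
                           umi_len = 12L,
                           r2_prefix_len = 7L,
                           dup_mean = 1,
                           dup_model = c("poisson1", "fixed"),
                           p_err = 0) {
  dup_model <- match.arg(dup_model)
  p_eff <- p_term * az_bias
  if (p_eff <= 0 || p_eff >= 1) stop("effective termination probability must lie in (0, 1)")
  if (dup_mean < 1) stop("mean PCR duplication factor must be >= 1")
  if (p_err < 0 || p_err > 0.1) stop("p_err must lie in [0, 0.1]")
  if (min_len < 1L) stop("min_len must be >= 1")
  if (max_read_len <= umi_len || max_read_len <= r2_prefix_len) {
    stop("max_read_len must exceed both umi_len and r2_prefix_len")
  }
  structure(list(n_fragments = as.integer(n_fragments), p_term = p_term,
                 az_bias = az_bias, p_term_eff = p_eff,
                 min_len = as.integer(min_len),
                 max_read_len = as.integer(max_read_len),
                 umi_len = as.integer(umi_len),
                 r2_prefix_len = as.integer(r2_prefix_len),
                 dup_mean = dup_mean, dup_model = dup_model, p_err = p_err),
            class = "library_params")
}

#' Crosslink profile: per-U conversion probabilities
#'
#' Maps designated crosslink sites (reference-T positions, i.e. genomic U)
#' to a conversion probability `p_xl`, on top of a global background
#' transition rate `p_bg` applied at every covered U. In `CL-` libraries
#' only `p_bg` acts.
#'
#' @param ref a [genome_reference()].
#' @param sites data.frame with columns `segment`, `pos`, `p_xl`
#'   (may be empty / NULL for a crosslink-free profile).
#' @param p_bg background U-to-C transition rate, in `[0, 0.1]`.
#' @return object of class `crosslink_profile`.
#' @export
crosslink_profile <- function(ref, sites = NULL, p_bg = 0) {
  stopifnot(inherits(ref, "genome_reference"))
  if (is.null(sites)) {
    sites <- data.frame(segment = character(), pos = integer(), p_xl = numeric())
  }
  if (!all(c("segment", "pos", "p_xl") %in% names(sites))) {
    stop("crosslink sites need columns segment, pos, p_xl")
  }
  if (p_bg < 0 || p_bg > 0.1) stop("p_bg must lie in [0, 0.1]")
  if (nrow(sites)) {
    if (any(!sites$segment %in% names(ref$segments))) stop("crosslink site on unknown segment")
    if (any(sites$p_xl < 0 | sites$p_xl > 1)) stop("p_xl must lie in [0, 1]")
    base <- substring(ref$segments[sites$segment], sites$pos, sites$pos)
    if (any(base != "T")) {
      i <- which(base != "T")[1]
      stop(sprintf("crosslink site %s:%d is not a reference T (found '%s')",
                   sites$segment[i], sites$pos[i], base[i]))
    }
  }
  structure(list(sites = sites, p_bg = p_bg), class = "crosslink_profile")
}

random_umis <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Simulate primed, azido-terminated cDNA fragments
#'
#' Draws priming anchors `p` with probability proportional to the mean
#' exposure over the hexamer window `[p + 1, p + 6]`, then a fragment
#' length from a geometric termination law (success probability
#' `p_term * az_bias` per extended nucleotide) truncated below at
#' `min_len` and above at `p` (extension cannot run past position 1).
#' Each covered reference-T position converts to C with probability
#' `p_xl + p_bg` (`CL+`) or `p_bg` (`CL-`). UMIs are uniform over 4^12.
#'
#' Uses the current RNG state; seed with `set.seed()` for reproducibility.
#'
#' @param ref a [genome_reference()].
#' @param profile an [exposure_at_temperature()] result.
#' @param xl a [crosslink_profile()] or NULL (no conversions).
#' @param params a [library_params()].
#' @param condition `"CL+"` or `"CL-"`.
#' @return data.frame with columns `frag_id`, `segment`, `t`, `p`,
#'   `length`, `umi`, `condition`; attribute `conversions` is a data.frame
#'   (`frag_id`, `segment`, `pos`) of converted U positions.
#' @export
simulate_fragments <- function(ref, profile, xl = NULL, params = library_params(),
                               condition = c("CL-", "CL+")) {
  condition <- match.arg(condition)
  stopifnot(inherits(ref, "genome_reference"), inherits(profile, "exposure_profile"))
  if (!identical(names(profile), names(ref$segments)) ||
      !all(lengths(profile) == ref$lengths)) {
    stop("exposure profile does not match reference segments")
  }
  w <- priming_weights(profile, min_len = params$min_len)
  wall <- unlist(w, use.names = FALSE)
  if (all(wall <= 0)) stop("no priming-competent positions (all-zero exposure)")
  n <- params$n_fragments
  seg_names <- rep(names(ref$segments), ref$lengths)
  pos_all <- unlist(lapply(ref$lengths, seq_len), use.names = FALSE)
  idx <- sample.int(length(wall), n, replace = TRUE, prob = wall)
  seg <- seg_names[idx]
  p <- pos_all[idx]
  len <- pmin.int(params$min_len + stats::rgeom(n, params$p_term_eff), p)
  t <- p - len + 1L
  umi <- random_umis(n, params$umi_len)
  frags <- data.frame(frag_id = seq_len(n), segment = seg, t = t, p = p,
                      length = len, umi = umi, condition = condition,
                      stringsAsFactors = FALSE)
  attr(frags, "conversions") <- draw_conversions(frags, ref, xl, condition)
  frags
}

# Bernoulli U->C conversion draws, one pass per convertible T position
draw_conversions <- function(frags, ref, xl, condition) {
  empty <- data.frame(frag_id = integer(), segment = character(), pos = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(xl)) return(empty)
  stopifnot(inherits(xl, "crosslink_profile"))
  out <- list()
  for (seg in unique(frags$segment)) {
    probs <- numeric(0)
    if (xl$p_bg > 0) {
      tp <- t_positions(ref, seg)
      probs <- stats::setNames(rep(xl$p_bg, length(tp)), tp)
    }
    if (condition == "CL+" && nrow(xl$sites)) {
      s <- xl$sites[xl$sites$segment == seg, ]
      for (i in seq_len(nrow(s))) {
        key <- as.character(s$pos[i])
        probs[key] <- min(1, s$p_xl[i] + xl$p_bg)
      }
    }
    probs <- probs[probs > 0]
    if (!length(probs)) next
    in_seg <- which(frags$segment == seg)
    tt <- frags$t[in_seg]; pp <- frags$p[in_seg]
    for (key in names(probs)) {
      pos <- as.integer(key)
      cov <- in_seg[tt <= pos & pp >= pos]
      if (!length(cov)) next
      hit <- cov[stats::runif(length(cov)) < probs[[key]]]
      if (length(hit)) {
        out[[length(out) + 1L]] <- data.frame(frag_id = frags$frag_id[hit],
                                              segment = seg, pos = pos,
                                              stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$frag_id, res$pos), , drop = FALSE]
}

#' Expand molecules into PCR duplicates
#'
#' Each molecule is emitted an integer number of times (at least once)
#' according to the duplication model in `params`. Duplicate copies share
#' UMI, coordinates and conversion status; sequencing errors are drawn
#' independently per copy at render time.
#'
#' @param frags a [simulate_fragments()] table.
#' @param params a [library_params()].
#' @return expanded fragment table with a `molecule_id` column (the
#'   original `frag_id`) and fresh row-wise `frag_id`s; the `conversions`
#'   attribute is propagated to all copies.
#' @export
apply_pcr_duplication <- function(frags, params) {
  if (params$dup_mean < 1) stop("mean PCR duplication factor must be >= 1")
  n <- nrow(frags)
  factor <- if (params$dup_model == "fixed") {
    rep(as.integer(round(params$dup_mean)), n)
  } else if (params$dup_mean == 1) {
    rep(1L, n)
  } else {
    1L + stats::rpois(n, params$dup_mean - 1)
  }
  conv <- attr(frags, "conversions")
  idx <- rep(seq_len(n), factor)
  out <- frags[idx, , drop = FALSE]
  out$molecule_id <- frags$frag_id[idx]
  out$frag_id <- seq_along(idx)
  rownames(out) <- NULL
  if (!is.null(conv) && nrow(conv)) {
    # re-key conversions onto the expanded copies
    copies <- split(out$frag_id, out$molecule_id)
    reps <- copies[as.character(conv$frag_id)]
    conv2 <- data.frame(frag_id = unlist(reps, use.names = FALSE),
                        segment = rep(conv$segment, lengths(reps)),
                        pos = rep(conv$pos, lengths(reps)),
                        stringsAsFactors = FALSE)
    conv2 <- conv2[order(conv2$frag_id, conv2$pos), , drop = FALSE]
    rownames(conv2) <- NULL
    attr(out, "conversions") <- conv2
  } else {
    attr(out, "conversions") <- conv
  }
  out
}

apply_sequencing_errors <- function(reads, p_err, protect = 0L) {
  if (p_err <= 0) return(reads)
  lens <- nchar(reads)
  n_err <- stats::rbinom(length(reads), pmax(lens - protect, 0L), p_err)
  hit <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- protect + sample.int(lens[i] - protect, n_err[i])
    for (j in pos) {
      cur <- substr(reads[i], j, j)
      substr(reads[i], j, j) <- sample(setdiff(bases, cur), 1L)
    }
  }
  reads
}

#' Render fragments into paired sequencing reads
#'
#' R1 carries the 12-mer UMI followed by the sense-strand fragment
#' sequence starting at `t` (ascending), capped at `max_read_len`. R2
#' carries a 7-nt prefix (reverse complement of the hexamer annealing
#' window `[p + 1, p + 6]` plus one buffer base) followed by the antisense
#' fragment sequence starting at `p` (descending), capped at
#' `max_read_len`. Converted U positions read C on the sense strand
#' (G on the antisense strand). Sequencing errors are applied uniformly
#' at `p_err` over the full read, UMI and prefix included.
#'
#' @param frags fragment table ([simulate_fragments()], optionally after
#'   [apply_pcr_duplication()]).
#' @param ref a [genome_reference()].
#' @param params a [library_params()].
#' @return data.frame with columns `name`, `r1`, `r2`.
#' @export
render_read_pairs <- function(frags, ref, params = library_params()) {
  if (any(frags$length < params$min_len)) {
    stop("fragments shorter than min_len must be rejected before rendering")
  }
  if (any(frags$p + 6L > ref$lengths[frags$segment])) {
    stop("fragment hexamer window runs past segment end")
  }
  segseq <- ref$segments[frags$segment]
  fragseq <- substring(segseq, frags$t, frags$p)
  conv <- attr(frags, "conversions")
  if (!is.null(conv) && nrow(conv)) {
    row_of <- match(conv$frag_id, frags$frag_id)
    off <- conv$pos - frags$t[row_of] + 1L
    for (i in seq_along(row_of)) {
      substr(fragseq[row_of[i]], off[i], off[i]) <- "C"
    }
  }
  r1 <- paste0(frags$umi, substr(fragseq, 1L, params$max_read_len - params$umi_len))
  hexrc <- revcomp(substring(segseq, frags$p + 1L, frags$p + 6L))
  buffer <- sample(c("A", "C", "G", "T"), nrow(frags), replace = TRUE)
  r2 <- paste0(hexrc, buffer,
               substr(revcomp(fragseq), 1L, params$max_read_len - params$r2_prefix_len))
  r1 <- apply_sequencing_errors(r1, params$p_err)
  r2 <- apply_sequencing_errors(r2, params$p_err)
  data.frame(name = sprintf("sim%08d", frags$frag_id), r1 = r1, r2 = r2,
             stringsAsFactors = FALSE)
}

write_fastq <- function(names, seqs, path) {
  qual <- strrep("I", nchar(seqs))
  rec <- rbind(paste0("@", names), seqs, "+", qual)
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeLines(as.vector(rec), con)
  invisible(path)
}

#' Write a full simulated run to disk
#'
#' Emits gzip FASTQ mates, the FASTA reference, plain-TSV truth tables
#' (fragments and U-to-C conversions, plus the expected priming-weight
#' track) and a JSON manifest of all parameters.
#'
#' @param frags fragment table (after optional PCR duplication).
#' @param ref a [genome_reference()].
#' @param params a [library_params()].
#' @param out_dir output directory (created if missing).
#' @param profile optional exposure profile, stored as truth.
#' @param seed seed recorded in the manifest (informational).
#' @return named list of written paths, invisibly.
#' @export
write_run <- function(frags, ref, params, out_dir, profile = NULL, seed = NULL) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", out_dir)
  pairs <- render_read_pairs(frags, ref, params)
  paths <- list(
    r1 = file.path(out_dir, "reads_R1.fastq.gz"),
    r2 = file.path(out_dir, "reads_R2.fastq.gz"),
    fasta = file.path(out_dir, "reference.fasta"),
    fragments = file.path(out_dir, "truth_fragments.tsv"),
    conversions = file.path(out_dir, "truth_conversions.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  tryCatch({
    write_fastq(pairs$name, pairs$r1, paths$r1)
    write_fastq(pairs$name, pairs$r2, paths$r2)
    write_fasta(ref, paths$fasta)
    utils::write.table(frags, paths$fragments, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    conv <- attr(frags, "conversions")
    if (is.null(conv)) {
      conv <- data.frame(frag_id = integer(), segment = character(), pos = integer())
    }
    utils::write.table(conv, paths$conversions, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(profile)) {
      w <- priming_weights(profile, min_len = params$min_len)
      pw <- data.frame(segment = rep(names(w), lengths(w)),
                       pos = unlist(lapply(w, seq_along), use.names = FALSE),
                       weight = unlist(w, use.names = FALSE))
      paths$priming_weights <- file.path(out_dir, "truth_priming_weights.tsv")
      utils::write.table(pw, paths$priming_weights, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    manifest <- list(package = "ptclickseq",
                     seed = seed,
                     n_fragments = nrow(frags),
                     params = unclass(params),
                     segments = as.list(ref$lengths),
                     temperature = if (!is.null(profile)) attr(profile, "temperature"),
                     condition = unique(frags$condition))
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
  }, error = function(e) {
    stop("failed writing run to '", out_dir, "': ", conditionMessage(e))
  })
  invisible(paths)
}

#' Read back the truth tables written by [write_run()]
#'
#' @param out_dir directory written by [write_run()].
#' @return list with `fragments`, `conversions`, `manifest`.
#' @export
read_truth <- function(out_dir) {
  fp <- file.path(out_dir, "truth_fragments.tsv")
  cp <- file.path(out_dir, "truth_conversions.tsv")
  mp <- file.path(out_dir, "manifest.json")
  if (!file.exists(fp)) stop("missing truth table: ", fp)
  list(fragments = utils::read.delim(fp, stringsAsFactors = FALSE),
       conversions = utils::read.delim(cp, stringsAsFactors = FALSE),
       manifest = jsonlite::read_json(mp))
}
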