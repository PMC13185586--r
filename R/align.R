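#' k-mer seed index over a small reference
#'
#' Builds exact-match seed tables (hash environments keyed by k-mer) for
#' both strands of every segment. Suitable for references of a few kb;
#' this replaces an external aligner for the ungapped, high-identity
#' reads produced by the simulator or by ClickSeq libraries on a small
#' viral genome.
#'
#' @param ref a [genome_reference()].
#' @param k seed length (default 12).
#' @return object of class `kmer_index`.
#' @export
kmer_index <- function(ref, k = 12L) {
  stopifnot(inherits(ref, "genome_reference"))
  k <- as.integer(k)
  if (k < 4L || any(ref$lengths < k)) stop("seed length k unsuitable for this reference")
  strands <- lapply(names(ref$segments), function(seg) {
    fwd <- ref$segments[[seg]]
    rev <- revcomp(fwd)
    list(fwd = seed_env(fwd, k), rev = seed_env(rev, k),
         fwd_seq = fwd, rev_seq = rev, L = ref$lengths[[seg]])
  })
  names(strands) <- names(ref$segments)
  structure(list(k = k, segments = strands, ref = ref), class = "kmer_index")
}

seed_env <- function(seq, k) {
  L <- nchar(seq)
  n <- L - k + 1L
  kmers <- substring(seq, seq_len(n), seq_len(n) + k - 1L)
  list2env(split(seq_len(n), kmers), hash = TRUE, size = n)
}

# candidate (read, start-on-string) pairs from one seed offset
# (offset may be scalar or per-read)
seed_candidates <- function(inserts, env, offset, k) {
  lens <- nchar(inserts)
  offset <- rep_len(offset, length(inserts))
  ok <- which(lens >= offset + k - 1L & offset >= 1L)
  if (!length(ok)) return(data.frame(read = integer(), start = integer()))
  seeds <- substring(inserts[ok], offset[ok], offset[ok] + k - 1L)
  hits <- mget(seeds, envir = env, ifnotfound = list(integer(0)))
  nh <- lengths(hits)
  data.frame(read = rep(ok, nh),
             start = unlist(hits, use.names = FALSE) - rep(offset[ok], nh) + 1L)
}

count_mismatch_pairs <- function(a, b) {
  vapply(seq_along(a),
         function(i) sum(charToRaw(a[i]) != charToRaw(b[i])),
         integer(1))
}

#' Align inserts to the reference (ungapped, best placement)
#'
#' Exact k-mer seeding (offsets 1, 1+k, 1+2k as read length permits)
#' followed by full-length ungapped comparison; the best placement by
#' mismatch count wins, both strands tried. Ties are broken by segment
#' order in the reference, then leftmost sense coordinate, then plus
#' strand. Reads whose best mismatch fraction exceeds `max_mm_frac`, or
#' that are shorter than `k`, are reported unaligned.
#'
#' @param inserts character vector of read inserts.
#' @param index a [kmer_index()].
#' @param max_mm_frac maximum tolerated mismatch fraction (default 0.1).
#' @return data.frame with one row per insert: `query`, `aligned`,
#'   `segment`, `start`, `end`, `strand` (`+`/`-` on genome sense),
#'   `n_mm`; attribute `mismatches` is a data.frame (`query`, `pos`,
#'   `base`) giving mismatching genome-sense positions and the read base
#'   expressed on the sense strand.
#' @export
align_inserts <- function(inserts, index, max_mm_frac = 0.1) {
  stopifnot(inherits(index, "kmer_index"))
  k <- index$k
  n <- length(inserts)
  lens <- nchar(inserts)
  res <- data.frame(query = seq_len(n), aligned = FALSE,
                    segment = NA_character_, start = NA_integer_,
                    end = NA_integer_, strand = NA_character_,
                    n_mm = NA_integer_, stringsAsFactors = FALSE)
  mm_detail <- list()
  todo <- which(lens >= k)
  if (!length(todo)) {
    attr(res, "mismatches") <- data.frame(query = integer(), pos = integer(),
                                          base = character())
    return(res)
  }
  seg_names <- names(index$segments)
  # offsets into the read used for seeding; later offsets (and a tail
  # seed, for reads shorter than 2k) rescue reads whose first k bases
  # carry an error
  offset_list <- list(1L, 1L + k, 1L + 2L * k, pmax(lens - k + 1L, 1L))
  best <- NULL  # running best per read: data.frame columns
  for (si in seq_along(seg_names)) {
    entry <- index$segments[[si]]
    for (strand_i in 1:2) {
      env <- if (strand_i == 1L) entry$fwd else entry$rev
      seqstr <- if (strand_i == 1L) entry$fwd_seq else entry$rev_seq
      cand <- do.call(rbind, lapply(offset_list, function(o) {
        seed_candidates(inserts, env, o, k)
      }))
      if (!nrow(cand)) next
      cand <- cand[cand$start >= 1L & cand$start + lens[cand$read] - 1L <= entry$L, ,
                   drop = FALSE]
      cand <- cand[!duplicated(cand[c("read", "start")]), , drop = FALSE]
      if (!nrow(cand)) next
      win <- substring(seqstr, cand$start, cand$start + lens[cand$read] - 1L)
      exact <- win == inserts[cand$read]
      mm <- integer(nrow(cand))
      ne <- which(!exact)
      if (length(ne)) {
        mm[ne] <- count_mismatch_pairs(inserts[cand$read[ne]], win[ne])
      }
      # per read keep the best candidate on this (segment, strand)
      ord <- order(cand$read, mm, cand$start)
      first <- ord[!duplicated(cand$read[ord])]
      loc <- data.frame(read = cand$read[first], seg_i = si, strand_i = strand_i,
                        s1 = cand$start[first], mm = mm[first])
      best <- rbind(best, loc)
    }
  }
  if (!is.null(best) && nrow(best)) {
    # global tie-break: fewest mismatches, then segment order, then leftmost
    # sense coordinate, then plus strand
    L_of <- vapply(best$seg_i, function(i) index$segments[[i]]$L, numeric(1))
    len_of <- lens[best$read]
    sense_start <- ifelse(best$strand_i == 1L, best$s1, L_of - (best$s1 + len_of - 1L) + 1L)
    ord <- order(best$read, best$mm, best$seg_i, sense_start, best$strand_i)
    pick <- ord[!duplicated(best$read[ord])]
    sel <- best[pick, , drop = FALSE]
    sel$sense_start <- sense_start[pick]
    keep <- sel$mm <= max_mm_frac * lens[sel$read]
    sel <- sel[keep, , drop = FALSE]
    if (nrow(sel)) {
      r <- sel$read
      res$aligned[r] <- TRUE
      res$segment[r] <- seg_names[sel$seg_i]
      res$start[r] <- as.integer(sel$sense_start)
      res$end[r] <- as.integer(sel$sense_start + lens[r] - 1L)
      res$strand[r] <- ifelse(sel$strand_i == 1L, "+", "-")
      res$n_mm[r] <- sel$mm
      withmm <- which(sel$mm > 0L)
      for (j in withmm) {
        entry <- index$segments[[sel$seg_i[j]]]
        seqstr <- if (sel$strand_i[j] == 1L) entry$fwd_seq else entry$rev_seq
        rd <- inserts[sel$read[j]]
        win <- substr(seqstr, sel$s1[j], sel$s1[j] + nchar(rd) - 1L)
        d <- which(charToRaw(rd) != charToRaw(win))
        if (sel$strand_i[j] == 1L) {
          pos <- sel$s1[j] + d - 1L
          base <- substring(rd, d, d)
        } else {
          pos <- entry$L - (sel$s1[j] + d - 1L) + 1L
          base <- comp_base(substring(rd, d, d))
        }
        mm_detail[[length(mm_detail) + 1L]] <-
          data.frame(query = sel$read[j], pos = as.integer(pos), base = base,
                     stringsAsFactors = FALSE)
      }
    }
  }
  mmdf <- if (length(mm_detail)) do.call(rbind, mm_detail) else {
    data.frame(query = integer(), pos = integer(), base = character(),
               stringsAsFactors = FALSE)
  }
  attr(res, "mismatches") <- mmdf
  res
}

comp_base <- function(x) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[x]
}

#' @rdname align_inserts
#' @param insert a single insert sequence.
#' @export
align_insert <- function(insert, index, max_mm_frac = 0.1) {
  res <- align_inserts(insert, index, max_mm_frac)
  out <- as.list(res[1, ])
  out$mismatches <- attr(res, "mismatches")[, c("pos", "base")]
  out
}

#' Write ungapped alignments as SAM
#'
#' One record per aligned mate; the UMI is appended to the read name
#' after an underscore (umi-tools style). Unaligned mates are skipped.
#'
#' @param molecules a [process_run()] molecule table (pre- or
#'   post-dedup).
#' @param ref a [genome_reference()].
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(molecules, ref, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(ref$segments), ref$lengths)),
             con)
  emit <- function(name, umi, flagbase, seg, start, len, strand, seq) {
    flag <- flagbase + if (strand == "-") 16L else 0L
    oriented <- if (strand == "-") revcomp(seq) else seq
    writeLines(sprintf("%s_%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                       name, umi, flag, seg, start, len, oriented), con)
  }
  m <- molecules
  emit(m$name, m$umi, 64L + 1L, m$segment, m$r1_start,
       m$r1_end - m$r1_start + 1L, "+", m$insert1)
  emit(m$name, m$umi, 128L + 1L, m$segment, m$r2_start,
       m$r2_end - m$r2_start + 1L, "-", m$insert2)
  invisible(path)
}

#' Ingest externally aligned reads from a SAM file
#'
#' Primary, mapped, purely matched (`<n>M` CIGAR) records are converted
#' into the native alignment representation; records with indels, soft
#' clips or other CIGAR operations are skipped and counted. Mismatches
#' are recomputed against the reference from the SEQ field. The UMI is
#' taken from the read-name suffix after the last underscore
#' (umi-tools convention) unless `umi_from = "none"`.
#'
#' @param path SAM file path.
#' @param ref a [genome_reference()]; `@SQ` headers must match its
#'   segment names and lengths.
#' @param umi_from `"name"` or `"none"`.
#' @return data.frame of per-record alignments (`name`, `umi`, `mate`,
#'   `segment`, `start`, `end`, `strand`, `n_mm`) with attributes
#'   `mismatches` (`query`, `pos`, `base` on genome sense) and `counts`.
#' @export
ingest_sam <- function(path, ref, umi_from = c("name", "none")) {
  umi_from <- match.arg(umi_from)
  if (!file.exists(path)) stop("SAM file not found: ", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  sn <- sub(".*\\tSN:([^\t]+).*", "\\1", sq)
  ln <- as.integer(sub(".*\\tLN:([0-9]+).*", "\\1", sq))
  if (!setequal(sn, names(ref$segments)) ||
      !all(ln[match(names(ref$segments), sn)] == ref$lengths)) {
    stop("SAM header does not match reference segment names/lengths")
  }
  body <- lines[!startsWith(lines, "@")]
  body <- body[nzchar(body)]
  counts <- c(records = length(body), skipped_unmapped = 0L,
              skipped_secondary = 0L, skipped_cigar = 0L, kept = 0L)
  if (!length(body)) {
    out <- data.frame(name = character(), umi = character(), mate = integer(),
                      segment = character(), start = integer(), end = integer(),
                      strand = character(), n_mm = integer())
    attr(out, "mismatches") <- data.frame(query = integer(), pos = integer(),
                                          base = character())
    attr(out, "counts") <- counts
    return(out)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  qname <- vapply(f, `[`, "", 1L)
  flag <- as.integer(vapply(f, `[`, "", 2L))
  rname <- vapply(f, `[`, "", 3L)
  pos <- as.integer(vapply(f, `[`, "", 4L))
  cigar <- vapply(f, `[`, "", 6L)
  seqs <- toupper(vapply(f, `[`, "", 10L))
  unmapped <- bitwAnd(flag, 4L) != 0L
  secondary <- bitwAnd(flag, 256L) != 0L | bitwAnd(flag, 2048L) != 0L
  pure_m <- grepl("^[0-9]+M$", cigar)
  counts["skipped_unmapped"] <- sum(unmapped)
  counts["skipped_secondary"] <- sum(!unmapped & secondary)
  counts["skipped_cigar"] <- sum(!unmapped & !secondary & !pure_m)
  keep <- which(!unmapped & !secondary & pure_m)
  counts["kept"] <- length(keep)
  strand <- ifelse(bitwAnd(flag[keep], 16L) != 0L, "-", "+")
  mate <- ifelse(bitwAnd(flag[keep], 128L) != 0L, 2L, 1L)
  lens <- nchar(seqs[keep])
  end <- pos[keep] + lens - 1L
  over <- end > ref$lengths[rname[keep]]
  if (any(over)) stop("SAM record extends past segment end: ", qname[keep][which(over)[1]])
  umi <- if (umi_from == "name") sub(".*_", "", qname[keep]) else NA_character_
  name <- if (umi_from == "name") sub("_[^_]*$", "", qname[keep]) else qname[keep]
  refwin <- substring(ref$segments[rname[keep]], pos[keep], end)
  mmcount <- integer(length(keep))
  ne <- which(refwin != seqs[keep])
  if (length(ne)) mmcount[ne] <- count_mismatch_pairs(seqs[keep][ne], refwin[ne])
  mm_detail <- list()
  for (j in ne) {
    d <- which(charToRaw(seqs[keep][j]) != charToRaw(refwin[j]))
    mm_detail[[length(mm_detail) + 1L]] <-
      data.frame(query = j, pos = pos[keep][j] + d - 1L,
                 base = substring(seqs[keep][j], d, d), stringsAsFactors = FALSE)
  }
  out <- data.frame(name = name, umi = umi, mate = mate, segment = rname[keep],
                    start = pos[keep], end = end, strand = strand, n_mm = mmcount,
                    stringsAsFactors = FALSE)
  attr(out, "mismatches") <- if (length(mm_detail)) do.call(rbind, mm_detail) else {
    data.frame(query = integer(), pos = integer(), base = character())
  }
  attr(out, "counts") <- counts
  out
}
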