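#' Process a paired-end run into aligned molecule records
#'
#' Chains FASTQ parsing, UMI extraction / prefix trimming and ungapped
#' alignment of both mates. A pair is kept when both inserts align to the
#' same segment with R1 on the plus strand and R2 on the minus strand
#' (the library is strand-specific: R1 reads the cDNA sense, R2 reads
#' antisense from the priming end); anything else is counted as
#' unaligned. The R2 5' genomic coordinate (its sense-strand `end`) is
#' the priming anchor used for deduplication.
#'
#' @param r1_path,r2_path FASTQ paths, or pass `pairs` directly.
#' @param ref a [genome_reference()].
#' @param pairs optional pre-parsed [parse_fastq_pair()] table (overrides
#'   the paths).
#' @param index optional prebuilt [kmer_index()].
#' @param umi_len,umi_offset,r2_prefix_len see [extract_umi_and_trim()].
#' @param max_mm_frac see [align_inserts()].
#' @return data.frame of per-pair molecule records (`name`, `umi`,
#'   `segment`, `anchor`, `r1_start`, `r1_end`, `r2_start`, `r2_end`,
#'   `insert1`, `insert2`, `n_mm`); attributes `mismatches` (`query`
#'   indexing rows, `pos`, `base`, `mate`) and `counts`
#'   (`parsed`, `dropped_short`, `unaligned`, `aligned`).
#' @export
process_run <- function(r1_path = NULL, r2_path = NULL, ref, pairs = NULL,
                        index = NULL, umi_len = 12L, umi_offset = 0L,
                        r2_prefix_len = 7L, max_mm_frac = 0.1) {
  if (is.null(pairs)) pairs <- parse_fastq_pair(r1_path, r2_path)
  trimmed <- extract_umi_and_trim(pairs, umi_len = umi_len,
                                  umi_offset = umi_offset,
                                  r2_prefix_len = r2_prefix_len)
  if (is.null(index)) index <- kmer_index(ref)
  a1 <- align_inserts(trimmed$insert1, index, max_mm_frac)
  a2 <- align_inserts(trimmed$insert2, index, max_mm_frac)
  ok <- a1$aligned & a2$aligned & a1$segment == a2$segment &
    a1$strand == "+" & a2$strand == "-"
  ok[is.na(ok)] <- FALSE
  keep <- which(ok)
  mol <- data.frame(
    name = trimmed$name[keep],
    umi = trimmed$umi[keep],
    segment = a1$segment[keep],
    anchor = a2$end[keep],
    r1_start = a1$start[keep], r1_end = a1$end[keep],
    r2_start = a2$start[keep], r2_end = a2$end[keep],
    insert1 = trimmed$insert1[keep], insert2 = trimmed$insert2[keep],
    n_mm = a1$n_mm[keep] + a2$n_mm[keep],
    stringsAsFactors = FALSE
  )
  remap <- function(mmdf, mate) {
    m <- mmdf[mmdf$query %in% keep, , drop = FALSE]
    m$query <- match(m$query, keep)
    m$mate <- rep(mate, nrow(m))
    m
  }
  mm <- rbind(remap(attr(a1, "mismatches"), 1L), remap(attr(a2, "mismatches"), 2L))
  attr(mol, "mismatches") <- mm
  pc <- attr(pairs, "counts")["parsed"]
  dc <- attr(trimmed, "counts")["dropped_short"]
  attr(mol, "counts") <- c(parsed = unname(pc), dropped_short = unname(dc),
                           unaligned = nrow(trimmed) - length(keep),
                           aligned = length(keep))
  mol
}

#' Deduplicate molecules on (segment, priming anchor, UMI)
#'
#' Mirrors UMI-based PCR deduplication: PCR duplicates share both the
#' UMI and the R2-derived priming anchor, so exactly one representative
#' (the first encountered in input order) is retained per distinct key.
#' An optional 1-mismatch UMI clustering mode (off by default) greedily
#' merges low-count UMIs into a within-anchor neighbour that is one
#' substitution away.
#'
#' @param molecules a [process_run()] or [truth_molecules()] table.
#' @param cluster_umis merge UMIs within one substitution of a more
#'   abundant UMI at the same anchor.
#' @return the retained subset, with attribute `counts`
#'   (`input`, `retained`).
#' @export
dedup_molecules <- function(molecules, cluster_umis = FALSE) {
  if (!nrow(molecules)) {
    attr(molecules, "counts") <- c(input = 0L, retained = 0L)
    return(molecules)
  }
  umi <- molecules$umi
  if (cluster_umis) {
    grp <- paste(molecules$segment, molecules$anchor)
    for (g in unique(grp)) {
      i <- which(grp == g)
      tab <- sort(table(umi[i]), decreasing = TRUE)
      us <- names(tab)
      if (length(us) < 2L) next
      canon <- stats::setNames(us, us)
      for (a in seq(length(us), 2L)) {
        for (b in seq_len(a - 1L)) {
          if (sum(charToRaw(us[a]) != charToRaw(us[b])) <= 1L) {
            canon[us[a]] <- canon[us[b]]
            break
          }
        }
      }
      umi[i] <- canon[umi[i]]
    }
  }
  key <- paste(molecules$segment, molecules$anchor, umi, sep = "\r")
  keep <- !duplicated(key)
  out <- molecules[keep, , drop = FALSE]
  mm <- attr(molecules, "mismatches")
  if (!is.null(mm)) {
    kept_rows <- which(keep)
    m <- mm[mm$query %in% kept_rows, , drop = FALSE]
    m$query <- match(m$query, kept_rows)
    attr(out, "mismatches") <- m
  }
  attr(out, "counts") <- c(input = nrow(molecules), retained = nrow(out))
  rownames(out) <- NULL
  out
}

#' Molecule records directly from simulator truth
#'
#' Bypasses read rendering and alignment: converts a
#' [simulate_fragments()] table (optionally PCR-duplicated) into the
#' same molecule representation that [process_run()] produces, with mate
#' intervals derived from the read-length caps and mismatches taken from
#' the recorded U-to-C conversions. This is the fast, error-free route
#' used for statistical calibration at large fragment counts; the
#' render-parse-align route is validated against it by the closure
#' tests.
#'
#' @param frags fragment table with `conversions` attribute.
#' @param params a [library_params()].
#' @return molecule table as in [process_run()] (without insert
#'   sequences), with `mismatches` and `counts` attributes.
#' @export
truth_molecules <- function(frags, params = library_params()) {
  r1_len <- params$max_read_len - params$umi_len
  r2_len <- params$max_read_len - params$r2_prefix_len
  mol <- data.frame(
    name = sprintf("sim%08d", frags$frag_id),
    umi = frags$umi,
    segment = frags$segment,
    anchor = frags$p,
    r1_start = frags$t, r1_end = pmin.int(frags$t + r1_len - 1L, frags$p),
    r2_start = pmax.int(frags$p - r2_len + 1L, frags$t), r2_end = frags$p,
    stringsAsFactors = FALSE
  )
  conv <- attr(frags, "conversions")
  if (is.null(conv) || !nrow(conv)) {
    mm <- data.frame(query = integer(), pos = integer(), base = character(),
                     mate = integer(), stringsAsFactors = FALSE)
  } else {
    row_of <- match(conv$frag_id, frags$frag_id)
    on_r1 <- conv$pos <= mol$r1_end[row_of]
    on_r2 <- conv$pos >= mol$r2_start[row_of]
    seen <- on_r1 | on_r2
    mm <- data.frame(query = row_of[seen], pos = conv$pos[seen], base = "C",
                     mate = ifelse(on_r1[seen], 1L, 2L), stringsAsFactors = FALSE)
  }
  attr(mol, "mismatches") <- mm
  attr(mol, "counts") <- c(parsed = nrow(mol), dropped_short = 0L,
                           unaligned = 0L, aligned = nrow(mol))
  mol
}

#' Per-position base-count pileup from deduplicated molecules
#'
#' Each molecule contributes its merged mate footprint once: the R1
#' interval plus any part of the R2 interval not already covered by R1
#' (base calls in the overlap are taken from R1). Counts are tallied on
#' the genome sense; antisense (R2) reads contribute the complement of
#' their base calls, which the aligner already expresses in sense
#' orientation.
#'
#' @param molecules deduplicated molecule table ([dedup_molecules()]).
#' @param ref a [genome_reference()].
#' @return object of class `pileup_matrix`: named list (per segment) of
#'   integer matrices `L x 6` with columns `A, C, G, T, N, depth`.
#' @export
build_pileup <- function(molecules, ref) {
  stopifnot(inherits(ref, "genome_reference"))
  bases <- c("A", "C", "G", "T", "N")
  mm <- attr(molecules, "mismatches")
  if (is.null(mm)) {
    mm <- data.frame(query = integer(), pos = integer(), base = character(),
                     mate = integer())
  }
  out <- lapply(names(ref$segments), function(seg) {
    L <- ref$lengths[[seg]]
    M <- matrix(0L, nrow = L, ncol = 6L,
                dimnames = list(NULL, c(bases, "depth")))
    rows <- which(molecules$segment == seg)
    if (!length(rows)) return(M)
    s1 <- molecules$r1_start[rows]; e1 <- molecules$r1_end[rows]
    s2 <- molecules$r2_start[rows]; e2 <- molecules$r2_end[rows]
    if (any(s1 < 1L | e2 > L | s2 < 1L | e1 > L, na.rm = TRUE)) {
      stop("alignment outside segment bounds in pileup for ", seg)
    }
    # merged footprint = [s1, e1] plus the R2-only part [max(e1+1, s2), e2]
    s2b <- pmax.int(s2, e1 + 1L)
    add <- tabulate(s1, L + 1L) + tabulate(s2b[s2b <= e2], L + 1L)
    rem <- tabulate(e1 + 1L, L + 1L) + tabulate(e2[s2b <= e2] + 1L, L + 1L)
    depth <- cumsum(add - rem)[seq_len(L)]
    # mismatch bases: R1 calls win in the mate overlap
    m <- mm[mm$query %in% rows, , drop = FALSE]
    if (nrow(m)) {
      i <- m$query
      in_r1 <- m$pos >= molecules$r1_start[i] & m$pos <= molecules$r1_end[i]
      in_r2only <- !in_r1 & m$pos >= pmax.int(molecules$r2_start[i],
                                              molecules$r1_end[i] + 1L) &
        m$pos <= molecules$r2_end[i]
      use <- (m$mate == 1L & in_r1) | (m$mate == 2L & in_r2only)
      m <- m[use, , drop = FALSE]
    }
    mmtot <- if (nrow(m)) tabulate(m$pos, L) else integer(L)
    refcol <- match(strsplit(ref$segments[[seg]], "")[[1]], bases)
    M[cbind(seq_len(L), refcol)] <- depth - mmtot
    if (nrow(m)) {
      for (b in bases) {
        sel <- m$base == b
        if (any(sel)) M[, b] <- M[, b] + tabulate(m$pos[sel], L)
      }
    }
    M[, "depth"] <- depth
    storage.mode(M) <- "integer"
    M
  })
  names(out) <- names(ref$segments)
  structure(out, class = "pileup_matrix")
}
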