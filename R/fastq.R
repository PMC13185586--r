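#' Parse a pair of FASTQ files into mate-paired records
#'
#' Reads both mates fully into memory (references here are under 5 kb and
#' runs are at most a few hundred thousand pairs). Gzip and plain files
#' are both accepted. Record names must match between mates after
#' stripping a trailing `/1` / `/2` and anything after the first
#' whitespace; a mismatch or a truncated record is a hard error naming
#' the offending record index.
#'
#' @param r1_path,r2_path FASTQ paths.
#' @return data.frame with columns `name`, `seq1`, `qual1`, `seq2`,
#'   `qual2`; attribute `counts` holds `parsed` and `malformed`.
#' @export
parse_fastq_pair <- function(r1_path, r2_path) {
  r1 <- read_fastq_records(r1_path)
  r2 <- read_fastq_records(r2_path)
  if (nrow(r1) != nrow(r2)) {
    stop(sprintf("mate files differ in record count (%d vs %d); first missing mate at record %d",
                 nrow(r1), nrow(r2), min(nrow(r1), nrow(r2)) + 1L))
  }
  if (nrow(r1) == 0L) {
    warning("empty FASTQ input: ", r1_path)
  } else {
    bad <- which(r1$name != r2$name)
    if (length(bad)) {
      stop(sprintf("mate name mismatch at record %d: '%s' vs '%s'",
                   bad[1], r1$name[bad[1]], r2$name[bad[1]]))
    }
  }
  out <- data.frame(name = r1$name, seq1 = r1$seq, qual1 = r1$qual,
                    seq2 = r2$seq, qual2 = r2$qual, stringsAsFactors = FALSE)
  attr(out, "counts") <- c(parsed = nrow(out), malformed = 0L)
  out
}

read_fastq_records <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("truncated FASTQ '%s': %d lines is not a multiple of 4",
                 path, length(lines)))
  }
  n <- length(lines) %/% 4L
  if (n == 0L) {
    return(data.frame(name = character(), seq = character(), qual = character(),
                      stringsAsFactors = FALSE))
  }
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- toupper(lines[seq(2L, by = 4L, length.out = n)])
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad)) {
    stop(sprintf("malformed FASTQ record %d in '%s'", bad[1], path))
  }
  name <- sub("\\s.*$", "", substring(hdr, 2L))
  name <- sub("/[12]$", "", name)
  data.frame(name = name, seq = seqs, qual = qual, stringsAsFactors = FALSE)
}

#' Extract the R1 UMI and trim the R2 priming prefix
#'
#' Splits each pair into its 12-mer UMI (taken from R1 at a configurable
#' offset), the R1 insert (R1 minus UMI) and the R2 insert (R2 minus the
#' 7-nt hexamer+buffer prefix). Reads too short to yield a non-empty
#' insert on both mates are dropped and counted, not errored. UMIs
#' containing `N` are retained verbatim.
#'
#' @param pairs a [parse_fastq_pair()] table.
#' @param umi_len UMI length (default 12).
#' @param umi_offset bases to skip on R1 before the UMI (default 0).
#' @param r2_prefix_len R2 prefix length removed before mapping (default 7).
#' @return data.frame with columns `name`, `umi`, `insert1`, `insert2`;
#'   attribute `counts` holds `kept` and `dropped_short`.
#' @export
extract_umi_and_trim <- function(pairs, umi_len = 12L, umi_offset = 0L,
                                 r2_prefix_len = 7L) {
  lead <- umi_offset + umi_len
  keep <- nchar(pairs$seq1) > lead & nchar(pairs$seq2) > r2_prefix_len
  kept <- pairs[keep, , drop = FALSE]
  out <- data.frame(
    name = kept$name,
    umi = substr(kept$seq1, umi_offset + 1L, lead),
    insert1 = substring(kept$seq1, lead + 1L),
    insert2 = substring(kept$seq2, r2_prefix_len + 1L),
    stringsAsFactors = FALSE
  )
  attr(out, "counts") <- c(kept = nrow(out), dropped_short = sum(!keep))
  out
}
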