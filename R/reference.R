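#' Genome reference for a small segmented viral genome
#'
#' A `genome_reference` holds one or more named segments as uppercase DNA
#' strings (the RNA genome is stored in the DNA alphabet, i.e. U as T).
#' Synthetic references must be unambiguous; references ingested from FASTA
#' may contain `N`, which is excluded from transition calling downstream.
#'
#' @param segments named character vector (or named list of single strings)
#'   mapping segment id to sequence. Sequences are uppercased.
#' @param min_length minimum accepted segment length.
#' @param allow_n allow `N` in sequences (set by [read_fasta()]).
#' @return object of class `genome_reference` with elements `segments`
#'   (named character vector) and `lengths` (named integer vector).
#' @examples
#' ref <- genome_reference(c(seg = strrep("ACGT", 30)))
#' segment_lengths(ref)
#' @export
genome_reference <- function(segments, min_length = 100L, allow_n = FALSE) {
  segments <- unlist(segments)
  if (length(segments) < 1L) {
    stop("a genome_reference needs at least one segment")
  }
  if (is.null(names(segments)) || any(!nzchar(names(segments)))) {
    stop("segments must be named")
  }
  if (anyDuplicated(names(segments))) {
    stop("duplicated segment ids: ",
         paste(unique(names(segments)[duplicated(names(segments))]), collapse = ", "))
  }
  segments <- toupper(segments)
  lens <- nchar(segments)
  if (any(lens < min_length)) {
    stop("segment(s) shorter than ", min_length, " nt: ",
         paste(names(segments)[lens < min_length], collapse = ", "))
  }
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  bad <- grepl(sprintf("[^%s]", alphabet), segments)
  if (any(bad)) {
    stop("segment(s) contain characters outside {", alphabet, "}: ",
         paste(names(segments)[bad], collapse = ", "))
  }
  structure(
    list(segments = segments, lengths = stats::setNames(as.integer(lens), names(segments))),
    class = "genome_reference"
  )
}

#' @export
print.genome_reference <- function(x, ...) {
  cat("genome_reference with", length(x$segments), "segment(s):\n")
  for (s in names(x$segments)) {
    cat(sprintf("  %s: %d nt\n", s, x$lengths[[s]]))
  }
  invisible(x)
}

#' @rdname genome_reference
#' @param ref a `genome_reference`.
#' @export
segment_lengths <- function(ref) {
  stopifnot(inherits(ref, "genome_reference"))
  ref$lengths
}

#' Simulate a random reference genome
#'
#' Draws i.i.d. bases per segment under the supplied base composition.
#' Uses the current RNG state; call `set.seed()` beforehand for
#' reproducibility.
#'
#' @param lengths named integer vector of segment lengths.
#' @param base_probs probabilities for A, C, G, T (in that order).
#' @return a [genome_reference()].
#' @export
random_genome <- function(lengths, base_probs = c(A = 0.27, C = 0.22, G = 0.24, T = 0.27)) {
  stopifnot(length(base_probs) == 4L, all(base_probs >= 0))
  segs <- vapply(lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = base_probs),
          collapse = "")
  }, character(1))
  genome_reference(segs)
}

#' Default two-segment nodavirus-like reference
#'
#' Random synthetic stand-in for the bipartite Flock House virus genome:
#' RNA1 of 3107 nt and RNA2 of 1400 nt. The sequence content is random
#' (this is a synthetic reference, not the real FHV sequence); only the
#' segment naming and lengths mirror the real genome.
#'
#' @param seed optional integer seed applied locally.
#' @return a [genome_reference()] with segments `RNA1` and `RNA2`.
#' @export
fhv_like_reference <- function(seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  random_genome(c(RNA1 = 3107L, RNA2 = 1400L))
}

#' Read / write FASTA references
#'
#' Thin wrappers around Biostrings FASTA I/O that produce and consume
#' [genome_reference()] objects.
#'
#' @param path FASTA file path.
#' @return `read_fasta()` returns a `genome_reference`; `write_fasta()`
#'   returns `path` invisibly.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  xs <- Biostrings::readDNAStringSet(path)
  segs <- stats::setNames(as.character(xs), sub("\\s.*$", "", names(xs)))
  genome_reference(segs, allow_n = TRUE)
}

#' @rdname read_fasta
#' @param ref a `genome_reference`.
#' @export
write_fasta <- function(ref, path) {
  stopifnot(inherits(ref, "genome_reference"))
  xs <- Biostrings::DNAStringSet(ref$segments)
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}

#' Genomic regions (1-based inclusive)
#'
#' @param segment segment id.
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @param ref optional `genome_reference` to validate against.
#' @return a `region` object (list with `segment`, `start`, `end`, `width`).
#' @examples
#' parse_region("RNA1:26-75")
#' @export
region <- function(segment, start, end, ref = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start) {
    stop(sprintf("invalid region %s:%s-%s (need 1 <= start <= end)", segment, start, end))
  }
  if (!is.null(ref)) {
    if (!segment %in% names(ref$segments)) {
      stop("region references unknown segment '", segment, "'")
    }
    if (end > ref$lengths[[segment]]) {
      stop(sprintf("region %s:%d-%d exceeds segment length %d",
                   segment, start, end, ref$lengths[[segment]]))
    }
  }
  structure(list(segment = segment, start = start, end = end,
                 width = end - start + 1L),
            class = "region")
}

#' @rdname region
#' @param text region in `"SEGMENT:START-END"` syntax, e.g. `"RNA1:26-75"`.
#' @export
parse_region <- function(text, ref = NULL) {
  m <- regmatches(text, regexec("^\\s*([^:]+):([0-9,]+)\\s*-\\s*([0-9,]+)\\s*$", text))[[1]]
  if (length(m) != 4L) stop("cannot parse region '", text, "' (expected SEGMENT:START-END)")
  region(m[2], as.integer(gsub(",", "", m[3])), as.integer(gsub(",", "", m[4])), ref = ref)
}

#' Reference positions whose base is T (genomic U)
#'
#' @param ref a `genome_reference`.
#' @param segment segment id.
#' @return integer vector of 1-based positions with reference base `T`.
#' @export
t_positions <- function(ref, segment) {
  stopifnot(inherits(ref, "genome_reference"))
  if (!segment %in% names(ref$segments)) stop("unknown segment '", segment, "'")
  which(strsplit(ref$segments[[segment]], "")[[1]] == "T")
}

# reverse complement for plain character vectors (delegates to Biostrings)
revcomp <- function(x) {
  out <- character(length(x))
  nz <- nzchar(x)
  if (any(nz)) {
    out[nz] <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz])))
  }
  out
}
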