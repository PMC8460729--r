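# fragment container, paired-read merging and PCR deduplication

FRAGMENT_FLAGS <- c("redundant", "solo", "primer_trimmed", "gap_filled")

#' Build a fragment table
#'
#' Fragments are the unit record of the pipeline: a mapped double-stranded
#' tagmentation product as a genomic interval, optionally carrying its
#' sequence. Coordinates are 0-based half-open throughout; strand is
#' deliberately absent (the products are double-stranded, so the cut
#' coordinates alone index a fragment).
#'
#' @param chrom,start,end interval coordinates (0-based, half-open)
#' @param id optional identifiers; generated when missing
#' @param seq optional nucleotide strings, `NA` when absent
#' @param dup_count observed copies before deduplication (>= 1)
#' @param flags comma-joined status flags drawn from
#'   `redundant`, `solo`, `primer_trimmed`, `gap_filled`
#' @return a `data.frame` in canonical (chrom, start, end, id) order
#' @export
fragment_table <- function(chrom = character(), start = integer(), end = integer(),
                           id = NULL, seq = NA_character_, dup_count = 1L,
                           flags = "") {
  n <- length(start)
  if (is.null(id)) id <- if (n) sprintf("frag_%06d", seq_len(n)) else character()
  df <- data.frame(id = as.character(id), chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   seq = as.character(rep_len(seq, n)),
                   dup_count = as.integer(rep_len(dup_count, n)),
                   flags = as.character(rep_len(flags, n)),
                   stringsAsFactors = FALSE)
  as_fragment_table(df)
}

#' Validate and canonicalise a fragment table
#'
#' Checks the fragment invariants (positive length, sequence length equal to
#' the interval width when present, `dup_count >= 1`) and sorts rows by
#' (chrom, start, end, id). Missing optional columns are added with defaults;
#' extra columns are preserved.
#'
#' @param x a data.frame with at least `chrom`, `start`, `end`
#' @return validated fragment table
#' @export
as_fragment_table <- function(x) {
  if (!is.data.frame(x)) stop("fragments must be a data.frame")
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("fragment table missing column(s): ", paste(miss, collapse = ", "))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (is.null(x$id)) x$id <- if (nrow(x)) sprintf("frag_%06d", seq_len(nrow(x))) else character()
  if (is.null(x$seq)) x$seq <- NA_character_
  if (is.null(x$dup_count)) x$dup_count <- 1L
  if (is.null(x$flags)) x$flags <- ""
  x$chrom <- as.character(x$chrom); x$id <- as.character(x$id)
  x$start <- as.integer(x$start); x$end <- as.integer(x$end)
  x$seq <- as.character(x$seq); x$dup_count <- as.integer(x$dup_count)
  x$flags <- ifelse(is.na(x$flags), "", as.character(x$flags))
  if (nrow(x)) {
    if (any(x$start < 0) || any(x$end <= x$start))
      stop("fragment intervals must satisfy 0 <= start < end")
    if (any(x$dup_count < 1)) stop("dup_count must be >= 1")
    with_seq <- !is.na(x$seq)
    if (any(nchar(x$seq[with_seq]) != (x$end - x$start)[with_seq]))
      stop("fragment seq length must equal end - start")
    x <- x[order(x$chrom, x$start, x$end, x$id), , drop = FALSE]
    rownames(x) <- NULL
  }
  front <- c("id", "chrom", "start", "end", "seq", "dup_count", "flags")
  x[, c(front, setdiff(names(x), front)), drop = FALSE]
}

fragment_width <- function(fragments) fragments$end - fragments$start

#' Merge a mapped read pair into one fragment
#'
#' A proper pair defines a fragment spanning the outermost mapped
#' coordinates. When the reads overlap (short fragments, up to the combined
#' read length) the overlapping bases are merged; when the implied fragment
#' is longer than the combined read length the interior gap is filled from
#' the reference and the fragment is flagged `gap_filled`.
#'
#' @param read1,read2 lists (or one-row data.frames) with `chrom`, `start`,
#'   `end` (0-based half-open) and optionally `seq`
#' @param reference genome (named character or `DNAStringSet`); required to
#'   fill gaps, or to attach sequence when the reads carry none
#' @param merge_max_len fragment length at or below which reads are expected
#'   to overlap (default 150, the combined read length regime)
#' @param fragment_max_len maximum valid fragment length (default 1000)
#' @param id identifier for the resulting fragment
#' @return one-row fragment table
#' @export
merge_read_pair <- function(read1, read2, reference = NULL,
                            merge_max_len = 150L, fragment_max_len = 1000L,
                            id = "frag_000001") {
  r1 <- as.list(read1); r2 <- as.list(read2)
  for (r in list(r1, r2)) {
    if (is.null(r$chrom) || is.null(r$start) || is.null(r$end))
      stop("malformed read pair: reads need chrom, start, end")
    if (r$end <= r$start)
      stop("malformed read pair: negative or zero implied read length")
  }
  if (r1$chrom != r2$chrom)
    stop("pair inconsistency: reads map to different references (",
         r1$chrom, " vs ", r2$chrom, ")")
  if (r2$start < r1$start) { tmp <- r1; r1 <- r2; r2 <- tmp }
  start <- as.integer(r1$start); end <- as.integer(max(r1$end, r2$end))
  len <- end - start
  if (len <= 0) stop("malformed read pair: negative implied fragment length")
  if (len > fragment_max_len)
    stop("fragment length ", len, " exceeds maximum of ", fragment_max_len)
  seq1 <- r1$seq %||% NA_character_
  seq2 <- r2$seq %||% NA_character_
  gap <- r2$start > r1$end
  flags <- if (gap) "gap_filled" else ""
  seq <- NA_character_
  if (!is.na(seq1) && !is.na(seq2)) {
    if (gap) {
      if (is.null(reference))
        stop("reference required to fill the interior gap between reads")
      fill <- get_seq(reference, r1$chrom, r1$end, r2$start)
      seq <- paste0(seq1, fill, seq2)
    } else {
      # reads overlap or abut; keep read1 then the non-overlapping tail of read2
      tail2 <- if (r2$end > r1$end) substring(seq2, r1$end - r2$start + 1, nchar(seq2)) else ""
      seq <- paste0(seq1, tail2)
    }
    seq <- substring(seq, 1, len)   # r2 contained in r1
  } else if (!is.null(reference)) {
    seq <- get_seq(reference, r1$chrom, start, end)
  }
  fragment_table(chrom = r1$chrom, start = start, end = end, id = id,
                 seq = seq, flags = flags)
}

#' Collapse PCR duplicates by unique fragment index
#'
#' The unique fragment index (UFI) of a tagmentation product is its cut
#' coordinate pair `(chrom, start, end)`: a double-stranded fragment is fully
#' indexed by where the transpososomes cut. Rows sharing a UFI collapse to a
#' single record whose `dup_count` is the total number of observed copies.
#'
#' @param fragments fragment table (amplified library)
#' @return an object of class `dedup_result`: a list with `fragments`
#'   (deduplicated table), `total_in`, `total_unique` and
#'   `duplication_rate = total_in / total_unique` (`NA` for empty input)
#' @export
deduplicate_fragments <- function(fragments) {
  frs <- as_fragment_table(fragments)
  if (!nrow(frs)) {
    return(structure(list(fragments = frs, total_in = 0L, total_unique = 0L,
                          duplication_rate = NA_real_),
                     class = "dedup_result"))
  }
  key <- paste(frs$chrom, frs$start, frs$end)
  total_in <- sum(frs$dup_count)
  grp <- match(key, unique(key))
  first <- !duplicated(grp)
  out <- frs[first, , drop = FALSE]
  out$dup_count <- as.integer(tapply(frs$dup_count, grp, sum)[as.character(grp[first])])
  # keep a sequence if any group member carries one; union the flags
  if (anyNA(out$seq)) {
    seq_by_grp <- tapply(frs$seq, grp, function(s) {
      s <- s[!is.na(s)]; if (length(s)) s[[1]] else NA_character_
    })
    out$seq <- as.character(seq_by_grp[as.character(grp[first])])
  }
  flag_by_grp <- tapply(frs$flags, grp, function(f) {
    f <- unique(unlist(strsplit(f[nzchar(f)], ",", fixed = TRUE)))
    paste(f, collapse = ",")
  })
  out$flags <- as.character(flag_by_grp[as.character(grp[first])])
  out <- as_fragment_table(out)
  structure(list(fragments = out,
                 total_in = as.integer(total_in),
                 total_unique = nrow(out),
                 duplication_rate = total_in / nrow(out)),
            class = "dedup_result")
}

#' @export
print.dedup_result <- function(x, ...) {
  cat("PCR deduplication by unique fragment index\n")
  cat("  fragments in:     ", x$total_in, "\n")
  cat("  unique fragments: ", x$total_unique, "\n")
  cat("  duplication rate: ", format_rate1(x$duplication_rate), "\n")
  invisible(x)
}
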