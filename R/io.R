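# interval and alignment file IO

#' Read a fragment table from BED
#'
#' Dialect: tab-separated `chrom start end name dup_count strand flags`,
#' where columns 4-7 are optional; flags are comma-joined in column 7 and
#' column 6 (strand) is ignored (fragments are double-stranded). Input need
#' not be sorted; unsorted files are accepted and re-sorted with a notice.
#'
#' @param path BED file path
#' @return fragment table
#' @export
read_fragment_table <- function(path) {
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !grepl("^(#|track|browser)", lines))
  if (!length(keep)) return(fragment_table())
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  bad <- which(ncols < 3)
  if (length(bad))
    stop("malformed BED line ", keep[bad[1]], ": fewer than 3 columns")
  col <- function(i, default) vapply(fields, function(f)
    if (length(f) >= i && nzchar(f[i]) && f[i] != ".") f[i] else default, character(1))
  start <- suppressWarnings(as.integer(col(2, NA_character_)))
  end   <- suppressWarnings(as.integer(col(3, NA_character_)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", keep[bad[1]], ": non-numeric coordinates")
  chrom <- col(1, NA_character_)
  name <- col(4, NA_character_)
  if (anyNA(name)) name <- sprintf("frag_%06d", seq_along(chrom))
  dupc <- suppressWarnings(as.integer(col(5, "1")))
  bad <- which(is.na(dupc))
  if (length(bad))
    stop("malformed BED line ", keep[bad[1]], ": non-numeric dup_count")
  flags <- col(7, "")
  unsorted <- is.unsorted(order(chrom, start, end))
  out <- fragment_table(chrom = chrom, start = start, end = end, id = name,
                        dup_count = dupc, flags = flags)
  if (any(order(chrom, start, end, name) != seq_along(chrom)))
    message("input intervals were not sorted; re-sorted canonically")
  out
}

#' Write intervals as BED or BEDGRAPH
#'
#' `BED` expects a fragment-like table (`chrom,start,end` plus optional
#' `id`, `dup_count`/`score`, `flags`); `BEDGRAPH` expects a `value` (or
#' `copies`) column and writes 4 columns.
#'
#' @param records data.frame of intervals
#' @param path output path
#' @param format `"BED"` or `"BEDGRAPH"`
#' @return `path`, invisibly
#' @export
write_intervals <- function(records, path, format = c("BED", "BEDGRAPH")) {
  format <- match.arg(format)
  if (!nrow(records)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  if (format == "BED") {
    x <- as.data.frame(records, stringsAsFactors = FALSE)
    if (is.null(x$id)) x$id <- if (nrow(x)) sprintf("iv_%06d", seq_len(nrow(x))) else character()
    score <- x$dup_count %||% x$score %||% rep(1L, nrow(x))
    flags <- x$flags %||% rep("", nrow(x))
    out <- data.frame(x$chrom, x$start, x$end, x$id, score, ".",
                      ifelse(nzchar(flags), flags, "."),
                      stringsAsFactors = FALSE)
  } else {
    value <- records$value %||% records$copies
    if (is.null(value)) stop("BEDGRAPH output needs a `value` or `copies` column")
    out <- data.frame(records$chrom, records$start, records$end, value,
                      stringsAsFactors = FALSE)
  }
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# reference-space width of a CIGAR string (M/D/N/=/X consume reference)
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]", "", ops))
    op <- sub("\\d+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Convert mapped paired-end alignments into fragments
#'
#' Reads a coordinate- or name-sorted SAM/BAM file, pairs reads by query
#' name, and merges each proper pair into one fragment with
#' [merge_read_pair()]. Pairs that fail the pair checks (different
#' references, over-long or malformed fragments) are dropped and counted.
#'
#' @param path SAM or BAM file
#' @param reference optional genome for gap filling
#' @param merge_max_len,fragment_max_len,min_fragment_len see
#'   [merge_read_pair()]; fragments shorter than `min_fragment_len` are
#'   discarded
#' @return list with `fragments` (fragment table) and `dropped`
#'   (named counts of rejected pairs)
#' @export
read_alignments <- function(path, reference = NULL, merge_max_len = 150L,
                            fragment_max_len = 1000L, min_fragment_len = 25L) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    tmp <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = tmp, overwrite = TRUE,
                            indexDestination = FALSE)
  } else bam <- path
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    flag = Rsamtools::scanBamFlag(isPaired = TRUE, isUnmappedQuery = FALSE))
  aln <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(aln$qname)
  if (!n) return(list(fragments = fragment_table(), dropped = c(unpaired = 0L)))
  reads <- data.frame(qname = aln$qname, chrom = as.character(aln$rname),
                      start = aln$pos - 1L,
                      end = aln$pos - 1L + cigar_ref_width(aln$cigar),
                      seq = as.character(aln$seq), stringsAsFactors = FALSE)
  by_q <- split(seq_len(n), reads$qname)
  dropped <- c(unpaired = 0L, inconsistent = 0L, too_long = 0L, too_short = 0L)
  frags <- vector("list", length(by_q))
  for (i in seq_along(by_q)) {
    idx <- by_q[[i]]
    if (length(idx) != 2) { dropped["unpaired"] <- dropped["unpaired"] + 1L; next }
    fr <- tryCatch(
      merge_read_pair(reads[idx[1], ], reads[idx[2], ], reference = reference,
                      merge_max_len = merge_max_len,
                      fragment_max_len = fragment_max_len,
                      id = names(by_q)[i]),
      error = function(e) e)
    if (inherits(fr, "error")) {
      kind <- if (grepl("different references", conditionMessage(fr))) "inconsistent"
              else if (grepl("exceeds maximum", conditionMessage(fr))) "too_long"
              else "inconsistent"
      dropped[kind] <- dropped[kind] + 1L
      next
    }
    if (fr$end - fr$start < min_fragment_len) {
      dropped["too_short"] <- dropped["too_short"] + 1L
      next
    }
    frags[[i]] <- fr
  }
  frags <- frags[!vapply(frags, is.null, logical(1))]
  fragments <- if (length(frags)) as_fragment_table(do.call(rbind, frags))
               else fragment_table()
  list(fragments = fragments, dropped = dropped)
}
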