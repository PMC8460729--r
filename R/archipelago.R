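# clustering of fragments into archipelagos; coverage and GC statistics

#' Cluster fragments into archipelagos
#'
#' Mapped fragments from a sparse (~10% of genome) molecule pool sit in
#' dense clusters -- archipelagos -- separated by long blank stretches.
#' Consecutive fragments on a chromosome belong to the same archipelago iff
#' the uncovered gap between them is at most `gap_threshold` bases;
#' single-fragment clusters are flagged solo (candidate contamination) and
#' are excluded from phasing downstream.
#'
#' @param fragments deduplicated fragment table
#' @param gap_threshold maximum uncovered gap (bases) within an archipelago;
#'   the 1000-base default separates within-archipelago dropout gaps
#'   (hundreds of bases at ~80% coverage) from the kilobase-scale blanks
#'   between molecules, and matches the fragment-length cap of the mapper
#' @return data.frame with one row per archipelago: `id`, `chrom`, `start`,
#'   `end`, `n_fragments`, `covered_bases` (union, not depth),
#'   `coverage = covered_bases / span`, `is_solo`, and a `fragment_ids`
#'   list-column of members in canonical order
#' @export
call_archipelagos <- function(fragments, gap_threshold = 1000L) {
  if (!is.numeric(gap_threshold) || gap_threshold <= 0)
    stop("gap_threshold must be a positive number of bases")
  frs <- as_fragment_table(fragments)
  empty <- data.frame(id = character(), chrom = character(), start = integer(),
                      end = integer(), n_fragments = integer(),
                      covered_bases = integer(), coverage = numeric(),
                      is_solo = logical(), stringsAsFactors = FALSE)
  empty$fragment_ids <- list()
  if (!nrow(frs)) return(empty)
  rows <- list()
  for (ch in unique(frs$chrom)) {
    sub <- frs[frs$chrom == ch, , drop = FALSE]
    n <- nrow(sub)
    grp <- integer(n); grp[1] <- 1L
    run_end <- sub$end[1]
    if (n > 1) for (i in 2:n) {
      grp[i] <- grp[i - 1] + (sub$start[i] - run_end > gap_threshold)
      run_end <- max(run_end, sub$end[i])
    }
    for (gi in unique(grp)) {
      mem <- sub[grp == gi, , drop = FALSE]
      covered <- sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(start = mem$start + 1L, end = mem$end))))
      rows[[length(rows) + 1L]] <- list(
        chrom = ch, start = min(mem$start), end = max(mem$end),
        n_fragments = nrow(mem), covered_bases = covered,
        fragment_ids = mem$id)
    }
  }
  out <- data.frame(
    id = sprintf("arch_%04d", seq_along(rows)),
    chrom = vapply(rows, `[[`, "", "chrom"),
    start = vapply(rows, function(x) as.integer(x$start), 1L),
    end = vapply(rows, function(x) as.integer(x$end), 1L),
    n_fragments = vapply(rows, function(x) as.integer(x$n_fragments), 1L),
    covered_bases = vapply(rows, function(x) as.integer(x$covered_bases), 1L),
    stringsAsFactors = FALSE)
  out$coverage <- out$covered_bases / (out$end - out$start)
  out$is_solo <- out$n_fragments == 1L
  out$fragment_ids <- lapply(rows, `[[`, "fragment_ids")
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  out$id <- sprintf("arch_%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Summary statistics over archipelagos
#'
#' Reports the archipelago census (count, size median and range, median
#' per-archipelago coverage, percent of the genome covered by fragments,
#' solo-fragment fraction) and four base-weighted GC means used to judge
#' library bias: archipelago spans vs blank regions outside them, and
#' fragment-covered vs uncovered bases within archipelagos. An unbiased
#' library shows indistinguishable pairs.
#'
#' @param archipelagos output of [call_archipelagos()]
#' @param fragments the deduplicated fragment table the archipelagos were
#'   called from
#' @param genome reference genome (named character or `DNAStringSet`);
#'   `NULL` skips the GC section
#' @return a list of summary fields (class `archipelago_stats`)
#' @export
archipelago_stats <- function(archipelagos, fragments, genome = NULL) {
  frs <- as_fragment_table(fragments)
  arch <- archipelagos
  gsize <- if (!is.null(genome)) genome_size(genome) else NA_integer_
  covered_by_frag <- if (nrow(frs)) {
    by_ch <- split(seq_len(nrow(frs)), frs$chrom)
    lapply(by_ch, function(ii) IRanges::reduce(
      IRanges::IRanges(frs$start[ii] + 1L, frs$end[ii])))
  } else list()
  frag_union <- sum(vapply(covered_by_frag, function(x) sum(IRanges::width(x)), 1))
  out <- list(
    n_archipelagos = nrow(arch),
    size_median = if (nrow(arch)) median(arch$end - arch$start) else NA_real_,
    size_range = if (nrow(arch)) range(arch$end - arch$start) else c(NA_real_, NA_real_),
    coverage_median = if (nrow(arch)) median(arch$coverage) else NA_real_,
    pct_genome_covered = if (!is.na(gsize)) 100 * frag_union / gsize else NA_real_,
    solo_fraction = if (nrow(frs)) sum(arch$n_fragments[arch$is_solo]) / nrow(frs)
                    else NA_real_)
  if (!is.null(genome) && nrow(arch)) {
    g <- as_genome_chars(genome)
    # archipelago spans vs the blank complement
    gc_arch <- gc_of_intervals(g, arch$chrom, arch$start, arch$end)
    blank <- do.call(rbind, lapply(names(g), function(ch) {
      a <- arch[arch$chrom == ch, , drop = FALSE]
      gaps <- IRanges::gaps(IRanges::reduce(IRanges::IRanges(a$start + 1L, a$end)),
                            start = 1L, end = nchar(g[[ch]]))
      if (!length(gaps)) return(NULL)
      data.frame(chrom = ch, start = IRanges::start(gaps) - 1L,
                 end = IRanges::end(gaps), stringsAsFactors = FALSE)
    }))
    gc_blank <- gc_of_intervals(g, blank$chrom, blank$start, blank$end)
    # fragment-covered vs uncovered bases within archipelago spans
    cov_df <- do.call(rbind, lapply(names(covered_by_frag), function(ch)
      data.frame(chrom = ch, start = IRanges::start(covered_by_frag[[ch]]) - 1L,
                 end = IRanges::end(covered_by_frag[[ch]]),
                 stringsAsFactors = FALSE)))
    gc_cov <- gc_of_intervals(g, cov_df$chrom, cov_df$start, cov_df$end)
    uncov <- do.call(rbind, lapply(names(g), function(ch) {
      a <- arch[arch$chrom == ch, , drop = FALSE]
      if (!nrow(a)) return(NULL)
      spans <- IRanges::reduce(IRanges::IRanges(a$start + 1L, a$end))
      covr <- covered_by_frag[[ch]] %||% IRanges::IRanges()
      un <- IRanges::setdiff(spans, covr)
      if (!length(un)) return(NULL)
      data.frame(chrom = ch, start = IRanges::start(un) - 1L,
                 end = IRanges::end(un), stringsAsFactors = FALSE)
    }))
    gc_uncov <- if (!is.null(uncov) && nrow(uncov))
      gc_of_intervals(g, uncov$chrom, uncov$start, uncov$end) else NA_real_
    out$gc <- c(archipelagos = gc_arch, blank = gc_blank,
                covered_within = gc_cov, uncovered_within = gc_uncov)
  }
  structure(out, class = "archipelago_stats")
}

#' @export
print.archipelago_stats <- function(x, ...) {
  cat("Archipelago summary\n")
  cat("  archipelagos:        ", x$n_archipelagos, "\n")
  cat("  span median (range): ", x$size_median, " (",
      x$size_range[1], "-", x$size_range[2], ")\n", sep = "")
  cat("  coverage median:     ", format_rate1(100 * x$coverage_median), "%\n", sep = "")
  cat("  genome covered:      ", format_rate1(x$pct_genome_covered), "%\n", sep = "")
  cat("  solo fraction:       ", format_rate1(100 * x$solo_fraction), "%\n", sep = "")
  if (!is.null(x$gc)) {
    cat("  GC means: archipelagos ", format_rate1(100 * x$gc[["archipelagos"]]),
        "%, blank ", format_rate1(100 * x$gc[["blank"]]),
        "%, covered ", format_rate1(100 * x$gc[["covered_within"]]),
        "%, uncovered ", format_rate1(100 * x$gc[["uncovered_within"]]), "%\n",
        sep = "")
  }
  invisible(x)
}
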