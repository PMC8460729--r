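# end-to-end reconstruction: dedup -> repair -> archipelagos -> junctions ->
# artifact filter -> islands -> phasing -> copy number

#' Reconstruct haploid molecules from a fragment library
#'
#' Runs the full secondary-analysis chain on a (possibly amplified)
#' fragment table: PCR deduplication by unique fragment index, primer
#' remnant repair, archipelago clustering, junction detection, defective
#' transpososome artifact filtering, island chaining, greedy phasing under
#' exclusivity, and integer copy-number profiling. Solo archipelagos
#' (single fragments flanked by blank genome) are reported but excluded
#' from phasing, as candidate cross-contamination.
#'
#' @param fragments fragment table (e.g. from [read_fragment_table()],
#'   [read_alignments()] or [simulate_library()])
#' @param reference optional genome; enables primer repair, strict junction
#'   sequence checks, GC statistics and genome-coverage percentages
#' @param gap_threshold archipelago clustering gap (bases)
#' @param k_set allowed junction duplication lengths
#' @param artifact_filter remove shared-end artifact fragments before
#'   phasing
#' @param trim_primers repair 3-base primer remnants (needs `reference` and
#'   fragment sequences)
#' @param min_fragment_len minimum retained fragment length
#' @param solo_max_len fragments shorter than this that participate in no
#'   junction and share no end with another fragment are flagged `solo`
#'   (candidate cross-contamination) and excluded from phasing; 200 bases
#'   reflects the observed size ceiling of contamination fragments
#' @param strict require sequence identity across junction overlaps where
#'   sequence is available
#' @return an object of class `molecule_set`; see Details
#' @details The returned list carries `fragments` (deduplicated, flagged),
#'   `dedup` (totals and duplication rate), `repair_log`, `archipelagos`,
#'   `junctions`, `groups` (classified shared-end groups), `redundant`,
#'   `islands`, `molecules` (one row per molecule with its archipelago and
#'   1-based rank), `copy_number`, and `params`.
#' @export
reconstruct_molecules <- function(fragments, reference = NULL,
                                  gap_threshold = 1000L,
                                  k_set = c(8L, 9L, 10L),
                                  artifact_filter = TRUE,
                                  trim_primers = !is.null(reference),
                                  min_fragment_len = 25L,
                                  solo_max_len = 200L,
                                  strict = TRUE) {
  k_set <- check_k_set(k_set)
  dd <- deduplicate_fragments(fragments)
  frs <- dd$fragments
  frs <- frs[(frs$end - frs$start) >= min_fragment_len, , drop = FALSE]
  repair_log <- NULL
  if (trim_primers && !is.null(reference) && nrow(frs)) {
    tp <- trim_primer_remnants(frs, reference, k_set = k_set,
                               min_fragment_len = min_fragment_len)
    repair_log <- tp$repair_log
    if (any(tp$repair_log$applied))   # repairs can re-create UFI duplicates
      frs <- deduplicate_fragments(tp$fragments)$fragments
    else frs <- tp$fragments
  }
  arch <- call_archipelagos(frs, gap_threshold)
  junctions <- find_junctions(frs, k_set, reference = reference, strict = strict)
  if (artifact_filter && nrow(frs)) {
    groups <- classify_scenarios(group_shared_ends(frs))
    mr <- mark_redundant(frs, groups)
    retained <- mr$retained; redundant <- mr$redundant
  } else {
    groups <- classify_scenarios(group_shared_ends(fragment_table()))
    retained <- frs; redundant <- frs[0, , drop = FALSE]
  }
  # fragments in singleton archipelagos are candidate cross-contamination,
  # excluded from phasing but reported; further solo calls are made after
  # chaining, below
  solo_ids <- unlist(arch$fragment_ids[arch$is_solo], use.names = FALSE)
  grouped_ids <- unlist(groups$member_ids, use.names = FALSE)
  molecules <- list(); islands_all <- list()
  for (i in seq_len(nrow(arch))) {
    if (arch$is_solo[i]) next
    mem <- retained[retained$id %in% arch$fragment_ids[[i]], , drop = FALSE]
    if (!nrow(mem)) next
    jn <- junctions[junctions$up_id %in% mem$id & junctions$down_id %in% mem$id, ,
                    drop = FALSE]
    ch <- chain_islands(mem, jn)
    # contamination-like fragments: unchained after matching, shorter than
    # solo_max_len, sharing no end with another fragment -- excluded from
    # phasing but reported (a chained fragment is never a solo)
    loose <- ch$loose
    lonely <- (loose$end - loose$start) < solo_max_len &
      !(loose$id %in% grouped_ids)
    solo_ids <- union(solo_ids, loose$id[lonely])
    ph <- phase_archipelago(ch$islands, loose[!lonely, , drop = FALSE], k_set)
    if (nrow(ch$islands)) {
      isl <- ch$islands
      isl$archipelago <- arch$id[i]
      islands_all[[length(islands_all) + 1L]] <- isl
    }
    if (nrow(ph)) {
      ph$archipelago <- arch$id[i]
      molecules[[length(molecules) + 1L]] <- ph
    }
  }
  frs$flags[frs$id %in% solo_ids] <- add_flag(frs$flags[frs$id %in% solo_ids], "solo")
  mol0 <- data.frame(molecule = integer(), chrom = character(),
                     start = integer(), end = integer(),
                     n_elements = integer(), stringsAsFactors = FALSE)
  mol0$element_ids <- list(); mol0$archipelago <- character()
  molecules <- do.call(rbind, c(molecules, list(mol0)))
  isl0 <- data.frame(id = character(), chrom = character(), start = integer(),
                     end = integer(), n_fragments = integer(),
                     stringsAsFactors = FALSE)
  isl0$fragment_ids <- list(); isl0$junction_ks <- list()
  isl0$archipelago <- character()
  islands <- do.call(rbind, c(islands_all, list(isl0)))
  cn <- copy_number_profile(molecules)
  structure(list(fragments = frs, dedup = dd, repair_log = repair_log,
                 archipelagos = arch, junctions = junctions, groups = groups,
                 redundant = redundant, islands = islands,
                 molecules = molecules, copy_number = cn,
                 params = list(gap_threshold = gap_threshold, k_set = k_set,
                               artifact_filter = artifact_filter,
                               trim_primers = trim_primers,
                               min_fragment_len = min_fragment_len,
                               solo_max_len = solo_max_len,
                               strict = strict),
                 genome_size = if (!is.null(reference)) genome_size(reference)
                               else NA_real_),
            class = "molecule_set")
}

#' Per-sample summary of a reconstruction
#'
#' Produces the per-sample sequencing-statistics record: total fragments
#' before deduplication, unique fragments, average duplication rate, mean
#' fragment length, and percent of the genome covered by fragments (when
#' the genome size is known), together with the reconstruction census.
#'
#' @param object a `molecule_set`
#' @param ... unused
#' @return a one-row data.frame (class `summary.molecule_set`)
#' @export
summary.molecule_set <- function(object, ...) {
  frs <- object$fragments
  covered <- if (nrow(frs)) {
    by_ch <- split(seq_len(nrow(frs)), frs$chrom)
    sum(vapply(by_ch, function(ii) sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(frs$start[ii] + 1L, frs$end[ii])))), 1))
  } else 0
  out <- data.frame(
    total_fragments = object$dedup$total_in,
    unique_fragments = object$dedup$total_unique,
    duplication_rate = format_rate1(object$dedup$duplication_rate),
    mean_fragment_length = format_rate1(if (nrow(frs)) mean(frs$end - frs$start)
                                        else NA_real_),
    pct_genome_covered = format_rate1(100 * covered / object$genome_size),
    n_archipelagos = nrow(object$archipelagos),
    n_solo = sum(object$archipelagos$is_solo),
    n_junctions = nrow(object$junctions),
    n_redundant = nrow(object$redundant),
    n_islands = nrow(object$islands),
    n_molecules = nrow(object$molecules),
    stringsAsFactors = FALSE)
  class(out) <- c("summary.molecule_set", class(out))
  out
}

#' @export
print.molecule_set <- function(x, ...) {
  cat("Molecule reconstruction from tagmentation fragments\n")
  cat("  fragments: ", x$dedup$total_in, " observed, ", x$dedup$total_unique,
      " unique (duplication rate ", format_rate1(x$dedup$duplication_rate),
      ")\n", sep = "")
  tb <- table(factor(x$junctions$k, levels = c(8, 9, 10)))
  cat("  junctions: ", nrow(x$junctions), " (k=8: ", tb[["8"]],
      ", k=9: ", tb[["9"]], ", k=10: ", tb[["10"]], ")\n", sep = "")
  cat("  archipelagos: ", nrow(x$archipelagos), " (",
      sum(x$archipelagos$is_solo), " solo)\n", sep = "")
  cat("  redundant artifact fragments: ", nrow(x$redundant), "\n", sep = "")
  cat("  islands: ", nrow(x$islands), "; molecules: ", nrow(x$molecules),
      "\n", sep = "")
  invisible(x)
}

# per-archipelago JSON-able report
molecule_set_report <- function(ms) {
  arch <- ms$archipelagos
  per_arch <- lapply(seq_len(nrow(arch)), function(i) {
    aid <- arch$id[i]
    mem <- arch$fragment_ids[[i]]
    jn <- ms$junctions[ms$junctions$up_id %in% mem, , drop = FALSE]
    list(id = aid, chrom = arch$chrom[i], start = arch$start[i],
         end = arch$end[i], n_fragments = arch$n_fragments[i],
         coverage = round(arch$coverage[i], 4), is_solo = arch$is_solo[i],
         n_islands = sum(ms$islands$archipelago == aid),
         junction_k = as.list(table(factor(jn$k, levels = c(8, 9, 10)))),
         n_redundant = sum(ms$redundant$id %in% mem),
         n_molecules = sum(ms$molecules$archipelago == aid))
  })
  list(summary = as.list(summary(ms)), archipelagos = per_arch)
}
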