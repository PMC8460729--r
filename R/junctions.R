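# junction detection, primer-remnant repair, cut-site base profiles

JUNCTION_K <- 8:10

empty_junctions <- function() {
  data.frame(up_id = character(), down_id = character(), chrom = character(),
             overlap_start = integer(), overlap_end = integer(), k = integer(),
             stringsAsFactors = FALSE)
}

check_k_set <- function(k_set) {
  k_set <- as.integer(k_set)
  if (!length(k_set) || !all(k_set %in% JUNCTION_K))
    stop("k_set must be a subset of {8, 9, 10} (transpososome duplication lengths)")
  sort(unique(k_set))
}

#' Detect k-base junctions between fragments
#'
#' Two fragments cut from one molecule by adjacent transpososomes share a
#' duplicated overlap of k bases (canonically 9, uncanonically 8 or 10):
#' the downstream fragment starts exactly `k` bases before the upstream
#' fragment ends. Every ordered pair satisfying the coordinate test for some
#' `k` in `k_set` is emitted; when both fragments carry sequence
#' (`strict = TRUE`) a single mismatch in the overlapping bases voids the
#' junction. Multiple candidates per fragment end are all emitted and
#' resolved later during chaining.
#'
#' @param fragments deduplicated, canonically sorted fragment table
#' @param k_set allowed duplication lengths, subset of `{8, 9, 10}`
#' @param reference optional genome used for the sequence test when one or
#'   both fragment sequences are absent
#' @param strict apply the sequence-identity test where sequence is
#'   available (coordinate equality alone suffices when it is not)
#' @return data.frame with `up_id`, `down_id`, `chrom`, `overlap_start`,
#'   `overlap_end`, `k`
#' @export
find_junctions <- function(fragments, k_set = c(8L, 9L, 10L), reference = NULL,
                           strict = TRUE) {
  k_set <- check_k_set(k_set)
  frs <- as_fragment_table(fragments)
  if (nrow(frs) < 2) return(empty_junctions())
  down_lookup <- split(seq_len(nrow(frs)), paste(frs$chrom, frs$start))
  out <- vector("list", length(k_set))
  for (kk in seq_along(k_set)) {
    k <- k_set[kk]
    key <- paste(frs$chrom, frs$end - k)
    hit <- key %in% names(down_lookup)
    ups <- which(hit)
    if (!length(ups)) { out[[kk]] <- empty_junctions(); next }
    downs_per_up <- down_lookup[key[ups]]
    ui <- rep(ups, lengths(downs_per_up))
    di <- unlist(downs_per_up, use.names = FALSE)
    keep <- ui != di & frs$end[di] > frs$end[ui]  # downstream extends past up
    ui <- ui[keep]; di <- di[keep]
    if (strict && length(ui)) {
      ok <- vapply(seq_along(ui), function(i) {
        u <- ui[i]; d <- di[i]
        up_seq <- frs$seq[u]; dn_seq <- frs$seq[d]
        up_ov <- if (!is.na(up_seq))
          substring(up_seq, frs$end[u] - frs$start[u] - k + 1) else NA_character_
        dn_ov <- if (!is.na(dn_seq)) substring(dn_seq, 1, k) else NA_character_
        ref_ov <- if (!is.null(reference))
          get_seq(reference, frs$chrom[u], frs$start[d], frs$end[u]) else NA_character_
        obs <- c(up_ov, dn_ov, ref_ov)
        obs <- obs[!is.na(obs)]
        length(obs) < 2 || all(obs == obs[[1]])
      }, logical(1))
      ui <- ui[ok]; di <- di[ok]
    }
    out[[kk]] <- data.frame(up_id = frs$id[ui], down_id = frs$id[di],
                            chrom = frs$chrom[ui],
                            overlap_start = frs$start[di],
                            overlap_end = frs$start[di] + k,
                            k = rep(k, length(ui)), stringsAsFactors = FALSE)
  }
  jn <- do.call(rbind, out)
  jn <- jn[order(jn$chrom, jn$overlap_start, jn$k, jn$up_id, jn$down_id), , drop = FALSE]
  rownames(jn) <- NULL
  jn
}

#' Repair 3-base primer remnants that mask junctions
#'
#' PCR primers ending in `...CAG` can leave up to 3 residual bases on a
#' fragment end: `CAG` at a downstream fragment's 5' end, or the reverse
#' complement `CTG` at an upstream fragment's 3' end. Such a remnant widens
#' the observed overlap (e.g. 12 bases of which only 9 truly overlap) and
#' hides the junction. A terminal subsequence of 1-3 bases is trimmed when
#' (i) it matches the corresponding end of a primer tail (tried
#' longest-first), (ii) it mismatches the reference at those positions, and
#' (iii) its removal restores a junction with `k` in `k_set` against a
#' neighbouring fragment. Fragments already carrying a valid junction at
#' that end, and repairs that would drop a fragment below
#' `min_fragment_len`, are left untouched.
#'
#' @param fragments fragment table with sequences
#' @param reference genome (required: remnants are recognised by reference
#'   mismatch)
#' @param k_set allowed duplication lengths
#' @param primer_tails named character vector with entries `five_prime`
#'   (default `"CAG"`) and `three_prime` (default `"CTG"`)
#' @param min_fragment_len repairs reducing a fragment below this length
#'   are refused (and logged)
#' @return list with `fragments` (repaired table, `primer_trimmed` flag set)
#'   and `repair_log` (one row per attempted repair: `id`, `end`, `n_bases`,
#'   `applied`, `reason`)
#' @export
trim_primer_remnants <- function(fragments, reference,
                                 k_set = c(8L, 9L, 10L),
                                 primer_tails = c(five_prime = "CAG",
                                                  three_prime = "CTG"),
                                 min_fragment_len = 25L) {
  k_set <- check_k_set(k_set)
  frs <- as_fragment_table(fragments)
  log <- list()
  note <- function(id, end, t, applied, reason) {
    log[[length(log) + 1L]] <<- data.frame(id = id, end = end, n_bases = t,
                                           applied = applied, reason = reason,
                                           stringsAsFactors = FALSE)
  }
  if (!nrow(frs))
    return(list(fragments = frs, repair_log = do.call(rbind, c(log, list(
      data.frame(id = character(), end = character(), n_bases = integer(),
                 applied = logical(), reason = character()))))))
  tail5 <- primer_tails[["five_prime"]]; tail3 <- primer_tails[["three_prime"]]
  g <- as_genome_chars(reference)
  glens <- nchar(g)
  for (r in which(!is.na(frs$seq))) {
    ch <- frs$chrom[r]
    same <- which(frs$chrom == ch)
    # ---- 5' end: leading bases are the last t bases of the forward primer
    if (!any(frs$end[same] %in% (frs$start[r] + k_set))) {  # no junction here yet
      w <- frs$end[r] - frs$start[r]
      for (t in 3:1) {
        lead <- substring(frs$seq[r], 1, t)
        if (lead != substring(tail5, nchar(tail5) - t + 1)) next
        refb <- get_seq(g, ch, frs$start[r], frs$start[r] + t)
        if (lead == refb) { note(frs$id[r], "five_prime", t, FALSE, "matches reference"); break }
        partner <- any(frs$end[same] %in% (frs$start[r] + t + k_set))
        if (!partner) { note(frs$id[r], "five_prime", t, FALSE, "no junction created"); next }
        if (w - t < min_fragment_len) {
          note(frs$id[r], "five_prime", t, FALSE, "below min_fragment_len"); break
        }
        frs$start[r] <- frs$start[r] + t
        frs$seq[r] <- substring(frs$seq[r], t + 1)
        frs$flags[r] <- add_flag(frs$flags[r], "primer_trimmed")
        note(frs$id[r], "five_prime", t, TRUE, "junction restored")
        break
      }
    }
    # ---- 3' end: trailing bases are the reverse complement, prefix of CTG
    if (!any(frs$start[same] %in% (frs$end[r] - k_set))) {
      w <- frs$end[r] - frs$start[r]
      for (t in 3:1) {
        trail <- substring(frs$seq[r], w - t + 1, w)
        if (trail != substring(tail3, 1, t)) next
        refb <- get_seq(g, ch, frs$end[r] - t, frs$end[r])
        if (trail == refb) { note(frs$id[r], "three_prime", t, FALSE, "matches reference"); break }
        partner <- any(frs$start[same] %in% ((frs$end[r] - t) - k_set))
        if (!partner) { note(frs$id[r], "three_prime", t, FALSE, "no junction created"); next }
        if (w - t < min_fragment_len) {
          note(frs$id[r], "three_prime", t, FALSE, "below min_fragment_len"); break
        }
        frs$end[r] <- frs$end[r] - t
        frs$seq[r] <- substring(frs$seq[r], 1, w - t)
        frs$flags[r] <- add_flag(frs$flags[r], "primer_trimmed")
        note(frs$id[r], "three_prime", t, TRUE, "junction restored")
        break
      }
    }
  }
  empty_log <- data.frame(id = character(), end = character(),
                          n_bases = integer(), applied = logical(),
                          reason = character(), stringsAsFactors = FALSE)
  list(fragments = as_fragment_table(frs),
       repair_log = do.call(rbind, c(log, list(empty_log))))
}

#' Base-composition profile around transpososome cut sites
#'
#' For each junction, extracts the top-strand bases at the six positions
#' flanking the cut: `-2`, `-1` (immediately outside the cut) and
#' `Dup1`-`Dup4` (the first four duplicated bases inside the overlap), and
#' accumulates base counts separately per duplication length. The result is
#' a position-frequency matrix suitable for logo rendering.
#'
#' @param junctions junction table from [find_junctions()]
#' @param genome reference genome
#' @param k_set duplication classes to profile (zero-count matrices are
#'   returned for classes without junctions)
#' @return named list (one element per `k`) of 4 x 6 count matrices with
#'   rows `A,C,G,T` and columns `-2,-1,Dup1..Dup4`
#' @export
cut_site_profile <- function(junctions, genome, k_set = c(8L, 9L, 10L)) {
  k_set <- check_k_set(k_set)
  pos_labels <- c("-2", "-1", "Dup1", "Dup2", "Dup3", "Dup4")
  empty <- matrix(0L, nrow = 4, ncol = 6,
                  dimnames = list(c("A", "C", "G", "T"), pos_labels))
  out <- setNames(rep(list(empty), length(k_set)), as.character(k_set))
  if (!nrow(junctions)) return(out)
  skip <- junctions$overlap_start < 2
  if (any(skip))
    message(sum(skip), " junction(s) within 2 bases of a chromosome start skipped")
  jn <- junctions[!skip & junctions$k %in% k_set, , drop = FALSE]
  if (!nrow(jn)) return(out)
  ctx <- get_seq(genome, jn$chrom, jn$overlap_start - 2L, jn$overlap_start + 4L)
  for (k in intersect(k_set, unique(jn$k))) {
    m <- empty
    for (p in 1:6) {
      b <- substring(ctx[jn$k == k], p, p)
      tb <- table(factor(b, levels = rownames(m)))
      m[, p] <- as.integer(tb)
    }
    out[[as.character(k)]] <- m
  }
  out
}
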