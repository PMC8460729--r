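# island chaining, greedy molecule phasing, integer copy-number tracks

#' Chain junction-linked fragments into islands
#'
#' Starting from the 5'-most fragment and scanning 3'-wards, fragments
#' linked pairwise by junctions are joined into maximal contiguous chains
#' ("islands"). Each fragment takes at most one upstream and one downstream
#' link; when one fragment end has several junction candidates the longest
#' candidate is chained (ties broken by id) and the loser seeds a competing
#' island. Fragments with no link remain loose.
#'
#' @param fragments retained (non-redundant) fragment table
#' @param junctions junction table from [find_junctions()] restricted to
#'   these fragments
#' @return list with `islands` (data.frame: `id`, `chrom`, `start`, `end`,
#'   `n_fragments`, plus `fragment_ids` and `junction_ks` list-columns in
#'   5'->3' order) and `loose` (fragment table of unchained fragments)
#' @export
chain_islands <- function(fragments, junctions) {
  frs <- as_fragment_table(fragments)
  empty_isl <- data.frame(id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          n_fragments = integer(), stringsAsFactors = FALSE)
  empty_isl$fragment_ids <- list(); empty_isl$junction_ks <- list()
  if (!nrow(frs) || !nrow(junctions))
    return(list(islands = empty_isl, loose = frs))
  unknown <- setdiff(unique(c(junctions$up_id, junctions$down_id)), frs$id)
  if (length(unknown))
    stop("junction references unknown fragment id(s): ",
         paste(head(unknown, 5), collapse = ", "))
  width <- setNames(frs$end - frs$start, frs$id)
  # candidate downstream partners per fragment: canonical 9-base junctions
  # are preferred over uncanonical ones (they outnumber them ~8:1, so an
  # uncanonical candidate competing with a canonical one is most likely a
  # coincidence), then the longest candidate, then id
  by_up <- split(seq_len(nrow(junctions)), junctions$up_id)
  by_up <- lapply(by_up, function(ix) {
    dn <- junctions$down_id[ix]
    ix[order(junctions$k[ix] != 9L, -width[dn], dn)]
  })
  # one up link and one down link per fragment: a bipartite matching.
  # Augmenting-path assignment maximises the number of chained junctions,
  # so a coincidental inter-molecule candidate cannot steal a downstream
  # fragment from its true upstream partner; genuinely ambiguous ends keep
  # the longest-first preference.
  env <- new.env(parent = emptyenv())
  env$up_of_down <- setNames(rep(NA_character_, nrow(frs)), frs$id)
  env$pick_of_up <- setNames(rep(NA_integer_, nrow(frs)), frs$id)
  try_assign <- function(u) {
    for (ji in by_up[[u]]) {
      d <- junctions$down_id[ji]
      if (d %in% env$visited) next
      env$visited <- c(env$visited, d)
      owner <- env$up_of_down[[d]]
      if (is.na(owner) || try_assign(owner)) {
        env$up_of_down[[d]] <- u
        env$pick_of_up[[u]] <- ji
        return(TRUE)
      }
    }
    FALSE
  }
  for (fid in intersect(frs$id, names(by_up))) {  # canonical 5'->3' scan order
    env$visited <- character()
    try_assign(fid)
  }
  next_of <- setNames(rep(NA_character_, nrow(frs)), frs$id)
  prev_of <- next_of
  k_of <- setNames(rep(NA_integer_, nrow(frs)), frs$id)
  linked <- !is.na(env$pick_of_up)
  for (u in names(env$pick_of_up)[linked]) {
    ji <- env$pick_of_up[[u]]
    d <- junctions$down_id[ji]
    next_of[u] <- d
    prev_of[d] <- u
    k_of[d] <- junctions$k[ji]
  }
  heads <- frs$id[is.na(prev_of[frs$id]) & !is.na(next_of[frs$id])]
  islands <- vector("list", length(heads))
  for (i in seq_along(heads)) {
    chain <- heads[i]
    while (!is.na(next_of[[chain[length(chain)]]]))
      chain <- c(chain, next_of[[chain[length(chain)]]])
    idx <- match(chain, frs$id)
    islands[[i]] <- list(chrom = frs$chrom[idx[1]],
                         start = min(frs$start[idx]), end = max(frs$end[idx]),
                         fragment_ids = chain,
                         junction_ks = unname(k_of[chain[-1]]))
  }
  isl <- data.frame(
    id = sprintf("isl_%04d", seq_along(islands)),
    chrom = vapply(islands, `[[`, "", "chrom"),
    start = vapply(islands, function(x) as.integer(x$start), 1L),
    end = vapply(islands, function(x) as.integer(x$end), 1L),
    n_fragments = vapply(islands, function(x) length(x$fragment_ids), 1L),
    stringsAsFactors = FALSE)
  isl$fragment_ids <- lapply(islands, `[[`, "fragment_ids")
  isl$junction_ks <- lapply(islands, `[[`, "junction_ks")
  if (nrow(isl)) {
    ord <- order(isl$chrom, isl$start, isl$end)
    isl <- isl[ord, , drop = FALSE]
    isl$id <- sprintf("isl_%04d", seq_len(nrow(isl)))
    rownames(isl) <- NULL
  }
  chained <- unlist(isl$fragment_ids, use.names = FALSE)
  list(islands = isl, loose = frs[!frs$id %in% chained, , drop = FALSE])
}

# conflict rule shared by the greedy phaser and the brute-force oracle:
# two elements conflict iff they overlap and the overlap is not a k-base
# junction-style abutment (which means they share a junction)
elements_conflict <- function(s1, e1, s2, e2, k_set = c(8L, 9L, 10L)) {
  ov <- min(e1, e2) - max(s1, s2)
  if (ov <= 0) return(FALSE)
  if (s1 <= s2 && e2 >= e1 && (e1 - s2) %in% k_set) return(FALSE)
  if (s2 <= s1 && e1 >= e2 && (e2 - s1) %in% k_set) return(FALSE)
  TRUE
}

# normalise islands + loose fragments into one element table
phase_elements <- function(islands, loose_fragments) {
  isl <- if (!is.null(islands) && nrow(islands))
    data.frame(id = islands$id, chrom = islands$chrom, start = islands$start,
               end = islands$end, type = "island", stringsAsFactors = FALSE)
  else NULL
  lo <- if (!is.null(loose_fragments) && nrow(loose_fragments))
    data.frame(id = loose_fragments$id, chrom = loose_fragments$chrom,
               start = loose_fragments$start, end = loose_fragments$end,
               type = "fragment", stringsAsFactors = FALSE)
  else NULL
  el <- rbind(isl, lo)
  if (is.null(el))
    el <- data.frame(id = character(), chrom = character(), start = integer(),
                     end = integer(), type = character(), stringsAsFactors = FALSE)
  # islands anchor molecule structure: at equal start they are placed first
  el[order(el$start, el$type == "fragment", -(el$end - el$start), el$id), ,
     drop = FALSE]
}

#' Assign islands and loose fragments to molecules
#'
#' Implements the exclusivity and greediness rules: any element belongs to
#' exactly one molecule; two overlapping elements must belong to separate
#' molecules unless they share a junction (a k-base abutment); and elements
#' are packed into the lowest-numbered molecule that admits them, opening a
#' new molecule only when none does. Elements are scanned by
#' (start, islands-before-loose-fragments, decreasing length, id), which
#' makes the greedy assignment deterministic.
#'
#' @param islands island table from [chain_islands()] (may be empty)
#' @param loose_fragments fragment table of unchained fragments
#' @param k_set duplication lengths treated as junction abutments
#' @return data.frame with one row per molecule: `molecule` (1-based rank),
#'   `chrom`, `start`, `end`, `n_elements` and an `element_ids` list-column
#' @export
phase_archipelago <- function(islands, loose_fragments, k_set = c(8L, 9L, 10L)) {
  el <- phase_elements(islands, loose_fragments)
  mol_of <- integer(nrow(el))
  members <- list()
  for (i in seq_len(nrow(el))) {
    placed <- FALSE
    for (m in seq_along(members)) {
      ok <- all(!vapply(members[[m]], function(j)
        elements_conflict(el$start[i], el$end[i], el$start[j], el$end[j], k_set),
        logical(1)))
      if (ok) { members[[m]] <- c(members[[m]], i); mol_of[i] <- m; placed <- TRUE; break }
    }
    if (!placed) { members[[length(members) + 1L]] <- i; mol_of[i] <- length(members) }
  }
  out <- data.frame(molecule = seq_along(members),
                    chrom = vapply(members, function(ii) el$chrom[ii[1]], ""),
                    start = vapply(members, function(ii) min(el$start[ii]), 1L),
                    end = vapply(members, function(ii) max(el$end[ii]), 1L),
                    n_elements = lengths(members), stringsAsFactors = FALSE)
  out$element_ids <- lapply(members, function(ii) el$id[ii])
  out
}

#' Integer copy-number track from molecule spans
#'
#' The copy number at every base is the number of reconstructed molecule
#' spans covering it. The track is emitted as maximal constant-copy
#' intervals partitioning the region between the outermost molecule
#' boundaries on each chromosome (interior zero-copy stretches included).
#'
#' @param molecules data.frame with `chrom`, `start`, `end` (one row per
#'   molecule span)
#' @param copies_name name of the value column in the result
#' @return data.frame `chrom`, `start`, `end`, `copies`
#' @export
copy_number_profile <- function(molecules, copies_name = "copies") {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      copies = integer(), stringsAsFactors = FALSE)
  names(empty)[4] <- copies_name
  if (is.null(molecules) || !nrow(molecules)) return(empty)
  out <- list()
  for (ch in sort(unique(molecules$chrom))) {
    m <- molecules[molecules$chrom == ch, , drop = FALSE]
    bp <- sort(unique(c(m$start, m$end)))
    if (length(bp) < 2) next
    s <- bp[-length(bp)]; e <- bp[-1]
    copies <- vapply(seq_along(s), function(i)
      sum(m$start <= s[i] & m$end >= e[i]), 1L)
    # merge adjacent intervals with equal copies
    keep <- c(TRUE, copies[-1] != copies[-length(copies)])
    grp <- cumsum(keep)
    out[[ch]] <- data.frame(
      chrom = ch,
      start = as.integer(tapply(s, grp, min)),
      end = as.integer(tapply(e, grp, max)),
      copies = as.integer(tapply(copies, grp, `[`, 1)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, list(empty)))
  rownames(res) <- NULL
  names(res)[4] <- copies_name
  res
}

#' Brute-force minimum chain partition (test oracle)
#'
#' Exhaustively searches assignments of elements to molecules respecting
#' the exclusivity rule and returns the minimum number of molecules. Only
#' intended as an independent oracle for the greedy phaser on tiny
#' instances; refuses more than 12 elements.
#'
#' @param elements data.frame with `chrom`, `start`, `end`
#' @param k_set duplication lengths treated as junction abutments
#' @return minimum molecule count (integer)
#' @export
brute_force_min_chain_partition <- function(elements, k_set = c(8L, 9L, 10L)) {
  el <- as.data.frame(elements, stringsAsFactors = FALSE)
  n <- nrow(el)
  if (n == 0) return(0L)
  if (n > 12) stop("oracle refuses instances with more than 12 elements")
  el <- el[order(el$start, el$end), , drop = FALSE]
  conflict <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    conflict[i, j] <- el$chrom[i] == el$chrom[j] &&
      elements_conflict(el$start[i], el$end[i], el$start[j], el$end[j], k_set)
  best <- n
  assign <- integer(n)
  recurse <- function(i, ngroups) {
    if (ngroups >= best) return()
    if (i > n) { best <<- ngroups; return() }
    for (g in seq_len(ngroups)) {
      if (!any(conflict[i, which(assign[seq_len(i - 1)] == g)])) {
        assign[i] <<- g
        recurse(i + 1L, ngroups)
        assign[i] <<- 0L
      }
    }
    assign[i] <<- ngroups + 1L
    recurse(i + 1L, ngroups + 1L)
    assign[i] <<- 0L
  }
  recurse(1L, 0L)
  as.integer(best)
}
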