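# defective-transpososome artifact detection: shared-end groups,
# scenario classification, redundant-fragment marking

#' Group fragments sharing an identical 5' or 3' end
#'
#' A transpososome with one defective reaction centre leaves characteristic
#' short fragments whose start (5') or end (3') coordinate exactly equals
#' that of a longer fragment. Equality is exact: tagmentation cut positions
#' are discrete, and any tolerance would conflate distinct cut sites.
#' Singleton ends produce no group.
#'
#' @param fragments deduplicated fragment table
#' @return data.frame with `group_id`, `anchor_end`
#'   (`"five_prime"`/`"three_prime"`), `chrom`, `coordinate`, and a
#'   `member_ids` list-column ordered by decreasing length
#' @export
group_shared_ends <- function(fragments) {
  frs <- as_fragment_table(fragments)
  collect <- function(key_coord, anchor) {
    key <- paste(frs$chrom, key_coord)
    tb <- table(key)
    multi <- names(tb)[tb >= 2]
    lapply(multi, function(kk) {
      idx <- which(key == kk)
      idx <- idx[order(-(frs$end[idx] - frs$start[idx]), frs$id[idx])]
      list(anchor_end = anchor, chrom = frs$chrom[idx[1]],
           coordinate = if (anchor == "five_prime") frs$start[idx[1]]
                        else frs$end[idx[1]],
           member_ids = frs$id[idx])
    })
  }
  groups <- c(if (nrow(frs)) collect(frs$start, "five_prime"),
              if (nrow(frs)) collect(frs$end, "three_prime"))
  out <- data.frame(
    group_id = if (length(groups)) sprintf("grp_%04d", seq_along(groups)) else character(),
    anchor_end = vapply(groups, `[[`, "", "anchor_end"),
    chrom = vapply(groups, `[[`, "", "chrom"),
    coordinate = vapply(groups, function(x) as.integer(x$coordinate), 1L),
    stringsAsFactors = FALSE)
  out$member_ids <- lapply(groups, `[[`, "member_ids")
  if (nrow(out)) {
    out <- out[order(out$chrom, out$coordinate, out$anchor_end), , drop = FALSE]
    out$group_id <- sprintf("grp_%04d", seq_len(nrow(out)))
    rownames(out) <- NULL
  }
  out
}

#' Classify the defect scenario behind a shared-end group
#'
#' Two members sharing a 5' end indicate a single top-strand defective cut
#' (`0/1`); two sharing a 3' end the bottom-strand mirror (`1/0`); three or
#' more members one-sided indicate adjacent same-strand defects
#' (`00/11`/`11/00`); a pair of two-member groups in which one short
#' fragment shares the 5' end and another shares the 3' end of the *same*
#' longest fragment indicates `01/10`. Anything else is `unclassified` --
#' notably `10/01`, which produces two overlapping fragments with no shared
#' end and is indistinguishable from two separate molecules.
#'
#' @param groups output of [group_shared_ends()]
#' @return `groups` with a `scenario` column added
#' @export
classify_scenarios <- function(groups) {
  if (!nrow(groups)) { groups$scenario <- character(); return(groups) }
  scen <- vapply(seq_len(nrow(groups)), function(i)
    classify_scenario(groups[i, ]), character(1))
  # cross-check for 01/10: same longest fragment anchors a 5' and a 3' pair
  longest <- vapply(groups$member_ids, `[[`, "", 1)
  two <- lengths(groups$member_ids) == 2
  for (lid in unique(longest)) {
    hit5 <- which(two & longest == lid & groups$anchor_end == "five_prime")
    hit3 <- which(two & longest == lid & groups$anchor_end == "three_prime")
    if (length(hit5) && length(hit3)) scen[c(hit5, hit3)] <- "01/10"
  }
  groups$scenario <- scen
  groups
}

#' @rdname classify_scenarios
#' @param group a single group row
#' @export
classify_scenario <- function(group) {
  n <- length(group$member_ids[[1]])
  if (n == 2) {
    if (group$anchor_end == "five_prime") "0/1" else "1/0"
  } else if (n >= 3) {
    if (group$anchor_end == "five_prime") "00/11" else "11/00"
  } else "unclassified"
}

#' Mark redundant fragments before phasing
#'
#' Within every shared-end group all members except the longest are flagged
#' `redundant` and excluded from molecule reconstruction: the longer
#' fragment already covers them, and the shorts are amplification artifacts
#' of a defective tagmentation event. An exact length tie leaves both
#' members retained with a warning (ambiguous artifact). A genuinely
#' homologous fragment that coincidentally shares one end with a longer
#' fragment is wrongly flagged by this rule; this faithful simplification is
#' visible in the logs.
#'
#' @param fragments deduplicated fragment table
#' @param groups output of [group_shared_ends()] (optionally classified)
#' @return list with `retained` and `redundant` fragment tables
#'   (`retained` plus `redundant` equals the input)
#' @export
mark_redundant <- function(fragments, groups) {
  frs <- as_fragment_table(fragments)
  redundant_ids <- character()
  for (i in seq_len(nrow(groups))) {
    mem <- groups$member_ids[[i]]
    w <- (frs$end - frs$start)[match(mem, frs$id)]
    if (length(mem) >= 2 && w[1] == w[2]) {
      warning("exact length tie in shared-end group ", groups$group_id[i],
              "; both members retained (ambiguous artifact)")
      tied <- mem[w == w[1]]
      redundant_ids <- c(redundant_ids, setdiff(mem, tied))
    } else {
      redundant_ids <- c(redundant_ids, mem[-1])
    }
  }
  redundant_ids <- unique(redundant_ids)
  is_red <- frs$id %in% redundant_ids
  frs$flags[is_red] <- add_flag(frs$flags[is_red], "redundant")
  list(retained = frs[!is_red, , drop = FALSE],
       redundant = frs[is_red, , drop = FALSE])
}
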