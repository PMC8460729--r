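# tagmentation library simulator with molecule-level ground truth

DEFECT_SIMPLE <- c("0/1", "1/0")
DEFECT_COMPLEX <- c("00/11", "11/00", "01/10", "10/01")
DEFECT_SCENARIOS <- c(DEFECT_SIMPLE, DEFECT_COMPLEX)

#' Simulation configuration
#'
#' Defaults describe the library regime the pipeline targets: haploid
#' molecules around 10 kb amounting to ~10% of the genome, fragments
#' averaging ~230 bases, canonical 9-base junction duplications with
#' minority 8- and 10-base cuts (proportions 97:1889:139), PCR duplication
#' around 6.4x, rare 3-base primer remnants, ~20% per-fragment dropout
#' (per-molecule coverage near 80%) and ~10% solo contamination fragments.
#'
#' @param molecule_len_mean mean molecule length in bases
#' @param molecule_len_cv coefficient of variation of molecule length
#'   (lognormal); 0.7 reproduces a broad 1-30 kb spread with a median below
#'   the mean
#' @param genome_fraction target fraction of the genome present as molecules
#' @param frag_len_mean mean fragment length in bases
#' @param frag_len_min minimum inter-cut distance in bases
#' @param junction_k_probs named probabilities for duplication lengths
#'   `"8"`, `"9"`, `"10"`; must sum to 1
#' @param defect_rate probability that an interior cut comes from a
#'   single-strand-defective transpososome
#' @param defect_scenarios subset of
#'   `c("0/1","1/0","00/11","11/00","01/10","10/01")` the simulator may emit
#' @param pcr_copy_mean expected observed copies per fragment
#'   (copies ~ 1 + Poisson(mean - 1))
#' @param primer_tail_prob probability a fragment keeps a residual 3-base
#'   primer tail (`CAG` at its 5' end or `CTG` at its 3' end)
#' @param dropout_rate per-fragment loss probability
#' @param contamination_rate expected solo contamination fragments per
#'   primary fragment
#' @param min_fragment_len fragments shorter than this are lost in library
#'   preparation
#' @param site_bias optional weight (>= 0) favouring G at the first
#'   duplicated base and A/T immediately outside the cut; 0 disables
#' @param emit_seq attach fragment sequences (required for primer-tail and
#'   junction sequence checks)
#' @param seed integer seed; fully determines simulator output
#' @return a validated list of class `sim_config`
#' @export
sim_config <- function(molecule_len_mean = 10000, molecule_len_cv = 0.7,
                       genome_fraction = 0.10, frag_len_mean = 230,
                       frag_len_min = 35,
                       junction_k_probs = c("8" = 97, "9" = 1889, "10" = 139) / 2125,
                       defect_rate = 0.10,
                       defect_scenarios = DEFECT_SCENARIOS,
                       pcr_copy_mean = 6.4, primer_tail_prob = 0.005,
                       dropout_rate = 0.2, contamination_rate = 0.1,
                       min_fragment_len = 25, site_bias = 0,
                       emit_seq = TRUE, seed = 1L) {
  cfg <- list(molecule_len_mean = molecule_len_mean,
              molecule_len_cv = molecule_len_cv,
              genome_fraction = genome_fraction,
              frag_len_mean = frag_len_mean, frag_len_min = frag_len_min,
              junction_k_probs = junction_k_probs,
              defect_rate = defect_rate, defect_scenarios = defect_scenarios,
              pcr_copy_mean = pcr_copy_mean,
              primer_tail_prob = primer_tail_prob,
              dropout_rate = dropout_rate,
              contamination_rate = contamination_rate,
              min_fragment_len = min_fragment_len, site_bias = site_bias,
              emit_seq = emit_seq, seed = seed)
  probs <- c(defect_rate, primer_tail_prob, dropout_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (genome_fraction < 0 || genome_fraction >= 1)
    stop("genome_fraction must lie in [0, 1)")
  if (!setequal(names(junction_k_probs), c("8", "9", "10")) ||
      abs(sum(junction_k_probs) - 1) > 1e-8)
    stop("junction_k_probs must be named \"8\",\"9\",\"10\" and sum to 1")
  if (pcr_copy_mean < 1) stop("pcr_copy_mean must be >= 1")
  if (!all(defect_scenarios %in% DEFECT_SCENARIOS))
    stop("unknown defect scenario(s)")
  if (frag_len_mean <= frag_len_min) stop("frag_len_mean must exceed frag_len_min")
  structure(cfg, class = "sim_config")
}

# internal row constructor: fragment rows in molecule order with truth columns
sim_frag_rows <- function(id, chrom, start, end, seq = NA_character_,
                          molecule = NA_character_, artifact = FALSE,
                          scenario = NA_character_) {
  n <- length(start)
  data.frame(id = id, chrom = rep_len(chrom, n),
             start = as.integer(start), end = as.integer(end),
             seq = rep_len(seq, n), dup_count = rep_len(1L, n),
             flags = rep_len("", n),
             molecule = rep_len(molecule, n),
             artifact = rep_len(artifact, n),
             scenario = rep_len(scenario, n),
             stringsAsFactors = FALSE)
}

empty_sim_frags <- function() sim_frag_rows(character(), character(), integer(), integer())

#' Sample haploid molecules from a genome
#'
#' Molecules are placed independently and uniformly (chromosome chosen
#' proportionally to its length), so homologous overlaps occur by chance --
#' that is the phasing challenge. Lengths are lognormal with the configured
#' mean and CV. Drawing stops when the cumulative length reaches
#' `genome_fraction * genome size`; the final draw is kept only if keeping
#' it lands closer to the target than dropping it, so the expected count is
#' `fraction * genome / mean length` without overshoot bias.
#'
#' @param genome named character vector or `DNAStringSet`
#' @param config [sim_config()]
#' @param n_molecules optional fixed number of molecules (overrides the
#'   cumulative-length rule)
#' @param seed seed (defaults to `config$seed`); `NULL` uses the current
#'   RNG stream
#' @return data.frame with `molecule_id`, `chrom`, `start`, `end`
#' @export
sample_molecules <- function(genome, config = sim_config(), n_molecules = NULL,
                             seed = config$seed) {
  g <- as_genome_chars(genome)
  if (!length(g) || !sum(nchar(g))) stop("genome is empty")
  with_seed(seed, sample_molecules_impl(g, config, n_molecules))
}

sample_molecules_impl <- function(g, config, n_molecules = NULL) {
  lens <- nchar(g)
  target <- config$genome_fraction * sum(lens)
  empty <- data.frame(molecule_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(n_molecules) && target <= 0) return(empty)
  if (!is.null(n_molecules) && n_molecules == 0) return(empty)
  sdlog <- sqrt(log(1 + config$molecule_len_cv^2))
  meanlog <- log(config$molecule_len_mean) - sdlog^2 / 2
  draw_one <- function() {
    L <- round(rlnorm(1, meanlog, sdlog))
    L <- max(min(L, min(lens)), 2L * config$min_fragment_len)
    ch <- sample(names(g), 1, prob = lens)
    s <- sample.int(lens[[ch]] - L + 1L, 1) - 1L
    list(chrom = ch, start = s, end = s + as.integer(L))
  }
  out <- list(); cum <- 0
  repeat {
    if (!is.null(n_molecules)) {
      if (length(out) >= n_molecules) break
    } else if (cum >= target) {
      # drop the final molecule if that lands closer to the target
      last_len <- out[[length(out)]]$end - out[[length(out)]]$start
      if (length(out) > 0 && abs(cum - last_len - target) < abs(cum - target))
        out <- out[-length(out)]
      break
    }
    m <- draw_one()
    cum <- cum + (m$end - m$start)
    out[[length(out) + 1L]] <- m
  }
  if (!length(out)) return(empty)
  data.frame(molecule_id = sprintf("m%04d", seq_along(out)),
             chrom = vapply(out, `[[`, "", "chrom"),
             start = vapply(out, function(x) as.integer(x$start), 1L),
             end = vapply(out, function(x) as.integer(x$end), 1L),
             stringsAsFactors = FALSE)
}

#' Tagment one molecule into overlapping fragments
#'
#' Interior cut positions are drawn with i.i.d. geometric-like inter-cut
#' distances averaging `frag_len_mean`. At each interior cut the two
#' transpososome reaction centres nick the strands `k` bases apart
#' (k drawn from `junction_k_probs`), duplicating `k` bases: the downstream
#' fragment starts `k` bases before the upstream fragment ends. Terminal
#' fragments end at the molecule boundaries, so trimming the duplicated
#' leading bases of every non-first fragment and concatenating reproduces
#' the molecule sequence exactly.
#'
#' @param molecule list or one-row data.frame with `chrom`, `start`, `end`
#'   and optionally `molecule_id`
#' @param config [sim_config()]
#' @param genome genome (needed when `emit_seq` is `TRUE` or `site_bias > 0`)
#' @param seed seed (defaults to `config$seed`); `NULL` uses the current
#'   RNG stream
#' @return list with `fragments` (rows in 5'->3' molecule order) and
#'   `cut_events` (`pos` = upstream fragment end, `overlap_start`, `k`,
#'   `scenario` initially `NA`)
#' @export
tagment_molecule <- function(molecule, config = sim_config(), genome = NULL,
                             seed = config$seed) {
  with_seed(seed, tagment_molecule_impl(molecule, config, genome))
}

tagment_molecule_impl <- function(molecule, config, genome = NULL) {
  m <- as.list(molecule)
  mid <- m$molecule_id %||% "m0001"
  s <- as.integer(m$start); e <- as.integer(m$end)
  L <- e - s
  min_d <- config$frag_len_min
  p <- 1 / (config$frag_len_mean - min_d + 1)
  n_draw <- max(8L, ceiling(2 * L / config$frag_len_mean) + 8L)
  d <- min_d + rgeom(n_draw, p)
  while (sum(d) < L) d <- c(d, min_d + rgeom(n_draw, p))
  cuts <- s + cumsum(d)
  cuts <- cuts[cuts < e]
  ks <- if (length(cuts))
    as.integer(sample(c(8L, 9L, 10L), length(cuts), replace = TRUE,
                      prob = config$junction_k_probs[c("8", "9", "10")]))
  else integer()
  if (length(cuts) && config$site_bias > 0 && !is.null(genome)) {
    gch <- as_genome_chars(genome)[[m$chrom]]
    for (i in seq_along(cuts)) {
      cand <- cuts[i] + (-3:3)
      cand <- cand[cand > s & cand < e & cand - ks[i] >= 2]
      if (!length(cand)) next
      dup1 <- substring(gch, cand - ks[i] + 1L, cand - ks[i] + 1L)
      m1 <- substring(gch, cand - ks[i], cand - ks[i])
      w <- (1 + config$site_bias * (dup1 == "G")) *
           (1 + config$site_bias * (m1 %in% c("A", "T")))
      cuts[i] <- cand[sample.int(length(cand), 1, prob = w)]
    }
  }
  f_start <- as.integer(c(s, cuts - ks))
  f_end <- as.integer(c(cuts, e))
  seqs <- if (isTRUE(config$emit_seq) && !is.null(genome))
    get_seq(genome, m$chrom, f_start, f_end) else NA_character_
  frs <- sim_frag_rows(id = sprintf("%s_f%03d", mid, seq_along(f_start)),
                       chrom = m$chrom, start = f_start, end = f_end,
                       seq = seqs, molecule = mid)
  ce <- data.frame(molecule_id = rep(mid, length(cuts)),
                   chrom = rep(m$chrom, length(cuts)),
                   pos = as.integer(cuts),
                   overlap_start = as.integer(cuts - ks), k = ks,
                   scenario = rep(NA_character_, length(cuts)),
                   stringsAsFactors = FALSE)
  list(fragments = frs, cut_events = ce)
}

#' Apply defective-transpososome events to tagmented fragments
#'
#' A transpososome with one inactive reaction centre nicks only one strand;
#' after amplification the suppressed cut yields characteristic artifact
#' fragments sharing a 5' or 3' end with a longer fragment. Isolated
#' defective cuts produce scenarios `0/1` (two indistinguishable long pieces
#' plus a short piece sharing the 5' end) or `1/0` (mirror, shared 3' ends);
#' two adjacent defective cuts produce `00/11`/`11/00` (four fragments,
#' three unique lengths, one shared end), `01/10` (two identical long pieces
#' with two shorter ones sharing their 5' and 3' ends) or `10/01` (exactly
#' two overlapping fragments with no shared end). Cuts whose flanking
#' fragments were consumed by an earlier event, and molecule boundaries, are
#' never defective.
#'
#' Pre-set `scenario` values in `cut_events` force that scenario at that cut
#' (complex scenarios consume the next cut as well); `NA` entries are drawn
#' with probability `defect_rate` from `config$defect_scenarios`.
#'
#' @param fragments fragments in molecule order (from [tagment_molecule()])
#' @param cut_events matching cut table
#' @param config [sim_config()]
#' @param genome genome for artifact sequences
#' @param seed seed (defaults to `config$seed`); `NULL` uses the current
#'   RNG stream
#' @return list with `fragments` (artifact rows carry `artifact = TRUE` and
#'   a `scenario` label) and `cut_events` with scenarios filled in
#' @export
apply_defective_events <- function(fragments, cut_events, config = sim_config(),
                                   genome = NULL, seed = config$seed) {
  with_seed(seed, apply_defective_events_impl(fragments, cut_events, config, genome))
}

apply_defective_events_impl <- function(fragments, cut_events, config, genome = NULL) {
  allowed <- config$defect_scenarios
  simple_ok <- intersect(DEFECT_SIMPLE, allowed)
  complex_ok <- intersect(DEFECT_COMPLEX, allowed)
  out_frags <- list(); out_cuts <- list()
  for (mid in unique(fragments$molecule)) {
    frs <- fragments[fragments$molecule == mid, , drop = FALSE]
    frs <- frs[order(frs$start, frs$end), , drop = FALSE]
    ce <- cut_events[cut_events$molecule_id == mid, , drop = FALSE]
    ce <- ce[order(ce$pos), , drop = FALSE]
    m <- nrow(frs)
    forced <- !is.na(ce$scenario)
    defective <- forced | (runif(nrow(ce)) < config$defect_rate)
    consumed <- rep(FALSE, m)
    drop_idx <- integer(); extra <- list(); counter <- 0L
    seq_for <- function(st, en) {
      if (isTRUE(config$emit_seq) && !is.null(genome))
        get_seq(genome, frs$chrom[1], st, en) else NA_character_
    }
    new_rows <- function(st, en, n_copies, artifact, scen) {
      counter <<- counter + 1L
      sim_frag_rows(id = sprintf("%s_d%02d%s", mid, counter, letters[seq_len(n_copies)]),
                    chrom = frs$chrom[1], start = rep(st, n_copies),
                    end = rep(en, n_copies), seq = rep(seq_for(st, en), n_copies),
                    molecule = mid, artifact = artifact, scenario = scen)
    }
    j <- 1L
    while (j <= nrow(ce)) {
      if (!defective[j] || consumed[j] || consumed[j + 1L]) { j <- j + 1L; next }
      want <- if (forced[j]) ce$scenario[j] else NA_character_
      pair_ok <- j < nrow(ce) && (j + 2L) <= m && !consumed[j + 2L] &&
        (if (forced[j]) want %in% DEFECT_COMPLEX else
           (defective[j + 1L] && length(complex_ok) > 0))
      if (pair_ok) {
        scen <- if (forced[j]) want
                else complex_ok[sample.int(length(complex_ok), 1)]
        A <- frs[j, ]; B <- frs[j + 1L, ]; C <- frs[j + 2L, ]
        if (scen == "00/11") {
          extra <- c(extra, list(new_rows(A$start, C$end, 2L, FALSE, scen),
                                 new_rows(A$start, B$end, 1L, TRUE, scen)))
          frs$artifact[j] <- TRUE; frs$scenario[j] <- scen
          drop_idx <- c(drop_idx, j + 1L, j + 2L)
        } else if (scen == "11/00") {
          extra <- c(extra, list(new_rows(A$start, C$end, 2L, FALSE, scen),
                                 new_rows(B$start, C$end, 1L, TRUE, scen)))
          frs$artifact[j + 2L] <- TRUE; frs$scenario[j + 2L] <- scen
          drop_idx <- c(drop_idx, j, j + 1L)
        } else if (scen == "01/10") {
          extra <- c(extra, list(new_rows(A$start, C$end, 2L, FALSE, scen)))
          frs$artifact[c(j, j + 2L)] <- TRUE; frs$scenario[c(j, j + 2L)] <- scen
          drop_idx <- c(drop_idx, j + 1L)
        } else { # 10/01: two overlapping fragments, no shared ends
          extra <- c(extra, list(new_rows(A$start, B$end, 1L, FALSE, scen),
                                 new_rows(B$start, C$end, 1L, FALSE, scen)))
          drop_idx <- c(drop_idx, j, j + 1L, j + 2L)
        }
        ce$scenario[c(j, j + 1L)] <- scen
        consumed[j:(j + 2L)] <- TRUE
        j <- j + 2L
      } else if (length(simple_ok) || (forced[j] && want %in% DEFECT_SIMPLE)) {
        scen <- if (forced[j]) want else simple_ok[sample.int(length(simple_ok), 1)]
        if (!scen %in% DEFECT_SIMPLE) { j <- j + 1L; next }
        A <- frs[j, ]; B <- frs[j + 1L, ]
        extra <- c(extra, list(new_rows(A$start, B$end, 2L, FALSE, scen)))
        if (scen == "0/1") {
          frs$artifact[j] <- TRUE; frs$scenario[j] <- scen
          drop_idx <- c(drop_idx, j + 1L)
        } else {
          frs$artifact[j + 1L] <- TRUE; frs$scenario[j + 1L] <- scen
          drop_idx <- c(drop_idx, j)
        }
        ce$scenario[j] <- scen
        consumed[j:(j + 1L)] <- TRUE
        j <- j + 1L
      } else j <- j + 1L
    }
    if (length(drop_idx)) frs <- frs[-drop_idx, , drop = FALSE]
    out_frags[[mid]] <- rbind(frs, do.call(rbind, extra))
    out_cuts[[mid]] <- ce
  }
  frs <- do.call(rbind, c(out_frags, list(empty_sim_frags())))
  rownames(frs) <- NULL
  list(fragments = frs,
       cut_events = do.call(rbind, c(out_cuts, list(cut_events[0, ]))))
}

#' Apply library-preparation noise
#'
#' In order: fragments below `min_fragment_len` are lost; each fragment
#' drops out with `dropout_rate` (this sets per-molecule coverage, ~80% at
#' the default 0.2); with `primer_tail_prob` a fragment keeps a residual
#' 3-base primer tail (`CAG` prepended at its 5' end or `CTG` appended at
#' its 3' end, with mapped coordinates extended past the true junction; a
#' tail that would match the reference is not applied, as it would be
#' unobservable); each fragment is then amplified to
#' `1 + Poisson(pcr_copy_mean - 1)` observed copies; finally solo
#' contamination fragments (length < 200, uniform placement, never given
#' junction partners) are added at `contamination_rate` per primary fragment
#' and amplified likewise.
#'
#' @param fragments fragment rows (from [apply_defective_events()] or
#'   [tagment_molecule()])
#' @param config [sim_config()]
#' @param genome genome (needed for tails and contamination sequence)
#' @param seed seed (defaults to `config$seed`); `NULL` uses the current
#'   RNG stream
#' @return list with `fragments` (the observed amplified library; column
#'   `parent` links each copy to its pre-amplification fragment) and
#'   `truth_fragments` (unique surviving fragments with `tail_side` and
#'   `tail_interior` truth columns)
#' @export
apply_library_noise <- function(fragments, config = sim_config(), genome = NULL,
                                seed = config$seed) {
  with_seed(seed, apply_library_noise_impl(fragments, config, genome))
}

apply_library_noise_impl <- function(fragments, config, genome = NULL) {
  frs <- fragments
  if (is.null(frs$molecule)) frs$molecule <- NA_character_
  if (is.null(frs$artifact)) frs$artifact <- FALSE
  if (is.null(frs$scenario)) frs$scenario <- NA_character_
  frs <- frs[(frs$end - frs$start) >= config$min_fragment_len, , drop = FALSE]
  if (nrow(frs)) frs <- frs[runif(nrow(frs)) >= config$dropout_rate, , drop = FALSE]
  frs$tail_side <- rep("none", nrow(frs))
  frs$tail_interior <- rep(FALSE, nrow(frs))
  can_tail <- isTRUE(config$emit_seq) && !is.null(genome) &&
    config$primer_tail_prob > 0 && nrow(frs) > 0
  if (can_tail) {
    g <- as_genome_chars(genome)
    lens <- nchar(g)
    tailed <- which(runif(nrow(frs)) < config$primer_tail_prob)
    side <- sample(c("five", "three"), length(tailed), replace = TRUE)
    orig_start <- frs$start; orig_end <- frs$end
    for (i in seq_along(tailed)) {
      r <- tailed[i]
      if (side[i] == "five") {
        ns <- frs$start[r] - 3L
        if (ns < 0) next
        if (get_seq(g, frs$chrom[r], ns, frs$start[r]) == "CAG") next
        frs$seq[r] <- paste0("CAG", frs$seq[r])
        frs$start[r] <- ns
        frs$tail_side[r] <- "five"
      } else {
        ne <- frs$end[r] + 3L
        if (ne > lens[[frs$chrom[r]]]) next
        if (get_seq(g, frs$chrom[r], frs$end[r], ne) == "CTG") next
        frs$seq[r] <- paste0(frs$seq[r], "CTG")
        frs$end[r] <- ne
        frs$tail_side[r] <- "three"
      }
    }
    # a tail is repairable iff the masked junction partner survives untailed
    for (r in which(frs$tail_side != "none")) {
      same <- frs$chrom == frs$chrom[r]
      frs$tail_interior[r] <- if (frs$tail_side[r] == "five")
        any(same & frs$end %in% ((frs$start[r] + 3L) + 8:10))
      else
        any(same & frs$start %in% ((frs$end[r] - 3L) - 8:10))
    }
  }
  truth <- frs
  # contamination pool: scattered lonely fragments from cross-contamination
  n_solo <- if (config$contamination_rate > 0 && nrow(frs))
    rpois(1, config$contamination_rate * nrow(frs)) else 0L
  if (n_solo > 0) {
    g <- as_genome_chars(genome)
    lens <- nchar(g)
    ch <- sample(names(g), n_solo, replace = TRUE, prob = lens)
    len <- sample(50:199, n_solo, replace = TRUE)
    st <- vapply(seq_len(n_solo), function(i)
      sample.int(lens[[ch[i]]] - len[i] + 1L, 1) - 1L, 1L)
    solo <- sim_frag_rows(id = sprintf("solo_%03d", seq_len(n_solo)),
                          chrom = ch, start = st, end = st + len,
                          seq = if (isTRUE(config$emit_seq))
                            get_seq(g, ch, st, st + len) else NA_character_,
                          molecule = "solo")
    solo$tail_side <- "none"; solo$tail_interior <- FALSE
    truth <- rbind(truth, solo)
  }
  if (!nrow(truth)) {
    obs <- truth; obs$parent <- character()
    return(list(fragments = obs, truth_fragments = truth))
  }
  copies <- 1L + rpois(nrow(truth), config$pcr_copy_mean - 1)
  idx <- rep(seq_len(nrow(truth)), copies)
  obs <- truth[idx, , drop = FALSE]
  obs$parent <- obs$id
  obs$id <- paste0(obs$id, ".c", unlist(lapply(copies, seq_len)))
  rownames(obs) <- rownames(truth) <- NULL
  list(fragments = obs, truth_fragments = truth)
}

#' Simulate a complete tagmentation library with ground truth
#'
#' Orchestrates molecule sampling, tagmentation, defective-transpososome
#' events and library noise under a single seed; identical configurations
#' (including the seed) give byte-identical output.
#'
#' @param genome named character vector or `DNAStringSet`
#' @param config [sim_config()]
#' @param molecules optional pre-specified molecule table (as from
#'   [sample_molecules()]); drawn from `config` when `NULL`
#' @return an object of class `sim_library`: list with `fragments` (the
#'   observed pre-deduplication library as a fragment table with truth
#'   columns) and `truth` (`molecules`, `cut_events`, `fragments` = unique
#'   emitted fragments, `fragment_origins` mapping every observed id to its
#'   molecule or `"solo"`, and the `config`)
#' @export
simulate_library <- function(genome, config = sim_config(), molecules = NULL) {
  g <- as_genome_chars(genome)
  with_seed(config$seed, {
    mols <- molecules %||% sample_molecules_impl(g, config)
    tg <- lapply(seq_len(nrow(mols)), function(i)
      tagment_molecule_impl(mols[i, ], config, g))
    frs <- do.call(rbind, c(lapply(tg, `[[`, "fragments"), list(empty_sim_frags())))
    ce0 <- data.frame(molecule_id = character(), chrom = character(),
                      pos = integer(), overlap_start = integer(), k = integer(),
                      scenario = character(), stringsAsFactors = FALSE)
    ce <- do.call(rbind, c(lapply(tg, `[[`, "cut_events"), list(ce0)))
    def <- if (nrow(frs)) apply_defective_events_impl(frs, ce, config, g)
           else list(fragments = frs, cut_events = ce)
    noisy <- apply_library_noise_impl(def$fragments, config, g)
    obs <- noisy$fragments
    if (nrow(obs)) obs <- obs[order(obs$chrom, obs$start, obs$end, obs$id), , drop = FALSE]
    rownames(obs) <- NULL
    structure(list(
      fragments = obs,
      truth = list(molecules = mols, cut_events = def$cut_events,
                   fragments = noisy$truth_fragments,
                   fragment_origins = setNames(obs$molecule, obs$id),
                   config = config)),
      class = "sim_library")
  })
}

#' @export
print.sim_library <- function(x, ...) {
  cat("Simulated tagmentation library\n")
  cat("  molecules:          ", nrow(x$truth$molecules), "\n")
  cat("  unique fragments:   ", nrow(x$truth$fragments), "\n")
  cat("  observed fragments: ", nrow(x$fragments), "\n")
  cat("  truth artifacts:    ", sum(x$truth$fragments$artifact), "\n")
  invisible(x)
}

#' Perfect-tiling in-silico fragment simulation
#'
#' Tiles a region end to end with fragments whose lengths are uniform over
#' `insert_range` and where every adjacent pair overlaps exactly 9 bases
#' (the canonical duplication), the calibration pattern used to verify
#' mapping specificity. The last fragment is truncated at the region end,
#' so the fragment union equals the region exactly.
#'
#' @param chrom chromosome name
#' @param start,end region coordinates (0-based, half-open)
#' @param read_len nominal read length in bases (reads at these insert
#'   sizes overlap and merge into full fragments; recorded for
#'   provenance only)
#' @param insert_range length-2 integer vector of insert (fragment) sizes
#' @param seed optional integer seed
#' @return fragment table tiling `[start, end)`
#' @export
simulate_perfect_tiling <- function(chrom, start, end, read_len = 50L,
                                    insert_range = c(35L, 150L), seed = NULL) {
  stopifnot(end > start, insert_range[1] > 9, insert_range[2] >= insert_range[1])
  with_seed(seed, {
    span <- end - start
    n_guess <- ceiling(span / (insert_range[1] - 9)) + 2L
    L <- insert_range[1] + sample.int(insert_range[2] - insert_range[1] + 1L,
                                      n_guess, replace = TRUE) - 1L
    st <- start + cumsum(c(0L, L[-length(L)] - 9L))
    en <- st + L
    last <- match(TRUE, en >= end)
    st <- st[seq_len(last)]; en <- en[seq_len(last)]
    en[last] <- end
    fragment_table(chrom = chrom, start = st, end = en,
                   id = sprintf("tile_%05d", seq_along(st)))
  })
}
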