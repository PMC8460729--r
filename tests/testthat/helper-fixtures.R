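# shared fixtures: all inputs are generated in code at test time

has_flag <- function(...) tagphase:::has_flag(...)

# quick fragment constructor on one chromosome
frags <- function(starts, ends, chrom = "chr1", ...) {
  fragment_table(chrom = chrom, start = starts, end = ends, ...)
}

# a noise-free simulator configuration; override fields as needed
quiet_config <- function(...) {
  args <- list(...)
  defaults <- list(defect_rate = 0, dropout_rate = 0, pcr_copy_mean = 1,
                   contamination_rate = 0, primer_tail_prob = 0, seed = 1L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# tagment a set of pre-placed molecules and return the observed library
sim_placed <- function(genome, molecules, config) {
  simulate_library(genome, config, molecules = molecules)
}

mol_df <- function(starts, ends, chrom = "chr1") {
  data.frame(molecule_id = sprintf("m%04d", seq_along(starts)),
             chrom = chrom, start = as.integer(starts), end = as.integer(ends),
             stringsAsFactors = FALSE)
}

# fragments + cut_events in the molecule-order layout the defect stage expects
sim_frags_manual <- function(starts, ends, genome = NULL, chrom = "chr1",
                             molecule = "m0001") {
  seqs <- if (!is.null(genome)) get_seq(genome, rep(chrom, length(starts)),
                                        starts, ends) else NA_character_
  data.frame(id = sprintf("%s_f%03d", molecule, seq_along(starts)),
             chrom = chrom, start = as.integer(starts), end = as.integer(ends),
             seq = seqs, dup_count = 1L, flags = "",
             molecule = molecule, artifact = FALSE, scenario = NA_character_,
             stringsAsFactors = FALSE)
}

cuts_manual <- function(pos, k, chrom = "chr1", molecule = "m0001",
                        scenario = NA_character_) {
  data.frame(molecule_id = molecule, chrom = chrom, pos = as.integer(pos),
             overlap_start = as.integer(pos - k), k = as.integer(k),
             scenario = scenario, stringsAsFactors = FALSE)
}

# write a minimal SAM file for alignment-ingestion tests
write_test_sam <- function(path, genome, pairs) {
  g <- sapply(genome, nchar)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(g), g))
  recs <- character()
  for (p in pairs) {
    s1 <- get_seq(genome, p$chrom, p$r1[1], p$r1[2])
    s2 <- get_seq(genome, p$chrom, p$r2[1], p$r2[2])
    l1 <- p$r1[2] - p$r1[1]; l2 <- p$r2[2] - p$r2[1]
    isize <- max(p$r1[2], p$r2[2]) - min(p$r1[1], p$r2[1])
    recs <- c(recs,
      sprintf("%s\t99\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s",
              p$name, p$chrom, p$r1[1] + 1L, l1, p$r2[1] + 1L, isize,
              s1, strrep("I", l1)),
      sprintf("%s\t147\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s",
              p$name, p$chrom, p$r2[1] + 1L, l2, p$r1[1] + 1L, -isize,
              s2, strrep("I", l2)))
  }
  writeLines(c(hdr, recs), path)
  path
}
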