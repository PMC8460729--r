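# reference genome handling: FASTA in/out, random genomes, 0-based slicing

#' Load a reference genome from FASTA
#'
#' Sequence names are truncated to the first whitespace-separated token so
#' they match SAM/BED chromosome names.
#'
#' @param path path to a FASTA file
#' @return a named character vector, one element per sequence
#' @export
load_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*", "", names(g))
  as_genome_chars(g)
}

#' Write a genome to FASTA
#' @param genome named character vector or `DNAStringSet`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(as_dnastringset(genome), path)
  invisible(path)
}

#' Generate a random genome
#'
#' Bases are drawn i.i.d. with the given GC fraction; useful for simulation
#' and tests where only junction arithmetic matters.
#'
#' @param lengths named integer vector of chromosome lengths
#' @param gc probability of G or C at each position
#' @param seed optional integer seed
#' @return named character vector of sequences
#' @export
random_genome <- function(lengths, gc = 0.5, seed = NULL) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("`lengths` must be a named vector of chromosome lengths")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(seed, {
    vapply(lengths, function(n)
      paste(sample(names(p), n, replace = TRUE, prob = p), collapse = ""),
      character(1))
  })
}

# normalise genome representations -------------------------------------------

as_genome_chars <- function(genome) {
  if (is.character(genome)) {
    if (is.null(names(genome))) stop("genome sequences must be named")
    return(genome)
  }
  x <- as.character(genome)
  names(x) <- names(genome)
  x
}

as_dnastringset <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  Biostrings::DNAStringSet(as_genome_chars(genome))
}

genome_size <- function(genome) sum(nchar(as_genome_chars(genome)))

#' Extract genome sequence over 0-based half-open intervals
#'
#' @param genome named character vector or `DNAStringSet`
#' @param chrom,start,end parallel vectors of interval coordinates
#'   (0-based, half-open)
#' @return character vector of sequences
#' @export
get_seq <- function(genome, chrom, start, end) {
  g <- as_genome_chars(genome)
  bad <- !(chrom %in% names(g))
  if (any(bad)) stop("unknown chromosome(s): ", paste(unique(chrom[bad]), collapse = ", "))
  len <- nchar(g)[chrom]
  if (any(start < 0 | end > len | start > end))
    stop("interval out of chromosome bounds")
  unname(substring(g[chrom], start + 1, end))
}

# GC fraction over a set of 0-based intervals (base-weighted)
gc_of_intervals <- function(genome, chrom, start, end) {
  keep <- end > start
  chrom <- chrom[keep]; start <- start[keep]; end <- end[keep]
  if (!length(chrom)) return(NA_real_)
  seqs <- Biostrings::DNAStringSet(get_seq(genome, chrom, start, end))
  gc <- sum(Biostrings::letterFrequency(seqs, letters = "GC"))
  acgt <- sum(Biostrings::letterFrequency(seqs, letters = "ACGT"))
  gc / acgt
}
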