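#' Read a genome from a FASTA file
#'
#' Reads a (multi-record, line-wrapped) FASTA file into a named character
#' vector, one uppercase sequence per chromosome. The chromosome name is the
#' first whitespace-delimited token of the header line.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences over `A,C,G,T,N`.
#' @export
read_genome <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  genome <- toupper(as.character(dss))
  names(genome) <- sub("\\s.*$", "", names(dss))
  validate_genome(genome)
  genome
}

#' Write a genome to a FASTA file
#'
#' @param genome Named character vector of sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  validate_genome(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path, width = 70L)
  invisible(path)
}

validate_genome <- function(genome) {
  if (!is.character(genome) || length(genome) == 0L) {
    stop("genome must be a non-empty named character vector", call. = FALSE)
  }
  if (is.null(names(genome)) || anyDuplicated(names(genome)) || any(names(genome) == "")) {
    stop("chromosome names must be present and unique", call. = FALSE)
  }
  bad <- vapply(genome, function(s) {
    grepl("[^ACGTN]", toupper(s))
  }, logical(1))
  if (any(bad)) {
    stop("genome contains characters outside {A,C,G,T,N}: ",
         paste(names(genome)[bad], collapse = ", "), call. = FALSE)
  }
  invisible(genome)
}

#' Chromosome lengths of a genome
#'
#' @param genome Named character vector of sequences.
#' @return Named integer vector of lengths in bp.
#' @export
chrom_lengths <- function(genome) {
  vapply(genome, nchar, integer(1))
}

check_motif <- function(motif) {
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) != 2L) {
    stop("motif must be a single dinucleotide string of length 2", call. = FALSE)
  }
  motif <- toupper(motif)
  if (grepl("[^ACGT]", motif)) {
    stop("motif must be over {A,C,G,T}", call. = FALSE)
  }
  motif
}

#' Find dinucleotide sites in a sequence
#'
#' Scans a single sequence for a dinucleotide motif and returns 0-based site
#' coordinates. The reported coordinate is the position of the cytosine of the
#' dinucleotide when the motif contains one (so `"CG"` reports the first base
#' and `"GC"` the second -- the base whose methylation a bisulfite assay
#' reports); for C-free motifs the first base is reported. Matching is
#' case-insensitive and `N` never matches.
#'
#' @param seq A single sequence string.
#' @param motif Dinucleotide motif, e.g. `"CG"` or `"GC"`.
#' @return Sorted integer vector of 0-based coordinates.
#' @examples
#' find_sites("ACGT", "CG")     # 1
#' find_sites("CGCGNCG", "CG")  # 0 2 5
#' @export
find_sites <- function(seq, motif) {
  motif <- check_motif(motif)
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- charToRaw(toupper(seq))
  n <- length(s)
  if (n < 2L) return(integer(0))
  m <- charToRaw(motif)
  first <- which(s[-n] == m[1L] & s[-1L] == m[2L])  # 1-based index of first base
  offset <- if (substr(motif, 2L, 2L) == "C" && substr(motif, 1L, 1L) != "C") 1L else 0L
  as.integer(first - 1L + offset)
}

#' Find dinucleotide sites across a genome
#'
#' @param genome Named character vector of sequences.
#' @param motif Dinucleotide motif.
#' @return A data.frame with columns `chrom`, `pos` (0-based, see
#'   [find_sites()] for the coordinate convention) and `context`
#'   (`"CpG"` for motif CG, `"GpC"` for motif GC, otherwise the motif itself).
#' @export
genome_sites <- function(genome, motif) {
  motif <- check_motif(motif)
  validate_genome(genome)
  context <- switch(motif, CG = "CpG", GC = "GpC", motif)
  res <- lapply(names(genome), function(ch) {
    pos <- find_sites(genome[[ch]], motif)
    if (length(pos) == 0L) return(NULL)
    data.frame(chrom = ch, pos = pos, context = context, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), pos = integer(0), context = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Observed vs expected dinucleotide representation
#'
#' Computes the observed frequency of a dinucleotide (per valid dinucleotide
#' position, i.e. adjacent non-N pairs within a chromosome), the frequency
#' expected from the genome's mononucleotide composition
#' (`f(first base) * f(second base)` over non-N bases), and their ratio.
#' CpG dinucleotides are strongly under-represented in mammalian genomes
#' relative to this expectation, while GpC is not -- which is why GpC sites are
#' dense enough to read out chromatin accessibility.
#'
#' @param genome Named character vector of sequences.
#' @param motif Dinucleotide motif.
#' @return A list with `frequencies` (named A/C/G/T mononucleotide frequencies),
#'   `n_valid_pairs`, `n_observed`, `observed`, `expected` and `ratio`.
#' @export
dinucleotide_representation <- function(genome, motif) {
  motif <- check_motif(motif)
  validate_genome(genome)
  bases <- c("A", "C", "G", "T")
  raws <- vapply(bases, function(b) charToRaw(b), raw(1))
  rawN <- charToRaw("N")
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  n_valid <- 0
  n_obs <- 0
  m <- charToRaw(motif)
  for (ch in names(genome)) {
    s <- charToRaw(toupper(genome[[ch]]))
    n <- length(s)
    for (b in bases) counts[b] <- counts[b] + sum(s == raws[[b]])
    if (n >= 2L) {
      a <- s[-n]; b2 <- s[-1L]
      n_valid <- n_valid + sum(a != rawN & b2 != rawN)
      n_obs <- n_obs + sum(a == m[1L] & b2 == m[2L])
    }
  }
  if (n_valid == 0) {
    stop("genome has no valid dinucleotide positions", call. = FALSE)
  }
  freq <- counts / sum(counts)
  expected <- unname(freq[substr(motif, 1, 1)] * freq[substr(motif, 2, 2)])
  observed <- n_obs / n_valid
  if (expected == 0) {
    stop("expected frequency is zero for motif ", motif,
         "; observed/expected ratio undefined", call. = FALSE)
  }
  list(frequencies = freq, n_valid_pairs = n_valid, n_observed = n_obs,
       observed = observed, expected = expected, ratio = observed / expected)
}

#' Write dinucleotide sites as BED
#'
#' Writes 0-based half-open BED3 plus a fourth context column.
#'
#' @param sites data.frame as returned by [genome_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  stopifnot(all(c("chrom", "pos", "context") %in% names(sites)))
  bed <- data.frame(chrom = sites$chrom, start = sites$pos, end = sites$pos + 1L,
                    context = sites$context)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
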