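#' Read a genome from FASTA
#'
#' Loads a (possibly multi-contig, possibly gzipped) FASTA file into a
#' [Biostrings::DNAStringSet], uppercasing the sequence. Characters outside
#' the A/C/G/T/N alphabet are rejected, since downstream motif scanning and
#' simulation assume an unambiguous (or gap-N) genome.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet`, one element per contig, names taken from the
#'   first whitespace-delimited token of each FASTA header.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  bad <- setdiff(unique(unlist(strsplit(as.character(x), ""))),
                 c("A", "C", "G", "T", "N"))
  if (length(bad) > 0)
    stop("genome contains characters outside {A,C,G,T,N}: ",
         paste(bad, collapse = ", "))
  x
}

#' Coerce to a genome object
#'
#' Accepts a `DNAStringSet` or a named character vector of contig sequences.
#' @param genome Genome input.
#' @return A `DNAStringSet`.
#' @keywords internal
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome)) {
    if (is.null(names(genome))) names(genome) <- paste0("contig", seq_along(genome))
    return(Biostrings::DNAStringSet(toupper(genome)))
  }
  stop("genome must be a DNAStringSet or a named character vector")
}

#' Specify a PT consensus motif
#'
#' A PT (phosphorothioate) consensus motif is a short recognition sequence
#' carrying one PT internucleotide linkage. Single-stranded motifs (e.g. CCA
#' in Ssp systems, whose complement TGG is unmodified) are modified on one
#' strand only; bistranded motifs (e.g. GAAC/GTTC in Dnd systems) carry one
#' PT linkage per strand at the same duplex locus.
#'
#' @param recognition Recognition sequence over A/C/G/T (e.g. `"CCA"`,
#'   `"GAAC"`, `"GGCC"`).
#' @param mode `"single_stranded"` or `"bistranded"`.
#' @param linkage_offset Index of the PT linkage within the motif: the
#'   phosphate sits between bases `linkage_offset - 1` and `linkage_offset`
#'   (0-based bases). Default 1, i.e. between the first and second base, as
#'   in 5'-C_PS_CA-3' and 5'-G_PS_AAC-3'.
#' @return A `motif_spec` object (list with fields `recognition`, `mode`,
#'   `linkage_offset`, `palindromic`).
#' @examples
#' motif_spec("CCA", "single_stranded")
#' motif_spec("GAAC", "bistranded")
#' @export
motif_spec <- function(recognition,
                       mode = c("single_stranded", "bistranded"),
                       linkage_offset = 1L) {
  mode <- match.arg(mode)
  recognition <- toupper(recognition)
  if (!grepl("^[ACGT]+$", recognition))
    stop("recognition must be a non-empty string over {A,C,G,T}")
  linkage_offset <- as.integer(linkage_offset)
  if (linkage_offset <= 0L || linkage_offset >= nchar(recognition))
    stop("linkage_offset must satisfy 0 < linkage_offset < nchar(recognition)")
  rc <- revcomp(recognition)
  structure(
    list(recognition = recognition, mode = mode,
         linkage_offset = linkage_offset,
         palindromic = identical(recognition, rc)),
    class = "motif_spec")
}

#' Reverse complement of a DNA string
#' @param x A DNA string over A/C/G/T/N.
#' @return The reverse complement.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# All (overlapping) 0-based start positions of `pattern` in `subject`.
# Biostrings::matchPattern reports overlapping matches; fixed = TRUE means
# N in the subject never matches a literal base.
match_starts0 <- function(pattern, subject) {
  m <- Biostrings::matchPattern(pattern, subject, fixed = TRUE)
  BiocGenerics::start(m) - 1L
}

#' Scan a genome for PT consensus motif sites
#'
#' Locates every (overlapping) match of the motif on both strands.
#'
#' In `single_stranded` mode, forward-strand matches of the recognition
#' sequence are reported on strand `+` and forward-strand matches of its
#' reverse complement on strand `-`; the two strands carry independent PT
#' sites. In `bistranded` mode each match is one duplex locus carrying a PT
#' linkage on each strand; matches of the recognition sequence and of its
#' reverse complement are distinct duplex loci except for palindromic motifs
#' (e.g. GGCC), where each locus is reported once.
#'
#' `linkage_pos` projects the PT linkage onto forward coordinates: for a `+`
#' site at 0-based `start` it is `start + linkage_offset`; for a `-` site it
#' is `start + nchar(recognition) - linkage_offset`. Windows containing N
#' never match.
#'
#' @param genome A `DNAStringSet` (or named character vector).
#' @param spec A [motif_spec()].
#' @return A data.frame of sites, sorted by (contig, linkage_pos), with
#'   columns `contig`, `start` (0-based), `end` (exclusive), `strand`,
#'   `linkage_pos` (0-based), `motif`, `duplex`.
#' @examples
#' scan_motifs(c(chr = "CCACCA"), motif_spec("CCA", "single_stranded"))
#' @export
scan_motifs <- function(genome, spec) {
  stopifnot(inherits(spec, "motif_spec"))
  genome <- as_genome(genome)
  L <- nchar(spec$recognition)
  rc <- revcomp(spec$recognition)
  rows <- vector("list", length(genome))
  for (i in seq_along(genome)) {
    contig <- names(genome)[i]
    subj <- genome[[i]]
    if (length(subj) < L) { rows[[i]] <- empty_sites(); next }
    fwd <- match_starts0(spec$recognition, subj)
    # For a palindromic bistranded motif the rc-orientation match is the
    # same duplex locus, reported once; in single-stranded mode the two
    # strands are distinct PT sites even when the motif is palindromic.
    rev <- if (spec$palindromic && spec$mode == "bistranded") integer(0)
           else match_starts0(rc, subj)
    df <- rbind(
      site_rows(contig, fwd, "+", L, spec),
      site_rows(contig, rev, "-", L, spec))
    df$duplex <- rep(spec$mode == "bistranded", nrow(df))
    rows[[i]] <- df
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_sites())
  out <- out[order(out$contig, out$linkage_pos, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

site_rows <- function(contig, starts, strand, L, spec) {
  linkage <- if (strand == "+") starts + spec$linkage_offset
             else starts + L - spec$linkage_offset
  data.frame(
    contig = rep(contig, length(starts)),
    start = as.integer(starts),
    end = as.integer(starts + L),
    strand = rep(strand, length(starts)),
    linkage_pos = as.integer(linkage),
    motif = rep(spec$recognition, length(starts)),
    stringsAsFactors = FALSE)
}

empty_sites <- function() {
  data.frame(contig = character(0), start = integer(0), end = integer(0),
             strand = character(0), linkage_pos = integer(0),
             motif = character(0), duplex = logical(0),
             stringsAsFactors = FALSE)
}

#' Inter-site spacing under full modification
#'
#' The spacing null: successive differences of PT linkage coordinates over
#' the combined (both-strand) sorted site list of one contig. This is the
#' spacing distribution that would be observed if every consensus site were
#' modified and labeled at infinite optical resolution.
#'
#' @param sites Site table from [scan_motifs()], all rows from one contig.
#' @return Integer vector of bp distances, length `nrow(sites) - 1` (empty
#'   for fewer than 2 sites).
#' @export
spacing_null <- function(sites) {
  if (nrow(sites) == 0) return(integer(0))
  if (length(unique(sites$contig)) > 1)
    stop("spacing_null expects sites from a single contig")
  pos <- sort(sites$linkage_pos)
  if (length(pos) < 2) return(integer(0))
  diff(pos)
}

#' Write motif sites as BED6
#'
#' One line per site: contig, 0-based half-open interval covering the motif
#' match, name = motif string, score 0, strand. Tab-separated, no header.
#'
#' @param sites Site table from [scan_motifs()], sorted.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(sites, path) {
  bed <- data.frame(sites$contig, sites$start, sites$end, sites$motif,
                    rep(0L, nrow(sites)), sites$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 site file written by [write_bed()]
#'
#' Reconstructs the site table, recomputing `linkage_pos` from the interval,
#' strand and linkage offset.
#'
#' @param path BED6 path.
#' @param linkage_offset PT linkage offset used when the sites were scanned.
#' @param duplex Logical; whether the sites are duplex (bistranded) loci.
#' @return A site data.frame as from [scan_motifs()].
#' @export
read_bed <- function(path, linkage_offset = 1L, duplex = FALSE) {
  if (file.size(path) == 0) return(empty_sites())
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("contig", "start", "end", "name",
                                         "score", "strand"),
                           stringsAsFactors = FALSE)
  L <- bed$end - bed$start
  linkage <- ifelse(bed$strand == "+", bed$start + linkage_offset,
                    bed$start + L - linkage_offset)
  out <- data.frame(contig = bed$contig, start = as.integer(bed$start),
                    end = as.integer(bed$end), strand = bed$strand,
                    linkage_pos = as.integer(linkage), motif = bed$name,
                    duplex = rep(duplex, nrow(bed)),
                    stringsAsFactors = FALSE)
  out[order(out$contig, out$linkage_pos, out$start), , drop = FALSE]
}
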