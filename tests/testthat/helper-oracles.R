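# Independent brute-force oracles, deliberately implemented with plain
# string/matrix operations so they share no code with the package.

oracle_revcomp <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(x, "")[[1]]]), collapse = "")
}

# position-by-position scan of one sequence; returns the same columns as
# scan_motifs(), unsorted
oracle_scan <- function(seq, recognition, mode, linkage_offset = 1L) {
  L <- nchar(recognition)
  n <- nchar(seq)
  hits <- function(pat) {
    if (n < L) return(integer(0))
    starts <- 1:(n - L + 1)
    which(substring(seq, starts, starts + L - 1) == pat) - 1L
  }
  rc <- oracle_revcomp(recognition)
  fwd <- hits(recognition)
  rev <- if (mode == "bistranded" && recognition == rc) integer(0)
         else hits(rc)
  rbind(
    data.frame(start = fwd, strand = rep("+", length(fwd)),
               linkage_pos = fwd + linkage_offset),
    data.frame(start = rev, strand = rep("-", length(rev)),
               linkage_pos = rev + L - linkage_offset))
}

# O(n^2) transitive closure of the "closer than r" relation, then
# connected-component means and sizes
oracle_collapse <- function(pos, r) {
  n <- length(pos)
  if (n == 0) return(data.frame(position_nm = numeric(0),
                                multiplicity = integer(0)))
  adj <- abs(outer(pos, pos, "-")) < r
  reach <- adj | diag(n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) { cid <- cid + 1L; comp[which(reach[i, ])] <- cid }
  }
  out <- data.frame(
    position_nm = as.numeric(tapply(pos, comp, mean)),
    multiplicity = as.integer(tapply(pos, comp, length)))
  out[order(out$position_nm), ]
}

# exhaustive two-molecule pattern identity probability over m iid sites
oracle_identity_prob <- function(m, f) {
  if (m == 0) return(1)
  patterns <- as.matrix(expand.grid(rep(list(0:1), m)))
  pr <- apply(patterns, 1, function(x) prod(ifelse(x == 1, f, 1 - f)))
  sum(pr^2)  # P(two independent molecules draw the same pattern)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# a small fully-specified true molecule for chemistry tests
toy_molecule <- function(len, linkage_pos, strands,
                         modified = seq_along(linkage_pos),
                         native_left_end = TRUE, duplex = FALSE) {
  k <- length(linkage_pos)
  sites <- data.frame(
    contig = rep("chr", k), start = pmax(linkage_pos - 1L, 0L),
    end = pmax(linkage_pos - 1L, 0L) + 3L, strand = strands,
    linkage_pos = as.integer(linkage_pos), motif = rep("CCA", k),
    duplex = rep(duplex, k), stringsAsFactors = FALSE)
  structure(list(id = "toy", contig = "chr", start = 0L, end = as.integer(len),
                 sites = sites, native_left_end = native_left_end,
                 modified = as.integer(modified)),
            class = "true_molecule")
}

toy_fragment <- function(len, pos, provenance = rep("pt", length(pos)),
                         end_label = FALSE, origin = 0L,
                         has_left_end = origin == 0L) {
  structure(list(length = len,
                 labels = data.frame(pos = pos, provenance = provenance,
                                     stringsAsFactors = FALSE),
                 end_label_left = end_label, parent = "toy",
                 origin_offset = origin,
                 has_native_left_end = has_left_end),
            class = "labeled_fragment")
}
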