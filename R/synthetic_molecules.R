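#' Generate a random genome
#'
#' Synthesizes contigs of i.i.d. nucleotides at a given GC content. Used to
#' build study-scale genomes (e.g. a 48,502 bp linear phage-like standard)
#' without shipping sequence data.
#'
#' @param lengths Named integer vector of contig lengths in bp.
#' @param gc GC content in [0, 1] (default 0.5).
#' @param seed Optional integer seed.
#' @return A `DNAStringSet`.
#' @export
random_genome <- function(lengths, gc = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(lengths)))
    names(lengths) <- paste0("contig", seq_along(lengths))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(lengths, function(n) {
    paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(seqs)
}

#' Per-molecule PT occupancy model
#'
#' Describes how PT modifications are placed over consensus sites within one
#' molecule. `iid` mode modifies each site independently with probability
#' `f` (the occupancy fraction; population studies report 10-15%).
#' `clustered` mode runs a first-order Markov chain along the site order
#' with stationary occupancy `f` and persistence `rho`:
#' `P(mod | previous mod) = rho + (1 - rho) f` and
#' `P(mod | previous unmod) = (1 - rho) f`, so `rho = 0` reduces exactly to
#' `iid`.
#'
#' @param f Occupancy fraction in [0, 1]. Default 0.12.
#' @param mode `"iid"` or `"clustered"`.
#' @param rho Persistence probability in [0, 1) for clustered mode.
#' @return A `modification_model` object.
#' @export
modification_model <- function(f = 0.12, mode = c("iid", "clustered"),
                               rho = 0) {
  mode <- match.arg(mode)
  if (f < 0 || f > 1) stop("f must be in [0, 1]")
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  structure(list(f = f, mode = mode, rho = rho),
            class = "modification_model")
}

#' Sample molecule templates from a genome
#'
#' Draws `n` molecule intervals from one contig and attaches the consensus
#' sites falling inside each interval, in molecule-local coordinates.
#' `fixed` mode with the default length produces identical whole-contig
#' molecules (the full-length linear-genome design used with phage lambda);
#' `lognormal` mode draws lengths from a lognormal, places the start
#' uniformly, and truncates at the contig end (random genomic fragments).
#'
#' @param genome A `DNAStringSet` or named character vector.
#' @param n Number of molecules (>= 1).
#' @param sites Site table from [scan_motifs()] (may span several contigs;
#'   only rows of `contig` are used).
#' @param length_model `"fixed"` or `"lognormal"`.
#' @param length_bp Molecule length for `fixed` mode; defaults to the contig
#'   length.
#' @param meanlog,sdlog Lognormal parameters (bp scale) for
#'   `"lognormal"` mode.
#' @param contig Contig to sample from (default: first).
#' @param seed Optional integer seed.
#' @return List of `molecule_template` objects, each a list with `id`,
#'   `contig`, `start`, `end` (0-based half-open, genome coordinates),
#'   `sites` (local-coordinate site table) and `native_left_end` (TRUE iff
#'   the molecule starts at the contig's left terminus, hence eligible for
#'   the orientation end label).
#' @export
sample_molecules <- function(genome, n, sites,
                             length_model = c("fixed", "lognormal"),
                             length_bp = NULL, meanlog = log(20e3),
                             sdlog = 0.5, contig = NULL, seed = NULL) {
  length_model <- match.arg(length_model)
  genome <- as_genome(genome)
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(contig)) contig <- names(genome)[1]
  clen <- nchar(as.character(genome[[contig]]))
  csites <- sites[sites$contig == contig, , drop = FALSE]

  if (length_model == "fixed") {
    if (is.null(length_bp)) length_bp <- clen
    if (length_bp > clen)
      stop("fixed length_bp exceeds contig length (", clen, " bp)")
    starts <- if (length_bp == clen) rep(0L, n)
              else sample.int(clen - length_bp + 1L, n, replace = TRUE) - 1L
    ends <- starts + as.integer(length_bp)
  } else {
    if (meanlog <= 0 || sdlog <= 0) stop("lognormal parameters must be positive")
    lens <- pmax(1L, as.integer(round(stats::rlnorm(n, meanlog, sdlog))))
    starts <- as.integer(floor(stats::runif(n, 0, clen)))
    ends <- pmin(starts + lens, clen)
  }

  lapply(seq_len(n), function(i) {
    keep <- csites$linkage_pos >= starts[i] & csites$linkage_pos < ends[i]
    loc <- csites[keep, , drop = FALSE]
    loc$start <- loc$start - starts[i]
    loc$end <- loc$end - starts[i]
    loc$linkage_pos <- loc$linkage_pos - starts[i]
    loc <- loc[order(loc$linkage_pos), , drop = FALSE]
    rownames(loc) <- NULL
    structure(
      list(id = sprintf("mol%05d", i), contig = contig,
           start = starts[i], end = ends[i], sites = loc,
           native_left_end = starts[i] == 0L),
      class = "molecule_template")
  })
}

#' Place PT modifications on a molecule
#'
#' Draws the per-molecule set of modified sites under a
#' [modification_model()]. Bistranded duplex sites are modified as a unit
#' (one draw per duplex locus); single-stranded sites on opposite strands
#' are independent. Draws are independent across molecules, which is the
#' statistical origin of molecule-to-molecule PT heterogeneity.
#'
#' @param template A `molecule_template`.
#' @param model A [modification_model()].
#' @return A `true_molecule`: the template plus `modified`, an integer
#'   vector of modified row indices into `template$sites`.
#' @export
place_modifications <- function(template, model) {
  stopifnot(inherits(template, "molecule_template"),
            inherits(model, "modification_model"))
  m <- nrow(template$sites)
  mod <- if (m == 0) {
    integer(0)
  } else if (model$mode == "iid" || model$rho == 0) {
    which(stats::runif(m) < model$f)
  } else {
    state <- logical(m)
    u <- stats::runif(m)
    state[1] <- u[1] < model$f
    p11 <- model$rho + (1 - model$rho) * model$f
    p01 <- (1 - model$rho) * model$f
    for (i in seq_len(m)[-1])
      state[i] <- u[i] < (if (state[i - 1]) p11 else p01)
    which(state)
  }
  structure(c(unclass(template), list(modified = mod)),
            class = "true_molecule")
}

#' Probability two molecules share an identical PT pattern
#'
#' Under independent i.i.d. occupancy with fraction `f` over `m` sites, the
#' probability that two molecules agree at one site is `f^2 + (1 - f)^2`,
#' so the probability of a fully identical pattern is
#' `(f^2 + (1 - f)^2)^m`. At genome scale (thousands of sites) this is
#' astronomically small, which is why identical PT profiles are never
#' expected between single molecules.
#'
#' @param m Number of consensus sites (>= 0).
#' @param f Occupancy fraction in [0, 1].
#' @return The identity probability.
#' @examples
#' pattern_identity_probability(5, 0.12)
#' @export
pattern_identity_probability <- function(m, f) {
  if (m < 0) stop("m must be >= 0")
  if (f < 0 || f > 1) stop("f must be in [0, 1]")
  (f^2 + (1 - f)^2)^m
}

#' Write true molecules as a table
#'
#' One row per molecule: id, interval, site count, and the local
#' coordinates of modified sites (comma-separated).
#'
#' @param molecules List of `true_molecule` objects.
#' @param path Output path (TSV with header).
#' @return `path`, invisibly.
#' @export
write_molecule_table <- function(molecules, path) {
  df <- data.frame(
    id = vapply(molecules, `[[`, character(1), "id"),
    contig = vapply(molecules, `[[`, character(1), "contig"),
    start = vapply(molecules, `[[`, integer(1), "start"),
    end = vapply(molecules, `[[`, integer(1), "end"),
    n_sites = vapply(molecules, function(m) nrow(m$sites), integer(1)),
    modified_local_bp = vapply(molecules, function(m) {
      paste(m$sites$linkage_pos[m$modified], collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
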