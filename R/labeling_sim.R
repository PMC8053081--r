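#' Labeling chemistry parameters
#'
#' Parameters of the two PT labeling chemistries.
#'
#' For single-stranded PT sites, iodine cleaves the PT linkage into a
#' strand-specific nick; nick translation then deposits a fluorescent label.
#' Cleavage is treated as certain for modified sites, with all losses lumped
#' into `p_label_nick`. Residual nicks surviving the polymerase/ddNTP
#' blocking step appear as a background Poisson process. Two nicks on
#' opposite strands closer than `d_break` destabilize the duplex and produce
#' a double-strand break, which fragments the molecule and leaves labels at
#' the new fragment extremities.
#'
#' For bistranded PT sites, covalent alkylation (iodoacetyl-PEG2-biotin)
#' followed by streptavidin-quantum-dot attachment labels each modified
#' duplex with probability `p_label_qd` and causes no breakage; the default
#' 0.92 is the measured coupling yield of the reagent on a one-PT
#' oligonucleotide after 12 h.
#'
#' @param p_label_nick Probability a nick yields a fluorescent label
#'   (default 0.8; lumps cleavage and fill-in efficiency).
#' @param bg_nick_rate Expected background nicks per bp per strand after
#'   blocking (default 1e-6).
#' @param d_break bp threshold below which opposing nicks produce a
#'   double-strand break (default 500).
#' @param p_label_qd Quantum-dot labeling probability per modified duplex
#'   site (default 0.92).
#' @param p_end_label Probability the native left end receives the
#'   orientation (end) label (default 0.7).
#' @return A `chemistry_params` object.
#' @export
chemistry_params <- function(p_label_nick = 0.8, bg_nick_rate = 1e-6,
                             d_break = 500, p_label_qd = 0.92,
                             p_end_label = 0.7) {
  p <- list(p_label_nick = p_label_nick, bg_nick_rate = bg_nick_rate,
            d_break = d_break, p_label_qd = p_label_qd,
            p_end_label = p_end_label)
  for (nm in c("p_label_nick", "p_label_qd", "p_end_label"))
    if (p[[nm]] < 0 || p[[nm]] > 1) stop(nm, " must be in [0, 1]")
  if (bg_nick_rate < 0) stop("bg_nick_rate must be >= 0")
  if (d_break < 0) stop("d_break must be >= 0")
  structure(p, class = "chemistry_params")
}

new_fragment <- function(length, labels, parent, origin_offset,
                         has_native_left_end) {
  labels <- labels[order(labels$pos), , drop = FALSE]
  rownames(labels) <- NULL
  structure(
    list(length = length, labels = labels, end_label_left = FALSE,
         parent = parent, origin_offset = origin_offset,
         has_native_left_end = has_native_left_end),
    class = "labeled_fragment")
}

empty_labels <- function() {
  data.frame(pos = numeric(0), provenance = character(0),
             stringsAsFactors = FALSE)
}

#' Simulate iodine nick conversion and fluorescent labeling
#'
#' Applies the single-stranded PT chemistry to one molecule:
#' \enumerate{
#'   \item every modified site becomes a strand-specific nick at its PT
#'     linkage coordinate;
#'   \item background nicks are added per strand as a Poisson process at
#'     `bg_nick_rate`;
#'   \item opposite-strand nick pairs closer than `d_break` bp break the
#'     duplex at the (floored) midpoint; each nick joins at most one break
#'     and pairs are resolved left to right;
#'   \item surviving nicks become labels with probability `p_label_nick`;
#'     nicks consumed by a break surface, with the same probability, as
#'     `break_end` labels on the extremities flanking the junction;
#'   \item fragment lengths always sum exactly to the molecule length.
#' }
#'
#' @param mol A `true_molecule` whose sites are single-stranded.
#' @param params A [chemistry_params()].
#' @return List of `labeled_fragment` objects ordered left to right. Each
#'   has `length` (bp), `labels` (data.frame `pos` in fragment-local bp,
#'   `provenance` in pt/background/break_end), `parent`, `origin_offset`
#'   and `has_native_left_end`.
#' @export
simulate_nick_labeling <- function(mol, params) {
  stopifnot(inherits(mol, "true_molecule"),
            inherits(params, "chemistry_params"))
  len <- mol$end - mol$start
  msites <- mol$sites[mol$modified, , drop = FALSE]
  if (any(msites$duplex))
    stop("simulate_nick_labeling expects single-stranded sites")
  nicks <- data.frame(pos = msites$linkage_pos, strand = msites$strand,
                      provenance = rep("pt", nrow(msites)),
                      stringsAsFactors = FALSE)
  n_bg <- stats::rpois(2, params$bg_nick_rate * len)
  if (sum(n_bg) > 0) {
    bg <- data.frame(
      pos = floor(stats::runif(sum(n_bg), 0, len)),
      strand = rep(c("+", "-"), n_bg),
      provenance = "background", stringsAsFactors = FALSE)
    nicks <- rbind(nicks, bg)
  }
  nicks <- nicks[order(nicks$pos), , drop = FALSE]

  # Left-to-right greedy pairing of opposing nicks within d_break.
  n <- nrow(nicks)
  consumed <- logical(n)
  breaks <- integer(0)
  break_of <- rep(NA_integer_, n)   # break index each consumed nick joined
  for (i in seq_len(n)) {
    if (consumed[i]) next
    j <- which(!consumed & seq_len(n) > i &
                 nicks$strand != nicks$strand[i] &
                 abs(nicks$pos - nicks$pos[i]) < params$d_break)
    if (length(j) == 0) next
    j <- j[1]
    consumed[c(i, j)] <- TRUE
    breaks <- c(breaks, as.integer(floor((nicks$pos[i] + nicks$pos[j]) / 2)))
    break_of[c(i, j)] <- length(breaks)
  }

  cuts <- sort(unique(breaks))
  cuts <- cuts[cuts > 0L & cuts < len]   # a cut at a terminus severs nothing
  bounds <- c(0L, cuts, len)
  nfrag <- length(bounds) - 1L
  labeled <- !consumed & stats::runif(n) < params$p_label_nick
  # one draw per consumed nick for its break_end label
  break_labeled <- consumed & stats::runif(n) < params$p_label_nick

  fi <- integer(0); fpos <- numeric(0); fprov <- character(0)
  if (any(labeled)) {
    idx <- findInterval(nicks$pos[labeled], bounds)
    fi <- idx
    fpos <- nicks$pos[labeled] - bounds[idx]
    fprov <- nicks$provenance[labeled]
  }
  if (any(break_labeled)) {
    bpos <- breaks[break_of[break_labeled]]
    kleft <- match(bpos, bounds) - 1L        # fragment ending at the break
    is_left <- nicks$pos[break_labeled] <= bpos
    k2 <- ifelse(is_left, kleft, kleft + 1L)
    k2 <- pmin(pmax(k2, 1L), nfrag)
    p2 <- bpos - bounds[k2]   # = length of the left fragment, 0 on the right
    fi <- c(fi, k2); fpos <- c(fpos, p2)
    fprov <- c(fprov, rep("break_end", length(k2)))
  }
  by_frag <- split(seq_along(fi), factor(fi, levels = seq_len(nfrag)))
  frags <- vector("list", nfrag)
  for (k in seq_len(nfrag)) {
    sel <- by_frag[[k]]
    lab <- list2DF(list(pos = fpos[sel], provenance = fprov[sel]))
    frags[[k]] <- new_fragment(bounds[k + 1L] - bounds[k], lab, mol$id,
                               bounds[k], mol$native_left_end &&
                                 bounds[k] == 0L)
  }
  frags
}

#' Simulate quantum-dot labeling of bistranded PT sites
#'
#' Covalent labeling causes no breakage: the molecule stays one fragment
#' and each modified duplex site yields a label with probability
#' `p_label_qd` at its linkage coordinate. No background labels.
#'
#' @param mol A `true_molecule` whose sites are bistranded duplex loci.
#' @param params A [chemistry_params()].
#' @return A single `labeled_fragment`.
#' @export
simulate_qd_labeling <- function(mol, params) {
  stopifnot(inherits(mol, "true_molecule"),
            inherits(params, "chemistry_params"))
  len <- mol$end - mol$start
  msites <- mol$sites[mol$modified, , drop = FALSE]
  if (nrow(msites) > 0 && !all(msites$duplex))
    stop("simulate_qd_labeling expects bistranded (duplex) sites")
  keep <- stats::runif(nrow(msites)) < params$p_label_qd
  lab <- data.frame(pos = msites$linkage_pos[keep],
                    provenance = rep("pt", sum(keep)),
                    stringsAsFactors = FALSE)
  new_fragment(len, lab, mol$id, 0L, mol$native_left_end)
}

#' Attach the orientation end label
#'
#' A dye-tagged oligonucleotide ligated to the genome's left 5' overhang
#' marks molecule orientation. Only a fragment containing the parent
#' molecule's native left end is eligible; an eligible fragment is labeled
#' with probability `p_end_label`.
#'
#' @param fragment A `labeled_fragment`.
#' @param params A [chemistry_params()].
#' @return The fragment with `end_label_left` set.
#' @export
attach_end_label <- function(fragment, params) {
  stopifnot(inherits(fragment, "labeled_fragment"),
            inherits(params, "chemistry_params"))
  fragment$end_label_left <- fragment$has_native_left_end &&
    stats::runif(1) < params$p_end_label
  fragment
}

#' Write labeled fragments as a table
#'
#' One row per label (plus one row for label-free fragments), TSV with
#' header: molecule id, fragment id, origin offset, length, label bp,
#' provenance, end-label flag.
#'
#' @param fragments List of `labeled_fragment` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragment_table <- function(fragments, path) {
  nlab <- vapply(fragments, function(f) nrow(f$labels), integer(1))
  reps <- pmax(nlab, 1L)   # label-free fragments keep one NA row
  lab_bp <- unlist(lapply(fragments, function(f)
    if (nrow(f$labels) == 0) NA_real_ else f$labels$pos), use.names = FALSE)
  prov <- unlist(lapply(fragments, function(f)
    if (nrow(f$labels) == 0) NA_character_ else f$labels$provenance),
    use.names = FALSE)
  df <- list2DF(list(
    molecule_id = rep(vapply(fragments, `[[`, character(1), "parent"), reps),
    fragment_id = rep(seq_along(fragments), reps),
    origin_offset = rep(vapply(fragments, function(f)
      as.numeric(f$origin_offset), numeric(1)), reps),
    length_bp = rep(vapply(fragments, function(f)
      as.numeric(f$length), numeric(1)), reps),
    label_bp = lab_bp,
    provenance = prov,
    end_label_left = rep(vapply(fragments, `[[`, logical(1),
                                "end_label_left"), reps)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
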