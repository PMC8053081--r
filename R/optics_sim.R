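#' Combing and imaging parameters
#'
#' Physical constants and optical properties of the combing assay. B-form
#' DNA has a contour length of 0.34 nm/bp; flow-stretched (combed)
#' molecules extend to a near-constant fraction of that contour, 94.2 % on
#' average for the lambda standards, with small molecule-to-molecule
#' variation. Diffraction limits the minimum resolvable separation of two
#' fluorophores to a few hundred nm, and each spot's localization carries
#' jitter of tens of nm.
#'
#' @param nm_per_bp_B B-DNA contour length per bp (nm; default 0.34).
#' @param stretch_mean Mean stretch fraction (default 0.942).
#' @param stretch_sd Per-molecule stretch standard deviation (default 0.02).
#' @param resolution_nm Minimum resolvable separation (default 300).
#' @param localization_sd_nm Positional jitter of each resolved spot
#'   (default 50).
#' @param pixel_nm Rendering grid spacing (default 100).
#' @param psf_sigma_nm Gaussian point-spread sigma for rendering
#'   (default 150).
#' @return An `optics_params` object.
#' @export
optics_params <- function(nm_per_bp_B = 0.34, stretch_mean = 0.942,
                          stretch_sd = 0.02, resolution_nm = 300,
                          localization_sd_nm = 50, pixel_nm = 100,
                          psf_sigma_nm = 150) {
  p <- list(nm_per_bp_B = nm_per_bp_B, stretch_mean = stretch_mean,
            stretch_sd = stretch_sd, resolution_nm = resolution_nm,
            localization_sd_nm = localization_sd_nm, pixel_nm = pixel_nm,
            psf_sigma_nm = psf_sigma_nm)
  if (any(unlist(p[c("nm_per_bp_B", "stretch_mean", "pixel_nm",
                     "psf_sigma_nm")]) <= 0))
    stop("nm_per_bp_B, stretch_mean, pixel_nm and psf_sigma_nm must be > 0")
  if (stretch_sd < 0 || resolution_nm < 0 || localization_sd_nm < 0)
    stop("stretch_sd, resolution_nm and localization_sd_nm must be >= 0")
  structure(p, class = "optics_params")
}

# One stretch fraction per molecule, truncated to (0, 1.1].
draw_stretch <- function(params) draw_stretch_n(1L, params)

draw_stretch_n <- function(n, params) {
  s <- stats::rnorm(n, params$stretch_mean, params$stretch_sd)
  bad <- which(s <= 0 | s > 1.1)
  while (length(bad) > 0) {
    s[bad] <- stats::rnorm(length(bad), params$stretch_mean,
                           params$stretch_sd)
    bad <- bad[s[bad] <= 0 | s[bad] > 1.1]
  }
  s
}

#' Comb a labeled fragment onto physical coordinates
#'
#' Draws one stretch fraction `s` for the molecule and maps every bp
#' coordinate `x` to `x * nm_per_bp_B * s` nm. The map is affine and
#' strictly monotone: spacings in nm are exactly `delta_bp * 0.34 * s`.
#' No optical noise is applied at this stage.
#'
#' @param fragment A `labeled_fragment`.
#' @param params An [optics_params()].
#' @param stretch Optional fixed stretch fraction (bypasses the random
#'   draw, e.g. for calibration arithmetic).
#' @return A `combed_fragment`: list with `backbone_um`, `stretch`,
#'   `labels_nm` (data.frame `pos_nm`, `channel` in PT/end), `parent`.
#' @export
comb <- function(fragment, params, stretch = NULL) {
  stopifnot(inherits(fragment, "labeled_fragment"),
            inherits(params, "optics_params"))
  s <- if (is.null(stretch)) draw_stretch(params) else stretch
  scale <- params$nm_per_bp_B * s
  pos_nm <- fragment$labels$pos * scale
  channel <- rep("PT", length(pos_nm))
  if (isTRUE(fragment$end_label_left)) {
    pos_nm <- c(0, pos_nm)
    channel <- c("end", channel)
  }
  structure(
    list(backbone_um = fragment$length * scale / 1000, stretch = s,
         labels_nm = data.frame(pos_nm = pos_nm, channel = channel,
                                stringsAsFactors = FALSE),
         parent = fragment$parent),
    class = "combed_fragment")
}

#' Collapse labels into diffraction-limited spots
#'
#' Single-linkage 1D clustering: consecutive positions closer than
#' `resolution_nm` belong to one cluster, chains merging transitively. Each
#' cluster becomes one resolvable spot at the arithmetic mean of its
#' members with multiplicity equal to the cluster size, so multiplicities
#' always sum to the input label count.
#'
#' @param positions_nm Sorted numeric vector of label positions (nm).
#' @param resolution_nm Minimum resolvable separation (nm).
#' @return data.frame with `position_nm`, `multiplicity`.
#' @examples
#' collapse_spots(c(0, 100, 2000), 300)
#' @export
collapse_spots <- function(positions_nm, resolution_nm) {
  n <- length(positions_nm)
  if (n == 0)
    return(data.frame(position_nm = numeric(0), multiplicity = integer(0)))
  if (is.unsorted(positions_nm)) stop("positions_nm must be sorted")
  cluster <- cumsum(c(1L, as.integer(diff(positions_nm) >= resolution_nm)))
  data.frame(
    position_nm = as.numeric(tapply(positions_nm, cluster, mean)),
    multiplicity = as.integer(tapply(positions_nm, cluster, length)),
    row.names = NULL)
}

#' Image a combed fragment as resolvable spots
#'
#' Applies diffraction-limited merging per channel and adds localization
#' jitter to each resolved spot (truncated to the backbone extent).
#'
#' @param combed A `combed_fragment` from [comb()].
#' @param params An [optics_params()].
#' @param jitter Logical; apply localization jitter (default TRUE).
#' @return An `optical_molecule`: list with `backbone_um`, `stretch`,
#'   `spots` (data.frame `position_um`, `multiplicity`, `channel`) and
#'   `parent`.
#' @export
resolve_spots <- function(combed, params, jitter = TRUE) {
  stopifnot(inherits(combed, "combed_fragment"),
            inherits(params, "optics_params"))
  backbone_nm <- combed$backbone_um * 1000
  out <- lapply(unique(combed$labels_nm$channel), function(ch) {
    pos <- sort(combed$labels_nm$pos_nm[combed$labels_nm$channel == ch])
    sp <- collapse_spots(pos, params$resolution_nm)
    if (jitter && nrow(sp) > 0 && params$localization_sd_nm > 0) {
      sp$position_nm <- pmin(pmax(
        sp$position_nm + stats::rnorm(nrow(sp), 0, params$localization_sd_nm),
        0), backbone_nm)
    }
    sp$channel <- rep(ch, nrow(sp))
    sp
  })
  spots <- do.call(rbind, out)
  if (is.null(spots))
    spots <- data.frame(position_nm = numeric(0), multiplicity = integer(0),
                        channel = character(0))
  spots <- spots[order(spots$position_nm), , drop = FALSE]
  structure(
    list(backbone_um = combed$backbone_um, stretch = combed$stretch,
         spots = data.frame(position_um = spots$position_nm / 1000,
                            multiplicity = spots$multiplicity,
                            channel = spots$channel,
                            stringsAsFactors = FALSE),
         parent = combed$parent),
    class = "optical_molecule")
}

#' Image many fragments at once
#'
#' Bulk equivalent of [comb()] followed by [resolve_spots()] over a list of
#' fragments, producing the long-format spot table directly. All fragments
#' are laid end to end on one axis with inter-fragment gaps wider than the
#' resolution, so a single single-linkage pass collapses labels exactly as
#' the per-fragment path does; stretch draws and localization jitter are
#' vectorized. With `stretch_sd = 0` and `localization_sd_nm = 0` the
#' output coincides with mapping [resolve_spots()] over the fragments.
#'
#' @param fragments List of `labeled_fragment` objects.
#' @param params An [optics_params()].
#' @param jitter Logical; apply localization jitter (default TRUE).
#' @return data.frame in the spot-table dialect (`molecule_id`,
#'   `backbone_um`, `end_labeled`, `spot_position_um`, `channel`,
#'   `multiplicity`); fragments with no spots contribute one NA-spot row so
#'   every observed molecule is represented.
#' @export
observe_fragments <- function(fragments, params, jitter = TRUE) {
  nf <- length(fragments)
  ids <- vapply(seq_len(nf), function(k)
    sprintf("%s.f%03d", fragments[[k]]$parent, k), character(1))
  lens <- vapply(fragments, `[[`, numeric(1), "length")
  nlab <- vapply(fragments, function(f) nrow(f$labels), integer(1))
  endlab <- vapply(fragments, function(f) isTRUE(f$end_label_left),
                   logical(1))
  s <- draw_stretch_n(nf, params)
  scale <- params$nm_per_bp_B * s
  backbone_nm <- lens * scale
  # global axis: fragment k occupies [offset[k], offset[k] + backbone_nm[k]]
  gap <- params$resolution_nm + 1
  offset <- cumsum(c(0, backbone_nm[-nf] + gap))

  pos_local <- unlist(lapply(seq_len(nf), function(k)
    fragments[[k]]$labels$pos * scale[k]), use.names = FALSE)
  frag_of <- rep(seq_len(nf), nlab)
  gpos <- pos_local + offset[frag_of]
  sp <- collapse_spots(gpos, params$resolution_nm)
  sfrag <- findInterval(sp$position_nm, offset)
  spos <- sp$position_nm - offset[sfrag]
  if (jitter && nrow(sp) > 0 && params$localization_sd_nm > 0)
    spos <- pmin(pmax(spos + stats::rnorm(nrow(sp), 0,
                                          params$localization_sd_nm), 0),
                 backbone_nm[sfrag])

  # orientation (end) spots: at the left terminus of end-labeled fragments
  efrag <- which(endlab)
  epos <- rep(0, length(efrag))
  if (jitter && length(efrag) > 0 && params$localization_sd_nm > 0)
    epos <- pmin(pmax(stats::rnorm(length(efrag), 0,
                                   params$localization_sd_nm), 0),
                 backbone_nm[efrag])

  # fragments with no spots at all still appear, as one NA-spot row
  blank <- setdiff(seq_len(nf), union(sfrag, efrag))
  allfrag <- c(sfrag, efrag, blank)
  out <- list2DF(list(
    molecule_id = ids[allfrag],
    backbone_um = backbone_nm[allfrag] / 1000,
    end_labeled = endlab[allfrag],
    spot_position_um = c(spos, epos, rep(NA_real_, length(blank))) / 1000,
    channel = c(rep("PT", length(sfrag)), rep("end", length(efrag)),
                rep(NA_character_, length(blank))),
    multiplicity = c(sp$multiplicity, rep(1L, length(efrag)),
                     rep(NA_integer_, length(blank)))))
  out[order(match(out$molecule_id, ids), out$spot_position_um), ,
      drop = FALSE]
}

#' Render a 1D intensity profile
#'
#' Stands in for a confocal line scan: per channel, each spot contributes a
#' Gaussian of area proportional to its multiplicity, centered at its
#' position. The array covers the backbone extent at `pixel_nm` spacing;
#' pixel `i` is centered at `(i - 0.5) * pixel_nm` and values are scaled so
#' that the array sum approximates total multiplicity.
#'
#' @param optical An `optical_molecule`.
#' @param params An [optics_params()].
#' @return Named list of numeric vectors, one per channel, with attribute
#'   `pixel_nm`.
#' @export
render_profile <- function(optical, params) {
  stopifnot(inherits(optical, "optical_molecule"),
            inherits(params, "optics_params"))
  backbone_nm <- optical$backbone_um * 1000
  npx <- max(1L, as.integer(ceiling(backbone_nm / params$pixel_nm)))
  centers <- (seq_len(npx) - 0.5) * params$pixel_nm
  channels <- unique(optical$spots$channel)
  if (length(channels) == 0) channels <- "PT"
  out <- lapply(channels, function(ch) {
    sp <- optical$spots[optical$spots$channel == ch, , drop = FALSE]
    y <- numeric(npx)
    for (k in seq_len(nrow(sp))) {
      y <- y + sp$multiplicity[k] * params$pixel_nm *
        stats::dnorm(centers, sp$position_um[k] * 1000, params$psf_sigma_nm)
    }
    y
  })
  names(out) <- channels
  attr(out, "pixel_nm") <- params$pixel_nm
  out
}
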