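#' Call spots from a 1D intensity profile
#'
#' Local-maximum peak calling with sub-pixel refinement: candidate peaks
#' are strict local maxima above `min_prominence`; peaks closer than
#' `min_separation_px` are pruned keeping the brighter one; each surviving
#' peak position is refined by parabolic interpolation through the peak
#' pixel and its two neighbours.
#'
#' @param profile Numeric vector (one channel of [render_profile()]).
#' @param min_prominence Minimum peak height above the higher of the two
#'   flanking minima.
#' @param min_separation_px Minimum separation between called peaks, in
#'   pixels.
#' @param pixel_nm If given, returned positions are in nm (pixel centers at
#'   `(i - 0.5) * pixel_nm`); otherwise in fractional pixel units.
#' @return Numeric vector of called spot positions, sorted.
#' @export
call_spots <- function(profile, min_prominence = 0.05,
                       min_separation_px = 2, pixel_nm = NULL) {
  n <- length(profile)
  if (n < 3) return(numeric(0))
  y <- profile
  cand <- which(y[2:(n - 1)] >= y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
  if (length(cand) == 0) return(numeric(0))
  # prominence: height above the deeper valley toward each neighbouring
  # candidate (or the profile edge)
  prom <- vapply(seq_along(cand), function(k) {
    i <- cand[k]
    lo <- if (k == 1) 1L else cand[k - 1]
    hi <- if (k == length(cand)) n else cand[k + 1]
    y[i] - max(min(y[lo:i]), min(y[i:hi]))
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (length(keep) == 0) return(numeric(0))
  # enforce separation, brightest first
  keep <- keep[order(-y[keep])]
  sel <- integer(0)
  for (i in keep)
    if (all(abs(i - sel) >= min_separation_px)) sel <- c(sel, i)
  sel <- sort(sel)
  # parabolic sub-pixel refinement
  pos <- vapply(sel, function(i) {
    if (i <= 1 || i >= n) return(as.numeric(i))
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    delta <- if (denom == 0) 0 else 0.5 * (y[i - 1] - y[i + 1]) / denom
    i + max(min(delta, 0.5), -0.5)
  }, numeric(1))
  if (!is.null(pixel_nm)) pos <- (pos - 0.5) * pixel_nm
  sort(pos)
}

#' Calibrate the micrometre-to-kilobase conversion
#'
#' Standards of known genomic size (the 48.5-kb lambda genome in the
#' original assay) are combed alongside the samples; their mean measured
#' length fixes the conversion factor and the realized stretch fraction:
#' `kb_per_um = (genome_size_bp / 1000) / mean(lengths)` and
#' `stretch_fraction = mean(lengths) * 1000 / (genome_size_bp * nm_per_bp_B)`.
#'
#' @param standard_lengths_um Measured lengths (um) of the standards; all
#'   positive, at least one.
#' @param genome_size_bp True size of the standard genome in bp.
#' @param nm_per_bp_B B-form contour per bp (default 0.34 nm).
#' @return A `calibration_result`: list with `kb_per_um`,
#'   `stretch_fraction`, `n_standards`.
#' @examples
#' calibrate(15.53, 48502)  # kb_per_um ~ 3.123, stretch ~ 0.9417
#' @export
calibrate <- function(standard_lengths_um, genome_size_bp,
                      nm_per_bp_B = 0.34) {
  if (length(standard_lengths_um) == 0 || any(standard_lengths_um <= 0) ||
      anyNA(standard_lengths_um))
    stop("unusable calibration: need >= 1 positive standard length")
  mu <- mean(standard_lengths_um)
  structure(
    list(kb_per_um = (genome_size_bp / 1000) / mu,
         stretch_fraction = mu * 1000 / (genome_size_bp * nm_per_bp_B),
         n_standards = length(standard_lengths_um)),
    class = "calibration_result")
}

#' Build per-molecule records from a spot table
#'
#' Converts a long-format spot table (the documented exchange dialect, also
#' produced from simulations by [spot_table()]) into calibrated per-molecule
#' records. Molecules with an end label are oriented: PT spot positions are
#' measured from the end-labeled extremity (the end spot's side of the
#' backbone); unoriented molecules are measured from the lower coordinate.
#'
#' @param spots data.frame with columns `molecule_id`, `backbone_um`,
#'   `end_labeled` (logical), `spot_position_um`, `channel` (PT/end).
#'   Optional `multiplicity` (defaults to 1).
#' @param calib A [calibrate()] result.
#' @return A `molecule_records` object: list with `records` (one row per
#'   molecule: `id`, `backbone_um`, `backbone_kb`, `end_labeled`,
#'   `spot_count`) and `positions` (one row per PT spot: `molecule_id`,
#'   `position_um`, `position_kb`, `multiplicity`, oriented as described).
#' @export
molecule_records <- function(spots, calib) {
  stopifnot(inherits(calib, "calibration_result"))
  need <- c("molecule_id", "backbone_um", "end_labeled",
            "spot_position_um", "channel")
  miss <- setdiff(need, names(spots))
  if (length(miss) > 0)
    stop("spot table lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(spots$multiplicity)) spots$multiplicity <- 1L
  fid <- factor(spots$molecule_id, levels = unique(spots$molecule_id))
  rows <- split(seq_len(nrow(spots)), fid)
  ids <- levels(fid)
  backbone <- vapply(rows, function(i) spots$backbone_um[i[1]], numeric(1))
  end_lab <- vapply(rows, function(i) isTRUE(spots$end_labeled[i[1]]),
                    logical(1))
  posl <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    m <- rows[[k]]
    is_pt <- spots$channel[m] == "PT" & !is.na(spots$spot_position_um[m])
    pt <- m[which(is_pt)]
    pos <- spots$spot_position_um[pt]
    if (end_lab[k]) {
      endpos <- spots$spot_position_um[m][which(spots$channel[m] == "end")]
      # orient from the end-labeled extremity: flip if the end spot sits
      # nearer the high-coordinate end of the backbone
      if (length(endpos) > 0 && endpos[1] > backbone[k] / 2)
        pos <- backbone[k] - pos
    }
    o <- order(pos)
    posl[[k]] <- list(pos = pos[o], mult = spots$multiplicity[pt][o])
  }
  npos <- lengths(lapply(posl, `[[`, "pos"))
  pos_all <- unlist(lapply(posl, `[[`, "pos"), use.names = FALSE)
  if (is.null(pos_all)) pos_all <- numeric(0)
  mult_all <- unlist(lapply(posl, `[[`, "mult"), use.names = FALSE)
  if (is.null(mult_all)) mult_all <- integer(0)
  records <- list2DF(list(
    id = ids, backbone_um = unname(backbone),
    backbone_kb = unname(backbone) * calib$kb_per_um,
    end_labeled = unname(end_lab), spot_count = as.integer(npos)))
  positions <- list2DF(list(
    molecule_id = rep(ids, npos),
    position_um = pos_all,
    position_kb = pos_all * calib$kb_per_um,
    multiplicity = mult_all))
  structure(list(records = records, positions = positions,
                 calibration = calib),
            class = "molecule_records")
}

#' Flatten optical molecules into the spot-table dialect
#'
#' @param opticals List of `optical_molecule` objects.
#' @param end_labeled_ids Character vector of molecule ids carrying the
#'   orientation end label (their `end` channel spots are in the table).
#' @return data.frame in the exchange dialect accepted by
#'   [molecule_records()].
#' @export
spot_table <- function(opticals, end_labeled_ids = NULL) {
  rows <- lapply(seq_along(opticals), function(k) {
    o <- opticals[[k]]
    id <- if (!is.null(names(opticals))) names(opticals)[k]
          else sprintf("%s.f%02d", o$parent, k)
    end_lab <- "end" %in% o$spots$channel
    if (nrow(o$spots) == 0) {
      return(data.frame(molecule_id = id, backbone_um = o$backbone_um,
                        end_labeled = end_lab,
                        spot_position_um = NA_real_,
                        channel = NA_character_, multiplicity = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    data.frame(molecule_id = id, backbone_um = o$backbone_um,
               end_labeled = end_lab,
               spot_position_um = o$spots$position_um,
               channel = o$spots$channel,
               multiplicity = o$spots$multiplicity,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Select molecules for analysis
#'
#' The two selection criteria applied to combed molecules:
#' \describe{
#'   \item{A}{the molecule carries the orientation end label, is full
#'     length (within `length_tol` of the expected genome size) and has at
#'     least one PT spot — accurate positional PT profiling;}
#'   \item{B}{the molecule has at least two resolvable PT spots, so
#'     relative distances can be measured even without orientation.}
#' }
#' A molecule meeting both is tagged A.
#'
#' @param recs A `molecule_records` object.
#' @param expected_genome_kb Expected full-length size (kb).
#' @param length_tol Relative full-length tolerance (default 0.05).
#' @return A `molecule_records` object restricted to selected molecules;
#'   `records` gains a `criterion` column ("A" or "B").
#' @export
select_molecules <- function(recs, expected_genome_kb, length_tol = 0.05) {
  stopifnot(inherits(recs, "molecule_records"))
  r <- recs$records
  okA <- r$end_labeled &
    abs(r$backbone_kb - expected_genome_kb) <=
      length_tol * expected_genome_kb &
    r$spot_count >= 1
  okB <- r$spot_count >= 2
  keep <- okA | okB
  r <- r[keep, , drop = FALSE]
  r$criterion <- ifelse(okA[keep], "A", "B")
  structure(list(records = r,
                 positions = recs$positions[
                   recs$positions$molecule_id %in% r$id, , drop = FALSE],
                 calibration = recs$calibration),
            class = "molecule_records")
}

#' Neighbor spacings between resolvable PT spots
#'
#' For every molecule with at least two PT spots, consecutive differences
#' of the sorted spot positions, converted to kb with the calibration.
#' Distances are orientation-invariant, so unoriented (criterion B)
#' molecules contribute on equal terms.
#'
#' @param recs A (selected) `molecule_records` object.
#' @return A `spacing_dataset`: data.frame with `molecule_id`,
#'   `distance_kb`; attribute `selection_rule` records how molecules were
#'   chosen.
#' @export
neighbor_spacings <- function(recs) {
  stopifnot(inherits(recs, "molecule_records"))
  fid <- factor(recs$positions$molecule_id,
                levels = unique(recs$positions$molecule_id))
  by_mol <- split(recs$positions$position_kb, fid)
  by_mol <- lapply(by_mol, function(p) if (length(p) < 2) NULL
                   else diff(sort(p)))
  nn <- lengths(by_mol)
  out <- list2DF(list(
    molecule_id = rep(names(by_mol), nn),
    distance_kb = unlist(by_mol, use.names = FALSE) %||% numeric(0)))
  rule <- if (!is.null(recs$records$criterion)) "A-or-B" else "all"
  structure(out, selection_rule = rule, class = c("spacing_dataset",
                                                  "data.frame"))
}

#' Read / write the spot-table exchange dialect
#'
#' Tab-separated with a single header line, so measurements exported from
#' manual image analysis can be analyzed identically to simulated data.
#'
#' @param path File path.
#' @return `read_spot_table`: the spot data.frame.
#' @export
read_spot_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' @rdname read_spot_table
#' @param spots Spot data.frame.
#' @export
write_spot_table <- function(spots, path) {
  utils::write.table(spots, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
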