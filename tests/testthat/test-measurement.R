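test_that("calibration arithmetic matches the lambda-standard constants", {
  cal <- calibrate(15.53, 48502)
  expect_equal(signif(cal$kb_per_um, 4), 3.123)
  expect_equal(signif(cal$stretch_fraction, 4), 0.9417)
  # exact identity at full contour
  full <- calibrate(48502 * 0.34 / 1000, 48502)
  expect_equal(full$stretch_fraction, 1)
  expect_error(calibrate(numeric(0), 48502), "calibration")
  expect_error(calibrate(c(15, -1), 48502), "calibration")
})

test_that("calibration recovers the simulated stretch", {
  for (s in c(0.85, 0.942, 1.0)) {
    set.seed(101)
    lens <- simulate_standards(48502, 100,
                               optics_params(stretch_mean = s,
                                             stretch_sd = 0.02))
    cal <- calibrate(lens, 48502)
    expect_equal(cal$n_standards, 100)
    expect_lt(abs(cal$stretch_fraction - s), 3 * 0.02 / sqrt(100))
    expect_lt(abs(cal$stretch_fraction - s), 0.01)
  }
})

spot_row <- function(id, backbone, end, pos, ch = "PT") {
  data.frame(molecule_id = id, backbone_um = backbone, end_labeled = end,
             spot_position_um = pos, channel = ch,
             stringsAsFactors = FALSE)
}

test_that("molecule records are oriented from the end-labeled extremity", {
  cal <- calibrate(15.53, 48502)
  spots <- rbind(
    spot_row("m1", 15.5, TRUE, 0.02, "end"),
    spot_row("m1", 15.5, TRUE, c(2, 10)),
    spot_row("m2", 15.5, TRUE, 15.49, "end"),   # end label on the far side
    spot_row("m2", 15.5, TRUE, c(2, 10)),
    spot_row("m3", 15.5, FALSE, c(4, 6)))
  recs <- molecule_records(spots, cal)
  expect_equal(recs$records$spot_count, c(2L, 2L, 2L))
  p <- function(id) recs$positions$position_um[
    recs$positions$molecule_id == id]
  expect_equal(p("m1"), c(2, 10))
  expect_equal(p("m2"), c(5.5, 13.5))       # flipped: 15.5 - c(10, 2)
  expect_equal(p("m3"), c(4, 6))            # unoriented: lower coordinate
  expect_equal(recs$positions$position_kb,
               recs$positions$position_um * cal$kb_per_um)
})

test_that("selection applies the two criteria exhaustively", {
  cal <- calibrate(15.53, 48502)
  spots <- rbind(
    spot_row("a", 48.0 / cal$kb_per_um, TRUE, 1),      # A: full length, 1 spot
    spot_row("b", 48.0 / cal$kb_per_um, FALSE, 1),     # rejected
    spot_row("c", 6.0, FALSE, c(1, 2)),                # B: 2 spots
    spot_row("d", 48.0 / cal$kb_per_um, TRUE, c(1, 2)),# both -> tagged A
    spot_row("e", 30.0 / cal$kb_per_um, TRUE, 1),      # short -> rejected
    spot_row("f", 48.0 / cal$kb_per_um, TRUE, NA, NA)) # end only -> rejected
  recs <- molecule_records(spots, cal)
  sel <- select_molecules(recs, 48.502, length_tol = 0.05)
  expect_setequal(sel$records$id, c("a", "c", "d"))
  expect_equal(sel$records$criterion[match(c("a", "c", "d"),
                                           sel$records$id)],
               c("A", "B", "A"))

  # exhaustive check on a simulated population
  set.seed(61)
  ids <- sprintf("m%03d", 1:200)
  pop <- do.call(rbind, lapply(ids, function(id) {
    k <- sample(0:4, 1)
    end <- sample(c(TRUE, FALSE), 1)
    bl <- stats::runif(1, 5, 17)
    rows <- spot_row(id, bl, end, if (k > 0) sort(stats::runif(k, 0, bl))
                     else NA_real_, if (k > 0) "PT" else NA_character_)
    if (end) rows <- rbind(rows, spot_row(id, bl, TRUE, 0.01, "end"))
    rows
  }))
  recs <- molecule_records(pop, cal)
  sel <- select_molecules(recs, 48.502, 0.05)
  r <- recs$records
  okA <- r$end_labeled & abs(r$backbone_kb - 48.502) <= 0.05 * 48.502 &
    r$spot_count >= 1
  okB <- r$spot_count >= 2
  expect_setequal(sel$records$id, r$id[okA | okB])
})

test_that("neighbor spacings convert to kb and keep the count identity", {
  cal <- calibrate(15.53, 48502)
  spots <- rbind(spot_row("m1", 15.5, FALSE, c(1.0, 2.6)),
                 spot_row("m2", 15.5, FALSE, 1.0))
  recs <- molecule_records(spots, cal)
  sp <- neighbor_spacings(recs)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$distance_kb, 1.6 * cal$kb_per_um, tolerance = 1e-12)
  expect_equal(round(sp$distance_kb, 2), 5.00)

  # identity: |distances| = sum over molecules of (spot_count - 1)+
  set.seed(71)
  pop <- do.call(rbind, lapply(sprintf("x%02d", 1:50), function(id) {
    k <- sample(0:6, 1)
    spot_row(id, 16, FALSE, if (k > 0) sort(stats::runif(k, 0, 16))
             else NA_real_, if (k > 0) "PT" else NA_character_)
  }))
  recs <- molecule_records(pop, cal)
  sp <- neighbor_spacings(recs)
  expect_equal(nrow(sp),
               sum(pmax(recs$records$spot_count - 1L, 0L)))
  expect_true(all(sp$distance_kb > 0))
})

test_that("spacings on simulated molecules recover bp truth through calibration", {
  par <- optics_params(stretch_sd = 0, localization_sd_nm = 0)
  bp <- c(5000, 15000, 40000)
  f <- toy_fragment(48502, bp)
  tab <- observe_fragments(list(f), par, jitter = FALSE)
  cal <- calibrate(48502 * 0.34 * 0.942 / 1000, 48502)
  recs <- molecule_records(tab, cal)
  sp <- neighbor_spacings(recs)
  expect_equal(sp$distance_kb, diff(bp) / 1000, tolerance = 1e-9)
})

test_that("spot calling finds rendered peaks to sub-pixel accuracy", {
  par <- optics_params(pixel_nm = 50, psf_sigma_nm = 150, stretch_sd = 0,
                       localization_sd_nm = 0)
  om <- structure(list(backbone_um = 12, stretch = 0.942,
                       spots = data.frame(
                         position_um = c(2.013, 7.489), multiplicity = c(1L, 2L),
                         channel = "PT"),
                       parent = "x"),
                  class = "optical_molecule")
  prof <- render_profile(om, par)
  pos <- call_spots(prof$PT, min_prominence = 0.02, min_separation_px = 3,
                    pixel_nm = 50)
  expect_length(pos, 2)
  expect_lt(max(abs(pos - c(2013, 7489))), 50)  # within one pixel
  expect_length(call_spots(rep(0, 100)), 0)
  expect_length(call_spots(rep(1, 100)), 0)
})
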