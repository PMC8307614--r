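make_uniform_movie <- function(u, n, ny = 6, nx = 8, pixel_size = 1,
                               frame_interval = 5) {
  f <- velocity_field(matrix(u, ny, nx), matrix(0, ny, nx),
                      pixel_size = pixel_size,
                      frame_interval = frame_interval, units = "um_min")
  replicate(n, f, simplify = FALSE)
}

test_that("kymograph cells reproduce uniform fields and row arithmetic", {
  fl <- make_uniform_movie(2, 108)  # 9 h at 5 min/frame
  k <- xvelocity_kymograph(fl, row_duration = 10, col_width = 42)
  expect_equal(nrow(k$values), 54)  # 9 h of 10-min rows
  expect_true(all(abs(k$values - 2) < 1e-12, na.rm = TRUE))
  expect_error(xvelocity_kymograph(fl, row_duration = 1), "frame interval")
})

test_that("kymograph column means match a brute-force binning oracle", {
  set.seed(3)
  fields <- lapply(1:6, function(i) {
    u <- matrix(runif(16 * 20, -2, 2), 16, 20)
    valid <- matrix(runif(16 * 20) > 0.2, 16, 20)
    velocity_field(u, matrix(0, 16, 20), valid = valid, pixel_size = 2,
                   frame_interval = 5, units = "um_min")
  })
  k <- xvelocity_kymograph(fields, row_duration = 10, col_width = 15)
  # oracle: loop over every node of every field
  nr <- nrow(k$values); nc <- ncol(k$values)
  ssum <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    vel <- field_velocities(f)
    row <- floor(((i - 1) * 5) / 10) + 1
    for (a in 1:16) for (b in 1:20) {
      if (!f$valid[a, b]) next
      col <- floor((f$x[b] * 2) / 15) + 1
      ssum[row, col] <- ssum[row, col] + vel$u[a, b]
      cnt[row, col] <- cnt[row, col] + 1
    }
  }
  oracle <- ssum / cnt; oracle[cnt == 0] <- NA
  expect_equal(k$values, oracle, tolerance = 1e-9)
  # a left/right step field survives binning (grid aligned to the bins)
  u <- cbind(matrix(-1, 8, 10), matrix(1, 8, 10))
  fstep <- velocity_field(u, matrix(0, 8, 20), x = seq(0.5, 19.5, 1),
                          units = "um_min",
                          pixel_size = 1, frame_interval = 5)
  ks <- xvelocity_kymograph(list(fstep), row_duration = 5, col_width = 10)
  expect_equal(ks$values[1, 1], -1)
  expect_equal(ks$values[1, 2], 1)
})

test_that("texture segmentation finds the tissue boundary", {
  sc <- make_edge_scenario("static", 0, shape = c(120, 320), n_frames = 2,
                           seed = 5)
  m <- segment_tissue(sc$images$frames[[1]])
  expect_lt(abs(edge_positions(m, "leading") - sc$edge_px[1]), 5)
  # pure-noise frame: empty mask with a warning
  set.seed(1)
  noise <- matrix(rnorm(64 * 64, 0.5, 0.02), 64, 64)
  expect_warning(mn <- segment_tissue(noise), "empty mask")
  expect_equal(sum(mn), 0)
  # full-texture frame: full mask
  set.seed(2)
  full <- matrix(runif(64 * 64), 64, 64)
  expect_true(all(segment_tissue(full)))
})

test_that("edge positions use the row-median and physical units", {
  mask <- matrix(FALSE, 10, 500)
  mask[, 1:400] <- TRUE
  expect_equal(edge_positions(mask, "leading", pixel_size = 1.3), 520)
  expect_equal(edge_positions(mask, "trailing", pixel_size = 1.3), 0)
  # one 50-px finger on <50% of rows does not move the median
  finger <- mask
  finger[3, 401:450] <- TRUE
  expect_equal(edge_positions(finger, "leading", 1.3), 520)
  # brute-force median oracle
  per_row <- apply(finger, 1, function(r) max(which(r)))
  expect_equal(edge_positions(finger, "leading", 1), median(per_row))
  expect_error(edge_positions(matrix(FALSE, 4, 4), "leading"),
               class = "collmigr_undefined_edge")
})

test_that("edge displacement recovers advance, static and retract modes", {
  for (case in list(list(mode = "advance", sign = 1),
                    list(mode = "static", sign = 0),
                    list(mode = "retract", sign = -1))) {
    sc <- make_edge_scenario(case$mode, rate = 3, shape = c(120, 320),
                             n_frames = 11, seed = 8)
    et <- edge_displacement_series(sc$images)
    expect_s3_class(et, "edge_trace")
    expect_equal(et$leading_disp[1], 0)
    fin <- rev(et$leading_disp[!is.na(et$leading_disp)])[1]
    truth <- 3 * 10 * case$sign
    if (case$sign == 0) {
      expect_lt(abs(fin), 5)
    } else {
      expect_equal(sign(fin), case$sign)
      expect_lt(abs(fin - truth), 0.2 * abs(truth))
    }
  }
})

test_that("retraction slope is within 20% of the programmed rate", {
  sc <- make_edge_scenario("retract", rate = 2, shape = c(120, 320),
                           n_frames = 11, seed = 9)
  et <- edge_displacement_series(sc$images)
  slope <- coef(lm(leading_x ~ time, data = et))[2]
  expect_lt(abs(slope - (-2)), 0.2 * 2)
})

test_that("edge positions are translation-equivariant", {
  sc <- make_edge_scenario("static", 0, shape = c(80, 260), n_frames = 2,
                           seed = 4)
  m <- segment_tissue(sc$images$frames[[1]])
  k <- 17
  shifted <- cbind(matrix(FALSE, nrow(m), k), m[, 1:(ncol(m) - k)])
  expect_equal(edge_positions(shifted, "leading"),
               edge_positions(m, "leading") + k)
})

test_that("wound closure rate and closure time follow the gap geometry", {
  t <- 0:10
  left <- structure(data.frame(time = t, leading_x = 100 + t,
                               trailing_x = 0, leading_disp = t,
                               trailing_disp = 0),
                    class = c("edge_trace", "data.frame"))
  right <- structure(data.frame(time = t, leading_x = 400,
                                trailing_x = 130 - t, leading_disp = 0,
                                trailing_disp = -t),
                     class = c("edge_trace", "data.frame"))
  wc <- wound_closure_rate(left, right)
  expect_equal(wc$rate_um_min, 2)  # two edges approaching at 1 um/min each
  expect_true(is.na(wc$closure_time_min))  # gap still open at t = 10
  # static edges: zero rate, no closure
  static <- structure(data.frame(time = t, leading_x = 100, trailing_x = 0,
                                 leading_disp = 0, trailing_disp = 0),
                      class = c("edge_trace", "data.frame"))
  static_r <- structure(data.frame(time = t, leading_x = 400,
                                   trailing_x = 300, leading_disp = 0,
                                   trailing_disp = 0),
                        class = c("edge_trace", "data.frame"))
  wc2 <- wound_closure_rate(static, static_r)
  expect_equal(wc2$rate_um_min, 0)
  expect_true(is.na(wc2$closure_time_min))
  # closing gap (300 - (100 + 20t) = 0 at t = 10) reports first closure time
  fast <- structure(data.frame(time = t, leading_x = 100 + 20 * t,
                               trailing_x = 0, leading_disp = 20 * t,
                               trailing_disp = 0),
                    class = c("edge_trace", "data.frame"))
  wc3 <- wound_closure_rate(fast, static_r)
  expect_equal(wc3$closure_time_min, 10)
  expect_error(wound_closure_rate(left, structure(
    data.frame(time = t + 1, leading_x = 1, trailing_x = 1,
               leading_disp = 0, trailing_disp = 0),
    class = c("edge_trace", "data.frame"))), "time base")
})

test_that("noisy synthetic approach recovers the programmed closure rate", {
  sc_l <- make_edge_scenario("advance", rate = 2, shape = c(120, 320),
                             n_frames = 11, seed = 12)
  et_l <- edge_displacement_series(sc_l$images)
  # mirror a second advancing tissue to face the first across a 700-px gap
  et_r <- et_l
  et_r$trailing_x <- 900 - et_l$leading_x
  et_r$trailing_disp <- -et_l$leading_disp
  wc <- wound_closure_rate(et_l, et_r)
  expect_lt(abs(wc$rate_um_min - 4) / 4, 0.1)
})
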