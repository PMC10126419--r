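test_that("ROI detection matches a flood-fill component oracle", {
  m <- matrix(0, 90, 110)
  m <- draw_ellipse(m, cx = 60, cy = 40, a = 18, b = 12, value = 200)
  set.seed(2)
  frames <- replicate(6, pmax(m + matrix(rnorm(90 * 110, 0, 4), 90), 0),
                      simplify = FALSE)
  st <- frame_stack(frames, 10, 1)
  roi <- detect_heart_roi(st, 0.90, pad = 5)
  # oracle: same threshold, brute-force labeling, largest component
  maximg <- Reduce(pmax, frames)
  thr <- quantile(maximg, 0.90)
  lab <- oracle_label_components(maximg > thr)
  big <- which.max(tabulate(lab[lab > 0]))
  px <- which(lab == big, arr.ind = TRUE)
  # ROI contains the ellipse centroid and >= 99% of the component's pixels
  expect_true(roi$rows[1] <= 40 && 40 <= roi$rows[2])
  expect_true(roi$cols[1] <= 60 && 60 <= roi$cols[2])
  inside <- px[, 1] >= roi$rows[1] & px[, 1] <= roi$rows[2] &
    px[, 2] >= roi$cols[1] & px[, 2] <= roi$cols[2]
  expect_gte(mean(inside), 0.99)
  expect_equal(roi$rotation_angle, 0)
})

test_that("all-zero stacks raise a no-heart error", {
  st <- frame_stack(replicate(6, matrix(0, 20, 20), simplify = FALSE), 10, 1)
  expect_error(detect_heart_roi(st), class = "cb_no_heart_error")
})

test_that("a supra-threshold bridge keeps both chambers in a single ROI", {
  m <- matrix(0, 80, 140)
  m <- draw_ellipse(m, 40, 40, 15, 10, 200)
  m <- draw_ellipse(m, 100, 40, 15, 10, 200)
  m[36:44, 40:100] <- pmax(m[36:44, 40:100], 150)  # bright canal bridge
  st <- frame_stack(list(m, m, m, m, m, m), 10, 1)
  roi <- detect_heart_roi(st, 0.85, pad = 2)
  lab <- oracle_label_components(m > quantile(m, 0.85))
  expect_equal(max(lab), 1L)  # oracle agrees: one component
  expect_true(roi$cols[1] <= 25 && roi$cols[2] >= 115)  # covers both ellipses
})

test_that("chamber segmentation reaches IoU >= 0.9 against ground truth in every frame", {
  sim <- generate_heart_video(heart_sim_params(seed = 21, noise_sd = 10,
                                               duration = 3))
  roi <- detect_heart_roi(sim$stack)
  seeds <- seeds_from_truth(sim$truth, roi)
  masks <- segment_chambers(sim$stack, roi, seeds)
  for (ch in c("atrium", "ventricle")) {
    iou <- vapply(seq_along(masks[[ch]]), function(i) {
      gt <- sim$truth$masks[[ch]][[i]]
      sum(gt & masks[[ch]][[i]]) / sum(gt | masks[[ch]][[i]])
    }, numeric(1))
    expect_gte(min(iou), 0.9)
  }
})

test_that("mean IoU stays >= 0.85 across an amplitude/noise grid at SNR >= 5", {
  grid <- expand.grid(noise = c(15, 30), m = c(0.25, 0.45), seed = c(31, 32))
  ious <- apply(grid, 1, function(g) {
    sim <- generate_heart_video(heart_sim_params(
      seed = g[["seed"]], noise_sd = g[["noise"]], duration = 2,
      contraction_atrium = g[["m"]], contraction_ventricle = g[["m"]]))
    roi <- detect_heart_roi(sim$stack)
    masks <- segment_chambers(sim$stack, roi, seeds_from_truth(sim$truth, roi))
    mean(vapply(seq_along(masks$atrium), function(i) {
      gt <- sim$truth$masks$atrium[[i]]
      sum(gt & masks$atrium[[i]]) / sum(gt | masks$atrium[[i]])
    }, numeric(1)))
  })
  expect_true(all(ious >= 0.85))
})

test_that("atrium and ventricle masks are disjoint, including the shared-blob tie-break", {
  sim <- generate_heart_video(heart_sim_params(seed = 9, duration = 2))
  roi <- detect_heart_roi(sim$stack)
  seeds <- seeds_from_truth(sim$truth, roi)
  masks <- segment_chambers(sim$stack, roi, seeds)
  for (i in seq_along(masks$atrium))
    expect_false(any(masks$atrium[[i]] & masks$ventricle[[i]]))

  # both seeds drawn on the ventricle blob: split by centroid distance
  vc <- sim$truth$centers$ventricle
  offx <- vc["x"] - roi$cols[1] + 1
  offy <- vc["y"] - roi$rows[1] + 1
  sq <- function(cx, cy, h) cbind(x = c(cx - h, cx + h, cx + h, cx - h),
                                  y = c(cy - h, cy - h, cy + h, cy + h))
  both <- chamber_seeds(atrium = sq(offx - 8, offy, 4),
                        ventricle = sq(offx + 8, offy, 4))
  expect_warning(m2 <- segment_chambers(sim$stack, roi, both),
                 class = "cb_shared_component_warning")
  for (i in seq_along(m2$atrium)) {
    expect_false(any(m2$atrium[[i]] & m2$ventricle[[i]]))
    expect_gt(sum(m2$atrium[[i]]), 0)
    expect_gt(sum(m2$ventricle[[i]]), 0)
  }
})

test_that("seeds outside the ROI and unmatched seeds raise typed errors", {
  sim <- generate_heart_video(heart_sim_params(seed = 10, duration = 1))
  roi <- detect_heart_roi(sim$stack)
  far <- chamber_seeds(
    atrium = cbind(x = c(5000, 5010, 5010, 5000), y = c(5, 5, 15, 15)),
    ventricle = cbind(x = c(10, 20, 20, 10), y = c(5, 5, 15, 15)))
  expect_error(segment_chambers(sim$stack, roi, far),
               class = "cb_precondition_error")
  # in-ROI seed over dark background: no supra-threshold overlap anywhere
  dark <- chamber_seeds(
    atrium = cbind(x = c(2, 8, 8, 2), y = c(2, 2, 8, 8)),
    ventricle = seeds_from_truth(sim$truth, roi)$ventricle)
  err <- expect_error(segment_chambers(sim$stack, roi, dark),
                      class = "cb_segmentation_error")
  expect_match(conditionMessage(err), "atrium")
})

test_that("segmentation is equivariant under 90-degree rotation of stack and seeds", {
  sim <- generate_heart_video(heart_sim_params(seed = 13, duration = 1,
                                               noise_sd = 0))
  st <- sim$stack
  H <- nrow(st$frames[[1]]); W <- ncol(st$frames[[1]])
  rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]   # CCW quarter turn
  st_rot <- frame_stack(lapply(st$frames, rot90), st$frame_rate, st$pixel_size)
  roi <- heart_roi(c(1, H), c(1, W))
  roi_rot <- heart_roi(c(1, W), c(1, H))
  seeds <- seeds_from_truth(sim$truth, roi)
  # pixel (row r, col c) maps to (row W + 1 - c, col r): (x, y) -> (y, W + 1 - x)
  rot_poly <- function(p) cbind(x = p[, "y"], y = W + 1 - p[, "x"])
  seeds_rot <- chamber_seeds(atrium = rot_poly(seeds$atrium),
                             ventricle = rot_poly(seeds$ventricle))
  m1 <- segment_chambers(st, roi, seeds)
  m2 <- segment_chambers(st_rot, roi_rot, seeds_rot)
  for (i in seq_along(m1$atrium)) {
    expect_identical(rot90(m1$atrium[[i]]), m2$atrium[[i]])
    expect_identical(rot90(m1$ventricle[[i]]), m2$ventricle[[i]])
  }
})

test_that("chamber areas scale with the squared pixel size", {
  mk <- function(n_px) {
    m <- matrix(FALSE, 20, 20)
    m[seq_len(n_px)] <- TRUE
    m
  }
  masks <- make_mask_series(atrium = list(mk(100), mk(100)),
                            ventricle = list(mk(0), mk(50)),
                            pixel_size = 1.3)
  areas <- chamber_area_series(masks)
  expect_equal(areas$atrium, c(169, 169))       # 100 px * 1.3^2
  expect_equal(areas$ventricle, c(0, 50 * 1.69))
  expect_equal(diff(areas$atrium), 0)           # constant masks, constant trace
})
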