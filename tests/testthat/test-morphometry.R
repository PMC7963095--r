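# minimal hand-built section pair for unit semantics
fake_section <- function(truth, thickness = 1, n = 100) {
  structure(
    list(intensities = matrix(2000L, n, n), labels = matrix(0L, n, n),
         pixel_pitch = c(1, 1), thickness = thickness,
         normal = c(1, 0, 0), position = 0,
         axes = list(e1 = c(0, 1, 0), e2 = c(0, 0, 1),
                     u_origin = 0, v_origin = 0),
         profile_truth = truth),
    class = "section_image"
  )
}

nucleus_row <- function(id, present, y = 50, x = 50, r = 3) {
  tibble::tibble(cell_id = id, pixels = list(integer()),
                 nucleus_profile_present = present,
                 nucleus_y = y, nucleus_x = x, nucleus_profile_radius = r)
}

test_that("a nucleus present only in the reference section is counted once", {
  frames <- list(counting_frame(c(10, 10), c(80, 80)))
  ref <- fake_section(nucleus_row(1L, TRUE))
  luk <- fake_section(nucleus_row(1L, FALSE))
  dc <- physical_disector_count(ref, luk, frames)
  expect_equal(dc$q, 1)
  expect_equal(nrow(dc$tally), 2) # both directions
  expect_equal(dc$tally$q, c(1, 0))
  expect_equal(dc$tally$h, c(1, 1)) # h = reference section thickness
})

test_that("a nucleus present in both sections is never counted", {
  frames <- list(counting_frame(c(10, 10), c(80, 80)))
  ref <- fake_section(nucleus_row(1L, TRUE))
  luk <- fake_section(nucleus_row(1L, TRUE))
  expect_equal(physical_disector_count(ref, luk, frames)$q, 0)
})

test_that("nucleus profiles on exclusion edges are rejected", {
  frames <- list(counting_frame(c(10, 10), c(40, 40)))
  # nucleus disk crossing the left exclusion edge at x = 10
  ref <- fake_section(nucleus_row(1L, TRUE, y = 30, x = 10, r = 3))
  luk <- fake_section(nucleus_row(1L, FALSE))
  dc <- physical_disector_count(ref, luk, frames, both_directions = FALSE)
  expect_equal(dc$q, 0)
})

test_that("misaligned section pairs are rejected", {
  ref <- fake_section(nucleus_row(1L, TRUE))
  bad <- fake_section(nucleus_row(1L, FALSE))
  bad$pixel_pitch <- c(2, 2)
  expect_error(physical_disector_count(ref, bad, list(counting_frame(c(0, 0), c(50, 50)))),
               "aligned")
})

test_that("thick disectors trigger the nucleus-detectability warning", {
  frames <- list(counting_frame(c(10, 10), c(80, 80)))
  ref <- fake_section(nucleus_row(1L, TRUE), thickness = 5)
  luk <- fake_section(nucleus_row(1L, FALSE), thickness = 5)
  expect_warning(
    physical_disector_count(ref, luk, frames, both_directions = FALSE),
    "one third"
  )
})

test_that("serial-section disector counts match the geometric oracle", {
  ph <- small_phantom()
  series <- nucleus_section_series(ph, n_sections = 4, nominal_thickness = 1.34,
                                   thickness_jitter_sd = 0, pixel_pitch = 2,
                                   seed = 23)
  n_px <- dim(series[[1]]$intensities)
  frames <- tile_frames(n_px * 2, c(50, 50), guard = 1)
  for (i in 1:3) {
    ref <- series[[i]]; luk <- series[[i + 1]]
    dc <- suppressWarnings(
      physical_disector_count(ref, luk, frames, both_directions = TRUE)
    )
    p_ref <- ref$profile_truth$cell_id[ref$profile_truth$nucleus_profile_present]
    p_luk <- luk$profile_truth$cell_id[luk$profile_truth$nucleus_profile_present]
    q_oracle <- length(setdiff(p_ref, p_luk)) + length(setdiff(p_luk, p_ref))
    expect_equal(dc$q, q_oracle)
  }
})

test_that("profile morphometry measures areas and maximal Feret diameters", {
  img <- matrix(40000L, 200, 200)
  img[50:69, 50:69] <- 1000L # 20 x 20 square
  frames <- list(counting_frame(c(10, 10), c(180, 180)))
  ps <- profile_morphometry(img, frames, pixel_pitch = c(1, 1), min_area = 4)
  expect_equal(nrow(ps$profiles), 1)
  expect_equal(ps$profiles$area, 400)
  expect_equal(ps$profiles$max_diameter, 20 * sqrt(2))
  # disk of diameter 40
  img2 <- matrix(40000L, 200, 200)
  yy <- row(img2); xx <- col(img2)
  img2[(yy - 100.5)^2 + (xx - 100.5)^2 <= 20^2] <- 1000L
  ps2 <- profile_morphometry(img2, frames, pixel_pitch = c(1, 1), min_area = 4)
  expect_lt(abs(ps2$profiles$max_diameter - 40), 2.5)
})

test_that("numerical area density counts accepted profiles per frame area", {
  img <- matrix(40000L, 1000, 1000)
  centers <- cbind(c(150, 350, 550, 750, 250), c(150, 350, 550, 750, 650))
  for (i in 1:5) {
    img[centers[i, 1] + (-10:10), centers[i, 2] + (-10:10)] <- 1000L
  }
  frames <- list(counting_frame(c(100, 100), c(500, 500)),
                 counting_frame(c(100, 620), c(500, 300)),
                 counting_frame(c(620, 100), c(300, 500)),
                 counting_frame(c(620, 620), c(300, 300)))
  ps <- profile_morphometry(img, frames, pixel_pitch = c(1, 1), min_area = 4)
  expect_equal(ps$n_accepted, 5)
  expect_equal(ps$density_per_1e6um2, 5 / sum(sapply(frames, frame_area)) * 1e6)
})

test_that("maximal Feret never falls below the equivalent-circle diameter", {
  set.seed(31)
  for (rep in 1:20) {
    n <- 60
    m <- matrix(0L, n, n)
    cy <- runif(1, 20, 40); cx <- runif(1, 20, 40)
    a <- runif(1, 3, 12); b <- runif(1, 3, 12); th <- runif(1, 0, pi)
    yy <- row(m) - cy; xx <- col(m) - cx
    u <- yy * cos(th) + xx * sin(th); v <- -yy * sin(th) + xx * cos(th)
    sel <- (u / a)^2 + (v / b)^2 <= 1
    if (!any(sel)) next
    iy <- row(m)[sel]; ix <- col(m)[sel]
    feret <- adipostereo:::feret_max(iy, ix, c(1, 1))
    d_eq <- 2 * sqrt(sum(sel) / pi)
    expect_gte(feret, d_eq)
  }
})
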