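test_that("SUR index sampling is periodic with a random start", {
  expect_identical(sur_sample(60, 6, phase = 0), c(1L, 11L, 21L, 31L, 41L, 51L))
  s <- sur_sample(60, 6, seed = 3)
  expect_length(s, 6)
  expect_true(all(diff(s) == 10))
  expect_true(all(s >= 1 & s <= 60))
  expect_error(sur_sample(5, 6), "n_total")
  # non-integral interval stays distinct and increasing
  s2 <- sur_sample(10, 3, seed = 1)
  expect_true(all(diff(s2) > 0))
})

test_that("SUR sampling selects every index equiprobably", {
  set.seed(42)
  n_rep <- 40000
  counts <- integer(10)
  for (i in seq_len(n_rep)) {
    s <- sur_sample(10, 2)
    counts[s] <- counts[s] + 1L
  }
  freq <- counts / (n_rep * 2)
  expect_true(all(abs(freq - 0.1) < 0.01))
})

test_that("SUR fields tile the region exactly at zero phase", {
  f <- sur_fields(c(1000, 1000), c(100, 100), 100, phase = c(0, 0))
  expect_equal(nrow(f), 100)
  expect_setequal(unique(f$y), seq(0, 900, 100))
  # coverage map: every pixel covered exactly once
  cov <- matrix(0L, 100, 100) # 10 um pixels
  for (i in seq_len(nrow(f))) {
    iy <- f$y[i] / 10 + 1:10
    ix <- f$x[i] / 10 + 1:10
    cov[iy, ix] <- cov[iy, ix] + 1L
  }
  expect_true(all(cov == 1L))
  f4 <- sur_fields(c(1000, 1000), c(100, 100), 4, phase = c(0, 0))
  expect_equal(nrow(f4), 4)
  expect_setequal(unique(f4$y), c(0, 500))
  expect_error(sur_fields(c(50, 50), c(100, 100), 4), "larger")
})

test_that("point hits tally the containing pixel class", {
  img <- matrix(1L, 10, 10)
  h <- point_hits(point_grid(c(2, 2), c(1, 1), c(10, 10)), img, c(1, 1))
  expect_equal(h$hits[h$class == "1"], 25)
  expect_equal(attr(h, "total"), 25)
  # half-plane split aligned between grid columns: exact proportionality
  img2 <- cbind(matrix(1L, 10, 5), matrix(2L, 10, 5))
  h2 <- point_hits(point_grid(c(2.5, 2.5), c(1.25, 1.25), c(10, 10)),
                   img2, c(1, 1))
  expect_equal(h2$hits[h2$class == "1"], h2$hits[h2$class == "2"])
  expect_error(point_hits(point_grid(c(2, 2), c(1, 1), c(20, 20)), img, c(1, 1)),
               "exceeds")
})

test_that("point grid estimates area fractions without bias", {
  # disk of radius 30 in a 100 x 100 image
  n <- 100
  cx <- 50.3; cy <- 49.1; r <- 30
  img <- outer(seq_len(n) - 0.5, seq_len(n) - 0.5,
               function(y, x) as.integer((y - cy)^2 + (x - cx)^2 <= r^2))
  frac_true <- mean(img)
  g <- point_grid(c(1.9, 1.9), c(0.3, 0.3), c(100, 100))
  h <- point_hits(g, img, c(1, 1))
  frac_hat <- sum(h$hits[h$class == "1"]) / attr(h, "total")
  expect_lt(abs(frac_hat - frac_true), 2 / sqrt(attr(h, "total")))
  # expectation over random phases equals the area fraction
  set.seed(5)
  fr <- replicate(150, {
    off <- runif(2, 0, 5)
    h <- point_hits(point_grid(c(5, 5), off, c(100, 100)), img, c(1, 1))
    sum(h$hits[h$class == "1"]) / attr(h, "total")
  })
  expect_lt(abs(mean(fr) - frac_true), 3 * sd(fr) / sqrt(length(fr)))
})

test_that("counting frame accepts by the inclusion/exclusion edge rule", {
  fr <- counting_frame(c(10, 10), c(20, 20)) # frame [10,30] x [10,30]
  m <- matrix(0L, 50, 50) # pixel pitch 1, origin (0,0)
  m[15:20, 15:20] <- 1L # strictly inside
  m[12:18, 5:12] <- 2L # crosses the left exclusion edge (x = 10)
  m[28:34, 15:20] <- 3L # touches/crosses the top inclusion edge (y = 30)
  acc <- apply_counting_frame(fr, m, c(1, 1))
  expect_true(1L %in% acc)
  expect_false(2L %in% acc)
  expect_true(3L %in% acc)
  # profile crossing the bottom exclusion edge is rejected
  m2 <- matrix(0L, 50, 50)
  m2[8:15, 12:16] <- 4L # crosses y = 10 inside the frame's x-range
  expect_false(4L %in% apply_counting_frame(fr, m2, c(1, 1)))
  # profile touching the downward extension at the bottom-right corner
  m3 <- matrix(0L, 50, 50)
  m3[5:15, 28:33] <- 5L # crosses x = 30 below y = 10 and enters the frame
  expect_false(5L %in% apply_counting_frame(fr, m3, c(1, 1)))
})

test_that("tiled counting frames accept every profile exactly once", {
  set.seed(7)
  edge <- c(20, 20)
  for (rep in seq_len(100)) {
    m <- matrix(0L, 60, 60)
    n_prof <- sample(3:8, 1)
    for (p in seq_len(n_prof)) {
      if (runif(1) < 0.4) {
        # frame-sized tilted ellipse (exercises profiles larger than a tile)
        cy <- runif(1, 10, 50); cx <- runif(1, 10, 50)
        a <- runif(1, 8, 22); b <- runif(1, 4, 12); th <- runif(1, 0, pi)
        yy <- matrix(seq_len(60) - 0.5, 60, 60)
        xx <- t(yy)
        u <- (yy - cy) * cos(th) + (xx - cx) * sin(th)
        v <- -(yy - cy) * sin(th) + (xx - cx) * cos(th)
        m[(u / a)^2 + (v / b)^2 <= 1] <- p
      } else {
        h <- sample(2:18, 1); w <- sample(2:18, 1)
        y0 <- sample.int(60 - h, 1); x0 <- sample.int(60 - w, 1)
        m[y0 + seq_len(h), x0 + seq_len(w)] <- p
        # sometimes add an attached arm to make the profile non-convex
        if (runif(1) < 0.5) {
          ah <- sample(2:10, 1)
          ay <- min(y0 + h + seq_len(ah), 60)
          m[ay, min(x0 + 1, 60)] <- p
        }
      }
    }
    # overlapping draws can disconnect an earlier profile; keep the last
    # drawn labels only where still present and require connectedness
    for (p in sort(unique(m[m > 0]))) {
      comp <- matrix(adipostereo:::cpp_label_components(as.vector(m == p),
                                                        c(1L, 60L, 60L)), 60, 60)
      if (max(comp) > 1) { # keep the largest component
        keep <- which.max(tabulate(comp[comp > 0]))
        m[m == p & comp != keep] <- 0L
      }
    }
    frames <- tile_frames(c(60, 60), edge, guard = 2)
    present <- sort(unique(m[m > 0]))
    counts <- setNames(integer(length(present)), present)
    for (f in frames) {
      acc <- apply_counting_frame(f, m, c(1, 1))
      counts[as.character(acc)] <- counts[as.character(acc)] + 1L
    }
    expect_true(all(counts == 1L),
                info = sprintf("rep %d: counts %s", rep,
                               paste(counts, collapse = ",")))
  }
})

test_that("disector plane pairs come from the sampling zone", {
  p <- sample_disector_planes(322, 5, 10, seed = 2)
  expect_equal(p$h, 50)
  zone <- c(floor(322 / 3) + 1, floor(2 * 322 / 3))
  expect_gte(p$reference_index, zone[1])
  expect_lte(p$lookup_index, zone[2])
  expect_equal(p$lookup_index - p$reference_index, 10L)
  expect_error(sample_disector_planes(322, 5, 0), "h > 0")
  expect_error(sample_disector_planes(12, 5, 10), "infeasible")
})

test_that("reference plane index is uniform over the feasible zone", {
  refs <- vapply(seq_len(600), function(i) {
    sample_disector_planes(60, 5, 5, seed = i)$reference_index
  }, integer(1))
  zone <- c(floor(60 / 3) + 1, floor(2 * 60 / 3))
  feas <- seq(zone[1], zone[2] - 5)
  expect_true(all(refs %in% feas))
  tab <- tabulate(factor(refs, levels = feas))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})
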