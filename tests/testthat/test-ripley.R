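test_that("uncorrected K matches the literal definition on a hand-checked square", {
  pp <- point_pattern(c(4.5, 5.5, 4.5, 5.5), c(4.5, 4.5, 5.5, 5.5),
                      window = c(0, 10, 0, 10))
  k <- ripley_k(pp, r = c(1.2, 1.5), correction = "none")
  # lambda = 0.04; at r = 1.2 each corner sees its 2 side-neighbors,
  # at r = 1.5 also the diagonal one
  expect_equal(k$K, c(50, 75))
  expect_equal(k$lambda, 0.04)
})

test_that("ripley_k enforces its preconditions", {
  pp <- sim_csr(100, window = c(0, 1000, 0, 1000), seed = 1)
  expect_error(ripley_k(point_pattern(1, 1, window = c(0, 10, 0, 10))),
               "fewer than 2")
  expect_error(ripley_k(pp, r = c(0, 600)), "half the shorter")
  expect_error(ripley_k(pp, r = c(100, 50)), "strictly increasing")
})

test_that("uncorrected K equals the O(n^2) brute-force oracle on random patterns", {
  r <- seq(0, 400, by = 25)
  for (s in 1:6) {
    n <- c(10, 50, 200, 500, 1000, 2000)[s]
    pp <- sim_csr(n, window = c(0, 5000, 0, 5000), seed = 400 + s)
    k <- ripley_k(pp, r = r, correction = "none")
    expect_equal(k$K, k_oracle(pp, r), tolerance = 1e-12)
  }
  # clustered patterns too
  pt <- sim_thomas(20, 25, 60, seed = 17)
  k <- ripley_k(pt, r = r, correction = "none")
  expect_equal(k$K, k_oracle(pt, r), tolerance = 1e-12)
})

test_that("translation-corrected K tracks pi r^2 under CSR", {
  r <- seq(0, 500, by = 50)
  ks <- vapply(1:20, function(s) {
    ripley_k(sim_csr(2000, seed = 500 + s), r = r,
             correction = "translation")$K
  }, numeric(length(r)))
  mk <- rowMeans(ks)
  expect_equal(mk[-1], pi * r[-1]^2, tolerance = 0.02)
})

test_that("border-corrected K restricts to interior points and stays unbiased under CSR", {
  r <- seq(0, 400, by = 100)
  ks <- vapply(1:20, function(s) {
    ripley_k(sim_csr(1500, seed = 700 + s), r = r, correction = "border")$K
  }, numeric(length(r)))
  expect_equal(rowMeans(ks)[-1], pi * r[-1]^2, tolerance = 0.03)
})

test_that("the H-transform maps the CSR parabola to zero and inverts by hand", {
  r <- seq(0, 100, by = 5)
  k_csr <- structure(list(r = r, K = pi * r^2, correction = "none",
                          lambda = 1, n = 100, window = c(0, 1, 0, 1)),
                     class = "kest")
  expect_equal(k_to_h(k_csr)$H, rep(0, length(r)))

  k1 <- structure(list(r = 1, K = 4 * pi, correction = "none", lambda = 1,
                       n = 10, window = c(0, 1, 0, 1)), class = "kest")
  expect_equal(k_to_h(k1)$H, 1)

  k2 <- structure(list(r = 2, K = 0, correction = "none", lambda = 1,
                       n = 10, window = c(0, 1, 0, 1)), class = "kest")
  expect_equal(k_to_h(k2)$H, -2)

  kneg <- structure(list(r = 1, K = -1), class = "kest")
  expect_error(k_to_h(kneg), "negative K")
})

test_that("moving-average smoothing uses a shrinking window at the grid edges", {
  h <- structure(list(r = c(0, 15, 30), H = c(0, 3, 0), smoothed = FALSE,
                      smoothing_half_width = NA_real_), class = "hest")
  expect_equal(smooth_h(h, half_width = 15)$H, c(1.5, 1, 1.5))
  expect_equal(smooth_h(h, half_width = 0)$H, h$H)

  hc <- structure(list(r = seq(0, 100, 5), H = rep(2.5, 21), smoothed = FALSE,
                       smoothing_half_width = NA_real_), class = "hest")
  expect_equal(smooth_h(hc)$H, rep(2.5, 21))
  expect_true(smooth_h(hc)$smoothed)

  hi <- structure(list(r = c(0, 1, 10), H = c(1, 2, 3), smoothed = FALSE,
                       smoothing_half_width = NA_real_), class = "hest")
  expect_error(smooth_h(hi), "regular")
})

test_that("group averaging returns per-radius mean and SEM across animals", {
  r <- seq(0, 50, 10)
  mk <- function(H) structure(list(r = r, H = H, smoothed = TRUE,
                                   smoothing_half_width = 15),
                              class = "hest")
  one <- group_average_h(list(mk(rep(1.5, 6))))
  expect_equal(one$mean_H, rep(1.5, 6))
  expect_equal(one$sem_H, rep(0, 6))

  two <- group_average_h(list(mk(rep(0, 6)), mk(rep(2, 6))))
  expect_equal(two$mean_H, rep(1, 6))
  expect_equal(two$sem_H, rep(1, 6))  # sd = sqrt(2), sem = sqrt(2)/sqrt(2)

  same <- group_average_h(list(mk(1:6), mk(1:6), mk(1:6)))
  expect_equal(same$sem_H, rep(0, 6))

  bad <- structure(list(r = r + 1, H = rep(0, 6), smoothed = TRUE,
                        smoothing_half_width = 15), class = "hest")
  expect_error(group_average_h(list(mk(rep(0, 6)), bad)), "mismatched")
})

test_that("domain size is the argmax radius of the smoothed H, smallest on ties", {
  r <- seq(0, 300, 5)
  mk <- function(H) structure(list(r = r, H = H, smoothed = TRUE,
                                   smoothing_half_width = 15),
                              class = "hest")
  peak <- 150 * exp(-(r - 180)^2 / 1000)
  expect_equal(domain_size(mk(peak)), 180)
  expect_equal(domain_size(mk(rev(sort(peak)))), 0)  # decreasing -> first r
  flat <- rep(3, length(r))
  expect_equal(domain_size(mk(flat)), 0)             # ties -> smallest radius

  raw <- structure(list(r = r, H = peak, smoothed = FALSE,
                        smoothing_half_width = NA_real_), class = "hest")
  expect_error(domain_size(raw), "smooth")
  expect_error(domain_size(mk(rep(NA_real_, length(r)))), "all NA")
})

test_that("domain size is invariant to translation and rotation of the pattern", {
  pt <- sim_thomas(15, 25, 50, window = c(0, 3000, 0, 3000), seed = 23)
  ds <- function(p) {
    domain_size(smooth_h(k_to_h(ripley_k(p, r = seq(0, 400, 5)))))
  }
  d0 <- ds(pt)
  shifted <- point_pattern(pt$x + 120, pt$y - 40,
                           window = pt$window + c(120, 120, -40, -40))
  expect_equal(ds(shifted), d0)
  rotated <- point_pattern(pt$y, 3000 - pt$x, window = pt$window)
  expect_equal(ds(rotated), d0)
})

test_that("H separates clustered from random patterns at small radii", {
  r <- seq(0, 400, 5)
  h_pos <- vapply(1:20, function(s) {
    pt <- sim_thomas(20, 30, 60, seed = 900 + s)
    hs <- smooth_h(k_to_h(ripley_k(pt, r = r)))
    min(hs$H[hs$r >= 20 & hs$r <= 150])
  }, numeric(1))
  expect_gte(mean(h_pos > 0), 0.95)
})
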