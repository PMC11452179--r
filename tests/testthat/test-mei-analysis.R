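## Characterisation machinery that needs no trained model: temporal kernels,
## SVD decomposition, DoG fits, centre size/mask, temporal frequency,
## chromatic contrast, rank-1 reconstruction, calibration transform,
## weighted responses and the selectivity index.

test_that("temporal kernels follow the Fourier parameterisation", {
  k <- temporal_kernel(rep(0, 7), rep(0, 7), L = 21)
  expect_equal(k, rep(0, 21))
  expect_error(temporal_kernel(rep(0, 8), rep(0, 8), L = 21), "floor")
  expect_error(temporal_kernel(1, 1, L = 21, tau = -1), "tau")

  ## single cosine term vs an independent scalar-loop oracle
  beta <- c(1, 0, 0); L <- 11; tau <- 1
  k <- temporal_kernel(rep(0, 3), beta, L = L, tau = tau)
  tgrid <- seq(0, 1, length.out = L)
  oracle <- numeric(L)
  for (u in seq_len(L)) {
    env <- 1 / (1 + exp(-(tgrid[u] + L * 0.95 * tau)))
    oracle[u] <- cos(2 * pi * 1 * tau * tgrid[u] * env)
  }
  expect_close(k, oracle, 1e-10)
})

test_that("MEI decomposition recovers exact low-rank structure", {
  tens <- array(0, dim = c(2, 50, 18, 16))
  tset <- sin(seq(0, 6, length.out = 50))
  sp <- gaussian_blob(8, 9, 2)
  for (ci in 1:2) tens[ci, , , ] <- outer(tset, sp)
  d <- decompose_mei(tens)
  expect_lt(d$green$recon_error, 1e-10)
  ## components equal the generators up to scale (sign fixed to positive
  ## centre)
  cs <- cor(as.numeric(d$green$spatial), as.numeric(sp))
  expect_equal(abs(cs), 1, tolerance = 1e-9)
  expect_gt(d$green$spatial[which.max(abs(d$green$spatial))], 0)

  ## rank-2 with singular values (10, 1): Eckart-Young bound
  u2 <- cos(seq(0, 6, length.out = 50)); u2 <- u2 / l2norm(u2)
  sp2 <- gaussian_blob(4, 5, 1.5)
  m <- 10 * outer(tset / l2norm(tset), as.numeric(sp)) +
    1 * outer(u2, as.numeric(sp2) / l2norm(sp2))
  tens2 <- array(0, dim = c(2, 50, 18, 16))
  tens2[1, , , ] <- array(m, dim = c(50, 18, 16))
  tens2[2, , , ] <- array(m, dim = c(50, 18, 16))
  d2 <- decompose_mei(tens2)
  expect_gte(d2$green$var_explained, 100 / 101 - 1e-9)

  ## flattening round trip: reconstruction lives in the original layout
  rec <- reconstruct_rank1(d)
  expect_close(rec, tens, 1e-9)
})

test_that("all-zero channels are flagged, not fatal", {
  tens <- array(0, dim = c(2, 50, 18, 16))
  tens[2, , , ] <- outer(sin(1:50), gaussian_blob(8, 9, 2))
  d <- decompose_mei(tens)
  expect_true(d$green$zero)
  expect_equal(d$green$s1, 0)
})

test_that("DoG fit recovers known parameters within 5%", {
  H <- 18; W <- 16
  X <- matrix(rep(seq_len(W), each = H), H, W)
  Y <- matrix(rep(seq_len(H), W), H, W)
  truth <- list(mux = 8, muy = 9, Ac = 1, As = 0.3, sxc = 2, syc = 3,
                sxs = 5, sys = 6, th = 0.4)
  spat <- gauss2d(X, Y, truth$mux, truth$muy, truth$Ac, truth$sxc,
                  truth$syc, truth$th) -
    gauss2d(X, Y, truth$mux, truth$muy, truth$As, truth$sxs, truth$sys,
            truth$th)
  dog <- fit_dog(spat)
  expect_false(dog$failed)
  expect_lt(dog$cost, 1e-4)
  expect_equal(unname(dog$mu["x"]), truth$mux, tolerance = 0.05 * truth$mux)
  expect_equal(unname(dog$mu["y"]), truth$muy, tolerance = 0.05 * truth$muy)
  expect_equal(dog$A_c, truth$Ac, tolerance = 0.05)
  expect_equal(unname(dog$sigma_c["x"]), truth$sxc, tolerance = 0.05 * 2)
  expect_equal(unname(dog$sigma_c["y"]), truth$syc, tolerance = 0.05 * 3)
  expect_equal(unname(dog$sigma_s["x"]), truth$sxs, tolerance = 0.05 * 5)
})

test_that("a pure Gaussian yields a negligible surround", {
  H <- 18; W <- 16
  X <- matrix(rep(seq_len(W), each = H), H, W)
  Y <- matrix(rep(seq_len(H), W), H, W)
  spat <- gauss2d(X, Y, 8, 9, 1, 2.5, 2, 0.2)
  dog <- fit_dog(spat)
  expect_lt(abs(dog$A_s), 0.05 * abs(dog$A_c))
  expect_error(fit_dog(matrix(1, 18, 16)), "constant")
})

test_that("centre size averages the two diameters", {
  dog <- structure(list(mu = c(x = 8, y = 9), A_c = 1, A_s = 0,
                        sigma_c = c(x = 8, y = 8),
                        sigma_s = c(x = 10, y = 10),
                        theta_c = 0, theta_s = 0, cost = 0, failed = FALSE),
                   class = "dog_params")
  expect_equal(centre_size(dog, px_to_um = 6.25), 100)
  dog$sigma_c <- c(x = 6.4, y = 9.6)   # 40 and 60 um at 6.25 um/px
  expect_equal(centre_size(dog, px_to_um = 6.25), 100)
})

test_that("centre mask equals a rasterisation oracle and is symmetric", {
  dog <- structure(list(mu = c(x = 8, y = 9), A_c = 1, A_s = 0,
                        sigma_c = c(x = 2, y = 2),
                        sigma_s = c(x = 5, y = 5),
                        theta_c = 0.3, theta_s = 0, cost = 0,
                        failed = FALSE),
                   class = "dog_params")
  m <- centre_mask(dog)
  ## oracle: pixel-wise comparison of the Gaussian against its value at the
  ## one-sigma diagonal point (10, 11)
  oracle <- matrix(FALSE, 18, 16)
  for (x in 1:16) for (y in 1:18)
    oracle[y, x] <- gauss2d(x, y, 8, 9, 1, 2, 2, 0.3) >=
      gauss2d(10, 11, 8, 9, 1, 2, 2, 0.3) - 1e-12
  expect_equal(unname(m), oracle)
  ## the pixel nearest mu is always inside
  expect_true(m[9, 8])
  ## rotating theta by pi leaves the mask unchanged
  dog2 <- dog; dog2$theta_c <- dog$theta_c + pi
  expect_equal(centre_mask(dog2), m)
})

test_that("temporal frequency: pure tone, DC, and zero input", {
  fr <- 30
  tone <- sin(2 * pi * 2 * (0:49) / fr)
  expect_equal(as.numeric(temporal_frequency(tone, fr)), 2, tolerance = 0.3)
  dc <- rep(1, 50)
  expect_lt(as.numeric(temporal_frequency(dc, fr)), 0.2)
  z <- temporal_frequency(rep(0, 50), fr)
  expect_equal(as.numeric(z), 0)
  expect_true(isTRUE(attr(z, "flagged")))
})

test_that("chromatic contrast uses the last two UV peaks for both channels", {
  ## hand-built MEI: UV ramps +0.4 between the last two peaks, green -0.3
  Tn <- 50
  uvt <- sin(2 * pi * 3 * (0:(Tn - 1)) / Tn)      # 3 peaks
  tens <- array(0, dim = c(2, Tn, 18, 16))
  mask <- matrix(FALSE, 18, 16); mask[8:11, 7:10] <- TRUE
  pk <- which(diff(sign(diff(uvt))) < 0) + 1
  t1 <- pk[length(pk) - 1]; t2 <- pk[length(pk)]
  tens[2, t1, , ][mask] <- 0.1; tens[2, t2, , ][mask] <- 0.5
  tens[1, t1, , ][mask] <- 0.4; tens[1, t2, , ][mask] <- 0.1
  dec <- list(uv = list(temporal = uvt))
  ctr <- mei_contrast(tens, dec, mask)
  expect_equal(unname(ctr$gamma), c(0.1 - 0.4, 0.5 - 0.1), tolerance = 1e-9)
  expect_true(ctr$opponent)
  expect_equal(c(ctr$t1, ctr$t2), c(t1, t2))
  ## a monotonically rising channel between the peaks is ON (gamma > 0)
  expect_gt(ctr$gamma["uv"], 0)
  ## fewer than two peaks flags the cell
  dec1 <- list(uv = list(temporal = seq(0, 1, length.out = Tn)))
  expect_error(mei_contrast(tens, dec1, mask), "peaks")
})

test_that("rank-1 reconstruction is the best rank-1 approximation", {
  set.seed(8)
  tens <- array(rnorm(2 * 50 * 18 * 16, 0, 0.1), dim = c(2, 50, 18, 16))
  d <- decompose_mei(tens)
  rec <- reconstruct_rank1(d)
  for (ci in 1:2) {
    resid <- matrix(tens[ci, , , ] - rec[ci, , , ], 50, 288)
    ## residual orthogonal to both components (SVD optimality)
    expect_lt(abs(sum(resid %*% as.numeric(d[[ci]]$spatial))), 1e-8)
    expect_lt(abs(sum(t(resid) %*% d[[ci]]$temporal)), 1e-8)
  }
  norm <- list(mean = c(green = 0.12, uv = 0.12),
               sd = c(green = 0.03, uv = 0.03))
  disp <- reconstruct_rank1(d, norm, display = TRUE)
  expect_gte(min(disp), 0)
  expect_lte(max(disp), 255)
})

test_that("setup transform matches hand matrix algebra", {
  cal <- setup_calibration()
  ## A = B: identity before range restoration
  eq <- setup_transform(c(0.3, 0.7), list(A = cal$A, B = cal$A))
  expect_close(eq, c(0.3, 0.7), 1e-12)
  ## printed matrices, x = (1, 0): explicit 2x2 inversion oracle
  xp <- setup_transform(c(1, 0), cal)
  detB <- 1 - 0.9 * 0.035
  oracle <- c(1 / detB, -0.035 / detB) # B^-1 applied to A %*% (1,0) = (1,0)
  expect_close(xp, oracle, 1e-12)
  expect_equal(round(xp, 4), c(1.0325, -0.0361))
  ## cone-activation equivalence A x = B x'
  set.seed(9)
  for (i in 1:5) {
    x <- rnorm(2)
    expect_close(cal$A %*% x, cal$B %*% setup_transform(x, cal), 1e-12)
  }
  expect_error(setup_transform(c(1, 1), list(A = cal$A,
                                             B = matrix(1, 2, 2))),
               "singular")
})

test_that("weighted responses collapse correctly in limiting cases", {
  gx <- seq(4, 12, by = 2); gy <- seq(5, 13, by = 2)
  resp <- array(0, dim = c(2, 5, 5, 60))
  resp[1, 3, 3, ] <- 4            # only the central node responds
  resp[2, , , ] <- 1              # uniform responses
  ## delta limit: tiny sigma on the central node returns its response
  r <- weighted_response(resp, gx, gy, mu = c(x = gx[3], y = gy[3]),
                         sigma = 0.05)
  dens_ctr <- 1 / (2 * pi * 0.05^2)
  expect_equal(r[1] / dens_ctr, 4 * 20 / 20, tolerance = 1e-3)
  ## uniform responses: common value times the summed (unnormalised) density
  wsum <- sum(outer(gx - 8, gy - 9, function(dx, dy)
    exp(-(dx^2 + dy^2) / (2 * 4)) / (2 * pi * 4)))
  r2 <- weighted_response(resp, gx, gy, mu = c(x = 8, y = 9), sigma = 2)
  expect_equal(r2[2], wsum, tolerance = 1e-9)
  expect_error(weighted_response(resp, gx, gy, c(x = 8, y = 9), 0), "sigma")
})

test_that("selectivity index matches a hand calculation and affine invariance", {
  r <- rep(1, 11)
  si0 <- selectivity_index(r, 1)
  expect_equal(as.numeric(si0), 0)
  expect_true(isTRUE(attr(si0, "flagged")))
  ## own response equals the mean of the others
  r1 <- c(2, 1, 3, 2, 2, 2, 2, 2, 2, 2, 2)
  expect_equal(selectivity_index(r1, 1), 0, tolerance = 1e-12)
  ## hand-calculated 11-term example: r = (2, 0, ..., 0), own index 1
  r2 <- c(2, rep(0, 10))
  mu <- mean(r2); s <- sd(r2)
  z <- (r2 - mu) / s
  expect_equal(selectivity_index(r2, 1), z[1] - mean(z[-1]))
  ## invariance under affine rescaling of the raw responses
  expect_equal(selectivity_index(5 * r2 + 3, 1), selectivity_index(r2, 1))
})

test_that("grid experiment ranks a cell's own MEI first", {
  ## one cell with a central RF; stimulus 1 matches its filter, stimulus 2
  ## is spatially displaced
  cells <- generate_population(population_config(
    families = c(`ON` = 1), rf_sigma_range = c(2, 2), noise_level = 0),
    seed = 5)
  cl <- cells[[1]]
  cl$rf_location <- c(x = 8.5, y = 9.5)
  cl$spatial_filter$green <- gaussian_blob(8.5, 9.5, 2)
  cl$spatial_filter$uv <- cl$spatial_filter$green
  tset <- rev(cl$temporal_filter$green)
  own <- array(0, dim = c(2, 50, 18, 16))
  for (ci in 1:2)
    own[ci, 30:50, , ] <- outer(tset, cl$spatial_filter$green)[1:21, , ]
  other <- own
  other[, , , ] <- 0
  other[1, 30:50, , ] <- outer(tset, gaussian_blob(12, 13, 2))[1:21, , ]
  other[2, , , ] <- other[1, , , ]
  norm <- list(mean = c(green = 0.13, uv = 0.13),
               sd = c(green = 0.03, uv = 0.03))
  ge <- simulate_grid_experiment(list(cl), list(own, other), norm)
  rt <- weighted_response(ge$responses[1, , , , ], ge$grid_x, ge$grid_y,
                          mu = c(x = 8.5, y = 9.5), sigma = 2)
  expect_gt(rt[1], rt[2])
})

test_that("contrast basis equalises channel norms and preserves total contrast", {
  set.seed(10)
  tens <- array(rnorm(2 * 50 * 18 * 16), dim = c(2, 50, 18, 16))
  tens[1, , , ] <- 3 * tens[1, , , ]          # channel norms ratio 3:1-ish
  bb <- build_basis(tens)
  n1 <- sqrt(sum(bb$e1^2)); n2 <- sqrt(sum(bb$e2^2))
  expect_equal(n1, n2, tolerance = 1e-9)
  mei_at <- basis_stimulus(bb, -1, 1)
  expect_equal(sqrt(sum(mei_at^2)), sqrt(sum(tens^2)), tolerance = 1e-9)
  ## disjoint channel support: orthogonal basis vectors
  expect_equal(sum(bb$e1 * bb$e2), 0)
  ## equal channel norms: scale factors 1 and exact reproduction at (-1, 1)
  teq <- array(rnorm(2 * 50 * 18 * 16), dim = c(2, 50, 18, 16))
  teq[2, , , ] <- teq[1, , , ]
  beq <- build_basis(teq)
  expect_equal(beq$s1, 1, tolerance = 1e-12)
  expect_equal(beq$s2, 1, tolerance = 1e-12)
  expect_close(basis_stimulus(beq, -1, 1), teq, 1e-9)
  tz <- teq; tz[1, , , ] <- 0
  expect_error(build_basis(tz), "non-zero")
})
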