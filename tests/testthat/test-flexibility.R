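# 5-residue CA-only toy model for flexibility tests
flex_model <- function() {
  res <- lapply(1:5, function(i) {
    list(resno = i, resname = "GLY",
         atoms = data.frame(name = "CA", x = 3.8 * i, y = (i %% 2) * 2,
                            z = 0.5 * i, elem = "C"))
  })
  load_structure(write_fixture_pdb(res))
}

rand_frames <- function(m, n, jitter = 0, seed = 1) {
  set.seed(seed)
  base <- as.vector(t(as.matrix(m$atom[, c("x", "y", "z")])))
  t(vapply(seq_len(n), function(i) base + rnorm(length(base), 0, jitter),
           numeric(length(base))))
}

rot_z <- function(th) matrix(c(cos(th), -sin(th), 0,
                               sin(th), cos(th), 0, 0, 0, 1), 3, 3)

apply_rigid <- function(frame_vec, R, t = c(0, 0, 0)) {
  X <- matrix(frame_vec, ncol = 3, byrow = TRUE)
  as.vector(t(X %*% t(R) + matrix(t, nrow(X), 3, byrow = TRUE)))
}

test_that("identical frames superpose onto themselves", {
  m <- flex_model()
  h <- open_ensemble(m, rand_frames(m, 4), 300)
  al <- superpose_frames(h)
  expect_lt(max(abs(sweep(al$xyz, 2, al$xyz[1, ]))), 1e-8)
})

test_that("a rigidly rotated frame fits back to the reference", {
  m <- flex_model()
  base <- rand_frames(m, 1)
  rot <- apply_rigid(base[1, ], rot_z(0.7), t = c(5, -3, 2))
  h <- open_ensemble(m, rbind(base, rot), 300)
  al <- superpose_frames(h)
  expect_lt(sqrt(mean((al$xyz[2, ] - al$xyz[1, ])^2)), 1e-6)
})

test_that("superposition agrees with an independent Kabsch oracle", {
  m <- flex_model()
  xyz <- rand_frames(m, 5, jitter = 0.3, seed = 42)
  h <- open_ensemble(m, xyz, 300)
  al <- superpose_frames(h)
  # oracle: iterate mean-structure fitting with our own Kabsch until fixed
  oracle <- xyz
  for (it in 1:20) {
    ref <- matrix(colMeans(oracle), ncol = 3, byrow = TRUE)
    oracle <- t(apply(oracle, 1, function(f) {
      as.vector(t(kabsch_oracle(ref, matrix(f, ncol = 3, byrow = TRUE))))
    }))
  }
  # both must produce the same per-atom fluctuations (frames may differ by a
  # common global transform)
  pro <- rmsf_profile(al, m)
  por <- rmsf_profile(oracle, m, sel = al$sel)
  expect_equal(pro$rmsf, por$rmsf, tolerance = 1e-5)
  expect_lte(al$iterations, 10)
})

test_that("superposition requires >= 2 frames and >= 3 atoms", {
  m <- flex_model()
  expect_error(superpose_frames(open_ensemble(m, rand_frames(m, 1), 300)),
               "2 frames")
  h <- open_ensemble(m, rand_frames(m, 3), 300)
  expect_error(superpose_frames(h, sel = 1:2), "3 selected atoms")
})

test_that("RMSF closed forms: static zero, two-frame displacement d", {
  m <- flex_model()
  base <- rand_frames(m, 2)
  p0 <- rmsf_profile(base, m, sel = calpha_indices(m))
  expect_equal(p0$rmsf, rep(0, 5))

  d <- 1.7
  two <- rand_frames(m, 2)
  two[1, 4] <- two[1, 4] - d   # residue 2's CA x +/- d about its mean
  two[2, 4] <- two[2, 4] + d
  p <- rmsf_profile(two, m, sel = calpha_indices(m))
  expect_equal(p$rmsf[2], d)
  expect_equal(p$rmsf[-2], rep(0, 4))
})

test_that("single-frame RMSF is an error", {
  m <- flex_model()
  expect_error(rmsf_profile(rand_frames(m, 1), m,
                            sel = calpha_indices(m)), "single frame")
})

test_that("Gaussian jitter sigma gives RMSF close to sigma*sqrt(3)", {
  m <- flex_model()
  sigma <- 0.5
  xyz <- rand_frames(m, 1e4, jitter = sigma, seed = 7)
  p <- rmsf_profile(xyz, m, sel = calpha_indices(m))
  expect_equal(mean(p$rmsf), sigma * sqrt(3), tolerance = 0.03)
})

test_that("RMSF agrees with the bio3d implementation on aligned frames", {
  # bio3d divides by n - 1 frames; the definition used here averages over
  # frames, so the comparison carries the population-variance factor
  m <- flex_model()
  n <- 50
  xyz <- rand_frames(m, n, jitter = 0.4, seed = 9)
  p <- rmsf_profile(xyz, m, sel = calpha_indices(m))
  expect_equal(p$rmsf, bio3d::rmsf(xyz) * sqrt((n - 1) / n),
               tolerance = 1e-10)
})

test_that("RMSF is invariant to a global rigid transform of all frames", {
  m <- flex_model()
  h <- open_ensemble(m, rand_frames(m, 20, jitter = 0.3, seed = 3), 300)
  p1 <- ensemble_rmsf(h)
  moved <- t(apply(h$xyz, 1, apply_rigid, R = rot_z(1.1), t = c(9, 9, -4)))
  p2 <- ensemble_rmsf(open_ensemble(m, moved, 300))
  expect_equal(p1$rmsf, p2$rmsf, tolerance = 1e-6)
})

test_that("temperature sensitivity is the population SD across the ladder", {
  prof <- function(vals, temp) {
    structure(data.frame(key = paste0("A:", seq_along(vals)), rmsf = vals),
              temperature = temp, class = c("RMSFProfile", "data.frame"))
  }
  same <- lapply(c(283, 305, 327), function(t) prof(c(1, 2, 3), t))
  s <- temperature_sensitivity(same)
  expect_equal(s$sensitivity, rep(0, 3))

  two <- list(prof(c(1, 1), 283), prof(c(3, 1), 393))
  s2 <- temperature_sensitivity(two)
  expect_equal(s2$sensitivity, c(1, 0))  # population SD of {1,3} is 1

  expect_error(temperature_sensitivity(list(prof(c(1, 2), 283),
                                            prof(c(1, 2, 3), 300))),
               "mismatched")
})

test_that("sensitivity is permutation-invariant in temperature order and
           ranks planted hotspots first", {
  set.seed(13)
  n_res <- 30
  temps <- seq(283, 393, length.out = 6)
  hot <- c(4, 17, 25)
  profs <- lapply(temps, function(t) {
    v <- 1 + 0.001 * rnorm(n_res)
    # hotspots get strongly temperature-dependent RMSF
    v[hot] <- 1 + 2 * (t - 283) / 110 + 0.001 * rnorm(3)
    structure(data.frame(key = paste0("A:", 1:n_res), rmsf = v),
              temperature = t, class = c("RMSFProfile", "data.frame"))
  })
  s <- temperature_sensitivity(profs)
  s_perm <- temperature_sensitivity(profs[c(4, 1, 6, 2, 5, 3)])
  expect_equal(s$sensitivity, s_perm$sensitivity)
  expect_setequal(order(-s$sensitivity)[1:3], hot)
})
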