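mk_stack <- function(f0, fm, n = 8, noise = 0, seed = 10) {
  set.seed(seed)
  f0m <- matrix(f0, n, n); fmm <- matrix(fm, n, n)
  nz <- function() if (noise > 0) matrix(rnorm(n * n, 0, noise), n) else 0
  frames <- c(list(f0m + nz()),
              lapply(1:50, function(j) f0m + (fmm - f0m) * j / 50 + nz()),
              lapply(1:50, function(j) f0m + (fmm - f0m) * exp(-j / 8) + nz()))
  validate_stack(frames, plot_id = "p")
}

test_that("validate_stack enforces the 101-frame same-shape contract", {
  frames <- replicate(101, matrix(0, 4, 4), simplify = FALSE)
  st <- validate_stack(frames)
  expect_s3_class(st, "fluorescence_stack")
  expect_identical(st$timing$pre, 1L)
  expect_length(st$timing$pulse, 50)
  expect_error(validate_stack(frames[1:100]), "malformed-stack")
  bad <- frames; bad[[7]] <- matrix(0, 3, 4)
  expect_error(validate_stack(bad), "malformed-stack")
})

test_that("F0/FM maps recover generator truth exactly at zero noise", {
  st <- mk_stack(f0 = 100, fm = 500)
  thr <- contribution_thresholds(c(50, 200, 300, 400, 480))
  maps <- compute_f0_fm(st, thr)
  expect_true(all(maps$f0 == 100))
  expect_true(all(maps$fm == 500))
  expect_true(all(maps$bin == 5L))
  ## constant stack: F0 = FM, FV = 0
  cst <- validate_stack(replicate(101, matrix(7, 4, 4), simplify = FALSE))
  m2 <- compute_f0_fm(cst, thr)
  expect_identical(m2$f0, m2$fm)
  ## FM below the first edge lands in background bin 0
  low <- mk_stack(f0 = 5, fm = 20)
  m3 <- compute_f0_fm(low, thr)
  expect_true(all(m3$bin == 0L))
  expect_error(fluorescence_traits(m3$f0, m3$fm, m3$bin), "insufficient-data")
})

test_that("fluorescence traits follow FV = FM - F0 and FV/FM = (FM - F0)/FM", {
  f0 <- matrix(100, 2, 2); fm <- matrix(500, 2, 2); bin <- matrix(1, 2, 2)
  tr <- fluorescence_traits(f0, fm, bin)
  expect_equal(tr$fv, 400)
  expect_equal(tr$fvfm, 0.8)
  tr0 <- fluorescence_traits(fm, fm, bin)
  expect_equal(tr0$fv, 0); expect_equal(tr0$fvfm, 0)
  ## hand aggregation oracle: two pixels (100,500) and (200,600)
  f0b <- matrix(c(100, 200), 1); fmb <- matrix(c(500, 600), 1)
  trb <- fluorescence_traits(f0b, fmb, matrix(1, 1, 2))
  expect_equal(trb$f0, 150); expect_equal(trb$fm, 550)
  expect_equal(trb$fvfm, 400 / 550, tolerance = 1e-12)
  expect_error(fluorescence_traits(f0, fm, matrix(1, 3, 3)), "shape")
})

test_that("FV/FM is bounded and scale-invariant", {
  st <- mk_stack(f0 = 120, fm = 480, noise = 2)
  thr <- contribution_thresholds(c(50, 200, 300, 400, 470))
  m <- compute_f0_fm(st, thr)
  tr <- fluorescence_traits(m$f0, m$fm, m$bin)
  expect_gte(tr$fvfm, 0); expect_lt(tr$fvfm, 1)
  ## multiply all frames by a positive constant
  st2 <- st; st2$frames <- lapply(st$frames, function(f) f * 3)
  thr2 <- contribution_thresholds(c(50, 200, 300, 400, 470) * 3)
  m2 <- compute_f0_fm(st2, thr2)
  tr2 <- fluorescence_traits(m2$f0, m2$fm, m2$bin)
  expect_equal(tr2$fvfm, tr$fvfm, tolerance = 1e-12)
})

test_that("plot-level FV/FM error shrinks as frame noise goes to zero", {
  errs <- vapply(c(4, 1, 0.25), function(s) {
    st <- mk_stack(f0 = 100, fm = 500, n = 24, noise = s, seed = 11)
    m <- compute_f0_fm(st, contribution_thresholds(c(50, 200, 300, 400, 480)))
    abs(fluorescence_traits(m$f0, m$fm, m$bin)$fvfm - 0.8)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.005)
})

test_that("PSII stacks round-trip through the directory format", {
  st <- mk_stack(f0 = 90, fm = 450, n = 6)
  st$gt <- gt_northup()
  dir <- file.path(tempdir(), "psii_rt")
  unlink(dir, recursive = TRUE)
  write_psii_stack(st, dir, date = "2020-02-17")
  st2 <- read_psii_stack(dir)
  expect_identical(length(st2$frames), 101L)
  expect_equal(st2$frames[[1]], st$frames[[1]], tolerance = 1e-4)
  expect_equal(unclass(st2$gt), unclass(st$gt), tolerance = 1e-12)
  expect_identical(st2$plot_id, "p")
})
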