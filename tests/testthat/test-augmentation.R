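test_that("amplitude augmentation scales pointwise by 1 + a_a * u", {
  s <- rnorm(100)
  expect_identical(augment_amplitude(s, 0, 0.7), s)
  expect_equal(augment_amplitude(s, 0.5, 0.5), s * 1.25)
  expect_identical(augment_amplitude(s, 1, -1), s * 0)
})

test_that("sign flip triggers exactly when u < a_s", {
  s <- rnorm(50)
  expect_identical(augment_signflip(s, 0, 0.3), s)
  expect_identical(augment_signflip(s, 1, 0.999), -s)
  expect_identical(augment_signflip(s, 0.5, 0.5), s)     # boundary: u == a_s
  set.seed(8)
  flips <- vapply(runif(10000), function(u) {
    augment_signflip(1, 0.5, u) < 0
  }, logical(1))
  expect_lt(abs(mean(flips) - 0.5), 0.015)               # 3 sigma binomial
})

test_that("window warping shifts frequencies by T*/T", {
  fs <- 64
  T_len <- 640L
  src <- sin(2 * pi * 4 * (0:(20 * fs - 1)) / fs)
  start <- 321L
  s <- src[start:(start + T_len - 1)]
  expect_identical(augment_frequency(s, 0, 0.7, src, start), s)
  warped <- augment_frequency(s, 0.2, 1, src, start)      # T* = 768
  expect_identical(length(warped), T_len)
  expect_equal(peak_frequency(warped, fs), 4 * floor(1.2 * T_len) / T_len,
               tolerance = 0.05)
  shrunk <- augment_frequency(s, 0.2, -1, src, start)     # T* = 512
  expect_identical(length(shrunk), T_len)
  expect_equal(peak_frequency(shrunk, fs), 4 * 512 / 640, tolerance = 0.05)
})

test_that("time shift slides the window by floor(T * a_t * u) source samples", {
  T_len <- 1920L
  src <- as.numeric(1:10000)               # ramp: value == index
  start <- 2001L
  s <- src[start:(start + T_len - 1)]
  expect_identical(augment_timeshift(s, 0, 0.9, src, start), s)
  out <- augment_timeshift(s, 0.06, 1, src, start)
  expect_identical(out[1], src[start + 115])              # floor(115.2)
  expect_identical(out, src[(start + 115):(start + 115 + T_len - 1)])
  # edge replication beyond the recording
  s2 <- src[1001:(1000 + T_len)]
  out2 <- augment_timeshift(s2, 1, -1, src, 1001L)   # dt = -1920
  expect_identical(out2[1], src[1])
})

test_that("the composite augmentation honours order, identity and zeros", {
  set.seed(5)
  src <- rnorm(8000)
  cw <- windows_from_signal(src, 3, 1920L, spacing = 2000)
  p0 <- augmentation_params()
  expect_identical(augment_window(cw, 2, p0, u = c(0.3, 0.9, -0.2, 0.5)),
                   cw$x[2, ])
  # amplitude zeroing propagates through the whole chain
  pz <- augmentation_params(a_a = 1, a_f = 0.3, a_s = 0.5, a_t = 0.1)
  expect_identical(augment_window(cw, 1, pz, u = c(-1, 0.9, 0.4, 0.6)),
                   numeric(1920))
  # determinism under a fixed RNG stream
  pa <- augmentation_params(a_a = .5, a_f = .1, a_s = .5, a_t = .05)
  set.seed(77); o1 <- augment_window(cw, 2, pa)
  set.seed(77); o2 <- augment_window(cw, 2, pa)
  expect_identical(o1, o2)
})

test_that("the composite equals the explicit operator order on fixed draws", {
  set.seed(6)
  src <- rnorm(9000)
  cw <- windows_from_signal(src, 2, 1920L, spacing = 2500)
  s <- cw$x[1, ]; start <- cw$starts[1]
  # warp disabled: amplitude -> flip -> (identity warp) -> shift
  p <- augmentation_params(a_a = 0.4, a_f = 0, a_s = 1, a_t = 0.05)
  u <- c(0.6, 0.2, -0.8, 0.9)
  mfac <- (1 + p$a_a * u[1]) * -1
  explicit <- augment_timeshift(
    augment_frequency(augment_signflip(augment_amplitude(s, p$a_a, u[1]),
                                       p$a_s, u[2]),
                      p$a_f, u[3], source = mfac * src, start = start),
    p$a_t, u[4], source = mfac * src, start = start)
  expect_equal(augment_window(cw, 1, p, u = u), explicit)
  # shift disabled: amplitude -> flip -> warp
  p2 <- augmentation_params(a_a = 0.3, a_f = 0.15, a_s = 0, a_t = 0)
  u2 <- c(-0.4, 0.7, 0.9, 0.1)
  mfac2 <- 1 + p2$a_a * u2[1]
  explicit2 <- augment_frequency(augment_amplitude(s, p2$a_a, u2[1]),
                                 p2$a_f, u2[3], source = mfac2 * src,
                                 start = start)
  expect_equal(augment_window(cw, 1, p2, u = u2), explicit2)
})

test_that("all augmentation operators preserve window length", {
  set.seed(9)
  src <- rnorm(6000)
  cw <- windows_from_signal(src, 2, 1920L, spacing = 2000)
  p <- augmentation_params(a_a = 1, a_f = 0.5, a_s = 0.5, a_t = 0.1)
  for (i in 1:20) {
    expect_identical(length(augment_window(cw, 1 + i %% 2, p)), 1920L)
  }
})

test_that("amplitude augmentation is mean-preserving over the draw", {
  set.seed(11)
  scales <- 1 + 0.8 * runif(20000, -1, 1)
  expect_lt(abs(mean(scales) - 1), 0.01)
})

test_that("augmentation strengths outside [0, 1] are rejected", {
  expect_error(augmentation_params(a_a = 1.2), "\\[0, 1\\]")
  expect_error(augmentation_params(a_t = -0.1), "\\[0, 1\\]")
})
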