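# Flow-cytometry histogram I/O, peak calling, QC gating, genome sizing
# and ploidy inference.

test_that("event lists bin with count conservation; histograms round-trip;
           negative intensities are rejected", {
  f <- tempfile(fileext = ".csv")
  set.seed(2)
  ev <- rnorm(10000, 200, 10)
  write.csv(data.frame(intensity = ev), f, row.names = FALSE)
  h <- readCytometry(f)
  expect_equal(totalEvents(h), 10000)
  expect_equal(length(channels(h)), 1024)

  f2 <- tempfile(fileext = ".csv")
  write.csv(data.frame(channel = channels(h), count = counts(h)), f2,
            row.names = FALSE)
  h2 <- readCytometry(f2)
  expect_equal(channels(h2), channels(h))
  expect_equal(counts(h2), counts(h))

  f3 <- tempfile(fileext = ".csv")
  write.csv(data.frame(intensity = c(100, -5, 200)), f3, row.names = FALSE)
  expect_error(readCytometry(f3), "negative")
  f4 <- tempfile(fileext = ".csv")
  writeLines("intensity", f4)
  expect_error(readCytometry(f4), "no data rows")
})

test_that("peak calls recover simulated truth and come ordered by channel", {
  syn <- synthFcHistogram(peaks = data.frame(mean = 200, cv = 5,
                                             events = 10000), seed = 1)
  pk <- detectPeaks(syn$histogram)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$mean_channel, 200, tolerance = 0.01)
  expect_lt(abs(pk$cv_percent - 5), 0.5)

  syn2 <- synthFcHistogram(peaks = data.frame(mean = c(100, 300),
                                              cv = c(4, 4),
                                              events = c(8000, 8000)),
                           seed = 2)
  pk2 <- detectPeaks(syn2$histogram, n_expected = 2)
  expect_equal(nrow(pk2), 2L)
  expect_true(pk2$mean_channel[1] < pk2$mean_channel[2])
  expect_equal(pk2$mean_channel, c(100, 300), tolerance = 0.02)

  # structureless input yields no call
  expect_warning(pk3 <- detectPeaks(EventHistogram(1:200, rep(10, 200))),
                 "no peak")
  expect_equal(nrow(pk3), 0L)
})

test_that("CV recovery holds across the QC-relevant range and debris
           barely moves the peak mean", {
  fails <- 0L
  runs <- 0L
  for (cv in c(2, 5, 9)) for (sd in 1:12) {
    syn <- synthFcHistogram(peaks = data.frame(mean = 250, cv = cv,
                                               events = 6000),
                            seed = 1000 * cv + sd)
    pk <- detectPeaks(syn$histogram)
    runs <- runs + 1L
    if (nrow(pk) != 1L || abs(pk$cv_percent - cv) >= 1) fails <- fails + 1L
  }
  expect_lte(fails / runs, 0.05)

  clean <- detectPeaks(synthFcHistogram(
    peaks = data.frame(mean = 200, cv = 5, events = 10000),
    seed = 7)$histogram)
  noisy <- detectPeaks(synthFcHistogram(
    peaks = data.frame(mean = 200, cv = 5, events = 10000),
    debris_frac = 0.2, seed = 7)$histogram, n_expected = 1)
  expect_lt(abs(noisy$mean_channel / clean$mean_channel - 1), 0.02)
})

test_that("ratio sizing is linear and recovers simulated genome sizes
           within 1%", {
  pk <- function(m, cv = 2, ev = 8000)
    data.frame(mean_channel = m, cv_percent = cv, events = ev)
  # identity and doubling arithmetic
  expect_equal(estimateGenomeSize(pk(500), pk(500), "pisum")$pg, 9.09)
  expect_equal(estimateGenomeSize(pk(400), pk(200), "solanum")$pg, 3.92)
  # exact proportionality in the channel ratio
  base <- estimateGenomeSize(pk(100), pk(400), "secale")$pg
  expect_equal(estimateGenomeSize(pk(300), pk(400), "secale")$pg, 3 * base)
  expect_error(estimateGenomeSize(pk(100), pk(0), "pisum"), "> 0")

  # end-to-end simulated recovery against the fungal standard
  std <- detectPeaks(synthFcHistogram(
    peaks = data.frame(mean = 400, cv = 5, events = 8000),
    seed = 11)$histogram)
  for (r in c(0.5, 0.65, 0.8)) {
    sam <- detectPeaks(synthFcHistogram(
      peaks = data.frame(mean = 400 * r, cv = 5, events = 8000),
      seed = round(100 * r))$histogram)
    est <- estimateGenomeSize(sam, std, "colletotrichum",
                              qcPolicy("fungus"))
    expect_equal(est$pg, 0.069 * r, tolerance = 0.01)
    expect_true(est$qc_pass)
  }
})

test_that("QC gates flip exactly at the event and CV boundaries and are
           monotone in the policy", {
  pk <- function(m, cv, ev)
    data.frame(mean_channel = m, cv_percent = cv, events = ev)
  plant <- qcPolicy("plant")
  ok <- function(cv_s, ev_s, pol = plant)
    estimateGenomeSize(pk(100, cv_s, ev_s), pk(200, 2, 10000),
                       "solanum", pol)$qc_pass
  expect_true(ok(2.99, 5000))
  expect_true(ok(3.00, 5000))     # inclusive CV ceiling
  expect_false(ok(3.01, 5000))
  expect_true(ok(2, 5000))
  expect_false(ok(2, 4999))       # event floor
  fungal <- qcPolicy("fungus")
  expect_true(ok(10.0, 5000, fungal))
  expect_false(ok(10.01, 5000, fungal))

  # monotonicity: relaxing the policy never turns a pass into a fail
  set.seed(5)
  for (i in 1:50) {
    cv <- runif(1, 0, 12); ev <- sample(1000:9000, 1)
    strict <- ok(cv, ev, qcPolicy("plant", min_events = 5000,
                                  cv_max_percent = 3))
    relaxed <- ok(cv, ev, qcPolicy("plant", min_events = 4000,
                                   cv_max_percent = 5))
    expect_true(!strict || relaxed)
  }
})

test_that("ploidy calls match the cytotype series and break ties downward", {
  expect_equal(inferPloidy(7.54)$ploidy, 4)
  expect_equal(inferPloidy(12.81)$ploidy, 6)
  expect_equal(inferPloidy(15.58)$ploidy, 8)
  expect_equal(inferPloidy(2 * 1.7, monoploid_pg = 1.7,
                           candidates = 2)$ploidy, 2)
  expect_equal(inferPloidy(2 * 1.7, monoploid_pg = 1.7,
                           candidates = 2)$residual, 0)
  # exact tie between 4x and 8x models -> smaller ploidy wins
  tie <- inferPloidy(32 / 3, monoploid_pg = 2, candidates = c(4, 8))
  expect_equal(tie$ploidy, 4)
})

test_that("pg/Mb conversion uses 978 Mb per pg and round-trips", {
  expect_equal(pgMbConvert(1, "pg_to_mb"), 978)
  expect_equal(pgMbConvert(68, "mb_to_pg"), 0.0695, tolerance = 0.001)
  x <- c(0.045, 7.54, 15.58)
  expect_equal(pgMbConvert(pgMbConvert(x, "pg_to_mb"), "mb_to_pg"), x)
  expect_error(pgMbConvert(-1), "positive")
})

test_that("the standards registry carries the published calibration values", {
  reg <- referenceStandards()
  expect_equal(getStandard("pisum")$genome_pg, 9.09)
  expect_equal(getStandard("Solanum")$genome_pg, 1.96)
  expect_equal(getStandard("secale")$genome_pg, 16.19)
  std <- getStandard("colletotrichum")
  expect_equal(std$genome_pg, 0.069)
  expect_equal(std$basis, "1C")
  # 68 Mb and 0.069 pg/1C describe the same genome within rounding
  expect_equal(pgMbConvert(68, "mb_to_pg"), std$genome_pg,
               tolerance = 0.01)
  expect_error(getStandard("zea"), "unknown standard")
})
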