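test_that("growing-degree days accumulate temperature above the base", {
  expect_equal(growing_degree_days(rep(0, 365)), 0)
  expect_equal(growing_degree_days(rep(20, 365)), 7300)
  set.seed(1)
  tavg <- rnorm(365, 12, 8)
  acc <- 0                               # brute-force daily loop oracle
  for (t in tavg) if (t > 5) acc <- acc + (t - 5)
  expect_equal(growing_degree_days(tavg, base_temp = 5), acc)
  expect_error(growing_degree_days(numeric(0)), "empty")
})

test_that("aridity index and temperature seasonality follow their definitions", {
  expect_equal(aridity_index(500, 1000), 0.5)
  expect_equal(aridity_index(0, 1000), 0)
  expect_equal(aridity_index(734, 912) * 912, 734)      # algebra round trip
  expect_error(aridity_index(500, 0), "pet")

  expect_equal(temperature_seasonality(rep(17, 12)), 0)
  alt <- rep(c(10, 20), 6)
  expect_equal(temperature_seasonality(alt), 100 * sd(alt))
  set.seed(2)
  m <- rnorm(12, 15, 4)
  expect_equal(temperature_seasonality(m, "sd"), sd(m))
  expect_error(temperature_seasonality(1:11), "12")
})

test_that("zone classification uses half-open bins, upper bin on edges", {
  sch <- zone_scheme(gdd_edges = c(0, 1000, 2000, 3000),
                     ai_edges = c(0, 0.5, 1, 2),
                     ts_edges = c(0, 100, 200))
  expect_equal(classify_zone(1000, 0.5, 100, sch), "2-2-2")  # edges go up
  expect_equal(classify_zone(999.9, 0.49, 99, sch), "1-1-1")
  # identical summaries get identical codes
  expect_equal(classify_zone(c(1500, 1500), c(0.7, 0.7), c(50, 50), sch),
               rep("2-2-1", 2))
  expect_error(classify_zone(5000, 0.5, 50, sch), "gdd")
  expect_error(classify_zone(1500, 3, 50, sch), "ai")

  # single bins per variable: everything in one zone
  one <- zone_scheme(c(0, 1e5), c(0, 100), c(0, 1e5))
  expect_equal(unique(classify_zone(runif(20, 1, 9000), runif(20, 0, 3),
                                    runif(20, 0, 500), one)), "1-1-1")
})

test_that("refining bin edges only subdivides zones", {
  coarse <- zone_scheme(c(0, 2000, 4000), c(0, 1, 2), c(0, 200))
  fine <- zone_scheme(c(0, 1000, 2000, 3000, 4000), c(0, 0.5, 1, 1.5, 2),
                      c(0, 100, 200))
  set.seed(3)
  gdd <- runif(200, 0, 3999); ai <- runif(200, 0, 1.99)
  ts <- runif(200, 0, 199)
  cz <- classify_zone(gdd, ai, ts, coarse)
  fz <- classify_zone(gdd, ai, ts, fine)
  # each fine zone maps into exactly one coarse zone
  expect_true(all(tapply(cz, fz, function(z) length(unique(z))) == 1))
})

test_that("the default shipped scheme loads and classifies", {
  sch <- zone_scheme_default()
  expect_s3_class(sch, "zone_scheme")
  expect_equal(classify_zone(7300, 0.65, 120, sch), "8-7-1")
})

test_that("isolation filter drops a planted remote site, order-independently", {
  set.seed(7)
  n <- 50
  d <- data.frame(zone_code = "Z1",
                  lon = rnorm(n, 30, 0.2), lat = rnorm(n, -2, 0.2))
  d$lon[13] <- 40                        # ~1000 km away
  kept <- filter_isolated(d)
  expect_equal(nrow(kept), n - 1)
  expect_false(40 %in% kept$lon)

  shuf <- d[sample(n), ]
  kept2 <- filter_isolated(shuf)
  expect_setequal(kept2$lon, kept$lon)   # row order irrelevant

  same <- data.frame(zone_code = "Z1", lon = rep(30, 10), lat = rep(-2, 10))
  expect_equal(nrow(filter_isolated(same)), 10)
  tiny <- data.frame(zone_code = "Z1", lon = c(0, 50), lat = c(0, 0))
  expect_equal(nrow(filter_isolated(tiny)), 2)   # too few sites to judge
})

test_that("stratum eligibility is strict and per season", {
  d <- data.frame(
    zone_code = c(rep("A", 201), rep("B", 200), rep("C", 300)),
    season = c(rep("single", 401), rep("first", 150), rep("second", 150)))
  s <- select_strata(d, min_n = 200)
  expect_true(all(s$eligible[s$zone_code == "A"]))        # 201 > 200
  expect_false(any(s$eligible[s$zone_code == "B"]))       # 200 is not enough
  # a two-season zone with 150 + 150 fields: both strata ineligible
  expect_false(any(s$eligible[s$zone_code == "C"]))
  expect_equal(length(unique(s$stratum[s$zone_code == "C"])), 2)

  expect_warning(select_strata(d[d$zone_code == "B", ], min_n = 500),
                 "empty")
})

test_that("sowing deviations are stratum-centred and wrap across new year", {
  expect_equal(sowing_deviation(100, "s"), 0)
  expect_equal(sowing_deviation(c(100, 110, 120), rep("s", 3)),
               c(-10, 0, 10))
  # deviations average zero within each stratum (arithmetic case)
  set.seed(4)
  doy <- sample(60:150, 40, TRUE)
  st <- sample(c("a", "b"), 40, TRUE)
  dev <- sowing_deviation(doy, st)
  expect_equal(as.numeric(tapply(dev, st, mean)), c(0, 0), tolerance = 1e-12)

  # December/January wrap: circular mean oracle computed by hand
  doy2 <- c(360, 5, 10)
  th <- doy2 / 365 * 2 * pi
  mu <- atan2(mean(sin(th)), mean(cos(th))) / (2 * pi) * 365
  man <- ((doy2 - mu + 182.5) %% 365) - 182.5
  expect_equal(sowing_deviation(doy2, rep("s", 3)), man)   # auto => circular
  expect_true(all(abs(sowing_deviation(doy2, rep("s", 3))) < 15))
})
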