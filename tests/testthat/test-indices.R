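test_that("enrichment factor matches hand arithmetic and its identity", {
  expect_equal(enrichment_factor(10, 20000, 0.3, 47200),
               (10 / 20000) / (0.3 / 47200))
  expect_equal(round(enrichment_factor(10, 20000, 0.3, 47200), 2), 78.67)
  expect_equal(round(enrichment_factor(40, 20000, 20, 47200), 2), 4.72)
  # sample ratio equal to background ratio
  expect_equal(enrichment_factor(6, 300, 2, 100), 1)
  expect_error(enrichment_factor(-1, 2, 3, 4), "positive")
})

test_that("geo-accumulation index matches its printed endpoints", {
  expect_equal(geoaccumulation_index(1.5 * 0.3, 0.3), 0)
  expect_equal(round(geoaccumulation_index(12, 0.3), 2), 4.74)
  expect_equal(round(geoaccumulation_index(5.1, 13), 2), -1.93)
  expect_error(geoaccumulation_index(0, 1), "positive")
})

test_that("contamination factor and PLI match their definitions", {
  expect_equal(round(contamination_factor(5.27, 0.3), 2), 17.57)
  expect_equal(contamination_factor(49, 20), 2.45)
  expect_equal(contamination_factor(7, 7), 1)
  expect_equal(pollution_load_index(c(1, 1, 1)), 1)
  expect_equal(pollution_load_index(c(2, 8)), 4)
  expect_equal(pollution_load_index(c(1, 1, 1, 16)), 2)
  expect_error(pollution_load_index(numeric(0)), "non-empty")
  expect_error(pollution_load_index(c(1, -2)), "positive")
})

test_that("cross-index identities hold on random inputs", {
  set.seed(10)
  c_n <- exp(rnorm(200, 2, 1.5))
  b_n <- exp(rnorm(200, 1, 0.5))
  # Igeo = log2(CF / 1.5)
  expect_equal(geoaccumulation_index(c_n, b_n),
               log2(contamination_factor(c_n, b_n) / 1.5),
               tolerance = 1e-12)
  # CF linear in concentration
  k <- 3.7
  expect_equal(contamination_factor(k * c_n, b_n),
               k * contamination_factor(c_n, b_n), tolerance = 1e-12)
  # PLI scale covariance
  cfs <- contamination_factor(c_n[1:8], b_n[1:8])
  expect_equal(pollution_load_index(k * cfs),
               k * pollution_load_index(cfs), tolerance = 1e-12)
})

test_that("classification assigns left-closed intervals, bounds upward", {
  igeo <- class_scheme("igeo")
  expect_equal(classify_index(-0.5, igeo), "unpolluted")
  expect_equal(classify_index(0, igeo), "unpolluted to moderately polluted")
  expect_equal(classify_index(4.74, igeo), "strongly to extremely polluted")
  hq <- class_scheme("hq")
  expect_equal(classify_index(1, hq), "adverse non-carcinogenic risk")
  expect_equal(classify_index(0.999, hq),
               "no significant non-carcinogenic risk")
  pli <- class_scheme("pli")
  expect_equal(classify_index(1.95, pli), "moderately polluted")
  tcr <- class_scheme("tcr")
  expect_equal(classify_index(2e-4, tcr), "unacceptable carcinogenic risk")
  expect_equal(classify_index(5e-7, tcr), "insignificant risk")
})

test_that("index report reproduces published-style summaries", {
  tab <- moment_match(reference_stats(), n = 20, seed = 4)
  rep <- index_report(tab, background_values("ASV"))
  cf <- subset(rep$summary, index == "cf")
  stats <- reference_stats()
  asv <- background_values("ASV")$values
  for (m in stats$metal) {
    srow <- stats[stats$metal == m, ]
    crow <- cf[cf$metal == m, ]
    # linearity: mean CF equals CF of the mean concentration
    expect_equal(crow$mean, srow$mean / asv[[m]], tolerance = 1e-9,
                 info = m)
    expect_equal(crow$min, srow$min / asv[[m]], tolerance = 1e-9)
    expect_equal(crow$max, srow$max / asv[[m]], tolerance = 1e-9)
  }
  # per-sample PLI is the geometric mean of that sample's CFs
  ps <- rep$per_sample
  for (sid in c("S01", "S13")) {
    cfs <- ps$cf[ps$sample_id == sid]
    expect_equal(rep$pli$pli[rep$pli$sample_id == sid],
                 pollution_load_index(cfs), tolerance = 1e-12)
  }
  # EF of the reference element against itself is 1
  expect_equal(ps$ef[ps$metal == "Fe"], rep(1, 20))
})

test_that("single sample at 1.5 x background gives zero Igeo, PLI 1.5", {
  asv <- background_values("ASV")$values
  df <- as.data.frame(as.list(1.5 * asv))
  df$sample_id <- "only"
  rep <- index_report(sample_table(df), background_values("ASV"))
  expect_equal(rep$per_sample$igeo, rep(0, 8), tolerance = 1e-12)
  expect_equal(rep$pli$pli, 1.5, tolerance = 1e-12)
})

test_that("index report requires background coverage and Fe", {
  tab <- tiny_table()
  bg <- background_values("ASV")
  bg$values <- bg$values[c("As", "Pb")]
  expect_error(index_report(tab, bg), "lacks metal")
  df <- as.data.frame(tab)
  df$Fe <- NULL
  no_fe <- sample_table(df, metals = setdiff(soil_metals(), "Fe"))
  expect_error(index_report(no_fe), "Fe")
})
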