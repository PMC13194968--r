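child <- default_exposure_profiles()$child
adult <- default_exposure_profiles()$adult

test_that("pathway doses match hand arithmetic with the child defaults", {
  expect_equal(adi_ingestion(147.12, child),
               147.12 * 200 * 350 * 6 / (15 * 2190) * 1e-6)
  expect_equal(signif(adi_ingestion(147.12, child), 4), 1.881e-3)
  expect_equal(signif(adi_inhalation(147.12, child), 3), 5.26e-8)
  expect_equal(signif(adi_dermal(147.12, child, abs = 0.001), 3), 5.27e-6)
})

test_that("doses are linear in concentration and obey limits", {
  expect_equal(adi_ingestion(0, child), 0)
  expect_equal(adi_dermal(10, child, abs = 0), 0)
  expect_equal(adi_ingestion(20, child), 2 * adi_ingestion(10, child))
  # inhalation vanishes as PEF grows
  p_hi_pef <- child; p_hi_pef$pef <- 1e18
  expect_lt(adi_inhalation(100, p_hi_pef), 1e-15)
  # ingestion scales as 1/bw
  p2 <- exposure_profile("x", 200, 7.6, 350, 6, bw = 30, sa = 2800,
                         af = 0.2)
  expect_equal(adi_ingestion(50, p2), adi_ingestion(50, child) / 2)
  # dermal monotone in sa
  p3 <- exposure_profile("x", 200, 7.6, 350, 6, bw = 15, sa = 5600,
                         af = 0.2)
  expect_gt(adi_dermal(50, p3, 0.01), adi_dermal(50, child, 0.01))
  expect_error(adi_ingestion(-1, child), "non-negative")
})

test_that("exposure profile validation enforces its invariants", {
  expect_error(exposure_profile("x", -1, 7.6, 350, 6, 15, 2800, 0.2),
               "positive")
  expect_error(exposure_profile("x", 200, 7.6, 400, 6, 15, 2800, 0.2),
               "365")
  expect_error(exposure_profile("x", 200, 7.6, 350, 80, 15, 2800, 0.2,
                                at_ca = 70 * 365), "at_ca")
  expect_equal(child$at_nc, 6 * 365)
  expect_gte(child$at_ca, child$at_nc)
})

test_that("hazard quotients sum to the hazard index and classify", {
  tox <- default_toxicity()
  hq <- hazard_quotients(c(ing = 0, inh = 0, derm = 0), tox, metal = "As")
  expect_equal(hq$hi, 0)
  r <- tox[tox$metal == "As", ]
  adi <- c(ing = 0.5 * r$rfd_ing, inh = 0.3 * r$rfd_inh,
           derm = 0.2 * r$rfd_derm)
  hq <- hazard_quotients(adi, tox, metal = "As")
  expect_equal(hq$hi, 1, tolerance = 1e-12)
  expect_equal(hq$hi_class, "adverse non-carcinogenic risk")
  expect_equal(hazard_quotients(adi * 0.9, tox, metal = "As")$hi_class,
               "no significant non-carcinogenic risk")
  # missing RfD identifies metal and pathway
  tox2 <- tox; tox2$rfd_inh[tox2$metal == "As"] <- NA
  expect_error(hazard_quotients(adi, tox2, metal = "As"), "As.*inh")
})

test_that("cancer risks sum to TCR and flag CSF-free pathways", {
  tox <- default_toxicity()
  adi <- c(ing = 1e-4, inh = 1e-8, derm = 1e-6)
  cr <- cancer_risks(adi, tox, metal = "As")
  expect_equal(cr$tcr, cr$cr_ing + cr$cr_inh + cr$cr_derm)
  expect_true(all(c(cr$cr_ing, cr$cr_inh, cr$cr_derm) >= 0))
  # Pb has no dermal slope factor: flagged, contributes zero
  cr_pb <- cancer_risks(adi, tox, metal = "Pb")
  expect_equal(cr_pb$cr_derm, 0)
  expect_true("derm" %in% cr_pb$pathways_without_csf)
  # metals with no CSF at all refuse
  expect_error(cancer_risks(adi, tox, metal = "Zn"), "non-carcinogenic")
  # classes at the published thresholds
  expect_equal(cancer_risks(c(ing = 2e-4, inh = 0, derm = 0),
                            data.frame(metal = "X", csf_ing = 1,
                                       csf_inh = NA, csf_derm = NA))$tcr_class,
               "unacceptable carcinogenic risk")
  expect_equal(cancer_risks(c(ing = 5e-7, inh = 0, derm = 0),
                            data.frame(metal = "X", csf_ing = 1,
                                       csf_inh = NA, csf_derm = NA))$tcr_class,
               "insignificant risk")
})

test_that("deterministic report matches direct formula evaluation", {
  df <- data.frame(sample_id = "S1", As = 20, Pb = 100, Zn = 300,
                   Fe = 30000, Cd = 4, Cu = 50, Cr = 200, Ni = 70)
  tab <- sample_table(df)
  rr <- suppressMessages(risk_report(tab))
  tox <- default_toxicity()
  row <- rr[rr$metal == "Cr" & rr$receptor == "child", ]
  r <- tox[tox$metal == "Cr", ]
  adi <- c(ing = adi_ingestion(200, child),
           inh = adi_inhalation(200, child),
           derm = adi_dermal(200, child, r$abs))
  hq <- hazard_quotients(adi, r)
  expect_equal(row$hi, hq$hi, tolerance = 1e-12)
  adi_ca <- c(ing = adi_ingestion(200, child, at = child$at_ca),
              inh = adi_inhalation(200, child, at = child$at_ca),
              derm = adi_dermal(200, child, r$abs, at = child$at_ca))
  cr <- cancer_risks(adi_ca, r)
  expect_equal(row$tcr, cr$tcr, tolerance = 1e-12)
})

test_that("risk orderings: child above adult, ingestion above inhalation", {
  tab <- moment_match(reference_stats(), n = 20, seed = 5)
  rr <- suppressMessages(risk_report(tab))
  agg <- aggregate(cbind(hi, hq_ing, hq_inh) ~ metal + receptor, data = rr,
                   FUN = mean)
  for (m in soil_metals()) {
    hi_c <- agg$hi[agg$metal == m & agg$receptor == "child"]
    hi_a <- agg$hi[agg$metal == m & agg$receptor == "adult"]
    expect_gt(hi_c, hi_a)
  }
  expect_true(all(rr$hq_ing > rr$hq_inh))
  # non-carcinogenic-only metals carry NA cancer columns
  expect_true(all(is.na(rr$tcr[rr$metal %in% c("Zn", "Cu", "Fe")])))
  expect_false(anyNA(rr$tcr[rr$metal == "Cd"]))
})

test_that("per-pathway child/adult dose ratio is constant across metals", {
  tab <- moment_match(reference_stats(), n = 20, seed = 5)
  rr <- suppressMessages(risk_report(tab))
  ratios <- sapply(soil_metals(), function(m) {
    c_row <- rr[rr$metal == m & rr$receptor == "child", ]
    a_row <- rr[rr$metal == m & rr$receptor == "adult", ]
    mean(c_row$hq_ing / a_row$hq_ing)
  })
  expect_equal(max(ratios) - min(ratios), 0, tolerance = 1e-9)
})

test_that("carcinogenic averaging time reduces the dose", {
  # same concentration: lifetime-averaged ADI is strictly smaller
  expect_lt(adi_ingestion(100, child, at = child$at_ca),
            adi_ingestion(100, child, at = child$at_nc))
})
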