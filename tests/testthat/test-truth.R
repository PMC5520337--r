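cell2 <- c("MCF-7", "PC-3")

test_that("prop_null = 1 plants no effect anywhere", {
  cat_ <- generate_ase_catalog(20, seed = 5)
  truth <- generate_truth(cat_, cell2, prop_null = 1, seed = 6)
  expect_true(all(truth$effects$effect_dpsi == 0))
  re <- realized_effects(truth)
  expect_true(all(re$realized_dpsi == 0))
  expect_true(all(re$psi_kd == re$baseline_psi))
})

test_that("discordant_rate = 0 forces sign agreement between the two siRNAs", {
  cat_ <- generate_ase_catalog(60, seed = 7)
  truth <- generate_truth(cat_, cell2, prop_null = 0.2, discordant_rate = 0,
                          effect_dist = list(mean_abs = 20, sd = 5), seed = 8)
  re <- realized_effects(truth)
  wide <- merge(re[re$sirna == "siRNA1", ], re[re$sirna == "siRNA2", ],
                by = c("ase_id", "cell_line"))
  nz <- wide$realized_dpsi.x != 0 & wide$realized_dpsi.y != 0
  expect_true(any(nz))
  expect_true(all(sign(wide$realized_dpsi.x[nz]) == sign(wide$realized_dpsi.y[nz])))
})

test_that("a true target keeps one direction across its responsive cell lines", {
  cat_ <- generate_ase_catalog(80, seed = 21)
  truth <- generate_truth(cat_, unique(rbm10_kd_table()$cell_line),
                          prop_null = 0.3, seed = 22)
  signs <- tapply(sign(truth$effects$effect_dpsi[truth$effects$effect_dpsi != 0]),
                  truth$effects$ase_id[truth$effects$effect_dpsi != 0],
                  function(s) length(unique(s)))
  expect_true(all(signs == 1))
})

test_that("the realized null fraction stays within binomial bounds", {
  cat_ <- generate_ase_catalog(200, seed = 30)
  truth <- generate_truth(cat_, cell2, prop_null = 0.7, respond_prob = 1,
                          seed = 31)
  per_ase_null <- tapply(truth$effects$effect_dpsi, truth$effects$ase_id,
                         function(v) all(v == 0))
  n_null <- sum(per_ase_null)
  # central 95% binomial interval at n = 200, p = 0.7
  expect_gte(n_null, qbinom(0.025, 200, 0.7))
  expect_lte(n_null, qbinom(0.975, 200, 0.7))
})

test_that("within a cell line the stronger knockdown never shows the smaller shift", {
  for (seed in 1:5) {
    cat_ <- generate_ase_catalog(40, seed = seed)
    truth <- generate_truth(cat_, unique(rbm10_kd_table()$cell_line),
                            prop_null = 0.3, discordant_rate = 0,
                            seed = seed + 100)
    re <- realized_effects(truth)
    kd <- truth$kd
    re$kd <- kd$kd_fraction[match(paste(re$cell_line, re$sirna),
                                  paste(kd$cell_line, kd$sirna))]
    wide <- merge(re[re$sirna == "siRNA1", ], re[re$sirna == "siRNA2", ],
                  by = c("ase_id", "cell_line"))
    # pre-clamp scaling is |effect| * kd / max(kd); post-clamp magnitudes can
    # only shrink for the larger shift, never below the smaller one
    stronger_is_1 <- wide$kd.x >= wide$kd.y
    expect_true(all(abs(wide$realized_dpsi.x[stronger_is_1]) >=
                      abs(wide$realized_dpsi.y[stronger_is_1]) - 1e-9))
    expect_true(all(abs(wide$realized_dpsi.y[!stronger_is_1]) >=
                      abs(wide$realized_dpsi.x[!stronger_is_1]) - 1e-9))
  }
})

test_that("knocked-down psi is clamped to the percent scale", {
  cat_ <- generate_ase_catalog(50, seed = 40)
  truth <- generate_truth(cat_, cell2, prop_null = 0,
                          effect_dist = list(mean_abs = 60, sd = 20),
                          baseline_range = c(5, 95), seed = 41)
  re <- realized_effects(truth)
  expect_true(all(re$psi_kd >= 0 & re$psi_kd <= 100))
})

test_that("malformed knockdown tables are rejected", {
  cat_ <- generate_ase_catalog(5, seed = 1)
  kd <- rbm10_kd_table()
  expect_error(generate_truth(cat_, cell2, kd_table = kd[kd$sirna == "siRNA1", ]),
               "siRNA")
  expect_error(generate_truth(cat_, c("NOT-A-LINE"), kd_table = kd), "NOT-A-LINE")
  bad <- kd; bad$kd_fraction[1] <- 1.5
  expect_error(generate_truth(cat_, cell2, kd_table = bad), "0, 1")
  expect_error(generate_truth(cat_, cell2, kd_table = kd[, 1:2]), "columns")
})

test_that("identical seeds reproduce the truth table", {
  cat_ <- generate_ase_catalog(30, seed = 2)
  a <- generate_truth(cat_, cell2, prop_null = 0.5, discordant_rate = 0.1, seed = 3)
  b <- generate_truth(cat_, cell2, prop_null = 0.5, discordant_rate = 0.1, seed = 3)
  expect_identical(a, b)
})
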