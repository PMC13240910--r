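tab <- defaultResidueTables()

test_that("effective length and frequencies exclude ambiguity codes", {
  expect_equal(effectiveLength("ACDE"), 4)
  expect_equal(effectiveLength("AXA"), 2)
  expect_error(effectiveLength("XX"), "degenerate")
  f <- aaFrequencies("ACD")
  expect_equal(unname(f[c("A", "C", "D")]), rep(1 / 3, 3))
  expect_equal(sum(f), 1)
  f2 <- aaFrequencies("DDEE")
  expect_equal(unname(f2[c("D", "E")]), c(0.5, 0.5))
  f3 <- aaFrequencies("AXAD")
  expect_equal(unname(f3[c("A", "D")]), c(2 / 3, 1 / 3))
})

test_that("group ratios follow the physicochemical group definitions", {
  g <- groupRatios("KRH")
  expect_equal(g[["pos_ratio"]], 1)
  expect_equal(g[["neg_ratio"]], 0)
  g2 <- groupRatios("ACDE")
  expect_equal(g2[["neg_ratio"]], 0.5)
  expect_equal(g2[["sulfur_ratio"]], 0.25)
  g3 <- groupRatios("AGST")  # S,T belong to both tiny and polar
  expect_equal(g3[["tiny_ratio"]], 1)
  expect_equal(g3[["polar_ratio"]], 0.5)
})

test_that("molecular weight sums average residue masses plus one water", {
  expect_equal(molecularWeight("G"), 75.07, tolerance = 1e-4)
  expect_equal(molecularWeight("GG"),
               2 * residueMasses(tab)[["G"]] + tab@waterMass)
  expect_equal(molecularWeight("GXG"), molecularWeight("GG"))
})

test_that("net charge obeys protonation limits and monotonicity", {
  expect_equal(netCharge("K", pH = 0), 2, tolerance = 1e-2)
  expect_equal(netCharge("D", pH = 14), -2, tolerance = 1e-2)
  expect_lt(abs(netCharge("AAAA", pH = 7)), 0.05)
  grid <- seq(0, 14, by = 0.5)
  q <- vapply(grid, function(p) netCharge("MKKLVEEDDECY", pH = p), numeric(1))
  expect_true(all(diff(q) < 0))
})

test_that("isoelectric point is the root of the charge curve", {
  pka <- pkaSet(tab)
  expect_equal(isoelectricPoint("A"),
               (pka[["Nterm"]] + pka[["Cterm"]]) / 2, tolerance = 1e-4)
  set.seed(42)
  for (i in 1:20) {
    seq <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                        sample(3:30, 1), replace = TRUE), collapse = "")
    pI <- isoelectricPoint(seq)
    expect_lt(abs(netCharge(seq, pH = pI)), 1e-4)
    # adding a basic residue never decreases the pI
    expect_gte(isoelectricPoint(paste0(seq, "K")) - pI, -1e-6)
  }
})

test_that("hydropathy, propensity and disorder means behave as lookups", {
  expect_equal(meanHydropathy("I"), 4.5)
  expect_equal(meanHydropathy("IR"), 0)
  expect_equal(meanHydropathy("AXA"), hydropathyScale(tab)[["A"]])
  expect_equal(propensityMean("EEEE", "helix"),
               propensityScale(tab, "helix")[["E"]])
  expect_equal(propensityMean("AE", "sheet"),
               mean(propensityScale(tab, "sheet")[c("A", "E")]))
  expect_equal(propensityMean("KLMKLM", "turn"),
               propensityMean("MMKKLL", "turn"))
  # strict inequality at the threshold: residues at exactly tau don't count
  pathological <- tab
  pathological@disorderThreshold <- disorderScale(tab)[["A"]]
  expect_equal(disorderRatio("AAAA", pathological), 0)
  expect_equal(disorderRatio("PPPP", tab), 1)   # P well above tau = 0
  expect_equal(disorderRatio("PPWW", tab), 0.5)
})

test_that("aggregation ratio is the longest hydrophobic run over L", {
  expect_equal(aggregationRatio("DDDD"), 0)
  expect_equal(aggregationRatio("AAADAA"), 0.5)
  expect_equal(aggregationRatio("AVILDD"), 4 / 6)
  # an ambiguous residue interrupts a run and leaves the denominator
  expect_equal(aggregationRatio("AAXAA"), 2 / 4)
})

test_that("extractFeatures satisfies the feature-vector invariants", {
  ps <- ProteinSet(c(u = "ACDEFGHIKLMNPQRSTVWY"), labels = "soluble")
  v <- featureValues(extractFeatures(ps))[, 1]
  expect_equal(unname(v[paste0("freq_", strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                 "")[[1]])]),
               rep(0.05, 20))
  expect_equal(v[["length"]], 20)

  set.seed(7)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- vapply(1:25, function(i)
    paste(sample(aas, sample(5:80, 1), replace = TRUE), collapse = ""), "")
  names(seqs) <- sprintf("r%02d", 1:25)
  sf <- extractFeatures(ProteinSet(seqs, labels = "soluble"))
  vals <- featureValues(sf)
  freqs <- vals[paste0("freq_", aas), ]
  expect_equal(unname(colSums(freqs)), rep(1, 25), tolerance = 1e-12)
  expect_equal(vals["pos_ratio", ],
               vals["freq_K", ] + vals["freq_R", ] + vals["freq_H", ],
               tolerance = 1e-12)
  expect_equal(vals["neg_ratio", ], vals["freq_D", ] + vals["freq_E", ],
               tolerance = 1e-12)
  expect_true(all(vals["aggregation_ratio", ] <=
                  vals["hydrophobic_ratio", ] + 1e-12))
  expect_true(all(vals["isoelectric_point", ] > 0 &
                  vals["isoelectric_point", ] < 14))

  # vectorized extraction agrees with the per-sequence functions
  pick <- seqs[1:5]
  expect_equal(unname(vals["molecular_weight", 1:5]),
               vapply(pick, molecularWeight, numeric(1), USE.NAMES = FALSE))
  expect_equal(unname(vals["isoelectric_point", 1:5]),
               vapply(pick, isoelectricPoint, numeric(1), USE.NAMES = FALSE),
               tolerance = 1e-6)
  expect_equal(unname(vals["net_charge_pH7", 1:5]),
               vapply(pick, netCharge, numeric(1), USE.NAMES = FALSE))
  expect_equal(unname(vals["aggregation_ratio", 1:5]),
               vapply(pick, aggregationRatio, numeric(1), USE.NAMES = FALSE))
  expect_equal(unname(vals["disorder_ratio", 1:5]),
               vapply(pick, disorderRatio, numeric(1), USE.NAMES = FALSE))

  # lowercase input and duplicated records change nothing
  sfLower <- extractFeatures(ProteinSet(tolower(seqs), ids = names(seqs),
                                        labels = "soluble"))
  expect_equal(featureValues(sfLower), vals)
  dup <- ProteinSet(c(seqs[1], d2 = unname(seqs[1])), labels = "soluble")
  dv <- featureValues(extractFeatures(dup))
  expect_equal(dv[, 1], dv[, 2], ignore_attr = TRUE)

  # permutation invariance for everything except the aggregation run
  shuf <- vapply(seqs[1:5], function(s)
    paste(sample(strsplit(s, "")[[1]]), collapse = ""), "")
  sv <- featureValues(extractFeatures(ProteinSet(shuf, ids = names(pick),
                                                 labels = "soluble")))
  others <- setdiff(solubilityFeatureNames(), "aggregation_ratio")
  expect_equal(sv[others, ], vals[others, 1:5], tolerance = 1e-9)

  # degenerate record propagates its id
  expect_error(extractFeatures(ProteinSet(c(ghost = "XXX"),
                                          labels = "soluble")), "ghost")
})
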