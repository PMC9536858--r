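panelA <- standard_panel("A")

test_that("entropy matches direct evaluation of the formula", {
  # uniform profile: H = 1.43 * log10(5) ~ 0.9995
  h_unif <- response_entropy(rep(0.2, 5))
  expect_equal(as.numeric(h_unif), 0.9995, tolerance = 1e-4)
  # single-stimulus profile: H ~ 0 up to the epsilon substitution
  h_one <- response_entropy(c(1, 0, 0, 0, 0))
  expect_lt(as.numeric(h_one), 1e-4)
  # oracle sweep over random positive 5-vectors
  set.seed(101)
  for (i in 1:1000) {
    r <- stats::runif(5, 0.01, 50)
    p <- r / sum(r)
    expect_equal(as.numeric(response_entropy(r)),
                 -1.43 * sum(p * log10(p)), tolerance = 1e-10)
  }
})

test_that("tuning metrics combine count, N:S and entropy with exclusions", {
  prof <- make_profile("u", c(40, 30, 10, 2, 0),
                       significant = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  tm <- tuning_metrics(prof, "control", panelA)
  expect_equal(tm$n_significant, 3)
  # MSGai (2nd entry, 30) excluded: included (40, 10, 2, 0) -> 10/40
  expect_equal(tm$ns_ratio, 0.25)
  expect_true(tm$defined)
  # entropy uses all five responses
  expect_equal(tm$entropy_H,
               as.numeric(response_entropy(c(40, 30, 10, 2, 0))))

  # entirely unresponsive cell: undefined, flagged
  dead <- make_profile("u", c(0, -2, 0, -1, 0), significant = rep(FALSE, 5))
  tm0 <- tuning_metrics(dead, "control", panelA)
  expect_false(tm0$defined)
  expect_true(is.na(tm0$entropy_H))
})

test_that("H and N:S are invariant to scaling all responses", {
  r <- c(35, 12, 8, 3, 1)
  prof1 <- make_profile("u", r, significant = rep(TRUE, 5))
  prof2 <- make_profile("u", 7.3 * r, significant = rep(TRUE, 5))
  t1 <- tuning_metrics(prof1, "control", panelA)
  t2 <- tuning_metrics(prof2, "control", panelA)
  expect_equal(t1$entropy_H, t2$entropy_H, tolerance = 1e-12)
  expect_equal(t1$ns_ratio, t2$ns_ratio, tolerance = 1e-12)
})

test_that("average-linkage heights match a brute-force agglomeration", {
  set.seed(33)
  for (rep in 1:8) {
    n <- sample(4:8, 1)
    mat <- matrix(stats::rnorm(n * 5, 10, 6), n, 5)
    rownames(mat) <- paste0("u", seq_len(n))
    res <- cluster_profiles(mat)
    D <- 1 - stats::cor(t(mat))
    expect_equal(sort(res$hclust$height), sort(avg_linkage_oracle(D)),
                 tolerance = 1e-10)
    expect_true(all(diff(res$hclust$height) >= -1e-12)) # monotone merges
    expect_true(all(res$scree >= -1e-12 & res$scree <= 2 + 1e-12))
  }
})

test_that("identical profiles merge at height zero; scaled copies too", {
  a <- c(30, 2, 1, 0, 1)
  b <- c(0, 1, 2, 25, 3)
  mat <- rbind(u1 = a, u2 = 2 * a, u3 = b, u4 = b * 0.5)
  res <- cluster_profiles(mat)
  expect_equal(sort(res$hclust$height)[1:2], c(0, 0), tolerance = 1e-12)
  final <- max(res$hclust$height)
  expect_equal(final, 1 - pearson_oracle(a, b), tolerance = 1e-12)
  # flat cut at the largest gap finds the two families
  labels <- cluster_cut(res)
  expect_equal(length(unique(labels)), 2)
  expect_equal(labels[["u1"]], labels[["u2"]])
  expect_equal(labels[["u3"]], labels[["u4"]])
  # newick export carries all four tips
  nwk <- cluster_newick(res)
  expect_true(all(vapply(rownames(mat), grepl, logical(1), x = nwk,
                         fixed = TRUE)))
})

test_that("constant profiles are excluded from clustering with a warning", {
  mat <- rbind(u1 = c(1, 2, 3, 4, 5), u2 = c(5, 4, 3, 2, 1),
               u3 = c(2, 3, 1, 5, 4), u4 = c(3, 3, 3, 3, 3))
  expect_warning(res <- cluster_profiles(mat), "u4")
  expect_equal(res$excluded, "u4")
  expect_equal(nrow(res$matrix), 3)
})

test_that("profile stability is Pearson r across conditions", {
  ctrl <- c(40, 25, 10, 4, 0)
  expect_equal(profile_stability(make_profile("u", ctrl, 0.5 * ctrl))$r, 1)
  expect_equal(profile_stability(make_profile("u", ctrl, -ctrl))$r, -1)
  flat <- profile_stability(make_profile("u", ctrl, rep(2, 5)))
  expect_true(is.na(flat$r))
  expect_false(flat$defined)
})

test_that("noisy divisive suppression keeps profiles highly correlated", {
  specs <- population_specs(12, 0, 0, panelA, seed = 5, gain = 0.5)
  sim <- simulate_session(specs, panelA, trial_plan(panelA), seed = 5,
                          tag_frequencies = numeric(0))
  profs <- lapply(sim$spikes, function(st) {
    response_profile(st, sim$trials, panelA)
  })
  st <- profile_stability(profs)
  expect_gte(mean(st$r), 0.85)
})

test_that("tuning sharpens on average under divisive suppression", {
  specs <- population_specs(10, 0, 0, panelA, seed = 14, gain = 0.4)
  sim <- simulate_session(specs, panelA, trial_plan(panelA), seed = 14,
                          tag_frequencies = numeric(0))
  n_sig <- sapply(sim$spikes, function(st) {
    p <- flag_responses(response_profile(st, sim$trials, panelA))
    c(ctrl = sum(p$significant[p$light_condition == "control"]),
      light = sum(p$significant[p$light_condition == "light_br"]))
  })
  expect_lte(mean(n_sig["light", ]), mean(n_sig["ctrl", ]))
})

test_that("ensemble MDS reproduces correlations, stability and distances", {
  set.seed(77)
  ctrl <- matrix(stats::rnorm(5 * 12, 15, 8), nrow = 12,
                 dimnames = list(paste0("u", 1:12), five_stimuli))
  profs <- lapply(rownames(ctrl), function(u) {
    make_profile(u, ctrl[u, ], 0.5 * ctrl[u, ])
  })
  ens <- ensemble_mds(profs)
  # pure divisive suppression: cross-condition r = 1 for every stimulus
  expect_equal(unname(ens$cross_condition), rep(1, 5), tolerance = 1e-12)
  for (m in ens$correlations) {
    expect_equal(m, t(m))
    expect_equal(unname(diag(m)), rep(1, 5))
  }
  # distances between identical-condition points are 0 -> identical coords
  d <- as.matrix(stats::dist(ens$mds))
  for (s in five_stimuli) {
    expect_lt(d[paste0(s, ".control"), paste0(s, ".light_br")], 1e-8)
  }
})

test_that("classical MDS coordinates agree with the eigendecomposition oracle", {
  set.seed(9)
  ctrl <- matrix(stats::rnorm(5 * 10, 20, 10), nrow = 10,
                 dimnames = list(paste0("u", 1:10), five_stimuli))
  light <- ctrl * 0.4 + matrix(stats::rnorm(50, 0, 2), 10)
  profs <- lapply(rownames(ctrl), function(u) {
    make_profile(u, ctrl[u, ], light[u, ])
  })
  ens <- ensemble_mds(profs)
  oracle <- cmds_oracle(ens$distances, k = 2)
  # same configuration up to per-axis sign
  for (j in 1:2) {
    expect_equal(abs(ens$mds[, j]), abs(oracle[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # sign convention: first stimulus control point nonnegative on each axis
  expect_true(all(ens$mds[1, ] >= 0))
  expect_error(ensemble_mds(profs[1]), ">= 2 neurons")
})

test_that("perfectly correlated stimuli land on the same MDS point", {
  base <- stats::rnorm(6, 10, 4)
  ctrl <- cbind(SUC = base, MSGai = 2 * base + 1, NaCl = stats::rnorm(6),
                CIT = stats::rnorm(6), BIT = stats::rnorm(6))
  rownames(ctrl) <- paste0("u", 1:6)
  profs <- lapply(rownames(ctrl), function(u) {
    make_profile(u, ctrl[u, ], 0.5 * ctrl[u, ])
  })
  ens <- ensemble_mds(profs)
  d <- as.matrix(stats::dist(ens$mds))
  expect_lt(d["SUC.control", "MSGai.control"], 1e-6)
})
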