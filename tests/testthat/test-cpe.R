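test_that("cpe matches closed-form pairs and tie conventions", {
  expect_equal(cpe(c(0, 1)), 1 / (1 + exp(-1)))
  expect_equal(cpe(c(0, 1)), 0.7311, tolerance = 1e-4)
  expect_equal(cpe(c(2, 2, 2)), 0.5)       # fully tied input
  expect_gt(cpe(c(0, 100)), 0.999)         # large-separation limit
  expect_error(cpe(1), "at least two")
  # half-credit inclusion of ties lowers the average toward 0.5
  x <- c(0, 0, 1)
  expect_equal(cpe(x, ties = "exclude"), 1 / (1 + exp(-1)))
  expect_equal(cpe(x, ties = "half"), (0.5 + 2 / (1 + exp(-1))) / 3)
})

test_that("cpe equals the brute-force oracle and stays at or above 0.5", {
  set.seed(201)
  for (r in 1:5) {
    n <- sample(30:400, 1)
    eta <- round(rnorm(n), 1)  # ties present
    expect_equal(cpe(eta), brute_cpe(eta))
    expect_gte(cpe(eta), 0.5)
  }
})

test_that("the pairwise cpe kernel is location-invariant", {
  set.seed(17)
  eta <- rnorm(100)
  expect_equal(cpe(eta + 3.7), cpe(eta))
  # positive scaling changes the kernel value (it is not scale-free) but
  # the grouped refit objective in find_cutpoints absorbs scale; here we
  # only pin the location invariance of the kernel itself
  expect_gt(cpe(2 * eta), cpe(eta))
})

test_that("grouped cpe computation agrees with the expanded vector", {
  etas <- c(0, 0.4, 1.1, 2.0)
  counts <- c(5, 9, 3, 7)
  expanded <- rep(etas, counts)
  grouped <- mrdpi:::cpe_pairs_grouped(etas, counts, FALSE)
  expect_equal(grouped[["total"]] / grouped[["pairs"]], cpe(expanded))
})

test_that("risk-group assignment uses left-open right-closed intervals", {
  cuts <- cog_cutpoints()
  expect_equal(as.character(assign_risk_group(-2.1002, cuts)), "Low")
  expect_equal(as.character(assign_risk_group(0, cuts)), "Intermediate")
  expect_equal(as.character(assign_risk_group(-1.377, cuts)), "Low")
  expect_equal(as.character(assign_risk_group(-0.589, cuts)), "Standard")
  expect_equal(as.character(assign_risk_group(0.094, cuts)), "High")
  # monotone: sorted scores yield non-decreasing risk labels
  s <- sort(rnorm(200, 0, 2))
  g <- assign_risk_group(s, cuts)
  expect_true(all(diff(as.integer(g)) >= 0))
})

test_that("find_cutpoints recovers gaps between score clusters", {
  set.seed(301)
  n_per <- 1000
  centers <- c(-4, -1, 2, 5)
  scores <- rep(centers, each = n_per) + runif(4 * n_per, -0.45, 0.45)
  lp <- rep(c(-1.8, -0.6, 0.6, 1.8), each = n_per)
  t_ev <- rexp(4 * n_per, 0.08 * exp(lp))
  t_c <- runif(4 * n_per, 5, 30)
  out <- data.frame(time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c))
  res <- find_cutpoints(scores, out, k_groups = 4, grid_quantile_step = 0.05)
  cuts <- res$cutpoints$cutpoints
  gaps <- cbind(centers[-4] + 0.45, centers[-1] - 0.45)
  for (i in 1:3) {
    expect_gt(cuts[i], gaps[i, 1])
    expect_lt(cuts[i], gaps[i, 2])
  }
  expect_gt(res$cpe, 0.5)
  # two-cluster reduced case
  sel <- seq_len(2 * n_per)
  res2 <- find_cutpoints(scores[sel], out[sel, ], k_groups = 2,
                         grid_quantile_step = 0.05)
  expect_gt(res2$cutpoints$cutpoints, -3.55)
  expect_lt(res2$cutpoints$cutpoints, -1.45)
})

test_that("find_cutpoints rejects infeasible group constraints", {
  out <- data.frame(time = rexp(100), event = rbinom(100, 1, 0.8))
  expect_error(find_cutpoints(rnorm(100), out, k_groups = 4,
                              min_group_frac = 0.6),
               "infeasible")
})

test_that("clinical rules engine: first match, default, missing-field signal", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "default": "HR",
    "rules": [
      {"label": "VHR", "when": [{"field": "urg", "op": "eq", "value": true}]}
    ]
  }', path)
  rules <- read_clinical_rules(path)
  coh <- toy_cohort()
  labels <- classify_cog_clinical(coh, rules)
  expect_equal(labels, c("HR", "VHR", "HR"))
  # missing field referenced by a rule
  coh2 <- coh
  coh2$urg[1] <- NA
  expect_error(classify_cog_clinical(coh2, rules), "missing field 'urg'")
  expect_equal(classify_cog_clinical(coh2, rules, unclassified = "na")[1],
               NA_character_)
  # no default and no match
  writeLines('{"rules": [
      {"label": "VHR", "when": [{"field": "urg", "op": "eq", "value": true}]}
  ]}', path)
  rules2 <- read_clinical_rules(path)
  expect_error(classify_cog_clinical(coh[1, ], rules2), "no rule matches")
})

test_that("the shipped approximate clinical rules classify a synthetic cohort", {
  coh <- simulate_cohort(sim_config(n = 1000, seed = 83))
  labels <- classify_cog_clinical(coh, unclassified = "na")
  tab <- table(labels)
  expect_true(all(names(tab) %in%
                    c("SR-Fav", "SR-Avg", "SR-High", "HR-Fav", "HR", "VHR")))
  expect_gt(mean(!is.na(labels)), 0.5)
})

test_that("cross-tabulation counts, totals, suppression and KM consistency", {
  set.seed(401)
  n <- 120
  a <- rep(c("g1", "g2"), each = 60)
  b <- rep(c("h1", "h2"), times = 60)
  out <- data.frame(time = rexp(n, 0.1), event = rbinom(n, 1, 0.7))
  xt <- crosstab_riskgroups(a, b, out, horizon = 2, min_n = 25)
  expect_equal(sum(xt$counts), n)
  expect_equal(unname(xt$row_totals), c(60, 60))
  expect_equal(unname(xt$col_totals), c(60, 60))
  # each cell has 30 >= 25: all estimated, matching a direct KM
  sel <- a == "g1" & b == "h1"
  km <- km_estimate(out[sel, ])
  expect_equal(xt$estimate["g1", "h1"], survival_at(km, 2))
  # raising the threshold suppresses every cell
  xt2 <- crosstab_riskgroups(a, b, out, horizon = 2, min_n = 31)
  expect_true(all(is.na(xt2$estimate)))
  expect_equal(xt2$counts, xt$counts)
  expect_error(crosstab_riskgroups(a[-1], b, out), "equal length")
})
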