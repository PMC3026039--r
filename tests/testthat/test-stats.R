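# Counts and sizes below come from the published census overview tables
# shipped in inst/extdata/published_tables.

test_that("regional goodness-of-fit chi-square reproduces the census values", {
  # X overrepresentation: 138 of 806 insertions on 24.40 of 230.47 Mb
  g1 <- chisq_gof_region(138, 668, 24.40, 206.07)
  expect_lt(abs(g1$statistic - 36.39), 0.37)   # printed-precision inputs
  expect_lt(g1$p.value, 0.01)

  # short-arm excess: 2L+3L (325 / 91.32 Mb) vs 2R+3R (343 / 114.75 Mb)
  g2 <- chisq_gof_region(325, 343, 91.32, 114.75)
  expect_lt(abs(g2$statistic - 5.08), 0.05)

  # observed equal to expected -> exactly zero
  g0 <- chisq_gof_region(50, 50, 10, 10)
  expect_equal(g0$statistic, 0)
  expect_error(chisq_gof_region(0, 0, 1, 1), "expected")
})

test_that("goodness-of-fit is invariant to a common size rescaling", {
  a <- chisq_gof_region(90, 422, 15, 198.03)
  b <- chisq_gof_region(90, 422, 15e6, 198.03e6)
  expect_equal(a$statistic, b$statistic)
})

test_that("2x2 chi-square uses Pearson without continuity correction", {
  # proviral/solo in PH vs NPE: 157/67 against 216/196
  r <- chisq_2x2(157, 67, 216, 196)
  expect_lt(abs(r$statistic - 18.66), 0.05)
  expect_lt(r$p.value, 0.001)

  # proportional rows -> independence, statistic 0
  expect_equal(chisq_2x2(10, 20, 30, 60)$statistic, 0)
  expect_error(chisq_2x2(0, 0, 5, 5), "marginal")
})

test_that("2x2 chi-square equals the textbook formula on random tables", {
  set.seed(13)
  for (i in 1:100) {
    x <- sample(1:200, 4)
    r <- chisq_2x2(x[1], x[2], x[3], x[4])
    expect_equal(r$statistic, chisq_2x2_formula(x[1], x[2], x[3], x[4]),
                 tolerance = 1e-9)
  }
})

test_that("gof chi-square equals the direct formula on random inputs", {
  set.seed(14)
  for (i in 1:100) {
    o <- sample(1:500, 2); s <- runif(2, 1, 100)
    r <- chisq_gof_region(o[1], o[2], s[1], s[2])
    expect_equal(r$statistic, chisq_gof_formula(o[1], o[2], s[1], s[2]),
                 tolerance = 1e-9)
  }
})

test_that("the pooled t test reproduces the printed divergence contrast", {
  # per-arm mean divergences, heterochromatin vs NPE
  het <- c(2.54, 2.43, 2.50, 2.40, 2.46)
  npe <- c(2.09, 1.91, 2.10, 1.62, 1.94)
  r <- ttest_divergence(het, npe, "pooled")
  expect_lt(abs(r$t - 5.905), 0.01)         # printed as 5.91
  expect_lt(abs(r$p.value - 0.0004), 0.0002)

  same <- ttest_divergence(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  sw <- ttest_divergence(npe, het, "pooled")
  expect_equal(sw$t, -r$t)
  expect_equal(sw$p.value, r$p.value)

  const <- ttest_divergence(c(1, 1), c(1, 1))
  expect_equal(const$p.value, 1)
})

test_that("divergence histograms conserve totals across bin widths", {
  set.seed(15)
  copies <- data.frame(
    condition = sample(c("proviral", "solo-LTR"), 300, replace = TRUE),
    divergence = c(runif(280, 0, 0.1), rep(NA, 20)))
  h1 <- divergence_histogram(copies, bin_width = 0.005)
  h2 <- divergence_histogram(copies, bin_width = 0.02)
  expect_equal(sum(h1$counts), 280)
  expect_equal(sum(h2$counts), 280)
  expect_equal(nrow(h1$counts), 20)

  # headline shares recompute directly
  d <- copies[!is.na(copies$divergence) & copies$condition == "proviral", ]
  expect_equal(h1$headline$proviral_recent, mean(d$divergence <= 0.01))

  empty <- divergence_histogram(copies[0, ])
  expect_true(all(empty$counts == 0))
})

test_that("condition-by-age contrast grows with the planted effect", {
  mk <- function(py, sy, po, so) {
    data.frame(condition = c(rep("proviral", py + po), rep("solo-LTR", sy + so)),
               divergence = c(rep(0.001, py), rep(0.08, po),
                              rep(0.001, sy), rep(0.08, so)))
  }
  # equal proviral:solo ratios in both age classes -> no signal
  flat <- condition_ratio_by_age(mk(50, 50, 30, 30))
  expect_lt(flat$statistic, 1e-9)

  # declining proviral share with age -> matches the direct formula
  eff <- condition_ratio_by_age(mk(80, 40, 20, 60))
  expect_equal(eff$statistic, chisq_2x2_formula(80, 40, 20, 60),
               tolerance = 1e-9)
  expect_gt(eff$statistic, flat$statistic)

  expect_error(condition_ratio_by_age(mk(10, 10, 0, 0)), "empty")
})

test_that("published tables ship complete and self-consistent", {
  pt <- published_tables()
  expect_equal(nrow(pt$arms), 7)
  tot <- pt$arms[pt$arms$region == "Total", ]
  expect_equal(tot$n_insertions, 806)
  expect_equal(tot$in_clusters, 246)
  # densities recompute from counts and sizes at printed precision
  expect_equal(round(tot$n_insertions / tot$size_mb, 2), 3.50)
  ph <- pt$heterochromatin[pt$heterochromatin$region == "Total_PH", ]
  expect_equal(round(ph$n_insertions / ph$size_mb, 2), 18.48)
  # condition counts are consistent between the 2x2 inputs
  npe <- pt$euchromatin[pt$euchromatin$region == "Total_NPE", ]
  expect_equal(c(ph$n_proviral, ph$n_solo), c(157, 67))
  expect_equal(c(npe$n_proviral, npe$n_solo), c(216, 196))
})

test_that("summary tables reproduce known per-compartment counts", {
  run <- shared_sim_run()
  sim <- run$sim
  map <- derive_pericentromeric_euchromatin(compartment_map(sim$compartments),
                                            pe_size = 3e5)
  copies <- assign_compartment(run$copies, map)
  copies <- cluster_insertions(copies, 10000)
  tabs <- summarize_tables(copies, map, sim$genes)

  # per-arm insertion totals match the per-arm copy counts
  for (a in unique(map$arm)) {
    row <- tabs$arms[tabs$arms$region == a, ]
    expect_equal(row$n_insertions, sum(copies$arm == a))
  }
  # heterochromatin rows: PH counts equal the midpoint tallies
  ph_row <- tabs$heterochromatin[tabs$heterochromatin$region == "Total_PH", ]
  expect_equal(ph_row$n_insertions, sum(copies$compartment == "PH"))
  # region sizes are preserved even for empty compartments
  expect_true(all(tabs$heterochromatin$size_mb > 0))
  # PE+NPE insertions equal all euchromatic insertions
  e_row <- tabs$euchromatin[tabs$euchromatin$region == "Total_E", ]
  expect_equal(e_row$n_insertions,
               sum(copies$compartment %in% c("PE", "NPE")))
})
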