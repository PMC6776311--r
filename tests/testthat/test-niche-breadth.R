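test_that("Levin's B hits its closed-form limits", {
  expect_equal(levins_B(1), 1)
  expect_equal(levins_B(rep(0.2, 5)), 5)
  # direct-summation oracle on the Pasion 2015 record counts
  cnt <- c(36, 6, 6, 5, 5, 4, 2, rep(1, 9))
  expect_equal(sum(cnt), 73)
  oracle <- sum(cnt)^2 / sum(cnt^2)  # 1 / sum((c/N)^2)
  expect_equal(levins_B(cnt / sum(cnt)), oracle, tolerance = 1e-12)
  expect_equal(oracle, 5329 / 1447, tolerance = 1e-12)
})

test_that("Levin's B rejects invalid proportion vectors", {
  expect_error(levins_B(c(0.5, 0.4)), "sum to 1")
  expect_error(levins_B(c(1.2, -0.2)), "non-negative")
  expect_error(levins_B(c(0, 0)), "sum to 1")
})

test_that("standardized index reproduces the published group values", {
  sp2009 <- c(3, 9, 22, 3, 5, 4, 1, 10, 10, 1, 9, 1, 23, 1, 17, 17, 3)
  pa2015 <- c(36, 6, 6, 5, 5, 4, 2, rep(1, 9))
  expect_equal(round(standardized_levins(sp2009)$B_a, 2), 0.53)
  expect_equal(round(standardized_levins(pa2015)$B_a, 2), 0.18)
  # specialist limit
  single <- standardized_levins(c(taxonA = 17))
  expect_equal(single$B_a, 0)
  expect_equal(single$n, 1L)
  expect_equal(single$classification, "specialist")
})

test_that("B is invariant under relabeling and never grows when merging", {
  set.seed(101)
  for (i in 1:25) {
    cnt <- rpois(sample(3:12, 1), lambda = 5) + 1
    p <- cnt / sum(cnt)
    expect_equal(levins_B(sample(p)), levins_B(p))
    # merge two random categories: concentration rises, B cannot increase
    if (length(p) >= 3) {
      ij <- sample(length(p), 2)
      merged <- c(p[-ij], sum(p[ij]))
      expect_lte(levins_B(merged), levins_B(p) + 1e-12)
    }
  }
})

test_that("niche classification uses the conventional thresholds", {
  expect_equal(classify_niche(c(0.7, 0.5, 0.2)),
               c("generalist", "intermediate", "specialist"))
})

test_that("bootstrap degenerates correctly and is seed-reproducible", {
  identical_scats <- rep(list(c("a", "b")), 10)
  ci <- bootstrap_ci(identical_scats, ba_point <- function(x) {
    standardized_levins(table(unlist(x)))$B_a
  }, n_boot = 50, seed = 1)
  expect_equal(ci$low, ci$high)
  expect_equal(ci$low, standardized_levins(table(unlist(identical_scats)))$B_a)

  scats <- list("a", "a", "b", c("a", "c"), "c")
  one <- bootstrap_ci(scats, ba_point, n_boot = 1, seed = 3)
  expect_equal(one$low, one$high)

  a <- bootstrap_ci(scats, ba_point, n_boot = 100, seed = 7)
  b <- bootstrap_ci(scats, ba_point, n_boot = 100, seed = 7)
  expect_identical(a$replicates, b$replicates)
  expect_lte(a$low, a$high)
})

test_that("undefined replicates are excluded, or fatal past 50%", {
  # statistic undefined whenever the replicate holds a single category
  frail <- function(x) {
    tab <- table(unlist(x))
    if (length(tab) < 2) NA_real_ else standardized_levins(tab)$B_a
  }
  scats <- list("a", "a", "a", "a", "b")
  expect_warning(ci <- bootstrap_ci(scats, frail, n_boot = 40, seed = 2),
                 "undefined")
  expect_true(ci$n_used < 40)

  all_na <- function(x) NA_real_
  expect_error(
    suppressWarnings(bootstrap_ci(scats, all_na, n_boot = 20, seed = 2)),
    "more than half")
})

test_that("bootstrap CI covers the generating B_a at nominal rate", {
  # one-item scats from a fixed multinomial diet: analytic B_a is exact
  props <- c(a = 0.4, b = 0.3, c = 0.2, d = 0.1)
  truth <- (1 / sum(props^2) - 1) / (length(props) - 1)
  sims <- 150
  covered <- logical(sims)
  set.seed(2024)
  seeds <- sample.int(1e6, 2 * sims)
  for (i in seq_len(sims)) {
    sc <- generate_scats(one_item_scenario(props, 200), seed = seeds[i])
    items <- group_item_lists(sc)[[1]]$scats
    ci <- bootstrap_ci(items, function(x) {
      standardized_levins(table(unlist(x)))$B_a
    }, n_boot = 400, seed = seeds[sims + i])
    covered[i] <- ci$low <= truth && truth <= ci$high
  }
  expect_gte(mean(covered), 0.88)
  expect_lte(mean(covered), 0.995)
})

test_that("interval width shrinks with more scats", {
  props <- c(a = 0.4, b = 0.3, c = 0.2, d = 0.1)
  width_at <- function(n, seed) {
    sc <- generate_scats(one_item_scenario(props, n), seed = seed)
    items <- group_item_lists(sc)[[1]]$scats
    ci <- bootstrap_ci(items, function(x) {
      standardized_levins(table(unlist(x)))$B_a
    }, n_boot = 300, seed = seed + 1)
    ci$high - ci$low
  }
  w20 <- mean(vapply(1:5, function(s) width_at(20, s), numeric(1)))
  w200 <- mean(vapply(1:5, function(s) width_at(200, s + 50), numeric(1)))
  expect_lt(w200, w20)
})

test_that("per-group table recomputes n within replicates and sorts bounds", {
  nb <- niche_breadth_table(toy_collection(), n_boot = 200, seed = 9)
  expect_equal(nrow(nb), 1L)
  expect_lte(nb$ci_low, nb$ci_high)
  expect_equal(nb$n_taxa, 3L)
  expect_equal(nb$B_a, standardized_levins(c(3, 2, 2))$B_a)
})
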