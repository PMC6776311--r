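test_that("scat generator is deterministic and validates scenarios", {
  props <- c(a = 0.6, b = 0.4)
  sc1 <- generate_scats(one_item_scenario(props, 50), seed = 8)
  sc2 <- generate_scats(one_item_scenario(props, 50), seed = 8)
  expect_identical(sc1$items, sc2$items)
  expect_equal(n_scats(sc1), 50L)

  bad <- tibble::tibble(river = "R", year = 2015L, taxon = c("a", "b"),
                        prop = c(0.7, 0.7))
  expect_error(diet_scenario(tibble::tibble(river = "R", year = 2015L,
                                            n_scats = 10, mean_items = 1),
                             bad), "sum to 1")
})

test_that("record proportions converge to the scenario diet", {
  props <- c(a = 0.5, b = 0.3, c = 0.15, d = 0.05)
  sc <- generate_scats(one_item_scenario(props, 1e5), seed = 12)
  emp <- table(sc$items$taxon) / nrow(sc$items)
  expect_true(all(abs(emp[names(props)] - props) < 0.01))
})

test_that("single-taxon scenario is the specialist limit", {
  sc <- generate_scats(one_item_scenario(c(only = 1), 30), seed = 1)
  occ <- tabulate_occurrences(sc)
  expect_equal(standardized_levins(occ$n_records)$B_a, 0)
})

test_that("multi-item scats never repeat a taxon and hold >= 1 item", {
  scen <- diet_scenario(
    tibble::tibble(river = "R", year = 2015L, n_scats = 200, mean_items = 3),
    tibble::tibble(river = "R", year = 2015L, taxon = letters[1:6],
                   prop = c(0.3, 0.25, 0.15, 0.15, 0.1, 0.05)))
  sc <- generate_scats(scen, seed = 4)
  per_scat <- split(sc$items$taxon, sc$items$scat_id)
  expect_true(all(lengths(per_scat) >= 1))
  expect_true(all(vapply(per_scat, anyDuplicated, integer(1)) == 0))
  expect_equal(length(per_scat), 200L)
})

test_that("isotope generator hits scenario variances and couples to diet", {
  scen <- isotope_scenario(tibble::tibble(
    river = c("A", "B"), year = 2015L, n = 1e5,
    mean_d15N = c(10, 12), var_d15N = 4,
    mean_d13C = -28, var_d13C = 2))
  iso <- generate_isotopes(scen, seed = 3)
  vA <- var(iso$d15N[iso$river == "A"])
  expect_gt(vA, 3.9); expect_lt(vA, 4.1)
  iso2 <- generate_isotopes(scen, seed = 3)
  expect_identical(iso, iso2)

  # coupling identity: catfish share 0 vs 0.5 with a 1-level prey gap
  ref <- tibble::tibble(taxon = c("catfish", "cichlid"), ftl = c(2, 3))
  diet <- diet_scenario(
    tibble::tibble(river = c("A", "B"), year = 2015L, n_scats = 10,
                   mean_items = 1),
    tibble::tibble(river = rep(c("A", "B"), each = 2),
                   year = 2015L, taxon = rep(c("catfish", "cichlid"), 2),
                   prop = c(0, 1, 0.5, 0.5)))
  cs <- coupled_isotope_scenario(diet, ref)
  tef <- tef_constants()
  d_ftl <- scenario_ftl(diet, "A", 2015, ref) - scenario_ftl(diet, "B", 2015, ref)
  expect_equal(diff(rev(cs$groups$mean_d15N)),
               tef$delta15N_per_level * d_ftl, tolerance = 1e-12)
  expect_equal(d_ftl, 0.5)
})

test_that("packaged fixture reproduces the published marginals exactly", {
  fx1 <- otter_diet_fixture()
  fx2 <- otter_diet_fixture()
  expect_identical(fx1$items, fx2$items)  # idempotent

  occ <- tabulate_occurrences(fx1)
  g <- occurrence_groups(occ)
  sp15 <- g[g$river == "San Pedro" & g$year == 2015, ]
  expect_equal(sp15$n_scats, 117L)
  expect_equal(sp15$total_records, 289L)
  expect_equal(sp15$n_taxa, 29L)
  expect_equal(occ$n_records[occ$river == "Pasion" & occ$year == 2015 &
                               occ$taxon == "Pterygoplichthys spp"], 36L)

  # every packaged per-taxon count survives scat expansion + tabulation
  counts <- readr::read_csv(
    system.file("extdata", "otter_prey_record_counts.csv",
                package = "scatniche"), show_col_types = FALSE)
  merged <- dplyr::left_join(counts,
                             tibble::as_tibble(occ),
                             by = c("river", "year", "taxon"))
  expect_equal(merged$n_records.y, merged$n_records.x)
})

test_that("study-condition isotope scenario carries the reported structure", {
  scen <- default_isotope_scenario()
  g <- scen$groups
  sp <- g[g$river == "San Pedro", ]
  expect_equal(sp$var_d15N, c(4.83, 1.73))
  expect_equal(sp$n, c(20L, 55L))
  expect_equal(diff(rev(sp$mean_d15N)), 2.78)
  pa <- g[g$river == "Pasion", ]
  expect_equal(diff(rev(pa$mean_d15N)), 1.88)
})
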