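# small in-code fixtures shared across test files

toy_collection <- function() {
  scat_collection(tibble::tibble(
    scat_id = c("s1", "s1", "s2", "s3", "s3", "s3", "s4"),
    river = "R1", year = 2015L,
    taxon = c("catfish", "cichlid", "catfish", "crab", "catfish",
              "cichlid", "crab")))
}

# write a scat CSV and return its path
write_scat_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(c("scat_id,river,year,taxon", lines), path)
  path
}

toy_prey_ref <- function() {
  tibble::tibble(
    taxon = c("catfish", "cichlid", "crab", "mystery"),
    family = c("Loricariidae", "Cichlidae", "Pseudothelphusidae", "Unknown"),
    ftl = c(2.0, 3.1, 2.5, NA),
    max_total_length_mm = c(500, 250, 150, NA),
    ftl_source = "test")
}

# single-item-per-scat scenario: record distribution equals `props` exactly
one_item_scenario <- function(props, n_scats, river = "R", year = 2015L) {
  diet_scenario(
    tibble::tibble(river = river, year = year, n_scats = n_scats,
                   mean_items = 1),
    tibble::tibble(river = river, year = year,
                   taxon = names(props), prop = unname(props)))
}

# exhaustive mean richness over all size-h subsets (oracle for Mao Tau)
exhaustive_tau <- function(m, h) {
  subs <- utils::combn(nrow(m), h, simplify = FALSE)
  mean(vapply(subs, function(s) {
    sum(colSums(m[s, , drop = FALSE]) > 0)
  }, numeric(1)))
}
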