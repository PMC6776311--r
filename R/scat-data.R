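#' Scat collections
#'
#' A scat collection holds one row per scat (`scat_id`, `river`, `year`,
#' `contaminated`) together with a long table of prey-item records
#' (`scat_id`, `taxon`). The sampling unit throughout the package is the
#' scat; groups are river-year combinations. Duplicate taxa within one scat
#' are collapsed to presence, matching occurrence semantics: a scat either
#' contains a prey category or it does not.
#'
#' The `contaminated` flag marks scats whose fecal matter cannot be used for
#' stable-isotope analysis; such scats still contribute to gross scat
#' analysis (occurrence tabulation, niche breadth, accumulation, trophic
#' level).
#'
#' @param items tibble/data.frame with columns `scat_id`, `taxon`, and
#'   (unless `scats` is given) `river` and `year`. A missing (`NA`) taxon
#'   row denotes a scat with no identified items.
#' @param scats optional tibble with one row per scat: `scat_id`, `river`,
#'   `year`, and optionally `contaminated`. Needed to represent scats with
#'   zero items; derived from `items` when absent.
#' @return An object of class `scat_collection`: a list with tibbles
#'   `$scats` and `$items`.
#' @examples
#' sc <- scat_collection(tibble::tibble(
#'   scat_id = c("a", "a", "b"), river = "R", year = 2015,
#'   taxon = c("fish1", "fish2", "fish1")))
#' n_scats(sc)
#' @export
scat_collection <- function(items, scats = NULL) {
  items <- tibble::as_tibble(items)
  if (is.null(scats)) {
    req <- c("scat_id", "river", "year", "taxon")
    miss <- setdiff(req, names(items))
    if (length(miss) > 0) {
      abort_schema(paste0("missing required column(s): ",
                          paste(miss, collapse = ", ")))
    }
    scats <- dplyr::distinct(items, .data$scat_id, .data$river, .data$year)
  } else {
    scats <- tibble::as_tibble(scats)
    if (!all(c("scat_id", "river", "year") %in% names(scats))) {
      abort_schema("scats table needs scat_id, river, year")
    }
    if (!("taxon" %in% names(items))) abort_schema("items table needs taxon")
    if (!("scat_id" %in% names(items))) abort_schema("items table needs scat_id")
  }
  if (!("contaminated" %in% names(scats))) scats$contaminated <- FALSE
  scats$contaminated[is.na(scats$contaminated)] <- FALSE
  scats$year <- as.integer(scats$year)
  scats$scat_id <- as.character(scats$scat_id)
  if (anyDuplicated(scats$scat_id)) {
    abort_schema("scat_id must be unique within a collection")
  }
  if (any(scats$year <= 0L, na.rm = TRUE) || anyNA(scats$year)) {
    abort_schema("year must be a positive integer for every scat")
  }
  items <- items[!is.na(items$taxon) & items$taxon != "", , drop = FALSE]
  items <- tibble::tibble(scat_id = as.character(items$scat_id),
                          taxon   = as.character(items$taxon))
  unknown <- setdiff(items$scat_id, scats$scat_id)
  if (length(unknown) > 0) {
    abort_schema(paste0("items refer to unknown scat_id: ",
                        paste(utils::head(unknown, 5), collapse = ", ")))
  }
  items <- dplyr::distinct(items, .data$scat_id, .data$taxon)
  structure(list(scats = scats, items = items), class = "scat_collection")
}

#' @export
print.scat_collection <- function(x, ...) {
  g <- dplyr::count(x$scats, .data$river, .data$year, name = "n_scats")
  cat("<scat_collection> ", nrow(x$scats), " scats, ",
      nrow(x$items), " prey records, ", nrow(g), " river-year group(s)\n",
      sep = "")
  print(g, ...)
  invisible(x)
}

#' @rdname scat_collection
#' @param x a `scat_collection`
#' @export
n_scats <- function(x) {
  stopifnot(inherits(x, "scat_collection"))
  nrow(x$scats)
}

#' Split a collection into per-scat item lists by group
#'
#' Returns, for each river-year group, a list with the group labels, the
#' per-scat item vectors (one character vector per scat, zero-item scats
#' included as empty vectors), and the scat ids. This is the resampling
#' unit representation used by the bootstrap routines.
#'
#' @param collection a [scat_collection()]
#' @return named list keyed `river|year`, each element a list with
#'   `river`, `year`, `scats` (list of character vectors), `scat_ids`.
#' @export
group_item_lists <- function(collection) {
  stopifnot(inherits(collection, "scat_collection"))
  sc <- collection$scats
  it <- collection$items
  keys <- dplyr::distinct(sc, .data$river, .data$year)
  keys <- dplyr::arrange(keys, .data$river, .data$year)
  out <- vector("list", nrow(keys))
  names(out) <- paste(keys$river, keys$year, sep = "|")
  items_by_scat <- split(it$taxon, it$scat_id)
  for (i in seq_len(nrow(keys))) {
    ids <- sc$scat_id[sc$river == keys$river[i] & sc$year == keys$year[i]]
    lst <- items_by_scat[ids]
    lst[vapply(lst, is.null, logical(1))] <- list(character(0))
    names(lst) <- ids
    out[[i]] <- list(river = keys$river[i], year = keys$year[i],
                     scats = unname(lst), scat_ids = ids)
  }
  out
}

#' Read scat records from a long-format CSV
#'
#' Expected columns: `scat_id,river,year,taxon` with optional
#' `contaminated`. One row per (scat, prey taxon); rows with an empty taxon
#' mark scats with no identified items. Duplicate (scat_id, taxon) rows are
#' collapsed to a single presence record with a warning.
#'
#' @param path path to a UTF-8, comma-delimited file with a header
#' @return a [scat_collection()]
#' @export
read_scats <- function(path) {
  raw <- read_checked_csv(path, required = c("scat_id", "river", "year", "taxon"),
                          what = "scat file")
  raw$scat_id <- as.character(raw$scat_id)
  raw$taxon <- as.character(raw$taxon)
  keep <- !is.na(raw$taxon) & raw$taxon != ""
  dup <- duplicated(raw[keep, c("scat_id", "taxon")])
  if (any(dup)) {
    rlang::warn(paste0("collapsed ", sum(dup),
                       " duplicate (scat_id, taxon) row(s) to presence"))
  }
  scats <- dplyr::distinct(raw, .data$scat_id, .data$river, .data$year,
                           .keep_all = FALSE)
  if ("contaminated" %in% names(raw)) {
    cont <- dplyr::summarise(dplyr::group_by(raw, .data$scat_id),
                             contaminated = any(as.logical(.data$contaminated),
                                                na.rm = TRUE))
    scats <- dplyr::left_join(scats, cont, by = "scat_id")
  }
  scat_collection(raw[keep, c("scat_id", "taxon")], scats = scats)
}

#' Write a scat collection to a long-format CSV
#'
#' Inverse of [read_scats()]: scats with zero items are written as a single
#' row with an empty taxon field so that group sizes survive a round trip.
#'
#' @param collection a [scat_collection()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_scats <- function(collection, path) {
  stopifnot(inherits(collection, "scat_collection"))
  long <- dplyr::left_join(collection$scats, collection$items, by = "scat_id")
  long <- long[, c("scat_id", "river", "year", "taxon", "contaminated")]
  readr::write_csv(long, path, na = "")
  invisible(path)
}

#' Read per-scat isotope samples
#'
#' Expected columns: `scat_id,river,year,d15N,d13C`; values in per-mil
#' (delta-15N vs AIR, delta-13C vs VPDB). Non-negative d13C values are
#' biologically implausible for these samples and trigger a warning but are
#' not rejected.
#'
#' @param path path to a CSV file
#' @return tibble with columns `scat_id`, `river`, `year`, `d15N`, `d13C`
#' @export
read_isotopes <- function(path) {
  x <- read_checked_csv(path, required = c("scat_id", "river", "year",
                                           "d15N", "d13C"),
                        what = "isotope file")
  x$year <- as.integer(x$year)
  x$d15N <- as.numeric(x$d15N)
  x$d13C <- as.numeric(x$d13C)
  if (any(!is.finite(x$d15N))) abort_schema("non-finite d15N values")
  if (any(x$d13C >= 0, na.rm = TRUE)) {
    rlang::warn("d13C >= 0 for some samples; check reference scale")
  }
  tibble::as_tibble(x[, c("scat_id", "river", "year", "d15N", "d13C")])
}

#' Read a prey trophic-level reference table
#'
#' Expected columns: `taxon,family,ftl,max_total_length_mm,ftl_source`.
#' `ftl` is the prey's fractional trophic level (dimensionless, >= 1);
#' missing values are allowed and exclude the taxon from trophic-level
#' computations downstream.
#'
#' @param path path to a CSV file
#' @return tibble with the reference columns
#' @export
read_prey_reference <- function(path) {
  x <- read_checked_csv(path, required = c("taxon", "family", "ftl",
                                           "max_total_length_mm",
                                           "ftl_source"),
                        what = "prey reference")
  x$ftl <- as.numeric(x$ftl)
  x$max_total_length_mm <- as.numeric(x$max_total_length_mm)
  if (any(x$ftl < 1, na.rm = TRUE)) {
    abort_schema("prey ftl must be >= 1 where present")
  }
  tibble::as_tibble(x)
}

#' Filter a prey reference by maximum total length
#'
#' Keeps taxa whose reported maximum total length is at least
#' `min_length_mm` (boundary inclusive). Taxa with a missing length are
#' retained, each with a warning, since absence of a length report is not
#' evidence the prey is too small.
#'
#' @param reference tibble as returned by [read_prey_reference()]
#' @param min_length_mm length threshold in millimetres (>= 0)
#' @return the filtered reference tibble
#' @export
filter_prey_by_length <- function(reference, min_length_mm) {
  stopifnot(is.numeric(min_length_mm), length(min_length_mm) == 1,
            min_length_mm >= 0)
  len <- reference$max_total_length_mm
  missing_len <- is.na(len)
  for (tx in reference$taxon[missing_len]) {
    rlang::warn(paste0("no maximum length for '", tx, "'; retained"))
  }
  reference[missing_len | len >= min_length_mm, , drop = FALSE]
}

#' Tabulate prey occurrences per river-year group
#'
#' For every group and taxon, counts the number of scats containing the
#' taxon (`n_records`) and expresses it two ways: `pct_scats` (percentage
#' of the group's scats that contain the taxon; sums above 100 when scats
#' hold several taxa) and `pct_records` (the taxon's share of all prey
#' records in the group; sums to 100 and serves as the diet-composition
#' proportion downstream). Percentages are kept at full precision; round
#' for display.
#'
#' @param collection a [scat_collection()]
#' @return tibble of class `occurrence_table` with columns `river`, `year`,
#'   `taxon`, `n_records`, `pct_scats`, `pct_records`; attribute `"groups"`
#'   holds per-group `n_scats`, `total_records`, `n_taxa`.
#' @export
tabulate_occurrences <- function(collection) {
  stopifnot(inherits(collection, "scat_collection"))
  if (nrow(collection$scats) == 0) abort_schema("empty collection")
  lst <- group_item_lists(collection)
  rows <- list()
  grows <- list()
  for (g in lst) {
    n_sc <- length(g$scats)
    tab <- table(unlist(g$scats))
    total <- sum(tab)
    if (total == 0) {
      rlang::warn(paste0("group ", g$river, " ", g$year,
                         " has no prey records; omitted"))
      next
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      river = g$river, year = g$year,
      taxon = names(tab), n_records = as.integer(tab),
      pct_scats = 100 * as.integer(tab) / n_sc,
      pct_records = 100 * as.integer(tab) / total)
    grows[[length(grows) + 1L]] <- tibble::tibble(
      river = g$river, year = g$year, n_scats = n_sc,
      total_records = as.integer(total), n_taxa = length(tab))
  }
  if (length(rows) == 0) abort_schema("no group with prey records")
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$river, .data$year,
                        dplyr::desc(.data$n_records), .data$taxon)
  attr(out, "groups") <- dplyr::bind_rows(grows)
  class(out) <- c("occurrence_table", class(out))
  out
}

#' @rdname tabulate_occurrences
#' @param x an `occurrence_table`
#' @return `occurrence_groups()`: the per-group summary tibble
#' @export
occurrence_groups <- function(x) {
  stopifnot(inherits(x, "occurrence_table"))
  attr(x, "groups")
}

# shared CSV reader with schema validation
read_checked_csv <- function(path, required, what) {
  if (!file.exists(path)) abort_schema(paste0(what, " not found: ", path))
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss) > 0) {
    abort_schema(paste0(what, " is missing column(s): ",
                        paste(miss, collapse = ", ")))
  }
  if (nrow(x) == 0) abort_schema(paste0(what, " has a header but no rows"))
  x
}

abort_schema <- function(msg) {
  rlang::abort(msg, class = "scatniche_schema_error")
}
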