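#' Read a population table
#'
#' Reads a CSV file with one row per sampled population and validates it.
#' The expected columns are `id`, `lat`, `lon`, `year`, `n` (number of
#' individuals genotyped), `k` (number infected with the focal
#' endosymbiont strain), and optionally `haplotypes` (semicolon-joined
#' per-individual mitochondrial haplotype labels, `HT1`/`HT2`/`unknown`)
#' and `range_label` (`native` or `introduced`). Column names in the file
#' can be remapped through `dialect`.
#'
#' @param path Path to a CSV file with a header row (UTF-8).
#' @param dialect Optional named character vector mapping standard column
#'   names to the names used in the file, e.g.
#'   `c(lat = "latitude", lon = "longitude")`.
#' @return A tibble with one row per population, validated against the
#'   table invariants (see [validate_population_table()]).
#' @seealso [write_population_table()], [filter_duplicate_locations()],
#'   [pool_groups()]
#' @export
#' @examples
#' path <- system.file("extdata", "table1_populations.csv", package = "wolbtrace")
#' read_population_table(path)
read_population_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "wolb_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(dialect)) {
    for (std in names(dialect)) {
      if (dialect[[std]] %in% names(raw)) {
        names(raw)[names(raw) == dialect[[std]]] <- std
      }
    }
  }
  required <- c("id", "lat", "lon", "year", "n", "k")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(
      paste0("missing required column(s): ", paste(missing, collapse = ", ")),
      class = "wolb_schema_error"
    )
  }
  tbl <- tibble(
    id = as.character(raw$id),
    lat = as.numeric(raw$lat),
    lon = as.numeric(raw$lon),
    year = as.integer(raw$year),
    n = as.integer(raw$n),
    k = as.integer(raw$k),
    haplotypes = if ("haplotypes" %in% names(raw)) as.character(raw$haplotypes) else NA_character_,
    range_label = if ("range_label" %in% names(raw)) as.character(raw$range_label) else "native"
  )
  validate_population_table(tbl)
}

#' Validate a population table
#'
#' Checks the row-level invariants of a population table: coordinates in
#' range, `n >= 1`, `0 <= k <= n`, unique ids, and (when present) no more
#' haplotype calls than genotyped individuals. Violations are reported
#' with the offending row index.
#'
#' @param tbl A data frame of populations (see [read_population_table()]).
#' @return The validated table, invisibly unchanged, as a tibble.
#' @export
validate_population_table <- function(tbl) {
  tbl <- as_tibble(tbl)
  problems <- character(0)
  bad_row <- function(i, what) sprintf("row %d (id %s): %s", i, tbl$id[i], what)
  for (i in seq_len(nrow(tbl))) {
    if (is.na(tbl$lat[i]) || tbl$lat[i] < -90 || tbl$lat[i] > 90) {
      problems <- c(problems, bad_row(i, "lat outside [-90, 90]"))
    }
    if (is.na(tbl$lon[i]) || tbl$lon[i] < -180 || tbl$lon[i] > 180) {
      problems <- c(problems, bad_row(i, "lon outside [-180, 180]"))
    }
    if (is.na(tbl$n[i]) || tbl$n[i] < 1) {
      problems <- c(problems, bad_row(i, "n must be >= 1"))
    }
    if (is.na(tbl$k[i]) || tbl$k[i] < 0 || (!is.na(tbl$n[i]) && tbl$k[i] > tbl$n[i])) {
      problems <- c(problems, bad_row(i, "k must satisfy 0 <= k <= n"))
    }
    if ("haplotypes" %in% names(tbl) && !is.na(tbl$haplotypes[i]) && nzchar(tbl$haplotypes[i])) {
      calls <- strsplit(tbl$haplotypes[i], ";", fixed = TRUE)[[1]]
      calls <- trimws(calls)
      if (!all(calls %in% c("HT1", "HT2", "unknown"))) {
        problems <- c(problems, bad_row(i, "haplotype labels must be HT1, HT2 or unknown"))
      }
      if (!is.na(tbl$n[i]) && length(calls) > tbl$n[i]) {
        problems <- c(problems, bad_row(i, "more haplotype calls than genotyped individuals"))
      }
    }
  }
  if (anyDuplicated(tbl$id)) {
    dup <- unique(tbl$id[duplicated(tbl$id)])
    problems <- c(problems, paste0("duplicated id(s): ", paste(dup, collapse = ", ")))
  }
  if (length(problems) > 0) {
    abort(
      paste0(
        "population table failed validation:\n",
        paste0("  - ", problems, collapse = "\n")
      ),
      class = "wolb_validation_error"
    )
  }
  tbl
}

#' Write a population table
#'
#' Writes the table back in the same CSV dialect that
#' [read_population_table()] reads, so that read -> write -> read
#' round-trips losslessly.
#'
#' @param tbl A validated population table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_population_table <- function(tbl, path) {
  tbl <- validate_population_table(tbl)
  cols <- c("id", "lat", "lon", "year", "n", "k", "haplotypes", "range_label")
  readr::write_csv(tbl[, cols], path, progress = FALSE)
  invisible(path)
}

#' Drop resampled locations, keeping one population per site
#'
#' Spatial variance estimation assumes independent samples, so locations
#' sampled more than once must be reduced to a single population. Sites
#' whose coordinates agree within `tol_deg` degrees on both axes are
#' treated as one location, and one member of each such group is retained
#' uniformly at random under `seed`. Output rows keep their input order.
#'
#' @param tbl A population table.
#' @param seed Integer seed controlling which duplicate is retained.
#' @param tol_deg Coordinate tolerance in decimal degrees within which two
#'   records count as the same location. The default 1e-3 degrees
#'   (roughly 100 m) reflects the precision of field GPS records.
#' @return The filtered tibble, one row per distinct location.
#' @export
filter_duplicate_locations <- function(tbl, seed = 1L, tol_deg = 1e-3) {
  stopifnot(tol_deg >= 0)
  tbl <- as_tibble(tbl)
  n <- nrow(tbl)
  if (n <= 1) return(tbl)
  # union-find over pairs within tolerance; groups are transitive closures
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  ord <- order(tbl$lat, tbl$lon)
  lat <- tbl$lat[ord]
  lon <- tbl$lon[ord]
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      if (lat[b] - lat[a] > tol_deg) break
      if (abs(lon[b] - lon[a]) <= tol_deg) {
        ra <- find(ord[a]); rb <- find(ord[b])
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  keep <- logical(n)
  withr::with_seed(seed, {
    for (g in unique(root)) {
      members <- which(root == g)
      keep[if (length(members) == 1) members else sample(members, 1)] <- TRUE
    }
  })
  tbl[keep, ]
}

#' Pool populations into regional totals
#'
#' Sums genotyped and infected counts within named groups, e.g. to form a
#' pooled regional infection-frequency estimate across nearby populations
#' or sampling years.
#'
#' @param tbl A population table.
#' @param grouping Named character vector or list mapping population `id`
#'   to a group label. Every id named here must exist in `tbl`; ids not
#'   named are ignored.
#' @return A tibble with one row per group: `group_label`, `n_total`,
#'   `k_total`.
#' @export
#' @examples
#' path <- system.file("extdata", "table1_populations.csv", package = "wolbtrace")
#' tbl <- read_population_table(path)
#' pool_groups(tbl, c(
#'   "France 1" = "France", "France 2" = "France",
#'   "France 3" = "France", "France 4" = "France"
#' ))
pool_groups <- function(tbl, grouping) {
  grouping <- unlist(grouping)
  if (length(grouping) == 0) {
    return(tibble(group_label = character(0), n_total = integer(0), k_total = integer(0)))
  }
  unknown <- setdiff(names(grouping), tbl$id)
  if (length(unknown) > 0) {
    abort(
      paste0("grouping names id(s) not in table: ", paste(unknown, collapse = ", ")),
      class = "wolb_lookup_error"
    )
  }
  tbl |>
    dplyr::filter(.data$id %in% names(grouping)) |>
    dplyr::mutate(group_label = unname(grouping[.data$id])) |>
    dplyr::group_by(.data$group_label) |>
    dplyr::summarise(
      n_total = sum(.data$n),
      k_total = sum(.data$k),
      .groups = "drop"
    )
}

#' Parse per-individual haplotype calls
#'
#' Expands the semicolon-joined `haplotypes` column into one row per
#' scored individual, paired with the population's infection status
#' breakdown where unambiguous.
#'
#' @param tbl A population table.
#' @return A tibble with columns `id` and `haplotype`, one row per call.
#' @export
haplotype_calls <- function(tbl) {
  tbl |>
    dplyr::filter(!is.na(.data$haplotypes) & nzchar(.data$haplotypes)) |>
    dplyr::mutate(haplotype = strsplit(.data$haplotypes, ";", fixed = TRUE)) |>
    tidyr::unnest("haplotype") |>
    dplyr::mutate(haplotype = trimws(.data$haplotype)) |>
    dplyr::select("id", "haplotype")
}
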