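#' Validate a panel bundle
#'
#' Checks the structural invariants every downstream step relies on:
#' unique (county, year) yield records with non-negative yield and positive
#' area; geography covering every county used anywhere; complete 52-week
#' weather for every yield record; a soil row for every variable and county;
#' density for every yield record; progress curves that are monotone
#' non-decreasing in `[0, 1]`, never harvest more than was planted, and
#' reach full planting.
#'
#' @param bundle a [gem_bundle()].
#' @param strict error (instead of report) when any fatal violation is found.
#' @return object of class `gem_validation`: list with `coverage` (one-row
#'   tibble) and `violations` (tibble with `severity`, `table`, `message`).
#' @export
validate_bundle <- function(bundle, strict = FALSE) {
  v <- list()
  add <- function(severity, table, message) {
    v[[length(v) + 1L]] <<- tibble::tibble(severity = severity, table = table, message = message)
  }
  y <- bundle$yields
  geo <- bundle$geography

  dup <- y |> dplyr::count(.data$county_id, .data$year) |> dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    add("fatal", "yields", sprintf("duplicate (county, year) records: %s",
        paste(utils::head(paste0("(", dup$county_id, ", ", dup$year, ")"), 5), collapse = ", ")))
  }
  bad_y <- dplyr::filter(y, .data$yield < 0)
  for (i in seq_len(nrow(bad_y))) {
    add("fatal", "yields", sprintf("negative yield for (%s, %s): %g",
                                   bad_y$county_id[i], bad_y$year[i], bad_y$yield[i]))
  }
  bad_a <- dplyr::filter(y, .data$area <= 0)
  if (nrow(bad_a)) {
    add("fatal", "yields", sprintf("non-positive planted area for %d record(s), e.g. (%s, %s)",
                                   nrow(bad_a), bad_a$county_id[1], bad_a$year[1]))
  }

  used <- unique(c(y$county_id, bundle$weather$county_id, bundle$soil$county_id,
                   bundle$density$county_id, bundle$progress$county_id))
  miss_geo <- setdiff(used, geo$county_id)
  for (cid in miss_geo) add("fatal", "geography", sprintf("county %s missing from geography", cid))
  if (any(!is.finite(geo$lat)) || any(!is.finite(geo$lon))) {
    add("fatal", "geography", "non-finite centroid coordinates")
  }
  multi <- geo |> dplyr::count(.data$county_id) |> dplyr::filter(.data$n > 1)
  if (nrow(multi)) {
    add("fatal", "geography", sprintf("county mapped to multiple districts: %s",
                                      paste(multi$county_id, collapse = ", ")))
  }

  # weather completeness: 52 weeks x all declared vars for each yield record
  wv <- attr(bundle, "weather_vars")
  wcount <- bundle$weather |>
    dplyr::distinct(.data$county_id, .data$year, .data$week, .data$var) |>
    dplyr::count(.data$county_id, .data$year, name = "cells")
  wneed <- 52L * length(wv)
  wmiss <- y |>
    dplyr::left_join(wcount, by = c("county_id", "year")) |>
    dplyr::filter(is.na(.data$cells) | .data$cells < wneed)
  if (nrow(wmiss)) {
    add("fatal", "weather", sprintf("incomplete weekly weather for %d county-year record(s), e.g. (%s, %s)",
                                    nrow(wmiss), wmiss$county_id[1], wmiss$year[1]))
  }

  sv <- attr(bundle, "soil_vars")
  scount <- bundle$soil |> dplyr::count(.data$county_id, name = "cells")
  smiss <- tibble::tibble(county_id = unique(y$county_id)) |>
    dplyr::left_join(scount, by = "county_id") |>
    dplyr::filter(is.na(.data$cells) | .data$cells < length(sv))
  for (cid in smiss$county_id) {
    add("fatal", "soil", sprintf("missing soil variable(s) for county %s", cid))
  }

  dmiss <- dplyr::anti_join(y, bundle$density, by = c("county_id", "year"))
  if (nrow(dmiss)) {
    add("fatal", "density", sprintf("missing plant density for %d record(s), e.g. (%s, %s)",
                                    nrow(dmiss), dmiss$county_id[1], dmiss$year[1]))
  }

  pr <- bundle$progress |> dplyr::arrange(.data$county_id, .data$year, .data$week)
  chk <- pr |>
    dplyr::group_by(.data$county_id, .data$year) |>
    dplyr::summarise(
      nonmono = any(diff(.data$planting) < -1e-9) || any(diff(.data$harvesting) < -1e-9),
      out_of_range = any(.data$planting < -1e-9 | .data$planting > 1 + 1e-9 |
                           .data$harvesting < -1e-9 | .data$harvesting > 1 + 1e-9),
      h_exceeds_p = any(.data$harvesting > .data$planting + 1e-9),
      incomplete = max(.data$planting) < 1 - 1e-9,
      .groups = "drop")
  report_progress <- function(flag, msg) {
    bad <- chk[chk[[flag]], , drop = FALSE]
    if (nrow(bad)) {
      add("fatal", "progress", sprintf("%s for %d (county, year) pair(s), e.g. (%s, %s)",
                                       msg, nrow(bad), bad$county_id[1], bad$year[1]))
    }
  }
  report_progress("nonmono", "non-monotone planting/harvesting curve")
  report_progress("out_of_range", "progress fraction outside [0, 1]")
  report_progress("h_exceeds_p", "harvesting ahead of planting")
  report_progress("incomplete", "planting never reaches 100%")

  violations <- if (length(v)) dplyr::bind_rows(v) else {
    tibble::tibble(severity = character(), table = character(), message = character())
  }
  coverage <- tibble::tibble(
    n_county_years = nrow(y),
    n_counties = dplyr::n_distinct(y$county_id),
    n_districts = dplyr::n_distinct(geo$district_id[geo$county_id %in% y$county_id]),
    n_states = dplyr::n_distinct(geo$state_id[geo$county_id %in% y$county_id]),
    n_years = dplyr::n_distinct(y$year),
    coverage = nrow(y) / (dplyr::n_distinct(y$county_id) * dplyr::n_distinct(y$year))
  )
  out <- structure(list(coverage = coverage, violations = violations),
                   class = "gem_validation")
  if (strict && nrow(violations)) {
    abort(paste0("bundle validation failed:\n",
                 paste(utils::head(violations$message, 10), collapse = "\n")))
  }
  out
}

#' @export
print.gem_validation <- function(x, ...) {
  cv <- x$coverage
  cat(sprintf("<gem_validation> %d county-year records (%d counties, %d years, %.0f%% coverage)\n",
              cv$n_county_years, cv$n_counties, cv$n_years, 100 * cv$coverage))
  if (nrow(x$violations) == 0) {
    cat("  no violations\n")
  } else {
    cat(sprintf("  %d violation(s):\n", nrow(x$violations)))
    for (i in seq_len(min(nrow(x$violations), 10))) {
      cat(sprintf("  [%s] %s: %s\n", x$violations$severity[i],
                  x$violations$table[i], x$violations$message[i]))
    }
  }
  invisible(x)
}
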