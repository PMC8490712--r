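#' Read a panel bundle from delimited text files
#'
#' Accepts either a directory containing `geography.csv`, `yields.csv`,
#' `weather.csv`, `soil.csv`, `density.csv`, `progress.csv`, or a YAML
#' config file with a `paths:` mapping naming each file (plus optional
#' `strict: false`). Management tables given at state level (a `state_id`
#' column instead of `county_id` in `progress.csv` and/or `density.csv`)
#' are broadcast to every member county of the state. The assembled bundle
#' is validated before being returned.
#'
#' @param path directory or YAML config file.
#' @param strict passed to [validate_bundle()]; default `TRUE` (errors on
#'   fatal violations).
#' @return a [gem_bundle()].
#' @export
read_gem_bundle <- function(path, strict = TRUE) {
  files <- c(geography = "geography.csv", yields = "yields.csv",
             weather = "weather.csv", soil = "soil.csv",
             density = "density.csv", progress = "progress.csv")
  if (dir.exists(path)) {
    paths <- file.path(path, files)
    names(paths) <- names(files)
  } else {
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg$paths)) abort("config file must contain a 'paths:' mapping")
    paths <- unlist(cfg$paths)[names(files)]
    if (anyNA(paths)) {
      abort(sprintf("config is missing path(s) for: %s",
                    paste(names(files)[is.na(paths)], collapse = ", ")))
    }
    rel <- !grepl("^(/|[A-Za-z]:)", paths)
    paths[rel] <- file.path(dirname(path), paths[rel])
    if (!is.null(cfg$strict)) strict <- isTRUE(cfg$strict)
  }
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    abort(sprintf("input file(s) not found: %s", paste(missing, collapse = ", ")))
  }
  rd <- function(f) readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
  geography <- rd(paths[["geography"]])
  yields <- rd(paths[["yields"]])
  weather <- rd(paths[["weather"]])
  soil <- rd(paths[["soil"]])
  density <- rd(paths[["density"]])
  progress <- rd(paths[["progress"]])

  broadcast <- function(tb, name) {
    if ("county_id" %in% names(tb)) return(tb)
    if (!("state_id" %in% names(tb))) {
      abort(sprintf("'%s' needs a county_id or state_id column", name))
    }
    miss <- setdiff(unique(tb$state_id), geography$state_id)
    if (length(miss)) {
      abort(sprintf("state(s) in %s missing from geography: %s",
                    name, paste(miss, collapse = ", ")))
    }
    members <- dplyr::distinct(geography, .data$state_id, .data$county_id)
    dplyr::inner_join(tb, members, by = "state_id",
                      relationship = "many-to-many") |>
      dplyr::select(-"state_id")
  }
  progress <- broadcast(progress, "progress")
  density <- broadcast(density, "density")

  bundle <- gem_bundle(geography, yields, weather, soil, density, progress)
  validate_bundle(bundle, strict = strict)
  bundle
}

#' Write a panel bundle as delimited text files
#'
#' @param bundle a [gem_bundle()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_gem_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(bundle)) {
    readr::write_csv(bundle[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  invisible(dir)
}

#' Export a decomposition or prediction table to CSV
#'
#' @param x a tibble as returned by [decompose_yield()] or
#'   [predict_yield()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gem_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}
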