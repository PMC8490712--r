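#' Model parameters: genetic polynomials and stage coefficients
#'
#' Holds the district-level genetic trend coefficients (one polynomial of
#' order `K` in the normalized year per crop reporting district — counties in
#' a district share it) and the two stage-specific coefficient vectors for
#' the weekly growth potential (vegetative and reproductive). Each stage
#' vector has one entry per term of the quadratic expansion: with 7 weather
#' and 10 soil variables that is 1 intercept + 17 linear + 153 pairwise =
#' 171 coefficients.
#'
#' @param alpha numeric matrix, rows named by `district_id`, columns
#'   `k0..kK`; or a tidy tibble (`district_id`, `k`, `value`).
#' @param gamma_v,gamma_r named numeric vectors over the term names from the
#'   quadratic expansion (see [growth_potential_week()]); defaults to zero.
#' @param weather_vars,soil_vars variable names fixing the term set.
#' @param K polynomial order of the genetic trend (default 10).
#' @return object of class `gem_params`.
#' @export
gem_params <- function(alpha, gamma_v = NULL, gamma_r = NULL,
                       weather_vars, soil_vars, K = 10L) {
  terms <- gamma_term_names(weather_vars, soil_vars)
  if (is.data.frame(alpha)) {
    wide <- tidyr::pivot_wider(alpha, names_from = "k", values_from = "value",
                               names_prefix = "k")
    am <- as.matrix(wide[setdiff(names(wide), "district_id")])
    rownames(am) <- wide$district_id
    alpha <- am
  }
  alpha <- as.matrix(alpha)
  if (ncol(alpha) != K + 1L) {
    abort(sprintf("alpha must have K + 1 = %d columns, got %d", K + 1L, ncol(alpha)))
  }
  colnames(alpha) <- paste0("k", 0:K)
  zero <- setNames(numeric(length(terms)), terms)
  fill <- function(g) {
    if (is.null(g)) return(zero)
    if (is.null(names(g)) && length(g) == length(terms)) {
      return(setNames(as.numeric(g), terms))
    }
    bad <- setdiff(names(g), terms)
    if (length(bad)) {
      abort(sprintf("unknown coefficient term(s): %s", paste(utils::head(bad, 5), collapse = ", ")))
    }
    out <- zero
    out[names(g)] <- g
    out
  }
  structure(list(alpha = alpha, gamma_v = fill(gamma_v), gamma_r = fill(gamma_r)),
            class = "gem_params",
            weather_vars = as.character(weather_vars),
            soil_vars = as.character(soil_vars),
            K = as.integer(K))
}

#' @export
print.gem_params <- function(x, ...) {
  cat(sprintf("<gem_params> %d districts, genetic order K = %d, %d coefficients per stage\n",
              nrow(x$alpha), attr(x, "K"), length(x$gamma_v)))
  nz <- function(g) sum(abs(g) > 0)
  cat(sprintf("  nonzero stage coefficients: vegetative %d, reproductive %d\n",
              nz(x$gamma_v), nz(x$gamma_r)))
  invisible(x)
}

#' @describeIn gem_params tidy coefficient table (one row per district-power
#'   genetic coefficient and per stage term).
#' @param x a `gem_params` object.
#' @param ... unused.
#' @export
tidy.gem_params <- function(x, ...) {
  K <- attr(x, "K")
  a <- tibble::as_tibble(x$alpha, rownames = "district_id") |>
    tidyr::pivot_longer(-"district_id", names_to = "term", values_to = "estimate") |>
    dplyr::mutate(component = "genetic", .before = 1)
  g <- dplyr::bind_rows(
    tibble::tibble(component = "vegetative", district_id = NA_character_,
                   term = names(x$gamma_v), estimate = unname(x$gamma_v)),
    tibble::tibble(component = "reproductive", district_id = NA_character_,
                   term = names(x$gamma_r), estimate = unname(x$gamma_r)))
  dplyr::bind_rows(a, g)
}

# Evaluate the genetic polynomial for a vector of normalized years, per
# district row of alpha.
genetic_value <- function(alpha_row, t_norm) {
  K <- length(alpha_row) - 1L
  tp <- outer(t_norm, 0:K, `^`)
  as.numeric(tp %*% alpha_row)
}

#' Serialize model parameters (and scalers) to JSON
#'
#' The file keys genetic coefficients by district and power, stage
#' coefficients by term name (e.g. `"tmax*aws"`), and embeds the min-max
#' scalers so that predictions are reproducible from the file alone.
#'
#' @param x a `gem_params` or `gem_fit` object.
#' @param path output file path.
#' @param scalers [gem_scalers()] to embed (taken from a `gem_fit`
#'   automatically).
#' @param extra optional named list echoed into the file (e.g. solver
#'   settings).
#' @return `path`, invisibly.
#' @export
write_gem_model <- function(x, path, scalers = NULL, extra = NULL) {
  if (inherits(x, "gem_fit")) {
    scalers <- scalers %||% x$scalers
    extra <- extra %||% list(control = x$control[setdiff(names(x$control), "rng_seed")],
                             final_rmse = x$final_rmse)
    x <- x$params
  }
  stopifnot(inherits(x, "gem_params"))
  payload <- list(
    weather_vars = attr(x, "weather_vars"),
    soil_vars = attr(x, "soil_vars"),
    K = attr(x, "K"),
    alpha = lapply(seq_len(nrow(x$alpha)), function(i) as.list(x$alpha[i, ])) |>
      setNames(rownames(x$alpha)),
    gamma = list(vegetative = as.list(x$gamma_v), reproductive = as.list(x$gamma_r))
  )
  if (!is.null(scalers)) {
    payload$scalers <- list(
      weather = scalers$weather, soil = scalers$soil,
      density = as.list(scalers$density), year = as.list(scalers$year))
  }
  if (!is.null(extra)) payload <- c(payload, extra)
  # I(17) significant digits: doubles survive the text round trip exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "rows")
  invisible(path)
}

#' Read model parameters back from JSON
#'
#' @param path file written by [write_gem_model()].
#' @return list with elements `params` ([gem_params()]) and `scalers`
#'   ([gem_scalers()] or `NULL`).
#' @export
read_gem_model <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  wv <- as.character(unlist(js$weather_vars))
  sv <- as.character(unlist(js$soil_vars))
  K <- as.integer(js$K)
  alpha <- do.call(rbind, lapply(js$alpha, function(row) unlist(row)[paste0("k", 0:K)]))
  rownames(alpha) <- names(js$alpha)
  params <- gem_params(alpha,
                       gamma_v = unlist(js$gamma$vegetative),
                       gamma_r = unlist(js$gamma$reproductive),
                       weather_vars = wv, soil_vars = sv, K = K)
  scalers <- NULL
  if (!is.null(js$scalers)) {
    as_rng <- function(x) c(min = as.numeric(x$min), max = as.numeric(x$max))
    sc_tab <- function(rows) {
      dplyr::bind_rows(lapply(rows, function(r) {
        tibble::tibble(var = r$var, min = as.numeric(r$min), max = as.numeric(r$max))
      }))
    }
    scalers <- structure(list(
      weather = sc_tab(js$scalers$weather),
      soil = sc_tab(js$scalers$soil),
      density = as_rng(js$scalers$density),
      year = as_rng(js$scalers$year)
    ), class = "gem_scalers")
  }
  list(params = params, scalers = scalers)
}
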