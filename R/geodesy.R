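#' Great-circle distance matrix between languages
#'
#' Haversine distances on a sphere of radius 6371.0088 km (IUGG mean Earth
#' radius).  The ellipsoidal correction (< 0.5%) is irrelevant at the
#' resolution of a GP length-scale prior.
#'
#' @param coords a [coordinate_table()].
#' @return object of class `"geo_dist"`: list with `values` (L x L symmetric
#'   km matrix, zero diagonal), `language_ids`, `unit`, `divisor` (1 until
#'   [scale_unit_max()] is applied).
#' @export
great_circle_matrix <- function(coords) {
  stopifnot(inherits(coords, "coord_table"))
  L <- nrow(coords)
  if (L < 2L) stop("need at least 2 languages for a distance matrix")
  R <- 6371.0088
  lat <- coords$lat * pi / 180
  lon <- coords$lon * pi / 180
  dlat <- outer(lat, lat, "-")
  dlon <- outer(lon, lon, "-")
  a <- sin(dlat / 2)^2 + outer(cos(lat), cos(lat)) * sin(dlon / 2)^2
  a <- pmin(pmax(a, 0), 1)
  d <- 2 * R * asin(sqrt(a))
  diag(d) <- 0
  dimnames(d) <- list(coords$language, coords$language)
  structure(list(values = d, language_ids = coords$language,
                 unit = "km", divisor = 1),
            class = "geo_dist")
}

#' Scale a distance matrix so the maximum pairwise distance is 1
#'
#' Kernel length-scales carry Exponential(2) priors that only make sense on
#' an O(1) distance scale (the latent phylogenetic distances have an
#' Exponential(1) prior and are O(1) themselves), so geographic distances are
#' normalized to unit maximum before entering the kernel.
#'
#' @param d a `"geo_dist"` object.
#' @return `"geo_dist"` with `values` divided by the maximum off-diagonal
#'   entry and `divisor` recording the cumulative km divisor.
#' @export
scale_unit_max <- function(d) {
  stopifnot(inherits(d, "geo_dist"))
  off <- d$values[upper.tri(d$values)]
  m <- max(off)
  if (m <= 0) stop("all pairwise distances are zero; cannot scale")
  d$values <- d$values / m
  d$divisor <- d$divisor * m
  d
}

#' @export
print.geo_dist <- function(x, ...) {
  cat(sprintf("<geo_dist> %d languages, unit = %s / %.6g\n",
              length(x$language_ids), x$unit, x$divisor))
  print(round(x$values, 4))
  invisible(x)
}
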