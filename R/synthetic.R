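#' Simulate a random ultrametric language tree
#'
#' Coalescent-style random rooted ultrametric tree (via [ape::rcoal()]),
#' with pairwise path distances rescaled to mean 1 so that the simulated
#' world matches the Exponential(1) prior scale of the latent distances.
#'
#' @param L number of languages (>= 3).
#' @param seed RNG seed.
#' @return list with `tree` (`"phylo"`), `distances` (L x L path-distance
#'   matrix, mean off-diagonal = 1), `language_ids`.
#' @export
simulate_tree <- function(L, seed = 1L) {
  if (L < 3) stop("need L >= 3")
  set.seed(seed)
  labs <- paste0("L", seq_len(L))
  tr <- ape::rcoal(L, tip.label = labs)
  D <- cophenetic(tr)[labs, labs]
  sc <- mean(D[upper.tri(D)])
  D <- D / sc
  tr$edge.length <- tr$edge.length / sc
  list(tree = tr, distances = D, language_ids = labs)
}

#' Simulate language coordinates with planted contact zones
#'
#' Languages are placed in a Europe-sized window.  With `n_zones >= 1`, a
#' fraction `zone_frac` of the languages (at least 2 per zone) is gathered
#' into tight geographic clusters ("contact zones", sd ~ 0.7 degrees around
#' well-separated centers); the remainder is scattered uniformly.  Pairs of
#' languages sharing a zone are recorded as contact pairs.  `zone_frac = 1`
#' partitions all languages into zones.
#'
#' @param L number of languages.
#' @param n_zones number of contact zones (0 = fully scattered).
#' @param seed RNG seed.
#' @param zone_frac fraction of languages assigned to zones (default 1 so
#'   that every language belongs to exactly one zone; lower it to keep a
#'   scattered background population).
#' @param language_ids optional ids, default `L1..`.
#' @return list with `coordinates` (a [coordinate_table()]), `zone` (integer
#'   vector, 0 = background), `contact_pairs` (character vector of
#'   `"a|b"` pair keys).
#' @export
simulate_geography <- function(L, n_zones, seed = 1L, zone_frac = 1,
                               language_ids = paste0("L", seq_len(L))) {
  if (n_zones < 0 || L < n_zones) stop("need L >= n_zones >= 0")
  if (n_zones > 0 && zone_frac * L < 2 * n_zones) {
    stop("too few zoned languages: need at least 2 per zone")
  }
  set.seed(seed)
  lat0 <- 45; lon0 <- 5; lat1 <- 62; lon1 <- 35   # window
  zone <- integer(L)
  if (n_zones > 0) {
    n_zoned <- max(2L * n_zones, round(zone_frac * L))
    n_zoned <- min(n_zoned, L)
    members <- sort(sample.int(L, n_zoned))
    zone[members] <- rep(seq_len(n_zones), length.out = n_zoned)
    # centers on a coarse grid so zones are far apart relative to zone sd
    cs <- expand.grid(lat = seq(lat0 + 2, lat1 - 2, length.out = 3),
                      lon = seq(lon0 + 3, lon1 - 3, length.out = 3))
    cs <- cs[sample.int(nrow(cs), n_zones), , drop = FALSE]
  }
  lat <- runif(L, lat0, lat1)
  lon <- runif(L, lon0, lon1)
  for (z in seq_len(n_zones)) {
    idx <- which(zone == z)
    lat[idx] <- cs$lat[z] + rnorm(length(idx), 0, 0.7)
    lon[idx] <- cs$lon[z] + rnorm(length(idx), 0, 0.7)
  }
  lat <- pmin(pmax(lat, -89.9), 89.9)
  coords <- coordinate_table(data.frame(language = language_ids,
                                        lat = lat, lon = lon,
                                        stringsAsFactors = FALSE))
  cp <- character(0)
  for (z in seq_len(n_zones)) {
    idx <- which(zone == z)
    if (length(idx) >= 2) {
      for (i in seq_along(idx)[-length(idx)]) {
        for (j in seq.int(i + 1, length(idx))) {
          cp <- c(cp, paste(language_ids[idx[i]], language_ids[idx[j]],
                            sep = "|"))
        }
      }
    }
  }
  list(coordinates = coords, zone = zone, contact_pairs = cp)
}

#' Simulate a binary character matrix from known tree and geography
#'
#' Generates characters from the model itself read generatively: each
#' character draws a phylogenetic effect row from `MVN(0, P)` built on the
#' true tree path distances (OU kernel, length-scale 3) and a geographic
#' effect row from `MVN(0, G)` built on unit-scaled great-circle distances
#' (squared-exponential kernel); with probability `borrow_rate` the
#' geographic row is amplified by `boost` and the character labelled
#' "borrowed".  Cells are Bernoulli(plogis(rho + gamma)).  Constant
#' characters are redrawn (same label process) until S informative
#' characters exist.
#'
#' Generator defaults encode the simulated world: `alpha_P = 2` (cognate
#' presence is strongly tree-structured on the logit scale), `alpha_G = 1`
#' (contact effects real but weaker than descent), `lambda_G = 0.3`
#' (contact dies off well inside the maximal geographic span), `boost = 3`.
#'
#' @param truth list with `distances` (true L x L tree distances) and
#'   `coordinates` (a [coordinate_table()]), as from [simulate_tree()] /
#'   [simulate_geography()].
#' @param S number of characters.
#' @param borrow_rate probability a character is a borrowing (gamma
#'   amplified).
#' @param seed RNG seed.
#' @param alpha_P,alpha_G,lambda_G,boost generator parameters (see above).
#' @return list with `characters` (a [character_matrix()]), `origin`
#'   (factor "inherited"/"borrowed" per character), `params`.
#' @export
simulate_characters <- function(truth, S, borrow_rate = 0.2, seed = 1L,
                                alpha_P = 2, alpha_G = 1, lambda_G = 0.3,
                                boost = 3) {
  if (S < 1) stop("need S >= 1")
  if (borrow_rate < 0 || borrow_rate > 1) stop("borrow_rate must be in [0,1]")
  set.seed(seed)
  Dp <- truth$distances
  L <- nrow(Dp)
  langs <- truth$coordinates$language
  geo <- scale_unit_max(great_circle_matrix(truth$coordinates))
  P <- ensure_psd(phylo_kernel(Dp, alpha_P), jitter = 1e-9)
  G <- ensure_psd(geo_kernel(geo$values, alpha_G, lambda_G), jitter = 1e-9)
  RP <- attr(P, "chol")
  RG <- attr(G, "chol")
  vals <- matrix(NA_integer_, S, L)
  origin <- character(S)
  attempts <- 0L
  s <- 1L
  while (s <= S) {
    attempts <- attempts + 1L
    if (attempts > 100L * S) {
      stop("could not generate ", S, " non-constant characters in ",
           100L * S, " attempts")
    }
    borrowed <- runif(1) < borrow_rate
    rho <- drop(rnorm(L) %*% RP)
    gamma <- drop(rnorm(L) %*% RG)
    if (borrowed) gamma <- gamma * boost
    cell <- rbinom(L, 1L, plogis(rho + gamma))
    if (sum(cell) == 0L || sum(cell) == L) next   # constant: redraw
    vals[s, ] <- cell
    origin[s] <- if (borrowed) "borrowed" else "inherited"
    s <- s + 1L
  }
  cm <- character_matrix(vals,
                         character_ids = sprintf("char_%03d", seq_len(S)),
                         language_ids = langs, drop_constant = FALSE)
  list(characters = cm,
       origin = factor(origin, levels = c("inherited", "borrowed")),
       params = list(S = S, L = L, borrow_rate = borrow_rate,
                     alpha_P = alpha_P, alpha_G = alpha_G,
                     lambda_G = lambda_G, boost = boost, seed = seed))
}

#' One-call synthetic dataset with full ground truth
#'
#' Tree + geography + characters, with everything needed for recovery and
#' contact-zone tests.
#'
#' @param L,S languages and characters.
#' @param n_zones planted contact zones.
#' @param borrow_rate borrowing probability per character.
#' @param seed RNG seed (tree, geography and characters use derived
#'   sub-seeds).
#' @param zone_frac see [simulate_geography()].
#' @param ... passed to [simulate_characters()].
#' @return list of class `"ggp_synth"`: `characters`, `coordinates`,
#'   `tree`, `true_distances`, `zone`, `contact_pairs`, `origin`, `params`,
#'   `seed`.
#' @export
simulate_dataset <- function(L, S, n_zones = 1L, borrow_rate = 0.2,
                             seed = 1L, zone_frac = 0.6, ...) {
  tr <- simulate_tree(L, seed = seed)
  ge <- simulate_geography(L, n_zones, seed = seed + 1000L,
                           zone_frac = zone_frac,
                           language_ids = tr$language_ids)
  ch <- simulate_characters(list(distances = tr$distances,
                                 coordinates = ge$coordinates),
                            S = S, borrow_rate = borrow_rate,
                            seed = seed + 2000L, ...)
  structure(list(characters = ch$characters,
                 coordinates = ge$coordinates,
                 tree = tr$tree,
                 true_distances = tr$distances,
                 zone = ge$zone,
                 contact_pairs = ge$contact_pairs,
                 origin = ch$origin,
                 params = ch$params,
                 seed = seed),
            class = "ggp_synth")
}

#' Write a synthetic dataset to disk
#'
#' Emits the same CSV formats the readers consume (characters, coordinates,
#' loan flags derived from the true origin labels) plus a JSON truth record.
#'
#' @param synth a `"ggp_synth"`.
#' @param dir destination directory.
#' @export
write_synthetic <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_characters(synth$characters, file.path(dir, "characters.csv"))
  write.csv(as.data.frame(synth$coordinates),
            file.path(dir, "coordinates.csv"), row.names = FALSE)
  write.csv(data.frame(character = rownames(synth$characters),
                       is_loan = synth$origin == "borrowed"),
            file.path(dir, "loan_flags.csv"), row.names = FALSE)
  truth <- list(seed = synth$seed,
                params = synth$params,
                zone = synth$zone,
                contact_pairs = synth$contact_pairs,
                tree_newick = ape::write.tree(synth$tree),
                true_distances = as.vector(synth$true_distances),
                language_ids = colnames(synth$characters))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
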