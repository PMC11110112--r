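# shared fixtures and a cross-file fit cache (helpers are sourced once per
# test_dir run, so expensive fits are shared between test files)

table1_matrix <- function() {
  # the canonical 2-cognate x 4-language example shape
  character_matrix(rbind(c(1, 1, 1, 0),
                         c(0, 1, 0, 1)),
                   character_ids = c("Cognate 1", "Cognate 2"),
                   language_ids = c("A", "B", "C", "D"))
}

write_tmp <- function(lines, ext = ".csv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

sym_from_upper <- function(v, n) {
  M <- matrix(0, n, n)
  k <- 1L
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    M[i, j] <- v[k]; M[j, i] <- v[k]; k <- k + 1L
  }
  M
}

# paper-printed worked matrices
M1 <- function() sym_from_upper(c(1, 2, 1), 3)           # 3 taxa
M2 <- function() sym_from_upper(c(2, 4, 2), 3)
D1 <- function() sym_from_upper(c(1, 4, 1, 3, 4, 3), 4)  # 4 taxa
D2 <- function() sym_from_upper(c(1, 4, 1, 1, 4, 1), 4)

random_tree <- function(n, seed) {
  set.seed(seed)
  ape::rcoal(n, tip.label = paste0("t", seq_len(n)))
}

.fit_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fit_cache)) {
    assign(key, force(expr), envir = .fit_cache)
  }
  get(key, envir = .fit_cache)
}

# the shared desk-scale synthetic world + deconfounded/confounded fits used
# by several acceptance criteria (L=6, S=100, one contact zone)
acceptance_world <- function() {
  cached("world", simulate_dataset(L = 6, S = 100, n_zones = 1,
                                   borrow_rate = 0.2, seed = 101,
                                   zone_frac = 0.6))
}

acceptance_geo <- function() {
  cached("geo", scale_unit_max(great_circle_matrix(acceptance_world()$coordinates)))
}

acceptance_fit_deconf <- function() {
  cached("fit_deconf", fit_model(
    acceptance_world()$characters, geo = acceptance_geo(),
    config = model_config(chains = 2, warmup = 800, draws = 300, thin = 4,
                          seed = 7)))
}

acceptance_fit_conf <- function() {
  cached("fit_conf", fit_model(
    acceptance_world()$characters, geo = NULL,
    config = model_config(chains = 2, warmup = 800, draws = 300, thin = 4,
                          seed = 7)))
}
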