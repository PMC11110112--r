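# comparison analytics on small synthetic posteriors; fits here are tiny --
# the statistics are tested against independent recomputations, not against
# recovery quality

small_deconf_fit <- function() {
  cached("cmp_fit", {
    synth <- simulate_dataset(L = 5, S = 30, n_zones = 1, seed = 41,
                              zone_frac = 0.6)
    geo <- scale_unit_max(great_circle_matrix(synth$coordinates))
    list(synth = synth, geo = geo,
         fit = fit_model(synth$characters, geo = geo,
                         config = model_config(chains = 2, warmup = 150,
                                               draws = 60, seed = 4)))
  })
}

test_that("confound strength equals recomputation and respects geometry", {
  w <- small_deconf_fit()
  cs <- confound_strength(w$fit)
  expect_true(all(cs$strength > 0 & cs$strength <= 1))
  # oracle: recompute from the stored lambda_G draws and geo matrix
  lam <- as.vector(w$fit$draws$scalars[, , "lambda_G"])
  dg <- pack_distances(w$fit$geo)
  manual <- vapply(dg, function(dd) mean(exp(-dd^2 / lam)), numeric(1))
  key <- paste(cs$lang1, cs$lang2, sep = "|")
  expect_equal(cs$strength, unname(manual[key]), tolerance = 1e-12)
  # coincident languages would have strength exactly 1; monotone decrease
  ord <- order(dg)
  expect_equal(unname(manual[ord]), sort(unname(manual), decreasing = TRUE),
               tolerance = 1e-12)
  # confounded fits have no geographic component
  synth <- simulate_dataset(L = 4, S = 10, n_zones = 0, seed = 3)
  fc <- fit_model(synth$characters, geo = NULL,
                  config = model_config(chains = 1, warmup = 60, draws = 20,
                                        seed = 1))
  expect_error(confound_strength(fc), "no geographic component")
})

test_that("clade_delta counts match brute force and antisymmetrize", {
  set.seed(51)
  mk <- function(seed) lapply(1:10, function(i) random_tree(5, seed * 100 + i))
  a <- mk(1)
  b <- mk(2)
  cd <- clade_delta(a, b, top_k = Inf)
  # brute force on one specific clade
  count_in <- function(trees, members) {
    sum(vapply(trees, function(t) {
      sets <- lapply(glottogp:::clade_label_sets(t), sort)
      any(vapply(sets, identical, logical(1), y = sort(members)))
    }, logical(1)))
  }
  for (i in sample(nrow(cd), 5)) {
    members <- strsplit(cd$clade[i], ", ", fixed = TRUE)[[1]]
    expect_equal(cd$support_confounded[i], count_in(a, members) / 10)
    expect_equal(cd$support_deconfounded[i], count_in(b, members) / 10)
  }
  expect_equal(cd$difference,
               cd$support_deconfounded - cd$support_confounded)
  # antisymmetry under swapping inputs
  cd_sw <- clade_delta(b, a, top_k = Inf)
  key <- function(d) d$clade
  common <- intersect(key(cd), key(cd_sw))
  expect_equal(cd$difference[match(common, key(cd))],
               -cd_sw$difference[match(common, key(cd_sw))])
  # identical inputs -> no nonzero differences
  cd0 <- clade_delta(a, a)
  expect_equal(nrow(cd0), 0)
  # synthetic two-support example: 0.60 vs 0.39-ish shape
  t_cz <- ape::read.tree(text = "((Czech,Polish),Slovak,Russian);")
  t_alt <- ape::read.tree(text = "((Czech,Slovak),Polish,Russian);")
  conf <- c(rep(list(t_cz), 6), rep(list(t_alt), 4))
  deco <- c(rep(list(t_cz), 4), rep(list(t_alt), 6))
  cd2 <- clade_delta(conf, deco, top_k = 4)
  row <- cd2[cd2$clade == "Czech, Polish", ]
  expect_equal(row$support_confounded, 0.6)
  expect_equal(row$support_deconfounded, 0.4)
  expect_equal(row$difference, -0.2)
})

test_that("distance_delta normalizes per model and kills global scale", {
  w <- small_deconf_fit()
  fit <- w$fit
  # fabricate a second fit whose delta draws are exactly 2x: after
  # per-model mean normalization all differences must vanish
  fit2 <- fit
  fit2$draws$delta <- fit$draws$delta * 2
  dd <- distance_delta(fit, fit2, top_k = Inf)
  expect_true(all(abs(dd$difference) < 1e-12))
  # oracle recomputation
  fit3 <- fit
  set.seed(8)
  fit3$draws$delta <- fit$draws$delta *
    array(exp(rnorm(length(fit$draws$delta), 0, 0.2)),
          dim(fit$draws$delta))
  dd3 <- distance_delta(fit, fit3, top_k = Inf)
  mc <- apply(fit$draws$delta, 3, mean)
  md <- apply(fit3$draws$delta, 3, mean)
  manual <- md / mean(md) - mc / mean(mc)
  expect_equal(sort(dd3$difference), sort(unname(manual)), tolerance = 1e-12)
  # language-set mismatch
  fit4 <- fit
  fit4$language_ids <- rev(fit$language_ids)
  expect_error(distance_delta(fit, fit4), "different language sets")
})

test_that("top_changes layout keeps k strongest in each direction", {
  df <- data.frame(difference = c(-0.3, -0.1, 0.05, 0.2, 0.4, -0.02),
                   pair = letters[1:6])
  out <- glottogp:::top_changes(df, "difference", 4)
  expect_equal(out$difference, c(-0.3, -0.1, 0.4, 0.2))
})

test_that("character scores aggregate gamma over carriers and standardize", {
  w <- small_deconf_fit()
  sc <- character_scores(w$fit, w$synth$characters)
  expect_equal(nrow(sc), nrow(w$synth$characters))
  expect_equal(mean(sc$score), 0, tolerance = 1e-9)
  expect_equal(sd(sc$score), 1, tolerance = 1e-9)
  # oracle: recompute from archived gamma draws
  g <- w$fit$draws$gamma
  S <- length(w$fit$character_ids); L <- length(w$fit$language_ids)
  gbar <- matrix(apply(g, 3, mean), S, L)
  Cm <- unclass(w$synth$characters)
  raw <- rowSums(gbar * Cm) / rowSums(Cm)
  expect_equal(sc$score, unname((raw - mean(raw)) / sd(raw)),
               tolerance = 1e-9)
  # gamma identically zero -> all raw scores zero
  fit0 <- w$fit
  fit0$draws$gamma[] <- 0
  sc0 <- character_scores(fit0, w$synth$characters, standardize = FALSE)
  expect_true(all(sc0$score == 0))
  # confounded fit refuses
  expect_error(character_scores(
    structure(list(variant = "confounded"), class = "ggp_fit"),
    w$synth$characters), "deconfounded")
})

test_that("loan group comparison separates clearly distinct groups", {
  set.seed(71)
  scores <- data.frame(
    character = sprintf("c%02d", 1:80),
    score = c(rnorm(40, 1, 0.1), rnorm(40, -1, 0.1)))
  flags <- data.frame(character = sprintf("c%02d", 1:40), is_loan = TRUE)
  cmp <- loan_group_comparison(scores, flags, seed = 2)
  expect_true(cmp$separated)
  expect_gt(cmp$ci_difference[1], 0)
  # t-test oracle agrees on the direction and rough magnitude
  tt <- t.test(scores$score[1:40], scores$score[41:80])
  expect_equal(cmp$mean_difference, unname(diff(rev(tt$estimate))),
               tolerance = 0.1)
  # identical groups: interval spans 0
  scores2 <- scores
  scores2$score <- rep(rnorm(40), 2)
  cmp2 <- loan_group_comparison(scores2, flags, seed = 3)
  expect_false(cmp2$separated)
  # single-member group rejected
  flags1 <- data.frame(character = "c01", is_loan = TRUE)
  expect_error(loan_group_comparison(scores, flags1), "at least 2")
})
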