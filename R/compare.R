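#' Geographic confound strength per language pair
#'
#' The posterior mean of the normalized geographic covariance
#' `G[t, j] / alpha_G = exp(-delta_G[t, j]^2 / lambda_G)`, a number in
#' (0, 1] per language pair: 1 for coincident languages, decaying with
#' distance at a rate set by the posterior of `lambda_G`.  High values mean
#' a large share of the observed similarity of the pair is attributed to
#' geography rather than descent.
#'
#' @param fit a deconfounded `"ggp_fit"`.
#' @return data.frame with columns `lang1`, `lang2`, `strength`, sorted by
#'   decreasing strength.
#' @export
confound_strength <- function(fit) {
  if (fit$variant != "deconfounded") {
    stop("no geographic component in a confounded fit")
  }
  if (is.null(fit$geo)) stop("fit carries no geographic distance matrix")
  lam <- as.vector(fit$draws$scalars[, , "lambda_G"])
  dg <- pack_distances(fit$geo)
  strength <- vapply(dg, function(dd) mean(exp(-dd^2 / lam)), numeric(1))
  pairs <- strsplit(names(dg), "|", fixed = TRUE)
  out <- data.frame(lang1 = vapply(pairs, `[`, character(1), 1),
                    lang2 = vapply(pairs, `[`, character(1), 2),
                    strength = unname(strength),
                    stringsAsFactors = FALSE)
  out[order(-out$strength), , drop = FALSE]
}

# shared helper: keep the k strongest changes in each direction, negatives
# first (most negative on top), then positives (largest on top) -- the
# layout used for reporting clade-support and distance changes
top_changes <- function(df, col, top_k) {
  k_each <- ceiling(top_k / 2)
  v <- df[[col]]
  neg <- df[v < 0, , drop = FALSE]
  pos <- df[v > 0, , drop = FALSE]
  neg <- neg[order(neg[[col]]), , drop = FALSE]
  pos <- pos[order(-pos[[col]]), , drop = FALSE]
  out <- rbind(head(neg, k_each), head(pos, k_each))
  rownames(out) <- NULL
  out
}

#' Clade-support change between confounded and deconfounded posteriors
#'
#' For every clade appearing in either tree sample, the support under each
#' model and the difference (deconfounded minus confounded; a clade absent
#' from a sample has support 0 there).  A negative difference means the
#' geographic control reinterprets part of that clade's cohesion as
#' contact-induced.
#'
#' @param conf,deconf lists of `"phylo"` trees (posterior UPGMA samples of
#'   the confounded and deconfounded model) on the same leaf set.
#' @param top_k total rows returned: the `top_k/2` strongest decreases plus
#'   the `top_k/2` strongest increases (default 10); `Inf` returns all.
#' @return data.frame with columns `support_confounded`,
#'   `support_deconfounded`, `difference`, `clade`.
#' @export
clade_delta <- function(conf, deconf, top_k = 10L) {
  check_same_leaves(c(conf, deconf))
  cc <- clade_counts(conf) / length(conf)
  cd <- clade_counts(deconf) / length(deconf)
  keys <- union(names(cc), names(cd))
  s_c <- unname(ifelse(keys %in% names(cc), cc[keys], 0))
  s_d <- unname(ifelse(keys %in% names(cd), cd[keys], 0))
  df <- data.frame(
    support_confounded = s_c,
    support_deconfounded = s_d,
    difference = s_d - s_c,
    clade = vapply(strsplit(keys, SEP, fixed = TRUE), paste, character(1),
                   collapse = ", "),
    stringsAsFactors = FALSE)
  df <- df[abs(df$difference) > 0 | is.infinite(top_k), , drop = FALSE]
  if (is.infinite(top_k)) {
    df <- df[order(-abs(df$difference)), , drop = FALSE]
    rownames(df) <- NULL
    return(df)
  }
  top_changes(df, "difference", top_k)
}

#' Normalized pairwise-distance change between model variants
#'
#' Posterior-mean latent distances of each model are first divided by their
#' own mean -- the global distance scale is not identified (chains and
#' models can settle on proportional matrices), so only relative distances
#' are comparable -- and the difference (deconfounded minus confounded) is
#' reported per language pair.
#'
#' @param conf,deconf `"ggp_fit"` objects on the same language set.
#' @param top_k as in [clade_delta()]; `Inf` returns all pairs.
#' @return data.frame with columns `difference` and `pair`.
#' @export
distance_delta <- function(conf, deconf, top_k = 10L) {
  if (!identical(conf$language_ids, deconf$language_ids)) {
    stop("fits cover different language sets")
  }
  mc <- posterior_mean_delta(conf)
  md <- posterior_mean_delta(deconf)
  mc <- mc / mean(mc)
  md <- md / mean(md)
  df <- data.frame(difference = unname(md - mc),
                   pair = gsub("|", ", ", names(mc), fixed = TRUE),
                   stringsAsFactors = FALSE)
  if (is.infinite(top_k)) {
    df <- df[order(-abs(df$difference)), , drop = FALSE]
    rownames(df) <- NULL
    return(df)
  }
  top_changes(df, "difference", top_k)
}

#' Per-character geographic conditioning score
#'
#' For each character, the posterior mean of its geographic effect `gamma`
#' averaged over the languages that carry the character (cells with value
#' 1), standardized to z-scores across characters.  A high score marks a
#' character whose presence pattern the model attributes to geography --
#' i.e. a borrowing candidate.  The aggregation set is a modelling choice:
#' `aggregate = "all"` averages gamma over every language instead.
#'
#' @param fit a deconfounded `"ggp_fit"`.
#' @param C the [character_matrix()] the model was fitted to.
#' @param aggregate `"carriers"` (default) or `"all"`.
#' @param standardize z-score across characters (default `TRUE`).
#' @return data.frame with columns `character`, `score`.
#' @export
character_scores <- function(fit, C, aggregate = c("carriers", "all"),
                             standardize = TRUE) {
  aggregate <- match.arg(aggregate)
  if (fit$variant != "deconfounded") {
    stop("character scores require the geographic component (deconfounded fit)")
  }
  if (!identical(rownames(C), fit$character_ids) ||
      !identical(colnames(C), fit$language_ids)) {
    stop("character matrix does not match the fitted model")
  }
  g <- fit$draws$gamma        # iter x chains x (S*L), column-major in (s, l)
  S <- length(fit$character_ids)
  L <- length(fit$language_ids)
  gbar <- matrix(apply(g, 3, mean), S, L)   # posterior mean gamma, S x L
  W <- if (aggregate == "carriers") unclass(C) else matrix(1L, S, L)
  storage.mode(W) <- "double"
  if (any(rowSums(W) == 0)) stop("character with no carrier languages")
  score <- rowSums(gbar * W) / rowSums(W)
  if (standardize) score <- (score - mean(score)) / sd(score)
  data.frame(character = fit$character_ids, score = unname(score),
             stringsAsFactors = FALSE)
}

#' Two-group Bayesian comparison of character scores
#'
#' Compares mean geographic conditioning scores between flagged loanwords
#' and the rest under a two-group normal model: standard normal priors on
#' both group means, a weakly-informative half-Student-t(3, 0, 2.5) prior on
#' the shared residual scale, Gibbs updates for the means and a
#' random-walk update for the log scale.
#'
#' @param scores a [character_scores()] table.
#' @param flags a loan-flag table (columns `character`, `is_loan`); flags
#'   must reference characters present in `scores`, and each group needs at
#'   least 2 members.  Characters without a flag are treated as `is_loan =
#'   FALSE`.
#' @param iter,warmup MCMC iterations (default 4000/1000).
#' @param seed RNG seed.
#' @return list of class `"ggp_groupcmp"`: per-group posterior mean and 95%
#'   credible interval, the loan-minus-other difference interval, and
#'   `separated` (does the difference interval exclude 0).
#' @export
loan_group_comparison <- function(scores, flags, iter = 4000L,
                                  warmup = 1000L, seed = 1L) {
  if (!all(flags$character %in% scores$character)) {
    stop("flags reference characters absent from the score table")
  }
  is_loan <- scores$character %in% flags$character[flags$is_loan]
  y1 <- scores$score[is_loan]       # loans
  y0 <- scores$score[!is_loan]
  if (length(y1) < 2 || length(y0) < 2) {
    stop("each group needs at least 2 characters")
  }
  set.seed(seed)
  mu1 <- mean(y1); mu0 <- mean(y0); sig <- sd(c(y1 - mu1, y0 - mu0))
  n1 <- length(y1); n0 <- length(y0)
  s1 <- sum(y1); s0 <- sum(y0)
  lsig_step <- 0.3
  keep <- matrix(NA_real_, iter - warmup, 3,
                 dimnames = list(NULL, c("mu_loan", "mu_other", "sigma")))
  log_post_sig <- function(lsig, mu1, mu0) {
    s <- exp(lsig)
    -(n1 + n0) * lsig -
      (sum((y1 - mu1)^2) + sum((y0 - mu0)^2)) / (2 * s^2) +
      stats::dt(s / 2.5, df = 3, log = TRUE) + lsig   # half-t(3,0,2.5) + Jacobian
  }
  lsig <- log(sig)
  for (it in seq_len(iter)) {
    prec1 <- n1 / exp(2 * lsig) + 1    # N(0,1) prior precision
    mu1 <- rnorm(1, (s1 / exp(2 * lsig)) / prec1, sqrt(1 / prec1))
    prec0 <- n0 / exp(2 * lsig) + 1
    mu0 <- rnorm(1, (s0 / exp(2 * lsig)) / prec0, sqrt(1 / prec0))
    prop <- lsig + rnorm(1, 0, lsig_step)
    if (log(runif(1)) < log_post_sig(prop, mu1, mu0) -
        log_post_sig(lsig, mu1, mu0)) {
      lsig <- prop
    }
    if (it > warmup) keep[it - warmup, ] <- c(mu1, mu0, exp(lsig))
  }
  ci <- function(v) unname(quantile(v, c(0.025, 0.975)))
  dd <- keep[, 1] - keep[, 2]
  structure(list(
    n_loan = n1, n_other = n0,
    mean_loan = mean(keep[, 1]), ci_loan = ci(keep[, 1]),
    mean_other = mean(keep[, 2]), ci_other = ci(keep[, 2]),
    mean_difference = mean(dd), ci_difference = ci(dd),
    separated = prod(ci(dd)) > 0,
    draws = keep), class = "ggp_groupcmp")
}

#' @export
print.ggp_groupcmp <- function(x, ...) {
  cat("<two-group score comparison>\n")
  cat(sprintf("  loans   (n=%d): mean %.3f, 95%% CI [%.3f, %.3f]\n",
              x$n_loan, x$mean_loan, x$ci_loan[1], x$ci_loan[2]))
  cat(sprintf("  others  (n=%d): mean %.3f, 95%% CI [%.3f, %.3f]\n",
              x$n_other, x$mean_other, x$ci_other[1], x$ci_other[2]))
  cat(sprintf("  difference: %.3f [%.3f, %.3f] -- %s\n",
              x$mean_difference, x$ci_difference[1], x$ci_difference[2],
              if (x$separated) "interval excludes 0"
              else "interval spans 0"))
  invisible(x)
}
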