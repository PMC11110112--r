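#' Sampler configuration
#'
#' @param chains number of MCMC chains (default 4, mirroring a four-chain
#'   analysis setup; desk-scale tests use 2).
#' @param warmup,draws warmup iterations and retained draws per chain.
#' @param seed integer seed controlling initialization and sampling.
#' @param target_accept dual-averaging target acceptance (default 0.95; the
#'   positive-definiteness boundary of the latent-distance kernel rewards
#'   conservative step sizes).
#' @param thin keep every `thin`-th iteration: `draws * thin` iterations are
#'   run and `draws` retained.
#' @param jitter diagonal jitter added to both kernel matrices before
#'   factorization.
#' @param max_leapfrog maximum leapfrog steps per trajectory (lengths are
#'   jittered over the upper half of this range).
#' @param fix named list of pinned values (test harness): `alpha_G` and/or
#'   `lambda_G` are then constants, not sampled.
#' @return list of class `"model_config"`.
#' @export
model_config <- function(chains = 4L, warmup = 500L, draws = 500L, seed = 1L,
                         target_accept = 0.95, jitter = 1e-6,
                         max_leapfrog = 48L, thin = 1L, fix = list()) {
  stopifnot(chains >= 1, warmup >= 10, draws >= 1, thin >= 1,
            target_accept > 0, target_accept < 1)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 draws = as.integer(draws), seed = as.integer(seed),
                 target_accept = target_accept, jitter = jitter,
                 max_leapfrog = as.integer(max_leapfrog),
                 thin = as.integer(thin), fix = fix),
            class = "model_config")
}

#' Fit the latent-distance GP phylogenetic model
#'
#' Samples the joint posterior over latent pairwise phylogenetic distances
#' (Exponential(1) priors), kernel amplitudes (Exponential(2)), the
#' geographic length-scale (Exponential(2), deconfounded variant only), and
#' per-character GP effect rows, under a Bernoulli-logit observation model.
#' Sampling uses adaptive Hamiltonian Monte Carlo with a non-centered
#' parameterization of the GP rows and log-transformed positive parameters.
#'
#' Supplying `geo` selects the *deconfounded* variant (with the geographic
#' effect `gamma`); omitting it selects the *confounded* variant (pure
#' phylogeny).
#'
#' @param C a [character_matrix()].
#' @param geo a `"geo_dist"` object (will be scaled to unit maximum if it
#'   is not already), or `NULL` for the confounded variant.
#' @param config a [model_config()].
#' @return object of class `"ggp_fit"`; see [posterior_mean_delta()],
#'   [posterior_trees()], [convergence_summary()].
#' @export
fit_model <- function(C, geo = NULL, config = model_config()) {
  stopifnot(inherits(C, "char_matrix"))
  L <- ncol(C)
  if (L < 3) stop("need at least 3 languages")
  variant <- if (is.null(geo)) "confounded" else "deconfounded"
  geoD <- NULL
  if (!is.null(geo)) {
    if (inherits(geo, "geo_dist")) {
      if (!setequal(geo$language_ids, colnames(C))) {
        stop("geographic distances cover a different language set")
      }
      geo$values <- geo$values[colnames(C), colnames(C)]
      mx <- max(geo$values[upper.tri(geo$values)])
      if (mx > 0 && abs(mx - 1) > 1e-9) geo <- scale_unit_max(geo)
      geoD <- geo$values
    } else {
      geoD <- as.matrix(geo)
    }
  }
  lpobj <- make_logpost(C, geo = geoD, jitter = config$jitter,
                        fix = config$fix)
  S <- nrow(C)
  m <- lpobj$m
  chains <- config$chains
  iter <- config$draws
  langs <- colnames(C)
  pnames <- pair_names(langs)

  delta <- array(NA_real_, c(iter, chains, m),
                 dimnames = list(NULL, NULL, pnames))
  sc_names <- c("alpha_P",
                if (variant == "deconfounded") c("alpha_G", "lambda_G"))
  scalars <- array(NA_real_, c(iter, chains, length(sc_names)),
                   dimnames = list(NULL, NULL, sc_names))
  eff_names <- as.vector(outer(rownames(C), langs, paste, sep = "@"))
  rho <- array(NA_real_, c(iter, chains, S * L),
               dimnames = list(NULL, NULL, eff_names))
  gamma <- if (variant == "deconfounded") {
    array(NA_real_, c(iter, chains, S * L),
          dimnames = list(NULL, NULL, eff_names))
  } else NULL
  lp <- matrix(NA_real_, iter, chains)
  divergences <- integer(chains)
  step_sizes <- accept <- numeric(chains)

  # chains start from jittered normalized Hamming distances between
  # languages: an empirical tree-metric-like state inside the PSD region,
  # close to the data mode (pure-prior inits frequently start on the wrong
  # side of the positive-definiteness boundary)
  Cm <- unclass(C)
  ham <- as.matrix(dist(t(Cm), method = "manhattan")) / nrow(Cm)
  dh <- pack_distances(ham)
  dh <- dh / mean(dh)

  n_iter <- iter * config$thin
  run_chain <- function(seed, target) {
    set.seed(seed)
    theta0 <- lpobj$init(delta_init = dh)
    gp_gibbs_chain(lpobj, theta0, iter = n_iter,
                   warmup = config$warmup,
                   target_accept = target,
                   max_leapfrog = config$max_leapfrog)
  }
  for (ch in seq_len(chains)) {
    res <- run_chain(config$seed + (ch - 1L), config$target_accept)
    if (res$divergences > 0.1 * n_iter) {
      # failed adaptation for this chain: retry once, more conservatively
      res2 <- run_chain(config$seed + (ch - 1L) + 797L,
                        min(0.99, config$target_accept + 0.04))
      if (res2$divergences < res$divergences) res <- res2
    }
    keep_idx <- seq.int(config$thin, n_iter, by = config$thin)
    divergences[ch] <- res$divergences
    step_sizes[ch] <- res$step_size
    accept[ch] <- res$accept_rate
    lp[, ch] <- res$lp[keep_idx]
    for (it in seq_len(iter)) {
      mat <- materialize_effects(lpobj, res$draws[keep_idx[it], ], geo = geoD)
      delta[it, ch, ] <- mat$delta
      scalars[it, ch, "alpha_P"] <- mat$alpha_P
      if (variant == "deconfounded") {
        scalars[it, ch, "alpha_G"] <- mat$alpha_G
        scalars[it, ch, "lambda_G"] <- mat$lambda_G
        gamma[it, ch, ] <- mat$gamma
      }
      rho[it, ch, ] <- mat$rho
    }
  }

  rhat <- c(
    vapply(seq_along(sc_names), function(k) split_rhat(scalars[, , k]),
           numeric(1)),
    vapply(seq_len(m), function(k) split_rhat(delta[, , k]), numeric(1)))
  names(rhat) <- c(sc_names, paste0("delta[", pnames, "]"))
  ess <- c(
    vapply(seq_along(sc_names), function(k) ess_basic(scalars[, , k]),
           numeric(1)),
    vapply(seq_len(m), function(k) ess_basic(delta[, , k]), numeric(1)))
  names(ess) <- names(rhat)

  structure(list(
    variant = variant,
    language_ids = langs,
    character_ids = rownames(C),
    chains = chains, draws_per_chain = iter, warmup = config$warmup,
    seed = config$seed, config = config,
    geo = geoD,
    draws = list(delta = delta, scalars = scalars, rho = rho, gamma = gamma),
    lp = lp,
    diagnostics = list(divergences = divergences, rhat = rhat, ess = ess,
                       accept_rate = accept, step_size = step_sizes)),
    class = "ggp_fit")
}

#' @export
print.ggp_fit <- function(x, ...) {
  cat(sprintf("<ggp_fit> %s model: %d languages, %d characters\n",
              x$variant, length(x$language_ids), length(x$character_ids)))
  cat(sprintf("  %d chain(s) x %d draws (warmup %d), seed %d\n",
              x$chains, x$draws_per_chain, x$warmup, x$seed))
  cat(sprintf("  divergences: %s; mean accept: %.2f\n",
              paste(x$diagnostics$divergences, collapse = "/"),
              mean(x$diagnostics$accept_rate)))
  invisible(x)
}

#' Posterior mean latent distances
#'
#' @param fit a `"ggp_fit"`.
#' @return named vector of length L(L-1)/2 (row-major upper triangle).
#' @export
posterior_mean_delta <- function(fit) {
  apply(fit$draws$delta, 3, mean)
}

#' Extract latent-distance draws as a flat matrix
#'
#' @param fit a `"ggp_fit"`.
#' @return matrix (chains*draws) x npairs.
#' @export
delta_draws <- function(fit) {
  d <- fit$draws$delta
  out <- do.call(rbind, lapply(seq_len(dim(d)[2]), function(ch) d[, ch, ]))
  colnames(out) <- dimnames(d)[[3]]
  out
}

#' Write a posterior archive
#'
#' A directory holding a JSON manifest (draw/chain counts, seed, variant,
#' parameter layout, language and character ids, scaled geographic distance
#' matrix) plus per-chain columnar CSV files for the scalar kernel
#' parameters, latent distances, and GP effect matrices.
#'
#' @param fit a `"ggp_fit"`.
#' @param dir destination directory (created if missing).
#' @export
write_archive <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    format = "glottogp-archive-v1",
    variant = fit$variant,
    chains = fit$chains,
    draws_per_chain = fit$draws_per_chain,
    warmup = fit$warmup,
    seed = fit$seed,
    language_ids = fit$language_ids,
    character_ids = fit$character_ids,
    scalar_params = dimnames(fit$draws$scalars)[[3]],
    pair_ids = dimnames(fit$draws$delta)[[3]],
    geo = if (!is.null(fit$geo)) as.vector(fit$geo) else NULL,
    diagnostics = list(divergences = fit$diagnostics$divergences,
                       accept_rate = fit$diagnostics$accept_rate,
                       step_size = fit$diagnostics$step_size))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (ch in seq_len(fit$chains)) {
    pre <- file.path(dir, sprintf("chain%d_", ch))
    sc <- as.data.frame(fit$draws$scalars[, ch, , drop = TRUE])
    if (ncol(fit$draws$scalars) == 1) names(sc) <- dimnames(fit$draws$scalars)[[3]]
    sc$lp <- fit$lp[, ch]
    data.table::fwrite(sc, paste0(pre, "scalars.csv"))
    dl <- as.data.frame(fit$draws$delta[, ch, ])
    names(dl) <- dimnames(fit$draws$delta)[[3]]
    data.table::fwrite(dl, paste0(pre, "delta.csv"))
    rh <- as.data.frame(fit$draws$rho[, ch, ])
    names(rh) <- dimnames(fit$draws$rho)[[3]]
    data.table::fwrite(rh, paste0(pre, "rho.csv"))
    if (!is.null(fit$draws$gamma)) {
      gm <- as.data.frame(fit$draws$gamma[, ch, ])
      names(gm) <- dimnames(fit$draws$gamma)[[3]]
      data.table::fwrite(gm, paste0(pre, "gamma.csv"))
    }
  }
  invisible(dir)
}

#' Read a posterior archive written by [write_archive()]
#'
#' @param dir archive directory.
#' @return a `"ggp_fit"` (diagnostics restricted to what the manifest
#'   records; R-hat/ESS are recomputed).
#' @export
read_archive <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", dir)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  if (!identical(mf$format, "glottogp-archive-v1")) {
    stop("unrecognized archive format")
  }
  chains <- mf$chains
  iter <- mf$draws_per_chain
  langs <- mf$language_ids
  L <- length(langs)
  S <- length(mf$character_ids)
  m <- length(mf$pair_ids)
  sc_names <- mf$scalar_params
  delta <- array(NA_real_, c(iter, chains, m),
                 dimnames = list(NULL, NULL, mf$pair_ids))
  scalars <- array(NA_real_, c(iter, chains, length(sc_names)),
                   dimnames = list(NULL, NULL, sc_names))
  eff_names <- as.vector(outer(mf$character_ids, langs, paste, sep = "@"))
  rho <- array(NA_real_, c(iter, chains, S * L),
               dimnames = list(NULL, NULL, eff_names))
  gamma <- if (mf$variant == "deconfounded") {
    array(NA_real_, c(iter, chains, S * L),
          dimnames = list(NULL, NULL, eff_names))
  } else NULL
  lp <- matrix(NA_real_, iter, chains)
  for (ch in seq_len(chains)) {
    pre <- file.path(dir, sprintf("chain%d_", ch))
    sc <- data.table::fread(paste0(pre, "scalars.csv"), data.table = FALSE)
    lp[, ch] <- sc$lp
    for (nm in sc_names) scalars[, ch, nm] <- sc[[nm]]
    delta[, ch, ] <- as.matrix(
      data.table::fread(paste0(pre, "delta.csv"), data.table = FALSE))
    rho[, ch, ] <- as.matrix(
      data.table::fread(paste0(pre, "rho.csv"), data.table = FALSE))
    if (!is.null(gamma)) {
      gamma[, ch, ] <- as.matrix(
        data.table::fread(paste0(pre, "gamma.csv"), data.table = FALSE))
    }
  }
  geoD <- NULL
  if (!is.null(mf$geo) && length(mf$geo)) {
    geoD <- matrix(mf$geo, L, L, dimnames = list(langs, langs))
  }
  rhat <- c(
    vapply(seq_along(sc_names), function(k) split_rhat(scalars[, , k]),
           numeric(1)),
    vapply(seq_len(m), function(k) split_rhat(delta[, , k]), numeric(1)))
  names(rhat) <- c(sc_names, paste0("delta[", mf$pair_ids, "]"))
  structure(list(
    variant = mf$variant,
    language_ids = langs,
    character_ids = mf$character_ids,
    chains = chains, draws_per_chain = iter, warmup = mf$warmup,
    seed = mf$seed, config = NULL,
    geo = geoD,
    draws = list(delta = delta, scalars = scalars, rho = rho, gamma = gamma),
    lp = lp,
    diagnostics = list(divergences = mf$diagnostics$divergences,
                       rhat = rhat, ess = NULL,
                       accept_rate = mf$diagnostics$accept_rate,
                       step_size = mf$diagnostics$step_size)),
    class = "ggp_fit")
}
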