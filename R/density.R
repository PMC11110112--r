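#' Bernoulli-logit log-likelihood of a character matrix
#'
#' Each cell is Bernoulli with success probability
#' `p = plogis(rho + gamma)`: the log-odds of language `l` showing character
#' `s` is the sum of a phylogenetic effect `rho[s, l]` and (in the
#' deconfounded variant) a geographic effect `gamma[s, l]`.  Evaluated with
#' log1p-exp stabilization so saturated logits stay finite.
#'
#' @param C a [character_matrix()] (or 0/1 matrix), S x L.
#' @param effects list with `rho` (S x L) and optionally `gamma` (S x L or
#'   `NULL` for the confounded variant).
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(C, effects) {
  rho <- effects$rho
  gamma <- effects$gamma
  if (!all(dim(C) == dim(rho))) stop("shape mismatch between C and rho")
  eta <- if (is.null(gamma)) rho else {
    if (!all(dim(gamma) == dim(C))) stop("shape mismatch between C and gamma")
    rho + gamma
  }
  # log(1 + exp(eta)) = max(eta, 0) + log1p(exp(-|eta|))
  sum(unclass(C) * eta) - sum(pmax(eta, 0) + log1p(exp(-abs(eta))))
}

# log density of iid zero-mean MVN rows of X given upper Cholesky R of cov
dmvn_rows <- function(X, R) {
  n <- ncol(X)
  V <- forwardsolve(t(R), t(X))          # R^-T x per column
  -0.5 * nrow(X) * (n * log(2 * pi) + 2 * sum(log(diag(R)))) -
    0.5 * sum(V^2)
}

#' Joint log-prior of the latent-distance GP model
#'
#' Exponential(1) on each latent pairwise distance, Exponential(2) on
#' `alpha_P` (and on `alpha_G`, `lambda_G` when the geographic component is
#' present), and independent zero-mean multivariate normal rows for the GP
#' effect matrices: each character's `rho` row is one draw from
#' `MVN(0, P)` and each `gamma` row one draw from `MVN(0, G)`.
#'
#' @param params a [kernel_params()], or a list with at least `alpha_P` for
#'   the confounded variant.
#' @param distances vector of latent pairwise distances (length L(L-1)/2).
#' @param effects list with `rho` and optionally `gamma`.
#' @param G,P `"cov_matrix"` objects from [ensure_psd()] (G may be `NULL`
#'   for the confounded variant).
#' @return scalar log-prior; `-Inf` outside the support.
#' @export
log_prior <- function(params, distances, effects, G = NULL, P) {
  if (any(distances < 0) || params$alpha_P <= 0) return(-Inf)
  lp <- sum(dexp(distances, rate = 1, log = TRUE)) +
    dexp(params$alpha_P, rate = 2, log = TRUE)
  chol_of <- function(cm) {
    ch <- attr(cm, "chol")
    if (is.null(ch)) {
      ch <- tryCatch(chol(cm$values), error = function(e) {
        stop("covariance is not positive definite; run ensure_psd() first")
      })
    }
    ch
  }
  lp <- lp + dmvn_rows(effects$rho, chol_of(P))
  if (!is.null(effects$gamma)) {
    if (is.null(G)) stop("gamma supplied without G")
    if (params$alpha_G <= 0 || params$lambda_G <= 0) return(-Inf)
    lp <- lp + dexp(params$alpha_G, rate = 2, log = TRUE) +
      dexp(params$lambda_G, rate = 2, log = TRUE) +
      dmvn_rows(effects$gamma, chol_of(G))
  }
  lp
}

# lower-triangle projection with halved diagonal, used in the Cholesky
# reverse-mode rule
.phi_tril <- function(A) {
  A[upper.tri(A)] <- 0
  diag(A) <- diag(A) / 2
  A
}

# Reverse-mode through K = L L^T given gradient Fb w.r.t. the lower factor:
# Kbar = R^-1 Phi(L^T tril(Fb)) R^-T, symmetrized.  R is the upper Cholesky.
.chol_backward <- function(R, Fb) {
  Lmat <- t(R)
  Fb[upper.tri(Fb)] <- 0
  tmp <- .phi_tril(crossprod(Lmat, Fb))
  A <- backsolve(R, tmp)
  Kb <- t(backsolve(R, t(A)))
  (Kb + t(Kb)) / 2
}

# Build the internal unnormalized log-posterior (and its gradient) over the
# unconstrained parameter vector used by the sampler.
#
# Layout (deconfounded): [u (m), aP, aG, lg, z_rho (S*L), z_gamma (S*L)]
#         (confounded):  [u (m), aP, z_rho (S*L)]
# with delta = exp(u), alpha = exp(a), lambda_G = exp(lg); GP rows are
# non-centered: rho = Z_rho %*% chol(P), gamma = Z_gamma %*% chol(G).
# Entries of `fix` (alpha_G, lambda_G) are pinned constants removed from the
# parameter vector (test-harness use).
make_logpost <- function(C, geo = NULL, lambda_P = 3, jitter = 1e-8,
                         fix = list()) {
  C <- unclass(C)
  storage.mode(C) <- "double"
  S <- nrow(C)
  L <- ncol(C)
  m <- L * (L - 1L) / 2L
  deconf <- !is.null(geo)
  iu <- ju <- integer(m)
  k <- 1L
  for (i in seq_len(L - 1L)) for (j in seq.int(i + 1L, L)) {
    iu[k] <- i; ju[k] <- j; k <- k + 1L
  }
  up_idx <- cbind(iu, ju)
  lo_idx <- cbind(ju, iu)
  if (deconf) {
    geoD <- if (inherits(geo, "geo_dist")) geo$values else geo
    D2G <- geoD^2
  }
  fix_aG <- "alpha_G" %in% names(fix)
  fix_lG <- "lambda_G" %in% names(fix)
  # index bookkeeping
  i_u <- seq_len(m)
  i_aP <- m + 1L
  pos <- m + 1L
  i_aG <- i_lg <- NA_integer_
  if (deconf && !fix_aG) { pos <- pos + 1L; i_aG <- pos }
  if (deconf && !fix_lG) { pos <- pos + 1L; i_lg <- pos }
  i_zr <- pos + seq_len(S * L)
  pos <- pos + S * L
  i_zg <- if (deconf) pos + seq_len(S * L) else integer(0)
  n_par <- pos + if (deconf) S * L else 0L
  lconst_z <- -0.5 * log(2 * pi)

  unpack <- function(theta) {
    delta <- exp(theta[i_u])
    alpha_P <- exp(theta[i_aP])
    alpha_G <- if (!deconf) NULL else if (fix_aG) fix$alpha_G else exp(theta[i_aG])
    lambda_G <- if (!deconf) NULL else if (fix_lG) fix$lambda_G else exp(theta[i_lg])
    zr <- matrix(theta[i_zr], S, L)
    zg <- if (deconf) matrix(theta[i_zg], S, L) else NULL
    list(delta = delta, alpha_P = alpha_P, alpha_G = alpha_G,
         lambda_G = lambda_G, zr = zr, zg = zg)
  }

  lp_grad <- function(theta) {
    pr <- unpack(theta)
    delta <- pr$delta
    alpha_P <- pr$alpha_P
    Dm <- matrix(0, L, L)
    Dm[up_idx] <- delta
    Dm[lo_idx] <- delta
    # jitter is multiplicative (P = alpha_P * (P0 + jitter I)) so that the
    # amplitude/coefficient rescaling used by the interweaved scale move is
    # an exact likelihood invariance
    P0 <- exp(-Dm / lambda_P)
    diag(P0) <- 1 + jitter
    RP <- tryCatch(chol(alpha_P * P0), error = function(e) NULL)
    if (is.null(RP)) return(list(lp = -Inf, grad = numeric(n_par)))
    rho <- pr$zr %*% RP
    if (deconf) {
      G0 <- exp(-D2G / pr$lambda_G)
      diag(G0) <- 1 + jitter
      Gm <- pr$alpha_G * G0
      RG <- tryCatch(chol(Gm), error = function(e) NULL)
      if (is.null(RG)) return(list(lp = -Inf, grad = numeric(n_par)))
      gamma <- pr$zg %*% RG
      eta <- rho + gamma
    } else {
      eta <- rho
    }
    lse <- pmax(eta, 0) + log1p(exp(-abs(eta)))
    loglik <- sum(C * eta) - sum(lse)
    E <- C - plogis(eta)
    grad <- numeric(n_par)
    # z gradients (likelihood + standard-normal prior)
    grad[i_zr] <- E %*% t(RP) - pr$zr
    # kernel-side gradients via Cholesky reverse mode
    KbP <- .chol_backward(RP, crossprod(E, pr$zr))
    pu <- P0[up_idx]
    grad[i_u] <- -2 * KbP[up_idx] * alpha_P * pu / lambda_P * delta +
      (-delta + 1)                                   # Exp(1) prior + Jacobian
    grad[i_aP] <- alpha_P * sum(KbP * P0) + (-2 * alpha_P + 1)
    lp <- loglik +
      sum(-delta + theta[i_u]) +
      (log(2) - 2 * alpha_P + theta[i_aP]) +
      sum(-0.5 * pr$zr^2 + lconst_z)
    if (deconf) {
      grad[i_zg] <- E %*% t(RG) - pr$zg
      KbG <- .chol_backward(RG, crossprod(E, pr$zg))
      if (!fix_aG) {
        grad[i_aG] <- pr$alpha_G * sum(KbG * G0) + (-2 * pr$alpha_G + 1)
        lp <- lp + log(2) - 2 * pr$alpha_G + theta[i_aG]
      }
      if (!fix_lG) {
        grad[i_lg] <- sum(KbG * Gm * D2G) / pr$lambda_G + (-2 * pr$lambda_G + 1)
        lp <- lp + log(2) - 2 * pr$lambda_G + theta[i_lg]
      }
      lp <- lp + sum(-0.5 * pr$zg^2 + lconst_z)
    }
    if (!is.finite(lp)) return(list(lp = -Inf, grad = numeric(n_par)))
    list(lp = lp, grad = grad)
  }

  init <- function(delta_init = NULL) {
    theta <- numeric(n_par)
    # Distances: near-equal by default (compound-symmetric, hence PD, OU
    # kernel; arbitrary iid distances need not embed in Euclidean space and
    # can make the kernel indefinite -- such states are rejected as
    # divergent).  Callers can pass an empirical distance vector (e.g.
    # normalized Hamming distances) to start chains near the data mode.
    theta[i_u] <- if (is.null(delta_init)) rnorm(m, 0, 0.05) else
      log(pmax(delta_init, 0.05)) + rnorm(m, 0, 0.05)
    theta[i_aP] <- rnorm(1, log(0.7), 0.1)
    if (deconf && !fix_aG) theta[i_aG] <- rnorm(1, log(0.5), 0.2)
    if (deconf && !fix_lG) theta[i_lg] <- rnorm(1, log(0.5), 0.2)
    # GP field initialized at data-informed logits (+-1 for presence /
    # absence, jittered): starting with rho ~ 0 puts warmup inside the
    # no-signal basin (alpha -> 0, z decoupled), which is sticky for any
    # sampler in this family
    pr0 <- unpack(theta)
    Dm0 <- matrix(0, L, L)
    Dm0[up_idx] <- pr0$delta
    Dm0[lo_idx] <- pr0$delta
    P00 <- exp(-Dm0 / lambda_P)
    diag(P00) <- 1 + jitter
    RP0 <- chol(pr0$alpha_P * P00)
    rho0 <- (2 * C - 1) * (0.8 + matrix(runif(S * L, 0, 0.4), S, L))
    theta[i_zr] <- as.vector(t(backsolve(RP0, t(rho0), transpose = TRUE)))
    if (deconf) theta[i_zg] <- rnorm(S * L, 0, 0.1)
    theta
  }

  # Interweaved scale move (ancillarity-sufficiency interweaving): the map
  # alpha -> alpha e^t, z -> z e^(-t/2) leaves rho (hence the likelihood)
  # exactly invariant, so a cheap Metropolis step along this direction breaks
  # the amplitude-coefficient funnel that cripples plain HMC here.  Accept
  # ratio involves only the Exponential(2) prior on alpha, the standard
  # normal prior on z, the log-scale Jacobian of alpha (+t) and the z-block
  # Jacobian (-n t / 2).
  scale_move <- function(theta, sd_t = 0.3, reps = 3L) {
    n <- S * L
    do_block <- function(i_a, i_z, fixed) {
      if (fixed) return()
      for (r in seq_len(reps)) {
        t <- rnorm(1, 0, sd_t)
        a <- exp(theta[i_a])
        zz <- sum(theta[i_z]^2)
        logr <- (-0.5 * zz * exp(-t) - 2 * a * exp(t) + t) -
          (-0.5 * zz - 2 * a) - n * t / 2
        if (log(runif(1)) < logr) {
          theta[i_a] <<- theta[i_a] + t
          theta[i_z] <<- theta[i_z] * exp(-t / 2)
        }
      }
    }
    do_block(i_aP, i_zr, fixed = FALSE)
    if (deconf) do_block(i_aG, i_zg, fixed = fix_aG)
    theta
  }

  # Centered-parameterization kernel update (the other half of the
  # interweaving scheme): holding the realized GP field rho = z %*% chol(P)
  # fixed, the conditional density of (log delta, log alpha_P) is
  #   sum_s log MVN(rho_s; 0, P) + priors (+ Jacobians),
  # i.e. S iid multivariate-normal rows inform the kernel directly -- a
  # well-conditioned 16-dimensional target in which the latent distances mix
  # orders of magnitude faster than through the non-centered likelihood.
  # Componentwise random-walk Metropolis; z is re-derived from rho under the
  # updated Cholesky at the end.  Same scheme for (alpha_G, lambda_G) given
  # gamma.
  interweave <- function(theta, sweeps = 5L, step = 0.35) {
    zr <- matrix(theta[i_zr], S, L)
    # phylo block -------------------------------------------------------
    par <- c(theta[i_u], theta[i_aP])
    chol_p <- function(par) {
      Dm <- matrix(0, L, L)
      Dm[up_idx] <- exp(par[seq_len(m)])
      Dm[lo_idx] <- exp(par[seq_len(m)])
      P0 <- exp(-Dm / lambda_P)
      diag(P0) <- 1 + jitter
      tryCatch(chol(exp(par[m + 1L]) * P0), error = function(e) NULL)
    }
    logc_p <- function(par, R) {
      if (is.null(R)) return(-Inf)
      delta <- exp(par[seq_len(m)])
      a <- exp(par[m + 1L])
      dmvn_rows(rho, R) + sum(-delta + par[seq_len(m)]) +
        (log(2) - 2 * a + par[m + 1L])
    }
    Rcur <- chol_p(par)
    rho <- zr %*% Rcur
    lc <- logc_p(par, Rcur)
    for (sw in seq_len(sweeps)) {
      for (k in seq_len(m + 1L)) {
        prop <- par
        prop[k] <- prop[k] + rnorm(1, 0, step)
        Rp <- chol_p(prop)
        lp2 <- logc_p(prop, Rp)
        if (log(runif(1)) < lp2 - lc) {
          par <- prop; Rcur <- Rp; lc <- lp2
        }
      }
    }
    theta[i_u] <- par[seq_len(m)]
    theta[i_aP] <- par[m + 1L]
    theta[i_zr] <- as.vector(t(backsolve(Rcur, t(rho), transpose = TRUE)))
    # geo block ---------------------------------------------------------
    if (deconf && !(fix_aG && fix_lG)) {
      zg <- matrix(theta[i_zg], S, L)
      gpar <- c(if (!fix_aG) theta[i_aG] else log(fix$alpha_G),
                if (!fix_lG) theta[i_lg] else log(fix$lambda_G))
      free <- c(!fix_aG, !fix_lG)
      chol_g <- function(gp) {
        G0 <- exp(-D2G / exp(gp[2]))
        diag(G0) <- 1 + jitter
        tryCatch(chol(exp(gp[1]) * G0), error = function(e) NULL)
      }
      logc_g <- function(gp, R) {
        if (is.null(R)) return(-Inf)
        dmvn_rows(gam, R) +
          (if (free[1]) log(2) - 2 * exp(gp[1]) + gp[1] else 0) +
          (if (free[2]) log(2) - 2 * exp(gp[2]) + gp[2] else 0)
      }
      Rg <- chol_g(gpar)
      gam <- zg %*% Rg
      lcg <- logc_g(gpar, Rg)
      for (sw in seq_len(sweeps)) {
        for (k in which(free)) {
          prop <- gpar
          prop[k] <- prop[k] + rnorm(1, 0, step)
          Rp <- chol_g(prop)
          lp2 <- logc_g(prop, Rp)
          if (log(runif(1)) < lp2 - lcg) {
            gpar <- prop; Rg <- Rp; lcg <- lp2
          }
        }
      }
      if (!fix_aG) theta[i_aG] <- gpar[1]
      if (!fix_lG) theta[i_lg] <- gpar[2]
      theta[i_zg] <- as.vector(t(backsolve(Rg, t(gam), transpose = TRUE)))
    }
    theta
  }

  mix_moves <- function(theta) {
    interweave(scale_move(theta))
  }

  # Closure for the conditional z-target (GP coefficients given kernel
  # parameters): the kernel Cholesky factors are fixed for a whole HMC
  # trajectory, so the target is smooth (no positive-definiteness boundary)
  # and each gradient is two matrix products.
  z_closure <- function(theta) {
    pr <- unpack(theta)
    Dm <- matrix(0, L, L)
    Dm[up_idx] <- pr$delta
    Dm[lo_idx] <- pr$delta
    P0 <- exp(-Dm / lambda_P)
    diag(P0) <- 1 + jitter
    RP <- chol(pr$alpha_P * P0)
    RG <- NULL
    if (deconf) {
      G0 <- exp(-D2G / pr$lambda_G)
      diag(G0) <- 1 + jitter
      RG <- chol(pr$alpha_G * G0)
    }
    tRP <- t(RP)
    tRG <- if (deconf) t(RG) else NULL
    nz <- S * L * (1L + deconf)
    function(zvec) {
      zr <- matrix(zvec[seq_len(S * L)], S, L)
      eta <- zr %*% RP
      if (deconf) {
        zg <- matrix(zvec[S * L + seq_len(S * L)], S, L)
        eta <- eta + zg %*% RG
      }
      lse <- pmax(eta, 0) + log1p(exp(-abs(eta)))
      lp <- sum(C * eta) - sum(lse) - 0.5 * sum(zvec^2)
      E <- C - plogis(eta)
      g <- if (deconf) c(E %*% tRP - zr, E %*% tRG - zg) else
        as.vector(E %*% tRP - zr)
      list(lp = lp, grad = g)
    }
  }

  list(n_par = n_par, S = S, L = L, m = m, deconf = deconf,
       scale_move = scale_move, interweave = interweave,
       mix_moves = mix_moves, z_closure = z_closure,
       lambda_P = lambda_P, jitter = jitter, fix = fix,
       idx = list(u = i_u, aP = i_aP, aG = i_aG, lg = i_lg,
                  zr = i_zr, zg = i_zg),
       lp_grad = lp_grad, unpack = unpack, init = init)
}

# materialize rho/gamma for one unconstrained draw (used when assembling
# posterior arrays and archives)
materialize_effects <- function(lpobj, theta, geo = NULL) {
  pr <- lpobj$unpack(theta)
  L <- lpobj$L
  # draws can sit numerically on the PSD boundary; escalate jitter for the
  # report-side factorization only (does not affect the sampled density)
  chol_retry <- function(A0, scale) {
    j <- lpobj$jitter
    for (k in 1:12) {
      A <- A0
      diag(A) <- 1 + j
      ch <- tryCatch(chol(scale * A), error = function(e) NULL)
      if (!is.null(ch)) return(ch)
      j <- j * 4
    }
    stop("draw not factorizable even with escalated jitter")
  }
  Dm <- expand_distances(pr$delta)
  RP <- chol_retry(exp(-Dm / lpobj$lambda_P), pr$alpha_P)
  rho <- pr$zr %*% RP
  gamma <- NULL
  if (lpobj$deconf) {
    geoD <- if (inherits(geo, "geo_dist")) geo$values else geo
    RG <- chol_retry(exp(-geoD^2 / pr$lambda_G), pr$alpha_G)
    gamma <- pr$zg %*% RG
  }
  list(rho = rho, gamma = gamma, delta = pr$delta, alpha_P = pr$alpha_P,
       alpha_G = pr$alpha_G, lambda_G = pr$lambda_G)
}
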