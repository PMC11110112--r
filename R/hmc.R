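# Metropolis-within-Gibbs driver for the GP model: HMC over the non-centered
# GP coefficients z with the kernel parameters frozen per trajectory (smooth
# conditional, no positive-definiteness boundary, so step sizes stay large),
# interleaved with the centered-parameterization Metropolis updates and the
# amplitude scale move supplied by the model object (which are the only
# moves that change latent distances and kernel amplitudes).
gp_gibbs_chain <- function(lpobj, theta0, iter, warmup,
                           target_accept = 0.9, max_leapfrog = 24L,
                           eps0 = 0.1) {
  theta <- theta0
  iz <- c(lpobj$idx$zr, lpobj$idx$zg)
  zt <- lpobj$z_closure(theta)
  z <- theta[iz]
  cur <- zt(z)
  if (!is.finite(cur$lp)) stop("non-finite initial log-density")

  da_mu <- log(10 * eps0)
  da_logeps <- log(eps0)
  da_logeps_bar <- 0
  da_hbar <- 0
  da_t0 <- 10; da_gamma <- 0.05; da_kappa <- 0.75

  draws <- matrix(NA_real_, iter, length(theta0))
  lps <- numeric(iter)
  divergences <- 0L
  n_acc <- 0
  total <- warmup + iter
  lmin <- max(1L, floor(max_leapfrog / 2))

  for (it in seq_len(total)) {
    eps <- exp(if (it <= warmup) da_logeps else da_logeps_bar)
    r0 <- rnorm(length(z))
    H0 <- -cur$lp + 0.5 * sum(r0^2)
    nst <- if (max_leapfrog > lmin) {
      lmin + sample.int(max_leapfrog - lmin + 1L, 1L) - 1L
    } else lmin
    zp <- z
    r <- r0 + 0.5 * eps * cur$grad
    ok <- TRUE
    for (s in seq_len(nst)) {
      zp <- zp + eps * r
      prop <- zt(zp)
      if (!is.finite(prop$lp)) { ok <- FALSE; break }
      r <- r + (if (s < nst) eps else 0.5 * eps) * prop$grad
    }
    if (ok) {
      dH <- (-prop$lp + 0.5 * sum(r^2)) - H0
      if (!is.finite(dH) || dH > 1000) {
        alpha <- 0; ok <- FALSE
        divergences <- divergences + (it > warmup)
      } else alpha <- min(1, exp(-dH))
    } else {
      alpha <- 0
      divergences <- divergences + (it > warmup)
    }
    if (ok && runif(1) < alpha) {
      z <- zp
      cur <- prop
      if (it > warmup) n_acc <- n_acc + 1
    }
    # kernel-parameter moves (change delta, alphas, and rotate z)
    theta[iz] <- z
    theta <- lpobj$mix_moves(theta)
    zt <- lpobj$z_closure(theta)
    z <- theta[iz]
    cur <- zt(z)
    if (it <= warmup) {
      frac <- 1 / (it + da_t0)
      da_hbar <- (1 - frac) * da_hbar + frac * (target_accept - alpha)
      da_logeps <- da_mu - sqrt(it) / da_gamma * da_hbar
      w <- it^(-da_kappa)
      da_logeps_bar <- w * da_logeps + (1 - w) * da_logeps_bar
    } else {
      draws[it - warmup, ] <- theta
      lps[it - warmup] <- cur$lp
    }
  }
  list(draws = draws, lp = lps, divergences = divergences,
       accept_rate = n_acc / iter, step_size = exp(da_logeps_bar),
       inv_mass = NULL)
}

# Adaptive Hamiltonian Monte Carlo with dual-averaging step-size adaptation
# and a structured metric: a dense covariance block over the (few) kernel
# parameters -- latent distances, amplitudes, length-scale -- and a diagonal
# over the (many) non-centered GP coordinates.  The dense block matters: the
# latent-distance scale trades off against the kernel amplitude along a
# ridge that a diagonal metric explores by random walk.  Trajectory lengths
# are jittered uniformly over the upper half of `max_leapfrog`.  Divergences
# (energy error > 1000 or non-finite Hamiltonian) are counted and rejected.

hmc_chain <- function(lp_grad, theta0, iter, warmup,
                      target_accept = 0.9, max_leapfrog = 32L,
                      dense_idx = integer(0), eps0 = 0.05,
                      between_step = NULL) {
  d <- length(theta0)
  theta <- theta0
  cur <- lp_grad(theta)
  if (!is.finite(cur$lp)) stop("non-finite initial log-density")
  diag_idx <- setdiff(seq_len(d), dense_idx)
  nA <- length(dense_idx)

  # metric state: M^-1 = Sigma (estimated posterior covariance);
  # Sigma_A = RA' RA (upper chol) on the dense block, vector vD elsewhere
  RA <- if (nA) diag(1, nA) else NULL
  vD <- rep(1, length(diag_idx))
  sqrt_vD <- sqrt(vD)

  sample_momentum <- function() {
    r <- numeric(d)
    if (nA) r[dense_idx] <- backsolve(RA, rnorm(nA))
    r[diag_idx] <- rnorm(length(diag_idx)) / sqrt_vD
    r
  }
  kinetic <- function(r) {
    k <- 0.5 * sum((vD * r[diag_idx]) * r[diag_idx])
    if (nA) {
      w <- RA %*% r[dense_idx]
      k <- k + 0.5 * sum(w * w)
    }
    k
  }
  minv_times <- function(r) {
    out <- numeric(d)
    out[diag_idx] <- vD * r[diag_idx]
    if (nA) out[dense_idx] <- crossprod(RA, RA %*% r[dense_idx])
    out
  }
  update_metric <- function(X) {
    n <- nrow(X)
    shrink <- n / (n + 5)
    if (nA) {
      SA <- stats::cov(X[, dense_idx, drop = FALSE]) * shrink +
        diag(1e-3 * (5 / (n + 5)), nA)
      RA <<- tryCatch(chol(SA), error = function(e) {
        chol(diag(diag(SA)))
      })
    }
    v <- apply(X[, diag_idx, drop = FALSE], 2, var)
    vD <<- shrink * v + 1e-3 * (5 / (n + 5))
    sqrt_vD <<- sqrt(vD)
  }

  # dual averaging (Hoffman & Gelman 2014 defaults)
  da_mu <- log(10 * eps0)
  da_logeps <- log(eps0)
  da_logeps_bar <- 0
  da_hbar <- 0
  da_t0 <- 10; da_gamma <- 0.05; da_kappa <- 0.75
  da_count <- 0
  reset_da <- function(eps) {
    da_mu <<- log(10 * eps)
    da_logeps <<- log(eps)
    da_logeps_bar <<- 0
    da_hbar <<- 0
    da_count <<- 0
  }

  w1 <- max(1L, floor(0.15 * warmup))
  w2 <- max(w1 + 2L, floor(0.5 * warmup))
  w3 <- max(w2 + 2L, floor(0.85 * warmup))
  hist <- matrix(0, warmup, d)

  draws <- matrix(NA_real_, iter, d)
  lps <- numeric(iter)
  divergences <- 0L
  n_acc <- 0
  total <- warmup + iter
  lmin <- max(1L, floor(max_leapfrog / 2))

  for (it in seq_len(total)) {
    eps <- exp(if (it <= warmup) da_logeps else da_logeps_bar)
    r0 <- sample_momentum()
    H0 <- -cur$lp + kinetic(r0)
    nst <- if (max_leapfrog > lmin) {
      lmin + sample.int(max_leapfrog - lmin + 1L, 1L) - 1L
    } else lmin
    th <- theta
    r <- r0 + 0.5 * eps * cur$grad
    ok <- TRUE
    for (s in seq_len(nst)) {
      th <- th + eps * minv_times(r)
      prop <- lp_grad(th)
      if (!is.finite(prop$lp)) { ok <- FALSE; break }
      r <- r + (if (s < nst) eps else 0.5 * eps) * prop$grad
    }
    if (ok) {
      dH <- (-prop$lp + kinetic(r)) - H0
      if (!is.finite(dH) || dH > 1000) {
        alpha <- 0
        ok <- FALSE
        divergences <- divergences + (it > warmup)
      } else {
        alpha <- min(1, exp(-dH))
      }
    } else {
      alpha <- 0
      divergences <- divergences + (it > warmup)
    }
    if (ok && runif(1) < alpha) {
      theta <- th
      cur <- prop
      if (it > warmup) n_acc <- n_acc + 1
    }
    if (!is.null(between_step)) {
      th2 <- between_step(theta)
      if (!identical(th2, theta)) {
        theta <- th2
        cur <- lp_grad(theta)
      }
    }
    if (it <= warmup) {
      da_count <- da_count + 1
      frac <- 1 / (da_count + da_t0)
      da_hbar <- (1 - frac) * da_hbar + frac * (target_accept - alpha)
      da_logeps <- da_mu - sqrt(da_count) / da_gamma * da_hbar
      w <- da_count^(-da_kappa)
      da_logeps_bar <- w * da_logeps + (1 - w) * da_logeps_bar
      hist[it, ] <- theta
      if (it == w2) {
        update_metric(hist[seq.int(w1 + 1L, w2), , drop = FALSE])
        reset_da(exp(da_logeps_bar))
      } else if (it == w3) {
        update_metric(hist[seq.int(w2 + 1L, w3), , drop = FALSE])
        reset_da(exp(da_logeps_bar))
      }
    } else {
      draws[it - warmup, ] <- theta
      lps[it - warmup] <- cur$lp
    }
  }
  list(draws = draws, lp = lps, divergences = divergences,
       accept_rate = n_acc / iter, step_size = exp(da_logeps_bar),
       inv_mass = vD)
}
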