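# Gibbs sampler for the (multi-trait) GBLUP animal model
#
#   Y = X B + g + E,   vec(g) ~ N(0, G_RM (x) G0),   rows of E ~ iid N(0, R0)
#
# The blended GRM is eigendecomposed once (G* = U diag(d) U'); writing
# g = U a turns the genetic block into independent rows a_i ~ N(0, d_i G0),
# and because U is orthogonal the whole sampler can run in the eigenbasis:
# crossproducts with X use the precomputed U'X, and with complete records the
# residual scatter and the deviance are computed from U'Y - U'X B - a without
# ever forming g (only retained draws map back through U). Within an
# iteration, a simultaneous diagonalisation of (R0^-1, G0^-1)
# (Q'R0^-1 Q = I, Q'G0^-1 Q = diag(lambda)) makes the full conditional of
# z = Q^-1 a_i diagonal with precision 1 + lambda_j / d_i, so the
# genetic-effect draw vectorises across animals and traits. Missing
# phenotypes are data-augmented from the conditional residual distribution of
# their missingness pattern. Variance priors are the flat improper limits of
# the scaled-inverse-chi-square / inverse-Wishart families (posterior
# df = n - t - 1); see the G0 draw for why the Jeffreys-type alternative is
# unusable here.

# inverse-Wishart draw via the Bartlett decomposition: with S = Uu' Uu,
# Sigma = (A^-1 Uu)' (A^-1 Uu) is IW(df, S) and positive definite by
# construction even when S is ill-conditioned (e.g. a genetic correlation
# wandering near +/-1)
riwish_draw <- function(df, scale_mat) {
  t <- nrow(scale_mat)
  Uu <- tryCatch(chol(scale_mat), error = function(e) NULL)
  if (is.null(Uu)) {
    scale_mat <- scale_mat + diag(1e-8 * mean(diag(scale_mat)) + 1e-12, t)
    Uu <- chol(scale_mat)
  }
  A <- matrix(0, t, t)
  diag(A) <- sqrt(stats::rchisq(t, df - seq_len(t) + 1))
  A[lower.tri(A)] <- stats::rnorm(t * (t - 1) / 2)
  crossprod(forwardsolve(A, Uu))
}

# deviance (-2 log likelihood) of the observed data given current parameters
observed_deviance <- function(Y, mu, R0, patterns) {
  dev <- 0
  for (pt in patterns) {
    if (!length(pt$obs)) next
    Eo <- (Y - mu)[pt$rows, pt$obs, drop = FALSE]
    cR <- chol(R0[pt$obs, pt$obs, drop = FALSE])
    v <- forwardsolve(t(cR), t(Eo))
    dev <- dev + sum(length(pt$obs) * log(2 * pi) + 2 * sum(log(diag(cR))) +
                       colSums(v^2))
  }
  dev
}

# simultaneous diagonalisation of (R0^-1, G0^-1): returns Q with
# Q' R0^-1 Q = I and Q' G0^-1 Q = diag(lambda), plus R0^-1
double_diag <- function(G0, R0) {
  cR0 <- chol(R0)
  R0inv <- chol2inv(cR0)
  G0inv <- chol2inv(chol(G0))
  S <- cR0 %*% G0inv %*% t(cR0)
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  list(Q = t(cR0) %*% es$vectors, lam = pmax(es$values, 0),
       R0inv = R0inv, cR0 = cR0)
}

#' Gibbs sampler for univariate and multi-trait GBLUP animal models
#'
#' Low-level engine behind [fit_univariate()], [fit_bivariate()],
#' [fit_multitrait()] and [fit_null()]. Fixed effects get a flat prior;
#' genetic and residual (co)variances get flat improper priors (the
#' degree-of-belief limit of the scaled-inverse-chi-square / inverse-Wishart
#' families whose posterior has df = n - t - 1) unless fixed via `G0_fixed` /
#' `R0_fixed`. Missing phenotypes (`NA` in `Y`) are imputed by data
#' augmentation each sweep.
#'
#' @param Y n x t numeric matrix of phenotypes (NA = missing record).
#' @param X n x p full-rank fixed-effect design matrix.
#' @param grm a [build_grm()] object or symmetric n x n matrix.
#' @param n_iter,burn_in,thin MCMC settings; `burn_in < n_iter`, `thin >= 1`.
#' @param seed integer seed (optional).
#' @param G0_fixed,R0_fixed t x t matrices; when supplied the corresponding
#'   (co)variance is held fixed instead of sampled.
#' @param blend identity blending weight for the GRM (see [grm_stabilize()]).
#' @param include_genetic set `FALSE` to fit the reduced model without the
#'   genetic effect (used for DIC / Bayes-factor comparisons).
#' @param store_traits indices of traits whose per-animal genetic-effect
#'   draws are retained (default: all).
#' @return object of class `mcmc_fit`; see Details.
#' @details The returned list carries `samples` (thinned (co)variance draws,
#'   columns `G_i_j` / `R_i_j`), `b_samples`, `deviance` draws and
#'   `dev_at_mean` (deviance at posterior means, for DIC), `gebv` (list of
#'   per-trait draw matrices), `gebv_mean` / `gebv_sd`, `diagnostics`
#'   (Geweke Z and Monte-Carlo SE per (co)variance parameter), and the
#'   data/settings needed by [dic_compare()] and [bayes_factor()].
#' @export
gibbs_gblup <- function(Y, X, grm = NULL, n_iter = 100000, burn_in = 20000,
                        thin = 100, seed = NULL, G0_fixed = NULL,
                        R0_fixed = NULL, blend = 0.01, include_genetic = TRUE,
                        store_traits = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y); t <- ncol(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("trait", seq_len(t))
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (thin < 1) stop("thin must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  X <- as.matrix(X)
  p <- ncol(X)
  if (qr(X)$rank < p) stop("fixed-effect design matrix is not full rank")
  if (include_genetic) {
    gm <- if (inherits(grm, "grm")) grm$matrix else as.matrix(grm)
    if (nrow(gm) != n) stop("GRM dimension does not match the data")
    eg <- eigen(grm_stabilize(gm, blend), symmetric = TRUE)
    U <- eg$vectors; d <- eg$values
    if (min(d) <= 0) stop("stabilised GRM is not positive definite")
    Ut <- t(U); UtX <- Ut %*% X
  }
  miss <- is.na(Y)
  any_miss <- any(miss)
  if (all(miss)) stop("all records missing")
  # traits missing for every animal (e.g. CH4 treated as unknown in the
  # microbiome-only prediction scenario) carry no data: fit the observed
  # sub-model and reconstruct their genetic effects from the exact
  # between-trait conditional given G0 (valid with fixed (co)variances; also
  # avoids the improper posterior of the phantom trait's fixed effects)
  if (include_genetic && !is.null(G0_fixed) && !is.null(R0_fixed)) {
    all_mis <- which(colSums(!miss) == 0L)
    if (length(all_mis) > 0L && length(all_mis) < t) {
      return(gibbs_phantom_traits(Y, X, grm, all_mis, n_iter, burn_in, thin,
                                  seed, as.matrix(G0_fixed),
                                  as.matrix(R0_fixed), blend, store_traits))
    }
  }
  pat_key <- apply(miss, 1, function(r) paste(which(r), collapse = ","))
  patterns <- lapply(split(seq_len(n), pat_key), function(rows) {
    m <- which(miss[rows[1L], ])
    list(rows = rows, mis = m, obs = setdiff(seq_len(t), m))
  })
  Y_cur <- Y
  for (j in seq_len(t)) {
    cm <- mean(Y[, j], na.rm = TRUE)
    if (is.nan(cm)) cm <- 0
    Y_cur[miss[, j], j] <- cm
  }
  XtX <- crossprod(X)
  Cx <- chol(XtX)
  XtXinv <- chol2inv(Cx)
  XtY <- crossprod(X, Y_cur)
  if (include_genetic && !any_miss) UtY <- Ut %*% Y
  B <- XtXinv %*% XtY
  a <- matrix(0, n, t)
  g <- matrix(0, n, t)                     # only maintained when needed
  vy <- apply(Y_cur, 2, stats::var)
  vy[!is.finite(vy) | vy <= 0] <- 1
  G0 <- if (!is.null(G0_fixed)) as.matrix(G0_fixed) else diag(vy / 2, t)
  R0 <- if (!is.null(R0_fixed)) as.matrix(R0_fixed) else diag(vy / 2, t)
  sample_G0 <- is.null(G0_fixed) && include_genetic
  sample_R0 <- is.null(R0_fixed)
  varcomp_fixed <- !sample_G0 && !sample_R0
  univar <- t == 1L
  store_traits <- store_traits %||% seq_len(t)
  n_saved <- floor((n_iter - burn_in) / thin)
  if (n_saved < 1L) stop("settings retain no samples")
  ut_idx <- which(upper.tri(diag(t), diag = TRUE), arr.ind = TRUE)
  vc_names <- c(if (include_genetic) paste0("G_", ut_idx[, 1], "_", ut_idx[, 2]),
                paste0("R_", ut_idx[, 1], "_", ut_idx[, 2]))
  samples <- matrix(NA_real_, n_saved, length(vc_names),
                    dimnames = list(NULL, vc_names))
  b_names <- as.vector(outer(colnames(X), colnames(Y), paste, sep = ":"))
  b_samples <- matrix(NA_real_, n_saved, p * t, dimnames = list(NULL, b_names))
  deviance <- numeric(n_saved)
  gebv <- stats::setNames(
    lapply(store_traits, function(j) matrix(NA_real_, n_saved, n)),
    colnames(Y)[store_traits])
  a_sum <- matrix(0, n, t); g_sum <- matrix(0, n, t); g_sumsq <- matrix(0, n, t)
  a_cond_sum <- matrix(0, n, t); n_cond <- 0L
  B_sum <- matrix(0, p, t); R0_sum <- matrix(0, t, t)
  # with fixed (co)variances the transforms are constant: precompute
  if (include_genetic && !univar && varcomp_fixed) dd_fixed <- double_diag(G0, R0)
  if (any_miss) {
    # per-pattern conditional-residual transforms (constant when R0 is fixed)
    pattern_draw <- function(R0) {
      lapply(patterns, function(pt) {
        if (!length(pt$mis)) return(NULL)
        if (!length(pt$obs)) {
          return(list(A = NULL, cc = chol(R0[pt$mis, pt$mis, drop = FALSE])))
        }
        Roo_inv <- solve(R0[pt$obs, pt$obs, drop = FALSE])
        A <- R0[pt$mis, pt$obs, drop = FALSE] %*% Roo_inv
        cc <- R0[pt$mis, pt$mis, drop = FALSE] -
          A %*% R0[pt$obs, pt$mis, drop = FALSE]
        list(A = A, cc = chol((cc + t(cc)) / 2 + diag(1e-12, length(pt$mis))))
      })
    }
    if (!sample_R0) ptrans_fixed <- pattern_draw(R0)
  }
  isave <- 0L
  n_psd_proj <- 0L
  for (iter in seq_len(n_iter)) {
    ## fixed effects: vec(B) | . ~ N(vec(Bhat), R0 (x) (X'X)^-1)
    XtG <- if (include_genetic) crossprod(UtX, a) else 0
    Bhat <- XtXinv %*% (XtY - XtG)
    cR0 <- chol(R0)
    B <- Bhat + backsolve(Cx, matrix(stats::rnorm(p * t), p, t) %*% cR0)
    ## genetic effects
    if (include_genetic) {
      Yt <- if (any_miss) Ut %*% (Y_cur - X %*% B) else UtY - UtX %*% B
      if (univar) {
        sg2 <- G0[1, 1]; se2 <- R0[1, 1]
        prec <- 1 / se2 + 1 / (d * sg2)
        a_cond <- matrix(Yt / (se2 * prec))
        a <- a_cond + stats::rnorm(n) / sqrt(prec)
      } else {
        dd <- if (varcomp_fixed) dd_fixed else double_diag(G0, R0)
        Mn <- Yt %*% dd$R0inv %*% dd$Q
        Dn <- 1 + outer(1 / d, dd$lam)
        zm <- Mn / Dn
        a_cond <- zm %*% t(dd$Q)
        a <- (zm + matrix(stats::rnorm(n * t), n, t) / sqrt(Dn)) %*% t(dd$Q)
      }
      # Rao-Blackwellised accumulation of E[g | rest] over every
      # post-burn-in sweep (fast-converging posterior-mean estimate)
      if (iter > burn_in) {
        a_cond_sum <- a_cond_sum + a_cond
        n_cond <- n_cond + 1L
      }
    }
    ## data augmentation of missing records
    if (any_miss) {
      XB <- X %*% B
      if (include_genetic) g <- U %*% a
      E <- Y_cur - XB - g
      ptrans <- if (sample_R0) pattern_draw(R0) else ptrans_fixed
      for (k in seq_along(patterns)) {
        pt <- patterns[[k]]; tr <- ptrans[[k]]
        if (is.null(tr)) next
        nm <- length(pt$mis); nr <- length(pt$rows)
        noise <- matrix(stats::rnorm(nr * nm), nr, nm) %*% tr$cc
        e_m <- if (is.null(tr$A)) noise
               else E[pt$rows, pt$obs, drop = FALSE] %*% t(tr$A) + noise
        Y_cur[pt$rows, pt$mis] <- (XB + g)[pt$rows, pt$mis] + e_m
      }
      XtY <- crossprod(X, Y_cur)
    }
    ## (co)variance components under the flat improper prior (posterior
    ## df = n - t - 1): a Jeffreys-type nu = 0 prior is non-integrable at
    ## singular matrices (sigma_g^2 = 0, |rg| = 1), which turns those
    ## boundaries into numerically absorbing traps for the Gibbs chain
    if (sample_G0) {
      Sa <- crossprod(a, a / d)
      G0 <- if (univar) matrix(Sa / stats::rchisq(1, n - 2))
            else riwish_draw(n - t - 1, (Sa + t(Sa)) / 2)
      if (!univar) {
        ev <- eigen(G0, symmetric = TRUE, only.values = TRUE)$values
        if (min(ev) < 1e-10 * max(ev)) {
          n_psd_proj <- n_psd_proj + 1L
          ee <- eigen(G0, symmetric = TRUE)
          G0 <- ee$vectors %*% (pmax(ee$values, 1e-10 * max(ev)) *
                                  t(ee$vectors))
          G0 <- (G0 + t(G0)) / 2
        }
      }
    }
    need_Se <- sample_R0 ||
      (iter > burn_in && (iter - burn_in) %% thin == 0L && !any_miss)
    if (need_Se) {
      # residual scatter; with complete records, computed in the eigenbasis
      if (any_miss) {
        Se <- crossprod(Y_cur - X %*% B - g)
      } else if (include_genetic) {
        Se <- crossprod(UtY - UtX %*% B - a)
      } else {
        Se <- crossprod(Y_cur - X %*% B)
      }
    }
    if (sample_R0) {
      R0 <- if (univar) matrix(Se / stats::rchisq(1, n - 2))
            else riwish_draw(n - t - 1, (Se + t(Se)) / 2)
    }
    ## save
    if (iter > burn_in && (iter - burn_in) %% thin == 0L) {
      isave <- isave + 1L
      samples[isave, ] <- c(if (include_genetic) G0[upper.tri(G0, diag = TRUE)],
                            R0[upper.tri(R0, diag = TRUE)])
      b_samples[isave, ] <- as.vector(B)
      if (include_genetic && !any_miss) g <- U %*% a
      if (any_miss) {
        deviance[isave] <- observed_deviance(Y, X %*% B + g, R0, patterns)
      } else {
        cRd <- chol(R0)
        deviance[isave] <- n * t * log(2 * pi) + 2 * n * sum(log(diag(cRd))) +
          sum(chol2inv(cRd) * Se)
      }
      for (j in seq_along(store_traits)) gebv[[j]][isave, ] <- g[, store_traits[j]]
      a_sum <- a_sum + a; g_sum <- g_sum + g; g_sumsq <- g_sumsq + g^2
      B_sum <- B_sum + B; R0_sum <- R0_sum + R0
    }
  }
  g_mean <- g_sum / n_saved
  g_sd <- sqrt(pmax(g_sumsq / n_saved - g_mean^2, 0) *
                 n_saved / max(1, n_saved - 1))
  B_mean <- B_sum / n_saved; R0_mean <- R0_sum / n_saved
  dev_at_mean <- if (any_miss || !include_genetic) {
    observed_deviance(Y, X %*% B_mean + g_mean, R0_mean, patterns)
  } else {
    Se_m <- crossprod(UtY - UtX %*% B_mean - a_sum / n_saved)
    cRm <- chol(R0_mean)
    n * t * log(2 * pi) + 2 * n * sum(log(diag(cRm))) + sum(chol2inv(cRm) * Se_m)
  }
  diagnostics <- data.frame(
    parameter = colnames(samples),
    geweke_z = apply(samples, 2, function(ch) suppressWarnings(geweke_z(ch))),
    mcse = apply(samples, 2, function(ch) mcse_timeseries(ch)$mcse),
    sd_over_mcse = apply(samples, 2, function(ch) mcse_timeseries(ch)$ratio),
    row.names = NULL
  )
  structure(list(
    samples = samples, b_samples = b_samples, deviance = deviance,
    dev_at_mean = dev_at_mean, gebv = gebv, gebv_mean = g_mean,
    gebv_sd = g_sd,
    gebv_mean_rb = if (include_genetic && n_cond > 0)
      U %*% (a_cond_sum / n_cond) else g_sum * 0,
    n_traits = t, n = n, n_saved = n_saved,
    trait_names = colnames(Y), include_genetic = include_genetic,
    diagnostics = diagnostics, n_psd_projections = n_psd_proj,
    settings = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                    seed = seed, blend = blend),
    data_checksum = c(n = n, t = t, ss = sum(Y^2, na.rm = TRUE),
                      sw = sum(Y * seq_len(n), na.rm = TRUE), xs = sum(X)),
    eigen_data = if (univar && include_genetic && !any_miss)
      list(d = d, Uty = UtY, UtX = UtX) else NULL,
    raw_data = if (univar) list(y = Y, X = X) else NULL
  ), class = "mcmc_fit")
}

# sub-model fit + conditional reconstruction for traits with no records:
# rows of a satisfy a_i ~ N(0, d_i G0), so a_i,mis | a_i,obs ~
# N(Tm a_i,obs, d_i Sc) with Tm = G0[m,o] G0[o,o]^-1 and Sc the Schur
# complement; in g-space, g_mis = g_obs Tm' + U (sqrt(d) Z) chol(Sc)'
gibbs_phantom_traits <- function(Y, X, grm, mis, n_iter, burn_in, thin, seed,
                                 G0, R0, blend, store_traits) {
  t <- ncol(Y); n <- nrow(Y)
  obs <- setdiff(seq_len(t), mis)
  sub <- gibbs_gblup(Y[, obs, drop = FALSE], X, grm, n_iter = n_iter,
                     burn_in = burn_in, thin = thin, seed = seed,
                     G0_fixed = G0[obs, obs, drop = FALSE],
                     R0_fixed = R0[obs, obs, drop = FALSE], blend = blend,
                     store_traits = seq_along(obs))
  Goo_inv <- solve(G0[obs, obs, drop = FALSE])
  Tm <- G0[mis, obs, drop = FALSE] %*% Goo_inv
  Sc <- G0[mis, mis, drop = FALSE] -
    Tm %*% G0[obs, mis, drop = FALSE]
  cSc <- chol((Sc + t(Sc)) / 2 + diag(1e-12, length(mis)))
  gm <- if (inherits(grm, "grm")) grm$matrix else as.matrix(grm)
  eg <- eigen(grm_stabilize(gm, blend), symmetric = TRUE)
  U <- eg$vectors; sqd <- sqrt(eg$values)
  n_saved <- sub$n_saved
  nm <- length(mis)
  gebv_all <- stats::setNames(vector("list", t), colnames(Y))
  for (j in seq_along(obs)) gebv_all[[obs[j]]] <- sub$gebv[[j]]
  for (j in mis) gebv_all[[j]] <- matrix(NA_real_, n_saved, n)
  g_mean <- matrix(0, n, t); g_sd <- g_mean; g_rb <- g_mean
  g_mean[, obs] <- sub$gebv_mean; g_sd[, obs] <- sub$gebv_sd
  g_rb[, obs] <- sub$gebv_mean_rb
  g_rb[, mis] <- sub$gebv_mean_rb %*% t(Tm)
  for (s in seq_len(n_saved)) {
    g_obs_s <- vapply(seq_along(obs), function(j) sub$gebv[[j]][s, ],
                      numeric(n))
    noise <- U %*% (sqd * matrix(stats::rnorm(n * nm), n, nm)) %*% cSc
    gmis_s <- g_obs_s %*% t(Tm) + noise
    for (j in seq_len(nm)) gebv_all[[mis[j]]][s, ] <- gmis_s[, j]
  }
  for (j in mis) {
    g_mean[, j] <- colMeans(gebv_all[[j]])
    g_sd[, j] <- apply(gebv_all[[j]], 2, stats::sd)
  }
  ut_idx <- which(upper.tri(diag(t), diag = TRUE), arr.ind = TRUE)
  vc <- c(G0[upper.tri(G0, diag = TRUE)], R0[upper.tri(R0, diag = TRUE)])
  samples <- matrix(rep(vc, each = n_saved), n_saved,
                    dimnames = list(NULL, c(paste0("G_", ut_idx[, 1], "_",
                                                   ut_idx[, 2]),
                                            paste0("R_", ut_idx[, 1], "_",
                                                   ut_idx[, 2]))))
  out <- sub
  out$samples <- samples
  out$gebv <- gebv_all[store_traits %||% seq_len(t)]
  names(out$gebv) <- colnames(Y)[store_traits %||% seq_len(t)]
  out$gebv_mean <- g_mean; out$gebv_sd <- g_sd; out$gebv_mean_rb <- g_rb
  out$n_traits <- t
  out$trait_names <- colnames(Y)
  out$data_checksum <- c(n = n, t = t, ss = sum(Y^2, na.rm = TRUE),
                         sw = sum(Y * seq_len(n), na.rm = TRUE), xs = sum(X))
  out$phantom_traits <- mis
  out
}

#' @export
print.mcmc_fit <- function(x, ...) {
  cat(sprintf("mcmc_fit: %d traits, n = %d, %d retained samples (%s model)\n",
              x$n_traits, x$n, x$n_saved,
              if (x$include_genetic) "genomic" else "fixed-effects-only"))
  invisible(x)
}
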