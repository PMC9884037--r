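# Single-season occupancy model: zero-inflated detection likelihood with
# logit links on occupancy (psi) and detection (p), fitted by maximum
# likelihood.
#
# Site i with detections y_it over non-missing occasions contributes
#   psi_i * prod_t p_i^y (1-p_i)^(1-y)          if any y_it = 1
#   psi_i * prod_t (1-p_i) + (1 - psi_i)        otherwise.
# Missing occasions contribute nothing (missing-at-random handling);
# covariates are site-level, so p is constant across occasions at a site.

# Run code with the global RNG stream saved and restored, so internally
# seeded steps (multi-start jitters) do not perturb callers' streams.
with_preserved_rng <- function(expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Design matrices for psi and p from formulas over site covariates,
# aligned to the history's site order.
occu_design <- function(h, covs, psi, p) {
  sites <- rownames(h$y)
  if (is.null(covs)) {
    dat <- data.frame(row.names = sites)
  } else {
    ix <- match(sites, covs$station_id)
    if (anyNA(ix))
      stop("covariate table lacks site(s): ",
           paste(sites[is.na(ix)], collapse = ", "))
    dat <- covs[ix, setdiff(names(covs), "station_id"), drop = FALSE]
    rownames(dat) <- sites
  }
  Xpsi <- stats::model.matrix(psi, dat)
  Xp <- stats::model.matrix(p, dat)
  if (!all(is.finite(Xpsi)) || !all(is.finite(Xp)))
    stop("non-finite covariate value in design matrix")
  for (X in list(Xpsi, Xp)) {
    if (qr(X)$rank < ncol(X)) {
      q <- qr(X)
      aliased <- colnames(X)[setdiff(seq_len(ncol(X)),
                                     q$pivot[seq_len(q$rank)])]
      stop("rank-deficient design; aliased column(s): ",
           paste(aliased, collapse = ", "))
    }
  }
  list(Xpsi = Xpsi, Xp = Xp)
}

#' Negative log-likelihood of the occupancy model
#'
#' @param params numeric vector: occupancy coefficients followed by
#'   detection coefficients (logit scale).
#' @param y site x occasion matrix over \{0, 1, NA\}.
#' @param Xpsi,Xp design matrices (rows = sites) for occupancy and
#'   detection.
#' @return the negative log-likelihood; sites with all-missing occasions
#'   contribute zero.
#' @export
occu_negloglik <- function(params, y, Xpsi, Xp) {
  kpsi <- ncol(Xpsi)
  psi <- stats::plogis(drop(Xpsi %*% params[seq_len(kpsi)]))
  p <- stats::plogis(drop(Xp %*% params[-seq_len(kpsi)]))
  nd <- rowSums(!is.na(y))
  d1 <- rowSums(y == 1L, na.rm = TRUE)
  d0 <- nd - d1
  ll <- numeric(nrow(y))
  det <- d1 > 0
  # log on the mixture scale; clamp to avoid log(0) at hard boundaries
  ll[det] <- log(pmax(psi[det], 1e-300)) +
    d1[det] * log(pmax(p[det], 1e-300)) +
    d0[det] * log(pmax(1 - p[det], 1e-300))
  nodet <- !det & nd > 0
  ll[nodet] <- log(pmax(psi[nodet] * (1 - p[nodet])^nd[nodet] +
                          (1 - psi[nodet]), 1e-300))
  -sum(ll)
}

#' Fit a single-season occupancy model
#'
#' Maximum-likelihood fit with logit-linear covariates on occupancy and
#' detection. Optimisation is quasi-Newton (BFGS) from a multi-start set
#' (the zero vector plus 4 deterministic random jitters); standard errors
#' come from the inverse of the central-difference Hessian at the optimum.
#' Covariates referenced by the formulas should normally be screened and
#' z-scored first (\code{\link{screen_covariates}}).
#'
#' @param h \code{detection_history}.
#' @param covs covariate data.frame with a \code{station_id} column, or
#'   NULL for intercept-only models.
#' @param psi,p right-hand-side formulas for occupancy and detection
#'   (default intercept-only \code{~ 1}).
#' @param n_starts number of optimiser starts (first is the zero vector).
#' @param reltol convergence tolerance on the objective.
#' @return object of class \code{occu_fit}: coefficients (\code{beta_psi},
#'   \code{beta_p}) with standard errors, \code{logLik}, \code{K},
#'   \code{n_sites}, fitted \code{psi_hat}/\code{p_hat} per site,
#'   \code{converged} and \code{boundary} flags.
#' @export
fit_occupancy <- function(h, covs = NULL, psi = ~1, p = ~1,
                          n_starts = 5L, reltol = 1e-10) {
  stopifnot(inherits(h, "detection_history"))
  y <- h$y
  if (nrow(y) < 2L) stop("need at least 2 sites to fit")
  allmiss <- rowSums(!is.na(y)) == 0L
  if (any(allmiss))
    warning(sum(allmiss), " site(s) with all-missing occasions ",
            "contribute nothing to the likelihood")
  des <- occu_design(h, covs, psi, p)
  npar <- ncol(des$Xpsi) + ncol(des$Xp)
  obj <- function(par) occu_negloglik(par, y, des$Xpsi, des$Xp)
  starts <- with_preserved_rng({
    set.seed(20260929L)
    c(list(rep(0, npar)),
      lapply(seq_len(max(n_starts - 1L, 0L)),
             function(i) stats::rnorm(npar, 0, 0.75)))
  })
  best <- NULL
  for (s0 in starts) {
    fit <- tryCatch(
      stats::optim(s0, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-12) best <- fit
  }
  if (is.null(best)) stop("optimiser failed from every start")
  par <- best$par
  converged <- best$convergence == 0L
  boundary <- any(abs(par) > 10)
  se <- rep(NA_real_, npar)
  H <- tryCatch(stats::optimHess(par, obj), error = function(e) NULL)
  if (!is.null(H)) {
    Vi <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Vi)) {
      dg <- diag(Vi)
      se <- ifelse(dg > 0, sqrt(pmax(dg, 0)), NA_real_)
    }
  }
  kpsi <- ncol(des$Xpsi)
  beta_psi <- stats::setNames(par[seq_len(kpsi)], colnames(des$Xpsi))
  beta_p <- stats::setNames(par[-seq_len(kpsi)], colnames(des$Xp))
  structure(list(
    psi_formula = psi, p_formula = p,
    beta_psi = beta_psi, beta_p = beta_p,
    se_psi = stats::setNames(se[seq_len(kpsi)], names(beta_psi)),
    se_p = stats::setNames(se[-seq_len(kpsi)], names(beta_p)),
    logLik = -best$value, K = npar, n_sites = nrow(y),
    psi_hat = stats::plogis(drop(des$Xpsi %*% par[seq_len(kpsi)])),
    p_hat = stats::plogis(drop(des$Xp %*% par[-seq_len(kpsi)])),
    converged = converged, boundary = boundary,
    y = y, Xpsi = des$Xpsi, Xp = des$Xp
  ), class = "occu_fit")
}

#' @export
print.occu_fit <- function(x, ...) {
  cat(sprintf("Occupancy model: %d sites, logLik %.3f, K = %d%s%s\n",
              x$n_sites, x$logLik, x$K,
              if (x$converged) "" else " [NOT CONVERGED]",
              if (x$boundary) " [boundary]" else ""))
  cat("Occupancy (psi), logit scale:\n")
  print(round(cbind(estimate = x$beta_psi, se = x$se_psi), 4))
  cat("Detection (p), logit scale:\n")
  print(round(cbind(estimate = x$beta_p, se = x$se_p), 4))
  invisible(x)
}

#' @export
logLik.occu_fit <- function(object, ...) {
  structure(object$logLik, df = object$K, class = "logLik")
}

#' @export
coef.occu_fit <- function(object, ...) {
  c(stats::setNames(object$beta_psi,
                    paste0("psi_", names(object$beta_psi))),
    stats::setNames(object$beta_p, paste0("p_", names(object$beta_p))))
}

# Probability of one observed history (values v over its non-missing
# occasions) under site-level (psi, p). Vectorized over sites.
history_prob <- function(psi, p, v) {
  d1 <- sum(v == 1L); d0 <- sum(v == 0L)
  if (d1 > 0) psi * p^d1 * (1 - p)^d0
  else psi * (1 - p)^d0 + (1 - psi)
}

# Simulate a detection matrix from site-level (psi, p), preserving the
# missingness pattern of `template`.
simulate_history_matrix <- function(psi, p, template) {
  n <- nrow(template); Tt <- ncol(template)
  z <- stats::rbinom(n, 1L, psi)
  y <- matrix(stats::rbinom(n * Tt, 1L, rep(p * z, Tt)),
              nrow = n, ncol = Tt, dimnames = dimnames(template))
  y[is.na(template)] <- NA_integer_
  y
}

# MacKenzie-Bailey style Pearson chi-square: sites are grouped into
# cohorts sharing a missingness pattern; within each cohort, observed
# counts of each realised history are compared with expected counts
# summed over the cohort's site-specific (psi, p).  Realised histories
# with expected count below `pool_min` are pooled into one cell (keeps
# the statistic stable on sparse data); the probability mass of all
# unrealised histories forms a separate remainder cell with O = 0,
# contributing its expected count.
mb_chisq <- function(psi, p, y, pool_min = 0.5) {
  obs_sites <- rowSums(!is.na(y)) > 0
  y <- y[obs_sites, , drop = FALSE]
  psi <- psi[obs_sites]; p <- p[obs_sites]
  pat <- apply(is.na(y), 1, paste, collapse = "")
  chi2 <- 0
  for (cohort in split(seq_len(nrow(y)), pat)) {
    yc <- y[cohort, , drop = FALSE]
    keep <- !is.na(yc[1, ])
    vmat <- yc[, keep, drop = FALSE]
    hstr <- apply(vmat, 1, paste, collapse = "")
    ucount <- table(hstr)
    uh <- names(ucount)
    E <- vapply(uh, function(hs) {
      v <- as.integer(strsplit(hs, "")[[1]])
      sum(history_prob(psi[cohort], p[cohort], v))
    }, numeric(1))
    O <- as.numeric(ucount)
    big <- E >= pool_min
    chi2 <- chi2 + sum((O[big] - E[big])^2 / E[big])
    if (any(!big)) {
      Ep <- sum(E[!big]); Op <- sum(O[!big])
      chi2 <- chi2 + (Op - Ep)^2 / Ep
    }
    # unrealised histories: O = 0, so the cell contributes its E
    E_unobs <- length(cohort) - sum(E)
    if (E_unobs > 1e-12) chi2 <- chi2 + E_unobs
  }
  chi2
}

#' Parametric-bootstrap goodness-of-fit test
#'
#' Computes a Pearson chi-square over the expected counts of each realised
#' detection history (within cohorts of sites sharing a missingness
#' pattern), then simulates \code{n_boot} data sets from the fitted model,
#' refits, and recomputes the statistic. The bootstrap p-value is the
#' proportion of replicate statistics at least as large as the observed
#' one, and the overdispersion statistic is
#' c-hat = chi2_obs / mean(chi2_boot). Values of c-hat far above 1 (> 3)
#' or below it (< 0.90) indicate poor fit.
#'
#' @param fit converged \code{occu_fit}.
#' @param n_boot bootstrap replicates (>= 2; 1000 for production use,
#'   about 100 for quick checks).
#' @param seed RNG seed; identical seeds give identical results.
#' @return object of class \code{gof_result}: \code{chi2_obs},
#'   \code{boot_chi2}, \code{p_value}, \code{c_hat}, \code{n_boot},
#'   \code{n_failed} (dropped refit failures), \code{seed}.
#' @export
mb_gof <- function(fit, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(fit, "occu_fit"))
  if (!fit$converged) stop("goodness-of-fit requires a converged model")
  if (n_boot < 2L) stop("n_boot must be at least 2")
  chi2_obs <- mb_chisq(fit$psi_hat, fit$p_hat, fit$y)
  par0 <- c(fit$beta_psi, fit$beta_p)
  obj_for <- function(y) function(par)
    occu_negloglik(par, y, fit$Xpsi, fit$Xp)
  set.seed(seed)
  boot <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    yb <- simulate_history_matrix(fit$psi_hat, fit$p_hat, fit$y)
    ob <- obj_for(yb)
    ref <- tryCatch(
      stats::optim(par0, ob, method = "BFGS",
                   control = list(maxit = 300, reltol = 1e-9)),
      error = function(e) NULL)
    if (is.null(ref))
      ref <- tryCatch(
        stats::optim(rep(0, length(par0)), ob, method = "BFGS",
                     control = list(maxit = 300, reltol = 1e-9)),
        error = function(e) NULL)
    if (is.null(ref)) next
    kpsi <- ncol(fit$Xpsi)
    psi_b <- stats::plogis(drop(fit$Xpsi %*% ref$par[seq_len(kpsi)]))
    p_b <- stats::plogis(drop(fit$Xp %*% ref$par[-seq_len(kpsi)]))
    boot[b] <- mb_chisq(psi_b, p_b, yb)
  }
  failed <- sum(is.na(boot))
  boot <- boot[!is.na(boot)]
  if (!length(boot)) stop("all bootstrap refits failed")
  structure(list(chi2_obs = chi2_obs, boot_chi2 = boot,
                 p_value = mean(boot >= chi2_obs),
                 c_hat = chi2_obs / mean(boot),
                 n_boot = n_boot, n_failed = failed, seed = seed),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf(
    "Bootstrap GoF: chi2 = %.3f, p = %.3f, c-hat = %.3f (%d reps%s)\n",
    x$chi2_obs, x$p_value, x$c_hat, x$n_boot,
    if (x$n_failed) paste0(", ", x$n_failed, " refits dropped") else ""))
  invisible(x)
}

#' Choose the sampling-occasion length by the c-hat rule
#'
#' For each candidate occasion length k, the daily history is collapsed,
#' the operationality filter applied, the global (all-covariate) model
#' fitted and bootstrap goodness-of-fit run. Among lengths with
#' 0.90 <= c-hat <= 3 and chi-square p > 0.05, the one with c-hat closest
#' to 1 is chosen (ties go to the smaller k). If none qualifies the
#' species is flagged as having insufficient model fit — a reported
#' outcome, not an error.
#'
#' @param daily daily \code{detection_history}.
#' @param covs screened covariate table (or NULL).
#' @param psi,p formulas of the global model.
#' @param ks candidate occasion lengths (default 5:11).
#' @param min_operational_fraction station filter threshold.
#' @param n_boot bootstrap replicates per k.
#' @param seed RNG seed.
#' @return list with \code{chosen_k} (NA if none qualifies),
#'   \code{table} (per-k diagnostics), \code{fit} and \code{gof} of the
#'   chosen length (NULL when flagged).
#' @export
select_occasion_length <- function(daily, covs = NULL, psi = ~1, p = ~1,
                                   ks = 5:11,
                                   min_operational_fraction = 0.80,
                                   n_boot = 100L, seed = 1L) {
  rows <- list(); fits <- list(); gofs <- list()
  for (k in ks) {
    res <- tryCatch({
      hk <- collapse_occasions(daily, k)
      flt <- filter_stations(hk, min_operational_fraction)
      fit <- fit_occupancy(flt$history, covs, psi = psi, p = p)
      if (!fit$converged) stop("model did not converge")
      gof <- mb_gof(fit, n_boot = n_boot, seed = seed + k)
      list(fit = fit, gof = gof, n_sites = fit$n_sites)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rows[[as.character(k)]] <- data.frame(
        k = k, n_sites = NA_integer_, chi2 = NA_real_,
        p_value = NA_real_, c_hat = NA_real_, qualifies = FALSE,
        note = conditionMessage(res))
      next
    }
    fits[[as.character(k)]] <- res$fit
    gofs[[as.character(k)]] <- res$gof
    g <- res$gof
    rows[[as.character(k)]] <- data.frame(
      k = k, n_sites = res$n_sites, chi2 = g$chi2_obs,
      p_value = g$p_value, c_hat = g$c_hat,
      qualifies = g$c_hat >= 0.90 && g$c_hat <= 3 && g$p_value > 0.05,
      note = "")
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  k_star <- choose_occasion_k(tab)
  if (is.na(k_star))
    return(list(chosen_k = NA_integer_, table = tab,
                fit = NULL, gof = NULL))
  list(chosen_k = k_star, table = tab,
       fit = fits[[as.character(k_star)]],
       gof = gofs[[as.character(k_star)]])
}

#' Occasion-length decision rule
#'
#' Given a per-k diagnostics table with columns \code{k}, \code{c_hat}
#' and \code{p_value}, returns the k with c-hat closest to 1 among those
#' with 0.90 <= c-hat <= 3 and p > 0.05 (ties go to the smaller k), or NA
#' when no length qualifies (the species is then excluded for
#' insufficient model fit).
#'
#' @param tab data.frame with columns \code{k}, \code{c_hat},
#'   \code{p_value}.
#' @return chosen k (integer) or NA.
#' @export
choose_occasion_k <- function(tab) {
  ok <- !is.na(tab$c_hat) & !is.na(tab$p_value) &
    tab$c_hat >= 0.90 & tab$c_hat <= 3 & tab$p_value > 0.05
  qual <- tab[ok, , drop = FALSE]
  if (nrow(qual) == 0L) return(NA_integer_)
  # distance to 1 rounded so that e.g. 0.9 and 1.1 tie exactly despite
  # floating-point representation; ties go to the smaller k
  qual <- qual[order(round(abs(qual$c_hat - 1), 9), qual$k), ,
               drop = FALSE]
  as.integer(qual$k[1])
}
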