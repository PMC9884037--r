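# Covariate screening, QAICc ranking, two-stage model selection and
# strength-of-evidence classification.

#' Screen covariates: z-scores, dummy coding, VIF removal
#'
#' Continuous covariates are scaled to standardized z-scores; categorical
#' covariates are dummy-coded against a reference level (the first level
#' in sort order unless overridden); binary covariates pass through as
#' 0/1. Collinearity is then screened with variance inflation factors
#' (VIF = 1/(1 - R^2) from regressing each column on all others):
#' the largest-VIF column above the threshold is removed, iteratively,
#' until all retained columns are at or below it. A perfectly collinear
#' pair yields an infinite VIF and the later column (input order) is
#' removed.
#'
#' @param covs covariate data.frame with \code{station_id} (see
#'   \code{\link{read_covariates}}).
#' @param threshold VIF threshold (default 3).
#' @param reference_levels optional named list, categorical column ->
#'   reference level.
#' @return object of class \code{covariate_screen}: \code{data} (screened
#'   numeric table with \code{station_id}), \code{scaling} (per
#'   continuous covariate mean and sd), \code{dummy_map},
#'   \code{vif_trace} (data.frame of covariate, vif, removed),
#'   \code{removed}.
#' @export
screen_covariates <- function(covs, threshold = 3,
                              reference_levels = NULL) {
  covs <- validate_covariates(covs, attr(covs, "type_map"))
  tm <- attr(covs, "type_map")
  vars <- setdiff(names(covs), "station_id")
  if (length(vars) < 2L)
    stop("need at least 2 covariates to screen")
  X <- list(); scaling <- list(); dummy_map <- list()
  for (v in vars) {
    x <- covs[[v]]
    if (tm[[v]] == "continuous") {
      m <- mean(x); s <- stats::sd(x)
      if (s == 0) stop("constant continuous covariate: ", v)
      X[[v]] <- (x - m) / s
      scaling[[v]] <- c(mean = m, sd = s)
    } else if (tm[[v]] == "binary") {
      X[[v]] <- as.numeric(x)
    } else {
      lev <- sort(unique(as.character(x)))
      ref <- reference_levels[[v]]
      if (is.null(ref)) ref <- lev[1]
      if (!ref %in% lev) stop("reference level not observed for ", v)
      for (l in setdiff(lev, ref))
        X[[paste0(v, "_", l)]] <- as.numeric(x == l)
      dummy_map[[v]] <- list(reference = ref,
                             dummies = paste0(v, "_", setdiff(lev, ref)))
    }
  }
  M <- do.call(cbind, X)
  if (nrow(M) <= ncol(M))
    stop("fewer sites than covariate columns: VIF screening undefined")
  vif_one <- function(M, j) {
    fit <- stats::lm.fit(cbind(1, M[, -j, drop = FALSE]), M[, j])
    r2 <- 1 - sum(fit$residuals^2) /
      sum((M[, j] - mean(M[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  trace <- list(); removed <- character(0)
  repeat {
    if (ncol(M) < 2L) break
    vifs <- vapply(seq_len(ncol(M)), function(j) vif_one(M, j),
                   numeric(1))
    names(vifs) <- colnames(M)
    if (max(vifs) <= threshold) {
      for (v in names(vifs))
        trace[[length(trace) + 1L]] <-
          data.frame(covariate = v, vif = vifs[[v]], removed = FALSE)
      break
    }
    # worst offender; among ties (e.g. an exactly collinear pair, both
    # infinite) drop the later column in input order
    worst <- max(which(vifs == max(vifs)))
    trace[[length(trace) + 1L]] <-
      data.frame(covariate = colnames(M)[worst], vif = vifs[[worst]],
                 removed = TRUE)
    removed <- c(removed, colnames(M)[worst])
    M <- M[, -worst, drop = FALSE]
  }
  out <- data.frame(station_id = covs$station_id, M,
                    stringsAsFactors = FALSE, check.names = FALSE)
  structure(list(data = out, scaling = scaling, dummy_map = dummy_map,
                 vif_trace = do.call(rbind, trace), removed = removed,
                 threshold = threshold),
            class = "covariate_screen")
}

#' @export
print.covariate_screen <- function(x, ...) {
  cat(sprintf("Covariate screen: %d columns retained, %d removed (VIF > %g)\n",
              ncol(x$data) - 1L, length(x$removed), x$threshold))
  if (length(x$removed))
    cat("  removed:", paste(x$removed, collapse = ", "), "\n")
  invisible(x)
}

#' Quasi-likelihood small-sample information criterion
#'
#' QAICc = (-2 logL) / c-hat + 2K + 2K(K+1)/(n - K - 1). The
#' overdispersion statistic is floored at 1 (underdispersion is not used
#' to inflate the likelihood); by convention K should already include one
#' extra parameter for c-hat whenever c-hat > 1.
#'
#' @param logL maximized log-likelihood.
#' @param K parameter count (including the c-hat parameter if applicable).
#' @param n effective sample size (number of sites).
#' @param c_hat overdispersion statistic.
#' @return the QAICc value.
#' @export
qaicc <- function(logL, K, n, c_hat = 1) {
  c_hat <- max(c_hat, 1)
  if (n <= K + 1)
    stop("n must exceed K + 1 for the small-sample correction")
  (-2 * logL) / c_hat + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

# Rank a list of fitted candidates by QAICc.  Non-converged fits are
# excluded from the ranking but listed with NA scores.
rank_models <- function(fits, labels, c_hat, n) {
  K_extra <- as.integer(c_hat > 1)
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    ok <- !is.null(f) && f$converged
    data.frame(model = labels[i],
               logL = if (ok) f$logLik else NA_real_,
               K = if (ok) f$K + K_extra else NA_integer_,
               converged = ok,
               order = i)
  })
  tab <- do.call(rbind, rows)
  tab$QAICc <- NA_real_
  ok <- tab$converged
  tab$QAICc[ok] <- mapply(qaicc, tab$logL[ok], tab$K[ok],
                          MoreArgs = list(n = n, c_hat = c_hat))
  tab$delta_QAICc <- tab$QAICc - min(tab$QAICc, na.rm = TRUE)
  w <- exp(-tab$delta_QAICc / 2)
  tab$weight <- w / sum(w, na.rm = TRUE)
  # sort ascending by QAICc; ties broken by smaller K, then input order
  tab <- tab[order(tab$QAICc, tab$K, tab$order, na.last = TRUE), ,
             drop = FALSE]
  tab$order <- NULL
  rownames(tab) <- NULL
  tab
}

# All additive subsets of `pool` with at most `max_terms` terms,
# including the empty (intercept-only) model.
additive_subsets <- function(pool, max_terms) {
  out <- list(character(0))
  for (m in seq_len(min(length(pool), max_terms))) {
    cmb <- utils::combn(pool, m, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

terms_to_formula <- function(terms) {
  if (length(terms) == 0L) ~1
  else stats::reformulate(sprintf("`%s`", terms))
}

model_label <- function(p_terms, psi_terms) {
  pt <- if (length(p_terms)) paste(p_terms, collapse = "+") else "."
  st <- if (length(psi_terms)) paste(psi_terms, collapse = "+") else "."
  sprintf("psi(%s) p(%s)", st, pt)
}

#' Two-stage QAICc model selection
#'
#' Stage 1 models detection: every additive subset of
#' \code{candidates_p} (up to \code{max_terms} terms, plus the null) is
#' fitted with occupancy held at intercept-only, and ranked by QAICc
#' using the global-model overdispersion statistic. The best detection
#' structure is then fixed, and stage 2 fits every additive occupancy
#' subset of \code{candidates_psi}. Models with delta-QAICc < 2 and
#' weight > 0.10 in the occupancy stage are retained, and each covariate
#' in a retained model is classified for strength of evidence from its
#' 95% confidence interval (\code{\link{classify_evidence}}), with a
#' summed weight over the retained models containing it.
#'
#' @param h \code{detection_history} (collapsed, filtered).
#' @param covs screened covariate table (\code{screen_covariates(...)$data}).
#' @param candidates_p,candidates_psi character vectors of candidate
#'   covariate column names for detection and occupancy.
#' @param c_hat overdispersion statistic from the global-model
#'   goodness-of-fit.
#' @param max_terms maximum number of additive terms per model (default 4).
#' @param delta_max,w_min retention rule: delta-QAICc below
#'   \code{delta_max} (default 2) and weight above \code{w_min}
#'   (default 0.10).
#' @return object of class \code{two_stage_selection}: \code{p_table} and
#'   \code{psi_table} rank tables, \code{best_p_terms},
#'   \code{best_psi_terms}, \code{retained} (subset of \code{psi_table}),
#'   \code{evidence} (per covariate-parameter rows), \code{c_hat},
#'   \code{fits} (stage-2 fitted models, keyed by label).
#' @export
two_stage_selection <- function(h, covs, candidates_p, candidates_psi,
                                c_hat = 1, max_terms = 4,
                                delta_max = 2, w_min = 0.10) {
  stopifnot(inherits(h, "detection_history"))
  n <- nrow(h$y)
  fit_one <- function(psi_terms, p_terms) {
    tryCatch(fit_occupancy(h, covs,
                           psi = terms_to_formula(psi_terms),
                           p = terms_to_formula(p_terms)),
             error = function(e) NULL)
  }
  # stage 1: model p with psi(.)
  p_sets <- additive_subsets(candidates_p, max_terms)
  p_fits <- lapply(p_sets, function(tt) fit_one(character(0), tt))
  p_labels <- vapply(p_sets, function(tt) model_label(tt, character(0)),
                     character(1))
  if (!any(vapply(p_fits, function(f) !is.null(f) && f$converged,
                  logical(1))))
    stop("no detection-stage candidate converged")
  p_table <- rank_models(p_fits, p_labels, c_hat, n)
  best_p_terms <- p_sets[[match(p_table$model[1], p_labels)]]
  # stage 2: model psi with best p structure fixed
  psi_sets <- additive_subsets(candidates_psi, max_terms)
  psi_fits <- lapply(psi_sets, function(tt) fit_one(tt, best_p_terms))
  psi_labels <- vapply(psi_sets,
                       function(tt) model_label(best_p_terms, tt),
                       character(1))
  if (!any(vapply(psi_fits, function(f) !is.null(f) && f$converged,
                  logical(1))))
    stop("no occupancy-stage candidate converged")
  psi_table <- rank_models(psi_fits, psi_labels, c_hat, n)
  best_psi_terms <- psi_sets[[match(psi_table$model[1], psi_labels)]]
  retained <- psi_table[!is.na(psi_table$delta_QAICc) &
                          psi_table$delta_QAICc < delta_max &
                          psi_table$weight > w_min, , drop = FALSE]
  names(psi_fits) <- psi_labels
  evidence <- evidence_table(psi_fits, psi_sets, psi_labels,
                             best_p_terms, retained)
  structure(list(p_table = p_table, psi_table = psi_table,
                 best_p_terms = best_p_terms,
                 best_psi_terms = best_psi_terms,
                 retained = retained, evidence = evidence,
                 c_hat = c_hat, n = n, fits = psi_fits),
            class = "two_stage_selection")
}

# Per covariate-parameter evidence rows over the retained model set:
# weight is the summed Akaike weight of retained models containing the
# term; the coefficient and CI come from the highest-ranked retained
# model containing it.
evidence_table <- function(psi_fits, psi_sets, psi_labels, p_terms,
                           retained) {
  if (nrow(retained) == 0L)
    return(data.frame(covariate = character(0), parameter = character(0),
                      direction = character(0), strength = character(0),
                      weight = numeric(0)))
  rows <- list()
  ret_sets <- lapply(retained$model,
                     function(m) psi_sets[[match(m, psi_labels)]])
  psi_terms_all <- unique(unlist(ret_sets))
  for (cv in psi_terms_all) {
    has <- vapply(ret_sets, function(s) cv %in% s, logical(1))
    top <- retained$model[which(has)[1]]
    f <- psi_fits[[top]]
    cl <- classify_evidence(f$beta_psi[[cv]], f$se_psi[[cv]])
    rows[[length(rows) + 1L]] <- data.frame(
      covariate = cv, parameter = "psi", direction = cl$direction,
      strength = cl$strength, weight = sum(retained$weight[has]))
  }
  for (cv in p_terms) {
    f <- psi_fits[[retained$model[1]]]
    cl <- classify_evidence(f$beta_p[[cv]], f$se_p[[cv]])
    rows[[length(rows) + 1L]] <- data.frame(
      covariate = cv, parameter = "p", direction = cl$direction,
      strength = cl$strength, weight = sum(retained$weight))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.two_stage_selection <- function(x, ...) {
  cat(sprintf("Two-stage QAICc selection (c-hat = %.3f, n = %d sites)\n",
              x$c_hat, x$n))
  cat("Best detection structure: p(",
      if (length(x$best_p_terms)) paste(x$best_p_terms, collapse = " + ")
      else ".", ")\n", sep = "")
  cat("Occupancy-stage ranking (top 5):\n")
  top <- utils::head(x$psi_table, 5)
  top[c("logL", "QAICc", "delta_QAICc", "weight")] <-
    lapply(top[c("logL", "QAICc", "delta_QAICc", "weight")], round, 3)
  print(top, row.names = FALSE)
  if (nrow(x$evidence)) {
    cat("Evidence for covariates in retained models:\n")
    ev <- x$evidence
    ev$weight <- round(ev$weight, 3)
    print(ev, row.names = FALSE)
  }
  invisible(x)
}

#' Classify strength of evidence from a coefficient's 95% CI
#'
#' Strong when the Wald 95% confidence interval excludes zero; medium
#' when the interval overlaps zero but is not centred on it
#' (operationalized as the estimate lying more than one standard error
#' from zero); weak otherwise. Direction is the sign of the estimate.
#' The classification is scale-equivariant.
#'
#' @param beta coefficient estimate.
#' @param se standard error (> 0).
#' @return list with \code{strength} ("strong"/"medium"/"weak"),
#'   \code{direction} ("+" or "-"), and the \code{ci} bounds.
#' @export
classify_evidence <- function(beta, se) {
  if (!is.finite(se) || se <= 0) stop("se must be a positive number")
  z <- abs(beta) / se
  strength <- if (z > stats::qnorm(0.975)) "strong"
              else if (z > 1) "medium" else "weak"
  list(strength = strength,
       direction = if (beta >= 0) "+" else "-",
       ci = c(lower = beta - stats::qnorm(0.975) * se,
              upper = beta + stats::qnorm(0.975) * se))
}
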