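# Trait statistics: exhaustive OLS model enumeration over region-entropy
# predictors, ranked by small-sample-corrected AIC (AICc) with Akaike
# weights, adjusted R^2 and variance inflation factors.

#' Candidate model specification
#'
#' A response plus a set of main-effect terms (region entropies and/or
#' `body_length`) and optional interaction pairs. Marginality is enforced:
#' an interaction may only appear when both of its main effects do.
#'
#' @param response response column name (e.g. `"svd"`, `"pollen_load"`).
#' @param mains character vector of main-effect column names (may be empty:
#'   the intercept-only model).
#' @param interactions list of character pairs, e.g.
#'   `list(c("body_length", "face"))`.
#' @return A list of class `"modelSpec"`.
#' @export
modelSpec <- function(response, mains = character(0), interactions = list()) {
  mains <- unique(as.character(mains))
  for (ia in interactions) {
    if (length(ia) != 2L)
      stop("each interaction must be a pair of term names")
    if (!all(ia %in% mains))
      stop("marginality violation: interaction ", paste(ia, collapse = ":"),
           " requires both main effects")
  }
  structure(list(response = response, mains = mains,
                 interactions = interactions),
            class = "modelSpec")
}

#' @export
print.modelSpec <- function(x, ...) {
  cat(x$response, "~", modelLabel(x), "\n")
  invisible(x)
}

# human-readable term string; "(intercept)" for the null model
modelLabel <- function(spec) {
  terms <- c(spec$mains,
             vapply(spec$interactions, paste, character(1), collapse = ":"))
  if (!length(terms)) "(intercept)" else paste(terms, collapse = " + ")
}

nTerms <- function(spec) length(spec$mains) + length(spec$interactions)

# design matrix (with intercept) for a spec on complete-case rows
designMatrix <- function(table, spec) {
  X <- cbind(`(Intercept)` = rep(1, nrow(table)))
  for (m in spec$mains) X <- cbind(X, setNames(list(table[[m]]), m)[[1]])
  colnames(X) <- c("(Intercept)", spec$mains)
  for (ia in spec$interactions) {
    X <- cbind(X, table[[ia[1]]] * table[[ia[2]]])
    colnames(X)[ncol(X)] <- paste(ia, collapse = ":")
  }
  X
}

completeRows <- function(table, spec) {
  cols <- unique(c(spec$response, spec$mains, unlist(spec$interactions)))
  missing <- setdiff(cols, names(table))
  if (length(missing))
    stop("trait table lacks column(s): ", paste(missing, collapse = ", "))
  table[stats::complete.cases(table[, cols, drop = FALSE]), , drop = FALSE]
}

#' Fit one ordinary-least-squares model
#'
#' Least-squares fit with intercept on the complete-case rows for the
#' model's columns. The Gaussian log-likelihood includes its normalizing
#' constants, \eqn{L = -n/2 (\log(2\pi RSS/n) + 1)} (the convention of
#' `logLik.lm`), and the AICc parameter count is `k = p + 1` where `p`
#' counts the regression coefficients including the intercept and the
#' extra 1 is the residual variance.
#'
#' @param table trait data.frame (one row per species).
#' @param spec a [modelSpec()].
#' @return List of class `"modelFit"`: `coefficients`, `rss`, `r2`,
#'   `adj_r2`, `loglik`, `k`, `n`, `aicc`, `spec`. A perfect fit
#'   (RSS = 0) carries `loglik = Inf` with a warning and is excluded from
#'   Akaike weights by [rankModels()].
#' @examples
#' d <- data.frame(x = c(1, 2, 3), y = c(1, 2, 4))
#' f <- fitOls(d, modelSpec("y", "x"))
#' c(f$coefficients, rss = f$rss, r2 = f$r2)
#' @export
fitOls <- function(table, spec) {
  stopifnot(inherits(spec, "modelSpec"))
  tab <- completeRows(table, spec)
  n <- nrow(tab)
  y <- tab[[spec$response]]
  X <- designMatrix(tab, spec)
  p <- ncol(X)
  if (n <= p)
    stop("insufficient data: ", n, " complete rows for ", p, " coefficients")
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  res <- y - drop(X %*% beta)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  adjR2 <- 1 - (1 - r2) * (n - 1) / (n - p)
  k <- p + 1L
  if (rss <= 1e-12 * max(tss, 1)) {
    warning("perfect fit (RSS = 0) for model ", modelLabel(spec),
            "; log-likelihood reported as +Inf", call. = FALSE)
    loglik <- Inf
    aiccVal <- -Inf
  } else {
    loglik <- -n / 2 * (log(2 * pi * rss / n) + 1)
    aiccVal <- if (n - k - 1 > 0) aicc(loglik, k, n) else NA_real_
  }
  structure(list(coefficients = beta, rss = rss, r2 = r2, adj_r2 = adjR2,
                 loglik = loglik, k = k, n = n, aicc = aiccVal, spec = spec),
            class = "modelFit")
}

#' @export
print.modelFit <- function(x, ...) {
  cat(sprintf("OLS fit: %s ~ %s  (n = %d)\n", x$spec$response,
              modelLabel(x$spec), x$n))
  cat(sprintf("  RSS %.4g, R2 %.4f, adj R2 %.4f, AICc %.2f\n",
              x$rss, x$r2, x$adj_r2, x$aicc))
  invisible(x)
}

#' Small-sample-corrected Akaike information criterion
#'
#' \eqn{AIC = 2k - 2\ell}; \eqn{AICc = AIC + 2k(k+1)/(n-k-1)}, where `k`
#' counts all estimated parameters (regression coefficients including the
#' intercept, plus the residual variance).
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n sample size (must satisfy `n - k - 1 > 0`).
#' @return The AICc value.
#' @examples
#' aicc(0, 4, 10) - aicc(0, 4, 1e9)  # the correction term: 8 at n = 10
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0)
    stop("AICc undefined: n - k - 1 = ", n - k - 1, " (need > 0)")
  2 * k - 2 * loglik + 2 * k * (k + 1) / (n - k - 1)
}

#' Enumerate candidate models
#'
#' All subsets of the global main effects (including the intercept-only
#' model); when the global model holds interactions, each subset is also
#' expanded with every interaction subset that satisfies marginality.
#' Candidates whose AICc would be undefined at sample size `n`, or that
#' exceed `maxTerms` terms, are excluded (a message reports the count).
#'
#' @param mains character vector of global main-effect names.
#' @param interactions list of character pairs in the global model.
#' @param n sample size used to screen AICc finiteness.
#' @param maxTerms maximum number of terms (mains + interactions) per
#'   model; default `n - 4`.
#' @return List of [modelSpec()] objects (without responses assigned; see
#'   [rankModels()]).
#' @examples
#' length(enumerateModels(c("a", "b", "c"), n = 100))  # 2^3 = 8
#' @export
enumerateModels <- function(mains, interactions = list(), n = Inf,
                            maxTerms = if (is.finite(n)) n - 4 else Inf) {
  mains <- unique(as.character(mains))
  nm <- length(mains)
  out <- list()
  dropped <- 0L
  for (bit in 0:(2^nm - 1)) {
    ms <- mains[bitwAnd(bit, 2^(seq_len(nm) - 1)) > 0]
    ok <- Filter(function(ia) all(ia %in% ms), interactions)
    iaSets <- list(list())
    if (length(ok)) {
      iaSets <- unlist(lapply(0:(2^length(ok) - 1), function(b) {
        list(ok[bitwAnd(b, 2^(seq_along(ok) - 1)) > 0])
      }), recursive = FALSE)
    }
    for (ias in iaSets) {
      nt <- length(ms) + length(ias)
      k <- nt + 3L  # intercept + terms + residual variance, +1 for AICc test
      if (nt > maxTerms || (is.finite(n) && n - k <= 0)) {
        dropped <- dropped + 1L
        next
      }
      out[[length(out) + 1L]] <-
        structure(list(response = NA_character_, mains = ms,
                       interactions = ias), class = "modelSpec")
    }
  }
  if (dropped > 0L)
    message(dropped, " candidate model(s) excluded (too many terms for ",
            "n = ", n, ")")
  out
}

#' Rank candidate models by AICc
#'
#' Fits every candidate, ranks ascending by AICc and reports
#' \eqn{\Delta_i = AICc_i - AICc_{min}}, Akaike weights
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)} and their
#' cumulative sum in rank order. Ties are broken by fewer terms, then by
#' the lexicographic model label. Degenerate perfect fits (RSS = 0, only
#' possible on noiseless data) rank first with `aicc = -Inf` but are
#' excluded from the Akaike-weight normalization (`weight = NA`), with a
#' warning; rank-deficient candidates are dropped with a warning.
#'
#' @param table trait data.frame (see [readTraitTable()]).
#' @param response response column name.
#' @param candidates optional list of [modelSpec()]s; by default all
#'   subsets of `mains` are enumerated via [enumerateModels()].
#' @param mains global main effects; default every canonical region
#'   column present in `table`, plus `body_length` if present.
#' @param interactions `"none"` (default) or `"body_length"`, which adds
#'   `body_length x region` interactions to the global model under
#'   marginality; alternatively a list of character pairs.
#' @param maxTerms passed to [enumerateModels()].
#' @return data.frame of class `"rankingTable"`, sorted ascending by
#'   AICc, with columns `model`, `n_terms`, `adj_r2`, `aicc`, `delta`,
#'   `weight`, `acc_weight`; attribute `"n"` holds the sample size.
#' @examples
#' set.seed(1)
#' d <- data.frame(face = rnorm(10), thorax_dorsal = rnorm(10))
#' d$svd <- 2 * d$face + rnorm(10, sd = 0.1)
#' head(rankModels(d, "svd"), 3)
#' @export
rankModels <- function(table, response, candidates = NULL,
                       mains = NULL, interactions = "none",
                       maxTerms = NULL) {
  if (!response %in% names(table))
    stop("unknown response column '", response, "'")
  if (is.null(mains))
    mains <- intersect(c(canonicalRegions(), "body_length"), names(table))
  keep <- stats::complete.cases(table[, c(response, mains), drop = FALSE])
  tab <- table[keep, , drop = FALSE]
  n <- nrow(tab)
  if (n < 3L)
    stop("need at least 3 complete rows for response '", response,
         "'; found ", n)
  if (is.null(candidates)) {
    ias <- if (identical(interactions, "none")) {
      list()
    } else if (identical(interactions, "body_length")) {
      lapply(setdiff(mains, "body_length"),
             function(m) c("body_length", m))
    } else {
      interactions
    }
    if (is.null(maxTerms)) maxTerms <- n - 4
    candidates <- enumerateModels(mains, ias, n = n, maxTerms = maxTerms)
  }
  if (!length(candidates)) stop("no fittable candidate models")
  rows <- vector("list", length(candidates))
  nDropped <- 0L
  nPerfect <- 0L
  for (i in seq_along(candidates)) {
    spec <- candidates[[i]]
    spec$response <- response
    fit <- tryCatch(suppressWarnings(fitOls(tab, spec)),
                    error = function(e) NULL)
    if (is.null(fit) || is.na(fit$aicc)) {
      nDropped <- nDropped + 1L
      next
    }
    if (!is.finite(fit$aicc)) nPerfect <- nPerfect + 1L
    rows[[i]] <- data.frame(model = modelLabel(spec), n_terms = nTerms(spec),
                            adj_r2 = fit$adj_r2, aicc = fit$aicc,
                            stringsAsFactors = FALSE)
  }
  if (nDropped > 0L)
    warning(nDropped, " candidate(s) dropped (rank-deficient design, ",
            "undefined AICc, or too few rows)", call. = FALSE)
  if (nPerfect > 0L)
    warning(nPerfect, " perfect fit(s) (RSS = 0) excluded from Akaike ",
            "weights", call. = FALSE)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("all candidate models were unfittable")
  rt <- do.call(rbind, rows)
  rt <- rt[order(rt$aicc, rt$n_terms, rt$model), , drop = FALSE]
  fin <- is.finite(rt$aicc)
  rt$delta <- NA_real_
  rt$weight <- NA_real_
  if (any(fin)) {
    rt$delta[fin] <- rt$aicc[fin] - min(rt$aicc[fin])
    ew <- exp(-rt$delta[fin] / 2)
    rt$weight[fin] <- ew / sum(ew)
  }
  rt$acc_weight <- cumsum(ifelse(is.na(rt$weight), 0, rt$weight))
  rownames(rt) <- NULL
  attr(rt, "n") <- n
  class(rt) <- c("rankingTable", "data.frame")
  rt
}

#' @export
print.rankingTable <- function(x, digits = 3, ...) {
  cat(sprintf("Model ranking (n = %s), %d candidate(s):\n",
              attr(x, "n"), nrow(x)))
  print.data.frame(x, digits = digits, ...)
  invisible(x)
}

#' Variance inflation factors
#'
#' \eqn{VIF_j = 1 / (1 - R^2_j)} where \eqn{R^2_j} is from regressing
#' term `j` on the remaining terms (with intercept). Perfectly collinear
#' terms give an `Inf` sentinel with a warning.
#'
#' @param table trait data.frame.
#' @param terms character vector of at least two predictor column names.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(table, terms) {
  terms <- as.character(terms)
  if (length(terms) < 2L) stop("VIF needs at least 2 terms")
  tab <- table[stats::complete.cases(table[, terms, drop = FALSE]), terms,
               drop = FALSE]
  n <- nrow(tab)
  if (n <= length(terms) + 1L)
    stop("insufficient data for VIF: n = ", n)
  out <- setNames(numeric(length(terms)), terms)
  for (j in seq_along(terms)) {
    y <- tab[[terms[j]]]
    X <- cbind(1, as.matrix(tab[, terms[-j], drop = FALSE]))
    beta <- qr.coef(qr(X), y)
    beta[is.na(beta)] <- 0
    rss <- sum((y - drop(X %*% beta))^2)
    tss <- sum((y - mean(y))^2)
    r2 <- if (tss > 0) 1 - rss / tss else 1
    if (r2 > 1 - 1e-12) {
      warning("term '", terms[j], "' is perfectly collinear; VIF = Inf",
              call. = FALSE)
      out[j] <- Inf
    } else {
      out[j] <- 1 / (1 - r2)
    }
  }
  out
}

#' Read a species-level trait table from CSV
#'
#' Expected columns: `species`, the region entropy means (canonical names,
#' see [canonicalRegions()]), `body_length`, and one or more response
#' columns such as `svd` and `pollen_load` (responses optional; missing
#' values allowed). Column names are normalized to lower_snake_case.
#'
#' @param path CSV file path.
#' @return data.frame with one row per species.
#' @export
readTraitTable <- function(path) {
  if (!file.exists(path)) stop("trait table does not exist: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(tab) <- normalizeLabel(names(tab))
  if (!"species" %in% names(tab))
    stop("trait table lacks a 'species' column")
  if (anyDuplicated(tab$species))
    stop("duplicated species names in trait table")
  tab
}

#' Write a model ranking table to CSV
#'
#' Columns mirror the ranking layout: `model`, `adj_r2`, `aicc`, `delta`,
#' `weight`, `acc_weight`.
#'
#' @param rt a ranking table from [rankModels()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeRankingCsv <- function(rt, path) {
  utils::write.csv(
    rt[, c("model", "adj_r2", "aicc", "delta", "weight", "acc_weight")],
    path, row.names = FALSE)
  invisible(path)
}
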