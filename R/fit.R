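# Simultaneous regression models for chelate stability constants.
#
# The model estimates log K1 (mono complexes) or log beta2 (bis complexes)
# of the Mn, Fe, Co and Ni chelates from the third-order valence
# connectivity index, normalised on the nickel complex of the same ligand:
#
#   log K = a1 * x^2 + a2 * x + a3 * chi(NiB) + b,   x = chi(MB) - chi(NiB)
#
# (bis indices for log beta2). The chi difference x places every ligand's
# metal series on a common abscissa (x = 0 at Ni); the chi(NiB) term carries
# the ligand-to-ligand level. Cu is excluded: its complexes deviate strongly
# from the quadratic metal trend (it is the strongest Lewis acid of the
# Irving-Williams series), which is precisely why a single polynomial can
# cover Mn through Ni but not Cu.

#' Design features of the simultaneous stability model
#'
#' Expands stability records into the regressors of the normalised
#' quadratic model: `x` (chi difference from the Ni complex of the same
#' ligand), `x2` (its square) and `yref` (chi of that Ni complex). Cu
#' records and records lacking the requested response are dropped.
#'
#' @param data Stability records, as from [amino_acid_stability()].
#' @param chi Connectivity-index table, as from [chi_table()]; must contain
#'   a Ni row for every ligand present in `data`.
#' @param response `"K1"` (mono-complex constants, mono indices) or `"B2"`
#'   (bis-complex constants, bis indices).
#' @return Data frame with columns `metal`, `ligand`, `x`, `x2`, `yref`,
#'   `y`.
#' @export
stability_features <- function(data, chi, response = c("K1", "B2")) {
  response <- match.arg(response)
  ycol <- if (response == "K1") "logK1" else "logB2"
  species <- if (response == "K1") "mono" else "bis"
  keep <- data$metal != "Cu" & !is.na(data[[ycol]])
  d <- data[keep, , drop = FALSE]
  if (!nrow(d)) stop("no usable records for response ", response,
                     call. = FALSE)
  yref <- vapply(d$ligand, function(l) chi_lookup(chi, "Ni", l, species), 0)
  xm <- mapply(function(m, l) chi_lookup(chi, m, l, species),
               d$metal, d$ligand)
  data.frame(metal = d$metal, ligand = d$ligand,
             x = xm - yref, x2 = (xm - yref)^2, yref = yref,
             y = d[[ycol]], stringsAsFactors = FALSE, row.names = NULL)
}

#' Fit the simultaneous chelate stability model
#'
#' Ordinary least squares fit of
#' \deqn{\log K = a_1 x^2 + a_2 x + a_3\,{}^3\chi^v(\mathrm{NiB}) + b,
#'   \qquad x = {}^3\chi^v(\mathrm{MB}) - {}^3\chi^v(\mathrm{NiB})}
#' over the Mn, Fe, Co and Ni records (bis-complex indices and
#' \eqn{\log\beta_2} for `response = "B2"`), followed by leave-one-out
#' cross-validation: each record is predicted from a refit on the remaining
#' \eqn{N - 1}. The quoted standard errors use the \eqn{N - 1} denominator,
#' \eqn{\mathrm{S.E.} = \sqrt{\sum \Delta^2 / (N - 1)}}, for the fit and
#' cross-validation residuals alike.
#'
#' @inheritParams stability_features
#' @param loo Run leave-one-out cross-validation (default `TRUE`).
#' @return An object of class `"stability_fit"` with components
#'   `coefficients` (named `a1`, `a2`, `a3`, `intercept`), `se_coef`,
#'   `features`, `fitted`, `residuals`, `r` (Pearson correlation of observed
#'   and fitted), `se_fit`, and — when `loo` — `loo_pred`, `loo_residuals`,
#'   `se_cv`, `max_cv_error`. Supported methods: `print`, `summary`, `coef`,
#'   `fitted`, `residuals`, `predict`.
#' @examples
#' fit <- fit_stability("K1")
#' fit
#' predict(fit, "Mn", "glycine")
#' @export
fit_stability <- function(response = c("K1", "B2"),
                          data = amino_acid_stability(),
                          chi = chi_table(), loo = TRUE) {
  response <- match.arg(response)
  feats <- stability_features(data, chi, response)
  if (nrow(feats) < 5L) {
    stop("need at least 5 records to fit the 4-parameter model",
         call. = FALSE)
  }
  lmfit <- stats::lm(y ~ x2 + x + yref, data = feats)
  if (lmfit$rank < 4L) {
    stop("singular fit: the design matrix is rank deficient", call. = FALSE)
  }
  n <- nrow(feats)
  res <- stats::residuals(lmfit)
  cf <- stats::coef(lmfit)
  sm <- summary(lmfit)$coefficients
  ord <- c("x2", "x", "yref", "(Intercept)")
  out <- list(
    coefficients = stats::setNames(cf[ord], c("a1", "a2", "a3", "intercept")),
    se_coef = stats::setNames(sm[ord, "Std. Error"],
                              c("a1", "a2", "a3", "intercept")),
    features = feats,
    fitted = as.numeric(stats::fitted(lmfit)),
    residuals = as.numeric(res),
    r = stats::cor(feats$y, stats::fitted(lmfit)),
    se_fit = sqrt(sum(res^2) / (n - 1L)),
    n = n,
    response = response,
    species = if (response == "K1") "mono" else "bis",
    chi = chi,
    lm = lmfit,
    call = match.call()
  )
  if (loo) {
    pred <- vapply(seq_len(n), function(i) {
      fi <- stats::lm(y ~ x2 + x + yref, data = feats[-i, , drop = FALSE])
      as.numeric(stats::predict(fi, feats[i, , drop = FALSE]))
    }, 0)
    dcv <- feats$y - pred
    out$loo_pred <- pred
    out$loo_residuals <- dcv
    out$se_cv <- sqrt(sum(dcv^2) / (n - 1L))
    out$max_cv_error <- max(abs(dcv))
  }
  class(out) <- "stability_fit"
  out
}

#' @export
print.stability_fit <- function(x, digits = 3, ...) {
  lab <- if (x$response == "K1") "log K1 (mono complexes)" else
    "log beta2 (bis complexes)"
  cat("Simultaneous chelate stability model:", lab, "\n")
  cat(sprintf("  N = %d records (Mn, Fe, Co, Ni)\n", x$n))
  cf <- format(round(x$coefficients, digits))
  se <- format(round(x$se_coef, digits))
  cat(sprintf("  %s = %s (%s)\n", format(names(x$coefficients)), cf, se),
      sep = "")
  cat(sprintf("  r = %.3f   S.E. = %.2f", x$r, x$se_fit))
  if (!is.null(x$se_cv)) {
    cat(sprintf("   S.E.(cv) = %.2f   max |cv error| = %.2f",
                x$se_cv, x$max_cv_error))
  }
  cat("\n")
  invisible(x)
}

#' @export
coef.stability_fit <- function(object, ...) object$coefficients

#' @export
fitted.stability_fit <- function(object, ...) object$fitted

#' @export
residuals.stability_fit <- function(object, ...) object$residuals

#' @export
summary.stability_fit <- function(object, ...) {
  tab <- object$features
  tab$fitted <- object$fitted
  tab$residual <- object$residuals
  if (!is.null(object$loo_pred)) {
    tab$loo_pred <- object$loo_pred
    tab$loo_residual <- object$loo_residuals
  }
  structure(list(fit = object, records = tab), class = "summary.stability_fit")
}

#' @export
print.summary.stability_fit <- function(x, digits = 3, ...) {
  print(x$fit)
  cat("\nPer-record estimates:\n")
  tab <- x$records
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Predict a stability constant for a metal-ligand pair
#'
#' Evaluates the fitted simultaneous model at the connectivity indices of
#' the requested chelate. Works for any supported ligand of Mn, Fe, Co or
#' Ni, including pairs without experimental data. Cu is refused: the model
#' is fitted without Cu because its complexes deviate strongly from the
#' quadratic trend shared by the other four metals.
#'
#' @param object A `"stability_fit"`.
#' @param metal,ligand Character vectors (recycled to common length).
#' @param chi Connectivity table to take the indices from; defaults to the
#'   one the model was fitted with.
#' @param ... Unused.
#' @return Numeric vector of predicted log-constants.
#' @export
predict.stability_fit <- function(object, metal, ligand, chi = object$chi,
                                  ...) {
  k <- max(length(metal), length(ligand))
  metal <- rep_len(metal, k); ligand <- rep_len(ligand, k)
  if (any(metal == "Cu")) {
    stop("Cu is excluded from the simultaneous model: Cu(II) chelates ",
         "deviate strongly from the quadratic Mn-Ni trend; use ",
         "fit_linear_per_metal() for Cu", call. = FALSE)
  }
  bad <- !metal %in% c("Mn", "Fe", "Co", "Ni")
  if (any(bad)) {
    stop("unsupported metal for prediction: ",
         paste(unique(metal[bad]), collapse = ", "), call. = FALSE)
  }
  cf <- object$coefficients
  vapply(seq_len(k), function(i) {
    yref <- chi_lookup(chi, "Ni", ligand[i], object$species)
    x <- chi_lookup(chi, metal[i], ligand[i], object$species) - yref
    unname(cf["a1"] * x^2 + cf["a2"] * x + cf["a3"] * yref + cf["intercept"])
  }, 0)
}
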