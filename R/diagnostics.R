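# Diagnostic fits behind the simultaneous model: within one metal the
# stability constants fall linearly with the connectivity index from
# glycine to leucine; within one ligand the four metals Mn-Ni follow a
# quadratic, from which Cu deviates upward.

#' Linear stability trend within one metal
#'
#' Least-squares line of the stability constant against the third-order
#' valence connectivity index over the ligands of a single metal. For every
#' supported metal — Cu included — the slope is negative: bulkier side
#' chains raise chi and lower stability.
#'
#' @param metal A supported metal symbol (Cu allowed here).
#' @inheritParams stability_features
#' @return List with `slope`, `intercept`, `r` and `n`.
#' @export
fit_linear_per_metal <- function(metal, response = c("K1", "B2"),
                                 data = amino_acid_stability(),
                                 chi = chi_table()) {
  response <- match.arg(response)
  ycol <- if (response == "K1") "logK1" else "logB2"
  species <- if (response == "K1") "mono" else "bis"
  d <- data[data$metal == metal & !is.na(data[[ycol]]), , drop = FALSE]
  if (nrow(d) < 2L) {
    stop("need at least 2 records for metal ", metal, call. = FALSE)
  }
  xs <- vapply(d$ligand, function(l) chi_lookup(chi, metal, l, species), 0)
  f <- stats::lm(d[[ycol]] ~ xs)
  list(slope = unname(stats::coef(f)[2L]),
       intercept = unname(stats::coef(f)[1L]),
       r = stats::cor(d[[ycol]], stats::fitted(f)) *
         sign(unname(stats::coef(f)[2L])),
       n = nrow(d))
}

#' Quadratic metal trend within one ligand
#'
#' Least-squares quadratic of the stability constant against the
#' connectivity index over the non-Cu metals (Mn, Fe, Co, Ni) of a single
#' ligand, plus the deviation of Cu from the extrapolated curve. The
#' deviation is positive: Cu(II), the strongest Lewis acid of the
#' Irving-Williams series, is more stable than the quadratic trend of the
#' other four metals predicts.
#'
#' @param ligand A supported ligand name.
#' @inheritParams stability_features
#' @return List with `coefficients` (named `c2`, `c1`, `c0` of
#'   \eqn{c_2\chi^2 + c_1\chi + c_0}), `residuals` (over the non-Cu
#'   points), `cu_deviation` (observed Cu value minus extrapolation; `NA`
#'   if Cu has no datum) and `n`.
#' @export
fit_quadratic_per_ligand <- function(ligand, response = c("K1", "B2"),
                                     data = amino_acid_stability(),
                                     chi = chi_table()) {
  response <- match.arg(response)
  ycol <- if (response == "K1") "logK1" else "logB2"
  species <- if (response == "K1") "mono" else "bis"
  d <- data[data$metal != "Cu" & data$ligand == ligand &
              !is.na(data[[ycol]]), , drop = FALSE]
  if (nrow(d) < 3L) {
    stop("need at least 3 non-Cu records for ligand ", ligand, call. = FALSE)
  }
  xs <- vapply(d$metal, function(m) chi_lookup(chi, m, ligand, species), 0)
  f <- stats::lm(d[[ycol]] ~ I(xs^2) + xs)
  cf <- stats::setNames(unname(stats::coef(f)[c(2L, 3L, 1L)]),
                        c("c2", "c1", "c0"))
  cu_row <- data[data$metal == "Cu" & data$ligand == ligand, , drop = FALSE]
  cu_dev <- NA_real_
  if (nrow(cu_row) == 1L && !is.na(cu_row[[ycol]])) {
    xcu <- chi_lookup(chi, "Cu", ligand, species)
    cu_dev <- cu_row[[ycol]] - (cf["c2"] * xcu^2 + cf["c1"] * xcu + cf["c0"])
    cu_dev <- unname(cu_dev)
  }
  list(coefficients = cf, residuals = as.numeric(stats::residuals(f)),
       cu_deviation = cu_dev, n = nrow(d))
}
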