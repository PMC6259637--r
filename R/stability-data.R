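# Experimental stability constants of the metal(II) amino-acid chelates.

#' Experimental chelate stability constants
#'
#' The curated set of experimental stability constants for the metal(II)
#' mono- (\eqn{\log K_1}) and bis- (\eqn{\log \beta_2}) amino-acid chelates:
#' literature means measured at 25 degC (three Fe entries at 20 degC) and
#' ionic strength 0.01 mol/L or extrapolated to zero. Missing determinations
#' (\eqn{\log K_1} of Fe/alanine and Fe/valine; both constants of Ni/valine)
#' are `NA`. Zinc, though part of the Irving-Williams order, has no data and
#' no row.
#'
#' @param file Path of the CSV fixture to read. Defaults to the copy shipped
#'   with the package.
#' @return A data frame with columns `metal`, `ligand`, `logK1`, `logB2`
#'   (18 rows). Values are dimensionless (decadic log units).
#' @examples
#' tab <- amino_acid_stability()
#' subset(tab, metal == "Mn" & ligand == "glycine")
#' @export
amino_acid_stability <- function(file = system.file("extdata",
                                                    "stability_constants.csv",
                                                    package = "chelstab",
                                                    mustWork = TRUE)) {
  read_stability_csv(file)
}

#' Read or write a stability-constant table as CSV
#'
#' The CSV dialect has columns `metal`, `ligand`, `logK1`, `logB2`; an empty
#' cell means the constant was not determined (round-trips as `NA`).
#'
#' @param file Path to read from / write to.
#' @param x A data frame as returned by [amino_acid_stability()].
#' @return `read_stability_csv()` returns the data frame;
#'   `write_stability_csv()` returns `file` invisibly.
#' @export
read_stability_csv <- function(file) {
  x <- utils::read.csv(file, stringsAsFactors = FALSE,
                       colClasses = c(metal = "character",
                                      ligand = "character",
                                      logK1 = "numeric", logB2 = "numeric"))
  need <- c("metal", "ligand", "logK1", "logB2")
  if (!all(need %in% names(x))) {
    stop("stability CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  x[need]
}

#' @rdname read_stability_csv
#' @export
write_stability_csv <- function(x, file) {
  utils::write.csv(x, file, row.names = FALSE, na = "", quote = FALSE)
  invisible(file)
}
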