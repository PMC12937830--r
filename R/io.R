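#' Read long-format longitudinal phenotypes
#'
#' Expects a delimited text file with a header and columns \code{id},
#' \code{time}, \code{value} (extra columns are kept). Rows with missing or
#' non-finite time/value are dropped with a message giving the count.
#'
#' @param path File path.
#' @param sep Field separator (default tab; \code{","} for CSV).
#' @return Data frame with character \code{id} and numeric \code{time},
#'   \code{value}.
#' @export
read_phenotypes <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("id", "time", "value")
  if (!all(need %in% names(df)))
    stop("phenotype file must have header columns id, time, value")
  df$id <- as.character(df$id)
  df$time <- suppressWarnings(as.numeric(df$time))
  df$value <- suppressWarnings(as.numeric(df$value))
  bad <- !is.finite(df$time) | !is.finite(df$value)
  if (any(bad)) {
    message(sum(bad), " malformed phenotype row(s) skipped")
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no usable phenotype rows in ", path)
  df
}

#' Write curve fits to a tab-separated table
#'
#' One row per individual: id, family, coefficients, n_obs, residual
#' variance, R-squared, AIC, BIC, converged.
#'
#' @param fits A \code{growth_fit_list} (or list of \code{growth_fit}).
#' @param path Output file; \code{""} writes to stdout.
#' @return The data frame written, invisibly.
#' @export
write_curve_fits <- function(fits, path) {
  df <- as.data.frame(fits)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' @export
as.data.frame.growth_fit_list <- function(x, ...) {
  d <- x[[1]]$params$d
  cf <- t(vapply(x, function(f) f$params$coefficients, numeric(d)))
  colnames(cf) <- paste0("coefficient_", seq_len(d))
  data.frame(
    id = vapply(x, function(f) if (is.null(f$id)) NA_character_ else f$id, ""),
    family = vapply(x, function(f) f$params$family, ""),
    cf,
    n_obs = vapply(x, `[[`, 0L, "n_obs"),
    residual_variance = vapply(x, `[[`, 0, "residual_variance"),
    r_squared = vapply(x, `[[`, 0, "r_squared"),
    aic = vapply(x, `[[`, 0, "aic"),
    bic = vapply(x, `[[`, 0, "bic"),
    converged = vapply(x, `[[`, TRUE, "converged"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Read a curve-fit table written by \code{\link{write_curve_fits}}
#'
#' @param path Tab-separated file with the \code{write_curve_fits} layout.
#' @return List with \code{P} (regression-phenotype matrix of converged
#'   fits, row names the ids), \code{family}, and the full \code{table}.
#' @export
read_curve_fits <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  cc <- grep("^coefficient_", names(df))
  keep <- as.logical(df$converged)
  P <- as.matrix(df[keep, cc, drop = FALSE])
  rownames(P) <- df$id[keep]
  fam <- unique(df$family)
  if (length(fam) != 1L) stop("curve-fit table mixes families: ",
                              paste(fam, collapse = ", "))
  colnames(P) <- if (fam == "legendre") paste0("c", seq_along(cc) - 1L)
                 else family_coef_names(fam)
  list(P = P, family = fam, table = df)
}
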