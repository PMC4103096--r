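#' Construct a polytomous regression dataset
#'
#' Bundles a categorical response and an intercept-augmented design matrix
#' into the container used by all fitting functions.  Response labels may be
#' arbitrary (integer, character, factor); they are mapped to the internal
#' codes `1..J` in order of first appearance unless an explicit `levels`
#' ordering is supplied.  Category 1 (the first level) is the reference
#' category throughout the package.
#'
#' @param responses vector of category labels, one per observation.
#' @param covariates numeric matrix or data frame of covariates, `n` rows by
#'   `p` columns, *without* an intercept column (it is added here).  At least
#'   one covariate is expected to be continuous for the robust machinery to
#'   be meaningful, but this is not enforced.
#' @param levels optional character/integer vector giving the category order;
#'   the first entry becomes the reference category.
#' @return An object of class `plrm_data`: a list with elements `y` (integer
#'   codes in `1..J`), `x` (the `n x (p+1)` design matrix with leading
#'   intercept column), `levels`, `J`, `n` and `p`.
#' @examples
#' d <- plrm_data(c("a", "b", "c", "a"), cbind(x1 = rnorm(4)))
#' d$J
#' @export
plrm_data <- function(responses, covariates, levels = NULL) {
  covariates <- as.matrix(covariates)
  storage.mode(covariates) <- "double"
  n <- length(responses)
  if (nrow(covariates) != n)
    stop("`responses` and `covariates` disagree on the number of observations")
  if (anyNA(responses) || anyNA(covariates))
    stop("missing values are not allowed; drop or impute them first")

  lab <- as.character(responses)
  if (is.null(levels)) {
    levels <- unique(lab)
  } else {
    levels <- as.character(levels)
    unknown <- setdiff(unique(lab), levels)
    if (length(unknown))
      stop("responses contain labels not in `levels`: ",
           paste(unknown, collapse = ", "))
  }
  J <- length(levels)
  if (J < 2L) stop("the response must have at least 2 observed categories")
  y <- match(lab, levels)
  if (any(tabulate(y, J) == 0L))
    stop("every category in `levels` must be observed at least once; empty: ",
         paste(levels[tabulate(y, J) == 0L], collapse = ", "))

  p <- ncol(covariates)
  if (is.null(colnames(covariates)))
    colnames(covariates) <- paste0("x", seq_len(p))
  x <- cbind(`(Intercept)` = 1, covariates)

  npar <- (p + 1L) * (J - 1L)
  if (n < npar)
    stop("need at least ", npar, " observations to identify ", npar,
         " parameters; got ", n)

  structure(list(y = as.integer(y), x = x, levels = levels,
                 J = J, n = n, p = p),
            class = "plrm_data")
}

#' @export
print.plrm_data <- function(x, ...) {
  cat("Polytomous regression data: n =", x$n, ", J =", x$J,
      "categories, p =", x$p, "covariates\n")
  cat("Reference category:", x$levels[1L], "\n")
  cat("Category counts:\n")
  print(stats::setNames(tabulate(x$y, x$J), x$levels))
  invisible(x)
}

#' Read a dataset from a delimited text file
#'
#' Reads a CSV or TSV file (header required, delimiter inferred from the file
#' extension unless given) and assembles a [plrm_data] object.  Rows with
#' missing values in the used columns are dropped with a message.
#'
#' @param path path to the file.
#' @param response name of the response column.
#' @param covariates character vector of covariate column names.
#' @param levels optional explicit category order (first = reference).
#' @param sep field delimiter; defaults to `"\t"` for `.tsv`/`.txt`, `","`
#'   otherwise.
#' @return A [plrm_data] object.
#' @export
load_dataset <- function(path, response, covariates, levels = NULL,
                         sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(c(response, covariates), names(df))
  if (length(missing_cols))
    stop("columns not found in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  used <- df[, c(response, covariates), drop = FALSE]
  ok <- stats::complete.cases(used)
  if (!all(ok))
    message("dropping ", sum(!ok), " row(s) with missing values")
  used <- used[ok, , drop = FALSE]
  xm <- as.matrix(used[, covariates, drop = FALSE])
  storage.mode(xm) <- "double"
  const <- apply(xm, 2L, function(col) diff(range(col)) == 0)
  if (any(const))
    stop("constant covariate column(s): ",
         paste(covariates[const], collapse = ", "))
  plrm_data(used[[response]], xm, levels = levels)
}

.ystar <- function(data) {
  # n x (J-1) indicator matrix over categories 2..J (category 1 dropped)
  out <- matrix(0, data$n, data$J - 1L)
  keep <- data$y >= 2L
  out[cbind(which(keep), data$y[keep] - 1L)] <- 1
  out
}
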