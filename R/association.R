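#' Spearman rank correlation of two vectors
#'
#' Pearson correlation of mid-ranks (ties receive average ranks). Pairs with
#' a missing value in either vector are excluded. A constant vector makes
#' the coefficient undefined: `NA` is returned with a warning.
#'
#' @param x,y Numeric vectors of equal length (at least 3 complete pairs).
#' @return Spearman's rho in \[-1, 1\], or `NA`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) abort("fewer than 3 complete pairs")
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    warn("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  cor(rx, ry)
}

#' Cross-correlation matrix of two score tables
#'
#' Computes Spearman's rho between every column of `a` and every column of
#' `b` over the patients the two tables share, with pairwise-complete
#' deletion per cell (the number of pairs actually used is recorded per
#' cell). With `b = NULL` the correlation of `a` with itself is returned.
#'
#' @param a,b Tibbles: `patient_id` plus numeric columns (scores or cell
#'   fractions).
#' @return A `cor_tbl`: long tibble with columns `row`, `column`, `rho`,
#'   `n_pairs`, carrying the row/column label sets as attributes. Use
#'   [cor_matrix()] for the wide matrix form.
#' @export
cross_correlate <- function(a, b = NULL) {
  ma <- table_to_matrix(a, "a")
  symmetric <- is.null(b)
  mb <- if (symmetric) ma else table_to_matrix(b, "b")
  shared <- intersect(rownames(ma), rownames(mb))
  if (length(shared) < 3L) abort("fewer than 3 shared patients")
  ma <- ma[shared, , drop = FALSE]
  mb <- mb[shared, , drop = FALSE]
  grid <- tidyr::expand_grid(row = colnames(ma), column = colnames(mb))
  res <- purrr::pmap_dfr(grid, function(row, column) {
    x <- ma[, row]; y <- mb[, column]
    ok <- is.finite(x) & is.finite(y)
    rho <- if (sum(ok) < 3L) NA_real_ else
      suppressWarnings(spearman_rho(x[ok], y[ok]))
    tibble(row = row, column = column, rho = rho, n_pairs = sum(ok))
  })
  structure(res,
            row_labels = colnames(ma), col_labels = colnames(mb),
            symmetric = symmetric,
            class = c("cor_tbl", class(res)))
}

#' Wide matrix form of a correlation table
#'
#' @param x A `cor_tbl` from [cross_correlate()].
#' @return Numeric matrix of rho values (rows/columns as labelled).
#' @export
cor_matrix <- function(x) {
  stopifnot(inherits(x, "cor_tbl"))
  rows <- attr(x, "row_labels"); cols <- attr(x, "col_labels")
  m <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  m[cbind(match(x$row, rows), match(x$column, cols))] <- x$rho
  m
}

#' Correlation profiles of gene signatures over radiomic signatures
#'
#' Reshapes a gene-by-radiomic `cor_tbl` into the items-by-dimensions
#' profile matrix consumed by the cluster-stability filter: one row per gene
#' signature, one column per radiomic signature.
#'
#' @param x A `cor_tbl` with gene signatures as rows.
#' @return Numeric matrix (gene signatures x radiomic signatures).
#' @export
correlation_profiles <- function(x) {
  m <- cor_matrix(x)
  if (anyNA(m)) abort("correlation profiles contain undefined cells")
  m
}

#' Write a correlation table to CSV files
#'
#' Writes the wide matrix (`<stem>.csv`) and the long form with pair counts
#' (`<stem>_long.tsv`).
#'
#' @param x A `cor_tbl`.
#' @param stem Output path without extension.
#' @return The paths written, invisibly.
#' @export
write_cor_tbl <- function(x, stem) {
  wide <- cor_matrix(x)
  p1 <- paste0(stem, ".csv")
  p2 <- paste0(stem, "_long.tsv")
  write.csv(data.frame(row = rownames(wide), wide, check.names = FALSE),
            p1, row.names = FALSE)
  utils::write.table(as.data.frame(x), p2, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(p1, p2))
}
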