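#' Build a treatment-means table
#'
#' Collapses a long-format table (`treatment, variable, value`, or an
#' endpoint table with replicate values) to one row per treatment and one
#' column per variable, the input expected by [pearson_matrix()]. Wide
#' input (first column `treatment`, the rest numeric) is passed through.
#'
#' @param x data.frame, long or wide.
#' @return data.frame with rownames = treatments, numeric columns.
#' @export
treatment_means <- function(x) {
  x <- as.data.frame(x)
  if (all(c("treatment", "variable", "value") %in% names(x))) {
    agg <- stats::aggregate(value ~ treatment + variable, data = x, FUN = mean)
    wide <- stats::reshape(agg, idvar = "treatment", timevar = "variable",
                           direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
  } else if (all(c("endpoint", "treatment", "value") %in% names(x))) {
    return(treatment_means(data.frame(treatment = x$treatment,
                                      variable = x$endpoint,
                                      value = x$value)))
  } else if ("treatment" %in% names(x)) {
    wide <- x
  } else {
    stop("expected long (treatment,variable,value) or wide (treatment + numeric columns) input")
  }
  rownames(wide) <- wide$treatment
  wide$treatment <- NULL
  for (nm in names(wide)) wide[[nm]] <- as.numeric(wide[[nm]])
  wide
}

#' Pearson correlation matrix of treatment-wise averages
#'
#' Pairwise Pearson coefficients between all variables across treatments
#' (the rows). With the typical four-dose design this is an n = 4
#' exploratory correlation: the result carries an `n` attribute and no
#' p-values are attached -- significance testing at n = 4 would be
#' statistically meaningless, and the coefficients describe association,
#' not causality. Zero-variance variables give `NA` entries and a warning
#' (flagged, not silently zero).
#'
#' @param table treatment-means data.frame (see [treatment_means()]);
#'   needs at least 3 treatments.
#' @return An object of class `"correlation_matrix"`: symmetric numeric
#'   matrix with unit diagonal, attributes `n` (treatments) and
#'   `flagged` (zero-variance variable names).
#' @export
pearson_matrix <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) < 3) stop("need at least 3 treatments for a defined correlation")
  if (anyNA(m)) stop("missing cells in the treatment-means table")
  sds <- apply(m, 2, stats::sd)
  flagged <- colnames(m)[sds == 0]
  if (length(flagged)) {
    warning("zero-variance variable(s): ", paste(flagged, collapse = ", "),
            "; correlations undefined (NA)")
  }
  R <- suppressWarnings(stats::cor(m, method = "pearson"))
  diag(R) <- ifelse(colnames(R) %in% flagged, NA_real_, 1)
  attr(R, "n") <- nrow(m)
  attr(R, "flagged") <- flagged
  class(R) <- c("correlation_matrix", "matrix")
  R
}

#' Export a correlation heatmap
#'
#' Square heatmap of a correlation matrix with a diverging palette whose
#' colour limits are fixed at -1 and +1 regardless of the data range.
#' Variables are drawn in the column order of the matrix (order the input
#' plant-block then insect-block for the conventional layout, or pass
#' `order`).
#'
#' @param M a `"correlation_matrix"`.
#' @param path output image file (`.png`).
#' @param order optional character vector giving the variable display
#'   order.
#' @return `path`, invisibly.
#' @export
export_heatmap <- function(M, path, order = NULL) {
  stopifnot(inherits(M, "correlation_matrix"))
  m <- unclass(M)
  if (!is.null(order)) {
    if (!all(order %in% colnames(m))) stop("unknown variable in `order`")
    m <- m[order, order]
  }
  breaks <- seq(-1, 1, length.out = 101)
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(100)
  pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                     breaks = breaks, color = pal, na_col = "grey80",
                     display_numbers = ncol(m) <= 12, number_format = "%.2f",
                     filename = path, silent = TRUE)
  invisible(path)
}

#' Write a correlation matrix as TSV
#' @param M a `"correlation_matrix"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_correlation <- function(M, path) {
  df <- data.frame(variable = rownames(M), unclass(M), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
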