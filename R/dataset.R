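#' Construct a VimDataset
#'
#' @param X numeric matrix or data.frame of feature values (samples x
#'   features). Columns are named; unnamed columns get names \code{f1..fd}.
#' @param y class labels (factor, character or integer), one per sample.
#' @param name dataset identifier used in reports.
#' @return A \linkS4class{VimDataset}.
#' @examples
#' d <- VimDataset(matrix(rnorm(40), 20, 2), rep(c("a", "b"), 10))
#' nSamples(d); nFeatures(d); nClasses(d)
#' @export
VimDataset <- function(X, y, name = "dataset") {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- droplevels(as.factor(y))
  new("VimDataset", X = X, y = y, name = as.character(name))
}

#' Accessors for VimDataset
#'
#' \code{nSamples}, \code{nFeatures}, \code{nClasses} return the dataset
#' dimensions; \code{featureIds} the feature names in column order;
#' \code{classLabels} the label factor; \code{featureMatrix} the raw matrix;
#' \code{datasetName} the identifier.
#'
#' @param x a \linkS4class{VimDataset}.
#' @name VimDataset-accessors
#' @aliases nSamples nFeatures nClasses featureIds classLabels datasetName
#'   featureMatrix
NULL

#' @rdname VimDataset-accessors
setMethod("nSamples", "VimDataset", function(x) nrow(x@X))
#' @rdname VimDataset-accessors
setMethod("nFeatures", "VimDataset", function(x) ncol(x@X))
#' @rdname VimDataset-accessors
setMethod("nClasses", "VimDataset", function(x) nlevels(x@y))
#' @rdname VimDataset-accessors
setMethod("featureIds", "VimDataset", function(x) colnames(x@X))
#' @rdname VimDataset-accessors
setMethod("classLabels", "VimDataset", function(x) x@y)
#' @rdname VimDataset-accessors
setMethod("datasetName", "VimDataset", function(x) x@name)
#' @rdname VimDataset-accessors
setMethod("featureMatrix", "VimDataset", function(x) x@X)

setMethod("show", "VimDataset", function(object) {
  cat("VimDataset '", object@name, "': ", nrow(object@X), " samples, ",
      ncol(object@X), " features, ", nlevels(object@y), " classes\n",
      sep = "")
})

#' Subset a VimDataset by samples
#'
#' @param x a \linkS4class{VimDataset}.
#' @param i sample indices to keep.
#' @param j,...,drop ignored (features are never subset; rankings refer to
#'   the full feature set).
#' @export
setMethod("[", "VimDataset", function(x, i, j, ..., drop = FALSE) {
  VimDataset(x@X[i, , drop = FALSE], droplevels(x@y[i]), x@name)
})

sniffSep <- function(path) {
  line <- readLines(path, n = 1L)
  if (lengths(regmatches(line, gregexpr("\t", line))) > 0L) "\t" else ","
}

#' Load a delimited classification dataset
#'
#' Reads a comma- or tab-separated file (delimiter sniffed from the header
#' row) with one header line of column names, one row per sample, numeric
#' feature columns and one class-label column. Missing or non-numeric feature
#' cells are rejected with a row/column diagnostic.
#'
#' @param path path to the delimited text file.
#' @param label label column, by name or by 1-based column index.
#' @param name dataset identifier; defaults to the file name.
#' @return A \linkS4class{VimDataset}; feature identity follows the column
#'   order of the file with the label column removed.
#' @export
loadDataset <- function(path, label, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sniffSep(path)
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (is.numeric(label)) {
    if (label < 1 || label > ncol(df))
      stop("label column index ", label, " out of range")
    labIdx <- as.integer(label)
  } else {
    labIdx <- match(label, colnames(df))
    if (is.na(labIdx)) stop("label column '", label, "' not found")
  }
  y <- df[[labIdx]]
  feats <- df[, -labIdx, drop = FALSE]
  for (j in seq_along(feats)) {
    v <- feats[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      stop("non-numeric value in column '", colnames(feats)[j], "'",
           if (length(bad)) paste0(", row ", bad[1L]) else "")
    }
  }
  X <- as.matrix(feats)
  if (anyNA(X)) {
    cell <- which(is.na(X), arr.ind = TRUE)[1L, ]
    stop("missing value at row ", cell[1L], ", column '",
         colnames(X)[cell[2L]], "'")
  }
  if (anyNA(y)) stop("missing value in label column, row ",
                     which(is.na(y))[1L])
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  VimDataset(X, y, name)
}

#' Write a VimDataset to delimited text
#'
#' Inverse of \code{\link{loadDataset}}: writes the feature columns followed
#' by a \code{class} label column.
#'
#' @param data a \linkS4class{VimDataset}.
#' @param path output file path.
#' @param sep field separator ("," or "\t").
#' @export
writeDataset <- function(data, path, sep = ",") {
  df <- as.data.frame(featureMatrix(data), check.names = FALSE)
  df[["class"]] <- as.character(classLabels(data))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
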