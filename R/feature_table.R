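#' Construct a residue feature table
#'
#' The basic data container of the package: one row per interface
#' residue, numeric feature columns, an optional binary hot-spot label
#' (1 = hot spot, 0 = non-hot spot) and an identifier per row. Features
#' are assumed unitless; no scaling is applied here.
#'
#' @param X numeric matrix (or data frame of numerics), N rows x D features.
#' @param y optional integer/numeric vector of labels in \{0, 1\}.
#' @param ids optional character vector of unique sample identifiers;
#'   defaults to `s1..sN`.
#' @return An object of class `feature_table`: a list with elements
#'   `X` (numeric matrix), `y` (integer vector or NULL), `ids`.
#' @export
feature_table <- function(X, y = NULL, ids = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) > 0 && any(!is.finite(X))) {
    bad <- which(apply(X, 1, function(r) any(!is.finite(r))))
    stop("non-finite feature values in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  if (is.null(colnames(X)) && ncol(X) > 0)
    colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (!is.null(y)) {
    if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
    if (!all(y %in% c(0, 1))) stop("labels must be 0 (non-hot spot) or 1 (hot spot)")
    y <- as.integer(y)
  }
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(X)))
  ids <- as.character(ids)
  if (length(ids) != nrow(X)) stop("length(ids) must equal nrow(X)")
  if (anyDuplicated(ids)) stop("duplicate sample identifiers")
  structure(list(X = X, y = y, ids = ids), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$X), "samples x", ncol(x$X), "features")
  if (!is.null(x$y))
    cat(";", sum(x$y == 1), "hot spots /", sum(x$y == 0), "non-hot spots")
  cat("\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$X)

#' Subset a feature table by row
#' @param x a `feature_table`.
#' @param i row index vector.
#' @param ... unused.
#' @return A `feature_table` with the selected rows.
#' @export
`[.feature_table` <- function(x, i, ...) {
  feature_table(x$X[i, , drop = FALSE],
                if (!is.null(x$y)) x$y[i] else NULL,
                x$ids[i])
}

#' Read a residue feature table from delimited text
#'
#' Expects a header row; by default the first column holds sample
#' identifiers and the last column the 0/1 label. Lines starting with
#' `#` (provenance headers written by this package) are skipped.
#' Every remaining column must be numeric; any non-numeric cell is
#' reported by row and column name.
#'
#' @param path CSV (or TSV, by extension `.tsv`/`.txt`) file path.
#' @param id_col column name or index of identifiers (default 1).
#' @param label_col column name or index of the label column, or NA for
#'   an unlabelled table (default: last column).
#' @return A [feature_table].
#' @export
read_feature_table <- function(path, id_col = 1, label_col = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop("feature table needs at least an id and one feature column")
  col_idx <- function(col) {
    if (is.character(col)) {
      j <- match(col, names(df))
      if (is.na(j)) stop("column not found: ", col)
      j
    } else as.integer(col)
  }
  idj <- col_idx(id_col)
  labj <- if (is.null(label_col)) ncol(df)
          else if (length(label_col) == 1 && is.na(label_col)) NA_integer_
          else col_idx(label_col)
  ids <- as.character(df[[idj]])
  y <- NULL
  featj <- setdiff(seq_along(df), c(idj, if (!is.na(labj)) labj))
  if (!is.na(labj)) {
    y <- df[[labj]]
    if (!all(y %in% c(0, 1)))
      stop("label column '", names(df)[labj], "' must contain only 0/1")
  }
  X <- matrix(NA_real_, nrow(df), length(featj),
              dimnames = list(NULL, names(df)[featj]))
  for (m in seq_along(featj)) {
    v <- df[[featj[m]]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v))
    if (length(bad) || anyNA(v))
      stop("non-numeric or missing value in column '", names(df)[featj[m]],
           "', row ", if (length(bad)) bad[1] else which(is.na(v))[1])
    X[, m] <- num
  }
  feature_table(X, y, ids)
}

#' Write a feature table as CSV
#'
#' Inverse of [read_feature_table]: id column first, features, then the
#' label column (if present). An optional provenance comment line is
#' prepended. The write is atomic (temp file + rename).
#'
#' @param table a [feature_table].
#' @param path output path.
#' @param provenance optional single comment line (without leading `#`).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, provenance = NULL) {
  df <- data.frame(id = table$ids, table$X, check.names = FALSE)
  if (!is.null(table$y)) df$label <- table$y
  atomic_write(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  })
}
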