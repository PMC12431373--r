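#' Feature schema of the gallstone screening table
#'
#' Returns the 38-feature clinical schema used throughout the package:
#' demographics and bioimpedance measurements, comorbidity flags, and
#' laboratory values, each typed as binary, categorical, integer or
#' continuous. Feature indices are 0-based, matching the published index
#' convention for this dataset, and are used consistently in fold outcomes,
#' consolidated configurations and explanations.
#'
#' @return A data.frame with columns `index` (integer, 0..37), `name`
#'   (character), `kind` (one of `"binary"`, `"categorical"`, `"integer"`,
#'   `"continuous"`) and `description`.
#' @examples
#' sch <- gallstone_schema()
#' sch[sch$name %in% c("CRP", "Vitamin D", "AAST"), ]
#' @export
gallstone_schema <- function() {
  sch <- data.frame(
    index = 0:37,
    name = c(
      "Age", "Gender", "Comorbidity", "CAD", "Hypothyroidism",
      "Hyperlipidemia", "DM", "Height", "Weight", "BMI",
      "TBW", "ECW", "ICW", "ECF/TBW", "TBFR",
      "LM", "Protein", "VFR", "BM", "MM",
      "Obesity", "TFC", "VFA", "VMA", "HFA",
      "Glucose", "TC", "LDL", "HDL", "Triglyceride",
      "AAST", "ALT", "ALP", "Creatinine", "GFR",
      "CRP", "HGB", "Vitamin D"
    ),
    kind = c(
      "integer", "categorical", "categorical", "binary", "binary",
      "binary", "binary", "integer", "continuous", "continuous",
      "continuous", "continuous", "continuous", "continuous", "continuous",
      "continuous", "continuous", "integer", "continuous", "continuous",
      "continuous", "continuous", "continuous", "continuous", "categorical",
      "continuous", "continuous", "continuous", "continuous", "continuous",
      "continuous", "continuous", "continuous", "continuous", "continuous",
      "continuous", "continuous", "continuous"
    ),
    description = c(
      "Patient age", "Patient sex", "Other existing diseases",
      "Coronary artery disease", "Underactive thyroid",
      "Elevated blood fats", "Diabetes mellitus", "Height",
      "Weight", "Body mass index",
      "Total body water", "Extracellular water", "Intracellular water",
      "Extracellular fluid / total body water ratio", "Total body fat ratio",
      "Lean mass", "Body protein content", "Visceral fat rating",
      "Bone mass", "Muscle mass",
      "Obesity level", "Total fat content", "Visceral fat area",
      "Visceral muscle area", "Hepatic fat accumulation",
      "Blood glucose", "Total cholesterol", "Low density lipoprotein",
      "High density lipoprotein", "Triglyceride",
      "Aspartate aminotransferase", "Alanine aminotransferase",
      "Alkaline phosphatase", "Creatinine", "Glomerular filtration rate",
      "C-reactive protein", "Hemoglobin", "Vitamin D"
    ),
    stringsAsFactors = FALSE
  )
  sch
}

#' Construct a validated clinical dataset
#'
#' Bundles a numeric feature table and a binary target into the container
#' the rest of the package operates on. The target codes follow the
#' gallstone convention: 0 = disease present, 1 = absent. No missing values
#' are tolerated anywhere.
#'
#' @param X numeric matrix or data.frame, one column per schema feature.
#' @param y integer vector of 0/1 labels, one per row of `X`.
#' @param schema feature schema data.frame as returned by
#'   [gallstone_schema()]; may describe fewer features for toy data, as long
#'   as it matches `ncol(X)`.
#' @return An object of class `gs_dataset`: a list with elements `X`
#'   (numeric matrix with feature names as column names), `y` (integer
#'   vector) and `schema`.
#' @export
gs_dataset <- function(X, y, schema = gallstone_schema()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) == 0L) stop("dataset is empty (0 rows)")
  if (ncol(X) != nrow(schema)) {
    stop(sprintf("X has %d columns but the schema describes %d features",
                 ncol(X), nrow(schema)))
  }
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing/non-numeric value at row %d, column '%s'",
                 bad[1L], schema$name[bad[2L]]))
  }
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (anyNA(y) || !all(y %in% c(0L, 1L))) {
    stop("y must contain only 0/1 labels with no missing values")
  }
  colnames(X) <- schema$name
  structure(list(X = X, y = y, schema = schema), class = "gs_dataset")
}

#' @export
print.gs_dataset <- function(x, ...) {
  cat(sprintf("<gs_dataset> %d samples x %d features\n",
              nrow(x$X), ncol(x$X)))
  tab <- table(factor(x$y, levels = c(0, 1)))
  cat(sprintf("  class counts: 0 (present) = %d, 1 (absent) = %d\n",
              tab[["0"]], tab[["1"]]))
  invisible(x)
}

#' @export
dim.gs_dataset <- function(x) dim(x$X)

#' Load a clinical CSV into a validated dataset
#'
#' Reads a comma-separated, headered, UTF-8 table whose columns are the
#' schema's feature names plus a binary target column, validates it (no
#' missing or non-numeric cells, target strictly 0/1), and reports the row
#' and class counts.
#'
#' @param path path to the CSV file.
#' @param schema feature schema; defaults to [gallstone_schema()].
#' @param target name of the target column (default `"Gallstone Status"`).
#' @param quiet suppress the class-count log line.
#' @return A [gs_dataset()].
#' @export
load_gallstone_csv <- function(path, schema = gallstone_schema(),
                               target = "Gallstone Status", quiet = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c(schema$name, target), names(df))
  if (length(missing_cols)) {
    stop(sprintf("schema error: missing column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0L) stop("validation error: file has a header but no rows")
  Xdf <- df[, schema$name, drop = FALSE]
  for (j in seq_along(Xdf)) {
    v <- Xdf[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) {
        stop(sprintf("validation error: non-numeric cell at row %d, column '%s'",
                     bad[1L], schema$name[j]))
      }
      v <- vn
    }
    if (anyNA(v)) {
      stop(sprintf("validation error: missing cell at row %d, column '%s'",
                   which(is.na(v))[1L], schema$name[j]))
    }
    Xdf[[j]] <- v
  }
  ds <- gs_dataset(Xdf, df[[target]], schema)
  if (!quiet) {
    tab <- table(factor(ds$y, levels = c(0, 1)))
    message(sprintf("loaded %d rows; class counts: 0 = %d, 1 = %d",
                    nrow(ds$X), tab[["0"]], tab[["1"]]))
  }
  ds
}

#' Write a dataset back to CSV
#'
#' Inverse of [load_gallstone_csv()]: the written file round-trips to an
#' identical dataset.
#'
#' @param ds a [gs_dataset()].
#' @param path output path.
#' @param target target column name.
#' @return `path`, invisibly.
#' @export
write_gallstone_csv <- function(ds, path, target = "Gallstone Status") {
  stopifnot(inherits(ds, "gs_dataset"))
  out <- as.data.frame(ds$X, check.names = FALSE)
  out[[target]] <- ds$y
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Repeated stratified shuffled train/test splits
#'
#' Builds `n_splits` independent shuffled splits of the rows into a training
#' fraction and a held-out test remainder. The reference evaluation protocol
#' for this package is 10 repeated 70/30 splits of 319 records, giving 224
#' training and 95 test samples per split (the train size is
#' `ceiling(n * train_fraction)`). Splits are stratified by label so each
#' split's class ratio matches the whole set to within one sample, and are a
#' pure function of the dataset's row order and the seed.
#'
#' @param ds a [gs_dataset()], or a bare 0/1 label vector.
#' @param n_splits number of independent splits (default 10).
#' @param train_fraction fraction of rows used for training (default 0.7).
#' @param seed integer RNG seed.
#' @return An object of class `gs_splits`: a list of `n_splits` elements,
#'   each a list with integer row indices `train` and `test`.
#' @export
make_splits <- function(ds, n_splits = 10L, train_fraction = 0.7, seed = 1L) {
  y <- if (inherits(ds, "gs_dataset")) ds$y else as.integer(ds)
  n <- length(y)
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("train_fraction must be strictly between 0 and 1")
  }
  if (n_splits < 1L) stop("n_splits must be >= 1")
  n_train <- as.integer(ceiling(n * train_fraction))
  if (n_train <= 0L || n_train >= n) {
    stop("parameter error: train set size rounds to 0 or n")
  }
  classes <- sort(unique(y))
  # per-class train counts: floor each class target, then hand out the
  # remainder by largest fractional part (keeps ratios within +/- 1 sample)
  n_c <- vapply(classes, function(cl) sum(y == cl), integer(1))
  tgt <- n_c * n_train / n
  take <- floor(tgt)
  rem <- n_train - sum(take)
  if (rem > 0) {
    ord <- order(tgt - take, decreasing = TRUE)
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1
  }
  # pure function of (row order, seed): seed a local stream and restore the
  # caller's RNG state on exit
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  splits <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    train <- integer(0)
    for (ci in seq_along(classes)) {
      rows <- which(y == classes[ci])
      train <- c(train, sample(rows, take[ci]))
    }
    train <- sort(train)
    splits[[s]] <- list(train = train, test = setdiff(seq_len(n), train))
  }
  structure(splits, class = "gs_splits",
            n = n, seed = seed, train_fraction = train_fraction)
}

#' @export
print.gs_splits <- function(x, ...) {
  cat(sprintf("<gs_splits> %d splits of %d rows (train %d / test %d), seed %d\n",
              length(x), attr(x, "n"), length(x[[1]]$train),
              length(x[[1]]$test), attr(x, "seed")))
  invisible(x)
}

#' Write a split plan as a JSON manifest
#'
#' @param splits a `gs_splits` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(splits, path) {
  stopifnot(inherits(splits, "gs_splits"))
  jsonlite::write_json(
    lapply(unclass(splits), function(s) list(train = s$train, test = s$test)),
    path, auto_unbox = FALSE)
  invisible(path)
}
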