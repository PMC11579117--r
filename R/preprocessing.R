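# The feature pipeline: load -> merge transgenic lines -> drop incomplete
# rows -> stratified split -> z-score with train statistics. The order is
# fixed; the pipeline driver rejects reordering (normalizing before dropping
# incomplete rows would leak NaNs into the statistics).

.META_COLS <- c("sample_id", "organism", "broad_label", "line_tag",
                "subclass_label")

#' Read a per-neuron feature table from CSV
#'
#' Expects one row per neuron with numeric feature columns plus an `organism`
#' column; `sample_id`, `broad_label`, `line_tag` and `subclass_label` are
#' used when present. Empty cells and unparseable numerics become missing
#' values (rows are retained). Row and missing-cell counts are reported via
#' `message()`.
#'
#' @param path CSV file (UTF-8, comma separated, header row).
#' @param schema optional character vector naming the feature columns; by
#'   default, columns named `f00`, `f01`, ... are used, falling back to all
#'   non-annotation numeric columns.
#' @return an [EphysSet-class].
#' @export
loadFeatureTable <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  dt <- data.table::fread(path, na.strings = c("", "NA", "NaN"),
                          data.table = FALSE, encoding = "UTF-8")
  if (nrow(dt) == 0L) stop("input error: ", path, " contains no data rows")
  if (is.null(schema)) {
    schema <- grep("^f[0-9]+$", colnames(dt), value = TRUE)
    if (!length(schema))
      schema <- setdiff(colnames(dt)[vapply(dt, is.numeric, TRUE)],
                        .META_COLS)
  }
  missingCols <- setdiff(c(schema, "organism"), colnames(dt))
  if (length(missingCols))
    stop("schema error: missing required columns: ",
         paste(missingCols, collapse = ", "))
  X <- as.matrix(dt[, schema, drop = FALSE])
  storage.mode(X) <- "double"
  pick <- function(col, default) if (col %in% colnames(dt)) dt[[col]] else default
  es <- EphysSet(
    X,
    organism = dt$organism,
    broadLabel = pick("broad_label", NA_integer_),
    lineTag = pick("line_tag", NA_character_),
    subclassLabel = pick("subclass_label", NA_character_),
    sampleIds = as.character(pick("sample_id", sprintf("s%05d", seq_len(nrow(dt))))))
  message(sprintf("loaded %d rows, %d features, %d missing cells",
                  nrow(X), ncol(X), sum(is.na(X))))
  es
}

#' Write a feature table to CSV
#'
#' @param table an [EphysSet-class].
#' @param path destination; missing values are written as empty cells.
#' @return invisibly, `path`.
#' @export
writeFeatureTable <- function(table, path) {
  X <- featureMatrix(table)
  df <- data.frame(sample_id = colnames(table), X,
                   organism = organismLabel(table),
                   broad_label = broadLabel(table),
                   line_tag = lineTag(table),
                   subclass_label = subclassLabel(table),
                   check.names = FALSE)
  data.table::fwrite(df, path, na = "", quote = "auto")
  invisible(path)
}

#' Merge transgenic lines into subclasses
#'
#' Assigns `subclass_label` from each row's `line_tag` using a user-supplied
#' map; rows mapped to `"exclude"` are removed (their count is stored in
#' `metadata(result)$linesExcluded`). Any tag present in the table but absent
#' from the map is an error - there is no silent drop.
#'
#' @param table an [EphysSet-class] with `line_tag` set.
#' @param map named character vector or list: line tag -> subclass name or
#'   `"exclude"`.
#' @return the relabelled [EphysSet-class].
#' @export
mergeLines <- function(table, map) {
  map <- unlist(map)
  tags <- lineTag(table)
  unmapped <- setdiff(unique(tags[!is.na(tags)]), names(map))
  if (length(unmapped))
    stop("line-merge error: unmapped line tag(s): ",
         paste(unmapped, collapse = ", "))
  target <- unname(map[tags])
  keep <- is.na(target) | target != "exclude"
  nExcluded <- sum(!keep)
  out <- table[, keep]
  colData(out)$subclass_label <- ifelse(is.na(target[keep]),
                                        colData(out)$subclass_label,
                                        target[keep])
  validObject(out)
  metadata(out)$linesExcluded <- nExcluded
  message(sprintf("merged lines: %d rows excluded, %d retained",
                  nExcluded, ncol(out)))
  out
}

#' Drop rows with missing feature values
#'
#' @param table an [EphysSet-class].
#' @return list with `table` (complete rows only) and `nDropped`.
#' @export
dropIncomplete <- function(table) {
  X <- featureMatrix(table)
  keep <- rowSums(is.na(X)) == 0L
  if (!any(keep))
    stop("all rows contain missing values; pipeline cannot proceed")
  nDropped <- sum(!keep)
  out <- table[, keep]
  metadata(out)$nDropped <- nDropped
  message(sprintf("dropped %d incomplete rows, %d retained",
                  nDropped, sum(keep)))
  list(table = out, nDropped = nDropped)
}

#' Stratified train/validation/test split
#'
#' Partitions the table with a seeded, stratified largest-remainder
#' allocation: within every stratum the requested fractions are honoured to
#' within one row, so overall partition sizes match the fractions to within
#' rounding. With the study's 1723-row composition, fractions
#' `c(0.6797, 0.1201, 0.2002)` stratified on organism x broad label give the
#' published 1171 / 207 / 345 partition.
#'
#' @param table an [EphysSet-class].
#' @param fractions length-3 positive numeric summing to 1
#'   (train, validation, test).
#' @param stratifyOn subset of `c("organism", "broad_label",
#'   "subclass_label")`.
#' @param seed integer seed.
#' @return an un-normalized [EphysSplit-class].
#' @export
splitData <- function(table, fractions = c(0.6797, 0.1201, 0.2002),
                      stratifyOn = c("organism", "broad_label"),
                      seed = 1L) {
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three non-negative numbers summing to 1")
  bad <- setdiff(stratifyOn, c("organism", "broad_label", "subclass_label"))
  if (length(bad))
    stop("unknown stratification column(s): ", paste(bad, collapse = ", "))
  n <- ncol(table)
  cd <- as.data.frame(colData(table))
  strata <- if (length(stratifyOn))
    interaction(cd[stratifyOn], drop = TRUE, sep = ":")
  else factor(rep("all", n))
  set.seed(as.integer(seed))
  part <- integer(n)  # 1 train, 2 validation, 3 test
  for (s in levels(strata)) {
    rows <- which(strata == s)
    ns <- length(rows)
    if (ns < sum(fractions > 0))
      warning("stratum '", s, "' has fewer rows (", ns,
              ") than partitions; best-effort assignment")
    target <- ns * fractions
    sizes <- floor(target)
    rem <- target - sizes
    short <- ns - sum(sizes)
    if (short > 0) {
      extra <- order(rem, decreasing = TRUE)[seq_len(short)]
      sizes[extra] <- sizes[extra] + 1L
    }
    rows <- sample(rows)
    part[rows] <- rep.int(1:3, sizes)
  }
  new("EphysSplit",
      train = table[, part == 1L],
      validation = table[, part == 2L],
      test = table[, part == 3L],
      center = numeric(), scale = numeric(), normalized = FALSE,
      fractions = fractions, stratifyOn = as.character(stratifyOn),
      seed = as.integer(seed))
}

#' Z-score a split using train-partition statistics
#'
#' Per-feature mean and sd are fit on the train partition only and applied
#' unchanged to validation and test (no information leakage). Zero-variance
#' features pass through unscaled with a warning.
#'
#' @param split an [EphysSplit-class] with no missing values.
#' @return the normalized [EphysSplit-class] carrying `center` and `scale`.
#' @export
normalizeSplit <- function(split) {
  Xtr <- featureMatrix(split@train)
  if (nrow(Xtr) == 0L) stop("normalize error: empty train partition")
  if (anyNA(Xtr)) stop("normalize error: missing values present; run dropIncomplete first")
  center <- colMeans(Xtr)
  scl <- apply(Xtr, 2L, stats::sd)
  zeroVar <- !is.finite(scl) | scl < 1e-12
  if (any(zeroVar)) {
    warning("zero-variance feature(s) pass through unscaled: ",
            paste(colnames(Xtr)[zeroVar], collapse = ", "))
    scl[zeroVar] <- 1
    center[zeroVar] <- 0
  }
  zap <- function(es) {
    X <- featureMatrix(es)
    if (nrow(X))
      assay(es, "features") <- t(sweep(sweep(X, 2L, center, "-"),
                                       2L, scl, "/"))
    es
  }
  split@train <- zap(split@train)
  split@validation <- zap(split@validation)
  split@test <- zap(split@test)
  split@center <- center
  split@scale <- scl
  split@normalized <- TRUE
  split
}
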