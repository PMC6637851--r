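# Activity tables: Ki -> pKi conversion, CSV IO, and the stratified
# train/test split used before QSAR modelling.

#' Convert an inhibition constant to pKi
#'
#' `pKi = -log10(Ki * 1e-6)` with Ki given in micromolar, i.e. the
#' negative decadic logarithm of Ki in molar units.
#'
#' @param ki Inhibition constant(s) in uM; must be positive and finite.
#' @return pKi value(s), dimensionless.
#' @examples
#' ki_to_pki(0.00069)  # 9.16
#' ki_to_pki(1)        # 6
#' @export
ki_to_pki <- function(ki) {
  if (!is.numeric(ki) || any(!is.finite(ki)) || any(ki <= 0))
    stop("ki must be positive and finite (uM)")
  -log10(ki * 1e-6)
}

#' Build an activity table
#'
#' @param id Compound identifiers.
#' @param pki pKi values; if missing, computed from `ki_uM`.
#' @param ki_uM Optional Ki in uM.
#' @param split Optional labels in `train`, `test`, `unassigned`.
#' @return `data.frame` of class `activity_table` with columns
#'   `id`, `ki_uM`, `pKi`, `split`.
#' @export
activity_table <- function(id, pki = NULL, ki_uM = NULL, split = NULL) {
  id <- as.character(id)
  if (is.null(pki)) {
    if (is.null(ki_uM)) stop("supply pki or ki_uM")
    pki <- ki_to_pki(ki_uM)
  }
  if (is.null(ki_uM)) ki_uM <- NA_real_
  if (is.null(split)) split <- "unassigned"
  split <- as.character(split)
  if (!all(split %in% c("train", "test", "unassigned")))
    stop("split labels must be train, test or unassigned")
  if (any(!is.finite(pki))) stop("pKi must be finite")
  both <- is.finite(ki_uM)
  if (any(both) && any(abs(pki[both] - ki_to_pki(ki_uM[both])) > 1e-6))
    stop("inconsistent Ki and pKi: pKi must equal -log10(Ki * 1e-6)")
  structure(data.frame(id = id, ki_uM = ki_uM, pKi = pki, split = split,
                       stringsAsFactors = FALSE),
            class = c("activity_table", "data.frame"))
}

#' Read an activity table from CSV
#'
#' Expects header columns `id` and at least one of `ki_uM`, `pKi`;
#' optional `split`.
#' @param path CSV path.
#' @return An [activity_table()].
#' @export
read_activity_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop("activity CSV needs an 'id' column")
  activity_table(id = df$id,
                 pki = if ("pKi" %in% names(df)) df$pKi else NULL,
                 ki_uM = if ("ki_uM" %in% names(df)) df$ki_uM else NULL,
                 split = if ("split" %in% names(df)) df$split else NULL)
}

#' Write an activity table to CSV
#' @param table An [activity_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_activity_table <- function(table, path) {
  stopifnot(inherits(table, "activity_table"))
  out <- as.data.frame(table)
  out$pKi <- formatC(out$pKi, digits = 6, format = "f")
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Stratified train/test split
#'
#' Draws `n_test` test compounds so that the test set covers the whole
#' activity range: rows are ranked by pKi, partitioned into `n_test`
#' equal-rank bins, and one test row is drawn per bin with the seeded
#' generator.  This enforces the homogeneous activity distribution a
#' QSAR external set needs.
#'
#' @param table An [activity_table()].
#' @param n_test Number of test rows, `0 <= n_test < nrow(table)`.
#' @param seed Integer seed; fixed seed gives identical labels.
#' @return The table with `split` set to `train`/`test`.
#' @export
split_dataset <- function(table, n_test, seed = 1L) {
  stopifnot(inherits(table, "activity_table"))
  n <- nrow(table)
  if (n_test < 0 || n_test >= n)
    stop("n_test must satisfy 0 <= n_test < ", n)
  table$split <- "train"
  if (n_test == 0) return(table)
  ord <- order(table$pKi, table$id)   # id breaks pKi ties deterministically
  bins <- split(ord, cut(seq_len(n), breaks = n_test, labels = FALSE))
  picks <- with_seed(seed, vapply(bins, function(b) {
    b[sample.int(length(b), 1L)]
  }, integer(1)))
  table$split[picks] <- "test"
  table
}

# Run code with a private RNG stream, restoring .Random.seed afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(as.integer(seed))
  expr
}

#' Packaged sigma-1 receptor ligand activity table
#'
#' Loads the shipped fixture of 80 arylalkylamine sigma-1 receptor
#' ligands: experimental pKi, the pKi predicted by the two-field
#' steric+electrostatic PLS model, and the 64/16 train/test membership.
#'
#' @return `data.frame` with columns `id`, `pKi_exp`, `pKi_pred`, `split`.
#' @export
s1r_activity_table <- function() {
  path <- system.file("extdata", "s1r_pki_series.csv", package = "fieldsar",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
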