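#' Construct a validated multi-environment trial table
#'
#' A `met_table` is the single input currency of the package: a long-format
#' data frame with one row per genotype x environment x block x trait plot
#' value. Labels are treated as opaque strings; their order of first
#' appearance is preserved and used as the default ordering of all derived
#' matrices.
#'
#' @param data a data frame containing the mapped columns.
#' @param cols named character vector mapping the canonical names
#'   `genotype`, `environment`, `block`, `trait`, `value` to the column names
#'   present in `data`.
#' @return a data frame of class `met_table` with canonical column names
#'   `genotype`, `environment`, `block`, `trait`, `value`.
#' @details Validation enforces: all mapped columns present, numeric finite
#'   values, and no duplicated (genotype, environment, block, trait) key.
#' @examples
#' df <- expand.grid(genotype = c("G1", "G2"), environment = c("E1", "E2"),
#'                   block = c("B1", "B2"))
#' df$trait <- "FRY"
#' df$value <- rnorm(nrow(df), 25, 5)
#' met <- as_met_table(df)
#' @export
as_met_table <- function(data, cols = c(genotype = "genotype",
                                        environment = "environment",
                                        block = "block",
                                        trait = "trait",
                                        value = "value")) {
  canonical <- c("genotype", "environment", "block", "trait", "value")
  cols <- cols[canonical]
  if (anyNA(cols)) {
    stop("`cols` must map all of: ", paste(canonical, collapse = ", "))
  }
  missing_cols <- setdiff(unname(cols), names(data))
  if (length(missing_cols)) {
    stop("input is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    genotype = as.character(data[[cols[["genotype"]]]]),
    environment = as.character(data[[cols[["environment"]]]]),
    block = as.character(data[[cols[["block"]]]]),
    trait = as.character(data[[cols[["trait"]]]]),
    value = data[[cols[["value"]]]],
    stringsAsFactors = FALSE
  )
  if (!is.numeric(out$value)) {
    bad <- suppressWarnings(as.numeric(out$value))
    rows <- which(is.na(bad) & !is.na(out$value))
    if (length(rows)) {
      stop("non-numeric value(s) at row(s): ",
           paste(utils::head(rows, 5L), collapse = ", "))
    }
    out$value <- bad
  }
  if (any(!is.finite(out$value))) {
    stop("non-finite value(s) at row(s): ",
         paste(utils::head(which(!is.finite(out$value)), 5L), collapse = ", "))
  }
  key <- paste(out$genotype, out$environment, out$block, out$trait, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    stop("duplicate (genotype, environment, block, trait) key(s): ",
         paste(utils::head(gsub("\r", "/", unique(dup)), 5L), collapse = "; "))
  }
  if (nrow(out) == 0L) stop("table has no records")
  class(out) <- c("met_table", "data.frame")
  out
}

#' Read a long-format MET table from CSV
#'
#' @param path path to an RFC-4180 CSV file with a header row.
#' @param cols column-name mapping as in [as_met_table()].
#' @return a `met_table`.
#' @export
read_met_table <- function(path, cols = c(genotype = "genotype",
                                          environment = "environment",
                                          block = "block",
                                          trait = "trait",
                                          value = "value")) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_met_table(raw, cols = cols)
}

#' Read a wide genotype-by-environment matrix as a MET table
#'
#' Accepts a CSV whose first column holds genotype labels and whose remaining
#' columns are environments; each cell is taken as a single-replicate plot
#' value (`reps_per_cell = 1` downstream).
#'
#' @param path path to the CSV file.
#' @param trait trait label to attach to every record.
#' @return a `met_table` with a single block `"B1"`.
#' @export
read_met_wide <- function(path, trait = "trait") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(raw) < 2L) stop("wide matrix needs a genotype column plus environments")
  envs <- names(raw)[-1L]
  long <- data.frame(
    genotype = rep(as.character(raw[[1L]]), times = length(envs)),
    environment = rep(envs, each = nrow(raw)),
    block = "B1",
    trait = trait,
    value = unlist(raw[-1L], use.names = FALSE),
    stringsAsFactors = FALSE
  )
  as_met_table(long)
}

#' Write a MET table to CSV
#'
#' @param met a `met_table`.
#' @param path destination path; a UTF-8 CSV with header is written.
#' @return `path`, invisibly.
#' @export
write_met_table <- function(met, path) {
  stopifnot(inherits(met, "met_table"))
  utils::write.csv(as.data.frame(met), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Genotype-by-environment cell means
#'
#' Averages plot values over blocks to the genotype x environment table of
#' phenotypic means that feeds every multiplicative decomposition and
#' stability index.
#'
#' @param met a `met_table`.
#' @param trait trait label to extract.
#' @return an object of class `cell_means`: a list with `means` (g x e matrix
#'   with dimnames), `genotypes`, `environments`, and `reps_per_cell` (the
#'   common replicate count, or `NA` when the design is unbalanced).
#' @export
cell_means <- function(met, trait) {
  stopifnot(inherits(met, "met_table"))
  sub <- met[met$trait == trait, , drop = FALSE]
  if (nrow(sub) == 0L) stop("trait not present: ", trait)
  gens <- unique(sub$genotype)
  envs <- unique(sub$environment)
  gf <- factor(sub$genotype, levels = gens)
  ef <- factor(sub$environment, levels = envs)
  counts <- table(gf, ef)
  if (any(counts == 0L)) {
    empty <- which(counts == 0L, arr.ind = TRUE)
    lab <- paste(gens[empty[, 1L]], envs[empty[, 2L]], sep = "/")
    stop("empty genotype/environment cell(s): ",
         paste(utils::head(lab, 5L), collapse = ", "))
  }
  m <- tapply(sub$value, list(gf, ef), mean)
  reps <- if (length(unique(c(counts))) == 1L) c(counts)[1L] else NA_integer_
  structure(list(means = unclass(m), genotypes = gens, environments = envs,
                 reps_per_cell = as.integer(reps)),
            class = "cell_means")
}

#' Build a `cell_means` object directly from a matrix
#'
#' @param m a numeric genotype x environment matrix (dimnames optional).
#' @param reps_per_cell replicate count behind each cell mean.
#' @return a `cell_means` object.
#' @export
as_cell_means <- function(m, reps_per_cell = 1L) {
  m <- as.matrix(m)
  if (!is.numeric(m) || any(!is.finite(m))) stop("matrix must be finite numeric")
  if (is.null(rownames(m))) rownames(m) <- paste0("G", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("E", seq_len(ncol(m)))
  structure(list(means = m, genotypes = rownames(m),
                 environments = colnames(m),
                 reps_per_cell = as.integer(reps_per_cell)),
            class = "cell_means")
}

#' @export
print.cell_means <- function(x, ...) {
  cat("Cell-means matrix:", length(x$genotypes), "genotypes x",
      length(x$environments), "environments",
      if (!is.na(x$reps_per_cell)) paste0("(r = ", x$reps_per_cell, ")"),
      "\n")
  print(round(x$means, 3), ...)
  invisible(x)
}

#' Check replication balance of a MET table
#'
#' @param met a `met_table`.
#' @param trait trait label.
#' @return a list with `is_balanced`, `reps_per_cell` (common count or `NA`),
#'   `missing_cells` (data frame of genotype/environment pairs with no
#'   record), and `cell_counts` (g x e integer matrix).
#' @export
validate_balance <- function(met, trait) {
  stopifnot(inherits(met, "met_table"))
  sub <- met[met$trait == trait, , drop = FALSE]
  gens <- unique(met$genotype)
  envs <- unique(met$environment)
  gf <- factor(sub$genotype, levels = gens)
  ef <- factor(sub$environment, levels = envs)
  counts <- table(gf, ef)
  counts <- matrix(as.integer(counts), nrow = length(gens),
                   dimnames = list(gens, envs))
  empty <- which(counts == 0L, arr.ind = TRUE)
  missing_cells <- data.frame(
    genotype = gens[empty[, 1L]],
    environment = envs[empty[, 2L]],
    stringsAsFactors = FALSE
  )
  uniq <- unique(c(counts))
  balanced <- length(uniq) == 1L && uniq[1L] > 0L
  list(
    is_balanced = balanced,
    reps_per_cell = if (balanced) uniq[1L] else NA_integer_,
    missing_cells = missing_cells,
    cell_counts = counts
  )
}
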