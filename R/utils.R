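# Internal helpers.

# Evaluate `code` under a given RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Write a periods-by-positions matrix as TSV
#'
#' Header row carries the position axis; the first column carries the
#' period axis.
#'
#' @param mat Numeric (or logical) matrix, rows = periods.
#' @param periods,positions Axis values.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, periods, positions, path) {
  df <- data.frame(period = periods, mat + 0, check.names = FALSE)
  names(df) <- c("period", paste0("pos", positions))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#' @param path File path.
#' @return List with `periods`, `positions`, `mat`.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  periods <- df[[1]]
  mat <- as.matrix(df[, -1, drop = FALSE])
  positions <- as.integer(sub("^pos", "", colnames(mat)))
  dimnames(mat) <- NULL
  list(periods = periods, positions = positions, mat = mat)
}

# key = value config files; '#' comments allowed.
read_config_file <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    out[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
  }
  out
}
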